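#' Build an indexable structure record
#'
#' Runs the whole encoding pipeline for one structure: for a
#' [BackboneChain-class], torsions are computed, secondary structure is
#' taken from a DSSP code map when supplied (otherwise the torsion-window
#' heuristic), residues are mapped to descriptors, shingled, hashed and
#' run-position encoded, and a min-hash signature is drawn; the CA trace
#' and per-residue codes are kept for alignment. A
#' [DescriptorSequence-class] may be supplied instead to index an encoding
#' directly (no coordinates stored).
#'
#' @param x a [BackboneChain-class] or [DescriptorSequence-class].
#' @param id structure identifier; defaults to the input's label.
#' @param params [LSHParams-class] fixing the signature seed set.
#' @param regions [RegionMap-class] for descriptor assignment.
#' @param dssp optional named code vector from [readDssp()].
#' @param metadata named list of tags available to search filters.
#' @param shingleRuns passed to [bagOf()].
#' @return A [StructureRecord-class].
#' @export
makeStructureRecord <- function(x, id = NULL, params = lshParams(),
                                regions = defaultRegionMap(), dssp = NULL,
                                metadata = list(), shingleRuns = FALSE) {
  if (is(x, "BackboneChain")) {
    if (is.null(id)) id <- x@chainId
    geom <- computeTorsions(x)
    geom <- if (is.null(dssp)) assignSSHeuristic(geom) else {
      applyDssp(assignSSHeuristic(geom), dssp, chainId = x@chainId)
    }
    dseq <- encodeStructure(geom, regions, id = id)
    ca <- x@ca
    ss <- paste(geom$ss, collapse = "")
    nres <- length(x@resno)
  } else if (is(x, "DescriptorSequence")) {
    if (is.null(id)) id <- x@id
    dseq <- descriptorSequence(x@descriptors, id = id)
    ca <- matrix(numeric(0), 0, 3)
    ss <- ""
    nres <- length(dseq@descriptors)
  } else {
    stop("x must be a BackboneChain or DescriptorSequence")
  }
  bag <- bagOf(dseq, shingleRuns = shingleRuns)
  sig <- minhashSignature(bag, params)
  new("StructureRecord", id = id, descriptors = dseq, bag = bag,
      signature = sig, nResidues = as.integer(nres), ca = ca, ss = ss,
      metadata = metadata)
}

.emptyBandTables <- function(params) {
  replicate(params@bands, structure(list(), names = character(0)),
            simplify = FALSE)
}

#' Create an empty structure index
#'
#' @param params [LSHParams-class] the index will operate under.
#' @return An empty [StructureIndex-class].
#' @export
structureIndex <- function(params = lshParams()) {
  new("StructureIndex", params = params, records = list(),
      bandTables = .emptyBandTables(params),
      sigMatrix = matrix(integer(0), params@numHashes, 0))
}

#' Add one structure to an index
#'
#' Stores the record and inserts its band hashes into all band tables.
#' For bulk construction prefer [buildIndex()].
#'
#' @param index a [StructureIndex-class].
#' @param record a [StructureRecord-class] built under the index seed set.
#' @return The updated index.
#' @export
addStructure <- function(index, record) {
  stopifnot(is(index, "StructureIndex"), is(record, "StructureRecord"))
  if (record@id %in% names(index@records)) {
    stop(sprintf("structure id '%s' already indexed", record@id))
  }
  if (record@signature@seed != index@params@seed) {
    stop("record signature uses a different seed set than the index")
  }
  bh <- bandHashes(record@signature, index@params)
  bt <- index@bandTables
  for (b in seq_along(bt)) {
    key <- as.character(bh[b])
    bt[[b]][[key]] <- c(bt[[b]][[key]], record@id)
  }
  index@records[[record@id]] <- record
  index@bandTables <- bt
  index@sigMatrix <- cbind(index@sigMatrix, record@signature@hashes)
  colnames(index@sigMatrix) <- names(index@records)
  validObject(index)
  index
}

#' Build an index from a list of records
#'
#' @param records list of [StructureRecord-class] objects with distinct
#'   ids, all built under `params`.
#' @param params [LSHParams-class].
#' @return A populated [StructureIndex-class].
#' @export
buildIndex <- function(records, params = lshParams()) {
  ids <- vapply(records, structureId, character(1))
  if (anyDuplicated(ids)) stop("duplicate structure ids in records")
  seeds <- vapply(records, function(r) r@signature@seed, integer(1))
  if (any(seeds != params@seed)) {
    stop("some records use a different seed set than the index")
  }
  sig <- vapply(records, function(r) r@signature@hashes,
                integer(params@numHashes))
  sig <- matrix(sig, nrow = params@numHashes,
                dimnames = list(NULL, ids))
  bh <- vapply(records, function(r) bandHashes(r@signature, params),
               integer(params@bands))
  bt <- lapply(seq_len(params@bands), function(b) {
    sp <- split(ids, as.character(bh[b, ]))
    lapply(sp, unname)
  })
  names(records) <- ids
  new("StructureIndex", params = params, records = records,
      bandTables = bt, sigMatrix = sig)
}

#' Retrieve an indexed record
#'
#' @param index a [StructureIndex-class].
#' @param id structure identifier.
#' @return The [StructureRecord-class]; error when absent.
#' @export
getRecord <- function(index, id) {
  r <- index@records[[id]]
  if (is.null(r)) stop(sprintf("structure id '%s' not in index", id))
  r
}

#' @rdname getRecord
#' @export
indexIds <- function(index) names(index@records)

#' Candidate structures by single-band match
#'
#' Probes all band tables with the query's band hashes and returns the
#' union of structure ids sharing at least one band hash. The probes are
#' independent per band (parallelizable); the result equals the sequential
#' union. An optional metadata predicate restricts (never extends) the set.
#'
#' @param index a [StructureIndex-class].
#' @param query a [MinHashSignature-class] or [StructureRecord-class]
#'   under the index seed set.
#' @param filter optional predicate `function(metadata) -> logical` applied
#'   to each candidate's metadata tags.
#' @return Sorted character vector of candidate ids.
#' @export
candidates <- function(index, query, filter = NULL) {
  sig <- if (is(query, "StructureRecord")) query@signature else query
  stopifnot(is(sig, "MinHashSignature"))
  if (sig@seed != index@params@seed) {
    stop("query signature uses a different seed set than the index")
  }
  bh <- bandHashes(sig, index@params)
  ids <- unique(unlist(lapply(seq_along(bh), function(b) {
    index@bandTables[[b]][[as.character(bh[b])]]
  }), use.names = FALSE))
  if (is.null(ids)) ids <- character(0)
  if (!is.null(filter) && length(ids)) {
    keep <- vapply(ids, function(id) {
      isTRUE(filter(index@records[[id]]@metadata))
    }, logical(1))
    ids <- ids[keep]
  }
  sort(ids)
}

.INDEX_FORMAT <- "rupee-index"
.INDEX_VERSION <- 1L

#' Persist and restore a structure index
#'
#' The index is written as a single versioned archive with an explicit
#' header (format tag, version, LSH parameters including the hash seed
#' set); loading verifies the header and reproduces records, band tables
#' and signatures exactly.
#'
#' @param index a [StructureIndex-class].
#' @param path file path (conventional extension: `.rpx`).
#' @param params optional [LSHParams-class]; when supplied, the loaded
#'   index must have a compatible seed set and banding layout.
#' @return `saveIndex` returns `path` invisibly; `loadIndex` returns the
#'   [StructureIndex-class].
#' @export
saveIndex <- function(index, path) {
  stopifnot(is(index, "StructureIndex"))
  payload <- list(
    format = .INDEX_FORMAT, version = .INDEX_VERSION,
    params = list(numHashes = index@params@numHashes,
                  bands = index@params@bands,
                  rowsPerBand = index@params@rowsPerBand,
                  targetJaccard = index@params@targetJaccard,
                  seed = index@params@seed),
    records = index@records, bandTables = index@bandTables,
    sigMatrix = index@sigMatrix)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname saveIndex
#' @export
loadIndex <- function(path, params = NULL) {
  payload <- tryCatch(readRDS(path), error = function(e) {
    stop("cannot read index file (corrupt or truncated): ",
         conditionMessage(e), call. = FALSE)
  })
  if (!is.list(payload) || !identical(payload$format, .INDEX_FORMAT)) {
    stop("not a structure index archive")
  }
  if (!identical(payload$version, .INDEX_VERSION)) {
    stop(sprintf("index format version %s not supported (expected %d)",
                 payload$version, .INDEX_VERSION))
  }
  p <- payload$params
  loaded <- lshParams(numHashes = p$numHashes, bands = p$bands,
                      rowsPerBand = p$rowsPerBand,
                      targetJaccard = p$targetJaccard, seed = p$seed)
  if (!is.null(params)) {
    if (params@seed != loaded@seed || params@numHashes != loaded@numHashes ||
        params@bands != loaded@bands) {
      stop(sprintf(
        "index is incompatible: file seed set %d / %d hashes, expected %d / %d",
        loaded@seed, loaded@numHashes, params@seed, params@numHashes))
    }
  }
  new("StructureIndex", params = loaded, records = payload$records,
      bandTables = payload$bandTables, sigMatrix = payload$sigMatrix)
}
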