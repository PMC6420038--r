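#' Construct a descriptor sequence
#'
#' @param descriptors integer vector in 1..12.
#' @param id provenance label.
#' @return A [DescriptorSequence-class].
#' @examples
#' descriptorSequence(c(5, 5, 5, 7), id = "toy")
#' @export
descriptorSequence <- function(descriptors, id = "unnamed") {
  new("DescriptorSequence", descriptors = as.integer(descriptors),
      id = as.character(id))
}

#' @describeIn descriptorSequence extract the integer descriptors.
#' @param x a `DescriptorSequence`.
#' @export
descriptors <- function(x) {
  stopifnot(is(x, "DescriptorSequence"))
  x@descriptors
}

#' Accessors for shingle bags
#'
#' `bagElements()`/`bagCounts()` return the multiset support and
#' multiplicities; `orderedHashes()` the encoded hash sequence in shingle
#' order; `structureId()` the provenance label of a bag, sequence, record
#' or signature.
#'
#' @param x a [ShingleBag-class] (or for `structureId`, any object with an
#'   id slot).
#' @return vectors as described.
#' @export
bagElements <- function(x) { stopifnot(is(x, "ShingleBag")); x@elements }

#' @rdname bagElements
#' @export
bagCounts <- function(x) { stopifnot(is(x, "ShingleBag")); x@counts }

#' @rdname bagElements
#' @export
orderedHashes <- function(x) { stopifnot(is(x, "ShingleBag")); x@ordered }

#' @rdname bagElements
#' @export
structureId <- function(x) x@id

#' @export
setMethod("length", "DescriptorSequence", function(x) length(x@descriptors))

#' @export
setMethod("length", "ShingleBag", function(x) length(x@ordered))

#' @export
setMethod("length", "BackboneChain", function(x) length(x@resno))

#' @export
setMethod("length", "StructureIndex", function(x) length(x@records))

setMethod("show", "DescriptorSequence", function(object) {
  d <- object@descriptors
  cat(sprintf("DescriptorSequence '%s' (%d residues)\n", object@id,
              length(d)))
  cat(" [", paste(utils::head(d, 30), collapse = ","),
      if (length(d) > 30) ",...", "]\n", sep = "")
})

setMethod("show", "ShingleBag", function(object) {
  cat(sprintf("ShingleBag '%s': %d shingles, %d distinct encoded hashes\n",
              object@id, length(object@ordered), length(object@elements)))
  cat(" {", paste(utils::head(formatEncodedHashes(object@ordered), 12),
                  collapse = ","),
      if (length(object@ordered) > 12) ",...", "}\n", sep = "")
})

setMethod("show", "MinHashSignature", function(object) {
  cat(sprintf("MinHashSignature '%s': %d min-hashes (seed set %d)\n",
              object@id, length(object@hashes), object@seed))
})

setMethod("show", "LSHParams", function(object) {
  cat(sprintf(
    "LSHParams: %d min-hashes = %d bands x %d rows (target J = %.2f, seed %d)\n",
    object@numHashes, object@bands, object@rowsPerBand,
    object@targetJaccard, object@seed))
})

setMethod("show", "BackboneChain", function(object) {
  cat(sprintf("BackboneChain '%s': %d residues (%s...%s)\n", object@chainId,
              length(object@resno),
              if (length(object@resno)) object@resid[1] else "",
              if (length(object@resno)) object@resid[length(object@resno)]
              else ""))
})

setMethod("show", "StructureRecord", function(object) {
  cat(sprintf(
    "StructureRecord '%s': %d residues, %d shingles%s\n", object@id,
    object@nResidues, length(object@bag@ordered),
    if (nrow(object@ca) > 0) ", CA trace stored" else ""))
})

setMethod("show", "StructureIndex", function(object) {
  cat(sprintf("StructureIndex: %d structures, %d bands x %d rows (seed %d)\n",
              length(object@records), object@params@bands,
              object@params@rowsPerBand, object@params@seed))
})

setMethod("show", "AlignmentResult", function(object) {
  cat(sprintf(
    "AlignmentResult: TM-score %.4f (%s-normalized), RMSD %.3f A over %d pairs\n",
    object@tmScore, object@normalization, object@rmsd,
    object@alignedLength))
})

setMethod("show", "RegionMap", function(object) {
  cat(sprintf(
    "RegionMap: %d helix, %d strand, %d bend/coil torsion regions\n",
    nrow(object@helix), nrow(object@strand), nrow(object@coil)))
})

setMethod("show", "FixtureSpec", function(object) {
  cat(sprintf(
    "FixtureSpec: %d structures, %d-%d residues, run p=%.2f, seed %d\n",
    object@nStructures, object@lengthRange[1], object@lengthRange[2],
    object@runGeomProb, object@seed))
})

#' LSH parameter constructor
#'
#' @param numHashes signature length.
#' @param bands number of bands; must satisfy `bands * rowsPerBand ==
#'   numHashes`.
#' @param rowsPerBand min-hashes per band.
#' @param targetJaccard nominal similarity threshold (informational).
#' @param seed integer base seed of the hash family.
#' @return An [LSHParams-class].
#' @examples
#' lshParams()
#' @export
lshParams <- function(numHashes = 99L, bands = 33L, rowsPerBand = 3L,
                      targetJaccard = 0.6, seed = 1299721L) {
  new("LSHParams", numHashes = as.integer(numHashes),
      bands = as.integer(bands), rowsPerBand = as.integer(rowsPerBand),
      targetJaccard = targetJaccard, seed = as.integer(seed))
}
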