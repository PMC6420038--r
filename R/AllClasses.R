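#' @import methods
NULL

#' Backbone chain of a protein structure
#'
#' Holds the ordered backbone (N, CA, C and optionally O) coordinates of a
#' single protein chain, the raw material for torsion-angle computation.
#'
#' @slot chainId single chain identifier.
#' @slot resno integer residue numbers (author numbering).
#' @slot insert residue insertion codes ("" when absent).
#' @slot resid three-letter residue codes.
#' @slot n,ca,c numeric matrices (residues x 3) of atom coordinates in
#'   Angstroms; must be finite.
#' @slot o like `n` but optional: rows may be `NA` when the carbonyl oxygen
#'   is missing.
#'
#' @exportClass BackboneChain
setClass("BackboneChain",
  representation(
    chainId = "character",
    resno = "integer",
    insert = "character",
    resid = "character",
    n = "matrix",
    ca = "matrix",
    c = "matrix",
    o = "matrix"
  )
)

setValidity("BackboneChain", function(object) {
  nres <- length(object@resno)
  for (nm in c("n", "ca", "c")) {
    m <- slot(object, nm)
    if (!is.numeric(m) || nrow(m) != nres || ncol(m) != 3) {
      return(sprintf("slot '%s' must be a numeric %d x 3 matrix", nm, nres))
    }
    if (any(!is.finite(m))) {
      return(sprintf("slot '%s' contains non-finite coordinates", nm))
    }
  }
  if (length(object@resid) != nres || length(object@insert) != nres) {
    return("resid/insert length must match resno")
  }
  TRUE
})

#' Torsion-angle region map
#'
#' Maps DSSP secondary-structure groups and backbone (phi, psi) torsion
#' angles to integer residue descriptors 1..12. Each of the three torsion
#' groups (helix G/H/I, strand E, bend/coil S/C) carries a priority-ordered
#' list of axis-aligned angular boxes; the first box containing a point wins
#' and the last box of each group is an absorbing default, so the groups
#' always cover the full torus. Turns ('T') and bridges ('B') map directly
#' to descriptors 11 and 12 and carry no regions.
#'
#' @slot helix,strand,coil data.frames with columns `descriptor`, `phiMin`,
#'   `phiMax`, `psiMin`, `psiMax`; min > max denotes a wrapped interval.
#' @exportClass RegionMap
setClass("RegionMap",
  representation(helix = "data.frame", strand = "data.frame",
                 coil = "data.frame")
)

.checkRegionGroup <- function(df, ids, what) {
  need <- c("descriptor", "phiMin", "phiMax", "psiMin", "psiMax")
  if (!all(need %in% names(df))) {
    return(sprintf("%s regions must have columns %s", what,
                   paste(need, collapse = ", ")))
  }
  if (!all(df$descriptor %in% ids)) {
    return(sprintf("%s regions must use descriptors %s", what,
                   paste(range(ids), collapse = "..")))
  }
  last <- df[nrow(df), ]
  covers <- last$phiMin <= -180 && last$phiMax >= 180 &&
    last$psiMin <= -180 && last$psiMax >= 180
  if (!covers) {
    return(sprintf("last %s region must be an absorbing default box", what))
  }
  TRUE
}

setValidity("RegionMap", function(object) {
  for (spec in list(list(object@helix, 1:4, "helix"),
                    list(object@strand, 5:7, "strand"),
                    list(object@coil, 8:10, "coil"))) {
    ok <- .checkRegionGroup(spec[[1]], spec[[2]], spec[[3]])
    if (!isTRUE(ok)) return(ok)
  }
  TRUE
})

#' Linear descriptor encoding of a structure
#'
#' An ordered sequence of integer residue descriptors in 1..12 (helix
#' regions 1-4, strand regions 5-7, bend/coil regions 8-10, turn 11,
#' bridge 12), one per residue with defined torsions.
#'
#' @slot descriptors integer vector with all values in 1..12.
#' @slot id provenance label (structure id).
#' @exportClass DescriptorSequence
setClass("DescriptorSequence",
  representation(descriptors = "integer", id = "character")
)

setValidity("DescriptorSequence", function(object) {
  d <- object@descriptors
  if (anyNA(d) || (length(d) && (min(d) < 1L || max(d) > 12L))) {
    return("descriptors must be integers in 1..12")
  }
  if (length(object@id) != 1L) return("id must be a single string")
  TRUE
})

#' Run-position-encoded shingle bag
#'
#' The searchable representation of a structure: the multiset of
#' run-position-encoded shingle hashes (each element equals
#' runfactor * 1e5 + shash with shash < 1e5), together with the ordered
#' sequence of encoded hashes retained for longest-common-subsequence
#' scoring.
#'
#' @slot elements integer vector of distinct encoded hash values.
#' @slot counts integer multiplicities, parallel to `elements`.
#' @slot ordered integer vector: encoded hashes in shingle order.
#' @slot id provenance label.
#' @exportClass ShingleBag
setClass("ShingleBag",
  representation(elements = "integer", counts = "integer",
                 ordered = "integer", id = "character")
)

setValidity("ShingleBag", function(object) {
  if (length(object@elements) != length(object@counts)) {
    return("elements and counts must be parallel")
  }
  if (any(object@counts < 1L)) return("counts must be positive")
  if (sum(object@counts) != length(object@ordered)) {
    return("multiset cardinality must equal ordered length")
  }
  tab <- table(object@ordered)
  key <- as.character(object@elements)
  if (!setequal(key, names(tab)) ||
      any(object@counts != as.integer(tab[key]))) {
    return("counts must equal occurrence counts in the ordered sequence")
  }
  if (any(object@elements %% 100000L > 99999L)) {
    return("encoded hashes must decompose as runfactor*1e5 + shash")
  }
  TRUE
})

#' Min-hash / LSH parameters
#'
#' Signature length, banding layout and the base seed of the hash family.
#' The defaults (99 hashes in 33 bands of 3) put the single-band match
#' probability at a Jaccard similarity of 0.60 above 99 percent.
#'
#' @slot numHashes signature length (default 99).
#' @slot bands number of LSH bands (default 33).
#' @slot rowsPerBand min-hashes per band (default 3).
#' @slot targetJaccard nominal similarity threshold the banding is tuned
#'   for (default 0.60); informational.
#' @slot seed integer base seed identifying the hash family; signatures are
#'   only comparable within one seed set.
#' @exportClass LSHParams
setClass("LSHParams",
  representation(numHashes = "integer", bands = "integer",
                 rowsPerBand = "integer", targetJaccard = "numeric",
                 seed = "integer")
)

setValidity("LSHParams", function(object) {
  if (object@bands * object@rowsPerBand != object@numHashes) {
    return("bands * rowsPerBand must equal numHashes")
  }
  if (object@targetJaccard < 0 || object@targetJaccard > 1) {
    return("targetJaccard must lie in [0, 1]")
  }
  TRUE
})

#' Min-hash signature
#'
#' Fixed-length vector of per-hash-function minima over the expanded
#' (value, occurrence) tokens of a shingle bag; the expected fraction of
#' matching positions between two signatures equals the multiset Jaccard
#' similarity of the underlying bags.
#'
#' @slot hashes integer vector (length = numHashes of the generating
#'   parameter set).
#' @slot seed base seed of the hash family used.
#' @slot id provenance label.
#' @exportClass MinHashSignature
setClass("MinHashSignature",
  representation(hashes = "integer", seed = "integer", id = "character")
)

setValidity("MinHashSignature", function(object) {
  if (anyNA(object@hashes) || any(object@hashes < 0L)) {
    return("hashes must be non-negative integers")
  }
  TRUE
})

#' Indexed structure record
#'
#' Everything the index stores per structure: the descriptor sequence, the
#' run-position-encoded bag, the min-hash signature, and (optionally) the
#' CA trace, per-residue secondary structure string and metadata tags used
#' for alignment and filtering.
#'
#' @slot id structure identifier.
#' @slot descriptors a [DescriptorSequence-class].
#' @slot bag a [ShingleBag-class].
#' @slot signature a [MinHashSignature-class].
#' @slot nResidues residue count of the source structure.
#' @slot ca numeric matrix of CA coordinates (may have zero rows when the
#'   record was built from descriptors only).
#' @slot ss single secondary-structure string ("" when unknown).
#' @slot metadata named list of user tags (classification labels etc).
#' @exportClass StructureRecord
setClass("StructureRecord",
  representation(id = "character", descriptors = "DescriptorSequence",
                 bag = "ShingleBag", signature = "MinHashSignature",
                 nResidues = "integer", ca = "matrix", ss = "character",
                 metadata = "list")
)

setValidity("StructureRecord", function(object) {
  if (length(object@id) != 1L || !nzchar(object@id)) {
    return("id must be a non-empty string")
  }
  if (nrow(object@ca) > 0 && ncol(object@ca) != 3) {
    return("ca must have 3 columns")
  }
  TRUE
})

#' Searchable LSH structure index
#'
#' A collection of [StructureRecord-class] objects plus the 33 band tables
#' mapping band hashes to structure ids; any single band match nominates a
#' candidate.
#'
#' @slot params the [LSHParams-class] the index was built under.
#' @slot records named list of StructureRecord objects.
#' @slot bandTables list (length = bands) of named lists mapping band-hash
#'   keys to character vectors of structure ids.
#' @slot sigMatrix integer matrix (numHashes x N) of signatures, for fast
#'   Jaccard estimation.
#' @exportClass StructureIndex
setClass("StructureIndex",
  representation(params = "LSHParams", records = "list",
                 bandTables = "list", sigMatrix = "matrix")
)

setValidity("StructureIndex", function(object) {
  if (length(object@bandTables) != object@params@bands) {
    return("one band table per band required")
  }
  n <- length(object@records)
  if (n > 0 && (ncol(object@sigMatrix) != n ||
                nrow(object@sigMatrix) != object@params@numHashes)) {
    return("sigMatrix must be numHashes x nRecords")
  }
  TRUE
})

#' Pairwise structure alignment result
#'
#' @slot tmScore TM-score in (0, 1].
#' @slot rmsd RMSD over aligned CA pairs, Angstroms.
#' @slot alignedLength number of aligned residue pairs.
#' @slot rotation 3x3 proper rotation applied to the second structure.
#' @slot translation length-3 translation applied after rotation.
#' @slot pairing 2-column matrix of aligned residue indices (a, b).
#' @slot normalization "average" or "query" TM-score length normalization.
#' @exportClass AlignmentResult
setClass("AlignmentResult",
  representation(tmScore = "numeric", rmsd = "numeric",
                 alignedLength = "integer", rotation = "matrix",
                 translation = "numeric", pairing = "matrix",
                 normalization = "character")
)

setValidity("AlignmentResult", function(object) {
  if (object@tmScore <= 0 || object@tmScore > 1 + 1e-12) {
    return("tmScore must lie in (0, 1]")
  }
  if (object@rmsd < 0) return("rmsd must be non-negative")
  TRUE
})

#' Synthetic fixture specification
#'
#' Parameters of the synthetic descriptor-sequence generator: structures
#' are concatenations of maximal runs of identical descriptors, with run
#' lengths drawn from a truncated geometric distribution and descriptors
#' biased toward the dominant regular secondary-structure classes
#' (canonical helix 1 and dominant strand 5).
#'
#' @slot seed integer RNG seed; fixes all outputs.
#' @slot nStructures number of sequences to generate.
#' @slot lengthRange integer length-2 vector, residues.
#' @slot runGeomProb success probability of the geometric run-length law.
#' @slot maxRunLength truncation point of the run-length law.
#' @slot mutationRate fraction of descriptors resampled by
#'   [perturbFamily()].
#' @slot noiseScale coordinate perturbation scale in Angstroms.
#' @exportClass FixtureSpec
setClass("FixtureSpec",
  representation(seed = "integer", nStructures = "integer",
                 lengthRange = "integer", runGeomProb = "numeric",
                 maxRunLength = "integer", mutationRate = "numeric",
                 noiseScale = "numeric")
)

setValidity("FixtureSpec", function(object) {
  if (length(object@lengthRange) != 2L ||
      object@lengthRange[1] > object@lengthRange[2] ||
      object@lengthRange[1] < 3L) {
    return("lengthRange must be an ordered pair with minimum >= 3")
  }
  if (object@mutationRate < 0 || object@mutationRate > 1) {
    return("mutationRate must lie in [0, 1]")
  }
  if (object@runGeomProb <= 0 || object@runGeomProb >= 1) {
    return("runGeomProb must lie in (0, 1)")
  }
  TRUE
})
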