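#' Linear descriptor encoding of a structure
#'
#' Maps every residue with defined torsions and an assigned secondary
#' structure code to its descriptor (1..12), in chain order. Residues with
#' undefined phi or psi (termini, chain breaks) are excluded: a 16-residue
#' beta-turn-beta motif with both termini defined internally yields e.g.
#' `[5,5,5,5,5,5,7,5,11,11,5,5,5,5,5,5]`.
#'
#' @param geometries torsion table from [computeTorsions()] with the `ss`
#'   column filled ([applyDssp()] or [assignSSHeuristic()]).
#' @param regions a [RegionMap-class].
#' @param id provenance label for the encoding.
#' @return A [DescriptorSequence-class].
#' @export
encodeStructure <- function(geometries, regions = defaultRegionMap(),
                            id = "unnamed") {
  ok <- !is.na(geometries$phi) & !is.na(geometries$psi) &
    !is.na(geometries$ss)
  if (!any(ok)) {
    stop("empty encoding: no residue has defined torsions and a code")
  }
  g <- geometries[ok, , drop = FALSE]
  descriptorSequence(assignDescriptor(g$phi, g$psi, g$ss, regions), id = id)
}

.seqInts <- function(x) {
  if (is(x, "DescriptorSequence")) x@descriptors else as.integer(x)
}

#' Overlapping shingles of a descriptor sequence
#'
#' Slides a window of 3 consecutive descriptors along the sequence: a
#' sequence of length n yields n - 2 overlapping shingles with zero-based
#' start positions 0 .. n-3.
#'
#' @param x a [DescriptorSequence-class] or integer vector (length >= 3).
#' @return data.frame with columns `start` (zero-based), `s1`, `s2`, `s3`.
#' @examples
#' shinglesOf(c(5, 5, 5, 7))
#' @export
shinglesOf <- function(x) {
  d <- .seqInts(x)
  n <- length(d)
  if (n < 3L) stop("sequence too short to shingle (need length >= 3)")
  k <- n - 2L
  data.frame(start = 0:(k - 1L), s1 = d[1:k], s2 = d[2:(k + 1L)],
             s3 = d[3:(k + 2L)])
}

#' Base-13 shingle hash
#'
#' Hashes a shingle of three descriptors to `s1*13^2 + s2*13 + s3`. With
#' descriptors in 1..12 and the prime base 13 the map is injective (range
#' 183..2196), so distinct shingles never collide.
#'
#' @param s1,s2,s3 descriptor vectors in 1..12; alternatively pass the
#'   data.frame from [shinglesOf()] as `s1`.
#' @return Integer hash vector.
#' @examples
#' shash(5, 5, 5)    # 915
#' shash(11, 11, 5)  # 2007
#' @export
shash <- function(s1, s2 = NULL, s3 = NULL) {
  if (is.data.frame(s1)) {
    s3 <- s1$s3; s2 <- s1$s2; s1 <- s1$s1
  }
  s1 <- as.integer(s1); s2 <- as.integer(s2); s3 <- as.integer(s3)
  v <- c(s1, s2, s3)
  if (anyNA(v) || any(v < 1L | v > 12L)) {
    stop("descriptors must lie in 1..12")
  }
  169L * s1 + 13L * s2 + s3
}

#' Pyramidal run position factors
#'
#' Partitions a descriptor sequence into maximal runs of identical values
#' and gives the residue at zero-based within-run position i the factor
#' `i` when `i < floor(l/2)` and `l - i - 1` otherwise (run length l). The
#' factors rise toward the middle of a run and fall symmetrically, so
#' matches at run boundaries survive run-length differences while long and
#' short runs stop cross-matching wholesale.
#'
#' @param x a [DescriptorSequence-class] or integer vector.
#' @return Integer vector of run factors, one per element.
#' @examples
#' runFactors(c(5, 5, 5, 5, 5, 5, 7, 5, 11, 11, 5, 5, 5, 5, 5, 5))
#' @export
runFactors <- function(x) {
  d <- .seqInts(x)
  if (length(d) == 0L) return(integer(0))
  r <- rle(d)
  unlist(lapply(r$lengths, function(l) {
    i <- seq_len(l) - 1L
    as.integer(ifelse(i < l %/% 2L, i, l - i - 1L))
  }), use.names = FALSE)
}

#' Run-position-encoded shingle bag
#'
#' The searchable bag representation: each shingle hash is offset by 1e5
#' times the run factor of its first residue, yielding encoded values
#' `runfactor * 1e5 + shash`. Both the multiset (for Jaccard similarity)
#' and the ordered encoded sequence (for LCS adjustment) are retained.
#'
#' @param x a [DescriptorSequence-class] or integer vector (length >= 3).
#' @param shingleRuns if `TRUE`, run factors are computed over runs of
#'   identical shingle hashes instead of runs of identical descriptors (an
#'   alternative scheme, off by default).
#' @return A [ShingleBag-class].
#' @examples
#' bagOf(c(5, 5, 5, 5, 5, 5, 7, 5, 11, 11, 5, 5, 5, 5, 5, 5))
#' @export
bagOf <- function(x, shingleRuns = FALSE) {
  d <- .seqInts(x)
  sh <- shinglesOf(d)
  h <- shash(sh)
  rf <- if (shingleRuns) runFactors(h) else runFactors(d)[sh$start + 1L]
  enc <- rf * 100000L + h
  tab <- table(enc)
  new("ShingleBag", elements = as.integer(names(tab)),
      counts = as.integer(tab), ordered = enc,
      id = if (is(x, "DescriptorSequence")) x@id else "unnamed")
}

#' Display form of encoded shingle hashes
#'
#' Renders encoded values with the run factor as leading digit(s) followed
#' by the four-digit zero-padded base-13 hash (e.g. 100915 prints as
#' "10915" and 915 as "00915"). Presentation only: the normative value is
#' the integer `runfactor * 1e5 + shash`.
#'
#' @param x integer encoded hashes or a [ShingleBag-class].
#' @return Character vector.
#' @export
formatEncodedHashes <- function(x) {
  v <- if (is(x, "ShingleBag")) x@ordered else as.integer(x)
  sprintf("%d%04d", v %/% 100000L, v %% 100000L)
}
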