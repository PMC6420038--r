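.bagCountsOn <- function(a, b) {
  keys <- sort(union(a@elements, b@elements))
  ca <- integer(length(keys)); cb <- integer(length(keys))
  ca[match(a@elements, keys)] <- a@counts
  cb[match(b@elements, keys)] <- b@counts
  list(keys = keys, a = ca, b = cb)
}

#' Multiset Jaccard similarity of two shingle bags
#'
#' `J(a, b) = sum_i min(a_i, b_i) / sum_i max(a_i, b_i)` where `a_i`, `b_i`
#' are the multiplicities of encoded shingle hash i in each bag.
#'
#' @param a,b [ShingleBag-class] objects, at least one non-empty.
#' @return Similarity in \[0, 1\].
#' @examples
#' x <- bagOf(c(5, 5, 5, 7, 5))
#' multisetJaccard(x, x)  # 1
#' @export
multisetJaccard <- function(a, b) {
  stopifnot(is(a, "ShingleBag"), is(b, "ShingleBag"))
  if (length(a@ordered) == 0L && length(b@ordered) == 0L) {
    stop("similarity undefined: both bags are empty")
  }
  m <- .bagCountsOn(a, b)
  sum(pmin(m$a, m$b)) / sum(pmax(m$a, m$b))
}

#' Min-hash signature of a shingle bag
#'
#' Expands every multiset element into (value, occurrence-ordinal) tokens
#' and, for each of the `numHashes` seeded 64-bit mixing functions, records
#' the minimum token hash. Two signatures from the same seed set match at
#' any given position with probability equal to the multiset Jaccard
#' similarity of the bags. With `multiset = FALSE` duplicates are collapsed
#' first, so the estimator targets the plain set Jaccard instead.
#'
#' @param bag a non-empty [ShingleBag-class].
#' @param params [LSHParams-class]; fixes signature length and seed set.
#' @param multiset honour multiplicities (default) or use set semantics.
#' @return A [MinHashSignature-class].
#' @export
minhashSignature <- function(bag, params = lshParams(), multiset = TRUE) {
  stopifnot(is(bag, "ShingleBag"), is(params, "LSHParams"))
  if (length(bag@ordered) == 0L) stop("cannot min-hash an empty bag")
  counts <- if (multiset) bag@counts else rep(1L, length(bag@elements))
  h <- cpp_minhash(bag@elements, counts, params@numHashes, params@seed)
  new("MinHashSignature", hashes = h, seed = params@seed, id = bag@id)
}

#' Estimate Jaccard similarity from two min-hash signatures
#'
#' The fraction of signature positions with equal min-hashes; an unbiased
#' estimator of the (multiset) Jaccard similarity with binomial standard
#' error `sqrt(J(1-J)/numHashes)`.
#'
#' @param sigA,sigB [MinHashSignature-class] objects from the same seed
#'   set.
#' @return Estimate in \[0, 1\].
#' @export
estimateJaccard <- function(sigA, sigB) {
  stopifnot(is(sigA, "MinHashSignature"), is(sigB, "MinHashSignature"))
  if (sigA@seed != sigB@seed) {
    stop("signatures come from different seed sets and are not comparable")
  }
  if (length(sigA@hashes) != length(sigB@hashes)) {
    stop("signatures have different lengths")
  }
  mean(sigA@hashes == sigB@hashes)
}

#' LSH band hashes of a signature
#'
#' Splits the signature into `bands` contiguous bands of `rowsPerBand`
#' min-hashes and mixes each band (order-sensitively, with the band index
#' folded into the key) into a single integer hash. Structures sharing any
#' one band hash become candidate matches.
#'
#' @param sig a [MinHashSignature-class].
#' @param params [LSHParams-class] matching the signature length.
#' @return Integer vector of length `params@bands`.
#' @export
bandHashes <- function(sig, params = lshParams()) {
  stopifnot(is(sig, "MinHashSignature"), is(params, "LSHParams"))
  if (length(sig@hashes) != params@numHashes) {
    stop("signature length does not match bands * rowsPerBand")
  }
  cpp_band_hashes(sig@hashes, params@bands, params@rowsPerBand)
}

#' Probability of at least one band match
#'
#' For true Jaccard similarity `j`, a band of r rows matches with
#' probability `j^r`, so some band among b matches with probability
#' `1 - (1 - j^r)^b`. With the default 33 bands of 3 rows this exceeds
#' 0.99 at j = 0.60 - the similarity threshold the banding is tuned for.
#'
#' @param j Jaccard similarity in \[0, 1\] (vectorized).
#' @param params [LSHParams-class].
#' @return Probability in \[0, 1\].
#' @examples
#' bandMatchProbability(0.6)
#' @export
bandMatchProbability <- function(j, params = lshParams()) {
  stopifnot(all(j >= 0 & j <= 1))
  1 - (1 - j^params@rowsPerBand)^params@bands
}

#' Longest common subsequence length
#'
#' Standard O(|x||y|) dynamic program over two integer sequences (here,
#' run-position-encoded shingle hash sequences).
#'
#' @param x,y integer vectors or [ShingleBag-class] objects (ordered
#'   hashes are used).
#' @return Non-negative integer.
#' @examples
#' lcsLength(c(915, 917, 941), c(915, 941, 917))  # 2
#' @export
lcsLength <- function(x, y) {
  if (is(x, "ShingleBag")) x <- x@ordered
  if (is(y, "ShingleBag")) y <- y@ordered
  cpp_lcs_length(as.integer(x), as.integer(y))
}

#' LCS-adjusted Jaccard similarity
#'
#' Replaces the matched-shingle numerator of the multiset Jaccard
#' similarity with the length of the longest common subsequence of the two
#' ordered encoded hash sequences, keeping the exact multiset denominator:
#' `lcs(a, b) / sum_i max(a_i, b_i)`. Matches that are out of sequence
#' order no longer count, so the score never exceeds the multiset Jaccard.
#'
#' @param a,b [ShingleBag-class] objects carrying their ordered sequences.
#' @return Adjusted similarity in \[0, 1\].
#' @export
adjustedJaccard <- function(a, b) {
  stopifnot(is(a, "ShingleBag"), is(b, "ShingleBag"))
  if (length(a@ordered) == 0L && length(b@ordered) == 0L) {
    stop("similarity undefined: both bags are empty")
  }
  m <- .bagCountsOn(a, b)
  lcsLength(a@ordered, b@ordered) / sum(pmax(m$a, m$b))
}
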