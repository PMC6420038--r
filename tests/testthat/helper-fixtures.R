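# shared fixtures, built in code

# the beta-turn-beta worked descriptor sequence used throughout
betaTurnBetaDescriptors <- function() {
  c(5, 5, 5, 5, 5, 5, 7, 5, 11, 11, 5, 5, 5, 5, 5, 5)
}

# bag with arbitrary ordered values (bypasses shingling; for similarity and
# hashing tests that need controlled multisets)
makeBag <- function(values, id = "bag") {
  values <- as.integer(values)
  tab <- table(values)
  methods::new("ShingleBag", elements = as.integer(names(tab)),
               counts = as.integer(tab), ordered = values, id = id)
}

# pair of bags over random distinct elements with exact multiset Jaccard
# k / (2n - k); all counts 1
jaccardBagPair <- function(n, k, universe = 1e7L) {
  u <- sample.int(universe, 2L * n - k)
  list(a = makeBag(u[1:n], "a"), b = makeBag(u[(n - k + 1L):(2L * n - k)], "b"))
}

# random secondary-structure plan string like "H8-E5-C3"
randomPlan <- function(minSeg = 3L, maxSeg = 5L) {
  n <- sample(minSeg:maxSeg, 1)
  paste(sprintf("%s%d",
                sample(c("H", "E", "C"), n, replace = TRUE,
                       prob = c(0.4, 0.4, 0.2)),
                sample(4:10, n, replace = TRUE)), collapse = "-")
}

# collection of coordinate-bearing records from toy backbones; structures
# are kept only if their descriptor encodings are pairwise distinct, so
# self-retrieval is unambiguous
toyRecordSet <- function(n, seed = 1L, params = lshParams()) {
  set.seed(seed)
  recs <- list()
  seen <- character(0)
  i <- 0L
  while (length(recs) < n) {
    i <- i + 1L
    plan <- randomPlan()
    rec <- makeStructureRecord(buildToyBackbone(plan, seed = seed * 1000L + i),
                               id = sprintf("toy_%03d", length(recs) + 1L),
                               params = params)
    key <- paste(descriptors(rec@descriptors), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    recs[[length(recs) + 1L]] <- rec
  }
  recs
}

# exponential-time LCS oracle: longest subsequence of x that is also a
# subsequence of y, by enumeration (tiny inputs only)
bruteLcs <- function(x, y) {
  isSubseq <- function(s, v) {
    j <- 1L
    for (e in v) {
      if (j <= length(s) && s[j] == e) j <- j + 1L
    }
    j > length(s)
  }
  for (len in seq(length(x), 0L)) {
    if (len == 0L) return(0L)
    combos <- utils::combn(length(x), len, simplify = FALSE)
    for (idx in combos) {
      if (isSubseq(x[idx], y)) return(len)
    }
  }
}

# brute-force fast-mode oracle: adjusted Jaccard against every record, no LSH
bruteAdjustedRanking <- function(queryBag, records) {
  adj <- vapply(records, function(r) adjustedJaccard(queryBag, r@bag),
                numeric(1))
  ids <- vapply(records, structureId, character(1))
  ord <- order(-adj, ids)
  data.frame(id = ids[ord], jaccardAdj = adj[ord], stringsAsFactors = FALSE)
}

# 3-residue hand-written PDB fragment (two chains for selection tests)
tinyPdbText <- function() {
  c("HEADER    TEST FRAGMENT",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.421   0.000  1.00  0.00           C",
    "ATOM      4  N   GLY A   2       3.332   1.536   0.000  1.00  0.00           N",
    "ATOM      5  CA  GLY A   2       4.042   2.799   0.130  1.00  0.00           C",
    "ATOM      6  C   GLY A   2       5.486   2.607  -0.320  1.00  0.00           C",
    "ATOM      7  N   SER A   3       6.360   3.561  -0.030  1.00  0.00           N",
    "ATOM      8  CA  SER A   3       7.780   3.480  -0.350  1.00  0.00           C",
    "ATOM      9  C   SER A   3       8.480   4.800  -0.090  1.00  0.00           C",
    "ATOM     10  N   ALA B   1      20.000   0.000   0.000  1.00  0.00           N",
    "ATOM     11  CA  ALA B   1      21.458   0.000   0.000  1.00  0.00           C",
    "ATOM     12  C   ALA B   1      22.009   1.421   0.000  1.00  0.00           C",
    "ATOM     13  N   ALA B   2      23.332   1.536   0.000  1.00  0.00           N",
    "ATOM     14  CA  ALA B   2      24.042   2.799   0.130  1.00  0.00           C",
    "ATOM     15  C   ALA B   2      25.486   2.607  -0.320  1.00  0.00           C",
    "END")
}

# classic-format DSSP fixture: header boilerplate plus a residue block
tinyDsspText <- function() {
  c("==== Secondary Structure Definition by the program DSSP ====",
    "REFERENCE ...",
    "HEADER    TEST",
    "  4  1  0  0  0 TOTAL NUMBER OF RESIDUES ...",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
    "    1    1 A A  H  >,<       0   0    0",
    "    2    2 A G  E             0   0    0",
    "    3    3 A S  T             0   0    0",
    "    4    4 A V  B             0   0    0",
    "    5    5 A L               0   0    0",
    "    6        !*             0   0    0",
    "    7    6ZB K  E             0   0    0")
}

# random rigid motion applied to all coordinate slots of a chain
rotateChain <- function(chain, seed = 1L) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  shift <- rnorm(3, 0, 20)
  tx <- function(m) sweep(m %*% q, 2, shift, "+")
  backboneChain(resno = chain@resno, n = tx(chain@n), ca = tx(chain@ca),
                c = tx(chain@c), resid = chain@resid,
                chainId = chain@chainId, insert = chain@insert)
}
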