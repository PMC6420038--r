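test_that("Kabsch superposition recovers rigid transforms exactly", {
  set.seed(21)
  a <- matrix(rnorm(30, sd = 5), 10, 3)
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  shift <- c(3, -7, 11)
  b <- sweep(a %*% q, 2, shift, "+")
  # recover the inverse motion: fit b back onto a
  fit <- kabschSuperpose(a, b)
  expect_lt(fit$rmsd, 1e-6)
  expect_equal(fit$rotation, t(q), tolerance = 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-8)
  # mirrored coordinates: proper rotation enforced, RMSD > 0
  m <- a; m[, 1] <- -m[, 1]
  fitM <- kabschSuperpose(a, m)
  expect_equal(det(fitM$rotation), 1, tolerance = 1e-8)
  expect_gt(fitM$rmsd, 0.1)
  expect_error(kabschSuperpose(a[1:2, ], b[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabschSuperpose(line, line), "rank-deficient")
  # agrees with the bio3d least-squares fit
  fitted <- matrix(bio3d::fit.xyz(as.vector(t(a)), as.vector(t(b)),
                                  1:30, 1:30), ncol = 3, byrow = TRUE)
  expect_equal(fit$rmsd, sqrt(mean(rowSums((a - fitted)^2))),
               tolerance = 1e-6)
})

test_that("TM-score alignment is exact on self and symmetric when averaged", {
  a <- buildToyBackbone("H10-C4-E6-C3-E6", seed = 5)
  self <- tmAlignPair(a, a)
  expect_equal(self@tmScore, 1.0, tolerance = 1e-9)
  expect_lt(self@rmsd, 1e-9)
  expect_identical(self@alignedLength, length(a))

  b <- buildToyBackbone("H10-C3-E6-C4-E5", seed = 6)
  ab <- tmAlignPair(a, b)
  ba <- tmAlignPair(b, a)
  expect_equal(ab@tmScore, ba@tmScore, tolerance = 1e-9)
  expect_true(ab@tmScore > 0 && ab@tmScore <= 1)
  # rigid motion of one input does not change the score
  abRot <- tmAlignPair(a, rotateChain(b, seed = 3))
  expect_equal(abRot@tmScore, ab@tmScore, tolerance = 1e-6)
  expect_error(tmAlignPair(a@ca[1:4, ], b@ca), "at least 5")
})

test_that("TM-score degrades with coordinate noise and beats the random floor", {
  helix <- buildToyBackbone("H20", seed = 2)
  tms <- vapply(c(0.5, 1, 2, 4), function(noise) {
    mean(vapply(1:3, function(r) {
      tmAlignPair(helix, perturbBackbone(helix, noise, seed = r * 10))@tmScore
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(tms < 1))
  expect_gt(tms[1], 0.17)
  expect_true(all(diff(tms) < 0))
})

test_that("fast mode retrieves self first and follows the brute-force order", {
  params <- lshParams()
  set.seed(50)
  parent <- generateDescriptorSet(
    fixtureSpec(seed = 77, nStructures = 1, lengthRange = c(80L, 120L)))[[1]]
  family <- perturbFamily(parent, 10, rate = 0.05, seed = 3)
  randoms <- generateDescriptorSet(
    fixtureSpec(seed = 78, nStructures = 40, lengthRange = c(80L, 120L)))
  recs <- c(lapply(family, makeStructureRecord, params = params),
            lapply(randoms, makeStructureRecord, params = params))
  idx <- buildIndex(recs, params)
  q <- makeStructureRecord(parent, params = params)

  hits <- fastSearch(q, idx)
  famIds <- vapply(family, structureId, character(1))
  famRanks <- hits$rank[match(famIds, hits$id)]
  otherRanks <- hits$rank[!hits$id %in% famIds]
  expect_true(all(!is.na(famRanks)))
  expect_lt(max(famRanks), min(c(otherRanks, Inf)))

  # indexed query retrieves itself at rank 1 with adjusted Jaccard 1
  qIndexed <- recs[[1]]
  hits2 <- fastSearch(qIndexed, idx)
  expect_identical(hits2$id[1], structureId(qIndexed))
  expect_equal(hits2$jaccardAdj[1], 1.0)

  # ranking agrees with a no-LSH brute-force adjusted-Jaccard scan on the
  # structures the LSH filter retrieved
  oracle <- bruteAdjustedRanking(q@bag, recs)
  oracle <- oracle[oracle$id %in% hits$id, ]
  expect_identical(hits$id, oracle$id)
  expect_equal(hits$jaccardAdj, oracle$jaccardAdj)
})

test_that("search caps bound candidates scored and results returned", {
  params <- lshParams()
  parent <- generateDescriptorSet(
    fixtureSpec(seed = 90, nStructures = 1, lengthRange = c(60L, 60L)))[[1]]
  family <- perturbFamily(parent, 30, rate = 0.03, seed = 4)
  recs <- lapply(family, makeStructureRecord, params = params)
  idx <- buildIndex(recs, params)
  q <- makeStructureRecord(parent, params = params)
  hits <- fastSearch(q, idx, candidateCap = 12L, resultCap = 5L)
  expect_lte(nrow(hits), 5L)
  expect_identical(hits$rank, 1:5)
  # candidate cap kept only the 12 best estimates before rescoring
  shortlist <- rupee:::.fastShortlist(q, idx, 12L, NULL)
  expect_identical(nrow(shortlist), 12L)
  expect_true(all(hits$id %in% shortlist$id))
})

test_that("top-aligned mode re-ranks by alignment and never loses the query", {
  params <- lshParams()
  recs <- toyRecordSet(15, seed = 33, params = params)
  idx <- buildIndex(recs, params)
  q <- recs[[4]]
  res <- topAlignedSearch(q, idx)
  expect_identical(res$id[1], structureId(q))
  expect_equal(res$tmScore[1], 1.0, tolerance = 1e-9)
  expect_true(all(diff(res$tmScore) <= 1e-12))
  # full realignment never substantially worsens a stage-1 score
  stage1 <- attr(res, "stage1")
  common <- intersect(res$id, stage1$id)
  expect_gte(min(res$tmScore[match(common, res$id)] -
                   stage1$tmScore[match(common, stage1$id)]), -0.02)
  # rmsd sort ascends
  resR <- topAlignedSearch(q, idx, sortBy = "rmsd")
  expect_identical(resR$id[1], structureId(q))
  expect_true(all(diff(resR$rmsd) >= -1e-12))
  # determinism: identical repeated runs
  res2 <- topAlignedSearch(q, idx)
  attr(res, "stage1") <- NULL; attr(res2, "stage1") <- NULL
  expect_identical(res, res2)
  # result cap respected
  expect_lte(nrow(topAlignedSearch(q, idx, resultCap = 3L)), 3L)
})

test_that("descriptor-only records refuse top-aligned mode", {
  params <- lshParams()
  recs <- c(toyRecordSet(4, seed = 13, params = params),
            list(makeStructureRecord(
              descriptorSequence(rep(c(1L, 5L), 20), id = "noCoords"),
              params = params)))
  idx <- buildIndex(recs, params)
  expect_error(topAlignedSearch(recs[[5]], idx), "CA coordinates")
})
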