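test_that("beta-turn-beta worked example reproduces every stage exactly", {
  dseq <- descriptorSequence(betaTurnBetaDescriptors(), id = "motif")

  sh <- shinglesOf(dseq)
  expect_identical(nrow(sh), 14L)
  expect_identical(sh$start, 0:13)
  expect_identical(unlist(sh[1, c("s1", "s2", "s3")], use.names = FALSE),
                   c(5L, 5L, 5L))
  expect_identical(unlist(sh[7, c("s1", "s2", "s3")], use.names = FALSE),
                   c(7L, 5L, 11L))

  expect_identical(shash(sh),
                   c(915L, 915L, 915L, 915L, 917L, 941L, 1259L, 999L,
                     2007L, 1929L, 915L, 915L, 915L, 915L))

  expect_identical(runFactors(dseq),
                   c(0L, 1L, 2L, 2L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 1L, 2L,
                     2L, 1L, 0L))

  bag <- bagOf(dseq)
  expect_identical(orderedHashes(bag),
                   c(915L, 100915L, 200915L, 200915L, 100917L, 941L, 1259L,
                     999L, 2007L, 1929L, 915L, 100915L, 200915L, 200915L))
  expect_identical(formatEncodedHashes(bag),
                   c("00915", "10915", "20915", "20915", "10917", "00941",
                     "01259", "00999", "02007", "01929", "00915", "10915",
                     "20915", "20915"))
  expect_identical(sum(bagCounts(bag)), 14L)
})

test_that("shash is the base-13 polynomial and is injective on triples", {
  expect_identical(shash(5, 5, 5), 915L)
  expect_identical(shash(11, 11, 5), 2007L)
  expect_identical(shash(1, 1, 1), 183L)
  expect_identical(shash(12, 12, 12), 2196L)
  all3 <- expand.grid(s1 = 1:12, s2 = 1:12, s3 = 1:12)
  h <- shash(all3$s1, all3$s2, all3$s3)
  expect_identical(anyDuplicated(h), 0L)
  expect_true(all(h >= 183L & h <= 2196L))
  expect_error(shash(0, 5, 5), "1..12")
  expect_error(shash(5, 13, 5), "1..12")
})

test_that("shingling requires length >= 3 and yields n-2 windows", {
  expect_identical(nrow(shinglesOf(c(1L, 2L, 3L))), 1L)
  expect_error(shinglesOf(c(1L, 2L)), "too short")
  set.seed(3)
  for (n in c(3L, 10L, 57L)) {
    d <- sample.int(12L, n, replace = TRUE)
    expect_identical(nrow(shinglesOf(d)), n - 2L)
  }
})

test_that("run factors are pyramidal, symmetric and capped", {
  expect_identical(runFactors(7L), 0L)
  expect_identical(runFactors(rep(3L, 5)), c(0L, 1L, 2L, 1L, 0L))
  set.seed(5)
  for (rep in 1:20) {
    lens <- sample.int(25L, sample(2:6, 1), replace = TRUE)
    vals <- sample.int(12L, length(lens))
    vals <- vals + c(0L, cumsum(diff(vals) == 0))  # no accidental merges
    vals <- ((vals - 1L) %% 12L) + 1L
    d <- rep(vals, lens)
    rf <- runFactors(d)
    off <- 0L
    for (j in seq_along(lens)) {
      run <- rf[(off + 1L):(off + lens[j])]
      expect_identical(run, rev(run))
      expect_identical(max(run), (lens[j] - 1L) %/% 2L)
      off <- off + lens[j]
    }
  }
})

test_that("bags decompose as runfactor * 1e5 + shash and match their counts", {
  set.seed(9)
  for (rep in 1:10) {
    d <- sample.int(12L, sample(10:60, 1), replace = TRUE)
    bag <- bagOf(d)
    v <- orderedHashes(bag)
    expect_true(all(v %% 100000L >= 183L & v %% 100000L <= 2196L))
    expect_identical(v %% 100000L, shash(shinglesOf(d)))
    expect_identical(v %/% 100000L, runFactors(d)[shinglesOf(d)$start + 1L])
    tab <- table(v)
    expect_identical(bagCounts(bag), as.integer(tab[as.character(bagElements(bag))]))
  }
  # all-distinct descriptors: every run factor 0, bag equals plain hashes
  d <- c(1L, 2L, 3L, 4L, 5L, 6L, 7L)
  expect_identical(orderedHashes(bagOf(d)), shash(shinglesOf(d)))
  # determinism
  expect_identical(bagOf(betaTurnBetaDescriptors()), bagOf(betaTurnBetaDescriptors()))
})

test_that("alternative shingle-run encoding differs only when hash runs do", {
  d <- c(1L, 2L, 3L, 4L, 5L, 6L)            # no repeated shingle hashes
  expect_identical(orderedHashes(bagOf(d, shingleRuns = TRUE)),
                   orderedHashes(bagOf(d)))
  d2 <- betaTurnBetaDescriptors()                      # long runs of [5,5,5]
  expect_false(identical(orderedHashes(bagOf(d2, shingleRuns = TRUE)),
                         orderedHashes(bagOf(d2))))
  v <- orderedHashes(bagOf(d2, shingleRuns = TRUE))
  expect_identical(v %/% 100000L, runFactors(shash(shinglesOf(d2))))
})

test_that("descriptor assignment follows codes and torsion regions", {
  expect_identical(assignDescriptor(12, 34, "T"), 11L)
  expect_identical(assignDescriptor(-120, 135, "B"), 12L)
  expect_identical(assignDescriptor(-120, 135, "E"), 5L)
  expect_identical(assignDescriptor(-57, -47, "H"), 1L)
  # every angle lands in its group's descriptor range (default absorbs)
  set.seed(13)
  phi <- runif(200, -180, 180); psi <- runif(200, -180, 180)
  expect_true(all(assignDescriptor(phi, psi, rep("H", 200)) %in% 1:4))
  expect_true(all(assignDescriptor(phi, psi, rep("E", 200)) %in% 5:7))
  expect_true(all(assignDescriptor(phi, psi, rep("S", 200)) %in% 8:10))
  expect_error(assignDescriptor(0, 0, "X"), "unrecognized")
})

test_that("encodeStructure composes assignment over eligible residues", {
  g <- data.frame(resno = 1:4, insert = "",
                  phi = c(-120, -120, -120, -170),
                  psi = c(135, 135, 135, 100),
                  ss = c("E", "E", "E", "E"))
  expect_identical(descriptors(encodeStructure(g, id = "s")),
                   c(5L, 5L, 5L, 5L))
  gt <- data.frame(resno = 1:4, insert = "", phi = 0, psi = 0, ss = "T")
  expect_identical(descriptors(encodeStructure(gt)), rep(11L, 4))
  # residues with undefined torsions are excluded
  g$phi[2] <- NA
  expect_identical(length(encodeStructure(g)), 3L)
  gNA <- data.frame(resno = 1:3, insert = "", phi = NA_real_,
                    psi = NA_real_, ss = "E")
  expect_error(encodeStructure(gNA), "empty encoding")
})

test_that("region maps load from JSON and validate their structure", {
  rm <- defaultRegionMap()
  expect_s4_class(rm, "RegionMap")
  # a config whose last strand box is not absorbing is rejected
  bad <- list(
    helix = list(list(descriptor = 1, box = c(-180, 180, -180, 180))),
    strand = list(list(descriptor = 5, box = c(-180, -45, 85, -155))),
    coil = list(list(descriptor = 8, box = c(-180, 180, -180, 180))))
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(bad, path, auto_unbox = TRUE)
  expect_error(readRegionMap(path), "absorbing")
})
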