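test_that("parsePdb reads back an authored fragment and selects chains", {
  chain <- parsePdb(text = tinyPdbText())
  expect_s4_class(chain, "BackboneChain")
  expect_identical(length(chain), 3L)
  expect_equal(chain@ca[1, ], c(1.458, 0, 0))
  expect_identical(chain@chainId, "A")

  chainB <- parsePdb(text = tinyPdbText(), chain = "B")
  expect_identical(length(chainB), 2L)
  expect_true(all(chainB@ca[, 1] > 19))

  expect_error(parsePdb(text = tinyPdbText(), chain = "Z"), "not found")
  expect_error(parsePdb(text = c("HEADER    EMPTY", "END")))
})

test_that("writePdb/parsePdb round-trips a constructed backbone", {
  chain <- buildToyBackbone("H6-E4", seed = 3)
  back <- parsePdb(text = writePdb(chain))
  expect_equal(back@ca, chain@ca, tolerance = 1e-3)
  expect_equal(back@n, chain@n, tolerance = 1e-3)
  expect_identical(back@resno, chain@resno)
})

test_that("torsion round-trip recovers constructed angles within 0.5 deg", {
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(6:15, 1)
    phi <- runif(n, -179, 179)
    psi <- runif(n, -179, 179)
    g <- computeTorsions(buildBackboneFromTorsions(phi, psi))
    expect_equal(g$phi[2:n], phi[2:n], tolerance = 0.5)
    expect_equal(g$psi[1:(n - 1)], psi[1:(n - 1)], tolerance = 0.5)
    expect_true(is.na(g$phi[1]) && is.na(g$psi[n]))
  }
})

test_that("torsions are invariant under rigid motions", {
  chain <- buildToyBackbone("H8-C3-E5", seed = 11)
  g0 <- computeTorsions(chain)
  for (s in 1:4) {
    g1 <- computeTorsions(rotateChain(chain, seed = s))
    expect_equal(g1$phi, g0$phi, tolerance = 1e-8)
    expect_equal(g1$psi, g0$psi, tolerance = 1e-8)
  }
})

test_that("dihedral computation agrees with bio3d", {
  set.seed(42)
  for (rep in 1:20) {
    p <- matrix(rnorm(12, sd = 3), 4, 3)
    ref <- bio3d::torsion.xyz(as.vector(t(p)), atm.inc = 4)
    got <- rupee:::.dihedral(p[1, , drop = FALSE], p[2, , drop = FALSE],
                             p[3, , drop = FALSE], p[4, , drop = FALSE])
    # both use (-180, 180]-style conventions; compare on the circle
    delta <- (got - ref) %% 360
    expect_true(min(delta, 360 - delta) < 1e-6)
  }
})

test_that("chain breaks and termini leave torsions undefined", {
  a <- buildToyBackbone("H5", seed = 1)
  b <- buildToyBackbone("H5", seed = 2)
  shift <- function(m) sweep(m, 2, c(50, 0, 0), "+")
  merged <- backboneChain(resno = 1:10, n = rbind(a@n, shift(b@n)),
                          ca = rbind(a@ca, shift(b@ca)),
                          c = rbind(a@c, shift(b@c)))
  g <- computeTorsions(merged)
  expect_true(is.na(g$psi[5]) && is.na(g$phi[6]))
  # defined count = length - termini - break-adjacent residues
  expect_identical(sum(!is.na(g$phi) & !is.na(g$psi)),
                   10L - 2L * 2L)       # two fragments, two termini each
  one <- backboneChain(resno = 1L, n = a@n[1, , drop = FALSE],
                       ca = a@ca[1, , drop = FALSE],
                       c = a@c[1, , drop = FALSE])
  expect_error(computeTorsions(one), "at least 2")
})

test_that("degenerate collinear geometry yields undefined torsions", {
  pos <- seq(0, by = 0.5, length.out = 9)
  line <- cbind(pos, 0, 0)
  chain <- backboneChain(resno = 1:3, n = line[c(1, 4, 7), ],
                         ca = line[c(2, 5, 8), ], c = line[c(3, 6, 9), ])
  expect_warning(g <- computeTorsions(chain), "degenerate")
  expect_true(all(is.na(g$phi)) && all(is.na(g$psi)))
})

test_that("DSSP reader handles codes, blanks, breaks and insertion codes", {
  codes <- readDssp(text = tinyDsspText())
  expect_identical(unname(codes[c("A:1", "A:2", "A:3", "A:4")]),
                   c("H", "E", "T", "B"))
  expect_identical(unname(codes["A:5"]), "C")    # blank column -> coil
  expect_true("B:6Z" %in% names(codes))          # insertion code preserved
  expect_identical(length(codes), 6L)            # '!' break line skipped
  expect_error(readDssp(text = c("not dssp", "at all")), "malformed")
})

test_that("torsion-window heuristic gates on run length", {
  helix <- data.frame(resno = 1:8, insert = "", phi = -57, psi = -47,
                      ss = NA_character_)
  expect_identical(assignSSHeuristic(helix)$ss, rep("H", 8))
  strand <- data.frame(resno = 1:4, insert = "", phi = -120, psi = 130,
                       ss = NA_character_)
  expect_identical(assignSSHeuristic(strand)$ss, rep("E", 4))
  # alternating singletons never reach the run-length gates
  mix <- data.frame(resno = 1:6, insert = "",
                    phi = c(-57, 60, -57, 60, -57, 60),
                    psi = c(-47, 60, -47, 60, -47, 60), ss = NA_character_)
  expect_identical(assignSSHeuristic(mix)$ss, rep("C", 6))
  # undefined torsions are coil
  gap <- data.frame(resno = 1:2, insert = "", phi = c(NA, -57),
                    psi = c(-47, NA), ss = NA_character_)
  expect_identical(assignSSHeuristic(gap)$ss, rep("C", 2))
})

test_that("altLoc records resolve to the highest-occupancy conformer", {
  lines <- c(
    "ATOM      1  N  AALA A   1       0.000   0.000   0.000  0.40  0.00           N",
    "ATOM      2  N  BALA A   1       9.000   9.000   9.000  0.60  0.00           N",
    "ATOM      3  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      4  C   ALA A   1       2.009   1.421   0.000  1.00  0.00           C",
    "END")
  chain <- parsePdb(text = lines)
  expect_equal(chain@n[1, ], c(9, 9, 9))
})
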