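# run body with a private RNG stream, restoring global state afterwards
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Synthetic fixture specification constructor
#'
#' @param seed integer RNG seed fixing all outputs.
#' @param nStructures number of descriptor sequences to generate.
#' @param lengthRange residue-count range (inclusive).
#' @param runGeomProb success probability of the truncated geometric
#'   run-length distribution (mean run length about `1/runGeomProb`).
#' @param maxRunLength truncation point of the run-length distribution.
#' @param mutationRate default descriptor resampling fraction for
#'   [perturbFamily()].
#' @param noiseScale default coordinate noise (Angstroms) for
#'   [perturbBackbone()].
#' @return A [FixtureSpec-class].
#' @export
fixtureSpec <- function(seed = 1L, nStructures = 100L,
                        lengthRange = c(50L, 300L), runGeomProb = 0.25,
                        maxRunLength = 15L, mutationRate = 0.05,
                        noiseScale = 1) {
  new("FixtureSpec", seed = as.integer(seed),
      nStructures = as.integer(nStructures),
      lengthRange = as.integer(lengthRange), runGeomProb = runGeomProb,
      maxRunLength = as.integer(maxRunLength), mutationRate = mutationRate,
      noiseScale = noiseScale)
}

.runLengthProbs <- function(spec) {
  p <- spec@runGeomProb
  w <- p * (1 - p)^(0:(spec@maxRunLength - 1L))
  w / sum(w)
}

# descriptor frequencies mimic real chains: canonical helix (1) and the
# dominant strand region (5) carry most of the mass
.DESC_WEIGHTS <- c(0.28, 0.02, 0.03, 0.02, 0.28, 0.04, 0.03, 0.08, 0.08,
                   0.08, 0.04, 0.02)

#' Generate synthetic descriptor sequences
#'
#' Builds each sequence as a concatenation of maximal runs: run lengths are
#' drawn from a truncated geometric distribution and run descriptors from a
#' secondary-structure-like frequency profile dominated by descriptors 1
#' and 5, with consecutive runs forced to differ (so the drawn runs are the
#' maximal runs). Fully reproducible from the spec seed.
#'
#' @param spec a [FixtureSpec-class].
#' @return Named list of [DescriptorSequence-class] objects.
#' @export
generateDescriptorSet <- function(spec) {
  stopifnot(is(spec, "FixtureSpec"))
  probs <- .runLengthProbs(spec)
  .withSeed(spec@seed, {
    lapply(stats::setNames(seq_len(spec@nStructures),
                           sprintf("synth_%03d", seq_len(spec@nStructures))),
           function(i) {
      len <- sample(spec@lengthRange[1]:spec@lengthRange[2], 1L)
      d <- integer(0)
      prev <- 0L
      while (length(d) < len) {
        repeat {
          desc <- sample.int(12L, 1L, prob = .DESC_WEIGHTS)
          if (desc != prev) break
        }
        rl <- sample.int(spec@maxRunLength, 1L, prob = probs)
        d <- c(d, rep(desc, min(rl, len - length(d))))
        prev <- desc
      }
      descriptorSequence(d, id = sprintf("synth_%03d", i))
    })
  })
}

#' Perturbed descriptor-sequence family
#'
#' Derives `k` children from a parent sequence by resampling
#' `ceiling(rate * length)` positions uniformly over descriptors 1..12
#' (the resampled value may coincide with the original). The expected
#' multiset Jaccard similarity of child bags to the parent bag decreases
#' monotonically with `rate`.
#'
#' @param parent a [DescriptorSequence-class].
#' @param k number of children.
#' @param rate mutation rate in \[0, 1\].
#' @param seed RNG seed.
#' @return Named list of [DescriptorSequence-class] children
#'   (`<parent>_m1` ...).
#' @export
perturbFamily <- function(parent, k, rate, seed = 1L) {
  stopifnot(is(parent, "DescriptorSequence"), rate >= 0, rate <= 1)
  len <- length(parent@descriptors)
  nmut <- ceiling(rate * len)
  .withSeed(seed, {
    out <- lapply(seq_len(k), function(i) {
      d <- parent@descriptors
      if (nmut > 0L) {
        pos <- sample.int(len, nmut)
        d[pos] <- sample.int(12L, nmut, replace = TRUE)
      }
      descriptorSequence(d, id = sprintf("%s_m%d", parent@id, i))
    })
    names(out) <- vapply(out, structureId, character(1))
    out
  })
}

# NeRF atom placement: position D given A-B-C, bond length r(C-D), bond
# angle theta(B-C-D) and dihedral chi(A-B-C-D), angles in degrees.
.placeAtom <- function(a, b, c3, r, theta, chi) {
  th <- theta * pi / 180; ch <- chi * pi / 180
  bc <- c3 - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-r * cos(th), r * sin(th) * cos(ch), r * sin(th) * sin(ch))
  c3 + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Ideal-geometry backbone from torsion angles
#'
#' Forward-constructs N/CA/C coordinates with ideal bond lengths
#' (N-CA 1.458, CA-C 1.525, C-N 1.329 A), ideal bond angles and trans
#' peptide bonds (omega = 180), realizing the requested phi/psi at every
#' internal residue. `phi[1]` and `psi[n]` are unused (undefined at the
#' termini).
#'
#' @param phi,psi torsion angle vectors in degrees, equal length >= 2.
#' @param chainId chain label of the result.
#' @return A [BackboneChain-class].
#' @export
buildBackboneFromTorsions <- function(phi, psi, chainId = "A") {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 2L)
  N <- matrix(0, n, 3); CA <- matrix(0, n, 3); C <- matrix(0, n, 3)
  CA[1, ] <- c(1.458, 0, 0)
  th <- 111.2 * pi / 180
  C[1, ] <- CA[1, ] + 1.525 * c(-cos(th), sin(th), 0)
  for (i in 2:n) {
    N[i, ] <- .placeAtom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                         1.329, 116.2, psi[i - 1])
    CA[i, ] <- .placeAtom(CA[i - 1, ], C[i - 1, ], N[i, ],
                          1.458, 121.7, 180)
    C[i, ] <- .placeAtom(C[i - 1, ], N[i, ], CA[i, ],
                         1.525, 111.2, phi[i])
  }
  backboneChain(resno = seq_len(n), n = N, ca = CA, c = C,
                chainId = chainId)
}

.SEGMENT_TORSIONS <- list(H = c(-57, -47), E = c(-120, 135))

#' Toy backbone from a secondary-structure plan
#'
#' Builds an ideal-geometry backbone from a plan string like `"H8-C3-E5"`
#' (8 helix, 3 coil, 5 strand residues). Helix residues get canonical
#' (phi, psi) = (-57, -47), strand residues (-120, +135); coil residues
#' draw phi from (-160, -110) and psi from (-150, -100), windows that the
#' torsion-window heuristic classifies as coil.
#'
#' @param plan plan string: dash-separated `<H|E|C><count>` segments with
#'   positive counts.
#' @param seed RNG seed for the coil torsions.
#' @param chainId chain label.
#' @return A [BackboneChain-class].
#' @examples
#' buildToyBackbone("H8-C3-E5")
#' @export
buildToyBackbone <- function(plan, seed = 1L, chainId = "A") {
  segs <- strsplit(plan, "-", fixed = TRUE)[[1]]
  if (!length(segs) || !all(grepl("^[HEC][0-9]+$", segs))) {
    stop("malformed plan: expected segments like 'H8-C3-E5'")
  }
  type <- substr(segs, 1, 1)
  count <- as.integer(substring(segs, 2))
  if (any(count < 1L)) stop("malformed plan: segment lengths must be >= 1")
  .withSeed(seed, {
    phi <- numeric(0); psi <- numeric(0)
    for (s in seq_along(segs)) {
      if (type[s] == "C") {
        phi <- c(phi, stats::runif(count[s], -160, -110))
        psi <- c(psi, stats::runif(count[s], -150, -100))
      } else {
        t <- .SEGMENT_TORSIONS[[type[s]]]
        phi <- c(phi, rep(t[1], count[s]))
        psi <- c(psi, rep(t[2], count[s]))
      }
    }
    buildBackboneFromTorsions(phi, psi, chainId = chainId)
  })
}

#' Add Gaussian coordinate noise to a backbone
#'
#' Perturbs every backbone atom independently with isotropic Gaussian
#' noise; used to emulate structural divergence for alignment tests.
#'
#' @param chain a [BackboneChain-class].
#' @param noise standard deviation per coordinate, Angstroms.
#' @param seed RNG seed.
#' @return A perturbed [BackboneChain-class].
#' @export
perturbBackbone <- function(chain, noise, seed = 1L) {
  stopifnot(is(chain, "BackboneChain"), noise >= 0)
  .withSeed(seed, {
    jitter <- function(m) m + matrix(stats::rnorm(length(m), 0, noise),
                                     nrow(m), 3)
    backboneChain(resno = chain@resno, n = jitter(chain@n),
                  ca = jitter(chain@ca), c = jitter(chain@c),
                  o = chain@o, resid = chain@resid,
                  chainId = chain@chainId, insert = chain@insert)
  })
}
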