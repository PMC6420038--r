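#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of paired CA coordinates: returns the proper
#' rotation (determinant +1) and translation minimizing the RMSD of
#' `coordsB[pairing[,2], ] %*% rotation + translation` onto
#' `coordsA[pairing[,1], ]`, computed by singular value decomposition of
#' the cross-covariance with a chirality guard.
#'
#' @param coordsA,coordsB numeric matrices (n x 3) of coordinates.
#' @param pairing 2-column matrix of aligned row indices; defaults to the
#'   identity pairing (equal row counts required).
#' @return list with `rotation` (3x3), `translation` (length 3) and `rmsd`
#'   over the pairing, in Angstroms.
#' @export
kabschSuperpose <- function(coordsA, coordsB, pairing = NULL) {
  coordsA <- as.matrix(coordsA); coordsB <- as.matrix(coordsB)
  if (is.null(pairing)) {
    if (nrow(coordsA) != nrow(coordsB)) {
      stop("identity pairing needs equal numbers of coordinates")
    }
    pairing <- cbind(seq_len(nrow(coordsA)), seq_len(nrow(coordsA)))
  }
  if (nrow(pairing) < 3L) stop("need at least 3 aligned pairs")
  pa <- coordsA[pairing[, 1], , drop = FALSE]
  pb <- coordsB[pairing[, 2], , drop = FALSE]
  tr <- .kabschCore(pa, pb)
  if (is.null(tr)) {
    stop("rank-deficient configuration: superposition is not unique")
  }
  fitted <- .applyTransform(pb, tr)
  list(rotation = tr$rotation, translation = tr$translation,
       rmsd = sqrt(mean(rowSums((pa - fitted)^2))))
}

# unchecked least-squares fit of pb onto pa; NULL when degenerate
.kabschCore <- function(pa, pb) {
  mua <- colMeans(pa); mub <- colMeans(pb)
  ac <- pa; ac[, 1] <- ac[, 1] - mua[1]; ac[, 2] <- ac[, 2] - mua[2]
  ac[, 3] <- ac[, 3] - mua[3]
  bc <- pb; bc[, 1] <- bc[, 1] - mub[1]; bc[, 2] <- bc[, 2] - mub[2]
  bc[, 3] <- bc[, 3] - mub[3]
  h <- crossprod(bc, ac)
  sv <- tryCatch(svd(h), error = function(e) NULL)
  if (is.null(sv) || sv$d[2] < 1e-8 * max(sv$d[1], 1e-8)) return(NULL)
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  list(rotation = rot, translation = as.numeric(mua - mub %*% rot))
}

.applyTransform <- function(x, tr) {
  y <- x %*% tr$rotation
  y[, 1] <- y[, 1] + tr$translation[1]
  y[, 2] <- y[, 2] + tr$translation[2]
  y[, 3] <- y[, 3] + tr$translation[3]
  y
}

.tmD0 <- function(lnorm) {
  if (lnorm > 15) max(0.5, 1.24 * (lnorm - 15)^(1 / 3) - 1.8) else 0.5
}

.pairDist <- function(pa, pb) sqrt(rowSums((pa - pb)^2))

# TM-score of a fixed pairing, maximized over superpositions: iterative
# close-pair reseeding in the style of the TM-score rotation search.
# thorough = TRUE additionally tries half-alignment starting fragments.
.tmScoreSearch <- function(xa, xb, pairing, d0, lnorm, thorough = TRUE) {
  pa <- xa[pairing[, 1], , drop = FALSE]
  pb <- xb[pairing[, 2], , drop = FALSE]
  np <- nrow(pairing)
  best <- list(tm = -Inf, transform = NULL)
  starts <- list(seq_len(np))
  if (thorough && np >= 8L) {
    half <- np %/% 2L
    starts <- c(starts, list(1:half, (np - half + 1L):np))
  }
  for (sel in starts) {
    if (length(sel) < 3L) next
    tr <- .kabschCore(pa[sel, , drop = FALSE], pb[sel, , drop = FALSE])
    if (is.null(tr)) next
    prev <- integer(0)
    for (it in 1:8) {
      d <- .pairDist(pa, .applyTransform(pb, tr))
      tm <- sum(1 / (1 + (d / d0)^2)) / lnorm
      if (tm > best$tm) best <- list(tm = tm, transform = tr)
      cut <- d0
      repeat {
        sel2 <- which(d < cut)
        if (length(sel2) >= 3L) break
        cut <- cut + 0.5
      }
      if (identical(sel2, prev)) break
      prev <- sel2
      tr2 <- .kabschCore(pa[sel2, , drop = FALSE], pb[sel2, , drop = FALSE])
      if (is.null(tr2)) break
      tr <- tr2
    }
  }
  best
}

# cheap seed score: one superposition on the pairing, no iteration
.tmQuickScore <- function(xa, xb, pairing, d0, lnorm) {
  pa <- xa[pairing[, 1], , drop = FALSE]
  pb <- xb[pairing[, 2], , drop = FALSE]
  tr <- .kabschCore(pa, pb)
  if (is.null(tr)) return(-Inf)
  d <- .pairDist(pa, .applyTransform(pb, tr))
  sum(1 / (1 + (d / d0)^2)) / lnorm
}

.threadingSeeds <- function(la, lb) {
  minOv <- max(5L, min(la, lb) %/% 2L)
  ks <- seq(-(lb - minOv), la - minOv,
            by = max(2L, (la + lb) %/% 30L))
  lapply(ks, function(k) {
    i <- max(1L, 1L + k):min(la, lb + k)
    cbind(i, i - k)
  })
}

.ssSeed <- function(ssa, ssb) {
  a <- strsplit(ssa, "")[[1]]; b <- strsplit(ssb, "")[[1]]
  s <- outer(a, b, function(x, y) ifelse(x == y, 1, 0))
  cpp_nw_pairing(s, -1)
}

.tmAlignOne <- function(xa, xb, ssa, ssb, maxRounds, d0, lnorm, gapOpen) {
  la <- nrow(xa); lb <- nrow(xb)
  seeds <- .threadingSeeds(la, lb)
  scored <- vapply(seeds, function(p) {
    .tmQuickScore(xa, xb, p, d0, lnorm)
  }, numeric(1))
  seeds <- seeds[order(-scored)[seq_len(min(2L, length(seeds)))]]
  if (nzchar(ssa) && nzchar(ssb)) {
    p <- .ssSeed(ssa, ssb)
    if (nrow(p) >= 3L) seeds <- c(seeds, list(p))
  }
  best <- list(tm = -Inf, pairing = NULL, transform = NULL)
  for (pairing in seeds) {
    for (round in seq_len(max(1L, maxRounds))) {
      sc <- .tmScoreSearch(xa, xb, pairing, d0, lnorm, thorough = FALSE)
      if (sc$tm > best$tm) {
        best <- list(tm = sc$tm, pairing = pairing,
                     transform = sc$transform)
      }
      xbT <- .applyTransform(xb, sc$transform)
      d2 <- outer(rowSums(xa^2), rep(1, lb)) +
        outer(rep(1, la), rowSums(xbT^2)) - 2 * xa %*% t(xbT)
      d2[d2 < 0] <- 0
      s <- 1 / (1 + d2 / d0^2)
      newPairing <- cpp_nw_pairing(s, gapOpen)
      if (nrow(newPairing) < 3L || identical(newPairing, pairing)) break
      pairing <- newPairing
    }
    sc <- .tmScoreSearch(xa, xb, pairing, d0, lnorm)
    if (sc$tm > best$tm) {
      best <- list(tm = sc$tm, pairing = pairing, transform = sc$transform)
    }
  }
  best
}

# rotation- and translation-invariant canonical ordering of a chain pair:
# longer chain first, ties broken on the sorted centroid-distance profile
.canonicalFirst <- function(xa, xb) {
  if (nrow(xa) != nrow(xb)) return(nrow(xa) > nrow(xb))
  da <- .pairDist(xa, matrix(colMeans(xa), nrow(xa), 3, byrow = TRUE))
  db <- .pairDist(xb, matrix(colMeans(xb), nrow(xb), 3, byrow = TRUE))
  diffIdx <- which(abs(da - db) > 1e-9)
  if (length(diffIdx) == 0L) return(TRUE)
  da[diffIdx[1]] >= db[diffIdx[1]]
}

.chainCa <- function(x) {
  if (is(x, "BackboneChain")) x@ca else as.matrix(x)
}

.chainSS <- function(x) {
  if (is(x, "BackboneChain")) {
    paste(assignSSHeuristic(computeTorsions(x))$ss, collapse = "")
  } else ""
}

#' Iterative TM-score pairwise structure alignment
#'
#' Aligns two CA traces by the TM-score optimization scheme: seed
#' alignments (gapless threading at multiple offsets plus a
#' secondary-structure alignment when codes are available) are refined by
#' alternating dynamic programming over the TM-score distance kernel
#' `1 / (1 + (d_ij/d0)^2)` with superposition refreshes, until the pairing
#' converges or the round cap is reached. The TM-score is
#' `max over superpositions of (1/L_norm) * sum_i 1/(1 + (d_i/d0)^2)` with
#' `d0 = max(0.5, 1.24 (L_norm - 15)^(1/3) - 1.8)`, where `L_norm` is the
#' average length of the two structures (symmetric, the default) or the
#' query (first) length. Deterministic for fixed inputs.
#'
#' @param a,b [BackboneChain-class] objects or CA coordinate matrices
#'   (n x 3), at least 5 residues each.
#' @param iterations `"reduced"` (2 dynamic-programming rounds, used for
#'   shortlist screening), `"full"` (30 rounds) or an integer round cap.
#' @param normalization `"average"` (symmetric in argument order) or
#'   `"query"` (normalizes by the length of `a`).
#' @param ssA,ssB optional secondary-structure strings used for seeding
#'   when coordinate matrices are passed directly.
#' @param gapOpen dynamic-programming gap-opening penalty.
#' @return An [AlignmentResult-class]; its rotation/translation map `b`
#'   onto `a` and `rmsd` is the least-squares RMSD over the final pairing.
#' @export
tmAlignPair <- function(a, b, iterations = c("full", "reduced"),
                        normalization = c("average", "query"),
                        ssA = NULL, ssB = NULL, gapOpen = -0.6) {
  normalization <- match.arg(normalization)
  rounds <- if (is.numeric(iterations)) as.integer(iterations[1]) else {
    switch(match.arg(iterations), full = 30L, reduced = 2L)
  }
  xa <- .chainCa(a); xb <- .chainCa(b)
  if (nrow(xa) < 5L || nrow(xb) < 5L) {
    stop("chains must have at least 5 CA coordinates")
  }
  if (is.null(ssA)) ssA <- .chainSS(a)
  if (is.null(ssB)) ssB <- .chainSS(b)
  la <- nrow(xa); lb <- nrow(xb)
  lnorm <- if (normalization == "average") (la + lb) / 2 else la
  d0 <- .tmD0(lnorm)
  # under the symmetric normalization the pair is aligned in a canonical,
  # rotation-invariant argument order so that swapping the inputs cannot
  # change the score
  swap <- normalization == "average" && !.canonicalFirst(xa, xb)
  if (swap) {
    best <- .tmAlignOne(xb, xa, ssB, ssA, rounds, d0, lnorm, gapOpen)
    rot <- t(best$transform$rotation)
    best <- list(
      tm = best$tm,
      pairing = best$pairing[, 2:1, drop = FALSE],
      transform = list(
        rotation = rot,
        translation = as.numeric(-best$transform$translation %*% rot)))
  } else {
    best <- .tmAlignOne(xa, xb, ssA, ssB, rounds, d0, lnorm, gapOpen)
  }
  fit <- kabschSuperpose(xa, xb, best$pairing)
  new("AlignmentResult", tmScore = min(1, best$tm), rmsd = fit$rmsd,
      alignedLength = nrow(best$pairing),
      rotation = best$transform$rotation,
      translation = best$transform$translation,
      pairing = unname(best$pairing), normalization = normalization)
}
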