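#' Construct a backbone chain
#'
#' Low-level constructor used by [parsePdb()] and the toy-backbone builder.
#'
#' @param resno integer residue numbers.
#' @param n,ca,c numeric matrices (residues x 3), Angstroms.
#' @param o optional carbonyl-oxygen matrix (NA rows allowed).
#' @param resid three-letter residue codes (recycled if length 1).
#' @param chainId chain label.
#' @param insert insertion codes ("" when absent).
#' @return A [BackboneChain-class].
#' @export
backboneChain <- function(resno, n, ca, c, o = NULL, resid = "ALA",
                          chainId = "A", insert = "") {
  nres <- length(resno)
  if (is.null(o)) o <- matrix(NA_real_, nres, 3)
  new("BackboneChain", chainId = as.character(chainId),
      resno = as.integer(resno),
      insert = rep_len(as.character(insert), nres),
      resid = rep_len(as.character(resid), nres),
      n = as.matrix(n), ca = as.matrix(ca), c = as.matrix(c),
      o = as.matrix(o))
}

#' Parse a protein chain from PDB text or file
#'
#' Reads ATOM/HETATM records through `bio3d::read.pdb` (first model only),
#' restricts to the selected protein chain, resolves alternate locations by
#' highest occupancy (ties by altLoc label order), and keeps residues --
#' standard or not -- that carry a complete N/CA/C backbone.
#'
#' @param file path to a PDB file (ignored when `text` is given).
#' @param text character scalar or vector of PDB-format lines.
#' @param chain chain identifier to extract; `NULL` selects the first
#'   protein chain in the file.
#' @return A [BackboneChain-class].
#' @export
parsePdb <- function(file = NULL, text = NULL, chain = NULL) {
  if (!is.null(text)) {
    file <- tempfile(fileext = ".pdb")
    on.exit(unlink(file))
    writeLines(if (length(text) == 1L)
      strsplit(text, "\n", fixed = TRUE)[[1]] else text, file)
  }
  if (is.null(file)) stop("supply 'file' or 'text'")
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(file, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("PDB parse error: ", conditionMessage(e),
                             call. = FALSE))
  at <- pdb$atom
  # protein residues: anything with an N/CA/C backbone on a chain
  bb <- at[at$elety %in% c("N", "CA", "C", "O"), , drop = FALSE]
  if (nrow(bb) == 0L) stop("no protein chain found: no backbone ATOM records")
  chains <- unique(bb$chain)
  if (is.null(chain)) {
    chain <- chains[1]
  } else if (!chain %in% chains) {
    stop(sprintf("chain '%s' not found (available: %s)", chain,
                 paste(chains, collapse = ", ")))
  }
  bb <- bb[bb$chain %in% chain, , drop = FALSE]
  bb$insert[is.na(bb$insert)] <- ""
  bb$alt[is.na(bb$alt)] <- ""
  bb$o[is.na(bb$o)] <- 1
  # resolve altLoc: highest occupancy, ties by altLoc label order
  ord <- order(-bb$o, bb$alt)
  bb <- bb[ord, , drop = FALSE]
  key <- paste(bb$resno, bb$insert, bb$elety, sep = "|")
  bb <- bb[!duplicated(key), , drop = FALSE]
  # restore residue order of appearance, atoms within residue as N,CA,C,O
  rkey <- paste(bb$resno, bb$insert, sep = "|")
  rorder <- unique(paste(at$resno, ifelse(is.na(at$insert), "", at$insert),
                         sep = "|")[at$chain %in% chain])
  res <- rorder[rorder %in% rkey]
  pick <- function(ety) {
    m <- matrix(NA_real_, length(res), 3)
    sub <- bb[bb$elety == ety, , drop = FALSE]
    idx <- match(paste(sub$resno, sub$insert, sep = "|"), res)
    m[idx[!is.na(idx)], ] <- as.matrix(
      sub[!is.na(idx), c("x", "y", "z")])
    m
  }
  n <- pick("N"); ca <- pick("CA"); cc <- pick("C"); o <- pick("O")
  complete <- stats::complete.cases(n) & stats::complete.cases(ca) &
    stats::complete.cases(cc)
  if (!any(complete)) stop("no protein chain found: no complete backbones")
  keep <- which(complete)
  info <- bb[match(res[keep], paste(bb$resno, bb$insert, sep = "|")), ]
  backboneChain(resno = info$resno, n = n[keep, , drop = FALSE],
                ca = ca[keep, , drop = FALSE], c = cc[keep, , drop = FALSE],
                o = o[keep, , drop = FALSE], resid = info$resid,
                chainId = chain, insert = info$insert)
}

#' Write a backbone chain as PDB text
#'
#' Emits fixed-width ATOM records (N, CA, C and O where present) for a
#' [BackboneChain-class]; the inverse of [parsePdb()] for backbone-only
#' models.
#'
#' @param chain a [BackboneChain-class].
#' @param path optional output file; when `NULL` the lines are returned.
#' @return Character vector of PDB lines (invisibly when writing).
#' @export
writePdb <- function(chain, path = NULL) {
  stopifnot(is(chain, "BackboneChain"))
  lines <- character(0)
  serial <- 0L
  for (i in seq_along(chain@resno)) {
    for (ety in c("N", "CA", "C", "O")) {
      xyz <- slot(chain, tolower(ety))[i, ]
      if (anyNA(xyz)) next
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s%4s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           %1s",
        serial, ety, chain@resid[i], chain@chainId, chain@resno[i],
        ifelse(nzchar(chain@insert[i]), chain@insert[i], " "),
        xyz[1], xyz[2], xyz[3], 1, 0, substr(ety, 1, 1)))
    }
  }
  lines <- c(lines, "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

# Signed dihedral (degrees) for rows of four coordinate matrices.
# Normalized to (-180, 180]; degenerate (collinear) rows give NA.
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(u, v) {
    cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
          u[, 3] * v[, 1] - u[, 1] * v[, 3],
          u[, 1] * v[, 2] - u[, 2] * v[, 1])
  }
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  nb2 <- sqrt(rowSums(b2^2))
  m1 <- cross(n1, b2 / nb2)
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  # IUPAC sign convention (matches bio3d::torsion.xyz)
  ang <- -atan2(y, x) * 180 / pi
  deg <- sqrt(rowSums(n1^2)) < 1e-9 | sqrt(rowSums(n2^2)) < 1e-9 |
    nb2 < 1e-9
  ang[deg] <- NA_real_
  # half-open convention: -180 maps to +180
  ang[!is.na(ang) & ang <= -180] <- 180
  ang
}

#' Backbone torsion angles of a chain
#'
#' Computes per-residue phi (C(i-1), N(i), CA(i), C(i)) and psi (N(i),
#' CA(i), C(i), N(i+1)) dihedrals in degrees, normalized to (-180, 180]
#' with -180 reported as +180. Consecutive residues count as bonded only
#' when the C(i)-N(i+1) distance does not exceed `breakCutoff`; angles are
#' `NA` at termini and across chain breaks. Degenerate (collinear)
#' geometry yields `NA` with a warning.
#'
#' @param chain a [BackboneChain-class] with at least 2 residues.
#' @param breakCutoff chain-break distance cutoff in Angstroms (the peptide
#'   C-N bond is about 1.33 A).
#' @return data.frame with columns `resno`, `insert`, `phi`, `psi` and an
#'   unassigned `ss` column.
#' @export
computeTorsions <- function(chain, breakCutoff = 2.5) {
  stopifnot(is(chain, "BackboneChain"))
  nres <- length(chain@resno)
  if (nres < 2L) stop("need at least 2 residues to compute torsions")
  cn <- sqrt(rowSums((chain@c[-nres, , drop = FALSE] -
                        chain@n[-1, , drop = FALSE])^2))
  bonded <- cn <= breakCutoff            # bonded[i]: i -- i+1
  phi <- rep(NA_real_, nres)
  psi <- rep(NA_real_, nres)
  iPhi <- which(c(FALSE, bonded))        # residues with a bonded predecessor
  if (length(iPhi)) {
    phi[iPhi] <- .dihedral(chain@c[iPhi - 1L, , drop = FALSE],
                           chain@n[iPhi, , drop = FALSE],
                           chain@ca[iPhi, , drop = FALSE],
                           chain@c[iPhi, , drop = FALSE])
  }
  iPsi <- which(c(bonded, FALSE))        # residues with a bonded successor
  if (length(iPsi)) {
    psi[iPsi] <- .dihedral(chain@n[iPsi, , drop = FALSE],
                           chain@ca[iPsi, , drop = FALSE],
                           chain@c[iPsi, , drop = FALSE],
                           chain@n[iPsi + 1L, , drop = FALSE])
  }
  if (anyNA(phi[iPhi]) || anyNA(psi[iPsi])) {
    warning("degenerate geometry: some torsions reported as undefined")
  }
  data.frame(resno = chain@resno, insert = chain@insert, phi = phi,
             psi = psi, ss = NA_character_, stringsAsFactors = FALSE)
}

#' Read secondary structure from classic DSSP output
#'
#' Parses the columnar residue block of a classic DSSP output file. Blank
#' structure codes map to 'C'; chain-break marker lines ('!') are skipped;
#' insertion codes are preserved in the residue identifiers.
#'
#' @param file path to a DSSP output file (ignored when `text` given).
#' @param text character scalar or vector of DSSP output lines.
#' @return Named character vector of one-letter codes in
#'   \{G,H,I,E,S,C,T,B\}; names are `"<chain>:<resno><icode>"`.
#' @export
readDssp <- function(file = NULL, text = NULL) {
  lines <- if (!is.null(text)) {
    if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  } else readLines(file, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0L) {
    stop("malformed DSSP output: residue header line not found")
  }
  body <- lines[seq(hdr[1] + 1L, length(lines))]
  body <- body[nchar(body) >= 17]
  aa <- substr(body, 14, 14)
  body <- body[aa != "!"]               # chain-break markers
  if (length(body) == 0L) return(stats::setNames(character(0), character(0)))
  resno <- as.integer(substr(body, 6, 10))
  icode <- trimws(substr(body, 11, 11))
  chain <- trimws(substr(body, 12, 12))
  ss <- substr(body, 17, 17)
  ss[ss == " "] <- "C"
  bad <- !ss %in% c("G", "H", "I", "E", "S", "C", "T", "B")
  if (any(bad)) ss[bad] <- "C"
  stats::setNames(ss, paste0(chain, ":", resno, icode))
}

.inWindow <- function(x, lo, hi) !is.na(x) & x > lo & x <= hi

# run-length gate: TRUE only inside maximal runs of `flag` of length >= k
.gateRuns <- function(flag, k) {
  r <- rle(flag)
  r$values <- r$values & r$lengths >= k
  inverse.rle(r)
}

#' Heuristic secondary-structure assignment from torsions
#'
#' A coarse stand-in for DSSP when no DSSP output file is available:
#' assigns 'H' to runs of at least 4 residues with phi in (-100, -30) and
#' psi in (-80, -5); 'E' to runs of at least 2 residues with phi in
#' (-180, -40) and psi in (90, 180] or (-180, -170); everything else
#' (including residues with undefined torsions) is 'C'. This is a
#' torsion-window approximation, not a reimplementation of DSSP's
#' hydrogen-bond calculus: it never emits G/I/S/T/B.
#'
#' @param geometries data.frame from [computeTorsions()].
#' @return The same data.frame with the `ss` column filled.
#' @export
assignSSHeuristic <- function(geometries) {
  phi <- geometries$phi; psi <- geometries$psi
  hWin <- .inWindow(phi, -100, -30) & .inWindow(psi, -80, -5)
  eWin <- .inWindow(phi, -180, -40) &
    (.inWindow(psi, 90, 180) | .inWindow(psi, -180, -170))
  ss <- rep("C", length(phi))
  ss[.gateRuns(eWin, 2L)] <- "E"
  ss[.gateRuns(hWin, 4L)] <- "H"
  geometries$ss <- ss
  geometries
}

#' Attach DSSP codes to computed torsions
#'
#' Joins a DSSP code map from [readDssp()] onto a torsion table by chain,
#' residue number and insertion code; residues missing from the map keep
#' an unassigned (`NA`) code.
#'
#' @param geometries data.frame from [computeTorsions()].
#' @param dssp named code vector from [readDssp()].
#' @param chainId chain identifier used in the DSSP names.
#' @return The torsion data.frame with `ss` filled where known.
#' @export
applyDssp <- function(geometries, dssp, chainId = "A") {
  key <- paste0(chainId, ":", geometries$resno, trimws(geometries$insert))
  hit <- match(key, names(dssp))
  geometries$ss <- ifelse(is.na(hit), geometries$ss, unname(dssp[hit]))
  geometries
}
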