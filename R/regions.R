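.regionGroupFrame <- function(lst) {
  do.call(rbind, lapply(lst, function(r) {
    b <- as.numeric(r$box)
    data.frame(descriptor = as.integer(r$descriptor), phiMin = b[1],
               phiMax = b[2], psiMin = b[3], psiMax = b[4])
  }))
}

#' Read a torsion-region configuration
#'
#' Loads a [RegionMap-class] from a JSON configuration file. Each group
#' (`helix`, `strand`, `coil`) lists boxes `[phiMin, phiMax, psiMin,
#' psiMax]` in degrees, tried in order; `min > max` denotes an interval
#' wrapped across the +/-180 degree seam, and the last box of each group
#' must absorb all remaining angles.
#'
#' @param path path to the JSON file.
#' @return A [RegionMap-class].
#' @export
readRegionMap <- function(path) {
  cfg <- jsonlite::read_json(path)
  for (g in c("helix", "strand", "coil")) {
    if (is.null(cfg[[g]])) stop("region config must define group '", g, "'")
  }
  new("RegionMap", helix = .regionGroupFrame(cfg$helix),
      strand = .regionGroupFrame(cfg$strand),
      coil = .regionGroupFrame(cfg$coil))
}

#' Built-in default torsion-region map
#'
#' The region boundaries shipped with the package: qualitative axis-aligned
#' boxes around the canonical right- and left-handed helical, extended
#' beta/polyproline and alpha-like basins, with an absorbing default region
#' per group. Boundaries are a configuration, not a calibration: users can
#' refine them via [readRegionMap()].
#'
#' @return A [RegionMap-class].
#' @examples
#' defaultRegionMap()
#' @export
defaultRegionMap <- function() {
  readRegionMap(system.file("extdata", "region_map.json", package = "rupee",
                            mustWork = TRUE))
}

# interval membership with wrap-around; angles live in (-180, 180]
.inBox <- function(x, lo, hi) {
  ifelse(rep(lo <= hi, length(x)), x >= lo & x <= hi, x >= lo | x <= hi)
}

.assignGroup <- function(phi, psi, grp) {
  out <- rep(NA_integer_, length(phi))
  for (r in seq_len(nrow(grp))) {
    hit <- is.na(out) & .inBox(phi, grp$phiMin[r], grp$phiMax[r]) &
      .inBox(psi, grp$psiMin[r], grp$psiMax[r])
    out[hit] <- grp$descriptor[r]
  }
  out
}

#' Assign residue descriptors from torsions and secondary structure
#'
#' Turns ('T') map to descriptor 11 and bridges ('B') to 12 regardless of
#' torsions; the remaining six DSSP codes are grouped (helix G/H/I, strand
#' E, bend/coil S/C) and the (phi, psi) point is placed in the group's
#' first matching torsion region (helix 1-4, strand 5-7, bend/coil 8-10).
#'
#' @param phi,psi torsion angles in degrees, vectors.
#' @param ss one-letter DSSP codes, same length.
#' @param regions a [RegionMap-class]; default [defaultRegionMap()].
#' @return Integer descriptors in 1..12.
#' @examples
#' assignDescriptor(-120, 135, "E")   # dominant strand region -> 5
#' assignDescriptor(0, 0, "T")        # turn -> 11
#' @export
assignDescriptor <- function(phi, psi, ss, regions = defaultRegionMap()) {
  stopifnot(is(regions, "RegionMap"))
  nr <- max(length(phi), length(psi), length(ss))
  phi <- rep_len(phi, nr); psi <- rep_len(psi, nr); ss <- rep_len(ss, nr)
  if (anyNA(ss)) stop("secondary-structure codes must be assigned")
  out <- rep(NA_integer_, nr)
  out[ss == "T"] <- 11L
  out[ss == "B"] <- 12L
  grpIdx <- list(helix = ss %in% c("G", "H", "I"), strand = ss == "E",
                 coil = ss %in% c("S", "C"))
  for (g in names(grpIdx)) {
    sel <- grpIdx[[g]]
    if (any(sel)) {
      if (anyNA(phi[sel]) || anyNA(psi[sel])) {
        stop("torsions must be defined for region assignment")
      }
      out[sel] <- .assignGroup(phi[sel], psi[sel], slot(regions, g))
    }
  }
  if (anyNA(out)) stop("unrecognized secondary-structure code")
  out
}
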