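# Solvent-accessible surface area by the Shrake-Rupley rolling-probe
# point-counting method, with a Fibonacci-lattice sphere sampling.

# Bondi van der Waals radii (A) for the elements found in proteins.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
               P = 1.80, SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

#' Quasi-uniform points on the unit sphere (Fibonacci lattice)
#'
#' @param n number of points (>= 1).
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Per-residue solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a spherical probe over the heavy-atom surface: each atom is
#' expanded by the probe radius, `n_points` quasi-uniform test points are
#' placed on the expanded sphere, and the accessible fraction (points not
#' inside any neighbouring expanded sphere) scales the sphere area
#' 4*pi*(r+probe)^2. Atom areas are summed per residue.
#'
#' @param state a `conf_state` (its full heavy-atom table is used), or a
#'   data.frame of atoms with columns x, y, z, element, chain, resno.
#' @param probe probe radius in A (water: 1.4).
#' @param n_points points per atom sphere (>= 92).
#' @return data.frame with chain, resno, resid (when available) and
#'   `sasa` in A^2, one row per residue, in first-appearance order.
#' @export
shrake_rupley_sasa <- function(state, probe = 1.4, n_points = 960) {
  stopifnot(probe > 0, n_points >= 92)
  at <- if (inherits(state, "conf_state")) state$atoms else state
  stopifnot(is.data.frame(at), nrow(at) >= 1)
  el <- toupper(at$element)
  unknown <- !(el %in% names(VDW_RADII))
  if (any(unknown)) {
    i <- which(unknown)[1]
    stop("unknown element '", at$element[i], "' for atom ",
         if (!is.null(at$elety)) at$elety[i] else i,
         " in residue ", at$chain[i], ":", at$resno[i])
  }
  area <- atom_sasa(as.matrix(at[, c("x", "y", "z")]),
                    VDW_RADII[el] + probe, n_points)
  key <- paste(at$chain, at$resno, sep = "|")
  ord <- unique(key)
  tot <- vapply(split(area, factor(key, levels = ord)), sum, 0)
  out <- data.frame(chain = at$chain[match(ord, key)],
                    resno = at$resno[match(ord, key)],
                    sasa = as.numeric(tot), stringsAsFactors = FALSE)
  if (!is.null(at$resid)) out$resid <- at$resid[match(ord, key)]
  rownames(out) <- NULL
  out[, intersect(c("chain", "resno", "resid", "sasa"), names(out))]
}

# per-atom accessible area; R = expanded radii (r_vdw + probe)
atom_sasa <- function(xyz, R, n_points) {
  n <- nrow(xyz)
  pts <- fibonacci_sphere(n_points)
  # neighbour lists from squared distances (n is a few thousand at most)
  d2 <- as.matrix(stats::dist(xyz))^2
  area <- numeric(n)
  for (i in seq_len(n)) {
    cut <- (R[i] + R)^2
    nb <- which(d2[i, ] < cut & seq_len(n) != i)
    p <- sweep(pts * R[i], 2, xyz[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dx <- p[acc, 1] - xyz[j, 1]
      dy <- p[acc, 2] - xyz[j, 2]
      dz <- p[acc, 3] - xyz[j, 3]
      acc[acc] <- (dx * dx + dy * dy + dz * dz) >= R[j]^2
    }
    area[i] <- 4 * pi * R[i]^2 * sum(acc) / n_points
  }
  area
}

# Maximum accessible surface areas (A^2) in a Gly-X-Gly tripeptide,
# theoretical values of Tien et al. (2013), used to normalize absolute SASA.
MAX_SASA_GXG <- c(
  ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
  GLN = 225.0, GLU = 223.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
  LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
  SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0)

#' Relative solvent accessibility
#'
#' Absolute SASA divided by the residue type's maximum exposure in a
#' Gly-X-Gly tripeptide. Values above 1 (distorted geometry) are reported
#' as-is, not clipped.
#'
#' @param abs_sasa absolute SASA in A^2 (vectorized).
#' @param residue_name 3-letter residue code(s).
#' @return relative SASA fraction(s).
#' @export
relative_sasa <- function(abs_sasa, residue_name) {
  rn <- toupper(residue_name)
  bad <- !(rn %in% names(MAX_SASA_GXG))
  if (any(bad)) {
    stop("no maximum-SASA reference for residue type(s): ",
         paste(unique(rn[bad]), collapse = ", "))
  }
  unname(as.numeric(abs_sasa) / MAX_SASA_GXG[rn])
}

#' Maximum-SASA reference table (Gly-X-Gly scale)
#'
#' @return named numeric vector of maximum accessible areas (A^2) per
#'   3-letter residue code.
#' @export
max_sasa_reference <- function() MAX_SASA_GXG
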