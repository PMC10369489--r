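# Solvent-accessible surface area by Shrake-Rupley sphere-point sampling.
# Each atom is inflated by the probe radius and covered with a deterministic
# quasi-uniform point set; the accessible fraction is the fraction of points
# not swallowed by any neighboring inflated sphere.

# van der Waals radii (Angstrom), Bondi-style set.
.vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
                SE = 1.90)

# Maximum solvent-accessible surface area per residue type (Angstrom^2),
# theoretical Gly-X-Gly tripeptide values (Tien et al. 2013). Used to convert
# a residue's buried area into a percentage of its maximal exposure.
.max_sasa_table <- c(
  ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
  GLN = 225.0, GLU = 223.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
  LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
  SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0)

# Deterministic quasi-uniform points on the unit sphere (golden-spiral
# lattice).
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  az <- golden * (seq_len(n) - 1)
  cbind(r * cos(az), r * sin(az), z)
}

.atom_radii <- function(elements, radii = NULL) {
  tab <- .vdw_radii
  if (!is.null(radii)) tab[toupper(names(radii))] <- radii
  r <- unname(tab[toupper(elements)])
  if (anyNA(r)) {
    bad <- sort(unique(elements[is.na(r)]))
    stop("no van der Waals radius for element(s): ",
         paste(bad, collapse = ", "),
         " (supply them via the 'radii' argument)", call. = FALSE)
  }
  r
}

# Per-atom SASA (Angstrom^2) for a coordinate set.
.atom_sasa <- function(coords, radii, probe = 1.4, n_points = 960L) {
  coords <- .as_coord_matrix(coords)
  n <- nrow(coords)
  big <- radii + probe
  pts <- .sphere_points(n_points)
  # neighbor lists from squared distances
  d2 <- as.matrix(stats::dist(coords))^2
  out <- numeric(n)
  for (i in seq_len(n)) {
    lim <- (big[i] + big)^2
    nb <- which(d2[i, ] < lim)
    nb <- nb[nb != i]
    surf <- sweep(pts * big[i], 2L, coords[i, ], "+")
    if (length(nb)) {
      acc <- rep(TRUE, n_points)
      for (j in nb) {
        dj <- (surf[, 1L] - coords[j, 1L])^2 +
              (surf[, 2L] - coords[j, 2L])^2 +
              (surf[, 3L] - coords[j, 3L])^2
        acc <- acc & dj >= big[j]^2
        if (!any(acc)) break
      }
      frac <- sum(acc) / n_points
    } else {
      frac <- 1
    }
    out[i] <- 4 * pi * big[i]^2 * frac
  }
  out
}

#' Per-residue solvent-accessible surface area
#'
#' Computes the SASA of every residue of a structure with the Shrake-Rupley
#' algorithm: each atom's sphere (van der Waals radius plus probe radius) is
#' sampled with a deterministic quasi-uniform point lattice and the area is
#' the unblocked fraction of the sphere. Residue areas are sums over their
#' atoms, so the residue areas add up exactly to the total molecular SASA.
#'
#' @param structure A [molstruct()].
#' @param probe Probe radius in Angstrom (default 1.4, a water molecule).
#' @param n_points Sample points per atom (default 960; accuracy improves
#'   roughly with the square root of this number).
#' @param model Model number (default 1).
#' @param radii Optional named vector of van der Waals radii overriding or
#'   extending the built-in element table (names are element symbols).
#' @return A data frame with one row per residue: `chain`, `resno`, `resid`
#'   and `area` (Angstrom^2), plus the per-atom areas as attribute
#'   `atom_area` and the total as attribute `total`.
#' @export
residue_sasa <- function(structure, probe = 1.4, n_points = 960L,
                         model = 1L, radii = NULL) {
  stopifnot(inherits(structure, "molstruct"))
  at <- structure$atoms
  r <- .atom_radii(at$element, radii)
  a <- .atom_sasa(structure_coords(structure, model), r,
                  probe = probe, n_points = as.integer(n_points))
  key <- paste(at$chain, at$resno, sep = "\r")
  first <- !duplicated(key)
  res <- data.frame(chain = at$chain[first], resno = at$resno[first],
                    resid = at$resid[first],
                    area = as.numeric(tapply(a, factor(key, levels = key[first]),
                                             sum)),
                    stringsAsFactors = FALSE)
  attr(res, "atom_area") <- a
  attr(res, "total") <- sum(a)
  res
}
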