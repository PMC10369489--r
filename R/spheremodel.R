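# Idealized two-sphere dimer and its propagation into a chain of tangent
# spheres. Lengths are in sphere-radius units: monomers are unit spheres with
# centers 2 apart.

# Polar position of the interface marker on sphere A for a requested
# polymerization angle. With the marker at (cos a, sin a, 0) and centers at
# the origin and (-2, 0, 0), cos(theta) = (1 + 2 cos a) / sqrt(5 + 4 cos a);
# inverting the quadratic gives a closed form, monotone over (0, 180).
.marker_alpha <- function(theta) {
  ct <- cos(.deg2rad(theta))
  c_ <- (-sin(.deg2rad(theta))^2 + ct * sqrt(ct^2 + 3)) / 2
  acos(max(-1, min(1, c_)))
}

# Rotation about the x axis (the inter-center axis) by `a` radians.
.rot_x <- function(a) {
  matrix(c(1, 0, 0,
           0, cos(a), -sin(a),
           0, sin(a), cos(a)), 3L, 3L, byrow = TRUE)
}

# Next center of an ideal chain with bond length `l`, bond angle `beta` and
# torsion `tau` (degrees), given the three preceding centers: the natural
# extension reference frame used by polymer-chain builders.
.extend_chain <- function(c1, c2, c3, l, beta, tau) {
  b <- .unit(c3 - c2, "chain bond")
  nrm <- .unit(.cross3(c2 - c1, b), "chain plane normal")
  m <- .cross3(nrm, b)
  br <- .deg2rad(180 - beta)
  tr <- .deg2rad(tau)
  c3 + l * cos(br) * b + l * sin(br) * cos(tr) * m + l * sin(br) * sin(tr) * nrm
}

# Exact generator transform mapping the center triplet (c1, c2, c3) onto
# (c2, c3, c4): orthonormal frames built from consecutive bonds.
.triplet_transform <- function(p, q) {
  frame <- function(a, b, cc) {
    u <- .unit(b - a)
    w <- .unit(.cross3(u, cc - b))
    cbind(u, .cross3(w, u), w)
  }
  f1 <- frame(p[1, ], p[2, ], p[3, ])
  f2 <- frame(q[1, ], q[2, ], q[3, ])
  rot <- f2 %*% t(f1)
  rigid_transform(rot, q[1, ] - as.numeric(rot %*% p[1, ]))
}

#' Build the two-sphere model of a dimer
#'
#' Constructs the idealized dimer used by the growth landscape: two tangent
#' unit spheres, monomer A centered at the origin and monomer B at
#' `(-2, 0, 0)`, decorated with interface markers that realize a requested
#' polymerization angle and dihedral. The marker of A is placed on its
#' surface in the upper half of the xy plane at the (closed-form) polar
#' position giving exactly `theta`; the marker of B is placed at the mirrored
#' polar position and rotated about the inter-center axis until the dihedral
#' equals `phi`. Measuring the construction with
#' [polymerization_angle()] / [polymerization_dihedral()] recovers
#' `(theta, phi)` to numerical precision.
#'
#' The propagation transform `T` maps each monomer onto its successor.
#' Because the two angles constrain only the interface, the remaining rigid
#' degrees of freedom of the propagation are fixed by an ideal-chain
#' convention: successive sphere centers form a chain with bond length 2,
#' bond angle `theta` and torsion `phi` (see the package vignette for why
#' this convention, and not a marker-frame alignment, reproduces the growth
#' landscape). For `theta = 180` the transform degenerates to a pure
#' translation by 2 along the inter-center axis (straight chain); for
#' `theta = 0` it is the half-turn that folds the chain back onto itself.
#'
#' @param theta Polymerization angle in degrees, in `[0, 180]`.
#' @param phi Polymerization dihedral in degrees, in `[0, 180]`.
#' @return An object of class `sphere_dimer`: centers and interface markers
#'   of both spheres, the requested angles, and the propagation transform
#'   `transform` (a [rigid_transform()] with translation length 2).
#' @examples
#' sd <- build_sphere_dimer(81, 160)  # an open, unlimited-growth interface
#' polymerization_angle(sd$center_a, sd$center_b, sd$marker_a)
#' @export
build_sphere_dimer <- function(theta, phi) {
  theta <- as.numeric(theta)
  phi <- as.numeric(phi)
  if (!is.finite(theta) || theta < 0 || theta > 180) {
    stop("'theta' must lie in [0, 180] degrees", call. = FALSE)
  }
  if (!is.finite(phi) || phi < 0 || phi > 180) {
    stop("'phi' must lie in [0, 180] degrees", call. = FALSE)
  }
  center_a <- c(0, 0, 0)
  center_b <- c(-2, 0, 0)

  degenerate <- theta < 1e-9 || theta > 180 - 1e-9
  if (degenerate) {
    # Markers collapse onto the inter-center axis.
    if (theta > 90) {
      marker_a <- c(-1, 0, 0)
      marker_b <- c(-1, 0, 0)
      transform <- rigid_transform(diag(3), center_b)          # straight chain
    } else {
      marker_a <- c(1, 0, 0)
      marker_b <- c(-3, 0, 0)
      transform <- rigid_transform(diag(c(-1, 1, -1)), center_b) # fold-back
    }
  } else {
    a <- .marker_alpha(theta)
    marker_a <- c(cos(a), sin(a), 0)
    mirrored <- c(-2 - cos(a), sin(a), 0)
    rho <- .deg2rad(180 - phi)
    marker_b <- center_b + as.numeric(.rot_x(rho) %*% (mirrored - center_b))
    # Ideal-chain propagation: bond length 2, bond angle theta, torsion phi.
    c3 <- center_b + 2 * c(cos(.deg2rad(theta)), sin(.deg2rad(theta)), 0)
    c4 <- .extend_chain(center_a, center_b, c3, 2, theta, -phi)
    transform <- .triplet_transform(rbind(center_a, center_b, c3),
                                    rbind(center_b, c3, c4))
  }
  structure(list(center_a = center_a, center_b = center_b,
                 marker_a = marker_a, marker_b = marker_b,
                 theta = theta, phi = phi,
                 transform = transform),
            class = "sphere_dimer")
}

#' @export
print.sphere_dimer <- function(x, ...) {
  cat(sprintf("Sphere dimer: theta = %.2f deg, phi = %.2f deg\n",
              x$theta, x$phi))
  print(x$transform)
  invisible(x)
}

#' Propagate a sphere dimer into a chain
#'
#' Applies the dimer's propagation transform repeatedly to generate the
#' centers of an `n`-monomer chain of tangent unit spheres: center `k` is
#' `T^(k-1)` applied to the origin. Rigidity of the transform guarantees all
#' consecutive centers stay exactly 2 radii apart.
#'
#' @param dimer A [build_sphere_dimer()] result.
#' @param n Number of monomers (>= 2).
#' @return An object of class `sphere_chain`: `centers` (n x 3 matrix),
#'   `n`, `radius` (1), the generating `transform` and the defining angles.
#' @export
propagate_chain <- function(dimer, n) {
  stopifnot(inherits(dimer, "sphere_dimer"))
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("'n' must be at least 2", call. = FALSE)
  centers <- matrix(0, n, 3L)
  x <- c(0, 0, 0)
  for (k in 2:n) {
    x <- apply_transform(dimer$transform, x)
    centers[k, ] <- x
  }
  structure(list(centers = centers, n = n, radius = 1,
                 transform = dimer$transform,
                 theta = dimer$theta, phi = dimer$phi),
            class = "sphere_chain")
}

#' @export
print.sphere_chain <- function(x, ...) {
  cat(sprintf("Sphere chain: %d monomers, theta = %.2f deg, phi = %.2f deg\n",
              x$n, x$theta, x$phi))
  invisible(x)
}

#' Detect overlapping spheres in a chain
#'
#' Two non-adjacent monomers overlap when their centers come closer than
#' `2 * (1 - delta)` radii; consecutive monomers are tangent by construction
#' and are excluded via the index gap. A small tolerance `delta` prevents
#' exact tangency (e.g. a chain that closes into a perfect ring of touching
#' spheres) from being counted as a collision.
#'
#' @param chain A [propagate_chain()] result, or any object with a `centers`
#'   matrix.
#' @param delta Overlap tolerance as a fraction of the diameter
#'   (default 0.05).
#' @param min_gap Minimum index separation for a pair to be tested
#'   (default 2).
#' @return A list with `pairs` (two-column matrix of overlapping index pairs,
#'   1-based, ordered by first then second index; zero rows when none),
#'   `min_distance` (smallest distance among tested pairs) and `first_pair`
#'   (the earliest overlapping pair or `NULL`).
#' @export
detect_overlap <- function(chain, delta = 0.05, min_gap = 2L) {
  centers <- if (is.matrix(chain)) chain else chain$centers
  centers <- .as_coord_matrix(centers, "centers")
  n <- nrow(centers)
  min_gap <- as.integer(min_gap)
  if (min_gap < 1L) stop("'min_gap' must be >= 1", call. = FALSE)
  cutoff <- 2 * (1 - delta)
  d <- as.matrix(stats::dist(centers))
  idx <- which(upper.tri(d), arr.ind = TRUE)
  idx <- idx[idx[, 2L] - idx[, 1L] >= min_gap, , drop = FALSE]
  if (nrow(idx) == 0L) {
    return(list(pairs = matrix(integer(), 0L, 2L),
                min_distance = Inf, first_pair = NULL))
  }
  dv <- d[idx]
  hit <- dv < cutoff
  pairs <- idx[hit, , drop = FALSE]
  ord <- order(pairs[, 1L], pairs[, 2L])
  pairs <- pairs[ord, , drop = FALSE]
  colnames(pairs) <- c("i", "j")
  list(pairs = pairs,
       min_distance = min(dv),
       first_pair = if (nrow(pairs)) pairs[1L, ] else NULL)
}

#' Screw decomposition of a rigid transform
#'
#' Every proper rigid motion is a screw: a rotation by angle `omega` about an
#' axis combined with a translation (the pitch) along that axis. Iterated, a
#' screw generates a helix (pitch away from 0), a closed ring (pitch near 0,
#' rotation away from 0) or a straight line (rotation near 0).
#'
#' @param transform A [rigid_transform()].
#' @return A list with `axis` (unit 3-vector), `angle` (degrees, in
#'   `[0, 180]`) and `pitch` (translation component along the axis per
#'   application; for a near-zero rotation the axis is the translation
#'   direction and the pitch the full translation length).
#' @export
screw_parameters <- function(transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  r <- transform$rotation
  t <- transform$translation
  omega <- acos(max(-1, min(1, (sum(diag(r)) - 1) / 2)))
  if (.rad2deg(omega) < 1e-7) {
    axis <- if (.vnorm(t) > 1e-12) t / .vnorm(t) else c(1, 0, 0)
    return(list(axis = axis, angle = 0, pitch = .vnorm(t)))
  }
  v <- c(r[3, 2] - r[2, 3], r[1, 3] - r[3, 1], r[2, 1] - r[1, 2])
  axis <- if (.vnorm(v) > 1e-8) {
    v / .vnorm(v)
  } else {
    # omega ~ 180 deg: axis from the dominant column of R + I
    m <- r + diag(3)
    .unit(m[, which.max(colSums(m^2))], "rotation axis")
  }
  list(axis = axis, angle = .rad2deg(omega), pitch = sum(t * axis))
}

# Effective per-step rotation used to separate linear from helical growth.
# A planar zigzag has a screw angle of 180 degrees but its square is a pure
# translation, so the smaller of the one-step and two-step screw angles is
# the meaningful winding rate.
.effective_omega <- function(transform) {
  s1 <- screw_parameters(transform)
  s2 <- screw_parameters(compose_transform(transform, transform))
  min(s1$angle, s2$angle)
}

#' Classify the growth mode of a sphere-model interface
#'
#' Builds the two-sphere dimer for `(theta, phi)`, propagates it into an
#' `n`-monomer chain and classifies the growth mode: *limited* when any two
#' non-adjacent spheres overlap within the propagation horizon, *unlimited*
#' otherwise. Limited chains are subtyped as head-to-head (`"h2h"`, the
#' chain folds straight back: first overlap between monomers 1 and 3),
#' doughnut (`"don"`, the chain closes into a flat ring: screw pitch below
#' `doughnut_pitch`) or `"generic"`. Unlimited chains are linear (`"lin"`)
#' when the effective winding per step is below `linear_omega` degrees and
#' helical (`"hel"`) otherwise; a planar zigzag counts as linear via the
#' two-step screw (see [screw_parameters()]).
#'
#' Subtype thresholds are conventions for automating what is otherwise a
#' visual call; the limited/unlimited mode is the robust, threshold-free
#' verdict.
#'
#' @inheritParams build_sphere_dimer
#' @param n Propagation horizon in monomers (default 32).
#' @param delta Overlap tolerance, see [detect_overlap()].
#' @param linear_omega Winding threshold (degrees/step) separating linear
#'   from helical unlimited growth (default 15).
#' @param doughnut_pitch Pitch threshold (radius units/step) below which a
#'   limited, non-head-to-head chain is called a doughnut (default 0.1).
#' @return An object of class `growth_classification`: `mode` ("limited" or
#'   "unlimited"), `subtype` ("h2h", "don", "hel", "lin" or "generic"), and
#'   an `evidence` list (minimal non-adjacent center distance, first
#'   overlapping pair, screw angle `omega` in degrees, screw `pitch` in
#'   radius units, and the effective winding rate).
#' @examples
#' classify_sphere_growth(81, 160)$mode   # "unlimited"
#' classify_sphere_growth(123, 16)$subtype # "hel"
#' @export
classify_sphere_growth <- function(theta, phi, n = 32L, delta = 0.05,
                                   linear_omega = 15, doughnut_pitch = 0.1) {
  dimer <- build_sphere_dimer(theta, phi)
  chain <- propagate_chain(dimer, n)
  ov <- detect_overlap(chain, delta = delta)
  s <- screw_parameters(dimer$transform)
  om_eff <- .effective_omega(dimer$transform)
  limited <- nrow(ov$pairs) > 0L
  subtype <- if (limited) {
    if (!is.null(ov$first_pair) && ov$first_pair[1L] == 1L &&
        ov$first_pair[2L] == 3L) {
      "h2h"
    } else if (abs(s$pitch) < doughnut_pitch) {
      "don"
    } else {
      "generic"
    }
  } else {
    if (om_eff < linear_omega) "lin" else "hel"
  }
  structure(list(mode = if (limited) "limited" else "unlimited",
                 subtype = subtype,
                 theta = theta, phi = phi,
                 evidence = list(min_distance = ov$min_distance,
                                 first_pair = ov$first_pair,
                                 omega = s$angle,
                                 pitch = s$pitch,
                                 effective_omega = om_eff,
                                 n = as.integer(n), delta = delta)),
            class = "growth_classification")
}

#' @export
print.growth_classification <- function(x, ...) {
  cat(sprintf("Growth mode: %s (%s)\n", x$mode, x$subtype))
  cat(sprintf("  theta = %.1f deg, phi = %.1f deg\n", x$theta, x$phi))
  ev <- x$evidence
  cat(sprintf("  min non-adjacent distance = %.3f, omega = %.1f deg, pitch = %.3f\n",
              ev$min_distance, ev$omega, ev$pitch))
  if (!is.null(ev$first_pair)) {
    cat(sprintf("  first overlap: monomers %d and %d\n",
                ev$first_pair[1], ev$first_pair[2]))
  }
  invisible(x)
}
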