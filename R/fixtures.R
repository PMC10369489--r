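# Synthetic pseudo-monomers and dimers with controlled geometry. The
# generator emulates the morphology relevant to the growth-mode analysis -- a
# compact, nearly spherical core with optional protruding termini -- using
# carbon-like pseudo-atoms (one per residue by default) so that the SASA,
# interface and angle machinery can be exercised end-to-end without any
# external structure.

# Run code with a private, restored RNG state.
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Random rotation matrix (uniform via QR of a Gaussian matrix).
.random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3L, 3L))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# Minimal rotation taking unit vector `a` to unit vector `b`.
.rotation_between <- function(a, b) {
  a <- .unit(a); b <- .unit(b)
  v <- .cross3(a, b)
  s <- .vnorm(v)
  c_ <- sum(a * b)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate 180 deg about any axis orthogonal to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- .unit(.cross3(a, p))
    return(2 * tcrossprod(axis) - diag(3))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3L, 3L,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
}

# Quasi-uniform filling of a ball of radius R with ~n points: concentric
# golden-spiral shells with counts proportional to shell area. Far more
# isotropic than uniform sampling, which keeps the sphericity high.
.ball_points <- function(n, spacing = 2) {
  if (n == 1L) return(matrix(0, 1L, 3L))
  r_max <- spacing * (3 * n / (4 * pi))^(1 / 3)
  shells <- max(1L, round(r_max / spacing))
  radii <- seq_len(shells) * r_max / shells
  w <- radii^2 / sum(radii^2)
  counts <- pmax(1L, round((n - 1L) * w))
  while (sum(counts) + 1L > n) counts[which.max(counts)] <-
      counts[which.max(counts)] - 1L
  while (sum(counts) + 1L < n) counts[which.max(w)] <- counts[which.max(w)] + 1L
  pts <- matrix(0, 1L, 3L)
  for (k in seq_len(shells)) {
    shell <- .sphere_points(counts[k]) %*% t(.random_rotation()) * radii[k]
    pts <- rbind(pts, shell)
  }
  pts
}

#' Generate a synthetic pseudo-monomer
#'
#' Builds a monomer of carbon-like pseudo-atoms, one residue per atom by
#' default. In `"spherical"` mode the atoms quasi-uniformly fill a ball,
#' giving a sphericity above 90 percent. In `"with-termini"` mode two
#' straight terminal strands protrude from opposite sides of a spherical
#' core, lowering the sphericity in a controlled way and providing the
#' protruding contact features through which angle-targeted dimers are
#' posed (compact convex monomers cannot present an off-axis interface, so
#' termini are what make low polymerization angles reachable; see
#' [make_dimer()]).
#'
#' @param n_residues Total residue count (>= 4).
#' @param atoms_per_residue Pseudo-atoms per residue (default 1; additional
#'   atoms are jittered satellites).
#' @param shape `"spherical"` or `"with-termini"`.
#' @param termini_length Residues per terminus in `"with-termini"` mode
#'   (default 10; two termini are added, taken out of `n_residues`).
#' @param spacing Target inter-atom spacing in the core, Angstrom
#'   (default 2).
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return A [molstruct()] with chain `"A"`, residue type `UNK`, element C.
#'   The fixture geometry (shape, core radius, binding-tip residues, tip
#'   axis) is attached as attribute `"fixture"`.
#' @examples
#' m <- make_monomer(50, seed = 7)
#' shape_descriptor(structure_coords(m))$sphericity  # > 90
#' @export
make_monomer <- function(n_residues, atoms_per_residue = 1L,
                         shape = c("spherical", "with-termini"),
                         termini_length = 10L, spacing = 2, seed = 1L) {
  shape <- match.arg(shape)
  n_residues <- as.integer(n_residues)
  atoms_per_residue <- as.integer(atoms_per_residue)
  termini_length <- as.integer(termini_length)
  if (is.na(n_residues) || n_residues < 4L) {
    stop("'n_residues' must be at least 4", call. = FALSE)
  }
  if (atoms_per_residue < 1L) {
    stop("'atoms_per_residue' must be at least 1", call. = FALSE)
  }
  n_core <- n_residues
  if (shape == "with-termini") {
    if (termini_length < 2L) {
      stop("'termini_length' must be at least 2", call. = FALSE)
    }
    n_core <- n_residues - 2L * termini_length
    if (n_core < 4L) {
      stop("termini leave fewer than 4 core residues", call. = FALSE)
    }
  }
  .with_seed(seed, {
    core <- .ball_points(n_core, spacing = spacing)
    r_core <- max(sqrt(rowSums(core^2)))
    centers <- core
    tip_resnos <- integer(0)
    if (shape == "with-termini") {
      step <- 1.5
      tail1 <- cbind(r_core + step * seq_len(termini_length), 0, 0)
      tail2 <- cbind(-(r_core + step * seq_len(termini_length)), 0, 0)
      centers <- rbind(core, tail1, tail2)
      tip_resnos <- (n_core + termini_length - 2L):(n_core + termini_length)
    }
    n_atoms_total <- nrow(centers) * atoms_per_residue
    resno <- rep(seq_len(nrow(centers)), each = atoms_per_residue)
    coords <- centers[resno, , drop = FALSE]
    if (atoms_per_residue > 1L) {
      sat <- rep(seq_len(atoms_per_residue), times = nrow(centers)) > 1L
      coords[sat, ] <- coords[sat, ] +
        matrix(stats::rnorm(3 * sum(sat), sd = 0.8), ncol = 3L)
    }
    elety_res <- if (atoms_per_residue == 1L) "CA" else
      c("CA", paste0("C", seq_len(atoms_per_residue - 1L)))
    elety <- rep(elety_res, times = nrow(centers))[seq_len(n_atoms_total)]
    atoms <- data.frame(eleno = seq_len(n_atoms_total), elety = elety,
                        element = "C", resno = resno, resid = "UNK",
                        chain = "A",
                        x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
                        stringsAsFactors = FALSE)
    out <- molstruct(atoms)
    attr(out, "fixture") <- list(shape = shape, r_core = r_core,
                                 tip_resnos = tip_resnos,
                                 tip_axis = c(1, 0, 0), seed = seed)
    out
  })
}


# --- dimer posing ----------------------------------------------------------

# Pose two copies of the monomer: copy A at the origin with its binding tail
# along dir_a, copy B at (-D, 0, 0) + offset with its tail along dir_b.
# Chain ids A/B; atom numbering continues across the copies.
.pose_dimer <- function(monomer, dir_a, dir_b, D, tail_axis = c(1, 0, 0),
                        offset_b = c(0, 0, 0)) {
  coords <- structure_coords(monomer)
  gc_body <- colMeans(coords)
  body <- sweep(coords, 2L, gc_body)
  a_pos <- body %*% t(.rotation_between(tail_axis, dir_a))
  b_pos <- body %*% t(.rotation_between(tail_axis, dir_b))
  b_pos <- sweep(b_pos, 2L, c(-D, 0, 0) + offset_b, "+")
  at <- rbind(monomer$atoms, monomer$atoms)
  at$chain <- rep(c("A", "B"), each = nrow(monomer$atoms))
  at$eleno <- seq_len(nrow(at))
  at$x <- c(a_pos[, 1L], b_pos[, 1L])
  at$y <- c(a_pos[, 2L], b_pos[, 2L])
  at$z <- c(a_pos[, 3L], b_pos[, 3L])
  molstruct(at)
}

#' Pose two monomer copies at prescribed polymerization angles
#'
#' Builds a homodimer fixture whose polymerization angle and dihedral, as
#' measured through the full SASA interface-detection pipeline
#' ([angles_from_dimer()]), land within `tol` degrees of the requested
#' targets. The two copies bind through their protruding termini; the pose
#' (the direction of each monomer's binding tail, the twist of monomer B
#' about the inter-center axis, and the center separation) is refined
#' numerically against the *measured* angles, so the closed loop
#' pose -> SASA -> interface centers -> angles is what converges.
#'
#' A compact convex monomer necessarily buries a contact patch centered on
#' the axis between the two monomer centers, which pins the measured
#' polymerization angle near 180 degrees; that is why angle-targeted
#' dimers require a monomer with protruding termini
#' (`make_monomer(shape = "with-termini")`) - the same structural feature
#' that produces bent, off-axis interfaces in termini-mediated amyloid
#' dimers. For spherical monomers only near-axial targets
#' (`theta >= 165`) are accepted. Very small polymerization angles
#' (roughly below 70 degrees) correspond to interfaces that wrap around
#' the partner monomer and are outside what a rigid two-tail fixture can
#' realize; the pose search reports the achieved angles in its error
#' message when a target is out of reach.
#'
#' @param monomer A [make_monomer()] result (single chain).
#' @param theta Target polymerization angle, degrees.
#' @param phi Target polymerization dihedral, degrees.
#' @param gap Extra tip-to-tip spacing in Angstrom added to the van der
#'   Waals contact distance (default 0.5). A large gap (>= 10) produces a
#'   deliberately separated, non-interacting pair, returned without any
#'   angle refinement.
#' @param tol Acceptance tolerance on the measured angles, degrees
#'   (default 5).
#' @param threshold,n_points Interface-detection parameters, see
#'   [interface_descriptor()].
#' @param max_eval Total objective-evaluation budget for the pose search.
#' @param seed Seed controlling the deterministic restarts.
#' @return A [molstruct()] dimer with chains `"A"` and `"B"`; the measured
#'   angles, targets and final [interface_descriptor()] are attached as
#'   attribute `"pose"`. Errors (reporting achieved versus requested
#'   angles) when the target cannot be reached within `tol`.
#' @export
make_dimer <- function(monomer, theta, phi, gap = 0.5, tol = 5,
                       threshold = 10, n_points = 960L, max_eval = 400L,
                       seed = 1L) {
  stopifnot(inherits(monomer, "molstruct"))
  theta <- as.numeric(theta); phi <- as.numeric(phi)
  if (!is.finite(theta) || theta < 0 || theta > 180 ||
      !is.finite(phi) || phi < 0 || phi > 180) {
    stop("target angles must lie in [0, 180] degrees", call. = FALSE)
  }
  fx <- attr(monomer, "fixture")
  has_tip <- !is.null(fx) && length(fx$tip_resnos) > 0L
  coords <- structure_coords(monomer)
  gc_body <- colMeans(coords)
  r_body <- max(sqrt(rowSums(sweep(coords, 2L, gc_body)^2)))
  r_core <- if (!is.null(fx)) fx$r_core else r_body
  contact <- 3.4 + gap  # carbon-carbon van der Waals contact plus gap

  if (gap >= 10) {
    # deliberately separated pair: tails face to face, far apart
    dimer <- .pose_dimer(monomer, c(-1, 0, 0), c(1, 0, 0),
                         D = 2 * r_body + contact)
    attr(dimer, "pose") <- list(target = c(theta = theta, phi = phi),
                                measured = c(theta = NA_real_,
                                             phi = NA_real_),
                                descriptor = NULL)
    attr(dimer, "fixture") <- fx
    return(dimer)
  }

  if (!has_tip) {
    if (theta < 165) {
      stop("spherical monomers can only form near-axial interfaces ",
           "(theta >= 165); use make_monomer(shape = \"with-termini\") ",
           "for angle-targeted dimers", call. = FALSE)
    }
    dimer <- .pose_dimer(monomer, c(-1, 0, 0), c(1, 0, 0),
                         D = 2 * r_core + contact)
    desc <- interface_descriptor(dimer, threshold = threshold,
                                 n_points = n_points)
    th_m <- polymerization_angle(desc$gc_a, desc$gc_b, desc$gc_ia)
    attr(dimer, "pose") <- list(target = c(theta = theta, phi = phi),
                                measured = c(theta = th_m, phi = NA_real_),
                                descriptor = desc)
    attr(dimer, "fixture") <- fx
    return(dimer)
  }

  tail_len <- r_body - r_core
  measure <- function(dimer) {
    desc <- interface_descriptor(dimer, threshold = threshold,
                                 n_points = n_points)
    if (desc$no_interface) return(list(ok = FALSE, desc = desc))
    ang <- tryCatch(angles_from_dimer(dimer, desc), error = function(e) NULL)
    if (is.null(ang)) return(list(ok = FALSE, desc = desc))
    list(ok = TRUE, theta = ang$theta_pol, phi = ang$phi_pol, desc = desc)
  }
  skip_phi <- theta > 170
  pose_from_par <- function(p) {
    ua <- .deg2rad(p[1]); ub <- .deg2rad(p[2]); rr <- .deg2rad(p[3])
    .pose_dimer(monomer,
                dir_a = c(-cos(ua), sin(ua), 0),
                dir_b = c(cos(ub), sin(ub) * cos(rr), sin(ub) * sin(rr)),
                D = p[4])
  }
  objective <- function(p) {
    if (p[4] < 2 || p[4] > 2 * r_body + 10) return(1e6)
    m <- measure(pose_from_par(p))
    if (!m$ok) return(1e4 + p[4])  # pull back towards contact
    e <- (m$theta - theta)^2
    if (!skip_phi) e <- e + (m$phi - phi)^2
    e
  }
  d_mid <- 2 * r_core + tail_len * 0.8
  starts <- list()
  u0 <- 180 - theta
  for (du in c(0, -25, 25, -50)) {
    uu <- min(170, max(5, u0 + du))
    starts[[length(starts) + 1L]] <- c(uu, uu, 180 - phi, d_mid)
  }
  starts[[length(starts) + 1L]] <- c(60, 120, 180 - phi, d_mid + 1)
  best <- NULL
  evals_per_start <- max(40L, ceiling(max_eval / length(starts)))
  .with_seed(seed, {
    for (s in starts) {
      fit <- stats::optim(s, objective, method = "Nelder-Mead",
                          control = list(maxit = evals_per_start,
                                         reltol = 1e-6))
      if (is.null(best) || fit$value < best$value) best <- fit
      if (best$value < 1) break
    }
    if (best$value >= 1) {
      fit <- stats::optim(best$par, objective, method = "Nelder-Mead",
                          control = list(maxit = 2L * evals_per_start,
                                         reltol = 1e-8))
      if (fit$value < best$value) best <- fit
    }
  })
  dimer <- pose_from_par(best$par)
  m <- measure(dimer)
  err_theta <- if (m$ok) abs(m$theta - theta) else Inf
  err_phi <- if (m$ok && !skip_phi) abs(m$phi - phi) else 0
  if (!m$ok || err_theta > tol || err_phi > tol) {
    stop(sprintf(
      paste0("dimer pose did not converge: achieved (theta = %.1f, ",
             "phi = %.1f) for targets (%.1f, %.1f); this corner of the ",
             "angle plane may be unreachable for this monomer shape"),
      if (m$ok) m$theta else NA, if (m$ok) m$phi else NA, theta, phi),
      call. = FALSE)
  }
  attr(dimer, "pose") <- list(target = c(theta = theta, phi = phi),
                              measured = c(theta = m$theta,
                                           phi = if (skip_phi) NA_real_
                                                 else m$phi),
                              descriptor = m$desc)
  attr(dimer, "fixture") <- fx
  dimer
}
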