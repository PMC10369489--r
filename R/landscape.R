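#' Scan the growth landscape
#'
#' Classifies every cell of a regular grid over the (polymerization angle,
#' polymerization dihedral) plane with [classify_sphere_growth()], producing
#' the growth landscape: the map of which interface geometries can sustain
#' indefinite polymer growth. For each dihedral column the largest angle
#' still classified limited is recorded as a transition point; these points
#' trace the limited/unlimited boundary.
#'
#' @param step Grid spacing in degrees; must divide 180 (default 5).
#' @param n Propagation horizon in monomers per cell (default 32).
#' @param delta Overlap tolerance, see [detect_overlap()].
#' @return An object of class `growth_landscape`: `theta` and `phi` grid
#'   vectors, `modes` (character matrix, theta in rows, phi in columns,
#'   `"limited"` / `"unlimited"`), `transitions` (data frame with `phi` and
#'   `theta_star`), plus the scan parameters. The boundary fit slot is empty
#'   until [fit_boundary()] is called.
#' @examples
#' ls5 <- scan_landscape(step = 15)  # coarse scan
#' table(ls5$modes)
#' @export
scan_landscape <- function(step = 5, n = 32L, delta = 0.05) {
  step <- as.numeric(step)
  if (!is.finite(step) || step <= 0 || abs(180 / step - round(180 / step)) > 1e-9) {
    stop("'step' must be a positive divisor of 180 degrees", call. = FALSE)
  }
  theta <- seq(0, 180, by = step)
  phi <- seq(0, 180, by = step)
  modes <- matrix(NA_character_, length(theta), length(phi),
                  dimnames = list(theta = theta, phi = phi))
  for (i in seq_along(theta)) {
    for (j in seq_along(phi)) {
      modes[i, j] <- classify_sphere_growth(theta[i], phi[j], n = n,
                                            delta = delta)$mode
    }
  }
  theta_star <- vapply(seq_along(phi), function(j) {
    lim <- theta[modes[, j] == "limited"]
    if (length(lim)) max(lim) else NA_real_
  }, numeric(1))
  structure(list(theta = theta, phi = phi, modes = modes,
                 transitions = data.frame(phi = phi, theta_star = theta_star),
                 step = step, n = as.integer(n), delta = delta,
                 boundary = NULL),
            class = "growth_landscape")
}

#' @export
print.growth_landscape <- function(x, ...) {
  cat(sprintf("Growth landscape: %d x %d grid (step %g deg, %d monomers)\n",
              length(x$theta), length(x$phi), x$step, x$n))
  tab <- table(x$modes)
  cat(sprintf("  limited: %d cells, unlimited: %d cells\n",
              tab[["limited"]], tab[["unlimited"]]))
  if (!is.null(x$boundary)) {
    b <- x$boundary
    cat(sprintf(
      "  boundary fit: theta*(phi) = %.3f * exp(%.5f * phi) + %.3f (RMS %.2f deg)\n",
      b$a, b$b, b$c, b$rms))
    cat(sprintf("  uncertain band: +/- %g deg\n", b$band))
  }
  invisible(x)
}

#' Fit the limited/unlimited boundary
#'
#' Fits a three-parameter exponential `theta*(phi) = a * exp(b * phi) + c`
#' through the transition points of a scanned landscape by nonlinear least
#' squares (Levenberg-Marquardt). The fitted curve delimits the limited
#' region; together with an uncertain band of half-width `band` degrees it
#' partitions the plane into limited, uncertain and unlimited regions.
#'
#' @param landscape A [scan_landscape()] result.
#' @param band Half-width of the uncertain band in degrees (default 10).
#' @return The landscape with its `boundary` slot filled: parameters `a`,
#'   `b`, `c`, per-point `residuals`, their root mean square `rms`, and
#'   `band`.
#' @export
fit_boundary <- function(landscape, band = 10) {
  stopifnot(inherits(landscape, "growth_landscape"))
  tp <- landscape$transitions
  tp <- tp[is.finite(tp$theta_star), , drop = FALSE]
  if (nrow(tp) < 3L) {
    stop("boundary fit needs at least 3 transition points", call. = FALSE)
  }
  if (stats::sd(tp$theta_star) < 1e-9) {
    warning("all transition points identical: returning a constant fit")
    pars <- list(a = 0, b = 0, c = tp$theta_star[1])
    res <- rep(0, nrow(tp))
  } else {
    c0 <- min(tp$theta_star)
    a0 <- max(tp$theta_star) - c0
    fit <- minpack.lm::nlsLM(
      theta_star ~ a * exp(b * phi) + c,
      data = tp,
      start = list(a = a0, b = -0.02, c = c0),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(fit)
    pars <- list(a = unname(cf["a"]), b = unname(cf["b"]), c = unname(cf["c"]))
    res <- unname(stats::residuals(fit))
  }
  landscape$boundary <- list(a = pars$a, b = pars$b, c = pars$c,
                             residuals = res,
                             rms = sqrt(mean(res^2)),
                             band = band,
                             transitions = tp)
  landscape
}

#' Boundary angle predicted by the fitted curve
#'
#' @param landscape A landscape with a fitted boundary (see [fit_boundary()]).
#' @param phi Dihedral value(s) in degrees.
#' @return The fitted transition angle `theta*(phi)` in degrees.
#' @export
boundary_theta <- function(landscape, phi) {
  stopifnot(inherits(landscape, "growth_landscape"))
  if (is.null(landscape$boundary)) {
    stop("landscape has no fitted boundary; call fit_boundary() first",
         call. = FALSE)
  }
  b <- landscape$boundary
  b$a * exp(b$b * phi) + b$c
}

#' Classify a point of the angle plane into a landscape region
#'
#' Uses the fitted boundary to assign a (theta, phi) pair to the limited,
#' uncertain or unlimited region: points within the uncertain band around
#' the boundary curve require closer (atomic-level) inspection, points below
#' the band are limited and points above it unlimited.
#'
#' @inheritParams boundary_theta
#' @param theta Polymerization angle in degrees.
#' @param phi Polymerization dihedral in degrees.
#' @return One of `"limited"`, `"uncertain"`, `"unlimited"`.
#' @export
classify_region <- function(landscape, theta, phi) {
  stopifnot(inherits(landscape, "growth_landscape"))
  theta <- as.numeric(theta)
  phi <- as.numeric(phi)
  if (!is.finite(theta) || !is.finite(phi) ||
      theta < 0 || theta > 180 || phi < 0 || phi > 180) {
    stop("angles must lie in [0, 180] degrees", call. = FALSE)
  }
  ts <- boundary_theta(landscape, phi)
  band <- landscape$boundary$band
  if (abs(theta - ts) <= band) {
    "uncertain"
  } else if (theta < ts) {
    "limited"
  } else {
    "unlimited"
  }
}

#' Representative conformation of an angle ensemble
#'
#' Given the (theta, phi) pairs of an ensemble of dimer conformations,
#' returns the index of the conformation closest (Euclidean distance in the
#' angle plane) to the component-wise mean: the "average conformation" used
#' to represent the ensemble on the growth landscape. Ties are broken by the
#' lowest index.
#'
#' @param angles A two-column matrix or data frame of (theta, phi) pairs in
#'   degrees, or a list of [polymerization_angles()] objects.
#' @return Integer index into the ensemble.
#' @export
ensemble_representative <- function(angles) {
  if (is.list(angles) && !is.data.frame(angles) &&
      all(vapply(angles, inherits, logical(1), "polymerization_angles"))) {
    angles <- do.call(rbind, lapply(angles, function(a) {
      c(a$theta_pol, a$phi_pol)
    }))
  }
  if (is.data.frame(angles)) angles <- as.matrix(angles)
  if (!is.matrix(angles) || ncol(angles) != 2L || nrow(angles) < 1L) {
    stop("'angles' must be a non-empty two-column matrix of (theta, phi)",
         call. = FALSE)
  }
  storage.mode(angles) <- "double"
  ctr <- colMeans(angles)
  d2 <- (angles[, 1L] - ctr[1L])^2 + (angles[, 2L] - ctr[2L])^2
  which.min(d2)  # ties: lowest index
}

#' Export a landscape grid as a data frame
#'
#' Long-format view of the scanned grid, convenient for writing TSV output
#' or plotting.
#'
#' @param x A [scan_landscape()] result.
#' @param ... Unused.
#' @return A data frame with columns `theta`, `phi`, `mode`.
#' @export
as.data.frame.growth_landscape <- function(x, ...) {
  data.frame(theta = rep(x$theta, times = length(x$phi)),
             phi = rep(x$phi, each = length(x$theta)),
             mode = as.vector(x$modes),
             stringsAsFactors = FALSE)
}
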