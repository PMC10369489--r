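#' Polymerization angle of a dimer interface
#'
#' The polymerization angle summarizes how much a growing chain of monomers
#' bends at each interface. It is the angle, measured at the geometric center
#' of the interfacial residues of monomer A (`gc_ia`), between the direction
#' towards the geometric center of monomer A and the direction towards the
#' geometric center of monomer B. An angle of 180 degrees means the interface
#' sits on the axis joining the two monomer centers (straight growth); smaller
#' angles bend the chain and eventually force it to collide with itself.
#'
#' Mapping the interface center onto the surface of either monomer only
#' rescales the two vectors without changing their directions, so the angle is
#' computed directly from the center positions.
#'
#' @param gc_a Geometric center of monomer A (3-vector, Angstrom).
#' @param gc_b Geometric center of monomer B (3-vector, Angstrom).
#' @param gc_ia Geometric center of the interfacial residues of monomer A
#'   (3-vector, Angstrom).
#' @return Angle in degrees, in `[0, 180]`.
#' @examples
#' polymerization_angle(c(0, 0, 0), c(-2, 0, 0), c(-1, 0, 0)) # 180
#' polymerization_angle(c(0, 0, 0), c(-2, 0, 0), c(0, 1, 0))  # acos(1/sqrt(5))
#' @seealso [polymerization_dihedral()], [angles_from_dimer()]
#' @export
polymerization_angle <- function(gc_a, gc_b, gc_ia) {
  gc_a <- .as_coord3(gc_a, "gc_a")
  gc_b <- .as_coord3(gc_b, "gc_b")
  gc_ia <- .as_coord3(gc_ia, "gc_ia")
  v_a <- gc_ia - gc_a
  v_b <- gc_ia - gc_b
  if (.vnorm(v_a) < 1e-9 || .vnorm(v_b) < 1e-9) {
    stop("degenerate geometry: interface center coincides with a monomer center",
         call. = FALSE)
  }
  .angle_deg(v_a, v_b)
}

#' Polymerization dihedral of a dimer interface
#'
#' The polymerization dihedral measures the relative twist of the two monomers
#' about the axis joining their geometric centers. It is the angle between the
#' normals of two planes: the plane through the inter-center axis and the
#' interface center of monomer B, and the plane through the inter-center axis
#' and the interface center of monomer A,
#' \deqn{P_A = (GC_B - GC_A) \times (GC_{IB} - GC_A), \quad
#'       P_B = (GC_A - GC_B) \times (GC_{IA} - GC_B).}
#' The dihedral is reported unsigned in `[0, 180]` degrees; mirror-image
#' dimers give the same value, as do coplanar interfaces (0 or 180 depending
#' on whether the two interface centers lie on opposite or the same side of
#' the inter-center axis).
#'
#' @inheritParams polymerization_angle
#' @param gc_ib Geometric center of the interfacial residues of monomer B
#'   (3-vector, Angstrom).
#' @return Angle in degrees, in `[0, 180]`.
#' @export
polymerization_dihedral <- function(gc_a, gc_b, gc_ia, gc_ib) {
  gc_a <- .as_coord3(gc_a, "gc_a")
  gc_b <- .as_coord3(gc_b, "gc_b")
  gc_ia <- .as_coord3(gc_ia, "gc_ia")
  gc_ib <- .as_coord3(gc_ib, "gc_ib")
  p_a <- .cross3(gc_b - gc_a, gc_ib - gc_a)
  p_b <- .cross3(gc_a - gc_b, gc_ia - gc_b)
  if (.vnorm(p_a) < 1e-9) {
    stop("degenerate geometry: GC_A, GC_B and GC_IB are colinear ",
         "(plane through monomer A collapsed)", call. = FALSE)
  }
  if (.vnorm(p_b) < 1e-9) {
    stop("degenerate geometry: GC_B, GC_A and GC_IA are colinear ",
         "(plane through monomer B collapsed)", call. = FALSE)
  }
  .angle_deg(p_a, p_b)
}

#' Polymerization angle pair
#'
#' Container for a (polymerization angle, polymerization dihedral) pair.
#' Both values are validated to lie in `[0, 180]` degrees and to be finite.
#'
#' @param theta_pol Polymerization angle in degrees.
#' @param phi_pol Polymerization dihedral in degrees.
#' @return An object of class `polymerization_angles`: a list with elements
#'   `theta_pol` and `phi_pol`.
#' @export
polymerization_angles <- function(theta_pol, phi_pol) {
  theta_pol <- as.numeric(theta_pol)
  phi_pol <- as.numeric(phi_pol)
  if (length(theta_pol) != 1L || length(phi_pol) != 1L ||
      !is.finite(theta_pol) || !is.finite(phi_pol)) {
    stop("angles must be finite scalars", call. = FALSE)
  }
  if (theta_pol < 0 || theta_pol > 180 || phi_pol < 0 || phi_pol > 180) {
    stop("angles must lie in [0, 180] degrees", call. = FALSE)
  }
  structure(list(theta_pol = theta_pol, phi_pol = phi_pol),
            class = "polymerization_angles")
}

#' @export
print.polymerization_angles <- function(x, ...) {
  cat(sprintf("Polymerization angles: theta = %.2f deg, phi = %.2f deg\n",
              x$theta_pol, x$phi_pol))
  invisible(x)
}

#' Gyration-tensor shape descriptor
#'
#' Computes the radius of gyration, the eigenvalues of the gyration tensor
#' (the squared principal radii of gyration), the asphericity and the
#' sphericity of a point configuration. With eigenvalues
#' \eqn{\lambda_1 \ge \lambda_2 \ge \lambda_3} and mean
#' \eqn{\bar\lambda = (\lambda_1+\lambda_2+\lambda_3)/3}, the asphericity is
#' the relative shape anisotropy
#' \deqn{A_s = \frac{3}{2}\,
#'   \frac{\sum_i (\lambda_i - \bar\lambda)^2}{(\sum_i \lambda_i)^2},}
#' which is 0 for any configuration with three equal principal radii (an
#' ideal sphere), 1 in the collinear (rod) limit and bounded by `[0, 1]` for
#' every configuration. Sphericity is reported as a percentage,
#' \eqn{\psi = (1 - A_s) \times 100}.
#'
#' @param coords n x 3 coordinate matrix (Angstrom).
#' @param weights `"uniform"` for the geometric (unweighted) tensor or
#'   `"mass"` to weight by `masses`.
#' @param masses Optional numeric vector of per-point masses (Da), required
#'   when `weights = "mass"`.
#' @return An object of class `shape_descriptor`: a list with `rg` (Angstrom),
#'   `lambdas` (three eigenvalues, descending, Angstrom squared),
#'   `asphericity` and `sphericity` (percent).
#' @examples
#' oct <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
#' shape_descriptor(oct)$asphericity  # 0: three equal principal radii
#' @export
shape_descriptor <- function(coords, weights = c("uniform", "mass"),
                             masses = NULL) {
  coords <- .as_coord_matrix(coords)
  weights <- match.arg(weights)
  n <- nrow(coords)
  if (n < 1L) stop("no coordinates supplied", call. = FALSE)
  w <- if (weights == "mass") {
    if (is.null(masses) || length(masses) != n || any(!is.finite(masses)) ||
        any(masses <= 0)) {
      stop("'masses' must be positive and match the number of points",
           call. = FALSE)
    }
    masses / sum(masses)
  } else {
    rep(1 / n, n)
  }
  center <- colSums(coords * w)
  d <- sweep(coords, 2L, center)
  s <- crossprod(d * w, d)  # 3x3 gyration tensor
  lambdas <- sort(pmax(eigen(s, symmetric = TRUE, only.values = TRUE)$values, 0),
                  decreasing = TRUE)
  tr <- sum(lambdas)
  if (tr < 1e-12) {
    stop("all points coincide: radius of gyration is zero", call. = FALSE)
  }
  lbar <- tr / 3
  as_ <- 1.5 * sum((lambdas - lbar)^2) / tr^2
  as_ <- max(0, min(1, as_))
  structure(list(rg = sqrt(tr),
                 lambdas = lambdas,
                 asphericity = as_,
                 sphericity = (1 - as_) * 100),
            class = "shape_descriptor")
}

#' @export
print.shape_descriptor <- function(x, ...) {
  cat(sprintf("Shape: Rg = %.3f A, As = %.4f, psi = %.1f%%\n",
              x$rg, x$asphericity, x$sphericity))
  cat(sprintf("  gyration eigenvalues (A^2): %.4f %.4f %.4f\n",
              x$lambdas[1], x$lambdas[2], x$lambdas[3]))
  invisible(x)
}

#' Rigid-body transform
#'
#' A proper rigid transform `y = R x + t` with an orthonormal rotation matrix
#' of determinant +1. Used for dimer propagation, sphere-chain generation and
#' superposition results.
#'
#' @param rotation 3 x 3 rotation matrix.
#' @param translation 3-vector.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation, translation) {
  rotation <- as.matrix(rotation)
  translation <- .as_coord3(translation, "translation")
  if (!all(dim(rotation) == c(3L, 3L)) || !all(is.finite(rotation))) {
    stop("'rotation' must be a finite 3 x 3 matrix", call. = FALSE)
  }
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    stop("'rotation' is not orthonormal to 1e-9", call. = FALSE)
  }
  if (det(rotation) < 0) {
    stop("'rotation' must be proper (determinant +1)", call. = FALSE)
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  s <- screw_parameters(x)
  cat(sprintf(
    "Rigid transform: rotation %.2f deg about (%.3f, %.3f, %.3f), pitch %.3f\n",
    s$angle, s$axis[1], s$axis[2], s$axis[3], s$pitch))
  invisible(x)
}

#' Apply a rigid transform to coordinates
#'
#' @param transform A [rigid_transform()].
#' @param coords n x 3 coordinate matrix or a 3-vector.
#' @return Transformed coordinates with the same shape as the input.
#' @export
apply_transform <- function(transform, coords) {
  stopifnot(inherits(transform, "rigid_transform"))
  single <- is.null(dim(coords)) && length(coords) == 3L
  m <- if (single) matrix(coords, 1L, 3L) else .as_coord_matrix(coords)
  out <- m %*% t(transform$rotation)
  out <- sweep(out, 2L, transform$translation, "+")
  if (single) as.numeric(out) else out
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `first`, then `second`.
#'
#' @param first,second [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
compose_transform <- function(first, second) {
  stopifnot(inherits(first, "rigid_transform"),
            inherits(second, "rigid_transform"))
  rigid_transform(second$rotation %*% first$rotation,
                  as.numeric(second$rotation %*% first$translation) +
                    second$translation)
}

# T^k applied to a point set, used by chain propagation.
.transform_power <- function(transform, k) {
  out <- rigid_transform(diag(3), c(0, 0, 0))
  for (i in seq_len(k)) out <- compose_transform(out, transform)
  out
}

#' Least-squares rigid superposition
#'
#' Finds the proper rigid transform (rotation + translation, no reflection)
#' that minimizes the root-mean-square deviation between `mobile` and
#' `target` after transformation, using the SVD of the cross-covariance
#' matrix. Point correspondence is by row.
#'
#' @param mobile,target n x 3 coordinate matrices with matching rows
#'   (n >= 3, not all collinear).
#' @return A list with `transform` (a [rigid_transform()]) and `rmsd`
#'   (Angstrom, after applying the transform to `mobile`).
#' @export
superpose <- function(mobile, target) {
  mobile <- .as_coord_matrix(mobile, "mobile")
  target <- .as_coord_matrix(target, "target")
  if (nrow(mobile) != nrow(target)) {
    stop("'mobile' and 'target' must have the same number of points",
         call. = FALSE)
  }
  if (nrow(mobile) < 3L) {
    stop("superposition needs at least 3 points", call. = FALSE)
  }
  cm <- colMeans(mobile)
  ct <- colMeans(target)
  h <- crossprod(sweep(mobile, 2L, cm), sweep(target, 2L, ct))
  sv <- svd(h)
  # Rank check: a collinear (or coincident) point set leaves the rotation
  # about the degenerate axis undetermined.
  mob_rank <- svd(sweep(mobile, 2L, cm), nu = 0, nv = 0)$d
  tar_rank <- svd(sweep(target, 2L, ct), nu = 0, nv = 0)$d
  if (mob_rank[2] < 1e-8 || tar_rank[2] < 1e-8) {
    stop("rank-deficient configuration: points are collinear", call. = FALSE)
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- rigid_transform(rot, ct - as.numeric(rot %*% cm))
  fitted <- apply_transform(tr, mobile)
  list(transform = tr,
       rmsd = sqrt(mean(rowSums((fitted - target)^2))))
}

#' Polymerization angles of an atomic dimer
#'
#' Composes the interface detection with the two angle definitions: the four
#' geometric centers (both monomers and both interfacial residue sets) are
#' taken from an [interface_descriptor()] and converted into the
#' (polymerization angle, polymerization dihedral) pair that places the dimer
#' on the growth landscape.
#'
#' @param dimer A [read_structure()] result (or other molecular structure)
#'   with the two monomers as separate chains.
#' @param descriptor Optional precomputed [interface_descriptor()]; computed
#'   from `dimer` when omitted.
#' @param ... Passed to [interface_descriptor()] when `descriptor` is missing.
#' @return A [polymerization_angles()] object.
#' @export
angles_from_dimer <- function(dimer, descriptor = NULL, ...) {
  if (is.null(descriptor)) descriptor <- interface_descriptor(dimer, ...)
  stopifnot(inherits(descriptor, "interface_descriptor"))
  if (isTRUE(descriptor$no_interface)) {
    stop("dimer has no interface: polymerization angles are undefined",
         call. = FALSE)
  }
  theta <- polymerization_angle(descriptor$gc_a, descriptor$gc_b,
                                descriptor$gc_ia)
  phi <- polymerization_dihedral(descriptor$gc_a, descriptor$gc_b,
                                 descriptor$gc_ia, descriptor$gc_ib)
  polymerization_angles(theta, phi)
}
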