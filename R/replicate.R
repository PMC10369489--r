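# Replication protocol for atomic dimers: the rigid transform that maps
# monomer A onto monomer B, applied iteratively, propagates the dimer into
# an n-monomer chain whose steric self-consistency decides the growth mode
# at atomic resolution.

#' Propagation transform of an atomic dimer
#'
#' Superposes the core C-alpha atoms of monomer A onto those of monomer B,
#' yielding the rigid transform that duplicates the dimer one step along
#' the growing chain. Because the two monomers are copies of the same
#' protein, the fit RMSD doubles as a homodimer-similarity diagnostic:
#' values near zero mean the two chains share one conformation.
#'
#' @param dimer A [molstruct()] with the two monomers as chains.
#' @param chains The two chain ids (default: the first two chains).
#' @param core A [core_selection()] naming the residue ranges used for the
#'   alignment.
#' @param model Model number (default 1).
#' @return A list with `transform` (a [rigid_transform()]) and `rmsd`
#'   (Angstrom).
#' @export
dimer_transform <- function(dimer, chains = NULL, core = core_selection(),
                            model = 1L) {
  stopifnot(inherits(dimer, "molstruct"))
  if (is.null(chains)) {
    if (length(dimer$chains) < 2L) {
      stop("dimer must contain two chains", call. = FALSE)
    }
    chains <- dimer$chains[1:2]
  }
  core_a <- select_core(dimer, chains[1], core, model = model)
  core_b <- select_core(dimer, chains[2], core, model = model)
  res_a <- rownames(core_a)
  res_b <- rownames(core_b)
  if (!identical(res_a, res_b)) {
    missing_in_b <- setdiff(res_a, res_b)
    missing_in_a <- setdiff(res_b, res_a)
    stop("core residues differ between chains (heterodimer?): ",
         if (length(missing_in_b)) {
           paste0("missing in ", chains[2], ": ",
                  paste(missing_in_b, collapse = ", "), "; ")
         } else "",
         if (length(missing_in_a)) {
           paste0("missing in ", chains[1], ": ",
                  paste(missing_in_a, collapse = ", "))
         } else "",
         call. = FALSE)
  }
  superpose(core_a, core_b)
}

#' Propagate an atomic dimer into a polymer chain
#'
#' Implements the replication protocol: monomer k of the polymer is the
#' A-onto-B transform applied k times to the full atom set of monomer A.
#' Monomer 2 therefore reproduces monomer B's core up to the dimer's own
#' fit RMSD, and the whole chain inherits the dimer's interface geometry at
#' every junction, without any conformational relaxation.
#'
#' @inheritParams dimer_transform
#' @param n Number of monomers in the polymer (>= 2).
#' @return A multi-model [molstruct()] whose models are the monomers
#'   (monomer A's topology, chain relabeled `"A"`), with attributes
#'   `transform` (the generating [rigid_transform()]) and `rmsd` (the dimer
#'   fit RMSD, Angstrom).
#' @export
polymerize_structure <- function(dimer, n, chains = NULL,
                                 core = core_selection(), model = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("'n' must be at least 2", call. = FALSE)
  if (is.null(chains)) chains <- dimer$chains[1:2]
  fit <- dimer_transform(dimer, chains, core, model = model)
  rows <- .chain_rows(dimer, chains[1])
  at <- dimer$atoms[rows, , drop = FALSE]
  coords <- structure_coords(dimer, model)[rows, , drop = FALSE]
  at$x <- coords[, 1L]; at$y <- coords[, 2L]; at$z <- coords[, 3L]
  at$chain <- "A"
  models <- vector("list", n)
  models[[1L]] <- coords
  cur <- coords
  for (k in 2:n) {
    cur <- apply_transform(fit$transform, cur)
    models[[k]] <- cur
  }
  out <- molstruct(at, models)
  attr(out, "transform") <- fit$transform
  attr(out, "rmsd") <- fit$rmsd
  out
}

# Count atom pairs between monomers at least `min_gap` apart that come
# closer than each cutoff. Spatial hashing on a grid of cell size
# max(cutoffs) keeps this near-linear in atom count.
.close_pair_counts <- function(models, heavy, cutoffs, min_gap = 2L) {
  n_mod <- length(models)
  coords <- do.call(rbind, lapply(models, function(m) m[heavy, , drop = FALSE]))
  mono <- rep(seq_len(n_mod), each = sum(heavy))
  cell <- max(cutoffs)
  key <- paste(floor(coords[, 1L] / cell),
               floor(coords[, 2L] / cell),
               floor(coords[, 3L] / cell), sep = ",")
  buckets <- split(seq_len(nrow(coords)), key)
  cellidx <- floor(coords / cell)
  counts <- numeric(length(cutoffs))
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  cut2 <- cutoffs^2
  for (i in seq_len(nrow(coords))) {
    neigh_keys <- paste(cellidx[i, 1L] + offsets[, 1L],
                        cellidx[i, 2L] + offsets[, 2L],
                        cellidx[i, 3L] + offsets[, 3L], sep = ",")
    js <- unlist(buckets[neigh_keys], use.names = FALSE)
    js <- js[js > i & abs(mono[js] - mono[i]) >= min_gap]
    if (!length(js)) next
    d2 <- (coords[js, 1L] - coords[i, 1L])^2 +
          (coords[js, 2L] - coords[i, 2L])^2 +
          (coords[js, 3L] - coords[i, 3L])^2
    for (k in seq_along(cutoffs)) counts[k] <- counts[k] + sum(d2 < cut2[k])
  }
  counts
}

#' Count interatomic clashes in a polymer
#'
#' Counts heavy-atom pairs between non-adjacent monomers (index gap at
#' least `min_gap`) that approach closer than `cutoff`. Adjacent monomers
#' form the legitimate interface and are excluded. A spatial grid makes the
#' count near-linear in the number of atoms.
#'
#' @param polymer A [polymerize_structure()] result (multi-model
#'   [molstruct()], one monomer per model).
#' @param cutoff Clash distance in Angstrom (default 2.0).
#' @param min_gap Minimum monomer index separation (default 2).
#' @return Integer clash count.
#' @export
clash_count <- function(polymer, cutoff = 2.0, min_gap = 2L) {
  stopifnot(inherits(polymer, "molstruct"))
  if (length(polymer$models) < 3L) {
    stop("clash counting needs a polymer of at least 3 monomers",
         call. = FALSE)
  }
  heavy <- polymer$atoms$element != "H"
  as.integer(.close_pair_counts(polymer$models, heavy, cutoff,
                                min_gap = as.integer(min_gap)))
}

# Growth classification of a screw-generated chain of monomer centers with
# inter-center step `step`; shared by the sphere model (step = 2 radii) and
# the atomic transform (step = |translation| Angstrom, i.e. radius =
# step / 2).
.classify_transform <- function(transform, origin, step, n, delta,
                                linear_omega, doughnut_pitch_frac) {
  centers <- matrix(0, n, 3L)
  centers[1L, ] <- origin
  x <- origin
  for (k in 2:n) {
    x <- apply_transform(transform, x)
    centers[k, ] <- x
  }
  cutoff <- step * (1 - delta)
  d <- as.matrix(stats::dist(centers))
  idx <- which(upper.tri(d), arr.ind = TRUE)
  idx <- idx[idx[, 2L] - idx[, 1L] >= 2L, , drop = FALSE]
  dv <- d[idx]
  hit <- which(dv < cutoff)
  limited <- length(hit) > 0L
  first <- if (limited) {
    hp <- idx[hit, , drop = FALSE]
    hp[order(hp[, 1L], hp[, 2L])[1L], ]
  } else NULL
  s <- screw_parameters(transform)
  om_eff <- .effective_omega(transform)
  subtype <- if (limited) {
    if (!is.null(first) && first[1L] == 1L && first[2L] == 3L) "h2h"
    else if (abs(s$pitch) < doughnut_pitch_frac * step / 2) "don"
    else "generic"
  } else {
    if (om_eff < linear_omega) "lin" else "hel"
  }
  list(limited = limited, subtype = subtype,
       min_distance = min(dv), first_pair = first,
       omega = s$angle, pitch = s$pitch, effective_omega = om_eff)
}

#' Classify the growth mode of an atomic dimer
#'
#' Full growth-mode verdict for a real dimer structure. The polymerization
#' angles are measured through the SASA interface pipeline and located on
#' the sphere-model growth landscape. Conformations in the limited or
#' unlimited region inherit that verdict; conformations in the uncertain
#' band (where the sphere idealization is unreliable) are resolved at
#' atomic resolution by propagating the actual structure into an
#' `n`-monomer polymer and counting steric clashes: growth is limited when
#' the clash count exceeds a budget proportional to the number of
#' inter-monomer atom pairs in contact range, since a few clashes are
#' relievable by small conformational rearrangement while widespread
#' overlap is not. Subtypes come from the screw decomposition of the
#' atomic propagation transform, with the same conventions as the sphere
#' model.
#'
#' @inheritParams polymerize_structure
#' @param landscape Optional fitted [scan_landscape()] landscape; the
#'   package-default 5-degree scan is (computed once and) reused when
#'   omitted.
#' @param n Propagation horizon in monomers (default 32).
#' @param clash_cutoff Heavy-atom clash distance, Angstrom (default 2.0).
#' @param clash_budget Tolerated clash fraction of the inter-monomer atom
#'   pairs within twice the clash cutoff (default 0.005).
#' @param force_atomic Always use the atomic clash verdict instead of only
#'   inside the uncertain band.
#' @param threshold,n_points Interface-detection parameters.
#' @param linear_omega,doughnut_pitch Subtype thresholds, see
#'   [classify_sphere_growth()] (the doughnut pitch threshold is in units
#'   of the monomer step, i.e. scaled by half the inter-monomer distance).
#' @return A `growth_classification` object whose evidence also records the
#'   landscape `region`, the measured angles, the clash count and the
#'   contact-pair count.
#' @export
classify_structure_growth <- function(dimer, n = 32L, chains = NULL,
                                      core = core_selection(),
                                      landscape = NULL,
                                      clash_cutoff = 2.0,
                                      clash_budget = 0.005,
                                      force_atomic = FALSE,
                                      threshold = 10, n_points = 960L,
                                      linear_omega = 15,
                                      doughnut_pitch = 0.1,
                                      model = 1L) {
  stopifnot(inherits(dimer, "molstruct"))
  if (is.null(chains)) chains <- dimer$chains[1:2]
  desc <- interface_descriptor(dimer, chains = chains, threshold = threshold,
                               n_points = n_points, model = model)
  angles <- angles_from_dimer(dimer, desc)
  if (is.null(landscape)) landscape <- default_landscape()
  region <- classify_region(landscape, angles$theta_pol, angles$phi_pol)

  fit <- dimer_transform(dimer, chains, core, model = model)
  step <- .vnorm(fit$transform$translation)
  tcls <- .classify_transform(fit$transform, origin = desc$gc_a, step = step,
                              n = n, delta = 0.05,
                              linear_omega = linear_omega,
                              doughnut_pitch_frac = doughnut_pitch)
  clashes <- NA_integer_
  contact_pairs <- NA_integer_
  if (region == "uncertain" || force_atomic) {
    polymer <- polymerize_structure(dimer, n = n, chains = chains,
                                    core = core, model = model)
    heavy <- polymer$atoms$element != "H"
    cnt <- .close_pair_counts(polymer$models, heavy,
                              cutoffs = c(clash_cutoff, 2 * clash_cutoff))
    clashes <- as.integer(cnt[1L])
    contact_pairs <- as.integer(cnt[2L])
    limited <- clashes > clash_budget * contact_pairs
  } else {
    limited <- region == "limited"
  }
  subtype <- if (limited) {
    if (tcls$limited) tcls$subtype else "generic"
  } else {
    if (tcls$effective_omega < linear_omega) "lin" else "hel"
  }
  structure(list(mode = if (limited) "limited" else "unlimited",
                 subtype = subtype,
                 theta = angles$theta_pol, phi = angles$phi_pol,
                 evidence = list(region = region,
                                 min_distance = tcls$min_distance,
                                 first_pair = tcls$first_pair,
                                 omega = tcls$omega, pitch = tcls$pitch,
                                 effective_omega = tcls$effective_omega,
                                 clash_count = clashes,
                                 contact_pairs = contact_pairs,
                                 rmsd = fit$rmsd,
                                 n = as.integer(n))),
            class = "growth_classification")
}

# Package-level cache for the default landscape scan.
.dimergrow_cache <- new.env(parent = emptyenv())

#' Default fitted growth landscape
#'
#' The 5-degree, 32-monomer landscape with its fitted exponential boundary,
#' computed on first use and cached for the session.
#'
#' @return A fitted `growth_landscape`.
#' @export
default_landscape <- function() {
  if (is.null(.dimergrow_cache$landscape)) {
    .dimergrow_cache$landscape <- fit_boundary(scan_landscape())
  }
  .dimergrow_cache$landscape
}
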