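# Interface detection from the SASA difference between the complex and the
# isolated monomers, per-residue normalization to a relative (percentage)
# interfacial area, and the four geometric centers used by the angle
# calculations.

# Extract one chain of one model as a standalone molstruct.
.chain_substructure <- function(structure, chain, model = 1L) {
  rows <- .chain_rows(structure, chain)
  at <- structure$atoms[rows, , drop = FALSE]
  coords <- structure_coords(structure, model)[rows, , drop = FALSE]
  at$x <- coords[, 1L]; at$y <- coords[, 2L]; at$z <- coords[, 3L]
  molstruct(at)
}

#' Per-residue interfacial areas of a dimer
#'
#' The interfacial area of each residue is the solvent-accessible surface
#' area it loses upon complexation: the difference between its SASA in the
#' isolated monomer and in the dimer (clamped at zero against sampling
#' noise). The difference is normalized into a percentage of the residue
#' type's maximum solvent-accessible area, so that a threshold on the
#' percentage selects interface residues independently of residue size.
#'
#' Two normalization references are available. `"reference-table"` (default)
#' uses fixed per-residue-type maxima (theoretical Gly-X-Gly values) for the
#' 20 standard amino acids and, for non-standard residue types such as the
#' pseudo-atoms of the fixture generator, falls back to the residue's own
#' isolated-monomer SASA. `"ensemble-max"` uses the maximum isolated-monomer
#' SASA of each residue across all models of the supplied (multi-model)
#' structure, mirroring how an ensemble of simulation snapshots defines the
#' attainable exposure of each residue; it requires at least two models.
#'
#' @param dimer A [molstruct()] with exactly two chains (or `chains` naming
#'   two of its chains).
#' @param chains Character vector of the two chain ids to treat as monomers
#'   A and B; defaults to the first two chains of the structure.
#' @param probe Probe radius in Angstrom (default 1.4).
#' @param n_points Shrake-Rupley sample points per atom (default 960).
#' @param normalization `"reference-table"` or `"ensemble-max"`.
#' @param model Model used for the area calculation (default 1).
#' @param radii Optional van der Waals radius overrides, see
#'   [residue_sasa()].
#' @return A data frame with one row per residue of both monomers: `chain`,
#'   `resno`, `resid`, `sasa_free`, `sasa_complex`, `delta_sasa` (Angstrom^2)
#'   and `rel_pct` (percent of maximal exposure, in `[0, 100]`). The total
#'   interfacial area of the dimer (sum of both sides) is attached as
#'   attributes `total_area` (Angstrom^2) and `total_area_nm2` (nm^2).
#' @export
interfacial_areas <- function(dimer, chains = NULL, probe = 1.4,
                              n_points = 960L,
                              normalization = c("reference-table",
                                                "ensemble-max"),
                              model = 1L, radii = NULL) {
  stopifnot(inherits(dimer, "molstruct"))
  normalization <- match.arg(normalization)
  if (is.null(chains)) {
    if (length(dimer$chains) < 2L) {
      stop("dimer must contain two chains", call. = FALSE)
    }
    chains <- dimer$chains[1:2]
  }
  if (length(chains) != 2L || chains[1] == chains[2]) {
    stop("'chains' must name two distinct chains", call. = FALSE)
  }
  mono <- lapply(chains, .chain_substructure, structure = dimer,
                 model = model)
  names(mono) <- chains
  free <- lapply(mono, residue_sasa, probe = probe, n_points = n_points,
                 radii = radii)

  # Complex SASA on the union of the two chains (other chains are excluded
  # from the calculation entirely so they do not shadow the interface).
  rows <- c(.chain_rows(dimer, chains[1]), .chain_rows(dimer, chains[2]))
  at <- dimer$atoms[rows, , drop = FALSE]
  coords <- structure_coords(dimer, model)[rows, , drop = FALSE]
  at$x <- coords[, 1L]; at$y <- coords[, 2L]; at$z <- coords[, 3L]
  cplx <- residue_sasa(molstruct(at), probe = probe, n_points = n_points,
                       radii = radii)

  freedf <- rbind(free[[1L]], free[[2L]])
  key_f <- paste(freedf$chain, freedf$resno, sep = "\r")
  key_c <- paste(cplx$chain, cplx$resno, sep = "\r")
  sasa_complex <- cplx$area[match(key_f, key_c)]
  delta <- pmax(0, freedf$area - sasa_complex)

  ref <- unname(.max_sasa_table[freedf$resid])
  if (normalization == "reference-table") {
    ref[is.na(ref)] <- freedf$area[is.na(ref)]  # fall back to own exposure
  } else {
    if (length(dimer$models) < 2L) {
      stop("normalization = \"ensemble-max\" requires a multi-model ",
           "structure (a conformational ensemble)", call. = FALSE)
    }
    ens <- lapply(seq_along(dimer$models), function(m) {
      do.call(rbind, lapply(chains, function(ch) {
        residue_sasa(.chain_substructure(dimer, ch, model = m),
                     probe = probe, n_points = n_points, radii = radii)
      }))
    })
    ens_area <- do.call(cbind, lapply(ens, `[[`, "area"))
    ref <- apply(ens_area, 1L, max)
  }
  rel <- ifelse(ref > 1e-9, 100 * delta / ref, 0)
  out <- data.frame(chain = freedf$chain, resno = freedf$resno,
                    resid = freedf$resid,
                    sasa_free = freedf$area, sasa_complex = sasa_complex,
                    delta_sasa = delta,
                    rel_pct = pmin(100, rel),
                    stringsAsFactors = FALSE)
  attr(out, "total_area") <- sum(delta)
  attr(out, "total_area_nm2") <- sum(delta) / 100
  attr(out, "chains") <- chains
  out
}

#' Interface descriptor of a dimer
#'
#' Applies the relative-area threshold to the per-residue interfacial areas
#' and assembles everything the angle calculations need: the interface
#' residue sets of both monomers and the four geometric centers - the
#' (unweighted) centers of monomer A and monomer B, and the centers of the
#' interfacial residues of A and of B. Residues whose relative interfacial
#' area exceeds `threshold` percent are considered located at the interface.
#'
#' @inheritParams interfacial_areas
#' @param threshold Relative interfacial area (percent) above which a
#'   residue belongs to the interface (default 10).
#' @param center_atoms `"heavy"` (default) to compute geometric centers from
#'   all non-hydrogen atoms, or `"calpha"` for C-alpha atoms only.
#' @param areas Optional precomputed [interfacial_areas()] result.
#' @return An object of class `interface_descriptor`: the `areas` table,
#'   `threshold`, interface residue sets `interface_a` / `interface_b`
#'   (residue numbers), centers `gc_a`, `gc_b`, `gc_ia`, `gc_ib`, the
#'   `no_interface` flag (TRUE when either side has no interface residues,
#'   in which case `gc_ia` / `gc_ib` are `NULL`), and the total interfacial
#'   area in nm^2.
#' @export
interface_descriptor <- function(dimer, chains = NULL, threshold = 10,
                                 center_atoms = c("heavy", "calpha"),
                                 probe = 1.4, n_points = 960L,
                                 normalization = "reference-table",
                                 model = 1L, radii = NULL, areas = NULL) {
  stopifnot(inherits(dimer, "molstruct"))
  center_atoms <- match.arg(center_atoms)
  if (!is.finite(threshold) || threshold < 0 || threshold > 100) {
    stop("'threshold' must be a percentage in [0, 100]", call. = FALSE)
  }
  if (is.null(areas)) {
    areas <- interfacial_areas(dimer, chains = chains, probe = probe,
                               n_points = n_points,
                               normalization = normalization,
                               model = model, radii = radii)
  }
  chains <- attr(areas, "chains")
  iface <- areas$rel_pct > threshold
  set_a <- areas$resno[iface & areas$chain == chains[1]]
  set_b <- areas$resno[iface & areas$chain == chains[2]]

  coords <- structure_coords(dimer, model)
  pick <- function(chain, resnos = NULL) {
    rows <- .chain_rows(dimer, chain)
    at <- dimer$atoms[rows, , drop = FALSE]
    sel <- at$element != "H"
    if (center_atoms == "calpha") sel <- at$elety == "CA"
    if (!is.null(resnos)) sel <- sel & at$resno %in% resnos
    if (!any(sel)) return(NULL)
    colMeans(coords[rows[sel], , drop = FALSE])
  }
  gc_a <- pick(chains[1])
  gc_b <- pick(chains[2])
  no_interface <- length(set_a) == 0L || length(set_b) == 0L
  structure(list(areas = areas, threshold = threshold,
                 chains = chains,
                 interface_a = set_a, interface_b = set_b,
                 gc_a = gc_a, gc_b = gc_b,
                 gc_ia = if (no_interface) NULL else pick(chains[1], set_a),
                 gc_ib = if (no_interface) NULL else pick(chains[2], set_b),
                 no_interface = no_interface,
                 total_area_nm2 = attr(areas, "total_area_nm2")),
            class = "interface_descriptor")
}

#' @export
print.interface_descriptor <- function(x, ...) {
  if (x$no_interface) {
    cat("Interface descriptor: no interface (threshold ",
        x$threshold, "%)\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("Interface descriptor (threshold %g%%):\n", x$threshold))
  cat(sprintf("  chain %s: %d interface residues; chain %s: %d\n",
              x$chains[1], length(x$interface_a),
              x$chains[2], length(x$interface_b)))
  cat(sprintf("  total interfacial area: %.2f nm^2\n", x$total_area_nm2))
  invisible(x)
}

#' Fraction of a reference interface that is conserved
#'
#' Measures how much of a reference interface survives in another
#' conformation of the same dimer: the percentage of residues present in
#' the reference interface (union of both monomers' interface sets,
#' identified by chain and residue number) that are still classified as
#' interface residues in the current descriptor. Area magnitudes are
#' ignored; conservation is a set overlap, matching how interface stability
#' is tabulated across simulation snapshots.
#'
#' @param reference,current [interface_descriptor()] objects computed on the
#'   same topology.
#' @return Percentage in `[0, 100]`.
#' @export
conserved_interface_fraction <- function(reference, current) {
  stopifnot(inherits(reference, "interface_descriptor"),
            inherits(current, "interface_descriptor"))
  tag <- function(d) {
    c(if (length(d$interface_a)) paste(d$chains[1], d$interface_a),
      if (length(d$interface_b)) paste(d$chains[2], d$interface_b))
  }
  ref_set <- tag(reference)
  cur_set <- tag(current)
  if (!length(ref_set)) {
    stop("reference interface is empty: conserved fraction undefined",
         call. = FALSE)
  }
  100 * length(intersect(ref_set, cur_set)) / length(ref_set)
}

#' Tabular interface report
#'
#' Writes (or returns) the per-residue interface table in TSV form: chain,
#' residue number and type, buried area, relative percentage and interface
#' flag.
#'
#' @param descriptor An [interface_descriptor()].
#' @param path Optional output path; when `NULL` the data frame is returned
#'   without writing.
#' @return The table, invisibly when written.
#' @export
interface_table <- function(descriptor, path = NULL) {
  stopifnot(inherits(descriptor, "interface_descriptor"))
  a <- descriptor$areas
  tab <- data.frame(chain = a$chain, resno = a$resno, resid = a$resid,
                    delta_sasa = round(a$delta_sasa, 3),
                    rel_pct = round(a$rel_pct, 2),
                    interface = a$rel_pct > descriptor$threshold,
                    stringsAsFactors = FALSE)
  if (is.null(path)) return(tab)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
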