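#' Molecular structure container
#'
#' Lightweight atomic-structure container used throughout the package: a
#' per-atom table plus one coordinate set per model. Residue numbering is
#' taken verbatim from the source (author numbering, 1-based); no
#' renumbering is ever performed, so residue-range selections match the
#' numbering printed in structural papers.
#'
#' @param atoms Data frame with columns `eleno` (atom serial), `elety` (atom
#'   name), `element` (element symbol), `resno` (residue number), `resid`
#'   (3-letter residue type), `chain` (chain id), `x`, `y`, `z` (Angstrom).
#' @param models Optional list of n x 3 coordinate matrices (one per model,
#'   identical atom ordering). Model 1 defaults to the coordinates in
#'   `atoms`.
#' @return An object of class `molstruct` with elements `atoms`, `models`
#'   and `chains` (unique chain ids in order of appearance).
#' @export
molstruct <- function(atoms, models = NULL) {
  required <- c("eleno", "elety", "element", "resno", "resid", "chain",
                "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols)) {
    stop("'atoms' is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(atoms) == 0L) stop("structure has zero atoms", call. = FALSE)
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  storage.mode(coords) <- "double"
  if (!all(is.finite(coords))) {
    stop("non-finite atomic coordinates", call. = FALSE)
  }
  if (is.null(models)) {
    models <- list(coords)
  } else {
    dims_ok <- vapply(models, function(m) {
      is.matrix(m) && nrow(m) == nrow(atoms) && ncol(m) == 3L &&
        all(is.finite(m))
    }, logical(1))
    if (!all(dims_ok)) {
      stop("all models must be finite matrices with one row per atom",
           call. = FALSE)
    }
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms,
                 models = models,
                 chains = unique(as.character(atoms$chain))),
            class = "molstruct")
}

#' @export
print.molstruct <- function(x, ...) {
  cat(sprintf("Molecular structure: %d atoms, %d residues, chains [%s], %d model(s)\n",
              nrow(x$atoms),
              nrow(unique(x$atoms[, c("chain", "resno")])),
              paste(x$chains, collapse = ", "),
              length(x$models)))
  invisible(x)
}

#' Number of models in a structure
#' @param structure A [molstruct()].
#' @return Integer model count.
#' @export
n_models <- function(structure) {
  stopifnot(inherits(structure, "molstruct"))
  length(structure$models)
}

#' Coordinates of one model
#'
#' @param structure A [molstruct()].
#' @param model Model number (default 1).
#' @return n x 3 coordinate matrix.
#' @export
structure_coords <- function(structure, model = 1L) {
  stopifnot(inherits(structure, "molstruct"))
  model <- as.integer(model)
  if (model < 1L || model > length(structure$models)) {
    stop("model ", model, " not present (structure has ",
         length(structure$models), ")", call. = FALSE)
  }
  structure$models[[model]]
}

# Replace working coordinates (atoms x/y/z and model 1, or a chosen model).
.set_coords <- function(structure, coords, model = 1L) {
  coords <- .as_coord_matrix(coords)
  stopifnot(nrow(coords) == nrow(structure$atoms))
  structure$models[[model]] <- coords
  if (model == 1L) {
    structure$atoms$x <- coords[, 1L]
    structure$atoms$y <- coords[, 2L]
    structure$atoms$z <- coords[, 3L]
  }
  structure
}

# Row indices of one chain's atoms.
.chain_rows <- function(structure, chain) {
  rows <- which(structure$atoms$chain == chain)
  if (!length(rows)) {
    stop("chain '", chain, "' not found (available: ",
         paste(structure$chains, collapse = ", "), ")", call. = FALSE)
  }
  rows
}

#' Read a PDB structure
#'
#' Parses a PDB file (via bio3d) into a [molstruct()]. All models are
#' retained with identical atom ordering; chain order follows the file.
#' When alternate locations are present, only the highest-occupancy
#' conformer of each atom is kept.
#'
#' @param path Path to a PDB file.
#' @param format Input format; only `"pdb"` is supported.
#' @return A [molstruct()].
#' @export
read_structure <- function(path, format = "pdb") {
  format <- match.arg(format, "pdb")
  if (!file.exists(path)) {
    stop("cannot read structure: file '", path, "' does not exist",
         call. = FALSE)
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) {
      stop("failed to parse '", path, "' as PDB: ", conditionMessage(e),
           call. = FALSE)
    })
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) {
    stop("'", path, "' contains no atoms", call. = FALSE)
  }
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  if (ncol(xyz) != 3L * nrow(at)) {
    stop("'", path, "' has models with inconsistent atom counts",
         call. = FALSE)
  }
  # Altloc: keep the highest-occupancy conformer per atom site.
  alt <- at$alt
  alt[is.na(alt)] <- ""
  keep <- rep(TRUE, nrow(at))
  if (any(alt != "")) {
    occ <- at$o
    occ[is.na(occ)] <- 1
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
    best <- tapply(seq_len(nrow(at)), key, function(i) i[which.max(occ[i])])
    keep <- seq_len(nrow(at)) %in% unlist(best)
  }
  element <- at$elesy
  element[is.na(element) | element == ""] <-
    toupper(substr(trimws(at$elety[is.na(element) | element == ""]), 1L, 1L))
  atoms <- data.frame(eleno = at$eleno, elety = trimws(at$elety),
                      element = trimws(element),
                      resno = at$resno, resid = trimws(at$resid),
                      chain = as.character(at$chain),
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- " "
  atoms <- atoms[keep, , drop = FALSE]
  models <- lapply(seq_len(nrow(xyz)), function(m) {
    mm <- matrix(xyz[m, ], ncol = 3L, byrow = TRUE)
    mm[keep, , drop = FALSE]
  })
  atoms$x <- models[[1L]][, 1L]
  atoms$y <- models[[1L]][, 2L]
  atoms$z <- models[[1L]][, 3L]
  molstruct(atoms, models)
}

# One model of one structure as PDB ATOM records.
.pdb_atom_lines <- function(atoms, coords, chain_override = NULL) {
  name4 <- ifelse(nchar(atoms$elety) < 4L,
                  sprintf(" %-3s", atoms$elety),
                  substr(atoms$elety, 1L, 4L))
  chain <- if (is.null(chain_override)) atoms$chain else chain_override
  sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          (seq_len(nrow(atoms)) - 1L) %% 99999L + 1L,
          name4, atoms$resid, chain, atoms$resno,
          coords[, 1L], coords[, 2L], coords[, 3L],
          1, 0, atoms$element)
}

#' Write a polymer (or any set of monomers) to a PDB file
#'
#' Writes each monomer as a separate MODEL record (the default; chain ids
#' are preserved within each model) or, for at most 62 monomers, as
#' consecutive chains of a single model. Coordinates survive a write/read
#' round trip to PDB precision (3 decimals).
#'
#' @param monomers A list of [molstruct()] objects sharing one topology, or
#'   a single multi-model [molstruct()] (e.g. a [polymerize_structure()]
#'   result) whose models are the monomers.
#' @param path Output file path.
#' @param mode `"model"` (default) or `"chain"`.
#' @return `path`, invisibly.
#' @export
write_polymer <- function(monomers, path, mode = c("model", "chain")) {
  mode <- match.arg(mode)
  if (inherits(monomers, "molstruct")) {
    monomers <- lapply(seq_along(monomers$models), function(m) {
      .set_coords(molstruct(monomers$atoms), monomers$models[[m]])
    })
  }
  if (!is.list(monomers) || length(monomers) == 0L) {
    stop("no monomers to write", call. = FALSE)
  }
  if (!all(vapply(monomers, inherits, logical(1), "molstruct"))) {
    stop("'monomers' must be molstruct objects", call. = FALSE)
  }
  n_atoms <- vapply(monomers, function(m) nrow(m$atoms), integer(1))
  if (length(unique(n_atoms)) != 1L) {
    stop("monomers do not share a topology (atom counts differ)",
         call. = FALSE)
  }
  if (mode == "model" && n_atoms[1L] > 99999L) {
    stop("more than 99999 atoms per model: split the polymer into several ",
         "files", call. = FALSE)
  }
  lines <- character(0)
  if (mode == "model") {
    for (k in seq_along(monomers)) {
      m <- monomers[[k]]
      lines <- c(lines,
                 sprintf("MODEL     %4d", k),
                 .pdb_atom_lines(m$atoms, structure_coords(m)),
                 "ENDMDL")
    }
  } else {
    if (length(monomers) > 62L) {
      stop("chain mode supports at most 62 monomers (chain-id namespace); ",
           "use mode = \"model\"", call. = FALSE)
    }
    ids <- c(LETTERS, letters, as.character(0:9))
    if (sum(n_atoms) > 99999L) {
      stop("more than 99999 atoms in chain mode: split the polymer or use ",
           "mode = \"model\"", call. = FALSE)
    }
    for (k in seq_along(monomers)) {
      m <- monomers[[k]]
      lines <- c(lines,
                 .pdb_atom_lines(m$atoms, structure_coords(m),
                                 chain_override = ids[k]),
                 "TER")
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Residue-range core selection
#'
#' Describes the residue ranges (author numbering, inclusive) and atom
#' filter used to pick the structural core for superposition and RMSD.
#' The default ranges are the beta-sandwich core strands of
#' beta-2-microglobulin (residues 23-27, 36-39, 51-55, 62-66, 78-82), which
#' exclude the mobile loops and the unstructured N-/C-termini; any other
#' protein core can be described by passing its own ranges.
#'
#' @param ranges List of 2-vectors `c(start, end)`, non-overlapping,
#'   `start <= end`.
#' @param calpha Restrict to C-alpha atoms (default TRUE).
#' @return An object of class `core_selection`.
#' @export
core_selection <- function(ranges = list(c(23, 27), c(36, 39), c(51, 55),
                                         c(62, 66), c(78, 82)),
                           calpha = TRUE) {
  if (!length(ranges)) stop("empty range list", call. = FALSE)
  m <- do.call(rbind, lapply(ranges, function(r) {
    r <- as.numeric(r)
    if (length(r) != 2L || !all(is.finite(r)) || r[1] > r[2]) {
      stop("each range must be c(start, end) with start <= end",
           call. = FALSE)
    }
    r
  }))
  m <- m[order(m[, 1L]), , drop = FALSE]
  if (nrow(m) > 1L && any(m[-1L, 1L] <= m[-nrow(m), 2L])) {
    stop("ranges overlap", call. = FALSE)
  }
  structure(list(ranges = m, calpha = isTRUE(calpha)),
            class = "core_selection")
}

#' @export
print.core_selection <- function(x, ...) {
  cat("Core selection:",
      paste(sprintf("%g-%g", x$ranges[, 1], x$ranges[, 2]), collapse = ", "),
      if (x$calpha) "(C-alpha only)" else "(all atoms)", "\n")
  invisible(x)
}

#' Select core coordinates of one chain
#'
#' Returns the coordinates of the atoms of `chain` whose residue numbers
#' fall inside the selection ranges, in residue order. With the default
#' C-alpha filter this is the coordinate set used for structural alignment
#' and RMSD of the folded core.
#'
#' @param structure A [molstruct()].
#' @param chain Chain id.
#' @param selection A [core_selection()].
#' @param model Model number (default 1).
#' @return n x 3 coordinate matrix with residue numbers as row names.
#' @export
select_core <- function(structure, chain, selection = core_selection(),
                        model = 1L) {
  stopifnot(inherits(structure, "molstruct"),
            inherits(selection, "core_selection"))
  rows <- .chain_rows(structure, chain)
  at <- structure$atoms[rows, , drop = FALSE]
  in_range <- rep(FALSE, nrow(at))
  for (k in seq_len(nrow(selection$ranges))) {
    in_range <- in_range | (at$resno >= selection$ranges[k, 1L] &
                            at$resno <= selection$ranges[k, 2L])
  }
  pick <- in_range
  if (selection$calpha) pick <- pick & at$elety == "CA"
  if (!any(pick)) {
    stop("core selection matches no atoms in chain '", chain, "'",
         call. = FALSE)
  }
  sel_rows <- rows[pick][order(at$resno[pick])]
  coords <- structure_coords(structure, model)[sel_rows, , drop = FALSE]
  rownames(coords) <- structure$atoms$resno[sel_rows]
  coords
}
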