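# Shared fixtures, computed once per test run. Angle-targeted dimers are the
# expensive objects (each one runs the pose optimizer through the SASA
# pipeline), so they are cached.

.fx <- new.env(parent = emptyenv())

tail_monomer <- function() {
  if (is.null(.fx$tail_monomer)) {
    .fx$tail_monomer <- make_monomer(16, shape = "with-termini",
                                     termini_length = 4, seed = 3)
  }
  .fx$tail_monomer
}

fixture_dimer <- function(theta, phi) {
  key <- sprintf("dimer_%g_%g", theta, phi)
  if (is.null(.fx[[key]])) {
    .fx[[key]] <- make_dimer(tail_monomer(), theta, phi)
  }
  .fx[[key]]
}

# A dimer whose chain B is an exact rigid copy of chain A under `transform`.
rigid_copy_dimer <- function(monomer, transform) {
  a <- structure_coords(monomer)
  b <- apply_transform(transform, a)
  at <- rbind(monomer$atoms, monomer$atoms)
  at$chain <- rep(c("A", "B"), each = nrow(monomer$atoms))
  at$eleno <- seq_len(nrow(at))
  at$x <- c(a[, 1], b[, 1]); at$y <- c(a[, 2], b[, 2])
  at$z <- c(a[, 3], b[, 3])
  molstruct(at)
}

rotation_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}
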