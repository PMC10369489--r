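# The replicate tests use small pseudo-monomers; their full residue range is
# the superposition core.
full_core <- function(monomer) {
  core_selection(list(c(1, max(monomer$atoms$resno))))
}

test_that("dimer transforms recover exact rigid relations", {
  m <- make_monomer(20, seed = 8)
  core <- full_core(m)

  shift <- rigid_transform(diag(3), c(10, 0, 0))
  d <- rigid_copy_dimer(m, shift)
  fit <- dimer_transform(d, core = core)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit$transform$rotation, diag(3), tolerance = 1e-9)
  expect_equal(fit$transform$translation, c(10, 0, 0), tolerance = 1e-9)

  rt <- rigid_transform(rotation_z(90), c(4, -3, 7))
  fit <- dimer_transform(rigid_copy_dimer(m, rt), core = core)
  expect_equal(fit$transform$rotation, rt$rotation, tolerance = 1e-9)
  expect_equal(fit$transform$translation, rt$translation, tolerance = 1e-9)
})

test_that("conformationally perturbed monomers report the quaternion-oracle RMSD", {
  m <- make_monomer(20, seed = 8)
  a <- structure_coords(m)
  set.seed(99)
  b <- apply_transform(rigid_transform(rotation_z(40), c(8, 1, -2)), a) +
    matrix(rnorm(length(a), sd = 0.2), ncol = 3)
  at <- rbind(m$atoms, m$atoms)
  at$chain <- rep(c("A", "B"), each = nrow(m$atoms))
  at$eleno <- seq_len(nrow(at))
  at$x <- c(a[, 1], b[, 1]); at$y <- c(a[, 2], b[, 2]); at$z <- c(a[, 3], b[, 3])
  d <- molstruct(at)
  fit <- dimer_transform(d, core = full_core(m))
  expect_equal(fit$rmsd, quaternion_rmsd(a, b), tolerance = 1e-9)
})

test_that("missing core residues are reported by name", {
  m <- make_monomer(20, seed = 8)
  d <- rigid_copy_dimer(m, rigid_transform(diag(3), c(10, 0, 0)))
  d$atoms <- d$atoms[!(d$atoms$chain == "B" & d$atoms$resno %in% 4:5), ]
  d <- molstruct(d$atoms)
  expect_error(dimer_transform(d, core = full_core(m)), "missing in B: 4, 5")
})

test_that("polymerization iterates the transform over the full atom set", {
  m <- make_monomer(15, seed = 10)
  core <- full_core(m)
  shift <- rigid_transform(diag(3), c(20, 0, 0))
  d <- rigid_copy_dimer(m, shift)

  pol <- polymerize_structure(d, n = 5, core = core)
  expect_equal(n_models(pol), 5)
  for (k in 1:5) {
    expect_equal(structure_coords(pol, k),
                 structure_coords(m) +
                   matrix(rep(c(20, 0, 0) * (k - 1), each = nrow(m$atoms)),
                          ncol = 3),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }

  # 32-monomer horizon with the monomer topology preserved
  pol <- polymerize_structure(d, n = 32, core = core)
  expect_equal(n_models(pol), 32)
  expect_equal(nrow(pol$atoms), nrow(m$atoms))

  # monomer 2 reproduces chain B within the fit RMSD (here exactly)
  rows_b <- d$atoms$chain == "B"
  expect_equal(structure_coords(pol, 2),
               structure_coords(d)[rows_b, , drop = FALSE],
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(polymerize_structure(d, n = 1, core = core), "at least 2")
})

test_that("sequential propagation equals iterated transform powers", {
  d <- fixture_dimer(123, 16)
  core <- full_core(tail_monomer())
  pol <- polymerize_structure(d, n = 8, core = core)
  tr <- attr(pol, "transform")
  acc <- rigid_transform(diag(3), c(0, 0, 0))
  for (k in 2:8) {
    acc <- compose_transform(acc, tr)
    expect_equal(structure_coords(pol, k),
                 apply_transform(acc, structure_coords(pol, 1)),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("clash counting matches brute force and behaves monotonically", {
  m <- make_monomer(15, seed = 10)
  core <- full_core(m)

  # widely spaced straight polymer: no clashes
  far <- polymerize_structure(
    rigid_copy_dimer(m, rigid_transform(diag(3), c(25, 0, 0))),
    n = 6, core = core)
  expect_equal(clash_count(far), 0)

  # tightly curling polymer: must collide with itself
  curl <- polymerize_structure(
    rigid_copy_dimer(m, rigid_transform(rotation_z(120), c(6, 0, 0))),
    n = 16, core = core)
  heavy <- curl$atoms$element != "H"
  n2 <- clash_count(curl, cutoff = 2)
  expect_gt(n2, 0)
  expect_equal(n2, bruteforce_clashes(curl$models, heavy, cutoff = 2))
  n4 <- clash_count(curl, cutoff = 4)
  expect_gte(n4, n2)
  expect_equal(n4, bruteforce_clashes(curl$models, heavy, cutoff = 4))
  expect_error(clash_count(rigid_copy_dimer(m, rigid_transform(diag(3),
    c(25, 0, 0)))), "at least 3")
})

test_that("structure-level growth classification matches the landscape regions", {
  core <- full_core(tail_monomer())

  hel <- classify_structure_growth(fixture_dimer(123, 16), core = core)
  expect_equal(hel$mode, "unlimited")
  expect_equal(hel$subtype, "hel")

  lim <- classify_structure_growth(fixture_dimer(105, 10), core = core)
  expect_equal(lim$mode, "limited")

  expect_error(
    classify_structure_growth(make_dimer(tail_monomer(), 90, 90, gap = 100),
                              core = core),
    "no interface")
})

test_that("a translation-only homodimer polymerizes linearly without limit", {
  m <- make_monomer(24, shape = "with-termini", termini_length = 5,
                    seed = 13)
  b <- structure_coords(m)
  span <- max(b[, 1]) - min(b[, 1])
  d <- rigid_copy_dimer(m, rigid_transform(diag(3), c(span + 3.6, 0, 0)))
  cl <- classify_structure_growth(d, core = full_core(m), force_atomic = TRUE)
  expect_equal(cl$mode, "unlimited")
  expect_equal(cl$subtype, "lin")
})
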