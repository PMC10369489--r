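# Small hand-built structures used by the SASA and interface checks.
atom_cluster <- function(coords, chain = "A", resno = NULL) {
  coords <- matrix(coords, ncol = 3)
  if (is.null(resno)) resno <- seq_len(nrow(coords))
  molstruct(data.frame(
    eleno = seq_len(nrow(coords)), elety = "CA", element = "C",
    resno = resno, resid = "UNK", chain = chain,
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    stringsAsFactors = FALSE))
}

test_that("single-sphere SASA matches the closed form", {
  s <- atom_cluster(c(0, 0, 0))
  a <- residue_sasa(s)
  expect_equal(a$area, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.02)

  # two fully separated atoms: no burial
  s2 <- atom_cluster(rbind(c(0, 0, 0), c(100, 0, 0)))
  a2 <- residue_sasa(s2)
  expect_equal(a2$area, rep(4 * pi * 3.1^2, 2), tolerance = 0.02)

  expect_error(residue_sasa(atom_cluster(c(0, 0, 0)) |>
    (\(m) { m$atoms$element <- "XX"; m })()), "XX")
})

test_that("cluster SASA agrees with a brute-force oracle", {
  set.seed(31)
  coords <- matrix(rnorm(30, sd = 2.2), ncol = 3)
  s <- atom_cluster(coords)
  mine <- attr(residue_sasa(s), "atom_area")
  oracle <- bruteforce_sasa(coords, rep(1.7, 10))
  expect_equal(mine, oracle, tolerance = 0.03)
  # per-residue areas sum to the molecular total
  res <- residue_sasa(s)
  expect_equal(sum(res$area), attr(res, "total"), tolerance = 1e-9)
})

test_that("interfacial areas vanish for separated monomers and match the oracle in contact", {
  far <- atom_cluster(rbind(matrix(rnorm(15, sd = 2), ncol = 3),
                            matrix(rnorm(15, sd = 2) + 100, ncol = 3)),
                      chain = rep(c("A", "B"), each = 5),
                      resno = rep(1:5, 2))
  ia <- interfacial_areas(far)
  expect_true(all(ia$delta_sasa == 0))
  expect_true(interface_descriptor(far)$no_interface)

  # two 15-atom clusters in contact
  set.seed(12)
  ca <- matrix(rnorm(45, sd = 2.0), ncol = 3)
  cb <- sweep(matrix(rnorm(45, sd = 2.0), ncol = 3), 2, c(6.5, 0, 0), "+")
  dimer <- atom_cluster(rbind(ca, cb), chain = rep(c("A", "B"), each = 15),
                        resno = rep(1:15, 2))
  ia <- interfacial_areas(dimer)
  total <- attr(ia, "total_area")
  expect_gt(total, 0)

  radii <- rep(1.7, 15)
  or_a <- bruteforce_sasa(ca, radii)
  or_b <- bruteforce_sasa(cb, radii)
  or_c <- bruteforce_sasa(rbind(ca, cb), rep(1.7, 30))
  or_total <- sum(pmax(0, c(or_a, or_b) - or_c))
  expect_equal(total, or_total, tolerance = 0.05)
  expect_equal(attr(ia, "total_area_nm2"), total / 100)

  # the interface residue set matches the oracle's at the same threshold
  # (residues with only marginal isolated exposure are excluded: their
  # relative burial is a 0/0 artifact in either implementation)
  rel_or <- 100 * pmax(0, c(or_a, or_b) - or_c) / c(or_a, or_b)
  exposed <- c(or_a, or_b) > 10
  desc <- interface_descriptor(dimer)
  expect_setequal(intersect(desc$interface_a, which(exposed[1:15])),
                  which(rel_or[1:15] > 10 & exposed[1:15]))
  expect_setequal(intersect(desc$interface_b, which(exposed[16:30])),
                  which(rel_or[16:30] > 10 & exposed[16:30]))
})

test_that("total interfacial area is symmetric under chain relabeling", {
  d <- fixture_dimer(90, 90)
  ab <- interfacial_areas(d, chains = c("A", "B"))
  ba <- interfacial_areas(d, chains = c("B", "A"))
  expect_equal(attr(ab, "total_area"), attr(ba, "total_area"),
               tolerance = 1e-9)
})

test_that("per-residue burial never exceeds the isolated exposure", {
  d <- fixture_dimer(90, 90)
  ia <- interfacial_areas(d)
  expect_true(all(ia$delta_sasa <= ia$sasa_free + 1e-9))
  expect_true(all(ia$rel_pct >= 0 & ia$rel_pct <= 100))
})

test_that("raising the threshold never grows an interface set", {
  d <- fixture_dimer(90, 90)
  ia <- interfacial_areas(d)
  prev_a <- NULL
  for (thr in c(5, 10, 20, 40)) {
    desc <- interface_descriptor(d, threshold = thr, areas = ia)
    if (!is.null(prev_a)) {
      expect_true(all(desc$interface_a %in% prev_a))
      expect_true(all(desc$interface_b %in% prev_b))
    }
    prev_a <- desc$interface_a
    prev_b <- desc$interface_b
  }
})

test_that("geometric centers obey the descriptor contract", {
  d <- fixture_dimer(90, 90)
  desc <- interface_descriptor(d)
  rows_a <- d$atoms$chain == "A"
  expect_equal(desc$gc_a,
               colMeans(structure_coords(d)[rows_a, , drop = FALSE]),
               tolerance = 1e-9)
  ia_rows <- rows_a & d$atoms$resno %in% desc$interface_a
  expect_equal(desc$gc_ia,
               colMeans(structure_coords(d)[ia_rows, , drop = FALSE]),
               tolerance = 1e-9)
  # every listed interface residue clears the threshold
  a <- desc$areas
  listed <- a$rel_pct[a$chain == "A" & a$resno %in% desc$interface_a]
  expect_true(all(listed > desc$threshold))
})

test_that("ensemble-max normalization requires an ensemble", {
  d <- fixture_dimer(90, 90)
  expect_error(interfacial_areas(d, normalization = "ensemble-max"),
               "multi-model")
})

test_that("conserved interface fraction counts residue identities", {
  fake <- function(a, b) {
    structure(list(chains = c("A", "B"), interface_a = a, interface_b = b),
              class = "interface_descriptor")
  }
  expect_equal(conserved_interface_fraction(fake(1:5, 1:5), fake(1:5, 1:5)),
               100)
  expect_equal(conserved_interface_fraction(fake(1:5, 1:5),
                                            fake(11:15, 11:15)), 0)
  expect_equal(conserved_interface_fraction(fake(1:10, integer(0)),
                                            fake(1:5, integer(0))), 50)
  expect_error(conserved_interface_fraction(fake(integer(0), integer(0)),
                                            fake(1:5, 1:5)), "empty")
})

test_that("interface tables round values and flag interface residues", {
  d <- fixture_dimer(90, 90)
  desc <- interface_descriptor(d)
  tab <- interface_table(desc)
  expect_equal(sum(tab$interface),
               length(desc$interface_a) + length(desc$interface_b))
  path <- tempfile(fileext = ".tsv")
  interface_table(desc, path)
  back <- read.delim(path)
  expect_equal(nrow(back), nrow(tab))
})
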