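test_that("polymerization angle matches hand-computed cases", {
  gca <- c(0, 0, 0); gcb <- c(-2, 0, 0)
  expect_equal(polymerization_angle(gca, gcb, c(-1, 0, 0)), 180)
  expect_equal(polymerization_angle(gca, gcb, c(1, 0, 0)), 0)
  # vectors (0,1,0) and (2,1,0): cosine 1/sqrt(5)
  expect_equal(polymerization_angle(gca, gcb, c(0, 1, 0)),
               acos(1 / sqrt(5)) * 180 / pi, tolerance = 1e-12)
  expect_error(polymerization_angle(gca, gcb, gca), "degenerate")
})

test_that("polymerization dihedral matches hand-computed cases", {
  gca <- c(0, 0, 0); gcb <- c(-2, 0, 0); gcia <- c(0, 1, 0)
  # opposite sides, coplanar: both normals (0,0,2)
  expect_equal(polymerization_dihedral(gca, gcb, gcia, c(-2, -1, 0)), 0)
  # same side, coplanar: normals anti-aligned
  expect_equal(polymerization_dihedral(gca, gcb, gcia, c(-2, 1, 0)), 180)
  # perpendicular placement
  expect_equal(polymerization_dihedral(gca, gcb, gcia, c(-2, 0, 1)), 90)
  expect_error(polymerization_dihedral(gca, gcb, gcia, c(-4, 0, 0)),
               "colinear")
})

test_that("angles are invariant under rigid motion and scaling", {
  set.seed(11)
  for (rep in 1:5) {
    pts <- lapply(1:4, function(i) rnorm(3, sd = 4))
    names(pts) <- c("gca", "gcb", "gcia", "gcib")
    th <- polymerization_angle(pts$gca, pts$gcb, pts$gcia)
    ph <- polymerization_dihedral(pts$gca, pts$gcb, pts$gcia, pts$gcib)
    r <- rotation_z(runif(1, 0, 360))
    shift <- rnorm(3, sd = 10)
    s <- runif(1, 0.2, 5)  # uniform scaling about an arbitrary fixed point
    pivot <- rnorm(3)
    mv <- lapply(pts, function(p) as.numeric(r %*% p) + shift)
    sc <- lapply(pts, function(p) pivot + s * (p - pivot))
    expect_equal(polymerization_angle(mv$gca, mv$gcb, mv$gcia), th,
                 tolerance = 1e-9)
    expect_equal(polymerization_dihedral(mv$gca, mv$gcb, mv$gcia, mv$gcib),
                 ph, tolerance = 1e-9)
    expect_equal(polymerization_angle(sc$gca, sc$gcb, sc$gcia), th,
                 tolerance = 1e-9)
    expect_equal(polymerization_dihedral(sc$gca, sc$gcb, sc$gcia, sc$gcib),
                 ph, tolerance = 1e-9)
  }
})

test_that("surface mapping of interface centers leaves angles unchanged", {
  # mapping GC_IA onto a monomer surface rescales the vector from the
  # center without changing its direction
  gca <- c(0, 0, 0); gcb <- c(-2, 0, 0)
  gcia <- c(-0.4, 1.3, 0.2); gcib <- c(-1.7, -0.8, 0.9)
  mapped_ia <- gcb + 1 * (gcia - gcb) / sqrt(sum((gcia - gcb)^2))
  expect_equal(
    polymerization_dihedral(gca, gcb, mapped_ia, gcib),
    polymerization_dihedral(gca, gcb, gcia, gcib),
    tolerance = 1e-9)
})

test_that("shape descriptor reproduces closed-form limits", {
  oct <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  s <- shape_descriptor(oct)
  expect_equal(s$asphericity, 0, tolerance = 1e-12)
  expect_equal(s$sphericity, 100, tolerance = 1e-9)

  rod <- cbind(seq(-3, 3, length.out = 9), 0, 0)
  expect_equal(shape_descriptor(rod)$asphericity, 1, tolerance = 1e-12)

  # regular planar hexagon: eigenvalues (a, a, 0) give As = 1/4
  ang <- seq(0, 300, by = 60) * pi / 180
  hexagon <- cbind(cos(ang), sin(ang), 0)
  s <- shape_descriptor(hexagon)
  expect_equal(s$asphericity, 0.25, tolerance = 1e-12)
  expect_equal(s$sphericity, 75, tolerance = 1e-9)
})

test_that("shape descriptor invariants hold on random configurations", {
  set.seed(5)
  for (rep in 1:20) {
    pts <- matrix(runif(60), ncol = 3)
    s <- shape_descriptor(pts)
    expect_gte(s$asphericity, 0)
    expect_lte(s$asphericity, 1)
    expect_equal(sum(s$lambdas), s$rg^2, tolerance = 1e-9)
    perm <- shape_descriptor(pts[sample(nrow(pts)), ])
    expect_equal(perm$lambdas, s$lambdas, tolerance = 1e-9)
  }
  expect_error(shape_descriptor(matrix(1, 4, 3)), "zero")
})

test_that("mass weighting shifts the gyration tensor as expected", {
  pts <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, 2, 0), c(0, 0, 1))
  uni <- shape_descriptor(pts)
  heavy <- shape_descriptor(pts, weights = "mass", masses = c(1, 1, 100, 1))
  # dominant mass collapses the cloud towards that point: smaller Rg
  expect_lt(heavy$rg, uni$rg)
  expect_error(shape_descriptor(pts, weights = "mass"), "masses")
})

test_that("superposition recovers exact transforms and matches the quaternion oracle", {
  set.seed(7)
  pts <- matrix(rnorm(30, sd = 3), ncol = 3)

  same <- superpose(pts, pts)
  expect_equal(same$rmsd, 0, tolerance = 1e-9)
  expect_equal(same$transform$rotation, diag(3), tolerance = 1e-9)

  r0 <- rotation_z(37.5)
  target <- sweep(pts %*% t(r0), 2, c(1, -2, 3), "+")
  fit <- superpose(pts, target)
  expect_equal(fit$transform$rotation, r0, tolerance = 1e-9)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)

  noisy <- target + matrix(rnorm(30, sd = 0.1), ncol = 3)
  fit <- superpose(pts, noisy)
  expect_equal(fit$rmsd, quaternion_rmsd(pts, noisy), tolerance = 1e-9)
  # self-consistency: applying the transform reproduces the reported RMSD
  moved <- apply_transform(fit$transform, pts)
  expect_equal(sqrt(mean(rowSums((moved - noisy)^2))), fit$rmsd,
               tolerance = 1e-12)

  expect_error(superpose(pts[1:2, ], pts[1:2, ]), "3 points")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "collinear")
})

test_that("angles_from_dimer recovers the prescribed angles of a fixture dimer", {
  d <- fixture_dimer(90, 90)
  ang <- angles_from_dimer(d)
  expect_lt(abs(ang$theta_pol - 90), 5)
  expect_lt(abs(ang$phi_pol - 90), 5)
})

test_that("a mirror-symmetric dimer has a coplanar dihedral", {
  m <- tail_monomer()
  a <- structure_coords(m)
  gc <- colMeans(a)
  body <- sweep(a, 2, gc)
  u <- 60 * pi / 180
  rot <- dimergrow:::.rotation_between(c(1, 0, 0), c(-cos(u), sin(u), 0))
  a_pos <- body %*% t(rot)
  b_pos <- a_pos
  b_pos[, 1] <- -8 - b_pos[, 1]  # reflect through the contact plane x = -4
  at <- rbind(m$atoms, m$atoms)
  at$chain <- rep(c("A", "B"), each = nrow(m$atoms))
  at$eleno <- seq_len(nrow(at))
  at$x <- c(a_pos[, 1], b_pos[, 1])
  at$y <- c(a_pos[, 2], b_pos[, 2])
  at$z <- c(a_pos[, 3], b_pos[, 3])
  dimer <- molstruct(at)
  ang <- angles_from_dimer(dimer)
  expect_lt(min(ang$phi_pol, 180 - ang$phi_pol), 1)
})

test_that("angles_from_dimer rejects separated monomers", {
  m <- tail_monomer()
  d <- make_dimer(m, 90, 90, gap = 100)
  expect_error(angles_from_dimer(d), "no interface")
})
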