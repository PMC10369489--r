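# Independent oracles used to cross-check the implementation. These are
# deliberately written with different algorithms/code paths than the
# package internals.

# Horn's quaternion method for optimal superposition RMSD: the maximum
# eigenvalue of the 4x4 key matrix gives the optimal rotation.
quaternion_rmsd <- function(mobile, target) {
  p <- sweep(mobile, 2, colMeans(mobile))
  q <- sweep(target, 2, colMeans(target))
  m <- crossprod(p, q)  # sum over points of p_i q_i^T
  sxx <- m[1, 1]; sxy <- m[1, 2]; sxz <- m[1, 3]
  syx <- m[2, 1]; syy <- m[2, 2]; syz <- m[2, 3]
  szx <- m[3, 1]; szy <- m[3, 2]; szz <- m[3, 3]
  key <- matrix(c(
    sxx + syy + szz, syz - szy,       szx - sxz,       sxy - syx,
    syz - szy,       sxx - syy - szz, sxy + syx,       szx + sxz,
    szx - sxz,       sxy + syx,       -sxx + syy - szz, syz + szy,
    sxy - syx,       szx + sxz,       syz + szy,       -sxx - syy + szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(key, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(p^2) + sum(q^2) - 2 * lam) / nrow(p)
  sqrt(max(0, msd))
}

# Brute-force Shrake-Rupley SASA with random (seeded) surface points and a
# naive all-against-all double loop.
bruteforce_sasa <- function(coords, radii, probe = 1.4, n_points = 10000,
                            seed = 42) {
  set.seed(seed)
  n <- nrow(coords)
  big <- radii + probe
  areas <- numeric(n)
  for (i in seq_len(n)) {
    v <- matrix(rnorm(3 * n_points), ncol = 3)
    v <- v / sqrt(rowSums(v^2))
    pts <- sweep(v * big[i], 2, coords[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in seq_len(n)) {
      if (j == i) next
      d2 <- (pts[, 1] - coords[j, 1])^2 + (pts[, 2] - coords[j, 2])^2 +
        (pts[, 3] - coords[j, 3])^2
      acc <- acc & d2 >= big[j]^2
    }
    areas[i] <- 4 * pi * big[i]^2 * mean(acc)
  }
  areas
}

# Brute-force clash count: all-against-all atom pairs across monomers.
bruteforce_clashes <- function(models, heavy, cutoff, min_gap = 2) {
  n <- length(models)
  count <- 0L
  for (i in seq_len(n - min_gap)) {
    for (j in seq(i + min_gap, n)) {
      a <- models[[i]][heavy, , drop = FALSE]
      b <- models[[j]][heavy, , drop = FALSE]
      for (k in seq_len(nrow(a))) {
        d2 <- (b[, 1] - a[k, 1])^2 + (b[, 2] - a[k, 2])^2 +
          (b[, 3] - a[k, 3])^2
        count <- count + sum(d2 < cutoff^2)
      }
    }
  }
  count
}

# Minimal independent PDB ATOM-record reader (fixed-column substrings).
naive_pdb_read <- function(path) {
  lines <- readLines(path)
  at <- lines[startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")]
  data.frame(
    elety = trimws(substr(at, 13, 16)),
    resid = trimws(substr(at, 18, 20)),
    chain = trimws(substr(at, 22, 22)),
    resno = as.integer(substr(at, 23, 26)),
    x = as.numeric(substr(at, 31, 38)),
    y = as.numeric(substr(at, 39, 46)),
    z = as.numeric(substr(at, 47, 54)),
    stringsAsFactors = FALSE)
}
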