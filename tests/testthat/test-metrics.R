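rot_z <- function(deg) {
  th <- deg * pi / 180
  rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
}

test_that("superposition exactly recovers a rigid motion", {
  set.seed(21)
  ref <- matrix(rnorm(30, sd = 5), ncol = 3)
  mob <- sweep(ref %*% rot_z(37), 2L, c(5, -2, 1), `+`)
  fit <- superpose(mob, ref)
  expect_lt(fit$rmsd, 1e-6)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-8)
  expect_lt(max(abs(sweep(mob %*% fit$rotation, 2L, fit$translation, `+`) -
                      ref)), 1e-8)
  idfit <- superpose(ref, ref)
  expect_equal(idfit$rotation, diag(3), tolerance = 1e-8)
  expect_equal(idfit$translation, rep(0, 3), tolerance = 1e-8)
  expect_equal(idfit$rmsd, 0, tolerance = 1e-10)
})

test_that("fitted RMSD matches the independent bio3d implementation", {
  set.seed(22)
  for (i in 1:10) {
    ref <- matrix(rnorm(33, sd = 4), ncol = 3)
    mob <- ref
    mob[1, ] <- mob[1, ] + c(1, 0, 0)  # one atom displaced
    mob <- sweep(mob %*% rot_z(runif(1, 0, 360)), 2L, rnorm(3, sd = 8), `+`)
    ours <- superpose(mob, ref)$rmsd
    fitted <- suppressWarnings(bio3d::fit.xyz(
      fixed = as.vector(t(ref)), mobile = as.vector(t(mob))))
    theirs <- sqrt(mean(rowSums(
      (matrix(fitted, ncol = 3, byrow = TRUE) - ref)^2)))
    expect_equal(ours, theirs, tolerance = 1e-6)
  }
})

test_that("superposition never returns a reflection", {
  set.seed(23)
  for (i in 1:20) {
    a <- matrix(rnorm(15), ncol = 3)
    b <- matrix(rnorm(15), ncol = 3)
    expect_equal(det(superpose(a, b)$rotation), 1, tolerance = 1e-8)
  }
  expect_error(superpose(matrix(0, 2, 3), matrix(0, 2, 3)), "degenerate")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line + 1), "degenerate")
})

test_that("rmsd series of rigid-body motions of the reference is zero", {
  set.seed(24)
  base <- matrix(rnorm(60, sd = 5), ncol = 3)
  coords <- array(0, c(20, 3, 6))
  for (f in 1:6)
    coords[, , f] <- sweep(base %*% rot_z(f * 25), 2L, rnorm(3, sd = 10), `+`)
  traj <- trajectory(carbon_topology(20), coords)
  rs <- rmsd_series(traj, 1L, 1:20)
  expect_true(all(rs$rmsd < 1e-8))
  # no-fit mode reports the raw displacement norm
  coords2 <- array(0, c(20, 3, 2))
  coords2[, , 1] <- base
  coords2[, , 2] <- sweep(base, 2L, c(3, 4, 0), `+`)
  rs2 <- rmsd_series(trajectory(carbon_topology(20), coords2), 1L, 1:20,
                     fit = FALSE)
  expect_equal(rs2$rmsd[2], 5, tolerance = 1e-10)
})

test_that("no-fit RMSD obeys the triangle inequality", {
  set.seed(25)
  a <- matrix(rnorm(30), ncol = 3)
  b <- matrix(rnorm(30), ncol = 3)
  cc <- matrix(rnorm(30), ncol = 3)
  d <- function(x, y) sqrt(mean(rowSums((x - y)^2)))
  expect_lte(d(a, cc), d(a, b) + d(b, cc) + 1e-12)
})

test_that("planted Gaussian jitter gives mean RMSD near sigma*sqrt(3)", {
  set.seed(26)
  base <- matrix(rnorm(300, sd = 8), ncol = 3)
  nf <- 60; sigma <- 0.5
  coords <- array(0, c(100, 3, nf))
  for (f in 1:nf) coords[, , f] <- base + matrix(rnorm(300, sd = sigma),
                                                 ncol = 3)
  traj <- trajectory(carbon_topology(100), coords)
  rs <- rmsd_series(traj, base, 1:100, fit = FALSE)
  expect_equal(mean(rs$rmsd), sigma * sqrt(3), tolerance = 0.05)
})

test_that("RMSF limits: static zero and alternating unit displacement", {
  base <- matrix(rnorm(45, sd = 5), ncol = 3)
  coords <- array(base, c(15, 3, 8))
  traj <- trajectory(carbon_topology(15), coords)
  rf <- rmsf_per_residue(traj, 1:15, fit = FALSE)
  expect_true(all(rf$rmsf < 1e-12))
  expect_error(rmsf_per_residue(trajectory(carbon_topology(15),
                                           coords[, , 1, drop = FALSE])),
               "insufficient frames")
  # one atom alternating +/-1 A in x, fit off
  coords2 <- coords
  for (f in 1:8) coords2[1, 1, f] <- base[1, 1] + (-1)^f
  rf2 <- rmsf_per_residue(trajectory(carbon_topology(15), coords2), 1:15,
                          fit = FALSE)
  expect_equal(rf2$rmsf[1], 1, tolerance = 1e-12)
  expect_true(all(rf2$rmsf[-1] < 1e-12))
})

test_that("two planted mobility classes are recovered within 10%", {
  set.seed(27)
  n <- 40; nf <- 400
  base <- matrix(rnorm(n * 3, sd = 10), ncol = 3)
  sig <- rep(c(0.3, 1.0), each = n / 2)
  coords <- array(0, c(n, 3, nf))
  for (f in 1:nf) coords[, , f] <- base + matrix(rnorm(n * 3, sd = sig),
                                                 ncol = 3)
  traj <- trajectory(carbon_topology(n), coords)
  rf <- rmsf_per_residue(traj, 1:n, fit = FALSE)
  expect_equal(mean(rf$rmsf[1:(n / 2)]), 0.3 * sqrt(3), tolerance = 0.1)
  expect_equal(mean(rf$rmsf[(n / 2 + 1):n]), 1.0 * sqrt(3), tolerance = 0.1)
})

test_that("RMSF with fitting is invariant under per-frame rigid motions", {
  set.seed(28)
  n <- 30; nf <- 30
  base <- matrix(rnorm(n * 3, sd = 6), ncol = 3)
  coords <- array(0, c(n, 3, nf))
  jitter <- array(rnorm(n * 3 * nf, sd = 0.4), c(n, 3, nf))
  for (f in 1:nf) coords[, , f] <- base + jitter[, , f]
  plain <- rmsf_per_residue(trajectory(carbon_topology(n), coords),
                            1:n, fit = TRUE)
  for (f in 1:nf)
    coords[, , f] <- sweep(coords[, , f] %*% rot_z(f * 11), 2L,
                           c(f, -2 * f, 0.5 * f), `+`)
  moved <- rmsf_per_residue(trajectory(carbon_topology(n), coords),
                            1:n, fit = TRUE)
  expect_equal(plain$rmsf, moved$rmsf, tolerance = 1e-6)
})
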