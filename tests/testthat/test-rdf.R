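# build a trajectory holding one reference atom and target atoms at scripted
# positions; extra machinery-free constructor for RDF tests
rdf_traj <- function(target_positions_by_frame, box = c(20, 20, 20)) {
  nf <- length(target_positions_by_frame)
  nt <- nrow(target_positions_by_frame[[1]])
  coords <- array(0, c(nt + 1, 3, nf))
  for (f in seq_len(nf)) coords[2:(nt + 1), , f] <-
      target_positions_by_frame[[f]]
  trajectory(carbon_topology(nt + 1), coords,
             box = matrix(box, nf, 3, byrow = TRUE))
}

test_that("uniform ideal-gas targets give g near 1 beyond the first bins", {
  set.seed(31)
  nf <- 60; nt <- 400
  frames <- lapply(seq_len(nf), function(f)
    matrix(runif(nt * 3, -10, 10), ncol = 3))
  traj <- rdf_traj(frames)
  prof <- rdf(traj, 1L, 2:(nt + 1), r_max = 8, bin_width = 0.25)
  sel <- prof$r > 2
  expect_equal(mean(prof$g[sel]), 1, tolerance = 0.05)
  expect_true(all(abs(prof$g[sel] - 1) < 0.35))
})

test_that("a fixed 5.0 A pair lands all counts in the 5.0 A bin", {
  frames <- lapply(1:10, function(f) matrix(c(5, 0, 0), 1))
  traj <- rdf_traj(frames)
  prof <- rdf(traj, 1L, 2L, r_max = 10, bin_width = 0.1)
  expect_equal(sum(prof$counts), 10L)
  expect_equal(prof$r[which(prof$counts > 0)], 4.95, tolerance = 0.051)
  # all pairs beyond r_max: g identically zero
  far <- rdf_traj(lapply(1:5, function(f) matrix(c(19, 0, 0), 1)))
  prof0 <- rdf(far, 1L, 2L, r_max = 10, bin_width = 0.1)
  expect_true(all(prof0$g == 0))
  expect_error(pmf_from_rdf(prof0), "no defined PMF")
})

test_that("histogram counts conserve the within-range pair total", {
  set.seed(32)
  nf <- 8; nt <- 50
  frames <- lapply(seq_len(nf), function(f)
    matrix(runif(nt * 3, -6, 6), ncol = 3))
  traj <- rdf_traj(frames)
  prof <- rdf(traj, 1L, 2:(nt + 1), r_max = 7, bin_width = 0.05)
  manual <- 0L
  for (f in seq_len(nf)) {
    d <- sqrt(rowSums(frames[[f]]^2))
    manual <- manual + sum(d < 7)
  }
  expect_equal(sum(prof$counts), manual)
})

test_that("the PMF transform has the stated closed forms", {
  prof <- structure(list(r = c(1, 2, 3), g = c(1, 1, 1), counts = c(1, 1, 1),
                         normalization = "box_density", r_max = 3,
                         bin_width = 1, n_ref = 1, n_target = 1,
                         n_frames = 1), class = "RDFProfile")
  pmf <- pmf_from_rdf(prof, 310)
  expect_equal(pmf$pmf, c(0, 0, 0))
  prof$g <- c(1, exp(1), 1)
  pmf2 <- pmf_from_rdf(prof, 310)
  expect_equal(pmf2$pmf[2], -8.314462618e-3 * 310, tolerance = 1e-9)
  expect_equal(pmf2$pmf[2], -2.577, tolerance = 1e-3)
  expect_equal(pmf2$minimum$location, 2)
  # zero-g bins are undefined, not -Inf
  prof$g <- c(0, exp(1), 0)
  pmf3 <- pmf_from_rdf(prof, 310)
  expect_true(is.na(pmf3$pmf[1]) && is.na(pmf3$pmf[3]))
  expect_error(pmf_from_rdf(prof, -10), "temperature")
})

test_that("PMF minimum ties break toward the smaller distance", {
  prof <- structure(list(r = c(1, 2, 3), g = c(2, 1, 2), counts = c(2, 1, 2),
                         normalization = "box_density", r_max = 3,
                         bin_width = 1, n_ref = 1, n_target = 1,
                         n_frames = 1), class = "RDFProfile")
  pmf <- pmf_from_rdf(prof, 310)
  expect_equal(pmf$minimum$location, 1)
  # monotone decreasing pmf: minimum at the last bin
  prof$g <- c(1, 2, 4)
  expect_equal(pmf_from_rdf(prof, 310)$minimum$location, 3)
  # minimum location coincides with the g maximum
  set.seed(33)
  prof$g <- runif(3, 0.1, 5)
  expect_equal(pmf_from_rdf(prof, 310)$minimum$location,
               prof$r[which.max(prof$g)])
})

test_that("a planted well is recovered within one bin width", {
  set.seed(34)
  nf <- 600
  bulk <- function(n) {
    # uniform bulk points outside the reference's excluded volume
    m <- matrix(runif(3 * n * 3, -9, 9), ncol = 3)
    m[rowSums(m^2) > 2.2^2, , drop = FALSE][seq_len(n), ]
  }
  frames <- lapply(seq_len(nf), function(f) {
    d <- max(2.2, rnorm(1, 2.7, 0.1))
    rbind(c(d, 0, 0), bulk(20))
  })
  traj <- rdf_traj(frames)
  for (bw in c(0.05, 0.1)) {
    prof <- rdf(traj, 1L, 2:22, r_max = 12, bin_width = bw)
    pmf <- pmf_from_rdf(prof, 310)
    expect_lt(abs(pmf$minimum$location - 2.7), bw + 1e-9)
  }
})

test_that("normalization modes differ by a constant and share the minimum", {
  set.seed(35)
  nf <- 100
  frames <- lapply(seq_len(nf), function(f) {
    d <- max(2.2, rnorm(1, 3.0, 0.2))
    rbind(c(d, 0, 0), matrix(runif(45, -8, 8), ncol = 3))
  })
  traj <- rdf_traj(frames)
  p_box <- rdf(traj, 1L, 2:17, r_max = 10, bin_width = 0.2,
               normalization = "box_density")
  p_tail <- rdf(traj, 1L, 2:17, r_max = 10, bin_width = 0.2,
                normalization = "tail_unit")
  ratio <- p_box$g[p_box$g > 0] / p_tail$g[p_tail$g > 0]
  expect_lt(diff(range(ratio)), 1e-9)
  m_box <- pmf_from_rdf(p_box, 310)$minimum
  m_tail <- pmf_from_rdf(p_tail, 310)$minimum
  expect_equal(m_box$location, m_tail$location)
  # PMF offset between modes is constant where defined
  d_box <- pmf_from_rdf(p_box, 310)$pmf
  d_tail <- pmf_from_rdf(p_tail, 310)$pmf
  off <- d_box - d_tail
  expect_lt(diff(range(off[!is.na(off)])), 1e-9)
})

test_that("group preconditions are enforced", {
  traj <- rdf_traj(lapply(1:3, function(f) matrix(c(5, 0, 0), 1)))
  expect_error(rdf(traj, 1L, 1L, 10, 0.1), "disjoint")
  expect_error(rdf(traj, integer(0), 2L, 10, 0.1), "nonempty")
  expect_error(rdf(traj, 1L, 2L, r_max = 0.05, bin_width = 0.1), "r_max")
})
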