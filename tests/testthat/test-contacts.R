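test_that("the 4 Angstrom cutoff is strictly exclusive", {
  co <- rbind(c(0, 0, 0), c(3.9, 0, 0), c(4.0, 0, 0))
  expect_equal(count_contacts(co, 1L, 2L, cutoff = 4), 1L)
  expect_equal(count_contacts(co, 1L, 3L, cutoff = 4), 0L)
  expect_equal(count_contacts(co, 1L, integer(0), cutoff = 4), 0L)
  expect_error(count_contacts(co, 1:2, 2:3, cutoff = 4), "overlap")
  expect_error(count_contacts(co, 1L, 2L, cutoff = 0), "cutoff")
})

test_that("cell-list counts equal the all-pairs oracle on random systems", {
  set.seed(42)
  for (rep in 1:60) {
    n <- sample(50:500, 1)
    co <- random_cloud(n, L = sample(10:40, 1))
    na <- sample(seq_len(n - 1), 1)
    ga <- seq_len(na); gb <- (na + 1):n
    cutoff <- runif(1, 1, 6)
    oracle <- r_count_contacts(co[ga, , drop = FALSE],
                               co[gb, , drop = FALSE], cutoff)
    expect_identical(count_contacts(co, ga, gb, cutoff, method = "cell"),
                     oracle)
    expect_identical(count_contacts(co, ga, gb, cutoff, method = "brute"),
                     oracle)
  }
})

test_that("minimum-image counting matches an R oracle and needs a box", {
  set.seed(7)
  box <- c(12, 15, 10)
  co <- random_cloud(40, L = 12)
  frm <- frame(co, box = box)
  oracle <- r_count_contacts(co[1:15, ], co[16:40, ], 4, box = box)
  expect_identical(count_contacts(frm, 1:15, 16:40, 4, pbc = TRUE), oracle)
  expect_error(count_contacts(frame(co), 1:15, 16:40, 4, pbc = TRUE),
               "configuration error")
  # a pair split across the boundary is found only with pbc
  co2 <- rbind(c(0.5, 5, 5), c(11.5, 5, 5))
  expect_equal(count_contacts(frame(co2, box = box), 1L, 2L, 4, pbc = TRUE),
               1L)
  expect_equal(count_contacts(frame(co2, box = box), 1L, 2L, 4), 0L)
})

test_that("counts are invariant under rigid translation and symmetric", {
  set.seed(1)
  co <- random_cloud(120)
  shift <- sweep(co, 2L, c(103.7, -55.1, 20.9), `+`)
  expect_identical(count_contacts(co, 1:50, 51:120, 4.5),
                   count_contacts(shift, 1:50, 51:120, 4.5))
  expect_identical(count_contacts(co, 1:50, 51:120, 4.5),
                   count_contacts(co, 51:120, 1:50, 4.5))
})

test_that("occupancy follows the frame-indicator definition", {
  gen <- .shared_gen()
  traj <- gen$trajectory
  ma <- assign_moieties(traj$topology)
  cm <- contact_timeseries(traj, 2163, ma, 4, "hydrophilic",
                           frames = gen$truth$settled_start:n_frames(traj))
  col <- which(cm$moieties$moiety == "carboxylate" &
                 cm$moieties$lipid == "DOPS")
  counts <- cm$counts[, 1, col]
  expect_equal(cm$occupancy[1, col], mean(counts >= 1))
  # occupancy is invariant under frame reordering
  expect_equal(mean(rev(counts) >= 1), cm$occupancy[1, col])
  # hand computation: per-frame counts 1,0,2,0 give occupancy 0.5
  expect_equal(mean(c(1, 0, 2, 0) >= 1), 0.5)
})

test_that("occupancy is monotone non-decreasing in the cutoff", {
  gen <- .shared_gen()
  traj <- gen$trajectory
  ma <- assign_moieties(traj$topology)
  fr <- gen$truth$settled_start:n_frames(traj)
  occ <- lapply(c(3, 4, 5), function(cu)
    contact_timeseries(traj, c(2090, 2163), ma, cu, "hydrophilic",
                       frames = fr)$occupancy)
  expect_true(all(occ[[2]] >= occ[[1]]))
  expect_true(all(occ[[3]] >= occ[[2]]))
})

test_that("a static trajectory gives occupancies of exactly 0 or 1", {
  sys <- tiny_system()
  coords <- array(sys$frame$coords, c(n_atoms(sys$topology), 3, 10))
  traj <- trajectory(sys$topology, coords)
  ma <- assign_moieties(traj$topology)
  cm <- contact_timeseries(traj, c(2093, 2163), ma, 4, "all")
  expect_true(all(cm$occupancy %in% c(0, 1)))
})

test_that("replicate averaging is the arithmetic mean with axis checks", {
  gen <- .shared_gen()
  traj <- gen$trajectory
  ma <- assign_moieties(traj$topology)
  m1 <- contact_timeseries(traj, 2163, ma, 4, "hydrophilic", frames = 1:50)
  m2 <- contact_timeseries(traj, 2163, ma, 4, "hydrophilic",
                           frames = 251:300)
  avg <- average_replicates(list(m1, m2))
  expect_equal(avg$occupancy, (m1$occupancy + m2$occupancy) / 2)
  expect_equal(average_replicates(list(m1))$occupancy, m1$occupancy)
  m3 <- contact_timeseries(traj, 2090, ma, 4, "hydrophilic", frames = 1:50)
  expect_error(average_replicates(list(m1, m3)), "shape error")
})

test_that("hydrophobic mode with no hydrophobic residues warns and is empty", {
  gen <- .shared_gen()
  traj <- gen$trajectory
  ma <- assign_moieties(traj$topology)
  expect_warning(
    cm <- contact_timeseries(traj, 2163, ma, 4, "hydrophobic",
                             frames = 1:5),
    "empty analysis")
  expect_true(all(cm$occupancy == 0))
})
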