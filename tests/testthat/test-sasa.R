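test_that("an isolated carbon matches the analytic sphere area", {
  top <- carbon_topology(1)
  sp <- sasa_per_residue(top, matrix(0, 1, 3), 1L, 1L,
                         probe = 1.4, n_points = 960)
  analytic <- 4 * pi * (1.70 + 1.4)^2
  expect_equal(sp$atoms$sasa, analytic, tolerance = 0.01)
  expect_equal(sp$residues$sasa, analytic, tolerance = 0.01)
})

test_that("full burial and full separation are exact limits", {
  # small atom centred inside a much larger occluding sphere
  top <- topology(name = c("C", "S"), resname = "UNK", resid = c(1L, 2L),
                  chain = "A", element = c("C", "S"), segment = "protein")
  big <- vdw_radii(); big["S"] <- 10
  sp <- sasa_per_residue(top, rbind(c(0, 0, 0), c(0, 0, 0.5)), 1L, 1:2,
                         radii = big, n_points = 480)
  expect_equal(sp$atoms$sasa[1], 0)
  # two identical atoms far apart each equal the isolated value
  top2 <- carbon_topology(2)
  sp2 <- sasa_per_residue(top2, rbind(c(0, 0, 0), c(100, 0, 0)), 1:2, 1:2,
                          n_points = 960)
  expect_equal(sp2$atoms$sasa, rep(4 * pi * 3.1^2, 2), tolerance = 0.01)
})

test_that("adding occluders never increases SASA (monotonicity)", {
  set.seed(9)
  for (rep in 1:20) {
    n <- sample(10:40, 1)
    co <- random_cloud(n, L = 8)
    top <- carbon_topology(n)
    surf <- seq_len(5)
    base <- sasa_per_residue(top, co, surf, surf, n_points = 240)
    more <- sasa_per_residue(top, co, surf, seq_len(n), n_points = 240)
    expect_true(all(more$atoms$sasa <= base$atoms$sasa + 1e-9))
  }
})

test_that("SASA converges with the sphere point count", {
  set.seed(12)
  co <- random_cloud(50, L = 10)
  top <- carbon_topology(50)
  s1 <- sum(sasa_per_residue(top, co, 1:50, 1:50, n_points = 960)$atoms$sasa)
  s2 <- sum(sasa_per_residue(top, co, 1:50, 1:50, n_points = 3840)$atoms$sasa)
  expect_lt(abs(s1 - s2) / s2, 0.01)
})

test_that("SASA is invariant under rigid motion", {
  set.seed(4)
  co <- random_cloud(30, L = 8)
  top <- carbon_topology(30)
  s1 <- sasa_per_residue(top, co, 1:30, 1:30, n_points = 960)
  # translation moves the sphere points with the atoms: exactly invariant
  s_tr <- sasa_per_residue(top, sweep(co, 2L, c(50, -20, 7), `+`),
                           1:30, 1:30, n_points = 960)
  expect_equal(s1$atoms$sasa, s_tr$atoms$sasa, tolerance = 1e-12)
  # rotation is invariant up to the fixed-orientation quadrature error
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  s_rot <- sasa_per_residue(top, co %*% R, 1:30, 1:30, n_points = 960)
  expect_lt(abs(sum(s_rot$atoms$sasa) - sum(s1$atoms$sasa)) /
              sum(s1$atoms$sasa), 0.02)
  expect_lt(max(abs(s_rot$atoms$sasa - s1$atoms$sasa)), 3)
})

test_that("unknown elements raise a missing-radius error naming the atom", {
  top <- topology(name = "FE", resname = "HEM", resid = 1L, chain = "A",
                  element = "FE", segment = "protein")
  expect_error(sasa_per_residue(top, matrix(0, 1, 3), 1L, 1L), "FE")
})

test_that("delta-SASA is zero for identical states and tracks lipid occlusion", {
  gen <- .shared_gen()
  traj <- gen$trajectory
  top <- traj$topology
  pro <- which(top$segment == "protein")
  lip <- which(top$segment == "lipid")
  fr <- seq(gen$truth$settled_start, n_frames(traj), by = 40)
  same <- delta_sasa(traj, traj, pro, pro, pro,
                     n_points = 240, frames_bound = fr, frames_unbound = fr)
  expect_true(all(abs(same$delta_sasa) < 1e-9))
  ds <- delta_sasa(traj, traj, pro, c(pro, lip), pro,
                   n_points = 240, frames_bound = fr, frames_unbound = fr)
  buried <- ds[ds$residue_id %in% gen$truth$buried, ]
  controls <- ds[ds$residue_id %in%
                   unlist(lapply(gen$truth$domains, `[[`, "controls")), ]
  expect_true(all(buried$delta_sasa > 10))
  expect_true(all(abs(controls$delta_sasa) < 2))
  # removing lipids from the bound occluders ablates the signal
  expect_true(all(abs(same$delta_sasa[same$residue_id %in%
                                        gen$truth$buried]) < 1e-9))
})
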