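two_atom_params <- function(q = c(1, 1), sig = c(3.5, 3.5),
                            eps = c(0, 0)) {
  as_nonbonded_params(data.frame(
    residue_name = "UNK", atom_name = c("A1", "A2"),
    charge_e = q, sigma_A = sig, epsilon_kJmol = eps))
}

two_atom_top <- function() {
  topology(name = c("A1", "A2"), resname = "UNK", resid = 1:2, chain = "A",
           element = "C", segment = "protein")
}

test_that("Coulomb and Lennard-Jones closed forms hold", {
  top <- two_atom_top()
  co <- function(d) rbind(c(0, 0, 0), c(d, 0, 0))
  e <- nonbonded_energy(co(10), 1L, 2L, top, two_atom_params(), cutoff = 12)
  expect_equal(unname(e["E_coulomb"]), 138.94, tolerance = 1e-4)
  expect_equal(unname(e["E_lj"]), 0)
  # LJ root at sigma and minimum -epsilon at 2^(1/6) sigma
  p <- two_atom_params(q = c(0, 0), eps = c(0.5, 0.5))
  expect_equal(unname(nonbonded_energy(co(3.5), 1L, 2L, top, p)["E_lj"]), 0,
               tolerance = 1e-12)
  expect_equal(unname(nonbonded_energy(co(2^(1/6) * 3.5), 1L, 2L, top,
                                       p)["E_lj"]), -0.5, tolerance = 1e-10)
  # beyond the cutoff the pair contributes nothing
  expect_equal(unname(nonbonded_energy(co(13), 1L, 2L, top,
                                       two_atom_params())["E_total"]), 0)
  # E_total is the sum of the components
  e2 <- nonbonded_energy(co(3), 1L, 2L, top, two_atom_params(eps = c(1, 1)))
  expect_equal(unname(e2["E_total"]),
               unname(e2["E_coulomb"] + e2["E_lj"]))
})

test_that("pair sums match an all-pairs R oracle on random systems", {
  set.seed(41)
  for (rep in 1:10) {
    n <- 30
    co <- random_cloud(n, L = 12) + 1  # keep distances off the clash floor
    q <- runif(n, -1, 1); sig <- runif(n, 3, 4); eps <- runif(n, 0, 1)
    top <- topology(name = sprintf("X%d", 1:n), resname = "UNK",
                    resid = 1:n, chain = "A", element = "C",
                    segment = "protein")
    params <- as_nonbonded_params(data.frame(
      residue_name = "UNK", atom_name = sprintf("X%d", 1:n),
      charge_e = q, sigma_A = sig, epsilon_kJmol = eps))
    ga <- 1:12; gb <- 13:30
    e <- nonbonded_energy(co, ga, gb, top, params, cutoff = 9)
    oracle <- r_pair_energy(co, ga, gb, q, sig, eps, cutoff = 9)
    expect_equal(unname(e["E_coulomb"]), oracle[1], tolerance = 1e-8)
    expect_equal(unname(e["E_lj"]), oracle[2], tolerance = 1e-8)
    # symmetry
    e2 <- nonbonded_energy(co, gb, ga, top, params, cutoff = 9)
    expect_equal(unname(e["E_total"]), unname(e2["E_total"]),
                 tolerance = 1e-10)
  }
})

test_that("energies are additive over disjoint partitions and rigid-motion invariant", {
  gen <- .shared_gen()
  traj <- gen$trajectory
  top <- traj$topology
  params <- default_nonbonded_params(top)
  pro <- which(top$segment == "protein")
  dopc <- which(top$resname == "DOPC")
  dops <- which(top$resname == "DOPS")
  f <- n_frames(traj)  # settled frame
  cf <- traj$coords[, , f]
  e_all <- nonbonded_energy(cf, pro, c(dopc, dops), top, params)
  e_c <- nonbonded_energy(cf, pro, dopc, top, params)
  e_s <- nonbonded_energy(cf, pro, dops, top, params)
  expect_equal(unname(e_all["E_total"]),
               unname(e_c["E_total"] + e_s["E_total"]), tolerance = 1e-9)
  th <- 0.5
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- sweep(cf %*% R, 2L, c(30, -10, 5), `+`)
  e_m <- nonbonded_energy(moved, pro, c(dopc, dops), top, params)
  expect_equal(unname(e_m["E_total"]), unname(e_all["E_total"]),
               tolerance = 1e-8)
})

test_that("opposite charges attract monotonically above the clash floor", {
  top <- two_atom_top()
  p <- two_atom_params(q = c(1, -1))
  d <- c(8, 6, 4, 2, 1)
  e <- vapply(d, function(dd)
    unname(nonbonded_energy(rbind(c(0, 0, 0), c(dd, 0, 0)), 1L, 2L, top,
                            p)["E_coulomb"]), 1)
  expect_true(all(diff(e) < 0))
  expect_error(nonbonded_energy(rbind(c(0, 0, 0), c(0.05, 0, 0)), 1L, 2L,
                                top, p), "clash")
})

test_that("missing parameters are reported by atom", {
  top <- two_atom_top()
  p <- as_nonbonded_params(data.frame(
    residue_name = "UNK", atom_name = "A1", charge_e = 0, sigma_A = 3.5,
    epsilon_kJmol = 0))
  expect_error(nonbonded_energy(rbind(c(0, 0, 0), c(3, 0, 0)), 1L, 2L, top,
                                p), "missing parameter.*A2")
})

test_that("series argmin follows the tie rule and a no-contact series is flat", {
  # protein never within cutoff of lipids: zero everywhere, argmin = frame 1
  sysname <- c("A1", "P")
  top <- topology(name = sysname, resname = c("UNK", "DOPC"),
                  resid = 1:2, chain = c("A", "L"), element = c("C", "P"))
  params <- as_nonbonded_params(data.frame(
    residue_name = c("UNK", "DOPC"), atom_name = sysname,
    charge_e = c(1, 1), sigma_A = 3.5, epsilon_kJmol = 0))
  coords <- array(0, c(2, 3, 4))
  for (f in 1:4) coords[2, , f] <- c(100, 0, 0)
  traj <- trajectory(top, coords)
  es <- energy_series(traj, 1L, params)
  expect_true(all(es$table$E_total == 0))
  expect_equal(es$argmin, 1L)
})

test_that("the lowest-energy frame is exported as a readable structure", {
  gen <- .shared_gen()
  traj <- gen$trajectory
  top <- traj$topology
  params <- default_nonbonded_params(top)
  es <- energy_series(traj, which(top$segment == "protein"), params,
                      frames = seq(1, n_frames(traj), by = 10))
  f <- tempfile(fileext = ".pdb")
  export_lowest_energy_frame(traj, es, f)
  back <- read_structure(f)
  expect_equal(nrow(back$topology), n_atoms(traj))
  expect_lt(max(abs(back$frame$coords - traj$coords[, , es$argmin])),
            0.0011)
})
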