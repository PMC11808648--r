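test_that("the default nanodisc has the stated composition and anchors", {
  nano <- build_nanodisc(seed = 2)
  top <- nano$topology
  lip <- top$segment == "lipid"
  n_dopc <- length(unique(top$resid[lip & top$resname == "DOPC"]))
  n_dops <- length(unique(top$resid[lip & top$resname == "DOPS"]))
  expect_equal(n_dopc + n_dops, 160L)
  expect_equal(n_dops / (n_dopc + n_dops), 0.20)
  # scaffold anchors exist with the expected residue names
  expect_equal(top$resname[top$chain == "S" & top$resid == 32], "MET")
  expect_equal(top$resname[top$chain == "S" & top$resid == 93], "GLU")
  expect_equal(top$resname[top$chain == "S" & top$resid == 158], "GLU")
  # two leaflets, mirrored in z
  p_z <- nano$frame$coords[lip & top$name == "P", 3]
  expect_equal(sum(p_z > 0), sum(p_z < 0))
  expect_error(build_nanodisc(area_per_lipid = -1), "area_per_lipid")
})

test_that("a DOPC-only disc has an empty carboxylate class", {
  nano <- build_nanodisc(10, 0, seed = 3)
  ma <- assign_lipid_moieties(nano$topology)
  expect_equal(sum(ma$lipid_class == "carboxylate", na.rm = TRUE), 0L)
})

test_that("generation is deterministic in the seed", {
  n1 <- build_nanodisc(seed = 5)
  n2 <- build_nanodisc(seed = 5)
  expect_identical(n1$frame$coords, n2$frame$coords)
  n3 <- build_nanodisc(seed = 6)
  expect_false(identical(n1$frame$coords, n3$frame$coords))
  p1 <- build_probe_protein(5); p2 <- build_probe_protein(5)
  expect_identical(p1$frame$coords, p2$frame$coords)
  g1 <- generate_binding_trajectory(n1, p1, n_frames = 20, seed = 9)
  g2 <- generate_binding_trajectory(n1, p1, n_frames = 20, seed = 9)
  expect_identical(g1$trajectory$coords, g2$trajectory$coords)
  # byte-identical files too
  f1 <- tempfile(fileext = ".pdb"); f2 <- tempfile(fileext = ".pdb")
  write_trajectory_pdb(g1$trajectory, f1)
  write_trajectory_pdb(g2$trajectory, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("the probe protein satisfies the structural contract", {
  probe <- build_probe_protein(1)
  top <- probe$topology
  # backbone completeness: every residue has N, CA, C, O
  for (r in unique(top$resid)) {
    nm <- top$name[top$resid == r]
    expect_true(all(c("N", "CA", "C", "O") %in% nm))
  }
  # residues live in the C-domain numbering range
  expect_true(all(top$resid >= 2021 & top$resid <= 2332))
  # guanidino and ammonium nitrogens present
  expect_equal(length(select(top, "resname ARG and name NE NH1 NH2")), 9L)
  expect_gte(length(select(top, "resname LYS and name NZ")), 2L)
  # axis endpoints flagged and resolvable to alpha carbons
  for (dn in c("C1", "C2")) {
    ax <- probe$info[[dn]]$axis
    expect_equal(length(atom_index(top, ax, "CA")), 2L)
  }
})

test_that("generated systems parse through the standard readers", {
  nano <- build_nanodisc(8, 2, seed = 4)
  probe <- build_probe_protein(1)
  gen <- generate_binding_trajectory(nano, probe, n_frames = 12, seed = 2)
  traj <- gen$trajectory
  expect_silent(validate_topology(traj$topology))
  f <- tempfile(fileext = ".pdb")
  write_trajectory_pdb(traj, f)
  back <- read_trajectory(f)
  expect_equal(n_frames(back), 12L)
  expect_identical(back$topology$name, traj$topology$name)
  expect_identical(back$topology$segment, traj$topology$segment)
  expect_lt(max(abs(back$coords - traj$coords)), 0.0011)
  g <- tempfile(fileext = ".gro")
  write_structure(traj$topology, get_frame(traj, 1), g, "gro")
  backg <- read_structure(g)
  expect_lt(max(abs(backg$frame$coords - traj$coords[, , 1])), 0.0051)
})

test_that("noiseless planting with degenerate occupancies is exact", {
  truth <- planted_truth()
  truth$contacts$occupancy <- rep(c(0, 1),
                                  length.out = nrow(truth$contacts))
  nano <- build_nanodisc(seed = 1)
  probe <- build_probe_protein(1)
  gen <- generate_binding_trajectory(nano, probe, n_frames = 60,
                                     truth = truth, noise_sigma = 0,
                                     seed = 13)
  traj <- gen$trajectory
  ma <- assign_moieties(traj$topology)
  fr <- gen$truth$settled_start:n_frames(traj)
  pl <- gen$truth$planted
  for (ch in unique(pl$channel)) {
    rows <- pl[pl$channel == ch, ]
    cm <- contact_timeseries(traj, rows$resid, ma, 4, ch, frames = fr)
    df <- as.data.frame(cm)
    for (k in seq_len(nrow(rows))) {
      got <- df$occupancy[df$residue_id == rows$resid[k] &
                            df$moiety == rows$moiety[k] &
                            df$lipid == rows$lipid[k]]
      expect_equal(got, rows$occupancy[k])
    }
  }
})

test_that("planted truth validates its inputs", {
  expect_error(planted_truth(contacts = data.frame(
    resid = 2090, channel = "hydrophilic", moiety = "phosphate",
    lipid = "DOPC", occupancy = 1.2, probe_atom = "NH1",
    placement = "lateral")), "occupancy")
  expect_error(planted_truth(rdf = list(resid = 2320, probe_atom = "NH1",
                                        r0 = 1.5, spread = 0.1,
                                        target_atom = "O13A")), "well")
  nano <- build_nanodisc(seed = 1)
  probe <- build_probe_protein(1)
  expect_error(generate_binding_trajectory(nano, probe, n_frames = 5),
               "n_frames")
})
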