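# Synthetic nanodisc + probe-protein generator.
#
# Kinematically scripted (posed rigid bodies, no physics): the point is exact
# planted ground truth for validating the analysis stack, not realistic
# dynamics.  Reduced CHARMM36-named lipid atom sets keep systems small while
# covering every moiety class.

# per-lipid atom templates: name, element, dx, dy, dz (Angstrom, dz relative
# to the phosphorus plane of the leaflet, positive toward water)
lipid_template <- function(resname) {
  glycerol_tail <- list(
    c("O11", "O", 0.9, 0.9, -0.5), c("O12", "O", -0.9, 0.9, 0.5),
    c("O13", "O", 0.9, -0.9, 0.5), c("O14", "O", -0.9, -0.9, -0.5),
    c("C1", "C", 0.2, 0.3, -1.5), c("C2", "C", 0.8, 0.0, -2.5),
    c("C3", "C", -0.8, 0.0, -2.5),
    c("O21", "O", 1.4, 0.4, -3.2), c("O22", "O", 2.0, -0.6, -3.8),
    c("O31", "O", -1.4, 0.4, -3.2), c("O32", "O", -2.0, -0.6, -3.8),
    c("C22", "C", 1.2, 0.0, -5.0), c("C23", "C", 1.2, 0.0, -6.6),
    c("C24", "C", 1.2, 0.0, -8.2), c("C25", "C", 1.2, 0.0, -9.8),
    c("C26", "C", 1.2, 0.0, -11.4), c("C27", "C", 1.2, 0.0, -13.0),
    c("C32", "C", -1.2, 0.0, -5.0), c("C33", "C", -1.2, 0.0, -6.6),
    c("C34", "C", -1.2, 0.0, -8.2), c("C35", "C", -1.2, 0.0, -9.8),
    c("C36", "C", -1.2, 0.0, -11.4), c("C37", "C", -1.2, 0.0, -13.0))
  head <- if (resname == "DOPC") {
    list(c("N", "N", 0.3, 0.0, 3.0),
         c("C13", "C", 1.2, 0.9, 3.8), c("C14", "C", -1.2, 0.9, 3.8),
         c("C15", "C", 0.0, -1.4, 3.8),
         c("C12", "C", 0.4, 0.2, 2.0), c("C11", "C", 0.2, -0.2, 1.0),
         c("P", "P", 0.0, 0.0, 0.0))
  } else if (resname == "DOPS") {
    list(c("N", "N", 0.6, 0.3, 3.4),
         c("C12", "C", 0.3, 0.1, 2.2), c("C13", "C", -0.6, -0.3, 3.4),
         c("O13A", "O", -0.6, -1.1, 4.2), c("O13B", "O", -1.4, 0.2, 3.7),
         c("C11", "C", 0.2, -0.2, 1.0),
         c("P", "P", 0.0, 0.0, 0.0))
  } else stop("unsupported lipid template: ", resname)
  rows <- c(head, glycerol_tail)
  data.frame(name = vapply(rows, `[`, "", 1L),
             element = vapply(rows, `[`, "", 2L),
             dx = as.numeric(vapply(rows, `[`, "", 3L)),
             dy = as.numeric(vapply(rows, `[`, "", 4L)),
             dz = as.numeric(vapply(rows, `[`, "", 5L)),
             stringsAsFactors = FALSE)
}

#' Build a synthetic DOPC/DOPS nanodisc
#'
#' Two leaflets of reduced CHARMM36-named lipids on a jittered square
#' lattice sized by the area per lipid, with DOPS positions drawn by a
#' seeded shuffle, plus an alpha-carbon scaffold ring (resids 1-180, chain
#' `"S"`) whose residues 32, 93 and 158 serve as the membrane plane anchors.
#' The default composition is 64 DOPC + 16 DOPS per leaflet (80:20).
#'
#' @param n_dopc_per_leaflet,n_dops_per_leaflet lipid counts per leaflet.
#' @param area_per_lipid lateral area per lipid in square Angstrom
#'   (default 70).
#' @param seed RNG seed (placement shuffle and lattice jitter).
#' @return list with `topology`, `frame` (box included), and `info`
#'   (lattice spacing, leaflet z, composition).
#' @export
build_nanodisc <- function(n_dopc_per_leaflet = 64, n_dops_per_leaflet = 16,
                           area_per_lipid = 70, seed = 1) {
  if (area_per_lipid <= 0) stop("area_per_lipid must be positive")
  n_leaf <- n_dopc_per_leaflet + n_dops_per_leaflet
  if (n_leaf <= 0) stop("need at least one lipid per leaflet")
  set.seed(seed)
  sp <- sqrt(area_per_lipid)
  nx <- ceiling(sqrt(n_leaf))
  z_p <- 16  # phosphorus plane height

  site <- expand.grid(ix = seq_len(nx), iy = seq_len(nx))
  site <- site[seq_len(n_leaf), , drop = FALSE]
  cx <- (site$ix - (nx + 1) / 2) * sp
  cy <- (site$iy - (nx + 1) / 2) * sp

  name <- character(0); element <- character(0); resname <- character(0)
  resid <- integer(0)
  xyz <- matrix(0, 0, 3)
  rid <- 0L
  for (leaflet in c(1, -1)) {
    is_dops <- rep(FALSE, n_leaf)
    if (n_dops_per_leaflet > 0)
      is_dops[sample.int(n_leaf, n_dops_per_leaflet)] <- TRUE
    jx <- runif(n_leaf, -0.7, 0.7)
    jy <- runif(n_leaf, -0.7, 0.7)
    for (i in seq_len(n_leaf)) {
      rid <- rid + 1L
      rn <- if (is_dops[i]) "DOPS" else "DOPC"
      tpl <- lipid_template(rn)
      name <- c(name, tpl$name)
      element <- c(element, tpl$element)
      resname <- c(resname, rep(rn, nrow(tpl)))
      resid <- c(resid, rep(rid, nrow(tpl)))
      xyz <- rbind(xyz, cbind(cx[i] + jx[i] + tpl$dx,
                              cy[i] + jy[i] + tpl$dy,
                              leaflet * (z_p + tpl$dz)))
    }
  }
  n_lip_atoms <- length(name)

  # scaffold ring of alpha carbons at the bilayer midplane
  n_scaffold <- 180L
  ring_r <- nx * sp / 2 + 8
  th <- 2 * pi * (seq_len(n_scaffold) - 1) / n_scaffold
  scaf_resname <- rep("ALA", n_scaffold)
  scaf_resname[c(32L, 93L)] <- c("MET", "GLU")
  scaf_resname[158L] <- "GLU"
  name <- c(name, rep("CA", n_scaffold))
  element <- c(element, rep("C", n_scaffold))
  resname <- c(resname, scaf_resname)
  resid <- c(resid, seq_len(n_scaffold))
  xyz <- rbind(xyz, cbind(ring_r * cos(th), ring_r * sin(th),
                          rep(0, n_scaffold)))

  chain <- c(rep("L", n_lip_atoms), rep("S", n_scaffold))
  top <- topology(name = name, resname = resname, resid = resid,
                  chain = chain, element = element, scaffold_chain = "S")
  box <- c(nx * sp + 40, nx * sp + 40, 120)
  list(topology = top, frame = frame(xyz, box = box),
       info = list(spacing = sp, z_phosphate = z_p, ring_radius = ring_r,
                   n_dopc = 2L * n_dopc_per_leaflet,
                   n_dops = 2L * n_dops_per_leaflet,
                   dops_fraction = n_dops_per_leaflet / n_leaf))
}

SIDE_CHAIN_ATOMS <- list(
  ALA = c("CB"), SER = c("CB", "OG"), ARG = c("CB", "CZ", "NE", "NH1", "NH2"),
  LYS = c("CB", "NZ"), PHE = c("CB", "CG", "CD1", "CD2"),
  ILE = c("CB", "CG1"), MET = c("CB", "CG", "SD"),
  LEU = c("CB", "CG", "CD1", "CD2"), ASN = c("CB", "OD1", "ND2"),
  GLN = c("CB", "OE1", "NE2"), HIS = c("CB", "ND1", "NE2"),
  PRO = c("CB", "CG"))

probe_domain_spec <- function() {
  c1 <- data.frame(resid = c(2086:2096, 2140:2150, 2158:2168),
                   resname = "ALA", stringsAsFactors = FALSE)
  c1$resname[match(c(2086, 2090, 2091, 2092, 2093, 2145, 2163), c1$resid)] <-
    c("SER", "ARG", "GLN", "LYS", "PHE", "ILE", "ARG")
  c2 <- data.frame(resid = c(2195:2205, 2245:2255, 2295:2305, 2315:2325),
                   resname = "ALA", stringsAsFactors = FALSE)
  c2$resname[match(c(2198, 2199, 2200, 2249, 2250, 2251, 2252, 2299, 2315,
                     2316, 2320), c2$resid)] <-
    c("ASN", "MET", "PHE", "LYS", "SER", "LEU", "LEU", "PRO", "HIS", "GLN",
      "ARG")
  list(C1 = list(spec = c1, axis = c(2093, 2145), loop = 2093,
                 planted_deep = c(2090, 2091, 2092, 2163),
                 x_center = -16),
       C2 = list(spec = c2, axis = c(2200, 2299),
                 loop = c(2199, 2200, 2251, 2252),
                 planted_deep = c(2249, 2316, 2320),
                 x_center = 16))
}

# depth in [0, 1]: 0 = axis-distal (top), 1 = membrane-inserting loop
residue_depths <- function(dom) {
  sp <- dom$spec
  depth <- seq(0.25, 0.75, length.out = nrow(sp))
  names(depth) <- as.character(sp$resid)
  depth[as.character(dom$axis[2L])] <- 0
  top_nb <- setdiff(sp$resid[abs(sp$resid - dom$axis[2L]) <= 5], dom$axis[2L])
  depth[as.character(top_nb)] <- seq(0.05, 0.2, length.out = length(top_nb))
  depth[as.character(dom$planted_deep)] <- 0.85
  depth[as.character(dom$loop)] <- 1
  depth
}

#' Build the synthetic two-domain probe protein
#'
#' Two rigid mini-domains emulating tandem membrane-binding C domains:
#' backbone (N, CA, C, O) per residue along a compact coil, a hydrophobic
#' loop at the membrane-proximal end (PHE/MET/LEU side-chain carbons),
#' arginines with guanidino NE/NH1/NH2 and lysines with NZ.  Residue ids lie
#' in the 2021-2332 range so standard C-domain selections apply; the axis
#' endpoint residues (membrane-proximal first) are flagged in `info`.
#'
#' @param seed RNG seed (reserved; construction is deterministic).
#' @return list with `topology`, `frame` (internal coordinates, domain axis
#'   along +z) and `info` (per-domain residue ids, axis pairs, loop and
#'   control residues).
#' @export
build_probe_protein <- function(seed = 1) {
  set.seed(seed)
  doms <- probe_domain_spec()
  name <- character(0); element <- character(0); resname <- character(0)
  resid <- integer(0)
  xyz <- matrix(0, 0, 3)
  info <- list()
  for (dn in names(doms)) {
    dom <- doms[[dn]]
    sp <- dom$spec
    depth <- residue_depths(dom)
    n <- nrow(sp)
    theta <- 4 * pi * (seq_len(n) - 1) / n
    R <- 6.5
    z_top <- 26
    H <- 26
    for (i in seq_len(n)) {
      d <- depth[as.character(sp$resid[i])]
      ca <- c(dom$x_center + R * cos(theta[i]), R * sin(theta[i]),
              z_top - H * d)
      bb_names <- c("N", "CA", "C", "O")
      bb <- rbind(ca + c(-1.0, 0.5, 0.6), ca, ca + c(1.0, -0.5, -0.6),
                  ca + c(1.4, 0.6, -1.0))
      sc_names <- SIDE_CHAIN_ATOMS[[sp$resname[i]]]
      # deep residues point their side chains down (toward the membrane),
      # others point radially outward
      u <- if (d >= 0.85) c(0, 0, -1)
           else c(cos(theta[i]), sin(theta[i]), 0)
      sc <- NULL
      if (length(sc_names)) {
        reach <- seq(1.5, 1.5 + 1.4 * (length(sc_names) - 1), by = 1.4)
        sc <- t(vapply(seq_along(sc_names), function(k)
          ca + u * reach[k] + c(0.3 * (k %% 2), -0.3 * (k %% 2), 0),
          numeric(3L)))
      }
      nm <- c(bb_names, sc_names)
      name <- c(name, nm)
      element <- c(element, guess_element(nm))
      resname <- c(resname, rep(sp$resname[i], length(nm)))
      resid <- c(resid, rep(sp$resid[i], length(nm)))
      xyz <- rbind(xyz, bb, sc)
    }
    info[[dn]] <- list(resids = sp$resid, axis = dom$axis, loop = dom$loop,
                       planted_deep = dom$planted_deep,
                       x_center = dom$x_center,
                       controls = setdiff(
                         sp$resid[abs(sp$resid - dom$axis[2L]) <= 5],
                         dom$axis[2L]))
  }
  top <- topology(name = name, resname = resname, resid = resid,
                  chain = "A", element = element)
  list(topology = top, frame = frame(xyz), info = info)
}

#' Planted ground truth for a synthetic binding trajectory
#'
#' Defines what the generator plants: per-residue contact occupancies (per
#' moiety class and lipid type), the settled tilt distribution per domain,
#' the arginine-carboxylate RDF well, the buried-residue list, and the
#' scripted phase fractions.  Defaults mirror the study conditions the
#' analyses target: a 68/69 degree settled tilt, beta-hairpin hydrophobic
#' loops in near-permanent chain contact, and an arginine-carboxylate well
#' at 2.70 Angstrom.
#'
#' @param tilt_mean,tilt_sd named numeric (`C1`, `C2`), degrees.
#' @param contacts data.frame of planted occupancies (columns `resid`,
#'   `channel`, `moiety`, `lipid`, `occupancy`, `probe_atom`, `placement`).
#' @param rdf list with `resid`, `probe_atom`, `r0`, `spread`,
#'   `target_atom`.
#' @param phases named fractions (`approach`, `insert1`, `insert2`); the
#'   remainder is the settled phase.
#' @return a `PlantedTruth` list.
#' @export
planted_truth <- function(
    tilt_mean = c(C1 = 68, C2 = 69),
    tilt_sd = c(C1 = 8, C2 = 9),
    contacts = NULL,
    rdf = list(resid = 2320, probe_atom = "NH1", r0 = 2.70, spread = 0.15,
               target_atom = "O13A"),
    phases = c(approach = 0.20, insert1 = 0.075, insert2 = 0.075)) {
  if (is.null(contacts)) {
    contacts <- rbind(
      data.frame(resid = c(2090, 2091, 2092, 2163, 2249, 2316),
                 channel = "hydrophilic",
                 moiety = c("phosphate", "amine_nitrogen", "phosphate",
                            "carboxylate", "phosphate", "amine_nitrogen"),
                 lipid = c("DOPC", "DOPC", "DOPS", "DOPS", "DOPC", "DOPS"),
                 occupancy = c(0.60, 0.45, 0.55, 0.50, 0.62, 0.48),
                 probe_atom = c("NH1", "NE2", "NZ", "NH1", "NZ", "NE2"),
                 placement = c("lateral", "above", "lateral", "above",
                               "lateral", "above"),
                 stringsAsFactors = FALSE),
      data.frame(resid = c(2093, 2199, 2200, 2251, 2252),
                 channel = "hydrophobic",
                 moiety = "chain_carbon",
                 lipid = c("DOPC", "DOPC", "DOPS", "DOPC", "DOPS"),
                 occupancy = c(0.98, 0.98, 0.99, 0.98, 0.99),
                 probe_atom = c("CG", "CG", "CD1", "CD1", "CD2"),
                 placement = "chain",
                 stringsAsFactors = FALSE))
  }
  bad <- contacts$occupancy < 0 | contacts$occupancy > 1
  if (any(bad)) stop("planted occupancy outside [0, 1]")
  if (rdf$r0 <= 2) stop("planted RDF well location must exceed 2 A")
  structure(list(tilt_mean = tilt_mean, tilt_sd = tilt_sd,
                 contacts = contacts, rdf = rdf, phases = phases,
                 buried = c(2093, 2199, 2200, 2251, 2252),
                 seed = NA_integer_),
            class = "PlantedTruth")
}

# rotation matrix taking unit vector u to unit vector v (Rodrigues)
rotation_between <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  cr <- c(u[2L] * v[3L] - u[3L] * v[2L],
          u[3L] * v[1L] - u[1L] * v[3L],
          u[1L] * v[2L] - u[2L] * v[1L])
  s <- sqrt(sum(cr^2)); d <- sum(u * v)
  if (s < 1e-12) {
    if (d > 0) return(diag(3))
    w <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    a <- w - sum(w * u) * u; a <- a / sqrt(sum(a^2))
    return(2 * outer(a, a) - diag(3))
  }
  K <- matrix(c(0, cr[3L], -cr[2L], -cr[3L], 0, cr[1L], cr[2L], -cr[1L], 0),
              3L, 3L)
  diag(3) + K + K %*% K * ((1 - d) / s^2)
}

#' Generate a scripted nanodisc-binding trajectory with planted truth
#'
#' Scripted phases: rigid approach from above, first-domain loop insertion,
#' second-domain insertion, then a settled phase in which each domain's tilt
#' is drawn per frame from the planted normal distribution, planted contact
#' atoms are placed within 3.5 Angstrom of their designated moiety atoms
#' with the planted Bernoulli occupancy (else lifted beyond 6 Angstrom), and
#' one arginine guanidino nitrogen-DOPS carboxylate oxygen distance is drawn
#' from the planted normal well.  Isotropic Gaussian coordinate jitter is
#' added last.  All randomness derives from `seed`.
#'
#' @param nanodisc output of [build_nanodisc()].
#' @param probe output of [build_probe_protein()].
#' @param n_frames number of frames (>= 10).
#' @param truth a [planted_truth()].
#' @param noise_sigma per-axis coordinate jitter in Angstrom (default 0.1).
#' @param seed RNG seed.
#' @return list with `trajectory` (time stride 240 ps) and `truth` (the
#'   input truth completed with `seed`, `settled_start`, `insertion_frame`,
#'   `controls`, and per-domain axis/anchor bookkeeping).
#' @export
generate_binding_trajectory <- function(nanodisc, probe, n_frames = 1000,
                                        truth = planted_truth(),
                                        noise_sigma = 0.1, seed = 1) {
  if (n_frames < 10L) stop("n_frames must be at least 10")
  set.seed(seed)
  ntop <- nanodisc$topology
  ptop <- probe$topology
  n_nano <- nrow(ntop)
  top <- topology(name = c(ntop$name, ptop$name),
                  resname = c(ntop$resname, ptop$resname),
                  resid = c(ntop$resid, ptop$resid),
                  chain = c(ntop$chain, ptop$chain),
                  element = c(ntop$element, ptop$element),
                  scaffold_chain = "S")
  base_nano <- nanodisc$frame$coords
  z_head_top <- max(base_nano[ntop$segment == "lipid", 3L])

  # phase schedule
  ph <- truth$phases
  n_appr <- max(1L, round(ph[["approach"]] * n_frames))
  n_ins1 <- max(1L, round(ph[["insert1"]] * n_frames))
  n_ins2 <- max(1L, round(ph[["insert2"]] * n_frames))
  settled_start <- n_appr + n_ins1 + n_ins2 + 1L
  if (settled_start > n_frames)
    stop("phase fractions leave no settled frames")

  doms <- probe$info
  dom_rows <- lapply(doms, function(d)
    n_nano + which(ptop$resid %in% d$resids))
  # internal (centered) coordinates and axis per domain
  dom_int <- list()
  for (dn in names(doms)) {
    rows <- dom_rows[[dn]] - n_nano
    ci <- probe$frame$coords[rows, , drop = FALSE]
    ctr <- colMeans(ci)
    ci <- sweep(ci, 2L, ctr)
    ax_from <- which(ptop$resid[rows] == doms[[dn]]$axis[1L] &
                       ptop$name[rows] == "CA")
    ax_to <- which(ptop$resid[rows] == doms[[dn]]$axis[2L] &
                     ptop$name[rows] == "CA")
    loop_ca <- which(ptop$resid[rows] %in% doms[[dn]]$loop &
                       ptop$name[rows] == "CA")
    dom_int[[dn]] <- list(coords = ci, rows = dom_rows[[dn]],
                          axis_int = ci[ax_to, ] - ci[ax_from, ],
                          loop_ca = loop_ca)
  }

  # designated planted targets: nearest class atom in the top leaflet to the
  # residue's domain center, one lipid per planted row
  lip_class <- assign_lipid_moieties(top)$lipid_class
  ctr_for <- function(rid) {
    dn <- if (rid %in% doms$C1$resids) "C1" else "C2"
    doms[[dn]]$x_center
  }
  used_lipids <- integer(0)
  plant <- truth$contacts
  plant$target_idx <- NA_integer_
  for (k in seq_len(nrow(plant))) {
    cand <- which(!is.na(lip_class) & lip_class == plant$moiety[k] &
                    top$resname == plant$lipid[k] &
                    base_nano_z_positive(top, base_nano, n_nano) &
                    !(top$resid %in% used_lipids & top$chain == "L"))
    if (plant$placement[k] == "chain")
      cand <- cand[top$name[cand] %in% c("C22", "C32")]
    if (!length(cand)) {
      # small discs: fall back to reusing an already-designated lipid
      cand <- which(!is.na(lip_class) & lip_class == plant$moiety[k] &
                      top$resname == plant$lipid[k] &
                      base_nano_z_positive(top, base_nano, n_nano))
      if (plant$placement[k] == "chain")
        cand <- cand[top$name[cand] %in% c("C22", "C32")]
    }
    if (!length(cand))
      stop("no planted target available for moiety ", plant$moiety[k],
           " of ", plant$lipid[k])
    d2 <- (base_nano[cand, 1L] - ctr_for(plant$resid[k]))^2 +
      base_nano[cand, 2L]^2
    pick <- cand[which.min(d2)]
    plant$target_idx[k] <- pick
    used_lipids <- c(used_lipids, top$resid[pick])
  }
  # RDF pair: nearest DOPS carboxylate O to the RDF residue's domain
  rcand <- which(!is.na(lip_class) & lip_class == "carboxylate" &
                   top$name == truth$rdf$target_atom &
                   base_nano_z_positive(top, base_nano, n_nano) &
                   !(top$resid %in% used_lipids & top$chain == "L"))
  if (!length(rcand))
    rcand <- which(!is.na(lip_class) & lip_class == "carboxylate" &
                     top$name == truth$rdf$target_atom &
                     base_nano_z_positive(top, base_nano, n_nano))
  if (!length(rcand))
    stop("no DOPS carboxylate target available for the planted RDF pair")
  d2 <- (base_nano[rcand, 1L] - ctr_for(truth$rdf$resid))^2 +
    base_nano[rcand, 2L]^2
  rdf_target <- rcand[which.min(d2)]
  rdf_probe <- n_nano + which(ptop$resid == truth$rdf$resid &
                                ptop$name == truth$rdf$probe_atom)
  # lateral planting azimuth per target: scan candidate directions and keep
  # the one whose planted position is farthest from every other membrane
  # atom, so scripted placements never collide with neighbouring lipids
  lip_rows <- which(top$segment == "lipid")
  lat_dir <- function(tidx) {
    az <- seq(0, 2 * pi, length.out = 25L)[-25L]
    tpos <- base_nano[tidx, ]
    others <- setdiff(lip_rows, tidx)
    best <- c(1, 0); best_d <- -Inf
    for (a in az) {
      dir <- c(cos(a), sin(a))
      pos <- tpos + c(dir * 3.1, 0)
      d2 <- (base_nano[others, 1L] - pos[1L])^2 +
        (base_nano[others, 2L] - pos[2L])^2 +
        (base_nano[others, 3L] - pos[3L])^2
      dmin <- min(d2)
      if (dmin > best_d) { best_d <- dmin; best <- dir }
    }
    best
  }
  plant_dirs <- lapply(seq_len(nrow(plant)), function(k)
    if (plant$placement[k] %in% c("lateral", "chain"))
      lat_dir(plant$target_idx[k]) else NULL)
  plant$probe_idx <- vapply(seq_len(nrow(plant)), function(k)
    n_nano + which(ptop$resid == plant$resid[k] &
                     ptop$name == plant$probe_atom[k])[1L], 1L)
  # side-chain atom rows for buried residues (whole side chain follows the
  # planted probe into the acyl slab)
  sc_rows <- lapply(seq_len(nrow(plant)), function(k) {
    if (plant$placement[k] != "chain") return(integer(0))
    n_nano + which(ptop$resid == plant$resid[k] &
                     !(ptop$name %in% c("N", "CA", "C", "O")))
  })

  nat <- nrow(top)
  coords <- array(0, c(nat, 3L, n_frames))
  z_loop_settled <- z_head_top + 6.5
  dom_tilt <- vector("list", length(doms))
  names(dom_tilt) <- names(doms)
  for (dn in names(doms)) dom_tilt[[dn]] <- numeric(n_frames)

  for (f in seq_len(n_frames)) {
    cf <- matrix(0, nat, 3L)
    cf[seq_len(n_nano), ] <- base_nano
    phase <- if (f <= n_appr) "approach"
             else if (f <= n_appr + n_ins1) "insert1"
             else if (f < settled_start) "insert2"
             else "settled"
    for (dn in names(doms)) {
      d <- dom_int[[dn]]
      tl <- if (phase == "settled")
        rnorm(1, truth$tilt_mean[[dn]], truth$tilt_sd[[dn]])
      else truth$tilt_mean[[dn]]
      tl <- max(-89, min(89, tl))
      dom_tilt[[dn]][f] <- tl
      beta <- (90 - tl) * pi / 180
      Rm <- rotation_between(d$axis_int, c(sin(beta), 0, cos(beta)))
      rot <- d$coords %*% t(Rm)
      target_z <- switch(phase,
        approach = z_loop_settled + 33 * (1 - (f - 1) / max(1L, n_appr)) + 3,
        insert1 = if (dn == "C1") z_loop_settled else z_loop_settled + 4,
        insert2 = z_loop_settled,
        settled = z_loop_settled)
      shift <- c(doms[[dn]]$x_center - mean(rot[, 1L]), -mean(rot[, 2L]),
                 target_z - min(rot[d$loop_ca, 3L]))
      cf[d$rows, ] <- sweep(rot, 2L, shift, `+`)
    }
    # planting becomes active per domain once its insertion phase begins
    active_dom <- switch(phase, approach = character(0),
                         insert1 = "C1", insert2 = c("C1", "C2"),
                         settled = c("C1", "C2"))
    active_resids <- unlist(lapply(active_dom, function(dn)
      doms[[dn]]$resids), use.names = FALSE)
    for (k in seq_len(nrow(plant))) {
      if (!(plant$resid[k] %in% active_resids)) next
      tpos <- base_nano[plant$target_idx[k], ]
      hit <- runif(1) < plant$occupancy[k]
      if (hit) {
        dd <- runif(1, 2.8, 3.4)
        pos <- switch(plant$placement[k],
          above = {
            j <- runif(2, -0.3, 0.3)
            tpos + c(j, sqrt(dd^2 - sum(j^2)))
          },
          lateral = ,
          chain = {
            dir <- plant_dirs[[k]]
            dz <- runif(1, -0.3, 0.3)
            tpos + c(dir * sqrt(dd^2 - dz^2), dz)
          })
      } else {
        # no-contact draw: lift well above the headgroup surface
        pos <- c(tpos[1:2], z_head_top + 6 + runif(1, 0, 2))
      }
      cf[plant$probe_idx[k], ] <- pos
      sc <- setdiff(sc_rows[[k]], plant$probe_idx[k])
      if (length(sc)) {
        # stack the rest of the side chain above the probe atom
        cf[sc, ] <- matrix(pos, length(sc), 3L, byrow = TRUE) +
          cbind(0.4 * ((seq_along(sc) %% 2) - 0.5), 0,
                1.4 * seq_along(sc))
      }
    }
    if (phase == "settled") {
      dd <- max(2.2, rnorm(1, truth$rdf$r0, truth$rdf$spread))
      j <- runif(2, -0.25, 0.25)
      cf[rdf_probe, ] <- base_nano[rdf_target, ] + c(j, sqrt(dd^2 - sum(j^2)))
    }
    cf <- cf + matrix(rnorm(nat * 3L, 0, noise_sigma), nat, 3L)
    coords[, , f] <- cf
  }

  traj <- trajectory(top, coords,
                     box = nanodisc$frame$box,
                     time = (seq_len(n_frames) - 1) * 240)
  truth$seed <- seed
  truth$settled_start <- settled_start
  truth$insertion_frame <- settled_start
  truth$n_frames <- n_frames
  truth$noise_sigma <- noise_sigma
  truth$domains <- lapply(doms, function(d)
    list(resids = d$resids, axis = d$axis, loop = d$loop,
         controls = d$controls))
  truth$anchors <- c(32, 93, 158)
  truth$rdf$target_idx <- rdf_target
  truth$planted <- plant
  truth$tilt_drawn <- dom_tilt
  list(trajectory = traj, truth = truth)
}

# helper: logical over all atoms, TRUE for nanodisc atoms in the upper
# leaflet (z > 0); FALSE for protein rows
base_nano_z_positive <- function(top, base_nano, n_nano) {
  out <- rep(FALSE, nrow(top))
  out[seq_len(n_nano)] <- base_nano[, 3L] > 0
  out
}

#' Default nonbonded parameters for synthetic systems
#'
#' Emits a `NonbondedParams` table covering every (residue name, atom name)
#' pair in the topology, with CHARMM-flavoured partial charges on polar
#' groups (guanidino/ammonium nitrogens positive, phosphate and carboxylate
#' oxygens negative, zwitterionic choline/phosphate pairing) and simple
#' element-based Lennard-Jones parameters.  These are generator parameters
#' for exercising the energy module, not force-field values.
#'
#' @param top a `Topology`.
#' @return a `NonbondedParams` data.frame.
#' @export
default_nonbonded_params <- function(top) {
  key <- unique(data.frame(residue_name = top$resname, atom_name = top$name,
                           element = top$element, stringsAsFactors = FALSE))
  q <- rep(0, nrow(key))
  nm <- key$atom_name
  rn <- key$residue_name
  lip <- rn %in% c("DOPC", "DOPS")
  q[lip & nm == "N"] <- 0.60
  q[lip & nm %in% c("C13", "C14", "C15") & rn == "DOPC"] <- 0.10
  q[lip & nm == "P"] <- 1.50
  q[lip & nm %in% c("O11", "O12")] <- -0.57
  q[lip & nm %in% c("O13", "O14")] <- -0.78
  q[lip & nm %in% c("O21", "O31")] <- -0.30
  q[lip & nm %in% c("O22", "O32")] <- -0.50
  q[rn == "DOPS" & nm == "C13"] <- 0.34
  q[rn == "DOPS" & nm %in% c("O13A", "O13B")] <- -0.76
  pro <- !lip
  q[pro & nm == "N"] <- -0.47
  q[pro & nm == "CA"] <- 0.07
  q[pro & nm == "C"] <- 0.51
  q[pro & nm == "O"] <- -0.51
  q[pro & nm %in% c("NH1", "NH2")] <- 0.45
  q[pro & nm == "NE"] <- 0.10
  q[pro & nm == "CZ"] <- 0.30
  q[pro & nm == "NZ"] <- 0.80
  q[pro & nm %in% c("NE2", "ND2", "ND1")] <- -0.30
  q[pro & nm %in% c("OE1", "OD1", "OG")] <- -0.55
  # apolar epsilons are zero: the scripted poses are not sterically relaxed,
  # so the attraction signal is carried by Coulomb terms on polar groups and
  # repulsive LJ artifacts from posed overlaps are excluded by construction
  sig <- c(C = 3.6, N = 3.3, O = 3.0, P = 3.8, S = 3.6)[key$element]
  eps <- c(C = 0, N = 0.80, O = 0.80, P = 2.40, S = 0)[key$element]
  as_nonbonded_params(data.frame(residue_name = key$residue_name,
                                 atom_name = key$atom_name,
                                 charge_e = q, sigma_A = unname(sig),
                                 epsilon_kJmol = unname(eps),
                                 stringsAsFactors = FALSE))
}

#' Write a nonbonded parameter table to TSV
#' @param params a `NonbondedParams`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_nonbonded_params <- function(params, path) {
  utils::write.table(params, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Serialize planted truth to JSON
#' @param truth a `PlantedTruth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_planted_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' The default synthetic study preset
#'
#' Builds the default nanodisc (64 DOPC + 16 DOPS per leaflet) and probe,
#' then generates replicate scripted binding trajectories with the default
#' planted truth.  Each replicate uses `seed + replicate - 1`.
#'
#' @param seed base RNG seed.
#' @param n_frames frames per replicate (default 1000).
#' @param n_replicates number of replicate trajectories (default 2).
#' @param truth a [planted_truth()].
#' @param noise_sigma coordinate jitter (Angstrom).
#' @return list with `replicates` (list of `$trajectory`/`$truth`),
#'   `nanodisc`, `probe`, `params` (a `NonbondedParams`).
#' @export
synthetic_preset <- function(seed = 1, n_frames = 1000, n_replicates = 2,
                             truth = planted_truth(), noise_sigma = 0.1) {
  nano <- build_nanodisc(seed = seed)
  probe <- build_probe_protein(seed = seed)
  reps <- lapply(seq_len(n_replicates), function(r)
    generate_binding_trajectory(nano, probe, n_frames, truth, noise_sigma,
                                seed = seed + r - 1L))
  params <- default_nonbonded_params(reps[[1L]]$trajectory$topology)
  list(replicates = reps, nanodisc = nano, probe = probe, params = params)
}

#' @export
print.PlantedTruth <- function(x, ...) {
  cat("PlantedTruth: tilt",
      paste(sprintf("%s %g+/-%g", names(x$tilt_mean), x$tilt_mean,
                    x$tilt_sd), collapse = ", "),
      "deg;", nrow(x$contacts), "planted contact rows; RDF well at",
      x$rdf$r0, "A\n")
  invisible(x)
}
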