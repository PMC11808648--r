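#' Deterministic quasi-uniform sphere point set (golden spiral)
#'
#' @param n number of points.
#' @return `n x 3` matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Default van der Waals radii (Angstrom)
#'
#' @return named numeric vector by element symbol.
#' @export
vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)
}

atom_radii <- function(top, radii = vdw_radii()) {
  r <- unname(radii[top$element])
  if (any(is.na(r))) {
    bad <- which(is.na(r))[1L]
    stop("missing radius for atom ", bad, " (", top$name[bad], ", element '",
         top$element[bad], "')")
  }
  r
}

#' Shrake-Rupley SASA per atom and per residue for one frame
#'
#' For each surface atom, `n_points` quasi-uniform points are placed on the
#' sphere of radius (vdW radius + probe); the accessible fraction is the
#' share of points not strictly inside any other occluder's expanded sphere,
#' and the atomic SASA is that fraction times the expanded-sphere area.
#' Residue values are sums over the residue's atoms (no normalisation).
#'
#' @param top a `Topology`.
#' @param frm a `Frame` or coordinate matrix.
#' @param surface_selection atom indices whose SASA is reported.
#' @param occluder_selection atom indices that occlude (must contain the
#'   surface selection).
#' @param probe probe radius in Angstrom (default 1.4, a water molecule).
#' @param n_points sphere points per atom (default 960; >= 32 required).
#' @param radii named vdW radii by element (default [vdw_radii()]).
#' @return a `SASAProfile`: list with `atoms` (data.frame index/sasa),
#'   `residues` (data.frame residue_id, residue_name, sasa), and parameters.
#' @export
sasa_per_residue <- function(top, frm, surface_selection,
                             occluder_selection = surface_selection,
                             probe = 1.4, n_points = 960,
                             radii = vdw_radii()) {
  coords <- if (inherits(frm, "Frame")) frm$coords else as.matrix(frm)
  if (n_points < 32) stop("n_points must be at least 32")
  if (!all(surface_selection %in% occluder_selection))
    stop("surface selection must be a subset of the occluder selection")
  r <- atom_radii(top, radii)
  pts <- sphere_points(n_points)
  sasa <- .cpp_sasa_atoms(coords, as.integer(surface_selection) - 1L,
                          as.integer(occluder_selection) - 1L, r, probe, pts)
  at <- data.frame(index = surface_selection, sasa = sasa)
  key <- paste(top$chain[surface_selection], top$resid[surface_selection])
  agg <- rowsum(sasa, key, reorder = FALSE)
  first <- !duplicated(key)
  res <- data.frame(residue_id = top$resid[surface_selection][first],
                    residue_name = top$resname[surface_selection][first],
                    chain = top$chain[surface_selection][first],
                    sasa = agg[, 1L])
  rownames(res) <- NULL
  structure(list(atoms = at, residues = res, probe_radius = probe,
                 n_sphere_points = n_points, radii_set = radii),
            class = "SASAProfile")
}

#' Mean per-residue SASA over trajectory frames
#'
#' @inheritParams sasa_per_residue
#' @param traj a `Trajectory`.
#' @param frames optional frame subset (default all frames).
#' @return data.frame with `residue_id`, `residue_name`, `sasa_mean`,
#'   `sasa_sd`, `n_frames`.
#' @export
sasa_trajectory <- function(traj, surface_selection,
                            occluder_selection = surface_selection,
                            probe = 1.4, n_points = 960,
                            radii = vdw_radii(), frames = NULL) {
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  acc <- NULL
  for (f in frames) {
    sp <- sasa_per_residue(traj$topology, traj$coords[, , f],
                           surface_selection, occluder_selection,
                           probe, n_points, radii)
    acc <- cbind(acc, sp$residues$sasa)
  }
  last <- sp$residues
  data.frame(residue_id = last$residue_id, residue_name = last$residue_name,
             sasa_mean = rowMeans(acc),
             sasa_sd = apply(acc, 1L, stats::sd),
             n_frames = length(frames))
}

#' Bound-vs-unbound per-residue delta-SASA
#'
#' `delta = mean SASA(unbound) - mean SASA(bound)` per residue, so positive
#' values indicate burial upon membrane binding.  The canonical use is one
#' trajectory analysed twice: occluders = protein + lipids for the bound
#' state and protein only for the unbound state, which isolates the lipid
#' occlusion that membrane burial produces.
#'
#' @param bound,unbound `Trajectory` objects with identical protein
#'   topology (they may be the same object).
#' @param surface_selection protein atom indices whose SASA is profiled.
#' @param occluders_bound,occluders_unbound occluder index sets for the two
#'   states.
#' @param probe,n_points,radii see [sasa_per_residue()].
#' @param frames_bound,frames_unbound optional frame subsets.
#' @return data.frame with `residue_id`, `residue_name`, `sasa_bound`,
#'   `sasa_unbound`, `delta_sasa`.
#' @export
delta_sasa <- function(bound, unbound, surface_selection,
                       occluders_bound, occluders_unbound,
                       probe = 1.4, n_points = 960, radii = vdw_radii(),
                       frames_bound = NULL, frames_unbound = NULL) {
  tb <- bound$topology[surface_selection, c("name", "resname", "resid")]
  tu <- unbound$topology[surface_selection, c("name", "resname", "resid")]
  if (!identical(tb$resid, tu$resid) || !identical(tb$name, tu$name))
    stop("topology mismatch: surface selections differ between trajectories")
  sb <- sasa_trajectory(bound, surface_selection, occluders_bound,
                        probe, n_points, radii, frames_bound)
  su <- sasa_trajectory(unbound, surface_selection, occluders_unbound,
                        probe, n_points, radii, frames_unbound)
  data.frame(residue_id = sb$residue_id, residue_name = sb$residue_name,
             sasa_bound = sb$sasa_mean, sasa_unbound = su$sasa_mean,
             delta_sasa = su$sasa_mean - sb$sasa_mean)
}

#' @export
print.SASAProfile <- function(x, ...) {
  cat("SASAProfile:", nrow(x$atoms), "atoms,", nrow(x$residues),
      "residues; probe", x$probe_radius, "A,", x$n_sphere_points,
      "sphere points\n")
  cat(sprintf("total SASA %.1f A^2\n", sum(x$atoms$sasa)))
  invisible(x)
}
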