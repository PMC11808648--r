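#' Build and validate a pipeline run configuration
#'
#' A declarative configuration for [run_pipeline()].  Either pass trajectory
#' file paths (multi-model PDB) or in-memory `Trajectory` objects (e.g. from
#' [synthetic_preset()]).  All defaults the analyses depend on (cutoffs,
#' probe radius, sphere points, bins, temperature) are recorded here and
#' echoed into the output manifest, so results are self-describing.
#'
#' @param trajectories list of `Trajectory` objects, or character paths to
#'   multi-model PDB files (each entry one replicate).
#' @param domains named list of residue-id vectors to profile (e.g.
#'   `list(C1 = 2021:2170, C2 = 2171:2332)`).
#' @param anchors three scaffold residue ids defining the membrane plane.
#' @param axis_pairs named list (per domain) of two residue ids
#'   (membrane-proximal first); tilt uses their alpha carbons.
#' @param rdf_pairs named list of lists with `resid` (arginine) giving the
#'   guanidino-N reference and implicit DOPS carboxylate-oxygen target.
#' @param params a `NonbondedParams` table (or TSV path).
#' @param contact_cutoff,energy_cutoff Angstrom.
#' @param sasa_probe,sasa_points SASA parameters.
#' @param rdf_r_max,rdf_bin_width,rdf_normalization RDF parameters.
#' @param temperature K, for the PMF transform.
#' @param frames optional frame subset applied to every analysis.
#' @param sasa_frames optional frame subset for the SASA stage (SASA is the
#'   most expensive stage; a stride of the analysis frames is typical).
#' @param hydrophobic_residues residue-name set for the hydrophobic channel.
#' @param output_dir directory for CSV/JSON outputs, or `NULL` to skip
#'   writing.
#' @param seed integer recorded in the manifest.
#' @return a validated `RunConfig` list.
#' @export
run_config <- function(trajectories, domains, anchors = c(32, 93, 158),
                       axis_pairs, rdf_pairs = list(), params = NULL,
                       contact_cutoff = 4, energy_cutoff = 12,
                       sasa_probe = 1.4, sasa_points = 960,
                       rdf_r_max = 15, rdf_bin_width = 0.02,
                       rdf_normalization = "box_density",
                       temperature = 310, frames = NULL, sasa_frames = NULL,
                       hydrophobic_residues = default_hydrophobic(),
                       output_dir = NULL, seed = 1) {
  if (contact_cutoff <= 0) stop("validation error: contact cutoff must be > 0")
  if (energy_cutoff <= 0) stop("validation error: energy cutoff must be > 0")
  if (sasa_points < 32) stop("validation error: sasa_points must be >= 32")
  if (temperature <= 0) stop("validation error: temperature must be > 0")
  if (length(anchors) != 3L) stop("validation error: need 3 anchor residues")
  if (!length(trajectories)) stop("validation error: no trajectories")
  if (!length(domains) || is.null(names(domains)))
    stop("validation error: domains must be a named list of residue ids")
  if (is.null(names(axis_pairs)) ||
      !all(names(domains) %in% names(axis_pairs)))
    stop("validation error: axis_pairs must name every domain")
  if (is.character(params)) params <- read_nonbonded_params(params)
  structure(list(trajectories = trajectories, domains = domains,
                 anchors = anchors, axis_pairs = axis_pairs,
                 rdf_pairs = rdf_pairs, params = params,
                 contact_cutoff = contact_cutoff,
                 energy_cutoff = energy_cutoff, sasa_probe = sasa_probe,
                 sasa_points = sasa_points, rdf_r_max = rdf_r_max,
                 rdf_bin_width = rdf_bin_width,
                 rdf_normalization = rdf_normalization,
                 temperature = temperature, frames = frames,
                 sasa_frames = sasa_frames,
                 hydrophobic_residues = hydrophobic_residues,
                 output_dir = output_dir, seed = seed),
            class = "RunConfig")
}

load_replicate <- function(x) {
  if (inherits(x, "Trajectory")) return(x)
  read_trajectory(x)
}

#' Run the full analysis pipeline
#'
#' For every replicate trajectory: hydrophilic/hydrophobic/combined contact
#' occupancy matrices per domain residue, tilt series per domain, SASA and
#' bound-vs-unbound delta-SASA, backbone RMSD/RMSF, guanidino-carboxylate
#' RDF/PMF with minima, and the protein-lipid energy series with its
#' lowest-energy frame.  Replicate-averaged occupancies are appended when
#' more than one replicate is given.
#'
#' @param config a [run_config()].
#' @return a `ReportBundle`: nested list with `replicates` (per-replicate
#'   results), `averaged` (replicate means), `manifest` (the configuration
#'   echo).  If `config$output_dir` is set, CSV/JSON outputs are written
#'   there too.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  stage <- function(name, expr) {
    out <- try(expr, silent = TRUE)
    if (inherits(out, "try-error"))
      stop("pipeline stage '", name, "' failed: ",
           attr(out, "condition")$message)
    out
  }
  reps <- lapply(config$trajectories, load_replicate)
  results <- vector("list", length(reps))
  for (r in seq_along(reps)) {
    traj <- reps[[r]]
    top <- traj$topology
    frames <- if (is.null(config$frames)) seq_len(n_frames(traj))
              else config$frames
    ma <- stage("moieties", assign_moieties(
      top, hydrophobic_residues = config$hydrophobic_residues))
    anchors_idx <- stage("anchors",
                         atom_index(top, config$anchors, "CA", chain = "S"))
    res <- list()
    res$contacts <- lapply(config$domains, function(resids) {
      present <- intersect(resids, top$resid[top$segment == "protein"])
      list(hydrophilic = contact_timeseries(traj, present, ma,
                                            config$contact_cutoff,
                                            "hydrophilic", frames),
           hydrophobic = contact_timeseries(traj, present, ma,
                                            config$contact_cutoff,
                                            "hydrophobic", frames),
           all = contact_timeseries(traj, present, ma,
                                    config$contact_cutoff, "all", frames))
    })
    res$tilt <- lapply(names(config$domains), function(dn) {
      ap <- config$axis_pairs[[dn]]
      tilt_series(traj, anchors_idx, atom_index(top, ap, "CA"), frames)
    })
    names(res$tilt) <- names(config$domains)
    protein_idx <- which(top$segment == "protein")
    lipid_idx <- which(top$segment == "lipid")
    sasa_frames <- if (!is.null(config$sasa_frames)) config$sasa_frames
                   else frames[seq(1L, length(frames),
                                   by = max(1L, length(frames) %/% 25L))]
    res$delta_sasa <- stage("sasa", delta_sasa(
      traj, traj, protein_idx,
      occluders_bound = c(protein_idx, lipid_idx),
      occluders_unbound = protein_idx,
      probe = config$sasa_probe, n_points = config$sasa_points,
      frames_bound = sasa_frames, frames_unbound = sasa_frames))
    bb <- backbone_selection(top)
    res$rmsd <- stage("rmsd", rmsd_series(traj, 1L, bb))
    res$rmsf <- stage("rmsf", rmsf_per_residue(traj, bb))
    res$rdf <- lapply(config$rdf_pairs, function(rp) {
      ref <- which(top$segment == "protein" & top$resid == rp$resid &
                     top$name %in% c("NE", "NH1", "NH2"))
      tgt <- which(top$resname == "DOPS" & top$name %in% c("O13A", "O13B"))
      if (!length(ref) || !length(tgt)) return(NULL)
      prof <- rdf(traj, ref, tgt, config$rdf_r_max, config$rdf_bin_width,
                  config$rdf_normalization, frames)
      pmf <- pmf_from_rdf(prof, config$temperature)
      list(rdf = prof, pmf = pmf, minimum = pmf$minimum)
    })
    res$energy <- stage("energy", energy_series(
      traj, protein_idx, config$params, config$energy_cutoff,
      lipid_idx, frames))
    results[[r]] <- res
  }
  averaged <- NULL
  if (length(results) > 1L) {
    averaged <- list(contacts = lapply(names(config$domains), function(dn)
      lapply(c("hydrophilic", "hydrophobic", "all"), function(mode)
        average_replicates(lapply(results, function(r)
          r$contacts[[dn]][[mode]])))))
    names(averaged$contacts) <- names(config$domains)
    for (dn in names(config$domains))
      names(averaged$contacts[[dn]]) <- c("hydrophilic", "hydrophobic",
                                          "all")
    averaged$tilt <- lapply(names(config$domains), function(dn) {
      m <- vapply(results, function(r) r$tilt[[dn]]$mean, 1)
      s <- vapply(results, function(r) r$tilt[[dn]]$sd, 1)
      c(mean = mean(m), sd = mean(s))
    })
    names(averaged$tilt) <- names(config$domains)
  }
  manifest <- config
  manifest$trajectories <- sprintf("replicate_%d", seq_along(reps))
  manifest$n_frames <- vapply(reps, n_frames, 1L)
  manifest$package_version <- as.character(utils::packageVersion("nanotraj"))
  bundle <- structure(list(replicates = results, averaged = averaged,
                           manifest = manifest),
                      class = "ReportBundle")
  if (!is.null(config$output_dir))
    write_bundle(bundle, reps, config)
  bundle
}

write_bundle <- function(bundle, reps, config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  od <- config$output_dir
  for (r in seq_along(bundle$replicates)) {
    res <- bundle$replicates[[r]]
    for (dn in names(res$contacts))
      utils::write.csv(as.data.frame(res$contacts[[dn]]$all),
                       file.path(od, sprintf("contacts_%s_rep%d.csv", dn, r)),
                       row.names = FALSE)
    for (dn in names(res$tilt))
      utils::write.csv(as.data.frame(res$tilt[[dn]]),
                       file.path(od, sprintf("tilt_%s_rep%d.csv", dn, r)),
                       row.names = FALSE)
    utils::write.csv(res$delta_sasa,
                     file.path(od, sprintf("delta_sasa_rep%d.csv", r)),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(res$rmsf),
                     file.path(od, sprintf("rmsf_rep%d.csv", r)),
                     row.names = FALSE)
    utils::write.csv(data.frame(frame = seq_along(res$rmsd$rmsd),
                                rmsd_A = res$rmsd$rmsd),
                     file.path(od, sprintf("rmsd_rep%d.csv", r)),
                     row.names = FALSE)
    for (pn in names(res$rdf)) {
      if (is.null(res$rdf[[pn]])) next
      df <- as.data.frame(res$rdf[[pn]]$rdf)
      df$pmf_kJmol <- res$rdf[[pn]]$pmf$pmf
      utils::write.csv(df, file.path(od, sprintf("rdf_%s_rep%d.csv", pn, r)),
                       row.names = FALSE)
    }
    utils::write.csv(res$energy$table,
                     file.path(od, sprintf("energy_rep%d.csv", r)),
                     row.names = FALSE)
    export_lowest_energy_frame(reps[[r]], res$energy,
                               file.path(od, sprintf(
                                 "lowest_energy_frame_rep%d.pdb", r)))
  }
  man <- bundle$manifest
  man$params <- NULL
  jsonlite::write_json(man[!vapply(man, is.null, TRUE)],
                       file.path(od, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(od)
}

#' Render a human-readable pipeline summary
#'
#' @param bundle a `ReportBundle` from [run_pipeline()].
#' @return character vector of report lines (also printed).
#' @export
render_report <- function(bundle) {
  stopifnot(inherits(bundle, "ReportBundle"))
  ln <- c("== nanodisc-binding analysis report ==", "")
  if (!length(bundle$replicates)) {
    ln <- c(ln, "WARNING: empty bundle, nothing to report")
    cat(ln, sep = "\n")
    return(invisible(ln))
  }
  for (r in seq_along(bundle$replicates)) {
    res <- bundle$replicates[[r]]
    ln <- c(ln, sprintf("-- replicate %d --", r))
    for (dn in names(res$tilt))
      ln <- c(ln, sprintf("tilt %-4s: %6.1f +/- %4.1f deg", dn,
                          res$tilt[[dn]]$mean, res$tilt[[dn]]$sd))
    for (dn in names(res$contacts)) {
      oc <- as.data.frame(res$contacts[[dn]]$all)
      oc <- oc[order(-oc$occupancy), ][seq_len(min(3L, nrow(oc))), ]
      ln <- c(ln, sprintf("top %s contacts: %s", dn,
                          paste(sprintf("%s%d-%s(%s) %.0f%%",
                                        oc$residue_name, oc$residue_id,
                                        oc$moiety, oc$lipid,
                                        100 * oc$occupancy),
                                collapse = "; ")))
    }
    ds <- res$delta_sasa
    buried <- ds[ds$delta_sasa >= 10, ]
    ln <- c(ln, sprintf("residues buried >= 10 A^2: %s",
                        if (nrow(buried))
                          paste(sprintf("%s%d (%.0f)", buried$residue_name,
                                        buried$residue_id,
                                        buried$delta_sasa),
                                collapse = ", ") else "none"))
    ln <- c(ln, sprintf("backbone RMSD %.2f +/- %.2f A; mean RMSF %.2f A",
                        res$rmsd$mean, res$rmsd$sd, mean(res$rmsf$rmsf)))
    for (pn in names(res$rdf)) {
      if (is.null(res$rdf[[pn]])) next
      mn <- res$rdf[[pn]]$minimum
      ln <- c(ln, sprintf("PMF %s: %.2f kJ/mol at %.2f A (%s)", pn,
                          mn$depth, mn$location,
                          res$rdf[[pn]]$pmf$normalization))
    }
    ln <- c(ln, sprintf(
      "energy: %.0f +/- %.0f kJ/mol (truncated pair-sum surrogate), lowest-energy frame %d",
      res$energy$mean, res$energy$sd, res$energy$argmin), "")
  }
  if (!is.null(bundle$averaged)) {
    ln <- c(ln, "-- replicate average --")
    for (dn in names(bundle$averaged$tilt))
      ln <- c(ln, sprintf("tilt %-4s: %6.1f +/- %4.1f deg", dn,
                          bundle$averaged$tilt[[dn]]["mean"],
                          bundle$averaged$tilt[[dn]]["sd"]))
  }
  cat(ln, sep = "\n")
  invisible(ln)
}

#' @export
print.ReportBundle <- function(x, ...) {
  cat("ReportBundle:", length(x$replicates), "replicate(s)",
      if (!is.null(x$averaged)) "with replicate averages" else "", "\n")
  invisible(x)
}
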