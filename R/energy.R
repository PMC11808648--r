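COULOMB_K <- 1389.35458  # kJ mol^-1 A e^-2

#' Read a nonbonded parameter table
#'
#' TSV with columns `residue_name`, `atom_name`, `charge_e`, `sigma_A`,
#' `epsilon_kJmol`.  Parameters are matched to atoms by exact
#' (residue name, atom name).
#'
#' @param path file path.
#' @return a `NonbondedParams` data.frame.
#' @export
read_nonbonded_params <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_nonbonded_params(tb)
}

#' Validate/coerce a nonbonded parameter table
#' @param tb data.frame with columns `residue_name`, `atom_name`,
#'   `charge_e`, `sigma_A`, `epsilon_kJmol`.
#' @return the table, classed `NonbondedParams`.
#' @export
as_nonbonded_params <- function(tb) {
  need <- c("residue_name", "atom_name", "charge_e", "sigma_A",
            "epsilon_kJmol")
  if (!all(need %in% names(tb)))
    stop("parameter table must have columns: ", paste(need, collapse = ", "))
  if (any(tb$epsilon_kJmol < 0)) stop("epsilon must be >= 0")
  if (any(tb$sigma_A <= 0)) stop("sigma must be > 0")
  class(tb) <- c("NonbondedParams", "data.frame")
  tb
}

# per-atom parameter vectors for a topology; errors name the first
# unparameterized atom among 'needed'
map_params <- function(top, params, needed) {
  key <- paste(top$resname, top$name)
  pk <- paste(params$residue_name, params$atom_name)
  hit <- match(key, pk)
  miss <- needed[is.na(hit[needed])]
  if (length(miss))
    stop("missing parameter for atom ", miss[1L], " (",
         top$resname[miss[1L]], " ", top$name[miss[1L]], ")")
  list(charge = params$charge_e[hit], sigma = params$sigma_A[hit],
       epsilon = params$epsilon_kJmol[hit])
}

#' Cutoff nonbonded interaction energy between two groups
#'
#' Plain-truncation pair sum over pairs closer than `cutoff`:
#' Coulomb `k q_i q_j / d` plus Lennard-Jones
#' `4 eps_ij ((sig_ij/d)^12 - (sig_ij/d)^6)` with Lorentz-Berthelot
#' combining (arithmetic sigma, geometric epsilon) and no long-range
#' correction.  This is a documented surrogate for force-field interaction
#' energies: it ranks frames and resolves species contributions, but its
#' absolute values are not PME/force-field energies.
#'
#' @param frm a `Frame` or coordinate matrix.
#' @param group_a,group_b disjoint atom index sets.
#' @param top the `Topology` the indices refer to.
#' @param params a `NonbondedParams` table.
#' @param cutoff pair cutoff in Angstrom (default 12).
#' @param clash_floor distances below this are an error (default 0.1 A).
#' @return named numeric: `E_coulomb`, `E_lj`, `E_total` (kJ/mol).
#' @export
nonbonded_energy <- function(frm, group_a, group_b, top, params,
                             cutoff = 12, clash_floor = 0.1) {
  coords <- if (inherits(frm, "Frame")) frm$coords else as.matrix(frm)
  group_a <- as.integer(group_a); group_b <- as.integer(group_b)
  if (length(intersect(group_a, group_b)))
    stop("invalid groups: group_a and group_b overlap")
  pm <- map_params(top, params, c(group_a, group_b))
  e <- .cpp_nonbonded_energy(coords, group_a - 1L, group_b - 1L,
                             pm$charge, pm$sigma, pm$epsilon,
                             cutoff, clash_floor, COULOMB_K)
  c(E_coulomb = e[1L], E_lj = e[2L], E_total = e[1L] + e[2L])
}

#' Per-frame protein-lipid interaction energy series
#'
#' Computes the cutoff nonbonded energy between the protein selection and
#' each lipid species (by residue name) in every frame, plus the total and
#' the index of the lowest-total-energy frame (ties resolved to the earliest
#' frame).
#'
#' @param traj a `Trajectory`.
#' @param protein_selection protein atom indices.
#' @param params a `NonbondedParams` table.
#' @param cutoff pair cutoff in Angstrom (default 12).
#' @param lipid_selection lipid atom indices (default: all lipid atoms).
#' @param frames optional frame subset.
#' @return an `EnergySeries`: list with `table` (data.frame: frame, species
#'   columns `E_coulomb_*`, `E_lj_*`, and `E_total`), `species`, `argmin`
#'   (frame index), `mean`, `sd`, `cutoff`.
#' @export
energy_series <- function(traj, protein_selection, params, cutoff = 12,
                          lipid_selection = NULL, frames = NULL) {
  top <- traj$topology
  if (is.null(lipid_selection)) lipid_selection <- which(top$segment == "lipid")
  lipid_selection <- setdiff(lipid_selection, protein_selection)
  species <- sort(unique(top$resname[lipid_selection]))
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  pm <- map_params(top, params, c(protein_selection, lipid_selection))
  groups <- lapply(species, function(s)
    lipid_selection[top$resname[lipid_selection] == s])
  tab <- data.frame(frame = frames)
  ec <- matrix(0, length(frames), length(species))
  el <- matrix(0, length(frames), length(species))
  for (f in seq_along(frames)) {
    cf <- traj$coords[, , frames[f]]
    for (s in seq_along(species)) {
      e <- .cpp_nonbonded_energy(cf, protein_selection - 1L,
                                 groups[[s]] - 1L, pm$charge, pm$sigma,
                                 pm$epsilon, cutoff, 0.1, COULOMB_K)
      ec[f, s] <- e[1L]; el[f, s] <- e[2L]
    }
  }
  for (s in seq_along(species)) {
    tab[[paste0("E_coulomb_", species[s])]] <- ec[, s]
    tab[[paste0("E_lj_", species[s])]] <- el[, s]
    tab[[paste0("E_total_", species[s])]] <- ec[, s] + el[, s]
  }
  tab$E_total <- rowSums(ec) + rowSums(el)
  argmin <- frames[which.min(tab$E_total)]
  structure(list(table = tab, species = species, argmin = argmin,
                 mean = mean(tab$E_total), sd = if (nrow(tab) > 1L)
                   stats::sd(tab$E_total) else 0,
                 cutoff = cutoff),
            class = "EnergySeries")
}

#' Write the lowest-energy frame to a structure file
#'
#' @param traj the `Trajectory` the series was computed from.
#' @param series an `EnergySeries`.
#' @param path output path (PDB).
#' @return `path`, invisibly.
#' @export
export_lowest_energy_frame <- function(traj, series, path) {
  stopifnot(inherits(series, "EnergySeries"))
  if (!nrow(series$table)) stop("empty energy series")
  write_structure(traj$topology, get_frame(traj, series$argmin), path,
                  format = "pdb")
  invisible(path)
}

#' @export
print.EnergySeries <- function(x, ...) {
  cat(sprintf(
    "EnergySeries: %d frames, E_total %.1f +/- %.1f kJ/mol (cutoff %g A, truncated pair sum)\n",
    nrow(x$table), x$mean, x$sd, x$cutoff))
  cat("lowest-energy frame:", x$argmin, "\n")
  invisible(x)
}
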