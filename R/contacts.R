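#' Count atom-pair contacts between two groups
#'
#' A contact is an atom pair `(i in group_a, j in group_b)` whose distance is
#' strictly less than `cutoff` (a pair at exactly the cutoff is not a
#' contact).  With `pbc = TRUE` and a box on the frame, the minimum-image
#' convention is applied.
#'
#' @param frm a `Frame` (or plain `n x 3` coordinate matrix).
#' @param group_a,group_b disjoint integer atom index sets (1-based).
#' @param cutoff distance cutoff in Angstrom (default 4).
#' @param pbc apply minimum-image convention (requires a box).
#' @param method `"cell"` (cell-list accelerated) or `"brute"` (all pairs).
#'   PBC counting always uses the all-pairs path.
#' @return integer contact count.
#' @export
count_contacts <- function(frm, group_a, group_b, cutoff = 4,
                           pbc = FALSE, method = c("cell", "brute")) {
  method <- match.arg(method)
  coords <- if (inherits(frm, "Frame")) frm$coords else as.matrix(frm)
  box <- if (inherits(frm, "Frame")) frm$box else NULL
  if (cutoff <= 0) stop("cutoff must be positive")
  group_a <- as.integer(group_a)
  group_b <- as.integer(group_b)
  if (length(intersect(group_a, group_b)))
    stop("invalid groups: group_a and group_b overlap")
  if (!length(group_a) || !length(group_b)) return(0L)
  if (any(c(group_a, group_b) < 1L) ||
      any(c(group_a, group_b) > nrow(coords)))
    stop("atom index out of range")
  xa <- coords[group_a, , drop = FALSE]
  xb <- coords[group_b, , drop = FALSE]
  if (pbc) {
    if (is.null(box))
      stop("configuration error: pbc requested but frame has no box")
    return(.cpp_count_contacts_brute(xa, xb, cutoff, box))
  }
  if (method == "brute")
    return(.cpp_count_contacts_brute(xa, xb, cutoff, NULL))
  .cpp_count_contacts_cell(xa, xb, cutoff)
}

moiety_axis <- function(top, ma, mode) {
  lipid_types <- sort(unique(top$resname[top$segment == "lipid"]))
  classes <- switch(mode,
                    hydrophilic = HYDROPHILIC_LIPID_CLASSES,
                    hydrophobic = HYDROPHOBIC_LIPID_CLASSES,
                    all = c(HYDROPHILIC_LIPID_CLASSES,
                            HYDROPHOBIC_LIPID_CLASSES))
  ax <- expand.grid(moiety = classes, lipid = lipid_types,
                    stringsAsFactors = FALSE)
  ax$channel <- ifelse(ax$moiety %in% HYDROPHILIC_LIPID_CLASSES,
                       "hydrophilic", "hydrophobic")
  # keep only populated (moiety, lipid) combinations (e.g. carboxylate
  # exists only for DOPS)
  keep <- vapply(seq_len(nrow(ax)), function(k)
    any(ma$lipid_class == ax$moiety[k] & top$resname == ax$lipid[k],
        na.rm = TRUE), TRUE)
  ax[keep, , drop = FALSE]
}

#' Per-residue x moiety contact time series and occupancy
#'
#' For every requested residue and every (moiety class, lipid type) column,
#' counts contacting atom pairs per frame and computes the contact
#' *occupancy*: the fraction of frames in which at least one pair is within
#' the cutoff.  In `"hydrophilic"` mode the residue-side atoms are the
#' residue's nitrogens and oxygens and the lipid side is restricted to the
#' polar classes (ester oxygens, amine nitrogen, phosphate, carboxylate); in
#' `"hydrophobic"` mode the residue side is the carbon atoms of residues in
#' the hydrophobic set and the lipid side is the apolar classes (chain and
#' headgroup carbons); `"all"` reports both channels side by side.
#' Hydrogens are never counted.
#'
#' @param traj a `Trajectory`.
#' @param residue_ids integer residue ids to profile (protein residues).
#' @param moieties a `MoietyAssignment` from [assign_moieties()].
#' @param cutoff contact cutoff in Angstrom (default 4).
#' @param mode `"hydrophilic"`, `"hydrophobic"` or `"all"`.
#' @param frames optional integer frame subset.
#' @return a `ContactMatrix`: list with `residues`, `residue_names`,
#'   `moieties` (data.frame: moiety, lipid, channel), `counts`
#'   (`n_frames x n_res x n_moiety` integer array), `occupancy`
#'   (`n_res x n_moiety` matrix), `cutoff`, `mode`, `n_frames`.
#' @export
contact_timeseries <- function(traj, residue_ids, moieties, cutoff = 4,
                               mode = c("hydrophilic", "hydrophobic", "all"),
                               frames = NULL) {
  mode <- match.arg(mode)
  top <- traj$topology
  ma <- moieties
  if (all(is.na(ma$protein_class)))
    stop("moiety assignment lacks protein classes; run assign_moieties()")
  residue_ids <- as.integer(residue_ids)
  pro <- top$segment == "protein"
  missing_res <- setdiff(residue_ids, unique(top$resid[pro]))
  if (length(missing_res))
    stop("residues not in topology: ", paste(missing_res, collapse = ", "))
  ax <- moiety_axis(top, ma, mode)
  if (!nrow(ax)) stop("no lipid moiety columns available")

  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  nf <- length(frames)
  nres <- length(residue_ids)
  nmo <- nrow(ax)
  counts <- array(0L, c(nf, nres, nmo))

  channels <- intersect(c("hydrophilic", "hydrophobic"),
                        if (mode == "all") c("hydrophilic", "hydrophobic")
                        else mode)
  for (ch in channels) {
    probe_class <- paste0(ch, "_probe")
    # probe atoms: per residue, the channel's protein probe atoms
    probe_idx <- integer(0); probe_grp <- integer(0)
    for (k in seq_along(residue_ids)) {
      w <- which(pro & top$resid == residue_ids[k] &
                   ma$protein_class == probe_class)
      probe_idx <- c(probe_idx, w)
      probe_grp <- c(probe_grp, rep(k, length(w)))
    }
    if (ch == "hydrophobic" && mode == "hydrophobic" && !length(probe_idx))
      warning("empty analysis: no hydrophobic probe atoms in the selection")
    cols <- which(ax$channel == ch)
    # target atoms: one slot per (moiety, lipid) column of this channel
    tgt_idx <- integer(0); tgt_grp <- integer(0)
    for (j in seq_along(cols)) {
      w <- which(!is.na(ma$lipid_class) & ma$lipid_class == ax$moiety[cols[j]] &
                   top$resname == ax$lipid[cols[j]] & top$element != "H")
      tgt_idx <- c(tgt_idx, w)
      tgt_grp <- c(tgt_grp, rep(j, length(w)))
    }
    if (!length(probe_idx) || !length(tgt_idx)) next
    for (f in seq_len(nf)) {
      cm <- .cpp_grouped_contact_counts(traj$coords[, , frames[f]],
                                        probe_idx - 1L, probe_grp - 1L,
                                        tgt_idx - 1L, tgt_grp - 1L,
                                        nres, length(cols), cutoff)
      counts[f, , cols] <- counts[f, , cols] + cm
    }
  }
  occupancy <- apply(counts >= 1L, c(2L, 3L), mean)
  dim(occupancy) <- c(nres, nmo)
  rn <- vapply(residue_ids, function(r) top$resname[pro & top$resid == r][1L],
               "")
  structure(list(residues = residue_ids, residue_names = rn,
                 moieties = ax, counts = counts, occupancy = occupancy,
                 cutoff = cutoff, mode = mode, n_frames = nf,
                 frames = frames),
            class = "ContactMatrix")
}

#' Average contact occupancy across replicate trajectories
#'
#' @param matrices list of `ContactMatrix` objects with identical residue
#'   and moiety axes.
#' @return a `ContactMatrix` with `occupancy` the arithmetic mean across
#'   replicates; per-frame counts are dropped.
#' @export
average_replicates <- function(matrices) {
  stopifnot(length(matrices) >= 1L)
  m1 <- matrices[[1L]]
  for (m in matrices[-1L]) {
    if (!identical(m$residues, m1$residues) ||
        !identical(m$moieties$moiety, m1$moieties$moiety) ||
        !identical(m$moieties$lipid, m1$moieties$lipid))
      stop("shape error: replicate contact matrices have different axes")
  }
  occ <- Reduce(`+`, lapply(matrices, `[[`, "occupancy")) / length(matrices)
  out <- m1
  out$occupancy <- occ
  out$counts <- NULL
  out$n_replicates <- length(matrices)
  out
}

#' Tidy export of a contact occupancy matrix
#'
#' @param x a `ContactMatrix`.
#' @param row.names,optional,... ignored (data.frame method signature).
#' @return data.frame with columns `residue_id`, `residue_name`, `moiety`,
#'   `lipid`, `channel`, `occupancy`.
#' @export
as.data.frame.ContactMatrix <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  nres <- length(x$residues)
  nmo <- nrow(x$moieties)
  data.frame(residue_id = rep(x$residues, nmo),
             residue_name = rep(x$residue_names, nmo),
             moiety = rep(x$moieties$moiety, each = nres),
             lipid = rep(x$moieties$lipid, each = nres),
             channel = rep(x$moieties$channel, each = nres),
             occupancy = as.vector(x$occupancy),
             stringsAsFactors = FALSE)
}

#' @export
print.ContactMatrix <- function(x, ...) {
  cat("ContactMatrix (", x$mode, "): ", length(x$residues), " residues x ",
      nrow(x$moieties), " moiety columns, ", x$n_frames, " frames, cutoff ",
      x$cutoff, " A\n", sep = "")
  top <- as.data.frame(x)
  top <- top[order(-top$occupancy), ]
  cat("highest occupancies:\n")
  print(utils::head(top, 5L), row.names = FALSE)
  invisible(x)
}

#' @export
summary.ContactMatrix <- function(object, ...) {
  df <- as.data.frame(object)
  df[df$occupancy > 0, ]
}
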