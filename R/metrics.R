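#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimising the (optionally
#' weighted) RMSD between `mobile` and `reference` coordinate sets, via SVD
#' of the weighted covariance matrix with the determinant sign corrected so
#' the rotation is proper (det = +1, never a reflection).
#'
#' @param mobile,reference `n x 3` coordinate matrices, equal `n >= 3`.
#' @param weights optional non-negative per-atom weights.
#' @return a `FitResult`: list with `rotation` (3x3), `translation`
#'   (length 3), `rmsd` (Angstrom).  Apply as
#'   `mobile %*% rotation + translation` (row vectors).
#' @export
superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n < 3L || nrow(reference) != n)
    stop("degenerate fit: need equal coordinate sets with at least 3 atoms")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w < 0) || sum(w) <= 0)
    stop("invalid weights")
  w <- w / sum(w)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  X <- sweep(mobile, 2L, cm)
  Y <- sweep(reference, 2L, cr)
  H <- t(X * w) %*% Y
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (any(sv$d < 1e-12 * max(sv$d, 1e-300)) &&
      qr(X)$rank < 2L)
    stop("degenerate fit: rank-deficient coordinates")
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  tr <- cr - as.vector(cm %*% R)
  fitted <- X %*% R
  rmsd <- sqrt(sum(w * rowSums((fitted - Y)^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd),
            class = "FitResult")
}

#' @export
print.FitResult <- function(x, ...) {
  cat(sprintf("FitResult: rmsd %.4f A\n", x$rmsd))
  invisible(x)
}

apply_fit <- function(coords, fit) {
  sweep(coords %*% fit$rotation, 2L, fit$translation, `+`)
}

#' Backbone RMSD time series
#'
#' Each frame is (optionally) superposed on the reference over `selection`
#' and the RMSD over that selection reported.
#'
#' @param traj a `Trajectory`.
#' @param reference reference frame index (default 1) or an `n x 3`
#'   coordinate matrix for the selection.
#' @param selection atom indices (e.g. a backbone selection).
#' @param fit superpose before measuring (default `TRUE`); with
#'   `fit = FALSE` the raw displacement RMSD is reported.
#' @return an `RMSDSeries`: list with `rmsd` (per frame, Angstrom), `mean`,
#'   `sd`, `fit`, `selection`.
#' @export
rmsd_series <- function(traj, reference = 1L, selection, fit = TRUE) {
  if (!length(selection)) stop("empty selection")
  ref <- if (is.matrix(reference)) reference
         else traj$coords[selection, , reference]
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    x <- traj$coords[selection, , f]
    if (fit) superpose(x, ref)$rmsd
    else sqrt(mean(rowSums((x - ref)^2)))
  }, 1)
  structure(list(rmsd = vals, mean = mean(vals),
                 sd = if (length(vals) > 1L) stats::sd(vals) else 0,
                 fit = fit, selection = selection),
            class = "RMSDSeries")
}

#' @export
print.RMSDSeries <- function(x, ...) {
  cat(sprintf("RMSDSeries: %d frames, %.2f +/- %.2f A (%s)\n",
              length(x$rmsd), x$mean, x$sd,
              if (x$fit) "fitted" else "no fit"))
  invisible(x)
}

BACKBONE_NAMES <- c("N", "CA", "C", "O")

#' Backbone selection helper
#'
#' @param top a `Topology`.
#' @param resid optional residue id filter.
#' @return atom indices of protein backbone atoms (N, CA, C, O).
#' @export
backbone_selection <- function(top, resid = NULL) {
  m <- top$segment == "protein" & top$name %in% BACKBONE_NAMES
  if (!is.null(resid)) m <- m & top$resid %in% resid
  which(m)
}

#' Per-residue backbone RMSF
#'
#' Root-mean-square fluctuation about the time-average structure.  With
#' `fit = TRUE` each frame is first superposed on the reference (frame 1),
#' the time average taken, and frames re-superposed on that average once
#' (the usual fit-average iteration) before fluctuations are measured.
#' The residue value is the unweighted mean over its selected atoms.
#'
#' @param traj a `Trajectory` with at least 2 frames.
#' @param selection backbone atom indices (default
#'   `backbone_selection(traj$topology)`).
#' @param fit superpose frames before measuring (default `TRUE`).
#' @return an `RMSFProfile`: data.frame with `residue_id`, `residue_name`,
#'   `rmsf` (Angstrom), plus attribute `atomic` (per-atom RMSF).
#' @export
rmsf_per_residue <- function(traj, selection = NULL, fit = TRUE) {
  if (n_frames(traj) < 2L)
    stop("insufficient frames: RMSF needs at least 2 frames")
  top <- traj$topology
  if (is.null(selection)) selection <- backbone_selection(top)
  if (!length(selection)) stop("empty selection")
  nf <- n_frames(traj)
  X <- traj$coords[selection, , , drop = FALSE]
  if (fit) {
    ref <- X[, , 1L]
    for (f in seq_len(nf)) X[, , f] <- apply_fit(X[, , f],
                                                 superpose(X[, , f], ref))
    avg <- apply(X, c(1L, 2L), mean)
    for (f in seq_len(nf)) X[, , f] <- apply_fit(X[, , f],
                                                 superpose(X[, , f], avg))
  }
  avg <- apply(X, c(1L, 2L), mean)
  dev2 <- matrix(0, length(selection), nf)
  for (f in seq_len(nf)) dev2[, f] <- rowSums((X[, , f] - avg)^2)
  atomic <- sqrt(rowMeans(dev2))
  key <- paste(top$chain[selection], top$resid[selection])
  agg <- rowsum(atomic, key, reorder = FALSE) /
    as.vector(table(factor(key, levels = unique(key))))
  first <- !duplicated(key)
  out <- data.frame(residue_id = top$resid[selection][first],
                    residue_name = top$resname[selection][first],
                    rmsf = agg[, 1L])
  rownames(out) <- NULL
  attr(out, "atomic") <- data.frame(index = selection, rmsf = atomic)
  class(out) <- c("RMSFProfile", "data.frame")
  out
}
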