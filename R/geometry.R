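#' Membrane-plane normal from three anchor points
#'
#' The plane is spanned by the three anchor atoms (conventionally the alpha
#' carbons of three scaffold residues); the normal is the normalized cross
#' product of (p2 - p1) and (p3 - p1).
#'
#' @param frm a `Frame` or coordinate matrix.
#' @param p1,p2,p3 atom indices of the three anchors.
#' @return unit 3-vector.
#' @export
membrane_normal <- function(frm, p1, p2, p3) {
  coords <- if (inherits(frm, "Frame")) frm$coords else as.matrix(frm)
  v12 <- coords[p2, ] - coords[p1, ]
  v13 <- coords[p3, ] - coords[p1, ]
  n <- c(v12[2L] * v13[3L] - v12[3L] * v13[2L],
         v12[3L] * v13[1L] - v12[1L] * v13[3L],
         v12[1L] * v13[2L] - v12[2L] * v13[1L])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-6)
    stop("degenerate plane: anchor points are collinear")
  n / nn
}

#' Tilt angle of a protein axis relative to the membrane plane
#'
#' The tilt is `90 - acos(n . p)` in degrees, where `n` is the unit membrane
#' normal from the anchors and `p` the unit protein vector from the first to
#' the second axis atom.  A vector lying in the membrane plane has tilt 0;
#' parallel to the normal +90; antiparallel -90.  The sign is kept (tilt is
#' in [-90, 90]), so the axis endpoints should be given membrane-proximal
#' first for the usual positive-tilt convention.
#'
#' @param frm a `Frame` or coordinate matrix.
#' @param anchors integer vector of three anchor atom indices.
#' @param axis_pair integer vector of two protein axis atom indices
#'   (from, to).
#' @param normal_sign +1 or -1, multiplies the cross-product normal (used by
#'   [tilt_series()] to keep the normal pointing toward the protein).
#' @return tilt angle in degrees.
#' @export
tilt_angle <- function(frm, anchors, axis_pair, normal_sign = 1) {
  coords <- if (inherits(frm, "Frame")) frm$coords else as.matrix(frm)
  n <- normal_sign * membrane_normal(coords, anchors[1L], anchors[2L],
                                     anchors[3L])
  p <- coords[axis_pair[2L], ] - coords[axis_pair[1L], ]
  pn <- sqrt(sum(p^2))
  if (pn < 1e-9) stop("degenerate axis: zero-length protein vector")
  d <- sum(n * p) / pn
  d <- max(-1, min(1, d))
  90 - acos(d) * 180 / pi
}

#' Per-frame tilt angle series
#'
#' Computes the tilt angle in every frame, plus its arithmetic mean and
#' sample standard deviation.  The normal orientation is disambiguated at
#' the first frame by requiring a positive component along the vector from
#' the anchor centroid to the axis-atom centroid (i.e. the normal points
#' toward the protein); that sign is then held fixed for all frames.
#'
#' @param traj a `Trajectory`.
#' @param anchors three anchor atom indices (e.g.
#'   `atom_index(top, c(32, 93, 158))`).
#' @param axis_pair two protein axis atom indices (membrane-proximal first).
#' @param frames optional integer frame subset.
#' @return a `TiltSeries`: list with `angles` (degrees), `mean`, `sd`,
#'   `anchors`, `axis_pair`, `frames`.
#' @export
tilt_series <- function(traj, anchors, axis_pair, frames = NULL) {
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  c0 <- traj$coords[, , frames[1L]]
  n0 <- membrane_normal(c0, anchors[1L], anchors[2L], anchors[3L])
  toward <- colMeans(c0[axis_pair, , drop = FALSE]) -
    colMeans(c0[anchors, , drop = FALSE])
  s <- if (sum(n0 * toward) < 0) -1 else 1
  angles <- vapply(frames, function(f) {
    a <- try(tilt_angle(traj$coords[, , f], anchors, axis_pair,
                        normal_sign = s), silent = TRUE)
    if (inherits(a, "try-error"))
      stop("tilt computation failed at frame ", f, ": ",
           attr(a, "condition")$message)
    a
  }, 1)
  structure(list(angles = angles,
                 mean = mean(angles),
                 sd = if (length(angles) > 1L) stats::sd(angles) else 0,
                 anchors = anchors, axis_pair = axis_pair, frames = frames),
            class = "TiltSeries")
}

#' @export
print.TiltSeries <- function(x, ...) {
  cat(sprintf("TiltSeries: %d frames, tilt %.1f +/- %.1f degrees\n",
              length(x$angles), x$mean, x$sd))
  invisible(x)
}

#' @export
summary.TiltSeries <- function(object, ...) {
  c(mean = object$mean, sd = object$sd, n = length(object$angles),
    min = min(object$angles), max = max(object$angles))
}

#' Tidy export of a tilt series
#' @param x a `TiltSeries`.
#' @param row.names,optional,... ignored.
#' @return data.frame with `frame` and `angle_deg`.
#' @export
as.data.frame.TiltSeries <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  data.frame(frame = x$frames, angle_deg = x$angles)
}
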