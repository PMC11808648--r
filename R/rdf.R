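GAS_CONSTANT_KJ <- 8.314462618e-3  # kJ mol^-1 K^-1

#' Radial distribution function between two atom groups
#'
#' Histograms all reference-target distances over the frames, then
#' normalises per bin:
#' `g(r) = count(r) / (N_ref * N_frames * 4 pi r^2 dr * rho)`, with
#' `rho = N_target / V_box` in `"box_density"` mode.  For a finite system
#' without a meaningful bulk density, `"tail_unit"` mode rescales g so its
#' mean over the last 10% of bins is 1; the two modes differ by a constant
#' factor, so the location of extrema is mode-independent.
#'
#' @param traj a `Trajectory`.
#' @param reference,target disjoint, nonempty atom index sets.
#' @param r_max histogram range in Angstrom (default 15).
#' @param bin_width bin width in Angstrom (default 0.02).
#' @param normalization `"box_density"` or `"tail_unit"`.
#' @param frames optional frame subset.
#' @return an `RDFProfile`: list with `r` (bin centres), `g`, `counts`,
#'   `normalization`, `r_max`, `bin_width`, `n_ref`, `n_target`,
#'   `n_frames`.
#' @export
rdf <- function(traj, reference, target, r_max = 15, bin_width = 0.02,
                normalization = c("box_density", "tail_unit"),
                frames = NULL) {
  normalization <- match.arg(normalization)
  if (!length(reference) || !length(target))
    stop("reference and target groups must be nonempty")
  if (length(intersect(reference, target)))
    stop("reference and target groups must be disjoint")
  if (!(r_max > bin_width && bin_width > 0))
    stop("need r_max > bin_width > 0")
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  breaks <- seq(0, r_max, by = bin_width)
  if (breaks[length(breaks)] < r_max) breaks <- c(breaks, r_max)
  nb <- length(breaks) - 1L
  counts <- integer(nb)
  for (f in frames) {
    cf <- traj$coords[, , f]
    a <- cf[reference, , drop = FALSE]
    b <- cf[target, , drop = FALSE]
    d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * (a %*% t(b))
    d <- sqrt(pmax(d2, 0))
    d <- d[d < r_max]
    if (length(d))
      counts <- counts + tabulate(findInterval(d, breaks,
                                               rightmost.closed = FALSE,
                                               left.open = TRUE) , nb)
  }
  centers <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  widths <- diff(breaks)
  shell <- 4 * pi * centers^2 * widths
  if (normalization == "box_density") {
    if (is.null(traj$box))
      stop("configuration error: box_density normalization needs a box")
    vol <- mean(apply(traj$box[frames, , drop = FALSE], 1L, prod))
    rho <- length(target) / vol
    g <- counts / (length(reference) * length(frames) * shell * rho)
  } else {
    gg <- counts / (length(reference) * length(frames) * shell)
    tail_bins <- seq.int(max(1L, nb - ceiling(nb / 10) + 1L), nb)
    tail_mean <- mean(gg[tail_bins])
    if (tail_mean <= 0)
      stop("tail_unit normalization undefined: empty histogram tail")
    g <- gg / tail_mean
  }
  structure(list(r = centers, g = g, counts = counts,
                 normalization = normalization, r_max = r_max,
                 bin_width = bin_width, n_ref = length(reference),
                 n_target = length(target), n_frames = length(frames)),
            class = "RDFProfile")
}

#' Potential of mean force from an RDF
#'
#' `PMF(r) = -R T ln g(r)` in kJ/mol, defined only where `g > 0`.  The
#' reported minimum is the most negative defined PMF value, which coincides
#' with the maximum of g.  Because depth (but not location) depends on the
#' RDF normalization mode, depths should be read as effective/qualitative
#' binding estimates.
#'
#' @param profile an `RDFProfile`.
#' @param temperature absolute temperature in K (default 310).
#' @return a `PMFProfile`: list with `r`, `pmf` (NA where undefined),
#'   `defined`, `temperature`, `minimum` (list `depth`, `location`),
#'   `normalization`.
#' @export
pmf_from_rdf <- function(profile, temperature = 310) {
  stopifnot(inherits(profile, "RDFProfile"))
  if (temperature <= 0) stop("temperature must be positive")
  defined <- profile$g > 0
  if (!any(defined))
    stop("no defined PMF: g(r) is zero everywhere")
  pmf <- rep(NA_real_, length(profile$g))
  pmf[defined] <- -GAS_CONSTANT_KJ * temperature * log(profile$g[defined])
  out <- structure(list(r = profile$r, pmf = pmf, defined = defined,
                        temperature = temperature,
                        normalization = profile$normalization),
                   class = "PMFProfile")
  out$minimum <- pmf_minimum(out)
  out
}

#' Global PMF minimum (depth and location)
#'
#' Ties are broken toward the smaller distance.
#'
#' @param profile a `PMFProfile`.
#' @return list with `depth` (kJ/mol) and `location` (Angstrom).
#' @export
pmf_minimum <- function(profile) {
  stopifnot(inherits(profile, "PMFProfile"))
  ok <- which(profile$defined)
  if (!length(ok)) stop("no defined PMF bins")
  mn <- min(profile$pmf[ok])
  loc <- profile$r[ok[which(profile$pmf[ok] == mn)[1L]]]
  list(depth = mn, location = loc)
}

#' @export
print.RDFProfile <- function(x, ...) {
  cat(sprintf(
    "RDFProfile: %d bins to %.1f A (width %.3f), %d ref x %d target, %d frames [%s]\n",
    length(x$r), x$r_max, x$bin_width, x$n_ref, x$n_target, x$n_frames,
    x$normalization))
  pk <- which.max(x$g)
  cat(sprintf("g(r) peak %.2f at %.2f A\n", x$g[pk], x$r[pk]))
  invisible(x)
}

#' @export
print.PMFProfile <- function(x, ...) {
  cat(sprintf(
    "PMFProfile (T = %g K, %s): minimum %.2f kJ/mol at %.2f A\n",
    x$temperature, x$normalization, x$minimum$depth, x$minimum$location))
  invisible(x)
}

#' Tidy export of RDF/PMF profiles
#' @param x an `RDFProfile`.
#' @param row.names,optional,... ignored.
#' @return data.frame with `r`, `g`, `counts`.
#' @export
as.data.frame.RDFProfile <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  data.frame(r = x$r, g = x$g, counts = x$counts)
}
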