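#' Construct a Topology
#'
#' A Topology is the static description of a molecular system: one row per
#' atom with its name, element, residue, chain and segment class.  It is a
#' `data.frame` (class `"Topology"`) so all the usual data-frame tools apply.
#' Atom indices are 1-based and contiguous.
#'
#' @param name character, atom names (CHARMM36 dialect for lipids).
#' @param resname character, residue names (e.g. `"ARG"`, `"DOPC"`).
#' @param resid integer, author residue numbering (carried verbatim, never
#'   re-indexed, so e.g. C1-domain residues 2021-2170 keep their ids).
#' @param chain character, chain identifiers.
#' @param element character or `NULL`; inferred from atom names if omitted.
#' @param segment character or `NULL`; one of `"protein"`, `"lipid"`,
#'   `"scaffold"`, `"solvent"`, `"ion"`.  Inferred via
#'   [infer_segment_class()] if omitted.
#' @param scaffold_chain chain id(s) treated as nanodisc scaffold when
#'   inferring segments (default `"S"`).
#' @return a `Topology` data.frame with columns `index`, `name`, `element`,
#'   `resname`, `resid`, `chain`, `segment`.
#' @export
topology <- function(name, resname, resid, chain = "A", element = NULL,
                     segment = NULL, scaffold_chain = "S") {
  n <- length(name)
  if (n == 0L) stop("empty topology: zero atoms")
  name    <- as.character(name)
  resname <- rep_len(as.character(resname), n)
  resid   <- rep_len(as.integer(resid), n)
  chain   <- rep_len(as.character(chain), n)
  if (is.null(element)) element <- guess_element(name)
  element <- rep_len(as.character(element), n)
  if (is.null(segment))
    segment <- infer_segment_class(resname, chain, scaffold_chain)
  segment <- rep_len(as.character(segment), n)
  top <- data.frame(index = seq_len(n), name = name, element = element,
                    resname = resname, resid = resid, chain = chain,
                    segment = segment, stringsAsFactors = FALSE)
  class(top) <- c("Topology", "data.frame")
  validate_topology(top)
  top
}

#' Validate Topology invariants
#'
#' Checks contiguous 1-based indices, a segment class for every atom, and
#' residue ids monotone non-decreasing within each chain.
#'
#' @param top a `Topology`.
#' @return `top`, invisibly; errors describe the violated invariant.
#' @export
validate_topology <- function(top) {
  if (!identical(top$index, seq_len(nrow(top))))
    stop("topology indices must be 1-based and contiguous")
  ok <- top$segment %in% c("protein", "lipid", "scaffold", "solvent", "ion",
                           "other")
  if (!all(ok))
    stop("unassigned segment class for atoms: ",
         paste(utils::head(top$index[!ok], 5L), collapse = ", "))
  for (ch in unique(top$chain)) {
    r <- top$resid[top$chain == ch]
    if (is.unsorted(r))
      stop("residue ids not monotone within chain '", ch, "'")
  }
  invisible(top)
}

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "HSD", "HSE", "HSP", "ILE", "LEU", "LYS", "MET",
                 "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
WATER_RES <- c("TIP3", "TIP3P", "HOH", "WAT", "SOL", "SPC", "TIP4")
ION_RES   <- c("SOD", "CLA", "POT", "NA", "CL", "K", "MG", "CAL", "NA+",
               "CL-")
LIPID_RES <- c("DOPC", "DOPS")

#' Infer segment classes from residue names and chains
#'
#' Standard amino-acid residue names map to `"protein"` unless the chain is a
#' designated scaffold chain (then `"scaffold"`); DOPC/DOPS map to `"lipid"`;
#' common water and ion names map to `"solvent"`/`"ion"`; anything else maps
#' to `"other"`.
#'
#' @param resname,chain character vectors, one entry per atom.
#' @param scaffold_chain chain id(s) whose amino acids are nanodisc scaffold.
#' @return character vector of segment classes.
#' @export
infer_segment_class <- function(resname, chain, scaffold_chain = "S") {
  seg <- rep("other", length(resname))
  aa <- resname %in% STANDARD_AA
  seg[aa] <- "protein"
  seg[aa & chain %in% scaffold_chain] <- "scaffold"
  seg[resname %in% LIPID_RES] <- "lipid"
  seg[resname %in% WATER_RES] <- "solvent"
  seg[resname %in% ION_RES] <- "ion"
  seg
}

# Element from atom name: leading digits stripped, first alphabetic character,
# with two-letter cases recognised for common bio elements.
guess_element <- function(name) {
  nm <- toupper(gsub("^[0-9']+", "", name))
  el <- substr(nm, 1L, 1L)
  two <- substr(nm, 1L, 2L)
  el[two %in% c("CL", "NA", "MG", "FE", "ZN")] <- two[two %in%
    c("CL", "NA", "MG", "FE", "ZN")]
  el
}

#' Number of atoms in a Topology, Frame or Trajectory
#' @param x a `Topology`, `Frame` or `Trajectory`.
#' @return integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "Topology")) return(nrow(x))
  if (inherits(x, "Frame")) return(nrow(x$coords))
  if (inherits(x, "Trajectory")) return(dim(x$coords)[1L])
  stop("n_atoms: unsupported type")
}

#' Construct a coordinate Frame
#'
#' @param coords numeric matrix, one row per atom, columns x, y, z in
#'   Angstrom.
#' @param box optional orthorhombic box lengths (3 values, Angstrom).
#' @param time optional time stamp in ps.
#' @return a `Frame` object.
#' @export
frame <- function(coords, box = NULL, time = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an n x 3 matrix")
  if (!all(is.finite(coords))) stop("non-finite coordinates in frame")
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
      stop("box must be three positive lengths (Angstrom)")
  }
  structure(list(coords = coords, box = box, time = time), class = "Frame")
}

#' Construct a Trajectory
#'
#' @param topology a `Topology`.
#' @param coords numeric array `n_atoms x 3 x n_frames`, or a list of
#'   `Frame`s.
#' @param box optional box lengths recycled across frames (or `n_frames x 3`
#'   matrix).
#' @param time optional per-frame times in ps.
#' @return a `Trajectory` object.
#' @export
trajectory <- function(topology, coords, box = NULL, time = NULL) {
  stopifnot(inherits(topology, "Topology"))
  if (is.list(coords) && all(vapply(coords, inherits, TRUE, "Frame"))) {
    frames <- coords
    if (length(frames) == 0L) stop("trajectory needs at least one frame")
    na <- vapply(frames, n_atoms, 1L)
    if (!all(na == na[1L])) stop("topology mismatch: frames differ in atom count")
    coords <- array(0, c(na[1L], 3L, length(frames)))
    for (i in seq_along(frames)) coords[, , i] <- frames[[i]]$coords
    if (is.null(box) && !is.null(frames[[1L]]$box))
      box <- do.call(rbind, lapply(frames, function(f)
        if (is.null(f$box)) rep(NA_real_, 3L) else f$box))
    if (is.null(time)) {
      tt <- vapply(frames, function(f)
        if (is.null(f$time)) NA_real_ else as.numeric(f$time), 1)
      if (!all(is.na(tt))) time <- tt
    }
  }
  coords <- as.array(coords)
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  if (dim(coords)[1L] != nrow(topology))
    stop("topology mismatch: coordinate count differs from topology atom count")
  if (dim(coords)[3L] < 1L) stop("trajectory needs at least one frame")
  if (!all(is.finite(coords))) stop("non-finite coordinates in trajectory")
  if (!is.null(box) && !is.matrix(box))
    box <- matrix(box, nrow = dim(coords)[3L], ncol = 3L, byrow = TRUE)
  structure(list(topology = topology, coords = coords, box = box,
                 time = time),
            class = "Trajectory")
}

#' Number of frames in a Trajectory
#' @param traj a `Trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3L]

#' Extract one Frame from a Trajectory
#' @param traj a `Trajectory`.
#' @param i frame index (1-based).
#' @return a `Frame`.
#' @export
get_frame <- function(traj, i) {
  i <- as.integer(i)
  if (i < 1L || i > n_frames(traj)) stop("frame index out of range: ", i)
  frame(traj$coords[, , i, drop = TRUE],
        box = if (!is.null(traj$box)) {
          b <- traj$box[i, ]
          if (all(is.finite(b))) b else NULL
        },
        time = if (!is.null(traj$time)) traj$time[i])
}

#' Look up atom indices by residue id and atom name
#'
#' Convenience accessor used for anchor residues and axis endpoints.
#'
#' @param top a `Topology`.
#' @param resid residue id(s).
#' @param name atom name (default `"CA"`).
#' @param chain optional chain filter.
#' @return integer atom indices (1-based), in the order of `resid`.
#' @export
atom_index <- function(top, resid, name = "CA", chain = NULL) {
  out <- integer(length(resid))
  for (k in seq_along(resid)) {
    hit <- top$resid == resid[k] & top$name == name
    if (!is.null(chain)) hit <- hit & top$chain %in% chain
    w <- which(hit)
    if (length(w) == 0L)
      stop("no atom '", name, "' in residue ", resid[k])
    out[k] <- w[1L]
  }
  out
}

#' @export
print.Topology <- function(x, ...) {
  cat("Topology:", nrow(x), "atoms,",
      length(unique(paste(x$chain, x$resid))), "residues\n")
  cat("segments:", paste(sprintf("%s=%d", names(table(x$segment)),
                                 table(x$segment)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("Trajectory:", n_frames(x), "frames x", n_atoms(x), "atoms",
      if (!is.null(x$box)) "(with box)" else "", "\n")
  invisible(x)
}

#' @export
print.Frame <- function(x, ...) {
  cat("Frame:", nrow(x$coords), "atoms",
      if (!is.null(x$box)) paste0("box ", paste(signif(x$box, 5),
                                                collapse = " x "), " A")
      else "", "\n")
  invisible(x)
}
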