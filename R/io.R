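#' Read a molecular structure file
#'
#' Reads PDB (fixed-column v3.3, via bio3d), GRO or plain XYZ.  Coordinates
#' are returned in Angstrom (GRO nm values are converted on read).  For a
#' multi-model PDB only the first model is returned; use [read_trajectory()]
#' for all models.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"pdb"`, `"gro"`, `"xyz"`; `"auto"` picks
#'   by extension.
#' @param scaffold_chain chain id(s) used for segment-class inference.
#' @return list with elements `topology` (a [topology()]) and `frame`
#'   (a [frame()]).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro", "xyz"),
                           scaffold_chain = "S") {
  format <- resolve_format(match.arg(format), path)
  if (!file.exists(path)) stop("file not found: ", path)
  out <- switch(format,
                pdb = read_pdb_file(path, multi = FALSE, scaffold_chain),
                gro = read_gro_file(path, multi = FALSE, scaffold_chain),
                xyz = read_xyz_file(path, multi = FALSE, scaffold_chain))
  list(topology = out$topology, frame = out$frames[[1L]])
}

#' Read one or more trajectory files
#'
#' Frames are concatenated in path order.  All files must share one topology
#' (same atom count and atom names).
#'
#' @inheritParams read_structure
#' @param paths character vector of file paths.
#' @return a [trajectory()].
#' @export
read_trajectory <- function(paths, format = c("auto", "pdb", "gro", "xyz"),
                            scaffold_chain = "S") {
  fmt0 <- match.arg(format)
  top <- NULL
  frames <- list()
  for (p in paths) {
    format <- resolve_format(fmt0, p)
    if (!file.exists(p)) stop("file not found: ", p)
    out <- switch(format,
                  pdb = read_pdb_file(p, multi = TRUE, scaffold_chain),
                  gro = read_gro_file(p, multi = TRUE, scaffold_chain),
                  xyz = read_xyz_file(p, multi = TRUE, scaffold_chain))
    if (is.null(top)) {
      top <- out$topology
    } else if (nrow(out$topology) != nrow(top) ||
               !identical(out$topology$name, top$name)) {
      stop("topology mismatch: '", p,
           "' does not share the topology of the first file")
    }
    frames <- c(frames, out$frames)
  }
  trajectory(top, frames)
}

resolve_format <- function(format, path) {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("pdb", "ent")) return("pdb")
  if (ext == "gro") return("gro")
  if (ext == "xyz") return("xyz")
  stop("cannot infer format from extension of '", path, "'")
}

# -- PDB ---------------------------------------------------------------------

read_pdb_file <- function(path, multi, scaffold_chain) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  bad <- which(is_atom & nchar(lines) < 54L)
  if (length(bad))
    stop("PDB parse error at line ", bad[1L],
         ": truncated ATOM/HETATM record")
  if (!any(is_atom)) stop("empty input: no ATOM/HETATM records in ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = multi,
                                          verbose = FALSE))
  at <- pdb$atom
  if (nrow(at) == 0L) stop("empty input: no atoms parsed from ", path)
  if (any(is.na(at$resno)))
    stop("PDB parse error: unreadable residue number (check column layout)")
  element <- at$elesy
  if (is.null(element) || all(is.na(element)) || all(element == ""))
    element <- guess_element(at$elety)
  element[is.na(element) | element == ""] <-
    guess_element(at$elety)[is.na(element) | element == ""]
  chain <- at$chain
  chain[is.na(chain)] <- " "
  top <- topology(name = at$elety, resname = at$resid, resid = at$resno,
                  chain = chain, element = trimws(element),
                  scaffold_chain = scaffold_chain)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  if (!multi) xyz <- xyz[1L, , drop = FALSE]
  frames <- lapply(seq_len(nrow(xyz)), function(i)
    frame(matrix(xyz[i, ], ncol = 3L, byrow = TRUE), box = read_cryst1(lines)))
  list(topology = top, frames = frames)
}

read_cryst1 <- function(lines) {
  w <- which(startsWith(lines, "CRYST1"))
  if (!length(w)) return(NULL)
  b <- as.numeric(c(substr(lines[w[1L]], 7, 15), substr(lines[w[1L]], 16, 24),
                    substr(lines[w[1L]], 25, 33)))
  if (any(is.na(b)) || any(b <= 0)) return(NULL)
  b
}

#' Write a structure file
#'
#' Emits fixed-column PDB v3.3 (occupancy 1.00, B-factor 0.00) or GRO
#' (coordinates converted to nm).  The written file re-reads to equal
#' content within format precision (PDB/GRO store 3 decimals).
#'
#' @param top a `Topology`.
#' @param frm a `Frame`.
#' @param path output file path.
#' @param format `"pdb"` or `"gro"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(top, frm, path, format = c("pdb", "gro")) {
  format <- match.arg(format)
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write to path: ", path)
  on.exit(close(con))
  if (format == "pdb") {
    writeLines(c(pdb_header(frm$box), pdb_atom_lines(top, frm$coords), "END"),
               con)
  } else {
    writeLines(gro_block(top, frm), con)
  }
  invisible(path)
}

#' Write a multi-model PDB trajectory
#'
#' @param traj a `Trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write to path: ", path)
  on.exit(close(con))
  box <- if (!is.null(traj$box)) traj$box[1L, ] else NULL
  writeLines(pdb_header(box), con)
  for (i in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(pdb_atom_lines(traj$topology, traj$coords[, , i]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

pdb_header <- function(box) {
  if (is.null(box)) return(character())
  sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
          box[1L], box[2L], box[3L], 90, 90, 90)
}

pdb_atom_lines <- function(top, coords) {
  if (any(abs(coords) > 9999.999))
    stop("format overflow: coordinate exceeds PDB fixed columns (9999.999 A)")
  if (any(top$resid > 9999L))
    stop("format overflow: residue id exceeds PDB fixed columns")
  nm <- top$name
  # standard PDB atom-name justification: 1-letter elements start in col 14
  nm4 <- ifelse(nchar(nm) >= 4L, substr(nm, 1L, 4L),
                ifelse(nchar(top$element) == 1L,
                       sprintf(" %-3s", nm), sprintf("%-4s", nm)))
  res4 <- sprintf("%-4s", substr(top$resname, 1L, 4L))
  chain <- substr(paste0(top$chain, " "), 1L, 1L)
  serial <- top$index %% 100000L
  sprintf("ATOM  %5d %s %s%s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nm4, res4, chain, top$resid,
          coords[, 1L], coords[, 2L], coords[, 3L], 1, 0,
          sprintf("%2s", top$element))
}

# -- GRO ---------------------------------------------------------------------
# GROMACS coordinate file; positions stored in nm, converted to/from Angstrom.

gro_block <- function(top, frm, title = "written by nanotraj") {
  xyz <- frm$coords / 10  # Angstrom -> nm
  lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                   top$resid %% 100000L, substr(top$resname, 1L, 5L),
                   substr(top$name, 1L, 5L), top$index %% 100000L,
                   xyz[, 1L], xyz[, 2L], xyz[, 3L])
  box <- if (is.null(frm$box)) c(0, 0, 0) else frm$box / 10
  c(title, sprintf("%5d", nrow(top)), lines,
    sprintf("%10.5f%10.5f%10.5f", box[1L], box[2L], box[3L]))
}

read_gro_file <- function(path, multi, scaffold_chain) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  top <- NULL
  pos <- 1L
  while (pos + 1L <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[pos + 1L])))
    if (is.na(nat) || nat <= 0L)
      stop("GRO parse error at line ", pos + 1L, ": bad atom count")
    if (pos + 1L + nat + 1L > length(lines))
      stop("GRO parse error: file truncated (expected ", nat, " atom lines)")
    al <- lines[pos + 2L:(nat + 1L)]
    short <- which(nchar(al) < 44L)
    if (length(short))
      stop("GRO parse error at line ", pos + 1L + short[1L],
           ": truncated atom line")
    resid <- as.integer(substr(al, 1L, 5L))
    resnm <- trimws(substr(al, 6L, 10L))
    atnm  <- trimws(substr(al, 11L, 15L))
    x <- as.numeric(substr(al, 21L, 28L)) * 10
    y <- as.numeric(substr(al, 29L, 36L)) * 10
    z <- as.numeric(substr(al, 37L, 44L)) * 10
    if (any(is.na(c(x, y, z))))
      stop("GRO parse error: unreadable coordinates in ", path)
    bl <- suppressWarnings(as.numeric(strsplit(trimws(
      lines[pos + nat + 2L]), "\\s+")[[1L]]))
    box <- if (length(bl) >= 3L && all(is.finite(bl[1:3])) &&
               all(bl[1:3] > 0)) bl[1:3] * 10 else NULL
    if (is.null(top)) {
      # GRO carries no chain ids: open a new chain wherever the residue
      # numbering restarts, so the monotonicity invariant is preserved
      brk <- c(TRUE, diff(resid) < 0)
      chain <- LETTERS[pmin(cumsum(brk), 26L)]
      top <- topology(name = atnm, resname = resnm, resid = resid,
                      chain = chain, scaffold_chain = scaffold_chain)
    } else if (nat != nrow(top))
      stop("topology mismatch: frame atom counts differ within ", path)
    frames <- c(frames, list(frame(cbind(x, y, z), box = box)))
    pos <- pos + nat + 3L
    if (!multi) break
    while (pos <= length(lines) && !nzchar(trimws(lines[pos]))) pos <- pos + 1L
    if (pos > length(lines)) break
  }
  if (is.null(top)) stop("empty input: no atoms in ", path)
  list(topology = top, frames = frames)
}

# -- XYZ ---------------------------------------------------------------------
# Plain XYZ frame stream: natoms / comment / "El x y z" lines, Angstrom.

read_xyz_file <- function(path, multi, scaffold_chain) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  top <- NULL
  pos <- 1L
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(nat) || nat <= 0L)
      stop("XYZ parse error at line ", pos, ": bad atom count")
    if (pos + 1L + nat > length(lines))
      stop("XYZ parse error: file truncated")
    al <- strsplit(trimws(lines[pos + 1L + seq_len(nat)]), "\\s+")
    nf <- lengths(al)
    if (any(nf < 4L))
      stop("XYZ parse error at line ", pos + 1L + which(nf < 4L)[1L],
           ": expected 'element x y z'")
    el <- vapply(al, `[`, "", 1L)
    xyz <- t(vapply(al, function(v) as.numeric(v[2:4]), numeric(3L)))
    if (any(is.na(xyz))) stop("XYZ parse error: unreadable coordinates")
    if (is.null(top))
      top <- topology(name = el, resname = "UNK", resid = 1L, chain = "A",
                      element = el, scaffold_chain = scaffold_chain)
    else if (nat != nrow(top))
      stop("topology mismatch: frame atom counts differ within ", path)
    frames <- c(frames, list(frame(xyz)))
    pos <- pos + 2L + nat
    if (!multi) break
  }
  if (is.null(top)) stop("empty input: no atoms in ", path)
  list(topology = top, frames = frames)
}

#' Write a plain XYZ frame stream
#'
#' @param traj a `Trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_xyz <- function(traj, path) {
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write to path: ", path)
  on.exit(close(con))
  for (i in seq_len(n_frames(traj))) {
    writeLines(c(sprintf("%d", n_atoms(traj)), sprintf("frame %d", i),
                 sprintf("%-2s %12.5f %12.5f %12.5f", traj$topology$element,
                         traj$coords[, 1L, i], traj$coords[, 2L, i],
                         traj$coords[, 3L, i])), con)
  }
  invisible(path)
}
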