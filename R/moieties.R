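MOIETY_CLASSES <- c("chain_carbon", "headgroup_carbon", "ester_oxygen",
                    "amine_nitrogen", "phosphate", "carboxylate", "other")
HYDROPHILIC_LIPID_CLASSES <- c("ester_oxygen", "amine_nitrogen", "phosphate",
                               "carboxylate")
HYDROPHOBIC_LIPID_CLASSES <- c("chain_carbon", "headgroup_carbon")

#' Default hydrophobic residue set
#'
#' Residue names whose carbon atoms act as hydrophobic contact probes.  The
#' set is configurable in every function that takes it.
#' @return character vector of residue names.
#' @export
default_hydrophobic <- function() {
  c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP", "PRO")
}

#' Load a lipid moiety classification table
#'
#' The packaged table maps CHARMM36-dialect (residue name, atom-name glob)
#' pairs to one of the moiety classes used for contact resolution:
#' `chain_carbon`, `headgroup_carbon`, `ester_oxygen`, `amine_nitrogen`,
#' `phosphate`, `carboxylate`, `other` (hydrogens).  Rows are matched first
#' to last, so exact names shadow later globs (e.g. glycerol `C2` is a
#' headgroup carbon while `C2*` catches the sn-2 chain carbons `C22`,
#' `C23`, ...).
#'
#' @param path optional path to a user table (TSV with columns
#'   `residue_name`, `atom_name`, `class`); default is the packaged
#'   CHARMM36 table.
#' @return data.frame with the three columns above.
#' @export
moiety_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "charmm36_moieties.tsv",
                        package = "nanotraj", mustWork = TRUE)
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("residue_name", "atom_name", "class")
  if (!all(need %in% names(tb)))
    stop("moiety table must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(tb$class), MOIETY_CLASSES)
  if (length(bad))
    stop("unknown moiety class in table: ", paste(bad, collapse = ", "))
  tb
}

#' Classify lipid atoms into moiety classes
#'
#' Assigns every lipid atom to one of the moiety classes via the
#' (residue name, atom-name glob) table.  Hydrogens fall in class `other`
#' and are excluded from default contact counting; any unmatched heavy atom
#' is an error, as is a lipid residue name absent from the table.
#'
#' @param top a `Topology`.
#' @param dialect atom-name dialect; only `"charmm36"` is shipped.
#' @param table optional override table (see [moiety_table()]).
#' @return a `MoietyAssignment`: list with `lipid_class` (character vector,
#'   `NA` for non-lipid atoms), `protein_class` (filled by
#'   [assign_protein_classes()]), and the table used.
#' @export
assign_lipid_moieties <- function(top, dialect = "charmm36", table = NULL) {
  dialect <- match.arg(dialect, "charmm36")
  tb <- if (is.null(table)) moiety_table() else table
  lip <- which(top$segment == "lipid")
  cls <- rep(NA_character_, nrow(top))
  if (length(lip)) {
    unknown <- setdiff(unique(top$resname[lip]), unique(tb$residue_name))
    if (length(unknown))
      stop("unsupported lipid residue(s): ", paste(unknown, collapse = ", "),
           " (extend the moiety table to add them)")
    for (rn in unique(top$resname[lip])) {
      rows <- tb[tb$residue_name == rn, , drop = FALSE]
      idx <- lip[top$resname[lip] == rn]
      nm <- top$name[idx]
      assigned <- rep(NA_character_, length(idx))
      for (k in seq_len(nrow(rows))) {
        hit <- is.na(assigned) &
          grepl(utils::glob2rx(rows$atom_name[k]), nm)
        assigned[hit] <- rows$class[k]
      }
      miss <- which(is.na(assigned) & top$element[idx] != "H")
      if (length(miss))
        stop("unclassified heavy lipid atom(s) in ", rn, ": ",
             paste(unique(nm[miss]), collapse = ", "))
      assigned[is.na(assigned)] <- "other"
      cls[idx] <- assigned
    }
  }
  structure(list(lipid_class = cls,
                 protein_class = rep(NA_character_, nrow(top)),
                 table = tb),
            class = "MoietyAssignment")
}

#' Classify protein atoms into contact probe classes
#'
#' Every protein nitrogen and oxygen becomes a `hydrophilic_probe`; every
#' carbon of a residue in `hydrophobic_residues` becomes a
#' `hydrophobic_probe`; all other protein atoms are `none`.
#'
#' @param top a `Topology`.
#' @param hydrophobic_residues residue-name set (default
#'   [default_hydrophobic()]).
#' @param assignment optional existing `MoietyAssignment` to fill in place.
#' @return a `MoietyAssignment` with `protein_class` populated.
#' @export
assign_protein_classes <- function(top,
                                   hydrophobic_residues = default_hydrophobic(),
                                   assignment = NULL) {
  pro <- which(top$segment == "protein")
  if (!length(pro)) stop("empty selection: no protein atoms in topology")
  pc <- rep(NA_character_, nrow(top))
  pc[pro] <- "none"
  pc[pro][top$element[pro] %in% c("N", "O")] <- "hydrophilic_probe"
  hyd <- top$element[pro] == "C" & top$resname[pro] %in% hydrophobic_residues
  pc[pro][hyd] <- "hydrophobic_probe"
  if (is.null(assignment))
    assignment <- structure(list(lipid_class = rep(NA_character_, nrow(top)),
                                 protein_class = pc, table = NULL),
                            class = "MoietyAssignment")
  else assignment$protein_class <- pc
  assignment
}

#' Full moiety assignment (lipid + protein)
#'
#' Convenience wrapper running [assign_lipid_moieties()] then
#' [assign_protein_classes()].
#'
#' @inheritParams assign_lipid_moieties
#' @inheritParams assign_protein_classes
#' @return a `MoietyAssignment`.
#' @export
assign_moieties <- function(top, dialect = "charmm36", table = NULL,
                            hydrophobic_residues = default_hydrophobic()) {
  ma <- assign_lipid_moieties(top, dialect, table)
  assign_protein_classes(top, hydrophobic_residues, ma)
}

#' @export
print.MoietyAssignment <- function(x, ...) {
  lc <- table(x$lipid_class[!is.na(x$lipid_class)])
  pc <- table(x$protein_class[!is.na(x$protein_class)])
  cat("MoietyAssignment\n  lipid:  ",
      paste(sprintf("%s=%d", names(lc), lc), collapse = ", "), "\n",
      " protein:", paste(sprintf("%s=%d", names(pc), pc), collapse = ", "),
      "\n")
  invisible(x)
}
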