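#' Select atoms with a selection expression
#'
#' A small selection mini-language over a [topology()]:
#'
#' * `resid 2021-2170 2200` — residue ids and inclusive ranges
#' * `resname ARG DOPS` — residue names
#' * `name NH1 NH2 NE` — atom names
#' * `element N O` — element symbols
#' * `chain A` — chain ids
#' * bare keywords `protein`, `lipid`, `scaffold`, `solvent`, `ion`,
#'   `all`, `none`, `hydrogen`, `noh`
#' * boolean `and`, `or`, `not` and parentheses; `and` binds tighter than
#'   `or`.
#'
#' Example: `"resid 2021-2170 and protein and not hydrogen"`.
#'
#' @param top a `Topology`.
#' @param expr selection string.
#' @return sorted, duplicate-free integer vector of 1-based atom indices.
#' @export
select <- function(top, expr) {
  stopifnot(inherits(top, "Topology"))
  mask <- selection_mask(top, expr)
  which(mask)
}

selection_mask <- function(top, expr) {
  toks <- tokenize_selection(expr)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  mask <- parse_or(st, top)
  if (st$pos <= nrow(st$toks))
    sel_error(st, "unexpected token")
  mask
}

tokenize_selection <- function(expr) {
  if (!is.character(expr) || length(expr) != 1L || !nzchar(trimws(expr)))
    stop("selection syntax error: empty expression")
  pat <- "\\(|\\)|[^\\s()]+"
  m <- gregexpr(pat, expr, perl = TRUE)[[1L]]
  if (m[1L] == -1L) stop("selection syntax error: empty expression")
  tok <- regmatches(expr, gregexpr(pat, expr, perl = TRUE))[[1L]]
  data.frame(tok = tok, pos = as.integer(m), stringsAsFactors = FALSE)
}

sel_peek <- function(st) if (st$pos <= nrow(st$toks)) st$toks$tok[st$pos] else NA_character_
sel_next <- function(st) { t <- sel_peek(st); st$pos <- st$pos + 1L; t }
sel_error <- function(st, msg) {
  at <- if (st$pos <= nrow(st$toks))
    paste0("'", st$toks$tok[st$pos], "' at position ", st$toks$pos[st$pos])
  else "end of expression"
  stop("selection syntax error: ", msg, " (", at, ")")
}

SEL_KEYWORDS <- c("protein", "lipid", "scaffold", "solvent", "ion", "all",
                  "none", "hydrogen", "noh")
SEL_FIELDS <- c("resid", "resname", "name", "element", "chain")
SEL_RESERVED <- c(SEL_KEYWORDS, SEL_FIELDS, "and", "or", "not", "(", ")")

parse_or <- function(st, top) {
  m <- parse_and(st, top)
  while (!is.na(sel_peek(st)) && sel_peek(st) == "or") {
    sel_next(st)
    m <- m | parse_and(st, top)
  }
  m
}

parse_and <- function(st, top) {
  m <- parse_not(st, top)
  while (!is.na(sel_peek(st)) && sel_peek(st) == "and") {
    sel_next(st)
    m <- m & parse_not(st, top)
  }
  m
}

parse_not <- function(st, top) {
  if (!is.na(sel_peek(st)) && sel_peek(st) == "not") {
    sel_next(st)
    return(!parse_not(st, top))
  }
  parse_primary(st, top)
}

parse_primary <- function(st, top) {
  t <- sel_peek(st)
  if (is.na(t)) sel_error(st, "expected a selection term")
  if (t == "(") {
    sel_next(st)
    m <- parse_or(st, top)
    if (is.na(sel_peek(st)) || sel_peek(st) != ")")
      sel_error(st, "expected ')'")
    sel_next(st)
    return(m)
  }
  if (t %in% SEL_KEYWORDS) {
    sel_next(st)
    return(switch(t,
      protein  = top$segment == "protein",
      lipid    = top$segment == "lipid",
      scaffold = top$segment == "scaffold",
      solvent  = top$segment == "solvent",
      ion      = top$segment == "ion",
      all      = rep(TRUE, nrow(top)),
      none     = rep(FALSE, nrow(top)),
      hydrogen = top$element == "H",
      noh      = top$element != "H"))
  }
  if (t %in% SEL_FIELDS) {
    sel_next(st)
    vals <- character()
    while (!is.na(sel_peek(st)) && !(sel_peek(st) %in% SEL_RESERVED)) {
      vals <- c(vals, sel_next(st))
    }
    if (!length(vals)) sel_error(st, paste0("'", t, "' needs at least one value"))
    return(field_mask(st, top, t, vals))
  }
  sel_error(st, "unknown token")
}

field_mask <- function(st, top, field, vals) {
  if (field == "resid") {
    m <- rep(FALSE, nrow(top))
    for (v in vals) {
      if (grepl("^-?[0-9]+--?[0-9]+$", v) || grepl("^[0-9]+-[0-9]+$", v)) {
        parts <- regmatches(v, regexec("^(-?[0-9]+)-(-?[0-9]+)$", v))[[1L]]
        lo <- as.integer(parts[2L]); hi <- as.integer(parts[3L])
        if (is.na(lo) || is.na(hi) || lo > hi)
          sel_error(st, paste0("bad resid range '", v, "'"))
        m <- m | (top$resid >= lo & top$resid <= hi)
      } else if (grepl("^-?[0-9]+$", v)) {
        m <- m | top$resid == as.integer(v)
      } else {
        sel_error(st, paste0("bad resid value '", v, "'"))
      }
    }
    return(m)
  }
  col <- switch(field, resname = top$resname, name = top$name,
                element = top$element, chain = top$chain)
  col %in% vals
}
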