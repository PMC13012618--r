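# Atom selection mini-grammar.
#
# Grammar (documented in README):
#   expr      := term ("or" term)*
#   term      := factor ("and" factor)*
#   factor    := "not" factor | "(" expr ")" | primitive
#   primitive := "resid" range+ | "resname" NAME+ | "name" NAME+
#              | "chain" ID+ | "backbone" | "heavy" | "calpha"
#              | "protein" | "all"
#   range     := INT | INT "-" INT
#
# Selections are pure functions of (topology, expression); unknown names and
# empty residue ranges raise errors rather than returning empty results.

.sel_keywords <- c("resid", "resname", "name", "chain", "backbone", "heavy",
                   "calpha", "protein", "all", "and", "or", "not", "(", ")")

#' Select atoms by expression
#'
#' Evaluates a selection expression against a topology and returns a
#' deterministic, order-preserving [atom_selection()]. Ranges such as
#' `"resid 40-115 and backbone"` mirror the spans used to define protein
#' subdomains.
#'
#' @param top a `topology`
#' @param expression selection string (see grammar in README)
#' @return an `atom_selection`
#' @examples
#' top <- topology(name = c("N", "CA", "C"), resid = c(1, 1, 1),
#'                 resname = c("ALA", "ALA", "ALA"))
#' select_atoms(top, "calpha")
#' @export
select_atoms <- function(top, expression) {
  tokens <- .sel_tokenize(expression)
  st <- new.env(parent = emptyenv())
  st$tokens <- tokens
  st$pos <- 1L
  mask <- .sel_expr(st, top)
  if (st$pos <= length(st$tokens))
    stop("selection syntax error near '", st$tokens[st$pos], "'")
  atom_selection(which(mask), top, expression)
}

.sel_tokenize <- function(expression) {
  if (!is.character(expression) || length(expression) != 1)
    stop("selection expression must be a single string")
  s <- gsub("([()])", " \\1 ", expression)
  tokens <- strsplit(trimws(s), "\\s+")[[1]]
  if (length(tokens) == 0) stop("empty selection expression")
  tokens
}

.sel_peek <- function(st) {
  if (st$pos > length(st$tokens)) NA_character_ else st$tokens[st$pos]
}

.sel_next <- function(st) {
  tok <- .sel_peek(st)
  st$pos <- st$pos + 1L
  tok
}

.sel_expr <- function(st, top) {
  mask <- .sel_term(st, top)
  while (!is.na(.sel_peek(st)) && .sel_peek(st) == "or") {
    .sel_next(st)
    mask <- mask | .sel_term(st, top)
  }
  mask
}

.sel_term <- function(st, top) {
  mask <- .sel_factor(st, top)
  while (!is.na(.sel_peek(st)) && .sel_peek(st) == "and") {
    .sel_next(st)
    mask <- mask & .sel_factor(st, top)
  }
  mask
}

.sel_factor <- function(st, top) {
  tok <- .sel_peek(st)
  if (is.na(tok)) stop("selection syntax error: unexpected end of expression")
  if (tok == "not") {
    .sel_next(st)
    return(!.sel_factor(st, top))
  }
  if (tok == "(") {
    .sel_next(st)
    mask <- .sel_expr(st, top)
    if (is.na(.sel_peek(st)) || .sel_peek(st) != ")")
      stop("selection syntax error: missing ')'")
    .sel_next(st)
    return(mask)
  }
  .sel_primitive(st, top)
}

.sel_primitive <- function(st, top) {
  tok <- .sel_next(st)
  at <- top$atoms
  switch(tok,
    backbone = at$backbone,
    heavy = at$heavy,
    calpha = at$name == "CA" & at$resname != "CA",
    protein = at$resname %in% .protein_resnames,
    all = rep(TRUE, nrow(at)),
    resid = .sel_resid(st, top),
    resname = .sel_names(st, top, "resname"),
    name = .sel_names(st, top, "name"),
    chain = .sel_names(st, top, "chain"),
    stop("selection syntax error: unexpected token '", tok, "'")
  )
}

.protein_resnames <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU",
                       "GLY", "HIS", "HSD", "HSE", "ILE", "LEU", "LYS",
                       "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR",
                       "VAL")

.sel_resid <- function(st, top) {
  at <- top$atoms
  mask <- rep(FALSE, nrow(at))
  got <- FALSE
  while (!is.na(.sel_peek(st)) && grepl("^[0-9]+(-[0-9]+)?$", .sel_peek(st))) {
    tok <- .sel_next(st)
    got <- TRUE
    if (grepl("-", tok)) {
      lohi <- as.integer(strsplit(tok, "-")[[1]])
      if (lohi[1] > lohi[2])
        stop("selection syntax error: empty residue range '", tok, "'")
      hit <- at$resid >= lohi[1] & at$resid <= lohi[2]
    } else {
      hit <- at$resid == as.integer(tok)
    }
    if (!any(hit)) stop("unknown residue id '", tok, "' in selection")
    mask <- mask | hit
  }
  if (!got) stop("selection syntax error: 'resid' needs at least one range")
  mask
}

.sel_names <- function(st, top, field) {
  at <- top$atoms
  mask <- rep(FALSE, nrow(at))
  got <- FALSE
  while (!is.na(.sel_peek(st)) && !(.sel_peek(st) %in% .sel_keywords)) {
    tok <- .sel_next(st)
    got <- TRUE
    hit <- at[[field]] == tok
    if (!any(hit)) stop("unknown ", field, " '", tok, "' in selection")
    mask <- mask | hit
  }
  if (!got) stop("selection syntax error: '", field, "' needs a value")
  mask
}
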