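# Predicate-based atom selection with a small expression grammar:
#   clause  := "resid" items | "name" words | "chain" words | "bead" | "atom"
#   items   := (N | N-M)+        (inclusive residue ranges)
#   expr    := clause (("and"|"or") clause)* , with "(" ")" grouping
# Selection never looks at coordinates.

#' Select atoms by a selection expression
#'
#' Supported clauses: `resid <n>`/`resid <a>-<b>` (inclusive, possibly
#' several), `name <names...>`, `chain <ids...>`, `resname <names...>`,
#' `bead`/`atom`, combined with `and`, `or` and parentheses.  Matching is
#' purely predicate-based (residue ids, names, chains); coordinates are
#' never consulted.
#'
#' @param s a [structure3d()] object
#' @param expr selection string, e.g. `"resid 710-724 and name CA"`
#' @return integer atom indices in ascending order (possibly empty)
#' @export
#' @examples
#' s <- structure3d(data.frame(name = c("CA", "CB"), res_id = c(1, 1)),
#'                  matrix(0, 2, 3))
#' select_atoms(s, "name CA")
select_atoms <- function(s, expr) {
  toks <- .sel_tokens(expr)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  mask <- .sel_or(st, s)
  if (st$pos <= length(st$toks))
    stop("selection syntax error: unexpected token '", st$toks[st$pos], "'")
  which(mask)
}

.sel_tokens <- function(expr) {
  if (!is.character(expr) || length(expr) != 1)
    stop("selection expression must be a single string")
  expr <- gsub("\\(", " ( ", expr)
  expr <- gsub("\\)", " ) ", expr)
  toks <- strsplit(trimws(expr), "\\s+")[[1]]
  if (length(toks) == 0) stop("selection syntax error: empty expression")
  toks
}

.sel_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

.sel_or <- function(st, s) {
  mask <- .sel_and(st, s)
  while (!is.na(.sel_peek(st)) && tolower(.sel_peek(st)) == "or") {
    st$pos <- st$pos + 1L
    mask <- mask | .sel_and(st, s)
  }
  mask
}

.sel_and <- function(st, s) {
  mask <- .sel_term(st, s)
  while (!is.na(.sel_peek(st)) && tolower(.sel_peek(st)) == "and") {
    st$pos <- st$pos + 1L
    mask <- mask & .sel_term(st, s)
  }
  mask
}

.sel_term <- function(st, s) {
  tok <- .sel_peek(st)
  if (is.na(tok)) stop("selection syntax error: unexpected end of expression")
  if (tok == "(") {
    st$pos <- st$pos + 1L
    mask <- .sel_or(st, s)
    if (is.na(.sel_peek(st)) || .sel_peek(st) != ")")
      stop("selection syntax error: missing ')'")
    st$pos <- st$pos + 1L
    return(mask)
  }
  if (tolower(tok) == "not") {
    st$pos <- st$pos + 1L
    return(!.sel_term(st, s))
  }
  st$pos <- st$pos + 1L
  kw <- tolower(tok)
  if (kw == "bead") return(s$atoms$is_bead)
  if (kw == "atom") return(!s$atoms$is_bead)
  args <- character(0)
  while (!is.na(.sel_peek(st)) &&
         !(tolower(.sel_peek(st)) %in% c("and", "or", "not")) &&
         !(.sel_peek(st) %in% c("(", ")"))) {
    args <- c(args, st$toks[st$pos])
    st$pos <- st$pos + 1L
  }
  if (length(args) == 0)
    stop("selection syntax error: clause '", kw, "' needs arguments")
  switch(kw,
    resid = {
      mask <- rep(FALSE, nrow(s$atoms))
      for (a in args) {
        if (grepl("^-?[0-9]+--?[0-9]+$", a)) {
          m <- regmatches(a, regexec("^(-?[0-9]+)-(-?[0-9]+)$", a))[[1]]
          lo <- as.integer(m[2]); hi <- as.integer(m[3])
          if (lo > hi) stop("selection syntax error: bad range '", a, "'")
          mask <- mask | (s$atoms$res_id >= lo & s$atoms$res_id <= hi)
        } else if (grepl("^-?[0-9]+$", a)) {
          mask <- mask | (s$atoms$res_id == as.integer(a))
        } else stop("selection syntax error: bad resid item '", a, "'")
      }
      mask
    },
    name = s$atoms$name %in% args,
    resname = s$atoms$res_name %in% args,
    chain = s$atoms$chain %in% args,
    stop("selection syntax error: unknown clause '", kw, "'")
  )
}
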