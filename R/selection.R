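## Atom-selection mini-language.
##
## Grammar (keywords are case-sensitive, tokens whitespace-separated):
##   expr     := and_expr ( "or" and_expr )*
##   and_expr := unary ( "and" unary )*
##   unary    := "not" unary | primary
##   primary  := "(" expr ")"
##             | "all" | "protein" | "nucleic"
##             | "name" <ident>+ | "resname" <ident>+ | "chain" <ident>+
##             | "resid" range ( range )*        range := N | N "to" M
##             | "within" <R> "of" unary
## "within R of S" selects every atom (including S itself) whose distance to
## any atom of S is <= R (closed ball), evaluated on a designated reference
## frame -- typically the crystal structure.

NUCLEIC_RESNAMES <- c("A", "U", "G", "C", "I", "DA", "DT", "DG", "DC",
                      "ADE", "URA", "GUA", "CYT", "THY", "RA", "RU",
                      "RG", "RC")

sel_tokenize <- function(expression) {
  s <- gsub("\\(", " ( ", expression)
  s <- gsub("\\)", " ) ", s)
  toks <- strsplit(trimws(s), "\\s+")[[1]]
  toks[nzchar(toks)]
}

## Recursive-descent parser over a token stream held in a mutable
## environment; every rule returns a logical mask over atoms.
sel_parse <- function(tokens, atoms, refxyz) {
  env <- new.env(parent = emptyenv())
  env$toks <- tokens
  env$pos <- 1L
  peek <- function() if (env$pos <= length(env$toks)) env$toks[env$pos] else NA
  advance <- function() {
    t <- peek(); env$pos <- env$pos + 1L; t
  }
  expect <- function(what) {
    t <- advance()
    if (is.na(t) || t != what)
      stop(sprintf("selection syntax error: expected '%s', got '%s'",
                   what, ifelse(is.na(t), "<end>", t)))
    t
  }
  is_kw <- function(t) t %in% c("and", "or", "not", "name", "resname",
                                "chain", "resid", "within", "of", "to",
                                "all", "protein", "nucleic", "(", ")")
  take_idents <- function() {
    out <- character()
    while (!is.na(peek()) && !is_kw(peek())) out <- c(out, advance())
    if (!length(out))
      stop(sprintf("selection syntax error: value list expected near '%s'",
                   ifelse(is.na(peek()), "<end>", peek())))
    out
  }

  p_expr <- function() {
    m <- p_and()
    while (!is.na(peek()) && peek() == "or") {
      advance(); m <- m | p_and()
    }
    m
  }
  p_and <- function() {
    m <- p_unary()
    while (!is.na(peek()) && peek() == "and") {
      advance(); m <- m & p_unary()
    }
    m
  }
  p_unary <- function() {
    if (!is.na(peek()) && peek() == "not") {
      advance(); return(!p_unary())
    }
    p_primary()
  }
  p_primary <- function() {
    t <- advance()
    if (is.na(t)) stop("selection syntax error: unexpected end of expression")
    switch(t,
      "(" = { m <- p_expr(); expect(")"); m },
      "all" = rep(TRUE, nrow(atoms)),
      "protein" = !(atoms$residue_name %in% NUCLEIC_RESNAMES),
      "nucleic" = atoms$residue_name %in% NUCLEIC_RESNAMES,
      "name" = atoms$atom_name %in% take_idents(),
      "resname" = atoms$residue_name %in% take_idents(),
      "chain" = atoms$chain_id %in% take_idents(),
      "resid" = {
        m <- rep(FALSE, nrow(atoms))
        repeat {
          v <- suppressWarnings(as.integer(peek()))
          if (is.na(v)) break
          advance()
          if (!is.na(peek()) && peek() == "to") {
            advance()
            hi <- suppressWarnings(as.integer(advance()))
            if (is.na(hi)) stop("selection syntax error: bad resid range")
            m <- m | (atoms$residue_seq >= v & atoms$residue_seq <= hi)
          } else m <- m | (atoms$residue_seq == v)
        }
        if (!any(m) && all(!m) && env$pos == 1L)
          stop("selection syntax error: resid needs at least one number")
        m
      },
      "within" = {
        r <- suppressWarnings(as.numeric(advance()))
        if (is.na(r)) stop("selection syntax error: within needs a distance")
        expect("of")
        inner <- p_unary()
        if (!any(inner)) return(rep(FALSE, nrow(atoms)))
        ref <- refxyz[inner, , drop = FALSE]
        d2min <- min_dist2_to_set(refxyz, ref)
        d2min <= r * r + 1e-12
      },
      stop(sprintf("selection syntax error: unexpected token '%s'", t))
    )
  }

  m <- p_expr()
  if (!is.na(peek()))
    stop(sprintf("selection syntax error: trailing token '%s'", peek()))
  m
}

## squared distance from every row of X to the nearest row of S
min_dist2_to_set <- function(X, S) {
  ns <- nrow(S)
  d2 <- rep(Inf, nrow(X))
  ## chunk over the (usually small) set S to stay vectorised
  for (k in seq_len(ns)) {
    dd <- (X[, 1] - S[k, 1])^2 + (X[, 2] - S[k, 2])^2 + (X[, 3] - S[k, 3])^2
    d2 <- pmin(d2, dd)
  }
  d2
}

#' Resolve an atom selection expression
#'
#' Evaluates the selection mini-language (see Details) against a structure's
#' atom table, returning a deterministic, sorted, duplicate-free set of
#' 0-based atom ids.  `"within R of ..."` clauses are closed balls
#' (distance <= R) evaluated on `reference_coords`, by default the
#' structure's own coordinates (the crystal reference).
#'
#' @details Supported clauses: `all`, `protein`, `nucleic`,
#' `name <n>...`, `resname <n>...`, `chain <c>...`,
#' `resid <a> [to <b>] ...`, `within <R> of <sel>`, combined with
#' `and`, `or`, `not` and parentheses.
#'
#' @param structure `Structure`.
#' @param expression selection string.
#' @param reference_coords n x 3 matrix used for `within` distances
#'   (defaults to the structure coordinates).
#' @return Object of class `"AtomSelection"`: list with `expression` and
#'   sorted 0-based `ids`.  An empty result is returned (with a warning),
#'   not an error.
#' @export
select_atoms <- function(structure, expression,
                         reference_coords = structure$xyz) {
  stopifnot(inherits(structure, "Structure"))
  toks <- sel_tokenize(expression)
  if (!length(toks)) stop("empty selection expression")
  mask <- sel_parse(toks, structure$atoms, as.matrix(reference_coords))
  ids <- structure$atoms$atom_id[mask]
  if (!length(ids))
    warning(sprintf("selection '%s' matched no atoms", expression))
  structure(list(expression = expression, ids = sort(unique(ids))),
            class = "AtomSelection")
}

## Accept an AtomSelection, integer 0-based ids, or NULL (= all atoms);
## return 1-based row indices into the atom table.
sel_index <- function(selection, structure) {
  n <- n_atoms(structure)
  if (is.null(selection)) return(seq_len(n))
  ids <- if (inherits(selection, "AtomSelection")) selection$ids
         else as.integer(selection)
  if (any(ids < 0L) || any(ids >= n)) stop("selection ids outside topology")
  sort(unique(ids)) + 1L
}

#' @export
print.AtomSelection <- function(x, ...) {
  cat(sprintf("AtomSelection '%s': %d atoms\n", x$expression, length(x$ids)))
  invisible(x)
}
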