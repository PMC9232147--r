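#' Boolean guard formulas over entity identifiers
#'
#' A guard is the Boolean condition attached to a guarded transition: a
#' formula over entity identifiers built from \code{and}, \code{or},
#' \code{not}, atoms and the constant \code{TRUE}. Guards are represented as
#' plain recursive lists with an \code{op} field, one of \code{"true"},
#' \code{"atom"}, \code{"not"}, \code{"and"}, \code{"or"}; \code{atom} nodes
#' carry \code{id}, the others carry \code{args} (a list of sub-guards,
#' exactly one for \code{not}, at least two for \code{and}/\code{or}).
#'
#' @param id entity identifier (single character string).
#' @param ... sub-guards (guard objects or entity-id strings, which are
#'   promoted to atoms).
#' @return A guard object (classed list, class \code{"gtGuard"}).
#' @examples
#' g <- gtAnd("A", gtOr("P", "L", "K"), gtNot("M"))
#' formulaToString(g)
#' guardAtoms(g)
#' @name guards
NULL

newGuard <- function(op, args = NULL, id = NULL) {
  structure(list(op = op, args = args, id = id), class = "gtGuard")
}

asGuard <- function(x) {
  if (inherits(x, "gtGuard")) return(x)
  if (is.character(x) && length(x) == 1L) return(gtAtom(x))
  if (isTRUE(x)) return(gtTrue())
  stop("cannot interpret object of class '", class(x)[1L], "' as a guard")
}

#' @rdname guards
#' @export
gtTrue <- function() newGuard("true")

#' @rdname guards
#' @export
gtAtom <- function(id) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  newGuard("atom", id = id)
}

#' @rdname guards
#' @export
gtNot <- function(...) {
  args <- lapply(list(...), asGuard)
  if (length(args) != 1L) stop("'not' takes exactly one sub-guard")
  newGuard("not", args = args)
}

#' @rdname guards
#' @export
gtAnd <- function(...) {
  args <- lapply(list(...), asGuard)
  if (length(args) == 0L) return(gtTrue())
  if (length(args) == 1L) return(args[[1L]])
  newGuard("and", args = args)
}

#' @rdname guards
#' @export
gtOr <- function(...) {
  args <- lapply(list(...), asGuard)
  if (length(args) == 0L) stop("'or' needs at least one sub-guard")
  if (length(args) == 1L) return(args[[1L]])
  newGuard("or", args = args)
}

#' Atoms referenced by a guard
#'
#' @param guard a guard object.
#' @return Character vector of entity ids occurring in the formula (sorted,
#'   unique).
#' @export
guardAtoms <- function(guard) {
  rec <- function(g) switch(g$op,
    true = character(0),
    atom = g$id,
    unlist(lapply(g$args, rec), use.names = FALSE)
  )
  sort(unique(rec(asGuard(guard))))
}

#' Evaluate a guard against a Boolean state
#'
#' Evaluation is total: atoms absent from \code{state} evaluate to
#' \code{FALSE}.
#'
#' @param guard a guard object.
#' @param state named logical vector, or a character vector of active entity
#'   ids.
#' @return Logical scalar.
#' @export
guardEval <- function(guard, state) {
  if (is.character(state)) {
    active <- state
  } else {
    active <- names(state)[as.logical(state)]
  }
  rec <- function(g) switch(g$op,
    true = TRUE,
    atom = g$id %in% active,
    not  = !rec(g$args[[1L]]),
    and  = all(vapply(g$args, rec, logical(1))),
    or   = any(vapply(g$args, rec, logical(1)))
  )
  rec(asGuard(guard))
}

#' Flatten nested and/or and drop redundant TRUE conjuncts
#'
#' No further Boolean minimisation is performed, so guards remain auditable
#' against their source interactions.
#'
#' @param guard a guard object.
#' @return Simplified guard.
#' @export
simplifyGuard <- function(guard) {
  g <- asGuard(guard)
  if (g$op %in% c("true", "atom")) return(g)
  args <- lapply(g$args, simplifyGuard)
  if (g$op == "not") return(newGuard("not", args = args))
  flat <- list()
  for (a in args) {
    if (a$op == g$op) flat <- c(flat, a$args)
    else if (g$op == "and" && a$op == "true") next
    else flat <- c(flat, list(a))
  }
  if (length(flat) == 0L) return(gtTrue())
  # dedupe syntactically identical children, keep first occurrence
  keys <- vapply(flat, formulaToString, character(1))
  flat <- flat[!duplicated(keys)]
  if (length(flat) == 1L) return(flat[[1L]])
  newGuard(g$op, args = flat)
}

#' Serialise a guard to / from prefix-notation lists
#'
#' The native model format stores guards as nested prefix arrays, e.g.
#' \code{["and","A",["or","P","L","K"],["not","M"]]}; a bare string is an
#' atom and \code{["true"]} is the constant TRUE.
#'
#' @param guard a guard object.
#' @param x a nested list / character as read back from JSON.
#' @return \code{guardToPrefix}: nested list; \code{prefixToGuard}: guard.
#' @export
guardToPrefix <- function(guard) {
  g <- asGuard(guard)
  switch(g$op,
    true = list("true"),
    atom = g$id,
    c(list(g$op), lapply(g$args, guardToPrefix))
  )
}

#' @rdname guardToPrefix
#' @export
prefixToGuard <- function(x) {
  if (is.character(x) && length(x) == 1L) return(gtAtom(x))
  x <- as.list(x)
  if (length(x) == 1L && identical(x[[1L]], "true")) return(gtTrue())
  op <- x[[1L]]
  if (!is.character(op) || !op %in% c("and", "or", "not"))
    stop("malformed prefix guard: unknown operator ", deparse(op))
  args <- lapply(x[-1L], prefixToGuard)
  switch(op,
    "not" = { if (length(args) != 1L) stop("'not' takes one argument")
              newGuard("not", args = args) },
    "and" = do.call(gtAnd, args),
    "or"  = do.call(gtOr, args))
}

#' Render a guard in the query mini-language
#'
#' The mini-language has identifiers, \code{and}, \code{or}, \code{not} and
#' parentheses; \code{parseFormula} and \code{formulaToString} round-trip.
#'
#' @param guard a guard object.
#' @return Character scalar.
#' @export
formulaToString <- function(guard) {
  g <- asGuard(guard)
  rec <- function(g, parentOp) {
    s <- switch(g$op,
      true = "true",
      atom = g$id,
      not  = paste0("not ", rec(g$args[[1L]], "not")),
      {
        body <- paste(vapply(g$args, rec, character(1), g$op),
                      collapse = paste0(" ", g$op, " "))
        body
      })
    needParen <- switch(g$op,
      "and" = parentOp %in% c("not", "or"),
      "or"  = parentOp %in% c("not", "and"),
      FALSE)
    if (needParen) paste0("(", s, ")") else s
  }
  rec(g, "")
}

#' Parse a phenotype formula
#'
#' Grammar (lowest to highest precedence):
#' \preformatted{
#'   formula := term ("or" term)*
#'   term    := factor ("and" factor)*
#'   factor  := "not" factor | "(" formula ")" | identifier | "true" | "false"
#' }
#' Identifiers match \code{[A-Za-z0-9_.:/-]+} excluding the reserved words.
#'
#' @param text formula string, e.g. \code{"C and not J"}.
#' @return A guard object.
#' @export
parseFormula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- regmatches(text, gregexpr("[A-Za-z0-9_.:/-]+|\\(|\\)", text))[[1L]]
  leftover <- gsub("\\s+", "", text)
  for (t in toks) leftover <- sub(t, "", leftover, fixed = TRUE)
  if (nzchar(leftover))
    stop("unexpected character(s) in formula: ", leftover)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  factor_ <- function() {
    t <- peek()
    if (is.na(t)) stop("formula ended unexpectedly")
    if (t == "not") { advance(); return(gtNot(factor_())) }
    if (t == "(") {
      advance()
      f <- formula_()
      if (!identical(peek(), ")")) stop("missing closing parenthesis")
      advance()
      return(f)
    }
    if (t %in% c(")", "and", "or")) stop("unexpected token '", t, "'")
    advance()
    if (t == "true") gtTrue() else if (t == "false") gtNot(gtTrue())
    else gtAtom(t)
  }
  term_ <- function() {
    parts <- list(factor_())
    while (identical(peek(), "and")) { advance(); parts <- c(parts, list(factor_())) }
    do.call(gtAnd, parts)
  }
  formula_ <- function() {
    parts <- list(term_())
    while (identical(peek(), "or")) { advance(); parts <- c(parts, list(term_())) }
    do.call(gtOr, parts)
  }
  out <- formula_()
  if (!is.na(peek())) stop("trailing tokens after formula: '", peek(), "'")
  out
}

#' Negation normal form
#'
#' Pushes negations to the atoms. Used by the query encoder, where negative
#' literals are enforced over the whole trajectory.
#'
#' @param guard a guard object.
#' @param negate internal recursion flag.
#' @return Guard in negation normal form (NOT only over atoms or TRUE).
#' @keywords internal
guardNNF <- function(guard, negate = FALSE) {
  g <- asGuard(guard)
  switch(g$op,
    true = if (negate) newGuard("not", args = list(gtTrue())) else g,
    atom = if (negate) newGuard("not", args = list(g)) else g,
    not  = guardNNF(g$args[[1L]], !negate),
    and  = {
      args <- lapply(g$args, guardNNF, negate = negate)
      newGuard(if (negate) "or" else "and", args = args)
    },
    or   = {
      args <- lapply(g$args, guardNNF, negate = negate)
      newGuard(if (negate) "and" else "or", args = args)
    })
}

#' @export
print.gtGuard <- function(x, ...) {
  cat("<guard> ", formulaToString(x), "\n", sep = "")
  invisible(x)
}
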