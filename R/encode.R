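#' Low-level SAT interface
#'
#' Solves a CNF formula with the package's built-in DPLL solver. Clauses are
#' integer vectors of non-zero DIMACS-style literals (\code{+v} / \code{-v}).
#' Branching tries \code{FALSE} first in a deterministic variable order, so
#' repeated calls are reproducible and solutions favour small activation
#' sets.
#'
#' @param nvars number of variables (ids \code{1..nvars}).
#' @param clauses list of integer literal vectors.
#' @param assumptions integer vector of literals fixed before search.
#' @param varOrder integer vector of variables to branch on first.
#' @return List with \code{sat} (logical) and \code{model} (logical vector
#'   of length \code{nvars}, or \code{NULL} when unsatisfiable).
#' @export
satSolve <- function(nvars, clauses, assumptions = integer(0),
                     varOrder = integer(0)) {
  .sat_solve_cpp(as.integer(nvars),
                 lapply(clauses, as.integer),
                 as.integer(assumptions), as.integer(varOrder))
}

#' Encode the bounded unfolding of a model as CNF
#'
#' Builds the propositional constraint system whose satisfying assignments
#' correspond one-to-one with legal trajectories of length \code{horizon}
#' that reach the query. Variables are \code{place(p, t)} for
#' \code{t = 0..horizon} (entity \code{p} active at step \code{t}) and
#' \code{fire(h, t)} for \code{t = 0..horizon-1} (event \code{h} fires at
#' step \code{t}); guard formulas and the frame/update rule are translated
#' with Tseitin auxiliary variables. The encoding asserts:
#' \itemize{
#' \item reactive firing: \code{fire(h,t)} holds iff every transition of
#'   \code{h} has an active input and a satisfied guard at \code{t} (every
#'   enabled event fires);
#' \item state update: an entity is active at \code{t+1} iff some fired
#'   transition outputs it, or it was active and no fired transition
#'   consumes it without replacement;
#' \item initial state: non-boundary places are false at step 0, boundary
#'   places are free;
#' \item the query at the final step, with negative query literals enforced
#'   over the whole trajectory (the entity is never active).
#' }
#'
#' @param model a [GTModel-class] (cycles already resolved).
#' @param query a guard object or a formula string (see [parseFormula()]).
#' @param horizon number of steps \eqn{k \ge 0}.
#' @return List with \code{nvars}, \code{clauses}, \code{placeVar} (entity
#'   by step matrix of variable ids, steps \code{0..horizon}),
#'   \code{fireVar} (event by step matrix, steps \code{0..horizon-1}),
#'   \code{boundary} (boundary entity ids) and \code{boundaryVar} (their
#'   step-0 place variables, named).
#' @export
encodeUnfolding <- function(model, query, horizon) {
  if (is.character(query)) query <- parseFormula(query)
  query <- asGuard(query)
  k <- as.integer(horizon)
  stopifnot(k >= 0L)
  ids <- entityIds(model)
  missing <- setdiff(guardAtoms(query), ids)
  if (length(missing))
    stop("query atom(s) not in model: ", paste(missing, collapse = ", "))
  evs <- events(model)
  evNames <- sort(names(evs))
  nV <- 0L
  clauses <- vector("list", 0L)
  nC <- 0L
  newVar <- function(n = 1L) {
    v <- nV + seq_len(n)
    nV <<- nV + n
    v
  }
  addClause <- function(lits) {
    nC <<- nC + 1L
    clauses[[nC]] <<- as.integer(lits)
  }
  placeVar <- matrix(newVar(length(ids) * (k + 1L)), nrow = length(ids),
                     dimnames = list(ids, as.character(0:k)))
  fireVar <- if (k > 0L && length(evNames))
    matrix(newVar(length(evNames) * k), nrow = length(evNames),
           dimnames = list(evNames, as.character(0:(k - 1L))))
  else
    matrix(integer(0), nrow = length(evNames), ncol = 0L,
           dimnames = list(evNames, NULL))
  TRUEVAR <- newVar()
  addClause(TRUEVAR)
  mkAnd <- function(lits) {
    lits <- as.integer(lits)
    if (length(lits) == 0L) return(TRUEVAR)
    if (length(lits) == 1L) return(lits)
    v <- newVar()
    for (l in lits) addClause(c(-v, l))
    addClause(c(v, -lits))
    v
  }
  mkOr <- function(lits) {
    lits <- as.integer(lits)
    if (length(lits) == 0L) return(-TRUEVAR)
    if (length(lits) == 1L) return(lits)
    v <- newVar()
    addClause(c(-v, lits))
    for (l in lits) addClause(c(v, -l))
    v
  }
  guardLit <- function(g, t) {  # t is a step in 0..k
    switch(g$op,
      true = TRUEVAR,
      atom = placeVar[g$id, t + 1L],
      not  = -guardLit(g$args[[1L]], t),
      and  = mkAnd(vapply(g$args, guardLit, integer(1), t)),
      or   = mkOr(vapply(g$args, guardLit, integer(1), t)))
  }

  trs <- model@transitions
  # fire(h,t) <-> all transitions of h enabled at t
  if (k > 0L) for (h in evNames) {
    htrs <- trs[evs[[h]]]
    for (t in 0:(k - 1L)) {
      parts <- unlist(lapply(htrs, function(tr)
        c(placeVar[tr$input, t + 1L], guardLit(tr$guard, t))))
      en <- mkAnd(parts)
      f <- fireVar[h, t + 1L]
      addClause(c(-f, en))
      addClause(c(f, -en))
    }
  }

  # frame / update rule
  producers <- lapply(setNames(ids, ids), function(p)
    unique(vapply(trs[vapply(trs, function(tr) tr$output == p, logical(1))],
                  `[[`, character(1), "event")))
  consumers <- lapply(setNames(ids, ids), function(p)
    unique(vapply(trs[vapply(trs, function(tr) tr$input == p, logical(1))],
                  `[[`, character(1), "event")))
  fvar <- function(evset, t)
    if (length(evset)) fireVar[evset, t] else integer(0)
  if (k > 0L) for (p in ids) {
    for (t in 0:(k - 1L)) {
      cur <- placeVar[p, t + 1L]
      nxt <- placeVar[p, t + 2L]
      pLit <- mkOr(fvar(producers[[p]], t + 1L))
      cLit <- mkOr(fvar(consumers[[p]], t + 1L))
      addClause(c(-nxt, pLit, cur))
      addClause(c(-nxt, pLit, -cLit))
      addClause(c(nxt, -pLit))
      addClause(c(nxt, -cur, cLit))
    }
  }

  # initial state: non-boundary inactive, boundary free
  bnd <- boundaryEntities(model)
  for (p in setdiff(ids, bnd)) addClause(-placeVar[p, 1L])

  # query at the final step; negative literals over the whole trajectory
  qlit <- local({
    rec <- function(g) {
      switch(g$op,
        true = TRUEVAR,
        atom = placeVar[g$id, k + 1L],
        not  = {
          child <- g$args[[1L]]
          if (child$op == "true") return(-TRUEVAR)
          # NNF guarantees the child is an atom: never active at any step
          mkAnd(-placeVar[child$id, seq_len(k + 1L)])
        },
        and  = mkAnd(vapply(g$args, rec, integer(1))),
        or   = mkOr(vapply(g$args, rec, integer(1))))
    }
    rec(guardNNF(query))
  })
  addClause(qlit)

  list(nvars = nV, clauses = clauses[seq_len(nC)], placeVar = placeVar,
       fireVar = fireVar, boundary = bnd,
       boundaryVar = setNames(placeVar[bnd, 1L], bnd))
}
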