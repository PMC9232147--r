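#' One minimal trajectory solution
#'
#' @slot boundary boundary entity ids activated at step 0 (raw ids: a
#'   cycle-initiation virtual node appears under its own id).
#' @slot schedule list of character vectors: the event ids fired at each
#'   step of the witness trajectory.
#' @slot intermediates non-boundary entity ids ever active along the
#'   witness trajectory.
#' @slot horizon step count of the witness.
#' @export
setClass("TrajectorySolution",
  representation(boundary = "character", schedule = "list",
                 intermediates = "character", horizon = "integer"))

setMethod("show", "TrajectorySolution", function(object) {
  cat("TrajectorySolution: boundary {",
      paste(object@boundary, collapse = ", "), "}, horizon ",
      object@horizon, "\n", sep = "")
  invisible(NULL)
})

#' Result of a phenotype query
#'
#' Holds the enumerated minimal boundary activation sets with their witness
#' schedules, plus derived sets. \emph{Controllers} are the boundary
#' entities activated in at least one trajectory reaching the phenotype;
#' \emph{trajectory entities} are the intermediate entities activated along
#' at least one such trajectory; their union is the causal signature of the
#' phenotype. By default the accessors present each cycle-initiation
#' virtual node as the cycle entity it feeds, matching how unfeedable
#' cycles enter the boundary.
#'
#' @slot queryText the query formula as text.
#' @slot query the parsed guard.
#' @slot solutions list of [TrajectorySolution-class] (enumeration order,
#'   pairwise distinct boundary sets).
#' @slot capped TRUE when enumeration stopped at \code{maxSolutions}.
#' @slot status \code{"ok"} or \code{"unreachable within horizon"}.
#' @slot boundary all boundary entity ids of the (cycle-resolved) model.
#' @slot virtualMap named character vector mapping cycle-initiation node ids
#'   to the entity they feed.
#' @slot maxHorizon largest horizon searched.
#' @export
setClass("QueryResult",
  representation(queryText = "character", query = "ANY", solutions = "list",
                 capped = "logical", status = "character",
                 boundary = "character", virtualMap = "character",
                 maxHorizon = "integer"))

setMethod("show", "QueryResult", function(object) {
  cat("QueryResult for '", object@queryText, "': ",
      length(object@solutions), " solution(s)",
      if (object@capped) " [capped]", "\n", sep = "")
  if (length(object@solutions)) {
    cat("  controllers (", length(controllers(object)), "): ",
        paste(controllers(object), collapse = ", "), "\n", sep = "")
    cat("  trajectory entities (", length(trajectoryEntities(object)),
        ")\n", sep = "")
  } else cat("  status: ", object@status, "\n", sep = "")
  invisible(NULL)
})

mapVirtualIds <- function(ids, virtualMap) {
  hit <- ids %in% names(virtualMap)
  ids[hit] <- virtualMap[ids[hit]]
  sort(unique(ids))
}

#' Accessors for query results
#'
#' @param result a [QueryResult-class].
#' @param mapVirtual present cycle-initiation virtual nodes as the entity
#'   they feed (default TRUE).
#' @return \code{gtSolutions}: list of [TrajectorySolution-class];
#'   \code{controllers}, \code{trajectoryEntities}, \code{gtSignature}:
#'   sorted character vectors; \code{isCapped}: logical.
#' @name result-accessors
NULL

#' @rdname result-accessors
#' @export
gtSolutions <- function(result) result@solutions

#' @rdname result-accessors
#' @export
controllers <- function(result, mapVirtual = TRUE) {
  raw <- sort(unique(unlist(lapply(result@solutions, function(s) s@boundary),
                            use.names = FALSE)))
  if (is.null(raw)) raw <- character(0)
  if (mapVirtual) mapVirtualIds(raw, result@virtualMap) else raw
}

#' @rdname result-accessors
#' @export
trajectoryEntities <- function(result) {
  te <- sort(unique(unlist(lapply(result@solutions,
                                  function(s) s@intermediates),
                           use.names = FALSE)))
  if (is.null(te)) character(0) else te
}

#' @rdname result-accessors
#' @export
gtSignature <- function(result, mapVirtual = TRUE)
  sort(union(controllers(result, mapVirtual), trajectoryEntities(result)))

#' @rdname result-accessors
#' @export
isCapped <- function(result) result@capped

#' Enumerate minimal boundary activation sets for a phenotype query
#'
#' Searches trajectories of increasing length \code{k = 1, 2, ...} up to
#' \code{maxHorizon}. At each horizon the bounded unfolding
#' ([encodeUnfolding()]) is solved repeatedly: every satisfying assignment's
#' boundary activation set is reduced to minimality by iterated removal
#' re-checks (in sorted-id order, re-solving with the reduced set fixed),
#' recorded with a witness firing schedule, then blocked together with all
#' of its supersets, until the horizon is exhausted or \code{maxSolutions}
#' distinct sets have been found. Solution identity is the boundary set:
#' two schedules over the same set count once. Negative literals in the
#' query are enforced over the whole trajectory (the entity is never
#' active), so inhibitors can never appear among controllers or trajectory
#' entities.
#'
#' @param model a [GTModel-class]; cycles are resolved first (idempotent)
#'   unless \code{resolve = FALSE}.
#' @param query formula string (see [parseFormula()]) or guard object.
#' @param maxSolutions cap on the number of distinct boundary sets
#'   (default 400).
#' @param maxHorizon largest trajectory length searched; defaults to the
#'   number of entities, which suffices for any acyclic chain.
#' @param seed retained for interface stability; enumeration is fully
#'   deterministic, so the seed does not alter results.
#' @param resolve apply [resolveCycles()] first (default TRUE).
#' @return A [QueryResult-class].
#' @examples
#' m <- buildToyModel()
#' res <- solveQuery(m, "C")
#' controllers(res)          # D, E, F, I, L
#' @export
solveQuery <- function(model, query, maxSolutions = 400, maxHorizon = NULL,
                       seed = NULL, resolve = TRUE) {
  if (is.character(query)) {
    queryText <- query
    q <- parseFormula(query)
  } else {
    q <- asGuard(query)
    queryText <- formulaToString(q)
  }
  if (resolve) model <- resolveCycles(model)
  missing <- setdiff(guardAtoms(q), entityIds(model))
  if (length(missing))
    stop("query atom(s) not in model: ", paste(missing, collapse = ", "))
  if (is.null(maxHorizon)) maxHorizon <- max(1L, length(entityIds(model)))
  maxHorizon <- as.integer(maxHorizon)
  bnd <- boundaryEntities(model)
  found <- list()
  blocked <- list()
  capped <- FALSE

  for (k in seq_len(maxHorizon)) {
    enc <- encodeUnfolding(model, q, k)
    bvars <- enc$boundaryVar
    blockCl <- lapply(blocked, function(S)
      if (length(S)) -unname(bvars[S]) else integer(0))
    if (any(lengths(blockCl) == 0L) && length(blocked)) break  # {} found
    varOrder <- unname(bvars)  # bnd is sorted; FALSE-first favours minimal
    exactSolve <- function(S) {
      assume <- ifelse(bnd %in% S, bvars, -bvars)
      satSolve(enc$nvars, enc$clauses, assumptions = as.integer(assume),
               varOrder = varOrder)
    }
    repeat {
      res <- satSolve(enc$nvars, c(enc$clauses, blockCl),
                      varOrder = varOrder)
      if (!res$sat) break
      S <- bnd[res$model[bvars]]
      # iterated removal re-checks until no single element can be dropped
      repeat {
        dropped <- FALSE
        for (b in sort(S)) {
          if (exactSolve(setdiff(S, b))$sat) {
            S <- setdiff(S, b)
            dropped <- TRUE
          }
        }
        if (!dropped) break
      }
      wit <- exactSolve(S)
      stopifnot(wit$sat)
      sched <- lapply(seq_len(k), function(t) {
        if (nrow(enc$fireVar) == 0L) return(character(0))
        rownames(enc$fireVar)[wit$model[enc$fireVar[, t]]]
      })
      everActive <- rownames(enc$placeVar)[
        apply(matrix(wit$model[enc$placeVar], nrow = nrow(enc$placeVar)),
              1L, any)]
      sol <- new("TrajectorySolution", boundary = sort(S), schedule = sched,
                 intermediates = sort(setdiff(everActive, bnd)),
                 horizon = k)
      found[[length(found) + 1L]] <- sol
      blocked[[length(blocked) + 1L]] <- sort(S)
      newCl <- if (length(S)) list(-unname(bvars[sort(S)])) else
        list(integer(0))
      blockCl <- c(blockCl, newCl)
      if (length(found) >= maxSolutions) {
        capped <- TRUE
        break
      }
      if (length(S) == 0L) break  # everything is a superset of {}
    }
    if (capped) break
  }

  # keep only subset-minimal boundary sets across horizons
  if (length(found) > 1L && !capped) {
    sets <- lapply(found, function(s) s@boundary)
    keep <- vapply(seq_along(sets), function(i) {
      !any(vapply(seq_along(sets), function(j) {
        i != j && length(sets[[j]]) < length(sets[[i]]) &&
          all(sets[[j]] %in% sets[[i]])
      }, logical(1)))
    }, logical(1))
    found <- found[keep]
  }

  new("QueryResult",
      queryText = queryText, query = q, solutions = found,
      capped = capped,
      status = if (length(found)) "ok" else "unreachable within horizon",
      boundary = bnd, virtualMap = virtualFeedMap(model),
      maxHorizon = maxHorizon)
}

#' Brute-force reference search over all boundary subsets
#'
#' Independent reference semantics for equivalence testing: enumerates every
#' subset of the boundary, simulates the reactive trajectory step by step
#' with [step()]/[enabledEvents()] (no SAT encoding involved), accepts a
#' subset when the query holds at some step within the horizon (negative
#' query literals must never have been active up to that step), and returns
#' the subset-minimal accepted sets. Refuses models beyond desk scale.
#'
#' @param model a [GTModel-class]; cycles resolved first unless
#'   \code{resolve = FALSE}.
#' @param query formula string or guard object.
#' @param maxHorizon maximum trajectory length (at most 8).
#' @param resolve apply [resolveCycles()] first (default TRUE).
#' @return A [QueryResult-class] (solutions sorted by size then
#'   lexicographically).
#' @export
bruteForceOracle <- function(model, query, maxHorizon = NULL,
                             resolve = TRUE) {
  if (is.character(query)) {
    queryText <- query
    q <- parseFormula(query)
  } else {
    q <- asGuard(query)
    queryText <- formulaToString(q)
  }
  if (resolve) model <- resolveCycles(model)
  missing <- setdiff(guardAtoms(q), entityIds(model))
  if (length(missing))
    stop("query atom(s) not in model: ", paste(missing, collapse = ", "))
  bnd <- boundaryEntities(model)
  if (length(entityIds(model)) > 16L || length(bnd) > 14L)
    stop("model beyond brute-force bounds (> 16 entities or > 14 boundary)")
  if (is.null(maxHorizon)) maxHorizon <- min(8L, length(entityIds(model)))
  maxHorizon <- as.integer(maxHorizon)
  if (maxHorizon > 8L)
    stop("horizon beyond brute-force bounds (> 8)")
  qn <- guardNNF(q)
  holdsAt <- function(states, t) {  # t: step index, states[[t + 1]]
    rec <- function(g) {
      switch(g$op,
        true = TRUE,
        atom = g$id %in% states[[t + 1L]],
        not  = {
          child <- g$args[[1L]]
          if (child$op == "true") return(FALSE)
          !any(vapply(states[seq_len(t + 1L)],
                      function(s) child$id %in% s, logical(1)))
        },
        and  = all(vapply(g$args, rec, logical(1))),
        or   = any(vapply(g$args, rec, logical(1))))
    }
    rec(qn)
  }
  accepted <- list()
  nb <- length(bnd)
  for (mask in 0:(2^nb - 1L)) {
    S <- bnd[bitwAnd(mask, 2^(seq_len(nb) - 1L)) > 0L]
    traj <- simulateReactive(model, S, maxHorizon)
    for (t in seq_len(maxHorizon)) {
      if (holdsAt(traj$states, t)) {
        accepted[[length(accepted) + 1L]] <- list(
          boundary = sort(S), schedule = traj$schedule[seq_len(t)],
          intermediates = sort(setdiff(
            unique(unlist(traj$states[seq_len(t + 1L)], use.names = FALSE)),
            bnd)),
          horizon = t)
        break
      }
    }
  }
  sets <- lapply(accepted, `[[`, "boundary")
  minimal <- vapply(seq_along(sets), function(i) {
    !any(vapply(seq_along(sets), function(j) {
      length(sets[[j]]) < length(sets[[i]]) && all(sets[[j]] %in% sets[[i]])
    }, logical(1)))
  }, logical(1))
  accepted <- accepted[minimal]
  ord <- order(lengths(lapply(accepted, `[[`, "boundary")),
               vapply(accepted, function(a)
                 paste(a$boundary, collapse = "\r"), character(1)))
  accepted <- accepted[ord]
  sols <- lapply(accepted, function(a)
    new("TrajectorySolution", boundary = a$boundary, schedule = a$schedule,
        intermediates = a$intermediates, horizon = as.integer(a$horizon)))
  new("QueryResult",
      queryText = queryText, query = q, solutions = sols, capped = FALSE,
      status = if (length(sols)) "ok" else "unreachable within horizon",
      boundary = bnd, virtualMap = virtualFeedMap(model),
      maxHorizon = maxHorizon)
}
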