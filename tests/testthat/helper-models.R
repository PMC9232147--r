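# small builders and an independent query evaluator used across tests

# linear chain e1 -> e2 -> ... -> en, one event per link
chainModel <- function(n, guard = gtTrue()) {
  ids <- sprintf("e%d", seq_len(n))
  ents <- lapply(ids, gtEntity)
  trs <- lapply(seq_len(n - 1L), function(i)
    gtTransition(sprintf("t%d", i), ids[i], ids[i + 1L],
                 sprintf("h%d", i), guard = guard))
  gtModel(ents, trs)
}

# two disjoint unfed 2-cycles {A1,A2} and {B1,B2}
twoCycleModel <- function() {
  ids <- c("A1", "A2", "B1", "B2")
  gtModel(lapply(ids, gtEntity), list(
    gtTransition("t1", "A1", "A2", "h1"),
    gtTransition("t2", "A2", "A1", "h2"),
    gtTransition("t3", "B1", "B2", "h3"),
    gtTransition("t4", "B2", "B1", "h4")))
}

# independent query check over a simulated trajectory: positive atoms at
# step t, negated atoms never active up to t (queries in tests keep NOT on
# atoms)
queryHoldsAt <- function(query, states, t) {
  g <- if (is.character(query)) parseFormula(query) else query
  rec <- function(g) {
    switch(g$op,
      true = TRUE,
      atom = g$id %in% states[[t + 1L]],
      not  = {
        ch <- g$args[[1L]]
        stopifnot(ch$op %in% c("atom", "true"))
        if (ch$op == "true") FALSE
        else !any(vapply(states[seq_len(t + 1L)],
                         function(s) ch$id %in% s, logical(1)))
      },
      and  = all(vapply(g$args, rec, logical(1))),
      or   = any(vapply(g$args, rec, logical(1))))
  }
  rec(g)
}

# does initial boundary set S reach the query within `horizon` steps under
# the reactive policy? (independent of the SAT path)
reachesQuery <- function(model, S, query, horizon) {
  traj <- simulateReactive(model, S, horizon)
  any(vapply(seq_len(horizon), function(t)
    queryHoldsAt(query, traj$states, t), logical(1)))
}

boundarySets <- function(result)
  lapply(gtSolutions(result), function(s) s@boundary)

sameSetOfSets <- function(a, b) {
  key <- function(x) vapply(x, function(s) paste(sort(s), collapse = ","),
                            character(1))
  setequal(key(a), key(b))
}

writeBiopaxCase <- function(case) {
  f <- tempfile(fileext = ".owl")
  buildBiopaxCase(case, f)
  f
}
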