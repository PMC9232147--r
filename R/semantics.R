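#' Non-deterministic guarded-transition dynamics
#'
#' A state is the set of active entities (all others inactive). An event is
#' \emph{enabled} in a state when every one of its transitions has an active
#' input and a satisfied guard; transitions sharing an event fire
#' simultaneously, so a multi-reactant reaction only proceeds when all
#' substrates are present. Firing updates the state with a partially
#' parallel rule: an entity becomes active if some fired transition outputs
#' it; it becomes inactive if some fired transition consumes it as input and
#' no fired transition outputs it; otherwise it is unchanged. Guard atoms
#' are read, never consumed.
#'
#' \code{step} applies one synchronous update for an arbitrary set of
#' enabled events (firing a non-enabled event is a contract violation).
#' \code{enabledEvents} lists the events enabled in a state. The solver and
#' the brute-force oracle explore the reactive policy in which \emph{every}
#' enabled event fires at each step (see the package vignette for why this
#' policy is the one that reproduces the intended query semantics);
#' \code{step} itself accepts any subset so that witness schedules can be
#' replayed and checked.
#'
#' @param model a [GTModel-class].
#' @param state character vector of active entity ids (or named logical).
#' @param fired character vector of event ids to fire (may be empty).
#' @return \code{step}: the next state as a sorted character vector of
#'   active ids. \code{enabledEvents}: sorted character vector of event ids.
#' @examples
#' m <- buildToyModel()
#' step(m, "N", "h1")       # h1 consumes N, produces P and M together
#' @export
step <- function(model, state, fired = character(0)) {
  state <- asState(model, state)
  fired <- unique(as.character(fired))
  evs <- events(model)
  unknown <- setdiff(fired, names(evs))
  if (length(unknown))
    stop("unknown event(s): ", paste(unknown, collapse = ", "))
  en <- enabledEvents(model, state)
  notEnabled <- setdiff(fired, en)
  if (length(notEnabled))
    stop("contract violation: firing non-enabled event(s): ",
         paste(notEnabled, collapse = ", "))
  firedTrs <- model@transitions[unlist(evs[fired], use.names = FALSE)]
  produced <- unique(vapply(firedTrs, `[[`, character(1), "output"))
  consumed <- unique(vapply(firedTrs, `[[`, character(1), "input"))
  if (length(firedTrs) == 0L) produced <- consumed <- character(0)
  sort(union(produced, setdiff(state, setdiff(consumed, produced))))
}

#' @rdname step
#' @export
enabledEvents <- function(model, state) {
  state <- asState(model, state)
  evs <- events(model)
  ok <- vapply(evs, function(tids) {
    all(vapply(model@transitions[tids], function(tr) {
      tr$input %in% state && guardEval(tr$guard, state)
    }, logical(1)))
  }, logical(1))
  sort(names(evs)[ok])
}

asState <- function(model, state) {
  if (is.logical(state)) state <- names(state)[state]
  state <- unique(as.character(state))
  unknown <- setdiff(state, entityIds(model))
  if (length(unknown))
    stop("state names unknown entit",
         if (length(unknown) > 1) "ies: " else "y: ",
         paste(unknown, collapse = ", "))
  sort(state)
}

#' Simulate the reactive (maximal firing) trajectory
#'
#' From an initial state, repeatedly fires all enabled events. Under this
#' policy the trajectory is deterministic; non-determinism in the query
#' semantics resides entirely in the choice of initially active boundary
#' entities.
#'
#' @param model a [GTModel-class].
#' @param init character vector of initially active entity ids.
#' @param horizon number of steps to simulate.
#' @return List with \code{states} (list of length \code{horizon + 1} of
#'   active-id vectors, element 1 being the initial state) and
#'   \code{schedule} (list of length \code{horizon} of fired event-id
#'   vectors).
#' @export
simulateReactive <- function(model, init, horizon) {
  state <- asState(model, init)
  states <- vector("list", horizon + 1L)
  schedule <- vector("list", horizon)
  states[[1L]] <- state
  for (t in seq_len(horizon)) {
    fired <- enabledEvents(model, state)
    state <- step(model, state, fired)
    schedule[[t]] <- fired
    states[[t + 1L]] <- state
  }
  list(states = states, schedule = schedule)
}
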