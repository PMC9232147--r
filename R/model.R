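#' @import methods
#' @importFrom stats setNames
#' @useDynLib gtreach, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

ENTITY_KINDS <- c("protein", "complex", "small_molecule", "dna", "rna",
                  "gene", "virtual")

#' Guarded-transition model
#'
#' A discrete dynamical system of biological entities linked by guarded
#' transitions. A guarded transition is a quadruplet (input, output, event,
#' condition): it moves activity from its input entity to its output entity
#' when its clock event occurs, provided the input is active and the Boolean
#' condition over entity states holds. Transitions sharing an event fire
#' simultaneously, which encodes multi-reactant/multi-product reactions.
#'
#' @slot entities named list of entity records (see [gtEntity()]).
#' @slot transitions named list of transition records (see [gtTransition()]).
#' @slot metadata provenance list (source files, curation options, tool
#'   version).
#' @seealso [gtModel()], [boundaryEntities()], [resolveCycles()],
#'   [modelStats()], [solveQuery()]
#' @export
setClass("GTModel",
  representation(entities = "list", transitions = "list", metadata = "list"),
  prototype(entities = list(), transitions = list(), metadata = list()))

# structural invariants are checked by validateModel(); the constructor
# enforces them by default while still allowing deliberately broken models
# to be built (validate = FALSE) for inspection and testing

#' Entity and transition records
#'
#' @param id unique identifier string.
#' @param name display name (defaults to \code{id}).
#' @param kind one of \code{protein}, \code{complex}, \code{small_molecule},
#'   \code{dna}, \code{rna}, \code{gene}, \code{virtual}. \code{virtual} is
#'   reserved for cycle-initiation nodes.
#' @param location optional compartment string (\code{NA} if unknown).
#' @param modifications character vector of feature strings.
#' @param sourceURIs character vector of provenance URIs.
#' @return A named list record.
#' @export
gtEntity <- function(id, name = id, kind = "protein", location = NA_character_,
                     modifications = character(0), sourceURIs = character(0)) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!kind %in% ENTITY_KINDS)
    stop("unknown entity kind '", kind, "'")
  list(id = id, name = name, kind = kind,
       location = as.character(location)[1L],
       modifications = sort(unique(as.character(modifications))),
       sourceURIs = sort(unique(as.character(sourceURIs))))
}

#' @rdname gtEntity
#' @param input,output entity ids.
#' @param event event id shared by simultaneously firing transitions.
#' @param guard a guard object (see [gtAnd()]); default TRUE.
#' @param selfLoop set TRUE to permit input == output explicitly.
#' @export
gtTransition <- function(id, input, output, event, guard = gtTrue(),
                         selfLoop = FALSE) {
  stopifnot(is.character(id), length(id) == 1L)
  list(id = id, input = input, output = output, event = event,
       guard = asGuard(guard), selfLoop = isTRUE(selfLoop))
}

#' Construct a guarded-transition model
#'
#' @param entities list of entity records ([gtEntity()]).
#' @param transitions list of transition records ([gtTransition()]).
#' @param metadata provenance list.
#' @param validate if TRUE (default) run the S4 validity check.
#' @return A [GTModel-class] object.
#' @examples
#' m <- gtModel(
#'   entities = list(gtEntity("A"), gtEntity("B"), gtEntity("F")),
#'   transitions = list(gtTransition("t1", "A", "B", "h1", gtAtom("F"))))
#' boundaryEntities(m)
#' @export
gtModel <- function(entities = list(), transitions = list(),
                    metadata = list(), validate = TRUE) {
  names(entities) <- vapply(entities, `[[`, character(1), "id")
  names(transitions) <- vapply(transitions, `[[`, character(1), "id")
  obj <- new("GTModel", entities = entities, transitions = transitions,
             metadata = metadata)
  if (validate) {
    rep <- validateModel(obj)
    if (nrow(rep) > 0L)
      stop("invalid model: ",
           paste0(rep$invariant, ": ", rep$message, collapse = "; "))
  }
  obj
}

#' Accessors for guarded-transition models
#'
#' \code{entities} / \code{transitions} return the record lists;
#' \code{entityIds} the entity identifiers; \code{events} a named list
#' mapping each event id to the ids of its transitions (derived).
#'
#' @param model a [GTModel-class].
#' @name gt-accessors
NULL

#' @rdname gt-accessors
#' @export
entities <- function(model) model@entities

#' @rdname gt-accessors
#' @export
transitions <- function(model) model@transitions

#' @rdname gt-accessors
#' @export
entityIds <- function(model) unname(names(model@entities))

#' @rdname gt-accessors
#' @export
events <- function(model) {
  if (length(model@transitions) == 0L) return(list())
  ev <- vapply(model@transitions, `[[`, character(1), "event")
  split(unname(names(model@transitions)), ev)
}

#' @rdname gt-accessors
#' @export
modelMetadata <- function(model) model@metadata

setMethod("show", "GTModel", function(object) {
  st <- modelStats(object)
  cat("GTModel with", st$entities, "entities,", st$transitions,
      "transitions,", st$events, "events\n")
  cat("  boundary entities:", st$boundary, "\n")
  if (!is.null(object@metadata$source))
    cat("  source:", object@metadata$source, "\n")
  invisible(NULL)
})

#' Validate the structural invariants of a model
#'
#' Checks referential integrity (transition inputs/outputs and guard atoms
#' name existing entities), id uniqueness, event naming, self-loop flags and
#' the reservation of the \code{virtual} kind for cycle-initiation nodes.
#' Reporting, not raising: an empty report means a well-formed model.
#'
#' @param model a [GTModel-class].
#' @return data.frame with columns \code{invariant}, \code{ids},
#'   \code{message}; zero rows iff all invariants hold.
#' @export
validateModel <- function(model) {
  bad <- list()
  note <- function(invariant, ids, message)
    bad[[length(bad) + 1L]] <<- data.frame(
      invariant = invariant, ids = paste(ids, collapse = ","),
      message = message, stringsAsFactors = FALSE)
  ents <- model@entities
  trs <- model@transitions
  eids <- vapply(ents, `[[`, character(1), "id")
  if (anyDuplicated(eids))
    note("entity-id-unique", unique(eids[duplicated(eids)]),
         "duplicated entity id")
  if (length(ents) && !identical(unname(names(ents)), unname(eids)))
    note("entity-key", character(0), "entity list names differ from ids")
  for (e in ents) {
    if (!e$kind %in% ENTITY_KINDS)
      note("entity-kind", e$id, paste0("unknown kind '", e$kind, "'"))
    if (e$kind == "virtual" && !grepl("^cycle_initiation_node", e$id))
      note("virtual-kind", e$id,
           "kind 'virtual' is reserved for cycle-initiation nodes")
  }
  tids <- vapply(trs, `[[`, character(1), "id")
  if (anyDuplicated(tids))
    note("transition-id-unique", unique(tids[duplicated(tids)]),
         "duplicated transition id")
  for (tr in trs) {
    for (fld in c("input", "output")) {
      ref <- tr[[fld]]
      if (!ref %in% eids)
        note("referential-integrity", c(tr$id, ref),
             paste0("transition ", tr$id, " ", fld,
                    " references missing entity '", ref, "'"))
    }
    if (identical(tr$input, tr$output) && !isTRUE(tr$selfLoop))
      note("self-loop", tr$id,
           "input equals output but transition not flagged selfLoop")
    if (!is.character(tr$event) || length(tr$event) != 1L || !nzchar(tr$event))
      note("event-name", tr$id, "transition must name exactly one event")
    missing <- setdiff(guardAtoms(tr$guard), eids)
    if (length(missing))
      note("guard-atoms", c(tr$id, missing),
           paste0("guard of ", tr$id, " references missing entity '",
                  paste(missing, collapse = "','"), "'"))
  }
  if (length(bad) == 0L)
    return(data.frame(invariant = character(0), ids = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  do.call(rbind, bad)
}

#' Boundary entities of a model
#'
#' Boundary entities ("frontier places") are the entities that are not the
#' output of any guarded transition. There is no way to produce them with
#' reactions in the model, so they are the only entities allowed to be
#' active in initial states of the dynamics.
#'
#' @param model a [GTModel-class].
#' @return Sorted character vector of entity ids.
#' @export
boundaryEntities <- function(model) {
  outs <- vapply(model@transitions, `[[`, character(1), "output")
  sort(setdiff(entityIds(model), outs))
}

#' Resolve unproducible cycles with virtual initiation nodes
#'
#' A strongly connected component of two or more entities in the
#' input-to-output transition graph that receives no transition from outside
#' the component can never be activated from the boundary. Each such
#' component gets one virtual entity (kind \code{virtual}, id
#' \code{cycle_initiation_node_<k>}) and one unguarded transition from it to
#' the lexicographically smallest member id, which makes the cycle
#' activatable from the (enlarged) boundary. The operation is idempotent and
#' leaves original entities and transitions untouched. Self-loop transitions
#' are ignored when qualifying components: a self-loop alone is not a
#' production path.
#'
#' @param model a [GTModel-class].
#' @return A [GTModel-class] with virtual feed nodes added (or the input
#'   unchanged when no component qualifies).
#' @export
resolveCycles <- function(model) {
  trs <- model@transitions
  if (length(trs) == 0L) return(model)
  ein <- vapply(trs, `[[`, character(1), "input")
  eout <- vapply(trs, `[[`, character(1), "output")
  keep <- ein != eout
  ids <- entityIds(model)
  g <- igraph::graph_from_data_frame(
    data.frame(from = ein[keep], to = eout[keep], stringsAsFactors = FALSE),
    directed = TRUE, vertices = data.frame(name = ids))
  comp <- igraph::components(g, mode = "strong")
  members <- split(ids, comp$membership[ids])
  ents <- model@entities
  newTrs <- trs
  k <- sum(grepl("^cycle_initiation_node_", ids))  # idempotence: continue index
  existingFeeds <- eout  # all outputs, incl. previous virtual feeds
  for (grp in members) {
    if (length(grp) < 2L) next
    feeders <- ein[keep & eout %in% grp & !(ein %in% grp)]
    if (length(feeders) > 0L) next  # already fed from outside
    k <- k + 1L
    vid <- sprintf("cycle_initiation_node_%d", k)
    target <- sort(grp)[1L]
    ents[[vid]] <- gtEntity(vid, kind = "virtual")
    tid <- sprintf("t_%s", vid)
    newTrs[[tid]] <- gtTransition(tid, vid, target,
                                  event = sprintf("h_%s", vid))
  }
  if (identical(names(ents), names(model@entities))) return(model)
  md <- model@metadata
  md$cycleInitiationNodes <- c(md$cycleInitiationNodes,
    setdiff(names(ents), names(model@entities)))
  gtModel(ents, newTrs, md)
}

#' Map cycle-initiation virtual nodes to the entities they feed
#'
#' @param model a [GTModel-class].
#' @return Named character vector: names are virtual node ids, values the
#'   fed entity id.
#' @keywords internal
virtualFeedMap <- function(model) {
  vids <- entityIds(model)[vapply(model@entities, `[[`, character(1),
                                  "kind") == "virtual"]
  if (length(vids) == 0L) return(setNames(character(0), character(0)))
  ins <- vapply(model@transitions, `[[`, character(1), "input")
  outs <- vapply(model@transitions, `[[`, character(1), "output")
  setNames(vapply(vids, function(v) outs[ins == v][1L], character(1)), vids)
}

#' Structural statistics of a model
#'
#' Counts entities (total and by kind), events, transitions and boundary
#' entities, and classifies each boundary entity by role: input of a
#' transition, member of a guard condition, both, or condition-only
#' (pure control).
#'
#' @param model a [GTModel-class].
#' @return Named list with components \code{entities}, \code{entitiesByKind},
#'   \code{events}, \code{transitions}, \code{boundary},
#'   \code{boundaryByKind} and \code{boundaryRoles} (named integer vector
#'   with entries \code{inputOfTransition}, \code{memberOfCondition},
#'   \code{both}, \code{conditionOnly}, \code{neither}).
#' @export
modelStats <- function(model) {
  ents <- model@entities
  trs <- model@transitions
  kinds <- vapply(ents, `[[`, character(1), "kind")
  bnd <- boundaryEntities(model)
  ins <- unique(vapply(trs, `[[`, character(1), "input"))
  condMembers <- unique(unlist(lapply(trs, function(tr) guardAtoms(tr$guard)),
                               use.names = FALSE))
  isIn <- bnd %in% ins
  isCond <- bnd %in% condMembers
  list(
    entities = length(ents),
    entitiesByKind = table(factor(kinds, levels = ENTITY_KINDS)),
    events = length(events(model)),
    transitions = length(trs),
    boundary = length(bnd),
    boundaryByKind = table(factor(kinds[match(bnd, names(ents))],
                                  levels = ENTITY_KINDS)),
    boundaryRoles = c(
      inputOfTransition = sum(isIn),
      memberOfCondition = sum(isCond),
      both = sum(isIn & isCond),
      conditionOnly = sum(!isIn & isCond),
      neither = sum(!isIn & !isCond))
  )
}

#' Read and write the native model format
#'
#' The native format is a JSON document
#' \code{\{"entities": [...], "transitions": [...], "metadata": \{...\}\}}
#' with guards as nested prefix-notation arrays, e.g.
#' \code{["and","A",["or","P","L","K"],["not","M"]]}. Keys are written in a
#' stable order so serialisation round-trips are byte-identical and
#' diffable.
#'
#' @param model a [GTModel-class].
#' @param path file path (\code{.json}).
#' @return \code{readGTModel} returns a [GTModel-class];
#'   \code{writeGTModel} invisibly returns \code{path}.
#' @export
writeGTModel <- function(model, path) {
  entRec <- lapply(model@entities, function(e) {
    r <- list(id = e$id, name = e$name, kind = e$kind)
    if (!is.na(e$location)) r$location <- e$location
    if (length(e$modifications)) r$modifications <- as.list(e$modifications)
    if (length(e$sourceURIs)) r$source_uris <- as.list(e$sourceURIs)
    r
  })
  trRec <- lapply(model@transitions, function(tr) {
    r <- list(id = tr$id, input = tr$input, output = tr$output,
              event = tr$event, guard = guardToPrefix(tr$guard))
    if (isTRUE(tr$selfLoop)) r$self_loop <- TRUE
    r
  })
  doc <- list(entities = unname(entRec), transitions = unname(trRec),
              metadata = model@metadata)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                           null = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname writeGTModel
#' @export
readGTModel <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  ents <- lapply(doc$entities, function(e)
    gtEntity(e$id, name = e$name %||% e$id, kind = e$kind %||% "protein",
             location = e$location %||% NA_character_,
             modifications = unlist(e$modifications) %||% character(0),
             sourceURIs = unlist(e$source_uris) %||% character(0)))
  trs <- lapply(doc$transitions, function(tr)
    gtTransition(tr$id, tr$input, tr$output, tr$event,
                 guard = prefixToGuard(tr$guard),
                 selfLoop = isTRUE(tr$self_loop)))
  # collapse unnamed scalar lists back to vectors so a write-read-write
  # cycle is byte-identical
  simplifyMeta <- function(x) {
    if (!is.list(x)) return(x)
    x <- lapply(x, simplifyMeta)
    if (length(x) && is.null(names(x)) &&
        all(vapply(x, function(e) is.atomic(e) && length(e) == 1L,
                   logical(1))))
      return(unlist(x, use.names = FALSE))
    x
  }
  gtModel(ents, trs, metadata = simplifyMeta(doc$metadata %||% list()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
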