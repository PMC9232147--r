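#' Build the aggregated trajectory graph of a query result
#'
#' All solutions are merged into one graph over entity and reaction nodes.
#' Node classes follow the standard rendering: \code{boundary} (red) for
#' model boundary entities present in the result, \code{intermediate}
#' (grey) for other entities, \code{reaction} (blue) only where an event
#' has more than one reagent or more than one product, and
#' \code{inhibitor} (white) for atoms under NOT in the guards of used
#' events — inhibitors are never in the solutions nor the trajectories,
#' their presence rules out the production of the targets. Edge classes
#' are \code{unary-reaction} (grey, one-to-one events), \code{reaction}
#' (grey, into/out of reaction nodes), \code{activation} (green, positive
#' guard atoms) and \code{inhibition} (red).
#'
#' @param result a [QueryResult-class].
#' @param model the [GTModel-class] the query was solved on (cycles
#'   resolved).
#' @return List with data.frames \code{nodes} (\code{id}, \code{class}) and
#'   \code{edges} (\code{from}, \code{to}, \code{class}), both in sorted
#'   deterministic order.
#' @export
trajectoryGraph <- function(result, model) {
  usedEvents <- sort(unique(unlist(lapply(result@solutions, function(s)
    unlist(s@schedule, use.names = FALSE)), use.names = FALSE)))
  evs <- events(model)
  nodes <- list(); edges <- list()
  addNode <- function(id, class)
    nodes[[length(nodes) + 1L]] <<- data.frame(id = id, class = class,
                                               stringsAsFactors = FALSE)
  addEdge <- function(from, to, class)
    edges[[length(edges) + 1L]] <<- data.frame(from = from, to = to,
                                               class = class,
                                               stringsAsFactors = FALSE)
  entClass <- character(0)
  markEntity <- function(id, class) {
    prev <- entClass[id]
    rank <- c(intermediate = 1, boundary = 2, inhibitor = 3)
    if (is.na(prev) || rank[class] > rank[prev]) entClass[id] <<- class
  }
  # cycle-initiation virtual nodes are presented as the entity they feed,
  # which is how unfeedable cycles enter the (red) boundary
  vm <- result@virtualMap
  rn <- function(x) {
    hit <- x %in% names(vm)
    x[hit] <- vm[x[hit]]
    x
  }
  bnd <- unique(rn(result@boundary))
  for (h in usedEvents) {
    trs <- model@transitions[evs[[h]]]
    ins <- unique(rn(vapply(trs, `[[`, character(1), "input")))
    outs <- unique(rn(vapply(trs, `[[`, character(1), "output")))
    if (length(ins) == 1L && identical(ins, outs)) {
      # virtual feed collapsed onto its cycle entity: node only, no edge
      markEntity(ins[[1L]], if (ins[[1L]] %in% bnd) "boundary"
                 else "intermediate")
      next
    }
    pos <- character(0); neg <- character(0)
    for (tr in trs) {
      nnf <- guardNNF(tr$guard)
      walk <- function(g) {
        if (g$op == "atom") pos <<- c(pos, g$id)
        else if (g$op == "not") {
          if (g$args[[1L]]$op == "atom") neg <<- c(neg, g$args[[1L]]$id)
        } else if (g$op %in% c("and", "or"))
          for (a in g$args) walk(a)
      }
      walk(nnf)
    }
    pos <- sort(setdiff(unique(pos), ins))  # co-reactants already inputs
    neg <- sort(unique(neg))
    many <- length(ins) > 1L || length(outs) > 1L
    target <- if (many) paste0("reaction_", h) else outs[[1L]]
    if (many) {
      addNode(target, "reaction")
      for (i in ins) addEdge(i, target, "reaction")
      for (o in outs) addEdge(target, o, "reaction")
    } else {
      addEdge(ins[[1L]], outs[[1L]], "unary-reaction")
    }
    for (a in pos) addEdge(a, target, "activation")
    for (a in neg) {
      addEdge(a, target, "inhibition")
      markEntity(a, "inhibitor")
    }
    for (e in c(ins, outs, pos))
      markEntity(e, if (e %in% bnd) "boundary" else "intermediate")
  }
  for (id in names(entClass)) addNode(id, entClass[[id]])
  nodes <- if (length(nodes)) unique(do.call(rbind, nodes)) else
    data.frame(id = character(0), class = character(0),
               stringsAsFactors = FALSE)
  edges <- if (length(edges)) unique(do.call(rbind, edges)) else
    data.frame(from = character(0), to = character(0),
               class = character(0), stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  edges <- edges[order(edges$from, edges$to, edges$class), , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  list(nodes = nodes, edges = edges)
}

GRAPH_COLORS <- c(boundary = "red", intermediate = "grey",
                  reaction = "blue", inhibitor = "white")
EDGE_COLORS <- c(`unary-reaction` = "grey", reaction = "grey",
                 activation = "green", inhibition = "red")

#' Export the aggregated trajectory graph
#'
#' @param result a [QueryResult-class].
#' @param model the [GTModel-class] the query was solved on.
#' @param format \code{"dot"} or \code{"graphml"}.
#' @param path optional output file.
#' @return The document as a character string (invisibly when \code{path}
#'   is given). An empty result yields an empty graph document.
#' @export
exportTrajectoryGraph <- function(result, model,
                                  format = c("dot", "graphml"),
                                  path = NULL) {
  if (is.character(format) && length(format) == 1L &&
      !format %in% c("dot", "graphml"))
    stop("unknown format '", format,
         "'; supported formats: dot, graphml")
  format <- match.arg(format)
  g <- trajectoryGraph(result, model)
  doc <- if (format == "dot") {
    lines <- c("digraph trajectories {",
      sprintf('  "%s" [class="%s", color="%s"];', g$nodes$id,
              g$nodes$class, GRAPH_COLORS[g$nodes$class]),
      sprintf('  "%s" -> "%s" [class="%s", color="%s"];', g$edges$from,
              g$edges$to, g$edges$class, EDGE_COLORS[g$edges$class]),
      "}")
    paste0(paste(lines, collapse = "\n"), "\n")
  } else {
    esc <- xmlEsc
    paste0(
      '<?xml version="1.0" encoding="UTF-8"?>\n',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">\n',
      '  <key id="class" for="all" attr.name="class" attr.type="string"/>\n',
      '  <graph id="trajectories" edgedefault="directed">\n',
      paste0(sprintf(
        '    <node id="%s"><data key="class">%s</data></node>\n',
        esc(g$nodes$id), g$nodes$class), collapse = ""),
      paste0(sprintf(
        paste0('    <edge source="%s" target="%s">',
               '<data key="class">%s</data></edge>\n'),
        esc(g$edges$from), esc(g$edges$to), g$edges$class), collapse = ""),
      "  </graph>\n</graphml>\n")
  }
  if (!is.null(path)) {
    writeLines(doc, path, useBytes = TRUE)
    return(invisible(doc))
  }
  doc
}

#' Trajectory-by-controller occupancy matrix
#'
#' Binary matrix with one row per solution (enumeration order) and one
#' column per controller (sorted): cell (i, j) is 1 iff controller j is in
#' the boundary activation set of solution i. The matrix feeds clustering
#' and heatmap analyses of trajectory composition; the clustering itself is
#' left to downstream tooling.
#'
#' @param result a [QueryResult-class].
#' @param path optional CSV output (UTF-8, comma-separated, header row,
#'   first column \code{trajectory}).
#' @param mapVirtual present cycle-initiation nodes as the entity they feed.
#' @return Integer matrix (invisibly when \code{path} is given).
#' @export
occupancyMatrix <- function(result, path = NULL, mapVirtual = TRUE) {
  ctl <- controllers(result, mapVirtual = mapVirtual)
  sols <- result@solutions
  m <- matrix(0L, nrow = length(sols), ncol = length(ctl),
              dimnames = list(
                if (length(sols)) sprintf("trajectory_%d",
                                          seq_along(sols)) else NULL,
                ctl))
  for (i in seq_along(sols)) {
    b <- sols[[i]]@boundary
    if (mapVirtual) b <- mapVirtualIds(b, result@virtualMap)
    m[i, ctl %in% b] <- 1L
  }
  if (!is.null(path)) {
    utils::write.csv(data.frame(trajectory = rownames(m), m,
                                check.names = FALSE),
                     path, row.names = FALSE, fileEncoding = "UTF-8")
    return(invisible(m))
  }
  m
}

#' Compare controller sets across queries
#'
#' Computes every region of the Venn partition of two or more controller
#' sets: for each non-empty combination of queries, the controllers found
#' in exactly those queries. Pure set algebra; region cardinalities sum to
#' the size of the union.
#'
#' @param results named list of [QueryResult-class] objects (or plain
#'   character vectors of controller ids); at least two.
#' @param mapVirtual present cycle-initiation nodes as the entity they feed.
#' @return List with \code{sets} (the input controller sets),
#'   \code{regions} (named list; names like \code{"a&b"} list the exclusive
#'   members of that intersection region) and \code{counts} (named integer
#'   vector over the same regions).
#' @export
compareControllers <- function(results, mapVirtual = TRUE) {
  if (length(results) < 2L)
    stop("need at least two results to compare")
  if (is.null(names(results)) || any(!nzchar(names(results))))
    stop("'results' must be a named list")
  sets <- lapply(results, function(r)
    if (is.character(r)) sort(unique(r)) else controllers(r, mapVirtual))
  nm <- names(sets)
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L,
                                                   dimnames = list(NULL, nm))
  regions <- list()
  combos <- unlist(lapply(seq_along(nm), function(k)
    utils::combn(nm, k, simplify = FALSE)), recursive = FALSE)
  for (combo in combos) {
    inAll <- if (length(universe))
      rowSums(membership[, combo, drop = FALSE]) == length(combo) &
        rowSums(membership[, setdiff(nm, combo), drop = FALSE]) == 0L
    else logical(0)
    regions[[paste(combo, collapse = "&")]] <- universe[inAll]
  }
  list(sets = sets, regions = regions,
       counts = vapply(regions, length, integer(1)))
}
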