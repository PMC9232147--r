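BIOPAX_NS <- "http://www.biopax.org/release/biopax-level3.owl#"

PE_CLASSES <- c("Protein", "Complex", "SmallMolecule", "Dna", "Rna",
                "PhysicalEntity")
INTERACTION_CLASSES <- c("BiochemicalReaction", "ComplexAssembly",
                         "Transport", "TransportWithBiochemicalReaction",
                         "Degradation", "TemplateReaction",
                         "MolecularInteraction", "GeneticInteraction",
                         "Conversion")
CONTROL_CLASSES <- c("Control", "Catalysis", "TemplateReactionRegulation",
                     "Modulation")
# BioPAX classes that are legitimate but carry nothing the compiler needs
IGNORED_CLASSES <- c("Pathway", "PathwayStep", "BiochemicalPathwayStep",
                     "UnificationXref", "RelationshipXref",
                     "PublicationXref", "Provenance", "BioSource",
                     "Stoichiometry", "Evidence", "Score",
                     "RelationshipTypeVocabulary", "Ontology",
                     "CellularLocationVocabulary", "ModificationFeature",
                     "SequenceModificationVocabulary", "FragmentFeature",
                     "SequenceSite", "SequenceInterval",
                     "EntityReference", "ProteinReference",
                     "SmallMoleculeReference", "DnaReference",
                     "RnaReference", "ChemicalStructure", "Gene")

#' Intermediate object model of a parsed BioPAX Level-3 document
#'
#' @slot physicalEntities named list (by uri) of records with fields
#'   \code{uri}, \code{type}, \code{name}, \code{location},
#'   \code{modifications}, \code{members}, \code{components}.
#' @slot interactions named list of records with fields \code{uri},
#'   \code{type}, \code{reactants}, \code{products}, \code{template}.
#' @slot controls named list of records with fields \code{uri}, \code{type},
#'   \code{controller}, \code{controlled}, \code{sign}.
#' @slot dangling character vector of unresolved reference uris (kept as
#'   metadata only, never fatal).
#' @slot log list of per-step curation notes and counts.
#' @export
setClass("BioPAXGraph",
  representation(physicalEntities = "list", interactions = "list",
                 controls = "list", dangling = "character", log = "list"),
  prototype(physicalEntities = list(), interactions = list(),
            controls = list(), dangling = character(0), log = list()))

setMethod("show", "BioPAXGraph", function(object) {
  cat("BioPAXGraph:", length(object@physicalEntities), "physical entities,",
      length(object@interactions), "interactions,",
      length(object@controls), "controls\n")
  if (length(object@dangling))
    cat("  dangling references:", length(object@dangling), "\n")
  invisible(NULL)
})

biopaxGraph <- function(physicalEntities = list(), interactions = list(),
                        controls = list(), dangling = character(0),
                        log = list()) {
  names(physicalEntities) <- vapply(physicalEntities, `[[`, character(1),
                                    "uri")
  names(interactions) <- vapply(interactions, `[[`, character(1), "uri")
  names(controls) <- vapply(controls, `[[`, character(1), "uri")
  new("BioPAXGraph", physicalEntities = physicalEntities,
      interactions = interactions, controls = controls,
      dangling = dangling, log = log)
}

nodeUri <- function(node) {
  id <- xml2::xml_attr(node, "ID")
  if (!is.na(id)) return(paste0("#", id))
  about <- xml2::xml_attr(node, "about")
  if (!is.na(about)) return(about)
  NA_character_
}

childRefs <- function(node, prop) {
  kids <- xml2::xml_find_all(node, sprintf("./*[local-name()='%s']", prop))
  refs <- xml2::xml_attr(kids, "resource")
  refs[!is.na(refs)]
}

childText <- function(node, prop) {
  kids <- xml2::xml_find_all(node, sprintf("./*[local-name()='%s']", prop))
  txt <- xml2::xml_text(kids)
  txt[nzchar(txt)]
}

#' Parse a BioPAX Level-3 RDF/XML document
#'
#' Captures all instances of the PhysicalEntity, Interaction and Control
#' subclasses with the properties the compiler consumes (names, cellular
#' locations, modification features, class members, complex components,
#' reactants/products/templates, controllers and control signs). Subclass
#' membership is resolved internally; no external reasoner is used.
#' References that do not resolve within the document are logged as
#' dangling, not fatal. Gzip-compressed input is accepted.
#'
#' @param path path to a \code{.owl} (RDF/XML) file, optionally
#'   \code{.gz}-compressed.
#' @return A [BioPAXGraph-class].
#' @export
loadBiopax <- function(path) {
  if (!file.exists(path)) stop("cannot read BioPAX file: ", path)
  doc <- tryCatch({
    if (grepl("\\.gz$", path)) {
      con <- gzfile(path, "rb")
      on.exit(close(con), add = TRUE)
      xml2::read_xml(con)
    } else xml2::read_xml(path)
  }, error = function(e)
    stop("parse error in BioPAX file '", path, "': ",
         conditionMessage(e), call. = FALSE))
  if (xml2::xml_name(doc) != "RDF")
    stop("parse error in BioPAX file '", path, "': not an RDF document")
  nodes <- xml2::xml_children(doc)
  pes <- list(); ints <- list(); ctrls <- list()
  locVocab <- list(); modFeat <- list(); modVocab <- list()
  for (node in nodes) {
    cls <- xml2::xml_name(node)
    uri <- nodeUri(node)
    if (cls %in% PE_CLASSES) {
      nm <- c(childText(node, "displayName"),
              childText(node, "standardName"), childText(node, "name"))
      pes[[uri]] <- list(
        uri = uri, type = cls,
        name = if (length(nm)) nm[[1L]] else uri,
        location = { r <- childRefs(node, "cellularLocation")
                     if (length(r)) r[[1L]] else NA_character_ },
        modifications = childRefs(node, "feature"),
        members = childRefs(node, "memberPhysicalEntity"),
        components = childRefs(node, "component"))
    } else if (cls %in% INTERACTION_CLASSES) {
      ints[[uri]] <- list(
        uri = uri, type = cls,
        reactants = childRefs(node, "left"),
        products = childRefs(node, "right"),
        template = { r <- childRefs(node, "template")
                     if (length(r)) r[[1L]] else NA_character_ })
      if (cls == "TemplateReaction")
        ints[[uri]]$products <- childRefs(node, "product")
    } else if (cls %in% CONTROL_CLASSES) {
      ct <- childText(node, "controlType")
      sign <- if (length(ct) && grepl("^INHIBITION", ct[[1L]]))
        "inhibition" else "activation"
      ctrls[[uri]] <- list(
        uri = uri, type = cls,
        controller = { r <- childRefs(node, "controller")
                       if (length(r)) r[[1L]] else NA_character_ },
        controlled = { r <- childRefs(node, "controlled")
                       if (length(r)) r[[1L]] else NA_character_ },
        sign = sign)
    } else if (cls == "CellularLocationVocabulary") {
      tm <- childText(node, "term")
      locVocab[[uri]] <- if (length(tm)) tm[[1L]] else uri
    } else if (cls == "ModificationFeature") {
      modFeat[[uri]] <- { r <- childRefs(node, "modificationType")
                          if (length(r)) r[[1L]] else NA_character_ }
    } else if (cls == "SequenceModificationVocabulary") {
      tm <- childText(node, "term")
      modVocab[[uri]] <- if (length(tm)) tm[[1L]] else uri
    } else if (!cls %in% IGNORED_CLASSES) {
      warning("unknown BioPAX class '", cls, "' skipped (", uri, ")",
              call. = FALSE)
    }
  }
  # resolve location and modification terms to plain strings
  resolveLoc <- function(ref) {
    if (is.na(ref)) return(NA_character_)
    locVocab[[ref]] %||% ref
  }
  resolveMod <- function(refs) {
    vapply(refs, function(r) {
      v <- modFeat[[r]]
      if (is.null(v) || is.na(v)) return(r)
      modVocab[[v]] %||% v
    }, character(1), USE.NAMES = FALSE)
  }
  pes <- lapply(pes, function(pe) {
    pe$location <- resolveLoc(pe$location)
    pe$modifications <- sort(unique(resolveMod(pe$modifications)))
    pe
  })
  g <- biopaxGraph(pes, ints, ctrls)
  g@dangling <- danglingRefs(g)
  g
}

danglingRefs <- function(graph) {
  known <- c(names(graph@physicalEntities), names(graph@interactions),
             names(graph@controls))
  refs <- c(
    unlist(lapply(graph@physicalEntities,
                  function(pe) c(pe$members, pe$components)),
           use.names = FALSE),
    unlist(lapply(graph@interactions, function(it)
      c(it$reactants, it$products,
        if (!is.na(it$template)) it$template)), use.names = FALSE),
    unlist(lapply(graph@controls, function(ct)
      c(if (!is.na(ct$controller)) ct$controller,
        if (!is.na(ct$controlled)) ct$controlled)), use.names = FALSE))
  as.character(sort(unique(setdiff(refs, known))))
}

rewriteRefs <- function(graph, map) {
  subst <- function(x) {
    hit <- x %in% names(map)
    x[hit] <- unname(map[x[hit]])
    unique(x)
  }
  graph@physicalEntities <- lapply(graph@physicalEntities, function(pe) {
    pe$members <- subst(pe$members)
    pe$components <- subst(pe$components)
    pe
  })
  graph@interactions <- lapply(graph@interactions, function(it) {
    it$reactants <- subst(it$reactants)
    it$products <- subst(it$products)
    if (!is.na(it$template)) it$template <- subst(it$template)
    it
  })
  graph@controls <- lapply(graph@controls, function(ct) {
    if (!is.na(ct$controller)) ct$controller <- subst(ct$controller)
    ct
  })
  graph
}

#' Merge duplicated physical entities
#'
#' Entities identical on the tuple (type, name, location, modification
#' features, member set, component set) are collapsed to one representative
#' (smallest uri); all references are rewritten. Exact-tuple matching makes
#' the grouping reproducible.
#'
#' @param graph a [BioPAXGraph-class].
#' @return List with \code{graph} (merged) and \code{report} (list with
#'   \code{groups}, a list of uri vectors of size >= 2;
#'   \code{duplicatedEntities}, total entities in such groups;
#'   \code{groupCount}).
#' @export
mergeDuplicateEntities <- function(graph) {
  pes <- graph@physicalEntities
  keys <- vapply(pes, function(pe) paste(
    pe$type, pe$name, pe$location,
    paste(sort(pe$modifications), collapse = "|"),
    paste(sort(pe$members), collapse = "|"),
    paste(sort(pe$components), collapse = "|"), sep = "\r"), character(1))
  groups <- split(names(pes), keys)
  dup <- groups[lengths(groups) >= 2L]
  dup <- lapply(dup, sort)
  dup <- dup[order(vapply(dup, `[[`, character(1), 1L))]
  map <- character(0)
  for (grp in dup) {
    rep <- grp[[1L]]
    map[setdiff(grp, rep)] <- rep
  }
  if (length(map)) {
    graph@physicalEntities <- pes[!names(pes) %in% names(map)]
    graph <- rewriteRefs(graph, map)
  }
  report <- list(groups = unname(dup),
                 duplicatedEntities = sum(lengths(dup)),
                 groupCount = length(dup))
  graph@log$merge <- report[c("duplicatedEntities", "groupCount")]
  list(graph = graph, report = report)
}

#' Reify reactant-products as catalysts
#'
#' Any entity playing both the reactant and product role in the same
#' interaction is removed from the reactant list and reattached as a fresh
#' Catalysis control (sign activation) on that interaction. Applied before
#' compilation. An interaction whose sole reactant equals its sole product
#' ends up reactant-less and is flagged in the log; the compiler then
#' treats it as a template-like production guarded by its catalyst.
#'
#' @param graph a [BioPAXGraph-class].
#' @return The rewritten [BioPAXGraph-class] (reification count in the log).
#' @export
reifyReactantProducts <- function(graph) {
  ctrls <- graph@controls
  n <- 0L
  emptied <- character(0)
  graph@interactions <- lapply(graph@interactions, function(it) {
    both <- intersect(it$reactants, it$products)
    if (length(both) == 0L) return(it)
    for (e in sort(both)) {
      n <<- n + 1L
      uri <- sprintf("#reified_catalysis_%d", n)
      ctrls[[uri]] <<- list(uri = uri, type = "Catalysis", controller = e,
                            controlled = it$uri, sign = "activation")
    }
    it$reactants <- setdiff(it$reactants, both)
    if (length(it$reactants) == 0L) emptied <<- c(emptied, it$uri)
    it
  })
  graph@controls <- ctrls
  names(graph@controls) <- vapply(graph@controls, `[[`, character(1), "uri")
  graph@log$reify <- list(catalysesCreated = n,
                          reactantLessInteractions = emptied)
  graph
}

#' Drop interaction and control classes outside the formalism
#'
#' MolecularInteraction and GeneticInteraction cannot be interpreted as
#' controlled biochemical reactions and are removed, as are Modulation
#' controls (all of them; counts are logged). Under the \code{"acsn"}
#' profile the analysis is refocused on Protein, Complex and SmallMolecule
#' entities: other entities and the interactions/controls touching them are
#' removed as well.
#'
#' @param graph a [BioPAXGraph-class].
#' @param profile \code{"default"} or \code{"acsn"}.
#' @return The filtered [BioPAXGraph-class].
#' @export
dropUnsupported <- function(graph, profile = c("default", "acsn")) {
  profile <- match.arg(profile)
  itypes <- vapply(graph@interactions, `[[`, character(1), "type")
  dropInt <- names(graph@interactions)[
    itypes %in% c("MolecularInteraction", "GeneticInteraction")]
  ctypes <- vapply(graph@controls, `[[`, character(1), "type")
  dropCtl <- names(graph@controls)[ctypes == "Modulation"]
  dropPE <- character(0)
  if (profile == "acsn") {
    ptypes <- vapply(graph@physicalEntities, `[[`, character(1), "type")
    dropPE <- names(graph@physicalEntities)[
      !ptypes %in% c("Protein", "Complex", "SmallMolecule")]
    touches <- vapply(graph@interactions, function(it)
      any(c(it$reactants, it$products,
            if (!is.na(it$template)) it$template) %in% dropPE),
      logical(1))
    dropInt <- union(dropInt, names(graph@interactions)[touches])
  }
  graph@interactions <- graph@interactions[
    !names(graph@interactions) %in% dropInt]
  graph@physicalEntities <- graph@physicalEntities[
    !names(graph@physicalEntities) %in% dropPE]
  # controls over dropped interactions or by dropped controllers go too
  bad <- vapply(graph@controls, function(ct)
    ct$uri %in% dropCtl || ct$controlled %in% dropInt ||
      ct$controller %in% dropPE || is.na(ct$controlled), logical(1))
  graph@controls <- graph@controls[!bad]
  graph@physicalEntities <- lapply(graph@physicalEntities, function(pe) {
    pe$members <- setdiff(pe$members, dropPE)
    pe$components <- setdiff(pe$components, dropPE)
    pe
  })
  graph@log$drop <- list(profile = profile,
                         interactionsRemoved = length(dropInt),
                         modulationsRemoved = sum(ctypes == "Modulation"),
                         entitiesRemoved = length(dropPE))
  graph
}

#' Expand or collapse generic entity classes
#'
#' A generic entity (a class with \code{memberPhysicalEntity} records) is
#' handled by context, one nesting level at a time, to fixpoint:
#' \itemize{
#' \item if the class participates in no interaction or control it is
#'   removed outright; its members inherit its modification features and
#'   location when they lack their own;
#' \item if no member participates individually in any interaction or
#'   control, the class is kept as a single compound and the members are
#'   eliminated (collapse);
#' \item otherwise the class is deleted and every interaction/control
#'   referencing it is replicated once per member (expansion); controls on
#'   a replicated interaction are replicated alongside it.
#' }
#'
#' @param graph a [BioPAXGraph-class] (duplicates already merged).
#' @return The rewritten [BioPAXGraph-class].
#' @export
expandGenericClasses <- function(graph) {
  # cyclic membership is a hard error
  memb <- lapply(graph@physicalEntities, `[[`, "members")
  edges <- do.call(rbind, lapply(names(memb), function(u)
    if (length(memb[[u]]))
      data.frame(from = u, to = memb[[u]], stringsAsFactors = FALSE)))
  if (!is.null(edges) && nrow(edges)) {
    known <- intersect(unique(c(edges$from, edges$to)),
                       names(graph@physicalEntities))
    edges <- edges[edges$to %in% known, , drop = FALSE]
    if (nrow(edges)) {
      g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                         vertices = data.frame(name = known))
      comp <- igraph::components(g, mode = "strong")
      if (any(comp$csize >= 2L)) {
        cyc <- names(comp$membership)[
          comp$membership == which(comp$csize >= 2L)[1L]]
        stop("cyclic class membership involving: ",
             paste(sort(cyc), collapse = ", "))
      }
    }
  }
  nCollapse <- 0L; nExpand <- 0L; nRemoved <- 0L
  repeat {
    pes <- graph@physicalEntities
    participants <- function() {
      unique(c(
        unlist(lapply(graph@interactions, function(it)
          c(it$reactants, it$products,
            if (!is.na(it$template)) it$template)), use.names = FALSE),
        unlist(lapply(graph@controls, function(ct)
          if (!is.na(ct$controller)) ct$controller), use.names = FALSE)))
    }
    part <- participants()
    # molecule identity for individual-participation tests: the same
    # molecule in another compartment still counts as acting individually
    molKey <- function(u) paste(pes[[u]]$type, pes[[u]]$name, sep = "\r")
    partKeys <- vapply(intersect(part, names(pes)), molKey, character(1))
    generic <- names(pes)[lengths(lapply(pes, `[[`, "members")) > 0L]
    # innermost first: classes whose members are not themselves classes
    generic <- generic[vapply(generic, function(u) {
      ms <- intersect(pes[[u]]$members, names(pes))
      all(lengths(lapply(pes[ms], `[[`, "members")) == 0L)
    }, logical(1))]
    if (length(generic) == 0L) break
    u <- sort(generic)[[1L]]
    cls <- pes[[u]]
    members <- intersect(cls$members, names(pes))
    inherit <- function(m) {
      pe <- pes[[m]]
      if (is.na(pe$location)) pe$location <- cls$location
      if (length(pe$modifications) == 0L)
        pe$modifications <- cls$modifications
      pe
    }
    if (!u %in% part) {
      for (m in members) graph@physicalEntities[[m]] <- inherit(m)
      graph@physicalEntities[[u]] <- NULL
      graph <- rewriteRefs(graph, setNames(character(0), character(0)))
      graph@physicalEntities <- lapply(graph@physicalEntities, function(pe) {
        pe$members <- setdiff(pe$members, u)
        pe
      })
      nRemoved <- nRemoved + 1L
      next
    }
    individually <- vapply(members, function(m)
      m %in% part || molKey(m) %in% partKeys, logical(1))
    if (!any(individually)) {
      # collapse: the class stays as a single compound, members vanish
      graph@physicalEntities[[u]]$members <- character(0)
      for (m in setdiff(members, u)) graph@physicalEntities[[m]] <- NULL
      nCollapse <- nCollapse + 1L
      next
    }
    # expansion: replicate referencing interactions/controls per member
    for (m in members) graph@physicalEntities[[m]] <- inherit(m)
    newInts <- list()
    replicatedInts <- character(0)
    for (it in graph@interactions) {
      touches <- u %in% c(it$reactants, it$products,
                          if (!is.na(it$template)) it$template)
      if (!touches) { newInts[[it$uri]] <- it; next }
      replicatedInts <- c(replicatedInts, it$uri)
      for (i in seq_along(members)) {
        m <- members[[i]]
        cp <- it
        cp$uri <- sprintf("%s__m%d", it$uri, i)
        subst <- function(x) unique(replace(x, x == u, m))
        cp$reactants <- subst(cp$reactants)
        cp$products <- subst(cp$products)
        if (!is.na(cp$template) && cp$template == u) cp$template <- m
        # paired substitution: a sibling class in the same interaction
        # whose member set mirrors this one (same molecule identities,
        # e.g. the other compartment of a transport) follows the member
        # choice instead of being cross-multiplied later
        sibSubst <- function(x) {
          for (s in intersect(x, names(pes))) {
            if (s == u || length(pes[[s]]$members) == 0L) next
            sm <- intersect(pes[[s]]$members, names(pes))
            hit <- sm[vapply(sm, function(z)
              identical(molKey(z), molKey(m)), logical(1))]
            if (length(hit) == 1L) x <- replace(x, x == s, hit)
          }
          unique(x)
        }
        cp$reactants <- sibSubst(cp$reactants)
        cp$products <- sibSubst(cp$products)
        newInts[[cp$uri]] <- cp
      }
    }
    newCtrls <- list()
    for (ct in graph@controls) {
      onReplicated <- ct$controlled %in% replicatedInts
      byClass <- identical(ct$controller, u)
      if (!onReplicated && !byClass) { newCtrls[[ct$uri]] <- ct; next }
      if (onReplicated) {
        for (i in seq_along(members)) {
          cp <- ct
          cp$uri <- sprintf("%s__m%d", ct$uri, i)
          cp$controlled <- sprintf("%s__m%d", ct$controlled, i)
          if (byClass) cp$controller <- members[[i]]
          newCtrls[[cp$uri]] <- cp
        }
      } else {  # controller is the class on an untouched interaction
        for (i in seq_along(members)) {
          cp <- ct
          cp$uri <- sprintf("%s__m%d", ct$uri, i)
          cp$controller <- members[[i]]
          newCtrls[[cp$uri]] <- cp
        }
      }
    }
    graph@interactions <- newInts
    graph@controls <- newCtrls
    graph@physicalEntities[[u]] <- NULL
    graph@physicalEntities <- lapply(graph@physicalEntities, function(pe) {
      pe$members <- setdiff(pe$members, u)
      pe
    })
    nExpand <- nExpand + 1L
  }
  graph@log$expand <- list(collapsed = nCollapse, expanded = nExpand,
                           removedUninvolved = nRemoved)
  graph
}

#' Run the full curation pipeline
#'
#' Fixed order: merge duplicates, reify reactant-products as catalysts,
#' drop unsupported classes, expand generic classes. Duplicates must
#' collapse before class-membership tests and reification must precede
#' compilation; re-running the pipeline on its own output is the identity.
#'
#' @param graph a [BioPAXGraph-class] fresh from [loadBiopax()].
#' @param profile \code{"default"} or \code{"acsn"}.
#' @return List with \code{graph} (curated) and \code{report} (per-rule
#'   counts, mirroring the structure of published curation tables).
#' @export
curateBiopax <- function(graph, profile = c("default", "acsn")) {
  profile <- match.arg(profile)
  m <- mergeDuplicateEntities(graph)
  g <- reifyReactantProducts(m$graph)
  g <- dropUnsupported(g, profile)
  g <- expandGenericClasses(g)
  report <- list(
    physicalEntitiesBefore = length(graph@physicalEntities),
    physicalEntitiesAfter = length(g@physicalEntities),
    duplicatedEntities = m$report$duplicatedEntities,
    duplicateGroups = m$report$groupCount,
    catalysesCreated = g@log$reify$catalysesCreated,
    interactionsRemoved = g@log$drop$interactionsRemoved,
    modulationsRemoved = g@log$drop$modulationsRemoved,
    classesCollapsed = g@log$expand$collapsed,
    classesExpanded = g@log$expand$expanded,
    classesRemovedUninvolved = g@log$expand$removedUninvolved,
    controlsAfter = length(g@controls),
    interactionsAfter = length(g@interactions))
  list(graph = g, report = report)
}
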