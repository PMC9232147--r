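#' Compilation options
#'
#' @param profile curation profile name (\code{"default"} or \code{"acsn"}).
#' @param geneSuffix suffix appended to template ids when creating the
#'   gene-kind input of a template reaction (default \code{"_gene"}).
#' @param locationInId qualify entity ids with their compartment so the
#'   same molecule in two compartments is two entities (default TRUE).
#' @param degradationSinkId id of the pseudo-entity receiving degraded
#'   inputs.
#' @return Named list of options; compilation is deterministic under fixed
#'   options.
#' @export
compileOptions <- function(profile = "default", geneSuffix = "_gene",
                           locationInId = TRUE,
                           degradationSinkId = "degradation_sink") {
  list(profile = profile, geneSuffix = geneSuffix,
       locationInId = isTRUE(locationInId),
       degradationSinkId = degradationSinkId)
}

normalizeId <- function(x) {
  x <- gsub("[^A-Za-z0-9]+", "_", x)
  gsub("^_+|_+$", "", x)
}

UNKNOWN_LOCATION <- "cellular_component_unknown"

peKind <- function(type) {
  switch(type,
    Protein = "protein", Complex = "complex",
    SmallMolecule = "small_molecule", Dna = "dna", Rna = "rna",
    "protein")  # generic PhysicalEntity: no finer type available
}

# deterministic uri -> compiled entity id map (collisions suffixed _2, _3..)
compiledIdMap <- function(graph, options) {
  uris <- sort(names(graph@physicalEntities))
  base <- vapply(uris, function(u) {
    pe <- graph@physicalEntities[[u]]
    id <- normalizeId(pe$name)
    if (!nzchar(id)) id <- normalizeId(sub("^#", "", u))
    if (options$locationInId && !is.na(pe$location))
      id <- paste0(id, "_", normalizeId(pe$location))
    id
  }, character(1))
  ids <- base
  for (d in unique(base[duplicated(base)])) {
    hit <- which(base == d)
    ids[hit] <- paste0(d, c("", paste0("_", seq_len(length(hit) - 1L) + 1L)))
  }
  ids
}

#' Fold controls into a guard condition
#'
#' The condition contributed by the controls of one interaction: the
#' disjunction of its activator atoms (omitted when there are none)
#' conjoined with the negation of each inhibitor atom. Atom ordering is
#' sorted, so compilation is deterministic.
#'
#' @param controls list of control records whose \code{controller} field is
#'   already a compiled entity id (all targeting the same interaction).
#' @return A guard object (TRUE when \code{controls} is empty).
#' @export
compileControlCondition <- function(controls) {
  act <- sort(unique(vapply(
    Filter(function(ct) ct$sign == "activation", controls),
    `[[`, character(1), "controller")))
  inh <- sort(unique(vapply(
    Filter(function(ct) ct$sign == "inhibition", controls),
    `[[`, character(1), "controller")))
  parts <- list()
  if (length(act))
    parts <- c(parts, list(do.call(gtOr, lapply(act, gtAtom))))
  parts <- c(parts, lapply(inh, function(i) gtNot(gtAtom(i))))
  simplifyGuard(do.call(gtAnd, parts))
}

newIds <- function(state, prefix, n = 1L) {
  ids <- sprintf("%s%d", prefix, state$counter + seq_len(n))
  state$counter <- state$counter + n
  ids
}

#' Compile one conversion interaction
#'
#' A reaction with reactants \eqn{r_1..r_m} and products \eqn{p_1..p_n}
#' becomes \eqn{m \times n} guarded transitions sharing one fresh event: for
#' each (reactant, product) pair one transition reactant -> product whose
#' guard conjoins the presence atoms of all co-reactants with the control
#' condition. Because all transitions share the event, the reaction proceeds
#' only when every reactant is present and every guard holds, which encodes
#' the simultaneity of multi-substrate chemistry. A reactant-less conversion
#' (possible after catalyst reification) is compiled as a template-like
#' production: one created source input per product, guarded by the
#' catalysts.
#'
#' @param reactants,products character vectors of compiled entity ids.
#' @param controls control records with compiled \code{controller} ids.
#' @param eventId fresh event id.
#' @param tidPrefix prefix for transition ids.
#' @return List with \code{transitions} (list of transition records) and
#'   \code{createdEntities} (entity records invented here, if any).
#' @export
compileConversion <- function(reactants, products, controls, eventId,
                              tidPrefix = eventId) {
  cond <- compileControlCondition(controls)
  created <- list()
  trs <- list()
  if (length(reactants) == 0L) {
    # template-like production guarded by the catalysts
    n <- 0L
    for (p in products) {
      src <- paste0(p, "_source")
      created[[src]] <- gtEntity(src, kind = "gene")
      n <- n + 1L
      tid <- sprintf("%s_t%d", tidPrefix, n)
      trs[[tid]] <- gtTransition(tid, src, p, eventId, guard = cond)
    }
    return(list(transitions = trs, createdEntities = created))
  }
  n <- 0L
  for (r in reactants) {
    co <- setdiff(reactants, r)
    guard <- simplifyGuard(do.call(gtAnd, c(lapply(sort(co), gtAtom),
                                            list(cond))))
    for (p in products) {
      n <- n + 1L
      tid <- sprintf("%s_t%d", tidPrefix, n)
      trs[[tid]] <- gtTransition(tid, r, p, eventId, guard = guard,
                                 selfLoop = identical(r, p))
    }
  }
  list(transitions = trs, createdEntities = created)
}

#' Compile one template reaction
#'
#' Creates (if absent) a gene-kind input entity named after the template
#' with the gene suffix, then one transition gene -> product per product,
#' all sharing one fresh event. Template-reaction regulations fold into the
#' guard via [compileControlCondition()]. The gene entity is an input and
#' is therefore typically a boundary entity of the compiled model.
#'
#' @param templateId compiled id of the template (NA when the source omits
#'   it; the first product then names the gene).
#' @param products character vector of compiled product ids.
#' @param controls control records with compiled \code{controller} ids.
#' @param eventId fresh event id.
#' @param options see [compileOptions()].
#' @return As [compileConversion()]; empty when there is nothing to produce
#'   (skipped with a warning).
#' @export
compileTemplateReaction <- function(templateId, products, controls, eventId,
                                    options = compileOptions()) {
  if (length(products) == 0L && (is.null(templateId) || is.na(templateId))) {
    warning("template reaction ", eventId,
            " has no template and no product; skipped", call. = FALSE)
    return(list(transitions = list(), createdEntities = list()))
  }
  base <- if (!is.null(templateId) && !is.na(templateId)) templateId
          else products[[1L]]
  gene <- paste0(base, options$geneSuffix)
  created <- list()
  created[[gene]] <- gtEntity(gene, kind = "gene")
  cond <- compileControlCondition(controls)
  trs <- list()
  n <- 0L
  for (p in products) {
    n <- n + 1L
    tid <- sprintf("%s_t%d", eventId, n)
    trs[[tid]] <- gtTransition(tid, gene, p, eventId, guard = cond)
  }
  list(transitions = trs, createdEntities = created)
}

#' Compile one transport interaction
#'
#' Entity ids carry compartment qualifiers, so the same molecule in two
#' compartments is two entities. Compounds are paired across the membrane
#' by their unqualified molecule id, and each moved compound gets its own
#' transition on its own fresh event (independent transports), unlike the
#' shared event of a multi-reactant conversion. A transport whose two sides
#' compile to the same id (same compartment) degenerates to a single
#' self-loop transition with a warning. Transports with a biochemical
#' change are handled by [compileConversion()] on location-qualified ids.
#'
#' @param reactants,products compiled entity ids (location-qualified).
#' @param reactantBases,productBases the unqualified molecule ids used for
#'   pairing (same order as \code{reactants} / \code{products}).
#' @param controls control records with compiled \code{controller} ids.
#' @param eventPrefix prefix for the per-compound fresh events.
#' @return As [compileConversion()].
#' @export
compileTransport <- function(reactants, products, reactantBases,
                             productBases, controls,
                             eventPrefix = "transport") {
  cond <- compileControlCondition(controls)
  trs <- list()
  n <- 0L
  usedProd <- logical(length(products))
  for (i in seq_along(reactants)) {
    j <- which(!usedProd & productBases == reactantBases[[i]])
    if (length(j) == 0L) j <- which(!usedProd)
    if (length(j) == 0L) next
    j <- j[[1L]]
    usedProd[j] <- TRUE
    n <- n + 1L
    ev <- sprintf("%s_c%d", eventPrefix, n)
    tid <- sprintf("%s_t1", ev)
    self <- identical(reactants[[i]], products[[j]])
    if (self)
      warning("transport ", eventPrefix, " moves '", reactants[[i]],
              "' within one compartment", call. = FALSE)
    trs[[tid]] <- gtTransition(tid, reactants[[i]], products[[j]], ev,
                               guard = cond, selfLoop = self)
  }
  list(transitions = trs, createdEntities = list())
}

#' Compile a curated BioPAX graph into a guarded-transition model
#'
#' Applies the per-interaction compilers ([compileConversion()],
#' [compileTemplateReaction()], [compileTransport()]) over the interactions
#' in sorted-uri order, creating one fresh event per interaction occurrence,
#' then resolves unproducible cycles with [resolveCycles()]. Degradations
#' compile as input -> degradation-sink transitions. Compilation is
#' deterministic: identical input and options give byte-identical native
#' output.
#'
#' @param graph a curated [BioPAXGraph-class] (see [curateBiopax()]).
#' @param options see [compileOptions()].
#' @return A [GTModel-class]; metadata records the source and options.
#' @export
compileModel <- function(graph, options = compileOptions()) {
  idMap <- compiledIdMap(graph, options)
  pes <- graph@physicalEntities
  ents <- lapply(sort(names(pes)), function(u) {
    pe <- pes[[u]]
    gtEntity(idMap[[u]], name = pe$name, kind = peKind(pe$type),
             location = pe$location,
             modifications = pe$modifications, sourceURIs = u)
  })
  names(ents) <- vapply(ents, `[[`, character(1), "id")
  mapRefs <- function(uris) unname(idMap[intersect(uris, names(idMap))])
  ctrlFor <- function(iuri) {
    cts <- Filter(function(ct) identical(ct$controlled, iuri) &&
                    !is.na(ct$controller) && ct$controller %in% names(idMap),
                  graph@controls)
    lapply(cts, function(ct) {
      ct$controller <- idMap[[ct$controller]]
      ct
    })
  }
  trs <- list()
  state <- new.env(parent = emptyenv())
  state$counter <- 0L
  addCompiled <- function(out) {
    for (e in out$createdEntities)
      if (is.null(ents[[e$id]])) ents[[e$id]] <<- e
    trs <<- c(trs, out$transitions)
  }
  conversionTypes <- c("BiochemicalReaction", "ComplexAssembly",
                       "Conversion", "TransportWithBiochemicalReaction")
  for (iuri in sort(names(graph@interactions))) {
    it <- graph@interactions[[iuri]]
    ctrls <- ctrlFor(iuri)
    ev <- newIds(state, "h")
    if (it$type %in% conversionTypes) {
      addCompiled(compileConversion(mapRefs(it$reactants),
                                    mapRefs(it$products), ctrls, ev))
    } else if (it$type == "Degradation") {
      sink <- options$degradationSinkId
      if (is.null(ents[[sink]]))
        ents[[sink]] <- gtEntity(sink, kind = "small_molecule")
      addCompiled(compileConversion(mapRefs(it$reactants), sink, ctrls, ev))
    } else if (it$type == "Transport") {
      rb <- vapply(intersect(it$reactants, names(idMap)), function(u)
        normalizeId(pes[[u]]$name), character(1))
      pb <- vapply(intersect(it$products, names(idMap)), function(u)
        normalizeId(pes[[u]]$name), character(1))
      addCompiled(compileTransport(mapRefs(it$reactants),
                                   mapRefs(it$products), rb, pb, ctrls,
                                   eventPrefix = ev))
    } else if (it$type == "TemplateReaction") {
      tpl <- if (!is.na(it$template) && it$template %in% names(idMap))
        idMap[[it$template]] else NA_character_
      addCompiled(compileTemplateReaction(tpl, mapRefs(it$products), ctrls,
                                          ev, options))
    } else {
      warning("interaction type '", it$type, "' not compiled (", iuri, ")",
              call. = FALSE)
    }
  }
  model <- gtModel(ents, trs, metadata = list(
    source = "biopax", options = options,
    tool = paste0("gtreach ",
                  as.character(utils::packageVersion("gtreach"))),
    curation = graph@log))
  resolveCycles(model)
}
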