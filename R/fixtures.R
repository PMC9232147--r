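#' The toy guarded-transition model
#'
#' A 15-entity, 11-transition didactic model exercising every dynamical
#' feature: a two-substrate production (C from A and B on the shared event
#' h0, guarded by \code{(P or L or K) and not M} plus the co-substrate
#' atoms), a guarded supply chain (D feeds A; E feeds B under the activator
#' F), a competing event h1 that consumes N to produce P and M
#' simultaneously (M inhibits h0, so h1 is never useful for reaching C), an
#' isolated branch G -> H, and a three-entity cycle I -> J -> K -> I with
#' no external feed, which [resolveCycles()] opens with a virtual
#' cycle-initiation node on I.
#'
#' The model's documented census (15 biomolecules, 11 transitions) leaves
#' one transition unconstrained: only ten arrows are enumerable across the
#' events h0..h7. The eleventh transition here is K -> J attached to the
#' existing event h7: it creates no new producer of any queried entity and
#' leaves all documented query outcomes unchanged.
#'
#' @return A [GTModel-class] with 15 entities and 11 transitions (cycles
#'   NOT yet resolved; [solveQuery()] resolves them on the fly).
#' @examples
#' m <- buildToyModel()
#' modelStats(m)$entities      # 15
#' boundaryEntities(m)         # D E F G L N
#' @export
buildToyModel <- function() {
  ids <- c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J", "K", "L",
           "M", "N", "P")
  ents <- lapply(ids, gtEntity)
  h0guard <- function(co) gtAnd(gtAtom(co), gtOr("P", "L", "K"), gtNot("M"))
  trs <- list(
    gtTransition("t1",  "D", "A", "h2"),
    gtTransition("t2",  "E", "B", "h3", guard = gtAtom("F")),
    gtTransition("t3",  "A", "C", "h0", guard = h0guard("B")),
    gtTransition("t4",  "B", "C", "h0", guard = h0guard("A")),
    gtTransition("t5",  "N", "P", "h1"),
    gtTransition("t6",  "N", "M", "h1"),
    gtTransition("t7",  "G", "H", "h4"),
    gtTransition("t8",  "I", "J", "h5"),
    gtTransition("t9",  "J", "K", "h6"),
    gtTransition("t10", "K", "I", "h7"),
    gtTransition("t11", "K", "J", "h7"))
  gtModel(ents, trs, metadata = list(source = "toy-fixture"))
}

biopaxHeader <- function() {
  paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"\n',
    '         xmlns:bp="http://www.biopax.org/release/biopax-level3.owl#"\n',
    '         xmlns:owl="http://www.w3.org/2002/07/owl#"\n',
    '         xml:base="http://example.org/gtreach#">\n')
}

xmlEsc <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

bpResource <- function(prop, refs)
  paste0(vapply(refs, function(r)
    sprintf('  <bp:%s rdf:resource="%s"/>\n', prop, r), character(1)),
    collapse = "")

bpPE <- function(class, id, name, location = NULL, members = character(0),
                 components = character(0)) {
  paste0(sprintf(' <bp:%s rdf:ID="%s">\n', class, id),
         sprintf('  <bp:displayName>%s</bp:displayName>\n', xmlEsc(name)),
         if (!is.null(location))
           sprintf('  <bp:cellularLocation rdf:resource="#%s"/>\n',
                   location),
         bpResource("memberPhysicalEntity", members),
         bpResource("component", components),
         sprintf(' </bp:%s>\n', class))
}

bpLoc <- function(id, term)
  sprintf(paste0(' <bp:CellularLocationVocabulary rdf:ID="%s">\n',
                 '  <bp:term>%s</bp:term>\n',
                 ' </bp:CellularLocationVocabulary>\n'), id, xmlEsc(term))

bpRxn <- function(class, id, left = character(0), right = character(0)) {
  paste0(sprintf(' <bp:%s rdf:ID="%s">\n', class, id),
         bpResource("left", left), bpResource("right", right),
         sprintf(' </bp:%s>\n', class))
}

bpTemplate <- function(id, template, products) {
  paste0(sprintf(' <bp:TemplateReaction rdf:ID="%s">\n', id),
         if (!is.null(template))
           sprintf('  <bp:template rdf:resource="%s"/>\n', template),
         bpResource("product", products),
         ' </bp:TemplateReaction>\n')
}

bpControl <- function(class, id, controller, controlled,
                      sign = "ACTIVATION") {
  paste0(sprintf(' <bp:%s rdf:ID="%s">\n', class, id),
         sprintf('  <bp:controller rdf:resource="%s"/>\n', controller),
         sprintf('  <bp:controlled rdf:resource="%s"/>\n', controlled),
         sprintf('  <bp:controlType>%s</bp:controlType>\n', sign),
         sprintf(' </bp:%s>\n', class))
}

#' Minimal BioPAX documents for the four rewriting cases
#'
#' Each case is a hand-sized, valid BioPAX Level-3 RDF/XML document
#' realising one rewriting pattern:
#' \describe{
#' \item{complex_assembly}{PKG + cGMP assemble into a complex; compiles to
#'   two transitions sharing one event, each guarded by the other
#'   substrate.}
#' \item{catalysis}{4MTOBUT decomposes into L-Met and 2-Oxoacid under Asat
#'   catalysis; two transitions, one event, Asat in both guards.}
#' \item{class_collapse}{a generic class A = \{A1, A2\} whose members never
#'   act individually; the compiled path uses the single compound A.}
#' \item{class_expand}{a class Cx26/Cx32 transported between compartments
#'   while its members assemble individually; the transport is replicated
#'   per member on independent events.}
#' }
#'
#' @param case one of \code{"complex_assembly"}, \code{"catalysis"},
#'   \code{"class_collapse"}, \code{"class_expand"}.
#' @param path optional file to write; the document string is returned
#'   invisibly then.
#' @return The OWL document as a character string (invisibly when
#'   \code{path} is given).
#' @export
buildBiopaxCase <- function(case = c("complex_assembly", "catalysis",
                                     "class_collapse", "class_expand"),
                            path = NULL) {
  case <- match.arg(case)
  body <- switch(case,
    complex_assembly = paste0(
      bpPE("Protein", "PKG", "PKG"),
      bpPE("SmallMolecule", "cGMP", "cGMP"),
      bpPE("Complex", "PKG_cGMP", "PKG_cGMP",
           components = c("#PKG", "#cGMP")),
      bpRxn("ComplexAssembly", "assembly1", left = c("#PKG", "#cGMP"),
            right = "#PKG_cGMP")),
    catalysis = paste0(
      bpPE("SmallMolecule", "MTOB", "4MTOBUT"),
      bpPE("SmallMolecule", "LMet", "L_Met"),
      bpPE("SmallMolecule", "Oxoacid", "Oxoacid_2"),
      bpPE("Protein", "Asat", "Asat"),
      bpRxn("BiochemicalReaction", "rxn1", left = "#MTOB",
            right = c("#LMet", "#Oxoacid")),
      bpControl("Catalysis", "cat1", "#Asat", "#rxn1")),
    class_collapse = paste0(
      bpPE("Protein", "A1", "A1"),
      bpPE("Protein", "A2", "A2"),
      bpPE("Protein", "A", "A", members = c("#A1", "#A2")),
      bpPE("Protein", "B", "B"),
      bpPE("Complex", "AB", "AB", components = c("#A", "#B")),
      bpPE("Protein", "C", "C"),
      bpPE("Protein", "D", "D"),
      bpRxn("ComplexAssembly", "assembly1", left = c("#A", "#B"),
            right = "#AB"),
      bpRxn("BiochemicalReaction", "rxn1", left = "#AB",
            right = c("#C", "#D"))),
    class_expand = paste0(
      bpLoc("locER", "endoplasmic reticulum membrane"),
      bpLoc("locERGI", "endoplasmic reticulum-Golgi intermediate compartment"),
      bpPE("Protein", "Cx26_ER", "Connexin26", location = "locER"),
      bpPE("Protein", "Cx32_ER", "Connexin32", location = "locER"),
      bpPE("Protein", "CxClass_ER", "Cx26_Cx32", location = "locER",
           members = c("#Cx26_ER", "#Cx32_ER")),
      bpPE("Protein", "Cx26_ERGI", "Connexin26", location = "locERGI"),
      bpPE("Protein", "Cx32_ERGI", "Connexin32", location = "locERGI"),
      bpPE("Protein", "CxClass_ERGI", "Cx26_Cx32", location = "locERGI",
           members = c("#Cx26_ERGI", "#Cx32_ERGI")),
      bpPE("Complex", "CxComplex", "Cx26_Cx32_complex",
           location = "locERGI",
           components = c("#Cx26_ERGI", "#Cx32_ERGI")),
      bpRxn("Transport", "transport1", left = "#CxClass_ER",
            right = "#CxClass_ERGI"),
      bpRxn("ComplexAssembly", "assembly1",
            left = c("#Cx26_ERGI", "#Cx32_ERGI"), right = "#CxComplex")))
  doc <- paste0(biopaxHeader(), body, "</rdf:RDF>\n")
  if (!is.null(path)) {
    writeLines(doc, path, useBytes = TRUE)
    return(invisible(doc))
  }
  doc
}

#' Specification for the synthetic BioPAX generator
#'
#' @param nConversions number of uncontrolled-or-controlled biochemical
#'   reactions.
#' @param reactantRange,productRange inclusive ranges for reactant /
#'   product multiplicities m and n (each reaction compiles to m x n
#'   transitions).
#' @param catalysisProb probability a conversion gets an activating
#'   Catalysis by a fresh protein.
#' @param inhibitionProb probability a conversion additionally gets an
#'   inhibiting Control by a fresh protein.
#' @param duplicateGroups number of injected duplicate-entity groups.
#' @param duplicateGroupSize entities per duplicate group (>= 2).
#' @param collapseClasses number of generic classes whose members stay
#'   anonymous (collapse case).
#' @param expandClasses number of generic classes whose members also act
#'   individually (expansion case).
#' @param plantedPathLength length of a planted boundary-to-target chain of
#'   1-to-1 reactions guaranteeing a known query solution (0 disables).
#' @param seed integer seed; generation is reproducible and documents are
#'   diffable.
#' @return Named list of class \code{"synthSpec"}.
#' @export
synthSpec <- function(nConversions = 4, reactantRange = c(1, 2),
                      productRange = c(1, 2), catalysisProb = 0.3,
                      inhibitionProb = 0.1, duplicateGroups = 0,
                      duplicateGroupSize = 2, collapseClasses = 0,
                      expandClasses = 0, plantedPathLength = 0, seed = 1) {
  if (nConversions == 0 && plantedPathLength == 0 && collapseClasses == 0 &&
      expandClasses == 0)
    stop("infeasible spec: no interactions requested")
  structure(list(nConversions = nConversions,
                 reactantRange = reactantRange,
                 productRange = productRange,
                 catalysisProb = catalysisProb,
                 inhibitionProb = inhibitionProb,
                 duplicateGroups = duplicateGroups,
                 duplicateGroupSize = duplicateGroupSize,
                 collapseClasses = collapseClasses,
                 expandClasses = expandClasses,
                 plantedPathLength = plantedPathLength,
                 seed = seed), class = "synthSpec")
}

SYNTH_WORDS <- c("apok", "brilin", "cadrin", "dextrin", "ersin", "fabrin",
                 "gantin", "hepsin", "irin", "jasin", "kelin", "lumin",
                 "mersin", "noblin", "orin", "persin", "quolin", "rasin",
                 "selin", "tarin", "ursin", "vexin", "wolin", "xanin",
                 "yarin", "zelin")

#' Generate a seeded synthetic BioPAX document with ground truth
#'
#' Emits a reproducible BioPAX Level-3 document realising the requested mix
#' of reactions, controls, duplicates and generic classes, together with a
#' ground-truth record of what curation and compilation must produce:
#' expected post-curation entity count, duplicate groups, compiled
#' transition/event counts (by the m x n law), and, when a path is planted,
#' the boundary id whose activation provably reaches the target id.
#'
#' @param spec a [synthSpec()].
#' @param path optional file to write the OWL document to.
#' @return List with \code{doc} (OWL string) and \code{groundTruth} (list
#'   with \code{peCount}, \code{peAfterCuration}, \code{duplicatedEntities},
#'   \code{duplicateGroups}, \code{transitions}, \code{events},
#'   \code{plantedBoundary}, \code{plantedTarget}).
#' @export
generateBiopax <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "synthSpec"))
  set.seed(spec$seed)
  body <- character(0)
  peCount <- 0L; nameIdx <- 0L
  newName <- function() {
    nameIdx <<- nameIdx + 1L
    w <- SYNTH_WORDS[((nameIdx - 1L) %% length(SYNTH_WORDS)) + 1L]
    sprintf("%s%03d", w, nameIdx)
  }
  emitPE <- function(class, id, name, ...) {
    body <<- c(body, bpPE(class, id, name, ...))
    peCount <<- peCount + 1L
    id
  }
  freshProtein <- function() {
    nm <- newName()
    emitPE("Protein", nm, nm)
  }
  transitionsExpected <- 0L; eventsExpected <- 0L
  rint <- function(range) {
    v <- seq(range[1], range[2])
    v[sample.int(length(v), 1L)]
  }
  rxnIdx <- 0L; ctlIdx <- 0L
  addConversion <- function(reactIds, prodIds, catalyst = NULL,
                            inhibitor = NULL) {
    # force args first: they may emit entities into `body` themselves
    force(reactIds); force(prodIds); force(catalyst); force(inhibitor)
    rxnIdx <<- rxnIdx + 1L
    id <- sprintf("rxn%03d", rxnIdx)
    body <<- c(body, bpRxn("BiochemicalReaction", id,
                           left = paste0("#", reactIds),
                           right = paste0("#", prodIds)))
    if (!is.null(catalyst)) {
      ctlIdx <<- ctlIdx + 1L
      body <<- c(body, bpControl("Catalysis", sprintf("ctl%03d", ctlIdx),
                                 paste0("#", catalyst), paste0("#", id)))
    }
    if (!is.null(inhibitor)) {
      ctlIdx <<- ctlIdx + 1L
      body <<- c(body, bpControl("Control", sprintf("ctl%03d", ctlIdx),
                                 paste0("#", inhibitor), paste0("#", id),
                                 sign = "INHIBITION"))
    }
    transitionsExpected <<- transitionsExpected +
      length(reactIds) * length(prodIds)
    eventsExpected <<- eventsExpected + 1L
    id
  }
  for (i in seq_len(spec$nConversions)) {
    m <- rint(spec$reactantRange)
    n <- rint(spec$productRange)
    reacts <- vapply(seq_len(m), function(j) freshProtein(), character(1))
    prods <- vapply(seq_len(n), function(j) freshProtein(), character(1))
    cat <- if (stats::runif(1) < spec$catalysisProb) freshProtein()
    inh <- if (stats::runif(1) < spec$inhibitionProb) freshProtein()
    addConversion(reacts, prods, cat, inh)
  }
  plantedBoundary <- plantedTarget <- NA_character_
  if (spec$plantedPathLength > 0) {
    chain <- vapply(seq_len(spec$plantedPathLength + 1L),
                    function(j) freshProtein(), character(1))
    for (j in seq_len(spec$plantedPathLength))
      addConversion(chain[j], chain[j + 1L])
    plantedBoundary <- chain[1L]
    plantedTarget <- chain[length(chain)]
  }
  dupTotal <- 0L
  for (g in seq_len(spec$duplicateGroups)) {
    nm <- newName()
    for (j in seq_len(spec$duplicateGroupSize))
      emitPE("Protein", sprintf("%s_copy%d", nm, j), nm)
    dupTotal <- dupTotal + spec$duplicateGroupSize
  }
  collapsedMembers <- 0L
  for (g in seq_len(spec$collapseClasses)) {
    m1 <- freshProtein(); m2 <- freshProtein()
    cls <- newName()
    emitPE("Protein", cls, cls, members = paste0("#", c(m1, m2)))
    addConversion(cls, freshProtein())
    collapsedMembers <- collapsedMembers + 2L
  }
  expandExtra <- 0L
  for (g in seq_len(spec$expandClasses)) {
    m1 <- freshProtein(); m2 <- freshProtein()
    addConversion(m1, freshProtein())
    addConversion(m2, freshProtein())
    cls <- newName()
    emitPE("Protein", cls, cls, members = paste0("#", c(m1, m2)))
    addConversion(cls, freshProtein())
    # the class reaction is replicated once per member: one extra
    # transition and event beyond the Sigma m x n already counted
    expandExtra <- expandExtra + 1L
  }
  transitionsExpected <- transitionsExpected + expandExtra
  eventsExpected <- eventsExpected + expandExtra
  doc <- paste0(biopaxHeader(), paste0(body, collapse = ""), "</rdf:RDF>\n")
  if (!is.null(path)) writeLines(doc, path, useBytes = TRUE)
  # each duplicate group of size s keeps 1; collapse deletes the 2 members;
  # expansion deletes the class itself, members stay
  gt <- list(
    peCount = peCount,
    peAfterCuration = peCount -
      spec$duplicateGroups * (spec$duplicateGroupSize - 1L) -
      collapsedMembers - spec$expandClasses,
    duplicatedEntities = dupTotal,
    duplicateGroups = spec$duplicateGroups,
    transitions = transitionsExpected,
    events = eventsExpected,
    plantedBoundary = plantedBoundary,
    plantedTarget = plantedTarget)
  list(doc = doc, groundTruth = gt)
}

#' Seeded random guarded-transition models
#'
#' Desk-scale random models for property testing: random single- or
#' two-transition events over a fixed entity set, with optional positive
#' and negative guard atoms. Always structurally valid; may contain cycles
#' (resolve with [resolveCycles()] before querying).
#'
#' @param seed integer seed.
#' @param nEntities number of entities (ids \code{e01..}).
#' @param nEvents number of events; each has 1 or 2 transitions.
#' @param pTwoTransitions probability an event carries two transitions.
#' @param pGuardAtom probability a transition gets one positive guard atom.
#' @param pNegGuard probability a transition additionally gets one negated
#'   guard atom.
#' @return A [GTModel-class].
#' @export
randomGTModel <- function(seed, nEntities = 10, nEvents = 6,
                          pTwoTransitions = 0.3, pGuardAtom = 0.4,
                          pNegGuard = 0.15) {
  set.seed(seed)
  ids <- sprintf("e%02d", seq_len(nEntities))
  ents <- lapply(ids, gtEntity)
  trs <- list()
  tid <- 0L
  for (h in seq_len(nEvents)) {
    ntr <- if (stats::runif(1) < pTwoTransitions) 2L else 1L
    for (j in seq_len(ntr)) {
      io <- sample(ids, 2L)
      parts <- list()
      if (stats::runif(1) < pGuardAtom)
        parts <- c(parts, list(gtAtom(sample(setdiff(ids, io), 1L))))
      if (stats::runif(1) < pNegGuard)
        parts <- c(parts, list(gtNot(sample(setdiff(ids, io), 1L))))
      guard <- if (length(parts)) do.call(gtAnd, parts) else gtTrue()
      tid <- tid + 1L
      trs[[tid]] <- gtTransition(sprintf("t%02d", tid), io[1L], io[2L],
                                 sprintf("h%02d", h), guard = guard)
    }
  }
  gtModel(ents, trs, metadata = list(source = sprintf("random(seed=%d)",
                                                      seed)))
}
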