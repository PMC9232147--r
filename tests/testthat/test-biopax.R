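test_that("loading captures entities, interactions and controls", {
  g <- loadBiopax(writeBiopaxCase("complex_assembly"))
  expect_s4_class(g, "BioPAXGraph")
  expect_length(g@physicalEntities, 3L)
  expect_length(g@interactions, 1L)
  expect_length(g@controls, 0L)
  it <- g@interactions[[1]]
  expect_equal(it$type, "ComplexAssembly")
  expect_length(it$reactants, 2L)

  g2 <- loadBiopax(writeBiopaxCase("catalysis"))
  expect_length(g2@physicalEntities, 4L)
  expect_length(g2@interactions, 1L)
  expect_length(g2@controls, 1L)
  expect_equal(g2@controls[[1]]$sign, "activation")

  # empty RDF document parses to an empty graph
  f <- tempfile(fileext = ".owl")
  writeLines(paste0('<rdf:RDF xmlns:rdf=',
                    '"http://www.w3.org/1999/02/22-rdf-syntax-ns#"/>'), f)
  g3 <- loadBiopax(f)
  expect_length(g3@physicalEntities, 0L)

  # gzip-compressed input is accepted
  fz <- tempfile(fileext = ".owl.gz")
  con <- gzfile(fz, "w")
  writeLines(buildBiopaxCase("catalysis"), con)
  close(con)
  expect_length(loadBiopax(fz)@physicalEntities, 4L)

  expect_error(loadBiopax(tempfile()), "cannot read")
  fbad <- tempfile(fileext = ".owl")
  writeLines("this is not xml", fbad)
  expect_error(loadBiopax(fbad), "parse error")
})

test_that("duplicate entities merge on the exact similarity tuple", {
  mk <- function(uri, name, loc = "cytosol")
    list(uri = uri, type = "Protein", name = name, location = loc,
         modifications = character(0), members = character(0),
         components = character(0))
  rxn <- list(uri = "#r1", type = "BiochemicalReaction",
              reactants = "#p1", products = "#p2",
              template = NA_character_)
  g <- new("BioPAXGraph",
           physicalEntities = setNames(
             list(mk("#p1", "ALPHA"), mk("#p2", "ALPHA"),
                  mk("#p3", "ALPHA", loc = "nucleus")),
             c("#p1", "#p2", "#p3")),
           interactions = list(`#r1` = rxn), controls = list())
  out <- mergeDuplicateEntities(g)
  # same name+location merge; different location does not
  expect_equal(out$report$groupCount, 1L)
  expect_equal(out$report$duplicatedEntities, 2L)
  expect_length(out$graph@physicalEntities, 2L)
  # references rewritten to the representative
  it <- out$graph@interactions[[1]]
  expect_equal(it$reactants, "#p1")
  expect_equal(it$products, "#p1")

  # synthetic graph with 6 duplicates in 2 groups
  sp <- synthSpec(nConversions = 1, duplicateGroups = 2,
                  duplicateGroupSize = 3, seed = 7)
  f <- tempfile(fileext = ".owl")
  generateBiopax(sp, f)
  rep2 <- mergeDuplicateEntities(loadBiopax(f))$report
  expect_equal(rep2$duplicatedEntities, 6L)
  expect_equal(rep2$groupCount, 2L)

  # no duplicates: empty report
  sp0 <- synthSpec(nConversions = 1, seed = 7)
  f0 <- tempfile(fileext = ".owl")
  generateBiopax(sp0, f0)
  expect_equal(mergeDuplicateEntities(loadBiopax(f0))$report$groupCount, 0L)
})

test_that("reactant-products are reified as catalysts", {
  mk <- function(uri) list(uri = uri, type = "Protein", name = uri,
                           location = NA_character_,
                           modifications = character(0),
                           members = character(0),
                           components = character(0))
  g <- new("BioPAXGraph",
    physicalEntities = setNames(lapply(c("#X", "#S", "#P"), mk),
                                c("#X", "#S", "#P")),
    interactions = list(`#r1` = list(
      uri = "#r1", type = "BiochemicalReaction",
      reactants = c("#X", "#S"), products = c("#X", "#P"),
      template = NA_character_)),
    controls = list())
  out <- reifyReactantProducts(g)
  it <- out@interactions[[1]]
  expect_equal(it$reactants, "#S")          # X removed from reactants
  expect_equal(sort(it$products), c("#P", "#X"))
  expect_length(out@controls, 1L)
  ct <- out@controls[[1]]
  expect_equal(ct$type, "Catalysis")
  expect_equal(ct$controller, "#X")
  expect_equal(ct$sign, "activation")
  # disjoint reactants/products stay unchanged
  g2 <- g
  g2@interactions[[1]]$products <- "#P"
  expect_length(reifyReactantProducts(g2)@controls, 0L)
  # sole reactant equals sole product: reactant list emptied and flagged
  g3 <- g
  g3@interactions[[1]]$reactants <- "#X"
  g3@interactions[[1]]$products <- "#X"
  out3 <- reifyReactantProducts(g3)
  expect_length(out3@interactions[[1]]$reactants, 0L)
  expect_equal(out3@log$reify$reactantLessInteractions, "#r1")
})

test_that("unsupported interaction and control classes are dropped", {
  f <- tempfile(fileext = ".owl")
  writeLines(paste0(
    gtreach:::biopaxHeader(),
    gtreach:::bpPE("Protein", "P1", "P1"),
    gtreach:::bpPE("Protein", "P2", "P2"),
    gtreach:::bpPE("Rna", "R1", "R1"),
    gtreach:::bpRxn("BiochemicalReaction", "rxn1", "#P1", "#P2"),
    gtreach:::bpRxn("MolecularInteraction", "mi1", "#P1", "#P2"),
    gtreach:::bpControl("Modulation", "mod1", "#P2", "#rxn1"),
    "</rdf:RDF>"), f)
  g <- loadBiopax(f)
  out <- dropUnsupported(g)
  expect_equal(vapply(out@interactions, `[[`, character(1), "type"),
               c(`#rxn1` = "BiochemicalReaction"))
  expect_length(out@controls, 0L)
  expect_equal(out@log$drop$modulationsRemoved, 1L)
  # the default profile keeps Dna/Rna entities, acsn does not
  expect_true("#R1" %in% names(out@physicalEntities))
  out2 <- dropUnsupported(g, profile = "acsn")
  expect_false("#R1" %in% names(out2@physicalEntities))
})

test_that("generic classes collapse or expand by member context", {
  # collapse: members never act individually; compiled path uses A itself
  g <- loadBiopax(writeBiopaxCase("class_collapse"))
  cur <- expandGenericClasses(dropUnsupported(g))
  expect_false("#A1" %in% names(cur@physicalEntities))
  expect_true("#A" %in% names(cur@physicalEntities))
  expect_equal(cur@log$expand$collapsed, 1L)
  # expansion: transport replicated per member on the member entities
  g2 <- loadBiopax(writeBiopaxCase("class_expand"))
  cur2 <- expandGenericClasses(dropUnsupported(g2))
  expect_equal(cur2@log$expand$expanded, 1L)
  tr <- Filter(function(it) it$type == "Transport", cur2@interactions)
  expect_length(tr, 2L)
  lefts <- sort(vapply(tr, function(it) it$reactants, character(1)))
  expect_equal(unname(lefts), c("#Cx26_ER", "#Cx32_ER"))
  # a class with members but no interactions is removed outright
  f <- tempfile(fileext = ".owl")
  writeLines(paste0(
    gtreach:::biopaxHeader(),
    gtreach:::bpPE("Protein", "M1", "M1"),
    gtreach:::bpPE("Protein", "M2", "M2"),
    gtreach:::bpPE("Protein", "CL", "CL", members = c("#M1", "#M2")),
    "</rdf:RDF>"), f)
  out <- expandGenericClasses(loadBiopax(f))
  expect_false("#CL" %in% names(out@physicalEntities))
  expect_equal(out@log$expand$removedUninvolved, 1L)
  # cyclic membership is a hard error
  fc <- tempfile(fileext = ".owl")
  writeLines(paste0(
    gtreach:::biopaxHeader(),
    gtreach:::bpPE("Protein", "M1", "M1", members = "#M2"),
    gtreach:::bpPE("Protein", "M2", "M2", members = "#M1"),
    "</rdf:RDF>"), fc)
  expect_error(expandGenericClasses(loadBiopax(fc)), "cyclic")
})

test_that("the curation pipeline is idempotent on its own output", {
  for (case in c("class_collapse", "class_expand", "catalysis")) {
    cur1 <- curateBiopax(loadBiopax(writeBiopaxCase(case)))$graph
    cur2 <- curateBiopax(cur1)$graph
    expect_setequal(names(cur2@physicalEntities),
                    names(cur1@physicalEntities))
    expect_setequal(names(cur2@interactions), names(cur1@interactions))
    expect_length(gtreach:::danglingRefs(cur1), 0L)
  }
})
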