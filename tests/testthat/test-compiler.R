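test_that("control conditions fold activators and inhibitors", {
  ctl <- function(id, sign) list(controller = id, sign = sign)
  g <- compileControlCondition(list(ctl("P", "activation"),
                                    ctl("L", "activation"),
                                    ctl("K", "activation"),
                                    ctl("M", "inhibition")))
  expect_equal(formulaToString(g), "(K or L or P) and not M")
  expect_equal(formulaToString(compileControlCondition(list())), "true")
  expect_equal(formulaToString(compileControlCondition(
    list(ctl("M", "inhibition")))), "not M")
  expect_equal(formulaToString(compileControlCondition(
    list(ctl("E", "activation")))), "E")
})

test_that("conversions compile to m x n transitions on one shared event", {
  # A + B -> C + D catalysed by E: four guarded transitions
  out <- compileConversion(c("A", "B"), c("C", "D"),
                           list(list(controller = "E",
                                     sign = "activation")), "h1")
  expect_length(out$transitions, 4L)
  expect_equal(unique(vapply(out$transitions, `[[`, character(1), "event")),
               "h1")
  t1 <- out$transitions[[1]]
  expect_equal(c(t1$input, t1$output), c("A", "C"))
  expect_equal(formulaToString(t1$guard), "B and E")
  # single reactant, single product, no controls: guard TRUE
  out2 <- compileConversion("A", "B", list(), "h2")
  expect_length(out2$transitions, 1L)
  expect_equal(formulaToString(out2$transitions[[1]]$guard), "true")
  # reactant-less conversion: template-like production guarded by catalyst
  out3 <- compileConversion(character(0), "X",
                            list(list(controller = "X",
                                      sign = "activation")), "h3")
  expect_length(out3$transitions, 1L)
  expect_equal(out3$transitions[[1]]$input, "X_source")
  expect_equal(formulaToString(out3$transitions[[1]]$guard), "X")
  expect_equal(out3$createdEntities[["X_source"]]$kind, "gene")
})

test_that("the m x n transition law holds over seeded random conversions", {
  set.seed(42)
  for (i in 1:200) {
    m <- sample(1:4, 1)
    n <- sample(1:3, 1)
    reacts <- sprintf("r%d_%d", i, seq_len(m))
    prods <- sprintf("p%d_%d", i, seq_len(n))
    nctl <- sample(0:2, 1)
    ctls <- if (nctl) lapply(seq_len(nctl), function(j)
      list(controller = sprintf("c%d_%d", i, j),
           sign = sample(c("activation", "inhibition"), 1))) else list()
    out <- compileConversion(reacts, prods, ctls, sprintf("h%d", i))
    expect_length(out$transitions, m * n)
    expect_equal(unique(vapply(out$transitions, `[[`, character(1),
                               "event")), sprintf("h%d", i))
    # every activator appears as an atom, every inhibitor under NOT
    for (tr in out$transitions) {
      atoms <- guardAtoms(tr$guard)
      for (ct in ctls)
        expect_true(ct$controller %in% atoms)
      if (length(ctls) == 0 && m == 1)
        expect_equal(tr$guard$op, "true")
    }
  }
})

test_that("template reactions create gene inputs and fold regulators", {
  out <- compileTemplateReaction("SPP1", "SPP1_prot",
                                 list(list(controller = "p53",
                                           sign = "activation")), "h1")
  expect_length(out$transitions, 1L)
  tr <- out$transitions[[1]]
  expect_equal(tr$input, "SPP1_gene")
  expect_equal(tr$output, "SPP1_prot")
  expect_equal(formulaToString(tr$guard), "p53")
  expect_equal(out$createdEntities[["SPP1_gene"]]$kind, "gene")
  # no regulators: guard TRUE; two products share one event
  out2 <- compileTemplateReaction("G", c("P1", "P2"), list(), "h2")
  expect_length(out2$transitions, 2L)
  expect_equal(unique(vapply(out2$transitions, `[[`, character(1),
                             "event")), "h2")
  expect_equal(formulaToString(out2$transitions[[1]]$guard), "true")
  expect_warning(
    out3 <- compileTemplateReaction(NA_character_, character(0), list(),
                                    "h3"),
    "skipped")
  expect_length(out3$transitions, 0L)
})

test_that("transports move each compound on its own event", {
  out <- compileTransport(c("Cx26_ER", "Cx32_ER"),
                          c("Cx26_ERGI", "Cx32_ERGI"),
                          c("Cx26", "Cx32"), c("Cx26", "Cx32"),
                          list(), eventPrefix = "h9")
  expect_length(out$transitions, 2L)
  evs <- vapply(out$transitions, `[[`, character(1), "event")
  expect_length(unique(evs), 2L)  # independent events, unlike conversions
  io <- vapply(out$transitions, function(tr)
    paste(tr$input, tr$output, sep = ">"), character(1))
  expect_setequal(unname(io), c("Cx26_ER>Cx26_ERGI", "Cx32_ER>Cx32_ERGI"))
  # same-compartment transport degenerates to a flagged self-loop
  expect_warning(
    out2 <- compileTransport("A_cyt", "A_cyt", "A", "A", list(), "h1"),
    "within one compartment")
  expect_length(out2$transitions, 1L)
  expect_true(out2$transitions[[1]]$selfLoop)
})

test_that("the rewriting fixtures compile to their documented structure", {
  compiled <- function(case)
    compileModel(curateBiopax(loadBiopax(writeBiopaxCase(case)))$graph)
  # complex assembly: 2 transitions, one shared event, cross guards
  m <- compiled("complex_assembly")
  st <- modelStats(m)
  expect_equal(st$transitions, 2L)
  expect_equal(st$events, 1L)
  guards <- vapply(transitions(m), function(tr)
    formulaToString(tr$guard), character(1))
  expect_setequal(unname(guards), c("PKG", "cGMP"))
  # catalysis: 2 transitions sharing one event and the Asat guard
  m2 <- compiled("catalysis")
  expect_equal(modelStats(m2)$transitions, 2L)
  expect_equal(modelStats(m2)$events, 1L)
  for (tr in transitions(m2))
    expect_true("Asat" %in% guardAtoms(tr$guard))
  # collapse: the class A survives as a single compound, members are gone
  m3 <- compiled("class_collapse")
  expect_true("A" %in% entityIds(m3))
  expect_false(any(c("A1", "A2") %in% entityIds(m3)))
  # expansion: per-member transports on distinct events
  m4 <- compiled("class_expand")
  tp <- Filter(function(tr) grepl("reticulum_membrane$", tr$input),
               transitions(m4))
  expect_length(tp, 2L)
  expect_length(unique(vapply(tp, `[[`, character(1), "event")), 2L)
})

test_that("compilation is deterministic and matches closed-form counts", {
  sp <- synthSpec(nConversions = 5, reactantRange = c(2, 2),
                  productRange = c(1, 1), catalysisProb = 0, seed = 11)
  f <- tempfile(fileext = ".owl")
  gt <- generateBiopax(sp, f)$groundTruth
  m <- compileModel(curateBiopax(loadBiopax(f))$graph)
  st <- modelStats(m)
  expect_equal(st$transitions, 10L)  # 2 x 1 x 5
  expect_equal(st$events, 5L)
  expect_equal(st$transitions, gt$transitions)
  # byte-identical native output for identical input and options
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  writeGTModel(m, f1)
  writeGTModel(compileModel(curateBiopax(loadBiopax(f))$graph), f2)
  expect_identical(readLines(f1), readLines(f2))
  # empty graph compiles to an empty model
  e <- tempfile(fileext = ".owl")
  writeLines(paste0('<rdf:RDF xmlns:rdf=',
                    '"http://www.w3.org/1999/02/22-rdf-syntax-ns#"/>'), e)
  expect_equal(modelStats(compileModel(
    curateBiopax(loadBiopax(e))$graph))$entities, 0L)
})
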