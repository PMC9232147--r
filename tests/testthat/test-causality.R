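test_that("the bounded unfolding is satisfiable exactly when reachable", {
  m <- resolveCycles(buildToyModel())
  sat <- function(query, k) {
    enc <- encodeUnfolding(m, query, k)
    satSolve(enc$nvars, enc$clauses)$sat
  }
  expect_true(sat("C", 3))            # D->A; E->B; h0 with L
  expect_false(sat("C", 1))           # two production layers needed
  expect_false(sat("C and not A", 6)) # A is required to produce C
  # k = 0: a boundary atom can simply be active initially
  expect_true(sat("D", 0))
  expect_false(sat("A", 0))           # non-boundary places start inactive
  expect_error(encodeUnfolding(m, "nosuch", 2), "nosuch")
})

test_that("toy-model queries return the documented controller sets", {
  m <- buildToyModel()
  r1 <- solveQuery(m, "C")
  expect_length(gtSolutions(r1), 2L)
  expect_true(sameSetOfSets(boundarySets(r1),
    list(c("D", "E", "F", "L"),
         c("D", "E", "F", "cycle_initiation_node_1"))))
  expect_equal(controllers(r1), c("D", "E", "F", "I", "L"))
  expect_true("I" %in% trajectoryEntities(r1))   # reached via the cycle
  expect_false(isCapped(r1))

  expect_length(gtSolutions(solveQuery(m, "C and not A")), 0L)
  expect_length(gtSolutions(solveQuery(m, "C and N")), 0L)

  r5 <- solveQuery(m, "C and not J")
  expect_length(gtSolutions(r5), 1L)
  expect_equal(controllers(r5), c("D", "E", "F", "L"))

  r4 <- solveQuery(m, "C and H")
  expect_equal(controllers(r4), c("D", "E", "F", "G", "I", "L"))

  expect_equal(solveQuery(m, "C and not C")@status,
               "unreachable within horizon")
  expect_error(solveQuery(m, "C and XX"), "XX")
})

test_that("witness schedules replay legally and satisfy the query", {
  m <- resolveCycles(buildToyModel())
  for (q in c("C", "C and not J", "C and H")) {
    res <- solveQuery(m, q, resolve = FALSE)
    for (sol in gtSolutions(res)) {
      states <- list(sol@boundary)
      s <- sol@boundary
      for (t in seq_along(sol@schedule)) {
        s <- step(m, s, sol@schedule[[t]])     # errors if not enabled
        states[[t + 1]] <- s
      }
      expect_true(queryHoldsAt(q, states, sol@horizon))
      active <- setdiff(unique(unlist(states)), res@boundary)
      expect_setequal(sol@intermediates, active)
    }
  }
})

test_that("every solution is minimal: removing any element breaks it", {
  m <- resolveCycles(buildToyModel())
  for (q in c("C", "C and not J", "C and H")) {
    res <- solveQuery(m, q, resolve = FALSE)
    for (sol in gtSolutions(res)) {
      for (b in sol@boundary) {
        expect_false(reachesQuery(m, setdiff(sol@boundary, b), q,
                                  res@maxHorizon),
                     info = paste(q, "minus", b))
      }
    }
  }
})

test_that("solver and brute-force oracle agree on random models", {
  # the two routes share nothing: CNF unfolding vs explicit simulation
  mismatches <- 0L
  for (seed in 1:50) {
    m <- resolveCycles(randomGTModel(seed, nEntities = 9 + seed %% 4,
                                     nEvents = 6 + seed %% 3))
    nonB <- setdiff(entityIds(m), boundaryEntities(m))
    if (length(nonB) == 0) next
    target <- nonB[1 + seed %% length(nonB)]
    query <- if (seed %% 3 == 0 && length(nonB) > 1)
      paste(target, "and not", nonB[length(nonB)]) else target
    o <- bruteForceOracle(m, query, maxHorizon = 6, resolve = FALSE)
    s <- solveQuery(m, query, maxHorizon = 6, resolve = FALSE)
    if (!sameSetOfSets(boundarySets(o), boundarySets(s)))
      mismatches <- mismatches + 1L
  }
  expect_equal(mismatches, 0L)
})

test_that("inhibited entities never appear in controllers or trajectories", {
  for (seed in 1:20) {
    m <- resolveCycles(randomGTModel(seed + 100, nEntities = 10,
                                     nEvents = 7))
    ids <- entityIds(m)
    nonB <- setdiff(ids, boundaryEntities(m))
    if (length(nonB) == 0) next
    target <- nonB[1 + seed %% length(nonB)]
    x <- setdiff(ids, target)[[1 + seed %% (length(ids) - 1L)]]
    res <- solveQuery(m, paste(target, "and not", x), maxHorizon = 6,
                      resolve = FALSE)
    expect_false(x %in% controllers(res, mapVirtual = FALSE))
    expect_false(x %in% controllers(res))
    expect_false(x %in% trajectoryEntities(res))
  }
})

test_that("disconnected entities never change a query result", {
  m <- buildToyModel()
  m2 <- gtModel(c(entities(m), list(gtEntity("ZZ_unrelated"))),
                transitions(m), modelMetadata(m))
  for (q in c("C", "C and not J")) {
    a <- solveQuery(m, q)
    b <- solveQuery(m2, q)
    expect_true(sameSetOfSets(boundarySets(a), boundarySets(b)))
    expect_equal(trajectoryEntities(a), trajectoryEntities(b))
  }
})

test_that("the solution cap is honoured and flagged", {
  m <- buildToyModel()
  r <- solveQuery(m, "C", maxSolutions = 1)
  expect_length(gtSolutions(r), 1L)
  expect_true(isCapped(r))
  r2 <- solveQuery(m, "C")  # default cap far above the solution count
  expect_false(isCapped(r2))
  expect_length(gtSolutions(r2), 2L)
})

test_that("the oracle refuses beyond its size bounds", {
  big <- gtModel(lapply(sprintf("x%02d", 1:20), gtEntity), list())
  expect_error(bruteForceOracle(big, "x01"), "bounds")
  expect_error(bruteForceOracle(buildToyModel(), "C", maxHorizon = 9),
               "bounds")
  # trivial single-transition model: {A} is the unique minimal set
  m <- gtModel(lapply(c("A", "B"), gtEntity),
               list(gtTransition("t1", "A", "B", "h1")))
  o <- bruteForceOracle(m, "B")
  expect_true(sameSetOfSets(boundarySets(o), list("A")))
  expect_length(gtSolutions(bruteForceOracle(m, "false")), 0L)
})
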