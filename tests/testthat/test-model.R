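test_that("validation reports referential-integrity violations", {
  expect_equal(nrow(validateModel(buildToyModel())), 0L)
  # transition referencing a missing entity
  m <- gtModel(list(gtEntity("A")),
               list(gtTransition("t1", "A", "Z", "h1")), validate = FALSE)
  rep <- validateModel(m)
  expect_equal(nrow(rep), 1L)
  expect_match(rep$message, "'Z'")
  # guard atom over an unknown id
  m2 <- gtModel(list(gtEntity("A"), gtEntity("B")),
                list(gtTransition("t1", "A", "B", "h1", gtAtom("Q"))),
                validate = FALSE)
  rep2 <- validateModel(m2)
  expect_equal(nrow(rep2), 1L)
  expect_equal(rep2$invariant, "guard-atoms")
  # the constructor enforces validity by default
  expect_error(gtModel(list(gtEntity("A")),
                       list(gtTransition("t1", "A", "Z", "h1"))))
})

test_that("boundary entities are exactly the never-produced entities", {
  m <- buildToyModel()
  expect_equal(boundaryEntities(m), c("D", "E", "F", "G", "L", "N"))
  outs <- vapply(transitions(m), `[[`, character(1), "output")
  expect_length(intersect(boundaryEntities(m), outs), 0L)
  # zero transitions: all entities are boundary
  m0 <- gtModel(list(gtEntity("X"), gtEntity("Y")), list())
  expect_equal(boundaryEntities(m0), c("X", "Y"))
})

test_that("cycle resolution adds one virtual feed per unfed SCC", {
  mr <- resolveCycles(buildToyModel())
  vm <- entities(mr)[["cycle_initiation_node_1"]]
  expect_false(is.null(vm))
  expect_equal(vm$kind, "virtual")
  feed <- Filter(function(tr) tr$input == "cycle_initiation_node_1",
                 transitions(mr))
  expect_length(feed, 1L)
  expect_equal(feed[[1]]$output, "I")  # lexicographically smallest of I,J,K
  expect_true("cycle_initiation_node_1" %in% boundaryEntities(mr))
  # idempotent
  expect_equal(modelStats(resolveCycles(mr)), modelStats(mr))
  # acyclic models come back unchanged
  ch <- chainModel(4)
  expect_identical(resolveCycles(ch), ch)
  # two disjoint unfed cycles get two virtual nodes, feeding A1 and B1
  tc <- resolveCycles(twoCycleModel())
  vids <- grep("^cycle_initiation_node_", entityIds(tc), value = TRUE)
  expect_length(vids, 2L)
  fed <- sort(vapply(vids, function(v)
    Filter(function(tr) tr$input == v, transitions(tc))[[1]]$output,
    character(1)))
  expect_equal(unname(fed), c("A1", "B1"))
})

test_that("after resolution every entity is reachable from the boundary", {
  for (seed in 1:10) {
    m <- resolveCycles(randomGTModel(seed, nEntities = 9, nEvents = 7))
    reach <- boundaryEntities(m)
    repeat {
      nxt <- unique(c(reach, unlist(lapply(transitions(m), function(tr)
        if (tr$input %in% reach) tr$output), use.names = FALSE)))
      if (length(nxt) == length(reach)) break
      reach <- nxt
    }
    expect_setequal(reach, entityIds(m))
  }
})

test_that("model statistics count entities, events and boundary roles", {
  st <- modelStats(buildToyModel())
  expect_equal(st$entities, 15L)
  expect_equal(st$transitions, 11L)
  expect_equal(st$events, 8L)
  expect_equal(st$boundary, 6L)
  st0 <- modelStats(gtModel(list(), list()))
  expect_equal(st0$entities, 0L)
  expect_equal(st0$transitions, 0L)
  # single transition A -> B guarded by F: boundary {A, F}
  m <- gtModel(list(gtEntity("A"), gtEntity("B"), gtEntity("F")),
               list(gtTransition("t1", "A", "B", "h1", gtAtom("F"))))
  expect_equal(boundaryEntities(m), c("A", "F"))
  roles <- modelStats(m)$boundaryRoles
  expect_equal(roles[["inputOfTransition"]], 1L)   # A
  expect_equal(roles[["conditionOnly"]], 1L)       # F
  expect_equal(roles[["both"]], 0L)
})

test_that("native JSON serialisation round-trips", {
  for (m in list(buildToyModel(), resolveCycles(twoCycleModel()),
                 randomGTModel(3))) {
    f <- tempfile(fileext = ".json")
    writeGTModel(m, f)
    m2 <- readGTModel(f)
    expect_setequal(entityIds(m2), entityIds(m))
    expect_equal(modelStats(m2), modelStats(m))
    guards1 <- vapply(transitions(m), function(tr)
      formulaToString(tr$guard), character(1))
    guards2 <- vapply(transitions(m2), function(tr)
      formulaToString(tr$guard), character(1))
    expect_equal(guards2, guards1)
    # byte-stable: writing the re-read model reproduces the file
    f2 <- tempfile(fileext = ".json")
    writeGTModel(m2, f2)
    expect_identical(readLines(f2), readLines(f))
  }
})
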