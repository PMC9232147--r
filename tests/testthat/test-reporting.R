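test_that("trajectory graphs class nodes and edges as rendered", {
  m <- resolveCycles(buildToyModel())
  res <- solveQuery(m, "C", resolve = FALSE)
  g <- trajectoryGraph(res, m)
  cls <- setNames(g$nodes$class, g$nodes$id)
  # boundary entities in the result are red; I stands for its virtual feed
  for (b in c("D", "E", "F", "L", "I"))
    expect_equal(unname(cls[b]), "boundary")
  for (i in c("A", "B", "J", "K"))
    expect_equal(unname(cls[i]), "intermediate")
  expect_equal(unname(cls["M"]), "inhibitor")
  # h0 has two reagents: a blue reaction node with an inhibition edge in
  expect_true("reaction_h0" %in% g$nodes$id)
  inh <- g$edges[g$edges$class == "inhibition", ]
  expect_equal(inh$from, "M")
  expect_equal(inh$to, "reaction_h0")
  act <- g$edges[g$edges$class == "activation", ]
  expect_true(all(c("L", "K") %in% act$from))
  # an empty result gives an empty graph document
  empty <- solveQuery(m, "C and not A", resolve = FALSE)
  ge <- trajectoryGraph(empty, m)
  expect_equal(nrow(ge$nodes), 0L)
  # a single unary chain has no blue reaction nodes
  ch <- chainModel(3)
  rch <- solveQuery(ch, "e3")
  gch <- trajectoryGraph(rch, ch)
  expect_false(any(gch$nodes$class == "reaction"))
})

test_that("graph exports round-trip their class multisets", {
  m <- resolveCycles(buildToyModel())
  res <- solveQuery(m, "C", resolve = FALSE)
  g <- trajectoryGraph(res, m)
  # GraphML parses back to the same node/edge class multiset
  xml <- xml2::read_xml(exportTrajectoryGraph(res, m, "graphml"))
  ns <- xml2::xml_ns_rename(xml2::xml_ns(xml), d1 = "g")
  nodes <- xml2::xml_find_all(xml, ".//g:node", ns)
  edges <- xml2::xml_find_all(xml, ".//g:edge", ns)
  expect_equal(sort(xml2::xml_text(nodes)), sort(g$nodes$class))
  expect_equal(sort(xml2::xml_text(edges)), sort(g$edges$class))
  # DOT contains one line per node and edge
  dot <- exportTrajectoryGraph(res, m, "dot")
  lines <- strsplit(dot, "\n")[[1]]
  expect_length(grep("->", lines), nrow(g$edges))
  expect_error(exportTrajectoryGraph(res, m, "svg"), "supported formats")
})

test_that("occupancy matrices mirror the boundary sets", {
  m <- buildToyModel()
  res <- solveQuery(m, "C")
  occ <- occupancyMatrix(res)
  expect_equal(dim(occ), c(2L, 5L))
  expect_equal(colnames(occ), c("D", "E", "F", "I", "L"))
  # D, E, F in every solution; L and I one-hot
  expect_equal(unname(colSums(occ[, c("D", "E", "F")])), c(2, 2, 2))
  expect_equal(unname(colSums(occ[, c("I", "L")])), c(1, 1))
  # row sums equal the boundary set sizes
  for (i in seq_along(gtSolutions(res)))
    expect_equal(sum(occ[i, ]), length(gtSolutions(res)[[i]]@boundary))
  # CSV round-trip
  f <- tempfile(fileext = ".csv")
  occupancyMatrix(res, path = f)
  back <- utils::read.csv(f, check.names = FALSE)
  expect_equal(colnames(back), c("trajectory", colnames(occ)))
  expect_equal(as.matrix(back[, -1]), occ, ignore_attr = TRUE)
  # single solution: one all-ones row over its own controllers
  r5 <- solveQuery(m, "C and not J")
  occ5 <- occupancyMatrix(r5)
  expect_equal(unname(occ5[1, ]), rep(1L, 4))
})

test_that("controller comparisons enumerate all Venn regions", {
  out <- compareControllers(list(a = c("D", "E"), b = c("E", "F")))
  expect_equal(out$regions$a, "D")
  expect_equal(out$regions$b, "F")
  expect_equal(out$regions$`a&b`, "E")
  expect_equal(sum(out$counts), 3L)
  # identical sets: all mass in the intersection
  out2 <- compareControllers(list(x = c("A", "B"), y = c("A", "B")))
  expect_equal(out2$counts[["x&y"]], 2L)
  expect_equal(out2$counts[["x"]], 0L)
  # three constructed sets: region counts match the construction,
  # cardinalities sum to the union size
  A <- sprintf("m%02d", 1:10); B <- sprintf("m%02d", 6:56)
  C <- sprintf("m%02d", c(1:3, 40:99))
  out3 <- compareControllers(list(a = A, b = B, c = C))
  expect_equal(sum(out3$counts), length(union(A, union(B, C))))
  expect_equal(out3$counts[["a&b&c"]], 0L)
  expect_equal(out3$counts[["a&b"]], length(setdiff(intersect(A, B), C)))
  expect_equal(out3$counts[["b&c"]], length(setdiff(intersect(B, C), A)))
  expect_error(compareControllers(list(a = "X")), "at least two")
})
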