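list_table <- function(name, elements) {
  source_table(name, "list", "element",
               records = data.frame(element = elements, stringsAsFactors = FALSE))
}

test_that("list integration counts distinct sources with provenance", {
  tabs <- list(list_table("S1", c("g1", "g2", "g3")),
               list_table("S2", c("g2", "g3")),
               list_table("S3", c("g2")))
  out <- integrate_lists(tabs, mode = "undefined")
  expect_equal(out$element, c("g2", "g3", "g1"))
  expect_equal(out$reoccurrence, c(3L, 2L, 1L))
  expect_equal(out$sources, c("S1;S2;S3", "S1;S2", "S1"))

  one <- integrate_lists(list(list_table("S1", c("g1", "g2"))), mode = "undefined")
  expect_true(all(one$reoccurrence == 1L))

  dup <- integrate_lists(list(list_table("S1", c("g5", "g5"))), mode = "undefined")
  expect_equal(dup$reoccurrence, 1L)

  expect_error(
    integrate_lists(list(list_table("S1", "g1"),
                         source_table("S2", "network", c("a", "b"),
                                      records = data.frame(a = "A", b = "B")))),
    "mix")
  expect_error(integrate_lists(list(list_table("S1", "g1"), list_table("S1", "g2"))),
               "duplicate source")
})

test_that("edge keys are canonical unordered case-sensitive pairs", {
  k <- canonical_edge_key("B", "A")
  expect_equal(k$node_a, "A")
  expect_equal(k$node_b, "B")
  expect_identical(canonical_edge_key("A", "B")$key, canonical_edge_key("B", "A")$key)
  expect_equal(canonical_edge_key("A", "A")$key, "A|A")
  k2 <- canonical_edge_key("nrl", "Nrl")
  expect_equal(c(k2$node_a, k2$node_b), c("Nrl", "nrl"))
})

test_that("network integration merges directions and computes degrees", {
  tabs <- make_network_tables(list(
    S1 = rbind(c("A", "B"), c("B", "C")),
    S2 = rbind(c("A", "B"), c("C", "D"))))
  net <- integrate_networks(tabs, mode = "undefined",
                            directedness = c(S1 = "undirected", S2 = "directed"))
  e <- net$edges
  ab <- e[e$node_a == "A" & e$node_b == "B", ]
  expect_equal(ab$reoccurrence, 2L)
  expect_equal(ab$direction_status, "merged")
  expect_equal(ab$sources, "S1;S2")
  expect_equal(e$direction_status[e$node_a == "B" & e$node_b == "C"], "undirected")
  expect_equal(e$direction_status[e$node_a == "C" & e$node_b == "D"], "directed")
  deg <- stats::setNames(net$nodes$degree, net$nodes$node)
  expect_equal(deg[c("A", "B", "C", "D")], c(A = 1L, B = 2L, C = 2L, D = 1L))
  # node provenance from the worked example
  expect_equal(net$nodes$sources[net$nodes$node == "B"], "S1;S2")
  expect_equal(net$nodes$reoccurrence[net$nodes$node == "B"], 2L)
})

test_that("a source merged with a renamed copy doubles reoccurrence only", {
  edges <- rbind(c("A", "B"), c("B", "C"), c("C", "C"))
  tabs <- make_network_tables(list(S1 = edges, S1copy = edges))
  net <- integrate_networks(tabs, mode = "undefined")
  expect_true(all(net$edges$reoccurrence == 2L))
  solo <- integrate_networks(make_network_tables(list(S1 = edges)), mode = "undefined")
  expect_identical(net$edges[, c("node_a", "node_b")],
                   solo$edges[, c("node_a", "node_b")])
  expect_identical(net$nodes$degree, solo$nodes$degree)
})

test_that("opposite orientations share one edge and keep both directions", {
  tabs <- make_network_tables(list(S1 = rbind(c("A", "B")), S2 = rbind(c("B", "A"))))
  net <- integrate_networks(tabs, mode = "undefined",
                            directedness = c(S1 = "directed", S2 = "directed"))
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$reoccurrence, 2L)
  expect_equal(net$edges$direction_status, "directed")
  expect_setequal(strsplit(net$edges$directions, ",")[[1]], c("a->b", "b->a"))
})

test_that("ranking is descending by reoccurrence with lexicographic ties", {
  df <- data.frame(element = c("B", "A", "C"), reoccurrence = c(2L, 2L, 1L),
                   sources = c("x", "x", "x"), stringsAsFactors = FALSE)
  expect_equal(rank_candidates(df)$element, c("A", "B", "C"))
  ties <- data.frame(element = c("c", "a", "b"), reoccurrence = c(1L, 1L, 1L))
  expect_equal(rank_candidates(ties)$element, c("a", "b", "c"))
  empty <- data.frame(element = character(), reoccurrence = integer())
  expect_equal(nrow(rank_candidates(empty)), 0L)
})

test_that("integration is invariant to source and row permutations", {
  set.seed(21)
  for (i in 1:10) {
    sets <- lapply(1:4, function(j) sample(sprintf("g%d", 1:12), sample(3:8, 1)))
    names(sets) <- sprintf("S%d", 1:4)
    tabs <- lapply(names(sets), function(nm) list_table(nm, sets[[nm]]))
    base <- integrate_lists(tabs, mode = "undefined")
    perm <- sample(length(tabs))
    shuf <- lapply(tabs[perm], function(t) {
      t$records <- t$records[sample(nrow(t$records)), , drop = FALSE]
      rownames(t$records) <- NULL
      t
    })
    expect_identical(as.data.frame(integrate_lists(shuf, mode = "undefined")),
                     as.data.frame(base))
    # conservation: source sets reproduce exactly the (source, element) pairs
    got <- unlist(mapply(function(e, s) paste(strsplit(s, ";")[[1]], e),
                         base$element, base$sources, SIMPLIFY = FALSE), use.names = FALSE)
    want <- unlist(lapply(names(sets), function(nm) paste(nm, unique(sets[[nm]]))))
    expect_setequal(got, want)
  }
})

test_that("undefined mode equals defined mode with empty filter sets", {
  set.seed(22)
  tabs <- lapply(1:3, function(i) random_list_table(sprintf("S%d", i)))
  empty <- lapply(tabs, function(t) filter_set(t$name))
  names(empty) <- vapply(tabs, `[[`, character(1), "name")
  expect_identical(
    as.data.frame(integrate_lists(tabs, filters = empty, mode = "defined")),
    as.data.frame(integrate_lists(tabs, mode = "undefined")))
})
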