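test_that("cumulative stats enumerate observed levels with >= counts", {
  expect_equal(cumulative_stats(c(3, 2, 2, 1)),
               data.frame(level = 1:3, count_at_or_above = c(4L, 3L, 1L)))
  expect_equal(cumulative_stats(c(1, 1, 1)),
               data.frame(level = 1L, count_at_or_above = 3L))
  expect_equal(cumulative_stats(c(3, 2, 1, 1)),
               data.frame(level = 1:3, count_at_or_above = c(4L, 2L, 1L)))
  expect_error(cumulative_stats(integer()), "non-empty")
})

test_that("cumulative stats agree with brute-force threshold counting", {
  set.seed(31)
  for (i in 1:30) {
    v <- sample.int(8, sample(1:40, 1), replace = TRUE)
    st <- cumulative_stats(v)
    for (r in seq_len(nrow(st))) {
      expect_equal(st$count_at_or_above[r], sum(v >= st$level[r]))
    }
    expect_true(all(diff(st$level) > 0))
    expect_true(all(diff(st$count_at_or_above) <= 0))
    expect_equal(st$count_at_or_above[1], length(v))
    expect_true(all(st$count_at_or_above >= 1))
  }
})

test_that("list reports carry provenance and round-trip the ranking", {
  tabs <- list(
    source_table("S1", "list", "element", records = data.frame(element = c("g1", "g2", "g3"))),
    source_table("S2", "list", "element", records = data.frame(element = c("g2", "g3"))),
    source_table("S3", "list", "element", records = data.frame(element = "g2")))
  res <- integrate_lists(tabs, mode = "undefined")
  p <- tempfile(fileext = ".tsv")
  write_list_report(res, list(integrated_files = c("S1", "S2", "S3"),
                              mode = "undefined", applied_filters = list()), p)
  lines <- readLines(p)
  expect_true("g2\t3\tS1;S2;S3" %in% lines)
  expect_true(any(grepl("^# integrated_files: S1;S2;S3$", lines)))
  back <- read_list_report(p)
  expect_identical(back$elements, as.data.frame(res))

  empty <- integrate_lists(list(source_table("S1", "list", "element",
    records = data.frame(element = character()))), mode = "undefined")
  p2 <- tempfile(fileext = ".tsv")
  write_list_report(empty, list(integrated_files = "S1", mode = "undefined"), p2)
  expect_equal(nrow(read_list_report(p2)$elements), 0L)
})

test_that("network reports hold four tables and round-trip exactly", {
  tabs <- make_network_tables(list(S1 = rbind(c("A", "B"), c("B", "C")),
                                   S2 = rbind(c("A", "B"), c("C", "D"))))
  net <- integrate_networks(tabs, mode = "undefined",
                            directedness = c(S1 = "undirected", S2 = "directed"))
  p <- tempfile(fileext = ".tsv")
  write_network_report(net, list(integrated_files = c("S1", "S2"), mode = "undefined"), p)
  lines <- readLines(p)
  expect_true("A\tB\tmerged\t2\tS1;S2" %in% lines)
  expect_true("B\t2\tS1;S2" %in% lines)
  expect_equal(sum(startsWith(lines, "# table:")), 4L)

  back <- read_network_report(p)
  expect_identical(back$edges,
                   net$edges[, c("node_a", "node_b", "direction_status",
                                 "reoccurrence", "sources")])
  expect_identical(back$nodes, net$nodes[, c("node", "reoccurrence", "sources")])
  expect_equal(back$node_statistics$nodes, cumulative_stats(net$nodes$degree)$count_at_or_above)
  expect_equal(names(back$edges),
               c("node_a", "node_b", "direction_status", "reoccurrence", "sources"))

  single <- integrate_networks(make_network_tables(list(S1 = rbind(c("A", "B")))),
                               mode = "undefined")
  p2 <- tempfile(fileext = ".tsv")
  write_network_report(single, list(integrated_files = "S1", mode = "undefined"), p2)
  st <- read_network_report(p2)$node_statistics
  expect_equal(st, data.frame(degree = 1L, nodes = 2L))
})

test_that("degree-sum identity holds across random networks", {
  set.seed(32)
  for (i in 1:15) {
    n_src <- sample(2:4, 1)
    edge_lists <- lapply(seq_len(n_src), function(j) {
      n_e <- sample(2:10, 1)
      cbind(sample(LETTERS[1:8], n_e, replace = TRUE),
            sample(LETTERS[1:8], n_e, replace = TRUE))
    })
    names(edge_lists) <- sprintf("S%d", seq_len(n_src))
    dd <- stats::setNames(sample(c("directed", "undirected"), n_src, replace = TRUE),
                          names(edge_lists))
    net <- integrate_networks(make_network_tables(edge_lists),
                              mode = "undefined", directedness = dd)
    loops <- sum(net$edges$node_a == net$edges$node_b)
    expect_equal(sum(net$nodes$degree), 2L * (nrow(net$edges) - loops) + loops)
    expect_true(all(net$edges$reoccurrence >= 1 & net$edges$reoccurrence <= n_src))
  }
})

test_that("overrepresentation p-values match the spec'd worked cases", {
  expect_equal(enrichment_test(4, 4, 5, 10), 5 / 210)
  expect_equal(enrichment_test(0, 3, 5, 10), 1.0)
  expect_equal(enrichment_test(5, 10, 5, 10), 1.0)  # selected == universe
  expect_error(enrichment_test(6, 4, 5, 10), "inconsistent")
  expect_error(enrichment_test(1, 4, 5, 3), "inconsistent")
})
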