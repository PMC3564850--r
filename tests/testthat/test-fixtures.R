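test_that("list fixtures honor planted guarantees and ground truth", {
  spec <- fixture_spec(n_sources = 3, universe = sprintf("g%02d", 1:20),
                       planted = "g01", background_pass_prob = 0, seed = 5)
  fx <- generate_list_sources(spec)
  res <- integrate_lists(fx$tables, fx$filters, mode = "defined")
  expect_equal(res$element[res$reoccurrence == 3], "g01")
  expect_equal(nrow(res), 1L)

  all_pass <- generate_list_sources(
    fixture_spec(n_sources = 3, universe = sprintf("g%02d", 1:20),
                 planted = character(), background_pass_prob = 1, seed = 5))
  res2 <- integrate_lists(all_pass$tables, all_pass$filters, mode = "defined")
  expect_true(all(res2$reoccurrence == 3))
  expect_equal(nrow(res2), 20L)
})

test_that("fixture generation is deterministic and byte-stable per seed", {
  spec <- fixture_spec(seed = 9)
  a <- generate_list_sources(spec)
  b <- generate_list_sources(spec)
  expect_identical(a$tables, b$tables)
  d1 <- tempfile(); d2 <- tempfile()
  write_fixture(a, d1); write_fixture(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  cs1 <- generate_case_study_fixture(seed = 4, universe_size = 40, n_planted = 3)
  cs2 <- generate_case_study_fixture(seed = 4, universe_size = 40, n_planted = 3)
  expect_identical(cs1, cs2)
})

test_that("defined-mode integration recovers exactly the planted tier", {
  set.seed(51)
  for (i in 1:5) {
    spec <- fixture_spec(n_sources = sample(2:5, 1),
                         universe = sprintf("g%02d", 1:30),
                         planted = sprintf("g%02d", sample(30, 3)),
                         background_pass_prob = runif(1, 0, 0.6),
                         seed = sample.int(1e6, 1))
    fx <- generate_list_sources(spec)
    res <- integrate_lists(fx$tables, fx$filters, mode = "defined")
    # brute-force reoccurrence from the ground-truth pass sets
    oracle <- oracle_integrate_lists(fx$truth)
    expect_identical(as.data.frame(res), rank_candidates(oracle))
    full <- oracle$element[oracle$reoccurrence == spec$n_sources]
    expect_true(all(spec$planted %in% full))
    expect_setequal(res$element[res$reoccurrence == spec$n_sources], full)
  }
})

test_that("the case-study fixture mirrors the retinal workflow's shape", {
  fx <- generate_case_study_fixture(seed = 2, n_planted = 5, universe_size = 272)
  expect_length(fx$tables, 8L)
  corr <- Filter(function(t) "corr" %in% t$schema$name, fx$tables)
  deg <- Filter(function(t) "age" %in% t$schema$name, fx$tables)
  expect_length(corr, 6L)
  expect_length(deg, 2L)
  expect_true(all(vapply(corr, function(t) nrow(t$records) == 272, logical(1))))
  pool <- unique(unlist(lapply(fx$tables, function(t) t$records$gene)))
  expect_length(pool, 272L)
  # planted pass all 8 by construction; backgrounds fail at least one
  res <- integrate_lists(fx$tables, fx$filters, mode = "defined")
  expect_setequal(res$element[res$reoccurrence == 8], fx$planted)
  # the |r| > 0.9 any-group and the P6/P10 tag filter are what is applied
  f1 <- fx$filters[[names(corr)[1]]]
  expect_equal(f1$groups$corr$logic, "any")
  expect_setequal(vapply(f1$groups$corr$criteria, format, character(1)),
                  c("corr > 0.9", "corr < -0.9"))
  f2 <- fx$filters[[names(deg)[1]]]
  expect_setequal(f2$groups$age$criteria[[1]]$tags, c("P6", "P10"))
  # undefined mode cannot separate planted from background by reoccurrence
  und <- integrate_lists(fx$tables, mode = "undefined")
  expect_true(all(und$reoccurrence == 8))

  none <- generate_case_study_fixture(seed = 3, n_planted = 0, universe_size = 50)
  res0 <- integrate_lists(none$tables, none$filters, mode = "defined")
  expect_false(any(res0$reoccurrence == 8))
})

test_that("network fixtures plant shared edges with declared directedness", {
  spec <- fixture_spec(n_sources = 2, universe = LETTERS[1:12],
                       planted = c("A", "B"), seed = 6, n_background_edges = 4)
  fx <- generate_network_sources(spec, directedness = c("undirected", "directed"))
  net <- integrate_networks(fx$tables, mode = "undefined",
                            directedness = fx$directedness)
  ab <- net$edges[net$edges$node_a == "A" & net$edges$node_b == "B", ]
  expect_equal(ab$reoccurrence, 2L)
  expect_equal(ab$direction_status, "merged")
  expect_true(all(net$edges$reoccurrence[!(net$edges$node_a == "A" &
                                           net$edges$node_b == "B")] == 1L))
  # no planted overlap: all unique background edges
  only_bg <- generate_network_sources(
    fixture_spec(n_sources = 3, universe = LETTERS[1:12], planted = c("A", "B"),
                 seed = 7, n_background_edges = 3))
  bg_net <- integrate_networks(only_bg$tables, mode = "undefined",
                               directedness = only_bg$directedness)
  bg <- bg_net$edges[!(bg_net$edges$node_a == "A" & bg_net$edges$node_b == "B"), ]
  expect_true(all(bg$reoccurrence == 1L))
  expect_identical(generate_network_sources(spec, c("undirected", "directed")),
                   fx)
})
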