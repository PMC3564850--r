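#' Specification for synthetic source generation
#'
#' Describes a family of synthetic sources with planted structure: a
#' universe of element identifiers, a planted subset guaranteed to pass
#' every source's filter, and background elements that pass each source's
#' filter independently with a stated probability. Attribute values are
#' drawn from the passing or failing region of the filter, so the
#' per-source ground truth is exact by construction rather than
#' probabilistic. Generation is deterministic for a fixed seed.
#'
#' @param n_sources Number of sources to generate.
#' @param universe Character vector of element identifiers.
#' @param planted Identifiers (subset of \code{universe}) that pass all
#'   filters in all sources.
#' @param background_pass_prob Probability that a background element
#'   passes any one source's filter.
#' @param seed Integer seed.
#' @param attribute_name Name of the numeric attribute carried by list
#'   sources.
#' @param threshold Filter cutoff for list sources (criterion
#'   \code{attribute > threshold}, with attribute values in [0, 1]).
#' @param n_background_edges Background (source-unique) edges per network
#'   source.
#' @return A \code{fixture_spec} object.
#' @export
fixture_spec <- function(n_sources = 3L, universe = sprintf("g%02d", 1:40),
                         planted = universe[1:3], background_pass_prob = 0.3,
                         seed = 1L, attribute_name = "score", threshold = 0.5,
                         n_background_edges = 5L) {
  if (!length(universe)) stop("universe must be non-empty", call. = FALSE)
  if (anyDuplicated(universe)) stop("universe identifiers must be unique", call. = FALSE)
  if (!all(planted %in% universe)) {
    stop("planted identifiers must be a subset of the universe", call. = FALSE)
  }
  stopifnot(n_sources >= 1, background_pass_prob >= 0, background_pass_prob <= 1,
            threshold > 0, threshold < 1)
  structure(list(n_sources = as.integer(n_sources), universe = universe,
                 planted = planted, background_pass_prob = background_pass_prob,
                 seed = as.integer(seed), attribute_name = attribute_name,
                 threshold = threshold,
                 n_background_edges = as.integer(n_background_edges)),
            class = "fixture_spec")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else rm(".Random.seed", envir = .GlobalEnv), add = TRUE)
  set.seed(seed)
  expr
}

#' Generate synthetic list sources with planted candidates
#'
#' Every source contains all universe elements with one numeric attribute.
#' Planted elements draw from the passing region of the source's filter
#' (\code{attribute > threshold}); background elements draw from the
#' passing region with probability \code{background_pass_prob} and from
#' the failing region otherwise. The returned ground truth records each
#' source's exact pass set, so defined-mode integration can be checked
#' against construction: planted elements reach reoccurrence
#' \code{n_sources}, and only elements whose pass sets span all sources
#' share that tier.
#'
#' @param spec A \code{\link{fixture_spec}}.
#' @return A list with \code{tables} (source tables named
#'   \code{S1..Sn}), \code{filters} (named \code{\link{filter_set}}s),
#'   \code{truth} (per-source pass sets), \code{planted}, and
#'   \code{mode = "defined"}.
#' @export
generate_list_sources <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  att <- spec$attribute_name
  thr <- spec$threshold
  n_u <- length(spec$universe)
  is_planted <- spec$universe %in% spec$planted
  with_seed(spec$seed, {
    out <- lapply(seq_len(spec$n_sources), function(i) {
      src <- sprintf("S%d", i)
      pass <- is_planted | stats::runif(n_u) < spec$background_pass_prob
      vals <- ifelse(pass,
                     stats::runif(n_u, thr + 1e-3, 1),
                     stats::runif(n_u, 0, thr - 1e-3))
      rec <- data.frame(element = spec$universe, v = vals, stringsAsFactors = FALSE)
      names(rec)[2] <- att
      rec <- rec[sample.int(n_u), , drop = FALSE]
      rownames(rec) <- NULL
      tab <- source_table(src, "list", "element",
                          data.frame(name = att, kind = "value",
                                     stringsAsFactors = FALSE), rec)
      fs <- filter_set(src, stats::setNames(
        list(list(criteria = list(criterion(att, ">", thr)), logic = "all")), att))
      list(table = tab, filter = fs, pass_set = spec$universe[pass])
    })
    nms <- vapply(out, function(x) x$table$name, character(1))
    list(tables = stats::setNames(lapply(out, `[[`, "table"), nms),
         filters = stats::setNames(lapply(out, `[[`, "filter"), nms),
         truth = stats::setNames(lapply(out, `[[`, "pass_set"), nms),
         planted = spec$planted, mode = "defined")
  })
}

# ages a rod-photoreceptor developmental series is sampled at
CASE_STUDY_AGES <- c("E16", "P2", "P6", "P10", "4wk")
CASE_STUDY_PASS_AGES <- c("P6", "P10")

#' Generate the retinal case-study-shaped fixture
#'
#' Emulates the structure of the retinal candidate-gene workflow: eight
#' list sources over one gene universe — six co-expression lists (three
#' wild-type, three knockout, one per anchor gene) carrying a numeric
#' correlation attribute and filtered at an absolute correlation above
#' 0.9 (an any-logic group of \code{corr > 0.9} or \code{corr < -0.9}),
#' and two differentially-expressed-gene lists carrying a developmental
#' age label over \{E16, P2, P6, P10, 4wk\} filtered to \{P6, P10\}.
#' Planted genes pass all eight filters; every background gene is forced
#' to fail at least one source (and passes each remaining source with
#' probability \code{background_pass_prob}), so the reoccurrence-8 tier of
#' a defined-mode integration is exactly the planted set. The fixture
#' reproduces the workflow's shape — attributes, criteria, cardinalities —
#' not any real gene identities.
#'
#' @param seed Integer seed.
#' @param n_planted Number of planted candidate genes.
#' @param universe_size Number of unique genes in the candidate pool.
#' @param background_pass_prob Per-source pass probability for background
#'   genes away from their forced-fail source.
#' @return As \code{\link{generate_list_sources}}, with eight tables:
#'   \code{wt_corr_A1..A3}, \code{ko_corr_A1..A3}, \code{deg_list1},
#'   \code{deg_list2}.
#' @export
generate_case_study_fixture <- function(seed = 1L, n_planted = 5L,
                                        universe_size = 272L,
                                        background_pass_prob = 0.35) {
  stopifnot(n_planted >= 0, universe_size >= 1, n_planted <= universe_size)
  universe <- sprintf("g%04d", seq_len(universe_size))
  corr_names <- c(paste0("wt_corr_A", 1:3), paste0("ko_corr_A", 1:3))
  deg_names <- c("deg_list1", "deg_list2")
  src_names <- c(corr_names, deg_names)
  n_src <- length(src_names)

  with_seed(seed, {
    planted <- sort_c(sample(universe, n_planted))
    is_planted <- universe %in% planted
    n_u <- universe_size
    # each background gene is forced to fail one randomly chosen source
    forced_fail <- sample.int(n_src, n_u, replace = TRUE)
    forced_fail[is_planted] <- 0L

    pass_corr <- function(n) sample(c(-1, 1), n, replace = TRUE) *
      stats::runif(n, 0.905, 0.995)
    fail_corr <- function(n) stats::runif(n, -0.895, 0.895)

    out <- lapply(seq_len(n_src), function(i) {
      src <- src_names[i]
      pass <- is_planted |
        (forced_fail != i & stats::runif(n_u) < background_pass_prob)
      if (src %in% corr_names) {
        vals <- numeric(n_u)
        vals[pass] <- pass_corr(sum(pass))
        vals[!pass] <- fail_corr(sum(!pass))
        rec <- data.frame(gene = universe, corr = vals, stringsAsFactors = FALSE)
        schema <- data.frame(name = "corr", kind = "value", stringsAsFactors = FALSE)
        fs <- filter_set(src, list(corr = list(
          criteria = list(criterion("corr", ">", 0.9), criterion("corr", "<", -0.9)),
          logic = "any")))
      } else {
        vals <- character(n_u)
        vals[pass] <- sample(CASE_STUDY_PASS_AGES, sum(pass), replace = TRUE)
        vals[!pass] <- sample(setdiff(CASE_STUDY_AGES, CASE_STUDY_PASS_AGES),
                              sum(!pass), replace = TRUE)
        rec <- data.frame(gene = universe, age = vals, stringsAsFactors = FALSE)
        schema <- data.frame(name = "age", kind = "label", stringsAsFactors = FALSE)
        fs <- filter_set(src, list(age = list(
          criteria = list(criterion("age", tags = CASE_STUDY_PASS_AGES)),
          logic = "any")))
      }
      rec <- rec[sample.int(n_u), , drop = FALSE]
      rownames(rec) <- NULL
      list(table = source_table(src, "list", "gene", schema, rec),
           filter = fs, pass_set = universe[pass])
    })
    list(tables = stats::setNames(lapply(out, `[[`, "table"), src_names),
         filters = stats::setNames(lapply(out, `[[`, "filter"), src_names),
         truth = stats::setNames(lapply(out, `[[`, "pass_set"), src_names),
         planted = planted, mode = "defined")
  })
}

#' Generate synthetic network sources with planted shared edges
#'
#' Emits \code{n_sources} edge-list sources over the spec's universe of
#' node identifiers: a common set of planted edges appears in every
#' source (the ground-truth reoccurring edges), plus
#' \code{n_background_edges} edges unique to each source (reoccurrence 1
#' by construction). Directed sources record a fixed orientation per
#' planted edge, so planted edges integrate as \code{"merged"} whenever
#' the plan mixes directed and undirected sources.
#'
#' @param spec A \code{\link{fixture_spec}}; \code{planted} names the
#'   nodes whose consecutive pairs form the planted edges.
#' @param directedness Character vector of length \code{n_sources} of
#'   \code{"directed"}/\code{"undirected"}; default alternates, starting
#'   undirected.
#' @return A list with \code{tables}, \code{directedness} (named),
#'   \code{truth} (data frame of planted edges with expected reoccurrence
#'   and direction status), and \code{mode = "undefined"}.
#' @export
generate_network_sources <- function(spec, directedness = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (is.null(directedness)) {
    directedness <- rep(c("undirected", "directed"), length.out = spec$n_sources)
  }
  stopifnot(length(directedness) == spec$n_sources,
            all(directedness %in% c("directed", "undirected")))
  nodes <- spec$universe
  if (length(spec$planted) < 2L) stop("need at least 2 planted nodes to form edges",
                                      call. = FALSE)
  planted_a <- spec$planted[-length(spec$planted)]
  planted_b <- spec$planted[-1L]
  planted_keys <- canonical_edge_key(planted_a, planted_b)$key

  with_seed(spec$seed, {
    # pool of candidate background pairs, excluding planted keys
    all_pairs <- t(utils::combn(nodes, 2L))
    keys <- canonical_edge_key(all_pairs[, 1], all_pairs[, 2])$key
    pool <- which(!(keys %in% planted_keys))
    need <- spec$n_sources * spec$n_background_edges
    if (length(pool) < need) {
      stop("universe too small for the requested number of unique background edges",
           call. = FALSE)
    }
    picks <- sample(pool, need)
    src_names <- sprintf("N%d", seq_len(spec$n_sources))
    tabs <- lapply(seq_len(spec$n_sources), function(i) {
      bg <- picks[((i - 1L) * spec$n_background_edges + 1L):(i * spec$n_background_edges)]
      rec <- data.frame(
        node_a = c(planted_a, all_pairs[bg, 1]),
        node_b = c(planted_b, all_pairs[bg, 2]),
        stringsAsFactors = FALSE
      )
      rec <- rec[sample.int(nrow(rec)), , drop = FALSE]
      rownames(rec) <- NULL
      source_table(src_names[i], "network", c("node_a", "node_b"),
                   empty_schema(), rec)
    })
    has_dir <- any(directedness == "directed")
    has_und <- any(directedness == "undirected")
    status <- if (has_dir && has_und) "merged" else if (has_dir) "directed" else "undirected"
    truth <- data.frame(node_a = pmin_chr(planted_a, planted_b),
                        node_b = pmax_chr(planted_a, planted_b),
                        reoccurrence = spec$n_sources,
                        direction_status = status, stringsAsFactors = FALSE)
    list(tables = stats::setNames(tabs, src_names),
         directedness = stats::setNames(directedness, src_names),
         truth = truth, mode = "undefined")
  })
}

filters_to_config <- function(fs) {
  if (!length(fs$groups)) return(NULL)
  lapply(fs$groups, function(g) {
    list(logic = g$logic,
         criteria = vapply(g$criteria, format, character(1)))
  })
}

#' Write a generated fixture to disk as TSV sources plus a run config
#'
#' Materializes a fixture from \code{\link{generate_list_sources}} or
#' \code{\link{generate_case_study_fixture}} as one TSV file per source
#' and a ready-to-run YAML configuration (\code{config.yaml}) wiring the
#' sources, attribute kinds, and filter criteria together, so the fixture
#' doubles as an end-to-end command-line example. Fixture files are
#' byte-identical across runs with the same seed.
#'
#' @param fixture A generated fixture list.
#' @param dir Output directory (created if needed).
#' @return The path to the written config file.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  srcs <- lapply(names(fixture$tables), function(nm) {
    tab <- fixture$tables[[nm]]
    fn <- paste0(nm, ".tsv")
    write_source_table(tab, file.path(dir, fn))
    entry <- list(path = fn, name = nm,
                  key_columns = as.list(tab$key_columns))
    if (nrow(tab$schema)) {
      entry$attributes <- as.list(stats::setNames(tab$schema$kind, tab$schema$name))
    }
    if (!is.null(fixture$directedness)) {
      entry$directed <- unname(fixture$directedness[nm] == "directed")
    }
    fs <- fixture$filters[[nm]]
    if (!is.null(fs)) {
      fc <- filters_to_config(fs)
      if (!is.null(fc)) entry$filters <- fc
    }
    entry
  })
  kind <- fixture$tables[[1]]$kind
  cfg <- list(kind = kind, mode = fixture$mode %||% "defined",
              output = paste0("integrated_", kind, ".tsv"), sources = srcs)
  path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, path)
  path
}
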