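config_error <- function(msgs) {
  stop(errorCondition(
    paste0("invalid run configuration:\n", paste0("  - ", msgs, collapse = "\n")),
    class = c("reoccur_config_error", "error")
  ))
}

#' Load and validate a run configuration
#'
#' The YAML run configuration replaces an interactive session: it names
#' the sources to integrate, their column roles and attribute kinds, the
#' per-source filter criteria with group logic, the run mode, and output
#' paths. All validation problems are collected and reported together.
#'
#' Layout:
#' \preformatted{
#' kind: list                 # or network
#' mode: defined              # or undefined
#' output: integrated_list.tsv
#' sources:
#'   - path: wt_corr_A1.tsv
#'     name: wt_corr_A1       # optional; defaults to file base name
#'     key_columns: [gene]    # optional; defaults to leading column(s)
#'     attributes: {corr: value}
#'     directed: false        # network sources only
#'     filters:
#'       corr: {logic: any, criteria: ["corr > 0.9", "corr < -0.9"]}
#' render:                    # optional, network runs only
#'   seed: 1
#'   format: png
#' }
#' Relative paths resolve against the config file's directory. Attribute
#' kinds must be declared for every attribute a filter references, so
#' filtering never depends on silent type inference.
#'
#' @param path Path to the YAML file.
#' @return A validated \code{run_config} object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) config_error(sprintf("config file not found: %s", path))
  y <- tryCatch(yaml::read_yaml(path),
                error = function(e) config_error(sprintf("cannot parse YAML: %s",
                                                         conditionMessage(e))))
  errs <- character()
  note <- function(msg) errs <<- c(errs, msg)

  known_top <- c("kind", "mode", "output", "sources", "render")
  extra <- setdiff(names(y), known_top)
  if (length(extra)) note(sprintf("unknown top-level key(s): %s", paste(extra, collapse = ", ")))

  kind <- y$kind %||% "list"
  if (!kind %in% c("list", "network")) note(sprintf("kind must be 'list' or 'network', got '%s'", kind))
  mode <- y$mode %||% "defined"
  if (!mode %in% c("defined", "undefined")) note(sprintf("mode must be 'defined' or 'undefined', got '%s'", mode))
  if (is.null(y$sources) || !length(y$sources)) note("at least one source is required")

  base <- dirname(normalizePath(path))
  known_src <- c("path", "name", "key_columns", "attributes", "directed", "filters")
  sources <- list()
  seen <- character()
  for (i in seq_along(y$sources)) {
    s <- y$sources[[i]]
    where <- sprintf("sources[%d]", i)
    extra <- setdiff(names(s), known_src)
    if (length(extra)) note(sprintf("%s: unknown key(s): %s", where, paste(extra, collapse = ", ")))
    if (is.null(s$path)) { note(sprintf("%s: missing 'path'", where)); next }
    spath <- s$path
    if (!grepl("^(/|[A-Za-z]:)", spath)) spath <- file.path(base, spath)
    if (!file.exists(spath)) note(sprintf("%s: file not found: %s", where, s$path))
    nm <- s$name %||% tools::file_path_sans_ext(basename(spath))
    if (nm %in% seen) note(sprintf("%s: duplicate source name '%s'", where, nm))
    seen <- c(seen, nm)
    attrs <- s$attributes
    schema <- if (length(attrs)) {
      data.frame(name = names(attrs), kind = unlist(attrs, use.names = FALSE),
                 stringsAsFactors = FALSE)
    } else empty_schema()
    if (nrow(schema) && !all(schema$kind %in% c("value", "label"))) {
      note(sprintf("%s: attribute kinds must be 'value' or 'label'", where))
    }
    fs <- NULL
    if (!is.null(s$filters)) {
      if (is.null(names(s$filters)) || any(!nzchar(names(s$filters)))) {
        note(sprintf("%s: 'filters' must be a mapping from attribute name to criteria", where))
      } else {
        groups <- list()
        for (a in names(s$filters)) {
          g <- s$filters[[a]]
          if (is.character(g)) g <- list(criteria = g)
          logic <- g$logic %||% "all"
          if (!logic %in% c("all", "any")) {
            note(sprintf("%s: filter group '%s': logic must be 'all' or 'any'", where, a))
            next
          }
          if (!a %in% schema$name) {
            note(sprintf("%s: filter references undeclared attribute '%s'", where, a))
            next
          }
          crits <- tryCatch(
            lapply(g$criteria, parse_criterion, schema = schema),
            error = function(e) { note(sprintf("%s: %s", where, conditionMessage(e))); NULL })
          if (is.null(crits) || !length(crits)) next
          wrong <- vapply(crits, function(cr) cr$attribute != a, logical(1))
          if (any(wrong)) {
            note(sprintf("%s: filter group '%s' contains criteria on other attributes", where, a))
            next
          }
          groups[[a]] <- list(criteria = crits, logic = logic)
        }
        fs <- tryCatch(filter_set(nm, groups),
                       error = function(e) { note(sprintf("%s: %s", where, conditionMessage(e))); NULL })
      }
    }
    sources[[length(sources) + 1L]] <- list(
      path = spath, name = nm,
      key_columns = if (!is.null(s$key_columns)) unlist(s$key_columns) else NULL,
      attr_kinds = if (nrow(schema)) stats::setNames(schema$kind, schema$name) else NULL,
      directed = isTRUE(s$directed), filters = fs
    )
  }

  render <- y$render
  if (!is.null(render)) {
    fmt <- render$format %||% "png"
    if (!fmt %in% c("png", "tiff")) note(sprintf("render: format must be 'png' or 'tiff', got '%s'", fmt))
  }

  if (length(errs)) config_error(errs)
  structure(list(kind = kind, mode = mode,
                 output = if (grepl("^(/|[A-Za-z]:)", y$output %||% "") ) y$output
                          else file.path(base, y$output %||% sprintf("integrated_%s.tsv", kind)),
                 sources = sources, render = render),
            class = "run_config")
}

#' Execute an integration run
#'
#' Reads every configured source, applies the configured filters (defined
#' mode), integrates, ranks by reoccurrence, and writes the report file.
#' Per-source in/out record counts and applied filters are logged to
#' standard error and duplicated into the report's provenance header.
#'
#' @param config A \code{\link{load_config}} result.
#' @param verbose Log per-source counts (default \code{TRUE}).
#' @return Invisibly, a list with \code{result} (the ranked
#'   \code{integrated_list} or \code{integrated_network}), \code{path}
#'   (the written report), and \code{counts} (per-source records in/out).
#' @export
run_integrate <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  tables <- lapply(config$sources, function(s) {
    read_source_table(s$path, name = s$name, kind = config$kind,
                      key_columns = s$key_columns, attr_kinds = s$attr_kinds)
  })
  filters <- Filter(Negate(is.null), stats::setNames(
    lapply(config$sources, `[[`, "filters"),
    vapply(config$sources, `[[`, character(1), "name")))

  counts <- do.call(rbind, lapply(tables, function(t) {
    n_in <- nrow(t$records)
    n_out <- if (config$mode == "defined" && !is.null(filters[[t$name]])) {
      nrow(suppressWarnings(apply_filter_set(t, filters[[t$name]]))$records)
    } else n_in
    data.frame(source = t$name, records_in = n_in, records_out = n_out,
               stringsAsFactors = FALSE)
  }))
  if (verbose) {
    for (i in seq_len(nrow(counts))) {
      fs <- filters[[counts$source[i]]]
      message(sprintf("[%s] %d -> %d record(s)%s", counts$source[i],
                      counts$records_in[i], counts$records_out[i],
                      if (config$mode == "defined" && !is.null(fs))
                        paste0(" | ", format(fs)) else ""))
    }
  }

  prov <- provenance_header(tables, filters, config$mode)
  if (config$kind == "list") {
    result <- integrate_lists(tables, filters, config$mode)
    write_list_report(result, prov, config$output)
  } else {
    dd <- vapply(config$sources, function(s)
      if (s$directed) "directed" else "undirected", character(1))
    names(dd) <- vapply(config$sources, `[[`, character(1), "name")
    result <- integrate_networks(tables, filters, config$mode, directedness = dd)
    write_network_report(result, prov, config$output)
  }
  if (verbose) message(sprintf("wrote %s", config$output))
  invisible(list(result = result, path = config$output, counts = counts))
}

#' Render a network report to images
#'
#' Batch equivalent of interactive network exploration: re-reads the edges
#' table of a written network report, applies degree / reoccurrence
#' thresholds, lays the subnetwork out deterministically, and writes the
#' network image plus the companion cumulative-statistics chart.
#'
#' @param report_path Path to a \code{\link{write_network_report}} file.
#' @param out_image Output image path.
#' @param min_degree,min_reoccurrence Optional thresholds, as in
#'   \code{\link{threshold_network}}.
#' @param seed Layout seed.
#' @param format \code{"png"} or \code{"tiff"}.
#' @param stats_image Optional path for the statistics chart; default
#'   alongside \code{out_image} with a \code{_stats} suffix.
#' @return Invisibly, the paths of the written images.
#' @export
run_render <- function(report_path, out_image, min_degree = NULL,
                       min_reoccurrence = NULL, seed = 1L,
                       format = c("png", "tiff"), stats_image = NULL) {
  format <- match.arg(format)
  rep <- read_network_report(report_path)
  network <- network_from_edges(rep$edges)
  sub <- threshold_network(network, min_degree, min_reoccurrence)
  if (!nrow(sub$edges)) {
    stop("thresholds remove every edge; nothing to render", call. = FALSE)
  }
  lay <- layout_network(sub, seed)
  render_network(sub, lay, out_image, format)
  if (is.null(stats_image)) {
    stats_image <- paste0(tools::file_path_sans_ext(out_image), "_stats.",
                          tools::file_ext(out_image))
  }
  render_stats_chart(network, stats_image, format)
  invisible(list(network_image = out_image, stats_image = stats_image))
}
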