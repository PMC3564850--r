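#' Cumulative at-or-above statistics
#'
#' For node degrees or edge reoccurrences, tabulates for each distinct
#' observed level \code{v} the number of items whose value is \code{>= v}.
#' Only observed levels are enumerated. Counts are strictly positive and
#' non-increasing in the level; the first row's count equals the total
#' number of items.
#'
#' @param values Non-empty vector of positive integers.
#' @return A data frame with columns \code{level} and
#'   \code{count_at_or_above}, levels strictly increasing.
#' @export
cumulative_stats <- function(values) {
  if (!length(values)) stop("cumulative_stats needs a non-empty input", call. = FALSE)
  stopifnot(is.numeric(values), all(values >= 1), all(values == round(values)))
  lv <- sort(unique(as.integer(values)))
  data.frame(
    level = lv,
    count_at_or_above = vapply(lv, function(v) sum(values >= v), integer(1))
  )
}

#' One-sided overrepresentation test
#'
#' Fisher's exact test for overrepresentation of a hit category among
#' selected items: the hypergeometric upper tail
#' \eqn{P(X \ge hits\_selected)} when drawing \code{selected} items from a
#' universe of \code{universe} items of which \code{hits_total} are hits.
#' Used to ask whether, say, known disease genes are enriched among the
#' prioritized candidates relative to the full candidate pool.
#'
#' @param hits_selected Hits among the selected items.
#' @param selected Number of selected items.
#' @param hits_total Hits in the whole universe.
#' @param universe Universe size.
#' @return The one-sided p-value.
#' @export
enrichment_test <- function(hits_selected, selected, hits_total, universe) {
  stopifnot(length(hits_selected) == 1L, length(selected) == 1L,
            length(hits_total) == 1L, length(universe) == 1L)
  if (hits_selected < 0 || selected < 0 || hits_total < 0 || universe < 1 ||
      hits_selected > min(selected, hits_total) ||
      selected > universe || hits_total > universe ||
      selected - hits_selected > universe - hits_total) {
    stop("inconsistent contingency counts", call. = FALSE)
  }
  stats::phyper(hits_selected - 1, hits_total, universe - hits_total,
                selected, lower.tail = FALSE)
}

format_provenance <- function(provenance) {
  stopifnot(is.list(provenance))
  lines <- c(
    sprintf("# integrated_files: %s", paste(provenance$integrated_files, collapse = ";")),
    sprintf("# mode: %s", provenance$mode %||% "defined")
  )
  filt <- provenance$applied_filters
  if (length(filt)) {
    lines <- c(lines, vapply(names(filt), function(s) {
      sprintf("# filter %s: %s", s, filt[[s]])
    }, character(1)))
  } else {
    lines <- c(lines, "# filter: none")
  }
  lines
}

provenance_header <- function(tables, filters, mode) {
  applied <- if (mode == "defined" && length(filters)) {
    fs <- filters[vapply(filters, function(f) length(f$groups) > 0, logical(1))]
    lapply(fs, format)
  } else list()
  list(integrated_files = vapply(tables, `[[`, character(1), "name"),
       mode = mode, applied_filters = applied)
}

df_to_tsv_lines <- function(df) {
  cols <- lapply(df, as.character)
  c(paste(names(df), collapse = "\t"),
    if (nrow(df)) do.call(paste, c(cols, sep = "\t")))
}

#' Write an integrated-list report
#'
#' Tab-delimited report: "#"-prefixed provenance header (integrated files,
#' mode, applied filters), then the three-column result table — element,
#' reoccurrence across all lists, semicolon-joined sorted source names — in
#' rank order.
#'
#' @param elements An \code{integrated_list} (see
#'   \code{\link{integrate_lists}}).
#' @param provenance List with \code{integrated_files}, \code{mode},
#'   \code{applied_filters} (named character).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_list_report <- function(elements, provenance, path) {
  df <- as.data.frame(elements)[, c("element", "reoccurrence", "sources")]
  writeLines(c(format_provenance(provenance), df_to_tsv_lines(df)),
             path, useBytes = TRUE)
  invisible(path)
}

#' Read back an integrated-list report
#'
#' @param path Path to a file written by \code{\link{write_list_report}}.
#' @return A list with \code{elements} (the ranked result data frame) and
#'   \code{provenance} (the raw header lines).
#' @export
read_list_report <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  df <- parse_tsv_block(body)
  df$reoccurrence <- as.integer(df$reoccurrence)
  list(elements = df, provenance = hdr)
}

parse_tsv_block <- function(lines) {
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  n <- length(lines) - 1L
  out <- as.data.frame(matrix("", nrow = n, ncol = length(header),
                              dimnames = list(NULL, header)),
                       stringsAsFactors = FALSE)
  if (n) {
    parts <- strsplit(lines[-1L], "\t", fixed = TRUE)
    for (i in seq_len(n)) {
      p <- parts[[i]]
      length(p) <- length(header)
      p[is.na(p)] <- ""
      out[i, ] <- p
    }
  }
  out
}

#' Write an integrated-network report
#'
#' Tab-delimited report with the provenance header followed by four tables
#' separated by blank lines, each introduced by a \code{# table:} marker:
#' \enumerate{
#'   \item node statistics — node degree and the number of nodes with
#'     degree at or above it;
#'   \item edge statistics — edge reoccurrence and the number of edges at
#'     or above it;
#'   \item nodes — node, reoccurrence, source networks;
#'   \item edges — \code{node_a}, \code{node_b}, \code{direction_status},
#'     \code{reoccurrence}, \code{sources}: a well-formed five-column edge
#'     list that imports directly into Cytoscape.
#' }
#'
#' @param network An \code{integrated_network}.
#' @param provenance As for \code{\link{write_list_report}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_network_report <- function(network, provenance, path) {
  stopifnot(inherits(network, "integrated_network"))
  node_stats <- if (nrow(network$nodes)) {
    stats::setNames(cumulative_stats(network$nodes$degree), c("degree", "nodes"))
  } else data.frame(degree = integer(), nodes = integer())
  edge_stats <- if (nrow(network$edges)) {
    stats::setNames(cumulative_stats(network$edges$reoccurrence),
                    c("reoccurrence", "edges"))
  } else data.frame(reoccurrence = integer(), edges = integer())
  nodes <- network$nodes[, c("node", "reoccurrence", "sources")]
  edges <- network$edges[, c("node_a", "node_b", "direction_status",
                             "reoccurrence", "sources")]
  lines <- c(
    format_provenance(provenance),
    "# table: node_statistics", df_to_tsv_lines(node_stats), "",
    "# table: edge_statistics", df_to_tsv_lines(edge_stats), "",
    "# table: nodes", df_to_tsv_lines(nodes), "",
    "# table: edges", df_to_tsv_lines(edges)
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read back an integrated-network report
#'
#' @param path Path to a file written by \code{\link{write_network_report}}.
#' @return A list with data frames \code{node_statistics},
#'   \code{edge_statistics}, \code{nodes}, \code{edges}, plus
#'   \code{provenance} (header lines).
#' @export
read_network_report <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  prov <- lines[startsWith(lines, "#") & !startsWith(lines, "# table:")]
  marks <- which(startsWith(lines, "# table:"))
  if (length(marks) != 4L) {
    stop(sprintf("malformed network report '%s': expected 4 tables, found %d",
                 path, length(marks)), call. = FALSE)
  }
  bounds <- c(marks, length(lines) + 1L)
  tabs <- lapply(seq_along(marks), function(i) {
    nm <- trimws(sub("^# table:", "", lines[marks[i]]))
    block <- lines[(marks[i] + 1L):(bounds[i + 1L] - 1L)]
    block <- block[nzchar(block) & !startsWith(block, "#")]
    list(name = nm, df = parse_tsv_block(block))
  })
  out <- stats::setNames(lapply(tabs, `[[`, "df"), vapply(tabs, `[[`, character(1), "name"))
  need <- c("node_statistics", "edge_statistics", "nodes", "edges")
  if (!all(need %in% names(out))) {
    stop(sprintf("malformed network report '%s': missing table(s) %s", path,
                 paste(setdiff(need, names(out)), collapse = ", ")), call. = FALSE)
  }
  for (nm in c("node_statistics", "edge_statistics")) {
    out[[nm]][] <- lapply(out[[nm]], as.integer)
  }
  out$nodes$reoccurrence <- as.integer(out$nodes$reoccurrence)
  out$edges$reoccurrence <- as.integer(out$edges$reoccurrence)
  out$provenance <- prov
  out[c(need, "provenance")]
}

#' Rebuild an integrated network from a report's edges table
#'
#' The report stores direction status but not the individual orientations;
#' rebuilt directed and merged edges are assigned the canonical
#' \code{"a->b"} orientation for rendering purposes.
#'
#' @param edges A five-column edges data frame as written by
#'   \code{\link{write_network_report}}.
#' @return An \code{integrated_network}.
#' @export
network_from_edges <- function(edges) {
  need <- c("node_a", "node_b", "direction_status", "reoccurrence", "sources")
  stopifnot(all(need %in% names(edges)))
  edges <- edges[, need]
  edges$reoccurrence <- as.integer(edges$reoccurrence)
  edges$directions <- vapply(edges$direction_status, function(s) {
    switch(s, undirected = "none", directed = "a->b", merged = "a->b,none",
           stop(sprintf("unknown direction status '%s'", s), call. = FALSE))
  }, character(1), USE.NAMES = FALSE)
  edges <- rank_candidates(edges)
  structure(list(nodes = nodes_from_edges(edges), edges = edges),
            class = "integrated_network")
}
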