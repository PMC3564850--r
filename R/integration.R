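#' Canonical edge key
#'
#' Edge identity is the unordered node pair: the key of \code{(a, b)}
#' equals the key of \code{(b, a)}. The pair is ordered lexicographically
#' under C collation, so the convention is locale independent; comparison
#' is case sensitive, so \code{"nrl"} and \code{"Nrl"} are distinct nodes.
#' Self-loops \code{(a, a)} are valid keys.
#'
#' @param a,b Node identifiers (vectorized).
#' @return A data frame with columns \code{node_a}, \code{node_b}
#'   (canonical order) and \code{key} (the \code{"a|b"} edge label).
#' @export
canonical_edge_key <- function(a, b) {
  stopifnot(all(nzchar(a)), all(nzchar(b)))
  na <- pmin_chr(a, b)
  nb <- pmax_chr(a, b)
  data.frame(node_a = na, node_b = nb, key = edge_label(na, nb),
             stringsAsFactors = FALSE)
}

check_sources <- function(tables, kind) {
  stopifnot(length(tables) >= 1L)
  for (t in tables) {
    stopifnot(inherits(t, "source_table"))
    if (t$kind != kind) {
      stop(sprintf("cannot mix list and network sources in one run ('%s' is a %s)",
                   t$name, t$kind), call. = FALSE)
    }
  }
  nms <- vapply(tables, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop(sprintf("duplicate source name(s): %s",
                 paste(unique(nms[duplicated(nms)]), collapse = ", ")), call. = FALSE)
  }
  nms
}

maybe_filter <- function(table, filters, mode) {
  fs <- filters[[table$name]]
  if (mode == "defined" && !is.null(fs)) apply_filter_set(table, fs) else table
}

#' Integrate list sources
#'
#' Merges list sources into a single ranked candidate list. In
#' \code{"defined"} mode each source is first filtered with its
#' \code{\link{filter_set}} (sources without one pass through unfiltered);
#' \code{"undefined"} mode ignores all filters and attributes. Each source
#' contributes each distinct element at most once — duplicate rows within a
#' source collapse — and an element's reoccurrence is the number of
#' distinct sources containing it after filtering.
#'
#' @param tables List of list-kind \code{\link{source_table}} objects with
#'   unique names.
#' @param filters Named list (by source name) of \code{\link{filter_set}}s.
#' @param mode \code{"defined"} or \code{"undefined"}.
#' @return An \code{integrated_list}: a data frame with columns
#'   \code{element}, \code{reoccurrence}, \code{sources}
#'   (semicolon-joined, sorted), ordered by \code{\link{rank_candidates}}.
#' @export
integrate_lists <- function(tables, filters = list(), mode = c("defined", "undefined")) {
  mode <- match.arg(mode)
  check_sources(tables, "list")
  pairs <- lapply(tables, function(t) {
    ft <- maybe_filter(t, filters, mode)
    el <- unique(ft$records[[ft$key_columns[1]]])
    if (!length(el)) return(NULL)
    data.frame(element = el, source = t$name, stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs) || !nrow(pairs)) {
    out <- data.frame(element = character(), reoccurrence = integer(),
                      sources = character(), stringsAsFactors = FALSE)
    return(structure(out, class = c("integrated_list", "data.frame")))
  }
  by_el <- split(pairs$source, pairs$element)
  out <- data.frame(
    element = names(by_el),
    reoccurrence = lengths(by_el),
    sources = vapply(by_el, join_sources, character(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(rank_candidates(out), class = c("integrated_list", "data.frame"))
}

# Node table (node, degree, reoccurrence, sources) derived from an edge
# table carrying reoccurrence and sources. Degree counts distinct incident
# edge keys (a self-loop contributes 1); node reoccurrence counts the
# distinct sources in which the node appears in any retained edge.
nodes_from_edges <- function(edges) {
  if (!nrow(edges)) {
    return(data.frame(node = character(), degree = integer(),
                      reoccurrence = integer(), sources = character(),
                      stringsAsFactors = FALSE))
  }
  loop <- edges$node_a == edges$node_b
  ends <- data.frame(
    node = c(edges$node_a, edges$node_b[!loop]),
    sources = c(edges$sources, edges$sources[!loop]),
    stringsAsFactors = FALSE
  )
  by_node <- split(ends$sources, ends$node)
  srcs <- lapply(by_node, function(s) unique(unlist(split_sources(s))))
  data.frame(
    node = names(by_node),
    degree = lengths(by_node),
    reoccurrence = lengths(srcs),
    sources = vapply(srcs, join_sources, character(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )[order_c(names(by_node)), , drop = FALSE]
}

#' Integrate network sources
#'
#' Merges edge-list sources into a composite network. Edge identity is the
#' unordered node pair (\code{\link{canonical_edge_key}}); a source
#' contributes each distinct pair once regardless of row duplicates or of
#' observing both orientations. Per edge, the observed orientations
#' accumulate: \code{"none"} from undirected sources, \code{"a->b"} /
#' \code{"b->a"} from directed sources (relative to the canonical order).
#' The direction status is \code{"merged"} when both an undirected and a
#' directed observation exist, \code{"directed"} when only directed ones
#' do, and \code{"undirected"} otherwise.
#'
#' @param tables List of network-kind \code{\link{source_table}}s.
#' @param filters Named list of \code{\link{filter_set}}s (defined mode).
#' @param mode \code{"defined"} or \code{"undefined"}.
#' @param directedness Named character vector mapping each source name to
#'   \code{"directed"} or \code{"undirected"}. Sources not named are
#'   \code{"undirected"} (the edge-list format carries no direction
#'   marker, so directedness is a per-source declaration).
#' @return An \code{integrated_network}: a list with \code{nodes}
#'   (\code{node}, \code{degree}, \code{reoccurrence}, \code{sources}) and
#'   \code{edges} (\code{node_a}, \code{node_b}, \code{direction_status},
#'   \code{reoccurrence}, \code{sources}, \code{directions}) ranked by
#'   \code{\link{rank_candidates}}.
#' @export
integrate_networks <- function(tables, filters = list(),
                               mode = c("defined", "undefined"),
                               directedness = character()) {
  mode <- match.arg(mode)
  nms <- check_sources(tables, "network")
  dd <- stats::setNames(rep("undirected", length(nms)), nms)
  if (length(directedness)) {
    bad <- setdiff(names(directedness), nms)
    if (length(bad)) stop(sprintf("directedness declared for unknown source(s): %s",
                                  paste(bad, collapse = ", ")), call. = FALSE)
    stopifnot(all(directedness %in% c("directed", "undirected")))
    dd[names(directedness)] <- directedness
  }

  obs <- lapply(tables, function(t) {
    ft <- maybe_filter(t, filters, mode)
    a <- ft$records[[ft$key_columns[1]]]
    b <- ft$records[[ft$key_columns[2]]]
    if (!length(a)) return(NULL)
    ck <- canonical_edge_key(a, b)
    orient <- if (dd[[t$name]] == "directed") {
      ifelse(a == ck$node_a & b == ck$node_b, "a->b", "b->a")
    } else "none"
    unique(data.frame(ck, orient = orient, source = t$name,
                      stringsAsFactors = FALSE))
  })
  obs <- do.call(rbind, obs)

  if (is.null(obs) || !nrow(obs)) {
    edges <- data.frame(node_a = character(), node_b = character(),
                        direction_status = character(), reoccurrence = integer(),
                        sources = character(), directions = character(),
                        stringsAsFactors = FALSE)
    return(structure(list(nodes = nodes_from_edges(edges), edges = edges),
                     class = "integrated_network"))
  }

  by_key <- split(obs, obs$key)
  edges <- do.call(rbind, lapply(by_key, function(e) {
    dirs <- sort_c(unique(e$orient))
    has_dir <- any(dirs != "none")
    has_und <- any(dirs == "none")
    status <- if (has_dir && has_und) "merged" else if (has_dir) "directed" else "undirected"
    data.frame(node_a = e$node_a[1], node_b = e$node_b[1],
               direction_status = status,
               reoccurrence = length(unique(e$source)),
               sources = join_sources(e$source),
               directions = paste(dirs, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(edges) <- NULL
  edges <- rank_candidates(edges)
  structure(list(nodes = nodes_from_edges(edges), edges = edges),
            class = "integrated_network")
}

#' @export
print.integrated_network <- function(x, ...) {
  cat(sprintf("<integrated_network> %d node(s), %d edge(s)\n",
              nrow(x$nodes), nrow(x$edges)))
  st <- table(x$edges$direction_status)
  if (length(st)) cat("  ", paste(names(st), st, sep = ": ", collapse = ", "), "\n")
  invisible(x)
}

#' Rank integrated candidates by reoccurrence
#'
#' Orders an integrated element or edge table descending by reoccurrence;
#' ties break by ascending lexicographic identifier (the element, or the
#' \code{"a|b"} edge label), under C collation so the order is
#' deterministic across platforms.
#'
#' @param items Data frame with a \code{reoccurrence} column and either an
#'   \code{element} column or \code{node_a}/\code{node_b} columns.
#' @return The same data frame, reordered.
#' @export
rank_candidates <- function(items) {
  if (!nrow(items)) return(items)
  id <- if ("element" %in% names(items)) items$element
        else edge_label(items$node_a, items$node_b)
  out <- items[order_c(-items$reoccurrence, id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
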