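#' Threshold an integrated network
#'
#' Extracts the subnetwork at a chosen level of node degree and/or edge
#' reoccurrence: an edge is retained when its reoccurrence is at least
#' \code{min_reoccurrence} (if given) and both endpoints have degree at
#' least \code{min_degree} (if given) \emph{in the original network} — the
#' degrees shown by the cumulative statistics the user selects from.
#' Nodes left without incident edges are dropped and degrees are
#' recomputed on the result. Raising either threshold never adds nodes or
#' edges; thresholds of 1 are the identity.
#'
#' @param network An \code{integrated_network}.
#' @param min_degree,min_reoccurrence Optional integer thresholds
#'   (\code{>= 1}).
#' @return The thresholded \code{integrated_network}.
#' @export
threshold_network <- function(network, min_degree = NULL, min_reoccurrence = NULL) {
  stopifnot(inherits(network, "integrated_network"))
  if (!is.null(min_degree)) stopifnot(min_degree >= 1)
  if (!is.null(min_reoccurrence)) stopifnot(min_reoccurrence >= 1)
  edges <- network$edges
  keep <- rep(TRUE, nrow(edges))
  if (!is.null(min_reoccurrence)) keep <- keep & edges$reoccurrence >= min_reoccurrence
  if (!is.null(min_degree)) {
    deg <- stats::setNames(network$nodes$degree, network$nodes$node)
    keep <- keep & deg[edges$node_a] >= min_degree & deg[edges$node_b] >= min_degree
  }
  edges <- edges[keep, , drop = FALSE]
  rownames(edges) <- NULL
  if (!nrow(edges) && nrow(network$edges)) {
    warning("all edges removed by thresholding; the result is empty", call. = FALSE)
  }
  structure(list(nodes = nodes_from_edges(edges), edges = edges),
            class = "integrated_network")
}

#' Deterministic force-directed layout
#'
#' Computes Fruchterman–Reingold node positions with a seeded RNG, so the
#' same (network, seed) pair always yields the same coordinates — the
#' batch replacement for interactive node dragging. Coordinates are
#' rescaled to the unit square; a single node sits at the canvas center.
#'
#' @param network A non-empty \code{integrated_network}.
#' @param seed Integer seed.
#' @return A \code{layout_result}: list with \code{positions} (matrix of
#'   x,y rows named by node) and \code{seed}.
#' @export
layout_network <- function(network, seed = 1L) {
  stopifnot(inherits(network, "integrated_network"))
  if (!nrow(network$nodes)) stop("cannot lay out an empty network", call. = FALSE)
  nodes <- network$nodes$node
  if (length(nodes) == 1L) {
    pos <- matrix(0, 1, 2, dimnames = list(nodes, c("x", "y")))
    return(structure(list(positions = pos, seed = as.integer(seed)),
                     class = "layout_result"))
  }
  g <- igraph::graph_from_data_frame(
    network$edges[, c("node_a", "node_b")], directed = FALSE,
    vertices = data.frame(name = nodes)
  )
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
  set.seed(as.integer(seed))
  pos <- igraph::layout_with_fr(g, niter = 500)
  pos <- igraph::norm_coords(pos, -1, 1, -1, 1)
  dimnames(pos) <- list(igraph::V(g)$name, c("x", "y"))
  stopifnot(all(is.finite(pos)))
  structure(list(positions = pos[nodes, , drop = FALSE], seed = as.integer(seed)),
            class = "layout_result")
}

# Visual vocabulary: blue line = undirected observation, pink line with
# pink arrow = directed, blue line with pink arrow = merged. Node radius
# grows with degree, stroke width with reoccurrence.
default_style <- function() {
  list(
    col_undirected = "#2C66C9",
    col_directed = "#E4559B",
    node_fill = "#F2A33C",
    node_border = "#8A5A10",
    node_radius = function(degree) 0.028 + 0.012 * (degree - 1),
    edge_lwd = function(reoccurrence) 1.4 + 1.8 * (reoccurrence - 1),
    label_cex = 0.85
  )
}

open_device <- function(path, format, width, height) {
  switch(format,
    png = grDevices::png(path, width = width, height = height, res = 96),
    tiff = grDevices::tiff(path, width = width, height = height, res = 96),
    stop(sprintf("unsupported image format '%s'", format), call. = FALSE))
}

draw_arrowhead <- function(x0, y0, x1, y1, at, col, size = 0.035) {
  # arrowhead on the segment, pointing from (x0,y0) toward (x1,y1), tip at `at`
  dx <- x1 - x0; dy <- y1 - y0
  len <- sqrt(dx^2 + dy^2)
  if (len < 1e-9) return(invisible())
  ux <- dx / len; uy <- dy / len
  tipx <- x0 + at * dx; tipy <- y0 + at * dy
  bx <- tipx - size * ux; by <- tipy - size * uy
  px <- -uy; py <- ux
  graphics::polygon(
    c(tipx, bx + 0.5 * size * px, bx - 0.5 * size * px),
    c(tipy, by + 0.5 * size * py, by - 0.5 * size * py),
    col = col, border = col
  )
}

#' Render an integrated network to an image file
#'
#' Static rendering with the composite-network edge semantics: undirected
#' edges are blue lines; directed edges are pink lines with a pink
#' arrowhead per observed orientation; merged edges (undirected + directed
#' support) are a single blue line carrying the pink arrow. Circle size is
#' proportional to node degree and line stroke to edge reoccurrence, so
#' equal reoccurrence renders with equal stroke. Output is PNG or TIFF;
#' identical inputs produce identical decoded pixels.
#'
#' @param network A non-empty \code{integrated_network}.
#' @param layout A \code{\link{layout_network}} result covering all nodes.
#' @param path Output image path.
#' @param format \code{"png"} or \code{"tiff"}.
#' @param style Style list as from \code{default_style}; override entries
#'   to adjust colors or size rules.
#' @param width,height Image size in pixels.
#' @param labels Draw node labels (default \code{TRUE}).
#' @return Invisibly, \code{path}.
#' @export
render_network <- function(network, layout, path, format = c("png", "tiff"),
                           style = default_style(), width = 900, height = 900,
                           labels = TRUE) {
  format <- match.arg(format)
  stopifnot(inherits(network, "integrated_network"), inherits(layout, "layout_result"))
  if (!nrow(network$nodes)) stop("cannot render an empty network", call. = FALSE)
  missing <- setdiff(network$nodes$node, rownames(layout$positions))
  if (length(missing)) {
    stop(sprintf("layout lacks position(s) for node(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  pos <- layout$positions
  open_device(path, format, width, height)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mar = rep(0.5, 4))
  graphics::plot.new()
  graphics::plot.window(xlim = c(-1.2, 1.2), ylim = c(-1.2, 1.2), asp = 1)

  deg <- stats::setNames(network$nodes$degree, network$nodes$node)
  for (i in seq_len(nrow(network$edges))) {
    e <- network$edges[i, ]
    x0 <- pos[e$node_a, "x"]; y0 <- pos[e$node_a, "y"]
    x1 <- pos[e$node_b, "x"]; y1 <- pos[e$node_b, "y"]
    lwd <- style$edge_lwd(e$reoccurrence)
    line_col <- if (e$direction_status == "directed") style$col_directed else style$col_undirected
    if (e$node_a == e$node_b) {
      r <- style$node_radius(deg[[e$node_a]])
      theta <- seq(0, 2 * pi, length.out = 60)
      graphics::lines(x0 + 1.6 * r + 1.4 * r * cos(theta),
                      y0 + 1.4 * r * sin(theta), col = line_col, lwd = lwd)
    } else {
      graphics::segments(x0, y0, x1, y1, col = line_col, lwd = lwd)
      dirs <- strsplit(e$directions, ",", fixed = TRUE)[[1]]
      r_b <- style$node_radius(deg[[e$node_b]])
      r_a <- style$node_radius(deg[[e$node_a]])
      len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
      if ("a->b" %in% dirs) {
        draw_arrowhead(x0, y0, x1, y1, at = max(0.5, 1 - (r_b + 0.01) / len),
                       col = style$col_directed)
      }
      if ("b->a" %in% dirs) {
        draw_arrowhead(x1, y1, x0, y0, at = max(0.5, 1 - (r_a + 0.01) / len),
                       col = style$col_directed)
      }
    }
  }
  for (i in seq_len(nrow(network$nodes))) {
    n <- network$nodes[i, ]
    r <- style$node_radius(n$degree)
    graphics::symbols(pos[n$node, "x"], pos[n$node, "y"], circles = r,
                      inches = FALSE, add = TRUE,
                      bg = style$node_fill, fg = style$node_border)
    if (labels) {
      graphics::text(pos[n$node, "x"], pos[n$node, "y"] - r - 0.045, n$node,
                     cex = style$label_cex)
    }
  }
  invisible(path)
}

#' Render the network statistics chart
#'
#' Companion chart to \code{\link{render_network}}: the two cumulative
#' plots used to balance network size against quality — number of nodes
#' at or above each node degree (top) and number of edges at or above each
#' edge reoccurrence (bottom). These are the levels at which
#' \code{\link{threshold_network}} re-draws the network.
#'
#' @param network A non-empty \code{integrated_network}.
#' @param path Output image path.
#' @param format \code{"png"} or \code{"tiff"}.
#' @param width,height Image size in pixels.
#' @return Invisibly, \code{path}.
#' @export
render_stats_chart <- function(network, path, format = c("png", "tiff"),
                               width = 600, height = 700) {
  format <- match.arg(format)
  stopifnot(inherits(network, "integrated_network"))
  if (!nrow(network$nodes)) stop("cannot chart an empty network", call. = FALSE)
  ns <- cumulative_stats(network$nodes$degree)
  es <- cumulative_stats(network$edges$reoccurrence)
  open_device(path, format, width, height)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mfrow = c(2, 1), mar = c(4.2, 4.2, 2.2, 1))
  graphics::plot(ns$level, ns$count_at_or_above, type = "b", pch = 19,
                 col = "#2C66C9", xlab = "node degree",
                 ylab = "nodes with degree >= level", main = "Nodes vs degree",
                 xaxt = "n", ylim = c(0, max(ns$count_at_or_above)))
  graphics::axis(1, at = ns$level)
  graphics::plot(es$level, es$count_at_or_above, type = "b", pch = 19,
                 col = "#E4559B", xlab = "edge reoccurrence",
                 ylab = "edges with reoccurrence >= level",
                 main = "Edges vs reoccurrence", xaxt = "n",
                 ylim = c(0, max(es$count_at_or_above)))
  graphics::axis(1, at = es$level)
  invisible(path)
}
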