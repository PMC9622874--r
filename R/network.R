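#' Build a bipartite interaction network from an edge list
#'
#' The node sets are exactly the endpoints observed in the edges, optionally
#' extended with isolated nodes (e.g. disease genes for which no interacting
#' miRNA is recorded); isolated nodes keep degree 0 and never enter hub
#' selection.
#'
#' @param edges an `interaction_edges` collection from [read_edge_list()] or
#'   [make_edges()], all of one layer.
#' @param left_nodes,right_nodes optional character vectors of node ids to
#'   retain even when they have no edge.
#' @return An object of class `bipartite_network`: a list with `left`,
#'   `right` (node id vectors), `edges` and the layer tag.
#' @export
build_network <- function(edges, left_nodes = NULL, right_nodes = NULL) {
  if (!inherits(edges, "interaction_edges")) {
    stop("edges must be an interaction_edges collection; see make_edges()")
  }
  if (!nrow(edges)) stop("cannot build a network from an empty edge collection")
  left <- unique(c(edges$source, setdiff(left_nodes, edges$source)))
  right <- unique(c(edges$target, setdiff(right_nodes, edges$target)))
  net <- list(left = left, right = right, edges = edges,
              layer = attr(edges, "layer"))
  class(net) <- "bipartite_network"
  net
}

#' Node degrees of one side of a bipartite network
#'
#' @param net a `bipartite_network`.
#' @param side `"left"` or `"right"`.
#' @return A data frame with columns `node` and `degree`, sorted by
#'   decreasing degree; isolated nodes appear with degree 0.
#' @export
network_degrees <- function(net, side = c("left", "right")) {
  side <- match.arg(side)
  nodes <- net[[side]]
  ends <- if (side == "left") net$edges$source else net$edges$target
  deg <- table(factor(norm_id(ends), levels = norm_id(nodes)))
  out <- data.frame(node = nodes, degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  out[order(-out$degree, out$node), , drop = FALSE]
}

#' Select hub nodes by whole-degree-tier accumulation
#'
#' Scans degree tiers from the highest degree downwards and accumulates whole
#' tiers while the cumulative node count stays within `max_nodes`. A tier is
#' taken in full or not at all, so ties are never broken; with the default
#' `max_nodes = 15` this reproduces both published hub choices (7 miRNAs at
#' degree 4; 11 lncRNAs at degrees 7 and 6). If even the top tier exceeds
#' `max_nodes` it is returned whole with `overflow = TRUE`. Degree-0
#' (isolated) nodes are never selected.
#'
#' @param net a `bipartite_network`.
#' @param side which side to select hubs from.
#' @param max_nodes largest acceptable cumulative selection size.
#' @return An object of class `hub_selection`: list with `side`,
#'   `degree_cutoff`, `ids`, `degree_table`, `overflow`.
#' @export
select_hubs <- function(net, side = c("left", "right"), max_nodes = 15) {
  side <- match.arg(side)
  stopifnot(max_nodes >= 1)
  deg <- network_degrees(net, side)
  deg <- deg[deg$degree > 0, , drop = FALSE]
  if (!nrow(deg)) stop("no nodes with positive degree on the ", side, " side")
  tiers <- sort(unique(deg$degree), decreasing = TRUE)
  sizes <- vapply(tiers, function(d) sum(deg$degree == d), 1L)
  cum <- cumsum(sizes)
  overflow <- FALSE
  if (cum[1L] > max_nodes) {
    cutoff <- tiers[1L]
    overflow <- TRUE
  } else {
    k <- max(which(cum <= max_nodes))
    cutoff <- tiers[k]
  }
  sel <- deg[deg$degree >= cutoff, , drop = FALSE]
  out <- list(side = side, degree_cutoff = cutoff, ids = sel$node,
              degree_table = deg, overflow = overflow)
  class(out) <- "hub_selection"
  out
}

#' Restrict two stacked bipartite networks to their selected hubs
#'
#' Assembles the final three-layer (tripartite) view: edges of the first
#' network incident to the selected middle-layer hubs, plus edges of the
#' second network joining those hubs to the selected third-layer hubs. No
#' edge is ever introduced, only dropped.
#'
#' @param p_net first-layer network (e.g. mRNA-miRNA), hubs on its right side.
#' @param m_hubs a `hub_selection` (or character vector) of middle-layer ids.
#' @param l_net second-layer network (e.g. miRNA-lncRNA) whose left side are
#'   middle-layer ids.
#' @param l_hubs a `hub_selection` (or character vector) of third-layer ids.
#' @return A data frame of class `tripartite_network` with columns `layer`,
#'   `source`, `target`.
#' @export
assemble_tripartite <- function(p_net, m_hubs, l_net, l_hubs) {
  m_ids <- if (inherits(m_hubs, "hub_selection")) m_hubs$ids else m_hubs
  l_ids <- if (inherits(l_hubs, "hub_selection")) l_hubs$ids else l_hubs
  if (!length(intersect(norm_id(m_ids), norm_id(p_net$right)))) {
    stop("middle-layer hub set is disjoint from the first network's right side")
  }
  if (!length(intersect(norm_id(l_ids), norm_id(l_net$right)))) {
    stop("third-layer hub set is disjoint from the second network's right side")
  }
  e1 <- p_net$edges[norm_id(p_net$edges$target) %in% norm_id(m_ids), , drop = FALSE]
  e2 <- l_net$edges[norm_id(l_net$edges$source) %in% norm_id(m_ids) &
                    norm_id(l_net$edges$target) %in% norm_id(l_ids), , drop = FALSE]
  out <- rbind(
    data.frame(layer = rep(p_net$layer, nrow(e1)), source = e1$source,
               target = e1$target, stringsAsFactors = FALSE),
    data.frame(layer = rep(l_net$layer, nrow(e2)), source = e2$source,
               target = e2$target, stringsAsFactors = FALSE)
  )
  rownames(out) <- NULL
  class(out) <- c("tripartite_network", "data.frame")
  out
}

#' @rdname assemble_tripartite
#' @param x a `tripartite_network`.
#' @param path output TSV path (3 columns: layer, source, target).
#' @export
write_tripartite <- function(x, path) {
  stopifnot(inherits(x, "tripartite_network"))
  write_report_tsv(as.data.frame(x), path)
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("Bipartite network [%s]: %d left x %d right nodes, %d edges\n",
              x$layer, length(x$left), length(x$right), nrow(x$edges)))
  invisible(x)
}

#' @export
print.hub_selection <- function(x, ...) {
  cat(sprintf("Hub selection (%s side): %d nodes at degree >= %d%s\n",
              x$side, length(x$ids), x$degree_cutoff,
              if (x$overflow) " [top tier exceeded max_nodes]" else ""))
  print(x$degree_table[x$degree_table$degree >= x$degree_cutoff, ],
        row.names = FALSE)
  invisible(x)
}
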