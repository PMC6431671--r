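#' Construct a typed interaction network
#'
#' A simple undirected graph whose nodes carry a role (canonically one of
#' herb, compound, putative_target, disease_target; integration stages may
#' use provenance roles) and whose edges carry a combined confidence score
#' in \[0, 1\]. Self-loops are dropped and duplicate edges collapsed (the
#' maximum score is retained) with a warning, so the invariant of a simple
#' graph always holds on the returned object.
#'
#' @param nodes `data.frame` with `node_id` and `role`, or a character
#'   vector of ids (role defaults to `"putative_target"`).
#' @param edges `data.frame` with `node_a`, `node_b` and optionally
#'   `combined_score` (defaults to 1).
#' @return An object of class `typed_network` with elements `nodes`, `edges`.
#' @export
typed_network <- function(nodes, edges) {
  if (is.character(nodes))
    nodes <- data.table(node_id = nodes, role = "putative_target")
  nodes <- as.data.table(nodes)
  edges <- as.data.table(edges)
  if (!"combined_score" %in% names(edges)) edges[, combined_score := 1]
  if (anyDuplicated(nodes$node_id)) nodes <- unique(nodes, by = "node_id")
  missing <- setdiff(c(edges$node_a, edges$node_b), nodes$node_id)
  if (length(missing))
    stop_config("edge endpoint(s) absent from node table: ",
                paste(sort(missing), collapse = ", "))
  if (any(edges$combined_score < 0 | edges$combined_score > 1))
    stop_config("combined scores must lie in [0, 1]")
  loops <- edges$node_a == edges$node_b
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop(s)", sum(loops)))
    edges <- edges[!loops]
  }
  ## canonical endpoint order, then collapse multi-edges keeping max score
  swap <- edges$node_a > edges$node_b
  if (any(swap)) {
    tmp <- edges$node_a[swap]
    edges[swap, node_a := node_b]
    edges[swap, node_b := tmp]
  }
  if (anyDuplicated(edges, by = c("node_a", "node_b"))) {
    warning("collapsed duplicate edges (keeping maximum combined score)")
    edges <- edges[, .(combined_score = max(combined_score)),
                   by = .(node_a, node_b)]
  }
  setkey(edges, node_a, node_b)
  structure(list(nodes = nodes[], edges = edges[]), class = "typed_network")
}

#' @export
print.typed_network <- function(x, ...) {
  cat(sprintf("typed_network: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  print(table(x$nodes$role))
  invisible(x)
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges[, .(node_a, node_b)], directed = FALSE,
    vertices = net$nodes$node_id)
}

#' Filter edges by the strict combined-score median cut
#'
#' Retains edges whose combined score strictly exceeds the median of all
#' input scores, the screen used to restrict an interaction network to its
#' higher-confidence half. If every score is equal, zero edges survive the
#' strict cut and a warning is emitted. The retained fraction is attached
#' as attribute `retained_fraction` (always at most 0.5).
#'
#' @param edges Edge table with `combined_score`, or a `typed_network`.
#' @return Filtered edge table (or network of the same nodes).
#' @export
filter_edges_by_median_score <- function(edges) {
  if (inherits(edges, "typed_network")) {
    kept <- filter_edges_by_median_score(edges$edges)
    net <- typed_network(edges$nodes, kept)
    setattr(net, "retained_fraction", attr(kept, "retained_fraction"))
    return(net)
  }
  e <- as.data.table(edges)
  if (nrow(e) == 0) stop_config("cannot median-filter an empty edge list")
  med <- stats::median(e$combined_score)
  out <- e[combined_score > med]
  if (nrow(out) == 0)
    warning("no edge strictly exceeds the median combined score; all edges dropped")
  setattr(out, "retained_fraction", nrow(out) / nrow(e))
  out[]
}

#' Node centralities of a typed network
#'
#' Computes the three topological features used for hub screening on the
#' undirected, unweighted graph (combined scores play no role in shortest
#' paths):
#' \describe{
#'   \item{degree}{number of links to the node;}
#'   \item{betweenness}{for node v, the sum over unordered pairs (s, t) of
#'     the fraction of shortest s--t paths running through v (unnormalized
#'     pair-fraction convention);}
#'   \item{closeness}{the inverse of the farness, normalized per connected
#'     component: `(n_comp - 1) / sum of distances` to the other nodes of
#'     v's component; an isolated node has closeness 0.}
#' }
#'
#' @param net A `typed_network`, or an edge table (optionally with a
#'   `nodes` argument to include isolated nodes).
#' @param nodes Optional node ids when `net` is an edge table.
#' @return `data.table` with `node_id`, `degree`, `betweenness`,
#'   `closeness`, sorted by `node_id`.
#' @export
node_topology <- function(net, nodes = NULL) {
  if (inherits(net, "typed_network")) {
    ids <- net$nodes$node_id
    ea <- net$edges$node_a
    eb <- net$edges$node_b
  } else {
    ea <- as.character(net$node_a)
    eb <- as.character(net$node_b)
    ids <- unique(c(ea, eb, nodes))
  }
  ## numeric edge encoding avoids per-call data-frame plumbing; simplify()
  ## enforces the simple-graph invariant for raw edge-table input
  g <- igraph::simplify(igraph::make_graph(
    rbind(match(ea, ids), match(eb, ids)), n = length(ids),
    directed = FALSE))
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  D <- igraph::distances(g)
  clo <- vapply(seq_len(nrow(D)), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    if (length(d) == 0) 0 else length(d) / sum(d)
  }, numeric(1))
  ord <- order(ids)
  out <- data.table(node_id = ids[ord], degree = as.integer(deg[ord]),
                    betweenness = as.numeric(btw[ord]), closeness = clo[ord])
  setkey(out, node_id)
  out[]
}

#' Screen major hubs by the triple-median rule
#'
#' Computes the network-wide cut value (median by default, mean available)
#' of each of the three centralities and selects the nodes whose degree,
#' betweenness and closeness all strictly exceed the corresponding cuts.
#' An audit table records each node's pass/fail on every criterion.
#'
#' @param records Topology table from [node_topology()].
#' @param cut `"median"` (default) or `"mean"`.
#' @return List of class `hub_selection`: `cuts` (named numeric of the
#'   three cut values), `hubs` (character vector of selected node ids,
#'   sorted), `audit` (per-node pass/fail table), `cut_statistic`.
#' @export
select_hubs <- function(records, cut = c("median", "mean")) {
  cut <- match.arg(cut)
  r <- as.data.table(records)
  if (nrow(r) == 0) stop_config("no topology records to screen")
  stat <- switch(cut, median = stats::median, mean = mean)
  cuts <- c(degree = stat(r$degree), betweenness = stat(r$betweenness),
            closeness = stat(r$closeness))
  audit <- r[, .(node_id,
                 degree, betweenness, closeness,
                 pass_degree = degree > cuts[["degree"]],
                 pass_betweenness = betweenness > cuts[["betweenness"]],
                 pass_closeness = closeness > cuts[["closeness"]])]
  audit[, hub := pass_degree & pass_betweenness & pass_closeness]
  structure(list(cuts = cuts, hubs = sort(audit[hub == TRUE, node_id]),
                 audit = audit[], cut_statistic = cut),
            class = "hub_selection")
}

#' @export
print.hub_selection <- function(x, ...) {
  cat(sprintf("hub_selection (%s cut): %d of %d nodes pass all three cuts\n",
              x$cut_statistic, length(x$hubs), nrow(x$audit)))
  cat(sprintf("cuts: degree > %g, betweenness > %g, closeness > %g\n",
              x$cuts[["degree"]], x$cuts[["betweenness"]],
              x$cuts[["closeness"]]))
  if (length(x$hubs)) cat("hubs:", paste(x$hubs, collapse = ", "), "\n")
  invisible(x)
}

utils::globalVariables(c("hub", "pass_degree", "pass_betweenness",
                         "pass_closeness"))
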