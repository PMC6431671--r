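#' Merge predicted hubs with experimental differential proteins
#'
#' The integration step's candidate set: the deduplicated union of major
#' predicted hubs and experimentally called differential proteins, with
#' dual provenance preserved (a node may be both). Differential-protein
#' accessions may be translated to the hubs' gene-symbol namespace via a
#' two-column mapping; unmappable accessions are kept under their own id
#' with a warning.
#'
#' @param hubs Character vector of hub node ids (gene symbols).
#' @param deps Character vector of differential-protein ids (accessions or
#'   symbols).
#' @param mapping Optional `data.frame` with columns `accession`, `symbol`.
#' @return `data.table` of class `candidate_set`: `node_id`, `from_hub`,
#'   `from_dep`, sorted by id.
#' @export
merge_candidates <- function(hubs, deps, mapping = NULL) {
  hubs <- unique(as.character(hubs))
  deps <- unique(as.character(deps))
  if (!is.null(mapping)) {
    mapping <- as.data.table(mapping)
    if (!all(c("accession", "symbol") %in% names(mapping)))
      stop_config("mapping must have columns accession, symbol")
    hit <- match(deps, mapping$accession)
    unmapped <- deps[is.na(hit) & !(deps %in% mapping$symbol)]
    if (length(unmapped))
      warning("unmappable accession(s) kept under their own id: ",
              paste(sort(unmapped), collapse = ", "))
    deps <- unique(ifelse(is.na(hit), deps, mapping$symbol[hit]))
  }
  merged <- sort(union(hubs, deps))
  out <- data.table(node_id = merged,
                    from_hub = merged %in% hubs,
                    from_dep = merged %in% deps)
  setattr(out, "class", c("candidate_set", class(out)))
  out[]
}

#' Induced interaction network on a candidate set
#'
#' Subsets a scored interaction edge table to edges whose both endpoints
#' are candidates, then applies the strict combined-score median filter
#' (computed on the induced edges). Candidates absent from the edge table
#' remain as isolated nodes. An edgeless induced graph skips the filter
#' (all centralities are then 0).
#'
#' @param candidates A [merge_candidates()] result or character vector.
#' @param edges Edge table with `node_a`, `node_b`, `combined_score`.
#' @param median_filter Apply the median score filter (default `TRUE`).
#' @return A `typed_network` whose node roles encode provenance
#'   (`hub`, `DEP`, `hub+DEP`, or `candidate` when unknown).
#' @export
induced_interaction_network <- function(candidates, edges,
                                        median_filter = TRUE) {
  if (is.character(candidates)) {
    nodes <- data.table(node_id = sort(unique(candidates)), role = "candidate")
  } else {
    cs <- as.data.table(candidates)
    nodes <- cs[, .(node_id,
                    role = ifelse(from_hub & from_dep, "hub+DEP",
                           ifelse(from_hub, "hub", "DEP")))]
  }
  e <- as.data.table(edges)
  sub <- e[node_a %in% nodes$node_id & node_b %in% nodes$node_id]
  isolated <- setdiff(nodes$node_id, unique(c(sub$node_a, sub$node_b)))
  if (length(isolated))
    message(sprintf("%d candidate(s) have no induced interactions", length(isolated)))
  if (median_filter && nrow(sub) > 0)
    sub <- filter_edges_by_median_score(sub)
  typed_network(nodes, sub)
}

#' Nominate key targets from an induced candidate network
#'
#' Applies the triple-median hub screen to the induced network: the
#' nodes whose degree, betweenness and closeness all strictly exceed the
#' network-wide medians are the key targets, ranked by degree, ties broken
#' by betweenness, closeness, then node id. The report carries the full
#' topology and audit tables; when no node clears all three cuts (e.g. a
#' topologically homogeneous network) the nomination is empty and a note
#' explains why.
#'
#' @param net A `typed_network` from [induced_interaction_network()]
#'   (at least 3 nodes).
#' @param cut Cut statistic for the screen, `"median"` (default) or `"mean"`.
#' @param db Optional [pathway_db()]; when given, an overrepresentation
#'   analysis of the full candidate set is included in the report.
#' @return Object of class `key_target_report`: `key_targets` (ranked
#'   `data.table` with provenance), `topology`, `selection`
#'   (the [select_hubs()] audit), `pathways` (or `NULL`), `note`.
#' @export
nominate_key_targets <- function(net, cut = c("median", "mean"), db = NULL) {
  cut <- match.arg(cut)
  if (!inherits(net, "typed_network")) stop_config("net must be a typed_network")
  if (nrow(net$nodes) < 3)
    stop_config("key-target nomination needs at least 3 candidate nodes")
  topo <- node_topology(net)
  sel <- select_hubs(topo, cut = cut)
  ranked <- topo[node_id %in% sel$hubs]
  setorder(ranked, -degree, -betweenness, -closeness, node_id)
  ranked <- merge(ranked, net$nodes, by = "node_id", sort = FALSE)
  note <- if (nrow(ranked) == 0)
    paste("no node strictly exceeds all three", cut,
          "cuts; the network is too topologically homogeneous to single out key targets")
  else NA_character_
  pathways <- if (!is.null(db)) enrich(net$nodes$node_id, db) else NULL
  structure(list(key_targets = ranked[], topology = topo, selection = sel,
                 pathways = pathways, note = note),
            class = "key_target_report")
}

#' @export
print.key_target_report <- function(x, ...) {
  if (nrow(x$key_targets) == 0) {
    cat("key_target_report: no key targets nominated\n")
    if (!is.na(x$note)) cat("note:", x$note, "\n")
  } else {
    cat(sprintf("key_target_report: %d key target(s)\n", nrow(x$key_targets)))
    print(x$key_targets)
  }
  invisible(x)
}

utils::globalVariables(c("from_hub", "from_dep", "role"))
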