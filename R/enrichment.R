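#' Pathway database container
#'
#' @param pathways Named list mapping pathway id to a character vector of
#'   gene ids (duplicates within a set are collapsed).
#' @param universe Background gene set; defaults to the union of all
#'   pathway genes (the only background recoverable from a gene-set file).
#'   Every pathway gene must belong to the universe.
#' @param descriptions Optional named character vector of pathway
#'   descriptions.
#' @return Object of class `pathway_db`.
#' @export
pathway_db <- function(pathways, universe = NULL, descriptions = NULL) {
  if (is.null(names(pathways)) || anyDuplicated(names(pathways)))
    stop_config("pathways must be a uniquely named list")
  pathways <- lapply(pathways, function(g) sort(unique(as.character(g))))
  if (is.null(universe)) universe <- sort(unique(unlist(pathways)))
  universe <- sort(unique(as.character(universe)))
  if (length(universe) == 0) stop_config("universe must be nonempty")
  stray <- setdiff(unlist(pathways), universe)
  if (length(stray))
    stop_config("pathway gene(s) outside the universe: ",
                paste(head(sort(stray), 5), collapse = ", "))
  structure(list(pathways = pathways, universe = universe,
                 descriptions = descriptions),
            class = "pathway_db")
}

#' @export
print.pathway_db <- function(x, ...) {
  cat(sprintf("pathway_db: %d pathways over a universe of %d genes\n",
              length(x$pathways), length(x$universe)))
  invisible(x)
}

#' Upper-tail hypergeometric probability for overrepresentation
#'
#' `P[X >= k]` where `X ~ Hypergeometric(N, K, n)`: the probability of
#' drawing at least `k` pathway members when `n` genes are drawn without
#' replacement from a universe of `N` genes containing `K` pathway
#' members. This is the classical overrepresentation p-value.
#'
#' @param k Observed overlap, `0 <= k <= min(n, K)`.
#' @param n Query size.
#' @param K Pathway size.
#' @param N Universe size.
#' @return The p-value.
#' @examples
#' hypergeom_upper_tail(5, 5, 5, 10)  # 1/choose(10, 5)
#' @export
hypergeom_upper_tail <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0) || n > N || K > N || k > min(n, K))
    stop_config("require 0 <= k <= min(n, K) and n, K <= N")
  ## P[X >= k] = 1 - P[X <= k-1]
  phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Overrepresentation analysis of a gene list against pathway sets
#'
#' For every pathway with at least one query gene, computes the overlap,
#' the upper-tail hypergeometric p-value, and the fold enrichment
#' `(k/n) / (K/N)` (observed over expected overlap rate). Query genes
#' outside the universe are dropped with a warning; the effective query
#' size `n` counts only in-universe genes. Results are sorted by p-value
#' ascending, ties by pathway id.
#'
#' @param query Character vector of gene ids.
#' @param db A [pathway_db()].
#' @param adjust If `TRUE`, append Benjamini--Hochberg adjusted p-values
#'   (column `p_adjusted`); off by default since raw overrepresentation
#'   p-values are the conventional report.
#' @return `data.table` with `pathway_id`, `k`, `n`, `K`, `N`, `p_value`,
#'   `fold_enrichment`, `overlap_genes` (comma-separated).
#' @export
enrich <- function(query, db, adjust = FALSE) {
  if (!inherits(db, "pathway_db")) stop_config("db must be a pathway_db")
  query <- unique(as.character(query))
  outside <- setdiff(query, db$universe)
  if (length(outside))
    warning(sprintf("%d query gene(s) outside the universe dropped", length(outside)))
  query <- intersect(query, db$universe)
  if (length(query) == 0)
    stop_config("query is empty after intersecting with the universe")
  n <- length(query)
  N <- length(db$universe)
  rows <- lapply(names(db$pathways), function(pid) {
    genes <- db$pathways[[pid]]
    ov <- intersect(query, genes)
    k <- length(ov)
    if (k == 0) return(NULL)
    K <- length(genes)
    data.table(pathway_id = pid, k = k, n = n, K = K, N = N,
               p_value = hypergeom_upper_tail(k, n, K, N),
               fold_enrichment = (k / n) / (K / N),
               overlap_genes = paste(sort(ov), collapse = ","))
  })
  out <- rbindlist(rows)
  if (nrow(out) == 0) return(out)
  setorder(out, p_value, pathway_id)
  if (adjust) out[, p_adjusted := stats::p.adjust(p_value, method = "BH")]
  out[]
}

utils::globalVariables(c("p_adjusted", "pathway_id"))
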