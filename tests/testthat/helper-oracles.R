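## Independent oracles used across the suite. These deliberately avoid the
## code paths of the package: centralities come from adjacency-matrix power
## counting (every walk of minimal length is a shortest path), and the
## hypergeometric tail comes from exhaustive enumeration of draws.

## Degree, pair-fraction betweenness and per-component closeness from an
## adjacency matrix, by brute force.
bf_centralities <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  S <- diag(n)                      # number of shortest paths
  Ak <- diag(n)
  for (k in seq_len(max(1, n - 1))) {
    Ak <- Ak %*% A
    newly <- (Ak > 0) & !is.finite(D)
    if (any(newly)) {
      D[newly] <- k
      S[newly] <- Ak[newly]
    }
  }
  btw <- numeric(n)
  for (v in seq_len(n)) {
    on_path <- outer(D[, v], D[v, ], "+") == D & is.finite(D)
    on_path[v, ] <- FALSE
    on_path[, v] <- FALSE
    diag(on_path) <- FALSE
    contrib <- ifelse(on_path, outer(S[, v], S[v, ]) / pmax(S, 1), 0)
    btw[v] <- sum(contrib) / 2      # each unordered pair counted twice
  }
  clo <- numeric(n)
  for (v in seq_len(n)) {
    d <- D[v, -v]
    d <- d[is.finite(d)]
    if (length(d)) clo[v] <- length(d) / sum(d)
  }
  list(degree = rowSums(A), betweenness = btw, closeness = clo)
}

## Adjacency matrix -> edge table with node ids v1..vn.
adj_to_edges <- function(A) {
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(node_a = character(), node_b = character(),
                      combined_score = numeric()))
  data.frame(node_a = paste0("v", idx[, 1]),
             node_b = paste0("v", idx[, 2]),
             combined_score = 1)
}

## Package centralities on an adjacency matrix, aligned to node order 1..n.
pkg_centralities <- function(A) {
  n <- nrow(A)
  ids <- paste0("v", seq_len(n))
  topo <- node_topology(adj_to_edges(A), nodes = ids)
  topo <- topo[match(ids, topo$node_id), ]
  list(degree = topo$degree, betweenness = topo$betweenness,
       closeness = topo$closeness)
}

## Exhaustive upper-tail hypergeometric: enumerate all size-n draws from a
## universe of N with the first K marked, count overlaps >= k.
enum_hypergeom_upper <- function(k, n, K, N) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  overlaps <- colSums(draws <= K)
  mean(overlaps >= k)
}

## Independent sort-median-compare hub filter.
oracle_hubs <- function(topo) {
  med <- function(x) stats::median(x)
  sort(topo$node_id[topo$degree > med(topo$degree) &
                      topo$betweenness > med(topo$betweenness) &
                      topo$closeness > med(topo$closeness)])
}

## Random adjacency matrix on n nodes with edge probability p.
random_adj <- function(n, p) {
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, p)
  A + t(A)
}

## Tanimoto by raw set arithmetic on bit positions.
oracle_tanimoto <- function(a, b) {
  on_a <- which(strsplit(a, "")[[1]] == "1")
  on_b <- which(strsplit(b, "")[[1]] == "1")
  u <- length(union(on_a, on_b))
  if (u == 0) 0 else length(intersect(on_a, on_b)) / u
}

## Path to the packaged published 13-protein differential summary.
dep_reference_path <- function() {
  system.file("extdata", "serum_dep_reference.tsv", package = "itraqnet")
}

## Load that fixture in call_deps()-ready form: the published table reports
## proteins that passed the patient-consensus screen, so consensus is set
## to 26/30 and the unused score is the table's protein score.
dep_reference_summary <- function() {
  tab <- read_table(dep_reference_path(), "protein_summary")
  tab$unused_score <- tab$protein_score
  tab$consensus_fraction <- 26 / 30
  tab
}
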