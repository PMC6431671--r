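#' Tanimoto similarity of two binary fingerprints
#'
#' `|on(a) & on(b)| / |on(a) | on(b)|`, the set-overlap coefficient on
#' \[0, 1\]: 1 means identical structures (identical on-bit sets), 0 means
#' no shared substructure bits. Two all-zero fingerprints have an empty
#' union; their similarity is defined as 0 with a warning.
#'
#' @param a,b Fingerprints: 0/1 numeric vectors, logical vectors, or
#'   bitstrings like `"010110"`. Lengths must match.
#' @return Similarity score in \[0, 1\].
#' @examples
#' tanimoto("0111", "0011")  # 2/3
#' @export
tanimoto <- function(a, b) {
  a <- as_fingerprint(a)
  b <- as_fingerprint(b)
  if (length(a) != length(b))
    stop_config("fingerprint lengths differ (", length(a), " vs ", length(b), ")")
  union_n <- sum(a | b)
  if (union_n == 0) {
    warning("both fingerprints are all-zero; Tanimoto defined as 0")
    return(0)
  }
  sum(a & b) / union_n
}

#' Coerce a fingerprint representation to a logical bit vector
#'
#' @param x A 0/1 numeric vector, logical vector, or single bitstring.
#' @return Logical vector of bits.
#' @export
as_fingerprint <- function(x) {
  if (is.character(x)) {
    if (length(x) != 1) stop_config("a bitstring fingerprint must be a single string")
    bits <- strsplit(x, "", fixed = TRUE)[[1]]
    if (!all(bits %in% c("0", "1")))
      stop_config("fingerprint string may contain only 0 and 1")
    return(bits == "1")
  }
  if (!all(x %in% c(0, 1)))
    stop_config("fingerprint vector may contain only 0 and 1")
  as.logical(x)
}

#' Screen a compound library against reference-drug fingerprints
#'
#' For each library compound, `best_tanimoto` is the maximum Tanimoto
#' similarity over all references, and the compound is kept iff that score
#' strictly exceeds the threshold (compounds at exactly the threshold are
#' treated as redundant and dropped).
#'
#' @param library Compound table with `compound_id` and `fingerprint`
#'   (bitstring) columns.
#' @param references Reference table with the same schema (ids may differ).
#' @param threshold Similarity cut, default 0.8.
#' @return `data.table` with `compound_id`, `best_tanimoto`, `kept`;
#'   attribute `n_kept` carries the kept count.
#' @export
screen_compounds <- function(library, references, threshold = 0.8) {
  library <- as.data.table(library)
  references <- as.data.table(references)
  if (nrow(references) == 0) stop_config("reference fingerprint set is empty")
  if (nrow(library) == 0) {
    message("compound library is empty; nothing to screen")
    out <- data.table(compound_id = character(), best_tanimoto = numeric(),
                      kept = logical())
    setattr(out, "n_kept", 0L)
    return(out)
  }
  refs <- lapply(references$fingerprint, as_fingerprint)
  best <- vapply(library$fingerprint, function(f) {
    fp <- as_fingerprint(f)
    max(vapply(refs, function(r) tanimoto(fp, r), numeric(1)))
  }, numeric(1), USE.NAMES = FALSE)
  out <- data.table(compound_id = library$compound_id,
                    best_tanimoto = best,
                    kept = best > threshold)
  setattr(out, "n_kept", sum(out$kept))
  out[]
}

#' Build the compound-to-putative-target edge table
#'
#' Restricts the compound--target mapping to screened-in compounds,
#' deduplicates edges, and reports per-compound target counts plus the
#' mean number of distinct targets per kept compound. A kept compound with
#' no targets contributes 0 to the numerator but still counts in the
#' denominator.
#'
#' @param kept Screening result ([screen_compounds()]) or a character
#'   vector of kept compound ids.
#' @param compound_targets Table with `compound_id`, `target_id`. Every
#'   `compound_id` must be a kept compound; dangling references are an
#'   error naming the offenders.
#' @return List with `edges` (deduplicated), `counts` (per compound) and
#'   `mean_targets_per_compound`.
#' @export
build_compound_target_edges <- function(kept, compound_targets) {
  ids <- if (is.character(kept)) kept else as.data.table(kept)[kept == TRUE, compound_id]
  ct <- as.data.table(compound_targets)
  dangling <- setdiff(ct$compound_id, ids)
  if (length(dangling))
    stop_config("compound-target table references non-kept compound(s): ",
                paste(sort(dangling), collapse = ", "))
  edges <- unique(ct[, .(compound_id, target_id)])
  counts <- edges[, .(n_targets = .N), by = compound_id]
  counts <- rbind(counts,
                  data.table(compound_id = setdiff(ids, counts$compound_id),
                             n_targets = 0L))
  setkey(counts, compound_id)
  list(edges = edges[],
       counts = counts[],
       mean_targets_per_compound =
         if (length(ids)) nrow(edges) / length(ids) else NaN)
}
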