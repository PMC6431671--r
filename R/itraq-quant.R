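#' Thresholds for differential-protein calling
#'
#' The defaults encode the standard serum-biomarker criteria for 4-plex
#' iTRAQ studies: relative expression above 1.2 or below 0.8 versus the
#' pooled control, Student t-test p below 0.05, at least two distinct
#' peptides, unused protein score above 2 (99\% identification confidence),
#' and a patient-consensus requirement that strictly more than 25 of 30
#' patients fall on the same side of 1.0 as the protein's mean ratio. All
#' comparisons are strict inequalities.
#'
#' @param up,down Fold-change cuts (must satisfy `down < 1 < up`).
#' @param alpha Significance level.
#' @param min_peptides Minimum distinct peptides.
#' @param min_unused_score Minimum unused protein score.
#' @param min_consensus Minimum consensus fraction (strictly exceeded).
#' @return An object of class `dep_thresholds`.
#' @export
dep_thresholds <- function(up = 1.2, down = 0.8, alpha = 0.05,
                           min_peptides = 2L, min_unused_score = 2.0,
                           min_consensus = 25 / 30) {
  if (!(down < 1 && up > 1)) stop_config("thresholds must satisfy down < 1 < up")
  if (alpha <= 0 || alpha >= 1) stop_config("alpha must lie in (0, 1)")
  structure(list(up = up, down = down, alpha = alpha,
                 min_peptides = as.integer(min_peptides),
                 min_unused_score = min_unused_score,
                 min_consensus = min_consensus),
            class = "dep_thresholds")
}

validate_purity_matrix <- function(M, tol = 1e-6) {
  if (!is.matrix(M) || any(dim(M) != 4))
    stop_config("purity matrix must be 4x4")
  cs <- colSums(M)
  if (any(abs(cs - 1) > tol))
    stop_config("purity matrix columns must each sum to 1 (each tag's signal fully distributed)")
  if (rcond(M) < 1e-12)
    stop_config("purity matrix is singular or ill-conditioned")
  invisible(M)
}

#' Read a 4x4 isotope purity matrix from a text file
#'
#' The file holds 16 whitespace-delimited numbers, row = observed channel,
#' column = true channel, columns summing to 1. Vendors certify these
#' isotope-carryover factors per reagent lot; with no certificate the
#' identity matrix (no correction) is the appropriate default.
#'
#' @param path Path to the matrix file.
#' @return A validated 4x4 numeric matrix.
#' @export
read_purity_matrix <- function(path) {
  v <- scan(path, what = numeric(), quiet = TRUE, comment.char = "#")
  if (length(v) != 16) stop_config("purity matrix file must contain 16 numbers")
  M <- matrix(v, nrow = 4, byrow = TRUE)
  validate_purity_matrix(M)
  M
}

#' Correct reporter areas for overlapping isotopic contributions
#'
#' Solves `M x = observed` per spectrum, where `M` maps true channel
#' intensities to observed ones. Corrected areas that come out negative
#' (possible when noise exceeds the overlap signal) are clipped to zero
#' with a warning.
#'
#' @param spectra Spectra table with columns `area_114`..`area_117`.
#' @param purity 4x4 purity matrix, or `NULL` for no correction.
#' @return The spectra table with corrected areas.
#' @export
correct_isotope_overlap <- function(spectra, purity = NULL) {
  spectra <- as.data.table(spectra)
  if (is.null(purity)) return(spectra[])
  validate_purity_matrix(purity)
  cols <- paste0("area_", 114:117)
  A <- as.matrix(spectra[, cols, with = FALSE])
  X <- t(solve(purity, t(A)))
  neg <- X < 0
  if (any(neg)) {
    warning(sprintf("clipped %d negative corrected areas to 0", sum(neg)))
    X[neg] <- 0
  }
  for (j in seq_along(cols)) set(spectra, j = cols[j], value = X[, j])
  spectra[]
}

#' Compute per-spectrum reporter ratios against the control channel
#'
#' Divides the peak areas observed at channels 115, 116 and 117 by the
#' area at channel 114 (the pooled healthy control). Spectra with a
#' non-positive 114 area cannot be ratioed and are excluded with a warning
#' rather than aborting the run.
#'
#' @param spectra Spectra table (schema of [gen_itraq_dataset()]).
#' @return `data.table` with `peptide_id`, `protein_acc`, `batch`,
#'   `ratio_115`, `ratio_116`, `ratio_117`, `protein_score`, `unused_score`.
#'   The number of excluded spectra is attached as attribute `n_excluded`.
#' @export
compute_peptide_ratios <- function(spectra) {
  spectra <- as.data.table(spectra)
  bad <- !(spectra$area_114 > 0)
  if (any(bad))
    warning(sprintf("excluded %d spectra with non-positive channel-114 area",
                    sum(bad)))
  s <- spectra[!bad]
  if (nrow(s) == 0) stop_config("no usable spectra (all channel-114 areas non-positive)")
  out <- s[, .(peptide_id, protein_acc, batch,
               ratio_115 = area_115 / area_114,
               ratio_116 = area_116 / area_114,
               ratio_117 = area_117 / area_114,
               protein_score, unused_score)]
  setattr(out, "n_excluded", sum(bad))
  out[]
}

#' Roll peptide ratios up to per-protein, per-batch average ratios
#'
#' For each protein in each batch, the three channel ratios are the
#' arithmetic means of the peptide ratios originating from that protein.
#' The distinct-peptide count and the protein/unused scores (maxima over
#' the protein's spectra) are carried along as identification metadata.
#' Input row order never affects the result: rows are keyed before
#' aggregation.
#'
#' @param ratios Output of [compute_peptide_ratios()].
#' @return Per (protein, batch) table with `ratio_115`..`ratio_117`,
#'   `n_peptides`, `protein_score`, `unused_score`.
#' @export
rollup_proteins <- function(ratios) {
  r <- as.data.table(ratios)
  setkey(r, protein_acc, batch, peptide_id)
  meta <- r[, .(n_peptides = uniqueN(peptide_id),
                protein_score = max(protein_score),
                unused_score = max(unused_score)), by = protein_acc]
  q <- r[, .(ratio_115 = mean(ratio_115),
             ratio_116 = mean(ratio_116),
             ratio_117 = mean(ratio_117)), by = .(protein_acc, batch)]
  out <- meta[q, on = "protein_acc"]
  setcolorder(out, c("protein_acc", "batch", "ratio_115", "ratio_116",
                     "ratio_117", "n_peptides", "protein_score", "unused_score"))
  setkey(out, protein_acc, batch)
  out[]
}

#' Normalize protein ratios by the overall per-channel ratio of each batch
#'
#' Corrects for small differences in protein loading between channels:
#' within each batch, every channel's ratios are divided by that channel's
#' overall ratio across all proteins in the batch. The aggregate defining
#' "overall" is the median by default (robust to the differentially
#' expressed tail); the mean is available. After normalization the
#' per-channel aggregate equals 1, and normalizing twice is a no-op.
#'
#' @param quant Output of [rollup_proteins()].
#' @param aggregate `"median"` (default) or `"mean"`.
#' @return The normalized quant table.
#' @export
normalize_ratios <- function(quant, aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  q <- as.data.table(quant)
  if (nrow(q) == 0) stop_config("cannot normalize an empty batch")
  agg <- switch(aggregate, median = stats::median, mean = mean)
  cols <- paste0("ratio_", 115:117)
  q[, (cols) := lapply(.SD, function(x) x / agg(x)), by = batch, .SDcols = cols]
  q[]
}

#' Reshape per-batch protein ratios to one row per protein and patient
#'
#' Patients are identified by (batch, channel): channel 115--117 of batch b
#' is patient `b<batch>_ch<channel>`.
#'
#' @param quant Normalized quant table.
#' @return Long `data.table` with `protein_acc`, `patient_id`, `batch`,
#'   `channel`, `ratio` plus metadata columns.
#' @export
quant_to_patients <- function(quant) {
  q <- as.data.table(quant)
  long <- melt(q, measure.vars = paste0("ratio_", 115:117),
               variable.name = "channel", value.name = "ratio")
  long[, channel := as.integer(sub("ratio_", "", channel))]
  long[, patient_id := sprintf("b%02d_ch%d", batch, channel)]
  setkey(long, protein_acc, patient_id)
  long[]
}

#' One-sample differential test on log2 ratios
#'
#' Two-sided one-sample Student t-test of the log2 patient ratios against
#' 0. Because the control is the ratio denominator (every control value is
#' identically 1 after normalization), a two-sample test would be
#' degenerate; the one-sample form on log ratios is the matching analysis
#' for a 3-patients-per-control batch design. With fewer than two ratios
#' or zero variance the protein is not testable and `NA` is returned.
#'
#' @param ratios Positive patient ratios for one protein.
#' @return p-value in \[0, 1\], or `NA_real_` if not testable.
#' @export
test_differential <- function(ratios) {
  l <- log2(ratios)
  l <- l[is.finite(l)]
  if (length(l) < 2 || sd(l) == 0) return(NA_real_)
  stats::t.test(l, mu = 0)$p.value
}

#' Summarize patient-level ratios into per-protein statistics
#'
#' Computes, per protein: the mean patient ratio, the one-sample t-test
#' p-value on log2 ratios ([test_differential()]), and the consensus
#' fraction -- the fraction of patients whose individual ratio lies on the
#' same side of 1.0 as the protein's mean ratio (a mean ratio of exactly
#' 1 has no side and gets consensus 0).
#'
#' @param patients Output of [quant_to_patients()].
#' @return Per-protein `data.table` with `mean_ratio`, `p_value`,
#'   `consensus_fraction`, `n_patients`, `n_peptides`, `protein_score`,
#'   `unused_score`, keyed by `protein_acc`.
#' @export
summarize_proteins <- function(patients) {
  p <- as.data.table(patients)
  setkey(p, protein_acc, patient_id)
  consensus <- function(r) {
    m <- mean(r)
    if (m > 1) mean(r > 1) else if (m < 1) mean(r < 1) else 0
  }
  out <- p[, .(mean_ratio = mean(ratio),
               p_value = test_differential(ratio),
               consensus_fraction = consensus(ratio),
               n_patients = .N,
               n_peptides = n_peptides[1],
               protein_score = protein_score[1],
               unused_score = unused_score[1]), by = protein_acc]
  setkey(out, protein_acc)
  out[]
}

#' Call differentially expressed proteins
#'
#' A protein is called differentially expressed iff all of the following
#' hold with strict comparisons: mean ratio above the up cut or below the
#' down cut; p-value below alpha; at least `min_peptides` distinct
#' peptides; unused score above `min_unused_score`; and consensus fraction
#' above `min_consensus`. Proteins whose test was degenerate (`NA`
#' p-value) are never called. Output is sorted by `|log2(mean_ratio)|`
#' descending, ties by accession.
#'
#' @param summary Per-protein summary with columns `protein_acc`,
#'   `mean_ratio`, `p_value`, `n_peptides`, `unused_score`,
#'   `consensus_fraction` (e.g. from [summarize_proteins()]).
#' @param thresholds A [dep_thresholds()].
#' @return `data.table` of calls: `protein_acc`, `mean_ratio`, `p_value`,
#'   `direction` (up/down), `n_peptides`, `consensus_fraction`.
#' @export
call_deps <- function(summary, thresholds = dep_thresholds()) {
  if (!inherits(thresholds, "dep_thresholds"))
    stop_config("thresholds must come from dep_thresholds()")
  s <- as.data.table(summary)
  need <- c("protein_acc", "mean_ratio", "p_value", "n_peptides",
            "unused_score", "consensus_fraction")
  miss <- setdiff(need, names(s))
  if (length(miss))
    stop_config("summary table lacks column(s): ", paste(miss, collapse = ", "))
  th <- thresholds
  s <- s[!is.na(p_value)]
  called <- s[(mean_ratio > th$up | mean_ratio < th$down) &
                p_value < th$alpha &
                n_peptides >= th$min_peptides &
                unused_score > th$min_unused_score &
                consensus_fraction > th$min_consensus]
  called[, direction := ifelse(mean_ratio > 1, "up", "down")]
  called[, abs_log2 := abs(log2(mean_ratio))]
  setorder(called, -abs_log2, protein_acc)
  called[, .(protein_acc, mean_ratio, p_value, direction, n_peptides,
             consensus_fraction)]
}

#' Run the full iTRAQ quantification chain on a spectra table
#'
#' Fixed stage order: isotope correction, per-spectrum ratios,
#' peptide-to-protein rollup, per-batch normalization, patient reshaping,
#' per-protein summary.
#'
#' @param spectra Spectra table (schema of [gen_itraq_dataset()]).
#' @param purity Optional 4x4 purity matrix (`NULL` = identity/no correction).
#' @param aggregate Normalization aggregate, see [normalize_ratios()].
#' @return List with `quant` (per protein x batch), `patients` (long) and
#'   `summary` (per protein), class `itraq_quant`.
#' @export
quantify_spectra <- function(spectra, purity = NULL,
                             aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  corrected <- correct_isotope_overlap(spectra, purity)
  ratios <- compute_peptide_ratios(corrected)
  quant <- normalize_ratios(rollup_proteins(ratios), aggregate)
  patients <- quant_to_patients(quant)
  structure(list(quant = quant, patients = patients,
                 summary = summarize_proteins(patients)),
            class = "itraq_quant")
}
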