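#' Configuration for the synthetic iTRAQ experiment generator
#'
#' Describes a 4-plex iTRAQ study design: patients' sera carry reporter
#' channels 115--117 and a pooled healthy control carries channel 114, so
#' each labelling batch contributes three patients and one control, and the
#' default 10 batches give the 30-patient design typical of serum biomarker
#' discovery studies.
#'
#' @param n_proteins Number of simulated proteins.
#' @param frac_up,frac_down Fractions of proteins planted as up-/down-regulated.
#'   The number planted is `round(frac * n_proteins)`; up-regulated proteins
#'   are planted first, and the down count is truncated so up + down never
#'   exceeds `n_proteins` (this rounding rule makes planted counts exact, not
#'   merely expected).
#' @param up_fold,down_fold True NPC/control abundance ratios planted for
#'   up-/down-regulated proteins. Must satisfy `up_fold > 1 > down_fold > 0`.
#' @param peptides_per_protein Length-2 integer vector `(min, max)`; each
#'   protein receives a uniform random number of distinct peptides in this
#'   range.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise applied independently to each reporter channel of each spectrum.
#' @param n_batches Number of iTRAQ labelling batches (default 10).
#' @param patients_per_batch Patients per batch, one per channel 115--117
#'   (default 3, fixed by the 4-plex chemistry).
#' @param batch_effect_cv Coefficient of variation of an optional per-batch,
#'   per-channel loading scalar (default 0 = off). Turning it on perturbs
#'   channel loadings so that the per-batch normalization step has real work
#'   to do.
#' @param seed Integer seed; identical configurations produce identical tables.
#' @return An object of class `itraq_sim_config`.
#' @seealso [gen_itraq_dataset()]
#' @export
itraq_sim_config <- function(n_proteins = 500L, frac_up = 0.1, frac_down = 0.1,
                             up_fold = 2.0, down_fold = 0.5,
                             peptides_per_protein = c(2L, 6L),
                             noise_cv = 0.2, n_batches = 10L,
                             patients_per_batch = 3L,
                             batch_effect_cv = 0, seed = 1L) {
  if (!is.numeric(n_proteins) || n_proteins < 1)
    stop_config("n_proteins must be a positive count")
  if (frac_up < 0 || frac_up > 1 || frac_down < 0 || frac_down > 1)
    stop_config("frac_up and frac_down must lie in [0, 1]")
  if (frac_up + frac_down > 1)
    stop_config("frac_up + frac_down must not exceed 1")
  if (!(up_fold > 1 && down_fold < 1 && down_fold > 0))
    stop_config("fold changes must satisfy up_fold > 1 > down_fold > 0")
  if (length(peptides_per_protein) != 2 ||
      any(peptides_per_protein < 1) ||
      peptides_per_protein[1] > peptides_per_protein[2])
    stop_config("peptides_per_protein must be (min, max) with 1 <= min <= max")
  if (noise_cv < 0 || batch_effect_cv < 0)
    stop_config("coefficients of variation must be non-negative")
  if (n_batches < 1 || patients_per_batch < 1 || patients_per_batch > 3)
    stop_config("need n_batches >= 1 and 1 <= patients_per_batch <= 3 (channels 115-117)")
  structure(list(
    n_proteins = as.integer(n_proteins), frac_up = frac_up,
    frac_down = frac_down, up_fold = up_fold, down_fold = down_fold,
    peptides_per_protein = as.integer(peptides_per_protein),
    noise_cv = noise_cv, n_batches = as.integer(n_batches),
    patients_per_batch = as.integer(patients_per_batch),
    batch_effect_cv = batch_effect_cv, seed = as.integer(seed)
  ), class = "itraq_sim_config")
}

## sdlog of a lognormal with unit median and coefficient of variation cv
lnorm_sdlog <- function(cv) sqrt(log(1 + cv^2))

#' Generate a synthetic iTRAQ reporter-ion dataset with planted effects
#'
#' Simulates peptide-spectrum rows for a 4-plex iTRAQ study. Channel 114
#' (pooled control) areas are drawn around a per-protein baseline with
#' per-peptide ionization efficiencies; channels 115--117 (patients) are the
#' 114 area scaled by the protein's true fold change times independent
#' multiplicative lognormal noise at the configured CV. The returned truth
#' table records each protein's planted direction and fold change.
#'
#' @param cfg An [itraq_sim_config()].
#' @return A list with `spectra` (one row per peptide x batch, columns
#'   `peptide_id`, `protein_acc`, `batch`, `area_114`..`area_117`,
#'   `protein_score`, `unused_score`) and `truth` (`protein_acc`,
#'   `direction` in up/down/null, `true_fold`), both `data.table`s.
#' @examples
#' sim <- gen_itraq_dataset(itraq_sim_config(n_proteins = 20, seed = 7))
#' table(sim$truth$direction)
#' @export
gen_itraq_dataset <- function(cfg) {
  if (!inherits(cfg, "itraq_sim_config"))
    stop_config("cfg must be an itraq_sim_config")
  with_seed(cfg$seed, {
    n <- cfg$n_proteins
    n_up <- as.integer(round(cfg$frac_up * n))
    n_down <- min(as.integer(round(cfg$frac_down * n)), n - n_up)
    direction <- rep("null", n)
    if (n_up > 0) direction[seq_len(n_up)] <- "up"
    if (n_down > 0) direction[n_up + seq_len(n_down)] <- "down"
    true_fold <- c(up = cfg$up_fold, down = cfg$down_fold, null = 1.0)[direction]
    acc <- sprintf("SIMP%04d", seq_len(n))
    truth <- data.table(protein_acc = acc, direction = direction,
                        true_fold = unname(true_fold))

    baseline <- rlnorm(n, meanlog = log(5000), sdlog = 0.8)
    npep <- sample(seq(cfg$peptides_per_protein[1], cfg$peptides_per_protein[2]),
                   n, replace = TRUE)
    protein_score <- round(runif(n, 4, 60), 2)
    unused_score <- round(runif(n, 2.5, 30), 2)

    pep <- data.table(
      protein_acc = rep(acc, npep),
      pep_idx = sequence(npep),
      pep_eff = rlnorm(sum(npep), 0, 0.5)
    )
    pep[, peptide_id := sprintf("%s_pep%02d", protein_acc, pep_idx)]

    spectra <- pep[rep(seq_len(.N), each = cfg$n_batches)]
    spectra[, batch := rep(seq_len(cfg$n_batches), times = nrow(pep))]

    idx <- match(spectra$protein_acc, acc)
    sdlog <- lnorm_sdlog(cfg$noise_cv)
    m <- nrow(spectra)
    base114 <- baseline[idx] * spectra$pep_eff * rlnorm(m, 0, sdlog)
    fold <- unname(true_fold)[idx]

    channels <- cfg$patients_per_batch   # channels 115 .. 114+patients_per_batch
    be <- matrix(1, nrow = cfg$n_batches, ncol = 3)
    if (cfg$batch_effect_cv > 0)
      be[] <- rlnorm(length(be), 0, lnorm_sdlog(cfg$batch_effect_cv))
    area <- matrix(0, nrow = m, ncol = 3)
    for (j in seq_len(channels))
      area[, j] <- base114 * fold * rlnorm(m, 0, sdlog) * be[spectra$batch, j]

    out <- data.table(
      peptide_id = spectra$peptide_id,
      protein_acc = spectra$protein_acc,
      batch = spectra$batch,
      area_114 = base114,
      area_115 = area[, 1],
      area_116 = if (channels >= 2) area[, 2] else 0,
      area_117 = if (channels >= 3) area[, 3] else 0,
      protein_score = protein_score[idx],
      unused_score = unused_score[idx]
    )
    setkey(out, protein_acc, peptide_id, batch)
    list(spectra = out[], truth = truth[])
  })
}

#' Generate a compound library with planted Tanimoto-similar members
#'
#' Builds binary fingerprints for a compound library together with a small
#' set of reference-drug fingerprints. Exactly `n_similar` compounds are
#' constructed to exceed Tanimoto 0.8 against some reference (by copying a
#' reference and toggling at most `floor(0.2 m) - 1` bits, where `m` is the
#' reference's on-bit count, which bounds the similarity strictly above
#' 0.8); the remaining compounds are drawn at random and re-drawn until
#' their best similarity falls below 0.8.
#'
#' @param n_compounds Library size.
#' @param fp_length Fingerprint length in bits (>= 8).
#' @param n_similar Number of compounds planted above the 0.8 threshold.
#' @param n_references Number of reference-drug fingerprints.
#' @param seed Integer seed.
#' @return List with `compounds` (`compound_id`, `fingerprint` bitstring,
#'   `tanimoto_truth` logical) and `references` (`compound_id`, `fingerprint`).
#' @export
gen_compound_library <- function(n_compounds, fp_length = 128L, n_similar,
                                 n_references = 3L, seed = 1L) {
  if (fp_length < 8) stop_config("fp_length must be at least 8 bits")
  if (n_similar > n_compounds) stop_config("n_similar must not exceed n_compounds")
  if (n_references < 1) stop_config("need at least one reference fingerprint")
  with_seed(seed, {
    draw_ref <- function() {
      repeat {
        f <- rbinom(fp_length, 1L, 0.5)
        if (sum(f) >= max(5, fp_length %/% 4)) return(f)
      }
    }
    refs <- replicate(n_references, draw_ref(), simplify = FALSE)

    make_similar <- function() {
      r <- refs[[sample.int(n_references, 1L)]]
      m <- sum(r)
      fmax <- max(0L, as.integer(ceiling(0.2 * m)) - 1L)
      nf <- if (fmax > 0) sample.int(fmax + 1L, 1L) - 1L else 0L
      if (nf > 0) {
        pos <- sample.int(fp_length, nf)
        r[pos] <- 1L - r[pos]
      }
      r
    }
    make_dissimilar <- function() {
      for (try in seq_len(200)) {
        f <- rbinom(fp_length, 1L, 0.3)
        best <- max(vapply(refs, function(r) tanimoto(f, r), numeric(1)))
        if (best < 0.8) return(f)
      }
      stop_config("fp_length too small to guarantee separation below Tanimoto 0.8")
    }

    is_similar <- rep(FALSE, n_compounds)
    if (n_similar > 0) is_similar[sample.int(n_compounds, n_similar)] <- TRUE
    fps <- lapply(is_similar, function(s) if (s) make_similar() else make_dissimilar())

    compounds <- data.table(
      compound_id = sprintf("CMP%03d", seq_len(n_compounds)),
      fingerprint = vapply(fps, paste, character(1), collapse = ""),
      tanimoto_truth = is_similar
    )
    references <- data.table(
      compound_id = sprintf("REF%02d", seq_len(n_references)),
      fingerprint = vapply(refs, paste, character(1), collapse = "")
    )
    list(compounds = compounds, references = references)
  })
}

#' Configuration for the synthetic network and pathway generator
#'
#' @param n_targets Number of putative compound targets.
#' @param n_disease_targets Number of known disease therapeutic targets.
#' @param n_compounds Number of compounds feeding the compound--target table.
#' @param n_overlap Targets shared between the putative and disease sets;
#'   must not exceed either set size.
#' @param edge_model `"preferential-attachment"` (Barabasi--Albert, scale-free
#'   degree tail, the default because protein interaction networks are
#'   heavy-tailed) or `"configuration"` (random multigraph on a heavy-tailed
#'   degree sequence, simplified).
#' @param score_beta_params Length-2 positive vector; interaction combined
#'   scores are i.i.d. Beta(a, b) on \[0, 1\].
#' @param edges_per_node Attachment parameter of the preferential-attachment
#'   model (also sets the density of the configuration model).
#' @param n_pathways Number of background pathway gene sets.
#' @param planted_pathway_size Size of the one pathway planted among
#'   high-degree nodes (id `"PWY_PLANTED"`).
#' @param pathway_size_range Size range of background pathways.
#' @param seed Integer seed.
#' @return An object of class `network_sim_config`.
#' @export
network_sim_config <- function(n_targets = 240L, n_disease_targets = 134L,
                               n_compounds = 20L, n_overlap = 30L,
                               edge_model = c("preferential-attachment",
                                              "configuration"),
                               score_beta_params = c(2, 2),
                               edges_per_node = 3L,
                               n_pathways = 20L, planted_pathway_size = 15L,
                               pathway_size_range = c(10L, 40L),
                               seed = 1L) {
  edge_model <- match.arg(edge_model)
  if (n_overlap > min(n_targets, n_disease_targets))
    stop_config("n_overlap must not exceed min(n_targets, n_disease_targets)")
  if (any(score_beta_params <= 0) || length(score_beta_params) != 2)
    stop_config("score_beta_params must be two positive shape parameters")
  structure(list(
    n_targets = as.integer(n_targets),
    n_disease_targets = as.integer(n_disease_targets),
    n_compounds = as.integer(n_compounds), n_overlap = as.integer(n_overlap),
    edge_model = edge_model, score_beta_params = score_beta_params,
    edges_per_node = as.integer(edges_per_node),
    n_pathways = as.integer(n_pathways),
    planted_pathway_size = as.integer(planted_pathway_size),
    pathway_size_range = as.integer(pathway_size_range),
    seed = as.integer(seed)
  ), class = "network_sim_config")
}

#' Generate a synthetic interaction network, pathway sets and target lists
#'
#' Produces every network-side input of the pipeline: a scored
#' protein--protein interaction edge table on the union of putative and
#' disease targets (scale-free-like topology, Beta-distributed combined
#' scores), a pathway collection with one set planted among high-degree
#' nodes, a compound-to-target table, and the disease therapeutic-target
#' list.
#'
#' @param cfg A [network_sim_config()].
#' @return List with `nodes` (`node_id`, `role`), `edges`
#'   (`node_a`, `node_b`, `combined_score`), `pathways` (named list of gene
#'   vectors), `planted_pathway` (its id), `compound_targets`
#'   (`compound_id`, `target_id`) and `disease_targets` (`target_id`).
#' @export
gen_ppi_and_pathways <- function(cfg) {
  if (!inherits(cfg, "network_sim_config"))
    stop_config("cfg must be a network_sim_config")
  with_seed(cfg$seed, {
    shared <- sprintf("SHR%03d", seq_len(cfg$n_overlap))
    tgt_only <- sprintf("TGT%03d", seq_len(cfg$n_targets - cfg$n_overlap))
    dis_only <- sprintf("DIS%03d", seq_len(cfg$n_disease_targets - cfg$n_overlap))
    putative <- c(shared, tgt_only)
    disease <- c(shared, dis_only)
    all_nodes <- c(shared, tgt_only, dis_only)
    n <- length(all_nodes)

    g <- switch(cfg$edge_model,
      "preferential-attachment" = igraph::sample_pa(
        n, m = cfg$edges_per_node, directed = FALSE),
      "configuration" = {
        deg <- pmin(n - 1L, 1L + stats::rpois(n, 1) +
                      as.integer(round(stats::rexp(n, 1 / cfg$edges_per_node))))
        if (sum(deg) %% 2 == 1) deg[1] <- deg[1] + 1L
        igraph::simplify(igraph::sample_degseq(deg, method = "configuration"))
      })
    ## shuffle labels so structural hubs are spread across roles
    lab <- sample(all_nodes)
    el <- igraph::as_edgelist(g, names = FALSE)
    edges <- data.table(
      node_a = lab[el[, 1]], node_b = lab[el[, 2]],
      combined_score = rbeta(nrow(el), cfg$score_beta_params[1],
                             cfg$score_beta_params[2])
    )
    edges <- edges[node_a != node_b]
    edges <- unique(edges, by = c("node_a", "node_b"))

    deg <- igraph::degree(g)
    names(deg) <- lab
    top <- names(sort(deg, decreasing = TRUE))[seq_len(max(
      cfg$planted_pathway_size, ceiling(0.2 * n)))]
    planted <- sample(top, min(cfg$planted_pathway_size, length(top)))
    pathways <- list(PWY_PLANTED = sort(planted))
    for (i in seq_len(cfg$n_pathways)) {
      sz <- sample(seq(cfg$pathway_size_range[1], cfg$pathway_size_range[2]), 1)
      pathways[[sprintf("PWY%03d", i)]] <- sort(sample(all_nodes, min(sz, n)))
    }

    compound_targets <- data.table(
      compound_id = rep(sprintf("CMP%03d", seq_len(cfg$n_compounds)),
                        times = {k <- sample(1:5, cfg$n_compounds, replace = TRUE); k})
    )
    compound_targets[, target_id := sample(putative, .N, replace = TRUE)]
    compound_targets <- unique(compound_targets)

    nodes <- data.table(node_id = all_nodes,
                        role = ifelse(all_nodes %in% shared, "disease_target",
                               ifelse(all_nodes %in% dis_only, "disease_target",
                                      "putative_target")))
    list(nodes = nodes, edges = edges[], pathways = pathways,
         planted_pathway = "PWY_PLANTED",
         compound_targets = compound_targets[],
         disease_targets = data.table(target_id = disease))
  })
}

#' Generate an integration scenario with planted key targets
#'
#' Builds a study-shaped integration input: 12 major predicted hubs and 13
#' experimental differential proteins whose intersection contains three
#' planted key targets (`KT1`--`KT3`). The interaction edge table is
#' constructed so that after the combined-score median filter only the
#' edges incident to the key targets (plus the key-target triangle) remain:
#' every core edge scores in (0.78, 0.98) and exactly as many filler edges
#' among non-key nodes score in (0.05, 0.65), so the score median separates
#' the two groups. On the filtered graph the key targets strictly dominate
#' all three centrality medians and the triple-median screen nominates
#' exactly them.
#'
#' @param seed Integer seed.
#' @return List with `hubs` and `deps` (character id vectors), `edges`
#'   (scored edge table) and `key_truth` (the three planted ids).
#' @export
gen_key_target_scenario <- function(seed = 1L) {
  with_seed(seed, {
    keys <- c("KT1", "KT2", "KT3")
    hubs <- c(sprintf("HUB%02d", 1:9), keys)
    deps <- c(sprintf("DEP%02d", 1:10), keys)
    others <- setdiff(union(hubs, deps), keys)

    core <- rbind(
      data.table(node_a = rep(keys, each = length(others)),
                 node_b = rep(others, times = length(keys))),
      data.table(node_a = c("KT1", "KT1", "KT2"),
                 node_b = c("KT2", "KT3", "KT3"))
    )
    core[, combined_score := runif(.N, 0.78, 0.98)]

    pairs <- t(combn(others, 2))
    pick <- sample.int(nrow(pairs), nrow(core))
    filler <- data.table(node_a = pairs[pick, 1], node_b = pairs[pick, 2],
                         combined_score = runif(nrow(core), 0.05, 0.65))
    edges <- rbind(core, filler)
    edges <- edges[sample.int(nrow(edges))]
    list(hubs = hubs, deps = deps, edges = edges[], key_truth = keys)
  })
}
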