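make_spectra <- function(areas, peptide_id = "pep1", protein_acc = "P1",
                         batch = 1L, protein_score = 10, unused_score = 5) {
  data.frame(peptide_id = peptide_id, protein_acc = protein_acc, batch = batch,
             area_114 = areas[1], area_115 = areas[2], area_116 = areas[3],
             area_117 = areas[4], protein_score = protein_score,
             unused_score = unused_score)
}

test_that("per-spectrum ratios divide patient channels by the control channel", {
  r <- compute_peptide_ratios(make_spectra(c(50, 100, 50, 25)))
  expect_equal(unlist(r[, .(ratio_115, ratio_116, ratio_117)]),
               c(ratio_115 = 2, ratio_116 = 1, ratio_117 = 0.5))
  r <- compute_peptide_ratios(make_spectra(c(7, 7, 7, 7)))
  expect_equal(unname(unlist(r[, .(ratio_115, ratio_116, ratio_117)])),
               c(1, 1, 1))
  ## zero control area: excluded with a warning, never an abort
  two <- rbind(make_spectra(c(0, 1, 1, 1)), make_spectra(c(10, 20, 10, 5),
                                                         peptide_id = "pep2"))
  expect_warning(r <- compute_peptide_ratios(two), "non-positive")
  expect_equal(nrow(r), 1)
  expect_equal(attr(r, "n_excluded"), 1L)
})

test_that("isotope-overlap correction inverts a known purity matrix", {
  areas <- c(100, 80, 60, 40)
  expect_equal(
    as.numeric(correct_isotope_overlap(make_spectra(areas), diag(4))[
      , .(area_114, area_115, area_116, area_117)]),
    areas)
  ## 10% of tag 115's signal leaks into channel 114
  M <- diag(4)
  M[1, 2] <- 0.1
  M[2, 2] <- 0.9
  true <- c(100, 80, 60, 40)
  observed <- as.numeric(M %*% true)
  got <- correct_isotope_overlap(make_spectra(observed), M)
  expect_equal(as.numeric(got[, .(area_114, area_115, area_116, area_117)]),
               true, tolerance = 1e-12)
  ## invalid matrices rejected at load time
  bad <- diag(4) * 0.9
  expect_error(correct_isotope_overlap(make_spectra(areas), bad), "sum to 1")
  tmp <- tempfile()
  writeLines(paste(rep("0.25", 16), collapse = " "), tmp)
  expect_error(read_purity_matrix(tmp), "singular|ill-conditioned")
})

test_that("protein rollup is the arithmetic mean of peptide ratios", {
  s <- rbind(make_spectra(c(10, 20, 20, 20), peptide_id = "a"),
             make_spectra(c(10, 40, 40, 40), peptide_id = "b"))
  q <- rollup_proteins(compute_peptide_ratios(s))
  expect_equal(as.numeric(q[, .(ratio_115, ratio_116, ratio_117)]), c(3, 3, 3))
  expect_equal(q$n_peptides, 1L + 1L)
  ## three peptides vs a spreadsheet-style recomputation
  s3 <- rbind(make_spectra(c(10, 15, 30, 5), peptide_id = "a"),
              make_spectra(c(20, 25, 10, 30), peptide_id = "b"),
              make_spectra(c(5, 10, 5, 20), peptide_id = "c"))
  q3 <- rollup_proteins(compute_peptide_ratios(s3))
  expect_equal(q3$ratio_115, mean(c(15 / 10, 25 / 20, 10 / 5)))
  expect_equal(q3$ratio_116, mean(c(30 / 10, 10 / 20, 5 / 5)))
  expect_equal(q3$ratio_117, mean(c(5 / 10, 30 / 20, 20 / 5)))
})

test_that("normalization divides by the per-batch channel aggregate and is idempotent", {
  q <- data.frame(protein_acc = c("P1", "P2", "P3"), batch = 1L,
                  ratio_115 = c(1, 2, 4), ratio_116 = c(2, 2, 2),
                  ratio_117 = c(0.5, 1, 8), n_peptides = 2L,
                  protein_score = 10, unused_score = 5)
  n1 <- normalize_ratios(q)
  expect_equal(n1$ratio_115, c(0.5, 1, 2))   # median 2
  expect_equal(median(n1$ratio_116), 1)
  expect_equal(median(n1$ratio_117), 1)
  n2 <- normalize_ratios(n1)
  expect_equal(as.matrix(n2[, .(ratio_115, ratio_116, ratio_117)]),
               as.matrix(n1[, .(ratio_115, ratio_116, ratio_117)]),
               tolerance = 1e-12)
  expect_error(normalize_ratios(q[0, ]), "empty")
})

test_that("the differential test matches the closed-form t oracle", {
  r <- c(2.0, 2.1, 1.9, 2.05)
  l <- log2(r)
  tstat <- mean(l) / (sd(l) / sqrt(length(l)))
  p_oracle <- 2 * pt(-abs(tstat), df = length(l) - 1)
  expect_equal(test_differential(r), p_oracle, tolerance = 1e-10)
  ## doubling every ratio shifts the mean log2 by +1
  r2 <- 2 * r
  l2 <- log2(r2)
  expect_equal(mean(l2), mean(l) + 1, tolerance = 1e-12)
  t2 <- mean(l2) / (sd(l2) / sqrt(length(l2)))
  expect_equal(test_differential(r2), 2 * pt(-abs(t2), df = 3), tolerance = 1e-10)
  ## degenerate inputs are not testable
  expect_true(is.na(test_differential(c(1, 1, 1))))
  expect_true(is.na(test_differential(2)))
})

test_that("DEP calling enforces every filter with strict comparisons", {
  base <- data.frame(protein_acc = "P1", mean_ratio = 2, p_value = 0.01,
                     n_peptides = 3L, unused_score = 5,
                     consensus_fraction = 28 / 30)
  expect_equal(nrow(call_deps(base)), 1)
  expect_equal(call_deps(base)$direction, "up")
  cases <- list(
    list(mean_ratio = 1.0),          # dead zone
    list(mean_ratio = 1.2),          # boundary: strictly greater required
    list(mean_ratio = 0.8),          # boundary on the down side
    list(p_value = 0.05),            # alpha boundary
    list(p_value = NA_real_),        # untestable
    list(n_peptides = 1L),           # too few peptides
    list(unused_score = 2.0),        # unused score boundary
    list(consensus_fraction = 25 / 30)  # consensus boundary
  )
  for (mod in cases) {
    row <- base
    row[names(mod)] <- mod
    expect_equal(nrow(call_deps(row)), 0)
  }
  ## sorted by |log2 ratio| descending
  multi <- rbind(base,
                 within(base, {protein_acc <- "P2"; mean_ratio <- 0.3}),
                 within(base, {protein_acc <- "P3"; mean_ratio <- 1.5}))
  expect_equal(call_deps(multi)$protein_acc, c("P2", "P1", "P3"))
  expect_error(call_deps(base[, 1:3]), "lacks column")
})

test_that("input row order and common scaling never change the calls", {
  sim <- gen_itraq_dataset(itraq_sim_config(n_proteins = 40, seed = 21))
  s <- sim$spectra
  base <- call_deps(quantify_spectra(s)$summary)
  perm <- s[sample(nrow(s))]
  expect_identical(call_deps(quantify_spectra(perm)$summary), base)
  scaled <- data.table::copy(s)
  for (col in paste0("area_", 114:117))
    data.table::set(scaled, j = col, value = scaled[[col]] * 7.5)
  expect_equal(call_deps(quantify_spectra(scaled)$summary), base,
               tolerance = 1e-12)
})

test_that("planted fold changes are recovered from the default synthetic design", {
  sim <- gen_itraq_dataset(itraq_sim_config(n_proteins = 200, seed = 31))
  deps <- call_deps(quantify_spectra(sim$spectra)$summary)
  truthpos <- sim$truth[direction != "null"]
  sens <- mean(truthpos$protein_acc %in% deps$protein_acc)
  fdp <- if (nrow(deps)) mean(!(deps$protein_acc %in% truthpos$protein_acc)) else 0
  expect_gte(sens, 0.90)
  expect_lte(fdp, 0.10)
  ## called directions match the planted ones
  hit <- merge(deps, sim$truth, by = "protein_acc")
  expect_true(all(hit$direction.x == hit$direction.y))
})
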