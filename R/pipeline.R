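#' Load and validate a pipeline configuration
#'
#' Configurations are flat YAML with sections `simulate`, `quant`,
#' `screen`, `network` and `integrate`; see the packaged demo
#' (`system.file("extdata", "demo_config.yaml", package = "itraqnet")`).
#' Missing sections fall back to the generator and threshold defaults.
#'
#' @param path YAML file path, or a pre-built list.
#' @param seed Optional seed overriding the configured one.
#' @return Validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(path, seed = NULL) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  cfg$seed <- as.integer(seed %||% cfg$seed %||% 1L)
  cfg$simulate <- cfg$simulate %||% list()
  cfg$quant <- cfg$quant %||% list()
  cfg$screen <- cfg$screen %||% list()
  cfg$network <- cfg$network %||% list()
  cfg$integrate <- cfg$integrate %||% list()
  th <- cfg$quant$thresholds %||% list()
  cfg$quant$thresholds <- do.call(dep_thresholds, th)
  cfg$screen$tanimoto_threshold <- cfg$screen$tanimoto_threshold %||% 0.8
  cfg$network$hub_cut <- match.arg(cfg$network$hub_cut %||% "median",
                                   c("median", "mean"))
  for (p in c(cfg$quant$purity_matrix, cfg$integrate$mapping))
    if (!is.null(p) && !file.exists(p))
      stop_config("configured input path does not exist: ", p)
  structure(cfg, class = "pipeline_config")
}

#' Run the full integrative pipeline on synthetic inputs
#'
#' Chains every stage end to end: simulate the iTRAQ experiment, compound
#' library and interaction network; quantify and call differential
#' proteins; screen compounds by Tanimoto similarity and build the
#' compound--target edge table; median-filter the interaction network and
#' screen major hubs; run pathway overrepresentation; merge hubs with
#' differential proteins and nominate key targets. All outputs (TSV
#' tables, SIF exports, JSON report, run manifest) are written under
#' `out_dir`. Deterministic: a fixed configuration and seed reproduce
#' byte-identical tables.
#'
#' @param config A [pipeline_config()], a path to one, or `NULL` for the
#'   packaged demo configuration.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional seed override.
#' @return Invisible list with all stage results (`truth`, `deps`,
#'   `screen`, `hubs`, `enrichment`, `report`, `manifest`).
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("itraqnet_run_"),
                         seed = NULL) {
  if (is.null(config))
    config <- system.file("extdata", "demo_config.yaml", package = "itraqnet")
  if (!inherits(config, "pipeline_config"))
    config <- pipeline_config(config, seed = seed)
  else if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_warn <- 0L
  counted <- function(expr) withCallingHandlers(expr, warning = function(w) {
    n_warn <<- n_warn + 1L
    invokeRestart("muffleWarning")
  })
  seed <- config$seed

  ## stage: simulate
  icfg <- do.call(itraq_sim_config,
                  c(config$simulate$itraq %||% list(),
                    list(seed = seed)))
  sim <- gen_itraq_dataset(icfg)
  lib <- do.call(gen_compound_library,
                 c(config$simulate$compounds %||%
                     list(n_compounds = 40, n_similar = 20),
                   list(seed = seed + 1L)))
  ncfg <- do.call(network_sim_config,
                  c(config$simulate$network %||% list(),
                    list(seed = seed + 2L)))
  net_in <- gen_ppi_and_pathways(ncfg)
  write_table(sim$spectra, file.path(out_dir, "spectra.tsv"), "spectra")
  write_table(sim$truth, file.path(out_dir, "truth.tsv"), "truth")
  write_table(net_in$edges, file.path(out_dir, "ppi_edges.tsv"), "edges")
  write_gmt(net_in$pathways, file.path(out_dir, "pathways.gmt"))

  ## stage: quant
  purity <- if (!is.null(config$quant$purity_matrix))
    read_purity_matrix(config$quant$purity_matrix) else NULL
  q <- counted(quantify_spectra(sim$spectra, purity = purity))
  deps <- call_deps(q$summary, config$quant$thresholds)
  write_table(deps, file.path(out_dir, "dep_table.tsv"), "dep")

  ## stage: screen
  scr <- counted(screen_compounds(lib$compounds, lib$references,
                                  config$screen$tanimoto_threshold))
  kept_ids <- scr[kept == TRUE, compound_id]
  ct <- net_in$compound_targets[compound_id %in% kept_ids]
  ct_edges <- build_compound_target_edges(kept_ids, ct)
  write_table(scr, file.path(out_dir, "compound_screen.tsv"))

  ## stage: network + hubs
  filtered <- counted(filter_edges_by_median_score(net_in$edges))
  topo <- node_topology(filtered, nodes = net_in$nodes$node_id)
  sel <- select_hubs(topo, cut = config$network$hub_cut)
  write_table(topo, file.path(out_dir, "topology.tsv"), "topology")
  write_table(data.table(node_id = sel$hubs),
              file.path(out_dir, "hubs.tsv"))
  write_sif(filtered, file.path(out_dir, "ppi_filtered.sif"))

  ## stage: enrich
  db <- pathway_db(net_in$pathways)
  query <- if (length(sel$hubs) >= 3) sel$hubs else
    head(topo[order(-degree)]$node_id, 10)
  enr <- counted(enrich(query, db))
  write_table(enr, file.path(out_dir, "enrichment.tsv"))

  ## stage: integrate
  mapping <- if (!is.null(config$integrate$mapping))
    read_table(config$integrate$mapping, "mapping") else NULL
  cand <- counted(merge_candidates(sel$hubs, deps$protein_acc, mapping))
  report <- NULL
  if (nrow(cand) >= 3) {
    inet <- counted(induced_interaction_network(cand, net_in$edges))
    report <- counted(nominate_key_targets(inet, cut = config$network$hub_cut,
                                           db = db))
    write_sif(inet, file.path(out_dir, "integration.sif"))
    write_json_report(list(
      key_targets = report$key_targets,
      cuts = as.list(report$selection$cuts),
      note = report$note
    ), file.path(out_dir, "key_targets.json"))
  }

  manifest <- run_manifest(
    config = unclass(config),
    inputs = if (!is.null(config$quant$purity_matrix)) config$quant$purity_matrix
             else character(),
    counts = list(spectra = nrow(sim$spectra), proteins = icfg$n_proteins,
                  deps = nrow(deps), compounds_kept = length(kept_ids),
                  edges = nrow(net_in$edges),
                  edges_retained = nrow(filtered),
                  hubs = length(sel$hubs),
                  key_targets = if (is.null(report)) 0L
                                else nrow(report$key_targets)),
    warnings_count = n_warn)
  write_json_report(manifest, file.path(out_dir, "manifest.json"))

  invisible(list(config = config, truth = sim$truth, quant = q, deps = deps,
                 screen = scr, compound_edges = ct_edges, topology = topo,
                 hubs = sel, enrichment = enr, candidates = cand,
                 report = report, manifest = manifest, out_dir = out_dir))
}
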