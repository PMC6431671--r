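## Documented column schemas for every tabular interchange format.
## type codes: c = character, i = integer, n = numeric, l = logical.
table_schemas <- list(
  spectra = c(peptide_id = "c", protein_acc = "c", batch = "i",
              area_114 = "n", area_115 = "n", area_116 = "n",
              area_117 = "n", protein_score = "n", unused_score = "n"),
  truth = c(protein_acc = "c", direction = "c", true_fold = "n"),
  compounds = c(compound_id = "c", fingerprint = "c"),
  compound_targets = c(compound_id = "c", target_id = "c"),
  edges = c(node_a = "c", node_b = "c", combined_score = "n"),
  nodes = c(node_id = "c", role = "c"),
  disease_targets = c(target_id = "c"),
  dep = c(protein_acc = "c", mean_ratio = "n", p_value = "n",
          direction = "c", n_peptides = "i", consensus_fraction = "n"),
  protein_summary = c(protein_acc = "c", mean_ratio = "n", p_value = "n",
                      n_peptides = "i", protein_score = "n"),
  mapping = c(accession = "c", symbol = "c"),
  topology = c(node_id = "c", degree = "i", betweenness = "n",
               closeness = "n")
)

#' Read and validate a TSV table against a documented schema
#'
#' Lines starting with `#` are treated as comments (the writers emit a
#' schema-version header in that form). The named schema's columns must
#' all be present -- a missing column is an error naming it -- and numeric
#' columns must parse, with the first offending row reported. Extra
#' columns are allowed and preserved. An empty file (no data rows) is an
#' error, not an empty table.
#'
#' @param path File path.
#' @param schema One of `r paste0('\x60', names(table_schemas), '\x60', collapse = ", ")`.
#' @return Validated `data.table`.
#' @export
read_table <- function(path, schema) {
  if (!file.exists(path)) stop_config("file not found: ", path)
  spec <- table_schemas[[schema]]
  if (is.null(spec)) stop_config("unknown table schema: ", schema)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2)
    stop_config("file '", path, "' has no data rows (schema '", schema, "')")
  dt <- fread(text = paste(lines, collapse = "\n"), sep = "\t",
              colClasses = "character", header = TRUE)
  miss <- setdiff(names(spec), names(dt))
  if (length(miss))
    stop_config("file '", path, "' is missing required column(s): ",
                paste(miss, collapse = ", "))
  for (col in names(spec)) {
    val <- dt[[col]]
    conv <- switch(spec[[col]],
                   c = val,
                   i = suppressWarnings(as.integer(val)),
                   n = suppressWarnings(as.numeric(val)),
                   l = as.logical(val))
    if (spec[[col]] != "c") {
      bad <- which(is.na(conv) & !is.na(val) & nzchar(val))
      if (length(bad))
        stop_config("file '", path, "', column '", col, "': value '",
                    val[bad[1]], "' at data row ", bad[1],
                    " is not of type ", spec[[col]])
    }
    set(dt, j = col, value = conv)
  }
  dt[]
}

#' Write a TSV table with a schema-version header comment
#'
#' @param x Table to write.
#' @param path Destination.
#' @param schema Optional schema name recorded in the `#` header line.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, schema = NULL) {
  hdr <- sprintf("# itraqnet table%s v1",
                 if (is.null(schema)) "" else paste0(" schema=", schema))
  writeLines(hdr, path)
  fwrite(as.data.table(x), path, sep = "\t", append = TRUE,
         col.names = TRUE)
  invisible(path)
}

#' Read a GMT gene-set file into a pathway database
#'
#' Standard gene-matrix-transposed parsing: each line is
#' `pathway_id TAB description TAB gene1 TAB gene2 ...`. Duplicate genes
#' within a set are collapsed; CRLF endings are accepted. A line with
#' fewer than three fields is an error reporting the line number.
#'
#' @param path GMT file path.
#' @param universe Optional background gene set overriding the default
#'   (union of all pathway genes).
#' @return A [pathway_db()].
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) stop_config("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- nzchar(lines)
  pathways <- list()
  descriptions <- character()
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop_config("GMT line ", i, " has fewer than 3 tab-separated fields")
    pathways[[f[1]]] <- unique(f[-(1:2)])
    descriptions[f[1]] <- f[2]
  }
  if (length(pathways) == 0) stop_config("GMT file '", path, "' is empty")
  pathway_db(pathways, universe = universe, descriptions = descriptions)
}

#' Write a pathway list as a GMT file
#'
#' @param pathways Named list of gene vectors, or a `pathway_db`.
#' @param path Destination.
#' @param descriptions Optional named descriptions (default `"na"`).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(pathways, path, descriptions = NULL) {
  if (inherits(pathways, "pathway_db")) {
    descriptions <- descriptions %||% pathways$descriptions
    pathways <- pathways$pathways
  }
  lines <- vapply(names(pathways), function(pid) {
    desc <- if (!is.null(descriptions) && pid %in% names(descriptions))
      descriptions[[pid]] else "na"
    paste(c(pid, desc, pathways[[pid]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Export edges in SIF format for network-visualization tools
#'
#' Three-column `node_a TAB interaction TAB node_b` lines; isolated nodes
#' (if supplied) are written as single-column lines, the SIF convention.
#'
#' @param edges Edge table or `typed_network`.
#' @param path Destination.
#' @param interaction Interaction type label (default `"pp"`).
#' @return `path`, invisibly.
#' @export
write_sif <- function(edges, path, interaction = "pp") {
  iso <- character()
  if (inherits(edges, "typed_network")) {
    iso <- setdiff(edges$nodes$node_id,
                   unique(c(edges$edges$node_a, edges$edges$node_b)))
    edges <- edges$edges
  }
  e <- as.data.table(edges)
  lines <- c(sprintf("%s\t%s\t%s", e$node_a, interaction, e$node_b), iso)
  writeLines(lines, path)
  invisible(path)
}

#' Build a run manifest for reproducibility audits
#'
#' Records the tool version, a hash of the canonicalized configuration,
#' MD5 checksums of input files, a timestamp, per-stage row counts and
#' warning counts. Two runs on identical config and inputs differ only in
#' the timestamp.
#'
#' @param config Configuration list.
#' @param inputs Character vector of input file paths (existing files are
#'   checksummed).
#' @param counts Named list/vector of per-stage row counts.
#' @param warnings_count Number of warnings accumulated during the run.
#' @return Manifest list.
#' @export
run_manifest <- function(config, inputs = character(), counts = list(),
                         warnings_count = 0L) {
  cfg_file <- tempfile()
  on.exit(unlink(cfg_file))
  writeLines(paste(deparse(config[order(names(config))]), collapse = ""), cfg_file)
  inputs <- inputs[file.exists(inputs)]
  list(
    tool = "itraqnet",
    version = as.character(utils::packageVersion("itraqnet")),
    config_hash = unname(tools::md5sum(cfg_file)),
    input_checksums = as.list(tools::md5sum(inputs)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    row_counts = as.list(counts),
    warnings = warnings_count
  )
}

#' Write a manifest (or any report list) as JSON
#'
#' @param x List to serialize.
#' @param path Destination.
#' @return `path`, invisibly.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
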