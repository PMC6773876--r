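# End-to-end orchestration: configuration, validation, pipeline run with
# file outputs, run manifest and a minimal static HTML report.

#' Pipeline run configuration
#'
#' Collects every stage's parameters with their standard defaults:
#' significance threshold 0.05, subnetwork score quantile 0.80, at least
#' 10 significant genes per subnetwork, overlap threshold 0.5, 10
#' iterations for greedy and simulated annealing (1 for the genetic
#' algorithm), Bonferroni adjustment and enrichment threshold 0.05.
#'
#' @param pin_path path to a SIF network file.
#' @param deg_path path to the DEG TSV table.
#' @param gene_sets_path path to a GMT file.
#' @param out_dir output directory.
#' @param expression_path optional expression TSV for per-sample pathway
#'   scoring.
#' @param alias_path optional two-column alias map TSV.
#' @param p_threshold input significance threshold (default 0.05).
#' @param algorithm search algorithm (default `"greedy"`).
#' @param iterations search-and-enrich iterations; `NULL` means 10 for
#'   greedy/sa and 1 for ga.
#' @param enrichment_threshold adjusted-p cutoff for enrichment
#'   (default 0.05).
#' @param adjust_method `"bonferroni"` (default) or `"bh"`.
#' @param score_quantile,min_sig_genes subnetwork filter parameters.
#' @param cluster_method `"hierarchical"` (default) or `"fuzzy"`.
#' @param kappa_threshold fuzzy clustering neighbor cutoff (default 0.35).
#' @param calib_draws Monte Carlo draws per subnetwork size (default 2000).
#' @param seed master RNG seed (default 1).
#' @param ... further [search_config()] fields (e.g. `sa_iters`,
#'   `ga_pop`).
#' @return A `run_config` list.
#' @export
run_config <- function(pin_path = NULL, deg_path = NULL,
                       gene_sets_path = NULL, out_dir = NULL,
                       expression_path = NULL, alias_path = NULL,
                       p_threshold = 0.05,
                       algorithm = c("greedy", "sa", "ga"),
                       iterations = NULL,
                       enrichment_threshold = 0.05,
                       adjust_method = c("bonferroni", "bh"),
                       score_quantile = 0.80, min_sig_genes = 10L,
                       cluster_method = c("hierarchical", "fuzzy"),
                       kappa_threshold = 0.35,
                       calib_draws = 2000L, seed = 1L, ...) {
  algorithm <- match.arg(algorithm)
  cfg <- list(pin_path = pin_path, deg_path = deg_path,
              gene_sets_path = gene_sets_path, out_dir = out_dir,
              expression_path = expression_path, alias_path = alias_path,
              p_threshold = p_threshold, algorithm = algorithm,
              iterations = iterations,
              enrichment_threshold = enrichment_threshold,
              adjust_method = match.arg(adjust_method),
              score_quantile = score_quantile,
              min_sig_genes = as.integer(min_sig_genes),
              cluster_method = match.arg(cluster_method),
              kappa_threshold = kappa_threshold,
              calib_draws = as.integer(calib_draws),
              seed = as.integer(seed),
              search = search_config(algorithm = algorithm, seed = seed, ...))
  class(cfg) <- "run_config"
  cfg
}

#' Validate a run configuration
#'
#' Returns (rather than raises) the list of violations so callers can
#' report them all at once. A genetic-algorithm run with more than one
#' iteration is flagged as a warning, not a violation: a single iteration
#' is the standard choice there, but more are permitted.
#'
#' @param config a [run_config()].
#' @return Character vector of violations (empty when valid); warnings
#'   are attached as attribute `"warnings"`.
#' @export
validate_config <- function(config) {
  v <- character()
  w <- character()
  chk <- function(ok, msg) if (!ok) v <<- c(v, msg)
  chk(config$p_threshold > 0 && config$p_threshold <= 1,
      "p_threshold must be in (0, 1]")
  chk(config$enrichment_threshold > 0 && config$enrichment_threshold <= 1,
      "enrichment_threshold must be in (0, 1]")
  chk(config$score_quantile >= 0 && config$score_quantile <= 1,
      "score_quantile must be in [0, 1]")
  chk(config$search$overlap_threshold >= 0 && config$search$overlap_threshold <= 1,
      "overlap_threshold must be in [0, 1]")
  chk(config$search$sa_cooling > 0 && config$search$sa_cooling < 1,
      "sa_cooling must be in (0, 1)")
  chk(config$search$ga_mutation >= 0 && config$search$ga_mutation <= 1,
      "ga_mutation must be in [0, 1]")
  chk(config$min_sig_genes >= 1, "min_sig_genes must be >= 1")
  chk(is.null(config$iterations) || config$iterations >= 1,
      "iterations must be >= 1")
  if (config$algorithm == "ga" && !is.null(config$iterations) &&
      config$iterations != 1L)
    w <- c(w, "genetic algorithm is usually run with a single iteration")
  structure(v, warnings = w)
}

#' Run the full pipeline on files
#'
#' Reads the inputs, processes the DEG table, runs the iterated
#' search-and-enrich analysis, clusters the enriched pathways (when at
#' least two), optionally scores pathways per sample, and writes:
#' `enrichment.tsv`, `clusters.tsv`, `pathway_scores.tsv` (if an
#' expression matrix was given), `subnetworks.tsv`, `report.html` and a
#' machine-readable `manifest.json` (configuration echo, seed, input and
#' dropped-gene counts, subnetwork and pathway counts).
#'
#' @param config a [run_config()] with the input paths and `out_dir` set.
#' @return Invisibly, a list with elements `result` (the
#'   `enrichment_result`), `clusters`, `pathway_scores`, `manifest` and
#'   `files`.
#' @export
run_pipeline <- function(config) {
  violations <- validate_config(config)
  if (length(violations) > 0L)
    stop_input("invalid configuration: ", paste(violations, collapse = "; "))
  for (f in c("pin_path", "deg_path", "gene_sets_path"))
    if (is.null(config[[f]]) || !file.exists(config[[f]]))
      stop_input("missing input file for ", f, ": ",
                 config[[f]] %||% "<unset>")
  if (is.null(config$out_dir)) stop_input("out_dir is not set")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  pin <- read_sif(config$pin_path)
  deg <- read_deg_table(config$deg_path)
  gene_sets <- read_gmt(config$gene_sets_path)
  aliases <- if (!is.null(config$alias_path)) read_alias_map(config$alias_path)
  message("inputs: ", n_nodes(pin), " network nodes, ", nrow(deg),
          " DEG rows, ", length(gene_sets$sets), " gene sets")

  processed <- process_input(deg, pin, config$p_threshold, aliases)
  message("processed: ", length(processed$genes), " significant genes in PIN, ",
          nrow(processed$dropped), " dropped")

  result <- run_active_enrichment(
    processed, pin, gene_sets, config$search,
    iterations = config$iterations,
    enrichment_threshold = config$enrichment_threshold,
    adjust_method = config$adjust_method,
    score_quantile = config$score_quantile,
    min_sig_genes = config$min_sig_genes,
    calib_draws = config$calib_draws)
  message("enrichment: ", nrow(result), " pathways")

  files <- list(enrichment = file.path(config$out_dir, "enrichment.tsv"))
  write_result_table(result, files$enrichment)

  clusters <- NULL
  if (nrow(result) >= 2L) {
    clusters <- cluster_pathways(result, processed$genes,
                                 method = config$cluster_method)
    files$clusters <- file.path(config$out_dir, "clusters.tsv")
    utils::write.table(as.data.frame(clusters), files$clusters, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    message("clustering: ", attr(clusters, "k"), " clusters")
  }

  ps <- NULL
  if (!is.null(config$expression_path) && nrow(result) >= 1L) {
    em <- read_expression_matrix(config$expression_path)
    gs <- gene_scores(em)
    keep <- intersect(result$ID, names(gene_sets$sets))
    ps <- suppressWarnings(pathway_scores(gs, gene_sets$sets[keep]))
    files$pathway_scores <- file.path(config$out_dir, "pathway_scores.tsv")
    df <- data.frame(pathway = rownames(ps), ps, check.names = FALSE)
    utils::write.table(df, files$pathway_scores, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  subs <- attr(result, "subnetworks")
  files$subnetworks <- file.path(config$out_dir, "subnetworks.tsv")
  utils::write.table(subnetworks_as_table(subs), files$subnetworks,
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    seed = config$seed,
    algorithm = config$algorithm,
    parameters = config[c("p_threshold", "enrichment_threshold",
                          "adjust_method", "score_quantile",
                          "min_sig_genes", "cluster_method",
                          "calib_draws")],
    iterations = config$iterations %||%
      (if (config$algorithm == "ga") 1L else 10L),
    counts = list(
      pin_nodes = n_nodes(pin), pin_edges = n_edges(pin),
      deg_rows = nrow(deg),
      significant_in_pin = length(processed$genes),
      dropped = as.list(table(processed$dropped$reason)),
      subnetworks_last_iteration = length(subs),
      enriched_pathways = nrow(result),
      clusters = if (is.null(clusters)) 0L else attr(clusters, "k")))
  files$manifest <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, files$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  files$report <- file.path(config$out_dir, "report.html")
  write_html_report(result, manifest, files$report)

  invisible(list(result = result, clusters = clusters, pathway_scores = ps,
                 manifest = manifest, files = files))
}

# Single-file static HTML summary: parameter echo plus the result table.
write_html_report <- function(result, manifest, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  df <- as.data.frame(result)
  header <- paste0("<tr>", paste0("<th>", esc(names(df)), "</th>",
                                  collapse = ""), "</tr>")
  rows <- apply(df, 1L, function(r)
    paste0("<tr>", paste0("<td>", esc(as.character(r)), "</td>",
                          collapse = ""), "</tr>"))
  params <- paste(sprintf("<li>%s = %s</li>",
                          esc(names(unlist(manifest$parameters))),
                          esc(as.character(unlist(manifest$parameters)))),
                  collapse = "\n")
  html <- c("<!DOCTYPE html><html><head><meta charset='utf-8'>",
            "<title>Active-subnetwork pathway enrichment</title>",
            "<style>table{border-collapse:collapse}td,th{border:1px solid #999;padding:3px 6px;font:13px sans-serif}</style>",
            "</head><body>",
            "<h1>Active-subnetwork-oriented pathway enrichment</h1>",
            sprintf("<p>%d enriched pathway(s); seed %s; algorithm %s, %s iteration(s).</p>",
                    nrow(df), manifest$seed, manifest$algorithm,
                    manifest$iterations),
            "<h2>Parameters</h2><ul>", params, "</ul>",
            "<h2>Results</h2><table>", header, rows, "</table>",
            "</body></html>")
  writeLines(html, path)
  invisible(path)
}
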