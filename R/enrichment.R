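# Over-representation analysis on filtered active subnetworks, adjusted and
# aggregated across subnetworks and search iterations.

#' Filter active subnetworks before enrichment
#'
#' Keeps subnetworks that (i) have a calibrated score strictly larger than
#' the empirical `score_quantile` of this run's subnetwork scores (linear
#' interpolation between order statistics) and (ii) contain at least
#' `min_sig_genes` significant input genes. When only one subnetwork
#' exists, the score criterion is waived (any score equals its own
#' quantile, which would make the step vacuous).
#'
#' @param subnetworks list of scored `subnetwork` objects.
#' @param score_quantile quantile threshold in `[0, 1]` (default 0.80).
#' @param min_sig_genes minimum number of significant input genes
#'   (default 10).
#' @return The kept list; warns when the input is empty.
#' @export
filter_subnetworks <- function(subnetworks, score_quantile = 0.80,
                               min_sig_genes = 10L) {
  if (length(subnetworks) == 0L) {
    warning("no subnetworks to filter", call. = FALSE)
    return(subnetworks)
  }
  scores <- vapply(subnetworks, `[[`, numeric(1L), "s_a")
  n_sig <- vapply(subnetworks, `[[`, integer(1L), "n_sig")
  if (length(subnetworks) == 1L) {
    score_ok <- TRUE
  } else {
    q <- stats::quantile(scores, probs = score_quantile, names = FALSE,
                         type = 7)
    score_ok <- scores > q
  }
  subnetworks[score_ok & n_sig >= min_sig_genes]
}

#' One-sided hypergeometric over-representation test
#'
#' Tests whether `query_genes` over-represents `pathway_genes` against the
#' background `pool_genes` (the network's node set, so that the background
#' matches the space the subnetworks were searched in). Genes outside the
#' pool are dropped from both query and pathway. With `N = |pool|`,
#' `K = |pathway|`, `n = |query|` and `x = |overlap|`, the p value is the
#' upper tail `P(X >= x)` of the hypergeometric distribution and fold
#' enrichment is `(x/n) / (K/N)`.
#'
#' @param query_genes character vector (typically a subnetwork's genes).
#' @param pathway_genes character vector of pathway member genes.
#' @param pool_genes character vector, the background gene pool.
#' @return List with `p`, `fold_enrichment` and `overlap_genes` (sorted).
#' @export
hypergeometric_ora <- function(query_genes, pathway_genes, pool_genes) {
  pool <- unique(pool_genes)
  if (length(pool) == 0L) stop_input("empty background gene pool")
  query <- intersect(unique(query_genes), pool)
  pathway <- intersect(unique(pathway_genes), pool)
  N <- length(pool); K <- length(pathway); n <- length(query)
  overlap <- intersect(query, pathway)
  x <- length(overlap)
  p <- stats::phyper(x - 1L, K, N - K, n, lower.tail = FALSE)
  fold <- if (n == 0L || K == 0L) 0 else (x / n) / (K / N)
  list(p = p, fold_enrichment = fold, overlap_genes = sort(overlap))
}

#' Adjust p values for multiple testing
#'
#' Bonferroni (`min(1, p * m)`, the default downstream) or
#' Benjamini-Hochberg step-up. Output order matches input order.
#'
#' @param ps numeric vector of p values in `[0, 1]`.
#' @param method `"bonferroni"` or `"bh"`.
#' @return Adjusted p values.
#' @export
adjust_pvalues <- function(ps, method = c("bonferroni", "bh")) {
  assert_probability(ps, "p values")
  method <- match.arg(method)
  stats::p.adjust(ps, method = if (method == "bh") "BH" else "bonferroni")
}

#' Aggregate per-subnetwork enrichment records
#'
#' Discards records with adjusted p strictly greater than `threshold`
#' (records at the boundary are kept), then keeps, for each pathway
#' enriched in several subnetworks, the record with the minimum adjusted p
#' (ties broken by larger fold enrichment, then by pathway id).
#'
#' @param records data.frame with columns `id`, `p`, `adj_p`,
#'   `fold_enrichment`, `overlap_genes` (list column), one row per
#'   (subnetwork, pathway) test.
#' @param threshold enrichment significance threshold (default 0.05).
#' @return data.frame with one row per surviving pathway.
#' @export
aggregate_subnetworks <- function(records, threshold = 0.05) {
  records <- records[records$adj_p <= threshold, , drop = FALSE]
  if (nrow(records) == 0L) return(records)
  o <- order(records$id, records$adj_p, -records$fold_enrichment)
  records <- records[o, , drop = FALSE]
  records <- records[!duplicated(records$id), , drop = FALSE]
  records[order(records$adj_p, records$id), , drop = FALSE]
}

# ORA of every gene set against one subnetwork's genes; one adjustment
# family per subnetwork (m = number of gene sets tested).
enrich_subnetwork <- function(sub_genes, gene_sets, pool,
                              adjust_method = "bonferroni") {
  res <- lapply(names(gene_sets$sets), function(id) {
    ora <- hypergeometric_ora(sub_genes, gene_sets$sets[[id]], pool)
    data.frame(id = id, p = ora$p, fold_enrichment = ora$fold_enrichment,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, res)
  df$adj_p <- adjust_pvalues(df$p, adjust_method)
  df$overlap_genes <- lapply(names(gene_sets$sets), function(id)
    sort(intersect(sub_genes, gene_sets$sets[[id]])))
  df
}

#' Active-subnetwork-oriented pathway enrichment analysis
#'
#' The core pipeline: for each iteration, run the configured subnetwork
#' search with a fresh RNG substream, filter the subnetworks
#' ([filter_subnetworks()]), test every gene set against each filtered
#' subnetwork by one-sided hypergeometric ORA with the network's genes as
#' background pool, adjust within each subnetwork's test family, and
#' aggregate by lowest adjusted p ([aggregate_subnetworks()]). Across
#' iterations, each pathway's lowest and highest adjusted p, its number of
#' occurrences (iterations in which it was significantly enriched) and the
#' fold enrichment of its lowest-p record are reported, together with the
#' significant input genes it contains, split into up- and down-regulated
#' by the sign of the change value (a single `Involved_genes` column when
#' the input has no change column; zero-change genes are listed under
#' neither).
#'
#' @param processed a `processed_input` from [process_input()].
#' @param pin an [interaction_network()].
#' @param gene_sets a `gene_set_collection`.
#' @param config a [search_config()].
#' @param iterations number of search-and-enrich iterations; defaults to
#'   10 for greedy and simulated annealing, 1 for the genetic algorithm.
#' @param enrichment_threshold adjusted-p cutoff for a pathway to count as
#'   enriched (default 0.05).
#' @param adjust_method `"bonferroni"` (default) or `"bh"`.
#' @param score_quantile,min_sig_genes passed to [filter_subnetworks()].
#' @param calib_draws Monte Carlo draws per size for score calibration
#'   (default 2000).
#' @return An `enrichment_result` data.frame sorted by `lowest_p`, with
#'   columns `ID`, `Description`, `Fold_Enrichment`, `occurrence`,
#'   `lowest_p`, `highest_p` and `Up_regulated`/`Down_regulated` (or
#'   `Involved_genes`), gene lists `";"`-joined alphabetically. The
#'   per-pathway significant input genes are attached as the list
#'   attribute `"input_genes"`; the subnetworks of the last iteration as
#'   attribute `"subnetworks"`.
#' @export
run_active_enrichment <- function(processed, pin, gene_sets, config,
                                  iterations = NULL,
                                  enrichment_threshold = 0.05,
                                  adjust_method = c("bonferroni", "bh"),
                                  score_quantile = 0.80,
                                  min_sig_genes = 10L,
                                  calib_draws = 2000L) {
  stopifnot(inherits(processed, "processed_input"))
  adjust_method <- match.arg(adjust_method)
  if (length(processed$genes) == 0L)
    stop_input("no significant genes mapped to the network")
  if (is.null(iterations))
    iterations <- if (config$algorithm == "ga") 1L else 10L
  zmap <- p_to_z(processed$p)
  pool <- pin$nodes
  per_iter <- vector("list", iterations)
  last_subs <- list()
  for (it in seq_len(iterations)) {
    it_seed <- derive_seed(config$seed, it)
    it_config <- config
    it_config$seed <- it_seed
    calib <- calibrate_background(pin, zmap, draws = calib_draws,
                                  seed = it_seed)
    subs <- active_search(pin, zmap, processed$genes, it_config, calib)
    subs <- suppressWarnings(
      filter_subnetworks(subs, score_quantile, min_sig_genes))
    last_subs <- subs
    if (length(subs) == 0L) {
      per_iter[[it]] <- data.frame()
      next
    }
    recs <- do.call(rbind, lapply(subs, function(s)
      enrich_subnetwork(s$genes, gene_sets, pool, adjust_method)))
    per_iter[[it]] <- aggregate_subnetworks(recs, enrichment_threshold)
  }
  build_result_table(per_iter, processed, gene_sets, iterations, last_subs)
}

# Collapse per-iteration aggregated records into the final result table.
build_result_table <- function(per_iter, processed, gene_sets, iterations,
                               subnetworks = list()) {
  nonempty <- Filter(function(d) nrow(d) > 0L, per_iter)
  has_change <- !is.null(processed$change)
  if (length(nonempty) == 0L) {
    warning("no pathway enriched in any iteration", call. = FALSE)
    return(empty_result_table(has_change, subnetworks))
  }
  all_recs <- do.call(rbind, lapply(nonempty, function(d)
    d[, c("id", "adj_p", "fold_enrichment"), drop = FALSE]))
  ids <- sort(unique(all_recs$id))
  rows <- lapply(ids, function(id) {
    r <- all_recs[all_recs$id == id, , drop = FALSE]
    best <- which.min(r$adj_p)
    data.frame(ID = id,
               Description = unname(gene_sets$descriptions[[id]]),
               Fold_Enrichment = r$fold_enrichment[[best]],
               occurrence = nrow(r),
               lowest_p = min(r$adj_p),
               highest_p = max(r$adj_p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  input_genes <- lapply(ids, function(id)
    sort(intersect(gene_sets$sets[[id]], processed$genes)))
  names(input_genes) <- ids
  if (has_change) {
    out$Up_regulated <- vapply(input_genes, function(g)
      paste(g[processed$change[g] > 0], collapse = ";"), character(1L))
    out$Down_regulated <- vapply(input_genes, function(g)
      paste(g[processed$change[g] < 0], collapse = ";"), character(1L))
  } else {
    out$Involved_genes <- vapply(input_genes, paste, character(1L),
                                 collapse = ";")
  }
  o <- order(out$lowest_p, out$ID)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "input_genes") <- input_genes[o]
  attr(out, "subnetworks") <- subnetworks
  attr(out, "iterations") <- iterations
  class(out) <- c("enrichment_result", "data.frame")
  out
}

empty_result_table <- function(has_change, subnetworks = list()) {
  out <- data.frame(ID = character(), Description = character(),
                    Fold_Enrichment = numeric(), occurrence = integer(),
                    lowest_p = numeric(), highest_p = numeric(),
                    stringsAsFactors = FALSE)
  if (has_change) {
    out$Up_regulated <- character()
    out$Down_regulated <- character()
  } else {
    out$Involved_genes <- character()
  }
  attr(out, "input_genes") <- list()
  attr(out, "subnetworks") <- subnetworks
  class(out) <- c("enrichment_result", "data.frame")
  out
}
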