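# Per-sample pathway activity scores from an expression matrix.

#' Standardized gene scores
#'
#' For each gene (row), `GS(g, s) = (EM[g, s] - mean_g) / sd_g`, where the
#' mean and standard deviation are taken across samples (sample sd, n - 1
#' denominator by default). Zero-variance genes score 0 in every sample
#' rather than being dropped, which keeps pathway gene counts stable
#' across samples.
#'
#' @param em numeric gene x sample matrix (see
#'   [read_expression_matrix()]); at least 2 samples.
#' @param sd_convention `"sample"` (n - 1, default) or `"population"` (n).
#' @return Numeric matrix of the same shape; every finite-variance row has
#'   mean 0 across samples.
#' @export
gene_scores <- function(em, sd_convention = c("sample", "population")) {
  sd_convention <- match.arg(sd_convention)
  if (!is.matrix(em) || !is.numeric(em)) stop_input("em must be a numeric matrix")
  n <- ncol(em)
  if (n < 2L) stop_input("at least 2 samples are required")
  mu <- rowMeans(em)
  centered <- em - mu
  ss <- rowSums(centered^2)
  denom <- if (sd_convention == "sample") n - 1L else n
  sdv <- sqrt(ss / denom)
  gs <- centered / ifelse(sdv == 0, 1, sdv)
  gs[sdv == 0, ] <- 0
  gs
}

#' Per-sample pathway activity scores
#'
#' `PS[i, j]` is the mean standardized gene score ([gene_scores()]) over
#' the genes of pathway i that are present in the matrix, for sample j -
#' a single-sample summary of how active the pathway is relative to the
#' cohort average. Pathways with no gene present are dropped with a
#' warning.
#'
#' @param gs gene score matrix from [gene_scores()].
#' @param pathways a `gene_set_collection`, or a named list of gene
#'   vectors.
#' @param gene_selection `"pathway_genes"` (all pathway genes present in
#'   the matrix, default) or `"input_genes"` (restrict to
#'   `significant_genes` first, matching per-pathway heat maps over the
#'   experiment's significant genes).
#' @param significant_genes required when
#'   `gene_selection = "input_genes"`.
#' @return Numeric pathway x sample matrix; attribute `"gene_selection"`
#'   records the mode.
#' @export
pathway_scores <- function(gs, pathways,
                           gene_selection = c("pathway_genes", "input_genes"),
                           significant_genes = NULL) {
  gene_selection <- match.arg(gene_selection)
  sets <- if (inherits(pathways, "gene_set_collection")) pathways$sets
          else pathways
  if (gene_selection == "input_genes") {
    if (is.null(significant_genes))
      stop_input("significant_genes required for gene_selection = \"input_genes\"")
    sets <- lapply(sets, intersect, significant_genes)
  }
  present <- lapply(sets, intersect, rownames(gs))
  keep <- lengths(present) > 0L
  if (!any(keep)) stop_input("no pathway has genes in the expression matrix")
  if (any(!keep))
    warning(sum(!keep), " pathway(s) with no gene in the matrix dropped",
            call. = FALSE)
  ps <- t(vapply(present[keep], function(g)
    colMeans(gs[g, , drop = FALSE]), numeric(ncol(gs))))
  rownames(ps) <- names(sets)[keep]
  colnames(ps) <- colnames(gs)
  attr(ps, "gene_selection") <- gene_selection
  ps
}
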