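# Independent oracles and small constructors shared across tests.

# Inverse standard normal CDF by bisection on pnorm, independent of qnorm.
bisect_inv_norm <- function(q, tol = 1e-9) {
  lo <- -10; hi <- 10
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (stats::pnorm(mid) < q) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Exact hypergeometric upper-tail P(X >= x) as a sum of point masses from
# binomial coefficients (exact in double for the small N used in tests).
exact_hyper_tail <- function(N, K, n, x) {
  i <- x:min(K, n)
  i <- i[i >= max(0L, n - (N - K))]
  if (length(i) == 0L) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Benjamini-Hochberg step-up by the direct definition.
bh_oracle <- function(ps) {
  m <- length(ps)
  o <- order(ps)
  ranked <- ps[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Connected components via igraph, as an independent traversal oracle.
igraph_components <- function(pin, on_genes) {
  on_genes <- unique(on_genes)
  if (length(on_genes) == 0L) return(list())
  keep <- pin$edges[, 1L] %in% on_genes & pin$edges[, 2L] %in% on_genes
  g <- igraph::graph_from_data_frame(
    as.data.frame(pin$edges[keep, , drop = FALSE]),
    directed = FALSE,
    vertices = data.frame(name = on_genes))
  cl <- igraph::components(g)
  comps <- split(names(cl$membership), cl$membership)
  comps <- lapply(unname(comps), sort)
  sizes <- lengths(comps)
  firsts <- vapply(comps, `[[`, character(1L), 1L)
  comps[order(-sizes, firsts)]
}

is_connected_in <- function(pin, genes) {
  length(igraph_components(pin, genes)) == 1L
}

# Average silhouette width from the direct per-point formula.
silhouette_oracle <- function(cl, dmat) {
  dmat <- as.matrix(dmat)
  n <- length(cl)
  s <- vapply(seq_len(n), function(i) {
    own <- setdiff(which(cl == cl[i]), i)
    if (length(own) == 0L) return(0)
    a <- mean(dmat[i, own])
    b <- min(vapply(setdiff(unique(cl), cl[i]), function(k)
      mean(dmat[i, cl == k]), numeric(1L)))
    (b - a) / max(a, b)
  }, numeric(1L))
  mean(s)
}

# Adjusted Rand index between two partitions.
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Path graph A-B-C-... over the given symbols.
path_pin <- function(symbols) {
  interaction_network(cbind(symbols[-length(symbols)], symbols[-1L]))
}

# A fake scored subnetwork record for filter tests.
fake_subnetwork <- function(genes, s_a, n_sig = length(genes)) {
  structure(list(genes = sort(genes), seed = genes[[1L]], z_a = s_a,
                 s_a = s_a, n_sig = as.integer(n_sig)),
            class = "subnetwork")
}

# A minimal enrichment_result for clustering tests.
fake_result <- function(ids, gene_lists, lowest_p = NULL, fold = NULL) {
  gene_lists <- lapply(gene_lists, sort)
  n <- length(ids)
  lowest_p <- lowest_p %||% seq(0.001, 0.01, length.out = n)
  df <- data.frame(ID = ids, Description = ids,
                   Fold_Enrichment = fold %||% rep(2, n),
                   occurrence = rep(1L, n),
                   lowest_p = lowest_p, highest_p = lowest_p,
                   Up_regulated = vapply(gene_lists, paste, character(1L),
                                         collapse = ";"),
                   Down_regulated = rep("", n),
                   stringsAsFactors = FALSE)
  attr(df, "input_genes") <- stats::setNames(gene_lists, ids)
  class(df) <- c("enrichment_result", "data.frame")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Default fixture used by the heavier tests.
default_spec <- function(...) fixture_spec(...)

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
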