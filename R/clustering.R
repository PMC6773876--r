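# Clustering of enriched pathways by pairwise kappa statistics.

#' Pairwise kappa statistic matrix of enriched pathways
#'
#' For each pathway, a binary membership vector over the `universe` (the
#' significance-filtered input genes mapped to the network) marks which
#' genes are input genes of that pathway. For each pair, Cohen's kappa is
#' computed from the 2x2 contingency counts: `kappa = (Po - Pe) / (1 - Pe)`
#' with observed agreement `Po` and chance agreement `Pe` from the
#' marginals. Degenerate pairs with `Pe = 1` (both vectors constant) get
#' kappa 1 if the vectors are identical and 0 otherwise, keeping the
#' matrix total.
#'
#' @param result_table an `enrichment_result` (from
#'   [run_active_enrichment()]), carrying per-pathway input genes.
#' @param universe character vector of significant input genes.
#' @return Symmetric numeric matrix with unit diagonal, pathway ids as
#'   dimnames; values in `[-1, 1]`.
#' @export
kappa_matrix <- function(result_table, universe) {
  memberships <- pathway_memberships(result_table)
  if (length(memberships) < 2L) stop_input("nothing to cluster: need >= 2 pathways")
  universe <- unique(universe)
  if (length(universe) == 0L) stop_input("empty gene universe")
  ids <- names(memberships)
  vecs <- vapply(memberships, function(g) universe %in% g,
                 logical(length(universe)))
  n <- length(ids)
  km <- diag(1, n)
  dimnames(km) <- list(ids, ids)
  N <- length(universe)
  for (i in seq_len(n - 1L)) {
    vi <- vecs[, i]
    for (j in (i + 1L):n) {
      vj <- vecs[, j]
      a <- sum(vi & vj); b <- sum(vi & !vj)
      c_ <- sum(!vi & vj); d <- sum(!vi & !vj)
      po <- (a + d) / N
      pe <- ((a + b) * (a + c_) + (c_ + d) * (b + d)) / N^2
      k <- if (pe == 1) {
        if (identical(vi, vj)) 1 else 0
      } else {
        (po - pe) / (1 - pe)
      }
      km[i, j] <- km[j, i] <- k
    }
  }
  km
}

pathway_memberships <- function(result_table) {
  mem <- attr(result_table, "input_genes")
  if (!is.null(mem)) return(mem)
  # fall back to the written gene-list columns
  if ("Involved_genes" %in% names(result_table)) {
    mem <- strsplit(result_table$Involved_genes, ";", fixed = TRUE)
  } else {
    mem <- Map(function(u, d) unique(c(u, d)),
               strsplit(result_table$Up_regulated, ";", fixed = TRUE),
               strsplit(result_table$Down_regulated, ";", fixed = TRUE))
    mem <- lapply(mem, function(g) g[nzchar(g)])
  }
  stats::setNames(mem, result_table$ID)
}

#' Hierarchical clustering of pathways with silhouette-selected k
#'
#' Agglomerative clustering (average linkage by default) on the distance
#' `1 - kappa`. The tree is cut at every k in `2..(n-1)`; the cut
#' maximizing the average silhouette width is returned (ties broken
#' towards the smallest k). With exactly two pathways the silhouette is
#' undefined, so both fall into a single cluster when their kappa is
#' positive and into two singleton clusters otherwise. Each cluster's
#' representative is its pathway with the minimum `lowest_p` (ties broken
#' by higher fold enrichment, then by id).
#'
#' @param kmat kappa matrix from [kappa_matrix()].
#' @param result_table the `enrichment_result` the matrix was built from
#'   (for representative selection); may be `NULL`, in which case the
#'   first pathway of each cluster is the representative.
#' @param linkage linkage method for [stats::hclust()] (default
#'   `"average"`).
#' @return A `cluster_assignment`: data.frame with columns `ID`, `cluster`
#'   and `is_representative`, plus attribute `"k"`.
#' @export
hierarchical_cluster <- function(kmat, result_table = NULL,
                                 linkage = "average") {
  ids <- rownames(kmat)
  n <- length(ids)
  if (n < 2L) stop_input("nothing to cluster: need >= 2 pathways")
  d <- stats::as.dist(1 - kmat)
  if (n == 2L) {
    members <- if (kmat[1L, 2L] > 0) c(1L, 1L) else c(1L, 2L)
    return(finish_assignment(ids, members, result_table))
  }
  tree <- stats::hclust(d, method = linkage)
  ks <- 2L:(n - 1L)
  asw <- vapply(ks, function(k) {
    cl <- stats::cutree(tree, k = k)
    mean(cluster::silhouette(cl, d)[, "sil_width"])
  }, numeric(1L))
  k_best <- ks[which.max(asw)]  # which.max takes the first = smallest k on ties
  finish_assignment(ids, stats::cutree(tree, k = k_best), result_table)
}

finish_assignment <- function(ids, members, result_table,
                              multi = NULL) {
  df <- data.frame(ID = ids, cluster = as.integer(members),
                   stringsAsFactors = FALSE)
  df$is_representative <- FALSE
  for (cl in unique(df$cluster)) {
    in_cl <- df$ID[df$cluster == cl]
    df$is_representative[df$cluster == cl & df$ID == representative_of(in_cl, result_table)] <- TRUE
  }
  attr(df, "k") <- length(unique(df$cluster))
  class(df) <- c("cluster_assignment", "data.frame")
  df
}

# Lowest adjusted p wins; ties -> higher fold enrichment, then id.
representative_of <- function(ids, result_table) {
  if (is.null(result_table)) return(sort(ids)[1L])
  r <- as.data.frame(result_table)
  r <- r[match(ids, r$ID), , drop = FALSE]
  o <- order(r$lowest_p, -r$Fold_Enrichment, r$ID)
  r$ID[o[1L]]
}

#' Fuzzy clustering of pathways
#'
#' Heuristic multi-membership clustering in the style of functional
#' annotation clustering: (1) every pathway whose close-neighbor set
#' (other pathways with pairwise kappa at or above `kappa_threshold`) has
#' at least `min_neighbors` members seeds an initial group consisting of
#' itself and those neighbors; (2) any two groups sharing more than
#' `merge_overlap` of the smaller group's members are merged, repeatedly,
#' until no merge applies; (3) each pathway is a member of every final
#' group containing it, so multi-membership is possible. Pathways in no
#' group become singletons.
#'
#' @param kmat kappa matrix from [kappa_matrix()].
#' @param result_table the `enrichment_result` (for representative
#'   selection); may be `NULL`.
#' @param kappa_threshold close-neighbor kappa cutoff (default 0.35).
#' @param min_neighbors minimum close-neighbor count for seeding a group
#'   (default 3).
#' @param merge_overlap member-sharing fraction above which two groups
#'   merge (default 0.5).
#' @return A `fuzzy_cluster_assignment`: data.frame with columns `ID`,
#'   `cluster`, `is_representative`; a pathway in m clusters has m rows.
#' @export
fuzzy_cluster <- function(kmat, result_table = NULL, kappa_threshold = 0.35,
                          min_neighbors = 3L, merge_overlap = 0.5) {
  ids <- rownames(kmat)
  n <- length(ids)
  if (n < 2L) stop_input("nothing to cluster: need >= 2 pathways")
  groups <- list()
  for (i in seq_len(n)) {
    nb <- which(kmat[i, ] >= kappa_threshold)
    nb <- setdiff(nb, i)
    if (length(nb) >= min_neighbors)
      groups[[length(groups) + 1L]] <- sort(c(i, nb))
  }
  # iterative merging of groups sharing > merge_overlap of the smaller one
  repeat {
    merged <- FALSE
    for (i in seq_along(groups)) {
      if (merged) break
      for (j in seq_along(groups)) {
        if (j <= i) next
        shared <- length(intersect(groups[[i]], groups[[j]]))
        if (shared > merge_overlap * min(length(groups[[i]]),
                                         length(groups[[j]]))) {
          groups[[i]] <- sort(union(groups[[i]], groups[[j]]))
          groups[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  covered <- sort(unique(unlist(groups)))
  for (i in setdiff(seq_len(n), covered))
    groups[[length(groups) + 1L]] <- i
  rows <- do.call(rbind, lapply(seq_along(groups), function(g)
    data.frame(ID = ids[groups[[g]]], cluster = g,
               stringsAsFactors = FALSE)))
  rows$is_representative <- FALSE
  for (g in seq_along(groups)) {
    in_g <- ids[groups[[g]]]
    rep_id <- representative_of(in_g, result_table)
    rows$is_representative[rows$cluster == g & rows$ID == rep_id] <- TRUE
  }
  attr(rows, "k") <- length(groups)
  class(rows) <- c("fuzzy_cluster_assignment", "data.frame")
  rows
}

#' Cluster enriched pathways
#'
#' Wrapper that builds the kappa matrix and dispatches to
#' [hierarchical_cluster()] (default) or [fuzzy_cluster()].
#'
#' @param result_table an `enrichment_result` with at least 2 rows.
#' @param universe character vector of significant input genes.
#' @param method `"hierarchical"` or `"fuzzy"`.
#' @param ... passed to the chosen clustering function.
#' @return A cluster assignment data.frame (see the two methods).
#' @export
cluster_pathways <- function(result_table, universe,
                             method = c("hierarchical", "fuzzy"), ...) {
  method <- match.arg(method)
  kmat <- kappa_matrix(result_table, universe)
  if (method == "hierarchical") hierarchical_cluster(kmat, result_table, ...)
  else fuzzy_cluster(kmat, result_table, ...)
}
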