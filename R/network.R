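#' Construct a protein-protein interaction network
#'
#' An `interaction_network` is an undirected, simple graph over gene symbols:
#' self-loops are removed and duplicate edges (in either orientation)
#' collapse to one. Symbols are compared case-sensitively after trimming
#' surrounding whitespace; HGNC symbols are case-significant, so no automatic
#' upper-casing is performed.
#'
#' @param edges two-column character matrix or data.frame of endpoints, one
#'   interaction per row. Any relation/interaction-type column must already
#'   have been dropped.
#' @param nodes optional character vector of additional isolated nodes.
#' @return An object of class `interaction_network` with elements
#'   `nodes` (character vector, sorted), `edges` (two-column character matrix
#'   in canonical orientation, deduplicated) and `adj` (adjacency list of
#'   integer node indices, used by the search algorithms).
#' @examples
#' pin <- interaction_network(cbind(c("A", "B"), c("B", "C")))
#' pin$nodes
#' @export
interaction_network <- function(edges, nodes = character()) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(character(), ncol = 2L)
  }
  if (!is.character(edges)) storage.mode(edges) <- "character"
  if (ncol(edges) != 2L) stop_input("edges must have exactly two columns")
  a <- trimws(edges[, 1L]); b <- trimws(edges[, 2L])
  keep <- a != b            # drop self-interactions
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  dup <- duplicated(paste(lo, hi, sep = "\r"))
  lo <- lo[!dup]; hi <- hi[!dup]
  node_set <- sort(unique(c(lo, hi, trimws(nodes))))
  node_set <- node_set[node_set != ""]
  em <- cbind(lo, hi)
  dimnames(em) <- NULL
  net <- structure(
    list(nodes = node_set, edges = em, adj = NULL),
    class = "interaction_network"
  )
  net$adj <- build_adjacency(node_set, em)
  net
}

# Adjacency list of integer indices into `nodes`; isolated nodes get
# integer(0). The search hot loops run on this representation.
build_adjacency <- function(nodes, edges) {
  adj <- vector("list", length(nodes))
  for (i in seq_along(adj)) adj[[i]] <- integer()
  if (nrow(edges) > 0L) {
    ia <- match(edges[, 1L], nodes)
    ib <- match(edges[, 2L], nodes)
    sp_a <- split(ib, ia)
    sp_b <- split(ia, ib)
    for (k in names(sp_a)) {
      i <- as.integer(k)
      adj[[i]] <- c(adj[[i]], sp_a[[k]])
    }
    for (k in names(sp_b)) {
      i <- as.integer(k)
      adj[[i]] <- c(adj[[i]], sp_b[[k]])
    }
    adj <- lapply(adj, function(v) sort(unique(v)))
  }
  adj
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("interaction_network:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Number of nodes / edges of a network
#' @param pin an `interaction_network`.
#' @return Integer count.
#' @export
n_nodes <- function(pin) length(pin$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(pin) nrow(pin$edges)

#' Connected components of a node subset
#'
#' Partitions a set of "on" genes into maximal groups that are connected
#' within the subgraph of the network induced by those genes. This is the
#' decomposition step of the annealing and genetic searches, where a
#' candidate solution is an on/off assignment over all network nodes.
#'
#' @param pin an `interaction_network`.
#' @param on_genes character vector of gene symbols; must all be network
#'   nodes.
#' @return A list of character vectors (each sorted), ordered by decreasing
#'   size and then by lexicographically smallest member, so the output is a
#'   deterministic function of the input set.
#' @examples
#' pin <- interaction_network(cbind(c("A", "B"), c("B", "C")))
#' connected_components(pin, c("A", "C"))
#' @export
connected_components <- function(pin, on_genes) {
  stopifnot(inherits(pin, "interaction_network"))
  on_genes <- unique(on_genes)
  if (length(on_genes) == 0L) return(list())
  idx <- match(on_genes, pin$nodes)
  if (anyNA(idx)) stop_input("on_genes contains symbols not in the network: ",
                             paste(utils::head(on_genes[is.na(idx)], 3L), collapse = ", "))
  comp <- components_idx(pin$adj, idx)
  out <- lapply(comp, function(ii) sort(pin$nodes[ii]))
  order_components(out)
}

# BFS component labelling restricted to the node indices in `idx`.
# Returns a list of integer index vectors.
components_idx <- function(adj, idx) {
  n_on <- length(idx)
  if (n_on == 0L) return(list())
  in_on <- logical(length(adj))
  in_on[idx] <- TRUE
  seen <- logical(length(adj))
  comps <- vector("list", n_on)
  nc <- 0L
  for (s in idx) {
    if (seen[s]) next
    queue <- s
    seen[s] <- TRUE
    members <- integer()
    while (length(queue) > 0L) {
      v <- queue[[1L]]; queue <- queue[-1L]
      members <- c(members, v)
      nb <- adj[[v]]
      nb <- nb[in_on[nb] & !seen[nb]]
      if (length(nb) > 0L) {
        seen[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
    nc <- nc + 1L
    comps[[nc]] <- members
  }
  comps[seq_len(nc)]
}

order_components <- function(comps) {
  if (length(comps) <= 1L) return(comps)
  sizes <- lengths(comps)
  firsts <- vapply(comps, function(g) g[[1L]], character(1L))
  comps[order(-sizes, firsts)]
}

# Shortest-path (hop) distances from the node-index set `from` to every
# node, BFS over the full network. Unreachable nodes get Inf.
bfs_distances <- function(adj, from) {
  dist <- rep(Inf, length(adj))
  dist[from] <- 0
  frontier <- from
  d <- 0
  while (length(frontier) > 0L) {
    d <- d + 1
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[is.infinite(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}
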