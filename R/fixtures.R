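# Seedable synthetic-data generators: networks with a planted active
# module, DEG tables, gene set collections and expression matrices. These
# emulate the statistical structure the method assumes - a densely
# interconnected group of significantly altered genes inside a larger
# background network - so the whole pipeline is testable offline.

#' Specification of a synthetic fixture
#'
#' @param n_genes number of network nodes (default 300).
#' @param avg_degree target mean degree of the background random graph
#'   (default 4, i.e. `n_genes * avg_degree / 2` candidate edges).
#' @param module_size size m of the planted active module (default 15).
#' @param module_topology `"clique"` (default; the module genes are fully
#'   interconnected, the canonical planted-module structure) or `"tree"`
#'   (a random spanning tree, the minimal connected wiring).
#' @param module_p_range range of the planted genes' adjusted p values,
#'   drawn uniformly (default `c(1e-6, 1e-3)`); background genes draw
#'   p ~ Uniform(0, 1).
#' @param n_decoy_sets number of decoy gene sets (default 50).
#' @param set_size_range decoy set sizes, drawn uniformly (default 10-40).
#' @param target_filler extra non-module genes added to the target set
#'   (default 10), so the target strictly contains the module.
#' @param n_cases,n_controls sample group sizes for the expression matrix
#'   (default 10 + 10).
#' @param delta mean expression shift of module genes in cases
#'   (default 1).
#' @param noise_sd Gaussian noise standard deviation (default 1).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_genes = 300L, avg_degree = 4,
                         module_size = 15L,
                         module_topology = c("clique", "tree"),
                         module_p_range = c(1e-6, 1e-3),
                         n_decoy_sets = 50L, set_size_range = c(10L, 40L),
                         target_filler = 10L,
                         n_cases = 10L, n_controls = 10L,
                         delta = 1, noise_sd = 1) {
  module_topology <- match.arg(module_topology)
  if (module_size > n_genes) stop_input("module_size exceeds n_genes")
  if (module_p_range[1L] >= module_p_range[2L] || module_p_range[2L] > 1)
    stop_input("module_p_range must satisfy p_lo < p_hi <= 1")
  structure(list(n_genes = as.integer(n_genes), avg_degree = avg_degree,
                 module_size = as.integer(module_size),
                 module_topology = module_topology,
                 module_p_range = module_p_range,
                 n_decoy_sets = as.integer(n_decoy_sets),
                 set_size_range = as.integer(set_size_range),
                 target_filler = as.integer(target_filler),
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 delta = delta, noise_sd = noise_sd),
            class = "fixture_spec")
}

fixture_genes <- function(spec) sprintf("G%04d", seq_len(spec$n_genes))

#' Planted module genes of a fixture
#'
#' The module members are a deterministic function of `(spec, seed)`,
#' shared by all generators so that the network, DEG table, gene sets and
#' expression matrix agree on which genes are planted.
#'
#' @param spec a [fixture_spec()].
#' @param seed integer RNG seed.
#' @return Character vector of module gene symbols.
#' @export
planted_module <- function(spec, seed = 1L) {
  genes <- fixture_genes(spec)
  with_seed(derive_seed(seed, 1L), sort(sample(genes, spec$module_size)))
}

#' Generate a synthetic interaction network with a planted module
#'
#' Background: an Erdos-Renyi random graph with `n_genes * avg_degree / 2`
#' edges. Planted on top: the module genes are wired as a clique (default)
#' or a random spanning tree, so they always induce a connected subgraph.
#'
#' @param spec a [fixture_spec()].
#' @param seed integer RNG seed.
#' @return An [interaction_network()] over all `n_genes` fixture genes.
#' @export
generate_pin <- function(spec, seed = 1L) {
  genes <- fixture_genes(spec)
  module <- planted_module(spec, seed)
  with_seed(derive_seed(seed, 2L), {
    n <- spec$n_genes
    m_bg <- round(spec$avg_degree * n / 2)
    bg <- if (m_bg > 0) {
      a <- sample.int(n, m_bg, replace = TRUE)
      b <- sample.int(n, m_bg, replace = TRUE)
      cbind(genes[a], genes[b])
    } else matrix(character(), ncol = 2L)
    mod_edges <- if (spec$module_topology == "clique") {
      idx <- t(utils::combn(module, 2L))
      idx
    } else {
      perm <- sample(module)
      attach_to <- vapply(seq_along(perm)[-1L], function(i)
        perm[sample.int(i - 1L, 1L)], character(1L))
      cbind(perm[-1L], attach_to)
    }
    interaction_network(rbind(bg, mod_edges), nodes = genes)
  })
}

#' Generate a synthetic DEG table with a planted significant module
#'
#' Module genes draw adjusted p values from
#' `Uniform(module_p_range[1], module_p_range[2])` (well below the usual
#' 0.05 cutoff) with positive change values; background genes draw
#' p ~ Uniform(0, 1) with signed change values.
#'
#' @param spec a [fixture_spec()].
#' @param seed integer RNG seed.
#' @return A [deg_table()] over all fixture genes (change column present).
#' @export
generate_deg_table <- function(spec, seed = 1L) {
  genes <- fixture_genes(spec)
  module <- planted_module(spec, seed)
  with_seed(derive_seed(seed, 3L), {
    p <- stats::runif(length(genes))
    change <- stats::rnorm(length(genes))
    is_mod <- genes %in% module
    p[is_mod] <- stats::runif(sum(is_mod), spec$module_p_range[1L],
                              spec$module_p_range[2L])
    change[is_mod] <- abs(stats::rnorm(sum(is_mod), mean = 2, sd = 0.5))
    deg_table(genes, p, change)
  })
}

#' Generate a synthetic gene set collection with one target set
#'
#' Decoy sets are uniform samples of fixture genes with sizes drawn from
#' `set_size_range`; the target set (`"TARGET"`) is the planted module
#' plus `target_filler` random non-module genes.
#'
#' @param spec a [fixture_spec()].
#' @param seed integer RNG seed.
#' @return A `gene_set_collection` of `n_decoy_sets + 1` sets.
#' @export
generate_gene_sets <- function(spec, seed = 1L) {
  genes <- fixture_genes(spec)
  module <- planted_module(spec, seed)
  with_seed(derive_seed(seed, 4L), {
    sizes <- sample(spec$set_size_range[1L]:spec$set_size_range[2L],
                    spec$n_decoy_sets, replace = TRUE)
    sets <- lapply(sizes, function(s) sort(sample(genes, s)))
    names(sets) <- sprintf("PW%03d", seq_len(spec$n_decoy_sets))
    filler <- sample(setdiff(genes, module), spec$target_filler)
    sets$TARGET <- sort(c(module, filler))
    desc <- c(sprintf("decoy gene set %d", seq_len(spec$n_decoy_sets)),
              "target set containing the planted module")
    names(desc) <- names(sets)
    gene_set_collection(sets, desc)
  })
}

#' Generate a synthetic expression matrix
#'
#' Gaussian noise (`noise_sd`) for every gene in `n_cases + n_controls`
#' samples; planted module genes get a `+delta` mean shift in case
#' samples. Sample labels are `case_1..n` and `ctrl_1..n`; the group
#' labels are attached as attribute `"groups"`.
#'
#' @param spec a [fixture_spec()].
#' @param seed integer RNG seed.
#' @return Numeric gene x sample matrix.
#' @export
generate_expression_matrix <- function(spec, seed = 1L) {
  genes <- fixture_genes(spec)
  module <- planted_module(spec, seed)
  with_seed(derive_seed(seed, 5L), {
    n_s <- spec$n_cases + spec$n_controls
    em <- matrix(stats::rnorm(length(genes) * n_s, sd = spec$noise_sd),
                 nrow = length(genes))
    rownames(em) <- genes
    colnames(em) <- c(sprintf("case_%d", seq_len(spec$n_cases)),
                      sprintf("ctrl_%d", seq_len(spec$n_controls)))
    em[genes %in% module, seq_len(spec$n_cases)] <-
      em[genes %in% module, seq_len(spec$n_cases)] + spec$delta
    attr(em, "groups") <- c(rep("case", spec$n_cases),
                            rep("control", spec$n_controls))
    em
  })
}

#' Permute the gene labels of a DEG table
#'
#' The permutation null: p values and change values are kept, but the
#' gene symbols are replaced by a uniform random sample (without
#' replacement) from `universe`, severing the link between significance
#' and network position. Running the pipeline on such permuted inputs
#' should yield fewer enriched pathways than on the planted input.
#'
#' @param deg a [deg_table()].
#' @param universe character vector of candidate gene symbols (e.g. all
#'   network genes); must be at least as large as the table.
#' @param seed integer RNG seed.
#' @return A `deg_table` with permuted symbols.
#' @export
permute_gene_labels <- function(deg, universe, seed = 1L) {
  universe <- unique(universe)
  if (length(universe) < nrow(deg))
    stop_input("universe smaller than the DEG table")
  with_seed(seed, {
    deg$gene <- sample(universe, nrow(deg))
    deg
  })
}

#' Write a full fixture to a directory
#'
#' Generates the network, DEG table, gene sets and expression matrix for
#' `(spec, seed)` and writes them as `pin.sif`, `deg.tsv`,
#' `gene_sets.gmt` and `expression.tsv`.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if missing).
#' @param seed integer RNG seed.
#' @return Invisibly, a named character vector of the file paths.
#' @export
write_fixtures <- function(spec, dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(pin = file.path(dir, "pin.sif"),
             deg = file.path(dir, "deg.tsv"),
             gene_sets = file.path(dir, "gene_sets.gmt"),
             expression = file.path(dir, "expression.tsv"))
  write_sif(generate_pin(spec, seed), paths[["pin"]])
  write_deg_table(generate_deg_table(spec, seed), paths[["deg"]])
  write_gmt(generate_gene_sets(spec, seed), paths[["gene_sets"]])
  write_expression_matrix(generate_expression_matrix(spec, seed),
                          paths[["expression"]])
  invisible(paths)
}
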