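# Active subnetwork search: greedy seed expansion, simulated annealing,
# and a genetic algorithm, all optimizing the calibrated subnetwork score.

#' Search configuration
#'
#' Collects the tunable parameters of the three search algorithms.
#' Greedy: `search_depth` (candidate nodes must lie within this hop
#' distance of the current subnetwork; default 1), `max_depth` (maximum
#' hop distance of any member from the seed; default 1) and
#' `overlap_threshold` (default 0.5) for discarding subnetworks
#' overlapping a higher-scoring one. Simulated annealing: iteration count,
#' initial temperature, geometric cooling factor, and the probability that
#' a node starts in the "on" state. Genetic algorithm: population size,
#' generation count, per-bit mutation rate (0 by default: uniform
#' crossover plus periodic random replacement already explore the space),
#' the fraction of worst solutions periodically replaced at random (0.10
#' every 10 generations).
#'
#' @param algorithm `"greedy"`, `"sa"` or `"ga"`.
#' @param search_depth,max_depth,overlap_threshold greedy parameters.
#' @param sa_iters,sa_temp,sa_cooling,sa_init_prob annealing parameters.
#' @param ga_pop,ga_gens,ga_mutation,ga_replace_frac,ga_replace_period
#'   genetic-algorithm parameters.
#' @param fitness scalar fitness of a multi-component solution (annealing /
#'   genetic): `"max"` (calibrated score of the best component, default) or
#'   `"sum_positive"` (sum of positive component scores).
#' @param seed integer RNG seed; all three algorithms are reproducible for
#'   a fixed seed and input.
#' @return A `search_config` list.
#' @export
search_config <- function(algorithm = c("greedy", "sa", "ga"),
                          search_depth = 1L, max_depth = 1L,
                          overlap_threshold = 0.5,
                          sa_iters = 10000L, sa_temp = 1.0,
                          sa_cooling = 0.995, sa_init_prob = 0.1,
                          ga_pop = 400L, ga_gens = 200L, ga_mutation = 0,
                          ga_replace_frac = 0.10, ga_replace_period = 10L,
                          fitness = c("max", "sum_positive"),
                          seed = 1L) {
  algorithm <- match.arg(algorithm)
  fitness <- match.arg(fitness)
  if (overlap_threshold < 0 || overlap_threshold > 1)
    stop_input("overlap_threshold must be in [0, 1]")
  if (sa_cooling <= 0 || sa_cooling >= 1)
    stop_input("sa_cooling must be in (0, 1)")
  if (ga_mutation < 0 || ga_mutation > 1)
    stop_input("ga_mutation must be in [0, 1]")
  structure(list(algorithm = algorithm,
                 search_depth = as.integer(search_depth),
                 max_depth = as.integer(max_depth),
                 overlap_threshold = overlap_threshold,
                 sa_iters = as.integer(sa_iters), sa_temp = sa_temp,
                 sa_cooling = sa_cooling, sa_init_prob = sa_init_prob,
                 ga_pop = as.integer(ga_pop), ga_gens = as.integer(ga_gens),
                 ga_mutation = ga_mutation,
                 ga_replace_frac = ga_replace_frac,
                 ga_replace_period = as.integer(ga_replace_period),
                 fitness = fitness, seed = as.integer(seed)),
            class = "search_config")
}

# Build one scored subnetwork record.
make_subnetwork <- function(genes, zmap, calib, significant_genes,
                            seed_gene = NA_character_) {
  genes <- sort(genes)
  z_a <- subnetwork_raw_score(genes, zmap,
                              normalization = calib$normalization)
  structure(list(genes = genes,
                 seed = seed_gene,
                 z_a = z_a,
                 s_a = calibrated_score(z_a, length(genes), calib),
                 n_sig = sum(genes %in% significant_genes)),
            class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf("subnetwork: %d genes (%d significant), s_A = %.3f\n",
              length(x$genes), x$n_sig, x$s_a))
  invisible(x)
}

#' Summarize a list of subnetworks as a data.frame
#' @param subnetworks list of `subnetwork` objects.
#' @return data.frame with rank, calibrated and raw score, seed,
#'   significant-gene count, size and `";"`-joined genes.
#' @export
subnetworks_as_table <- function(subnetworks) {
  data.frame(
    rank = seq_along(subnetworks),
    score = vapply(subnetworks, `[[`, numeric(1L), "s_a"),
    raw_score = vapply(subnetworks, `[[`, numeric(1L), "z_a"),
    seed = vapply(subnetworks, `[[`, character(1L), "seed"),
    n_sig = vapply(subnetworks, `[[`, integer(1L), "n_sig"),
    size = lengths(lapply(subnetworks, `[[`, "genes")),
    genes = vapply(subnetworks, function(s) paste(s$genes, collapse = ";"),
                   character(1L)),
    stringsAsFactors = FALSE)
}

#' Discard subnetworks overlapping a higher-scoring one
#'
#' Processes subnetworks in descending calibrated score; a subnetwork is
#' kept iff its overlap with every already-kept subnetwork is at most
#' `threshold`. Overlap between gene sets A and B is
#' `|A intersect B| / min(|A|, |B|)` (the boundary itself is kept:
#' discarding requires overlap strictly greater than the threshold).
#'
#' @param subnetworks list of scored `subnetwork` objects.
#' @param threshold overlap threshold in `[0, 1]` (default 0.5).
#' @return The kept list, in descending score order.
#' @export
filter_overlapping <- function(subnetworks, threshold = 0.5) {
  if (length(subnetworks) == 0L) return(subnetworks)
  o <- order(-vapply(subnetworks, `[[`, numeric(1L), "s_a"),
             vapply(subnetworks, function(s) s$genes[[1L]], character(1L)))
  subnetworks <- subnetworks[o]
  kept <- list()
  for (s in subnetworks) {
    ok <- TRUE
    for (kpt in kept) {
      ov <- length(intersect(s$genes, kpt$genes)) /
        min(length(s$genes), length(kpt$genes))
      if (ov > threshold) { ok <- FALSE; break }
    }
    if (ok) kept[[length(kept) + 1L]] <- s
  }
  kept
}

#' Greedy seed-expansion search for active subnetworks
#'
#' Every significant gene is tried as a seed, in descending z-score order.
#' From a seed, the candidate set is every non-member node within
#' `search_depth` hops of the current subnetwork whose distance from the
#' seed is at most `max_depth`; at each step the candidate whose addition
#' maximizes the calibrated score is added iff it strictly increases the
#' score (ties among candidates broken alphabetically). With the defaults
#' (`search_depth = 1`, `max_depth = 1`) the reachable candidates are
#' exactly the seed's direct neighbors. The per-seed results are then
#' passed through [filter_overlapping()].
#'
#' @param pin an [interaction_network()].
#' @param zmap named z-score vector of the significant input genes.
#' @param significant_genes character vector of significant genes mapped to
#'   the network (the seeds).
#' @param config a [search_config()].
#' @param calib a [calibrate_background()] calibration.
#' @return List of `subnetwork` objects in descending score order.
#' @export
greedy_search <- function(pin, zmap, significant_genes, config, calib) {
  seeds <- intersect(significant_genes, pin$nodes)
  if (length(seeds) == 0L) stop_input("no seeds: no significant gene is in the network")
  seeds <- seeds[order(-zmap[seeds], seeds)]
  adj <- pin$adj
  nodes <- pin$nodes
  subs <- lapply(seeds, function(seed) {
    seed_idx <- match(seed, nodes)
    dist_seed <- bfs_distances(adj, seed_idx)
    current <- seed_idx
    cur_z <- sum_z(nodes[current], zmap)
    cur_s <- calibrated_score(norm_z(cur_z, length(current), calib),
                              length(current), calib)
    repeat {
      dist_cur <- bfs_distances(adj, current)
      cand <- which(dist_cur > 0 & dist_cur <= config$search_depth &
                      dist_seed <= config$max_depth)
      if (length(cand) == 0L) break
      k_new <- length(current) + 1L
      s_cand <- vapply(cand, function(ci) {
        calibrated_score(norm_z(cur_z + gene_z(nodes[ci], zmap), k_new, calib),
                         k_new, calib)
      }, numeric(1L))
      o <- order(-s_cand, nodes[cand])
      best <- o[[1L]]
      if (s_cand[best] <= cur_s) break
      cur_s <- s_cand[best]
      cur_z <- cur_z + gene_z(nodes[cand[best]], zmap)
      current <- c(current, cand[best])
    }
    make_subnetwork(nodes[current], zmap, calib, significant_genes,
                    seed_gene = seed)
  })
  filter_overlapping(subs, config$overlap_threshold)
}

gene_z <- function(gene, zmap) {
  z <- zmap[gene]
  if (is.na(z)) 0 else unname(z)
}

sum_z <- function(genes, zmap) {
  z <- zmap[genes]
  sum(z[!is.na(z)])
}

norm_z <- function(total, k, calib) {
  if (calib$normalization == "sqrt") total / sqrt(k) else total / k
}

#' Simulated annealing acceptance probability
#'
#' Probability of accepting a new solution: 1 when the score improves,
#' otherwise `exp((score_new - score_current) / temperature)`.
#'
#' @param score_new,score_current solution scores.
#' @param temperature current temperature, strictly positive.
#' @return Acceptance probability in `(0, 1]`.
#' @export
sa_acceptance <- function(score_new, score_current, temperature) {
  if (any(temperature <= 0)) stop_input("temperature must be > 0")
  delta <- score_new - score_current
  ifelse(delta > 0, 1, exp(delta / temperature))
}

# Scalar fitness of an on/off assignment: decompose the on-set into
# connected components and aggregate their calibrated scores.
solution_fitness <- function(on_idx, adj, nodes, zmap, calib, fitness) {
  if (length(on_idx) == 0L) return(-Inf)
  comps <- components_idx(adj, on_idx)
  scores <- vapply(comps, function(ii) {
    calibrated_score(norm_z(sum_z(nodes[ii], zmap), length(ii), calib),
                     length(ii), calib)
  }, numeric(1L))
  if (fitness == "max") max(scores) else sum(scores[scores > 0])
}

#' Simulated annealing search for active subnetworks
#'
#' A candidate solution assigns an on/off state to every network node;
#' nodes start "on" independently with probability `sa_init_prob`. Each
#' iteration toggles one uniformly random node, recomputes the connected
#' components of the on-set and the solution fitness (by default, the
#' calibrated score of the best component), and accepts the move with
#' probability [sa_acceptance()] under a geometrically cooled temperature
#' (`sa_temp * sa_cooling^t`). Returns the connected components of the
#' best-seen solution.
#'
#' @inheritParams greedy_search
#' @return List of `subnetwork` objects (all components of the best
#'   solution), in descending score order.
#' @export
simulated_annealing_search <- function(pin, zmap, significant_genes, config,
                                       calib) {
  nodes <- pin$nodes
  adj <- pin$adj
  n <- length(nodes)
  with_seed(config$seed, {
    state <- stats::runif(n) < config$sa_init_prob
    cur_fit <- solution_fitness(which(state), adj, nodes, zmap, calib,
                                config$fitness)
    best_state <- state
    best_fit <- cur_fit
    temp <- config$sa_temp
    for (it in seq_len(config$sa_iters)) {
      temp <- temp * config$sa_cooling
      flip <- sample.int(n, 1L)
      state[flip] <- !state[flip]
      new_fit <- solution_fitness(which(state), adj, nodes, zmap, calib,
                                  config$fitness)
      # equal fitness (including two empty solutions at -Inf) is a free move
      acc <- if (new_fit == cur_fit) 1 else sa_acceptance(new_fit, cur_fit, temp)
      if (stats::runif(1L) <= acc) {
        cur_fit <- new_fit
        if (new_fit > best_fit) {
          best_fit <- new_fit
          best_state <- state
        }
      } else {
        state[flip] <- !state[flip]  # reject: undo the toggle
      }
    }
    assignment_subnetworks(best_state, pin, zmap, calib, significant_genes)
  })
}

# All connected components of an on/off assignment, as scored subnetworks.
assignment_subnetworks <- function(state, pin, zmap, calib,
                                   significant_genes) {
  on_idx <- which(state)
  if (length(on_idx) == 0L) return(list())
  comps <- components_idx(pin$adj, on_idx)
  subs <- lapply(comps, function(ii)
    make_subnetwork(pin$nodes[ii], zmap, calib, significant_genes))
  subs[order(-vapply(subs, `[[`, numeric(1L), "s_a"),
             vapply(subs, function(s) s$genes[[1L]], character(1L)))]
}

#' Genetic algorithm search for active subnetworks
#'
#' Individuals are on/off bit vectors over the network nodes. Parents are
#' chosen by rank selection (selection probability proportional to fitness
#' rank) and recombined by uniform crossover (each bit from either parent
#' with probability 1/2); optional per-bit mutation at rate `ga_mutation`
#' (0 by default). The fittest solution of the previous population is
#' preserved whenever the new population's best score falls below it, and
#' every `ga_replace_period` generations the worst-scoring
#' `ga_replace_frac` of the population is replaced with random solutions.
#' Returns the components of the best individual; the best-fitness trace
#' across generations is attached as attribute `"trace"` (non-decreasing,
#' by elitism).
#'
#' @inheritParams greedy_search
#' @return List of `subnetwork` objects, in descending score order, with a
#'   numeric `"trace"` attribute of length `ga_gens`.
#' @export
genetic_search <- function(pin, zmap, significant_genes, config, calib) {
  nodes <- pin$nodes
  adj <- pin$adj
  n <- length(nodes)
  pop_size <- config$ga_pop
  if (pop_size < 2L) stop_input("ga_pop must be >= 2")
  fit_of <- function(bits) solution_fitness(which(bits), adj, nodes, zmap,
                                            calib, config$fitness)
  with_seed(config$seed, {
    pop <- matrix(stats::runif(pop_size * n) < config$sa_init_prob,
                  nrow = pop_size)
    fits <- apply(pop, 1L, fit_of)
    trace <- numeric(config$ga_gens)
    for (gen in seq_len(config$ga_gens)) {
      prev_best <- which.max(fits)
      prev_best_bits <- pop[prev_best, ]
      prev_best_fit <- fits[prev_best]
      # rank selection: selection probability proportional to fitness rank
      prob <- rank(fits, ties.method = "first")
      parents_a <- sample.int(pop_size, pop_size, replace = TRUE, prob = prob)
      parents_b <- sample.int(pop_size, pop_size, replace = TRUE, prob = prob)
      mask <- matrix(stats::runif(pop_size * n) < 0.5, nrow = pop_size)
      new_pop <- ifelse(mask, pop[parents_a, ], pop[parents_b, ])
      if (config$ga_mutation > 0) {
        flips <- matrix(stats::runif(pop_size * n) < config$ga_mutation,
                        nrow = pop_size)
        new_pop <- xor(new_pop, flips)
      }
      new_fits <- apply(new_pop, 1L, fit_of)
      if (max(new_fits) < prev_best_fit) {  # elitism
        worst <- which.min(new_fits)
        new_pop[worst, ] <- prev_best_bits
        new_fits[worst] <- prev_best_fit
      }
      if (gen %% config$ga_replace_period == 0L) {
        n_replace <- floor(config$ga_replace_frac * pop_size)
        if (n_replace > 0L) {
          worst <- order(new_fits)[seq_len(n_replace)]
          repl <- matrix(stats::runif(n_replace * n) < config$sa_init_prob,
                         nrow = n_replace)
          new_pop[worst, ] <- repl
          new_fits[worst] <- apply(repl, 1L, fit_of)
          if (max(new_fits) < prev_best_fit) {
            w2 <- which.min(new_fits)
            new_pop[w2, ] <- prev_best_bits
            new_fits[w2] <- prev_best_fit
          }
        }
      }
      pop <- new_pop
      fits <- new_fits
      trace[gen] <- max(fits)
    }
    best <- pop[which.max(fits), ]
    out <- assignment_subnetworks(best, pin, zmap, calib, significant_genes)
    attr(out, "trace") <- trace
    out
  })
}

#' Run the configured search algorithm
#'
#' Dispatches to [greedy_search()], [simulated_annealing_search()] or
#' [genetic_search()] according to `config$algorithm`.
#'
#' @inheritParams greedy_search
#' @return List of `subnetwork` objects.
#' @export
active_search <- function(pin, zmap, significant_genes, config, calib) {
  switch(config$algorithm,
         greedy = greedy_search(pin, zmap, significant_genes, config, calib),
         sa = simulated_annealing_search(pin, zmap, significant_genes,
                                         config, calib),
         ga = genetic_search(pin, zmap, significant_genes, config, calib))
}
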