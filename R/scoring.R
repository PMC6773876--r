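# Subnetwork scoring: gene-level z scores, size-normalized subnetwork
# scores, and Monte Carlo calibration against a random-gene background.

#' Convert an adjusted p value to a gene z score
#'
#' `z = qnorm(1 - p)`, the inverse standard normal CDF of the survival
#' probability, so smaller p values map to larger z. To keep z finite, p is
#' clamped to `[eps, 1 - eps]` before inversion.
#'
#' @param p numeric vector of p values in `[0, 1]`.
#' @param eps clamping floor (default `1e-15`).
#' @return Numeric vector of z scores, strictly decreasing in p.
#' @examples
#' p_to_z(0.5) # 0
#' @export
p_to_z <- function(p, eps = 1e-15) {
  assert_probability(p)
  p <- pmin(pmax(p, eps), 1 - eps)
  stats::qnorm(p, lower.tail = FALSE)
}

#' Raw score of a subnetwork
#'
#' Aggregates the member genes' z scores, normalized by subnetwork size k:
#' `z_A = sum(z_i) / sqrt(k)` (default), so that under a null of i.i.d.
#' standard normal gene scores, `z_A` is itself standard normal for any k.
#' Genes missing from `zmap` - non-input connector nodes - contribute
#' `z = 0`, so insignificant connectors dilute the score.
#'
#' @param genes non-empty character vector of member gene symbols.
#' @param zmap named numeric vector, gene symbol -> z score (typically
#'   [p_to_z()] of the significant input genes).
#' @param normalization `"sqrt"` (divide by `sqrt(k)`, default) or `"mean"`
#'   (divide by `k`).
#' @return The raw subnetwork score, a scalar.
#' @export
subnetwork_raw_score <- function(genes, zmap,
                                 normalization = c("sqrt", "mean")) {
  if (length(genes) == 0L) stop_input("empty subnetwork")
  normalization <- match.arg(normalization)
  z <- zmap[genes]
  z[is.na(z)] <- 0
  s <- sum(z)
  k <- length(genes)
  if (normalization == "sqrt") s / sqrt(k) else s / k
}

#' Monte Carlo calibration of subnetwork scores
#'
#' For each subnetwork size k, draws `draws` uniform random k-subsets of
#' the network's nodes (no connectivity requirement), scores each with
#' [subnetwork_raw_score()], and records the sample mean and standard
#' deviation. These background moments standardize raw scores via
#' [calibrated_score()].
#'
#' Draws are coupled across sizes by common random numbers: draw j's
#' size-k subset is the k-prefix of draw j's random node sequence. Each
#' size's background is still `draws` uniform random k-subsets, but the
#' moments vary smoothly in k, which keeps comparisons between a
#' subnetwork and its one-node extension from being dominated by
#' independent per-size sampling noise. The table is identical whether
#' sizes are computed eagerly or on demand.
#'
#' @param pin an [interaction_network()].
#' @param zmap named numeric z-score vector over the significant input
#'   genes (absent nodes count as 0).
#' @param k_max largest size to precompute, or `NULL` for a lazy table that
#'   computes and caches any requested size.
#' @param draws random subsets per size (default 2000).
#' @param seed integer RNG seed.
#' @param normalization passed to [subnetwork_raw_score()].
#' @return A `calibration` object; `as.data.frame()` yields columns
#'   `k`, `mu`, `sigma`, `draws` for the sizes computed so far.
#' @export
calibrate_background <- function(pin, zmap, k_max = NULL, draws = 2000L,
                                 seed = 1L,
                                 normalization = c("sqrt", "mean")) {
  stopifnot(inherits(pin, "interaction_network"))
  normalization <- match.arg(normalization)
  if (draws < 2L) stop_input("draws must be >= 2")
  n <- length(pin$nodes)
  if (!is.null(k_max) && k_max > n)
    stop_input("k_max exceeds the number of network nodes")
  zvec <- rep(0, n)
  hit <- match(names(zmap), pin$nodes)
  zvec[hit[!is.na(hit)]] <- zmap[!is.na(hit)]
  cal <- new.env(parent = emptyenv())  # size k -> c(mu, sigma) cache
  obj <- structure(list(env = cal, zvec = zvec, n = n,
                        draws = as.integer(draws), seed = as.integer(seed),
                        k_max = k_max, normalization = normalization),
                   class = "calibration")
  if (!is.null(k_max)) for (k in seq_len(k_max)) calibration_moments(obj, k)
  obj
}

# mean/sd of the background score at size k, computed lazily and cached.
#
# Common random numbers across sizes: draw j's size-k subset is the
# k-prefix of draw j's random node sequence (stable because R samples
# without replacement sequentially for a fixed seed). Each size is still
# scored on `draws` uniform random k-subsets, but adjacent sizes share
# their sampling noise, so score comparisons between a subnetwork and its
# one-node extension - the greedy expansion step - are not dominated by
# independent Monte Carlo jitter in mu_k and sigma_k.
calibration_moments <- function(calib, k) {
  key <- as.character(k)
  cached <- calib$env[[key]]
  if (!is.null(cached)) return(cached)
  if (k < 1L || k > calib$n)
    stop_input("subnetwork size ", k, " outside 1..", calib$n)
  if (!is.null(calib$k_max) && k > calib$k_max)
    stop_input("size ", k, " not in calibration table (k_max = ",
               calib$k_max, ")")
  scores <- with_seed(calib$seed, {
    vapply(seq_len(calib$draws), function(j) {
      set.seed(derive_seed(calib$seed, j))
      idx <- sample.int(calib$n, k)
      s <- sum(calib$zvec[idx])
      if (calib$normalization == "sqrt") s / sqrt(k) else s / k
    }, numeric(1L))
  })
  m <- c(mu = mean(scores), sigma = stats::sd(scores))
  assign(key, m, envir = calib$env)
  m
}

#' @export
as.data.frame.calibration <- function(x, ...) {
  ks <- sort(as.integer(ls(x$env)))
  ms <- t(vapply(as.character(ks), function(k) x$env[[k]], numeric(2L)))
  data.frame(k = ks, mu = unname(ms[, 1L]), sigma = unname(ms[, 2L]),
             draws = x$draws)
}

#' @export
print.calibration <- function(x, ...) {
  cat("calibration:", length(ls(x$env)), "sizes cached,",
      x$draws, "draws each (seed", x$seed, ")\n")
  invisible(x)
}

#' Calibrated subnetwork score
#'
#' Standardizes a raw score against the Monte Carlo background of its size:
#' `s_A = (z_A - mu_k) / sigma_k`. When the background is degenerate
#' (`sigma_k = 0`), the score is 0 if `z_A = mu_k` and otherwise a signed
#' large sentinel (`+/- 1e9`) so that ordering comparisons stay total.
#'
#' @param z_a raw subnetwork score ([subnetwork_raw_score()]).
#' @param k subnetwork size.
#' @param calib a `calibration` from [calibrate_background()].
#' @return The calibrated score, a scalar.
#' @export
calibrated_score <- function(z_a, k, calib) {
  stopifnot(inherits(calib, "calibration"))
  m <- calibration_moments(calib, k)
  if (m[["sigma"]] == 0) {
    d <- z_a - m[["mu"]]
    if (d == 0) 0 else sign(d) * 1e9
  } else {
    (z_a - m[["mu"]]) / m[["sigma"]]
  }
}

#' Dump a calibration table as TSV
#' @param calib a `calibration`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_calibration <- function(calib, path) {
  utils::write.table(as.data.frame(calib), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
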