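#' Resampling null distribution of |delta(SNP-index)|
#'
#' Simulates the "replacement test" null for an unlinked locus in an F2
#' population: each replicate draws two bulks of `bulk_size` F2 genotypes
#' (dosages 0/1/2 with probabilities 1/4, 1/2, 1/4, so the pooled HHZ-allele
#' count is `Binomial(2*bulk_size, 1/2)`), converts them to pool allele
#' frequencies, samples reads binomially at the given depths (with optional
#' per-read miscall probability) and returns `|delta(SNP-index)|`.
#'
#' When `n_snps > 1` the replicate mimics a sliding-window mean over that
#' many SNPs: the bulk draw is made once per replicate and shared across the
#' window's sites -- SNPs within a window are tightly linked, so the
#' bulk-composition component of their indices is common -- while read
#' sampling is independent per site. Averaging therefore shrinks only the
#' read-noise component, which is how the variability of an observed window
#' mean actually behaves.
#'
#' @param depth_t,depth_s read depth per site in the tolerant / sensitive
#'   pool (integers >= 1).
#' @param bulk_size plants per bulk.
#' @param n_reps replicates (default 1000, the study's "thousand
#'   replacement tests"). A warning is emitted when the 99.9% tail is
#'   requested downstream with fewer than 10,000 replicates.
#' @param n_snps sites averaged per replicate (default 1).
#' @param seq_error per-read miscall probability (default 0).
#' @param seed optional seed for reproducibility.
#' @return numeric vector of `n_reps` values of `|delta|`.
#' @export
#' @examples
#' q <- quantile(null_delta_distribution(57, 57, 50, 2000, seed = 1), 0.999)
null_delta_distribution <- function(depth_t, depth_s, bulk_size,
                                    n_reps = 1000, n_snps = 1,
                                    seq_error = 0, seed = NULL) {
  stopifnot(depth_t >= 1, depth_s >= 1, bulk_size >= 1, n_reps >= 1,
            n_snps >= 1)
  with_seed(seed, {
    two_n <- 2L * as.integer(bulk_size)
    f_t <- rbinom(n_reps, two_n, 0.5) / two_n
    f_s <- rbinom(n_reps, two_n, 0.5) / two_n
    e <- seq_error
    p_t <- f_t * (1 - e) + (1 - f_t) * e
    p_s <- f_s * (1 - e) + (1 - f_s) * e
    if (n_snps == 1L) {
      it <- rbinom(n_reps, depth_t, p_t) / depth_t
      is <- rbinom(n_reps, depth_s, p_s) / depth_s
    } else {
      it <- colMeans(matrix(rbinom(n_reps * n_snps, depth_t,
                                   rep(p_t, each = n_snps)) / depth_t,
                            nrow = n_snps))
      is <- colMeans(matrix(rbinom(n_reps * n_snps, depth_s,
                                   rep(p_s, each = n_snps)) / depth_s,
                            nrow = n_snps))
    }
    abs(it - is)
  })
}

#' Null configuration for threshold construction
#'
#' @param n_reps replicates per window class (default 1000).
#' @param conf_levels confidence levels for the threshold curve
#'   (default 0.95, 0.99, 0.999).
#' @param bulk_size plants per bulk (default 50).
#' @param seq_error per-read miscall probability fed to the null
#'   (default 0.001).
#' @param seed seed for the resampling.
#' @return object of class `null_config`.
#' @export
null_config <- function(n_reps = 1000, conf_levels = c(0.95, 0.99, 0.999),
                        bulk_size = 50, seq_error = 0.001, seed = 1) {
  if (n_reps < 100) stop_cfg("n_reps must be at least 100")
  if (any(conf_levels <= 0 | conf_levels >= 1))
    stop_cfg("conf_levels must lie in (0, 1)")
  structure(list(n_reps = as.integer(n_reps), conf_levels = conf_levels,
                 bulk_size = as.integer(bulk_size), seq_error = seq_error,
                 seed = seed), class = "null_config")
}

#' Window-level confidence thresholds for |delta(SNP-index)|
#'
#' For every usable window the null of [null_delta_distribution()] is
#' simulated at the window's median pool depths, averaged over its `n_snps`
#' sites exactly as the observed window statistic is, and the upper
#' quantiles at each confidence level become the window's thresholds.
#' Windows sharing (`n_snps`, median depths) share one simulation, so the
#' threshold curve is deterministic under `cfg$seed` and identical for
#' identically-shaped windows.
#'
#' @param windows window table from [sliding_windows()].
#' @param cfg a [null_config()].
#' @return `windows` with one `thr_<level>` column per confidence level
#'   (e.g. `thr_0.999`); unusable windows get `NA` thresholds.
#' @export
threshold_for_windows <- function(windows, cfg = null_config()) {
  stopifnot(inherits(cfg, "null_config"))
  if (cfg$n_reps < 10000 && any(cfg$conf_levels >= 0.999))
    warning("the 99.9% quantile of ", cfg$n_reps, " replicates is noisy; ",
            "consider n_reps >= 10000 for production thresholds",
            call. = FALSE)
  use <- which(windows$usable & !is.na(windows$mean_delta))
  key <- paste(windows$n_snps[use],
               round(windows$med_depth_t[use]),
               round(windows$med_depth_s[use]))
  uk <- sort(unique(key))
  key_seeds <- stage_seeds(cfg$seed, uk)
  thr <- matrix(NA_real_, nrow(windows), length(cfg$conf_levels))
  for (k in uk) {
    parts <- as.integer(strsplit(k, " ", fixed = TRUE)[[1]])
    d <- null_delta_distribution(max(parts[2], 1L), max(parts[3], 1L),
                                 cfg$bulk_size, cfg$n_reps,
                                 n_snps = parts[1],
                                 seq_error = cfg$seq_error,
                                 seed = key_seeds[[k]])
    q <- stats::quantile(d, cfg$conf_levels, names = FALSE)
    thr[use[key == k], ] <- matrix(q, sum(key == k), length(q), byrow = TRUE)
  }
  colnames(thr) <- paste0("thr_", cfg$conf_levels)
  out <- cbind(windows, as.data.frame(thr))
  attr(out, "scan_config") <- attr(windows, "scan_config")
  attr(out, "null_config") <- cfg
  out
}
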