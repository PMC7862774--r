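#' Fit a bulked-segregant QTL-seq genome scan
#'
#' One-call driver for the mapping analysis: filters variants to effective
#' parent-polymorphic SNPs ([filter_effective()]), computes per-site
#' SNP-indices and delta(SNP-index) ([snp_indices()]), smooths them in
#' sliding windows ([sliding_windows()]), builds resampling confidence
#' thresholds ([threshold_for_windows()]) and calls candidate regions
#' ([call_regions()]).
#'
#' @param variants a `bsa_variants` table ([read_bsa_vcf()] or
#'   [simulate_pool_reads()]).
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param bulk_size plants per bulk (default 50), used by the null.
#' @param window,step,min_snps scan geometry, see [sliding_windows()]
#'   (defaults 500 kb, 5 kb, 3).
#' @param n_reps,conf_levels null resampling settings, see [null_config()].
#' @param confidence screening level for region calling (default 0.999).
#' @param index_t_min,index_s_max pool-index criteria (defaults 0.7 / 0.3).
#' @param gap_max merge gap in bp (default `2 * step`).
#' @param criteria `"window"` or `"region"`, see [call_regions()].
#' @param seq_error per-read miscall probability assumed by the null
#'   (default 0.001).
#' @param filter a [filter_config()].
#' @param seed seed for the resampling null.
#' @return object of class `bsa_scan`: list with `sites`, `windows` (with
#'   thresholds), `regions`, `filter_report` and `params`. Has `print`,
#'   `summary` and `plot` methods.
#' @export
#' @examples
#' sim <- simulate_bsa_dataset(sim_config(n_f2 = 60, bulk_size = 12,
#'   chrom_lengths = c(chr1 = 3e6), snp_density = 30,
#'   qtl = data.frame(chrom = "chr1", pos = 1.5e6, a = 0.2, d = 0),
#'   resid_sd = 0.05, seed = 2))
#' fit <- bsa_scan(sim$variants, sim$config$chrom_lengths, bulk_size = 12,
#'                 n_reps = 200, seed = 9)
#' fit
bsa_scan <- function(variants, chrom_lengths, bulk_size = 50,
                     window = 5e5, step = 5e3, min_snps = 3,
                     n_reps = 1000, conf_levels = c(0.95, 0.99, 0.999),
                     confidence = 0.999, index_t_min = 0.7,
                     index_s_max = 0.3, gap_max = NULL,
                     criteria = "window", seq_error = 0.001,
                     filter = filter_config(), seed = 1) {
  filt <- filter_effective(variants, filter)
  sites <- snp_indices(filt)
  windows <- sliding_windows(sites, chrom_lengths, window = window,
                             step = step, min_snps = min_snps)
  ncfg <- null_config(n_reps = n_reps, conf_levels = conf_levels,
                      bulk_size = bulk_size, seq_error = seq_error,
                      seed = seed)
  windows <- threshold_for_windows(windows, ncfg)
  regions <- call_regions(windows, confidence = confidence,
                          index_t_min = index_t_min,
                          index_s_max = index_s_max,
                          gap_max = gap_max, criteria = criteria)
  structure(list(call = match.call(), sites = sites, windows = windows,
                 regions = regions, filter_report = filt$report,
                 params = list(chrom_lengths = chrom_lengths,
                               bulk_size = bulk_size, window = window,
                               step = step, min_snps = min_snps,
                               n_reps = n_reps, confidence = confidence,
                               index_t_min = index_t_min,
                               index_s_max = index_s_max,
                               criteria = criteria, seed = seed)),
            class = "bsa_scan")
}

#' @export
print.bsa_scan <- function(x, ...) {
  cat("Bulked-segregant QTL-seq scan\n")
  cat(sprintf("  %d effective SNPs on %d chromosome(s); %d/%d usable windows (%g kb / %g kb)\n",
              nrow(x$sites), length(unique(x$sites$chrom)),
              sum(x$windows$usable), nrow(x$windows),
              x$params$window / 1000, x$params$step / 1000))
  cat(sprintf("  screening: delta > %s%% threshold, index_T >= %s, index_S <= %s\n",
              100 * x$params$confidence,
              format(x$params$index_t_min), format(x$params$index_s_max)))
  if (nrow(x$regions)) {
    cat(sprintf("  %d candidate region(s):\n", nrow(x$regions)))
    for (i in seq_len(nrow(x$regions)))
      cat(sprintf("    %s:%s-%s  %.3f Mb, peak delta %.3f at %s\n",
                  x$regions$chrom[i],
                  format(x$regions$start[i], big.mark = ","),
                  format(x$regions$end[i], big.mark = ","),
                  x$regions$size_mb[i], x$regions$peak_delta[i],
                  format(x$regions$peak_pos[i], big.mark = ",")))
  } else cat("  no candidate regions\n")
  invisible(x)
}

#' @export
summary.bsa_scan <- function(object, ...) {
  w <- object$windows[object$windows$usable, ]
  out <- list(
    n_sites = nrow(object$sites),
    filter_report = object$filter_report,
    n_windows = nrow(object$windows), n_usable = nrow(w),
    delta_range = range(w$mean_delta),
    mean_index_t = mean(object$sites$index_t),
    mean_index_s = mean(object$sites$index_s),
    regions = object$regions)
  class(out) <- "summary.bsa_scan"
  out
}

#' @export
print.summary.bsa_scan <- function(x, ...) {
  cat(sprintf("Effective SNPs: %d (filter: %s)\n", x$n_sites,
              paste(names(x$filter_report), x$filter_report,
                    sep = "=", collapse = ", ")))
  cat(sprintf("Windows: %d usable of %d; window delta range %.3f to %.3f\n",
              x$n_usable, x$n_windows, x$delta_range[1], x$delta_range[2]))
  cat(sprintf("Genome-wide mean SNP-index: T %.3f, S %.3f\n",
              x$mean_index_t, x$mean_index_s))
  print(x$regions)
  invisible(x)
}

#' Plot a QTL-seq scan
#'
#' Per-chromosome panels of the window mean delta(SNP-index) (or either
#' pool's window index) against position, with the confidence threshold and
#' called regions shaded.
#'
#' @param x a `bsa_scan` object.
#' @param statistic `"delta"` (default), `"index_t"` or `"index_s"`.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.bsa_scan <- function(x, statistic = c("delta", "index_t", "index_s"),
                          ...) {
  statistic <- match.arg(statistic)
  col <- switch(statistic, delta = "mean_delta", index_t = "mean_index_t",
                index_s = "mean_index_s")
  thr_col <- paste0("thr_", x$params$confidence)
  chroms <- unique(x$windows$chrom)
  old <- par(mfrow = c(length(chroms), 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(par(old))
  for (chrom in chroms) {
    w <- x$windows[x$windows$chrom == chrom & x$windows$usable, ]
    mid <- (w$start + w$end) / 2 / 1e6
    ylim <- if (statistic == "delta") c(-1, 1) else c(0, 1)
    plot(mid, w[[col]], type = "l", ylim = ylim, xlab = "", col = "steelblue",
         ylab = switch(statistic, delta = expression(Delta * "(SNP-index)"),
                       "SNP-index"),
         main = chrom, ...)
    if (statistic == "delta") {
      lines(mid, w[[thr_col]], col = "black", lty = 2)
      abline(h = 0, col = "grey70")
    } else abline(h = 0.5, col = "grey70")
    r <- x$regions[x$regions$chrom == chrom, ]
    if (nrow(r))
      rect(r$start / 1e6, ylim[1], r$end / 1e6, ylim[2],
           col = adjustcolor("firebrick", 0.15), border = NA)
  }
  invisible(x)
}
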