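#' SNP-index of one pool at one site
#'
#' The SNP-index is the fraction of a pool's reads that carry the allele of
#' the designated (tolerant, HHZ) parent: `n_hhz / depth`. It estimates the
#' pool's HHZ-allele frequency; 0.5 is expected at loci unlinked to the
#' trait, values near 1 (T-pool) or 0 (S-pool) indicate linkage.
#'
#' @param n_hhz reads supporting the HHZ allele (vectorised).
#' @param depth total reads at the site.
#' @return `n_hhz / depth`; `NA` where depth is 0.
#' @export
#' @examples
#' snp_index(7, 10)  # 0.7
snp_index <- function(n_hhz, depth) {
  if (any(n_hhz > depth, na.rm = TRUE) || any(n_hhz < 0, na.rm = TRUE))
    stop_cfg("need 0 <= n_hhz <= depth")
  ifelse(depth > 0, n_hhz / depth, NA_real_)
}

#' delta(SNP-index): tolerant-pool minus sensitive-pool index
#'
#' @param index_t,index_s pool SNP-indices in `[0, 1]`.
#' @return difference in `[-1, 1]`.
#' @export
#' @examples
#' delta_index(0.7, 0.3)  # 0.4
delta_index <- function(index_t, index_s) {
  if (any(index_t < 0 | index_t > 1 | index_s < 0 | index_s > 1, na.rm = TRUE))
    stop_cfg("indices must lie in [0, 1]")
  index_t - index_s
}

#' Per-site SNP-index table from filtered variants
#'
#' @param filtered result of [filter_effective()] (or its `variants`
#'   element).
#' @return data frame `chrom`, `pos`, `index_t`, `index_s`, `delta`,
#'   `depth_t`, `depth_s`, sorted by (chrom, pos); zero-depth sites (which
#'   the filter normally removes) are dropped defensively.
#' @export
snp_indices <- function(filtered) {
  v <- if (is.data.frame(filtered)) filtered else filtered$variants
  out <- data.frame(chrom = v$chrom, pos = v$pos,
                    index_t = snp_index(v$n_hhz_t, v$depth_t),
                    index_s = snp_index(v$n_hhz_s, v$depth_s),
                    depth_t = v$depth_t, depth_s = v$depth_s)
  out$delta <- delta_index(out$index_t, out$index_s)
  out <- out[!is.na(out$delta), ]
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  out[c("chrom", "pos", "index_t", "index_s", "delta", "depth_t", "depth_s")]
}

#' Sliding-window means of the SNP-index statistics
#'
#' Windows of width `window` are anchored at position 1 on each chromosome
#' and advanced by `step`; terminal windows are truncated at the chromosome
#' end and retained with their true span. Every SNP contributes to every
#' window covering it; window values are plain arithmetic means over the
#' contained SNPs. Windows holding fewer than `min_snps` SNPs are flagged
#' unusable (`usable = FALSE`) rather than interpolated, and are excluded
#' from region calling.
#'
#' @param sites per-site table from [snp_indices()], sorted by (chrom, pos).
#' @param chrom_lengths named vector of chromosome lengths (bp); every
#'   chromosome present in `sites` must be named here.
#' @param window window width in bp (default 500,000).
#' @param step increment in bp (default 5,000).
#' @param min_snps minimum SNPs for a usable window (default 3).
#' @return data frame `chrom`, `start`, `end`, `n_snps`, `mean_index_t`,
#'   `mean_index_s`, `mean_delta`, `med_depth_t`, `med_depth_s`, `usable`.
#' @export
sliding_windows <- function(sites, chrom_lengths, window = 5e5, step = 5e3,
                            min_snps = 3) {
  if (step <= 0 || window <= 0 || step > window)
    stop_cfg("need 0 < step <= window")
  unknown <- setdiff(unique(sites$chrom), names(chrom_lengths))
  if (length(unknown))
    stop_cfg("chromosome(s) absent from chrom_lengths: ",
             paste(unknown, collapse = ", "))
  pieces <- lapply(names(chrom_lengths), function(chrom) {
    len <- chrom_lengths[[chrom]]
    s <- sites[sites$chrom == chrom, , drop = FALSE]
    starts <- seq.int(1, len, by = step)
    ends <- pmin(starts + window - 1, len)
    n_win <- length(starts)
    pos <- s$pos
    i1 <- findInterval(starts - 1, pos) + 1L
    i2 <- findInterval(ends, pos)
    n_snps <- pmax(i2 - i1 + 1L, 0L)
    mt <- ms <- md <- dt <- ds <- rep(NA_real_, n_win)
    for (w in which(n_snps > 0L)) {
      idx <- i1[w]:i2[w]
      mt[w] <- mean(s$index_t[idx])
      ms[w] <- mean(s$index_s[idx])
      md[w] <- mean(s$delta[idx])
      dt[w] <- stats::median(s$depth_t[idx])
      ds[w] <- stats::median(s$depth_s[idx])
    }
    data.frame(chrom = chrom, start = starts, end = ends, n_snps = n_snps,
               mean_index_t = mt, mean_index_s = ms, mean_delta = md,
               med_depth_t = dt, med_depth_s = ds,
               usable = n_snps >= min_snps)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "scan_config") <- list(window = window, step = step,
                                   min_snps = min_snps,
                                   chrom_lengths = chrom_lengths)
  out
}
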