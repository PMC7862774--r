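#' Construct a candidate QTL region
#'
#' A candidate region is a 1-based inclusive interval; its size in Mb is the
#' endpoint difference `(end - start) / 1e6`, the convention under which the
#' mapped interval 3,555,000--4,520,000 bp has size 0.965 Mb.
#'
#' @param chrom chromosome name.
#' @param start,end interval endpoints in bp, `start < end`.
#' @param ... further fields (e.g. `peak_delta`) stored on the region row.
#' @return one-row data frame of class `candidate_regions`.
#' @export
#' @examples
#' candidate_region("chr08", 3555000, 4520000)$size_mb  # 0.965
candidate_region <- function(chrom, start, end, ...) {
  if (any(start >= end)) stop_cfg("need start < end")
  out <- data.frame(chrom = chrom, start = start, end = end,
                    size_mb = (end - start) / 1e6, ...)
  class(out) <- c("candidate_regions", "data.frame")
  out
}

#' Call candidate QTL regions from thresholded windows
#'
#' A window is significant when its mean delta(SNP-index) exceeds its
#' confidence threshold and, with the default window-level criteria, its
#' mean T-pool index is at least `index_t_min` (0.7) and its mean S-pool
#' index at most `index_s_max` (0.3). Overlapping or near-adjacent
#' significant windows (gap at most `gap_max`) are merged into regions; with
#' `criteria = "region"` the pool-index bounds are instead applied to each
#' merged region's mean indices, mirroring the study's statement of the
#' criteria for the mapped region as a whole.
#'
#' @param windows thresholded window table from [threshold_for_windows()].
#' @param confidence which confidence level's threshold to screen with
#'   (default 0.999, i.e. column `thr_0.999`).
#' @param index_t_min,index_s_max pool-index criteria; set to `NULL` to
#'   disable either bound.
#' @param gap_max largest merged gap in bp between significant windows;
#'   `NULL` (default) means twice the scan step.
#' @param criteria apply the pool-index bounds per `"window"` (default) or
#'   per `"region"`.
#' @return `candidate_regions` data frame: `chrom`, `start`, `end`,
#'   `size_mb`, `peak_delta`, `peak_pos`, `mean_index_t`, `mean_index_s`,
#'   `n_windows`; zero rows when nothing is significant.
#' @export
call_regions <- function(windows, confidence = 0.999,
                         index_t_min = 0.7, index_s_max = 0.3,
                         gap_max = NULL, criteria = c("window", "region")) {
  criteria <- match.arg(criteria)
  col <- paste0("thr_", confidence)
  if (!col %in% names(windows))
    stop_cfg("windows carry no threshold at confidence ", confidence,
             "; run threshold_for_windows() with this level")
  sc <- attr(windows, "scan_config")
  if (is.null(gap_max))
    gap_max <- if (!is.null(sc)) 2 * sc$step else 1e4
  sig <- windows$usable & !is.na(windows$mean_delta) &
    !is.na(windows[[col]]) & windows$mean_delta > windows[[col]]
  if (criteria == "window") {
    if (!is.null(index_t_min)) sig <- sig & windows$mean_index_t >= index_t_min
    if (!is.null(index_s_max)) sig <- sig & windows$mean_index_s <= index_s_max
  }
  empty <- candidate_region("z", 0, 1)[0, ]
  if (!any(sig)) return(empty)
  w <- windows[sig, , drop = FALSE]
  regions <- list()
  for (chrom in unique(w$chrom)) {
    wc <- w[w$chrom == chrom, , drop = FALSE]
    wc <- wc[order(wc$start), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(wc$start[-1] > head(cummax(wc$end), -1) + 1 + gap_max)))
    for (g in unique(grp)) {
      wg <- wc[grp == g, , drop = FALSE]
      pk <- which.max(wg$mean_delta)
      regions[[length(regions) + 1L]] <- candidate_region(
        chrom, min(wg$start), max(wg$end),
        peak_delta = wg$mean_delta[pk],
        peak_pos = (wg$start[pk] + wg$end[pk]) / 2,
        mean_index_t = mean(wg$mean_index_t),
        mean_index_s = mean(wg$mean_index_s),
        n_windows = nrow(wg))
    }
  }
  out <- do.call(rbind, regions)
  if (criteria == "region") {
    keep <- rep(TRUE, nrow(out))
    if (!is.null(index_t_min)) keep <- keep & out$mean_index_t >= index_t_min
    if (!is.null(index_s_max)) keep <- keep & out$mean_index_s <= index_s_max
    out <- out[keep, , drop = FALSE]
  }
  if (!nrow(out)) return(empty)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  class(out) <- c("candidate_regions", "data.frame")
  out
}

#' Export candidate regions as BED (0-based half-open)
#'
#' @param regions a `candidate_regions` data frame.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom,
                    start = as.integer(regions$start - 1),
                    end = as.integer(regions$end),
                    name = sprintf("region_%d", seq_len(nrow(regions))))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Import a BED file of regions (back to 1-based inclusive)
#'
#' @param path BED path.
#' @return `candidate_regions` data frame.
#' @export
read_regions_bed <- function(path) {
  bed <- utils::read.delim(path, header = FALSE)
  candidate_region(chrom = as.character(bed[[1]]), start = bed[[2]] + 1,
                   end = bed[[3]])
}
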