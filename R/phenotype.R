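#' Spikelet fertility from grain counts
#'
#' Fertility is the percentage of filled spikelets, counting both fully and
#' partially filled grains as filled:
#' `(N_FG + N_PG) / (N_FG + N_PG + N_EG) * 100`.
#' Plants with zero grains scored are unscorable and return `NA` with a
#' warning.
#'
#' @param n_fg fully filled grain counts, or a data frame with columns
#'   `N_FG`, `N_PG`, `N_EG`.
#' @param n_pg partially filled grain counts.
#' @param n_eg empty grain counts.
#' @return fertility percent in `[0, 100]`, vectorised; `NA` where all three
#'   counts are zero.
#' @export
#' @examples
#' spikelet_fertility(120, 30, 50)  # 75
spikelet_fertility <- function(n_fg, n_pg = NULL, n_eg = NULL) {
  if (is.data.frame(n_fg)) {
    df <- n_fg
    n_fg <- df$N_FG; n_pg <- df$N_PG; n_eg <- df$N_EG
  }
  if (any(c(n_fg, n_pg, n_eg) < 0, na.rm = TRUE))
    stop_cfg("grain counts must be non-negative")
  total <- n_fg + n_pg + n_eg
  out <- ifelse(total > 0, (n_fg + n_pg) / total * 100, NA_real_)
  if (anyNA(out))
    warning(sum(is.na(out)), " plant(s) with zero grains scored as missing",
            call. = FALSE)
  out
}

#' Coefficient of variation from two moments
#'
#' `100 * sd / mean`, the consistency check used to compare a mean/SD pair
#' (on the proportion scale) against a reported CV.
#'
#' @param mean,sd mean and standard deviation on a common scale; `mean` must
#'   be positive.
#' @return CV in percent.
#' @export
#' @examples
#' cv_from_moments(0.5, 0.1847)  # 36.94
cv_from_moments <- function(mean, sd) {
  if (any(mean <= 0)) stop_cfg("cv is undefined for non-positive means")
  100 * sd / mean
}

#' Summary statistics of a fertility distribution
#'
#' Sample statistics (SD with the n-1 denominator) of spikelet fertility
#' values. The CV is scale-invariant; the `scale` flag only records whether
#' the inputs were proportions or percents, to keep reported moments
#' unambiguous.
#'
#' @param fertility numeric vector (proportions or percents); `NA`s dropped.
#' @param scale `"proportion"` or `"percent"`.
#' @return object of class `fertility_stats`: `n`, `mean`, `sd`,
#'   `cv_percent`, `min`, `max`, `scale`.
#' @export
#' @examples
#' summarize_fertility(c(0.2, 0.4, 0.6))
summarize_fertility <- function(fertility, scale = c("proportion", "percent")) {
  scale <- match.arg(scale)
  x <- fertility[!is.na(fertility)]
  if (length(x) < 2) stop_cfg("need at least 2 non-missing fertility values")
  structure(list(n = length(x), mean = mean(x), sd = stats::sd(x),
                 cv_percent = cv_from_moments(mean(x), stats::sd(x)),
                 min = min(x), max = max(x), scale = scale),
            class = "fertility_stats")
}

#' @export
print.fertility_stats <- function(x, ...) {
  cat(sprintf("Spikelet fertility (%s scale), n = %d\n", x$scale, x$n))
  cat(sprintf("  mean %.4f, sd %.4f, CV %.2f%%, range %.4f-%.4f\n",
              x$mean, x$sd, x$cv_percent, x$min, x$max))
  invisible(x)
}

#' Select the extreme heat-tolerant and heat-sensitive bulks
#'
#' Ranks plants by fertility and takes the lowest `bulk_size` as the
#' sensitive bulk and the highest `bulk_size` as the tolerant bulk. Ties at
#' a cutoff are broken deterministically by plant id (ascending).
#'
#' @param fertility named numeric vector (names are plant ids); `NA`s are
#'   unscorable and excluded.
#' @param bulk_size plants per bulk (default 50).
#' @return object of class `bulk_design`: `bulk_size`, `tolerant_ids`,
#'   `sensitive_ids` and the fertility `range` of each bulk.
#' @export
#' @examples
#' f <- stats::setNames(1:10, paste0("P", 1:10))
#' select_bulks(f, 2)$tolerant_ids
select_bulks <- function(fertility, bulk_size = 50) {
  if (is.null(names(fertility)) || any(!nzchar(names(fertility))))
    stop_cfg("fertility must be named by plant id")
  f <- fertility[!is.na(fertility)]
  if (length(f) < 2 * bulk_size)
    stop_cfg("need at least 2*bulk_size (", 2 * bulk_size,
             ") scorable plants, have ", length(f))
  ord <- order(f, names(f))
  sens <- names(f)[ord[seq_len(bulk_size)]]
  tol <- names(f)[ord[seq.int(length(f) - bulk_size + 1L, length(f))]]
  rng <- function(ids) range(f[ids])
  if (max(f[sens]) >= min(f[tol]))
    warning("bulk fertility ranges touch: phenotype does not separate the tails",
            call. = FALSE)
  structure(list(bulk_size = as.integer(bulk_size),
                 tolerant_ids = tol, sensitive_ids = sens,
                 range = list(tolerant = rng(tol), sensitive = rng(sens))),
            class = "bulk_design")
}

#' @export
print.bulk_design <- function(x, ...) {
  cat(sprintf("Bulk design: %d plants per bulk\n", x$bulk_size))
  cat(sprintf("  tolerant  range %.2f-%.2f\n", x$range$tolerant[1], x$range$tolerant[2]))
  cat(sprintf("  sensitive range %.2f-%.2f\n", x$range$sensitive[1], x$range$sensitive[2]))
  invisible(x)
}
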