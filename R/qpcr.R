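#' Relative expression by the 2^-ddCt method
#'
#' `dCt = Ct_target - Ct_reference` within each condition;
#' `ddCt = dCt_condition - dCt_calibrator`; the relative expression (fold
#' change) is `2^-ddCt`. A plate-wide constant added to every Ct cancels,
#' and the calibrator condition measured against itself gives exactly 1.
#'
#' @param target_ct,ref_ct threshold cycles of the target and reference
#'   gene in the condition of interest (vectorised).
#' @param calibrator_target_ct,calibrator_ref_ct the same for the
#'   calibrator condition.
#' @return fold change `2^-ddCt` (positive).
#' @export
#' @examples
#' ddct(24, 20, 25, 20)  # one cycle lower dCt than calibrator: 2
ddct <- function(target_ct, ref_ct, calibrator_target_ct, calibrator_ref_ct) {
  cts <- c(target_ct, ref_ct, calibrator_target_ct, calibrator_ref_ct)
  if (anyNA(cts) || any(!is.finite(cts)))
    stop_cfg("all Ct values must be finite (missing reference Ct?)")
  2^-((target_ct - ref_ct) - (calibrator_target_ct - calibrator_ref_ct))
}

#' Read a long-format qPCR Ct table
#'
#' @param path TSV with columns `sample`, `gene`, `timepoint`, `replicate`,
#'   `ct`.
#' @return validated data frame.
#' @export
read_ct_table <- function(path) {
  ct <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "gene", "timepoint", "replicate", "ct")
  if (!all(need %in% names(ct)))
    stop_cfg("Ct table needs columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(ct$ct) | ct$ct <= 0))
    stop_cfg("Ct values must be positive and finite")
  ct
}

#' Per-replicate relative expression against a reference gene
#'
#' For each (sample, gene, timepoint), replicate-matched
#' `dCt = Ct_target - Ct_reference` is formed, the calibrator condition's
#' mean dCt is subtracted, and `2^-ddCt` is returned per replicate (the
#' replicate spread feeds the genotype comparison). The calibrator defaults
#' to the stated sample at the first timepoint.
#'
#' @param ct long Ct table (see [read_ct_table()]).
#' @param reference reference (internal-control) gene, default `"UBQ"`.
#' @param calibrator_sample,calibrator_timepoint calibrator condition; the
#'   timepoint defaults to the first timepoint in the table.
#' @return data frame `sample`, `gene`, `timepoint`, `replicate`, `fold`;
#'   attribute `summary` holds per-condition mean fold, SD and n.
#' @export
relative_expression <- function(ct, reference = "UBQ",
                                calibrator_sample = NULL,
                                calibrator_timepoint = NULL) {
  if (!reference %in% ct$gene)
    stop_cfg("reference gene '", reference, "' absent from the Ct table")
  if (is.null(calibrator_sample)) calibrator_sample <- ct$sample[1]
  if (is.null(calibrator_timepoint)) calibrator_timepoint <- ct$timepoint[1]
  ref <- ct[ct$gene == reference, ]
  tgt <- ct[ct$gene != reference, ]
  if (!nrow(tgt)) stop_cfg("no target genes in the Ct table")
  key <- function(d) paste(d$sample, d$timepoint, d$replicate)
  m <- match(key(tgt), key(ref))
  if (anyNA(m))
    stop_cfg("missing reference-gene Ct for ",
             paste(unique(key(tgt)[is.na(m)]), collapse = "; "))
  tgt$dct <- tgt$ct - ref$ct[m]
  out <- do.call(rbind, lapply(split(tgt, tgt$gene), function(d) {
    cal <- d$dct[d$sample == calibrator_sample &
                   d$timepoint == calibrator_timepoint]
    if (!length(cal))
      stop_cfg("calibrator condition (", calibrator_sample, ", ",
               calibrator_timepoint, ") missing for gene ", d$gene[1])
    data.frame(sample = d$sample, gene = d$gene, timepoint = d$timepoint,
               replicate = d$replicate, fold = 2^-(d$dct - mean(cal)))
  }))
  rownames(out) <- NULL
  agg <- stats::aggregate(fold ~ sample + gene + timepoint, out,
                          function(x) c(mean = mean(x), sd = stats::sd(x),
                                        n = length(x)))
  attr(out, "summary") <- do.call(data.frame, agg)
  out
}

#' Compare relative expression between two genotypes
#'
#' Two-sided two-sample Student's t-test (equal variances by default, Welch
#' optional) on replicate fold changes, with the conventional significance
#' stars: `*` for p < 0.05, `**` for p < 0.01.
#'
#' @param expr_a,expr_b numeric vectors of replicate fold changes (at least
#'   2 each).
#' @param var_equal equal-variance t-test (default `TRUE`).
#' @return list with `p_value`, `stars`, `t`, `df`, `estimate` (group
#'   means).
#' @export
#' @examples
#' compare_genotypes(c(2.0, 2.1, 1.9), c(1.0, 1.1, 0.9))$stars  # "**"
compare_genotypes <- function(expr_a, expr_b, var_equal = TRUE) {
  if (length(expr_a) < 2 || length(expr_b) < 2)
    stop_cfg("need at least 2 replicates per genotype; p undefined otherwise")
  ht <- tryCatch(stats::t.test(expr_a, expr_b, var.equal = var_equal),
                 error = function(e) NULL)
  if (is.null(ht)) {
    # both groups constant: no within-group spread to test against
    p <- if (isTRUE(all.equal(mean(expr_a), mean(expr_b)))) 1 else NA_real_
    return(list(p_value = p, stars = "", t = NA_real_, df = NA_real_,
                estimate = c(mean(expr_a), mean(expr_b))))
  }
  p <- ht$p.value
  list(p_value = p,
       stars = if (is.nan(p)) "" else if (p < 0.01) "**" else
         if (p < 0.05) "*" else "",
       t = unname(ht$statistic), df = unname(ht$parameter),
       estimate = unname(ht$estimate))
}

#' Genotype comparison across a relative-expression table
#'
#' Runs [compare_genotypes()] for every (gene, timepoint) present for both
#' genotypes.
#'
#' @param rel output of [relative_expression()].
#' @param sample_a,sample_b the two genotype labels.
#' @param var_equal equal-variance t-test (default `TRUE`).
#' @return data frame `gene`, `timepoint`, `fold_a`, `fold_b`, `p_value`,
#'   `stars`.
#' @export
compare_expression <- function(rel, sample_a, sample_b, var_equal = TRUE) {
  combos <- unique(rel[c("gene", "timepoint")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    a <- rel$fold[rel$gene == combos$gene[i] &
                    rel$timepoint == combos$timepoint[i] &
                    rel$sample == sample_a]
    b <- rel$fold[rel$gene == combos$gene[i] &
                    rel$timepoint == combos$timepoint[i] &
                    rel$sample == sample_b]
    if (length(a) < 2 || length(b) < 2) return(NULL)
    cmp <- compare_genotypes(a, b, var_equal)
    data.frame(gene = combos$gene[i], timepoint = combos$timepoint[i],
               fold_a = mean(a), fold_b = mean(b),
               p_value = cmp$p_value, stars = cmp$stars)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
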