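#' Rice chromosome lengths used as the simulator's default genome
#'
#' Approximate assembly lengths (bp) of the 12 rice (*Oryza sativa*)
#' chromosomes, 23--45 Mb each.
#'
#' @return named numeric vector of lengths in bp.
#' @export
#' @examples
#' rice_chrom_lengths()[["chr08"]]
rice_chrom_lengths <- function() {
  c(chr01 = 43.3e6, chr02 = 35.9e6, chr03 = 36.4e6, chr04 = 35.5e6,
    chr05 = 30.0e6, chr06 = 31.2e6, chr07 = 29.7e6, chr08 = 28.4e6,
    chr09 = 23.0e6, chr10 = 23.2e6, chr11 = 29.0e6, chr12 = 27.5e6)
}

#' Configuration for the F2 bulked-segregant simulator
#'
#' Bundles and validates every knob of the synthetic-data generator. Defaults
#' reproduce the statistical structure of the mapping study the package
#' implements: 365 F2 plants phenotyped as F2:3 family means, extreme bulks of
#' 50 plants each, one major spikelet-fertility QTL on chromosome 8 near
#' 4.0 Mb whose additive effect matches the parental difference
#' (54.5% vs 14.3% fertility, so `a = (0.545 - 0.143)/2`), a population mean
#' of 0.50 with total SD calibrated to about 0.1847 on the proportion scale,
#' and pooled sequencing at about 57x per bulk (36x per parent).
#'
#' @param n_f2 number of F2 plants (default 365).
#' @param bulk_size plants per extreme bulk (default 50); must be at most
#'   `n_f2 / 2`.
#' @param chrom_lengths named vector, chromosome name -> length in bp
#'   (default the 12-chromosome rice karyotype, [rice_chrom_lengths()]).
#' @param snp_density informative SNPs per Mb (default 20).
#' @param qtl data frame with columns `chrom`, `pos` (bp), `a` (additive
#'   effect on the fertility proportion scale) and `d` (dominance deviation);
#'   one row per QTL. Default: one QTL at chr08:4,000,000 with `a = 0.201`,
#'   `d = 0`.
#' @param baseline_mu population mean fertility proportion (default 0.50).
#' @param resid_sd SD of the family-level environmental deviation on the
#'   proportion scale (default 0.115, tuned so that with the default QTL the
#'   total phenotypic SD is about 0.1847).
#' @param mean_depth_pool mean sequencing depth per pool per site (default 57).
#' @param mean_depth_parent mean parent depth (default 36).
#' @param seq_error per-read allele miscall probability (default 0.001);
#'   must lie in `[0, 0.5)`.
#' @param bp_per_cM physical-to-genetic scale in bp per centimorgan
#'   (default 250,000, i.e. about 1500 cM for the rice genome).
#' @param n_f3_progeny F3 progeny simulated per F2 plant whose mean is the
#'   plant's family phenotype (default 12).
#' @param grains_per_plant spikelets counted per plant (default 200).
#' @param filled_split proportion of filled grains scored as fully (vs
#'   partially) filled (default 0.9, i.e. a 9:1 split).
#' @param seed root RNG seed for the whole dataset (default 1).
#' @return an object of class `sim_config` (a validated list).
#' @seealso [simulate_bsa_dataset()], [simulate_f2()]
#' @export
#' @examples
#' cfg <- sim_config(chrom_lengths = c(chr1 = 1e6), snp_density = 50)
#' cfg$n_f2
sim_config <- function(n_f2 = 365,
                       bulk_size = 50,
                       chrom_lengths = rice_chrom_lengths(),
                       snp_density = 20,
                       qtl = data.frame(chrom = "chr08", pos = 4.0e6,
                                        a = 0.201, d = 0),
                       baseline_mu = 0.50,
                       resid_sd = 0.115,
                       mean_depth_pool = 57,
                       mean_depth_parent = 36,
                       seq_error = 0.001,
                       bp_per_cM = 250e3,
                       n_f3_progeny = 12,
                       grains_per_plant = 200,
                       filled_split = 0.9,
                       seed = 1) {
  if (!is_count(n_f2) || n_f2 < 1) stop_cfg("n_f2 must be a positive integer")
  if (!is_count(bulk_size) || bulk_size < 1) stop_cfg("bulk_size must be a positive integer")
  if (bulk_size > n_f2 / 2) stop_cfg("bulk_size must not exceed n_f2/2")
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop_cfg("chrom_lengths must be a named vector")
  if (any(chrom_lengths <= 0)) stop_cfg("all chromosome lengths must be > 0")
  if (!is.numeric(seq_error) || seq_error < 0 || seq_error >= 0.5)
    stop_cfg("seq_error must lie in [0, 0.5)")
  if (snp_density <= 0) stop_cfg("snp_density must be > 0")
  if (bp_per_cM < 0) stop_cfg("bp_per_cM must be >= 0 (0 disables recombination)")
  if (resid_sd < 0) stop_cfg("resid_sd must be >= 0")
  if (!is.data.frame(qtl)) qtl <- as.data.frame(qtl)
  if (nrow(qtl)) {
    need <- c("chrom", "pos", "a", "d")
    if (!all(need %in% names(qtl)))
      stop_cfg("qtl needs columns chrom, pos, a, d")
    bad <- !(qtl$chrom %in% names(chrom_lengths))
    if (any(bad))
      stop_cfg("qtl chromosome(s) not in chrom_lengths: ",
               paste(unique(qtl$chrom[bad]), collapse = ", "))
    out_of_range <- qtl$pos < 1 | qtl$pos > chrom_lengths[qtl$chrom]
    if (any(out_of_range))
      stop_cfg("qtl position outside its chromosome")
  }
  if (filled_split < 0 || filled_split > 1) stop_cfg("filled_split must be in [0, 1]")
  structure(list(
    n_f2 = as.integer(n_f2), bulk_size = as.integer(bulk_size),
    chrom_lengths = chrom_lengths, snp_density = snp_density, qtl = qtl,
    baseline_mu = baseline_mu, resid_sd = resid_sd,
    mean_depth_pool = mean_depth_pool, mean_depth_parent = mean_depth_parent,
    seq_error = seq_error, bp_per_cM = bp_per_cM,
    n_f3_progeny = as.integer(n_f3_progeny),
    grains_per_plant = as.integer(grains_per_plant),
    filled_split = filled_split, seed = seed), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("F2 bulked-segregant simulator configuration\n")
  cat(sprintf("  %d F2 plants, bulks of %d; %d chromosome(s), %.0f SNPs/Mb\n",
              x$n_f2, x$bulk_size, length(x$chrom_lengths), x$snp_density))
  cat(sprintf("  depth %gx pools / %gx parents, seq error %g, %g kb/cM\n",
              x$mean_depth_pool, x$mean_depth_parent, x$seq_error,
              x$bp_per_cM / 1000))
  if (nrow(x$qtl)) {
    cat("  QTL:\n")
    for (i in seq_len(nrow(x$qtl)))
      cat(sprintf("    %s:%s  a = %g, d = %g\n", x$qtl$chrom[i],
                  format(x$qtl$pos[i], big.mark = ","), x$qtl$a[i], x$qtl$d[i]))
  } else cat("  no QTL (null genome)\n")
  invisible(x)
}
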