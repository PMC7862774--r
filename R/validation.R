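# Seeded validation experiments on the synthetic generator. These define the
# package's standard evaluation design -- a scaled three-chromosome genome
# that keeps repeated simulation affordable while preserving the window,
# depth and bulk structure of the full analysis -- and are shared by the test
# suite and the reproduction script.

#' Standard validation design for the simulator-based experiments
#'
#' Three 10 Mb chromosomes at 20 SNPs/Mb with the study's population
#' structure (365 F2 plants, bulks of 50, 57x pools) and, optionally, one
#' additive QTL of effect `a = 0.18` at 4.0 Mb of the chromosome labelled
#' "chr08".
#'
#' @param seed root seed for the dataset.
#' @param with_qtl plant the QTL (`TRUE`) or simulate a null genome.
#' @return a [sim_config()].
#' @export
validation_config <- function(seed, with_qtl = TRUE) {
  sim_config(
    n_f2 = 365, bulk_size = 50,
    chrom_lengths = c(chr07 = 1e7, chr08 = 1e7, chr09 = 1e7),
    snp_density = 20,
    qtl = if (with_qtl) data.frame(chrom = "chr08", pos = 4e6,
                                   a = 0.18, d = 0) else data.frame()[0, ],
    seed = seed)
}

# one full simulate -> filter -> scan -> threshold -> call run
run_validation_scan <- function(cfg, n_reps) {
  sim <- simulate_bsa_dataset(cfg)
  suppressWarnings(
    bsa_scan(sim$variants, cfg$chrom_lengths, bulk_size = cfg$bulk_size,
             n_reps = n_reps, seed = cfg$seed))
}

#' QTL recovery experiment on seeded simulations
#'
#' Repeatedly simulates the [validation_config()] design with its planted
#' chromosome-8 QTL, runs the full scan and region calling, and reports per
#' run whether any candidate region on the correct chromosome overlaps the
#' true QTL position and how far the best (peak-delta) region's midpoint
#' lies from the truth.
#'
#' @param n_runs number of seeded simulations (default 20).
#' @param base_seed seed from which per-run seeds are derived.
#' @param n_reps null replicates per threshold (default 1000).
#' @return data frame with one row per run: `seed`, `n_regions`,
#'   `recovered` (region on chr08 overlapping the truth), `best_chrom`,
#'   `best_start`, `best_end`, `midpoint_error_bp`, `peak_error_bp`.
#' @export
recovery_experiment <- function(n_runs = 20, base_seed = 1, n_reps = 1000) {
  seeds <- stage_seeds(base_seed, sprintf("recovery%02d", seq_len(n_runs)))
  rows <- lapply(seq_len(n_runs), function(i) {
    cfg <- validation_config(seeds[[i]])
    fit <- run_validation_scan(cfg, n_reps)
    r <- fit$regions
    truth_chrom <- cfg$qtl$chrom[1]; truth_pos <- cfg$qtl$pos[1]
    recovered <- any(r$chrom == truth_chrom & r$start <= truth_pos &
                       r$end >= truth_pos)
    if (nrow(r)) {
      best <- r[which.max(r$peak_delta), ]
      data.frame(seed = seeds[[i]], n_regions = nrow(r),
                 recovered = recovered, best_chrom = best$chrom,
                 best_start = best$start, best_end = best$end,
                 midpoint_error_bp = abs((best$start + best$end) / 2 -
                                           truth_pos),
                 peak_error_bp = abs(best$peak_pos - truth_pos))
    } else {
      data.frame(seed = seeds[[i]], n_regions = 0L, recovered = FALSE,
                 best_chrom = NA_character_, best_start = NA_real_,
                 best_end = NA_real_, midpoint_error_bp = NA_real_,
                 peak_error_bp = NA_real_)
    }
  })
  do.call(rbind, rows)
}

#' Type-I error experiment on null simulations
#'
#' Simulates the [validation_config()] design with no QTL and measures, per
#' run, the fraction of usable windows whose mean delta(SNP-index) exceeds
#' the 99.9% threshold and the number of candidate regions called under the
#' full screening criteria (threshold plus the 0.7/0.3 pool-index bounds).
#'
#' @inheritParams recovery_experiment
#' @return data frame with one row per run: `seed`, `frac_windows_above`,
#'   `n_regions`.
#' @export
null_calibration_experiment <- function(n_runs = 20, base_seed = 1,
                                        n_reps = 1000) {
  seeds <- stage_seeds(base_seed, sprintf("null%02d", seq_len(n_runs)))
  rows <- lapply(seq_len(n_runs), function(i) {
    cfg <- validation_config(seeds[[i]], with_qtl = FALSE)
    fit <- run_validation_scan(cfg, n_reps)
    w <- fit$windows[fit$windows$usable & !is.na(fit$windows$thr_0.999), ]
    data.frame(seed = seeds[[i]],
               frac_windows_above = mean(w$mean_delta > w$thr_0.999),
               n_regions = nrow(fit$regions))
  })
  do.call(rbind, rows)
}

#' Calibration of the observed SNP-index around its expectation
#'
#' Simulates independent null datasets (ten unlinked 200 kb chromosomes at
#' high SNP density, random bulks) and returns each dataset's mean observed
#' T-pool SNP-index. Under the read-sampling model the expectation at a
#' site with pool frequency `f` is `(1-2e)f + e`, which averages to exactly
#' 0.5 over a null genome; dataset means are independent replicates, so
#' their spread gives a valid standard error even though sites within one
#' chromosome are linked (the many short chromosomes keep each dataset's
#' mean from being dominated by a single bulk-composition draw).
#'
#' @param n_datasets independent simulated datasets (default 12).
#' @param sites_per_dataset SNPs per dataset (default 1000).
#' @param base_seed seed from which per-dataset seeds are derived.
#' @return data frame with `seed`, `n_sites`, `mean_index_t`.
#' @export
null_index_experiment <- function(n_datasets = 12, sites_per_dataset = 1000,
                                  base_seed = 1) {
  seeds <- stage_seeds(base_seed, sprintf("idx%02d", seq_len(n_datasets)))
  rows <- lapply(seq_len(n_datasets), function(i) {
    cfg <- sim_config(n_f2 = 100, bulk_size = 25,
                      chrom_lengths = stats::setNames(rep(2e5, 10),
                                                      sprintf("c%02d", 1:10)),
                      snp_density = sites_per_dataset / 2,
                      qtl = data.frame()[0, ], seed = seeds[[i]])
    sim <- simulate_bsa_dataset(cfg)
    filt <- filter_effective(sim$variants,
                             filter_config(max_pool_depth = 1000))
    idx <- snp_indices(filt)
    data.frame(seed = seeds[[i]], n_sites = nrow(idx),
               mean_index_t = mean(idx$index_t))
  })
  do.call(rbind, rows)
}
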