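#' Simulate F2:3 family-mean fertility phenotypes and grain counts
#'
#' Mirrors the study design in which each F2 plant is phenotyped through its
#' selfed F3 family while DNA bulks come from the F2 plants themselves. For
#' every F2 plant, `n_f3_progeny` F3 progeny genotypes at the QTL are drawn
#' by Mendelian selfing (heterozygotes segregate 1:2:1; homozygotes breed
#' true), their genetic values `g = a*(dosage - 1) + d*[dosage == 1]` are
#' averaged, one family-level environmental deviate `N(0, resid_sd)` is
#' added to `baseline_mu`, and the result is clamped to `[0, 1]`:
#'
#' `fertility_i = clamp(baseline_mu + mean_j(sum_q g_q(progeny_ij)) + e_i, 0, 1)`
#'
#' Grain counts per plant are then drawn as `grains_per_plant` spikelets with
#' filled count `Binomial(grains_per_plant, fertility_i)`, split into fully
#' vs partially filled at `filled_split` (default 9:1).
#'
#' @param pop an `f2_population` from [simulate_f2()].
#' @param config the [sim_config()] used to create `pop` (defaults to
#'   `pop$config`).
#' @return data frame with columns `plant_id`, `fertility` (true family-mean
#'   proportion), `N_FG`, `N_PG`, `N_EG`.
#' @export
#' @examples
#' cfg <- sim_config(n_f2 = 10, chrom_lengths = c(chr1 = 1e6),
#'                   qtl = data.frame()[0, ], resid_sd = 0)
#' ph <- simulate_phenotypes(simulate_f2(cfg), cfg)
#' all(ph$fertility == 0.5)
simulate_phenotypes <- function(pop, config = pop$config) {
  stopifnot(inherits(pop, "f2_population"))
  seeds <- stage_seeds(config$seed, c("map", "meiosis", "phenotype"))
  with_seed(seeds[["phenotype"]], {
    n <- nrow(pop$geno)
    gmean <- numeric(n)
    if (nrow(config$qtl)) {
      qidx <- match(paste(config$qtl$chrom, config$qtl$pos),
                    paste(pop$map$chrom, pop$map$pos))
      if (anyNA(qidx)) stop_cfg("QTL loci missing from the population map")
      m <- config$n_f3_progeny
      for (k in seq_along(qidx)) {
        dos <- pop$geno[, qidx[k]]
        a <- config$qtl$a[k]; d <- config$qtl$d[k]
        gv <- function(x) a * (x - 1) + d * (x == 1)
        fam <- numeric(n)
        het <- dos == 1L
        fam[!het] <- gv(dos[!het])          # homozygotes breed true
        if (any(het)) {
          prog <- matrix(sample(0:2, sum(het) * m, replace = TRUE,
                                prob = c(0.25, 0.5, 0.25)), ncol = m)
          fam[het] <- rowMeans(gv(prog))
        }
        gmean <- gmean + fam
      }
    }
    fert <- clamp01(config$baseline_mu + gmean + rnorm(n, 0, config$resid_sd))
    total <- config$grains_per_plant
    filled <- rbinom(n, total, fert)
    n_fg <- rbinom(n, filled, config$filled_split)
    data.frame(plant_id = rownames(pop$geno), fertility = fert,
               N_FG = n_fg, N_PG = filled - n_fg, N_EG = total - filled)
  })
}
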