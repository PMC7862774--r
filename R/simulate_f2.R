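# F2 genotype simulation: two independent meioses from the F1, crossovers as
# a Poisson process along each chromosome (Haldane model, no interference).

# allele (0/1) carried by one gamete at each of `pos` (sorted bp positions);
# breakpoints of the meiosis are Poisson with mean chrom_len_cM/100 crossovers
sim_gamete <- function(pos, chrom_len, bp_per_cM) {
  n_cross <- if (bp_per_cM > 0) rpois(1L, (chrom_len / bp_per_cM) / 100) else 0L
  start <- rbinom(1L, 1L, 0.5)
  if (n_cross == 0L) return(rep.int(start, length(pos)))
  breaks <- sort(runif(n_cross, 0, chrom_len))
  (start + findInterval(pos, breaks)) %% 2L
}

#' Simulate F2 genotypes by two meioses per plant
#'
#' Draws a marker map (uniform SNP positions at `snp_density` per Mb, plus
#' the configured QTL positions as unobserved causal loci) and, for each F2
#' plant, two independent gametes from the F1. Crossover counts per
#' chromosome follow a Poisson process at 1 crossover per 100 cM with
#' `bp_per_cM` bp per centimorgan, which implies Haldane's map function for
#' pairwise recombination fractions. Dosages count copies of the allele of
#' the tolerant parent (HHZ).
#'
#' @param config a [sim_config()].
#' @return an object of class `f2_population`: list with `map` (data frame
#'   `chrom`, `pos`, `is_qtl`), `geno` (integer matrix, plants x loci, values
#'   in 0/1/2) and `config`.
#' @export
#' @examples
#' pop <- simulate_f2(sim_config(n_f2 = 20, chrom_lengths = c(chr1 = 2e6),
#'                               snp_density = 10, qtl = data.frame()[0, ]))
#' dim(pop$geno)
simulate_f2 <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- stage_seeds(config$seed, c("map", "meiosis"))
  map <- with_seed(seeds[["map"]], draw_marker_map(config))
  geno <- with_seed(seeds[["meiosis"]], {
    g <- matrix(0L, nrow = config$n_f2, ncol = nrow(map))
    for (chrom in names(config$chrom_lengths)) {
      idx <- which(map$chrom == chrom)
      if (!length(idx)) next
      pos <- map$pos[idx]
      len <- config$chrom_lengths[[chrom]]
      for (i in seq_len(config$n_f2))
        g[i, idx] <- sim_gamete(pos, len, config$bp_per_cM) +
          sim_gamete(pos, len, config$bp_per_cM)
    }
    g
  })
  rownames(geno) <- sprintf("P%03d", seq_len(config$n_f2))
  structure(list(map = map, geno = geno, config = config),
            class = "f2_population")
}

# uniform unique SNP positions per chromosome; QTL positions appended as
# causal loci flagged is_qtl (not emitted to the VCF)
draw_marker_map <- function(config) {
  pieces <- lapply(names(config$chrom_lengths), function(chrom) {
    len <- config$chrom_lengths[[chrom]]
    n <- max(1L, round(len / 1e6 * config$snp_density))
    qp <- config$qtl$pos[config$qtl$chrom == chrom]
    repeat {
      pos <- sort(sample.int(len, n))
      if (!any(pos %in% qp)) break
    }
    data.frame(chrom = chrom,
               pos = sort(c(pos, qp)),
               is_qtl = sort(c(pos, qp)) %in% qp)
  })
  do.call(rbind, pieces)
}

#' @export
print.f2_population <- function(x, ...) {
  cat(sprintf("F2 population: %d plants, %d loci (%d causal) on %d chromosome(s)\n",
              nrow(x$geno), nrow(x$map), sum(x$map$is_qtl),
              length(unique(x$map$chrom))))
  invisible(x)
}
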