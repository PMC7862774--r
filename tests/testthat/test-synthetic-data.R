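test_that("config validation rejects impossible generator settings", {
  expect_error(sim_config(seq_error = 0.5), "seq_error")
  expect_error(sim_config(n_f2 = 100, bulk_size = 60), "bulk_size")
  expect_error(sim_config(chrom_lengths = c(chr1 = -5)), "lengths")
  expect_error(sim_config(chrom_lengths = c(chr1 = 1e6),
                          qtl = data.frame(chrom = "chrX", pos = 1,
                                           a = 0.1, d = 0)),
               "chromosome")
  expect_error(sim_config(chrom_lengths = c(chr1 = 1e6),
                          qtl = data.frame(chrom = "chr1", pos = 2e6,
                                           a = 0.1, d = 0)),
               "outside")
})

test_that("without recombination every plant is a constant gamete pair", {
  cfg <- sim_config(n_f2 = 15, bulk_size = 5, chrom_lengths = c(chr1 = 5e6),
                    snp_density = 10, qtl = data.frame()[0, ],
                    bp_per_cM = 0, seed = 4)
  pop <- simulate_f2(cfg)
  # each row is constant along the chromosome (0, 1 or 2)
  expect_true(all(apply(pop$geno, 1, function(r) length(unique(r)) == 1)))
})

test_that("single-locus dosages segregate 1:2:1", {
  cfg <- sim_config(n_f2 = 10000, bulk_size = 100,
                    chrom_lengths = c(chr1 = 1e5), snp_density = 10,
                    qtl = data.frame()[0, ], seed = 8)
  pop <- simulate_f2(cfg)
  p <- c(0.25, 0.5, 0.25)
  for (locus in c(1, nrow(pop$map))) {
    freq <- tabulate(pop$geno[, locus] + 1L, 3L) / cfg$n_f2
    se <- sqrt(p * (1 - p) / cfg$n_f2)
    expect_true(all(abs(freq - p) < 3 * se))
  }
})

test_that("recombination between linked loci follows Haldane's map function", {
  # two loci 250 kb = 1 cM apart; expected gamete recombination fraction
  # r = (1 - exp(-0.02)) / 2. Count recombinant dosage transitions among
  # plants homozygous at locus 1 (each such plant exposes both gametes).
  cfg <- sim_config(n_f2 = 8000, bulk_size = 100,
                    chrom_lengths = c(chr1 = 260e3), snp_density = 8,
                    qtl = data.frame()[0, ], seed = 21)
  pop <- simulate_f2(cfg)
  i <- which.min(abs(diff(pop$map$pos) - 250e3))
  d_bp <- pop$map$pos[i + 1] - pop$map$pos[i]
  r_exp <- (1 - exp(-2 * d_bp / (100 * cfg$bp_per_cM))) / 2
  g1 <- pop$geno[, i]; g2 <- pop$geno[, i + 1]
  hom <- g1 != 1L
  # among homozygous-at-locus-1 plants, each of the two gametes is
  # recombinant independently with prob r: |g2 - g1| ~ Binomial(2, r)
  n_gam <- 2 * sum(hom)
  n_rec <- sum(abs(g2[hom] - g1[hom]))
  se <- sqrt(r_exp * (1 - r_exp) / n_gam)
  expect_lt(abs(n_rec / n_gam - r_exp), 3 * se)
})

test_that("phenotypes follow the QTL model and calibrated variance", {
  # degenerate noise: no QTL, resid_sd 0 -> everyone at baseline
  cfg0 <- small_cfg(qtl = data.frame()[0, ], resid_sd = 0)
  ph0 <- simulate_phenotypes(simulate_f2(cfg0))
  expect_true(all(ph0$fertility == cfg0$baseline_mu))
  # dosage-2 plants at a single additive QTL, no noise: baseline + a
  cfg2 <- small_cfg(qtl = data.frame(chrom = "chr1", pos = 1e6,
                                     a = 0.2, d = 0), resid_sd = 0)
  pop2 <- simulate_f2(cfg2)
  ph2 <- simulate_phenotypes(pop2)
  dos <- pop2$geno[, which(pop2$map$is_qtl)]
  expect_equal(ph2$fertility[dos == 2], rep(0.7, sum(dos == 2)))
  expect_equal(ph2$fertility[dos == 0], rep(0.3, sum(dos == 0)))
  # default study calibration: sample SD of fertility lands in [0.13, 0.24]
  sds <- vapply(1:20, function(seed) {
    cfg <- sim_config(seed = seed, chrom_lengths = c(chr08 = 28.4e6),
                      snp_density = 2)
    sd(simulate_phenotypes(simulate_f2(cfg))$fertility)
  }, 0)
  expect_true(all(sds > 0.13 & sds < 0.24))
  expect_gt(mean(sds), 0.15)
})

test_that("pooled read sampling matches its binomial model", {
  cfg <- small_cfg()
  pop <- simulate_f2(cfg)
  ph <- simulate_phenotypes(pop)
  bulks <- select_bulks(setNames(ph$fertility, ph$plant_id), cfg$bulk_size)
  expect_error(simulate_pool_reads(pop, list(tolerant_ids = character(),
                                             sensitive_ids = character())),
               "empty bulk")
  v <- simulate_pool_reads(pop, bulks, cfg)
  expect_true(all(v$ad_t_ref >= 0 & v$ad_t_alt >= 0))
  # deterministic limit: f = 1 everywhere, no errors -> all reads are HHZ
  cfg1 <- small_cfg(qtl = data.frame()[0, ], seq_error = 0, bp_per_cM = 0)
  pop1 <- simulate_f2(cfg1)
  fixed <- rownames(pop1$geno)[pop1$geno[, 1] == 2L]   # HHZ-homozygous plants
  v1 <- simulate_pool_reads(pop1, list(tolerant_ids = fixed[1:3],
                                       sensitive_ids = fixed[4:6]), cfg1)
  n_hhz <- ifelse(v1$gt_hhz == "0/0", v1$ad_t_ref, v1$ad_t_alt)
  expect_equal(n_hhz, v1$ad_t_ref + v1$ad_t_alt)
  # f = 0.5, eps = 0: mean observed ratio over many sites within 3 SE of 0.5
  het <- rownames(pop1$geno)[pop1$geno[, 1] == 1L]
  cfg05 <- sim_config(n_f2 = 60, bulk_size = 12,
                      chrom_lengths = c(chr1 = 2e6), snp_density = 5000,
                      qtl = data.frame()[0, ], seq_error = 0, bp_per_cM = 0,
                      seed = 13)
  pop05 <- simulate_f2(cfg05)
  het <- rownames(pop05$geno)[pop05$geno[, 1] == 1L]
  v05 <- simulate_pool_reads(pop05, list(tolerant_ids = het[1:5],
                                         sensitive_ids = het[6:10]), cfg05)
  ratio <- ifelse(v05$gt_hhz == "0/0", v05$ad_t_ref, v05$ad_t_alt) /
    (v05$ad_t_ref + v05$ad_t_alt)
  ratio <- ratio[is.finite(ratio)]
  expect_gt(length(ratio), 9000)
  se <- sd(ratio) / sqrt(length(ratio))
  expect_lt(abs(mean(ratio) - 0.5), 3 * se)
})

test_that("observed SNP-index is centred on (1-2e)f + e given the truth", {
  cfg <- sim_config(n_f2 = 80, bulk_size = 20,
                    chrom_lengths = c(chr1 = 2e6), snp_density = 3000,
                    qtl = data.frame()[0, ], seq_error = 0.01, seed = 17)
  pop <- simulate_f2(cfg)
  ids <- rownames(pop$geno)
  bulks <- list(tolerant_ids = ids[1:20], sensitive_ids = ids[21:40])
  v <- simulate_pool_reads(pop, bulks, cfg)
  f <- colSums(pop$geno[bulks$tolerant_ids, ]) / 40
  n_hhz <- ifelse(v$gt_hhz == "0/0", v$ad_t_ref, v$ad_t_alt)
  depth <- v$ad_t_ref + v$ad_t_alt
  ok <- depth > 0
  idx <- n_hhz[ok] / depth[ok]
  expected <- (1 - 2 * cfg$seq_error) * f[ok] + cfg$seq_error
  resid <- idx - expected          # pure read noise, independent across sites
  se <- sd(resid) / sqrt(length(resid))
  expect_lt(abs(mean(resid)), 3 * se)
})

test_that("selected bulks enrich the tolerant bulk for the HHZ allele", {
  hits <- vapply(1:20, function(seed) {
    cfg <- small_cfg(seed = seed,
                     qtl = data.frame(chrom = "chr1", pos = 1e6,
                                      a = 0.15, d = 0), resid_sd = 0.12)
    pop <- simulate_f2(cfg)
    ph <- simulate_phenotypes(pop)
    b <- select_bulks(setNames(ph$fertility, ph$plant_id), cfg$bulk_size)
    q <- which(pop$map$is_qtl)
    mean(pop$geno[b$tolerant_ids, q]) > mean(pop$geno[b$sensitive_ids, q])
  }, NA)
  expect_true(all(hits))
})

test_that("the full dataset is reproducible under a fixed seed", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  cfg <- small_cfg(seed = 99)
  s1 <- simulate_bsa_dataset(cfg, dir = dir1)
  s2 <- simulate_bsa_dataset(cfg, dir = dir2)
  expect_identical(s1$variants, s2$variants)
  expect_identical(s1$phenotypes, s2$phenotypes)
  for (f in c("pools.vcf", "phenotypes.tsv", "bulks.tsv", "truth.json"))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
})

test_that("simulator VCF round-trips through the reader", {
  dir <- withr::local_tempdir()
  sim <- simulate_bsa_dataset(small_cfg(seed = 31), dir = dir)
  v <- read_bsa_vcf(sim$files$vcf)
  expect_equal(nrow(v), nrow(sim$variants))
  expect_equal(v$pos, as.integer(sim$variants$pos))
  expect_true(all(diff(v$pos) > 0))       # one chromosome, sorted
  for (col in c("chrom", "ref", "alt", "gt_hhz", "gt_9311",
                "ad_t_ref", "ad_t_alt", "ad_s_ref", "ad_s_alt"))
    expect_equal(v[[col]], sim$variants[[col]],
                 ignore_attr = TRUE, tolerance = 0)
})
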