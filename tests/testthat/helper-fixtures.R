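# shared fixtures: small configurations and hand-built variant tables

# scaled test genome: quick but structurally like the full karyotype
small_cfg <- function(seed = 1, qtl = data.frame(chrom = "chr1", pos = 1e6,
                                                 a = 0.2, d = 0), ...) {
  sim_config(n_f2 = 60, bulk_size = 12,
             chrom_lengths = c(chr1 = 2e6), snp_density = 25,
             qtl = qtl, seed = seed, ...)
}

# hand-built variant table: n sites on one chromosome, ideal parents
make_variants <- function(pos, n_hhz_t, depth_t, n_hhz_s, depth_s,
                          chrom = "chr1", parent_dp = 30) {
  n <- length(pos)
  data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G",
             gt_hhz = "0/0", gt_9311 = "1/1",
             dp_hhz = parent_dp, dp_9311 = parent_dp,
             ad_t_ref = n_hhz_t, ad_t_alt = depth_t - n_hhz_t,
             ad_s_ref = n_hhz_s, ad_s_alt = depth_s - n_hhz_s)
}

# brute-force window oracle: O(n * windows) logical-mask means
oracle_windows <- function(sites, chrom_lengths, window, step, min_snps = 3) {
  pieces <- lapply(names(chrom_lengths), function(chrom) {
    len <- chrom_lengths[[chrom]]
    s <- sites[sites$chrom == chrom, ]
    starts <- seq.int(1, len, by = step)
    do.call(rbind, lapply(starts, function(st) {
      en <- min(st + window - 1, len)
      mask <- s$pos >= st & s$pos <= en
      data.frame(chrom = chrom, start = st, end = en, n_snps = sum(mask),
                 mean_index_t = if (any(mask)) mean(s$index_t[mask]) else NA_real_,
                 mean_index_s = if (any(mask)) mean(s$index_s[mask]) else NA_real_,
                 mean_delta = if (any(mask)) mean(s$delta[mask]) else NA_real_,
                 usable = sum(mask) >= min_snps)
    }))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
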