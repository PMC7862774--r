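#' Read a multi-sample BSA VCF into a variant table
#'
#' Reads a VCF v4.x with per-sample `AD` allele depths and extracts the two
#' parents and the two bulk pools named in `samples`. Multi-allelic records
#' and non-SNP records (indels, symbolic alleles) are skipped with counts
#' recorded in the `skipped` attribute; records must be coordinate-sorted
#' within each chromosome.
#'
#' @param path VCF file path.
#' @param samples named character vector mapping roles to VCF sample names:
#'   `parent_a` (the index/tolerant parent whose allele the SNP-index
#'   tracks), `parent_b`, `pool_t`, `pool_s`.
#' @return a `bsa_variants` data frame (see [simulate_pool_reads()] for the
#'   columns), with attribute `skipped` (named counts of dropped records).
#' @export
read_bsa_vcf <- function(path,
                         samples = c(parent_a = "HHZ", parent_b = "9311",
                                     pool_t = "T_pool", pool_s = "S_pool")) {
  need <- c("parent_a", "parent_b", "pool_t", "pool_s")
  if (!all(need %in% names(samples)))
    stop_cfg("samples must name parent_a, parent_b, pool_t, pool_s")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (!all(samples %in% colnames(vcf@gt)))
    stop_cfg("VCF lacks sample(s): ",
             paste(setdiff(samples, colnames(vcf@gt)), collapse = ", "))
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  pos <- as.integer(fix$POS)
  # sortedness within chromosome runs
  for (chrom in unique(fix$CHROM)) {
    p <- pos[fix$CHROM == chrom]
    if (is.unsorted(p, strictly = TRUE))
      stop_cfg("VCF is not coordinate-sorted on ", chrom,
               "; sort it (e.g. bcftools sort) first")
  }
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  nonsnp <- !multi & (nchar(fix$REF) != 1L | nchar(fix$ALT) != 1L |
                        !fix$REF %in% c("A", "C", "G", "T") |
                        !fix$ALT %in% c("A", "C", "G", "T"))
  keep <- !multi & !nonsnp
  fmt <- vcf@gt[, "FORMAT"]
  if (!all(grepl("(^|:)AD(:|$)", fmt)))
    stop_cfg("record without an AD FORMAT field at ",
             fix$CHROM[!grepl("(^|:)AD(:|$)", fmt)][1], ":",
             fix$POS[!grepl("(^|:)AD(:|$)", fmt)][1])
  gt <- vcfR::extract.gt(vcf, "GT")
  ad <- vcfR::extract.gt(vcf, "AD")
  ad_ref <- vcfR::masplit(ad, record = 1, sort = FALSE, decreasing = FALSE)
  ad_alt <- vcfR::masplit(ad, record = 2, sort = FALSE, decreasing = FALSE)
  pa <- samples[["parent_a"]]; pb <- samples[["parent_b"]]
  pt <- samples[["pool_t"]]; ps <- samples[["pool_s"]]
  out <- data.frame(
    chrom = fix$CHROM, pos = pos, ref = fix$REF, alt = fix$ALT,
    gt_hhz = unname(gt[, pa]), gt_9311 = unname(gt[, pb]),
    dp_hhz = as.integer(ad_ref[, pa] + ad_alt[, pa]),
    dp_9311 = as.integer(ad_ref[, pb] + ad_alt[, pb]),
    ad_t_ref = as.integer(ad_ref[, pt]), ad_t_alt = as.integer(ad_alt[, pt]),
    ad_s_ref = as.integer(ad_ref[, ps]), ad_s_alt = as.integer(ad_alt[, ps]))[keep, ]
  rownames(out) <- NULL
  attr(out, "skipped") <- c(multiallelic = sum(multi), non_snp = sum(nonsnp))
  out
}

#' Filter configuration for effective SNP selection
#'
#' Depth and genotype criteria used by [filter_effective()]. The study this
#' package reimplements reports only the counts of "high-quality" and
#' "effective" SNPs, not its cutoffs; these defaults are explicit,
#' configurable stand-ins and every removal is tallied in the filter report.
#'
#' @param min_pool_depth minimum reads per pool at a site (default 8).
#' @param max_pool_depth maximum reads per pool; `NULL` (default) means 3x
#'   the mean observed pool depth, computed from the data.
#' @param min_parent_depth minimum reads per parent (default 6).
#' @param require_parent_homozygous_opposite keep only sites where the two
#'   parents are opposite homozygotes (default `TRUE`).
#' @return object of class `filter_config`.
#' @export
filter_config <- function(min_pool_depth = 8, max_pool_depth = NULL,
                          min_parent_depth = 6,
                          require_parent_homozygous_opposite = TRUE) {
  if (min_pool_depth <= 0) stop_cfg("min_pool_depth must be > 0")
  if (!is.null(max_pool_depth) && max_pool_depth < min_pool_depth)
    stop_cfg("max_pool_depth must be >= min_pool_depth")
  structure(list(min_pool_depth = min_pool_depth,
                 max_pool_depth = max_pool_depth,
                 min_parent_depth = min_parent_depth,
                 require_parent_homozygous_opposite = require_parent_homozygous_opposite),
            class = "filter_config")
}

gt_is_hom_ref <- function(gt) gt %in% c("0/0", "0|0", "0")
gt_is_hom_alt <- function(gt) gt %in% c("1/1", "1|1", "1")

#' Filter variants to effective parent-polymorphic SNPs
#'
#' Keeps sites where (by default) the parents are opposite homozygotes with
#' adequate depth and both pools fall inside the depth window, and orients
#' each kept site to the allele of parent A (HHZ) as determined from parent
#' A's genotype -- not from REF/ALT status -- so that the SNP-index is always
#' the HHZ-allele frequency. Each removed site is counted under the first
#' rule it fails, so the report conserves totals
#' (`kept + sum(removals) = input`).
#'
#' @param variants a `bsa_variants` data frame from [read_bsa_vcf()] or
#'   [simulate_pool_reads()].
#' @param cfg a [filter_config()].
#' @return list with `variants` (kept rows plus orientation columns
#'   `hhz_allele`, `n_hhz_t`, `depth_t`, `n_hhz_s`, `depth_s`) and `report`
#'   (named integer counts, including the applied depth bounds).
#' @export
filter_effective <- function(variants, cfg = filter_config()) {
  v <- variants
  n <- nrow(v)
  depth_t <- v$ad_t_ref + v$ad_t_alt
  depth_s <- v$ad_s_ref + v$ad_s_alt
  max_pool <- if (is.null(cfg$max_pool_depth))
    3 * mean(c(depth_t, depth_s)) else cfg$max_pool_depth
  a_ref <- gt_is_hom_ref(v$gt_hhz); a_alt <- gt_is_hom_alt(v$gt_hhz)
  b_ref <- gt_is_hom_ref(v$gt_9311); b_alt <- gt_is_hom_alt(v$gt_9311)
  fail_hom <- !((a_ref | a_alt) & (b_ref | b_alt))
  fail_same <- !fail_hom & ((a_ref & b_ref) | (a_alt & b_alt))
  if (!cfg$require_parent_homozygous_opposite) {
    # orientation still needs a homozygous parent A
    fail_hom <- !(a_ref | a_alt)
    fail_same <- rep(FALSE, n)
  }
  ok <- !fail_hom & !fail_same
  fail_parent_dp <- ok & (v$dp_hhz < cfg$min_parent_depth |
                            v$dp_9311 < cfg$min_parent_depth)
  ok <- ok & !fail_parent_dp
  fail_pool_low <- ok & (depth_t < cfg$min_pool_depth |
                           depth_s < cfg$min_pool_depth)
  ok <- ok & !fail_pool_low
  fail_pool_high <- ok & (depth_t > max_pool | depth_s > max_pool)
  ok <- ok & !fail_pool_high
  kept <- v[ok, , drop = FALSE]
  hhz_is_ref <- a_ref[ok]
  kept$hhz_allele <- ifelse(hhz_is_ref, "ref", "alt")
  kept$n_hhz_t <- ifelse(hhz_is_ref, kept$ad_t_ref, kept$ad_t_alt)
  kept$n_hhz_s <- ifelse(hhz_is_ref, kept$ad_s_ref, kept$ad_s_alt)
  kept$depth_t <- depth_t[ok]
  kept$depth_s <- depth_s[ok]
  rownames(kept) <- NULL
  report <- c(input = n,
              parent_not_homozygous = sum(fail_hom),
              parents_identical = sum(fail_same),
              parent_low_depth = sum(fail_parent_dp),
              pool_low_depth = sum(fail_pool_low),
              pool_high_depth = sum(fail_pool_high),
              kept = sum(ok))
  if (!sum(ok)) warning("no sites passed the effective-SNP filter", call. = FALSE)
  list(variants = kept,
       report = c(report, min_pool_depth = cfg$min_pool_depth,
                  max_pool_depth = max_pool,
                  min_parent_depth = cfg$min_parent_depth))
}

#' Export filtered sites as a per-site TSV
#'
#' @param filtered result of [filter_effective()] (or its `variants`
#'   element).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_sites_tsv <- function(filtered, path) {
  v <- if (is.data.frame(filtered)) filtered else filtered$variants
  utils::write.table(
    v[c("chrom", "pos", "n_hhz_t", "depth_t", "n_hhz_s", "depth_s")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
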