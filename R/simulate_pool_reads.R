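#' Simulate pooled sequencing reads over the two bulks
#'
#' At each non-causal SNP the true pool frequency of the tolerant-parent
#' (HHZ) allele is `f = sum(dosages) / (2 * bulk_size)`, assuming equimolar
#' DNA per plant. Site depth is `Poisson(mean_depth_pool)` per pool and the
#' HHZ-supporting read count is `Binomial(depth, f*(1-e) + (1-f)*e)` with
#' per-read miscall probability `e = seq_error`. Parents are written as
#' opposite fixed homozygotes with independent `Poisson(mean_depth_parent)`
#' depths. The HHZ allele is assigned to REF or ALT at random per site so
#' that downstream code must orient alleles from the parent genotypes rather
#' than REF/ALT status.
#'
#' @param pop an `f2_population` from [simulate_f2()].
#' @param bulk_members list with components `tolerant_ids` and
#'   `sensitive_ids` (plant ids, e.g. a [select_bulks()] result).
#' @param config the [sim_config()] (defaults to `pop$config`).
#' @return a `bsa_variants` data frame (the in-memory form of the VCF
#'   contract): `chrom`, `pos`, `ref`, `alt`, `gt_hhz`, `gt_9311`, `dp_hhz`,
#'   `dp_9311`, `ad_t_ref`, `ad_t_alt`, `ad_s_ref`, `ad_s_alt`.
#' @seealso [write_bsa_vcf()], [read_bsa_vcf()]
#' @export
simulate_pool_reads <- function(pop, bulk_members, config = pop$config) {
  stopifnot(inherits(pop, "f2_population"))
  tol <- bulk_members$tolerant_ids
  sen <- bulk_members$sensitive_ids
  if (!length(tol) || !length(sen)) stop_cfg("empty bulk")
  if (!all(c(tol, sen) %in% rownames(pop$geno)))
    stop_cfg("bulk member ids not found among plant ids")
  seeds <- stage_seeds(config$seed, c("map", "meiosis", "phenotype", "reads"))
  with_seed(seeds[["reads"]], {
    keep <- !pop$map$is_qtl
    map <- pop$map[keep, , drop = FALSE]
    n <- nrow(map)
    e <- config$seq_error
    f_t <- colSums(pop$geno[tol, keep, drop = FALSE]) / (2 * length(tol))
    f_s <- colSums(pop$geno[sen, keep, drop = FALSE]) / (2 * length(sen))
    dp_t <- rpois(n, config$mean_depth_pool)
    dp_s <- rpois(n, config$mean_depth_pool)
    n_hhz_t <- rbinom(n, dp_t, f_t * (1 - e) + (1 - f_t) * e)
    n_hhz_s <- rbinom(n, dp_s, f_s * (1 - e) + (1 - f_s) * e)
    hhz_is_ref <- runif(n) < 0.5
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- bases[(match(ref, bases) + sample(1:3, n, replace = TRUE) - 1L) %% 4L + 1L]
    dp_hhz <- rpois(n, config$mean_depth_parent)
    dp_9311 <- rpois(n, config$mean_depth_parent)
    data.frame(
      chrom = map$chrom, pos = map$pos, ref = ref, alt = alt,
      gt_hhz  = ifelse(hhz_is_ref, "0/0", "1/1"),
      gt_9311 = ifelse(hhz_is_ref, "1/1", "0/0"),
      dp_hhz = dp_hhz, dp_9311 = dp_9311,
      ad_t_ref = ifelse(hhz_is_ref, n_hhz_t, dp_t - n_hhz_t),
      ad_t_alt = ifelse(hhz_is_ref, dp_t - n_hhz_t, n_hhz_t),
      ad_s_ref = ifelse(hhz_is_ref, n_hhz_s, dp_s - n_hhz_s),
      ad_s_alt = ifelse(hhz_is_ref, dp_s - n_hhz_s, n_hhz_s))
  })
}

#' Write a `bsa_variants` table as a four-sample VCF v4.2 file
#'
#' Samples are written in the order HHZ, 9311, T_pool, S_pool with
#' `GT:AD:DP` FORMAT fields; parents carry their homozygous genotypes and
#' pools carry `./.` genotypes with allele depths.
#'
#' @param variants a `bsa_variants` data frame.
#' @param path output file path (plain text).
#' @param chrom_lengths named vector used for `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_bsa_vcf <- function(variants, path, chrom_lengths) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=bulkscan-", utils::packageVersion("bulkscan")),
    sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
            as.integer(chrom_lengths)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "HHZ", "9311", "T_pool", "S_pool", sep = "\t"))
  v <- variants[order(match(variants$chrom, names(chrom_lengths)), variants$pos), ]
  par_ad <- function(gt, dp) ifelse(gt == "0/0", paste0(dp, ",0"), paste0("0,", dp))
  rows <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", ".", "GT:AD:DP",
                paste0(v$gt_hhz, ":", par_ad(v$gt_hhz, v$dp_hhz), ":", v$dp_hhz),
                paste0(v$gt_9311, ":", par_ad(v$gt_9311, v$dp_9311), ":", v$dp_9311),
                paste0("./.:", v$ad_t_ref, ",", v$ad_t_alt, ":", v$ad_t_ref + v$ad_t_alt),
                paste0("./.:", v$ad_s_ref, ",", v$ad_s_alt, ":", v$ad_s_ref + v$ad_s_alt),
                sep = "\t")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# synthetic non-overlapping gene models, roughly 1 gene / 13 kb as in rice
simulate_gene_models <- function(config, mean_len = 3000, spacing = 13000) {
  pieces <- lapply(names(config$chrom_lengths), function(chrom) {
    len <- config$chrom_lengths[[chrom]]
    starts <- seq(1000, len - mean_len, by = spacing)
    starts <- starts + round(runif(length(starts), 0, spacing - mean_len - 1000))
    glen <- pmax(200, round(rnorm(length(starts), mean_len, mean_len / 4)))
    ends <- pmin(starts + glen - 1, len)
    data.frame(gene_id = sprintf("SYN_%s_g%04d", chrom, seq_along(starts)),
               chrom = chrom, start = starts, end = ends,
               strand = sample(c("+", "-"), length(starts), replace = TRUE),
               description = "synthetic gene model, expressed")
  })
  do.call(rbind, pieces)
}

write_gene_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start, genes$end),
                               strand = genes$strand)
  gr$type <- "gene"
  gr$source <- "bulkscan"
  gr$ID <- genes$gene_id
  gr$Name <- genes$gene_id
  gr$description <- genes$description
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Simulate a complete bulked-segregant dataset with known ground truth
#'
#' Runs the whole generator -- F2 meioses, F2:3 family phenotypes, extreme
#' bulk selection and pooled sequencing -- and (optionally) writes every
#' input the analysis pipeline consumes: a four-sample VCF, a GFF3 of
#' synthetic gene models, a TSV phenotype table (`plant_id`, `N_FG`, `N_PG`,
#' `N_EG`), a TSV bulk-membership table and a JSON truth file recording the
#' planted QTL, per-plant true fertility, bulk membership and the per-stage
#' RNG seeds.
#'
#' With `config$seed` fixed the dataset (in memory and on disk) is identical
#' across runs.
#'
#' @param config a [sim_config()].
#' @param dir output directory; `NULL` (default) skips writing files.
#' @return list of class `bsa_sim`: `population`, `phenotypes` (with scored
#'   fertility percent), `bulks`, `variants`, `genes`, `truth`, `config`,
#'   and `files` (paths, when written).
#' @export
#' @examples
#' cfg <- sim_config(n_f2 = 40, bulk_size = 10,
#'                   chrom_lengths = c(chr1 = 2e6), snp_density = 10,
#'                   qtl = data.frame()[0, ], seed = 7)
#' sim <- simulate_bsa_dataset(cfg)
#' nrow(sim$variants)
simulate_bsa_dataset <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  pop <- simulate_f2(config)
  pheno <- simulate_phenotypes(pop, config)
  fert_pct <- spikelet_fertility(pheno)
  bulks <- select_bulks(stats::setNames(fert_pct, pheno$plant_id),
                        config$bulk_size)
  variants <- simulate_pool_reads(pop, bulks, config)
  seeds <- stage_seeds(config$seed,
                       c("map", "meiosis", "phenotype", "reads", "genes"))
  genes <- with_seed(seeds[["genes"]], simulate_gene_models(config))
  truth <- list(qtl = config$qtl,
                fertility = stats::setNames(pheno$fertility, pheno$plant_id),
                tolerant_ids = bulks$tolerant_ids,
                sensitive_ids = bulks$sensitive_ids,
                stage_seeds = as.list(seeds))
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(
      vcf = file.path(dir, "pools.vcf"),
      gff = file.path(dir, "genes.gff3"),
      phenotypes = file.path(dir, "phenotypes.tsv"),
      bulks = file.path(dir, "bulks.tsv"),
      truth = file.path(dir, "truth.json"))
    write_bsa_vcf(variants, files$vcf, config$chrom_lengths)
    write_gene_gff3(genes, files$gff)
    ptab <- cbind(pheno[c("plant_id", "N_FG", "N_PG", "N_EG")],
                  fertility = round(fert_pct, 4))
    utils::write.table(ptab, files$phenotypes, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    btab <- data.frame(plant_id = c(bulks$tolerant_ids, bulks$sensitive_ids),
                       bulk = rep(c("tolerant", "sensitive"),
                                  c(length(bulks$tolerant_ids),
                                    length(bulks$sensitive_ids))))
    utils::write.table(btab, files$bulks, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(truth, files$truth, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  structure(list(population = pop, phenotypes = cbind(pheno, fertility_pct = fert_pct),
                 bulks = bulks, variants = variants, genes = genes,
                 truth = truth, config = config, files = files),
            class = "bsa_sim")
}

#' @export
print.bsa_sim <- function(x, ...) {
  cat(sprintf("Simulated BSA-seq dataset: %d F2 plants, %d SNPs, bulks of %d\n",
              x$config$n_f2, nrow(x$variants), x$config$bulk_size))
  if (nrow(x$config$qtl))
    cat(sprintf("  planted QTL: %s\n",
                paste(sprintf("%s:%g (a=%g, d=%g)", x$config$qtl$chrom,
                              x$config$qtl$pos, x$config$qtl$a,
                              x$config$qtl$d), collapse = "; ")))
  invisible(x)
}
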