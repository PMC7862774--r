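test_that("reader skips multi-allelic and non-SNP records and demands sorting", {
  dir <- withr::local_tempdir()
  sim <- simulate_bsa_dataset(small_cfg(seed = 41), dir = dir)
  lines <- readLines(sim$files$vcf)
  body <- grep("^[^#]", lines)
  # corrupt two records: one multi-allelic, one indel
  rec1 <- strsplit(lines[body[3]], "\t")[[1]]; rec1[5] <- "G,T"
  rec2 <- strsplit(lines[body[7]], "\t")[[1]]; rec2[4] <- "AT"
  lines[body[3]] <- paste(rec1, collapse = "\t")
  lines[body[7]] <- paste(rec2, collapse = "\t")
  bad <- file.path(dir, "mixed.vcf")
  writeLines(lines, bad)
  v <- read_bsa_vcf(bad)
  expect_equal(nrow(v), length(body) - 2)
  expect_equal(attr(v, "skipped"),
               c(multiallelic = 1L, non_snp = 1L), ignore_attr = FALSE)
  # unsorted input is refused with advice
  swapped <- lines
  swapped[body[1]] <- lines[body[2]]
  swapped[body[2]] <- lines[body[1]]
  unsorted <- file.path(dir, "unsorted.vcf")
  writeLines(swapped, unsorted)
  expect_error(read_bsa_vcf(unsorted), "sort")
  # unknown sample names are reported
  expect_error(read_bsa_vcf(sim$files$vcf,
                            samples = c(parent_a = "HHZ", parent_b = "9311",
                                        pool_t = "nope", pool_s = "S_pool")),
               "nope")
})

test_that("effective-SNP filter applies each rule once with conserved totals", {
  # 5-site fixture: one heterozygous parent, one depth-4 pool, three passing
  v <- make_variants(pos = c(100, 200, 300, 400, 500),
                     n_hhz_t = c(10, 10, 10, 10, 10),
                     depth_t = c(20, 20, 4, 20, 20),
                     n_hhz_s = c(5, 5, 3, 5, 5),
                     depth_s = c(20, 20, 18, 20, 20))
  v$gt_hhz[2] <- "0/1"
  res <- filter_effective(v, filter_config(min_pool_depth = 8,
                                           max_pool_depth = 100,
                                           min_parent_depth = 6))
  expect_equal(nrow(res$variants), 3)
  expect_equal(unname(res$report[["parent_not_homozygous"]]), 1)
  expect_equal(unname(res$report[["pool_low_depth"]]), 1)
  # conservation: kept + removals = input
  rules <- c("parent_not_homozygous", "parents_identical",
             "parent_low_depth", "pool_low_depth", "pool_high_depth")
  expect_equal(res$report[["kept"]] + sum(res$report[rules]),
               res$report[["input"]])
  # all-passing input comes back unchanged (site set identical)
  ok <- make_variants(pos = c(1, 2, 3), n_hhz_t = 5, depth_t = 10,
                      n_hhz_s = 5, depth_s = 10)
  res2 <- filter_effective(ok, filter_config(min_pool_depth = 8,
                                             max_pool_depth = 100))
  expect_equal(res2$variants$pos, ok$pos)
  expect_equal(res2$report[["kept"]], 3)
  # degenerate cutoff: nothing passes, with a warning
  expect_warning(
    res3 <- filter_effective(ok, filter_config(min_pool_depth = 50,
                                               max_pool_depth = 100)),
    "no sites")
  expect_equal(nrow(res3$variants), 0)
})

test_that("filtering is idempotent under a fixed configuration", {
  sim <- simulate_bsa_dataset(small_cfg(seed = 42))
  cfg <- filter_config(max_pool_depth = 150)
  once <- filter_effective(sim$variants, cfg)
  twice <- filter_effective(once$variants, cfg)
  expect_equal(twice$variants$pos, once$variants$pos)
  expect_equal(twice$variants$n_hhz_t, once$variants$n_hhz_t)
  expect_equal(twice$report[["kept"]], once$report[["kept"]])
})

test_that("orientation tracks the HHZ parent genotype, not REF/ALT", {
  v <- make_variants(pos = c(10, 20), n_hhz_t = c(9, 9), depth_t = 10,
                     n_hhz_s = c(1, 1), depth_s = 10)
  # flip site 2 so HHZ carries the ALT allele; swap its AD columns to match
  v$gt_hhz[2] <- "1/1"; v$gt_9311[2] <- "0/0"
  v[2, c("ad_t_ref", "ad_t_alt")] <- v[2, c("ad_t_alt", "ad_t_ref")]
  v[2, c("ad_s_ref", "ad_s_alt")] <- v[2, c("ad_s_alt", "ad_s_ref")]
  res <- filter_effective(v, filter_config(max_pool_depth = 100))
  expect_equal(res$variants$hhz_allele, c("ref", "alt"))
  expect_equal(res$variants$n_hhz_t, c(9, 9))
  expect_equal(res$variants$n_hhz_s, c(1, 1))
  idx <- snp_indices(res)
  expect_equal(idx$index_t, c(0.9, 0.9))
  expect_equal(idx$delta, c(0.8, 0.8))
})
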