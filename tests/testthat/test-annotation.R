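write_test_gff <- function(path, genes) {
  lines <- c("##gff-version 3",
             sprintf("%s\ttest\tgene\t%d\t%d\t.\t%s\t.\tID=%s;description=%s",
                     genes$chrom, genes$start, genes$end, genes$strand,
                     genes$gene_id, genes$description))
  writeLines(lines, path)
  path
}

test_that("gene overlap uses the 1 bp rule on gene spans", {
  dir <- withr::local_tempdir()
  genes <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
                      start = c(100, 950, 2000), end = c(200, 1050, 2100),
                      strand = c("+", "-", "+"),
                      description = c("kinase", "transporter", "unknown"))
  gff <- write_test_gff(file.path(dir, "genes.gff3"), genes)
  region <- candidate_region("chr1", 900, 1100)
  hit <- genes_in_region(gff, region)
  expect_equal(hit$gene_id, "g2")
  expect_equal(hit$strand, "-")
  # a gene straddling the region boundary is still included
  edge <- genes_in_region(gff, candidate_region("chr1", 1040, 1500))
  expect_equal(edge$gene_id, "g2")
  # results come back sorted by start
  all3 <- genes_in_region(gff, candidate_region("chr1", 1, 3000))
  expect_equal(all3$gene_id, c("g1", "g2", "g3"))
  # description-based exclusion is available for shortlisting
  expect_equal(genes_in_region(gff, candidate_region("chr1", 1, 3000),
                               exclude = "unknown")$gene_id, c("g1", "g2"))
  # absent chromosome: empty with a warning
  expect_warning(none <- genes_in_region(gff, candidate_region("chrZ", 1, 100)),
                 "absent")
  expect_equal(nrow(none), 0)
})

test_that("gene overlaps equal a brute-force all-pairs interval check", {
  set.seed(5)
  n_genes <- 400
  starts <- sort(sample.int(5e6, n_genes))
  genes <- data.frame(gene_id = sprintf("g%03d", seq_len(n_genes)),
                      chrom = "chr1", start = starts,
                      end = starts + sample(200:5000, n_genes, replace = TRUE),
                      strand = "+", description = "x")
  dir <- withr::local_tempdir()
  gff <- write_test_gff(file.path(dir, "many.gff3"), genes)
  region <- candidate_region("chr1", 2e6, 3e6)
  hit <- genes_in_region(gff, region)
  brute <- genes[genes$start <= 3e6 & genes$end >= 2e6, "gene_id"]
  expect_setequal(hit$gene_id, brute)
})

test_that("per-gene variant counts deduplicate and conserve totals", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      start = c(100, 1000), end = c(500, 1500),
                      strand = "+", description = "x")
  sites <- data.frame(chrom = "chr1",
                      pos = c(150, 200, 450, 700, 800, 1200, 1200))
  counted <- variants_per_gene(sites, genes)
  expect_equal(counted$n_variants, c(3, 1))
  expect_equal(attr(counted, "intergenic"), 2)
  expect_equal(attr(counted, "duplicates"), 1)
  expect_equal(attr(counted, "total"), 6)
  expect_equal(sum(counted$n_variants) + attr(counted, "intergenic"),
               attr(counted, "total"))
  # empty gene list: everything is intergenic
  none <- variants_per_gene(sites, genes[0, ])
  expect_equal(attr(none, "intergenic"), 6)
})

test_that("BED round-trip preserves regions and their gene lists", {
  dir <- withr::local_tempdir()
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      start = c(100, 1000), end = c(500, 1500),
                      strand = "+", description = "x")
  gff <- write_test_gff(file.path(dir, "rt.gff3"), genes)
  r <- candidate_region("chr1", 400, 1100)
  bed <- file.path(dir, "r.bed")
  write_regions_bed(r, bed)
  r2 <- read_regions_bed(bed)
  expect_equal(r2$start, r$start)
  expect_equal(r2$end, r$end)
  expect_equal(genes_in_region(gff, r2)$gene_id,
               genes_in_region(gff, r)$gene_id)
})

test_that("malformed GFF3 input is reported as such", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.gff3")
  writeLines(c("##gff-version 3", "chr1\tonly\tthree"), bad)
  expect_error(genes_in_region(bad, candidate_region("chr1", 1, 100)),
               "malformed|GFF")
})
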