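#' Gene models overlapping a candidate region
#'
#' Imports gene features from a GFF3 file and returns those whose span
#' overlaps the region by at least 1 bp (so genes straddling a boundary are
#' included), sorted by start. Gene spans are used as annotated -- not
#' CDS-restricted. Descriptions matching `exclude` (a regular expression,
#' e.g. for transposon or hypothetical-protein models) can be dropped.
#'
#' @param gff path to a GFF3 file, or a `GRanges` already imported.
#' @param region one-row `candidate_regions` data frame (or any list with
#'   `chrom`, `start`, `end`).
#' @param feature_type GFF3 `type` to keep (default `"gene"`).
#' @param exclude optional regex; genes whose description matches are
#'   dropped.
#' @return data frame `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `description`; zero rows (with a warning) when the region's chromosome
#'   is absent from the annotation.
#' @export
genes_in_region <- function(gff, region, feature_type = "gene",
                            exclude = NULL) {
  gr <- if (methods::is(gff, "GRanges")) gff else
    tryCatch(rtracklayer::import(gff, format = "gff3"),
             error = function(e) stop_cfg("malformed GFF3 '", gff, "': ",
                                          conditionMessage(e)))
  gr <- gr[gr$type %in% feature_type]
  if (!region$chrom[1] %in% as.character(GenomicRanges::seqnames(gr))) {
    warning("chromosome ", region$chrom[1], " absent from the annotation",
            call. = FALSE)
    return(data.frame(gene_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      strand = character(), description = character()))
  }
  target <- GenomicRanges::GRanges(region$chrom[1],
                                   IRanges::IRanges(region$start[1],
                                                    region$end[1]))
  hits <- gr[IRanges::overlapsAny(gr, target, minoverlap = 1L)]
  ids <- if (!is.null(hits$ID)) hits$ID else
    if (!is.null(hits$Name)) hits$Name else as.character(seq_along(hits))
  desc <- if (!is.null(hits$description)) as.character(hits$description)
    else if (!is.null(hits$Note)) vapply(hits$Note, paste, "", collapse = "; ")
    else rep("", length(hits))
  out <- data.frame(gene_id = as.character(ids),
                    chrom = as.character(GenomicRanges::seqnames(hits)),
                    start = GenomicRanges::start(hits),
                    end = GenomicRanges::end(hits),
                    strand = as.character(GenomicRanges::strand(hits)),
                    description = desc)
  if (!is.null(exclude)) out <- out[!grepl(exclude, out$description), ]
  out <- out[order(out$start), ]
  rownames(out) <- NULL
  out
}

#' Count variant positions per gene
#'
#' Counts distinct variant positions overlapping each gene span (duplicated
#' positions are counted once, with the number of duplicates recorded), plus
#' the intergenic remainder, so that for non-overlapping genes the per-gene
#' counts and the intergenic count conserve the region-wide total.
#'
#' @param sites data frame with `chrom` and `pos` columns (e.g. from
#'   [snp_indices()] or a filtered variant table).
#' @param genes gene table from [genes_in_region()].
#' @return `genes` with an `n_variants` column; attributes `intergenic`
#'   (positions outside every gene), `total` (distinct positions) and
#'   `duplicates` (positions dropped as duplicated).
#' @export
variants_per_gene <- function(sites, genes) {
  key <- paste(sites$chrom, sites$pos)
  dup <- duplicated(key)
  s <- sites[!dup, , drop = FALSE]
  out <- genes
  if (nrow(genes)) {
    sgr <- GenomicRanges::GRanges(s$chrom, IRanges::IRanges(s$pos, s$pos))
    ggr <- GenomicRanges::GRanges(genes$chrom,
                                  IRanges::IRanges(genes$start, genes$end))
    out$n_variants <- GenomicRanges::countOverlaps(ggr, sgr)
    covered <- IRanges::overlapsAny(sgr, ggr)
  } else {
    covered <- rep(FALSE, nrow(s))
  }
  attr(out, "total") <- nrow(s)
  attr(out, "intergenic") <- sum(!covered)
  attr(out, "duplicates") <- sum(dup)
  out
}
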