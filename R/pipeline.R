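#' Run the end-to-end BSA-seq workflow from a config
#'
#' Executes the requested stages in dependency order -- `simulate`,
#' `phenotype`, `scan` (filter + indices + windows), `regions` (thresholds +
#' calling), `annotate`, `qpcr` -- and writes a JSON run manifest recording
#' the package version, the config snapshot, input checksums, the root seed,
#' per-stage runtimes and all output paths. Re-running with the same config
#' and seed reproduces byte-identical outputs.
#'
#' The config is a YAML file (or an equivalent named list) with an optional
#' `stages` vector plus per-stage blocks; stage inputs default to the
#' outputs of earlier stages (e.g. `scan` uses the simulated VCF when
#' `simulate` ran). See the package vignette for a full example.
#'
#' @param config path to a YAML config, or a named list.
#' @param out_dir output directory (overrides `config$out_dir`; default
#'   `"bulkscan_run"`).
#' @param seed root seed (overrides `config$seed`).
#' @return the manifest, invisibly (also written to
#'   `<out_dir>/manifest.json`).
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stop_cfg("config must be a YAML file path or a list")
  stages <- cfg$stages %||% c("simulate", "phenotype", "scan", "regions")
  known <- c("simulate", "phenotype", "scan", "regions", "annotate", "qpcr")
  if (!length(stages) || !all(stages %in% known))
    stop_cfg("stages must be drawn from: ", paste(known, collapse = ", "))
  out_dir <- out_dir %||% cfg$out_dir %||% "bulkscan_run"
  seed <- seed %||% cfg$seed %||% 1

  # fail before any work if a stage lacks its input
  if ("scan" %in% stages && !"simulate" %in% stages &&
      is.null(cfg$scan$vcf))
    stop_cfg("scan stage needs scan$vcf when simulate is not run")
  if ("phenotype" %in% stages && !"simulate" %in% stages &&
      is.null(cfg$phenotype$input))
    stop_cfg("phenotype stage needs phenotype$input when simulate is not run")
  if ("regions" %in% stages && !"scan" %in% stages)
    stop_cfg("regions stage needs the scan stage")
  if ("annotate" %in% stages && is.null(cfg$annotate$gff) &&
      !"simulate" %in% stages)
    stop_cfg("annotate stage needs annotate$gff when simulate is not run")
  if ("qpcr" %in% stages && is.null(cfg$qpcr$ct))
    stop_cfg("qpcr stage needs qpcr$ct")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(tool = "bulkscan",
                   version = as.character(utils::packageVersion("bulkscan")),
                   created = format(Sys.time(), tz = "UTC"),
                   seed = seed, config = cfg, inputs = list(),
                   runtimes = list(), outputs = list(), stages = stages)
  inputs <- c(scan_vcf = cfg$scan$vcf, phenotype = cfg$phenotype$input,
              gff = cfg$annotate$gff, ct = cfg$qpcr$ct)
  for (nm in names(inputs))
    manifest$inputs[[nm]] <- list(path = inputs[[nm]],
                                  md5 = unname(tools::md5sum(inputs[[nm]])))
  timed <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- expr
    manifest$runtimes[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  sim <- NULL; fit_windows <- NULL; regions <- NULL
  vcf_path <- cfg$scan$vcf; pheno_path <- cfg$phenotype$input
  gff_path <- cfg$annotate$gff
  scan_cfg <- cfg$scan %||% list()
  sim_args <- cfg$sim %||% list()
  chrom_lengths <- if (!is.null(scan_cfg$chrom_lengths))
    unlist(scan_cfg$chrom_lengths) else NULL
  bulk_size <- cfg$regions$bulk_size %||% sim_args$bulk_size %||% 50

  if ("simulate" %in% stages) {
    sim <- timed("simulate", {
      if (!is.null(sim_args$chrom_lengths))
        sim_args$chrom_lengths <- unlist(sim_args$chrom_lengths)
      if (!is.null(sim_args$qtl)) sim_args$qtl <- as.data.frame(sim_args$qtl)
      sim_args$seed <- seed
      simulate_bsa_dataset(do.call(sim_config, sim_args),
                           dir = file.path(out_dir, "sim"))
    })
    vcf_path <- vcf_path %||% sim$files$vcf
    pheno_path <- pheno_path %||% sim$files$phenotypes
    gff_path <- gff_path %||% sim$files$gff
    chrom_lengths <- chrom_lengths %||% sim$config$chrom_lengths
    bulk_size <- sim$config$bulk_size
    manifest$outputs$sim <- sim$files
  }

  if ("phenotype" %in% stages) {
    timed("phenotype", {
      ptab <- utils::read.delim(pheno_path)
      fert <- spikelet_fertility(ptab)
      stats_out <- summarize_fertility(fert[!is.na(fert)] / 100,
                                       scale = "proportion")
      bulks <- select_bulks(stats::setNames(fert, ptab$plant_id),
                            cfg$phenotype$bulk_size %||% bulk_size)
      ppath <- file.path(out_dir, "phenotype_summary.json")
      jsonlite::write_json(list(stats = unclass(stats_out),
                                tolerant_ids = bulks$tolerant_ids,
                                sensitive_ids = bulks$sensitive_ids,
                                range = bulks$range),
                           ppath, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      manifest$outputs$phenotype <- ppath
    })
  }

  if ("scan" %in% stages) {
    fit_windows <- timed("scan", {
      variants <- if (!is.null(sim)) sim$variants else
        read_bsa_vcf(vcf_path, samples = unlist(
          scan_cfg$samples %||% c(parent_a = "HHZ", parent_b = "9311",
                                  pool_t = "T_pool", pool_s = "S_pool")))
      if (is.null(chrom_lengths)) stop_cfg("scan needs chrom_lengths")
      fargs <- scan_cfg$filter %||% list()
      filt <- filter_effective(variants, do.call(filter_config, fargs))
      sites <- snp_indices(filt)
      win <- sliding_windows(sites, chrom_lengths,
                             window = scan_cfg$window %||% 5e5,
                             step = scan_cfg$step %||% 5e3,
                             min_snps = scan_cfg$min_snps %||% 3)
      write_sites_tsv(filt, file.path(out_dir, "sites.tsv"))
      manifest$outputs$scan <- list(
        sites = file.path(out_dir, "sites.tsv"),
        filter_report = as.list(filt$report))
      list(sites = sites, windows = win, filt = filt)
    })
  }

  if ("regions" %in% stages) {
    regions <- timed("regions", {
      rcfg <- cfg$regions %||% list()
      ncfg <- null_config(n_reps = rcfg$reps %||% 1000,
                          conf_levels = rcfg$conf_levels %||%
                            c(0.95, 0.99, 0.999),
                          bulk_size = bulk_size,
                          seq_error = rcfg$seq_error %||% 0.001,
                          seed = seed)
      win <- suppressWarnings(threshold_for_windows(fit_windows$windows, ncfg))
      regs <- call_regions(win, confidence = rcfg$confidence %||% 0.999,
                           index_t_min = rcfg$index_t_min %||% 0.7,
                           index_s_max = rcfg$index_s_max %||% 0.3,
                           criteria = rcfg$criteria %||% "window")
      wpath <- file.path(out_dir, "windows.tsv")
      rpath <- file.path(out_dir, "regions.tsv")
      bpath <- file.path(out_dir, "regions.bed")
      utils::write.table(format(win, digits = 10), wpath, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(format(as.data.frame(regs), digits = 10), rpath,
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_regions_bed(regs, bpath)
      manifest$outputs$regions <- list(windows = wpath, regions = rpath,
                                        bed = bpath)
      regs
    })
  }

  if ("annotate" %in% stages) {
    timed("annotate", {
      if (is.null(regions) || !nrow(regions)) {
        manifest$outputs$annotate <- "no regions to annotate"
      } else {
        tabs <- lapply(seq_len(nrow(regions)), function(i) {
          g <- genes_in_region(gff_path, regions[i, ],
                               exclude = cfg$annotate$exclude)
          if (!is.null(fit_windows))
            g <- variants_per_gene(fit_windows$sites[
              fit_windows$sites$chrom == regions$chrom[i], ], g)
          cbind(region = i, g)
        })
        gpath <- file.path(out_dir, "region_genes.tsv")
        utils::write.table(do.call(rbind, tabs), gpath, sep = "\t",
                           quote = FALSE, row.names = FALSE)
        manifest$outputs$annotate <- gpath
      }
    })
  }

  if ("qpcr" %in% stages) {
    timed("qpcr", {
      qc <- cfg$qpcr
      ct <- read_ct_table(qc$ct)
      rel <- relative_expression(ct, reference = qc$reference %||% "UBQ",
                                 calibrator_sample = qc$calibrator_sample,
                                 calibrator_timepoint = qc$calibrator_timepoint)
      qpath <- file.path(out_dir, "qpcr_expression.tsv")
      utils::write.table(rel, qpath, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      manifest$outputs$qpcr <- qpath
      if (!is.null(qc$compare)) {
        cmp <- compare_expression(rel, qc$compare[[1]], qc$compare[[2]])
        cpath <- file.path(out_dir, "qpcr_comparison.tsv")
        utils::write.table(cmp, cpath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        manifest$outputs$qpcr_comparison <- cpath
      }
    })
  }

  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
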