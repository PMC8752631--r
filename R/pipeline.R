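#' Pipeline configuration
#'
#' Bundles every input path and tunable of the end-to-end scan: filtering,
#' window tiling, the XP-CLR model, composite calling percentiles, ROH
#' parameters and side analyses. Inputs can be files (VCF + GFF3 +
#' population map) or in-memory objects (a [geno_matrix()] and a gene
#' tibble). The resolved configuration is written beside the outputs of
#' every run.
#'
#' @param out_dir Output directory (created if needed).
#' @param vcf,gff,population_map Input paths (ignored when `genotypes` /
#'   `genes` are supplied).
#' @param genotypes Optional [geno_matrix()] (bypasses `vcf` and
#'   `population_map`).
#' @param genes Optional gene tibble (bypasses `gff`).
#' @param wild,cultivar Population labels of the reference (wild) and object
#'   (cultivar) groups.
#' @param filter A [filter_rules()] object.
#' @param window_size,step Window tiling in bp.
#' @param min_snps Minimum SNPs per defined window (shared by the statistics
#'   and the scan).
#' @param q_xpclr,q_fst Top-percentile quantiles for the composite call.
#' @param xpclr An [xpclr_model()].
#' @param roh List of ROH parameters: `max_het`, `min_snps`,
#'   `min_length_bp`, `frac_threshold`.
#' @param ld List of LD-decay parameters: `max_dist`, `n_bins`.
#' @param seed Integer seed for any stochastic step.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, vcf = NULL, gff = NULL,
                            population_map = NULL, genotypes = NULL,
                            genes = NULL, wild = "wild",
                            cultivar = "cultivar",
                            filter = filter_rules(),
                            window_size = 50000, step = 20000,
                            min_snps = 10, q_xpclr = 0.95, q_fst = 0.95,
                            xpclr = xpclr_model(), roh = list(),
                            ld = list(), seed = 1) {
  roh <- utils::modifyList(
    list(max_het = 0, min_snps = 25, min_length_bp = 0,
         frac_threshold = 0.25), roh)
  ld <- utils::modifyList(list(max_dist = 300000, n_bins = 30), ld)
  if (is.null(genotypes) && (is.null(vcf) || is.null(population_map))) {
    stop("either `genotypes` or both `vcf` and `population_map` are ",
         "required", call. = FALSE)
  }
  structure(
    list(out_dir = out_dir, vcf = vcf, gff = gff,
         population_map = population_map, genotypes = genotypes,
         genes = genes, wild = wild, cultivar = cultivar, filter = filter,
         window_size = window_size, step = step, min_snps = min_snps,
         q_xpclr = q_xpclr, q_fst = q_fst, xpclr = xpclr, roh = roh,
         ld = ld, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

log_stage <- function(...) message("[sweepscan] ", ...)

#' Run the end-to-end sweep-detection pipeline
#'
#' Stages, in order: read inputs, apply site filters, sliding-window
#' diversity/differentiation statistics, XP-CLR scan, composite sweep
#' calling, block merging and gene annotation; then the side analyses (ROH
#' with terminal-run report, folded SFS per population, LD decay per
#' population). Stage tables are written incrementally to `out_dir` (TSV and
#' BED) together with the resolved configuration and a JSON report; per-
#' stage counts are logged to standard error. Deterministic given the
#' config and seed.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `sweep_pipeline` holding every stage result.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  gm <- if (!is.null(config$genotypes)) config$genotypes else {
    log_stage("reading VCF: ", config$vcf)
    read_vcf(config$vcf, config$population_map)
  }
  genes <- if (!is.null(config$genes)) config$genes else if (
    !is.null(config$gff)) {
    log_stage("reading annotation: ", config$gff)
    read_gff(config$gff)
  }

  log_stage("filtering ", n_sites(gm), " sites")
  gm_f <- apply_site_filters(gm, config$filter)
  fc <- filter_counts(gm_f)
  log_stage("retained ", fc[["sites_out"]], "/", fc[["sites_in"]],
            " sites (removed: ",
            paste(names(fc)[1:5], fc[1:5], sep = "=", collapse = ", "), ")")

  windows <- make_windows(gm_f$contigs, config$window_size, config$step)
  log_stage("computing window statistics over ", nrow(windows), " windows")
  ws <- window_stats(gm_f, windows = windows,
                     populations = c(config$wild, config$cultivar),
                     min_snps = config$min_snps)

  log_stage("XP-CLR scan (reference: ", config$wild, ", object: ",
            config$cultivar, ")")
  scan <- xpclr_scan(gm_f, config$wild, config$cultivar, windows = windows,
                     model = config$xpclr, min_snps = config$min_snps)
  ws <- dplyr::left_join(
    ws, scan[, c("chrom", "start", "end", "n_snps_used", "xpclr",
                 "xpclr_s_hat")],
    by = c("chrom", "start", "end"))
  write_window_table(ws, file.path(config$out_dir, "window_stats.tsv"))

  log_stage("composite sweep calling (top ",
            round(100 * (1 - config$q_xpclr)), "% XP-CLR, top ",
            round(100 * (1 - config$q_fst)), "% FST, D sign filter)")
  calls <- call_sweeps(ws, wild = config$wild, cultivar = config$cultivar,
                       q_xpclr = config$q_xpclr, q_fst = config$q_fst)
  log_stage(calls$n_selected, " windows selected of ", calls$n_defined,
            " defined")
  blocks <- merge_blocks(calls)
  readr::write_tsv(calls$selected,
                   file.path(config$out_dir, "selected_windows.tsv"))
  readr::write_tsv(calls$overlap,
                   file.path(config$out_dir, "diagnostic_overlap.tsv"))
  readr::write_tsv(calls$xpclr_selected,
                   file.path(config$out_dir, "diagnostic_xpclr_top.tsv"))

  annot <- NULL
  if (!is.null(genes)) {
    annot <- annotate_blocks(blocks, genes)
    blocks <- annot$blocks
    readr::write_tsv(annot$genes,
                     file.path(config$out_dir, "selected_genes.tsv"))
    log_stage(nrow(blocks), " blocks containing ",
              annot$summary$n_selected_genes, " genes (",
              annot$summary$pct_selected, "% of ",
              annot$summary$n_total_genes, ")")
  } else {
    log_stage(nrow(blocks), " blocks (no annotation supplied)")
  }
  block_flat <- blocks
  block_flat$gene_ids <- NULL
  readr::write_tsv(block_flat, file.path(config$out_dir, "sweep_blocks.tsv"))
  if (nrow(blocks) > 0) {
    write_bed(blocks[, c("chrom", "start", "end")],
              file.path(config$out_dir, "sweep_blocks.bed"))
  }

  roh_res <- NULL
  if (!is.null(genes) && any(genes$single_copy)) {
    log_stage("ROH scan on single-copy-gene SNPs")
    gm_sc <- select_single_copy_snps(gm_f, genes)
    runs <- call_roh(gm_sc, max_het = config$roh$max_het,
                     min_snps = config$roh$min_snps,
                     min_length_bp = config$roh$min_length_bp)
    term <- terminal_roh(runs, gm_sc,
                         frac_threshold = config$roh$frac_threshold,
                         min_snps = config$roh$min_snps)
    roh_res <- list(runs = runs, terminal = term)
    readr::write_tsv(runs, file.path(config$out_dir, "roh_runs.tsv"))
    readr::write_tsv(term$per_chromosome,
                     file.path(config$out_dir, "roh_terminal.tsv"))
  }

  log_stage("folded SFS and LD decay per population")
  sfs <- purrr::map_dfr(c(config$wild, config$cultivar), function(p) {
    dplyr::mutate(folded_sfs(gm_f, p), population = p)
  })
  readr::write_tsv(sfs, file.path(config$out_dir, "folded_sfs.tsv"))
  ld <- purrr::map_dfr(c(config$wild, config$cultivar), function(p) {
    dplyr::mutate(ld_decay(gm_f, p, max_dist = config$ld$max_dist,
                           n_bins = config$ld$n_bins), population = p)
  })
  readr::write_tsv(ld, file.path(config$out_dir, "ld_decay.tsv"))

  res <- structure(
    list(config = config, filter_counts = fc, windows = ws, calls = calls,
         blocks = blocks, annotation = annot, roh = roh_res, sfs = sfs,
         ld = ld, genotypes = gm_f),
    class = "sweep_pipeline"
  )
  write_config_json(config,
                    file.path(config$out_dir, "resolved_config.json"))
  pipeline_report(res, file.path(config$out_dir, "report.json"))
  res
}

write_config_json <- function(config, path) {
  cfg <- unclass(config)
  cfg$genotypes <- if (!is.null(cfg$genotypes)) "<in-memory>" else NULL
  cfg$genes <- if (!is.null(cfg$genes)) "<in-memory>" else NULL
  cfg$filter <- unclass(cfg$filter)
  cfg$xpclr <- unclass(cfg$xpclr)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
}

#' @export
print.sweep_pipeline <- function(x, ...) {
  cat("<sweep_pipeline>\n")
  cat("  sites: ", x$filter_counts[["sites_out"]], "/",
      x$filter_counts[["sites_in"]], " after filtering\n", sep = "")
  cat("  windows: ", nrow(x$windows), " (",
      sum(x$windows$defined), " defined), selected: ",
      x$calls$n_selected, "\n", sep = "")
  cat("  blocks: ", nrow(x$blocks), "\n", sep = "")
  if (!is.null(x$annotation)) {
    cat("  genes: ", x$annotation$summary$n_selected_genes, " of ",
        x$annotation$summary$n_total_genes, " (",
        x$annotation$summary$pct_selected, "%)\n", sep = "")
  }
  invisible(x)
}

#' One-row summary of a pipeline run
#' @param x A [run_pipeline()] result.
#' @param ... Unused.
#' @return One-row tibble with the headline counts and thresholds.
#' @method glance sweep_pipeline
#' @export
glance.sweep_pipeline <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      sites_in = unname(x$filter_counts[["sites_in"]]),
      sites_out = unname(x$filter_counts[["sites_out"]]),
      n_blocks = nrow(x$blocks),
      n_selected_genes = if (!is.null(x$annotation))
        x$annotation$summary$n_selected_genes else NA_integer_,
      pct_selected_genes = if (!is.null(x$annotation))
        x$annotation$summary$pct_selected else NA_real_),
    glance(x$calls))
}

#' Machine-readable report of a pipeline run
#'
#' Collects the headline numbers of a run — per-rule filter counts, window
#' and block counts, percentile thresholds, selected gene count and the
#' percentage of annotated genes under selection — into a stable JSON
#' structure.
#'
#' @param x A [run_pipeline()] result.
#' @param path Optional path to write the JSON to.
#' @return The report as a named list, invisibly when `path` is given.
#' @export
pipeline_report <- function(x, path = NULL) {
  stopifnot(inherits(x, "sweep_pipeline"))
  rep <- list(
    sites = list(
      input = unname(x$filter_counts[["sites_in"]]),
      retained = unname(x$filter_counts[["sites_out"]]),
      removed = as.list(x$filter_counts[
        c("biallelic", "qual", "depth", "missing", "maf")])),
    windows = list(
      total = nrow(x$windows),
      defined = sum(x$windows$defined),
      xpclr_top = nrow(x$calls$xpclr_selected),
      overlap = nrow(x$calls$overlap),
      selected = x$calls$n_selected),
    thresholds = list(
      xpclr = unname(x$calls$thresholds[["xpclr"]]),
      fst = unname(x$calls$thresholds[["fst"]])),
    blocks = list(count = nrow(x$blocks)),
    genes = if (!is.null(x$annotation)) list(
      selected = x$annotation$summary$n_selected_genes,
      total = x$annotation$summary$n_total_genes,
      pct_selected = x$annotation$summary$pct_selected)
    else list(selected = NA, total = NA, pct_selected = NA),
    roh = if (!is.null(x$roh)) list(
      n_runs = nrow(x$roh$runs),
      n_terminal_flagged = sum(x$roh$terminal$per_chromosome$flagged))
    else NULL
  )
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    return(invisible(rep))
  }
  rep
}
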