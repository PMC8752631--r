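#' Read a sample-to-population map
#'
#' Two-column TSV (`sample_id`, `population`), no header required.
#'
#' @param path TSV path (gzip accepted).
#' @return Named character vector mapping sample to population.
#' @export
read_population_map <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           col.names = c("sample", "population"),
                           colClasses = "character")
  first <- tolower(tab$sample[1])
  if (first %in% c("sample", "sample_id")) tab <- tab[-1, ]
  stats::setNames(tab$population, tab$sample)
}

#' Write a sample-to-population map
#' @param populations Named character vector (names are sample ids).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_population_map <- function(populations, path) {
  utils::write.table(
    data.frame(sample = names(populations), population = unname(populations)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a multi-sample VCF into a genotype matrix
#'
#' SNP records are parsed into haplotype calls (`"./."` becomes missing on
#' both haplotypes); multiallelic records are retained but flagged and
#' dropped by the default filters; indel records (REF or any ALT longer than
#' one base) are skipped. Positions stay 1-based. Contig lengths are taken
#' from `##contig` header lines when present.
#'
#' @param path VCF path (`.vcf` or `.vcf.gz`).
#' @param population_map Named character vector (as from
#'   [read_population_map()]) or path to the map file. Samples in the map
#'   must all be present in the VCF; the matrix is restricted to them.
#' @return A [geno_matrix()].
#' @export
read_vcf <- function(path, population_map) {
  if (is.character(population_map) && length(population_map) == 1 &&
      file.exists(population_map)) {
    population_map <- read_population_map(population_map)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  vcf_samples <- colnames(v@gt)[-1]
  absent <- setdiff(names(population_map), vcf_samples)
  if (length(absent) > 0) {
    stop("samples in the population map but absent from the VCF: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  samples <- names(population_map)

  snp <- nchar(fix$REF) == 1 &
    vapply(strsplit(fix$ALT, ",", fixed = TRUE),
           function(a) all(nchar(a) == 1), logical(1))
  fix <- fix[snp, , drop = FALSE]

  gt <- vcfR::extract.gt(v, element = "GT")[snp, samples, drop = FALSE]
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)[
    snp, samples, drop = FALSE]
  alleles <- strsplit(sub("\\|", "/", gt), "/", fixed = FALSE)
  bad <- lengths(alleles) != 2 & !is.na(as.vector(gt))
  if (any(bad)) {
    rec <- which(matrix(bad, nrow = nrow(gt)), arr.ind = TRUE)[1, 1]
    stop("malformed genotype call at record ", rec, call. = FALSE)
  }
  a1 <- vapply(alleles, function(x) if (length(x) == 2) x[1] else
    NA_character_, character(1))
  a2 <- vapply(alleles, function(x) if (length(x) == 2) x[2] else
    NA_character_, character(1))
  to_int <- function(a) {
    out <- suppressWarnings(as.integer(a))
    out  # "." becomes NA
  }
  h1 <- matrix(to_int(a1), nrow = nrow(gt))
  h2 <- matrix(to_int(a2), nrow = nrow(gt))
  haps <- matrix(0L, nrow(gt), 2 * length(samples))
  haps[, seq(1, ncol(haps), 2)] <- h1
  haps[, seq(2, ncol(haps), 2)] <- h2

  dp[is.na(dp)] <- 0
  dimnames(dp) <- NULL
  contigs <- parse_contig_lengths(v@meta)

  geno_matrix(haps,
              chrom = fix$CHROM, pos = as.integer(fix$POS),
              samples = samples, populations = population_map,
              ref = fix$REF, alt = fix$ALT,
              qual = suppressWarnings(as.numeric(fix$QUAL)),
              dp = dp, contigs = contigs)
}

parse_contig_lengths <- function(meta) {
  ln <- grep("^##contig", meta, value = TRUE)
  if (length(ln) == 0) return(NULL)
  ids <- sub(".*ID=([^,>]+).*", "\\1", ln)
  lens <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", ln)))
  if (anyNA(lens)) return(NULL)
  stats::setNames(lens, ids)
}

#' Write a genotype matrix as VCFv4.2
#'
#' One record per site with QUAL populated and `GT:DP` per sample; missing
#' calls are written `./.`. Contig lengths go into the header.
#'
#' @param gm A [geno_matrix()].
#' @param path Output path (plain text; use a `.vcf` name).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=sweepscan",
    paste0("##contig=<ID=", names(gm$contigs), ",length=",
           format(gm$contigs, scientific = FALSE, trim = TRUE), ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")
  )
  n <- n_sites(gm)
  if (n == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  h1 <- gm$haps[, seq(1, ncol(gm$haps), 2), drop = FALSE]
  h2 <- gm$haps[, seq(2, ncol(gm$haps), 2), drop = FALSE]
  gt <- matrix(paste0(ifelse(is.na(h1), ".", h1), "/",
                      ifelse(is.na(h2), ".", h2), ":", gm$dp),
               nrow = n)
  body <- paste(gm$sites$chrom, gm$sites$pos, ".", gm$sites$ref,
                gm$sites$alt,
                format(gm$sites$qual, scientific = FALSE, trim = TRUE),
                "PASS", ".", "GT:DP",
                apply(gt, 1, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Emit a simulation as VCF plus population map
#'
#' Applies the configured observation model (QUAL, depth, missingness) and
#' writes the sampled genotypes; deterministic given the config seed.
#'
#' @param sim A [simulate_domestication()] result.
#' @param vcf_path Output VCF path.
#' @param map_path Output population-map TSV path (default: alongside the
#'   VCF with suffix `.popmap.tsv`).
#' @return The emitted [geno_matrix()], invisibly.
#' @export
emit_vcf <- function(sim, vcf_path,
                     map_path = paste0(vcf_path, ".popmap.tsv")) {
  gm <- sim_genotype_matrix(sim, noise = TRUE)
  write_vcf(gm, vcf_path)
  write_population_map(gm$populations, map_path)
  invisible(gm)
}

#' Gene annotation for a simulated genome
#'
#' Tiles non-overlapping genes of `gene_length` bp every `gene_spacing` bp
#' along each chromosome and flags a `single_copy_frac` Bernoulli subset as
#' single-copy (the gene class the terminal-homozygosity scan is restricted
#' to). Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @param path Optional GFF3 output path.
#' @return A gene tibble (`chrom`, `start`, `end` 0-based half-open,
#'   `strand`, `gene_id`, `single_copy`), invisibly when `path` is given.
#' @export
emit_annotation <- function(config, path = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2000003L)
  genes <- purrr::map_dfr(seq_len(config$n_chrom), function(ci) {
    cn <- paste0("chr", ci)
    starts1 <- seq(1, config$chrom_length, by = config$gene_spacing)
    starts1 <- starts1[starts1 + config$gene_length - 1 <=
                         config$chrom_length]
    if (length(starts1) == 0) {
      return(tibble::tibble(chrom = character(), start = numeric(),
                            end = numeric(), strand = character(),
                            gene_id = character(), single_copy = logical()))
    }
    tibble::tibble(
      chrom = cn,
      start = starts1 - 1,                       # 0-based half-open
      end = starts1 + config$gene_length - 1,
      strand = "+",
      gene_id = sprintf("%s_g%03d", cn, seq_along(starts1)),
      single_copy = stats::runif(length(starts1)) < config$single_copy_frac
    )
  })
  if (!is.null(path)) write_gff(genes, path)
  invisible(genes)
}

#' Write a gene set as GFF3
#'
#' @param genes Gene tibble with 0-based half-open `start`/`end` (as from
#'   [emit_annotation()] or [read_gff()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(genes, path) {
  lines <- "##gff-version 3"
  if (nrow(genes) > 0) {
    lines <- c(lines, paste(
      genes$chrom, "sweepscan", "gene",
      format(genes$start + 1, scientific = FALSE, trim = TRUE),  # 1-based
      format(genes$end, scientific = FALSE, trim = TRUE),        # inclusive
      ".", genes$strand, ".",
      paste0("ID=", genes$gene_id, ";single_copy=",
             ifelse(genes$single_copy, "true", "false")),
      sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene features from a GFF3 file
#'
#' GFF3 1-based inclusive coordinates are converted to the package's internal
#' 0-based half-open convention (a gene annotated 1..100 becomes the interval
#' `(0, 100]` of length 100). Only `gene` features are kept. A
#' `single_copy=true` attribute sets the single-copy flag.
#'
#' @param path GFF3 path (gzip accepted).
#' @return A tibble: `chrom`, `start`, `end` (0-based half-open), `strand`,
#'   `gene_id`, `single_copy`.
#' @export
read_gff <- function(path) {
  g <- ape::read.gff(path)
  g <- g[g$type == "gene", , drop = FALSE]
  get_attr <- function(attr, key) {
    hit <- grepl(paste0("(^|;)\\s*", key, "="), attr)
    val <- sub(paste0("(^|.*;)\\s*", key, "=([^;]*).*"), "\\2", attr)
    ifelse(hit, val, NA_character_)
  }
  ids <- get_attr(as.character(g$attributes), "ID")
  if (anyNA(ids)) ids[is.na(ids)] <- paste0("gene", which(is.na(ids)))
  if (anyDuplicated(ids)) {
    stop("duplicated gene IDs in GFF: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  sc <- tolower(get_attr(as.character(g$attributes), "single_copy"))
  tibble::tibble(
    chrom = as.character(g$seqid),
    start = as.numeric(g$start) - 1,
    end = as.numeric(g$end),
    strand = as.character(g$strand),
    gene_id = ids,
    single_copy = !is.na(sc) & sc == "true"
  )
}

#' Write intervals as BED
#'
#' BED is 0-based half-open, matching the package's interval convention, so
#' coordinates are written as stored. Any `name` and `score` columns are
#' appended as BED columns 4 and 5.
#'
#' @param intervals Tibble with `chrom`, `start`, `end` (and optionally
#'   `name`, `score`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score"),
                    names(intervals))
  out <- intervals[, cols, drop = FALSE]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file
#'
#' @param path BED path (gzip accepted).
#' @return A tibble with `chrom`, `start`, `end` and, when present, `name`
#'   and `score` (coordinates kept 0-based half-open).
#' @export
read_bed <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  names(tab) <- c("chrom", "start", "end", "name", "score")[
    seq_len(min(5, ncol(tab)))]
  tibble::as_tibble(tab[, seq_len(min(5, ncol(tab))), drop = FALSE])
}

#' Write a window-statistics table as TSV
#'
#' Columns are written in a stable documented order: `chrom`, `start`,
#' `end`, `n_snps`, then the per-population diversity columns, `fst`, the
#' scan columns when present, and `defined`.
#'
#' @param tbl A window table from [window_stats()] (possibly joined with an
#'   XP-CLR scan).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_window_table <- function(tbl, path) {
  lead <- c("chrom", "start", "end", "n_snps")
  stat_cols <- grep("^(pi|theta|tajd)_", names(tbl), value = TRUE)
  rest <- intersect(c("fst", "xpclr", "xpclr_s_hat", "n_snps_used",
                      "defined"), names(tbl))
  extra <- setdiff(names(tbl), c(lead, stat_cols, rest))
  readr::write_tsv(tbl[, c(lead, stat_cols, rest, extra)], path)
  invisible(path)
}

#' Write the simulation truth set
#'
#' Sweep loci go to BED (0-based half-open single-bp intervals with the
#' selection coefficient as score); the config snapshot and outcome go to
#' JSON.
#'
#' @param sim A [simulate_domestication()] result.
#' @param bed_path,json_path Output paths.
#' @return `bed_path`, invisibly.
#' @export
write_truth <- function(sim, bed_path, json_path = NULL) {
  tr <- sim$truth
  bed <- tibble::tibble(chrom = tr$sweeps$chrom,
                        start = tr$sweeps$pos - 1,
                        end = tr$sweeps$pos,
                        name = paste0("sweep_s", tr$sweeps$s),
                        score = tr$sweeps$s)
  write_bed(bed, bed_path)
  if (!is.null(json_path)) {
    cfg <- tr$config
    cfg$sweep_loci <- NULL
    jsonlite::write_json(
      list(sweeps = tr$sweeps, n_founders = tr$n_founders, seed = tr$seed,
           initializer = tr$initializer, restarts = tr$restarts,
           config = unclass(cfg)),
      json_path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(bed_path)
}
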