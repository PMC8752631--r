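#' Restrict a genotype matrix to SNPs in single-copy genes
#'
#' Keeps SNPs whose position falls inside any gene flagged single-copy
#' (intervals 0-based half-open, so a SNP at the first base of a gene is
#' retained and one just past the end is not).
#'
#' @param gm A [geno_matrix()].
#' @param genes Gene tibble with a `single_copy` flag (from [read_gff()] or
#'   [emit_annotation()]).
#' @return The masked `geno_matrix` (with a warning and zero sites when no
#'   gene is flagged single-copy).
#' @export
select_single_copy_snps <- function(gm, genes) {
  sc <- genes[genes$single_copy, , drop = FALSE]
  if (nrow(sc) == 0) {
    warning("no single-copy genes in the annotation; returning an empty ",
            "matrix", call. = FALSE)
    return(subset_sites(gm, integer(0)))
  }
  keep <- logical(n_sites(gm))
  for (i in seq_len(nrow(sc))) {
    keep <- keep | (gm$sites$chrom == sc$chrom[i] &
                      gm$sites$pos > sc$start[i] &
                      gm$sites$pos <= sc$end[i])
  }
  subset_sites(gm, keep)
}

#' Call runs of homozygosity per sample
#'
#' Scans each sample's genotypes along each chromosome (missing calls are
#' transparent: skipped, neither breaking nor extending a run) for maximal
#' stretches of homozygous calls allowing up to `max_het` heterozygous
#' interruptions. Segmentation is greedy left-to-right: when the het budget
#' would be exceeded the run closes before the breaking het and a new run
#' starts at it; runs are trimmed to homozygous end points, so reported runs
#' never overlap. Runs are then filtered by `min_snps` and `min_length_bp`.
#'
#' @param gm A [geno_matrix()] (typically masked with
#'   [select_single_copy_snps()] first).
#' @param samples Samples to scan (default: all).
#' @param max_het Heterozygous calls tolerated inside a run (default 0).
#' @param min_snps Minimum homozygous+het SNPs per reported run (default 25).
#' @param min_length_bp Minimum run span in bp (default 0 = off).
#' @return A tibble of runs: `sample`, `chrom`, `start`, `end` (0-based
#'   half-open, spanning the first to last SNP of the run), `n_snps`,
#'   `n_het`, `terminal` (contains the first or last retained SNP of the
#'   chromosome).
#' @export
call_roh <- function(gm, samples = NULL, max_het = 0, min_snps = 25,
                     min_length_bp = 0) {
  if (is.null(samples)) samples <- gm$samples
  dos <- dosage_matrix(gm)
  out <- list()
  for (cn in unique(gm$sites$chrom)) {
    on_chrom <- which(gm$sites$chrom == cn)
    pos <- gm$sites$pos[on_chrom]
    for (smp in samples) {
      g <- dos[on_chrom, smp]
      called <- which(!is.na(g))
      if (length(called) == 0) next
      het <- g[called] == 1L
      runs <- segment_runs(het, max_het)
      for (rn in runs) {
        if (length(rn) == 0) next
        n_snp <- length(rn)
        n_het <- sum(het[rn])
        if (n_snp < min_snps) next
        first <- called[rn[1]]; last <- called[rn[n_snp]]
        span_start <- pos[first] - 1
        span_end <- pos[last]
        if (span_end - span_start < min_length_bp) next
        out[[length(out) + 1]] <- tibble::tibble(
          sample = smp, chrom = cn, start = span_start, end = span_end,
          n_snps = n_snp, n_het = n_het,
          terminal = first == called[1] ||
            last == called[length(called)])
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(sample = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          n_snps = integer(), n_het = integer(),
                          terminal = logical()))
  }
  dplyr::bind_rows(out)
}

## greedy left-to-right segmentation of a logical het vector into runs with
## <= max_het TRUE entries, trimmed to homozygous (FALSE) end points;
## returns a list of index vectors into `het`
segment_runs <- function(het, max_het) {
  runs <- list()
  i <- 1L
  n <- length(het)
  while (i <= n) {
    budget <- max_het
    j <- i
    while (j <= n) {
      if (het[j]) {
        if (budget == 0L) break
        budget <- budget - 1L
      }
      j <- j + 1L
    }
    seg <- if (j > i) i:(j - 1L) else integer(0)
    ## trim het end points
    while (length(seg) > 0 && het[seg[1]]) seg <- seg[-1]
    while (length(seg) > 0 && het[seg[length(seg)]]) {
      seg <- seg[-length(seg)]
    }
    if (length(seg) > 0) runs[[length(runs) + 1]] <- seg
    i <- if (j > i) j else i + 1L  # the breaking het starts the next run
  }
  runs
}

#' Terminal-homozygosity report
#'
#' Flags runs that contain the first or last retained SNP of their
#' chromosome and summarises, per sample and chromosome, the fraction of the
#' chromosome's SNP extent covered by terminal runs — the signature expected
#' under long clonal propagation with mitotic recombination, and absent when
#' only a few sexual generations separate cultivars from the wild.
#'
#' @param runs Run tibble from [call_roh()].
#' @param gm The same (masked) [geno_matrix()] the runs were called on
#'   (supplies the per-chromosome SNP extent).
#' @param frac_threshold A chromosome end is called "extensively homozygous"
#'   when a terminal run covers at least this fraction of the chromosome's
#'   SNP extent (default 0.25).
#' @param min_snps Chromosomes with fewer retained SNPs are excluded.
#' @return A list: `per_chromosome` (tibble: sample, chrom, terminal run
#'   length fraction, flag) and `summary` (per sample: number of
#'   chromosomes with a flagged terminal run).
#' @export
terminal_roh <- function(runs, gm, frac_threshold = 0.25, min_snps = 25) {
  chroms <- unique(gm$sites$chrom)
  extents <- purrr::map_dfr(chroms, function(cn) {
    pos <- gm$sites$pos[gm$sites$chrom == cn]
    tibble::tibble(chrom = cn, n_snps = length(pos),
                   ext_start = min(pos) - 1, ext_end = max(pos))
  })
  extents <- extents[extents$n_snps >= min_snps, , drop = FALSE]
  samples <- gm$samples
  per <- purrr::map_dfr(seq_len(nrow(extents)), function(i) {
    ext <- extents[i, ]
    span <- ext$ext_end - ext$ext_start
    purrr::map_dfr(samples, function(smp) {
      r <- runs[runs$sample == smp & runs$chrom == ext$chrom &
                  runs$terminal, , drop = FALSE]
      frac <- if (nrow(r) == 0) 0 else
        max((r$end - r$start) / span)
      tibble::tibble(sample = smp, chrom = ext$chrom,
                     n_snps = ext$n_snps,
                     terminal_frac = frac,
                     flagged = frac >= frac_threshold)
    })
  })
  summary <- dplyr::summarise(
    dplyr::group_by(per, .data$sample),
    n_chrom = dplyr::n(),
    n_flagged = sum(.data$flagged),
    max_terminal_frac = max(.data$terminal_frac),
    .groups = "drop")
  list(per_chromosome = per, summary = summary)
}
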