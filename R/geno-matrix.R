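#' Genotype matrix container
#'
#' A `geno_matrix` holds diploid genotype calls for a set of samples at a set
#' of biallelic (or flagged multiallelic) SNP sites, together with per-site
#' metadata (chromosome, 1-based position, REF/ALT, QUAL), per-sample
#' sequencing depth, and a sample-to-population map. It is the object every
#' statistic in the package consumes.
#'
#' Site positions are stored 1-based (VCF convention); all interval outputs
#' (windows, genes, blocks, BED) use 0-based half-open coordinates, so a site
#' at position `p` falls in interval `(start, end]` when `start < p <= end`.
#'
#' @param haps Integer matrix, sites x (2 * n_samples). Haplotype allele codes
#'   (0 = REF, 1 = ALT, larger codes for multiallelic records, `NA` = missing).
#'   Columns are ordered sample1-hapA, sample1-hapB, sample2-hapA, ...
#' @param chrom Character vector of chromosome names, one per site.
#' @param pos Integer vector of 1-based positions, one per site.
#' @param samples Character vector of sample identifiers.
#' @param populations Named character vector mapping every sample to exactly
#'   one population.
#' @param ref,alt Allele strings per site (defaults "A"/"T"). A comma in `alt`
#'   marks a multiallelic record.
#' @param qual Numeric site quality, one per site (default 60).
#' @param dp Integer matrix of per-sample read depth, sites x n_samples
#'   (default: constant 20).
#' @param contigs Optional named numeric vector of chromosome lengths in bp.
#'   When absent, lengths are inferred as the maximum observed position.
#'
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(haps, chrom, pos, samples, populations,
                        ref = NULL, alt = NULL, qual = NULL, dp = NULL,
                        contigs = NULL) {
  haps <- as.matrix(haps)
  storage.mode(haps) <- "integer"
  n_sites <- nrow(haps)
  stopifnot(length(chrom) == n_sites, length(pos) == n_sites)
  if (ncol(haps) != 2L * length(samples)) {
    stop("`haps` must have two columns per sample", call. = FALSE)
  }
  if (!all(samples %in% names(populations))) {
    missing_samp <- setdiff(samples, names(populations))
    stop("samples missing from the population map: ",
         paste(missing_samp, collapse = ", "), call. = FALSE)
  }
  populations <- populations[samples]
  if (is.null(ref)) ref <- rep("A", n_sites)
  if (is.null(alt)) alt <- rep("T", n_sites)
  if (is.null(qual)) qual <- rep(60, n_sites)
  if (is.null(dp)) {
    dp <- matrix(20L, nrow = n_sites, ncol = length(samples))
  }
  dp <- as.matrix(dp)
  storage.mode(dp) <- "integer"
  stopifnot(nrow(dp) == n_sites, ncol(dp) == length(samples))

  sites <- tibble::tibble(
    chrom = as.character(chrom),
    pos = as.integer(pos),
    ref = as.character(ref),
    alt = as.character(alt),
    qual = as.numeric(qual),
    multiallelic = grepl(",", alt, fixed = TRUE)
  )

  ## enforce sorted, strictly increasing positions within chromosome
  ord <- order(sites$chrom, sites$pos)
  if (!identical(ord, seq_len(n_sites))) {
    sites <- sites[ord, ]
    haps <- haps[ord, , drop = FALSE]
    dp <- dp[ord, , drop = FALSE]
  }
  dup <- duplicated(paste(sites$chrom, sites$pos))
  if (any(dup)) {
    stop("duplicated site positions within a chromosome: ",
         paste(utils::head(paste0(sites$chrom[dup], ":", sites$pos[dup]), 3),
               collapse = ", "), call. = FALSE)
  }
  if (is.null(contigs)) {
    contigs <- tapply(sites$pos, sites$chrom, max)
    contigs <- stats::setNames(as.numeric(contigs), names(contigs))
  }
  colnames(haps) <- paste0(rep(samples, each = 2), c("_1", "_2"))
  colnames(dp) <- samples

  structure(
    list(sites = sites, haps = haps, dp = dp, samples = samples,
         populations = populations, contigs = contigs),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix> ", nrow(x$sites), " sites x ", length(x$samples),
      " samples (", length(unique(x$sites$chrom)), " chromosome",
      if (length(unique(x$sites$chrom)) != 1) "s", ")\n", sep = "")
  tab <- table(x$populations)
  cat("populations: ",
      paste(names(tab), "=", as.integer(tab), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of sites / samples in a genotype matrix
#' @param gm A [geno_matrix()].
#' @return An integer count.
#' @export
n_sites <- function(gm) nrow(gm$sites)

#' @rdname n_sites
#' @export
n_samples <- function(gm) length(gm$samples)

#' Samples belonging to a population
#' @param gm A [geno_matrix()].
#' @param population Population label.
#' @return Character vector of sample names.
#' @export
pop_samples <- function(gm, population) {
  out <- gm$samples[gm$populations == population]
  if (length(out) == 0) {
    stop("no samples in population '", population, "'", call. = FALSE)
  }
  out
}

## haplotype column indices for a population (or all samples)
hap_cols <- function(gm, population = NULL) {
  samp <- if (is.null(population)) gm$samples else pop_samples(gm, population)
  idx <- match(samp, gm$samples)
  as.vector(rbind(2L * idx - 1L, 2L * idx))
}

#' Keep a subset of sites
#' @param gm A [geno_matrix()].
#' @param idx Logical or integer site index.
#' @return A `geno_matrix` with the selected sites.
#' @export
subset_sites <- function(gm, idx) {
  gm$sites <- gm$sites[idx, ]
  gm$haps <- gm$haps[idx, , drop = FALSE]
  gm$dp <- gm$dp[idx, , drop = FALSE]
  gm
}

## integer site indices falling in a 0-based half-open interval
sites_in_interval <- function(gm, chrom, start, end) {
  which(gm$sites$chrom == chrom & gm$sites$pos > start & gm$sites$pos <= end)
}

#' Per-site allele counts for one population
#'
#' @param gm A [geno_matrix()].
#' @param population Population label (default: all samples).
#' @return A tibble with one row per site: `k` (ALT allele count over
#'   non-missing haplotypes) and `m` (non-missing allele count).
#' @export
allele_counts <- function(gm, population = NULL) {
  h <- gm$haps[, hap_cols(gm, population), drop = FALSE]
  tibble::tibble(
    k = as.integer(rowSums(h == 1L, na.rm = TRUE)),
    m = as.integer(rowSums(!is.na(h)))
  )
}

## per-site diploid counts: n_ind (both haplotypes called), n_het, alt freq
diploid_counts <- function(gm, population) {
  cols <- hap_cols(gm, population)
  h1 <- gm$haps[, cols[c(TRUE, FALSE)], drop = FALSE]
  h2 <- gm$haps[, cols[c(FALSE, TRUE)], drop = FALSE]
  ok <- !is.na(h1) & !is.na(h2)
  n_ind <- rowSums(ok)
  het <- rowSums(ok & (h1 != h2), na.rm = TRUE)
  k <- rowSums(ifelse(ok, h1 + h2, 0L))
  list(n_ind = n_ind, n_het = het, k = k)
}

#' Genotype dosage matrix
#'
#' @param gm A [geno_matrix()].
#' @param population Population label (default: all samples).
#' @return Integer matrix sites x individuals of ALT-allele dosage (0/1/2,
#'   `NA` when either haplotype call is missing).
#' @export
dosage_matrix <- function(gm, population = NULL) {
  cols <- hap_cols(gm, population)
  h1 <- gm$haps[, cols[c(TRUE, FALSE)], drop = FALSE]
  h2 <- gm$haps[, cols[c(FALSE, TRUE)], drop = FALSE]
  d <- h1 + h2
  colnames(d) <- sub("_1$", "", colnames(h1))
  d
}

#' @importFrom tibble as_tibble
#' @method as_tibble geno_matrix
#' @export
as_tibble.geno_matrix <- function(x, ...) {
  ac <- allele_counts(x)
  dplyr::bind_cols(x$sites, ac)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a genotype matrix into long per-sample genotype records
#'
#' @param x A [geno_matrix()].
#' @param ... Unused.
#' @return A tibble with one row per site x sample: chromosome, position,
#'   sample, population, dosage (0/1/2 or NA) and depth.
#' @method tidy geno_matrix
#' @export
tidy.geno_matrix <- function(x, ...) {
  d <- dosage_matrix(x)
  tibble::tibble(
    chrom = rep(x$sites$chrom, times = length(x$samples)),
    pos = rep(x$sites$pos, times = length(x$samples)),
    sample = rep(x$samples, each = nrow(x$sites)),
    population = rep(unname(x$populations), each = nrow(x$sites)),
    dosage = as.integer(d),
    dp = as.integer(x$dp)
  )
}

#' One-row summary of a genotype matrix
#'
#' @param x A [geno_matrix()].
#' @param ... Unused.
#' @return A one-row tibble: site, sample and chromosome counts, missing-call
#'   fraction and median depth.
#' @method glance geno_matrix
#' @export
glance.geno_matrix <- function(x, ...) {
  tibble::tibble(
    n_sites = nrow(x$sites),
    n_samples = length(x$samples),
    n_chrom = length(unique(x$sites$chrom)),
    missing_frac = mean(is.na(x$haps)),
    median_dp = stats::median(x$dp, na.rm = TRUE)
  )
}
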