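#' Tile sliding windows along chromosomes
#'
#' Windows start at 0, advance by `step`, and are truncated at the chromosome
#' end; the final partial window is kept (its per-bp statistics use the true
#' span). A chromosome shorter than `step` yields a single window covering it.
#' Coordinates are 0-based half-open.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp, or a
#'   data frame with columns `chrom` and `length`.
#' @param size Window size in bp (default 50 kb).
#' @param step Step between window starts in bp (default 20 kb).
#' @return A tibble with columns `chrom`, `start`, `end`.
#' @export
make_windows <- function(chrom_lengths, size = 50000, step = 20000) {
  stopifnot(size >= step, step > 0)
  if (is.data.frame(chrom_lengths)) {
    chrom_lengths <- stats::setNames(chrom_lengths$length, chrom_lengths$chrom)
  }
  purrr::map_dfr(names(chrom_lengths), function(cn) {
    len <- chrom_lengths[[cn]]
    starts <- seq(0, by = step, length.out = max(1L, ceiling(len / step)))
    starts <- starts[starts < len]
    tibble::tibble(chrom = cn, start = starts, end = pmin(starts + size, len))
  })
}

#' Tajima (1989) normalization constants
#'
#' @param n Number of sampled haplotypes (>= 2).
#' @return Named list with `a1`, `a2`, `b1`, `b2`, `c1`, `c2`, `e1`, `e2`.
#' @export
tajima_constants <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

## per-site mean pairwise difference: 2*p*q*m/(m-1) = 2k(m-k)/(m(m-1))
site_pairwise_diff <- function(k, m) {
  out <- numeric(length(k))
  ok <- m >= 2
  out[ok] <- 2 * k[ok] * (m[ok] - k[ok]) / (m[ok] * (m[ok] - 1))
  out
}

#' Nucleotide diversity in a window
#'
#' pi per bp: the window sum of per-site mean pairwise differences
#' `2*p*q*n/(n-1)` (with `n` the site's non-missing allele count) divided by
#' the window span. Monomorphic and missing-heavy (`n < 2`) sites contribute 0.
#'
#' @param gm A [geno_matrix()].
#' @param chrom Chromosome name.
#' @param start,end Window bounds, 0-based half-open.
#' @param population Population label (default: all samples).
#' @return pi per bp (`NA` if no site has two called alleles).
#' @export
nucleotide_diversity <- function(gm, chrom, start, end, population = NULL) {
  idx <- sites_in_interval(gm, chrom, start, end)
  ac <- allele_counts(subset_sites(gm, idx), population)
  if (length(idx) > 0 && all(ac$m < 2)) return(NA_real_)
  sum(site_pairwise_diff(ac$k, ac$m)) / (end - start)
}

#' Watterson's theta in a window
#'
#' theta_W per bp: `S / a1(n) / span`, with `S` the number of segregating
#' sites in the population and `n` the modal non-missing allele count over
#' those sites.
#'
#' @inheritParams nucleotide_diversity
#' @return theta_W per bp (0 when `S = 0`, `NA` when no usable site).
#' @export
wattersons_theta <- function(gm, chrom, start, end, population = NULL) {
  idx <- sites_in_interval(gm, chrom, start, end)
  ac <- allele_counts(subset_sites(gm, idx), population)
  seg <- ac$m >= 2 & ac$k > 0 & ac$k < ac$m
  if (!any(seg)) {
    if (length(idx) > 0 && all(ac$m < 2)) return(NA_real_)
    return(0)
  }
  n <- modal_value(ac$m[seg])
  sum(seg) / tajima_constants(n)$a1 / (end - start)
}

modal_value <- function(x) {
  tab <- table(x)
  as.integer(names(tab)[which.max(tab)])
}

#' Tajima's D in a window
#'
#' Standard Tajima (1989) statistic
#' `D = (Pi - S/a1) / sqrt(e1*S + e2*S*(S-1))`, where `Pi` is the window sum
#' of per-site mean pairwise differences. Only sites segregating in the
#' population with at least 4 non-missing alleles are used; the constants use
#' the minimum non-missing allele count across used sites (conservative
#' handling of missing data).
#'
#' @inheritParams nucleotide_diversity
#' @return D, or `NA` when `S = 0` (undefined, deliberately not 0) or fewer
#'   than 4 alleles are available.
#' @export
tajimas_d <- function(gm, chrom, start, end, population = NULL) {
  idx <- sites_in_interval(gm, chrom, start, end)
  ac <- allele_counts(subset_sites(gm, idx), population)
  tajimas_d_counts(ac$k, ac$m)
}

## D from per-site allele counts (k alt of m called)
tajimas_d_counts <- function(k, m) {
  used <- m >= 4 & k > 0 & k < m
  s <- sum(used)
  if (s == 0) return(NA_real_)
  n <- min(m[used])
  cc <- tajima_constants(n)
  ppi <- sum(site_pairwise_diff(k[used], m[used]))
  denom <- sqrt(cc$e1 * s + cc$e2 * s * (s - 1))
  if (denom == 0) return(NA_real_)
  (ppi - s / cc$a1) / denom
}

#' Weir-Cockerham FST in a window
#'
#' Two-population Weir & Cockerham (1984) estimator. Per-site variance
#' components `a` (among populations), `b` (among individuals within
#' populations) and `c` (within individuals) are computed from sample sizes,
#' allele frequencies and observed heterozygosity; the window estimate is the
#' ratio of sums `sum(a) / sum(a + b + c)`. Negative estimates are reported
#' as computed, not clamped.
#'
#' @inheritParams nucleotide_diversity
#' @param pop_a,pop_b The two population labels.
#' @return The window FST (`NA` when the denominator is not positive).
#' @export
weir_cockerham_fst <- function(gm, chrom, start, end, pop_a, pop_b) {
  idx <- sites_in_interval(gm, chrom, start, end)
  sub <- subset_sites(gm, idx)
  comp <- wc_components(diploid_counts(sub, pop_a), diploid_counts(sub, pop_b))
  denom <- sum(comp$a + comp$b + comp$c, na.rm = TRUE)
  if (!is.finite(denom) || denom <= 0) return(NA_real_)
  sum(comp$a, na.rm = TRUE) / denom
}

#' Per-site Weir-Cockerham variance components
#'
#' @param d1,d2 Per-population per-site diploid summaries: lists with `n_ind`
#'   (called individuals), `n_het` (heterozygotes) and `k` (ALT allele count),
#'   as produced internally from a [geno_matrix()]. Exposed mainly so the
#'   components can be checked against hand-evaluated examples.
#' @return A list of numeric vectors `a`, `b`, `c` (NA at sites where the
#'   estimator is undefined, e.g. fewer than 2 individuals overall).
#' @keywords internal
wc_components <- function(d1, d2) {
  r <- 2
  n1 <- d1$n_ind; n2 <- d2$n_ind
  p1 <- ifelse(n1 > 0, d1$k / (2 * n1), NA_real_)
  p2 <- ifelse(n2 > 0, d2$k / (2 * n2), NA_real_)
  h1 <- ifelse(n1 > 0, d1$n_het / n1, NA_real_)
  h2 <- ifelse(n2 > 0, d2$n_het / n2, NA_real_)
  nbar <- (n1 + n2) / r
  ok <- n1 > 0 & n2 > 0 & nbar > 1
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  a[!ok] <- NA_real_; b[!ok] <- NA_real_; cc[!ok] <- NA_real_
  list(a = a, b = b, c = cc)
}

#' Sliding-window diversity and differentiation table
#'
#' Computes, for every window, the SNP count, per-population nucleotide
#' diversity, Watterson's theta and Tajima's D, and (when the matrix holds
#' exactly two populations or `fst_pops` is given) the Weir-Cockerham FST.
#' Windows with fewer than `min_snps` SNPs are flagged `defined = FALSE`
#' and are excluded from percentile ranking downstream.
#'
#' @param gm A [geno_matrix()].
#' @param size,step Window size and step in bp.
#' @param windows Optional precomputed window tibble from [make_windows()];
#'   when `NULL`, windows are tiled over `gm$contigs`.
#' @param populations Populations to summarise (default: all in `gm`).
#' @param fst_pops Length-2 character vector naming the FST pair (default:
#'   `populations` when exactly two).
#' @param min_snps Minimum SNPs for a window to be `defined` (default 10).
#' @return A tibble: `chrom`, `start`, `end`, `n_snps`, then `pi_<pop>`,
#'   `theta_<pop>`, `tajd_<pop>` per population, `fst`, and `defined`.
#' @export
window_stats <- function(gm, size = 50000, step = 20000, windows = NULL,
                         populations = NULL, fst_pops = NULL, min_snps = 10) {
  if (is.null(windows)) windows <- make_windows(gm$contigs, size, step)
  if (is.null(populations)) populations <- unique(unname(gm$populations))
  if (is.null(fst_pops) && length(populations) == 2) fst_pops <- populations

  ac_pool <- allele_counts(gm)
  ac_pop <- lapply(stats::setNames(populations, populations),
                   function(p) allele_counts(gm, p))
  dip <- if (!is.null(fst_pops)) {
    lapply(stats::setNames(fst_pops, fst_pops),
           function(p) diploid_counts(gm, p))
  }
  comp <- if (!is.null(fst_pops)) wc_components(dip[[1]], dip[[2]])

  rows <- purrr::pmap_dfr(windows, function(chrom, start, end) {
    idx <- sites_in_interval(gm, chrom, start, end)
    span <- end - start
    kp <- ac_pool$k[idx]; mp <- ac_pool$m[idx]
    n_snps <- sum(mp >= 2 & kp > 0 & kp < mp)
    out <- list(chrom = chrom, start = start, end = end, n_snps = n_snps)
    for (p in populations) {
      k <- ac_pop[[p]]$k[idx]; m <- ac_pop[[p]]$m[idx]
      seg <- m >= 2 & k > 0 & k < m
      out[[paste0("pi_", p)]] <- sum(site_pairwise_diff(k, m)) / span
      out[[paste0("theta_", p)]] <- if (any(seg)) {
        sum(seg) / tajima_constants(modal_value(m[seg]))$a1 / span
      } else 0
      out[[paste0("tajd_", p)]] <- tajimas_d_counts(k, m)
    }
    if (!is.null(fst_pops)) {
      a <- comp$a[idx]; b <- comp$b[idx]; cc <- comp$c[idx]
      poly <- kp > 0 & kp < mp
      denom <- sum((a + b + cc)[poly], na.rm = TRUE)
      out$fst <- if (is.finite(denom) && denom > 0) {
        sum(a[poly], na.rm = TRUE) / denom
      } else NA_real_
    }
    tibble::as_tibble(out)
  })
  rows$defined <- rows$n_snps >= min_snps
  rows
}

#' Date a divergence or duplication from synonymous substitutions
#'
#' `T = Ks / (2 r)`: the age in years of a split (or whole-genome
#' duplication) given the synonymous substitutions per site `Ks` between the
#' diverged copies and the synonymous substitution rate `r` per site per year.
#'
#' @param ks Synonymous substitutions per site (>= 0). Vectorised.
#' @param r Synonymous substitution rate per site per year (> 0).
#' @return Age in years.
#' @export
divergence_date <- function(ks, r) {
  if (any(r <= 0)) stop("substitution rate `r` must be positive", call. = FALSE)
  stopifnot(all(ks >= 0))
  ks / (2 * r)
}
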