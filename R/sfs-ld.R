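#' Folded site frequency spectrum
#'
#' Counts polymorphic sites by minor-allele count at a fixed number of sampled
#' alleles `n`. Sites where fewer than `n` alleles are called are either
#' dropped (`mode = "drop"`, default) or projected down to `n` alleles by the
#' expected hypergeometric subsample (`mode = "project"`, which yields
#' fractional counts; mass projected onto the monomorphic bins is discarded).
#'
#' @param gm A [geno_matrix()].
#' @param population Population label (default: all samples).
#' @param n Number of alleles of the spectrum (default: two per sampled
#'   individual of the population). Must be >= 2.
#' @param mode `"drop"` or `"project"` (how sites with missing calls enter).
#' @return A tibble with `minor_count` (1 .. floor(n/2)) and `count`; the
#'   counts sum to the number of polymorphic sites used (exactly for
#'   `"drop"`, up to projected-out mass for `"project"`).
#' @export
folded_sfs <- function(gm, population = NULL, n = NULL,
                       mode = c("drop", "project")) {
  mode <- match.arg(mode)
  samp <- if (is.null(population)) gm$samples else pop_samples(gm, population)
  if (is.null(n)) n <- 2L * length(samp)
  n <- as.integer(n)
  if (n < 2) stop("folded SFS needs at least n = 2 alleles", call. = FALSE)
  ac <- allele_counts(gm, population)
  bins <- seq_len(n %/% 2L)
  counts <- numeric(length(bins))

  if (mode == "drop") {
    use <- ac$m == n & ac$k > 0 & ac$k < n
    mac <- pmin(ac$k[use], n - ac$k[use])
    tab <- table(factor(mac, levels = bins))
    counts <- as.numeric(tab)
  } else {
    use <- which(ac$m >= n & ac$k > 0 & ac$k < ac$m)
    for (i in use) {
      k <- ac$k[i]; m <- ac$m[i]
      j <- 0:n
      pj <- stats::dhyper(j, k, m - k, n)
      fold <- pmin(j, n - j)
      for (b in bins) counts[b] <- counts[b] + sum(pj[fold == b])
    }
  }
  tibble::tibble(minor_count = bins, count = counts)
}

#' Neutral expectation of the folded SFS
#'
#' Under the standard neutral model the expected count of sites with derived
#' allele count `i` is proportional to `1/i`; folding gives mass proportional
#' to `1/i + 1/(n-i)` for `i < n/2` and `1/i` at `i = n/2`. Returned as
#' probabilities over the folded bins, for goodness-of-fit checks against an
#' observed spectrum.
#'
#' @param n Number of sampled alleles.
#' @return Numeric vector of length `floor(n/2)` summing to 1.
#' @export
neutral_folded_sfs <- function(n) {
  bins <- seq_len(n %/% 2L)
  w <- (1 / bins + 1 / (n - bins)) / (1 + (bins == n - bins))
  w / sum(w)
}

#' LD decay: mean r-squared by physical distance
#'
#' Genotype-based composite linkage disequilibrium: the squared Pearson
#' correlation of diploid ALT dosages (phase-free), computed for all
#' intra-chromosome site pairs within `max_dist` and averaged in distance
#' bins. Monomorphic sites (and pairs without two complete observations) are
#' skipped.
#'
#' @param gm A [geno_matrix()].
#' @param population Population label (default: all samples).
#' @param max_dist Maximum pair distance in bp (default 300 kb).
#' @param n_bins Number of equal-width distance bins.
#' @param max_sites Per-chromosome cap on sites used (evenly thinned) to keep
#'   the pair count tractable; default 2000.
#' @return A tibble: `dist_lo`, `dist_hi`, `dist_mid`, `mean_r2`, `n_pairs`.
#' @export
ld_decay <- function(gm, population = NULL, max_dist = 300000, n_bins = 30,
                     max_sites = 2000) {
  if (n_sites(gm) < 2) stop("LD decay needs at least 2 SNPs", call. = FALSE)
  dos <- dosage_matrix(gm, population)
  breaks <- seq(0, max_dist, length.out = n_bins + 1)
  sums <- numeric(n_bins); npair <- integer(n_bins)

  for (cn in unique(gm$sites$chrom)) {
    on_chrom <- which(gm$sites$chrom == cn)
    if (length(on_chrom) > max_sites) {
      on_chrom <- on_chrom[round(seq(1, length(on_chrom),
                                     length.out = max_sites))]
    }
    pos <- gm$sites$pos[on_chrom]
    d <- dos[on_chrom, , drop = FALSE]
    sdv <- apply(d, 1, stats::sd, na.rm = TRUE)
    keep <- !is.na(sdv) & sdv > 0
    pos <- pos[keep]; d <- d[keep, , drop = FALSE]
    if (length(pos) < 2) next
    r2 <- suppressWarnings(stats::cor(t(d), use = "pairwise.complete.obs"))^2
    dist <- abs(outer(pos, pos, "-"))
    ut <- upper.tri(dist)
    sel <- ut & dist <= max_dist & dist > 0 & !is.na(r2)
    bin <- findInterval(dist[sel], breaks, rightmost.closed = TRUE,
                        left.open = TRUE)
    ok <- bin >= 1 & bin <= n_bins
    sums <- sums + as.numeric(tapply(r2[sel][ok], factor(bin[ok],
                                                         levels = 1:n_bins),
                                     sum, default = 0))
    npair <- npair + as.integer(table(factor(bin[ok], levels = 1:n_bins)))
  }
  tibble::tibble(
    dist_lo = breaks[-length(breaks)],
    dist_hi = breaks[-1],
    dist_mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
    mean_r2 = ifelse(npair > 0, sums / npair, NA_real_),
    n_pairs = npair
  )
}
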