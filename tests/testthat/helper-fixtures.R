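## Small in-code fixtures shared across the suite.

## geno_matrix from a sites x haplotypes matrix, two populations of equal
## size unless `pops` given
toy_gm <- function(haps, pos = NULL, chrom = NULL, pops = NULL,
                   qual = NULL, dp = NULL, alt = NULL, contigs = NULL) {
  haps <- as.matrix(haps)
  n_samp <- ncol(haps) / 2
  samples <- sprintf("s%02d", seq_len(n_samp))
  if (is.null(pops)) {
    pops <- stats::setNames(
      rep_len(rep(c("wild", "cultivar"), each = ceiling(n_samp / 2)), n_samp),
      samples)
  } else {
    pops <- stats::setNames(rep_len(pops, n_samp), samples)
  }
  if (is.null(pos)) pos <- seq_len(nrow(haps)) * 100L
  if (is.null(chrom)) chrom <- rep("chr1", nrow(haps))
  geno_matrix(haps, chrom = chrom, pos = pos, samples = samples,
              populations = pops, qual = qual, dp = dp, alt = alt,
              contigs = contigs)
}

## random biallelic haplotype matrix (no missing data)
random_haps <- function(n_sites, n_haps, maf_min = 0.05) {
  h <- matrix(0L, n_sites, n_haps)
  for (i in seq_len(n_sites)) {
    k <- sample(seq_len(n_haps - 1), 1)
    h[i, sample.int(n_haps, k)] <- 1L
  }
  h
}

## brute-force pi per bp: mean pairwise Hamming distance over all haplotype
## pairs, divided by span (independent oracle for nucleotide_diversity)
brute_pi <- function(haps, span) {
  n <- ncol(haps)
  tot <- 0
  np <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(haps[, i]) & !is.na(haps[, j])
      if (!any(ok)) next
      tot <- tot + sum(haps[ok, i] != haps[ok, j])
      np <- np + 1
    }
  }
  tot / np / span
}

## independent direct-summation evaluation of the Tajima constants
brute_tajima_d <- function(haps) {
  n <- ncol(haps)
  k <- rowSums(haps)
  seg <- k > 0 & k < n
  s <- sum(seg)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  ppi <- 0
  for (i in which(seg)) {
    diffs <- 0
    for (x in 1:(n - 1)) for (y in (x + 1):n) {
      diffs <- diffs + (haps[i, x] != haps[i, y])
    }
    ppi <- ppi + diffs / choose(n, 2)
  }
  (ppi - s / a1) / sqrt(e1 * s + e2 * s * (s - 1))
}

## tiny neutral config for fast property tests (overrides win)
fast_config <- function(...) {
  args <- list(n_chrom = 1, chrom_length = 2e5, N_wild = 200,
               n_sampled_wild = 10, n_sampled_cult = 10,
               qual_fail_frac = 0, missing_frac = 0)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

## 5-record toy: one low-QUAL site, one triallelic, one rare (MAF 0.02),
## one with 40% missing calls, one clean; hand-evaluating each rule
## independently says exactly the clean record survives.
five_record_toy <- function() {
  n_samp <- 25  # 50 alleles so a singleton has MAF 0.02
  haps <- matrix(0L, 5, 2 * n_samp)
  haps[1, 1:25] <- 1L            # QUAL=20 site, common allele
  haps[2, 1:10] <- 2L            # triallelic record
  haps[3, 1] <- 1L               # MAF = 1/50 = 0.02
  haps[4, 1:25] <- 1L
  haps[4, seq(1, 20)] <- NA_integer_  # 20% of 100 calls missing
  haps[5, 1:25] <- 1L            # clean
  alt <- c("T", "T,G", "T", "T", "T")
  qual <- c(20, 60, 60, 60, 60)
  toy_gm(haps, alt = alt, qual = qual,
         pops = rep(c("wild", "cultivar"), each = 1))
}

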