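#' SNP filter rules
#'
#' The standard hard-filter set for resequencing SNPs: biallelic sites with
#' site quality >= 30, genotype and site-mean depth within 4-60x, per-site
#' missing-call fraction <= 10% and pooled minor allele frequency >= 5%.
#'
#' @param min_depth,max_depth Depth bounds. Genotype calls with depth outside
#'   the range are set to missing before the missingness and MAF tests; the
#'   site-mean depth must also lie within the range.
#' @param min_site_qual Minimum site QUAL.
#' @param min_maf Minimum minor allele frequency, computed over non-missing
#'   alleles with all populations pooled.
#' @param max_missing Maximum fraction of missing genotype calls per site.
#' @param biallelic_only Drop records with more than one ALT allele.
#' @return An object of class `filter_rules`.
#' @export
filter_rules <- function(min_depth = 4, max_depth = 60, min_site_qual = 30,
                         min_maf = 0.05, max_missing = 0.10,
                         biallelic_only = TRUE) {
  stopifnot(min_maf >= 0, min_maf <= 0.5,
            min_depth <= max_depth,
            max_missing >= 0, max_missing <= 1)
  structure(
    list(min_depth = min_depth, max_depth = max_depth,
         min_site_qual = min_site_qual, min_maf = min_maf,
         max_missing = max_missing, biallelic_only = biallelic_only),
    class = "filter_rules"
  )
}

#' @export
print.filter_rules <- function(x, ...) {
  cat("<filter_rules> depth [", x$min_depth, ",", x$max_depth,
      "], QUAL >= ", x$min_site_qual, ", MAF >= ", x$min_maf,
      ", missing <= ", x$max_missing,
      if (x$biallelic_only) ", biallelic only", "\n", sep = "")
  invisible(x)
}

#' Apply site filters to a genotype matrix
#'
#' Genotype calls whose depth falls outside `[min_depth, max_depth]` are
#' masked to missing first. A site is then retained when it is biallelic,
#' QUAL >= `min_site_qual`, its mean depth (over originally called genotypes)
#' lies within the depth bounds, its missing-call fraction (after depth
#' masking) is <= `max_missing`, and its pooled minor allele frequency is
#' >= `min_maf`. Removal is attributed to the first failing rule in the order
#' biallelic, QUAL, depth, missingness, MAF.
#'
#' @param gm A [geno_matrix()].
#' @param rules A [filter_rules()] object.
#' @return The filtered `geno_matrix`, with an attribute `filter_counts`
#'   (named integer vector of removals per rule, plus `sites_in`/`sites_out`),
#'   retrievable with [filter_counts()].
#' @export
apply_site_filters <- function(gm, rules = filter_rules()) {
  stopifnot(inherits(gm, "geno_matrix"), inherits(rules, "filter_rules"))
  n_in <- n_sites(gm)
  counts <- c(biallelic = 0L, qual = 0L, depth = 0L, missing = 0L, maf = 0L)
  if (n_in == 0L) {
    warning("empty genotype matrix: nothing to filter", call. = FALSE)
    attr(gm, "filter_counts") <- c(counts, sites_in = 0L, sites_out = 0L)
    return(gm)
  }

  ## genotype-level depth mask
  bad_dp <- gm$dp < rules$min_depth | gm$dp > rules$max_depth
  bad_dp[is.na(bad_dp)] <- FALSE
  if (any(bad_dp)) {
    mask_hap <- bad_dp[, rep(seq_len(ncol(bad_dp)), each = 2), drop = FALSE]
    gm$haps[mask_hap] <- NA_integer_
  }

  ## site-level rules, first-failing attribution
  fail_biallelic <- if (rules$biallelic_only) gm$sites$multiallelic else
    rep(FALSE, n_in)
  fail_qual <- gm$sites$qual < rules$min_site_qual
  mean_dp <- rowMeans(gm$dp, na.rm = TRUE)
  fail_depth <- mean_dp < rules$min_depth | mean_dp > rules$max_depth
  miss_frac <- rowMeans(is.na(gm$haps))
  fail_missing <- miss_frac > rules$max_missing
  ac <- allele_counts(gm)
  f <- ifelse(ac$m > 0, ac$k / ac$m, 0)
  maf <- pmin(f, 1 - f)
  fail_maf <- maf < rules$min_maf

  first_fail <- rep(NA_character_, n_in)
  for (rule in c("maf", "missing", "depth", "qual", "biallelic")) {
    fails <- switch(rule, biallelic = fail_biallelic, qual = fail_qual,
                    depth = fail_depth, missing = fail_missing, maf = fail_maf)
    first_fail[fails] <- rule
  }
  keep <- is.na(first_fail)
  tab <- table(factor(first_fail, levels = names(counts)))
  counts[names(tab)] <- as.integer(tab)

  out <- subset_sites(gm, keep)
  attr(out, "filter_counts") <- c(counts, sites_in = n_in,
                                  sites_out = sum(keep))
  out
}

#' Removal accounting of the last filtering step
#'
#' @param gm A `geno_matrix` returned by [apply_site_filters()].
#' @return Named integer vector: removals per rule and `sites_in`/`sites_out`.
#' @export
filter_counts <- function(gm) {
  fc <- attr(gm, "filter_counts")
  if (is.null(fc)) stop("`gm` carries no filter accounting; run ",
                        "apply_site_filters() first", call. = FALSE)
  fc
}
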