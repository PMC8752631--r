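#' Cross-population composite likelihood (XP-CLR style) model
#'
#' The scan models the object (cultivar) population's allele frequency at a
#' site, given the reference (wild) frequency `p1`, as binomial sampling
#' around a drifted frequency. Under neutrality the pre-drift frequency is
#' `p1` itself; under a sweep a lineage escapes the sweeping haplotype with
#' probability `c` (rising with recombination distance, falling with
#' selection strength), giving a two-point mixture: frequency
#' `(1-c) + c*p1` with weight `p1` and `c*p1` with weight `1-p1`. Drift adds
#' Gaussian noise with variance `omega * m * (1-m)` (truncated to (0,1) with
#' boundary atoms). `c = 1` recovers the neutral model exactly.
#'
#' @param omega Genome-wide drift variance coefficient (dimensionless, > 0);
#'   `NULL` to estimate from data with [estimate_omega()].
#' @param s_grid Ascending selection coefficients scanned; the smallest acts
#'   as a quasi-neutral limit.
#' @param epsilon Post-sweep escape floor (the frequency a fully swept
#'   haplotype class retains); default `5e-5`, about `1/(2N)` for `N = 1e4`.
#' @param rrate Recombination rate in Morgans per bp used to convert physical
#'   distance into recombination distance (share the simulator's value when
#'   scanning simulated data).
#' @param n_grid Quadrature grid resolution for the frequency densities
#'   (>= 100).
#' @param pseudocount Added per allele class when estimating `p1`, keeping
#'   the likelihood finite at reference-fixed sites.
#' @return An object of class `xpclr_model`.
#' @export
xpclr_model <- function(omega = NULL,
                        s_grid = c(0.001, 0.005, 0.01, 0.05, 0.1, 0.5),
                        epsilon = 5e-5, rrate = 3e-6, n_grid = 200,
                        pseudocount = 0.5) {
  stopifnot(is.null(omega) || omega > 0,
            all(s_grid > 0), !is.unsorted(s_grid),
            epsilon > 0, epsilon < 1, rrate > 0,
            n_grid >= 100, pseudocount >= 0)
  structure(
    list(omega = omega, s_grid = s_grid, epsilon = epsilon, rrate = rrate,
         n_grid = n_grid, pseudocount = pseudocount),
    class = "xpclr_model"
  )
}

#' @export
print.xpclr_model <- function(x, ...) {
  cat("<xpclr_model> omega=",
      if (is.null(x$omega)) "(estimate from data)" else x$omega,
      ", s_grid={", paste(x$s_grid, collapse = ", "),
      "}, epsilon=", x$epsilon, ", rrate=", x$rrate,
      ", n_grid=", x$n_grid, "\n", sep = "")
  invisible(x)
}

#' Estimate the drift variance coefficient omega
#'
#' Method of moments on genome-wide SNPs with intermediate reference
#' frequency: `omega = mean[(p1-p2)^2 / (p1*(1-p1))] - mean[1/m1 + 1/m2]`,
#' floored at `omega_min`. The subtracted term removes the expected binomial
#' sampling variance, so pure sampling noise yields the floor.
#'
#' @param gm A [geno_matrix()].
#' @param ref_pop,obj_pop Reference and object population labels.
#' @param min_sites Minimum usable SNPs (reference frequency strictly inside
#'   `freq_bounds`); fewer is an error.
#' @param freq_bounds Reference-frequency bounds for usable SNPs.
#' @param omega_min Lower floor of the estimate.
#' @return The scalar omega estimate.
#' @export
estimate_omega <- function(gm, ref_pop, obj_pop, min_sites = 100,
                           freq_bounds = c(0.05, 0.95), omega_min = 1e-4) {
  ac1 <- allele_counts(gm, ref_pop)
  ac2 <- allele_counts(gm, obj_pop)
  p1 <- ifelse(ac1$m > 0, ac1$k / ac1$m, NA_real_)
  p2 <- ifelse(ac2$m > 0, ac2$k / ac2$m, NA_real_)
  use <- !is.na(p1) & !is.na(p2) &
    p1 > freq_bounds[1] & p1 < freq_bounds[2]
  if (sum(use) < min_sites) {
    stop("only ", sum(use), " usable SNPs for omega estimation (need >= ",
         min_sites, ")", call. = FALSE)
  }
  raw <- mean((p1[use] - p2[use])^2 / (p1[use] * (1 - p1[use])))
  samp <- mean(1 / ac1$m[use] + 1 / ac2$m[use])
  max(raw - samp, omega_min)
}

#' Probability that a lineage escapes a sweep
#'
#' Classic hitchhiking approximation: a neutral lineage at recombination
#' distance `r = rrate * distance` Morgans from a site sweeping with
#' selection coefficient `s` escapes the sweeping haplotype with probability
#' `c = 1 - epsilon^(r/s)`, clamped to `(c_min, 1]`.
#'
#' @param distance_bp Physical distance in bp (vectorised, >= 0).
#' @param s Selection coefficient (> 0).
#' @param model An [xpclr_model()] (supplies `rrate` and `epsilon`).
#' @param c_min Lower clamp (default 1e-6).
#' @return Escape probabilities in `(c_min, 1]`.
#' @export
escape_probability <- function(distance_bp, s, model = xpclr_model(),
                               c_min = 1e-6) {
  stopifnot(s > 0, all(distance_bp >= 0))
  r <- model$rrate * distance_bp
  cc <- 1 - exp(-(r / s) * log(1 / model$epsilon))
  pmin(pmax(cc, c_min), 1)
}

## component likelihood E_q[Binom(k | m, q)] for q ~ N(mean, omega*mean*(1-mean))
## truncated to (0,1) with boundary atoms; `bin_grid` is the shared
## dbinom(k, m, q_grid) matrix (n_grid x n_sites). Components whose sd falls
## below `sd_collapse` are evaluated as a point mass at the mean (fixed
## threshold so quadrature refinement is well defined).
component_lik <- function(mean, omega, k, m, q_grid, bin_grid,
                          sd_collapse = 3.5e-3) {
  sdv <- sqrt(pmax(omega * mean * (1 - mean), 0))
  .component_lik_cpp(as.numeric(mean), sdv, as.integer(k), as.integer(m),
                     q_grid, bin_grid, sd_collapse)
}

#' Per-site XP-CLR log-likelihood
#'
#' Log-likelihood of observing `k2` ALT alleles out of `m2` sampled in the
#' object population, given reference frequency `p1`, drift coefficient
#' `omega` and escape probability `c` (see [xpclr_model()] for the mixture).
#' Evaluated by fixed-grid quadrature with boundary atoms. Vectorised over
#' sites.
#'
#' @param p1 Reference allele frequency in `[0, 1]` (vectorised).
#' @param k2,m2 Object-population ALT count and non-missing allele count.
#' @param model An [xpclr_model()] with `omega` set.
#' @param c Escape probability in `(0, 1]`; `c = 1` is the neutral model.
#' @return Numeric vector of per-site log-likelihoods.
#' @export
xpclr_site_loglik <- function(p1, k2, m2, model, c) {
  stopifnot(!is.null(model$omega))
  n <- max(length(p1), length(k2), length(m2), length(c))
  p1 <- rep_len(p1, n); k2 <- rep_len(k2, n)
  m2 <- rep_len(m2, n); c <- rep_len(c, n)
  q_grid <- (seq_len(model$n_grid) - 0.5) / model$n_grid
  bin_grid <- matrix(stats::dbinom(rep(k2, each = model$n_grid),
                                   rep(m2, each = model$n_grid),
                                   rep(q_grid, n)),
                     nrow = model$n_grid)
  log(pmax(mixture_lik(p1, k2, m2, c, model$omega, q_grid, bin_grid),
           1e-320))
}

mixture_lik <- function(p1, k2, m2, c, omega, q_grid, bin_grid) {
  m_hi <- (1 - c) + c * p1
  m_lo <- c * p1
  l_hi <- component_lik(m_hi, omega, k2, m2, q_grid, bin_grid)
  l_lo <- component_lik(m_lo, omega, k2, m2, q_grid, bin_grid)
  p1 * l_hi + (1 - p1) * l_lo
}

#' Scan windows with the cross-population composite likelihood ratio
#'
#' For each window the focal point is the window midpoint; every SNP
#' contributes its sweep-vs-neutral log-likelihood difference with the escape
#' probability set by its distance to the focal point, and
#' `CLR = 2 * max_s sum_sites [ll_sweep(s) - ll_neutral]`, floored at 0.
#' Sites are weighted equally. Windows with fewer SNPs than `min_snps` are
#' flagged undefined.
#'
#' @param gm A [geno_matrix()].
#' @param ref_pop,obj_pop Reference (wild) and object (cultivar) populations.
#' @param windows Window tibble from [make_windows()]; `NULL` tiles
#'   `gm$contigs` with `size`/`step`.
#' @param model An [xpclr_model()]; a `NULL` omega is estimated genome-wide
#'   first.
#' @param size,step Window tiling when `windows` is `NULL`.
#' @param min_snps Minimum SNPs per scored window.
#' @return A tibble: `chrom`, `start`, `end`, `n_snps_used`, `xpclr`,
#'   `xpclr_s_hat` (argmax selection coefficient; `NA` when the sweep model
#'   never beats neutral), plus the `omega` used as an attribute.
#' @export
xpclr_scan <- function(gm, ref_pop, obj_pop, windows = NULL,
                       model = xpclr_model(), size = 50000, step = 20000,
                       min_snps = 10) {
  if (is.null(windows)) windows <- make_windows(gm$contigs, size, step)
  if (is.null(model$omega)) {
    model$omega <- estimate_omega(gm, ref_pop, obj_pop)
  }
  ac1 <- allele_counts(gm, ref_pop)
  ac2 <- allele_counts(gm, obj_pop)
  pc <- model$pseudocount
  p1_all <- (ac1$k + pc) / (ac1$m + 2 * pc)
  q_grid <- (seq_len(model$n_grid) - 0.5) / model$n_grid

  res <- purrr::pmap_dfr(windows, function(chrom, start, end) {
    idx <- sites_in_interval(gm, chrom, start, end)
    idx <- idx[ac1$m[idx] > 0 & ac2$m[idx] > 0]
    if (length(idx) < min_snps) {
      return(tibble::tibble(chrom = chrom, start = start, end = end,
                            n_snps_used = length(idx), xpclr = NA_real_,
                            xpclr_s_hat = NA_real_))
    }
    p1 <- p1_all[idx]
    k2 <- ac2$k[idx]; m2 <- ac2$m[idx]
    pos <- gm$sites$pos[idx]
    focal <- (start + end) / 2
    n_g <- model$n_grid
    bin_grid <- matrix(stats::dbinom(rep(k2, each = n_g),
                                     rep(m2, each = n_g),
                                     rep(q_grid, length(idx))),
                       nrow = n_g)
    ll0 <- sum(log(pmax(mixture_lik(p1, k2, m2, rep(1, length(idx)),
                                    model$omega, q_grid, bin_grid),
                        1e-320)))
    ll_s <- vapply(model$s_grid, function(s) {
      cc <- escape_probability(abs(pos - focal), s, model)
      sum(log(pmax(mixture_lik(p1, k2, m2, cc, model$omega, q_grid,
                               bin_grid), 1e-320)))
    }, numeric(1))
    best <- which.max(ll_s)
    clr <- 2 * max(0, ll_s[best] - ll0)
    tibble::tibble(chrom = chrom, start = start, end = end,
                   n_snps_used = length(idx), xpclr = clr,
                   xpclr_s_hat = if (clr > 0) model$s_grid[best] else
                     NA_real_)
  })
  attr(res, "omega") <- model$omega
  res
}
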