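## gm with two populations whose per-site ALT counts are given
gm_from_counts <- function(k1, m1, k2, m2) {
  n_site <- length(k1)
  h <- matrix(0L, n_site, m1 + m2)
  for (i in seq_len(n_site)) {
    if (k1[i] > 0) h[i, seq_len(k1[i])] <- 1L
    if (k2[i] > 0) h[i, m1 + seq_len(k2[i])] <- 1L
  }
  toy_gm(h, pos = seq_len(n_site) * 10L,
         pops = rep(c("wild", "cultivar"), c(m1 / 2, m2 / 2)))
}

test_that("omega estimation recovers known drift and floors pure sampling", {
  set.seed(21)
  n_site <- 8000
  m <- 100L
  p <- runif(n_site, 0.1, 0.9)
  ## sampling only: estimate collapses toward the omega_min floor
  gm0 <- gm_from_counts(rbinom(n_site, m, p), m, rbinom(n_site, m, p), m)
  w0 <- estimate_omega(gm0, "wild", "cultivar")
  expect_lt(w0, 0.01)

  ## known drift omega0 = 0.05 recovered within 20%
  omega0 <- 0.05
  p2 <- pmin(pmax(p + rnorm(n_site, 0, sqrt(omega0 * p * (1 - p))),
                  0), 1)
  gm1 <- gm_from_counts(rbinom(n_site, m, p), m, rbinom(n_site, m, p2), m)
  w1 <- estimate_omega(gm1, "wild", "cultivar")
  expect_equal(w1, omega0, tolerance = 0.2)

  ## identical frequency vectors, no sampling noise -> exact floor
  k <- round(p * m)
  gm2 <- gm_from_counts(k, m, k, m)
  expect_equal(estimate_omega(gm2, "wild", "cultivar"), 1e-4)

  expect_error(estimate_omega(gm_from_counts(rep(5L, 4), 10L,
                                             rep(5L, 4), 10L),
                              "wild", "cultivar"), "usable")
})

test_that("escape probability follows the hitchhiking closed form", {
  model <- xpclr_model(omega = 0.1, rrate = 1e-8, epsilon = 5e-5)
  ## r = 0 at the selected site -> clamp floor
  expect_equal(escape_probability(0, 0.01, model), 1e-6)
  ## r/s -> infinity: fully unlinked behaves neutrally
  expect_equal(escape_probability(1e12, 0.01, model), 1)
  ## stated toy arithmetic: 1 - exp(-(1e-3/0.01) * log(2e4)) = 0.6285
  expect_equal(escape_probability(1e5, 0.01, model), 0.6285,
               tolerance = 1e-3)
  ## monotone in distance
  d <- escape_probability(seq(0, 2e5, 1e4), 0.01, model)
  expect_true(all(diff(d) >= 0))
})

## independent brute-force site likelihood: fine-grid midpoint integration
## of the same mixture written directly from the formulas
brute_site_lik <- function(p1, k2, m2, omega, c, n_grid = 1e5) {
  q <- (seq_len(n_grid) - 0.5) / n_grid
  comp <- function(mu) {
    sdv <- sqrt(omega * mu * (1 - mu))
    if (sdv == 0) return(dbinom(k2, m2, mu))
    sum(dnorm(q, mu, sdv) * dbinom(k2, m2, q)) / n_grid +
      pnorm(0, mu, sdv) * (k2 == 0) +
      (1 - pnorm(1, mu, sdv)) * (k2 == m2)
  }
  p1 * comp((1 - c) + c * p1) + (1 - p1) * comp(c * p1)
}

test_that("site likelihood matches refined quadrature and its symmetries", {
  model <- xpclr_model(omega = 0.05, n_grid = 1000)
  ## toy case agrees with 1e5-point brute-force integration to 4 sig figs
  got <- exp(xpclr_site_loglik(0.3, 9, 10, model, c = 0.1))
  expect_equal(got, brute_site_lik(0.3, 9, 10, 0.05, 0.1),
               tolerance = 1e-4)
  ## and the default grid is already within 0.1%
  got_default <- exp(xpclr_site_loglik(0.3, 9, 10,
                                       xpclr_model(omega = 0.05), c = 0.1))
  expect_equal(got_default, brute_site_lik(0.3, 9, 10, 0.05, 0.1),
               tolerance = 1e-3)

  ## c = 1 collapses the mixture to the neutral single point
  neutral <- exp(xpclr_site_loglik(0.3, 9, 10, model, c = 1))
  expect_equal(neutral, brute_site_lik(0.3, 9, 10, 0.05, 1),
               tolerance = 1e-4)

  ## allele relabeling symmetry (p1, k2) -> (1 - p1, m2 - k2)
  for (cc in c(0.05, 0.3, 1)) {
    a <- xpclr_site_loglik(0.3, 9, 10, model, cc)
    b <- xpclr_site_loglik(0.7, 1, 10, model, cc)
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("the scan scores sweep-like windows and respects invariants", {
  set.seed(55)
  n_site <- 60
  m1 <- 40L; m2 <- 40L
  p <- runif(n_site, 0.2, 0.8)
  k1 <- rbinom(n_site, m1, p)
  ## object fixed for the reference-minor allele at every site
  minor_is_alt <- k1 < m1 / 2
  k2 <- ifelse(minor_is_alt, m2, 0L)
  gm <- gm_from_counts(k1, m1, k2, m2)
  gm$contigs <- c(chr1 = 1000)
  model <- xpclr_model(omega = 0.1, rrate = 1e-6)
  sc <- xpclr_scan(gm, "wild", "cultivar", model = model,
                   size = 1000, step = 1000, min_snps = 5)
  expect_equal(nrow(sc), 1L)
  expect_gt(sc$xpclr, 50)
  expect_equal(sc$xpclr_s_hat, max(model$s_grid))

  ## relabeling REF/ALT at every site leaves the CLR unchanged
  gm_flip <- gm
  gm_flip$haps <- 1L - gm_flip$haps
  sc_flip <- xpclr_scan(gm_flip, "wild", "cultivar", model = model,
                        size = 1000, step = 1000, min_snps = 5)
  expect_equal(sc_flip$xpclr, sc$xpclr, tolerance = 1e-10)

  ## neutral object: CLR floored at 0 and never negative
  k2n <- rbinom(n_site, m2, p)
  gmn <- gm_from_counts(k1, m1, k2n, m2)
  gmn$contigs <- c(chr1 = 1000)
  scn <- xpclr_scan(gmn, "wild", "cultivar", model = model,
                    size = 1000, step = 1000, min_snps = 5)
  expect_gte(scn$xpclr, 0)

  ## sparse window flagged undefined
  sc0 <- xpclr_scan(gmn, "wild", "cultivar", model = model,
                    size = 1000, step = 1000, min_snps = 1000)
  expect_true(is.na(sc0$xpclr))
})

test_that("doubling the quadrature grid moves no CLR by 0.1%", {
  sim <- simulate_domestication(
    fast_config(seed = 61, sweep_loci = data.frame(chrom = "chr1",
                                                   pos = 1e5, s = 1)))
  gm <- apply_site_filters(sim_genotype_matrix(sim, noise = FALSE))
  m1 <- xpclr_model(rrate = 3e-6, n_grid = 200)
  m2 <- xpclr_model(rrate = 3e-6, n_grid = 400)
  s1 <- xpclr_scan(gm, "wild", "cultivar", model = m1)
  s2 <- xpclr_scan(gm, "wild", "cultivar", model = m2)
  nz <- which(!is.na(s1$xpclr) & s1$xpclr > 1)
  rel <- abs(s1$xpclr[nz] - s2$xpclr[nz]) / s1$xpclr[nz]
  expect_lt(max(rel), 1e-3)
})

test_that("the top window localizes a strong sweep", {
  hits <- 0; n_rep <- 15
  for (r in 1:n_rep) {
    cfg <- sim_config(n_chrom = 1, chrom_length = 1e6, seed = 700 + r,
                      qual_fail_frac = 0, missing_frac = 0,
                      sweep_loci = data.frame(chrom = "chr1", pos = 5e5,
                                              s = 1))
    sim <- simulate_domestication(cfg)
    gm <- apply_site_filters(sim_genotype_matrix(sim))
    sc <- xpclr_scan(gm, "wild", "cultivar",
                     model = xpclr_model(rrate = 3e-6))
    top <- sc[which.max(sc$xpclr), ]
    ## contains or abuts (within one step) the true locus
    if (top$start - 20000 < 5e5 && 5e5 <= top$end + 20000) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.8)
})
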