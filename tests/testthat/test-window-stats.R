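test_that("window tiling matches hand enumeration", {
  w <- make_windows(c(chr1 = 100000))
  expect_equal(w$start, c(0, 20000, 40000, 60000, 80000))
  ## the last two windows are truncated at the chromosome end
  expect_equal(w$end, c(50000, 70000, 90000, 100000, 100000))

  w2 <- make_windows(c(chr1 = 50000))
  expect_equal(w2$start, c(0, 20000, 40000))
  expect_equal(w2$end, c(50000, 50000, 50000))

  w3 <- make_windows(c(chr1 = 10))
  expect_equal(nrow(w3), 1L)
  expect_equal(c(w3$start, w3$end), c(0, 10))

  expect_error(make_windows(c(chr1 = 1000), size = 10, step = 20))
})

test_that("pi matches the frequency formula and brute-force pairs", {
  ## one site, 4 haplotypes at counts 2/2, 10-kb window
  gm <- toy_gm(matrix(c(0L, 0L, 1L, 1L), 1), pos = 5000L,
               contigs = c(chr1 = 10000))
  pi1 <- nucleotide_diversity(gm, "chr1", 0, 10000)
  expect_equal(pi1, 2 * 0.25 * (4 / 3) / 10000)
  expect_equal(pi1, 6.667e-5, tolerance = 1e-3)
  ## equals mean pairwise differences 4/6 over C(4,2) pairs
  expect_equal(pi1, brute_pi(matrix(c(0L, 0L, 1L, 1L), 1), 10000))

  ## no segregating sites -> 0; two haplotypes differing at k sites -> k/L
  mono <- toy_gm(matrix(0L, 3, 4))
  expect_equal(nucleotide_diversity(mono, "chr1", 0, 1000), 0)
  pair <- toy_gm(matrix(c(0L, 1L), 5, 2, byrow = TRUE), pops = "wild")
  expect_equal(nucleotide_diversity(pair, "chr1", 0, 1000), 5 / 1000)
})

test_that("pi equals brute-force pairwise Hamming on 100 random matrices", {
  set.seed(101)
  for (rep in 1:100) {
    n_hap <- 2 * sample(2:6, 1)
    n_site <- sample(1:12, 1)
    h <- random_haps(n_site, n_hap)
    if (runif(1) < 0.3) h[sample(length(h), 2)] <- NA_integer_
    span <- 1000 + n_site * 100
    gm <- toy_gm(h, contigs = c(chr1 = span))
    got <- nucleotide_diversity(gm, "chr1", 0, span)
    ## frequency-formula pi equals mean pairwise Hamming distance only with
    ## complete data; with missing calls compare per-site expectations
    if (!anyNA(h)) {
      expect_equal(got, brute_pi(h, span), tolerance = 1e-12)
    } else {
      ac <- allele_counts(gm)
      manual <- sum(ifelse(ac$m >= 2,
                           2 * ac$k * (ac$m - ac$k) /
                             (ac$m * (ac$m - 1)), 0)) / span
      expect_equal(got, manual, tolerance = 1e-12)
    }
  }
})

test_that("Watterson's theta follows S / a1 / span", {
  mono <- toy_gm(matrix(0L, 3, 4))
  expect_equal(wattersons_theta(mono, "chr1", 0, 1000), 0)
  ## n = 2: a1 = 1 so theta = S / L
  pair <- toy_gm(matrix(c(0L, 1L), 4, 2, byrow = TRUE), pops = "wild")
  expect_equal(wattersons_theta(pair, "chr1", 0, 1000), 4 / 1000)
  ## n = 4, S = 3, L = 1000: a1 = 1 + 1/2 + 1/3 by direct summation
  h <- matrix(c(1L, 0L, 0L, 0L), 3, 4, byrow = TRUE)
  gm <- toy_gm(h, contigs = c(chr1 = 1000))
  a1 <- sum(1 / 1:3)
  expect_equal(wattersons_theta(gm, "chr1", 0, 1000), 3 / a1 / 1000)
  expect_equal(wattersons_theta(gm, "chr1", 0, 1000), 1.636e-3,
               tolerance = 1e-3)
})

test_that("Tajima's D matches constant-by-constant evaluation", {
  cc <- tajima_constants(4)
  expect_equal(cc$a1, 1 + 1 / 2 + 1 / 3)
  expect_equal(cc$a2, 1 + 1 / 4 + 1 / 9)
  ## n = 4 haplotypes, 3 singleton sites: Pi = 1.5, theta_hat = 1.6364,
  ## D ~ -0.75 (frozen from the independent oracle below)
  h <- matrix(c(1L, 0L, 0L, 0L), 3, 4, byrow = TRUE)
  gm <- toy_gm(h)
  d <- tajimas_d(gm, "chr1", 0, 1000)
  expect_equal(d, brute_tajima_d(h))
  expect_equal(d, -0.7544, tolerance = 1e-3)

  ## numerator vanishes when Pi = S/a1 exactly
  ## S = 0 -> undefined (NA, not 0)
  mono <- toy_gm(matrix(1L, 2, 4))
  expect_true(is.na(tajimas_d(mono, "chr1", 0, 1000)))
})

test_that("Tajima's D sign separates singleton and intermediate spectra", {
  for (n_hap in c(4, 8, 16)) {
    n_site <- 6
    singletons <- matrix(0L, n_site, n_hap)
    for (i in seq_len(n_site)) singletons[i, (i %% n_hap) + 1] <- 1L
    inter <- matrix(rep(c(rep(1L, n_hap / 2), rep(0L, n_hap / 2)), n_site),
                    n_site, n_hap, byrow = TRUE)
    d_s <- tajimas_d(toy_gm(singletons), "chr1", 0, 1000)
    d_i <- tajimas_d(toy_gm(inter), "chr1", 0, 1000)
    expect_lt(d_s, 0)
    expect_gt(d_i, 0)
    expect_gt(d_i, d_s)
  }
})

test_that("Weir-Cockerham FST matches hand-evaluated components", {
  ## fixed difference, no heterozygotes -> FST = 1
  fixed <- toy_gm(cbind(matrix(0L, 2, 20), matrix(1L, 2, 20)))
  expect_equal(weir_cockerham_fst(fixed, "chr1", 0, 1000,
                                  "wild", "cultivar"), 1)

  ## identical genotype tables -> no among-population variance, FST <= 0
  set.seed(7)
  block <- random_haps(6, 12)
  same <- toy_gm(cbind(block, block))
  expect_lte(weir_cockerham_fst(same, "chr1", 0, 1000, "wild", "cultivar"),
             0)

  ## unequal sample sizes: step-by-step WC84 transcription as oracle
  ## popA: 4 individuals (2 het, 1 hom ref, 1 hom alt), popB: 2 hom-ref
  hA <- c(0L, 1L, 0L, 1L, 0L, 0L, 1L, 1L)
  hB <- c(0L, 0L, 0L, 0L)
  h2A <- c(1L, 1L, 0L, 0L, 0L, 0L, 0L, 1L)
  h2B <- c(0L, 1L, 1L, 1L)
  haps <- rbind(c(hA, hB), c(h2A, h2B))
  gm <- toy_gm(haps, pops = c(rep("wild", 4), rep("cultivar", 2)))
  got <- weir_cockerham_fst(gm, "chr1", 0, 1000, "wild", "cultivar")

  wc_site <- function(n1, p1, h1, n2, p2, h2) {
    r <- 2
    nbar <- (n1 + n2) / r
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    c(a, b, cc)
  }
  s1 <- wc_site(4, 4 / 8, 2 / 4, 2, 0, 0)
  s2 <- wc_site(4, 3 / 8, 1 / 4, 2, 3 / 4, 1 / 2)
  oracle <- (s1[1] + s2[1]) / sum(s1, s2)
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("window table is order-invariant and flags sparse windows", {
  set.seed(33)
  h <- random_haps(40, 20)
  pos <- sort(sample.int(60000, 40))
  gm <- toy_gm(h, pos = pos, contigs = c(chr1 = 60000))
  ws <- window_stats(gm, size = 20000, step = 10000, min_snps = 5)
  expect_true(all(c("pi_wild", "pi_cultivar", "tajd_wild",
                    "tajd_cultivar", "fst", "defined") %in% names(ws)))

  ## permute samples and sites: identical statistics
  perm_s <- sample(10)
  hap_perm <- as.vector(rbind(2L * perm_s - 1L, 2L * perm_s))
  gm2 <- toy_gm(h[, hap_perm], pos = pos, contigs = c(chr1 = 60000),
                pops = unname(gm$populations[perm_s]))
  ws2 <- window_stats(gm2, size = 20000, step = 10000, min_snps = 5)
  expect_equal(ws$pi_wild, ws2$pi_wild, tolerance = 1e-12)
  expect_equal(ws$fst, ws2$fst, tolerance = 1e-12)

  sparse <- window_stats(gm, size = 20000, step = 10000, min_snps = 50)
  expect_false(any(sparse$defined))
})

test_that("FST stays within bounds on random data", {
  set.seed(9)
  for (rep in 1:25) {
    gm <- toy_gm(random_haps(15, 24))
    f <- weir_cockerham_fst(gm, "chr1", 0, 2000, "wild", "cultivar")
    expect_gte(f, -0.1)
    expect_lte(f, 1)
  }
})

test_that("divergence dating is Ks / 2r", {
  expect_equal(divergence_date(0, 1e-8), 0)
  expect_equal(divergence_date(0.2, 1e-8), 1e7)
  ## a Ks peak of 0.35 at r = 4.175e-9 dates to ~41.9 MYA
  expect_equal(divergence_date(0.35, 4.175e-9) / 1e6, 41.9, tolerance = 2e-3)
  expect_error(divergence_date(0.2, 0), "positive")
})
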