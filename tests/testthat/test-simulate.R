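test_that("config invariants are enforced", {
  expect_error(sim_config(n_founders = 300, N_wild = 200))
  expect_error(sim_config(n_sampled_cult = 50, n_cult = 20))
  expect_error(sim_config(missing_frac = 1.5))
  expect_error(sim_config(sweep_loci = data.frame(chrom = "chr1",
                                                  pos = 2e6, s = 1)))
  expect_error(sim_config(sweep_loci = data.frame(chrom = "chr1",
                                                  pos = 100, s = -1)))
})

test_that("segregating sites match the Watterson expectation", {
  ## theta = 4*N*mu*L = 20 per chromosome; over 50 replicates the mean S in
  ## a 20-haplotype wild sample must sit within 3 Monte-Carlo SE of
  ## theta * a1(20) (analytic neutral expectation as oracle)
  theta <- 20
  len <- 2e5
  mu <- theta / (4 * 200 * len)
  s_obs <- numeric(50)
  for (r in 1:50) {
    cfg <- fast_config(seed = 2000 + r, mu = mu)
    sim <- simulate_domestication(cfg)
    gm <- sim_genotype_matrix(sim, noise = FALSE)
    ac <- allele_counts(gm, "wild")
    s_obs[r] <- sum(ac$k > 0 & ac$k < ac$m)
  }
  a1 <- sum(1 / (1:19))
  expected <- theta * a1
  se <- stats::sd(s_obs) / sqrt(50)
  expect_lt(abs(mean(s_obs) - expected), 3 * se)
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- fast_config(seed = 99, missing_frac = 0.05, qual_fail_frac = 0.1,
                     sweep_loci = data.frame(chrom = "chr1", pos = 1e5,
                                             s = 0.5))
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  dir.create(d1, showWarnings = FALSE); dir.create(d2, showWarnings = FALSE)
  for (d in c(d1, d2)) {
    sim <- simulate_domestication(cfg)
    emit_vcf(sim, file.path(d, "sim.vcf"))
    emit_annotation(cfg, file.path(d, "genes.gff3"))
    write_truth(sim, file.path(d, "truth.bed"), file.path(d, "truth.json"))
  }
  for (f in c("sim.vcf", "sim.vcf.popmap.tsv", "genes.gff3", "truth.bed",
              "truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("founder bottleneck forces differentiation; panmixia does not", {
  ## neutral bottleneck: mean window FST > 0
  sim <- simulate_domestication(fast_config(seed = 41))
  gm <- sim_genotype_matrix(sim, noise = FALSE)
  ws <- window_stats(gm, size = 50000, step = 50000, min_snps = 5)
  expect_gt(mean(ws$fst, na.rm = TRUE), 0)

  ## n_founders = N_wild, no generations: one panmictic pool, FST ~ 0
  pan <- simulate_domestication(
    fast_config(seed = 42, n_founders = 200, n_cult = 200,
                n_generations_dom = 0))
  gm2 <- sim_genotype_matrix(pan, noise = FALSE)
  ws2 <- window_stats(gm2, size = 50000, step = 50000, min_snps = 5)
  expect_lt(abs(mean(ws2$fst, na.rm = TRUE)), 0.05)
})

test_that("a strong implanted sweep empties cultivar diversity locally", {
  ## s >= 0.5 with successful fixation: sweep-window cultivar pi below the
  ## genome median in >= 90% of replicates
  hits <- 0; n_rep <- 20
  for (r in 1:n_rep) {
    cfg <- sim_config(n_chrom = 1, chrom_length = 5e5, seed = 500 + r,
                      qual_fail_frac = 0, missing_frac = 0,
                      sweep_loci = data.frame(chrom = "chr1", pos = 2.5e5,
                                              s = 1))
    sim <- simulate_domestication(cfg)
    gm <- sim_genotype_matrix(sim, noise = FALSE)
    ws <- window_stats(gm, min_snps = 5)
    mid <- (ws$start + ws$end) / 2
    sweep_pi <- ws$pi_cultivar[which.min(abs(mid - 2.5e5))]
    if (sweep_pi < stats::median(ws$pi_cultivar, na.rm = TRUE)) {
      hits <- hits + 1
    }
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("the truth set records seeding, restarts and final frequencies", {
  cfg <- fast_config(seed = 11,
                     sweep_loci = data.frame(chrom = "chr1",
                                             pos = c(5e4, 15e4),
                                             s = c(1, 0)))
  sim <- simulate_domestication(cfg)
  tr <- sim$truth
  expect_equal(nrow(tr$sweeps), 2L)
  expect_true(all(tr$sweeps$final_freq >= 0 & tr$sweeps$final_freq <= 1))
  expect_gt(tr$sweeps$final_freq[1], 0)  # restart-on-loss guarantees this
  expect_equal(tr$initializer, "sfs")
  expect_equal(tr$seed, 11L)
})

test_that("the forward-burn-in initializer also reaches equilibrium", {
  ## tiny population so the 8N-generation burn-in stays fast; S should be
  ## within a factor of ~2 of theta * a1(n) (single stochastic draw)
  cfg <- sim_config(n_chrom = 1, chrom_length = 5e4, N_wild = 25,
                    mu = 2e-5, n_sampled_wild = 10, n_sampled_cult = 5,
                    n_founders = 5, n_cult = 5, n_generations_dom = 2,
                    qual_fail_frac = 0, missing_frac = 0,
                    init = "forward", seed = 4)
  sim <- simulate_domestication(cfg)
  gm <- sim_genotype_matrix(sim, noise = FALSE)
  ac <- allele_counts(gm, "wild")
  s_obs <- sum(ac$k > 0 & ac$k < ac$m)
  theta <- 4 * 25 * 2e-5 * 5e4
  expected <- theta * sum(1 / (1:19))
  expect_gt(s_obs, expected / 2.5)
  expect_lt(s_obs, expected * 2.5)
})

test_that("degenerate inputs raise the documented errors", {
  ## mutation rate so low that nothing segregates
  cfg <- sim_config(n_chrom = 1, chrom_length = 100, N_wild = 10,
                    mu = 1e-9, n_founders = 5, n_cult = 5,
                    n_sampled_wild = 3, n_sampled_cult = 3, seed = 2)
  expect_error(simulate_domestication(cfg), "zero segregating")
})
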