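## gm for one sample from a dosage string: H = hom, h = het, . = missing
gm_from_dosage <- function(code, pos = NULL) {
  g <- strsplit(code, "")[[1]]
  h1 <- ifelse(g == "h", 0L, ifelse(g == "H", 0L, NA_integer_))
  h2 <- ifelse(g == "h", 1L, ifelse(g == "H", 0L, NA_integer_))
  haps <- cbind(h1, h2)
  toy_gm(haps, pos = pos, pops = "cultivar")
}

test_that("single-copy masking is exact interval membership", {
  genes <- tibble::tibble(
    chrom = "chr1", start = c(100, 500, 900), end = c(200, 700, 1000),
    strand = "+", gene_id = c("g1", "g2", "g3"),
    single_copy = c(TRUE, FALSE, TRUE))
  pos <- as.integer(c(50, 101, 150, 200, 201, 550, 901, 1000, 990))
  gm <- toy_gm(matrix(rep(c(0L, 1L), length(pos)), ncol = 2, byrow = TRUE),
               pos = sort(pos), pops = "wild")
  masked <- select_single_copy_snps(gm, genes)
  ## brute-force membership: inside (100,200] or (900,1000]
  brute <- sort(pos)[vapply(sort(pos), function(p) {
    (p > 100 && p <= 200) || (p > 900 && p <= 1000)
  }, logical(1))]
  expect_equal(masked$sites$pos, brute)
  ## SNP at the first base of a gene (pos 101) retained, boundary 200 kept,
  ## intergenic and non-single-copy dropped
  expect_true(101L %in% masked$sites$pos)
  expect_false(550L %in% masked$sites$pos)

  genes$single_copy <- FALSE
  expect_warning(out <- select_single_copy_snps(gm, genes), "no single-copy")
  expect_equal(n_sites(out), 0L)
})

test_that("run segmentation matches hand enumeration", {
  ## HHHHH -> one run of 5
  r <- call_roh(gm_from_dosage("HHHHH"), min_snps = 3)
  expect_equal(nrow(r), 1L)
  expect_equal(r$n_snps, 5L)

  ## HHhHH, max_het = 0 -> two runs of 2, dropped at min_snps = 3
  r0 <- call_roh(gm_from_dosage("HHhHH"), max_het = 0, min_snps = 3)
  expect_equal(nrow(r0), 0L)
  r0b <- call_roh(gm_from_dosage("HHhHH"), max_het = 0, min_snps = 2)
  expect_equal(r0b$n_snps, c(2L, 2L))

  ## same genotypes with max_het = 1 -> one run of 5
  r1 <- call_roh(gm_from_dosage("HHhHH"), max_het = 1, min_snps = 3)
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$n_snps, 5L)
  expect_equal(r1$n_het, 1L)

  ## all heterozygous -> no runs
  expect_equal(nrow(call_roh(gm_from_dosage("hhhh"), min_snps = 1)), 0L)

  ## missing calls are transparent: skipped, not run-breaking
  rm <- call_roh(gm_from_dosage("HH..HH"), max_het = 0, min_snps = 4)
  expect_equal(nrow(rm), 1L)
  expect_equal(rm$n_snps, 4L)

  ## min_length_bp filters by span
  rl <- call_roh(gm_from_dosage("HHHHH"), min_snps = 3,
                 min_length_bp = 10000)
  expect_equal(nrow(rl), 0L)
})

test_that("for max_het = 0 runs plus gaps reconstruct the sequence", {
  set.seed(13)
  for (rep in 1:20) {
    code <- paste(sample(c("H", "h"), 60, replace = TRUE,
                         prob = c(0.8, 0.2)), collapse = "")
    gm <- gm_from_dosage(code)
    runs <- call_roh(gm, max_het = 0, min_snps = 1)
    ## every homozygous call is inside exactly one run; hets in none
    g <- strsplit(code, "")[[1]]
    covered <- logical(60)
    for (i in seq_len(nrow(runs))) {
      idx <- which(gm$sites$pos > runs$start[i] &
                     gm$sites$pos <= runs$end[i])
      expect_true(all(g[idx] == "H"))
      covered[idx] <- TRUE
    }
    expect_equal(sum(covered), sum(g == "H"))
  }
})

test_that("runs are reproducible under site-order permutation", {
  set.seed(14)
  code <- paste(sample(c("H", "h"), 40, replace = TRUE), collapse = "")
  gm <- gm_from_dosage(code)
  perm <- sample(40)
  ## same calls and positions fed in permuted order; the constructor
  ## re-sorts, so the runs must be identical
  gm2 <- toy_gm(gm$haps[perm, , drop = FALSE], pos = gm$sites$pos[perm],
                pops = "cultivar")
  expect_equal(call_roh(gm2, min_snps = 1), call_roh(gm, min_snps = 1))
})

test_that("terminal runs are flagged and summarised", {
  ## run covering the final SNP -> terminal; interior run -> not
  gm <- gm_from_dosage("hHHHhhHHHH")
  runs <- call_roh(gm, max_het = 0, min_snps = 3)
  expect_equal(nrow(runs), 2L)
  expect_equal(runs$terminal, c(FALSE, TRUE))
  term <- terminal_roh(runs, gm, frac_threshold = 0.25, min_snps = 3)
  expect_true(term$per_chromosome$flagged[1])
  expect_equal(term$summary$n_flagged, 1L)
})

test_that("engineered terminal tracts are detected; bottleneck-only is clean", {
  hits_pos <- 0; hits_neg <- 0; n_rep <- 10
  for (r in 1:n_rep) {
    cfg <- fast_config(seed = 800 + r, chrom_length = 1e6)
    sim <- simulate_domestication(cfg)
    gm <- sim_genotype_matrix(sim, noise = FALSE)
    genes <- emit_annotation(cfg)
    gm_sc <- select_single_copy_snps(gm, genes)

    neg <- terminal_roh(call_roh(gm_sc), gm_sc)
    if (!any(neg$per_chromosome$flagged)) hits_neg <- hits_neg + 1

    gm_eng <- implant_terminal_roh(gm_sc, "cult_01", fraction = 0.4)
    pos <- terminal_roh(call_roh(gm_eng), gm_eng)
    flagged <- pos$per_chromosome$flagged[
      pos$per_chromosome$sample == "cult_01"]
    if (any(flagged)) hits_pos <- hits_pos + 1
  }
  expect_gte(hits_pos / n_rep, 0.9)
  expect_gte(hits_neg / n_rep, 0.9)
})
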