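#' Configuration of the domestication simulator
#'
#' Describes a two-population history: a wild outcrossing population at
#' mutation-drift equilibrium, and a cultivar population founded from it by a
#' handful of individuals and carried through a few sexual generations of
#' strong artificial (truncation) selection — the regime of clonally
#' propagated orchard crops that are only two to four generations from the
#' wild. Hard sweeps are implanted at configurable loci.
#'
#' Default rates are desk-scale rescalings: with `N_wild = 200` the default
#' `mu` gives theta = 4*N*mu = 1e-3 per bp, and `rrate` preserves the
#' biological ratio r/mu of about 2.4 implied by the literal per-generation
#' rates (`mu_literal`, `rrate_literal`), which are recorded as metadata
#' alongside the generation time.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Chromosome length in bp (shared by all chromosomes).
#' @param N_wild Wild diploid population size (drives theta).
#' @param n_founders Diploid founders of the cultivar population (small
#'   bottleneck; must be <= `N_wild`).
#' @param n_cult Cultivar census size during the domestication generations
#'   (>= `n_sampled_cult`).
#' @param n_generations_dom Sexual generations after founding (2-4 for the
#'   crops this emulates; 0 allowed for control runs).
#' @param mu Mutation rate per bp per generation (desk-rescaled default).
#' @param rrate Recombination rate, Morgans per bp (desk-rescaled default).
#' @param sweep_loci Data frame with columns `chrom`, `pos`, `s` giving the
#'   implanted sweep loci; `NULL` for a neutral run. `s` is the per-locus
#'   genotypic value under truncation selection (0 = neutral).
#' @param n_sampled_wild,n_sampled_cult Diploids sampled per population for
#'   the emitted VCF.
#' @param fecundity Juveniles produced per adult slot each generation; the
#'   selected fraction is `1/fecundity`.
#' @param env_sd Environmental standard deviation of the selected phenotype
#'   (same units as `s`); controls how heritable the selected trait is.
#' @param mean_depth Mean per-genotype sequencing depth for the emitted VCF.
#' @param qual_fail_frac Fraction of sites emitted with QUAL below 30.
#' @param missing_frac Fraction of genotype calls masked to missing.
#' @param max_restarts Maximum domestication re-runs when a beneficial allele
#'   is lost.
#' @param init `"sfs"` (default): wild haplotypes drawn from a neutral
#'   coalescent-style generator with matched theta; `"forward"`: explicit
#'   Wright-Fisher burn-in of `burnin_factor * N_wild` generations.
#' @param burnin_factor Burn-in length multiplier for `init = "forward"`.
#' @param gene_length,gene_spacing,single_copy_frac Gene tiling used by
#'   [emit_annotation()]: gene length, start-to-start spacing (bp) and the
#'   fraction of genes flagged single-copy.
#' @param seed Integer seed; every simulator output is deterministic given
#'   the config.
#' @param mu_literal,rrate_literal,generation_years Literal per-generation /
#'   per-year rates recorded as metadata (not used by the desk-scale run).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 5, chrom_length = 1e6, N_wild = 200,
                       n_founders = 10, n_cult = 20, n_generations_dom = 3,
                       mu = 1.25e-6, rrate = 3e-6, sweep_loci = NULL,
                       n_sampled_wild = 20, n_sampled_cult = 20,
                       fecundity = 10, env_sd = 0.25,
                       mean_depth = 20, qual_fail_frac = 0.05,
                       missing_frac = 0.02, max_restarts = 100,
                       init = c("sfs", "forward"), burnin_factor = 8,
                       gene_length = 2000, gene_spacing = 10000,
                       single_copy_frac = 0.5, seed = 1,
                       mu_literal = 4.175e-9, rrate_literal = 1e-8,
                       generation_years = 8) {
  init <- match.arg(init)
  stopifnot(n_chrom >= 1, chrom_length >= 10,
            n_founders >= 1, n_founders <= N_wild,
            n_generations_dom >= 0,
            n_cult >= 1, n_sampled_cult <= n_cult,
            n_sampled_wild >= 1, mu > 0, rrate >= 0,
            fecundity >= 1, env_sd >= 0,
            qual_fail_frac >= 0, qual_fail_frac <= 1,
            missing_frac >= 0, missing_frac <= 1,
            max_restarts >= 0, seed == as.integer(seed))
  if (!is.null(sweep_loci)) {
    sweep_loci <- tibble::as_tibble(sweep_loci)
    stopifnot(all(c("chrom", "pos", "s") %in% names(sweep_loci)),
              all(sweep_loci$s >= 0),
              all(sweep_loci$pos >= 1), all(sweep_loci$pos <= chrom_length))
  }
  structure(
    list(n_chrom = n_chrom, chrom_length = chrom_length, N_wild = N_wild,
         n_founders = n_founders, n_cult = n_cult,
         n_generations_dom = n_generations_dom, mu = mu, rrate = rrate,
         sweep_loci = sweep_loci, n_sampled_wild = n_sampled_wild,
         n_sampled_cult = n_sampled_cult, fecundity = fecundity,
         env_sd = env_sd, mean_depth = mean_depth,
         qual_fail_frac = qual_fail_frac, missing_frac = missing_frac,
         max_restarts = max_restarts, init = init,
         burnin_factor = burnin_factor, gene_length = gene_length,
         gene_spacing = gene_spacing, single_copy_frac = single_copy_frac,
         seed = as.integer(seed), mu_literal = mu_literal,
         rrate_literal = rrate_literal, generation_years = generation_years),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_chrom, " x ", x$chrom_length / 1e3, " kb, N_wild=",
      x$N_wild, ", founders=", x$n_founders, ", generations=",
      x$n_generations_dom, ", sweeps=",
      if (is.null(x$sweep_loci)) 0 else nrow(x$sweep_loci),
      ", seed=", x$seed, "\n", sep = "")
  invisible(x)
}

harm1 <- function(n) sum(1 / seq_len(n - 1))

## random mating without selfing (these are outcrossing, largely
## self-incompatible trees): mother and father always distinct
draw_parent_pairs <- function(n_adults, n_offspring) {
  mothers <- sample.int(n_adults, n_offspring, replace = TRUE)
  fathers <- sample.int(n_adults, n_offspring, replace = TRUE)
  if (n_adults > 1) {
    while (any(same <- fathers == mothers)) {
      fathers[same] <- sample.int(n_adults, sum(same), replace = TRUE)
    }
  }
  list(mothers = mothers, fathers = fathers)
}

## draw a neutral coalescent-style sample: n_hap rows, theta-matched SFS,
## independent sites (linkage equilibrium); returns list(haps, pos)
draw_sfs_sample <- function(n_hap, theta_bp, len) {
  s <- stats::rpois(1, theta_bp * len * harm1(n_hap))
  s <- min(s, len)
  pos <- sort(sample.int(len, s))
  h <- matrix(0L, n_hap, s)
  if (s > 0) {
    i <- sample(seq_len(n_hap - 1), s, replace = TRUE,
                prob = 1 / seq_len(n_hap - 1))
    for (j in seq_len(s)) h[sample.int(n_hap, i[j]), j] <- 1L
  }
  list(haps = h, pos = pos)
}

## one gamete per entry of `parents` (diploid indices into H's row pairs)
make_gametes <- function(h, pos, len, rrate, parents) {
  .make_gametes_cpp(h, as.numeric(pos), len, rrate, as.integer(parents))
}

## add Poisson(2 * n_dip * mu * len) singleton mutations as new columns
add_mutations <- function(h, pos, used, mu, len) {
  n_mut <- stats::rpois(1, 2 * (nrow(h) / 2) * mu * len)
  if (n_mut == 0) return(list(haps = h, pos = pos, used = used))
  ## rejection-sample unused positions (collisions are rare at low density)
  new_pos <- integer(0)
  for (try in 1:20) {
    cand <- sample.int(len, n_mut - length(new_pos))
    cand <- cand[!used[cand] & !duplicated(cand)]
    used[cand] <- TRUE
    new_pos <- c(new_pos, cand)
    if (length(new_pos) == n_mut) break
  }
  n_mut <- length(new_pos)
  if (n_mut == 0) return(list(haps = h, pos = pos, used = used))
  add <- matrix(0L, nrow(h), n_mut)
  add[cbind(sample.int(nrow(h), n_mut, replace = TRUE), seq_len(n_mut))] <- 1L
  list(haps = cbind(h, add), pos = c(pos, new_pos), used = used)
}

## neutral Wright-Fisher burn-in (forward initializer)
forward_burnin <- function(n_dip, gens, mu, rrate, len) {
  h <- matrix(0L, 2 * n_dip, 0)
  pos <- integer(0)
  used <- logical(len)
  for (g in seq_len(gens)) {
    par <- draw_parent_pairs(n_dip, n_dip)
    mothers <- par$mothers
    fathers <- par$fathers
    g1 <- make_gametes(h, pos, len, rrate, mothers)
    g2 <- make_gametes(h, pos, len, rrate, fathers)
    h <- interleave_gametes(g1, g2)
    res <- add_mutations(h, pos, used, mu, len)
    h <- res$haps; pos <- res$pos; used <- res$used
    if (g %% 25 == 0 || g == gens) {
      cs <- colSums(h)
      keep <- cs > 0 & cs < nrow(h)
      h <- h[, keep, drop = FALSE]
      used[pos[!keep]] <- FALSE
      pos <- pos[keep]
    }
  }
  list(haps = h, pos = pos)
}

interleave_gametes <- function(g1, g2) {
  n <- nrow(g1)
  h <- matrix(0L, 2 * n, ncol(g1))
  h[seq(1, 2 * n, 2), ] <- g1
  h[seq(2, 2 * n, 2), ] <- g2
  h
}

#' Simulate a wild/cultivar pair with implanted sweeps
#'
#' Runs the two-population history described by a [sim_config()]: wild
#' haplotypes at neutral equilibrium, founding of the cultivar population by
#' `n_founders` diploids, then `n_generations_dom` generations of random
#' mating with truncation selection on a phenotype that sums the per-locus
#' genotypic values (0, s/2, s per sweep locus) plus Gaussian environmental
#' noise. Each generation `fecundity * n_cult` juveniles are produced and the
#' top `n_cult` by phenotype survive; at `s = 0` this is a neutral
#' Wright-Fisher bottleneck. Beneficial alleles absent from the founders are
#' seeded at one copy (frequency `1/(2*n_founders)`); a domestication phase
#' that loses a beneficial allele is re-run up to `max_restarts` times.
#'
#' @param config A [sim_config()].
#' @return An object of class `dom_sim`: sampled haplotypes per chromosome
#'   (wild sample rows first, then the cultivar sample), site positions, the
#'   sample/population map, and a `truth` record (sweep loci with final
#'   beneficial-allele frequency in the full cultivar population, seed,
#'   initializer, config snapshot).
#' @export
simulate_domestication <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chrom))
  len <- config$chrom_length
  n_w <- config$n_sampled_wild
  n_f <- config$n_founders
  n_tot_hap <- 2L * (n_w + n_f)
  theta_bp <- 4 * config$N_wild * config$mu

  ## wild pool: wild sample rows 1..2n_w, founder rows after
  pool <- vector("list", length(chroms))
  names(pool) <- chroms
  for (cn in chroms) {
    pool[[cn]] <- if (config$init == "sfs") {
      draw_sfs_sample(n_tot_hap, theta_bp, len)
    } else {
      bi <- forward_burnin(config$N_wild,
                           config$burnin_factor * config$N_wild,
                           config$mu, config$rrate, len)
      rows <- sample.int(2 * config$N_wild, n_tot_hap)
      list(haps = bi$haps[rows, , drop = FALSE], pos = bi$pos)
    }
  }

  ## seed beneficial alleles in founders where absent
  sweeps <- config$sweep_loci
  sweep_idx <- list()   # per chrom: column indices of sweep loci
  sweep_s <- list()
  if (!is.null(sweeps) && nrow(sweeps) > 0) {
    for (r in seq_len(nrow(sweeps))) {
      cn <- sweeps$chrom[r]
      if (!cn %in% chroms) stop("sweep locus on unknown chromosome ", cn,
                                call. = FALSE)
      p <- pool[[cn]]
      j <- match(sweeps$pos[r], p$pos)
      if (is.na(j)) {
        p$haps <- cbind(p$haps, 0L)
        p$pos <- c(p$pos, sweeps$pos[r])
        j <- length(p$pos)
      }
      founder_rows <- (2 * n_w + 1):n_tot_hap
      if (sum(p$haps[founder_rows, j]) == 0) {
        p$haps[sample(founder_rows, 1), j] <- 1L
      }
      pool[[cn]] <- p
      sweep_idx[[cn]] <- c(sweep_idx[[cn]], j)
      sweep_s[[cn]] <- c(sweep_s[[cn]], sweeps$s[r])
    }
  }

  founder_haps <- lapply(pool, function(p) {
    p$haps[(2 * n_w + 1):n_tot_hap, , drop = FALSE]
  })
  founder_pos <- lapply(pool, function(p) p$pos)

  run_domestication <- function() {
    h <- founder_haps
    pos <- founder_pos
    used <- lapply(pos, function(p) {
      u <- logical(len); u[p] <- TRUE; u
    })
    n_adults <- n_f
    for (g in seq_len(config$n_generations_dom)) {
      n_juv <- config$fecundity * config$n_cult
      par <- draw_parent_pairs(n_adults, n_juv)
      mothers <- par$mothers
      fathers <- par$fathers
      juv <- list()
      for (cn in chroms) {
        g1 <- make_gametes(h[[cn]], pos[[cn]], len, config$rrate, mothers)
        g2 <- make_gametes(h[[cn]], pos[[cn]], len, config$rrate, fathers)
        juv[[cn]] <- interleave_gametes(g1, g2)
      }
      ## truncation selection on phenotype
      z <- stats::rnorm(n_juv, 0, config$env_sd)
      for (cn in names(sweep_idx)) {
        for (q in seq_along(sweep_idx[[cn]])) {
          j <- sweep_idx[[cn]][q]
          dosage <- juv[[cn]][seq(1, 2 * n_juv, 2), j] +
            juv[[cn]][seq(2, 2 * n_juv, 2), j]
          z <- z + dosage / 2 * sweep_s[[cn]][q]
        }
      }
      sel <- order(z, decreasing = TRUE)[seq_len(config$n_cult)]
      hap_rows <- as.vector(rbind(2L * sel - 1L, 2L * sel))
      for (cn in chroms) {
        h[[cn]] <- juv[[cn]][hap_rows, , drop = FALSE]
        res <- add_mutations(h[[cn]], pos[[cn]], used[[cn]],
                             config$mu, len)
        h[[cn]] <- res$haps; pos[[cn]] <- res$pos; used[[cn]] <- res$used
      }
      n_adults <- config$n_cult
    }
    ## check beneficial alleles
    final_freq <- numeric(0)
    if (!is.null(sweeps) && nrow(sweeps) > 0) {
      final_freq <- numeric(nrow(sweeps))
      for (r in seq_len(nrow(sweeps))) {
        cn <- sweeps$chrom[r]
        j <- which(pos[[cn]] == sweeps$pos[r])
        final_freq[r] <- mean(h[[cn]][, j])
        if (sweeps$s[r] > 0 && final_freq[r] == 0) return(NULL)
      }
    }
    list(haps = h, pos = pos, final_freq = final_freq)
  }

  dom <- NULL
  attempts <- 0
  repeat {
    dom <- run_domestication()
    if (!is.null(dom)) break
    attempts <- attempts + 1
    if (attempts > config$max_restarts) {
      lost <- sweeps[1, ]
      stop("beneficial allele lost after ", config$max_restarts,
           " restarts at locus ", lost$chrom, ":", lost$pos,
           " (s = ", lost$s, "); increase s or n_founders", call. = FALSE)
    }
  }

  ## sample individuals and assemble pooled per-chromosome matrices
  cult_ind <- sort(sample.int(config$n_cult, config$n_sampled_cult))
  cult_rows <- as.vector(rbind(2L * cult_ind - 1L, 2L * cult_ind))
  haps <- list(); positions <- list()
  total_seg <- 0
  for (cn in chroms) {
    wild_mat <- pool[[cn]]$haps[1:(2 * n_w), , drop = FALSE]
    wild_pos <- pool[[cn]]$pos
    cult_mat <- dom$haps[[cn]][cult_rows, , drop = FALSE]
    cult_pos <- dom$pos[[cn]]
    n_extra <- length(cult_pos) - length(wild_pos)
    if (n_extra > 0) {
      wild_mat <- cbind(wild_mat, matrix(0L, nrow(wild_mat), n_extra))
    }
    pooled <- rbind(wild_mat, cult_mat)
    cs <- colSums(pooled)
    keep <- cs > 0 & cs < nrow(pooled)
    pooled <- pooled[, keep, drop = FALSE]
    p <- cult_pos[keep]
    ord <- order(p)
    haps[[cn]] <- pooled[, ord, drop = FALSE]
    positions[[cn]] <- p[ord]
    total_seg <- total_seg + length(p)
  }
  if (total_seg == 0) {
    stop("simulation produced zero segregating sites; increase mu, ",
         "chromosome length or burn-in", call. = FALSE)
  }

  samples <- c(sprintf("wild_%02d", seq_len(n_w)),
               sprintf("cult_%02d", seq_len(config$n_sampled_cult)))
  populations <- stats::setNames(
    rep(c("wild", "cultivar"), c(n_w, config$n_sampled_cult)), samples)

  truth_sweeps <- if (is.null(sweeps)) {
    tibble::tibble(chrom = character(), pos = integer(), s = numeric(),
                   final_freq = numeric(), fixed = logical())
  } else {
    tibble::tibble(chrom = sweeps$chrom, pos = as.integer(sweeps$pos),
                   s = sweeps$s, final_freq = dom$final_freq,
                   fixed = dom$final_freq == 1)
  }

  structure(
    list(haps = haps, positions = positions, samples = samples,
         populations = populations, chrom_lengths =
           stats::setNames(rep(len, length(chroms)), chroms),
         truth = structure(
           list(sweeps = truth_sweeps, n_founders = n_f,
                seed = config$seed, initializer = config$init,
                restarts = attempts, config = config),
           class = "sim_truth"),
         config = config),
    class = "dom_sim"
  )
}

#' @export
print.dom_sim <- function(x, ...) {
  cat("<dom_sim> ", sum(lengths(x$positions)), " segregating sites, ",
      length(x$samples), " samples (",
      sum(x$populations == "wild"), " wild + ",
      sum(x$populations == "cultivar"), " cultivar), ",
      length(x$haps), " chromosomes\n", sep = "")
  if (nrow(x$truth$sweeps) > 0) {
    cat("sweeps:\n"); print(x$truth$sweeps)
  }
  invisible(x)
}

#' Convert a simulation to a genotype matrix
#'
#' @param sim A [simulate_domestication()] result.
#' @param noise Apply the configured observation model (QUAL draws with
#'   `qual_fail_frac` below 30, Poisson depth around `mean_depth`, missing
#'   calls at `missing_frac`)? With `noise = FALSE` the calls are clean
#'   (QUAL 60, constant depth, no missingness). Deterministic given the
#'   config seed.
#' @return A [geno_matrix()].
#' @export
sim_genotype_matrix <- function(sim, noise = TRUE) {
  stopifnot(inherits(sim, "dom_sim"))
  chroms <- names(sim$haps)
  chrom <- rep(chroms, lengths(sim$positions))
  pos <- unlist(sim$positions, use.names = FALSE)
  haps <- t(do.call(cbind, sim$haps))  # sites x haplotypes
  n_samp <- length(sim$samples)
  cfg <- sim$config
  n_site <- nrow(haps)

  qual <- rep(60, n_site)
  dp <- matrix(cfg$mean_depth, n_site, n_samp)
  if (noise) {
    set.seed(cfg$seed + 1000003L)
    fail <- stats::runif(n_site) < cfg$qual_fail_frac
    qual <- ifelse(fail, stats::runif(n_site, 10, 29.9),
                   stats::runif(n_site, 30, 60))
    qual <- round(qual, 2)
    dp <- matrix(stats::rpois(n_site * n_samp, cfg$mean_depth),
                 n_site, n_samp)
    miss <- matrix(stats::runif(n_site * n_samp) < cfg$missing_frac,
                   n_site, n_samp)
    if (any(miss)) {
      mask <- miss[, rep(seq_len(n_samp), each = 2), drop = FALSE]
      haps[mask] <- NA_integer_
    }
  }
  geno_matrix(haps, chrom, pos, sim$samples, sim$populations,
              qual = qual, dp = dp, contigs = sim$chrom_lengths)
}

#' Implant a terminal homozygous tract (synthetic clonal signature)
#'
#' Overwrites one sample's genotypes so that the terminal `fraction` of SNPs
#' on each chromosome is homozygous (second haplotype copied from the first),
#' emulating the terminal runs of homozygosity expected under long clonal
#' propagation with mitotic recombination. Used to give the ROH scan a
#' positive control.
#'
#' @param gm A [geno_matrix()].
#' @param sample Sample name to modify.
#' @param fraction Fraction of each chromosome's SNPs in the tract.
#' @param side `"end"` or `"start"` of the chromosome.
#' @return The modified `geno_matrix`.
#' @export
implant_terminal_roh <- function(gm, sample, fraction = 0.4,
                                 side = c("end", "start")) {
  side <- match.arg(side)
  i <- match(sample, gm$samples)
  if (is.na(i)) stop("unknown sample '", sample, "'", call. = FALSE)
  c1 <- 2L * i - 1L; c2 <- 2L * i
  for (cn in unique(gm$sites$chrom)) {
    idx <- which(gm$sites$chrom == cn)
    n_tract <- ceiling(fraction * length(idx))
    if (n_tract == 0) next
    tract <- if (side == "end") utils::tail(idx, n_tract) else
      utils::head(idx, n_tract)
    a <- gm$haps[tract, c1]
    a[is.na(a)] <- 0L
    gm$haps[tract, c1] <- a
    gm$haps[tract, c2] <- a
  }
  gm
}
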