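test_that("genotype likelihoods match direct multinomial evaluation", {
  # empty pileup carries no information under any genotype
  for (g in rownames(genotypes())) {
    expect_equal(genotype_likelihood(c(0, 0, 0, 0), g, 0.01), 1)
  }
  # frozen oracle values: choose(9,3) * p3^9 for the matching heterozygote
  p3 <- 0.5 - 0.01 / 3
  expect_equal(genotype_likelihood(c(0, 3, 6, 0), "CG", 0.01),
               84 * p3^9, tolerance = 1e-12)
  expect_equal(84 * p3^9, 0.154477207228984, tolerance = 1e-12)
  # a homozygote for an unread allele must be astronomically less likely
  aa <- genotype_likelihood(c(0, 3, 6, 0), "AA", 0.01)
  expect_equal(aa, 84 * (0.01 / 3)^9, tolerance = 1e-12)
  expect_lt(aa / genotype_likelihood(c(0, 3, 6, 0), "CG", 0.01), 1e-15)
  # cross-check against stats::dmultinom on random cases
  set.seed(71)
  g <- genotypes()
  for (r in 1:25) {
    reads <- rpois(4, 2)
    a <- runif(1, 0, 0.015)
    gi <- sample(10, 1)
    expect_equal(genotype_likelihood(reads, g[gi, ], a),
                 dmultinom(reads,
                           prob = genotype_read_probs(g[gi, ], a)),
                 tolerance = 1e-12)
  }
})

test_that("zero-count category collapse reproduces the full likelihood", {
  set.seed(72)
  g <- genotypes()
  for (r in 1:100) {
    n_zero <- sample(1:3, 1)
    zero_cats <- sample(4, n_zero)
    reads <- rpois(4, 3) + 1
    reads[zero_cats] <- 0
    a <- runif(1, 0, 0.015)
    gi <- sample(10, 1)
    expect_equal(genotype_likelihood_collapsed(reads, g[gi, ], a),
                 genotype_likelihood(reads, g[gi, ], a),
                 tolerance = 1e-12)
  }
  # the single-read case collapses three categories into one
  expect_equal(genotype_likelihood_collapsed(c(0, 0, 0, 1), "TT", 0.009),
               genotype_likelihood(c(0, 0, 0, 1), "TT", 0.009),
               tolerance = 1e-15)
  expect_equal(genotype_likelihood_collapsed(c(0, 0, 0, 0), "AC", 0.01), 1)
  # no zero category: falls through to the full path
  expect_equal(genotype_likelihood_collapsed(c(1, 2, 3, 4), "CG", 0.01),
               genotype_likelihood(c(1, 2, 3, 4), "CG", 0.01))
})

test_that("Hardy-Weinberg priors are textbook and normalized", {
  p <- hwe_genotype_prior(c(1, 0, 0, 0))
  expect_equal(unname(p["AA"]), 1)
  expect_equal(sum(p), 1)
  p <- hwe_genotype_prior(c(0.5, 0.5, 0, 0))
  expect_equal(unname(p[c("AA", "AC", "CC")]), c(0.25, 0.5, 0.25))
  set.seed(73)
  for (r in 1:20) {
    f <- draw_frequencies(rpois(4, 2))
    expect_equal(sum(hwe_genotype_prior(f)), 1, tolerance = 1e-12)
  }
  expect_equal(hwe_genotype_prior(c(0.5, 0.5, 0, 0), genotype = "AC"), 0.5)
})

test_that("factorized locus likelihood equals the joint enumeration", {
  set.seed(74)
  for (r in 1:20) {
    n_ind <- sample(1:3, 1)
    reads <- matrix(rpois(n_ind * 4, 1.5), nrow = n_ind)
    if (r %% 3 == 0) reads[1, ] <- 0 # include zero-depth individuals
    f <- draw_frequencies(rpois(4, 4))
    a <- runif(1, 0, 0.015)
    expect_equal(locus_likelihood(reads, f, a),
                 oracle_locus_likelihood(reads, f, a),
                 tolerance = 1e-12)
  }
  # all-zero-depth locus: likelihood exactly 1
  expect_identical(locus_likelihood(matrix(0, 6, 4), c(0.7, 0.1, 0.1, 0.1),
                                    0.01), 1)
  # empty individuals contribute a factor of 1
  reads6 <- matrix(0, 6, 4)
  reads6[3, ] <- c(0, 2, 5, 0)
  f <- c(0.05, 0.5, 0.4, 0.05)
  expect_equal(locus_likelihood(reads6, f, 0.01),
               locus_likelihood(reads6[3, ], f, 0.01), tolerance = 1e-14)
})

test_that("cohort log-likelihood is additive over loci and models", {
  pb <- generate_panel(n_loci = 3, seed = 75)
  sim <- generate_cohort(pb$panel, pb$counts_a, n_individuals = 2,
                         depth = depth_model(mean_depth = 4), seed = 76)
  res <- cohort_loglikelihood(sim$cohort, pb$panel, pb$counts_a, 0.01,
                              per_locus = TRUE)
  expect_equal(res$total, sum(res$per_locus))
  # per-locus values match independent single-locus computations
  freqs <- point_frequencies(pb$counts_a)
  for (j in 1:3) {
    reads_j <- sim$cohort$reads[, j, ]
    expect_equal(unname(res$per_locus[j]),
                 locus_likelihood(reads_j, freqs[j, ], 0.01, log = TRUE),
                 tolerance = 1e-12)
  }
  # an empty cohort has log-likelihood 0 under every model
  empty <- pileup_cohort(individuals = c("a", "b"), panel = pb$panel)
  expect_identical(cohort_loglikelihood(empty, pb$panel, pb$counts_a, 0.01),
                   0)
  # identical population models give identical log-likelihoods
  twin <- population_counts(pb$counts_a$counts, "TWIN")
  expect_identical(
    cohort_loglikelihood(sim$cohort, pb$panel, pb$counts_a, 0.01),
    cohort_loglikelihood(sim$cohort, pb$panel, twin, 0.01))
})

test_that("log-likelihood is finite and continuous in alpha", {
  # nasty configurations: reads in all four categories, reads contradicting
  # the frequencies; empirical (zero-containing) frequencies
  panel <- toy_panel()
  cohort <- toy_cohort(panel, list(
    S1 = list("1:100 A>G" = c(5, 5, 5, 5), "2:200 C>T" = c(0, 0, 9, 0)),
    S2 = list("3:300 G>C" = c(12, 0, 0, 1))
  ))
  pop <- toy_counts(panel, path_counts = c(10, 0, 5))
  for (conv in c("posterior_mean", "empirical")) {
    lls <- vapply(seq(1e-6, 0.015, length.out = 40), function(a) {
      cohort_loglikelihood(cohort, panel, pop, a, freq_point = conv)
    }, numeric(1))
    expect_true(all(is.finite(lls)))
    # local continuity: vanishing alpha perturbations move the loglik
    # by a vanishing amount
    for (a in c(0.001, 0.008, 0.0149)) {
      d <- cohort_loglikelihood(cohort, panel, pop, a + 1e-8,
                                freq_point = conv) -
        cohort_loglikelihood(cohort, panel, pop, a, freq_point = conv)
      expect_lt(abs(d), 1e-3)
    }
  }
})

test_that("ML error rate is deterministic in grid mode and flags flat profiles", {
  pb <- generate_panel(n_loci = 25, seed = 77)
  sim <- generate_cohort(pb$panel, pb$counts_a, n_individuals = 4,
                         depth = depth_model(mean_depth = 6),
                         alpha_true = 0.009, seed = 78)
  m1 <- ml_error_rate(sim$cohort, pb$panel, pb$counts_a, n = 31)
  m2 <- ml_error_rate(sim$cohort, pb$panel, pb$counts_a, n = 31)
  expect_identical(m1$alpha_hat, m2$alpha_hat)
  expect_identical(m1$profile, m2$profile)
  # a cohort with no reads anywhere has a flat profile
  empty <- pileup_cohort(individuals = "a", panel = pb$panel)
  expect_warning(m0 <- ml_error_rate(empty, pb$panel, pb$counts_a, n = 11),
                 "boundary")
  expect_true(m0$flat)
  expect_equal(m0$alpha_hat, 0) # smallest alpha among (all) maxima
})

test_that("likelihood ratios are exactly 1 for no-information comparisons", {
  pb <- generate_panel(n_loci = 10, seed = 79)
  empty <- pileup_cohort(individuals = c("a", "b"), panel = pb$panel)
  rep0 <- likelihood_ratio_profile(empty, pb$panel, pb$counts_a,
                                   pb$counts_b, n_samples = 20, seed = 3)
  expect_identical(rep0$overall_lr, 1)
  expect_true(all(rep0$per_locus$lr == 1))
})

test_that("identical population models give LR 1 within MC tolerance", {
  pb <- generate_panel(n_loci = 30, seed = 80)
  sim <- generate_cohort(pb$panel, pb$counts_a, n_individuals = 3,
                         depth = depth_model(mean_depth = 3), seed = 81)
  twin <- population_counts(pb$counts_a$counts, "TWIN")
  rep1 <- likelihood_ratio_profile(sim$cohort, pb$panel, pb$counts_a, twin,
                                   n_samples = 300, seed = 4)
  expect_lt(abs(rep1$overall_log10_lr), 0.5)
  # per-locus LRs at point frequencies are exactly 1 when alpha_hat ties
  expect_equal(nrow(rep1$profile), 600) # n_samples rows per model
})

test_that("per-locus LR grows with the pathogenic-frequency ratio", {
  panel <- toy_panel()[1, ]
  attr(panel, "categories") <- NUCLEOTIDES
  class(panel) <- c("variant_panel", "data.frame")
  # one individual with only pathogenic (G) reads
  cohort <- toy_cohort(panel, list(S1 = list("1:100 A>G" = c(0, 0, 3, 0))))
  cb <- toy_counts(panel, path_counts = 10, totals = 10000, label = "B")
  ratios <- c(2, 5, 10, 25)
  lrs <- vapply(ratios, function(rr) {
    ca <- toy_counts(panel, path_counts = 10 * rr, totals = 10000,
                     label = "A")
    fa <- point_frequencies(ca)
    fb <- point_frequencies(cb)
    exp(locus_likelihood(cohort$reads[1, 1, ], fa[1, ], 0.009, log = TRUE) -
        locus_likelihood(cohort$reads[1, 1, ], fb[1, ], 0.009, log = TRUE))
  }, numeric(1))
  expect_true(all(diff(lrs) > 0))
  expect_true(all(lrs > 1))
})

test_that("the audit separates private from shared pathogenic loci", {
  panel <- toy_panel()
  cohort <- toy_cohort(panel, list(
    S1 = list("1:100 A>G" = c(0, 0, 2, 0), "2:200 C>T" = c(0, 0, 0, 1)),
    S2 = list("2:200 C>T" = c(0, 0, 0, 3))
  ))
  ca <- toy_counts(panel, path_counts = c(50, 50, 50), label = "A")
  cb <- toy_counts(panel, path_counts = c(5, 5, 5), label = "B")
  rep1 <- likelihood_ratio_profile(cohort, panel, ca, cb, n_samples = 50,
                                   seed = 5)
  audit <- private_allele_audit(rep1, cohort, panel)
  expect_setequal(audit$status[match(panel$locus_id, audit$locus_id)],
                  c("private", "shared", "no_pathogenic_reads"))
  expect_equal(audit$status[audit$locus_id == "1:100 A>G"], "private")
  expect_equal(audit$status[audit$locus_id == "2:200 C>T"], "shared")
  # ranked by |log LR| descending
  expect_true(!is.unsorted(rev(abs(audit$log_lr))))
})
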