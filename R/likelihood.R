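#' Multinomial likelihood of a read pileup given a genotype
#'
#' The probability of the observed per-category read counts for one
#' individual at one locus, given a diploid genotype and the symmetric
#' error rate: the multinomial pmf with the total depth as the number of
#' trials and [genotype_read_probs()] as the cell probabilities. The
#' multinomial coefficient is included (it is shared by every genotype,
#' so it cancels in all likelihood ratios). A zero-depth pileup has
#' likelihood exactly 1 under every genotype.
#'
#' @param reads Non-negative integer vector of per-category read counts.
#' @param genotype Length-2 character vector of alleles (or `"CG"`-style
#'   string).
#' @param alpha Per-read miscall probability in `[0, 1)`.
#' @param categories Ordered allele categories.
#' @param log Return the log likelihood?
#' @return The (log) likelihood.
#' @examples
#' genotype_likelihood(c(0, 3, 6, 0), "CG", 0.01) # 84 * (0.5 - 0.01/3)^9
#' @export
genotype_likelihood <- function(reads, genotype, alpha,
                                categories = NUCLEOTIDES, log = FALSE) {
  stopifnot(length(reads) == length(categories), all(reads >= 0))
  probs <- genotype_read_probs(genotype, alpha, categories)
  ll <- log_multinom(reads, probs)
  if (log) ll else exp(ll)
}

#' Genotype likelihood via zero-count category collapse
#'
#' Computes the same value as [genotype_likelihood()] after aggregating
#' all zero-count categories into a single "other" category. Because the
#' multinomial raises the "other" probability to the power zero, merging
#' zero-count cells leaves the pmf unchanged; this is the computational
#' shortcut that reduces the four-nucleotide genotype space (10 genotypes)
#' to 6 genotypes when two categories have zero counts and to 3 when
#' three do. With no zero-count category the computation falls through to
#' the full path; an all-zero pileup short-circuits to likelihood 1.
#'
#' @inheritParams genotype_likelihood
#' @return The (log) likelihood, identical to [genotype_likelihood()].
#' @export
genotype_likelihood_collapsed <- function(reads, genotype, alpha,
                                          categories = NUCLEOTIDES,
                                          log = FALSE) {
  stopifnot(length(reads) == length(categories), all(reads >= 0))
  if (sum(reads) == 0) return(if (log) 0 else 1)
  nz <- reads > 0
  if (all(nz)) {
    return(genotype_likelihood(reads, genotype, alpha, categories, log))
  }
  probs <- genotype_read_probs(genotype, alpha, categories)
  probs_c <- c(probs[nz], other = sum(probs[!nz]))
  reads_c <- c(reads[nz], 0)
  ll <- log_multinom(reads_c, probs_c)
  if (log) ll else exp(ll)
}

#' Hardy-Weinberg genotype prior
#'
#' Genotype probabilities implied by allele frequencies under random
#' mating: `f_a^2` for a homozygote, `2 f_a f_b` for a heterozygote. The
#' priors over all K(K+1)/2 genotypes sum to 1.
#'
#' @param freqs Allele-frequency vector over the categories, summing to 1.
#' @param genotype Optional single genotype; if `NULL`, the full named
#'   prior vector over [genotypes()] is returned.
#' @param categories Ordered allele categories.
#' @return A probability, or the named vector of all genotype priors.
#' @examples
#' hwe_genotype_prior(c(0.5, 0.5, 0, 0)) # AA .25, AC .5, CC .25, rest 0
#' @export
hwe_genotype_prior <- function(freqs, genotype = NULL,
                               categories = NUCLEOTIDES) {
  check_probs(freqs)
  stopifnot(length(freqs) == length(categories))
  if (!is.null(genotype)) {
    genotype <- split_genotype(genotype, categories)
    fa <- freqs[match(genotype[1], categories)]
    fb <- freqs[match(genotype[2], categories)]
    return(if (genotype[1] == genotype[2]) fa * fb else 2 * fa * fb)
  }
  g <- genotypes(categories)
  fa <- freqs[match(g[, 1], categories)]
  fb <- freqs[match(g[, 2], categories)]
  prior <- ifelse(g[, 1] == g[, 2], fa * fb, 2 * fa * fb)
  names(prior) <- rownames(g)
  prior
}

#' Genotype-marginalized likelihood of one locus
#'
#' The exact probability of all individuals' read pileups at one locus
#' given population allele frequencies and the error rate: the sum over
#' every joint assignment of genotypes to individuals of the HWE prior of
#' the assignment times the product of per-individual read likelihoods.
#' Because individuals are independent given the frequencies, the joint
#' sum over G^n assignments factorizes exactly into a product of
#' per-individual genotype-marginal sums, which is how it is computed
#' here (the literal joint enumeration is used as a test oracle).
#' A locus where every individual has zero depth carries no information
#' and has likelihood exactly 1.
#'
#' @param reads Matrix of read counts, one row per individual, one column
#'   per category (a vector is treated as a single individual).
#' @param freqs Population allele frequencies at the locus.
#' @param alpha Per-read miscall probability.
#' @param categories Ordered allele categories.
#' @param log Return the log likelihood?
#' @return The (log) likelihood of the locus.
#' @export
locus_likelihood <- function(reads, freqs, alpha,
                             categories = NUCLEOTIDES, log = FALSE) {
  if (is.null(dim(reads))) reads <- matrix(reads, nrow = 1)
  stopifnot(ncol(reads) == length(categories))
  reads <- reads[rowSums(reads) > 0, , drop = FALSE] # factor 1 per empty ind.
  if (nrow(reads) == 0) return(if (log) 0 else 1)
  log_prior <- log(hwe_genotype_prior(freqs, categories = categories))
  ll <- sum(cell_log_marginals(reads, rep(1L, nrow(reads)),
                               matrix(log_prior, nrow = 1), alpha,
                               categories))
  if (log) ll else exp(ll)
}

#' Cohort log-likelihood under one population model
#'
#' Sum over panel loci of the log genotype-marginalized locus likelihood,
#' with one global error rate shared by all loci and individuals. Loci
#' are treated as independent, so the cohort log-likelihood is additive.
#' All accumulation is in log space; zero-depth cells contribute 0.
#'
#' Frequency handling:
#' * `freq_mode = "point"`: each locus uses a fixed frequency vector,
#'   by default the Dirichlet posterior mean `(c_i + 1) / (sum(c) + K)`
#'   under the uniform prior (`freq_point = "posterior_mean"`), or the
#'   raw `c_i / sum(c)` (`freq_point = "empirical"`).
#' * `freq_mode = "dirichlet_sample"`: each locus uses one fresh
#'   Dirichlet(counts + 1) draw, propagating allele-frequency
#'   uncertainty into the likelihood.
#'
#' @param cohort A [pileup_cohort()].
#' @param panel The matching [variant_panel()].
#' @param pop A [population_counts()] for the candidate population.
#' @param alpha Per-read miscall probability.
#' @param freq_mode `"point"` or `"dirichlet_sample"`.
#' @param freq_point Point-frequency convention (see Details).
#' @param per_locus Also return the per-locus log-likelihood vector?
#' @return The total log-likelihood, or (if `per_locus`) a list with
#'   `total` and the named per-locus vector.
#' @export
cohort_loglikelihood <- function(cohort, panel, pop, alpha,
                                 freq_mode = c("point", "dirichlet_sample"),
                                 freq_point = c("posterior_mean", "empirical"),
                                 per_locus = FALSE) {
  freq_mode <- match.arg(freq_mode)
  freq_point <- match.arg(freq_point)
  categories <- panel_categories(panel)
  freqs <- switch(freq_mode,
    point = point_frequencies(pop, freq_point),
    dirichlet_sample = draw_frequencies(pop$counts))
  loglik_given_freqs(cohort, panel, freqs, alpha, categories, per_locus)
}

#' Point allele frequencies from population counts
#'
#' @param pop A [population_counts()] object.
#' @param convention `"posterior_mean"` for `(c_i + 1)/(sum(c) + K)`
#'   (Dirichlet posterior mean under the uniform prior; strictly positive,
#'   so every genotype keeps non-zero prior mass), or `"empirical"` for
#'   the raw `c_i / sum(c)`.
#' @return Frequency matrix, loci x categories.
#' @export
point_frequencies <- function(pop,
                              convention = c("posterior_mean", "empirical")) {
  convention <- match.arg(convention)
  k <- ncol(pop$counts)
  switch(convention,
    posterior_mean = (pop$counts + 1) / (rowSums(pop$counts) + k),
    empirical = allele_frequencies(pop))
}

# Core vectorized engine. reads_mat: N x K matrix of non-trivial cells;
# locus_of_row: index of each row's locus into the rows of log_prior_mat
# (n_loci x G). Returns N-vector of per-cell log genotype marginals.
cell_log_marginals <- function(reads_mat, locus_of_row, log_prior_mat, alpha,
                               categories = NUCLEOTIDES) {
  n <- nrow(reads_mat)
  if (n == 0) return(numeric(0))
  logP <- log(genotype_read_prob_matrix(alpha, categories))
  logP[logP == -Inf] <- -.Machine$double.xmax^0.4 # 0*log(0) := 0 at alpha = 0
  ll <- reads_mat %*% t(logP)
  coef <- lgamma(rowSums(reads_mat) + 1) - rowSums(lgamma(reads_mat + 1))
  lw <- ll + log_prior_mat[locus_of_row, , drop = FALSE]
  m <- lw[cbind(seq_len(n), max.col(lw, ties.method = "first"))]
  out <- m + log(rowSums(exp(lw - m))) + coef
  out[m == -Inf] <- -Inf
  out
}

# Cohort loglik for an explicit loci x categories frequency matrix.
loglik_given_freqs <- function(cohort, panel, freqs, alpha, categories,
                               per_locus = FALSE) {
  stopifnot(identical(cohort$loci, panel$locus_id))
  d <- depth_matrix(cohort)
  cells <- which(d > 0, arr.ind = TRUE)
  locus_ll <- stats::setNames(numeric(nrow(panel)), panel$locus_id)
  if (nrow(cells) > 0) {
    reads_mat <- t(vapply(seq_len(nrow(cells)), function(r) {
      cohort$reads[cells[r, 1], cells[r, 2], ]
    }, numeric(length(categories))))
    log_prior <- log_hwe_prior_matrix(freqs, categories)
    cl <- cell_log_marginals(reads_mat, cells[, 2], log_prior, alpha,
                             categories)
    if (any(!is.finite(cl)) && alpha > 0) {
      bad <- unique(panel$locus_id[cells[!is.finite(cl), 2]])
      stop("zero locus likelihood (underflow) at: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    agg <- rowsum(cl, group = cells[, 2])
    locus_ll[as.integer(rownames(agg))] <- agg[, 1]
  }
  if (per_locus) list(total = sum(locus_ll), per_locus = locus_ll)
  else sum(locus_ll)
}

# HWE log-prior matrix for a loci x categories frequency matrix:
# returns n_loci x G.
log_hwe_prior_matrix <- function(freqs, categories = NUCLEOTIDES) {
  g <- genotypes(categories)
  ia <- match(g[, 1], categories)
  ib <- match(g[, 2], categories)
  fa <- freqs[, ia, drop = FALSE]
  fb <- freqs[, ib, drop = FALSE]
  prior <- fa * fb * rep(ifelse(g[, 1] == g[, 2], 1, 2), each = nrow(freqs))
  out <- log(prior)
  dim(out) <- c(nrow(freqs), nrow(g))
  colnames(out) <- rownames(g)
  out
}

#' Maximum-likelihood read error rate
#'
#' Profiles the cohort log-likelihood over the error rate and returns the
#' maximizer. In `"grid"` mode the profile is evaluated on a deterministic
#' equally-spaced grid with point frequencies; in `"sampled"` mode `n`
#' error rates are drawn uniformly from `alpha_range`, each paired with a
#' fresh Dirichlet(counts + 1) frequency draw per locus (the convention
#' used for the likelihood-ratio profile). Ties are broken toward the
#' smallest error rate. A maximum on the range boundary, or a completely
#' flat profile (an all-zero-depth cohort), sets the `boundary` flag.
#'
#' @param cohort A [pileup_cohort()].
#' @param panel The matching [variant_panel()].
#' @param pop A [population_counts()] for the candidate population.
#' @param alpha_range Numeric length-2, the error-rate search interval.
#' @param mode `"grid"` (deterministic) or `"sampled"`.
#' @param n Number of grid points or samples (>= 2).
#' @param freq_point Point-frequency convention for grid mode.
#' @param seed Optional RNG seed for sampled mode.
#' @return A list with `alpha_hat`, `max_loglik`, `boundary`, `flat` and
#'   the `profile` data frame (columns `alpha`, `loglik`).
#' @export
ml_error_rate <- function(cohort, panel, pop, alpha_range = c(0, 0.015),
                          mode = c("grid", "sampled"), n = 61,
                          freq_point = "posterior_mean", seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(alpha_range) == 2, n >= 2,
            alpha_range[1] >= 0, alpha_range[2] < 1)
  if (!is.null(seed)) set.seed(seed)
  categories <- panel_categories(panel)
  if (mode == "grid") {
    alphas <- seq(alpha_range[1], alpha_range[2], length.out = n)
    freqs <- point_frequencies(pop, freq_point)
    ll <- vapply(alphas, function(a) {
      loglik_given_freqs(cohort, panel, freqs, a, categories)
    }, numeric(1))
  } else {
    alphas <- stats::runif(n, alpha_range[1], alpha_range[2])
    ll <- vapply(alphas, function(a) {
      loglik_given_freqs(cohort, panel, draw_frequencies(pop$counts), a,
                         categories)
    }, numeric(1))
  }
  flat <- diff(range(ll[is.finite(ll)])) < 1e-12
  best <- which(ll == max(ll))
  alpha_hat <- min(alphas[best]) # smallest alpha among maxima
  boundary <- flat || isTRUE(all.equal(alpha_hat, alpha_range[1])) ||
    isTRUE(all.equal(alpha_hat, alpha_range[2]))
  if (boundary) {
    warning("maximum-likelihood error rate at range boundary",
            if (flat) " (flat profile: no reads carry error information)",
            call. = FALSE)
  }
  list(alpha_hat = alpha_hat, max_loglik = max(ll), boundary = boundary,
       flat = flat, profile = data.frame(alpha = alphas, loglik = ll))
}

#' Likelihood-ratio profile between two candidate populations
#'
#' The main model-comparison routine. For each of `n_samples` draws of
#' (error rate ~ Uniform(`alpha_range`), per-locus allele frequencies ~
#' Dirichlet(counts + 1)) it evaluates the cohort log-likelihood under
#' each population model; each model then reports the error rate of its
#' best draw as `alpha_hat`, and the overall likelihood ratio is the
#' ratio of the two maximized likelihoods. Draws are independent between
#' the models by default; `paired = TRUE` shares the error-rate sequence.
#'
#' Per-locus likelihood ratios are reported at each model's `alpha_hat`
#' with point frequencies (posterior mean by default); loci where no
#' individual has any read have likelihood exactly 1 under both models
#' and hence LR exactly 1.
#'
#' @param cohort A [pileup_cohort()].
#' @param panel The matching [variant_panel()].
#' @param counts_a,counts_b [population_counts()] for models A and B.
#' @param n_samples Number of (error rate, frequency) draws per model.
#' @param alpha_range Error-rate sampling interval.
#' @param paired Share the sampled error-rate sequence between models?
#' @param freq_point Point-frequency convention for the per-locus LRs.
#' @param seed Optional RNG seed.
#' @return An object of class `likelihood_report`: a list with
#'   `alpha_hat` (named, per model), `max_loglik` (named), `overall_lr`,
#'   `overall_log10_lr`, `per_locus` (data frame with per-model log
#'   likelihoods and `lr` = A/B), `profile` (data frame `model`, `alpha`,
#'   `loglik`), `n_samples`, `populations` and `seed`.
#' @export
likelihood_ratio_profile <- function(cohort, panel, counts_a, counts_b,
                                     n_samples = 5000,
                                     alpha_range = c(0, 0.015),
                                     paired = FALSE,
                                     freq_point = "posterior_mean",
                                     seed = NULL) {
  stopifnot(n_samples >= 1)
  if (!is.null(seed)) set.seed(seed)
  categories <- panel_categories(panel)
  sample_model <- function(pop, alphas) {
    ll <- vapply(alphas, function(a) {
      loglik_given_freqs(cohort, panel, draw_frequencies(pop$counts), a,
                         categories)
    }, numeric(1))
    data.frame(alpha = alphas, loglik = ll)
  }
  alphas_a <- stats::runif(n_samples, alpha_range[1], alpha_range[2])
  prof_a <- sample_model(counts_a, alphas_a)
  alphas_b <- if (paired) alphas_a else {
    stats::runif(n_samples, alpha_range[1], alpha_range[2])
  }
  prof_b <- sample_model(counts_b, alphas_b)
  pick <- function(prof) {
    best <- which(prof$loglik == max(prof$loglik))
    c(alpha = min(prof$alpha[best]), loglik = max(prof$loglik))
  }
  ba <- pick(prof_a)
  bb <- pick(prof_b)
  labels <- c(counts_a$population, counts_b$population)
  per_a <- loglik_given_freqs(cohort, panel,
                              point_frequencies(counts_a, freq_point),
                              ba[["alpha"]], categories, per_locus = TRUE)
  per_b <- loglik_given_freqs(cohort, panel,
                              point_frequencies(counts_b, freq_point),
                              bb[["alpha"]], categories, per_locus = TRUE)
  per_locus <- data.frame(
    locus_id = panel$locus_id,
    loglik_a = as.numeric(per_a$per_locus),
    loglik_b = as.numeric(per_b$per_locus),
    lr = exp(per_a$per_locus - per_b$per_locus),
    stringsAsFactors = FALSE
  )
  structure(list(
    alpha_hat = stats::setNames(c(ba[["alpha"]], bb[["alpha"]]), labels),
    max_loglik = stats::setNames(c(ba[["loglik"]], bb[["loglik"]]), labels),
    overall_lr = exp(ba[["loglik"]] - bb[["loglik"]]),
    overall_log10_lr = (ba[["loglik"]] - bb[["loglik"]]) / log(10),
    per_locus = per_locus,
    profile = rbind(data.frame(model = labels[1], prof_a),
                    data.frame(model = labels[2], prof_b)),
    n_samples = n_samples, populations = labels, seed = seed
  ), class = "likelihood_report")
}

#' @export
print.likelihood_report <- function(x, ...) {
  cat("Population likelihood-ratio report\n")
  cat(sprintf("  models: %s (A) vs %s (B); %d (alpha, frequency) samples\n",
              x$populations[1], x$populations[2], x$n_samples))
  cat(sprintf("  alpha_hat: %s = %.4f, %s = %.4f\n",
              x$populations[1], x$alpha_hat[1],
              x$populations[2], x$alpha_hat[2]))
  cat(sprintf("  max log-likelihood: %s = %.3f, %s = %.3f\n",
              x$populations[1], x$max_loglik[1],
              x$populations[2], x$max_loglik[2]))
  cat(sprintf("  overall LR (A/B) = %.4g (log10 = %.3f)\n",
              x$overall_lr, x$overall_log10_lr))
  invisible(x)
}

#' Private/shared audit of likelihood-ratio-driving loci
#'
#' Classifies each locus that contributes to the overall likelihood ratio
#' by whether its pathogenic-allele reads come from exactly one individual
#' ("private") or several ("shared"), and ranks loci by |log LR|. Private
#' variants are immune to relatedness among the sampled individuals, so a
#' ratio dominated by private loci supports treating the individuals as
#' independent draws from the candidate population.
#'
#' @param report A [likelihood_ratio_profile()] result.
#' @param cohort The [pileup_cohort()] the report was computed from.
#' @param panel The matching [variant_panel()].
#' @return A data frame (one row per locus, sorted by decreasing
#'   |log LR|) with columns `locus_id`, `lr`, `log_lr`,
#'   `n_individuals_with_pathogenic_reads`, `pathogenic_reads`, `status`
#'   (`"private"`, `"shared"` or `"no_pathogenic_reads"`).
#' @export
private_allele_audit <- function(report, cohort, panel) {
  stopifnot(inherits(report, "likelihood_report"),
            identical(report$per_locus$locus_id, panel$locus_id))
  pr <- pathogenic_read_matrix(cohort, panel)
  n_carriers <- colSums(pr > 0)
  status <- ifelse(n_carriers == 0, "no_pathogenic_reads",
                   ifelse(n_carriers == 1, "private", "shared"))
  out <- data.frame(
    locus_id = panel$locus_id,
    lr = report$per_locus$lr,
    log_lr = log(report$per_locus$lr),
    n_individuals_with_pathogenic_reads = as.integer(n_carriers),
    pathogenic_reads = as.integer(colSums(pr)),
    status = status,
    stringsAsFactors = FALSE
  )
  out[order(-abs(out$log_lr)), , drop = FALSE]
}

# log multinomial pmf; 0 * log(0) treated as 0, positive count on a
# zero-probability cell gives -Inf.
log_multinom <- function(x, p) {
  stopifnot(length(x) == length(p), all(x >= 0), all(p >= -1e-15))
  if (any(p <= 0 & x > 0)) return(-Inf)
  nz <- x > 0
  lgamma(sum(x) + 1) - sum(lgamma(x + 1)) + sum(x[nz] * log(p[nz]))
}
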