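#' Draw allele frequencies from the Dirichlet posterior
#'
#' One Dirichlet draw with shape parameters `counts + 1` (observed
#' chromosome counts plus one pseudo-count per category, i.e. the
#' posterior under a uniform prior). This is how allele-frequency
#' uncertainty from finite reference-population samples is propagated
#' into both the simulator and the likelihood. Zero counts give a
#' uniform Dirichlet(1, ..., 1) draw; the posterior mean is
#' `(c_i + 1) / (sum(c) + K)`.
#'
#' @param counts Non-negative counts: a vector (one locus) or a loci x
#'   categories matrix (one independent draw per row).
#' @return A frequency vector summing to 1, or a matrix of row-wise draws.
#' @export
draw_frequencies <- function(counts) {
  if (is.matrix(counts)) {
    stopifnot(all(counts >= 0))
    g <- matrix(stats::rgamma(length(counts), shape = t(counts) + 1),
                nrow = ncol(counts))
    out <- t(g) / colSums(g)
    dimnames(out) <- dimnames(counts)
    return(out)
  }
  stopifnot(all(counts >= 0))
  g <- stats::rgamma(length(counts), shape = counts + 1)
  stats::setNames(g / sum(g), names(counts))
}

#' Simulate one read pileup
#'
#' Multinomial read counts for one (individual, locus) cell: the observed
#' total depth is the number of trials and the error-adjusted allele
#' frequencies ([adjust_frequencies()]) are the cell probabilities.
#'
#' @param freqs True allele frequencies at the locus (summing to 1).
#' @param alpha Per-read miscall probability.
#' @param depth Non-negative integer total read depth.
#' @return Integer vector of per-category read counts summing to `depth`.
#' @export
simulate_pileup <- function(freqs, alpha, depth) {
  stopifnot(depth >= 0, depth == round(depth))
  p <- adjust_frequencies(freqs, alpha)
  if (depth == 0) return(stats::setNames(rep(0L, length(p)), names(freqs)))
  stats::setNames(as.integer(stats::rmultinom(1, depth, p)), names(freqs))
}

#' Simulate a cohort of pileups under a population model
#'
#' One simulated dataset follows the three-stage scheme: per locus, draw
#' allele frequencies from Dirichlet(counts + 1); adjust them by the
#' error rate; then draw each individual's reads from a multinomial with
#' that cell's template depth as the number of trials. One fresh
#' frequency draw is made per locus per simulated dataset (individuals at
#' a locus share the draw; no caching across datasets).
#'
#' @param panel A [variant_panel()].
#' @param pop A [population_counts()] supplying the Dirichlet shape
#'   counts.
#' @param depth_template Integer matrix `n_individuals x n_loci` of total
#'   depths (typically the observed cohort's [depth_matrix()]).
#' @param alpha Per-read miscall probability.
#' @param seed Optional RNG seed.
#' @return A [pileup_cohort()].
#' @export
simulate_cohort <- function(panel, pop, depth_template, alpha, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dim(depth_template))) {
    depth_template <- matrix(depth_template, nrow = 1)
  }
  if (ncol(depth_template) != nrow(panel)) {
    stop("depth_template must have one column per panel locus",
         call. = FALSE)
  }
  individuals <- rownames(depth_template)
  if (is.null(individuals)) {
    individuals <- paste0("sim", seq_len(nrow(depth_template)))
  }
  categories <- panel_categories(panel)
  cohort <- pileup_cohort(individuals = individuals, panel = panel)
  freqs <- draw_frequencies(pop$counts)
  for (j in seq_len(nrow(panel))) {
    p <- adjust_frequencies(freqs[j, ], alpha)
    for (i in seq_len(nrow(depth_template))) {
      d <- depth_template[i, j]
      if (d > 0) {
        cohort$reads[i, j, ] <- as.integer(stats::rmultinom(1, d, p))
      }
    }
  }
  cohort
}

#' Disease-allele read-count statistic
#'
#' The number of panel loci at which at least one read of the pathogenic
#' allele is observed, pooling reads over all individuals (a locus with
#' pathogenic reads in several individuals still counts once).
#'
#' @param cohort A [pileup_cohort()].
#' @param panel The matching [variant_panel()].
#' @return Integer in `0 .. nrow(panel)`.
#' @export
disease_read_statistic <- function(cohort, panel) {
  sum(colSums(pathogenic_read_matrix(cohort, panel)) > 0)
}

#' Null distribution of the disease-read statistic
#'
#' Simulates the statistic under a population model at a fixed error
#' rate, using the observed depths as the template.
#'
#' `method = "binomial"` is an exact fast path: the statistic depends
#' only on the pathogenic category, whose Dirichlet(counts + 1) marginal
#' is Beta(c + 1, sum(c) - c + K - 1); given the error-adjusted
#' pathogenic probability p and the locus's pooled depth D (individuals
#' share the frequency draw, so their multinomials pool), the locus
#' contributes with probability 1 - (1 - p)^D. `method = "cohort"` runs
#' the literal three-stage cohort simulation; the two methods draw from
#' the same distribution (checked in the test suite).
#'
#' @param panel A [variant_panel()].
#' @param pop A [population_counts()].
#' @param depth_template Integer matrix `n_individuals x n_loci`.
#' @param alpha Per-read miscall probability.
#' @param n_sims Number of simulated datasets.
#' @param method `"binomial"` (exact fast path) or `"cohort"`.
#' @param seed Optional RNG seed.
#' @return Integer vector of `n_sims` statistic values.
#' @export
simulate_statistic_null <- function(panel, pop, depth_template, alpha,
                                    n_sims,
                                    method = c("binomial", "cohort"),
                                    seed = NULL) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dim(depth_template))) {
    depth_template <- matrix(depth_template, nrow = 1)
  }
  stopifnot(ncol(depth_template) == nrow(panel), n_sims >= 1)
  if (method == "cohort") {
    return(vapply(seq_len(n_sims), function(s) {
      disease_read_statistic(simulate_cohort(panel, pop, depth_template,
                                             alpha), panel)
    }, integer(1)))
  }
  k <- ncol(pop$counts)
  idx <- cbind(seq_len(nrow(panel)),
               match(panel$pathogenic_allele, colnames(pop$counts)))
  c_path <- pop$counts[idx]
  c_tot <- rowSums(pop$counts)
  d_locus <- colSums(depth_template)
  nl <- nrow(panel)
  live <- d_locus > 0
  out <- integer(n_sims)
  if (!any(live)) return(out)
  shape1 <- c_path[live] + 1
  shape2 <- c_tot[live] - c_path[live] + (k - 1)
  for (s in seq_len(n_sims)) {
    p <- stats::rbeta(sum(live), shape1, shape2)
    p_adj <- p * (1 - alpha) + (1 - p) * alpha / (k - 1)
    hit <- stats::runif(sum(live)) < 1 - (1 - p_adj)^d_locus[live]
    out[s] <- sum(hit)
  }
  out
}

#' Empirical one-tailed p-value
#'
#' The fraction of simulated statistic values greater than or equal to
#' the observed value. The optional `corrected` form `(b + 1)/(n + 1)`
#' never returns exactly zero.
#'
#' @param observed Observed statistic.
#' @param sims Vector of simulated statistic values.
#' @param corrected Use the +1 pseudo-count correction?
#' @return A probability in `[0, 1]`.
#' @export
empirical_tail_p <- function(observed, sims, corrected = FALSE) {
  stopifnot(length(sims) >= 1)
  b <- sum(sims >= observed)
  if (corrected) (b + 1) / (length(sims) + 1) else b / length(sims)
}

#' Statistic null distributions over a (population x error-rate) grid
#'
#' Runs [simulate_statistic_null()] for every combination of candidate
#' population and error-rate value, splitting `n_sims_total` evenly
#' across the error-rate grid within each population. Returns both the
#' raw per-cell statistic draws (the heatmap's columns) and per-cell and
#' pooled tail probabilities for an observed statistic.
#'
#' @param panel A [variant_panel()].
#' @param pop_list List of [population_counts()] objects.
#' @param alpha_grid Error-rate grid (e.g. `seq(0, 0.015, length.out = 15)`).
#' @param n_sims_total Total simulations per population, split evenly
#'   across the grid.
#' @param depth_template Integer matrix `n_individuals x n_loci`.
#' @param observed Observed statistic (or `NULL` to skip tail p-values).
#' @param method Passed to [simulate_statistic_null()].
#' @param seed Optional RNG seed.
#' @return A list with `draws` (data frame `population`, `alpha`,
#'   `statistic`), `cells` (per-cell summary with `tail_p`) and `pooled`
#'   (per-population tail p over all grid cells).
#' @export
heatmap_grid <- function(panel, pop_list, alpha_grid, n_sims_total,
                         depth_template, observed = NULL,
                         method = "binomial", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(alpha_grid) >= 1, n_sims_total >= length(alpha_grid))
  n_cell <- floor(n_sims_total / length(alpha_grid))
  draws <- do.call(rbind, lapply(pop_list, function(pop) {
    do.call(rbind, lapply(alpha_grid, function(a) {
      s <- simulate_statistic_null(panel, pop, depth_template, a, n_cell,
                                   method = method)
      data.frame(population = pop$population, alpha = a, statistic = s,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(draws) <- NULL
  cells <- do.call(rbind, lapply(split(draws, draws[c("population", "alpha")],
                                       drop = TRUE), function(d) {
    data.frame(population = d$population[1], alpha = d$alpha[1],
               n_sims = nrow(d), mean_statistic = mean(d$statistic),
               tail_p = if (is.null(observed)) NA_real_ else {
                 empirical_tail_p(observed, d$statistic)
               }, stringsAsFactors = FALSE)
  }))
  rownames(cells) <- NULL
  cells <- cells[order(cells$population, cells$alpha), , drop = FALSE]
  pooled <- do.call(rbind, lapply(split(draws, draws$population),
                                  function(d) {
    data.frame(population = d$population[1], n_sims = nrow(d),
               tail_p = if (is.null(observed)) NA_real_ else {
                 empirical_tail_p(observed, d$statistic)
               }, stringsAsFactors = FALSE)
  }))
  rownames(pooled) <- NULL
  list(draws = draws, cells = cells, pooled = pooled, observed = observed)
}
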