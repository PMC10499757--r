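#' Read-count test: observed disease-read statistic vs simulated nulls
#'
#' The first of the two headline analyses: computes the observed
#' disease-read statistic for a cohort, simulates its null distribution
#' under each candidate population across a grid of plausible error
#' rates (splitting the simulation budget evenly over the grid), and
#' reports per-cell and pooled one-tailed empirical p-values. If
#' `out_dir` is given, the per-cell table, pooled table and raw draws
#' are written as TSVs with a provenance header.
#'
#' @param cohort The observed [pileup_cohort()].
#' @param panel The matching [variant_panel()].
#' @param counts_a,counts_b [population_counts()] for the two candidate
#'   populations.
#' @param alpha_grid Error-rate grid.
#' @param n_sims_total Total simulations per population.
#' @param method Simulation method (see [simulate_statistic_null()]).
#' @param seed Optional RNG seed (recorded in outputs).
#' @param out_dir Optional output directory.
#' @return The [heatmap_grid()] result, plus elements `observed`,
#'   `summary` (a [cohort_summary()]) and `seed`.
#' @export
run_read_count_test <- function(cohort, panel, counts_a, counts_b,
                                alpha_grid = seq(0, 0.015,
                                                 length.out = 15),
                                n_sims_total = 22500,
                                method = "binomial", seed = NULL,
                                out_dir = NULL) {
  observed <- disease_read_statistic(cohort, panel)
  grid <- heatmap_grid(panel, list(counts_a, counts_b), alpha_grid,
                       n_sims_total, depth_matrix(cohort),
                       observed = observed, method = method, seed = seed)
  grid$summary <- cohort_summary(cohort, panel)
  grid$seed <- seed
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    hdr <- provenance_header(seed, list(
      analysis = "read_count_test", n_sims_total = n_sims_total,
      alpha_grid = paste(signif(alpha_grid, 6), collapse = ","),
      method = method, observed_statistic = observed))
    write_tsv_with_header(grid$cells, file.path(out_dir, "tail_p_cells.tsv"),
                          hdr)
    write_tsv_with_header(grid$pooled, file.path(out_dir, "tail_p_pooled.tsv"),
                          hdr)
    write_tsv_with_header(grid$draws, file.path(out_dir,
                                                "statistic_draws.tsv"), hdr)
  }
  grid
}

#' Population comparison: likelihood profiles and likelihood ratios
#'
#' The second headline analysis: samples (error rate, Dirichlet allele
#' frequency) pairs for each candidate population model, maximizes the
#' cohort likelihood per model, and reports per-model error-rate
#' estimates, the overall likelihood ratio, the per-locus LR table and
#' the private/shared audit. If `out_dir` is given, the profile,
#' per-locus LR table, audit and a key-value summary are written as TSVs
#' with a provenance header.
#'
#' @inheritParams run_read_count_test
#' @param n_samples Number of (error rate, frequency) draws per model.
#' @param alpha_range Error-rate sampling interval.
#' @param paired Share the error-rate sequence between models?
#' @return A list with `report` ([likelihood_ratio_profile()]) and
#'   `audit` ([private_allele_audit()]).
#' @export
run_population_comparison <- function(cohort, panel, counts_a, counts_b,
                                      n_samples = 5000,
                                      alpha_range = c(0, 0.015),
                                      paired = FALSE, seed = NULL,
                                      out_dir = NULL) {
  report <- likelihood_ratio_profile(cohort, panel, counts_a, counts_b,
                                     n_samples = n_samples,
                                     alpha_range = alpha_range,
                                     paired = paired, seed = seed)
  audit <- private_allele_audit(report, cohort, panel)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    hdr <- provenance_header(seed, list(
      analysis = "population_comparison", n_samples = n_samples,
      alpha_range = paste(alpha_range, collapse = ","), paired = paired))
    write_tsv_with_header(report$profile,
                          file.path(out_dir, "likelihood_profile.tsv"), hdr)
    write_tsv_with_header(report$per_locus,
                          file.path(out_dir, "per_locus_lr.tsv"), hdr)
    write_tsv_with_header(audit, file.path(out_dir, "private_audit.tsv"),
                          hdr)
    summ <- data.frame(
      key = c(paste0("alpha_hat_", report$populations),
              paste0("max_loglik_", report$populations),
              "overall_lr", "overall_log10_lr", "n_samples"),
      value = c(report$alpha_hat, report$max_loglik, report$overall_lr,
                report$overall_log10_lr, report$n_samples))
    write_tsv_with_header(summ, file.path(out_dir, "summary.tsv"), hdr)
  }
  list(report = report, audit = audit)
}

provenance_header <- function(seed, config) {
  ver <- tryCatch(as.character(utils::packageVersion("pileupLR")),
                  error = function(e) "dev")
  cfg <- paste(names(config), unlist(lapply(config, paste, collapse = ";")),
               sep = "=", collapse = " ")
  c(sprintf("# pileupLR %s", ver),
    sprintf("# seed=%s", if (is.null(seed)) "NA" else seed),
    sprintf("# config: %s", cfg))
}

write_tsv_with_header <- function(df, path, header_lines) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_lines, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
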