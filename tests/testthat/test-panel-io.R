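test_that("panel TSVs round-trip with order preserved", {
  panel <- toy_panel()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_panel(panel, path)
  back <- read_panel(path)
  expect_identical(back$locus_id, panel$locus_id)
  expect_identical(back$pathogenic_allele, panel$pathogenic_allele)
  expect_identical(back$condition, panel$condition)
})

test_that("malformed panels are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("locus_id\tchrom\tpos\tref\talt\tpathogenic_allele\tcondition",
               "1:100 A>G\t1\t100\tA\tG\tN\tcond"), path)
  expect_error(read_panel(path), "pathogenic_allele")
  writeLines(c("locus_id\tchrom\tpos\tref\talt\tpathogenic_allele\tcondition",
               "1:100 A>G\t1\t100\tA\tG\tG\tcond",
               "1:100 A>G\t1\t100\tA\tG\tG\tcond"), path)
  expect_error(read_panel(path), "duplicate")
  writeLines(c("locus_id\tchrom\tpos\tref\talt\tpathogenic_allele\tcondition",
               "\t1\t100\tA\tG\tG\tcond"), path)
  expect_error(read_panel(path), "malformed")
})

test_that("population counts attach to the panel and round-trip", {
  panel <- toy_panel()
  pop <- toy_counts(panel, path_counts = c(10, 0, 5))
  expect_equal(unname(pop$counts["1:100 A>G", ]), c(990, 0, 10, 0))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_population_counts(pop, path)
  back <- read_population_counts(path, "POPX", panel)
  expect_equal(back$counts, pop$counts)
  expect_identical(back$population, "POPX")
})

test_that("count-file edge cases: negatives, unknown loci, empty files", {
  panel <- toy_panel()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("locus_id\tA\tC\tG\tT", "1:100 A>G\t10\t0\t-1\t0"), path)
  expect_error(read_population_counts(path, "P", panel), "negative")
  writeLines(c("locus_id\tA\tC\tG\tT",
               "1:100 A>G\t990\t0\t10\t0",
               "9:900 A>C\t5\t5\t0\t0"), path)
  expect_warning(pop <- read_population_counts(path, "P", panel),
                 "not in panel")
  expect_equal(unname(pop$counts["1:100 A>G", ]), c(990, 0, 10, 0))
  # header-only file: all-zero counts, unusable under the frequency filter
  writeLines("locus_id\tA\tC\tG\tT", path)
  empty <- read_population_counts(path, "P", panel)
  expect_true(all(empty$counts == 0))
  expect_true(all(is.na(pathogenic_frequency(panel, empty))))
})

test_that("frequency filter keeps strict enrichment and is idempotent", {
  panel <- toy_panel()
  # locus 1: A enriched; locus 2: tie; locus 3: zero total in B
  ca <- toy_counts(panel, path_counts = c(10, 5, 5), label = "A")
  cb <- toy_counts(panel, path_counts = c(1, 5, 0), label = "B")
  cb$counts["3:300 G>C", ] <- 0
  expect_message(kept <- filter_panel_by_frequency(panel, ca, cb),
                 "zero total")
  expect_identical(kept$locus_id, "1:100 A>G")
  kept2 <- suppressMessages(filter_panel_by_frequency(kept, ca, cb))
  expect_identical(kept2$locus_id, kept$locus_id)
})

test_that("pileup files zero-fill unlisted cells and round-trip", {
  panel <- toy_panel()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("individual_id\tlocus_id\tA\tC\tG\tT",
               "S1\t1:100 A>G\t0\t3\t6\t0",
               "S2\t2:200 C>T\t1\t0\t0\t2"), path)
  cohort <- read_pileups(path, panel)
  expect_equal(unname(cohort$reads["S1", "1:100 A>G", ]), c(0, 3, 6, 0))
  expect_equal(sum(depth_matrix(cohort)["S1", ]), 9)
  # cells not listed are zero-depth, not missing
  expect_equal(unname(cohort$reads["S1", "3:300 G>C", ]), c(0, 0, 0, 0))
  expect_equal(unname(depth_matrix(cohort)["S2", ]), c(0, 3, 0))
  out <- withr::local_tempfile(fileext = ".tsv")
  write_pileups(cohort, out)
  back <- read_pileups(out, panel, individuals = cohort$individuals)
  expect_equal(back$reads, cohort$reads)
  writeLines(c("individual_id\tlocus_id\tA\tC\tG\tT",
               "S1\t9:900 A>C\t1\t0\t0\t0"), path)
  expect_warning(read_pileups(path, panel), "not in panel")
})

test_that("cohort summaries count pathogenic reads and loci correctly", {
  panel <- toy_panel()
  empty <- pileup_cohort(individuals = c("S1", "S2"), panel = panel)
  s0 <- cohort_summary(empty, panel)
  expect_equal(s0$n_reads, 0)
  expect_equal(s0$n_pathogenic_loci, 0)
  # pathogenic reads {2, 1, 1} across the three loci -> multiset {2:1, 1:2}
  cohort <- toy_cohort(panel, list(
    S1 = list("1:100 A>G" = c(0, 0, 2, 0), "2:200 C>T" = c(0, 0, 0, 1)),
    S2 = list("3:300 G>C" = c(0, 1, 0, 3))
  ))
  s <- cohort_summary(cohort, panel)
  expect_equal(s$n_pathogenic_reads, 4)
  expect_equal(s$n_pathogenic_loci, 3)
  expect_equal(as.integer(s$pathogenic_multiset[c("1", "2")]), c(2L, 1L))
  # a locus with pathogenic reads in two individuals counts once
  expect_equal(disease_read_statistic(cohort, panel), 3)
})

test_that("summary totals equal arithmetic sums on random cohorts", {
  set.seed(51)
  for (r in 1:10) {
    pb <- generate_panel(n_loci = 12)
    sim <- generate_cohort(pb$panel, pb$counts_a, n_individuals = 3,
                           depth = depth_model(mean_depth = 2))
    s <- cohort_summary(sim$cohort, pb$panel)
    expect_equal(s$n_reads, sum(sim$cohort$reads))
    expect_equal(s$n_pathogenic_reads,
                 sum(s$pathogenic_reads_per_locus))
    expect_equal(s$n_pathogenic_loci,
                 disease_read_statistic(sim$cohort, pb$panel))
  }
})

test_that("shipped synthetic fixtures load and pass the frequency filter", {
  ext <- function(f) system.file("extdata", f, package = "pileupLR")
  panel <- read_panel(ext("synthetic_panel_159.tsv"))
  expect_equal(nrow(panel), 159)
  ca <- read_population_counts(ext("synthetic_counts_POPA.tsv"), "POPA",
                               panel)
  cb <- read_population_counts(ext("synthetic_counts_POPB.tsv"), "POPB",
                               panel)
  kept <- filter_panel_by_frequency(panel, ca, cb)
  expect_equal(nrow(kept), 159) # enrichment built in by construction
  cohort <- read_pileups(ext("synthetic_pileups_6ind.tsv"), panel)
  expect_equal(length(cohort$individuals), 6)
  expect_gt(sum(cohort$reads), 0)
})
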