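#!/usr/bin/env Rscript
# Stage 1: assemble the study inputs.
#
# Loads the shipped synthetic stand-in panel (159 founder-enriched disease
# loci with allele counts for an enriched population A and a background
# population B), applies the pathogenic-frequency retention filter, and
# loads the 6-individual synthetic cohort of read pileups. Writes the
# filtered panel and a cohort summary under results/data/.

suppressPackageStartupMessages(library(pileupLR))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
ext <- function(f) system.file("extdata", f, package = "pileupLR")

panel <- read_panel(ext("synthetic_panel_159.tsv"))
counts_a <- read_population_counts(ext("synthetic_counts_POPA.tsv"),
                                   "POPA", panel)
counts_b <- read_population_counts(ext("synthetic_counts_POPB.tsv"),
                                   "POPB", panel)
message(nrow(panel), " candidate loci")

panel <- filter_panel_by_frequency(panel, counts_a, counts_b)
message(nrow(panel), " loci retained where the pathogenic allele is more ",
        "frequent in population A")

cohort <- read_pileups(ext("synthetic_pileups_6ind.tsv"), panel)
s <- cohort_summary(cohort, panel)
message(sprintf(
  "cohort: %d individuals, %d total reads, %d pathogenic reads at %d loci",
  length(cohort$individuals), s$n_reads, s$n_pathogenic_reads,
  s$n_pathogenic_loci))
message("pathogenic reads per locus (multiset): ",
        paste(sprintf("%s:%d", names(s$pathogenic_multiset),
                      as.integer(s$pathogenic_multiset)), collapse = " "))
message(sprintf("zero-depth cells: %.1f%%",
                100 * mean(depth_matrix(cohort) == 0)))

write_panel(panel, file.path(out, "panel_filtered.tsv"))
write_population_counts(counts_a, file.path(out, "counts_POPA.tsv"))
write_population_counts(counts_b, file.path(out, "counts_POPB.tsv"))
write_pileups(cohort, file.path(out, "pileups.tsv"))
per_locus <- data.frame(locus_id = names(s$pathogenic_reads_per_locus),
                        pathogenic_reads = as.integer(s$pathogenic_reads_per_locus))
write.table(per_locus, file.path(out, "pathogenic_reads_per_locus.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("inputs written to ", out)
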