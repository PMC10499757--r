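# Independent oracles, kept deliberately naive and separate from the
# package's computation paths.

# Literal joint-genotype enumeration of the locus likelihood: sums the
# HWE-weighted product of per-individual multinomial likelihoods over all
# G^n joint genotype assignments, with dmultinom() as the pmf. Feasible
# for <= 3 individuals at K = 4 (10^3 terms).
oracle_locus_likelihood <- function(reads, freqs, alpha,
                                    categories = NUCLEOTIDES) {
  if (is.null(dim(reads))) reads <- matrix(reads, nrow = 1)
  g <- genotypes(categories)
  n <- nrow(reads)
  k <- length(categories)
  p1 <- 1 - alpha
  p2 <- alpha / (k - 1)
  # heterozygote cell probability; at K = 4 this is the textbook 0.5 - p2
  p3 <- if (k == 4) 0.5 - p2 else (1 - (k - 2) * p2) / 2
  gprob <- function(gi) {
    pr <- rep(p2, length(categories))
    if (g[gi, 1] == g[gi, 2]) {
      pr[match(g[gi, 1], categories)] <- p1
    } else {
      pr[match(g[gi, ], categories)] <- p3
    }
    pr
  }
  prior <- vapply(seq_len(nrow(g)), function(gi) {
    fa <- freqs[match(g[gi, 1], categories)]
    fb <- freqs[match(g[gi, 2], categories)]
    if (g[gi, 1] == g[gi, 2]) fa * fb else 2 * fa * fb
  }, numeric(1))
  assignments <- expand.grid(rep(list(seq_len(nrow(g))), n))
  total <- 0
  for (r in seq_len(nrow(assignments))) {
    gi <- as.integer(assignments[r, ])
    term <- prod(prior[gi])
    for (i in seq_len(n)) {
      if (sum(reads[i, ]) > 0) {
        term <- term * dmultinom(reads[i, ], prob = gprob(gi[i]))
      }
    }
    total <- total + term
  }
  total
}

# Deterministic small panel + cohort used across test files.
toy_panel <- function() {
  variant_panel(
    locus_id = c("1:100 A>G", "2:200 C>T", "3:300 G>C"),
    chrom = c("1", "2", "3"), pos = c(100, 200, 300),
    ref = c("A", "C", "G"), alt = c("G", "T", "C"),
    pathogenic_allele = c("G", "T", "C"),
    condition = c("cond1", "cond2", "cond3")
  )
}

toy_counts <- function(panel, path_counts, totals = 1000,
                       label = "POPX") {
  k <- 4
  cnt <- matrix(0, nrow(panel), k,
                dimnames = list(panel$locus_id, NUCLEOTIDES))
  for (j in seq_len(nrow(panel))) {
    pa <- match(panel$pathogenic_allele[j], NUCLEOTIDES)
    ra <- match(panel$ref[j], NUCLEOTIDES)
    cnt[j, pa] <- path_counts[j]
    cnt[j, ra] <- totals - path_counts[j]
  }
  population_counts(cnt, label)
}

toy_cohort <- function(panel, reads_list, individuals = names(reads_list)) {
  cohort <- pileup_cohort(individuals = individuals, panel = panel)
  for (ind in individuals) {
    for (locus in names(reads_list[[ind]])) {
      j <- match(locus, panel$locus_id)
      cohort$reads[ind, j, ] <- reads_list[[ind]][[locus]]
    }
  }
  cohort
}
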