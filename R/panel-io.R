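#' Construct a variant panel
#'
#' A variant panel is the set of disease-associated biallelic loci under
#' study: an opaque locus identifier (typically "chrom:pos ref>alt" with a
#' genome-build label; no coordinate arithmetic is ever performed on it),
#' reference and alternate alleles, the allele designated as pathogenic,
#' and a free-text condition label. Carried as a data frame of class
#' `variant_panel`.
#'
#' @param locus_id Character, unique per locus.
#' @param chrom,pos,ref,alt Locus description columns (kept verbatim).
#' @param pathogenic_allele One symbol per locus, drawn from `categories`.
#' @param condition Free-text disease label.
#' @param source Optional provenance string (recycled).
#' @param categories Ordered allele categories shared by the panel.
#' @return A `variant_panel` data frame.
#' @export
variant_panel <- function(locus_id, chrom = NA, pos = NA, ref = NA, alt = NA,
                          pathogenic_allele, condition = NA,
                          source = NA_character_,
                          categories = NUCLEOTIDES) {
  panel <- data.frame(
    locus_id = as.character(locus_id),
    chrom = as.character(chrom), pos = pos,
    ref = as.character(ref), alt = as.character(alt),
    pathogenic_allele = as.character(pathogenic_allele),
    condition = as.character(condition),
    source = as.character(source),
    stringsAsFactors = FALSE
  )
  validate_panel(panel, categories)
  attr(panel, "categories") <- categories
  class(panel) <- c("variant_panel", "data.frame")
  panel
}

validate_panel <- function(panel, categories) {
  dup <- panel$locus_id[duplicated(panel$locus_id)]
  if (length(dup)) {
    stop("duplicate locus_id in panel: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad <- !(panel$pathogenic_allele %in% categories)
  if (any(bad)) {
    stop("pathogenic_allele not in categories at row(s) ",
         paste(which(bad), collapse = ", "), ": ",
         paste(unique(panel$pathogenic_allele[bad]), collapse = ", "),
         call. = FALSE)
  }
  invisible(panel)
}

#' Read a variant panel from a TSV file
#'
#' Expects a tab-separated file with a header containing at least the
#' columns `locus_id`, `chrom`, `pos`, `ref`, `alt`, `pathogenic_allele`,
#' `condition`. Lines starting with `#` are comments. Input row order is
#' preserved. Malformed rows (missing fields, pathogenic allele outside
#' the category set) and duplicated locus identifiers are hard errors.
#'
#' @param path Path to the panel TSV.
#' @param categories Ordered allele categories.
#' @return A [variant_panel()] data frame.
#' @export
read_panel <- function(path, categories = NUCLEOTIDES) {
  tab <- read_tsv_checked(path,
    required = c("locus_id", "chrom", "pos", "ref", "alt",
                 "pathogenic_allele", "condition"))
  incomplete <- which(is.na(tab$locus_id) | tab$locus_id == "" |
                        is.na(tab$pathogenic_allele))
  if (length(incomplete)) {
    stop("malformed panel row(s) (data line ",
         paste(incomplete, collapse = ", "), ") in ", path, call. = FALSE)
  }
  variant_panel(tab$locus_id, tab$chrom, tab$pos, tab$ref, tab$alt,
                tab$pathogenic_allele, tab$condition,
                source = if ("source" %in% names(tab)) tab$source else path,
                categories = categories)
}

#' Write a variant panel to TSV
#'
#' @param panel A [variant_panel()].
#' @param path Output path.
#' @export
write_panel <- function(panel, path) {
  write_tsv_plain(as.data.frame(panel), path)
}

#' Population allele counts for a panel
#'
#' Integer chromosome counts per category (exome and genome counts are
#' assumed pre-combined) for one reference population, aligned to the
#' panel loci. Stored as a loci x categories integer matrix plus the
#' population label.
#'
#' @param counts Integer matrix, one row per locus (rownames = locus_id),
#'   one column per category.
#' @param population_label Population name, e.g. `"ASJ"` or `"NFE"`.
#' @return An object of class `pop_counts` with elements `population` and
#'   `counts`.
#' @export
population_counts <- function(counts, population_label) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("allele counts must be non-negative integers", call. = FALSE)
  }
  storage.mode(counts) <- "double"
  structure(list(population = population_label, counts = counts),
            class = "pop_counts")
}

#' Read population allele counts from a TSV file
#'
#' Expects columns `locus_id` plus one integer count column per category
#' (default `A`, `C`, `G`, `T`). Loci present in the file but absent from
#' the panel are skipped with a warning; negative counts are a hard error.
#' Panel loci absent from the file get zero counts (such loci are unusable
#' under this population model and are excluded by the frequency filter).
#'
#' @param path Path to the counts TSV.
#' @param population_label Population name attached to the result.
#' @param panel The [variant_panel()] the counts belong to.
#' @return A [population_counts()] object with one row per panel locus, in
#'   panel order.
#' @export
read_population_counts <- function(path, population_label, panel) {
  categories <- panel_categories(panel)
  tab <- read_tsv_checked(path, required = c("locus_id", categories))
  cnt <- as.matrix(tab[, categories, drop = FALSE])
  if (any(is.na(cnt)) || any(cnt < 0)) {
    stop("negative or missing allele count in ", path, call. = FALSE)
  }
  unknown <- setdiff(tab$locus_id, panel$locus_id)
  if (length(unknown)) {
    warning("skipping ", length(unknown), " locus/loci not in panel: ",
            paste(utils::head(unknown, 5), collapse = ", "),
            if (length(unknown) > 5) ", ...", call. = FALSE)
  }
  out <- matrix(0, nrow = nrow(panel), ncol = length(categories),
                dimnames = list(panel$locus_id, categories))
  keep <- tab$locus_id %in% panel$locus_id
  out[tab$locus_id[keep], ] <- cnt[keep, , drop = FALSE]
  population_counts(out, population_label)
}

#' Write population allele counts to TSV
#'
#' @param pop A [population_counts()] object.
#' @param path Output path.
#' @export
write_population_counts <- function(pop, path) {
  df <- data.frame(locus_id = rownames(pop$counts), pop$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_plain(df, path)
}

panel_categories <- function(panel) {
  cats <- attr(panel, "categories")
  if (is.null(cats)) NUCLEOTIDES else cats
}

#' Per-locus allele frequencies from counts
#'
#' Plain count/total frequencies. Loci with zero total count get `NA`
#' frequencies (no information under that population model).
#'
#' @param pop A [population_counts()] object.
#' @return Numeric matrix of frequencies, same shape as `pop$counts`.
#' @export
allele_frequencies <- function(pop) {
  tot <- rowSums(pop$counts)
  f <- pop$counts / tot
  f[tot == 0, ] <- NA_real_
  f
}

#' Pathogenic-allele frequency per locus
#'
#' @param panel A [variant_panel()].
#' @param pop A [population_counts()] aligned to the panel.
#' @return Named numeric vector, one frequency per panel locus (`NA` where
#'   the population has zero total count).
#' @export
pathogenic_frequency <- function(panel, pop) {
  f <- allele_frequencies(pop)
  idx <- cbind(match(panel$locus_id, rownames(pop$counts)),
               match(panel$pathogenic_allele, colnames(pop$counts)))
  out <- f[idx]
  names(out) <- panel$locus_id
  out
}

#' Retain loci where the pathogenic allele is enriched in population A
#'
#' Keeps exactly the panel loci at which the pathogenic allele's frequency
#' (count / total) in population A strictly exceeds that in population B.
#' Loci with zero total count in either population are excluded (and
#' reported via a message), since no frequency comparison is possible.
#' The operation is idempotent.
#'
#' @param panel A [variant_panel()].
#' @param counts_a,counts_b [population_counts()] for the two populations.
#' @return The filtered [variant_panel()], input order preserved.
#' @export
filter_panel_by_frequency <- function(panel, counts_a, counts_b) {
  fa <- pathogenic_frequency(panel, counts_a)
  fb <- pathogenic_frequency(panel, counts_b)
  uninformative <- is.na(fa) | is.na(fb)
  if (any(uninformative)) {
    message("excluding ", sum(uninformative),
            " locus/loci with zero total count in a population")
  }
  keep <- !uninformative & fa > fb
  out <- panel[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "categories") <- panel_categories(panel)
  class(out) <- c("variant_panel", "data.frame")
  out
}

#' Construct a pileup cohort
#'
#' Per-individual, per-locus read counts over the allele categories, held
#' as a 3-d array indexed `[individual, locus, category]`. Zero-depth
#' cells are legal and common in low-coverage ancient-DNA data.
#'
#' @param reads Numeric array `n_individuals x n_loci x n_categories` with
#'   dimnames, or omitted to create an all-zero cohort.
#' @param individuals Individual identifiers.
#' @param panel The [variant_panel()] defining loci and categories.
#' @return An object of class `pileup_cohort` with elements `individuals`,
#'   `loci` and `reads`.
#' @export
pileup_cohort <- function(reads = NULL, individuals, panel) {
  categories <- panel_categories(panel)
  if (is.null(reads)) {
    reads <- array(0, dim = c(length(individuals), nrow(panel),
                              length(categories)),
                   dimnames = list(individuals, panel$locus_id, categories))
  }
  stopifnot(length(dim(reads)) == 3,
            dim(reads)[1] == length(individuals),
            dim(reads)[2] == nrow(panel),
            dim(reads)[3] == length(categories))
  if (any(reads < 0)) stop("read counts must be non-negative", call. = FALSE)
  dimnames(reads) <- list(individuals, panel$locus_id, categories)
  structure(list(individuals = individuals, loci = panel$locus_id,
                 reads = reads),
            class = "pileup_cohort")
}

#' Read per-individual pileups from a TSV file
#'
#' Expects columns `individual_id`, `locus_id` and one count column per
#' category. Cells not listed in the file are zero-depth (not errors:
#' zero-depth loci carry no information and contribute likelihood 1).
#' Rows whose locus is absent from the panel are skipped with a warning.
#'
#' @param path Path to the pileup TSV.
#' @param panel The [variant_panel()].
#' @param individuals Optional individual ordering; defaults to order of
#'   first appearance in the file.
#' @return A [pileup_cohort()].
#' @export
read_pileups <- function(path, panel, individuals = NULL) {
  categories <- panel_categories(panel)
  tab <- read_tsv_checked(path,
    required = c("individual_id", "locus_id", categories))
  unknown <- setdiff(tab$locus_id, panel$locus_id)
  if (length(unknown)) {
    warning("skipping ", length(unknown), " pileup locus/loci not in panel: ",
            paste(utils::head(unknown, 5), collapse = ", "),
            if (length(unknown) > 5) ", ...", call. = FALSE)
    tab <- tab[tab$locus_id %in% panel$locus_id, , drop = FALSE]
  }
  if (is.null(individuals)) individuals <- unique(tab$individual_id)
  cohort <- pileup_cohort(individuals = individuals, panel = panel)
  cnt <- as.matrix(tab[, categories, drop = FALSE])
  if (any(is.na(cnt)) || any(cnt < 0)) {
    stop("negative or missing read count in ", path, call. = FALSE)
  }
  i <- match(tab$individual_id, individuals)
  j <- match(tab$locus_id, panel$locus_id)
  for (k in seq_along(categories)) {
    # accumulate in case a cell is split across rows
    m <- cohort$reads[, , k]
    m[cbind(i, j)] <- m[cbind(i, j)] + cnt[, k]
    cohort$reads[, , k] <- m
  }
  cohort
}

#' Write a pileup cohort to TSV (long format)
#'
#' Only cells with depth > 0 are written; [read_pileups()] restores the
#' zero cells, so write-then-read round-trips the cohort exactly.
#'
#' @param cohort A [pileup_cohort()].
#' @param path Output path.
#' @export
write_pileups <- function(cohort, path) {
  d <- depth_matrix(cohort)
  idx <- which(d > 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  cats <- dimnames(cohort$reads)[[3]]
  cnt <- vapply(seq_along(cats), function(k) {
    m <- matrix(cohort$reads[, , k], nrow = dim(cohort$reads)[1])
    m[idx]
  }, numeric(nrow(idx)))
  cnt <- matrix(cnt, ncol = length(cats), dimnames = list(NULL, cats))
  df <- data.frame(individual_id = cohort$individuals[idx[, 1]],
                   locus_id = cohort$loci[idx[, 2]],
                   cnt, check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_plain(df, path)
}

#' Total read depth per (individual, locus) cell
#'
#' @param cohort A [pileup_cohort()].
#' @return Integer matrix `n_individuals x n_loci`.
#' @export
depth_matrix <- function(cohort) {
  apply(cohort$reads, c(1, 2), sum)
}

#' Summarize a cohort against its panel
#'
#' Reports the totals the method's inputs are usually described by: total
#' reads, reads of the pathogenic allele, the number of loci with at least
#' one pathogenic read, per-locus pathogenic read counts (summed over
#' individuals), and the multiset of those counts (how many loci have 1,
#' 2, ... pathogenic reads).
#'
#' @param cohort A [pileup_cohort()].
#' @param panel The matching [variant_panel()].
#' @return A list with elements `n_reads`, `n_pathogenic_reads`,
#'   `n_pathogenic_loci`, `pathogenic_reads_per_locus` (named vector) and
#'   `pathogenic_multiset` (table over positive counts).
#' @export
cohort_summary <- function(cohort, panel) {
  stopifnot(identical(cohort$loci, panel$locus_id))
  path_reads <- pathogenic_read_matrix(cohort, panel)
  per_locus <- colSums(path_reads)
  pos <- per_locus[per_locus > 0]
  list(
    n_reads = sum(cohort$reads),
    n_pathogenic_reads = sum(per_locus),
    n_pathogenic_loci = sum(per_locus > 0),
    pathogenic_reads_per_locus = per_locus,
    pathogenic_multiset = table(factor(pos))
  )
}

# n_individuals x n_loci matrix of pathogenic-allele read counts
pathogenic_read_matrix <- function(cohort, panel) {
  cats <- dimnames(cohort$reads)[[3]]
  k <- match(panel$pathogenic_allele, cats)
  n_ind <- length(cohort$individuals)
  out <- matrix(0, n_ind, nrow(panel),
                dimnames = list(cohort$individuals, panel$locus_id))
  for (j in seq_len(nrow(panel))) {
    out[, j] <- cohort$reads[, j, k[j]]
  }
  out
}

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE,
                           check.names = FALSE)
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
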