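#' Default allele categories
#'
#' Read pileups and allele frequencies are tallied over an ordered set of
#' allele categories; the default is the four nucleotides. All functions in
#' the package generalize to K >= 2 categories (e.g. REF/ALT two-category
#' loci for indels detected by realignment upstream), and reduce exactly to
#' the four-nucleotide formulas at K = 4.
#'
#' @format Character vector `c("A", "C", "G", "T")`.
#' @export
NUCLEOTIDES <- c("A", "C", "G", "T")

#' Enumerate unordered diploid genotypes
#'
#' All K(K+1)/2 unordered allele pairs over a category set, in the
#' conventional lexicographic order (for the nucleotides: AA, AC, AG, AT,
#' CC, CG, CT, GG, GT, TT).
#'
#' @param categories Character vector of allele symbols.
#' @return A two-column character matrix with one row per genotype; row
#'   names are the concatenated allele pairs (e.g. `"AC"`).
#' @examples
#' genotypes() # the 10 diploid nucleotide genotypes
#' genotypes(c("R", "A")) # RR, RA, AA
#' @export
genotypes <- function(categories = NUCLEOTIDES) {
  k <- length(categories)
  idx <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  g <- cbind(categories[idx[, "row"]], categories[idx[, "col"]])
  rownames(g) <- paste0(g[, 1], g[, 2])
  colnames(g) <- c("a1", "a2")
  g
}

# Validate a category-probability vector: non-negative, sums to 1.
check_probs <- function(probs, tol = 1e-8, what = "freqs") {
  if (!is.numeric(probs) || length(probs) < 2) {
    stop(what, " must be a numeric vector of length >= 2", call. = FALSE)
  }
  if (any(probs < 0)) stop(what, " must be non-negative", call. = FALSE)
  if (abs(sum(probs) - 1) > tol) {
    stop(what, " must sum to 1 (got ", format(sum(probs)), ")", call. = FALSE)
  }
  invisible(probs)
}
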