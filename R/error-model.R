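#' Error-adjust population allele frequencies
#'
#' Applies the symmetric per-read miscall model to a vector of true allele
#' frequencies: a read from an allele of frequency `f` is reported correctly
#' with probability `1 - alpha` and as each of the other K - 1 categories
#' with probability `alpha / (K - 1)`. The adjusted frequency of category i
#' is therefore
#'
#'   `f_i * (1 - alpha) + (1 - f_i) * alpha / (K - 1)`
#'
#' which at K = 4 is the familiar `f_i (1 - a) + (1 - f_i) a/3`. The
#' adjusted vector sums to 1, the uniform vector is a fixed point, and
#' `alpha = 0` is the identity.
#'
#' @param freqs Numeric vector of category frequencies, summing to 1.
#' @param alpha Per-read miscall probability in `[0, 1)`. The plausible
#'   range for UDG-treated, recalibrated ancient-DNA data is 0 to 0.015.
#' @return Numeric vector of adjusted frequencies, same length as `freqs`.
#' @examples
#' adjust_frequencies(c(1, 0, 0, 0), 0.015) # 0.985 0.005 0.005 0.005
#' @export
adjust_frequencies <- function(freqs, alpha) {
  check_probs(freqs)
  check_alpha(alpha)
  k <- length(freqs)
  freqs * (1 - alpha) + (1 - freqs) * alpha / (k - 1)
}

#' Read-category probabilities for a genotype
#'
#' The probability that a single read from a diploid individual of a given
#' genotype reports each allele category, under the symmetric error model.
#' Writing `p1 = 1 - alpha` and `p2 = alpha / (K - 1)`:
#'
#' * homozygote a/a: category a has probability `p1`, all others `p2`;
#' * heterozygote a/b: categories a and b each have probability
#'   `p3 = 0.5 * (1 - alpha) + 0.5 * alpha / (K - 1)` (at K = 4 this is
#'   `0.5 - alpha/3`), all others `p2`.
#'
#' The vector always sums to 1.
#'
#' @param genotype Length-2 character vector of alleles (unordered), or a
#'   single 2-character string such as `"CG"`.
#' @param alpha Per-read miscall probability in `[0, 1)`.
#' @param categories Ordered allele categories.
#' @return Named numeric probability vector over `categories`.
#' @examples
#' genotype_read_probs("GG", 0.009) # 0.003 0.003 0.991 0.003
#' genotype_read_probs(c("C", "G"), 0) # 0 0.5 0.5 0
#' @export
genotype_read_probs <- function(genotype, alpha, categories = NUCLEOTIDES) {
  check_alpha(alpha)
  genotype <- split_genotype(genotype, categories)
  k <- length(categories)
  p2 <- alpha / (k - 1)
  probs <- rep(p2, k)
  names(probs) <- categories
  if (genotype[1] == genotype[2]) {
    probs[genotype[1]] <- 1 - alpha
  } else {
    p3 <- 0.5 * (1 - alpha) + 0.5 * p2
    probs[genotype] <- p3
  }
  probs
}

#' Read-probability matrix over all genotypes
#'
#' Stacks [genotype_read_probs()] for every unordered genotype into a
#' G x K matrix (rows ordered as [genotypes()]). This is the building
#' block the vectorized likelihood engine uses: it depends on `alpha`
#' only, not on the locus.
#'
#' @inheritParams genotype_read_probs
#' @return Numeric matrix, one row per genotype, one column per category;
#'   each row sums to 1.
#' @export
genotype_read_prob_matrix <- function(alpha, categories = NUCLEOTIDES) {
  check_alpha(alpha)
  g <- genotypes(categories)
  k <- length(categories)
  p2 <- alpha / (k - 1)
  p3 <- 0.5 * (1 - alpha) + 0.5 * p2
  m <- matrix(p2, nrow = nrow(g), ncol = k,
              dimnames = list(rownames(g), categories))
  hom <- g[, 1] == g[, 2]
  m[cbind(which(hom), match(g[hom, 1], categories))] <- 1 - alpha
  m[cbind(which(!hom), match(g[!hom, 1], categories))] <- p3
  m[cbind(which(!hom), match(g[!hom, 2], categories))] <- p3
  m
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha < 0 || alpha >= 1) {
    stop("alpha must be a single probability in [0, 1)", call. = FALSE)
  }
  invisible(alpha)
}

split_genotype <- function(genotype, categories) {
  if (length(genotype) == 1 && nchar(genotype) == 2 &&
      all(nchar(categories) == 1)) {
    genotype <- strsplit(genotype, "")[[1]]
  }
  if (length(genotype) != 2 || !all(genotype %in% categories)) {
    stop("genotype must be two alleles drawn from the categories",
         call. = FALSE)
  }
  genotype
}
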