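#' Maximum-likelihood allele and genotype frequencies
#'
#' Under multinomial sampling of unordered genotypes, the MLE of the
#' genotype frequencies are the sample proportions p_jk = n_jk / N and the
#' MLE of the allele frequencies are the allele count ratios
#' p_j = n_j. / (2N), where n_j. = 2 n_jj + sum_{k != j} n_jk.
#' Frequencies are formed directly from the integer counts, so identities
#' such as sum_j p_j = 1 hold exactly.
#'
#' @param x a [genotype_dataset()] or a symmetric genotype count matrix.
#' @param which_locus locus index when `x` is a dataset.
#' @return A list with `p` (named allele frequencies), `P` (symmetric
#'   genotype frequency matrix, entries p_jk with the diagonal plus upper
#'   triangle summing to 1), `counts` and `N`.
#' @export
mle_frequencies <- function(x, which_locus = 1L) {
  counts <- if (inherits(x, "genotype_dataset")) genotype_counts(x, which_locus)
            else as.matrix(x)
  if (!isTRUE(all.equal(counts, t(counts))))
    stop("genotype count matrix must be symmetric")
  N <- sum(counts[upper.tri(counts, diag = TRUE)])
  if (N == 0) stop("no individuals: N = 0")
  nj <- diag(counts) + rowSums(counts)      # 2 n_jj + sum_{k != j} n_jk
  p <- nj / (2 * N)
  if (any(p == 1))
    warning("locus is monomorphic in this sample")
  P <- counts / N
  list(p = p, P = P, counts = counts, N = N)
}

#' Hardy-Weinberg disequilibrium coefficients
#'
#' The departure of genotype frequencies from the Hardy-Weinberg products:
#' D_jj = p_jj - p_j^2 and D_jk = p_jk / 2 - p_j p_k for j != k.  These
#' equal the covariances between the paternal and maternal allele
#' indicators, and every row and column of the D matrix sums to zero when
#' the frequencies come from one consistent count table.
#'
#' When the input carries integer counts the coefficients are formed from
#' an integer numerator over 4N^2 (D_jj = (4N n_jj - n_j.^2) / (4N^2) and
#' D_jk = (2N n_jk - n_j. n_k.) / (4N^2)), so exact Hardy-Weinberg counts
#' give coefficients that are exactly zero in floating point.
#'
#' @inheritParams mle_frequencies
#' @return An m-by-m symmetric matrix of D_jk estimates.
#' @examples
#' hwd_coefficients(matrix(c(4, 12, 12, 9), 2))  # exact HWE: all zero
#' @export
hwd_coefficients <- function(x, which_locus = 1L) {
  fr <- mle_frequencies(x, which_locus)
  N <- fr$N
  counts <- fr$counts
  nj <- diag(counts) + rowSums(counts)
  num <- 2 * N * counts - outer(nj, nj)
  diag(num) <- 4 * N * diag(counts) - nj^2
  num / (4 * N^2)
}

#' Joint two-locus disequilibrium coefficients
#'
#' Dependence between the inheritance of alleles at two loci, measured
#' cellwise as D_jkrs = p_jkrs / ((2 - 1\{j=k\})(2 - 1\{r=s\})) -
#' p_j p_k p_r p_s, where p_jkrs is the unordered joint genotype frequency.
#' All coefficients are zero when both loci are in exact HWE and the loci
#' are independent.
#'
#' @param ds a two-locus [genotype_dataset()].
#' @return A (m1, m1, m2, m2) array of D_jkrs estimates.
#' @export
joint_hwd_coefficients <- function(ds) {
  stopifnot(inherits(ds, "genotype_dataset"), length(ds$loci) == 2L)
  counts <- joint_genotype_counts(ds)
  N <- ds$n
  p1 <- mle_frequencies(ds, 1L)$p
  p2 <- mle_frequencies(ds, 2L)$p
  m1 <- length(p1); m2 <- length(p2)
  het1 <- 2 - outer(seq_len(m1), seq_len(m1), `==`)   # 2 - 1{j=k}
  het2 <- 2 - outer(seq_len(m2), seq_len(m2), `==`)
  denom <- outer(het1, het2)                          # (2-1{j=k})(2-1{r=s})
  expected <- outer(outer(p1, p1), outer(p2, p2))     # p_j p_k p_r p_s
  counts / N / denom - expected
}
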