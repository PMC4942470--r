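#' Genotype coding variables
#'
#' Two coding schemes for unordered genotypes are supported.  The GLM
#' (dummy-variable) scheme counts allele copies and indicates genotype
#' identity: w_j(g) is the number of copies of allele A_j carried (0, 1 or
#' 2) and v_jk(g) = 1 exactly when g = AjAk.  The GMA scheme applies a mean
#' correction derived from the latent (phase-level) allele indicators:
#'
#'   w*_j  = w_j - 2 p_j
#'   v*_jj = v_jj - p_j w_j + p_j^2
#'   v*_jk = v_jk - p_j w_k - p_k w_j + 2 p_j p_k   (j != k)
#'
#' Under any genotype distribution whose allele frequencies match the
#' supplied p, every w*_j has mean zero; under Hardy-Weinberg equilibrium
#' the v*_jk are also mean-zero and uncorrelated with the w*_j, which is
#' what makes the GMA variance partition orthogonal.
#'
#' Columns for the reference allele (the last allele of the locus) are
#' omitted unless `full = TRUE`; the reduced set parameterizes the model
#' without rank deficiency.
#'
#' @param geno an n-by-2 integer matrix of sorted allele indices, or a
#'   character vector of "a/b" genotype strings resolved against `loc`.
#' @param loc a [locus()] object.
#' @param p allele frequencies used for the mean correction (GMA only);
#'   defaults to `loc$freqs`.
#' @param full if `TRUE`, emit codes for all m alleles (used to examine the
#'   redundancy identities); otherwise only alleles 1..m-1.
#' @return A numeric matrix with labeled columns: first the w (or `w*`)
#'   columns, then the v (or `v*`) columns in pair order (1,1), (1,2), ...
#' @examples
#' loc <- locus("L1", c("1", "0"), freqs = c(0.4, 0.6))
#' glm_codes(c("1/1", "1/0", "0/0"), loc)
#' gma_codes(c("1/1", "1/0", "0/0"), loc)
#' @export
glm_codes <- function(geno, loc, full = FALSE) {
  g <- resolve_geno(geno, loc)
  m <- loc$m
  mm <- if (full) m else m - 1L
  w <- sapply(seq_len(mm), function(j) (g[, 1L] == j) + (g[, 2L] == j))
  w <- matrix(w, ncol = mm)
  pairs <- pair_index(mm)
  v <- matrix(0, nrow(g), nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    v[, i] <- as.numeric(g[, 1L] == pairs[i, 1L] & g[, 2L] == pairs[i, 2L])
  }
  out <- cbind(w, v)
  colnames(out) <- code_labels(loc, "glm", full)
  out
}

#' @rdname glm_codes
#' @export
gma_codes <- function(geno, loc, p = loc$freqs, full = FALSE) {
  if (is.null(p)) stop("allele frequencies are required for the GMA coding")
  stopifnot(length(p) == loc$m)
  g <- resolve_geno(geno, loc)
  m <- loc$m
  fullc <- glm_codes(g, loc, full = TRUE)
  w <- fullc[, seq_len(m), drop = FALSE]
  pairs <- pair_index(m)
  v <- fullc[, m + seq_len(nrow(pairs)), drop = FALSE]
  ws <- sweep(w, 2L, 2 * p)
  vs <- v
  for (i in seq_len(nrow(pairs))) {
    j <- pairs[i, 1L]; k <- pairs[i, 2L]
    if (j == k) {
      vs[, i] <- v[, i] - p[j] * w[, j] + p[j]^2
    } else {
      vs[, i] <- v[, i] - p[j] * w[, k] - p[k] * w[, j] + 2 * p[j] * p[k]
    }
  }
  mm <- if (full) m else m - 1L
  keep_w <- seq_len(mm)
  keep_v <- which(pairs[, 2L] <= mm)
  out <- cbind(ws[, keep_w, drop = FALSE], vs[, keep_v, drop = FALSE])
  colnames(out) <- code_labels(loc, "gma", full)
  out
}

resolve_geno <- function(geno, loc) {
  if (is.matrix(geno) && is.numeric(geno)) {
    stopifnot(ncol(geno) == 2L)
    if (any(geno < 1L | geno > loc$m)) stop("allele index out of range")
    return(cbind(pmin.int(geno[, 1L], geno[, 2L]),
                 pmax.int(geno[, 1L], geno[, 2L])))
  }
  chars <- parse_genotypes(geno)
  idx <- matrix(match(chars, loc$alleles), ncol = 2L)
  if (anyNA(idx))
    stop("unknown allele label(s): ",
         paste(unique(chars[is.na(idx)]), collapse = ", "))
  cbind(pmin.int(idx[, 1L], idx[, 2L]), pmax.int(idx[, 1L], idx[, 2L]))
}

# stable column labels: w*_<locus>_<allele>, v*_<locus>_<a1>/<a2>
code_labels <- function(loc, coding = c("gma", "glm"), full = FALSE) {
  coding <- match.arg(coding)
  star <- if (coding == "gma") "*" else ""
  mm <- if (full) loc$m else loc$m - 1L
  pairs <- pair_index(mm)
  c(paste0("w", star, "_", loc$name, "_", loc$alleles[seq_len(mm)]),
    paste0("v", star, "_", loc$name, "_",
           loc$alleles[pairs[, 1L]], "/", loc$alleles[pairs[, 2L]]))
}

# per-locus code matrix split into A and D blocks
locus_code_blocks <- function(geno, loc, coding, p = NULL) {
  X <- if (coding == "gma") gma_codes(geno, loc, p = p)
       else glm_codes(geno, loc)
  na <- loc$m - 1L
  list(A = X[, seq_len(na), drop = FALSE],
       D = X[, na + seq_len(ncol(X) - na), drop = FALSE])
}

#' Two-locus epistatic coding
#'
#' Builds the full set of coding columns for a two-locus model: the
#' per-locus additive (w) and dominance (v) columns plus the four
#' elementwise product blocks, in the canonical component order A1, D1,
#' A2, D2, A1A2, A1D2, D1A2, D1D2.  Product column labels join the factor
#' labels with ":".
#'
#' @param geno1,geno2 genotypes at locus 1 and 2 (see [glm_codes()]).
#' @param loc1,loc2 [locus()] objects.
#' @param coding `"gma"` or `"glm"`.
#' @param p1,p2 allele frequencies for the mean correction (GMA).
#' @return A list with `X` (the combined matrix) and `blocks` (a named
#'   list mapping each component block to its column indices).
#' @export
two_locus_codes <- function(geno1, geno2, loc1, loc2,
                            coding = c("gma", "glm"),
                            p1 = loc1$freqs, p2 = loc2$freqs) {
  coding <- match.arg(coding)
  b1 <- locus_code_blocks(geno1, loc1, coding, p1)
  b2 <- locus_code_blocks(geno2, loc2, coding, p2)
  prod_block <- function(L, R) {
    out <- matrix(0, nrow(L), ncol(L) * ncol(R))
    labs <- character(ncol(L) * ncol(R))
    i <- 0L
    for (a in seq_len(ncol(L))) for (b in seq_len(ncol(R))) {
      i <- i + 1L
      out[, i] <- L[, a] * R[, b]
      labs[i] <- paste(colnames(L)[a], colnames(R)[b], sep = ":")
    }
    colnames(out) <- labs
    out
  }
  parts <- list(A1 = b1$A, D1 = b1$D, A2 = b2$A, D2 = b2$D,
                A1A2 = prod_block(b1$A, b2$A),
                A1D2 = prod_block(b1$A, b2$D),
                D1A2 = prod_block(b1$D, b2$A),
                D1D2 = prod_block(b1$D, b2$D))
  X <- do.call(cbind, parts)
  sizes <- vapply(parts, ncol, 0L)
  ends <- cumsum(sizes)
  blocks <- mapply(function(e, s) seq.int(e - s + 1L, e), ends, sizes,
                   SIMPLIFY = FALSE)
  list(X = X, blocks = blocks)
}
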