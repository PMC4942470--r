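#' Per-individual fitted genetic components
#'
#' For each component block of a fitted genotype model, the inner product
#' of the block's coefficients with the individual's coding values: the
#' fitted additive, dominance and epistatic components A_i, D_i, ...  Their
#' sum plus the intercept (and any covariate part) equals the fitted value.
#'
#' @param fit a [fit_genotype_model()] result.
#' @return An N-by-(number of blocks) matrix, one column per block.
#' @export
fitted_components <- function(fit) {
  stopifnot(inherits(fit, "gma_fit"))
  out <- sapply(names(fit$blocks), function(b) {
    ix <- fit$blocks[[b]]
    as.vector(fit$design[, ix, drop = FALSE] %*% fit$coefficients[ix])
  })
  matrix(out, nrow = fit$N, dimnames = list(NULL, names(fit$blocks)))
}

# population/sample variance with denominator N, and matching covariance
var_n <- function(x, w = NULL) {
  if (is.null(w)) mean((x - mean(x))^2)
  else sum(w * (x - sum(w * x))^2)
}
cov_n <- function(x, y, w = NULL) {
  if (is.null(w)) mean((x - mean(x)) * (y - mean(y)))
  else sum(w * (x - sum(w * x)) * (y - sum(w * y)))
}

make_varcomp <- function(comps, w = NULL, v_eps = NA_real_, v_y = NA_real_) {
  B <- ncol(comps)
  vars <- vapply(seq_len(B), function(b) var_n(comps[, b], w), 0)
  covs <- matrix(0, B, B, dimnames = list(colnames(comps), colnames(comps)))
  for (a in seq_len(B)) for (b in seq_len(B))
    covs[a, b] <- cov_n(comps[, a], comps[, b], w)
  names(vars) <- colnames(comps)
  total <- rowSums(comps)
  v_g <- var_n(total, w)
  structure(list(variances = vars, covariances = covs, V_G = v_g,
                 V_eps = v_eps, V_Y = v_y,
                 cov_fraction = 1 - sum(vars) / v_g,
                 shares = 100 * vars / v_g),
            class = "varcomp")
}

#' @export
print.varcomp <- function(x, ...) {
  cat("Genetic variance components (V_G =", format(x$V_G), ")\n")
  tab <- data.frame(variance = x$variances, share_pct = x$shares)
  print(tab)
  cat("covariance fraction:", format(x$cov_fraction), "\n")
  if (!is.na(x$V_eps)) cat("V_eps =", format(x$V_eps), "\n")
  if (!is.na(x$V_Y)) cat("V_Y =", format(x$V_Y), "\n")
  invisible(x)
}

#' Variance components from a fitted model
#'
#' Estimates the genetic variance components as the sample variances of
#' the per-individual fitted components (denominator N), their pairwise
#' covariances as the corresponding sample covariances, and the genotypic
#' variance V_G as the sample variance of the summed components.  The
#' residual variance is the within-cell sum of squares over N for a
#' saturated, covariate-free fit (so that V_Y = sum of component variances
#' + 2 x covariances + V_eps holds exactly), and the mean-square error
#' otherwise.
#'
#' @param fit a [fit_genotype_model()] result.
#' @return An object of class `"varcomp"` with elements `variances`,
#'   `covariances`, `V_G`, `V_eps`, `V_Y`, `cov_fraction` (share of V_G
#'   not captured by the component variances) and `shares` (percent).
#' @export
varcomp_from_fit <- function(fit) {
  comps <- fitted_components(fit)
  nblocks_all <- if (is.null(fit$dataset) || length(fit$dataset$loci) == 1L)
    2L else 8L
  saturated <- length(fit$blocks) == nblocks_all &&
    length(fit$covariate_cols) == 0L
  v_eps <- if (saturated) fit$sse / fit$N else fit$mse
  v_y <- var_n(fit$y)
  make_varcomp(comps, v_eps = v_eps, v_y = v_y)
}

#' Closed-form HWE variance-component estimators (one locus)
#'
#' Under exact Hardy-Weinberg proportions the additive and dominance
#' variance estimators have closed forms in the weighted group means:
#' V_A = 2 sum_j p_j (ybar_j. - ybar..)^2 and V_D = sum_jk p_j p_k
#' (ybar_jk - ybar..)^2 - V_A, with ybar_j. the frequency-weighted allele
#' mean and ybar.. the weighted overall mean.  Both are non-negative and
#' agree with [varcomp_from_fit()] on exact-HWE samples.
#'
#' @param means symmetric m-by-m matrix of genotypic group means.
#' @param p allele frequencies (typically MLE from the same sample).
#' @return A list with `V_A` and `V_D`.
#' @export
varcomp_hwe_closed_form <- function(means, p) {
  if (anyNA(means)) stop("empty genotype cell(s) in the means table")
  ybar_j <- as.vector(means %*% p)
  ybar <- sum(p * ybar_j)
  V_A <- 2 * sum(p * (ybar_j - ybar)^2)
  V_D <- sum(outer(p, p) * (means - ybar)^2) - V_A
  list(V_A = V_A, V_D = V_D)
}

#' Residual and total phenotypic variance
#'
#' V_eps is the within-genotype-class sum of squares over N (the residual
#' variance of the saturated fit); V_Y is the total phenotypic variance
#' about the grand mean with denominator N.
#'
#' @param ds a [genotype_dataset()] with phenotype.
#' @return A list with `V_eps` and `V_Y`.
#' @export
residual_and_total <- function(ds) {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (is.null(ds$phenotype)) stop("dataset has no phenotype")
  y <- ds$phenotype
  key <- do.call(paste, lapply(ds$geno, function(g) paste(g[, 1L], g[, 2L])))
  cellmeans <- ave(y, key)
  list(V_eps = mean((y - cellmeans)^2), V_Y = var_n(y))
}

#' Exact variance components of a true model by enumeration
#'
#' Given a table of expected genotypic values and a genotype probability
#' distribution, computes the exact population variance components: the
#' model parameters of the requested coding are extracted at the
#' distribution's allele frequencies, each component's value is evaluated
#' in every genotype cell, and variances/covariances are taken with the
#' cell probabilities as weights.  This is the oracle against which
#' sample-based estimates converge.
#'
#' @param gv a [gvalue_table()] (or bare array with `loci` supplied).
#' @param probs genotype probability table matching the shape of `gv`:
#'   symmetric matrix (one locus) or 4-index array (two loci), with each
#'   unordered cell's probability replicated across symmetric positions
#'   and the canonical (j <= k, r <= s) cells summing to 1.
#' @param coding `"gma"` or `"glm"` component definitions.
#' @param loci loci when `gv` is a bare array.
#' @return An object of class `"varcomp"` with exact population values.
#' @export
true_varcomp_enumeration <- function(gv, probs, coding = c("gma", "glm"),
                                     loci = NULL) {
  coding <- match.arg(coding)
  if (!inherits(gv, "gvalue_table")) {
    stopifnot(!is.null(loci))
    gv <- gvalue_table(gv, loci)
  }
  loci <- attr(gv, "loci")
  nloci <- length(loci)
  probs <- unclass(probs)
  freqs <- probs_to_allele_freqs(probs, nloci)
  params <- extract_params(gv, coding, freqs = freqs)
  if (nloci == 1L) {
    cells <- pair_index(loci[[1L]]$m)
    w <- probs[cells]
    b <- locus_code_blocks(cells, loci[[1L]], coding, freqs[[1L]])
    parts <- list(A1 = b$A, D1 = b$D)
    block_cols <- list(A1 = seq_len(ncol(b$A)),
                       D1 = ncol(b$A) + seq_len(ncol(b$D)))
    X <- cbind(b$A, b$D)
  } else {
    c1 <- pair_index(loci[[1L]]$m); c2 <- pair_index(loci[[2L]]$m)
    grid <- cbind(c1[rep(seq_len(nrow(c1)), each = nrow(c2)), , drop = FALSE],
                  c2[rep(seq_len(nrow(c2)), times = nrow(c1)), , drop = FALSE])
    w <- probs[grid]
    tl <- two_locus_codes(grid[, 1:2, drop = FALSE], grid[, 3:4, drop = FALSE],
                          loci[[1L]], loci[[2L]], coding,
                          p1 = freqs[[1L]], p2 = freqs[[2L]])
    X <- tl$X
    block_cols <- tl$blocks
  }
  if (abs(sum(w) - 1) > 1e-9) stop("genotype probabilities do not sum to 1")
  if (any(w < 0)) stop("negative genotype probability")
  cf <- param_coef(params)
  comps <- sapply(names(block_cols), function(b) {
    ix <- block_cols[[b]]
    as.vector(X[, ix, drop = FALSE] %*% cf[ix])
  })
  comps <- matrix(comps, nrow = nrow(X),
                  dimnames = list(NULL, names(block_cols)))
  make_varcomp(comps, w = w)
}

# allele frequencies implied by a genotype probability table
probs_to_allele_freqs <- function(probs, nloci) {
  if (nloci == 1L) {
    p <- (rowSums(probs) + diag(probs)) / 2
    return(list(p))
  }
  m1 <- dim(probs)[1L]; m2 <- dim(probs)[3L]
  # marginal genotype tables: canonical cells only, to avoid double counting
  P1 <- matrix(0, m1, m1)
  for (j in seq_len(m1)) for (k in j:m1)
    P1[j, k] <- P1[k, j] <- sum_canonical2(probs[j, k, , ])
  P2 <- matrix(0, m2, m2)
  for (r in seq_len(m2)) for (s in r:m2)
    P2[r, s] <- P2[s, r] <- sum_canonical2(probs[, , r, s])
  p1 <- (rowSums(P1) + diag(P1)) / 2
  p2 <- (rowSums(P2) + diag(P2)) / 2
  list(p1, p2)
}

# sum of the canonical (upper triangle incl. diagonal) cells of a
# symmetric table whose unordered values are replicated across positions
sum_canonical2 <- function(mat) {
  mat <- as.matrix(mat)
  sum(mat[upper.tri(mat, diag = TRUE)])
}
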