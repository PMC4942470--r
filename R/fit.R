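#' Build a model design matrix
#'
#' Assembles the labeled design matrix for a one- or two-locus genotype
#' model: an intercept column, optional covariate columns, then the coding
#' columns of the requested component blocks in canonical order (A1, D1,
#' A2, D2, A1A2, A1D2, D1A2, D1D2).
#'
#' @param ds a [genotype_dataset()].
#' @param coding `"gma"` (mean-corrected codes) or `"glm"` (dummy codes).
#' @param blocks character vector of component blocks to include; defaults
#'   to all blocks available for the number of loci.
#' @param covariates character vector of covariate column names to include.
#' @param freqs frequency source for the GMA coding: `NULL` to use the
#'   maximum-likelihood estimates from `ds` (the default), or a list of
#'   per-locus allele frequency vectors for known population frequencies.
#' @return A list with `X` (design matrix), `blocks` (named list mapping
#'   block names to column indices of `X`), `p` (frequencies used) and
#'   `coding`.
#' @export
build_design <- function(ds, coding = c("gma", "glm"), blocks = NULL,
                         covariates = NULL, freqs = NULL) {
  coding <- match.arg(coding)
  stopifnot(inherits(ds, "genotype_dataset"))
  nloci <- length(ds$loci)
  all_blocks <- if (nloci == 1L) c("A1", "D1")
                else c("A1", "D1", "A2", "D2", "A1A2", "A1D2", "D1A2", "D1D2")
  if (is.null(blocks)) blocks <- all_blocks
  if (!all(blocks %in% all_blocks))
    stop("unknown or unavailable block(s): ",
         paste(setdiff(blocks, all_blocks), collapse = ", "),
         " (dataset has ", nloci, if (nloci == 1L) " locus)" else " loci)")
  blocks <- all_blocks[all_blocks %in% blocks]   # canonical order
  p <- if (is.null(freqs)) {
    lapply(seq_len(nloci), function(l) mle_frequencies(ds, l)$p)
  } else resolve_freqs(ds$loci, freqs)
  if (nloci == 1L) {
    b <- locus_code_blocks(ds$geno[[1L]], ds$loci[[1L]], coding, p[[1L]])
    parts <- list(A1 = b$A, D1 = b$D)[blocks]
    X <- do.call(cbind, parts)
    sizes <- vapply(parts, ncol, 0L)
  } else {
    tl <- two_locus_codes(ds$geno[[1L]], ds$geno[[2L]],
                          ds$loci[[1L]], ds$loci[[2L]], coding,
                          p1 = p[[1L]], p2 = p[[2L]])
    keep <- unlist(tl$blocks[blocks], use.names = FALSE)
    X <- tl$X[, keep, drop = FALSE]
    sizes <- lengths(tl$blocks[blocks])
  }
  lead <- matrix(1, ds$n, 1L, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(covariates)) {
    if (is.null(ds$covariates) || !all(covariates %in% names(ds$covariates)))
      stop("covariate(s) not found in dataset")
    Z <- as.matrix(ds$covariates[covariates])
    lead <- cbind(lead, Z)
  }
  X <- cbind(lead, X)
  offset <- ncol(lead)
  ends <- offset + cumsum(sizes)
  block_cols <- mapply(function(e, s) seq.int(e - s + 1L, e), ends, sizes,
                       SIMPLIFY = FALSE)
  names(block_cols) <- blocks
  list(X = X, blocks = block_cols, p = p, coding = coding,
       covariate_cols = if (is.null(covariates)) integer(0)
                        else 1L + seq_along(covariates))
}

#' Fit a genotype model by ordinary least squares
#'
#' Fits the GLM (dummy coding) or GMA (mean-corrected coding) model for
#' the phenotype, with optional covariates, by ordinary least squares.
#' Frequencies entering the GMA codes default to the maximum-likelihood
#' estimates from the same dataset.
#'
#' @inheritParams build_design
#' @param allow_rank_deficient if `TRUE`, drop linearly dependent columns
#'   with a warning instead of failing (rank deficiency typically signals
#'   an empty genotype class under a saturated model).
#' @return An object of class `"gma_fit"`: coefficients, fitted values,
#'   residuals, `ssr` (regression sum of squares about the mean), `sse`,
#'   `mse`, residual degrees of freedom, the design and block map, and the
#'   coefficient covariance matrix.
#' @examples
#' loc <- locus("L1", c("1", "0"), freqs = c(0.5, 0.5))
#' ds <- simulate_genotypes(200, list(loc), seed = 1)
#' true <- marker_params("gma", list(loc), mu = 0, a1 = 1, d1 = 0.5)
#' ds <- simulate_phenotypes(ds, true, v_eps = 1, seed = 2)
#' fit <- fit_genotype_model(ds, coding = "gma")
#' coef(fit)
#' @export
fit_genotype_model <- function(ds, coding = c("gma", "glm"), blocks = NULL,
                               covariates = NULL, freqs = NULL,
                               allow_rank_deficient = FALSE) {
  coding <- match.arg(coding)
  if (is.null(ds$phenotype)) stop("dataset has no phenotype")
  des <- build_design(ds, coding, blocks, covariates, freqs)
  fit_ols_design(des, ds$phenotype, ds, allow_rank_deficient)
}

# core OLS on a prepared design; shared by fit_genotype_model and refits
fit_ols_design <- function(des, y, ds = NULL, allow_rank_deficient = FALSE) {
  X <- des$X
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    if (!allow_rank_deficient)
      stop("design matrix is rank deficient (dependent columns: ",
           paste(dropped, collapse = ", "),
           "); an empty genotype class under a saturated model is the ",
           "usual cause. Set allow_rank_deficient = TRUE to drop them.")
    warning("dropping dependent column(s): ", paste(dropped, collapse = ", "))
    keep <- sort(qrx$pivot[seq_len(qrx$rank)])
    des$blocks <- lapply(des$blocks, function(ix) match(ix, keep))
    des$blocks <- lapply(des$blocks, function(ix) ix[!is.na(ix)])
    X <- X[, keep, drop = FALSE]
    qrx <- qr(X)
  }
  coefs <- qr.coef(qrx, y)
  fitted <- as.vector(X %*% coefs)
  resid <- y - fitted
  n <- length(y)
  sse <- sum(resid^2)
  ssr <- sum((fitted - mean(y))^2)
  df_resid <- n - qrx$rank
  mse <- if (df_resid > 0) sse / df_resid else NA_real_
  xtx_inv <- tryCatch(chol2inv(chol(crossprod(X))), error = function(e) NULL)
  vcov <- if (!is.null(xtx_inv) && !is.na(mse)) mse * xtx_inv else NULL
  if (!is.null(vcov)) dimnames(vcov) <- list(colnames(X), colnames(X))
  structure(list(coefficients = coefs, fitted = fitted, residuals = resid,
                 ssr = ssr, sse = sse, mse = mse, df_residual = df_resid,
                 N = n, design = X, blocks = des$blocks, p = des$p,
                 coding = des$coding, covariate_cols = des$covariate_cols,
                 y = y, vcov = vcov, dataset = ds),
            class = "gma_fit")
}

#' @export
print.gma_fit <- function(x, ...) {
  cat("Genotype model fit (", toupper(x$coding), " coding), N = ", x$N,
      "\n", sep = "")
  cat("  SSR =", format(x$ssr), " MSE =", format(x$mse),
      " residual df =", x$df_residual, "\n")
  cat("Coefficients:\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
coef.gma_fit <- function(object, ...) object$coefficients

#' @export
fitted.gma_fit <- function(object, ...) object$fitted

#' @export
residuals.gma_fit <- function(object, ...) object$residuals

#' @export
vcov.gma_fit <- function(object, ...) object$vcov

#' Type III (partial) sum of squares for a component block
#'
#' The reduction in the residual sum of squares attributable to a block
#' when it is added last: SSE(model without the block) - SSE(full model),
#' holding all other blocks and covariates in the model.  Computed by an
#' explicit refit of the reduced model.
#'
#' @param fit a [fit_genotype_model()] result.
#' @param block block name present in the fit.
#' @return The partial sum of squares (a scalar).
#' @export
type3_ss <- function(fit, block) {
  stopifnot(inherits(fit, "gma_fit"))
  if (!block %in% names(fit$blocks)) stop("block not in fitted model: ", block)
  drop_cols <- fit$blocks[[block]]
  Xr <- fit$design[, -drop_cols, drop = FALSE]
  cf <- qr.coef(qr(Xr), fit$y)
  sse_r <- sum((fit$y - Xr %*% cf)^2)
  sse_r - fit$sse
}

#' Partial F-test for a component block
#'
#' Tests whether all coefficients of a block are zero, given the rest of
#' the model: F = (Type III SS / block df) / MSE with the residual degrees
#' of freedom of the fitted model.
#'
#' @inheritParams type3_ss
#' @return A list with `F`, `df1`, `df2`, `p_value` and `ss`.
#' @export
group_f_test <- function(fit, block) {
  ss <- type3_ss(fit, block)
  df1 <- length(fit$blocks[[block]])
  if (is.na(fit$mse) || fit$mse <= 0)
    stop("saturated or noiseless fit: MSE is zero, no F-test possible")
  Fstat <- (ss / df1) / fit$mse
  list(F = Fstat, df1 = df1, df2 = fit$df_residual,
       p_value = stats::pf(Fstat, df1, fit$df_residual, lower.tail = FALSE),
       ss = ss)
}

#' ANOVA-style block table
#'
#' Per-block Type III sums of squares and partial F-tests for every
#' component block of a fitted genotype model.
#'
#' @param object a [fit_genotype_model()] result.
#' @param ... unused.
#' @return A data frame with one row per block: df, Type III SS, F and p.
#' @export
anova.gma_fit <- function(object, ...) {
  blocks <- names(object$blocks)
  rows <- lapply(blocks, function(b) {
    ft <- group_f_test(object, b)
    data.frame(block = b, df = ft$df1, type3_ss = ft$ss, F = ft$F,
               p_value = ft$p_value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Closed-form least-squares estimates from group means
#'
#' For the saturated (all-blocks, no-covariate) model the OLS fit matches
#' every genotypic group mean exactly, so the parameter estimates have
#' closed forms in the group means and estimated allele frequencies: for
#' one locus, mu* is the frequency-weighted overall mean, alpha*_j the
#' difference of weighted allele means from the reference allele's, and
#' delta*_jk the double difference of cell means against the reference
#' (identical for the GLM and GMA flavors).  The two-locus forms use the
#' weighted genotypic group means in the same pattern.
#'
#' @param means symmetric matrix (one locus) or (m1, m1, m2, m2) array
#'   (two loci) of genotypic group means; `NA` (empty) cells are an error.
#' @param freqs list of per-locus allele frequency vectors (typically the
#'   MLE from the same sample).
#' @param loci list of [locus()] objects.
#' @param flavor parameter flavor to return.
#' @return A [marker_params()] object whose entries equal the OLS
#'   coefficients of the corresponding saturated fit.
#' @export
closed_form_lse <- function(means, freqs, loci, flavor = c("gma", "glm")) {
  flavor <- match.arg(flavor)
  if (anyNA(means)) {
    bad <- which(is.na(means), arr.ind = TRUE)
    stop("empty genotype cell(s): ",
         paste(apply(bad, 1L, paste, collapse = ","), collapse = "; "))
  }
  gv <- gvalue_table(means, loci, freqs)
  extract_params(gv, flavor, freqs = freqs)
}
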