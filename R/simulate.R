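#' Genotype probability table from allele frequencies
#'
#' Builds the unordered genotype probability matrix at one locus from
#' allele frequencies and optional Hardy-Weinberg disequilibrium
#' coefficients: p_jj = p_j^2 + D_jj on the diagonal and
#' p_jk = 2 (p_j p_k + D_jk) off the diagonal, stored symmetrically so
#' the diagonal plus the upper triangle sums to 1.
#'
#' @param p allele frequency vector.
#' @param D optional symmetric matrix of disequilibrium coefficients with
#'   zero row sums (see [hwd_coefficients()]); default is HWE.
#' @return An m-by-m symmetric genotype probability matrix.
#' @examples
#' genotype_probs(c(0.4, 0.6))  # HWE: 0.16 / 0.48 / 0.36
#' @export
genotype_probs <- function(p, D = NULL) {
  m <- length(p)
  stopifnot(m >= 2L, all(p > 0), abs(sum(p) - 1) < 1e-12)
  if (is.null(D)) D <- matrix(0, m, m)
  D <- as.matrix(D)
  stopifnot(all(dim(D) == c(m, m)))
  if (max(abs(D - t(D))) > 1e-12 || max(abs(rowSums(D))) > 1e-10)
    stop("D must be symmetric with zero row sums")
  P <- 2 * (outer(p, p) + D)
  diag(P) <- p^2 + diag(D)
  if (any(P < -1e-12))
    stop("the D coefficients imply a negative genotype probability")
  P[P < 0] <- 0
  tot <- sum(P[upper.tri(P, diag = TRUE)])
  if (abs(tot - 1) > 1e-9)
    stop("genotype probabilities do not form a distribution")
  dimnames(P) <- list(names(p), names(p))
  P
}

#' Simulate genotypes
#'
#' Draws independent individuals from the genotype distribution at one or
#' two loci.  Each locus is sampled from its own unordered genotype
#' probability table (multinomial sampling); with two loci the default is
#' independent loci (gametic equilibrium), or a joint 4-index probability
#' table may be supplied.
#'
#' @param n number of individuals.
#' @param loci list of [locus()] objects; loci with attached frequencies
#'   default to their HWE genotype probabilities.
#' @param probs optional list of per-locus genotype probability matrices
#'   (see [genotype_probs()]).
#' @param joint optional (m1, m1, m2, m2) joint probability array for two
#'   dependent loci (symmetric storage, canonical cells summing to 1).
#' @param seed optional integer seed for reproducibility.
#' @return A [genotype_dataset()] without phenotype.
#' @export
simulate_genotypes <- function(n, loci, probs = NULL, joint = NULL,
                               seed = NULL) {
  if (inherits(loci, "locus")) loci <- list(loci)
  stopifnot(length(loci) %in% c(1L, 2L), n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(joint)) {
    stopifnot(length(loci) == 2L)
    m1 <- loci[[1L]]$m; m2 <- loci[[2L]]$m
    c1 <- pair_index(m1); c2 <- pair_index(m2)
    grid <- cbind(c1[rep(seq_len(nrow(c1)), each = nrow(c2)), , drop = FALSE],
                  c2[rep(seq_len(nrow(c2)), times = nrow(c1)), , drop = FALSE])
    w <- joint[grid]
    if (abs(sum(w) - 1) > 1e-9 || any(w < 0))
      stop("joint probabilities do not form a distribution")
    pick <- sample.int(nrow(grid), n, replace = TRUE, prob = w)
    geno <- list(grid[pick, 1:2, drop = FALSE], grid[pick, 3:4, drop = FALSE])
  } else {
    if (is.null(probs))
      probs <- lapply(loci, function(l) {
        if (is.null(l$freqs))
          stop("locus ", l$name, " has no frequencies and no probs supplied")
        genotype_probs(l$freqs)
      })
    geno <- lapply(seq_along(loci), function(l) {
      cells <- pair_index(loci[[l]]$m)
      w <- probs[[l]][cells]
      pick <- sample.int(nrow(cells), n, replace = TRUE, prob = w)
      cells[pick, , drop = FALSE]
    })
  }
  glabs <- lapply(seq_along(loci), function(l) {
    al <- loci[[l]]$alleles
    paste(al[geno[[l]][, 1L]], al[geno[[l]][, 2L]], sep = "/")
  })
  names(glabs) <- vapply(loci, `[[`, "", "name")
  genotype_dataset(glabs, loci = loci)
}

#' Simulate phenotypes on top of genotypes
#'
#' Adds a phenotype to a genotype dataset: y_i = G(g_i) + eps_i with the
#' genotypic value G evaluated from a true parameter set and residuals
#' i.i.d. Normal(0, v_eps), independent of the genotypes.
#'
#' @param ds a [genotype_dataset()].
#' @param params a [marker_params()] true model (any flavor).
#' @param v_eps residual variance (trait units squared); `v_eps = 0` gives
#'   phenotypes equal to the genotypic values.
#' @param seed optional integer seed.
#' @return The dataset with its `phenotype` filled in.
#' @export
simulate_phenotypes <- function(ds, params, v_eps, seed = NULL) {
  stopifnot(inherits(ds, "genotype_dataset"), inherits(params, "marker_params"))
  if (v_eps < 0) stop("v_eps must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  gv <- genotypic_values(params)
  G <- unclass_gv(gv)
  gvals <- if (length(ds$loci) == 1L) G[ds$geno[[1L]]]
           else G[cbind(ds$geno[[1L]], ds$geno[[2L]])]
  ds$phenotype <- gvals +
    if (v_eps > 0) stats::rnorm(ds$n, 0, sqrt(v_eps)) else 0
  ds
}

#' Residual variance from broad-sense heritability
#'
#' Converts a broad-sense heritability H^2 = V_G / (V_G + V_eps) into the
#' residual variance: V_eps = V_G (1 - H^2) / H^2.
#'
#' @param v_g genotypic variance.
#' @param h2 broad-sense heritability, in (0, 1).
#' @return The residual variance V_eps.
#' @examples
#' heritability_to_residual(3.09, 0.15)  # 17.51
#' @export
heritability_to_residual <- function(v_g, h2) {
  if (!(h2 > 0 && h2 < 1)) stop("h2 must lie strictly between 0 and 1")
  v_g * (1 - h2) / h2
}

#' The two-locus study model
#'
#' The default simulation conditions used throughout the package's
#' examples and the model-selection study: two biallelic loci with allele
#' "1" frequencies 0.4 and 0.2 (reference allele "0" at both), unlinked
#' and in HWE, a GLM true model with intercept 10, unit additive and
#' dominance effects at both loci and a unit additive-by-additive
#' interaction, and residual variance 17.51 (broad-sense heritability
#' about 15%).
#'
#' @param p1,p2 allele "1" frequencies at the two loci.
#' @param v_eps residual variance.
#' @return A list with `loci`, `glm` (the true GLM parameter set), `gma`
#'   (its GMA equivalent) and `v_eps`.
#' @export
default_study_model <- function(p1 = 0.4, p2 = 0.2, v_eps = 17.51) {
  loc1 <- locus("L1", c("1", "0"), freqs = c(p1, 1 - p1), ref_allele = "0")
  loc2 <- locus("L2", c("1", "0"), freqs = c(p2, 1 - p2), ref_allele = "0")
  glm <- marker_params("glm", list(loc1, loc2), mu = 10,
                       a1 = 1, d1 = 1, a2 = 1, d2 = 1, aa = 1)
  list(loci = list(loc1, loc2), glm = glm,
       gma = convert_params(glm, "gma"), v_eps = v_eps)
}
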