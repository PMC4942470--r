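#' Genotypic value table from model parameters
#'
#' Evaluates a parameter set at every genotype cell, giving the table of
#' expected genotypic values G_jk (one locus, an m-by-m symmetric matrix)
#' or G_jkrs (two loci, a symmetric 4-index array).  For the `"glm"` and
#' `"gma"` flavors the model is evaluated through the corresponding coding
#' variables; for the `"fisher"` flavor the constrained ANOVA model is
#' evaluated directly.
#'
#' @param params a [marker_params()] object.
#' @param freqs optional list of per-locus allele frequency vectors used by
#'   the `"gma"` coding; defaults to the frequencies attached to the loci.
#' @return An object of class `"gvalue_table"`: the G array with
#'   attributes `loci` and `freqs`.
#' @export
genotypic_values <- function(params, freqs = NULL) {
  stopifnot(inherits(params, "marker_params"))
  loci <- params$loci
  freqs <- resolve_freqs(loci, freqs)
  if (length(loci) == 1L) {
    m <- loci[[1L]]$m
    G <- matrix(0, m, m, dimnames = list(loci[[1L]]$alleles,
                                         loci[[1L]]$alleles))
    cells <- pair_index(m)
    vals <- eval_cells_one(params, cells, freqs[[1L]])
    G[cells] <- vals
    G[cells[, 2:1, drop = FALSE]] <- vals
  } else {
    m1 <- loci[[1L]]$m; m2 <- loci[[2L]]$m
    G <- array(0, dim = c(m1, m1, m2, m2))
    c1 <- pair_index(m1); c2 <- pair_index(m2)
    grid <- cbind(c1[rep(seq_len(nrow(c1)), each = nrow(c2)), , drop = FALSE],
                  c2[rep(seq_len(nrow(c2)), times = nrow(c1)), , drop = FALSE])
    vals <- eval_cells_two(params, grid, freqs)
    for (i in seq_len(nrow(grid))) {
      j <- grid[i, 1L]; k <- grid[i, 2L]; r <- grid[i, 3L]; s <- grid[i, 4L]
      G[j, k, r, s] <- G[k, j, r, s] <- G[j, k, s, r] <- G[k, j, s, r] <-
        vals[i]
    }
  }
  gvalue_table(G, loci, freqs)
}

#' Construct a genotypic value table
#'
#' @param G symmetric m-by-m matrix (one locus) or (m1, m1, m2, m2) array
#'   (two loci) of expected genotypic values.
#' @param loci list of [locus()] objects.
#' @param freqs optional list of allele frequency vectors to attach.
#' @return An object of class `"gvalue_table"`.
#' @export
gvalue_table <- function(G, loci, freqs = NULL) {
  if (inherits(loci, "locus")) loci <- list(loci)
  freqs <- resolve_freqs(loci, freqs, required = FALSE)
  structure(G, loci = loci, freqs = freqs, class = "gvalue_table")
}

#' @export
print.gvalue_table <- function(x, ...) {
  cat("Genotypic value table,", length(attr(x, "loci")),
      if (length(attr(x, "loci")) == 1L) "locus\n" else "loci\n")
  print(unclass_gv(x))
  invisible(x)
}

unclass_gv <- function(x) {
  attr(x, "loci") <- NULL
  attr(x, "freqs") <- NULL
  unclass(x)
}

resolve_freqs <- function(loci, freqs, required = TRUE) {
  if (is.null(freqs)) freqs <- lapply(loci, `[[`, "freqs")
  if (!is.list(freqs)) freqs <- list(freqs)
  if (required && any(vapply(freqs, is.null, TRUE)))
    stop("allele frequencies are required (attach them to the loci or pass freqs)")
  freqs
}

# evaluate the (glm|gma|fisher) model at one-locus cells given as (j, k) rows
eval_cells_one <- function(params, cells, p) {
  if (params$flavor == "fisher") {
    mu <- params$mu; a <- params$a1; d <- params$d1
    return(mu + a[cells[, 1L]] + a[cells[, 2L]] + d[cells])
  }
  loc <- params$loci[[1L]]
  X <- if (params$flavor == "gma") gma_codes(cells, loc, p = p)
       else glm_codes(cells, loc)
  as.vector(params$mu + X %*% param_coef(params))
}

# evaluate at two-locus cells given as (j, k, r, s) rows
eval_cells_two <- function(params, grid, freqs) {
  if (params$flavor == "fisher") {
    mu <- params$mu
    j <- grid[, 1L]; k <- grid[, 2L]; r <- grid[, 3L]; s <- grid[, 4L]
    return(mu +
      params$a1[j] + params$a1[k] + params$d1[cbind(j, k)] +
      params$a2[r] + params$a2[s] + params$d2[cbind(r, s)] +
      params$aa[cbind(j, r)] + params$aa[cbind(j, s)] +
      params$aa[cbind(k, r)] + params$aa[cbind(k, s)] +
      params$ad[cbind(j, r, s)] + params$ad[cbind(k, r, s)] +
      params$da[cbind(j, k, r)] + params$da[cbind(j, k, s)] +
      params$dd[cbind(j, k, r, s)])
  }
  tl <- two_locus_codes(grid[, 1:2, drop = FALSE], grid[, 3:4, drop = FALSE],
                        params$loci[[1L]], params$loci[[2L]],
                        coding = params$flavor,
                        p1 = freqs[[1L]], p2 = freqs[[2L]])
  as.vector(params$mu + tl$X %*% param_coef(params))
}

# ---- weighted (Fisher-style) hierarchical decomposition -------------------
#
# With weight vectors q1 (and q2), decompose the G table into an intercept,
# main effects, within-locus interactions and (for two loci) epistatic
# terms, each term being the residual after removing all lower-order terms
# from the corresponding q-weighted marginal mean of G.  With q = allele
# frequencies this yields the constrained Fisher parameterization (every
# q-weighted sum of a term over any index is zero); with a point mass at
# the reference allele it yields the GLM parameterization directly.

fisher_decompose_one <- function(G, q) {
  ybar_j <- as.vector(G %*% q)          # sum_k q_k G_jk
  mu <- sum(q * ybar_j)
  alpha <- ybar_j - mu
  delta <- G - outer(alpha, alpha, `+`) - mu
  list(mu = mu, a1 = alpha, d1 = delta)
}

fisher_decompose_two <- function(G, q1, q2) {
  m1 <- dim(G)[1L]; m2 <- dim(G)[3L]
  # weighted contractions; G is symmetric so one index per locus suffices
  red_k <- function(A) apply(A, c(1L, 3L, 4L), function(v) sum(q1 * v))
  red_s <- function(A) apply(A, c(1L, 2L, 3L), function(v) sum(q2 * v))
  G_j_rs <- red_k(G)                              # (j, r, s)
  G_jk_r <- red_s(G)                              # (j, k, r)
  G_jk <- apply(G_jk_r, c(1L, 2L), function(v) sum(q2 * v))     # (j, k)
  G_rs <- apply(G_j_rs, c(2L, 3L), function(v) sum(q1 * v))     # (r, s)
  G_j_r <- apply(G_j_rs, c(1L, 2L), function(v) sum(q2 * v))    # (j, r)
  G_j <- as.vector(G_jk %*% q1)
  G_r <- as.vector(G_rs %*% q2)
  mu <- sum(q1 * G_j)
  a1 <- G_j - mu
  a2 <- G_r - mu
  d1 <- G_jk - outer(a1, a1, `+`) - mu
  d2 <- G_rs - outer(a2, a2, `+`) - mu
  aa <- G_j_r - outer(a1, rep(1, m2)) - outer(rep(1, m1), a2) - mu
  ad <- array(0, c(m1, m2, m2))
  for (j in seq_len(m1)) for (r in seq_len(m2)) for (s in seq_len(m2))
    ad[j, r, s] <- G_j_rs[j, r, s] -
      (mu + a1[j] + a2[r] + a2[s] + d2[r, s] + aa[j, r] + aa[j, s])
  da <- array(0, c(m1, m1, m2))
  for (j in seq_len(m1)) for (k in seq_len(m1)) for (r in seq_len(m2))
    da[j, k, r] <- G_jk_r[j, k, r] -
      (mu + a1[j] + a1[k] + d1[j, k] + a2[r] + aa[j, r] + aa[k, r])
  dd <- array(0, c(m1, m1, m2, m2))
  for (j in seq_len(m1)) for (k in seq_len(m1))
    for (r in seq_len(m2)) for (s in seq_len(m2))
      dd[j, k, r, s] <- G[j, k, r, s] -
        (mu + a1[j] + a1[k] + d1[j, k] + a2[r] + a2[s] + d2[r, s] +
         aa[j, r] + aa[j, s] + aa[k, r] + aa[k, s] +
         ad[j, r, s] + ad[k, r, s] + da[j, k, r] + da[j, k, s])
  list(mu = mu, a1 = a1, d1 = d1, a2 = a2, d2 = d2,
       aa = aa, ad = ad, da = da, dd = dd)
}

# reference-allele differencing: maps full-m constrained effects to the
# reduced m-1 parameterization (model equivalence maps)
ref_reduce_vec <- function(v) {
  m <- length(v)
  v[-m] - v[m]
}
ref_reduce_pair <- function(mat) {
  m <- nrow(mat)
  j <- seq_len(m - 1L)
  mat[j, j, drop = FALSE] -
    outer(mat[j, m], rep(1, m - 1L)) -
    outer(rep(1, m - 1L), mat[j, m]) + mat[m, m]
}

# the intercept after reduction: value of the full model at mean-corrected
# codes is unchanged, so mu stays mu for the gma flavor

#' Extract model parameters from a genotypic value table
#'
#' The inverse of [genotypic_values()]: recovers the parameter set of any
#' flavor from a complete table of expected genotypic values and allele
#' frequencies.  The `"fisher"` flavor is obtained from the
#' frequency-weighted hierarchical decomposition of the table (each effect
#' is a weighted marginal mean of G minus all lower-order terms), which
#' satisfies the zero-sum constraints by construction.  The `"gma"` flavor
#' follows by reference-allele differencing of those effects, reproducing
#' the closed-form weighted-group-mean formulas; the `"glm"` flavor is the
#' same construction with a point mass at the reference allele instead of
#' the frequency weights.
#'
#' @param gv a [gvalue_table()] (or a bare matrix/array plus `loci`).
#' @param flavor target parameterization.
#' @param freqs optional list of allele frequency vectors; defaults to the
#'   table's attached frequencies.
#' @param loci loci when `gv` is a bare array.
#' @return A [marker_params()] object of the requested flavor.
#' @export
extract_params <- function(gv, flavor = c("gma", "glm", "fisher"),
                           freqs = NULL, loci = NULL) {
  flavor <- match.arg(flavor)
  if (!inherits(gv, "gvalue_table")) {
    stopifnot(!is.null(loci))
    gv <- gvalue_table(gv, loci, freqs)
  }
  loci <- attr(gv, "loci")
  freqs <- if (is.null(freqs)) attr(gv, "freqs") else resolve_freqs(loci, freqs)
  G <- unclass_gv(gv)
  point_mass <- function(m) c(rep(0, m - 1L), 1)
  q <- if (flavor == "glm") lapply(loci, function(l) point_mass(l$m))
       else resolve_freqs(loci, freqs)
  if (length(loci) == 1L) {
    dec <- fisher_decompose_one(G, q[[1L]])
    if (flavor == "fisher")
      return(marker_params("fisher", loci, dec$mu, a1 = dec$a1, d1 = dec$d1))
    marker_params(flavor, loci, dec$mu,
                  a1 = ref_reduce_vec(dec$a1),
                  d1 = ref_reduce_pair(dec$d1))
  } else {
    dec <- fisher_decompose_two(G, q[[1L]], q[[2L]])
    if (flavor == "fisher")
      return(marker_params("fisher", loci, dec$mu, a1 = dec$a1, d1 = dec$d1,
                           a2 = dec$a2, d2 = dec$d2, aa = dec$aa,
                           ad = dec$ad, da = dec$da, dd = dec$dd))
    m1 <- loci[[1L]]$m; m2 <- loci[[2L]]$m
    n1 <- m1 - 1L; n2 <- m2 - 1L
    aa <- matrix(0, n1, n2)
    for (j in seq_len(n1)) for (r in seq_len(n2))
      aa[j, r] <- dec$aa[j, r] - dec$aa[j, m2] - dec$aa[m1, r] +
        dec$aa[m1, m2]
    dpair2 <- function(sl) {           # difference a (r, s) slice at m2
      r <- seq_len(n2)
      sl[r, r, drop = FALSE] - outer(sl[r, m2], rep(1, n2)) -
        outer(rep(1, n2), sl[r, m2]) + sl[m2, m2]
    }
    dpair1 <- function(sl) {           # difference a (j, k) slice at m1
      j <- seq_len(n1)
      sl[j, j, drop = FALSE] - outer(sl[j, m1], rep(1, n1)) -
        outer(rep(1, n1), sl[j, m1]) + sl[m1, m1]
    }
    ad <- array(0, c(n1, n2, n2))
    for (j in seq_len(n1))
      ad[j, , ] <- dpair2(dec$ad[j, , ]) - dpair2(dec$ad[m1, , ])
    da <- array(0, c(n1, n1, n2))
    for (r in seq_len(n2))
      da[, , r] <- dpair1(dec$da[, , r]) - dpair1(dec$da[, , m2])
    dd <- array(0, c(n1, n1, n2, n2))
    for (r in seq_len(n2)) for (s in seq_len(n2)) {
      # difference over (r, s) first, then over (j, k)
      sl <- dec$dd[, , r, s] - dec$dd[, , r, m2] - dec$dd[, , s, m2] +
        dec$dd[, , m2, m2]
      dd[, , r, s] <- dpair1(sl)
    }
    marker_params(flavor, loci, dec$mu,
                  a1 = ref_reduce_vec(dec$a1), d1 = dpair1(dec$d1),
                  a2 = ref_reduce_vec(dec$a2), d2 = dpair2(dec$d2),
                  aa = aa, ad = ad, da = da, dd = dd)
  }
}

#' Convert between parameterizations
#'
#' Exact transformation of a parameter set into another flavor, routed
#' through the genotypic value table (a population-level identity, so
#' population allele frequencies must be attached to the loci or passed
#' explicitly).
#'
#' @param params a [marker_params()] object.
#' @param to target flavor.
#' @param freqs optional list of allele frequency vectors.
#' @return A [marker_params()] object of flavor `to`.
#' @examples
#' loc <- locus("L1", c("1", "0"), freqs = c(0.4, 0.6))
#' glm <- marker_params("glm", list(loc), mu = 0, a1 = 1, d1 = 1)
#' convert_params(glm, "gma")  # alpha* = a + p * d = 1.4
#' @export
convert_params <- function(params, to = c("gma", "glm", "fisher"),
                           freqs = NULL) {
  to <- match.arg(to)
  gv <- genotypic_values(params, freqs = freqs)
  extract_params(gv, to, freqs = freqs)
}
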