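#' Model parameter sets
#'
#' Containers for the three equivalent parameterizations of the expected
#' genotypic values:
#'
#' * `"glm"` — the dummy-variable parameterization: intercept mu = G at the
#'   all-reference genotype, fixed additive effects `a` and fixed allelic
#'   interactions `d` (plus the epistatic arrays `aa`, `ad`, `da`, `dd` for
#'   two loci), indexed over the non-reference alleles 1..m-1.
#' * `"gma"` — the mean-corrected parameterization: intercept mu = the
#'   frequency-weighted mean genotypic value, average additive effects and
#'   average allelic interactions over the non-reference alleles.
#' * `"fisher"` — the classical constrained parameterization: effects for
#'   all m alleles subject to frequency-weighted zero-sum constraints over
#'   every index.
#'
#' All effect slots are stored as full (possibly 1-by-1) arrays: `a1` a
#' vector, `d1` a symmetric matrix, `aa` a matrix (locus1 allele by locus2
#' allele), `ad` an array (j, r, s) symmetric in (r, s), `da` an array
#' (j, k, r) symmetric in (j, k), and `dd` a 4-index array with both pair
#' symmetries.  For the `"fisher"` flavor the index ranges run over all m
#' alleles; otherwise over the m-1 non-reference alleles.
#'
#' @param flavor `"glm"`, `"gma"` or `"fisher"`.
#' @param loci list of [locus()] objects (frequencies required for the
#'   `"gma"` and `"fisher"` flavors).
#' @param mu intercept (trait units).
#' @param a1,d1 locus-1 additive vector and dominance matrix.
#' @param a2,d2 locus-2 effects (two-locus models).
#' @param aa,ad,da,dd epistatic effect arrays (two-locus models); missing
#'   arrays default to zero.
#' @return An object of class `c("<flavor>_params", "marker_params")`.
#' @export
marker_params <- function(flavor = c("glm", "gma", "fisher"), loci, mu,
                          a1 = NULL, d1 = NULL, a2 = NULL, d2 = NULL,
                          aa = NULL, ad = NULL, da = NULL, dd = NULL) {
  flavor <- match.arg(flavor)
  if (inherits(loci, "locus")) loci <- list(loci)
  nloci <- length(loci)
  stopifnot(nloci %in% c(1L, 2L), is.numeric(mu), length(mu) == 1L)
  dim1 <- if (flavor == "fisher") loci[[1L]]$m else loci[[1L]]$m - 1L
  zv <- function(d) array(0, dim = d)
  a1 <- if (is.null(a1)) numeric(dim1) else unname(as.numeric(a1))
  d1 <- if (is.null(d1)) zv(c(dim1, dim1)) else
    unname(sym2(as.matrix(d1)))
  stopifnot(length(a1) == dim1, all(dim(d1) == c(dim1, dim1)))
  out <- list(flavor = flavor, loci = loci, mu = unname(mu), a1 = a1,
              d1 = d1)
  if (nloci == 2L) {
    dim2 <- if (flavor == "fisher") loci[[2L]]$m else loci[[2L]]$m - 1L
    a2 <- if (is.null(a2)) numeric(dim2) else unname(as.numeric(a2))
    d2 <- if (is.null(d2)) zv(c(dim2, dim2)) else
      unname(sym2(as.matrix(d2)))
    aa <- if (is.null(aa)) zv(c(dim1, dim2)) else
      array(as.numeric(aa), dim = c(dim1, dim2))
    ad <- if (is.null(ad)) zv(c(dim1, dim2, dim2)) else
      sym_last2(array(as.numeric(ad), dim = c(dim1, dim2, dim2)))
    da <- if (is.null(da)) zv(c(dim1, dim1, dim2)) else
      sym_first2(array(as.numeric(da), dim = c(dim1, dim1, dim2)))
    dd <- if (is.null(dd)) zv(c(dim1, dim1, dim2, dim2)) else
      sym_first2(sym_last2(array(as.numeric(dd),
                                 dim = c(dim1, dim1, dim2, dim2))))
    stopifnot(length(a2) == dim2, all(dim(d2) == c(dim2, dim2)))
    out <- c(out, list(a2 = a2, d2 = d2, aa = aa, ad = ad, da = da, dd = dd))
  }
  class(out) <- c(paste0(flavor, "_params"), "marker_params")
  out
}

# symmetrize a matrix from its upper triangle (values given for j <= k win)
sym2 <- function(mat) {
  mat[lower.tri(mat)] <- t(mat)[lower.tri(mat)]
  mat
}
# symmetrize the last two indices of a 3- or 4-d array
sym_last2 <- function(arr) {
  d <- dim(arr); nd <- length(d)
  for (r in seq_len(d[nd - 1L] - 1L)) for (s in (r + 1L):d[nd]) {
    if (nd == 3L) arr[, s, r] <- arr[, r, s]
    else arr[, , s, r] <- arr[, , r, s]
  }
  arr
}
# symmetrize the first two indices of a 3- or 4-d array
sym_first2 <- function(arr) {
  d <- dim(arr)
  for (j in seq_len(d[1L] - 1L)) for (k in (j + 1L):d[2L]) {
    if (length(d) == 3L) arr[k, j, ] <- arr[j, k, ]
    else arr[k, j, , ] <- arr[j, k, , ]
  }
  arr
}

#' @export
print.marker_params <- function(x, ...) {
  cat(toupper(x$flavor), "parameter set,", length(x$loci),
      if (length(x$loci) == 1L) "locus\n" else "loci\n")
  cat("  mu =", format(x$mu), "\n")
  show <- function(lbl, v) cat("  ", lbl, "=",
                               paste(format(as.vector(v)), collapse = ", "),
                               "\n")
  show("additive (locus 1)", x$a1)
  show("dominance (locus 1)", x$d1[upper.tri(x$d1, diag = TRUE)])
  if (length(x$loci) == 2L) {
    show("additive (locus 2)", x$a2)
    show("dominance (locus 2)", x$d2[upper.tri(x$d2, diag = TRUE)])
    show("A1A2", x$aa)
  }
  invisible(x)
}

# flatten the reduced-parameter (glm/gma) effects into the coefficient
# vector matching the design-matrix column order (intercept excluded)
param_coef <- function(params) {
  stopifnot(params$flavor %in% c("glm", "gma"))
  loci <- params$loci
  m1 <- loci[[1L]]$m
  p1pairs <- pair_index(m1 - 1L)
  d1v <- params$d1[p1pairs]
  if (length(loci) == 1L) return(c(params$a1, d1v))
  m2 <- loci[[2L]]$m
  p2pairs <- pair_index(m2 - 1L)
  d2v <- params$d2[p2pairs]
  aav <- as.vector(t(params$aa))                    # j outer, r inner
  adv <- unlist(lapply(seq_len(m1 - 1L), function(j)
    params$ad[j, , , drop = FALSE][cbind(1L, p2pairs)]))
  dav <- unlist(lapply(seq_len(nrow(p1pairs)), function(i)
    params$da[p1pairs[i, 1L], p1pairs[i, 2L], ]))
  ddv <- unlist(lapply(seq_len(nrow(p1pairs)), function(i)
    params$dd[p1pairs[i, 1L], p1pairs[i, 2L], , , drop = FALSE][
      cbind(1L, 1L, p2pairs)]))
  c(params$a1, d1v, params$a2, d2v, aav, adv, dav, ddv)
}

# inverse of param_coef: rebuild a params object from a coefficient vector
coef_to_params <- function(coefv, mu, flavor, loci) {
  m1 <- loci[[1L]]$m
  n_a1 <- m1 - 1L
  p1pairs <- pair_index(n_a1)
  n_d1 <- nrow(p1pairs)
  take <- function(k) {
    v <- coefv[seq_len(k)]
    coefv <<- coefv[-seq_len(k)]
    v
  }
  a1 <- take(n_a1)
  d1 <- matrix(0, n_a1, n_a1)
  d1[p1pairs] <- take(n_d1)
  d1 <- sym2from_upper(d1)
  if (length(loci) == 1L)
    return(marker_params(flavor, loci, mu, a1 = a1, d1 = d1))
  m2 <- loci[[2L]]$m
  n_a2 <- m2 - 1L
  p2pairs <- pair_index(n_a2)
  n_d2 <- nrow(p2pairs)
  a2 <- take(n_a2)
  d2 <- matrix(0, n_a2, n_a2)
  d2[p2pairs] <- take(n_d2)
  d2 <- sym2from_upper(d2)
  aa <- matrix(take(n_a1 * n_a2), n_a2, n_a1)       # r inner -> transpose
  aa <- t(aa)
  ad <- array(0, c(n_a1, n_a2, n_a2))
  for (j in seq_len(n_a1)) {
    vals <- take(n_d2)
    sl <- matrix(0, n_a2, n_a2)
    sl[p2pairs] <- vals
    ad[j, , ] <- sym2from_upper(sl)
  }
  da <- array(0, c(n_a1, n_a1, n_a2))
  for (i in seq_len(n_d1)) {
    vals <- take(n_a2)
    da[p1pairs[i, 1L], p1pairs[i, 2L], ] <- vals
    da[p1pairs[i, 2L], p1pairs[i, 1L], ] <- vals
  }
  dd <- array(0, c(n_a1, n_a1, n_a2, n_a2))
  for (i in seq_len(n_d1)) {
    vals <- take(n_d2)
    sl <- matrix(0, n_a2, n_a2)
    sl[p2pairs] <- vals
    sl <- sym2from_upper(sl)
    dd[p1pairs[i, 1L], p1pairs[i, 2L], , ] <- sl
    dd[p1pairs[i, 2L], p1pairs[i, 1L], , ] <- sl
  }
  marker_params(flavor, loci, mu, a1 = a1, d1 = d1, a2 = a2, d2 = d2,
                aa = aa, ad = ad, da = da, dd = dd)
}

sym2from_upper <- function(mat) {
  mat[lower.tri(mat)] <- t(mat)[lower.tri(mat)]
  mat
}
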