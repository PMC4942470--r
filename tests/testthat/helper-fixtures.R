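# shared fixtures and independent oracles used across test files

# a random polymorphic dataset at one or two loci, with every genotype
# cell guaranteed non-empty (needed by saturated fits and closed forms)
random_complete_dataset <- function(m1 = 2, m2 = NULL, n = 200, seed = 1) {
  set.seed(seed)
  make_locus <- function(m, nm) {
    p <- runif(m, 0.5, 1.5)
    locus(nm, paste0("a", seq_len(m)), freqs = p / sum(p),
          ref_allele = paste0("a", m))
  }
  loc1 <- make_locus(m1, "L1")
  loci <- list(loc1)
  cells1 <- gmanova:::pair_index(m1)
  g1 <- cells1[c(seq_len(nrow(cells1)),
                 sample.int(nrow(cells1), n - nrow(cells1), replace = TRUE)), ,
               drop = FALSE]
  geno <- list(L1 = matrix(loc1$alleles[g1], ncol = 2))
  if (!is.null(m2)) {
    loc2 <- make_locus(m2, "L2")
    loci <- list(loc1, loc2)
    cells2 <- gmanova:::pair_index(m2)
    # cover the full joint grid, then sample the rest
    grid <- cbind(cells1[rep(seq_len(nrow(cells1)), each = nrow(cells2)), ,
                         drop = FALSE],
                  cells2[rep(seq_len(nrow(cells2)), times = nrow(cells1)), ,
                         drop = FALSE])
    stopifnot(n >= nrow(grid))
    rows <- grid[c(seq_len(nrow(grid)),
                   sample.int(nrow(grid), n - nrow(grid), replace = TRUE)), ,
                 drop = FALSE]
    geno <- list(L1 = matrix(loc1$alleles[rows[, 1:2]], ncol = 2),
                 L2 = matrix(loc2$alleles[rows[, 3:4]], ncol = 2))
  }
  y <- rnorm(n)
  genotype_dataset(geno, loci = loci, phenotype = y)
}

# random reduced-flavor parameter set (glm or gma) over given loci
random_params <- function(flavor, loci, seed = 1) {
  set.seed(seed)
  n1 <- loci[[1]]$m - 1L
  rmat <- function(d) array(rnorm(prod(d)), dim = d)
  if (length(loci) == 1L)
    return(marker_params(flavor, loci, mu = rnorm(1), a1 = rnorm(n1),
                         d1 = gmanova:::sym2(rmat(c(n1, n1)))))
  n2 <- loci[[2]]$m - 1L
  marker_params(flavor, loci, mu = rnorm(1),
                a1 = rnorm(n1), d1 = gmanova:::sym2(rmat(c(n1, n1))),
                a2 = rnorm(n2), d2 = gmanova:::sym2(rmat(c(n2, n2))),
                aa = rmat(c(n1, n2)),
                ad = gmanova:::sym_last2(rmat(c(n1, n2, n2))),
                da = gmanova:::sym_first2(rmat(c(n1, n1, n2))),
                dd = gmanova:::sym_first2(gmanova:::sym_last2(
                  rmat(c(n1, n1, n2, n2)))))
}

# independent case-table evaluation of the mean-corrected codes for one
# genotype (j, k), following the published case definitions directly
gma_codes_case_table <- function(j, k, m, p) {
  ws <- numeric(m)
  for (a in seq_len(m)) {
    ws[a] <- if (j == a && k == a) 2 * (1 - p[a])
             else if (j == a || k == a) 1 - 2 * p[a]
             else -2 * p[a]
  }
  pairs <- gmanova:::pair_index(m)
  vs <- numeric(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    if (a == b) {
      vs[i] <- if (j == a && k == a) (1 - p[a])^2
               else if (j == a || k == a) -p[a] * (1 - p[a])
               else p[a]^2
    } else {
      hasa <- j == a || k == a; hasb <- j == b || k == b
      vs[i] <- if (hasa && hasb) (1 - p[a]) * (1 - p[b]) + p[a] * p[b]
               else if (j == a && k == a) -2 * p[b] * (1 - p[a])
               else if (j == b && k == b) -2 * p[a] * (1 - p[b])
               else if (hasa) -p[b] * (1 - 2 * p[a])
               else if (hasb) -p[a] * (1 - 2 * p[b])
               else 2 * p[a] * p[b]
    }
  }
  c(ws, vs)
}

# matrix-OLS oracle: plain lm() on an explicitly assembled design
ols_oracle <- function(y, X) {
  fit <- stats::lm.fit(cbind(1, X), y)
  stats::setNames(fit$coefficients, c("(Intercept)", colnames(X)))
}

study_probs <- function(model = default_study_model()) {
  outer(genotype_probs(model$loci[[1]]$freqs),
        genotype_probs(model$loci[[2]]$freqs))
}
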