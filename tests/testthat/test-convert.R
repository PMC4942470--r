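test_that("the two-locus study model converts to its known GMA form", {
  m <- default_study_model()
  gma <- m$gma
  expect_equal(gma$mu, 11.72, tolerance = 1e-12)
  expect_equal(as.vector(gma$a1), 1.8, tolerance = 1e-12)
  expect_equal(as.vector(gma$a2), 2, tolerance = 1e-12)
  expect_equal(as.vector(gma$d1), 1, tolerance = 1e-12)
  expect_equal(as.vector(gma$d2), 1, tolerance = 1e-12)
  expect_equal(as.vector(gma$aa), 1, tolerance = 1e-12)
  expect_equal(max(abs(c(gma$ad, gma$da, gma$dd))), 0, tolerance = 1e-12)
})

test_that("genotypic values evaluate the model at each cell", {
  m <- default_study_model()
  G <- genotypic_values(m$glm)
  # double reference homozygote and double allele-1 homozygote
  expect_equal(G[2, 2, 2, 2], 10)
  expect_equal(G[1, 1, 1, 1], 10 + 2 + 1 + 2 + 1 + 4)
  # symmetry
  expect_equal(G[1, 2, 2, 1], G[2, 1, 1, 2])

  # constant model gives a constant table
  loc <- locus("L1", c("a", "b"), freqs = c(0.3, 0.7))
  const <- marker_params("glm", list(loc), mu = 3)
  expect_equal(max(abs(unclass(genotypic_values(const)) - 3)), 0)
})

test_that("one-locus conversion matches the printed closed-form map", {
  set.seed(31)
  for (m in 2:4) {
    p <- runif(m, 0.5, 1.5); p <- p / sum(p)
    loc <- locus("L", paste0("a", seq_len(m)), freqs = p,
                 ref_allele = paste0("a", m))
    par <- random_params("glm", list(loc), seed = m + 1)
    gma <- convert_params(par, "gma")
    a <- as.vector(par$a1)
    d <- as.matrix(par$d1)
    # alpha*_j = a_j + sum_{k<m} p_k d_jk ; delta* = d ;
    # mu* = mu0 + 2 sum p_j a_j + sum_jk p_j p_k d_jk
    pj <- p[seq_len(m - 1)]
    expect_equal(as.vector(gma$a1), a + as.vector(d %*% pj),
                 tolerance = 1e-12)
    expect_equal(as.matrix(gma$d1), d, tolerance = 1e-12)
    expect_equal(gma$mu,
                 par$mu + 2 * sum(pj * a) + sum(outer(pj, pj) * d),
                 tolerance = 1e-12)
  }
})

test_that("biallelic conversion example: alpha* = a + p d", {
  loc <- locus("L1", c("1", "0"), freqs = c(0.4, 0.6), ref_allele = "0")
  glm <- marker_params("glm", list(loc), mu = 0, a1 = 1, d1 = 1)
  gma <- convert_params(glm, "gma")
  expect_equal(as.vector(gma$a1), 1.4, tolerance = 1e-12)
  expect_equal(as.vector(gma$d1), 1, tolerance = 1e-12)
  # with no dominance the additive effects carry over unchanged
  glm0 <- marker_params("glm", list(loc), mu = 2, a1 = 1.5)
  gma0 <- convert_params(glm0, "gma")
  expect_equal(as.vector(gma0$a1), 1.5, tolerance = 1e-12)
  expect_equal(gma0$mu, 2 + 2 * 0.4 * 1.5, tolerance = 1e-12)
})

test_that("round trips among flavors are identities", {
  set.seed(8)
  cases <- list(c(2, NA), c(3, NA), c(4, NA), c(2, 2), c(3, 2), c(3, 4))
  for (cs in cases) {
    m1 <- cs[1]; m2 <- if (is.na(cs[2])) NULL else cs[2]
    mk <- function(m, nm) {
      p <- runif(m, 0.5, 1.5); p <- p / sum(p)
      locus(nm, paste0("a", seq_len(m)), freqs = p,
            ref_allele = paste0("a", m))
    }
    loci <- if (is.null(m2)) list(mk(m1, "L1"))
            else list(mk(m1, "L1"), mk(m2, "L2"))
    s2 <- if (is.null(m2)) 0 else m2
    par <- random_params("glm", loci, seed = m1 * 10 + s2)
    back <- convert_params(convert_params(par, "gma"), "glm")
    expect_equal(back$mu, par$mu, tolerance = 1e-10)
    expect_equal(back$a1, par$a1, tolerance = 1e-10)
    expect_equal(back$d1, par$d1, tolerance = 1e-10)
    if (!is.null(m2)) {
      expect_equal(back$aa, par$aa, tolerance = 1e-10)
      expect_equal(back$ad, par$ad, tolerance = 1e-10)
      expect_equal(back$da, par$da, tolerance = 1e-10)
      expect_equal(back$dd, par$dd, tolerance = 1e-10)
    }
    gma <- random_params("gma", loci, seed = m1 * 17 + s2 + 1)
    back2 <- convert_params(convert_params(gma, "fisher"), "gma")
    for (fld in setdiff(names(back2), c("flavor", "loci")))
      expect_equal(back2[[fld]], gma[[fld]], tolerance = 1e-10)
    # round trip through the genotypic-value table itself
    G <- genotypic_values(gma)
    G2 <- genotypic_values(extract_params(G, "fisher"))
    expect_equal(unclass(G2), unclass(G), tolerance = 1e-10)
  }
})

test_that("fisher parameters satisfy the zero-sum constraints", {
  set.seed(9)
  for (rep_i in 1:5) {
    m1 <- sample(2:4, 1); m2 <- sample(2:4, 1)
    mk <- function(m, nm) {
      p <- runif(m, 0.5, 1.5); p <- p / sum(p)
      locus(nm, paste0("a", seq_len(m)), freqs = p,
            ref_allele = paste0("a", m))
    }
    loci <- list(mk(m1, "L1"), mk(m2, "L2"))
    par <- random_params("glm", loci, seed = rep_i * 3)
    fis <- convert_params(par, "fisher")
    p1 <- loci[[1]]$freqs; p2 <- loci[[2]]$freqs
    expect_lt(abs(sum(p1 * fis$a1)), 1e-10)
    expect_lt(abs(sum(p2 * fis$a2)), 1e-10)
    expect_lt(max(abs(p1 %*% fis$d1)), 1e-10)
    expect_lt(max(abs(p2 %*% fis$d2)), 1e-10)
    expect_lt(max(abs(p1 %*% fis$aa)), 1e-10)
    expect_lt(max(abs(fis$aa %*% p2)), 1e-10)
    # weighted sum over each index of every interaction array is zero
    expect_lt(max(abs(apply(fis$ad, c(2, 3), function(v) sum(p1 * v)))),
              1e-10)
    expect_lt(max(abs(apply(fis$ad, c(1, 3), function(v) sum(p2 * v)))),
              1e-10)
    expect_lt(max(abs(apply(fis$da, c(2, 3), function(v) sum(p1 * v)))),
              1e-10)
    expect_lt(max(abs(apply(fis$da, c(1, 2), function(v) sum(p2 * v)))),
              1e-10)
    expect_lt(max(abs(apply(fis$dd, c(2, 3, 4), function(v) sum(p1 * v)))),
              1e-10)
    expect_lt(max(abs(apply(fis$dd, c(1, 2, 3), function(v) sum(p2 * v)))),
              1e-10)
    # gma and fisher additive effects differ by the reference effect
    gma <- convert_params(par, "gma")
    expect_equal(as.vector(gma$a1),
                 fis$a1[seq_len(m1 - 1)] - fis$a1[m1], tolerance = 1e-10)
  }
})

test_that("two-locus (dd)* equals the GLM (dd) for the same table", {
  set.seed(12)
  mk <- function(m, nm) {
    p <- runif(m, 0.5, 1.5); p <- p / sum(p)
    locus(nm, paste0("a", seq_len(m)), freqs = p,
          ref_allele = paste0("a", m))
  }
  loci <- list(mk(3, "L1"), mk(3, "L2"))
  par <- random_params("glm", loci, seed = 4)
  G <- genotypic_values(par)
  gma <- extract_params(G, "gma")
  glm <- extract_params(G, "glm")
  expect_equal(gma$dd, glm$dd, tolerance = 1e-10)
  # one-locus analog: delta* = d (the highest-order within-locus term)
  loc <- loci[[1]]
  par1 <- random_params("glm", list(loc), seed = 5)
  gma1 <- convert_params(par1, "gma")
  expect_equal(gma1$d1, par1$d1, tolerance = 1e-10)
})
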