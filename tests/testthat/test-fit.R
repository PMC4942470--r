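test_that("saturated fits reproduce the genotypic group means", {
  ds <- random_complete_dataset(m1 = 3, n = 120, seed = 14)
  gm <- group_means(ds)$means
  for (coding in c("gma", "glm")) {
    fit <- fit_genotype_model(ds, coding = coding)
    cellfit <- gm[ds$geno[[1]]]
    expect_equal(fitted(fit), cellfit, tolerance = 1e-10)
  }
  # both codings are full reparameterizations: identical SSR and SSE
  f1 <- fit_genotype_model(ds, coding = "gma")
  f2 <- fit_genotype_model(ds, coding = "glm")
  expect_equal(f1$ssr, f2$ssr, tolerance = 1e-10)
  expect_equal(f1$sse, f2$sse, tolerance = 1e-10)
  # fitted + residuals = observed; SSR + SSE = total SS
  expect_equal(fitted(f1) + residuals(f1), ds$phenotype)
  expect_equal(f1$ssr + f1$sse, sum((ds$phenotype - mean(ds$phenotype))^2),
               tolerance = 1e-10)
})

test_that("constant phenotypes give zero effects and zero SSR", {
  ds <- random_complete_dataset(m1 = 2, n = 40, seed = 2)
  ds$phenotype <- rep(5, ds$n)
  fit <- fit_genotype_model(ds, coding = "gma")
  expect_equal(unname(coef(fit)[1]), 5, tolerance = 1e-12)
  expect_lt(max(abs(coef(fit)[-1])), 1e-12)
  expect_lt(fit$ssr, 1e-20)
})

test_that("closed-form LSE equals matrix OLS on complete datasets", {
  cases <- list(list(m1 = 2, m2 = NULL, n = 100, seed = 1),
                list(m1 = 3, m2 = NULL, n = 150, seed = 2),
                list(m1 = 4, m2 = NULL, n = 250, seed = 3),
                list(m1 = 2, m2 = 2, n = 120, seed = 4),
                list(m1 = 3, m2 = 2, n = 200, seed = 5),
                list(m1 = 3, m2 = 4, n = 700, seed = 6))
  for (cs in cases) {
    ds <- random_complete_dataset(cs$m1, cs$m2, cs$n, cs$seed)
    gm <- group_means(ds)$means
    p <- lapply(seq_along(ds$loci), function(l) mle_frequencies(ds, l)$p)
    for (flavor in c("gma", "glm")) {
      des <- build_design(ds, coding = flavor)
      oracle <- ols_oracle(ds$phenotype, des$X[, -1, drop = FALSE])
      cf <- closed_form_lse(gm, p, ds$loci, flavor = flavor)
      expect_equal(unname(cf$mu), unname(oracle[1]), tolerance = 1e-8)
      expect_equal(unname(gmanova:::param_coef(cf)), unname(oracle[-1]),
                   tolerance = 1e-8)
    }
  }
})

test_that("closed-form one-locus estimates match hand formulas", {
  # cell means (1, 0, -1) at p = 0.5: additive only
  loc <- locus("L", c("A", "B"), freqs = c(0.5, 0.5), ref_allele = "B")
  means <- matrix(c(1, 0, 0, -1), 2)
  cf <- closed_form_lse(means, list(c(0.5, 0.5)), list(loc), "gma")
  expect_equal(cf$mu, 0, tolerance = 1e-12)
  expect_equal(as.vector(cf$a1), 1, tolerance = 1e-12)
  expect_equal(as.vector(cf$d1), 0, tolerance = 1e-12)
  cfg <- closed_form_lse(means, list(c(0.5, 0.5)), list(loc), "glm")
  expect_equal(as.vector(cfg$a1), 1, tolerance = 1e-12)  # y12 - y22
  expect_equal(as.vector(cfg$d1), 0, tolerance = 1e-12)
  # constant means collapse to the intercept
  cfc <- closed_form_lse(matrix(2, 2, 2), list(c(0.5, 0.5)), list(loc), "gma")
  expect_equal(cfc$mu, 2)
  expect_equal(as.vector(cfc$a1), 0)
  # an empty cell is an error
  means_na <- means; means_na[1, 1] <- NA
  expect_error(closed_form_lse(means_na, list(c(0.5, 0.5)), list(loc)),
               "empty")
})

test_that("two-locus closed form recovers generating parameters", {
  m <- default_study_model()
  G <- unclass(genotypic_values(m$gma))
  p <- list(m$loci[[1]]$freqs, m$loci[[2]]$freqs)
  cf <- closed_form_lse(G, p, m$loci, "gma")
  for (fld in c("mu", "a1", "d1", "a2", "d2", "aa", "ad", "da", "dd"))
    expect_equal(cf[[fld]], m$gma[[fld]], tolerance = 1e-10)
})

test_that("rank deficiency errors by default and can drop columns", {
  ds <- random_complete_dataset(m1 = 2, n = 50, seed = 7)
  # force an empty heterozygote cell
  het <- ds$geno[[1]][, 1] == 1 & ds$geno[[1]][, 2] == 2
  ds$geno[[1]][het, ] <- matrix(rep(c(1L, 1L), sum(het)), ncol = 2,
                                byrow = TRUE)
  expect_error(fit_genotype_model(ds, coding = "glm"), "rank deficient")
  expect_warning(fit <- fit_genotype_model(ds, coding = "glm",
                                           allow_rank_deficient = TRUE),
                 "dropping")
  expect_lt(length(coef(fit)), 4)
})

test_that("Type III equals sequential SS under orthogonality", {
  ds <- exact_hwe_fixture(c(0.4, 0.6), 100)
  set.seed(15)
  loc <- ds$loci[[1]]
  true <- marker_params("gma", list(loc), mu = 1, a1 = 0.8, d1 = 0.5)
  ds <- simulate_phenotypes(ds, true, v_eps = 1, seed = 16)
  fit <- fit_genotype_model(ds, coding = "gma")
  ss_a <- type3_ss(fit, "A1")
  ss_d <- type3_ss(fit, "D1")
  # sequential SS for A1 alone (orthogonal blocks make these equal)
  X_a <- fit$design[, c(1, fit$blocks$A1), drop = FALSE]
  cf <- qr.coef(qr(X_a), fit$y)
  seq_a <- sum((X_a %*% cf - mean(fit$y))^2)
  expect_equal(ss_a, seq_a, tolerance = 1e-8)
  expect_equal(ss_a + ss_d, fit$ssr, tolerance = 1e-8)
})

test_that("Type III agrees with brute-force refits on random data", {
  ds <- random_complete_dataset(m1 = 3, m2 = 2, n = 300, seed = 23)
  fit <- fit_genotype_model(ds, coding = "gma", blocks = c("A1", "D1", "A2"))
  for (b in c("A1", "D1", "A2")) {
    keep <- setdiff(seq_len(ncol(fit$design)), fit$blocks[[b]])
    oracle_fit <- lm.fit(fit$design[, keep, drop = FALSE], fit$y)
    ss_oracle <- sum(oracle_fit$residuals^2) - fit$sse
    expect_equal(type3_ss(fit, b), ss_oracle, tolerance = 1e-8)
  }
  # a block with zero coefficients contributes zero Type III SS
  ds0 <- ds
  des <- build_design(ds0, coding = "gma", blocks = c("A1", "D1"))
  beta <- c(2, rnorm(length(des$blocks$A1)), rep(0, length(des$blocks$D1)))
  ds0$phenotype <- as.vector(des$X %*% beta)
  fit0 <- fit_genotype_model(ds0, coding = "gma", blocks = c("A1", "D1"))
  expect_lt(type3_ss(fit0, "D1"), 1e-18)
})

test_that("single-df block F equals the squared t statistic", {
  ds <- random_complete_dataset(m1 = 2, n = 80, seed = 33)
  fit <- fit_genotype_model(ds, coding = "gma")
  ft <- group_f_test(fit, "A1")
  tstat <- coef(fit)["w*_L1_a1"] / sqrt(vcov(fit)["w*_L1_a1", "w*_L1_a1"])
  expect_equal(ft$F, unname(tstat^2), tolerance = 1e-8)
  expect_equal(ft$df1, 1L)
})

test_that("block diagonality of X'X holds on exact-HWE fixtures", {
  ds <- exact_hwe_fixture(c(0.2, 0.3, 0.5), 200)
  des <- build_design(ds, coding = "gma")
  XtX <- crossprod(des$X)
  ia <- des$blocks$A1; id <- des$blocks$D1
  expect_lt(max(abs(XtX[1, c(ia, id)])), 1e-10)    # intercept vs blocks
  expect_lt(max(abs(XtX[ia, id])), 1e-10)          # A block vs D block
  expect_equal(XtX[1, 1], ds$n)
})

test_that("dropping the D block leaves GMA additive LSE unchanged in HWE", {
  ds <- exact_hwe_fixture(c(0.2, 0.3, 0.5), 200)
  set.seed(41)
  loc <- ds$loci[[1]]
  true <- marker_params("glm", list(loc), mu = 1, a1 = c(1, -0.5),
                        d1 = matrix(c(0.9, 0.4, 0.4, -0.7), 2))
  ds <- simulate_phenotypes(ds, true, v_eps = 0.5, seed = 42)
  full <- fit_genotype_model(ds, coding = "gma")
  red <- fit_genotype_model(ds, coding = "gma", blocks = "A1")
  expect_equal(coef(red)[1], coef(full)[1], tolerance = 1e-10)
  expect_equal(coef(red)[red$blocks$A1], coef(full)[full$blocks$A1],
               tolerance = 1e-10)
  # the GLM coding does not have this property on the same data
  fullg <- fit_genotype_model(ds, coding = "glm")
  redg <- fit_genotype_model(ds, coding = "glm", blocks = "A1")
  expect_gt(max(abs(coef(redg)[redg$blocks$A1] -
                      coef(fullg)[fullg$blocks$A1])), 0.05)
})

test_that("two-locus HWE fixtures keep excluded-block LSE consistent", {
  ds <- exact_hwe_fixture(list(c(0.4, 0.6), c(0.5, 0.5)), 400)
  true <- marker_params("glm", ds$loci, mu = 10, a1 = 1, d1 = 1,
                        a2 = 1, d2 = 1, aa = 1)
  ds <- simulate_phenotypes(ds, true, v_eps = 2, seed = 77)
  full <- fit_genotype_model(ds, coding = "gma")
  for (drop in c("D1D2", "A1D2", "D2")) {
    blocks <- setdiff(names(full$blocks), drop)
    red <- fit_genotype_model(ds, coding = "gma", blocks = blocks)
    shared <- intersect(names(coef(red)), names(coef(full)))
    expect_equal(coef(red)[shared], coef(full)[shared], tolerance = 1e-8)
  }
})

test_that("the A-block F-test holds its size under the null", {
  # additive effects zero, dominance present; exact-HWE genotypes
  loc <- locus("L1", c("1", "0"), freqs = c(0.5, 0.5), ref_allele = "0")
  base <- exact_hwe_fixture(c(0.5, 0.5), 400, loci = list(loc))
  true <- marker_params("gma", list(loc), mu = 0, a1 = 0, d1 = 1)
  nrej <- 0L
  nrep <- 600L
  set.seed(55)
  seeds <- sample.int(1e8, nrep)
  for (i in seq_len(nrep)) {
    ds <- simulate_phenotypes(base, true, v_eps = 1, seed = seeds[i])
    fit <- fit_genotype_model(ds, coding = "gma")
    if (group_f_test(fit, "A1")$p_value < 0.05) nrej <- nrej + 1L
  }
  rate <- nrej / nrep
  # 0.05 +/- 4 binomial SE (~0.0089)
  expect_gt(rate, 0.05 - 4 * sqrt(0.05 * 0.95 / nrep))
  expect_lt(rate, 0.05 + 4 * sqrt(0.05 * 0.95 / nrep))
})

test_that("covariates are carried through the fit", {
  ds <- random_complete_dataset(m1 = 2, n = 100, seed = 61)
  set.seed(62)
  z <- rnorm(ds$n)
  ds$covariates <- data.frame(z = z)
  ds$phenotype <- ds$phenotype + 2 * z
  fit <- fit_genotype_model(ds, coding = "gma", covariates = "z")
  expect_true("z" %in% names(coef(fit)))
  oracle <- ols_oracle(ds$phenotype, fit$design[, -1, drop = FALSE])
  expect_equal(unname(coef(fit)), unname(oracle), tolerance = 1e-10)
})
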