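test_that("fitted components decompose the fitted values", {
  ds <- random_complete_dataset(m1 = 3, m2 = 2, n = 300, seed = 71)
  fit <- fit_genotype_model(ds, coding = "gma")
  comps <- fitted_components(fit)
  expect_equal(rowSums(comps) + coef(fit)[1], fitted(fit),
               tolerance = 1e-10, ignore_attr = TRUE)
  # one-locus biallelic additive component takes at most 3 values
  ds1 <- random_complete_dataset(m1 = 2, n = 100, seed = 72)
  fit1 <- fit_genotype_model(ds1, coding = "gma")
  expect_lte(length(unique(round(fitted_components(fit1)[, "A1"], 12))), 3)
})

test_that("component variances are non-negative on arbitrary data", {
  for (sd in 1:5) {
    ds <- random_complete_dataset(m1 = sample(2:4, 1), n = 150,
                                  seed = 100 + sd)
    vc <- varcomp_from_fit(fit_genotype_model(ds, coding = "gma"))
    expect_true(all(vc$variances >= 0))
    vcg <- varcomp_from_fit(fit_genotype_model(ds, coding = "glm"))
    expect_true(all(vcg$variances >= 0))
    # V_G decomposes into variances plus twice the covariances
    off <- vc$covariances[upper.tri(vc$covariances)]
    expect_equal(vc$V_G, sum(vc$variances) + 2 * sum(off), tolerance = 1e-10)
  }
})

test_that("HWE closed-form estimators match hand cases and the fit route", {
  p <- c(0.5, 0.5)
  # additive pattern
  v <- varcomp_hwe_closed_form(matrix(c(1, 0, 0, -1), 2), p)
  expect_equal(v$V_A, 0.5, tolerance = 1e-12)
  expect_equal(v$V_D, 0, tolerance = 1e-12)
  # pure dominance pattern
  v2 <- varcomp_hwe_closed_form(matrix(c(1, -1, -1, 1), 2), p)
  expect_equal(v2$V_A, 0, tolerance = 1e-12)
  expect_equal(v2$V_D, 1, tolerance = 1e-12)
  # constant means
  v3 <- varcomp_hwe_closed_form(matrix(4, 2, 2), p)
  expect_equal(c(v3$V_A, v3$V_D), c(0, 0))

  # agreement with the fitted-component route on an exact-HWE sample
  ds <- exact_hwe_fixture(c(0.3, 0.7), 200)
  true <- marker_params("glm", ds$loci, mu = 0, a1 = 1, d1 = 0.6)
  ds <- simulate_phenotypes(ds, true, v_eps = 0.8, seed = 5)
  fit <- fit_genotype_model(ds, coding = "gma")
  vc <- varcomp_from_fit(fit)
  gm <- group_means(ds)$means
  cf <- varcomp_hwe_closed_form(gm, mle_frequencies(ds)$p)
  expect_equal(unname(vc$variances["A1"]), cf$V_A, tolerance = 1e-10)
  expect_equal(unname(vc$variances["D1"]), cf$V_D, tolerance = 1e-10)
  # orthogonality and the exact phenotypic variance identity
  expect_lt(abs(vc$covariances["A1", "D1"]), 1e-12)
  expect_equal(vc$V_Y, cf$V_A + cf$V_D + vc$V_eps, tolerance = 1e-10)
})

test_that("residual and total variance behave at the extremes", {
  ds <- exact_hwe_fixture(c(0.5, 0.5), 100)
  true <- marker_params("glm", ds$loci, mu = 1, a1 = 2, d1 = 1)
  dsn <- simulate_phenotypes(ds, true, v_eps = 0, seed = 1)
  rt <- residual_and_total(dsn)
  expect_equal(rt$V_eps, 0)
  # pure noise: residual share tends to one
  null <- marker_params("glm", ds$loci, mu = 0)
  big <- exact_hwe_fixture(c(0.5, 0.5), 10000)
  dsn2 <- simulate_phenotypes(big, null, v_eps = 4, seed = 2)
  rt2 <- residual_and_total(dsn2)
  expect_gt(rt2$V_eps / rt2$V_Y, 0.99)
})

test_that("exact enumeration reproduces the study model partition", {
  m <- default_study_model()
  gv <- genotypic_values(m$glm)
  tv <- true_varcomp_enumeration(gv, study_probs(m))
  expect_equal(tv$V_G, 3.072, tolerance = 1e-10)
  expect_equal(unname(tv$variances[c("A1", "D1", "A2", "D2", "A1A2")]),
               c(1.5552, 0.0576, 1.28, 0.0256, 0.1536), tolerance = 1e-10)
  # all covariances vanish under HWE and independence
  expect_lt(max(abs(tv$covariances[upper.tri(tv$covariances)])), 1e-12)
  expect_lt(abs(tv$cov_fraction), 1e-10)
  # additive-only model: V_G = V_A exactly
  loc <- locus("L", c("1", "0"), freqs = c(0.3, 0.7), ref_allele = "0")
  add <- marker_params("gma", list(loc), mu = 0, a1 = 1.5)
  tva <- true_varcomp_enumeration(genotypic_values(add),
                                  genotype_probs(loc$freqs))
  expect_equal(tva$V_G, unname(tva$variances["A1"]), tolerance = 1e-12)
  expect_equal(tva$V_G, 1.5^2 * 2 * 0.3 * 0.7, tolerance = 1e-12)
})

test_that("sample variance components converge to the enumeration values", {
  m <- default_study_model()
  gv <- genotypic_values(m$glm)
  tv <- true_varcomp_enumeration(gv, study_probs(m))
  for (n in c(1000, 10000, 100000)) {
    ds <- simulate_genotypes(n, m$loci, seed = 1000 + n)
    ds <- simulate_phenotypes(ds, m$glm, m$v_eps, seed = 2000 + n)
    vc <- varcomp_from_fit(fit_genotype_model(ds, coding = "gma"))
    # ~4 sigma Monte Carlo band for the dominant component, scaling 1/sqrt(n)
    expect_lt(max(abs(vc$variances - tv$variances)), 45 / sqrt(n))
  }
})

test_that("GLM and GMA partitions differ as the theory predicts", {
  m <- default_study_model()
  gv <- genotypic_values(m$glm)
  probs <- study_probs(m)
  tv_gma <- true_varcomp_enumeration(gv, probs, coding = "gma")
  tv_glm <- true_varcomp_enumeration(gv, probs, coding = "glm")
  expect_equal(tv_gma$V_G, tv_glm$V_G, tolerance = 1e-12)
  expect_lt(abs(tv_gma$cov_fraction), 1e-10)       # orthogonal partition
  expect_gt(tv_glm$cov_fraction, 0.5)              # heavy confounding
})

test_that("covariate-adjusted fits still yield variance components", {
  ds <- random_complete_dataset(m1 = 2, n = 200, seed = 91)
  set.seed(92)
  z <- rnorm(ds$n)
  ds$covariates <- data.frame(z = z)
  ds$phenotype <- ds$phenotype + 3 * z
  fit <- fit_genotype_model(ds, coding = "gma", covariates = "z")
  vc <- varcomp_from_fit(fit)
  expect_true(all(vc$variances >= 0))
  # the covariate part is not a genetic component
  expect_false("z" %in% names(vc$variances))
})
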