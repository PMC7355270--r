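ref <- reference_estimates()

test_that("standardized components exclude rater variance and sum to one", {
  p <- toy_params2(rater = TRUE)
  sc <- standardized_components(p)
  expect_equal(sc$a2 + sc$d2 + sc$e2, c(1, 1))
  expect_equal(sc$h2_broad, sc$a2 + sc$d2)
  # adding rater variance changes nothing
  p0 <- toy_params2(rater = FALSE)
  expect_equal(standardized_components(p0)[, -1], sc[, -1])
  # pure-A phenotype
  pa <- ade_parameters(1, 0, 1e-6, phenotypes = "X")
  sca <- standardized_components(pa)
  expect_equal(sca$a2, 1, tolerance = 1e-6)
})

test_that("component correlations equal brute-force normalization and report undefined entries as NA", {
  set.seed(61)
  for (r in 1:4) {
    M <- 3
    p <- ade_parameters(lower_tri(rnorm(6, 0.4, 0.3), M),
                        lower_tri(rnorm(6, 0.2, 0.2), M),
                        lower_tri(c(0.7, 0.1, 0.6, 0.05, 0.1, 0.5), M))
    cc <- component_correlations(p)
    for (nm in c("a", "d", "e")) {
      S <- cholesky_cov(p[[paste0("delta_", nm)]])
      brute <- matrix(NA_real_, M, M)
      for (i in 1:M) for (j in 1:M)
        if (S[i, i] > 0 && S[j, j] > 0) brute[i, j] <- S[i, j] / sqrt(S[i, i] * S[j, j])
      expect_equal(unname(cc[[paste0("corr_", nm)]]), brute)
    }
  }
  # diagonal Sigma -> identity correlations
  pd <- ade_parameters(diag(c(1, 2)), diag(c(0.5, 0.4)), diag(c(0.3, 0.3)))
  expect_equal(unname(component_correlations(pd)$corr_a), diag(2))
  # zero component variance -> NA, not 0
  pz <- ade_parameters(lower_tri(c(1, 0, 0), 2), diag(2) * 0.5, diag(2) * 0.5)
  expect_true(is.na(component_correlations(pz)$corr_a[1, 2]))
})

test_that("covariance proportions complement each other and reduce to h2 on the diagonal", {
  set.seed(62)
  p <- ade_parameters(lower_tri(rnorm(6, 0.5, 0.2), 3),
                      lower_tri(rnorm(6, 0.3, 0.2), 3),
                      lower_tri(c(0.7, 0.2, 0.6, 0.1, 0.2, 0.5), 3))
  pr <- covariance_proportions(p)
  expect_lt(max(abs(pr$prop_ad + pr$prop_e - 1), na.rm = TRUE), 1e-12)
  expect_equal(unname(diag(pr$prop_ad)), standardized_components(p)$h2_broad)
  # Sigma_E = 0 would give all ones; use near-zero E
  p1 <- ade_parameters(diag(2), diag(2) * 0.5, diag(2) * 1e-8)
  expect_equal(unname(diag(covariance_proportions(p1)$prop_ad)), c(1, 1),
               tolerance = 1e-6)
})

test_that("the two routes to implied phenotypic correlations agree on random parameters", {
  set.seed(63)
  for (r in 1:6) {
    p <- ade_parameters(lower_tri(rnorm(10, 0.4, 0.3), 4),
                        lower_tri(rnorm(10, 0.2, 0.2), 4),
                        lower_tri(c(0.7, .1, .0, .1, 0.6, .1, .0, 0.5, .1, 0.6), 4))
    r1 <- implied_phenotypic_correlations(p, method = "standardized")
    r2 <- implied_phenotypic_correlations(p, method = "direct")
    expect_lt(max(abs(r1 - r2)), 1e-10)
    expect_equal(diag(r1), rep(1, 4), ignore_attr = TRUE)
  }
  # orthogonal phenotypes -> identity
  po <- ade_parameters(diag(c(.8, .7)), diag(c(.4, .5)), diag(c(.45, .5)))
  expect_equal(unname(implied_phenotypic_correlations(po)), diag(2))
})

test_that("the published bivariate worked example reproduces (r_ph ~ .340, genetic share ~ .930)", {
  # printed inputs: h2 = .912/.658, A+D correlation .409, e2 = .088/.342,
  # E correlation .138
  out <- implied_correlations_from_standardized(
    h2 = c(.912, .658), e2 = c(.088, .342),
    corr_ad = matrix(c(1, .409, .409, 1), 2),
    corr_e = matrix(c(1, .138, .138, 1), 2))
  expect_equal(out$implied[1, 2], 0.340, tolerance = 0.0015 / 0.340)
  expect_equal(out$prop_ad[1, 2], 0.930, tolerance = 0.0015 / 0.930)
  expect_lt(abs(out$genetic[1, 2] - 0.316), 0.0015)
})

test_that("the full published table of implied correlations reconstructs within +/- 0.0015", {
  out <- implied_correlations_from_standardized(
    h2 = ref$components$h2_broad, e2 = ref$components$e2,
    corr_ad = ref$corr_ad, corr_e = ref$corr_e)
  off <- lower.tri(out$implied)
  expect_equal(sum(off), 28)
  expect_lt(max(abs(out$implied[off] - ref$pheno_corr[off])), 0.0015)
  # spot values
  expect_equal(out$implied["CPRS_H", "SWAN_H"], 0.478, tolerance = 0.0015 / 0.478)
  expect_equal(out$implied["SWAN_I", "SWAN_H"], 0.824, tolerance = 0.0015 / 0.824)
  expect_equal(out$implied["CTRS_H", "TRF_H"], 0.741, tolerance = 0.0015 / 0.741)
})

test_that("the published covariance-proportion entries reconstruct within +/- 0.0015", {
  out <- implied_correlations_from_standardized(
    h2 = ref$components$h2_broad, e2 = ref$components$e2,
    corr_ad = ref$corr_ad, corr_e = ref$corr_e)
  off <- lower.tri(out$prop_ad)
  expect_lt(max(abs(out$prop_ad[off] - t(ref$prop_ad)[off])), 0.0015)
  expect_equal(out$prop_ad["CPRS_H", "SWAN_H"], 0.888, tolerance = 0.0015 / 0.888)
  expect_equal(out$prop_ad["TRF_H", "SWAN_H"], 0.999, tolerance = 0.0015 / 0.999)
})

test_that("bivariate decomposition is internally consistent and rejects i == j", {
  p <- toy_params2(rater = TRUE)
  bd <- bivariate_decomposition(p, "MHYP", "TINATT")
  expect_equal(bd$genetic_share * bd$implied_correlation, bd$genetic_path)
  expect_equal(bd$implied_correlation,
               implied_phenotypic_correlations(p)[1, 2])
  expect_error(bivariate_decomposition(p, 1, 1), "different")
  # zero E correlation -> share exactly 1
  pz <- ade_parameters(lower_tri(c(.8, .4, .6), 2), diag(2) * 0.3,
                       diag(c(.4, .5)))
  bz <- bivariate_decomposition(pz, 1, 2)
  expect_equal(bz$genetic_share, 1)
})

test_that("decompose_ade bundles all tables consistently", {
  p <- toy_params2(rater = TRUE)
  dec <- decompose_ade(p)
  expect_s3_class(dec, "ade_decomposition")
  expect_equal(dec$components, standardized_components(p))
  expect_equal(dec$implied_pheno_corr, implied_phenotypic_correlations(p))
  expect_output(print(dec), "Standardized variance components")
})
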