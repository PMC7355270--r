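# shared fixtures: small parameter sets, simulated datasets, and independent
# brute-force oracles (kept free of the package's own linear-algebra paths)

lower_tri <- function(v, M) {
  L <- matrix(0, M, M)
  L[lower.tri(L, diag = TRUE)] <- v
  L
}

# a well-conditioned 2-phenotype ADE parameter set (standardized totals ~1)
toy_params2 <- function(rater = FALSE, beta_sex = c(-0.2, -0.1)) {
  ade_parameters(
    delta_a = lower_tri(c(0.7, 0.3, 0.6), 2),
    delta_d = lower_tri(c(0.4, 0.1, 0.35), 2),
    delta_e = lower_tri(c(0.5, 0.15, 0.45), 2),
    rater_loadings = if (rater) c(0, 0.6) else NULL,
    intercepts = c(0.1, -0.1),
    beta_sex = beta_sex,
    phenotypes = c("MHYP", "TINATT"),
    teacher_rated = c(FALSE, rater))
}

# independent multivariate-normal log density (solve/determinant, no Cholesky)
mvn_logdens <- function(y, mu, S) {
  k <- length(y)
  d <- y - mu
  ld <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
  -0.5 * (k * log(2 * pi) + ld + drop(t(d) %*% solve(S) %*% d))
}

# simulate, optionally with missingness, at modest size
toy_dataset <- function(n_mz = 150, n_dz = 150, params = toy_params2(),
                        miss = NULL, seed = 11) {
  des <- simulation_design(n_mz, n_dz, missingness = miss, seed = seed)
  dat <- simulate_twin_pairs(params, des)
  if (!is.null(miss)) dat <- impose_missingness(dat, des)
  dat
}
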