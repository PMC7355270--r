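miss2 <- list(list(phenotypes = "MHYP", prob = 0.2, unit = "twin"),
              list(phenotypes = "TINATT", prob = 0.3, unit = "twin"))

test_that("pair_loglik equals the brute-force observed-submatrix normal density", {
  p <- toy_params2(rater = TRUE)
  dat <- toy_dataset(100, 100, p, miss = miss2, seed = 12)
  cols <- c("MHYP_1", "TINATT_1", "MHYP_2", "TINATT_2")
  checked <- 0
  for (i in seq_len(nrow(dat))) {
    rec <- dat[i, ]
    y <- as.numeric(rec[c("MHYP_1", "TINATT_1", "MHYP_2", "TINATT_2")])
    obs <- which(!is.na(y))
    if (!length(obs)) next
    sig <- build_group_cov(p, rec$zygosity, rec$same_teacher)$sigma
    mu <- build_means(p, rec$sex_1, rec$sex_2)
    expect_equal(pair_loglik(p, rec),
                 mvn_logdens(y[obs], mu[obs], sig[obs, obs, drop = FALSE]),
                 tolerance = 1e-10)
    checked <- checked + 1
  }
  expect_gt(checked, 150)
  # one twin fully missing reduces to the single-twin marginal
  rec <- dat[which(stats::complete.cases(dat[cols]))[1], ]
  rec[c("MHYP_2", "TINATT_2")] <- NA_real_
  sig <- build_group_cov(p, rec$zygosity, rec$same_teacher)$sigma
  y1 <- as.numeric(rec[c("MHYP_1", "TINATT_1")])
  expect_equal(pair_loglik(p, rec),
               mvn_logdens(y1, build_means(p, rec$sex_1, rec$sex_2)[1:2],
                           sig[1:2, 1:2]))
})

test_that("pair_loglik matches the mvtnorm density oracle", {
  skip_if_not_installed("mvtnorm")
  p <- toy_params2(rater = TRUE)
  dat <- toy_dataset(40, 40, p, miss = miss2, seed = 13)
  for (i in c(1, 7, 20, 55, 78)) {
    rec <- dat[i, ]
    y <- as.numeric(rec[c("MHYP_1", "TINATT_1", "MHYP_2", "TINATT_2")])
    obs <- which(!is.na(y))
    if (!length(obs)) next
    sig <- build_group_cov(p, rec$zygosity, rec$same_teacher)$sigma
    mu <- build_means(p, rec$sex_1, rec$sex_2)
    expect_equal(pair_loglik(p, rec),
                 mvtnorm::dmvnorm(y[obs], mu[obs], sig[obs, obs, drop = FALSE],
                                  log = TRUE),
                 tolerance = 1e-10)
  }
})

test_that("the sufficient-statistics engine equals the casewise log-likelihood at arbitrary parameters", {
  p <- toy_params2(rater = TRUE)
  dat <- toy_dataset(120, 120, p, miss = miss2, seed = 14)
  spec <- ade_model_spec(c("MHYP", "TINATT"), teacher_rated = c(FALSE, TRUE))
  model <- twinade:::ade_internal_model(spec)
  prep <- twinade:::fiml_prepare(dat, model$phenotypes)
  set.seed(15)
  for (r in 1:4) {
    par <- model$start(prep) + rnorm(model$npar, sd = 0.05)
    nll <- as.numeric(twinade:::engine_nll(par, model, prep))
    casewise <- -dataset_loglik(model$build_estimates(par), dat)
    expect_equal(nll, casewise, tolerance = 1e-9)
    # per-pair vector agrees too
    vec <- twinade:::casewise_loglik_vector(par, model, prep)
    expect_equal(-sum(vec), nll, tolerance = 1e-9)
  }
})

test_that("analytic gradients match central finite differences", {
  p <- toy_params2(rater = TRUE)
  dat <- toy_dataset(80, 80, p, miss = miss2, seed = 16)
  spec <- ade_model_spec(c("MHYP", "TINATT"), teacher_rated = c(FALSE, TRUE))
  model <- twinade:::ade_internal_model(spec)
  prep <- twinade:::fiml_prepare(dat, model$phenotypes)
  set.seed(17)
  par <- model$start(prep) + rnorm(model$npar, sd = 0.03)
  g <- attr(twinade:::engine_nll(par, model, prep, want_grad = TRUE), "gradient")
  gn <- twinade:::num_gradient(function(q)
    as.numeric(twinade:::engine_nll(q, model, prep)), par)
  expect_equal(g, gn, tolerance = 1e-5)
  # and for the independent pathway parameterization
  fs <- factor_spec(c(MHYP = "F1", TINATT = "F2"), components_with_factors = "A")
  ipm <- twinade:::ip_internal_model(fs)
  par2 <- ipm$start(prep) * 0.9 + 0.02
  g2 <- attr(twinade:::engine_nll(par2, ipm, prep, want_grad = TRUE), "gradient")
  gn2 <- twinade:::num_gradient(function(q)
    as.numeric(twinade:::engine_nll(q, ipm, prep)), par2)
  expect_equal(g2, gn2, tolerance = 1e-5)
})

test_that("log-likelihood is invariant to pair order and MZ twin-label permutation", {
  p <- toy_params2()
  dat <- toy_dataset(100, 100, p, miss = miss2, seed = 18)
  ll <- dataset_loglik(p, dat)
  set.seed(19)
  expect_equal(dataset_loglik(p, dat[sample(nrow(dat)), ]), ll)
  swapped <- dat
  mz <- swapped$zygosity == "MZ"
  for (ph in c("MHYP", "TINATT")) {
    tmp <- swapped[[paste0(ph, "_1")]][mz]
    swapped[[paste0(ph, "_1")]][mz] <- swapped[[paste0(ph, "_2")]][mz]
    swapped[[paste0(ph, "_2")]][mz] <- tmp
  }
  tmp <- swapped$sex_1[mz]; swapped$sex_1[mz] <- swapped$sex_2[mz]
  swapped$sex_2[mz] <- tmp
  expect_equal(dataset_loglik(p, swapped), ll, tolerance = 1e-9)
})

test_that("fit on complete data matches an independent grouped sufficient-statistics fit", {
  p <- toy_params2(rater = TRUE)
  dat <- toy_dataset(250, 250, p, seed = 20)
  spec <- ade_model_spec(c("MHYP", "TINATT"), teacher_rated = c(FALSE, TRUE))
  fit <- fit_ade(dat, spec, fit_options(n_starts = 2))
  expect_true(fit$converged)

  ## oracle: group-by-(zygosity, teacher, sexes) Wishart-form likelihood from
  ## sample moments, maximized independently over the same parameterization
  model <- twinade:::ade_internal_model(spec)
  groups <- split(seq_len(nrow(dat)),
                  paste(dat$zygosity, dat$same_teacher, dat$sex_1, dat$sex_2))
  cols <- c("MHYP_1", "TINATT_1", "MHYP_2", "TINATT_2")
  stats_g <- lapply(groups, function(i) {
    Y <- as.matrix(dat[i, cols])
    list(n = nrow(Y), m = colMeans(Y), S = cov(Y) * (nrow(Y) - 1) / nrow(Y),
         zyg = dat$zygosity[i[1]], st = dat$same_teacher[i[1]],
         s1 = dat$sex_1[i[1]], s2 = dat$sex_2[i[1]])
  })
  oracle_nll <- function(par) {
    est <- model$build_estimates(par)
    tot <- 0
    for (g in stats_g) {
      sig <- build_group_cov(est, g$zyg, g$st)$sigma
      mu <- build_means(est, g$s1, g$s2)
      Sinv <- tryCatch(solve(sig), error = function(e) NULL)
      if (is.null(Sinv)) return(1e10)
      ld <- as.numeric(determinant(sig)$modulus)
      d <- g$m - mu
      tot <- tot + g$n * (length(mu) * log(2 * pi) + ld +
                            sum(Sinv * g$S) + drop(t(d) %*% Sinv %*% d))
    }
    tot / 2
  }
  prep <- twinade:::fiml_prepare(dat, model$phenotypes)
  o <- optim(model$start(prep), oracle_nll, method = "BFGS",
             control = list(maxit = 2000, reltol = 1e-14))
  expect_equal(fit$loglik, -o$value, tolerance = 1e-5 * abs(fit$loglik))
})

test_that("no converged parameter can be improved by a +/- 0.05 perturbation", {
  p <- toy_params2()
  dat <- toy_dataset(200, 200, p, seed = 22)
  spec <- ade_model_spec(c("MHYP", "TINATT"))
  fit <- fit_ade(dat, spec, fit_options(n_starts = 1))
  expect_true(fit$converged)
  model <- fit$model
  prep <- twinade:::fiml_prepare(dat, model$phenotypes)
  base <- as.numeric(twinade:::engine_nll(as.numeric(fit$par), model, prep))
  for (j in seq_along(fit$par)) for (d in c(-0.05, 0.05)) {
    par <- as.numeric(fit$par); par[j] <- par[j] + d
    expect_gte(as.numeric(twinade:::engine_nll(par, model, prep)), base - 1e-6)
  }
})

test_that("parameter recovery at moderate n and boundary behavior when a2 = 0", {
  p <- toy_params2(rater = TRUE)
  des <- simulation_design(1500, 1500, seed = 23, missingness = miss2)
  dat <- impose_missingness(simulate_twin_pairs(p, des), des)
  spec <- ade_model_spec(c("MHYP", "TINATT"), teacher_rated = c(FALSE, TRUE))
  fit <- fit_ade(dat, spec, fit_options(n_starts = 2))
  expect_true(fit$converged)
  truth <- standardized_components(p)
  est <- standardized_components(fit$estimates)
  expect_lt(max(abs(est$h2_broad - truth$h2_broad)), 0.05)
  expect_lt(max(abs(est$e2 - truth$e2)), 0.05)
  # sex effects and rater loading recovered
  expect_lt(max(abs(fit$estimates$beta_sex - p$beta_sex)), 0.06)
  expect_lt(abs(fit$estimates$rater_loadings[2] - 0.6), 0.08)

  # generating a2 = 0 (pure D + E): the additive estimate sits near zero
  p0 <- ade_parameters(0, sqrt(0.6), sqrt(0.4), phenotypes = "X")
  d0 <- simulate_twin_pairs(p0, simulation_design(1500, 1500, seed = 24))
  f0 <- fit_ade(d0, ade_model_spec("X"), fit_options(n_starts = 3))
  est0 <- standardized_components(f0$estimates)
  expect_lt(est0$a2, 0.1)
})

test_that("a single zygosity group triggers an identification warning", {
  p <- toy_params2()
  dat <- toy_dataset(120, 0, p, seed = 25)
  expect_warning(fit_ade(dat, ade_model_spec(c("MHYP", "TINATT")),
                         fit_options(n_starts = 1)),
                 "not separately identified")
})

test_that("robust and observed-information SEs agree under correct specification", {
  p <- ade_parameters(sqrt(0.5), sqrt(0.2), sqrt(0.3), intercepts = 0.2,
                      beta_sex = -0.2, phenotypes = "X")
  d <- simulate_twin_pairs(p, simulation_design(2000, 2000, seed = 26))
  fit <- fit_ade(d, ade_model_spec("X"), fit_options(n_starts = 2))
  se <- robust_se(fit, d)
  expect_true(all(is.finite(se$se_sandwich)))
  expect_lt(max(abs(se$se_sandwich / se$se_observed - 1)), 0.15)
})

test_that("heavy-tailed data inflate sandwich SEs above observed-information SEs", {
  p <- ade_parameters(sqrt(0.5), sqrt(0.2), sqrt(0.3), phenotypes = "X")
  d <- simulate_twin_pairs(p, simulation_design(1500, 1500, seed = 27))
  # elliptical t_5 scaling preserves the covariance structure shape but adds
  # kurtosis, the situation robust SEs exist for
  withr::with_seed(28, {
    w <- sqrt(5 / stats::rchisq(nrow(d), df = 5))
  })
  d$X_1 <- d$X_1 * w; d$X_2 <- d$X_2 * w
  fit <- fit_ade(d, ade_model_spec("X"), fit_options(n_starts = 2))
  se <- robust_se(fit, d)
  var_rows <- grepl("^[ade]\\[", se$term)
  expect_gt(mean(se$se_sandwich[var_rows] / se$se_observed[var_rows]), 1.1)
})

test_that("two runs with the same options are identical and multi-start keeps the best", {
  p <- toy_params2()
  dat <- toy_dataset(150, 150, p, seed = 29)
  spec <- ade_model_spec(c("MHYP", "TINATT"))
  f1 <- fit_ade(dat, spec, fit_options(n_starts = 3, seed = 5))
  f2 <- fit_ade(dat, spec, fit_options(n_starts = 3, seed = 5))
  expect_identical(f1$par, f2$par)
  expect_equal(nrow(f1$starts), 3)
  expect_equal(f1$loglik, max(f1$starts$loglik))
})
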