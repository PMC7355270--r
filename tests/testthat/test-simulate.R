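test_that("simulation is reproducible and honours the design structure", {
  p <- toy_params2(rater = TRUE)
  des <- simulation_design(300, 500, prop_opposite_sex_dz = 0.5, seed = 42)
  d1 <- simulate_twin_pairs(p, des)
  d2 <- simulate_twin_pairs(p, des)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 800)
  expect_equal(sum(d1$zygosity == "MZ"), 300)
  # MZ pairs are sex-concordant; opposite-sex only among DZ
  expect_true(all(d1$sex_1[d1$zygosity == "MZ"] == d1$sex_2[d1$zygosity == "MZ"]))
  expect_gt(sum(d1$sex_1 != d1$sex_2), 0)
  d3 <- simulate_twin_pairs(p, simulation_design(300, 500, seed = 43))
  expect_false(identical(d1$MHYP_1, d3$MHYP_1))
})

test_that("pure-A parameters give MZ within-phenotype correlation near one", {
  p <- ade_parameters(diag(2), diag(2) * 0, diag(2) * 1e-3,
                      phenotypes = c("X", "Y"))
  d <- simulate_twin_pairs(p, simulation_design(4000, 0, seed = 2))
  expect_gt(cor(d$X_1, d$X_2), 0.999)
})

test_that("empirical twin correlations match the closed-form ADE expectations at large n", {
  # magnitudes like the strongest published phenotype (broad-sense .912)
  p <- ade_parameters(lower_tri(c(sqrt(.687), .3, sqrt(.609 - .09)), 2),
                      lower_tri(c(sqrt(.226), .2, sqrt(.234 - .04)), 2),
                      lower_tri(c(sqrt(.088), .05, sqrt(.156 - .0025)), 2),
                      phenotypes = c("SWAN_H", "SWAN_I"))
  ex <- expected_twin_correlations(p)
  d <- simulate_twin_pairs(p, simulation_design(20000, 20000, seed = 3))
  mz <- d[d$zygosity == "MZ", ]; dz <- d[d$zygosity == "DZ", ]
  for (ph in c("SWAN_H", "SWAN_I")) {
    i <- match(ph, ex$phenotype)
    r_mz <- cor(mz[[paste0(ph, "_1")]], mz[[paste0(ph, "_2")]])
    r_dz <- cor(dz[[paste0(ph, "_1")]], dz[[paste0(ph, "_2")]])
    # MC error of a correlation at n = 20,000 is about 0.007 at r ~ .9
    expect_lt(abs(r_mz - ex$r_mz[i]), 0.02)
    expect_lt(abs(r_dz - ex$r_dz[i]), 0.02)
  }
})

test_that("same-teacher subsample differs from different-teacher exactly by the rater covariance", {
  p <- toy_params2(rater = TRUE)  # loading 0.6 on the teacher phenotype
  d <- simulate_twin_pairs(p, simulation_design(30000, 0,
                                                prop_same_teacher = 0.5, seed = 4))
  same <- d[d$same_teacher, ]; diff <- d[!d$same_teacher, ]
  cx_same <- cov(same$TINATT_1, same$TINATT_2)
  cx_diff <- cov(diff$TINATT_1, diff$TINATT_2)
  expect_lt(abs((cx_same - cx_diff) - 0.6^2), 0.04)  # ~3 MC SEs
  # mother-rated phenotype unaffected by teacher sharing
  expect_lt(abs(cov(same$MHYP_1, same$MHYP_2) - cov(diff$MHYP_1, diff$MHYP_2)),
            0.05)
})

test_that("pooled and cross-twin covariances converge to the model matrices", {
  p <- toy_params2(rater = TRUE)
  n <- 25000
  d <- simulate_twin_pairs(p, simulation_design(n, n, prop_same_teacher = 0.6,
                                                seed = 5))
  comp <- ade_components(p)
  tot <- comp$sigma_a + comp$sigma_d + comp$sigma_e + comp$rater
  Y1 <- as.matrix(d[, c("MHYP_1", "TINATT_1")])
  Y2 <- as.matrix(d[, c("MHYP_2", "TINATT_2")])
  # centered pooled covariance (sexes shift means; remove per-column means)
  pooled <- cov(rbind(Y1, Y2))
  beta_var <- p$beta_sex %o% p$beta_sex * var(c(d$sex_1, d$sex_2))
  expect_lt(max(abs(pooled - beta_var - tot)), 0.03)
  mz <- d$zygosity == "MZ"
  cx_mz <- cov(Y1[mz, ], Y2[mz, ])
  cx_dz <- cov(Y1[!mz, ], Y2[!mz, ])
  st_mz <- mean(d$same_teacher[mz]); st_dz <- mean(d$same_teacher[!mz])
  bv_mz <- p$beta_sex %o% p$beta_sex * cov(d$sex_1[mz], d$sex_2[mz])
  bv_dz <- p$beta_sex %o% p$beta_sex * cov(d$sex_1[!mz], d$sex_2[!mz])
  expect_lt(max(abs(cx_mz - bv_mz - (comp$sigma_a + comp$sigma_d + st_mz * comp$rater))), 0.03)
  expect_lt(max(abs(cx_dz - bv_dz - (0.5 * comp$sigma_a + 0.25 * comp$sigma_d +
                                       st_dz * comp$rater))), 0.03)
})

test_that("raw-scale mapping censors, skews, and passes relative scales through", {
  p <- toy_params2()
  d <- toy_dataset(2500, 2500, p, seed = 6)
  ident <- apply_raw_scale(d, raw_scale_spec("MHYP", "relative-normal"))
  expect_equal(ident$MHYP_1, d$MHYP_1)
  sp <- raw_scale_spec("TINATT", "absolute-censored", inverse_lambda = -3,
                       floor = 0)
  raw <- apply_raw_scale(d, sp)
  x <- c(raw$TINATT_1, raw$TINATT_2)
  expect_true(all(x >= 0))
  skew <- mean((x - mean(x))^3) / sd(x)^3
  expect_gt(skew, 0.5)
  expect_true(attr(raw, "n_clamped")["TINATT"] >= 0)
  # reverse coding negates
  rev <- apply_raw_scale(d, raw_scale_spec("MHYP", "relative-normal",
                                           reverse_coded = TRUE))
  expect_equal(rev$MHYP_1, -d$MHYP_1)
})

test_that("blockwise MCAR missingness matches its probabilities and leaves data untouched at zero", {
  p <- toy_params2()
  des0 <- simulation_design(500, 500, seed = 7,
                            missingness = list(list(phenotypes = "MHYP",
                                                    prob = 0, unit = "twin")))
  d <- simulate_twin_pairs(p, des0)
  expect_identical(impose_missingness(d, des0), d)

  des <- simulation_design(5000, 5000, seed = 8,
                           missingness = list(
                             list(phenotypes = "MHYP", prob = 0.5, unit = "twin"),
                             list(phenotypes = "TINATT", prob = 0.8, unit = "pair")))
  dm <- impose_missingness(simulate_twin_pairs(p, des), des)
  # 99% binomial interval at n = 10,000 twins: 0.5 +/- 0.013
  frac <- mean(is.na(c(dm$MHYP_1, dm$MHYP_2)))
  expect_gt(frac, 0.48); expect_lt(frac, 0.52)
  # pair-level masking: both twins jointly
  expect_equal(is.na(dm$TINATT_1), is.na(dm$TINATT_2))
  # complete-case count collapses roughly as the product of retentions
  cc <- mean(stats::complete.cases(dm[, c("MHYP_1", "MHYP_2", "TINATT_1", "TINATT_2")]))
  expect_lt(cc, 0.08)  # 0.25 * 0.2 = 0.05 expected
  expect_gt(cc, 0.02)
  expect_error(simulation_design(10, 10, missingness =
    list(list(phenotypes = "MHYP", prob = 1.4, unit = "twin"))), "\\[0, 1\\]")
})
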