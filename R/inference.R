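## Nested-model inference: sex-moderation likelihood-ratio tests on the
## univariate model, and LRT/AIC/BIC comparison of fitted models.

## two-group (by sex) univariate ADE engine model with optional equality
## constraints on the A, D, E standard-deviation parameters.  Opposite-sex
## pairs, when present, get sex-specific within-twin variances and a
## cross-twin covariance 0.5 a_m a_f + 0.25 d_m d_f (cross-sex genetic
## correlation one).
sex_two_group_model <- function(phenotype, equal = character(0)) {
  comps <- c("A", "D", "E")
  par_names <- character(0)
  idx <- list()
  nxt <- 1
  for (cm in comps) {
    if (cm %in% equal) {
      idx[[cm]] <- c(m = nxt, f = nxt)
      par_names <- c(par_names, tolower(cm))
      nxt <- nxt + 1
    } else {
      idx[[cm]] <- c(m = nxt, f = nxt + 1)
      par_names <- c(par_names, paste0(tolower(cm), c("_m", "_f")))
      nxt <- nxt + 2
    }
  }
  mu_idx <- c(m = nxt, f = nxt + 1)
  par_names <- c(par_names, "mu_m", "mu_f")
  npar <- nxt + 1

  sig1 <- function(par, sa, sb, zyg) {
    ## sa, sb: sexes of twin 1 and 2 ("m"/"f")
    a <- c(par[idx$A["m"]], par[idx$A["f"]]); names(a) <- c("m", "f")
    d <- c(par[idx$D["m"]], par[idx$D["f"]]); names(d) <- c("m", "f")
    e <- c(par[idx$E["m"]], par[idx$E["f"]]); names(e) <- c("m", "f")
    wa <- if (zyg == "MZ") 1 else 0.5
    wd <- if (zyg == "MZ") 1 else 0.25
    v1 <- a[sa]^2 + d[sa]^2 + e[sa]^2
    v2 <- a[sb]^2 + d[sb]^2 + e[sb]^2
    cx <- wa * a[sa] * a[sb] + wd * d[sa] * d[sb]
    matrix(c(v1, cx, cx, v2), 2)
  }
  sx <- function(s) if (s == 1) "f" else "m"

  list(phenotypes = phenotype, M = 1, npar = npar, par_names = par_names,
       lower = -Inf, upper = Inf, grad = NULL,
       single_zygosity_ok = NULL,
       key_of = function(zyg, st, s1, s2) paste(zyg, s1, s2, sep = "."),
       sigmas = function(par, keys) {
         out <- list()
         for (key in keys) {
           parts <- strsplit(key, ".", fixed = TRUE)[[1]]
           out[[key]] <- sig1(par, sx(as.numeric(parts[2])),
                              sx(as.numeric(parts[3])), parts[1])
         }
         out
       },
       means = function(par, s1, s2) c(par[mu_idx[sx(s1)]], par[mu_idx[sx(s2)]]),
       start = function(prep) {
         v <- var(c(prep$Y), na.rm = TRUE)
         if (!is.finite(v) || v <= 0) v <- 1
         s <- sqrt(v / 3)
         par <- numeric(npar)
         for (cm in comps) par[idx[[cm]]] <- s
         par[mu_idx] <- mean(prep$Y, na.rm = TRUE)
         par
       },
       ## sign conventions must preserve the likelihood: with opposite-sex
       ## pairs the cross-sex product a_m * a_f matters, so the male/female
       ## pair is flipped jointly; a shared parameter only enters squared
       canonicalize = function(par) {
         for (cm in comps) {
           i <- unique(idx[[cm]])
           if (length(i) == 1) par[i] <- abs(par[i])
           else if (all(par[i] < 0)) par[i] <- -par[i]
         }
         par
       },
       build_estimates = function(par) setNames(par, par_names),
       idx = idx, mu_idx = mu_idx)
}

#' Likelihood-ratio tests for sex moderation of variance components
#'
#' Fits a two-group (boys/girls) univariate ADE model to one phenotype with
#' all of A, D, E free over sex (free model) versus equated (null model), and
#' additionally each component equated on its own (1-df tests).  Sex-specific
#' means are estimated in every model, so the tests concern the variance
#' components only.  By default opposite-sex pairs are excluded from all
#' fits, which keeps the models strictly nested; with
#' `include_opposite_sex = TRUE` they enter every model, with sex-specific
#' within-twin structure and cross-sex genetic correlation one under the free
#' model.
#'
#' @param data Wide twin tibble.
#' @param phenotype Phenotype label to test.
#' @param include_opposite_sex Include opposite-sex DZ pairs in the fits?
#' @param component_tests Also run the three 1-df tests (each component
#'   equated on its own)?  Skipping them saves three fits per call.
#' @param options [fit_options()] for the underlying fits.
#' @return A list of class `sex_moderation_test`: `table` (tibble with one row
#'   per test: `test`, `statistic`, `df`, `p_value`), `loglik_free`,
#'   `n_pairs` and the fitted models.
#' @export
lrt_sex_moderation <- function(data, phenotype,
                               include_opposite_sex = FALSE,
                               component_tests = TRUE,
                               options = fit_options(n_starts = 2)) {
  cols <- paste0(phenotype, c("_1", "_2"))
  assert_that(all(cols %in% names(data)), "phenotype not present in data")
  same_sex <- data$sex_1 == data$sex_2
  d <- if (include_opposite_sex) data else data[same_sex, ]
  for (s in 0:1) {
    n_s <- sum(d$sex_1 == s & d$sex_2 == s)
    if (n_s < 20)
      warning(sprintf("fewer than 20 %s pairs (%d); test computed anyway",
                      if (s == 1) "female" else "male", n_s), call. = FALSE)
  }
  fit_one <- function(equal) fiml_fit(d, sex_two_group_model(phenotype, equal),
                                      options, model_type = "sex_two_group")
  free <- fit_one(character(0))
  equated <- fit_one(c("A", "D", "E"))
  comp_fits <- if (component_tests)
    lapply(setNames(c("A", "D", "E"), c("A", "D", "E")), fit_one)
  lrt_row <- function(nm, null_fit, df) {
    stat <- max(0, 2 * (free$loglik - null_fit$loglik))
    tibble(test = nm, statistic = stat, df = df,
           p_value = if (df > 0) pchisq(stat, df, lower.tail = FALSE) else 1)
  }
  table <- lrt_row("joint", equated, 3)
  if (component_tests)
    table <- bind_rows(table,
                       lrt_row("A", comp_fits$A, 1),
                       lrt_row("D", comp_fits$D, 1),
                       lrt_row("E", comp_fits$E, 1))
  structure(list(table = table, loglik_free = free$loglik,
                 n_pairs = free$n_pairs_used,
                 fits = c(list(free = free, equated = equated), comp_fits)),
            class = "sex_moderation_test")
}

#' @export
print.sex_moderation_test <- function(x, ...) {
  cat(sprintf("Sex-moderation LRTs (%d pairs)\n", x$n_pairs))
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' Compare two fitted twin models
#'
#' Likelihood-ratio test (degrees of freedom from the difference in parameter
#' counts) plus AIC and BIC (BIC sample size = number of pairs).  Both fits
#' must be to the same dataset.
#'
#' @param fit_a,fit_b `twin_fit` objects on the same data; conventionally
#'   `fit_a` is the larger (alternative) model.
#' @param nested Are the models nested?  When `FALSE` only the information
#'   criteria are meaningful and the p-value is omitted.
#' @return A list of class `model_comparison`: `table` (per-model loglik,
#'   npar, AIC, BIC) and `lrt` (statistic, df, p_value).
#' @export
compare_models <- function(fit_a, fit_b, nested = TRUE) {
  assert_that(inherits(fit_a, "twin_fit") && inherits(fit_b, "twin_fit"),
              "both arguments must be twin_fit objects")
  assert_that(isTRUE(all.equal(fit_a$checksum, fit_b$checksum)),
              "fits are not to the same dataset")
  n <- fit_a$n_pairs_used
  tab <- tibble(
    model = c(deparse(substitute(fit_a)), deparse(substitute(fit_b))),
    loglik = c(fit_a$loglik, fit_b$loglik),
    npar = c(fit_a$npar, fit_b$npar),
    aic = -2 * c(fit_a$loglik, fit_b$loglik) + 2 * c(fit_a$npar, fit_b$npar),
    bic = -2 * c(fit_a$loglik, fit_b$loglik) +
      log(n) * c(fit_a$npar, fit_b$npar))
  df <- abs(fit_a$npar - fit_b$npar)
  stat <- max(0, 2 * abs(fit_a$loglik - fit_b$loglik))
  lrt <- list(statistic = stat, df = df,
              p_value = if (!nested) NA_real_
                        else if (df > 0) pchisq(stat, df, lower.tail = FALSE)
                        else 1)
  structure(list(table = tab, lrt = lrt, nested = nested),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  print(as.data.frame(x$table), digits = 5)
  if (x$nested)
    cat(sprintf("LRT: chi^2 = %.3f, df = %d, p = %.4g\n",
                x$lrt$statistic, x$lrt$df, x$lrt$p_value))
  invisible(x)
}
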