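## Preprocessing: subscale scoring with a missing-item rule, the Box-Cox
## power transformation with profile-likelihood estimation of lambda, and
## pooled rescaling to approximately unit variance.

#' Score a subscale from item responses
#'
#' Returns the average item score.  If 20% or more of the items are missing
#' (inclusive threshold) the score is missing.  Otherwise each missing item is
#' imputed with the subject's mean over the observed items of the subscale,
#' which leaves the score equal to the mean of the observed items.
#'
#' @param item_scores Numeric vector of item responses (may contain `NA`).
#' @param n_items Number of items in the subscale; defaults to
#'   `length(item_scores)`.
#' @return The subscale score, or `NA` when too many items are missing.
#' @examples
#' score_subscale(c(0, 1, 2, 0, 3, NA)) # 1.2
#' score_subscale(c(2, 2, NA, NA, 2))   # NA: 2/5 = 40% missing
#' @export
score_subscale <- function(item_scores, n_items = length(item_scores)) {
  assert_that(length(item_scores) == n_items,
              "item vector length must equal n_items")
  n_miss <- sum(is.na(item_scores))
  if (n_miss / n_items >= 0.2) return(NA_real_)
  mean(item_scores, na.rm = TRUE)
}

#' Box-Cox power transformation
#'
#' Applies the shifted Box-Cox map `((y + 1)^lambda + 1) / lambda` elementwise.
#' The map is strictly increasing in `y` for every `lambda != 0`; at
#' `lambda = 0` the natural-log limit `log(y + 1)` is used (with a message).
#' The `+ 1 / lambda` offset is an affine shift relative to the textbook form
#' `((y + 1)^lambda - 1) / lambda`, so all covariances, correlations and
#' variance components are unaffected by the choice between the two.
#'
#' @param y Numeric vector with `y > -1` (scores are nonnegative in practice;
#'   the `+ 1` shift inside the map only requires `y + 1 > 0`).
#' @param lambda Transformation exponent.
#' @return Transformed values.
#' @examples
#' boxcox_transform(c(0, 1, 3), lambda = -2)
#' @export
boxcox_transform <- function(y, lambda) {
  assert_that(all(y > -1, na.rm = TRUE), "y must exceed -1")
  assert_that(length(lambda) == 1 && is.finite(lambda), "lambda must be a single number")
  if (lambda == 0) {
    message("lambda = 0: using the natural-log limit log(y + 1)")
    return(log(y + 1))
  }
  ((y + 1)^lambda + 1) / lambda
}

#' Inverse of the Box-Cox transformation
#'
#' Maps a transformed value `z` back to the raw scale,
#' `y = (lambda * z - 1)^(1 / lambda) - 1`.  Values outside the image of the
#' forward map are returned as `NA` (callers such as [apply_raw_scale()] clamp
#' and count them).
#'
#' @param z Numeric vector on the transformed scale.
#' @param lambda Transformation exponent (nonzero).
#' @return Raw-scale values, `NA` where the inverse is undefined.
#' @export
boxcox_inverse <- function(z, lambda) {
  assert_that(lambda != 0, "lambda must be nonzero")
  base <- lambda * z - 1
  out <- rep(NA_real_, length(z))
  ok <- !is.na(base) & base > 0
  out[ok] <- base[ok]^(1 / lambda) - 1
  out[!is.na(base) & base <= 0] <- NA_real_
  out[is.na(z)] <- NA_real_
  ## the inverse must land on the raw scale (y >= -1); y < 0 can arise for
  ## z below the image of y = 0 and is left for the caller's floor
  out
}

boxcox_profile_loglik <- function(lambda, y, logy1_sum) {
  z <- if (lambda == 0) log(y + 1) else ((y + 1)^lambda + 1) / lambda
  n <- length(y)
  s2 <- mean((z - mean(z))^2)
  -n / 2 * (log(2 * pi) + log(s2) + 1) + (lambda - 1) * logy1_sum
}

#' Estimate the Box-Cox exponent by profile maximum likelihood
#'
#' Finds the `lambda` maximizing the normal profile log-likelihood of the
#' transformed data (including the Jacobian term `(lambda - 1) * sum(log(y + 1))`)
#' by continuous optimization over a box, `[-6, 3]` by default.
#'
#' @param y Numeric vector with `y > -1` and at least 10 non-missing values.
#' @param lower,upper Search interval for `lambda`.
#' @param phenotype Optional label used in error messages.
#' @return An object of class `boxcox_result`: a list with `lambda`,
#'   `loglik_at_lambda`, `scale_factor` (filled by [standardize_scale()]),
#'   and `reverse_coded`.
#' @examples
#' set.seed(1)
#' estimate_lambda(exp(rnorm(500)) - 1)$lambda # near 0
#' @export
estimate_lambda <- function(y, lower = -6, upper = 3, phenotype = NULL) {
  y <- y[!is.na(y)]
  assert_that(length(y) >= 10, "need at least 10 non-missing values")
  assert_that(all(y > -1), "y must exceed -1")
  if (var(y) == 0)
    stop_twinade(sprintf("degenerate input (zero variance)%s",
                         if (is.null(phenotype)) "" else paste0(" for ", phenotype)))
  logy1_sum <- sum(log(y + 1))
  opt <- optimize(boxcox_profile_loglik, c(lower, upper), y = y,
                  logy1_sum = logy1_sum, maximum = TRUE, tol = 1e-7)
  ## optimize() assumes unimodality; guard with a coarse grid and re-polish
  ## from the best grid point if the golden-section result is beaten
  grid <- seq(lower, upper, by = 0.25)
  gl <- vapply(grid, boxcox_profile_loglik, numeric(1), y = y, logy1_sum = logy1_sum)
  if (max(gl) > opt$objective + 1e-8) {
    g0 <- grid[which.max(gl)]
    opt <- optimize(boxcox_profile_loglik,
                    c(max(lower, g0 - 0.3), min(upper, g0 + 0.3)),
                    y = y, logy1_sum = logy1_sum, maximum = TRUE, tol = 1e-7)
  }
  structure(list(lambda = opt$maximum, loglik_at_lambda = opt$objective,
                 scale_factor = NA_real_, reverse_coded = FALSE,
                 phenotype = phenotype),
            class = "boxcox_result")
}

#' @export
print.boxcox_result <- function(x, ...) {
  cat(sprintf("Box-Cox: lambda = %.3f (profile log-lik %.2f)%s\n", x$lambda,
              x$loglik_at_lambda,
              if (is.na(x$scale_factor)) ""
              else sprintf(", scale factor %.4f", x$scale_factor)))
  invisible(x)
}

#' Rescale phenotypes to unit pooled variance
#'
#' Divides each phenotype's values (both twins, all zygosities pooled) by the
#' pooled standard deviation, so that the pooled variance is 1 while group
#' (sex, zygosity, twin) variance differences are retained.
#'
#' @param data Wide twin tibble (see [simulate_twin_pairs()] for the layout).
#' @param phenotypes Character vector of phenotype labels; defaults to all
#'   phenotypes found in `data`.
#' @return `data` with the phenotype columns rescaled; the named vector of
#'   scale factors (the divisors) is attached as attribute `"scale_factors"`.
#' @export
standardize_scale <- function(data, phenotypes = NULL) {
  phenotypes <- phenotypes %||% detect_phenotypes(data)
  factors <- setNames(numeric(length(phenotypes)), phenotypes)
  for (ph in phenotypes) {
    cols <- paste0(ph, c("_1", "_2"))
    pooled <- unlist(data[cols], use.names = FALSE)
    s <- sd(pooled, na.rm = TRUE)
    if (!is.finite(s) || s == 0)
      stop_twinade(sprintf("zero pooled variance for %s", ph))
    data[cols] <- data[cols] / s
    factors[ph] <- s
  }
  attr(data, "scale_factors") <- factors
  data
}

## phenotype labels from the <ph>_1 / <ph>_2 column convention
detect_phenotypes <- function(data) {
  nm <- names(data)
  ph1 <- sub("_1$", "", nm[grepl("_1$", nm) & !nm %in% c("sex_1", "sex_2")])
  ph1 <- setdiff(ph1, c("sex", "pair_id", "zygosity", "same_teacher"))
  ph <- ph1[paste0(ph1, "_2") %in% nm]
  assert_that(length(ph) > 0, "no phenotype column pairs (<name>_1 / <name>_2) found")
  ph
}
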