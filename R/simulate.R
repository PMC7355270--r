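## Synthetic twin-pair generator: the ADE + rater model run forward, plus the
## inverse Box-Cox raw-scale map and blockwise MCAR missingness, so every
## downstream stage is testable without access to registry data.

#' Simulation design for a twin study
#'
#' @param n_mz_pairs,n_dz_pairs Numbers of MZ and DZ pairs.
#' @param prop_female Probability that a twin is female (MZ pairs and same-sex
#'   DZ pairs are concordant for sex).
#' @param prop_opposite_sex_dz Fraction of DZ pairs of opposite sex.
#' @param prop_same_teacher Fraction of pairs sharing a teacher (relevant to
#'   teacher-rated phenotypes; with teacher-block missingness this becomes the
#'   fraction among teacher-rated pairs).
#' @param missingness List of blocks, each a list with elements `phenotypes`
#'   (character vector), `prob` (missing probability in `[0, 1]`) and `unit`
#'   (`"twin"`: each twin's block masked independently; `"pair"`: both twins
#'   jointly).  `NULL` for complete data.
#' @param seed Integer seed; every simulation drawn from the design is
#'   reproducible under it.
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(n_mz_pairs, n_dz_pairs,
                              prop_female = 0.52,
                              prop_opposite_sex_dz = 0.48,
                              prop_same_teacher = 0.572,
                              missingness = NULL,
                              seed = 1L) {
  assert_that(n_mz_pairs >= 0 && n_dz_pairs >= 0, "pair counts must be >= 0")
  fr <- c(prop_female, prop_opposite_sex_dz, prop_same_teacher)
  assert_that(all(fr >= 0 & fr <= 1), "all fractions must lie in [0, 1]")
  if (!is.null(missingness)) {
    for (b in missingness) {
      assert_that(is.list(b) && !is.null(b$phenotypes) && !is.null(b$prob),
                  "each missingness block needs `phenotypes` and `prob`")
      assert_that(b$prob >= 0 && b$prob <= 1,
                  "missingness probabilities must lie in [0, 1]")
      assert_that((b$unit %||% "twin") %in% c("twin", "pair"),
                  "missingness unit must be 'twin' or 'pair'")
    }
  }
  structure(list(n_mz_pairs = as.integer(n_mz_pairs),
                 n_dz_pairs = as.integer(n_dz_pairs),
                 prop_female = prop_female,
                 prop_opposite_sex_dz = prop_opposite_sex_dz,
                 prop_same_teacher = prop_same_teacher,
                 missingness = missingness,
                 seed = as.integer(seed)),
            class = "simulation_design")
}

#' Simulate twin-pair phenotype data from an ADE model
#'
#' Draws, for each pair, the `2M` phenotype vector from a multivariate normal
#' whose mean comes from the sex coefficients and whose covariance is
#' [build_group_cov()] for the pair's zygosity and teacher-sharing status.
#'
#' @param params An [ade_parameters()] object.
#' @param design A [simulation_design()].
#' @return A wide tibble with one row per pair: `pair_id`, `zygosity`,
#'   `sex_1`, `sex_2` (0 = boy, 1 = girl), `same_teacher`, and columns
#'   `<phenotype>_1`, `<phenotype>_2`.
#' @examples
#' p <- ade_parameters(diag(2) * 0.8, diag(2) * 0.4, diag(2) * 0.45,
#'   phenotypes = c("HYP", "INATT"))
#' simulate_twin_pairs(p, simulation_design(100, 100, seed = 7))
#' @export
simulate_twin_pairs <- function(params, design) {
  assert_that(inherits(params, "ade_parameters"), "params must be ade_parameters")
  assert_that(inherits(design, "simulation_design"),
              "design must be a simulation_design")
  withr::local_seed(design$seed)
  M <- length(params$phenotypes)
  n <- design$n_mz_pairs + design$n_dz_pairs
  zygosity <- rep(c("MZ", "DZ"), c(design$n_mz_pairs, design$n_dz_pairs))
  sex1 <- rbinom(n, 1, design$prop_female)
  os <- zygosity == "DZ" & runif(n) < design$prop_opposite_sex_dz
  sex2 <- ifelse(os, 1 - sex1, sex1)
  same_teacher <- runif(n) < design$prop_same_teacher
  Y <- matrix(NA_real_, n, 2 * M)
  for (z in c("MZ", "DZ")) for (s in c(TRUE, FALSE)) {
    i <- which(zygosity == z & same_teacher == s)
    if (!length(i)) next
    U <- chol(build_group_cov(params, z, s)$sigma)
    Y[i, ] <- matrix(rnorm(length(i) * 2 * M), length(i)) %*% U
  }
  Y <- Y + cbind(matrix(params$intercepts, n, M, byrow = TRUE) +
                   outer(sex1, params$beta_sex),
                 matrix(params$intercepts, n, M, byrow = TRUE) +
                   outer(sex2, params$beta_sex))
  colnames(Y) <- c(paste0(params$phenotypes, "_1"), paste0(params$phenotypes, "_2"))
  out <- tibble(pair_id = seq_len(n), zygosity = zygosity,
                sex_1 = sex1, sex_2 = sex2, same_teacher = same_teacher)
  dplyr::bind_cols(out, as_tibble(Y))
}

#' Raw-scale specification for one phenotype
#'
#' Describes how a phenotype's latent (transformed-scale) values map back to a
#' realistic raw scale: relative-judgement instruments stay near-normal
#' (identity pass-through) while absolute-judgement symptom counts are mapped
#' through the inverse Box-Cox transform and left-censored at a floor,
#' producing the positive skew typical of such scales.
#'
#' @param phenotype Phenotype label.
#' @param kind `"relative-normal"` (identity) or `"absolute-censored"`.
#' @param inverse_lambda Box-Cox exponent of the forward transform whose
#'   inverse generates the raw scale; must be nonzero for absolute-censored.
#' @param floor Left-censoring point of the raw scale (finite for
#'   absolute-censored).
#' @param reverse_coded Flag: negate values (after centering conventions are
#'   the caller's concern), as for instruments where high scores are favorable.
#' @param center,scale Affine placement of the latent values inside the image
#'   of the forward map before inversion; defaults place a standard-normal
#'   latent comfortably inside the image of `y >= floor`.
#' @return An object of class `raw_scale_spec`.
#' @export
raw_scale_spec <- function(phenotype,
                           kind = c("relative-normal", "absolute-censored"),
                           inverse_lambda = -2, floor = 0,
                           reverse_coded = FALSE,
                           center = NULL, scale = NULL) {
  kind <- match.arg(kind)
  if (kind == "absolute-censored") {
    assert_that(is.finite(floor), "absolute-censored requires a finite floor")
    assert_that(inverse_lambda != 0, "inverse_lambda must be nonzero")
  }
  structure(list(phenotype = phenotype, kind = kind,
                 inverse_lambda = inverse_lambda, floor = floor,
                 reverse_coded = reverse_coded,
                 center = center %||% 1.5 / inverse_lambda,
                 scale = scale %||% 0.12 / abs(inverse_lambda)),
            class = "raw_scale_spec")
}

#' Map simulated transformed-scale data to raw scales
#'
#' For each `absolute-censored` spec the phenotype's values are placed
#' affinely inside the image of the forward Box-Cox map, inverted through
#' [boxcox_inverse()], and floored at the censoring point; values outside the
#' image are clamped to the floor and counted.  `relative-normal` phenotypes
#' pass through unchanged.  Reverse-coded phenotypes are negated.
#'
#' @param data Wide twin tibble.
#' @param specs A `raw_scale_spec` or list of them.
#' @return `data` with the raw-scale values; the per-phenotype count of
#'   clamped values is attached as attribute `"n_clamped"`.
#' @export
apply_raw_scale <- function(data, specs) {
  if (inherits(specs, "raw_scale_spec")) specs <- list(specs)
  clamped <- setNames(integer(length(specs)),
                      vapply(specs, `[[`, "", "phenotype"))
  for (sp in specs) {
    cols <- paste0(sp$phenotype, c("_1", "_2"))
    assert_that(all(cols %in% names(data)),
                sprintf("phenotype %s not present", sp$phenotype))
    if (sp$kind == "absolute-censored") {
      nc <- 0L
      for (cl in cols) {
        z <- sp$center + sp$scale * data[[cl]]
        y <- boxcox_inverse(z, sp$inverse_lambda)
        bad <- !is.na(data[[cl]]) & (is.na(y) | y < sp$floor)
        nc <- nc + sum(bad)
        y[bad] <- sp$floor
        data[[cl]] <- y
      }
      clamped[sp$phenotype] <- nc
    }
    if (isTRUE(sp$reverse_coded)) for (cl in cols) data[[cl]] <- -data[[cl]]
  }
  attr(data, "n_clamped") <- clamped
  data
}

#' Mask values blockwise completely at random
#'
#' Applies the design's blockwise missing-completely-at-random masking: each
#' block of phenotypes is removed jointly, per twin or per pair, with the
#' block's probability.  Reproducible under the design seed (offset so the
#' masks are independent of the simulated values).
#'
#' @param data Wide twin tibble.
#' @param design A [simulation_design()] whose `missingness` is used.
#' @return `data` with masked entries set to `NA`.
#' @export
impose_missingness <- function(data, design) {
  assert_that(inherits(design, "simulation_design"),
              "design must be a simulation_design")
  if (is.null(design$missingness)) return(data)
  withr::local_seed(design$seed + 1000003L)
  n <- nrow(data)
  for (b in design$missingness) {
    unit <- b$unit %||% "twin"
    cols1 <- paste0(b$phenotypes, "_1")
    cols2 <- paste0(b$phenotypes, "_2")
    assert_that(all(c(cols1, cols2) %in% names(data)),
                "missingness block names a phenotype not in the data")
    if (unit == "pair") {
      drop <- runif(n) < b$prob
      data[drop, c(cols1, cols2)] <- NA_real_
    } else {
      drop1 <- runif(n) < b$prob
      drop2 <- runif(n) < b$prob
      data[drop1, cols1] <- NA_real_
      data[drop2, cols2] <- NA_real_
    }
  }
  data
}
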