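## From fitted parameters to the reported quantities: standardized variance
## components, component correlation matrices, proportions of phenotypic
## covariance attributable to A+D and to E, and model-implied phenotypic
## correlations.  All denominators exclude the rater variance: the reported
## decomposition is "corrected for" the teacher-rater effect, i.e. expressed
## relative to the A+D+E phenotypic variance.

#' Standardized variance components
#'
#' Per phenotype j, with `tot_j` the A+D+E variance (rater variance excluded),
#' returns `a2 = Sigma_A[jj] / tot_j`, similarly `d2` and `e2`, and the
#' broad-sense heritability `h2_broad = a2 + d2`; `a2 + d2 + e2 = 1`.
#'
#' @param x An [ade_parameters()], `twin_fit`, or list with `sigma_a`,
#'   `sigma_d`, `sigma_e` matrices.
#' @return A tibble with columns `phenotype`, `a2`, `d2`, `e2`, `h2_broad`.
#' @export
standardized_components <- function(x) {
  comp <- ade_components(x)
  tot <- diag(comp$sigma_a) + diag(comp$sigma_d) + diag(comp$sigma_e)
  if (any(tot <= 0))
    stop_twinade(sprintf("zero total variance for %s",
                         paste(comp$phenotypes[tot <= 0], collapse = ", ")))
  tibble(phenotype = comp$phenotypes,
         a2 = unname(diag(comp$sigma_a) / tot),
         d2 = unname(diag(comp$sigma_d) / tot),
         e2 = unname(diag(comp$sigma_e) / tot),
         h2_broad = unname((diag(comp$sigma_a) + diag(comp$sigma_d)) / tot))
}

cov2cor_safe <- function(S) {
  v <- diag(S)
  out <- matrix(NA_real_, nrow(S), ncol(S), dimnames = dimnames(S))
  ok <- v > 0
  out[ok, ok] <- S[ok, ok] / sqrt(v[ok] %o% v[ok])
  diag(out)[ok] <- 1
  out
}

#' Component correlation matrices
#'
#' Correlations of the latent A, D, combined A+D, and E components:
#' `corr_X[i, j] = Sigma_X[i, j] / sqrt(Sigma_X[i, i] Sigma_X[j, j])`.
#' Entries involving a phenotype whose component variance is zero are
#' reported as `NA` (undefined), never as 0.
#'
#' @inheritParams standardized_components
#' @return A list with matrices `corr_a`, `corr_d`, `corr_ad`, `corr_e`.
#' @export
component_correlations <- function(x) {
  comp <- ade_components(x)
  list(corr_a = cov2cor_safe(comp$sigma_a),
       corr_d = cov2cor_safe(comp$sigma_d),
       corr_ad = cov2cor_safe(comp$sigma_a + comp$sigma_d),
       corr_e = cov2cor_safe(comp$sigma_e))
}

#' Proportions of phenotypic covariance attributable to A+D and to E
#'
#' Elementwise `(Sigma_A + Sigma_D) / (Sigma_A + Sigma_D + Sigma_E)` and
#' `Sigma_E / (Sigma_A + Sigma_D + Sigma_E)`.  The diagonal of `prop_ad` is
#' the broad-sense heritability.  Off-diagonal entries where the total
#' covariance is zero are reported as `NA`.
#'
#' @inheritParams standardized_components
#' @return A list with matrices `prop_ad` and `prop_e`
#'   (`prop_ad + prop_e = 1` wherever defined).
#' @export
covariance_proportions <- function(x) {
  comp <- ade_components(x)
  gen <- comp$sigma_a + comp$sigma_d
  tot <- gen + comp$sigma_e
  prop_ad <- gen / tot
  prop_ad[tot == 0] <- NA_real_
  prop_e <- comp$sigma_e / tot
  prop_e[tot == 0] <- NA_real_
  list(prop_ad = prop_ad, prop_e = prop_e)
}

#' Model-implied phenotypic correlations
#'
#' Two algebraically identical routes: `"standardized"` composes the
#' standardized quantities,
#' `r_ph[i,j] = sqrt(h2_i) corr_AD[i,j] sqrt(h2_j) + sqrt(e2_i) corr_E[i,j] sqrt(e2_j)`,
#' while `"direct"` normalizes `Sigma_A + Sigma_D + Sigma_E` to a correlation
#' matrix.  Both are implemented; they agree to numerical precision and are
#' cross-checked in the package tests.
#'
#' @inheritParams standardized_components
#' @param method `"standardized"` or `"direct"`.
#' @return An `M x M` correlation matrix.
#' @export
implied_phenotypic_correlations <- function(x, method = c("standardized", "direct")) {
  method <- match.arg(method)
  comp <- ade_components(x)
  if (method == "direct")
    return(cov2cor_safe(comp$sigma_a + comp$sigma_d + comp$sigma_e))
  sc <- standardized_components(comp)
  cc <- component_correlations(comp)
  g_ad <- cc$corr_ad; g_ad[is.na(g_ad)] <- 0
  g_e <- cc$corr_e; g_e[is.na(g_e)] <- 0
  out <- sqrt(sc$h2_broad %o% sc$h2_broad) * g_ad +
    sqrt(sc$e2 %o% sc$e2) * g_e
  dimnames(out) <- list(comp$phenotypes, comp$phenotypes)
  out
}

#' Implied correlations and genetic shares from standardized inputs
#'
#' Reconstructs the model-implied phenotypic correlation matrix and the
#' proportions of phenotypic covariance attributable to A+D directly from
#' standardized quantities (broad-sense heritabilities, unshared-environment
#' shares, and the A+D and E correlation matrices) — the derivation chain used
#' to rebuild a reported correlation table from reported components.
#'
#' @param h2 Vector of broad-sense heritabilities.
#' @param e2 Vector of unshared-environment variance shares.
#' @param corr_ad A+D correlation matrix.
#' @param corr_e E correlation matrix.
#' @return A list with `implied` (phenotypic correlation matrix), `genetic`
#'   (the genetic path `sqrt(h2_i) corr_AD sqrt(h2_j)`), and `prop_ad`
#'   (`genetic / implied`, diagonal = `h2`).
#' @export
implied_correlations_from_standardized <- function(h2, e2, corr_ad, corr_e) {
  assert_that(length(h2) == length(e2) &&
                all(dim(corr_ad) == length(h2)) && all(dim(corr_e) == length(h2)),
              "dimension mismatch among inputs")
  genetic <- sqrt(h2 %o% h2) * corr_ad
  implied <- genetic + sqrt(e2 %o% e2) * corr_e
  prop_ad <- genetic / implied
  diag(prop_ad) <- h2
  dimnames(genetic) <- dimnames(implied) <- dimnames(prop_ad) <- dimnames(corr_ad)
  list(implied = implied, genetic = genetic, prop_ad = prop_ad)
}

#' Bivariate decomposition of one phenotypic correlation
#'
#' The narrative for a pair of phenotypes: both broad-sense heritabilities,
#' the A+D and E correlations, each path product, the implied phenotypic
#' correlation, and the genetic share of it.
#'
#' @inheritParams standardized_components
#' @param i,j Phenotype labels or indices (`i != j`).
#' @return A list of class `bivariate_decomposition`.
#' @export
bivariate_decomposition <- function(x, i, j) {
  comp <- ade_components(x)
  to_idx <- function(k) if (is.character(k)) match(k, comp$phenotypes) else as.integer(k)
  i <- to_idx(i); j <- to_idx(j)
  assert_that(!anyNA(c(i, j)), "unknown phenotype")
  assert_that(i != j, "i and j must name two different phenotypes")
  sc <- standardized_components(comp)
  cc <- component_correlations(comp)
  genetic_path <- sqrt(sc$h2_broad[i] * sc$h2_broad[j]) * cc$corr_ad[i, j]
  env_path <- sqrt(sc$e2[i] * sc$e2[j]) * cc$corr_e[i, j]
  r_ph <- genetic_path + env_path
  structure(list(
    phenotypes = comp$phenotypes[c(i, j)],
    h2_broad = sc$h2_broad[c(i, j)],
    e2 = sc$e2[c(i, j)],
    corr_ad = cc$corr_ad[i, j], corr_e = cc$corr_e[i, j],
    genetic_path = genetic_path, env_path = env_path,
    implied_correlation = r_ph,
    genetic_share = genetic_path / r_ph),
    class = "bivariate_decomposition")
}

#' @export
print.bivariate_decomposition <- function(x, ...) {
  cat(sprintf("Bivariate decomposition: %s vs %s\n", x$phenotypes[1], x$phenotypes[2]))
  cat(sprintf("  h2_broad        : %.3f, %.3f\n", x$h2_broad[1], x$h2_broad[2]))
  cat(sprintf("  e2              : %.3f, %.3f\n", x$e2[1], x$e2[2]))
  cat(sprintf("  A+D correlation : %.3f   E correlation: %.3f\n", x$corr_ad, x$corr_e))
  cat(sprintf("  r_ph = %.3f (genetic path %.3f + environmental path %.3f)\n",
              x$implied_correlation, x$genetic_path, x$env_path))
  cat(sprintf("  genetic share of r_ph: %.3f\n", x$genetic_share))
  invisible(x)
}

#' Full decomposition tables for a fitted model
#'
#' Bundles [standardized_components()], [component_correlations()],
#' [covariance_proportions()] and [implied_phenotypic_correlations()] into one
#' object.
#'
#' @inheritParams standardized_components
#' @return An object of class `ade_decomposition`.
#' @export
decompose_ade <- function(x) {
  comp <- ade_components(x)
  structure(c(list(components = standardized_components(comp)),
              component_correlations(comp),
              covariance_proportions(comp),
              list(implied_pheno_corr = implied_phenotypic_correlations(comp),
                   phenotypes = comp$phenotypes)),
            class = "ade_decomposition")
}

#' @export
print.ade_decomposition <- function(x, digits = 3, ...) {
  cat("Standardized variance components:\n")
  print(as.data.frame(x$components), digits = digits)
  cat("\nA+D correlations (lower) / proportion of covariance from A+D (upper):\n")
  m <- x$corr_ad
  m[upper.tri(m)] <- x$prop_ad[upper.tri(m)]
  diag(m) <- x$components$h2_broad
  print(round(m, digits))
  cat("\nModel-implied phenotypic correlations:\n")
  print(round(x$implied_pheno_corr, digits))
  invisible(x)
}
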