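## Published reference estimates from a large Netherlands Twin Register study
## of four inattention (I) and four hyperactivity (H) measures at age 12
## (maternal SWAN and CPRS ratings; teacher CTRS and TRF ratings), stored as
## plain CSVs under inst/extdata.  They serve two purposes: reconstructing
## the study's derived tables (implied phenotypic correlations, covariance
## proportions) from its printed components, and parameterizing the synthetic
## generator at realistic magnitudes.

ref_path <- function(file) {
  p <- system.file("extdata", file, package = "twinade")
  if (!nzchar(p)) p <- file.path("inst", "extdata", file)
  p
}

ref_matrix <- function(long, phenotypes) {
  M <- length(phenotypes)
  out <- diag(M)
  dimnames(out) <- list(phenotypes, phenotypes)
  i <- match(long$row, phenotypes); j <- match(long$col, phenotypes)
  out[cbind(i, j)] <- long$value
  out[cbind(j, i)] <- long$value
  out
}

#' Published reference estimates for the eight ADHD-related phenotypes
#'
#' Point estimates from a published multivariate twin analysis of four
#' inattention and four hyperactivity measures (SWAN and CPRS rated by
#' mothers; TRF and CTRS rated by teachers) in 12-year-old Dutch twins:
#' standardized variance components, component correlation matrices, the
#' proportions of phenotypic covariance attributable to A+D and to E, the
#' model-implied phenotypic correlations, and the univariate results (sex
#' effects, twin correlations, rater variances, Box-Cox exponents).
#'
#' @return A list with elements `components` (tibble), `univariate` (tibble),
#'   `corr_a`, `corr_d`, `corr_ad`, `corr_e`, `prop_ad`, `prop_e`,
#'   `pheno_corr` (named 8 x 8 matrices) and `phenotypes`.
#' @export
reference_estimates <- function() {
  comp <- readr::read_csv(ref_path("reference_variance_components.csv"),
                          show_col_types = FALSE)
  uni <- readr::read_csv(ref_path("reference_univariate.csv"),
                         show_col_types = FALSE)
  corr <- readr::read_csv(ref_path("reference_component_correlations.csv"),
                          show_col_types = FALSE)
  props <- readr::read_csv(ref_path("reference_covariance_proportions.csv"),
                           show_col_types = FALSE)
  phc <- readr::read_csv(ref_path("reference_phenotypic_correlations.csv"),
                         show_col_types = FALSE)
  ph <- comp$phenotype
  pick <- function(df, cm) ref_matrix(df[df$component == cm, ], ph)
  prop_ad <- pick(props, "AD"); diag(prop_ad) <- comp$h2_broad
  prop_e <- pick(props, "E"); diag(prop_e) <- comp$e2
  list(components = comp, univariate = uni,
       corr_a = pick(corr, "A"), corr_d = pick(corr, "D"),
       corr_ad = pick(corr, "AD"), corr_e = pick(corr, "E"),
       prop_ad = prop_ad, prop_e = prop_e,
       pheno_corr = pick(phc, "phenotypic"), phenotypes = ph)
}

## project a symmetric matrix onto the PSD cone by eigenvalue clipping;
## printed 3-decimal correlation matrices can have slightly negative
## eigenvalues
psd_project <- function(S, floor = 1e-6) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  out <- e$vectors %*% diag(pmax(e$values, floor), nrow(S)) %*% t(e$vectors)
  dimnames(out) <- dimnames(S)
  (out + t(out)) / 2
}

lower_chol <- function(S) t(chol(psd_project(S)))

#' ADE parameters at the published reference magnitudes
#'
#' Builds an [ade_parameters()] object whose component covariance matrices
#' reproduce the published standardized variance components and component
#' correlation matrices (total A+D+E variance 1 per phenotype), whose rater
#' loadings reproduce the published univariate rater variance shares
#' (`lambda_j^2 / (1 + lambda_j^2) = r2_j`), and whose sex coefficients are
#' the published values.  Correlation matrices are PSD-projected (eigenvalue
#' clipping at 1e-6) before the Cholesky factorization, since 3-decimal
#' rounding leaves them very slightly indefinite.
#'
#' @param phenotypes Subset of the eight phenotype labels (default all).
#' @return An [ade_parameters()] object.
#' @examples
#' reference_ade_parameters(c("SWAN_H", "CPRS_H", "TRF_H", "CTRS_H"))
#' @export
reference_ade_parameters <- function(phenotypes = NULL) {
  ref <- reference_estimates()
  ph <- phenotypes %||% ref$phenotypes
  assert_that(all(ph %in% ref$phenotypes), "unknown phenotype label")
  i <- match(ph, ref$phenotypes)
  comp <- ref$components[i, ]
  sa <- sqrt(comp$a2 %o% comp$a2) * ref$corr_a[i, i, drop = FALSE]
  sd_ <- sqrt(comp$d2 %o% comp$d2) * ref$corr_d[i, i, drop = FALSE]
  se <- sqrt(comp$e2 %o% comp$e2) * ref$corr_e[i, i, drop = FALSE]
  uni <- ref$univariate[i, ]
  r2 <- ifelse(is.na(uni$rater_r2), 0, uni$rater_r2)
  lam <- sqrt(r2 / (1 - r2))
  ade_parameters(lower_chol(sa), lower_chol(sd_), lower_chol(se),
                 rater_loadings = lam,
                 intercepts = rep(0, length(ph)),
                 beta_sex = uni$beta_sex,
                 phenotypes = ph,
                 teacher_rated = !is.na(uni$rater_r2))
}

#' Registry-like default simulation design
#'
#' A [simulation_design()] emulating the reference study's structure: 620 MZ
#' and 973 DZ pairs, 52% girls, 48% of DZ pairs opposite-sex, 57.2% of pairs
#' sharing a teacher, and blockwise MCAR missingness at registry-like rates
#' (the SWAN block was collected only in sub-projects, so it is missing for
#' 69% of pairs jointly; the other maternal block for 30% of twins; the
#' teacher block for 56% of pairs jointly plus 12% of twins).
#'
#' @param phenotypes Phenotype labels (default: the eight reference
#'   phenotypes).  Missingness blocks are restricted to phenotypes present.
#' @param seed Integer seed.
#' @return A [simulation_design()].
#' @export
reference_design <- function(phenotypes = NULL, seed = 1L) {
  ref_ph <- c("SWAN_H", "CPRS_H", "TRF_H", "CTRS_H",
              "SWAN_I", "CPRS_I", "TRF_I", "CTRS_I")
  ph <- phenotypes %||% ref_ph
  blocks <- list(
    list(phenotypes = intersect(c("SWAN_H", "SWAN_I"), ph), prob = 0.69, unit = "pair"),
    list(phenotypes = intersect(c("CPRS_H", "CPRS_I"), ph), prob = 0.30, unit = "twin"),
    list(phenotypes = intersect(c("TRF_H", "CTRS_H", "TRF_I", "CTRS_I"), ph),
         prob = 0.56, unit = "pair"),
    list(phenotypes = intersect(c("TRF_H", "CTRS_H", "TRF_I", "CTRS_I"), ph),
         prob = 0.12, unit = "twin"))
  blocks <- purrr::keep(blocks, ~ length(.x$phenotypes) > 0)
  simulation_design(n_mz_pairs = 620, n_dz_pairs = 973,
                    prop_female = 0.52, prop_opposite_sex_dz = 0.48,
                    prop_same_teacher = 0.572,
                    missingness = if (length(blocks)) blocks else NULL,
                    seed = seed)
}
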