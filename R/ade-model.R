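## ADE Cholesky model structure: parameters, expected means and covariances.
##
## The model decomposes the M-phenotype covariance into additive genetic (A),
## dominance (D) and unshared environmental (E) parts, each parameterized as
## a Cholesky product Sigma_X = Delta_X %*% t(Delta_X) with Delta_X lower
## triangular, plus an optional rank-one teacher-rater factor on the
## teacher-rated phenotypes.  Cross-twin weights are 1 (MZ) / 0.5 (DZ) for A
## and 1 / 0.25 for D; the rater factor crosses twins with weight 1 when the
## pair shares a teacher and 0 otherwise.

#' ADE Cholesky parameter set
#'
#' Bundles the lower-triangular Cholesky factors of the A, D and E covariance
#' matrices, the teacher-rater factor loadings, and the mean structure
#' (intercepts and sex main effects, sex coded 0 = boys, 1 = girls) for a set
#' of labelled phenotypes.
#'
#' @param delta_a,delta_d,delta_e Lower-triangular `M x M` matrices; the
#'   component covariance matrices are `delta %*% t(delta)`.
#' @param rater_loadings Numeric length-`M` vector of loadings on the single
#'   teacher-rater factor; must be zero at phenotypes not rated by a teacher.
#' @param intercepts Numeric length-`M` vector of phenotype intercepts.
#' @param beta_sex Numeric length-`M` vector of sex main effects (difference
#'   girls minus boys, on the analysis scale).
#' @param phenotypes Character vector of phenotype labels.
#' @param teacher_rated Logical length-`M` vector flagging teacher-rated
#'   phenotypes.
#' @return An object of class `ade_parameters`.
#' @examples
#' p <- ade_parameters(diag(2), diag(2) * 0.5, diag(2) * 0.4,
#'   phenotypes = c("HYP", "INATT"))
#' build_group_cov(p, "DZ")
#' @export
ade_parameters <- function(delta_a, delta_d, delta_e,
                           rater_loadings = NULL,
                           intercepts = NULL,
                           beta_sex = NULL,
                           phenotypes = NULL,
                           teacher_rated = NULL) {
  delta_a <- as.matrix(delta_a); delta_d <- as.matrix(delta_d)
  delta_e <- as.matrix(delta_e)
  M <- nrow(delta_a)
  for (nm in c("delta_a", "delta_d", "delta_e")) {
    d <- get(nm)
    assert_that(nrow(d) == M && ncol(d) == M,
                sprintf("%s must be %d x %d", nm, M, M))
    assert_that(all(abs(d[upper.tri(d)]) < 1e-12),
                sprintf("%s must be lower triangular", nm))
  }
  phenotypes <- phenotypes %||% paste0("P", seq_len(M))
  assert_that(length(phenotypes) == M,
              "dimension mismatch between Cholesky factors and phenotype labels")
  teacher_rated <- teacher_rated %||% rep(FALSE, M)
  rater_loadings <- rater_loadings %||% rep(0, M)
  intercepts <- intercepts %||% rep(0, M)
  beta_sex <- beta_sex %||% rep(0, M)
  assert_that(length(rater_loadings) == M && length(intercepts) == M &&
                length(beta_sex) == M && length(teacher_rated) == M,
              "dimension mismatch between parameters and phenotype labels")
  assert_that(all(rater_loadings[!teacher_rated] == 0),
              "rater loadings must be zero at phenotypes not rated by a teacher")
  structure(
    list(delta_a = delta_a, delta_d = delta_d, delta_e = delta_e,
         rater_loadings = as.numeric(rater_loadings),
         intercepts = as.numeric(intercepts),
         beta_sex = as.numeric(beta_sex),
         phenotypes = as.character(phenotypes),
         teacher_rated = as.logical(teacher_rated)),
    class = "ade_parameters")
}

#' @export
print.ade_parameters <- function(x, ...) {
  cat("ADE Cholesky parameters for", length(x$phenotypes), "phenotypes:",
      paste(x$phenotypes, collapse = ", "), "\n")
  sc <- standardized_components(x)
  print(as.data.frame(sc), digits = 3)
  invisible(x)
}

#' Covariance matrix implied by a Cholesky factor
#'
#' @param delta A lower-triangular matrix.
#' @return The symmetric positive semidefinite matrix `delta %*% t(delta)`.
#' @examples
#' cholesky_cov(matrix(c(1, 0.5, 0, 1), 2, byrow = TRUE))
#' @export
cholesky_cov <- function(delta) {
  delta <- as.matrix(delta)
  assert_that(nrow(delta) == ncol(delta) &&
                all(abs(delta[upper.tri(delta)]) < 1e-12),
              "delta must be square and lower triangular")
  tcrossprod(delta)
}

## component covariance matrices (Sigma_A, Sigma_D, Sigma_E, rater) for a
## parameter set; also the common interface the derivation functions accept.
#' Component covariance matrices of an ADE parameter set
#'
#' @param x An `ade_parameters` object, or a list with elements `sigma_a`,
#'   `sigma_d`, `sigma_e` (and optionally `phenotypes`).
#' @return A list of class `ade_components` with `sigma_a`, `sigma_d`,
#'   `sigma_e`, `rater` (rank-one rater covariance) and `phenotypes`.
#' @export
ade_components <- function(x) {
  if (inherits(x, "ade_components")) return(x)
  if (inherits(x, "twin_fit")) x <- x$estimates
  if (inherits(x, "ade_parameters")) {
    out <- list(sigma_a = cholesky_cov(x$delta_a),
                sigma_d = cholesky_cov(x$delta_d),
                sigma_e = cholesky_cov(x$delta_e),
                rater = tcrossprod(x$rater_loadings),
                phenotypes = x$phenotypes)
  } else if (is.list(x) && all(c("sigma_a", "sigma_d", "sigma_e") %in% names(x))) {
    M <- nrow(as.matrix(x$sigma_a))
    out <- list(sigma_a = as.matrix(x$sigma_a),
                sigma_d = as.matrix(x$sigma_d),
                sigma_e = as.matrix(x$sigma_e),
                rater = x$rater %||% matrix(0, M, M),
                phenotypes = x$phenotypes %||% paste0("P", seq_len(M)))
  } else {
    stop_twinade("cannot interpret `x` as ADE component covariances")
  }
  for (nm in c("sigma_a", "sigma_d", "sigma_e", "rater"))
    dimnames(out[[nm]]) <- list(out$phenotypes, out$phenotypes)
  structure(out, class = "ade_components")
}

cross_twin_cov <- function(comp, zygosity, same_teacher) {
  wa <- if (zygosity == "MZ") 1 else 0.5
  wd <- if (zygosity == "MZ") 1 else 0.25
  cx <- wa * comp$sigma_a + wd * comp$sigma_d
  if (isTRUE(same_teacher)) cx <- cx + comp$rater
  cx
}

#' Expected covariance matrix of a twin-pair group
#'
#' Assembles the `2M x 2M` expected covariance for one group defined by
#' zygosity and teacher-sharing status.  The within-twin block is
#' `Sigma_A + Sigma_D + Sigma_E + lambda lambda'`; the cross-twin block is
#' `Sigma_A + Sigma_D` (MZ) or `0.5 Sigma_A + 0.25 Sigma_D` (DZ), plus the
#' rater covariance `lambda lambda'` if and only if the twins share a teacher.
#'
#' @param params An [ade_parameters()] object.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @param same_teacher Logical; do both twins have the same teacher?
#' @return An object of class `group_covariance`: a list with `sigma`
#'   (`2M x 2M`), `zygosity` and `same_teacher`.  Row/column names are
#'   `<phenotype>_1` and `<phenotype>_2`.
#' @export
build_group_cov <- function(params, zygosity = c("MZ", "DZ"),
                            same_teacher = FALSE) {
  zygosity <- match.arg(zygosity)
  comp <- ade_components(params)
  within <- comp$sigma_a + comp$sigma_d + comp$sigma_e + comp$rater
  ev <- eigen(comp$sigma_e, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12)
    stop_twinade("improper E covariance: Sigma_E must be positive definite")
  cx <- cross_twin_cov(comp, zygosity, same_teacher)
  sigma <- rbind(cbind(within, cx), cbind(t(cx), within))
  nm <- c(paste0(comp$phenotypes, "_1"), paste0(comp$phenotypes, "_2"))
  dimnames(sigma) <- list(nm, nm)
  structure(list(sigma = sigma, zygosity = zygosity,
                 same_teacher = isTRUE(same_teacher),
                 phenotypes = comp$phenotypes),
            class = "group_covariance")
}

#' @export
print.group_covariance <- function(x, ...) {
  cat(sprintf("Expected %s covariance (%s teacher)\n", x$zygosity,
              if (x$same_teacher) "same" else "different"))
  print(round(x$sigma, 3))
  invisible(x)
}

#' Expected mean vector of a twin pair
#'
#' Per-twin mean is `intercepts + beta_sex * sex`, with identical coefficients
#' across twins and zygosities.
#'
#' @param params An [ade_parameters()] object.
#' @param sex1,sex2 Sex of twin 1 and twin 2, coded 0 (boy) or 1 (girl).
#' @return Named numeric vector of length `2M`.
#' @export
build_means <- function(params, sex1, sex2) {
  assert_that(inherits(params, "ade_parameters"), "params must be ade_parameters")
  assert_that(all(c(sex1, sex2) %in% c(0, 1)), "sex must be coded 0 or 1")
  mu <- c(params$intercepts + params$beta_sex * sex1,
          params$intercepts + params$beta_sex * sex2)
  names(mu) <- c(paste0(params$phenotypes, "_1"), paste0(params$phenotypes, "_2"))
  mu
}

#' Model-implied twin correlations for one phenotype
#'
#' Returns the within-phenotype cross-twin correlations implied by the model
#' for MZ and DZ pairs, the quantities behind the classical model-choice
#' heuristic (`r_MZ > 2 r_DZ` points to dominance, hence an ADE rather than
#' ACE model).
#'
#' @inheritParams build_group_cov
#' @param phenotype Phenotype label or index.
#' @param same_teacher Logical; include the rater covariance in the cross-twin
#'   covariance (as for pairs sharing a teacher)?  The rater variance is part
#'   of the within-twin variance either way, as in [build_group_cov()].
#' @return A tibble with columns `phenotype`, `r_mz`, `r_dz` and `ade_favored`
#'   (`r_mz > 2 r_dz`).
#' @export
expected_twin_correlations <- function(params, phenotype = NULL,
                                       same_teacher = FALSE) {
  comp <- ade_components(params)
  j <- if (is.null(phenotype)) seq_along(comp$phenotypes)
       else if (is.character(phenotype)) match(phenotype, comp$phenotypes)
       else as.integer(phenotype)
  assert_that(!anyNA(j), "unknown phenotype")
  within <- comp$sigma_a + comp$sigma_d + comp$sigma_e + comp$rater
  v <- diag(within)[j]
  assert_that(all(v > 0), "zero phenotypic variance")
  r_mz <- diag(cross_twin_cov(comp, "MZ", same_teacher))[j] / v
  r_dz <- diag(cross_twin_cov(comp, "DZ", same_teacher))[j] / v
  tibble(phenotype = comp$phenotypes[j], r_mz = unname(r_mz),
         r_dz = unname(r_dz), ade_favored = unname(r_mz > 2 * r_dz))
}
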