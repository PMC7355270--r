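## Independent pathway (biometric factor) models: per component, two
## correlated common factors (one per symptom dimension) load directly on the
## phenotypes; phenotype residuals carry cross-twin correlations free per
## zygosity.  Also the fallback confirmatory two-factor fit to a component
## correlation matrix by unweighted least squares.

#' Specification of the independent pathway model
#'
#' @param factor_assignment Named character vector mapping each phenotype to
#'   its factor (e.g. `c(SWAN_H = "HYP", ..., CTRS_I = "INATT")`).  Every
#'   phenotype is assigned to exactly one factor.
#' @param components_with_factors Which biometric components get common
#'   factors: a subset of `c("A", "D", "E")`.  Components without factors are
#'   absorbed by the phenotype-specific residual structure.
#' @param sex_effect Estimate a sex main effect per phenotype?
#' @return An object of class `factor_spec`.
#' @export
factor_spec <- function(factor_assignment,
                        components_with_factors = c("A", "D", "E"),
                        sex_effect = TRUE) {
  assert_that(!is.null(names(factor_assignment)) &&
                all(nzchar(names(factor_assignment))),
              "factor_assignment must be a named vector: phenotype -> factor")
  assert_that(all(components_with_factors %in% c("A", "D", "E")),
              "components_with_factors must be a subset of A, D, E")
  structure(list(factor_assignment = factor_assignment,
                 factors = unique(unname(factor_assignment)),
                 components_with_factors = components_with_factors,
                 sex_effect = sex_effect),
            class = "factor_spec")
}

ip_internal_model <- function(spec) {
  ph <- names(spec$factor_assignment)
  M <- length(ph)
  facs <- spec$factors
  nf <- length(facs)
  load_pos <- cbind(seq_len(M), match(spec$factor_assignment, facs))
  comps <- list()
  par_names <- character(0)
  nxt <- 1
  lower <- numeric(0); upper <- numeric(0)
  add_idx <- function(k) { i <- nxt:(nxt + k - 1); nxt <<- nxt + k; i }
  assert_that(nf <= 2, "at most two factors are supported")
  has_phi <- nf == 2
  for (cm in spec$components_with_factors) {
    comps[[paste0("factor_", cm)]] <- list(
      name = cm, type = "factor", par_idx = add_idx(M + has_phi),
      load_pos = load_pos, n_factors = nf, has_phi = has_phi,
      within = 1, cross = cross_weights(cm))
    par_names <- c(par_names, paste0("load_", tolower(cm), "_", ph),
                   if (has_phi) paste0("phi_", tolower(cm)))
    lower <- c(lower, rep(-Inf, M), if (has_phi) -0.999)
    upper <- c(upper, rep(Inf, M), if (has_phi) 0.999)
  }
  ## phenotype-specific residuals: total within-twin variance v, cross-twin
  ## covariance free per zygosity (genetic/shared content of the residuals)
  comps$res_v <- list(name = "res_v", type = "diagonal", par_idx = add_idx(M),
                      within = 1, cross = setNames(rep(0, 4), ALL_KEYS))
  par_names <- c(par_names, paste0("res_var_", ph))
  lower <- c(lower, rep(1e-8, M)); upper <- c(upper, rep(Inf, M))
  comps$res_mz <- list(name = "res_mz", type = "diagonal", par_idx = add_idx(M),
                       within = 0,
                       cross = c(MZ.TRUE = 1, MZ.FALSE = 1, DZ.TRUE = 0, DZ.FALSE = 0))
  par_names <- c(par_names, paste0("res_cov_mz_", ph))
  lower <- c(lower, rep(-Inf, M)); upper <- c(upper, rep(Inf, M))
  comps$res_dz <- list(name = "res_dz", type = "diagonal", par_idx = add_idx(M),
                       within = 0,
                       cross = c(MZ.TRUE = 0, MZ.FALSE = 0, DZ.TRUE = 1, DZ.FALSE = 1))
  par_names <- c(par_names, paste0("res_cov_dz_", ph))
  lower <- c(lower, rep(-Inf, M)); upper <- c(upper, rep(Inf, M))
  ic_idx <- add_idx(M)
  par_names <- c(par_names, paste0("intercept_", ph))
  lower <- c(lower, rep(-Inf, M)); upper <- c(upper, rep(Inf, M))
  b_idx <- NULL
  if (spec$sex_effect) {
    b_idx <- add_idx(M)
    par_names <- c(par_names, paste0("beta_sex_", ph))
    lower <- c(lower, rep(-Inf, M)); upper <- c(upper, rep(Inf, M))
  }
  npar <- nxt - 1
  core <- component_model_core(comps, M, list(intercepts = ic_idx, beta_sex = b_idx))

  means <- function(par, s1, s2) {
    mu1 <- par[ic_idx]; mu2 <- par[ic_idx]
    if (!is.null(b_idx)) {
      mu1 <- mu1 + par[b_idx] * s1
      mu2 <- mu2 + par[b_idx] * s2
    }
    c(mu1, mu2)
  }

  start <- function(prep) {
    Y1 <- prep$Y[, 1:M, drop = FALSE]; Y2 <- prep$Y[, M + 1:M, drop = FALSE]
    v <- apply(rbind(Y1, Y2), 2, var, na.rm = TRUE)
    v[!is.finite(v) | v <= 0] <- 1
    par <- numeric(npar)
    k <- length(spec$components_with_factors)
    for (cm in spec$components_with_factors) {
      i <- comps[[paste0("factor_", cm)]]$par_idx
      par[i] <- c(sqrt(v / (2 * k)) * 0.9, if (has_phi) 0.4)
    }
    par[comps$res_v$par_idx] <- v / 2
    par[comps$res_mz$par_idx] <- v / 5
    par[comps$res_dz$par_idx] <- v / 10
    mu0 <- colMeans(rbind(Y1, Y2), na.rm = TRUE); mu0[!is.finite(mu0)] <- 0
    par[ic_idx] <- mu0
    par
  }

  canonicalize <- function(par) {
    ## per component factor, flip each factor's loading column to be
    ## majority-positive (likelihood-invariant together with phi's sign when
    ## both columns flip; a single-column flip must also flip phi)
    for (cm in spec$components_with_factors) {
      i <- comps[[paste0("factor_", cm)]]$par_idx
      lo <- par[i][seq_len(M)]
      flip <- vapply(seq_len(nf), function(f) {
        sum(lo[load_pos[, 2] == f]) < 0
      }, TRUE)
      for (f in which(flip)) lo[load_pos[, 2] == f] <- -lo[load_pos[, 2] == f]
      if (has_phi) {
        phi <- par[i][M + 1]
        if (xor(flip[1], flip[2])) phi <- -phi
        par[i] <- c(lo, phi)
      } else par[i] <- lo
    }
    par
  }

  build_estimates <- function(par) {
    out <- list(phenotypes = ph, factors = facs)
    for (cm in spec$components_with_factors) {
      i <- comps[[paste0("factor_", cm)]]$par_idx
      Lam <- matrix(0, M, nf, dimnames = list(ph, facs))
      Lam[load_pos] <- par[i][seq_len(M)]
      out[[paste0("loadings_", tolower(cm))]] <- Lam
      out[[paste0("factor_corr_", tolower(cm))]] <- if (has_phi) par[i][M + 1]
                                                    else NA_real_
    }
    out$residual_var <- setNames(par[comps$res_v$par_idx], ph)
    out$residual_cov_mz <- setNames(par[comps$res_mz$par_idx], ph)
    out$residual_cov_dz <- setNames(par[comps$res_dz$par_idx], ph)
    out$intercepts <- setNames(par[ic_idx], ph)
    if (!is.null(b_idx)) out$beta_sex <- setNames(par[b_idx], ph)
    out
  }

  list(phenotypes = ph, M = M, npar = npar, par_names = par_names,
       lower = lower, upper = upper,
       key_of = function(zyg, st, s1, s2) paste(zyg, st, sep = "."),
       sigmas = core$sigmas, grad = core$grad, means = means,
       start = start, canonicalize = canonicalize,
       build_estimates = build_estimates, spec = spec)
}

#' Fit the independent pathway model by FIML
#'
#' For each selected biometric component, two correlated common factors (one
#' per symptom dimension) load on the phenotypes; phenotype residuals have a
#' free within-twin variance and cross-twin covariances free per zygosity.
#' Fitted by the same FIML engine as [fit_ade()].  Non-convergence is a
#' legitimate, fully reported outcome; use [flattest_directions()] on a
#' non-converged fit to see which directions of the likelihood are flat.
#'
#' @param data Wide twin tibble.
#' @param spec A [factor_spec()].
#' @param options A [fit_options()].
#' @return A `twin_fit` whose `estimates` list the per-component loading
#'   matrices, factor correlations, residual structure, and means.
#' @export
fit_independent_pathway <- function(data, spec, options = fit_options()) {
  assert_that(inherits(spec, "factor_spec"), "spec must be a factor_spec")
  fit <- fiml_fit(data, ip_internal_model(spec), options,
                  model_type = "independent_pathway")
  if (!fit$converged)
    warning("independent pathway model did not converge; see flattest_directions(fit, data)",
            call. = FALSE)
  fit
}

#' Flattest directions of the likelihood at a solution
#'
#' Diagnoses weak identification or non-convergence: eigen-decomposes the
#' numerical Hessian of the negative log-likelihood and reports the smallest
#' eigenvalues with the parameters loading most on their eigenvectors.
#'
#' @param fit A `twin_fit`.
#' @param data The dataset the model was fitted to.
#' @param k Number of directions to report.
#' @return A tibble with `eigenvalue` and the dominant `terms` per direction.
#' @export
flattest_directions <- function(fit, data, k = 3) {
  model <- fit$model
  prep <- fiml_prepare(data, model$phenotypes)
  par <- as.numeric(fit$par)
  p <- length(par)
  gradf <- if (!is.null(model$grad)) {
    function(pp) attr(engine_nll(pp, model, prep, want_grad = TRUE), "gradient")
  } else {
    function(pp) num_gradient(function(q) as.numeric(engine_nll(q, model, prep)), pp)
  }
  H <- matrix(0, p, p)
  h <- 1e-5 * pmax(abs(par), 0.1)
  for (j in seq_len(p)) {
    e <- numeric(p); e[j] <- h[j]
    H[, j] <- (gradf(par + e) - gradf(par - e)) / (2 * h[j])
  }
  ev <- eigen((H + t(H)) / 2, symmetric = TRUE)
  ord <- order(ev$values)[seq_len(min(k, p))]
  tibble(
    eigenvalue = ev$values[ord],
    terms = vapply(ord, function(i) {
      w <- abs(ev$vectors[, i])
      paste(model$par_names[order(-w)[1:min(3, p)]], collapse = ", ")
    }, ""))
}

#' Confirmatory two-factor fit to a component correlation matrix
#'
#' Fits the two-correlated-factors model to a correlation matrix (typically a
#' genetic A+D correlation matrix).  The default `method = "ml"` minimizes the
#' normal-theory ML discrepancy with freely estimated uniquenesses, which on
#' the reference genetic correlation matrix reproduces the published loading
#' pattern and factor correlation; `method = "uls"` minimizes the unweighted
#' least-squares discrepancy over the off-diagonal entries,
#' `sum_{i<j} (corr_ij - implied_ij)^2` with `implied = Lambda Phi Lambda'`
#' (uniquenesses are then `1 - communality` and do not enter).  Point
#' estimates only (no standard errors).  Solutions with a communality above 1
#' are flagged as Heywood cases but still returned.  Factor signs are
#' canonicalized to majority-positive loadings.
#'
#' @param corr Symmetric correlation matrix with unit diagonal.
#' @param spec A [factor_spec()] (its `factor_assignment` must cover the
#'   row names of `corr`, or positions when unnamed).
#' @param method `"ml"` (default) or `"uls"`.
#' @param n_starts Number of seeded random starts.
#' @param seed Seed for the random starts.
#' @return A list of class `cfa_fit`: `loadings` (M x 2), `factor_correlation`,
#'   `uniquenesses`, `discrepancy`, `heywood`, `converged`.
#' @export
fit_cfa_on_matrix <- function(corr, spec, method = c("ml", "uls"),
                              n_starts = 10, seed = 1L) {
  method <- match.arg(method)
  corr <- as.matrix(corr)
  M <- nrow(corr)
  assert_that(isTRUE(all.equal(corr, t(corr), tolerance = 1e-8)) &&
                max(abs(diag(corr) - 1)) < 1e-8,
              "corr must be symmetric with unit diagonal")
  ph <- rownames(corr) %||% names(spec$factor_assignment)
  assert_that(all(ph %in% names(spec$factor_assignment)),
              "factor_assignment must cover all phenotypes in corr")
  facs <- spec$factors
  nf <- length(facs)
  fidx <- match(spec$factor_assignment[ph], facs)
  off <- which(lower.tri(corr))
  n_load <- M
  has_phi <- nf == 2
  implied_fn <- function(lo, phi) {
    Lam <- matrix(0, M, nf); Lam[cbind(seq_len(M), fidx)] <- lo
    Phi <- diag(nf); Phi[Phi == 0] <- phi
    Lam %*% Phi %*% t(Lam)
  }
  obj <- function(th) {
    lo <- th[seq_len(n_load)]
    phi <- if (has_phi) th[n_load + 1] else 0
    if (method == "uls") {
      imp <- implied_fn(lo, phi)
      sum((corr[off] - imp[off])^2)
    } else {
      psi <- th[n_load + has_phi + seq_len(M)]
      S <- implied_fn(lo, phi) + diag(psi, M)
      ch <- tryCatch(chol(S), error = function(e) NULL)
      if (is.null(ch)) return(1e10)
      2 * sum(log(diag(ch))) + sum(chol2inv(ch) * corr) - log(det(corr)) - M
    }
  }
  npar <- n_load + has_phi + if (method == "ml") M else 0
  lower <- c(rep(-Inf, n_load), if (has_phi) -0.999,
             rep(1e-6, npar - n_load - has_phi))
  upper <- c(rep(Inf, n_load), if (has_phi) 0.999,
             rep(Inf, npar - n_load - has_phi))
  withr::local_seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    th0 <- c(runif(n_load, 0.2, 0.9), if (has_phi) runif(1, 0.2, 0.8),
             if (method == "ml") runif(M, 0.2, 0.8))
    o <- nlminb(th0, obj, lower = lower, upper = upper,
                control = list(iter.max = 2000, eval.max = 10000))
    if (is.null(best) || o$objective < best$objective) best <- o
  }
  th <- best$par
  lo <- th[seq_len(n_load)]
  phi <- if (has_phi) th[n_load + 1] else NA_real_
  ## canonical signs: each factor's loadings majority-positive; flipping one
  ## factor negates the factor correlation, flipping both restores it
  flips <- vapply(seq_len(nf), function(f) sum(lo[fidx == f]) < 0, TRUE)
  for (f in which(flips)) lo[fidx == f] <- -lo[fidx == f]
  if (has_phi && sum(flips) %% 2 == 1) phi <- -phi
  Lam <- matrix(0, M, nf, dimnames = list(ph, facs))
  Lam[cbind(seq_len(M), fidx)] <- lo
  communality <- lo^2
  heywood <- communality > 1 + 1e-8
  if (any(heywood))
    warning(sprintf("Heywood case: communality > 1 for %s",
                    paste(ph[heywood], collapse = ", ")), call. = FALSE)
  uniq <- if (method == "ml") setNames(th[n_load + has_phi + seq_len(M)], ph)
          else setNames(1 - communality, ph)
  structure(list(loadings = Lam, factor_correlation = phi,
                 uniquenesses = uniq, communalities = setNames(communality, ph),
                 discrepancy = best$objective, method = method,
                 heywood = heywood, converged = best$convergence == 0),
            class = "cfa_fit")
}

#' @export
print.cfa_fit <- function(x, ...) {
  cat(sprintf("Two-factor confirmatory fit (%s discrepancy %.6g)\n",
              toupper(x$method), x$discrepancy))
  print(round(x$loadings, 3))
  cat(sprintf("factor correlation: %.3f\n", x$factor_correlation))
  if (any(x$heywood)) cat("Heywood case(s) flagged\n")
  invisible(x)
}
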