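## User-facing fitting: the multivariate ADE (or ACE) Cholesky model with the
## teacher-rater factor, by full-information maximum likelihood on raw
## twin-pair data.

#' Model specification for the Cholesky twin model
#'
#' @param phenotypes Character vector of phenotype labels (columns
#'   `<phenotype>_1` / `<phenotype>_2` must exist in the data).
#' @param teacher_rated Logical vector flagging teacher-rated phenotypes
#'   (default: none).
#' @param components Genetic/environmental components: `c("A", "D", "E")`
#'   (default) or `c("A", "C", "E")`; subsets such as `c("A", "E")` are
#'   allowed.  `E` is always required.
#' @param rater Include the teacher-rater factor (default: yes when any
#'   phenotype is teacher-rated)?
#' @param sex_effect Estimate a sex main effect per phenotype?
#' @param equal_rater_loadings Constrain the rater loadings equal across the
#'   teacher-rated phenotypes?
#' @return An object of class `ade_model_spec`.
#' @export
ade_model_spec <- function(phenotypes,
                           teacher_rated = rep(FALSE, length(phenotypes)),
                           components = c("A", "D", "E"),
                           rater = any(teacher_rated),
                           sex_effect = TRUE,
                           equal_rater_loadings = FALSE) {
  assert_that("E" %in% components, "the model must include an E component")
  assert_that(all(components %in% c("A", "D", "C", "E")),
              "components must be among A, D, C, E")
  assert_that(!("D" %in% components && "C" %in% components),
              "D and C are not jointly identified in the classical twin design")
  assert_that(length(teacher_rated) == length(phenotypes),
              "teacher_rated must match phenotypes")
  if (rater) assert_that(any(teacher_rated),
                         "a rater factor needs at least one teacher-rated phenotype")
  structure(list(phenotypes = phenotypes, teacher_rated = teacher_rated,
                 components = components, rater = rater,
                 sex_effect = sex_effect,
                 equal_rater_loadings = equal_rater_loadings),
            class = "ade_model_spec")
}

#' Optimizer options for FIML fits
#'
#' @param n_starts Number of optimizer starts: the documented starting values
#'   plus `n_starts - 1` seeded jittered perturbations; the best solution is
#'   kept.
#' @param seed Seed for the jittered starts.
#' @param jitter Relative jitter magnitude.
#' @param rel_tol,max_iter,max_eval `nlminb` control settings.
#' @param gradient_tol Convergence check: sup-norm of the final gradient must
#'   fall below this for the fit to be flagged converged.
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(n_starts = 5, seed = 1L, jitter = 0.1,
                        rel_tol = 1e-12, max_iter = 5000, max_eval = 50000,
                        gradient_tol = 0.05) {
  structure(list(n_starts = n_starts, seed = as.integer(seed), jitter = jitter,
                 rel_tol = rel_tol, max_iter = max_iter, max_eval = max_eval,
                 gradient_tol = gradient_tol),
            class = "fit_options")
}

## internal engine model for an ade_model_spec
ade_internal_model <- function(spec) {
  M <- length(spec$phenotypes)
  ntri <- M * (M + 1) / 2
  comps <- list()
  par_names <- character(0)
  nxt <- 1
  add_idx <- function(k) { i <- nxt:(nxt + k - 1); nxt <<- nxt + k; i }
  for (cm in intersect(c("A", "D", "C", "E"), spec$components)) {
    comps[[cm]] <- list(name = cm, type = "chol", par_idx = add_idx(ntri),
                        within = 1, cross = cross_weights(cm))
    par_names <- c(par_names, tri_names(tolower(cm), M))
  }
  if (spec$rater) {
    t_idx <- which(spec$teacher_rated)
    if (spec$equal_rater_loadings) {
      map <- matrix(0, M, 1); map[t_idx, 1] <- 1
      nm <- "rater"
    } else {
      map <- matrix(0, M, length(t_idx))
      map[cbind(t_idx, seq_along(t_idx))] <- 1
      nm <- paste0("rater_", spec$phenotypes[t_idx])
    }
    comps$rater <- list(name = "rater", type = "rank1",
                        par_idx = add_idx(ncol(map)), map = map,
                        within = 1, cross = cross_weights("rater"))
    par_names <- c(par_names, nm)
  }
  ic_idx <- add_idx(M)
  par_names <- c(par_names, paste0("intercept_", spec$phenotypes))
  b_idx <- NULL
  if (spec$sex_effect) {
    b_idx <- add_idx(M)
    par_names <- c(par_names, paste0("beta_sex_", spec$phenotypes))
  }
  npar <- nxt - 1
  core <- component_model_core(comps, M, list(intercepts = ic_idx, beta_sex = b_idx))
  ltri <- lower.tri(diag(M), diag = TRUE)

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
    pooled <- cov(rbind(Y1, Y2), use = "pairwise.complete.obs")
    pooled[!is.finite(pooled)] <- 0
    diag(pooled)[diag(pooled) <= 0] <- 1
    par <- numeric(npar)
    par[comps$E$par_idx] <- t(chol(psd_project(pooled / 2, 1e-4)))[ltri]
    mz <- prep$zygosity == "MZ"
    if (any(mz) && any(c("A", "C") %in% spec$components)) {
      cx <- cov(Y1[mz, , drop = FALSE], Y2[mz, , drop = FALSE],
                use = "pairwise.complete.obs")
      cx[!is.finite(cx)] <- 0
      cx <- psd_project(0.8 * (cx + t(cx)) / 2, 1e-6)
      first <- if ("A" %in% spec$components) "A" else "C"
      par[comps[[first]]$par_idx] <- t(chol(psd_project(cx, 1e-4)))[ltri]
    }
    if ("D" %in% spec$components)
      par[comps$D$par_idx] <- t(diag(0.05, M))[ltri]
    if (spec$rater) par[comps$rater$par_idx] <- 0.3
    mu0 <- colMeans(rbind(Y1, Y2), na.rm = TRUE)
    mu0[!is.finite(mu0)] <- 0
    par[ic_idx] <- mu0
    par
  }

  canonicalize <- function(par) {
    for (cm in names(comps)) {
      co <- comps[[cm]]
      if (co$type == "chol") {
        L <- matrix(0, M, M); L[ltri] <- par[co$par_idx]
        for (k in seq_len(M)) if (L[k, k] < 0) L[, k] <- -L[, k]
        par[co$par_idx] <- L[ltri]
      }
      if (co$type == "rank1" && sum(par[co$par_idx]) < 0)
        par[co$par_idx] <- -par[co$par_idx]
    }
    par
  }

  build_estimates <- function(par) {
    zero <- matrix(0, M, M)
    getL <- function(cm) {
      if (is.null(comps[[cm]])) return(zero)
      L <- zero; L[ltri] <- par[comps[[cm]]$par_idx]; L
    }
    lam <- if (spec$rater) drop(comps$rater$map %*% par[comps$rater$par_idx])
           else rep(0, M)
    ade_parameters(getL("A"), if ("D" %in% spec$components) getL("D") else getL("C"),
                   getL("E"),
                   rater_loadings = lam,
                   intercepts = par[ic_idx],
                   beta_sex = if (is.null(b_idx)) rep(0, M) else par[b_idx],
                   phenotypes = spec$phenotypes,
                   teacher_rated = spec$teacher_rated)
  }

  list(phenotypes = spec$phenotypes, M = M, npar = npar, par_names = par_names,
       lower = -Inf, upper = Inf,
       key_of = function(zyg, st, s1, s2) paste(zyg, st, sep = "."),
       sigmas = core$sigmas, grad = core$grad, means = means,
       start = start, canonicalize = canonicalize,
       build_estimates = build_estimates, spec = spec)
}

## shared fitting driver: prepare, sanity-check, optimize, package the result
fiml_fit <- function(data, model, options, model_type) {
  prep <- fiml_prepare(data, model$phenotypes)
  assert_that(prep$n_pairs_used >= 30, "need at least 30 usable pairs")
  zy <- unique(data$zygosity)
  needs_both <- is.null(model$single_zygosity_ok)
  if (needs_both && length(zy) < 2)
    warning("only one zygosity group present: A and D (or C) are not ",
            "separately identified; the information matrix will be rank deficient",
            call. = FALSE)
  opt <- fiml_optimize(model, prep, options)
  structure(
    list(estimates = model$build_estimates(opt$par),
         par = setNames(opt$par, model$par_names),
         loglik = opt$loglik,
         n_pairs_used = prep$n_pairs_used,
         n_pairs_excluded = prep$n_excluded,
         converged = opt$converged,
         gradient_norm = opt$gradient_norm,
         nlminb_code = opt$nlminb_code,
         n_function_evals = opt$n_function_evals,
         npar = model$npar,
         starts = opt$starts,
         model = model, options = options, model_type = model_type,
         checksum = prep$checksum),
    class = "twin_fit")
}

#' Fit the Cholesky twin model by full-information maximum likelihood
#'
#' Maximizes the casewise FIML log-likelihood over the Cholesky factors,
#' rater loadings and mean coefficients by quasi-Newton optimization with
#' analytic gradients, from documented starting values plus seeded jittered
#' multi-starts.  Sign indeterminacy of the Cholesky factors is resolved
#' post hoc (diagonals nonnegative).  Non-convergence is reported, never
#' silent.
#'
#' @param data Wide twin tibble ([simulate_twin_pairs()] layout or
#'   [read_twin_csv()]).
#' @param spec An [ade_model_spec()].
#' @param options A [fit_options()] list.
#' @return An object of class `twin_fit` with elements `estimates` (an
#'   [ade_parameters()]), `loglik`, `n_pairs_used`, `converged`,
#'   `gradient_norm`, `npar`, `starts` (per-start summary) and bookkeeping.
#' @export
fit_ade <- function(data, spec = NULL, options = fit_options()) {
  if (is.null(spec)) spec <- ade_model_spec(detect_phenotypes(data))
  fiml_fit(data, ade_internal_model(spec), options, model_type = "ade_cholesky")
}

#' @export
print.twin_fit <- function(x, ...) {
  cat(sprintf("FIML %s fit: %d phenotypes, %d pairs, %d parameters\n",
              x$model_type, length(x$model$phenotypes), x$n_pairs_used, x$npar))
  cat(sprintf("log-likelihood %.3f; %s (|grad| = %.2g)\n", x$loglik,
              if (x$converged) "converged" else "DID NOT CONVERGE",
              x$gradient_norm))
  invisible(x)
}

#' Casewise log-likelihood of one twin pair
#'
#' The multivariate-normal log density of the pair's observed coordinates,
#' with mean and covariance obtained by selecting the observed rows/columns of
#' [build_means()] and [build_group_cov()] for the pair's group
#' (marginalization by row/column deletion).  This is the definitional
#' casewise route; the fitting engine computes the identical quantity from
#' grouped sufficient statistics.
#'
#' @param params An [ade_parameters()] object.
#' @param record One-row wide twin tibble (or a row of one).
#' @return The log-likelihood; `-Inf` with attribute `flagged = TRUE` when the
#'   observed submatrix is not positive definite.
#' @export
pair_loglik <- function(params, record) {
  ph <- params$phenotypes
  y <- as.numeric(record[1, c(paste0(ph, "_1"), paste0(ph, "_2"))])
  obs <- which(!is.na(y))
  assert_that(length(obs) >= 1, "record has no observed values")
  st <- isTRUE(as.logical(record$same_teacher[1]))
  sigma <- build_group_cov(params, record$zygosity[1], st)$sigma[obs, obs, drop = FALSE]
  s1 <- if ("sex_1" %in% names(record)) record$sex_1[1] else 0
  s2 <- if ("sex_2" %in% names(record)) record$sex_2[1] else 0
  mu <- build_means(params, s1, s2)[obs]
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) return(structure(-Inf, flagged = TRUE))
  z <- backsolve(ch, y[obs] - mu, transpose = TRUE)
  -0.5 * (length(obs) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
}

#' Total casewise log-likelihood of a dataset
#'
#' Sums [pair_loglik()] over the rows of `data` (rows with no observed values
#' contribute zero).  Invariant to row order and to twin-label permutation
#' within MZ pairs.
#'
#' @inheritParams pair_loglik
#' @param data Wide twin tibble.
#' @return Total log-likelihood.
#' @export
dataset_loglik <- function(params, data) {
  ph <- params$phenotypes
  cols <- c(paste0(ph, "_1"), paste0(ph, "_2"))
  tot <- 0
  for (i in seq_len(nrow(data))) {
    if (all(is.na(data[i, cols]))) next
    tot <- tot + pair_loglik(params, data[i, ])
  }
  tot
}

## per-pair log-likelihood vector at an arbitrary engine parameter vector
casewise_loglik_vector <- function(par, model, prep) {
  keys <- unique(vapply(prep$cells, function(ci)
    model$key_of(ci$zygosity, ci$same_teacher, ci$s1, ci$s2), ""))
  sig <- model$sigmas(par, keys)
  out <- numeric(nrow(prep$Y))
  for (ci in prep$cells) {
    key <- model$key_of(ci$zygosity, ci$same_teacher, ci$s1, ci$s2)
    S <- sig[[key]][ci$cols, ci$cols, drop = FALSE]
    ch <- chol(S)
    mu <- model$means(par, ci$s1, ci$s2)[ci$cols]
    R <- t(prep$Y[ci$rows, ci$cols, drop = FALSE]) - mu
    Z <- backsolve(ch, R, transpose = TRUE)
    out[ci$rows] <- -0.5 * (length(ci$cols) * log(2 * pi) +
                              2 * sum(log(diag(ch))) + colSums(Z^2))
  }
  out
}

#' Robust (sandwich) and observed-information standard errors
#'
#' Computes the sandwich estimator `A^-1 B A^-1`, with `A` the observed
#' information (numerical Hessian of the total negative log-likelihood,
#' obtained by finite differences of the analytic gradient) and `B` the sum of
#' per-pair score outer products (scores by central finite differences of the
#' per-pair log-likelihoods).  Plain observed-information standard errors are
#' returned alongside.  Parameters at which the information matrix is singular
#' get `NA` standard errors and a note.
#'
#' @param fit A converged [fit_ade()] (or [fit_independent_pathway()]) result.
#' @param data The dataset the model was fitted to.
#' @return A tibble with columns `term`, `estimate`, `se_observed`,
#'   `se_sandwich`; attribute `"note"` carries singularity warnings.
#' @export
robust_se <- function(fit, data) {
  assert_that(inherits(fit, "twin_fit"), "fit must be a twin_fit")
  if (!fit$converged)
    warning("standard errors at a non-converged solution are unreliable",
            call. = FALSE)
  model <- fit$model
  prep <- fiml_prepare(data, model$phenotypes)
  assert_that(isTRUE(all.equal(prep$checksum, fit$checksum)),
              "data does not match the dataset the model was fitted to")
  par <- as.numeric(fit$par)
  p <- length(par)
  h <- 1e-5 * pmax(abs(par), 0.1)
  gradf <- if (!is.null(model$grad)) {
    function(pp) attr(engine_nll(pp, model, prep, want_grad = TRUE), "gradient")
  } else {
    function(pp) num_gradient(function(q) as.numeric(engine_nll(q, model, prep)), pp)
  }
  A <- matrix(0, p, p)
  scores <- matrix(0, nrow(prep$Y), p)
  for (j in seq_len(p)) {
    e <- numeric(p); e[j] <- h[j]
    A[, j] <- (gradf(par + e) - gradf(par - e)) / (2 * h[j])
    scores[, j] <- (casewise_loglik_vector(par + e, model, prep) -
                      casewise_loglik_vector(par - e, model, prep)) / (2 * h[j])
  }
  A <- (A + t(A)) / 2
  B <- crossprod(scores)
  Ainv <- tryCatch(solve(A), error = function(e) NULL)
  note <- NULL
  if (is.null(Ainv)) {
    ev <- eigen(A, symmetric = TRUE)
    ok <- ev$values > max(ev$values) * 1e-10
    note <- sprintf("information matrix singular (rank %d of %d); SEs undefined in the null space",
                    sum(ok), p)
    Ainv <- ev$vectors[, ok, drop = FALSE] %*%
      diag(1 / ev$values[ok], sum(ok)) %*% t(ev$vectors[, ok, drop = FALSE])
    flat <- rowSums(ev$vectors[, !ok, drop = FALSE]^2) > 1e-6
  } else flat <- rep(FALSE, p)
  sw <- Ainv %*% B %*% Ainv
  se_obs <- sqrt(pmax(diag(Ainv), 0)); se_sw <- sqrt(pmax(diag(sw), 0))
  se_obs[flat] <- NA_real_; se_sw[flat] <- NA_real_
  out <- tibble(term = model$par_names, estimate = par,
                se_observed = se_obs, se_sandwich = se_sw)
  attr(out, "note") <- note
  if (!is.null(note)) warning(note, call. = FALSE)
  out
}
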