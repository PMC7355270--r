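## Internal full-information ML engine.
##
## The casewise FIML log-likelihood (each pair contributes the normal log
## density of its observed coordinates) is computed from sufficient
## statistics: pairs are grouped into cells sharing (zygosity,
## teacher-sharing, sex pattern, missingness pattern); within a cell the mean
## and the observed-coordinate covariance are constant, so the cell's
## contribution is
##   n [k log 2pi + log|S| + (ybar - mu)' S^-1 (ybar - mu)] + tr(S^-1 Sc)
## with Sc the centered cross-product matrix, precomputed once.  This is
## algebraically identical to the casewise sum but costs O(#cells) per
## evaluation.  Gradients are analytic, chained through the linear structure
## of the group covariances in the component matrices (Delta Delta', lambda
## lambda', Lambda Phi Lambda', diagonals).
##
## A model object provides:
##   phenotypes, npar, par_names, lower, upper
##   key_of(zygosity, same_teacher, sex1, sex2) -> covariance-group key
##   sigmas(par, keys)    -> named list of 2M x 2M matrices
##   means(par, s1, s2)   -> length-2M mean vector
##   grad(par, accum)     -> gradient vector, from accumulated d NLL / d Sigma
##                           per key plus mean-gradient accumulators (optional;
##                           NULL means finite-difference optimization)
##   start(prep), canonicalize(par), build_estimates(par)

fiml_prepare <- function(data, phenotypes) {
  cols1 <- paste0(phenotypes, "_1"); cols2 <- paste0(phenotypes, "_2")
  assert_that(all(c(cols1, cols2) %in% names(data)),
              "dataset lacks required phenotype columns")
  assert_that(all(data$zygosity %in% c("MZ", "DZ")),
              "zygosity must be 'MZ' or 'DZ'")
  Y <- as.matrix(data[c(cols1, cols2)])
  storage.mode(Y) <- "double"
  st <- if ("same_teacher" %in% names(data)) {
    ifelse(is.na(data$same_teacher), FALSE, as.logical(data$same_teacher))
  } else rep(FALSE, nrow(data))
  s1 <- if ("sex_1" %in% names(data)) data$sex_1 else rep(0, nrow(data))
  s2 <- if ("sex_2" %in% names(data)) data$sex_2 else rep(0, nrow(data))
  assert_that(all(c(s1, s2) %in% c(0, 1)), "sex must be coded 0 or 1")
  obs <- !is.na(Y)
  n_obs <- rowSums(obs)
  keep <- n_obs > 0
  patt <- apply(obs, 1, function(r) paste(as.integer(r), collapse = ""))
  cell_key <- paste(data$zygosity, st, s1, s2, patt)
  idx <- split(which(keep), cell_key[keep])
  cells <- lapply(idx, function(i) {
    cols <- which(obs[i[1], ])
    Yc <- Y[i, cols, drop = FALSE]
    ybar <- colMeans(Yc)
    list(n = length(i), rows = i, cols = cols, ybar = ybar,
         Sc = crossprod(sweep(Yc, 2, ybar)),
         zygosity = data$zygosity[i[1]], same_teacher = st[i[1]],
         s1 = s1[i[1]], s2 = s2[i[1]])
  })
  list(Y = Y, cells = cells, M = length(phenotypes),
       n_pairs_used = sum(keep), n_excluded = sum(!keep),
       zygosity = data$zygosity, same_teacher = st, s1 = s1, s2 = s2,
       checksum = c(n = sum(keep), y = sum(Y, na.rm = TRUE)))
}

## value (and, if requested and supported, gradient) of the total negative
## log-likelihood
engine_nll <- function(par, model, prep, want_grad = FALSE) {
  keys <- unique(vapply(prep$cells, function(ci)
    model$key_of(ci$zygosity, ci$same_teacher, ci$s1, ci$s2), ""))
  sig <- model$sigmas(par, keys)
  M <- prep$M
  total <- 0
  if (want_grad) {
    Gk <- lapply(sig, function(s) matrix(0, 2 * M, 2 * M))
    g_ic <- numeric(M); g_b <- numeric(M)
  }
  for (ci in prep$cells) {
    key <- model$key_of(ci$zygosity, ci$same_teacher, ci$s1, ci$s2)
    S <- sig[[key]][ci$cols, ci$cols, drop = FALSE]
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) {
      out <- 1e10
      if (want_grad) attr(out, "gradient") <- numeric(model$npar)
      return(out)
    }
    Sinv <- chol2inv(ch)
    mu <- model$means(par, ci$s1, ci$s2)[ci$cols]
    dv <- ci$ybar - mu
    Sid <- drop(Sinv %*% dv)
    k <- length(ci$cols)
    total <- total + ci$n * (k * log(2 * pi) + 2 * sum(log(diag(ch))) +
                               sum(dv * Sid)) + sum(Sinv * ci$Sc)
    if (want_grad) {
      Gc <- 0.5 * (ci$n * Sinv -
                     Sinv %*% (ci$n * tcrossprod(dv) + ci$Sc) %*% Sinv)
      Gk[[key]][ci$cols, ci$cols] <- Gk[[key]][ci$cols, ci$cols] + Gc
      gm <- numeric(2 * M)
      gm[ci$cols] <- -ci$n * Sid
      g_ic <- g_ic + gm[1:M] + gm[M + 1:M]
      g_b <- g_b + gm[1:M] * ci$s1 + gm[M + 1:M] * ci$s2
    }
  }
  out <- total / 2
  if (want_grad)
    attr(out, "gradient") <- model$grad(par, list(Gk = Gk, g_ic = g_ic, g_b = g_b))
  out
}

## --- component machinery -------------------------------------------------
## a component owns a slice of the parameter vector, builds an M x M matrix P
## and back-maps d NLL / d P onto its parameters.  Group covariance:
##   Sigma_key = [ sum_c w_c P_c ,  sum_c q_c(key) P_c ; t(...) , ... ]

comp_build <- function(comp, par, M) {
  th <- par[comp$par_idx]
  switch(comp$type,
    chol = {
      L <- matrix(0, M, M); L[lower.tri(L, diag = TRUE)] <- th
      tcrossprod(L)
    },
    rank1 = {
      lam <- drop(comp$map %*% th)
      tcrossprod(lam)
    },
    diagonal = diag(th, M),
    factor = {
      Lam <- matrix(0, M, comp$n_factors)
      Lam[comp$load_pos] <- th[seq_len(nrow(comp$load_pos))]
      Phi <- diag(comp$n_factors)
      if (comp$has_phi) Phi[Phi == 0] <- th[length(th)]
      Lam %*% Phi %*% t(Lam)
    })
}

comp_grad <- function(comp, par, Gp, M) {
  th <- par[comp$par_idx]
  Gs <- Gp + t(Gp)
  switch(comp$type,
    chol = {
      L <- matrix(0, M, M); L[lower.tri(L, diag = TRUE)] <- th
      (Gs %*% L)[lower.tri(L, diag = TRUE)]
    },
    rank1 = {
      lam <- drop(comp$map %*% th)
      drop(t(comp$map) %*% (Gs %*% lam))
    },
    diagonal = diag(Gp),
    factor = {
      nl <- nrow(comp$load_pos)
      Lam <- matrix(0, M, comp$n_factors)
      Lam[comp$load_pos] <- th[seq_len(nl)]
      Phi <- diag(comp$n_factors)
      if (comp$has_phi) Phi[Phi == 0] <- th[length(th)]
      gl <- (Gs %*% Lam %*% Phi)[comp$load_pos]
      if (!comp$has_phi) return(gl)
      E <- matrix(1, comp$n_factors, comp$n_factors) - diag(comp$n_factors)
      gphi <- 0.5 * sum((t(Lam) %*% Gs %*% Lam) * E)
      c(gl, gphi)
    })
}

## assemble the four lookup pieces used by generic component models
component_model_core <- function(components, M, mean_idx) {
  sigmas <- function(par, keys) {
    P <- lapply(components, comp_build, par = par, M = M)
    out <- list()
    for (key in keys) {
      W <- matrix(0, M, M); Cx <- matrix(0, M, M)
      for (j in seq_along(components)) {
        co <- components[[j]]
        if (co$within != 0) W <- W + co$within * P[[j]]
        q <- co$cross[[key]]
        if (q != 0) Cx <- Cx + q * P[[j]]
      }
      out[[key]] <- rbind(cbind(W, Cx), cbind(t(Cx), W))
    }
    out
  }
  grad <- function(par, accum) {
    g <- numeric(length(par))
    for (j in seq_along(components)) {
      co <- components[[j]]
      Gp <- matrix(0, M, M)
      for (key in names(accum$Gk)) {
        Gg <- accum$Gk[[key]]
        if (co$within != 0)
          Gp <- Gp + co$within * (Gg[1:M, 1:M] + Gg[M + 1:M, M + 1:M])
        q <- co$cross[[key]]
        if (q != 0)
          Gp <- Gp + q * (Gg[1:M, M + 1:M] + t(Gg[M + 1:M, 1:M]))
      }
      g[co$par_idx] <- g[co$par_idx] + comp_grad(co, par, Gp, M)
    }
    if (!is.null(mean_idx$intercepts))
      g[mean_idx$intercepts] <- g[mean_idx$intercepts] + accum$g_ic
    if (!is.null(mean_idx$beta_sex))
      g[mean_idx$beta_sex] <- g[mean_idx$beta_sex] + accum$g_b
    g
  }
  list(sigmas = sigmas, grad = grad)
}

## cross-twin weight table for the biometric components, keyed by
## "<zygosity>.<same_teacher>"
ALL_KEYS <- c("MZ.TRUE", "MZ.FALSE", "DZ.TRUE", "DZ.FALSE")
cross_weights <- function(type) {
  switch(type,
    A = c(MZ.TRUE = 1, MZ.FALSE = 1, DZ.TRUE = 0.5, DZ.FALSE = 0.5),
    D = c(MZ.TRUE = 1, MZ.FALSE = 1, DZ.TRUE = 0.25, DZ.FALSE = 0.25),
    C = c(MZ.TRUE = 1, MZ.FALSE = 1, DZ.TRUE = 1, DZ.FALSE = 1),
    E = c(MZ.TRUE = 0, MZ.FALSE = 0, DZ.TRUE = 0, DZ.FALSE = 0),
    rater = c(MZ.TRUE = 1, MZ.FALSE = 0, DZ.TRUE = 1, DZ.FALSE = 0))
}

tri_names <- function(prefix, M) {
  ij <- which(lower.tri(diag(M), diag = TRUE), arr.ind = TRUE)
  ij <- ij[order(ij[, 2], ij[, 1]), , drop = FALSE]
  sprintf("%s[%d,%d]", prefix, ij[, 1], ij[, 2])
}

## NOTE: R fills lower.tri indices column-major; tri_names matches that order.

## optimizer driver shared by all model types
fiml_optimize <- function(model, prep, options) {
  base <- model$start(prep)
  p <- model$npar
  withr::local_seed(options$seed)
  starts <- list(base)
  if (options$n_starts > 1)
    for (i in seq_len(options$n_starts - 1))
      starts[[i + 1]] <- base + options$jitter * rnorm(p) * pmax(abs(base), 0.2)
  obj <- function(par) as.numeric(engine_nll(par, model, prep, want_grad = FALSE))
  gr <- if (!is.null(model$grad))
    function(par) attr(engine_nll(par, model, prep, want_grad = TRUE), "gradient")
  runs <- purrr::map(starts, function(s0)
    tryCatch(
      nlminb(s0, obj, gradient = gr,
             lower = model$lower %||% -Inf, upper = model$upper %||% Inf,
             control = list(eval.max = options$max_eval,
                            iter.max = options$max_iter,
                            rel.tol = options$rel_tol)),
      error = function(e) list(objective = Inf, par = s0, convergence = 999,
                               message = conditionMessage(e),
                               evaluations = c(0, 0), iterations = 0)))
  objs <- vapply(runs, `[[`, numeric(1), "objective")
  best <- runs[[which.min(objs)]]
  par <- model$canonicalize(best$par)
  gfin <- if (!is.null(gr)) gr(par) else num_gradient(obj, par)
  gnorm <- max(abs(gfin))
  list(par = par, loglik = -best$objective, gradient_norm = gnorm,
       converged = is.finite(best$objective) && gnorm < options$gradient_tol,
       nlminb_code = best$convergence,
       n_function_evals = sum(unlist(lapply(runs, `[[`, "evaluations"))),
       starts = tibble(start = seq_along(runs),
                       loglik = -objs,
                       nlminb_code = vapply(runs, `[[`, numeric(1), "convergence")))
}

num_gradient <- function(f, par, h = 1e-6) {
  vapply(seq_along(par), function(j) {
    e <- numeric(length(par)); e[j] <- h
    (f(par + e) - f(par - e)) / (2 * h)
  }, numeric(1))
}
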