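## Data readers/writers and the end-to-end pipeline.
##
## Wide dialect: one row per pair with columns pair_id, zygosity (MZ/DZ),
## sex_1, sex_2 (0 = boy, 1 = girl), same_teacher, and <phenotype>_1 /
## <phenotype>_2; empty cells or "NA" are missing.  Long dialect: one row per
## twin (pair_id, twin, zygosity, sex, same_teacher, one column per
## phenotype); the two rows of a pair are matched by pair_id, twin 1 being
## the first in file order.

#' Read twin-pair data from CSV
#'
#' @param path File path.
#' @param format `"auto"` (detect by column names), `"wide"` or `"long"`.
#' @param missing_tokens Strings read as missing, besides empty cells.
#' @param quiet Suppress the row-count/missingness log message?
#' @return A wide twin tibble as produced by [simulate_twin_pairs()], with a
#'   [missingness_table()] attached as attribute `"missingness"`.
#' @export
read_twin_csv <- function(path, format = c("auto", "wide", "long"),
                          missing_tokens = c("", "NA"), quiet = FALSE) {
  format <- match.arg(format)
  raw <- readr::read_csv(path, na = missing_tokens, show_col_types = FALSE,
                         progress = FALSE)
  nm0 <- names(raw)
  names(raw)[nm0 == "pairid"] <- "pair_id"
  names(raw)[nm0 == "zyg"] <- "zygosity"
  names(raw)[nm0 == "sex1"] <- "sex_1"
  names(raw)[nm0 == "sex2"] <- "sex_2"
  if (format == "auto")
    format <- if ("sex_1" %in% names(raw) || any(grepl("_1$", names(raw))))
      "wide" else "long"
  if (format == "long") {
    assert_that(all(c("pair_id", "zygosity", "sex") %in% names(raw)),
                "long format needs pair_id, zygosity and sex columns")
    counts <- table(raw$pair_id)
    if (any(counts != 2)) {
      bad <- names(counts)[counts != 2][1]
      stop_twinade(sprintf("long format: pair_id %s has %d row(s), expected 2",
                           bad, counts[[bad]]))
    }
    meta <- c("pair_id", "twin", "zygosity", "sex", "same_teacher")
    ph <- setdiff(names(raw), meta)
    raw$twin <- stats::ave(seq_len(nrow(raw)), raw$pair_id,
                           FUN = seq_along)
    w1 <- raw[raw$twin == 1, , drop = FALSE]
    w2 <- raw[raw$twin == 2, , drop = FALSE]
    w2 <- w2[match(w1$pair_id, w2$pair_id), , drop = FALSE]
    data <- tibble(pair_id = w1$pair_id, zygosity = w1$zygosity,
                   sex_1 = w1$sex, sex_2 = w2$sex,
                   same_teacher = if ("same_teacher" %in% names(raw))
                     w1$same_teacher else NA)
    for (p in ph) {
      data[[paste0(p, "_1")]] <- w1[[p]]
      data[[paste0(p, "_2")]] <- w2[[p]]
    }
  } else {
    assert_that(all(c("pair_id", "zygosity") %in% names(raw)),
                "wide format needs pair_id and zygosity columns")
    data <- as_tibble(raw)
  }
  assert_that(all(data$zygosity %in% c("MZ", "DZ")),
              sprintf("unknown zygosity value(s): %s",
                      paste(setdiff(unique(data$zygosity), c("MZ", "DZ")),
                            collapse = ", ")))
  mt <- missingness_table(data)
  attr(data, "missingness") <- mt
  if (!quiet)
    message(sprintf("read %d pairs, %d phenotypes, %d missing values",
                    nrow(data), length(detect_phenotypes(data)),
                    sum(is.na(data[grep("_[12]$", names(data))]))))
  data
}

#' Write twin-pair data to CSV
#'
#' @param data Wide twin tibble.
#' @param path Output path.
#' @param format `"wide"` (one row per pair) or `"long"` (one row per twin).
#' @return `path`, invisibly.
#' @export
write_twin_csv <- function(data, path, format = c("wide", "long")) {
  format <- match.arg(format)
  if (format == "wide") {
    readr::write_csv(data, path, na = "")
  } else {
    ph <- detect_phenotypes(data)
    one <- function(tw) {
      out <- tibble(pair_id = data$pair_id, twin = tw,
                    zygosity = data$zygosity,
                    sex = data[[paste0("sex_", tw)]],
                    same_teacher = data$same_teacher)
      for (p in ph) out[[p]] <- data[[paste0(p, "_", tw)]]
      out
    }
    long <- bind_rows(one(1), one(2)) %>% arrange(.data$pair_id, .data$twin)
    readr::write_csv(long %>% select(-"twin"), path, na = "")
  }
  invisible(path)
}

#' Two-way missingness summary
#'
#' Cross-tabulates, over pairs, the number of missing phenotype values in twin
#' 1 against the number in twin 2 — the standard two-way representation of
#' blockwise missingness in twin data.
#'
#' @param data Wide twin tibble.
#' @param phenotypes Phenotype labels (default: detected).
#' @return An `(M+1) x (M+1)` count matrix with dimnames `0..M`.
#' @export
missingness_table <- function(data, phenotypes = NULL) {
  phenotypes <- phenotypes %||% detect_phenotypes(data)
  M <- length(phenotypes)
  m1 <- rowSums(is.na(data[paste0(phenotypes, "_1")]))
  m2 <- rowSums(is.na(data[paste0(phenotypes, "_2")]))
  table(factor(m1, levels = 0:M), factor(m2, levels = 0:M),
        dnn = c("twin_1_missing", "twin_2_missing"))
}

#' Run the full analysis pipeline
#'
#' Executes, from a configuration list or YAML file: data simulation (or CSV
#' input), Box-Cox transformation per phenotype (skipped for phenotypes in
#' `no_transform`), pooled rescaling to unit variance, univariate fits per
#' phenotype, the multivariate Cholesky fit, the decomposition tables, and
#' optionally the independent pathway model.  Every seed, estimated lambda and
#' scale factor is recorded in the result bundle; a failed stage marks the
#' bundle failed at that stage and preserves the diagnostics.
#'
#' Configuration fields: either `simulate = list(n_mz_pairs, n_dz_pairs, ...)`
#' (passed to [simulation_design()]; parameters default to
#' [reference_ade_parameters()] of `phenotypes`) or `input` (CSV path);
#' `phenotypes`; `teacher_rated` (labels); `no_transform` (labels);
#' `components`; `n_starts`; `seed`; `factor_model = list(factor_assignment,
#' components_with_factors)` (optional); `univariate` (logical, default TRUE).
#'
#' @param config A named list or path to a YAML file.
#' @param out Optional path: write the bundle (minus fitted objects) as JSON.
#' @return A list of class `twin_pipeline`.
#' @export
run_pipeline <- function(config, out = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  bundle <- list(config = config, seed = seed,
                 package_version = as.character(utils::packageVersion("twinade")),
                 failed_stage = NULL)
  run_stage <- function(name, expr) {
    if (!is.null(bundle$failed_stage)) return(NULL)
    tryCatch(expr, error = function(e) {
      bundle$failed_stage <<- name
      bundle$errors <- c(bundle$errors, setNames(conditionMessage(e), name))
      NULL
    })
  }

  data <- run_stage("input", {
    if (!is.null(config$input)) {
      read_twin_csv(config$input, quiet = TRUE)
    } else {
      ph <- config$phenotypes %||% c("SWAN_H", "CPRS_H", "TRF_H", "CTRS_H",
                                     "SWAN_I", "CPRS_I", "TRF_I", "CTRS_I")
      params <- reference_ade_parameters(ph)
      des_args <- config$simulate %||% list()
      des_args$seed <- seed
      design <- if (all(c("n_mz_pairs", "n_dz_pairs") %in% names(des_args))) {
        do.call(simulation_design, des_args)
      } else {
        d <- reference_design(ph, seed = seed)
        modifyList(d, des_args[setdiff(names(des_args), c("n_mz_pairs", "n_dz_pairs"))])
      }
      impose_missingness(simulate_twin_pairs(params, design), design)
    }
  })
  ph <- config$phenotypes %||% (if (!is.null(data)) detect_phenotypes(data))

  data <- run_stage("transform", {
    skip <- config$no_transform %||% character(0)
    lambdas <- setNames(rep(NA_real_, length(ph)), ph)
    for (p in setdiff(ph, skip)) {
      cols <- paste0(p, c("_1", "_2"))
      pooled <- unlist(data[cols], use.names = FALSE)
      shift <- min(pooled, na.rm = TRUE)  # Box-Cox needs y >= 0
      bc <- estimate_lambda(pooled - shift, phenotype = p)
      lambdas[p] <- bc$lambda
      for (cl in cols)
        data[[cl]] <- boxcox_transform(data[[cl]] - shift, bc$lambda)
    }
    bundle$lambdas <- lambdas
    data
  })

  data <- run_stage("standardize", {
    d <- standardize_scale(data, ph)
    bundle$scale_factors <- attr(d, "scale_factors")
    d
  })

  teacher <- ph %in% (config$teacher_rated %||% character(0))
  opts <- fit_options(n_starts = config$n_starts %||% 3, seed = seed)

  bundle$univariate <- run_stage("univariate", {
    if (isFALSE(config$univariate)) NULL else
      purrr::map(setNames(ph, ph), function(p) {
        sp <- ade_model_spec(p, teacher_rated = teacher[match(p, ph)],
                             components = config$components %||% c("A", "D", "E"))
        f <- fit_ade(data, sp, opts)
        list(components = standardized_components(f$estimates),
             loglik = f$loglik, converged = f$converged)
      })
  })

  fit <- run_stage("multivariate", {
    sp <- ade_model_spec(ph, teacher_rated = teacher,
                         components = config$components %||% c("A", "D", "E"))
    fit_ade(data, sp, opts)
  })
  bundle$fit <- fit

  bundle$decomposition <- run_stage("decompose", decompose_ade(fit$estimates))

  if (!is.null(config$factor_model))
    bundle$factor <- run_stage("factor", {
      fa <- config$factor_model$factor_assignment
      sp <- factor_spec(setNames(as.character(unlist(fa)), names(fa)),
                        config$factor_model$components_with_factors %||% c("A", "D", "E"))
      f <- fit_independent_pathway(data, sp, opts)
      list(estimates = f$estimates, loglik = f$loglik, converged = f$converged)
    })

  bundle$data <- data
  class(bundle) <- "twin_pipeline"
  if (!is.null(out)) {
    ser <- pipeline_serializable(bundle)
    jsonlite::write_json(ser, out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  bundle
}

## JSON-friendly view of the bundle (numbers and tables only)
pipeline_serializable <- function(bundle) {
  fit <- bundle$fit
  list(
    seed = bundle$seed,
    package_version = bundle$package_version,
    failed_stage = bundle$failed_stage,
    errors = bundle$errors,
    lambdas = as.list(bundle$lambdas),
    scale_factors = as.list(bundle$scale_factors),
    univariate = purrr::map(bundle$univariate, function(u)
      list(components = as.list(u$components), loglik = u$loglik,
           converged = u$converged)),
    multivariate = if (!is.null(fit)) list(
      loglik = fit$loglik, converged = fit$converged,
      n_pairs_used = fit$n_pairs_used,
      par = as.list(fit$par)),
    decomposition = if (!is.null(bundle$decomposition)) list(
      components = as.list(bundle$decomposition$components),
      corr_ad = unclass(bundle$decomposition$corr_ad),
      corr_e = unclass(bundle$decomposition$corr_e),
      prop_ad = unclass(bundle$decomposition$prop_ad),
      implied_pheno_corr = unclass(bundle$decomposition$implied_pheno_corr)),
    factor = if (!is.null(bundle$factor)) list(
      loglik = bundle$factor$loglik, converged = bundle$factor$converged))
}

#' @export
print.twin_pipeline <- function(x, ...) {
  cat("twinade pipeline bundle (seed", x$seed, ")\n")
  if (!is.null(x$failed_stage)) {
    cat("FAILED at stage:", x$failed_stage, "\n")
    cat(x$errors[[x$failed_stage]], "\n")
  } else {
    cat("stages: input, transform, standardize, univariate, multivariate, decompose",
        if (!is.null(x$factor)) ", factor", "\n", sep = "")
    if (!is.null(x$fit)) print(x$fit)
  }
  invisible(x)
}
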