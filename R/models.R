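# The statistical layer: covariate standardization, collinearity screen,
# 30-s thinning, binomial GLMMs with a per-bird random intercept (lme4),
# all-subsets model generation with Akaike-weight averaging, variance
# partition R-squared, k-fold predictive accuracy, and the nonparametric
# metric comparisons.

#' Standardize covariate columns
#'
#' Centres and scales the named columns to mean 0, SD 1 (denominator n-1),
#' recording the original mean and SD for back-transformation in the
#' `"scaling"` attribute. Standardizing makes model coefficients comparable
#' across covariates.
#'
#' @param data A data frame.
#' @param columns Character vector of numeric columns to scale.
#' @return `data` with the columns scaled and a `scaling` attribute (tibble
#'   of `column`, `mean`, `sd`).
#' @export
standardize <- function(data, columns) {
  miss <- setdiff(columns, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  scl <- tibble::tibble(
    column = columns,
    mean = unname(vapply(columns, function(cl) mean(data[[cl]]), 0)),
    sd = unname(vapply(columns, function(cl) stats::sd(data[[cl]]), 0))
  )
  if (any(scl$sd == 0)) {
    stop("cannot standardize constant column(s): ",
         paste(scl$column[scl$sd == 0], collapse = ", "))
  }
  for (i in seq_along(columns)) {
    data[[columns[i]]] <- (data[[columns[i]]] - scl$mean[i]) / scl$sd[i]
  }
  attr(data, "scaling") <- scl
  data
}

#' Screen covariates for collinearity
#'
#' Computes pairwise Pearson correlations and, for every pair at or above
#' `r_max` in absolute value, drops the lower-priority member (priority is
#' the order of `columns` unless overridden). The screen is applied
#' iteratively so the retained set has all pairwise `|r| < r_max`.
#'
#' @param data A data frame.
#' @param columns Columns to screen; defaults to all numeric columns.
#' @param r_max Correlation threshold (default 0.6, i.e. only variables with
#'   `r < 0.6` are used together).
#' @param priority Character vector, highest priority first.
#' @return A list with `retained` (character vector) and `dropped` (tibble of
#'   `dropped`, `against`, `r`).
#' @export
collinearity_screen <- function(data, columns = NULL, r_max = 0.6,
                                priority = NULL) {
  if (is.null(columns)) {
    columns <- names(data)[vapply(data, is.numeric, TRUE)]
  }
  if (is.null(priority)) priority <- columns
  rank_of <- function(x) match(x, priority, nomatch = length(priority) + 1L)
  retained <- columns
  dropped <- tibble::tibble(dropped = character(), against = character(),
                            r = numeric())
  repeat {
    if (length(retained) < 2) break
    cm <- stats::cor(data[retained])
    diag(cm) <- 0
    worst <- which(abs(cm) == max(abs(cm)), arr.ind = TRUE)[1, ]
    if (max(abs(cm)) < r_max) break
    a <- retained[worst[1]]; b <- retained[worst[2]]
    loser <- if (rank_of(a) <= rank_of(b)) b else a
    winner <- setdiff(c(a, b), loser)
    dropped <- dplyr::bind_rows(dropped, tibble::tibble(
      dropped = loser, against = winner, r = cm[worst[1], worst[2]]
    ))
    retained <- setdiff(retained, loser)
  }
  list(retained = retained, dropped = dropped)
}

#' Thin 1 Hz labelled fixes to one row per 30 s
#'
#' Divides each burst into non-overlapping blocks of `block_s` consecutive
#' fixes, keeps only complete blocks, and emits one row per block: the
#' behaviour at the block's first fix as the response and the block means of
#' the weather covariates. Thinning reduces the residual autocorrelation
#' that full 1 Hz data induce in the behaviour models.
#'
#' @param fixes A tibble of labelled annotated fixes with a burst identifier
#'   column, a behaviour column and weather covariates.
#' @param covariate_cols Covariate columns to average.
#' @param block_s Block length in fixes/seconds (default 30).
#' @param burst_col Name of the burst identifier column.
#' @param behavior_col Name of the behaviour column.
#' @return A tibble with `bird_id`, the burst id, `block`, the behaviour,
#'   block-start `timestamp` and averaged covariates.
#' @export
thin_30s <- function(fixes, covariate_cols, block_s = 30,
                     burst_col = "segment_id", behavior_col = "behavior") {
  need <- c("bird_id", burst_col, behavior_col)
  miss <- setdiff(c(need, covariate_cols), names(fixes))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  fixes |>
    dplyr::group_by(.data$bird_id, .data[[burst_col]]) |>
    dplyr::mutate(block = (dplyr::row_number() - 1L) %/% block_s,
                  .in_block = dplyr::row_number() - 1L - .data$block * block_s) |>
    dplyr::group_by(.data$block, .add = TRUE) |>
    dplyr::filter(dplyr::n() == block_s) |>
    dplyr::summarise(
      behavior = .data[[behavior_col]][1],
      timestamp = .data$timestamp[1],
      dplyr::across(dplyr::all_of(covariate_cols), mean),
      .groups = "drop"
    )
}

# ---- model specification and fitting ---------------------------------------

#' Specify a binomial (mixed) model family
#'
#' @param response Name of the binary response column.
#' @param terms Character vector of fixed-effect terms, e.g.
#'   `c("tailwind", "sidewind", "delta_T", "tailwind:delta_T")` or
#'   `"poly(tailwind, 2)"`. Polynomial terms are treated as a single unit by
#'   the subset generator; an interaction enters a subset only when both of
#'   its parent variables are present (marginality).
#' @param random_intercept Include a per-bird random intercept?
#' @param group Grouping column for the random intercept.
#' @param criterion `"AIC"` or `"AICc"` for model ranking.
#' @return A `model_spec` object.
#' @export
model_spec <- function(response, terms, random_intercept = TRUE,
                       group = "bird_id", criterion = c("AIC", "AICc")) {
  criterion <- match.arg(criterion)
  if (anyDuplicated(terms)) stop("model terms must be unique")
  spec <- list(response = response, terms = terms,
               random_intercept = random_intercept, group = group,
               criterion = criterion)
  class(spec) <- "model_spec"
  spec
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", x$response, " ~ ",
      paste(x$terms, collapse = " + "),
      if (x$random_intercept) paste0(" + (1 | ", x$group, ")") else "",
      "  [", x$criterion, "]\n", sep = "")
  invisible(x)
}

# Variable underlying a term unit: poly(x, 2) -> x, x:y -> c(x, y).
.term_vars <- function(term) {
  if (grepl(":", term, fixed = TRUE)) {
    return(unlist(lapply(strsplit(term, ":", fixed = TRUE)[[1]], .term_vars)))
  }
  m <- regmatches(term, regexec("^poly\\(\\s*([^,\\s]+)", term))[[1]]
  if (length(m) == 2) m[2] else term
}

.build_formula <- function(spec, terms = spec$terms) {
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  re <- if (spec$random_intercept) paste0(" + (1 | ", spec$group, ")") else ""
  stats::as.formula(paste0(spec$response, " ~ ", rhs, re))
}

#' Fit one binomial (mixed) model
#'
#' Logit-link binomial fit: `lme4::glmer` with a Laplace approximation when a
#' random intercept is requested, `stats::glm` otherwise. Convergence
#' warnings are captured and flagged rather than raised.
#'
#' @param spec A [model_spec()].
#' @param data The model table.
#' @param terms Optional term subset to fit (defaults to the full spec).
#' @return A `glmm_fit` list: `model`, `coefs` (tibble of `term`,
#'   `estimate`, `std_error`, `z`, `p`), `aic`, `aicc`, `criterion_value`,
#'   `n`, `k`, `converged`, `terms`.
#' @export
fit_glmm <- function(spec, data, terms = spec$terms) {
  stopifnot(inherits(spec, "model_spec"))
  if (!all(data[[spec$response]] %in% c(0, 1))) {
    stop("response must be binary 0/1")
  }
  if (spec$random_intercept &&
      length(unique(data[[spec$group]])) < 2) {
    stop("random intercept requested but fewer than 2 groups present")
  }
  f <- .build_formula(spec, terms)
  warn <- character()
  fit <- withCallingHandlers(
    if (spec$random_intercept) {
      lme4::glmer(f, data = data, family = stats::binomial())
    } else {
      stats::glm(f, data = data, family = stats::binomial())
    },
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  converged <- if (inherits(fit, "merMod")) {
    # a singular fit (random-effect variance on the boundary) is a valid
    # optimum, not a convergence failure
    msgs <- c(fit@optinfo$conv$lme4$messages, warn)
    msgs <- msgs[!grepl("singular", msgs, ignore.case = TRUE)]
    !any(grepl("converge", msgs, ignore.case = TRUE))
  } else {
    isTRUE(fit$converged)
  }
  cf <- if (inherits(fit, "merMod")) {
    summary(fit)$coefficients
  } else {
    summary(fit)$coefficients
  }
  coefs <- tibble::tibble(
    term = rownames(cf),
    estimate = unname(cf[, 1]), std_error = unname(cf[, 2]),
    z = unname(cf[, 1] / cf[, 2]),
    p = unname(2 * stats::pnorm(-abs(cf[, 1] / cf[, 2])))
  )
  n <- stats::nobs(fit)
  k <- attr(stats::logLik(fit), "df")
  aic <- stats::AIC(fit)
  aicc <- aic + 2 * k * (k + 1) / (n - k - 1)
  out <- list(model = fit, coefs = coefs, aic = aic, aicc = aicc,
              criterion_value = if (spec$criterion == "AICc") aicc else aic,
              n = n, k = k, converged = converged, terms = terms,
              spec = spec)
  class(out) <- "glmm_fit"
  out
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat("<glmm_fit> ", deparse(.build_formula(x$spec, x$terms)), "\n", sep = "")
  cat("  n = ", x$n, ", AIC = ", round(x$aic, 2),
      if (!x$converged) "  [NOT CONVERGED]" else "", "\n", sep = "")
  print(as.data.frame(x$coefs), digits = 3)
  invisible(x)
}

# All term subsets of a spec respecting marginality; poly units are atomic
# and an interaction requires both parent variables.
.term_subsets <- function(terms) {
  mains <- terms[!grepl(":", terms, fixed = TRUE)]
  ints <- setdiff(terms, mains)
  main_sets <- unlist(lapply(0:length(mains), function(k) {
    utils::combn(mains, k, simplify = FALSE)
  }), recursive = FALSE)
  out <- list()
  for (ms in main_sets) {
    have <- unlist(lapply(ms, .term_vars))
    ok_ints <- ints[vapply(ints, function(it) {
      all(.term_vars(it) %in% have)
    }, TRUE)]
    int_sets <- unlist(lapply(0:length(ok_ints), function(k) {
      utils::combn(ok_ints, k, simplify = FALSE)
    }), recursive = FALSE)
    for (is_ in int_sets) out[[length(out) + 1L]] <- c(ms, is_)
  }
  out
}

#' All-subsets model selection with Akaike-weight averaging
#'
#' Fits every fixed-term subset of the spec that respects marginality, ranks
#' them by AIC or AICc, and averages coefficients over the models within
#' `delta` of the best using Akaike weights. Full (zero-substituted)
#' averaging is the default: a term absent from a model contributes an
#' estimate of 0 with no sampling variance, shrinking weakly supported
#' effects; `method = "conditional"` averages only over the models that
#' contain each term. Averaged standard errors use the usual
#' variance-plus-squared-deviation form.
#'
#' @param spec A [model_spec()].
#' @param data The model table.
#' @param delta Criterion difference defining the averaging set (default 2).
#' @param method `"full"` or `"conditional"` averaging.
#' @param accuracy Compute 10-fold predictive accuracy of the best model?
#' @param folds Number of cross-validation folds.
#' @param fold_seed Seed for the fold assignment (recorded in the result).
#' @return A `model_result` list: `coefs` (averaged tibble), `n_models_fit`,
#'   `n_models_averaged`, `weights`, `model_table` (per-model terms and
#'   criterion values), `best` ([fit_glmm()] result for the best model),
#'   `r2_marginal`, `r2_conditional`, `predictive_accuracy`, `fold_seed`.
#' @export
dredge_average <- function(spec, data, delta = 2,
                           method = c("full", "conditional"),
                           accuracy = TRUE, folds = 10, fold_seed = 1L) {
  method <- match.arg(method)
  subsets <- .term_subsets(spec$terms)
  fits <- lapply(subsets, function(tm) fit_glmm(spec, data, terms = tm))
  conv <- vapply(fits, function(f) f$converged, TRUE)
  if (any(!conv)) {
    warning(sum(!conv), " model(s) failed to converge and were excluded ",
            "from averaging")
    fits <- fits[conv]
    subsets <- subsets[conv]
  }
  if (length(fits) == 0) stop("no model converged")
  crit <- vapply(fits, function(f) f$criterion_value, 0)
  dlt <- crit - min(crit)
  in_set <- dlt < delta
  w <- exp(-dlt[in_set] / 2)
  w <- w / sum(w)
  avg_fits <- fits[in_set]

  all_terms <- unique(unlist(lapply(avg_fits, function(f) f$coefs$term)))
  # keep the ordering of the full model where possible
  full_order <- fits[[which.max(vapply(subsets, length, 0L))]]$coefs$term
  all_terms <- c(intersect(full_order, all_terms),
                 setdiff(all_terms, full_order))

  avg <- lapply(all_terms, function(tm) {
    est <- vapply(avg_fits, function(f) {
      i <- match(tm, f$coefs$term)
      if (is.na(i)) 0 else f$coefs$estimate[i]
    }, 0)
    se <- vapply(avg_fits, function(f) {
      i <- match(tm, f$coefs$term)
      if (is.na(i)) 0 else f$coefs$std_error[i]
    }, 0)
    present <- vapply(avg_fits, function(f) tm %in% f$coefs$term, TRUE)
    if (method == "full") {
      wt <- w
    } else {
      if (!any(present)) return(NULL)
      wt <- w[present] / sum(w[present])
      est <- est[present]
      se <- se[present]
    }
    e_bar <- sum(wt * est)
    se_bar <- sum(wt * sqrt(se^2 + (est - e_bar)^2))
    tibble::tibble(term = tm, estimate = e_bar, std_error = se_bar,
                   z = e_bar / se_bar,
                   p = 2 * stats::pnorm(-abs(e_bar / se_bar)),
                   n_containing = sum(present))
  })
  coefs <- dplyr::bind_rows(avg)

  best <- avg_fits[[which.min(crit[in_set])]]
  r2 <- nakagawa_r2(best)
  pa <- if (accuracy) {
    kfold_accuracy(spec, data, k = folds, terms = best$terms,
                   fold_seed = fold_seed)
  } else NA_real_

  model_table <- tibble::tibble(
    terms = vapply(subsets, function(tm) {
      if (length(tm)) paste(tm, collapse = " + ") else "(intercept only)"
    }, ""),
    k = vapply(fits, function(f) f$k, 0),
    criterion = crit, delta = dlt, averaged = in_set
  )
  out <- list(coefs = coefs, n_models_fit = length(fits),
              n_models_averaged = sum(in_set), weights = w,
              model_table = model_table[order(model_table$delta), ],
              best = best,
              r2_marginal = r2[["r2_marginal"]],
              r2_conditional = r2[["r2_conditional"]],
              predictive_accuracy = as.numeric(pa), fold_seed = fold_seed,
              method = method, delta = delta)
  class(out) <- "model_result"
  out
}

#' @export
print.model_result <- function(x, ...) {
  cat("<model_result> averaged over ", x$n_models_averaged, " of ",
      x$n_models_fit, " models (", x$method, " averaging, delta < ",
      x$delta, ")\n", sep = "")
  print(as.data.frame(x$coefs), digits = 3)
  cat("  R2m = ", round(x$r2_marginal, 3),
      ", R2c = ", round(x$r2_conditional, 3), sep = "")
  if (is.finite(x$predictive_accuracy)) {
    cat(", predictive accuracy = ", round(100 * x$predictive_accuracy), "%",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Variance-partition R-squared for binomial logit models
#'
#' The marginal R-squared is the fixed-effect variance over the total
#' (fixed + random-intercept + logit-link distribution variance pi^2/3);
#' the conditional R-squared adds the random-effect variance to the
#' numerator. For a plain GLM the two coincide.
#'
#' @param fit A [fit_glmm()] result, `merMod` or `glm`.
#' @return Named numeric vector `c(r2_marginal, r2_conditional)`.
#' @export
nakagawa_r2 <- function(fit) {
  if (inherits(fit, "glmm_fit")) fit <- fit$model
  if (inherits(fit, "merMod")) {
    X <- lme4::getME(fit, "X")
    var_f <- stats::var(as.vector(X %*% lme4::fixef(fit)))
    vc <- lme4::VarCorr(fit)
    var_re <- sum(vapply(vc, function(m) sum(diag(m)), 0))
  } else {
    eta <- stats::predict(fit, type = "link")
    var_f <- stats::var(eta)
    var_re <- 0
  }
  var_d <- pi^2 / 3
  tot <- var_f + var_re + var_d
  c(r2_marginal = var_f / tot, r2_conditional = (var_f + var_re) / tot)
}

#' K-fold predictive accuracy
#'
#' Rows are partitioned into `k` folds stratified by the response; each fold
#' is predicted from a model fitted on the remaining folds and scored as the
#' proportion of held-out responses correctly predicted at a 0.5 probability
#' cutoff. The fold assignment is seeded so the measure is reproducible.
#'
#' @param spec A [model_spec()].
#' @param data The model table.
#' @param k Number of folds (default 10).
#' @param terms Term subset to fit (defaults to the full spec).
#' @param fold_seed Seed for the fold assignment.
#' @return Mean held-out accuracy (numeric scalar) with the per-fold values
#'   in attribute `"per_fold"`.
#' @export
kfold_accuracy <- function(spec, data, k = 10, terms = spec$terms,
                           fold_seed = 1L) {
  y <- data[[spec$response]]
  n <- length(y)
  fold <- integer(n)
  rng <- local({
    set.seed(fold_seed)
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <<- rep_len(seq_len(k), length(idx))
    }
  })
  acc <- vapply(seq_len(k), function(i) {
    train <- data[fold != i, , drop = FALSE]
    test <- data[fold == i, , drop = FALSE]
    fit <- fit_glmm(spec, train, terms = terms)
    p <- if (inherits(fit$model, "merMod")) {
      stats::predict(fit$model, newdata = test, type = "response",
                     allow.new.levels = TRUE)
    } else {
      stats::predict(fit$model, newdata = test, type = "response")
    }
    mean((p >= 0.5) == (test[[spec$response]] == 1))
  }, 0)
  out <- mean(acc)
  attr(out, "per_fold") <- acc
  out
}

#' Compare a flight metric between two groups
#'
#' The nonparametric comparison used for sea-versus-land flight metrics:
#' Shapiro-Wilk normality per group followed by a two-sided Mann-Whitney U
#' test (the W statistic of `stats::wilcox.test` is the U statistic).
#'
#' @param a,b Numeric samples.
#' @return A list with `shapiro_a`, `shapiro_b` (`htest`, `NULL` when the
#'   group is too small), `u` (the U statistic) and `p`.
#' @export
compare_metrics <- function(a, b) {
  sw <- function(x) {
    if (length(x) >= 3 && length(x) <= 5000) stats::shapiro.test(x) else NULL
  }
  mw <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
  list(shapiro_a = sw(a), shapiro_b = sw(b),
       u = unname(mw$statistic), p = mw$p.value, test = mw)
}

#' Chi-square test on a contingency table
#'
#' @param counts A matrix (or table) of counts.
#' @return The `htest` from `stats::chisq.test` without continuity
#'   correction.
#' @export
compare_counts <- function(counts) {
  stats::chisq.test(as.matrix(counts), correct = FALSE)
}
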