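#' ROC analysis of a diagnostic score
#'
#' Full threshold sweep with trapezoid AUC (via [pROC::roc()]); higher
#' scores predict the positive class. The AUC equals the tie-averaged
#' Mann-Whitney U statistic divided by `n_pos * n_neg`.
#'
#' @param data Data frame holding scores and class labels.
#' @param score,label Column names (strings) of the numeric score and the
#'   class label.
#' @param positive Label of the positive class; default `"stroke"`.
#' @return An `sdi_roc` object; `glance()` gives `auc`, `n_pos`, `n_neg`;
#'   `tidy()` the threshold / sensitivity / specificity sweep;
#'   `autoplot()` the ROC curve.
#' @export
roc_analysis <- function(data, score = "sdi", label = "group",
                         positive = "stroke") {
  y <- as.character(data[[label]])
  x <- data[[score]]
  classes <- unique(y)
  if (!(positive %in% classes) || length(classes) != 2) {
    abort("both classes must be present, one of them `positive`")
  }
  negative <- setdiff(classes, positive)
  r <- pROC::roc(response = y, predictor = x,
                 levels = c(negative, positive), direction = "<",
                 quiet = TRUE)
  structure(
    list(
      auc = as.numeric(pROC::auc(r)),
      curve = tibble(threshold = r$thresholds,
                     sensitivity = r$sensitivities,
                     specificity = r$specificities),
      n_pos = sum(y == positive), n_neg = sum(y == negative),
      positive = positive
    ),
    class = "sdi_roc"
  )
}

#' @export
print.sdi_roc <- function(x, ...) {
  cat(sprintf("<sdi_roc> AUC = %.1f%% (%d positive, %d negative)\n",
              100 * x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
tidy.sdi_roc <- function(x, ...) x$curve

#' @export
glance.sdi_roc <- function(x, ...) {
  tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Spearman rank correlation
#'
#' Midrank Spearman rho with the p-value of [stats::cor.test()] (exact
#' enumeration for small untied samples, t/AS89 approximation otherwise).
#' Constant input is flagged with a warning and returns `NA` rho.
#'
#' @param x,y Numeric vectors, `n >= 3`.
#' @return Tibble with `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("need at least 3 complete pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warn("constant input: Spearman correlation undefined")
    return(tibble(rho = NA_real_, p_value = NA_real_, n = length(x)))
  }
  ht <- suppressWarnings(cor.test(x, y, method = "spearman"))
  tibble(rho = unname(ht$estimate), p_value = ht$p.value, n = length(x))
}

#' Group characteristics table
#'
#' Per-variable two-group comparison in the style of clinical baseline
#' tables. Continuous variables: if Shapiro-Wilk does not reject normality
#' in either group (p > 0.05), mean (SD) with Welch t-test, otherwise
#' median (IQR) with Wilcoxon rank-sum. Binary/categorical variables:
#' n (%) with chi-square, switching to Fisher's exact test when any
#' expected or observed cell count is below 5.
#'
#' @param records Data frame of per-sample records.
#' @param group Name of the two-level grouping column.
#' @param vars Variables to summarize; default all columns except
#'   `sample_id` and the grouping column.
#' @return Tibble with one row per variable: `variable`, `type`, the two
#'   formatted group summaries, `p_value` and `test`.
#' @export
summarize_groups <- function(records, group = "group", vars = NULL) {
  g <- as.factor(records[[group]])
  if (nlevels(g) != 2) abort("grouping must have exactly two levels")
  if (any(table(g) == 0)) abort("empty group")
  vars <- vars %||% setdiff(names(records), c("sample_id", group))
  lv <- levels(g)
  rows <- purrr::map(vars, function(v) {
    x <- records[[v]]
    ok <- !is.na(x)
    x1 <- x[ok & g == lv[1]]; x2 <- x[ok & g == lv[2]]
    if (is.numeric(x) && length(unique(x[ok])) > 2) {
      normal <- shapiro_ok(x1) && shapiro_ok(x2)
      if (normal) {
        p <- tryCatch(t.test(x1, x2)$p.value, error = function(e) NA_real_)
        tibble(variable = v, type = "continuous",
               g1 = sprintf("%.2f (%.2f)", mean(x1), sd(x1)),
               g2 = sprintf("%.2f (%.2f)", mean(x2), sd(x2)),
               p_value = p, test = "t")
      } else {
        p <- rank_sum_test(x1, x2)$p_value
        tibble(variable = v, type = "continuous",
               g1 = sprintf("%.2f (%.2f)", median(x1), IQR(x1)),
               g2 = sprintf("%.2f (%.2f)", median(x2), IQR(x2)),
               p_value = p, test = "wilcoxon")
      }
    } else {
      xf <- factor(x[ok])
      tab <- table(xf, droplevels(g[ok]))
      lev <- if (nlevels(xf) == 2) levels(xf)[2] else levels(xf)[1]
      n1 <- sum(xf[g[ok] == lv[1]] == lev); N1 <- sum(g[ok] == lv[1])
      n2 <- sum(xf[g[ok] == lv[2]] == lev); N2 <- sum(g[ok] == lv[2])
      if (nrow(tab) < 2) {
        p <- 1; test <- "none"
      } else {
        expected <- suppressWarnings(chisq.test(tab, correct = FALSE)$expected)
        if (any(expected < 5) || any(tab < 5)) {
          p <- fisher.test(tab)$p.value; test <- "fisher"
        } else {
          p <- suppressWarnings(chisq.test(tab)$p.value); test <- "chisq"
        }
      }
      tibble(variable = v, type = "categorical",
             g1 = sprintf("%d (%.1f%%)", n1, 100 * n1 / N1),
             g2 = sprintf("%d (%.1f%%)", n2, 100 * n2 / N2),
             p_value = p, test = test)
    }
  }) |> purrr::list_rbind()
  names(rows)[names(rows) == "g1"] <- lv[1]
  names(rows)[names(rows) == "g2"] <- lv[2]
  rows
}

shapiro_ok <- function(x) {
  if (length(x) < 3 || length(unique(x)) == 1L) return(FALSE)
  if (length(x) > 5000) x <- sample(x, 5000)
  tryCatch(shapiro.test(x)$p.value > 0.05, error = function(e) FALSE)
}

#' Univariate screen for model candidates
#'
#' Fits a single-covariate logistic regression per candidate predictor of a
#' dichotomized clinical outcome and flags those with Wald p below `p_in`
#' for inclusion in the multivariable model. Severity is `nihss_in >= 8`,
#' unfavorable outcome `mrs_out > 2`; NIHSS and mRS columns are never used
#' as predictors because they define the outcomes.
#'
#' @param records Patient records (one row per patient) with the outcome
#'   ingredients and candidate covariates.
#' @param outcome `"severe"` (NIHSS on admission >= 8) or `"unfavorable"`
#'   (mRS at discharge > 2).
#' @param p_in Screening threshold; default 0.20 (strict `<`).
#' @param predictors Candidate columns; default every column except ids,
#'   group and the NIHSS/mRS scores.
#' @return Tibble per candidate: `term`, `estimate`, `odds_ratio`,
#'   `p_value`, `separation`, `included`. Predictors with perfect
#'   separation are flagged with an infinite odds-ratio sentinel.
#' @export
univariate_screen <- function(records, outcome = c("severe", "unfavorable"),
                              p_in = 0.20, predictors = NULL) {
  outcome <- match.arg(outcome)
  y <- clinical_outcome(records, outcome)
  predictors <- predictors %||%
    setdiff(names(records),
            c("sample_id", "group", "nihss_in", "nihss_out", "mrs_out"))
  purrr::map(predictors, function(v) {
    d <- tibble(y = y, x = records[[v]])
    d <- d[complete.cases(d), ]
    fit <- tryCatch(
      logistic_fit(d, outcome_col = "y", predictors = "x"),
      sdindex_separation = function(c) NULL,
      error = function(e) NA
    )
    if (is.null(fit)) {
      tibble(term = v, estimate = Inf, odds_ratio = Inf, p_value = NA_real_,
             separation = TRUE, included = TRUE)
    } else if (!inherits(fit, "sdi_logistic")) {
      tibble(term = v, estimate = NA_real_, odds_ratio = NA_real_,
             p_value = NA_real_, separation = FALSE, included = FALSE)
    } else {
      td <- tidy(fit)
      row <- td[td$term != "(Intercept)", ][1, ]
      tibble(term = v, estimate = row$estimate, odds_ratio = row$odds_ratio,
             p_value = row$p_value, separation = FALSE,
             included = !is.na(row$p_value) && row$p_value < p_in)
    }
  }) |> purrr::list_rbind()
}

clinical_outcome <- function(records, outcome) {
  switch(outcome,
    severe = {
      if (!"nihss_in" %in% names(records)) abort("`nihss_in` column required")
      records$nihss_in >= 8
    },
    unfavorable = {
      if (!"mrs_out" %in% names(records)) abort("`mrs_out` column required")
      records$mrs_out > 2
    },
    abort("unknown outcome")
  )
}

#' Multivariable logistic regression with Wald intervals
#'
#' Maximum-likelihood logit fit (IRLS via [stats::glm()], convergence
#' tolerance 1e-8, at most 100 iterations). Odds ratios are `exp(estimate)`
#' with Wald 95% intervals `exp(estimate +- 1.96 SE)`. Perfect separation
#' raises an error naming the offending covariate; non-convergence is
#' reported, never silent.
#'
#' @param data Data frame with the outcome and predictor columns.
#' @param outcome_col Name of the outcome column (logical/0-1), or one of
#'   `"severe"` / `"unfavorable"` to derive it from NIHSS/mRS columns.
#' @param predictors Character vector of predictor columns; empty for an
#'   intercept-only model.
#' @return An `sdi_logistic` object wrapping the glm fit; `tidy()` gives
#'   `term`, `estimate`, `std_error`, `odds_ratio`, `conf_low`,
#'   `conf_high`, `p_value`; `glance()` gives `n`, `n_events`, `converged`,
#'   `outcome`.
#' @export
logistic_fit <- function(data, outcome_col, predictors = character()) {
  if (outcome_col %in% c("severe", "unfavorable")) {
    y <- clinical_outcome(data, outcome_col)
    outcome_name <- outcome_col
  } else {
    y <- data[[outcome_col]]
    outcome_name <- outcome_col
  }
  y <- as.logical(y)
  keep <- !is.na(y)
  if (length(predictors)) {
    keep <- keep & complete.cases(data[predictors])
  }
  d <- data[keep, , drop = FALSE]
  y <- y[keep]
  if (nrow(d) <= length(predictors) + 1) {
    abort("need more observations than model terms")
  }
  if (all(!y)) abort("no events: outcome is all FALSE")
  if (all(y)) abort("no non-events: outcome is all TRUE")
  d$.outcome <- y
  fml <- if (length(predictors)) {
    as.formula(paste(".outcome ~", paste(sprintf("`%s`", predictors),
                                         collapse = " + ")))
  } else {
    .outcome ~ 1
  }
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(fml, data = d, family = binomial(),
        control = list(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  se <- sqrt(diag(vcov(fit)))
  # a perfectly separating covariate drives the residual deviance to zero
  # (every outcome fitted with probability ~0 or ~1); glm's own warning only
  # fires when fitted values reach machine epsilon, so check the deviance too
  separated <- length(predictors) &&
    (fit$deviance < 1e-6 || (sep_warn && any(se[-1] > 100)))
  if (separated) {
    bad <- names(coef(fit))[-1][which.max(se[-1])]
    abort(paste0("perfect separation on covariate ", gsub("`", "", bad)),
          class = "sdindex_separation")
  }
  if (!fit$converged) {
    warn("logistic fit did not converge within 100 iterations")
  }
  structure(
    list(fit = fit, n = nrow(d), n_events = sum(y), outcome = outcome_name,
         converged = fit$converged),
    class = "sdi_logistic"
  )
}

#' @export
print.sdi_logistic <- function(x, ...) {
  cat(sprintf("<sdi_logistic> outcome `%s`: %d events / %d observations%s\n",
              x$outcome, x$n_events, x$n,
              if (x$converged) "" else " (NOT converged)"))
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.sdi_logistic <- function(x, ...) {
  est <- coef(x$fit)
  se <- sqrt(diag(vcov(x$fit)))
  z <- est / se
  tibble(
    term = gsub("`", "", names(est)),
    estimate = unname(est),
    std_error = unname(se),
    odds_ratio = exp(unname(est)),
    conf_low = exp(unname(est - 1.96 * se)),
    conf_high = exp(unname(est + 1.96 * se)),
    p_value = 2 * stats::pnorm(-abs(unname(z)))
  )
}

#' @export
glance.sdi_logistic <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events, converged = x$converged,
         outcome = x$outcome)
}

#' Edema-corrected infarct volume
#'
#' Applies the per-section edema correction
#' `ischemic area = direct lesion area - (ipsilateral - contralateral
#' hemisphere area)`, floored at zero, and integrates over sections:
#' `volume = sum(corrected area) * section_interval`.
#'
#' @param direct_lesion_areas,ipsi_areas,contra_areas Equal-length numeric
#'   vectors of per-section areas (e.g. mm^2).
#' @param section_interval Distance between sections (same length unit).
#' @return List with `corrected_areas` and `volume`.
#' @examples
#' correct_infarct(5, 12, 10, 0.4)  # corrected area 3, volume 1.2
#' @export
correct_infarct <- function(direct_lesion_areas, ipsi_areas, contra_areas,
                            section_interval) {
  n <- length(direct_lesion_areas)
  if (length(ipsi_areas) != n || length(contra_areas) != n) {
    abort("area vectors must have equal length")
  }
  if (!is.numeric(section_interval) || length(section_interval) != 1 ||
      section_interval <= 0) {
    abort("`section_interval` must be a single positive number")
  }
  corrected <- pmax(direct_lesion_areas - (ipsi_areas - contra_areas), 0)
  list(corrected_areas = corrected,
       volume = sum(corrected) * section_interval)
}
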