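# Standard vs. hierarchical binary logistic readmission models and their
# comparison: discrimination (C-statistic, paired DeLong test), calibration
# (calibration-in-the-large and slope), per-subgroup discrimination, net
# reclassification improvement and integrated discrimination improvement.

#' Fit a standard or hierarchical readmission model
#'
#' Binary logistic regression of 30-day readmission (`is_case`) on the
#' selected comorbidities and demographics; the hierarchical variant adds
#' subgroup membership as K-1 indicator variables with subgroup 1 as the
#' reference (a single integer coding would impose ordinality). Complete
#' separation is detected and handled with a small ridge refit (recorded on
#' the model).
#'
#' @param data Training `data.frame` with `is_case`, the comorbidity and
#'   demographic columns, and (for the hierarchical model) the membership
#'   column.
#' @param kind `"standard"` or `"hierarchical"`.
#' @param comorbidities Comorbidity predictor columns.
#' @param demographics Demographic predictor columns (may be empty).
#' @param membership Membership column name (hierarchical only).
#' @param ridge_lambda Ridge penalty used by the separation fallback.
#' @return Object of class `prediction_model`.
#' @export
fit_prediction_model <- function(data, kind = c("standard", "hierarchical"),
                                 comorbidities,
                                 demographics = c("age_band", "sex", "race",
                                                  "medicaid"),
                                 membership = "assigned_subgroup",
                                 ridge_lambda = 1e-4) {
  kind <- match.arg(kind)
  demographics <- intersect(demographics, names(data))
  vars <- c(comorbidities, demographics)
  dat <- data[c(comorbidities, demographics)]
  for (v in demographics) dat[[v]] <- factor(dat[[v]])
  if (kind == "hierarchical") {
    stopifnot(membership %in% names(data))
    dat$.subgroup <- factor(data[[membership]],
                            levels = sort(unique(data[[membership]])))
    vars <- c(vars, ".subgroup")
  }
  dat$.y <- as.integer(data$is_case)
  f <- reformulate(sprintf("`%s`", setdiff(names(dat), ".y")),
                   response = ".y")
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(f, data = dat, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  # glm's own warning threshold (10 * eps) misses clear separation; flag
  # fits whose probabilities saturate or that did not converge
  separation <- separation || !fit$converged ||
    any(fit$fitted.values > 1 - 1e-10) || any(fit$fitted.values < 1e-10)
  ridge <- NULL
  if (separation) {
    mm <- stats::model.matrix(f, dat)
    ridge <- glmnet::glmnet(mm[, -1, drop = FALSE], dat$.y,
                            family = "binomial", alpha = 0,
                            lambda = ridge_lambda)
  }
  structure(list(kind = kind, fit = fit, ridge = ridge,
                 separation = separation, formula = f,
                 comorbidities = comorbidities, demographics = demographics,
                 membership = if (kind == "hierarchical") membership else NULL,
                 subgroup_levels = if (kind == "hierarchical")
                   levels(dat$.subgroup) else NULL,
                 xlevels = fit$xlevels),
            class = "prediction_model")
}

# Rebuild the model frame used at fit time from new data.
prediction_frame <- function(model, newdata) {
  dat <- newdata[c(model$comorbidities, model$demographics)]
  for (v in model$demographics)
    dat[[v]] <- factor(dat[[v]], levels = model$xlevels[[v]] %||%
                         sort(unique(as.character(dat[[v]]))))
  if (model$kind == "hierarchical")
    dat$.subgroup <- factor(newdata[[model$membership]],
                            levels = model$subgroup_levels)
  dat
}

#' Predict from a readmission model
#'
#' @param object A [fit_prediction_model()] result.
#' @param newdata Data with the model's predictor columns.
#' @param type `"link"` for the linear predictor, `"response"` for the
#'   predicted probability.
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.prediction_model <- function(object, newdata,
                                     type = c("link", "response"), ...) {
  type <- match.arg(type)
  dat <- prediction_frame(object, newdata)
  if (!is.null(object$ridge)) {
    dat$.y <- 0L
    mm <- stats::model.matrix(object$formula, dat)
    lp <- as.numeric(mm[, -1, drop = FALSE] %*%
                       as.numeric(object$ridge$beta) + object$ridge$a0)
  } else {
    lp <- as.numeric(predict(object$fit, newdata = dat, type = "link"))
  }
  if (type == "link") lp else plogis(lp)
}

#' @export
print.prediction_model <- function(x, ...) {
  cat(sprintf("%s readmission model: %d coefficients%s\n", x$kind,
              length(coef(x$fit)),
              if (x$separation) " (separation; ridge fallback recorded)" else ""))
  invisible(x)
}

# --- discrimination ---------------------------------------------------------

roc_of <- function(scores, outcomes) {
  outcomes <- as.logical(outcomes)
  if (length(unique(outcomes)) < 2)
    stop("validation data contain a single outcome class")
  pROC::roc(response = outcomes, predictor = as.numeric(scores),
            levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
}

#' C-statistic with DeLong confidence interval
#'
#' `C = P(score_case > score_control) + 0.5 * P(tie)` over all case-control
#' pairs (the ROC AUC), with a 95% CI from the DeLong variance estimator.
#'
#' @param x A [fit_prediction_model()] result, or a numeric score vector.
#' @param ... Passed to methods.
#' @return Object of class `discrimination_result`: `c_statistic`, `ci95`,
#'   `n_cases`, `n_controls`.
#' @export
c_statistic <- function(x, ...) UseMethod("c_statistic")

#' @rdname c_statistic
#' @param validation Validation `data.frame` with `is_case`.
#' @export
c_statistic.prediction_model <- function(x, validation, ...) {
  c_statistic(predict(x, validation, type = "link"),
              outcomes = validation$is_case)
}

#' @rdname c_statistic
#' @param outcomes Logical (or 0/1) outcome vector aligned with the scores.
#' @export
c_statistic.default <- function(x, outcomes, ...) {
  r <- roc_of(x, outcomes)
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong")))
  structure(list(c_statistic = as.numeric(r$auc),
                 ci95 = c(ci[1], ci[3]),
                 n_cases = sum(as.logical(outcomes)),
                 n_controls = sum(!as.logical(outcomes))),
            class = "discrimination_result")
}

#' @export
print.discrimination_result <- function(x, ...) {
  cat(sprintf("C-statistic %.3f (95%% CI %.3f-%.3f)\n",
              x$c_statistic, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Compare two models' C-statistics on the same validation patients
#'
#' Paired DeLong contrast of correlated AUCs; the squared z statistic is
#' reported as a 1-df chi-squared with a two-sided P. Identical score
#' vectors give `chi2 = 0`, `p = 1` by definition.
#'
#' @param model_a,model_b [fit_prediction_model()] results, or numeric score
#'   vectors.
#' @param validation Validation `data.frame` (model interface) or logical
#'   outcome vector (score interface).
#' @return Object of class `c_comparison`: `chi2`, `df`, `p`, `z`, `c_a`,
#'   `c_b`.
#' @export
compare_c <- function(model_a, model_b, validation) {
  if (inherits(model_a, "prediction_model")) {
    sa <- predict(model_a, validation, type = "link")
    sb <- predict(model_b, validation, type = "link")
    outcomes <- validation$is_case
  } else {
    sa <- as.numeric(model_a)
    sb <- as.numeric(model_b)
    outcomes <- validation
  }
  ra <- roc_of(sa, outcomes)
  rb <- roc_of(sb, outcomes)
  if (all(sa == sb) ||
      isTRUE(all.equal(as.numeric(ra$auc), as.numeric(rb$auc))) &&
      all(rank(sa) == rank(sb))) {
    z <- 0
  } else {
    rt <- suppressWarnings(pROC::roc.test(ra, rb, method = "delong",
                                          paired = TRUE))
    z <- unname(rt$statistic)
    if (!is.finite(z)) z <- 0
  }
  chi2 <- z^2
  structure(list(chi2 = chi2, df = 1L,
                 p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                 z = z, c_a = as.numeric(ra$auc), c_b = as.numeric(rb$auc)),
            class = "c_comparison")
}

#' @export
print.c_comparison <- function(x, ...) {
  cat(sprintf("C %.3f vs %.3f: chi2(1) = %.3f, P = %.3g\n",
              x$c_a, x$c_b, x$chi2, x$p))
  invisible(x)
}

#' C-statistic of one model within each subgroup
#'
#' Applies the (standard) model's scores to the patients of each subgroup
#' separately. These within-subgroup C-statistics are not comparable with
#' the whole-population C (different populations); subgroups lacking cases
#' or controls in the validation data are reported undefined.
#'
#' @param model A [fit_prediction_model()] result.
#' @param validation Validation `data.frame`.
#' @param memberships A [classify_all()] table covering the validation
#'   patients.
#' @return data.frame: `subgroup`, `n`, `n_cases`, `c_statistic`, `ci_low`,
#'   `ci_high`, `defined`.
#' @export
per_subgroup_c <- function(model, validation, memberships) {
  sub <- memberships$assigned_subgroup[
    match(validation$patient_id, memberships$patient_id)]
  if (anyNA(sub)) stop("memberships do not cover all validation patients")
  scores <- predict(model, validation, type = "link")
  rows <- lapply(sort(unique(sub)), function(L) {
    idx <- sub == L
    y <- validation$is_case[idx]
    if (length(unique(y)) < 2)
      return(data.frame(subgroup = L, n = sum(idx), n_cases = sum(y),
                        c_statistic = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, defined = FALSE))
    d <- c_statistic(scores[idx], outcomes = y)
    data.frame(subgroup = L, n = sum(idx), n_cases = sum(y),
               c_statistic = d$c_statistic, ci_low = d$ci95[1],
               ci_high = d$ci95[2], defined = TRUE)
  })
  do.call(rbind, rows)
}

# --- calibration ------------------------------------------------------------

#' Calibration-in-the-large and calibration slope
#'
#' The calibration slope is the coefficient of the linear predictor in a
#' logistic refit of the outcome on the linear predictor; the
#' calibration-in-the-large intercept comes from a logistic refit with the
#' linear predictor as a fixed offset. Ideal values are 1 and 0.
#'
#' @param x A [fit_prediction_model()] result, or a numeric linear-predictor
#'   vector.
#' @param ... Passed to methods.
#' @return Object of class `calibration_result`: `slope`, `slope_ci`,
#'   `citl`, `citl_ci`.
#' @export
calibration <- function(x, ...) UseMethod("calibration")

#' @rdname calibration
#' @param validation Validation `data.frame` with `is_case`.
#' @export
calibration.prediction_model <- function(x, validation, ...) {
  calibration(predict(x, validation, type = "link"),
              outcomes = validation$is_case)
}

#' @rdname calibration
#' @param outcomes Logical (or 0/1) outcome vector aligned with the linear
#'   predictor.
#' @export
calibration.default <- function(x, outcomes, ...) {
  lp <- as.numeric(x)
  y <- as.integer(as.logical(outcomes))
  if (sd(lp) == 0) stop("degenerate constant linear predictor")
  fs <- glm(y ~ lp, family = binomial())
  fo <- glm(y ~ 1 + offset(lp), family = binomial())
  ss <- summary(fs)$coefficients
  so <- summary(fo)$coefficients
  zq <- qnorm(0.975)
  structure(list(
    slope = unname(coef(fs)["lp"]),
    slope_ci = unname(coef(fs)["lp"] + c(-1, 1) * zq * ss["lp", 2]),
    citl = unname(coef(fo)[1]),
    citl_ci = unname(coef(fo)[1] + c(-1, 1) * zq * so[1, 2])),
    class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("calibration slope %.3f (%.3f-%.3f); in-the-large %.3f (%.3f-%.3f)\n",
              x$slope, x$slope_ci[1], x$slope_ci[2],
              x$citl, x$citl_ci[1], x$citl_ci[2]))
  invisible(x)
}

# --- reclassification -------------------------------------------------------

nri_component <- function(up, down, n) {
  p_up <- sum(up) / n
  p_down <- sum(down) / n
  list(est = p_up - p_down,
       var = (p_up + p_down - (p_up - p_down)^2) / n)
}

nri_from_moves <- function(up, down, events) {
  n_e <- sum(events)
  n_ne <- sum(!events)
  ev <- nri_component(up[events], down[events], n_e)
  ne <- nri_component(down[!events], up[!events], n_ne)
  est <- ev$est + ne$est
  se <- sqrt(ev$var + ne$var)
  z <- if (se > 0) est / se else 0
  zq <- qnorm(0.975)
  list(estimate = est, ci95 = est + c(-1, 1) * zq * se, z = z,
       p = if (se > 0) 2 * pnorm(-abs(z)) else 1,
       event = ev$est, nonevent = ne$est, se = se)
}

#' Net reclassification improvement
#'
#' Event NRI is `P(up | event) - P(down | event)`; non-event NRI is
#' `P(down | non-event) - P(up | non-event)`; the total is their sum (range
#' -2..2). The continuous variant counts any directional change of the
#' predicted risk; the categorical variant counts risk-category crossings
#' over the supplied strictly increasing cutpoints. z, P, and the CI use
#' the standard large-sample variance (sum of the two proportion-difference
#' variances).
#'
#' @param old_probs,new_probs Aligned predicted risks under the two models.
#' @param outcomes Logical (or 0/1) event indicator.
#' @param cutpoints Strictly increasing risk cutpoints for the categorical
#'   variant (`NULL` computes the continuous variant only).
#' @return Object of class `nri_result`: `continuous`, `categorical` (or
#'   `NULL`), `cutpoints`.
#' @export
nri <- function(old_probs, new_probs, outcomes, cutpoints = NULL) {
  stopifnot(length(old_probs) == length(new_probs),
            length(old_probs) == length(outcomes))
  events <- as.logical(outcomes)
  if (!any(events)) stop("no events in the data")
  if (all(events)) stop("no non-events in the data")
  cont <- nri_from_moves(new_probs > old_probs, new_probs < old_probs,
                         events)
  cat_res <- NULL
  if (!is.null(cutpoints)) {
    if (any(diff(cutpoints) <= 0) || length(cutpoints) < 1)
      stop("cutpoints must be strictly increasing")
    co <- findInterval(old_probs, cutpoints)
    cn <- findInterval(new_probs, cutpoints)
    cat_res <- nri_from_moves(cn > co, cn < co, events)
  }
  structure(list(continuous = cont, categorical = cat_res,
                 cutpoints = cutpoints),
            class = "nri_result")
}

#' Integrated discrimination improvement
#'
#' `IDI = (mean new - mean old | events) - (mean new - mean old |`
#' `non-events)`: the change in mean predicted-risk separation between
#' events and non-events. z and CI come from the two-sample variance of the
#' per-subject risk differences.
#'
#' @inheritParams nri
#' @return Object of class `idi_result`: `estimate`, `ci95`, `z`, `p`.
#' @export
idi <- function(old_probs, new_probs, outcomes) {
  stopifnot(length(old_probs) == length(new_probs),
            length(old_probs) == length(outcomes))
  events <- as.logical(outcomes)
  if (!any(events)) stop("no events in the data")
  if (all(events)) stop("no non-events in the data")
  d <- new_probs - old_probs
  de <- d[events]
  dn <- d[!events]
  est <- mean(de) - mean(dn)
  v_e <- if (length(de) > 1) stats::var(de) / length(de) else 0
  v_n <- if (length(dn) > 1) stats::var(dn) / length(dn) else 0
  se <- sqrt(v_e + v_n)
  z <- if (se > 0) est / se else 0
  zq <- qnorm(0.975)
  structure(list(estimate = est, ci95 = est + c(-1, 1) * zq * se, z = z,
                 p = if (se > 0) 2 * pnorm(-abs(z)) else 1, se = se),
            class = "idi_result")
}

#' Compare a standard and a hierarchical readmission model
#'
#' One-stop comparison on a validation fold: C-statistics with DeLong CIs,
#' the paired DeLong chi-squared contrast, calibration of both models,
#' per-subgroup C of the standard model, and NRI (categorical + continuous)
#' and IDI for replacing the standard with the hierarchical model.
#' Categorical NRI cutpoints default to tertiles of the standard model's
#' predicted risk and are echoed in the result.
#'
#' @param standard,hierarchical [fit_prediction_model()] results.
#' @param validation Validation `data.frame` with `is_case` and
#'   `patient_id`.
#' @param memberships [classify_all()] table (for per-subgroup C);
#'   optional.
#' @param cutpoints Categorical NRI cutpoints (`NULL` = tertiles of the
#'   standard model's validation risks).
#' @return Object of class `model_comparison`.
#' @export
compare_models <- function(standard, hierarchical, validation,
                           memberships = NULL, cutpoints = NULL) {
  p_old <- predict(standard, validation, type = "response")
  p_new <- predict(hierarchical, validation, type = "response")
  y <- validation$is_case
  if (is.null(cutpoints)) {
    cutpoints <- unname(quantile(p_old, c(1 / 3, 2 / 3)))
    if (any(diff(cutpoints) <= 0)) {
      warning("degenerate tertile cutpoints; categorical NRI skipped")
      cutpoints <- NULL
    }
  }
  structure(list(
    c_standard = c_statistic(standard, validation),
    c_hierarchical = c_statistic(hierarchical, validation),
    c_test = compare_c(standard, hierarchical, validation),
    calibration_standard = calibration(standard, validation),
    calibration_hierarchical = calibration(hierarchical, validation),
    per_subgroup = if (!is.null(memberships))
      per_subgroup_c(standard, validation, memberships) else NULL,
    nri = nri(p_old, p_new, y, cutpoints = cutpoints),
    idi = idi(p_old, p_new, y),
    cutpoints = cutpoints,
    n_validation = nrow(validation)),
    class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  fmt_ci <- function(e, ci) sprintf("%.3f (%.3f to %.3f)", e, ci[1], ci[2])
  cat("Standard:     ", fmt_ci(x$c_standard$c_statistic, x$c_standard$ci95), "\n")
  cat("Hierarchical: ", fmt_ci(x$c_hierarchical$c_statistic,
                               x$c_hierarchical$ci95), "\n")
  cat(sprintf("DeLong chi2(1) = %.3f, P = %.3g\n", x$c_test$chi2, x$c_test$p))
  if (!is.null(x$nri$categorical))
    cat("NRI categorical:", fmt_ci(x$nri$categorical$estimate,
                                   x$nri$categorical$ci95),
        sprintf("z = %.2f, P = %.3g\n", x$nri$categorical$z,
                x$nri$categorical$p))
  cat("NRI continuous: ", fmt_ci(x$nri$continuous$estimate,
                                 x$nri$continuous$ci95),
      sprintf("z = %.2f, P = %.3g\n", x$nri$continuous$z, x$nri$continuous$p))
  cat("IDI:            ", fmt_ci(x$idi$estimate, x$idi$ci95),
      sprintf("z = %.2f, P = %.3g\n", x$idi$z, x$idi$p))
  invisible(x)
}
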