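# Multinomial classification of patients into discovered subgroups,
# repeated-split internal validation, subgroup risks, and per-patient
# importance scores.

#' Attach discovered subgroup labels to a cohort
#'
#' Maps the patient-node labels of a bicluster partition onto the cohort as
#' a `subgroup` column.
#'
#' @param cohort Cohort `data.frame`.
#' @param partition A [bicluster_partition()] whose patient nodes cover the
#'   cohort's `patient_id`s.
#' @return The cohort with an integer `subgroup` column.
#' @export
attach_subgroups <- function(cohort, partition) {
  lab <- partition$patient_labels[cohort$patient_id]
  if (anyNA(lab))
    stop("partition is missing labels for ", sum(is.na(lab)), " patients")
  cohort$subgroup <- unname(lab)
  cohort
}

# Hard assignment from a probability matrix: argmax with exact ties broken
# by the lowest subgroup index; ties are flagged.
assign_from_probs <- function(probs, class_labels, tol = 1e-12) {
  best <- max.col(probs, ties.method = "first")
  top <- probs[cbind(seq_len(nrow(probs)), best)]
  p2 <- probs
  p2[cbind(seq_len(nrow(probs)), best)] <- -Inf
  second <- p2[cbind(seq_len(nrow(probs)), max.col(p2, ties.method = "first"))]
  list(assigned = class_labels[best], tie = (top - second) <= tol)
}

#' Fit the multinomial subgroup classifier
#'
#' Maximum-likelihood multinomial logistic regression of the discovered
#' subgroup label on the selected comorbidities, with a small ridge penalty
#' (`decay`) for stability on separable planted data (set `decay = 0` for
#' the unpenalized fit).
#'
#' @param cases Cohort `data.frame` of cases with a `subgroup` column (see
#'   [attach_subgroups()]).
#' @param features Character vector of comorbidity columns to use as
#'   predictors.
#' @param decay Ridge penalty passed to [nnet::multinom()].
#' @param seed Integer RNG seed (the optimizer's weight initialization draws
#'   from the RNG; the fit is then deterministic given the seed).
#' @param maxit Optimizer iteration cap.
#' @return Object of class `subgroup_model` with the fit, `class_labels`,
#'   `features`, `decay`, `training_accuracy` and `converged`.
#' @export
fit_subgroup_model <- function(cases, features, decay = 1e-4, seed = 1L,
                               maxit = 500) {
  stopifnot("subgroup" %in% names(cases))
  tab <- table(cases$subgroup)
  if (length(tab) < 2) stop("need at least 2 subgroups to fit a classifier")
  small <- names(tab)[tab < 2]
  if (length(small))
    stop("subgroup(s) with fewer than 2 members: ",
         paste(small, collapse = ", "))
  dat <- data.frame(subgroup = factor(cases$subgroup),
                    cases[features], check.names = FALSE)
  fit <- withr::with_seed(seed, nnet::multinom(
    subgroup ~ ., data = dat, decay = decay, trace = FALSE,
    maxit = maxit, MaxNWts = 1e5))
  model <- structure(list(fit = fit, features = features,
                          class_labels = levels(dat$subgroup),
                          decay = decay, seed = seed,
                          converged = fit$convergence == 0),
                     class = "subgroup_model")
  pred <- predict_subgroup(model, cases)
  model$training_accuracy <-
    mean(pred$assigned_subgroup == as.character(cases$subgroup))
  model
}

#' Predict subgroup membership probabilities and hard labels
#'
#' Returns the full softmax probability vector per patient (columns
#' `p_<label>`, summing to 1) together with the dichotomized label
#' (highest predicted probability; exact ties flagged and broken toward the
#' lowest subgroup index). Probabilities are retained because downstream
#' importance scoring weights subgroup risk by membership probability.
#'
#' @param model A [fit_subgroup_model()] result.
#' @param patients Cohort `data.frame` with the model's feature columns.
#' @return data.frame with `patient_id`, `assigned_subgroup`, `tie`, and
#'   probability columns `p_<label>`.
#' @export
predict_subgroup <- function(model, patients) {
  missing_cols <- setdiff(model$features, names(patients))
  if (length(missing_cols))
    stop("feature schema mismatch; missing: ",
         paste(missing_cols, collapse = ", "))
  nd <- patients[model$features]
  pr <- predict(model$fit, newdata = nd, type = "probs")
  if (is.null(dim(pr))) {
    if (length(model$class_labels) == 2) {
      # two-class fits return P(second level) as a vector
      pr <- cbind(1 - pr, pr)
      colnames(pr) <- model$class_labels
    } else {
      # single-row predictions come back as a named vector
      pr <- matrix(pr, nrow = 1, dimnames = list(NULL, names(pr)))
    }
  }
  pr <- pr[, model$class_labels, drop = FALSE]
  hard <- assign_from_probs(pr, model$class_labels)
  out <- data.frame(patient_id = patients$patient_id,
                    assigned_subgroup = as.integer(hard$assigned),
                    tie = hard$tie,
                    stringsAsFactors = FALSE)
  colnames(pr) <- paste0("p_", model$class_labels)
  cbind(out, as.data.frame(pr, row.names = seq_len(nrow(pr))))
}

#' Repeated-split internal validation of the classifier
#'
#' Randomly splits the labeled cases into training/testing folds
#' `n_splits` times, refits the classifier on each training fold and
#' measures accuracy on both folds. Splits where the training fold misses a
#' subgroup (or has a singleton) are resampled, up to a cap. Summaries are
#' reported in percent.
#'
#' @param cases Labeled cohort (`subgroup` column present).
#' @param features Predictor columns.
#' @param n_splits Number of repeated splits.
#' @param train_frac Training fraction per split.
#' @param seed Integer RNG seed; the whole summary is a pure function of
#'   (data, n_splits, train_frac, seed).
#' @param decay Ridge penalty for each refit.
#' @param max_resample Cap on total resampled splits.
#' @return Object of class `validation_summary`: matrices of quantiles
#'   (2.5/25/50/75/97.5%), mean, sd and range for training- and
#'   testing-fold accuracy, all in percent.
#' @export
internal_validation <- function(cases, features, n_splits = 1000,
                                train_frac = 0.75, seed = 1L,
                                decay = 1e-4, max_resample = 100) {
  stopifnot("subgroup" %in% names(cases), train_frac > 0, train_frac < 1)
  n <- nrow(cases)
  classes <- sort(unique(cases$subgroup))
  acc_tr <- acc_te <- numeric(n_splits)
  n_resampled <- 0L
  withr::with_seed(seed, {
    for (s in seq_len(n_splits)) {
      repeat {
        idx <- sample(n, round(train_frac * n))
        tab <- table(cases$subgroup[idx])
        ok <- length(tab) == length(classes) && min(tab) >= 2 &&
          length(idx) < n
        if (ok) break
        n_resampled <- n_resampled + 1L
        if (n_resampled > max_resample)
          stop("exceeded resampling cap: some subgroup is too small ",
               "to appear in training folds")
      }
      tr <- cases[idx, , drop = FALSE]
      te <- cases[-idx, , drop = FALSE]
      dat <- data.frame(subgroup = factor(tr$subgroup), tr[features],
                        check.names = FALSE)
      fit <- nnet::multinom(subgroup ~ ., data = dat, decay = decay,
                            trace = FALSE, maxit = 500, MaxNWts = 1e5)
      model <- structure(list(fit = fit, features = features,
                              class_labels = levels(dat$subgroup)),
                         class = "subgroup_model")
      acc_tr[s] <- mean(predict_subgroup(model, tr)$assigned_subgroup ==
                          tr$subgroup)
      acc_te[s] <- mean(predict_subgroup(model, te)$assigned_subgroup ==
                          te$subgroup)
    }
  })
  summarize <- function(a) {
    a <- 100 * a
    c(q025 = unname(quantile(a, 0.025)), q25 = unname(quantile(a, 0.25)),
      q50 = unname(quantile(a, 0.5)), q75 = unname(quantile(a, 0.75)),
      q975 = unname(quantile(a, 0.975)), mean = mean(a), sd = sd(a),
      min = min(a), max = max(a))
  }
  structure(list(training = summarize(acc_tr), testing = summarize(acc_te),
                 n_splits = n_splits, train_frac = train_frac, seed = seed,
                 n_resampled = n_resampled),
            class = "validation_summary")
}

#' @export
print.validation_summary <- function(x, ...) {
  fmt <- function(s)
    sprintf("%6.2f %6.2f %6.2f %6.2f %6.2f   %.2f (%.2f; %.1f-%.1f)",
            s["q025"], s["q25"], s["q50"], s["q75"], s["q975"],
            s["mean"], s["sd"], s["min"], s["max"])
  cat(sprintf("Internal validation over %d splits (train %.0f%%), accuracy %%\n",
              x$n_splits, 100 * x$train_frac))
  cat("           Q.025  Q.25   Q.50   Q.75   Q.975  mean (SD; range)\n")
  cat("Training ", fmt(x$training), "\n")
  cat("Testing  ", fmt(x$testing), "\n")
  invisible(x)
}

#' Classify every case and control
#'
#' Applies the trained classifier to the full cohort (cases and controls);
#' only comorbidities enter as features, never case/control status.
#'
#' @param model A [fit_subgroup_model()] result.
#' @param cases,controls Cohort `data.frame`s.
#' @return Memberships data.frame: `patient_id`, `is_case`,
#'   `assigned_subgroup`, `tie`, `p_<label>` columns.
#' @export
classify_all <- function(model, cases, controls) {
  pc <- predict_subgroup(model, cases)
  pc$is_case <- cases$is_case
  pk <- predict_subgroup(model, controls)
  pk$is_case <- controls$is_case
  out <- rbind(pc, pk)
  out[c("patient_id", "is_case", "assigned_subgroup", "tie",
        grep("^p_", names(out), value = TRUE))]
}

#' Readmission risk per subgroup
#'
#' `risk_k = cases_k / (cases_k + controls_k)` over the classified
#' memberships; subgroups with no members are reported as undefined
#' (`NA` risk, `defined = FALSE`), never as zero.
#'
#' @param memberships A [classify_all()] table.
#' @param subgroups Optional label set (defaults to the probability columns
#'   present).
#' @return `subgroup_risk_table` data.frame: `subgroup`, `n_cases`,
#'   `n_controls`, `risk`, `defined`.
#' @export
subgroup_risk <- function(memberships, subgroups = NULL) {
  if (is.null(subgroups)) {
    pcols <- grep("^p_", names(memberships), value = TRUE)
    subgroups <- if (length(pcols)) as.integer(sub("^p_", "", pcols)) else
      sort(unique(memberships$assigned_subgroup))
  }
  rows <- lapply(sort(subgroups), function(L) {
    nc <- sum(memberships$assigned_subgroup == L & memberships$is_case)
    nn <- sum(memberships$assigned_subgroup == L & !memberships$is_case)
    data.frame(subgroup = L, n_cases = nc, n_controls = nn,
               risk = if (nc + nn > 0) nc / (nc + nn) else NA_real_,
               defined = nc + nn > 0)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("subgroup_risk_table", "data.frame")
  out
}

#' Importance scores: membership-weighted subgroup risk
#'
#' For one patient, `IS_k = MP_k * R_k` where `MP_k` is the membership
#' probability for subgroup k and `R_k` its readmission risk; subgroups are
#' ranked by descending IS (stable order on ties) so a clinician can scan
#' subgroup-targeted interventions in order of expected relevance.
#' Subgroups with undefined risk are excluded from the ranking and reported
#' via the `"excluded"` attribute.
#'
#' @param probabilities Named numeric membership-probability vector
#'   (names = subgroup labels), or a matrix/data.frame with one row per
#'   patient and `p_<label>` or label column names.
#' @param risks A [subgroup_risk()] table.
#' @return For a single patient, a data.frame (`subgroup`,
#'   `membership_probability`, `risk`, `importance`) sorted by descending
#'   importance; for a matrix, a list of such data.frames.
#' @examples
#' risks <- data.frame(subgroup = 1:2, n_cases = c(10, 30),
#'                     n_controls = c(90, 70), risk = c(0.1, 0.3),
#'                     defined = TRUE)
#' importance_scores(c(`1` = 0.5, `2` = 0.5), risks)
#' @export
importance_scores <- function(probabilities, risks) {
  if (is.matrix(probabilities) || is.data.frame(probabilities)) {
    pm <- as.matrix(probabilities)
    colnames(pm) <- sub("^p_", "", colnames(pm))
    return(lapply(seq_len(nrow(pm)), function(i)
      importance_scores(pm[i, ], risks)))
  }
  stopifnot(!is.null(names(probabilities)))
  labs <- sub("^p_", "", names(probabilities))
  r <- setNames(risks$risk, as.character(risks$subgroup))[labs]
  is_k <- unname(probabilities) * unname(r)
  df <- data.frame(subgroup = as.integer(labs),
                   membership_probability = unname(probabilities),
                   risk = unname(r), importance = is_k)
  excluded <- df$subgroup[is.na(df$importance)]
  if (length(excluded))
    message("excluded subgroup(s) with undefined risk from ranking: ",
            paste(excluded, collapse = ", "))
  df <- df[!is.na(df$importance), , drop = FALSE]
  df <- df[order(-df$importance), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "excluded") <- excluded
  df
}
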