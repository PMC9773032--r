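# Variable screening: 1:1 exact demographic matching, prevalence filter,
# univariable odds ratios with Bonferroni correction, and the requirement
# of significance in both split halves.

#' Match controls to cases 1:1 within exact demographic strata
#'
#' Greedy exact matching: within each stratum defined by the matching keys,
#' controls are drawn uniformly at random without replacement and paired to
#' cases. Each control is used at most once. Cases in strata with too few
#' controls are returned in `unmatched_cases` rather than silently dropped.
#'
#' @param cases,control_pool Cohort `data.frame`s sharing the key columns.
#' @param keys Demographic fields defining the exact strata.
#' @param seed Integer RNG seed for the within-stratum control draw.
#' @return An object of class `matched_set`: list with `pairs` (data.frame
#'   of `case_id`, `control_id`), `matching_keys`, and `unmatched_cases`.
#' @export
match_controls <- function(cases, control_pool,
                           keys = c("age_band", "sex", "race", "medicaid"),
                           seed = 1L) {
  missing_keys <- setdiff(keys, intersect(names(cases), names(control_pool)))
  if (length(missing_keys))
    stop("matching key(s) absent from schema: ",
         paste(missing_keys, collapse = ", "))
  if (nrow(control_pool) == 0) stop("empty control pool")
  stratum <- function(df) do.call(paste, c(df[keys], sep = "\r"))
  sc <- stratum(cases)
  sp <- stratum(control_pool)
  pair_list <- list()
  unmatched <- character(0)
  withr::with_seed(seed, {
    for (s in unique(sc)) {
      case_ids <- cases$patient_id[sc == s]
      ctrl_ids <- control_pool$patient_id[sp == s]
      if (length(ctrl_ids) > 1) ctrl_ids <- sample(ctrl_ids)
      n_pair <- min(length(case_ids), length(ctrl_ids))
      if (n_pair > 0)
        pair_list[[s]] <- data.frame(
          case_id = case_ids[seq_len(n_pair)],
          control_id = ctrl_ids[seq_len(n_pair)],
          stringsAsFactors = FALSE)
      if (length(case_ids) > n_pair)
        unmatched <- c(unmatched, case_ids[-seq_len(n_pair)])
    }
  })
  pairs <- if (length(pair_list)) do.call(rbind, pair_list) else
    data.frame(case_id = character(0), control_id = character(0))
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, matching_keys = keys,
                 unmatched_cases = unmatched),
            class = "matched_set")
}

#' Resolve a matched set into a combined case+control cohort table
#'
#' @param matched A [match_controls()] result.
#' @param cases,control_pool The cohorts the pairs were drawn from.
#' @return A cohort `data.frame` containing the matched cases followed by
#'   their matched controls.
#' @export
matched_cohort <- function(matched, cases, control_pool) {
  stopifnot(inherits(matched, "matched_set"))
  out <- rbind(
    cases[match(matched$pairs$case_id, cases$patient_id), , drop = FALSE],
    control_pool[match(matched$pairs$control_id, control_pool$patient_id), ,
                 drop = FALSE])
  rownames(out) <- NULL
  class(out) <- c("cohort", "data.frame")
  out
}

#' Retain comorbidities at or above a prevalence threshold
#'
#' Keeps comorbidity `j` iff its prevalence over the supplied (matched
#' case+control) table is `>= threshold`; strictly-below drops, exact ties
#' are retained.
#'
#' @param cohort Cohort `data.frame`.
#' @param threshold Prevalence threshold (default 0.01, i.e. the <1% rule).
#' @return Character vector of retained comorbidity column names, with the
#'   full prevalence vector attached as attribute `"prevalence"`.
#' @export
prevalence_filter <- function(cohort, threshold = 0.01) {
  if (nrow(cohort) == 0) stop("empty cohort")
  cols <- comorbidity_cols(cohort)
  prev <- colMeans(as.matrix(cohort[cols]))
  out <- cols[prev >= threshold]
  attr(out, "prevalence") <- prev
  out
}

#' Univariable odds ratio for one comorbidity
#'
#' Computes the 2x2-table odds ratio `OR = (a*d)/(b*c)` for case status by
#' comorbidity exposure (equivalent to univariable logistic regression for a
#' binary predictor), with a Wald confidence interval on the log scale and a
#' two-sided Wald P value. Zero cells are handled by adding the
#' Haldane-Anscombe 0.5 correction to every cell and flagging the result as
#' degenerate; a comorbidity constant in the sample gets `p = NA` and is
#' excluded from feature survival.
#'
#' @param cohort Cohort `data.frame` with an `is_case` column.
#' @param comorbidity Comorbidity column name (or index into the
#'   comorbidity columns).
#' @param conf_level Confidence level for the Wald interval.
#' @return List with `or`, `ci_low`, `ci_high`, `p`, `degenerate`,
#'   `constant` and the 2x2 `table` (a, b, c, d).
#' @examples
#' coh <- data.frame(is_case = rep(c(TRUE, FALSE), each = 100),
#'                   c1 = c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90)))
#' univariable_or(coh, "c1")$or  # (30*90)/(10*70) = 3.857
#' @export
univariable_or <- function(cohort, comorbidity, conf_level = 0.95) {
  if (is.numeric(comorbidity))
    comorbidity <- comorbidity_cols(cohort)[comorbidity]
  x <- cohort[[comorbidity]]
  y <- cohort$is_case
  a <- sum(x == 1 & y)
  b <- sum(x == 1 & !y)
  cc <- sum(x == 0 & y)
  dd <- sum(x == 0 & !y)
  constant <- (a + b == 0) || (cc + dd == 0)
  degenerate <- constant || any(c(a, b, cc, dd) == 0)
  cells <- c(a = a, b = b, c = cc, d = dd)
  if (degenerate) cells <- cells + 0.5
  or <- (cells["a"] * cells["d"]) / (cells["b"] * cells["c"])
  se <- sqrt(sum(1 / cells))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  p <- if (constant) NA_real_ else unname(2 * pnorm(-abs(log(or)) / se))
  list(or = unname(or),
       ci_low = unname(exp(log(or) - zq * se)),
       ci_high = unname(exp(log(or) + zq * se)),
       p = p, degenerate = degenerate, constant = constant,
       table = c(a = a, b = b, c = cc, d = dd))
}

# Univariable OR stats for every comorbidity column, as a data.frame.
all_univariable_or <- function(cohort, cols) {
  stats <- lapply(cols, function(j) univariable_or(cohort, j))
  data.frame(
    comorbidity = cols,
    or = vapply(stats, `[[`, 0, "or"),
    ci_low = vapply(stats, `[[`, 0, "ci_low"),
    ci_high = vapply(stats, `[[`, 0, "ci_high"),
    p = vapply(stats, `[[`, 0, "p"),
    degenerate = vapply(stats, `[[`, TRUE, "degenerate"),
    constant = vapply(stats, `[[`, TRUE, "constant"),
    stringsAsFactors = FALSE)
}

#' Select comorbidities significant in both split halves
#'
#' Applies the prevalence filter to the combined matched set, Bonferroni-
#' corrects `alpha` by the number of comorbidities passing the filter, and
#' requires the univariable Wald P value to be below the corrected level in
#' both the training and the replication half. Comorbidities constant in
#' either half cannot survive.
#'
#' @param train,repl Matched case+control cohort tables for the two halves
#'   (identical comorbidity schema).
#' @param alpha Family-wise significance level before correction.
#' @param prevalence_threshold Prevalence threshold for the pre-filter.
#' @return A `feature_report` data.frame with one row per comorbidity:
#'   prevalence, per-half OR/CI/P, degeneracy flags, `retained` (passed the
#'   prevalence filter) and `survived`. Attributes: `alpha`, `alpha_bonf`,
#'   `d_tested`, `prevalence_threshold`.
#' @export
select_features <- function(train, repl, alpha = 0.05,
                            prevalence_threshold = 0.01) {
  cols <- comorbidity_cols(train)
  if (!setequal(cols, comorbidity_cols(repl)))
    stop("comorbidity schema mismatch between halves")
  combined <- rbind(train[c("is_case", cols)], repl[c("is_case", cols)])
  prev <- colMeans(as.matrix(combined[cols]))
  retained <- prev >= prevalence_threshold
  d_tested <- sum(retained)
  if (d_tested == 0) stop("no comorbidity passes the prevalence filter")
  alpha_bonf <- alpha / d_tested
  st <- all_univariable_or(train, cols)
  sr <- all_univariable_or(repl, cols)
  survived <- retained & !st$constant & !sr$constant &
    !is.na(st$p) & !is.na(sr$p) & st$p < alpha_bonf & sr$p < alpha_bonf
  out <- data.frame(
    comorbidity = cols,
    prevalence = unname(prev),
    retained = unname(retained),
    or_train = st$or, ci_low_train = st$ci_low, ci_high_train = st$ci_high,
    p_train = st$p, degenerate_train = st$degenerate,
    or_repl = sr$or, ci_low_repl = sr$ci_low, ci_high_repl = sr$ci_high,
    p_repl = sr$p, degenerate_repl = sr$degenerate,
    survived = unname(survived),
    stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  attr(out, "alpha_bonf") <- alpha_bonf
  attr(out, "d_tested") <- d_tested
  attr(out, "prevalence_threshold") <- prevalence_threshold
  class(out) <- c("feature_report", "data.frame")
  out
}

#' Drop patients with none of the selected comorbidities
#'
#' Removes patients whose selected-comorbidity vector is all zero (they
#' carry no edge in the bipartite graph). The number removed is attached as
#' attribute `"n_dropped"` and reported via `message()`.
#'
#' @param cohort Cohort `data.frame`.
#' @param selected Character vector of selected comorbidity column names.
#' @return The filtered cohort; errors if every patient would be removed.
#' @export
drop_empty_patients <- function(cohort, selected) {
  stopifnot(length(selected) > 0)
  empty <- rowSums(as.matrix(cohort[selected])) == 0
  if (all(empty)) stop("all patients have none of the selected comorbidities")
  out <- cohort[!empty, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(empty)
  class(out) <- c("cohort", "data.frame")
  if (any(empty))
    message(sprintf("dropped %d of %d patients with none of the %d selected comorbidities",
                    sum(empty), length(empty), length(selected)))
  out
}
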