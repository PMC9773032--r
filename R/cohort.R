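# Synthetic cohort generator: matched case/control structure, planted
# patient-comorbidity biclusters, and subgroup-dependent readmission risk.

#' Default demographic level sets and sampling weights
#'
#' Age bands, sex, race/ethnicity and Medicaid eligibility with sampling
#' weights loosely shaped like an elderly hospitalized population (Medicare
#' enrollees are 66+, mostly female at these ages, predominantly White, and
#' a minority are dually Medicaid-eligible). The exact weights are a
#' convention of the generator, not an estimate.
#'
#' @return Named list of named weight vectors, one per demographic field.
#' @export
default_demographics <- function() {
  list(
    age_band = c("66-70" = 0.30, "71-75" = 0.25, "76-80" = 0.20,
                 "81-85" = 0.15, "86+" = 0.10),
    sex      = c(F = 0.55, M = 0.45),
    race     = c(White = 0.80, Black = 0.10, Hispanic = 0.06, Other = 0.04),
    medicaid = c(no = 0.85, yes = 0.15)
  )
}

#' Specification for a synthetic patient cohort
#'
#' Defines a cohort with `n_subgroups` planted biclusters: each patient is
#' assigned a subgroup, carries each comorbidity in their subgroup's block
#' with probability `p_in` and every other comorbidity with probability
#' `p_out`, and is readmitted (case) with the subgroup's risk. Comorbidities
#' are split into contiguous blocks of equal size; when `n_comorbidities`
#' is not divisible by `n_subgroups` the remainder is assigned to the last
#' block.
#'
#' @param n_cases,n_controls Requested numbers of cases (readmitted within
#'   30 days) and controls.
#' @param n_comorbidities Number of binary comorbidity variables (d).
#' @param n_subgroups Number of planted subgroups (K >= 2).
#' @param p_in Probability that a patient carries a comorbidity in their
#'   subgroup's block.
#' @param p_out Probability for any other comorbidity; must satisfy
#'   `0 <= p_out <= p_in <= 1` (equality gives the structureless null
#'   cohort used for calibration checks).
#' @param subgroup_risks Vector of K readmission probabilities.
#' @param subgroup_weights Optional subgroup assignment weights (default
#'   uniform).
#' @param demographic_levels Named list of named weight vectors; see
#'   [default_demographics()].
#' @param confound_demographics If `TRUE`, the age-band distribution is
#'   rotated by subgroup so demographics carry subgroup signal (a stress
#'   switch; the default keeps demographics independent of subgroup so that
#'   demographic matching removes no subgroup structure).
#' @param seed Integer RNG seed; generation is a pure function of
#'   (spec, seed).
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_cases, n_controls, n_comorbidities, n_subgroups,
                        p_in, p_out, subgroup_risks,
                        subgroup_weights = NULL,
                        demographic_levels = default_demographics(),
                        confound_demographics = FALSE,
                        seed = 1L) {
  # configs loaded from YAML/JSON deliver vectors and weight maps as lists
  subgroup_risks <- unlist(subgroup_risks)
  if (!is.null(subgroup_weights)) subgroup_weights <- unlist(subgroup_weights)
  stopifnot(n_cases >= 0, n_controls >= 0, n_cases + n_controls > 0,
            n_comorbidities >= 1, n_subgroups >= 2,
            n_comorbidities >= n_subgroups)
  if (!(p_out >= 0 && p_out <= p_in && p_in <= 1))
    stop("require 0 <= p_out <= p_in <= 1")
  stopifnot(length(subgroup_risks) == n_subgroups,
            all(subgroup_risks >= 0), all(subgroup_risks <= 1))
  if (is.null(subgroup_weights))
    subgroup_weights <- rep(1 / n_subgroups, n_subgroups)
  stopifnot(length(subgroup_weights) == n_subgroups, all(subgroup_weights > 0))
  stopifnot(is.list(demographic_levels), length(demographic_levels) >= 1,
            !is.null(names(demographic_levels)))
  demographic_levels <- lapply(demographic_levels, unlist)
  structure(list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_comorbidities = as.integer(n_comorbidities),
    n_subgroups = as.integer(n_subgroups),
    p_in = p_in, p_out = p_out,
    subgroup_risks = as.double(subgroup_risks),
    subgroup_weights = subgroup_weights / sum(subgroup_weights),
    demographic_levels = demographic_levels,
    confound_demographics = isTRUE(confound_demographics),
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

# Block id (1..K) of each comorbidity; remainder goes to the last block.
comorbidity_blocks <- function(d, K) {
  base <- d %/% K
  rep.int(seq_len(K), c(rep.int(base, K - 1L), d - base * (K - 1L)))
}

# Draw n patients from the population model (before any case/control
# truncation). Used directly by generate_cohort() and by convergence checks.
draw_patients <- function(spec, n, id_offset = 0L) {
  K <- spec$n_subgroups
  d <- spec$n_comorbidities
  g <- sample.int(K, n, replace = TRUE, prob = spec$subgroup_weights)
  blocks <- comorbidity_blocks(d, K)
  pmat <- matrix(spec$p_out, n, d)
  pmat[outer(g, blocks, "==")] <- spec$p_in
  cm <- matrix(as.integer(runif(n * d) < pmat), n, d)
  colnames(cm) <- paste0("c", seq_len(d))
  demo <- lapply(names(spec$demographic_levels), function(field) {
    w <- spec$demographic_levels[[field]]
    if (spec$confound_demographics && field == names(spec$demographic_levels)[1]) {
      # rotate weights by subgroup so this field is informative about g
      out <- character(n)
      for (gg in seq_len(K)) {
        idx <- which(g == gg)
        wg <- w[((seq_along(w) + gg - 2L) %% length(w)) + 1L]
        out[idx] <- sample(names(w), length(idx), replace = TRUE, prob = wg)
      }
      out
    } else {
      sample(names(w), n, replace = TRUE, prob = w)
    }
  })
  names(demo) <- names(spec$demographic_levels)
  is_case <- runif(n) < spec$subgroup_risks[g]
  out <- data.frame(
    patient_id = sprintf("P%07d", id_offset + seq_len(n)),
    is_case = is_case,
    demo,
    cm,
    true_subgroup = g,
    stringsAsFactors = FALSE
  )
  class(out) <- c("cohort", "data.frame")
  out
}

#' Generate a synthetic cohort with planted biclusters
#'
#' Patients are drawn from the population model of the spec (uniform or
#' weighted subgroup assignment, block-structured Bernoulli comorbidities,
#' Bernoulli case status with subgroup-specific risk), then the generator
#' oversamples and truncates to exactly `n_cases` cases and `n_controls`
#' controls in draw order, discarding the excess. Truncation keeps the
#' subgroup composition of cases and of controls unbiased, so per-subgroup
#' readmission risks are recovered whenever `n_cases / (n_cases +
#' n_controls)` matches the population case rate.
#'
#' @param spec A [cohort_spec()].
#' @return A `cohort` data.frame with columns `patient_id`, `is_case`, the
#'   demographic fields, `c1..cd`, and `true_subgroup`; the spec is attached
#'   as attribute `"spec"`.
#' @examples
#' spec <- cohort_spec(50, 50, n_comorbidities = 10, n_subgroups = 2,
#'                     p_in = 1, p_out = 0, subgroup_risks = c(0.3, 0.7))
#' cohort <- generate_cohort(spec)
#' table(cohort$is_case)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_cases > 0 && all(spec$subgroup_risks == 0))
    stop("infeasible request: n_cases > 0 but every subgroup risk is 0")
  if (spec$n_controls > 0 && all(spec$subgroup_risks == 1))
    stop("infeasible request: n_controls > 0 but every subgroup risk is 1")
  withr::with_seed(spec$seed, {
    batch <- max(1000L, spec$n_cases + spec$n_controls)
    acc <- list()
    drawn <- 0L; got_cases <- 0L; got_controls <- 0L; iter <- 0L
    while ((got_cases < spec$n_cases || got_controls < spec$n_controls) &&
           iter < 1000L) {
      iter <- iter + 1L
      b <- draw_patients(spec, batch, id_offset = drawn)
      drawn <- drawn + batch
      acc[[iter]] <- b
      got_cases <- got_cases + sum(b$is_case)
      got_controls <- got_controls + sum(!b$is_case)
    }
    if (got_cases < spec$n_cases || got_controls < spec$n_controls)
      stop("infeasible request: could not fill n_cases/n_controls ",
           "(subgroup risks too extreme)")
    pop <- do.call(rbind, acc)
    keep <- c(which(pop$is_case)[seq_len(spec$n_cases)],
              which(!pop$is_case)[seq_len(spec$n_controls)])
    out <- pop[sort(keep), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "spec") <- spec
    class(out) <- c("cohort", "data.frame")
    out
  })
}

#' Split a cohort into two random halves
#'
#' Random disjoint 50/50 split, stratified by case/control status so both
#' halves retain the case/control balance. Odd strata place the extra
#' patient in the first (training) half.
#'
#' @param cohort A cohort `data.frame`.
#' @param seed Integer RNG seed.
#' @return A list with elements `train` and `replication`.
#' @export
split_halves <- function(cohort, seed = 1L) {
  if (nrow(cohort) == 0) stop("empty cohort")
  idx_case <- which(cohort$is_case)
  idx_ctrl <- which(!cohort$is_case)
  withr::with_seed(seed, {
    pc <- sample(idx_case)
    pq <- sample(idx_ctrl)
  })
  first <- c(pc[seq_len(ceiling(length(pc) / 2))],
             pq[seq_len(ceiling(length(pq) / 2))])
  train <- cohort[sort(first), , drop = FALSE]
  repl <- cohort[sort(setdiff(seq_len(nrow(cohort)), first)), , drop = FALSE]
  rownames(train) <- rownames(repl) <- NULL
  attr(train, "spec") <- attr(cohort, "spec")
  attr(repl, "spec") <- attr(cohort, "spec")
  list(train = train, replication = repl)
}

#' Write / read a cohort as CSV with a JSON metadata sidecar
#'
#' The CSV has one row per patient (columns `patient_id`, `is_case`,
#' demographics, `c1..cd`, `true_subgroup` when present); the sidecar
#' `<path>.json` records the generating spec and seed when the cohort was
#' produced by [generate_cohort()].
#'
#' @param cohort A cohort `data.frame`.
#' @param path CSV file path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns the cohort with the spec re-attached when a sidecar exists.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE)
  spec <- attr(cohort, "spec")
  if (!is.null(spec)) {
    meta <- unclass(spec)
    meta$demographic_levels <- lapply(meta$demographic_levels, as.list)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("patient_id", "is_case") %in% names(out)))
  out$is_case <- as.logical(out$is_case)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    meta$demographic_levels <- lapply(meta$demographic_levels, unlist)
    attr(out, "spec") <- structure(meta, class = "cohort_spec")
  }
  class(out) <- c("cohort", "data.frame")
  out
}
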