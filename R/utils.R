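# Shared internal helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministically derive a per-stage seed from a master seed. Kept below
# .Machine$integer.max so it is always a valid 32-bit seed.
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  offset <- sum(utf8ToInt(stage))
  as.integer((abs(as.double(seed)) + offset * 7919) %% 2147483647)
}

#' Names of comorbidity columns in a cohort table
#'
#' Cohort tables store the binary comorbidity vector in columns named
#' `c1`, `c2`, ... This helper returns those column names in order.
#'
#' @param cohort A cohort `data.frame`.
#' @return Character vector of comorbidity column names.
#' @export
comorbidity_cols <- function(cohort) {
  cols <- grep("^c[0-9]+$", names(cohort), value = TRUE)
  cols[order(as.integer(sub("^c", "", cols)))]
}

#' Size of the binary comorbidity profile space
#'
#' The number of distinct presence/absence profiles over `n` binary
#' comorbidities, i.e. 2^n. Enumerating profiles combinatorially explodes:
#' with the 31 Elixhauser comorbidities there are already
#' 2,147,483,648 combinations, which motivates clustering patients and
#' comorbidities jointly instead of enumerating profiles.
#'
#' @param n_comorbidities Number of binary comorbidity variables.
#' @return The count 2^n as a double (exact for n <= 52).
#' @examples
#' comorbidity_profile_count(31)
#' @export
comorbidity_profile_count <- function(n_comorbidities) {
  stopifnot(is.numeric(n_comorbidities), length(n_comorbidities) == 1L,
            n_comorbidities >= 0, n_comorbidities <= 52)
  2^as.double(n_comorbidities)
}
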