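# Fixtures are generated in code; nothing is stored on disk.

# Wrap an incidence matrix as a cases-only cohort and build the graph.
graph_from_incidence <- function(M) {
  colnames(M) <- paste0("c", seq_len(ncol(M)))
  coh <- data.frame(patient_id = sprintf("P%03d", seq_len(nrow(M))),
                    is_case = TRUE, M)
  build_graph(coh, colnames(M))
}

# Block-diagonal incidence with K perfect biclusters.
perfect_biclusters <- function(K, patients_per = 2, comorb_per = 2) {
  n <- K * patients_per
  d <- K * comorb_per
  M <- matrix(0L, n, d)
  for (g in seq_len(K)) {
    rows <- (g - 1) * patients_per + seq_len(patients_per)
    cols <- (g - 1) * comorb_per + seq_len(comorb_per)
    M[rows, cols] <- 1L
  }
  M
}

# Random bipartite incidence where every patient has degree >= 1.
random_incidence <- function(n, d, p, seed) {
  withr::with_seed(seed, {
    repeat {
      M <- matrix(rbinom(n * d, 1, p), n, d)
      if (all(rowSums(M) >= 1) && sum(M) > 0) return(M)
    }
  })
}

# Cases-only planted cohort (block comorbidity structure, equal risks),
# filtered to patients with at least one comorbidity as the graph stage
# requires.
planted_cases <- function(n, d, K, p_in, p_out, seed) {
  spec <- cohort_spec(n_cases = n, n_controls = 0, n_comorbidities = d,
                      n_subgroups = K, p_in = p_in, p_out = p_out,
                      subgroup_risks = rep(0.5, K), seed = seed)
  coh <- generate_cohort(spec)
  suppressMessages(drop_empty_patients(coh, comorbidity_cols(coh)))
}

# Simple two-level demographics so exact matching strata stay coarse.
coarse_demographics <- function() {
  list(age_band = c("66-75" = 0.6, "76+" = 0.4),
       sex = c(F = 0.55, M = 0.45),
       race = c(White = 0.8, Other = 0.2),
       medicaid = c(no = 0.85, yes = 0.15))
}

# Planted comorbidity block labels (ground truth for comorbidity nodes).
true_comorbidity_blocks <- function(d, K) subgroupnet:::comorbidity_blocks(d, K)
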