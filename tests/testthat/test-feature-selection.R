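# Matching, prevalence filtering, univariable odds ratios, and the
# both-halves Bonferroni survival rule.

make_matched_pool <- function(seed = 4) {
  spec <- cohort_spec(120, 400, n_comorbidities = 6, n_subgroups = 2,
                      p_in = 0.5, p_out = 0.1,
                      subgroup_risks = c(0.15, 0.35),
                      demographic_levels = coarse_demographics(),
                      seed = seed)
  coh <- generate_cohort(spec)
  list(cases = coh[coh$is_case, ], controls = coh[!coh$is_case, ])
}

test_that("exact matching is 1:1 without replacement and seeded", {
  pool <- make_matched_pool()
  m <- match_controls(pool$cases, pool$controls, seed = 1)
  expect_s3_class(m, "matched_set")
  expect_false(any(duplicated(m$pairs$control_id)))
  expect_false(any(duplicated(m$pairs$case_id)))
  # every pair agrees exactly on all matching keys
  keyval <- function(df, ids)
    do.call(paste, df[match(ids, df$patient_id), m$matching_keys])
  expect_identical(keyval(pool$cases, m$pairs$case_id),
                   keyval(pool$controls, m$pairs$control_id))
  # with a deep control pool every case finds a stratum mate
  expect_length(m$unmatched_cases, 0)
  m2 <- match_controls(pool$cases, pool$controls, seed = 1)
  expect_identical(m$pairs, m2$pairs)
})

test_that("overfull strata leave the pigeonholed cases unmatched", {
  cases <- data.frame(patient_id = paste0("A", 1:3), is_case = TRUE,
                      age_band = "66-75", sex = "F", race = "White",
                      medicaid = "no")
  ctrl <- data.frame(patient_id = paste0("B", 1:2), is_case = FALSE,
                     age_band = "66-75", sex = "F", race = "White",
                     medicaid = "no")
  m <- match_controls(cases, ctrl, seed = 1)
  expect_equal(nrow(m$pairs), 2)
  expect_length(m$unmatched_cases, 1)
  expect_error(match_controls(cases, ctrl[0, ], seed = 1), "empty control")
  expect_error(match_controls(cases, ctrl, keys = c("sex", "zipcode")),
               "zipcode")
})

test_that("prevalence filter drops strictly-below and keeps boundary ties", {
  coh <- data.frame(patient_id = sprintf("P%03d", 1:200), is_case = TRUE,
                    c1 = 0L,                        # zero prevalence
                    c2 = rep(c(1L, rep(0L, 199))),  # 0.005
                    c3 = c(rep(1L, 2), rep(0L, 198)),   # exactly 0.01
                    c4 = c(rep(1L, 50), rep(0L, 150)))  # 0.25
  kept <- prevalence_filter(coh, threshold = 0.01)
  expect_setequal(kept, c("c3", "c4"))
})

test_that("univariable OR matches 2x2 arithmetic and its stated correction", {
  coh <- data.frame(is_case = rep(c(TRUE, FALSE), each = 100),
                    c1 = c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90)))
  r <- univariable_or(coh, "c1")
  expect_equal(r$or, (30 * 90) / (10 * 70), tolerance = 1e-12)
  expect_false(r$degenerate)
  # equal exposure proportions -> OR = 1
  coh2 <- data.frame(is_case = rep(c(TRUE, FALSE), each = 50),
                     c1 = rep(c(1, 1, 0, 0, 0), 20))
  expect_equal(univariable_or(coh2, "c1")$or, 1)
  # zero cell: Haldane-Anscombe +0.5 on all cells with the degeneracy flag
  coh3 <- data.frame(is_case = c(rep(TRUE, 10), rep(FALSE, 90)),
                     c1 = c(rep(0, 10), rep(1, 5), rep(0, 85)))
  r3 <- univariable_or(coh3, "c1")
  expect_true(r3$degenerate)
  expect_equal(r3$or, (0.5 * 85.5) / (5.5 * 10.5), tolerance = 1e-12)
  # constant comorbidity is flagged and gets no P value
  coh4 <- data.frame(is_case = rep(c(TRUE, FALSE), 10), c1 = 1)
  r4 <- univariable_or(coh4, "c1")
  expect_true(r4$constant)
  expect_true(is.na(r4$p))
})

test_that("2x2 OR and Wald P agree with a logistic-regression oracle", {
  withr::with_seed(42, {
    for (rep in 1:8) {
      n <- 400
      y <- rep(c(TRUE, FALSE), each = n / 2)
      x <- rbinom(n, 1, ifelse(y, runif(1, 0.2, 0.6), runif(1, 0.2, 0.6)))
      if (length(unique(x)) < 2) next
      coh <- data.frame(is_case = y, c1 = x)
      r <- univariable_or(coh, "c1")
      if (r$degenerate) next
      fit <- glm(y ~ x, family = binomial(),
                 control = stats::glm.control(epsilon = 1e-14))
      sm <- summary(fit)$coefficients
      expect_equal(log(r$or), unname(coef(fit)["x"]), tolerance = 1e-8)
      # compare P values on the log scale: tiny tails amplify coef noise
      expect_equal(log(r$p), log(unname(sm["x", 4])), tolerance = 1e-6)
    }
  })
})

test_that("survival needs Bonferroni significance in both halves", {
  # one comorbidity strongly associated in train only, one in both
  make_half <- function(p_case_c1, p_ctrl_c1, p_case_c2, p_ctrl_c2, seed) {
    withr::with_seed(seed, {
      n <- 1000
      y <- rep(c(TRUE, FALSE), each = n)
      data.frame(is_case = y,
                 c1 = rbinom(2 * n, 1, ifelse(y, p_case_c1, p_ctrl_c1)),
                 c2 = rbinom(2 * n, 1, ifelse(y, p_case_c2, p_ctrl_c2)),
                 c3 = rbinom(2 * n, 1, 0.3))
    })
  }
  train <- make_half(0.45, 0.2, 0.45, 0.2, 1)
  repl <- make_half(0.2, 0.2, 0.45, 0.2, 2)   # c1 null in replication
  rep_out <- select_features(train, repl, alpha = 0.05)
  expect_equal(attr(rep_out, "alpha_bonf"), 0.05 / 3)
  expect_false(rep_out$survived[rep_out$comorbidity == "c1"])
  expect_true(rep_out$survived[rep_out$comorbidity == "c2"])
  expect_false(rep_out$survived[rep_out$comorbidity == "c3"])
  # the Bonferroni denominator is the post-filter count
  expect_equal(attr(rep_out, "d_tested"), 3)
  # column order does not change the outcome
  perm <- c("c3", "c1", "c2")
  rep_perm <- select_features(
    cbind(train["is_case"], train[perm]),
    cbind(repl["is_case"], repl[perm]), alpha = 0.05)
  expect_equal(
    sort(rep_perm$comorbidity[rep_perm$survived]),
    sort(rep_out$comorbidity[rep_out$survived]))
})

test_that("a strong risk comorbidity survives in at least 95% of replicates", {
  # OR = 3 via exposure 0.2 in controls vs 0.4286 in cases, n = 2000/half
  hits <- 0
  n_rep <- 100
  withr::with_seed(2024, {
    for (r in seq_len(n_rep)) {
      half <- function() {
        y <- rep(c(TRUE, FALSE), each = 1000)
        data.frame(
          is_case = y,
          c1 = rbinom(2000, 1, ifelse(y, 0.75 / 1.75, 0.2)),
          c2 = rbinom(2000, 1, 0.2),
          c3 = rbinom(2000, 1, 0.2))
      }
      fr <- select_features(half(), half())
      hits <- hits + fr$survived[fr$comorbidity == "c1"]
    }
  })
  expect_gte(hits, 95)
})

test_that("under the global null the family-wise survival rate stays below alpha", {
  fams <- 0
  n_rep <- 200
  withr::with_seed(77, {
    for (r in seq_len(n_rep)) {
      half <- function() {
        y <- rep(c(TRUE, FALSE), each = 150)
        cm <- matrix(rbinom(300 * 8, 1, 0.25), 300, 8)
        colnames(cm) <- paste0("c", 1:8)
        data.frame(is_case = y, cm)
      }
      fr <- select_features(half(), half())
      fams <- fams + any(fr$survived)
    }
  })
  expect_lte(fams / n_rep, 0.05)
})

test_that("patients with none of the selected comorbidities are dropped", {
  coh <- data.frame(patient_id = sprintf("P%03d", 1:100), is_case = TRUE,
                    c1 = c(rep(0L, 7), rep(1L, 93)),
                    c2 = 0L)
  out <- suppressMessages(drop_empty_patients(coh, c("c1", "c2")))
  expect_equal(nrow(out), 93)
  expect_equal(attr(out, "n_dropped"), 7)
  # no all-zero patients -> identity
  out2 <- drop_empty_patients(coh[8:100, ], c("c1", "c2"))
  expect_equal(nrow(out2), 93)
  expect_error(drop_empty_patients(coh, "c2"), "all patients")
})
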