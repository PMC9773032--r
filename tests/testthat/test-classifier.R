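# Multinomial subgroup classifier, repeated-split validation, subgroup
# risks, and importance scores.

labeled_cases <- function(n, d, K, p_in, p_out, seed) {
  coh <- planted_cases(n, d, K, p_in, p_out, seed)
  coh$subgroup <- coh$true_subgroup
  coh
}

test_that("noise-free planted classes are fit perfectly and deterministically", {
  coh <- labeled_cases(200, 12, 3, p_in = 1, p_out = 0, seed = 51)
  m <- fit_subgroup_model(coh, comorbidity_cols(coh), seed = 7)
  expect_equal(m$training_accuracy, 1)
  m2 <- fit_subgroup_model(coh, comorbidity_cols(coh), seed = 7)
  expect_identical(coef(m$fit), coef(m2$fit))
  # probability vectors are a softmax: they sum to one
  pr <- predict_subgroup(m, coh)
  psum <- rowSums(pr[grep("^p_", names(pr))])
  expect_true(all(abs(psum - 1) < 1e-12))
  # self-consistency: predictions on the training data reproduce fit accuracy
  expect_equal(mean(pr$assigned_subgroup == coh$subgroup),
               m$training_accuracy)
})

test_that("degenerate label sets are rejected with the offending subgroup named", {
  coh <- labeled_cases(50, 8, 2, p_in = 0.8, p_out = 0.1, seed = 52)
  coh$subgroup <- 1L
  expect_error(fit_subgroup_model(coh, comorbidity_cols(coh)),
               "at least 2 subgroups")
  coh$subgroup[1] <- 2L
  expect_error(fit_subgroup_model(coh, comorbidity_cols(coh)), "2")
})

test_that("ties and argmax follow the stated dichotomization rule", {
  probs <- rbind(c(0.7, 0.1, 0.1, 0.1),
                 c(0.25, 0.25, 0.25, 0.25),
                 c(0.5, 0.5, 0, 0))
  hard <- subgroupnet:::assign_from_probs(probs, class_labels = 1:4)
  expect_equal(hard$assigned, c(1, 1, 1))
  expect_equal(hard$tie, c(FALSE, TRUE, TRUE))
})

test_that("schema mismatches are explicit errors", {
  coh <- labeled_cases(80, 6, 2, p_in = 0.9, p_out = 0.05, seed = 53)
  m <- fit_subgroup_model(coh, comorbidity_cols(coh))
  bad <- coh[setdiff(names(coh), "c3")]
  expect_error(predict_subgroup(m, bad), "c3")
})

test_that("internal validation summarizes ordered quantiles and is reproducible", {
  coh <- labeled_cases(200, 12, 3, p_in = 1, p_out = 0, seed = 54)
  v <- internal_validation(coh, comorbidity_cols(coh), n_splits = 8, seed = 2)
  expect_equal(unname(v$testing[c("q025", "q25", "q50", "q75", "q975")]),
               rep(100, 5))
  v2 <- internal_validation(coh, comorbidity_cols(coh), n_splits = 8, seed = 2)
  expect_identical(v, v2)
  # noisy data still give ordered quantiles within [0, 100]
  coh2 <- labeled_cases(150, 10, 2, p_in = 0.5, p_out = 0.25, seed = 55)
  v3 <- internal_validation(coh2, comorbidity_cols(coh2), n_splits = 12,
                            seed = 3)
  qs <- v3$testing[c("q025", "q25", "q50", "q75", "q975")]
  expect_true(all(diff(qs) >= 0))
  expect_true(all(qs >= 0 & qs <= 100))
  expect_gte(v3$testing["mean"], v3$testing["q025"])
  expect_lte(v3$testing["mean"], v3$testing["q975"])
})

test_that("the classifier beats the majority-class baseline", {
  for (seed in c(61, 62)) {
    coh <- labeled_cases(250, 12, 3, p_in = 0.45, p_out = 0.1, seed = seed)
    m <- fit_subgroup_model(coh, comorbidity_cols(coh))
    baseline <- max(table(coh$subgroup)) / nrow(coh)
    expect_gte(m$training_accuracy, baseline)
  }
})

test_that("classify_all covers everyone and is idempotent on training cases", {
  spec <- cohort_spec(300, 700, n_comorbidities = 12, n_subgroups = 3,
                      p_in = 0.6, p_out = 0.05,
                      subgroup_risks = c(0.2, 0.3, 0.4), seed = 63)
  coh <- generate_cohort(spec)
  cases <- coh[coh$is_case, ]
  cases$subgroup <- cases$true_subgroup
  m <- fit_subgroup_model(cases, comorbidity_cols(coh))
  mem <- classify_all(m, cases, coh[!coh$is_case, ])
  expect_equal(nrow(mem), nrow(coh))
  fit_time <- predict_subgroup(m, cases)$assigned_subgroup
  expect_equal(mem$assigned_subgroup[match(cases$patient_id,
                                           mem$patient_id)], fit_time)
  # a control carrying exactly a subgroup's signature lands in that subgroup
  sig <- coh[!coh$is_case, ][1, ]
  sig[comorbidity_cols(coh)] <- as.list(
    as.integer(true_comorbidity_blocks(12, 3) == 2))
  expect_equal(predict_subgroup(m, sig)$assigned_subgroup, 2L)
})

test_that("subgroup risks are simple proportions with undefined flagged", {
  mem <- data.frame(patient_id = sprintf("P%03d", 1:100),
                    is_case = rep(c(TRUE, FALSE), c(20, 80)),
                    assigned_subgroup = 1L, tie = FALSE,
                    p_1 = 1, p_2 = 0)
  r <- subgroup_risk(mem)
  expect_equal(r$risk[r$subgroup == 1], 0.2)
  expect_false(r$defined[r$subgroup == 2])
  expect_true(is.na(r$risk[r$subgroup == 2]))
  expect_equal(sum(r$n_cases), 20)
})

test_that("importance scores are membership-weighted risks, ranked stably", {
  risks <- data.frame(subgroup = 1:4, n_cases = 1, n_controls = 1,
                      risk = c(0.2, 0.3, 0.25, 0.15), defined = TRUE)
  is1 <- importance_scores(c(`1` = 1, `2` = 0, `3` = 0, `4` = 0), risks)
  expect_equal(is1$importance[1], 0.2)
  expect_equal(is1$subgroup[1], 1)
  is2 <- importance_scores(c(`1` = 0.5, `2` = 0.5), risks[1:2, ])
  expect_equal(is2$importance, c(0.15, 0.10))
  expect_equal(is2$subgroup, c(2, 1))
  # uniform membership and equal risks -> stable index order
  risks3 <- data.frame(subgroup = 1:3, n_cases = 1, n_controls = 1,
                       risk = 0.2, defined = TRUE)
  is3 <- importance_scores(c(`1` = 1 / 3, `2` = 1 / 3, `3` = 1 / 3), risks3)
  expect_equal(is3$subgroup, 1:3)
  # undefined risk is excluded and reported
  risks4 <- risks3
  risks4$risk[2] <- NA
  expect_message(is4 <- importance_scores(
    c(`1` = 0.5, `2` = 0.3, `3` = 0.2), risks4), "excluded")
  expect_equal(attr(is4, "excluded"), 2L)
  expect_false(2 %in% is4$subgroup)
})
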