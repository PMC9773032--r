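# Readmission models and their comparison machinery: DeLong C-statistics,
# calibration, NRI, IDI, and model nesting.

# Cohort-shaped data from a known binary logistic model.
logistic_fixture <- function(n, beta, delta = NULL, p_in = 0.4,
                             p_out = 0.05, K = 4, seed = 1) {
  d <- length(beta)
  spec <- cohort_spec(n_cases = 10, n_controls = 10, n_comorbidities = d,
                      n_subgroups = K, p_in = p_in, p_out = p_out,
                      subgroup_risks = rep(0.5, K), seed = seed)
  pop <- withr::with_seed(seed, subgroupnet:::draw_patients(spec, n))
  X <- as.matrix(pop[comorbidity_cols(pop)])
  lp <- drop(X %*% beta) - 1.5
  if (!is.null(delta)) lp <- lp + delta[pop$true_subgroup]
  pop$is_case <- withr::with_seed(seed + 1, runif(n) < plogis(lp))
  pop$assigned_subgroup <- pop$true_subgroup
  pop
}

test_that("hierarchical coding adds exactly K-1 subgroup indicators", {
  dat <- logistic_fixture(2000, beta = rep(0.3, 6), seed = 5)
  std <- fit_prediction_model(dat, "standard", comorbidity_cols(dat))
  hier <- fit_prediction_model(dat, "hierarchical", comorbidity_cols(dat))
  expect_equal(length(coef(hier$fit)) - length(coef(std$fit)), 3)
  expect_true(all(grepl("^\\.subgroup", setdiff(names(coef(hier$fit)),
                                                names(coef(std$fit))))))
  # nesting: the richer model can never fit the training data worse
  expect_gte(logLik(hier$fit), logLik(std$fit))
})

test_that("coefficients are recovered from a known generating model", {
  # independent balanced predictors keep every standard error well under
  # the 0.05 recovery band at n = 50,000
  beta <- c(0.8, -0.5, 0.3, 0)
  dat <- logistic_fixture(50000, beta, p_in = 0.5, p_out = 0.5, K = 2,
                          seed = 9)
  std <- fit_prediction_model(dat, "standard", comorbidity_cols(dat),
                              demographics = character(0))
  est <- coef(std$fit)[paste0("c", 1:4)]
  expect_true(all(abs(unname(est) - beta) < 0.05))
})

test_that("null slopes stay within three standard errors", {
  ok <- 0
  tot <- 0
  for (seed in 1:20) {
    dat <- logistic_fixture(1500, beta = rep(0, 5), seed = 100 + seed)
    std <- fit_prediction_model(dat, "standard", comorbidity_cols(dat),
                                demographics = character(0))
    sm <- summary(std$fit)$coefficients
    zvals <- sm[paste0("c", 1:5), 3]
    ok <- ok + sum(abs(zvals) <= 3)
    tot <- tot + 5
  }
  expect_gte(ok / tot, 0.95)
})

test_that("c_statistic equals exhaustive pair counting", {
  # the worked micro-example
  scores <- c(0.9, 0.8, 0.7, 0.9)
  y <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(c_statistic(scores, outcomes = y)$c_statistic, 0.625)
  # perfect separation
  expect_equal(c_statistic(c(2, 3, 0, 1),
                           outcomes = c(TRUE, TRUE, FALSE, FALSE))$c_statistic,
               1)
  # oracle equivalence on random score vectors with ties, n <= 200
  withr::with_seed(77, {
    for (i in 1:10) {
      n <- sample(20:200, 1)
      y <- runif(n) < 0.4
      if (!any(y) || all(y)) next
      s <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)
      d <- c_statistic(s, outcomes = y)
      expect_equal(d$c_statistic, oracle_c(s, y), tolerance = 1e-12)
      expect_true(d$ci95[1] <= d$c_statistic && d$c_statistic <= d$ci95[2])
    }
  })
  # independent scores sit at the null value
  withr::with_seed(3, {
    y <- runif(10000) < 0.3
    s <- runif(10000)
    expect_equal(c_statistic(s, outcomes = y)$c_statistic, 0.5,
                 tolerance = 0.02)
  })
  expect_error(c_statistic(1:5, outcomes = rep(TRUE, 5)), "single")
})

test_that("DeLong intervals cover the true AUC at near-nominal rate", {
  mu <- 1
  true_auc <- pnorm(mu / sqrt(2))
  cover <- 0
  n_sim <- 500
  withr::with_seed(2718, {
    for (i in seq_len(n_sim)) {
      y <- rep(c(TRUE, FALSE), each = 250)
      s <- rnorm(500, mean = ifelse(y, mu, 0))
      d <- c_statistic(s, outcomes = y)
      cover <- cover + (d$ci95[1] <= true_auc && true_auc <= d$ci95[2])
    }
  })
  expect_gte(cover / n_sim, 0.92)
})

test_that("comparing a model with itself is exactly null", {
  withr::with_seed(8, {
    y <- runif(300) < 0.4
    s <- rnorm(300) + y
  })
  cmp <- compare_c(s, s, y)
  expect_equal(cmp$chi2, 0)
  expect_equal(cmp$p, 1)
})

test_that("DeLong comparison P values are super-uniform under the null", {
  pvals <- numeric(200)
  withr::with_seed(314, {
    for (i in 1:200) {
      y <- rep(c(TRUE, FALSE), each = 150)
      x <- rnorm(300, mean = ifelse(y, 0.8, 0))
      s1 <- x + rnorm(300)
      s2 <- x + rnorm(300)
      pvals[i] <- compare_c(s1, s2, y)$p
    }
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif",
                                        alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
})

test_that("per-subgroup C isolates subgroups where scores are uninformative", {
  withr::with_seed(55, {
    n <- 4000
    sub <- sample.int(2, n, replace = TRUE)
    x <- rnorm(n)
    lp <- ifelse(sub == 1, 0, 1.5 * x)   # scores pure noise in subgroup 1
    y <- runif(n) < plogis(lp - 0.5)
    dat <- data.frame(patient_id = sprintf("P%05d", 1:n), is_case = y,
                      c1 = x)
    mem <- data.frame(patient_id = dat$patient_id, is_case = y,
                      assigned_subgroup = sub, tie = FALSE)
    fit <- glm(is_case ~ c1, data = dat, family = binomial())
    model <- structure(list(kind = "standard", fit = fit, ridge = NULL,
                            separation = FALSE,
                            formula = is_case ~ c1,
                            comorbidities = "c1",
                            demographics = character(0), membership = NULL,
                            xlevels = list()),
                       class = "prediction_model")
    ps <- per_subgroup_c(model, dat, mem)
    expect_equal(ps$c_statistic[ps$subgroup == 1], 0.5, tolerance = 0.05)
    expect_gt(ps$c_statistic[ps$subgroup == 2], 0.6)
    # a subgroup with all validation patients equals the global C
    mem_all <- mem
    mem_all$assigned_subgroup <- 1L
    ps_all <- per_subgroup_c(model, dat, mem_all)
    expect_equal(ps_all$c_statistic,
                 c_statistic(model, dat)$c_statistic, tolerance = 1e-12)
    # a single-class subgroup is undefined, not zero
    mem2 <- mem
    mem2$assigned_subgroup[1] <- 3L
    dat2 <- dat
    ps2 <- per_subgroup_c(model, dat2, mem2)
    expect_false(ps2$defined[ps2$subgroup == 3])
  })
})

test_that("calibration transforms behave as the definitions demand", {
  withr::with_seed(21, {
    lp <- rnorm(20000, -1, 1.2)
    y <- runif(20000) < plogis(lp)
  })
  cal <- calibration(lp, outcomes = y)
  expect_equal(cal$slope, 1, tolerance = 0.1)
  expect_equal(cal$citl, 0, tolerance = 0.1)
  # doubling the linear predictor halves the slope
  cal2 <- calibration(2 * lp, outcomes = y)
  expect_equal(cal2$slope, 0.5, tolerance = 0.05)
  # shifting the linear predictor by +1 moves the intercept to -1
  cal3 <- calibration(lp + 1, outcomes = y)
  expect_equal(cal3$citl, -1, tolerance = 0.1)
  expect_error(calibration(rep(0.3, 100), outcomes = y[1:100]),
               "degenerate")
})

test_that("NRI reproduces the worked micro-examples exactly", {
  # identical probabilities -> 0 for both variants
  r0 <- nri(c(0.2, 0.4, 0.6), c(0.2, 0.4, 0.6), c(TRUE, FALSE, TRUE),
            cutpoints = 0.5)
  expect_equal(r0$continuous$estimate, 0)
  expect_equal(r0$categorical$estimate, 0)
  # events move (+0.10, -0.05); the non-event moves -0.20 -> continuous 1.0
  r1 <- nri(old_probs = c(0.30, 0.50, 0.40),
            new_probs = c(0.40, 0.45, 0.20),
            outcomes = c(TRUE, TRUE, FALSE))
  expect_equal(r1$continuous$estimate, 1.0)
  # categorical at cutpoint 0.15: event up, non-event down -> 2
  r2 <- nri(old_probs = c(0.10, 0.20), new_probs = c(0.20, 0.10),
            outcomes = c(TRUE, FALSE), cutpoints = 0.15)
  expect_equal(r2$categorical$estimate, 2)
  expect_error(nri(c(0.1), c(0.2), TRUE), "non-events")
  expect_error(nri(c(0.1, 0.2), c(0.2, 0.3), c(TRUE, FALSE),
                   cutpoints = c(0.5, 0.5)), "strictly increasing")
})

test_that("IDI reproduces the worked micro-example and is antisymmetric", {
  old <- c(0.6, 0.8, 0.3)
  new <- c(0.7, 0.9, 0.2)
  y <- c(TRUE, TRUE, FALSE)
  expect_equal(idi(old, new, y)$estimate, 0.2)
  expect_equal(idi(new, old, y)$estimate, -0.2)
  expect_equal(idi(old, old, y)$estimate, 0)
  expect_equal(idi(old, old, y)$p, 1)
})

test_that("NRI and IDI match per-subject tabulation on random inputs", {
  withr::with_seed(99, {
    for (i in 1:10) {
      n <- sample(10:50, 1)
      y <- runif(n) < 0.5
      if (!any(y) || all(y)) next
      old <- runif(n)
      new <- pmin(pmax(old + rnorm(n, 0, 0.2), 0), 1)
      cp <- sort(runif(2, 0.2, 0.8))
      r <- nri(old, new, y, cutpoints = cp)
      expect_equal(r$continuous$estimate, oracle_nri(old, new, y),
                   tolerance = 1e-12)
      expect_equal(r$categorical$estimate, oracle_nri(old, new, y, cp),
                   tolerance = 1e-12)
      expect_equal(idi(old, new, y)$estimate, oracle_idi(old, new, y),
                   tolerance = 1e-12)
    }
  })
})

test_that("separation triggers the recorded ridge fallback", {
  dat <- data.frame(patient_id = sprintf("P%03d", 1:80),
                    is_case = rep(c(TRUE, FALSE), each = 40),
                    c1 = rep(c(1L, 0L), each = 40),
                    c2 = rbinom(80, 1, 0.5))
  std <- fit_prediction_model(dat, "standard", c("c1", "c2"),
                              demographics = character(0))
  expect_true(std$separation)
  expect_false(is.null(std$ridge))
  lp <- predict(std, dat, type = "link")
  expect_gt(min(lp[dat$is_case]), max(lp[!dat$is_case]))
})
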