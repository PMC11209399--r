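outcome_records <- function() {
  # 46 cases mirroring a realistic 250-day follow-up composition:
  # 8 lost early, 10 tumor deaths, 3 unrelated deaths, 25 survivors
  data.frame(
    case_id = sprintf("c%02d", 1:46),
    time_days = c(seq(20, 230, length.out = 8),        # lost
                  seq(30, 240, length.out = 10),       # tumor deaths
                  c(60, 120, 200),                     # other deaths
                  seq(260, 1900, length.out = 25)),    # alive past horizon
    event = c(rep("lost", 8), rep("tumor_death", 10),
              rep("other_death", 3), rep("alive", 25)),
    score = c(runif(8, 5, 25), runif(10, 12, 30), runif(3, 5, 25),
              runif(25, 2, 20)))
}

test_that("cohort preparation applies the 250-day rules", {
  set.seed(1)
  rec <- outcome_records()
  coh <- prepare_cohort(rec, horizon_days = 250)
  expect_equal(sum(coh$binary$label == 1), 10)
  expect_equal(sum(coh$binary$label == 0), 25)
  expect_equal(nrow(coh$survival), 38)          # 46 - 8 lost
  expect_equal(sum(coh$survival$status), 10)
  expect_true(all(coh$survival$time <= 250))
  # alive at 400 days -> censored at 250
  expect_equal(coh$survival$time[coh$survival$case_id == "c22"], 250)
  # tumor death at day 30 -> event at its own time
  expect_equal(coh$survival$time[coh$survival$case_id == "c09"],
               rec$time_days[9])
  # unrelated deaths censored at death time, excluded from binary labels
  expect_equal(coh$survival$status[coh$survival$case_id == "c19"], 0)
  expect_true(all(c("c19", "c20", "c21") %in%
                  coh$excluded$case_id[coh$excluded$reason ==
                                       "no_binary_label"]))
})

test_that("cohort preparation rejects malformed records", {
  rec <- outcome_records()
  rec$event[1] <- "vanished"
  expect_error(prepare_cohort(rec), "unknown event")
})

test_that("AUC equals the brute-force pairwise probability", {
  expect_equal(roc_auc(c(2, 3, 0, 1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(5, 6), rep(c(1, 0), 3))$auc, 0.5)
  expect_equal(roc_auc(c(1, 3, 2, 4), c(1, 1, 0, 0))$auc, 0.25)

  set.seed(17)
  for (rep in 1:25) {
    n <- sample(4:50, 1)
    labels <- c(1, 1, 0, 0, rbinom(n - 4, 1, 0.5))
    scores <- round(rnorm(n), sample(0:2, 1))  # ties likely at 0 digits
    a <- roc_auc(scores, labels)
    expect_equal(a$auc, brute_auc(scores, labels), tolerance = 1e-12)
    expect_true(a$ci[1] <= a$auc && a$auc <= a$ci[2])
  }
})

test_that("AUC refuses a single-class input", {
  expect_error(roc_auc(1:5, rep(1, 5)), "both")
})

test_that("threshold selection is exhaustive-search optimal", {
  # documented worked example: minimal admissible Sen is 1.0, Sp = 2/3
  th <- select_threshold(c(4, 5, 6, 1, 2, 5), c(1, 1, 1, 0, 0, 0), 0.70)
  expect_equal(th$sensitivity, 1)
  expect_equal(th$specificity, 2 / 3)
  expect_true(th$threshold > 2 && th$threshold <= 4)

  # perfectly separated classes
  th2 <- select_threshold(c(10, 11, 12, 1, 2, 3), c(1, 1, 1, 0, 0, 0), 0.70)
  expect_equal(th2$specificity, 1)
  expect_gte(th2$sensitivity, 0.70)

  # with 10 positives a threshold classifying exactly 7 gives Sen 0.70
  set.seed(23)
  scores <- c(1:10, runif(25, 0, 8))
  labels <- rep(c(1, 0), c(10, 25))
  th3 <- select_threshold(scores, labels, 0.70)
  expect_equal(th3$sensitivity, 0.7)
  expect_equal(th3$TP, 7L)

  set.seed(29)
  for (rep in 1:20) {
    n <- sample(6:30, 1)
    labels <- c(1, 1, 0, rbinom(n - 3, 1, 0.4))
    scores <- round(runif(n, 0, 10), 1)
    th <- select_threshold(scores, labels, 0.70)
    # invariants: Sen >= target; no candidate with the same Sen beats its Sp
    expect_gte(th$sensitivity, 0.70)
    cand <- c(-Inf, sort(unique(scores)), Inf)
    for (t in cand) {
      pos <- scores >= t
      sen <- sum(pos & labels == 1) / sum(labels == 1)
      sp <- sum(!pos & labels == 0) / sum(labels == 0)
      if (sen >= 0.70) expect_lte(th$sensitivity, sen)
      if (sen == th$sensitivity) expect_gte(th$specificity, sp)
    }
    # confusion identities hold exactly
    expect_equal(th$sensitivity, th$TP / (th$TP + th$FN))
    expect_equal(th$specificity, th$TN / (th$TN + th$FP))
    if (th$TP + th$FP > 0)
      expect_equal(th$precision, th$TP / (th$TP + th$FP))
  }
})

test_that("precision reconstructs from rounded rates and class sizes", {
  expect_equal(precision_from_rates(0.70, 0.68, 10, 25), 7 / 15)
  expect_equal(precision_from_rates(1.0, 1.0, 10, 25), 1)
  expect_equal(precision_from_rates(0.70, 0.92, 10, 25), 7 / 9)
  expect_equal(precision_from_rates(0.70, 0.48, 10, 25), 7 / 20)
})

test_that("Cox estimate matches a 1-D partial-likelihood oracle", {
  x <- c(1, 0, 1, 0)
  fit <- cox_univariate(x, c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(fit$hr, brute_cox_hr(x, c(1, 2, 3, 4), c(1, 1, 1, 1)),
               tolerance = 1e-4)

  set.seed(31)
  for (rep in 1:5) {
    n <- 12
    x <- rnorm(n)
    time <- sample(seq_len(100), n)  # unique times: ties play no role
    status <- rbinom(n, 1, 0.7)
    if (sum(status) < 2 || length(unique(x)) < 2) next
    fit <- cox_univariate(x, time, status)
    expect_equal(fit$hr, brute_cox_hr(x, time, status), tolerance = 1e-3)
  }
})

test_that("Cox flags complete separation as non-estimable", {
  # all events in one group, ordered so the likelihood is monotone
  expect_warning(
    fit <- cox_univariate(c(1, 1, 1, 0, 0, 0), c(1, 2, 3, 10, 11, 12),
                          c(1, 1, 1, 0, 0, 0)),
    "not estimable")
  expect_false(fit$estimable)
})

test_that("null Cox CIs cover HR = 1 at the nominal rate", {
  covered <- vapply(1:200, function(i) {
    sp <- cohort_spec(n_cases = 100,
                      covariates = list(g = list(type = "binary",
                                                 prob = 0.5)),
                      coef = c(g = 0), baseline_rate = 1 / 300,
                      seed = 5000 + i)
    coh <- generate_outcome_cohort(sp)
    fit <- cox_univariate(coh$g, coh$time_days,
                          as.integer(coh$event == "tumor_death"))
    fit$ci[1] <= 1 && 1 <= fit$ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})

test_that("Kaplan-Meier matches the empirical survival when uncensored", {
  km <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))

  km2 <- kaplan_meier(c(5, 7, 9), c(0, 0, 0))
  expect_true(all(km2$surv == 1))
})

test_that("log-rank of identical groups is null; separated groups are not", {
  t <- c(1:10, 1:10); s <- rep(1, 20)
  g <- rep(c("a", "b"), each = 10)
  lr <- log_rank(t, s, g)
  expect_lt(lr$chisq, 1e-10)
  expect_equal(lr$p, 1, tolerance = 1e-6)
  expect_equal(lr$df, 1)

  lr2 <- log_rank(c(1:10, 101:110), rep(1, 20), g)
  expect_lt(lr2$p, 1e-4)
})

test_that("Cohen's kappa follows the chance-corrected formula", {
  a <- rep(c("x", "x", "y", "y"), c(20, 5, 5, 20))
  b <- rep(c("x", "y", "x", "y"), c(20, 5, 5, 20))
  expect_equal(cohens_kappa(a, b), 0.6, tolerance = 1e-12)
  expect_equal(cohens_kappa(a, b), cohens_kappa(b, a))
  expect_equal(cohens_kappa(a, a), 1)
  # both constant and identical
  expect_equal(cohens_kappa(rep(1, 5), rep(1, 5)), 1)
  expect_error(cohens_kappa(rep(1, 5), c(1, 1, 1, 1, 2)), NA)
})

test_that("kappa agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(37)
  for (rep in 1:5) {
    a <- sample(1:3, 60, replace = TRUE)
    b <- ifelse(runif(60) < 0.6, a, sample(1:3, 60, replace = TRUE))
    tab <- table(factor(a, 1:3), factor(b, 1:3))
    expect_equal(cohens_kappa(a, b), e1071::classAgreement(tab)$kappa,
                 tolerance = 1e-10)
  }
})

test_that("Light's kappa averages pairs and labels agreement", {
  panel <- cbind(R1 = c(1, 2, 3, 1, 2), R2 = c(1, 2, 3, 1, 2),
                 R3 = c(1, 2, 3, 1, 2))
  lk <- lights_kappa(panel)
  expect_equal(lk$lights_kappa, 1)
  expect_equal(lk$interpretation, "almost perfect")
  expect_equal(mean(lk$pairwise[upper.tri(lk$pairwise)]), 1)
})

test_that("kappa interpretation bins round to 2 decimals first", {
  expect_equal(interpret_kappa(0.204), "slight")
  expect_equal(interpret_kappa(0.272), "fair")
  expect_equal(interpret_kappa(0.90), "almost perfect")
  expect_equal(interpret_kappa(-0.1), "poor")
  expect_equal(interpret_kappa(0.405), "moderate")  # rounds to 0.41
  expect_equal(interpret_kappa(0.61), "substantial")
})
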