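# Evaluation statistics: correlation, ROC/AUC, Youden cutoff, diagnostic
# metrics, DeLong comparisons, screening and logistic regression.

test_that("pearson correlation matches closed form and flags degeneracy", {
  x <- seq_len(20)
  expect_equal(pearson_corr(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  y <- c(1, -1, 1, -1, 1, -1)
  x2 <- c(1, 1, -1, -1, 0, 0)     # orthogonal, both zero-mean
  expect_lt(abs(pearson_corr(x2, y)$r), 1e-12)
  set.seed(4)
  a <- rnorm(50); b <- 0.3 * a + rnorm(50)
  hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_corr(a, b)$r, hand, tolerance = 1e-12)
  expect_error(pearson_corr(rep(1, 10), rnorm(10)), "zero variance")
})

test_that("AUC matches the stated example and brute force with ties", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 10), c(0, 0, 1, 1))$auc, 1.0)
  set.seed(14)
  for (i in 1:25) {
    n <- sample(8:30, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels)$auc,
                 auc_bruteforce(scores, labels), tolerance = 1e-12)
  }
  expect_error(roc_auc(rnorm(10), rep(1, 10)), "both")
})

test_that("null AUC sits near one half", {
  set.seed(15)
  scores <- rnorm(1000)
  labels <- rbinom(1000, 1, 0.5)
  expect_lt(abs(roc_auc(scores, labels)$auc - 0.5), 0.05)
})

test_that("AUC confidence intervals agree with the DeLong reference", {
  skip_if_not_installed("pROC")
  set.seed(16)
  scores <- rnorm(80) + 0.8 * rbinom(80, 1, 0.4)
  labels <- rbinom(80, 1, 0.4)
  labels[1:2] <- c(0, 1)
  mine <- roc_auc(scores, labels)
  ref <- pROC::ci.auc(pROC::roc(labels, scores, quiet = TRUE,
                                direction = "<"), method = "delong")
  expect_equal(mine$auc, as.numeric(ref[2]), tolerance = 1e-10)
  expect_equal(mine$ci, as.numeric(ref[c(1, 3)]), tolerance = 1e-6)
})

test_that("Youden cutoff equals exhaustive midpoint search", {
  set.seed(17)
  for (i in 1:10) {
    scores <- round(rnorm(20), 2)
    labels <- rbinom(20, 1, 0.5)
    if (length(unique(labels)) < 2 || length(unique(scores)) < 2) next
    got <- youden_cutoff(scores, labels)
    u <- sort(unique(scores))
    cand <- (u[-1] + u[-length(u)]) / 2
    j <- sapply(cand, function(cut)
      mean(scores[labels == 1] > cut) + mean(scores[labels == 0] <= cut) - 1)
    best <- cand[j >= max(j) - 1e-12]
    expect_equal(as.numeric(got), max(best), tolerance = 1e-12)
    expect_equal(attr(got, "youden"), max(j), tolerance = 1e-12)
  }
})

test_that("Youden cutoff splits separable data and rejects constants", {
  cut <- youden_cutoff(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(as.numeric(cut), 6.5)
  expect_error(youden_cutoff(rep(2, 6), c(0, 0, 0, 1, 1, 1)), "degenerate")
})

test_that("diagnostic metrics reproduce the 2x2 hand computation", {
  # TP=40 FN=10 FP=30 TN=120: scores > 0 called positive
  scores <- c(rep(1, 40), rep(-1, 10), rep(1, 30), rep(-1, 120))
  labels <- c(rep(1, 50), rep(0, 150))
  bm <- binary_metrics(scores, labels, 0)
  est <- setNames(bm$estimate, bm$metric)
  expect_equal(unname(est["sensitivity"]), 0.80)
  expect_equal(unname(est["specificity"]), 0.80)
  expect_equal(unname(est["ppv"]), 40 / 70, tolerance = 1e-12)
  expect_equal(unname(est["npv"]), 120 / 130, tolerance = 1e-12)
  expect_equal(attr(bm, "table"), c(TP = 40L, FN = 10L, FP = 30L, TN = 120L))
  # CI bounds are exact Clopper-Pearson
  ref <- binom.test(40, 50)$conf.int
  expect_equal(c(bm$lo[1], bm$hi[1]), as.numeric(ref), tolerance = 1e-12)
  # margins reconstruct n; PPV * predicted positives = TP
  expect_equal(sum(attr(bm, "table")), length(labels))
  expect_equal(est[["ppv"]] * 70, 40, tolerance = 1e-9)
})

test_that("metric edge cases: perfect classifier and off-scale cutoffs", {
  scores <- c(1, 2, 3, 11, 12, 13)
  labels <- c(0, 0, 0, 1, 1, 1)
  bm <- binary_metrics(scores, labels, 6.5)
  expect_true(all(bm$estimate == 1))
  hi <- binary_metrics(scores, labels, 100)
  est <- setNames(hi$estimate, hi$metric)
  expect_equal(unname(est["sensitivity"]), 0)
  expect_true(is.na(est["ppv"]))                # no predicted positives
  expect_equal(unname(est["npv"]), 0.5)         # complement of prevalence
})

test_that("DeLong test is null for identical scores, detects reversal", {
  set.seed(18)
  y <- rbinom(40, 1, 0.5); y[1:2] <- c(0, 1)
  a <- rnorm(40) + y
  same <- delong_test(a, a, y)
  expect_equal(same$diff, 0)
  expect_equal(same$p, 1)
  # strongly separable scores reversed: difference detected
  b <- -a
  rev <- delong_test(a, b, y)
  expect_equal(rev$auc_b, 1 - rev$auc_a, tolerance = 1e-12)
  if (rev$auc_a > 0.85) expect_lt(rev$p, 0.01)
})

test_that("DeLong agrees with the paired reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(77)
  n <- 40
  y <- rbinom(n, 1, 0.5); y[1:2] <- c(0, 1)
  lat <- rnorm(n) + 1.1 * y
  a <- lat + rnorm(n, 0, 0.8)
  b <- lat + rnorm(n, 0, 1.3) + 0.12
  mine <- delong_test(a, b, y)
  ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE, direction = "<"),
                        pROC::roc(y, b, quiet = TRUE, direction = "<"),
                        method = "delong", paired = TRUE)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
})

test_that("screening keeps strong effects, drops constants and nulls", {
  set.seed(19)
  n <- 100
  co <- data.frame(
    outcome = rep(c(0, 1), each = n / 2),
    strong = c(rnorm(n / 2, 0), rnorm(n / 2, 3)),
    constant = rep(1.5, n),
    nullv = rnorm(n),
    flag = rbinom(n, 1, 0.5)
  )
  expect_warning(sc <- screen_variables(co, "outcome"), "constant")
  expect_true("strong" %in% attr(sc, "selected"))
  expect_false("constant" %in% attr(sc, "selected"))
  expect_equal(sc$test[sc$variable == "flag"], "chisq")
  expect_equal(sc$test[sc$variable == "strong"], "t")
})

test_that("logistic model reproduces the contingency closed form", {
  # 2x2 table a=30 b=10 c=20 d=40 -> OR = 6
  co <- data.frame(
    outcome = c(rep(1, 40), rep(0, 60)),
    x = c(rep(1, 30), rep(0, 10), rep(1, 20), rep(0, 40))
  )
  m <- logistic_model(co, "outcome", "x")
  expect_equal(m$coefficients$or[m$coefficients$term == "x"],
               (30 * 40) / (10 * 20), tolerance = 1e-6)
})

test_that("logistic model flags separation and degenerate outcomes", {
  co <- data.frame(outcome = rep(c(0, 1), each = 20),
                   x = rep(c(0, 1), each = 20))
  expect_error(logistic_model(co, "outcome", "x"), "separation")
  co2 <- data.frame(outcome = rep(1, 30), x = rnorm(30))
  expect_error(logistic_model(co2, "outcome", "x"), "constant")
})

test_that("adding an informative GWR never lowers in-sample AUC", {
  co <- simulate_cohort(400, seed = 31L)
  base_preds <- c("age", "epinephrine", "dbp", "witnessed")
  m0 <- logistic_model(co, "outcome", base_preds)
  m1 <- logistic_model(co, "outcome", c(base_preds, "automated_s"))
  expect_gte(m1$auc, m0$auc - 1e-9)
})

test_that("stratified split keeps proportions within strata", {
  co <- simulate_cohort(300, seed = 41L)
  sp <- split_cohort(co)
  expect_setequal(unique(sp$set), c("derivation", "validation"))
  frac <- mean(sp$set == "derivation")
  expect_gt(frac, 0.5); expect_lt(frac, 0.7)
  # age and sex distributions balanced across sets
  expect_gt(t.test(age ~ set, data = sp)$p.value, 0.01)
})
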