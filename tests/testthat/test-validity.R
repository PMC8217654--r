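test_that("roc_curve enumerates midpoint thresholds with exact Se/Sp", {
  scores <- c(5, 9, 3, 7)
  labels <- c(TRUE, TRUE, FALSE, FALSE)
  roc <- roc_curve(scores, labels)
  expect_equal(nrow(roc), 5)
  expect_equal(roc$threshold, c(2, 4, 6, 8, 10))
  for (i in seq_len(nrow(roc))) {
    oracle <- count_se_sp(scores, labels, roc$threshold[i])
    expect_equal(roc$sensitivity[i], unname(oracle["se"]))
    expect_equal(roc$specificity[i], unname(oracle["sp"]))
  }
  # monotone in the threshold
  expect_true(all(diff(roc$sensitivity) <= 0))
  expect_true(all(diff(roc$specificity) >= 0))
  expect_error(roc_curve(scores, rep(TRUE, 4)), "degenerate")
})

test_that("perfect separation and uninformative scores behave as expected", {
  roc <- roc_curve(c(10, 10, 2, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_true(any(roc$sensitivity == 1 & roc$specificity == 1))
  roc2 <- roc_curve(c(4, 7, 4, 7), c(TRUE, TRUE, FALSE, FALSE))
  expect_true(all(roc2$sensitivity + roc2$specificity <= 1 + 1e-12))
})

test_that("the equal-Se/Sp cutpoint minimizes |Se - Sp| with stated tie breaks", {
  roc <- tibble::tibble(threshold = c(1, 2, 3),
                        sensitivity = c(1.0, 0.9, 0.5),
                        specificity = c(0.2, 0.9, 0.8))
  oc <- optimal_cutpoint(roc)
  expect_equal(oc$threshold, 2)
  expect_equal(oc$sensitivity, 0.9)

  # |Se-Sp| ties resolved by the larger Se+Sp
  roc2 <- tibble::tibble(threshold = c(1, 2),
                         sensitivity = c(0.7, 0.9),
                         specificity = c(0.7, 0.9))
  expect_equal(optimal_cutpoint(roc2)$threshold, 2)

  # full ties resolved by the smaller threshold
  roc3 <- tibble::tibble(threshold = c(4, 2),
                         sensitivity = c(0.8, 0.8),
                         specificity = c(0.8, 0.8))
  expect_equal(optimal_cutpoint(roc3)$threshold, 2)

  # Youden alternative maximizes Se + Sp - 1, not |Se - Sp|
  roc4 <- tibble::tibble(threshold = c(1, 2),
                         sensitivity = c(1.0, 0.8),
                         specificity = c(0.7, 0.8))
  expect_equal(optimal_cutpoint(roc4, method = "youden")$threshold, 1)
  expect_equal(optimal_cutpoint(roc4)$threshold, 2)
})

test_that("Mann-Whitney AUC equals pairwise counting and handles ties", {
  expect_equal(auc(c(5, 9, 3, 7), c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_equal(auc(c(10, 9, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auc(rep(4, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  set.seed(3)
  for (i in 1:20) {
    inst <- random_roc_instance()
    expect_equal(auc(inst$scores, inst$labels),
                 pairwise_auc(inst$scores, inst$labels))
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(8)
  for (i in 1:10) {
    inst <- random_roc_instance()
    a0 <- auc(inst$scores, inst$labels)
    expect_equal(auc(exp(inst$scores / 3), inst$labels), a0)
    expect_equal(auc(rank(inst$scores, ties.method = "average"),
                     inst$labels), a0)
  }
})

test_that("AUC agrees with pROC on random instances", {
  set.seed(21)
  for (i in 1:10) {
    inst <- random_roc_instance()
    ref <- as.numeric(suppressMessages(
      pROC::auc(pROC::roc(inst$labels, inst$scores, quiet = TRUE,
                          levels = c(FALSE, TRUE), direction = "<"))))
    expect_equal(auc(inst$scores, inst$labels), ref)
  }
})

test_that("Hanley-McNeil interval matches the closed form and edge cases", {
  # closed-form oracle evaluated term by term
  hm_oracle <- function(a, n1, n0, level = 0.95) {
    q1 <- a / (2 - a)
    q2 <- 2 * a^2 / (1 + a)
    se <- sqrt((a * (1 - a) + (n1 - 1) * (q1 - a^2) +
                (n0 - 1) * (q2 - a^2)) / (n1 * n0))
    a + c(-1, 1) * stats::qnorm(1 - (1 - level) / 2) * se
  }
  ci <- auc_ci(0.918, 16, 20)
  expect_equal(unname(ci), hm_oracle(0.918, 16, 20))

  ci5 <- auc_ci(0.5, 100, 100)
  expect_equal(unname(ci5[1] + ci5[2]), 1)  # symmetric about 0.5

  ci1 <- auc_ci(1, 12, 13)
  expect_equal(unname(ci1), c(1, 1))  # SE collapses at the boundary

  # small-sample high AUC: the untruncated upper bound may exceed 1
  expect_gt(auc_ci(0.96, 12, 13)[["upper"]], 1)
  expect_error(auc_ci(0.9, 0, 10), "degenerate")
})

test_that("Clopper-Pearson interval matches binom.test and hits the bounds", {
  ci <- binomial_ci(14, 16)
  ref <- stats::binom.test(14, 16)$conf.int
  expect_equal(unname(ci), as.numeric(ref), tolerance = 1e-10)
  expect_equal(round(unname(ci), 3), c(0.617, 0.984), tolerance = 0.005)
  expect_equal(binomial_ci(0, 7)[["lower"]], 0)
  expect_equal(binomial_ci(7, 7)[["upper"]], 1)
  set.seed(4)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    x <- sample(0:n, 1)
    expect_equal(unname(binomial_ci(x, n)),
                 as.numeric(stats::binom.test(x, n)$conf.int),
                 tolerance = 1e-10)
  }
  expect_error(binomial_ci(0, 0), "trials")
})

test_that("evaluate reproduces confusion arithmetic at a cutoff", {
  # 16 cases (14 above cutoff), 20 non-cases (2 above): TP=14 FN=2 TN=18 FP=2
  scores <- c(rep(10, 14), rep(2, 2), rep(10, 2), rep(2, 18))
  labels <- rep(c(TRUE, FALSE), c(16, 20))
  rep_ <- evaluate(scores, labels, cutoff = 6)
  expect_equal(rep_$true_positives, 14)
  expect_equal(rep_$false_negatives, 2)
  expect_equal(rep_$true_negatives, 18)
  expect_equal(rep_$false_positives, 2)
  expect_equal(rep_$accuracy, 32 / 36)
  expect_equal(rep_$sensitivity, 0.875)
  expect_equal(rep_$specificity, 0.9)

  lo <- evaluate(scores, labels, cutoff = 0)
  expect_equal(lo$sensitivity, 1)
  expect_equal(lo$specificity, 0)
  hi <- evaluate(scores, labels, cutoff = 99)
  expect_equal(hi$sensitivity, 0)
  expect_equal(hi$specificity, 1)
})

test_that("reporter correlation pairs families and needs three pairs", {
  sc <- tibble::tibble(
    informant_id = c(paste0("F", 1:5, "-a"), paste0("F", 1:5, "-c")),
    family_id = rep(paste0("F", 1:5), 2),
    reporter_group = rep(c("adult", "child"), each = 5),
    total = c(1, 5, 9, 13, 17, 1, 5, 9, 13, 17),
    valid = TRUE
  )
  expect_equal(reporter_correlation(sc), 1)
  sc$total[6:10] <- 30 - sc$total[6:10]
  expect_equal(reporter_correlation(sc), -1)
  expect_error(reporter_correlation(sc[c(1, 2, 6, 7), ]), "pairs")
})

test_that("reporter correlation recovers the generator's latent correlation", {
  cfg <- generator_config(n_families = 500,
                          child_adult_latent_correlation = 0.85,
                          seed = 2024)
  co <- generate_cohort(cfg)
  sc <- score_cohort(co$responses, battery_items())
  expect_lt(abs(reporter_correlation(sc) - 0.85), 0.05)
})
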