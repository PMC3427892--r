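test_that("roc_curve reproduces the hand-enumerated 4-subject curve", {
  roc <- roc_curve(c(1, 3, 0, 2), c(1, 1, 0, 0), "higher_is_positive")
  expect_equal(nrow(roc), 5L)
  expect_equal(roc$sensitivity[1], 0)
  expect_equal(roc$fpr[1], 0)
  expect_equal(roc$sensitivity[nrow(roc)], 1)
  ops <- roc[!is.na(roc$label), c("sensitivity", "fpr")]
  expect_true(any(ops$sensitivity == 0.5 & ops$fpr == 0))
  expect_true(any(ops$sensitivity == 1.0 & ops$fpr == 0.5))
  expect_error(roc_curve(1:4, c(1, 1, 1, 1), "higher_is_positive"),
               "case and one control")
})

test_that("perfect separation passes through (0, 1) with AUROC 1", {
  roc <- roc_curve(c(9, 8, 2, 1), c(0, 0, 1, 1), "lower_is_positive")
  expect_true(any(roc$sensitivity == 1 & roc$fpr == 0))
  expect_equal(auroc(c(9, 8, 2, 1), c(0, 0, 1, 1), "lower_is_positive")$auc, 1)
})

test_that("direction flip equals negating the scores", {
  set.seed(1)
  s <- rnorm(60); y <- rbinom(60, 1, 0.4)
  a <- roc_curve(s, y, "lower_is_positive")
  b <- roc_curve(-s, y, "higher_is_positive")
  expect_equal(a$sensitivity, b$sensitivity)
  expect_equal(a$fpr, b$fpr)
  expect_equal(auroc(s, y, "lower_is_positive")$auc,
               auroc(-s, y, "higher_is_positive")$auc)
})

test_that("AUROC is the tie-corrected rank statistic", {
  expect_equal(auroc(c(1, 3, 0, 2), c(1, 1, 0, 0),
                     "higher_is_positive")$auc, 0.75)
  # half-credit for ties
  expect_equal(auroc(c(1, 1), c(1, 0), "higher_is_positive")$auc, 0.5)
})

test_that("trapezoid area equals the rank statistic to 1e-12 without ties", {
  set.seed(88)
  for (rep in 1:20) {
    s <- rnorm(80)
    y <- rbinom(80, 1, 0.5)
    if (length(unique(y)) < 2) next
    roc <- roc_curve(s, y, "higher_is_positive")
    au <- auroc(s, y, "higher_is_positive")$auc
    expect_equal(trapezoid_auc(roc), au, tolerance = 1e-12)
  }
})

test_that("AUROC is invariant under strictly monotone score transforms", {
  set.seed(5)
  s <- rnorm(100); y <- rbinom(100, 1, 0.3)
  base <- auroc(s, y, "higher_is_positive")$auc
  expect_equal(auroc(exp(s), y, "higher_is_positive")$auc, base)
  expect_equal(auroc(qlogis(plogis(s)) * 3 + 2, y,
                     "higher_is_positive")$auc, base)
})

test_that("DeLong and Hanley-McNeil intervals bracket the estimate", {
  set.seed(9)
  s <- c(rnorm(80, 1), rnorm(120))
  y <- rep(c(1, 0), c(80, 120))
  for (m in c("delong", "hanley-mcneil")) {
    a <- auroc(s, y, "higher_is_positive", ci_method = m)
    expect_true(a$ci[1] <= a$auc && a$auc <= a$ci[2])
    expect_true(a$ci[1] >= 0 && a$ci[2] <= 1)
    expect_gt(a$se, 0)
  }
})

test_that("youden reproduces the printed-index arithmetic", {
  expect_equal(round(youden(0.879, 0.997), 2), 0.88)
  expect_equal(youden(1, 1), 1)
  expect_equal(youden(0.5, 0.5), 0)
  expect_error(youden(1.2, 0.5), "\\[0, 1\\]")
})

test_that("optimal cutpoint maximizes J and dual-reports close seconds", {
  set.seed(33)
  cases <- pmax(0, pmin(9, round(rnorm(120, 3.4, 1.8))))
  controls <- pmax(0, pmin(9, round(rnorm(200, 7.4, 1.4))))
  scores <- c(cases, controls)
  y <- rep(c(1, 0), c(120, 200))
  roc <- roc_curve(scores, y, "lower_is_positive")
  cp <- optimal_cutpoint(roc, delta_j = 0.05)
  interior <- roc[!is.na(roc$label), ]
  jall <- interior$sensitivity + interior$specificity - 1
  expect_equal(max(cp$youden), max(jall))
  if (nrow(cp) == 2L) {
    expect_equal(cp$favors, c("specificity", "sensitivity"))
    expect_gte(cp$specificity[1], cp$specificity[2])
    expect_true(min(cp$youden) >= max(jall) - 0.05)
  }
  one <- optimal_cutpoint(roc, preference = "favor_sensitivity")
  expect_equal(nrow(one), 1L)
  expect_equal(one$sensitivity, max(cp$sensitivity))
})

test_that("degenerate identical scores give a documented error", {
  expect_error(optimal_cutpoint(
    roc_curve(rep(3, 10), rep(c(1, 0), 5), "lower_is_positive")),
    "degenerate")
})

test_that("cutpoint semantics match the </> notation", {
  cp5 <- cutpoint(5, "below")
  expect_equal(cp5$label, "<5")
  expect_true(apply_cutpoint(4, cp5))
  expect_false(apply_cutpoint(5, cp5))
  cp1 <- cutpoint(1, "above")
  expect_equal(cp1$label, ">1")
  expect_true(apply_cutpoint(2, cp1))
  expect_false(apply_cutpoint(1, cp1))
})

test_that("stratified validation reports per-stratum operating measures", {
  scores <- c(2, 3, 8, 9, 4, 8, 9, 3)
  labels <- c(1, 1, 1, 0, 1, 0, 0, 0)
  severity <- c("mild", "moderate", "mild", NA, "moderate", NA, NA, NA)
  education <- c(NA, NA, NA, "high", NA, "low", "high", "low")
  out <- stratified_validation(scores, labels, cutpoint(6, "below"),
                               severity = severity, education = education)
  get <- function(type, stratum) out$value[out$stratum_type == type &
                                           out$stratum == stratum]
  expect_equal(get("overall", "all_cases"), 0.75)
  expect_equal(get("severity", "mild"), 0.5)
  expect_equal(get("severity", "moderate"), 1)
  expect_equal(get("education", "low"), 0.5)
  expect_equal(get("education", "high"), 1)
})

test_that("an empty stratum is reported as not estimable", {
  out <- stratified_validation(c(2, 3, 8), c(1, 1, 0), cutpoint(6, "below"),
                               severity = c("mild", "mild", NA))
  mod <- out[out$stratum == "moderate", ]
  expect_false(mod$estimable)
  expect_true(is.na(mod$value))
})

test_that("validate_scale ties the pieces together consistently", {
  cc <- generator_config("case_control", seed = 7)
  sim <- generate_case_control(cc)
  sc <- score_cohort(sim$cohort)
  vr <- validate_scale(sc$combined, sim$cohort$subjects$diagnosis,
                       "lower_is_positive", scale = "combined",
                       severity = sim$cohort$subjects$severity,
                       education = sim$cohort$subjects$education)
  expect_true(vr$auroc$auc >= 0 && vr$auroc$auc <= 1)
  # the reported cutpoint row agrees with its ROC operating point
  row <- vr$roc[!is.na(vr$roc$label) &
                  vr$roc$threshold == vr$cutpoints$threshold[1], ]
  expect_equal(row$sensitivity, vr$cutpoints$sensitivity[1])
  expect_equal(row$specificity, vr$cutpoints$specificity[1])
  expect_equal(vr$cutpoints$youden,
               vr$cutpoints$sensitivity + vr$cutpoints$specificity - 1)
})
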