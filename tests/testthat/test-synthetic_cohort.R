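test_that("generator config enforces its invariants", {
  expect_error(generator_config(prevalence = 0), "\\(0, 1\\)")
  expect_error(generator_config(mild_offset = -3, moderate_offset = -2),
               "mild_offset > moderate_offset")
  expect_error(generator_config(mild_offset = 1, moderate_offset = -2),
               "negative")
  expect_error(generator_config("case_control",
                                group_sizes = c(mild = 10)), "group_sizes")
  expect_error(generate_population(generator_config(seed = 1, n = 1)),
               "n >= 2")
})

test_that("calibration hits targets, is monotone, and refuses bad targets", {
  std <- data.frame(weight = 1, mean = 0, sd = 1)
  # symmetric trait and 50% target puts the location at the trait mean
  expect_equal(unname(calibrate_item_locations(c(x = 0.5), 2, std)), 0,
               tolerance = 1e-7)
  b <- calibrate_item_locations(c(a = 0.2, b = 0.4, c = 0.6), 1.5, std)
  expect_true(all(diff(b) > 0))  # harder target, higher location
  expect_error(calibrate_item_locations(c(x = 1.2), 2, std), "\\(0, 1\\)")
})

test_that("simulated marginal difficulties match their calibration targets", {
  cfg <- generator_config(n = 15000, seed = 101)
  sim <- generate_population(cfg)
  km <- key_responses(sim$cohort)
  d <- item_difficulty(km)
  targets <- c(cfg$cognitive_targets, cfg$informant_targets)
  for (id in names(targets)) {
    se <- sqrt(targets[[id]] * (1 - targets[[id]]) / cfg$n)
    expect_lt(abs(d[[id]] - targets[[id]]), 3 * se + 1e-12)
  }
})

test_that("identical config and seed give byte-identical cohorts", {
  cfg <- generator_config(n = 400, seed = 77)
  s1 <- generate_population(cfg)
  s2 <- generate_population(cfg)
  expect_identical(s1$cohort$responses, s2$cohort$responses)
  expect_identical(s1$truth$trait, s2$truth$trait)
  s3 <- generate_population(generator_config(n = 400, seed = 78))
  expect_false(identical(s1$cohort$responses, s3$cohort$responses))
})

test_that("near-deterministic response functions give a perfect scale", {
  set.seed(3)
  theta <- rnorm(400)
  irfs <- lapply(c(-1, 0, 1),
                 function(b) function(t) as.numeric(t > b))
  names(irfs) <- paste0("s", 1:3)
  m <- simulate_irf_matrix(theta, irfs, seed = 3)
  st <- scale_scalability(m)
  expect_equal(st$total$H, 1)
})

test_that("whole-scale H increases with the common discrimination", {
  hs <- vapply(c(0.5, 1, 2, 4), function(a) {
    mean(vapply(1:20, function(s) {
      set.seed(1000 + 97 * s + round(100 * a))
      theta <- rnorm(5000)
      irfs <- lapply(seq(-1.5, 1.5, length.out = 7),
                     function(b) function(t) plogis(a * (t - b)))
      names(irfs) <- paste0("v", 1:7)
      scale_scalability(simulate_irf_matrix(theta, irfs))$total$H
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(hs) > 0))
})

test_that("MHM-generated data pass the monotonicity check across seeds", {
  ok <- vapply(1:20, function(s) {
    sim <- generate_population(generator_config(n = 5000, seed = 3000 + s))
    km <- key_responses(sim$cohort,
                        items = subset(brief_item_bank(),
                                       scale == "cognitive")$item_id)
    all(check_monotonicity(km)$vi == 0)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("case-control groups order as severity and education dictate", {
  cfg <- generator_config("case_control", seed = 1)
  worse_mod <- logical(25); worse_lowed <- logical(25)
  for (s in 1:25) {
    cfg$seed <- s
    sim <- generate_case_control(cfg)
    sc <- score_cohort(sim$cohort)
    sv <- sim$cohort$subjects$severity
    ed <- sim$cohort$subjects$education
    ctrl <- sim$cohort$subjects$diagnosis == 0L
    worse_mod[s] <- mean(sc$cognitive_total[!is.na(sv) & sv == "moderate"]) <
      mean(sc$cognitive_total[!is.na(sv) & sv == "mild"])
    worse_lowed[s] <- mean(sc$cognitive_total[ctrl & ed == "low"]) <
      mean(sc$cognitive_total[ctrl & ed == "high"])
  }
  expect_gte(mean(worse_mod), 0.9)
  expect_gte(mean(worse_lowed), 0.9)
})

test_that("null configuration is exchangeable with AUROC near 0.5", {
  cfg <- generator_config("case_control",
                          mild_offset = -1e-9, moderate_offset = -2e-9,
                          education_dif = 0, seed = 55)
  sim <- generate_case_control(cfg)
  sc <- score_cohort(sim$cohort)
  au <- auroc(sc$combined, sim$cohort$subjects$diagnosis,
              "lower_is_positive")
  # 200 cases vs 200 controls: MC error ~ sqrt(1/12)*sqrt(1/200+1/200) ~ 0.029
  expect_lt(abs(au$auc - 0.5), 3 * 0.029)
})

test_that("truth labels never leak into the exported analysis table", {
  sim <- generate_population(generator_config(n = 50, seed = 5))
  path <- write_tmp_cohort(sim$cohort)
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  expect_false(any(c("trait", "group") %in% header))
  expect_true(all(brief_item_bank()$item_id %in% header))
})
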