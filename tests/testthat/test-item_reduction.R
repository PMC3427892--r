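# build a scalability object by hand to exercise the selection rules
fake_stats <- function(item_id, H_i, difficulty) {
  k <- length(item_id)
  pairs <- data.frame(item_i = character(0), item_j = character(0),
                      n_ij = integer(0), F_ij = numeric(0),
                      E_ij = numeric(0), H_ij = numeric(0),
                      z_ij = numeric(0), p_ij = numeric(0),
                      degenerate = logical(0))
  structure(list(
    items = data.frame(item_id = item_id, n = 1000L,
                       difficulty = difficulty,
                       F_i = 0, E_i = 1, H_i = H_i, z_i = 1, p_i = 0.1,
                       band = "strong", stringsAsFactors = FALSE),
    pairs = pairs,
    total = list(n = 1000L, F = 0, E = 1, H = mean(H_i), z = 1, p = 0.1,
                 band = "strong")),
    class = "scale_scalability")
}

fake_bank <- function(item_id, domain_tag) {
  item_bank(item_id, scale = "informant", n_levels = 2L,
            keyed_level_meaning = "symptom_present", domain_tag = domain_tag)
}

test_that("selection is top-k by H_i when constraints are inactive", {
  st <- fake_stats(c("a", "b", "c", "d"),
                   H_i = c(0.8, 0.7, 0.6, 0.5),
                   difficulty = c(0.1, 0.3, 0.5, 0.7))
  sel <- select_items(st, fake_bank(c("a", "b", "c", "d"),
                                    c("d1", "d2", "d3", "d4")), k = 3)
  expect_setequal(sel$selected, c("a", "b", "c"))
  # reported in ascending difficulty order
  expect_equal(sel$selected, c("a", "b", "c"))
})

test_that("a tied item covering a missing domain is preferred", {
  # b and c tie on H_i; b repeats a's domain while c covers a new one
  st <- fake_stats(c("a", "b", "c", "d"),
                   H_i = c(0.8, 0.6, 0.6, 0.55),
                   difficulty = c(0.1, 0.3, 0.5, 0.7))
  sel <- select_items(st, fake_bank(c("a", "b", "c", "d"),
                                    c("mem", "mem", "adl", "mem")), k = 2)
  expect_setequal(sel$selected, c("a", "c"))
  log <- sel$log
  expect_equal(log$action[log$item_id == "b"], "skip")
  expect_match(log$reason[log$item_id == "b"], "domain")
})

test_that("near-duplicate difficulties are skipped for a spaced alternative", {
  st <- fake_stats(c("a", "b", "c"),
                   H_i = c(0.8, 0.7, 0.65),
                   difficulty = c(0.100, 0.105, 0.500))
  sel <- select_items(st, fake_bank(c("a", "b", "c"), c("d1", "d2", "d3")),
                      k = 2, epsilon = 0.02)
  expect_setequal(sel$selected, c("a", "c"))
  expect_equal(sel$log$action[sel$log$item_id == "b"], "skip")
})

test_that("selection backfills to k and warns below the strong floor", {
  st <- fake_stats(c("a", "b", "c"),
                   H_i = c(0.45, 0.4, 0.35),
                   difficulty = c(0.1, 0.3, 0.5))
  expect_warning(
    sel <- select_items(st, fake_bank(c("a", "b", "c"), c("d1", "d2", "d3")),
                        k = 3),
    "best-effort")
  expect_equal(length(sel$selected), 3L)
})

test_that("selection is deterministic and recovers a planted strong subset", {
  pool <- generate_planted_pool(n = 5000, seed = 2)
  st <- scale_scalability(pool$matrix)
  sel1 <- suppressWarnings(select_items(st, pool$item_bank, k = 6))
  sel2 <- suppressWarnings(select_items(st, pool$item_bank, k = 6))
  expect_identical(sel1$selected, sel2$selected)
  expect_setequal(sel1$selected, pool$planted)
  # the planted subset is strictly more scalable than the full pool
  expect_gt(sel1$subset_H, st$total$H)
})

test_that("optimal dichotomization picks the discriminating cut", {
  # 3-level item whose level-1 responses are noise: only "often" tracks theta
  n <- 3000
  set.seed(42)
  theta <- rnorm(n)
  p2 <- plogis(2 * theta)          # P(response >= 2)
  p1 <- 0.7 + 0.3 * p2             # P(response >= 1): mostly noise
  u <- runif(n)
  tri <- as.integer(u <= p1) + as.integer(u <= p2)
  anchors <- simulate_irf_matrix(
    theta, lapply(c(-0.5, 0, 0.5),
                  function(b) function(t) plogis(2 * (t - b))), seed = 43)
  colnames(anchors) <- c("a1", "a2", "a3")
  bank <- item_bank(c("tri", "a1", "a2", "a3"), scale = "informant",
                    n_levels = c(3L, 2L, 2L, 2L),
                    keyed_level_meaning = "symptom_present")
  co <- cohort_table(cbind(tri = tri, anchors), bank)
  plan <- optimal_dichotomy(co)
  expect_equal(unname(plan$cuts["tri"]), 2L)
  # dichotomous items are not in the plan
  expect_setequal(names(plan$cuts), "tri")
})

test_that("exact ties between cuts break toward the lower cut", {
  # no subject endorses level 1, so cuts 1 and 2 key identically
  set.seed(7)
  tri <- sample(c(0L, 2L), 200, replace = TRUE)
  bin <- as.integer(tri == 2L)
  bin[sample(200, 40)] <- 1L - bin[sample(200, 40)]
  bank <- item_bank(c("tri", "b1", "b2"), scale = "informant",
                    n_levels = c(3L, 2L, 2L),
                    keyed_level_meaning = "symptom_present")
  co <- cohort_table(cbind(tri = tri, b1 = bin,
                           b2 = as.integer(tri == 2L)), bank)
  plan <- optimal_dichotomy(co)
  expect_equal(unname(plan$cuts["tri"]), 1L)
})

test_that("an item constant at every cut is flagged unusable", {
  bank <- item_bank(c("tri", "b1", "b2"), scale = "informant",
                    n_levels = c(3L, 2L, 2L),
                    keyed_level_meaning = "symptom_present")
  co <- cohort_table(cbind(tri = rep(0L, 50),
                           b1 = rep(c(0L, 1L), 25),
                           b2 = rep(c(1L, 0L), 25)), bank)
  expect_warning(plan <- optimal_dichotomy(co), "unusable")
  expect_equal(plan$unusable, "tri")
  expect_false("tri" %in% names(plan$cuts))
})
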