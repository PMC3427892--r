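test_that("item difficulty is the non-keyed proportion", {
  m <- cbind(all1 = c(1, 1, 1, 1), half = c(1, 1, 0, 0))
  expect_equal(unname(item_difficulty(m, "all1")), 0)
  expect_equal(unname(item_difficulty(m, "half")), 0.5)
  m_na <- cbind(x = c(NA, NA))
  expect_error(item_difficulty(m_na), "no non-missing")
})

test_that("pairwise Guttman counts match the hand-enumerated example", {
  # harder item i [1,1,0,0], easier j [1,0,1,1]: the lone error is subject 2
  m <- cbind(i = c(1, 1, 0, 0), j = c(1, 0, 1, 1))
  pg <- pairwise_guttman(m, "i", "j")
  expect_equal(pg$F_ij, 1)
  expect_equal(pg$E_ij, 4 * 0.5 * 0.25)
  expect_equal(pg$H_ij, -1)
  # symmetric in the pair
  pg_rev <- pairwise_guttman(m, "j", "i")
  expect_equal(pg_rev$F_ij, pg$F_ij)
  expect_equal(pg_rev$H_ij, pg$H_ij)
})

test_that("perfect Guttman data have zero errors and H = 1 exactly", {
  m <- perfect_guttman(24, 4)
  pg <- pairwise_guttman(m, "g1", "g4")
  expect_equal(pg$F_ij, 0)
  expect_equal(pg$H_ij, 1)
  st <- scale_scalability(m)
  expect_identical(st$total$F, 0L)
  expect_equal(st$total$H, 1)
  expect_true(all(st$items$H_i == 1))
})

test_that("Loevinger coefficient reproduces published counts and guards E", {
  expect_equal(round(loevinger_from_counts(486, 2289.2), 2), 0.79)
  expect_equal(round(loevinger_from_counts(5567, 15262.7), 2), 0.64)
  expect_equal(loevinger_from_counts(0, 100), 1)
  expect_error(loevinger_from_counts(5, 0), "undefined")
  expect_error(loevinger_from_counts(-1, 10), ">= 0")
})

test_that("z statistic sign contract and degenerate guards hold", {
  expect_equal(z_statistic(10, 10, 4), 0)
  expect_gt(z_statistic(5, 10, 4), 0)
  expect_lt(z_statistic(15, 10, 4), 0)
  expect_error(z_statistic(5, 0, 4), "undefined")
  expect_error(z_statistic(5, 10, 0), "undefined")
})

test_that("pairwise F matches a brute-force subject enumeration oracle", {
  set.seed(4711)
  for (rep in seq_len(250)) {
    n <- sample(4:12, 1)
    J <- sample(3:6, 1)
    X <- matrix(rbinom(n * J, 1, runif(1, 0.2, 0.8)), n, J,
                dimnames = list(NULL, paste0("v", seq_len(J))))
    st <- tryCatch(suppressWarnings(scale_scalability(X)),
                   error = function(e) NULL)
    if (is.null(st)) next   # all-degenerate draw
    for (r in seq_len(nrow(st$pairs))) {
      i <- match(st$pairs$item_i[r], colnames(X))
      j <- match(st$pairs$item_j[r], colnames(X))
      expect_identical(st$pairs$F_ij[r], brute_force_F(X, i, j))
    }
  }
})

test_that("aggregation identities hold on arbitrary inputs", {
  set.seed(99)
  for (rep in seq_len(25)) {
    X <- matrix(rbinom(40 * 5, 1, 0.5), 40, 5)
    st <- suppressWarnings(scale_scalability(X))
    expect_equal(st$total$F, sum(st$items$F_i) / 2)
    expect_equal(st$total$E, sum(st$items$E_i) / 2)
    expect_equal(st$total$H, 1 - st$total$F / st$total$E)
    expect_true(all(st$pairs$H_ij <= 1, na.rm = TRUE))
  }
})

test_that("H statistics are invariant under row and column permutation", {
  set.seed(12)
  X <- matrix(rbinom(200 * 5, 1, runif(5, 0.2, 0.8)), 200, 5, byrow = TRUE,
              dimnames = list(NULL, paste0("v", 1:5)))
  st <- scale_scalability(X)
  Xp <- X[sample(nrow(X)), sample(ncol(X))]
  stp <- scale_scalability(Xp)
  expect_equal(stp$total$H, st$total$H)
  expect_equal(stp$total$z, st$total$z)
  o <- match(st$items$item_id, stp$items$item_id)
  expect_equal(stp$items$H_i[o], st$items$H_i)
})

test_that("independent items at n = 10000 give |z| < 3 for H near 0", {
  set.seed(2024)
  n <- 10000
  X <- cbind(a = rbinom(n, 1, 0.5), b = rbinom(n, 1, 0.3),
             c = rbinom(n, 1, 0.7), d = rbinom(n, 1, 0.5))
  st <- scale_scalability(X)
  # |H| < 3 SE(H) is equivalent to |z| < 3 under the null variance
  expect_lt(abs(st$total$z), 3)
  expect_lt(abs(st$total$H), 0.05)
})

test_that("pairwise z test has calibrated type-I error under independence", {
  set.seed(123)
  rej <- vapply(seq_len(1000), function(r) {
    m <- cbind(a = rbinom(200, 1, 0.5), b = rbinom(200, 1, 0.3))
    pairwise_guttman(m, "a", "b")$p_ij < 0.05
  }, logical(1))
  # binomial 99% bounds around 0.05 at 1000 replicates
  half <- 2.576 * sqrt(0.05 * 0.95 / 1000)
  expect_gt(mean(rej), 0.05 - half)
  expect_lt(mean(rej), 0.05 + half)
})

test_that("degenerate (constant) items are flagged and excluded", {
  m <- cbind(ok1 = c(1, 0, 1, 0), ok2 = c(1, 1, 0, 0), const = c(1, 1, 1, 1))
  expect_warning(st <- scale_scalability(m), "degenerate")
  degen <- st$pairs[st$pairs$degenerate, ]
  expect_true(all(degen$E_ij == 0))
  expect_true(all(is.na(degen$H_ij)))
  # aggregates only cover the non-degenerate pair
  expect_equal(st$total$E,
               st$pairs$E_ij[!st$pairs$degenerate])
  expect_error(suppressWarnings(
    scale_scalability(cbind(a = rep(1, 4), b = rep(0, 4)))),
    "degenerate")
})

test_that("scalability bands follow the 0.3/0.4/0.5 convention", {
  st <- scale_scalability(perfect_guttman(24, 3))
  expect_true(all(st$items$band == "strong"))
  tab <- scalability_table(st, scale = "cognitive")
  expect_equal(tab$item_id[nrow(tab)], "whole_scale")
  expect_equal(tab$H[nrow(tab)], 1)
})

test_that("synthetic difficulties preserve the calibrated item ordering", {
  sim <- generate_population(generator_config(n = 15000, seed = 31))
  km <- key_responses(sim$cohort,
                      items = subset(brief_item_bank(),
                                     scale == "cognitive")$item_id)
  d <- item_difficulty(km)
  # hammer easiest ... delayed recall hardest, as calibrated
  expect_equal(names(sort(d)),
               c("hammer", "elbow", "point2", "store", "season",
                 "dayweek", "recall3"))
})
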