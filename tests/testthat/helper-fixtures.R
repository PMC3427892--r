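# shared fixtures and independent oracles

# perfect Guttman matrix: subject i keyed on the i easiest items
perfect_guttman <- function(n_subjects, n_items) {
  m <- matrix(0L, n_subjects, n_items,
              dimnames = list(NULL, paste0("g", seq_len(n_items))))
  for (i in seq_len(n_subjects)) {
    k <- min(n_items, (i - 1L) %% (n_items + 1L))
    if (k > 0L) m[i, seq_len(k)] <- 1L
  }
  m
}

# brute-force Guttman error count for a pair: enumerate subjects, with the
# harder item (higher difficulty, ties to the higher column index) keyed
# while the easier is not
brute_force_F <- function(X, i, j) {
  d <- 1 - colMeans(X)
  harder <- if (d[i] > d[j] || (d[i] == d[j] && i > j)) i else j
  easier <- if (harder == i) j else i
  sum(vapply(seq_len(nrow(X)),
             function(s) X[s, harder] == 1L && X[s, easier] == 0L,
             logical(1)))
}

# trapezoid-rule area under an empirical ROC curve
trapezoid_auc <- function(roc) {
  o <- order(roc$fpr, roc$sensitivity)
  x <- roc$fpr[o]; y <- roc$sensitivity[o]
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

# small cohort carrying the full brief item bank
tiny_brief_cohort <- function(n = 40, seed = 1) {
  set.seed(seed)
  bank <- brief_item_bank()
  resp <- sapply(bank$n_levels, function(m) {
    sample(0:(m - 1L), n, replace = TRUE)
  })
  colnames(resp) <- bank$item_id
  cohort_table(resp, bank)
}

write_tmp_cohort <- function(cohort, ...) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  write_cohort(cohort, path, ...)
  path
}
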