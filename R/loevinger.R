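#' Loevinger scalability coefficient from Guttman error counts
#'
#' The Loevinger coefficient is `H = 1 - F/E`, where `F` is the observed
#' number of Guttman errors (keyed response on the harder item without the
#' keyed response on the easier one) and `E` its expectation under marginal
#' independence of the items.
#'
#' @param f observed Guttman error count (>= 0).
#' @param e expected Guttman error count under independence (> 0).
#' @return `1 - f/e`, at most 1.
#' @examples
#' loevinger_from_counts(486, 2289.2)   # 0.79 for a strongly scalable item
#' loevinger_from_counts(0, 100)        # 1: a perfect hierarchical scale
#' @export
loevinger_from_counts <- function(f, e) {
  f <- as.numeric(f); e <- as.numeric(e)
  if (any(f < 0)) stop("observed Guttman error count must be >= 0")
  if (any(e <= 0)) {
    stop("Loevinger coefficient undefined: expected Guttman error count <= 0")
  }
  1 - f / e
}

#' Normal-approximation z statistic for H > 0
#'
#' Tests the null of marginal independence (`H = 0`) using the deficit of
#' observed relative to expected Guttman errors, `z = (E - F) / sqrt(V)`,
#' where `V` is the null variance of the error count with item margins held
#' fixed (hypergeometric allocation; the Mokken/MSP convention). Positive
#' when fewer errors are observed than chance predicts.
#'
#' @param f observed Guttman error count.
#' @param e expected Guttman error count (> 0).
#' @param variance null variance of the observed count (> 0). For a single
#'   item pair on `n` complete cases with keyed proportions `p_i`, `p_j` this
#'   is `n^2 p_i (1-p_i) p_j (1-p_j) / (n-1)`; for item and scale aggregates,
#'   the sum of the pairwise variances.
#' @return The z statistic; `0` when `f == e`.
#' @export
z_statistic <- function(f, e, variance) {
  if (any(e <= 0)) stop("z statistic undefined: expected count <= 0")
  if (any(variance <= 0)) stop("z statistic undefined: variance <= 0")
  (e - f) / sqrt(variance)
}

#' Item difficulty
#'
#' The proportion of complete cases *not* giving the keyed response, so easy
#' or commonly endorsed items have difficulties near 0 and rare/hard ones
#' near 1. This is the convention under which items are listed in ascending
#' difficulty order.
#'
#' @param matrix a [key_responses()] matrix, or any 0/1/`NA` matrix.
#' @param item optional item id or index; default: all items.
#' @return Named numeric difficulties in `[0, 1]`.
#' @export
item_difficulty <- function(matrix, item = NULL) {
  m <- strip_keyed(matrix)
  if (!is.null(item)) m <- m[, item, drop = FALSE]
  nn <- colSums(!is.na(m))
  if (any(nn == 0L)) {
    stop("item(s) with no non-missing responses: ",
         paste(colnames(m)[nn == 0L], collapse = ", "))
  }
  1 - colMeans(m, na.rm = TRUE)
}

# Given 0/1 matrix X (no NA), difficulty ordering with ties broken by
# ascending column index: returns TRUE if column i is "easier or tied" vs j.
.easier <- function(d, i, j) (d[i] < d[j]) || (d[i] == d[j] && i < j)

#' Pairwise Guttman error statistics
#'
#' For a pair of keyed dichotomous items, a Guttman error is a subject keyed
#' on the harder item (higher difficulty) but not on the easier one.
#' `F_ij` counts them on the pairwise complete cases; `E_ij = n P(harder
#' keyed) P(easier not keyed)` is the count expected under independence.
#' Difficulty ties are broken by ascending item index (lower index treated
#' as easier).
#'
#' @param matrix a keyed 0/1/`NA` matrix.
#' @param i,j item ids or column indices.
#' @return A one-row data frame: `item_i`, `item_j`, `n_ij`, `F_ij`, `E_ij`,
#'   `H_ij`, `z_ij`, `p_ij` (one-sided), `degenerate`. A pair with a constant
#'   item has `E_ij = 0` and is flagged degenerate (`H_ij`, `z_ij` are `NA`).
#' @examples
#' m <- cbind(hard = c(1, 1, 0, 0), easy = c(1, 0, 1, 1))
#' pairwise_guttman(m, "hard", "easy")  # F = 1, E = 0.5, H = -1
#' @export
pairwise_guttman <- function(matrix, i, j) {
  m <- if (inherits(matrix, "keyed_matrix")) unclass(matrix) else as.matrix(matrix)
  sub <- m[, c(i, j), drop = FALSE]
  sub <- sub[stats::complete.cases(sub), , drop = FALSE]
  n <- nrow(sub)
  if (n < 1L) stop("no complete cases for pair (", i, ", ", j, ")")
  p <- colMeans(sub)
  d <- 1 - p
  e_first <- .easier(d, 1L, 2L)
  h <- if (e_first) 2L else 1L   # harder column within sub
  e <- if (e_first) 1L else 2L
  Fij <- sum(sub[, h] == 1L & sub[, e] == 0L)
  Eij <- n * p[h] * (1 - p[e])
  degenerate <- any(p %in% c(0, 1))
  if (degenerate) {
    warning("degenerate pair (constant item): (",
            colnames(sub)[1], ", ", colnames(sub)[2], ")")
  }
  Vij <- n^2 * p[1] * (1 - p[1]) * p[2] * (1 - p[2]) / max(n - 1, 1)
  Hij <- if (!degenerate) 1 - Fij / Eij else NA_real_
  zij <- if (!degenerate) (Eij - Fij) / sqrt(Vij) else NA_real_
  data.frame(
    item_i = colnames(sub)[1], item_j = colnames(sub)[2], n_ij = n,
    F_ij = Fij, E_ij = if (degenerate) 0 else Eij, H_ij = Hij, z_ij = zij,
    p_ij = if (!degenerate) stats::pnorm(zij, lower.tail = FALSE) else NA_real_,
    degenerate = degenerate, stringsAsFactors = FALSE
  )
}

scalability_band <- function(h) {
  cut(h, breaks = c(-Inf, 0.3, 0.4, 0.5, Inf), right = FALSE,
      labels = c("unscalable", "weak", "moderate", "strong"))
}

#' Mokken scalability analysis of a keyed item set
#'
#' Computes, on the scale-wise complete cases, the full set of Mokken
#' scalability statistics: item difficulties, observed (`F`) and expected
#' (`E`) Guttman error counts for every item pair, per item and for the
#' whole scale, Loevinger coefficients `H = 1 - F/E` at all three levels,
#' and normal-approximation z statistics for `H > 0` (see [z_statistic()]).
#' Item and scale aggregates satisfy `F_total = sum(F_i) / 2` (each pair
#' counted once) and likewise for `E`.
#'
#' Items keyed constantly (difficulty 0 or 1) make every pair containing
#' them degenerate; such pairs are excluded from aggregation with a warning.
#'
#' @param matrix a [key_responses()] matrix or plain 0/1/`NA` matrix; rows
#'   with any missing value are dropped (complete-case policy).
#' @return A list of class `"scale_scalability"`: `items` (data frame with
#'   `item_id`, `n`, `difficulty`, `F_i`, `E_i`, `H_i`, `z_i`, `p_i`,
#'   `band`), `pairs` (as [pairwise_guttman()] rows), and `total` (list with
#'   `n`, `F`, `E`, `H`, `z`, `p`, `band`).
#' @examples
#' km <- cbind(a = c(1, 1, 1, 0), b = c(1, 1, 0, 0), c = c(1, 0, 0, 0))
#' scale_scalability(km)$total$H  # 1: perfect Guttman scale
#' @export
scale_scalability <- function(matrix) {
  X <- as_binary_matrix(matrix)
  n <- nrow(X); J <- ncol(X)
  if (J < 2L) stop("scalability analysis needs >= 2 items")
  if (n < 2L) stop("scalability analysis needs >= 2 complete cases")
  p <- colMeans(X)
  d <- 1 - p
  ids <- colnames(X)
  N11 <- crossprod(X)
  n1 <- diag(N11)
  pr <- t(utils::combn(J, 2L))
  a <- pr[, 1L]; b <- pr[, 2L]
  # harder member of each pair (ties: lower index is easier)
  h <- ifelse(d[a] > d[b] | (d[a] == d[b] & a > b), a, b)
  e <- ifelse(h == a, b, a)
  Fp <- as.integer(round(n1[h] - N11[cbind(h, e)]))
  Ep <- n1[h] * (n - n1[e]) / n
  Vp <- n^2 * p[a] * (1 - p[a]) * p[b] * (1 - p[b]) / (n - 1)
  degen <- p[a] %in% c(0, 1) | p[b] %in% c(0, 1)
  if (all(degen)) stop("all item pairs degenerate (constant items)")
  if (any(degen)) {
    warning(sum(degen), " degenerate pair(s) excluded from aggregation")
  }
  Hp <- ifelse(degen, NA_real_, 1 - Fp / Ep)
  zp <- ifelse(degen, NA_real_, (Ep - Fp) / sqrt(Vp))
  pairs <- data.frame(
    item_i = ids[a], item_j = ids[b], n_ij = n,
    F_ij = Fp, E_ij = ifelse(degen, 0, Ep), H_ij = Hp, z_ij = zp,
    p_ij = stats::pnorm(zp, lower.tail = FALSE),
    degenerate = degen, stringsAsFactors = FALSE
  )
  ok <- !degen
  agg <- function(v) {
    out <- numeric(J)
    for (k in seq_len(J)) out[k] <- sum(v[ok & (a == k | b == k)])
    out
  }
  Fi <- agg(Fp); Ei <- agg(Ep); Vi <- agg(Vp)
  Hi <- ifelse(Ei > 0, 1 - Fi / Ei, NA_real_)
  zi <- ifelse(Vi > 0, (Ei - Fi) / sqrt(Vi), NA_real_)
  items <- data.frame(
    item_id = ids, n = n, difficulty = d,
    F_i = Fi, E_i = Ei, H_i = Hi, z_i = zi,
    p_i = stats::pnorm(zi, lower.tail = FALSE),
    band = scalability_band(Hi),
    stringsAsFactors = FALSE, row.names = NULL
  )
  Ft <- sum(Fp[ok]); Et <- sum(Ep[ok]); Vt <- sum(Vp[ok])
  Ht <- 1 - Ft / Et
  zt <- (Et - Ft) / sqrt(Vt)
  structure(list(
    items = items, pairs = pairs,
    total = list(n = n, F = Ft, E = Et, H = Ht, z = zt,
                 p = stats::pnorm(zt, lower.tail = FALSE),
                 band = as.character(scalability_band(Ht)))
  ), class = "scale_scalability")
}

#' @export
print.scale_scalability <- function(x, digits = 3, ...) {
  cat("Mokken scalability analysis: ", nrow(x$items), " items, n = ",
      x$total$n, " complete cases\n", sep = "")
  df <- x$items
  df$difficulty <- round(df$difficulty, digits)
  df$E_i <- round(df$E_i, 1); df$H_i <- round(df$H_i, digits)
  df$z_i <- round(df$z_i, 1)
  print.data.frame(df[, c("item_id", "difficulty", "F_i", "E_i",
                          "H_i", "z_i", "band")], row.names = FALSE)
  cat(sprintf("Whole scale: F = %.0f, E = %.1f, H = %.*f (%s), z = %.1f\n",
              x$total$F, x$total$E, digits, x$total$H, x$total$band,
              x$total$z))
  invisible(x)
}

#' Export scalability statistics as a table
#'
#' Flattens a [scale_scalability()] result into one data frame with the item
#' rows followed by a whole-scale row, mirroring the columns conventionally
#' reported for Mokken analyses (n, difficulty, observed and expected
#' Guttman errors, H, z, p).
#'
#' @param stats a `"scale_scalability"` object.
#' @param scale optional scale label column.
#' @return A data frame.
#' @export
scalability_table <- function(stats, scale = NA_character_) {
  stopifnot(inherits(stats, "scale_scalability"))
  it <- stats$items
  out <- data.frame(
    scale = scale, item_id = c(it$item_id, "whole_scale"),
    n = c(it$n, stats$total$n),
    difficulty = c(it$difficulty, NA_real_),
    observed_errors = c(it$F_i, stats$total$F),
    expected_errors = c(it$E_i, stats$total$E),
    H = c(it$H_i, stats$total$H),
    z = c(it$z_i, stats$total$z),
    p = c(it$p_i, stats$total$p),
    band = c(as.character(it$band), stats$total$band),
    stringsAsFactors = FALSE
  )
  out
}
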