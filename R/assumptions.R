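#' Crit diagnostic for an assumption check
#'
#' A composite statistic summarizing the evidence that an item violates a
#' scaling assumption, combining its scalability with the number, size and
#' frequency of observed violations:
#' `Crit = 50 (0.30 - H_i)_+ + sqrt(vi) + 100 vi/ac + 100 maxvi +
#'  10 sqrt(sumvi) + 1000 sumvi/ac` (first term truncated at zero).
#' Conventional bands: `<= 40` satisfactory, `40-79` questionable,
#' `>= 80` strongly suggesting an assumption violation.
#'
#' @param h_i the item's Loevinger coefficient.
#' @param ac number of active comparisons made for the item.
#' @param vi number of violations (comparisons off by at least `minvi`).
#' @param maxvi largest violation.
#' @param sumvi sum of all violations.
#' @return The Crit value (0 when no comparisons were possible).
#' @export
crit_value <- function(h_i, ac, vi, maxvi, sumvi) {
  if (ac <= 0) return(0)
  50 * pmax(0, 0.30 - h_i) + sqrt(vi) + 100 * vi / ac +
    100 * maxvi + 10 * sqrt(sumvi) + 1000 * sumvi / ac
}

crit_band <- function(crit) {
  ifelse(crit <= 40, "satisfactory",
         ifelse(crit < 80, "questionable", "violation"))
}

new_assumption_report <- function(items, check, settings) {
  structure(items, check = check, settings = settings,
            class = c("assumption_report", "data.frame"))
}

# Merge adjacent rest scores (ascending) into groups of >= minsize subjects;
# a trailing undersized group is merged backwards.
restscore_groups <- function(rest, minsize) {
  tab <- table(rest)
  vals <- as.numeric(names(tab))
  counts <- as.integer(tab)
  bounds <- integer(0)  # index of last rest-score value in each group
  acc <- 0L
  for (k in seq_along(vals)) {
    acc <- acc + counts[k]
    if (acc >= minsize) { bounds <- c(bounds, k); acc <- 0L }
  }
  if (acc > 0L) {
    if (length(bounds)) bounds[length(bounds)] <- length(vals)
    else bounds <- length(vals)
  }
  grp <- rep(NA_integer_, length(rest))
  lo <- 1L
  for (g in seq_along(bounds)) {
    members <- vals[lo:bounds[g]]
    grp[rest %in% members] <- g
    lo <- bounds[g] + 1L
  }
  grp
}

#' Check the monotonicity assumption (restscore method)
#'
#' Under the monotone homogeneity model the probability of the keyed
#' response is non-decreasing in the latent trait, hence (approximately) in
#' the rest score -- the subject's total over the other items of the scale.
#' For each item, subjects are binned into rest-score groups of at least
#' `min_group_size` members; a decrease of at least `minvi` in the keyed
#' proportion between a lower and a higher group counts as a violation, and
#' each violation is tested one-sided at level `alpha` (two-proportion
#' z test). Violation evidence is summarized per item by [crit_value()].
#'
#' @param matrix a keyed 0/1/`NA` matrix (>= 3 items); complete cases used.
#' @param minvi minimum decrease counted as a violation (default 0.03).
#' @param alpha significance level for individual violations (default 0.05).
#' @param min_group_size minimum subjects per rest-score group; default
#'   `max(50, n %/% 10)`.
#' @return An `"assumption_report"` data frame, one row per item: `item_id`,
#'   `assessable`, `n_groups`, `ac` (active comparisons), `vi`, `maxvi`,
#'   `sumvi`, `zsig` (significant violations), `crit`, `band`. The
#'   rest-score group keyed proportions are kept in `attr(, "groups")`.
#' @export
check_monotonicity <- function(matrix, minvi = 0.03, alpha = 0.05,
                               min_group_size = NULL) {
  X <- as_binary_matrix(matrix)
  n <- nrow(X); J <- ncol(X)
  if (J < 3L) stop("monotonicity check needs >= 3 items")
  if (is.null(min_group_size)) min_group_size <- max(50, n %/% 10)
  zcrit <- stats::qnorm(1 - alpha)
  hi <- scale_scalability(X)$items$H_i
  rows <- vector("list", J)
  groups <- vector("list", J)
  for (k in seq_len(J)) {
    x <- X[, k]
    rest <- rowSums(X[, -k, drop = FALSE])
    res <- list(item_id = colnames(X)[k], assessable = TRUE, n_groups = 0L,
                ac = 0L, vi = 0L, maxvi = 0, sumvi = 0, zsig = 0L,
                crit = 0, band = "satisfactory")
    if (length(unique(x)) < 2L) {
      res$assessable <- FALSE; res$band <- "not_assessable"
      rows[[k]] <- res; next
    }
    grp <- restscore_groups(rest, min_group_size)
    G <- max(grp, na.rm = TRUE)
    if (is.na(G) || G < 2L) {
      res$assessable <- FALSE; res$band <- "not_assessable"
      rows[[k]] <- res; next
    }
    ng <- tabulate(grp, G)
    pg <- vapply(seq_len(G), function(g) mean(x[grp == g]), numeric(1))
    groups[[k]] <- data.frame(item_id = colnames(X)[k], group = seq_len(G),
                              n = ng, prop_keyed = pg,
                              stringsAsFactors = FALSE)
    cmb <- utils::combn(G, 2L)
    viol <- numeric(0); nsig <- 0L
    for (c2 in seq_len(ncol(cmb))) {
      g <- cmb[1L, c2]; h <- cmb[2L, c2]
      dec <- pg[g] - pg[h]          # a decrease violates monotonicity
      if (dec >= minvi) {
        viol <- c(viol, dec)
        pool <- (pg[g] * ng[g] + pg[h] * ng[h]) / (ng[g] + ng[h])
        se <- sqrt(pool * (1 - pool) * (1 / ng[g] + 1 / ng[h]))
        if (se > 0 && dec / se > zcrit) nsig <- nsig + 1L
      }
    }
    res$n_groups <- G
    res$ac <- ncol(cmb)
    res$vi <- length(viol)
    res$maxvi <- if (length(viol)) max(viol) else 0
    res$sumvi <- sum(viol)
    res$zsig <- nsig
    res$crit <- crit_value(hi[k], res$ac, res$vi, res$maxvi, res$sumvi)
    res$band <- crit_band(res$crit)
    rows[[k]] <- res
  }
  out <- do.call(rbind, lapply(rows, as.data.frame,
                               stringsAsFactors = FALSE))
  rep <- new_assumption_report(
    out, check = "monotonicity",
    settings = list(minvi = minvi, alpha = alpha,
                    min_group_size = min_group_size))
  attr(rep, "groups") <- do.call(rbind, groups)
  rep
}

#' Check the non-intersection assumption (P-matrix method)
#'
#' The double monotonicity model additionally requires that item response
#' functions do not intersect, so the difficulty ordering of items is the
#' same at every trait level. Observable consequence: with items ordered by
#' ascending difficulty, each row of the `P(++)` matrix (probability both
#' items of a pair are keyed) is non-increasing and each row of `P(--)`
#' (both not keyed) is non-decreasing. For every anchor item `i` and
#' difficulty-ordered pair `j < k` of other items, a reversal of at least
#' `minvi` counts as a violation (tested one-sided at `alpha` by a McNemar
#' z test on the discordant counts) and is attributed to all three items
#' involved. Evidence is summarized per item by [crit_value()].
#'
#' @inheritParams check_monotonicity
#' @return An `"assumption_report"` data frame as in [check_monotonicity()],
#'   with the `P(++)`/`P(--)` matrices in `attr(, "pmatrices")`.
#' @export
check_nonintersection <- function(matrix, minvi = 0.03, alpha = 0.05) {
  X <- as_binary_matrix(matrix)
  n <- nrow(X); J <- ncol(X)
  if (J < 3L) stop("non-intersection check needs >= 3 items")
  p <- colMeans(X)
  keep <- !(p %in% c(0, 1))
  if (sum(keep) < 3L) stop("fewer than 3 non-degenerate items")
  if (any(!keep)) {
    warning("degenerate item(s) excluded: ",
            paste(colnames(X)[!keep], collapse = ", "))
  }
  X <- X[, keep, drop = FALSE]
  J <- ncol(X); p <- colMeans(X)
  d <- 1 - p
  ord <- order(d, seq_len(J))  # ascending difficulty, ties by index
  X <- X[, ord, drop = FALSE]
  p <- p[ord]
  ids <- colnames(X)
  hi <- scale_scalability(X)$items$H_i
  zcrit <- stats::qnorm(1 - alpha)
  P11 <- crossprod(X) / n
  P00 <- crossprod(1 - X) / n
  ac <- vi <- zsig <- integer(J)
  maxvi <- sumvi <- numeric(J)
  for (i in seq_len(J)) {
    sel1 <- X[, i] == 1L
    others <- setdiff(seq_len(J), i)
    for (aa in seq_len(length(others) - 1L)) {
      for (bb in seq((aa + 1L), length(others))) {
        j <- others[aa]; k <- others[bb]    # j easier than k
        trio <- c(i, j, k)
        ac[trio] <- ac[trio] + 2L
        # P(++): expect P11[i,j] >= P11[i,k]
        dev11 <- P11[i, k] - P11[i, j]
        if (dev11 >= minvi) {
          vi[trio] <- vi[trio] + 1L
          maxvi[trio] <- pmax(maxvi[trio], dev11)
          sumvi[trio] <- sumvi[trio] + dev11
          b <- sum(sel1 & X[, j] == 0L & X[, k] == 1L)
          cc <- sum(sel1 & X[, j] == 1L & X[, k] == 0L)
          if (b + cc > 0 && (b - cc) / sqrt(b + cc) > zcrit) {
            zsig[trio] <- zsig[trio] + 1L
          }
        }
        # P(--): expect P00[i,j] <= P00[i,k]
        dev00 <- P00[i, j] - P00[i, k]
        if (dev00 >= minvi) {
          vi[trio] <- vi[trio] + 1L
          maxvi[trio] <- pmax(maxvi[trio], dev00)
          sumvi[trio] <- sumvi[trio] + dev00
          b <- sum(!sel1 & X[, j] == 0L & X[, k] == 1L)
          cc <- sum(!sel1 & X[, j] == 1L & X[, k] == 0L)
          if (b + cc > 0 && (b - cc) / sqrt(b + cc) > zcrit) {
            zsig[trio] <- zsig[trio] + 1L
          }
        }
      }
    }
  }
  crit <- mapply(crit_value, hi, ac, vi, maxvi, sumvi)
  out <- data.frame(
    item_id = ids, assessable = TRUE, n_groups = NA_integer_,
    ac = ac, vi = vi, maxvi = maxvi, sumvi = sumvi, zsig = zsig,
    crit = crit, band = crit_band(crit), stringsAsFactors = FALSE
  )
  rep <- new_assumption_report(
    out, check = "non_intersection",
    settings = list(minvi = minvi, alpha = alpha))
  attr(rep, "pmatrices") <- list(P11 = P11, P00 = P00)
  rep
}

#' @export
print.assumption_report <- function(x, ...) {
  cat("Assumption check:", attr(x, "check"), "\n")
  s <- attr(x, "settings")
  cat("  settings:", paste(names(s), unlist(s), sep = " = ",
                           collapse = ", "), "\n")
  print.data.frame(as.data.frame(x), row.names = FALSE, ...)
  invisible(x)
}
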