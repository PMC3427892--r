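#' Screening cutpoint with explicit direction
#'
#' Cutpoints are stored as half-open thresholds with a direction flag to
#' avoid off-by-one drift between the "`<6`" (positive iff score below 6,
#' i.e. 5 or less) and "`>1`" (positive iff score above 1, i.e. 2 or more)
#' reporting styles.
#'
#' @param threshold numeric threshold.
#' @param direction `"below"` (positive iff `score < threshold`) or
#'   `"above"` (positive iff `score > threshold`).
#' @return A list of class `"cutpoint"` with a `label` (`"<6"`, `">1"`, ...).
#' @examples
#' apply_cutpoint(4, cutpoint(5, "below"))  # TRUE: 4 screens positive at <5
#' @export
cutpoint <- function(threshold, direction = c("below", "above")) {
  direction <- match.arg(direction)
  structure(list(threshold = threshold, direction = direction,
                 label = paste0(if (direction == "below") "<" else ">",
                                format(threshold, trim = TRUE))),
            class = "cutpoint")
}

#' @rdname cutpoint
#' @param score numeric score(s).
#' @param cut a `cutpoint` object.
#' @return `apply_cutpoint`: logical, `TRUE` when the score screens positive.
#' @export
apply_cutpoint <- function(score, cut) {
  stopifnot(inherits(cut, "cutpoint"))
  if (cut$direction == "below") score < cut$threshold
  else score > cut$threshold
}

#' @export
print.cutpoint <- function(x, ...) {
  cat("cutpoint: positive iff score ", x$label, "\n", sep = "")
  invisible(x)
}

check_roc_input <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length")
  }
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- as.integer(labels[keep])
  if (any(!labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  if (!any(labels == 1L) || !any(labels == 0L)) {
    stop("labels must include at least one case and one control")
  }
  if (any(!is.finite(scores))) stop("scores must be finite")
  list(scores = scores, labels = labels)
}

# Impairment-oriented scores: larger = more impaired.
impairment_scores <- function(scores, direction) {
  if (direction == "lower_is_positive") -scores else scores
}

#' Empirical ROC curve
#'
#' One operating point per distinct score threshold, plus the (0,0) and
#' (1,1) endpoints. Thresholds are placed midway between adjacent distinct
#' score values (half-integers for integer scores), so "positive" is
#' unambiguous. `direction` states which end of the scale is impaired:
#' `"lower_is_positive"` for the cognitive scale (low score = impaired),
#' `"higher_is_positive"` for the informant scale.
#'
#' @param scores numeric scale scores.
#' @param labels binary gold standard (1 = case).
#' @param direction `"lower_is_positive"` or `"higher_is_positive"`.
#' @return A data frame of class `"roc_curve"`: `threshold` (on the original
#'   score scale; `NA` at the endpoints), `label` (e.g. `"<6"`),
#'   `sensitivity`, `specificity`, `fpr`; ordered from (0,0) to (1,1).
#' @examples
#' roc_curve(c(1, 3, 0, 2), c(1, 1, 0, 0), "higher_is_positive")
#' @export
roc_curve <- function(scores, labels,
                      direction = c("lower_is_positive",
                                    "higher_is_positive")) {
  direction <- match.arg(direction)
  inp <- check_roc_input(scores, labels)
  s <- impairment_scores(inp$scores, direction)
  y <- inp$labels
  v <- sort(unique(s))
  mids <- if (length(v) > 1L) (v[-1] + v[-length(v)]) / 2 else numeric(0)
  # positive iff impairment score > t; t descending from above max to below min
  ts <- c(v[length(v)] + 1, rev(mids), v[1] - 1)
  sens <- vapply(ts, function(t) mean(s[y == 1L] > t), numeric(1))
  fpr <- vapply(ts, function(t) mean(s[y == 0L] > t), numeric(1))
  orig <- if (direction == "lower_is_positive") -ts else ts
  lab <- vapply(seq_along(ts), function(k) {
    if (k == 1L || k == length(ts)) return(NA_character_)
    if (direction == "lower_is_positive") {
      paste0("<", format(ceiling(orig[k] - 1e-9), trim = TRUE))
    } else {
      paste0(">", format(floor(orig[k] + 1e-9), trim = TRUE))
    }
  }, character(1))
  out <- data.frame(threshold = orig, label = lab, sensitivity = sens,
                    specificity = 1 - fpr, fpr = fpr,
                    stringsAsFactors = FALSE)
  structure(out, direction = direction,
            n_cases = sum(y == 1L), n_controls = sum(y == 0L),
            class = c("roc_curve", "data.frame"))
}

#' Area under the ROC curve with confidence interval
#'
#' AUROC computed as the rank statistic: the probability that a random case
#' scores as more impaired than a random control, ties counted half. The
#' 95\% CI uses the DeLong placement-value variance by default
#' (Hanley-McNeil as an alternative), truncated to `[0, 1]`.
#'
#' @inheritParams roc_curve
#' @param ci_method `"delong"` (default) or `"hanley-mcneil"`.
#' @param conf_level confidence level (default 0.95).
#' @return A list of class `"auroc"`: `auc`, `ci` (length 2), `se`,
#'   `ci_method`, `n_cases`, `n_controls`.
#' @examples
#' auroc(c(1, 3, 0, 2), c(1, 1, 0, 0), "higher_is_positive")$auc  # 0.75
#' @export
auroc <- function(scores, labels,
                  direction = c("lower_is_positive", "higher_is_positive"),
                  ci_method = c("delong", "hanley-mcneil"),
                  conf_level = 0.95) {
  direction <- match.arg(direction)
  ci_method <- match.arg(ci_method)
  inp <- check_roc_input(scores, labels)
  s <- impairment_scores(inp$scores, direction)
  y <- inp$labels
  cases <- s[y == 1L]; controls <- s[y == 0L]
  n1 <- length(cases); n0 <- length(controls)
  r <- rank(c(cases, controls))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (ci_method == "delong") {
    # placement values: per case, fraction of controls ranked below (+ half ties)
    v10 <- vapply(cases, function(x) {
      (sum(controls < x) + 0.5 * sum(controls == x)) / n0
    }, numeric(1))
    v01 <- vapply(controls, function(x) {
      (sum(cases > x) + 0.5 * sum(cases == x)) / n1
    }, numeric(1))
    se <- sqrt(stats::var(v10) / n1 + stats::var(v01) / n0)
  } else {
    q1 <- auc / (2 - auc)
    q2 <- 2 * auc^2 / (1 + auc)
    se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                  (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  }
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * zq * se))
  structure(list(auc = auc, ci = ci, se = se, ci_method = ci_method,
                 conf_level = conf_level, n_cases = n1, n_controls = n0),
            class = "auroc")
}

#' @export
print.auroc <- function(x, digits = 3, ...) {
  cat(sprintf("AUROC = %.*f (%d%% CI %.*f-%.*f, %s; %d cases / %d controls)\n",
              digits, x$auc, round(100 * x$conf_level), digits, x$ci[1],
              digits, x$ci[2], x$ci_method, x$n_cases, x$n_controls))
  invisible(x)
}

#' Youden's index
#'
#' `J = sensitivity + specificity - 1`, the vertical distance of an ROC
#' operating point above the chance diagonal; maximized to choose an
#' optimal cutpoint.
#'
#' @param sensitivity,specificity proportions in `[0, 1]`.
#' @return `J` in `[-1, 1]`.
#' @examples
#' youden(0.879, 0.997)  # 0.876
#' @export
youden <- function(sensitivity, specificity) {
  if (any(sensitivity < 0 | sensitivity > 1, na.rm = TRUE) ||
      any(specificity < 0 | specificity > 1, na.rm = TRUE)) {
    stop("sensitivity and specificity must lie in [0, 1]")
  }
  sensitivity + specificity - 1
}

#' Youden-optimal cutpoint(s) from an ROC curve
#'
#' Returns the interior operating point maximizing Youden's J. When an
#' adjacent threshold comes within `delta_j` of the maximum, both are
#' reported -- ordered (specificity-favoring, sensitivity-favoring) -- the
#' dual-cutpoint style in which brief cognitive scales are conventionally
#' reported. `preference` collapses the pair to a single row.
#'
#' @param roc a [roc_curve()].
#' @param preference `"max_youden"` (default, may return two rows),
#'   `"favor_sensitivity"` or `"favor_specificity"`.
#' @param delta_j window below the maximum J within which an adjacent
#'   threshold is co-reported (default 0.05).
#' @return A data frame: `threshold`, `label`, `sensitivity`, `specificity`,
#'   `youden`, `favors`.
#' @export
optimal_cutpoint <- function(roc, preference = c("max_youden",
                                                 "favor_sensitivity",
                                                 "favor_specificity"),
                             delta_j = 0.05) {
  preference <- match.arg(preference)
  stopifnot(inherits(roc, "roc_curve"))
  interior <- roc[!is.na(roc$label), , drop = FALSE]
  if (!nrow(interior)) {
    stop("degenerate ROC curve: no interior operating point")
  }
  j <- youden(interior$sensitivity, interior$specificity)
  best <- which.max(j)
  cand <- best
  for (nb in c(best - 1L, best + 1L)) {
    if (nb >= 1L && nb <= nrow(interior) && j[nb] >= j[best] - delta_j) {
      cand <- c(cand, nb)
    }
  }
  cand <- sort(unique(cand))
  out <- interior[cand, c("threshold", "label", "sensitivity",
                          "specificity"), drop = FALSE]
  out$youden <- j[cand]
  # interior rows run from high specificity to high sensitivity
  out <- out[order(-out$specificity, out$sensitivity), , drop = FALSE]
  out$favors <- if (nrow(out) == 1L) "balanced" else
    c("specificity", rep("sensitivity", nrow(out) - 1L))
  if (nrow(out) > 1L && preference != "max_youden") {
    out <- if (preference == "favor_sensitivity") {
      out[which.max(out$sensitivity), , drop = FALSE]
    } else {
      out[which.max(out$specificity), , drop = FALSE]
    }
  }
  rownames(out) <- NULL
  out
}

#' Sensitivity and specificity stratified by severity and education
#'
#' At a fixed cutpoint, computes sensitivity within case-severity strata
#' (mild vs moderate dementia) and specificity within control-education
#' strata (low vs high), alongside the overall values. An empty stratum is
#' reported as not estimable (`NA`).
#'
#' @param scores numeric scale scores.
#' @param labels binary gold standard (1 = case).
#' @param cut a [cutpoint()].
#' @param severity optional per-subject `"mild"`/`"moderate"` (cases).
#' @param education optional per-subject `"low"`/`"high"`.
#' @return A data frame: `stratum_type`, `stratum`, `measure`, `value`, `n`,
#'   `estimable`.
#' @export
stratified_validation <- function(scores, labels, cut, severity = NULL,
                                  education = NULL) {
  stopifnot(inherits(cut, "cutpoint"))
  labels <- as.integer(labels)
  pos <- apply_cutpoint(scores, cut)
  rows <- list()
  add <- function(type, stratum, measure, sel) {
    sel <- sel & !is.na(pos)
    n <- sum(sel, na.rm = TRUE)
    val <- if (n > 0) {
      if (measure == "sensitivity") mean(pos[sel]) else mean(!pos[sel])
    } else NA_real_
    rows[[length(rows) + 1L]] <<- data.frame(
      stratum_type = type, stratum = stratum, measure = measure,
      value = val, n = n, estimable = n > 0, stringsAsFactors = FALSE)
  }
  add("overall", "all_cases", "sensitivity", labels == 1L)
  add("overall", "all_controls", "specificity", labels == 0L)
  if (!is.null(severity)) {
    for (sv in c("mild", "moderate")) {
      add("severity", sv, "sensitivity",
          labels == 1L & !is.na(severity) & severity == sv)
    }
  }
  if (!is.null(education)) {
    for (ed in c("low", "high")) {
      add("education", ed, "specificity",
          labels == 0L & !is.na(education) & education == ed)
    }
  }
  do.call(rbind, rows)
}

#' Full validity assessment of one scale
#'
#' Bundles the ROC curve, AUROC with CI, Youden-optimal cutpoint(s) and the
#' severity/education-stratified sensitivity and specificity for one scale
#' against a gold-standard diagnosis.
#'
#' @inheritParams roc_curve
#' @inheritParams auroc
#' @inheritParams optimal_cutpoint
#' @param scale label for the scale (`"cognitive"`, `"informant"`,
#'   `"combined"`).
#' @param severity,education optional per-subject strata labels.
#' @param region optional region label carried into the result.
#' @return A list of class `"validation_result"`: `scale`, `region`, `roc`,
#'   `auroc`, `cutpoints` (with sensitivity/specificity/J), `strata`.
#' @export
validate_scale <- function(scores, labels,
                           direction = c("lower_is_positive",
                                         "higher_is_positive"),
                           scale = NA_character_, severity = NULL,
                           education = NULL, region = NA_character_,
                           ci_method = "delong", delta_j = 0.05) {
  direction <- match.arg(direction)
  roc <- roc_curve(scores, labels, direction)
  au <- auroc(scores, labels, direction, ci_method = ci_method)
  cp <- optimal_cutpoint(roc, delta_j = delta_j)
  primary <- cutpoint(cp$threshold[1],
                      if (direction == "lower_is_positive") "below"
                      else "above")
  strata <- stratified_validation(scores, labels, primary,
                                  severity = severity, education = education)
  structure(list(scale = scale, region = region, roc = roc, auroc = au,
                 cutpoints = cp, strata = strata),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, digits = 3, ...) {
  cat("Validation of", x$scale, "scale",
      if (!is.na(x$region)) paste0("(", x$region, ")"), "\n")
  print(x$auroc, digits = digits)
  cat("Optimal cutpoint(s):\n")
  cp <- x$cutpoints
  cp$sensitivity <- round(cp$sensitivity, digits)
  cp$specificity <- round(cp$specificity, digits)
  cp$youden <- round(cp$youden, digits)
  print.data.frame(cp, row.names = FALSE)
  invisible(x)
}
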