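cognitive_item_ids <- function() {
  c("hammer", "elbow", "point2", "store", "season", "dayweek", "recall3")
}
informant_item_ids <- function() {
  c("put_things", "mental_decline", "think_reason",
    "forget_yesterday", "forget_where", "dressing")
}

#' Score the brief cognitive scale
#'
#' Sum of six pass/fail cognitive test items (1 = correct) plus the delayed
#' recall count of three words (0-3), giving a total of 0-9 where higher
#' means better performance.
#'
#' @param responses a named vector/list, or a data frame / matrix with one
#'   row per subject, holding the seven brief cognitive items
#'   (`hammer`, `elbow`, `point2`, `store`, `season`, `dayweek` coded 0/1;
#'   `recall3` coded 0-3).
#' @param on_missing `"error"` (default) to fail on a missing response,
#'   naming the item; `"na"` to return `NA` for incomplete subjects.
#' @return Integer total(s) in 0-9.
#' @examples
#' score_cognitive(c(hammer = 1, elbow = 1, point2 = 1, store = 1,
#'                   season = 1, dayweek = 1, recall3 = 3))  # 9
#' @export
score_cognitive <- function(responses, on_missing = c("error", "na")) {
  on_missing <- match.arg(on_missing)
  m <- score_input(responses, cognitive_item_ids())
  binary <- m[, setdiff(cognitive_item_ids(), "recall3"), drop = FALSE]
  check_range(binary, 0L, 1L)
  check_range(m[, "recall3", drop = FALSE], 0L, 3L)
  handle_missing(m, on_missing)
  as.integer(rowSums(m))
}

#' Score the brief informant scale
#'
#' Counts the six informant items reported at or above their keyed frequency
#' cut (symptom present), giving a total of 0-6 where higher means more
#' reported decline. Raw never/sometimes/often codes (0/1/2) are
#' dichotomized by `plan`; already-keyed 0/1 input is accepted with
#' `plan = NULL`.
#'
#' @param responses named vector/list or data frame/matrix with the six
#'   informant items (`put_things`, `mental_decline`, `think_reason`,
#'   `forget_yesterday`, `forget_where`, `dressing`).
#' @param plan named cuts as in [key_responses()]; default: the brief
#'   CSI-D plan (`put_things` keyed at "often", the rest at "sometimes").
#'   Use `NULL` when `responses` are already 0/1 keyed.
#' @inheritParams score_cognitive
#' @return Integer total(s) in 0-6.
#' @examples
#' score_informant(c(put_things = 1, mental_decline = 0, think_reason = 0,
#'                   forget_yesterday = 0, forget_where = 0, dressing = 0))
#' # 0: "sometimes" misplacing things does not reach the "often" cut
#' @export
score_informant <- function(responses, plan = informant_default_plan(),
                            on_missing = c("error", "na")) {
  on_missing <- match.arg(on_missing)
  m <- score_input(responses, informant_item_ids())
  if (is.null(plan)) {
    check_range(m, 0L, 1L)
    keyed <- m
  } else {
    check_range(m, 0L, 2L)
    keyed <- m
    for (id in colnames(m)) {
      cut <- plan[[id]]
      if (is.null(cut)) stop("plan lacks a cut for item '", id, "'")
      keyed[, id] <- as.integer(m[, id] >= cut)
    }
  }
  handle_missing(keyed, on_missing)
  as.integer(rowSums(keyed))
}

#' Default informant dichotomization plan of the brief CSI-D
#' @return Named integer cut levels for the six informant items.
#' @export
informant_default_plan <- function() {
  p <- attr(brief_item_bank(), "default_plan")
  p[informant_item_ids()]
}

#' Combined brief score
#'
#' The informant total (0-6) subtracted from the cognitive total (0-9) --
#' subtraction, not addition, because impairment lowers the cognitive score
#' but raises the informant score. Possible range -6 to 9.
#'
#' @param cognitive_total integer(s) 0-9.
#' @param informant_total integer(s) 0-6.
#' @return Integer combined score(s) in -6..9; `NA` propagates.
#' @examples
#' score_combined(9, 0)  # 9, the ceiling
#' score_combined(0, 6)  # -6, the floor
#' @export
score_combined <- function(cognitive_total, informant_total) {
  check_total(cognitive_total, 0L, 9L, "cognitive_total")
  check_total(informant_total, 0L, 6L, "informant_total")
  as.integer(cognitive_total) - as.integer(informant_total)
}

#' Two-stage triage rule for the brief screen
#'
#' Cognitive-first triage: a cognitive total of `suggestive_max` (4) or less
#' is highly suggestive of dementia (screen positive); `improbable_min` (7)
#' or more renders it highly improbable (negative). In the intermediate band
#' (5-6) the informant interview decides: positive iff the combined score is
#' `combined_max` (4) or less; with no informant available the result is
#' indeterminate (re-assessment or informant follow-up indicated).
#'
#' @param cognitive_total integer(s) 0-9.
#' @param informant_total optional integer(s) 0-6; `NA` = no informant.
#' @param suggestive_max cognitive score at or below which the screen is
#'   positive outright (default 4).
#' @param improbable_min cognitive score at or above which it is negative
#'   outright (default 7).
#' @param combined_max combined-score threshold for the intermediate band
#'   (default 4: positive iff combined <= 4).
#' @return Factor with levels `positive`, `negative`, `indeterminate`.
#' @examples
#' triage(4)                       # positive
#' triage(7)                       # negative
#' triage(5, informant_total = 2)  # combined 3 -> positive
#' triage(6)                       # indeterminate without an informant
#' @export
triage <- function(cognitive_total, informant_total = NULL,
                   suggestive_max = 4L, improbable_min = 7L,
                   combined_max = 4L) {
  check_total(cognitive_total, 0L, 9L, "cognitive_total")
  n <- length(cognitive_total)
  if (is.null(informant_total)) informant_total <- rep(NA_integer_, n)
  if (length(informant_total) == 1L) informant_total <- rep(informant_total, n)
  check_total(informant_total, 0L, 6L, "informant_total")
  out <- rep(NA_character_, n)
  out[cognitive_total <= suggestive_max] <- "positive"
  out[cognitive_total >= improbable_min] <- "negative"
  mid <- is.na(out) & !is.na(cognitive_total)
  has_inf <- mid & !is.na(informant_total)
  out[has_inf] <- ifelse(
    cognitive_total[has_inf] - informant_total[has_inf] <= combined_max,
    "positive", "negative")
  out[mid & is.na(informant_total)] <- "indeterminate"
  factor(out, levels = c("positive", "negative", "indeterminate"))
}

#' Score a whole cohort on the brief scales
#'
#' Applies [score_cognitive()], [score_informant()], [score_combined()] and
#' [triage()] to every subject of a cohort carrying the brief CSI-D items.
#' Scale totals use complete cases per scale: a subject missing any item of
#' a scale gets `NA` on that scale and, when the informant scale is missing,
#' cognitive-only triage (the conservative strategy).
#'
#' @param cohort a [cohort_table()] with the [brief_item_bank()] items.
#' @param plan informant dichotomization plan (default the brief CSI-D cuts).
#' @return A data frame: `subject_id`, `cognitive_total`, `informant_total`,
#'   `combined`, `triage`, `informant_missing`.
#' @export
score_cohort <- function(cohort, plan = informant_default_plan()) {
  stopifnot(inherits(cohort, "cohort"))
  resp <- cohort$responses
  cog <- score_cognitive(resp[, cognitive_item_ids(), drop = FALSE],
                         on_missing = "na")
  inf <- score_informant(resp[, informant_item_ids(), drop = FALSE],
                         plan = plan, on_missing = "na")
  comb <- ifelse(is.na(cog) | is.na(inf), NA_integer_, cog - inf)
  data.frame(
    subject_id = cohort$subjects$subject_id,
    cognitive_total = cog, informant_total = inf, combined = comb,
    triage = triage(cog, inf),
    informant_missing = is.na(inf),
    stringsAsFactors = FALSE
  )
}

# --- input plumbing -------------------------------------------------------

score_input <- function(responses, ids) {
  if (is.data.frame(responses)) responses <- as.matrix(responses)
  if (!is.matrix(responses)) {
    responses <- matrix(unlist(responses), nrow = 1,
                        dimnames = list(NULL, names(responses)))
  }
  if (is.null(colnames(responses))) {
    stop("responses must be named by item id")
  }
  absent <- setdiff(ids, colnames(responses))
  if (length(absent)) {
    stop("missing item response(s): ", paste(absent, collapse = ", "))
  }
  m <- responses[, ids, drop = FALSE]
  storage.mode(m) <- "integer"
  m
}

check_range <- function(m, lo, hi) {
  bad <- which(!is.na(m) & (m < lo | m > hi), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("response for item '%s' outside %d..%d",
                 colnames(m)[bad[1, 2]], lo, hi))
  }
  invisible(m)
}

check_total <- function(x, lo, hi, what) {
  if (any(!is.na(x) & (x < lo | x > hi))) {
    stop(what, " must lie in ", lo, "..", hi)
  }
  invisible(x)
}

handle_missing <- function(m, on_missing) {
  if (on_missing == "error" && anyNA(m)) {
    miss <- which(is.na(m), arr.ind = TRUE)
    stop("missing response for item '", colnames(m)[miss[1, 2]], "'")
  }
  invisible(m)
}
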