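#' Define an item bank
#'
#' An item bank describes the items of one or more scales: identity, scale
#' membership (cognitive test of the participant vs informant interview),
#' number of ordered response levels, the meaning of the keyed direction and
#' a cognitive/functional domain tag used when selecting brief subsets.
#'
#' Responses are coded `0 .. n_levels - 1`. For dichotomous items the raw
#' coding may be reversed relative to the keyed direction (`reverse_coded`);
#' [key_responses()] always produces `1 = keyed` (correct answer on cognitive
#' items, symptom present on informant items).
#'
#' @param item_id character, unique short identifiers.
#' @param label character, free-text item descriptions.
#' @param scale character, one of `"cognitive"` or `"informant"` per item.
#' @param n_levels integer >= 2, number of ordered response levels per item.
#' @param keyed_level_meaning `"correct_response"` or `"symptom_present"`.
#' @param domain_tag character, short domain labels (e.g. `"naming"`,
#'   `"orientation_time"`, `"adl"`).
#' @param reverse_coded logical, `TRUE` when the raw coding runs against the
#'   keyed direction (dichotomous items only).
#' @return A data frame of class `"item_bank"` with one row per item.
#' @examples
#' bank <- item_bank(
#'   item_id = c("a", "b"), label = c("Item A", "Item B"),
#'   scale = "cognitive", n_levels = 2L,
#'   keyed_level_meaning = "correct_response", domain_tag = c("naming", "praxis")
#' )
#' @export
item_bank <- function(item_id, label = item_id, scale, n_levels,
                      keyed_level_meaning, domain_tag = item_id,
                      reverse_coded = FALSE) {
  k <- length(item_id)
  bank <- data.frame(
    item_id = as.character(item_id),
    label = rep_len(as.character(label), k),
    scale = rep_len(as.character(scale), k),
    n_levels = rep_len(as.integer(n_levels), k),
    keyed_level_meaning = rep_len(as.character(keyed_level_meaning), k),
    domain_tag = rep_len(as.character(domain_tag), k),
    reverse_coded = rep_len(as.logical(reverse_coded), k),
    stringsAsFactors = FALSE
  )
  validate_item_bank(bank)
}

validate_item_bank <- function(bank) {
  stopifnot(is.data.frame(bank))
  required <- c("item_id", "label", "scale", "n_levels",
                "keyed_level_meaning", "domain_tag", "reverse_coded")
  missing_cols <- setdiff(required, names(bank))
  if (length(missing_cols)) {
    stop("item bank lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(bank$item_id)) {
    stop("duplicate item_id in item bank: ",
         paste(unique(bank$item_id[duplicated(bank$item_id)]), collapse = ", "))
  }
  if (any(bank$n_levels < 2L)) {
    stop("n_levels must be >= 2 for item(s): ",
         paste(bank$item_id[bank$n_levels < 2L], collapse = ", "))
  }
  bad_scale <- !bank$scale %in% c("cognitive", "informant")
  if (any(bad_scale)) {
    stop("scale must be 'cognitive' or 'informant' for item(s): ",
         paste(bank$item_id[bad_scale], collapse = ", "))
  }
  bad_key <- !bank$keyed_level_meaning %in% c("correct_response", "symptom_present")
  if (any(bad_key)) {
    stop("keyed_level_meaning must be 'correct_response' or 'symptom_present'")
  }
  if (any(bank$reverse_coded & bank$n_levels > 2L)) {
    stop("reverse_coded applies to dichotomous items only")
  }
  class(bank) <- c("item_bank", "data.frame")
  bank
}

#' The brief CSI-D item bank
#'
#' The thirteen items of the brief Community Screening Instrument for
#' Dementia: seven cognitive test items (six pass/fail plus a three-word
#' delayed recall scored 0-3) and six informant items, each originally rated
#' never / sometimes / often (0/1/2).
#'
#' The attached default dichotomization plan (`attr(bank, "default_plan")`)
#' keys each informant item at its named frequency cut: "often" for
#' forgetting where things are put (cut 2), "sometimes" or worse for the
#' remaining symptom items (cut 1); the delayed recall item is keyed at
#' recalling at least one word when it enters scalability analyses.
#'
#' @return An [item_bank()] data frame with 13 rows and a `default_plan`
#'   attribute (named integer vector of cut levels for polytomous items).
#' @examples
#' bank <- brief_item_bank()
#' subset(bank, scale == "cognitive")$item_id
#' @export
brief_item_bank <- function() {
  bank <- item_bank(
    item_id = c("hammer", "elbow", "point2", "store", "season", "dayweek",
                "recall3",
                "put_things", "mental_decline", "think_reason",
                "forget_yesterday", "forget_where", "dressing"),
    label = c("Describing the use of a hammer",
              "Naming elbow",
              "Pointing to window and then to door",
              "Locating nearest store",
              "Orientation to season",
              "Orientation to day of the week",
              "Delayed recall of three words",
              "Often forgets where she/he had put things",
              "General decline in mental functioning",
              "Change in ability to think and reason",
              "Sometimes forgets what happened the day before",
              "Sometimes forgets where she/he is",
              "Difficulty dressing"),
    scale = c(rep("cognitive", 7L), rep("informant", 6L)),
    n_levels = c(2L, 2L, 2L, 2L, 2L, 2L, 4L, rep(3L, 6L)),
    keyed_level_meaning = c(rep("correct_response", 7L),
                            rep("symptom_present", 6L)),
    domain_tag = c("semantic_knowledge", "naming", "comprehension_praxis",
                   "spatial_orientation", "orientation_time_season",
                   "orientation_time_day", "recall",
                   "memory_misplacing", "global_decline", "reasoning",
                   "memory_recent", "disorientation", "adl")
  )
  attr(bank, "default_plan") <- c(
    recall3 = 1L, put_things = 2L, mental_decline = 1L, think_reason = 1L,
    forget_yesterday = 1L, forget_where = 1L, dressing = 1L
  )
  bank
}

#' Read an item bank from a delimited file
#'
#' @param path path to a delimited text file with the [item_bank()] columns
#'   (`reverse_coded` optional, defaulting to `FALSE`).
#' @param delim field delimiter.
#' @return An [item_bank()] data frame.
#' @export
read_item_bank <- function(path, delim = ",") {
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE)
  if (is.null(df$reverse_coded)) df$reverse_coded <- FALSE
  if (is.null(df$label)) df$label <- df$item_id
  if (is.null(df$domain_tag)) df$domain_tag <- df$item_id
  df$n_levels <- as.integer(df$n_levels)
  validate_item_bank(df)
}

#' @export
print.item_bank <- function(x, ...) {
  cat("Item bank:", nrow(x), "items (",
      sum(x$scale == "cognitive"), "cognitive,",
      sum(x$scale == "informant"), "informant )\n")
  print.data.frame(x, ...)
  invisible(x)
}
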