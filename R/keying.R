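#' Key cohort responses into a common binary coding
#'
#' Converts raw response codes into the canonical internal coding in which
#' `1` always means the keyed direction -- a correct answer on cognitive test
#' items, a symptom reported present on informant items. Dichotomous items
#' are keyed directly (honouring `reverse_coded`); polytomous items are
#' dichotomized at a cut level, keyed iff `response >= cut`. Missing
#' responses propagate.
#'
#' @param cohort a [cohort_table()] object.
#' @param items character, the item ids to key (default: all items of
#'   `cohort$item_bank`). All must belong to the cohort's bank.
#' @param plan named integer vector of cut levels for polytomous items
#'   (`1 <= cut <= n_levels - 1`), or a [optimal_dichotomy()] plan. Defaults
#'   to the bank's `default_plan` attribute.
#' @param exclude character, polytomous items to drop instead of keying.
#' @return An integer matrix of class `"keyed_matrix"` (values 0/1/`NA`) with
#'   attributes `item_bank` (the keyed items' definitions), `plan` and
#'   `n_item` (per-item non-missing counts).
#' @examples
#' bank <- brief_item_bank()
#' resp <- matrix(1L, 2, 13, dimnames = list(NULL, bank$item_id))
#' km <- key_responses(cohort_table(resp, bank))
#' @export
key_responses <- function(cohort, items = NULL, plan = NULL,
                          exclude = character()) {
  stopifnot(inherits(cohort, "cohort"))
  bank <- cohort$item_bank
  if (is.null(items)) items <- bank$item_id
  unknown <- setdiff(items, bank$item_id)
  if (length(unknown)) {
    stop("unknown item(s): ", paste(unknown, collapse = ", "))
  }
  if (inherits(plan, "dichotomization_plan")) plan <- plan$cuts
  if (is.null(plan)) plan <- attr(bank, "default_plan")
  items <- setdiff(items, exclude)
  out <- matrix(NA_integer_, nrow(cohort$responses), length(items),
                dimnames = list(NULL, items))
  keep_rows <- seq_len(nrow(cohort$responses))
  for (id in items) {
    def <- bank[bank$item_id == id, ]
    x <- cohort$responses[, id]
    if (def$n_levels == 2L) {
      out[, id] <- if (def$reverse_coded) 1L - x else x
    } else {
      cut <- plan[[id]]
      if (is.null(cut) || is.na(cut)) {
        stop("polytomous item '", id,
             "' has no dichotomization cut and is not excluded")
      }
      cut <- as.integer(cut)
      if (cut < 1L || cut > def$n_levels - 1L) {
        stop("cut for item '", id, "' must lie in 1..", def$n_levels - 1L)
      }
      out[, id] <- as.integer(x >= cut)
    }
  }
  structure(out,
            item_bank = bank[match(items, bank$item_id), , drop = FALSE],
            plan = plan,
            n_item = colSums(!is.na(out)),
            class = c("keyed_matrix", class(out)))
}

# Drop keyed_matrix attributes, keeping dim/dimnames.
strip_keyed <- function(km) {
  m <- unclass(km)
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  m
}

# Strip a keyed_matrix down to its scale-wise complete cases.
complete_keyed <- function(km) {
  x <- strip_keyed(km)
  x[stats::complete.cases(x), , drop = FALSE]
}

as_binary_matrix <- function(matrix) {
  if (inherits(matrix, "keyed_matrix")) return(complete_keyed(matrix))
  m <- as.matrix(matrix)
  storage.mode(m) <- "integer"
  if (any(!is.na(m) & !m %in% c(0L, 1L))) {
    stop("keyed matrix values must be 0, 1 or missing")
  }
  if (is.null(colnames(m))) colnames(m) <- paste0("item", seq_len(ncol(m)))
  m[stats::complete.cases(m), , drop = FALSE]
}
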