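#' Construct a cohort table
#'
#' A cohort holds one row per subject: raw item responses (integer codes
#' `0 .. n_levels - 1`, `NA` for missing) plus optional per-subject labels --
#' a gold-standard dementia diagnosis, clinical severity for cases (mild =
#' CDR 1, moderate = CDR 2), an education stratum and a region label.
#'
#' @param responses integer matrix or data frame, subjects x items; column
#'   names must match `item_bank$item_id`.
#' @param item_bank an [item_bank()] describing the response columns.
#' @param subject_id unique subject identifiers (default `s1, s2, ...`).
#' @param diagnosis optional binary gold standard (0/1, `NA` allowed).
#' @param severity optional `"mild"`/`"moderate"`, only for `diagnosis == 1`.
#' @param education optional `"low"`/`"high"`.
#' @param region optional character label.
#' @return A list of class `"cohort"` with elements `subjects` (data frame of
#'   ids and labels), `responses` (integer matrix) and `item_bank`.
#' @examples
#' bank <- item_bank(c("a", "b"), scale = "cognitive", n_levels = 2L,
#'                   keyed_level_meaning = "correct_response")
#' co <- cohort_table(matrix(c(1L, 0L, 1L, 1L), 2,
#'                           dimnames = list(NULL, c("a", "b"))), bank)
#' @export
cohort_table <- function(responses, item_bank, subject_id = NULL,
                         diagnosis = NULL, severity = NULL,
                         education = NULL, region = NULL) {
  item_bank <- validate_item_bank(item_bank)
  responses <- as.matrix(responses)
  storage.mode(responses) <- "integer"
  n <- nrow(responses)
  if (is.null(colnames(responses))) {
    stop("response matrix must have item_id column names")
  }
  unknown <- setdiff(colnames(responses), item_bank$item_id)
  if (length(unknown)) {
    stop("unknown item column(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(subject_id)) subject_id <- paste0("s", seq_len(n))
  subject_id <- as.character(subject_id)
  if (anyDuplicated(subject_id)) {
    stop("duplicate subject_id: ",
         paste(unique(subject_id[duplicated(subject_id)]), collapse = ", "))
  }
  bank_idx <- match(colnames(responses), item_bank$item_id)
  for (k in seq_len(ncol(responses))) {
    v <- responses[, k]
    top <- item_bank$n_levels[bank_idx[k]] - 1L
    bad <- which(!is.na(v) & (v < 0L | v > top))
    if (length(bad)) {
      stop(sprintf(
        "response out of range for item '%s', subject '%s': code %d (levels 0..%d)",
        colnames(responses)[k], subject_id[bad[1]], v[bad[1]], top))
    }
  }
  recycle <- function(x, what) {
    if (is.null(x)) return(rep(NA_character_, n))
    x <- as.character(x)
    if (length(x) == 1L) x <- rep(x, n)
    if (length(x) != n) stop(what, " must have one value per subject")
    x
  }
  diag_chr <- if (is.null(diagnosis)) rep(NA_integer_, n) else {
    d <- as.integer(diagnosis)
    if (length(d) == 1L) d <- rep(d, n)
    if (length(d) != n) stop("diagnosis must have one value per subject")
    if (any(!is.na(d) & !d %in% c(0L, 1L))) stop("diagnosis must be 0/1")
    d
  }
  sev <- recycle(severity, "severity")
  if (any(!is.na(sev) & !sev %in% c("mild", "moderate"))) {
    stop("severity must be 'mild' or 'moderate'")
  }
  if (any(!is.na(sev) & (is.na(diag_chr) | diag_chr != 1L))) {
    stop("severity may only be set for subjects with diagnosis = 1")
  }
  edu <- recycle(education, "education")
  if (any(!is.na(edu) & !edu %in% c("low", "high"))) {
    stop("education must be 'low' or 'high'")
  }
  subjects <- data.frame(
    subject_id = subject_id, diagnosis = diag_chr, severity = sev,
    education = edu, region = recycle(region, "region"),
    stringsAsFactors = FALSE
  )
  structure(list(subjects = subjects, responses = responses,
                 item_bank = item_bank),
            class = "cohort")
}

#' Load a cohort from a delimited file
#'
#' Reads a header-delimited text file with a `subject_id` column, one column
#' per item of `item_bank`, and optional `diagnosis`, `severity`, `education`
#' and `region` columns. All item codes are validated against the declared
#' level ranges.
#'
#' @param path file path.
#' @param item_bank an [item_bank()]; every `item_id` must appear as a column.
#' @param delim field delimiter (default comma).
#' @param missing token denoting a missing response (default `"NA"`).
#' @param quiet suppress the summary message.
#' @return A [cohort_table()] object; row order of the file is preserved.
#' @export
load_cohort <- function(path, item_bank, delim = ",", missing = "NA",
                        quiet = FALSE) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          na.strings = missing, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!"subject_id" %in% names(df)) stop("file lacks a subject_id column")
  item_bank <- validate_item_bank(item_bank)
  absent <- setdiff(item_bank$item_id, names(df))
  if (length(absent)) {
    stop("cohort file lacks item column(s): ", paste(absent, collapse = ", "))
  }
  label_cols <- intersect(c("diagnosis", "severity", "education", "region"),
                          names(df))
  extra <- setdiff(names(df),
                   c("subject_id", item_bank$item_id, label_cols))
  if (length(extra)) {
    stop("unknown item column(s): ", paste(extra, collapse = ", "))
  }
  resp <- as.matrix(df[, item_bank$item_id, drop = FALSE])
  suppressWarnings(storage.mode(resp) <- "integer")
  co <- cohort_table(
    resp, item_bank, subject_id = df$subject_id,
    diagnosis = if ("diagnosis" %in% label_cols) df$diagnosis,
    severity = if ("severity" %in% label_cols) df$severity,
    education = if ("education" %in% label_cols) df$education,
    region = if ("region" %in% label_cols) df$region
  )
  if (!quiet) {
    message(sprintf("loaded cohort: %d subjects, %d items, %d missing cells",
                    nrow(resp), ncol(resp), sum(is.na(resp))))
  }
  co
}

#' Write a cohort to a delimited file
#'
#' @param cohort a [cohort_table()] object.
#' @param path output file path.
#' @param delim field delimiter.
#' @param missing token written for missing responses.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, delim = ",", missing = "NA") {
  stopifnot(inherits(cohort, "cohort"))
  out <- data.frame(subject_id = cohort$subjects$subject_id,
                    cohort$responses, check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (lab in c("diagnosis", "severity", "education", "region")) {
    if (!all(is.na(cohort$subjects[[lab]]))) out[[lab]] <- cohort$subjects[[lab]]
  }
  utils::write.table(out, path, sep = delim, na = missing, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @export
print.cohort <- function(x, ...) {
  cat("Cohort:", nrow(x$responses), "subjects x", ncol(x$responses),
      "items;", sum(is.na(x$responses)), "missing cells\n")
  d <- x$subjects$diagnosis
  if (!all(is.na(d))) {
    cat("  diagnosis: ", sum(d == 1L, na.rm = TRUE), " cases / ",
        sum(d == 0L, na.rm = TRUE), " non-cases\n", sep = "")
  }
  invisible(x)
}
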