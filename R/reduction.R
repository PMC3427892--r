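#' Optimal dichotomization of polytomous items
#'
#' Searches, for every polytomous item of a candidate scale, the cut level
#' that maximizes that item's Loevinger coefficient `H_i` within the scale
#' (the other items held at their current cuts). The search is
#' coordinate-wise: all cuts start at the middle level, each item is
#' optimized in bank order, and one refinement pass repeats the sweep.
#' Ties are broken toward the lower cut (the more prevalent symptom level);
#' cuts that make an item constant are skipped, and an item constant at
#' every cut is flagged unusable.
#'
#' @param cohort a [cohort_table()].
#' @param item_bank an [item_bank()]; defaults to the cohort's bank.
#' @param items character, the candidate scale (ids); all must share one
#'   `scale`. Default: all items of the bank's single scale.
#' @param sweeps number of full passes (default 2: initial + one refinement).
#' @return A list of class `"dichotomization_plan"`: `cuts` (named integer
#'   vector for polytomous items), `unusable` (character), and `log` (data
#'   frame of every cut evaluated with its `H_i`).
#' @export
optimal_dichotomy <- function(cohort, item_bank = cohort$item_bank,
                              items = NULL, sweeps = 2L) {
  stopifnot(inherits(cohort, "cohort"))
  item_bank <- validate_item_bank(item_bank)
  if (is.null(items)) items <- item_bank$item_id
  defs <- item_bank[match(items, item_bank$item_id), , drop = FALSE]
  if (anyNA(defs$item_id)) stop("candidate items not all in item bank")
  if (length(unique(defs$scale)) > 1L) {
    stop("candidate scale mixes cognitive and informant items")
  }
  poly <- defs$item_id[defs$n_levels > 2L]
  cuts <- vapply(poly, function(id) {
    defs$n_levels[defs$item_id == id] %/% 2L
  }, integer(1))
  log <- list()
  unusable <- character(0)
  h_of <- function(plan, target) {
    km <- key_responses(cohort, items = setdiff(items, unusable), plan = plan)
    st <- tryCatch(suppressWarnings(scale_scalability(km)),
                   error = function(e) NULL)
    if (is.null(st)) return(NA_real_)
    h <- st$items$H_i[st$items$item_id == target]
    if (length(h) != 1L) NA_real_ else h
  }
  is_constant_at <- function(id, cut) {
    x <- cohort$responses[, id]
    x <- x[!is.na(x)]
    length(unique(as.integer(x >= cut))) < 2L
  }
  for (sweep in seq_len(sweeps)) {
    for (id in poly) {
      if (id %in% unusable) next
      m <- defs$n_levels[defs$item_id == id] - 1L
      cand <- seq_len(m)
      ok <- !vapply(cand, function(cc) is_constant_at(id, cc), logical(1))
      if (!any(ok)) {
        unusable <- union(unusable, id)
        cuts <- cuts[names(cuts) != id]
        warning("item '", id, "' constant at every cut; flagged unusable")
        next
      }
      hs <- rep(NA_real_, length(cand))
      for (cc in cand[ok]) {
        trial <- cuts; trial[id] <- cc
        hs[cc] <- h_of(trial, id)
      }
      log[[length(log) + 1L]] <- data.frame(
        sweep = sweep, item_id = id, cut = cand, H_i = hs,
        stringsAsFactors = FALSE)
      best <- max(hs, na.rm = TRUE)
      cuts[id] <- cand[which(!is.na(hs) & hs >= best - 1e-12)][1L]  # lower cut on ties
    }
  }
  structure(list(cuts = cuts, unusable = unusable,
                 log = if (length(log)) do.call(rbind, log) else
                   data.frame(sweep = integer(), item_id = character(),
                              cut = integer(), H_i = numeric())),
            class = "dichotomization_plan")
}

#' @export
print.dichotomization_plan <- function(x, ...) {
  cat("Dichotomization plan (keyed iff response >= cut):\n")
  for (id in names(x$cuts)) cat("  ", id, ": cut ", x$cuts[[id]], "\n", sep = "")
  if (length(x$unusable)) {
    cat("  unusable:", paste(x$unusable, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Hierarchical selection of a brief item subset
#'
#' Selects `k` items from a scalability analysis of a candidate pool by
#' ranking items on their Loevinger `H_i` (descending) and walking the
#' ranking greedily. An item is passed over when (a) its domain is already
#' represented while an unrepresented domain still has a strongly scalable
#' item available, or (b) its difficulty lies within `epsilon` of an already
#' selected item and a strong alternative with differing difficulty remains.
#' If the walk ends short, skipped items are admitted back in rank order.
#' Every decision is recorded in the selection log.
#'
#' @param stats a [scale_scalability()] result for the full candidate pool.
#' @param item_bank an [item_bank()] supplying `domain_tag` per item.
#' @param k number of items to select (default 6).
#' @param h_floor `H_i` threshold for "strong" scalability (default 0.5);
#'   a warning is issued when fewer than `k` items reach it.
#' @param epsilon minimum difficulty spacing (default 0.02).
#' @param domain_priority,difficulty_priority logical switches for rules (a)
#'   and (b).
#' @return A list of class `"selection_result"`: `selected` (item ids in
#'   ascending difficulty order), `items` (their `H_i` and difficulty at
#'   selection), `subset_H` (whole-scale H of the selected subset, from the
#'   pool's pairwise counts), and `log` (decision trace).
#' @export
select_items <- function(stats, item_bank, k = 6L, h_floor = 0.5,
                         epsilon = 0.02, domain_priority = TRUE,
                         difficulty_priority = TRUE) {
  stopifnot(inherits(stats, "scale_scalability"))
  item_bank <- validate_item_bank(item_bank)
  if (k < 2L) stop("k must be >= 2")
  it <- stats$items
  it$domain_tag <- item_bank$domain_tag[match(it$item_id, item_bank$item_id)]
  if (anyNA(it$domain_tag)) {
    stop("item(s) missing from item bank: ",
         paste(it$item_id[is.na(it$domain_tag)], collapse = ", "))
  }
  if (k > nrow(it)) stop("k exceeds the number of candidate items")
  if (sum(it$H_i >= h_floor, na.rm = TRUE) < k) {
    warning("fewer than k items reach H_i >= ", h_floor,
            "; best-effort selection")
  }
  ranked <- it[order(-it$H_i, seq_len(nrow(it))), , drop = FALSE]
  selected <- character(0); sel_dom <- character(0); sel_dif <- numeric(0)
  skipped <- character(0)
  log <- list()
  note <- function(id, action, reason) {
    log[[length(log) + 1L]] <<- data.frame(
      step = length(log) + 1L, item_id = id, action = action,
      reason = reason, stringsAsFactors = FALSE)
  }
  strong_left <- function(excl) {
    ranked[!ranked$item_id %in% c(selected, excl) &
             !is.na(ranked$H_i) & ranked$H_i >= h_floor, , drop = FALSE]
  }
  for (r in seq_len(nrow(ranked))) {
    if (length(selected) >= k) break
    row <- ranked[r, ]
    if (domain_priority && row$domain_tag %in% sel_dom) {
      alt <- strong_left(row$item_id)
      if (any(!alt$domain_tag %in% sel_dom)) {
        skipped <- c(skipped, row$item_id)
        note(row$item_id, "skip",
             paste0("domain '", row$domain_tag, "' already represented"))
        next
      }
    }
    if (difficulty_priority && length(sel_dif) &&
        any(abs(row$difficulty - sel_dif) < epsilon)) {
      alt <- strong_left(row$item_id)
      spaced <- vapply(alt$difficulty, function(dd) {
        all(abs(dd - sel_dif) >= epsilon)
      }, logical(1))
      if (any(spaced)) {
        skipped <- c(skipped, row$item_id)
        note(row$item_id, "skip",
             sprintf("difficulty %.3f within %.3f of a selected item",
                     row$difficulty, epsilon))
        next
      }
    }
    selected <- c(selected, row$item_id)
    sel_dom <- c(sel_dom, row$domain_tag)
    sel_dif <- c(sel_dif, row$difficulty)
    note(row$item_id, "select", sprintf("H_i = %.3f", row$H_i))
  }
  if (length(selected) < k) {
    for (id in c(skipped,
                 setdiff(ranked$item_id, c(selected, skipped)))) {
      if (length(selected) >= k) break
      if (id %in% selected) next
      selected <- c(selected, id)
      note(id, "backfill", "filled to k from skipped/remaining items")
    }
  }
  sel <- it[match(selected, it$item_id), , drop = FALSE]
  sel <- sel[order(sel$difficulty, match(sel$item_id, it$item_id)), ,
             drop = FALSE]
  pr <- stats$pairs
  inpair <- pr$item_i %in% selected & pr$item_j %in% selected & !pr$degenerate
  subset_H <- if (any(inpair)) {
    1 - sum(pr$F_ij[inpair]) / sum(pr$E_ij[inpair])
  } else NA_real_
  structure(list(
    selected = sel$item_id,
    items = sel[, c("item_id", "difficulty", "H_i", "band", "domain_tag")],
    subset_H = subset_H,
    k = k,
    log = do.call(rbind, log)
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Selected", length(x$selected), "items (ascending difficulty):\n")
  print.data.frame(x$items, row.names = FALSE)
  cat(sprintf("Whole-scale H of the selected subset: %.3f\n", x$subset_H))
  invisible(x)
}
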