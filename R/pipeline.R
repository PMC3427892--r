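#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end pipeline with its documented
#' default: Mokken criteria (minimum violation 0.03, alpha 0.05, scalability
#' bands 0.3/0.4/0.5, Crit bands 40/80), selection settings (k = 6, strong
#' floor 0.5, difficulty spacing 0.02), the triage cutpoints (cognitive <= 4
#' positive / >= 7 negative, combined <= 4) and validation settings (DeLong
#' CI, dual-cutpoint window 0.05), plus the generator config and seed.
#'
#' @param seed integer master seed for the run.
#' @param generator a [generator_config()] (its seed is set from `seed` when
#'   absent).
#' @param cohort_path optional path to an existing cohort CSV, used when the
#'   `simulate` stage is not requested.
#' @param mokken,selection,scoring,validation named lists overriding the
#'   defaults shown above.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed,
                            generator = generator_config(n = 5000L,
                                                         seed = seed),
                            cohort_path = NULL,
                            mokken = list(),
                            selection = list(),
                            scoring = list(),
                            validation = list()) {
  merge_defaults <- function(defaults, user) {
    defaults[names(user)] <- user
    defaults
  }
  if (is.null(generator$seed)) generator$seed <- seed
  cfg <- list(
    seed = as.integer(seed),
    generator = generator,
    cohort_path = cohort_path,
    mokken = merge_defaults(
      list(minvi = 0.03, alpha = 0.05, min_group_size = NULL), mokken),
    selection = merge_defaults(
      list(k = 6L, h_floor = 0.5, epsilon = 0.02), selection),
    scoring = merge_defaults(
      list(suggestive_max = 4L, improbable_min = 7L, combined_max = 4L),
      scoring),
    validation = merge_defaults(
      list(ci_method = "delong", delta_j = 0.05), validation)
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the analysis pipeline
#'
#' Chains the pipeline stages in order -- `simulate` (synthetic cohort),
#' `mokken` (scalability and assumption checks per scale), `reduce`
#' (informant dichotomization and item selection), `score` (brief scale
#' totals and triage) and `validate` (ROC validity of the three scales) --
#' writing each stage's artifacts (CSV/JSON) and a combined markdown report
#' into `out_dir`. No stage mutates its inputs; identical config and seed
#' reproduce an identical bundle.
#'
#' @param config a [pipeline_config()].
#' @param stages character subset of
#'   `c("simulate", "mokken", "reduce", "score", "validate")`, executed in
#'   canonical order.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the computed objects and the paths of all
#'   artifacts written.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "mokken", "reduce",
                                    "score", "validate"),
                         out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  all_stages <- c("simulate", "mokken", "reduce", "score", "validate")
  stages <- all_stages[all_stages %in% match.arg(stages, all_stages,
                                                 several.ok = TRUE)]
  if (!length(stages)) stop("no stages requested")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- list()
  bank <- brief_item_bank()
  objects <- list(config = config)
  report <- c("# Brief screen derivation and validation pipeline", "",
              paste0("seed: ", config$seed),
              paste0("stages: ", paste(stages, collapse = ", ")), "")
  write_json_art <- function(x, name) {
    path <- file.path(out_dir, name)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
    art[[name]] <<- path
  }
  write_csv_art <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    art[[name]] <<- path
  }
  write_json_art(config[setdiff(names(config), "generator")], "config.json")

  cohort <- NULL
  if ("simulate" %in% stages) {
    gen <- config$generator
    sim <- if (gen$design == "population") generate_population(gen)
           else generate_case_control(gen)
    cohort <- sim$cohort
    objects$synthetic <- sim
    write_cohort(cohort, file.path(out_dir, "cohort.csv"))
    art[["cohort.csv"]] <- file.path(out_dir, "cohort.csv")
    report <- c(report, "## Simulated cohort",
                sprintf("- %d subjects (%s design), %d cases",
                        nrow(cohort$responses), gen$design,
                        sum(cohort$subjects$diagnosis == 1L, na.rm = TRUE)),
                "")
  } else if (any(c("mokken", "reduce", "score", "validate") %in% stages)) {
    if (is.null(config$cohort_path) || !file.exists(config$cohort_path %||% "")) {
      stop("stage input missing: cohort file not found: ",
           config$cohort_path %||% "<unset>")
    }
    cohort <- load_cohort(config$cohort_path, bank, quiet = TRUE)
  }

  plan <- attr(bank, "default_plan")
  if ("reduce" %in% stages) {
    plan_obj <- optimal_dichotomy(cohort, bank,
                                  items = informant_item_ids())
    plan[names(plan_obj$cuts)] <- plan_obj$cuts
    objects$plan <- plan_obj
    write_json_art(as.list(plan_obj$cuts), "dichotomization_plan.json")
  }

  if ("mokken" %in% stages) {
    mk <- config$mokken
    tabs <- list(); assum <- list()
    for (sc in c("cognitive", "informant")) {
      ids <- bank$item_id[bank$scale == sc]
      km <- key_responses(cohort, items = ids, plan = plan)
      st <- scale_scalability(km)
      tabs[[sc]] <- scalability_table(st, scale = sc)
      mono <- check_monotonicity(km, minvi = mk$minvi, alpha = mk$alpha,
                                 min_group_size = mk$min_group_size)
      nip <- check_nonintersection(km, minvi = mk$minvi, alpha = mk$alpha)
      assum[[sc]] <- rbind(
        cbind(scale = sc, check = "monotonicity", as.data.frame(mono)),
        cbind(scale = sc, check = "non_intersection", as.data.frame(nip)))
      objects[[paste0("mokken_", sc)]] <- st
      report <- c(report, paste0("## Mokken analysis: ", sc, " scale"),
                  sprintf("- whole-scale H = %.3f (%s), n = %d",
                          st$total$H, st$total$band, st$total$n),
                  sprintf("- monotonicity Crit bands: %s",
                          paste(mono$band, collapse = ", ")),
                  sprintf("- non-intersection Crit bands: %s",
                          paste(nip$band, collapse = ", ")), "")
    }
    write_csv_art(do.call(rbind, tabs), "scalability.csv")
    write_csv_art(do.call(rbind, assum), "assumptions.csv")
  }

  if ("reduce" %in% stages) {
    k <- config$selection$k
    sel <- list()
    for (sc in c("cognitive", "informant")) {
      ids <- bank$item_id[bank$scale == sc]
      km <- key_responses(cohort, items = ids, plan = plan)
      st <- objects[[paste0("mokken_", sc)]] %||% scale_scalability(km)
      sel[[sc]] <- select_items(st, bank, k = min(k, length(ids)),
                                h_floor = config$selection$h_floor,
                                epsilon = config$selection$epsilon)
      report <- c(report, paste0("## Item selection: ", sc, " scale"),
                  sprintf("- selected (ascending difficulty): %s",
                          paste(sel[[sc]]$selected, collapse = ", ")),
                  sprintf("- subset whole-scale H = %.3f",
                          sel[[sc]]$subset_H), "")
    }
    objects$selection <- sel
    write_json_art(lapply(sel, function(s) {
      list(selected = s$selected, subset_H = s$subset_H)
    }), "selection.json")
  }

  scores <- NULL
  if ("score" %in% stages) {
    scores <- score_cohort(cohort, plan = plan[informant_item_ids()])
    objects$scores <- scores
    write_csv_art(scores, "scores.csv")
    report <- c(report, "## Brief scores",
                sprintf("- triage: %s",
                        paste(names(table(scores$triage)),
                              table(scores$triage),
                              sep = " = ", collapse = ", ")), "")
  }

  if ("validate" %in% stages) {
    if (is.null(scores)) {
      stop("stage input missing: no scores computed; ",
           "request the 'score' stage or provide scores.csv upstream")
    }
    lab <- cohort$subjects$diagnosis
    if (all(is.na(lab))) stop("validation needs a diagnosis label")
    vd <- config$validation
    rows <- list(); vres <- list()
    specs <- list(cognitive = list(scores$cognitive_total,
                                   "lower_is_positive"),
                  informant = list(scores$informant_total,
                                   "higher_is_positive"),
                  combined = list(scores$combined, "lower_is_positive"))
    for (sc in names(specs)) {
      vr <- validate_scale(specs[[sc]][[1]], lab,
                           direction = specs[[sc]][[2]], scale = sc,
                           severity = cohort$subjects$severity,
                           education = cohort$subjects$education,
                           ci_method = vd$ci_method, delta_j = vd$delta_j)
      vres[[sc]] <- vr
      rows[[sc]] <- data.frame(
        scale = sc, auroc = vr$auroc$auc,
        ci_low = vr$auroc$ci[1], ci_high = vr$auroc$ci[2],
        cutpoint = paste(vr$cutpoints$label, collapse = "/"),
        sensitivity = paste(round(100 * vr$cutpoints$sensitivity, 1),
                            collapse = "/"),
        specificity = paste(round(100 * vr$cutpoints$specificity, 1),
                            collapse = "/"),
        youden = paste(round(vr$cutpoints$youden, 2), collapse = "/"),
        stringsAsFactors = FALSE)
      report <- c(report, paste0("## Validation: ", sc, " scale"),
                  sprintf("- AUROC %.3f (95%% CI %.3f-%.3f)",
                          vr$auroc$auc, vr$auroc$ci[1], vr$auroc$ci[2]),
                  sprintf("- optimal cutpoint(s): %s",
                          paste(vr$cutpoints$label, collapse = " / ")), "")
    }
    objects$validation <- vres
    write_csv_art(do.call(rbind, rows), "validation.csv")
    write_json_art(lapply(vres, function(v) {
      list(scale = v$scale, auroc = v$auroc$auc, ci = v$auroc$ci,
           cutpoints = v$cutpoints, strata = v$strata)
    }), "validation.json")
  }

  writeLines(report, file.path(out_dir, "report.md"))
  art[["report.md"]] <- file.path(out_dir, "report.md")
  invisible(list(objects = objects, artifacts = art))
}
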