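#' Configuration of the synthetic cohort generator
#'
#' Describes the generative world the analysis assumes: a single latent
#' cognitive trait (standard normal in non-cases), dementia cases shifted
#' down by severity-specific offsets, monotone logistic response functions
#' for the cognitive items (common discrimination, locations calibrated to
#' target marginal difficulties), graded never/sometimes/often informant
#' items driven by the negated trait, and an additive education effect
#' (DIF) on cognitive item locations for the low-education stratum.
#'
#' Defaults state the emulated designs once: a population survey of
#' n = 15 022 with 8\% dementia prevalence and 60\% low education, or a
#' pilot case-control design with four groups of 100 (mild cases, moderate
#' cases, high- and low-education controls). Severity offsets -2 (mild) and
#' -3.5 (moderate) trait SDs; education DIF +0.8 on the location scale,
#' sized to reproduce the published low- vs high-education specificity
#' split at the cognitive screening cutpoint;
#' discriminations 1.7 chosen so the brief scales scale strongly
#' (whole-scale H around 0.6-0.7). Item parameters are always calibrated
#' against the population marginals, as a screening instrument's norms are.
#'
#' @param design `"population"` or `"case_control"`.
#' @param n subjects (population design).
#' @param prevalence dementia prevalence in the population design.
#' @param p_moderate probability a case is moderate (CDR 2) rather than
#'   mild (CDR 1).
#' @param group_sizes named integer vector for the case-control design:
#'   `mild`, `moderate`, `control_high_ed`, `control_low_ed`.
#' @param mild_offset,moderate_offset trait shifts for cases (negative;
#'   `mild_offset > moderate_offset`).
#' @param p_low_education probability of the low-education stratum.
#' @param education_dif additive shift of cognitive item locations for
#'   low-education subjects (0 disables the DIF).
#' @param cognitive_targets,informant_targets named target marginal
#'   difficulties in (0,1); defaults are the brief CSI-D development values.
#' @param discrimination_cognitive,discrimination_informant common logistic
#'   slopes.
#' @param recall_threshold_gap spacing of the upper delayed-recall
#'   thresholds above the calibrated first threshold (latent scale).
#' @param informant_threshold_gap spacing between the "sometimes" and
#'   "often" thresholds of informant items.
#' @param noise_sd SD of subject-level measurement noise added to the trait
#'   independently for the cognitive test and the informant interview;
#'   folded into calibration by SD inflation.
#' @param seed integer seed; every source of randomness flows from it.
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(design = c("population", "case_control"),
                             n = 15022L,
                             prevalence = 0.08,
                             p_moderate = 0.5,
                             group_sizes = c(mild = 100L, moderate = 100L,
                                             control_high_ed = 100L,
                                             control_low_ed = 100L),
                             mild_offset = -2.0,
                             moderate_offset = -3.5,
                             p_low_education = 0.6,
                             education_dif = 0.8,
                             cognitive_targets = c(
                               hammer = 0.024, elbow = 0.032, point2 = 0.040,
                               store = 0.059, season = 0.062, dayweek = 0.100,
                               recall3 = 0.283),
                             informant_targets = c(
                               put_things = 0.523, mental_decline = 0.868,
                               think_reason = 0.908,
                               forget_yesterday = 0.913,
                               forget_where = 0.968, dressing = 0.982),
                             discrimination_cognitive = 1.7,
                             discrimination_informant = 1.7,
                             recall_threshold_gap = 0.8,
                             informant_threshold_gap = 1.0,
                             noise_sd = 0,
                             seed = NULL) {
  design <- match.arg(design)
  cfg <- list(design = design, n = as.integer(n), prevalence = prevalence,
              p_moderate = p_moderate, group_sizes = group_sizes,
              mild_offset = mild_offset, moderate_offset = moderate_offset,
              p_low_education = p_low_education,
              education_dif = education_dif,
              cognitive_targets = cognitive_targets,
              informant_targets = informant_targets,
              discrimination_cognitive = discrimination_cognitive,
              discrimination_informant = discrimination_informant,
              recall_threshold_gap = recall_threshold_gap,
              informant_threshold_gap = informant_threshold_gap,
              noise_sd = noise_sd, seed = seed)
  probs <- c(prevalence = prevalence, p_moderate = p_moderate,
             p_low_education = p_low_education)
  if (any(probs <= 0 | probs >= 1)) {
    stop("prevalence, p_moderate and p_low_education must lie in (0, 1)")
  }
  if (!(mild_offset < 0 && moderate_offset < 0 &&
        mild_offset > moderate_offset)) {
    stop("offsets must be negative with mild_offset > moderate_offset")
  }
  if (any(cognitive_targets <= 0 | cognitive_targets >= 1) ||
      any(informant_targets <= 0 | informant_targets >= 1)) {
    stop("target difficulties must lie in (0, 1)")
  }
  if (design == "case_control") {
    need <- c("mild", "moderate", "control_high_ed", "control_low_ed")
    if (!all(need %in% names(group_sizes)) || any(group_sizes[need] < 1L)) {
      stop("group_sizes must name ", paste(need, collapse = ", "),
           ", each >= 1")
    }
  } else if (cfg$n < 2L) stop("population design needs n >= 2")
  class(cfg) <- "generator_config"
  cfg
}

# Mixture components of the latent trait in the population design, on the
# scale relevant for item generation. Education DIF enters as an equivalent
# trait shift (-dif for low education on cognitive items).
trait_components <- function(config, instrument = c("cognitive", "informant")) {
  instrument <- match.arg(instrument)
  sdv <- sqrt(1 + config$noise_sd^2)
  w_case <- config$prevalence
  base <- data.frame(
    weight = c(1 - w_case,
               w_case * (1 - config$p_moderate),
               w_case * config$p_moderate),
    mean = c(0, config$mild_offset, config$moderate_offset),
    sd = sdv
  )
  if (instrument == "informant") {
    base$mean <- -base$mean   # informant items load on impairment = -trait
    return(base)
  }
  if (config$education_dif != 0) {
    lo <- base; hi <- base
    lo$weight <- lo$weight * config$p_low_education
    lo$mean <- lo$mean - config$education_dif
    hi$weight <- hi$weight * (1 - config$p_low_education)
    base <- rbind(lo, hi)
  }
  base
}

marginal_nonkeyed <- function(b, a, comps) {
  tot <- 0
  for (k in seq_len(nrow(comps))) {
    tot <- tot + comps$weight[k] * stats::integrate(
      function(th) {
        (1 - stats::plogis(a * (th - b))) *
          stats::dnorm(th, comps$mean[k], comps$sd[k])
      }, -Inf, Inf, rel.tol = 1e-10)$value
  }
  tot
}

#' Calibrate item locations to target marginal difficulties
#'
#' Solves, per item, for the logistic location parameter `b` such that the
#' model-implied marginal proportion of the non-keyed response under the
#' given trait mixture equals the target difficulty:
#' `E[1 - plogis(a (theta - b))] = target`. One-dimensional root finding;
#' the residual is checked to be below `1e-6`.
#'
#' @param target_difficulties named numeric targets in (0, 1).
#' @param discrimination common logistic slope `a > 0`.
#' @param trait data frame of normal mixture components (`weight`, `mean`,
#'   `sd`) describing the marginal trait distribution.
#' @return Named numeric locations.
#' @examples
#' calibrate_item_locations(c(x = 0.5), 2,
#'                          data.frame(weight = 1, mean = 0, sd = 1))
#' @export
calibrate_item_locations <- function(target_difficulties, discrimination,
                                     trait) {
  stopifnot(is.data.frame(trait),
            all(c("weight", "mean", "sd") %in% names(trait)))
  if (discrimination <= 0) stop("discrimination must be positive")
  if (any(target_difficulties <= 0 | target_difficulties >= 1)) {
    stop("target difficulties must lie in (0, 1)")
  }
  lo <- min(trait$mean) - 40 / discrimination - 10 * max(trait$sd)
  hi <- max(trait$mean) + 40 / discrimination + 10 * max(trait$sd)
  out <- vapply(seq_along(target_difficulties), function(k) {
    tgt <- target_difficulties[[k]]
    f <- function(b) marginal_nonkeyed(b, discrimination, trait) - tgt
    root <- tryCatch(
      stats::uniroot(f, c(lo, hi), tol = 1e-10)$root,
      error = function(e) NA_real_)
    if (is.na(root) || abs(f(root)) >= 1e-6) {
      stop("cannot calibrate item '",
           names(target_difficulties)[k] %||% k,
           "' to target difficulty ", tgt)
    }
    root
  }, numeric(1))
  names(out) <- names(target_difficulties)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic item-parameter set implied by a config.
generator_item_params <- function(config) {
  comps_cog <- trait_components(config, "cognitive")
  comps_inf <- trait_components(config, "informant")
  a_c <- config$discrimination_cognitive
  a_i <- config$discrimination_informant
  b_cog <- calibrate_item_locations(config$cognitive_targets, a_c, comps_cog)
  # delayed recall: 4 graded levels; the first threshold carries the target
  # (keyed iff recalling >= 1 word), the upper two sit gap and 2*gap higher
  recall_b <- c(b_cog[["recall3"]],
                b_cog[["recall3"]] + config$recall_threshold_gap,
                b_cog[["recall3"]] + 2 * config$recall_threshold_gap)
  # informant items: the keyed threshold (per the default plan) carries the
  # target; the other threshold sits gap below/above on the latent scale
  plan <- informant_default_plan()
  c_keyed <- calibrate_item_locations(config$informant_targets, a_i, comps_inf)
  inf_thresholds <- lapply(names(c_keyed), function(id) {
    gap <- config$informant_threshold_gap
    if (plan[[id]] == 2L) c(c_keyed[[id]] - gap, c_keyed[[id]])
    else c(c_keyed[[id]], c_keyed[[id]] + gap)
  })
  names(inf_thresholds) <- names(c_keyed)
  list(a_cognitive = a_c, a_informant = a_i,
       b_binary = b_cog[setdiff(names(b_cog), "recall3")],
       recall_thresholds = recall_b,
       informant_thresholds = inf_thresholds)
}

# Draw graded responses with a single uniform per subject-item:
# level = #{l : u <= P(response >= l)}.
draw_graded <- function(u, eta, a, thresholds) {
  lev <- integer(length(eta))
  for (th in thresholds) {
    lev <- lev + as.integer(u <= stats::plogis(a * (eta - th)))
  }
  lev
}

generate_from_groups <- function(config, group, education, subject_prefix) {
  n <- length(group)
  trait <- stats::rnorm(n) +
    ifelse(group == "mild", config$mild_offset,
           ifelse(group == "moderate", config$moderate_offset, 0))
  noise_cog <- if (config$noise_sd > 0) {
    stats::rnorm(n, 0, config$noise_sd)
  } else numeric(n)
  noise_inf <- if (config$noise_sd > 0) {
    stats::rnorm(n, 0, config$noise_sd)
  } else numeric(n)
  params <- generator_item_params(config)
  bank <- brief_item_bank()
  theta_c <- trait + noise_cog -
    ifelse(education == "low", config$education_dif, 0)
  eta_i <- -(trait + noise_inf)
  resp <- matrix(NA_integer_, n, nrow(bank),
                 dimnames = list(NULL, bank$item_id))
  u <- matrix(stats::runif(n * nrow(bank)), n, nrow(bank),
              dimnames = list(NULL, bank$item_id))
  for (id in names(params$b_binary)) {
    p <- stats::plogis(params$a_cognitive * (theta_c - params$b_binary[[id]]))
    resp[, id] <- as.integer(u[, id] <= p)
  }
  resp[, "recall3"] <- draw_graded(u[, "recall3"], theta_c,
                                   params$a_cognitive,
                                   params$recall_thresholds)
  for (id in names(params$informant_thresholds)) {
    resp[, id] <- draw_graded(u[, id], eta_i, params$a_informant,
                              params$informant_thresholds[[id]])
  }
  is_case <- group %in% c("mild", "moderate")
  co <- cohort_table(
    resp, bank,
    subject_id = paste0(subject_prefix, seq_len(n)),
    diagnosis = as.integer(is_case),
    severity = ifelse(is_case, group, NA_character_),
    education = education,
    region = "synthetic"
  )
  structure(list(cohort = co,
                 truth = list(trait = trait, group = group,
                              education = education, params = params,
                              config = config)),
            class = "synthetic_cohort")
}

#' Generate a synthetic population survey cohort
#'
#' Emulates a single-phase population survey: dementia status drawn at the
#' configured prevalence, severity within cases, an education stratum,
#' a latent trait per subject (standard normal for non-cases, shifted by the
#' severity offset for cases), and brief CSI-D item responses from the
#' calibrated monotone response functions. Identical config and seed give a
#' byte-identical cohort.
#'
#' @param config a [generator_config()] with `design = "population"` and a
#'   `seed`.
#' @return A list of class `"synthetic_cohort"`: `cohort` (a
#'   [cohort_table()]) and `truth` (latent traits, group labels, calibrated
#'   item parameters, the config).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (config$design != "population") stop("config design is not 'population'")
  if (is.null(config$seed)) stop("config must carry a seed")
  if (config$n < 2L) stop("population design needs n >= 2")
  set.seed(config$seed)
  n <- config$n
  # fixed draw order: education, case status, severity, trait, noise, items
  education <- ifelse(stats::runif(n) < config$p_low_education, "low", "high")
  is_case <- stats::runif(n) < config$prevalence
  sev_draw <- stats::runif(n) < config$p_moderate
  group <- ifelse(!is_case, "control",
                  ifelse(sev_draw, "moderate", "mild"))
  generate_from_groups(config, group, education, "p")
}

#' Generate a synthetic pilot case-control cohort
#'
#' Emulates the four-group pilot validation design: mild (CDR 1) and
#' moderate (CDR 2) dementia case groups and two non-case control groups,
#' one high- and one low-education. Cases are assigned education at the
#' population rate; the education DIF applies to every low-education
#' subject's cognitive items.
#'
#' @param config a [generator_config()] with `design = "case_control"` and a
#'   `seed`.
#' @return A `"synthetic_cohort"` as in [generate_population()].
#' @export
generate_case_control <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (config$design != "case_control") {
    stop("config design is not 'case_control'")
  }
  if (is.null(config$seed)) stop("config must carry a seed")
  set.seed(config$seed)
  gs <- config$group_sizes
  group <- rep(c("mild", "moderate", "control", "control"),
               times = gs[c("mild", "moderate", "control_high_ed",
                            "control_low_ed")])
  n_cases <- gs[["mild"]] + gs[["moderate"]]
  education <- c(
    ifelse(stats::runif(n_cases) < config$p_low_education, "low", "high"),
    rep("high", gs[["control_high_ed"]]),
    rep("low", gs[["control_low_ed"]]))
  generate_from_groups(config, group, education, "cc")
}

#' Simulate keyed responses from arbitrary response functions
#'
#' Draws a binary subject-by-item matrix with `P(keyed | theta)` given by
#' caller-supplied item response functions -- the tool for constructing
#' engineered violations (dipping or crossing response functions) that the
#' assumption checks must detect, and deterministic step functions that
#' yield perfect Guttman scales.
#'
#' @param theta numeric latent trait values, one per subject.
#' @param irfs named list of functions `theta -> probability`.
#' @param seed optional integer seed.
#' @return An integer 0/1 matrix, subjects x items.
#' @examples
#' m <- simulate_irf_matrix(rnorm(100),
#'                          list(easy = function(t) plogis(2 * (t + 1)),
#'                               hard = function(t) plogis(2 * (t - 1))),
#'                          seed = 1)
#' @export
simulate_irf_matrix <- function(theta, irfs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(theta)
  out <- matrix(NA_integer_, n, length(irfs),
                dimnames = list(NULL, names(irfs) %||%
                                  paste0("item", seq_along(irfs))))
  for (k in seq_along(irfs)) {
    p <- pmin(1, pmax(0, irfs[[k]](theta)))
    out[, k] <- as.integer(stats::runif(n) <= p)
  }
  out
}

#' Generate an item pool with a planted strongly scalable subset
#'
#' Builds a dichotomous item pool in which a designated subset of items has
#' high discrimination and spread difficulties (a strongly scalable
#' hierarchical core) while the remaining items discriminate weakly --
#' the planted-subset world used to test that hierarchical item selection
#' recovers the scalable core.
#'
#' @param n subjects.
#' @param n_strong,n_weak numbers of planted and filler items.
#' @param a_strong,a_weak logistic discriminations of the two groups.
#' @param seed integer seed.
#' @return A list: `matrix` (0/1 responses, planted items named
#'   `strong1..`, fillers `weak1..`), `item_bank` (distinct domain per
#'   planted item), `planted` (the planted item ids).
#' @export
generate_planted_pool <- function(n = 5000L, n_strong = 6L, n_weak = 20L,
                                  a_strong = 3, a_weak = 0.7, seed) {
  set.seed(seed)
  theta <- stats::rnorm(n)
  b_strong <- seq(-1.6, 1.6, length.out = n_strong)
  b_weak <- seq(-2, 2, length.out = n_weak)
  ids <- c(paste0("strong", seq_len(n_strong)),
           paste0("weak", seq_len(n_weak)))
  irfs <- c(
    lapply(b_strong, function(b) function(t) stats::plogis(a_strong * (t - b))),
    lapply(b_weak, function(b) function(t) stats::plogis(a_weak * (t - b))))
  names(irfs) <- ids
  m <- simulate_irf_matrix(theta, irfs)
  bank <- item_bank(
    item_id = ids, scale = "informant", n_levels = 2L,
    keyed_level_meaning = "symptom_present",
    domain_tag = c(paste0("domain_s", seq_len(n_strong)),
                   paste0("domain_w", seq_len(n_weak)))
  )
  list(matrix = m, item_bank = bank,
       planted = paste0("strong", seq_len(n_strong)))
}
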