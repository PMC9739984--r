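#' Generator default tables
#'
#' The building blocks behind [generator_config()]'s defaults, exported so
#' configurations can start from them and override selectively:
#' `default_class_params()` (per food class: synthetic footprint
#' coefficient medians per kg, caloric density, baseline consumption
#' frequency and amounts, reporting unit, questionnaire/recall reporting
#' probabilities), `default_category_marginals()` (covariate category
#' probabilities matching the reference cohort's composition), and
#' `default_dadk_rates()` (per-item "don't know / didn't answer" rates).
#'
#' @return A tibble (`default_class_params`) or named list/vector.
#' @name generator_defaults
NULL

# Food-class parameter table behind the generator. Coefficient magnitudes
# are synthetic but ordered realistically: the ruminant-meat class carries
# carbon/water/ecological intensities an order of magnitude above the plant
# classes, so animal-source groups dominate the simulated footprints.
# Columns: median coefficient per kg (cf g CO2eq, wf L, ef m2), median kcal
# per 100 g, baseline consumption frequency (occasions/day), median amount
# per occasion (g, or mL for liquid classes), reporting unit, probability a
# respondent reports the group on the PQ, probability a respondent x group
# shows up in the 24HR.
#' @rdname generator_defaults
#' @export
default_class_params <- function() {
  tibble::tribble(
    ~class,          ~cf, ~wf, ~ef, ~kcal, ~freq, ~amount, ~unit, ~pq_p, ~recall_p,
    "ruminant_meat", 30000, 15000, 150, 220, 0.25, 120, "g",  0.80, 0.30,
    "other_meat",     6000,  5000,  60, 180, 0.20, 110, "g",  0.85, 0.35,
    "eggs",           3500,  3000,  25, 150, 0.15,  90, "g",  0.80, 0.25,
    "dairy",          3000,  2500,  20, 120, 0.30, 140, "g",  0.85, 0.40,
    "beverage",        500,   800,   4,  30, 0.40, 180, "mL", 0.90, 0.50,
    "staple",         1500,  1500,  12, 250, 0.30, 150, "g",  0.90, 0.50,
    "fruit_veg",       700,   800,   6,  60, 0.20, 100, "g",  0.85, 0.40,
    "processed",      2500,  2000,  15, 350, 0.08,  80, "g",  0.70, 0.20
  )
}

# Share of the 41 questionnaire groups falling in each class; scaled to any
# n_groups while keeping every class represented when room allows.
default_class_counts <- c(ruminant_meat = 2, other_meat = 3, eggs = 1,
                          dairy = 4, beverage = 4, staple = 8,
                          fruit_veg = 10, processed = 9)

assign_group_classes <- function(n_groups) {
  base <- rep(names(default_class_counts), default_class_counts)
  if (n_groups == length(base)) return(base)
  base[round(seq(1, length(base), length.out = n_groups))]
}

# Category marginals reproducing the reference cohort's composition: counts
# per category normalized over the respondents who answered each item.
#' @rdname generator_defaults
#' @export
default_category_marginals <- function() {
  list(
    sex = c(male = 173, female = 238) / 411,
    age_group = c(adult = 220, elderly = 191) / 411,
    ethnicity = c(white = 145, non_white = 266) / 411,
    schooling = c(`0-5y` = 146, `6-9y` = 62, `10-13y` = 126, `14y+` = 74) / 408,
    income_quintile = c(Q1 = 84, Q2 = 76, Q3 = 81, Q4 = 80, Q5 = 80) / 401,
    fast_food = c(never = 262, sometimes = 117, often = 20) / 399,
    snack_bar = c(never = 230, hardly_ever = 119, weekly = 51) / 400,
    street_fair = c(never = 116, sometimes = 154, often = 129) / 399,
    delivery = c(never = 247, sometimes = 123, often = 29) / 399
  )
}

# "Don't know / didn't answer" rates per covariate, from the survey's
# per-item missingness footnotes.
#' @rdname generator_defaults
#' @export
default_dadk_rates <- function() {
  c(sex = 0, age_group = 0, ethnicity = 0,
    schooling = 3 / 411, income_quintile = 10 / 411,
    fast_food = 12 / 411, snack_bar = 11 / 411,
    street_fair = 12 / 411, delivery = 12 / 411)
}

#' Covariate effects on consumption
#'
#' An effect specification is a tibble with columns `variable` (covariate
#' name), `category`, `class` (food class the effect acts on), and
#' `multiplier` (> 0), applied multiplicatively to both the consumption
#' frequency and the per-occasion amount of every group in the class for
#' respondents in the category.
#'
#' `default_effect_spec()` encodes the study-pattern gradient: men, adults,
#' and richer respondents eat more of the high-footprint (meat) classes.
#' `null_effect_spec()` has no effects (all multipliers 1), and
#' `income_effect_spec(top)` isolates a single income gradient on the meat
#' classes rising to `top` in the highest quintile.
#'
#' @return An effect-spec tibble.
#' @export
default_effect_spec <- function() {
  meat <- c("ruminant_meat", "other_meat")
  dplyr::bind_rows(
    tidyr::expand_grid(variable = "sex", category = "male", class = meat,
                       multiplier = 1.3),
    tidyr::expand_grid(variable = "age_group", category = "adult",
                       class = meat, multiplier = 1.2),
    tibble::tibble(variable = "income_quintile",
                   category = rep(paste0("Q", 1:5), each = length(meat)),
                   class = rep(meat, 5),
                   multiplier = rep(c(1, 1.1, 1.2, 1.35, 1.5),
                                    each = length(meat)))
  )
}

#' @rdname default_effect_spec
#' @export
null_effect_spec <- function() {
  tibble::tibble(variable = character(), category = character(),
                 class = character(), multiplier = numeric())
}

#' @rdname default_effect_spec
#' @param top Multiplier reached in the top quintile (Q1 stays at 1; the
#'   intermediate quintiles interpolate the log-gradient).
#' @export
income_effect_spec <- function(top = 1.5) {
  tibble::tibble(variable = "income_quintile",
                 category = rep(paste0("Q", 1:5), each = 2),
                 class = rep(c("ruminant_meat", "other_meat"), 5),
                 multiplier = rep(exp(seq(0, log(top), length.out = 5)), each = 2))
}

#' Configuration for the synthetic-cohort generator
#'
#' Defaults reproduce the reference study conditions: 411 respondents, 41
#' questionnaire food groups, covariate marginals and per-item missingness
#' from the published cohort table, and the study-pattern consumption
#' effects of [default_effect_spec()].
#'
#' @param n_respondents Cohort size (>= 3).
#' @param n_groups Number of questionnaire food groups (>= 2).
#' @param seed Integer seed; the single source of randomness for all tables.
#' @param category_marginals Named list, variable -> named probability
#'   vector; each must sum to 1 (tolerance 1e-9).
#' @param effect_spec Effect tibble, see [default_effect_spec()].
#' @param class_params Food-class parameter tibble; override rows of
#'   `default_class_params()` to move coefficient ranges.
#' @param dadk_rates Named missingness probabilities per covariate.
#' @param foods_per_group Coefficient-table foods per group.
#' @param freq_sdlog,amount_sdlog,coef_sdlog,kcal_sdlog Log-normal spreads
#'   for individual frequency, per-occasion amount, within-class
#'   coefficients, and within-group caloric density.
#' @return Validated list of class `enf_generator_config`.
#' @export
generator_config <- function(n_respondents = 411L, n_groups = 41L, seed = 1L,
                             category_marginals = default_category_marginals(),
                             effect_spec = default_effect_spec(),
                             class_params = default_class_params(),
                             dadk_rates = default_dadk_rates(),
                             foods_per_group = 3L,
                             freq_sdlog = 0.6, amount_sdlog = 0.35,
                             coef_sdlog = 0.25, kcal_sdlog = 0.2) {
  if (n_respondents < 3L) stop("n_respondents must be >= 3", call. = FALSE)
  if (n_groups < 2L) stop("n_groups must be >= 2", call. = FALSE)
  for (v in names(category_marginals)) {
    p <- category_marginals[[v]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop("marginals for '", v, "' must be non-negative and sum to 1",
           call. = FALSE)
    }
  }
  if (nrow(effect_spec) > 0) {
    if (any(effect_spec$multiplier <= 0)) {
      stop("effect multipliers must be > 0", call. = FALSE)
    }
    bad_var <- setdiff(effect_spec$variable, names(category_marginals))
    if (length(bad_var)) {
      stop("effect on unknown covariate(s): ", paste(bad_var, collapse = ", "),
           call. = FALSE)
    }
    bad_cls <- setdiff(effect_spec$class, class_params$class)
    if (length(bad_cls)) {
      stop("effect on unknown food class(es): ",
           paste(bad_cls, collapse = ", "), call. = FALSE)
    }
  }
  bad_rate <- dadk_rates < 0 | dadk_rates > 1
  if (any(bad_rate)) stop("dadk_rates must lie in [0, 1]", call. = FALSE)
  structure(list(
    n_respondents = as.integer(n_respondents),
    n_groups = as.integer(n_groups), seed = as.integer(seed),
    category_marginals = category_marginals, effect_spec = effect_spec,
    class_params = class_params, dadk_rates = dadk_rates,
    foods_per_group = as.integer(foods_per_group),
    freq_sdlog = freq_sdlog, amount_sdlog = amount_sdlog,
    coef_sdlog = coef_sdlog, kcal_sdlog = kcal_sdlog
  ), class = "enf_generator_config")
}

# Encode a latent daily frequency as the questionnaire's (count, period)
# pair: the finest period whose rounded count lands in 1..10.
encode_frequency <- function(f) {
  count_day <- round(f)
  count_week <- round(f * 7)
  count_month <- round(f * 30)
  count_year <- pmin(10L, pmax(1L, round(f * 365)))
  period <- ifelse(count_day >= 1, "day",
                   ifelse(count_week >= 1, "week",
                          ifelse(count_month >= 1, "month", "year")))
  count <- ifelse(period == "day", pmin(10, count_day),
                  ifelse(period == "week", pmin(10, count_week),
                         ifelse(period == "month", pmin(10, count_month),
                                count_year)))
  list(count = as.integer(count), period = period)
}

#' Generate a complete synthetic study input set
#'
#' Produces, from one seed, every table the pipeline consumes: footprint
#' coefficient table, food-composition table, group registry, covariates,
#' propensity-questionnaire responses, 24-hour recall observations, and a
#' dilution table -- with referential integrity across tables and the
#' configured covariate -> consumption effects baked in. Same config, same
#' seed, byte-identical output.
#'
#' @param config An `enf_generator_config`.
#' @return List of class `enf_cohort` with elements `registry`,
#'   `coefficients`, `composition`, `covariates`, `pq`, `recall`,
#'   `dilution`, `groups` (group -> class map), `effect_spec`, `config`.
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "enf_generator_config"))
  set.seed(config$seed)
  cp <- config$class_params
  n <- config$n_respondents
  g <- config$n_groups

  # --- groups and registry ---------------------------------------------
  classes <- assign_group_classes(g)
  group_id <- sprintf("g%02d", seq_len(g))
  ci <- match(classes, cp$class)
  registry <- food_group_registry(group_id,
                                  paste0(classes, " (", group_id, ")"))
  groups <- tibble::tibble(group_id = group_id, class = classes)

  # --- coefficient table -----------------------------------------------
  fpg <- config$foods_per_group
  food_group <- rep(group_id, each = fpg)
  food_ci <- rep(ci, each = fpg)
  food_id <- paste0(food_group, "_f", rep(seq_len(fpg), g))
  preps_pool <- c("raw", "boiled", "fried", "roasted")
  n_preps <- 1L + stats::rbinom(length(food_id), 1L, 0.5)
  prep1 <- sample(preps_pool, length(food_id), replace = TRUE)
  prep2 <- preps_pool[(match(prep1, preps_pool)) %% 4L + 1L]
  coef_rows <- tibble::tibble(
    food_id = c(food_id, food_id[n_preps == 2L]),
    group_id = c(food_group, food_group[n_preps == 2L]),
    preparation = c(prep1, prep2[n_preps == 2L]),
    class_idx = c(food_ci, food_ci[n_preps == 2L])
  )
  m <- nrow(coef_rows)
  coefficients <- tibble::tibble(
    food_id = coef_rows$food_id,
    group_id = coef_rows$group_id,
    preparation = coef_rows$preparation,
    cf_g_co2eq_per_kg = stats::rlnorm(m, log(cp$cf[coef_rows$class_idx]),
                                      config$coef_sdlog),
    wf_l_per_kg = stats::rlnorm(m, log(cp$wf[coef_rows$class_idx]),
                                config$coef_sdlog),
    ef_m2_per_kg = stats::rlnorm(m, log(cp$ef[coef_rows$class_idx]),
                                 config$coef_sdlog)
  )
  coefficients <- coefficients[order(coefficients$food_id,
                                     coefficients$preparation), ]

  # --- composition table -----------------------------------------------
  composition <- tibble::tibble(
    food_id = food_id, group_id = food_group,
    kcal_per_100g = stats::rlnorm(length(food_id), log(cp$kcal[food_ci]),
                                  config$kcal_sdlog)
  )

  # --- covariates -------------------------------------------------------
  respondent_id <- sprintf("r%04d", seq_len(n))
  covariates <- tibble::tibble(respondent_id = respondent_id)
  for (v in names(config$category_marginals)) {
    p <- config$category_marginals[[v]]
    draw <- sample(names(p), n, replace = TRUE, prob = p)
    rate <- config$dadk_rates[[v]]
    if (!is.null(rate) && !is.na(rate) && rate > 0) {
      draw[stats::runif(n) < rate] <- NA_character_
    }
    covariates[[v]] <- factor(draw, levels = names(p))
  }

  # --- per-respondent x class effect multipliers ------------------------
  mult <- matrix(1, n, nrow(cp), dimnames = list(NULL, cp$class))
  es <- config$effect_spec
  if (nrow(es) > 0) {
    for (k in seq_len(nrow(es))) {
      hit <- !is.na(covariates[[es$variable[k]]]) &
        covariates[[es$variable[k]]] == es$category[k]
      mult[hit, es$class[k]] <- mult[hit, es$class[k]] * es$multiplier[k]
    }
  }

  # --- propensity questionnaire ----------------------------------------
  grid_r <- rep(seq_len(n), times = g)
  grid_g <- rep(seq_len(g), each = n)
  grid_ci <- ci[grid_g]
  participates <- stats::runif(n * g) < cp$pq_p[grid_ci]
  lat_freq <- cp$freq[grid_ci] * mult[cbind(grid_r, grid_ci)] *
    stats::rlnorm(n * g, 0, config$freq_sdlog)
  keep <- which(participates)
  enc <- encode_frequency(lat_freq[keep])
  pq <- tibble::tibble(
    respondent_id = respondent_id[grid_r[keep]],
    group_id = group_id[grid_g[keep]],
    count = enc$count, period = enc$period
  )
  pq <- pq[order(pq$respondent_id, pq$group_id), ]

  # --- 24-hour recall ---------------------------------------------------
  in_recall <- which(stats::runif(n * g) < cp$recall_p[grid_ci])
  rr <- grid_r[in_recall]; rg <- grid_g[in_recall]; rc <- grid_ci[in_recall]
  pick <- sample.int(fpg, length(in_recall), replace = TRUE)
  r_food <- paste0(group_id[rg], "_f", pick)
  # sample one preparation actually present for the food
  food_prep1 <- prep1[match(r_food, food_id)]
  food_prep2 <- prep2[match(r_food, food_id)]
  has2 <- n_preps[match(r_food, food_id)] == 2L
  use2 <- has2 & stats::runif(length(r_food)) < 0.4
  r_prep <- ifelse(use2, food_prep2, food_prep1)
  recall <- tibble::tibble(
    respondent_id = respondent_id[rr],
    food_id = r_food,
    group_id = group_id[rg],
    amount = stats::rlnorm(length(rr), log(cp$amount[rc]),
                           config$amount_sdlog) * mult[cbind(rr, rc)],
    unit = cp$unit[rc],
    preparation = r_prep,
    times = sample(1:3, length(rr), replace = TRUE, prob = c(0.6, 0.3, 0.1))
  )
  recall <- recall[order(recall$respondent_id, recall$food_id,
                         recall$preparation), ]

  # --- dilution rules (group-level, thin liquids at 1 g/mL) -------------
  liquid_groups <- group_id[cp$unit[ci] == "mL"]
  dilution <- tibble::tibble(key = liquid_groups,
                             grams_per_mL = rep(1.0, length(liquid_groups)))

  structure(list(registry = registry, coefficients = coefficients,
                 composition = composition, covariates = covariates,
                 pq = pq, recall = recall, dilution = dilution,
                 groups = groups, effect_spec = es, config = config),
            class = "enf_cohort")
}

#' @export
print.enf_cohort <- function(x, ...) {
  cat("<enf_cohort> ", x$config$n_respondents, " respondents, ",
      x$config$n_groups, " food groups (seed ", x$config$seed, ")\n", sep = "")
  cat("  PQ rows:", nrow(x$pq), " recall rows:", nrow(x$recall),
      " coefficient rows:", nrow(x$coefficients), "\n")
  cat("  effects:", if (nrow(x$effect_spec)) nrow(x$effect_spec) else "none (null)",
      "\n")
  invisible(x)
}

#' Expected qualitative pattern of a generated cohort
#'
#' Reads the effect specification a cohort was generated with and states,
#' per footprint-relevant covariate, which category ordering the analysis
#' should recover (e.g. top income quintile above bottom in median carbon
#' footprint). With a null specification the expectation is "no ordering".
#'
#' @param cohort An `enf_cohort`.
#' @return Tibble `variable`, `expectation`.
#' @export
ground_truth_report <- function(cohort) {
  stopifnot(inherits(cohort, "enf_cohort"))
  es <- cohort$effect_spec
  if (nrow(es) == 0) {
    return(tibble::tibble(variable = "all",
                          expectation = "no ordering (null specification)"))
  }
  hi_classes <- c("ruminant_meat", "other_meat")
  per_var <- split(es, es$variable)
  rows <- lapply(names(per_var), function(v) {
    sub <- per_var[[v]][per_var[[v]]$class %in% hi_classes, ]
    if (nrow(sub) == 0) return(NULL)
    agg <- tapply(sub$multiplier, sub$category, max)
    hi <- names(agg)[which.max(agg)]
    lo_candidates <- setdiff(names(cohort$config$category_marginals[[v]]),
                             names(agg)[agg > 1])
    lo <- if (length(lo_candidates)) lo_candidates[1] else names(agg)[which.min(agg)]
    tibble::tibble(
      variable = v,
      expectation = paste0("median CF/WF/EF higher for '", hi,
                           "' than for '", lo, "'"))
  })
  dplyr::bind_rows(rows)
}

#' Write a cohort's tables as the pipeline's CSV inputs
#'
#' Emits the exact CSV dialects consumed by the loaders, plus the registry
#' as a plain list, into a directory.
#'
#' @param cohort An `enf_cohort`.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort_csvs <- function(cohort, dir) {
  stopifnot(inherits(cohort, "enf_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    coefficients = file.path(dir, "coefficients.csv"),
    composition = file.path(dir, "composition.csv"),
    registry = file.path(dir, "registry.txt"),
    covariates = file.path(dir, "covariates.csv"),
    pq = file.path(dir, "pq.csv"),
    recall = file.path(dir, "recall.csv"),
    dilution = file.path(dir, "dilution.csv")
  )
  readr::write_csv(cohort$coefficients, paths[["coefficients"]])
  readr::write_csv(cohort$composition, paths[["composition"]])
  writeLines(cohort$registry$group_id, paths[["registry"]])
  readr::write_csv(cohort$covariates, paths[["covariates"]])
  readr::write_csv(cohort$pq, paths[["pq"]])
  readr::write_csv(cohort$recall, paths[["recall"]])
  readr::write_csv(cohort$dilution, paths[["dilution"]])
  invisible(paths)
}
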