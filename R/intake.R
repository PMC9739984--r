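#' Read propensity-questionnaire (PQ) responses
#'
#' One row per respondent x food group: how many times (1--10) the group was
#' consumed per day, week, month, or year over the last 12 months. Counts
#' outside 1--10 or unknown period units are validation errors.
#'
#' @param path CSV with columns `respondent_id`, `group_id`, `count`, `period`.
#' @param registry An `enf_registry`; unknown groups are rejected.
#' @return Validated tibble.
#' @export
load_pq <- function(path, registry) {
  if (!file.exists(path)) stop("PQ file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  validate_pq(raw, registry, source = path)
}

#' @rdname load_pq
#' @param table In-memory data frame with the same columns.
#' @param source Label used in error messages.
#' @export
validate_pq <- function(table, registry, source = "PQ table") {
  cols <- c("respondent_id", "group_id", "count", "period")
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols)) {
    stop(source, ": missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(table)[cols]
  cnt <- suppressWarnings(as.numeric(out$count))
  bad <- which(is.na(cnt) | cnt != round(cnt) | cnt < 1 | cnt > 10)
  if (length(bad)) {
    stop(source, ": count must be an integer in 1..10; bad row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out$count <- as.integer(cnt)
  badp <- which(!out$period %in% names(period_divisors))
  if (length(badp)) {
    stop(source, ": period must be one of ",
         paste(names(period_divisors), collapse = "/"), "; bad row(s) ",
         paste(badp, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(unique(out$group_id), registry$group_id)
  if (length(unknown)) {
    stop(source, ": unknown group_id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Read 24-hour recall (24HR) observations
#'
#' One row per observed food: amount consumed (grams or milliliters), the
#' preparation it was consumed in, and the number of times it was observed.
#' Pooled over the cohort, the 24HR supplies per-capita amounts and the
#' raw/prepared mix behind the group-level footprint coefficients.
#'
#' @param path CSV with columns `respondent_id`, `food_id`, `group_id`,
#'   `amount`, `unit`, `preparation`, `times`.
#' @param registry An `enf_registry`.
#' @return Validated tibble.
#' @export
load_recall <- function(path, registry) {
  if (!file.exists(path)) stop("recall file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  validate_recall(raw, registry, source = path)
}

#' @rdname load_recall
#' @param table In-memory data frame with the same columns.
#' @param source Label used in error messages.
#' @export
validate_recall <- function(table, registry, source = "recall table") {
  cols <- c("respondent_id", "food_id", "group_id", "amount", "unit",
            "preparation", "times")
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols)) {
    stop(source, ": missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(table)[cols]
  amt <- suppressWarnings(as.numeric(out$amount))
  bad <- which(is.na(amt) | amt <= 0)
  if (length(bad)) {
    stop(source, ": amount must be a positive number; bad row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out$amount <- amt
  badu <- which(!out$unit %in% c("g", "mL"))
  if (length(badu)) {
    stop(source, ": unit must be 'g' or 'mL'; bad row(s) ",
         paste(badu, collapse = ", "), call. = FALSE)
  }
  tms <- suppressWarnings(as.numeric(out$times))
  badt <- which(is.na(tms) | tms != round(tms) | tms < 1)
  if (length(badt)) {
    stop(source, ": times must be a positive integer; bad row(s) ",
         paste(badt, collapse = ", "), call. = FALSE)
  }
  out$times <- as.integer(tms)
  unknown <- setdiff(unique(out$group_id), registry$group_id)
  if (length(unknown)) {
    stop(source, ": unknown group_id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Read a dilution-rule table
#'
#' Rules converting volumes to masses, keyed by `food_id` or `group_id`
#' (food-level rules take precedence). Thin liquids such as coffee and tea
#' conventionally use 1 g/mL; reconstituted powders need explicit entries.
#'
#' @param path CSV with columns `key`, `grams_per_mL`.
#' @return Validated tibble.
#' @export
load_dilution <- function(path) {
  if (!file.exists(path)) stop("dilution file not found: ", path, call. = FALSE)
  out <- readr::read_csv(path, col_types = readr::cols(
    key = readr::col_character(), grams_per_mL = readr::col_double()))
  if (any(is.na(out$grams_per_mL) | out$grams_per_mL <= 0)) {
    stop(path, ": grams_per_mL must be > 0", call. = FALSE)
  }
  out
}

#' Read an alias map
#'
#' Maps food names as observed in the 24HR onto `food_id`s of the
#' coefficient table, for foods whose recall spelling does not match the
#' footprint database directly.
#'
#' @param path CSV with columns `observed_name`, `food_id`.
#' @return Named character vector (`observed_name -> food_id`).
#' @export
load_alias <- function(path) {
  if (!file.exists(path)) stop("alias file not found: ", path, call. = FALSE)
  tab <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  stats::setNames(tab$food_id, tab$observed_name)
}

#' Convert a consumed volume to mass
#'
#' Applies the dilution rule for the food (falling back to its group). There
#' is never a silent 1:1 assumption: a liquid food with no applicable rule
#' is an error naming the food, so missing rules surface during validation.
#'
#' @param amount_ml Volume in mL.
#' @param food_id,group_id Keys used to look up the rule.
#' @param rules Dilution tibble (see [load_dilution()]).
#' @return Mass in grams.
#' @export
volume_to_mass <- function(amount_ml, food_id, group_id, rules) {
  g_per_ml <- dilution_factor(food_id, group_id, rules)
  if (anyNA(g_per_ml)) {
    miss <- unique(food_id[is.na(g_per_ml)])
    stop("no dilution rule for food(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  amount_ml * g_per_ml
}

# Vectorized rule lookup; food-level keys win over group-level keys.
dilution_factor <- function(food_id, group_id, rules) {
  if (is.null(rules) || nrow(rules) == 0L) return(rep(NA_real_, length(food_id)))
  by_food <- rules$grams_per_mL[match(food_id, rules$key)]
  by_group <- rules$grams_per_mL[match(group_id, rules$key)]
  ifelse(is.na(by_food), by_group, by_food)
}

# Mass in grams for every recall observation (identity for unit == "g").
recall_mass_g <- function(recall, rules) {
  mass <- recall$amount
  is_ml <- recall$unit == "mL"
  if (any(is_ml)) {
    mass[is_ml] <- volume_to_mass(recall$amount[is_ml], recall$food_id[is_ml],
                                  recall$group_id[is_ml], rules)
  }
  mass
}

#' Per-capita amount of one food group
#'
#' The group's amount per consumption occasion, in grams: the mean of the
#' observed mass amounts weighted by the number of times each food was
#' consumed (`estimator = "weighted_mean"`, the default), or alternatively
#' the plain median of the mass amounts (`estimator = "median"`).
#'
#' @param observations Recall tibble rows for a single group.
#' @param rules Dilution tibble for mL -> g conversion.
#' @param estimator `"weighted_mean"` or `"median"`.
#' @return Grams per consumption occasion.
#' @export
group_per_capita <- function(observations, rules = NULL,
                             estimator = c("weighted_mean", "median")) {
  estimator <- match.arg(estimator)
  if (nrow(observations) == 0L) {
    stop("no observations: group must be absent from the profile, not zero",
         call. = FALSE)
  }
  if (length(unique(observations$group_id)) != 1L) {
    stop("observations must all share one group_id", call. = FALSE)
  }
  mass <- recall_mass_g(observations, rules)
  if (estimator == "weighted_mean") {
    stats::weighted.mean(mass, observations$times)
  } else {
    stats::median(mass)
  }
}

#' Consumption-weighted footprint coefficients of one food group
#'
#' Each of the three coefficients is the mean over the observed
#' food/preparation pairs of the group, weighted by the number of times each
#' was consumed in the pooled 24HR. Every observed pair must resolve to a
#' coefficient row, directly or through the alias map.
#'
#' @param observations Recall tibble rows for a single group.
#' @param coefficients Validated coefficient tibble.
#' @param alias Optional named character vector mapping observed food names
#'   to coefficient-table `food_id`s.
#' @return Named numeric vector `c(cf_per_kg, wf_per_kg, ef_per_kg)`.
#' @export
group_coefficients <- function(observations, coefficients, alias = NULL) {
  if (nrow(observations) == 0L) stop("no observations for group", call. = FALSE)
  food <- observations$food_id
  if (!is.null(alias)) {
    mapped <- alias[food]
    food <- ifelse(is.na(mapped), food, mapped)
  }
  idx <- match(paste(food, observations$preparation, sep = "\r"),
               paste(coefficients$food_id, coefficients$preparation, sep = "\r"))
  if (anyNA(idx)) {
    miss <- unique(paste0(observations$food_id[is.na(idx)], " (",
                          observations$preparation[is.na(idx)], ")"))
    stop("unresolved food/preparation(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  w <- observations$times
  c(cf_per_kg = stats::weighted.mean(coefficients$cf_g_co2eq_per_kg[idx], w),
    wf_per_kg = stats::weighted.mean(coefficients$wf_l_per_kg[idx], w),
    ef_per_kg = stats::weighted.mean(coefficients$ef_m2_per_kg[idx], w))
}

#' Build group profiles from pooled 24HR data
#'
#' For every food group with at least one recall observation, derives the
#' per-capita amount per occasion ([group_per_capita()]), the
#' consumption-weighted footprint coefficients ([group_coefficients()]) and
#' the group's mean caloric density ([group_mean_kcal()]). Groups that were
#' never observed are absent from the result (not imputed as zero).
#'
#' @param recall Validated recall tibble (pooled over the cohort).
#' @param coefficients Validated coefficient tibble.
#' @param composition Validated composition tibble.
#' @param rules Optional dilution tibble.
#' @param alias Optional alias map.
#' @param estimator Per-capita estimator, see [group_per_capita()].
#' @return Tibble with columns `group_id`, `per_capita_g`, `cf_per_kg`,
#'   `wf_per_kg`, `ef_per_kg`, `kcal_per_100g`.
#' @export
build_group_profiles <- function(recall, coefficients, composition,
                                 rules = NULL, alias = NULL,
                                 estimator = c("weighted_mean", "median")) {
  estimator <- match.arg(estimator)
  mass <- recall_mass_g(recall, rules)
  food <- recall$food_id
  if (!is.null(alias)) {
    mapped <- alias[food]
    food <- ifelse(is.na(mapped), food, mapped)
  }
  idx <- match(paste(food, recall$preparation, sep = "\r"),
               paste(coefficients$food_id, coefficients$preparation, sep = "\r"))
  if (anyNA(idx)) {
    miss <- unique(paste0(recall$food_id[is.na(idx)], " (",
                          recall$preparation[is.na(idx)], ")"))
    stop("unresolved food/preparation(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  g <- factor(recall$group_id)
  w <- recall$times
  wsum <- as.vector(rowsum(w, g))
  per_capita <- if (estimator == "weighted_mean") {
    as.vector(rowsum(mass * w, g)) / wsum
  } else {
    as.vector(tapply(mass, g, stats::median))
  }
  wmean_by_group <- function(v) as.vector(rowsum(v * w, g)) / wsum
  gids <- levels(g)
  kcal <- vapply(gids, function(gg) group_mean_kcal(composition, gg), numeric(1))
  tibble::tibble(
    group_id = gids,
    per_capita_g = per_capita,
    cf_per_kg = wmean_by_group(coefficients$cf_g_co2eq_per_kg[idx]),
    wf_per_kg = wmean_by_group(coefficients$wf_l_per_kg[idx]),
    ef_per_kg = wmean_by_group(coefficients$ef_m2_per_kg[idx]),
    kcal_per_100g = unname(kcal)
  )
}
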