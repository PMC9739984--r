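# Period divisors converting questionnaire frequency reports to occurrences
# per day: yearly counts / 365, monthly / 30, weekly / 7, daily / 1.
period_divisors <- c(day = 1, week = 7, month = 30, year = 365)

#' Daily consumption frequency from a questionnaire report
#'
#' @param count Times consumed (integer, >= 1), vectorized.
#' @param period One of `"day"`, `"week"`, `"month"`, `"year"`, vectorized.
#' @return Occurrences per day.
#' @export
#' @examples
#' daily_frequency(3, "week") # 3/7
daily_frequency <- function(count, period) {
  if (any(count < 1)) stop("count must be >= 1", call. = FALSE)
  div <- period_divisors[period]
  if (anyNA(div)) {
    stop("unknown period(s): ",
         paste(unique(period[is.na(div)]), collapse = ", "), call. = FALSE)
  }
  unname(count / div)
}

#' Estimated food consumption (EFC)
#'
#' Daily consumption frequency times the per-capita amount per occasion,
#' converted from grams to kilograms: `EFC = freq x per_capita_g / 1000`,
#' in kg/day.
#'
#' @param daily_freq Occurrences per day (>= 0).
#' @param per_capita_g Grams per occasion (>= 0).
#' @return kg/day.
#' @export
efc <- function(daily_freq, per_capita_g) {
  if (any(daily_freq < 0) || any(per_capita_g < 0)) {
    stop("efc inputs must be non-negative", call. = FALSE)
  }
  daily_freq * per_capita_g / 1000
}

#' Final footprint of one individual
#'
#' Sums, over the food groups the individual consumed, EFC (kg/day) times
#' the group's footprint coefficient for the selected footprint kind:
#' carbon (g CO2eq/day), water (L/day), or ecological (m2/day).
#'
#' @param efc_by_group Named numeric vector, `group_id -> kg/day`.
#' @param profiles Group-profile tibble (see [build_group_profiles()]).
#' @param which `"CF"`, `"WF"`, or `"EF"`.
#' @return List with `total` (scalar) and `addends` (named per-group vector
#'   summing to `total`).
#' @export
individual_footprint <- function(efc_by_group, profiles, which = c("CF", "WF", "EF")) {
  which <- match.arg(which)
  if (length(efc_by_group) == 0L) {
    return(list(total = 0, addends = stats::setNames(numeric(0), character(0))))
  }
  if (any(efc_by_group < 0)) stop("EFC values must be >= 0", call. = FALSE)
  idx <- match(names(efc_by_group), profiles$group_id)
  if (anyNA(idx)) {
    stop("no profile for group(s): ",
         paste(names(efc_by_group)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  coef_col <- c(CF = "cf_per_kg", WF = "wf_per_kg", EF = "ef_per_kg")[[which]]
  addends <- efc_by_group * profiles[[coef_col]][idx]
  list(total = sum(addends), addends = addends)
}

#' Estimated daily energy intake
#'
#' Sums EFC (kg/day) times the group's mean caloric density. Caloric
#' densities are per 100 g, so a kilogram contributes ten 100-g portions:
#' `Ekcal = sum(EFC_i * 10 * kcal_per_100g_i)`, in kcal/day.
#'
#' @inheritParams individual_footprint
#' @return kcal/day.
#' @export
energy_intake <- function(efc_by_group, profiles) {
  if (length(efc_by_group) == 0L) return(0)
  idx <- match(names(efc_by_group), profiles$group_id)
  if (anyNA(idx)) {
    stop("no kcal profile for group(s): ",
         paste(names(efc_by_group)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  sum(efc_by_group * 10 * profiles$kcal_per_100g[idx])
}

#' Standardize a footprint to 1000 kcal
#'
#' `EEF = total * 1000 / Ekcal`. Respondents with non-positive estimated
#' energy have no defined adjusted value; callers flag and exclude them
#' (with a logged count) rather than dividing by zero.
#'
#' @param total Footprint per day.
#' @param energy_kcal Estimated energy intake, kcal/day (> 0).
#' @return Footprint per 1000 kcal.
#' @export
adjust_per_1000kcal <- function(total, energy_kcal) {
  if (any(energy_kcal <= 0)) {
    stop("energy must be > 0 to standardize; flag and exclude the respondent",
         call. = FALSE)
  }
  total * 1000 / energy_kcal
}

#' Compute per-respondent footprints for a cohort
#'
#' Vectorized cohort-level driver for the equation chain: PQ reports are
#' converted to daily frequencies, multiplied by the group per-capita
#' amounts into EFC (kg/day), multiplied by the weighted group coefficients
#' and summed into carbon/water/ecological totals per day, and standardized
#' to 1000 kcal of estimated intake. Respondents whose estimated energy is
#' not positive keep their raw totals but get `NA` adjusted values; their
#' count is recorded in the `exclusions` attribute.
#'
#' @param pq Validated PQ tibble.
#' @param profiles Group-profile tibble (see [build_group_profiles()]).
#' @param on_missing_profile `"error"` (default): a PQ group with no profile
#'   is an error naming the group; `"drop"`: such rows are excluded with a
#'   logged count (the pooled-24HR policy used by [run_pipeline()]).
#' @return List of class `enf_footprints`:
#'   * `footprints`: tibble `respondent_id`, `cf_total`, `wf_total`,
#'     `ef_total`, `energy_kcal`, `cf_1000`, `wf_1000`, `ef_1000`;
#'   * `addends`: long tibble `respondent_id`, `group_id`, `efc_kg_day`,
#'     `cf`, `wf`, `ef`, `kcal` (the per-group decomposition);
#'   * attribute `exclusions`: named counts of dropped PQ rows and
#'     zero-energy respondents.
#' @export
compute_footprints <- function(pq, profiles,
                               on_missing_profile = c("error", "drop")) {
  on_missing_profile <- match.arg(on_missing_profile)
  respondents <- unique(pq$respondent_id)
  idx <- match(pq$group_id, profiles$group_id)
  dropped_rows <- 0L
  if (anyNA(idx)) {
    if (on_missing_profile == "error") {
      stop("no profile for group(s): ",
           paste(unique(pq$group_id[is.na(idx)]), collapse = ", "),
           call. = FALSE)
    }
    keep <- !is.na(idx)
    dropped_rows <- sum(!keep)
    pq <- pq[keep, ]
    idx <- idx[keep]
  }
  freq <- daily_frequency(pq$count, pq$period)
  efc_kg <- efc(freq, profiles$per_capita_g[idx])
  addends <- tibble::tibble(
    respondent_id = pq$respondent_id,
    group_id = pq$group_id,
    efc_kg_day = efc_kg,
    cf = efc_kg * profiles$cf_per_kg[idx],
    wf = efc_kg * profiles$wf_per_kg[idx],
    ef = efc_kg * profiles$ef_per_kg[idx],
    kcal = efc_kg * 10 * profiles$kcal_per_100g[idx]
  )
  r <- factor(addends$respondent_id, levels = respondents)
  present <- rowsum(as.matrix(addends[c("cf", "wf", "ef", "kcal")]), r)
  # respondents whose every PQ row was dropped still appear, with zeros
  sums <- matrix(0, length(respondents), 4,
                 dimnames = list(respondents, colnames(present)))
  sums[rownames(present), ] <- present
  out <- tibble::tibble(
    respondent_id = respondents,
    cf_total = unname(sums[, "cf"]),
    wf_total = unname(sums[, "wf"]),
    ef_total = unname(sums[, "ef"]),
    energy_kcal = unname(sums[, "kcal"])
  )
  ok <- out$energy_kcal > 0
  out$cf_1000 <- ifelse(ok, out$cf_total * 1000 / out$energy_kcal, NA_real_)
  out$wf_1000 <- ifelse(ok, out$wf_total * 1000 / out$energy_kcal, NA_real_)
  out$ef_1000 <- ifelse(ok, out$ef_total * 1000 / out$energy_kcal, NA_real_)
  res <- list(footprints = out, addends = addends)
  attr(res, "exclusions") <- c(pq_rows_without_profile = dropped_rows,
                               zero_energy_respondents = sum(!ok))
  class(res) <- "enf_footprints"
  res
}

#' @export
print.enf_footprints <- function(x, ...) {
  n <- nrow(x$footprints)
  cat("<enf_footprints> ", n, " respondents, ",
      length(unique(x$addends$group_id)), " food groups\n", sep = "")
  excl <- attr(x, "exclusions")
  if (any(excl > 0)) {
    cat("exclusions:", paste(names(excl), excl, sep = "=", collapse = ", "), "\n")
  }
  print(x$footprints, ...)
  invisible(x)
}
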