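#' Food-group registry
#'
#' The propensity questionnaire (PQ) records consumption frequency for a
#' fixed, ordered list of food groups (41 in the reference study design).
#' The registry carries that list and is used to validate every other input
#' table: coefficient rows, composition rows, and intake records whose
#' `group_id` is not registered are rejected rather than silently kept.
#'
#' @param group_ids Character vector of unique group identifiers, in
#'   questionnaire order.
#' @param display_names Optional character vector of human-readable names,
#'   same length as `group_ids`. Defaults to the ids themselves.
#'
#' @return A tibble of class `enf_registry` with columns `group_id` and
#'   `display_name`, one row per questionnaire group.
#' @export
#' @examples
#' food_group_registry(c("beef", "poultry", "fruit"))
food_group_registry <- function(group_ids, display_names = group_ids) {
  group_ids <- as.character(group_ids)
  if (length(group_ids) == 0L) {
    stop("registry must contain at least one food group", call. = FALSE)
  }
  if (anyDuplicated(group_ids)) {
    stop("registry group_ids must be unique", call. = FALSE)
  }
  if (any(!nzchar(group_ids))) {
    stop("registry group_ids must be non-empty strings", call. = FALSE)
  }
  if (length(display_names) != length(group_ids)) {
    stop("display_names must match group_ids in length", call. = FALSE)
  }
  out <- tibble::tibble(group_id = group_ids,
                        display_name = as.character(display_names))
  class(out) <- c("enf_registry", class(out))
  out
}

#' Read a registry from a plain-text or YAML file
#'
#' Accepts either one group id per line, or a YAML list.
#'
#' @param path Path to the registry file.
#' @return An `enf_registry` tibble (see [food_group_registry()]).
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    ids <- unlist(yaml::read_yaml(path), use.names = FALSE)
  } else {
    ids <- readLines(path, warn = FALSE)
    ids <- trimws(ids)
    ids <- ids[nzchar(ids)]
  }
  food_group_registry(ids)
}

coefficient_cols <- c("food_id", "group_id", "preparation",
                      "cf_g_co2eq_per_kg", "wf_l_per_kg", "ef_m2_per_kg")

#' Load and validate a footprint-coefficient table
#'
#' The coefficient table holds life-cycle assessment (LCA, farm-to-fork)
#' footprint values per kilogram of each food/preparation: carbon
#' (g CO2eq/kg), water (L/kg) and ecological (m2/kg). Each
#' `(food_id, preparation)` pair must be unique, coefficients must be
#' non-negative numbers, and every `group_id` must be present in the
#' registry; violations are reported with the offending row numbers rather
#' than dropped silently, because coefficient tables are curated inputs.
#'
#' @param path CSV file with columns `food_id`, `group_id`, `preparation`,
#'   `cf_g_co2eq_per_kg`, `wf_l_per_kg`, `ef_m2_per_kg`.
#' @param registry An `enf_registry`; rows whose `group_id` is absent are
#'   rejected with an error listing the unknown groups.
#' @return A validated tibble of coefficients.
#' @export
load_coefficients <- function(path, registry) {
  if (!file.exists(path)) stop("coefficient file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  validate_coefficients(raw, registry, source = path)
}

#' @rdname load_coefficients
#' @param table A data frame already in memory, same columns as the CSV.
#' @param source Label used in error messages.
#' @export
validate_coefficients <- function(table, registry, source = "coefficient table") {
  missing_cols <- setdiff(coefficient_cols, names(table))
  if (length(missing_cols)) {
    stop(source, ": missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(table)[coefficient_cols]
  num_cols <- c("cf_g_co2eq_per_kg", "wf_l_per_kg", "ef_m2_per_kg")
  for (col in num_cols) {
    vals <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(vals) & !is.na(out[[col]]))
    if (length(bad)) {
      stop(source, ": non-numeric ", col, " at row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    neg <- which(vals < 0)
    if (length(neg)) {
      stop(source, ": negative ", col, " at row(s) ",
           paste(neg, collapse = ", "), call. = FALSE)
    }
    if (anyNA(vals)) {
      stop(source, ": missing ", col, " at row(s) ",
           paste(which(is.na(vals)), collapse = ", "), call. = FALSE)
    }
    out[[col]] <- vals
  }
  if (any(!nzchar(out$group_id) | is.na(out$group_id))) {
    stop(source, ": empty group_id at row(s) ",
         paste(which(!nzchar(out$group_id) | is.na(out$group_id)), collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(unique(out$group_id), registry$group_id)
  if (length(unknown)) {
    rows <- which(out$group_id %in% unknown)
    stop(source, ": unknown group_id(s) not in registry: ",
         paste(unknown, collapse = ", "),
         " (row(s) ", paste(rows, collapse = ", "), ")", call. = FALSE)
  }
  key <- paste(out$food_id, out$preparation, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop(source, ": duplicate (food_id, preparation) at row(s) ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  out
}

#' Write a coefficient table to CSV
#'
#' Inverse of [load_coefficients()]; `load_coefficients(write_coefficients(x))`
#' round-trips valid tables.
#'
#' @param table Validated coefficient tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_coefficients <- function(table, path) {
  readr::write_csv(table[coefficient_cols], path)
  invisible(path)
}

#' Load a food-composition (energy) table
#'
#' Energy density per food, in kcal per 100 g of edible portion, used for
#' the per-group caloric means that drive the 1000-kcal standardization.
#'
#' @param path CSV with columns `food_id`, `group_id`, `kcal_per_100g`.
#' @param registry An `enf_registry`.
#' @return A validated tibble.
#' @export
load_composition <- function(path, registry) {
  if (!file.exists(path)) stop("composition file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  validate_composition(raw, registry, source = path)
}

#' @rdname load_composition
#' @param table In-memory data frame with the same columns.
#' @param source Label used in error messages.
#' @export
validate_composition <- function(table, registry, source = "composition table") {
  cols <- c("food_id", "group_id", "kcal_per_100g")
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols)) {
    stop(source, ": missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(table)[cols]
  vals <- suppressWarnings(as.numeric(out$kcal_per_100g))
  bad <- which((is.na(vals) & !is.na(out$kcal_per_100g)) | vals < 0)
  if (length(bad) || anyNA(vals)) {
    stop(source, ": invalid kcal_per_100g at row(s) ",
         paste(union(bad, which(is.na(vals))), collapse = ", "), call. = FALSE)
  }
  out$kcal_per_100g <- vals
  unknown <- setdiff(unique(out$group_id), registry$group_id)
  if (length(unknown)) {
    stop(source, ": unknown group_id(s) not in registry: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  out
}

#' Mean caloric density of a food group
#'
#' The unweighted arithmetic mean of `kcal_per_100g` over every composition
#' entry belonging to the group -- all foods in the composition table that
#' fit the group count equally, with no consumption weighting.
#'
#' @param entries Composition tibble (see [load_composition()]).
#' @param group_id Group to average over.
#' @return Mean kcal per 100 g (a scalar).
#' @export
#' @examples
#' comp <- tibble::tibble(food_id = c("a", "b", "c"), group_id = "g",
#'                        kcal_per_100g = c(100, 200, 300))
#' group_mean_kcal(comp, "g") # 200
group_mean_kcal <- function(entries, group_id) {
  vals <- entries$kcal_per_100g[entries$group_id == group_id]
  if (length(vals) == 0L) {
    stop("no composition entries for group '", group_id,
         "'; refusing to impute 0 kcal", call. = FALSE)
  }
  mean(vals)
}
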