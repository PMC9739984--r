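#' Run configuration for the end-to-end pipeline
#'
#' Bundles the input paths and analysis options of a full run. Paths are
#' checked for existence up front; `alpha` must lie strictly in (0, 1).
#'
#' @param coefficients,composition,registry,pq,recall,covariates Input file
#'   paths (required).
#' @param dilution,alias Optional input file paths.
#' @param out_dir Output directory, created if missing.
#' @param alpha Significance level for tests and verdicts.
#' @param per_capita_mode `"pooled"` (per-capita amounts from the cohort's
#'   pooled 24HR, the default) or `"individual"` (a respondent's own recall
#'   amounts where available, pooled fallback otherwise).
#' @param tertile_basis `"adjusted"` (per-1000-kcal values, default) or
#'   `"raw"` (unadjusted daily totals).
#' @return Validated list of class `enf_run_config`.
#' @export
run_config <- function(coefficients, composition, registry, pq, recall,
                       covariates, dilution = NULL, alias = NULL,
                       out_dir = "enf_output", alpha = 0.05,
                       per_capita_mode = c("pooled", "individual"),
                       tertile_basis = c("adjusted", "raw")) {
  per_capita_mode <- match.arg(per_capita_mode)
  tertile_basis <- match.arg(tertile_basis)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly between 0 and 1", call. = FALSE)
  }
  paths <- list(coefficients = coefficients, composition = composition,
                registry = registry, pq = pq, recall = recall,
                covariates = covariates, dilution = dilution, alias = alias)
  for (nm in names(paths)) {
    p <- paths[[nm]]
    if (!is.null(p) && !file.exists(p)) {
      stop("input '", nm, "' not found: ", p, call. = FALSE)
    }
  }
  structure(c(paths, list(out_dir = out_dir, alpha = alpha,
                          per_capita_mode = per_capita_mode,
                          tertile_basis = tertile_basis)),
            class = "enf_run_config")
}

#' Read covariates from CSV
#'
#' Empty cells and the literal markers `DA/DK`, `NA` are treated as missing.
#'
#' @param path CSV with `respondent_id` plus one column per variable.
#' @return Tibble with character covariate columns.
#' @export
load_covariates <- function(path) {
  if (!file.exists(path)) stop("covariate file not found: ", path, call. = FALSE)
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                  na = c("", "NA", "DA/DK"))
}

#' Full in-memory analysis of a cohort
#'
#' The analysis chain on already-loaded tables: group profiles from the
#' pooled 24HR, per-respondent footprints, tertiles per footprint kind,
#' contribution decompositions, the stratified comparison table, and a
#' correspondence analysis with verdict per covariate x footprint kind.
#'
#' @param cohort An `enf_cohort`, or any list with elements `registry`,
#'   `coefficients`, `composition`, `covariates`, `pq`, `recall` and
#'   optionally `dilution`, `alias`.
#' @param alpha Significance level.
#' @param per_capita_mode,tertile_basis See [run_config()].
#' @param estimator Per-capita estimator, see [group_per_capita()].
#' @return List of class `enf_analysis` with elements `profiles`,
#'   `footprints` (an `enf_footprints`), `tertiles` (list CF/WF/EF),
#'   `contributions` (long tibble), `comparison` (Table-style tibble),
#'   `ca` (per variable: list of per-kind `enf_ca` + verdict),
#'   `summary` (medians/IQRs), `exclusions` (named counts).
#' @export
analyze_cohort <- function(cohort, alpha = 0.05,
                           per_capita_mode = c("pooled", "individual"),
                           tertile_basis = c("adjusted", "raw"),
                           estimator = c("weighted_mean", "median")) {
  per_capita_mode <- match.arg(per_capita_mode)
  tertile_basis <- match.arg(tertile_basis)
  estimator <- match.arg(estimator)

  profiles <- build_group_profiles(cohort$recall, cohort$coefficients,
                                   cohort$composition, cohort$dilution,
                                   cohort$alias, estimator)
  fp <- if (per_capita_mode == "pooled") {
    compute_footprints(cohort$pq, profiles, on_missing_profile = "drop")
  } else {
    compute_footprints_individual(cohort, profiles)
  }
  foot <- fp$footprints

  kinds <- c(CF = "cf", WF = "wf", EF = "ef")
  basis_cols <- if (tertile_basis == "adjusted") {
    c(CF = "cf_1000", WF = "wf_1000", EF = "ef_1000")
  } else {
    c(CF = "cf_total", WF = "wf_total", EF = "ef_total")
  }
  defined <- !is.na(foot[[basis_cols[["CF"]]]])
  tertiles <- lapply(names(kinds), function(kind) {
    v <- foot[[basis_cols[[kind]]]][defined]
    assign_tertiles(v, foot$respondent_id[defined])
  })
  names(tertiles) <- names(kinds)

  contributions <- dplyr::bind_rows(lapply(names(kinds), function(kind) {
    contribution_table(fp$addends, tertiles[[kind]], kind)
  }))

  comparison <- footprint_comparison_table(foot, cohort$covariates,
                                           alpha = alpha)

  vars <- setdiff(names(cohort$covariates), "respondent_id")
  ca_results <- lapply(vars, function(v) {
    per_kind <- lapply(names(kinds), function(kind) {
      tab <- build_ca_table(tertiles[[kind]], cohort$covariates, v)
      res <- correspondence(tab, alpha = alpha)
      list(table = tab, ca = res,
           verdict = association_verdict(res, alpha = alpha))
    })
    names(per_kind) <- names(kinds)
    per_kind
  })
  names(ca_results) <- vars

  summarise_one <- function(x) {
    x <- x[!is.na(x)]
    q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
    list(median = stats::median(x), mean = mean(x),
         p25 = q[1], p75 = q[2], min = min(x), max = max(x))
  }
  summary <- list(
    n_respondents = nrow(foot),
    n_adjusted = sum(defined),
    cf = list(total = summarise_one(foot$cf_total),
              per_1000kcal = summarise_one(foot$cf_1000)),
    wf = list(total = summarise_one(foot$wf_total),
              per_1000kcal = summarise_one(foot$wf_1000)),
    ef = list(total = summarise_one(foot$ef_total),
              per_1000kcal = summarise_one(foot$ef_1000)),
    energy_kcal = summarise_one(foot$energy_kcal),
    tertile_medians = lapply(tertiles, function(tt) {
      vals <- stats::setNames(tt$value, tt$respondent_id)
      lapply(split(tt$respondent_id, tt$label), function(mem) {
        stratum_median(vals, mem)
      })
    })
  )

  exclusions <- c(attr(fp, "exclusions"),
                  comparison_dadk = sum(attr(comparison, "exclusions")))

  structure(list(profiles = profiles, footprints = fp, tertiles = tertiles,
                 contributions = contributions, comparison = comparison,
                 ca = ca_results, summary = summary, exclusions = exclusions),
            class = "enf_analysis")
}

# Individual per-capita mode: respondents with their own recall rows for a
# group use their personal per-capita amount; everyone else falls back to
# the pooled profile. Coefficients and kcal stay pooled (they describe the
# group's raw/prepared mix, not a person).
compute_footprints_individual <- function(cohort, profiles) {
  mass <- recall_mass_g(cohort$recall, cohort$dilution)
  key <- paste(cohort$recall$respondent_id, cohort$recall$group_id, sep = "\r")
  w <- cohort$recall$times
  per_key <- rowsum(mass * w, key) / rowsum(w, key)
  pq <- cohort$pq
  own <- per_key[match(paste(pq$respondent_id, pq$group_id, sep = "\r"),
                       rownames(per_key)), 1]
  pooled <- profiles$per_capita_g[match(pq$group_id, profiles$group_id)]
  pc <- ifelse(is.na(own), pooled, own)
  # reuse the pooled driver with per-row per-capita via a temporary profile
  idx <- match(pq$group_id, profiles$group_id)
  keep <- !is.na(idx)
  dropped <- sum(!keep)
  pq <- pq[keep, ]; idx <- idx[keep]; pc <- pc[keep]
  freq <- daily_frequency(pq$count, pq$period)
  efc_kg <- efc(freq, pc)
  addends <- tibble::tibble(
    respondent_id = pq$respondent_id, group_id = pq$group_id,
    efc_kg_day = efc_kg,
    cf = efc_kg * profiles$cf_per_kg[idx],
    wf = efc_kg * profiles$wf_per_kg[idx],
    ef = efc_kg * profiles$ef_per_kg[idx],
    kcal = efc_kg * 10 * profiles$kcal_per_100g[idx]
  )
  respondents <- unique(cohort$pq$respondent_id)
  r <- factor(addends$respondent_id, levels = respondents)
  present <- rowsum(as.matrix(addends[c("cf", "wf", "ef", "kcal")]), r)
  sums <- matrix(0, length(respondents), 4,
                 dimnames = list(respondents, colnames(present)))
  sums[rownames(present), ] <- present
  out <- tibble::tibble(
    respondent_id = respondents,
    cf_total = unname(sums[, "cf"]), wf_total = unname(sums[, "wf"]),
    ef_total = unname(sums[, "ef"]), energy_kcal = unname(sums[, "kcal"])
  )
  ok <- out$energy_kcal > 0
  out$cf_1000 <- ifelse(ok, out$cf_total * 1000 / out$energy_kcal, NA_real_)
  out$wf_1000 <- ifelse(ok, out$wf_total * 1000 / out$energy_kcal, NA_real_)
  out$ef_1000 <- ifelse(ok, out$ef_total * 1000 / out$energy_kcal, NA_real_)
  res <- list(footprints = out, addends = addends)
  attr(res, "exclusions") <- c(pq_rows_without_profile = dropped,
                               zero_energy_respondents = sum(!ok))
  class(res) <- "enf_footprints"
  res
}

#' Run the full pipeline from files
#'
#' Loads and validates every input, runs [analyze_cohort()], and writes the
#' result set to `config$out_dir`: per-respondent footprints, per-group
#' addends, tertile assignments, contribution tables, the stratified
#' comparison table, correspondence-analysis coordinates and verdicts, a
#' machine-readable summary, and an exclusion log. A failure in any stage
#' aborts with a stage-named message and removes partial outputs. Outputs
#' carry no timestamps, so re-running on identical inputs reproduces them
#' byte for byte.
#'
#' @param config An `enf_run_config`.
#' @return The `enf_analysis`, invisibly, with attribute `files` (paths
#'   written).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "enf_run_config"))
  written <- character(0)
  fail <- function(stage, e) {
    unlink(written)
    stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) fail(name, e))
  }

  registry <- stage("foodb", read_registry(config$registry))
  coefficients <- stage("foodb", load_coefficients(config$coefficients, registry))
  composition <- stage("foodb", load_composition(config$composition, registry))
  pq <- stage("intake", load_pq(config$pq, registry))
  recall <- stage("intake", load_recall(config$recall, registry))
  dilution <- if (!is.null(config$dilution)) {
    stage("intake", load_dilution(config$dilution))
  }
  alias <- if (!is.null(config$alias)) stage("intake", load_alias(config$alias))
  covariates <- stage("covariates", load_covariates(config$covariates))

  cohort <- list(registry = registry, coefficients = coefficients,
                 composition = composition, pq = pq, recall = recall,
                 dilution = dilution, alias = alias, covariates = covariates)
  analysis <- stage("analysis",
                    analyze_cohort(cohort, alpha = config$alpha,
                                   per_capita_mode = config$per_capita_mode,
                                   tertile_basis = config$tertile_basis))

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) {
    p <- file.path(config$out_dir, name)
    written <<- c(written, p)
    p
  }
  stage("report", {
    readr::write_csv(analysis$footprints$footprints, out("footprints.csv"))
    readr::write_csv(analysis$footprints$addends, out("addends.csv"))
    tert <- dplyr::bind_rows(lapply(names(analysis$tertiles), function(kind) {
      tibble::add_column(analysis$tertiles[[kind]], footprint_kind = kind,
                         .before = 1)
    }))
    readr::write_csv(tert, out("tertiles.csv"))
    readr::write_csv(analysis$contributions, out("contributions.csv"))
    readr::write_csv(analysis$comparison, out("comparison_table.csv"))
    coords <- dplyr::bind_rows(lapply(names(analysis$ca), function(v) {
      dplyr::bind_rows(lapply(names(analysis$ca[[v]]), function(kind) {
        res <- analysis$ca[[v]][[kind]]$ca
        share <- res$principal_inertias / max(res$total_inertia,
                                              .Machine$double.eps)
        rbind(
          tibble::tibble(variable = v, footprint_kind = kind, type = "row",
                         label = rownames(res$row_coords),
                         dim1 = res$row_coords[, 1],
                         dim2 = if (ncol(res$row_coords) > 1)
                           res$row_coords[, 2] else 0,
                         inertia_share_dim1 = share[1]),
          tibble::tibble(variable = v, footprint_kind = kind, type = "col",
                         label = rownames(res$col_coords),
                         dim1 = res$col_coords[, 1],
                         dim2 = if (ncol(res$col_coords) > 1)
                           res$col_coords[, 2] else 0,
                         inertia_share_dim1 = share[1]))
      }))
    }))
    readr::write_csv(coords, out("ca_coordinates.csv"))
    verdicts <- lapply(analysis$ca, function(per_kind) {
      lapply(per_kind, function(x) x$verdict)
    })
    jsonlite::write_json(verdicts, out("ca_verdicts.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    jsonlite::write_json(analysis$summary, out("summary.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    jsonlite::write_json(as.list(analysis$exclusions), out("exclusions.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  })
  attr(analysis, "files") <- written
  invisible(analysis)
}
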