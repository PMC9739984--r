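#' Tertile classification of adjusted footprints
#'
#' Splits a cohort into low/medium/high footprint thirds. Cut points are the
#' empirical 1/3 and 2/3 quantiles (linear interpolation); membership is
#' assigned by stable rank so that ties straddling a cut are broken by the
#' input order of respondents and group sizes differ by at most one. When
#' `n %% 3 != 0` the extra members go to the lower tertiles.
#'
#' @param values Numeric vector of (adjusted) footprints, one per
#'   respondent; `NA`s are not allowed (exclude undefined respondents
#'   upstream).
#' @param ids Respondent identifiers, defaults to `names(values)`.
#' @return Tibble `respondent_id`, `value`, `label`
#'   (factor low/medium/high), with attribute `cut_points` (the two
#'   interpolated quantiles).
#' @export
#' @examples
#' assign_tertiles(c(a = 1, b = 5, c = 9))
assign_tertiles <- function(values, ids = names(values)) {
  if (is.null(ids)) ids <- as.character(seq_along(values))
  if (anyNA(values)) stop("values must not contain NA", call. = FALSE)
  n <- length(values)
  if (n < 3L) stop("need at least 3 respondents for tertiles", call. = FALSE)
  if (length(unique(values)) == 1L) {
    warning("all footprint values equal; tertiles assigned by stable order",
            call. = FALSE)
  }
  ord <- order(values, seq_len(n))   # stable: ties keep input order
  base <- n %/% 3L
  sizes <- base + (seq_len(3L) <= n %% 3L)
  label <- factor(rep(c("low", "medium", "high"), sizes)[order(ord)],
                  levels = c("low", "medium", "high"))
  out <- tibble::tibble(respondent_id = as.character(ids),
                        value = values, label = label)
  attr(out, "cut_points") <- stats::quantile(values, c(1, 2) / 3, names = FALSE)
  out
}

#' Per-group contribution to a stratum's footprint
#'
#' For the given members, pools the per-group addends and expresses each
#' group's share of the pooled total as a percentage. Percentages sum to
#' 100 within the stratum by construction.
#'
#' @param addends Long addend tibble from [compute_footprints()].
#' @param members Respondent ids forming the stratum.
#' @param kind `"CF"`, `"WF"`, or `"EF"`.
#' @return Tibble `group_id`, `percent`, sorted by descending contribution.
#' @export
contribution <- function(addends, members, kind = c("CF", "WF", "EF")) {
  kind <- match.arg(kind)
  if (length(members) == 0L) stop("members must be non-empty", call. = FALSE)
  col <- c(CF = "cf", WF = "wf", EF = "ef")[[kind]]
  sub <- addends[addends$respondent_id %in% members, ]
  totals <- tapply(sub[[col]], sub$group_id, sum)
  grand <- sum(totals)
  if (!isTRUE(grand > 0)) {
    stop("stratum grand total is zero; contributions undefined", call. = FALSE)
  }
  out <- tibble::tibble(group_id = names(totals),
                        percent = 100 * as.vector(totals) / grand)
  out[order(-out$percent, out$group_id), ]
}

#' Contribution decomposition across tertile strata
#'
#' Runs [contribution()] for the whole cohort and for each tertile of one
#' footprint kind, returning the long tabular twin of the per-tertile
#' stacked contribution figures.
#'
#' @param addends Long addend tibble from [compute_footprints()].
#' @param tertiles Tertile tibble from [assign_tertiles()] for this kind.
#' @param kind `"CF"`, `"WF"`, or `"EF"`.
#' @return Tibble `stratum` (all/low/medium/high), `footprint_kind`,
#'   `group_id`, `percent`, sorted descending within stratum.
#' @export
contribution_table <- function(addends, tertiles, kind = c("CF", "WF", "EF")) {
  kind <- match.arg(kind)
  strata <- list(all = tertiles$respondent_id)
  for (lev in levels(tertiles$label)) {
    strata[[lev]] <- tertiles$respondent_id[tertiles$label == lev]
  }
  dplyr::bind_rows(lapply(names(strata), function(s) {
    tibble::add_column(contribution(addends, strata[[s]], kind),
                       stratum = s, footprint_kind = kind, .before = 1)
  }))
}

#' Median footprint of a stratum
#'
#' Empirical median (mean of the two central order statistics for even n)
#' of the members' values.
#'
#' @param values Named numeric vector, `respondent_id -> value`.
#' @param members Respondent ids of the stratum.
#' @return Scalar median.
#' @export
stratum_median <- function(values, members) {
  if (length(members) == 0L) stop("members must be non-empty", call. = FALSE)
  miss <- setdiff(members, names(values))
  if (length(miss)) {
    stop("no value for member(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  stats::median(values[members])
}
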