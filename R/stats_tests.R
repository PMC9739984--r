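# Constructor for the common test-result container.
enf_test <- function(statistic, p_value, method, n_per_group,
                     tie_corrected = FALSE, notes = character()) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 method = method, n_per_group = unname(n_per_group),
                 tie_corrected = tie_corrected, notes = notes),
            class = "enf_test")
}

#' @export
print.enf_test <- function(x, ...) {
  cat("<", x$method, ">\n", sep = "")
  cat("  statistic =", format(x$statistic), "  p =", format(x$p_value), "\n")
  cat("  n =", paste(x$n_per_group, collapse = ", "),
      if (x$tie_corrected) " (tie-corrected)", "\n")
  for (nt in x$notes) cat("  note:", nt, "\n")
  invisible(x)
}

#' Kolmogorov-Smirnov normality screen
#'
#' One-sample KS statistic of the data against a normal distribution with
#' the sample mean and standard deviation, with the standard asymptotic
#' p-value. Because the reference parameters are estimated from the same
#' sample (the Lilliefors situation), the asymptotic p-value is
#' conservative; the result carries an explicit note to that effect.
#'
#' @param values Numeric vector, n >= 4, non-constant.
#' @return An `enf_test`.
#' @export
ks_normality <- function(values) {
  if (length(values) < 4L) stop("need n >= 4 for the KS screen", call. = FALSE)
  if (stats::sd(values) == 0) stop("zero variance: KS undefined", call. = FALSE)
  res <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean(values), stats::sd(values)))
  enf_test(res$statistic, res$p.value,
           "Kolmogorov-Smirnov normality screen (estimated parameters)",
           length(values),
           notes = paste("reference mean/SD estimated from the sample;",
                         "asymptotic p-value is conservative"))
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two independent samples. The reported
#' statistic is `min(U_x, U_y)`. With `mode = "auto"` the p-value is exact
#' (full enumeration of rank assignments) when `n_x + n_y <= 12` and the
#' pooled data are untied, otherwise the normal approximation with tie and
#' continuity corrections is used.
#'
#' @param x,y Numeric samples, both non-empty.
#' @param mode `"auto"`, `"exact"`, or `"normal_approx"`.
#' @return An `enf_test`.
#' @export
#' @examples
#' mann_whitney(c(1, 2), c(3, 4)) # U = 0, exact p = 1/3
mann_whitney <- function(x, y, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  ties <- anyDuplicated(pooled) > 0L
  r <- rank(pooled)
  u_x <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  u <- min(u_x, nx * ny - u_x)
  exact <- switch(mode, exact = TRUE, normal_approx = FALSE,
                  auto = (nx + ny) <= 12L && !ties)
  if (exact && ties) stop("exact p-value requires untied data", call. = FALSE)
  p <- if (exact) {
    stats::wilcox.test(x, y, exact = TRUE)$p.value
  } else {
    suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))$p.value
  }
  enf_test(u, p,
           paste0("Mann-Whitney U (two-sided, ",
                  if (exact) "exact" else "normal approximation", ")"),
           c(nx, ny), tie_corrected = ties && !exact)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic across k independent samples, with the
#' chi-square reference on k - 1 degrees of freedom.
#'
#' @param groups List of numeric samples, each non-empty, total n >= 3.
#' @return An `enf_test`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  sizes <- lengths(groups)
  if (any(sizes == 0L)) stop("every group must be non-empty", call. = FALSE)
  if (sum(sizes) < 3L) stop("need total n >= 3", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), sizes))
  res <- stats::kruskal.test(values, g)
  enf_test(res$statistic, res$p.value,
           "Kruskal-Wallis rank test (tie-corrected, chi-square reference)",
           sizes, tie_corrected = anyDuplicated(values) > 0L)
}

#' Compact letter display from pairwise Mann-Whitney tests
#'
#' Assigns letters to groups so that two groups share a letter if and only
#' if their two-sided pairwise Mann-Whitney p-value is >= `alpha` (after
#' the optional adjustment). Letters are built by the insert-and-absorb
#' construction over the non-significance graph.
#'
#' @param groups Named list of numeric samples (names become labels).
#' @param alpha Significance level for each pairwise comparison.
#' @param adjust `"none"` (default; the conventional unadjusted display) or
#'   `"bonferroni"`.
#' @return Tibble `group`, `n`, `median`, `letters`.
#' @export
pairwise_letters <- function(groups, alpha = 0.05,
                             adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  k <- length(groups)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  if (k == 1L) {
    return(tibble::tibble(group = names(groups), n = lengths(groups),
                          median = stats::median(groups[[1]]), letters = "a"))
  }
  pairs <- utils::combn(k, 2)
  pvals <- apply(pairs, 2, function(ij) {
    mann_whitney(groups[[ij[1]]], groups[[ij[2]]])$p_value
  })
  if (adjust == "bonferroni") pvals <- stats::p.adjust(pvals, "bonferroni")
  sig <- matrix(FALSE, k, k)
  for (j in seq_len(ncol(pairs))) {
    if (pvals[j] < alpha) {
      sig[pairs[1, j], pairs[2, j]] <- TRUE
      sig[pairs[2, j], pairs[1, j]] <- TRUE
    }
  }
  letter_sets <- cld_insert_absorb(sig)
  lab <- vapply(seq_len(k), function(i) {
    paste(letters[which(vapply(letter_sets, function(s) i %in% s, logical(1)))],
          collapse = ",")
  }, character(1))
  tibble::tibble(group = names(groups), n = unname(lengths(groups)),
                 median = vapply(groups, stats::median, numeric(1),
                                 USE.NAMES = FALSE),
                 letters = lab)
}

# Insert-and-absorb: start from one set holding all groups; for every
# significantly different pair occurring together in a set, split the set
# into two copies omitting one member each, then absorb subsets.
cld_insert_absorb <- function(sig) {
  k <- nrow(sig)
  sets <- list(seq_len(k))
  pairs <- which(upper.tri(sig) & sig, arr.ind = TRUE)
  for (row in seq_len(nrow(pairs))) {
    i <- pairs[row, 1]; j <- pairs[row, 2]
    new_sets <- list()
    for (s in sets) {
      if (i %in% s && j %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    # absorb: drop sets contained in another set, and duplicates
    keep <- rep(TRUE, length(new_sets))
    for (a in seq_along(new_sets)) {
      for (b in seq_along(new_sets)) {
        if (a != b && keep[a] && keep[b] &&
            all(new_sets[[a]] %in% new_sets[[b]]) &&
            (length(new_sets[[a]]) < length(new_sets[[b]]) || a > b)) {
          keep[a] <- FALSE
        }
      }
    }
    sets <- new_sets[keep]
  }
  # stable ordering: by smallest member
  sets[order(vapply(sets, min, numeric(1)))]
}

#' Stratified comparison table for adjusted footprints
#'
#' For each categorical covariate, tabulates category sizes, frequency
#' percentages with a normal-approximation 95% CI, the median adjusted
#' footprint per kind, compact letters from pairwise Mann-Whitney tests,
#' and the omnibus p-value (Mann-Whitney for two categories,
#' Kruskal-Wallis otherwise). Respondents with a missing category
#' ("don't know / didn't answer") are dropped per variable with a logged
#' count in the `exclusions` attribute.
#'
#' @param footprints Footprint tibble from [compute_footprints()].
#' @param covariates Tibble with `respondent_id` and one column per
#'   categorical variable (factor or character; `NA` = missing).
#' @param variables Which covariate columns to use; defaults to all but
#'   `respondent_id`.
#' @param alpha Level for the compact letters.
#' @return Long tibble: `variable`, `category`, `n`, `percent`, `ci_low`,
#'   `ci_high`, then per kind `median_<kind>`, `letters_<kind>`,
#'   `p_<kind>`.
#' @export
footprint_comparison_table <- function(footprints, covariates,
                                       variables = NULL, alpha = 0.05) {
  if (is.null(variables)) {
    variables <- setdiff(names(covariates), "respondent_id")
  }
  kinds <- c(CF = "cf_1000", WF = "wf_1000", EF = "ef_1000")
  idx <- match(covariates$respondent_id, footprints$respondent_id)
  exclusions <- integer(0)
  rows <- lapply(variables, function(v) {
    cat_v <- as.character(covariates[[v]])
    ok <- !is.na(cat_v) & !is.na(idx) & !is.na(footprints$cf_1000[idx])
    exclusions[[v]] <<- sum(!ok)
    cats <- cat_v[ok]
    lv <- if (is.factor(covariates[[v]])) {
      intersect(levels(covariates[[v]]), unique(cats))
    } else sort(unique(cats))
    n_tot <- length(cats)
    out <- tibble::tibble(variable = v, category = lv,
                          n = as.integer(table(factor(cats, lv))))
    p_hat <- out$n / n_tot
    se <- sqrt(p_hat * (1 - p_hat) / n_tot)
    out$percent <- 100 * p_hat
    out$ci_low <- pmax(0, 100 * (p_hat - 1.96 * se))
    out$ci_high <- pmin(100, 100 * (p_hat + 1.96 * se))
    for (kind in names(kinds)) {
      vals <- footprints[[kinds[[kind]]]][idx][ok]
      by_cat <- split(vals, factor(cats, lv))
      cl <- pairwise_letters(by_cat, alpha = alpha)
      omnibus <- if (length(lv) == 2L) {
        mann_whitney(by_cat[[1]], by_cat[[2]])
      } else {
        kruskal_wallis(by_cat)
      }
      out[[paste0("median_", kind)]] <- cl$median
      out[[paste0("letters_", kind)]] <- cl$letters
      out[[paste0("p_", kind)]] <- omnibus$p_value
    }
    out
  })
  res <- dplyr::bind_rows(rows)
  attr(res, "exclusions") <- exclusions
  res
}
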