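rand_table <- function(nr, nc) {
  repeat {
    tab <- matrix(rpois(nr * nc, 8), nr, nc)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) return(tab)
  }
}

test_that("exact independence yields zero inertia and zero coordinates", {
  tab <- outer(c(10, 20, 30), c(2, 3, 5))
  res <- correspondence(tab)
  expect_equal(res$total_inertia, 0, tolerance = 1e-12)
  expect_equal(res$chi2, 0, tolerance = 1e-9)
  expect_equal(max(abs(res$row_coords)), 0, tolerance = 1e-7)
  expect_equal(max(abs(res$col_coords)), 0, tolerance = 1e-7)
})

test_that("the 2x2 cross table matches the closed-form chi-square", {
  tab <- matrix(c(20, 10, 10, 20), 2, byrow = TRUE)
  res <- correspondence(tab)
  # n (ad - bc)^2 / (r1 r2 c1 c2)
  expect_equal(res$chi2, 60 * (20 * 20 - 10 * 10)^2 / (30 * 30 * 30 * 30))
  expect_equal(res$chi2, 20 / 3)
  expect_equal(res$df, 1)
})

test_that("total inertia times n equals the chi-square loop on random tables", {
  set.seed(101)
  for (i in 1:100) {
    tab <- rand_table(sample(2:4, 1), sample(2:6, 1))
    res <- correspondence(tab)
    expect_equal(res$total_inertia * res$n, chisq_by_loop(tab),
                 tolerance = 1e-9)
    expect_equal(sum(res$principal_inertias), res$total_inertia,
                 tolerance = 1e-9)
    expect_equal(length(res$principal_inertias), min(dim(tab)) - 1L)
  }
})

test_that("coordinates are mass-centered, transpose-symmetric, reconstructive", {
  set.seed(202)
  for (i in 1:20) {
    tab <- rand_table(3, sample(3:5, 1))
    res <- correspondence(tab)
    # weighted mean zero with the marginal masses as weights
    expect_equal(max(abs(crossprod(res$row_mass, res$row_coords))), 0,
                 tolerance = 1e-9)
    expect_equal(max(abs(crossprod(res$col_mass, res$col_coords))), 0,
                 tolerance = 1e-9)
    # transposition swaps the point clouds and keeps the inertias
    tres <- correspondence(t(tab))
    expect_equal(tres$principal_inertias, res$principal_inertias,
                 tolerance = 1e-9)
    expect_equal(abs(tres$row_coords), abs(res$col_coords), tolerance = 1e-7,
                 ignore_attr = TRUE)
    # P rebuilt from margins plus the decomposed residuals
    P <- tab / sum(tab)
    r <- rowSums(P); cc <- colSums(P)
    S <- sweep(sweep(P - outer(r, cc), 1, sqrt(r), "/"), 2, sqrt(cc), "/")
    sv <- svd(S)
    rebuilt <- outer(r, cc) +
      sweep(sweep(sv$u %*% diag(sv$d) %*% t(sv$v), 1, sqrt(r), "*"),
            2, sqrt(cc), "*")
    expect_equal(rebuilt, P, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("degenerate tables are rejected", {
  expect_error(correspondence(matrix(0, 2, 2)), "grand total")
  expect_error(correspondence(matrix(c(1, 0, 2, 0), 2)), "all-zero")
  expect_error(correspondence(matrix(c(-1, 2, 2, 2), 2)), "non-negative")
})

test_that("association verdict applies the strict p < alpha rule", {
  tab <- rand_table(3, 4)
  res <- correspondence(tab)
  # a CA with p = 0.21 is reported as not associated at alpha = 0.05
  res$p_value <- 0.21
  expect_equal(association_verdict(res)$verdict, "not_associated")
  res$p_value <- 0.001
  expect_equal(association_verdict(res)$verdict, "associated")
  res$p_value <- 0.05
  expect_equal(association_verdict(res)$verdict, "not_associated")
  v <- association_verdict(res)
  expect_type(v$literal_rule_met, "logical")
  expect_match(v$rationale, "critical")
})

test_that("tertile x covariate tables drop missing categories with a count", {
  tert <- assign_tertiles(setNames(1:6, paste0("r", 1:6)))
  cov <- tibble::tibble(respondent_id = paste0("r", 1:6),
                        grp = c("a", "b", "a", "b", "a", "b"))
  tab <- build_ca_table(tert, cov, "grp")
  expect_equal(unclass(tab)[1:6], rep(1L, 6), ignore_attr = TRUE)
  expect_equal(attr(tab, "dropped_missing"), 0)

  cov$grp[3] <- NA
  tab2 <- build_ca_table(tert, cov, "grp")
  expect_equal(attr(tab2, "dropped_missing"), 1)
  expect_equal(sum(tab2), 5)

  cov_disjoint <- tibble::tibble(respondent_id = paste0("x", 1:6),
                                 grp = rep("a", 6))
  expect_error(build_ca_table(tert, cov_disjoint, "grp"), "no respondents")
})

test_that("nearest-tertile assignment uses chi-square map distances", {
  tab <- matrix(c(30, 2, 2, 2, 30, 2, 2, 2, 30), 3, byrow = TRUE,
                dimnames = list(c("low", "medium", "high"), c("a", "b", "c")))
  nt <- nearest_tertile(correspondence(tab))
  expect_equal(nt$nearest_tertile[match(c("a", "b", "c"), nt$category)],
               c("low", "medium", "high"))
})
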