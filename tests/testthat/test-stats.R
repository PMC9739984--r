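test_that("Mann-Whitney matches hand-checked exact cases", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 2 / 6)

  r2 <- mann_whitney(1, 2)
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p_value, 1)

  # identical multisets: U at its null mean, p in the no-evidence region
  r3 <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(r3$statistic, 4 * 4 / 2)
  expect_gte(r3$p_value, 0.99)
  expect_true(r3$tie_corrected)

  expect_error(mann_whitney(numeric(0), 1), "non-empty")
  expect_error(mann_whitney(c(1, 1, 2), c(1, 3), mode = "exact"), "untied")
})

test_that("exact Mann-Whitney p equals brute-force enumeration", {
  set.seed(42)
  for (nx in 1:5) {
    for (ny in nx:(10 - nx)) {
      x <- sample(1000, nx)
      y <- sample(setdiff(1:1000, x), ny)
      expect_equal(mann_whitney(x, y, mode = "exact")$p_value,
                   mw_exact_enum(x, y),
                   info = sprintf("nx=%d ny=%d", nx, ny))
    }
  }
})

test_that("Kruskal-Wallis matches the direct rank formula", {
  r <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(r$statistic, kw_by_hand(list(c(1, 2), c(3, 4), c(5, 6))))
  expect_equal(r$statistic, 12 / 42 * (2 * 4 + 2 * 4)) # hand value 32/7

  same <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  r0 <- kruskal_wallis(same)
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p_value, 1)

  set.seed(9)
  for (i in 1:20) {
    g <- lapply(sample(2:5, sample(2:4, 1), replace = TRUE), runif)
    expect_equal(kruskal_wallis(g)$statistic, kw_by_hand(g),
                 tolerance = 1e-12)
  }
  expect_error(kruskal_wallis(list(1:3)), "at least 2")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")
})

test_that("two-group Kruskal-Wallis equals the squared MW normal z", {
  set.seed(31)
  for (i in 1:25) {
    x <- rnorm(sample(4:20, 1))
    y <- rnorm(sample(4:20, 1), mean = runif(1, -1, 1))
    p_kw <- kruskal_wallis(list(x, y))$p_value
    p_mw <- suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = FALSE))$p.value
    expect_equal(p_kw, p_mw, tolerance = 1e-6)
  }
})

test_that("rank tests are invariant under strictly monotone transforms", {
  set.seed(77)
  for (i in 1:10) {
    x <- rlnorm(12)
    y <- rlnorm(15, 0.4)
    z <- rlnorm(9)
    f <- function(v) log(v) * 3 + 1
    expect_equal(mann_whitney(x, y)$p_value,
                 mann_whitney(f(x), f(y))$p_value)
    expect_equal(kruskal_wallis(list(x, y, z))$statistic,
                 kruskal_wallis(list(f(x), f(y), f(z)))$statistic)
  }
})

test_that("KS screen computes the sup-distance with estimated parameters", {
  set.seed(3)
  x <- rnorm(40, 5, 2)
  r <- ks_normality(x)
  expect_equal(r$statistic, ks_stat_by_hand(x, mean(x), sd(x)),
               tolerance = 1e-12)
  expect_match(r$notes, "estimated")
  # a sample laid on exact normal quantiles attains a near-minimal distance
  grid <- qnorm((1:20 - 0.5) / 20)
  expect_lte(ks_normality(grid)$statistic, 0.06)
  expect_error(ks_normality(rep(2, 10)), "zero variance")
  expect_error(ks_normality(c(1, 2)), "n >= 4")
})

test_that("compact letters separate exactly the significantly different pairs", {
  all_same <- pairwise_letters(list(a = 1:9, b = 1:9, c = 1:9))
  expect_equal(all_same$letters, rep("a", 3))

  apart <- pairwise_letters(list(lo = 1:20, hi = 101:120))
  expect_equal(apart$letters, c("a", "b"))

  single <- pairwise_letters(list(only = c(1, 2, 3)))
  expect_equal(single$letters, "a")

  # middle group overlapping both extremes shares a letter with each
  set.seed(12)
  lo <- rnorm(40, 0)
  mid <- rnorm(40, 0.5)
  hi <- rnorm(40, 4)
  cl <- pairwise_letters(list(lo = lo, mid = mid, hi = hi))
  shared <- function(a, b) {
    length(intersect(strsplit(a, ",")[[1]], strsplit(b, ",")[[1]])) > 0
  }
  p_lo_mid <- mann_whitney(lo, mid)$p_value
  expect_equal(shared(cl$letters[1], cl$letters[2]), p_lo_mid >= 0.05)
  expect_false(shared(cl$letters[1], cl$letters[3]))
  expect_false(shared(cl$letters[2], cl$letters[3]))
})

test_that("type-I error of the KW screen is near nominal under the null", {
  set.seed(2024)
  reps <- 2000
  rejections <- 0L
  for (i in seq_len(reps)) {
    g <- list(rnorm(30), rnorm(30), rnorm(30))
    if (kruskal_wallis(g)$p_value < 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / reps
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})
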