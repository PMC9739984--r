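profiles2 <- tibble::tibble(
  group_id = c("g1", "g2"), per_capita_g = c(150, 200),
  cf_per_kg = c(5000, 1000), wf_per_kg = c(2000, 800),
  ef_per_kg = c(20, 4), kcal_per_100g = c(350, 100))

test_that("daily frequency uses the fixed period divisors", {
  expect_equal(daily_frequency(3, "week"), 3 / 7)
  expect_equal(daily_frequency(1, "year"), 1 / 365)
  expect_equal(daily_frequency(5, "month"), 5 / 30)
  expect_equal(daily_frequency(2, "day"), 2)
  expect_error(daily_frequency(1, "fortnight"), "unknown period")
  expect_error(daily_frequency(0, "day"), ">= 1")
})

test_that("EFC converts grams to kg/day", {
  expect_equal(efc(3 / 7, 150), 3 / 7 * 150 / 1000)
  expect_equal(efc(0, 500), 0)
  expect_equal(efc(1, 1000), 1)
  expect_error(efc(-1, 100), "non-negative")
})

test_that("individual footprint sums EFC times the group coefficient", {
  res <- individual_footprint(c(g1 = 0.1, g2 = 0.2), profiles2, "CF")
  expect_equal(res$total, 0.1 * 5000 + 0.2 * 1000) # 700
  expect_equal(sum(res$addends), res$total)
  expect_equal(individual_footprint(setNames(numeric(0), character(0)),
                                    profiles2, "CF")$total, 0)
  one <- individual_footprint(c(g1 = 0.5), profiles2, "WF")
  expect_equal(one$total, 1000)
  expect_error(individual_footprint(c(g9 = 0.1), profiles2, "CF"), "g9")
})

test_that("energy intake applies the 100-g portion factor", {
  expect_equal(energy_intake(c(g1 = 0.1), profiles2), 0.1 * 10 * 350) # 350
  expect_equal(energy_intake(c(g2 = 1.0), profiles2), 1000)
  expect_equal(energy_intake(setNames(numeric(0), character(0)), profiles2), 0)
})

test_that("standardization to 1000 kcal is the stated ratio", {
  expect_equal(adjust_per_1000kcal(2000, 1000), 2000)
  expect_equal(adjust_per_1000kcal(2000, 2000), 1000)
  expect_equal(adjust_per_1000kcal(0, 1500), 0)
  expect_error(adjust_per_1000kcal(100, 0), "energy must be > 0")
})

test_that("cohort driver conserves addends and flags zero energy", {
  pq <- tibble::tibble(respondent_id = c("r1", "r1", "r2"),
                       group_id = c("g1", "g2", "g1"),
                       count = c(3L, 7L, 1L),
                       period = c("week", "week", "year"))
  fp <- compute_footprints(pq, profiles2)
  expect_equal(nrow(fp$footprints), 2)
  by_r <- tapply(fp$addends$cf, fp$addends$respondent_id, sum)
  expect_equal(as.vector(by_r[fp$footprints$respondent_id]),
               fp$footprints$cf_total)
  expect_equal(fp$footprints$cf_1000 * fp$footprints$energy_kcal,
               fp$footprints$cf_total * 1000)
  # unknown group: error by default, dropped-with-count under pipeline policy
  pq_bad <- dplyr::bind_rows(pq, tibble::tibble(
    respondent_id = "r3", group_id = "g9", count = 1L, period = "day"))
  expect_error(compute_footprints(pq_bad, profiles2), "g9")
  fp2 <- compute_footprints(pq_bad, profiles2, on_missing_profile = "drop")
  excl <- attr(fp2, "exclusions")
  expect_equal(unname(excl["pq_rows_without_profile"]), 1L)
  # r3 lost every row: zero totals, undefined adjusted values
  r3 <- fp2$footprints[fp2$footprints$respondent_id == "r3", ]
  expect_equal(r3$cf_total, 0)
  expect_true(is.na(r3$cf_1000))
  expect_equal(unname(excl["zero_energy_respondents"]), 1L)
})

test_that("totals are linear in coefficients and invariant to amount scaling", {
  for (seed in 1:8) {
    co <- small_cohort(seed)
    prof <- build_group_profiles(co$recall, co$coefficients, co$composition,
                                 co$dilution)
    fp <- compute_footprints(co$pq, prof, on_missing_profile = "drop")
    # scaling every coefficient by c scales totals by c
    prof_c <- prof
    for (col in c("cf_per_kg", "wf_per_kg", "ef_per_kg")) {
      prof_c[[col]] <- prof_c[[col]] * 3
    }
    fp_c <- compute_footprints(co$pq, prof_c, on_missing_profile = "drop")
    expect_equal(fp_c$footprints$cf_total, 3 * fp$footprints$cf_total)
    expect_equal(fp_c$footprints$ef_total, 3 * fp$footprints$ef_total)
    # scaling per-capita amounts scales totals and energy, not adjusted values
    prof_a <- prof
    prof_a$per_capita_g <- prof_a$per_capita_g * 2.5
    fp_a <- compute_footprints(co$pq, prof_a, on_missing_profile = "drop")
    expect_equal(fp_a$footprints$energy_kcal, 2.5 * fp$footprints$energy_kcal)
    expect_equal(fp_a$footprints$cf_1000, fp$footprints$cf_1000,
                 tolerance = 1e-9)
    expect_equal(fp_a$footprints$wf_1000, fp$footprints$wf_1000,
                 tolerance = 1e-9)
  }
})

test_that("increasing one EFC component never decreases a total", {
  set.seed(5)
  for (i in 1:10) {
    v <- setNames(runif(2, 0, 1), c("g1", "g2"))
    base <- individual_footprint(v, profiles2, "CF")$total
    bump <- v
    j <- sample(2, 1)
    bump[j] <- bump[j] + runif(1)
    expect_gte(individual_footprint(bump, profiles2, "CF")$total, base)
  }
})
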