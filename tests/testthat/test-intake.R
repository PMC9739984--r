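obs <- function(amount, times = 1, unit = "g", food = "f1", prep = "raw",
                group = "g1") {
  tibble::tibble(respondent_id = "r1", food_id = food, group_id = group,
                 amount = amount, unit = unit, preparation = prep,
                 times = as.integer(times))
}

test_that("volume-to-mass conversion applies the dilution rule", {
  rules <- tibble::tibble(key = c("coffee", "g_bev"),
                          grams_per_mL = c(1.0, 0.5))
  expect_equal(volume_to_mass(100, "coffee", "g_bev", rules), 100)
  # group-level fallback when the food has no rule of its own
  expect_equal(volume_to_mass(200, "tea", "g_bev", rules), 100)
  expect_error(volume_to_mass(50, "juice", "g_other", rules),
               "no dilution rule.*juice")
  # linear in amount
  expect_equal(volume_to_mass(c(10, 20, 40), "coffee", "g_bev", rules),
               c(10, 20, 40))
})

test_that("per-capita amount is the times-weighted mean of masses", {
  two <- dplyr::bind_rows(obs(100), obs(200))
  expect_equal(group_per_capita(two), 150)
  weighted <- dplyr::bind_rows(obs(100, times = 3), obs(200, times = 1))
  expect_equal(group_per_capita(weighted), 125) # (3*100 + 1*200)/4
  expect_equal(group_per_capita(obs(80)), 80)
  expect_error(group_per_capita(obs(80)[0, ]), "absent from the profile")
  # median estimator variant
  three <- dplyr::bind_rows(obs(50), obs(100, times = 5), obs(400))
  expect_equal(group_per_capita(three, estimator = "median"), 100)
})

coef3 <- tibble::tibble(
  food_id = c("f1", "f2", "f2"), group_id = "g1",
  preparation = c("raw", "raw", "fried"),
  cf_g_co2eq_per_kg = c(2000, 6000, 7000),
  wf_l_per_kg = c(500, 900, 950), ef_m2_per_kg = c(2, 10, 12))

test_that("group coefficients are times-weighted over observed preparations", {
  single <- obs(100, food = "f1")
  single_coef <- group_coefficients(single,
                                    dplyr::mutate(coef3,
                                                  cf_g_co2eq_per_kg = 5000))
  expect_equal(unname(single_coef["cf_per_kg"]), 5000)

  even <- dplyr::bind_rows(obs(1, food = "f1"), obs(1, food = "f2"))
  expect_equal(unname(group_coefficients(even, coef3)["cf_per_kg"]), 4000)

  weighted <- dplyr::bind_rows(obs(1, times = 3, food = "f1"),
                               obs(1, times = 1, food = "f2"))
  expect_equal(unname(group_coefficients(weighted, coef3)["cf_per_kg"]), 3000)

  expect_error(group_coefficients(obs(1, food = "mystery"), coef3),
               "unresolved food/preparation.*mystery")
  # alias map resolves observed names onto coefficient food ids
  aliased <- group_coefficients(obs(1, food = "mystery"), coef3,
                                alias = c(mystery = "f1"))
  expect_equal(unname(aliased["cf_per_kg"]), 2000)
})

test_that("weighted means are convex and weight-scale invariant", {
  set.seed(21)
  for (i in 1:20) {
    k <- sample(2:8, 1)
    o <- tibble::tibble(respondent_id = "r", food_id = sample(c("f1", "f2"), k,
                                                              replace = TRUE),
                        group_id = "g1", amount = runif(k, 10, 400),
                        unit = "g", preparation = "raw",
                        times = sample(1:5, k, replace = TRUE))
    pc <- group_per_capita(o)
    expect_gte(pc, min(o$amount))
    expect_lte(pc, max(o$amount))
    doubled <- o
    doubled$times <- o$times * 2L
    expect_equal(group_per_capita(doubled), pc)
    cc <- group_coefficients(o, coef3)
    cc2 <- group_coefficients(doubled, coef3)
    expect_equal(cc, cc2)
    expect_true(all(cc >= c(min(coef3$cf_g_co2eq_per_kg),
                            min(coef3$wf_l_per_kg), min(coef3$ef_m2_per_kg))))
  }
})

test_that("PQ and recall validation enforces the questionnaire contract", {
  reg <- food_group_registry("g1")
  ok_pq <- tibble::tibble(respondent_id = "r1", group_id = "g1",
                          count = 3, period = "week")
  expect_equal(validate_pq(ok_pq, reg)$count, 3L)
  expect_error(validate_pq(dplyr::mutate(ok_pq, count = 11), reg), "1..10")
  expect_error(validate_pq(dplyr::mutate(ok_pq, count = 0), reg), "1..10")
  expect_error(validate_pq(dplyr::mutate(ok_pq, period = "fortnight"), reg),
               "period")
  ok_rec <- obs(100)
  expect_silent(validate_recall(ok_rec, reg))
  expect_error(validate_recall(dplyr::mutate(ok_rec, amount = -5), reg),
               "positive")
  expect_error(validate_recall(dplyr::mutate(ok_rec, unit = "cups"), reg),
               "unit")
})

test_that("group profiles combine per-capita, coefficients and kcal", {
  recall <- dplyr::bind_rows(
    obs(100, times = 3, food = "f1"),
    obs(200, times = 1, food = "f2"))
  comp <- tibble::tibble(food_id = c("f1", "f2"), group_id = "g1",
                         kcal_per_100g = c(100, 300))
  prof <- build_group_profiles(recall, coef3, comp)
  expect_equal(nrow(prof), 1)
  expect_equal(prof$per_capita_g, 125)
  expect_equal(prof$cf_per_kg, 3000)
  expect_equal(prof$kcal_per_100g, 200)
  # a group never observed is absent, not zero
  comp2 <- dplyr::bind_rows(comp, tibble::tibble(
    food_id = "f9", group_id = "g9", kcal_per_100g = 50))
  expect_false("g9" %in% build_group_profiles(recall, coef3, comp2)$group_id)
})
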