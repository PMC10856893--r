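test_that("zero-variance generator returns the stage means exactly", {
  p <- stage_params("flowering_fruit_setting", n_days = 5, mean_dar = 83.67,
                    mean_vpd = 0.48, mean_ta = 21.27, mean_w = 0.10,
                    cv = 0, seed = 1)
  m <- generate_microclimate(p)
  expect_equal(m$dar, rep(83.67, 5))
  expect_equal(m$vpd, rep(0.48, 5))
  expect_equal(m$ta, rep(21.27, 5))
  expect_equal(m$w, rep(0.10, 5))
})

test_that("generator is deterministic per seed and leaves global RNG alone", {
  p1 <- flowering_params(seed = 1, n_days = 50)
  p2 <- flowering_params(seed = 2, n_days = 50)
  set.seed(123)
  state <- .Random.seed
  a <- generate_microclimate(p1)
  expect_identical(.Random.seed, state)
  b <- generate_microclimate(p1)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$dar, generate_microclimate(p2)$dar)))
})

test_that("sample means recover configured means within 3 standard errors", {
  p <- flowering_params(seed = 1, n_days = 1000)
  m <- generate_microclimate(p)
  means <- c(dar = 83.67, ta = 21.27, vpd = 0.48, w = 0.10)
  # AR(1) inflates the variance of the mean by (1 + ar1) / (1 - ar1)
  infl <- sqrt((1 + p$ar1) / (1 - p$ar1))
  for (v in names(means)) {
    se <- p$cv * means[[v]] / sqrt(p$n_days) * infl
    expect_lt(abs(mean(m[[v]]) - means[[v]]), 3 * se)
  }
})

test_that("VPD and Ta are positively coupled to DAR and all values positive", {
  p <- stage_params("picking", n_days = 500, mean_dar = 50.60,
                    mean_vpd = 0.27, mean_ta = 16.06, mean_w = 0.09,
                    cv = 0.5, seed = 7)
  m <- generate_microclimate(p)
  expect_gt(cor(m$dar, m$vpd), 0.3)
  expect_gt(cor(m$dar, m$ta), 0.3)
  expect_true(all(m$dar > 0 & m$vpd > 0 & m$ta > 0 & m$w > 0))
})

test_that("generator rejects invalid stage parameters", {
  expect_error(stage_params("picking", n_days = 10, mean_dar = -1,
                            mean_vpd = 0.3, mean_ta = 16, mean_w = 0.1),
               "mean_dar")
  expect_error(stage_params("picking", n_days = 10, mean_dar = 50,
                            mean_vpd = 0.3, mean_ta = 16, mean_w = 0.1,
                            ar1 = 1), "ar1")
})

test_that("noiseless LAI trajectory is logistic: monotone, bounded, saturating", {
  lp <- lai_params(lai_max = 2.64, midpoint_day = 45, rate = 0.12,
                   measurement_days = c(30, 40, 50, 60, 70, 80, 500))
  g <- generate_lai_trajectory(lp)
  expect_true(all(diff(g$lai) >= 0))
  expect_true(all(g$lai > 0 & g$lai <= 2.64))
  expect_equal(g$lai[g$days_after_transplant == 500], 2.64, tolerance = 1e-6)
  expect_error(lai_params(lai_max = 2.64, midpoint_day = 45, rate = 0.12,
                          measurement_days = numeric()), "empty")
})

test_that("noise_sd = 0 transpiration equals the model evaluation pointwise", {
  micro <- generate_microclimate(flowering_params(seed = 3, n_days = 40))
  lai <- flowering_lai(40)
  tm <- generate_transpiration(micro, lai, published_coefficients("flowering"),
                               noise_sd = 0)
  expect_identical(tm$tm,
                   evaluate_flowering(micro$dar, micro$vpd, micro$ta, lai))
  expect_false(any(tm$clipped))
})

test_that("transpiration noise has the configured standard deviation", {
  micro <- generate_microclimate(flowering_params(seed = 4, n_days = 1000))
  lai <- rep(2.5, 1000)
  noiseless <- generate_transpiration(micro, lai,
                                      published_coefficients("flowering"),
                                      noise_sd = 0)
  noisy <- generate_transpiration(micro, lai,
                                  published_coefficients("flowering"),
                                  noise_sd = 0.05, seed = 11)
  resid <- noisy$tm - noiseless$tm
  # SE of a sample SD is about sd / sqrt(2 n)
  expect_lt(abs(sd(resid) - 0.05), 3 * 0.05 / sqrt(2 * 1000))
})

test_that("transpiration generator enforces series alignment", {
  micro <- generate_microclimate(flowering_params(seed = 1, n_days = 10))
  expect_error(generate_transpiration(micro, rep(2, 9),
                                      published_coefficients("flowering")),
               "length mismatch")
})

test_that("static system: zero transpiration gives constant masses", {
  w <- generate_weighing_records(rep(0, 10), capacity = 3)
  expect_true(all(w$w_morning == w$w_morning[1]))
  expect_true(all(w$irrigation == 0))
  td <- daily_transpiration(w)
  expect_true(all(td$td_mass == 0))
})

test_that("weighing round trip recovers the generated series bit-for-bit", {
  set.seed(99)
  tm <- runif(200, 0.2, 0.9)
  w <- generate_weighing_records(tm, capacity = 3, lower_limit_frac = 0.7)
  td <- daily_transpiration(w)
  expect_identical(td$td_mass, attr(w, "tm_realized"))
  expect_lt(max(abs(attr(w, "tm_realized") - tm)), 2^-20)
  # masses already on the resolution grid round-trip to the input itself
  tm_g <- round(tm * 2^20) / 2^20
  w_g <- generate_weighing_records(tm_g, capacity = 3)
  expect_identical(daily_transpiration(w_g)$td_mass, tm_g)
})

test_that("substrate store respects capacity and non-negativity", {
  set.seed(5)
  tm <- runif(100, 0, 1.2)
  w <- generate_weighing_records(tm, capacity = 2, lower_limit_frac = 0.6,
                                 tare_mass = 30)
  store <- w$w_morning - 30
  expect_true(all(store >= 0))
  expect_true(all(store <= 2))
})

test_that("demand exceeding the store forces an irrigation event", {
  # store starts at 0.5 kg, trigger at 0.2 kg, but day 1 needs 0.6 kg
  w <- generate_weighing_records(c(0.6, 0.1), capacity = 1,
                                 lower_limit_frac = 0.2,
                                 initial_store = 0.5)
  expect_gt(w$irrigation[1], 0)
  expect_true(all(w$w_morning - w$w_morning[1] + 0.5 >= 0))
  expect_identical(daily_transpiration(w)$td_mass, attr(w, "tm_realized"))
  expect_equal(daily_transpiration(w)$td_mass, c(0.6, 0.1),
               tolerance = 1e-5)
  expect_error(generate_weighing_records(5, capacity = 1), "exceeds capacity")
})

test_that("mass conservation holds over any generated scenario", {
  set.seed(8)
  tm <- runif(60, 0.1, 0.8)
  w <- generate_weighing_records(tm, capacity = 3, lower_limit_frac = 0.8)
  n <- nrow(w)
  lhs <- sum(attr(w, "tm_realized"))
  rhs <- sum(w$irrigation[-n]) - sum(w$return_flow[-n]) -
    (w$w_morning[n] - w$w_morning[1])
  expect_equal(lhs, rhs, tolerance = 1e-12)
})
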