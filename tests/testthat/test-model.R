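test_that("flowering form matches independent term-by-term evaluation", {
  # unit-argument collapse: all log terms vanish
  expect_equal(evaluate_flowering(1, 1, 1, 1), 0.001)
  terms <- c(0.001 * 83.67^1.261, 0.689 * log(0.48), 0.399 * log(21.27),
             0.527 * log(2.5))
  expect_equal(evaluate_flowering(83.67, 0.48, 21.27, 2.5), sum(terms),
               tolerance = 1e-12)
  expect_equal(round(evaluate_flowering(83.67, 0.48, 21.27, 2.5), 2), 1.46)
  # doubling a doubles only the power-law term
  co <- published_coefficients("flowering")
  co2 <- model_coefficients("flowering",
                            replace(co$values, "a", 2 * co$values["a"]))
  expect_equal(evaluate_flowering(83.67, 0.48, 21.27, 2.5, co2) -
                 evaluate_flowering(83.67, 0.48, 21.27, 2.5, co),
               0.001 * 83.67^1.261, tolerance = 1e-12)
  expect_error(evaluate_flowering(-1, 0.5, 20, 2), "dar")
  expect_error(evaluate_flowering(80, 0, 20, 2), "vpd")
})

test_that("picking form reproduces its unit-argument collapse (negative)", {
  expect_equal(evaluate_picking(1, 0, 1, 1), 0.011 + 0.189 - 6.01,
               tolerance = 1e-12)
  # zero wind coefficient and intercept kill the wind term
  co <- model_coefficients("picking",
                           c(a = 0.011, b = 1.04, c = 0.189, d = -0.110,
                             e = 0, f = 0))
  expect_equal(evaluate_picking(1, 0, 1, 0.5, co),
               evaluate_picking(1, 0, 1, 5, co))
})

test_that("unsegmented form matches independent recomputation", {
  expect_equal(evaluate_unsegmented(1, 1, 1, 1, 0), 0.006 + 0.249)
  terms <- c(0.514 * log(99.21), 0.08 * log(0.84), 0.379 * log(26.23),
             1.05 * log(0.17), 0.006 * exp(3.0), 0.249)
  expect_equal(evaluate_unsegmented(99.21, 0.84, 26.23, 0.17, 3.0),
               sum(terms), tolerance = 1e-12)
  expect_equal(round(sum(terms), 2), 2.10)
  zero <- model_coefficients("unsegmented",
                             c(a = 0, c = 0, d = 0, e = 0, g = 0, f = 0))
  expect_equal(evaluate_unsegmented(99.21, 0.84, 26.23, 0.17, 3, zero), 0)
})

test_that("stage calendar assigns days with closed-left picking boundary", {
  cal <- stage_calendar(0, 10, 45, 100)
  expect_equal(stage_of(c(5, 10, 44, 45, 100), cal),
               c("seedling", "flowering_fruit_setting",
                 "flowering_fruit_setting", "picking", "picking"))
  expect_error(stage_of(101, cal), "outside")
  expect_error(stage_calendar(0, 45, 10, 100), "increasing")
})

test_that("predict_series applies the right form per stage and clips", {
  micro <- generate_microclimate(flowering_params(seed = 6, n_days = 30))
  days <- data.frame(date = 1:30, micro[, c("dar", "vpd", "ta", "w")],
                     lai = flowering_lai(30))
  cal <- stage_calendar(0, 1, 31, 40)  # flowering only
  out <- predict_series(days, cal)
  expect_equal(out$ts_raw,
               evaluate_flowering(days$dar, days$vpd, days$ta, days$lai))
  expect_true(all(out$stage == "flowering_fruit_setting"))
  # picking with the published coefficients goes negative at low wind: clipped
  cal2 <- stage_calendar(0, 1, 16, 31)
  out2 <- predict_series(days, cal2)
  pick <- out2[out2$stage == "picking", ]
  expect_true(all(pick$ts >= 0))
  expect_true(any(pick$flag == "negative_clipped"))
  expect_true(all(pick$ts_raw <= pick$ts))
  # seedling days are excluded
  cal3 <- stage_calendar(1, 11, 31, 40)
  expect_equal(nrow(predict_series(days, cal3)), 20)
})

test_that("noiseless flowering data is recovered to 1e-6 relative error", {
  d <- flowering_scenario(seed = 1, n_days = 150, noise_sd = 0)
  fit <- fit_stage_model(d$tm, d, "flowering")
  truth <- published_coefficients("flowering")$values
  expect_true(fit$converged)
  expect_lt(max(abs(fit$coefficients$values - truth) / abs(truth)), 1e-6)
  expect_lt(fit$residual_sum_squares, 1e-10)
})

test_that("refitting a model on its own predictions is a fixed point", {
  d <- flowering_scenario(seed = 2, n_days = 150, noise_sd = 0.05)
  fit1 <- fit_stage_model(d$tm, d, "flowering")
  pred <- evaluate_flowering(d$dar, d$vpd, d$ta, d$lai, fit1$coefficients)
  fit2 <- fit_stage_model(pred, d, "flowering")
  expect_lt(max(abs(fit2$coefficients$values - fit1$coefficients$values) /
                  pmax(abs(fit1$coefficients$values), 1e-8)), 1e-5)
})

test_that("unsegmented closed-form fit agrees with iterative LM to 1e-6", {
  d <- flowering_scenario(seed = 3, n_days = 120, noise_sd = 0.05)
  fit <- fit_stage_model(d$tm, d, "unsegmented")
  # independent iterative route: damped least squares on the same residuals
  resid_fn <- function(p) {
    p["a"] * log(d$dar) + p["c"] * log(d$vpd) + p["d"] * log(d$ta) +
      p["e"] * log(pmax(d$w, 0.01)) + p["g"] * exp(d$lai) + p["f"] - d$tm
  }
  start <- c(a = 0.1, c = 0.1, d = 0.1, e = 0.1, g = 0.1, f = 0)
  lm_fit <- minpack.lm::nls.lm(start, fn = resid_fn)
  expect_lt(max(abs(coef(lm_fit) - fit$coefficients$values)), 1e-6)
})

test_that("fitting is invariant to observation order", {
  d <- flowering_scenario(seed = 4, n_days = 100, noise_sd = 0.05)
  fit <- fit_stage_model(d$tm, d, "flowering")
  perm <- sample(nrow(d))
  fit_p <- fit_stage_model(d$tm[perm], d[perm, ], "flowering")
  expect_equal(fit_p$coefficients$values, fit$coefficients$values,
               tolerance = 1e-5)
})

test_that("degenerate designs raise informative fit errors", {
  d <- data.frame(dar = rep(80, 60), vpd = rep(0.5, 60), ta = rep(20, 60),
                  lai = rep(2, 60))
  expect_error(fit_stage_model(rnorm(60, 1.5, 0.1), d, "flowering"),
               "rank-deficient")
  expect_error(fit_stage_model(1:10, d[1:10, ], "flowering"),
               "at least 15")
})

test_that("segmented fits beat the unsegmented fit on two-stage data", {
  for (seed in c(11, 12, 13)) {
    n <- 80
    m_fl <- generate_microclimate(flowering_params(seed, n))
    m_pk <- generate_microclimate(picking_params(seed + 100, n))
    lai_fl <- flowering_lai(n)
    lai_pk <- rep(2.64, n)
    co_pk <- model_coefficients("picking",
                                c(a = 0.02, b = 1.0, c = 0.3, d = 0.1,
                                  e = 0.05, f = 0.2))
    tm_fl <- generate_transpiration(m_fl, lai_fl,
                                    published_coefficients("flowering"),
                                    noise_sd = 0.05, seed = seed)$tm
    tm_pk <- generate_transpiration(m_pk, lai_pk, co_pk, noise_sd = 0.05,
                                    seed = seed + 1)$tm
    all_drv <- rbind(cbind(m_fl, lai = lai_fl), cbind(m_pk, lai = lai_pk))
    tm <- c(tm_fl, tm_pk)
    rss_seg <-
      fit_stage_model(tm_fl, cbind(m_fl, lai = lai_fl),
                      "flowering")$residual_sum_squares +
      fit_stage_model(tm_pk, m_pk, "picking")$residual_sum_squares
    rss_unseg <- fit_stage_model(tm, all_drv,
                                 "unsegmented")$residual_sum_squares
    expect_lt(rss_seg, rss_unseg)
  }
})
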