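#' Stage parameters for the synthetic microclimate generator
#'
#' Bundles the target daily means of the four microclimate drivers for one
#' phenological stage together with the variability structure used to
#' simulate them. Drivers are simulated as mean-reverting lag-1
#' autoregressive series; vapour-pressure deficit and air temperature are
#' coupled to the day's solar-radiation anomaly, mirroring the observed
#' co-fluctuation of VPD and Ta with radiation in greenhouse data.
#'
#' @param stage_name `"flowering_fruit_setting"` or `"picking"`.
#' @param n_days number of days to simulate (>= 1).
#' @param mean_dar target mean daily accumulated solar radiation,
#'   water-equivalent depth (mm d^-1).
#' @param mean_vpd target mean vapour-pressure deficit (kPa).
#' @param mean_ta target mean air temperature (degrees C).
#' @param mean_w target mean wind speed (m s^-1).
#' @param cv fractional day-to-day variability (standard deviation / mean)
#'   applied to every driver. Default 0.2.
#' @param ar1 lag-1 autocorrelation of each driver, in `[0, 1)`. Default 0.5.
#' @param coupling correlation of the VPD and Ta anomalies with the DAR
#'   anomaly, in `[0, 1)`. Default 0.6.
#' @param seed integer seed; identical seeds give identical series.
#' @return An object of class `"stage_params"`.
#' @seealso [generate_microclimate()], [stage_climate_means()]
#' @export
stage_params <- function(stage_name = c("flowering_fruit_setting", "picking"),
                         n_days, mean_dar, mean_vpd, mean_ta, mean_w,
                         cv = 0.2, ar1 = 0.5, coupling = 0.6, seed = 1L) {
  stage_name <- match.arg(stage_name)
  check_number(n_days, "n_days", lower = 1)
  for (nm in c("mean_dar", "mean_vpd", "mean_ta", "mean_w"))
    check_number(get(nm), nm, lower = 0, strict_lower = TRUE)
  check_number(cv, "cv", lower = 0)
  check_number(ar1, "ar1", lower = 0, upper = 1, strict_upper = TRUE)
  check_number(coupling, "coupling", lower = 0, upper = 1, strict_upper = TRUE)
  check_number(seed, "seed")
  structure(list(stage_name = stage_name, n_days = as.integer(n_days),
                 mean_dar = mean_dar, mean_vpd = mean_vpd, mean_ta = mean_ta,
                 mean_w = mean_w, cv = cv, ar1 = ar1, coupling = coupling,
                 seed = as.integer(seed)),
            class = "stage_params")
}

# Stationary standard AR(1) series: marginal N(0, 1), lag-1 correlation ar1.
ar1_series <- function(n, ar1) {
  z <- numeric(n)
  z[1] <- stats::rnorm(1)
  if (n > 1) {
    innov <- sqrt(1 - ar1^2)
    for (i in 2:n) z[i] <- ar1 * z[i - 1] + innov * stats::rnorm(1)
  }
  z
}

#' Simulate a daily greenhouse microclimate series
#'
#' Generates `n_days` of daily accumulated solar radiation (DAR),
#' vapour-pressure deficit (VPD), air temperature (Ta) and wind speed (W)
#' with the configured means, fractional variability `cv`, lag-1
#' autocorrelation `ar1`, and positive DAR-VPD / DAR-Ta coupling. Each
#' driver's anomaly is a stationary standardized AR(1) process; the VPD and
#' Ta anomalies share a component with the DAR anomaly (weight `coupling`).
#' All values are floored just above zero, so a `cv` of 0 returns the means
#' exactly and positive `cv` never produces non-positive drivers.
#'
#' @param params a [stage_params()] object.
#' @return A data frame with columns `day`, `dar`, `ta`, `vpd`, `w`.
#' @examples
#' p <- stage_params("flowering_fruit_setting", n_days = 10,
#'                   mean_dar = 83.67, mean_vpd = 0.48, mean_ta = 21.27,
#'                   mean_w = 0.10, seed = 1)
#' head(generate_microclimate(p))
#' @export
generate_microclimate <- function(params) {
  if (!inherits(params, "stage_params"))
    stop_param("`params` must be created by stage_params()")
  n <- params$n_days
  means <- c(dar = params$mean_dar, vpd = params$mean_vpd,
             ta = params$mean_ta, w = params$mean_w)
  sds <- params$cv * means
  k <- params$coupling
  with_seed(params$seed, {
    z_dar <- ar1_series(n, params$ar1)
    z_vpd <- k * z_dar + sqrt(1 - k^2) * ar1_series(n, params$ar1)
    z_ta  <- k * z_dar + sqrt(1 - k^2) * ar1_series(n, params$ar1)
    z_w   <- ar1_series(n, params$ar1)
    data.frame(
      day = seq_len(n),
      dar = pmax(means["dar"] + sds["dar"] * z_dar, 1e-8),
      ta  = pmax(means["ta"]  + sds["ta"]  * z_ta,  1e-8),
      vpd = pmax(means["vpd"] + sds["vpd"] * z_vpd, 1e-8),
      w   = pmax(means["w"]   + sds["w"]   * z_w,   1e-8),
      row.names = NULL)
  })
}

#' Parameters of a synthetic leaf-area-index trajectory
#'
#' The underlying truth curve is logistic,
#' `lai(t) = lai_max / (1 + exp(-rate * (t - midpoint_day)))`: LAI rises
#' through the flowering and fruit-setting stage and plateaus at `lai_max`
#' as the crop enters picking. Field-style measurements are taken at
#' `measurement_days` with additive Gaussian noise.
#'
#' @param lai_max plateau leaf area index (m^2 m^-2), > 0.
#' @param midpoint_day day (after transplant) at which LAI reaches half of
#'   `lai_max`.
#' @param rate logistic growth rate (d^-1), > 0.
#' @param measurement_noise_sd standard deviation of measurement noise
#'   (m^2 m^-2). Default 0.
#' @param measurement_days strictly increasing days on which measurements
#'   are taken.
#' @param seed integer seed for the measurement noise.
#' @return An object of class `"lai_params"`.
#' @export
lai_params <- function(lai_max, midpoint_day, rate,
                       measurement_noise_sd = 0, measurement_days,
                       seed = 1L) {
  check_number(lai_max, "lai_max", lower = 0, strict_lower = TRUE)
  check_number(midpoint_day, "midpoint_day")
  check_number(rate, "rate", lower = 0, strict_lower = TRUE)
  check_number(measurement_noise_sd, "measurement_noise_sd", lower = 0)
  if (length(measurement_days) == 0)
    stop_param("`measurement_days` must not be empty")
  check_number(measurement_days, "measurement_days", allow_vector = TRUE)
  if (is.unsorted(measurement_days, strictly = TRUE))
    stop_param("`measurement_days` must be strictly increasing")
  check_number(seed, "seed")
  structure(list(lai_max = lai_max, midpoint_day = midpoint_day, rate = rate,
                 measurement_noise_sd = measurement_noise_sd,
                 measurement_days = measurement_days, seed = as.integer(seed)),
            class = "lai_params")
}

# Noiseless logistic LAI truth curve.
lai_logistic <- function(day, lai_max, midpoint_day, rate) {
  lai_max / (1 + exp(-rate * (day - midpoint_day)))
}

#' Generate synthetic LAI measurements along a logistic growth curve
#'
#' @param params a [lai_params()] object.
#' @return A data frame with columns `days_after_transplant`, `lai`
#'   (measured, noisy) and `lai_true` (noiseless logistic value). Noisy
#'   values are floored just above zero.
#' @export
generate_lai_trajectory <- function(params) {
  if (!inherits(params, "lai_params"))
    stop_param("`params` must be created by lai_params()")
  days <- params$measurement_days
  truth <- lai_logistic(days, params$lai_max, params$midpoint_day, params$rate)
  noisy <- if (params$measurement_noise_sd > 0) {
    with_seed(params$seed,
              pmax(truth + stats::rnorm(length(days), 0,
                                        params$measurement_noise_sd), 1e-8))
  } else truth
  data.frame(days_after_transplant = days, lai = noisy, lai_true = truth)
}

#' Generate daily transpiration from a driving model plus noise
#'
#' Uses one of the transpiration model forms as the data-generating truth:
#' `Tm_i = model(drivers_i; coefs) + eps_i`, `eps ~ N(0, noise_sd^2)`.
#' Negative draws are floored at zero and flagged. With `noise_sd = 0` the
#' output equals the corresponding `evaluate_*()` call pointwise.
#'
#' @param microclimate data frame with columns `dar`, `vpd`, `ta`, `w` (as
#'   from [generate_microclimate()]).
#' @param lai daily LAI series, same length as `microclimate` rows (ignored
#'   by the picking form, which is insensitive to the plateaued LAI).
#' @param coefs a [model_coefficients()] object selecting the form and truth
#'   coefficients.
#' @param noise_sd standard deviation of additive observation noise
#'   (mm d^-1).
#' @param seed integer seed for the noise.
#' @return Data frame with columns `day`, `tm` (mm d^-1) and logical
#'   `clipped` marking negative draws floored at zero.
#' @export
generate_transpiration <- function(microclimate, lai, coefs, noise_sd = 0,
                                   seed = 1L) {
  check_columns(microclimate, c("dar", "vpd", "ta", "w"), "microclimate")
  n <- nrow(microclimate)
  if (length(lai) != n)
    stop_param(sprintf(
      "length mismatch: %d microclimate days vs %d LAI values", n,
      length(lai)))
  check_number(noise_sd, "noise_sd", lower = 0)
  base <- switch(coefs$form,
    flowering = evaluate_flowering(microclimate$dar, microclimate$vpd,
                                   microclimate$ta, lai, coefs),
    picking = evaluate_picking(microclimate$dar, microclimate$vpd,
                               microclimate$ta, microclimate$w, coefs),
    unsegmented = evaluate_unsegmented(microclimate$dar, microclimate$vpd,
                                       microclimate$ta, microclimate$w,
                                       lai, coefs))
  raw <- if (noise_sd > 0)
    base + with_seed(seed, stats::rnorm(n, 0, noise_sd))
  else base
  clipped <- raw < 0
  data.frame(day = seq_len(n), tm = pmax(raw, 0), clipped = clipped)
}

#' Generate weighing-lysimeter records consistent with a transpiration series
#'
#' Simulates the morning weighing protocol: the system (tank + substrate +
#' plant) is weighed at 08:00; if the substrate water store has fallen below
#' `lower_limit_frac` of its water-holding capacity, it is refilled to
#' capacity, with a fraction `flush_frac` of the refill passing through as
#' return flow. The day's transpiration then depletes the store. Records are
#' constructed so the mass-balance identity
#' `Td_i = W_i + I_i - R_i - W_{i+1}` recovers the generated series
#' exactly -- bit for bit, not merely to rounding -- and the store never
#' exceeds capacity nor goes negative. If a day's demand would overdraw the
#' store before the next trigger, an extra refill is inserted that morning.
#'
#' Exactness is achieved by quantizing every mass to a dyadic resolution
#' (`resolution`, default 2^-20 kg, about 1 microgram -- six orders of
#' magnitude below the 1 g accuracy of the scale), so that all masses are
#' exact binary fractions and the balance sums and differences incur no
#' floating-point rounding. The realized (quantized) transpiration series
#' is attached as attribute `"tm_realized"`; an input already on the
#' resolution grid is recovered identically, and any input to within half
#' a quantum.
#'
#' @param tm_mass daily transpiration per plant-unit (kg), non-negative.
#' @param capacity substrate water-holding capacity (kg), > 0.
#' @param lower_limit_frac irrigation trigger as a fraction of capacity, in
#'   (0, 1]. Default 0.7 (the optimum treatment's lower limit).
#' @param tare_mass constant mass of tank + substrate dry matter + plant
#'   (kg). Default 30.
#' @param initial_store starting water store (kg). Default `capacity`.
#' @param flush_frac fraction of each refill that drains as return flow.
#'   Default 0.1.
#' @param start_date optional `Date` of the first morning; if omitted,
#'   integer day indices are used.
#' @param resolution mass quantum (kg); must be a power of two. Default
#'   `2^-20`.
#' @return Data frame of `length(tm_mass) + 1` morning records with columns
#'   `date`, `w_morning`, `irrigation`, `return_flow` (kg).
#' @seealso [daily_transpiration()] for the inverse operation.
#' @export
generate_weighing_records <- function(tm_mass, capacity,
                                      lower_limit_frac = 0.7,
                                      tare_mass = 30,
                                      initial_store = capacity,
                                      flush_frac = 0.1,
                                      start_date = NULL,
                                      resolution = 2^-20) {
  check_number(capacity, "capacity", lower = 0, strict_lower = TRUE)
  check_number(lower_limit_frac, "lower_limit_frac", lower = 0, upper = 1,
               strict_lower = TRUE)
  check_number(tm_mass, "tm_mass", lower = 0, allow_vector = TRUE)
  check_number(flush_frac, "flush_frac", lower = 0, upper = 1,
               strict_upper = TRUE)
  check_number(initial_store, "initial_store", lower = 0, upper = capacity)
  check_number(resolution, "resolution", lower = 0, strict_lower = TRUE)
  if (log2(resolution) != round(log2(resolution)))
    stop_param("`resolution` must be a power of two")
  quant <- function(x) round(x / resolution) * resolution
  tm_q <- quant(tm_mass)
  capacity <- quant(capacity)
  tare_mass <- quant(tare_mass)
  n <- length(tm_q)
  store <- numeric(n + 1)
  irr <- ret <- numeric(n + 1)
  store[1] <- quant(initial_store)
  for (i in seq_len(n)) {
    s <- store[i]
    refill <- 0
    dec <- irrigation_trigger(s, capacity, lower_limit_frac)
    if (dec$decision == "irrigate") refill <- dec$refill  # = capacity - s
    # demand would overdraw the store before the next morning check
    if (s + refill - tm_q[i] < 0) refill <- capacity - s
    if (capacity - tm_q[i] < 0)
      stop_param(sprintf(
        "day %d transpiration (%.3f kg) exceeds capacity (%.3f kg)",
        i, tm_q[i], capacity))
    irr[i] <- quant(refill * (1 + flush_frac))
    ret[i] <- irr[i] - refill  # exact: gross minus net refill
    store[i + 1] <- s + refill - tm_q[i]
  }
  dates <- if (is.null(start_date)) seq_len(n + 1)
           else seq(start_date, by = "day", length.out = n + 1)
  out <- data.frame(date = dates, w_morning = tare_mass + store,
                    irrigation = irr, return_flow = ret)
  attr(out, "tm_realized") <- tm_q
  out
}

#' Stage-mean microclimate statistics of the two study seasons
#'
#' Daily-mean driver values by year and phenological stage for the 2022
#' (autumn) and 2023 (spring) cropping seasons, shipped as package data.
#' These are the targets the synthetic generator emulates and convenient
#' defaults for [stage_params()].
#'
#' @return Data frame with columns `year`, `stage`, `dar` (mm d^-1), `vpd`
#'   (kPa), `ta` (degrees C), `w` (m s^-1).
#' @export
stage_climate_means <- function() {
  read_extdata("stage_climate_means.csv")
}
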