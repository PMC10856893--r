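#' Coefficients of a daily-transpiration model form
#'
#' Three forms are supported. Flowering / fruit-setting:
#' `Ts = a * DAR^b + c * ln(VPD) + d * ln(Ta) + e * ln(LAI)`.
#' Picking: `Ts = a * DAR^b + c * exp(VPD) + d * ln(Ta) + e * ln(W) + f`.
#' Unsegmented (whole season, linear after transforms):
#' `T' = a * ln(DAR) + c * ln(VPD) + d * ln(Ta) + e * ln(W) + g * exp(LAI) + f`.
#'
#' @param form `"flowering"`, `"picking"` or `"unsegmented"`.
#' @param values named numeric vector of coefficients; names must match the
#'   form's coefficient set (see [published_coefficients()] for the
#'   defaults and naming).
#' @return Object of class `"model_coefficients"`.
#' @export
model_coefficients <- function(form = c("flowering", "picking", "unsegmented"),
                               values) {
  form <- match.arg(form)
  needed <- switch(form,
    flowering = c("a", "b", "c", "d", "e"),
    picking = c("a", "b", "c", "d", "e", "f"),
    unsegmented = c("a", "c", "d", "e", "g", "f"))
  if (!is.numeric(values) || anyNA(values) || any(!is.finite(values)))
    stop_param("coefficients must be finite numeric")
  miss <- setdiff(needed, names(values))
  if (length(miss))
    stop_param("missing coefficient(s) for form '", form, "': ",
               paste(miss, collapse = ", "))
  structure(list(form = form, values = values[needed]),
            class = "model_coefficients")
}

#' Published coefficient sets of the fitted transpiration models
#'
#' The coefficient values reported for the optimum (70 % lower-limit)
#' treatment, shipped as defaults. Note a plausibility caveat for the
#' picking set: evaluated at that stage's own mean drivers (wind speed well
#' below 1 m s^-1) the large `ln W` term and intercept drive the prediction
#' strongly negative, suggesting a transcription or unit issue in the
#' source values. The functional form is implemented as reported; analyses
#' in this package that depend on the picking stage refit the coefficients
#' rather than trusting these constants.
#'
#' @param form `"flowering"`, `"picking"` or `"unsegmented"`.
#' @return A [model_coefficients()] object.
#' @export
published_coefficients <- function(form = c("flowering", "picking",
                                            "unsegmented")) {
  form <- match.arg(form)
  values <- switch(form,
    flowering = c(a = 0.001, b = 1.261, c = 0.689, d = 0.399, e = 0.527),
    picking = c(a = 0.011, b = 1.04, c = 0.189, d = -0.110, e = 5.625,
                f = -6.01),
    unsegmented = c(a = 0.514, c = 0.08, d = 0.379, e = 1.05, g = 0.006,
                    f = 0.249))
  model_coefficients(form, values)
}

# Domain floors before log transforms: greenhouse wind speed is near zero
# and early LAI can be tiny; ln(0) is undefined.
LAI_FLOOR <- 0.01
W_FLOOR <- 0.01

floor_input <- function(x, floor) pmax(x, floor)

check_positive_drivers <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    x <- args[[nm]]
    if (!is.numeric(x) || anyNA(x)) stop_param("`", nm, "` must be numeric")
    if (any(x <= 0)) stop_param("`", nm, "` must be strictly positive")
  }
}

#' Evaluate the flowering / fruit-setting transpiration form
#'
#' `Ts = a * dar^b + c * ln(vpd) + d * ln(ta) + e * ln(lai)`. The raw value
#' is returned (it can be negative for dry, cold, low-LAI days); clipping
#' for reporting is done by [predict_series()].
#'
#' @param dar daily accumulated solar radiation (mm d^-1), > 0.
#' @param vpd vapour-pressure deficit (kPa), > 0.
#' @param ta air temperature (degrees C), > 0.
#' @param lai leaf area index (m^2 m^-2); floored at 0.01 before the log.
#' @param coefs a [model_coefficients()] object of form `"flowering"`.
#' @return Simulated transpiration (mm d^-1). Vectorized.
#' @examples
#' evaluate_flowering(83.67, 0.48, 21.27, 2.5)  # ~1.46 mm/d
#' @export
evaluate_flowering <- function(dar, vpd, ta, lai,
                               coefs = published_coefficients("flowering")) {
  stopifnot(coefs$form == "flowering")
  check_positive_drivers(dar = dar, vpd = vpd, ta = ta)
  v <- coefs$values
  lai <- floor_input(lai, LAI_FLOOR)
  unname(v["a"] * dar^v["b"] + v["c"] * log(vpd) + v["d"] * log(ta) +
           v["e"] * log(lai))
}

#' Evaluate the picking-stage transpiration form
#'
#' `Ts = a * dar^b + c * exp(vpd) + d * ln(ta) + e * ln(w) + f`.
#'
#' @inheritParams evaluate_flowering
#' @param w wind speed (m s^-1); floored at 0.01 before the log.
#' @param coefs a [model_coefficients()] object of form `"picking"`.
#' @return Simulated transpiration (mm d^-1), raw (may be negative; see
#'   [published_coefficients()] for the caveat on the published set).
#' @export
evaluate_picking <- function(dar, vpd, ta, w,
                             coefs = published_coefficients("picking")) {
  stopifnot(coefs$form == "picking")
  check_positive_drivers(dar = dar, ta = ta)
  if (!is.numeric(vpd) || anyNA(vpd) || any(vpd < 0))
    stop_param("`vpd` must be non-negative")
  v <- coefs$values
  w <- floor_input(w, W_FLOOR)
  unname(v["a"] * dar^v["b"] + v["c"] * exp(vpd) + v["d"] * log(ta) +
           v["e"] * log(w) + v["f"])
}

#' Evaluate the unsegmented whole-season transpiration form
#'
#' `T' = a * ln(dar) + c * ln(vpd) + d * ln(ta) + e * ln(w) + g * exp(lai) + f`.
#'
#' @inheritParams evaluate_picking
#' @param lai leaf area index (m^2 m^-2), >= 0.
#' @param coefs a [model_coefficients()] object of form `"unsegmented"`.
#' @return Simulated transpiration (mm d^-1). Vectorized.
#' @examples
#' evaluate_unsegmented(99.21, 0.84, 26.23, 0.17, 3.0)  # ~2.10 mm/d
#' @export
evaluate_unsegmented <- function(dar, vpd, ta, w, lai,
                                 coefs = published_coefficients("unsegmented")) {
  stopifnot(coefs$form == "unsegmented")
  check_positive_drivers(dar = dar, vpd = vpd, ta = ta)
  v <- coefs$values
  w <- floor_input(w, W_FLOOR)
  unname(v["a"] * log(dar) + v["c"] * log(vpd) + v["d"] * log(ta) +
           v["e"] * log(w) + v["g"] * exp(lai) + v["f"])
}

#' Stage calendar for segmented prediction
#'
#' Contiguous, chronological stage intervals. The boundary convention is
#' closed-left toward the later stage: a day equal to `picking_start`
#' belongs to picking. The segmented model's switch condition
#' ("LAI has reached its plateau") is operationalized by calendar stage
#' rather than a fragile equality test on a real-valued LAI.
#'
#' @param seedling_start,flowering_start,picking_start,end stage boundary
#'   days (Date or numeric day index), strictly increasing.
#' @return Object of class `"stage_calendar"`.
#' @export
stage_calendar <- function(seedling_start, flowering_start, picking_start,
                           end) {
  b <- c(seedling_start, flowering_start, picking_start, end)
  if (is.unsorted(as.numeric(b), strictly = TRUE))
    stop_param("calendar boundaries must be strictly increasing")
  structure(list(seedling_start = seedling_start,
                 flowering_start = flowering_start,
                 picking_start = picking_start, end = end),
            class = "stage_calendar")
}

#' Stage membership of days under a calendar
#'
#' @param dates days (same type as the calendar boundaries).
#' @param calendar a [stage_calendar()] object.
#' @return Character vector: `"seedling"`, `"flowering_fruit_setting"` or
#'   `"picking"`. Days outside the calendar are an error.
#' @export
stage_of <- function(dates, calendar) {
  d <- as.numeric(dates)
  if (any(d < as.numeric(calendar$seedling_start)) ||
      any(d > as.numeric(calendar$end)))
    stop_param("day(s) outside the stage calendar")
  ifelse(d >= as.numeric(calendar$picking_start), "picking",
         ifelse(d >= as.numeric(calendar$flowering_start),
                "flowering_fruit_setting", "seedling"))
}

#' Predict daily transpiration with the segmented model
#'
#' Applies the flowering form to days in the flowering / fruit-setting
#' interval and the picking form to days from `picking_start` on; seedling
#' days are excluded from the output. Negative raw predictions are clipped
#' to zero and flagged.
#'
#' @param days data frame with columns `date`, `dar`, `vpd`, `ta`, `w`,
#'   `lai`.
#' @param calendar a [stage_calendar()] object covering every `date`.
#' @param coefs_flowering,coefs_picking coefficient sets for the two
#'   stages; defaults are the published values (see the caveat in
#'   [published_coefficients()]).
#' @return Data frame with columns `date`, `stage`, `ts_raw`, `ts`
#'   (clipped at 0) and `flag` (`"ok"` or `"negative_clipped"`).
#' @export
predict_series <- function(days, calendar,
                           coefs_flowering = published_coefficients("flowering"),
                           coefs_picking = published_coefficients("picking")) {
  check_columns(days, c("date", "dar", "vpd", "ta", "w", "lai"), "days")
  stage <- stage_of(days$date, calendar)
  keep <- stage != "seedling"
  days <- days[keep, ]
  stage <- stage[keep]
  raw <- numeric(nrow(days))
  fl <- stage == "flowering_fruit_setting"
  if (any(fl))
    raw[fl] <- evaluate_flowering(days$dar[fl], days$vpd[fl], days$ta[fl],
                                  days$lai[fl], coefs_flowering)
  if (any(!fl))
    raw[!fl] <- evaluate_picking(days$dar[!fl], days$vpd[!fl], days$ta[!fl],
                                 days$w[!fl], coefs_picking)
  data.frame(date = days$date, stage = stage, ts_raw = raw,
             ts = pmax(raw, 0),
             flag = ifelse(raw < 0, "negative_clipped", "ok"))
}

# Design matrix of the linear-in-coefficients part of each form, at a given
# power-law exponent b (flowering/picking) or for the unsegmented form.
model_design <- function(form, drivers, b = NULL) {
  switch(form,
    flowering = cbind(a = drivers$dar^b,
                      c = log(drivers$vpd),
                      d = log(drivers$ta),
                      e = log(floor_input(drivers$lai, LAI_FLOOR))),
    picking = cbind(a = drivers$dar^b,
                    c = exp(drivers$vpd),
                    d = log(drivers$ta),
                    e = log(floor_input(drivers$w, W_FLOOR)),
                    f = 1),
    unsegmented = cbind(a = log(drivers$dar),
                        c = log(drivers$vpd),
                        d = log(drivers$ta),
                        e = log(floor_input(drivers$w, W_FLOOR)),
                        g = exp(drivers$lai),
                        f = 1))
}

#' Fit a transpiration model form by damped least squares
#'
#' Minimizes the residual sum of squares of the chosen form against
#' measured daily transpiration. The flowering and picking forms are
#' nonlinear in the power-law exponent `b` and are fitted by
#' Levenberg-Marquardt (via \pkg{minpack.lm}), multi-started over a small
#' grid of exponents with the linear coefficients initialized from an
#' ordinary least-squares fit at each grid exponent; the best converged
#' start by RSS is returned. `b` is constrained to (0.2, 3). The
#' unsegmented form is linear after its transforms and is solved in closed
#' form by ordinary least squares.
#'
#' @param observed measured daily transpiration (mm d^-1).
#' @param drivers data frame with the form's driver columns (`dar`, `vpd`,
#'   `ta`, and `lai` and/or `w`).
#' @param form `"flowering"`, `"picking"` or `"unsegmented"`.
#' @param b_grid initialization grid for the power-law exponent.
#' @return Object of class `"fit_result"`: list with `coefficients` (a
#'   [model_coefficients()] object), `residual_sum_squares`, `n_obs`,
#'   `converged`, `covariance`, `n_iterations`.
#' @export
fit_stage_model <- function(observed, drivers,
                            form = c("flowering", "picking", "unsegmented"),
                            b_grid = c(0.8, 1.0, 1.3)) {
  form <- match.arg(form)
  needed <- switch(form,
    flowering = c("dar", "vpd", "ta", "lai"),
    picking = c("dar", "vpd", "ta", "w"),
    unsegmented = c("dar", "vpd", "ta", "w", "lai"))
  check_columns(drivers, needed, "drivers")
  n <- length(observed)
  if (n != nrow(drivers)) stop_param("`observed` must match nrow(drivers)")
  n_coef <- switch(form, flowering = 5L, picking = 6L, unsegmented = 6L)
  if (n < 3 * n_coef)
    stop_param("need at least ", 3 * n_coef, " observations to fit the ",
               form, " form")
  X1 <- model_design(form, drivers, b = 1)
  if (qr(X1)$rank < ncol(X1))
    stop_param("rank-deficient design (constant or collinear drivers)")

  if (form == "unsegmented") {
    fit <- stats::lm.fit(X1, observed)
    rss <- sum(fit$residuals^2)
    sigma2 <- rss / (n - n_coef)
    XtXinv <- chol2inv(chol(crossprod(X1)))
    co <- stats::setNames(fit$coefficients, colnames(X1))
    return(structure(list(
      coefficients = model_coefficients("unsegmented", co),
      residual_sum_squares = rss, n_obs = n, converged = TRUE,
      covariance = sigma2 * XtXinv, n_iterations = 0L),
      class = "fit_result"))
  }

  fml <- if (form == "flowering")
    observed ~ a * dar^b + c * log(vpd) + d * log(ta) + e * log(lai_f)
  else
    observed ~ a * dar^b + c * exp(vpd) + d * log(ta) + e * log(w_f) + f
  dat <- data.frame(observed = observed, dar = drivers$dar,
                    vpd = drivers$vpd, ta = drivers$ta)
  if (form == "flowering")
    dat$lai_f <- floor_input(drivers$lai, LAI_FLOOR)
  else dat$w_f <- floor_input(drivers$w, W_FLOOR)
  k_lin <- n_coef - 1L  # linear coefficients beside b
  lower <- c(rep(-Inf, 1), 0.2, rep(-Inf, k_lin - 1))
  upper <- c(rep(Inf, 1), 3, rep(Inf, k_lin - 1))
  best <- NULL
  diagnostics <- character()
  for (b0 in b_grid) {
    Xb <- model_design(form, drivers, b = b0)
    lin <- tryCatch(stats::lm.fit(Xb, observed)$coefficients,
                    error = function(e) NULL)
    if (is.null(lin) || anyNA(lin)) next
    start <- as.list(c(lin[1], b0, lin[-1]))
    names(start) <- c("a", "b", names(lin)[-1])
    fit <- tryCatch(
      minpack.lm::nlsLM(fml, data = dat, start = start, lower = lower,
                        upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) {
        diagnostics <<- c(diagnostics,
                          sprintf("start b=%.2f: %s", b0,
                                  conditionMessage(e)))
        NULL
      })
    if (is.null(fit)) next
    if (is.null(best) || stats::deviance(fit) < stats::deviance(best))
      best <- fit
  }
  if (is.null(best))
    stop_param("Levenberg-Marquardt failed to converge from any start: ",
               paste(diagnostics, collapse = " | "))
  co <- stats::coef(best)
  structure(list(
    coefficients = model_coefficients(form, co),
    residual_sum_squares = stats::deviance(best), n_obs = n,
    converged = best$convInfo$isConv,
    covariance = tryCatch(stats::vcov(best), error = function(e) NULL),
    n_iterations = best$convInfo$finIter),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Transpiration model fit (", x$coefficients$form, " form)\n", sep = "")
  print(round(x$coefficients$values, 4))
  cat("RSS:", format(x$residual_sum_squares, digits = 5),
      " n:", x$n_obs, " converged:", x$converged,
      " iterations:", x$n_iterations, "\n")
  invisible(x)
}
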