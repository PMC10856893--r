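#' Vapour-pressure deficit from air temperature and relative humidity
#'
#' Tetens saturation vapour pressure,
#' `e_s(ta) = 0.6108 * exp(17.27 * ta / (ta + 237.3))` (kPa), combined with
#' relative humidity: `VPD = e_s(ta) * (1 - rh / 100)`.
#'
#' @param ta air temperature (degrees C).
#' @param rh relative humidity (percent, 0-100).
#' @return VPD in kPa, >= 0. Vectorized.
#' @examples
#' vpd_from_ta_rh(20, 50)  # ~1.169 kPa
#' @export
vpd_from_ta_rh <- function(ta, rh) {
  if (!is.numeric(rh) || anyNA(rh) || any(rh < 0 | rh > 100))
    stop_param("`rh` must lie in [0, 100]")
  if (!is.numeric(ta) || anyNA(ta))
    stop_param("`ta` must be numeric")
  es <- 0.6108 * exp(17.27 * ta / (ta + 237.3))
  es * (1 - rh / 100)
}

#' Convert solar radiation to water-equivalent evaporation depth
#'
#' Divides daily accumulated radiation by the latent heat of vaporization
#' (fixed at 2.45 MJ kg^-1, the FAO-56 convention); 1 kg m^-2 of water is
#' 1 mm depth, so `dar = rs / 2.45`.
#'
#' @param rs radiation (MJ m^-2 d^-1), >= 0.
#' @return DAR in mm d^-1. Vectorized.
#' @export
radiation_to_dar <- function(rs) {
  if (!is.numeric(rs) || anyNA(rs) || any(rs < 0))
    stop_param("`rs` must be non-negative numeric")
  rs / 2.45
}

#' Aggregate half-hourly sensor readings to daily driver values
#'
#' Computes per-day means of air temperature, wind speed and per-reading
#' VPD (VPD is computed reading by reading from `ta` and `rh`, then
#' averaged -- not from daily-mean temperature and humidity, since VPD is a
#' convex function of temperature), and integrates radiation over the day
#' to a water-equivalent depth. Days with fewer readings than
#' `coverage * expected_per_day` are emitted but flagged.
#'
#' @param records data frame with columns `timestamp` (POSIXct or anything
#'   `as.POSIXct()` accepts), `rs` (instantaneous radiation rate,
#'   MJ m^-2 d^-1), `ta` (degrees C), `rh` (percent), `w` (m s^-1).
#' @param expected_per_day expected readings per day (48 for 30-minute
#'   logging).
#' @param coverage minimum fraction of expected readings for an unflagged
#'   day. Default 0.8.
#' @return Data frame with columns `date`, `dar`, `ta`, `vpd`, `w`,
#'   `n_readings`, `low_coverage`.
#' @export
aggregate_daily <- function(records, expected_per_day = 48, coverage = 0.8) {
  if (nrow(records) == 0)
    return(data.frame(date = as.Date(character()), dar = numeric(),
                      ta = numeric(), vpd = numeric(), w = numeric(),
                      n_readings = integer(), low_coverage = logical()))
  check_columns(records, c("timestamp", "rs", "ta", "rh", "w"), "records")
  ts <- tryCatch(as.POSIXct(records$timestamp, tz = "UTC"),
                 error = function(e) stop_param("unparseable timestamps: ",
                                                conditionMessage(e)))
  if (anyNA(ts)) stop_param("unparseable timestamps at row(s) ",
                            paste(utils::head(which(is.na(ts)), 5),
                                  collapse = ", "))
  day <- as.Date(ts)
  vpd <- vpd_from_ta_rh(records$ta, records$rh)
  out <- do.call(rbind, lapply(split(seq_along(day), day), function(idx) {
    n <- length(idx)
    # rs is a rate in MJ m^-2 d^-1; the mean rate over the sampled fraction
    # of the day integrates to mean(rs) * (n / expected_per_day) MJ m^-2
    rs_total <- mean(records$rs[idx]) * n / expected_per_day
    data.frame(dar = radiation_to_dar(rs_total),
               ta = mean(records$ta[idx]),
               vpd = mean(vpd[idx]),
               w = mean(records$w[idx]),
               n_readings = n,
               low_coverage = n < coverage * expected_per_day)
  }))
  out <- cbind(date = as.Date(rownames(out)), out)
  rownames(out) <- NULL
  out[order(out$date), c("date", "dar", "ta", "vpd", "w", "n_readings",
                         "low_coverage")]
}
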