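#' Daily transpiration from consecutive morning weighing records
#'
#' Applies the lysimeter mass balance
#' `Td_i = W_i + I_i - R_i - W_{i+1}`: the water transpired on day *i* is
#' the morning system mass plus irrigation minus return flow minus the next
#' morning's mass. Surface evaporation is taken as zero (the substrate is
#' film-wrapped). Negative results (condensation or weighing error) are
#' clipped to zero and flagged `"negative_clipped"`.
#'
#' @param records data frame of consecutive morning records with columns
#'   `date` (Date or integer day index), `w_morning`, `irrigation`,
#'   `return_flow` (kg). `n` records yield `n - 1` transpiration days.
#' @param plant_density optional planting density (plants m^-2); when
#'   given, `tm_depth` (mm d^-1) is added via [mass_to_depth()].
#' @return Data frame with columns `date`, `td_mass` (kg plant^-1), `flag`
#'   (`"ok"` or `"negative_clipped"`), and `tm_depth` if `plant_density`
#'   was supplied.
#' @examples
#' rec <- data.frame(date = 1:2, w_morning = c(52.40, 51.80),
#'                   irrigation = c(1.50, 0), return_flow = c(0.20, 0))
#' daily_transpiration(rec)  # td_mass = 1.90 kg
#' @export
daily_transpiration <- function(records, plant_density = NULL) {
  check_columns(records, c("date", "w_morning", "irrigation", "return_flow"),
                "records")
  if (nrow(records) < 2)
    stop_param("need at least two consecutive morning records")
  check_consecutive(records$date)
  n <- nrow(records)
  i <- seq_len(n - 1)
  td <- records$w_morning[i] + records$irrigation[i] -
    records$return_flow[i] - records$w_morning[i + 1]
  flag <- ifelse(td < 0, "negative_clipped", "ok")
  out <- data.frame(date = records$date[i], td_mass = pmax(td, 0),
                    flag = flag)
  if (!is.null(plant_density))
    out$tm_depth <- mass_to_depth(out$td_mass, plant_density)
  out
}

#' Convert per-plant water mass to an areal depth
#'
#' `tm = td_mass * plant_density`: 1 kg of water spread over 1 m^2 is 1 mm
#' of depth, so mass per plant times plants per square metre gives
#' mm d^-1.
#'
#' @param td_mass transpired mass (kg plant^-1).
#' @param plant_density planting density (plants m^-2), > 0.
#' @return Depth in mm d^-1. Vectorized in `td_mass`.
#' @export
mass_to_depth <- function(td_mass, plant_density) {
  check_number(plant_density, "plant_density", lower = 0, strict_lower = TRUE)
  if (!is.numeric(td_mass) || anyNA(td_mass))
    stop_param("`td_mass` must be numeric")
  td_mass * plant_density
}

#' Default planting density of the wide/narrow-row layout
#'
#' One plant per 0.7 m x 0.3 m of ground (mean row spacing of a 1 m wide /
#' 0.4 m narrow double-row layout, 0.3 m in-row spacing): about 4.76
#' plants m^-2.
#'
#' @return plants m^-2.
#' @export
default_plant_density <- function() 1 / (0.7 * 0.3)

#' Water use efficiency
#'
#' `WUE = Ya / T`: harvested yield per unit water consumed.
#'
#' @param yield_per_plant yield (kg plant^-1), >= 0.
#' @param water_consumption seasonal water consumption (m^3 plant^-1), > 0.
#' @return WUE in kg m^-3.
#' @export
wue <- function(yield_per_plant, water_consumption) {
  if (!is.numeric(water_consumption) || anyNA(water_consumption) ||
      any(water_consumption <= 0))
    stop_param("`water_consumption` must be > 0")
  if (!is.numeric(yield_per_plant) || anyNA(yield_per_plant) ||
      any(yield_per_plant < 0))
    stop_param("`yield_per_plant` must be >= 0")
  yield_per_plant / water_consumption
}

#' Signed percent change between two values
#'
#' `100 * (value - reference) / denominator`, with the denominator chosen as
#' either the reference (the usual "changed by x% relative to reference")
#' or the value itself (used for year-on-year comparisons expressed
#' relative to the later value). Sign is preserved; rounding is left to the
#' caller.
#'
#' @param reference baseline value.
#' @param value comparison value.
#' @param denominator `"reference"` (default) or `"value"`.
#' @return Percent change (numeric). Vectorized.
#' @examples
#' percent_change(1.28, 1.14)                         # -10.94
#' percent_change(40.83, 31.39, denominator = "value") # -30.07
#' @export
percent_change <- function(reference, value,
                           denominator = c("reference", "value")) {
  denominator <- match.arg(denominator)
  den <- if (denominator == "reference") reference else value
  if (any(den == 0)) stop_param("chosen denominator is zero")
  100 * (value - reference) / den
}

#' Irrigation trigger decision
#'
#' Deficit-irrigation rule: irrigate when the substrate water store has
#' fallen strictly below `lower_limit_frac` of the water-holding capacity
#' (the treatment lower limits are 80 %, 70 % and 60 % for T1, T2, T3);
#' the refill brings the store back to capacity. The boundary case
#' `store == limit` holds (strict inequality).
#'
#' @param store current substrate water store (kg).
#' @param capacity substrate water-holding capacity (kg), > 0.
#' @param lower_limit_frac trigger fraction, in (0, 1].
#' @return List with `decision` (`"irrigate"` or `"hold"`) and `refill`
#'   (kg, 0 when holding).
#' @export
irrigation_trigger <- function(store, capacity, lower_limit_frac) {
  check_number(capacity, "capacity", lower = 0, strict_lower = TRUE)
  check_number(lower_limit_frac, "lower_limit_frac", lower = 0, upper = 1,
               strict_lower = TRUE)
  check_number(store, "store", lower = 0)
  if (store < lower_limit_frac * capacity)
    list(decision = "irrigate", refill = capacity - store)
  else
    list(decision = "hold", refill = 0)
}

#' Percent-change comparison of yield and WUE across irrigation treatments
#'
#' Recomputes, from the packaged yield / water-use-efficiency table, the
#' deficit treatments' changes relative to the wettest treatment T1:
#' yield per plant, total yield and WUE for T2 and T3 in each year
#' (denominator = T1), plus the year-on-year WUE decrease for each
#' treatment expressed relative to the later year's value.
#'
#' @param yield_table optional replacement for the packaged table (columns
#'   `year`, `treatment`, `yield_per_plant`, `yield_total`, `wue`).
#' @return Data frame with columns `year`, `treatment`, `quantity`,
#'   `pct_change` (signed) and `pct_vs` (the comparison baseline).
#' @export
yield_wue_changes <- function(yield_table = published_yield_wue()) {
  check_columns(yield_table,
                c("year", "treatment", "yield_per_plant", "yield_total",
                  "wue"), "yield_table")
  rows <- list()
  for (yr in unique(yield_table$year)) {
    tab <- yield_table[yield_table$year == yr, ]
    ref <- tab[tab$treatment == "T1", ]
    for (tr in c("T2", "T3")) {
      cur <- tab[tab$treatment == tr, ]
      for (q in c("yield_per_plant", "yield_total", "wue")) {
        rows[[length(rows) + 1]] <- data.frame(
          year = yr, treatment = tr, quantity = q,
          pct_change = percent_change(ref[[q]], cur[[q]]),
          pct_vs = "T1")
      }
    }
  }
  yrs <- sort(unique(yield_table$year))
  if (length(yrs) == 2) {
    for (tr in unique(yield_table$treatment)) {
      w1 <- yield_table$wue[yield_table$year == yrs[1] &
                              yield_table$treatment == tr]
      w2 <- yield_table$wue[yield_table$year == yrs[2] &
                              yield_table$treatment == tr]
      rows[[length(rows) + 1]] <- data.frame(
        year = yrs[2], treatment = tr, quantity = "wue",
        pct_change = percent_change(w1, w2, denominator = "value"),
        pct_vs = paste0("same treatment, ", yrs[1]))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
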