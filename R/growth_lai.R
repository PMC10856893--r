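#' Single-leaf area from length and maximum width
#'
#' `area = length * width * 0.64`: the rectangle spanned by leaf length and
#' maximum width, shrunk by the reduction coefficient 0.64 for the tomato
#' leaf outline.
#'
#' @param length leaf length (cm), >= 0.
#' @param max_width maximum leaf width (cm), >= 0.
#' @param coef reduction coefficient. Default 0.64.
#' @return Leaf area (cm^2). Vectorized.
#' @export
leaf_area <- function(length, max_width, coef = 0.64) {
  if (!is.numeric(length) || !is.numeric(max_width) || anyNA(length) ||
      anyNA(max_width) || any(length < 0) || any(max_width < 0))
    stop_param("leaf dimensions must be non-negative numeric")
  length * max_width * coef
}

#' Leaf area index of one plant
#'
#' Sums single-leaf areas (cm^2, converted to m^2) and divides by the
#' ground area allotted to the plant. Dimensions enter in cm and the
#' conversion to m^2 is explicit here, so no silent factor-10^4 error can
#' slip through the schema.
#'
#' @param leaves data frame or matrix with columns `length` and `width`
#'   (cm); zero rows give LAI 0.
#' @param ground_area_per_plant ground area per plant (m^2), > 0. The
#'   default layout value is `1 / default_plant_density()` (0.21 m^2).
#' @return LAI (m^2 m^-2).
#' @export
lai_from_plant <- function(leaves,
                           ground_area_per_plant = 1 / default_plant_density()) {
  check_number(ground_area_per_plant, "ground_area_per_plant", lower = 0,
               strict_lower = TRUE)
  leaves <- as.data.frame(leaves)
  if (nrow(leaves) == 0) return(0)
  check_columns(leaves, c("length", "width"), "leaves")
  area_m2 <- sum(leaf_area(leaves$length, leaves$width)) * 1e-4
  area_m2 / ground_area_per_plant
}

#' Interpolate periodic LAI measurements to daily resolution
#'
#' Shape-preserving piecewise cubic Hermite interpolation (PCHIP) through
#' the measured (day, LAI) knots, evaluated at every integer day in the
#' measured range. The interpolant passes through all knots exactly and
#' does not overshoot the local data range on monotone segments, so a
#' rising-then-plateauing LAI record stays within its measured ceiling.
#' Extrapolation outside the measured range is refused.
#'
#' @param measurements data frame with columns `day` and `lai`, at least
#'   two rows, strictly increasing days.
#' @param at integer days at which to evaluate; default every integer day
#'   from the first to the last measurement.
#' @return Data frame with columns `day` and `lai`.
#' @export
interpolate_daily_lai <- function(measurements,
                                  at = seq(ceiling(min(measurements$day)),
                                           floor(max(measurements$day)))) {
  check_columns(measurements, c("day", "lai"), "measurements")
  d <- measurements$day
  if (anyDuplicated(d))
    stop_param("duplicate measurement days: ",
               paste(unique(d[duplicated(d)]), collapse = ", "))
  if (length(d) < 2)
    stop_param("need at least two measurements to interpolate")
  if (is.unsorted(d, strictly = TRUE))
    stop_param("`day` must be strictly increasing")
  if (any(at < min(d)) || any(at > max(d)))
    stop_param("refusing to extrapolate outside the measured day range [",
               min(d), ", ", max(d), "]")
  # two knots define a straight segment (the shape-preserving limit);
  # pracma's PCHIP needs at least three
  lai <- if (length(d) == 2)
    stats::approx(d, measurements$lai, xout = at)$y
  else pracma::pchip(d, measurements$lai, at)
  data.frame(day = at, lai = lai)
}
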