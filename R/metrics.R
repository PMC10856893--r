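#' Model-evaluation statistics for a simulated vs measured series
#'
#' Computes the standard accuracy statistics for paired daily series:
#' mean absolute error `MAE = mean(|T - M|)`, root-mean-square error
#' `RMSE = sqrt(mean((T - M)^2))`, mean relative error
#' `MRE = 100 * mean(|T - M| / M)` (percent), Nash-Sutcliffe efficiency
#' `NSE = 1 - sum((T - M)^2) / sum((M - mean(M))^2)`, and the coefficient
#' of determination R^2 of the ordinary least-squares fit of simulated on
#' measured. MRE uses the absolute error and NSE the squared sums: these
#' are the standard definitions, which the value ranges of typical reports
#' (MRE in percent, NSE between 0 and 1) imply.
#'
#' @param simulated simulated series (mm d^-1).
#' @param measured measured series, same length, n >= 2; must not be
#'   constant (NSE undefined).
#' @return Object of class `"metrics_report"`: list with `n`, `mae`,
#'   `rmse`, `mre`, `nse`, `r2` and `mre_flag` (`TRUE` when zero measured
#'   values made MRE undefined, reported as `NA`).
#' @examples
#' compute_metrics(c(2, 2), c(1, 3))  # MAE 1, RMSE 1, MRE 66.67, NSE 0
#' @export
compute_metrics <- function(simulated, measured) {
  n <- length(measured)
  if (length(simulated) != n) stop_param("series lengths differ")
  if (n < 2) stop_param("need at least 2 paired observations")
  if (anyNA(simulated) || anyNA(measured))
    stop_param("series must not contain NA")
  if (stats::sd(measured) == 0)
    stop_param("measured series is constant; NSE undefined")
  err <- simulated - measured
  mre_flag <- any(measured == 0)
  mre <- if (mre_flag) NA_real_ else 100 * mean(abs(err) / measured)
  ss_res <- sum(err^2)
  ss_m <- sum((measured - mean(measured))^2)
  r2 <- if (stats::sd(simulated) == 0) NA_real_
        else suppressWarnings(
          summary(stats::lm(simulated ~ measured))$r.squared)
  structure(list(n = n, mae = mean(abs(err)), rmse = sqrt(mean(err^2)),
                 mre = mre, nse = 1 - ss_res / ss_m, r2 = r2,
                 mre_flag = mre_flag),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "n = %d  MAE = %.2f  RMSE = %.2f  MRE = %s%%  NSE = %.2f  R2 = %.2f\n",
    x$n, x$mae, x$rmse,
    if (is.na(x$mre)) "NA" else sprintf("%.2f", x$mre), x$nse, x$r2))
  invisible(x)
}

#' Side-by-side comparison of model accuracy reports
#'
#' Collates [compute_metrics()] reports into a stage-by-model table with
#' MRE / MAE / RMSE / NSE columns and marks, within each stage, the best
#' model per column (lowest error, highest NSE).
#'
#' @param reports named list of `metrics_report` objects (names are the
#'   model labels).
#' @param stage optional character vector (recycled) assigning each report
#'   to a stage; default a single unnamed stage.
#' @return Data frame with columns `stage`, `model`, `mre`, `mae`, `rmse`,
#'   `nse` and `best` (comma-separated column names on which that model is
#'   the stage's best).
#' @export
compare_models <- function(reports, stage = "all") {
  if (length(reports) < 1) stop_param("need at least one report")
  if (is.null(names(reports)) || any(names(reports) == ""))
    stop_param("`reports` must be a named list")
  stage <- rep_len(stage, length(reports))
  tab <- do.call(rbind, Map(function(r, m, s) {
    data.frame(stage = s, model = m, mre = r$mre, mae = r$mae,
               rmse = r$rmse, nse = r$nse)
  }, reports, names(reports), stage))
  rownames(tab) <- NULL
  tab$best <- ""
  for (s in unique(tab$stage)) {
    idx <- which(tab$stage == s)
    marks <- rep("", length(idx))
    for (col in c("mre", "mae", "rmse", "nse")) {
      v <- tab[[col]][idx]
      if (all(is.na(v))) next
      winner <- if (col == "nse") which.max(v) else which.min(v)
      marks[winner] <- paste(c(marks[winner][marks[winner] != ""], col),
                             collapse = ",")
    }
    tab$best[idx] <- marks
  }
  tab
}
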