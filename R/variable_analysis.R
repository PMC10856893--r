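#' Pearson correlation of each predictor with the response
#'
#' Standard Pearson r with the two-sided t-test p-value,
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' Constant columns are flagged and get `NA` for r and p.
#'
#' @param X data frame or matrix of predictors (columns named).
#' @param y response vector, same length as `nrow(X)`.
#' @return Data frame with columns `variable`, `r`, `p`, `constant`.
#' @export
pearson_with_response <- function(X, y) {
  X <- as.data.frame(X)
  n <- nrow(X)
  if (n < 3) stop_param("need at least 3 observations")
  if (length(y) != n) stop_param("`y` must match nrow(X)")
  res <- lapply(names(X), function(v) {
    x <- X[[v]]
    if (stats::sd(x) == 0)
      return(data.frame(variable = v, r = NA_real_, p = NA_real_,
                        constant = TRUE))
    r <- stats::cor(x, y)
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    data.frame(variable = v, r = r,
               p = 2 * stats::pt(-abs(tt), df = n - 2), constant = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Path analysis of a response on correlated predictors
#'
#' Decomposes each predictor's Pearson correlation with the response into a
#' direct effect (its standardized partial regression coefficient) and
#' indirect effects routed through the other predictors. Direct
#' coefficients `P` solve the normal equations on the correlation scale,
#' `R_xx P = r_xy`; the indirect effect of variable *i* via variable *j*
#' is `r_ij * P_j`. For full-rank data the decomposition identity
#' `r_i = P_i + sum_j indirect_ij` holds to numerical precision.
#' Standardization uses the sample standard deviation (n - 1 denominator).
#'
#' @param X data frame or matrix of predictors, `n > ncol(X)` rows.
#' @param y response vector.
#' @return An object of class `"path_result"`: list with `variables`,
#'   `direct`, `indirect` (square matrix, zero diagonal), `indirect_sum`,
#'   `correlation`, `p_values`, `n`.
#' @export
path_analysis <- function(X, y) {
  X <- as.data.frame(X)
  p <- ncol(X)
  n <- nrow(X)
  if (n <= p) stop_param("need more observations than predictors")
  const <- vapply(X, function(x) stats::sd(x) == 0, logical(1))
  if (any(const))
    stop_param("constant predictor(s): ",
               paste(names(X)[const], collapse = ", "))
  Rxx <- stats::cor(X)
  rxy <- drop(stats::cor(as.matrix(X), y))
  ev <- eigen(Rxx, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10) {
    cc <- which(abs(Rxx) > 0.9999 & upper.tri(Rxx), arr.ind = TRUE)
    offending <- if (nrow(cc)) {
      paste(apply(cc, 1, function(ij)
        paste(colnames(Rxx)[ij], collapse = " ~ ")), collapse = "; ")
    } else paste(names(X), collapse = ", ")
    stop_param("predictor correlation matrix is singular ",
               "(multicollinearity): ", offending)
  }
  direct <- drop(solve(Rxx, rxy))
  indirect <- Rxx * rep(direct, each = p)  # entry (i, j) = r_ij * P_j
  diag(indirect) <- 0
  cor_tab <- pearson_with_response(X, y)
  structure(list(variables = names(X), direct = stats::setNames(direct, names(X)),
                 indirect = indirect,
                 indirect_sum = stats::setNames(rowSums(indirect), names(X)),
                 correlation = stats::setNames(rxy, names(X)),
                 p_values = stats::setNames(cor_tab$p, names(X)), n = n),
            class = "path_result")
}

#' @export
print.path_result <- function(x, digits = 3, ...) {
  stars <- ifelse(x$p_values < 0.01, "**",
                  ifelse(x$p_values < 0.05, "*", ""))
  tab <- data.frame(direct = round(x$direct, digits),
                    indirect_sum = round(x$indirect_sum, digits),
                    r = paste0(round(x$correlation, digits), " ", stars))
  cat("Path analysis (n = ", x$n, ")\n", sep = "")
  print(tab, ...)
  invisible(x)
}

#' Rank drivers by absolute correlation with the response
#'
#' Orders the screened variables from strongest to weakest absolute
#' Pearson correlation, the screening rule used to pick each stage's model
#' drivers. Ties are broken alphabetically and flagged.
#'
#' @param result a [path_result][path_analysis()] object, or anything with
#'   named `correlation` entries.
#' @return Character vector of variable names, strongest first; attribute
#'   `"ties"` is `TRUE` when any absolute correlations were tied.
#' @export
rank_drivers <- function(result) {
  r <- if (inherits(result, "path_result")) result$correlation
       else result
  if (is.null(names(r))) stop_param("correlations must be named")
  a <- abs(r)
  ord <- order(-a, names(r))
  out <- names(r)[ord]
  attr(out, "ties") <- anyDuplicated(a) > 0
  out
}
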