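#' Decision matrix for multi-criteria treatment ranking
#'
#' Alternatives (irrigation treatments) by criteria (yield, WUE and
#' fruit-quality indicators), with a benefit/cost direction per criterion.
#'
#' @param values numeric matrix or data frame, alternatives in rows,
#'   criteria in columns, all values > 0.
#' @param alternatives row (alternative) names; default taken from rownames.
#' @param criteria column (criterion) names; default taken from colnames.
#' @param directions per-criterion `"benefit"` (higher is better) or
#'   `"cost"`; default all benefit.
#' @return Object of class `"decision_matrix"` (numeric matrix with a
#'   `directions` attribute).
#' @export
decision_matrix <- function(values, alternatives = rownames(values),
                            criteria = colnames(values),
                            directions = rep("benefit", ncol(values))) {
  m <- as.matrix(values)
  storage.mode(m) <- "double"
  if (anyNA(m) || any(m <= 0))
    stop_param("decision matrix values must be positive numbers")
  if (nrow(m) < 2) stop_param("need at least 2 alternatives")
  if (ncol(m) < 1) stop_param("need at least 1 criterion")
  if (is.null(alternatives)) alternatives <- paste0("A", seq_len(nrow(m)))
  if (is.null(criteria)) criteria <- paste0("C", seq_len(ncol(m)))
  directions <- match.arg(directions, c("benefit", "cost"),
                          several.ok = TRUE)
  if (length(directions) != ncol(m))
    stop_param("`directions` must have one entry per criterion")
  dimnames(m) <- list(alternatives, criteria)
  structure(m, directions = directions, class = c("decision_matrix",
                                                  "matrix", "array"))
}

#' Normalize a decision matrix
#'
#' `"vector"`: each column divided by its Euclidean norm (directions are
#' handled later, at ideal-point selection). `"minmax"`: benefit columns
#' mapped by `(x - min) / (max - min)`, cost columns inverted by
#' `(max - x) / (max - min)` so that after normalization every column is a
#' benefit.
#'
#' @param matrix a [decision_matrix()].
#' @param method `"vector"` (default) or `"minmax"`.
#' @return Normalized matrix with the (possibly updated) `directions`
#'   attribute.
#' @export
topsis_normalize <- function(matrix, method = c("vector", "minmax")) {
  method <- match.arg(method)
  if (!inherits(matrix, "decision_matrix"))
    stop_param("`matrix` must be a decision_matrix()")
  dirs <- attr(matrix, "directions")
  m <- unclass(matrix)
  if (method == "vector") {
    norms <- sqrt(colSums(m^2))
    if (any(norms == 0)) stop_param("zero column norm")
    out <- sweep(m, 2, norms, "/")
  } else {
    rng <- apply(m, 2, range)
    if (any(rng[2, ] == rng[1, ]))
      stop_param("constant column under minmax normalization")
    out <- sweep(sweep(m, 2, rng[1, ], "-"), 2, rng[2, ] - rng[1, ], "/")
    cost <- dirs == "cost"
    out[, cost] <- 1 - out[, cost]
    dirs <- rep("benefit", ncol(m))
  }
  structure(out, directions = dirs, class = class(matrix))
}

#' Shannon-entropy criterion weights
#'
#' Weights criteria by their discriminating power: columns whose values
#' differ strongly across alternatives carry low entropy and get high
#' weight. With proportions `p_ij = x_ij / sum_i x_ij`, entropy
#' `e_j = -sum_i p_ij ln p_ij / ln(m)` and divergence `d_j = 1 - e_j`, the
#' weights are `w_j = d_j / sum_j d_j`. A fully non-discriminating matrix
#' (all divergences ~ 0) falls back to uniform weights with a
#' `"degenerate"` attribute.
#'
#' @param normalized non-negative matrix (typically a normalized decision
#'   matrix).
#' @return Named weight vector, non-negative, summing to 1.
#' @export
entropy_weights <- function(normalized) {
  m <- as.matrix(normalized)
  if (anyNA(m) || any(m < 0)) stop_param("values must be non-negative")
  nalt <- nrow(m)
  p <- sweep(m, 2, colSums(m), "/")
  plogp <- ifelse(p > 0, p * log(p), 0)
  e <- -colSums(plogp) / log(nalt)
  d <- 1 - e
  if (all(d < 1e-12)) {
    w <- rep(1 / ncol(m), ncol(m))
    names(w) <- colnames(m)
    attr(w, "degenerate") <- TRUE
    return(w)
  }
  w <- d / sum(d)
  names(w) <- colnames(m)
  attr(w, "degenerate") <- FALSE
  w
}

#' TOPSIS ranking of alternatives
#'
#' Technique for Order Preference by Similarity to Ideal Solution: the
#' normalized decision matrix is weighted, the ideal point takes each
#' criterion's best value (maximum for benefit, minimum for cost) and the
#' anti-ideal its worst; each alternative's Euclidean distances `D+` and
#' `D-` to the two points give the closeness index `Ci = D- / (D+ + D-)`,
#' and alternatives are ranked by `Ci` descending (rank 1 = best, ties get
#' the minimum rank).
#'
#' @param matrix a [decision_matrix()].
#' @param weights per-criterion weights, non-negative, summing to 1;
#'   default equal weights.
#' @param normalize normalization method passed to [topsis_normalize()].
#' @return Object of class `"topsis_result"`: data frame with columns
#'   `alternative`, `d_plus`, `d_minus`, `ci`, `rank`.
#' @examples
#' m <- decision_matrix(rbind(T1 = c(1.28, 38.18), T2 = c(1.14, 40.83)),
#'                      criteria = c("yield", "wue"))
#' topsis(m)
#' @export
topsis <- function(matrix, weights = NULL,
                   normalize = c("vector", "minmax")) {
  normalize <- match.arg(normalize)
  nm <- topsis_normalize(matrix, normalize)
  dirs <- attr(nm, "directions")
  k <- ncol(nm)
  if (is.null(weights)) weights <- rep(1 / k, k)
  if (length(weights) != k || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8)
    stop_param("`weights` must be non-negative and sum to 1")
  v <- sweep(unclass(nm), 2, weights, "*")
  ideal <- ifelse(dirs == "benefit", apply(v, 2, max), apply(v, 2, min))
  anti <- ifelse(dirs == "benefit", apply(v, 2, min), apply(v, 2, max))
  d_plus <- sqrt(rowSums(sweep(v, 2, ideal)^2))
  d_minus <- sqrt(rowSums(sweep(v, 2, anti)^2))
  if (any(d_plus + d_minus == 0))
    stop_param("degenerate decision matrix: alternatives indistinguishable")
  ci <- d_minus / (d_plus + d_minus)
  out <- data.frame(alternative = rownames(nm), d_plus = d_plus,
                    d_minus = d_minus, ci = ci,
                    rank = rank(-ci, ties.method = "min"))
  rownames(out) <- NULL
  class(out) <- c("topsis_result", "data.frame")
  out
}

#' Ranking report table
#'
#' Formats a [topsis()] result as the conventional report table, ordered
#' by rank, flagging ties in the closeness index.
#'
#' @param result a `topsis_result`.
#' @return Data frame with columns `alternative`, `d_plus`, `d_minus`,
#'   `ci`, `rank`, `tie`.
#' @export
rank_report <- function(result) {
  if (!inherits(result, "topsis_result"))
    stop_param("`result` must come from topsis()")
  out <- as.data.frame(result)
  out$tie <- duplicated(out$ci) | duplicated(out$ci, fromLast = TRUE)
  out[order(out$rank), ]
}
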