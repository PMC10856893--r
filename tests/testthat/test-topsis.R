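# Independent spreadsheet-style TOPSIS oracle: explicit loops, no reuse of
# the package's vectorized implementation.
topsis_oracle <- function(m, directions = rep("benefit", ncol(m))) {
  nr <- nrow(m); nc <- ncol(m)
  nm <- m
  for (j in seq_len(nc)) {
    norm <- sqrt(sum(m[, j]^2))
    for (i in seq_len(nr)) nm[i, j] <- m[i, j] / norm * (1 / nc)
  }
  dp <- dm <- numeric(nr)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      best <- if (directions[j] == "benefit") max(nm[, j]) else min(nm[, j])
      worst <- if (directions[j] == "benefit") min(nm[, j]) else max(nm[, j])
      dp[i] <- dp[i] + (nm[i, j] - best)^2
      dm[i] <- dm[i] + (nm[i, j] - worst)^2
    }
    dp[i] <- sqrt(dp[i]); dm[i] <- sqrt(dm[i])
  }
  list(d_plus = dp, d_minus = dm, ci = dm / (dp + dm))
}

test_that("normalizations reproduce hand values", {
  m <- decision_matrix(cbind(c(3, 4)), criteria = "x",
                       alternatives = c("A", "B"))
  expect_equal(unclass(topsis_normalize(m))[, 1], c(A = 0.6, B = 0.8))
  m3 <- decision_matrix(cbind(c(1, 2, 3)), criteria = "x")
  expect_equal(unname(unclass(topsis_normalize(m3, "minmax"))[, 1]),
               c(0, 0.5, 1))
  mc <- decision_matrix(cbind(c(1, 2, 3)), criteria = "x",
                        directions = "cost")
  expect_equal(unname(unclass(topsis_normalize(mc, "minmax"))[, 1]),
               c(1, 0.5, 0))
  const <- decision_matrix(cbind(c(2, 2, 2)), criteria = "x")
  expect_error(topsis_normalize(const, "minmax"), "constant")
})

test_that("entropy weights follow discriminating power and sum to one", {
  m <- matrix(c(1, 1, 1, 2, 2, 2), 3)
  w <- entropy_weights(m)
  expect_equal(as.vector(w), c(0.5, 0.5))
  expect_true(attr(w, "degenerate"))
  m2 <- matrix(c(10, 0.1, 0.1, 2, 2, 2), 3)  # first column discriminates
  w2 <- entropy_weights(m2)
  expect_equal(as.vector(w2), c(1, 0))
  set.seed(20)
  for (rep in 1:10) {
    w3 <- entropy_weights(matrix(runif(12, 0.1, 1), 3))
    expect_lt(abs(sum(w3) - 1), 1e-12)
    expect_true(all(w3 >= 0))
  }
})

test_that("a dominating alternative gets closeness 1, the dominated 0", {
  m <- decision_matrix(rbind(A = c(5, 9, 3), B = c(4, 7, 2)))
  res <- topsis(m)
  expect_equal(res$ci, c(1, 0))
  expect_equal(res$rank, c(1L, 2L))
})

test_that("published indicator matrices rank T2 > T3 > T1 in both years", {
  for (yr in c(2022, 2023)) {
    dm <- indicator_matrix(yr)
    res <- topsis(dm)
    expect_equal(res$alternative, c("T1", "T2", "T3"))
    expect_equal(res$rank, c(3L, 1L, 2L))
    expect_equal(res$rank,
                 published_topsis()$rank[published_topsis()$year == yr])
    oracle <- topsis_oracle(unclass(dm))
    expect_equal(res$ci, oracle$ci, tolerance = 1e-12)
    expect_equal(res$d_plus, oracle$d_plus, tolerance = 1e-12)
    expect_equal(res$d_minus, oracle$d_minus, tolerance = 1e-12)
  }
})

test_that("reversing every criterion direction swaps the two distances", {
  dm <- indicator_matrix(2022)
  res_b <- topsis(dm)
  dm_cost <- decision_matrix(unclass(dm),
                             directions = rep("cost", ncol(dm)))
  res_c <- topsis(dm_cost)
  expect_equal(res_c$d_plus, res_b$d_minus, tolerance = 1e-12)
  expect_equal(res_c$d_minus, res_b$d_plus, tolerance = 1e-12)
  expect_equal(res_c$ci, 1 - res_b$ci, tolerance = 1e-12)
})

test_that("vector-normalized ranking is invariant to column scaling", {
  dm <- indicator_matrix(2023)
  m2 <- unclass(dm)
  m2[, "vc"] <- m2[, "vc"] * 1000
  dm2 <- decision_matrix(m2)
  expect_equal(topsis(dm2)$ci, topsis(dm)$ci, tolerance = 1e-12)
})

test_that("ties share the minimum rank and are flagged in the report", {
  m <- decision_matrix(rbind(A = c(1, 2), B = c(2, 1), C = c(2, 2)))
  res <- topsis(m)
  rep <- rank_report(res)
  expect_equal(sort(res$rank), c(1L, 2L, 2L))
  expect_true(all(rep$tie[rep$rank == 2]))
  expect_false(any(rep$tie[rep$rank == 1]))
  ident <- matrix(1:6, 2, 3, byrow = FALSE)
  expect_error(topsis(decision_matrix(rbind(A = c(1, 2), B = c(1, 2)))),
               "degenerate")
})

test_that("decision matrix validation rejects bad inputs", {
  expect_error(decision_matrix(rbind(A = c(1, -2), B = c(2, 1))),
               "positive")
  expect_error(decision_matrix(rbind(A = c(1, 2))), "2 alternatives")
  expect_error(decision_matrix(rbind(A = c(1, 2), B = c(2, 1)),
                               directions = "benefit"),
               "one entry per criterion")
})
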