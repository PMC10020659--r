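test_that("interval transform matches the closed forms", {
  tr <- transform_interval(c(6.0, 6.5, 6.8), 7, 8)
  expect_equal(tr$values, c(0.0, 0.5, 0.8))
  expect_equal(tr$params$scale, 1)
  expect_equal(tr$params$observed_min, 6.0)

  # the minimum always scores 0 when everything sits below the range
  x <- c(5.2, 6.1, 6.9)
  expect_equal(transform_interval(x, 7, 8)$values[which.min(x)], 0)

  # inside the optimum range scores exactly 1
  expect_equal(transform_interval(c(6, 7, 7.5, 8), 7, 8)$values[2:4],
               c(1, 1, 1))

  # symmetric handling above the upper bound
  expect_equal(transform_interval(c(8.5, 9), 7, 8)$values, c(0.5, 0))

  # all inside: no division, all 1s
  expect_equal(transform_interval(c(7.1, 7.9), 7, 8)$values, c(1, 1))

  # all equal and outside: scale is that value's distance to the range
  tr <- transform_interval(c(5, 5), 7, 8)
  expect_equal(tr$params$scale, 2)
  expect_equal(tr$values, c(0, 0))

  expect_error(transform_interval(numeric(0), 7, 8), "empty")
  expect_error(transform_interval(c(6, 7), 8, 7), "lower_bound")
})

test_that("normalization behaves per method and names offending columns", {
  ind <- indicator_set(c("a", "b"), c("benefit", "cost"))
  dm <- decision_matrix(rbind(c(3, 1), c(4, 2)), ind)
  vn <- normalize_matrix(dm, "vector")
  expect_equal(unname(vn$values[, "a"]), c(0.6, 0.8))
  # idempotent on unit-norm columns
  expect_equal(normalize_matrix(vn, "vector")$values, vn$values)

  dm3 <- decision_matrix(cbind(c(1, 2, 3)), indicator_set("x", "benefit"))
  expect_equal(unname(normalize_matrix(dm3, "minmax")$values[, 1]),
               c(0, 0.5, 1))
  dmc <- decision_matrix(cbind(c(1, 2, 3)), indicator_set("x", "cost"))
  mm <- normalize_matrix(dmc, "minmax")
  expect_equal(unname(mm$values[, 1]), c(1, 0.5, 0))
  expect_equal(mm$indicators$direction, "benefit")

  dz <- decision_matrix(cbind(c(0, 0), c(1, 2)),
                        indicator_set(c("zeroes", "ok")))
  expect_error(normalize_matrix(dz, "vector"), "zeroes")
  dk <- decision_matrix(cbind(c(5, 5), c(1, 2)),
                        indicator_set(c("flat", "ok")))
  expect_error(normalize_matrix(dk, "minmax"), "flat")
})

test_that("ideal solutions follow indicator direction", {
  dm <- decision_matrix(rbind(c(0.6, 0.2), c(0.3, 0.4)),
                        indicator_set(c("a", "b")))
  id <- ideal_solutions(dm)
  expect_equal(unname(id$positive), c(0.6, 0.4))
  expect_equal(unname(id$negative), c(0.3, 0.2))

  dmc <- decision_matrix(cbind(c(0.1, 0.5)), indicator_set("c", "cost"))
  idc <- ideal_solutions(dmc)
  expect_equal(unname(idc$positive), 0.1)
  expect_equal(unname(idc$negative), 0.5)
})

test_that("distances are Euclidean against each ideal", {
  dm <- decision_matrix(rbind(c(0.6, 0.2), c(0.3, 0.4)),
                        indicator_set(c("a", "b")))
  id <- ideal_solutions(dm)
  d <- topsis_distances(dm, id$positive, id$negative)
  expect_equal(unname(d$d_plus), c(0.2, 0.3))
  # a row equal to the positive ideal has d_plus = 0
  dm2 <- decision_matrix(rbind(c(0.6, 0.4), c(0.3, 0.2)),
                         indicator_set(c("a", "b")))
  id2 <- ideal_solutions(dm2)
  expect_equal(unname(topsis_distances(dm2, id2$positive,
                                       id2$negative)$d_plus[1]), 0)
  # 1-D case reduces to the absolute difference
  dm1 <- decision_matrix(cbind(c(0.2, 0.7)), indicator_set("x"))
  id1 <- ideal_solutions(dm1)
  d1 <- topsis_distances(dm1, id1$positive, id1$negative)
  expect_equal(unname(d1$d_plus), c(0.5, 0))
})

test_that("closeness reproduces published distance pairs and edge cases", {
  expect_lt(abs(closeness(0.023, 0.106) - 0.821), 0.002)
  expect_equal(closeness(0.068, 0.068), 0.5)
  expect_equal(closeness(0, 0.3), 1)
  expect_error(closeness(0, 0), "undefined")
  expect_error(closeness(-0.1, 0.2), "non-negative")
})

test_that("ranking is closeness-descending with stable ties", {
  expect_equal(rank_by_closeness(c(0.821, 0.625, 0.357)), c(1L, 2L, 3L))
  expect_equal(rank_by_closeness(c(0.5, 0.5, 0.5)), c(1L, 2L, 3L))
  herb_ci <- c(0.625, 0.821, 0.357, 0.500, 0.419, 0.496, 0.452, 0.181)
  expect_equal(rank_by_closeness(herb_ci), c(2L, 1L, 7L, 3L, 6L, 4L, 5L, 8L))
})

test_that("run_topsis composes the stages coherently", {
  dm <- decision_matrix(rbind(a = c(1, 1), b = c(2, 2), c = c(3, 3)),
                        indicator_set(c("x", "y")))
  res <- run_topsis(dm)
  expect_true(all(diff(res$closeness) > 0))
  expect_equal(res$rank, c(3L, 2L, 1L))
  expect_equal(res$closeness,
               res$d_minus / (res$d_plus + res$d_minus))
  expect_true(all(res$closeness >= 0 & res$closeness <= 1))

  # identical rows: closeness undefined, error names the failing stage
  deg <- decision_matrix(rbind(c(1, 2), c(1, 2)), indicator_set(c("x", "y")))
  expect_error(run_topsis(deg), "closeness")

  # all weight on one indicator: ranking is that column, descending
  set.seed(7)
  col1 <- c(4, 1, 3, 2)
  dm4 <- decision_matrix(matrix(c(col1, runif(4)), ncol = 2),
                         indicator_set(c("main", "noise"), weight = c(1, 0)))
  expect_equal(run_topsis(dm4)$rank, as.integer(rank(-col1)))
})

test_that("entropy weighting rewards informative columns", {
  # constant column carries no information -> weight 0
  dm <- decision_matrix(cbind(c(2, 2, 2), c(1, 2, 3)),
                        indicator_set(c("flat", "vary")))
  expect_equal(unname(entropy_weights(dm)), c(0, 1))

  # 3x2 toy against a hand-evaluated entropy formula
  v <- cbind(c(1, 2, 3), c(5, 1, 4))
  dm2 <- decision_matrix(v, indicator_set(c("a", "b")))
  e <- numeric(2)
  for (j in 1:2) {
    r <- (v[, j] - min(v[, j])) / (max(v[, j]) - min(v[, j]))
    p <- r / sum(r)
    e[j] <- -sum(ifelse(p > 0, p * log(p), 0)) / log(3)
  }
  expect_equal(unname(entropy_weights(dm2)), (1 - e) / sum(1 - e),
               tolerance = 1e-12)

  flat <- decision_matrix(cbind(c(1, 1), c(2, 2)),
                          indicator_set(c("a", "b")))
  expect_error(entropy_weights(flat), "constant")
})

test_that("indicator and matrix validation enforce the contracts", {
  expect_error(indicator_set(c("a", "a")), "unique")
  expect_error(indicator_set("a", "sideways"), "direction")
  expect_error(indicator_set("a", "benefit", weight = -1), "non-negative")
  expect_error(indicator_set("pH", "interval"), "interval_low")
  expect_error(indicator_set("pH", "interval", interval_low = 8,
                             interval_high = 7), "exceed")
  ind <- indicator_set(c("a", "b"))
  expect_error(decision_matrix(rbind(c(1, 2)), ind), "at least 2")
  expect_error(decision_matrix(rbind(c(1, NA), c(2, 3)), ind), "finite")
  expect_error(decision_matrix(rbind(c(1, 2), c(2, 3)), ind,
                               treatments = c("t", "t")), "unique")
})
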