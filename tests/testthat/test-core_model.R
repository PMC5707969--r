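# Domain containers, mean normalization, zero-point imaging.

test_that("panel_matrix and panel_set validate their invariants", {
  expect_error(panel_matrix(matrix(c(1, NA), 1), "x"), "non-finite")
  expect_error(panel_matrix(matrix(1, 2, 2), "x", sample_labels = "only1"),
               "sample_labels")
  expect_error(panel_matrix(matrix(1, 2, 2), ""), "series_id")

  a <- panel_matrix(matrix(1:4, 2), "a")
  b <- panel_matrix(matrix(4:1, 2), "b")
  expect_error(panel_set(list(a)), "at least 2")
  expect_error(panel_set(list(a, a)), "duplicate series_id")
  expect_error(panel_set(list(a, panel_matrix(matrix(1:6, 2), "b"))),
               "shape")
  wrong_labels <- panel_matrix(matrix(4:1, 2), "b",
                               sample_labels = c("p", "q"))
  expect_error(panel_set(list(a, wrong_labels)), "labels")

  ps <- panel_set(list(a, b))
  expect_identical(series_ids(ps), c("a", "b"))
  expect_length(ps, 2L)
})

test_that("mean_normalize matches hand-computed examples", {
  # constant row maps to ones
  p <- panel_matrix(matrix(c(2, 2, 2, 2), 1), "c")
  expect_equal(unname(mean_normalize(p)$values[1, ]), rep(1, 4))
  # row [1,2,3]: mean 2
  p <- panel_matrix(matrix(c(1, 2, 3), 1), "r")
  expect_equal(unname(mean_normalize(p)$values[1, ]), c(0.5, 1.0, 1.5))
  # two rows normalized independently under row-mean scope
  p <- panel_matrix(matrix(c(1, 2, 3, 10, 20, 30), 2, byrow = TRUE), "r2")
  nv <- mean_normalize(p)$values
  expect_equal(unname(nv[1, ]), unname(nv[2, ]))
  # matrix-mean scope divides by the grand mean instead
  nm <- mean_normalize(p, scope = "matrix-mean")$values
  expect_equal(mean(nm), 1)
  expect_false(isTRUE(all.equal(unname(nm[1, ]), unname(nm[2, ]))))
})

test_that("zero-mean rows follow the configured policy", {
  p <- panel_matrix(matrix(c(0, 0, 0, 1, 2, 3), 2, byrow = TRUE), "z",
                    sample_labels = c("dead", "alive"))
  expect_equal(unname(mean_normalize(p)$values[1, ]), c(0, 0, 0))
  expect_equal(unname(mean_normalize(p)$values[2, ]), c(0.5, 1, 1.5))
  expect_error(mean_normalize(p, zero_row_policy = "error"), "dead")
  allzero <- panel_matrix(matrix(0, 2, 2), "z0")
  expect_error(mean_normalize(allzero, scope = "matrix-mean",
                              zero_row_policy = "error"), "zero")
  expect_equal(unname(mean_normalize(allzero, scope = "matrix-mean")$values),
               matrix(0, 2, 2))
})

test_that("mean_normalize is scale invariant and idempotent", {
  set.seed(101)
  for (rep in 1:20) {
    p <- random_panel(N = sample(1:6, 1), n = sample(1:6, 1))
    k <- stats::runif(1, 0.001, 1000)
    scaled <- panel_matrix(k * p$values, p$series_id)
    for (scope in c("row-mean", "matrix-mean")) {
      n1 <- mean_normalize(p, scope = scope)
      expect_equal(mean_normalize(scaled, scope = scope)$values, n1$values)
      # idempotence: scope means are 1 after the first pass
      expect_equal(mean_normalize(n1, scope = scope)$values, n1$values)
    }
    expect_equal(unname(rowMeans(mean_normalize(p)$values)),
                 rep(1, nrow(p$values)))
  }
})

test_that("zero_point_image subtracts each row's first value", {
  expect_equal(unname(zero_point_image(
    panel_matrix(matrix(c(5, 7, 6), 1), "x"))$values[1, ]), c(0, 2, 1))
  expect_equal(unname(zero_point_image(
    panel_matrix(matrix(c(1, 4, 2, 3), 2), "x"))$values),
    matrix(c(0, 0, 1, -1), 2))
  # constant rows vanish
  expect_equal(unname(zero_point_image(
    panel_matrix(matrix(3, 2, 4), "c"))$values), matrix(0, 2, 4))
  # translation invariance per row
  set.seed(7)
  p <- random_panel(3, 4)
  shifted <- panel_matrix(p$values + c(10, -2, 0.5), "x")
  expect_equal(zero_point_image(shifted)$values,
               zero_point_image(p)$values)
  # first column identically zero on random input
  expect_equal(unname(zero_point_image(p)$values[, 1]), rep(0, 3))
})
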