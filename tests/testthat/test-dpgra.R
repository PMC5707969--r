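# Distance field, dispersion statistic, cohort means, degrees, ranking.

test_that("distance_field is the entrywise absolute difference", {
  a <- panel_matrix(matrix(1, 2, 2), "a")
  b <- panel_matrix(matrix(c(0, 1, 1, 1), 2), "b")
  expect_equal(unname(distance_field(a, b)), matrix(c(1, 0, 0, 0), 2))
  expect_equal(distance_field(a, a), matrix(0, 2, 2,
               dimnames = dimnames(a$values)))
  expect_equal(unname(distance_field(b, a)), unname(distance_field(a, b)))
  expect_error(distance_field(a, panel_matrix(matrix(1, 2, 3), "c")),
               "shapes")
})

test_that("dispersion matches the hand-worked example and is symmetric", {
  a <- panel_matrix(matrix(1, 2, 2), "a")
  b <- panel_matrix(matrix(c(0, 1, 1, 1), 2), "b")
  rec <- dispersion(a, b)
  expect_s3_class(rec, "dispersion_record")
  expect_equal(rec$mean_distance, 0.25)
  expect_equal(rec$dispersion, (0.75^2 + 3 * 0.25^2) / 4)  # 0.1875
  expect_equal(dispersion(b, a)$dispersion, rec$dispersion)
  # constant-offset panels: constant distance field, zero dispersion
  off <- panel_matrix(a$values + 3.7, "off")
  expect_equal(dispersion(a, off)$dispersion, 0)
})

test_that("dispersion equals a brute-force population variance", {
  set.seed(202)
  for (rep in 1:50) {
    pr <- random_panel_pair(N = sample(1:6, 1), n = sample(1:6, 1))
    expect_equal(dispersion(pr$a, pr$b)$dispersion,
                 brute_force_dispersion(pr$a, pr$b), tolerance = 1e-12)
  }
})

test_that("cohort_mean_dispersion implements both conventions", {
  # reference mode: plain mean of comparison dispersions (the published
  # 3.6747 is the exact 3.67475 truncated at 4 dp)
  expect_lt(abs(cohort_mean_dispersion(
    published_indicator_dispersions, "reference") - 3.6747), 5e-5)
  # pairwise mode: lower-triangle sum over m(m+1)/2
  pd <- storm_tide_dispersions("provinces")
  expect_equal(round(cohort_mean_dispersion(
    pd[lower.tri(pd)], "pairwise", m = 5), 4), 8.1261)
  expect_equal(cohort_mean_dispersion(c(0, 0, 0), "pairwise", m = 3), 0)
  expect_error(cohort_mean_dispersion(numeric(0), "reference"), "no disp")
  expect_error(cohort_mean_dispersion(c(1, -1), "reference"), "nonnegative")
  expect_error(cohort_mean_dispersion(1:4, "pairwise", m = 5), "m\\(m-1\\)/2")
  expect_error(cohort_mean_dispersion(1:3, "pairwise"), "needs `m`")
})

test_that("dpgra_degree reproduces published values and edge conventions", {
  Dbar <- mean(published_indicator_dispersions)
  expect_lt(abs(dpgra_degree(1.0942, Dbar) - 0.7705), 1e-4)
  expect_lt(abs(dpgra_degree(13.3995, Dbar) - 0.2152), 1e-4)
  expect_equal(dpgra_degree(0, Dbar), 1)
  expect_equal(dpgra_degree(c(1, 5, 100), 0), c(1, 1, 1))
  expect_error(dpgra_degree(-1, 2), "nonnegative")
  expect_error(dpgra_degree(1, -2), "nonnegative")
  # strictly decreasing in D
  d <- sort(stats::runif(10, 0, 50))
  expect_true(all(diff(dpgra_degree(d, 3)) < 0))
})

test_that("rank_series ranks degrees descending with tie policies", {
  eps <- c(0.7164, 0.7131, 0.2152, 0.7608, 0.5145, 0.7705)
  expect_identical(unname(rank_series(eps)), c(3L, 4L, 6L, 2L, 5L, 1L))
  expect_identical(unname(rank_series(c(1, 1, 0.5))), c(1L, 1L, 3L))
  expect_equal(unname(rank_series(c(1, 1, 0.5), "average")), c(1.5, 1.5, 3))
  # ranking of eps is the ranking of -D (oracle: sort-based)
  set.seed(9)
  D <- stats::runif(8, 0, 20)
  eps <- dpgra_degree(D, 4)
  expect_identical(unname(rank_series(eps)),
                   as.integer(rank(D, ties.method = "min")))
})

test_that("epsilon_from_dispersions reproduces the published analyses", {
  ref <- epsilon_from_dispersions(published_indicator_dispersions,
                                  "reference")
  expect_lt(max(abs(ref$degrees - published_indicator_degrees)), 1e-4)
  expect_identical(ref$ranking, published_indicator_ranks)
  # equal dispersions: every degree is exactly 1/2
  eq <- epsilon_from_dispersions(c(a = 2, b = 2, c = 2), "reference")
  expect_equal(unname(eq$degrees), rep(0.5, 3))
  # pairwise on the published province matrix
  pw <- epsilon_from_dispersions(storm_tide_dispersions("provinces"),
                                 "pairwise")
  expect_lt(max(abs(pw$degrees - published_province_degrees)), 1e-4)
  expect_equal(unname(diag(pw$degrees)), rep(1, 5))
  expect_identical(pw$degrees, t(pw$degrees))
})

test_that("epsilon_from_dispersions validates pairwise input", {
  bad_diag <- matrix(c(1, 2, 2, 0), 2)
  expect_error(epsilon_from_dispersions(bad_diag, "pairwise"), "diagonal")
  asym <- matrix(c(0, 2, 3, 0), 2)
  expect_error(epsilon_from_dispersions(asym, "pairwise"), "symmetric")
  neg <- matrix(c(0, -1, -1, 0), 2)
  expect_error(epsilon_from_dispersions(neg, "pairwise"), "nonnegative")
  expect_error(epsilon_from_dispersions(matrix(0, 1, 1), "pairwise"),
               "m >= 2")
})

test_that("dpgra_reference ranks a self-identical comparison first", {
  set.seed(11)
  ref <- random_panel(4, 5, "ref")
  twin <- panel_matrix(2.5 * ref$values, "twin")  # scale removed by Z
  other <- random_panel(4, 5, "other")
  res <- dpgra_reference(panel_set(list(ref, twin, other)), "ref")
  expect_equal(unname(res$degrees["twin"]), 1)
  expect_identical(unname(res$ranking["twin"]), 1L)
  expect_error(dpgra_reference(panel_set(list(ref, twin)), "nope"),
               "not found")
})

test_that("dpgra_reference recovers a constructed dispersion ordering", {
  # comparisons with strictly growing noise must rank strictly worse
  set.seed(33)
  base <- matrix(stats::runif(25, 5, 15), 5)
  mk <- function(sig, id)
    panel_matrix(pmax(base + matrix(stats::rnorm(25, 0, sig), 5), 0.01), id)
  ps <- panel_set(list(panel_matrix(base, "ref"),
                       mk(0.1, "low"), mk(1, "mid"), mk(4, "high")))
  res <- dpgra_reference(ps, "ref")
  expect_identical(res$ranking[c("low", "mid", "high")],
                   c(low = 1L, mid = 2L, high = 3L))
  expect_true(all(diff(res$dispersions[c("low", "mid", "high")]) > 0))
})

test_that("dpgra_pairwise returns a symmetric unit-diagonal matrix", {
  set.seed(12)
  a <- random_panel(3, 4, "a")
  b <- panel_matrix(a$values * 4, "b")
  c_ <- random_panel(3, 4, "c")
  res <- dpgra_pairwise(panel_set(list(a, b, c_)))
  expect_identical(res$degrees, t(res$degrees))
  expect_equal(unname(diag(res$degrees)), rep(1, 3))
  expect_equal(res$degrees["a", "b"], 1)   # identical after normalization
  expect_true(all(res$degrees > 0 & res$degrees <= 1))
  expect_error(dpgra_pairwise(panel_set(list(a))), "at least 2")
})
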