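# Shared fixture builders: small random panels with controllable shape.

random_panel <- function(N = 4, n = 5, id = "x", positive = TRUE) {
  v <- matrix(stats::runif(N * n, if (positive) 0.5 else -5, 10), N, n)
  panel_matrix(v, id)
}

random_panel_pair <- function(N = 4, n = 5) {
  list(a = random_panel(N, n, "a"), b = random_panel(N, n, "b"))
}

# Independent oracle for the dispersion statistic: flatten the distance
# field and take a literal two-pass population variance.
brute_force_dispersion <- function(a, b) {
  l <- as.vector(abs(a$values - b$values))
  mu <- sum(l) / length(l)
  sum((l - mu)^2) / length(l)
}

# The six published indicator dispersions and the degrees/ranks printed
# alongside them (storm-tide study, direct economic losses as reference).
published_indicator_dispersions <- c(
  mariculture_loss = 1.4547, coastal_engineering_loss = 1.4778,
  death_toll = 13.3995, ship_loss = 1.1552,
  collapsed_home_loss = 3.4671, storm_surge_frequency = 1.0942)

published_indicator_degrees <- c(
  mariculture_loss = 0.7164, coastal_engineering_loss = 0.7131,
  death_toll = 0.2152, ship_loss = 0.7608,
  collapsed_home_loss = 0.5145, storm_surge_frequency = 0.7705)

published_indicator_ranks <- c(
  mariculture_loss = 3L, coastal_engineering_loss = 4L, death_toll = 6L,
  ship_loss = 2L, collapsed_home_loss = 5L, storm_surge_frequency = 1L)

# Published pairwise province degrees (lower triangle, row-major).
published_province_degrees <- local({
  p <- matrix(1, 5, 5, dimnames = list(
    c("Jiangsu", "Zhejiang", "Fujian", "Guangdong", "Guangxi"),
    c("Jiangsu", "Zhejiang", "Fujian", "Guangdong", "Guangxi")))
  lower <- c(0.3102, 0.3490, 0.3221, 0.5377,   # vs Jiangsu
             0.6992, 0.4632, 0.3551,           # vs Zhejiang
             0.4410, 0.3566,                   # vs Fujian
             0.4047)                           # vs Guangdong
  p[lower.tri(p)] <- lower
  p[upper.tri(p)] <- t(p)[upper.tri(p)]
  p
})
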