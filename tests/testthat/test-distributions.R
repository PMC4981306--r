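test_that("count-based Beta fits carry the effectively-treated counts", {
  d <- fit_beta_from_counts(50, 38)
  expect_equal(d$params$alpha, 50)
  expect_equal(d$params$beta, 38)
  expect_equal(dist_mean(d), 50 / 88, tolerance = 1e-12)
  expect_equal(round(dist_mean(d), 3), 0.568)

  expect_equal(dist_mean(fit_beta_from_counts(1, 1)), 0.5)
  expect_equal(dist_mean(fit_beta_from_counts(245, 159)), 245 / 404)

  expect_error(fit_beta_from_counts(0, 0), "unidentifiable")
  expect_error(fit_beta_from_counts(5, 0), "degenerate")
  expect_silent(fit_beta_from_counts(5, 0, prior = TRUE))
})

test_that("mean/CI Beta fits recover published parameterisations", {
  # elicited probability: most likely 0.329, range 0.200-0.483
  for (m in c("moments", "quantile")) {
    d <- fit_beta_from_mean_ci(0.329, 0.200, 0.483, method = m)
    expect_equal(dist_mean(d), 0.329, tolerance = 1e-9)
    expect_equal(d$params$alpha, 13.42, tolerance = 0.03)
    expect_equal(d$params$beta, 27.36, tolerance = 0.03)
  }
  # symmetry: mean 0.5 with a symmetric interval gives alpha = beta
  d <- fit_beta_from_mean_ci(0.5, 0.3, 0.7)
  expect_equal(d$params$alpha, d$params$beta, tolerance = 1e-9)

  expect_error(fit_beta_from_mean_ci(0.5, 0.6, 0.7), "ci_low < mean")
  expect_error(fit_beta_from_mean_ci(0.01, 0.001, 0.999), "too wide")
})

test_that("quantile-matching fit agrees with a brute-force grid oracle", {
  m <- 0.329; lo <- 0.200; hi <- 0.483
  obj <- function(a) {
    b <- a * (1 - m) / m
    (qbeta(0.025, a, b) - lo)^2 + (qbeta(0.975, a, b) - hi)^2
  }
  grid <- seq(5, 30, by = 1e-3)
  a_star <- grid[which.min(vapply(grid, obj, numeric(1)))]
  d <- fit_beta_from_mean_ci(m, lo, hi, method = "quantile")
  expect_equal(d$params$alpha, a_star, tolerance = 2e-3)

  mg <- 2221; log_ <- 1274; hig <- 2838
  objg <- function(s) {
    (qgamma(0.025, s, scale = mg / s) - log_)^2 +
      (qgamma(0.975, s, scale = mg / s) - hig)^2
  }
  gridg <- seq(20, 50, by = 1e-3)
  s_star <- gridg[which.min(vapply(gridg, objg, numeric(1)))]
  dg <- fit_gamma_from_mean_ci(mg, log_, hig, method = "quantile")
  expect_equal(dg$params$shape, s_star, tolerance = 2e-3)
})

test_that("mean/CI Gamma fits recover published cost parameterisations", {
  d <- fit_gamma_from_mean_ci(401, 216, 462)
  expect_equal(dist_mean(d), 401, tolerance = 1e-9)
  expect_equal(d$params$shape, 40.65, tolerance = 0.01)
  expect_equal(d$params$scale, 9.86, tolerance = 0.01)

  d <- fit_gamma_from_mean_ci(3917, 2599, 5309)
  expect_equal(d$params$shape, 31.93, tolerance = 0.01)
  expect_equal(d$params$scale, 122.69, tolerance = 0.01)

  expect_error(fit_gamma_from_mean_ci(100, 120, 140), "ci_low < mean")
})

test_that("dispersed Gamma fit sets sd equal to the mean", {
  expect_equal(fit_gamma_dispersed(51.07)$params, list(shape = 1, scale = 51.07))
  expect_equal(dist_mean(fit_gamma_dispersed(84)), 84)
  expect_equal(dist_mean(fit_gamma_dispersed(1)), 1)
  expect_error(fit_gamma_dispersed(-3), "positive")
})

test_that("analytic means match closed forms", {
  expect_equal(round(dist_mean(dist_beta(10.69, 0.93)), 3), 0.920)
  expect_equal(round(dist_mean(dist_gamma(57.14, 114.28))), 6530)
  expect_equal(dist_mean(dist_dirichlet(c(1, 1, 1, 1))), rep(0.25, 4))
  expect_equal(dist_mean(dist_point(0.4)), 0.4)
})

test_that("round-trip: quantile fit recovers Beta shapes within 2%", {
  set.seed(11)
  for (i in 1:25) {
    a <- exp(runif(1, log(0.5), log(600)))
    b <- exp(runif(1, log(0.5), log(600)))
    m <- a / (a + b)
    lo <- qbeta(0.025, a, b)
    hi <- qbeta(0.975, a, b)
    if (lo <= 0 || hi >= 1 || lo >= m || hi <= m) next
    d <- fit_beta_from_mean_ci(m, lo, hi, method = "quantile")
    expect_equal(d$params$alpha, a, tolerance = 0.02)
    expect_equal(d$params$beta, b, tolerance = 0.02)
  }
})

test_that("sampling is reproducible and mean-consistent", {
  set.seed(99)
  x1 <- dist_sample(dist_beta(50, 38), 5)
  set.seed(99)
  x2 <- dist_sample(dist_beta(50, 38), 5)
  expect_identical(x1, x2)

  expect_equal(dist_sample(dist_point(0.5), 10), rep(0.5, 10))

  set.seed(7)
  x <- dist_sample(dist_beta(50, 38), 1e5)
  se <- sqrt(0.568 * 0.432 / 89) / sqrt(1e5)
  expect_lt(abs(mean(x) - 50 / 88), 3 * se)
  expect_true(all(x > 0 & x < 1))

  set.seed(8)
  g <- dist_sample(dist_dirichlet(c(2, 3, 5)), 100)
  expect_equal(rowSums(g), rep(1, 100), tolerance = 1e-12)
  expect_true(all(g > 0))
})
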