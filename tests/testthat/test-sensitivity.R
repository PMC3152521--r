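test_that("the default range brackets the base case by 25%", {
  p <- make_default_range(100)
  expect_equal(c(p$low, p$mode, p$high), c(75, 100, 125))
  p2 <- make_default_range(16.71)
  expect_equal(c(p2$low, p2$mode, p2$high), c(12.5325, 16.71, 20.8875))
  expect_error(make_default_range(100, fraction = 0), "\\(0, 1\\)")
  expect_error(make_default_range(100, fraction = 1), "\\(0, 1\\)")
  expect_warning(pz <- make_default_range(0), "degenerate")
  expect_equal(c(pz$low, pz$high), c(0, 0))
})

test_that("the inverse-CDF sampler hits the boundaries and the mode", {
  p <- triangular_param(75, 100, 125)
  expect_equal(sample_triangular(p, 0), 75)
  expect_equal(sample_triangular(p, 1), 125)
  # symmetric triangle: the median is the mode
  expect_equal(sample_triangular(p, 0.5), 100)
  expect_error(sample_triangular(p, 1.5), "\\[0, 1\\]")
  # draws always inside [low, high], including asymmetric shapes
  pa <- triangular_param(0, 0.157, 0.373)
  u <- seq(0, 1, length.out = 101)
  x <- sample_triangular(pa, u)
  expect_true(all(x >= 0 & x <= 0.373))
  expect_true(all(diff(x) >= 0))  # inverse CDF is monotone
})

test_that("the sampler's empirical mean matches the analytic triangular mean", {
  set.seed(2024)
  for (p in list(triangular_param(12.5325, 16.71, 20.8875),
                 triangular_param(0, 0.157, 0.373),
                 triangular_param(0.05, 0.18, 0.25))) {
    n <- 1e5
    x <- sample_triangular(p, runif(n))
    se <- triangular_sd(p) / sqrt(n)
    expect_lt(abs(mean(x) - triangular_mean(p)), 3 * se)
  }
})

test_that("interval summaries use linear-interpolation quantiles", {
  res <- structure(list(samples = cbind(out = 1:100),
                        mean = c(out = mean(1:100)),
                        n_invalid = 0L, invalid = rep(FALSE, 100),
                        n_iterations = 100L, seed = 1L),
                   class = "simulation_result")
  s <- summarise_psa(res, 0.90)
  expect_equal(s$lower, 5.95)
  expect_equal(s$upper, 95.05)
  s2 <- summarise_psa(res, 1)
  expect_equal(c(s2$lower, s2$upper), c(1, 100))
  # constant samples collapse the interval onto the mean
  resc <- res; resc$samples <- cbind(out = rep(7, 100)); resc$mean <- c(out = 7)
  sc <- summarise_psa(resc, 0.9)
  expect_equal(c(sc$lower, sc$upper, sc$mean), c(7, 7, 7))
})

test_that("identical specs reproduce identical simulations", {
  params <- list(make_default_range(10, target = "a"),
                 make_default_range(20, target = "b"))
  model <- function(x) c(total = sum(x))
  s <- simulation_spec(500, seed = 123, params = params)
  r1 <- run_monte_carlo(model, s)
  r2 <- run_monte_carlo(model, s)
  expect_identical(r1$samples, r2$samples)
  r3 <- run_monte_carlo(model, simulation_spec(500, seed = 124,
                                               params = params))
  expect_false(identical(r1$samples, r3$samples))
})

test_that("sibling probability groups are renormalised to sum to one", {
  params <- list(make_default_range(0.3, target = "p1", group = "g"),
                 make_default_range(0.7, target = "p2", group = "g"))
  model <- function(x) c(s = x[["p1"]] + x[["p2"]], p1 = x[["p1"]])
  r <- run_monte_carlo(model, simulation_spec(200, seed = 5, params = params))
  expect_equal(unname(r$samples[, "s"]), rep(1, 200))
  expect_true(all(r$samples[, "p1"] >= 0 & r$samples[, "p1"] <= 1))
  expect_identical(r$n_invalid, 0L)
})

test_that("widening the ranges never narrows the interval (same seed)", {
  q90 <- function(frac) {
    params <- list(make_default_range(100, frac, target = "a"),
                   make_default_range(50, frac, target = "b"))
    model <- function(x) c(total = x[["a"]] + x[["b"]])
    s <- summarise_psa(run_monte_carlo(
      model, simulation_spec(500, seed = 77, params = params)))
    s$upper - s$lower
  }
  widths <- vapply(c(0.1, 0.25, 0.4), q90, numeric(1))
  expect_true(all(diff(widths) > 0))
})
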