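# Exponential shadow fitting, dB conversion, power-law calibration,
# fold changes and replicate aggregation.

test_that("exponential fits are exact on noiseless profiles", {
  t <- seq(0, 2, by = 0.01)
  prof <- list(t = t, intensity = 200 * exp(-0.5 * t))
  fit <- fit_exponential(prof)
  expect_equal(fit$alpha_np_per_cm, 0.5, tolerance = 1e-6)
  expect_equal(fit$I0, 200, tolerance = 1e-4)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$alpha_db_per_cm, 0.5 * 10 * log10(exp(1)), tolerance = 1e-6)
  expect_equal(fit$fit_start_row, 0)

  expect_error(fit_exponential(list(t = 1:3, intensity = c(3, 2, 1))),
               class = "echogel_invalid_input")
  expect_warning(flat <- fit_exponential(list(t = t, intensity = rep(40, length(t)))),
                 class = "echogel_degenerate_input")
  expect_equal(flat$alpha_np_per_cm, 0)
  expect_equal(flat$r_squared, 0)
})

test_that("the fit window locks onto the boundary peak, not deep maxima", {
  t <- seq(0, 2, by = 0.01)
  I <- 180 * exp(-0.8 * t)
  I[5] <- 220            # boundary peak within the upper 20%
  I[190] <- 240          # spurious bright speckle deep in the shadow
  fit <- fit_exponential(list(t = t, intensity = I))
  expect_equal(fit$fit_start_row, 4)  # 0-based index of the early peak
  expect_lt(abs(fit$alpha_np_per_cm - 0.8), 0.05)
})

test_that("neper/dB conversion follows both conventions and round-trips", {
  expect_equal(to_db_per_cm(1, "intensity"), 4.3429, tolerance = 1e-4)
  expect_equal(to_db_per_cm(1, "amplitude"), 8.6859, tolerance = 1e-4)
  x <- c(0.3, 1.7, 12)
  expect_equal(to_np_per_cm(to_db_per_cm(x, "intensity"), "intensity"), x,
               tolerance = 1e-12)
  expect_equal(to_np_per_cm(to_db_per_cm(x, "amplitude"), "amplitude"), x,
               tolerance = 1e-12)
  expect_error(to_db_per_cm(1, "loudness"))
})

test_that("power-law fits recover alpha0 and n", {
  f <- c(6.5, 7.5, 8.5, 11)
  pf <- fit_power_law(f, 0.5 * f^0.7)
  expect_equal(pf$alpha0, 0.5, tolerance = 1e-6)
  expect_equal(pf$n, 0.7, tolerance = 1e-6)
  expect_equal(pf$r_squared, 1, tolerance = 1e-9)

  # frequency-independent attenuation fits to n ~ 0
  pc <- fit_power_law(c(2, 5, 9), rep(3.2, 3))
  expect_lt(abs(pc$n), 1e-6)
  expect_equal(pc$alpha0, 3.2, tolerance = 1e-6)

  expect_error(fit_power_law(c(6.5, 7.5), c(1, 2)),
               class = "echogel_invalid_input")
  expect_error(fit_power_law(c(6.5, 7.5, -8), c(1, 2, 3)),
               class = "echogel_invalid_input")
  expect_error(fit_power_law(c(6.5, 6.5, 6.5), c(1, 2, 3)),
               class = "echogel_invalid_input")
})

test_that("noisy power-law fits agree with the log-log OLS oracle", {
  f <- c(6.5, 7.5, 8.5, 11)
  truth_n <- 0.7
  set.seed(101)
  ns <- ns_ols <- numeric(200)
  for (i in 1:200) {
    a <- 0.5 * f^truth_n * (1 + rnorm(4, sd = 0.05))
    pf <- fit_power_law(f, a)
    ns[i] <- pf$n
    ns_ols[i] <- ols_slope_oracle(log(f), log(a))
    expect_equal(pf$init$n, ns_ols[i], tolerance = 1e-9)
  }
  expect_lt(abs(mean(ns) - truth_n), 0.05)
  # refinement stays within each seed's sampling scatter of the initializer
  expect_lt(max(abs(ns - ns_ols)), 3 * sd(ns_ols))
})

test_that("fold changes reproduce the reference environment arithmetic", {
  expect_equal(fold_change(8.21, 20.84), 1.538, tolerance = 1e-3)
  expect_equal(fold_change(8.21, 13.76), 0.676, tolerance = 1e-3)
  expect_equal(fold_change(3.7, 3.7), 0)
  expect_error(fold_change(0, 5), class = "echogel_invalid_input")
})

test_that("replicate aggregation reports mean and SEM", {
  r <- aggregate_replicates(c(5, 5, 5), material = "m", environment = "Aq",
                            frequency_MHz = 8.5)
  expect_equal(r$alpha_db_cm, 5)
  expect_equal(r$sem, 0)
  expect_equal(r$n_reps, 3)

  r2 <- aggregate_replicates(c(8.07, 8.21, 8.35))
  expect_equal(r2$alpha_db_cm, 8.21)
  expect_equal(r2$sem, 0.14 / sqrt(3), tolerance = 1e-9)
  expect_equal(round(r2$sem, 4), 0.0808)

  r3 <- aggregate_replicates(6.53)
  expect_equal(r3$sem, 0)
  expect_equal(r3$n_reps, 1)
  expect_error(aggregate_replicates(list()), class = "echogel_invalid_input")

  # list-of-fits input carries the mean R^2 through
  t <- seq(0, 2, 0.01)
  fits <- lapply(c(0.4, 0.5), function(a)
    fit_exponential(list(t = t, intensity = 150 * exp(-a * t))))
  ra <- aggregate_replicates(fits, material = "x")
  expect_equal(ra$alpha_db_cm, mean(vapply(fits, `[[`, numeric(1), "alpha_db_per_cm")))
  expect_gt(ra$r_squared, 0.999)
})

test_that("fitted alpha is strictly monotone in the generated attenuation", {
  alphas_true <- c(1, 3, 6, 12, 18)
  rois <- default_rois(small_spec())
  fitted <- vapply(alphas_true, function(a) {
    spec <- small_spec(speckle_cv = 0, alpha0_true = a, n_true = 0)
    ph <- generate_phantom(spec, 8.5, seed = 1)
    fit_exponential(extract_axial_profile(ph$image, rois$posterior_shadow))$alpha_db_per_cm
  }, numeric(1))
  expect_true(all(diff(fitted) > 0))
  expect_equal(fitted, alphas_true, tolerance = 0.02)
})
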