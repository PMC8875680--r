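# Phantom generator: determinism, the encoded decay law, speckle
# statistics, and closed-loop recovery by the downstream estimators.

test_that("phantoms are deterministic and noiseless limits are exact", {
  spec <- small_spec(speckle_cv = 0)
  a <- generate_phantom(spec, 8.5, seed = 4)
  b <- generate_phantom(spec, 8.5, seed = 4)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth, b$truth)

  # no noise, no contrast, no attenuation: uniform outside the boundary band
  flat <- small_spec(speckle_cv = 0, implant_deltaE = 0, alpha0_true = 0)
  ph <- generate_phantom(flat, 8.5, seed = 1)
  px <- ph$image$pixels
  band <- 31:33  # boundary rows (0-based 30..32) in 1-based indexing
  expect_true(all(px[band, 21:80] == 250))
  expect_true(all(px[-band, ] == 100) && all(px[band, c(1:20, 81:100)] == 100))
  expect_equal(ph$truth$alpha_true_db_cm, 0)
})

test_that("the posterior shadow decays log-linearly at the ground-truth rate", {
  # alpha0 * f^n = 5 dB/cm at f = 8.5 with n = 0.7
  spec <- small_spec(speckle_cv = 0, alpha0_true = 5 / 8.5^0.7, n_true = 0.7)
  ph <- generate_phantom(spec, 8.5, seed = 1, quantize = FALSE)
  expect_equal(ph$truth$alpha_true_db_cm, 5, tolerance = 1e-12)
  rois <- default_rois(spec)
  prof <- extract_axial_profile(ph$image, rois$posterior_shadow)
  db <- 10 * log10(prof$intensity)
  slope <- ols_slope_oracle(prof$t, db)
  expect_equal(slope, -5, tolerance = 1e-9)
  # residuals from the log-linear law are numerically zero
  fitline <- ols_fit_oracle(prof$t, db)
  expect_lt(max(abs(db - fitline[1] - fitline[2] * prof$t)), 1e-9)
})

test_that("frequency series and replicates follow their contracts", {
  spec <- small_spec(alpha0_true = 0.5, n_true = 0.7)
  ser <- generate_frequency_series(spec, c(6.5, 7.5, 8.5, 11), seed = 2)
  alphas <- vapply(ser, function(p) p$truth$alpha_true_db_cm, numeric(1))
  expect_equal(alphas, 0.5 * c(6.5, 7.5, 8.5, 11)^0.7, tolerance = 1e-12)

  lin <- small_spec(alpha0_true = 1, n_true = 1)
  ser2 <- generate_frequency_series(lin, c(2, 4), seed = 1)
  expect_equal(vapply(ser2, function(p) p$truth$alpha_true_db_cm, numeric(1)),
               c(2, 4))
  flat <- small_spec(alpha0_true = 2, n_true = 0)
  ser3 <- generate_frequency_series(flat, c(2, 8, 13), seed = 1)
  expect_equal(unique(vapply(ser3, function(p) p$truth$alpha_true_db_cm,
                             numeric(1))), 2)
  expect_error(generate_frequency_series(spec, numeric(0), seed = 1),
               class = "echogel_invalid_input")

  reps0 <- generate_replicates(small_spec(speckle_cv = 0), 8.5, 3, base_seed = 5)
  expect_identical(reps0[[1]]$image$pixels, reps0[[2]]$image$pixels)
  reps <- generate_replicates(small_spec(speckle_cv = 0.2), 8.5, 3, base_seed = 5)
  expect_false(identical(reps[[1]]$image$pixels, reps[[2]]$image$pixels))
  expect_false(identical(reps[[2]]$image$pixels, reps[[3]]$image$pixels))
  tr <- lapply(reps, function(p) p$truth[setdiff(names(p$truth), "seed")])
  expect_identical(tr[[1]], tr[[2]])
  expect_error(generate_replicates(spec, 8.5, 0, 1),
               class = "echogel_invalid_input")
})

test_that("speckle is unit-mean with the requested coefficient of variation", {
  # per-pixel CV across replicates inside the homogeneous background
  spec <- phantom_spec(height_px = 40L, width_px = 40L,
                       implant_rect = c(5L, 5L, 12L, 35L),
                       speckle_cv = 0.2, alpha0_true = 0)
  reps <- generate_replicates(spec, 8.5, 100, base_seed = 1)
  stack <- vapply(reps, function(p) p$image$pixels[30:40, 1:4],
                  matrix(0, 11, 4))  # background block below/left of implant
  cv <- apply(stack, c(1, 2), function(v) sd(v) / mean(v))
  expect_lt(abs(mean(cv) - 0.2), 0.02)

  s <- with_seed_helper(99, speckle_field(2e5, 0.35))
  expect_equal(mean(s), 1, tolerance = 5e-3)
  expect_equal(sd(s) / mean(s), 0.35, tolerance = 5e-3)
})

test_that("calibration and monotonicity invariants hold", {
  spec <- small_spec()
  ph <- generate_phantom(spec, 8.5, seed = 1)
  expect_equal(ph$truth$boundary_row * spec$axial_scale,
               spec$implant_rect[1] * spec$axial_scale, tolerance = spec$axial_scale)
  expect_equal(ph$truth$alpha_true_db_cm,
               spec$alpha0_true * 8.5^spec$n_true, tolerance = 1e-9)

  # stronger attenuation -> strictly darker shadow at any fixed depth
  depth_means <- vapply(c(1, 2, 4, 8), function(a0) {
    s <- small_spec(speckle_cv = 0, alpha0_true = a0, n_true = 0)
    p <- generate_phantom(s, 8.5, seed = 1, quantize = FALSE)
    mean(p$image$pixels[120, 21:80])
  }, numeric(1))
  expect_true(all(diff(depth_means) < 0))

  expect_error(phantom_spec(implant_rect = c(10, 10, 300, 50),
                            height_px = 200, width_px = 100),
               class = "echogel_invalid_input")
})

test_that("downstream estimators close the loop on phantom ground truth", {
  # attenuation: exact on the continuous-valued scene, <1% after 8-bit
  spec <- small_spec(speckle_cv = 0, alpha0_true = 6 / 8.5^0.7)
  rois <- default_rois(spec)
  ph <- generate_phantom(spec, 8.5, seed = 1, quantize = FALSE)
  fit <- fit_exponential(extract_axial_profile(ph$image, rois$posterior_shadow))
  expect_equal(fit$alpha_db_per_cm, ph$truth$alpha_true_db_cm, tolerance = 1e-3)
  phq <- generate_phantom(spec, 8.5, seed = 1)
  fitq <- fit_exponential(extract_axial_profile(phq$image, rois$posterior_shadow))
  expect_equal(fitq$alpha_db_per_cm, ph$truth$alpha_true_db_cm, tolerance = 1e-2)

  # echogenicity: exact recovery of the programmed contrast (no shadow scene)
  spec2 <- small_spec(speckle_cv = 0, alpha0_true = 0, implant_deltaE = -24)
  base <- generate_phantom(spec2, 8.5, 1, implant = FALSE, quantize = FALSE)$image
  imp <- generate_phantom(spec2, 8.5, 1, quantize = FALSE)$image
  rep2 <- echogenicity_report(base, imp, default_rois(spec2))
  expect_equal(rep2$deltaE_pct[rep2$region == "implant_area"], -24,
               tolerance = 1e-6)
})

test_that("phantoms round-trip through disk with their ground truth sidecar", {
  spec <- small_spec()
  ph <- generate_phantom(spec, 8.5, seed = 3)
  img_path <- tempfile(fileext = ".png")
  write_phantom(ph, img_path, spec = spec)
  back <- read_bmode(img_path, spec$axial_scale, spec$lateral_scale)
  expect_equal(back$pixels, ph$image$pixels, ignore_attr = TRUE)
  side <- jsonlite::fromJSON(sub("\\.png$", ".json", img_path))
  expect_equal(side$truth$alpha_true_db_cm, ph$truth$alpha_true_db_cm)
  expect_equal(side$calibration$axial_scale, spec$axial_scale)
})
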