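# Synthetic B-mode phantom generator: speckled tissue background, bright
# implant boundary echo, implant-area contrast, and an exponentially
# decaying posterior shadow with known frequency-dependent attenuation
# alpha(f) = alpha0 * f^n. Every phantom carries its ground truth so the
# downstream estimators can be validated in closed loop.

#' Phantom specification
#'
#' Geometry, calibration and ground-truth acoustics of one synthetic
#' B-mode scene. Defaults emulate a superficial linear-array scan: a
#' 3.9 x 2 cm field of view at 0.01 cm/pixel, a 1 x 0.4 cm implant whose
#' upper boundary sits 0.5 cm deep, a bright 3-row boundary echo, and
#' fully developed multiplicative speckle with a coefficient of variation
#' of 0.2. The attenuation defaults (`alpha0_true = 1.5` dB/(cm MHz^n),
#' `n_true = 0.7`) put the shadow decay at mid-range of the bundled
#' reference measurements for a muscle-like frequency exponent.
#'
#' @param height_px,width_px image size in pixels.
#' @param axial_scale,lateral_scale cm per pixel.
#' @param background_mean expected tissue pixel level, in (0, 255).
#' @param implant_rect integer vector `c(row0, col0, row1, col1)`, 0-based
#'   half-open, strictly inside the image.
#' @param boundary_thickness_px rows of the boundary echo band (>= 1).
#' @param boundary_level pixel level of the echo band.
#' @param implant_deltaE target implant-area echogenicity change, percent
#'   relative to the background (applied before shadowing).
#' @param alpha0_true attenuation prefactor, dB/(cm MHz^n).
#' @param n_true frequency exponent (dimensionless).
#' @param speckle_cv coefficient of variation of the multiplicative speckle
#'   field (>= 0; 0 disables speckle).
#' @param environment placement tag: `"Aq"`, `"SC"` or `"SM"`.
#' @param temperature_C ambient temperature tag (metadata only; the
#'   generator encodes no temperature dependence).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(height_px = 390L, width_px = 200L,
                         axial_scale = 0.01, lateral_scale = 0.01,
                         background_mean = 100,
                         implant_rect = c(50L, 50L, 90L, 150L),
                         boundary_thickness_px = 3L, boundary_level = 250,
                         implant_deltaE = 0, alpha0_true = 1.5, n_true = 0.7,
                         speckle_cv = 0.2, environment = "Aq",
                         temperature_C = 22) {
  if (!is_scalar_num(height_px) || !is_scalar_num(width_px) ||
      height_px < 1 || width_px < 1)
    abort_invalid("image dimensions must be positive")
  if (!is_scalar_num(background_mean) || background_mean <= 0 ||
      background_mean >= 255)
    abort_invalid("background_mean must lie in (0, 255)")
  if (length(implant_rect) != 4L || any(!is.finite(implant_rect)))
    abort_invalid("implant_rect must be c(row0, col0, row1, col1)")
  r <- as.integer(implant_rect)
  if (r[1] < 0 || r[2] < 0 || r[3] <= r[1] || r[4] <= r[2] ||
      r[3] >= height_px || r[4] > width_px)
    abort_invalid("implant_rect must lie strictly inside the image")
  if (!is_scalar_num(boundary_thickness_px) || boundary_thickness_px < 1)
    abort_invalid("boundary_thickness_px must be >= 1")
  if (r[1] + boundary_thickness_px > r[3])
    abort_invalid("boundary band must fit inside implant_rect")
  if (!is_scalar_num(speckle_cv) || speckle_cv < 0)
    abort_invalid("speckle_cv must be >= 0")
  if (!environment %in% c("Aq", "SC", "SM"))
    abort_invalid("environment must be 'Aq', 'SC' or 'SM'")
  structure(list(height_px = as.integer(height_px),
                 width_px = as.integer(width_px),
                 axial_scale = axial_scale, lateral_scale = lateral_scale,
                 background_mean = background_mean, implant_rect = r,
                 boundary_thickness_px = as.integer(boundary_thickness_px),
                 boundary_level = boundary_level,
                 implant_deltaE = implant_deltaE,
                 alpha0_true = alpha0_true, n_true = n_true,
                 speckle_cv = speckle_cv, environment = environment,
                 temperature_C = temperature_C),
            class = "phantom_spec")
}

#' Unit-mean multiplicative speckle field
#'
#' Rayleigh-shaped multiplicative speckle: a standardized Rayleigh variate
#' rescaled to mean 1 and the requested coefficient of variation (a pure
#' Rayleigh envelope has a fixed CV of `sqrt(4/pi - 1)` ~ 0.523; rescaling
#' preserves the distribution shape while making the dispersion tunable,
#' reflecting the variance-reducing processing applied by B-mode devices).
#' The (impossible for `cv <= 0.5`) negative tail is clamped at 0.
#'
#' @param n number of variates, or a length-2 vector `c(nrow, ncol)` to
#'   return a matrix.
#' @param cv target coefficient of variation (>= 0).
#' @return numeric vector or matrix of unit-mean multiplicative factors.
#' @export
speckle_field <- function(n, cv) {
  if (!is.numeric(cv) || length(cv) != 1L || !is.finite(cv) || cv < 0)
    abort_invalid("cv must be a non-negative scalar")
  dims <- NULL
  if (length(n) == 2L) { dims <- n; n <- prod(n) }
  if (cv == 0) {
    out <- rep(1, n)
  } else {
    r <- sqrt(-2 * log(stats::runif(n)))        # Rayleigh, scale 1
    mu <- sqrt(pi / 2)
    cv_r <- sqrt(4 / pi - 1)
    out <- pmax(0, 1 + cv * (r / mu - 1) / cv_r)
  }
  if (!is.null(dims)) dim(out) <- dims
  out
}

#' Generate one synthetic B-mode phantom
#'
#' Builds the noiseless scene (tissue background, implant contrast,
#' boundary echo, exponential posterior shadow), multiplies in speckle,
#' then clips to `[0, 255]` and rounds half-up to 8-bit levels. The shadow
#' multiplies every pixel below the boundary band within the implant's
#' lateral extent by `exp(-alpha_np * t)`, with `t = 0` at the first
#' shadowed row and `alpha_np` the ground-truth attenuation
#' `alpha0_true * f^n_true` (dB/cm) converted to nepers/cm under
#' `db_convention`. Deterministic for a fixed `(spec, frequency, seed)`.
#'
#' @param spec [phantom_spec()].
#' @param frequency_MHz scan frequency (> 0).
#' @param seed integer seed for the speckle realization.
#' @param implant if `FALSE`, generate the implant-free baseline scene
#'   (uniform speckled tissue; no boundary, contrast or shadow).
#' @param db_convention `"intensity"` (dB = 4.343 x nepers) or
#'   `"amplitude"` (8.686 x); see [to_db_per_cm()].
#' @param quantize clip and round to integer 8-bit levels (the default,
#'   matching device output). `FALSE` returns the continuous-valued scene,
#'   useful for closed-form validation of the decay law.
#' @return list with `image` ([bmode_image()], carrying attribute
#'   `n_clipped` = number of pixels clipped at 0/255) and `truth` (class
#'   `phantom_truth`: `alpha_true_db_cm`, `boundary_row`, `deltaE_true`,
#'   `seed`, `frequency_MHz`).
#' @export
generate_phantom <- function(spec, frequency_MHz, seed, implant = TRUE,
                             db_convention = c("intensity", "amplitude"),
                             quantize = TRUE) {
  if (!inherits(spec, "phantom_spec")) abort_invalid("spec must be a phantom_spec")
  if (!is_scalar_num(frequency_MHz) || frequency_MHz <= 0)
    abort_invalid("frequency_MHz must be positive")
  db_convention <- match.arg(db_convention)

  alpha_db <- spec$alpha0_true * frequency_MHz^spec$n_true
  alpha_np <- to_np_per_cm(alpha_db, db_convention)
  h <- spec$height_px; w <- spec$width_px
  base <- matrix(spec$background_mean, nrow = h, ncol = w)

  r0 <- spec$implant_rect[1]; c0 <- spec$implant_rect[2]
  r1 <- spec$implant_rect[3]; c1 <- spec$implant_rect[4]
  if (implant) {
    rows_band <- (r0 + 1L):(r0 + spec$boundary_thickness_px)
    cols_imp <- (c0 + 1L):c1
    # implant interior contrast (before shadowing)
    if (r0 + spec$boundary_thickness_px < r1)
      base[(r0 + spec$boundary_thickness_px + 1L):r1, cols_imp] <-
        spec$background_mean * (1 + spec$implant_deltaE / 100)
    # posterior shadow: everything below the band, implant columns only
    shadow_start <- r0 + spec$boundary_thickness_px  # 0-based first shadow row
    if (shadow_start < h) {
      rows_sh <- (shadow_start + 1L):h
      t_cm <- (rows_sh - (shadow_start + 1L)) * spec$axial_scale
      decay <- exp(-alpha_np * t_cm)
      base[rows_sh, cols_imp] <- base[rows_sh, cols_imp] * decay
    }
    base[rows_band, cols_imp] <- spec$boundary_level
  }

  img <- base * with_seed(seed, speckle_field(c(h, w), spec$speckle_cv))
  n_clipped <- sum(img < 0 | img > 255)
  img <- pmin(pmax(img, 0), 255)
  if (quantize) img <- round_half_up(img)

  image <- bmode_image(img, spec$axial_scale, spec$lateral_scale,
                       frequency_MHz, spec$environment, spec$temperature_C,
                       source = "synthetic")
  attr(image, "n_clipped") <- n_clipped
  truth <- structure(list(alpha_true_db_cm = alpha_db,
                          boundary_row = if (implant) r0 else NA_integer_,
                          deltaE_true = if (implant) spec$implant_deltaE else 0,
                          seed = as.integer(seed),
                          frequency_MHz = frequency_MHz,
                          alpha0_true = spec$alpha0_true,
                          n_true = spec$n_true,
                          db_convention = db_convention),
                     class = "phantom_truth")
  list(image = image, truth = truth)
}

#' Generate a frequency series of phantoms
#'
#' One phantom per scan frequency with ground-truth attenuation following
#' `alpha0 * f^n` exactly; speckle realizations differ across frequencies
#' (seed offsets `0, 1, ...` from `seed`).
#'
#' @inheritParams generate_phantom
#' @param freqs vector of scan frequencies, MHz (all > 0).
#' @return list of `(image, truth)` pairs, one per frequency.
#' @export
generate_frequency_series <- function(spec, freqs, seed, ...) {
  if (length(freqs) == 0L) abort_invalid("freqs must not be empty")
  if (any(!is.finite(freqs)) || any(freqs <= 0))
    abort_invalid("all frequencies must be positive")
  lapply(seq_along(freqs), function(i)
    generate_phantom(spec, freqs[i], seed + i - 1L, ...))
}

#' Generate replicate phantoms at one frequency
#'
#' Replicates differ only in their speckle realization (seeds
#' `base_seed, base_seed + 1, ...`); ground truth is identical, mirroring
#' repeat acquisitions of the same scene.
#'
#' @inheritParams generate_phantom
#' @param n_reps number of replicates (>= 1).
#' @param base_seed seed of the first replicate.
#' @return list of `(image, truth)` pairs.
#' @export
generate_replicates <- function(spec, frequency_MHz, n_reps, base_seed, ...) {
  if (!is_scalar_num(n_reps) || n_reps < 1)
    abort_invalid("n_reps must be >= 1")
  lapply(seq_len(n_reps), function(i)
    generate_phantom(spec, frequency_MHz, base_seed + i - 1L, ...))
}

#' Write a phantom and its ground truth to disk
#'
#' The image goes to 8-bit grayscale PNG or BMP; the spec, ground truth and
#' calibration go to a JSON sidecar (the image file itself carries no
#' calibration).
#'
#' @param phantom `(image, truth)` pair from [generate_phantom()].
#' @param image_path output image path (.png or .bmp).
#' @param json_path output sidecar path; default replaces the image
#'   extension with `.json`.
#' @param spec the [phantom_spec()] used, stored alongside the truth.
#' @return `image_path`, invisibly.
#' @export
write_phantom <- function(phantom, image_path, json_path = NULL, spec = NULL) {
  write_bmode(phantom$image, image_path)
  if (is.null(json_path))
    json_path <- paste0(tools::file_path_sans_ext(image_path), ".json")
  payload <- list(truth = unclass(phantom$truth),
                  calibration = list(axial_scale = phantom$image$axial_scale,
                                     lateral_scale = phantom$image$lateral_scale),
                  metadata = list(frequency_MHz = phantom$image$frequency_MHz,
                                  environment = phantom$image$environment,
                                  temperature_C = phantom$image$temperature_C))
  if (!is.null(spec)) payload$spec <- unclass(spec)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  invisible(image_path)
}

#' Default analysis ROIs for a phantom scene
#'
#' Implant-area ROI = implant interior below the boundary band; posterior
#' shadow ROI = from the implant's lower edge to the bottom of the image,
#' within the implant's lateral extent. Baseline ROIs share the same
#' coordinates (they are applied to the implant-free image).
#'
#' @param spec [phantom_spec()].
#' @param shadow_depth_px optional cap on the shadow ROI depth in rows.
#' @return named list of [roi()] objects: `implant`, `posterior_shadow`,
#'   `baseline_implant_area`, `baseline_shadow_area`.
#' @export
default_rois <- function(spec, shadow_depth_px = NULL) {
  r <- spec$implant_rect
  top <- r[1] + spec$boundary_thickness_px
  sh_end <- spec$height_px
  if (!is.null(shadow_depth_px)) sh_end <- min(sh_end, r[3] + shadow_depth_px)
  list(
    implant = roi(top, r[2], r[3], r[4], role = "implant"),
    posterior_shadow = roi(r[3], r[2], sh_end, r[4], role = "posterior_shadow"),
    baseline_implant_area = roi(top, r[2], r[3], r[4],
                                role = "baseline_implant_area"),
    baseline_shadow_area = roi(r[3], r[2], sh_end, r[4],
                               role = "baseline_shadow_area"))
}
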