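# Posterior-shadow attenuation analysis: exponential decay fitting of the
# axial intensity profile, neper/dB conversion, power-law frequency
# calibration, replicate aggregation and environment fold changes.

db_conversion_factor <- function(convention = c("intensity", "amplitude")) {
  convention <- match.arg(convention)
  switch(convention,
         intensity = 10 / log(10),   # 4.342944819...
         amplitude = 20 / log(10))
}

#' Convert attenuation between nepers/cm and dB/cm
#'
#' Under the intensity convention (`I ~ exp(-alpha t)`, the form the decay
#' model is written in) 1 neper/cm = 10*log10(e) ~ 4.3429 dB/cm; under the
#' amplitude convention (`A ~ exp(-alpha t)`) it is 20*log10(e) ~ 8.6859.
#' B-mode pixel levels are device-log-compressed amplitudes, so the choice
#' is a modeling convention; the package default is `"intensity"`
#' everywhere.
#'
#' @param alpha_np_per_cm attenuation in nepers/cm.
#' @param convention `"intensity"` or `"amplitude"`.
#' @return attenuation in dB/cm.
#' @export
to_db_per_cm <- function(alpha_np_per_cm, convention = c("intensity", "amplitude")) {
  if (!is.numeric(alpha_np_per_cm) || any(!is.finite(alpha_np_per_cm)))
    abort_invalid("alpha_np_per_cm must be finite")
  alpha_np_per_cm * db_conversion_factor(convention)
}

#' @rdname to_db_per_cm
#' @param alpha_db_per_cm attenuation in dB/cm.
#' @export
to_np_per_cm <- function(alpha_db_per_cm, convention = c("intensity", "amplitude")) {
  if (!is.numeric(alpha_db_per_cm) || any(!is.finite(alpha_db_per_cm)))
    abort_invalid("alpha_db_per_cm must be finite")
  alpha_db_per_cm / db_conversion_factor(convention)
}

#' Exponential fit of a posterior-shadow intensity profile
#'
#' Fits `I(t) = I0 * exp(-alpha * t)` by nonlinear least squares to the
#' laterally averaged axial profile. The fit window starts at the profile's
#' maximum within its upper 20% (the implant boundary echo; the guard keeps
#' deep speckle maxima from capturing the window) and extends to the end of
#' the profile; depth is measured from the window start. Initial values come
#' from a log-linear regression (zero intensities floored at 1 for the log
#' only), refined by Levenberg-Marquardt on the unfloored values.
#'
#' A fitted `alpha` may be negative (increasing profile); validity is the
#' caller's decision. An all-constant window yields `alpha = 0` and
#' `r_squared = 0` with a warning rather than an error.
#'
#' @param profile [extract_axial_profile()] result, or any list with
#'   numeric fields `t` (cm) and `intensity` (>= 4 points).
#' @param convention dB convention for the reported `alpha_db_per_cm`.
#' @param floor_value positive floor applied before taking logs in the
#'   initialization step.
#' @return object of class `attenuation_fit`: `I0`, `alpha_np_per_cm`,
#'   `alpha_db_per_cm`, `r_squared` (computed on the fit window in linear
#'   space), `fit_start_row`, `fit_end_row` (0-based profile rows),
#'   `n_points`, `convention`.
#' @export
fit_exponential <- function(profile, convention = c("intensity", "amplitude"),
                            floor_value = 1) {
  convention <- match.arg(convention)
  t <- profile$t; I <- profile$intensity
  if (!is.numeric(t) || !is.numeric(I) || length(t) != length(I))
    abort_invalid("profile must have numeric t and intensity of equal length")
  if (length(t) < 4L) abort_invalid("at least 4 profile points are required")

  guard <- max(1L, ceiling(0.2 * length(I)))
  k <- which.max(I[seq_len(guard)])
  win <- k:length(I)
  if (length(win) < 4L)
    abort_invalid("fewer than 4 points remain after the boundary-peak window")
  tw <- t[win] - t[k]
  Iw <- I[win]

  ss_tot <- sum((Iw - mean(Iw))^2)
  if (ss_tot == 0) {
    warning(warningCondition(
      "constant intensity profile; attenuation is undefined (alpha set to 0)",
      class = "echogel_degenerate_input"))
    return(new_attenuation_fit(Iw[1], 0, 0, k, length(I), length(win),
                               convention))
  }

  lf <- stats::lm(log(pmax(Iw, floor_value)) ~ tw)
  I0_init <- exp(unname(stats::coef(lf)[1]))
  a_init <- -unname(stats::coef(lf)[2])
  fit <- tryCatch(
    minpack.lm::nlsLM(Iw ~ I0 * exp(-a * tw),
                      start = list(I0 = I0_init, a = a_init),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    I0_hat <- I0_init; a_hat <- a_init
  } else {
    co <- stats::coef(fit)
    I0_hat <- unname(co["I0"]); a_hat <- unname(co["a"])
  }
  ss_res <- sum((Iw - I0_hat * exp(-a_hat * tw))^2)
  new_attenuation_fit(I0_hat, a_hat, 1 - ss_res / ss_tot,
                      k, length(I), length(win), convention)
}

new_attenuation_fit <- function(I0, a_np, r2, k, n_total, n_win, convention) {
  structure(list(I0 = I0, alpha_np_per_cm = a_np,
                 alpha_db_per_cm = a_np * db_conversion_factor(convention),
                 r_squared = r2, fit_start_row = k - 1L,
                 fit_end_row = n_total - 1L, n_points = n_win,
                 convention = convention),
            class = "attenuation_fit")
}

#' @export
print.attenuation_fit <- function(x, ...) {
  cat(sprintf("<attenuation_fit> alpha = %.4g dB/cm (%.4g np/cm), I0 = %.4g, R^2 = %.4f, %d pts\n",
              x$alpha_db_per_cm, x$alpha_np_per_cm, x$I0, x$r_squared,
              x$n_points))
  invisible(x)
}

#' Power-law fit of attenuation versus frequency
#'
#' Fits `alpha = alpha0 * f^n` to (frequency, attenuation) pairs.
#' Initialized by ordinary least squares on `log(alpha) ~ log(f)`, refined
#' by nonlinear least squares in linear space; `r_squared` is reported in
#' linear space. Requires at least 3 distinct positive frequencies and
#' positive attenuations.
#'
#' @param freqs frequencies, MHz; alternatively a data.frame/list with
#'   fields `frequency_MHz` and `alpha_db_per_cm` (then `alphas` is unused).
#' @param alphas attenuation values, dB/cm.
#' @return object of class `power_law_fit`: `alpha0` (dB/(cm MHz^n)), `n`,
#'   `r_squared`, `n_points`, and `init` (the log-log OLS starting values).
#' @export
fit_power_law <- function(freqs, alphas = NULL) {
  if (is.null(alphas)) {
    alphas <- freqs$alpha_db_per_cm
    freqs <- freqs$frequency_MHz
  }
  if (!is.numeric(freqs) || !is.numeric(alphas) ||
      length(freqs) != length(alphas))
    abort_invalid("freqs and alphas must be numeric vectors of equal length")
  if (length(freqs) < 3L)
    abort_invalid("at least 3 (frequency, alpha) points are required")
  if (any(!is.finite(freqs)) || any(freqs <= 0) ||
      any(!is.finite(alphas)) || any(alphas <= 0))
    abort_invalid("frequencies and attenuations must all be positive")
  if (length(unique(freqs)) < 3L)
    abort_invalid("at least 3 distinct frequencies are required")

  lf <- stats::lm(log(alphas) ~ log(freqs))
  a0_init <- exp(unname(stats::coef(lf)[1]))
  n_init <- unname(stats::coef(lf)[2])
  fit <- tryCatch(
    minpack.lm::nlsLM(alphas ~ a0 * freqs^nn,
                      start = list(a0 = a0_init, nn = n_init),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    a0 <- a0_init; n <- n_init
  } else {
    co <- stats::coef(fit)
    a0 <- unname(co["a0"]); n <- unname(co["nn"])
  }
  ss_res <- sum((alphas - a0 * freqs^n)^2)
  ss_tot <- sum((alphas - mean(alphas))^2)
  structure(list(alpha0 = a0, n = n,
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
                 n_points = length(freqs),
                 init = list(alpha0 = a0_init, n = n_init)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> alpha = %.4g * f^%.4g, R^2 = %.4f (%d pts)\n",
              x$alpha0, x$n, x$r_squared, x$n_points))
  invisible(x)
}

#' Fold change of attenuation between environments
#'
#' `(alpha_new - alpha_ref) / alpha_ref`: e.g. 1.5 means a 1.5-fold
#' increase over the reference (typically the aqueous-bath measurement).
#'
#' @param alpha_ref reference attenuation (> 0).
#' @param alpha_new comparison attenuation; vectorized.
#' @return dimensionless fold change.
#' @export
fold_change <- function(alpha_ref, alpha_new) {
  if (!is.numeric(alpha_ref) || any(!is.finite(alpha_ref)) || any(alpha_ref <= 0))
    abort_invalid("alpha_ref must be positive")
  (alpha_new - alpha_ref) / alpha_ref
}

#' Aggregate replicate attenuation fits
#'
#' Mean and standard error of the mean (sample SD / sqrt(N); 0 when N = 1)
#' of the replicate `alpha_db_per_cm` values, with grouping metadata.
#'
#' @param fits list of [fit_exponential()] results, or a numeric vector of
#'   alpha values in dB/cm.
#' @param material,environment,frequency_MHz,temperature_C grouping metadata.
#' @return one-row data.frame: `material`, `environment`, `frequency_MHz`,
#'   `temperature_C`, `alpha_db_cm`, `sem`, `n_reps`, `r_squared` (mean of
#'   replicate R^2; `NA` for plain numeric input).
#' @export
aggregate_replicates <- function(fits, material = NA_character_,
                                 environment = NA_character_,
                                 frequency_MHz = NA_real_,
                                 temperature_C = NA_real_) {
  if (is.numeric(fits)) {
    alphas <- fits
    r2 <- NA_real_
  } else if (is.list(fits) && length(fits) > 0 &&
             all(vapply(fits, inherits, logical(1), "attenuation_fit"))) {
    alphas <- vapply(fits, `[[`, numeric(1), "alpha_db_per_cm")
    r2 <- mean(vapply(fits, `[[`, numeric(1), "r_squared"))
  } else {
    abort_invalid("fits must be a nonempty list of attenuation_fit or numeric")
  }
  if (length(alphas) == 0L) abort_invalid("no replicate fits supplied")
  n <- length(alphas)
  data.frame(material = material, environment = environment,
             frequency_MHz = frequency_MHz, temperature_C = temperature_C,
             alpha_db_cm = mean(alphas),
             sem = if (n > 1) stats::sd(alphas) / sqrt(n) else 0,
             n_reps = n, r_squared = r2,
             stringsAsFactors = FALSE)
}
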