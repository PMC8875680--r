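# B-mode image data model: calibrated 8-bit grayscale images, regions of
# interest (0-based, half-open), axial intensity profiles, ROI statistics
# and normalized intensity-map export.

#' Calibrated B-mode image
#'
#' Wraps an 8-bit grayscale pixel grid (rows = axial depth, increasing away
#' from the transducer face; columns = lateral position) with its physical
#' calibration and acquisition metadata.
#'
#' @param pixels numeric matrix with values in `[0, 255]`.
#' @param axial_scale,lateral_scale cm per pixel (> 0).
#' @param frequency_MHz scan frequency; optional.
#' @param environment one of `"Aq"`, `"SC"`, `"SM"` (aqueous bath,
#'   subcutaneous, submuscular placement); optional.
#' @param temperature_C ambient temperature; optional.
#' @param source file path or `"synthetic"`.
#' @return object of class `bmode_image`.
#' @export
bmode_image <- function(pixels, axial_scale, lateral_scale,
                        frequency_MHz = NA_real_, environment = NA_character_,
                        temperature_C = NA_real_, source = "synthetic") {
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0L)
    abort_invalid("pixels must be a nonempty numeric matrix")
  if (any(!is.finite(pixels)) || any(pixels < 0) || any(pixels > 255))
    abort_invalid("pixel values must lie in [0, 255]")
  if (!is_scalar_num(axial_scale) || axial_scale <= 0 ||
      !is_scalar_num(lateral_scale) || lateral_scale <= 0)
    abort_config("axial_scale and lateral_scale must be positive (cm/pixel)")
  if (!is.na(environment) && !environment %in% c("Aq", "SC", "SM"))
    abort_invalid("environment must be one of 'Aq', 'SC', 'SM'")
  structure(list(pixels = pixels, axial_scale = axial_scale,
                 lateral_scale = lateral_scale, frequency_MHz = frequency_MHz,
                 environment = environment, temperature_C = temperature_C,
                 source = source),
            class = "bmode_image")
}

#' @export
print.bmode_image <- function(x, ...) {
  cat(sprintf("<bmode_image> %d x %d px (%.2f x %.2f cm), %s\n",
              nrow(x$pixels), ncol(x$pixels),
              nrow(x$pixels) * x$axial_scale, ncol(x$pixels) * x$lateral_scale,
              x$source))
  if (!is.na(x$frequency_MHz))
    cat(sprintf("  f = %g MHz, env = %s, T = %g C\n",
                x$frequency_MHz, x$environment, x$temperature_C))
  invisible(x)
}

#' Rectangular region of interest
#'
#' 0-based, half-open pixel rectangle `[row0, row1) x [col0, col1)`. Roles
#' mirror the two-region echogenicity protocol: the implant area and its
#' posterior shadow on the implant image, and the matching baseline regions
#' on the implant-free image.
#'
#' @param row0,col0,row1,col1 pixel indices, 0-based, half-open.
#' @param role one of `"implant"`, `"posterior_shadow"`,
#'   `"baseline_implant_area"`, `"baseline_shadow_area"`.
#' @return object of class `roi`.
#' @export
roi <- function(row0, col0, row1, col1,
                role = c("implant", "posterior_shadow",
                         "baseline_implant_area", "baseline_shadow_area")) {
  role <- match.arg(role)
  v <- c(row0, col0, row1, col1)
  if (any(!is.finite(v)) || any(v != floor(v)) || any(v < 0))
    abort_invalid("ROI bounds must be non-negative integers")
  if (!(row0 < row1) || !(col0 < col1))
    abort_invalid("ROI must satisfy row0 < row1 and col0 < col1")
  structure(list(row0 = as.integer(row0), col0 = as.integer(col0),
                 row1 = as.integer(row1), col1 = as.integer(col1),
                 role = role),
            class = "roi")
}

check_roi_in <- function(img, r) {
  if (!inherits(r, "roi")) abort_invalid("expected an roi object")
  if (r$row1 > nrow(img$pixels) || r$col1 > ncol(img$pixels))
    abort_invalid(sprintf(
      "ROI [%d,%d)x[%d,%d) exceeds image %d x %d",
      r$row0, r$row1, r$col0, r$col1, nrow(img$pixels), ncol(img$pixels)))
  invisible(r)
}

roi_rows <- function(r) (r$row0 + 1L):r$row1
roi_cols <- function(r) (r$col0 + 1L):r$col1

#' Read ROI definitions from JSON
#'
#' JSON array of objects `{role, row0, col0, row1, col1}`.
#'
#' @param path JSON file path.
#' @return list of [roi()] objects.
#' @export
read_roi_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  lapply(raw, function(x)
    roi(x$row0, x$col0, x$row1, x$col1, role = x$role))
}

#' Write ROI definitions to JSON
#'
#' @param rois list of [roi()] objects.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_roi_json <- function(rois, path) {
  jsonlite::write_json(lapply(rois, unclass), path, auto_unbox = TRUE)
  invisible(path)
}

#' Read a calibrated grayscale image
#'
#' Accepts 8-bit grayscale PNG or BMP; RGB files are accepted only when all
#' channels are identical (a grayscale image stored as RGB). Higher bit
#' depths are rejected.
#'
#' @param path image file (.png or .bmp).
#' @param axial_scale,lateral_scale cm per pixel; required (calibration is
#'   carried in sidecar metadata, never inferred from the image).
#' @inheritParams bmode_image
#' @return [bmode_image()] with `source = path`.
#' @export
read_bmode <- function(path, axial_scale, lateral_scale,
                       frequency_MHz = NA_real_, environment = NA_character_,
                       temperature_C = NA_real_) {
  if (missing(axial_scale) || missing(lateral_scale))
    abort_config("axial_scale and lateral_scale (cm/pixel) are required")
  if (!file.exists(path)) abort_config(sprintf("image not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path)
    if (length(dim(arr)) == 3L) {
      nch <- dim(arr)[3]
      rgb <- arr[, , seq_len(min(nch, 3L)), drop = FALSE]
      if (dim(rgb)[3] > 1L) {
        for (k in 2:dim(rgb)[3])
          if (any(rgb[, , k] != rgb[, , 1]))
            abort_format("RGB image with differing channels is not grayscale")
      }
      arr <- rgb[, , 1]
    }
    px <- arr * 255
    if (max(abs(px - round(px))) > 1e-9)
      abort_format("image is not 8-bit (pixel levels are not multiples of 1/255)")
    px <- round(px)
  } else if (ext == "bmp") {
    px <- read_bmp_gray(path)
  } else {
    abort_format(sprintf("unsupported image format: .%s (use PNG or BMP)", ext))
  }
  bmode_image(px, axial_scale, lateral_scale, frequency_MHz, environment,
              temperature_C, source = path)
}

#' Write a B-mode image to PNG or BMP
#'
#' Pixels are written as 8-bit grayscale; round-trips bit-exactly with
#' [read_bmode()].
#'
#' @param img [bmode_image()].
#' @param path output path ending in .png or .bmp.
#' @return `path`, invisibly.
#' @export
write_bmode <- function(img, path) {
  if (!inherits(img, "bmode_image")) abort_invalid("img must be a bmode_image")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img$pixels / 255, path)
  } else if (ext == "bmp") {
    write_bmp_gray(img$pixels, path)
  } else {
    abort_format(sprintf("unsupported image format: .%s (use PNG or BMP)", ext))
  }
  invisible(path)
}

#' Laterally averaged axial intensity profile
#'
#' Averages pixel intensity across the ROI width for each row, producing
#' mean intensity versus depth `t` (cm), with `t = 0` at the top of the ROI
#' (attenuation is fitted relative to the implant boundary, not the
#' transducer face). A width-1 ROI returns the single pixel column.
#'
#' @param img [bmode_image()].
#' @param roi [roi()] lying within the image.
#' @return object of class `intensity_profile` with fields `t` (cm,
#'   ascending from 0, spacing = `axial_scale`), `intensity` (mean pixel
#'   value per row) and `n_cols_averaged`.
#' @export
extract_axial_profile <- function(img, roi) {
  check_roi_in(img, roi)
  sub <- img$pixels[roi_rows(roi), roi_cols(roi), drop = FALSE]
  structure(list(t = (seq_len(nrow(sub)) - 1) * img$axial_scale,
                 intensity = rowMeans(sub),
                 n_cols_averaged = ncol(sub),
                 axial_scale = img$axial_scale),
            class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("<intensity_profile> %d rows x %d cols averaged, depth %.2f cm\n",
              length(x$t), x$n_cols_averaged, max(x$t)))
  invisible(x)
}

#' Mean pixel intensity of an ROI
#'
#' @param img [bmode_image()].
#' @param roi [roi()] lying within the image.
#' @return arithmetic mean of all pixels in the ROI, in `[0, 255]`.
#' @export
mean_pixel_intensity <- function(img, roi) {
  check_roi_in(img, roi)
  mean(img$pixels[roi_rows(roi), roi_cols(roi)])
}

#' Normalized 2-D and 3-D intensity maps
#'
#' @param img [bmode_image()].
#' @return list with `map` (pixels / 255, in `[0, 1]`) and `surface`
#'   (`x` lateral cm, `y` axial cm, `z` raw pixel matrix) for surface plots
#'   where height/color encodes pixel intensity.
#' @export
intensity_maps <- function(img) {
  if (!inherits(img, "bmode_image")) abort_invalid("img must be a bmode_image")
  list(map = img$pixels / 255,
       surface = list(
         x = (seq_len(ncol(img$pixels)) - 1) * img$lateral_scale,
         y = (seq_len(nrow(img$pixels)) - 1) * img$axial_scale,
         z = img$pixels))
}

#' Export an intensity map as a CSV grid
#'
#' @param maps result of [intensity_maps()].
#' @param path output CSV path (the normalized 2-D map is written as a
#'   plain numeric grid without headers).
#' @return `path`, invisibly.
#' @export
write_intensity_map_csv <- function(maps, path) {
  utils::write.table(maps$map, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
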