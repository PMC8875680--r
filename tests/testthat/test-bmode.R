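# Image container, ROI statistics, profiles, maps and file round trips.

test_that("axial profiles average laterally and match a brute-force oracle", {
  px <- matrix(rep(200 - (0:99), 20), nrow = 100)  # pixels[r, c] = 200 - r
  img <- bmode_image(px, axial_scale = 0.01, lateral_scale = 0.01)
  prof <- extract_axial_profile(img, roi(10, 5, 40, 10))
  expect_equal(prof$intensity, 200 - 10 - (0:29))
  expect_equal(prof$t, (0:29) * 0.01)
  expect_equal(prof$n_cols_averaged, 5)

  # width-1 ROI is the raw pixel column
  set.seed(11)
  rnd <- matrix(sample(0:255, 100 * 30, replace = TRUE), nrow = 100)
  rimg <- bmode_image(rnd, 0.01, 0.01)
  expect_equal(extract_axial_profile(rimg, roi(0, 7, 100, 8))$intensity,
               rnd[, 8])

  # arbitrary ROI against the double-loop oracle
  expect_equal(extract_axial_profile(rimg, roi(15, 4, 35, 14))$intensity,
               brute_axial_profile(rnd, 15, 4, 35, 14))
  expect_error(extract_axial_profile(rimg, roi(0, 0, 101, 5)),
               class = "echogel_invalid_input")
})

test_that("ROI mean pixel intensity matches brute force and profiles are consistent", {
  img <- bmode_image(matrix(37, 50, 50), 0.01, 0.01)
  expect_equal(mean_pixel_intensity(img, roi(0, 0, 50, 50)), 37)

  checker <- matrix(0, 10, 10); checker[(row(checker) + col(checker)) %% 2 == 0] <- 255
  expect_equal(mean_pixel_intensity(bmode_image(checker, 1, 1), roi(0, 0, 10, 10)),
               127.5)

  set.seed(3)
  rnd <- matrix(sample(0:255, 80 * 40, replace = TRUE), nrow = 80)
  rimg <- bmode_image(rnd, 0.02, 0.01)
  r <- roi(12, 3, 60, 33)
  expect_equal(mean_pixel_intensity(rimg, r), brute_roi_mean(rnd, 12, 3, 60, 33))
  # averaging the lateral-mean profile over depth equals the ROI mean
  expect_equal(mean(extract_axial_profile(rimg, r)$intensity),
               mean_pixel_intensity(rimg, r))
  # purity: operations leave the image untouched
  before <- rimg$pixels
  invisible(extract_axial_profile(rimg, r)); invisible(mean_pixel_intensity(rimg, r))
  expect_identical(rimg$pixels, before)
})

test_that("intensity maps normalize to [0,1] and invert to the pixel grid", {
  expect_true(all(intensity_maps(bmode_image(matrix(255, 5, 5), 1, 1))$map == 1))
  set.seed(9)
  px <- matrix(sample(0:255, 600, replace = TRUE), nrow = 30)
  maps <- intensity_maps(bmode_image(px, 0.01, 0.02))
  expect_equal(round(maps$map * 255), px)
  expect_equal(which.max(maps$surface$z), which.max(px))
  expect_equal(maps$surface$x, (0:19) * 0.02)
  path <- tempfile(fileext = ".csv")
  write_intensity_map_csv(maps, path)
  grid <- as.matrix(utils::read.csv(path, header = FALSE))
  expect_equal(unname(grid), unname(maps$map), tolerance = 1e-12)
})

test_that("PNG and BMP files round-trip bit-exactly", {
  set.seed(21)
  px <- matrix(sample(0:255, 64 * 48, replace = TRUE), nrow = 64)
  img <- bmode_image(px, 0.01, 0.01, frequency_MHz = 8.5, environment = "SC")
  for (ext in c(".png", ".bmp")) {
    path <- tempfile(fileext = ext)
    write_bmode(img, path)
    back <- read_bmode(path, 0.01, 0.01, frequency_MHz = 8.5, environment = "SC")
    expect_equal(back$pixels, px, ignore_attr = TRUE)
  }
  # BMP with width not divisible by 4 exercises row padding
  odd <- bmode_image(px[, 1:45], 0.01, 0.01)
  p <- tempfile(fileext = ".bmp")
  write_bmode(odd, p)
  expect_equal(read_bmode(p, 0.01, 0.01)$pixels, px[, 1:45], ignore_attr = TRUE)
})

test_that("grayscale-as-RGB is accepted, differing channels and 16-bit are rejected", {
  gray <- matrix(runif(100), 10, 10)
  gray <- round(gray * 255) / 255
  rgb_equal <- array(gray, dim = c(10, 10, 3))
  p1 <- tempfile(fileext = ".png")
  png::writePNG(rgb_equal, p1)
  img <- read_bmode(p1, 0.01, 0.01)
  expect_equal(img$pixels, round(gray * 255), ignore_attr = TRUE)

  rgb_diff <- rgb_equal
  rgb_diff[, , 2] <- (gray + 3 / 255) %% 1
  p2 <- tempfile(fileext = ".png")
  png::writePNG(rgb_diff, p2)
  expect_error(read_bmode(p2, 0.01, 0.01), class = "echogel_format_error")

  p3 <- tempfile(fileext = ".png")
  write_png16(matrix(as.integer(seq(0, 65535, length.out = 48)), 6, 8), p3)
  expect_error(read_bmode(p3, 0.01, 0.01), class = "echogel_format_error")

  expect_error(read_bmode(p1), class = "echogel_config_error")
})

test_that("ROI JSON round-trips with roles preserved", {
  rois <- list(roi(0, 0, 10, 10, "implant"),
               roi(10, 0, 40, 10, "posterior_shadow"))
  path <- tempfile(fileext = ".json")
  write_roi_json(rois, path)
  back <- read_roi_json(path)
  expect_equal(back, rois)
  expect_error(roi(5, 0, 5, 10), class = "echogel_invalid_input")
  expect_error(roi(-1, 0, 5, 10), class = "echogel_invalid_input")
})
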