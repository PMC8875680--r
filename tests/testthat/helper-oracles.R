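# Independent oracles used to cross-check the package's estimators.
# Deliberately naive implementations: normal equations, double loops,
# grid search. They share no code with the functions they validate.

# least-squares slope via the normal equations
ols_slope_oracle <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
}

# intercept/slope of y ~ x via normal equations
ols_fit_oracle <- function(x, y) {
  slope <- ols_slope_oracle(x, y)
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# brute-force ROI mean with an explicit double loop (0-based half-open ROI)
brute_roi_mean <- function(pixels, row0, col0, row1, col1) {
  total <- 0; count <- 0
  for (r in (row0 + 1):row1)
    for (c in (col0 + 1):col1) {
      total <- total + pixels[r, c]
      count <- count + 1
    }
  total / count
}

# brute-force per-row lateral mean
brute_axial_profile <- function(pixels, row0, col0, row1, col1) {
  out <- numeric(row1 - row0)
  for (r in seq_len(row1 - row0)) {
    s <- 0
    for (c in (col0 + 1):col1) s <- s + pixels[row0 + r, c]
    out[r] <- s / (col1 - col0)
  }
  out
}

# 2-parameter grid search for I(t) = I0 * exp(-a * t), iteratively zoomed
# until the grid step drops below 1e-4 in both parameters
grid_fit_oracle <- function(t, I, I0_range = c(150, 250), a_range = c(0, 1)) {
  best <- c(NA, NA)
  for (zoom in 1:6) {
    I0s <- seq(I0_range[1], I0_range[2], length.out = 41)
    as <- seq(a_range[1], a_range[2], length.out = 41)
    sse <- outer(I0s, as, function(i0, a)
      vapply(seq_along(i0), function(k)
        sum((I - i0[k] * exp(-a[k] * t))^2), numeric(1)))
    idx <- which(sse == min(sse), arr.ind = TRUE)[1, ]
    best <- c(I0s[idx[1]], as[idx[2]])
    dI <- diff(I0_range) / 8; da <- diff(a_range) / 8
    I0_range <- best[1] + c(-dI, dI)
    a_range <- best[2] + c(-da, da)
  }
  c(I0 = best[1], a = best[2])
}

# --- minimal PNG writer with arbitrary bit depth (for format-contract tests)

crc32_table <- local({
  tbl <- numeric(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (c %% 2 == 1) {
        x <- c %/% 2
        hi <- bitwXor(x %/% 65536, 0xEDB8)
        lo <- bitwXor(x %% 65536, 0x8320)
        hi * 65536 + lo
      } else c %/% 2
    }
    tbl[n + 1] <- c
  }
  tbl
})

crc32 <- function(bytes) {
  c <- 4294967295
  for (b in bytes) {
    idx <- bitwXor(c %% 256, b)
    x <- c %/% 256
    t <- crc32_table[idx + 1]
    hi <- bitwXor(x %/% 65536, t %/% 65536)
    lo <- bitwXor(x %% 65536, t %% 65536)
    c <- hi * 65536 + lo
  }
  bitwXor(c %/% 65536, 65535) * 65536 + bitwXor(c %% 65536, 65535)
}

u32be <- function(x) as.raw(c(x %/% 16777216, (x %/% 65536) %% 256,
                              (x %/% 256) %% 256, x %% 256))

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32be(length(data)), body, u32be(crc32(as.integer(body))))
}

# grayscale PNG with 16-bit samples (values in 0..65535, matrix by rows)
write_png16 <- function(mat, path) {
  h <- nrow(mat); w <- ncol(mat)
  ihdr <- c(u32be(w), u32be(h), as.raw(c(16, 0, 0, 0, 0)))
  rows <- lapply(seq_len(h), function(r) {
    v <- as.integer(mat[r, ])
    as.raw(c(0, rbind(v %/% 256, v %% 256)))
  })
  idat <- memCompress(do.call(c, rows), type = "gzip")
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr), png_chunk("IDAT", idat),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

with_seed_helper <- function(seed, expr) {
  set.seed(seed)
  expr
}

# small fast phantom geometry used where full-size scenes are unnecessary
small_spec <- function(...) {
  phantom_spec(height_px = 200L, width_px = 100L,
               implant_rect = c(30L, 20L, 70L, 80L), ...)
}
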