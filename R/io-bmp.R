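# Minimal 8-bit grayscale BMP reader/writer (BITMAPINFOHEADER, uncompressed,
# 256-entry gray palette, bottom-up row order). Written in-package because
# the ultrasound device exports BMP and no installed R package handles the
# format; only the subset the device produces is supported.

read_u16 <- function(raw, off) as.double(raw[off + 1]) + 256 * as.double(raw[off + 2])
read_u32 <- function(raw, off) {
  sum(as.double(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
}

read_bmp_gray <- function(path) {
  raw <- as.integer(readBin(path, "raw", n = file.size(path)))
  if (length(raw) < 54 || raw[1] != 0x42 || raw[2] != 0x4D)  # "BM"
    abort_format("not a BMP file")
  data_off <- read_u32(raw, 10)
  header_size <- read_u32(raw, 14)
  if (header_size < 40) abort_format("unsupported BMP header")
  width  <- read_u32(raw, 18)
  height <- read_u32(raw, 22)
  if (height >= 2^31) abort_format("top-down BMP not supported")
  bitcount <- read_u16(raw, 28)
  compression <- read_u32(raw, 30)
  if (bitcount != 8) abort_format("only 8-bit BMP is supported")
  if (compression != 0) abort_format("compressed BMP is not supported")
  n_colors <- read_u32(raw, 46)
  if (n_colors == 0) n_colors <- 256
  pal_off <- 14 + header_size
  pal <- matrix(raw[pal_off + seq_len(4 * n_colors)], nrow = 4)
  if (any(pal[1, ] != pal[2, ]) || any(pal[1, ] != pal[3, ]))
    abort_format("BMP palette is not grayscale")
  gray_of <- pal[1, ]  # maps palette index+1 -> gray level
  stride <- 4 * ceiling(width / 4)
  px <- matrix(0, nrow = height, ncol = width)
  for (r in seq_len(height)) {
    row_start <- data_off + (height - r) * stride
    idx <- raw[row_start + seq_len(width)]
    px[r, ] <- gray_of[idx + 1]
  }
  px
}

write_bmp_gray <- function(pixels, path) {
  if (any(pixels != floor(pixels)))
    abort_invalid("BMP writer requires integer pixel levels")
  height <- nrow(pixels); width <- ncol(pixels)
  stride <- 4 * ceiling(width / 4)
  data_off <- 14 + 40 + 4 * 256
  file_size <- data_off + stride * height
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("BM"), con)
  u32(file_size); u16(0); u16(0); u32(data_off)
  u32(40); u32(width); u32(height); u16(1); u16(8)
  u32(0); u32(stride * height); u32(2835); u32(2835); u32(256); u32(0)
  pal <- as.raw(rbind(0:255, 0:255, 0:255, rep(0L, 256)))
  writeBin(pal, con)
  pad <- as.raw(rep(0L, stride - width))
  for (r in rev(seq_len(height))) {
    writeBin(as.raw(pixels[r, ]), con)
    if (length(pad)) writeBin(pad, con)
  }
  invisible(path)
}
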