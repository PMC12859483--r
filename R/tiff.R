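# Minimal baseline TIFF codec for segmentation label images.
#
# Scope: uncompressed, single-sample (grayscale) rasters, 8/16/32-bit
# unsigned integer or 32-bit float samples, single- or multi-page (pages
# become the third array dimension). This is all that object-prediction
# exports need; no compression schemes, palettes or RGB are supported.
# No TIFF package ships with the supported runtime, hence the in-repo codec.

.TIFF_TYPE_SIZES <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L)

read_uint <- function(raw, offset, size, endian) {
  v <- readBin(raw[(offset + 1):(offset + size)], "integer",
    n = 1L, size = size, signed = FALSE, endian = endian
  )
  as.numeric(v)
}

# 4-byte unsigned read that survives values >= 2^31
read_uint32 <- function(raw, offset, endian) {
  b <- as.integer(raw[(offset + 1):(offset + 4)])
  if (endian == "big") b <- rev(b)
  b[1] + b[2] * 256 + b[3] * 65536 + b[4] * 16777216
}

uint32_bytes <- function(x) {
  x <- as.numeric(x)
  as.raw(as.vector(rbind(
    x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256, (x %/% 16777216) %% 256
  )))
}

uint16_bytes <- function(x) {
  as.raw(c(x %% 256, x %/% 256))
}

#' Read an uncompressed grayscale TIFF
#'
#' @param path path to a TIFF file.
#' @return numeric array, `dim = c(height, width)` for a single page or
#'   `c(height, width, pages)` for a stack, with attribute `sample_format`
#'   (`"uint"` or `"float"`) and `bits`.
#' @keywords internal
read_tiff_gray <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  magic <- rawToChar(raw[1:2])
  endian <- switch(magic,
    II = "little",
    MM = "big",
    stop("not a TIFF file: ", path)
  )
  if (read_uint(raw, 2, 2, endian) != 42) stop("bad TIFF magic in ", path)
  ifd_off <- read_uint32(raw, 4, endian)
  pages <- list()
  fmt <- NULL
  bits <- NULL
  while (ifd_off != 0) {
    n_tags <- read_uint(raw, ifd_off, 2, endian)
    tags <- list()
    for (i in seq_len(n_tags)) {
      base <- ifd_off + 2 + (i - 1) * 12
      id <- read_uint(raw, base, 2, endian)
      type <- read_uint(raw, base + 2, 2, endian)
      count <- read_uint32(raw, base + 4, endian)
      size <- .TIFF_TYPE_SIZES[type] * count
      voff <- if (size <= 4) base + 8 else read_uint32(raw, base + 8, endian)
      unit <- .TIFF_TYPE_SIZES[type]
      vals <- vapply(seq_len(count), function(j) {
        o <- voff + (j - 1) * unit
        if (type == 3L) read_uint(raw, o, 2, endian) else read_uint32(raw, o, endian)
      }, numeric(1))
      tags[[as.character(id)]] <- vals
    }
    need <- function(id, default = NULL) {
      v <- tags[[as.character(id)]]
      if (is.null(v)) {
        if (is.null(default)) stop("TIFF tag ", id, " missing in ", path)
        default
      } else {
        v
      }
    }
    width <- need(256)
    height <- need(257)
    bps <- need(258, 1)[1]
    if (need(259, 1) != 1) stop("compressed TIFF not supported: ", path)
    if (need(277, 1) != 1) stop("multi-sample TIFF not supported: ", path)
    sf <- need(339, 1)[1]
    page_fmt <- if (sf == 3) "float" else "uint"
    offs <- need(273)
    counts <- need(279)
    data_raw <- raw(0)
    for (s in seq_along(offs)) {
      data_raw <- c(data_raw, raw[(offs[s] + 1):(offs[s] + counts[s])])
    }
    bytes <- bps / 8
    n_px <- width * height
    px <- if (page_fmt == "float") {
      readBin(data_raw, "double", n = n_px, size = 4, endian = endian)
    } else if (bytes <= 2) {
      readBin(data_raw, "integer", n = n_px, size = bytes, signed = FALSE, endian = endian)
    } else {
      # 32-bit unsigned: reassemble from halves to dodge signed overflow
      lo_hi <- readBin(data_raw, "integer", n = 2 * n_px, size = 2, signed = FALSE, endian = endian)
      if (endian == "little") {
        lo_hi[seq(1, 2 * n_px, 2)] + lo_hi[seq(2, 2 * n_px, 2)] * 65536
      } else {
        lo_hi[seq(1, 2 * n_px, 2)] * 65536 + lo_hi[seq(2, 2 * n_px, 2)]
      }
    }
    page <- matrix(px, nrow = height, ncol = width, byrow = TRUE)
    pages[[length(pages) + 1L]] <- page
    fmt <- fmt %||% page_fmt
    bits <- bits %||% bps
    ifd_off <- read_uint32(raw, ifd_off + 2 + n_tags * 12, endian)
  }
  arr <- if (length(pages) == 1L) {
    pages[[1L]]
  } else {
    array(unlist(pages), dim = c(dim(pages[[1L]]), length(pages)))
  }
  structure(arr, sample_format = fmt, bits = bits)
}

#' Write an uncompressed grayscale TIFF
#'
#' @param arr numeric/integer array of dim (height, width) or
#'   (height, width, pages).
#' @param path output path.
#' @param bits bits per sample: 8, 16 or 32.
#' @param sample_format `"uint"` or `"float"` (float forces `bits = 32`).
#' @keywords internal
write_tiff_gray <- function(arr, path, bits = 16L, sample_format = "uint") {
  if (sample_format == "float") bits <- 32L
  stopifnot(bits %in% c(8L, 16L, 32L))
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  h <- dim(arr)[1]
  w <- dim(arr)[2]
  n_pages <- dim(arr)[3]
  if (sample_format == "uint") {
    if (any(arr < 0) || any(arr > 2^bits - 1)) {
      stop("values out of range for ", bits, "-bit unsigned TIFF")
    }
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(uint16_bytes(42), con)
  # IFD chain starts right after the 8-byte header; per page: IFD then data
  n_tags <- 10L
  ifd_size <- 2 + n_tags * 12 + 4
  data_size <- h * w * (bits / 8)
  page_size <- ifd_size + data_size
  writeBin(uint32_bytes(8), con)
  sf_code <- if (sample_format == "float") 3 else 1
  for (p in seq_len(n_pages)) {
    ifd_off <- 8 + (p - 1) * page_size
    data_off <- ifd_off + ifd_size
    next_ifd <- if (p < n_pages) ifd_off + page_size else 0
    tag <- function(id, type, count, value) {
      out <- c(uint16_bytes(id), uint16_bytes(type), uint32_bytes(count))
      val <- if (type == 3) c(uint16_bytes(value), as.raw(c(0, 0))) else uint32_bytes(value)
      c(out, val)
    }
    ifd <- c(
      uint16_bytes(n_tags),
      tag(256, 4, 1, w),
      tag(257, 4, 1, h),
      tag(258, 3, 1, bits),
      tag(259, 3, 1, 1), # no compression
      tag(262, 3, 1, 1), # black-is-zero
      tag(273, 4, 1, data_off),
      tag(277, 3, 1, 1),
      tag(278, 4, 1, h),
      tag(279, 4, 1, data_size),
      tag(339, 3, 1, sf_code),
      uint32_bytes(next_ifd)
    )
    writeBin(ifd, con)
    px <- as.numeric(t(arr[, , p])) # row-major
    if (sample_format == "float") {
      writeBin(px, con, size = 4, endian = "little")
    } else if (bits == 32L) {
      writeBin(uint32_bytes(px), con)
    } else {
      writeBin(as.integer(px), con, size = bits / 8, endian = "little")
    }
  }
  invisible(path)
}
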