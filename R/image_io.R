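#' Read a grayscale image
#'
#' Reads an 8-bit image file into the package's internal convention: a
#' numeric matrix of intensities in `[0, 1]`, rows indexing image rows
#' (top to bottom) and columns indexing image columns. Color inputs are
#' converted to luma with the Rec. 601 weights (0.299 R, 0.587 G,
#' 0.114 B).
#'
#' Supported containers: PNG (via the \pkg{png} package), PGM (plain `P2`
#' and binary `P5`, maximum gray value up to 65535), and uncompressed BMP
#' (8-bit palette or 24-bit BGR).
#'
#' @param path path to a `.png`, `.pgm` or `.bmp` file.
#' @return numeric matrix in `[0, 1]`.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) vp_stop("invalid_input", sprintf("no such image file: '%s'", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = .read_png_gray(path),
    pgm = .read_pgm(path),
    bmp = .read_bmp_gray(path),
    vp_stop("invalid_input", sprintf("unsupported image format '.%s' (use png, pgm or bmp)", ext))
  )
  img
}

#' Write a grayscale image
#'
#' Writes a `[0, 1]` intensity matrix as an 8-bit grayscale PNG or plain
#' (`P2`) PGM, chosen by file extension.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param path destination path ending in `.png` or `.pgm`.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path) {
  check_gray_image(img)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img, target = path)
  } else if (ext == "pgm") {
    vals <- round(pmin(pmax(img, 0), 1) * 255)
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(img), nrow(img)), "255"), con)
    write(t(vals), file = con, ncolumns = ncol(img))
  } else {
    vp_stop("invalid_input", "write_gray_image writes .png or .pgm only")
  }
  invisible(path)
}

check_gray_image <- function(img, min_dim = 1L) {
  if (!is.matrix(img) || !is.numeric(img)) {
    vp_stop("invalid_input", "a gray image must be a 2-D numeric matrix")
  }
  if (nrow(img) < min_dim || ncol(img) < min_dim) {
    vp_stop("invalid_input",
            sprintf("image is %dx%d but at least %dx%d is required",
                    nrow(img), ncol(img), min_dim, min_dim))
  }
  if (anyNA(img)) vp_stop("invalid_input", "image contains missing values")
  invisible(TRUE)
}

.luma <- function(arr) {
  0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
}

.read_png_gray <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 2L) return(arr)
  if (dim(arr)[3] >= 3L) return(.luma(arr))
  arr[, , 1]  # gray + alpha
}

# PGM: plain P2 or raw P5, with '#' comments permitted in the header.
.read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- function() {
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) vp_stop("invalid_input", "truncated PGM header")
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "\n") break
        }
      } else if (!grepl("[ \t\r\n]", ch)) break
    }
    out <- ch
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L || grepl("[ \t\r\n]", ch)) break
      out <- paste0(out, ch)
    }
    out
  }
  magic <- tok()
  if (!magic %in% c("P2", "P5")) {
    vp_stop("invalid_input", sprintf("not a PGM file (magic '%s')", magic))
  }
  w <- as.integer(tok()); h <- as.integer(tok()); maxval <- as.integer(tok())
  if (anyNA(c(w, h, maxval)) || w < 1L || h < 1L || maxval < 1L) {
    vp_stop("invalid_input", "malformed PGM header")
  }
  n <- w * h
  if (magic == "P5") {
    if (maxval < 256L) {
      vals <- as.integer(readBin(con, "raw", n))
    } else {
      hi <- readBin(con, "raw", 2L * n)
      vals <- as.integer(hi[c(TRUE, FALSE)]) * 256L + as.integer(hi[c(FALSE, TRUE)])
    }
  } else {
    rest <- readChar(con, file.info(path)$size, useBytes = TRUE)
    vals <- as.integer(scan(text = rest, what = integer(), n = n, quiet = TRUE))
  }
  if (length(vals) < n) vp_stop("invalid_input", "truncated PGM pixel data")
  matrix(vals / maxval, nrow = h, ncol = w, byrow = TRUE)
}

# BMP: BITMAPINFOHEADER, uncompressed (BI_RGB), 8-bit palette or 24-bit BGR.
.read_bmp_gray <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  u16 <- function(i) as.integer(bytes[i]) + 256L * as.integer(bytes[i + 1L])
  u32 <- function(i) sum(as.numeric(bytes[i + 0:3]) * 256^(0:3))
  if (rawToChar(bytes[1:2]) != "BM") vp_stop("invalid_input", "not a BMP file")
  data_off <- u32(11L)
  header_size <- u32(15L)
  w <- u32(19L); h_raw <- u32(23L)
  top_down <- h_raw > 2^31
  h <- if (top_down) 2^32 - h_raw else h_raw
  bpp <- u16(29L)
  compression <- u32(31L)
  if (compression != 0) vp_stop("invalid_input", "compressed BMP is not supported")
  if (!bpp %in% c(8L, 24L)) vp_stop("invalid_input", "only 8-bit and 24-bit BMP are supported")
  row_bytes <- ((w * bpp / 8 + 3) %/% 4) * 4
  img <- matrix(0, nrow = h, ncol = w)
  if (bpp == 8L) {
    pal_off <- 15L + header_size
    n_colors <- u32(47L); if (n_colors == 0) n_colors <- 256
    pal <- matrix(as.integer(bytes[pal_off - 1L + seq_len(4 * n_colors)]),
                  ncol = 4L, byrow = TRUE)  # B, G, R, reserved
    gray <- (0.299 * pal[, 3] + 0.587 * pal[, 2] + 0.114 * pal[, 1]) / 255
  }
  for (r in seq_len(h)) {
    off <- data_off + (r - 1L) * row_bytes
    out_row <- if (top_down) r else h - r + 1L
    if (bpp == 8L) {
      idx <- as.integer(bytes[off + seq_len(w)]) + 1L
      img[out_row, ] <- gray[idx]
    } else {
      trip <- as.integer(bytes[off + seq_len(3L * w)])
      b <- trip[c(TRUE, FALSE, FALSE)]; g <- trip[c(FALSE, TRUE, FALSE)]
      r_ <- trip[c(FALSE, FALSE, TRUE)]
      img[out_row, ] <- (0.299 * r_ + 0.587 * g + 0.114 * b) / 255
    }
  }
  img
}
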