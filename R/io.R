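# ---- PNG codec -------------------------------------------------------
# Dependency-free PNG reader/writer built on base R's zlib bindings
# (memCompress/memDecompress emit RFC 1950 streams, which is exactly the
# PNG IDAT payload). Supports 8/16-bit greyscale and RGB, non-interlaced;
# alpha channels are read and dropped.

crc32_table <- local({
  tab <- integer(256)
  for (i in 0:255) {
    c <- i
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L)
        bitwXor(-306674912L, bitwShiftR(bitwAnd(c, -2L), 1))  # 0xEDB88320
      else bitwShiftR(bitwAnd(c, -2L), 1)
    }
    tab[i + 1] <- c
  }
  tab
})

crc32 <- function(bytes) {
  c <- -1L
  v <- as.integer(bytes)
  for (b in v) {
    idx <- bitwAnd(bitwXor(c, b), 255L)
    c <- bitwXor(crc32_table[idx + 1L], bitwShiftR(bitwAnd(c, -256L), 8))
  }
  bitwXor(c, -1L)
}

u32be <- function(x) {
  x <- as.numeric(x) %% 2^32
  as.raw(c(x %/% 2^24, (x %/% 2^16) %% 256, (x %/% 256) %% 256, x %% 256))
}

read_u32be <- function(r) {
  sum(as.integer(r) * c(2^24, 2^16, 2^8, 1))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32be(length(data)), body, u32be(crc32(body)))
}

#' Write an image as PNG
#'
#' Values are clamped to `[0, 1]` (with a warning if anything was out of
#' range) and quantized to the requested bit depth. Greyscale matrices
#' are written as single-channel PNGs; `H x W x 3` arrays as RGB. The
#' encoder is deterministic: identical input produces identical bytes.
#'
#' @param image `H x W` matrix or `H x W x 3` array.
#' @param path Output path.
#' @param bit_depth 8 or 16.
#' @return Invisibly, `path`.
#' @export
write_image <- function(image, path, bit_depth = 8L) {
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  if (any(image < 0 | image > 1, na.rm = TRUE)) {
    warning("image values outside [0, 1] clamped before quantization")
    image <- pmin(pmax(image, 0), 1)
  }
  image[is.na(image)] <- 0
  gray <- is.matrix(image)
  if (!gray && (length(dim(image)) != 3L || dim(image)[3] != 3L))
    stop("expected an H x W matrix or H x W x 3 array")
  h <- dim(image)[1]; w <- dim(image)[2]
  maxv <- 2^bit_depth - 1
  q <- round(image * maxv)
  nch <- if (gray) 1L else 3L
  # interleave channels row-major (PNG scanline order)
  px <- if (gray) as.vector(t(q)) else {
    m <- matrix(0, nch, h * w)
    for (c in 1:3) m[c, ] <- as.vector(t(q[, , c]))
    as.vector(m)
  }
  bytes <- if (bit_depth == 8L) as.raw(px) else
    as.raw(as.vector(rbind(px %/% 256, px %% 256)))
  bpr <- w * nch * (bit_depth / 8)               # bytes per row
  rows <- matrix(bytes, nrow = bpr)
  scan <- as.raw(rbind(as.raw(0L), rows))        # filter byte 0 per row
  ihdr <- c(u32be(w), u32be(h), as.raw(c(bit_depth, if (gray) 0L else 2L,
                                         0L, 0L, 0L)))
  out <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", memCompress(as.vector(scan), type = "gzip")),
           png_chunk("IEND", raw(0)))
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(out, con)
  invisible(path)
}

paeth <- function(a, b, c) {
  p <- a + b - c
  pa <- abs(p - a); pb <- abs(p - b); pc <- abs(p - c)
  ifelse(pa <= pb & pa <= pc, a, ifelse(pb <= pc, b, c))
}

png_unfilter <- function(scan, h, bpr, bpp) {
  out <- matrix(0L, bpr, h)
  prev <- integer(bpr)
  pos <- 1L
  for (y in seq_len(h)) {
    ft <- as.integer(scan[pos])
    row <- as.integer(scan[(pos + 1L):(pos + bpr)])
    pos <- pos + bpr + 1L
    if (ft == 0L) {
      # none
    } else if (ft == 2L) {
      row <- (row + prev) %% 256L
    } else if (ft == 1L) {
      for (i in seq_len(bpr)) {
        left <- if (i > bpp) row[i - bpp] else 0L
        row[i] <- (row[i] + left) %% 256L
      }
    } else if (ft == 3L) {
      for (i in seq_len(bpr)) {
        left <- if (i > bpp) row[i - bpp] else 0L
        row[i] <- (row[i] + (left + prev[i]) %/% 2L) %% 256L
      }
    } else if (ft == 4L) {
      for (i in seq_len(bpr)) {
        left <- if (i > bpp) row[i - bpp] else 0L
        ul <- if (i > bpp) prev[i - bpp] else 0L
        row[i] <- (row[i] + paeth(left, prev[i], ul)) %% 256L
      }
    } else stop("unsupported PNG filter type ", ft)
    out[, y] <- row
    prev <- row
  }
  out
}

#' Read a PNG image as normalized radiance
#'
#' Reads 8- or 16-bit, greyscale or RGB (alpha dropped), non-interlaced
#' PNG files and returns an `H x W x 3` array normalized to `[0, 1]` by
#' the file's bit depth. Greyscale data is replicated to three channels.
#'
#' @param path Path to a PNG file.
#' @return `H x W x 3` numeric array in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  raw_all <- readBin(path, "raw", file.info(path)$size)
  sig <- as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))
  if (length(raw_all) < 8 || !identical(raw_all[1:8], sig))
    stop("unsupported or corrupt image file (PNG expected): ", path)
  pos <- 9L
  idat <- raw(0)
  ihdr <- NULL
  while (pos + 8 <= length(raw_all)) {
    len <- read_u32be(raw_all[pos:(pos + 3L)])
    type <- rawToChar(raw_all[(pos + 4L):(pos + 7L)])
    data <- if (len > 0) raw_all[(pos + 8L):(pos + 7L + len)] else raw(0)
    if (type == "IHDR") ihdr <- data
    if (type == "IDAT") idat <- c(idat, data)
    if (type == "IEND") break
    pos <- pos + 12L + len
  }
  if (is.null(ihdr)) stop("corrupt PNG (no IHDR): ", path)
  w <- read_u32be(ihdr[1:4]); h <- read_u32be(ihdr[5:8])
  bit_depth <- as.integer(ihdr[9]); colour <- as.integer(ihdr[10])
  if (as.integer(ihdr[13]) != 0L) stop("interlaced PNG not supported: ", path)
  nch <- switch(as.character(colour), "0" = 1L, "2" = 3L, "4" = 2L, "6" = 4L,
                stop("unsupported PNG colour type ", colour, ": ", path))
  if (!bit_depth %in% c(8L, 16L))
    stop("unsupported PNG bit depth ", bit_depth, ": ", path)
  scan <- memDecompress(idat, type = "gzip")
  bpp <- nch * bit_depth %/% 8L
  bpr <- w * bpp
  if (length(scan) != h * (bpr + 1L)) stop("corrupt PNG scanline data: ", path)
  bytes <- png_unfilter(scan, h, bpr, bpp)        # bpr x h (columns = rows)
  if (bit_depth == 16L) {
    v <- (bytes[seq(1, bpr, 2), , drop = FALSE] * 256 +
            bytes[seq(2, bpr, 2), , drop = FALSE]) / 65535
  } else v <- bytes / 255
  # v is (w*nch) x h with channel-interleaved rows; split channels
  arr <- array(0, c(h, w, 3))
  keep <- if (nch >= 3L) 1:3 else c(1L, 1L, 1L)
  for (ci in 1:3) {
    ch <- keep[ci]
    arr[, , ci] <- t(v[seq(ch, w * nch, nch), , drop = FALSE])
  }
  arr
}

# ---- plain-text maps and sidecars ------------------------------------

#' Write a numeric map as a plain-text matrix
#'
#' Whitespace-separated full-precision text, one image row per line;
#' lossless for later [read_matrix_txt()]. Used for transmission,
#' difference and radiance maps.
#'
#' @param m Matrix (or one plane of an array).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_matrix_txt <- function(m, path) {
  utils::write.table(format(m, digits = 17, scientific = TRUE, trim = TRUE),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_txt
#' @export
read_matrix_txt <- function(path) {
  as.matrix(utils::read.table(path, header = FALSE))
}

# Provenance sidecar written next to every artifact output.
write_sidecar <- function(dir, params) {
  params$tool <- "desmokeR"
  params$version <- as.character(utils::packageVersion("desmokeR"))
  params$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(params, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

# ---- minimal TOML subset parser --------------------------------------

#' Read a TOML-subset configuration file
#'
#' Parses the subset of TOML used by the simulator configs: `[section]`
#' headers, `key = value` lines with numeric, boolean, quoted-string or
#' flat-array (`[1, 2, 3]`) values, and `#` comments.
#'
#' @param path Path to the config file.
#' @return Nested named list (one element per section).
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list(); section <- NULL
  parse_val <- function(v) {
    v <- trimws(v)
    if (grepl("^\\[.*\\]$", v)) {
      parts <- strsplit(substr(v, 2, nchar(v) - 1), ",")[[1]]
      return(vapply(parts, function(p) parse_val(p), numeric(1),
                    USE.NAMES = FALSE))
    }
    if (v %in% c("true", "false")) return(v == "true")
    if (grepl('^".*"$', v)) return(substr(v, 2, nchar(v) - 1))
    n <- suppressWarnings(as.numeric(v))
    if (is.na(n)) stop("cannot parse config value: ", v)
    n
  }
  for (ln in lines) {
    ln <- sub("#.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- substr(ln, 2, nchar(ln) - 1)
      out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      val <- parse_val(paste(kv[-1], collapse = "="))
      if (is.null(section)) out[[key]] <- val else out[[section]][[key]] <- val
    }
  }
  out
}
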