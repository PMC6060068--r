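# Minimal grayscale PNG codec (color type 0, bit depth 8/16, no interlace).
# R's memCompress(type = "gzip") emits a zlib-framed deflate stream (0x78
# header + Adler-32 trailer), which is exactly PNG's IDAT payload format;
# memDecompress inverts it.

crc32_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- integer(256)
      for (n in 0:255) {
        c <- n
        for (k in 1:8)
          c <- if (bitwAnd(c, 1L) != 0L)
            bitwXor(-306674912L, bitwShiftR(bitwAnd(c, -2L), 1))  # 0xEDB88320
          else bitwShiftR(bitwAnd(c, -2L), 1)
        t[n + 1] <- c
      }
      tab <<- t
    }
    tab
  }
})

crc32 <- function(bytes) {
  tab <- crc32_table()
  c <- -1L  # 0xFFFFFFFF
  v <- as.integer(bytes)
  for (b in v) {
    idx <- bitwAnd(bitwXor(c, b), 255L)
    c <- bitwXor(bitwShiftR(bitwAnd(c, -256L), 8), tab[idx + 1])
  }
  bitwXor(c, -1L)
}

int_to_raw4 <- function(x) {
  x <- as.numeric(x) %% 4294967296
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  crc <- crc32(body)
  c(int_to_raw4(length(data)), body, int_to_raw4(as.numeric(crc) %% 4294967296))
}

#' Write a matrix as a grayscale PNG
#'
#' Stores a nonnegative integer-valued matrix as an 8- or 16-bit grayscale
#' PNG.
#'
#' @param values Numeric matrix with values in `0..2^bit_depth - 1`.
#' @param path Output path.
#' @param bit_depth 8 or 16 (default 16).
#' @return `path`, invisibly.
#' @export
write_png <- function(values, path, bit_depth = 16L) {
  stopifnot(is.matrix(values), bit_depth %in% c(8L, 16L))
  h <- nrow(values); w <- ncol(values)
  maxv <- 2^bit_depth - 1
  if (any(values < 0 | values > maxv))
    stop("values outside 0..", maxv, call. = FALSE)
  # build filtered scanlines: filter byte 0 + big-endian samples
  scan <- vector("list", h)
  for (r in seq_len(h)) {
    rowv <- as.integer(round(values[r, ]))
    bytes <- if (bit_depth == 16L) as.raw(c(rbind(rowv %/% 256L, rowv %% 256L)))
             else as.raw(rowv)
    scan[[r]] <- c(as.raw(0L), bytes)
  }
  payload <- do.call(c, scan)
  zl <- memCompress(payload, "gzip")
  if (as.integer(zl[1]) != 0x78L)     # zlib CMF byte; guards header drift
    stop("memCompress did not return a zlib stream", call. = FALSE)
  ihdr <- c(int_to_raw4(w), int_to_raw4(h), as.raw(c(bit_depth, 0, 0, 0, 0)))
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr), png_chunk("IDAT", zl),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

#' Read a grayscale PNG
#'
#' Reads 8- or 16-bit grayscale (color type 0, non-interlaced) PNG files.
#' Colour images are rejected: holograms are single-channel intensities.
#'
#' @param path File path.
#' @return Numeric matrix.
#' @export
read_png <- function(path) {
  raw_all <- readBin(path, "raw", file.size(path))
  sig <- as.integer(raw_all[1:8])
  if (!identical(sig, c(137L, 80L, 78L, 71L, 13L, 10L, 26L, 10L)))
    stop("not a PNG file", call. = FALSE)
  pos <- 8L
  w <- h <- depth <- ctype <- NULL; idat <- raw(0)
  r4 <- function(p) sum(as.integer(raw_all[p + 1:4]) * c(16777216, 65536, 256, 1))
  while (pos < length(raw_all)) {
    len <- r4(pos); type <- rawToChar(raw_all[pos + 5:8])
    data <- if (len > 0) raw_all[pos + 8 + seq_len(len)] else raw(0)
    if (type == "IHDR") {
      w <- r4(pos + 8); h <- r4(pos + 12)
      depth <- as.integer(data[9]); ctype <- as.integer(data[10])
      if (ctype != 0L)
        stop("colour PNG not supported; supply grayscale", call. = FALSE)
      if (!depth %in% c(8L, 16L)) stop("unsupported PNG bit depth", call. = FALSE)
      if (as.integer(data[13]) != 0L) stop("interlaced PNG not supported", call. = FALSE)
    } else if (type == "IDAT") {
      idat <- c(idat, data)
    } else if (type == "IEND") break
    pos <- pos + 12L + len
  }
  payload <- memDecompress(idat, "gzip")
  bpp <- depth %/% 8L
  stride <- 1L + w * bpp
  if (length(payload) != h * stride) stop("corrupt PNG payload", call. = FALSE)
  m <- matrix(0, h, w)
  prev <- integer(w * bpp)
  for (r in seq_len(h)) {
    line <- payload[(r - 1) * stride + seq_len(stride)]
    filt <- as.integer(line[1])
    cur <- as.integer(line[-1])
    # undo per-byte filters (types 0..4); "left" neighbour is bpp back
    if (filt != 0L) {
      recon <- integer(length(cur))
      for (i in seq_along(cur)) {
        a <- if (i > bpp) recon[i - bpp] else 0L
        b <- prev[i]
        cc <- if (i > bpp) prev[i - bpp] else 0L
        add <- switch(filt + 1L, 0L, a, b, (a + b) %/% 2L, {
          p <- a + b - cc
          pa <- abs(p - a); pb <- abs(p - b); pc <- abs(p - cc)
          if (pa <= pb && pa <= pc) a else if (pb <= pc) b else cc
        })
        recon[i] <- (cur[i] + add) %% 256L
      }
      cur <- recon
    }
    prev <- cur
    m[r, ] <- if (bpp == 2L) cur[c(TRUE, FALSE)] * 256 + cur[c(FALSE, TRUE)]
              else cur
  }
  m
}
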