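# Minimal baseline TIFF codec: uncompressed, little-endian, single-channel,
# 32-bit float or 16-bit unsigned, one strip per page, multi-page. Written
# by hand because the target environment ships no R TIFF reader; the
# format subset is the plain baseline profile that any TIFF tool reads.
# Acquisition metadata (pixel pitch, wavelength, intensity scale, frame
# tags) travels in a JSON sidecar `<path>.json` for portability rather
# than in vendor TIFF tags.

TIFF_TAGS <- c(ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
               Compression = 259L, Photometric = 262L, StripOffsets = 273L,
               RowsPerStrip = 278L, StripByteCounts = 279L,
               SampleFormat = 339L)

# one 12-byte IFD entry: tag, type, count, value (types: 3 = SHORT, 4 = LONG)
tiff_entry <- function(tag, type, value) {
  v <- as.integer(value)
  c(writeBin(as.integer(tag), raw(), size = 2, endian = "little"),
    writeBin(as.integer(type), raw(), size = 2, endian = "little"),
    writeBin(1L, raw(), size = 4, endian = "little"),
    if (type == 3L) {
      c(writeBin(v, raw(), size = 2, endian = "little"), as.raw(c(0, 0)))
    } else {
      writeBin(v, raw(), size = 4, endian = "little")
    })
}

#' Write matrices as a single- or multi-page TIFF
#'
#' @param path output file path.
#' @param frames a numeric matrix or list of matrices (one page each, all
#'   the same shape).
#' @param sample_format `"float"` (32-bit IEEE) or `"uint16"`; `uint16`
#'   values must already lie in `[0, 65535]`.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(path, frames, sample_format = c("float", "uint16")) {
  sample_format <- match.arg(sample_format)
  if (is.matrix(frames)) frames <- list(frames)
  stopifnot(length(frames) >= 1)
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  bps <- if (sample_format == "float") 32L else 16L
  fmt <- if (sample_format == "float") 3L else 1L
  bytes_pp <- bps %/% 8L
  strip_bytes <- h * w * bytes_pp
  n <- length(frames)
  # layout: 8-byte header, then per page [pixel strip][IFD (9 entries)]
  ifd_bytes <- 2L + 9L * 12L + 4L
  offs <- 8L + cumsum(c(0L, rep(strip_bytes + ifd_bytes, n - 1)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x49, 0x49, 0x2a, 0x00)), con)                 # "II", 42
  writeBin(as.integer(offs[1] + strip_bytes), con, size = 4, endian = "little")
  for (i in seq_len(n)) {
    f <- frames[[i]]
    if (nrow(f) != h || ncol(f) != w) stop("all pages must share one shape", call. = FALSE)
    vals <- as.vector(t(f))                                        # row-major
    if (sample_format == "float") {
      writeBin(as.numeric(vals), con, size = 4, endian = "little")
    } else {
      if (any(vals < 0 | vals > 65535)) {
        stop("uint16 values must lie in [0, 65535]", call. = FALSE)
      }
      writeBin(as.integer(round(vals)), con, size = 2, endian = "little")
    }
    writeBin(9L, con, size = 2, endian = "little")
    writeBin(tiff_entry(TIFF_TAGS["ImageWidth"], 4L, w), con)
    writeBin(tiff_entry(TIFF_TAGS["ImageLength"], 4L, h), con)
    writeBin(tiff_entry(TIFF_TAGS["BitsPerSample"], 3L, bps), con)
    writeBin(tiff_entry(TIFF_TAGS["Compression"], 3L, 1L), con)
    writeBin(tiff_entry(TIFF_TAGS["Photometric"], 3L, 1L), con)
    writeBin(tiff_entry(TIFF_TAGS["StripOffsets"], 4L, offs[i]), con)
    writeBin(tiff_entry(TIFF_TAGS["RowsPerStrip"], 4L, h), con)
    writeBin(tiff_entry(TIFF_TAGS["StripByteCounts"], 4L, strip_bytes), con)
    writeBin(tiff_entry(TIFF_TAGS["SampleFormat"], 3L, fmt), con)
    next_off <- if (i < n) offs[i + 1] + strip_bytes else 0L
    writeBin(as.integer(next_off), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a (multi-page) uncompressed grayscale TIFF
#'
#' Supports the baseline subset written by [write_tiff()] plus any
#' uncompressed single-channel little/big-endian file with contiguous
#' strips (e.g. `tifffile`/ImageJ output).
#'
#' @param path TIFF file path.
#' @param simplify return a bare matrix when the file has one page.
#' @return a matrix, or a list of matrices for multi-page files.
#' @export
read_tiff <- function(path, simplify = TRUE) {
  raw_ <- readBin(path, "raw", file.info(path)$size)
  if (length(raw_) < 8) stop("not a TIFF file: ", path, call. = FALSE)
  order_le <- identical(as.integer(raw_[1:2]), c(0x49L, 0x49L))
  order_be <- identical(as.integer(raw_[1:2]), c(0x4dL, 0x4dL))
  if (!order_le && !order_be) stop("not a TIFF file: ", path, call. = FALSE)
  rd <- function(off, size) {
    b <- as.integer(raw_[off + seq_len(size)])
    if (order_be) b <- rev(b)
    sum(b * 256^(seq_len(size) - 1))
  }
  if (rd(2, 2) != 42) stop("not a TIFF file: ", path, call. = FALSE)
  pages <- list()
  ifd <- rd(4, 4)
  while (ifd != 0) {
    n_ent <- rd(ifd, 2)
    tags <- list()
    for (e in seq_len(n_ent)) {
      base <- ifd + 2 + (e - 1) * 12
      tag <- rd(base, 2); type <- rd(base + 2, 2); count <- rd(base + 4, 4)
      val <- if (type == 3) rd(base + 8, 2) else rd(base + 8, 4)
      if (count > 1 && tag %in% c(273, 279)) {
        # offset/bytecount arrays (multiple strips): value is a pointer
        sz <- if (type == 3) 2 else 4
        val <- vapply(seq_len(count) - 1, function(k) rd(val + k * sz, sz),
                      numeric(1))
      }
      tags[[as.character(tag)]] <- val
    }
    need <- c("256", "257", "258", "273", "279")
    if (!all(need %in% names(tags))) stop("unsupported TIFF: missing tags", call. = FALSE)
    if (!is.null(tags[["259"]]) && tags[["259"]] != 1) {
      stop("unsupported TIFF: compressed data", call. = FALSE)
    }
    w <- tags[["256"]]; h <- tags[["257"]]; bps <- tags[["258"]]
    fmt <- if (is.null(tags[["339"]])) 1 else tags[["339"]]
    offsets <- tags[["273"]]; counts <- tags[["279"]]
    buf <- unlist(lapply(seq_along(offsets), function(k) {
      raw_[offsets[k] + seq_len(counts[k])]
    }), use.names = FALSE)
    endian <- if (order_le) "little" else "big"
    vals <- if (fmt == 3 && bps == 32) {
      readBin(buf, "numeric", n = h * w, size = 4, endian = endian)
    } else if (fmt == 1 && bps == 16) {
      readBin(buf, "integer", n = h * w, size = 2, signed = FALSE,
              endian = endian)
    } else if (fmt == 1 && bps == 8) {
      as.integer(buf[seq_len(h * w)])
    } else {
      stop(sprintf("unsupported TIFF sample type: format %d, %d bits", fmt, bps),
           call. = FALSE)
    }
    pages[[length(pages) + 1]] <- matrix(vals, h, w, byrow = TRUE)
    ifd <- rd(ifd + 2 + n_ent * 12, 4)
  }
  if (simplify && length(pages) == 1) pages[[1]] else pages
}

#' Write an image (or frame stack) with sidecar metadata
#'
#' Float phase/mass maps are stored losslessly as 32-bit float TIFF;
#' intensity stacks can be stored as 16-bit unsigned with a recorded
#' linear scale (`stored = round(value / scale)`). Metadata is written to
#' `<path>.json`.
#'
#' @param path output TIFF path.
#' @param image matrix, list of matrices, [phase_map()] or
#'   [interferogram_stack()].
#' @param metadata named list merged into the sidecar.
#' @param sample_format `"float"` or `"uint16"`.
#' @return `path`, invisibly.
#' @export
write_image <- function(path, image, metadata = list(),
                        sample_format = c("float", "uint16")) {
  sample_format <- match.arg(sample_format)
  if (inherits(image, "phase_map")) {
    metadata$pixel_pitch_um <- image$pixel_pitch
    metadata$kind <- "phase"
    image <- image$phi
  } else if (inherits(image, "interferogram_stack")) {
    metadata$pixel_pitch_um <- image$pixel_pitch
    metadata$kind <- "interferogram_stack"
    metadata$modulation_phases_rad <- image$mod_phases
    image <- image$frames
  }
  frames <- if (is.matrix(image)) list(image) else image
  if (sample_format == "uint16") {
    mx <- max(vapply(frames, max, numeric(1)), 0)
    scale <- if (mx > 0) mx / 65535 else 1
    frames <- lapply(frames, function(f) pmin(pmax(round(f / scale), 0), 65535))
    metadata$intensity_scale <- scale
  }
  write_tiff(path, frames, sample_format)
  jsonlite::write_json(metadata, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an image written by [write_image()]
#'
#' @param path TIFF path.
#' @return matrix or list of matrices with the sidecar metadata attached as
#'   attribute `"metadata"`; `uint16` data are rescaled back to physical
#'   units via the recorded `intensity_scale`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  img <- read_tiff(path)
  meta <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (!is.null(meta$intensity_scale)) {
    img <- if (is.matrix(img)) img * meta$intensity_scale
           else lapply(img, function(f) f * meta$intensity_scale)
  }
  attr(img, "metadata") <- meta
  img
}
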