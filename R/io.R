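# Readers and writers for the formats instrument software exports:
# tab/comma-separated pixel tables (one row per pixel, one column per mass
# channel), multi-page 32-bit float TIFF stacks, and per-channel CSV grids.
#
# Reading TIFFs goes through tiff::readTIFF (full float32 support).  Writing
# uses a minimal uncompressed float32 TIFF writer defined below, because
# tiff::writeTIFF stores quantized integer samples and cannot represent
# arbitrary count values bit-exactly.

# ---- channel header grammar ------------------------------------------------

#' Parse a channel header or label
#'
#' Recognizes headers in which an element symbol and a 2-3 digit mass number
#' co-occur in either order, e.g. `"128Te"`, `"Te128"`, `"128Te(Te128Di)"`.
#' Element symbols are case-sensitive.
#'
#' @param header A single header string.
#' @return A list with `element`, `mass` and `raw_header`, or `NULL` if the
#'   string is not a channel header.
#' @export
#' @examples
#' parse_channel_header("128Te(Te128Di)")
parse_channel_header <- function(header) {
  stopifnot(is.character(header), length(header) == 1L)
  m <- regexpr("(\\d{2,3})([A-Z][a-z]?)", header, perl = TRUE)
  if (m != -1L) {
    s <- regmatches(header, m)
    mass <- as.integer(sub("^(\\d{2,3}).*$", "\\1", s))
    element <- sub("^\\d{2,3}", "", s)
  } else {
    m <- regexpr("([A-Z][a-z]?)(\\d{2,3})", header, perl = TRUE)
    if (m == -1L) return(NULL)
    s <- regmatches(header, m)
    element <- sub("\\d{2,3}$", "", s)
    mass <- as.integer(sub("^\\D+", "", s))
  }
  list(element = element, mass = mass, raw_header = header)
}

# ---- pixel tables ----------------------------------------------------------

#' Read an instrument pixel table into an image stack
#'
#' Reads the tab-separated (or comma-separated) pixel-table export: one row
#' per pixel with `X` and `Y` raster coordinates plus one column per mass
#' channel.  Non-channel columns (`Z`, push counters, ...) are skipped and
#' recorded in the stack's provenance.  Row order is irrelevant; the `X`/`Y`
#' coordinates must cover a complete rectangular raster.
#'
#' @param path Path to the table.
#' @param dialect `"tab"` or `"comma"` field separator.
#' @param pixel_size_um Pixel pitch to attach to the channels.
#' @return An [image_stack()].
#' @export
read_pixel_table <- function(path, dialect = c("tab", "comma"),
                             pixel_size_um = 1) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tab") "\t" else ","
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          data.table = FALSE, showProgress = FALSE)
  if (!all(c("X", "Y") %in% names(dt))) {
    stop("pixel table format error: required columns X and Y not found in ",
         path)
  }
  x <- as.integer(dt$X)
  y <- as.integer(dt$Y)
  if (min(x) == 1L && min(y) == 1L) {
    message("pixel table coordinates look 1-based; shifting to 0-based")
    x <- x - 1L
    y <- y - 1L
  }
  w <- max(x) + 1L
  h <- max(y) + 1L
  idx <- y * w + x  # row-major pixel index
  if (anyDuplicated(idx)) stop("pixel table has duplicate (X, Y) coordinates")
  if (length(idx) != h * w) {
    absent <- setdiff(seq_len(h * w) - 1L, idx)[1]
    stop(sprintf("ragged raster: pixel (X=%d, Y=%d) is absent",
                 absent %% w, absent %/% w))
  }
  other <- setdiff(names(dt), c("X", "Y"))
  parsed <- lapply(other, parse_channel_header)
  is_channel <- !vapply(parsed, is.null, logical(1))
  skipped <- other[!is_channel]
  if (length(skipped)) {
    message("skipping non-channel column(s): ", paste(skipped, collapse = ", "))
  }
  if (!any(is_channel)) stop("no parseable channel columns in ", path)
  channels <- Map(function(col, p) {
    m <- matrix(0, h, w)
    m[cbind(y + 1L, x + 1L)] <- as.numeric(dt[[col]])
    channel_image(m, p$element, p$mass, pixel_size_um)
  }, other[is_channel], parsed[is_channel])
  image_stack(unname(channels),
              provenance = list(source = path,
                                skipped_columns = skipped))
}

#' Write an image stack as a pixel table
#'
#' The inverse of [read_pixel_table()]: one row per pixel with 0-based `X`/`Y`
#' coordinates and one column per channel labelled `"<mass><element>"`.
#' Values are written with enough digits to round-trip doubles exactly.
#'
#' @param stack An [image_stack()].
#' @param path Output path.
#' @param dialect `"tab"` or `"comma"`.
#' @export
write_pixel_table <- function(stack, path, dialect = c("tab", "comma")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tab") "\t" else ","
  sh <- stack_shape(stack)
  h <- sh[1]; w <- sh[2]
  xy <- expand.grid(X = 0:(w - 1L), Y = 0:(h - 1L))  # row-major: X fastest
  cols <- c(list(X = xy$X, Y = xy$Y),
            lapply(stack$channels, function(ch) {
              fmt_num(as.vector(t(ch_pixels(ch))))
            }))
  header <- paste(names(cols), collapse = sep)
  body <- do.call(paste, c(unname(cols), list(sep = sep)))
  writeLines(c(header, body), path)
  invisible(NULL)
}

# Shortest decimal representation that round-trips a double exactly.
fmt_num <- function(v) {
  out <- sprintf("%.15g", v)
  bad <- as.numeric(out) != v
  if (any(bad)) out[bad] <- sprintf("%.17g", v[bad])
  out
}

# ---- per-channel CSV grids -------------------------------------------------

#' Read per-channel CSV grids into an image stack
#'
#' Each file holds one channel as a headerless grid of counts; the channel
#' label (e.g. `"128Te"`) is taken from the file name.
#'
#' @param paths Character vector of CSV file paths.
#' @param pixel_size_um Pixel pitch to attach.
#' @return An [image_stack()].
#' @export
read_csv_grids <- function(paths, pixel_size_um = 1) {
  channels <- lapply(paths, function(p) {
    lab <- parse_channel_header(basename(p))
    if (is.null(lab)) {
      stop("cannot parse a channel label from file name: ", basename(p))
    }
    m <- as.matrix(data.table::fread(p, header = FALSE, data.table = FALSE,
                                     showProgress = FALSE))
    dimnames(m) <- NULL
    channel_image(m, lab$element, lab$mass, pixel_size_um)
  })
  image_stack(channels, provenance = list(source = paste(paths, collapse = ";")))
}

#' Write an image stack as per-channel CSV grids
#'
#' @param stack An [image_stack()].
#' @param dir Output directory (created if needed); one `<label>.csv` per
#'   channel.
#' @return Invisibly, the paths written.
#' @export
write_csv_grids <- function(stack, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(stack$channels, function(ch) {
    p <- file.path(dir, paste0(ch_label(ch), ".csv"))
    m <- ch_pixels(ch)
    lines <- apply(m, 1, function(r) paste(fmt_num(r), collapse = ","))
    writeLines(lines, p)
    p
  }, character(1))
  invisible(paths)
}

# ---- TIFF stacks -----------------------------------------------------------

#' Read a multi-page TIFF into an image stack
#'
#' Per-page channel labels are taken from each page's ImageDescription tag, or
#' supplied positionally via `channel_labels`.
#'
#' @param path Path to a multi-page TIFF.
#' @param channel_labels Optional character vector of labels (e.g.
#'   `"128Te"`), one per page, overriding page metadata.
#' @param pixel_size_um Pixel pitch to attach.
#' @return An [image_stack()].
#' @export
read_tiff_stack <- function(path, channel_labels = NULL, pixel_size_um = 1) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.null(channel_labels) && length(channel_labels) != length(pages)) {
    stop(sprintf("page count (%d) does not match label count (%d)",
                 length(pages), length(channel_labels)))
  }
  channels <- lapply(seq_along(pages), function(i) {
    lab <- if (!is.null(channel_labels)) channel_labels[i]
           else attr(pages[[i]], "description")
    if (is.null(lab) || is.na(lab) || !nzchar(lab)) {
      stop(sprintf("TIFF page %d has no label and no override was given", i))
    }
    p <- parse_channel_header(lab)
    if (is.null(p)) stop("cannot parse channel label: ", lab)
    m <- pages[[i]]
    if (length(dim(m)) == 3L) m <- m[, , 1]  # tolerate grey-stored-as-RGB
    m <- matrix(as.numeric(m), nrow(m), ncol(m))
    channel_image(m, p$element, p$mass, pixel_size_um)
  })
  image_stack(channels, provenance = list(source = path))
}

#' Write an image stack as a 32-bit float multi-page TIFF
#'
#' One page per channel, labelled `"<mass><element>"` in the page's
#' ImageDescription.  Samples are IEEE float32, so a write/read round trip is
#' bit-exact for any value representable in single precision (all raw counts
#' are).
#'
#' @param stack A non-empty [image_stack()].
#' @param path Output path.
#' @export
write_tiff_stack <- function(stack, path) {
  if (!inherits(stack, "image_stack") || length(stack$channels) == 0L) {
    stop("stack must be a non-empty image_stack")
  }
  mats <- lapply(stack$channels, ch_pixels)
  labels <- vapply(stack$channels, ch_label, character(1))
  write_float_tiff(mats, labels, path)
  invisible(NULL)
}

# Minimal little-endian uncompressed float32 multi-page TIFF writer.
# Tags per IFD: width, length, bits/sample=32, compression=1, photometric=1,
# description, strip offset, samples/pixel=1, rows/strip, strip bytes,
# sample format=3 (IEEE float).
write_float_tiff <- function(mats, labels, path) {
  stopifnot(length(mats) == length(labels), length(mats) >= 1L)
  n <- length(mats)
  hs <- vapply(mats, nrow, integer(1))
  ws <- vapply(mats, ncol, integer(1))
  data_size <- hs * ws * 4L
  # tag count includes the single NUL terminator; values of <= 4 bytes are
  # stored inline in the tag, longer ones out-of-line padded to even offsets
  desc_count <- nchar(labels, type = "bytes") + 1L
  desc_inline <- desc_count <= 4L
  desc_bytes <- lapply(seq_along(labels), function(i) {
    b <- c(charToRaw(labels[i]), as.raw(0L))
    pad <- if (desc_inline[i]) 4L - length(b) else length(b) %% 2L
    c(b, rep(as.raw(0L), pad))
  })
  desc_size <- ifelse(desc_inline, 0L,
                      vapply(desc_bytes, length, integer(1)))
  ifd_size <- 2L + 11L * 12L + 4L

  data_off <- 8L + c(0L, cumsum(data_size))[seq_len(n)]
  desc_off <- 8L + sum(data_size) + c(0L, cumsum(desc_size))[seq_len(n)]
  ifd_off <- 8L + sum(data_size) + sum(desc_size) +
    (seq_len(n) - 1L) * ifd_size

  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  w4 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")

  writeBin(charToRaw("II"), con)
  w2(42L)
  w4(ifd_off[1])
  for (i in seq_len(n)) {
    writeBin(as.numeric(t(mats[[i]])), con, size = 4, endian = "little")
  }
  for (i in seq_len(n)) if (!desc_inline[i]) writeBin(desc_bytes[[i]], con)
  entry_long <- function(tag, value) { w2(tag); w2(4L); w4(1L); w4(value) }
  entry_short <- function(tag, value) { w2(tag); w2(3L); w4(1L); w2(value); w2(0L) }
  for (i in seq_len(n)) {
    w2(11L)
    entry_long(256L, ws[i])                    # ImageWidth
    entry_long(257L, hs[i])                    # ImageLength
    entry_short(258L, 32L)                     # BitsPerSample
    entry_short(259L, 1L)                      # Compression: none
    entry_short(262L, 1L)                      # Photometric: black is zero
    w2(270L); w2(2L); w4(desc_count[i])                   # ImageDescription
    if (desc_inline[i]) writeBin(desc_bytes[[i]], con) else w4(desc_off[i])
    entry_long(273L, data_off[i])              # StripOffsets
    entry_short(277L, 1L)                      # SamplesPerPixel
    entry_long(278L, hs[i])                    # RowsPerStrip
    entry_long(279L, data_size[i])             # StripByteCounts
    entry_short(339L, 3L)                      # SampleFormat: IEEE float
    w4(if (i < n) ifd_off[i + 1L] else 0L)
  }
  invisible(NULL)
}

# ---- format dispatch (used by the CLI) -------------------------------------

# Guess a stack format from a path's extension.
stack_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tif = , tiff = "tiff",
         txt = , tsv = "tab",
         csv = "comma",
         stop("cannot infer stack format from extension: ", path))
}

#' Read or write an image stack, dispatching on file extension
#'
#' `.tif`/`.tiff` use the TIFF stack format; `.txt`/`.tsv` the tab-separated
#' pixel table; `.csv` the comma-separated pixel table.
#'
#' @param path File path.
#' @param stack An [image_stack()] (for writing).
#' @return `read_stack()` returns an [image_stack()].
#' @export
read_stack <- function(path) {
  fmt <- stack_format(path)
  if (fmt == "tiff") read_tiff_stack(path) else read_pixel_table(path, fmt)
}

#' @rdname read_stack
#' @export
write_stack <- function(stack, path) {
  fmt <- stack_format(path)
  if (fmt == "tiff") write_tiff_stack(stack, path)
  else write_pixel_table(stack, path, fmt)
}
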