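# Containers, layouts, readers/writers.
#
# Conventions: pixel grids are numeric matrices indexed [row, col]; pixel
# coordinates reported to users are 0-based with a pixel's center at integer
# coordinates. Intensities are 16-bit-range floats; TIFF writers quantize to
# 16-bit.

#' Single acquisition field
#'
#' Lightweight container for one field of view: a 2-D intensity grid (or a
#' `height x width x channels` array for multi-channel acquisitions), the
#' physical pixel size, and optional channel names.
#'
#' @param pixels numeric matrix or 3-D array of non-negative intensities.
#' @param pixel_size micrometres per pixel (> 0).
#' @param channel_names optional character vector, one per channel.
#' @return object of class `field_image`.
#' @export
field_image <- function(pixels, pixel_size = 1, channel_names = NULL) {
  stopifnot(is.numeric(pixels), length(dim(pixels)) %in% c(2, 3),
            pixel_size > 0)
  if (any(pixels < 0)) stop("intensities must be non-negative", call. = FALSE)
  if (!is.null(channel_names)) {
    nch <- if (length(dim(pixels)) == 3) dim(pixels)[3] else 1L
    stopifnot(length(channel_names) == nch)
  }
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 channel_names = channel_names),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat("<field_image>", d[1], "x", d[2],
      if (length(d) == 3) paste0("x", d[3], "ch") else "",
      " pixel_size:", x$pixel_size, "um/px\n")
  invisible(x)
}

# n-th channel as a plain matrix
channel <- function(field, i = 1) {
  p <- field$pixels
  if (length(dim(p)) == 2) {
    if (i != 1) stop("single-channel image", call. = FALSE)
    p
  } else p[, , i]
}

n_channels <- function(field)
  if (length(dim(field$pixels)) == 3) dim(field$pixels)[3] else 1L

#' Ordered set of fields for one well
#'
#' @param fields list of [field_image()] objects, one per layout position,
#'   in layout order.
#' @param layout the [field_layout()] the fields were acquired under.
#' @return object of class `well_scan`.
#' @export
well_scan <- function(fields, layout) {
  stopifnot(is.list(fields), inherits(layout, "field_layout"),
            length(fields) == nrow(layout$field_positions))
  structure(list(fields = fields, layout = layout), class = "well_scan")
}

#' Acquisition layout of imaging fields within a well
#'
#' Standard formats follow the acquisition scheme of confluency well scans:
#' 38 fields per well of a 6-well plate and 384 fields for a 1-well plate.
#' The 38 fields are laid out as a centered packing on a 7-row grid (rows
#' of 4, 6, 6, 6, 6, 6, 4 fields, fitting a round well); the 384 fields as
#' a 16 x 24 rectangle. Both are defaults only: explicit positions override
#' them, since the true instrument geometry is configurable.
#'
#' @param plate_format `"six_well"`, `"one_well"`, `"ninety_six_well"` or
#'   `"three_eighty_four_well"`.
#' @param field_positions optional integer matrix (n x 2, `(row, col)` grid
#'   coordinates); must be unique.
#' @return object of class `field_layout` with `plate_format`,
#'   `fields_per_well` and `field_positions`.
#' @examples
#' nrow(field_layout("six_well")$field_positions)  # 38
#' @export
field_layout <- function(plate_format = c("six_well", "one_well",
                                          "ninety_six_well",
                                          "three_eighty_four_well"),
                         field_positions = NULL) {
  plate_format <- match.arg(plate_format)
  if (is.null(field_positions)) {
    field_positions <- switch(plate_format,
      six_well = {
        counts <- c(4, 6, 6, 6, 6, 6, 4)
        do.call(rbind, lapply(seq_along(counts), function(r) {
          k <- counts[r]
          off <- (6 - k) / 2
          cbind(r, seq_len(k) + off)
        }))
      },
      one_well = as.matrix(expand.grid(row = 1:16, col = 1:24)),
      ninety_six_well = matrix(c(1, 1), 1, 2),
      three_eighty_four_well = matrix(c(1, 1), 1, 2))
  }
  field_positions <- as.matrix(field_positions)
  stopifnot(ncol(field_positions) == 2)
  if (anyDuplicated(field_positions))
    stop("duplicate field positions in layout", call. = FALSE)
  colnames(field_positions) <- c("row", "col")
  rownames(field_positions) <- NULL
  structure(list(plate_format = plate_format,
                 fields_per_well = nrow(field_positions),
                 field_positions = field_positions),
            class = "field_layout")
}

#' @export
print.field_layout <- function(x, ...) {
  cat("<field_layout>", x$plate_format, "-", x$fields_per_well, "fields\n")
  invisible(x)
}

#' Load an acquisition layout from a configuration file or list
#'
#' The configuration (YAML or JSON file, or an R list) declares either a
#' `plate_format` (defaulting to the standard 38/384 field grids) or
#' explicit `field_positions`, which are echoed back after validation.
#'
#' @param config path to a `.yaml`/`.yml`/`.json` file, or a named list.
#' @return a [field_layout()].
#' @export
load_layout <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  pos <- config$field_positions
  if (!is.null(pos)) {
    pos <- as.matrix(as.data.frame(pos))
    storage.mode(pos) <- "double"
  }
  if (is.null(config$plate_format) && is.null(pos))
    stop("config must declare plate_format or field_positions", call. = FALSE)
  field_layout(plate_format = config$plate_format %||% "six_well",
               field_positions = pos)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a TIFF image
#'
#' Reads 8- or 16-bit single- or multi-page (1-4 channels) TIFF files
#' losslessly into a [field_image()]; integer sample values are preserved
#' exactly as floats.
#'
#' @param path file path.
#' @param pixel_size micrometres per pixel (TIFFs written by this package
#'   carry no physical calibration; supply it from your acquisition
#'   configuration).
#' @param channel_names optional channel names.
#' @return a [field_image()].
#' @export
read_image <- function(path, pixel_size = 1, channel_names = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      stop("not a readable TIFF: ", path, " (", conditionMessage(e), ")",
                           call. = FALSE))
  if (length(pages) < 1 || length(pages) > 4)
    stop("unsupported channel count in ", path, call. = FALSE)
  mats <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]   # collapse grayscale-as-RGB
    matrix(as.numeric(p), nrow(p), ncol(p))
  })
  px <- if (length(mats) == 1) mats[[1]]
        else array(unlist(mats), dim = c(nrow(mats[[1]]), ncol(mats[[1]]),
                                         length(mats)))
  field_image(px, pixel_size = pixel_size, channel_names = channel_names)
}

#' Write a field image as a 16-bit TIFF (one page per channel)
#'
#' Intensities are quantized by rounding to integers in the 16-bit range;
#' images generated by this package use integer-valued intensities well
#' inside the range, so write/read round-trips are bit-identical.
#'
#' @param field a [field_image()] (or plain matrix).
#' @param path destination path.
#' @param truth optional [scene_truth()]; when given, a sidecar JSON file
#'   `<path>.truth.json` is written next to the image (the ground-truth
#'   mask is stored as run-length-free row/col indices only if small).
#' @return `invisible(path)`.
#' @export
write_image <- function(field, path, truth = NULL) {
  if (is.matrix(field)) field <- field_image(field)
  ch <- lapply(seq_len(n_channels(field)), function(i) {
    m <- round(channel(field, i))
    m[m < 0] <- 0
    m[m > 65535] <- 65535
    m / 65535
  })
  ok <- tryCatch({tiff::writeTIFF(ch, path, bits.per.sample = 16); TRUE},
                 error = function(e) FALSE)
  if (!ok) stop("cannot write TIFF: ", path, call. = FALSE)
  if (!is.null(truth)) {
    tr <- truth[setdiff(names(truth), "mask")]
    jsonlite::write_json(tr, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Write tabular results as CSV or JSON
#'
#' Column order is stable (as given); floats are serialized with 6
#' significant digits; CSV output is RFC 4180 (quoted strings, CRLF-free
#' LF line endings as produced by [utils::write.csv()]).
#'
#' @param records data.frame (or list of homogeneous named lists).
#' @param path destination path.
#' @param format `"csv"` or `"json"`.
#' @return `invisible(path)`.
#' @export
write_results <- function(records, path, format = c("csv", "json")) {
  format <- match.arg(format)
  df <- if (is.data.frame(records)) records
        else do.call(rbind, lapply(records, function(r) as.data.frame(r)))
  if (is.null(df)) df <- data.frame()
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  ok <- tryCatch({
    if (format == "csv") utils::write.csv(df, path, row.names = FALSE)
    else jsonlite::write_json(df, path, dataframe = "rows", digits = NA)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write results to ", path, call. = FALSE)
  invisible(path)
}

# minimal stage logging; silenced unless options(platequant.verbose = TRUE)
pq_log <- function(stage, ...) {
  if (isTRUE(getOption("platequant.verbose", FALSE)))
    message("[", stage, "] ", ...)
  invisible(NULL)
}
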