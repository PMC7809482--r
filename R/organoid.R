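# Brightfield organoid morphometrics: area, Feret's diameter, batch CVs.

#' Segment the organoid in a brightfield well image
#'
#' One dark compact object per well is assumed. Intensities are inverted,
#' thresholded globally by Otsu's method, the largest 8-connected
#' component is kept and its holes filled. The measurement is flagged
#' `"no_organoid"` (no error) when no component reaches `min_px` pixels
#' or when the candidate is not genuinely dark — its mean intensity must
#' be below `max_rel_intensity` of the background mean. The contrast
#' requirement matters on blank wells: Otsu always splits something, and
#' on a pure-noise field the thresholded half of the pixels percolates
#' into one large component that would pass a size floor alone.
#'
#' @param field a [field_image()] or single-channel matrix.
#' @param min_px minimum believable organoid size in pixels.
#' @param max_rel_intensity maximum object/background mean-intensity
#'   ratio for a believable organoid (brightfield organoids image far
#'   darker than this).
#' @return logical mask (attribute `flag` set to `"no_organoid"` and an
#'   all-`FALSE` mask when nothing qualifies).
#' @export
segment_organoid <- function(field, min_px = 500, max_rel_intensity = 0.7) {
  x <- if (inherits(field, "field_image")) channel(field, 1) else field
  stopifnot(is.matrix(x))
  inv <- max(x) - x
  rng <- range(inv)
  empty <- structure(matrix(FALSE, nrow(x), ncol(x)), flag = "no_organoid")
  if (diff(rng) == 0) return(empty)
  norm <- (inv - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  mask <- norm > thr
  lab <- label8(mask)
  if (max(lab) == 0) return(empty)
  sz <- tabulate(lab[lab > 0L])
  big <- which.max(sz)
  if (sz[big] < min_px) return(empty)
  keep <- lab == big
  filled <- EBImage::fillHull(EBImage::Image(matrix(as.numeric(keep),
                                                    nrow(keep), ncol(keep))))
  out <- matrix(as.numeric(EBImage::imageData(filled)) > 0.5,
                nrow(keep), ncol(keep))
  if (all(out) ||
      mean(x[out]) >= max_rel_intensity * mean(x[!out]))
    return(empty)
  structure(out, flag = character(0))
}

#' Maximum caliper (Feret's) diameter of a binary mask
#'
#' Distance between the two most distant foreground pixel centers,
#' computed via the convex hull (the diameter is attained at hull
#' vertices, over which all antipodal pairs are examined); equals the
#' brute-force maximum over all pixel pairs. A mask with a single pixel
#' has diameter 0 (center-to-center convention); `convention = "edge"`
#' instead measures between pixel corners (the caliper around the pixel
#' squares), which is larger by about one pixel.
#'
#' @param mask logical matrix.
#' @param pixel_size micrometres per pixel.
#' @param convention `"center"` (default) or `"edge"`.
#' @return Feret's diameter in micrometres.
#' @export
feret_diameter <- function(mask, pixel_size = 1,
                           convention = c("center", "edge")) {
  convention <- match.arg(convention)
  pts <- which(mask != 0, arr.ind = TRUE)
  if (nrow(pts) == 0) return(NA_real_)
  if (convention == "edge") {
    pts <- rbind(cbind(pts[, 1] - 0.5, pts[, 2] - 0.5),
                 cbind(pts[, 1] - 0.5, pts[, 2] + 0.5),
                 cbind(pts[, 1] + 0.5, pts[, 2] - 0.5),
                 cbind(pts[, 1] + 0.5, pts[, 2] + 0.5))
  }
  if (nrow(pts) == 1) return(0)
  h <- grDevices::chull(pts[, 2], pts[, 1])
  hp <- pts[h, , drop = FALSE]
  if (nrow(hp) == 1) return(0)
  d2max <- 0
  for (i in seq_len(nrow(hp) - 1)) {
    d2 <- (hp[(i + 1):nrow(hp), 1] - hp[i, 1])^2 +
          (hp[(i + 1):nrow(hp), 2] - hp[i, 2])^2
    d2max <- max(d2max, max(d2))
  }
  sqrt(d2max) * pixel_size
}

#' Measure an organoid mask
#'
#' Area is the foreground pixel count times `pixel_size^2`; Feret's
#' diameter is the maximum pairwise distance between foreground pixel
#' centers (see [feret_diameter()]).
#'
#' @param mask logical matrix (nonempty).
#' @param pixel_size micrometres per pixel.
#' @param well_id,line_id optional identifiers carried into the record.
#' @return object of class `organoid_measurement` with `area` (um^2),
#'   `feret_diameter` (um), `n_px`, ids.
#' @export
measure_organoid <- function(mask, pixel_size, well_id = NA_character_,
                             line_id = NA_character_) {
  stopifnot(is.matrix(mask))
  n <- sum(mask != 0)
  if (n == 0) stop("empty mask", call. = FALSE)
  structure(list(area = n * pixel_size^2,
                 feret_diameter = feret_diameter(mask, pixel_size),
                 n_px = n, well_id = well_id, line_id = line_id,
                 pixel_size = pixel_size),
            class = "organoid_measurement")
}

#' @export
print.organoid_measurement <- function(x, ...) {
  cat(sprintf("<organoid_measurement> area %.4g um^2 | Feret %.4g um\n",
              x$area, x$feret_diameter))
  invisible(x)
}

#' Per-line batch statistics of organoid sizes
#'
#' Groups organoid measurements by cell line and reports, per line and
#' parameter (area, Feret's diameter), the mean and the coefficient of
#' variation (100 x sample sd / mean; requires n >= 2, otherwise flagged
#' `NA`). With `pool_batches = FALSE` statistics are reported per
#' line-and-batch; with the default `TRUE`, batches of the same line are
#' pooled into one group (the convention used when several independent
#' differentiations of a line are assessed together).
#'
#' @param measurements data.frame with columns `line_id`, `area`, `feret`
#'   and optionally `batch_id`.
#' @param pool_batches pool batches of the same line?
#' @return data.frame with one row per group: `line_id` (and `batch_id`
#'   if unpooled), `n`, `mean_area`, `cv_area`, `mean_feret`, `cv_feret`.
#' @examples
#' df <- data.frame(line_id = "a", area = c(90, 100, 110),
#'                  feret = c(9, 10, 11))
#' batch_stats(df)  # cv_area = 10
#' @export
batch_stats <- function(measurements, pool_batches = TRUE) {
  stopifnot(is.data.frame(measurements),
            all(c("line_id", "area", "feret") %in% names(measurements)))
  keys <- if (!pool_batches && "batch_id" %in% names(measurements))
    interaction(measurements$line_id, measurements$batch_id, drop = TRUE)
  else factor(measurements$line_id)
  cv <- function(x) if (length(x) < 2) NA_real_ else 100 * stats::sd(x) / mean(x)
  rows <- lapply(levels(keys), function(k) {
    sub <- measurements[keys == k, , drop = FALSE]
    data.frame(group = k, line_id = sub$line_id[1], n = nrow(sub),
               mean_area = mean(sub$area), cv_area = cv(sub$area),
               mean_feret = mean(sub$feret), cv_feret = cv(sub$feret))
  })
  do.call(rbind, rows)
}
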