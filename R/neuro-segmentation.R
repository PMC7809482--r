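# Nuclei -> single-cell ROI -> neurite mask -> TH+ calling pipeline.
#
# The chain: nuclei are segmented by a difference of Gaussians
# ((10, 2) minus (60, 20), mirror padding) thresholded at > 50; touching
# nuclei are split along the watershed ridges of the negated Euclidean
# distance transform after h-minima suppression of depth 1; single-cell
# ROIs are the ridge-separated components of the nuclei mask dilated by an
# exact Euclidean disk of radius 10; marker (TH / Tuj1) masks combine two
# band-pass thresholds (fine (11,1)-(11,3), large (99,3)-(99,11)) with a
# global threshold on the 3x3 median-filtered channel; a cell is a neuron
# when its ROI overlaps the combined neuronal mask, and TH-positive when
# the ROI mean of the background-subtracted TH channel exceeds 20
# (background = mean TH intensity outside nuclei). All comparisons are
# strict (">").

#' Pipeline thresholds and structural parameters
#'
#' All defaults are the pipeline's standard operating point; every
#' comparison in the chain is strict (greater-than).
#'
#' @param nuc_dog nuclei difference-of-Gaussians threshold (intensity).
#' @param th_fine,th_big,tuj1_fine,tuj1_big local band-pass thresholds for
#'   the TH and Tuj1 channels.
#' @param th_median_global,tuj1_median_global global thresholds applied to
#'   the 3x3 median-filtered channels.
#' @param th_positive threshold on the ROI statistic of the
#'   background-subtracted TH channel.
#' @param hmin_depth h-minima suppression depth on the negated distance
#'   transform (distance units).
#' @param roi_dilation_radius Euclidean disk radius (px) dilating the
#'   nuclei mask into single-cell ROIs.
#' @return list of class `pipeline_thresholds`.
#' @export
pipeline_thresholds <- function(nuc_dog = 50, th_fine = 3, th_big = 10,
                                tuj1_fine = 2, tuj1_big = 3,
                                th_median_global = 50,
                                tuj1_median_global = 20,
                                th_positive = 20, hmin_depth = 1,
                                roi_dilation_radius = 10) {
  structure(list(nuc_dog = nuc_dog, th_fine = th_fine, th_big = th_big,
                 tuj1_fine = tuj1_fine, tuj1_big = tuj1_big,
                 th_median_global = th_median_global,
                 tuj1_median_global = tuj1_median_global,
                 th_positive = th_positive, hmin_depth = hmin_depth,
                 roi_dilation_radius = roi_dilation_radius),
            class = "pipeline_thresholds")
}

# kernel (size, sigma) pairs of the chain
NUC_FINE <- c(10, 2); NUC_COARSE <- c(60, 20)
MARKER_FINE <- list(c(11, 1), c(11, 3))
MARKER_BIG <- list(c(99, 3), c(99, 11))

#' Segment nuclei and split touching ones
#'
#' The nuclei mask is `dog_filter(channel, (10, 2), (60, 20)) > nuc_dog`.
#' The splitting stencil is the watershed (8-connectivity) of the negated
#' Euclidean distance transform of the mask after h-minima suppression of
#' depth `hmin_depth` (realized by grayscale reconstruction; negation of
#' the distance map is used directly since watershed and h-minima are
#' invariant to the affine complement re-expression). Applying the
#' stencil means labeling by watershed basin membership: nuclei labels
#' are the basins restricted to the mask with ridge pixels removed
#' (ridge curves that run diagonally do not 4-disconnect the plane, so
#' re-running connected components after ridge removal would let labels
#' leak across them; basin membership is the leak-free reading).
#' Basins are renumbered by ascending minimum column-major pixel index
#' of their nucleus pixels.
#'
#' @param nuc_channel single-channel matrix (nuclei stain).
#' @param thresholds a [pipeline_thresholds()].
#' @return list with `nuc_mask` (logical), `nuc_labels` (integer),
#'   `ridge` (logical watershed ridge stencil), `basins` (full watershed
#'   label map), `basin_map` (basin id -> nucleus label), `n_nuclei`.
#' @export
segment_nuclei <- function(nuc_channel, thresholds = pipeline_thresholds()) {
  stopifnot(is.matrix(nuc_channel))
  d <- dog_filter(nuc_channel, NUC_FINE, NUC_COARSE)
  nuc_mask <- d > thresholds$nuc_dog
  if (!any(nuc_mask)) {
    z <- matrix(0L, nrow(nuc_mask), ncol(nuc_mask))
    return(list(nuc_mask = nuc_mask, nuc_labels = z,
                ridge = matrix(FALSE, nrow(nuc_mask), ncol(nuc_mask)),
                basins = z, basin_map = integer(0), n_nuclei = 0L))
  }
  dt <- distance_transform(nuc_mask)
  rec <- reconstruct_dilate(dt - thresholds$hmin_depth, dt)
  ws <- watershed_dt(-rec)
  ridge <- ws == -1L
  sel <- nuc_mask & !ridge
  nuc_labels <- matrix(0L, nrow(ws), ncol(ws))
  basin_map <- integer(max(ws))
  if (any(sel)) {
    pos <- which(sel)
    first <- tapply(pos, ws[pos], min)
    ids <- as.integer(names(first))[order(first)]
    basin_map[ids] <- seq_along(ids)
    nuc_labels[pos] <- basin_map[ws[pos]]
  }
  pq_log("neuro", "nuclei: ", max(nuc_labels))
  list(nuc_mask = nuc_mask, nuc_labels = nuc_labels, ridge = ridge,
       basins = ws, basin_map = basin_map, n_nuclei = max(nuc_labels))
}

#' Build single-cell regions of interest around nuclei
#'
#' Dilates the nuclei mask by an exact Euclidean disk, removes the
#' watershed ridge pixels of the splitting stencil, and labels the
#' remaining pixels by the watershed basin they belong to, keeping only
#' basins that contain a nucleus (each ROI inherits its nucleus's label).
#' Pixels of basins containing no nucleus are discarded. A ROI containing
#' two nucleus labels is impossible by construction (one basin maps to
#' one nucleus) and raises an error if ever observed.
#'
#' @param seg output of [segment_nuclei()].
#' @param thresholds a [pipeline_thresholds()] (uses
#'   `roi_dilation_radius`).
#' @return integer matrix `roi_labels`; ROI labels match nucleus labels.
#' @export
build_cell_rois <- function(seg, thresholds = pipeline_thresholds()) {
  if (seg$n_nuclei == 0L)
    return(matrix(0L, nrow(seg$nuc_mask), ncol(seg$nuc_mask)))
  dil <- dilate_mask(seg$nuc_mask, disk_brush(thresholds$roi_dilation_radius))
  sel <- dil & !seg$ridge & seg$basins > 0L
  roi <- matrix(0L, nrow(dil), ncol(dil))
  roi[sel] <- seg$basin_map[seg$basins[sel]]
  nl <- seg$nuc_labels
  chk <- roi > 0L & nl > 0L
  if (any(nl[chk] != roi[chk]))
    stop("ROI contains more than one nucleus label; splitting stencil violated",
         call. = FALSE)
  roi
}

#' Marker (TH / Tuj1) mask segmentation
#'
#' `mask = (DoG_fine > local_fine_thr) | (DoG_big > local_big_thr) |
#' (median3x3(channel) > global_thr)`, where the fine band-pass is
#' (11, 1) - (11, 3), the large band-pass (99, 3) - (99, 11), and the 3x3
#' median filter uses zero padding.
#'
#' @param ch single-channel matrix.
#' @param local_fine_thr,local_big_thr,global_thr strict thresholds; use
#'   (3, 10, 50) for TH and (2, 3, 20) for Tuj1 (see
#'   [pipeline_thresholds()]).
#' @return logical mask.
#' @export
segment_marker_mask <- function(ch, local_fine_thr, local_big_thr,
                                global_thr) {
  stopifnot(is.matrix(ch))
  fine <- dog_filter(ch, MARKER_FINE[[1]], MARKER_FINE[[2]])
  big <- dog_filter(ch, MARKER_BIG[[1]], MARKER_BIG[[2]])
  (fine > local_fine_thr) | (big > local_big_thr) | (median3(ch) > global_thr)
}

#' Classify cells as neurons and call TH-positive cells
#'
#' The neuronal mask is the pixel-wise OR of the TH and Tuj1 masks. A cell
#' is a neuron when its ROI overlaps the neuronal mask in at least one
#' pixel (a minimum overlap fraction may be required instead). The TH
#' background is the mean TH intensity outside nuclei and is subtracted
#' from the raw TH channel; a neuron is TH-positive when the ROI statistic
#' (mean by default) of the background-subtracted TH channel strictly
#' exceeds `thresholds$th_positive`.
#'
#' @param roi_labels integer ROI label matrix (labels = nucleus labels).
#' @param nuc_mask logical nuclei mask.
#' @param th_channel raw TH channel matrix.
#' @param tuj1_mask,th_mask marker masks from [segment_marker_mask()].
#' @param thresholds a [pipeline_thresholds()].
#' @param min_overlap minimum ROI/neuronal-mask overlap fraction required
#'   to call a neuron; the default 0 keeps any overlapping ROI.
#' @param statistic per-ROI statistic compared against the TH threshold:
#'   `"mean"` (default), `"median"` or `"max"`.
#' @param n_nuclei optional true nucleus count (defaults to the number of
#'   distinct ROI labels).
#' @return object of class `segmentation_result`: masks, per-cell table
#'   (`cells`), counts and summary fractions.
#' @export
classify_cells <- function(roi_labels, nuc_mask, th_channel, tuj1_mask,
                           th_mask, thresholds = pipeline_thresholds(),
                           min_overlap = 0,
                           statistic = c("mean", "median", "max"),
                           n_nuclei = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(identical(dim(roi_labels), dim(nuc_mask)),
            identical(dim(roi_labels), dim(th_channel)),
            identical(dim(roi_labels), dim(tuj1_mask)),
            identical(dim(roi_labels), dim(th_mask)))
  neuro_mask <- th_mask | tuj1_mask
  ids <- sort(unique(roi_labels[roi_labels > 0L]))
  if (is.null(n_nuclei)) n_nuclei <- length(ids)
  out <- !nuc_mask
  if (!any(out)) {
    warning("image entirely covered by nuclei; TH background set to 0")
    bg <- 0
  } else bg <- mean(th_channel[out])
  stat_fun <- switch(statistic, mean = mean, median = stats::median, max = max)
  cells <- lapply(ids, function(id) {
    sel <- roi_labels == id
    nsel <- sum(sel)
    ov <- sum(sel & neuro_mask)
    is_neuron <- if (min_overlap > 0) ov / nsel >= min_overlap else ov >= 1
    th_stat <- stat_fun(th_channel[sel] - bg)
    pts <- which(sel, arr.ind = TRUE)
    nucsel <- sel & nuc_mask
    data.frame(cell_id = id,
               centroid_x = mean(pts[, 2]) - 1,
               centroid_y = mean(pts[, 1]) - 1,
               nucleus_area_px = sum(nucsel),
               roi_area_px = nsel,
               is_neuron = is_neuron,
               th_mean_bgsub = th_stat,
               is_th_positive = is_neuron && th_stat > thresholds$th_positive)
  })
  cells <- if (length(cells)) do.call(rbind, cells)
           else data.frame(cell_id = integer(0), centroid_x = numeric(0),
                           centroid_y = numeric(0),
                           nucleus_area_px = integer(0),
                           roi_area_px = integer(0), is_neuron = logical(0),
                           th_mean_bgsub = numeric(0),
                           is_th_positive = logical(0))
  n_neurons <- sum(cells$is_neuron)
  n_th <- sum(cells$is_th_positive)
  structure(list(roi_labels = roi_labels, nuc_mask = nuc_mask,
                 th_mask = th_mask, tuj1_mask = tuj1_mask,
                 neuro_mask = neuro_mask, th_background = bg,
                 cells = cells,
                 n_nuclei = n_nuclei, n_neurons = n_neurons,
                 n_th_positive = n_th,
                 neuron_fraction = if (n_nuclei > 0) n_neurons / n_nuclei else NA_real_,
                 th_fraction_of_neurons = if (n_neurons > 0) n_th / n_neurons else NA_real_),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(paste0("<segmentation_result> %d nuclei | %d neurons",
                     " (%.1f%%) | %d TH+ (%s of neurons)\n"),
              x$n_nuclei, x$n_neurons,
              100 * (if (is.na(x$neuron_fraction)) 0 else x$neuron_fraction),
              x$n_th_positive,
              if (is.na(x$th_fraction_of_neurons)) "NA"
              else sprintf("%.1f%%", 100 * x$th_fraction_of_neurons)))
  invisible(x)
}

#' Run the full immunofluorescence pipeline on a three-channel scene
#'
#' Convenience wrapper: nuclei segmentation and splitting, ROI
#' construction, TH and Tuj1 marker masks, neuron classification and
#' TH-positive calling.
#'
#' @param field a [field_image()] with at least three channels, or a
#'   `height x width x 3` array.
#' @param channels named integer vector mapping `nuclei`, `tuj1`, `th` to
#'   channel indices.
#' @param thresholds a [pipeline_thresholds()].
#' @param ... passed to [classify_cells()].
#' @return a `segmentation_result` (with `nuc_labels` attached).
#' @examples
#' \donttest{
#' sc <- gen_neuro_scene(128, 128, n_cells = 8, seed = 1)
#' res <- segment_scene(sc$field)
#' res$n_nuclei
#' }
#' @export
segment_scene <- function(field,
                          channels = c(nuclei = 1, tuj1 = 2, th = 3),
                          thresholds = pipeline_thresholds(), ...) {
  px <- if (inherits(field, "field_image")) field$pixels else field
  stopifnot(length(dim(px)) == 3, dim(px)[3] >= max(channels))
  nuc <- px[, , channels[["nuclei"]]]
  tuj <- px[, , channels[["tuj1"]]]
  th <- px[, , channels[["th"]]]
  seg <- segment_nuclei(nuc, thresholds)
  roi <- build_cell_rois(seg, thresholds)
  th_mask <- segment_marker_mask(th, thresholds$th_fine, thresholds$th_big,
                                 thresholds$th_median_global)
  tuj1_mask <- segment_marker_mask(tuj, thresholds$tuj1_fine,
                                   thresholds$tuj1_big,
                                   thresholds$tuj1_median_global)
  res <- classify_cells(roi, seg$nuc_mask, th, tuj1_mask, th_mask,
                        thresholds, n_nuclei = seg$n_nuclei, ...)
  res$nuc_labels <- seg$nuc_labels
  res
}
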