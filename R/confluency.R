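# Label-free confluency estimation and well-level homogeneity QC.
#
# The coverage detector is an open surrogate for the proprietary
# "stain-free" detection of multimode plate readers: adherent cells are
# visible in transmitted light through local intensity texture, so
# foreground is declared where the local standard deviation exceeds an
# automatic, image-relative threshold. The well-level summaries follow the
# screening convention: the mean over all fields is the well confluency and
# the coefficient of variation of the per-field values scores seeding
# homogeneity.

#' Label-free per-field coverage estimation
#'
#' Computes the fraction of pixels covered by cells in a single
#' transmitted-light field. Foreground is the set of pixels whose local
#' standard deviation (`window x window` sample sd, mirror-padded) exceeds
#' `k_sd` times a robust scale estimate of the local-sd map (its median
#' absolute deviation times 1.4826), followed by a 3x3 morphological
#' closing and removal of connected components smaller than
#' `min_object_px`. The MAD term has a 50% breakdown point: on a field
#' about half covered by cells the local-sd map is evenly bimodal and the
#' MAD inflates to the distance between the background and texture modes,
#' so the threshold is additionally capped at half the 99th percentile of
#' the local-sd map, which keeps it strictly between the two modes at any
#' coverage. The rule is invariant to adding a constant to all
#' intensities and to positive rescaling. The automatic threshold assumes
#' an essentially texture-free background: appreciable background noise
#' raises the local-sd floor above the MAD-based cutoff.
#'
#' @param field a [field_image()] or single-channel matrix.
#' @param window odd local window edge in pixels (>= 3).
#' @param k_sd threshold multiplier (dimensionless).
#' @param min_object_px minimum surviving component area in pixels.
#' @return estimated coverage fraction in `[0, 1]`.
#' @examples
#' sc <- gen_adherent_field(128, 128, 0.3, seed = 1)
#' detect_coverage(sc$field)
#' @export
detect_coverage <- function(field, window = 15, k_sd = 3, min_object_px = 25) {
  x <- if (inherits(field, "field_image")) {
    if (n_channels(field) != 1)
      stop("detect_coverage expects a single-channel image", call. = FALSE)
    channel(field, 1)
  } else {
    if (length(dim(field)) != 2)
      stop("detect_coverage expects a single-channel image", call. = FALSE)
    field
  }
  stopifnot(window %% 2 == 1, window >= 3)
  ls <- local_sd(x, window)
  # MAD auto-threshold, capped below the cell-texture mode (the MAD alone
  # breaks down on evenly bimodal half-covered fields)
  thr <- min(k_sd * stats::mad(ls),
             0.5 * stats::quantile(ls, 0.99, names = FALSE))
  fg <- ls > thr
  if (any(fg)) {
    fg <- close_mask(fg, matrix(1, 3, 3))
    lab <- label8(fg)
    if (max(lab) > 0) {
      sz <- tabulate(lab[lab > 0L])
      keep <- which(sz >= min_object_px)
      fg <- matrix(lab %in% keep, nrow(lab), ncol(lab))
    }
  }
  pq_log("confluency", "coverage ", signif(mean(fg), 4))
  mean(fg)
}

#' Summarize per-field coverages into a well-level QC record
#'
#' @param per_field_coverage numeric vector of coverage fractions in
#'   layout order.
#' @return object of class `confluency_result` with `per_field_coverage`,
#'   `well_mean` (percent, `100 * mean`), `well_cv` (percent,
#'   `100 * sample sd / mean`; `NA` and flagged when the mean is zero) and
#'   `n_fields`.
#' @export
confluency_summary <- function(per_field_coverage) {
  stopifnot(is.numeric(per_field_coverage), length(per_field_coverage) >= 1)
  m <- mean(per_field_coverage)
  cv <- if (m == 0) NA_real_
        else 100 * stats::sd(per_field_coverage) / m
  structure(list(per_field_coverage = per_field_coverage,
                 well_mean = 100 * m,
                 well_cv = cv,
                 n_fields = length(per_field_coverage),
                 flags = if (m == 0) "cv_undefined_zero_mean" else character(0)),
            class = "confluency_result")
}

#' @export
print.confluency_result <- function(x, ...) {
  cat(sprintf("<confluency_result> %d fields | mean %.1f%% | CV %s\n",
              x$n_fields, x$well_mean,
              if (is.na(x$well_cv)) "undefined (zero mean)"
              else sprintf("%.1f%%", x$well_cv)))
  invisible(x)
}

#' Assess confluency and seeding homogeneity of a whole well
#'
#' Applies [detect_coverage()] to every field of a well scan in layout
#' order and summarizes the per-field coverages: the well mean (percent)
#' is the confluency readout and the coefficient of variation across
#' fields scores how evenly the cells were seeded.
#'
#' @param scan a [well_scan()] (all fields the same shape), or a plain
#'   list of single-channel matrices/[field_image()]s.
#' @param window,k_sd,min_object_px detector parameters, see
#'   [detect_coverage()].
#' @return a `confluency_result`, see [confluency_summary()].
#' @export
assess_well <- function(scan, window = 15, k_sd = 3, min_object_px = 25) {
  fields <- if (inherits(scan, "well_scan")) scan$fields else scan
  if (length(fields) == 0) stop("empty scan", call. = FALSE)
  dims <- unique(lapply(fields, function(f)
    dim(if (inherits(f, "field_image")) f$pixels else f)))
  if (length(dims) != 1) stop("all fields must share one shape", call. = FALSE)
  cov <- vapply(fields, detect_coverage, numeric(1),
                window = window, k_sd = k_sd, min_object_px = min_object_px)
  confluency_summary(cov)
}

#' Fit the saturating dilution-response curve
#'
#' Least-squares fit of `y = ymax * (1 - exp(-k * x))` to confluency reads
#' of a serial dilution, by bounded Levenberg-Marquardt
#' (`ymax` in `(0, 120]`, `k > 0`) with a fixed deterministic initializer
#' (`ymax0 = max(y)`; `k0` from the first point's implied rate). The model
#' is monotone and bounded; near-linear dilutions are captured by small
#' `k * x`. Goodness of fit is `r_squared = 1 - SS_res / SS_tot`, with
#' `SS_tot` about the mean; when all responses are equal `SS_tot = 0` and
#' `r_squared` is flagged undefined.
#'
#' @param seeded strictly increasing seeded amounts (>= 4).
#' @param confluency matching confluency reads in percent, in `[0, 100]`.
#' @return object of class `dilution_fit` with `ymax`, `k`, `r_squared`,
#'   `fitted`, `flags`.
#' @examples
#' d <- gen_dilution_series(c(1, 2, 4, 8, 16), noise_sd = 0)
#' fit_dilution_curve(d$seeded_amount, d$confluency_pct)$r_squared  # 1
#' @export
fit_dilution_curve <- function(seeded, confluency) {
  stopifnot(length(seeded) >= 4, length(confluency) == length(seeded),
            all(diff(seeded) > 0),
            all(confluency >= 0), all(confluency <= 100))
  ss_tot <- sum((confluency - mean(confluency))^2)
  if (ss_tot == 0) {
    return(structure(list(ymax = mean(confluency), k = NA_real_,
                          r_squared = NA_real_, fitted = confluency,
                          flags = "degenerate_constant_response"),
                     class = "dilution_fit"))
  }
  ymax0 <- max(confluency)
  ratio <- confluency[1] / (ymax0 * 1.05)
  k0 <- if (ratio > 0 && ratio < 1) -log(1 - ratio) / seeded[1] else 1 / seeded[1]
  df <- data.frame(x = seeded, y = confluency)
  fit <- minpack.lm::nlsLM(y ~ ymax * (1 - exp(-k * x)), data = df,
                           start = list(ymax = ymax0, k = k0),
                           lower = c(ymax = 1e-6, k = 1e-9),
                           upper = c(ymax = 120, k = Inf),
                           control = minpack.lm::nls.lm.control(
                             maxiter = 200, ftol = 1e-12, ptol = 1e-12))
  co <- stats::coef(fit)
  yhat <- co[["ymax"]] * (1 - exp(-co[["k"]] * seeded))
  r2 <- 1 - sum((confluency - yhat)^2) / ss_tot
  structure(list(ymax = co[["ymax"]], k = co[["k"]], r_squared = r2,
                 fitted = yhat, flags = character(0)),
            class = "dilution_fit")
}

#' @export
print.dilution_fit <- function(x, ...) {
  cat(sprintf("<dilution_fit> ymax %.4g | k %.4g | R^2 %s\n",
              x$ymax, x$k,
              if (is.na(x$r_squared)) "undefined" else sprintf("%.4f", x$r_squared)))
  invisible(x)
}
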