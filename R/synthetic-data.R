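# Synthetic scene generators with exact ground truth.
#
# Every generator is a pure function of (parameters, seed): identical calls
# give bit-identical images and truth records. Truth quantities (coverage
# fraction, organoid area/Feret) are stored exactly as recomputable from the
# emitted masks.

round_half_up <- function(x) floor(x + 0.5)

#' Ground-truth record for a synthetic scene
#'
#' Carries exact per-scene ground truth emitted alongside synthetic images:
#' achieved coverage, cell centers, neuron and TH-positive identities,
#' organoid geometry. Downstream tests compare pipeline output against these
#' fields.
#'
#' @param kind one of `"adherent_field"`, `"neuro_scene"`, `"organoid"`,
#'   `"dilution_series"`, `"well_scan"`.
#' @param seed integer RNG seed used to generate the scene.
#' @param ... further truth fields (e.g. `coverage_true`, `n_cells_true`,
#'   `th_positive_ids`, `organoid_area_true`, `mask`).
#' @return object of class `scene_truth`.
#' @export
scene_truth <- function(kind, seed, ...) {
  structure(c(list(kind = kind, seed = seed), list(...)),
            class = "scene_truth")
}

#' @export
print.scene_truth <- function(x, ...) {
  cat("<scene_truth>", x$kind, "seed", x$seed, "\n")
  for (f in setdiff(names(x), c("kind", "seed", "mask")))
    if (!is.null(x[[f]]) && length(x[[f]]) <= 12)
      cat(" ", f, ":", format(x[[f]]), "\n")
  invisible(x)
}

#' Simulate a transmitted-light field of adherent cells
#'
#' Emulates a label-free (stain-free) acquisition field: textured cell
#' patches on a flat background. Cells are visible through local intensity
#' variance only (zero-mean speckle, sd 60 over a constant background
#' level of 500), which is the contrast model the variance-based coverage
#' detector assumes. Elliptical patches are placed at random, then the
#' foreground is trimmed or grown pixel-by-pixel (patch rims first) until
#' it covers exactly `round(coverage * width * height)` pixels, so the
#' truth record carries the exactly achieved fraction.
#'
#' @param width,height field size in pixels (>= 32).
#' @param coverage target foreground fraction in `[0, 1]`.
#' @param clumpiness patch-size scale: characteristic patch radius is
#'   `clumpiness * min(width, height) / 4`. Large patches mimic confluent
#'   monolayer islands at low magnification.
#' @param seed integer RNG seed.
#' @param pixel_size micrometres per pixel.
#' @return list with `field` (a [field_image()]) and `truth`
#'   (a [scene_truth()] whose `mask` is the ground-truth foreground).
#' @examples
#' sc <- gen_adherent_field(128, 128, coverage = 0.4, seed = 7)
#' mean(sc$truth$mask)  # == sc$truth$coverage_true
#' @export
gen_adherent_field <- function(width, height, coverage, clumpiness = 1,
                               seed, pixel_size = 1) {
  if (coverage < 0 || coverage > 1) stop("coverage must be in [0, 1]", call. = FALSE)
  stopifnot(width >= 32, height >= 32)
  set.seed(seed)
  n <- width * height
  target <- round(coverage * n)
  mask <- matrix(FALSE, height, width)
  r0 <- clumpiness * min(width, height) / 4
  it <- 0L
  while (sum(mask) < target && it < 1000L) {
    it <- it + 1L
    cy <- stats::runif(1, 1, height); cx <- stats::runif(1, 1, width)
    a <- stats::runif(1, 0.7, 1.3) * r0; b <- stats::runif(1, 0.7, 1.3) * r0
    th <- stats::runif(1, 0, pi)
    dy <- outer(seq_len(height) - cy, rep(1, width))
    dx <- outer(rep(1, height), seq_len(width) - cx)
    u <- (dx * cos(th) + dy * sin(th)) / a
    v <- (-dx * sin(th) + dy * cos(th)) / b
    mask <- mask | (u * u + v * v <= 1)
  }
  fg <- sum(mask)
  if (fg > target) {
    d <- distance_transform(mask)
    idx <- which(mask)
    idx <- idx[order(d[idx], idx)]
    mask[idx[seq_len(fg - target)]] <- FALSE
  } else if (fg < target) {
    if (fg == 0) {
      # no seed patches (target tiny or zero): fill in scan order
      if (target > 0) mask[seq_len(target)] <- TRUE
    } else {
      d <- distance_transform(!mask)
      idx <- which(!mask)
      idx <- idx[order(d[idx], idx)]
      mask[idx[seq_len(target - fg)]] <- TRUE
    }
  }
  img <- matrix(500, height, width)
  nf <- sum(mask)
  if (nf > 0) img[mask] <- pmax(0, 500 + stats::rnorm(nf, 0, 60))
  truth <- scene_truth("adherent_field", seed,
                       coverage_true = sum(mask) / n, mask = mask,
                       gradient_strength = 0)
  list(field = field_image(img, pixel_size = pixel_size), truth = truth)
}

#' Simulate a full well scan with a controllable seeding gradient
#'
#' Generates one adherent-cell field per layout position. Per-field true
#' coverages follow a smooth linear ramp across the field grid (random
#' direction), with relative amplitude `gradient_strength` around
#' `mean_coverage`, clipped to `[0, 1]`; `gradient_strength = 0` gives a
#' perfectly homogeneous well (true CV = 0).
#'
#' @param layout a [field_layout()] with at least 2 positioned fields.
#' @param mean_coverage mean true coverage fraction.
#' @param gradient_strength dimensionless relative ramp amplitude (>= 0).
#' @param seed integer RNG seed.
#' @param field_width,field_height per-field image size in pixels.
#' @param clumpiness passed to [gen_adherent_field()].
#' @return list with `scan` (a [well_scan()]) and `truth` (per-field true
#'   coverages in layout order).
#' @export
gen_well_scan <- function(layout, mean_coverage, gradient_strength = 0, seed,
                          field_width = 256, field_height = 256,
                          clumpiness = 1) {
  stopifnot(inherits(layout, "field_layout"))
  pos <- layout$field_positions
  if (nrow(pos) < 2) stop("layout must have >= 2 fields", call. = FALSE)
  stopifnot(mean_coverage >= 0, mean_coverage <= 1, gradient_strength >= 0)
  set.seed(seed)
  theta <- stats::runif(1, 0, 2 * pi)
  subseeds <- sample.int(.Machine$integer.max - 1L, nrow(pos))
  ctr <- function(v) {
    rg <- range(v)
    if (diff(rg) == 0) return(rep(0, length(v)))
    (v - mean(rg)) / (diff(rg) / 2)
  }
  g <- cos(theta) * ctr(pos[, 2]) + sin(theta) * ctr(pos[, 1])
  if (max(abs(g)) > 0) g <- g / max(abs(g))
  cov_true <- pmin(1, pmax(0, mean_coverage * (1 + gradient_strength * g)))
  fields <- vector("list", nrow(pos))
  achieved <- numeric(nrow(pos))
  for (i in seq_len(nrow(pos))) {
    sc <- gen_adherent_field(field_width, field_height, cov_true[i],
                             clumpiness = clumpiness, seed = subseeds[i])
    fields[[i]] <- sc$field
    achieved[i] <- sc$truth$coverage_true
  }
  truth <- scene_truth("well_scan", seed,
                       per_field_coverage = achieved,
                       gradient_strength = gradient_strength)
  list(scan = well_scan(fields, layout), truth = truth)
}

# draw a curvilinear stroke (random walk) into img with ~2 px width,
# combining by per-pixel maximum; returns the updated matrix
draw_stroke <- function(img, y0, x0, n_steps, intensity) {
  h <- nrow(img); w <- ncol(img)
  ang <- stats::runif(1, 0, 2 * pi)
  y <- y0; x <- x0
  for (s in seq_len(n_steps)) {
    ang <- ang + stats::rnorm(1, 0, 0.25)
    y <- y + sin(ang); x <- x + cos(ang)
    ry <- round(y); rx <- round(x)
    for (o in list(c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      yy <- ry + o[1]; xx <- rx + o[2]
      if (yy >= 1 && yy <= h && xx >= 1 && xx <= w)
        img[yy, xx] <- max(img[yy, xx], intensity)
    }
  }
  img
}

# smooth-edged soma disk, max-combined
draw_soma <- function(img, y0, x0, radius, intensity) {
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(radius + 2)
  ys <- max(1, y0 - r):min(h, y0 + r)
  xs <- max(1, x0 - r):min(w, x0 + r)
  d2 <- outer((ys - y0)^2, (xs - x0)^2, "+")
  patch <- intensity * exp(-(d2 / radius^2)^2)
  img[ys, xs] <- pmax(img[ys, xs], patch)
  img
}

#' Simulate a three-channel immunofluorescence neuron scene
#'
#' Channel 1 holds nuclei (Gaussian blobs, sigma 4 px, peak amplitude
#' 160-220 over a background below 10), channel 2 a pan-neuronal stain
#' (somatic disks plus curvilinear neurite strokes through each neuron
#' position), channel 3 the dopaminergic (TH) stain drawn only at
#' TH-positive cells. Cell centers are sampled with a minimum spacing of
#' `min_spacing` pixels (default 13; nuclei closer than ~11 px merge
#' irresolvably under the segmentation chain's difference-of-Gaussians
#' threshold and h-minima depth) and at least 12 px from the borders.
#' Neuron and TH-positive counts are realized exactly by nearest-integer
#' rounding (ties up) of the requested fractions.
#'
#' @param width,height scene size in pixels.
#' @param n_cells number of cells to place (>= 0).
#' @param neuron_fraction fraction of cells that are neurons, in `[0, 1]`.
#' @param th_fraction_of_neurons fraction of neurons that are TH-positive.
#' @param seed integer RNG seed.
#' @param min_spacing minimum center-to-center distance in pixels (>= 8).
#' @return list with `field` (a [field_image()] with a `height x width x 3`
#'   pixel array, channels `nuclei`, `tuj1`, `th`) and `truth` (centers as
#'   an `n x 2` matrix of (row, col), `neuron_ids`, `th_positive_ids`).
#' @export
gen_neuro_scene <- function(width, height, n_cells, neuron_fraction = 1,
                            th_fraction_of_neurons = 0.25, seed,
                            min_spacing = 13) {
  stopifnot(n_cells >= 0, neuron_fraction >= 0, neuron_fraction <= 1,
            th_fraction_of_neurons >= 0, th_fraction_of_neurons <= 1,
            min_spacing >= 8)
  border <- 12
  set.seed(seed)
  centers <- matrix(numeric(0), 0, 2)
  if (n_cells > 0) {
    if (width - 2 * border < 1 || height - 2 * border < 1)
      stop("field too small for the requested cells at minimum spacing",
           call. = FALSE)
    tries <- 0L; max_tries <- 400L * n_cells
    while (nrow(centers) < n_cells && tries < max_tries) {
      tries <- tries + 1L
      p <- c(stats::runif(1, border, height - border),
             stats::runif(1, border, width - border))
      if (nrow(centers) == 0 ||
          min((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2) >=
            min_spacing^2)
        centers <- rbind(centers, p)
    }
    if (nrow(centers) < n_cells)
      stop("requested n_cells infeasible for the field size at the minimum spacing",
           call. = FALSE)
  }
  n_neurons <- round_half_up(n_cells * neuron_fraction)
  neuron_ids <- if (n_neurons > 0) sort(sample.int(n_cells, n_neurons)) else integer(0)
  n_th <- round_half_up(n_neurons * th_fraction_of_neurons)
  th_ids <- if (n_th > 0) sort(sample(neuron_ids, n_th)) else integer(0)

  nuc <- matrix(stats::runif(width * height, 0, 8), height, width)
  tuj <- matrix(stats::runif(width * height, 0, 6), height, width)
  th <- matrix(stats::runif(width * height, 0, 6), height, width)
  for (i in seq_len(n_cells)) {
    cy <- centers[i, 1]; cx <- centers[i, 2]
    amp <- stats::runif(1, 160, 220)
    r <- 14
    ys <- max(1, round(cy) - r):min(height, round(cy) + r)
    xs <- max(1, round(cx) - r):min(width, round(cx) + r)
    d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
    nuc[ys, xs] <- nuc[ys, xs] + amp * exp(-d2 / (2 * 16))
    if (i %in% neuron_ids) {
      tuj <- draw_soma(tuj, round(cy), round(cx), 6, stats::runif(1, 60, 100))
      for (k in seq_len(2))
        tuj <- draw_stroke(tuj, cy, cx, round(stats::runif(1, 40, 70)),
                           stats::runif(1, 40, 80))
    }
    if (i %in% th_ids) {
      th <- draw_soma(th, round(cy), round(cx), 6, stats::runif(1, 140, 180))
      for (k in seq_len(2))
        th <- draw_stroke(th, cy, cx, round(stats::runif(1, 40, 70)),
                          stats::runif(1, 60, 90))
    }
  }
  px <- array(0, dim = c(height, width, 3))
  px[, , 1] <- nuc; px[, , 2] <- tuj; px[, , 3] <- th
  truth <- scene_truth("neuro_scene", seed,
                       n_cells_true = n_cells, centers = centers,
                       neuron_ids = neuron_ids, th_positive_ids = th_ids,
                       neuron_fraction = if (n_cells > 0) n_neurons / n_cells else NA_real_,
                       th_fraction_of_neurons = if (n_neurons > 0) n_th / n_neurons else NA_real_)
  list(field = field_image(px, channel_names = c("nuclei", "tuj1", "th")),
       truth = truth)
}

# brute-force maximum pairwise distance between boundary-pixel centers
feret_brute <- function(mask, pixel_size = 1) {
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) <= 1) return(0)
  inner <- shift_fill(mask, 1, 0, FALSE) & shift_fill(mask, -1, 0, FALSE) &
           shift_fill(mask, 0, 1, FALSE) & shift_fill(mask, 0, -1, FALSE)
  bnd <- which(mask & !inner, arr.ind = TRUE)
  if (nrow(bnd) <= 1) return(0)
  mx <- 0
  for (i in seq_len(nrow(bnd) - 1)) {
    d2 <- (bnd[(i + 1):nrow(bnd), 1] - bnd[i, 1])^2 +
          (bnd[(i + 1):nrow(bnd), 2] - bnd[i, 2])^2
    mx <- max(mx, max(d2))
  }
  sqrt(mx) * pixel_size
}

#' Simulate a brightfield organoid image
#'
#' One dark compact object (intensity ~28% of the background level) on a
#' bright background with mild shading and noise. The truth record stores
#' the exactly rasterized mask, its pixel count times `pixel_size^2` as
#' the true area, and the brute-force maximum pairwise distance between
#' boundary-pixel centers times `pixel_size` as the true Feret diameter
#' (center-to-center convention: a single-pixel object has Feret 0).
#'
#' @param shape `"disk"` (size_params = radius), `"ellipse"`
#'   (size_params = c(a, b) semi-axes), or `"blob"` (size_params = mean
#'   radius; a smooth random radial perturbation of ~12% is applied).
#' @param size_params shape size parameters in pixels.
#' @param pixel_size micrometres per pixel.
#' @param seed integer RNG seed.
#' @param width,height optional frame size; defaults to the object extent
#'   plus a 12 px margin. The object must fit with >= 5 px margin.
#' @return list with `field` (a [field_image()]) and `truth`.
#' @export
gen_organoid_image <- function(shape = c("disk", "ellipse", "blob"),
                               size_params, pixel_size = 1, seed,
                               width = NULL, height = NULL) {
  shape <- match.arg(shape)
  set.seed(seed)
  rmax <- switch(shape,
                 disk = size_params[1],
                 ellipse = max(size_params[1:2]),
                 blob = size_params[1] * 1.2)
  if (is.null(width)) width <- 2 * ceiling(rmax) + 25
  if (is.null(height)) height <- 2 * ceiling(rmax) + 25
  if (2 * rmax + 10 > min(width, height))
    stop("object does not fit inside the frame with a 5 px margin", call. = FALSE)
  cy <- floor((height + 1) / 2); cx <- floor((width + 1) / 2)
  dy <- outer(seq_len(height) - cy, rep(1, width))
  dx <- outer(rep(1, height), seq_len(width) - cx)
  mask <- switch(shape,
    disk = dy^2 + dx^2 <= size_params[1]^2,
    ellipse = (dx / size_params[1])^2 + (dy / size_params[2])^2 <= 1,
    blob = {
      nh <- sample(3:5, 1)
      ak <- stats::runif(nh, 0.02, 0.12) / seq_len(nh)
      ph <- stats::runif(nh, 0, 2 * pi)
      theta <- atan2(dy, dx)
      rr <- size_params[1] *
        (1 + Reduce(`+`, lapply(seq_len(nh),
                                function(k) ak[k] * cos(k * theta + ph[k]))))
      sqrt(dy^2 + dx^2) <= rr
    })
  area_true <- sum(mask) * pixel_size^2
  feret_true <- feret_brute(mask, pixel_size)
  shade <- 30 * (dx / width + dy / height)
  img <- 900 + shade + matrix(stats::rnorm(width * height, 0, 5), height, width)
  img[mask] <- 250 + stats::rnorm(sum(mask), 0, 8)
  img <- pmax(img, 0)
  truth <- scene_truth("organoid", seed, mask = mask,
                       organoid_area_true = area_true,
                       organoid_feret_true = feret_true)
  list(field = field_image(img, pixel_size = pixel_size), truth = truth)
}

#' Simulate a serial-dilution confluency series
#'
#' Confluency reads are drawn from the saturating monotone model
#' `y = ymax * (1 - exp(-k * x))` (the model fitted by
#' [fit_dilution_curve()]) plus Gaussian noise, clipped to `[0, 100]`.
#'
#' @param levels strictly increasing seeded amounts (>= 4 levels).
#' @param noise_sd Gaussian noise standard deviation in confluency points.
#' @param seed integer RNG seed.
#' @param ymax,k generating curve parameters (percent plateau; per-unit
#'   seeded rate).
#' @return data.frame with columns `seeded_amount`, `confluency_pct`.
#' @export
gen_dilution_series <- function(levels, noise_sd = 0, seed = 1,
                                ymax = 95, k = 0.3) {
  stopifnot(length(levels) >= 4, noise_sd >= 0)
  if (any(diff(levels) <= 0))
    stop("levels must be strictly increasing", call. = FALSE)
  set.seed(seed)
  y <- ymax * (1 - exp(-k * levels))
  if (noise_sd > 0) y <- y + stats::rnorm(length(levels), 0, noise_sd)
  data.frame(seeded_amount = levels,
             confluency_pct = pmin(100, pmax(0, y)))
}
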