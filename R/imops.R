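# ---- padding -----------------------------------------------------------

# MATLAB-style 'symmetric' mirror padding: the edge pixel is duplicated
# (... 2,1 | 1,2,3 ... | n, n-1 ...). pad_left/pad_right must not exceed
# the image extent along that axis.
pad_mirror <- function(x, pad_top, pad_bottom, pad_left, pad_right) {
  nr <- nrow(x); nc <- ncol(x)
  if (pad_top > nr || pad_bottom > nr || pad_left > nc || pad_right > nc)
    stop("image too small for the requested filter window", call. = FALSE)
  ri <- c(if (pad_top > 0) pad_top:1 else integer(0), seq_len(nr),
          if (pad_bottom > 0) nr:(nr - pad_bottom + 1) else integer(0))
  ci <- c(if (pad_left > 0) pad_left:1 else integer(0), seq_len(nc),
          if (pad_right > 0) nc:(nc - pad_right + 1) else integer(0))
  x[ri, ci, drop = FALSE]
}

pad_const <- function(x, pt, pb, pl, pr, value = 0) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(value, nr + pt + pb, nc + pl + pr)
  out[pt + seq_len(nr), pl + seq_len(nc)] <- x
  out
}

# ---- Gaussian kernels and correlation ----------------------------------

#' Truncated, normalized Gaussian kernel
#'
#' Builds the 1-D profile of a truncated Gaussian on a `size`-tap window
#' with symmetric sample positions `(-(size-1)/2, ..., (size-1)/2)`,
#' normalized to sum to one. The 2-D kernel used throughout the pipeline
#' is the (normalized) outer product of this profile with itself; even
#' window sizes are supported and place the anchor pixel at index
#' `floor(size/2)` (0-based), i.e. half a pixel off the window centre.
#'
#' @param size window edge length in pixels (may be even).
#' @param sigma Gaussian standard deviation in pixels.
#' @return numeric vector of length `size` summing to 1.
#' @export
gauss_profile <- function(size, sigma) {
  stopifnot(size >= 1, sigma > 0)
  x <- seq_len(size) - 1 - (size - 1) / 2
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}

# Separable correlation with mirror padding; anchor at floor(size/2)
# (0-based) along both axes. `k` is the normalized 1-D profile.
correlate_sep <- function(x, k) {
  n <- length(k)
  a <- n %/% 2                # anchor index, 0-based
  pl <- a; pr <- n - 1 - a
  # rows axis
  p <- pad_mirror(x, a, n - 1 - a, 0, 0)
  nr <- nrow(x)
  out <- matrix(0, nr, ncol(x))
  for (j in seq_len(n)) out <- out + k[j] * p[j:(j + nr - 1), , drop = FALSE]
  # cols axis
  p <- pad_mirror(out, 0, 0, pl, pr)
  nc <- ncol(x)
  out2 <- matrix(0, nr, nc)
  for (j in seq_len(n)) out2 <- out2 + k[j] * p[, j:(j + nc - 1), drop = FALSE]
  out2
}

#' Gaussian filter with mirror boundary padding
#'
#' Correlates an image with the normalized truncated Gaussian described by
#' a `(size, sigma)` pair, using mirror ("symmetric") boundary padding.
#' Implemented separably; the 2-D kernel is the outer product of
#' [gauss_profile()] with itself.
#'
#' @param x numeric matrix.
#' @param size,sigma kernel window edge (px) and standard deviation (px).
#' @return filtered matrix, same dimensions as `x`.
#' @export
gauss_filter <- function(x, size, sigma) correlate_sep(x, gauss_profile(size, sigma))

#' Difference-of-Gaussians band-pass filter
#'
#' Returns `gauss_filter(x, fine) - gauss_filter(x, coarse)`. Both kernels
#' are normalized to unit sum, so constant images map to exactly zero and
#' the output may be negative. The fine sigma must be smaller than the
#' coarse sigma.
#'
#' @param x numeric matrix (single channel).
#' @param fine,coarse numeric length-2 vectors `c(size, sigma)` in pixels.
#' @return signed numeric matrix.
#' @examples
#' img <- matrix(0, 64, 64); img[32, 32] <- 1000
#' d <- dog_filter(img, c(10, 2), c(60, 20))
#' @export
dog_filter <- function(x, fine, coarse) {
  stopifnot(length(fine) == 2, length(coarse) == 2)
  if (fine[2] >= coarse[2])
    stop("fine sigma must be smaller than coarse sigma", call. = FALSE)
  gauss_filter(x, fine[1], fine[2]) - gauss_filter(x, coarse[1], coarse[2])
}

# ---- 3x3 median, zero padded -------------------------------------------

# median-of-9 exchange network (Paeth); ~19 pmin/pmax passes, exact.
#' 3x3 median filter with zero padding
#'
#' @param x numeric matrix.
#' @return matrix of running 3x3 medians; pixels outside the image count
#'   as zeros (the source environment's default padding).
#' @export
median3 <- function(x) {
  p <- pad_const(x, 1, 1, 1, 1, 0)
  nr <- nrow(x); nc <- ncol(x)
  v <- vector("list", 9)
  idx <- 1
  for (dc in 0:2) for (dr in 0:2) {
    v[[idx]] <- p[dr + seq_len(nr), dc + seq_len(nc), drop = FALSE]
    idx <- idx + 1
  }
  sw <- function(i, j) {
    lo <- pmin(v[[i]], v[[j]]); hi <- pmax(v[[i]], v[[j]])
    v[[i]] <<- lo; v[[j]] <<- hi
  }
  sw(2, 3); sw(5, 6); sw(8, 9)
  sw(1, 2); sw(4, 5); sw(7, 8)
  sw(2, 3); sw(5, 6); sw(8, 9)
  sw(1, 4); sw(6, 9); sw(5, 8)
  sw(4, 7); sw(2, 5); sw(3, 6)
  sw(5, 8); sw(5, 3); sw(7, 5); sw(5, 3)
  v[[5]]
}

# ---- local standard deviation ------------------------------------------

# Moving-window (win x win) sample standard deviation, mirror padded.
# The image median is subtracted first so that constant regions yield
# exactly zero variance (no catastrophic cancellation); the local sd is
# shift-invariant so the result is unchanged mathematically. Variances
# below 1e-9 x max are clamped to zero.
local_sd <- function(x, win) {
  stopifnot(win %% 2 == 1, win >= 3)
  a <- win %/% 2
  x0 <- x - stats::median(x)
  p <- pad_mirror(x0, a, a, a, a)
  s1 <- box_sum(p, win)
  s2 <- box_sum(p * p, win)
  n <- win * win
  v <- (s2 - s1 * s1 / n) / (n - 1)
  v[v < 0] <- 0
  mx <- max(v)
  if (mx > 0) v[v < 1e-9 * mx] <- 0
  sqrt(v)
}

# running win x win sums over a padded matrix; output has padded dims - win + 1
box_sum <- function(p, win) {
  cs <- apply(p, 2, cumsum)
  cs <- rbind(0, cs)
  rs <- cs[win + seq_len(nrow(p) - win + 1), , drop = FALSE] -
        cs[seq_len(nrow(p) - win + 1), , drop = FALSE]
  cs2 <- t(apply(rs, 1, cumsum))
  cs2 <- cbind(0, cs2)
  cs2[, win + seq_len(ncol(p) - win + 1), drop = FALSE] -
    cs2[, seq_len(ncol(p) - win + 1), drop = FALSE]
}

# ---- connected components, 8-connectivity ------------------------------

#' Label connected components (8-connectivity)
#'
#' EBImage's `bwlabel` uses 4-connectivity; this routine merges labels
#' that touch diagonally and renumbers components in order of their
#' minimum column-major linear index, giving a canonical, reproducible
#' labeling.
#'
#' @param mask logical (or 0/1) matrix.
#' @return integer matrix of component labels (0 = background).
#' @export
label8 <- function(mask) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  if (!any(m > 0)) return(matrix(0L, nrow(m), ncol(m)))
  l4 <- matrix(as.integer(EBImage::imageData(EBImage::bwlabel(m))),
               nrow(m), ncol(m))
  k <- max(l4)
  if (k > 1) {
    edges <- integer(0)
    for (sh in list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))) {
      nb <- shift_fill(l4, sh[1], sh[2], 0L)
      sel <- l4 > 0L & nb > 0L & l4 != nb
      if (any(sel)) edges <- c(edges, rbind(l4[sel], nb[sel]))
    }
    if (length(edges)) {
      g <- igraph::make_graph(as.numeric(edges), n = k, directed = FALSE)
      comp <- igraph::components(g)$membership
      pos <- l4 > 0L
      l4[pos] <- as.integer(comp[l4[pos]])
    }
  }
  relabel_by_min_index(l4)
}

# renumber labels 1..k by ascending minimum column-major linear index
relabel_by_min_index <- function(lab) {
  pos <- which(lab > 0L)
  if (!length(pos)) return(lab)
  first <- tapply(pos, lab[pos], min)
  ord <- order(first)
  map <- integer(max(lab))
  map[as.integer(names(first))[ord]] <- seq_along(ord)
  lab[pos] <- map[lab[pos]]
  lab
}

# result[i, j] = m[i + dr, j + dc], out-of-range -> fill
shift_fill <- function(m, dr, dc, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ri <- max(1L, 1L - dr):min(nr, nr - dr)
  ci <- max(1L, 1L - dc):min(nc, nc - dc)
  out[ri, ci] <- m[ri + dr, ci + dc]
  out
}

# ---- morphological reconstruction and h-minima --------------------------

#' Grayscale reconstruction by dilation
#'
#' Iterates `marker = min(dilate8(marker), mask)` to its (unique) fixed
#' point. Used to realize the h-minima transform on the negated distance
#' transform: suppressing minima shallower than depth `h` on `-d` equals
#' `-reconstruct_dilate(d - h, d)`.
#'
#' @param marker,mask numeric matrices, `marker <= mask` elementwise.
#' @return reconstructed matrix.
#' @export
reconstruct_dilate <- function(marker, mask) {
  stopifnot(all(marker <= mask + 1e-12))
  cur <- pmin(marker, mask)
  repeat {
    d <- cur
    for (sh in nbr8_shifts())
      d <- pmax(d, shift_fill(cur, sh[1], sh[2], -Inf))
    nxt <- pmin(d, mask)
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  cur
}

nbr8_shifts <- function() list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                               c(0, 1), c(1, -1), c(1, 0), c(1, 1))

#' Watershed transform by level-synchronous flooding
#'
#' Deterministic watershed of an altitude surface, 8-connectivity.
#' Levels (unique surface values) are processed in ascending order; at
#' each level, unlabeled pixels adjacent to exactly one basin adopt its
#' label and pixels adjacent to two or more distinct basins become ridge
#' pixels (label -1), with all updates applied synchronously per
#' iteration; level pixels reached by no basin seed new basins, numbered
#' by ascending minimum column-major linear index. This pinned
#' tie-breaking makes the transform reproducible bit-for-bit by an
#' independent implementation of the same definition.
#'
#' @param s numeric matrix (altitude surface; basins grow from minima).
#' @return integer matrix: positive basin labels, -1 on ridge lines.
#' @export
watershed_dt <- function(s) {
  nr <- nrow(s); nc <- ncol(s)
  L <- matrix(0L, nr, nc)
  nextlab <- 0L
  for (v in sort(unique(as.vector(s)))) {
    Tm <- (s == v) & (L == 0L)
    if (!any(Tm)) next
    repeat {
      mm <- nbr_label_range(L)
      cand <- Tm & (L == 0L) & !is.na(mm$lo)
      if (!any(cand)) break
      one <- cand & (mm$lo == mm$hi)
      rdg <- cand & (mm$lo != mm$hi)
      if (any(one)) L[one] <- mm$lo[one]
      if (any(rdg)) L[rdg] <- -1L
    }
    rest <- Tm & (L == 0L)
    if (any(rest)) {
      cc <- label8(rest)
      L[rest] <- cc[rest] + nextlab
      nextlab <- nextlab + max(cc)
    }
  }
  L
}

# min/max positive neighbor label per pixel (NA when none)
nbr_label_range <- function(L) {
  lo <- matrix(NA_integer_, nrow(L), ncol(L))
  hi <- lo
  for (sh in nbr8_shifts()) {
    nb <- shift_fill(L, sh[1], sh[2], 0L)
    nb[nb <= 0L] <- NA_integer_
    lo <- pmin(lo, nb, na.rm = TRUE)
    hi <- pmax(hi, nb, na.rm = TRUE)
  }
  list(lo = lo, hi = hi)
}

# ---- structuring elements ----------------------------------------------

#' Exact Euclidean disk structuring element
#'
#' The set \{(dx, dy) : dx^2 + dy^2 <= r^2\} on a (2r+1) x (2r+1) window.
#' Unlike decomposed "disc" brushes this is the exact rasterized disk,
#' reproducible across languages.
#'
#' @param r integer radius in pixels.
#' @return 0/1 numeric matrix of size `2r+1`.
#' @export
disk_brush <- function(r) {
  stopifnot(r >= 1)
  d <- outer((-r):r, (-r):r, function(a, b) a * a + b * b)
  (d <= r * r) * 1
}

# binary dilation with an arbitrary brush (EBImage)
dilate_mask <- function(mask, brush) {
  m <- EBImage::dilate(EBImage::Image(matrix(as.numeric(mask != 0),
                                             nrow(mask), ncol(mask))), brush)
  matrix(as.numeric(EBImage::imageData(m)) > 0.5, nrow(mask), ncol(mask))
}

close_mask <- function(mask, brush) {
  m <- EBImage::closing(EBImage::Image(matrix(as.numeric(mask != 0),
                                              nrow(mask), ncol(mask))), brush)
  matrix(as.numeric(EBImage::imageData(m)) > 0.5, nrow(mask), ncol(mask))
}

# Euclidean distance to nearest background pixel (0 on background)
distance_transform <- function(mask) {
  d <- EBImage::distmap(EBImage::Image(matrix(as.numeric(mask != 0),
                                              nrow(mask), ncol(mask))),
                        metric = "euclidean")
  matrix(as.numeric(EBImage::imageData(d)), nrow(mask), ncol(mask))
}
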