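# Independent straight-line re-implementations of the segmentation chain
# and brute-force statistical oracles. Deliberately shares no code with the
# package: kernels are built as explicit 2-D matrices, filtering loops over
# kernel taps on an explicitly mirror-indexed pad, labeling is queue-based
# flood fill, Feret is an all-pairs maximum, and the rank tests are
# enumerated. Used to pin down every pipeline stage bit-for-bit (binary and
# label images) or to 1e-8 (float images).

# explicit 2-D truncated Gaussian, normalized over the whole window
o_kernel2d <- function(size, sigma) {
  ax <- seq_len(size) - 1 - (size - 1) / 2
  K <- exp(-outer(ax^2, ax^2, "+") / (2 * sigma^2))
  K / sum(K)
}

# mirror ('symmetric') index sequence of length n padded by pl/pr
o_reflect_idx <- function(n, pl, pr)
  c(if (pl > 0) pl:1 else integer(0), 1:n,
    if (pr > 0) n:(n - pr + 1) else integer(0))

# correlation with an explicit 2-D kernel, anchor at floor(size/2) 0-based
o_imfilter <- function(img, K) {
  n <- nrow(K)
  a <- n %/% 2
  P <- img[o_reflect_idx(nrow(img), a, n - 1 - a),
           o_reflect_idx(ncol(img), a, n - 1 - a), drop = FALSE]
  out <- matrix(0, nrow(img), ncol(img))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (K[i, j] == 0) next
    out <- out + K[i, j] *
      P[i:(i + nrow(img) - 1), j:(j + ncol(img) - 1), drop = FALSE]
  }
  out
}

o_dog <- function(img, fine, coarse)
  o_imfilter(img, o_kernel2d(fine[1], fine[2])) -
  o_imfilter(img, o_kernel2d(coarse[1], coarse[2]))

# 3x3 median, zero padded, one median() call per pixel
o_median3 <- function(img) {
  P <- rbind(0, cbind(0, img, 0), 0)
  out <- img
  for (r in seq_len(nrow(img))) for (cc in seq_len(ncol(img)))
    out[r, cc] <- stats::median(P[r:(r + 2), cc:(cc + 2)])
  out
}

# brute-force Euclidean distance to the nearest background pixel
o_distmap <- function(mask) {
  out <- matrix(0, nrow(mask), ncol(mask))
  bg <- which(!mask, arr.ind = TRUE)
  if (nrow(bg) == 0) stop("o_distmap: mask has no background")
  fg <- which(mask, arr.ind = TRUE)
  for (i in seq_len(nrow(fg)))
    out[fg[i, 1], fg[i, 2]] <-
      sqrt(min((bg[, 1] - fg[i, 1])^2 + (bg[, 2] - fg[i, 2])^2))
  out
}

# 3x3 grayscale maximum with -Inf outside (rbind/cbind padding)
o_max3 <- function(m) {
  P <- rbind(-Inf, cbind(-Inf, m, -Inf), -Inf)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(-Inf, nr, nc)
  for (dr in 0:2) for (dc in 0:2)
    out <- pmax(out, P[dr + seq_len(nr), dc + seq_len(nc), drop = FALSE])
  out
}

# morphological reconstruction by dilation (unique fixed point)
o_reconstruct <- function(marker, mask) {
  cur <- pmin(marker, mask)
  repeat {
    nxt <- pmin(o_max3(cur), mask)
    if (identical(nxt, cur)) return(cur)
    cur <- nxt
  }
}

# queue-based 8-connected flood fill, components numbered by ascending
# minimum column-major linear index
o_label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (p in which(as.vector(mask))) {
    if (lab[p] != 0L) next
    nxt <- nxt + 1L
    queue <- p; lab[p] <- nxt
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      r0 <- ((q - 1) %% nr) + 1; c0 <- ((q - 1) %/% nr) + 1
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r0 + dr; cc <- c0 + dc
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        qq <- (cc - 1) * nr + rr
        if (mask[qq] && lab[qq] == 0L) { lab[qq] <- nxt; queue <- c(queue, qq) }
      }
    }
  }
  lab
}

# level-synchronous Meyer flooding per the pinned definition, written as
# frontier-queue loops
o_watershed <- function(s) {
  nr <- nrow(s); nc <- ncol(s)
  L <- matrix(0L, nr, nc)
  nextlab <- 0L
  nbrs <- function(p) {
    r0 <- ((p - 1) %% nr) + 1; c0 <- ((p - 1) %/% nr) + 1
    out <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r0 + dr; cc <- c0 + dc
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc)
        out <- c(out, (cc - 1) * nr + rr)
    }
    out
  }
  for (v in sort(unique(as.vector(s)))) {
    Tset <- which(as.vector(s) == v & as.vector(L) == 0L)
    if (!length(Tset)) next
    in_T <- logical(nr * nc); in_T[Tset] <- TRUE
    # initial candidates: T pixels already adjacent to a basin
    cand <- Tset[vapply(Tset, function(p) any(L[nbrs(p)] > 0L), logical(1))]
    while (length(cand)) {
      upd_p <- integer(0); upd_v <- integer(0)
      for (p in cand) {
        if (L[p] != 0L) next
        nl <- L[nbrs(p)]
        nl <- unique(nl[nl > 0L])
        if (length(nl) == 0) next
        upd_p <- c(upd_p, p)
        upd_v <- c(upd_v, if (length(nl) == 1) nl else -1L)
      }
      if (!length(upd_p)) break
      L[upd_p] <- upd_v                      # synchronous apply
      newly <- upd_p[upd_v > 0L]
      cand <- unique(unlist(lapply(newly, nbrs)))
      cand <- cand[in_T[cand] & L[cand] == 0L]
    }
    rest <- Tset[L[Tset] == 0L]
    if (length(rest)) {
      rmask <- matrix(FALSE, nr, nc); rmask[rest] <- TRUE
      cc <- o_label8(rmask)
      L[rest] <- cc[rest] + nextlab
      nextlab <- nextlab + max(cc)
    }
  }
  L
}

# naive binary dilation by the exact Euclidean disk: stamp a disk on
# every foreground pixel
o_dilate_disk <- function(mask, r) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  offs <- which(outer((-r):r, (-r):r, function(a, b) a^2 + b^2) <= r^2,
                arr.ind = TRUE) - r - 1
  for (p in which(mask, arr.ind = TRUE) |> asplit(1)) {
    rr <- p[1] + offs[, 1]; cc <- p[2] + offs[, 2]
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    out[cbind(rr[ok], cc[ok])] <- TRUE
  }
  out
}

# literal straight-line re-execution of the whole quoted chain
o_run_chain <- function(px, thr = platequant::pipeline_thresholds()) {
  nuc <- px[, , 1]; tuj <- px[, , 2]; th <- px[, , 3]
  dog_nuc <- o_dog(nuc, c(10, 2), c(60, 20))
  nuc_mask <- dog_nuc > thr$nuc_dog
  if (!any(nuc_mask)) {
    z <- matrix(0L, nrow(nuc), ncol(nuc))
    return(list(dog_nuc = dog_nuc, nuc_mask = nuc_mask, nuc_labels = z,
                roi_labels = z, n_nuclei = 0L))
  }
  dt <- o_distmap(nuc_mask)
  rec <- o_reconstruct(dt - thr$hmin_depth, dt)
  ws <- o_watershed(-rec)
  ridge <- ws == -1L
  sel <- nuc_mask & !ridge
  nuc_labels <- matrix(0L, nrow(nuc), ncol(nuc))
  ids <- unique(ws[sel][order(which(sel))])
  for (i in seq_along(ids)) nuc_labels[sel & ws == ids[i]] <- i
  dil <- o_dilate_disk(nuc_mask, thr$roi_dilation_radius)
  roi_labels <- matrix(0L, nrow(nuc), ncol(nuc))
  rsel <- dil & !ridge
  for (i in seq_along(ids)) roi_labels[rsel & ws == ids[i]] <- i
  th_mask <- (o_dog(th, c(11, 1), c(11, 3)) > thr$th_fine) |
             (o_dog(th, c(99, 3), c(99, 11)) > thr$th_big) |
             (o_median3(th) > thr$th_median_global)
  tuj_mask <- (o_dog(tuj, c(11, 1), c(11, 3)) > thr$tuj1_fine) |
              (o_dog(tuj, c(99, 3), c(99, 11)) > thr$tuj1_big) |
              (o_median3(tuj) > thr$tuj1_median_global)
  neuro <- th_mask | tuj_mask
  bg <- mean(th[!nuc_mask])
  ncell <- length(ids)
  is_neuron <- logical(ncell); is_th <- logical(ncell)
  for (i in seq_len(ncell)) {
    sel_i <- roi_labels == i
    is_neuron[i] <- sum(sel_i & neuro) >= 1
    is_th[i] <- is_neuron[i] && mean(th[sel_i] - bg) > thr$th_positive
  }
  list(dog_nuc = dog_nuc, nuc_mask = nuc_mask, dt = dt, rec = rec, ws = ws,
       nuc_labels = nuc_labels, dil = dil, roi_labels = roi_labels,
       th_mask = th_mask, tuj_mask = tuj_mask,
       n_nuclei = ncell, is_neuron = is_neuron, is_th_positive = is_th)
}

# all-pairs Feret over every foreground pixel center
o_feret_brute <- function(mask, pixel_size = 1) {
  pts <- which(mask != 0, arr.ind = TRUE)
  if (nrow(pts) <= 1) return(0)
  max(stats::dist(pts)) * pixel_size
}

# exhaustive Mann-Whitney enumeration: two-sided p = fraction of label
# assignments whose min-U is at most the observed min-U
o_mw_enum <- function(a, b) {
  na <- length(a); nb <- length(b)
  pool <- c(a, b)
  r <- rank(pool)
  ua_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  u_obs <- min(ua_obs, na * nb - ua_obs)
  combos <- utils::combn(na + nb, na)
  us <- apply(combos, 2, function(ix) {
    ua <- sum(r[ix]) - na * (na + 1) / 2
    min(ua, na * nb - ua)
  })
  list(U = u_obs, p = mean(us <= u_obs + 1e-9))
}

# Kruskal-Wallis H via the rank-sum formula with tie correction
o_kw_hand <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  Ri <- tapply(r, g, sum)
  ni <- tapply(r, g, length)
  H <- 12 / (N * (N + 1)) * sum(Ri^2 / ni) - 3 * (N + 1)
  tt <- table(x)
  C <- 1 - sum(tt^3 - tt) / (N^3 - N)
  H / C
}

o_cv_pct <- function(v) 100 * stats::sd(v) / mean(v)
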