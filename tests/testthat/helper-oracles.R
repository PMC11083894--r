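# Brute-force reference implementations, deliberately naive: plain R loops
# over full neighbourhoods, used to validate the compiled kernels.

reflect_idx <- function(i, n) {
  if (n == 1) return(rep(1L, length(i)))
  vapply(i, function(k) {
    while (k < 1 || k > n) {
      if (k < 1) k <- 1 - k + 1 - 1  # mirror about 0.5 boundary: -0 -> 1
      if (k < 1) k <- 2 - k
      if (k > n) k <- 2 * n - k + 1
    }
    k
  }, integer(1))
}

# simpler scalar reflection matching the C++ kernel (0-based mirror)
refl <- function(i, n) {
  if (n == 1) return(1L)
  i0 <- i - 1L
  while (i0 < 0 || i0 >= n) {
    if (i0 < 0) i0 <- -i0 - 1L
    if (i0 >= n) i0 <- 2L * n - i0 - 1L
  }
  i0 + 1L
}

oracle_median3d <- function(a, r) {
  d <- dim(a)
  out <- a
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    nb <- numeric(0)
    for (dz in -r[1]:r[1]) for (dy in -r[2]:r[2]) for (dx in -r[3]:r[3]) {
      nb <- c(nb, a[refl(z + dz, d[1]), refl(y + dy, d[2]), refl(x + dx, d[3])])
    }
    out[z, y, x] <- median(nb)
  }
  out
}

oracle_morph <- function(a, se, op = c("erode", "dilate")) {
  op <- match.arg(op)
  f <- if (op == "erode") min else max
  d <- dim(a)
  out <- a
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    vals <- apply(se, 1, function(o) {
      a[refl(z + o[1], d[1]), refl(y + o[2], d[2]), refl(x + o[3], d[3])]
    })
    out[z, y, x] <- f(vals)
  }
  out
}

oracle_tophat <- function(a, se) {
  pmax(a - oracle_morph(oracle_morph(a, se, "erode"), se, "dilate"), 0)
}

neighbours_of <- function(idx, d, connectivity) {
  z <- idx[1]; y <- idx[2]; x <- idx[3]
  out <- NULL
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    ord <- abs(dz) + abs(dy) + abs(dx)
    if (ord == 0) next
    if (connectivity == 6 && ord > 1) next
    if (connectivity == 18 && ord > 2) next
    p <- c(z + dz, y + dy, x + dx)
    if (all(p >= 1) && all(p <= d)) out <- rbind(out, p)
  }
  out
}

oracle_flood_label <- function(mask, connectivity = 26) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  coords <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(coords))) {
    st <- coords[k, ]
    if (lab[st[1], st[2], st[3]] != 0L) next
    nxt <- nxt + 1L
    queue <- list(st)
    lab[st[1], st[2], st[3]] <- nxt
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      nb <- neighbours_of(cur, d, connectivity)
      for (i in seq_len(NROW(nb))) {
        p <- nb[i, ]
        if (mask[p[1], p[2], p[3]] && lab[p[1], p[2], p[3]] == 0L) {
          lab[p[1], p[2], p[3]] <- nxt
          queue <- c(queue, list(p))
        }
      }
    }
  }
  lab
}

oracle_fill_holes <- function(mask) {
  d <- dim(mask)
  outside <- array(FALSE, d)
  border <- which(!mask, arr.ind = TRUE)
  border <- border[border[, 1] %in% c(1, d[1]) | border[, 2] %in% c(1, d[2]) |
                     border[, 3] %in% c(1, d[3]), , drop = FALSE]
  queue <- lapply(seq_len(nrow(border)), function(i) border[i, ])
  for (q in queue) outside[q[1], q[2], q[3]] <- TRUE
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    nb <- neighbours_of(cur, d, 6)
    for (i in seq_len(NROW(nb))) {
      p <- nb[i, ]
      if (!mask[p[1], p[2], p[3]] && !outside[p[1], p[2], p[3]]) {
        outside[p[1], p[2], p[3]] <- TRUE
        queue <- c(queue, list(p))
      }
    }
  }
  mask | !outside
}

# two labelings describe the same partition of foreground voxels
same_partition <- function(l1, l2) {
  fg1 <- l1 > 0; fg2 <- l2 > 0
  if (!identical(fg1, fg2)) return(FALSE)
  a <- l1[fg1]; b <- l2[fg2]
  all(tapply(b, a, function(v) length(unique(v)) == 1)) &&
    all(tapply(a, b, function(v) length(unique(v)) == 1))
}

rand_grid <- function(d, dz = 1, dy = 1, dx = 1, max_val = 100) {
  voxel_grid(array(sample.int(max_val, prod(d), replace = TRUE), d),
             dz = dz, dy = dy, dx = dx)
}

make_mask <- function(a, dz = 1, dy = 1, dx = 1) {
  g <- voxel_grid(array(as.numeric(a), dim(a)), dz, dy, dx)
  threshold_constant(g, 1)
}

# small deterministic series for trend tests
linear_series <- function(beta, n_rois = 2, n = 10, alpha = 1) {
  tt <- (seq_len(n) - 1) / (n - 1)
  out <- purrr::map_dfr(seq_len(n_rois), function(r) {
    tibble::tibble(roi_id = paste0("roi", r), dye = "TMRM",
                   microscope = "SDCM", acquisition = seq_len(n), t = tt,
                   raw = 200 * (alpha + beta * tt),
                   relative = alpha + beta * tt)
  })
  class(out) <- c("intensity_series", class(out))
  out
}
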