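# Independent reference implementations used as oracles. These stay
# deliberately naive (loops, recursion, direct set arithmetic) so they
# share no code path with the package internals they check.

# de Casteljau recursion for a single parameter value
de_casteljau <- function(P, t) {
  Q <- P
  while (nrow(Q) > 1L) {
    Q <- (1 - t) * Q[-nrow(Q), , drop = FALSE] + t * Q[-1, , drop = FALSE]
  }
  Q[1, ]
}

# exhaustive nearest-neighbour search, one query at a time
loop_nearest <- function(query, ref) {
  vapply(seq_len(nrow(query)), function(i) {
    d2 <- (ref[, 1] - query[i, 1])^2 + (ref[, 2] - query[i, 2])^2
    which.min(d2)
  }, integer(1))
}

# cost via the loop oracle, literally (1/m) * sum of m+1 distances
loop_cost <- function(curve, skel_pts, m) {
  t <- seq(0, 1, length.out = m + 1L)
  b <- bezier_eval(curve, t)
  idx <- loop_nearest(b, skel_pts)
  sum(sqrt(rowSums((b - skel_pts[idx, , drop = FALSE])^2))) / m
}

# stack-based 8-connected flood fill labelling
flood_label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (cc0 in seq_len(nc)) for (rr0 in seq_len(nr)) {
    if (!mask[rr0, cc0] || lab[rr0, cc0] != 0L) next
    cur <- cur + 1L
    stack <- list(c(rr0, cc0))
    lab[rr0, cc0] <- cur
    while (length(stack) > 0L) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- cur
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# direct set-arithmetic dilation: shift the mask by every structuring
# element offset (floor-centre origin) and take the union
dilate_oracle <- function(mask, size = c(20L, 20L)) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  drs <- (0:(size[1] - 1L)) - size[1] %/% 2L
  dcs <- (0:(size[2] - 1L)) - size[2] %/% 2L
  idx <- which(mask, arr.ind = TRUE)
  for (dr in drs) for (dc in dcs) {
    r <- idx[, 1] + dr; c <- idx[, 2] + dc
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    out[cbind(r[ok], c[ok])] <- TRUE
  }
  out
}

# breadth-first distances from one pixel over the 8-neighbour graph,
# on a (row, col) pixel list
bfs_distances <- function(pix, from) {
  n <- nrow(pix)
  key <- paste(pix[, 1], pix[, 2])
  idx_of <- function(r, c) match(paste(r, c), key)
  dist <- rep(NA_integer_, n)
  dist[from] <- 0L
  queue <- from
  while (length(queue) > 0L) {
    v <- queue[1]; queue <- queue[-1]
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      w <- idx_of(pix[v, 1] + dr, pix[v, 2] + dc)
      if (!is.na(w) && is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        queue <- c(queue, w)
      }
    }
  }
  dist
}

# random blob mask: union of a few discs
make_blobs <- function(nr = 48L, nc = 48L, n_disks = 3L, rmax = 6,
                       seed = 1L, rmin = 2) {
  set.seed(seed)
  m <- matrix(FALSE, nr, nc)
  px <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  py <- matrix(rep(seq_len(nr), times = nc), nr, nc)
  for (i in seq_len(n_disks)) {
    cx <- runif(1, rmax + 1, nc - rmax)
    cy <- runif(1, rmax + 1, nr - rmax)
    r <- runif(1, rmin, rmax)
    m <- m | ((px - cx)^2 + (py - cy)^2 <= r^2)
  }
  m
}

random_bezier <- function(degree, seed) {
  set.seed(seed)
  bezier_curve(matrix(runif(2 * (degree + 1), -10, 10), ncol = 2))
}

# arc-length-uniform sampling of a curve, as a skeleton_curve
arc_uniform_skeleton <- function(curve, n_points, shape = c(256L, 256L)) {
  t <- seq(0, 1, length.out = 4001)
  b <- bezier_eval(curve, t)
  s <- c(0, cumsum(sqrt(rowSums(diff(b)^2))))
  tt <- stats::approx(s, t, xout = seq(0, max(s), length.out = n_points))$y
  skeleton_curve(bezier_eval(curve, tt), shape)
}

# partition equivalence of two labelled images (same grouping of pixels)
same_partition <- function(lab1, lab2) {
  fg1 <- lab1 > 0L; fg2 <- lab2 > 0L
  if (!identical(fg1, fg2)) return(FALSE)
  pairs <- unique(cbind(lab1[fg1], lab2[fg2]))
  !anyDuplicated(pairs[, 1]) && !anyDuplicated(pairs[, 2])
}
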