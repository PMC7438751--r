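# Medial-axis extraction and ordering of the arch centre-line.

# shift a 0/1 matrix so out[r, c] = m[r + dr, c + dc], zero outside
shift01 <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  rs <- max(1L, 1L - dr):min(nr, nr - dr)
  cs <- max(1L, 1L - dc):min(nc, nc - dc)
  if (length(rs) == 0L || length(cs) == 0L) return(out)
  out[rs, cs] <- m[rs + dr, cs + dc]
  out
}

#' Medial axis of a binary mask
#'
#' Topology-preserving iterative thinning (Zhang-Suen): the mask is peeled
#' from alternating sides until only a 1-px-wide, 8-connected skeleton
#' remains. The skeleton is always contained in the mask and stays
#' connected when the mask is connected.
#'
#' @param mask logical matrix with at least one foreground pixel
#'   (typically the single-component arch mask).
#' @return logical matrix marking skeleton pixels.
#' @export
medial_axis <- function(mask) {
  if (!any(mask))
    pd_error("empty mask: nothing to skeletonise", "pdx_empty_segmentation")
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbours clockwise from north: P2..P9
      n2 <- shift01(m, -1L, 0L);  n3 <- shift01(m, -1L, 1L)
      n4 <- shift01(m, 0L, 1L);   n5 <- shift01(m, 1L, 1L)
      n6 <- shift01(m, 1L, 0L);   n7 <- shift01(m, 1L, -1L)
      n8 <- shift01(m, 0L, -1L);  n9 <- shift01(m, -1L, -1L)
      b <- n2 + n3 + n4 + n5 + n6 + n7 + n8 + n9
      a <- (n2 < n3) + (n3 < n4) + (n4 < n5) + (n5 < n6) +
        (n6 < n7) + (n7 < n8) + (n8 < n9) + (n9 < n2)
      if (step == 1L) {
        cond <- m == 1 & b >= 2 & b <= 6 & a == 1 &
          (n2 * n4 * n6 == 0) & (n4 * n6 * n8 == 0)
      } else {
        cond <- m == 1 & b >= 2 & b <= 6 & a == 1 &
          (n2 * n4 * n8 == 0) & (n2 * n6 * n8 == 0)
      }
      if (any(cond)) {
        m[cond] <- 0
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m > 0.5
}

# 8-neighbour graph over the foreground pixels of a mask.
# Returns the igraph plus the (row, col) coordinates of each vertex.
pixel_graph8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask)
  vid <- integer(nr * nc)
  vid[fg] <- seq_along(fg)
  edges <- list()
  for (o in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    dr <- o[1]; dc <- o[2]
    r1 <- max(1L, 1L - dr):min(nr, nr - dr)
    c1 <- max(1L, 1L - dc):min(nc, nc - dc)
    a <- mask[r1, c1, drop = FALSE] & mask[r1 + dr, c1 + dc, drop = FALSE]
    hit <- which(a, arr.ind = TRUE)
    if (nrow(hit) == 0L) next
    ra <- r1[hit[, 1]]; ca <- c1[hit[, 2]]
    edges[[length(edges) + 1L]] <-
      cbind(vid[(ca - 1L) * nr + ra], vid[(ca + dc - 1L) * nr + ra + dr])
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges) > 0L)
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  list(graph = g,
       rows = ((fg - 1L) %% nr) + 1L,
       cols = ((fg - 1L) %/% nr) + 1L)
}

#' Ordered skeleton curve
#'
#' Container for the ordered medial-axis polyline: an n x 2 matrix of
#' `(x, y)` pixel coordinates (x = column, y = row, 1-based) plus the
#' shape of the source image.
#'
#' @param points numeric matrix with columns x, y; at least 2 rows, no
#'   repeated points.
#' @param source_shape integer `(rows, cols)` of the image the skeleton
#'   came from.
#' @return A `skeleton_curve` object.
#' @export
skeleton_curve <- function(points, source_shape) {
  points <- as.matrix(points)
  if (nrow(points) < 2L)
    pd_error("a skeleton curve needs at least 2 points", "pdx_input_error")
  if (anyDuplicated(points))
    pd_error("skeleton curve points must be unique", "pdx_input_error")
  if (any(points[, 1] < 1) || any(points[, 1] > source_shape[2]) ||
      any(points[, 2] < 1) || any(points[, 2] > source_shape[1]))
    pd_error("skeleton points outside image bounds", "pdx_input_error")
  colnames(points) <- c("x", "y")
  structure(list(points = points, source_shape = as.integer(source_shape)),
            class = "skeleton_curve")
}

#' @export
print.skeleton_curve <- function(x, ...) {
  cat(sprintf("skeleton_curve: %d points in a %d x %d image\n",
              nrow(x$points), x$source_shape[1], x$source_shape[2]))
  invisible(x)
}

#' Prune skeleton branches and order the main arch path
#'
#' Builds the 8-neighbour graph of the skeleton pixels, finds the longest
#' shortest path between endpoint pixels (the graph-diameter path, i.e.
#' the main arch branch), discards side branches, and orients the path
#' from the image-left endpoint (smaller x) to the right one. Skeletons
#' without degree-1 endpoints (closed loops) fall back to a double
#' breadth-first sweep to pick the two farthest pixels.
#'
#' @param skeleton_pixels logical matrix from [medial_axis()].
#' @return A [skeleton_curve()].
#' @export
prune_and_order <- function(skeleton_pixels) {
  if (sum(skeleton_pixels) < 2L)
    pd_error("skeleton has fewer than 2 pixels", "pdx_input_error")
  pg <- pixel_graph8(skeleton_pixels)
  g <- pg$graph

  comp <- igraph::components(g)
  main <- which.max(comp$csize)
  members <- which(comp$membership == main)

  deg <- igraph::degree(g)
  endpoints <- intersect(which(deg <= 1L), members)
  if (length(endpoints) < 2L) {
    # loop or blob: double sweep from an arbitrary member
    d0 <- igraph::distances(g, v = members[1])[1, members]
    u <- members[which.max(d0)]
    du <- igraph::distances(g, v = u)[1, members]
    v <- members[which.max(du)]
    pair <- c(u, v)
  } else {
    dmat <- igraph::distances(g, v = endpoints, to = endpoints)
    dmat[!is.finite(dmat)] <- -1
    best <- which(dmat == max(dmat), arr.ind = TRUE)
    # deterministic tie-break: smallest vertex indices
    best <- best[order(endpoints[best[, 1]], endpoints[best[, 2]]), ,
                 drop = FALSE]
    pair <- c(endpoints[best[1, 1]], endpoints[best[1, 2]])
  }
  path <- igraph::shortest_paths(g, from = pair[1], to = pair[2],
                                 output = "vpath")$vpath[[1]]
  path <- as.integer(path)
  xs <- pg$cols[path]
  ys <- pg$rows[path]
  n <- length(path)
  if (xs[n] < xs[1] || (xs[n] == xs[1] && ys[n] < ys[1])) {
    xs <- rev(xs); ys <- rev(ys)
  }
  skeleton_curve(cbind(x = xs, y = ys), dim(skeleton_pixels))
}
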