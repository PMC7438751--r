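# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
pd_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "panodont_error")))
}

#' Round half away from zero
#'
#' Deterministic rounding used for integer pixel quantisation (base
#' `round()` rounds half to even).
#' @noRd
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Evaluate an expression with a private RNG stream
#'
#' Seeds the RNG, runs `expr`, and restores the caller's RNG state so that
#' package randomness never perturbs user code.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Bilinear interpolation of a 2D image at continuous pixel coordinates
#'
#' Coordinates are 1-based with pixel centres at integers; `x` indexes
#' columns and `y` rows. Samples outside `[1, ncol] x [1, nrow]` receive
#' `fill`.
#' @noRd
bilinear_sample <- function(img, x, y, fill = -1000) {
  nr <- nrow(img)
  nc <- ncol(img)
  out <- rep(fill, length(x))
  inb <- x >= 1 & x <= nc & y >= 1 & y <= nr & is.finite(x) & is.finite(y)
  if (!any(inb)) return(out)
  xi <- x[inb]; yi <- y[inb]
  x0 <- pmin(floor(xi), nc - 1L); x0 <- pmax(x0, 1L)
  y0 <- pmin(floor(yi), nr - 1L); y0 <- pmax(y0, 1L)
  fx <- xi - x0
  fy <- yi - y0
  v00 <- img[cbind(y0, x0)]
  v01 <- img[cbind(y0, x0 + 1)]
  v10 <- img[cbind(y0 + 1, x0)]
  v11 <- img[cbind(y0 + 1, x0 + 1)]
  out[inb] <- (1 - fy) * ((1 - fx) * v00 + fx * v01) +
    fy * ((1 - fx) * v10 + fx * v11)
  out
}

#' 8-connected component labelling
#'
#' Builds the 8-neighbour pixel graph of the foreground and labels its
#' connected components with igraph. Labels are renumbered so that
#' component 1 owns the smallest pixel in row-major (top-left raster)
#' order, which makes tie-breaking deterministic downstream.
#'
#' @param mask logical matrix.
#' @return integer matrix of the same shape; 0 = background.
#' @noRd
label_components8 <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  fg <- which(mask)
  if (length(fg) == 0L) return(lab)
  vid <- integer(nr * nc)
  vid[fg] <- seq_along(fg)

  edges <- list()
  # offsets covering all 8-neighbour pairs once: E, S, SE, SW
  offs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  for (o in offs) {
    dr <- o[1]; dc <- o[2]
    r1 <- max(1L, 1L - dr):min(nr, nr - dr)
    c1 <- max(1L, 1L - dc):min(nc, nc - dc)
    a <- mask[r1, c1, drop = FALSE] & mask[r1 + dr, c1 + dc, drop = FALSE]
    hit <- which(a, arr.ind = TRUE)
    if (nrow(hit) == 0L) next
    ra <- r1[hit[, 1]]; ca <- c1[hit[, 2]]
    ia <- (ca - 1L) * nr + ra
    ib <- (ca + dc - 1L) * nr + (ra + dr)
    edges[[length(edges) + 1L]] <- cbind(vid[ia], vid[ib])
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges) > 0L) {
    em <- do.call(rbind, edges)
    g <- igraph::add_edges(g, t(em))
  }
  memb <- igraph::components(g)$membership
  # renumber by row-major order of each component's first pixel
  rows <- ((fg - 1L) %% nr) + 1L
  cols <- ((fg - 1L) %/% nr) + 1L
  raster <- (rows - 1L) * nc + cols
  first <- tapply(raster, memb, min)
  new_id <- integer(length(first))
  new_id[order(first)] <- seq_along(first)
  lab[fg] <- new_id[memb]
  lab
}
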