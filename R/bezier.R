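# Bezier arch curve: Bernstein evaluation, derivative, discrete
# point-to-skeleton cost, and control-point optimisation.

#' Bezier curve
#'
#' A degree-n Bezier curve defined by its `n + 1` control points
#' `P_0 .. P_n`:
#' \deqn{B(t) = \sum_{i=0}^{n} \binom{n}{i} (1-t)^{n-i} t^i P_i,
#'   \quad t \in [0, 1].}
#'
#' @param control_points numeric matrix with columns x, y and at least 2
#'   rows; all coordinates finite.
#' @return A `bezier_curve` with elements `control_points` and `degree`.
#' @examples
#' bz <- bezier_curve(rbind(c(0, 0), c(1, 2), c(2, 0)))
#' bezier_eval(bz, c(0, 0.5, 1))
#' @export
bezier_curve <- function(control_points) {
  control_points <- as.matrix(control_points)
  if (nrow(control_points) < 2L)
    pd_error("a Bezier curve needs at least 2 control points",
             "pdx_input_error")
  if (ncol(control_points) != 2L || any(!is.finite(control_points)))
    pd_error("control points must be finite (x, y) pairs", "pdx_input_error")
  colnames(control_points) <- c("x", "y")
  structure(list(control_points = control_points,
                 degree = nrow(control_points) - 1L),
            class = "bezier_curve")
}

#' @export
print.bezier_curve <- function(x, ...) {
  cat(sprintf("bezier_curve of degree %d (%d control points)\n",
              x$degree, nrow(x$control_points)))
  invisible(x)
}

# Bernstein basis matrix: length(t) x (n + 1), entry [i, j+1] =
# C(n, j) (1 - t_i)^(n - j) t_i^j. Binomials from choose(); stable well
# past degree 20.
bernstein_matrix <- function(n, t) {
  j <- 0:n
  outer(t, j, function(ti, ji) {
    choose(n, ji) * (1 - ti)^(n - ji) * ti^ji
  })
}

check_t <- function(t) {
  if (any(!is.finite(t)) || any(t < 0) || any(t > 1))
    pd_error("curve parameter t must lie in [0, 1]", "pdx_domain_error")
  t
}

#' Evaluate a Bezier curve
#'
#' Bernstein-form evaluation of `B(t)`; `t = 0` gives the first control
#' point and `t = 1` the last.
#'
#' @param curve a [bezier_curve()].
#' @param t numeric vector of parameters in `[0, 1]`.
#' @return numeric matrix `length(t) x 2` with columns x, y.
#' @export
bezier_eval <- function(curve, t) {
  check_t(t)
  M <- bernstein_matrix(curve$degree, t)
  out <- M %*% curve$control_points
  colnames(out) <- c("x", "y")
  out
}

#' Derivative of a Bezier curve
#'
#' The hodograph form: a degree-(n-1) Bernstein sum over the control-point
#' differences, scaled by n:
#' \deqn{B'(t) = n \sum_{i=0}^{n-1} b_{i,n-1}(t) (P_{i+1} - P_i).}
#'
#' @param curve a [bezier_curve()] of degree >= 1.
#' @param t numeric vector of parameters in `[0, 1]`.
#' @return numeric matrix `length(t) x 2` with columns dx, dy.
#' @export
bezier_derivative <- function(curve, t) {
  check_t(t)
  n <- curve$degree
  D <- diff(curve$control_points)
  M <- bernstein_matrix(n - 1L, t)
  out <- n * (M %*% D)
  colnames(out) <- c("dx", "dy")
  out
}

# Exact nearest-neighbour indices of query points among reference points.
# Chunked vectorised exhaustive search; ties resolved to the lowest
# reference index.
nearest_indices <- function(query, ref, chunk = 512L) {
  nq <- nrow(query)
  idx <- integer(nq)
  rx <- ref[, 1]; ry <- ref[, 2]
  for (s in seq(1L, nq, by = chunk)) {
    e <- min(s + chunk - 1L, nq)
    d2 <- outer(query[s:e, 1], rx, "-")^2 + outer(query[s:e, 2], ry, "-")^2
    idx[s:e] <- max.col(-d2, ties.method = "first")
  }
  idx
}

#' Discrete mean distance from a Bezier curve to a skeleton
#'
#' Samples the curve at `t_i = i/m` for `i = 0..m` and, for every sample
#' `b_i`, finds the closest skeleton point `e_i` (exact Euclidean nearest
#' neighbour, lowest index on ties). The cost is
#' \deqn{f = \frac{1}{m} \sum_{i=0}^{m} |e_i - b_i|}
#' — note the divisor is `m` while the sum runs over the `m + 1` sample
#' points; the formula is implemented literally in that form.
#'
#' @param curve a [bezier_curve()].
#' @param skeleton a [skeleton_curve()] (or a matrix of skeleton points).
#' @param m_samples the sampling density m (default 1000, i.e. 1001
#'   sample points).
#' @return non-negative scalar cost, in pixels.
#' @export
cost_function <- function(curve, skeleton, m_samples = 1000L) {
  if (m_samples < 1L)
    pd_error("m_samples must be >= 1", "pdx_input_error")
  pts <- if (inherits(skeleton, "skeleton_curve")) skeleton$points
         else as.matrix(skeleton)
  if (nrow(pts) == 0L)
    pd_error("empty skeleton", "pdx_input_error")
  t <- seq(0, 1, length.out = m_samples + 1L)
  b <- bezier_eval(curve, t)
  e <- pts[nearest_indices(b, pts), , drop = FALSE]
  sum(sqrt(rowSums((e - b)^2))) / m_samples
}

#' Fit configuration
#'
#' @param n_control_points number of control points (the studied settings
#'   are 3, 7, 11 and 15; default 11).
#' @param m_samples curve sampling density m (default 1000).
#' @param max_iter optimiser iteration cap.
#' @param tol relative convergence tolerance.
#' @param seed seed for the random initialisation mode.
#' @param init_mode `"skeleton_uniform"` (deterministic: control points at
#'   uniformly spaced skeleton indices) or `"random_in_bbox"` (uniform in
#'   the skeleton bounding box).
#' @return A `fit_config` list.
#' @export
fit_config <- function(n_control_points = 11L, m_samples = 1000L,
                       max_iter = 500L, tol = 1e-6, seed = 0L,
                       init_mode = c("skeleton_uniform", "random_in_bbox")) {
  init_mode <- match.arg(init_mode)
  n_control_points <- as.integer(n_control_points)
  m_samples <- as.integer(m_samples)
  if (n_control_points < 2L)
    pd_error("n_control_points must be >= 2", "pdx_input_error")
  if (n_control_points > m_samples)
    pd_error("n_control_points must not exceed m_samples", "pdx_input_error")
  structure(list(n_control_points = n_control_points, m_samples = m_samples,
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed), init_mode = init_mode),
            class = "fit_config")
}

#' Initial control points for the arch fit
#'
#' `skeleton_uniform` picks skeleton points at uniformly spaced indices
#' along the ordered curve (deterministic); `random_in_bbox` draws the
#' control points uniformly in the skeleton's bounding box using the seed.
#'
#' @param skeleton a [skeleton_curve()].
#' @param n_points number of control points.
#' @param init_mode see [fit_config()].
#' @param seed RNG seed for the random mode.
#' @return A [bezier_curve()].
#' @export
initialize_control_points <- function(skeleton, n_points,
                                      init_mode = "skeleton_uniform",
                                      seed = 0L) {
  pts <- skeleton$points
  N <- nrow(pts)
  if (n_points > N)
    pd_error("more control points than skeleton points", "pdx_input_error")
  if (init_mode == "skeleton_uniform") {
    idx <- round(seq(1, N, length.out = n_points))
    bezier_curve(pts[idx, , drop = FALSE])
  } else if (init_mode == "random_in_bbox") {
    with_seed(seed, {
      x <- stats::runif(n_points, min(pts[, 1]), max(pts[, 1]))
      y <- stats::runif(n_points, min(pts[, 2]), max(pts[, 2]))
      bezier_curve(cbind(x, y))
    })
  } else {
    pd_error(sprintf("unknown init_mode '%s'", init_mode), "pdx_input_error")
  }
}

#' Fit a Bezier curve to a skeleton by cost minimisation
#'
#' Minimises [cost_function()] over the `2(n+1)` control-point
#' coordinates with a quasi-Newton (BFGS) minimiser. The gradient is
#' analytic under a locally fixed nearest-neighbour assignment: with
#' `u_i = (b_i - e_i)/|b_i - e_i|`, the gradient with respect to control
#' point `P_j` is `(1/m) \sum_i B_{j,n}(t_i) u_i`. No bounds or
#' constraints are imposed; control points may leave the image and only
#' final curve samples are clipped at volume-sampling time.
#'
#' The returned `fit_result` always satisfies `f_final <= f_initial`: if
#' the optimiser fails or worsens the cost, the best curve seen so far is
#' returned with `converged = FALSE` rather than raising an error.
#'
#' @param skeleton a [skeleton_curve()].
#' @param cfg a [fit_config()].
#' @return A `fit_result` with elements `curve`, `f_initial`, `f_final`,
#'   `n_iterations`, `converged` and `config`.
#' @export
fit_bezier <- function(skeleton, cfg = fit_config()) {
  pts <- skeleton$points
  init <- initialize_control_points(skeleton, cfg$n_control_points,
                                    cfg$init_mode, cfg$seed)
  m <- cfg$m_samples
  t <- seq(0, 1, length.out = m + 1L)
  n <- cfg$n_control_points - 1L
  M <- bernstein_matrix(n, t)
  Mt <- t(M)

  cost_of <- function(par) {
    P <- matrix(par, ncol = 2L)
    b <- M %*% P
    e <- pts[nearest_indices(b, pts), , drop = FALSE]
    sum(sqrt(rowSums((b - e)^2))) / m
  }
  grad_of <- function(par) {
    P <- matrix(par, ncol = 2L)
    b <- M %*% P
    e <- pts[nearest_indices(b, pts), , drop = FALSE]
    diffv <- b - e
    d <- sqrt(rowSums(diffv^2))
    u <- diffv
    nz <- d > 1e-12
    u[nz, ] <- diffv[nz, , drop = FALSE] / d[nz]
    u[!nz, ] <- 0
    as.vector(Mt %*% u) / m
  }

  par0 <- as.vector(init$control_points)
  f_initial <- cost_of(par0)

  res <- tryCatch(
    stats::optim(par0, cost_of, grad_of, method = "BFGS",
                 control = list(maxit = cfg$max_iter, reltol = cfg$tol)),
    error = function(e) NULL)

  if (is.null(res) || !is.finite(res$value) || res$value > f_initial) {
    curve <- init
    f_final <- f_initial
    converged <- FALSE
    iters <- 0L
  } else {
    curve <- bezier_curve(matrix(res$par, ncol = 2L))
    f_final <- res$value
    converged <- res$convergence == 0L
    iters <- unname(res$counts[1])
  }
  structure(list(curve = curve, f_initial = f_initial, f_final = f_final,
                 n_iterations = iters, converged = converged,
                 config = unclass(cfg)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "fit_result: %d control points, f_initial = %.3f, f_final = %.3f px%s\n",
    nrow(x$curve$control_points), x$f_initial, x$f_final,
    if (x$converged) "" else " (not converged)"))
  invisible(x)
}
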