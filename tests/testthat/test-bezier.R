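test_that("Bernstein evaluation interpolates endpoints and midpoints", {
  bz <- bezier_curve(rbind(c(0, 0), c(1, 1)))
  expect_equal(bezier_eval(bz, 0.5), cbind(x = 0.5, y = 0.5),
               ignore_attr = TRUE)
  for (seed in 1:5) {
    cv <- random_bezier(sample(1:15, 1), seed)
    P <- cv$control_points
    expect_equal(unname(bezier_eval(cv, 0)[1, ]), unname(P[1, ]))
    expect_equal(unname(bezier_eval(cv, 1)[1, ]), unname(P[nrow(P), ]))
  }
  expect_error(bezier_eval(bz, 1.2), class = "pdx_domain_error")
  expect_error(bezier_eval(bz, -0.1), class = "pdx_domain_error")
})

test_that("Bernstein form agrees with de Casteljau recursion", {
  set.seed(42)
  for (i in 1:20) {
    cv <- random_bezier(sample(1:15, 1), 1000 + i)
    for (t in runif(20)) {
      expect_equal(unname(bezier_eval(cv, t)[1, ]),
                   unname(de_casteljau(cv$control_points, t)),
                   tolerance = 1e-12)
    }
  }
})

test_that("the hodograph derivative matches closed forms and differences", {
  lin <- bezier_curve(rbind(c(0, 0), c(2, 0)))
  for (t in c(0, 0.3, 1))
    expect_equal(unname(bezier_derivative(lin, t)[1, ]), c(2, 0))

  quad <- bezier_curve(rbind(c(0, 0), c(1, 2), c(2, 0)))
  expect_equal(unname(bezier_derivative(quad, 0.5)[1, ]), c(2, 0))

  h <- 1e-6
  for (i in 1:10) {
    cv <- random_bezier(sample(2:12, 1), 2000 + i)
    for (t in runif(5, 0.01, 0.99)) {
      fd <- (bezier_eval(cv, t + h) - bezier_eval(cv, t - h)) / (2 * h)
      expect_equal(unname(bezier_derivative(cv, t)[1, ]), unname(fd[1, ]),
                   tolerance = 1e-4)
    }
  }
})

test_that("the discrete cost implements (1/m) * sum over m+1 samples", {
  # all samples on skeleton points -> zero
  sk <- cbind(0:5, 0:5)
  lin <- bezier_curve(rbind(c(0, 0), c(5, 5)))
  expect_equal(cost_function(lin, sk, m_samples = 5), 0)

  # constant distance 5 from a single skeleton point
  one <- rbind(c(0, 0))
  still <- bezier_curve(rbind(c(3, 4), c(3, 4)))
  expect_equal(cost_function(still, one, m_samples = 1000), 5 * 1001 / 1000)
  expect_equal(cost_function(bezier_curve(rbind(c(0, 0), c(0, 0))), one,
                             m_samples = 10), 0)

  expect_error(cost_function(lin, sk[0, , drop = FALSE], 10),
               class = "pdx_input_error")
})

test_that("nearest-neighbour search equals the exhaustive loop oracle", {
  for (i in 1:50) {
    set.seed(3000 + i)
    skel <- matrix(runif(2 * sample(5:200, 1), 0, 50), ncol = 2)
    cv <- random_bezier(sample(1:6, 1), 4000 + i)
    m <- sample(5:50, 1)
    expect_equal(cost_function(cv, skel, m), loop_cost(cv, skel, m),
                 tolerance = 1e-12)
  }
})

test_that("the cost is invariant under a common rigid translation", {
  set.seed(5)
  skel <- matrix(runif(60, 0, 30), ncol = 2)
  cv <- random_bezier(4, 77)
  shift <- c(12.3, -4.5)
  cv2 <- bezier_curve(sweep(cv$control_points, 2, shift, "+"))
  skel2 <- sweep(skel, 2, shift, "+")
  expect_equal(cost_function(cv, skel, 100), cost_function(cv2, skel2, 100),
               tolerance = 1e-9)
})

test_that("control-point initialisation is deterministic or seeded", {
  pts <- cbind(seq(10, 110, length.out = 101),
               seq(20, 60, length.out = 101))
  sk <- skeleton_curve(pts, c(128, 128))
  init <- initialize_control_points(sk, 3, "skeleton_uniform")
  expect_equal(unname(init$control_points),
               unname(pts[c(1, 51, 101), ]))

  r1 <- initialize_control_points(sk, 5, "random_in_bbox", seed = 42)
  r2 <- initialize_control_points(sk, 5, "random_in_bbox", seed = 42)
  r3 <- initialize_control_points(sk, 5, "random_in_bbox", seed = 43)
  expect_identical(r1$control_points, r2$control_points)
  expect_false(identical(r1$control_points, r3$control_points))
  expect_true(all(r1$control_points[, 1] >= 10 &
                    r1$control_points[, 1] <= 110))
  expect_true(all(r1$control_points[, 2] >= 20 &
                    r1$control_points[, 2] <= 60))

  expect_error(initialize_control_points(sk, 200, "skeleton_uniform"),
               class = "pdx_input_error")
})

test_that("degenerate skeletons fit without errors or cost increase", {
  # two isolated points: the discrete cost of any non-degenerate segment
  # is bounded away from zero (mid samples are far from both points), so
  # only the monotonicity contract applies
  sk <- skeleton_curve(rbind(c(10, 10), c(20, 18)), c(64, 64))
  fit <- fit_bezier(sk, fit_config(2, m_samples = 10))
  expect_lte(fit$f_final, fit$f_initial)

  # a collinear skeleton whose points coincide with the curve samples is
  # fitted exactly by its endpoints
  line <- cbind(10 + 0:10, rep(7, 11))
  sk2 <- skeleton_curve(line, c(64, 64))
  fit2 <- fit_bezier(sk2, fit_config(2, m_samples = 10))
  expect_lt(fit2$f_final, 1e-6)
})

test_that("fitting recovers a curve sampled from a known quadratic", {
  truth <- bezier_curve(rbind(c(40, 200), c(128, 40), c(216, 200)))
  sk <- arc_uniform_skeleton(truth, 201)
  fit <- fit_bezier(sk, fit_config(3))
  expect_lt(fit$f_final, 0.5)
  expect_lt(arch_distance(fit$curve, list(arch_curve = truth)), 0.5)
  expect_true(fit$converged)
})

test_that("optimisation never increases the cost, for either init mode", {
  skel <- cached_skeleton("default", 1L)
  for (mode in c("skeleton_uniform", "random_in_bbox")) {
    fit <- fit_bezier(skel, fit_config(7, m_samples = 300,
                                       init_mode = mode, seed = 4))
    expect_lte(fit$f_final, fit$f_initial)
    expect_gte(fit$f_final, 0)
  }
})
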