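test_that("offsets of a straight line are parallel lines at k*q", {
  lin <- bezier_curve(rbind(c(0, 0), c(10, 0)))
  fam <- offset_curves(lin, q = 2, n_offsets_per_side = 1, m_samples = 10)
  expect_equal(fam$k, -1:1)
  up <- fam$curves[[3]]   # k = +1: rotate90CCW of (1, 0) is (0, 1)
  dn <- fam$curves[[1]]
  expect_equal(unname(up[, 2]), rep(2, 11))
  expect_equal(unname(dn[, 2]), rep(-2, 11))
  expect_equal(unname(up[, 1]), seq(0, 10, 1))
})

test_that("the central offset curve is the sampled curve itself", {
  cv <- random_bezier(5, 9)
  fam <- offset_curves(cv, q = 1.5, n_offsets_per_side = 3, m_samples = 40)
  expect_equal(fam$curves[[fam$central_index]],
               bezier_eval(cv, seq(0, 1, length.out = 41)),
               ignore_attr = TRUE)
})

test_that("offset points sit exactly k*q from their base points", {
  arc <- bezier_curve(rbind(c(0, 0), c(0, 5.5228475), c(4.4771525, 10),
                            c(10, 10)))  # quarter-circle-ish cubic
  fam <- offset_curves(arc, q = 0.7, n_offsets_per_side = 4, m_samples = 50)
  base <- fam$curves[[fam$central_index]]
  for (i in seq_along(fam$k)) {
    d <- sqrt(rowSums((fam$curves[[i]] - base)^2))
    expect_equal(d, rep(abs(fam$k[i]) * 0.7, 51), tolerance = 1e-9)
  }
})

test_that("degenerate curves error and isolated cusps borrow a normal", {
  flat <- bezier_curve(rbind(c(3, 3), c(3, 3), c(3, 3)))
  expect_error(offset_curves(flat, 1, 1, 10),
               class = "pdx_degenerate_curve")

  cusp <- bezier_curve(rbind(c(0, 0), c(1, 1), c(0, 0)))  # B'(0.5) = 0
  fam <- offset_curves(cusp, 1, 1, 10)
  expect_true(all(is.finite(unlist(fam$curves))))
})

test_that("slice sampling interpolates bilinearly with air fill", {
  sl <- matrix(500, 20, 20)
  poly <- cbind(seq(2, 18, length.out = 7), rep(10.5, 7))
  expect_equal(sample_slice(sl, poly), rep(500, 7))

  sl2 <- matrix(0, 16, 16)
  sl2[3, 5] <- 42
  expect_equal(sample_slice(sl2, cbind(5, 3)), 42)

  block <- rbind(c(0, 10), c(20, 30))
  sl3 <- matrix(-1000, 16, 16)
  sl3[1:2, 1:2] <- block
  expect_equal(sample_slice(sl3, cbind(1.5, 1.5)), 15)

  expect_equal(sample_slice(sl, cbind(-5, 10)), -1000)
  expect_equal(sample_slice(sl, cbind(10, 25)), -1000)
})

test_that("AIP averages the offset lanes: striped phantom gives the mean", {
  vox <- array(-1000, c(16, 40, 1))
  vox[8, , 1] <- 300   # lane of curve k = -1 (y = 8)
  vox[10, , 1] <- 200  # central lane (y = 10)
  vox[12, , 1] <- 100  # lane of curve k = +1 (y = 12)
  v <- ct_volume(vox)
  lin <- bezier_curve(rbind(c(5, 10), c(35, 10)))
  fam <- offset_curves(lin, q = 2, n_offsets_per_side = 1, m_samples = 30)
  pano <- reconstruct_panoramic(v, fam)
  expect_equal(dim(pano$pixels), c(1, 31))
  expect_equal(unname(pano$pixels[1, ]), rep(200, 31))
})

test_that("K = 0 reduces the panoramic to direct curve sampling", {
  ph <- cached_phantom("default", 1L)
  cv <- bezier_curve(ph$truth$arch_curve$control_points)
  fam0 <- offset_curves(cv, q = 2, n_offsets_per_side = 0, m_samples = 200)
  pano <- reconstruct_panoramic(ph$volume, fam0)
  z <- 30L
  direct <- sample_slice(ph$volume$voxels[, , z], fam0$curves[[1]])
  expect_identical(unname(pano$pixels[z, ]), direct)
})

test_that("a constant volume produces a constant panoramic", {
  v <- ct_volume(array(200, c(16, 16, 3)))
  lin <- bezier_curve(rbind(c(4, 8), c(12, 8)))
  fam <- offset_curves(lin, q = 1, n_offsets_per_side = 2, m_samples = 20)
  pano <- reconstruct_panoramic(v, fam)
  expect_true(all(pano$pixels == 200))
})

test_that("panoramic values stay within the volume range padded by fill", {
  ph <- cached_phantom("default", 1L)
  res <- run_pipeline(ph$volume, pipeline_config(m_samples = 300))
  lo <- min(ph$volume$voxels)
  hi <- max(ph$volume$voxels)
  expect_gte(min(res$panoramic$pixels), min(lo, -1000))
  expect_lte(max(res$panoramic$pixels), hi)
})

test_that("the pipeline is deterministic and shape-correct on phantoms", {
  ph <- cached_phantom("default", 1L)
  cfg <- pipeline_config(m_samples = 300)
  r1 <- run_pipeline(ph$volume, cfg)
  r2 <- run_pipeline(ph$volume, cfg)
  expect_identical(r1$panoramic$pixels, r2$panoramic$pixels)
  expect_equal(dim(r1$panoramic$pixels), c(dim(ph$volume)[3], 301))
  expect_lte(r1$fit$f_final, r1$fit$f_initial)
})

test_that("stage errors carry the failing stage's name", {
  flat <- ct_volume(array(-1000, c(16, 16, 2)))
  err <- tryCatch(run_pipeline(flat), error = function(e) e)
  expect_s3_class(err, "pdx_empty_segmentation")
  expect_match(conditionMessage(err), "^\\[segment\\]")
})
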