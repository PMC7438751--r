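test_that("thresholding keeps the limit value and is monotone", {
  vox <- array(-1000, c(16, 16, 3))
  vox[4, 4, 2] <- 1500
  v <- ct_volume(vox)
  bv <- threshold_volume(v, 1500)
  expect_equal(sum(bv), 1)
  expect_true(bv[4, 4, 2])

  expect_false(any(threshold_volume(v, 1501)))
  expect_true(all(threshold_volume(v, -2000)))

  # raising the threshold never adds voxels
  set.seed(3)
  v2 <- ct_volume(array(rnorm(16 * 16 * 4, 500, 700), c(16, 16, 4)))
  for (thr in c(0, 500, 1000, 1500)) {
    lo <- threshold_volume(v2, thr)
    hi <- threshold_volume(v2, thr + 250)
    expect_true(all(lo | !hi))
  }
})

test_that("reference slice is the argmax of per-slice counts", {
  mk <- function(counts) {
    vox <- array(-1000, c(16, 16, length(counts)))
    for (z in seq_along(counts))
      if (counts[z] > 0) vox[seq_len(counts[z]), 1, z] <- 2000
    threshold_volume(ct_volume(vox), 1500)
  }
  expect_equal(select_reference_slice(mk(c(5, 9, 2))), 2)
  expect_equal(select_reference_slice(mk(c(4, 4, 1))), 1)  # tie -> smallest
  expect_error(select_reference_slice(mk(c(0, 0))),
               class = "pdx_empty_segmentation")

  # agreement with an independent per-slice summation oracle
  set.seed(9)
  for (i in 1:50) {
    bv <- array(runif(16 * 16 * 5) < 0.2, c(16, 16, 5))
    if (!any(bv)) next
    counts <- vapply(1:5, function(z) sum(bv[, , z] != 0), numeric(1))
    expect_equal(select_reference_slice(bv), which.max(counts))
  }
})

test_that("dilation bridges gaps, is extensive, and matches set arithmetic", {
  m <- matrix(FALSE, 40, 40)
  m[20, 10] <- TRUE
  m[20, 25] <- TRUE  # 15 px apart: within the 20 x 20 reach
  expect_equal(max(flood_label8(m)), 2)
  d <- connect_regions(m)
  expect_equal(max(flood_label8(d)), 1)

  for (i in 1:50) {
    blob <- make_blobs(seed = i)
    dil <- connect_regions(blob)
    expect_true(all(dil | !blob))  # superset of the input
  }

  # single centred pixel -> the structuring-element footprint
  one <- matrix(FALSE, 41, 41)
  one[21, 21] <- TRUE
  expect_identical(connect_regions(one), dilate_oracle(one))

  # oracle agreement and monotonicity on small random masks
  for (i in 1:10) {
    blob <- make_blobs(seed = 100 + i)
    expect_identical(connect_regions(blob), dilate_oracle(blob))
    sub <- blob & make_blobs(seed = 200 + i)
    expect_true(all(connect_regions(blob) | !connect_regions(sub)))
  }
})

test_that("mask smoothing keeps constants and erases isolated pixels", {
  allT <- matrix(TRUE, 32, 32)
  expect_true(all(smooth_mask(allT)))
  allF <- matrix(FALSE, 32, 32)
  expect_false(any(smooth_mask(allF)))

  # a blurred unit impulse peaks near 1/(2*pi*sigma^2) ~ 0.01 << 0.5
  one <- matrix(FALSE, 65, 65)
  one[33, 33] <- TRUE
  peak <- max(EBImage::gblur(one * 1, sigma = 4))
  expect_lt(peak, 0.5)
  expect_false(any(smooth_mask(one)))
})

test_that("largest component selection matches a flood-fill oracle", {
  m <- matrix(FALSE, 30, 30)
  m[2:6, 2:7] <- TRUE        # 30 px
  m[15:18, 15:17] <- TRUE    # 12 px
  m[25, 25:27] <- TRUE       # 3 px
  out <- largest_component(m)
  expect_equal(sum(out), 30)
  expect_true(all(out[2:6, 2:7]))

  single <- matrix(FALSE, 10, 10)
  single[3:5, 3:5] <- TRUE
  expect_identical(largest_component(single), single)
  expect_error(largest_component(matrix(FALSE, 5, 5)),
               class = "pdx_empty_segmentation")

  for (i in 1:50) {
    blob <- make_blobs(n_disks = 4L, seed = 300 + i)
    if (!any(blob)) next
    ours <- panodont:::label_components8(blob)
    oracle <- flood_label8(blob)
    expect_true(same_partition(ours, oracle))
    biggest <- largest_component(blob)
    sizes <- tabulate(oracle[oracle > 0])
    expect_equal(sum(biggest), max(sizes))
    expect_true(all(blob | !biggest))  # subset of input
    expect_equal(max(flood_label8(biggest)), 1)  # connected
  }
})

test_that("smoothing after dilation rarely splits components", {
  # blobs at the scale of dilated teeth (radius comparable to the
  # structuring element), the structures this chain actually smooths
  worse <- 0L
  for (i in 1:100) {
    blob <- make_blobs(64L, 64L, n_disks = 3L, rmax = 8, rmin = 4,
                       seed = 400 + i)
    if (!any(blob)) next
    dil <- connect_regions(blob)
    smo <- smooth_mask(dil)
    if (!any(smo) ||
        max(flood_label8(smo)) > max(flood_label8(dil)))
      worse <- worse + 1L
  }
  expect_lte(worse, 5L)
})

test_that("the segmentation chain yields one arch component on phantoms", {
  ph <- cached_phantom("default", 1L)
  seg <- segment_arch(ph$volume)
  expect_equal(max(flood_label8(seg$mask)), 1)
  expect_true(seg$slice_index %in% ph$truth$tooth_slab)

  # two missing adjacent teeth still bridge under the 20 x 20 dilation
  ph2 <- cached_phantom("missing-teeth", 1L)
  seg2 <- segment_arch(ph2$volume)
  expect_gte(max(flood_label8(seg2$stages$threshold)), 2)
  expect_equal(max(flood_label8(seg2$mask)), 1)

  # no teeth at all -> empty segmentation error
  empty <- generate_phantom(phantom_spec(n_slices = 12L,
                                         missing_teeth = 1:14, seed = 1L))
  expect_error(segment_arch(empty$volume),
               class = "pdx_empty_segmentation")
})
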