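test_that("vascularized area separates vessels from microbleeds exactly", {
  spec <- phantom_spec(shape = c(64, 64, 32), pixel_size = 5, n_vessels = 3,
                       radius_range = c(10, 15), tortuosity_target = 1.05,
                       noise_sd = 0, background_level = 100,
                       vessel_level = 20, seed = 3)
  pp <- generate_t2star_pair(spec, n_microbleeds = 2)
  roi <- array(TRUE, dim(pp$pre$values))
  va <- vascularized_area(pp$pre, pp$post, roi, hypo_threshold = 60)
  expect_identical(va$included, pp$truth$vessel_mask)
  expect_equal(va$included_voxel_count, sum(pp$truth$vessel_mask))
  expect_equal(va$excluded_precontrast_voxel_count,
               sum(pp$truth$microbleed_mask))
  # area arithmetic: voxel in-plane area times count
  expect_equal(va$area_mm2,
               sum(pp$truth$vessel_mask) * 25 / 1e6)
  expect_equal(sum(va$area_mm2_per_slice), va$area_mm2)
})

test_that("vascularized area degenerate cases", {
  img <- image_stack(matrix(100, 16, 16), 80)
  roi <- matrix(TRUE, 16, 16)
  # no contrast effect: zero area
  va <- vascularized_area(img, img, roi, hypo_threshold = 50)
  expect_equal(va$area_mm2, 0)
  # grid mismatch refused
  expect_error(vascularized_area(img,
                                 image_stack(matrix(0, 8, 8), 80), roi),
               "grid")
  # roi disjoint from vessels
  pre <- image_stack(matrix(100, 16, 16), 80)
  postv <- matrix(100, 16, 16); postv[5:8, 5:8] <- 10
  post <- image_stack(postv, 80)
  roi2 <- matrix(FALSE, 16, 16); roi2[12:16, 12:16] <- TRUE
  expect_equal(vascularized_area(pre, post, roi2,
                                 hypo_threshold = 50)$area_mm2, 0)
})

test_that("lowering the threshold never adds included voxels", {
  # with no pre-contrast hypointensities the exclusion set is empty and the
  # included count is monotone in the threshold; with a shared threshold
  # the exclusion set shrinks alongside, so global monotonicity cannot hold
  set.seed(8)
  pre <- image_stack(matrix(100, 32, 32), 80)
  post <- image_stack(matrix(rnorm(32^2, 90, 20), 32, 32), 80)
  roi <- matrix(TRUE, 32, 32)
  counts <- vapply(c(95, 80, 60, 40, 20), function(thr) {
    vascularized_area(pre, post, roi, hypo_threshold = thr)$included_voxel_count
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("histogram normalization matches closed forms", {
  # outside: half at mu - a, half at mu + a with sample SD exactly 10
  n_out <- 200
  a <- 10 * sqrt((n_out - 1) / n_out)
  outside_vals <- rep(c(100 - a, 100 + a), n_out / 2)
  # tumor: 70% at 100, 30% darkened by 3 SD -> summary -0.9
  tumor_vals <- c(rep(100, 70), rep(100 - 30, 30))
  v <- matrix(0, 10, 30)
  v[1:10, 1:20] <- outside_vals
  v[1:10, 21:30] <- tumor_vals
  outside_roi <- matrix(FALSE, 10, 30); outside_roi[, 1:20] <- TRUE
  tumor_roi <- matrix(FALSE, 10, 30); tumor_roi[, 21:30] <- TRUE
  hn <- histogram_normalize(image_stack(v, 80), tumor_roi, outside_roi)
  expect_equal(hn$summary, -0.9, tolerance = 1e-12)
  expect_equal(hn$outside_sd, 10, tolerance = 1e-12)
  expect_length(hn$normalized_values, 100)

  # tumor identical to outside: summary 0
  v2 <- matrix(rep(outside_vals, 2), 10, 40)
  roi_a <- matrix(FALSE, 10, 40); roi_a[, 1:20] <- TRUE
  roi_b <- matrix(FALSE, 10, 40); roi_b[, 21:40] <- TRUE
  expect_equal(histogram_normalize(image_stack(v2, 80), roi_b, roi_a)$summary,
               0, tolerance = 1e-12)

  # tumor shifted down by exactly one SD: summary -1
  v3 <- v2
  v3[, 21:40] <- v3[, 21:40] - 10
  expect_equal(histogram_normalize(image_stack(v3, 80), roi_b, roi_a)$summary,
               -1, tolerance = 1e-12)

  expect_error(histogram_normalize(image_stack(matrix(5, 4, 4), 80),
                                   matrix(c(TRUE, rep(FALSE, 15)), 4, 4),
                                   matrix(c(FALSE, TRUE, rep(FALSE, 14)),
                                          4, 4)),
               "zero SD")
})

test_that("histogram summary is invariant under affine intensity rescaling", {
  set.seed(12)
  v <- matrix(rnorm(40 * 40, 100, 15), 40, 40)
  tumor <- matrix(FALSE, 40, 40); tumor[10:20, 10:20] <- TRUE
  outside <- matrix(FALSE, 40, 40); outside[25:38, 25:38] <- TRUE
  h1 <- histogram_normalize(image_stack(v, 80), tumor, outside)$summary
  h2 <- histogram_normalize(image_stack(3.2 * v + 17, 80), tumor,
                            outside)$summary
  expect_equal(h2, h1, tolerance = 1e-12)
})

test_that("shrinkage report reproduces the CT worked example", {
  shr <- shrinkage_report(c(1.33, 1.05), c(0.79, 0.62))
  expect_equal(shr$length_factor, 1.33 / 0.79, tolerance = 1e-12)
  expect_equal(shr$width_factor, 1.05 / 0.62, tolerance = 1e-12)
  expect_gte(shr$correction_factor, 1.6)
  expect_lte(shr$correction_factor, 1.75)
  expect_true(all(shr$linear_reduction_pct >= 40))
  expect_equal(shr$pre_ratio, 1.33 / 1.05, tolerance = 1e-12)

  # no shrinkage: unit factors, zero reduction
  none <- shrinkage_report(c(1.2, 1.0), c(1.2, 1.0))
  expect_equal(none$correction_factor, 1)
  expect_true(all(none$linear_reduction_pct == 0))

  # isotropic shrink preserves the aspect ratio exactly
  iso <- shrinkage_report(c(1.4, 1.1), 0.6 * c(1.4, 1.1))
  expect_equal(iso$pre_ratio, iso$post_ratio, tolerance = 1e-12)

  expect_error(shrinkage_report(c(1, -1), c(0.5, 0.5)), "positive")
})

test_that("MR-UM correlation is ordinary least squares", {
  # perfectly linear pairs (summary.lm warns on an exact fit; expected)
  x <- 1:6
  fit <- suppressWarnings(correlate_mr_um(x, 2.5 * x - 1))
  expect_equal(fit$r_squared, 1.0)
  expect_equal(fit$slope, 2.5)
  expect_equal(fit$intercept, -1)

  # 3-point hand-OLS example: R^2 = Sxy^2/(Sxx Syy) = 9/(2*14/3) = 27/28
  f3 <- correlate_mr_um(c(1, 2, 3), c(2, 4, 5))
  expect_equal(f3$r_squared, 27 / 28, tolerance = 1e-12)
  # cross-check against the closed-form Pearson correlation
  expect_equal(f3$r_squared, cor(c(1, 2, 3), c(2, 4, 5))^2,
               tolerance = 1e-12)

  # joint permutation of pairs leaves R^2 unchanged
  set.seed(4)
  xs <- rnorm(10); ys <- 2 * xs + rnorm(10, 0, 0.3)
  p <- sample(10)
  expect_equal(correlate_mr_um(xs[p], ys[p])$r_squared,
               correlate_mr_um(xs, ys)$r_squared, tolerance = 1e-12)

  expect_error(correlate_mr_um(1:2, 2:3), "at least 3")
  expect_error(correlate_mr_um(c(1, 1, 1), 1:3), "zero variance")
})
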