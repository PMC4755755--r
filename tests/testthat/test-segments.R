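as_mask <- function(m, spacing = 1) {
  angioquant:::as_vessel_mask(m, rep(spacing, length(dim(m))))
}

skel_from <- function(mask, spacing = 1) {
  structure(list(mask = mask,
                 spacing = rep(spacing, length(dim(mask))),
                 connectivity = if (length(dim(mask)) == 2) 8L else 26L),
            class = "skeleton")
}

test_that("segment lengths follow the Euclidean step metric", {
  # straight 11-pixel horizontal path at 0.5 um spacing -> 5.0 um
  m <- matrix(FALSE, 5, 15)
  m[3, 3:13] <- TRUE
  segs <- split_segments(skel_from(m, 0.5))
  expect_length(segs, 1)
  expect_equal(segs[[1]]$length_um, 5.0)
  expect_equal(segs[[1]]$tortuosity, 1.0)

  # 10-pixel diagonal at 1 um -> 9 * sqrt(2)
  md <- matrix(FALSE, 14, 14)
  for (i in 1:10) md[i + 2, i + 2] <- TRUE
  segs_d <- split_segments(skel_from(md, 1))
  expect_length(segs_d, 1)
  expect_equal(segs_d[[1]]$length_um, 9 * sqrt(2))
})

test_that("branch-point removal splits a plus into four arms", {
  m <- matrix(FALSE, 25, 25)
  m[13, 3:23] <- TRUE
  m[3:23, 13] <- TRUE
  segs <- split_segments(skel_from(m, 1))
  expect_length(segs, 4)
  expect_true(all(vapply(segs, function(s) s$tortuosity, numeric(1)) == 1))
  # arms lose the junction cluster symmetrically
  expect_equal(length(unique(vapply(segs, function(s) s$length_um,
                                    numeric(1)))), 1L)
})

test_that("loops are flagged and excluded from tortuosity", {
  # octagonal ring: every pixel has exactly two 8-neighbors (square-ring
  # corners would create spurious degree-3 pixels via diagonal adjacency)
  m <- matrix(FALSE, 12, 12)
  m[3, 4:8] <- TRUE; m[9, 4:8] <- TRUE
  m[4:8, 3] <- TRUE; m[4:8, 9] <- TRUE
  segs <- split_segments(skel_from(m, 1))
  expect_length(segs, 1)
  expect_true(segs[[1]]$is_loop)
  expect_true(is.na(segs[[1]]$tortuosity))
  expect_error(tortuosity_top_decile(segs), "loops")
})

test_that("length filter implements the mean-minus-SEM rule", {
  segs <- lapply(c(10, 10, 10, 40), make_straight_segment)
  # mean 17.5, SD 15, SEM 7.5 -> threshold 10; only the 40 um segment stays
  kept <- filter_segments_by_length(segs)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$length_um, 40)
  expect_equal(attr(kept, "threshold"), 10)

  # SD spread variant keeps everything above 2.5
  kept_sd <- filter_segments_by_length(segs, spread = "sd")
  expect_length(kept_sd, 4)

  # degenerate: all equal lengths are retained via the tie rule
  eq <- lapply(rep(12, 5), make_straight_segment)
  expect_length(filter_segments_by_length(eq), 5)

  # single segment is kept
  expect_length(filter_segments_by_length(list(make_straight_segment(3))), 1)
  expect_length(filter_segments_by_length(list()), 0)
})

test_that("radii come from exact distances to the background", {
  # 7-px-tall band: center-row radius 4 um (background at rows 1 and 9)
  m <- matrix(FALSE, 9, 30)
  m[2:8, ] <- TRUE
  seg <- make_path_segment(cbind(rep(5, 20), 6:25))
  seg <- compute_segment_radii(seg, as_mask(m))
  expect_true(all(seg$radii_um == 4))
  expect_equal(seg$mean_radius_um, 4)

  # 1-px line: radius 1 everywhere
  ml <- matrix(FALSE, 5, 20)
  ml[3, 2:19] <- TRUE
  segl <- make_path_segment(cbind(rep(3, 18), 2:19))
  segl <- compute_segment_radii(segl, as_mask(ml))
  expect_true(all(segl$radii_um == 1))

  # half-pixel correction subtracts 0.5 px
  segc <- compute_segment_radii(make_path_segment(cbind(rep(5, 20), 6:25)),
                                as_mask(m), half_pixel_correction = TRUE)
  expect_true(all(segc$radii_um == 3.5))

  expect_error(distance_transform(array(TRUE, c(4, 4)), 1), "background")
})

test_that("distance transform equals the brute-force scan exactly", {
  for (seed in 1:6) {
    set.seed(seed)
    m <- matrix(runif(32 * 32) > 0.6, 32, 32)
    sp <- c(1, sample(c(0.5, 1, 2), 1))
    expect_equal(distance_transform(m, sp), brute_force_edt(m, sp),
                 tolerance = 1e-12)
  }
  for (seed in 1:3) {
    set.seed(100 + seed)
    a <- array(runif(16^3) > 0.7, c(16, 16, 16))
    sp <- c(1, 1, sample(c(1, 2.5), 1))
    expect_equal(distance_transform(a, sp), brute_force_edt(a, sp),
                 tolerance = 1e-12)
  }
})

test_that("dilating the mask never decreases any radius", {
  for (seed in 1:3) {
    set.seed(seed)
    m <- matrix(runif(24 * 24) > 0.65, 24, 24)
    if (!any(m)) next
    dil <- m
    dil[-1, ] <- dil[-1, ] | m[-24, ]
    dil[, -1] <- dil[, -1] | m[, -24]
    if (all(dil)) next
    d1 <- distance_transform(m, 1)
    d2 <- distance_transform(dil, 1)
    expect_true(all(d2[m] >= d1[m]))
  }
})

test_that("overall mean radius is a mean of per-segment means", {
  s1 <- make_straight_segment(4); s1$mean_radius_um <- 2
  s2 <- make_straight_segment(5); s2$mean_radius_um <- 4
  expect_equal(overall_mean_radius(list(s1, s2)), 3)
  expect_equal(overall_mean_radius(list(s1)), 2)
  expect_error(overall_mean_radius(list()), "undefined")

  # unequal pixel counts: mean of means differs from the pooled mean
  s3 <- make_straight_segment(2); s3$radii_um <- rep(1, 3)
  s4 <- make_straight_segment(10); s4$radii_um <- rep(4, 11)
  s5 <- make_straight_segment(4); s5$radii_um <- rep(2.5, 5)
  segs <- lapply(list(s3, s4, s5), function(s) {
    s$mean_radius_um <- mean(s$radii_um); s
  })
  expect_equal(overall_mean_radius(segs), mean(c(1, 4, 2.5)))
  pooled <- mean(unlist(lapply(segs, function(s) s$radii_um)))
  expect_false(isTRUE(all.equal(overall_mean_radius(segs), pooled)))
})

test_that("r~ is invariant under relabeling and path reversal", {
  set.seed(3)
  m <- random_blob_mask(c(40, 40), 9)
  sk <- skeletonize_mask(m, 1)
  segs <- split_segments(sk)
  segs <- compute_segment_radii(segs, as_mask(m))
  r1 <- overall_mean_radius(segs)
  rev_segs <- lapply(rev(segs), function(s) {
    s$path <- s$path[rev(seq_len(nrow(s$path))), , drop = FALSE]
    s$radii_um <- rev(s$radii_um)
    s
  })
  expect_equal(overall_mean_radius(rev_segs), r1)
})

test_that("tortuosity statistics follow the arc/chord definition", {
  # straight segment: exactly 1
  expect_equal(make_straight_segment(25)$tortuosity, 1.0)

  # quarter circle of radius 50 um sampled at 0.5 um arc steps
  n_pts <- ceiling(50 * pi / 2 / 0.5)
  th <- seq(0, pi / 2, length.out = n_pts)
  arc <- make_path_segment(cbind(50 * cos(th) + 60, 50 * sin(th) + 60))
  expect_lt(abs(arc$tortuosity - pi / (2 * sqrt(2))) / (pi / (2 * sqrt(2))),
            0.02)

  # ceiling rule: 15 segments -> the 2 longest enter the mean
  segs <- lapply(5:19, make_straight_segment)
  segs[[15]]$tortuosity <- 1.5
  segs[[14]]$tortuosity <- 1.3
  expect_equal(tortuosity_top_decile(segs), 1.4)
})

test_that("tortuosity is 1 iff the path is collinear", {
  set.seed(11)
  for (rep in 1:10) {
    dir <- c(sample(-1:1, 1), sample(c(1, 1, 2), 1))
    n <- sample(5:25, 1)
    path <- cbind(10 + dir[1] * (0:n), 10 + dir[2] * (0:n))
    expect_equal(make_path_segment(path)$tortuosity, 1.0, tolerance = 1e-9)
  }
  bent <- rbind(cbind(5, 1:10), cbind(6:14, 10))
  expect_gt(make_path_segment(bent)$tortuosity, 1 + 1e-9)
})

test_that("vessel density is the ROI fraction covered", {
  m <- matrix(FALSE, 10, 10)
  m[, 1:5] <- TRUE
  roi <- matrix(TRUE, 10, 10)
  expect_equal(vessel_density(m, roi), 0.5)
  expect_equal(vessel_density(matrix(FALSE, 10, 10), roi), 0)
  expect_error(vessel_density(m, matrix(FALSE, 10, 10)), "empty roi")
  expect_error(vessel_density(m, matrix(TRUE, 5, 5)), "shape")
})
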