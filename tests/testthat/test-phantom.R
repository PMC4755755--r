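test_that("phantom generation is bit-reproducible from seed + spec", {
  spec <- phantom_spec(shape = c(64, 64, 32), pixel_size = 5, n_vessels = 5,
                       radius_range = c(10, 25), tortuosity_target = 1.1,
                       noise_sd = 4, seed = 7)
  a <- generate_tube_network(spec)
  b <- generate_tube_network(spec)
  expect_identical(a$stack$values, b$stack$values)
  expect_identical(a$truth, b$truth)
  # different seed changes the output
  spec2 <- phantom_spec(shape = c(64, 64, 32), pixel_size = 5, n_vessels = 5,
                        radius_range = c(10, 25), tortuosity_target = 1.1,
                        noise_sd = 4, seed = 8)
  expect_false(identical(generate_tube_network(spec2)$stack$values,
                         a$stack$values))
})

test_that("a straight-line phantom has tortuosity exactly 1", {
  spec <- phantom_spec(shape = c(48, 48, 24), pixel_size = 5, n_vessels = 1,
                       radius_range = c(15, 15), tortuosity_target = 1,
                       noise_sd = 0, seed = 2)
  ph <- generate_tube_network(spec)
  expect_equal(ph$truth$per_vessel_tortuosity, 1.0, tolerance = 1e-9)
})

test_that("noiseless phantoms are exactly two-level and truth is exact", {
  spec <- phantom_spec(shape = c(64, 64), pixel_size = 5, n_vessels = 3,
                       radius_range = c(8, 16), tortuosity_target = 1.05,
                       noise_sd = 0, background_level = 10,
                       vessel_level = 100, seed = 4)
  ph <- generate_tube_network(spec)
  expect_setequal(unique(as.vector(ph$stack$values)), c(10, 100))
  # truth density equals the rendered-mask fraction exactly
  expect_identical(ph$truth$density, mean(ph$truth$mask))
  expect_identical(ph$stack$values == 100, ph$truth$mask)
  expect_true(all(ph$truth$per_vessel_tortuosity >= 1))
})

test_that("tortuosity targets are hit within 5%", {
  spec <- phantom_spec(shape = c(96, 96, 48), pixel_size = 5, n_vessels = 4,
                       radius_range = c(10, 15), tortuosity_target = 1.2,
                       noise_sd = 0, seed = 9)
  ph <- generate_tube_network(spec)
  expect_true(all(abs(ph$truth$per_vessel_tortuosity - 1.2) / 1.2 <= 0.05))
})

test_that("impossible density targets fail explicitly", {
  expect_error(generate_tube_network(
    phantom_spec(shape = c(64, 64, 32), pixel_size = 5, n_vessels = 1,
                 radius_range = c(5, 6), tortuosity_target = 1,
                 target_density = 0.8, noise_sd = 0, seed = 1)),
    "impossible density")
})

test_that("phantom_spec rejects invalid parameters", {
  expect_error(phantom_spec(radius_range = c(0.5, 3), pixel_size = 5),
               "at least 1 pixel")
  expect_error(phantom_spec(tortuosity_target = 0.8), ">= 1")
  expect_error(phantom_spec(branching_prob = 1.5), "\\[0, 1\\]")
  expect_error(phantom_spec(target_density = 1.2), "\\[0, 1\\]")
})

test_that("branching spawns extra child vessels", {
  spec <- phantom_spec(shape = c(96, 96, 48), pixel_size = 5, n_vessels = 3,
                       radius_range = c(10, 15), tortuosity_target = 1.05,
                       branching_prob = 0.05, noise_sd = 0, seed = 21)
  ph <- generate_tube_network(spec)
  expect_gt(ph$truth$n_branches, 0)
  expect_length(ph$truth$centerlines_um, 3 + ph$truth$n_branches)
})

test_that("T2* pair: vessels post-only, microbleeds in both, sets disjoint", {
  spec <- phantom_spec(shape = c(64, 64, 32), pixel_size = 5, n_vessels = 3,
                       radius_range = c(10, 15), tortuosity_target = 1.05,
                       noise_sd = 0, background_level = 100,
                       vessel_level = 20, seed = 3)
  pp <- generate_t2star_pair(spec, n_microbleeds = 2)
  expect_false(any(pp$truth$vessel_mask & pp$truth$microbleed_mask))
  thr <- 60
  hypo_post <- pp$post$values < thr
  hypo_pre <- pp$pre$values < thr
  # post-only hypointensities are exactly the vessel voxels
  expect_identical(hypo_post & !hypo_pre, pp$truth$vessel_mask)
  # pre hypointensities are exactly the microbleed voxels
  expect_identical(hypo_pre, pp$truth$microbleed_mask)
  expect_equal(pp$truth$density, mean(pp$truth$vessel_mask))

  # no microbleeds: pre is uniform background
  pp0 <- generate_t2star_pair(spec, n_microbleeds = 0)
  expect_true(all(pp0$pre$values == 100))
})

test_that("DCE series: zero transfer gives identical ROIs; SR >= 1 noiseless", {
  aif <- aif_biexponential(t0 = 60)
  s0 <- generate_dce_series(dce_sim_params(K_trans = 0, noise_sd = 0), aif)
  expect_identical(s0$tumor_signal, s0$contralateral_signal)
  s1 <- generate_dce_series(dce_sim_params(K_trans = 0.08, v_e = 0.25,
                                           noise_sd = 0), aif)
  expect_true(all(s1$tumor_signal / s1$contralateral_signal >= 1))
  # determinism under seed
  s2 <- generate_dce_series(dce_sim_params(K_trans = 0.08, v_e = 0.25,
                                           noise_sd = 3, seed = 5), aif)
  s3 <- generate_dce_series(dce_sim_params(K_trans = 0.08, v_e = 0.25,
                                           noise_sd = 3, seed = 5), aif)
  expect_identical(s2$tumor_signal, s3$tumor_signal)
})

test_that("phantom truth export writes consistent tables", {
  spec <- phantom_spec(shape = c(48, 48), pixel_size = 5, n_vessels = 2,
                       radius_range = c(8, 12), tortuosity_target = 1.05,
                       noise_sd = 0, seed = 6)
  ph <- generate_tube_network(spec)
  csv <- file.path(tempdir(), "truth.csv")
  js <- file.path(tempdir(), "truth.json")
  df <- write_phantom_truth(ph$truth, json_path = js, csv_path = csv)
  back <- read.csv(csv)
  expect_equal(back$tortuosity, df$tortuosity, tolerance = 1e-12)
  expect_equal(jsonlite::read_json(js)$density, ph$truth$density)
  unlink(c(csv, js))
})
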