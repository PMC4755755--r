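aif0 <- aif_biexponential(t0 = 60)
times0 <- seq(0, 598, by = 2)

test_that("tofts_forward degenerate and analytic cases", {
  expect_equal(tofts_forward(0, 0.2, aif0, times0), numeric(300))
  expect_error(tofts_forward(0.1, 0, aif0, times0), "v_e")
  expect_error(tofts_forward(-0.1, 0.2, aif0, times0), "K_trans")

  # impulse input: pure exponential washout from t0
  imp <- aif_impulse(t0 = 30, area = 2)
  ct <- tofts_forward(0.1, 0.25, imp, times0)
  tau <- pmax(times0 / 60 - 0.5, 0)
  expected <- ifelse(times0 / 60 < 0.5, 0, 0.1 * 2 * exp(-0.4 * tau))
  expect_equal(ct, expected, tolerance = 1e-12)
})

test_that("tofts_forward matches a fine trapezoid quadrature oracle", {
  for (p in list(c(0.1, 0.3), c(0.05, 0.2), c(0.2, 0.4))) {
    mine <- tofts_forward(p[1], p[2], aif0, times0)
    oracle <- trapz_tofts(p[1], p[2], biexp_cp(t0_min = 1), times0 / 60)
    expect_lt(max(abs(mine - oracle)) / max(oracle), 1e-5)
  }
  # sampled-AIF numerical path agrees with the analytic biexponential path
  samp <- aif_sampled(seq(0, 598, by = 1),
                      aif_eval(aif0, seq(0, 598, by = 1) / 60))
  mine_num <- tofts_forward(0.1, 0.3, samp, times0)
  mine_ana <- tofts_forward(0.1, 0.3, aif0, times0)
  # 1 s sampling linearizes the discontinuous bolus arrival, so agreement
  # is limited by the kink, not by the convolution scheme
  expect_lt(max(abs(mine_num - mine_ana)) / max(mine_ana), 0.01)
})

test_that("forward model is linear in the input function but not in K_trans", {
  doubled <- aif_biexponential(a1 = 2 * 0.798, a2 = 2 * 0.956, t0 = 60)
  c1 <- tofts_forward(0.08, 0.3, aif0, times0)
  c2 <- tofts_forward(0.08, 0.3, doubled, times0)
  expect_equal(c2, 2 * c1, tolerance = 1e-12)
  # doubling K_trans at fixed v_e changes k_ep, so the curve does not double
  c3 <- tofts_forward(0.16, 0.3, aif0, times0)
  expect_gt(max(abs(c3 - 2 * c1)) / max(c1), 0.01)
})

test_that("noiseless round trip recovers the parameters within 1%", {
  for (k in c(0.02, 0.1)) {
    for (ve in c(0.15, 0.4)) {
      ct <- tofts_forward(k, ve, aif0, times0)
      f <- fit_tofts(ct, aif0, times0)
      expect_true(f$converged)
      expect_lt(abs(f$K_trans - k) / k, 0.01)
      expect_lt(abs(f$v_e - ve) / ve, 0.01)
      expect_equal(f$k_ep, f$K_trans / f$v_e)
    }
  }
})

test_that("flat curves yield K_trans 0 with v_e flagged at its bound", {
  f <- fit_tofts(numeric(300), aif0, times0)
  expect_equal(f$K_trans, 0)
  expect_false(f$identifiable)
  expect_true(f$converged)
})

test_that("noisy fits stay within 10% median error at SNR 20", {
  # SNR defined against the peak signal enhancement of the true curve
  peak <- 50 * max(tofts_forward(0.05, 0.2, aif0, times0))
  errs <- vapply(1:30, function(i) {
    ser <- generate_dce_series(
      dce_sim_params(K_trans = 0.05, v_e = 0.2, noise_sd = peak / 20,
                     seed = i), aif0)
    conc <- (ser$tumor_signal - 100) / 50
    f <- fit_tofts(conc, aif0, ser$times_s)
    abs(f$K_trans - 0.05) / 0.05
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("ktrans_map recovers a two-level pattern and handles edge cases", {
  truth <- matrix(0, 8, 8)
  truth[, 5:8] <- 0.05
  sim <- simulate_dce_volume(truth, aif = aif0)
  km <- ktrans_map(sim$volume, sim$times_s, aif0, signal_to_conc = 50)
  expect_equal(km$n_nonconverged, 0)
  expect_lt(max(abs(km$k_trans$values[, 5:8] - 0.05)) / 0.05, 0.10)
  expect_true(all(km$k_trans$values[, 1:4] < 0.005))

  # all-baseline volume maps to zero everywhere
  flat <- array(100, c(4, 4, 300))
  km0 <- ktrans_map(flat, times0, aif0, signal_to_conc = 50)
  expect_true(all(km0$k_trans$values == 0))

  # single-voxel map equals a direct fit of that curve
  one <- array(sim$volume[1, 8, ], c(1, 1, 300))
  km1 <- ktrans_map(one, times0, aif0, signal_to_conc = 50)
  conc <- (sim$volume[1, 8, ] - mean(sim$volume[1, 8, times0 < 60])) / 50
  direct <- fit_tofts(conc, aif0, times0)
  expect_equal(km1$k_trans$values[1, 1], direct$K_trans)

  expect_error(ktrans_map(sim$volume, times0, aif_biexponential(t0 = 0),
                          signal_to_conc = 50), "baseline")
})

test_that("bbbd score follows the signal-ratio definition", {
  t_s <- seq(0, 118, by = 2)
  flat <- list(times_s = t_s, tumor_signal = rep(100, 60),
               contralateral_signal = rep(100, 60))
  expect_equal(bbbd_score(flat)$score, 0)
  expect_true(all(bbbd_score(flat)$sr_curve == 1))

  ratio <- list(times_s = t_s, tumor_signal = rep(120, 60),
                contralateral_signal = rep(100, 60))
  expect_equal(bbbd_score(ratio)$score, 0.2)

  bad <- list(times_s = t_s, tumor_signal = rep(1, 60),
              contralateral_signal = c(rep(100, 59), 0))
  expect_error(bbbd_score(bad), "contralateral")
})

test_that("bbbd score is invariant to a common gain and increases in K_trans", {
  ser <- generate_dce_series(dce_sim_params(K_trans = 0.05, v_e = 0.2,
                                            noise_sd = 0), aif0)
  g <- ser
  g$tumor_signal <- 3.7 * g$tumor_signal
  g$contralateral_signal <- 3.7 * g$contralateral_signal
  expect_equal(bbbd_score(g)$score, bbbd_score(ser)$score, tolerance = 1e-12)

  scores <- vapply(c(0, 0.02, 0.05, 0.1), function(k) {
    s <- generate_dce_series(dce_sim_params(K_trans = k, v_e = 0.2,
                                            noise_sd = 0), aif0)
    bbbd_score(s)$score
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
})
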