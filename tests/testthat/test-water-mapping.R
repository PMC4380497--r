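# Helper: build a synthetic flip-angle series volume from a b1t value map.
b1_series_from <- function(b_map, angles = c(30, 60, 90, 120), amp = 50) {
  dm <- dim(b_map)
  out <- array(0, c(dm, length(angles)))
  for (k in seq_along(angles))
    out[, , , k] <- amp * sin(b_map * angles[k] * pi / 180)
  out
}

test_that("transmit field fit recovers exact and scaled flip-angle maps", {
  dm <- c(12, 12, 12)
  mask <- array(TRUE, dm)

  # b = 1 everywhere: raw fit exact to 1e-6 before smoothing
  fit1 <- estimate_b1t(b1_series_from(array(1, dm)), c(30, 60, 90, 120), mask)
  expect_equal(fit1$b1t_raw, array(1, dm), tolerance = 1e-6)

  # signals proportional to sin(1.1 alpha)
  fit2 <- estimate_b1t(b1_series_from(array(1.1, dm)), c(30, 60, 90, 120),
                       mask)
  expect_equal(fit2$b1t_raw, array(1.1, dm), tolerance = 1e-3)

  # all-zero series: flagged and set to 1
  z <- array(0, c(dm, 4))
  fitz <- estimate_b1t(z, c(30, 60, 90, 120), mask)
  expect_true(all(fitz$b1t_raw == 1))
  expect_true(all(fitz$flagged))

  expect_error(estimate_b1t(z[, , , 1:2], c(30, 60), mask), "3 flip angles")
})

test_that("transmit field and T1 fits match independent 1-D optimizers on
           random noiseless voxels", {
  set.seed(202)
  angles <- c(30, 60, 90, 120)
  b_true <- runif(100, 0.75, 1.3)
  t1_true <- runif(100, 400, 4500)

  # B1+: brute-force RSS minimization via optimize() as oracle
  b_map <- array(1, c(100, 1, 1)); b_map[, 1, 1] <- b_true
  series <- b1_series_from(b_map, angles)
  fit <- estimate_b1t(series, angles, array(TRUE, c(100, 1, 1)))
  for (i in seq_len(100)) {
    oracle <- oracle_b1_fit(series[i, 1, 1, ], angles)
    expect_equal(fit$b1t_raw[i, 1, 1], oracle, tolerance = 1e-3)
    expect_equal(fit$b1t_raw[i, 1, 1], b_true[i], tolerance = 1e-3)
  }

  # T1: forward-evaluate the scan ratio, invert, compare to truth
  pd <- array(oracle_sat(1800, 40, t1_true), c(100, 1, 1))
  t1s <- array(oracle_sat(500, 90, t1_true), c(100, 1, 1))
  tf <- estimate_t1(pd, t1s, array(1, c(100, 1, 1)),
                    array(TRUE, c(100, 1, 1)))
  expect_lt(max(abs(tf$t1[, 1, 1] - t1_true)), 1)
})

test_that("T1 inversion reproduces the closed-form ratio example", {
  # R(1000) = 0.61436 / 0.39347 = 1.5614 (independent saturation oracle)
  r <- oracle_sat(1800, 40, 1000) / oracle_sat(500, 90, 1000)
  expect_equal(r, 1.5614, tolerance = 1e-4)
  pd <- array(r, c(4, 4, 4)); t1s <- array(1, c(4, 4, 4))
  fit <- estimate_t1(pd, t1s, array(1, c(4, 4, 4)), array(TRUE, c(4, 4, 4)))
  expect_equal(fit$t1[1, 1, 1], 1000, tolerance = 1)

  # supplying the correct b1t makes the estimate flip-angle invariant
  b <- 1.1
  pd_b <- array(oracle_sat(1800, 40 * b, 1000), c(4, 4, 4))
  t1_b <- array(oracle_sat(500, 90 * b, 1000), c(4, 4, 4))
  fit_b <- estimate_t1(pd_b, t1_b, array(b, c(4, 4, 4)),
                       array(TRUE, c(4, 4, 4)))
  expect_equal(fit_b$t1[2, 2, 2], fit$t1[2, 2, 2], tolerance = 1)

  # out-of-range ratios clamp to the bracket end and are flagged
  fit_hi <- estimate_t1(array(100, c(4, 4, 4)), t1s, array(1, c(4, 4, 4)),
                        array(TRUE, c(4, 4, 4)))
  expect_true(all(fit_hi$t1 == 6000))
  expect_true(all(fit_hi$flagged))
})

test_that("T1 from a noiseless simulated CSF voxel round-trips to 4000 ms", {
  ph <- small_phantom()
  acq <- noiseless_acq()
  fit <- estimate_t1(acq$pd_scan, acq$t1_scan,
                     array(small_fields()$b1t, dim(ph$labels)),
                     ph$brain_mask)
  csf <- ph$labels == 3
  expect_lt(max(abs(fit$t1[csf] - 4000)), 5)
  wm <- ph$labels == 1
  expect_lt(max(abs(fit$t1[wm] - 900)), 2)
})

test_that("T2* log-linear fit is exact on noiseless decays", {
  dm <- c(6, 6, 6)
  te <- 2.3 + (0:7) * 2.27
  mask <- array(TRUE, dm)
  me <- array(0, c(dm, 8))
  for (e in 1:8) me[, , , e] <- 120 * exp(-te[e] / 50)
  fit <- estimate_t2star(me, te, mask)
  expect_equal(fit$t2star, array(50, dm), tolerance = 0.01)
  # s0 / S(TE1) = exp(TE1 / T2*) = 1.0471
  expect_equal(fit$s0[1, 1, 1] / me[1, 1, 1, 1], exp(2.3 / 50),
               tolerance = 1e-9)
  expect_equal(fit$s0[1, 1, 1] / me[1, 1, 1, 1], 1.0471, tolerance = 1e-4)

  # zero decay: capped at the configured maximum
  flat <- array(7, c(dm, 8))
  expect_true(all(estimate_t2star(flat, te, mask)$t2star == 2000))

  # non-positive echoes: positive prefix used when >= 3 echoes remain
  me2 <- me
  me2[, , , 4:8] <- 0
  fit2 <- estimate_t2star(me2, te, mask)
  expect_equal(fit2$t2star[2, 2, 2], 50, tolerance = 0.01)
  expect_false(any(fit2$flagged))
  me3 <- me
  me3[, , , 3:8] <- -1
  fit3 <- estimate_t2star(me3, te, mask)
  expect_true(all(fit3$flagged))
  expect_true(all(fit3$t2star == 50))  # config default for flagged voxels
})

test_that("PD correction inverts the forward model and cancels fields", {
  ph <- small_phantom()
  dm <- dim(ph$labels)
  acq <- simulate_protocol(ph, flat_fields(), default_protocol(noise_sd = 0),
                           seed = 1)
  ones <- array(1, dm)
  pc <- correct_pd(acq$pd_scan, ph$truth$t2star, ph$truth$t1, ones, ones,
                   ph$brain_mask)
  ratio <- pc$pd_corrected[ph$brain_mask] / ph$truth$water[ph$brain_mask]
  expect_lt(sd(ratio) / mean(ratio), 1e-4)

  # receive-field doubling in a region cancels exactly when b1r_hat is exact
  b1r <- ones; b1r[1:24, , ] <- 2
  fl2 <- structure(list(b1t = ones, b1r = b1r), class = "field_maps")
  acq2 <- simulate_protocol(ph, fl2, default_protocol(noise_sd = 0), seed = 1)
  pc2 <- correct_pd(acq2$pd_scan, ph$truth$t2star, ph$truth$t1, ones, b1r,
                    ph$brain_mask)
  expect_equal(pc2$pd_corrected[ph$brain_mask], pc$pd_corrected[ph$brain_mask],
               tolerance = 1e-9)

  # omitting the T1-saturation correction underestimates CSF by the
  # TR = 1800 ms saturation factor at T1 = 4000 (the flip-angle term is
  # still applied, so the ratio is f / sin(alpha))
  pc3 <- correct_pd(acq$pd_scan, ph$truth$t2star, ph$truth$t1, ones, ones,
                    ph$brain_mask, apply_t1 = FALSE)
  csf <- ph$labels == 3
  sat_only <- oracle_sat(1800, 40, 4000) / sin(40 * pi / 180)
  expect_equal(mean(pc3$pd_corrected[csf] / pc$pd_corrected[csf]),
               sat_only, tolerance = 1e-6)
  expect_equal(sat_only, 0.7084, tolerance = 1e-4)
})

test_that("receive field estimation is accurate and normalized", {
  ph <- small_phantom()
  fl <- small_fields()
  acq <- noiseless_acq()
  fit <- estimate_receive_field(acq$recv_body, acq$recv_array, ph$brain_mask)
  expect_lt(max(abs(fit$b1r[ph$brain_mask] - fl$b1r[ph$brain_mask])), 0.01)
  expect_equal(mean(fit$b1r[ph$brain_mask]), 1, tolerance = 1e-12)
  expect_error(estimate_receive_field(acq$recv_body, acq$recv_array,
                                      array(FALSE, dim(acq$recv_body))),
               "empty brain mask")
})

test_that("residual bias removal is near-identity on clean maps and
           suppresses smooth multiplicative perturbations", {
  ph <- small_phantom()
  map <- ph$truth$water
  out <- remove_residual_bias(map, ph$brain_mask)
  rel <- abs(out$map[ph$brain_mask] - map[ph$brain_mask]) / map[ph$brain_mask]
  expect_lt(max(rel), 0.002)

  # a smooth multiplicative field of amplitude 0.1 is mostly divided out;
  # run at the acceptance scale (64^3), where the brain spans the 60 mm
  # estimation kernel
  ph64 <- make_phantom(c(64, 64, 64))
  map64 <- ph64$truth$water
  out64 <- remove_residual_bias(map64, ph64$brain_mask)
  pert <- make_fields(dim(map64), amplitude = 0.1, smoothness_mm = 40,
                      seed = 31, mask = ph64$brain_mask)$b1t
  out2 <- remove_residual_bias(map64 * pert, ph64$brain_mask)
  rel2 <- abs(out2$map[ph64$brain_mask] - out64$map[ph64$brain_mask]) /
    out64$map[ph64$brain_mask]
  expect_lt(mean(rel2), 0.01)
})

test_that("CSF normalization pins the ventricular mean at exactly 100", {
  ph <- small_phantom()
  chain <- noiseless_chain()
  expect_equal(mean(chain$water_map[chain$csf_mask]), 100)
  # error names the mask when it is too small
  expect_error(normalize_to_csf(ph$truth$water,
                                array(FALSE, dim(ph$labels))),
               "ventricle_mask")
})

test_that("full noiseless chain recovers the phantom ground truth", {
  ph <- small_phantom()
  chain <- noiseless_chain()
  expect_identical(chain$applied_steps,
                   c("b1_transmit", "t2star", "t1_saturation",
                     "residual_bias", "csf_normalization"))
  for (lbl in 1:3) {
    truth <- c(71.46, 82.93, 100)[lbl]
    sel <- ph$labels == lbl & !chain$exclude_mask
    expect_lt(abs(mean(chain$water_map[sel]) - truth), 0.2)
  }
})

test_that("water map is invariant under a global scanner gain", {
  ph <- small_phantom()
  acq2 <- simulate_protocol(ph, small_fields(),
                            default_protocol(noise_sd = 0), seed = 1,
                            gain = 2)
  chain2 <- map_water(acq2, ph$ventricle_mask)
  expect_identical(chain2$water_map, noiseless_chain()$water_map)
})

test_that("ablating individual corrections biases the map as physics
           predicts", {
  ph <- small_phantom()
  full <- noiseless_chain()
  wm <- ph$labels == 1; gm <- ph$labels == 2
  wm_full <- mean(full$water_map[wm]); gm_full <- mean(full$water_map[gm])

  # no T2* compensation: short-T2* tissue is depressed
  no_t2s <- map_water(noiseless_acq(), ph$ventricle_mask,
                      disable_steps = "t2star")
  expect_lt(mean(no_t2s$water_map[wm]), wm_full - 1)

  # no T1-saturation correction: CSF (long T1) is underestimated relative
  # to tissue, so CSF-normalized tissue values inflate
  no_t1 <- map_water(noiseless_acq(), ph$ventricle_mask,
                     disable_steps = "t1_saturation")
  expect_gt(mean(no_t1$water_map[wm]), wm_full + 5)

  # disabling T2* and T1 corrections shrinks the WM-GM contrast
  no_both <- map_water(noiseless_acq(), ph$ventricle_mask,
                       disable_steps = c("t2star", "t1_saturation"))
  contrast_full <- gm_full - wm_full
  contrast_abl <- mean(no_both$water_map[gm]) - mean(no_both$water_map[wm])
  expect_lt(abs(contrast_abl), abs(contrast_full))

  expect_error(map_water(noiseless_acq(), ph$ventricle_mask,
                         disable_steps = "csf_normalization"),
               "unknown steps")
})

test_that("SNR-50 chain meets the parameter recovery error budget", {
  ph <- small_phantom()
  fl <- small_fields()
  chain <- noisy_chain()

  # transmit field: median absolute error below 0.02 over the brain
  expect_lt(median(abs(chain$b1t_hat[ph$brain_mask] -
                       fl$b1t[ph$brain_mask])), 0.02)

  # voxelwise water RMSE < 2 percentage points in pure-tissue voxels
  for (lbl in 1:2) {
    sel <- ph$labels == lbl & !chain$exclude_mask
    err <- chain$water_map[sel] - ph$truth$water[sel]
    expect_lt(sqrt(mean(err^2)), 2)
  }

  # tissue-mean bias < 0.3 points, averaged over seeded replicates (the
  # single-run tissue mean carries the CSF-reference sampling noise)
  more <- lapply(c(22, 23, 24), function(s) {
    acq <- simulate_protocol(ph, fl, default_protocol(noise_sd = 0.02),
                             seed = s)
    map_water(acq, ph$ventricle_mask)$water_map
  })
  for (lbl in 1:2) {
    sel <- ph$labels == lbl
    biases <- vapply(c(list(chain$water_map), more), function(w)
      mean(w[sel] - ph$truth$water[sel]), numeric(1))
    expect_lt(abs(mean(biases)), 0.3)
  }
})
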