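#' Estimate the transmit field (B1+) from a multi-flip-angle series
#'
#' Per voxel, fits the saturation-free model `S(alpha) = A * sin(b * alpha)`
#' over the relative flip-angle scale `b` by least squares: for fixed `b` the
#' amplitude `A` is profiled out analytically, and `b` is located by a coarse
#' grid search over `b_range` followed by two quadratic refinement passes.
#' The raw map is then smoothed with a wide Gaussian kernel inside the brain
#' mask, since the transmit field is physically smooth.
#'
#' @param b1_series 4-D array (x, y, z, angle).
#' @param angles_deg nominal flip angles (>= 3).
#' @param brain_mask logical array; only brain voxels are fitted.
#' @param b_range search interval for `b`.
#' @param grid_step coarse grid step.
#' @param smooth_fwhm_mm FWHM of the post-fit smoothing kernel (mm).
#' @param voxel_mm voxel size (mm).
#' @return list with `b1t` (smoothed map, 1 outside brain), `b1t_raw`
#'   (pre-smoothing fit) and `flagged` (logical array; all-zero voxel series
#'   are set to `b = 1` and flagged).
#' @export
estimate_b1t <- function(b1_series, angles_deg, brain_mask,
                         b_range = c(0.3, 1.7), grid_step = 0.005,
                         smooth_fwhm_mm = 4, voxel_mm = c(1, 1, 1)) {
  check_that(length(angles_deg) >= 3, "need at least 3 flip angles")
  dm <- dim(b1_series)[1:3]
  idx <- which(brain_mask)
  nv <- length(idx)
  S <- matrix(0, nv, length(angles_deg))
  for (k in seq_along(angles_deg)) S[, k] <- b1_series[, , , k][idx]
  a_rad <- angles_deg * pi / 180

  qeval <- function(bvec) {
    sinb <- sin(outer(bvec, a_rad))
    num <- rowSums(S * sinb)
    s2 <- rowSums(sinb * sinb)
    num * num / s2
  }

  grid <- seq(b_range[1], b_range[2], by = grid_step)
  best_q <- rep(-Inf, nv); best_b <- rep(1, nv)
  for (b in grid) {
    sinb <- sin(b * a_rad)
    s2 <- sum(sinb * sinb)
    num <- as.vector(S %*% sinb)
    q <- num * num / s2
    upd <- q > best_q
    best_q[upd] <- q[upd]; best_b[upd] <- b
  }
  # Two quadratic (parabolic-vertex) refinement passes around the grid max.
  refine <- function(b0, h) {
    qm <- qeval(pmax(b_range[1], b0 - h))
    q0 <- qeval(b0)
    qp <- qeval(pmin(b_range[2], b0 + h))
    den <- qm - 2 * q0 + qp
    step <- ifelse(abs(den) > 0, 0.5 * h * (qm - qp) / den, 0)
    pmin(b_range[2], pmax(b_range[1], b0 + pmax(-h, pmin(h, step))))
  }
  b_hat <- refine(best_b, grid_step)
  b_hat <- refine(b_hat, 5e-4)

  dead <- rowSums(abs(S)) == 0
  b_hat[dead] <- 1

  raw <- array(1, dm)
  raw[idx] <- b_hat
  flagged <- array(FALSE, dm)
  flagged[idx] <- dead
  smoothed <- gaussian_smooth(raw, smooth_fwhm_mm, voxel_mm, mask = brain_mask)
  list(b1t = smoothed, b1t_raw = raw, flagged = flagged)
}

#' Estimate T2* and the TE=0 intercept from a multi-echo series
#'
#' Per voxel log-linear regression of the signal on echo time. The fit is
#' parameterized on `log(S_e / S_1)` (relative to the first echo), which
#' makes the estimate exactly invariant under any global scanner gain;
#' `s0_hat` is recovered as `S_1 * exp(TE_1 / t2star_hat)` equivalent via the
#' fitted intercept. Voxels with a non-positive echo are fitted on their
#' positive prefix when it has at least `min_echoes` echoes, otherwise
#' flagged and set to `default_t2star_ms`. Non-negative fitted slopes
#' (no measurable decay) are capped at `max_t2star_ms`.
#'
#' @param multiecho 4-D array (x, y, z, echo).
#' @param te_ms echo times (ms), length >= 3.
#' @param brain_mask logical array.
#' @param max_t2star_ms cap for the no-decay degenerate case (default 2000).
#' @param default_t2star_ms value assigned to flagged voxels.
#' @param min_echoes minimum usable echoes for a fit.
#' @return list with `t2star` (ms), `s0` (TE=0 intercept, signal units) and
#'   `flagged` (logical array).
#' @export
estimate_t2star <- function(multiecho, te_ms, brain_mask,
                            max_t2star_ms = 2000, default_t2star_ms = 50,
                            min_echoes = 3L) {
  ne <- length(te_ms)
  check_that(ne >= 3, "need at least 3 echoes")
  dm <- dim(multiecho)[1:3]
  idx <- which(brain_mask)
  nv <- length(idx)
  S <- matrix(0, nv, ne)
  for (e in seq_len(ne)) S[, e] <- multiecho[, , , e][idx]

  pos <- S > 0
  # Usable prefix length: echoes before the first non-positive signal.
  first_bad <- apply(!pos, 1, function(r) if (any(r)) which(r)[1] else ne + 1L)
  prefix <- pmin(first_bad - 1L, ne)

  t2s <- rep(default_t2star_ms, nv)
  s0 <- rep(NA_real_, nv)
  flg <- prefix < min_echoes

  for (p in unique(prefix[!flg])) {
    sel <- which(prefix == p & !flg)
    te <- te_ms[1:p]
    y <- log(S[sel, 1:p, drop = FALSE] / S[sel, 1])
    te_c <- te - mean(te)
    slope <- as.vector(y %*% te_c) / sum(te_c^2)
    ybar <- rowMeans(y)
    icpt <- ybar - slope * mean(te)   # intercept of log(S/S_1) at TE = 0
    t2_fit <- ifelse(slope < 0, -1 / slope, Inf)
    t2s[sel] <- pmin(t2_fit, max_t2star_ms)
    s0[sel] <- S[sel, 1] * exp(icpt)
  }

  out_t2s <- array(default_t2star_ms, dm)
  out_t2s[idx] <- t2s
  out_s0 <- array(0, dm)
  out_s0[idx] <- ifelse(is.na(s0), 0, s0)
  flagged <- array(FALSE, dm)
  flagged[idx] <- flg
  list(t2star = out_t2s, s0 = out_s0, flagged = flagged)
}

#' Estimate T1 from the PD-scan / T1-scan ratio
#'
#' Both scans share the same echo time, receive field and gain, so their
#' ratio depends only on T1 and the effective flip angles:
#' `R(T1) = f(TR_pd, b1t * fa_pd) / f(TR_t1, b1t * fa_t1)` with
#' `f(TR, a) = sin(a) (1 - E1) / (1 - cos(a) E1)`, `E1 = exp(-TR / T1)`.
#' `R` is strictly increasing in T1 on the bracket (asserted at runtime);
#' the equation is solved per voxel by vectorized bisection to `tol_ms`.
#' Ratios outside the attainable range are clamped to the bracket end and
#' flagged.
#'
#' @param pd_scan,t1_scan 3-D arrays sharing TE.
#' @param b1t_hat transmit field map.
#' @param brain_mask logical array.
#' @param tr_pd_ms,fa_pd_deg,tr_t1_ms,fa_t1_deg scan parameters.
#' @param bracket_ms T1 search interval (default 100-6000 ms).
#' @param tol_ms bisection tolerance.
#' @return list with `t1` (ms) and `flagged`.
#' @export
estimate_t1 <- function(pd_scan, t1_scan, b1t_hat, brain_mask,
                        tr_pd_ms = 1800, fa_pd_deg = 40,
                        tr_t1_ms = 500, fa_t1_deg = 90,
                        bracket_ms = c(100, 6000), tol_ms = 0.1) {
  dm <- dim(pd_scan)
  idx <- which(brain_mask & t1_scan > 0)
  ratio <- pd_scan[idx] / t1_scan[idx]
  b1t <- b1t_hat[idx]
  a_pd <- b1t * fa_pd_deg * pi / 180
  a_t1 <- b1t * fa_t1_deg * pi / 180

  rat_of <- function(t1) {
    e1p <- exp(-tr_pd_ms / t1); e1t <- exp(-tr_t1_ms / t1)
    (sin(a_pd) * (1 - e1p) / (1 - cos(a_pd) * e1p)) /
      (sin(a_t1) * (1 - e1t) / (1 - cos(a_t1) * e1t))
  }

  r_lo <- rat_of(bracket_ms[1])
  r_mid <- rat_of(mean(bracket_ms))
  r_hi <- rat_of(bracket_ms[2])
  check_that(all(r_lo < r_mid & r_mid < r_hi),
             "PD/T1 scan ratio is not monotone in T1 on the bracket")

  low_clip <- ratio <= r_lo
  high_clip <- ratio >= r_hi
  lo <- rep(bracket_ms[1], length(ratio))
  hi <- rep(bracket_ms[2], length(ratio))
  n_iter <- ceiling(log2(diff(bracket_ms) / tol_ms)) + 1
  for (k in seq_len(n_iter)) {
    mid <- 0.5 * (lo + hi)
    below <- rat_of(mid) < ratio
    lo <- ifelse(below, mid, lo)
    hi <- ifelse(below, hi, mid)
  }
  t1 <- 0.5 * (lo + hi)
  t1[low_clip] <- bracket_ms[1]
  t1[high_clip] <- bracket_ms[2]

  out <- array(NA_real_, dm)
  out[idx] <- t1
  flagged <- array(FALSE, dm)
  flagged[idx] <- low_clip | high_clip
  flagged[brain_mask & !(t1_scan > 0)] <- TRUE
  out[brain_mask & is.na(out)] <- mean(bracket_ms)
  list(t1 = out, flagged = flagged)
}

#' Estimate the receive field (B1-) from a body/array coil scan pair
#'
#' The two low-resolution scans differ only in the receive sensitivity (the
#' body coil is taken as a homogeneous reference), so their voxelwise ratio
#' `array / body` estimates the receive field. The ratio is smoothed within
#' the brain mask and mean-normalized to 1 over the brain; outside the brain
#' the field is set to 1.
#'
#' @param recv_body,recv_array the low-resolution scan pair (on the
#'   full-resolution grid after upsampling).
#' @param brain_mask logical array.
#' @param smooth_fwhm_mm smoothing kernel FWHM (mm).
#' @param voxel_mm voxel size.
#' @return list with `b1r` and `flagged` (voxels with non-positive body-coil
#'   signal).
#' @export
estimate_receive_field <- function(recv_body, recv_array, brain_mask,
                                   smooth_fwhm_mm = 3, voxel_mm = c(1, 1, 1)) {
  check_that(any(brain_mask), "empty brain mask")
  dm <- dim(recv_body)
  ok <- brain_mask & recv_body > 0
  ratio <- array(1, dm)
  ratio[ok] <- recv_array[ok] / recv_body[ok]
  sm <- gaussian_smooth(ratio, smooth_fwhm_mm, voxel_mm, mask = ok)
  out <- array(1, dm)
  out[brain_mask] <- sm[brain_mask] / mean(sm[brain_mask])
  list(b1r = out, flagged = brain_mask & !ok)
}

#' Correct the PD scan for B1, T2* decay and T1 saturation
#'
#' Applies the inverse of the spoiled-GRE signal model:
#' `pd_corrected = pd * exp(TE / T2*) / (b1r * sin(a) (1 - E1) /
#' (1 - cos(a) E1))` with `a = b1t * fa` and `E1 = exp(-TR / T1)`. In the
#' noiseless limit the result is proportional to the true water content.
#' Individual corrections can be switched off (for ablation studies): with
#' `apply_t1 = FALSE` full relaxation is assumed (`E1 = 0`), with
#' `apply_b1t = FALSE` the nominal flip angle is used, and so on.
#'
#' @param pd_scan 3-D array.
#' @param t2star_hat,t1_hat,b1t_hat,b1r_hat estimated maps on the same grid.
#' @param brain_mask logical array.
#' @param tr_ms,fa_deg,te_ms PD-scan parameters.
#' @param apply_b1t,apply_b1r,apply_t2star,apply_t1 step switches.
#' @return list with `pd_corrected` and `flagged` (near-zero denominator).
#' @export
correct_pd <- function(pd_scan, t2star_hat, t1_hat, b1t_hat, b1r_hat,
                       brain_mask, tr_ms = 1800, fa_deg = 40, te_ms = 5.2,
                       apply_b1t = TRUE, apply_b1r = TRUE,
                       apply_t2star = TRUE, apply_t1 = TRUE) {
  dm <- dim(pd_scan)
  a <- (if (apply_b1t) b1t_hat else array(1, dm)) * fa_deg * pi / 180
  e1 <- if (apply_t1) exp(-tr_ms / t1_hat) else array(0, dm)
  denom <- sin(a) * (1 - e1) / (1 - cos(a) * e1)
  if (apply_b1r) denom <- denom * b1r_hat
  decay <- if (apply_t2star) exp(te_ms / t2star_hat) else array(1, dm)

  eps <- 1e-6
  flagged <- brain_mask & !(abs(denom) > eps)
  out <- array(0, dm)
  use <- brain_mask & !flagged
  out[use] <- pd_scan[use] * decay[use] / denom[use]
  list(pd_corrected = out, flagged = flagged)
}

#' Remove residual low-frequency intensity nonuniformity
#'
#' Estimates the residual multiplicative bias field in the log domain over
#' the brain mask and divides it out, preserving the brain mean. Because a
#' brain-sized smoothing kernel cannot by itself distinguish smooth bias
#' from large-scale anatomy (tissue classes occupy coherent regions), the
#' piecewise-constant intensity structure is first removed: log intensities
#' are clustered into `n_levels` levels (deterministic 1-D k-means seeded
#' from intensity quantiles), each voxel's level is subtracted, and only the
#' remaining residual is smoothed heavily (FWHM >= 60 mm). On a bias-free
#' piecewise-constant map the residual is identically zero, so the step is
#' an exact identity.
#'
#' @param map 3-D array (positive inside the brain).
#' @param brain_mask logical array.
#' @param fwhm_mm smoothing FWHM in mm (default 60).
#' @param voxel_mm voxel size.
#' @param n_levels number of intensity levels removed before smoothing
#'   (default 3: WM, GM, CSF).
#' @param n_iter number of level-fit / bias-smooth alternations. The first
#'   pass can misassign levels where the bias exceeds half the inter-level
#'   gap; subsequent passes see a smaller residual field and converge.
#' @return list with `map` (corrected), `bias` (estimated multiplicative
#'   field, 1 outside brain) and `flagged` (non-positive input voxels,
#'   excluded from the bias fit and left unchanged).
#' @export
remove_residual_bias <- function(map, brain_mask, fwhm_mm = 60,
                                 voxel_mm = c(1, 1, 1), n_levels = 3L,
                                 n_iter = 3L) {
  check_that(any(brain_mask), "empty brain mask")
  dm <- dim(map)
  ok <- brain_mask & map > 0
  m0 <- mean(map[brain_mask])

  # deterministic 1-D k-means (quantile starts) on log intensities
  fit_levels <- function(x) {
    centers <- stats::quantile(x, (seq_len(n_levels) * 2 - 1) / (2 * n_levels),
                               names = FALSE)
    centers <- unique(centers)
    for (it in 1:50) {
      a <- max.col(-abs(outer(x, centers, "-")), ties.method = "first")
      new_c <- vapply(seq_along(centers),
                      function(j) if (any(a == j)) mean(x[a == j])
                      else centers[j], numeric(1))
      if (max(abs(new_c - centers)) < 1e-12) { centers <- new_c; break }
      centers <- new_c
    }
    a <- max.col(-abs(outer(x, centers, "-")), ties.method = "first")
    centers[a]
  }

  x <- log(map[ok] / m0)
  bias_log_total <- rep(0, sum(ok))
  resid_vol <- array(0, dm)
  for (it in seq_len(n_iter)) {
    resid_vol[ok] <- x - fit_levels(x)
    step_log <- gaussian_smooth(resid_vol, fwhm_mm, voxel_mm, mask = ok)[ok]
    if (max(abs(step_log)) < 1e-12 && it > 1) break
    bias_log_total <- bias_log_total + step_log
    x <- x - step_log
  }
  bias <- array(1, dm)
  bias[ok] <- exp(bias_log_total)
  out <- map
  out[ok] <- map[ok] / bias[ok]
  out[ok] <- out[ok] * (m0 / mean(out[brain_mask]))
  list(map = out, bias = bias, flagged = brain_mask & !ok)
}

#' Normalize a corrected PD map to ventricular CSF
#'
#' Divides by the mean over the eroded ventricular CSF mask and scales by
#' 100, yielding water content in percent of pure water molarity; pure CSF
#' maps to 100 % by construction.
#'
#' @param pd_corrected 3-D array.
#' @param ventricle_mask logical array of ventricular CSF.
#' @param erode_voxels erosion passes guarding against partial-volume rim
#'   voxels (default 1).
#' @param min_voxels minimum size of the eroded mask.
#' @return list with `water_map` and `csf_mask` (the eroded mask used).
#' @export
normalize_to_csf <- function(pd_corrected, ventricle_mask, erode_voxels = 1L,
                             min_voxels = 20L) {
  m <- if (erode_voxels > 0) erode_mask(ventricle_mask, erode_voxels)
       else ventricle_mask
  check_that(sum(m) >= min_voxels,
             "ventricle_mask too small after erosion (",
             sum(m), " < ", min_voxels, " voxels)")
  ref <- mean(pd_corrected[m])
  check_that(is.finite(ref) && ref > 0,
             "ventricle_mask yields a non-positive CSF reference")
  list(water_map = 100 * pd_corrected / ref, csf_mask = m)
}

#' Run the full water-content correction chain
#'
#' Inverts a [simulate_protocol()] acquisition into a quantitative water
#' content map through the fixed five-step chain: (i) transmit and receive
#' field compensation, (ii) T2* decay compensation, (iii) T1-saturation
#' correction, (iv) residual nonuniformity removal, (v) normalization to
#' ventricular CSF. All intermediate maps are retained for inspection, and
#' flagged voxels from any step are pooled into an exclusion mask that
#' downstream statistics honour.
#'
#' @param acq a `study_acquisition`.
#' @param ventricle_mask logical array of ventricular CSF (on real data this
#'   would come from a manual or atlas mask).
#' @param brain_mask logical array; defaults to the acquisition's mask.
#' @param disable_steps character subset of `c("b1_transmit", "t2star",
#'   "t1_saturation", "residual_bias")` for ablation studies (CSF
#'   normalization cannot be disabled: it defines the output units).
#' @param b1t_smooth_fwhm_mm,b1r_smooth_fwhm_mm,bias_fwhm_mm smoothing
#'   parameters of the respective steps.
#' @param t1_bracket_ms T1 solver bracket.
#' @param relaxation_median_filter if `TRUE` (default), the voxelwise T1 and
#'   T2* maps are passed through one [median_filter()] pass before the PD
#'   correction. Relaxation times are piecewise-constant tissue properties,
#'   so the edge-preserving median suppresses the noise that the nonlinear
#'   T1/T2* corrections would otherwise rectify into a bias, while leaving
#'   noiseless maps untouched away from single-voxel structures.
#' @return object of class `water_chain`; see individual estimators for the
#'   component maps. `applied_steps` records the chain actually run.
#' @export
map_water <- function(acq, ventricle_mask, brain_mask = acq$brain_mask,
                      disable_steps = character(),
                      b1t_smooth_fwhm_mm = 4, b1r_smooth_fwhm_mm = 3,
                      bias_fwhm_mm = 60, t1_bracket_ms = c(100, 6000),
                      relaxation_median_filter = TRUE) {
  bad <- setdiff(disable_steps,
                 c("b1_transmit", "t2star", "t1_saturation", "residual_bias"))
  check_that(length(bad) == 0, "unknown steps: ", paste(bad, collapse = ", "))
  vx <- acq$voxel_mm
  dm <- dim(acq$pd_scan)
  do_b1 <- !("b1_transmit" %in% disable_steps)
  do_t2s <- !("t2star" %in% disable_steps)
  do_t1 <- !("t1_saturation" %in% disable_steps)
  do_bias <- !("residual_bias" %in% disable_steps)

  pd_spec <- acq$protocol$pd
  t1_spec <- acq$protocol$t1
  tr_pd <- if (!is.null(pd_spec)) pd_spec$tr_ms else 1800
  fa_pd <- if (!is.null(pd_spec)) pd_spec$fa_deg else 40
  te_pd <- if (!is.null(pd_spec)) pd_spec$te_ms[1] else 5.2
  tr_t1 <- if (!is.null(t1_spec)) t1_spec$tr_ms else 500
  fa_t1 <- if (!is.null(t1_spec)) t1_spec$fa_deg else 90

  b1t_fit <- estimate_b1t(acq$b1_series, acq$b1_angles, brain_mask,
                          smooth_fwhm_mm = b1t_smooth_fwhm_mm, voxel_mm = vx)
  b1r_fit <- estimate_receive_field(acq$recv_body, acq$recv_array, brain_mask,
                                    smooth_fwhm_mm = b1r_smooth_fwhm_mm,
                                    voxel_mm = vx)
  t2s_fit <- estimate_t2star(acq$multiecho, acq$te_multiecho, brain_mask)
  b1t_for_t1 <- if (do_b1) b1t_fit$b1t else array(1, dm)
  t1_fit <- estimate_t1(acq$pd_scan, acq$t1_scan, b1t_for_t1, brain_mask,
                        tr_pd_ms = tr_pd, fa_pd_deg = fa_pd,
                        tr_t1_ms = tr_t1, fa_t1_deg = fa_t1,
                        bracket_ms = t1_bracket_ms)
  if (relaxation_median_filter) {
    t2s_fit$t2star <- median_filter(t2s_fit$t2star, brain_mask)
    t1_fit$t1 <- median_filter(t1_fit$t1, brain_mask)
  }
  pd_fit <- correct_pd(acq$pd_scan, t2s_fit$t2star, t1_fit$t1,
                       b1t_fit$b1t, b1r_fit$b1r, brain_mask,
                       tr_ms = tr_pd, fa_deg = fa_pd, te_ms = te_pd,
                       apply_b1t = do_b1, apply_b1r = do_b1,
                       apply_t2star = do_t2s, apply_t1 = do_t1)
  if (do_bias) {
    bias_fit <- remove_residual_bias(pd_fit$pd_corrected, brain_mask,
                                     fwhm_mm = bias_fwhm_mm, voxel_mm = vx)
  } else {
    bias_fit <- list(map = pd_fit$pd_corrected, bias = array(1, dm),
                     flagged = array(FALSE, dm))
  }
  norm <- normalize_to_csf(bias_fit$map, ventricle_mask)

  flags <- list(b1t = b1t_fit$flagged, b1r = b1r_fit$flagged,
                t2star = t2s_fit$flagged, t1 = t1_fit$flagged,
                pd = pd_fit$flagged, bias = bias_fit$flagged)
  exclude <- Reduce(`|`, flags)

  steps <- c(if (do_b1) "b1_transmit", if (do_t2s) "t2star",
             if (do_t1) "t1_saturation", if (do_bias) "residual_bias",
             "csf_normalization")

  structure(list(
    water_map = norm$water_map,
    b1t_hat = b1t_fit$b1t, b1t_raw = b1t_fit$b1t_raw,
    b1r_hat = b1r_fit$b1r,
    t2star_hat = t2s_fit$t2star, s0_hat = t2s_fit$s0,
    t1_hat = t1_fit$t1,
    pd_corrected = pd_fit$pd_corrected,
    bias_hat = bias_fit$bias,
    csf_mask = norm$csf_mask,
    brain_mask = brain_mask,
    flags = flags, exclude_mask = exclude,
    applied_steps = steps,
    qc = list(n_flagged = vapply(flags, sum, numeric(1)),
              csf_mask_voxels = sum(norm$csf_mask),
              brain_voxels = sum(brain_mask))
  ), class = "water_chain")
}

#' @export
print.water_chain <- function(x, ...) {
  cat("water_chain: steps [", paste(x$applied_steps, collapse = ", "), "]\n")
  cat("  brain voxels:", x$qc$brain_voxels,
      " CSF reference voxels:", x$qc$csf_mask_voxels, "\n")
  cat("  flagged:", paste(sprintf("%s=%d", names(x$qc$n_flagged),
                                  x$qc$n_flagged), collapse = " "), "\n")
  invisible(x)
}

#' Write the water map and QC summary of a chain run
#'
#' @param chain a `water_chain`.
#' @param out_nii output NIfTI path for the water map.
#' @param qc_dir optional directory for intermediate maps and a QC JSON.
#' @param voxel_mm voxel size.
#' @export
write_water_chain <- function(chain, out_nii, qc_dir = NULL,
                              voxel_mm = c(1, 1, 1)) {
  write_volume(chain$water_map, out_nii, voxel_mm)
  if (!is.null(qc_dir)) {
    dir.create(qc_dir, recursive = TRUE, showWarnings = FALSE)
    for (m in c("b1t_hat", "b1r_hat", "t2star_hat", "t1_hat",
                "pd_corrected", "bias_hat"))
      write_volume(chain[[m]], file.path(qc_dir, paste0(m, ".nii.gz")),
                   voxel_mm)
    jsonlite::write_json(
      list(applied_steps = chain$applied_steps,
           n_flagged = as.list(chain$qc$n_flagged),
           csf_mask_voxels = chain$qc$csf_mask_voxels,
           brain_voxels = chain$qc$brain_voxels),
      file.path(qc_dir, "qc.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(out_nii)
}
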