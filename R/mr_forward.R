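#' Scan specification for the spoiled gradient-echo forward model
#'
#' @param kind `"gre"` (steady-state spoiled GRE) or `"epi"` (single-shot
#'   GRE-EPI used for the B1+ series; simulated saturation-free, i.e.
#'   effectively TR >> T1, so the series isolates `sin(b1t * fa)`).
#' @param tr_ms repetition time (ms); `Inf` allowed for the saturation-free
#'   EPI case.
#' @param te_ms echo time(s), ms; a vector yields one volume per echo.
#' @param fa_deg nominal flip angle, degrees, in `(0, 180]`.
#' @param noise_sd magnitude noise SD relative to the mean brain signal of
#'   the (first-echo) noiseless volume.
#' @param downsample integer block-averaging factor for low-resolution scans.
#' @param label free-text scan label.
#' @return object of class `scan_spec`.
#' @export
scan_spec <- function(kind = c("gre", "epi"), tr_ms, te_ms, fa_deg,
                      noise_sd = 0, downsample = 1L, label = kind[1]) {
  kind <- match.arg(kind)
  check_that(tr_ms > 0, "tr_ms must be positive")
  check_that(all(te_ms > 0), "all te_ms must be positive")
  check_that(fa_deg > 0 && fa_deg <= 180, "fa_deg must be in (0, 180]")
  check_that(noise_sd >= 0, "noise_sd must be non-negative")
  structure(list(kind = kind, tr_ms = tr_ms, te_ms = te_ms, fa_deg = fa_deg,
                 noise_sd = noise_sd, downsample = as.integer(downsample),
                 label = label),
            class = "scan_spec")
}

#' Spoiled GRE steady-state signal
#'
#' The standard perfectly-spoiled gradient-echo steady state:
#' \deqn{S = g \, b_{1r} \, W \, \frac{\sin(b_{1t}\alpha)\,(1 - E_1)}
#'   {1 - \cos(b_{1t}\alpha)\,E_1} \, e^{-TE/T_2^*}, \quad E_1 = e^{-TR/T_1}.}
#' The signal is linear in the water content `W`, the receive sensitivity
#' `b1r` and the global gain `g`; the transmit field `b1t` scales the
#' effective flip angle.
#'
#' @param water water content, percent of pure water (vectorized).
#' @param t1_ms,t2star_ms relaxation times (ms), vectorized.
#' @param b1t,b1r transmit / receive field multipliers, vectorized.
#' @param scan a [scan_spec()].
#' @param echo echo index into `scan$te_ms`.
#' @param gain global scanner gain `g`.
#' @return signal in arbitrary units, same shape as the inputs.
#' @export
spgr_signal <- function(water, t1_ms, t2star_ms, b1t = 1, b1r = 1,
                        scan, echo = 1L, gain = 1) {
  check_that(all(t1_ms > 0, na.rm = TRUE), "T1 must be positive")
  check_that(all(t2star_ms > 0, na.rm = TRUE), "T2* must be positive")
  a <- b1t * scan$fa_deg * pi / 180
  e1 <- if (is.finite(scan$tr_ms)) exp(-scan$tr_ms / t1_ms) else 0
  te <- scan$te_ms[echo]
  gain * b1r * water * sin(a) * (1 - e1) / (1 - cos(a) * e1) *
    exp(-te / t2star_ms)
}

saturation_factor <- function(tr_ms, fa_deg, t1_ms) {
  a <- fa_deg * pi / 180
  e1 <- exp(-tr_ms / t1_ms)
  sin(a) * (1 - e1) / (1 - cos(a) * e1)
}

#' Simulate one scan (possibly multi-echo) from a phantom
#'
#' Evaluates [spgr_signal()] voxelwise on the phantom truth maps and field
#' maps, then adds zero-mean Gaussian noise on the magnitude (clipped at 0;
#' Rician optional). The noise SD is `scan$noise_sd` times the mean brain
#' signal of the first-echo noiseless volume, and the same SD is used for
#' every echo of a series (thermal noise does not decay with the signal).
#' `downsample > 1` applies block averaging followed by nearest-neighbour
#' upsampling back to the phantom grid.
#'
#' @param phantom a `digital_phantom`.
#' @param fields a `field_maps` object on the same grid.
#' @param scan a [scan_spec()].
#' @param seed integer seed for the noise stream.
#' @param gain global scanner gain.
#' @param rician if `TRUE`, noise is Rician (magnitude of complex Gaussian)
#'   instead of clipped Gaussian.
#' @return a 3-D array, or a 4-D array (x, y, z, echo) for multi-echo scans.
#' @export
simulate_scan <- function(phantom, fields, scan, seed = 1L, gain = 1,
                          rician = FALSE) {
  dm <- dim(phantom$labels)
  check_that(identical(dm, dim(fields$b1t)),
             "phantom and field grids do not match",
             class = "hydromap_shape_error")
  n_echo <- length(scan$te_ms)
  vols <- array(0, c(dm, n_echo))
  for (e in seq_len(n_echo)) {
    s <- spgr_signal(phantom$truth$water, phantom$truth$t1,
                     phantom$truth$t2star, fields$b1t, fields$b1r,
                     scan, echo = e, gain = gain)
    s[!phantom$brain_mask] <- 0
    vols[, , , e] <- s
  }
  sd_abs <- scan$noise_sd * mean(vols[, , , 1][phantom$brain_mask])
  if (scan$noise_sd > 0) {
    withr::with_seed(seed, {
      for (e in seq_len(n_echo)) {
        v <- vols[, , , e]
        if (rician) {
          v <- sqrt((v + array(rnorm(prod(dm), 0, sd_abs), dm))^2 +
                    array(rnorm(prod(dm), 0, sd_abs), dm)^2)
        } else {
          v <- pmax(0, v + array(rnorm(prod(dm), 0, sd_abs), dm))
        }
        vols[, , , e] <- v
      }
    })
  }
  if (scan$downsample > 1L) {
    for (e in seq_len(n_echo)) {
      vols[, , , e] <- nn_upsample(
        block_downsample(vols[, , , e], scan$downsample), scan$downsample)
    }
  }
  if (n_echo == 1L) array(vols, dm) else vols
}

#' Default five-scan water mapping protocol
#'
#' The acquisition set inverted by the correction chain:
#' \itemize{
#'   \item PD scan: GRE, TR 1800 ms, TE 5.2 ms, FA 40 deg;
#'   \item T1 scan: GRE, TR 500 ms, TE 5.2 ms, FA 90 deg;
#'   \item B1+ series: four GRE-EPI volumes, TE 11 ms, FA 30/60/90/120 deg
#'     (saturation-free);
#'   \item receive-field pair: two low-resolution GRE scans, TR 500 ms,
#'     TE 5.2 ms, FA 40 deg (body-coil reference and array coil);
#'   \item multi-echo T2* scan: GRE, TR 35 ms, FA 12 deg, 8 echoes,
#'     TE = 2.3 + k * 2.27 ms.
#' }
#'
#' @param noise_sd relative magnitude noise SD for every scan (default 0.02,
#'   i.e. SNR 50).
#' @param recv_downsample downsampling factor of the receive-field pair.
#' @return named list of [scan_spec()]s.
#' @export
default_protocol <- function(noise_sd = 0.02, recv_downsample = 2L) {
  list(
    pd = scan_spec("gre", tr_ms = 1800, te_ms = 5.2, fa_deg = 40,
                   noise_sd = noise_sd, label = "pd"),
    t1 = scan_spec("gre", tr_ms = 500, te_ms = 5.2, fa_deg = 90,
                   noise_sd = noise_sd, label = "t1"),
    b1 = lapply(c(30, 60, 90, 120), function(fa)
      scan_spec("epi", tr_ms = Inf, te_ms = 11, fa_deg = fa,
                noise_sd = noise_sd, label = sprintf("b1_fa%03d", fa))),
    recv = scan_spec("gre", tr_ms = 500, te_ms = 5.2, fa_deg = 40,
                     noise_sd = noise_sd, downsample = recv_downsample,
                     label = "recv"),
    multiecho = scan_spec("gre", tr_ms = 35, te_ms = 2.3 + (0:7) * 2.27,
                          fa_deg = 12, noise_sd = noise_sd,
                          label = "multiecho")
  )
}

#' Simulate the full water-mapping protocol
#'
#' Runs [simulate_scan()] for each member of the protocol. The receive-field
#' pair is simulated as a body-coil scan (receive sensitivity identically 1)
#' and an array-coil scan (receive sensitivity `fields$b1r`), differing only
#' in the receive field. Per-scan sub-seeds are derived deterministically
#' from `seed` via [spawn_seed()].
#'
#' @param phantom a `digital_phantom`.
#' @param fields a `field_maps` object.
#' @param protocol a protocol list from [default_protocol()].
#' @param seed master seed.
#' @param gain global scanner gain applied to every scan.
#' @param rician passed to [simulate_scan()].
#' @return object of class `study_acquisition` with elements `pd_scan`,
#'   `t1_scan`, `b1_series` (4-D), `b1_angles`, `recv_body`, `recv_array`,
#'   `multiecho` (4-D), `te_multiecho`, `protocol`, `voxel_mm`, `brain_mask`.
#' @export
simulate_protocol <- function(phantom, fields, protocol = default_protocol(),
                              seed = 1L, gain = 1, rician = FALSE) {
  dm <- dim(phantom$labels)
  body_fields <- structure(list(b1t = fields$b1t,
                                b1r = array(1, dm)), class = "field_maps")
  b1_angles <- vapply(protocol$b1, function(s) s$fa_deg, numeric(1))
  b1_series <- array(0, c(dm, length(protocol$b1)))
  for (k in seq_along(protocol$b1)) {
    b1_series[, , , k] <- simulate_scan(phantom, fields, protocol$b1[[k]],
                                        seed = spawn_seed(seed, 10L + k),
                                        gain = gain, rician = rician)
  }
  structure(list(
    pd_scan = simulate_scan(phantom, fields, protocol$pd,
                            seed = spawn_seed(seed, 1L), gain = gain,
                            rician = rician),
    t1_scan = simulate_scan(phantom, fields, protocol$t1,
                            seed = spawn_seed(seed, 2L), gain = gain,
                            rician = rician),
    b1_series = b1_series,
    b1_angles = b1_angles,
    recv_body = simulate_scan(phantom, body_fields, protocol$recv,
                              seed = spawn_seed(seed, 3L), gain = gain,
                              rician = rician),
    recv_array = simulate_scan(phantom, fields, protocol$recv,
                               seed = spawn_seed(seed, 4L), gain = gain,
                               rician = rician),
    multiecho = simulate_scan(phantom, fields, protocol$multiecho,
                              seed = spawn_seed(seed, 5L), gain = gain,
                              rician = rician),
    te_multiecho = protocol$multiecho$te_ms,
    protocol = protocol,
    voxel_mm = phantom$voxel_mm,
    brain_mask = phantom$brain_mask
  ), class = "study_acquisition")
}

#' Write a study acquisition as NIfTI volumes with JSON sidecars
#'
#' Each scan is written as NIfTI-1 with a BIDS-style JSON sidecar recording
#' RepetitionTime (s), EchoTime (s) and FlipAngle (deg).
#'
#' @param acq a `study_acquisition`.
#' @param dir output directory.
#' @export
write_acquisition <- function(acq, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vx <- acq$voxel_mm
  sidecar <- function(spec, path, echo = 1) {
    jsonlite::write_json(list(RepetitionTime = spec$tr_ms / 1000,
                              EchoTime = spec$te_ms[echo] / 1000,
                              FlipAngle = spec$fa_deg),
                         path, auto_unbox = TRUE, digits = NA)
  }
  p <- acq$protocol
  write_volume(acq$pd_scan, file.path(dir, "pd.nii.gz"), vx)
  sidecar(p$pd, file.path(dir, "pd.json"))
  write_volume(acq$t1_scan, file.path(dir, "t1.nii.gz"), vx)
  sidecar(p$t1, file.path(dir, "t1.json"))
  for (k in seq_along(acq$b1_angles)) {
    f <- sprintf("b1_fa%03d", acq$b1_angles[k])
    write_volume(acq$b1_series[, , , k], file.path(dir, paste0(f, ".nii.gz")), vx)
    sidecar(p$b1[[k]], file.path(dir, paste0(f, ".json")))
  }
  write_volume(acq$recv_body, file.path(dir, "recv_body.nii.gz"), vx)
  write_volume(acq$recv_array, file.path(dir, "recv_array.nii.gz"), vx)
  sidecar(p$recv, file.path(dir, "recv_body.json"))
  sidecar(p$recv, file.path(dir, "recv_array.json"))
  for (e in seq_along(acq$te_multiecho)) {
    f <- sprintf("multiecho_e%d", e)
    write_volume(acq$multiecho[, , , e], file.path(dir, paste0(f, ".nii.gz")), vx)
    sidecar(p$multiecho, file.path(dir, paste0(f, ".json")), echo = e)
  }
  write_volume(acq$brain_mask, file.path(dir, "brain_mask.nii.gz"), vx)
  jsonlite::write_json(list(b1_angles = acq$b1_angles,
                            te_multiecho = acq$te_multiecho,
                            voxel_mm = as.numeric(vx)),
                       file.path(dir, "acquisition.json"), digits = NA)
  invisible(dir)
}

#' Read a study acquisition directory written by [write_acquisition()]
#'
#' @param dir acquisition directory.
#' @return a `study_acquisition` (without the generating protocol specs).
#' @export
read_acquisition <- function(dir) {
  meta_path <- file.path(dir, "acquisition.json")
  check_that(file.exists(meta_path),
             "acquisition directory is missing acquisition.json: ", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  need <- function(f) {
    p <- file.path(dir, f)
    check_that(file.exists(p), "acquisition directory is missing ", f)
    read_volume(p)
  }
  pd <- need("pd.nii.gz")
  dm <- dim(pd)
  b1 <- array(0, c(dm, length(meta$b1_angles)))
  for (k in seq_along(meta$b1_angles))
    b1[, , , k] <- need(sprintf("b1_fa%03d.nii.gz", meta$b1_angles[k]))
  me <- array(0, c(dm, length(meta$te_multiecho)))
  for (e in seq_along(meta$te_multiecho))
    me[, , , e] <- need(sprintf("multiecho_e%d.nii.gz", e))
  structure(list(
    pd_scan = pd, t1_scan = need("t1.nii.gz"),
    b1_series = b1, b1_angles = meta$b1_angles,
    recv_body = need("recv_body.nii.gz"),
    recv_array = need("recv_array.nii.gz"),
    multiecho = me, te_multiecho = meta$te_multiecho,
    protocol = NULL, voxel_mm = meta$voxel_mm,
    brain_mask = need("brain_mask.nii.gz") > 0.5
  ), class = "study_acquisition")
}
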