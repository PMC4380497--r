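#' Tissue parameter set for the digital phantom
#'
#' Default water content per tissue class follows the healthy-adult values
#' used as ground truth throughout the package: white matter 71.46 %, gray
#' matter 82.93 % of pure water molarity, CSF exactly 100 % (it is the
#' normalization reference). Relaxation times are typical 3T values: they are
#' not part of the water-content ground truth and are freely overridable.
#'
#' @param water_pct named numeric, percent of pure water molarity for
#'   `wm`, `gm`, `csf`. CSF must be exactly 100.
#' @param t1_ms named numeric, longitudinal relaxation times (ms).
#' @param t2star_ms named numeric, effective transverse relaxation times (ms).
#' @return object of class `tissue_params`.
#' @export
tissue_params <- function(water_pct = c(wm = 71.46, gm = 82.93, csf = 100),
                          t1_ms = c(wm = 900, gm = 1400, csf = 4000),
                          t2star_ms = c(wm = 50, gm = 60, csf = 200)) {
  cls <- c("wm", "gm", "csf")
  water_pct <- water_pct[cls]; t1_ms <- t1_ms[cls]; t2star_ms <- t2star_ms[cls]
  check_that(all(is.finite(water_pct)) && all(water_pct > 0) &&
             all(water_pct <= 100),
             "water_pct must satisfy 0 < water_pct <= 100 for all classes")
  check_that(water_pct[["csf"]] == 100, "CSF water_pct must be exactly 100")
  check_that(water_pct[["wm"]] < water_pct[["gm"]],
             "WM water_pct must be below GM water_pct")
  check_that(water_pct[["gm"]] < water_pct[["csf"]],
             "GM water_pct must be below CSF water_pct")
  check_that(all(t1_ms > 0) && all(t2star_ms > 0),
             "relaxation times must be positive")
  structure(list(water_pct = water_pct, t1_ms = t1_ms, t2star_ms = t2star_ms),
            class = "tissue_params")
}

# Tissue label codes used in all label volumes.
LBL_BG <- 0L; LBL_WM <- 1L; LBL_GM <- 2L; LBL_CSF <- 3L

ellipsoid_mask <- function(shape, center, semi_axes) {
  g <- lapply(1:3, function(a) (seq_len(shape[a]) - center[a]) / semi_axes[a])
  x2 <- array(g[[1]]^2, shape)
  y2 <- aperm(array(g[[2]]^2, shape[c(2, 1, 3)]), c(2, 1, 3))
  z2 <- aperm(array(g[[3]]^2, shape[c(3, 1, 2)]), c(2, 3, 1))
  (x2 + y2 + z2) <= 1
}

#' Generate a digital brain phantom
#'
#' Deterministic concentric-ellipsoid geometry: a white matter core, a gray
#' matter shell, an outer CSF rim, and two interior ellipsoidal ventricles
#' (CSF). The geometry is analytic rather than anatomical so that tissue
#' volumes and ground truth are exactly known. Probability maps are one-hot
#' (pure-class) by default; an optional Gaussian within-class texture can be
#' added to the water truth map.
#'
#' @param shape length-3 integer, volume dimensions (each >= 32).
#' @param params a [tissue_params()] object giving the ground-truth values.
#' @param seed integer seed (used only when `texture_sd > 0`).
#' @param voxel_mm voxel size in mm.
#' @param texture_sd SD (water %) of optional within-class Gaussian texture
#'   on the water truth map; 0 (default) gives a pure-class phantom.
#' @return object of class `digital_phantom` with elements `labels`,
#'   `prob_maps` (list `wm`, `gm`, `csf`), `truth` (list `water`, `t1`,
#'   `t2star`), `brain_mask`, `ventricle_mask`, `voxel_mm`, `params`.
#' @export
make_phantom <- function(shape = c(64, 64, 64), params = tissue_params(),
                         seed = 1L, voxel_mm = c(1, 1, 1), texture_sd = 0) {
  shape <- as.integer(shape)
  check_that(length(shape) == 3 && all(shape >= 32),
             "phantom shape must be at least 32 voxels per axis")
  ctr <- (shape + 1) / 2
  csf_out <- ellipsoid_mask(shape, ctr, 0.44 * shape)
  gm_out  <- ellipsoid_mask(shape, ctr, 0.40 * shape)
  wm_out  <- ellipsoid_mask(shape, ctr, 0.30 * shape)
  vent_l <- ellipsoid_mask(shape, ctr + c(-0.08 * shape[1], 0, 0),
                           c(0.08, 0.11, 0.08) * shape)
  vent_r <- ellipsoid_mask(shape, ctr + c(+0.08 * shape[1], 0, 0),
                           c(0.08, 0.11, 0.08) * shape)
  ventricles <- vent_l | vent_r

  labels <- array(LBL_BG, shape)
  labels[csf_out] <- LBL_CSF
  labels[gm_out]  <- LBL_GM
  labels[wm_out]  <- LBL_WM
  labels[ventricles] <- LBL_CSF
  brain <- labels != LBL_BG

  n_brain <- sum(brain)
  for (lbl in c(LBL_WM, LBL_GM, LBL_CSF)) {
    check_that(sum(labels == lbl) >= 0.01 * n_brain,
               "phantom shape too small: a tissue class occupies < 1% of brain",
               class = "hydromap_sizing_error")
  }

  prob_maps <- list(
    wm  = array(as.numeric(labels == LBL_WM), shape),
    gm  = array(as.numeric(labels == LBL_GM), shape),
    csf = array(as.numeric(labels == LBL_CSF), shape)
  )

  class_map <- function(vals, background = 0) {
    out <- array(background, shape)
    out[labels == LBL_WM]  <- vals[["wm"]]
    out[labels == LBL_GM]  <- vals[["gm"]]
    out[labels == LBL_CSF] <- vals[["csf"]]
    out
  }
  water <- class_map(params$water_pct)
  if (texture_sd > 0) {
    withr::with_seed(seed, {
      tex <- array(rnorm(prod(shape), 0, texture_sd), shape)
    })
    keep <- brain & !ventricles
    water[keep] <- pmin(100, pmax(1, water[keep] + tex[keep]))
  }

  structure(list(
    labels = labels,
    prob_maps = prob_maps,
    # background relaxation set to 1 ms (any positive value): water is 0
    # there, so the simulated signal is 0 regardless.
    truth = list(water = water, t1 = class_map(params$t1_ms, background = 1),
                 t2star = class_map(params$t2star_ms, background = 1)),
    brain_mask = brain,
    ventricle_mask = ventricles,
    voxel_mm = voxel_mm,
    params = params
  ), class = "digital_phantom")
}

#' @export
print.digital_phantom <- function(x, ...) {
  cat("digital_phantom:", paste(dim(x$labels), collapse = " x "),
      "voxels;", sum(x$brain_mask), "brain voxels\n")
  for (t in c("wm", "gm", "csf")) {
    cat(sprintf("  %-3s water %.2f%%  T1 %g ms  T2* %g ms\n", toupper(t),
                x$params$water_pct[[t]], x$params$t1_ms[[t]],
                x$params$t2star_ms[[t]]))
  }
  invisible(x)
}

#' Generate smooth multiplicative B1 field maps
#'
#' Transmit (B1+) and receive (B1-) inhomogeneity are modeled as smooth
#' multiplicative fields near 1: Gaussian white noise is smoothed with a
#' kernel of FWHM `smoothness_mm`, demeaned over the mask, and scaled so the
#' maximum absolute deviation equals `amplitude`. Both fields then have mean
#' exactly 1 over the mask and values in `[1 - amplitude, 1 + amplitude]`.
#'
#' @param shape length-3 integer volume dimensions.
#' @param amplitude maximum fractional deviation from 1; in `[0, 0.5)`.
#' @param smoothness_mm FWHM of the smoothing kernel (mm).
#' @param seed integer seed.
#' @param voxel_mm voxel size (mm).
#' @param mask logical array over which the mean-1 constraint and amplitude
#'   scaling are applied; defaults to the whole volume.
#' @return object of class `field_maps` with elements `b1t`, `b1r`.
#' @export
make_fields <- function(shape, amplitude = 0.2, smoothness_mm = 40,
                        seed = 1L, voxel_mm = c(1, 1, 1), mask = NULL) {
  shape <- as.integer(shape)
  check_that(amplitude >= 0 && amplitude < 0.5,
             "field amplitude must be in [0, 0.5)")
  if (is.null(mask)) mask <- array(TRUE, shape)
  one_field <- function(sub) {
    if (amplitude == 0) return(array(1, shape))
    withr::with_seed(sub, {
      noise <- array(rnorm(prod(shape)), shape)
    })
    f <- gaussian_smooth(noise, smoothness_mm, voxel_mm)
    f <- f - mean(f[mask])
    f <- f * (amplitude / max(abs(f)))
    1 + f
  }
  structure(list(b1t = one_field(spawn_seed(seed, 1)),
                 b1r = one_field(spawn_seed(seed, 2))),
            class = "field_maps")
}

#' Specification of a two-group, two-timepoint phantom cohort
#'
#' Emulates a hemodialysis (HD) vs healthy-control study design: each group
#' has `n_per_group` subjects scanned at two timepoints. HD subjects carry an
#' additive water offset per tissue; subjects carry a random tissue-level
#' water effect; clinical covariates (dialysis vintage in months,
#' intradialytic weight change in kg) are drawn correlated with the subject's
#' white matter water offset.
#'
#' @param n_per_group subjects per group (>= 2).
#' @param group_offsets named numeric, additive water % offsets for the HD
#'   group per tissue (`wm`, `gm`). Defaults reproduce the control-vs-HD
#'   baseline differences used as study conditions (+1.43 WM, +1.49 GM).
#' @param between_subject_sd named numeric, between-subject water SD per
#'   tissue (defaults 1.06 WM, 1.00 GM).
#' @param timepoint_sd within-subject water SD between timepoints (default
#'   0.2, a small physiological test-retest fluctuation).
#' @param vintage_cor correlation between dialysis vintage and the subject's
#'   WM water offset (HD group).
#' @param weight_change_cor correlation between intradialytic weight change
#'   and the WM water offset (HD group; negative: larger fluid removal,
#'   lower water).
#' @param vintage_mean,vintage_sd distribution of dialysis vintage (months).
#' @param weight_mean,weight_sd distribution of intradialytic weight change (kg).
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 10L,
                        group_offsets = c(wm = 1.43, gm = 1.49),
                        between_subject_sd = c(wm = 1.06, gm = 1.00),
                        timepoint_sd = 0.2,
                        vintage_cor = 0.69,
                        weight_change_cor = -0.74,
                        vintage_mean = 44.5, vintage_sd = 20,
                        weight_mean = -1.5, weight_sd = 0.8,
                        seed = 1L) {
  check_that(n_per_group >= 2, "n_per_group must be >= 2")
  check_that(all(between_subject_sd >= 0) && timepoint_sd >= 0,
             "SDs must be non-negative")
  check_that(abs(vintage_cor) <= 1 && abs(weight_change_cor) <= 1,
             "correlations must lie in [-1, 1]")
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a two-group, two-timepoint phantom cohort
#'
#' Subject-level water truth is `control value + group offset (HD only) +
#' between-subject effect + timepoint fluctuation`; CSF stays at exactly
#' 100 % for every subject (it is the normalization reference). Phantom
#' volumes are realized lazily via [realize_phantom()] so that a large cohort
#' does not hold all volumes in memory; the returned manifest carries every
#' per-subject parameter needed to rebuild any phantom deterministically.
#'
#' @param spec a [cohort_spec()].
#' @param params_control baseline [tissue_params()] (control group truth).
#' @param shape,voxel_mm phantom geometry passed to [make_phantom()].
#' @return object of class `phantom_cohort` with a `manifest` data frame
#'   (subject, group, timepoint, water truth per tissue, covariates, seeds)
#'   and the generating spec.
#' @export
make_cohort <- function(spec = cohort_spec(), params_control = tissue_params(),
                        shape = c(64, 64, 64), voxel_mm = c(1, 1, 1)) {
  n <- spec$n_per_group
  base <- params_control$water_pct
  withr::with_seed(spec$seed, {
    rows <- list()
    for (g in c("control", "hd")) {
      # Subject random effects per tissue; WM effect drives covariates.
      z_wm <- rnorm(n); z_gm <- rnorm(n)
      off_wm <- spec$between_subject_sd[["wm"]] * z_wm
      off_gm <- spec$between_subject_sd[["gm"]] * z_gm
      if (g == "hd") {
        off_wm <- off_wm + spec$group_offsets[["wm"]]
        off_gm <- off_gm + spec$group_offsets[["gm"]]
      }
      rv <- spec$vintage_cor; rw <- spec$weight_change_cor
      vint_z <- rv * z_wm + sqrt(1 - rv^2) * rnorm(n)
      wchg_z <- rw * z_wm + sqrt(1 - rw^2) * rnorm(n)
      vintage <- pmax(0.5, spec$vintage_mean + spec$vintage_sd * vint_z)
      wchange <- spec$weight_mean + spec$weight_sd * wchg_z
      if (g == "control") { vintage <- rep(NA_real_, n); wchange <- rep(NA_real_, n) }
      for (i in seq_len(n)) {
        for (tp in 1:2) {
          dtp <- if (tp == 1) c(0, 0) else rnorm(2, 0, spec$timepoint_sd)
          rows[[length(rows) + 1]] <- data.frame(
            subject = sprintf("%s%02d", if (g == "hd") "HD" else "C", i),
            group = g, timepoint = tp,
            water_wm = base[["wm"]] + off_wm[i] + dtp[1],
            water_gm = base[["gm"]] + off_gm[i] + dtp[2],
            water_csf = 100,
            vintage_months = vintage[i],
            weight_change_kg = wchange[i],
            stringsAsFactors = FALSE
          )
        }
      }
    }
  })
  manifest <- do.call(rbind, rows)
  manifest$phantom_seed <- vapply(seq_len(nrow(manifest)), function(i)
    spawn_seed(spec$seed, 100L + i), integer(1))
  structure(list(manifest = manifest, spec = spec,
                 params_control = params_control,
                 shape = shape, voxel_mm = voxel_mm),
            class = "phantom_cohort")
}

#' Realize the digital phantom of one cohort row
#'
#' @param cohort a [make_cohort()] result.
#' @param row row index into `cohort$manifest`.
#' @return a `digital_phantom` whose water truth equals that row's
#'   subject/timepoint tissue values.
#' @export
realize_phantom <- function(cohort, row) {
  m <- cohort$manifest[row, ]
  # Clamp within tissue_params invariants; offsets never realistically reach
  # the bounds under default study conditions.
  wm <- min(m$water_wm, m$water_gm - 1e-6)
  p <- tissue_params(
    water_pct = c(wm = wm, gm = min(m$water_gm, 100 - 1e-6), csf = 100),
    t1_ms = cohort$params_control$t1_ms,
    t2star_ms = cohort$params_control$t2star_ms
  )
  make_phantom(cohort$shape, p, seed = m$phantom_seed,
               voxel_mm = cohort$voxel_mm)
}

#' Write a phantom to disk as a NIfTI set plus YAML config
#'
#' One NIfTI file per map (labels, per-class probabilities, water/T1/T2*
#' truth, ventricle and brain masks), with the generating parameters in
#' `phantom.yaml`.
#'
#' @param phantom a `digital_phantom`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vx <- phantom$voxel_mm
  write_volume(phantom$labels, file.path(dir, "labels.nii.gz"), vx)
  for (t in names(phantom$prob_maps))
    write_volume(phantom$prob_maps[[t]], file.path(dir, paste0("prob_", t, ".nii.gz")), vx)
  for (t in names(phantom$truth))
    write_volume(phantom$truth[[t]], file.path(dir, paste0("truth_", t, ".nii.gz")), vx)
  write_volume(phantom$ventricle_mask, file.path(dir, "ventricle_mask.nii.gz"), vx)
  write_volume(phantom$brain_mask, file.path(dir, "brain_mask.nii.gz"), vx)
  yaml::write_yaml(list(
    voxel_mm = as.numeric(vx),
    water_pct = as.list(phantom$params$water_pct),
    t1_ms = as.list(phantom$params$t1_ms),
    t2star_ms = as.list(phantom$params$t2star_ms)
  ), file.path(dir, "phantom.yaml"))
  invisible(dir)
}

#' Write a cohort manifest as TSV
#'
#' @param cohort a `phantom_cohort`.
#' @param path output TSV path.
#' @export
write_cohort_manifest <- function(cohort, path) {
  write.table(cohort$manifest, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
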