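#' Construct a probabilistic ROI
#'
#' @param name unique ROI name.
#' @param prob 3-D probability array in `[0, 1]`.
#' @param composition optional named numeric with nominal WM/GM fractions.
#' @return object of class `atlas_roi`.
#' @export
atlas_roi <- function(name, prob, composition = c(wm = NA_real_, gm = NA_real_)) {
  check_that(all(prob >= 0 & prob <= 1), "ROI probabilities must be in [0, 1]")
  structure(list(name = name, prob = prob, composition = composition),
            class = "atlas_roi")
}

#' Synthetic geometric atlas for a phantom
#'
#' Stands in for a probabilistic anatomical atlas with the same file and
#' masking contract: lobe-like sectors (frontal/occipital by the anterior /
#' posterior halves, left/right temporal and parietal octants), a mid-plane
#' "callosal" slab inside the white matter core, and a periventricular
#' region. Probabilities are 1 in the region core and fall off linearly over
#' an `edge_voxels`-wide rim, so the 75 % masking rule is exercised.
#'
#' @param phantom a `digital_phantom`.
#' @param edge_voxels width of the probabilistic rim.
#' @return named list of `atlas_roi` objects.
#' @export
make_synthetic_atlas <- function(phantom, edge_voxels = 2) {
  dm <- dim(phantom$labels)
  brain <- phantom$brain_mask
  ctr <- (dm + 1) / 2
  ax <- function(a) {
    g <- array(0, dm)
    if (a == 1) g[] <- rep(seq_len(dm[1]), times = dm[2] * dm[3])
    if (a == 2) g[] <- rep(rep(seq_len(dm[2]), each = dm[1]), times = dm[3])
    if (a == 3) g[] <- rep(seq_len(dm[3]), each = dm[1] * dm[2])
    g
  }
  X <- ax(1); Y <- ax(2); Z <- ax(3)

  # Linear probability ramp: 1 at `d >= edge`, 0 at d <= 0, where d is the
  # signed distance (in voxels) into the region along its defining axis.
  ramp <- function(d) pmin(1, pmax(0, d / edge_voxels))

  rois <- list(
    frontal = ramp(Y - ctr[2]) ,
    occipital = ramp(ctr[2] - Y),
    parietal = ramp(Z - ctr[3]) * ramp(X - ctr[1]),
    temporal = ramp(ctr[3] - Z) * ramp(ctr[1] - X),
    callosum = ramp(3 - abs(Z - ctr[3])) *
      array(as.numeric(phantom$labels == 1L), dm),
    periventricular = ramp(6 - abs(X - ctr[1])) * ramp(8 - abs(Y - ctr[2])) *
      ramp(8 - abs(Z - ctr[3]))
  )
  out <- lapply(names(rois), function(nm) {
    p <- rois[[nm]] * brain
    atlas_roi(nm, p)
  })
  names(out) <- names(rois)
  out
}

#' Threshold a probabilistic ROI into a mask
#'
#' Voxels with probability greater than or equal to `threshold` (inclusive,
#' default 75 %) are retained.
#'
#' @param roi an `atlas_roi`.
#' @param threshold probability threshold in `(0, 1]`.
#' @return logical array; a warning is raised if the mask is empty.
#' @export
roi_mask <- function(roi, threshold = 0.75) {
  check_that(threshold > 0 && threshold <= 1, "threshold must be in (0, 1]")
  m <- roi$prob >= threshold
  if (!any(m)) warning("ROI '", roi$name, "' has no voxels at threshold ",
                       threshold, call. = FALSE)
  m
}

#' Split an ROI mask by subject tissue
#'
#' Intersects the ROI mask with the subject-specific WM and GM masks. A
#' per-tissue mask is emitted only when that tissue occupies strictly more
#' than `min_fraction` (default 7 %) of the ROI's voxels, so a region that is
#' essentially single-tissue yields a single row downstream.
#'
#' @param mask logical ROI mask.
#' @param tissue_masks named list of logical arrays (`WM`, `GM`).
#' @param min_fraction minimum within-ROI tissue fraction.
#' @return named list of logical arrays (possibly empty).
#' @export
split_by_tissue <- function(mask, tissue_masks, min_fraction = 0.07) {
  n_roi <- sum(mask)
  out <- list()
  if (n_roi == 0) return(out)
  for (t in names(tissue_masks)) {
    m <- mask & tissue_masks[[t]]
    if (sum(m) / n_roi > min_fraction) out[[t]] <- m
  }
  out
}

#' Per-ROI, per-tissue water statistics for one water map
#'
#' @param water_map 3-D array.
#' @param atlas list of `atlas_roi` objects.
#' @param tissue_masks named list (`WM`, `GM`) of subject tissue masks.
#' @param threshold ROI probability threshold.
#' @param min_fraction tissue-composition rule threshold.
#' @param exclude_mask optional voxels to drop (flagged by the chain).
#' @return data frame with columns `roi`, `tissue`, `mean_water`,
#'   `sd_water`, `n_voxels`. ROIs or tissues failing the rules produce no
#'   row.
#' @export
roi_water_stats <- function(water_map, atlas, tissue_masks,
                            threshold = 0.75, min_fraction = 0.07,
                            exclude_mask = NULL) {
  rows <- list()
  for (roi in atlas) {
    m <- suppressWarnings(roi_mask(roi, threshold))
    if (!any(m)) next
    per_tissue <- split_by_tissue(m, tissue_masks, min_fraction)
    for (t in names(per_tissue)) {
      sel <- per_tissue[[t]]
      if (!is.null(exclude_mask)) sel <- sel & !exclude_mask
      if (!any(sel)) next
      v <- water_map[sel]
      rows[[length(rows) + 1]] <- data.frame(
        roi = roi$name, tissue = t, mean_water = mean(v),
        sd_water = if (length(v) > 1) sd(v) else 0,
        n_voxels = length(v), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(roi = character(), tissue = character(),
                      mean_water = numeric(), sd_water = numeric(),
                      n_voxels = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Tabulate regional water content across a cohort
#'
#' Applies [roi_water_stats()] to each subject/timepoint water map, stamping
#' subject, group and timepoint columns; the result has the shape of a
#' regional water content summary table (one row per subject x timepoint x
#' ROI x tissue).
#'
#' @param maps a list; each element must have `water_map`, `tissue_masks`,
#'   and metadata fields `subject`, `group`, `timepoint` (plus optionally
#'   `exclude_mask`).
#' @param atlas list of `atlas_roi`s.
#' @param threshold,min_fraction masking rules.
#' @return `roi_stats_table` data frame.
#' @export
roi_water_table <- function(maps, atlas, threshold = 0.75,
                            min_fraction = 0.07) {
  out <- lapply(maps, function(m) {
    df <- roi_water_stats(m$water_map, atlas, m$tissue_masks,
                          threshold, min_fraction,
                          exclude_mask = m$exclude_mask)
    if (nrow(df) == 0) return(NULL)
    cbind(data.frame(subject = m$subject, group = m$group,
                     timepoint = m$timepoint, stringsAsFactors = FALSE),
          df)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("roi_stats_table", "data.frame"))
}

#' Write / read an atlas as a directory of NIfTI volumes plus TSV index
#'
#' The on-disk contract matches real probabilistic atlases: one probability
#' NIfTI per region and an `index.tsv` with columns `name`, `file`,
#' `wm_fraction`, `gm_fraction`.
#'
#' @param atlas list of `atlas_roi`s.
#' @param dir directory.
#' @param voxel_mm voxel size for the NIfTI headers.
#' @export
write_atlas <- function(atlas, dir, voxel_mm = c(1, 1, 1)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- data.frame(name = character(), file = character(),
                    wm_fraction = numeric(), gm_fraction = numeric(),
                    stringsAsFactors = FALSE)
  for (roi in atlas) {
    f <- paste0(roi$name, ".nii.gz")
    write_volume(roi$prob, file.path(dir, f), voxel_mm)
    idx[nrow(idx) + 1, ] <- list(roi$name, f,
                                 roi$composition[["wm"]],
                                 roi$composition[["gm"]])
  }
  write.table(idx, file.path(dir, "index.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(dir) {
  idx <- read.delim(file.path(dir, "index.tsv"), stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(idx)), function(i) {
    atlas_roi(idx$name[i], read_volume(file.path(dir, idx$file[i])),
              c(wm = idx$wm_fraction[i], gm = idx$gm_fraction[i]))
  })
  names(out) <- idx$name
  out
}
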