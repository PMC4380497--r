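#' Partial-volume suppression mask
#'
#' Keeps exactly the voxels in which some tissue-class probability equals 1
#' (within `tol`): any voxel with all of its gray matter, white matter and
#' CSF probabilities below one is discarded. This is a deliberately strict
#' rule that trades brain coverage for purity of the retained voxels.
#'
#' @param prob_maps named list of probability arrays (`wm`, `gm`, `csf`).
#' @param tol numerical tolerance on "equals one".
#' @return logical array.
#' @export
pure_tissue_mask <- function(prob_maps, tol = 1e-9) {
  Reduce(`|`, lapply(prob_maps, function(p) p >= 1 - tol))
}

#' Bivariate (water, T1) histogram
#'
#' @param water,t1 numeric vectors of voxel values (same length).
#' @param water_breaks,t1_breaks bin edges (strictly increasing); defaults
#'   cover the physiological range.
#' @return object of class `bivariate_histogram` with `water_edges`,
#'   `t1_edges`, `counts` (matrix water x t1) and `n_voxels`.
#' @export
bivariate_histogram <- function(water, t1,
                                water_breaks = seq(50, 110, by = 0.5),
                                t1_breaks = seq(200, 5000, by = 25)) {
  check_that(length(water) == length(t1), "water and t1 lengths differ")
  keep <- water >= min(water_breaks) & water <= max(water_breaks) &
    t1 >= min(t1_breaks) & t1 <= max(t1_breaks)
  wi <- cut(water[keep], water_breaks, include.lowest = TRUE)
  ti <- cut(t1[keep], t1_breaks, include.lowest = TRUE)
  counts <- table(wi, ti)
  structure(list(water_edges = water_breaks, t1_edges = t1_breaks,
                 counts = unclass(counts), n_voxels = sum(counts)),
            class = "bivariate_histogram")
}

#' Fit a bivariate Gaussian mixture to (water, T1) voxel values
#'
#' Model-based WM/GM discrimination: an EM fit of a `k`-component Gaussian
#' mixture with full (unconstrained) covariances on the voxelwise
#' (water, T1) pairs, via \pkg{mclust}. Initialization uses model-based
#' hierarchical clustering on a seeded subsample, so the fit is reproducible
#' for a fixed seed and invariant to voxel order. Components are relabeled
#' by ascending mean water content, so class 1 is WM and class 2 is GM.
#'
#' @param water,t1 numeric voxel vectors (>= 100 values).
#' @param k number of mixture components (default 2: WM, GM).
#' @param seed integer seed for the fitting/initialization subsample.
#' @param init_subset maximum number of points used for initialization.
#' @param max_fit_voxels EM is run on a seeded random subsample of at most
#'   this many voxels (the Gaussian parameters are estimated to well within
#'   the reporting precision long before this size); all voxels are then
#'   classified under the fitted model.
#' @return object of class `tissue_class_stats`: a data frame with one row
#'   per class (`class`, `mean_water`, `sd_water`, `mean_t1`, `sd_t1`,
#'   `weight`, `n_voxels`), plus the classification vector as attribute
#'   `classification`.
#' @export
fit_bivariate_gmm <- function(water, t1, k = 2L, seed = 1L,
                              init_subset = 1000L, max_fit_voxels = 20000L) {
  check_that(length(water) >= 100, "need at least 100 pure-tissue voxels",
             class = "hydromap_no_pure_voxels")
  X <- cbind(water = water, t1 = t1)
  withr::with_seed(seed, {
    Xfit <- if (nrow(X) > max_fit_voxels)
      X[sample.int(nrow(X), max_fit_voxels), , drop = FALSE] else X
    init <- if (nrow(Xfit) > init_subset) {
      list(subset = sample.int(nrow(Xfit), init_subset))
    } else NULL
    fit <- if (k == 1L) {
      mclust::Mclust(Xfit, G = 1, modelNames = "XXX", verbose = FALSE,
                     initialization = init)
    } else {
      mclust::Mclust(Xfit, G = k, modelNames = "VVV", verbose = FALSE,
                     initialization = init)
    }
  })
  check_that(!is.null(fit), "Gaussian mixture fit failed to converge (k = ",
             k, ", n = ", nrow(X), ")")
  classification <- if (nrow(X) > nrow(Xfit))
    predict(fit, newdata = X)$classification else fit$classification
  mu <- matrix(fit$parameters$mean, nrow = 2)
  ord <- order(mu[1, ])
  cls <- match(classification, ord)
  sigma <- fit$parameters$variance$sigma
  if (is.null(dim(sigma)) || length(dim(sigma)) < 3)
    sigma <- array(sigma, c(2, 2, 1))
  stats <- data.frame(
    class = seq_len(k),
    tissue = if (k == 2L) c("WM", "GM") else paste0("class", seq_len(k)),
    mean_water = mu[1, ord],
    sd_water = sqrt(vapply(ord, function(j) sigma[1, 1, j], numeric(1))),
    mean_t1 = mu[2, ord],
    sd_t1 = sqrt(vapply(ord, function(j) sigma[2, 2, j], numeric(1))),
    weight = fit$parameters$pro[ord],
    n_voxels = as.integer(tabulate(cls, nbins = k)),
    stringsAsFactors = FALSE
  )
  structure(stats, class = c("tissue_class_stats", "data.frame"),
            classification = cls)
}

#' Global WM/GM water content of one subject by mixture classification
#'
#' Composition of [pure_tissue_mask()] and [fit_bivariate_gmm()]: suppresses
#' partial-volume voxels, drops CSF (the normalization reference) and voxels
#' flagged by the correction chain, and fits the 2-component bivariate
#' mixture on the remaining (water, T1) pairs.
#'
#' @param water_map,t1_map maps from the correction chain.
#' @param prob_maps tissue probability maps (list `wm`, `gm`, `csf`).
#' @param seed passed to [fit_bivariate_gmm()].
#' @param exclude_mask optional logical array of voxels to drop (e.g. the
#'   chain's flagged voxels).
#' @param include_csf if `TRUE`, CSF voxels are kept and `k = 3` fitted.
#' @return a `tissue_class_stats` data frame.
#' @export
global_tissue_water <- function(water_map, t1_map, prob_maps, seed = 1L,
                                exclude_mask = NULL, include_csf = FALSE) {
  pure <- pure_tissue_mask(prob_maps)
  check_that(any(pure), "no pure voxels", class = "hydromap_no_pure_voxels")
  if (!include_csf) pure <- pure & !(prob_maps$csf >= 1 - 1e-9)
  if (!is.null(exclude_mask)) pure <- pure & !exclude_mask
  fit_bivariate_gmm(water_map[pure], t1_map[pure],
                    k = if (include_csf) 3L else 2L, seed = seed)
}
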