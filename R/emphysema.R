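# Emphysema extent (%LAA-950 / EI) and emphysema size (D-slope) from
# 3-D size-based clustering of the low-attenuation mask.

#' Emphysema index (%LAA-950) per region
#'
#' Percentage of lung voxels strictly below the threshold (default
#' -950 HU), per reporting region. Boundary voxels at exactly the threshold
#' are not counted as low-attenuation.
#'
#' @param volume A [ct_volume()].
#' @param lungs A [label_mask()] with lung labels (1/2 or lobar 11..22).
#' @param threshold_hu Densitometric threshold, HU.
#' @param regions Regions to report, a subset of [lung_regions()].
#' @return Data frame with columns `region`, `value` (percent, in
#'   \[0, 100\]).
#' @export
emphysema_index <- function(volume, lungs, threshold_hu = -950,
                            regions = lung_regions()) {
  stop_if_misaligned(volume, lungs)
  vox <- volume$voxels
  lab <- lungs$labels
  vals <- vapply(regions, function(rg) {
    sel <- lab %in% region_labels(rg)
    n <- sum(sel)
    if (n == 0L) stop("region error: region '", rg, "' is empty in the mask")
    100 * sum(vox[sel] < threshold_hu) / n
  }, 1.0)
  data.frame(region = regions, value = unname(vals), row.names = NULL)
}

#' Low-attenuation (LAA) mask
#'
#' Logical grid marking lung voxels strictly below the threshold.
#'
#' @inheritParams emphysema_index
#' @param region Restrict to one reporting region (default whole lung).
#' @return Logical 3-D array.
#' @export
laa_mask <- function(volume, lungs, threshold_hu = -950, region = "whole") {
  stop_if_misaligned(volume, lungs)
  volume$voxels < threshold_hu & lungs$labels %in% region_labels(region)
}

#' Emphysema cluster set
#'
#' Container for 3-D emphysema clusters: equivalent-sphere diameters and
#' voxel counts, sorted by ascending diameter.
#'
#' @param diameters_mm Positive equivalent-sphere diameters, mm.
#' @param voxel_counts Positive integer voxel counts, same length.
#' @param spacing Voxel spacing of the grid the clusters came from, mm.
#' @return Object of class `cluster_set`.
#' @export
cluster_set <- function(diameters_mm, voxel_counts, spacing) {
  stopifnot(length(diameters_mm) == length(voxel_counts))
  if (length(diameters_mm)) {
    stopifnot(all(diameters_mm > 0), all(voxel_counts > 0))
    o <- order(diameters_mm)
    diameters_mm <- diameters_mm[o]
    voxel_counts <- voxel_counts[o]
  }
  structure(list(diameters_mm = diameters_mm,
                 voxel_counts = as.integer(voxel_counts),
                 spacing = as.numeric(spacing)),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("Cluster set: %d clusters", length(x$diameters_mm)))
  if (length(x$diameters_mm))
    cat(sprintf(", diameters %.2f-%.2f mm", min(x$diameters_mm),
                max(x$diameters_mm)))
  cat("\n")
  invisible(x)
}

#' 3-D size-based emphysema clustering
#'
#' Labels connected components of the low-attenuation mask (26-connectivity
#' by default, i.e. full 3-D adjacency; 6 available for sensitivity
#' analysis) and converts each component's voxel volume V to an
#' equivalent-sphere diameter `(6 V / pi)^(1/3)`.
#'
#' @param laa Logical 3-D array (see [laa_mask()]).
#' @param spacing Voxel spacing in mm (length 3).
#' @param connectivity 26 (default) or 6.
#' @return A [cluster_set()]; empty mask gives an empty set.
#' @export
cluster_emphysema <- function(laa, spacing, connectivity = 26) {
  stopifnot(is.array(laa), length(dim(laa)) == 3L, is.logical(laa))
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  lab <- .label_components_3d(as.vector(laa), dim(laa),
                              as.integer(connectivity))
  ncomp <- attr(lab, "n_components")
  if (ncomp == 0L)
    return(cluster_set(numeric(0), integer(0), spacing))
  counts <- tabulate(lab, nbins = ncomp)
  vol_mm3 <- counts * prod(spacing)
  cluster_set((6 * vol_mm3 / pi)^(1 / 3), counts, spacing)
}

#' D-slope: power-law exponent of the emphysema cluster-size distribution
#'
#' The cumulative number of clusters with diameter >= d is plotted against
#' d on log10-log10 axes, evaluated at the distinct observed diameters, and
#' fitted by unweighted ordinary least squares. The absolute slope is
#' returned: a steeper (larger) D-slope means smaller emphysema holes.
#' Clusters below `min_diameter_mm` (default twice the voxel spacing) are
#' discarded first to suppress single-voxel noise components.
#'
#' @param clusters A [cluster_set()], or a numeric vector of diameters.
#' @param min_diameter_mm Minimum diameter retained, mm. Defaults to twice
#'   the mean voxel spacing when `clusters` is a `cluster_set`, else 0.
#' @return The positive D-slope (absolute fitted slope).
#' @export
d_slope <- function(clusters, min_diameter_mm = NULL) {
  if (inherits(clusters, "cluster_set")) {
    d <- clusters$diameters_mm
    if (is.null(min_diameter_mm)) min_diameter_mm <- 2 * mean(clusters$spacing)
  } else {
    d <- as.numeric(clusters)
    if (is.null(min_diameter_mm)) min_diameter_mm <- 0
  }
  d <- d[d >= min_diameter_mm]
  dd <- sort(unique(d))
  if (length(dd) < 2L)
    stop("insufficient data: D-slope needs >= 2 distinct cluster diameters",
         " at or above ", format(min_diameter_mm), " mm")
  cum <- vapply(dd, function(x) sum(d >= x), 1.0)
  fit <- lm(log10(cum) ~ log10(dd))
  abs(unname(coef(fit)[2]))
}
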