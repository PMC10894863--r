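#' CT volume container
#'
#' A 3-D grid of Hounsfield-unit values with physical voxel spacing and
#' origin, the raw input for all quantitative measures. HU values are
#' clamped to \[-1100, 3100\] on construction: densitometric thresholds
#' assume calibrated HU and values outside that range are nonphysical.
#'
#' Voxel index order is (x, y, z); index `(i, j, k)` (1-based) maps to the
#' physical point `origin + (c(i, j, k) - 1) * spacing` in mm.
#'
#' @param voxels 3-D numeric array of HU values.
#' @param spacing Numeric length-3, voxel spacing in mm (all > 0).
#' @param origin Numeric length-3, physical position of voxel (1,1,1) in mm.
#' @return An object of class `ct_volume` with elements `voxels`, `spacing`,
#'   `origin`.
#' @export
ct_volume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3-D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)")
  storage.mode(voxels) <- "double"
  voxels[voxels < -1100] <- -1100
  voxels[voxels > 3100] <- 3100
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "ct_volume")
}

#' Integer label mask aligned to a CT volume
#'
#' @param labels 3-D array of non-negative integer labels (0 = background).
#' @param spacing,origin As in [ct_volume()].
#' @param schema Named integer vector mapping region names to labels;
#'   defaults to [lung_label_schema()].
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(labels, spacing, origin = c(0, 0, 0),
                       schema = lung_label_schema()) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3-D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite values (mm)")
  storage.mode(labels) <- "integer"
  if (anyNA(labels) || min(labels) < 0L)
    stop("labels must be non-negative integers")
  structure(list(labels = labels, spacing = spacing, origin = origin,
                 schema = schema),
            class = "label_mask")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("CT volume: %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  HU range [%.0f, %.0f], origin (%.4g, %.4g, %.4g) mm\n",
              min(x$voxels), max(x$voxels),
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' @export
print.label_mask <- function(x, ...) {
  d <- dim(x$labels)
  tab <- table(x$labels[x$labels > 0L])
  cat(sprintf("Label mask: %d x %d x %d voxels, %d labelled voxels in %d labels\n",
              d[1], d[2], d[3], sum(tab), length(tab)))
  invisible(x)
}

grid_of <- function(x) {
  if (inherits(x, "ct_volume")) {
    list(dim = dim(x$voxels), spacing = x$spacing, origin = x$origin)
  } else if (inherits(x, "label_mask")) {
    list(dim = dim(x$labels), spacing = x$spacing, origin = x$origin)
  } else stop("expected a ct_volume or label_mask")
}

#' Check that a volume and a mask share the same grid
#'
#' True iff the shapes are equal and spacing and origin agree within
#' 1e-6 mm. A pure predicate: never errors on mismatch.
#'
#' @param volume A [ct_volume()] (or another mask).
#' @param mask A [label_mask()] (or another volume).
#' @param tol_mm Agreement tolerance in mm.
#' @return Logical scalar.
#' @export
validate_aligned <- function(volume, mask, tol_mm = 1e-6) {
  a <- grid_of(volume); b <- grid_of(mask)
  identical(a$dim, b$dim) &&
    all(abs(a$spacing - b$spacing) <= tol_mm) &&
    all(abs(a$origin - b$origin) <= tol_mm)
}

stop_if_misaligned <- function(volume, mask) {
  if (!validate_aligned(volume, mask))
    stop("mask is not aligned with the volume (shape/spacing/origin mismatch)")
  invisible(TRUE)
}

# Trilinear (or nearest) sampling of a 3-D array at physical points.
# pts: n x 3 matrix of physical coordinates (mm). Points outside the grid
# are clamped to the border.
sample_volume <- function(arr, spacing, origin, pts,
                          interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  d <- dim(arr)
  # fractional 1-based voxel index
  fx <- (pts[, 1] - origin[1]) / spacing[1] + 1
  fy <- (pts[, 2] - origin[2]) / spacing[2] + 1
  fz <- (pts[, 3] - origin[3]) / spacing[3] + 1
  if (interpolation == "nearest") {
    ix <- pmin(pmax(round(fx), 1), d[1])
    iy <- pmin(pmax(round(fy), 1), d[2])
    iz <- pmin(pmax(round(fz), 1), d[3])
    return(arr[cbind(ix, iy, iz)])
  }
  fx <- pmin(pmax(fx, 1), d[1]); fy <- pmin(pmax(fy, 1), d[2])
  fz <- pmin(pmax(fz, 1), d[3])
  x0 <- pmin(floor(fx), d[1] - 1); y0 <- pmin(floor(fy), d[2] - 1)
  z0 <- pmin(floor(fz), d[3] - 1)
  if (d[1] == 1L) x0 <- rep(1, length(fx))
  if (d[2] == 1L) y0 <- rep(1, length(fy))
  if (d[3] == 1L) z0 <- rep(1, length(fz))
  tx <- fx - x0; ty <- fy - y0; tz <- fz - z0
  g <- function(i, j, k) arr[cbind(i, j, k)]
  x1 <- pmin(x0 + 1, d[1]); y1 <- pmin(y0 + 1, d[2]); z1 <- pmin(z0 + 1, d[3])
  c000 <- g(x0, y0, z0); c100 <- g(x1, y0, z0)
  c010 <- g(x0, y1, z0); c110 <- g(x1, y1, z0)
  c001 <- g(x0, y0, z1); c101 <- g(x1, y0, z1)
  c011 <- g(x0, y1, z1); c111 <- g(x1, y1, z1)
  c00 <- c000 * (1 - tx) + c100 * tx
  c10 <- c010 * (1 - tx) + c110 * tx
  c01 <- c001 * (1 - tx) + c101 * tx
  c11 <- c011 * (1 - tx) + c111 * tx
  c0 <- c00 * (1 - ty) + c10 * ty
  c1 <- c01 * (1 - ty) + c11 * ty
  c0 * (1 - tz) + c1 * tz
}

#' Resample a volume or mask to isotropic spacing
#'
#' Resamples onto an isotropic grid of spacing `target_mm`, preserving the
#' physical extent within one voxel. Grid nodes are placed so that the first
#' node coincides with the input origin; when `target_mm` equals the input
#' spacing on every axis the voxels are returned unchanged. Nearest-neighbour
#' interpolation is mandatory for masks.
#'
#' @param volume A [ct_volume()] or [label_mask()].
#' @param target_mm Positive target spacing in mm.
#' @param interpolation `"linear"` (volumes) or `"nearest"` (masks).
#' @return Object of the same class on the isotropic grid.
#' @export
resample_isotropic <- function(volume, target_mm,
                               interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (!is.numeric(target_mm) || length(target_mm) != 1L || target_mm <= 0)
    stop("`target_mm` must be a positive number")
  is_mask <- inherits(volume, "label_mask")
  if (is_mask && interpolation != "nearest")
    stop("masks must be resampled with nearest interpolation")
  g <- grid_of(volume)
  arr <- if (is_mask) volume$labels else volume$voxels
  if (all(abs(g$spacing - target_mm) < 1e-12)) return(volume)
  newdim <- pmax(1L, as.integer(round((g$dim - 1) * g$spacing / target_mm)) + 1L)
  xs <- g$origin[1] + (seq_len(newdim[1]) - 1) * target_mm
  ys <- g$origin[2] + (seq_len(newdim[2]) - 1) * target_mm
  zs <- g$origin[3] + (seq_len(newdim[3]) - 1) * target_mm
  pts <- cbind(rep(xs, times = newdim[2] * newdim[3]),
               rep(rep(ys, each = newdim[1]), times = newdim[3]),
               rep(zs, each = newdim[1] * newdim[2]))
  vals <- sample_volume(arr, g$spacing, g$origin, pts, interpolation)
  out <- array(vals, dim = newdim)
  if (is_mask) {
    label_mask(out, spacing = rep(target_mm, 3), origin = g$origin,
               schema = volume$schema)
  } else {
    ct_volume(out, spacing = rep(target_mm, 3), origin = g$origin)
  }
}
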