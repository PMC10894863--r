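# Peripheral pulmonary vessel quantification: vessels with cross-section
# under 5 mm2 are counted where they pierce the surface 12 mm deep to the
# pleura, normalized per cm2 of that surface.

# Shell-voxel counting underestimates the area of an isotropically oriented
# iso-surface by the mean largest normal component E[max|n_i|] = 0.8314
# (Monte-Carlo over uniform orientations); the inverse is applied as a
# fixed correction.
SHELL_AREA_CORRECTION <- 1 / 0.8314

#' Subpleural counting surface at a fixed depth
#'
#' Computes the Euclidean distance transform of the lung mask (distance of
#' every lung voxel to the nearest non-lung voxel) and extracts the
#' one-voxel-thick iso-surface where the distance crosses `depth_mm`: lung
#' voxels at distance >= depth with a 6-neighbour below depth. The surface
#' area is estimated as shell voxel count times the mean in-plane voxel
#' area, corrected for orientation (see `SHELL_AREA_CORRECTION`).
#'
#' @param lungs A [label_mask()] whose non-zero voxels fill the lung
#'   interior out to the pleura (use solid lobar territories, not a
#'   parenchyma mask with carved-out airways).
#' @param depth_mm Depth of the counting surface below the pleura, mm.
#' @return Object of class `subpleural_surface`: linear voxel `indices` of
#'   the shell, their `region_labels` (copied from the mask), the grid
#'   `dim`/`spacing`, `area_cm2`, and `depth_mm`.
#' @export
peripheral_surface <- function(lungs, depth_mm = 12) {
  stopifnot(inherits(lungs, "label_mask"), depth_mm > 0)
  lab <- lungs$labels
  dims <- dim(lab)
  inside <- lab > 0L
  if (!any(inside)) stop("lung mask is empty")
  d <- array(.edt_3d(as.vector(inside), dims, lungs$spacing), dim = dims)
  deep <- d >= depth_mm
  if (!any(deep))
    stop("empty surface: no lung voxel reaches a depth of ", depth_mm, " mm")
  shallow_nb <- shift_any_less(d, depth_mm)
  shell <- inside & deep & shallow_nb
  idx <- which(shell)
  inplane <- mean(lungs$spacing[1:2])
  area <- length(idx) * inplane^2 * SHELL_AREA_CORRECTION / 100
  # distance slab [depth, depth + voxel): same surface, but contiguous
  # through its thickness, so a vessel piercing it cannot split into
  # spurious components the way the 6-neighbour iso-surface can
  slab <- which(inside & deep & d < depth_mm + max(lungs$spacing))
  structure(list(indices = idx, region_labels = lab[idx],
                 slab_indices = slab, slab_region_labels = lab[slab],
                 dim = dims, spacing = lungs$spacing, area_cm2 = area,
                 depth_mm = depth_mm),
            class = "subpleural_surface")
}

#' @export
print.subpleural_surface <- function(x, ...) {
  cat(sprintf("Subpleural surface at %.1f mm: %d voxels, %.1f cm2\n",
              x$depth_mm, length(x$indices), x$area_cm2))
  invisible(x)
}

# TRUE where any 6-neighbour of a voxel has d < depth (border-padded with
# its own value, so the volume border never creates shell voxels)
shift_any_less <- function(d, depth) {
  dims <- dim(d)
  out <- array(FALSE, dims)
  below <- d < depth
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  out[-1, , ] <- out[-1, , ] | below[-nx, , ]
  out[-nx, , ] <- out[-nx, , ] | below[-1, , ]
  out[, -1, ] <- out[, -1, ] | below[, -ny, ]
  out[, -ny, ] <- out[, -ny, ] | below[, -1, ]
  out[, , -1] <- out[, , -1] | below[, , -nz]
  out[, , -nz] <- out[, , -nz] | below[, , -1]
  out
}

#' Count peripheral vessels crossing the subpleural surface
#'
#' Intersects the vessel mask with the counting surface; each 26-connected
#' component of the intersection is one vessel crossing with area equal to
#' its voxel count times the mean in-plane voxel area. Crossings with area
#' strictly below `max_area_mm2` are counted and normalized per cm2 of the
#' (regional) surface.
#'
#' @param vessels A [label_mask()] of vessel voxels (non-zero = vessel),
#'   aligned with the lung grid the surface was built from.
#' @param surface A [peripheral_surface()] result.
#' @param max_area_mm2 Inclusion threshold on crossing area (strict `<`).
#' @param regions Regions to report (regional assignment comes from the
#'   surface's mask labels; a crossing belongs to the majority label of its
#'   voxels).
#' @return Data frame with columns `region`, `n_crossings`, `area_cm2`
#'   (regional surface area), `vn_per_cm2`.
#' @export
count_peripheral_vessels <- function(vessels, surface, max_area_mm2 = 5,
                                     regions = lung_regions()) {
  stopifnot(inherits(vessels, "label_mask"),
            inherits(surface, "subpleural_surface"))
  if (!identical(dim(vessels$labels), surface$dim) ||
      any(abs(vessels$spacing - surface$spacing) > 1e-6))
    stop("vessel mask is not aligned with the surface grid")
  inter <- array(FALSE, surface$dim)
  inter[surface$slab_indices] <- TRUE
  inter <- inter & vessels$labels > 0L
  lab <- .label_components_3d(as.vector(inter), surface$dim, 26L)
  ncomp <- attr(lab, "n_components")
  inplane <- mean(surface$spacing[1:2])
  slab_region <- integer(prod(surface$dim))
  slab_region[surface$slab_indices] <- surface$slab_region_labels
  comp_region <- integer(0)
  comp_area <- numeric(0)
  iso <- logical(prod(surface$dim))
  iso[surface$indices] <- TRUE
  if (ncomp > 0L) {
    hit <- which(lab > 0L)
    # area from the one-voxel iso-surface members of each component: the
    # slab gives robust connectivity, the iso-surface an area estimate
    # that cannot double-count through the slab thickness
    counts <- vapply(split(iso[hit], lab[hit]), sum, 1L)
    comp_area <- counts * inplane^2
    # majority mask label over each component's voxels
    comp_region <- vapply(split(slab_region[hit], lab[hit]), function(v) {
      tb <- table(v)
      as.integer(names(tb)[which.max(tb)])
    }, 1L)
  }
  res <- lapply(regions, function(rg) {
    labs <- region_labels(rg)
    n_area <- sum(surface$region_labels %in% labs) * inplane^2 *
      SHELL_AREA_CORRECTION / 100
    n_cross <- sum(comp_region %in% labs & comp_area < max_area_mm2)
    data.frame(region = rg, n_crossings = n_cross, area_cm2 = n_area,
               vn_per_cm2 = if (n_area > 0) n_cross / n_area else NA_real_)
  })
  do.call(rbind, res)
}
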