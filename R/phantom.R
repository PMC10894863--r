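# Synthetic lung phantom with known ground truth: two ellipsoidal lungs of
# noisy parenchyma (~ -850 HU), emphysema "holes" at -1024 HU with a
# truncated-Pareto cluster-size distribution, airway tubes of known lumen
# radius and wall thickness, and subpleural vessel cylinders of known
# cross-section. Every downstream quantifier can be checked against the
# construction.

#' Specification of a synthetic lung phantom
#'
#' Defaults emulate an obstructive-lung-disease scan: parenchyma at
#' -850 HU, emphysema occupying 12.2% of lung voxels (a cohort-mean
#' emphysema index), a truncated-Pareto cluster-size distribution with
#' exponent 3.5, six measurable airway generations (3-8), and 56
#' subpleural vessels under 5 mm2.
#'
#' @param lung_semiaxes_mm Ellipsoid semi-axes (x, y, z) of each lung, mm.
#' @param lung_gap_mm Mediastinal gap between the two lungs, mm.
#' @param margin_mm Background margin around the lungs, mm (>= 15 so the
#'   distance transform is unaffected by the volume border).
#' @param spacing_mm Isotropic voxel spacing, mm.
#' @param parenchyma_hu_mean,parenchyma_hu_sd Normal parenchyma HU model.
#' @param emphysema_fraction Target fraction of lung voxels at -1024 HU.
#' @param cluster_exponent Power-law (Pareto) exponent of emphysema-cluster
#'   diameters; larger means smaller holes.
#' @param diameter_range_mm Truncation range (min, max) of cluster
#'   diameters, mm; min must be >= 2 voxels.
#' @param airway_generations Data frame with columns `generation`,
#'   `inner_radius_mm`, `wall_thickness_mm`; one tube per generation is
#'   placed in each lung.
#' @param vessel_areas_mm2 Cross-sectional areas of the subpleural vessel
#'   cylinders, mm2.
#' @param vessel_depth_range_mm Depth span (along the inward surface
#'   normal) of each vessel cylinder, mm; must bracket the 12 mm counting
#'   surface.
#' @param seed RNG seed; generation is fully deterministic given the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(lung_semiaxes_mm = c(22, 28, 48),
                         lung_gap_mm = 10,
                         margin_mm = 15,
                         spacing_mm = 1,
                         parenchyma_hu_mean = -850,
                         parenchyma_hu_sd = 15,
                         emphysema_fraction = 0.122,
                         cluster_exponent = 3.5,
                         diameter_range_mm = c(3 * spacing_mm, 12),
                         airway_generations = default_airway_generations(),
                         vessel_areas_mm2 = rep(c(1, 1.8, 2.6, 3.4), 14),
                         vessel_depth_range_mm = c(3, 16),
                         seed = 1L) {
  stopifnot(length(lung_semiaxes_mm) == 3, all(lung_semiaxes_mm > 0),
            spacing_mm > 0, margin_mm >= 0, lung_gap_mm >= 0)
  if (emphysema_fraction < 0 || emphysema_fraction >= 1)
    stop("emphysema_fraction must be in [0, 1)")
  if (cluster_exponent <= 0) stop("cluster_exponent must be > 0")
  if (diameter_range_mm[1] < 2 * spacing_mm)
    stop("minimum cluster diameter must be at least 2 voxels")
  if (diameter_range_mm[2] <= diameter_range_mm[1])
    stop("diameter_range_mm must be increasing")
  ag <- airway_generations
  if (!all(c("generation", "inner_radius_mm", "wall_thickness_mm") %in%
           names(ag)))
    stop("airway_generations needs generation, inner_radius_mm, wall_thickness_mm")
  if (any(ag$inner_radius_mm <= 0) || any(ag$wall_thickness_mm <= 0))
    stop("airway radii and wall thicknesses must be > 0")
  if (any(vessel_areas_mm2 <= 0)) stop("vessel areas must be > 0")
  if (vessel_depth_range_mm[1] >= 12 || vessel_depth_range_mm[2] <= 12)
    stop("vessel_depth_range_mm must bracket the 12 mm counting depth")
  structure(list(lung_semiaxes_mm = lung_semiaxes_mm,
                 lung_gap_mm = lung_gap_mm, margin_mm = margin_mm,
                 spacing_mm = spacing_mm,
                 parenchyma_hu_mean = parenchyma_hu_mean,
                 parenchyma_hu_sd = parenchyma_hu_sd,
                 emphysema_fraction = emphysema_fraction,
                 cluster_exponent = cluster_exponent,
                 diameter_range_mm = diameter_range_mm,
                 airway_generations = ag,
                 vessel_areas_mm2 = vessel_areas_mm2,
                 vessel_depth_range_mm = vessel_depth_range_mm,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @export
default_airway_generations <- function() {
  data.frame(generation = 3:8,
             inner_radius_mm = c(2.5, 2.1, 1.8, 1.5, 1.25, 1.0),
             wall_thickness_mm = c(1.4, 1.25, 1.1, 1.0, 0.9, 0.8))
}

# run code with a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  code
}

# truncated Pareto on [lo, hi] with tail exponent k (density ~ d^-(k+1))
rtrunc_pareto <- function(n, k, lo, hi) {
  u <- runif(n)
  (lo^-k - u * (lo^-k - hi^-k))^(-1 / k)
}

#' @rdname rtrunc_pareto_doc
#' @noRd
ptrunc_pareto <- function(q, k, lo, hi) {
  p <- (lo^-k - pmin(pmax(q, lo), hi)^-k) / (lo^-k - hi^-k)
  pmin(pmax(p, 0), 1)
}

#' Generate a synthetic lung phantom
#'
#' Builds the CT volume, label masks, and ground truth defined by a
#' [phantom_spec()]. Emphysema spheres are packed without overlap (largest
#' first, rejection sampling) until the target voxel fraction is reached;
#' ground truth is computed from the realized voxel grid, not the analytic
#' spec, so recovery tests are exact rather than discretization-limited.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `lung_phantom`: list with elements
#'   \describe{
#'     \item{volume}{[ct_volume()] of HU values.}
#'     \item{masks}{List of [label_mask()]: `lungs` (solid lobar
#'       territories bounded by the pleura), `lobes` (parenchyma-only lobar
#'       labels, excluding airway and vessel voxels), `airway` (lumen 30,
#'       wall 31), `vessels` (40).}
#'     \item{truth}{Ground truth: realized per-region emphysema index,
#'       realized cluster diameters and their D-slope, analytic per-tube
#'       airway geometry and Pi10, per-region vessel-crossing counts.}
#'     \item{sites}{Airway measurement sites (one per tube).}
#'     \item{spec}{The input spec.}
#'   }
#' @export
generate_lung_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, build_phantom(spec))
}

build_phantom <- function(spec) {
  h <- spec$spacing_mm
  ax <- spec$lung_semiaxes_mm
  a <- ax[1]; b <- ax[2]; cc <- ax[3]
  gap <- spec$lung_gap_mm; mar <- spec$margin_mm
  cxr <- -(gap / 2 + a)   # right lung centre (patient right = -x)
  cxl <- +(gap / 2 + a)
  ext_x <- gap / 2 + 2 * a + mar
  xs <- seq(-ext_x, ext_x, by = h)
  ys <- seq(-(b + mar), b + mar, by = h)
  zs <- seq(-(cc + mar), cc + mar, by = h)
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  dims <- c(nx, ny, nz)
  origin <- c(xs[1], ys[1], zs[1])
  nxny <- nx * ny

  # solid lobar territories, slice by slice
  exr <- ((xs - cxr) / a)^2; exl <- ((xs - cxl) / a)^2
  ey <- (ys / b)^2; ez <- (zs / cc)^2
  m_r <- outer(exr, ey, "+"); m_l <- outer(exl, ey, "+")
  lungs_solid <- integer(nx * ny * nz)
  for (k in seq_len(nz)) {
    in_r <- m_r + ez[k] <= 1
    in_l <- m_l + ez[k] <= 1
    zf <- zs[k] / cc
    lab_r <- if (zf > 0.3) 11L else if (zf > 0) 12L else 13L
    lab_l <- if (zf > 0.05) 21L else 22L
    sl <- integer(nxny)
    sl[in_r] <- lab_r
    sl[in_l] <- lab_l
    lungs_solid[(k - 1L) * nxny + seq_len(nxny)] <- sl
  }
  dim(lungs_solid) <- dims
  in_lung <- lungs_solid > 0L

  # volume: soft tissue background, noisy parenchyma inside the lungs
  vol <- array(50, dim = dims)
  n_in <- sum(in_lung)
  vol[in_lung] <- spec$parenchyma_hu_mean +
    if (spec$parenchyma_hu_sd > 0) rnorm(n_in, 0, spec$parenchyma_hu_sd) else 0

  structures <- integer(nx * ny * nz)  # 30/31 airway, 40 vessels
  dim(structures) <- dims

  # ---- airway tubes (one per generation per lung, parallel to z) ----------
  ag <- spec$airway_generations
  ngen <- nrow(ag)
  sites <- NULL
  truth_airway <- NULL
  zmin_t <- -0.45 * cc; zmax_t <- 0.45 * cc
  kz <- which(zs >= zmin_t & zs <= zmax_t)
  for (side in c("right", "left")) {
    cx <- if (side == "right") cxr else cxl
    for (i in seq_len(ngen)) {
      th <- 2 * pi * (i - 0.5) / ngen
      x0 <- cx + 0.45 * a * cos(th)
      y0 <- 0.45 * b * sin(th)
      r <- ag$inner_radius_mm[i]; w <- ag$wall_thickness_mm[i]
      ixr <- which(abs(xs - x0) <= r + w + h)
      iyr <- which(abs(ys - y0) <= r + w + h)
      rad2 <- sqrt(outer((xs[ixr] - x0)^2, (ys[iyr] - y0)^2, "+"))
      lin2 <- outer(ixr, (iyr - 1L) * nx, "+")
      # partial-volume (one-voxel linear ramp) edges, as a CT point-spread
      # function would produce; half-maximum edge detection then recovers
      # the true radii
      f_in <- pmin(pmax((rad2 - (r - h / 2)) / h, 0), 1)
      f_out <- pmin(pmax((rad2 - (r + w - h / 2)) / h, 0), 1)
      touched <- rad2 <= r + w + h / 2
      base <- (1 - f_in[touched]) * -1000  # lumen/wall mix (wall = 0 HU)
      fo <- f_out[touched]
      lin_t <- lin2[touched]
      lab_t <- ifelse(rad2[touched] < r, 30L, 31L)
      offs <- (kz - 1L) * nxny
      nt <- length(lin_t)
      lin <- rep(lin_t, length(offs)) + rep(offs, each = nt)
      vol[lin] <- rep(base, length(offs)) +
        rep(fo, length(offs)) * (vol[lin] - rep(base, length(offs)))
      structures[lin] <- rep(lab_t, length(offs))
      sites <- rbind(sites, data.frame(
        x_mm = x0, y_mm = y0, z_mm = 0,
        axis_x = 0, axis_y = 0, axis_z = 1,
        generation = ag$generation[i], region = side))
      truth_airway <- rbind(truth_airway, data.frame(
        region = side, generation = ag$generation[i],
        inner_radius_mm = r, wall_thickness_mm = w,
        pi_mm = 2 * pi * r, wa_mm2 = pi * ((r + w)^2 - r^2)))
    }
  }

  # ---- subpleural vessel cylinders ----------------------------------------
  # Each vessel runs along the local gradient of the depth map (the true
  # "radial" direction), so it pierces the 12-mm counting surface exactly
  # once and perpendicularly, making the crossing count and area of the
  # construction unambiguous.
  dr <- spec$vessel_depth_range_mm
  n_ves <- length(spec$vessel_areas_mm2)
  edt_solid <- .edt_3d(as.vector(in_lung), dims, rep(h, 3))
  darr <- array(edt_solid, dims)
  slab_pool <- which(edt_solid >= 12 & edt_solid < 12 + h)
  ves_samples <- NULL  # points along every accepted centreline
  zcuts <- c(0.3, 0, 0.05) * cc  # lobe boundary planes
  truth_vessels <- NULL
  tseq <- seq(0, 1, length.out = 16)
  for (j in seq_len(n_ves)) {
    area <- spec$vessel_areas_mm2[j]
    r <- sqrt(area / pi)
    side <- if (j %% 2 == 1) "right" else "left"
    side_labs <- if (side == "right") c(11L, 12L, 13L) else c(21L, 22L)
    placed <- FALSE
    for (try in seq_len(4000)) {
      ci <- slab_pool[sample.int(length(slab_pool), 1L)]
      if (!(lungs_solid[ci] %in% side_labs)) next
      k <- (ci - 1L) %/% nxny
      rem <- (ci - 1L) %% nxny
      jj <- rem %/% nx
      ii <- rem %% nx
      if (ii < 2L || ii > nx - 3L || jj < 2L || jj > ny - 3L ||
          k < 2L || k > nz - 3L) next
      pos <- c(xs[ii + 1L], ys[jj + 1L], zs[k + 1L])
      if (any(abs(pos[3] - zcuts) < 3)) next  # unambiguous lobe
      # depth gradient by central differences
      g <- c(darr[ii + 2L, jj + 1L, k + 1L] - darr[ii, jj + 1L, k + 1L],
             darr[ii + 1L, jj + 2L, k + 1L] - darr[ii + 1L, jj, k + 1L],
             darr[ii + 1L, jj + 1L, k + 2L] - darr[ii + 1L, jj + 1L, k]) /
        (2 * h)
      gn <- sqrt(sum(g^2))
      if (gn < 0.5) next  # medial-axis neighbourhood, direction unstable
      g <- g / gn
      d0 <- darr[ii + 1L, jj + 1L, k + 1L]
      p0 <- pos - (d0 - dr[1]) * g   # shallow end
      p1 <- pos + (dr[2] - d0) * g   # deep end
      samp <- cbind(p0[1] + tseq * (p1[1] - p0[1]),
                    p0[2] + tseq * (p1[2] - p0[2]),
                    p0[3] + tseq * (p1[3] - p0[3]))
      # depth must grow monotonically along the centreline (single crossing)
      si <- round(sweep(samp, 2, origin) / h) + 1
      if (any(si < 1) || any(si[, 1] > nx) || any(si[, 2] > ny) ||
          any(si[, 3] > nz)) next
      dsamp <- darr[si]
      # exactly one crossing of the counting depth, well clear on each side
      deep_min <- 12 + min(1.5, (dr[2] - 12) / 2)
      if (sum(diff(dsamp >= 12) != 0) != 1 || any(diff(dsamp) < -0.5) ||
          dsamp[1] > dr[1] + 1.5 || dsamp[length(dsamp)] < deep_min) next
      if (!is.null(ves_samples) &&
          min(fields_dist(samp, ves_samples)) < 2 * r + 4) next
      idx <- raster_cylinder(p0, p1, r, xs, ys, zs, dims)
      if (length(idx) == 0L) next
      if (any(structures[idx] != 0L)) next
      if (!all(in_lung[idx])) next
      vol[idx] <- 100
      structures[idx] <- 40L
      ves_samples <- rbind(ves_samples, samp)
      truth_vessels <- rbind(truth_vessels, data.frame(
        area_mm2 = area, lobe_label = lungs_solid[ci], side = side))
      placed <- TRUE
      break
    }
    if (!placed)
      stop("generation error: could not place vessel ", j,
           " without conflicts")
  }

  # parenchyma lobar labels exclude airway and vessel voxels
  lobes <- lungs_solid
  lobes[structures != 0L] <- 0L
  n_lung <- sum(lobes > 0L)

  # ---- emphysema spheres (non-overlapping, largest first) -----------------
  cluster_counts <- numeric(0)
  target_d <- numeric(0)
  if (spec$emphysema_fraction > 0) {
    dlo <- spec$diameter_range_mm[1]; dhi <- spec$diameter_range_mm[2]
    kexp <- spec$cluster_exponent
    target_vox <- spec$emphysema_fraction * n_lung
    ds <- numeric(0); cumvox <- 0
    while (cumvox < target_vox) {
      d <- rtrunc_pareto(1000, kexp, dlo, dhi)
      ds <- c(ds, d)
      cumvox <- sum(pi / 6 * ds^3 / h^3)
      if (cumvox >= target_vox) {
        keep <- which(cumsum(pi / 6 * ds^3 / h^3) >= target_vox)[1]
        ds <- ds[seq_len(keep)]
        break
      }
    }
    target_d <- ds
    ordd <- order(ds, decreasing = TRUE)
    ds <- ds[ordd]
    pool <- which(as.vector(lobes) > 0L)
    centers <- matrix(NA_real_, length(ds), 3)
    radii <- ds / 2
    sep <- 1.75 * h  # keeps rasterized spheres 26-disconnected
    total_budget <- 10 * length(ds) * 60
    tries_total <- 0
    placed_n <- 0
    cluster_counts <- numeric(length(ds))
    for (s in seq_along(ds)) {
      r <- radii[s]
      ok <- FALSE
      for (try in seq_len(5000)) {
        tries_total <- tries_total + 1
        if (tries_total > total_budget)
          stop("generation error: emphysema packing infeasible for the ",
               "requested fraction and diameter range")
        ci <- pool[sample.int(length(pool), 1L)]
        if (edt_solid[ci] <= r + h) next
        k <- (ci - 1L) %/% nxny
        rem <- (ci - 1L) %% nxny
        jj <- rem %/% nx
        ii <- rem %% nx
        cen <- c(xs[ii + 1L], ys[jj + 1L], zs[k + 1L])
        if (placed_n > 0) {
          dd <- sqrt(colSums((t(centers[seq_len(placed_n), , drop = FALSE]) -
                                cen)^2))
          if (any(dd < radii[seq_len(placed_n)] + r + sep)) next
        }
        idx <- raster_ball(cen, r, xs, ys, zs, dims)
        if (length(idx) == 0L) next
        if (any(structures[idx] != 0L)) next
        vol[idx] <- -1024
        placed_n <- placed_n + 1
        centers[placed_n, ] <- cen
        cluster_counts[placed_n] <- length(idx)
        ok <- TRUE
        break
      }
      if (!ok)
        stop("generation error: emphysema packing infeasible (retry cap hit)")
    }
    cluster_counts <- cluster_counts[seq_len(placed_n)]
  }

  volume <- ct_volume(vol, spacing = rep(h, 3), origin = origin)
  masks <- list(
    lungs = label_mask(lungs_solid, rep(h, 3), origin),
    lobes = label_mask(lobes, rep(h, 3), origin),
    airway = label_mask(array(ifelse(structures == 30L | structures == 31L,
                                     structures, 0L), dims),
                        rep(h, 3), origin),
    vessels = label_mask(array(ifelse(structures == 40L, 40L, 0L), dims),
                         rep(h, 3), origin))

  # ---- ground truth from the realized grid --------------------------------
  ei <- vapply(lung_regions(), function(rg) {
    sel <- masks$lobes$labels %in% region_labels(rg)
    100 * sum(vol[sel] < -950) / sum(sel)
  }, 1.0)
  realized_d <- sort((6 * cluster_counts * h^3 / pi)^(1 / 3))
  dsl <- tryCatch(
    d_slope(cluster_set(realized_d, sort(cluster_counts),
                        spacing = rep(h, 3))),
    error = function(e) NA_real_)
  pi10_truth <- vapply(c("whole", "right", "left"), function(rg) {
    ta <- truth_airway
    if (rg != "whole") ta <- ta[ta$region == rg, ]
    unname(coef(lm(sqrt(wa_mm2) ~ pi_mm, data = ta)) %*% c(1, 10))
  }, 1.0)
  lobe_to_region <- c(`11` = "RUL", `12` = "RML", `13` = "RLL",
                      `21` = "LUL", `22` = "LLL")
  vreg <- lobe_to_region[as.character(truth_vessels$lobe_label)]
  vn_counts <- vapply(lung_regions(), function(rg) {
    labs <- region_labels(rg)
    sum(truth_vessels$lobe_label %in% labs & truth_vessels$area_mm2 < 5)
  }, 1L)

  truth <- list(
    ei_percent = data.frame(region = lung_regions(), value = unname(ei)),
    cluster_diameters_mm = realized_d,
    cluster_voxel_counts = sort(cluster_counts),
    cluster_target_diameters_mm = target_d,
    d_slope = dsl,
    airway = truth_airway,
    pi10_mm = data.frame(region = c("whole", "right", "left"),
                         value = unname(pi10_truth)),
    vessels = transform(truth_vessels, region = unname(vreg)),
    vessel_counts = data.frame(region = lung_regions(),
                               n_crossings = unname(vn_counts)),
    n_lung_voxels = n_lung,
    laa_fraction = sum(vol[masks$lobes$labels > 0L] < -950) / n_lung,
    seed = spec$seed)

  structure(list(volume = volume, masks = masks, truth = truth,
                 sites = sites, spec = spec),
            class = "lung_phantom")
}

#' @export
print.lung_phantom <- function(x, ...) {
  d <- dim(x$volume$voxels)
  cat(sprintf("Lung phantom: %d x %d x %d voxels at %.3g mm\n",
              d[1], d[2], d[3], x$spec$spacing_mm))
  cat(sprintf("  %d emphysema clusters (LAA fraction %.4f), %d airway tubes, %d vessels\n",
              length(x$truth$cluster_diameters_mm), x$truth$laa_fraction,
              nrow(x$truth$airway), nrow(x$truth$vessels)))
  invisible(x)
}

# all pairwise distances between two point sets (rows)
fields_dist <- function(a, b) {
  aa <- rowSums(a^2); bb <- rowSums(b^2)
  d2 <- outer(aa, bb, "+") - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

# linear indices of voxels whose centre lies within radius r of `center`
raster_ball <- function(center, r, xs, ys, zs, dims) {
  ix <- which(abs(xs - center[1]) <= r)
  iy <- which(abs(ys - center[2]) <= r)
  iz <- which(abs(zs - center[3]) <= r)
  if (!length(ix) || !length(iy) || !length(iz)) return(integer(0))
  d2 <- outer((xs[ix] - center[1])^2, (ys[iy] - center[2])^2, "+")
  lin2 <- outer(ix, (iy - 1L) * dims[1], "+")
  dz2 <- (zs[iz] - center[3])^2
  n2 <- length(d2)
  sel <- rep(as.vector(d2), length(iz)) + rep(dz2, each = n2) <= r^2
  lin <- rep(as.vector(lin2), length(iz)) +
    rep((iz - 1L) * dims[1] * dims[2], each = n2)
  lin[sel]
}

# linear indices of voxels within radius r of the segment p0-p1
raster_cylinder <- function(p0, p1, r, xs, ys, zs, dims) {
  lo <- pmin(p0, p1) - r - 1e-9
  hi <- pmax(p0, p1) + r + 1e-9
  ix <- which(xs >= lo[1] & xs <= hi[1])
  iy <- which(ys >= lo[2] & ys <= hi[2])
  iz <- which(zs >= lo[3] & zs <= hi[3])
  if (!length(ix) || !length(iy) || !length(iz)) return(integer(0))
  qx <- rep(xs[ix], times = length(iy) * length(iz))
  qy <- rep(rep(ys[iy], each = length(ix)), times = length(iz))
  qz <- rep(zs[iz], each = length(ix) * length(iy))
  v <- p1 - p0
  L2 <- sum(v^2)
  t <- ((qx - p0[1]) * v[1] + (qy - p0[2]) * v[2] + (qz - p0[3]) * v[3]) / L2
  t <- pmin(pmax(t, 0), 1)
  d2 <- (qx - p0[1] - t * v[1])^2 + (qy - p0[2] - t * v[2])^2 +
    (qz - p0[3] - t * v[3])^2
  lin <- rep(ix, times = length(iy) * length(iz)) +
    rep(rep((iy - 1L) * dims[1], each = length(ix)), times = length(iz)) +
    rep((iz - 1L) * dims[1] * dims[2], each = length(ix) * length(iy))
  lin[d2 <= r^2]
}
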