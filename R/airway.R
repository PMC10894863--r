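# Airway cross-sectional measurement (internal perimeter Pi, wall area WA)
# by radial ray casting in the plane perpendicular to the airway axis, and
# the Pi10 summary regression. Airway site detection on real CT is out of
# scope: sites come from the phantom truth or a user-supplied site table.

#' Define an airway measurement site
#'
#' @param center Physical position (x, y, z) of the lumen centre, mm.
#' @param axis Direction of the airway axis (will be normalized; must be
#'   non-zero).
#' @param generation Airway generation (1 = trachea; measurable range is
#'   usually 3-8).
#' @param region Optional lung side ("right"/"left") for regional Pi10.
#' @return Object of class `airway_site`.
#' @export
airway_site <- function(center, axis, generation, region = NA_character_) {
  center <- as.numeric(center); axis <- as.numeric(axis)
  stopifnot(length(center) == 3, length(axis) == 3)
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-12) stop("axis must be a non-zero vector")
  if (generation < 1) stop("generation must be >= 1")
  structure(list(center = center, axis = axis / nrm,
                 generation = as.integer(generation), region = region),
            class = "airway_site")
}

#' Measure an airway cross-section
#'
#' Resamples the plane perpendicular to the airway axis on a fine grid
#' (default 0.1 mm steps, a tenfold magnification relative to typical CT
#' spacing) and casts `n_rays` radial rays from the lumen centre. On each
#' ray the inner wall edge is the half-maximum crossing between the lumen
#' minimum and the wall peak, and the outer edge is the half-maximum
#' crossing between the wall peak and the parenchyma beyond the wall (a
#' half-maximum approximation of integral-based wall-edge detection). The
#' internal perimeter Pi is the perimeter of the inner-edge polygon and the
#' wall area WA is the area between the outer and inner polygons
#' (shoelace). Rays with no detectable wall are dropped; the site fails if
#' more than `max_fail_frac` of rays fail.
#'
#' @param volume A [ct_volume()].
#' @param site An [airway_site()], or a one-row data frame with columns
#'   `x_mm, y_mm, z_mm, axis_x, axis_y, axis_z, generation` (and optional
#'   `region`).
#' @param n_rays Number of radial rays.
#' @param step_mm Radial sampling step, mm.
#' @param max_radius_mm Maximum radius probed, mm.
#' @param max_fail_frac Maximum tolerated fraction of failed rays.
#' @return Object of class `airway_measurement` with
#'   `internal_perimeter_mm`, `wall_area_mm2`, `generation`, `region`,
#'   `n_rays_used`.
#' @export
measure_cross_section <- function(volume, site, n_rays = 64, step_mm = 0.1,
                                  max_radius_mm = 8, max_fail_frac = 0.25) {
  if (is.data.frame(site))
    site <- airway_site(c(site$x_mm, site$y_mm, site$z_mm),
                        c(site$axis_x, site$axis_y, site$axis_z),
                        site$generation,
                        if ("region" %in% names(site)) site$region else NA)
  stopifnot(inherits(site, "airway_site"))
  ax <- site$axis
  # in-plane orthonormal basis
  ref <- if (abs(ax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * ax) * ax
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(ax[2] * e1[3] - ax[3] * e1[2],
          ax[3] * e1[1] - ax[1] * e1[3],
          ax[1] * e1[2] - ax[2] * e1[1])

  hu0 <- sample_volume(volume$voxels, volume$spacing, volume$origin,
                       matrix(site$center, 1, 3))
  if (hu0 >= -500)
    stop("site centre is not inside an air-filled lumen (HU = ",
         round(hu0), ")")

  rr <- seq(0, max_radius_mm, by = step_mm)
  th <- 2 * pi * (seq_len(n_rays) - 1) / n_rays
  # all sample points of all rays in one trilinear call
  dirx <- outer(cos(th), e1[1]) + outer(sin(th), e2[1])
  diry <- outer(cos(th), e1[2]) + outer(sin(th), e2[2])
  dirz <- outer(cos(th), e1[3]) + outer(sin(th), e2[3])
  pts <- cbind(site$center[1] + as.vector(outer(dirx[, 1], rr)),
               site$center[2] + as.vector(outer(diry[, 1], rr)),
               site$center[3] + as.vector(outer(dirz[, 1], rr)))
  hu <- matrix(sample_volume(volume$voxels, volume$spacing, volume$origin,
                             pts), nrow = n_rays)

  r_in <- r_out <- rep(NA_real_, n_rays)
  for (j in seq_len(n_rays)) {
    prof <- hu[j, ]
    # the wall peak is the maximum of the FIRST wall passage: from the
    # first rise out of the lumen until the profile falls back towards
    # parenchyma, so a neighbouring airway further out is never mistaken
    # for the wall of this one
    rise <- which(prof >= prof[1] + 250)[1]
    if (is.na(rise)) next
    runmax <- cummax(prof[seq.int(rise, length(prof))])
    fall <- which(prof[seq.int(rise, length(prof))] <= runmax - 250)[1]
    wend <- if (is.na(fall)) length(prof) else rise + fall - 2L
    ipk <- rise - 1L + which.max(prof[seq.int(rise, wend)])
    peak <- prof[ipk]
    lumen_min <- min(prof[seq_len(ipk)])
    if (ipk <= 1L || peak - lumen_min < 150) next  # no wall on this ray
    t_in <- (lumen_min + peak) / 2
    jin <- which(prof[seq_len(ipk)] >= t_in)[1]
    if (is.na(jin) || jin <= 1L) next
    r_in[j] <- rr[jin - 1] + step_mm * (t_in - prof[jin - 1]) /
      (prof[jin] - prof[jin - 1])
    # parenchyma estimate from a local window 1-3 mm beyond the peak
    wlo <- rr[ipk] + 1; whi <- rr[ipk] + 3
    wsel <- which(rr > wlo & rr <= whi)
    if (!length(wsel)) next
    outer_par <- median(prof[wsel])
    if (peak - outer_par < 150) next
    t_out <- (peak + outer_par) / 2
    after <- seq.int(ipk, length(rr))
    jout <- after[which(prof[after] <= t_out)[1]]
    if (is.na(jout) || jout <= ipk) next
    r_out[j] <- rr[jout - 1] + step_mm * (t_out - prof[jout - 1]) /
      (prof[jout] - prof[jout - 1])
  }

  ok <- !is.na(r_in) & !is.na(r_out)
  if (mean(!ok) > max_fail_frac)
    stop("measurement failed: wall edges not found on ",
         sum(!ok), "/", n_rays, " rays")
  thk <- th[ok]
  inner <- cbind(r_in[ok] * cos(thk), r_in[ok] * sin(thk))
  outer_poly <- cbind(r_out[ok] * cos(thk), r_out[ok] * sin(thk))
  Pi <- polygon_perimeter(inner)
  WA <- polygon_area(outer_poly) - polygon_area(inner)
  m <- structure(list(internal_perimeter_mm = Pi, wall_area_mm2 = WA,
                      generation = site$generation, region = site$region,
                      n_rays_used = sum(ok)),
                 class = "airway_measurement")
  if (WA <= 0 || sqrt(WA) >= Pi)
    warning("implausible wall measurement: sqrt(WA) >= Pi")
  m
}

#' @export
print.airway_measurement <- function(x, ...) {
  cat(sprintf("Airway cross-section (gen %d): Pi = %.2f mm, WA = %.2f mm2 (%d rays)\n",
              x$generation, x$internal_perimeter_mm, x$wall_area_mm2,
              x$n_rays_used))
  invisible(x)
}

polygon_perimeter <- function(v) {
  w <- rbind(v, v[1, , drop = FALSE])
  sum(sqrt(rowSums(diff(w)^2)))
}

polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  abs(sum(x * y2 - x2 * y)) / 2
}

#' Pi10: standardized airway wall thickness
#'
#' Ordinary least squares of the square root of wall area on the internal
#' perimeter over all retained cross-sections, evaluated at an internal
#' perimeter of 10 mm. Measurements outside `generation_range` are
#' discarded first.
#'
#' @param measurements A list of [measure_cross_section()] results, or a
#'   data frame with columns `internal_perimeter_mm`, `wall_area_mm2`,
#'   `generation`.
#' @param generation_range Inclusive generation filter (default 3-8,
#'   lobar to subsegmental bronchi).
#' @return Fitted sqrt(wall area) at Pi = 10 mm (mm).
#' @export
pi10 <- function(measurements, generation_range = c(3, 8)) {
  df <- as_measurement_df(measurements)
  df <- df[df$generation >= generation_range[1] &
             df$generation <= generation_range[2], ]
  if (nrow(df) == 0L)
    stop("filter error: no measurements within the generation range")
  if (length(unique(df$internal_perimeter_mm)) < 2L)
    stop("insufficient data: Pi10 needs >= 2 distinct internal perimeters")
  fit <- lm(sqrt(wall_area_mm2) ~ internal_perimeter_mm, data = df)
  unname(predict(fit, data.frame(internal_perimeter_mm = 10)))
}

as_measurement_df <- function(measurements) {
  if (is.data.frame(measurements)) return(measurements)
  if (inherits(measurements, "airway_measurement"))
    measurements <- list(measurements)
  do.call(rbind, lapply(measurements, function(m)
    data.frame(internal_perimeter_mm = m$internal_perimeter_mm,
               wall_area_mm2 = m$wall_area_mm2,
               generation = m$generation,
               region = if (is.null(m$region)) NA_character_ else m$region)))
}
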