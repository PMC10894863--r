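# Assembly of the 22-feature quantitative vector for one scan:
# EI x 8 regions, D-slope x 3, Pi10 x 3, VN x 8.

#' Names and categories of the 22 quantitative features
#'
#' @return `feature_names()`: character vector of the 22 feature names in
#'   canonical order. `feature_categories()`: named character vector
#'   mapping each feature name to its category (`EI`, `Dslope`, `Pi10`,
#'   `VN`).
#' @export
feature_names <- function() {
  c(paste0("EI_", lung_regions()),
    paste0("Dslope_", c("whole", "right", "left")),
    paste0("Pi10_", c("whole", "right", "left")),
    paste0("VN_", lung_regions()))
}

#' @rdname feature_names
#' @export
feature_categories <- function() {
  fn <- feature_names()
  setNames(sub("_.*$", "", fn), fn)
}

#' Extract the full quantitative feature vector from one scan
#'
#' Runs all four quantifiers: emphysema index per 8 regions, D-slope for
#' whole/right/left, Pi10 for whole/right/left from the supplied airway
#' sites, and peripheral vessel counts per 8 regions.
#'
#' @param volume A [ct_volume()].
#' @param masks List with [label_mask()] elements `lobes` (parenchyma
#'   lobar labels, used for densitometry), `lungs` (solid lung/lobar
#'   territories, used for the subpleural surface) and `vessels`.
#' @param sites Data frame of airway sites (columns `x_mm, y_mm, z_mm,
#'   axis_x, axis_y, axis_z, generation, region`).
#' @param scan_id Identifier stored in the output row.
#' @param threshold_hu Densitometric threshold.
#' @param depth_mm Subpleural counting depth.
#' @param max_area_mm2 Vessel crossing area threshold.
#' @return One-row data frame: `scan_id` plus the 22 features.
#' @export
extract_features <- function(volume, masks, sites, scan_id = "scan",
                             threshold_hu = -950, depth_mm = 12,
                             max_area_mm2 = 5) {
  ei <- emphysema_index(volume, masks$lobes, threshold_hu)
  dsl <- vapply(c("whole", "right", "left"), function(rg) {
    m <- laa_mask(volume, masks$lobes, threshold_hu, region = rg)
    d_slope(cluster_emphysema(m, masks$lobes$spacing))
  }, 1.0)
  p10 <- vapply(c("whole", "right", "left"), function(rg) {
    s <- sites
    if (rg != "whole") s <- s[s$region == rg, , drop = FALSE]
    ms <- lapply(seq_len(nrow(s)),
                 function(i) measure_cross_section(volume, s[i, , drop = FALSE]))
    pi10(ms)
  }, 1.0)
  surf <- peripheral_surface(masks$lungs, depth_mm)
  vn <- count_peripheral_vessels(masks$vessels, surf, max_area_mm2)
  vals <- c(ei$value, unname(dsl), unname(p10), vn$vn_per_cm2)
  out <- data.frame(scan_id = scan_id)
  out[feature_names()] <- as.list(vals)
  out
}
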