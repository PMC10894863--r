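# Synthetic feature tables and reader ratings: the "desk-scale cohort"
# counterpart of the voxel phantom. Baseline feature vectors are drawn from
# marginals matching the study population (EI ~ 12.2, D-slope ~ 5.1,
# Pi10 ~ 4.0, VN ~ 0.6); follow-ups add controlled longitudinal noise.

rnorm_trunc <- function(n, mean, sd, lower = 0) {
  pmax(rnorm(n, mean, sd), lower)
}

one_feature_vector_table <- function(n, prefix) {
  # EI: lognormal matched to mean 12.2, sd 13.1; regional values scatter
  # around the whole-lung value (upper/lower-lobe predominance)
  s2 <- log(1 + (13.1 / 12.2)^2)
  ei_w <- exp(rnorm(n, log(12.2) - s2 / 2, sqrt(s2)))
  regional <- function(base, sdlog) base * exp(rnorm(n, 0, sdlog))
  ei <- cbind(ei_w, regional(ei_w, 0.2), regional(ei_w, 0.2),
              regional(ei_w, 0.4), regional(ei_w, 0.4), regional(ei_w, 0.4),
              regional(ei_w, 0.4), regional(ei_w, 0.4))
  ds_w <- rnorm_trunc(n, 5.1, 1.5, 0.5)
  ds <- cbind(ds_w, ds_w + rnorm(n, 0, 0.2), ds_w + rnorm(n, 0, 0.2))
  p_w <- rnorm_trunc(n, 4.0, 0.8, 1)
  p <- cbind(p_w, p_w + rnorm(n, 0, 0.15), p_w + rnorm(n, 0, 0.15))
  vn_w <- rnorm_trunc(n, 0.6, 0.1, 0.05)
  vn <- cbind(vn_w, regional(vn_w, 0.1), regional(vn_w, 0.1),
              regional(vn_w, 0.2), regional(vn_w, 0.2), regional(vn_w, 0.2),
              regional(vn_w, 0.2), regional(vn_w, 0.2))
  out <- data.frame(scan_id = sprintf("%s%04d", prefix, seq_len(n)))
  out[feature_names()] <- as.data.frame(cbind(ei, ds, p, vn))
  out
}

default_longitudinal_sd <- function() {
  # per-category absolute noise of a stable ~3-year interval
  cats <- feature_categories()
  sds <- c(EI = 1.0, Dslope = 0.15, Pi10 = 0.12, VN = 0.02)
  setNames(unname(sds[cats]), names(cats))
}

#' Generate a paired baseline/follow-up feature table
#'
#' Emulates the cohort geometry of a CBIR study: `n_pairs` patients with a
#' baseline scan (database member) and a follow-up scan (query), plus
#' `n_singletons` unpaired database scans. Follow-up vectors equal their
#' baseline plus Normal(0, `noise_sd`) noise truncated at 0; with the
#' default `n_pairs = 50`, `n_singletons = 500` the searchable database
#' (baselines + singletons) has 550 scans.
#'
#' @param n_pairs Number of baseline/follow-up pairs.
#' @param n_singletons Number of unpaired database scans.
#' @param noise_sd Longitudinal noise SD: a scalar, or a named vector over
#'   [feature_names()]. The default reflects stable disease over a ~3-year
#'   interval.
#' @param seed RNG seed.
#' @return Data frame: `scan_id`, `pair_id` (NA for singletons), `role`
#'   (`baseline`, `followup`, `singleton`), and the 22 features.
#' @export
generate_paired_feature_table <- function(n_pairs = 50, n_singletons = 500,
                                          noise_sd = default_longitudinal_sd(),
                                          seed = 1) {
  stopifnot(n_pairs >= 1, n_singletons >= 0)
  if (length(noise_sd) == 1L)
    noise_sd <- setNames(rep(noise_sd, 22), feature_names())
  noise_sd <- noise_sd[feature_names()]
  if (any(is.na(noise_sd)) || any(noise_sd < 0))
    stop("noise_sd must be non-negative and cover all features")
  with_seed(seed, {
    base <- one_feature_vector_table(n_pairs, "P")
    base$scan_id <- paste0(base$scan_id, "_b")
    fol <- base
    fol$scan_id <- sub("_b$", "_f", fol$scan_id)
    fn <- feature_names()
    noise <- matrix(rnorm(n_pairs * 22, 0, rep(noise_sd, each = n_pairs)),
                    n_pairs, 22)
    fol[fn] <- pmax(as.matrix(base[fn]) + noise, 0)
    pair_ids <- sprintf("P%04d", seq_len(n_pairs))
    base$pair_id <- pair_ids; fol$pair_id <- pair_ids
    base$role <- "baseline"; fol$role <- "followup"
    single <- if (n_singletons > 0) {
      s <- one_feature_vector_table(n_singletons, "S")
      s$pair_id <- NA_character_; s$role <- "singleton"
      s
    }
    out <- rbind(base, fol, single)
    out[c("scan_id", "pair_id", "role", fn)]
  })
}

#' Map of query scans to their baseline pairs
#'
#' @param features A [generate_paired_feature_table()] result.
#' @return Named character vector: follow-up (query) scan_id to baseline
#'   scan_id.
#' @export
pair_map <- function(features) {
  fol <- features[features$role == "followup", ]
  base <- features[features$role == "baseline", ]
  setNames(base$scan_id[match(fol$pair_id, base$pair_id)], fol$scan_id)
}

#' Generate synthetic reader ratings for retrieval results
#'
#' Two synthetic readers score every (query, rank) on the 5-point
#' similarity scale. Reader 1 draws a score from a latent model in which
#' the expected score decreases with the combined retrieval distance;
#' reader 2 copies reader 1 with probability `concordance` and otherwise
#' draws an independent score from the same marginal distribution
#' (distance-shuffled), so `concordance = 1` gives identical readers and
#' `concordance = 0` gives independent ones (kappa ~ 0).
#'
#' @param results List of [query_index()] results (or data frame with
#'   `query_id`, `rank`, `distance`).
#' @param concordance Probability in \[0, 1\] that reader 2 copies
#'   reader 1.
#' @param seed RNG seed.
#' @return Ratings data frame: `query_id`, `rank`, `reader`, `score`.
#' @export
generate_reader_ratings <- function(results, concordance = 0.8, seed = 1) {
  stopifnot(concordance >= 0, concordance <= 1)
  df <- results_to_df(results)
  if (nrow(df) == 0L) stop("no retrieval results to rate")
  with_seed(seed, {
    n <- nrow(df)
    draw <- function(dist) {
      lat <- 5 - 6 * pmin(dist, 1) + rnorm(length(dist), 0, 0.6)
      pmin(pmax(round(lat), 1), 5)
    }
    s1 <- draw(df$distance)
    s2_indep <- draw(sample(df$distance))  # same marginal, no dependence
    copy <- runif(n) < concordance
    s2 <- ifelse(copy, s1, s2_indep)
    rbind(data.frame(query_id = df$query_id, rank = df$rank, reader = 1L,
                     score = as.integer(s1)),
          data.frame(query_id = df$query_id, rank = df$rank, reader = 2L,
                     score = as.integer(s2)))
  })
}
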