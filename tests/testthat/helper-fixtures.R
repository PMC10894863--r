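# Shared fixtures, all generated in code.

# Ideal airway annulus volume (inner radius rin, wall thickness `wall`)
# with one-voxel partial-volume edges, the discrete analogue of a CT
# point-spread function.
make_annulus_volume <- function(h, rin, wall, size = 16, nz = 9,
                                lumen = -1000, wall_hu = 0, par = -850) {
  xs <- seq(-size, size, by = h)
  n <- length(xs)
  r <- sqrt(outer(xs^2, xs^2, "+"))
  f_in <- pmin(pmax((r - (rin - h / 2)) / h, 0), 1)
  f_out <- pmin(pmax((r - (rin + wall - h / 2)) / h, 0), 1)
  base <- (1 - f_in) * lumen + f_in * wall_hu
  sl <- base + f_out * (par - base)
  vol <- array(rep(sl, nz), c(n, n, nz))
  ct_volume(vol, rep(h, 3), origin = c(xs[1], xs[1], -(nz - 1) / 2 * h))
}

# Small, fast phantoms shared between tests (built once per test run)
.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_env)) assign(key, force(expr), .fixture_env)
  get(key, .fixture_env)
}

small_phantom <- function() cached("small_phantom", generate_lung_phantom(
  phantom_spec(lung_semiaxes_mm = c(16, 20, 32), spacing_mm = 1,
               emphysema_fraction = 0.10, cluster_exponent = 3,
               diameter_range_mm = c(3, 9),
               vessel_areas_mm2 = rep(c(1, 2, 3), 2), seed = 42)))

# finer grid, no emphysema: clean airway + vessel geometry
fine_phantom <- function() cached("fine_phantom", generate_lung_phantom(
  phantom_spec(lung_semiaxes_mm = c(16, 20, 32), spacing_mm = 0.5,
               emphysema_fraction = 0, diameter_range_mm = c(1.5, 8),
               vessel_areas_mm2 = rep(c(1, 2, 3), 2), seed = 3)))

# Feature table with one scan per row and specified values for a single
# feature (other features filled with a constant 1)
toy_feature_table <- function(values, feature = "EI_whole",
                              ids = sprintf("s%02d", seq_along(values))) {
  df <- data.frame(scan_id = ids)
  df[feature_names()] <- 1
  df[[feature]] <- values
  df
}

# Flat-slab "lung" whose 12-mm counting surface is a single plane, with a
# region-1 window sized so the package's area estimate is 20 cm2, plus 12
# vertical vessel cylinders of 2 mm2 cross-section piercing it.
flat_shell_fixture <- function(n_vessels = 12, vessel_r = sqrt(2 / pi),
                               h = 0.5) {
  nx <- 120; ny <- 120; nz <- 44
  lab <- array(0L, c(nx, ny, nz))
  lab[, , 5:nz] <- 2L  # lung occupies full x-y up to the top border
  # region-1 window: exactly 6651 columns -> area estimate 20.00 cm2
  lab[1:81, 1:82, 5:nz] <- 1L
  lab[82, 1:9, 5:nz] <- 1L
  lungs <- label_mask(lab, rep(h, 3), c(0, 0, 0))
  ves <- array(0L, c(nx, ny, nz))
  set.seed(7)
  centers <- cbind(seq(8, 75, length.out = n_vessels),
                   seq(8, 75, length.out = n_vessels)[sample(n_vessels)])
  xs <- (seq_len(nx) - 1) * h; ys <- (seq_len(ny) - 1) * h
  for (i in seq_len(n_vessels)) {
    cxy <- centers[i, ] * h
    ix <- which((xs - cxy[1])^2 <= vessel_r^2 * 4)
    iy <- which((ys - cxy[2])^2 <= vessel_r^2 * 4)
    for (x in ix) for (y in iy)
      if ((xs[x] - cxy[1])^2 + (ys[y] - cxy[2])^2 <= vessel_r^2)
        ves[x, y, 20:36] <- 40L
  }
  vessels <- label_mask(ves, rep(h, 3), c(0, 0, 0))
  list(lungs = lungs, vessels = vessels)
}

# Ratings table matching given per-(reader, rank) counts of scores >= 4,
# score sums, and numbers of fives, with fives allocated so each reader
# covers a specified number of distinct queries.
build_rating_set <- function(n_queries, counts_ge4, sums, fives,
                             coverage) {
  ranks <- seq_along(counts_ge4)
  # queries receiving a five at each rank: fill new queries up to the
  # coverage target, then reuse query 1..
  out <- NULL
  next_new <- 1
  five_q <- vector("list", length(ranks))
  for (k in order(fives, decreasing = TRUE)) {
    a <- fives[k]
    take_new <- min(a, coverage - (next_new - 1))
    qs <- integer(0)
    if (take_new > 0) {
      qs <- seq(next_new, next_new + take_new - 1)
      next_new <- next_new + take_new
    }
    if (a - take_new > 0) qs <- c(qs, seq_len(a - take_new))
    five_q[[k]] <- qs
  }
  stopifnot(next_new - 1 == coverage)
  for (k in ranks) {
    a <- fives[k]; cge <- counts_ge4[k]; b <- cge - a
    n_sub <- n_queries - cge
    s3 <- sums[k] - 5 * a - 4 * b
    stopifnot(a >= 0, b >= 0, s3 >= n_sub, s3 <= 3 * n_sub)
    sub <- rep(3L, n_sub)
    deficit <- 3 * n_sub - s3
    i <- 1
    while (deficit > 0) {
      dec <- min(2L, deficit, sub[i] - 1L)
      sub[i] <- sub[i] - dec
      deficit <- deficit - dec
      i <- i + 1
    }
    score <- integer(n_queries)
    score[five_q[[k]]] <- 5L
    rest <- setdiff(seq_len(n_queries), five_q[[k]])
    score[rest[seq_len(b)]] <- 4L
    score[rest[seq.int(b + 1, length.out = n_sub)]] <- sub
    out <- rbind(out, data.frame(query_id = sprintf("q%02d", seq_len(n_queries)),
                                 rank = k, score = score))
  }
  out
}

# Ratings reproducing the published per-rank summary counts: percent of
# scores >= 4 and mean scores per reader and rank, with the published
# per-reader numbers of queries that received at least one score of 5.
table4_like_ratings <- function() {
  r1 <- build_rating_set(50, counts_ge4 = c(37, 32, 24, 23, 17),
                         sums = c(208, 187, 180, 169, 162),
                         fives = c(21, 5, 6, 3, 3), coverage = 38)
  r1$reader <- 1L
  r2 <- build_rating_set(50, counts_ge4 = c(44, 41, 41, 32, 33),
                         sums = c(217, 204, 201, 190, 186),
                         fives = c(23, 13, 10, 8, 3), coverage = 36)
  r2$reader <- 2L
  rbind(r1, r2)[, c("query_id", "rank", "reader", "score")]
}
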