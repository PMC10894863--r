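test_that("p95 normalizers use linear interpolation between order stats", {
  df <- toy_feature_table(0:20)
  idx <- build_index(df)
  expect_equal(unname(idx$normalizers["EI_whole"]), 19)
  expect_equal(unname(idx$normalized[df$scan_id == "s11", "EI_whole"]),
               10 / 19, tolerance = 1e-12)
})

test_that("a feature constant at zero gets a unit normalizer", {
  df <- toy_feature_table(rep(0, 10))
  expect_warning(idx <- build_index(df), "constant at 0")
  expect_equal(unname(idx$normalizers["EI_whole"]), 1)
  expect_true(all(idx$normalized[, "EI_whole"] == 0))
})

test_that("the index validates completeness and identity", {
  df <- toy_feature_table(1:5)
  expect_error(build_index(df[, -2]), "completeness")
  df$scan_id[2] <- df$scan_id[1]
  expect_error(build_index(df), "identity")
  dfn <- toy_feature_table(1:5); dfn$VN_whole[3] <- NA
  expect_error(build_index(dfn), "completeness")
  expect_error(build_index(toy_feature_table(1)), "at least 2")
})

test_that("a query identical to an entry ranks first at distance zero", {
  set.seed(5)
  df <- toy_feature_table(runif(8, 1, 10))
  df[feature_names()] <- matrix(runif(8 * 22, 0.1, 5), 8)
  idx <- build_index(df)
  r <- query_index(idx, df[3, ], k = 3)
  expect_equal(r$results$scan_id[1], df$scan_id[3])
  expect_lt(r$results$distance[1], 1e-12)
  # self-exclusion drops that entry
  r2 <- query_index(idx, df[3, ], k = 3, exclude_self = TRUE)
  expect_false(df$scan_id[3] %in% r2$results$scan_id)
})

test_that("orthogonal category sub-vectors give combined distance one", {
  df <- toy_feature_table(c(1, 1))
  fn <- feature_names()
  cats <- feature_categories()
  # entry s01 loads only the first feature of each category, the query
  # only the second, so every category pair is orthogonal
  df[fn] <- 0
  for (cl in unique(cats)) {
    cols <- names(cats)[cats == cl]
    df[1, cols[1]] <- 3
    df[2, cols[1]] <- 3  # keeps normalizers positive
    df[1, cols[2]] <- 0
  }
  q <- setNames(rep(0, 22), fn)
  for (cl in unique(cats)) q[names(cats)[cats == cl][2]] <- 2
  idx <- suppressWarnings(build_index(df))  # unused features constant at 0
  r <- query_index(idx, q, k = 2)
  expect_equal(max(r$results$distance), 1)
})

test_that("rankings match a brute-force cosine oracle on a toy database", {
  set.seed(9)
  n <- 5
  vals <- matrix(runif(n * 22, 0.2, 8), n)
  df <- data.frame(scan_id = c("e", "b", "d", "a", "c"))
  df[feature_names()] <- as.data.frame(vals)
  q <- setNames(runif(22, 0.2, 8), feature_names())
  idx <- build_index(df)
  r <- query_index(idx, q, k = n)

  # oracle: recompute every cosine distance directly
  p95 <- apply(vals, 2, function(x) unname(quantile(x, 0.95, type = 7)))
  Vn <- sweep(vals, 2, p95, "/")
  qn <- q / p95
  cats <- feature_categories()
  dist_oracle <- vapply(seq_len(n), function(i) {
    mean(vapply(unique(cats), function(cl) {
      u <- Vn[i, cats == cl]; v <- qn[cats == cl]
      1 - sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    }, 1.0))
  }, 1.0)
  o <- order(dist_oracle, df$scan_id)
  expect_equal(r$results$scan_id, df$scan_id[o])
  expect_equal(r$results$distance, dist_oracle[o], tolerance = 1e-12)
})

test_that("combined distance is symmetric between normalized vectors", {
  set.seed(13)
  df <- toy_feature_table(1:6)
  df[feature_names()] <- matrix(runif(6 * 22, 0.1, 4), 6)
  idx <- build_index(df)
  d12 <- query_index(idx, df[1, ], k = 6)
  d21 <- query_index(idx, df[2, ], k = 6)
  expect_equal(d12$results$distance[d12$results$scan_id == df$scan_id[2]],
               d21$results$distance[d21$results$scan_id == df$scan_id[1]],
               tolerance = 1e-12)
})

test_that("rescaling one feature everywhere leaves rankings unchanged", {
  set.seed(17)
  df <- toy_feature_table(1:7)
  df[feature_names()] <- matrix(runif(7 * 22, 0.1, 4), 7)
  q <- setNames(runif(22, 0.1, 4), feature_names())
  r1 <- query_index(build_index(df), q, k = 7)
  df2 <- df; df2$Pi10_whole <- df2$Pi10_whole * 37
  q2 <- q; q2["Pi10_whole"] <- q2["Pi10_whole"] * 37
  r2 <- query_index(build_index(df2), q2, k = 7)
  expect_equal(r1$results$scan_id, r2$results$scan_id)
  expect_equal(r1$results$distance, r2$results$distance, tolerance = 1e-12)
})

test_that("zero-noise pairs are retrieved at rank one with distance zero", {
  ft <- generate_paired_feature_table(20, 80, noise_sd = 0, seed = 21)
  idx <- build_index(ft[ft$role != "followup", ])
  qs <- ft[ft$role == "followup", ]
  pm <- pair_map(ft)
  for (i in seq_len(nrow(qs))) {
    r <- query_index(idx, qs[i, ])
    expect_equal(r$results$scan_id[1], unname(pm[qs$scan_id[i]]))
    expect_lt(r$results$distance[1], 1e-12)
  }
})

test_that("top-k hit indicator is monotone in k", {
  ft <- generate_paired_feature_table(25, 100, seed = 22)
  idx <- build_index(ft[ft$role != "followup", ])
  qs <- ft[ft$role == "followup", ]
  res <- lapply(seq_len(nrow(qs)), function(i) query_index(idx, qs[i, ]))
  rr <- pair_retrieval_rate(res, pair_map(ft), ks = 1:5)
  expect_true(all(diff(rr$hits) >= 0))
})

test_that("k and mode parameters behave as documented", {
  set.seed(23)
  df <- toy_feature_table(1:9)
  df[feature_names()] <- matrix(runif(9 * 22, 0.1, 4), 9)
  idx <- build_index(df)
  q <- setNames(runif(22, 0.1, 4), feature_names())
  expect_equal(nrow(query_index(idx, q, k = 3)$results), 3)
  expect_equal(nrow(query_index(idx, q, k = 99)$results), 9)
  expect_error(query_index(idx, q, k = 0), "parameter")
  rc <- query_index(idx, q, k = 9, mode = "concat")
  expect_s3_class(rc, "cbir_result")
  expect_true(all(rc$results$distance >= 0 & rc$results$distance <= 1))
})

test_that("save/load round trip preserves rankings bit-exact", {
  set.seed(27)
  df <- toy_feature_table(1:12)
  df[feature_names()] <- matrix(runif(12 * 22, 0.1, 4), 12)
  idx <- build_index(df)
  p <- tempfile(fileext = ".json")
  save_index(idx, p)
  idx2 <- load_index(p)
  expect_equal(idx2$normalizers, idx$normalizers, tolerance = 0)
  expect_equal(idx2$normalized, idx$normalized, tolerance = 0,
               ignore_attr = TRUE)
  q <- setNames(runif(22, 0.1, 4), feature_names())
  expect_identical(query_index(idx, q)$results,
                   query_index(idx2, q)$results)
  # truncated file is a format error
  txt <- readLines(p, warn = FALSE)
  writeLines(substr(paste(txt, collapse = ""), 1, 50),
             p2 <- tempfile(fileext = ".json"))
  expect_error(load_index(p2), "format error")
})

test_that("a database-scale index serves queries quickly", {
  ft <- generate_paired_feature_table(50, 500, seed = 30)
  idx <- build_index(ft[ft$role != "followup", ])
  expect_equal(length(idx$scan_ids), 550)
  p <- tempfile(fileext = ".json")
  save_index(idx, p)
  q <- ft[ft$role == "followup", ][1, ]
  el <- system.time({
    idx2 <- load_index(p)
    query_index(idx2, q)
  })[["elapsed"]]
  expect_lt(el, 1)
})
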