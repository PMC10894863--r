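test_that("phantom spec validates its physical constraints", {
  expect_error(phantom_spec(emphysema_fraction = 1), "fraction")
  expect_error(phantom_spec(cluster_exponent = 0), "exponent")
  expect_error(phantom_spec(spacing_mm = 2, diameter_range_mm = c(3, 10)),
               "2 voxels")
  expect_error(phantom_spec(vessel_depth_range_mm = c(13, 16)), "bracket")
})

test_that("zero emphysema fraction gives an empty LAA mask and zero EI", {
  ph <- fine_phantom()
  expect_identical(ph$spec$emphysema_fraction, 0)
  expect_true(all(ph$truth$ei_percent$value == 0))
  expect_equal(sum(laa_mask(ph$volume, ph$masks$lobes)), 0)
})

test_that("generation is deterministic given the seed", {
  sp <- phantom_spec(lung_semiaxes_mm = c(16, 20, 32), spacing_mm = 1,
                     emphysema_fraction = 0.05, cluster_exponent = 3,
                     diameter_range_mm = c(3, 8),
                     vessel_areas_mm2 = c(1, 2, 3), seed = 9)
  a <- generate_lung_phantom(sp)
  b <- generate_lung_phantom(sp)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$truth$cluster_diameters_mm, b$truth$cluster_diameters_mm)
})

test_that("realized LAA fraction hits the target within packing tolerance", {
  sp <- phantom_spec(lung_semiaxes_mm = c(18, 22, 36), spacing_mm = 0.5,
                     parenchyma_hu_sd = 0, emphysema_fraction = 0.15,
                     cluster_exponent = 3.5, diameter_range_mm = c(2.4, 10),
                     vessel_areas_mm2 = c(1, 2), seed = 4)
  ph <- generate_lung_phantom(sp)
  lungvox <- ph$masks$lobes$labels > 0
  measured <- sum(ph$volume$voxels[lungvox] <= -950) / sum(lungvox)
  expect_equal(measured, 0.15, tolerance = 0.01 / 0.15)
  # truth records the realized fraction exactly
  expect_equal(ph$truth$laa_fraction,
               sum(ph$volume$voxels[lungvox] < -950) / sum(lungvox),
               tolerance = 1e-12)
})

test_that("all phantom masks are aligned with the phantom volume", {
  ph <- small_phantom()
  for (m in ph$masks) expect_true(validate_aligned(ph$volume, m))
})

test_that("sampled cluster diameters follow the truncated Pareto law", {
  sp <- phantom_spec(lung_semiaxes_mm = c(20, 26, 42), spacing_mm = 0.8,
                     emphysema_fraction = 0.12, cluster_exponent = 3.5,
                     diameter_range_mm = c(2.4, 12),
                     vessel_areas_mm2 = c(1, 2), seed = 8)
  ph <- generate_lung_phantom(sp)
  d <- ph$truth$cluster_target_diameters_mm
  expect_gte(length(d), 500)
  ks <- suppressWarnings(ks.test(d, function(q)
    lungcbir:::ptrunc_pareto(q, 3.5, 2.4, 12)))
  expect_gt(ks$p.value, 0.01)
})

test_that("truth EI equals the voxel-counted LAA fraction on the grid", {
  ph <- small_phantom()
  ei <- emphysema_index(ph$volume, ph$masks$lobes)
  expect_equal(ei$value, ph$truth$ei_percent$value, tolerance = 1e-12)
})

test_that("infeasible packing fails with a generation error", {
  sp <- phantom_spec(lung_semiaxes_mm = c(10, 10, 14), spacing_mm = 1,
                     emphysema_fraction = 0.6, cluster_exponent = 3,
                     diameter_range_mm = c(4, 8),
                     vessel_areas_mm2 = numeric(0),
                     airway_generations = data.frame(
                       generation = 3, inner_radius_mm = 1,
                       wall_thickness_mm = 0.5), seed = 1)
  expect_error(generate_lung_phantom(sp), "generation error")
})

test_that("paired feature tables have the requested geometry and noise", {
  ft <- generate_paired_feature_table(50, 500, noise_sd = 0, seed = 1)
  expect_equal(nrow(ft), 600)
  expect_equal(sum(ft$role != "followup"), 550)  # searchable database
  fn <- feature_names()
  base <- ft[ft$role == "baseline", ]
  fol <- ft[ft$role == "followup", ]
  expect_equal(as.matrix(fol[fn]),
               as.matrix(base[match(fol$pair_id, base$pair_id), fn]),
               ignore_attr = TRUE)
  expect_true(all(as.matrix(ft[fn]) >= 0))
  # determinism
  ft2 <- generate_paired_feature_table(50, 500, noise_sd = 0, seed = 1)
  expect_identical(ft, ft2)
  # noise perturbs follow-ups but not baselines
  ftn <- generate_paired_feature_table(10, 0, noise_sd = 0.5, seed = 2)
  expect_false(isTRUE(all.equal(
    as.matrix(ftn[ftn$role == "followup", fn]),
    as.matrix(ftn[ftn$role == "baseline", fn]), check.attributes = FALSE)))
})

test_that("baseline feature marginals sit near the population means", {
  ft <- generate_paired_feature_table(400, 0, noise_sd = 0, seed = 6)
  base <- ft[ft$role == "baseline", ]
  expect_equal(mean(base$EI_whole), 12.2, tolerance = 0.15)
  expect_equal(mean(base$Dslope_whole), 5.1, tolerance = 0.05)
  expect_equal(mean(base$Pi10_whole), 4.0, tolerance = 0.05)
  expect_equal(mean(base$VN_whole), 0.6, tolerance = 0.05)
})

test_that("reader ratings respond to concordance as designed", {
  ft <- generate_paired_feature_table(30, 100, noise_sd = 0, seed = 3)
  idx <- build_index(ft[ft$role != "followup", ])
  qs <- ft[ft$role == "followup", ]
  res <- lapply(seq_len(nrow(qs)), function(i) query_index(idx, qs[i, ]))
  r_same <- generate_reader_ratings(res, concordance = 1, seed = 5)
  expect_true(all(r_same$score %in% 1:5))
  k1 <- weighted_kappa(r_same$score[r_same$reader == 1],
                       r_same$score[r_same$reader == 2], n_boot = 0)
  expect_equal(k1$kappa, 1)
  expect_identical(r_same, generate_reader_ratings(res, concordance = 1,
                                                   seed = 5))
})

test_that("independent readers (concordance 0) have kappa near zero", {
  # many rating units so the permutation-scale noise is small
  df <- data.frame(query_id = rep(sprintf("q%03d", 1:200), each = 5),
                   rank = rep(1:5, 200),
                   scan_id = "x", distance = runif(1000, 0, 0.6))
  r0 <- generate_reader_ratings(df, concordance = 0, seed = 11)
  k0 <- weighted_kappa(r0$score[r0$reader == 1],
                       r0$score[r0$reader == 2], n_boot = 0)
  expect_lt(abs(k0$kappa), 0.08)
})
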