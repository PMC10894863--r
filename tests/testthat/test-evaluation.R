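make_results_df <- function(hit_ranks, n_ranks = 5) {
  # synthetic retrieval results: query qXX has its pair "bXX" at the given
  # rank (NA = never retrieved)
  do.call(rbind, lapply(seq_along(hit_ranks), function(i) {
    ids <- sprintf("f%02d_%d", i, seq_len(n_ranks))
    if (!is.na(hit_ranks[i])) ids[hit_ranks[i]] <- sprintf("b%02d", i)
    data.frame(query_id = sprintf("q%02d", i), rank = seq_len(n_ranks),
               scan_id = ids, distance = seq_len(n_ranks) / 10)
  }))
}

pairs_for <- function(n) setNames(sprintf("b%02d", seq_len(n)),
                                  sprintf("q%02d", seq_len(n)))

test_that("pair retrieval rates reproduce the published worked examples", {
  # 20 rank-1 hits, 10 more at rank 2-3, 3 more at rank 4-5, 17 misses
  ranks <- c(rep(1, 20), rep(2, 4), rep(3, 6), rep(4, 2), 5,
             rep(NA, 17))
  rr <- pair_retrieval_rate(make_results_df(ranks), pairs_for(50))
  expect_equal(rr$hits, c(20, 30, 33))
  expect_equal(rr$percent, c(40.0, 60.0, 66.0))
  expect_true(all(diff(rr$percent) >= 0))  # monotone in k
  # saturation: all hits at rank 1
  rr2 <- pair_retrieval_rate(make_results_df(rep(1, 10)), pairs_for(10))
  expect_equal(rr2$percent, rep(100, 3))
  expect_equal(rr2$ci_upper, rep(100, 3))
  # unknown query is a mapping error
  expect_error(pair_retrieval_rate(make_results_df(c(1, 1)),
                                   pairs_for(1)), "mapping error")
})

test_that("Wilson intervals bracket the point estimate sensibly", {
  ci <- lungcbir:::wilson_ci(20, 50)
  expect_lt(ci[["lower"]], 40); expect_gt(ci[["upper"]], 40)
  expect_gt(ci[["lower"]], 0); expect_lt(ci[["upper"]], 100)
})

test_that("median split reproduces the published subgroup comparison", {
  # 18/25 hits above the median, 12/25 at or below
  ranks <- c(rep(1, 18), rep(NA, 7), rep(1, 12), rep(NA, 13))
  fv <- setNames(c(rep(10, 25), rep(1, 25)), sprintf("q%02d", 1:50))
  ms <- median_split_comparison(make_results_df(ranks), pairs_for(50),
                                fv, k = 3)
  expect_equal(ms$rate_high, 72.0)
  expect_equal(ms$rate_low, 48.0)
  expect_equal(ms$hits, c(18, 12))
  # standard two-sided Fisher p for this table, frozen from the
  # hypergeometric enumeration oracle below
  expect_equal(ms$p_value, 0.1481603, tolerance = 1e-6)
  # the mid-p variant matches the published 0.09
  expect_equal(ms$p_midp, 0.09, tolerance = 0.02 / 0.09)
  expect_error(median_split_comparison(make_results_df(ranks),
                                       pairs_for(50),
                                       setNames(rep(1, 50), names(fv)), 3),
               "degenerate")
})

test_that("Fisher p matches exhaustive hypergeometric enumeration", {
  enum_fisher <- function(x1, n1, x2, n2) {
    K <- x1 + x2
    xs <- max(0, K - n2):min(K, n1)
    pr <- vapply(xs, function(x)
      choose(n1, x) * choose(n2, K - x) / choose(n1 + n2, K), 1.0)
    pobs <- choose(n1, x1) * choose(n2, K - x1) / choose(n1 + n2, K)
    sum(pr[pr <= pobs * (1 + 1e-7)])
  }
  cases <- list(c(18, 25, 12, 25), c(25, 25, 0, 25), c(10, 25, 10, 25),
                c(5, 12, 9, 14), c(0, 8, 8, 8))
  for (cs in cases) {
    expect_equal(fisher_p_2x2(cs[c(1, 3)], cs[c(2, 4)]),
                 enum_fisher(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-12)
  }
  # identical outcomes give p = 1, extreme tables a point mass
  expect_equal(fisher_p_2x2(c(10, 10), c(25, 25)), 1)
  expect_lt(fisher_p_2x2(c(25, 0), c(25, 25)), 1e-12)
})

test_that("score summaries reproduce the published pooled values", {
  rt <- table4_like_ratings()
  ss <- score_summaries(rt, n_boot = 200, seed = 99)
  g <- function(rd, rk) ss[ss$reader == rd & ss$rank == rk, ]
  expect_equal(g("1", "overall")$pct_ge_threshold, 53.2)
  expect_equal(g("2", "overall")$pct_ge_threshold, 76.4)
  expect_equal(g("pooled", "overall")$pct_ge_threshold, 64.8)
  expect_equal(g("pooled", "1")$pct_ge_threshold, 81.0)
  expect_equal(g("pooled", "1")$mean_score, 4.25)
  expect_equal(g("pooled", "overall")$mean_score, 3.8, tolerance = 0.005)
  # pooled percent equals the count-weighted mean of reader percents
  expect_equal(g("pooled", "overall")$pct_ge_threshold,
               (g("1", "overall")$pct_ge_threshold +
                  g("2", "overall")$pct_ge_threshold) / 2)
  # bootstrap CI brackets the estimate
  expect_lt(g("pooled", "overall")$pct_ci_lower, 64.8)
  expect_gt(g("pooled", "overall")$pct_ci_upper, 64.8)
})

test_that("constant maximal scores collapse the summaries", {
  rt <- expand.grid(query_id = sprintf("q%d", 1:10), rank = 1:5,
                    reader = 1:2)
  rt$score <- 5L
  ss <- score_summaries(rt, n_boot = 50)
  expect_true(all(ss$pct_ge_threshold == 100))
  expect_true(all(ss$mean_score == 5))
  expect_true(all(ss$mean_se == 0))
})

test_that("at-least-one-score summaries match the published counts", {
  rt <- table4_like_ratings()
  a5 <- at_least_one_score(rt, 5)
  expect_equal(a5$hits, c(38, 36, 74))
  expect_equal(a5$percent[3], 74)
  # the >= 4 variant
  a4 <- at_least_one_score(rt, 4, comparison = "ge")
  expect_true(all(a4$percent >= a5$percent))
  # zero and saturation cases
  rt0 <- rt; rt0$score <- pmin(rt0$score, 4L)
  expect_equal(at_least_one_score(rt0, 5)$percent, c(0, 0, 0))
  rt1 <- rt; rt1$score[rt1$rank == 1] <- 5L
  expect_equal(at_least_one_score(rt1, 5)$percent, c(100, 100, 100))
})

test_that("ratings are validated for completeness", {
  rt <- table4_like_ratings()
  expect_error(score_summaries(rt[-1, ]), "completeness")
  bad <- rt; bad$score[1] <- 7L
  expect_error(score_summaries(bad), "1..5")
})

test_that("weighted kappa matches its defining formula", {
  # perfect agreement
  expect_equal(weighted_kappa(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5),
                              n_boot = 0)$kappa, 1)
  # hand-computed 4-pair case: all mass on the two off-diagonal cells,
  # uniform marginals: sum(wO) = 1, sum(wE) = 0.5, kappa = -1
  expect_equal(weighted_kappa(c(1, 1, 2, 2), c(2, 2, 1, 1),
                              n_boot = 0)$kappa, -1, tolerance = 1e-12)
  # direct evaluation of the O/E formula on a random case
  set.seed(41)
  r1 <- sample(1:5, 60, TRUE); r2 <- sample(1:5, 60, TRUE)
  O <- table(factor(r1, 1:5), factor(r2, 1:5)) / 60
  E <- outer(rowSums(O), colSums(O))
  W <- abs(outer(1:5, 1:5, "-")) / 4
  expect_equal(weighted_kappa(r1, r2, n_boot = 0)$kappa,
               1 - sum(W * O) / sum(W * E), tolerance = 1e-12)
  expect_equal(weighted_kappa(r1, r2, "quadratic", n_boot = 0)$kappa,
               1 - sum(W^2 * O) / sum(W^2 * E), tolerance = 1e-12)
})

test_that("kappa is symmetric and invariant to order-preserving relabels", {
  set.seed(43)
  r1 <- sample(1:5, 80, TRUE); r2 <- sample(1:5, 80, TRUE)
  expect_equal(weighted_kappa(r1, r2, n_boot = 0)$kappa,
               weighted_kappa(r2, r1, n_boot = 0)$kappa)
  # common affine relabel preserves ordinal spacing
  expect_equal(weighted_kappa(2 * r1 + 1, 2 * r2 + 1, n_boot = 0)$kappa,
               weighted_kappa(r1, r2, n_boot = 0)$kappa, tolerance = 1e-12)
  expect_error(weighted_kappa(rep(3, 5), rep(3, 5), n_boot = 0),
               "single observed")
})

test_that("independent random scores give kappa near zero", {
  set.seed(47)
  r1 <- sample(1:5, 2000, TRUE)
  r2 <- sample(1:5, 2000, TRUE)
  expect_lt(abs(weighted_kappa(r1, r2, n_boot = 0)$kappa), 0.05)
})

test_that("ICC(2,1) matches a direct two-way ANOVA computation", {
  r1 <- c(1, 2, 3, 4, 5, 5); r2 <- c(2, 2, 4, 4, 5, 4)
  # oracle: mean squares from aov on the long layout
  long <- data.frame(y = c(r1, r2),
                     unit = factor(rep(1:6, 2)),
                     rater = factor(rep(1:2, each = 6)))
  ms <- summary(aov(y ~ unit + rater, data = long))[[1]]$`Mean Sq`
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
  n <- 6; k <- 2
  oracle <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  expect_equal(icc(r1, r2)$icc, oracle, tolerance = 1e-9)
})

test_that("ICC semantics: identity, bias, and degenerate input", {
  r <- c(1, 2, 3, 4, 5, 5)
  expect_equal(icc(r, r)$icc, 1)
  shifted <- icc(r + 1, r)
  expect_lt(shifted$icc, 1)  # absolute agreement penalizes bias
  expect_equal(icc(r + 1, r, type = "consistency")$icc, 1)
  expect_warning(z <- icc(rep(3, 6), rep(3, 6)), "degenerate")
  expect_equal(z$icc, 0)
  # CI brackets the estimate
  set.seed(51)
  a <- rnorm(40); b <- a + rnorm(40, 0, 0.5)
  out <- icc(a, b)
  expect_lt(out$ci_lower, out$icc)
  expect_gt(out$ci_upper, out$icc)
})
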