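# Evaluation protocol: paired-query retrieval accuracy with Wilson CIs,
# median-split subgroup comparison with Fisher exact tests, similarity-score
# summaries with query-clustered bootstrap CIs, and inter-reader agreement
# (weighted kappa, ICC).

results_to_df <- function(results) {
  if (is.data.frame(results)) return(results)
  if (inherits(results, "cbir_result")) results <- list(results)
  do.call(rbind, lapply(results, function(r) {
    data.frame(query_id = r$query_id, rank = r$results$rank,
               scan_id = r$results$scan_id, distance = r$results$distance)
  }))
}

# Wilson score interval for a binomial proportion, in percent
wilson_ci <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  100 * c(lower = max(0, ctr - hw), upper = min(1, ctr + hw))
}

#' Rate of retrieving the paired baseline scan within the top k
#'
#' A query "hits" at k when its baseline pair appears among its first k
#' retrievals. Confidence intervals are Wilson score intervals.
#'
#' @param results List of [query_index()] results (or a data frame with
#'   columns `query_id`, `rank`, `scan_id`).
#' @param pairs Named character vector mapping query_id to its baseline
#'   scan_id.
#' @param ks Values of k to report.
#' @param conf Confidence level.
#' @return Data frame with `k`, `hits`, `n`, `percent`, `ci_lower`,
#'   `ci_upper`.
#' @export
pair_retrieval_rate <- function(results, pairs, ks = c(1, 3, 5),
                                conf = 0.95) {
  df <- results_to_df(results)
  qids <- unique(df$query_id)
  miss <- setdiff(qids, names(pairs))
  if (length(miss))
    stop("mapping error: queries without a pair entry: ",
         paste(miss, collapse = ", "))
  n <- length(qids)
  hit_rank <- vapply(qids, function(q) {
    sub <- df[df$query_id == q, ]
    w <- which(sub$scan_id == pairs[[q]])
    if (length(w)) min(sub$rank[w]) else Inf
  }, 1.0)
  out <- lapply(ks, function(k) {
    hits <- sum(hit_rank <= k)
    ci <- wilson_ci(hits, n, conf)
    data.frame(k = k, hits = hits, n = n, percent = 100 * hits / n,
               ci_lower = ci[["lower"]], ci_upper = ci[["upper"]])
  })
  do.call(rbind, out)
}

#' Two-sided Fisher exact p for a 2x2 hit table
#'
#' `method = "fisher"` is the standard two-sided Fisher exact test
#' (hypergeometric enumeration, as in [stats::fisher.test()]);
#' `method = "midp"` is the mid-p variant, which counts the observed
#' table's probability with weight 1/2 and is less conservative.
#'
#' @param hits Length-2 integer vector of hits per group.
#' @param n Length-2 integer vector of group sizes.
#' @param method `"fisher"` or `"midp"`.
#' @return p value.
#' @export
fisher_p_2x2 <- function(hits, n, method = c("fisher", "midp")) {
  method <- match.arg(method)
  tab <- matrix(c(hits[1], n[1] - hits[1], hits[2], n[2] - hits[2]),
                2, byrow = TRUE)
  if (method == "fisher") return(fisher.test(tab)$p.value)
  K <- sum(hits)
  xs <- max(0, K - n[2]):min(K, n[1])
  probs <- dhyper(xs, n[1], n[2], K)
  pobs <- dhyper(hits[1], n[1], n[2], K)
  tol <- pobs * 1e-7
  sum(probs[probs < pobs - tol]) + 0.5 * sum(probs[abs(probs - pobs) <= tol])
}

#' Median-split subgroup comparison of retrieval accuracy
#'
#' Splits the queries at the median of a feature (`> median` vs
#' `<= median`), compares the top-k pair-retrieval rates of the two halves,
#' and tests the 2x2 hit table with Fisher's exact test (standard two-sided
#' p plus the mid-p variant).
#'
#' @param results,pairs As in [pair_retrieval_rate()].
#' @param feature_values Named numeric vector: one feature value per query.
#' @param k Retrieval depth of the hit definition.
#' @return List: `threshold` (the median), `rate_high`, `rate_low`
#'   (percent), `hits` and `n` per group (high first), `p_value`
#'   (two-sided Fisher), `p_midp`.
#' @export
median_split_comparison <- function(results, pairs, feature_values, k = 3) {
  df <- results_to_df(results)
  qids <- unique(df$query_id)
  fv <- feature_values[qids]
  if (any(is.na(fv))) stop("feature_values missing for some queries")
  if (length(unique(fv)) == 1L)
    stop("degenerate split: all feature values identical")
  thr <- median(fv)
  grp_high <- fv > thr
  hit <- vapply(qids, function(q) {
    sub <- df[df$query_id == q & df$rank <= k, ]
    pairs[[q]] %in% sub$scan_id
  }, TRUE)
  hits <- c(sum(hit[grp_high]), sum(hit[!grp_high]))
  ns <- c(sum(grp_high), sum(!grp_high))
  list(threshold = unname(thr),
       rate_high = 100 * hits[1] / ns[1],
       rate_low = 100 * hits[2] / ns[2],
       hits = hits, n = ns,
       p_value = fisher_p_2x2(hits, ns, "fisher"),
       p_midp = fisher_p_2x2(hits, ns, "midp"))
}

check_ratings <- function(ratings) {
  need <- c("query_id", "rank", "reader", "score")
  if (!is.data.frame(ratings) || !all(need %in% names(ratings)))
    stop("ratings need columns ", paste(need, collapse = ", "))
  if (any(!ratings$score %in% 1:5))
    stop("scores must be integers in 1..5")
  cells <- with(ratings, paste(query_id, rank, reader))
  if (anyDuplicated(cells))
    stop("completeness error: duplicated (query, rank, reader) cells")
  counts <- table(ratings$reader)
  if (length(unique(counts)) > 1L ||
      length(unique(table(ratings$query_id))) > 1L)
    stop("completeness error: ratings are not complete per (query, rank, reader)")
  invisible(ratings)
}

# cluster (query) bootstrap of a statistic over a ratings subset
cluster_boot <- function(data, stat, n_boot, seed, conf = 0.95) {
  qs <- unique(data$query_id)
  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      pick <- sample(qs, length(qs), replace = TRUE)
      idx <- unlist(lapply(pick, function(q) which(data$query_id == q)))
      stat(data[idx, , drop = FALSE])
    }, 1.0)
  })
  a <- (1 - conf) / 2
  c(se = sd(reps), lower = unname(quantile(reps, a, names = FALSE)),
    upper = unname(quantile(reps, 1 - a, names = FALSE)))
}

#' Similarity-score summaries per reader, rank, and pooled
#'
#' For each reader, each retrieval rank, and the pooled data: the percent
#' of ratings at or above `threshold`, the mean score, and query-clustered
#' bootstrap standard errors and confidence intervals (queries resampled
#' with replacement, preserving the within-query correlation of the five
#' ranked ratings).
#'
#' @param ratings Data frame with columns `query_id`, `rank` (1..5),
#'   `reader`, `score` (1..5); complete for every (query, rank, reader).
#' @param threshold Score threshold (default 4: "two or more similar
#'   features").
#' @param n_boot Bootstrap resamples.
#' @param seed Bootstrap seed.
#' @param conf Confidence level.
#' @return Data frame with one row per (reader or "pooled") x (rank or
#'   "overall"): `pct_ge_threshold`, `mean_score` and their `se`/CI
#'   columns.
#' @export
score_summaries <- function(ratings, threshold = 4, n_boot = 1000,
                            seed = 1, conf = 0.95) {
  check_ratings(ratings)
  readers <- sort(unique(ratings$reader))
  ranks <- sort(unique(ratings$rank))
  groups <- expand.grid(reader = c(as.character(readers), "pooled"),
                        rank = c(as.character(ranks), "overall"),
                        stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(groups)), function(i) {
    rd <- groups$reader[i]; rk <- groups$rank[i]
    sub <- ratings
    if (rd != "pooled") sub <- sub[as.character(sub$reader) == rd, ]
    if (rk != "overall") sub <- sub[as.character(sub$rank) == rk, ]
    pct <- function(d) 100 * mean(d$score >= threshold)
    mn <- function(d) mean(d$score)
    bp <- cluster_boot(sub, pct, n_boot, seed + i, conf)
    bm <- cluster_boot(sub, mn, n_boot, seed + i + 10000, conf)
    data.frame(reader = rd, rank = rk, n = nrow(sub),
               pct_ge_threshold = pct(sub),
               pct_se = bp[["se"]], pct_ci_lower = bp[["lower"]],
               pct_ci_upper = bp[["upper"]],
               mean_score = mn(sub), mean_se = bm[["se"]],
               mean_ci_lower = bm[["lower"]], mean_ci_upper = bm[["upper"]])
  })
  do.call(rbind, out)
}

#' Percent of queries with at least one retrieval at a given score
#'
#' Per reader, the fraction of queries whose ranked retrievals contain at
#' least one rating equal to `score` (`comparison = "eq"`) or at least
#' `score` (`"ge"`); pooled over reader-query units.
#'
#' @inheritParams score_summaries
#' @param score Target score (default 5: "all features similar").
#' @param comparison `"eq"` or `"ge"`.
#' @return Data frame with rows per reader and pooled: `hits`, `n`,
#'   `percent`.
#' @export
at_least_one_score <- function(ratings, score = 5,
                               comparison = c("eq", "ge")) {
  comparison <- match.arg(comparison)
  check_ratings(ratings)
  cmp <- if (comparison == "eq") `==` else `>=`
  readers <- sort(unique(ratings$reader))
  per <- lapply(readers, function(rd) {
    sub <- ratings[ratings$reader == rd, ]
    byq <- tapply(cmp(sub$score, score), sub$query_id, any)
    data.frame(reader = as.character(rd), hits = sum(byq), n = length(byq))
  })
  per <- do.call(rbind, per)
  pooled <- data.frame(reader = "pooled", hits = sum(per$hits),
                       n = sum(per$n))
  out <- rbind(per, pooled)
  out$percent <- 100 * out$hits / out$n
  out
}

#' Weighted kappa for two readers' ordinal scores
#'
#' Chance-corrected agreement `1 - sum(w * O) / sum(w * E)` with
#' disagreement weights growing with category distance: linear
#' `|i - j| / (c - 1)` or quadratic. The observed proportions O come from
#' the cross-tabulation, the expected E from the product of the marginals.
#' The confidence interval is a cluster bootstrap (over `cluster` units if
#' given, else over observations).
#'
#' @param r1,r2 Integer score vectors of equal length.
#' @param weights `"linear"` or `"quadratic"`.
#' @param cluster Optional cluster ids (e.g. query ids) for the bootstrap.
#' @param n_boot,seed,conf Bootstrap settings; `n_boot = 0` skips the CI.
#' @return List: `kappa`, `ci_lower`, `ci_upper`, `weights`.
#' @export
weighted_kappa <- function(r1, r2, weights = c("linear", "quadratic"),
                           cluster = NULL, n_boot = 1000, seed = 1,
                           conf = 0.95) {
  weights <- match.arg(weights)
  stopifnot(length(r1) == length(r2))
  if (length(unique(c(r1, r2))) < 2L)
    stop("undefined kappa: a single observed category")
  k <- kappa_stat(r1, r2, weights)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    if (is.null(cluster)) cluster <- seq_along(r1)
    dat <- data.frame(query_id = cluster, r1 = r1, r2 = r2)
    b <- cluster_boot(dat, function(d) {
      tryCatch(kappa_stat(d$r1, d$r2, weights), error = function(e) NA_real_)
    }, n_boot, seed, conf)
    ci <- c(b[["lower"]], b[["upper"]])
  }
  list(kappa = k, ci_lower = ci[1], ci_upper = ci[2], weights = weights)
}

kappa_stat <- function(r1, r2, weights) {
  cats <- sort(unique(c(r1, r2)))
  c_n <- length(cats)
  if (c_n < 2L) stop("undefined kappa: a single observed category")
  O <- table(factor(r1, cats), factor(r2, cats)) / length(r1)
  p1 <- rowSums(O); p2 <- colSums(O)
  E <- outer(p1, p2)
  # weights from the actual score values, so sparse category sets keep
  # their ordinal spacing
  W <- abs(outer(cats, cats, "-")) / (max(cats) - min(cats))
  if (weights == "quadratic") W <- W^2
  1 - sum(W * O) / sum(W * E)
}

#' Intraclass correlation coefficient for two readers
#'
#' Two-way random-effects, single-measures ICC. `type = "agreement"` is
#' ICC(2,1) (absolute agreement; reader bias counts as disagreement),
#' `type = "consistency"` ignores a constant reader shift. The confidence
#' interval is the standard F-based interval.
#'
#' @param r1,r2 Numeric score vectors of equal length (one row per unit).
#' @param type `"agreement"` or `"consistency"`.
#' @param conf Confidence level.
#' @return List: `icc`, `ci_lower`, `ci_upper`, `type`.
#' @export
icc <- function(r1, r2, type = c("agreement", "consistency"), conf = 0.95) {
  type <- match.arg(type)
  stopifnot(length(r1) == length(r2))
  n <- length(r1); k <- 2
  Y <- cbind(r1, r2)
  if (var(as.vector(Y)) == 0 || var(rowMeans(Y)) == 0) {
    warning("degenerate: no between-unit variance; ICC reported as 0")
    return(list(icc = 0, ci_lower = NA_real_, ci_upper = NA_real_,
                type = type))
  }
  grand <- mean(Y)
  rowm <- rowMeans(Y); colm <- colMeans(Y)
  MSR <- k * sum((rowm - grand)^2) / (n - 1)
  MSC <- n * sum((colm - grand)^2) / (k - 1)
  SSE <- sum((Y - outer(rowm, rep(1, k)) -
                outer(rep(1, n), colm) + grand)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  if (type == "consistency") {
    est <- (MSR - MSE) / (MSR + (k - 1) * MSE)
    Fv <- MSR / MSE
    df1 <- n - 1; df2 <- (n - 1) * (k - 1)
    FL <- Fv / qf(1 - (1 - conf) / 2, df1, df2)
    FU <- Fv * qf(1 - (1 - conf) / 2, df2, df1)
    ci <- c((FL - 1) / (FL + k - 1), (FU - 1) / (FU + k - 1))
  } else {
    est <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
    # McGraw & Wong F-based interval for ICC(A,1)
    a <- (k * est) / (n * (1 - est))
    b <- 1 + k * est * (n - 1) / (n * (1 - est))
    v <- (a * MSC + b * MSE)^2 /
      ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    FL <- qf(1 - (1 - conf) / 2, n - 1, v)
    FU <- qf(1 - (1 - conf) / 2, v, n - 1)
    lo <- n * (MSR - FL * MSE) /
      (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    hi <- n * (FU * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
    ci <- c(lo, hi)
  }
  list(icc = unname(est), ci_lower = unname(ci[1]), ci_upper = unname(ci[2]),
       type = type)
}
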