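# The CBIR core: a database of 22-feature vectors normalized by per-feature
# 95th percentiles, queried by per-category cosine distance.

check_feature_table <- function(features) {
  if (!is.data.frame(features)) stop("`features` must be a data frame")
  fn <- feature_names()
  missing_cols <- setdiff(c("scan_id", fn), names(features))
  if (length(missing_cols))
    stop("completeness error: missing feature columns: ",
         paste(missing_cols, collapse = ", "))
  vals <- as.matrix(features[fn])
  if (any(!is.finite(vals)))
    stop("completeness error: non-finite feature values")
  if (any(vals < 0))
    stop("feature values must be non-negative")
  if (anyDuplicated(features$scan_id))
    stop("identity error: duplicate scan_id in feature table")
  vals
}

#' Build a retrieval index from a feature table
#'
#' Computes, for each of the 22 features, its 95th percentile over the
#' database (linear interpolation between order statistics) and stores
#' every feature vector divided by these normalizers. A feature constant at
#' zero gets a normalizer of 1 (with a warning) so the division is defined.
#'
#' @param features Data frame with a `scan_id` column and the 22 columns of
#'   [feature_names()]; all values finite and non-negative.
#' @return Object of class `cbir_index`: `scan_ids`, `normalized` matrix
#'   (scans x features), `normalizers`, `categories`.
#' @export
build_index <- function(features) {
  vals <- check_feature_table(features)
  if (nrow(vals) < 2L) stop("an index needs at least 2 feature vectors")
  normalizers <- apply(vals, 2, quantile, probs = 0.95, type = 7, names = FALSE)
  zero <- normalizers <= 0
  if (any(zero)) {
    warning("features constant at 0 get a unit normalizer: ",
            paste(colnames(vals)[zero], collapse = ", "))
    normalizers[zero] <- 1
  }
  structure(list(scan_ids = as.character(features$scan_id),
                 normalized = sweep(vals, 2, normalizers, "/"),
                 normalizers = normalizers,
                 categories = feature_categories()),
            class = "cbir_index")
}

#' @export
print.cbir_index <- function(x, ...) {
  cat(sprintf("CBIR index: %d scans x %d features (p95-normalized)\n",
              length(x$scan_ids), ncol(x$normalized)))
  invisible(x)
}

# cosine distance of a vector against the rows of a matrix, with the
# zero-norm convention: both zero -> 0, one zero -> 1
cosine_distance_rows <- function(U, v) {
  nu <- sqrt(rowSums(U^2))
  nv <- sqrt(sum(v^2))
  d <- rep(NA_real_, nrow(U))
  both0 <- nu == 0 & nv == 0
  one0 <- xor(nu == 0, nv == 0)
  ok <- !both0 & !one0
  d[both0] <- 0
  d[one0] <- 1
  if (any(ok)) d[ok] <- 1 - (U[ok, , drop = FALSE] %*% v) / (nu[ok] * nv)
  pmin(pmax(d, 0), 1)
}

#' Query the index for the most similar scans
#'
#' The query vector is normalized by the index's stored 95th percentiles;
#' for each database entry a cosine distance is computed per feature
#' category (EI, D-slope, Pi10, VN sub-vectors) and the combined distance
#' is their unweighted mean (`mode = "mean"`) or the cosine distance of the
#' concatenated 22-vector (`mode = "concat"`). The most similar scans have
#' the smallest distance; ties are broken by scan_id.
#'
#' @param index A [build_index()] result.
#' @param q Query: named numeric vector covering [feature_names()], or a
#'   one-row data frame with `scan_id` + features.
#' @param k Number of results (default 5).
#' @param exclude_self Drop the database entry whose scan_id equals the
#'   query's.
#' @param mode Distance combination rule.
#' @return Object of class `cbir_result`: data frame with `rank`,
#'   `scan_id`, `distance` and per-category distances, sorted ascending,
#'   with the query id in attribute/field `query_id`.
#' @export
query_index <- function(index, q, k = 5, exclude_self = FALSE,
                        mode = c("mean", "concat")) {
  mode <- match.arg(mode)
  stopifnot(inherits(index, "cbir_index"))
  if (!is.numeric(k) || length(k) != 1 || k < 1)
    stop("parameter error: k must be >= 1")
  query_id <- NA_character_
  if (is.data.frame(q)) {
    if ("scan_id" %in% names(q)) query_id <- as.character(q$scan_id[1])
    q <- unlist(q[1, feature_names(), drop = TRUE])
  }
  fn <- feature_names()
  if (!all(fn %in% names(q)))
    stop("completeness error: query is missing features: ",
         paste(setdiff(fn, names(q)), collapse = ", "))
  qv <- as.numeric(q[fn])
  if (any(!is.finite(qv))) stop("completeness error: non-finite query values")
  qn <- qv / index$normalizers

  cats <- unique(unname(index$categories))
  dcat <- sapply(cats, function(cl) {
    cols <- which(index$categories == cl)
    cosine_distance_rows(index$normalized[, cols, drop = FALSE], qn[cols])
  })
  combined <- if (mode == "mean") rowMeans(dcat)
  else cosine_distance_rows(index$normalized, qn)

  keep <- rep(TRUE, length(index$scan_ids))
  if (exclude_self && !is.na(query_id)) keep <- index$scan_ids != query_id
  ids <- index$scan_ids[keep]
  combined <- combined[keep]
  dcat <- dcat[keep, , drop = FALSE]
  o <- order(combined, ids)
  top <- head(o, min(k, length(o)))
  res <- data.frame(rank = seq_along(top), scan_id = ids[top],
                    distance = combined[top])
  res[paste0("d_", cats)] <- dcat[top, , drop = FALSE]
  structure(list(query_id = query_id, mode = mode, results = res),
            class = "cbir_result")
}

#' @export
print.cbir_result <- function(x, ...) {
  cat(sprintf("Query %s (mode = %s):\n",
              if (is.na(x$query_id)) "<unnamed>" else x$query_id, x$mode))
  print(x$results, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Save or load a retrieval index as JSON
#'
#' Reals are serialized at full precision (17 significant digits) so a
#' save/load round trip reproduces rankings exactly.
#'
#' @param index A `cbir_index`.
#' @param path JSON file path.
#' @return `load_index()` returns the `cbir_index`; `save_index()` returns
#'   `path` invisibly.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "cbir_index"))
  obj <- list(format = "lungcbir-index", version = 1L,
              scan_ids = index$scan_ids,
              features = colnames(index$normalized),
              normalizers = unname(index$normalizers),
              normalized = lapply(seq_len(nrow(index$normalized)),
                                  function(i) unname(index$normalized[i, ])))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("format error: unreadable index: ",
                                           conditionMessage(e)))
  need <- c("format", "scan_ids", "features", "normalizers", "normalized")
  if (!is.list(obj) || !all(need %in% names(obj)) ||
      !identical(obj$format, "lungcbir-index"))
    stop("format error: not a lungcbir index file")
  fn <- feature_names()
  if (!identical(as.character(obj$features), fn))
    stop("format error: feature schema mismatch")
  normalized <- obj$normalized
  if (is.list(normalized)) normalized <- do.call(rbind, normalized)
  if (!is.matrix(normalized) || ncol(normalized) != length(fn) ||
      nrow(normalized) != length(obj$scan_ids))
    stop("format error: malformed normalized matrix")
  colnames(normalized) <- fn
  structure(list(scan_ids = as.character(obj$scan_ids),
                 normalized = normalized,
                 normalizers = setNames(as.numeric(obj$normalizers), fn),
                 categories = feature_categories()),
            class = "cbir_index")
}
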