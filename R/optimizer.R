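# Binding-feature threshold optimization: per-feature coverage curves on
# verified vs predicted hits, candidate-range selection at the largest
# coverage gap, and an Enrichment x Coverage grid search.

#' Coverage curve of one binding feature
#'
#' For each candidate threshold value v, the coverage of a set is the
#' fraction of its hits whose feature is <= v. Curves are computed
#' separately for experimentally verified and for predicted hits; their
#' difference (`gap`) drives candidate-range selection.
#'
#' @param hits hit tibble with feature columns and a logical `verified`
#'   column flagging the experimentally verified subset.
#' @param feature_name one of `"mm_mrna"`, `"mm_mirna"`, `"gu_whole"`,
#'   `"gu_seed"`.
#' @param values threshold values to evaluate (default `0:max` of the
#'   feature's scanned range).
#' @return A tibble of class `coverage_curve` with columns `feature`,
#'   `value`, `cov_verified`, `cov_predicted`, `gap`.
#' @export
coverage_curve <- function(hits, feature_name,
                           values = 0:feature_ranges()[[feature_name]]) {
  if (!feature_name %in% feature_names()) {
    abort(paste0("unknown feature: ", feature_name))
  }
  if (!"verified" %in% names(hits)) abort("hits must carry a `verified` flag")
  if (!any(hits$verified)) abort("no verified hits: coverage gap undefined")
  if (!any(!hits$verified)) abort("no predicted hits: coverage gap undefined")
  f <- hits[[feature_name]]
  cov <- function(x, v) vapply(v, function(t) mean(x <= t), numeric(1))
  out <- tibble(
    feature = feature_name,
    value = as.integer(values),
    cov_verified = cov(f[hits$verified], values),
    cov_predicted = cov(f[!hits$verified], values)
  )
  out$gap <- out$cov_verified - out$cov_predicted
  structure(arrange(out, .data$value), class = c("coverage_curve", class(out)))
}

#' Select candidate threshold ranges from coverage curves
#'
#' For each feature, keeps the `k` threshold values with the largest
#' verified-minus-predicted coverage gap (ties resolved toward stricter,
#' i.e. smaller, values), returned in ascending order. The default grid
#' shape (5, 5, 5, 4) yields 500 parameter combinations.
#'
#' @param curves a list of [coverage_curve()] tibbles (or one combined
#'   tibble), covering each feature once.
#' @param k_per_feature named integer vector, values in `{4, 5}`.
#' @return Named list of integer vectors, one per feature.
#' @export
select_ranges <- function(curves,
                          k_per_feature = c(mm_mrna = 5, mm_mirna = 5,
                                            gu_whole = 5, gu_seed = 4)) {
  if (is.data.frame(curves)) curves <- split(curves, curves$feature)
  curves <- setNames(curves, vapply(curves, function(c) c$feature[1],
                                    character(1)))
  purrr::imap(k_per_feature, function(k, fname) {
    cur <- curves[[fname]]
    if (is.null(cur)) abort(paste0("no curve supplied for feature ", fname))
    if (k > nrow(cur)) {
      abort(paste0("k = ", k, " exceeds the ", nrow(cur),
                   " scanned values of ", fname))
    }
    ord <- order(-cur$gap, cur$value) # largest gap first, stricter on ties
    sort(cur$value[ord[seq_len(k)]])
  })
}

#' Grid search over binding-feature threshold combinations
#'
#' Evaluates every combination in the Cartesian product of the candidate
#' ranges. For each combination: coverage = percent of verified hits kept,
#' enrichment = (percent of verified kept) / (percent of predicted kept),
#' and EC = enrichment x coverage (unrounded). The best combination
#' maximises EC; ties are broken by higher coverage, then by stricter
#' thresholds in the order mm_mrna, mm_mirna, gu_whole, gu_seed.
#'
#' @param hits hit tibble with feature columns and a logical `verified`
#'   column.
#' @param candidate_ranges named list of threshold values per feature, as
#'   from [select_ranges()].
#' @param n_ver_total,n_pred_total denominators for coverage and enrichment;
#'   default to the verified / predicted hits present in `hits` (the step-1
#'   baseline).
#' @return A list of class `grid_search` with elements `grid` (tibble of all
#'   combinations with `n_pred_kept`, `n_ver_kept`, `coverage_pct`,
#'   `enrichment`, `ec`) and `best` (one-row tibble).
#' @export
grid_search <- function(hits, candidate_ranges,
                        n_ver_total = NULL, n_pred_total = NULL) {
  fn <- feature_names()
  if (!all(fn %in% names(candidate_ranges))) {
    abort("candidate_ranges must name all four features")
  }
  if (any(lengths(candidate_ranges) == 0)) abort("empty candidate range")
  ver <- hits$verified
  n_ver_total <- n_ver_total %||% sum(ver)
  n_pred_total <- n_pred_total %||% sum(!ver)
  if (n_ver_total == 0) abort("no verified hits: optimization undefined")
  grid <- expand.grid(candidate_ranges[fn], KEEP.OUT.ATTRS = FALSE)
  names(grid) <- fn
  fm <- as.matrix(hits[fn])
  res <- purrr::pmap_dfr(grid, function(mm_mrna, mm_mirna, gu_whole, gu_seed) {
    keep <- fm[, 1] <= mm_mrna & fm[, 2] <= mm_mirna &
      fm[, 3] <= gu_whole & fm[, 4] <= gu_seed
    n_ver <- sum(keep & ver)
    n_pred <- sum(keep & !ver)
    cov <- 100 * n_ver / n_ver_total
    pred_pct <- 100 * n_pred / n_pred_total
    enr <- if (pred_pct == 0) {
      if (cov > 0) Inf else NA_real_
    } else cov / pred_pct
    tibble(n_pred_kept = n_pred, n_ver_kept = n_ver,
           coverage_pct = cov, enrichment = enr,
           ec = enr * cov)
  })
  grid <- dplyr::bind_cols(as_tibble(grid), res)
  ord <- order(-grid$ec, -grid$coverage_pct, grid$mm_mrna, grid$mm_mirna,
               grid$gu_whole, grid$gu_seed)
  structure(list(grid = grid, best = grid[ord[1], ]), class = "grid_search")
}

#' @export
print.grid_search <- function(x, ...) {
  cat("<grid_search: ", nrow(x$grid), " parameter combinations>\n", sep = "")
  cat("best (max EC):\n")
  print(as.data.frame(x$best), row.names = FALSE)
  invisible(x)
}

#' @describeIn grid_search optimal thresholds as a [filter_params()] vector.
#' @param x a `grid_search` object.
#' @export
best_params <- function(x) {
  stopifnot(inherits(x, "grid_search"))
  filter_params(x$best$mm_mrna, x$best$mm_mirna, x$best$gu_whole,
                x$best$gu_seed)
}
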