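# Step 2: the four duplex binding features and threshold filtering.
#
# For one duplex: mm_mrna = unpaired UTR positions inside the duplex span,
# mm_mirna = unpaired miRNA positions over the whole miRNA (dangling ends
# included), gu_whole = G-U wobble pairs anywhere in the duplex, gu_seed =
# G-U wobble pairs whose miRNA position lies in the hit's seed window.

feature_names <- function() c("mm_mrna", "mm_mirna", "gu_whole", "gu_seed")

#' Scanned feature ranges
#'
#' Upper ends of the scanned ranges for the four binding features:
#' mismatches of mRNA 28-0, mismatches of miRNA 14-0, G-U pairs overall
#' 10-0, G-U pairs in the seed 6-0.
#' @return Named integer vector of maxima.
#' @export
feature_ranges <- function() {
  c(mm_mrna = 28L, mm_mirna = 14L, gu_whole = 10L, gu_seed = 6L)
}

features_of_hit <- function(pair_tbl, seed_offset, mirna_len) {
  span <- pair_tbl$utr_pos[1]:pair_tbl$utr_pos[nrow(pair_tbl)]
  win <- seed_window_positions[[seed_offset]]
  gu <- pair_tbl$pair_class == "GU"
  c(mm_mrna = sum(!span %in% pair_tbl$utr_pos),
    mm_mirna = sum(!seq_len(mirna_len) %in% pair_tbl$mirna_pos),
    gu_whole = sum(gu),
    gu_seed = sum(gu & pair_tbl$mirna_pos %in% win))
}

#' Compute the four binding features of duplex hits
#'
#' Appends the columns `mm_mrna`, `mm_mirna`, `gu_whole` and `gu_seed` to a
#' hit table. Mismatches of the mRNA are counted only inside the duplex span
#' `[site_start, site_end]`; mismatches of the miRNA are counted over the
#' whole miRNA including unpaired terminal nucleotides.
#'
#' @param hits duplex-hit tibble with a non-`NA` `seed_offset` (run
#'   [seed_constraint()] first); features of the seed are undefined without
#'   it.
#' @param mirnas tibble supplying miRNA lengths (matched on `mirna_id`), or
#'   `NULL` if `hits` already carries a `mirna_length` column.
#' @return `hits` with four feature columns appended.
#' @export
compute_features <- function(hits, mirnas = NULL) {
  if (nrow(hits) == 0) {
    return(mutate(hits, mm_mrna = integer(), mm_mirna = integer(),
                  gu_whole = integer(), gu_seed = integer()))
  }
  if (anyNA(hits$seed_offset)) {
    abort("hits without a seed_offset label: seed features are undefined")
  }
  if (!"mirna_length" %in% names(hits)) {
    if (is.null(mirnas)) abort("supply `mirnas` to resolve miRNA lengths")
    hits$mirna_length <- nchar(
      mirnas$sequence[match(hits$mirna_id, mirnas$mirna_id)])
    if (anyNA(hits$mirna_length)) abort("hit miRNA id missing from `mirnas`")
  }
  fx <- purrr::pmap(
    list(hits$pairs, hits$seed_offset, hits$mirna_length),
    features_of_hit
  )
  fx <- do.call(rbind, fx)
  hits$mm_mrna <- as.integer(fx[, "mm_mrna"])
  hits$mm_mirna <- as.integer(fx[, "mm_mirna"])
  hits$gu_whole <- as.integer(fx[, "gu_whole"])
  hits$gu_seed <- as.integer(fx[, "gu_seed"])
  hits
}

#' Binding-feature thresholds
#'
#' Container for the four feature maxima. The defaults are the optimal
#' combination selected by the Enrichment x Coverage grid search on the
#' full-scale screen: at most 12 mRNA mismatches, 10 miRNA mismatches,
#' 4 G-U pairs overall and 0 G-U pairs in the seed.
#'
#' @param max_mm_mrna,max_mm_mirna,max_gu_whole,max_gu_seed feature maxima.
#' @return A named integer vector of class `filter_params`.
#' @export
filter_params <- function(max_mm_mrna = 12, max_mm_mirna = 10,
                          max_gu_whole = 4, max_gu_seed = 0) {
  p <- c(mm_mrna = as.integer(max_mm_mrna), mm_mirna = as.integer(max_mm_mirna),
         gu_whole = as.integer(max_gu_whole), gu_seed = as.integer(max_gu_seed))
  if (any(p < 0)) abort("feature thresholds must be non-negative")
  structure(p, class = c("filter_params", class(p)))
}

#' Apply the binding-feature filter
#'
#' A hit passes when every feature is less than or equal to its threshold
#' (inclusive semantics: the optimal `gu_seed = 0` admits hits with zero
#' seed wobbles).
#'
#' @param features a hit tibble carrying the four feature columns (from
#'   [compute_features()]), or a named vector of the four counts.
#' @param params a [filter_params()] vector.
#' @return Logical vector, one element per hit.
#' @export
apply_filter <- function(features, params = filter_params()) {
  fn <- feature_names()
  if (is.data.frame(features)) {
    m <- as.matrix(features[fn])
  } else {
    m <- matrix(features[fn], nrow = 1, dimnames = list(NULL, fn))
  }
  as.vector(rowSums(sweep(m, 2, params[fn], `>`)) == 0)
}

#' Filter a hit table on its binding features
#'
#' Convenience wrapper: computes features if absent and keeps passing hits.
#'
#' @inheritParams compute_features
#' @inheritParams apply_filter
#' @return The filtered hit tibble (features included).
#' @export
filter_hits <- function(hits, params = filter_params(), mirnas = NULL) {
  if (!all(feature_names() %in% names(hits))) {
    hits <- compute_features(hits, mirnas)
  }
  hits[apply_filter(hits, params), , drop = FALSE]
}
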