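# Step 1: minimum-free-energy duplex prediction with seed-match screening.

empty_hits <- function() {
  tibble(
    mirna_id = character(), family = character(), species = character(),
    gene_id = character(), transcript_id = character(),
    site_start = integer(), site_end = integer(), dG = numeric(),
    seed_offset = character(), pairs = list(),
    utr_length = integer(), dist_from_stop = integer(),
    dist_from_3end = integer()
  )
}

#' Predict candidate miRNA target sites in one 3'-UTR
#'
#' Scans a 3'-UTR for intermolecular miRNA:mRNA duplexes by dynamic
#' programming over the nearest-neighbour energy model: the returned sites
#' are minimum-free-energy duplexes, enumerated greedily (the best site is
#' reported, its UTR span masked, and the scan repeated) so that reported
#' sites never overlap. No intramolecular structure is modelled. Hits are
#' unfiltered: apply [seed_constraint()] and a free-energy cutoff (see
#' [screen_step1()]) to obtain the step-1 candidate set.
#'
#' @param mirna one row of a mature-miRNA tibble (see [read_mirna_fasta()]).
#' @param utr one row of a 3'-UTR tibble (see [read_utr_fasta()]).
#' @param model an [energy_model()].
#' @param dG_keep only duplexes with `dG` (kcal/mol) strictly below this are
#'   enumerated; the default 0 keeps every stabilising duplex.
#' @param max_sites cap on the number of non-overlapping sites per UTR.
#'
#' @return A tibble of duplex hits, one row per site, with 1-based inclusive
#'   UTR coordinates, the duplex free energy `dG`, a `pairs` list-column
#'   (tibble of `utr_pos`, `mirna_pos`, `pair_class` in `{"WC","GU"}`), and
#'   site positions relative to the stop codon (`dist_from_stop`, the number
#'   of UTR nucleotides 5' of the site) and to the UTR 3' end.
#' @export
hybridize <- function(mirna, utr, model = energy_model(), dG_keep = 0,
                      max_sites = 25L) {
  stopifnot(inherits(model, "energy_model"))
  mseq <- if (is.list(mirna) || is.data.frame(mirna)) mirna$sequence else mirna
  useq <- if (is.list(utr) || is.data.frame(utr)) utr$sequence else utr
  ucodes <- encode_rna(useq)
  mcodes <- encode_rna(mseq)
  pen <- loop_penalty_tables(model)
  raw <- .duplex_scan(ucodes, mcodes, model$stack_dG, pen$bulge, pen$internal,
                      model$init_dG, model$max_gap_utr, model$max_gap_mirna,
                      dG_keep, as.integer(max_sites))
  if (length(raw) == 0) return(empty_hits())
  utr_len <- length(ucodes)
  hits <- purrr::map_dfr(raw, function(h) {
    tibble(
      mirna_id = if (is.data.frame(mirna)) mirna$mirna_id else NA_character_,
      family = if (is.data.frame(mirna) && !is.null(mirna$family))
        mirna$family else NA_character_,
      species = if (is.data.frame(utr)) utr$species else NA_character_,
      gene_id = if (is.data.frame(utr)) utr$gene_id else NA_character_,
      transcript_id = if (is.data.frame(utr)) utr$transcript_id else NA_character_,
      site_start = h$site_start, site_end = h$site_end, dG = h$dG,
      seed_offset = NA_character_,
      pairs = list(tibble(
        utr_pos = h$utr_pos, mirna_pos = h$mirna_pos,
        pair_class = c("WC", "GU")[h$pair_class + 1L]
      )),
      utr_length = utr_len,
      dist_from_stop = h$site_start - 1L,
      dist_from_3end = utr_len - h$site_end
    )
  })
  arrange(hits, .data$dG, .data$site_start)
}

seed_window_positions <- list("1-7" = 1:7, "2-8" = 2:8, "3-9" = 3:9)

# first satisfied seed window label for one pair table, or NA.
# A window is satisfied when all seven miRNA positions are paired with seven
# consecutive UTR positions (a contiguous helix: no bulge on either side).
seed_offset_of <- function(pair_tbl) {
  for (lab in names(seed_window_positions)) {
    win <- seed_window_positions[[lab]]
    idx <- match(win, pair_tbl$mirna_pos)
    if (anyNA(idx)) next
    u <- pair_tbl$utr_pos[idx] # utr positions at miRNA pos 1..7 of window
    if (all(diff(u) == -1L)) return(lab) # contiguous, antiparallel
  }
  NA_character_
}

#' Seed-match constraint on duplex hits
#'
#' A hit satisfies the constraint when one of the three 7-nt seed windows
#' (miRNA positions 1-7, 2-8 or 3-9 from the 5' end) is fully paired with
#' consecutive UTR positions, with no bulge inside the window. G-U wobbles
#' count as paired here; they are penalised later as a binding feature. The
#' first satisfying label in the order 1-7, 2-8, 3-9 is recorded in the
#' `seed_offset` column.
#'
#' @param hits a duplex-hit tibble from [hybridize()].
#' @return `hits` with `seed_offset` filled in; hits with no satisfying
#'   window keep `NA`.
#' @export
seed_constraint <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  hits$seed_offset <- purrr::map_chr(hits$pairs, seed_offset_of)
  hits
}

#' Step 1: free-energy and seed-match screen over a corpus
#'
#' Runs [hybridize()] for every miRNA against every 3'-UTR of the same
#' species and keeps hits with duplex free energy strictly below `dG_max`
#' that satisfy the complete seed-match constraint. With
#' `per_gene = TRUE` (the default) only the lowest-energy hit per
#' (miRNA family, gene, species) is retained, so downstream counts are on
#' the gene scale.
#'
#' @param mirnas tibble of mature miRNAs (`mirna_id`, `species`, `sequence`,
#'   optionally `family`); each miRNA is scanned against UTRs of its own
#'   species.
#' @param utrs tibble of 3'-UTR records.
#' @param model an [energy_model()].
#' @param dG_max free-energy cutoff in kcal/mol; hits must have
#'   `dG < dG_max` (strict). Default -17.
#' @param per_gene collapse to the best hit per (family, gene, species)?
#'
#' @return A duplex-hit tibble (see [hybridize()]) with `seed_offset` set.
#' @export
screen_step1 <- function(mirnas, utrs, model = energy_model(),
                         dG_max = -17, per_gene = TRUE) {
  if (nrow(mirnas) == 0 || nrow(utrs) == 0) return(empty_hits())
  out <- vector("list", nrow(mirnas))
  for (k in seq_len(nrow(mirnas))) {
    mi <- mirnas[k, ]
    uk <- utrs[utrs$species == mi$species, , drop = FALSE]
    if (nrow(uk) == 0) next
    hk <- purrr::map_dfr(seq_len(nrow(uk)), function(j) {
      hybridize(mi, uk[j, ], model, dG_keep = dG_max)
    })
    out[[k]] <- hk
  }
  hits <- bind_rows(out)
  if (nrow(hits) == 0) return(empty_hits())
  hits <- seed_constraint(hits)
  hits <- filter(hits, .data$dG < dG_max, !is.na(.data$seed_offset))
  if (per_gene && nrow(hits) > 0) {
    key <- dplyr::coalesce(hits$family, hits$mirna_id)
    hits <- hits |>
      mutate(.fam_key = key) |>
      group_by(.data$.fam_key, .data$gene_id, .data$species) |>
      slice_min(.data$dG, n = 1, with_ties = FALSE) |>
      ungroup() |>
      select(-".fam_key")
  }
  arrange(hits, .data$species, .data$gene_id, .data$dG)
}

#' Encode / decode the pair list of a duplex hit
#'
#' Compact text form `"utrPos:mirnaPos:class,..."` used in TSV output.
#' @param pairs a tibble with `utr_pos`, `mirna_pos`, `pair_class`.
#' @return `encode_pairs()` a string; `decode_pairs()` the tibble.
#' @export
encode_pairs <- function(pairs) {
  paste(sprintf("%d:%d:%s", pairs$utr_pos, pairs$mirna_pos, pairs$pair_class),
        collapse = ",")
}

#' @rdname encode_pairs
#' @param x an encoded pair string.
#' @export
decode_pairs <- function(x) {
  parts <- strsplit(strsplit(x, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
  tibble(
    utr_pos = vapply(parts, function(p) as.integer(p[1]), integer(1)),
    mirna_pos = vapply(parts, function(p) as.integer(p[2]), integer(1)),
    pair_class = vapply(parts, function(p) p[3], character(1))
  )
}
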