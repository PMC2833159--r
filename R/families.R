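# Extraction of miRNA families conserved across all configured species:
# a shared 7-nt seed window plus high overall mature-sequence identity.

#' Seed windows of a mature miRNA
#'
#' The three 7-mers at 1-based positions 1-7, 2-8 and 3-9 from the miRNA
#' 5' end.
#'
#' @param sequence a mature miRNA sequence (length >= 9) or a one-row
#'   miRNA tibble.
#' @return A tibble with columns `offset_label`, `seed_seq`.
#' @export
#' @examples
#' seed_variants("UGAGGUAGUAGGUUGUAUAGUU")
seed_variants <- function(sequence) {
  if (is.list(sequence) || is.data.frame(sequence)) sequence <- sequence$sequence
  if (nchar(sequence) < 9) {
    abort("sequence must be at least 9 nt to carry all three seed windows")
  }
  tibble(
    offset_label = c("1-7", "2-8", "3-9"),
    seed_seq = substring(sequence, 1:3, 7:9)
  )
}

#' Global pairwise sequence identity
#'
#' Percent identity of two RNA sequences under a fixed global alignment with
#' affine gap costs (gap opening 22.5, gap extension 0.83; match 1,
#' mismatch 0). Identity is the number of identical aligned columns divided
#' by the alignment length (gap columns count as non-matching), times 100.
#'
#' @param a,b RNA strings.
#' @param gap_opening,gap_extension affine gap penalties.
#' @return Percent identity in `[0, 100]`.
#' @export
#' @examples
#' pairwise_identity("UGAGGUAGUAGGUU", "UGAGGUAGUAGGUU")
pairwise_identity <- function(a, b, gap_opening = 22.5, gap_extension = 0.83) {
  if (!nzchar(a) || !nzchar(b)) abort("sequences must be non-empty")
  sub <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "U"),
                                         c("A", "C", "G", "U")))
  diag(sub) <- 1
  al <- Biostrings::pairwiseAlignment(
    Biostrings::RNAString(a), Biostrings::RNAString(b), type = "global",
    substitutionMatrix = sub, gapOpening = gap_opening,
    gapExtension = gap_extension
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  100 * sum(pa == pb & pa != "-") / length(pa)
}

# min and mean pairwise identity over a character vector of sequences
identity_stats <- function(seqs, ...) {
  pairs <- utils::combn(length(seqs), 2)
  ids <- apply(pairs, 2, function(p)
    pairwise_identity(seqs[p[1]], seqs[p[2]], ...))
  c(min = min(ids), mean = mean(ids))
}

# family name from a member id: strip the species prefix and trailing
# lineage letters/arm labels, e.g. "hsa-let-7a" -> "let-7", "mmu-miR-125b-5p"
# -> "miR-125"
family_name_of <- function(mirna_id) {
  x <- sub("^[a-z]{3}-", "", mirna_id)
  x <- sub("-[35]p$", "", x)
  sub("^((let|miR|lin|bantam)[-]?[0-9]+).*$", "\\1", x)
}

#' Extract miRNA families conserved across all species
#'
#' A family is a choice of one mature miRNA per species such that (1) some
#' common seed window (1-7, 2-8 or 3-9) carries the identical 7-mer in every
#' member, and (2) the minimum pairwise global identity across members
#' exceeds `identity_threshold`. When a species offers several candidates
#' with the shared seed (paralogous family members), the combination
#' maximising the minimum cross-species identity is chosen, ties broken
#' lexicographically by miRNA id. An optional `family_whitelist` restricts
#' results to families on an externally curated high-conservation list.
#'
#' @param mirnas tibble of mature miRNAs covering at least two species.
#' @param identity_threshold minimum pairwise identity must be strictly
#'   greater than this (percent, default 75).
#' @param family_whitelist optional character vector of family names.
#' @param species optional species set; defaults to all species in `mirnas`.
#' @return A tibble with one row per family member: `family`, `species`,
#'   `mirna_id`, `sequence`, `seed_offset`, `seed_seq`, `identity_min_pct`,
#'   `identity_mean_pct`.
#' @export
extract_conserved_families <- function(mirnas, identity_threshold = 75,
                                       family_whitelist = NULL,
                                       species = NULL) {
  species <- species %||% unique(mirnas$species)
  if (length(species) < 2) abort("at least two species are required")
  missing_sp <- species[!species %in% mirnas$species]
  if (length(missing_sp) > 0) {
    abort(paste0("species with zero miRNAs: ",
                 paste(missing_sp, collapse = ", ")))
  }
  mirnas <- filter(mirnas, .data$species %in% !!species)

  # index: per (offset, seed 7-mer), the member candidates per species
  seeds <- mirnas |>
    mutate(.row = dplyr::row_number()) |>
    dplyr::rowwise() |>
    dplyr::reframe(seed_variants(.data$sequence),
                   mirna_id = .data$mirna_id, species = .data$species,
                   sequence = .data$sequence)
  shared <- seeds |>
    group_by(.data$offset_label, .data$seed_seq) |>
    filter(dplyr::n_distinct(.data$species) == length(!!species)) |>
    ungroup()
  if (nrow(shared) == 0) return(empty_families())

  keys <- distinct(shared, .data$offset_label, .data$seed_seq)
  # honour window preference order 1-7, 2-8, 3-9
  keys <- arrange(keys, match(.data$offset_label, c("1-7", "2-8", "3-9")))

  rows <- list()
  seen_members <- character()
  for (k in seq_len(nrow(keys))) {
    cand <- filter(shared, .data$offset_label == keys$offset_label[k],
                   .data$seed_seq == keys$seed_seq[k]) |>
      arrange(.data$mirna_id)
    by_sp <- split(cand, factor(cand$species, levels = species))
    combos <- purrr::map(by_sp, ~ seq_len(nrow(.x)))
    n_combo <- prod(lengths(combos))
    if (n_combo > 5000) {
      # too many paralog combinations: rank members within species by mean
      # identity to the other species' candidates and keep the top 3 each
      by_sp <- purrr::map(by_sp, function(tb) {
        if (nrow(tb) <= 3) return(tb)
        others <- cand$sequence[!cand$species %in% tb$species]
        sc <- vapply(tb$sequence, function(s)
          mean(vapply(others, function(o) pairwise_identity(s, o),
                      numeric(1))), numeric(1))
        tb[order(-sc, tb$mirna_id), ][1:3, ]
      })
      combos <- purrr::map(by_sp, ~ seq_len(nrow(.x)))
    }
    grid <- expand.grid(combos, KEEP.OUT.ATTRS = FALSE)
    best <- NULL
    for (g in seq_len(nrow(grid))) {
      members <- purrr::map2_dfr(by_sp, as.integer(grid[g, ]), ~ .x[.y, ])
      st <- identity_stats(members$sequence)
      if (is.null(best) || st["min"] > best$st["min"] + 1e-12) {
        best <- list(members = members, st = st)
      }
    }
    if (best$st["min"] <= identity_threshold) next
    key <- paste(sort(best$members$mirna_id), collapse = "|")
    if (key %in% seen_members) next # same member set via another window
    seen_members <- c(seen_members, key)
    fam <- family_name_of(best$members$mirna_id[1])
    if (!is.null(family_whitelist) && !fam %in% family_whitelist) next
    rows[[length(rows) + 1]] <- mutate(
      best$members[c("species", "mirna_id", "sequence")],
      family = fam,
      seed_offset = keys$offset_label[k], seed_seq = keys$seed_seq[k],
      identity_min_pct = unname(best$st["min"]),
      identity_mean_pct = unname(best$st["mean"])
    )
  }
  if (length(rows) == 0) return(empty_families())
  out <- bind_rows(rows)
  # one family per name: keep the variant with the highest min identity
  out <- out |>
    group_by(.data$family) |>
    filter(.data$identity_min_pct == max(.data$identity_min_pct)) |>
    filter(.data$seed_offset == .data$seed_offset[1]) |>
    ungroup()
  select(out, "family", "species", "mirna_id", "sequence", "seed_offset",
         "seed_seq", "identity_min_pct", "identity_mean_pct") |>
    arrange(.data$family, match(.data$species, !!species))
}

empty_families <- function() {
  tibble(family = character(), species = character(), mirna_id = character(),
         sequence = character(), seed_offset = character(),
         seed_seq = character(), identity_min_pct = numeric(),
         identity_mean_pct = numeric())
}
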