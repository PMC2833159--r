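# Step 3: cross-species conservation of (miRNA family, ortholog cluster)
# target pairs.

#' Extract conserved miRNA-family / ortholog-cluster target pairs
#'
#' Groups surviving hits by (family, ortholog cluster) and keeps groups with
#' target sites in at least `min_species` distinct species, one of which
#' must be the anchor species. Hits on genes absent from the ortholog map
#' are dropped (a count is reported via a message). A species contributes
#' once per cluster even if several paralogous member genes carry sites; the
#' best (lowest-dG) hit per species represents it.
#'
#' @param hits step-2 hit tibble (must carry `family`, `gene_id`, `species`,
#'   `dG`).
#' @param ortholog_map tibble with `gene_id`, `species`, `cluster_id`.
#' @param min_species minimum number of species with a site (default 4).
#' @param anchor_species species that must be among them (default
#'   `"H. sapiens"`).
#' @return A tibble with one row per conserved pair: `family`, `cluster_id`,
#'   `anchor_gene_id`, `n_species`, `species_with_site` (list-column) and
#'   `per_species_hits` (list-column of the best hit rows, one per species).
#' @export
conserved_pairs <- function(hits, ortholog_map, min_species = 4,
                            anchor_species = "H. sapiens") {
  if (!anchor_species %in% ortholog_map$species) {
    abort(paste0("anchor species '", anchor_species,
                 "' absent from the ortholog map"))
  }
  mapped <- inner_join(hits, ortholog_map,
                       by = c("gene_id", "species"))
  n_drop <- nrow(hits) - nrow(mapped)
  if (n_drop > 0) {
    message(n_drop, " hit(s) on genes not covered by the ortholog map were dropped")
  }
  if (nrow(mapped) == 0) return(empty_conserved_pairs())
  fam <- dplyr::coalesce(mapped$family, mapped$mirna_id)
  mapped$family <- fam
  best_per_species <- mapped |>
    group_by(.data$family, .data$cluster_id, .data$species) |>
    slice_min(.data$dG, n = 1, with_ties = FALSE) |>
    ungroup()
  out <- best_per_species |>
    group_by(.data$family, .data$cluster_id) |>
    summarise(
      n_species = dplyr::n_distinct(.data$species),
      species_with_site = list(sort(unique(.data$species))),
      anchor_gene_id = .data$gene_id[match(!!anchor_species, .data$species)],
      per_species_hits = list(dplyr::pick(dplyr::everything())),
      .groups = "drop"
    ) |>
    filter(.data$n_species >= min_species,
           purrr::map_lgl(.data$species_with_site,
                          ~ anchor_species %in% .x))
  out <- select(out, "family", "cluster_id", "anchor_gene_id", "n_species",
                "species_with_site", "per_species_hits")
  arrange(out, .data$family, .data$cluster_id)
}

empty_conserved_pairs <- function() {
  tibble(family = character(), cluster_id = character(),
         anchor_gene_id = character(), n_species = integer(),
         species_with_site = list(), per_species_hits = list())
}

#' Ortholog clusters targeted by multiple miRNA families
#'
#' @param pairs output of [conserved_pairs()].
#' @return A tibble with `cluster_id`, `families` (list-column),
#'   `n_families` and `multi` (flag for clusters with >= 2 families).
#' @export
multi_mirna_targets <- function(pairs) {
  out <- pairs |>
    group_by(.data$cluster_id) |>
    summarise(families = list(sort(unique(.data$family))), .groups = "drop") |>
    mutate(n_families = lengths(.data$families),
           multi = .data$n_families >= 2)
  arrange(out, dplyr::desc(.data$n_families), .data$cluster_id)
}
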