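# Enrichment / Coverage / EC accounting, the stage summary table, and the
# species-specific-miRNA negative control with a Welch t-test.

#' Enrichment of verified pairs across a filtering step
#'
#' Enrichment is the ratio of the verified-pair retention fraction to the
#' predicted-pair retention fraction: (100 * n_ver_kept / n_ver_total) /
#' (100 * n_pred_kept / n_pred_total). All fields are stored unrounded;
#' round only for display.
#'
#' @param n_ver_kept,n_ver_total verified pairs retained / in total.
#' @param n_pred_kept,n_pred_total predicted pairs retained / in total.
#' @param stage_label optional label for the row.
#' @return A one-row tibble of class `enrichment_result` with fields
#'   `stage_label`, the four counts, `ratio_pred_pct`, `ratio_ver_pct`,
#'   `enrichment`.
#' @export
#' @examples
#' enrichment(112, 145, 153387, 357430) # 1.8-fold after the step-1 screen
enrichment <- function(n_ver_kept, n_ver_total, n_pred_kept, n_pred_total,
                       stage_label = NA_character_) {
  stopifnot(n_ver_total > 0, n_pred_total > 0,
            n_ver_kept <= n_ver_total, n_pred_kept <= n_pred_total)
  ratio_ver <- 100 * n_ver_kept / n_ver_total
  ratio_pred <- 100 * n_pred_kept / n_pred_total
  if (ratio_pred == 0 && ratio_ver > 0) {
    warn("no predicted pairs kept: enrichment reported as Inf")
    enr <- Inf
  } else if (ratio_pred == 0) {
    enr <- NA_real_
  } else {
    enr <- ratio_ver / ratio_pred
  }
  out <- tibble(
    stage_label = stage_label,
    n_pred_kept = n_pred_kept, n_pred_total = n_pred_total,
    n_ver_kept = n_ver_kept, n_ver_total = n_ver_total,
    ratio_pred_pct = ratio_pred, ratio_ver_pct = ratio_ver,
    enrichment = enr
  )
  structure(out, class = c("enrichment_result", class(out)))
}

#' EC value: Enrichment times Coverage
#'
#' The grid-search objective: the unrounded enrichment multiplied by the
#' unrounded coverage percentage.
#'
#' @param enrichment_unrounded,coverage_pct_unrounded non-negative numerics.
#' @return Their product.
#' @export
#' @examples
#' ec_value(2.5, 40) # 100
ec_value <- function(enrichment_unrounded, coverage_pct_unrounded) {
  stopifnot(all(enrichment_unrounded >= 0), all(coverage_pct_unrounded >= 0))
  enrichment_unrounded * coverage_pct_unrounded
}

#' Welch's t-test on two count samples
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom.
#' Two-sided by default; the directional alternative is available since the
#' negative-control comparison is directional in nature.
#'
#' @param sample_a,sample_b numeric vectors, each of length >= 2.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (referring to `sample_a` relative to `sample_b`).
#' @return A one-row tibble with `t_stat`, `df`, `p_value`.
#' @export
welch_t <- function(sample_a, sample_b, alternative = "two.sided") {
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    abort("each sample must contain at least two observations")
  }
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0) {
    if (isTRUE(all.equal(mean(sample_a), mean(sample_b)))) {
      # degenerate but well-defined: identical constant samples
      return(tibble(t_stat = 0, df = NA_real_, p_value = 1))
    }
    abort("both samples have zero variance: t statistic undefined")
  }
  ht <- t.test(sample_a, sample_b, var.equal = FALSE,
               alternative = alternative)
  tibble(t_stat = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value)
}

#' Stage-by-stage extraction summary
#'
#' Builds the screening summary: one row per stage with retained counts of
#' predicted and verified pairs, their retention percentages, and the
#' enrichment index. Stage pair sets must be nested (each stage a subset of
#' the previous); this is asserted.
#'
#' @param stage_pairs named list of pair tibbles in screening order, each
#'   with columns `family`, `gene_id`, `species` (the first entry is the
#'   all-pairs baseline).
#' @param verified verified-pair tibble (`mirna_family`, `gene_id`,
#'   `species`).
#' @return A tibble with one `enrichment`-style row per stage.
#' @export
evaluate_stages <- function(stage_pairs, verified) {
  stopifnot(length(stage_pairs) >= 1)
  key <- function(p) {
    fam <- if ("family" %in% names(p)) p$family else p$mirna_family
    paste(fam, p$gene_id, p$species, sep = "\r")
  }
  vkey <- paste(verified$mirna_family, verified$gene_id, verified$species,
                sep = "\r")
  keys <- purrr::map(stage_pairs, key)
  for (i in seq_along(keys)[-1]) {
    if (!all(keys[[i]] %in% keys[[i - 1]])) {
      abort(paste0("stage '", names(stage_pairs)[i],
                   "' is not nested in the previous stage"))
    }
  }
  n_pred_total <- length(unique(keys[[1]]))
  n_ver_total <- length(unique(intersect(vkey, keys[[1]])))
  purrr::imap_dfr(keys, function(k, lab) {
    enrichment(
      n_ver_kept = length(unique(intersect(vkey, k))),
      n_ver_total = n_ver_total,
      n_pred_kept = length(unique(k)),
      n_pred_total = n_pred_total,
      stage_label = lab
    )
  })
}

#' Identify species-specific miRNAs
#'
#' A miRNA is species-specific when family extraction assigns it no
#' conserved family at the configured thresholds. Samples `n_per_species`
#' of them per species with an explicit seed.
#'
#' @param mirnas mature miRNA tibble.
#' @param families output of [extract_conserved_families()] (members listed
#'   there are excluded).
#' @param n_per_species how many to sample per species (default 5).
#' @param seed RNG seed for the sampling.
#' @return A miRNA tibble of the sampled species-specific miRNAs.
#' @export
species_specific_mirnas <- function(mirnas, families, n_per_species = 5,
                                    seed = 1L) {
  pool <- filter(mirnas, !.data$mirna_id %in% families$mirna_id)
  short <- pool |>
    dplyr::count(.data$species) |>
    filter(.data$n < n_per_species)
  missing_sp <- setdiff(unique(mirnas$species), pool$species)
  if (nrow(short) > 0 || length(missing_sp) > 0) {
    abort(paste0("fewer than ", n_per_species,
                 " species-specific miRNA candidates in: ",
                 paste(c(short$species, missing_sp), collapse = ", ")))
  }
  withr::with_seed(seed, {
    pool |>
      group_by(.data$species) |>
      dplyr::slice_sample(n = n_per_species) |>
      ungroup() |>
      arrange(.data$species, .data$mirna_id)
  })
}

#' Species-specific-miRNA negative control
#'
#' Runs the full screen (steps 1-3) for each control miRNA under the
#' counterfactual that it is conserved: the same mature sequence is scanned
#' in every species. Per-miRNA conserved-pair counts are compared with the
#' per-family counts of the real conserved families by Welch's t-test.
#'
#' @param control_mirnas tibble of species-specific miRNAs (e.g. from
#'   [species_specific_mirnas()]).
#' @param utrs 3'-UTR tibble covering all species.
#' @param ortholog_map ortholog map tibble.
#' @param conserved_counts integer vector of conserved-pair counts per real
#'   family (the comparison sample).
#' @param model,dG_max,params,min_species,anchor_species screen settings as
#'   elsewhere.
#' @param alternative sidedness of the Welch test (default two-sided).
#' @return A list of class `control_result`: `per_mirna` (tibble of control
#'   counts), `mean_control`, `mean_conserved`, `n_zero_control`, `t_stat`,
#'   `p_value`.
#' @export
control_experiment <- function(control_mirnas, utrs, ortholog_map,
                               conserved_counts, model = energy_model(),
                               dG_max = -17, params = filter_params(),
                               min_species = 4,
                               anchor_species = "H. sapiens",
                               alternative = "two.sided") {
  species <- unique(utrs$species)
  counts <- purrr::map_int(seq_len(nrow(control_mirnas)), function(k) {
    mi <- control_mirnas[k, ]
    # counterfactual conservation: the same sequence in every species
    fam <- paste0("control:", mi$mirna_id)
    pseudo <- tibble(mirna_id = paste0(mi$mirna_id, "@", species),
                     species = species, sequence = mi$sequence,
                     family = fam)
    h1 <- screen_step1(pseudo, utrs, model, dG_max = dG_max)
    h2 <- filter_hits(h1, params, mirnas = pseudo)
    cp <- suppressMessages(
      conserved_pairs(h2, ortholog_map, min_species, anchor_species))
    nrow(cp)
  })
  wt <- welch_t(counts, conserved_counts, alternative = alternative)
  structure(list(
    per_mirna = tibble(mirna_id = control_mirnas$mirna_id,
                       species = control_mirnas$species,
                       n_conserved_pairs = counts),
    per_mirna_counts_control = counts,
    per_mirna_counts_conserved = conserved_counts,
    mean_control = mean(counts),
    mean_conserved = mean(conserved_counts),
    n_zero_control = sum(counts == 0),
    t_stat = wt$t_stat, p_value = wt$p_value
  ), class = "control_result")
}

#' @export
print.control_result <- function(x, ...) {
  cat("<control_result: ", length(x$per_mirna_counts_control),
      " species-specific control miRNAs>\n", sep = "")
  cat(sprintf("  mean conserved pairs: control %.2f vs conserved %.2f\n",
              x$mean_control, x$mean_conserved))
  cat(sprintf("  controls with zero pairs: %d\n", x$n_zero_control))
  cat(sprintf("  Welch t = %.3f, p = %.4g\n", x$t_stat, x$p_value))
  invisible(x)
}
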