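# End-to-end orchestration: families -> step 1 -> step 2 -> step 3 ->
# evaluation, with a reproducible configuration object.

#' Pipeline configuration
#'
#' Bundles every tunable of the screen with the published defaults:
#' identity threshold 75%, free-energy cutoff -17 kcal/mol, binding-feature
#' thresholds (12, 10, 4, 0), grid shape (5, 5, 5, 4), conservation in at
#' least 4 species anchored on *H. sapiens*.
#'
#' @param species species set (default the five bilaterians).
#' @param anchor_species species required in every conserved pair.
#' @param identity_threshold family identity threshold (percent).
#' @param dG_max duplex free-energy cutoff (kcal/mol, strict `<`).
#' @param params [filter_params()] used when `optimize = FALSE`.
#' @param grid_shape candidate-range sizes per feature for the optimizer.
#' @param min_species conservation depth required in step 3.
#' @param optimize re-derive the binding thresholds by grid search against
#'   the corpus' verified pairs instead of using `params`?
#' @param family_whitelist optional externally curated family whitelist.
#' @param seed RNG seed recorded in the manifest.
#' @param model an [energy_model()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(species = bilaterian_species()$species,
                            anchor_species = "H. sapiens",
                            identity_threshold = 75,
                            dG_max = -17,
                            params = filter_params(),
                            grid_shape = c(mm_mrna = 5, mm_mirna = 5,
                                           gu_whole = 5, gu_seed = 4),
                            min_species = 4,
                            optimize = FALSE,
                            family_whitelist = NULL,
                            seed = 1L,
                            model = energy_model()) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Write / read a pipeline configuration
#'
#' YAML round-trip of every scalar field (the energy model is recorded by
#' its version tag and re-created with defaults on read).
#' @param config a [pipeline_config()].
#' @param path YAML file.
#' @return `read_pipeline_config()` a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  rlang::check_installed("yaml")
  x <- config[c("species", "anchor_species", "identity_threshold", "dG_max",
                "min_species", "optimize", "seed")]
  x$params <- as.list(unclass(config$params))
  x$grid_shape <- as.list(config$grid_shape)
  x$family_whitelist <- config$family_whitelist
  x$energy_model <- config$model$version_tag
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  rlang::check_installed("yaml")
  x <- yaml::read_yaml(path)
  pipeline_config(
    species = unlist(x$species),
    anchor_species = x$anchor_species,
    identity_threshold = x$identity_threshold,
    dG_max = x$dG_max,
    params = do.call(filter_params, unname(as.list(unlist(x$params)))),
    grid_shape = unlist(x$grid_shape),
    min_species = x$min_species,
    optimize = isTRUE(x$optimize),
    family_whitelist = if (length(x$family_whitelist)) unlist(x$family_whitelist),
    seed = x$seed
  )
}

# all-pairs universe: every conserved family against every gene with a UTR,
# per species in which the family has a member
all_possible_pairs <- function(families, utrs) {
  fam_sp <- distinct(families, .data$family, .data$species)
  genes <- distinct(utrs, .data$gene_id, .data$species)
  inner_join(fam_sp, genes, by = "species", relationship = "many-to-many")
}

#' Run the full conserved-target screen
#'
#' Orchestrates family extraction, the free-energy/seed screen (step 1), the
#' binding-feature filter (step 2, optionally with thresholds re-derived by
#' the Enrichment x Coverage grid search), the ortholog-conservation filter
#' (step 3), and the stage-by-stage evaluation against verified pairs.
#'
#' @param corpus a list with tibbles `mirnas`, `utrs`, `orthologs` and
#'   optionally `verified` (as produced by [generate_corpus()] or the
#'   readers in this package).
#' @param config a [pipeline_config()].
#' @param outdir optional directory for TSV stage tables and the manifest.
#' @return A list of class `bilatmir_run` with elements `families`,
#'   `hits_step1`, `hits_step2`, `conserved`, `params_used`, `grid`
#'   (when optimized), `evaluation`, `config` and `manifest`.
#' @export
run_pipeline <- function(corpus, config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  species <- intersect(config$species, unique(corpus$mirnas$species))
  families <- extract_conserved_families(
    corpus$mirnas, config$identity_threshold,
    family_whitelist = config$family_whitelist, species = species)
  if (nrow(families) == 0) abort("no conserved miRNA families in the corpus")
  members <- select(families, "mirna_id", "species", "sequence", "family")

  hits1 <- screen_step1(members, corpus$utrs, config$model,
                        dG_max = config$dG_max)
  hits1 <- compute_features(hits1, members)

  verified <- corpus$verified %||%
    tibble(mirna_family = character(), gene_id = character(),
           species = character())
  hits1$verified <- paste(hits1$family, hits1$gene_id, hits1$species) %in%
    paste(verified$mirna_family, verified$gene_id, verified$species)

  grid <- NULL
  params_used <- config$params
  if (isTRUE(config$optimize)) {
    curves <- purrr::map(feature_names(), ~ coverage_curve(hits1, .x))
    ranges <- select_ranges(curves, config$grid_shape)
    grid <- grid_search(hits1, ranges)
    params_used <- best_params(grid)
  }
  hits2 <- hits1[apply_filter(hits1, params_used), , drop = FALSE]

  conserved <- suppressMessages(conserved_pairs(
    hits2, corpus$orthologs, min_species = config$min_species,
    anchor_species = config$anchor_species))

  all_pairs <- all_possible_pairs(families, corpus$utrs)
  stage_pairs <- list(
    all_pairs = all_pairs,
    step1 = distinct(hits1, .data$family, .data$gene_id, .data$species),
    step2 = distinct(hits2, .data$family, .data$gene_id, .data$species)
  )
  evaluation <- evaluate_stages(stage_pairs, verified)
  # step 3 operates on the ortholog-mapped, anchor-species universe: report
  # it against that restricted baseline
  anchor <- config$anchor_species
  mapped2 <- inner_join(stage_pairs$step2,
                        corpus$orthologs, by = c("gene_id", "species"))
  base3 <- filter(mapped2, .data$species == anchor)
  kept3 <- tibble(family = conserved$family,
                  gene_id = conserved$anchor_gene_id,
                  species = anchor)
  ver3 <- dplyr::semi_join(
    base3, verified,
    by = c(family = "mirna_family", "gene_id", "species"))
  kept_ver3 <- dplyr::semi_join(
    kept3, verified, by = c(family = "mirna_family", "gene_id", "species"))
  evaluation <- bind_rows(
    evaluation,
    if (nrow(base3) > 0)
      enrichment(nrow(kept_ver3), max(1L, nrow(ver3)),
                 nrow(kept3), nrow(base3), stage_label = "step3")
  )

  manifest <- list(
    package_version = as.character(utils::packageVersion("bilatmir")),
    species = species, seed = config$seed,
    dG_max = config$dG_max, identity_threshold = config$identity_threshold,
    min_species = config$min_species,
    params_used = as.integer(params_used),
    energy_model = config$model$version_tag,
    n_families = dplyr::n_distinct(families$family),
    n_pairs_all = nrow(all_pairs), n_pairs_step1 = nrow(stage_pairs$step1),
    n_pairs_step2 = nrow(stage_pairs$step2), n_pairs_step3 = nrow(conserved)
  )
  run <- structure(list(
    families = families, hits_step1 = hits1, hits_step2 = hits2,
    conserved = conserved, params_used = params_used, grid = grid,
    evaluation = evaluation, config = config, manifest = manifest
  ), class = "bilatmir_run")
  if (!is.null(outdir)) write_run(run, outdir)
  run
}

flatten_conserved <- function(conserved) {
  if (nrow(conserved) == 0) {
    return(tibble(family = character(), cluster_id = character(),
                  anchor_gene_id = character(), n_species = integer(),
                  species_list = character(), sites = character()))
  }
  mutate(conserved,
         species_list = purrr::map_chr(.data$species_with_site,
                                       paste, collapse = ","),
         sites = purrr::map_chr(.data$per_species_hits, function(h)
           paste(sprintf("%s:%s:%d-%d:%.2f", h$species, h$gene_id,
                         h$site_start, h$site_end, h$dG), collapse = ";"))) |>
    select("family", "cluster_id", "anchor_gene_id", "n_species",
           "species_list", "sites")
}

write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  prm <- list(dG_max = run$config$dG_max,
              params = as.integer(run$params_used),
              min_species = run$config$min_species)
  write_result_tsv(run$families, file.path(outdir, "families.tsv"), prm)
  write_result_tsv(select(run$hits_step1, -dplyr::any_of("verified")),
                   file.path(outdir, "hits_step1.tsv"), prm)
  write_result_tsv(select(run$hits_step2, -dplyr::any_of("verified")),
                   file.path(outdir, "hits_step2.tsv"), prm)
  write_result_tsv(flatten_conserved(run$conserved),
                   file.path(outdir, "conserved_pairs.tsv"), prm)
  write_result_tsv(run$evaluation, file.path(outdir, "evaluation.tsv"), prm)
  if (requireNamespace("yaml", quietly = TRUE)) {
    yaml::write_yaml(run$manifest, file.path(outdir, "manifest.yaml"))
  }
  invisible(outdir)
}

#' @export
print.bilatmir_run <- function(x, ...) {
  m <- x$manifest
  cat("<bilatmir_run>\n")
  cat("  families: ", m$n_families, "; species: ",
      paste(m$species, collapse = ", "), "\n", sep = "")
  cat(sprintf("  pairs: all %d -> step1 %d -> step2 %d -> step3 %d\n",
              m$n_pairs_all, m$n_pairs_step1, m$n_pairs_step2,
              m$n_pairs_step3))
  cat("  thresholds: dG < ", m$dG_max, " kcal/mol; features <= (",
      paste(m$params_used, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Tidy a pipeline run into its conserved-pair table
#'
#' @param x a `bilatmir_run`.
#' @param ... unused.
#' @return A tibble with one row per conserved (family, ortholog cluster)
#'   pair, species list flattened to a string.
#' @export
tidy.bilatmir_run <- function(x, ...) {
  flatten_conserved(x$conserved)
}

#' One-row summary of a pipeline run
#'
#' @inheritParams tidy.bilatmir_run
#' @return A one-row tibble with stage counts and the final enrichment.
#' @export
glance.bilatmir_run <- function(x, ...) {
  m <- x$manifest
  ev <- x$evaluation
  tibble(
    n_families = m$n_families,
    n_pairs_all = m$n_pairs_all, n_pairs_step1 = m$n_pairs_step1,
    n_pairs_step2 = m$n_pairs_step2, n_pairs_step3 = m$n_pairs_step3,
    enrichment_step1 = ev$enrichment[ev$stage_label == "step1"],
    enrichment_step2 = ev$enrichment[ev$stage_label == "step2"],
    enrichment_step3 = if ("step3" %in% ev$stage_label)
      ev$enrichment[ev$stage_label == "step3"] else NA_real_
  )
}
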