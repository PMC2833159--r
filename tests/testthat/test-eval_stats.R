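test_that("enrichment reproduces the published stage arithmetic", {
  s1 <- enrichment(112, 145, 153387, 357430)
  expect_equal(round(s1$enrichment, 1), 1.8)
  expect_equal(round(s1$ratio_pred_pct, 1), 42.9)
  expect_equal(round(s1$ratio_ver_pct, 1), 77.2)
  s2 <- enrichment(76, 145, 28201, 357430)
  expect_equal(round(s2$enrichment, 1), 6.6)
  expect_equal(round(s2$ratio_pred_pct, 1), 7.9)
  expect_equal(round(s2$ratio_ver_pct, 1), 52.4)
  s3 <- enrichment(4, 52, 31, 10356)
  expect_equal(round(s3$enrichment, 1), 25.7)
  expect_equal(round(s3$ratio_pred_pct, 1), 0.3)
  expect_equal(round(s3$ratio_ver_pct, 1), 7.7)
})

test_that("keeping everything gives enrichment exactly 1", {
  for (nm in list(c(145, 357430), c(10, 10), c(3, 1000))) {
    expect_equal(enrichment(nm[1], nm[1], nm[2], nm[2])$enrichment, 1.0)
  }
})

test_that("degenerate enrichment inputs are handled explicitly", {
  expect_warning(e <- enrichment(5, 10, 0, 100), "Inf")
  expect_equal(e$enrichment, Inf)
  expect_error(enrichment(11, 10, 5, 100))
})

test_that("EC is the plain product of unrounded enrichment and coverage", {
  expect_equal(ec_value(1, 100), 100)
  expect_equal(ec_value(0, 57.3), 0)
  expect_equal(ec_value(2.5, 40), 100)
  # unrounded product: consistent with an enrichment_result's own fields
  e <- enrichment(76, 145, 28201, 357430)
  expect_equal(ec_value(e$enrichment, e$ratio_ver_pct),
               e$enrichment * e$ratio_ver_pct, tolerance = 1e-9)
})

test_that("Welch's test matches the defining formulas", {
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  w <- welch_t(a, b)
  o <- oracle_welch(a, b)
  expect_equal(w$t_stat, o$t, tolerance = 1e-12)
  expect_equal(w$df, o$df, tolerance = 1e-12)
  expect_equal(w$p_value, o$p, tolerance = 1e-12)
  set.seed(31)
  a2 <- rpois(8, 5); b2 <- rpois(12, 3) + 0.5
  w2 <- welch_t(a2, b2)
  o2 <- oracle_welch(a2, b2)
  expect_equal(w2$t_stat, o2$t, tolerance = 1e-12)
  expect_equal(w2$p_value, o2$p, tolerance = 1e-12)
})

test_that("Welch edge cases behave as documented", {
  expect_equal(welch_t(c(2, 2, 2), c(2, 2, 2))$p_value, 1)
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$t_stat, 0)
  expect_error(welch_t(c(1), c(1, 2)), "at least two")
  expect_error(welch_t(c(2, 2), c(3, 3)), "zero variance")
  # directional alternative
  wl <- welch_t(c(1, 2, 3), c(5, 6, 7), alternative = "less")
  expect_lt(wl$p_value, 0.05)
})

test_that("Welch type-I error sits near the nominal level under the null", {
  set.seed(123)
  n_rej <- 0
  for (r in 1:1000) {
    a <- rnorm(10); b <- rnorm(10)
    if (welch_t(a, b)$p_value < 0.05) n_rej <- n_rej + 1
  }
  expect_gte(n_rej / 1000, 0.03)
  expect_lte(n_rej / 1000, 0.07)
})

test_that("stage tables must nest and are summarised per stage", {
  all <- tidyr::expand_grid(family = c("f1", "f2"),
                            gene_id = paste0("g", 1:5),
                            species = "H. sapiens")
  s1 <- all[c(1:4, 6:7), ]
  s2 <- s1[1:3, ]
  ver <- tibble::tibble(mirna_family = c("f1", "f1", "f2"),
                        gene_id = c("g1", "g4", "g1"),
                        species = "H. sapiens")
  ev <- evaluate_stages(list(all = all, step1 = s1, step2 = s2), ver)
  expect_equal(ev$stage_label, c("all", "step1", "step2"))
  expect_equal(ev$enrichment[1], 1.0)
  expect_equal(ev$n_pred_kept, c(10L, 6L, 3L))
  expect_equal(ev$n_ver_kept[1], 3L)
  # non-nested stages are rejected
  bad <- tibble::tibble(family = "f9", gene_id = "g9", species = "H. sapiens")
  expect_error(evaluate_stages(list(all = all, step1 = bad), ver),
               "not nested")
})

test_that("the per-family average reproduces the published mean target count", {
  counts <- c(8, 7, 11, 3, 2) # let-7, miR-1, miR-124, miR-125/lin-4, miR-34
  expect_equal(mean(counts), 6.2)
})

test_that("species-specific sampling excludes family members and is seeded", {
  spec <- fixture_spec(seed = 2, n_conserved_families = 2,
                       n_decoy_mirnas_per_species = 7,
                       n_planted_conserved_sites = 2,
                       n_planted_partial_sites = 0,
                       n_planted_private_sites = 0, n_verified_pairs = 1)
  corpus <- generate_corpus(spec)
  fams <- extract_conserved_families(corpus$mirnas)
  ss1 <- species_specific_mirnas(corpus$mirnas, fams, 5, seed = 4)
  ss2 <- species_specific_mirnas(corpus$mirnas, fams, 5, seed = 4)
  expect_identical(ss1, ss2)
  expect_equal(nrow(ss1), 25)
  expect_false(any(ss1$mirna_id %in% fams$mirna_id))
  expect_error(species_specific_mirnas(corpus$mirnas, fams, 8), "fewer than")
})

test_that("the species-specific control yields fewer conserved pairs than
           real families on planted corpora", {
  spec <- fixture_spec(seed = 77, n_clusters = 15, n_genes_per_species = 20,
                       n_conserved_families = 3,
                       n_planted_conserved_sites = 9,
                       n_planted_partial_sites = 0,
                       n_planted_private_sites = 0,
                       n_decoy_mirnas_per_species = 5,
                       n_verified_pairs = 4,
                       utr_length_range = c(100L, 150L))
  corpus <- generate_corpus(spec)
  fams <- extract_conserved_families(corpus$mirnas)
  members <- dplyr::select(fams, "mirna_id", "species", "sequence", "family")
  h2 <- filter_hits(screen_step1(members, corpus$utrs, dG_max = -17),
                    mirnas = members)
  cp <- suppressMessages(conserved_pairs(h2, corpus$orthologs))
  conserved_counts <- as.integer(table(factor(cp$family,
                                              unique(fams$family))))
  controls <- species_specific_mirnas(corpus$mirnas, fams, 3, seed = 7)
  res <- control_experiment(controls, corpus$utrs, corpus$orthologs,
                            conserved_counts)
  expect_equal(length(res$per_mirna_counts_control), 15)
  expect_lt(res$mean_control, res$mean_conserved)
  expect_gte(res$n_zero_control, 10) # shuffled decoys mostly find nothing
  expect_equal(res$mean_control, mean(res$per_mirna_counts_control))
})
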