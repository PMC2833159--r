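test_that("corpus generation is byte-identical under a fixed seed", {
  spec <- fixture_spec(seed = 101, n_clusters = 6, n_genes_per_species = 8,
                       n_conserved_families = 2,
                       n_planted_conserved_sites = 3,
                       n_planted_partial_sites = 1,
                       n_planted_private_sites = 1, n_verified_pairs = 2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_corpus(spec, dir = d1)
  generate_corpus(spec, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # a different seed changes the corpus
  d3 <- withr::local_tempdir()
  generate_corpus(fixture_spec(seed = 102, n_clusters = 6,
                               n_genes_per_species = 8,
                               n_conserved_families = 2,
                               n_planted_conserved_sites = 3,
                               n_planted_partial_sites = 1,
                               n_planted_private_sites = 1,
                               n_verified_pairs = 2), dir = d3)
  expect_false(identical(readLines(file.path(d1, "mirnas.fa")),
                         readLines(file.path(d3, "mirnas.fa"))))
})

test_that("planted sites are exact reverse complements at mutation rate 0", {
  spec <- fixture_spec(seed = 55, n_clusters = 8, n_genes_per_species = 10,
                       n_conserved_families = 2,
                       n_planted_conserved_sites = 4,
                       n_planted_partial_sites = 0,
                       n_planted_private_sites = 0, n_verified_pairs = 2)
  corpus <- generate_corpus(spec)
  for (r in seq_len(nrow(corpus$truth))) {
    tr <- corpus$truth[r, ]
    u <- corpus$utrs[corpus$utrs$transcript_id == tr$transcript_id, ]
    site <- substr(u$sequence, tr$site_start, tr$site_end)
    member <- corpus$mirnas[which(corpus$mirnas$family == tr$family &
                                    corpus$mirnas$species == tr$species), ]
    expect_equal(site, rc_rna(member$sequence))
  }
  # conserved sites appear in >= 4 species including the anchor
  depth <- dplyr::count(corpus$truth, .data$family, .data$cluster_id)
  expect_true(all(depth$n >= 4))
  anchors <- dplyr::summarise(
    dplyr::group_by(corpus$truth, .data$family, .data$cluster_id),
    has_anchor = "H. sapiens" %in% species)
  expect_true(all(anchors$has_anchor))
})

test_that("engineered wobbles keep the site one G-U off a perfect duplex", {
  spec <- fixture_spec(seed = 66, n_clusters = 4, n_genes_per_species = 5,
                       n_conserved_families = 1,
                       n_planted_conserved_sites = 1,
                       n_planted_partial_sites = 0,
                       n_planted_private_sites = 0, n_verified_pairs = 1,
                       site_gu_count = 2)
  corpus <- generate_corpus(spec)
  tr <- corpus$truth[1, ]
  u <- corpus$utrs[corpus$utrs$transcript_id == tr$transcript_id, ]
  member <- corpus$mirnas[which(corpus$mirnas$family == tr$family &
                                  corpus$mirnas$species == tr$species), ]
  h <- seed_constraint(hybridize(member, u, energy_model(), max_sites = 1))
  h$mirna_length <- nchar(member$sequence)
  f <- compute_features(h)
  expect_equal(f$gu_whole, 2L)
  expect_equal(f$gu_seed, 0L) # wobbles are placed outside the seed window
})

test_that("a zero-family spec produces no conserved families", {
  spec <- fixture_spec(seed = 5, n_conserved_families = 0,
                       n_planted_conserved_sites = 0,
                       n_planted_partial_sites = 0,
                       n_planted_private_sites = 0, n_verified_pairs = 0)
  corpus <- generate_corpus(spec)
  expect_equal(nrow(extract_conserved_families(corpus$mirnas)), 0)
})

test_that("planted-feature corpora respect their cut and reject infeasible requests", {
  feats <- plant_features(n_verified = 200, n_decoys = 100,
                          cut = c(mm_mrna = 3, mm_mirna = 2, gu_whole = 2,
                                  gu_seed = 1), seed = 12)
  v <- feats[feats$verified, ]
  expect_true(all(v$mm_mrna <= 3 & v$mm_mirna <= 2 &
                    v$gu_whole <= 2 & v$gu_seed <= 1))
  expect_true(all(feats$gu_seed <= feats$gu_whole))
  expect_identical(attr(feats, "truth_cut"),
                   c(mm_mrna = 3L, mm_mirna = 2L, gu_whole = 2L, gu_seed = 1L))
  expect_error(plant_features(cut = c(mm_mrna = 30, mm_mirna = 1,
                                      gu_whole = 1, gu_seed = 0)),
               "outside the scanned range")
  expect_error(plant_features(cut = c(mm_mrna = 2, mm_mirna = 1,
                                      gu_whole = 1, gu_seed = 1),
                              wc_only = TRUE),
               "infeasible")
  # all-zero features give full coverage at every candidate grid point
  z <- plant_features(n_verified = 20, n_decoys = 20,
                      cut = c(mm_mrna = 0, mm_mirna = 0, gu_whole = 0,
                              gu_seed = 0), seed = 3)
  z[!z$verified, c("mm_mrna", "mm_mirna", "gu_whole", "gu_seed")] <- 0L
  gs <- grid_search(z, list(mm_mrna = 0:1, mm_mirna = 0:1, gu_whole = 0,
                            gu_seed = 0))
  expect_true(all(gs$grid$coverage_pct == 100))
})

test_that("pipeline recall decays with site mutation rate", {
  recall_at <- function(rate, seed) {
    spec <- fixture_spec(seed = seed, n_clusters = 6, n_genes_per_species = 6,
                         n_conserved_families = 2,
                         n_planted_conserved_sites = 4,
                         n_planted_partial_sites = 0,
                         n_planted_private_sites = 0, n_verified_pairs = 2,
                         site_mutation_rate = rate,
                         utr_length_range = c(80L, 120L))
    corpus <- generate_corpus(spec)
    members <- corpus$mirnas[!is.na(corpus$mirnas$family), ]
    h2 <- filter_hits(screen_step1(members, corpus$utrs, dG_max = -17),
                      mirnas = members)
    cp <- suppressMessages(conserved_pairs(h2, corpus$orthologs))
    truth <- unique(paste(corpus$truth$family, corpus$truth$cluster_id))
    mean(truth %in% paste(cp$family, cp$cluster_id))
  }
  seeds <- 1:6
  r0 <- mean(vapply(seeds, function(s) recall_at(0, s), numeric(1)))
  r40 <- mean(vapply(seeds, function(s) recall_at(0.4, s), numeric(1)))
  expect_equal(r0, 1)          # perfect sites always recovered
  expect_lt(r40, r0)           # heavy mutation destroys recovery
})
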