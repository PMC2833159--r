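test_that("a perfect complement decomposes into initiation plus stacks", {
  m <- energy_model()
  mir <- "UGAGGUAGG"
  utr <- paste0("AA", rc_rna(mir), "CC")
  h <- hybridize(mir, utr, m, max_sites = 1)
  expect_equal(nrow(h), 1)
  p <- h$pairs[[1]]
  expect_equal(nrow(p), nchar(mir))
  expect_true(all(p$pair_class == "WC"))
  # hand energy: init + stacks read along the UTR strand
  uv <- strsplit(utr, "")[[1]]
  mv <- strsplit(mir, "")[[1]]
  codes <- paste0(uv[p$utr_pos], mv[p$mirna_pos])
  stacks <- sum(m$stack_dG[cbind(codes[-length(codes)], codes[-1])])
  expect_equal(h$dG, m$init_dG + stacks, tolerance = 1e-9)
})

test_that("DP minimum equals the exhaustive enumeration oracle", {
  # spot check here; the full 200-instance sweep runs in the acceptance suite
  set.seed(2024)
  mdl <- tiny_model()
  for (k in 1:60) {
    mir <- random_rna_str(sample(7:10, 1))
    utr <- random_rna_str(sample(10:16, 1))
    o <- oracle_min_dG(mir, utr, mdl)
    h <- hybridize(mir, utr, mdl, dG_keep = 1e9, max_sites = 1)
    d <- if (nrow(h) == 0) Inf else h$dG[1]
    expect_equal(d, o, tolerance = 1e-9, info = paste(mir, utr))
  }
})

test_that("duplex structure invariants hold on random hits", {
  set.seed(7)
  mdl <- energy_model()
  for (k in 1:20) {
    mir <- random_rna_str(22)
    utr <- random_rna_str(80)
    h <- hybridize(mir, utr, mdl, dG_keep = 1e9)
    for (p in h$pairs) {
      expect_true(all(diff(p$utr_pos) > 0))    # strictly increasing on UTR
      expect_true(all(diff(p$mirna_pos) < 0))  # strictly decreasing on miRNA
    }
    if (nrow(h) > 1) {
      # greedy suboptimal sites never overlap
      iv <- h[order(h$site_start), ]
      expect_true(all(iv$site_start[-1] > iv$site_end[-nrow(iv)]))
    }
  }
})

test_that("dG is invariant under non-pairing flank padding", {
  mdl <- energy_model()
  mir <- "UGAGGUAGUAGGUUGUAUAGUU"
  core <- rc_rna(mir)
  # poly-C flanks cannot pair with anything already paired nor extend stacks
  h1 <- hybridize(mir, paste0("CCCC", core, "CCCC"), mdl, max_sites = 1)
  h2 <- hybridize(mir, paste0("CCCCCCCCCC", core, "CCCCCCCCCC"), mdl,
                  max_sites = 1)
  expect_equal(h1$dG, h2$dG, tolerance = 1e-9)
})

test_that("seed constraint requires a fully paired contiguous window", {
  full <- tibble::tibble(utr_pos = 22:1, mirna_pos = 1:22,
                         pair_class = "WC")
  h <- tibble::tibble(seed_offset = NA_character_, pairs = list(full))
  expect_equal(seed_constraint(h)$seed_offset, "1-7")
  # removing miRNA position 4 breaks all three windows
  h4 <- tibble::tibble(seed_offset = NA_character_,
                       pairs = list(full[full$mirna_pos != 4, ]))
  expect_true(is.na(seed_constraint(h4)$seed_offset))
  # removing position 1 leaves windows 2-8 and 3-9; first match wins
  h1 <- tibble::tibble(seed_offset = NA_character_,
                       pairs = list(full[full$mirna_pos != 1, ]))
  expect_equal(seed_constraint(h1)$seed_offset, "2-8")
  # a bulge inside the window (UTR positions not consecutive) fails it
  bulged <- full
  bulged$utr_pos[bulged$mirna_pos <= 4] <- bulged$utr_pos[bulged$mirna_pos <= 4] + 1
  hb <- tibble::tibble(seed_offset = NA_character_, pairs = list(bulged))
  expect_true(is.na(seed_constraint(hb)$seed_offset))
})

test_that("G-U wobbles count as paired inside the seed window", {
  mdl <- energy_model()
  mir <- "UGAGGUAGUAGGUUGUAUAGUU"
  site <- rc_rna(mir)
  # miRNA position 4 is G; pairing UTR C -> U creates a seed G-U wobble
  sv <- strsplit(site, "")[[1]]
  sp <- nchar(mir) - 4 + 1
  expect_equal(sv[sp], "C")
  sv[sp] <- "U"
  utr <- paste0("AA", paste(sv, collapse = ""), "AA")
  h <- seed_constraint(hybridize(mir, utr, mdl, max_sites = 1))
  expect_equal(h$seed_offset, "1-7")
  expect_equal(sum(h$pairs[[1]]$pair_class == "GU"), 1)
})

test_that("step-1 screening applies the strict energy cutoff and seed filter", {
  mdl <- energy_model()
  spec <- fixture_spec(seed = 21, n_clusters = 6, n_genes_per_species = 8,
                       n_conserved_families = 2,
                       n_planted_conserved_sites = 3,
                       n_planted_partial_sites = 0,
                       n_planted_private_sites = 0, n_verified_pairs = 2,
                       utr_length_range = c(120L, 200L))
  corpus <- generate_corpus(spec)
  members <- corpus$mirnas[!is.na(corpus$mirnas$family), ]
  hits <- screen_step1(members, corpus$utrs, mdl, dG_max = -17)
  expect_true(all(hits$dG < -17))
  expect_true(all(!is.na(hits$seed_offset)))
  # every planted conserved site is recovered
  truth <- corpus$truth[corpus$truth$site_type == "conserved", ]
  got <- paste(hits$family, hits$gene_id, hits$species)
  expect_true(all(paste(truth$family, truth$gene_id, truth$species) %in% got))
  # per-gene collapsing: one hit per (family, gene, species)
  expect_equal(anyDuplicated(got), 0)
})

test_that("the energy cutoff is a strict inequality", {
  mdl <- energy_model()
  mir <- tibble::tibble(mirna_id = "hsa-miR-x", species = "H. sapiens",
                        sequence = "UGAGGUAGUAGGUUGUAUAGUU",
                        family = "miR-x")
  utr <- tibble::tibble(transcript_id = "t1", gene_id = "g1",
                        species = "H. sapiens",
                        sequence = paste0("CC", rc_rna(mir$sequence), "AA"),
                        length_nt = 26L)
  d <- hybridize(mir, utr, mdl, max_sites = 1)$dG
  expect_equal(nrow(screen_step1(mir, utr, mdl, dG_max = d)), 0)
  expect_equal(nrow(screen_step1(mir, utr, mdl, dG_max = d + 1e-6)), 1)
})

test_that("tightening the energy cutoff never adds hits (monotone filter)", {
  mdl <- energy_model()
  spec <- fixture_spec(seed = 31, n_clusters = 5, n_genes_per_species = 6,
                       n_conserved_families = 1,
                       n_planted_conserved_sites = 2,
                       n_planted_partial_sites = 0,
                       n_planted_private_sites = 0, n_verified_pairs = 1)
  corpus <- generate_corpus(spec)
  members <- corpus$mirnas[!is.na(corpus$mirnas$family), ]
  key <- function(h) paste(h$mirna_id, h$gene_id, h$site_start)
  h_loose <- screen_step1(members, corpus$utrs, mdl, dG_max = -10)
  h_tight <- screen_step1(members, corpus$utrs, mdl, dG_max = -25)
  expect_true(all(key(h_tight) %in% key(h_loose)))
  expect_lte(nrow(h_tight), nrow(h_loose))
})

test_that("degenerate inputs yield empty results", {
  mdl <- energy_model()
  expect_equal(nrow(hybridize("UGAGGUAGA", "ACGU", mdl)), 0) # UTR < 7 nt
  expect_equal(nrow(screen_step1(tibble::tibble(mirna_id = character(),
                                                species = character(),
                                                sequence = character(),
                                                family = character()),
                                 tibble::tibble(transcript_id = "t", gene_id = "g",
                                                species = "H. sapiens",
                                                sequence = "ACGUACGUAC"),
                                 mdl)), 0)
  expect_error(hybridize("UGAGNUAGA", "ACGUACGUACGU", mdl), "non-RNA")
})
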