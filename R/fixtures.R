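# Seeded synthetic corpora with planted target sites and known ground
# truth: mature miRNAs (conserved families plus species-private decoys),
# per-species 3'-UTRs, an ortholog map, a verified-pair table, and a truth
# table recording every planted site.

RNA_BASES <- c("A", "C", "G", "U")

rna_revcomp <- function(seq) {
  paste(rev(chartr("ACGU", "UGCA", strsplit(seq, "")[[1]])), collapse = "")
}

random_rna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  paste(sample(RNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

mutate_positions <- function(seq, positions) {
  v <- strsplit(seq, "")[[1]]
  for (p in positions) v[p] <- sample(setdiff(RNA_BASES, v[p]), 1)
  paste(v, collapse = "")
}

#' Specification of a synthetic corpus
#'
#' Collects every knob of the generator: corpus dimensions, how many
#' conserved miRNA families to plant and at what mutual identity, how many
#' target sites to plant at each conservation depth, and the per-nucleotide
#' mutation rate applied to planted sites. With a fixed seed the generated
#' corpus is byte-identical across runs.
#'
#' @param seed RNG seed.
#' @param n_species number of species (2-5; default 5, taken in order from
#'   [bilaterian_species()]).
#' @param n_clusters ortholog clusters, one member gene per species.
#' @param n_genes_per_species total genes per species (clusters plus
#'   species-private genes).
#' @param utr_length_range min/max 3'-UTR length (nt).
#' @param n_conserved_families conserved miRNA families to plant.
#' @param family_identity_pct target mature-sequence identity within a
#'   family (percent).
#' @param n_decoy_mirnas_per_species species-private decoy miRNAs.
#' @param n_planted_conserved_sites sites planted in >= 4 species including
#'   the anchor (these should survive the full screen).
#' @param n_planted_partial_sites sites planted in exactly 2 species.
#' @param n_planted_private_sites sites planted in a single species.
#' @param site_mutation_rate per-nucleotide substitution probability applied
#'   to each planted site.
#' @param site_gu_count G-U wobbles engineered into each planted site by
#'   substituting a site nucleotide so the duplex pair becomes G-U (placed
#'   outside the 1-7 seed window).
#' @param n_verified_pairs verified (family, gene, species) pairs sampled
#'   from the planted conserved sites.
#' @param decoy_gc GC fraction of background UTR sequence.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_species = 5, n_clusters = 20,
                         n_genes_per_species = 40,
                         utr_length_range = c(150L, 400L),
                         n_conserved_families = 5,
                         family_identity_pct = 90,
                         n_decoy_mirnas_per_species = 10,
                         n_planted_conserved_sites = 10,
                         n_planted_partial_sites = 5,
                         n_planted_private_sites = 5,
                         site_mutation_rate = 0,
                         site_gu_count = 0,
                         n_verified_pairs = 10,
                         decoy_gc = 0.45) {
  spec <- as.list(environment())
  stopifnot(n_species >= 2, n_species <= 5,
            n_genes_per_species >= n_clusters,
            site_mutation_rate >= 0, site_mutation_rate <= 1,
            decoy_gc >= 0, decoy_gc <= 1,
            utr_length_range[1] >= 30)
  if (n_planted_conserved_sites > n_conserved_families * n_clusters) {
    abort("more conserved sites requested than (family, cluster) combinations")
  }
  structure(spec, class = "fixture_spec")
}

plant_site <- function(utr_seq, site_seq, occupied) {
  L <- nchar(site_seq)
  n <- nchar(utr_seq)
  if (n < L) abort("UTR too short to host a planted site")
  ok <- rep(TRUE, n - L + 1)
  for (iv in occupied) {
    lo <- max(1, iv[1] - L + 1)
    hi <- min(n - L + 1, iv[2])
    if (lo <= hi) ok[lo:hi] <- FALSE
  }
  starts <- which(ok)
  if (length(starts) == 0) abort("UTR too short to host a planted site")
  s <- sample(starts, 1)
  substr(utr_seq, s, s + L - 1) <- site_seq
  list(seq = utr_seq, start = s, end = s + L - 1)
}

# engineer wobbles: substitute a site base so the duplex pair becomes G-U
# (miRNA G: site C -> U; miRNA U: site A -> G); site runs 3'->5' of miRNA
add_gu_wobbles <- function(site_seq, mirna_seq, k) {
  if (k == 0) return(site_seq)
  L <- nchar(mirna_seq)
  mv <- strsplit(mirna_seq, "")[[1]]
  sv <- strsplit(site_seq, "")[[1]]
  # site position pairing miRNA position i is L - i + 1; keep the seed
  # window (miRNA 1-7) Watson-Crick so default filters are not tripped
  cand_m <- which(mv %in% c("G", "U") & seq_len(L) > 9)
  if (length(cand_m) < k) abort("not enough wobble-capable positions in site")
  pick <- sample(cand_m, k)
  for (i in pick) {
    sp <- L - i + 1
    sv[sp] <- if (mv[i] == "G") "U" else "G"
  }
  paste(sv, collapse = "")
}

#' Generate a synthetic corpus with planted target sites
#'
#' Builds the four inputs of the screen (mature miRNAs, per-species 3'-UTRs,
#' ortholog map, verified-pair table) plus a truth table of every planted
#' site. Planted sites are reverse complements of the hosting species'
#' family member (optionally carrying engineered G-U wobbles and random
#' substitutions), written into orthologous UTRs at the requested
#' conservation depth.
#'
#' @param spec a [fixture_spec()].
#' @param dir optional directory; when given, FASTA/TSV files are written
#'   there (`mirnas.fa`, `utrs_<prefix>.fa`, `orthologs.tsv`,
#'   `verified.tsv`, `truth.tsv`).
#' @return A list with tibbles `mirnas`, `utrs`, `orthologs`, `verified`,
#'   `truth`, and `species` (the species vector), invisibly also written to
#'   `dir` when requested.
#' @export
generate_corpus <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  registry <- bilaterian_species()[seq_len(spec$n_species), ]
  species <- registry$species
  anchor <- species[1]
  withr::with_seed(spec$seed, {
    ## conserved miRNA families -------------------------------------------
    L <- 22L
    n_mut <- max(0L, round((100 - spec$family_identity_pct) / 100 * L / 2))
    fam_rows <- list()
    for (f in seq_len(spec$n_conserved_families)) {
      base <- random_rna(L)
      fam <- sprintf("sim-%d", f)
      for (si in seq_along(species)) {
        sq <- base
        if (si > 1 && n_mut > 0) { # anchor member stays unmutated
          sq <- mutate_positions(sq, sample(10:L, n_mut))
        }
        fam_rows[[length(fam_rows) + 1]] <- tibble(
          mirna_id = sprintf("%s-%s", registry$prefix[si], fam),
          species = species[si], sequence = sq, family = fam
        )
      }
    }
    fam_schema <- tibble(mirna_id = character(), species = character(),
                         sequence = character(), family = character())
    fam_mirnas <- bind_rows(c(list(fam_schema), fam_rows))
    ## species-private decoy miRNAs ---------------------------------------
    dec_rows <- list()
    for (si in seq_along(species)) {
      for (d in seq_len(spec$n_decoy_mirnas_per_species)) {
        dec_rows[[length(dec_rows) + 1]] <- tibble(
          mirna_id = sprintf("%s-dec-%d", registry$prefix[si], d),
          species = species[si], sequence = random_rna(L),
          family = NA_character_
        )
      }
    }
    mirnas <- bind_rows(c(list(fam_schema), fam_rows, dec_rows))
    ## genes, UTRs, ortholog map ------------------------------------------
    utr_rows <- list()
    ort_rows <- list()
    for (si in seq_along(species)) {
      px <- registry$prefix[si]
      for (g in seq_len(spec$n_genes_per_species)) {
        in_cluster <- g <= spec$n_clusters
        gid <- if (in_cluster) sprintf("g%02d_%s", g, px)
        else sprintf("px%02d_%s", g, px)
        len <- sample(spec$utr_length_range[1]:spec$utr_length_range[2], 1)
        utr_rows[[length(utr_rows) + 1]] <- tibble(
          transcript_id = paste0("t_", gid), gene_id = gid,
          species = species[si], sequence = random_rna(len, spec$decoy_gc),
          length_nt = len
        )
        if (in_cluster) {
          ort_rows[[length(ort_rows) + 1]] <- tibble(
            gene_id = gid, species = species[si],
            cluster_id = sprintf("OG%02d", g)
          )
        }
      }
    }
    utrs <- bind_rows(utr_rows)
    orthologs <- bind_rows(ort_rows)
    ## choose planting assignments ----------------------------------------
    combos <- expand.grid(family = unique(fam_mirnas$family),
                          cluster = seq_len(spec$n_clusters),
                          stringsAsFactors = FALSE)
    n_sites <- spec$n_planted_conserved_sites +
      spec$n_planted_partial_sites
    if (n_sites > nrow(combos)) {
      abort("not enough (family, cluster) combinations for requested sites")
    }
    pick <- sample(nrow(combos), n_sites)
    cons_combo <- combos[pick[seq_len(spec$n_planted_conserved_sites)], ,
                         drop = FALSE]
    part_combo <- combos[pick[-seq_len(spec$n_planted_conserved_sites)], ,
                         drop = FALSE]
    occupied <- list() # per transcript: list of planted intervals
    truth_rows <- list()
    plant_into <- function(fam, cluster_gene, sp, depth_label) {
      i <- which(utrs$gene_id == cluster_gene & utrs$species == sp)
      member <- fam_mirnas[fam_mirnas$family == fam &
                             fam_mirnas$species == sp, ]
      site <- rna_revcomp(member$sequence)
      site <- add_gu_wobbles(site, member$sequence, spec$site_gu_count)
      nm <- nchar(site)
      if (spec$site_mutation_rate > 0) {
        hitpos <- which(stats::runif(nm) < spec$site_mutation_rate)
        if (length(hitpos) > 0) site <- mutate_positions(site, hitpos)
      }
      key <- utrs$transcript_id[i]
      res <- plant_site(utrs$sequence[i], site, occupied[[key]] %||% list())
      utrs$sequence[i] <<- res$seq
      occupied[[key]] <<- c(occupied[[key]] %||% list(),
                            list(c(res$start, res$end)))
      truth_rows[[length(truth_rows) + 1]] <<- tibble(
        site_type = depth_label, family = fam,
        cluster_id = sprintf("OG%02d", as.integer(sub("^g(\\d+)_.*$", "\\1",
                                                      cluster_gene))),
        species = sp, gene_id = cluster_gene,
        transcript_id = key, site_start = res$start, site_end = res$end,
        expected_stage = if (depth_label == "conserved") "step3" else "step2"
      )
    }
    for (r in seq_len(nrow(cons_combo))) {
      fam <- cons_combo$family[r]
      cl <- cons_combo$cluster[r]
      depth <- sample(min(4, spec$n_species):spec$n_species, 1)
      sps <- c(anchor, sample(species[-1], depth - 1))
      for (sp in sps) {
        gid <- sprintf("g%02d_%s",
                       cl, registry$prefix[match(sp, species)])
        plant_into(fam, gid, sp, "conserved")
      }
    }
    if (nrow(part_combo) > 0) {
      for (r in seq_len(nrow(part_combo))) {
        fam <- part_combo$family[r]
        cl <- part_combo$cluster[r]
        sps <- sample(species, 2)
        for (sp in sps) {
          gid <- sprintf("g%02d_%s", cl, registry$prefix[match(sp, species)])
          plant_into(fam, gid, sp, "partial")
        }
      }
    }
    priv_pool <- filter(utrs, startsWith(.data$gene_id, "px"))
    if (spec$n_planted_private_sites > 0 && nrow(priv_pool) > 0) {
      # species-private genes host single-species sites
      pk <- priv_pool[sample(nrow(priv_pool),
                             min(spec$n_planted_private_sites,
                                 nrow(priv_pool))), ]
      for (r in seq_len(nrow(pk))) {
        sp <- pk$species[r]
        fam <- sample(unique(fam_mirnas$family), 1)
        member <- fam_mirnas[fam_mirnas$family == fam &
                               fam_mirnas$species == sp, ]
        site <- rna_revcomp(member$sequence)
        i <- which(utrs$transcript_id == pk$transcript_id[r])
        res <- plant_site(utrs$sequence[i], site,
                          occupied[[pk$transcript_id[r]]] %||% list())
        utrs$sequence[i] <- res$seq
        occupied[[pk$transcript_id[r]]] <-
          c(occupied[[pk$transcript_id[r]]] %||% list(),
            list(c(res$start, res$end)))
        truth_rows[[length(truth_rows) + 1]] <- tibble(
          site_type = "private", family = fam, cluster_id = NA_character_,
          species = sp, gene_id = pk$gene_id[r],
          transcript_id = pk$transcript_id[r],
          site_start = res$start, site_end = res$end,
          expected_stage = "step2"
        )
      }
    }
    truth_schema <- tibble(
      site_type = character(), family = character(), cluster_id = character(),
      species = character(), gene_id = character(),
      transcript_id = character(), site_start = integer(),
      site_end = integer(), expected_stage = character())
    truth <- bind_rows(c(list(truth_schema), truth_rows))
    ## verified pairs sampled from planted conserved sites -----------------
    cons_truth <- filter(truth, .data$site_type == "conserved")
    nv <- min(spec$n_verified_pairs, nrow(cons_truth))
    vsel <- cons_truth[sample(nrow(cons_truth), nv), ]
    verified <- distinct(tibble(mirna_family = vsel$family,
                                gene_id = vsel$gene_id,
                                species = vsel$species))
    utrs$length_nt <- nchar(utrs$sequence)
    out <- list(mirnas = mirnas, utrs = utrs, orthologs = orthologs,
                verified = verified, truth = truth, species = species)
  })
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_mirna_fasta(out$mirnas, file.path(dir, "mirnas.fa"))
    for (si in seq_along(species)) {
      write_utr_fasta(out$utrs[out$utrs$species == species[si], ],
                      file.path(dir, paste0("utrs_", registry$prefix[si], ".fa")))
    }
    readr::write_tsv(out$orthologs, file.path(dir, "orthologs.tsv"),
                     progress = FALSE)
    readr::write_tsv(out$verified, file.path(dir, "verified.tsv"),
                     progress = FALSE)
    readr::write_tsv(out$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  }
  out
}

#' Synthesise a hit table with planted binding-feature structure
#'
#' Serves optimizer validation: verified hits receive features drawn
#' uniformly at or below a planted cut, decoy (predicted) hits receive
#' diffuse features over the full scanned ranges. The planted cut is
#' recorded as the `truth_cut` attribute.
#'
#' @param n_verified,n_decoys how many hits of each kind.
#' @param cut named integer vector of the planted per-feature maxima (order
#'   mm_mrna, mm_mirna, gu_whole, gu_seed).
#' @param wc_only if `TRUE` the planted duplexes contain only Watson-Crick
#'   pairs, so any requested wobble cut above zero is infeasible and raises
#'   an error.
#' @param seed RNG seed.
#' @return A tibble with columns `verified`, `mm_mrna`, `mm_mirna`,
#'   `gu_whole`, `gu_seed`.
#' @export
plant_features <- function(n_verified = 100, n_decoys = 2000,
                           cut = c(mm_mrna = 2, mm_mirna = 1,
                                   gu_whole = 1, gu_seed = 0),
                           wc_only = FALSE, seed = 1L) {
  rng <- feature_ranges()
  fn <- feature_names()
  cut <- setNames(as.integer(cut[fn]), fn)
  if (anyNA(cut)) abort("cut must name all four features")
  over <- cut > rng
  if (any(over)) {
    abort(paste0("planted cut outside the scanned range for: ",
                 paste(fn[over], collapse = ", ")))
  }
  if (wc_only && (cut["gu_whole"] > 0 || cut["gu_seed"] > 0)) {
    abort("wobble cut above zero is infeasible with Watson-Crick-only planting")
  }
  draw <- function(n, maxes) {
    r <- function(mx) as.integer(sample.int(mx + 1L, n, replace = TRUE) - 1L)
    gw <- r(maxes[["gu_whole"]])
    tibble(
      mm_mrna = r(maxes[["mm_mrna"]]),
      mm_mirna = r(maxes[["mm_mirna"]]),
      gu_whole = gw,
      gu_seed = vapply(pmin(gw, maxes[["gu_seed"]]), function(m)
        as.integer(sample.int(m + 1L, 1L) - 1L), integer(1))
    )
  }
  withr::with_seed(seed, {
    out <- bind_rows(
      mutate(draw(n_verified, cut), verified = TRUE),
      mutate(draw(n_decoys, rng), verified = FALSE)
    )
  })
  attr(out, "truth_cut") <- cut
  out
}
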