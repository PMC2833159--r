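# Independent oracles used across the suite. These deliberately share no
# code with the implementation paths they check.

# exhaustive duplex enumeration: minimum free energy over every legal
# antiparallel pairing (monotone pair chains with loop penalties), by DFS
oracle_min_dG <- function(mirna, utr, model) {
  pair_codes <- c("AU", "UA", "CG", "GC", "GU", "UG")
  mv <- strsplit(mirna, "")[[1]]
  uv <- strsplit(utr, "")[[1]]
  N <- length(uv); M <- length(mv)
  ptype <- matrix(NA_character_, N, M)
  for (j in seq_len(N)) for (i in seq_len(M)) {
    p <- paste0(uv[j], mv[i])
    if (p %in% pair_codes) ptype[j, i] <- p
  }
  best <- Inf
  maxgu <- model$max_gap_utr; maxgm <- model$max_gap_mirna
  rec <- function(j, i, e) {
    if (e < best) best <<- e
    for (nj in seq(j + 1, length.out = min(N - j, maxgu + 1))) {
      gu <- nj - j - 1
      for (ni in seq(i - 1, length.out = min(i - 1, maxgm + 1), by = -1)) {
        t2 <- ptype[nj, ni]
        if (is.na(t2)) next
        gm <- i - ni - 1
        step <- if (gu == 0 && gm == 0) {
          model$stack_dG[ptype[j, i], t2]
        } else if (gm == 0) {
          model$bulge_dG(gu)
        } else if (gu == 0) {
          model$bulge_dG(gm)
        } else {
          model$internal_loop_dG(gu, gm)
        }
        rec(nj, ni, e + step)
      }
    }
  }
  for (j in seq_len(N)) for (i in seq_len(M)) {
    if (!is.na(ptype[j, i])) rec(j, i, 0)
  }
  if (!is.finite(best)) return(Inf)
  model$init_dG + best
}

# exhaustive global-alignment oracle: best affine-gap score over all edit
# paths; returns the identities achieved by every co-optimal alignment
oracle_alignment_identities <- function(a, b, gap_open = 22.5,
                                        gap_ext = 0.83) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  best <- -Inf
  ids <- numeric()
  rec <- function(i, j, score, matches, len, state) {
    # admissible bound: every remaining column scores at most +1
    if (score + min(length(av) - i + 1, length(bv) - j + 1) < best - 1e-9) {
      return(invisible())
    }
    if (i > length(av) && j > length(bv)) {
      id <- 100 * matches / len
      if (score > best + 1e-9) { best <<- score; ids <<- id }
      else if (abs(score - best) <= 1e-9) ids <<- c(ids, id)
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) {
      rec(i + 1, j + 1, score + as.numeric(av[i] == bv[j]),
          matches + as.numeric(av[i] == bv[j]), len + 1, "m")
    }
    if (i <= length(av)) {
      pen <- if (state == "da") gap_ext else gap_open + gap_ext
      rec(i + 1, j, score - pen, matches, len + 1, "da")
    }
    if (j <= length(bv)) {
      pen <- if (state == "db") gap_ext else gap_open + gap_ext
      rec(i, j + 1, score - pen, matches, len + 1, "db")
    }
  }
  rec(1, 1, 0, 0, 0, "m")
  unique(round(ids, 9))
}

# naive recount of the four binding features straight from the pair list
oracle_features <- function(pair_tbl, seed_offset, mirna_len) {
  win <- list("1-7" = 1:7, "2-8" = 2:8, "3-9" = 3:9)[[seed_offset]]
  span <- seq(min(pair_tbl$utr_pos), max(pair_tbl$utr_pos))
  mm_mrna <- length(setdiff(span, pair_tbl$utr_pos))
  mm_mirna <- length(setdiff(seq_len(mirna_len), pair_tbl$mirna_pos))
  gu_whole <- sum(pair_tbl$pair_class == "GU")
  gu_seed <- sum(pair_tbl$pair_class == "GU" & pair_tbl$mirna_pos %in% win)
  c(mm_mrna = mm_mrna, mm_mirna = mm_mirna, gu_whole = gu_whole,
    gu_seed = gu_seed)
}

# independent coverage recount
oracle_coverage <- function(values, feature_vec, flag) {
  vapply(values, function(v) sum(feature_vec[flag] <= v) / sum(flag),
         numeric(1))
}

# Welch statistic and two-sided p from the defining formulas
oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

random_rna_str <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

rc_rna <- function(seq) {
  paste(rev(chartr("ACGU", "UGCA", strsplit(seq, "")[[1]])), collapse = "")
}

# small energy model with tight gap caps: keeps exhaustive enumeration fast
tiny_model <- function() {
  energy_model(max_gap_utr = 5, max_gap_mirna = 4)
}
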