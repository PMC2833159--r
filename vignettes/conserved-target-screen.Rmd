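---
title: "Screening for conserved miRNA target genes across bilaterians"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for conserved miRNA target genes across bilaterians}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(bilatmir)
library(dplyr)
```

## The screening problem

Animal microRNAs repress genes by base-pairing with sites in 3'-UTRs, and
the pairing is loose enough that naive complementarity scans drown true
targets in false positives. `bilatmir` implements a comparative screen that
uses deep evolutionary conservation as the noise filter: a miRNA/target
relationship that has persisted since the common bilaterian ancestor should
be detectable as (i) a miRNA family conserved across distantly related
species, targeting (ii) orthologous genes, through (iii) energetically
favourable duplexes with seed pairing, in (iv) several species at once.

The screen runs in three filtering steps after a family-extraction stage,
over five model species by default (*H. sapiens*, *M. musculus*,
*G. gallus*, *D. melanogaster*, *C. elegans*):

1. **Family extraction.** A conserved family is one mature miRNA per
   species sharing an identical 7-nt seed (positions 1-7, 2-8 or 3-9 from
   the 5' end) with overall mature-sequence identity above 75%.
2. **Step 1 — duplex energetics.** Candidate sites are minimum-free-energy
   miRNA:mRNA duplexes with `dG < -17` kcal/mol and a completely paired,
   contiguous seed window.
3. **Step 2 — binding pattern.** Four features of the duplex are
   thresholded: mismatched mRNA positions within the duplex, mismatched
   miRNA positions, G-U wobbles overall, and G-U wobbles inside the seed.
   The default thresholds (12, 10, 4, 0) maximise an Enrichment x Coverage
   objective against experimentally verified pairs; the grid search that
   produces them is part of the package.
4. **Step 3 — ortholog conservation.** A (family, ortholog cluster) pair
   survives when sites survive steps 1-2 in at least four species,
   including the anchor species (*H. sapiens*).

## The duplex energy model

Candidate sites are found by a dynamic program over intermolecular duplexes
only: an ordered set of base pairs, UTR positions increasing while miRNA
positions decrease (antiparallel, no crossings, no intramolecular
structure, no multiloops). The free energy decomposes as

$$
\Delta G \;=\; \Delta G_{\mathrm{init}}
 + \sum_{\text{adjacent pairs}} \Delta G_{\mathrm{stack}}
 + \sum_{\text{gaps}} \Delta G_{\mathrm{loop}},
$$

with a Turner-style nearest-neighbour stacking table over Watson-Crick and
G-U pairs, an initiation term of +4.09 kcal/mol, and affine penalties for
bulges ($3.7 + 0.55\,(\ell-1)$ kcal/mol) and internal loops
($1.5 + 0.5\,(\ell_1+\ell_2)$ kcal/mol). Suboptimal sites in the same UTR
are enumerated greedily: the best site is reported, its span masked, and
the scan repeated, so reported sites never overlap.

Numerical choices worth knowing:

* **Absolute energies are model-dependent.** The stacking table
  approximates published RNA/RNA nearest-neighbour values but will not
  bit-match other duplex predictors; for that reason the `-17` kcal/mol
  cutoff is an explicit, calibratable `pipeline_config()` parameter rather
  than a constant.
* **Dangling-end terms are omitted** (set to zero). They shift absolute
  energies by fractions of a kcal/mol and do not change site ranking
  noticeably at this model's resolution.
* **Gap caps.** Unpaired stretches between consecutive pairs are capped at
  28 nt on the mRNA side and 13 nt on the miRNA side, mirroring the
  scanned ranges of the step-2 mismatch features.
* **Tie-breaking.** Among equal-energy structures the DP prefers more
  paired positions, then the leftmost site; this makes runs reproducible.
* **Degenerate inputs.** UTRs shorter than 7 nt return no sites; non-RNA
  letters are an error (readers normalise `T` to `U` and uppercase first).
* The seed constraint accepts G-U wobbles as "paired": the step-2 feature
  counting wobbles *inside the seed* would be pointless otherwise. With
  the published thresholds (`gu_seed = 0`) seed wobbles are still rejected,
  but at the feature-filter stage, where the stringency is a measured
  choice rather than a hard-coded rule.

The DP is validated against an exhaustive enumeration oracle (every legal
antiparallel pairing of small random sequences) in the test suite — 200
seeded instances with miRNAs up to 10 nt and UTRs up to 16 nt.

## Family identity and its aggregation

Pairwise identity uses a fixed global alignment (gap opening 22.5,
extension 0.83, match 1, mismatch 0 — ClustalX-like parameters) and counts
identical columns over the alignment length, gap columns counting as
mismatches. A family's published-style single "identity" number is
ambiguous between several aggregations, so the package reports **minimum**
pairwise identity as the headline statistic (conservative: every member
pair must clear the threshold) and mean pairwise identity as a secondary
column. When a species has several paralogous candidates sharing the seed
(e.g. let-7a vs let-7b), the member maximising the minimum cross-species
identity is chosen, ties broken lexicographically by identifier. The
third published family criterion — membership of an externally curated
highly conserved category — is consumed as an optional whitelist file, not
recomputed, because it derives from an external classification.

## The threshold optimizer

For each binding feature, a coverage curve records the fraction of
verified and of predicted step-1 hits retained at each threshold value
(scanned ranges 28-0, 14-0, 10-0, 6-0). Candidate thresholds are the 4-5
values with the largest verified-minus-predicted coverage gap (ties
resolved toward stricter values); the default grid shape (5, 5, 5, 4)
yields 500 combinations. Each combination is scored by
EC = Enrichment x Coverage, both **unrounded** — rounding only happens in
display, which is why a reported EC can differ slightly from the product
of the two rounded factors. Ties on EC break by higher coverage, then
stricter thresholds.

During optimization, coverage and enrichment are computed against the
step-1 hit sets themselves (the sets the curves are drawn on). The
stage-summary table is a different report: there the denominators are the
all-pairs universe, and the step-3 row is reported against the
ortholog-mapped, anchor-species universe — the only universe on which the
step-3 filter acts. The two baselines answer different questions and are
deliberately not merged.

## The negative control

Species-specific miRNAs — miRNAs the family extraction leaves unassigned —
should mostly fail the conservation screen. `control_experiment()` takes
each sampled control miRNA, pretends it is conserved (the same mature
sequence is scanned in every species), runs steps 1-3, and compares the
per-miRNA conserved-pair counts against the real families' counts with
Welch's *t*-test. Sampling is explicit (`n_per_species`, default 5, with a
seed). The test's sidedness is configurable and defaults to two-sided,
the conservative reading of a directional claim. One degenerate case is
defined by fiat: two identical constant samples give `t = 0, p = 1`
(no evidence of difference), while constant samples with different means
raise an error since the statistic is undefined.

## What the synthetic corpus does and does not emulate

`generate_corpus()` builds a complete, seeded corpus: conserved families
(identical seed region, controlled mature-sequence divergence), decoy
miRNAs with scrambled seeds, i.i.d.-background UTRs at configurable GC
content, an ortholog map, planted target sites at three conservation
depths (>= 4 species, exactly 2 species, single species), optional
engineered G-U wobbles (created by substituting the site base so that the
duplex pair becomes a wobble, keeping the site energetically near-optimal,
and placed outside the seed window), per-site mutation noise, and a
verified-pair table drawn from the planted truth.

It emulates the *structure* of the real inputs, not their statistics: real
3'-UTRs are not i.i.d. sequence (they have composition bias, repeats, and
secondary structure), real ortholog maps are incomplete and paralog-rich,
and real verified-pair sets are biased toward well-studied genes. A
passing planted-site test therefore demonstrates that the pipeline's
logic is correct — recall of 100% at mutation rate zero, clean separation
of conservation depths, threshold recovery by the grid search — not that
its defaults are optimal for any particular genome release.

Default generator conditions are five species, 22-nt miRNAs, UTRs of
150-400 nt, family identity ~90%, and 10 planted conserved sites; tests
use corpora from ~50 genes (unit level) up to 5 species x 200 genes
(end-to-end recall), sizes chosen so the whole suite exercises every stage
on a desktop machine in minutes.

## Reporting conventions

Coordinates are 1-based and inclusive on the UTR 5'->3'; miRNA positions
are 1-based from the 5' end. `dist_from_stop = site_start - 1` counts the
nucleotides between the stop codon and the site; `dist_from_3end` the
nucleotides to the UTR 3' end. These columns support positional analyses
of target sites (conserved sites often cluster near the stop codon), but
the package deliberately stops at reporting them — no positional
statistics are computed.

## Worked example

```{r example}
corpus <- generate_corpus(fixture_spec(
  seed = 1, n_clusters = 10, n_genes_per_species = 14,
  n_conserved_families = 3, n_planted_conserved_sites = 6,
  n_planted_partial_sites = 2, n_planted_private_sites = 2,
  n_verified_pairs = 4, utr_length_range = c(100L, 160L)))

run <- run_pipeline(corpus, pipeline_config())
run

glance(run)
tidy(run)

# stage accounting in the style of the screen's summary table
run$evaluation |> mutate(across(where(is.numeric), ~ round(.x, 1)))
```

## Known limitations

* No mRNA secondary-structure or site-accessibility modelling; a site
  buried in a stable hairpin scores the same as an open one.
* One best hit per (family, gene) at the gene scale by default; isoform
  level analysis requires `longest_per_gene = FALSE` and
  `per_gene = FALSE`.
* Ortholog clusters are trusted input; no ortholog inference is attempted.
* The energy parameterization is intentionally simple (affine loops, no
  dangles, no coaxial terms); cutoffs calibrated under one parameter set
  should be re-examined under another.
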