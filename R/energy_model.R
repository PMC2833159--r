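# Nearest-neighbour duplex energy model.
#
# The duplex free energy is decomposed as
#   dG = init_dG + sum(stack terms over adjacent base pairs)
#              + sum(loop penalties over gaps between consecutive pairs)
# Stacks are indexed by the two flanking pairs written with the mRNA (UTR)
# strand on top, 5'->3', and the miRNA strand below, 3'->5'. Pair codes name
# (top, bottom): "AU" means A on the mRNA paired with U on the miRNA.

PAIR_CODES <- c("AU", "UA", "CG", "GC", "GU", "UG")

# Turner-style RNA/RNA stacking free energies at 37 degC (kcal/mol),
# including G-U wobbles. Rows: 5' pair, columns: 3' pair (both read along
# the top strand). Values obey the strand-reversal symmetry
# dG(5'XY3'/3'WZ5') == dG(5'ZW3'/3'YX5').
default_stack_table <- function() {
  m <- matrix(NA_real_, 6, 6, dimnames = list(PAIR_CODES, PAIR_CODES))
  # strand reversal maps stack (p1, p2) -> (swap(p2), swap(p1)), where
  # swap("XY") = "YX" is the same pair read from the opposite strand
  swap <- function(p) paste0(substr(p, 2, 2), substr(p, 1, 1))
  set <- function(p1, p2, v) {
    m[p1, p2] <<- v
    m[swap(p2), swap(p1)] <<- v
  }
  # Watson-Crick / Watson-Crick
  set("AU", "AU", -0.93); set("AU", "UA", -1.10); set("UA", "AU", -1.33)
  set("CG", "UA", -2.08); set("CG", "AU", -2.11); set("GC", "UA", -2.24)
  set("GC", "AU", -2.35); set("CG", "GC", -2.36); set("GC", "GC", -3.26)
  set("GC", "CG", -3.42)
  # one G-U wobble
  set("AU", "GU", -0.55); set("AU", "UG", -1.36); set("CG", "GU", -1.41)
  set("CG", "UG", -2.11); set("GC", "GU", -1.53); set("GC", "UG", -2.51)
  set("UA", "GU", -1.00); set("UA", "UG", -1.27)
  # tandem G-U
  set("GU", "GU", -0.50); set("GU", "UG", 0.47); set("UG", "GU", 0.30)
  m
}

#' Construct a duplex free-energy model
#'
#' Defines the thermodynamic parameterization used by [hybridize()]: a
#' nearest-neighbour stacking table over Watson-Crick and G-U pairs, a duplex
#' initiation term, and affine bulge / internal-loop penalties. The shipped
#' defaults are Turner-style RNA/RNA stacking free energies at 37 degC; the
#' absolute energies approximate, but do not bit-match, those of other duplex
#' prediction tools, which is why the downstream free-energy cutoff is
#' exposed as a calibratable parameter.
#'
#' @param stack_dG 6x6 numeric matrix of stacking energies (kcal/mol) with
#'   dimnames `c("AU","UA","CG","GC","GU","UG")`; rows are the 5' pair and
#'   columns the 3' pair, both read along the mRNA strand with the miRNA
#'   below (so code "GU" is mRNA G paired with miRNA U).
#' @param init_dG duplex initiation free energy (kcal/mol).
#' @param bulge_dG function of bulge length (nt) returning a penalty >= 0.
#' @param internal_loop_dG function of the two gap lengths returning a
#'   penalty >= 0.
#' @param max_gap_utr,max_gap_mirna largest unpaired gap allowed between
#'   consecutive pairs on the mRNA / miRNA side.
#' @param version_tag string identifying the parameter set.
#'
#' @return An object of class `energy_model`.
#' @export
#' @examples
#' m <- energy_model()
#' m$stack_dG["GC", "CG"]
energy_model <- function(stack_dG = default_stack_table(),
                         init_dG = 4.09,
                         bulge_dG = function(len) 3.7 + 0.55 * (len - 1),
                         internal_loop_dG = function(l1, l2) 1.5 + 0.5 * (l1 + l2),
                         max_gap_utr = 28,
                         max_gap_mirna = 13,
                         version_tag = "turner-like-1.0") {
  stopifnot(is.matrix(stack_dG), all(dim(stack_dG) == c(6, 6)))
  if (!identical(rownames(stack_dG), PAIR_CODES) ||
      !identical(colnames(stack_dG), PAIR_CODES)) {
    abort("stack_dG must have dimnames AU, UA, CG, GC, GU, UG in order")
  }
  if (anyNA(stack_dG)) abort("stack_dG must cover all WC/G-U stack combinations")
  wc <- c("AU", "UA", "CG", "GC")
  if (any(stack_dG[wc, wc] >= 0)) {
    abort("all Watson-Crick/Watson-Crick stacks must be negative")
  }
  bp <- vapply(seq_len(max_gap_utr), bulge_dG, numeric(1))
  ip <- vapply(2:(max_gap_utr + max_gap_mirna), function(n)
    internal_loop_dG(ceiling(n / 2), floor(n / 2)), numeric(1))
  if (any(bp < 0) || any(ip < 0)) abort("loop penalties must be non-negative")
  if (is.unsorted(bp) || is.unsorted(ip)) {
    abort("loop penalties must be non-decreasing in loop length")
  }
  structure(
    list(stack_dG = stack_dG, init_dG = init_dG, bulge_dG = bulge_dG,
         internal_loop_dG = internal_loop_dG, max_gap_utr = max_gap_utr,
         max_gap_mirna = max_gap_mirna, version_tag = version_tag),
    class = "energy_model"
  )
}

#' @export
print.energy_model <- function(x, ...) {
  cat("<energy_model ", x$version_tag, ">\n", sep = "")
  cat("  init_dG: ", x$init_dG, " kcal/mol\n", sep = "")
  cat("  max gap (mRNA/miRNA): ", x$max_gap_utr, "/", x$max_gap_mirna, " nt\n",
      sep = "")
  invisible(x)
}

# Precompute penalty lookups for the C++ scanner.
# bulge_pen[k] is the cost of a k-nt one-sided gap; il_pen[n] the cost of an
# internal loop of total size n (n >= 2; index 1 unused).
loop_penalty_tables <- function(model) {
  max_total <- model$max_gap_utr + model$max_gap_mirna
  bulge <- vapply(seq_len(max(model$max_gap_utr, model$max_gap_mirna)),
                  model$bulge_dG, numeric(1))
  il <- c(Inf, vapply(2:max_total, function(n)
    model$internal_loop_dG(ceiling(n / 2), floor(n / 2)), numeric(1)))
  list(bulge = bulge, internal = il)
}

# encode an RNA string as integer codes A=0 C=1 G=2 U=3; errors on other letters
encode_rna <- function(seq) {
  v <- strsplit(seq, "")[[1]]
  code <- match(v, c("A", "C", "G", "U")) - 1L
  if (anyNA(code)) {
    abort(paste0("sequence contains non-RNA letters: ",
                 paste(unique(v[is.na(code)]), collapse = ", ")))
  }
  code
}
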