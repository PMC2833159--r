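# Reading and writing the screen's external data: mature miRNA FASTA,
# per-species 3'-UTR FASTA, the ortholog map and the verified-pair table.

normalize_rna <- function(x) chartr("Tt", "Uu", toupper(x))

check_rna_alphabet <- function(seqs, what) {
  bad <- grepl("[^ACGU]", seqs)
  if (any(bad)) {
    abort(paste0(what, " contains letters outside {A,C,G,U} after T->U ",
                 "normalization (first offender: ",
                 names(seqs)[bad][1] %||% which(bad)[1], ")"))
  }
}

#' Read a mature miRNA FASTA file
#'
#' Headers are expected in the miRBase mature style: the first whitespace-
#' separated token is the miRNA identifier (e.g. `hsa-miR-1`), whose prefix
#' identifies the species. Sequences are uppercased and DNA `T` is
#' normalized to `U` on ingest.
#'
#' @param path FASTA file.
#' @param registry species registry tibble with columns `species`, `prefix`
#'   (default [bilaterian_species()]).
#' @return A tibble with columns `mirna_id`, `species`, `sequence`,
#'   `family` (`NA` until families are assigned).
#' @export
read_mirna_fasta <- function(path, registry = bilaterian_species()) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) {
    warn(paste0("no records in ", path))
    return(tibble(mirna_id = character(), species = character(),
                  sequence = character(), family = character()))
  }
  ids <- stringr::word(names(ss), 1)
  seqs <- normalize_rna(as.character(ss))
  names(seqs) <- ids
  check_rna_alphabet(seqs, "miRNA FASTA")
  len <- nchar(seqs)
  if (any(len < 15 | len > 30)) {
    abort(paste0("mature miRNA length outside [15, 30]: ",
                 paste(ids[len < 15 | len > 30], collapse = ", ")))
  }
  if (anyDuplicated(ids)) {
    abort(paste0("duplicated miRNA ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  tibble(mirna_id = ids, species = species_from_prefix(ids, registry),
         sequence = unname(seqs), family = NA_character_)
}

#' Read a 3'-UTR FASTA file for one species
#'
#' The header layout is configurable through `header_pattern`, a template
#' containing the placeholders `{transcript}` and `{gene}` (default
#' `"{transcript}|{gene}"`, i.e. `>ENST0001|ENSG0001`). Empty records are
#' skipped with a warning. With `longest_per_gene = TRUE` (default) only the
#' longest UTR per gene is kept, putting downstream counts on the gene
#' scale; set to `FALSE` to keep every transcript.
#'
#' @param path FASTA file.
#' @param species species label for every record in the file.
#' @param header_pattern template mapping the first header token to ids.
#' @param longest_per_gene keep only the longest 3'-UTR per gene?
#' @return A tibble with columns `transcript_id`, `gene_id`, `species`,
#'   `sequence`, `length_nt`.
#' @export
read_utr_fasta <- function(path, species,
                           header_pattern = "{transcript}|{gene}",
                           longest_per_gene = TRUE) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) {
    warn(paste0("no records in ", path))
    return(tibble(transcript_id = character(), gene_id = character(),
                  species = character(), sequence = character(),
                  length_nt = integer()))
  }
  heads <- stringr::word(names(ss), 1)
  rx <- stringr::str_escape(header_pattern)
  rx <- sub("\\{transcript\\}", "(?<transcript>[^|;, ]+)", rx, fixed = TRUE)
  rx <- sub("\\{gene\\}", "(?<gene>[^|;, ]+)", rx, fixed = TRUE)
  m <- stringr::str_match(heads, paste0("^", rx, "$"))
  if (anyNA(m[, 1])) {
    abort(paste0("UTR header does not match pattern '", header_pattern,
                 "': ", heads[is.na(m[, 1])][1]))
  }
  tid <- m[, "transcript"]
  gid <- m[, "gene"]
  seqs <- normalize_rna(as.character(ss))
  keep <- nchar(seqs) > 0
  if (!all(keep)) {
    warn(paste0("skipping ", sum(!keep), " zero-length UTR record(s)"))
  }
  tid <- tid[keep]; gid <- gid[keep]; seqs <- unname(seqs[keep])
  names(seqs) <- tid
  check_rna_alphabet(seqs, "UTR FASTA")
  if (anyDuplicated(tid)) {
    abort(paste0("duplicated (transcript_id, species): ",
                 paste(unique(tid[duplicated(tid)]), collapse = ", ")))
  }
  out <- tibble(transcript_id = tid, gene_id = gid, species = species,
                sequence = unname(seqs), length_nt = unname(nchar(seqs)))
  if (longest_per_gene) {
    out <- out |>
      arrange(.data$gene_id, dplyr::desc(.data$length_nt),
              .data$transcript_id) |>
      distinct(.data$gene_id, .keep_all = TRUE)
  }
  arrange(out, .data$gene_id)
}

#' Read the ortholog map and the verified-pair table
#'
#' Both are tab-separated files with header rows. The ortholog map has
#' columns `gene_id`, `species`, `cluster_id`; a gene may belong to at most
#' one cluster within a species. The verified-pair table has columns
#' `mirna_family`, `gene_id`, `species`; duplicate rows are collapsed.
#'
#' @param ortholog_path,verified_path TSV files.
#' @param registry species registry (used to validate species tokens).
#' @return A list with elements `orthologs` and `verified`, both tibbles.
#' @export
read_tables <- function(ortholog_path, verified_path,
                        registry = bilaterian_species()) {
  ort <- readr::read_tsv(ortholog_path, comment = "#", col_types = "ccc",
                         progress = FALSE)
  need <- c("gene_id", "species", "cluster_id")
  if (!all(need %in% names(ort))) {
    abort(paste0("ortholog map must have columns ",
                 paste(need, collapse = ", ")))
  }
  multi <- ort |>
    distinct(.data$gene_id, .data$species, .data$cluster_id) |>
    dplyr::count(.data$gene_id, .data$species) |>
    filter(.data$n > 1)
  if (nrow(multi) > 0) {
    row <- which(ort$gene_id == multi$gene_id[1] &
                   ort$species == multi$species[1])[2]
    abort(paste0("gene assigned to more than one ortholog cluster: ",
                 multi$gene_id[1], " (", multi$species[1], "), row ", row))
  }
  ort <- distinct(ort[need])
  ver <- readr::read_tsv(verified_path, comment = "#", col_types = "ccc",
                         progress = FALSE)
  needv <- c("mirna_family", "gene_id", "species")
  if (!all(needv %in% names(ver))) {
    abort(paste0("verified-pair table must have columns ",
                 paste(needv, collapse = ", ")))
  }
  ver <- distinct(ver[needv])
  badsp <- setdiff(unique(c(ort$species, ver$species)), registry$species)
  if (length(badsp) > 0) {
    abort(paste0("unknown species token: ", paste(badsp, collapse = ", ")))
  }
  list(orthologs = ort, verified = ver)
}

#' Write a result table as TSV with a provenance header
#'
#' List-columns of duplex pairs are flattened through [encode_pairs()].
#'
#' @param x a tibble.
#' @param path output file.
#' @param params optional named list recorded in `#`-prefixed header lines.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(x, path, params = list()) {
  if ("pairs" %in% names(x) && is.list(x$pairs)) {
    x <- mutate(x, pairs_encoded = purrr::map_chr(.data$pairs, encode_pairs)) |>
      select(-"pairs")
  }
  hdr <- c(
    paste0("# bilatmir ", as.character(utils::packageVersion("bilatmir"))),
    if (length(params) > 0)
      paste0("# ", names(params), " = ",
             vapply(params, function(v) paste(format(v), collapse = ","),
                    character(1)))
  )
  writeLines(hdr, path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Write miRNA / UTR tibbles back to FASTA
#'
#' @param mirnas,utrs corpus tibbles as returned by the readers.
#' @param path output FASTA file.
#' @return `path`, invisibly.
#' @export
write_mirna_fasta <- function(mirnas, path) {
  ss <- Biostrings::BStringSet(setNames(mirnas$sequence, mirnas$mirna_id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @rdname write_mirna_fasta
#' @export
write_utr_fasta <- function(utrs, path) {
  ss <- Biostrings::BStringSet(
    setNames(utrs$sequence, paste0(utrs$transcript_id, "|", utrs$gene_id)))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
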