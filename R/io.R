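# Template I/O. Templates are one 16S gene sequence per record (plus strand,
# gene orientation), optionally carrying ~50 nt flanks, with a two-level
# taxonomy label (phylum, class) supplied as a separate TSV.

#' Read 16S templates from FASTA plus a taxonomy TSV
#'
#' @param fasta_path Multi-FASTA of 16S rRNA gene sequences.
#' @param taxonomy_path TSV with header `id<TAB>phylum<TAB>class`; `class`
#'   may be empty. Every FASTA id must appear here unless `strict = FALSE`,
#'   in which case missing ids get phylum `"unclassified"`.
#' @param strict Error on FASTA ids absent from the taxonomy (default TRUE).
#' @param has_flanks Logical: do sequences carry ~50 nt beyond the gene ends?
#'   Recorded on each record; anchoring does not depend on it.
#' @return A tibble with columns `id`, `sequence`, `taxon_phylum`,
#'   `taxon_class`, `has_flanks`. Sequences are upper-cased with U
#'   normalized to T.
#' @export
read_templates <- function(fasta_path, taxonomy_path, strict = TRUE,
                           has_flanks = FALSE) {
  seqs <- tryCatch(
    Biostrings::readBStringSet(fasta_path),
    error = function(e) abort(paste0("malformed FASTA '", fasta_path, "': ",
                                     conditionMessage(e)))
  )
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate FASTA id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  sequences <- vapply(seq_along(seqs), function(i) {
    tryCatch(normalize_sequence(as.character(seqs[[i]])),
             error = function(e) abort(paste0("record '", ids[i], "': ",
                                              conditionMessage(e))))
  }, character(1))

  tax <- read.delim(taxonomy_path, stringsAsFactors = FALSE,
                    colClasses = "character")
  need <- c("id", "phylum", "class")
  if (!all(need %in% names(tax))) {
    abort("taxonomy TSV must have header: id<TAB>phylum<TAB>class")
  }
  missing <- setdiff(ids, tax$id)
  if (length(missing) > 0 && strict) {
    abort(paste0("FASTA id(s) missing from taxonomy: ",
                 paste(head(missing, 5), collapse = ", "),
                 if (length(missing) > 5) " ..."))
  }
  idx <- match(ids, tax$id)
  tibble::tibble(
    id = ids,
    sequence = sequences,
    taxon_phylum = ifelse(is.na(idx), "unclassified", tax$phylum[idx]),
    taxon_class = ifelse(is.na(idx), "", tax$class[idx]),
    has_flanks = has_flanks
  )
}

#' Write templates back to FASTA + taxonomy TSV
#'
#' Inverse of [read_templates()]: `read_templates(write_templates(x, ...))`
#' reproduces ids, sequences and taxa exactly.
#'
#' @param templates Template tibble as returned by [read_templates()] or
#'   [generate_templates()].
#' @param fasta_path,taxonomy_path Output paths.
#' @return Invisibly, the input `templates`.
#' @export
write_templates <- function(templates, fasta_path, taxonomy_path) {
  set <- Biostrings::BStringSet(setNames(templates$sequence, templates$id))
  Biostrings::writeXStringSet(set, fasta_path)
  tax <- data.frame(id = templates$id,
                    phylum = templates$taxon_phylum,
                    class = templates$taxon_class)
  write.table(tax, taxonomy_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(templates)
}

#' Read a single reference sequence from FASTA
#'
#' @param path FASTA with exactly one record.
#' @return The normalized sequence string.
#' @export
read_reference <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) != 1L) abort("reference FASTA must contain exactly one record")
  normalize_sequence(as.character(seqs[[1]]), "reference")
}
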