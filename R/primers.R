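# Primer definitions. A primer set is a tibble with one row per primer:
# name, sequence (IUPAC, 5'->3'), orientation (forward/reverse), and the
# intended footprint in E. coli numbering when one is known.

#' Construct a primer set
#'
#' @param name Character vector of short identifiers.
#' @param sequence IUPAC DNA strings, written 5'->3'.
#' @param orientation `"forward"` or `"reverse"`. A reverse primer anneals to
#'   the plus strand's complement; its plus-strand footprint is computed from
#'   its reverse complement.
#' @param footprint_start,footprint_end Optional intended footprint (closed
#'   interval, E. coli numbering, plus strand); `NA` when unknown.
#' @return A tibble with class `primer_set`.
#' @export
primer_set <- function(name, sequence, orientation,
                       footprint_start = NA_integer_,
                       footprint_end = NA_integer_) {
  stopifnot(length(name) == length(sequence),
            length(sequence) == length(orientation))
  if (anyDuplicated(name)) abort("primer names must be unique")
  orientation <- match.arg(orientation, c("forward", "reverse"),
                           several.ok = TRUE)
  if (length(orientation) != length(name)) {
    orientation <- rep_len(orientation, length(name))
  }
  sequence <- vapply(sequence, normalize_sequence, character(1),
                     what = "primer sequence", USE.NAMES = FALSE)
  out <- tibble::tibble(
    name = as.character(name),
    sequence = sequence,
    orientation = orientation,
    footprint_start = as.integer(rep_len(footprint_start, length(name))),
    footprint_end = as.integer(rep_len(footprint_end, length(name)))
  )
  class(out) <- c("primer_set", class(out))
  out
}

#' Bundled 16S rRNA amplification primers
#'
#' The six amplification primers used for full-length bacterial 16S rRNA
#' cloning: Bac1f (positions 1-18, avoiding the variable 19th nucleotide),
#' the classic Bac8f pair (8-27, with A or C over position 19), UN1542r
#' (1528-1542, avoiding the variable 1527th nucleotide), and the UN1541r
#' pair (1525-1541, with the U- or C-compatible base over 1527).
#'
#' @return A `primer_set` tibble with six rows.
#' @export
#' @examples
#' amplification_primers()
amplification_primers <- function() {
  primer_set(
    name = c("Bac1f", "Bac8f(A)", "Bac8f(C)",
             "UN1542r", "UN1541r(U)", "UN1541r(C)"),
    sequence = c("AAATTGAAGAGTTTGATC",
                 "AGAGTTTGATCATGGCTCAG",
                 "AGAGTTTGATCCTGGCTCAG",
                 "TAAGGAGGTGATCCA",
                 "AAGGAGGTGATCCAACC",
                 "AAGGAGGTGATCCAGCC"),
    orientation = c("forward", "forward", "forward",
                    "reverse", "reverse", "reverse"),
    footprint_start = c(1L, 8L, 8L, 1528L, 1525L, 1525L),
    footprint_end = c(18L, 27L, 27L, 1542L, 1541L, 1541L)
  )
}

#' Read a primer set from a TSV file
#'
#' Expects a header with columns `name`, `sequence`, `orientation` and
#' optionally `footprint_start`, `footprint_end`.
#'
#' @param path Path to a tab-separated file.
#' @return A `primer_set` tibble.
#' @export
read_primers <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "sequence", "orientation")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(paste0("primer TSV missing column(s): ", paste(miss, collapse = ", ")))
  }
  primer_set(df$name, df$sequence, df$orientation,
             footprint_start = df$footprint_start %||% NA_integer_,
             footprint_end = df$footprint_end %||% NA_integer_)
}

# fetch one primer row by name, erroring helpfully
get_primer <- function(primers, name) {
  row <- primers[primers$name == name, ]
  if (nrow(row) != 1L) {
    abort(paste0("primer '", name, "' not found in primer set"))
  }
  row
}

# plus-strand query sequence for placement: reverse primers are matched as
# their reverse complement against the plus strand
plus_strand_query <- function(sequence, orientation) {
  if (orientation == "reverse") revcomp(sequence) else sequence
}
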