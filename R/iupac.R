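# IUPAC nucleotide algebra: expansions, complement, reverse complement,
# ambiguity-aware base matching. The internal alphabet is DNA (T, not U);
# rRNA-style display may render U but nothing downstream ever stores it.
# (Expansion/complement tables live in aaa-constants.R.)

#' Expand an IUPAC nucleotide code
#'
#' Returns the set of unambiguous DNA bases an IUPAC code stands for
#' (e.g. `R` expands to `A` and `G`; `N` to all four).
#'
#' @param code A single IUPAC character (case-insensitive). `U` is accepted
#'   and treated as `T`.
#' @return Character vector, a subset of `c("A","C","G","T")`.
#' @export
#' @examples
#' iupac_expand("R")
#' iupac_expand("N")
iupac_expand <- function(code) {
  code <- normalize_base(code)
  exp <- IUPAC_EXPANSION[[code]]
  if (is.null(exp)) abort(paste0("invalid IUPAC code: '", code, "'"))
  exp
}

normalize_base <- function(x) {
  gsub("U", "T", toupper(x), fixed = TRUE)
}

#' Validate an IUPAC DNA string
#'
#' @param seq Character scalar. `U` and lower case are tolerated.
#' @param what Label used in error messages.
#' @return The normalized (upper-case, `T`-alphabet) sequence, invisibly
#'   usable as the canonical internal form.
#' @export
normalize_sequence <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    abort(paste0(what, " must be a single character string"))
  }
  s <- normalize_base(seq)
  bad <- setdiff(unique(strsplit(s, "")[[1]]), IUPAC_CODES)
  if (length(bad) > 0) {
    abort(paste0(what, " contains invalid IUPAC characters: ",
                 paste(bad, collapse = ", ")))
  }
  if (nchar(s) == 0L) abort(paste0(what, " must be non-empty"))
  s
}

#' Reverse complement of an IUPAC DNA string
#'
#' Complements under the full IUPAC rules (R<->Y, K<->M, B<->V, D<->H,
#' S, W and N self-complementary) and reverses. Vectorized over `seq`.
#'
#' @param seq Character vector of IUPAC DNA strings.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("TAAGGAGGTGATCCA")
revcomp <- function(seq) {
  vapply(seq, function(s) {
    s <- normalize_sequence(s)
    chars <- strsplit(s, "")[[1]]
    paste(rev(unname(IUPAC_COMPLEMENT[chars])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Ambiguity-aware base match
#'
#' Two IUPAC codes match iff their expansions intersect; a gap on the
#' template side (`-`) never matches. Vectorized and recycled like `==`.
#'
#' @param primer_base,template_base IUPAC codes; `template_base` may be `"-"`.
#' @return Logical vector: `TRUE` for match.
#' @export
#' @examples
#' iupac_match("R", c("A", "C", "G"))
iupac_match <- function(primer_base, template_base) {
  n <- max(length(primer_base), length(template_base))
  primer_base <- rep_len(normalize_base(primer_base), n)
  template_base <- rep_len(normalize_base(template_base), n)
  vapply(seq_len(n), function(i) {
    tb <- template_base[i]
    if (tb == "-") return(FALSE)
    length(intersect(iupac_expand(primer_base[i]), iupac_expand(tb))) > 0
  }, logical(1))
}

# split a sequence into a character vector of single bases
seq_chars <- function(seq) strsplit(seq, "")[[1]]
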