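# Packaged E. coli-like 16S reference. The true GenBank E. coli sequence is
# not bundled; instead a synthetic 1,542 nt stand-in is constructed so that
# every coordinate the analysis cares about behaves like E. coli:
#   * positions 1-18   = Bac1f           (AAATTGAAGAGTTTGATC)
#   * positions 8-27   = Bac8f(A)        (so 19 = A)
#   * positions 916-918 = T, G, A        (h2 partners of 19A, 18C, 17T)
#   * positions 1525-1542 compatible with UN1541r(U) and UN1542r
#     (so 1527 = T, the DNA form of 1527U)
# Everything else is filled by a fixed linear-congruential stream, so the
# sequence is byte-identical across sessions and independent of R's RNG.
# Users may substitute a real E. coli reference FASTA anywhere a reference
# is accepted.

REFERENCE_LENGTH <- 1542L

# variable-helix windows (E. coli numbering) where indels are tolerated by
# the synthetic generator; h6 is the classic length-variable terminal loop
VARIABLE_HELIX_WINDOWS <- list(h6 = c(61L, 106L), h10 = c(198L, 219L))

# conserved blocks never mutated by the core substitution process
CONSERVED_BLOCKS <- list(c(8L, 27L), c(916L, 918L), c(1525L, 1542L))

lcg_stream <- function(n, seed = 20161542L) {
  x <- as.double(seed)
  out <- integer(n)
  for (i in seq_len(n)) {
    x <- (1103515245 * x + 12345) %% 2147483648
    # use high-order bits: the low bits of a power-of-two-modulus LCG cycle
    out[i] <- as.integer((x %/% 65536) %% 4)
  }
  out
}

#' Synthetic E. coli-like 16S rRNA reference sequence
#'
#' A deterministic 1,542 nt DNA string whose primer footprints (Bac1f,
#' Bac8f, UN1541r, UN1542r), helix h2 pairing partners (17-19 with 918-916)
#' and variable site 1527 all carry the E. coli states. It is *synthetic*:
#' positions outside those constrained regions are arbitrary fixed bases,
#' not the GenBank sequence.
#'
#' @return A 1,542-character DNA string.
#' @export
#' @examples
#' substr(ecoli_like_reference(), 1, 18)   # the Bac1f footprint
ecoli_like_reference <- function() {
  bases <- c("A", "C", "G", "T")[lcg_stream(REFERENCE_LENGTH) + 1L]
  ref <- bases
  fixed_5p <- seq_chars("AAATTGAAGAGTTTGATCATGGCTCAG")   # 1-27
  ref[1:27] <- fixed_5p
  ref[916:918] <- c("T", "G", "A")
  ref[1525:1542] <- seq_chars("GGTTGGATCACCTCCTTA")
  paste(ref, collapse = "")
}

#' Write the packaged reference to a FASTA file
#'
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_reference <- function(path) {
  set <- Biostrings::BStringSet(
    setNames(ecoli_like_reference(), "ecoli_like_16S_synthetic"))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
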