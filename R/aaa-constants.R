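# Shared constant tables (this file collates first).

IUPAC_EXPANSION <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

IUPAC_CODES <- names(IUPAC_EXPANSION)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

# 16 codes x (16 codes + gap) compatibility matrix: match iff expansions
# intersect; template gap never matches
MATCH_MATRIX <- local({
  codes <- IUPAC_CODES
  m <- matrix(FALSE, length(codes), length(codes) + 1L,
              dimnames = list(codes, c(codes, "-")))
  for (a in codes) for (b in codes) {
    m[a, b] <- length(intersect(IUPAC_EXPANSION[[a]], IUPAC_EXPANSION[[b]])) > 0
  }
  m
})
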