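# Independent oracles and shared fixtures. The oracles deliberately avoid
# the package's internals: they carry their own IUPAC table and their own
# dynamic program, so agreement with the production code is evidence, not
# tautology.

# --- independent IUPAC table (hand-typed, not the package's) -------------
ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

oracle_compatible <- function(a, b) {
  if (b == "-") return(FALSE)
  length(intersect(ORACLE_IUPAC[[a]], ORACLE_IUPAC[[b]])) > 0
}

# exhaustive gap-free placement scan over the whole template: minimal
# mismatch count and every start achieving it
oracle_placements <- function(query, template) {
  qc <- strsplit(query, "")[[1]]
  tc <- strsplit(template, "")[[1]]
  L <- length(qc)
  n <- length(tc)
  if (n < L) return(list(min = NA_integer_, starts = integer(0)))
  mm <- vapply(seq_len(n - L + 1L), function(s) {
    sum(!mapply(oracle_compatible, qc, tc[s:(s + L - 1L)]))
  }, integer(1))
  list(min = min(mm), starts = which(mm == min(mm)), all = mm)
}

# brute-force affine-gap ends-free (semi-global both sides) alignment
# score; gap of length k costs open + k * ext, terminal gaps free
oracle_semiglobal_score <- function(x, y, match = 2, mismatch = -3,
                                    open = 5, ext = 2) {
  xc <- strsplit(x, "")[[1]]
  yc <- strsplit(y, "")[[1]]
  n <- length(xc); m <- length(yc)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in aligned pair
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in y (x consumed)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in x (y consumed)
  M[1, ] <- 0; M[, 1] <- 0         # free leading gaps
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (xc[i - 1] == yc[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + s
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
    }
  }
  best <- max(M[n + 1, ], M[, m + 1], Ix[n + 1, ], Iy[, m + 1])
  best
}

# --- shared fixtures (built once per test run) ---------------------------
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# 500 templates with a Bernoulli(0.6) 19A state, flanks, default noise
mix_corpus <- function() fixture("mix", function() {
  cfg <- synthetic_config(
    seed = 42L,
    n_per_class = c(gamma_like = 0L, beta_like = 0L, other = 500L),
    freq_19A = c(gamma_like = 1, beta_like = 0, other = 0.6))
  gen <- generate_templates(cfg)
  maps <- build_coordinate_maps(gen$templates)
  list(templates = gen$templates, truth = gen$truth, maps = maps,
       p_19A = 0.6)
})

# small clean gamma + beta corpus (no noise beyond the planted states)
gb_corpus <- function() fixture("gb", function() {
  cfg <- synthetic_config(
    seed = 7L, n_per_class = c(gamma_like = 30L, beta_like = 20L, other = 0L),
    five_prime_variability = 0.5, core_mutation_rate = 0.01)
  gen <- generate_templates(cfg)
  maps <- build_coordinate_maps(gen$templates)
  list(templates = gen$templates, truth = gen$truth, maps = maps)
})

ref_template <- function(id = "ref") {
  tibble::tibble(id = id, sequence = ecoli_like_reference(),
                 taxon_phylum = "Proteobacteria",
                 taxon_class = "Gammaproteobacteria", has_flanks = FALSE)
}

primer_by_name <- function(name) {
  p <- amplification_primers()
  p[p$name == name, ]
}

# plant an unambiguous base at an E. coli position of a reference-derived
# sequence (no indels, so position = coordinate)
plant_base <- function(seq, pos, base) {
  substr(seq, pos, pos) <- base
  seq
}
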