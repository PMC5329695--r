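# Synthetic 16S-like corpora. The generator plants exactly the features the
# analysis reasons about — class-specific 19/916 states, the variable 1527,
# a hypervariable 1-7 run, a conserved 8-27 block, ~50 nt flanks, occasional
# truncation — and returns a ground-truth table so every pipeline stage can
# be tested against known states without downloads.

SYNTH_CLASSES <- c(gamma_like = "Gammaproteobacteria",
                   beta_like = "Betaproteobacteria",
                   other = "Bacilli")
SYNTH_PHYLA <- c(gamma_like = "Proteobacteria",
                 beta_like = "Proteobacteria",
                 other = "Firmicutes")

#' Configuration for the synthetic template generator
#'
#' Defaults state the world the generator emulates: gamma-like templates
#' carry 19A (freq 1.0) with the native 916U partner, beta-like carry 19C
#' with 916G, the 1527th position splits C/U evenly, positions 1-7 are
#' hypervariable (per-position substitution probability 0.5), the core
#' mutates at 2% per position outside conserved blocks, and templates carry
#' 50 nt flanks.
#'
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   output.
#' @param n_per_class Named counts for `gamma_like`, `beta_like`, `other`.
#' @param freq_19A Per-class probability of 19A (vs 19C).
#' @param pair_consistency Probability that 916 carries 19's native partner
#'   (A->U, C->G); otherwise the other partner is planted.
#' @param freq_1527_C Probability of C (vs U) at position 1527.
#' @param five_prime_variability Per-position substitution probability over
#'   positions 1-7.
#' @param core_mutation_rate Substitution probability outside conserved
#'   blocks and registry sites.
#' @param indel_rate Probability of a 1-3 nt deletion per variable-helix
#'   window (default 0).
#' @param flank_length Random flank length added at both gene ends.
#' @param truncation_rate Probability a template is clipped to a short
#'   (80-190 nt) terminal fragment, making it unanchorable.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_per_class = c(gamma_like = 50L,
                                             beta_like = 50L, other = 0L),
                             freq_19A = c(gamma_like = 1.0, beta_like = 0.0,
                                          other = 0.5),
                             pair_consistency = 1.0,
                             freq_1527_C = 0.5,
                             five_prime_variability = 0.5,
                             core_mutation_rate = 0.02,
                             indel_rate = 0,
                             flank_length = 50L,
                             truncation_rate = 0) {
  probs <- c(freq_19A, pair_consistency, freq_1527_C,
             five_prime_variability, core_mutation_rate, indel_rate,
             truncation_rate)
  if (any(probs < 0 | probs > 1)) abort("probabilities must be in [0, 1]")
  if (any(n_per_class < 0)) abort("counts must be >= 0")
  structure(list(seed = as.integer(seed), n_per_class = n_per_class,
                 freq_19A = freq_19A, pair_consistency = pair_consistency,
                 freq_1527_C = freq_1527_C,
                 five_prime_variability = five_prime_variability,
                 core_mutation_rate = core_mutation_rate,
                 indel_rate = indel_rate,
                 flank_length = as.integer(flank_length),
                 truncation_rate = truncation_rate),
            class = "synthetic_config")
}

# run code under a seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  force(code)
}

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

substitute_base <- function(base) {
  sample(setdiff(c("A", "C", "G", "T"), base), 1)
}

#' Generate synthetic 16S-like templates with ground truth
#'
#' @param config A [synthetic_config()].
#' @param reference Reference DNA string (default the packaged synthetic
#'   E. coli-like sequence).
#' @return A list: `templates` (template tibble ready for the pipeline) and
#'   `truth` (one row per template listing every planted state: class,
#'   19/916/1527 bases, five-prime substitution positions, core mutation
#'   count, truncation).
#' @export
generate_templates <- function(config, reference = ecoli_like_reference()) {
  stopifnot(inherits(config, "synthetic_config"))
  if (sum(config$n_per_class) == 0) abort("zero total template count")
  ref <- seq_chars(normalize_sequence(reference, "reference"))
  L <- length(ref)
  conserved <- sort(unique(c(8:27, 916:918, 1525:1542)))
  core_sites <- setdiff(8:L, conserved)
  with_local_seed(config$seed, {
    rows <- list(); truths <- list(); k <- 0L
    for (cls in names(SYNTH_CLASSES)) {
      n <- config$n_per_class[[cls]] %||% 0L
      if (is.na(n) || n == 0) next
      for (j in seq_len(n)) {
        k <- k + 1L
        tc <- ref
        b19 <- if (stats::runif(1) < config$freq_19A[[cls]]) "A" else "C"
        native <- if (b19 == "A") "T" else "G"
        other <- if (b19 == "A") "G" else "T"
        b916 <- if (stats::runif(1) < config$pair_consistency) native else other
        b1527 <- if (stats::runif(1) < config$freq_1527_C) "C" else "T"
        tc[19] <- b19; tc[916] <- b916; tc[1527] <- b1527
        fp_subs <- which(stats::runif(7) < config$five_prime_variability)
        for (p in fp_subs) tc[p] <- substitute_base(tc[p])
        core_hit <- core_sites[stats::runif(length(core_sites)) <
                                 config$core_mutation_rate]
        for (p in core_hit) tc[p] <- substitute_base(tc[p])
        for (w in VARIABLE_HELIX_WINDOWS) {
          if (config$indel_rate > 0 && stats::runif(1) < config$indel_rate) {
            del_len <- sample(1:3, 1)
            del_at <- sample(seq.int(w[1], w[2] - del_len), 1)
            tc[del_at:(del_at + del_len - 1L)] <- ""
          }
        }
        seq <- paste(tc, collapse = "")
        if (config$flank_length > 0) {
          seq <- paste0(random_bases(config$flank_length), seq,
                        random_bases(config$flank_length))
        }
        truncated <- config$truncation_rate > 0 &&
          stats::runif(1) < config$truncation_rate
        if (truncated) {
          keep <- sample(80:190, 1)
          seq <- if (stats::runif(1) < 0.5) substr(seq, 1, keep)
          else substr(seq, nchar(seq) - keep + 1L, nchar(seq))
        }
        id <- sprintf("synth_%s_%04d", sub("_like$", "", cls), k)
        rows[[k]] <- tibble::tibble(
          id = id, sequence = seq,
          taxon_phylum = SYNTH_PHYLA[[cls]],
          taxon_class = SYNTH_CLASSES[[cls]],
          has_flanks = config$flank_length > 0)
        truths[[k]] <- tibble::tibble(
          id = id, class_key = cls, base_19 = b19, base_916 = b916,
          base_1527 = b1527,
          five_prime_subs = list(as.integer(fp_subs)),
          n_core_mutations = length(core_hit), truncated = truncated)
      }
    }
    list(templates = dplyr::bind_rows(rows), truth = dplyr::bind_rows(truths))
  })
}

#' Generate a synthetic clone set with planted 19-916 patterns
#'
#' Builds full-length clone sequences from the reference with the requested
#' focus-pair pattern planted at positions 19/916 (plus a light 0.5% neutral
#' substitution load elsewhere), so that sequence-level pair-state
#' extraction recovers the requested pattern counts exactly. Clones are
#' emitted in canonical pattern order (A-U, A-G, C-G, C-U) regardless of the
#' order of `pair_counts`, so the output depends only on the counts and the
#' seed.
#'
#' @param pair_counts Named integer vector over a subset of
#'   `c("A-U","A-G","C-G","C-U")`.
#' @param origin_counts Optional named integer vector of taxon-class labels;
#'   must sum to `sum(pair_counts)`. Labels are assigned in sorted-name
#'   order. Default: all `"Gammaproteobacteria"`.
#' @param library Library identifier stamped on every record.
#' @param seed Integer seed.
#' @param reference Reference DNA string.
#' @return A clone-record tibble (`id`, `library`, `taxon_class`,
#'   `sequence`, `base_19`, `base_916`) ready for [summarize_clones()].
#' @export
generate_clone_set <- function(pair_counts, origin_counts = NULL,
                               library = "library1", seed = 1L,
                               reference = ecoli_like_reference()) {
  bad <- setdiff(names(pair_counts), PAIR_PATTERN_KEYS)
  if (length(bad) > 0) {
    abort(paste0("unknown pair pattern(s): ", paste(bad, collapse = ", ")))
  }
  total <- sum(pair_counts)
  if (total == 0) abort("zero total clone count")
  if (!is.null(origin_counts) && sum(origin_counts) != total) {
    abort("origin_counts and pair_counts must have equal totals")
  }
  patterns <- unlist(purrr::map(PAIR_PATTERN_KEYS, function(k) {
    n <- unname(pair_counts[k])
    rep(k, if (is.na(n)) 0L else n)
  }))
  origins <- if (is.null(origin_counts)) {
    rep("Gammaproteobacteria", total)
  } else {
    oc <- origin_counts[sort(names(origin_counts))]
    rep(names(oc), oc)
  }
  ref <- seq_chars(normalize_sequence(reference, "reference"))
  planted <- list("A-U" = c("A", "T"), "A-G" = c("A", "G"),
                  "C-G" = c("C", "G"), "C-U" = c("C", "T"))
  mutable <- setdiff(seq_along(ref), c(1:27, 916:918, 1525:1542))
  with_local_seed(seed, {
    purrr::map(seq_len(total), function(i) {
      tc <- ref
      st <- planted[[patterns[i]]]
      tc[19] <- st[1]; tc[916] <- st[2]
      hit <- mutable[stats::runif(length(mutable)) < 0.005]
      for (p in hit) tc[p] <- substitute_base(tc[p])
      tibble::tibble(
        id = sprintf("%s_clone_%03d", library, i),
        library = library,
        taxon_class = origins[i],
        sequence = paste(tc, collapse = ""),
        base_19 = st[1], base_916 = st[2])
    }) |> dplyr::bind_rows()
  })
}
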