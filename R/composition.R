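# Per-position composition and primer coverage in the E. coli frame,
# mirroring terminal-region stacked-bar profiles and per-taxon coverage
# breakdowns.

#' Per-position nucleotide composition over an E. coli region
#'
#' Tallies A/C/G/T/gap counts at every E. coli position of `region` across
#' all templates with an anchorable coordinate map. A template whose map
#' does not span a position contributes `gap` there, so per-position counts
#' always sum to the number of anchorable templates. Ambiguity codes in
#' templates (rare) are tallied in their own `ambiguous` column.
#'
#' @param templates Template tibble.
#' @param maps Map tibble from [build_coordinate_maps()].
#' @param region Closed E. coli interval, e.g. `c(1, 30)`.
#' @return A tibble of class `composition_profile` with columns `ecoli_pos`,
#'   `A`, `C`, `G`, `T`, `gap`, `ambiguous`, `depth`.
#' @export
composition_profile <- function(templates, maps, region) {
  if (nrow(templates) == 0) abort("empty template set")
  stopifnot(length(region) == 2, region[1] >= 1, region[2] <= REFERENCE_LENGTH,
            region[1] <= region[2])
  pos <- seq.int(region[1], region[2])
  keep <- maps$anchored
  ids <- maps$template_id[keep]
  base_mat <- vapply(ids, function(id) {
    tc <- seq_chars(templates$sequence[match(id, templates$id)])
    tp <- maps$map[[match(id, maps$template_id)]][pos]
    b <- rep("-", length(pos))
    b[!is.na(tp)] <- tc[tp[!is.na(tp)]]
    b
  }, character(length(pos)))
  if (length(pos) == 1L) base_mat <- matrix(base_mat, nrow = 1)
  count <- function(b) rowSums(base_mat == b)
  plain <- c("A", "C", "G", "T")
  amb <- rowSums(!(base_mat %in% c(plain, "-")) |> matrix(nrow = length(pos)))
  out <- tibble::tibble(
    ecoli_pos = pos,
    A = count("A"), C = count("C"), G = count("G"), T = count("T"),
    gap = count("-"), ambiguous = amb,
    depth = length(ids))
  class(out) <- c("composition_profile", class(out))
  attr(out, "n_templates") <- nrow(templates)
  out
}

#' Primer coverage rates, overall or per taxon
#'
#' A template counts as covered iff the primer anchors on it with at most
#' `max_mismatch` IUPAC-incompatible mismatches over the full footprint
#' (default 0: the strictest reading of "covered"). The denominator excludes
#' templates whose coordinate map is unanchorable or that are truncated
#' away from the primer's intended footprint region; these are reported via
#' `n_total - n_anchorable`. `strict = TRUE` instead counts them as
#' uncovered (denominator `n_total`).
#'
#' @param templates Template tibble.
#' @param primers `primer_set` tibble (one or more rows).
#' @param maps Map tibble from [build_coordinate_maps()].
#' @param max_mismatch Mismatch tolerance (default 0).
#' @param by Grouping: `"overall"`, `"phylum"` or `"class"`.
#' @param window Terminal search window passed to [anchor_primers()].
#' @param strict Count non-anchorable templates as uncovered.
#' @param matches Optional precomputed [anchor_primers()] result to reuse.
#' @return A tibble: `primer_name`, `group_level`, `group`, `n_total`,
#'   `n_anchorable`, `n_covered`, `coverage_rate`, `max_mismatch`.
#'   `coverage_rate` is `NA` when `n_anchorable` is 0.
#' @export
coverage_rate <- function(templates, primers, maps, max_mismatch = 0L,
                          by = c("overall", "phylum", "class"),
                          window = 100L, strict = FALSE, matches = NULL) {
  by <- match.arg(by)
  if (is.null(matches)) {
    matches <- anchor_primers(templates, primers, maps, window = window)
  }
  map_ok <- setNames(maps$anchored, maps$template_id)
  df <- matches |>
    dplyr::left_join(
      templates |>
        dplyr::select("id", "taxon_phylum", "taxon_class"),
      by = c(template_id = "id")) |>
    dplyr::left_join(
      primers |>
        dplyr::select("name", "footprint_start", "footprint_end"),
      by = c(primer_name = "name"))
  spans <- vapply(seq_len(nrow(df)), function(i) {
    fp <- c(df$footprint_start[i], df$footprint_end[i])
    if (anyNA(fp)) return(df$anchored[i])
    m <- maps$map[[match(df$template_id[i], maps$template_id)]]
    any(!is.na(m[fp[1]:fp[2]]))
  }, logical(1))
  df$anchorable <- unname(map_ok[df$template_id]) & spans & df$anchored
  df$covered <- df$anchorable & df$n_mismatches <= max_mismatch
  df$group <- switch(by, overall = "overall",
                     phylum = df$taxon_phylum, class = df$taxon_class)
  out <- df |>
    dplyr::group_by(.data$primer_name, .data$group) |>
    dplyr::summarise(
      n_total = dplyr::n(),
      n_anchorable = sum(.data$anchorable),
      n_covered = sum(.data$covered),
      .groups = "drop") |>
    dplyr::mutate(
      group_level = by,
      denom = if (strict) .data$n_total else .data$n_anchorable,
      coverage_rate = ifelse(.data$denom > 0,
                             .data$n_covered / .data$denom, NA_real_),
      max_mismatch = max_mismatch) |>
    dplyr::select("primer_name", "group_level", "group", "n_total",
                  "n_anchorable", "n_covered", "coverage_rate",
                  "max_mismatch")
  out
}

#' Variable positions inside a primer footprint
#'
#' Reports every E. coli position of the primer's intended footprint whose
#' minor-allele frequency (1 minus the major-allele fraction of non-gap,
#' unambiguous calls) reaches `minor_freq_threshold`, annotated with helix
#' h2 pairing status from the registry. This is the screen that flags the
#' variable 19th nucleotide inside the Bac8f footprint and the variable
#' 1527th inside UN1541r's.
#'
#' @param primer One-row `primer_set` with a known intended footprint.
#' @param profile A [composition_profile()] spanning the footprint.
#' @param registry A [paired_site_registry()].
#' @param minor_freq_threshold In (0, 0.5]; default 0.05.
#' @return A tibble: `primer_name`, `ecoli_pos`, `major_allele`,
#'   `minor_freq`, per-base frequencies, `in_paired_site`, `partner_pos`.
#' @export
variable_sites_in_footprint <- function(primer, profile,
                                        registry = paired_site_registry(),
                                        minor_freq_threshold = 0.05) {
  stopifnot(nrow(primer) == 1)
  if (!(minor_freq_threshold > 0 && minor_freq_threshold <= 0.5)) {
    abort("minor_freq_threshold must be in (0, 0.5]")
  }
  fp <- c(primer$footprint_start, primer$footprint_end)
  if (anyNA(fp)) abort("primer has no intended footprint")
  if (fp[1] < min(profile$ecoli_pos) || fp[2] > max(profile$ecoli_pos)) {
    abort("profile does not span the primer footprint")
  }
  sub <- profile[profile$ecoli_pos >= fp[1] & profile$ecoli_pos <= fp[2], ]
  counts <- as.matrix(sub[, c("A", "C", "G", "T")])
  tot <- rowSums(counts)
  freqs <- counts / ifelse(tot > 0, tot, 1)
  major_i <- max.col(freqs, ties.method = "first")
  partner <- partner_of(registry, sub$ecoli_pos)
  out <- tibble::tibble(
    primer_name = primer$name,
    ecoli_pos = sub$ecoli_pos,
    major_allele = colnames(counts)[major_i],
    minor_freq = 1 - freqs[cbind(seq_len(nrow(sub)), major_i)],
    freq_A = freqs[, "A"], freq_C = freqs[, "C"],
    freq_G = freqs[, "G"], freq_T = freqs[, "T"],
    in_paired_site = !is.na(partner),
    partner_pos = partner)
  out[out$minor_freq >= minor_freq_threshold, ]
}
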