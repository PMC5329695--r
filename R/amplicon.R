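# Primer-templated artifact prediction. A PCR amplicon carries the primer's
# bases, not the template's, over both footprints; where primer and template
# disagree at a base-paired position this fixes a substitution into the
# product and can create a non-native pair (e.g. Bac8f(A) on a beta-like
# template turns 19C-916G into 19A-916G).

# substitutions a primer imposes over its anchored footprint
footprint_substitutions <- function(primer, match_row, tc, inv) {
  qc <- seq_chars(plus_strand_query(primer$sequence, primer$orientation))
  span <- seq.int(match_row$tpl_start, match_row$tpl_end)
  offs <- which(!MATCH_MATRIX[cbind(qc, tc[span])])
  if (length(offs) == 0) {
    return(tibble::tibble(template_pos = integer(0), ecoli_pos = integer(0),
                          template_base = character(0),
                          imposed_base = character(0),
                          ambiguous = logical(0)))
  }
  # a degenerate primer base compatible with the template imposes nothing;
  # an incompatible one imposes its lexicographically smallest expansion
  # member (flagged ambiguous when the expansion has several members)
  exp <- lapply(qc[offs], iupac_expand)
  tibble::tibble(
    template_pos = span[offs],
    ecoli_pos = inv[span[offs]],
    template_base = tc[span][offs],
    imposed_base = vapply(exp, function(e) sort(e)[1], character(1)),
    ambiguous = lengths(exp) > 1)
}

pair_state_table <- function(base_at, registry) {
  tibble::tibble(
    pos_a = vapply(registry$pairs, `[`, integer(1), 1),
    pos_b = vapply(registry$pairs, `[`, integer(1), 2)) |>
    dplyr::mutate(
      base_a = vapply(.data$pos_a, base_at, character(1)),
      base_b = vapply(.data$pos_b, base_at, character(1)),
      is_focus = .data$pos_a == registry$focus_pair[1] &
        .data$pos_b == registry$focus_pair[2],
      pair_class = ifelse(
        .data$is_focus,
        classify_pair(.data$base_a, .data$base_b),
        annotate_pair_geometry(.data$base_a, .data$base_b)))
}

#' Predict primer-templated substitutions in amplicons
#'
#' For each template, anchors the forward and reverse primers, overwrites
#' both footprints with primer-imposed bases (degenerate positions adopt the
#' template base when compatible), recomputes the registry pair states, and
#' flags the risk to the focus (19-916) pair: `artifact_defective` when the
#' pair becomes non-native defective, `artifact_functional` when it becomes
#' the non-native functional pair, `unknown_pair` when it becomes an
#' unassayed combination, `none` when unchanged.
#'
#' @param templates Template tibble.
#' @param fwd,rev One-row `primer_set` tibbles (forward / reverse primer).
#' @param maps Map tibble from [build_coordinate_maps()].
#' @param registry A [paired_site_registry()].
#' @param window Terminal search window for anchoring (default 100).
#' @return A tibble with one row per template: `amplifiable`,
#'   amplicon span in template coordinates, `amplicon_seq` (the predicted
#'   product on the plus strand), `n_substitutions`, and list-columns
#'   `substitutions`, `pairs_before`, `pairs_after`, plus focus-pair classes
#'   `focus_before`, `focus_after` and `risk_flag`.
#' @export
predict_amplicons <- function(templates, fwd, rev, maps,
                              registry = paired_site_registry(),
                              window = 100L) {
  stopifnot(nrow(fwd) == 1, nrow(rev) == 1)
  purrr::map(seq_len(nrow(templates)), function(i) {
    id <- templates$id[i]
    tc <- seq_chars(templates$sequence[i])
    m <- maps$map[[match(id, maps$template_id)]]
    inv <- invert_map(m, length(tc))
    tpl <- templates[i, ]
    mf <- anchor_one(fwd, id, templates$sequence[i], m, window)
    mr <- anchor_one(rev, id, templates$sequence[i], m, window)
    base <- tibble::tibble(template_id = id, fwd_primer = fwd$name,
                           rev_primer = rev$name)
    if (!mf$anchored || !mr$anchored || mf$tpl_start > mr$tpl_end) {
      return(dplyr::mutate(base, amplifiable = FALSE,
                           amplicon_start = NA_integer_,
                           amplicon_end = NA_integer_,
                           amplicon_seq = NA_character_,
                           n_substitutions = NA_integer_,
                           substitutions = list(NULL),
                           pairs_before = list(NULL), pairs_after = list(NULL),
                           focus_before = NA_character_,
                           focus_after = NA_character_,
                           risk_flag = "not_amplifiable"))
    }
    subs <- dplyr::bind_rows(
      footprint_substitutions(fwd, mf, tc, inv),
      footprint_substitutions(rev, mr, tc, inv))
    tc_after <- tc
    tc_after[subs$template_pos] <- subs$imposed_base
    base_at_before <- function(pos) {
      tp <- m[pos]; if (is.na(tp)) NA_character_ else tc[tp]
    }
    base_at_after <- function(pos) {
      tp <- m[pos]; if (is.na(tp)) NA_character_ else tc_after[tp]
    }
    before <- pair_state_table(base_at_before, registry)
    after <- pair_state_table(base_at_after, registry)
    fb <- before$pair_class[before$is_focus]
    fa <- after$pair_class[after$is_focus]
    risk <- if (identical(fa, fb)) "none"
    else if (fa == "nonnative_defective") "artifact_defective"
    else if (fa == "nonnative_functional") "artifact_functional"
    else if (fa == "unknown") "unknown_pair"
    else "none"
    dplyr::mutate(base, amplifiable = TRUE,
                  amplicon_start = mf$tpl_start, amplicon_end = mr$tpl_end,
                  amplicon_seq = paste(tc_after[mf$tpl_start:mr$tpl_end],
                                       collapse = ""),
                  n_substitutions = nrow(subs),
                  substitutions = list(subs),
                  pairs_before = list(before), pairs_after = list(after),
                  focus_before = fb, focus_after = fa,
                  risk_flag = risk)
  }) |> dplyr::bind_rows()
}
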