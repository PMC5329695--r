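# Central pseudoknot pairing audit. Helix h2 pairs nucleotides 17-19 with
# 918-916; the 19-916 pair is the focus because both positions are variable
# across species (gamma-like 19A-916U, beta-like 19C-916G) and position 19
# sits inside the classic Bac8f primer footprint, so a primer can template a
# non-native pair into the amplicon. The functionality labels encode only
# what growth assays established; untested combinations are "unknown",
# never extrapolated from RNA chemistry.

#' Registry of base-paired and lone variable sites
#'
#' @param pairs List of length-2 integer vectors `(pos_a, pos_b)` in E. coli
#'   numbering, `pos_a < pos_b`. Default: helix h2, 17-918, 18-917, 19-916.
#' @param lone_variable_sites Positions that are variable but unpaired
#'   (default 1527, which varies C/U but is likely not functional).
#' @param focus_pair The pair subject to functionality classification
#'   (default 19-916).
#' @return A list of class `paired_site_registry`.
#' @export
paired_site_registry <- function(pairs = list(c(17L, 918L), c(18L, 917L),
                                              c(19L, 916L)),
                                 lone_variable_sites = 1527L,
                                 focus_pair = c(19L, 916L)) {
  all_pos <- c(unlist(pairs), lone_variable_sites)
  if (anyDuplicated(all_pos)) abort("registry positions must be unique")
  for (p in pairs) {
    if (length(p) != 2 || p[1] >= p[2]) abort("each pair must be (pos_a < pos_b)")
  }
  structure(list(pairs = pairs,
                 lone_variable_sites = as.integer(lone_variable_sites),
                 focus_pair = as.integer(focus_pair)),
            class = "paired_site_registry")
}

# partner position for each queried position (NA when unpaired)
partner_of <- function(registry, positions) {
  lut <- integer(0)
  for (p in registry$pairs) {
    lut[as.character(p[1])] <- p[2]
    lut[as.character(p[2])] <- p[1]
  }
  out <- unname(lut[as.character(positions)])
  as.integer(out)
}

PAIR_RULE_TABLE <- c(
  "A|T" = "native_functional",     # gamma-like 19A-916U
  "C|G" = "native_functional",     # beta-like 19C-916G
  "A|G" = "nonnative_functional",  # primer-templated, retains function
  "C|T" = "nonnative_defective"    # primer-templated, defective
)

#' Classify a 19-916 base pair by experimentally derived functionality
#'
#' The rule table is an experimental result, not a thermodynamic model:
#' native 19A-916U and 19C-916G, and non-native 19A-916G, support growth;
#' non-native 19C-916U is defective; every untested combination is
#' `"unknown"`. Absent bases (gap or unspanned position) give `"absent"`.
#' Vectorized.
#'
#' @param base_19,base_916 Unambiguous bases (`U` accepted as `T`), or `NA`
#'   / `"-"` for absent.
#' @return Character vector over
#'   `{native_functional, nonnative_functional, nonnative_defective,
#'    absent, unknown}`.
#' @export
#' @examples
#' classify_pair("A", "T")
#' classify_pair("C", "U")
classify_pair <- function(base_19, base_916) {
  n <- max(length(base_19), length(base_916))
  a <- rep_len(as.character(base_19), n)
  b <- rep_len(as.character(base_916), n)
  vapply(seq_len(n), function(i) {
    if (is.na(a[i]) || is.na(b[i]) || a[i] == "-" || b[i] == "-") {
      return("absent")
    }
    x <- normalize_base(a[i]); y <- normalize_base(b[i])
    for (v in c(x, y)) {
      if (!v %in% c("A", "C", "G", "T")) {
        if (v %in% IUPAC_CODES) {
          abort(paste0("ambiguous base '", v, "': expand ambiguity codes ",
                       "before classification"))
        }
        abort(paste0("invalid base: '", v, "'"))
      }
    }
    v <- unname(PAIR_RULE_TABLE[paste(x, y, sep = "|")])
    if (is.na(v)) "unknown" else v
  }, character(1))
}

# geometric annotation for non-focus pairs (never functionality-classified)
annotate_pair_geometry <- function(a, b) {
  dplyr::case_when(
    is.na(a) | is.na(b) ~ "absent",
    paste0(a, b) %in% c("AT", "TA", "CG", "GC") ~ "watson_crick",
    paste0(a, b) %in% c("GT", "TG") ~ "wobble",
    TRUE ~ "mispair")
}

#' Read and classify registry pair states on templates
#'
#' Looks up the template base at each registry position through the
#' coordinate map. The focus pair (19-916 by default) is classified with
#' [classify_pair()]; other h2 pairs are annotated geometrically only
#' (watson_crick / wobble / mispair), since only 19-916 was assayed.
#' Unspanned positions yield `absent`.
#'
#' @param templates Template tibble.
#' @param maps Map tibble from [build_coordinate_maps()].
#' @param registry A [paired_site_registry()].
#' @return A tibble: `template_id`, `pos_a`, `pos_b`, `base_a`, `base_b`,
#'   `is_focus`, `pair_class` (functionality for the focus pair, geometry
#'   otherwise).
#' @export
template_pair_states <- function(templates, maps,
                                 registry = paired_site_registry()) {
  pair_df <- tibble::tibble(
    pos_a = vapply(registry$pairs, `[`, integer(1), 1),
    pos_b = vapply(registry$pairs, `[`, integer(1), 2))
  purrr::map(seq_len(nrow(templates)), function(i) {
    id <- templates$id[i]
    tc <- seq_chars(templates$sequence[i])
    m <- maps$map[[match(id, maps$template_id)]]
    base_at <- function(pos) {
      tp <- m[pos]
      ifelse(is.na(tp), NA_character_, tc[tp])
    }
    a <- vapply(pair_df$pos_a, base_at, character(1))
    b <- vapply(pair_df$pos_b, base_at, character(1))
    focus <- pair_df$pos_a == registry$focus_pair[1] &
      pair_df$pos_b == registry$focus_pair[2]
    cls <- character(nrow(pair_df))
    cls[focus] <- classify_pair(a[focus], b[focus])
    cls[!focus] <- annotate_pair_geometry(a[!focus], b[!focus])
    tibble::tibble(template_id = id, pair_df, base_a = a, base_b = b,
                   is_focus = focus, pair_class = cls)
  }) |> dplyr::bind_rows()
}

#' Audit a primer against paired and lone variable sites
#'
#' The verdict is `"unsafe"` if the primer's footprint overlaps any registry
#' pair member or lone variable site that is polymorphic at or above
#' `minor_freq_threshold` in the supplied composition profile, `"safe"`
#' otherwise. The report enumerates the offending positions together with
#' all other variable footprint positions.
#'
#' @inheritParams variable_sites_in_footprint
#' @return A list of class `primer_audit`: `primer_name`, `verdict`,
#'   `offending_positions`, `variable_sites` (the full
#'   [variable_sites_in_footprint()] report), `threshold`.
#' @export
audit_primer <- function(primer, profile, registry = paired_site_registry(),
                         minor_freq_threshold = 0.05) {
  vs <- variable_sites_in_footprint(primer, profile, registry,
                                    minor_freq_threshold)
  registry_pos <- c(unlist(registry$pairs), registry$lone_variable_sites)
  offending <- intersect(vs$ecoli_pos, registry_pos)
  structure(list(primer_name = primer$name,
                 verdict = if (length(offending) > 0) "unsafe" else "safe",
                 offending_positions = as.integer(offending),
                 variable_sites = vs,
                 threshold = minor_freq_threshold),
            class = "primer_audit")
}

#' @export
print.primer_audit <- function(x, ...) {
  cat("Primer audit:", x$primer_name, "->", toupper(x$verdict), "\n")
  if (length(x$offending_positions) > 0) {
    cat("  polymorphic paired/variable site(s) in footprint:",
        paste(x$offending_positions, collapse = ", "), "\n")
  }
  if (nrow(x$variable_sites) > 0) {
    cat("  variable footprint positions (minor freq >=", x$threshold, "):",
        paste(x$variable_sites$ecoli_pos, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname audit_primer
#' @param x A `primer_audit` object.
#' @param ... Unused.
#' @method tidy primer_audit
#' @export
tidy.primer_audit <- function(x, ...) {
  dplyr::mutate(x$variable_sites,
                offending = .data$ecoli_pos %in% x$offending_positions,
                verdict = x$verdict)
}

#' @rdname audit_primer
#' @method glance primer_audit
#' @export
glance.primer_audit <- function(x, ...) {
  tibble::tibble(primer_name = x$primer_name, verdict = x$verdict,
                 n_variable_sites = nrow(x$variable_sites),
                 n_offending = length(x$offending_positions),
                 threshold = x$threshold)
}
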