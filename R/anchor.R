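# Reference anchoring. E. coli numbering (1-1542) is the universal frame:
# every template is pairwise-aligned to the reference (semi-global, free end
# gaps on both sequences) and the alignment columns give a coordinate map.
# Primers are then placed gap-free in a terminal window, IUPAC-aware, and
# footprints are reported in both template and E. coli coordinates.

#' Build coordinate maps from templates to E. coli numbering
#'
#' Aligns each template to the reference with a semi-global (ends-free)
#' pairwise alignment and records, for every E. coli position, the matching
#' template position (`NA` at deletions and outside the aligned span).
#' This replaces a multiple alignment: the only products the downstream
#' analysis consumes are per-column composition in the reference frame and
#' the states at positions 19, 916 and 1527, all of which a pairwise map
#' provides.
#'
#' @param templates Template tibble (see [read_templates()]).
#' @param reference Reference DNA string of length 1542 (default the
#'   packaged [ecoli_like_reference()]).
#' @param min_length Templates shorter than this are flagged unanchorable
#'   without alignment (default 200).
#' @param min_identity Identity floor over the aligned span below which a
#'   map is flagged unanchorable (default 0.6).
#' @param match,mismatch,gap_open,gap_extend Alignment scoring (defaults
#'   +2 / -3 / 5 / 2; penalties positive).
#' @return A tibble with one row per template: `template_id`, `anchored`,
#'   `score`, `identity`, and a list-column `map` holding an integer vector
#'   of length 1542 (E. coli position -> template position).
#' @export
build_coordinate_maps <- function(templates, reference = ecoli_like_reference(),
                                  min_length = 200L, min_identity = 0.6,
                                  match = 2, mismatch = -3,
                                  gap_open = 5, gap_extend = 2) {
  reference <- normalize_sequence(reference, "reference")
  ref_len <- nchar(reference)
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE)
  rows <- purrr::map(seq_len(nrow(templates)), function(i) {
    seq <- templates$sequence[i]
    if (nchar(seq) < min_length) {
      return(tibble::tibble(template_id = templates$id[i], anchored = FALSE,
                            score = NA_real_, identity = NA_real_,
                            map = list(rep(NA_integer_, ref_len))))
    }
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(reference),
      subject = Biostrings::DNAString(seq),
      type = "overlap", substitutionMatrix = submat,
      gapOpening = gap_open, gapExtension = gap_extend)
    p_chars <- seq_chars(as.character(Biostrings::pattern(aln)))
    s_chars <- seq_chars(as.character(Biostrings::subject(aln)))
    map <- rep(NA_integer_, ref_len)
    ip <- Biostrings::start(Biostrings::pattern(aln)) - 1L
    is <- Biostrings::start(Biostrings::subject(aln)) - 1L
    both <- p_chars != "-" & s_chars != "-"
    ip_pos <- ip + cumsum(p_chars != "-")
    is_pos <- is + cumsum(s_chars != "-")
    map[ip_pos[both]] <- is_pos[both]
    ident <- mean(p_chars[both] == s_chars[both] |
                    p_chars[both] == "N" | s_chars[both] == "N")
    tibble::tibble(template_id = templates$id[i],
                   anchored = ident >= min_identity,
                   score = Biostrings::score(aln),
                   identity = ident,
                   map = list(map))
  })
  dplyr::bind_rows(rows)
}

#' Query a coordinate map at E. coli positions
#'
#' @param maps Map tibble from [build_coordinate_maps()].
#' @param template_id Which template.
#' @param positions Integer vector of E. coli positions (1-1542).
#' @return Integer template positions; `NA` where the template does not span
#'   the position (an absent state, not an error).
#' @export
map_positions <- function(maps, template_id, positions) {
  row <- maps[maps$template_id == template_id, ]
  if (nrow(row) != 1L) abort(paste0("no map for template '", template_id, "'"))
  row$map[[1]][positions]
}

# inverse map: template position -> ecoli position
invert_map <- function(map, template_length) {
  inv <- rep(NA_integer_, template_length)
  e <- which(!is.na(map))
  inv[map[e]] <- e
  inv
}

# Gap-free terminal placement of one primer on one template.
# Returns a one-row tibble (MatchResult).
anchor_one <- function(primer, template_id, template_seq, map, window) {
  query <- plus_strand_query(primer$sequence, primer$orientation)
  qc <- seq_chars(query)
  L <- length(qc)
  tc <- seq_chars(template_seq)
  n <- length(tc)
  empty <- tibble::tibble(
    template_id = template_id, primer_name = primer$name,
    anchored = FALSE, tpl_start = NA_integer_, tpl_end = NA_integer_,
    ecoli_start = NA_integer_, ecoli_end = NA_integer_,
    n_mismatches = NA_integer_, mismatch_ecoli = list(integer(0)),
    mismatch_tpl = list(integer(0)))
  if (n < L) return(empty)
  starts <- if (primer$orientation == "forward") {
    seq_len(min(window, n - L + 1L))
  } else {
    seq.int(max(1L, n - L + 2L - window), n - L + 1L)
  }
  if (length(starts) == 0) return(empty)
  mm <- vapply(starts, function(s) {
    sum(!MATCH_MATRIX[cbind(qc, tc[s:(s + L - 1L)])])
  }, integer(1))
  best <- starts[mm == min(mm)]
  inv <- if (is.null(map)) rep(NA_integer_, n) else invert_map(map, n)
  pick <- best[1]
  if (length(best) > 1) {
    intended <- c(primer$footprint_start, primer$footprint_end)
    hit <- vapply(best, function(s) {
      !anyNA(intended) && identical(inv[s], intended[1]) &&
        identical(inv[s + L - 1L], intended[2])
    }, logical(1))
    pick <- if (any(hit)) {
      best[hit][1]
    } else if (primer$orientation == "forward") min(best) else max(best)
  }
  mism_off <- which(!MATCH_MATRIX[cbind(qc, tc[pick:(pick + L - 1L)])])
  mism_tpl <- pick + mism_off - 1L
  tibble::tibble(
    template_id = template_id, primer_name = primer$name,
    anchored = TRUE, tpl_start = pick, tpl_end = pick + L - 1L,
    ecoli_start = inv[pick], ecoli_end = inv[pick + L - 1L],
    n_mismatches = length(mism_off),
    mismatch_ecoli = list(inv[mism_tpl]),
    mismatch_tpl = list(mism_tpl))
}

#' Anchor primers at template termini
#'
#' Finds the best gap-free placement of each primer in a terminal window of
#' each template (5' window for forward primers, 3' window for reverse
#' primers; reverse primers are matched as their reverse complement against
#' the plus strand), minimizing the IUPAC-aware mismatch count. Ties are
#' broken toward the placement whose E. coli footprint equals the primer's
#' intended footprint, then toward the terminus. Primer placement is
#' gap-free: PCR primers anneal contiguously, so indels inside a footprint
#' are not modelled.
#'
#' @param templates Template tibble.
#' @param primers A `primer_set` tibble (default [amplification_primers()]).
#' @param maps Map tibble from [build_coordinate_maps()]; optional — without
#'   it footprints are reported in template coordinates only.
#' @param window Size of the terminal search region in nt (default 100).
#' @return A tibble with one row per primer x template: template and E. coli
#'   footprint intervals, mismatch count and mismatch positions (list-column,
#'   E. coli numbering where mapped).
#' @export
anchor_primers <- function(templates, primers = amplification_primers(), maps = NULL,
                           window = 100L) {
  purrr::map(seq_len(nrow(primers)), function(p) {
    primer <- primers[p, ]
    purrr::map(seq_len(nrow(templates)), function(i) {
      map <- if (is.null(maps)) NULL else {
        maps$map[[match(templates$id[i], maps$template_id)]]
      }
      anchor_one(primer, templates$id[i], templates$sequence[i], map, window)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}
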