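# Clone-library tabulation: counts and integer percentages of clone sets by
# taxon origin and by 19-916 base-pair pattern, one summary per library
# (library = the primer set used for amplification).

PAIR_PATTERN_KEYS <- c("A-U", "A-G", "C-G", "C-U")

# display pattern for a 19/916 base combination (916 shown as RNA, T -> U)
pair_pattern <- function(base_19, base_916) {
  b19 <- normalize_base(as.character(base_19))
  b916 <- normalize_base(as.character(base_916))
  out <- paste0(b19, "-", ifelse(b916 == "T", "U", b916))
  out[is.na(b19) | is.na(b916)] <- "absent"
  out[!out %in% c(PAIR_PATTERN_KEYS, "absent")] <- "other"
  out
}

derive_states_from_sequences <- function(records, reference) {
  tpl <- tibble::tibble(id = records$id, sequence = records$sequence,
                        taxon_phylum = "", taxon_class = "",
                        has_flanks = FALSE)
  maps <- build_coordinate_maps(tpl, reference)
  focus <- c(19L, 916L)
  purrr::map(seq_len(nrow(tpl)), function(i) {
    tc <- seq_chars(tpl$sequence[i])
    tp <- maps$map[[i]][focus]
    tibble::tibble(id = tpl$id[i],
                   base_19 = ifelse(is.na(tp[1]), NA_character_, tc[tp[1]]),
                   base_916 = ifelse(is.na(tp[2]), NA_character_, tc[tp[2]]))
  }) |> dplyr::bind_rows()
}

#' Summarize clone libraries by origin and 19-916 pair pattern
#'
#' Produces per-library counts and integer percentages of clone origins
#' (taxon labels) and focus-pair patterns (A-U, A-G, C-G, C-U, plus
#' other/absent). When a record carries a sequence, its 19/916 states are
#' derived through a coordinate map against the reference; sequence-derived
#' states win over explicit `base_19`/`base_916` columns (discrepancies are
#' warned about). Percentages are rounded half-up and always recomputable
#' from the stored counts.
#'
#' @param records A tibble of clone records: `id`, `library`, `taxon_class`,
#'   and either `sequence` or explicit `base_19`/`base_916`.
#' @param reference Reference DNA string for coordinate mapping (default the
#'   packaged synthetic one).
#' @return A tibble of class `clone_summary`: `library`, `category`
#'   (`origin` / `pair`), `level`, `count`, `total`, `percentage`.
#' @export
summarize_clones <- function(records, reference = ecoli_like_reference()) {
  need <- c("id", "library", "taxon_class")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    abort(paste0("clone records missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  has_seq <- if ("sequence" %in% names(records)) !is.na(records$sequence)
  else rep(FALSE, nrow(records))
  has_states <- all(c("base_19", "base_916") %in% names(records)) &
    if (all(c("base_19", "base_916") %in% names(records))) {
      !is.na(records$base_19) & !is.na(records$base_916)
    } else rep(FALSE, nrow(records))
  bad <- !has_seq & !has_states
  if (any(bad)) {
    abort(paste0("record(s) with neither sequence nor explicit 19/916 ",
                 "states: ", paste(head(records$id[bad], 5), collapse = ", ")))
  }
  b19 <- if ("base_19" %in% names(records)) {
    normalize_base(as.character(records$base_19))
  } else rep(NA_character_, nrow(records))
  b916 <- if ("base_916" %in% names(records)) {
    normalize_base(as.character(records$base_916))
  } else rep(NA_character_, nrow(records))
  if (any(has_seq)) {
    derived <- derive_states_from_sequences(records[has_seq, ], reference)
    disagree <- has_states[has_seq] &
      (derived$base_19 != b19[has_seq] | derived$base_916 != b916[has_seq])
    if (any(disagree, na.rm = TRUE)) {
      warn(paste0("sequence-derived 19/916 states disagree with explicit ",
                  "states for: ",
                  paste(derived$id[which(disagree)], collapse = ", "),
                  " (sequence-derived states used)"))
    }
    b19[has_seq] <- derived$base_19
    b916[has_seq] <- derived$base_916
  }
  df <- tibble::tibble(library = records$library,
                       origin = records$taxon_class,
                       pattern = pair_pattern(b19, b916))
  tally <- function(d, category, level) {
    counts <- d |> dplyr::count(.data$library, level = .data[[level]])
    if (category == "pair") {
      counts <- tidyr::complete(
        counts, library = unique(d$library),
        level = union(PAIR_PATTERN_KEYS, unique(counts$level)),
        fill = list(n = 0L))
    }
    counts |> dplyr::mutate(category = category)
  }
  out <- dplyr::bind_rows(tally(df, "origin", "origin"),
                          tally(df, "pair", "pattern")) |>
    dplyr::group_by(.data$library, .data$category) |>
    dplyr::mutate(total = sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::rename(count = "n") |>
    dplyr::mutate(percentage = percent_half_up(.data$count, .data$total)) |>
    dplyr::select("library", "category", "level", "count", "total",
                  "percentage") |>
    dplyr::arrange(.data$library, .data$category, .data$level)
  class(out) <- c("clone_summary", class(out))
  out
}

# half-up integer percentage; NA (flagged) for empty totals
percent_half_up <- function(count, total) {
  ifelse(total > 0, as.integer(floor(100 * count / total + 0.5)), NA_integer_)
}

is_proteobacterial <- function(label) {
  grepl("proteobacteria", label, ignore.case = TRUE) |
    tolower(label) %in% c("alpha", "beta", "gamma", "delta", "epsilon")
}

#' Compare clone libraries side by side
#'
#' Lines up origin and pair-pattern composition across libraries and
#' computes the proteobacterial fraction of each (a label counts as
#' proteobacterial if it names the phylum or one of its classes).
#'
#' @param summaries A `clone_summary` covering at least two libraries, or a
#'   list of `clone_summary` objects to combine.
#' @return A list of class `library_comparison`: `composition` (wide tibble,
#'   one column pair per library) and `proteobacterial` (per-library totals,
#'   fraction and half-up percentage).
#' @export
compare_libraries <- function(summaries) {
  if (!inherits(summaries, "clone_summary")) {
    summaries <- dplyr::bind_rows(summaries)
  }
  libs <- unique(summaries$library)
  if (length(libs) < 2) abort("need at least two libraries to compare")
  for (l in libs) {
    if (!"origin" %in% summaries$category[summaries$library == l]) {
      abort(paste0("library '", l, "' lacks origin grouping"))
    }
  }
  composition <- summaries |>
    dplyr::select("library", "category", "level", "count", "percentage") |>
    tidyr::pivot_wider(names_from = "library",
                       values_from = c("count", "percentage"),
                       values_fill = list(count = 0L)) |>
    dplyr::arrange(.data$category, .data$level)
  proteo <- summaries |>
    dplyr::filter(.data$category == "origin") |>
    dplyr::group_by(.data$library) |>
    dplyr::summarise(
      n_total = sum(.data$count),
      n_proteobacterial = sum(.data$count[is_proteobacterial(.data$level)]),
      .groups = "drop") |>
    dplyr::mutate(
      fraction = ifelse(.data$n_total > 0,
                        .data$n_proteobacterial / .data$n_total, NA_real_),
      percentage = percent_half_up(.data$n_proteobacterial, .data$n_total))
  structure(list(composition = composition, proteobacterial = proteo),
            class = "library_comparison")
}

#' @export
print.library_comparison <- function(x, ...) {
  cat("Library comparison (", nrow(x$proteobacterial), " libraries)\n",
      sep = "")
  print(x$proteobacterial)
  invisible(x)
}

#' @rdname compare_libraries
#' @param x A `library_comparison`.
#' @param ... Unused.
#' @method tidy library_comparison
#' @export
tidy.library_comparison <- function(x, ...) x$composition

#' @rdname compare_libraries
#' @method glance library_comparison
#' @export
glance.library_comparison <- function(x, ...) x$proteobacterial

#' @rdname summarize_clones
#' @param x A `clone_summary`.
#' @param ... Unused.
#' @method glance clone_summary
#' @export
glance.clone_summary <- function(x, ...) {
  x |>
    dplyr::distinct(.data$library, .data$category, .data$total) |>
    tidyr::pivot_wider(names_from = "category", values_from = "total",
                       names_prefix = "n_")
}
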