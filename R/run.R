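# Pipeline entry point. `pa_run()` wires the stages behind named
# subcommands with a single flat config; the exec/ script is a thin shell
# wrapper over it. TSV is the universal tabular output; plots are optional
# and never load-bearing.

PA_SUBCOMMANDS <- c("simulate", "composition", "coverage", "audit-primer",
                    "pair-check", "predict-amplicons", "summarize-clones")

# write a table atomically (tempfile in the same directory, then rename)
write_tsv_atomic <- function(df, path) {
  df <- dplyr::mutate(df, dplyr::across(
    dplyr::where(is.list),
    ~ vapply(.x, function(v) paste(unlist(v), collapse = ","), character(1))))
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  path
}

resolve_primers <- function(config) {
  p <- config$primers
  if (is.null(p)) return(amplification_primers())
  if (length(p) == 1 && file.exists(p)) return(read_primers(p))
  all <- amplification_primers()
  miss <- setdiff(p, all$name)
  if (length(miss) > 0) {
    abort(paste0("unknown primer name(s): ", paste(miss, collapse = ", ")))
  }
  all[match(p, all$name), ]
}

resolve_reference <- function(config) {
  if (is.null(config$reference)) ecoli_like_reference()
  else read_reference(config$reference)
}

load_inputs <- function(config) {
  if (is.null(config$templates) || is.null(config$taxonomy)) {
    abort("config needs 'templates' (FASTA) and 'taxonomy' (TSV) paths")
  }
  templates <- read_templates(config$templates, config$taxonomy,
                              strict = !isTRUE(config$permissive))
  reference <- resolve_reference(config)
  maps <- build_coordinate_maps(templates, reference)
  list(templates = templates, reference = reference, maps = maps)
}

#' Run a pipeline stage
#'
#' A single entry point over all stages. Subcommands: `simulate` (synthetic
#' corpus to FASTA + taxonomy + ground truth), `composition` (per-position
#' composition TSV), `coverage` (per-primer coverage TSV, overall and per
#' taxon), `audit-primer` (variable-site audit + verdict), `pair-check`
#' (registry pair states per template), `predict-amplicons` (artifact
#' predictions for a primer pair), `summarize-clones` (origin- and pair-pattern library
#' summary from a clone TSV).
#'
#' @param subcommand One of the names above.
#' @param config A named list: input paths (`templates`, `taxonomy`,
#'   `reference`, `clones`), primer selection (`primers`, `fwd`, `rev`),
#'   numeric knobs (`window`, `max_mismatch`, `minor_freq`, `seed`,
#'   `region`, `n_per_class`, ...), and the output directory `out`.
#' @return Invisibly, a named list of written file paths (plus in-memory
#'   results where natural). The config is echoed into `out` for
#'   provenance.
#' @export
pa_run <- function(subcommand, config = list()) {
  if (!subcommand %in% PA_SUBCOMMANDS) {
    abort(paste0("unknown subcommand '", subcommand, "'; expected one of: ",
                 paste(PA_SUBCOMMANDS, collapse = ", ")))
  }
  out_dir <- config$out %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_echo <- file.path(out_dir, paste0(subcommand, ".config.txt"))
  writeLines(utils::capture.output(utils::str(config)), cfg_echo)
  window <- config$window %||% 100L
  outputs <- list(config_echo = cfg_echo)

  if (subcommand == "simulate") {
    cfg <- synthetic_config(
      seed = config$seed %||% 1L,
      n_per_class = config$n_per_class %||%
        c(gamma_like = 50L, beta_like = 50L, other = 0L),
      truncation_rate = config$truncation_rate %||% 0)
    gen <- generate_templates(cfg, resolve_reference(config))
    fasta <- file.path(out_dir, "templates.fasta")
    tax <- file.path(out_dir, "taxonomy.tsv")
    write_templates(gen$templates, fasta, tax)
    truth <- write_tsv_atomic(gen$truth, file.path(out_dir, "truth.tsv"))
    return(invisible(c(outputs, list(templates = fasta, taxonomy = tax,
                                     truth = truth))))
  }

  if (subcommand == "summarize-clones") {
    if (is.null(config$clones)) abort("config needs 'clones' (TSV path)")
    records <- tibble::as_tibble(
      read.delim(config$clones, stringsAsFactors = FALSE))
    summ <- summarize_clones(records, resolve_reference(config))
    path <- write_tsv_atomic(summ, file.path(out_dir, "clone_summary.tsv"))
    return(invisible(c(outputs, list(summary = path, result = summ))))
  }

  inputs <- load_inputs(config)
  primers <- resolve_primers(config)

  if (subcommand == "composition") {
    region <- config$region %||% c(1L, 60L)
    prof <- composition_profile(inputs$templates, inputs$maps, region)
    path <- write_tsv_atomic(prof, file.path(out_dir, "composition.tsv"))
    return(invisible(c(outputs, list(composition = path, result = prof))))
  }
  if (subcommand == "coverage") {
    res <- dplyr::bind_rows(lapply(c("overall", "phylum", "class"), function(b)
      coverage_rate(inputs$templates, primers, inputs$maps,
                    max_mismatch = config$max_mismatch %||% 0L,
                    by = b, window = window)))
    path <- write_tsv_atomic(res, file.path(out_dir, "coverage.tsv"))
    return(invisible(c(outputs, list(coverage = path, result = res))))
  }
  if (subcommand == "audit-primer") {
    registry <- paired_site_registry()
    audits <- lapply(seq_len(nrow(primers)), function(i) {
      fp <- c(primers$footprint_start[i], primers$footprint_end[i])
      prof <- composition_profile(inputs$templates, inputs$maps, fp)
      audit_primer(primers[i, ], prof, registry,
                   minor_freq_threshold = config$minor_freq %||% 0.05)
    })
    for (a in audits) print(a)
    report <- dplyr::bind_rows(lapply(audits, tidy))
    path <- write_tsv_atomic(report, file.path(out_dir, "primer_audit.tsv"))
    verdicts <- dplyr::bind_rows(lapply(audits, glance))
    vpath <- write_tsv_atomic(verdicts, file.path(out_dir, "verdicts.tsv"))
    return(invisible(c(outputs, list(audit = path, verdicts = vpath,
                                     result = audits))))
  }
  if (subcommand == "pair-check") {
    res <- template_pair_states(inputs$templates, inputs$maps)
    path <- write_tsv_atomic(res, file.path(out_dir, "pair_states.tsv"))
    return(invisible(c(outputs, list(pair_states = path, result = res))))
  }
  # predict-amplicons
  fwd <- get_primer(primers, config$fwd %||% "Bac1f")
  rev <- get_primer(primers, config$rev %||% "UN1542r")
  res <- predict_amplicons(inputs$templates, fwd, rev, inputs$maps,
                           window = window)
  flat <- res |>
    dplyr::mutate(substitutions = purrr::map_chr(.data$substitutions,
      function(s) if (is.null(s) || nrow(s) == 0) "" else
        paste(sprintf("%d:%s>%s", s$ecoli_pos, s$template_base,
                      s$imposed_base), collapse = ","))) |>
    dplyr::select(-"pairs_before", -"pairs_after", -"amplicon_seq")
  path <- write_tsv_atomic(flat, file.path(out_dir, "amplicon_predictions.tsv"))
  invisible(c(outputs, list(predictions = path, result = res)))
}
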