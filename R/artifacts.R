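#' Configuration of the recurrent sequencing-artifact rule
#'
#' A variant key is declared a sequencing artifact for a panel when all three
#' clauses hold: (i) every occurrence has VAF strictly below `vaf_max`
#' (a key ever seen at high VAF is plausibly real somewhere); (ii) the
#' occurrences span at least `recurrence_min` of the samples the panel
#' analyzed; (iii) the locus lies in repetitive sequence context — a
#' homopolymer run of at least `homopolymer_min_run` bases or at least
#' `triplet_min_units` tandem copies of a 3-mer, searched within
#' `context_window` bp of the position.
#'
#' @param vaf_max VAF upper bound, exclusive (default 0.05).
#' @param recurrence_min Minimum recurrent sample fraction, inclusive
#'   (default 0.30).
#' @param context_window Bases scanned on each side of the position
#'   (default 10).
#' @param homopolymer_min_run Minimum homopolymer run length (default 5).
#' @param triplet_min_units Minimum tandem 3-mer copies (default 3).
#' @return An `error_config` list.
#' @export
error_config <- function(vaf_max = 0.05, recurrence_min = 0.30,
                         context_window = 10, homopolymer_min_run = 5,
                         triplet_min_units = 3) {
  if (!(vaf_max > 0 && vaf_max < 1)) abort("vaf_max must be in (0, 1)")
  if (!(recurrence_min > 0 && recurrence_min <= 1)) {
    abort("recurrence_min must be in (0, 1]")
  }
  if (context_window < max(homopolymer_min_run, 3 * triplet_min_units)) {
    abort("context_window must be >= max(homopolymer_min_run, 3 * triplet_min_units)")
  }
  structure(list(vaf_max = vaf_max, recurrence_min = recurrence_min,
                 context_window = context_window,
                 homopolymer_min_run = homopolymer_min_run,
                 triplet_min_units = triplet_min_units),
            class = "error_config")
}

#' Repetitive-sequence context of a position
#'
#' Classifies the reference context at a position as `"homopolymer"` when a
#' single-base run of at least the configured length overlaps it,
#' `"triplet_repeat"` when at least the configured number of tandem 3-mer
#' copies overlaps it, and `"none"` otherwise. Homopolymer takes precedence.
#' The scan window is truncated at contig ends.
#'
#' @param reference Named character vector of contig sequences (or
#'   `DNAStringSet`).
#' @param chrom Contig name.
#' @param pos 1-based position (must lie on the contig).
#' @param cfg An [error_config()].
#' @return `"homopolymer"`, `"triplet_repeat"` or `"none"`.
#' @export
repeat_context <- function(reference, chrom, pos, cfg = error_config()) {
  seqs <- as_reference(reference)
  if (!chrom %in% names(seqs)) abort(sprintf("contig '%s' not in reference", chrom))
  contig_len <- nchar(seqs[[chrom]])
  if (pos < 1 || pos > contig_len) {
    abort(sprintf("position %d outside contig '%s' (length %d)", pos, chrom, contig_len))
  }
  from <- max(1L, pos - cfg$context_window)
  to <- min(contig_len, pos + cfg$context_window)
  window <- ref_fetch(seqs, chrom, from, to)
  focal <- pos - from + 1L  # position of interest within the window

  chars <- strsplit(window, "")[[1]]
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hp <- r$lengths >= cfg$homopolymer_min_run &
    starts <= focal & ends >= focal
  if (any(hp)) return("homopolymer")

  n <- length(chars)
  min_units <- cfg$triplet_min_units
  for (start in seq_len(max(0, n - 3 * min_units + 1))) {
    unit <- substr(window, start, start + 2)
    k <- 1L
    while (start + 3 * (k + 1) - 1 <= n &&
           substr(window, start + 3 * k, start + 3 * (k + 1) - 1) == unit) {
      k <- k + 1L
    }
    if (k >= min_units && start <= focal && start + 3 * k - 1 >= focal) {
      return("triplet_repeat")
    }
  }
  "none"
}

#' Detect recurrent low-VAF sequencing artifacts in one panel's raw calls
#'
#' Applies the three-clause artifact rule (see [error_config()]) to the
#' pre-filter calls of one panel — the sub-threshold calls the main
#' reporting filter would discard. Recurrence is computed over the samples
#' the panel itself analyzed by default; set `denominator = "cohort"` and
#' supply `cohort_samples` to use a study-wide denominator instead.
#'
#' @param raw_calls Unfiltered call tibble for one panel (`sample`, `chrom`,
#'   `pos`, `ref`, `alt`, `vaf`, optionally `gene`).
#' @param samples_analyzed Character vector of all samples the panel
#'   analyzed (the recurrence denominator; must be non-empty).
#' @param reference Named character vector of contig sequences.
#' @param cfg An [error_config()].
#' @param denominator `"panel"` (default) or `"cohort"`.
#' @param cohort_samples All samples in the study (required for
#'   `denominator = "cohort"`).
#' @return Tibble of artifact records sorted by recurrence (descending):
#'   `key`, `gene`, `chrom`, `pos`, `n_samples_with_call`,
#'   `n_samples_analyzed`, `recurrence`, `context_class`, `context_sequence`.
#' @export
detect_artifacts <- function(raw_calls, samples_analyzed, reference,
                             cfg = error_config(),
                             denominator = c("panel", "cohort"),
                             cohort_samples = NULL) {
  denominator <- match.arg(denominator)
  if (!length(samples_analyzed)) abort("samples_analyzed must be non-empty")
  denom_samples <- if (denominator == "panel") samples_analyzed else {
    if (is.null(cohort_samples)) abort("cohort_samples required for cohort denominator")
    cohort_samples
  }
  n_denom <- length(unique(denom_samples))

  calls <- raw_calls |>
    filter(.data$sample %in% samples_analyzed) |>
    mutate(key = variant_key(raw_calls[raw_calls$sample %in% samples_analyzed, ]))
  if (nrow(calls) == 0) return(empty_artifacts())

  per_key <- calls |>
    group_by(.data$key) |>
    summarise(chrom = .data$chrom[1], pos = .data$pos[1],
              gene = (.data$gene %||% NA_character_)[1],
              n_samples_with_call = n_distinct(.data$sample),
              all_low_vaf = all(.data$vaf < cfg$vaf_max),
              .groups = "drop") |>
    mutate(n_samples_analyzed = n_denom,
           recurrence = .data$n_samples_with_call / n_denom)

  per_key$context_class <- map_chr(seq_len(nrow(per_key)), function(i) {
    repeat_context(reference, per_key$chrom[i], per_key$pos[i], cfg)
  })
  per_key$context_sequence <- map_chr(seq_len(nrow(per_key)), function(i) {
    ref_fetch(reference, per_key$chrom[i],
              per_key$pos[i] - cfg$context_window,
              per_key$pos[i] + cfg$context_window)
  })
  per_key |>
    filter(.data$all_low_vaf,
           .data$recurrence >= cfg$recurrence_min,
           .data$context_class != "none") |>
    select(-"all_low_vaf") |>
    arrange(desc(.data$recurrence), .data$key)
}

empty_artifacts <- function() {
  tibble(key = character(), chrom = character(), pos = integer(),
         gene = character(), n_samples_with_call = integer(),
         n_samples_analyzed = integer(), recurrence = numeric(),
         context_class = character(), context_sequence = character())
}

#' Which panels flag each artifact key?
#'
#' Joins per-panel artifact lists into a key-to-panels map with a summary of
#' how many keys were flagged by exactly k panels.
#'
#' @param per_panel Named list (>= 2 entries) of [detect_artifacts()] results.
#' @return Tibble (`key`, `panels` list-column, `n_panels`) with a
#'   `summary` attribute counting keys by number of flagging panels.
#' @export
cross_panel_artifact_overlap <- function(per_panel) {
  if (length(per_panel) < 2) abort("need artifact lists from >= 2 panels")
  long <- bind_rows(imap(per_panel, ~ mutate(.x, panel = .y)))
  if (nrow(long) == 0) {
    out <- tibble(key = character(), panels = list(), n_panels = integer())
    return(structure(out, summary = tibble(n_panels = integer(), n_keys = integer())))
  }
  out <- long |>
    group_by(.data$key) |>
    summarise(panels = list(sort(unique(.data$panel))), .groups = "drop") |>
    mutate(n_panels = lengths(.data$panels)) |>
    arrange(desc(.data$n_panels), .data$key)
  structure(out, summary = count(out, .data$n_panels, name = "n_keys"))
}
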