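#' Four-state cross-panel call matrix
#'
#' A `call_matrix` tabulates clinically relevant variants (rows) against
#' panels (columns) with one of four statuses per cell, in the dialect of
#' clinical panel-comparison reports:
#' \describe{
#'   \item{C}{called — the panel reported the variant}
#'   \item{NC}{not called — sample assessed, locus in the design, variant
#'     absent from the calls (a calling failure)}
#'   \item{NI}{not included — sample assessed but the locus is outside the
#'     panel design (a design gap)}
#'   \item{ND}{not done — the sample was not assessed with this panel}
#' }
#'
#' @param rows Tibble with identifying columns (`sample`, `key`, `gene`, ...)
#'   plus one status column per panel.
#' @param panels Character vector naming the status columns.
#' @return A `call_matrix` tibble.
#' @export
as_call_matrix <- function(rows, panels) {
  rows <- as_tibble(rows)
  missing_cols <- setdiff(panels, names(rows))
  if (length(missing_cols)) {
    abort(paste0("missing panel status column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  codes <- unlist(rows[panels], use.names = FALSE)
  bad <- setdiff(unique(codes), c("C", "NC", "NI", "ND"))
  if (length(bad)) abort(paste0("unknown status code(s): ", paste(bad, collapse = ", ")))
  structure(rows, class = c("call_matrix", class(tibble())),
            panels = unname(panels))
}

#' @export
print.call_matrix <- function(x, ...) {
  cat(sprintf("<call_matrix> %d variants x %d panels (%s)\n",
              nrow(x), length(matrix_panels(x)),
              paste(matrix_panels(x), collapse = ", ")))
  NextMethod()
}

#' Panels of a call matrix
#' @param matrix A `call_matrix`.
#' @return Character vector of panel (status column) names.
#' @export
matrix_panels <- function(matrix) attr(matrix, "panels")

#' Build the four-state call matrix from calls, designs and a manifest
#'
#' The row set is the union of distinct (sample, variant) pairs over all
#' panels' calls. Each cell is then assigned by precedence: `ND` when the
#' manifest says the sample was not assessed with the panel; else `NI` when
#' the variant locus is outside the panel design; else `C` when the panel's
#' calls contain the variant; else `NC`.
#'
#' @param calls Normalized, filtered, clinically relevant calls (tibble with
#'   `sample`, `panel`, `chrom`, `pos`, and `ref`/`alt` or `hgvs_c`).
#' @param designs List of [panel_design()] objects covering every panel that
#'   appears in `calls`.
#' @param manifest Manifest tibble (`sample`, `panels` list-column), see
#'   [read_manifest()].
#' @return A [as_call_matrix()] with one row per (sample, variant).
#' @export
build_matrix <- function(calls, designs, manifest) {
  names(designs) <- map_chr(designs, panel_name)
  panels <- names(designs)
  stray <- setdiff(unique(calls$panel), panels)
  if (length(stray)) {
    abort(paste0("calls from panel(s) without a design: ",
                 paste(stray, collapse = ", ")))
  }
  manifest_panels <- setNames(manifest$panels, manifest$sample)

  calls <- mutate(calls, key = variant_key(calls))
  rows <- calls |>
    group_by(.data$sample, .data$key) |>
    summarise(gene = .data$gene[1], chrom = .data$chrom[1], pos = .data$pos[1],
              ref = .data$ref[1], alt = .data$alt[1],
              hgvs_c = (.data$hgvs_c %||% NA_character_)[1],
              .groups = "drop")
  rows$indel_len <- ifelse(!is.na(rows$ref) & !is.na(rows$alt),
                           indel_length(rows$ref, rows$alt),
                           hgvs_c_span(rows$hgvs_c))

  called <- calls |> distinct(.data$sample, .data$key, .data$panel)
  for (p in panels) {
    d <- designs[[p]]
    called_here <- called$panel == p
    called_keys <- paste(called$sample[called_here], called$key[called_here])
    assessed <- map_lgl(rows$sample, function(s) {
      p %in% (manifest_panels[[s]] %||% character())
    })
    in_design <- covers(d, rows$chrom, rows$pos,
                        ifelse(is.na(rows$ref), "N", rows$ref))
    is_called <- paste(rows$sample, rows$key) %in% called_keys
    rows[[p]] <- ifelse(!assessed, "ND",
                        ifelse(!in_design, "NI",
                               ifelse(is_called, "C", "NC")))
  }
  as_call_matrix(arrange(rows, .data$sample, .data$key), panels)
}

status_long <- function(matrix) {
  tidyr::pivot_longer(as_tibble(matrix), all_of(matrix_panels(matrix)),
                      names_to = "panel", values_to = "status")
}

#' Count discordant variants in a call matrix
#'
#' A row (variant) is discordant when at least one assessed panel failed to
#' report it — a `NC` (calling failure) or `NI` (design gap) cell; `ND` cells
#' are ignored, since a panel the sample never ran on cannot disagree. The
#' per-row cause is `"design"` when only `NI` cells occur, `"calling"` when
#' only `NC`, `"both"` otherwise.
#'
#' @param matrix A `call_matrix`.
#' @return List with `n_discordant` and `rows` (the discordant rows with a
#'   `cause` column).
#' @export
count_discordant <- function(matrix) {
  panels <- matrix_panels(matrix)
  st <- as.matrix(as_tibble(matrix)[panels])
  any_nc <- rowSums(st == "NC") > 0
  any_ni <- rowSums(st == "NI") > 0
  disc <- any_nc | any_ni
  rows <- as_tibble(matrix)[disc, , drop = FALSE]
  rows$cause <- ifelse(any_nc[disc] & any_ni[disc], "both",
                       ifelse(any_nc[disc], "calling", "design"))
  list(n_discordant = sum(disc), rows = rows)
}

#' Restrict a call matrix to a core gene set
#'
#' Keeps rows whose gene belongs to `core_genes`; statuses are untouched.
#' Idempotent, and the full gene set returns the matrix unchanged.
#'
#' @param matrix A `call_matrix`.
#' @param core_genes Non-empty character vector of gene symbols.
#' @return A `call_matrix` with the subset of rows.
#' @export
subset_core <- function(matrix, core_genes) {
  if (!length(core_genes)) {
    return(as_call_matrix(as_tibble(matrix)[0, , drop = FALSE],
                          matrix_panels(matrix)))
  }
  as_call_matrix(filter(as_tibble(matrix), .data$gene %in% core_genes),
                 matrix_panels(matrix))
}

#' Indel lengths of variants missed by calling
#'
#' Lists every `NC` cell with the variant's indel length (from normalized
#' alleles when available, else from the HGVS c. span), and summarizes the
#' lengths of missed versus called indels. Rows with unknown length are kept
#' in the table but excluded from the summary.
#'
#' @param matrix A `call_matrix` (its rows must carry `indel_len`, as built
#'   by [build_matrix()] / [table3_matrix()]).
#' @return Tibble (`sample`, `key`, `gene`, `panel`, `status`, `indel_len`)
#'   of missed cells, with a `summary` attribute comparing missed vs called
#'   indel lengths (min/median/n).
#' @export
missed_indel_lengths <- function(matrix) {
  long <- status_long(matrix)
  missed <- long |>
    filter(.data$status == "NC") |>
    select("sample", "key", "gene", "panel", "status", "indel_len")
  called_indels <- long |>
    filter(.data$status == "C", !is.na(.data$indel_len), .data$indel_len > 0) |>
    distinct(.data$key, .keep_all = TRUE)
  summarize_len <- function(x) {
    x <- x[!is.na(x)]
    tibble(n = length(x),
           min = if (length(x)) min(x) else NA_real_,
           median = if (length(x)) median(x) else NA_real_)
  }
  summary <- bind_rows(
    mutate(summarize_len(missed$indel_len), group = "missed", .before = 1),
    mutate(summarize_len(called_indels$indel_len), group = "called_indels",
           .before = 1))
  structure(missed, summary = summary)
}

#' Cross-panel VAF concordance
#'
#' Pairs the two panels' calls by sample and identical normalized variant key
#' (no fuzzy matching), restricted to the genes the two panels share, and
#' reports the squared Pearson correlation of the paired VAFs. With fewer
#' than two pairs the coefficient is undefined (`NA`), not zero.
#'
#' @param calls_a,calls_b Normalized call tibbles for the two panels.
#' @param shared_genes Genes common to both designs (defaults to the genes
#'   observed in both call sets).
#' @return A `vaf_concordance` object: `r_squared`, `n_pairs`, `panels` and
#'   the `pairs` tibble for recomputation.
#' @export
vaf_concordance <- function(calls_a, calls_b,
                            shared_genes = intersect(calls_a$gene, calls_b$gene)) {
  a <- calls_a |>
    filter(.data$gene %in% shared_genes) |>
    mutate(key = variant_key(calls_a[calls_a$gene %in% shared_genes, ]))
  b <- calls_b |>
    filter(.data$gene %in% shared_genes) |>
    mutate(key = variant_key(calls_b[calls_b$gene %in% shared_genes, ]))
  pairs <- inner_join(
    a |> distinct(.data$sample, .data$key, .keep_all = TRUE) |>
      select("sample", "key", "gene", vaf_a = "vaf"),
    b |> distinct(.data$sample, .data$key, .keep_all = TRUE) |>
      select("sample", "key", vaf_b = "vaf"),
    by = c("sample", "key"))
  r2 <- if (nrow(pairs) >= 2 && sd(pairs$vaf_a) > 0 && sd(pairs$vaf_b) > 0) {
    cor(pairs$vaf_a, pairs$vaf_b)^2
  } else NA_real_
  structure(list(r_squared = r2, n_pairs = nrow(pairs),
                 panels = c(unique(calls_a$panel)[1] %||% "A",
                            unique(calls_b$panel)[1] %||% "B"),
                 pairs = pairs),
            class = "vaf_concordance")
}

#' @export
print.vaf_concordance <- function(x, ...) {
  cat(sprintf("<vaf_concordance> %s vs %s: r^2 = %s over %d shared calls\n",
              x$panels[1], x$panels[2],
              ifelse(is.na(x$r_squared), "undefined (< 2 pairs)",
                     sprintf("%.3f", x$r_squared)),
              x$n_pairs))
  invisible(x)
}

#' Per-panel summary of called variants
#'
#' Counts `C` cells per panel and divides by the number of samples the panel
#' assessed (samples with zero relevant variants count in the denominator).
#' Panels assessing no samples are dropped with a warning.
#'
#' @param matrix A `call_matrix`.
#' @param manifest Manifest tibble (`sample`, `panels` list-column).
#' @return Tibble (`panel`, `n_called`, `n_samples_assessed`,
#'   `mean_per_sample`).
#' @export
per_panel_summary <- function(matrix, manifest) {
  panels <- matrix_panels(matrix)
  st <- as.matrix(as_tibble(matrix)[panels])
  n_called <- colSums(st == "C")
  n_assessed <- map_int(panels, function(p) {
    sum(map_lgl(manifest$panels, ~ p %in% .x))
  })
  out <- tibble(panel = panels, n_called = unname(n_called),
                n_samples_assessed = n_assessed)
  empty <- out$n_samples_assessed == 0
  if (any(empty)) {
    warn(paste0("panel(s) assessing no samples excluded: ",
                paste(out$panel[empty], collapse = ", ")))
    out <- out[!empty, , drop = FALSE]
  }
  mutate(out, mean_per_sample = .data$n_called / .data$n_samples_assessed)
}

#' Write / read a call matrix as TSV
#'
#' The on-disk dialect is the status-code table itself: identifying columns
#' followed by one `C`/`NC`/`NI`/`ND` column per panel.
#'
#' @param matrix A `call_matrix`.
#' @param path Output (input) TSV path.
#' @param panels For reading: the panel column names.
#' @return `write_call_matrix()` returns `path` invisibly;
#'   `read_call_matrix()` returns a `call_matrix`.
#' @export
write_call_matrix <- function(matrix, path) {
  readr::write_tsv(as_tibble(matrix), path)
  invisible(path)
}

#' @rdname write_call_matrix
#' @export
read_call_matrix <- function(path, panels) {
  as_call_matrix(readr::read_tsv(path, show_col_types = FALSE) |>
                   mutate(sample = as.character(.data$sample)), panels)
}
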