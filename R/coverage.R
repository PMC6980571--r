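#' Read a per-base depth table
#'
#' Three-column, tab-separated `samtools depth` layout: contig, 1-based
#' position, read depth, for one sample x panel.
#'
#' @param path Path to the TSV (no header, or a header line starting `chrom`).
#' @return Tibble (`chrom`, `pos`, `depth`) with unique positions.
#' @export
read_depth_tsv <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("^chrom\\b", first)
  track <- readr::read_tsv(path,
                           col_names = if (has_header) TRUE else c("chrom", "pos", "depth"),
                           skip = 0, show_col_types = FALSE, comment = "#")
  track <- as_tibble(track) |>
    transmute(chrom = as.character(.data$chrom),
              pos = as.integer(.data$pos),
              depth = as.numeric(.data$depth))
  validate_depth_track(track)
}

validate_depth_track <- function(track) {
  if (any(track$depth < 0, na.rm = TRUE)) abort("negative depth in track")
  if (anyDuplicated(track[c("chrom", "pos")])) abort("duplicate (chrom, pos) in depth track")
  track
}

#' Mean sequencing depth over a panel's target span
#'
#' Averages depth over every base of the merged (union) target span of each
#' gene (or each raw region), so overlapping amplicons are not
#' double-weighted. Bases absent from the track count as depth 0 — a position
#' never reported by `samtools depth` is a position with no aligned reads.
#'
#' @param track Depth tibble (`chrom`, `pos`, `depth`), see [read_depth_tsv()].
#' @param design A [panel_design()].
#' @param granularity `"gene"` (default) or `"region"`.
#' @param min_supporting_reads Supporting-read cutoff used for the
#'   limit-of-detection annotation (default 10).
#' @return A `coverage_summary` tibble with columns `unit`, `gene`,
#'   `mean_depth`, `n_bases`, `lod`; per-base depth vectors are retained in
#'   the `"per_base"` attribute (used by [flag_poor_coverage()]).
#' @export
mean_depth <- function(track, design, granularity = c("gene", "region"),
                       min_supporting_reads = 10) {
  granularity <- match.arg(granularity)
  track <- validate_depth_track(as_tibble(track))
  depth_lookup <- split(setNames(track$depth, track$pos), track$chrom)

  units <- if (granularity == "gene") {
    as_tibble(design) |>
      group_by(unit = .data$gene, .data$gene, .data$chrom) |>
      reframe(merge_intervals(start, end))
  } else {
    as_tibble(design) |>
      mutate(unit = sprintf("%s:%s:%d-%d", .data$gene, .data$chrom,
                            .data$start, .data$end)) |>
      select("unit", "gene", "chrom", "start", "end")
  }

  per_base <- list()
  rows <- units |>
    group_by(.data$unit, .data$gene) |>
    group_map(function(df, key) {
      depths <- unlist(map(seq_len(nrow(df)), function(i) {
        pos <- seq.int(df$start[i] + 1L, df$end[i])
        lk <- depth_lookup[[df$chrom[i]]]
        d <- if (is.null(lk)) rep(0, length(pos)) else unname(lk[as.character(pos)])
        d[is.na(d)] <- 0
        d
      }))
      per_base[[key$unit]] <<- depths
      tibble(unit = key$unit, gene = key$gene,
             mean_depth = mean(depths), n_bases = length(depths))
    }) |>
    bind_rows()
  if (nrow(rows) == 0) abort("design yields no coverage units")
  rows$lod <- ifelse(rows$mean_depth > 0,
                     min_supporting_reads / rows$mean_depth, NA_real_)
  structure(arrange(rows, .data$unit),
            class = c("coverage_summary", class(tibble())),
            panel = panel_name(design),
            granularity = granularity,
            min_supporting_reads = min_supporting_reads,
            per_base = per_base)
}

#' Minimum detectable variant fraction at a given depth
#'
#' The limit of detection is the smallest clone size whose expected
#' supporting-read count reaches the caller's cutoff, i.e.
#' `min_supporting_reads / mean_depth` (assuming no strand bias). At 1000x
#' with a 10-read cutoff this is 0.01.
#'
#' @param mean_depth Mean depth in reads (> 0), vectorized.
#' @param min_supporting_reads Supporting-read cutoff (>= 1), default 10.
#' @return Variant fraction in (0, 1].
#' @export
detection_limit <- function(mean_depth, min_supporting_reads = 10) {
  if (any(mean_depth <= 0)) abort("detection limit undefined: mean depth must be > 0")
  if (any(min_supporting_reads < 1)) abort("min_supporting_reads must be >= 1")
  min_supporting_reads / mean_depth
}

#' Flag genes with low or heterogeneous coverage
#'
#' A gene is flagged `"low"` when its mean depth falls below `threshold`
#' reads, and `"heterogeneous"` when the coefficient of variation of its
#' per-base depths exceeds `uniformity_cv` — the signature of amplicon
#' dropout in GC-rich single-exon genes such as CEBPA, where part of the
#' target drops to near-zero depth while the rest is well covered.
#'
#' @param summary A gene-granularity [mean_depth()] result with per-base
#'   depths retained.
#' @param threshold Low-coverage mean-depth threshold (default 1000 reads).
#' @param uniformity_cv Coefficient-of-variation cutoff (default 0.5).
#' @return Tibble (`gene`, `reason`, `value`), one row per flag.
#' @export
flag_poor_coverage <- function(summary, threshold = 1000, uniformity_cv = 0.5) {
  if (!inherits(summary, "coverage_summary") || attr(summary, "granularity") != "gene") {
    abort("flag_poor_coverage() needs a gene-granularity coverage_summary")
  }
  per_base <- attr(summary, "per_base")
  flags <- map(seq_len(nrow(summary)), function(i) {
    g <- summary$gene[i]
    d <- per_base[[summary$unit[i]]]
    out <- list()
    if (summary$mean_depth[i] < threshold) {
      out <- c(out, list(tibble(gene = g, reason = "low",
                                value = summary$mean_depth[i])))
    }
    cv <- if (mean(d) > 0) sd(d) / mean(d) else NA_real_
    if (!is.na(cv) && cv > uniformity_cv) {
      out <- c(out, list(tibble(gene = g, reason = "heterogeneous", value = cv)))
    }
    out
  })
  out <- bind_rows(unlist(flags, recursive = FALSE))
  if (nrow(out) == 0) tibble(gene = character(), reason = character(),
                             value = numeric()) else out
}

#' Genes-by-panels mean-depth matrix
#'
#' Assembles gene-granularity coverage summaries from several panels into a
#' wide matrix (one row per gene, one column per panel) suitable for a
#' coverage heatmap.
#'
#' @param summaries List of gene-granularity `coverage_summary` objects.
#' @return Tibble with a `gene` column and one mean-depth column per panel.
#' @export
coverage_matrix <- function(summaries) {
  long <- bind_rows(map(summaries, function(s) {
    tibble(panel = attr(s, "panel") %||% "panel", gene = s$gene,
           mean_depth = s$mean_depth)
  }))
  tidyr::pivot_wider(long, names_from = "panel", values_from = "mean_depth")
}
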