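#' Construct a panel design from a region table
#'
#' A panel design is the unit of comparison: a named set of genomic target
#' intervals (BED convention, 0-based half-open) annotated with the gene each
#' interval belongs to, plus the library chemistry and sequencing read length
#' that drive chemistry-dependent failure modes (amplicon GC dropout,
#' short-read long-indel loss).
#'
#' @param regions Data frame with columns `chrom`, `start`, `end`, `gene` and
#'   optionally `label` (free text such as `"exon 12"`).
#' @param name Panel identifier.
#' @param chemistry `"amplicon"` or `"hybrid_capture"`.
#' @param read_length Read length in bp.
#' @return A `panel_design`: a tibble of target regions carrying the panel
#'   metadata as attributes.
#' @examples
#' panel_design(
#'   tibble::tibble(chrom = "19", start = 33792244L, end = 33793321L,
#'                  gene = "CEBPA"),
#'   name = "toy", chemistry = "hybrid_capture", read_length = 150)
#' @export
panel_design <- function(regions, name, chemistry = c("hybrid_capture", "amplicon"),
                         read_length = 150L) {
  chemistry <- match.arg(chemistry)
  regions <- as_tibble(regions)
  required <- c("chrom", "start", "end", "gene")
  missing_cols <- setdiff(required, names(regions))
  if (length(missing_cols)) {
    abort(paste0("panel regions lack column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!"label" %in% names(regions)) regions$label <- NA_character_
  regions <- regions |>
    mutate(start = as.integer(.data$start), end = as.integer(.data$end)) |>
    select("chrom", "start", "end", "gene", "label")
  if (nrow(regions) == 0) abort("no target regions")
  if (any(!nzchar(regions$chrom)) || anyNA(regions$chrom)) abort("empty contig name in regions")
  bad <- which(!(regions$start < regions$end))
  if (length(bad)) {
    abort(sprintf("invalid region (start >= end) at row %d: %s:%d-%d",
                  bad[1], regions$chrom[bad[1]], regions$start[bad[1]], regions$end[bad[1]]))
  }
  if (anyDuplicated(regions[c("chrom", "start", "end", "gene")])) {
    abort("duplicate (chrom, start, end, gene) records in panel regions")
  }
  structure(regions,
            class = c("panel_design", class(tibble())),
            panel_name = name,
            chemistry = chemistry,
            read_length = as.integer(read_length))
}

#' @export
print.panel_design <- function(x, ...) {
  cat(sprintf("<panel_design> %s (%s, %d bp reads): %d regions, %d genes, %.3f kb\n",
              panel_name(x), panel_chemistry(x), panel_read_length(x),
              nrow(x), length(gene_set(x)), footprint_kb(x)))
  NextMethod()
}

#' Panel metadata accessors
#'
#' @param design A `panel_design`.
#' @return The panel name, chemistry tag or read length stored on the design.
#' @export
panel_name <- function(design) attr(design, "panel_name")

#' @rdname panel_name
#' @export
panel_chemistry <- function(design) attr(design, "chemistry")

#' @rdname panel_name
#' @export
panel_read_length <- function(design) attr(design, "read_length")

#' Read a panel target design from a BED file
#'
#' Accepts 4-5 column BED (chrom, start, end, gene, optional label),
#' whitespace-separated, 0-based half-open. Lines starting with `#`, `track`
#' or `browser` are ignored. Overlapping records are kept distinct (amplicons
#' legitimately overlap); merging happens only when computing footprint or
#' coverage.
#'
#' @inheritParams panel_design
#' @param path Path to the BED file.
#' @return A [panel_design()].
#' @export
read_panel_bed <- function(path, name, chemistry = c("hybrid_capture", "amplicon"),
                           read_length = 150L) {
  chemistry <- match.arg(chemistry)
  lines <- readLines(path, warn = FALSE)
  keep_idx <- which(!grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines)))
  if (!length(keep_idx)) abort(sprintf("no target regions in '%s'", path))
  rows <- lapply(keep_idx, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 4) {
      abort(sprintf("malformed BED line %d in '%s': expected >= 4 fields, got %d",
                    i, path, length(f)))
    }
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end)) {
      abort(sprintf("malformed BED line %d in '%s': non-numeric coordinates", i, path))
    }
    if (start >= end) {
      abort(sprintf("invalid region at BED line %d in '%s': start >= end", i, path))
    }
    tibble(chrom = f[1], start = start, end = end, gene = f[4],
           label = if (length(f) >= 5) paste(f[-(1:4)], collapse = " ") else NA_character_)
  })
  panel_design(bind_rows(rows), name = name, chemistry = chemistry,
               read_length = read_length)
}

#' Genes targeted by a panel design
#'
#' @param design A `panel_design`.
#' @return Character vector of distinct gene symbols (sorted).
#' @export
gene_set <- function(design) sort(unique(design$gene))

#' Physical footprint of a panel in kilobases
#'
#' Overlapping regions are merged (union) first, so the footprint counts
#' physical bases, not amplicon tiling.
#'
#' @param design A `panel_design`.
#' @return Footprint in kb.
#' @export
footprint_kb <- function(design) {
  merged_width(design$chrom, design$start, design$end) / 1000
}

#' Partition the union of panel gene sets into Venn cells
#'
#' Every gene in the union of the designs' gene sets is assigned to exactly
#' one cell according to which panels target it (the cells of the Venn
#' diagram over panels).
#'
#' @param designs List of `panel_design` objects (>= 2).
#' @return Tibble with one row per non-empty cell: `cell` (panel names joined
#'   with `+`), `panels` (list of panel names), `genes` (list of symbols) and
#'   `n_genes`. Cell counts sum to the size of the gene-set union.
#' @export
compare_gene_sets <- function(designs) {
  if (length(designs) < 2) abort("compare_gene_sets() needs at least 2 designs")
  names(designs) <- map_chr(designs, panel_name)
  sets <- map(designs, gene_set)
  universe <- sort(unique(unlist(sets)))
  membership <- map(universe, function(g) names(sets)[map_lgl(sets, ~ g %in% .x)])
  cell_id <- map_chr(membership, ~ paste(.x, collapse = "+"))
  tibble(gene = universe, cell = cell_id, panels = membership) |>
    group_by(.data$cell) |>
    summarise(panels = list(.data$panels[[1]]),
              genes = list(.data$gene),
              n_genes = n(), .groups = "drop") |>
    arrange(desc(lengths(.data$panels)), .data$cell)
}

#' Per-gene interval differences between panel designs
#'
#' Decomposes the union of all panels' target intervals for one gene into
#' elementary half-open intervals and flags each according to which panels
#' cover it: `shared_all` when every design that targets the gene covers it,
#' `exclusive_to_<panel>` when exactly one does, `partial` otherwise.
#'
#' @param designs List of `panel_design` objects.
#' @param gene Gene symbol.
#' @return Tibble (`chrom`, `start`, `end`, `panels`, `flag`), intervals
#'   disjoint within the gene and covering exactly the per-gene union. When
#'   no design targets the gene an empty tibble is returned with a warning.
#' @export
region_diff <- function(designs, gene) {
  names(designs) <- map_chr(designs, panel_name)
  per_panel <- map(designs, ~ filter(as_tibble(.x), .data$gene == !!gene))
  involved <- names(per_panel)[map_int(per_panel, nrow) > 0]
  if (!length(involved)) {
    warn(sprintf("gene '%s' is not targeted by any design", gene))
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  panels = list(), flag = character()))
  }
  all_regions <- bind_rows(per_panel[involved], .id = "panel")
  out <- all_regions |>
    group_by(.data$chrom) |>
    group_modify(function(df, key) {
      cuts <- sort(unique(c(df$start, df$end)))
      elem <- tibble(start = head(cuts, -1), end = tail(cuts, -1))
      covered_by <- map(seq_len(nrow(elem)), function(i) {
        hit <- df$start < elem$end[i] & df$end > elem$start[i]
        sort(unique(df$panel[hit]))
      })
      elem$panels <- covered_by
      elem[lengths(covered_by) > 0, ]
    }) |>
    ungroup()
  out$flag <- map_chr(out$panels, function(p) {
    if (setequal(p, involved)) "shared_all"
    else if (length(p) == 1) paste0("exclusive_to_", p)
    else "partial"
  })
  # merge adjacent elementary intervals with identical coverage
  out |>
    group_by(.data$chrom) |>
    group_modify(function(df, key) {
      df <- arrange(df, .data$start)
      grp <- cumsum(c(TRUE, map_lgl(seq_len(nrow(df))[-1], function(i) {
        !(df$start[i] == df$end[i - 1] &&
            identical(df$panels[[i]], df$panels[[i - 1]]))
      })))
      df |>
        mutate(.grp = grp) |>
        group_by(.data$.grp) |>
        summarise(start = min(.data$start), end = max(.data$end),
                  panels = list(.data$panels[[1]]), flag = .data$flag[1],
                  .groups = "drop") |>
        select(-".grp")
    }) |>
    ungroup() |>
    arrange(.data$chrom, .data$start)
}

#' Does a panel design cover a variant locus?
#'
#' A variant covers the half-open reference span `[pos-1, pos-1+nchar(ref))`
#' (VCF 1-based position converted to BED coordinates); the design covers the
#' variant iff that span intersects any target region. Intersection suffices:
#' a long deletion starting inside a region but ending outside is covered.
#'
#' @param design A `panel_design`.
#' @param chrom Contig name.
#' @param pos 1-based variant position (vectorized).
#' @param ref Reference allele string(s); defaults to a 1 bp span.
#' @return Logical vector.
#' @export
covers <- function(design, chrom, pos, ref = "N") {
  n <- max(length(chrom), length(pos), length(ref))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n); ref <- rep_len(ref, n)
  span_start <- pos - 1L
  span_end <- pos - 1L + nchar(ref)
  map_lgl(seq_len(n), function(i) {
    any(design$chrom == chrom[i] &
          design$start < span_end[i] &
          design$end > span_start[i])
  })
}
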