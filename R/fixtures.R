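# Packaged study fixtures: the 32-sample manifest with conventional-testing
# truth, the 50 clinically relevant variants with per-panel statuses, the
# 19-gene core set, a partial gene-relevance table, and reduced (partial)
# per-panel target BEDs.

pc_extdata <- function(...) {
  path <- system.file("extdata", ..., package = "panelcompare", mustWork = TRUE)
  path
}

#' Study fixtures
#'
#' Loaders for the packaged transcriptions of the study's published tables:
#' `load_table1()` (32 samples, conventional molecular testing truth),
#' `load_table3()` (50 clinically relevant variants with per-panel call
#' status), `load_manifest()` (sample, diagnosis, panels assessed),
#' `load_core_genes()` (the 19 genes shared by all four panels),
#' `load_gene_relevance()` (partial gene-level relevance annotation) and
#' `load_panel_fixtures()` (partial target designs of the four panels).
#'
#' @return Tibbles (or, for `load_core_genes`, a character vector; for
#'   `load_panel_fixtures`, a named list of [panel_design()] objects).
#' @name fixtures
NULL

#' @rdname fixtures
#' @export
load_table1 <- function() {
  readr::read_tsv(pc_extdata("table1.tsv"), show_col_types = FALSE,
                  na = "NA") |>
    mutate(sample = as.character(.data$sample),
           flt3_itd_ratio = parse_decimal(.data$flt3_itd_ratio))
}

#' @rdname fixtures
#' @export
load_table3 <- function() {
  readr::read_tsv(pc_extdata("table3.tsv"), show_col_types = FALSE) |>
    mutate(sample = as.character(.data$sample), pos = as.integer(.data$pos))
}

#' @rdname fixtures
#' @export
load_manifest <- function() {
  read_manifest(pc_extdata("manifest.tsv"))
}

#' Read a sample manifest
#'
#' TSV with columns `sample`, `diagnosis` and `panels` (comma-separated list
#' of panels the sample was assessed with).
#'
#' @param path Path to the manifest TSV.
#' @return Tibble with `panels` as a list-column.
#' @export
read_manifest <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE) |>
    mutate(sample = as.character(.data$sample),
           panels = strsplit(.data$panels, ",", fixed = TRUE))
}

#' @rdname fixtures
#' @export
load_core_genes <- function() {
  readLines(pc_extdata("core_genes.txt"))
}

#' @rdname fixtures
#' @export
load_gene_relevance <- function() {
  readr::read_tsv(pc_extdata("gene_relevance.tsv"), comment = "#",
                  show_col_types = FALSE)
}

#' @rdname fixtures
#' @export
load_panel_fixtures <- function() {
  spec <- list(
    PMP     = list(chemistry = "hybrid_capture", read_length = 251L),
    MYS     = list(chemistry = "hybrid_capture", read_length = 251L),
    SureSeq = list(chemistry = "hybrid_capture", read_length = 151L),
    TSMP    = list(chemistry = "amplicon",       read_length = 201L)
  )
  imap(spec, function(s, nm) {
    read_panel_bed(pc_extdata("panels", paste0(nm, ".partial.bed")),
                   name = nm, chemistry = s$chemistry,
                   read_length = s$read_length)
  })
}

#' Call matrix transcribed from the study's per-panel status table
#'
#' Returns the packaged 50-variant status table as a [call_matrix] (rows
#' keyed by `chrom:pos:hgvs_c` since the printed table carries no allele
#' strings), ready for [count_discordant()], [subset_core()] and friends.
#'
#' @return A `call_matrix`.
#' @export
table3_matrix <- function() {
  t3 <- load_table3()
  panels <- c("PMP", "MYS", "SureSeq", "TSMP")
  rows <- t3 |>
    mutate(key = paste(.data$chrom, .data$pos, .data$hgvs_c, sep = ":"),
           indel_len = hgvs_c_span(.data$hgvs_c)) |>
    select("sample", "key", "gene", "chrom", "pos", "hgvs_c", "indel_len",
           all_of(panels))
  as_call_matrix(rows, panels = panels)
}

#' Reconstruct per-panel call records from the packaged status table
#'
#' Expands every `C` (called) cell of the packaged 50-variant table into one
#' call record stamped with that panel, with nominal VAF/depth placeholders
#' (the printed table reports statuses, not VAFs). Used to replay the matrix
#' construction end to end against the packaged designs and manifest.
#'
#' @return Call tibble (one row per called variant x panel).
#' @export
table3_calls <- function() {
  t3 <- load_table3()
  panels <- c("PMP", "MYS", "SureSeq", "TSMP")
  long <- tidyr::pivot_longer(t3, all_of(panels), names_to = "panel",
                              values_to = "status") |>
    filter(.data$status == "C")
  long |>
    transmute(sample = .data$sample, panel = .data$panel,
              chrom = .data$chrom, pos = .data$pos,
              ref = NA_character_, alt = NA_character_,
              vaf = 0.4, depth = 1000,
              gene = .data$gene, consequence = .data$consequence,
              classification = .data$classification, hgvs_c = .data$hgvs_c)
}
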