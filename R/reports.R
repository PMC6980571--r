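# Report assembly: each run_* function ties the modules into one stage of
# the end-to-end panel comparison, writes machine-readable outputs (JSON +
# TSV) under an output directory, and returns its main result invisibly.
# A thin command-line wrapper over these functions ships in inst/cli.

write_run_log <- function(out_dir, stage, params) {
  log <- c(list(stage = stage), params)
  jsonlite::write_json(log, file.path(out_dir, paste0(stage, ".log.json")),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
}

#' Design-comparison report
#'
#' Compares panel designs: gene-set Venn partition, footprints, and per-gene
#' region differences for genes not shared identically by all panels.
#' Writes `design_partition.tsv`, `region_diff.tsv` and
#' `design_compare.json` under `out_dir`.
#'
#' @param designs List of >= 2 [panel_design()] objects.
#' @param out_dir Output directory.
#' @param diff_genes Genes to run [region_diff()] on (default: all genes not
#'   targeted by every panel, plus multi-region genes).
#' @return The partition tibble, invisibly.
#' @export
run_design_compare <- function(designs, out_dir, diff_genes = NULL) {
  if (length(designs) < 2) abort("design comparison needs >= 2 designs")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  partition <- compare_gene_sets(designs)
  footprints <- tibble(panel = map_chr(designs, panel_name),
                       chemistry = map_chr(designs, panel_chemistry),
                       read_length = map_int(designs, panel_read_length),
                       n_genes = map_int(designs, ~ length(gene_set(.x))),
                       footprint_kb = map_dbl(designs, footprint_kb))
  if (is.null(diff_genes)) {
    all_panels_cell <- partition$cell[lengths(partition$panels) == length(designs)]
    shared_everywhere <- unlist(partition$genes[partition$cell %in% all_panels_cell])
    universe <- unique(unlist(partition$genes))
    multi <- unique(unlist(map(designs, function(d) {
      names(which(table(d$gene) > 1))
    })))
    diff_genes <- sort(unique(c(setdiff(universe, shared_everywhere), multi)))
  }
  diffs <- list_rbind(map(diff_genes, function(g) {
    suppressWarnings(region_diff(designs, g)) |>
      mutate(gene = g, panels = map_chr(.data$panels, paste, collapse = ","),
             .before = 1)
  }))
  readr::write_tsv(partition |>
                     mutate(panels = map_chr(.data$panels, paste, collapse = ","),
                            genes = map_chr(.data$genes, paste, collapse = ",")),
                   file.path(out_dir, "design_partition.tsv"))
  readr::write_tsv(diffs, file.path(out_dir, "region_diff.tsv"))
  jsonlite::write_json(list(footprints = footprints,
                            n_union_genes = sum(partition$n_genes)),
                       file.path(out_dir, "design_compare.json"),
                       auto_unbox = TRUE, digits = NA)
  write_run_log(out_dir, "design_compare",
                list(panels = map_chr(designs, panel_name)))
  invisible(partition)
}

#' Coverage report
#'
#' Gene-level mean depth, limit of detection and low/heterogeneous-coverage
#' flags per panel, plus a genes x panels mean-depth matrix. Writes
#' `coverage_by_gene.tsv`, `coverage_flags.tsv` and `coverage_matrix.tsv`.
#'
#' @param tracks Named list of depth tibbles, one per panel.
#' @param designs Named list of [panel_design()] objects (names matching
#'   `tracks`).
#' @param out_dir Output directory.
#' @param min_supporting_reads,threshold,uniformity_cv See [mean_depth()] and
#'   [flag_poor_coverage()].
#' @return Named list of `coverage_summary` objects, invisibly.
#' @export
run_coverage <- function(tracks, designs, out_dir, min_supporting_reads = 10,
                         threshold = 1000, uniformity_cv = 0.5) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summaries <- imap(tracks, function(track, p) {
    mean_depth(track, designs[[p]], granularity = "gene",
               min_supporting_reads = min_supporting_reads)
  })
  long <- bind_rows(imap(summaries, ~ mutate(as_tibble(.x), panel = .y,
                                             .before = 1)))
  flags <- bind_rows(imap(summaries, function(s, p) {
    mutate(flag_poor_coverage(s, threshold = threshold,
                              uniformity_cv = uniformity_cv),
           panel = p, .before = 1)
  }))
  readr::write_tsv(long, file.path(out_dir, "coverage_by_gene.tsv"))
  readr::write_tsv(flags, file.path(out_dir, "coverage_flags.tsv"))
  readr::write_tsv(coverage_matrix(summaries),
                   file.path(out_dir, "coverage_matrix.tsv"))
  write_run_log(out_dir, "coverage",
                list(min_supporting_reads = min_supporting_reads,
                     threshold = threshold, uniformity_cv = uniformity_cv))
  invisible(summaries)
}

#' Concordance report
#'
#' Builds the four-state call matrix from clinically relevant calls, counts
#' discordance with causes, subsets to the core gene set, tabulates missed
#' indel lengths, summarizes per-panel call counts, and computes pairwise
#' VAF concordance over each panel pair's shared genes. Writes
#' `call_matrix.tsv`, `discordant.tsv`, `missed_indels.tsv`,
#' `per_panel.tsv`, `vaf_r2.tsv` and `concordance.json`.
#'
#' @param calls Normalized, filtered, clinically relevant calls (may be
#'   empty: the report then contains zeros).
#' @param designs Named list of [panel_design()] objects.
#' @param manifest Manifest tibble.
#' @param core_genes Core gene set for the subset analysis.
#' @param out_dir Output directory.
#' @return List with `matrix`, `discordant`, `core`, `missed`, `per_panel`,
#'   `vaf_r2`, invisibly.
#' @export
run_concordance <- function(calls, designs, manifest, core_genes, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  panels <- map_chr(designs, panel_name)
  if (nrow(calls) == 0) {
    empty <- as_call_matrix(
      tibble(sample = character(), key = character(), gene = character(),
             chrom = character(), pos = integer(), ref = character(),
             alt = character(), hgvs_c = character(), indel_len = integer(),
             !!!setNames(rep(list(character()), length(panels)), panels)),
      panels)
    mat <- empty
  } else {
    mat <- build_matrix(calls, designs, manifest)
  }
  disc <- count_discordant(mat)
  core <- subset_core(mat, core_genes)
  core_disc <- count_discordant(core)
  missed <- missed_indel_lengths(mat)
  pps <- suppressWarnings(per_panel_summary(mat, manifest))
  r2 <- list_rbind(map(utils::combn(panels, 2, simplify = FALSE), function(pr) {
    shared <- intersect(gene_set(designs[[pr[1]]]), gene_set(designs[[pr[2]]]))
    vc <- vaf_concordance(filter(calls, .data$panel == pr[1]),
                          filter(calls, .data$panel == pr[2]),
                          shared_genes = shared)
    tibble(panel_a = pr[1], panel_b = pr[2], n_shared_genes = length(shared),
           n_pairs = vc$n_pairs, r_squared = vc$r_squared)
  }))
  write_call_matrix(mat, file.path(out_dir, "call_matrix.tsv"))
  readr::write_tsv(disc$rows, file.path(out_dir, "discordant.tsv"))
  readr::write_tsv(missed, file.path(out_dir, "missed_indels.tsv"))
  readr::write_tsv(pps, file.path(out_dir, "per_panel.tsv"))
  readr::write_tsv(r2, file.path(out_dir, "vaf_r2.tsv"))
  jsonlite::write_json(
    list(n_relevant = nrow(mat), n_discordant = disc$n_discordant,
         n_core = nrow(core), n_core_discordant = core_disc$n_discordant,
         missed_indel_summary = attr(missed, "summary")),
    file.path(out_dir, "concordance.json"), auto_unbox = TRUE, digits = NA)
  write_run_log(out_dir, "concordance",
                list(panels = unname(panels), n_core_genes = length(core_genes)))
  invisible(list(matrix = mat, discordant = disc, core = core,
                 missed = missed, per_panel = pps, vaf_r2 = r2))
}

#' Artifact report
#'
#' Runs the recurrent-artifact detector on each panel's raw (pre-filter)
#' calls and summarizes cross-panel overlap. Writes `artifacts.tsv` and
#' `artifact_overlap.tsv`.
#'
#' @param raw_calls Combined raw call tibble (with `panel` column).
#' @param manifest Manifest tibble.
#' @param reference Named character vector of contig sequences.
#' @param cfg An [error_config()].
#' @param out_dir Output directory.
#' @return Named list of per-panel artifact tibbles, invisibly.
#' @export
run_artifacts <- function(raw_calls, manifest, reference,
                          cfg = error_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  panels <- sort(unique(raw_calls$panel))
  per_panel <- setNames(map(panels, function(p) {
    analyzed <- manifest$sample[map_lgl(manifest$panels, ~ p %in% .x)]
    detect_artifacts(filter(raw_calls, .data$panel == p), analyzed, reference,
                     cfg)
  }), panels)
  long <- bind_rows(imap(per_panel, ~ mutate(.x, panel = .y, .before = 1)))
  readr::write_tsv(long, file.path(out_dir, "artifacts.tsv"))
  if (length(per_panel) >= 2) {
    overlap <- cross_panel_artifact_overlap(per_panel)
    readr::write_tsv(mutate(overlap,
                            panels = map_chr(.data$panels, paste, collapse = ",")),
                     file.path(out_dir, "artifact_overlap.tsv"))
  }
  write_run_log(out_dir, "artifacts",
                list(vaf_max = cfg$vaf_max, recurrence_min = cfg$recurrence_min,
                     context_window = cfg$context_window,
                     homopolymer_min_run = cfg$homopolymer_min_run,
                     triplet_min_units = cfg$triplet_min_units))
  invisible(per_panel)
}

#' Generate and write a synthetic cohort
#'
#' @param cfg A [cohort_config()].
#' @param out_dir Output directory for the cohort files.
#' @return The cohort object, invisibly.
#' @export
run_simulate <- function(cfg, out_dir) {
  cohort <- generate_cohort(cfg)
  write_cohort(cohort, out_dir)
  write_run_log(out_dir, "simulate", list(seed = cfg$seed,
                                          n_samples = cfg$n_samples))
  invisible(cohort)
}

#' Replay the packaged study fixtures through the pipeline
#'
#' Reconstructs the four-state matrix from the packaged 50-variant status
#' table, the partial panel designs and the 32-sample manifest, and reports
#' the headline quantities of the comparison: total clinically relevant
#' variants, discordant rows with causes, the core-gene subset, missed-indel
#' lengths, the core-gene intersection of the four designs, and the
#' conventional-testing consistency checks (cohort composition and FLT3-ITD
#' ratio classes). Writes `replay.json` when `out_dir` is given.
#'
#' @param out_dir Optional output directory.
#' @return List of replay results.
#' @export
run_replay_fixtures <- function(out_dir = NULL) {
  designs <- load_panel_fixtures()
  manifest <- load_manifest()
  core <- load_core_genes()
  t1 <- load_table1()

  mat_direct <- table3_matrix()
  mat_rebuilt <- build_matrix(table3_calls(), designs, manifest)
  disc <- count_discordant(mat_direct)
  core_mat <- subset_core(mat_direct, core)
  core_disc <- count_discordant(core_mat)
  missed <- missed_indel_lengths(mat_direct)
  pps <- per_panel_summary(mat_direct, manifest)
  core_intersection <- Reduce(intersect, map(designs, gene_set))

  ratio_known <- !is.na(t1$flt3_itd_ratio)
  derived_class <- flt3_itd_class(t1$flt3_itd_ratio[ratio_known])
  res <- list(
    n_relevant = nrow(mat_direct),
    n_discordant = disc$n_discordant,
    discordant_causes = as.list(table(disc$rows$cause)),
    n_core = nrow(core_mat),
    n_core_discordant = core_disc$n_discordant,
    n_missed_cells = nrow(missed),
    missed_lengths = missed$indel_len,
    min_missed_length = suppressWarnings(min(missed$indel_len, na.rm = TRUE)),
    core_intersection = core_intersection,
    n_core_intersection = length(core_intersection),
    matrix_rebuild_consistent = identical(
      as.data.frame(arrange(as_tibble(mat_direct), .data$sample, .data$key)[
        , c("sample", "key", matrix_panels(mat_direct))]),
      as.data.frame(arrange(as_tibble(mat_rebuilt), .data$sample, .data$key)[
        , c("sample", "key", matrix_panels(mat_rebuilt))])),
    n_samples = nrow(t1),
    n_aml = sum(t1$diagnosis == "AML"),
    flt3_ratio_class_match = all(derived_class ==
                                   t1$flt3_itd_class[ratio_known]),
    per_panel = pps)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(res, file.path(out_dir, "replay.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    write_run_log(out_dir, "replay_fixtures", list())
  }
  res
}
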