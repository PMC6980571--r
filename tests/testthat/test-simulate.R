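small_cfg <- function(seed, ...) {
  cohort_config(seed = seed, n_samples = 8, variants_per_sample = 2, ...)
}

test_that("the generator is deterministic in the seed", {
  a <- generate_cohort(small_cfg(101))
  b <- generate_cohort(small_cfg(101))
  expect_identical(a[setdiff(names(a), "cfg")], b[setdiff(names(b), "cfg")])
  c2 <- generate_cohort(small_cfg(102))
  expect_false(identical(a$truth, c2$truth))
  # written trees are byte-identical for the same seed
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(a, d1); write_cohort(b, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE),
                     info = f)
  }
})

test_that("with all failure modes off, observed calls are truth within design", {
  cfg <- small_cfg(111,
                   long_indel_miss_length = c(PanelA = Inf, PanelB = Inf,
                                              PanelC = Inf, PanelD = Inf),
                   gc_dropout_gene = NULL,
                   intronic_per_sample = 0,
                   artifact_spec = list())
  co <- generate_cohort(cfg)
  em <- expected_matrix(co)
  st <- as.matrix(tibble::as_tibble(em)[matrix_panels(em)])
  expect_false(any(st == "NC"))
  expect_equal(count_discordant(em)$n_discordant,
               sum(rowSums(st == "NI") > 0))
  # observed calls = truth restricted to each panel's design and manifest
  for (p in matrix_panels(em)) {
    obs <- co$calls[co$calls$panel == p, ]
    expected_c <- co$truth[co$truth[[paste0("status_", p)]] == "C", ]
    expect_setequal(paste(obs$sample, variant_key(obs)),
                    paste(expected_c$sample, expected_c$key))
  }
})

test_that("a long indel above the panel threshold is dropped only there", {
  # all four panels share the same two genes, so design never interferes:
  # every 36 bp indel is in scope for every assessed panel
  genes <- c("ASXL1", "CALR")
  panels <- list(
    list(name = "PanelA", chemistry = "hybrid_capture", read_length = 251L,
         genes = genes),
    list(name = "PanelB", chemistry = "hybrid_capture", read_length = 251L,
         genes = genes),
    list(name = "PanelC", chemistry = "hybrid_capture", read_length = 151L,
         genes = genes),
    list(name = "PanelD", chemistry = "amplicon", read_length = 201L,
         genes = genes))
  cfg <- cohort_config(seed = 121, n_samples = 4, variants_per_sample = 1,
                       panels = panels,
                       type_mix = c(snv = 0, short_indel = 0, long_indel = 1),
                       long_indel_range = c(36, 36),
                       classification_mix = c(pathogenic = 1,
                                              likely_pathogenic = 0, vus = 0),
                       gc_dropout_gene = NULL,
                       intronic_per_sample = 0, artifact_spec = list())
  co <- generate_cohort(cfg)
  em <- expected_matrix(co)
  # the 36 bp indels exceed PanelC's 35 bp limit wherever PanelC assessed
  # the sample; the other panels call them all
  pc <- em$PanelC
  expect_true(all(pc %in% c("NC", "ND")))
  expect_true(any(pc == "NC"))
  expect_true(all(em$PanelA == "C"))
  expect_true(all(em$PanelB %in% c("C", "ND")))
  expect_true(all(em$PanelD %in% c("C", "ND")))
  pm <- pipeline_matrix(co)
  expect_identical(as.data.frame(pm), as.data.frame(em))
})

test_that("probabilistic dropout hits within binomial bounds", {
  # one larger cohort gives a stable denominator for the binomial check
  cfg <- cohort_config(seed = 3001, n_samples = 40, variants_per_sample = 4,
                       type_mix = c(snv = 0, short_indel = 0, long_indel = 1),
                       dropout_prob = 0.5,
                       intronic_per_sample = 0, artifact_spec = list())
  co <- generate_cohort(cfg)
  st <- co$truth$status_PanelC
  eligible <- st %in% c("NC", "C")
  p_hat <- sum(st[eligible] == "NC") / sum(eligible)
  se <- sqrt(0.5 * 0.5 / sum(eligible))
  expect_gt(p_hat, 0.5 - 3 * se)
  expect_lt(p_hat, 0.5 + 3 * se)
})

test_that("end-to-end pipeline equals the expected matrix over many seeds", {
  for (s in 1:30) {
    cfg <- cohort_config(seed = 5000 + s,
                         n_samples = sample(4:12, 1),
                         variants_per_sample = 2)
    co <- generate_cohort(cfg)
    expect_identical(as.data.frame(pipeline_matrix(co)),
                     as.data.frame(expected_matrix(co)),
                     info = paste("seed", cfg$seed))
  }
})

test_that("written cohorts replay identically through the file readers", {
  co <- generate_cohort(small_cfg(131))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  ref <- read_reference_fasta(file.path(dir, "reference.fa"))
  expect_identical(ref, co$reference)
  manifest <- read_manifest(file.path(dir, "manifest.tsv"))
  expect_equal(manifest$sample, co$manifest$sample)
  expect_identical(manifest$panels, co$manifest$panels)
  calls <- dplyr::bind_rows(lapply(names(co$designs), function(p) {
    read_cohort_calls(dir, p)
  }))
  expect_equal(nrow(calls), nrow(co$calls))
  kept <- apply_filters(normalize_calls(calls, ref))$kept
  rel <- is_clinically_relevant(kept$classification)
  designs <- lapply(names(co$designs), function(p) {
    read_panel_bed(file.path(dir, paste0(p, ".bed")), name = p,
                   chemistry = panel_chemistry(co$designs[[p]]),
                   read_length = panel_read_length(co$designs[[p]]))
  })
  m <- build_matrix(kept[!is.na(rel) & rel, ], designs, manifest)
  expect_identical(as.data.frame(m), as.data.frame(expected_matrix(co)))
})

test_that("VAF concordance is perfect at zero noise and decays with noise", {
  sds <- c(0, 0.02, 0.06)
  r2 <- vapply(sds, function(s) {
    cfg <- cohort_config(seed = 141, n_samples = 24, variants_per_sample = 3,
                         vaf_noise_sd = c(PanelA = 0, PanelB = 0,
                                          PanelC = s, PanelD = 0),
                         intronic_per_sample = 0, artifact_spec = list())
    co <- generate_cohort(cfg)
    calls <- co$calls
    vc <- vaf_concordance(calls[calls$panel == "PanelA", ],
                          calls[calls$panel == "PanelC", ])
    vc$r_squared
  }, numeric(1))
  expect_equal(r2[1], 1.0)
  expect_true(all(diff(r2) < 0))
})

test_that("compare_gene_sets recovers the generator's panel overlap spec", {
  cfg <- small_cfg(151)
  co <- generate_cohort(cfg)
  part <- compare_gene_sets(co$designs)
  spec_genes <- lapply(cfg$panels, `[[`, "genes")
  names(spec_genes) <- vapply(cfg$panels, `[[`, character(1), "name")
  # every cell's genes are exactly those with that panel membership in the spec
  for (i in seq_len(nrow(part))) {
    member <- part$panels[[i]]
    expected <- Reduce(intersect, spec_genes[member])
    for (other in setdiff(names(spec_genes), member)) {
      expected <- setdiff(expected, spec_genes[[other]])
    }
    expect_setequal(part$genes[[i]], expected)
  }
})

test_that("injected artifacts are recovered exactly, including cross-panel overlap", {
  co <- generate_cohort(small_cfg(161))
  per_panel <- lapply(names(co$designs), function(p) {
    analyzed <- co$manifest$sample[
      vapply(co$manifest$panels, function(x) p %in% x, logical(1))]
    detect_artifacts(co$calls[co$calls$panel == p, ], analyzed, co$reference)
  })
  names(per_panel) <- names(co$designs)
  truth_by_panel <- split(variant_key(co$artifact_truth), co$artifact_truth$panel)
  for (p in names(per_panel)) {
    expect_setequal(per_panel[[p]]$key, unique(truth_by_panel[[p]] %||% character()))
  }
  ov <- cross_panel_artifact_overlap(per_panel)
  injected_multi <- names(which(table(unique(co$artifact_truth[c("panel", "chrom", "pos")])$chrom) > 1))
  multi_keys <- ov$key[ov$n_panels > 1]
  expect_setequal(sub(":.*", "", multi_keys), injected_multi)
})
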