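test_that("error_config validates its thresholds", {
  expect_error(error_config(vaf_max = 0), "vaf_max")
  expect_error(error_config(recurrence_min = 0), "recurrence_min")
  expect_error(error_config(context_window = 4), "context_window")
})

test_that("repeat context classifies constructed motifs", {
  ref <- c(c1 = paste0("GGTACGTACG", "GCAAAAAAT", "ACGTACGTAC"))
  # position on an A inside the 6-run
  expect_equal(repeat_context(ref, "c1", 14), "homopolymer")
  ref2 <- c(c1 = paste0("GGTACGTTAC", "TCAGCAGCAGT", "GATCGATCGA"))
  expect_equal(repeat_context(ref2, "c1", 15), "triplet_repeat")
  # plain sequence is none
  ref3 <- c(c1 = "GACTGACTTGCATGCAGTCAGT")
  expect_equal(repeat_context(ref3, "c1", 10), "none")
  # homopolymer takes precedence over a triplet overlapping the same spot
  ref4 <- c(c1 = paste0("TTT", strrep("AAA", 4), "GGT"))
  expect_equal(repeat_context(ref4, "c1", 6), "homopolymer")
  expect_error(repeat_context(ref3, "c1", 999), "outside contig")
})

test_that("repeat context agrees with a brute-force scanner (property)", {
  withr::with_seed(51, {
    for (rep in 1:40) {
      ref <- random_reference(60)
      # occasionally plant a motif so both classes get exercised
      if (rep %% 3 == 0) {
        s <- strsplit(ref[[1]], "")[[1]]
        at <- sample(10:40, 1)
        s[at:(at + 5)] <- "T"
        ref <- setNames(paste(s, collapse = ""), names(ref))
      }
      if (rep %% 5 == 0) {
        s <- strsplit(ref[[1]], "")[[1]]
        at <- sample(10:35, 1)
        s[at:(at + 8)] <- rep(c("G", "A", "T"), 3)
        ref <- setNames(paste(s, collapse = ""), names(ref))
      }
      for (pos in sample(3:58, 12)) {
        expect_equal(repeat_context(ref, "c1", pos),
                     brute_repeat_context(ref, "c1", pos),
                     info = sprintf("%s pos %d", ref[[1]], pos))
      }
    }
  })
})

test_that("artifact detection applies all three clauses", {
  ref <- c(c1 = paste0(strrep("GCAT", 5), "CAAAAAAG", strrep("TGCA", 5)))
  hp_pos <- 23L  # inside the A run
  plain_pos <- 5L
  samples <- paste0("S", 1:15)
  mk <- function(pos, vafs, samp) tibble::tibble(
    sample = samp, panel = "P", chrom = "c1", pos = pos,
    ref = "A", alt = "G", vaf = vafs, depth = 1000, gene = "G1",
    consequence = "missense", classification = "unclassified",
    hgvs_c = NA_character_)
  # recurrent low-VAF in homopolymer: flagged
  recurrent <- mk(hp_pos, rep(0.02, 6), paste0("S", 1:6))
  out <- detect_artifacts(recurrent, samples, ref)
  expect_equal(nrow(out), 1)
  expect_equal(out$recurrence, 0.4)
  expect_equal(out$context_class, "homopolymer")
  # insufficient recurrence: not flagged
  rare <- mk(hp_pos, rep(0.02, 2), paste0("S", 1:2))
  expect_equal(nrow(detect_artifacts(rare, samples, ref)), 0)
  # recurrent but non-repetitive context: not flagged
  plain <- mk(plain_pos, rep(0.02, 8), paste0("S", 1:8))
  expect_equal(nrow(detect_artifacts(plain, samples, ref)), 0)
  # one high-VAF occurrence disqualifies the key
  mixed <- dplyr::bind_rows(mk(hp_pos, rep(0.02, 6), paste0("S", 1:6)),
                            mk(hp_pos, 0.30, "S7"))
  expect_equal(nrow(detect_artifacts(mixed, samples, ref)), 0)
  expect_error(detect_artifacts(recurrent, character(0), ref), "non-empty")
})

test_that("artifact detection equals the brute-force three-clause filter (property)", {
  withr::with_seed(61, {
    n_sets <- 120
    for (rep in seq_len(n_sets)) {
      ref <- random_reference(80)
      # plant one homopolymer so some sets have qualifying context
      s <- strsplit(ref[[1]], "")[[1]]
      at <- sample(15:60, 1)
      s[at:(at + sample(4:7, 1))] <- sample(c("A", "C", "G", "T"), 1)
      ref <- setNames(paste(s, collapse = ""), "c1")
      samples <- paste0("S", 1:8)
      n_keys <- sample(2:5, 1)
      calls <- dplyr::bind_rows(lapply(seq_len(n_keys), function(k) {
        pos <- sample(5:75, 1)
        n_obs <- sample(1:8, 1)
        tibble::tibble(
          sample = sample(samples, n_obs), panel = "P", chrom = "c1",
          pos = pos, ref = substr(ref[[1]], pos, pos),
          alt = "N", vaf = runif(n_obs, 0.001, 0.12),
          depth = 500, gene = "G", consequence = "missense",
          classification = "unclassified", hgvs_c = NA_character_)
      }))
      got <- sort(detect_artifacts(calls, samples, ref)$key)
      want <- brute_artifacts(calls, samples, ref)
      expect_equal(got, want, info = paste("set", rep))
    }
  })
})

test_that("lowering thresholds never removes a flagged artifact (monotonicity)", {
  withr::with_seed(71, {
    ref <- random_reference(80)
    s <- strsplit(ref[[1]], "")[[1]]; s[30:36] <- "A"
    ref <- setNames(paste(s, collapse = ""), "c1")
    samples <- paste0("S", 1:10)
    calls <- dplyr::bind_rows(lapply(1:6, function(k) {
      pos <- sample(10:70, 1); n_obs <- sample(2:9, 1)
      tibble::tibble(sample = sample(samples, n_obs), panel = "P",
                     chrom = "c1", pos = pos,
                     ref = substr(ref[[1]], pos, pos), alt = "N",
                     vaf = runif(n_obs, 0.005, 0.045), depth = 500,
                     gene = "G", consequence = "missense",
                     classification = "unclassified", hgvs_c = NA_character_)
    }))
    base <- detect_artifacts(calls, samples, ref,
                             error_config(recurrence_min = 0.4,
                                          homopolymer_min_run = 6))$key
    looser_rec <- detect_artifacts(calls, samples, ref,
                                   error_config(recurrence_min = 0.2,
                                                homopolymer_min_run = 6))$key
    looser_run <- detect_artifacts(calls, samples, ref,
                                   error_config(recurrence_min = 0.4,
                                                homopolymer_min_run = 5))$key
    expect_true(all(base %in% looser_rec))
    expect_true(all(base %in% looser_run))
  })
})

test_that("cross-panel overlap maps keys to flagging panels", {
  a <- tibble::tibble(key = c("k1", "k2"), chrom = "c", pos = 1:2,
                      gene = "G", n_samples_with_call = 3L,
                      n_samples_analyzed = 10L, recurrence = 0.3,
                      context_class = "homopolymer", context_sequence = "AAAAA")
  b <- dplyr::mutate(a[1, ], key = "k1")
  ov <- cross_panel_artifact_overlap(list(A = a, B = b))
  expect_equal(ov$panels[ov$key == "k1"][[1]], c("A", "B"))
  expect_equal(ov$n_panels[ov$key == "k2"], 1)
  s <- attr(ov, "summary")
  expect_equal(s$n_keys[s$n_panels == 2], 1)
  # disjoint lists: everything at k = 1
  ov2 <- cross_panel_artifact_overlap(list(A = a[1, ], B = dplyr::mutate(a[2, ])))
  expect_true(all(ov2$n_panels == 1))
  expect_error(cross_panel_artifact_overlap(list(A = a)), ">= 2")
})

test_that("artifacts never survive the main reporting filter", {
  co <- generate_cohort(cohort_config(seed = 81, n_samples = 8))
  kept <- apply_filters(normalize_calls(co$calls, co$reference))$kept
  artifact_keys <- unique(variant_key(co$artifact_truth))
  expect_false(any(variant_key(kept) %in% artifact_keys))
})
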