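#' Configuration of a synthetic panel-comparison cohort
#'
#' Defines every condition of a simulated multi-panel study: cohort size and
#' diagnosis mix, the panels with their chemistries, read lengths and gene
#' subsets, the per-sample truth-variant spectrum (SNVs, short and long
#' indels), the deterministic failure modes (long-indel dropout above a
#' per-panel length threshold, GC dropout of one gene on amplicon panels),
#' per-panel VAF noise, and injected recurrent low-VAF artifacts in planted
#' repeat context. The defaults emulate the study conditions: 32 bone-marrow
#' samples (17 AML, 7 MPN, 6 MDS, 2 CMML) across three hybridization-capture
#' panels and one amplicon panel, with the short-read capture panel dropping
#' indels longer than 35 bp and the amplicon panel failing on the GC-rich
#' single-exon gene.
#'
#' @param seed Integer seed; the single source of randomness.
#' @param n_samples Number of samples (default 32).
#' @param diagnosis_mix Named proportions over diagnoses (must sum to 1).
#' @param panels List of panel specs `list(name, chemistry, read_length,
#'   genes)`.
#' @param variants_per_sample Truth variants per sample (default 3).
#' @param type_mix Named proportions of truth-variant types `snv`,
#'   `short_indel`, `long_indel` (must sum to 1).
#' @param short_indel_range,long_indel_range Length ranges (bp) for the two
#'   indel classes.
#' @param long_indel_miss_length Named per-panel length threshold L: indels
#'   longer than L bp are deterministically not called by that panel
#'   (`Inf` disables).
#' @param dropout_prob Optional probabilistic long-indel dropout: when
#'   non-`NULL`, a long indel above threshold is missed with this
#'   probability instead of deterministically.
#' @param gc_dropout_gene Gene whose variants amplicon panels miss
#'   (`NULL` disables).
#' @param vaf_noise_sd Named per-panel standard deviation of observed-VAF
#'   noise.
#' @param vaf_floor Lower clamp for observed VAFs of true calls (default
#'   0.06): assay noise models dispersion, not sensitivity — dropout is
#'   modeled explicitly.
#' @param mean_depth Named per-panel mean sequencing depth.
#' @param classification_mix Named proportions of truth classifications.
#' @param intronic_per_sample Accompanying intronic calls per sample (removed
#'   by the consequence filter; default 1).
#' @param artifact_spec List of artifact injections `list(gene, context
#'   ("homopolymer"/"triplet"), vaf_range, sample_fraction, panels)`.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(seed,
                          n_samples = 32,
                          diagnosis_mix = c(AML = 17, MPN = 7, MDS = 6, CMML = 2) / 32,
                          panels = default_panel_spec(),
                          variants_per_sample = 3,
                          type_mix = c(snv = 0.6, short_indel = 0.25, long_indel = 0.15),
                          short_indel_range = c(1, 10),
                          long_indel_range = c(36, 60),
                          long_indel_miss_length = c(PanelA = Inf, PanelB = Inf,
                                                     PanelC = 35, PanelD = Inf),
                          dropout_prob = NULL,
                          gc_dropout_gene = "CEBPA",
                          vaf_noise_sd = c(PanelA = 0.01, PanelB = 0.01,
                                           PanelC = 0.02, PanelD = 0.06),
                          vaf_floor = 0.06,
                          mean_depth = c(PanelA = 2500, PanelB = 2500,
                                         PanelC = 1200, PanelD = 2000),
                          classification_mix = c(pathogenic = 0.4,
                                                 likely_pathogenic = 0.3,
                                                 vus = 0.3),
                          intronic_per_sample = 1,
                          artifact_spec = default_artifact_spec()) {
  stopifnot(abs(sum(diagnosis_mix) - 1) < 1e-8,
            abs(sum(type_mix) - 1) < 1e-8,
            abs(sum(classification_mix) - 1) < 1e-8)
  panel_names <- map_chr(panels, "name")
  for (arg in list(long_indel_miss_length, vaf_noise_sd, mean_depth)) {
    if (!all(panel_names %in% names(arg))) {
      abort("per-panel parameters must name every panel")
    }
  }
  if (any(long_indel_miss_length <= 0)) abort("long-indel threshold L must be > 0")
  structure(list(seed = as.integer(seed), n_samples = n_samples,
                 diagnosis_mix = diagnosis_mix, panels = panels,
                 variants_per_sample = variants_per_sample, type_mix = type_mix,
                 short_indel_range = short_indel_range,
                 long_indel_range = long_indel_range,
                 long_indel_miss_length = long_indel_miss_length,
                 dropout_prob = dropout_prob,
                 gc_dropout_gene = gc_dropout_gene,
                 vaf_noise_sd = vaf_noise_sd, vaf_floor = vaf_floor,
                 mean_depth = mean_depth,
                 classification_mix = classification_mix,
                 intronic_per_sample = intronic_per_sample,
                 artifact_spec = artifact_spec),
            class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_panel_spec <- function() {
  shared <- c("ASXL1", "CALR", "CEBPA", "DNMT3A", "FLT3", "NPM1")
  list(
    list(name = "PanelA", chemistry = "hybrid_capture", read_length = 251L,
         genes = c(shared, "GATA2", "SH2B3", "SF3B1", "SRSF2")),
    list(name = "PanelB", chemistry = "hybrid_capture", read_length = 251L,
         genes = c(shared, "SF3B1", "SRSF2")),
    list(name = "PanelC", chemistry = "hybrid_capture", read_length = 151L,
         genes = shared),
    list(name = "PanelD", chemistry = "amplicon", read_length = 201L,
         genes = c(shared, "GATA2", "SF3B1"))
  )
}

#' @rdname cohort_config
#' @export
default_artifact_spec <- function() {
  list(
    list(gene = "ASXL1", context = "homopolymer", vaf_range = c(0.01, 0.045),
         sample_fraction = 0.4, panels = c("PanelA", "PanelB", "PanelC", "PanelD")),
    list(gene = "CALR", context = "triplet", vaf_range = c(0.01, 0.04),
         sample_fraction = 0.35, panels = "PanelD")
  )
}

# fixed layout of each synthetic contig (one contig per gene)
contig_len <- 3000L
target_span <- c(500L, 2500L)     # BED half-open target per gene per panel
hp_start <- 1501L; hp_len <- 8L   # planted A-homopolymer
tr_start <- 2001L; tr_units <- 5L # planted CAG triplet repeat
variant_span <- c(600L, 1400L)    # truth variants avoid planted repeats

#' Generate a synthetic multi-panel cohort
#'
#' Draws a complete study from a [cohort_config()]: a synthetic reference
#' (one 3 kb contig per gene with a planted homopolymer and triplet repeat at
#' recorded coordinates), per-panel target designs, a sample manifest, truth
#' variants with per-panel expected statuses derivable from the config alone,
#' observed per-panel calls with the configured failure modes and noise
#' applied, injected artifacts, and one depth track per panel. The same seed
#' reproduces the cohort exactly.
#'
#' @param cfg A [cohort_config()].
#' @return A `synthetic_cohort` list: `cfg`, `reference`, `designs`,
#'   `manifest`, `truth`, `calls`, `artifact_truth`, `depth_tracks`,
#'   `repeat_coords`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  withr::with_seed(cfg$seed, generate_cohort_impl(cfg))
}

generate_cohort_impl <- function(cfg) {
  panel_names <- map_chr(cfg$panels, "name")
  genes <- sort(unique(unlist(map(cfg$panels, "genes"))))

  # reference: random contig per gene with planted repeats
  reference <- setNames(map_chr(genes, function(g) {
    s <- sample(c("A", "C", "G", "T"), contig_len, replace = TRUE)
    # break accidental long runs outside planted regions
    s <- break_runs(s)
    s[seq(hp_start, hp_start + hp_len - 1)] <- "A"
    s[seq(tr_start, tr_start + 3 * tr_units - 1)] <-
      rep(c("C", "A", "G"), tr_units)
    paste(s, collapse = "")
  }), genes)
  repeat_coords <- tibble(
    gene = rep(genes, each = 2),
    context = rep(c("homopolymer", "triplet"), length(genes)),
    start = rep(c(hp_start, tr_start), length(genes)),
    end = rep(c(hp_start + hp_len - 1L, tr_start + 3L * tr_units - 1L),
              length(genes)))

  designs <- map(cfg$panels, function(p) {
    panel_design(tibble(chrom = p$genes, start = target_span[1],
                        end = target_span[2], gene = p$genes,
                        label = "target"),
                 name = p$name, chemistry = p$chemistry,
                 read_length = p$read_length)
  })
  names(designs) <- panel_names

  samples <- sprintf("S%02d", seq_len(cfg$n_samples))
  diagnosis <- sample(names(cfg$diagnosis_mix), cfg$n_samples, replace = TRUE,
                      prob = cfg$diagnosis_mix)
  manifest <- tibble(sample = samples, diagnosis = diagnosis,
                     panels = assessment_scheme(samples, panel_names))

  chemistry <- setNames(map_chr(cfg$panels, "chemistry"), panel_names)
  panel_genes <- setNames(map(cfg$panels, "genes"), panel_names)

  # truth variants
  truth <- list_rbind(map(seq_along(samples), function(si) {
    list_rbind(map(seq_len(cfg$variants_per_sample), function(vi) {
      type <- sample(names(cfg$type_mix), 1, prob = cfg$type_mix)
      gene <- sample(genes, 1)
      pos <- sample(seq(variant_span[1], variant_span[2]), 1)
      len <- switch(type,
        snv = 0L,
        short_indel = sample_range(cfg$short_indel_range),
        long_indel = sample_range(cfg$long_indel_range))
      al <- make_alleles(reference, gene, pos, type, len)
      consequence <- if (type == "snv") {
        sample(c("missense", "nonsense"), 1, prob = c(0.8, 0.2))
      } else if (len %% 3 == 0) "inframe" else "frameshift"
      tibble(sample = samples[si], gene = gene, chrom = gene,
             pos = al$pos, ref = al$ref, alt = al$alt, type = type,
             length = len,
             vaf = runif(1, 0.10, 0.60),
             consequence = consequence,
             classification = sample(names(cfg$classification_mix), 1,
                                     prob = cfg$classification_mix),
             hgvs_c = NA_character_)
    }))
  }))
  # store truth in canonical normalized representation so keys match the
  # pipeline's post-normalization keys exactly
  truth <- normalize_calls(truth, reference)
  truth$key <- variant_key(truth)
  # drop colliding duplicate keys within a sample (vanishingly rare)
  truth <- distinct(truth, .data$sample, .data$key, .keep_all = TRUE)

  # expected status per panel, from config alone
  for (p in panel_names) {
    assessed <- map_lgl(truth$sample, function(s) {
      p %in% manifest$panels[[match(s, manifest$sample)]]
    })
    in_design <- truth$gene %in% panel_genes[[p]]
    missed_long <- truth$type == "long_indel" &
      truth$length > cfg$long_indel_miss_length[[p]]
    if (!is.null(cfg$dropout_prob)) {
      missed_long <- missed_long & runif(nrow(truth)) < cfg$dropout_prob
    }
    missed_gc <- !is.null(cfg$gc_dropout_gene) &&
      chemistry[[p]] == "amplicon"
    missed_gc <- if (missed_gc) truth$gene == cfg$gc_dropout_gene else FALSE
    truth[[paste0("status_", p)]] <- ifelse(!assessed, "ND",
                                     ifelse(!in_design, "NI",
                                     ifelse(missed_long | missed_gc, "NC", "C")))
  }

  # observed calls: truth restricted to design/manifest minus dropouts,
  # VAF perturbed per panel
  calls <- list_rbind(map(panel_names, function(p) {
    st <- truth[[paste0("status_", p)]]
    obs <- truth[st == "C", , drop = FALSE]
    if (nrow(obs) == 0) return(empty_calls())
    noisy <- obs$vaf + rnorm(nrow(obs), 0, cfg$vaf_noise_sd[[p]])
    tibble(sample = obs$sample, panel = p, chrom = obs$chrom, pos = obs$pos,
           ref = obs$ref, alt = obs$alt,
           vaf = pmin(pmax(noisy, cfg$vaf_floor), 0.999),
           depth = pmax(cfg$mean_depth[[p]] %/% 10,
                        round(rnorm(nrow(obs), cfg$mean_depth[[p]],
                                    0.1 * cfg$mean_depth[[p]]))),
           gene = obs$gene, consequence = obs$consequence,
           classification = obs$classification, hgvs_c = NA_character_)
  }))

  # accompanying intronic calls (filtered out by consequence)
  if (cfg$intronic_per_sample > 0) {
    intronic <- list_rbind(map(panel_names, function(p) {
      assessed <- manifest$sample[map_lgl(manifest$panels, ~ p %in% .x)]
      if (!length(assessed)) return(empty_calls())
      list_rbind(map(assessed, function(s) {
        g <- sample(panel_genes[[p]], cfg$intronic_per_sample, replace = TRUE)
        pos <- sample(seq(variant_span[1], variant_span[2]),
                      cfg$intronic_per_sample)
        ref <- map_chr(seq_along(g), ~ ref_fetch(reference, g[.x], pos[.x], pos[.x]))
        tibble(sample = s, panel = p, chrom = g, pos = pos, ref = ref,
               alt = map_chr(ref, other_base),
               vaf = runif(cfg$intronic_per_sample, 0.1, 0.5),
               depth = round(cfg$mean_depth[[p]]),
               gene = g, consequence = "intronic",
               classification = "vus", hgvs_c = NA_character_)
      }))
    }))
    calls <- bind_rows(calls, intronic)
  }

  # injected artifacts at planted repeat loci
  artifact_truth <- list_rbind(map(cfg$artifact_spec, function(a) {
    pos <- if (a$context == "homopolymer") hp_start + 2L else tr_start + 4L
    ref <- ref_fetch(reference, a$gene, pos, pos)
    alt <- other_base(ref)
    list_rbind(map(intersect(a$panels, panel_names), function(p) {
      assessed <- manifest$sample[map_lgl(manifest$panels, ~ p %in% .x)]
      if (!length(assessed)) return(NULL)
      n_hit <- ceiling(a$sample_fraction * length(assessed))
      hit <- sample(assessed, n_hit)
      tibble(sample = hit, panel = p, gene = a$gene, chrom = a$gene,
             pos = pos, ref = ref, alt = alt,
             vaf = runif(n_hit, a$vaf_range[1], a$vaf_range[2]),
             context = a$context,
             expected_recurrence = n_hit / length(assessed))
    }))
  }))
  if (nrow(artifact_truth) > 0) {
    artifact_calls <- artifact_truth |>
      transmute(.data$sample, .data$panel, .data$chrom, .data$pos,
                .data$ref, .data$alt, .data$vaf,
                depth = round(unname(cfg$mean_depth[.data$panel])),
                gene = .data$gene, consequence = "missense",
                classification = "unclassified", hgvs_c = NA_character_)
    calls <- bind_rows(calls, artifact_calls)
  }

  # one representative depth track per panel
  depth_tracks <- map(panel_names, function(p) {
    list_rbind(map(panel_genes[[p]], function(g) {
      pos <- seq(target_span[1] + 1L, target_span[2])
      m <- cfg$mean_depth[[p]]
      d <- pmax(0, round(rnorm(length(pos), m, 0.08 * m)))
      if (!is.null(cfg$gc_dropout_gene) && g == cfg$gc_dropout_gene &&
          chemistry[[p]] == "amplicon") {
        # GC dropout: half the target collapses to near-zero depth
        lo <- seq_along(pos) > length(pos) / 2
        d[lo] <- pmax(0, round(rnorm(sum(lo), 25, 10)))
      }
      tibble(chrom = g, pos = pos, depth = d)
    }))
  })
  names(depth_tracks) <- panel_names

  structure(list(cfg = cfg, reference = reference, designs = designs,
                 manifest = manifest, truth = truth, calls = calls,
                 artifact_truth = artifact_truth,
                 depth_tracks = depth_tracks,
                 repeat_coords = repeat_coords),
            class = "synthetic_cohort")
}

# panel assessment mirrors the study shape: the first panel runs every
# sample; the second runs the first ~47%, the third the first half, the
# fourth sample 1 plus the second half
assessment_scheme <- function(samples, panel_names) {
  n <- length(samples)
  idx <- list(seq_len(n),
              seq_len(max(1, round(0.47 * n))),
              seq_len(max(1, round(0.50 * n))),
              sort(unique(c(1L, seq(round(0.50 * n) + 1L, n)))))
  map(seq_len(n), function(i) {
    panel_names[map_lgl(seq_along(panel_names), function(k) {
      i %in% idx[[min(k, length(idx))]]
    })]
  })
}

break_runs <- function(chars) {
  r <- rle(chars)
  long <- which(r$lengths >= 4)
  if (!length(long)) return(chars)
  ends <- cumsum(r$lengths)
  for (i in long) {
    p <- ends[i]  # replace the run's last base
    chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
  }
  chars
}

other_base <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]

# draw one integer from an inclusive range (safe for degenerate ranges)
sample_range <- function(range) {
  v <- seq.int(range[1], range[2])
  if (length(v) == 1) v else sample(v, 1)
}

# build normalized ref/alt strings for a truth variant
make_alleles <- function(reference, gene, pos, type, len) {
  base_at <- function(p) ref_fetch(reference, gene, p, p)
  if (type == "snv") {
    ref <- base_at(pos)
    return(list(pos = pos, ref = ref, alt = other_base(ref)))
  }
  ins <- runif(1) < 0.5
  if (ins) {
    ref <- base_at(pos)
    insert <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                    collapse = "")
    list(pos = pos, ref = ref, alt = paste0(ref, insert))
  } else {
    ref <- ref_fetch(reference, gene, pos, pos + len)
    list(pos = pos, ref = ref, alt = substr(ref, 1, 1))
  }
}

#' Expected call matrix of a synthetic cohort
#'
#' The oracle for end-to-end pipeline checks: the call matrix over the
#' cohort's clinically relevant truth variants with the per-panel statuses
#' recorded at generation time (derivable from the config alone).
#'
#' @param cohort A [generate_cohort()] result.
#' @return A [as_call_matrix()].
#' @export
expected_matrix <- function(cohort) {
  panel_names <- map_chr(cohort$cfg$panels, "name")
  relevant <- cohort$truth[is_clinically_relevant(cohort$truth$classification), ]
  rows <- relevant |>
    transmute(.data$sample, .data$key, .data$gene, .data$chrom, .data$pos,
              .data$ref, .data$alt, hgvs_c = NA_character_,
              indel_len = indel_length(.data$ref, .data$alt))
  for (p in panel_names) rows[[p]] <- relevant[[paste0("status_", p)]]
  as_call_matrix(arrange(rows, .data$sample, .data$key), panel_names)
}

#' Run the analysis pipeline on a synthetic cohort in memory
#'
#' Normalizes the cohort's observed calls against its reference, applies the
#' reporting filter, keeps clinically relevant calls, and builds the
#' four-state matrix — the exact path [expected_matrix()] predicts.
#'
#' @param cohort A [generate_cohort()] result.
#' @param cfg_filter A [filter_config()].
#' @return A `call_matrix`.
#' @export
pipeline_matrix <- function(cohort, cfg_filter = filter_config()) {
  calls <- normalize_calls(cohort$calls, cohort$reference)
  kept <- apply_filters(calls, cfg_filter)$kept
  rel <- is_clinically_relevant(kept$classification)
  relevant <- kept[!is.na(rel) & rel, , drop = FALSE]
  build_matrix(relevant, cohort$designs, cohort$manifest)
}

#' Write a synthetic cohort to standard file formats
#'
#' Emits the reference FASTA, per-panel BEDs, the manifest TSV, one VCF per
#' sample x panel (under `vcf/<panel>/<sample>.vcf`), one depth TSV per
#' panel, and the truth bookkeeping as JSON. All files are deterministic
#' functions of the cohort object; the seed is embedded in file headers.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cohort$cfg$seed

  fasta <- file.path(dir, "reference.fa")
  writeLines(unlist(map(names(cohort$reference), function(g) {
    c(paste0(">", g, " synthetic seed=", seed),
      strsplit(cohort$reference[[g]], sprintf("(?<=.{%d})", 70L),
               perl = TRUE)[[1]])
  })), fasta)

  for (p in names(cohort$designs)) {
    d <- cohort$designs[[p]]
    writeLines(c(sprintf("# synthetic panel design %s seed=%d", p, seed),
                 sprintf("%s\t%d\t%d\t%s\t%s", d$chrom, d$start, d$end,
                         d$gene, d$label)),
               file.path(dir, paste0(p, ".bed")))
  }

  manifest_out <- cohort$manifest |>
    mutate(panels = map_chr(.data$panels, paste, collapse = ","))
  readr::write_tsv(manifest_out, file.path(dir, "manifest.tsv"))

  vcf_dir <- file.path(dir, "vcf")
  for (p in names(cohort$designs)) {
    pdir <- file.path(vcf_dir, p)
    dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
    assessed <- cohort$manifest$sample[
      map_lgl(cohort$manifest$panels, ~ p %in% .x)]
    for (s in assessed) {
      calls <- filter(cohort$calls, .data$panel == p, .data$sample == s)
      write_vcf(calls, cohort$reference, s,
                file.path(pdir, paste0(s, ".vcf")), seed = seed)
    }
  }

  for (p in names(cohort$depth_tracks)) {
    readr::write_tsv(cohort$depth_tracks[[p]],
                     file.path(dir, paste0(p, ".depth.tsv")),
                     col_names = FALSE)
  }

  truth_out <- cohort$truth
  jsonlite::write_json(list(seed = seed, truth = truth_out,
                            artifact_truth = cohort$artifact_truth,
                            repeat_coords = cohort$repeat_coords),
                       file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}

# minimal deterministic single-sample VCF writer
write_vcf <- function(calls, reference, sample, path, seed = NA) {
  calls <- arrange(calls, .data$chrom, .data$pos, .data$alt)
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=panelcompare synthetic cohort (seed=%s)", seed),
    sprintf("##contig=<ID=%s,length=%d>", names(reference),
            nchar(reference)),
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    '##INFO=<ID=CSQ,Number=1,Type=String,Description="Coding consequence">',
    '##INFO=<ID=CLASS,Number=1,Type=String,Description="Clinical classification">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AF,Number=A,Type=Float,Description="Variant allele frequency">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample))
  body <- if (nrow(calls)) {
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tGENE=%s;CSQ=%s;CLASS=%s\tGT:AF:DP\t0/1:%.6f:%d",
            calls$chrom, calls$pos, calls$ref, calls$alt, calls$gene,
            calls$consequence, calls$classification, calls$vaf,
            as.integer(calls$depth))
  } else character()
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read all of a panel's per-sample VCFs from a written cohort
#'
#' @param dir Cohort directory written by [write_cohort()].
#' @param panel Panel name.
#' @return Combined call tibble for the panel.
#' @export
read_cohort_calls <- function(dir, panel) {
  pdir <- file.path(dir, "vcf", panel)
  files <- list.files(pdir, pattern = "\\.vcf$", full.names = TRUE)
  list_rbind(map(files, function(f) {
    read_vcf_calls(f, sample = sub("\\.vcf$", "", basename(f)), panel = panel)
  }))
}
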