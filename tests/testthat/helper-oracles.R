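# Independent brute-force oracles and toy-object builders used across tests.

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_design <- function(regions, name = "toy", chemistry = "hybrid_capture",
                       read_length = 150L) {
  panel_design(tibble::as_tibble(regions), name = name, chemistry = chemistry,
               read_length = read_length)
}

# apply a VCF-style edit (1-based pos, ref -> alt) to a sequence
apply_edit <- function(seq, pos, ref, alt) {
  stopifnot(substr(seq, pos, pos + nchar(ref) - 1) == ref)
  paste0(substr(seq, 1, pos - 1), alt,
         substr(seq, pos + nchar(ref), nchar(seq)))
}

# exhaustive normalization oracle: among all (pos, ref, alt) representations
# that produce the same edited haplotype, pick the most parsimonious
# (smallest total allele length), breaking ties by leftmost position
brute_normalize <- function(seq, pos, ref, alt) {
  hap <- apply_edit(seq, pos, ref, alt)
  n <- nchar(seq); m <- nchar(hap)
  best <- NULL
  for (p2 in seq_len(n)) {
    for (rl in 0:(nchar(ref) + nchar(alt) + 4)) {
      if (p2 + rl - 1 > n) next
      al <- rl + m - n
      if (al < 0 || p2 + al - 1 > m) next
      r2 <- substr(seq, p2, p2 + rl - 1)
      a2 <- substr(hap, p2, p2 + al - 1)
      if (rl == 0 || al == 0) next        # VCF alleles are non-empty
      if (r2 == a2 && rl == al) next      # no-op
      ok <- substr(seq, 1, p2 - 1) == substr(hap, 1, p2 - 1) &&
        substr(seq, p2 + rl, n) == substr(hap, p2 + al, m)
      if (!ok) next
      if (r2 == a2) next
      cand <- list(pos = p2, ref = r2, alt = a2,
                   score = c(rl + al, p2))
      if (is.null(best) ||
          cand$score[1] < best$score[1] ||
          (cand$score[1] == best$score[1] && cand$score[2] < best$score[2])) {
        best <- cand
      }
    }
  }
  best[c("pos", "ref", "alt")]
}

# brute-force per-base coverage test for covers()
brute_covers <- function(design, chrom, pos, ref = "N") {
  span <- seq(pos, pos + nchar(ref) - 1)      # 1-based bases of the variant
  any(vapply(span, function(b) {
    any(design$chrom == chrom & design$start < b & b <= design$end)
  }, logical(1)))
}

# brute-force mean depth over the merged target span of one gene
brute_gene_mean_depth <- function(track, design, gene) {
  regions <- design[design$gene == gene, ]
  bases <- unique(unlist(lapply(seq_len(nrow(regions)), function(i) {
    paste(regions$chrom[i], seq(regions$start[i] + 1, regions$end[i]))
  })))
  depth_of <- function(b) {
    parts <- strsplit(b, " ")[[1]]
    hit <- track$depth[track$chrom == parts[1] & track$pos == as.integer(parts[2])]
    if (length(hit)) hit else 0
  }
  mean(vapply(bases, depth_of, numeric(1)))
}

# brute-force repetitive-context scan, written independently of the
# implementation: examine every substring of the +-window context
brute_repeat_context <- function(reference, chrom, pos, cfg = error_config()) {
  seq <- reference[[chrom]]
  from <- max(1, pos - cfg$context_window)
  to <- min(nchar(seq), pos + cfg$context_window)
  win <- substr(seq, from, to)
  focal <- pos - from + 1
  n <- nchar(win)
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (j - i + 1 < cfg$homopolymer_min_run) next
      sub <- substr(win, i, j)
      if (length(unique(strsplit(sub, "")[[1]])) == 1 &&
          i <= focal && focal <= j) {
        return("homopolymer")
      }
    }
  }
  for (i in seq_len(n)) {
    k_max <- floor((n - i + 1) / 3)
    if (k_max < cfg$triplet_min_units) next
    for (k in cfg$triplet_min_units:k_max) {
      j <- i + 3 * k - 1
      sub <- substr(win, i, j)
      unit <- substr(sub, 1, 3)
      if (sub == strrep(unit, k) && i <= focal && focal <= j) {
        return("triplet_repeat")
      }
    }
  }
  "none"
}

# brute-force three-clause artifact filter
brute_artifacts <- function(raw_calls, samples_analyzed, reference,
                            cfg = error_config()) {
  calls <- raw_calls[raw_calls$sample %in% samples_analyzed, ]
  keys <- unique(paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":"))
  flagged <- character()
  for (k in keys) {
    idx <- paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":") == k
    sub <- calls[idx, ]
    c1 <- all(sub$vaf < cfg$vaf_max)
    c2 <- length(unique(sub$sample)) / length(unique(samples_analyzed)) >=
      cfg$recurrence_min
    c3 <- brute_repeat_context(reference, sub$chrom[1], sub$pos[1], cfg) != "none"
    if (c1 && c2 && c3) flagged <- c(flagged, k)
  }
  sort(flagged)
}

# random toy reference with occasional planted repeat motifs
random_reference <- function(len = 120, contig = "c1") {
  s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  setNames(paste(s, collapse = ""), contig)
}
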