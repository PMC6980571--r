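#' Filtering thresholds for variant calls
#'
#' The reporting filter applied to every panel's raw calls: keep variants with
#' VAF of at least `vaf_min` (default 5%) and depth of at least `depth_min`
#' (default 100 reads) whose consequence is not in `excluded_consequences`
#' (intronic, intergenic and splice-region calls are review noise for a
#' coding-panel comparison). Both numeric bounds are inclusive: "minimum X"
#' includes X.
#'
#' @param vaf_min Minimum variant allele frequency, in (0, 1).
#' @param depth_min Minimum read depth (>= 1).
#' @param excluded_consequences Consequence classes removed outright.
#' @return A `filter_config` list.
#' @export
filter_config <- function(vaf_min = 0.05, depth_min = 100,
                          excluded_consequences = c("intronic", "intergenic",
                                                    "splice_region")) {
  if (!(vaf_min > 0 && vaf_min < 1)) abort("vaf_min must be in (0, 1)")
  if (depth_min < 1) abort("depth_min must be >= 1")
  structure(list(vaf_min = vaf_min, depth_min = depth_min,
                 excluded_consequences = excluded_consequences),
            class = "filter_config")
}

#' Read variant calls from a VCF file
#'
#' Produces one call per ALT allele (multiallelic records are decomposed).
#' VAF is taken from the sample's `AF` FORMAT field when present, otherwise
#' derived from allelic depths as `AD[alt] / sum(AD)`; records offering
#' neither are skipped with a warning (different upstream callers emit
#' different fields). Depth comes from `DP`, falling back to `sum(AD)`.
#' Annotation (gene, consequence, classification, HGVS) is read from the
#' INFO fields `GENE`, `CSQ`, `CLASS`, `HGVSC` when present.
#'
#' @param path Path to a VCF 4.x file (single-sample).
#' @param sample Sample identifier to stamp on the calls.
#' @param panel Panel name to stamp on the calls.
#' @return Tibble of calls: `sample`, `panel`, `chrom`, `pos`, `ref`, `alt`,
#'   `vaf`, `depth`, `gene`, `consequence`, `classification`, `hgvs_c`.
#' @export
read_vcf_calls <- function(path, sample, panel) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) return(empty_calls(sample, panel))
  gt <- vcf@gt
  fmt_field <- function(field) {
    if (is.null(gt) || ncol(gt) < 2) return(rep(NA_character_, nrow(fix)))
    unname(vcfR::extract.gt(vcf, element = field, as.numeric = FALSE)[, 1])
  }
  af_raw <- fmt_field("AF")
  dp_raw <- fmt_field("DP")
  ad_raw <- fmt_field("AD")
  info_field <- function(key) {
    m <- regmatches(fix$INFO, regexec(paste0("(?:^|;)", key, "=([^;]*)"), fix$INFO))
    map_chr(m, ~ if (length(.x) == 2) .x[2] else NA_character_)
  }
  gene <- info_field("GENE"); csq <- info_field("CSQ")
  cls <- info_field("CLASS"); hgvs <- info_field("HGVSC")

  n_skipped <- 0L
  rows <- map(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    afs <- if (!is.na(af_raw[i])) suppressWarnings(
      as.numeric(strsplit(af_raw[i], ",", fixed = TRUE)[[1]])) else NULL
    ads <- if (!is.na(ad_raw[i])) suppressWarnings(
      as.numeric(strsplit(ad_raw[i], ",", fixed = TRUE)[[1]])) else NULL
    dp <- if (!is.na(dp_raw[i])) suppressWarnings(as.numeric(dp_raw[i])) else NULL
    out <- map(seq_along(alts), function(k) {
      vaf <- if (!is.null(afs) && length(afs) >= k && !is.na(afs[k])) {
        afs[k]
      } else if (!is.null(ads) && length(ads) >= k + 1 && sum(ads, na.rm = TRUE) > 0) {
        ads[k + 1] / sum(ads, na.rm = TRUE)
      } else NA_real_
      depth <- if (!is.null(dp) && !is.na(dp)) dp
      else if (!is.null(ads)) sum(ads, na.rm = TRUE) else NA_real_
      if (is.na(vaf)) return(NULL)
      tibble(sample = sample, panel = panel,
             chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
             ref = fix$REF[i], alt = alts[k],
             vaf = vaf, depth = depth,
             gene = gene[i], consequence = csq[i],
             classification = cls[i], hgvs_c = hgvs[i])
    })
    dropped <- sum(map_lgl(out, is.null))
    if (dropped > 0) n_skipped <<- n_skipped + dropped
    bind_rows(out)
  })
  if (n_skipped > 0) {
    warn(sprintf("%d record(s) in '%s' lacked both AF and AD; skipped",
                 n_skipped, path))
  }
  res <- bind_rows(rows)
  if (nrow(res) == 0) empty_calls(sample, panel) else res
}

empty_calls <- function(sample = character(), panel = character()) {
  tibble(sample = character(), panel = character(), chrom = character(),
         pos = integer(), ref = character(), alt = character(),
         vaf = numeric(), depth = numeric(), gene = character(),
         consequence = character(), classification = character(),
         hgvs_c = character())
}

#' Normalize variant calls (trim and left-align)
#'
#' Brings every call to its canonical minimal left-aligned representation so
#' that the same event reported differently by different callers gets the
#' same key: shared allele suffix then prefix are trimmed (always keeping at
#' least one base of each allele) and pure insertions/deletions are shifted
#' left through repeat context as far as the reference allows. Idempotent,
#' and preserves the edited haplotype.
#'
#' @param calls Call tibble with `chrom`, `pos`, `ref`, `alt` columns.
#' @param reference Named character vector of contig sequences (or
#'   `DNAStringSet`); must cover every call locus.
#' @return The call tibble with `pos`, `ref`, `alt` normalized.
#' @export
normalize_calls <- function(calls, reference) {
  reference <- as_reference(reference)
  norm <- pmap(list(calls$chrom, calls$pos, calls$ref, calls$alt),
               function(chrom, pos, ref, alt) {
                 normalize_one(chrom, pos, ref, alt, reference)
               })
  calls$pos <- map_int(norm, "pos")
  calls$ref <- map_chr(norm, "ref")
  calls$alt <- map_chr(norm, "alt")
  calls
}

normalize_one <- function(chrom, pos, ref, alt, reference) {
  obs <- ref_fetch(reference, chrom, pos, pos + nchar(ref) - 1L)
  if (!identical(obs, ref)) {
    abort(sprintf("reference mismatch at %s:%d: expected '%s', reference has '%s'",
                  chrom, pos, ref, obs))
  }
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  repeat {
    changed <- FALSE
    # trim shared trailing base
    while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]; a <- a[-length(a)]; changed <- TRUE
    }
    # left-align: if both alleles end with the same base we already trimmed;
    # for a pure indel whose alleles end identically after prepending the
    # previous reference base, shift left
    if (length(r) == 0 || length(a) == 0 ||
        (length(r) > 1 && length(a) > 1)) {
      # nothing more to do for balanced alleles
    } else if ((length(r) == 1 || length(a) == 1) &&
               r[length(r)] == a[length(a)] && pos > 1) {
      prev <- ref_fetch(reference, chrom, pos - 1L, pos - 1L)
      if (nzchar(prev)) {
        r <- c(prev, r[-length(r)])
        a <- c(prev, a[-length(a)])
        pos <- pos - 1L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # trim shared leading bases
  while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
    r <- r[-1]; a <- a[-1]; pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = paste(r, collapse = ""),
       alt = paste(a, collapse = ""))
}

#' Canonical identity key for a variant
#'
#' Equal keys identify equivalent variants across samples and panels; sample
#' and panel are deliberately excluded. Calls carrying allele strings are
#' keyed as `chrom:pos:ref:alt` (call [normalize_calls()] first); calls
#' transcribed from a printed table without allele strings fall back to
#' `chrom:pos:hgvs_c`.
#'
#' @param calls Call tibble (or any data frame with the relevant columns).
#' @return Character vector of keys.
#' @export
variant_key <- function(calls) {
  col <- function(nm) {
    if (nm %in% names(calls)) calls[[nm]] else rep(NA_character_, nrow(calls))
  }
  has_alleles <- !is.na(col("ref")) & !is.na(col("alt"))
  hgvs <- col("hgvs_c")
  ifelse(has_alleles,
         paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":"),
         paste(calls$chrom, calls$pos, hgvs, sep = ":"))
}

#' Insertion/deletion length of a call
#'
#' The absolute difference of allele lengths: 0 for SNVs and equal-length
#' multi-base substitutions (which are never counted as indels), the number
#' of inserted or deleted bases otherwise.
#'
#' @param ref,alt Allele strings (vectorized).
#' @return Integer vector of lengths in bp.
#' @export
indel_length <- function(ref, alt) {
  abs(nchar(ref) - nchar(alt))
}

#' Length of the edited segment from HGVS c. notation
#'
#' Parses the closed HGVS-cDNA dialect used in clinical panel reports:
#' underscore ranges with `del`/`dup` (optionally followed by the deleted or
#' duplicated bases), single-position `del`/`dup` forms like `c.1119delC`,
#' insertions with an explicit length (`c.1782_1783ins33`) or an inserted
#' sequence, and substitutions (length 0). Anything else returns `NA` —
#' abstention, never a guess.
#'
#' @param hgvs_c Character vector of c. notations.
#' @return Integer vector of segment lengths in bp (`NA` when unparseable).
#' @examples
#' hgvs_c_span(c("c.1099_1150del", "c.1800_1801ins21", "c.1119delC",
#'               "c.937_939dupAAG", "c.182A>G"))
#' @export
hgvs_c_span <- function(hgvs_c) {
  parse_one <- function(x) {
    if (is.na(x)) return(NA_integer_)
    x <- sub("^c\\.", "", trimws(x))
    m <- regexec("^(\\d+)_(\\d+)(del|dup)([ACGTacgt]*)$", x)[[1]]
    if (m[1] != -1) {
      g <- regmatches(x, regexec("^(\\d+)_(\\d+)(del|dup)([ACGTacgt]*)$", x))[[1]]
      return(as.integer(g[3]) - as.integer(g[2]) + 1L)
    }
    g <- regmatches(x, regexec("^(\\d+)(del|dup)([ACGTacgt]*)$", x))[[1]]
    if (length(g)) {
      return(if (nzchar(g[4])) nchar(g[4]) else 1L)
    }
    g <- regmatches(x, regexec("^(\\d+)_(\\d+)ins(\\d+)$", x))[[1]]
    if (length(g)) return(as.integer(g[4]))
    g <- regmatches(x, regexec("^(\\d+)_(\\d+)ins([ACGTacgt]+)$", x))[[1]]
    if (length(g)) return(nchar(g[4]))
    if (grepl("^\\d+[ACGTacgt]>[ACGTacgt]$", x)) return(0L)
    NA_integer_
  }
  vapply(hgvs_c, parse_one, integer(1), USE.NAMES = FALSE)
}

# canonical consequence class: "inframe_36" -> "inframe", "missense" unchanged
consequence_class <- function(consequence) {
  sub("_\\d+$", "", consequence)
}

#' Apply the reporting filter to variant calls
#'
#' Splits calls into kept and removed sets under a [filter_config()]. A
#' removed call carries the first failing reason in the fixed order
#' consequence, vaf, depth. Filtering is order-independent and idempotent.
#'
#' @param calls Call tibble with `vaf`, `depth`, `consequence` columns.
#' @param cfg A [filter_config()].
#' @return List with elements `kept` (tibble) and `removed` (tibble with an
#'   extra `reason` column); row counts add up to the input.
#' @export
apply_filters <- function(calls, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  cls <- consequence_class(calls$consequence %||% rep(NA_character_, nrow(calls)))
  reason <- rep(NA_character_, nrow(calls))
  reason[is.na(reason) & cls %in% cfg$excluded_consequences] <- "consequence"
  reason[is.na(reason) & calls$vaf < cfg$vaf_min] <- "vaf"
  reason[is.na(reason) & calls$depth < cfg$depth_min] <- "depth"
  list(kept = calls[is.na(reason), , drop = FALSE],
       removed = mutate(calls[!is.na(reason), , drop = FALSE],
                        reason = reason[!is.na(reason)]))
}
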