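make_vcf <- function(lines, format = "GT:AF:DP", sample = "S1") {
  path <- withr::local_tempfile(fileext = ".vcf", .local_envir = parent.frame())
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=GENE,Number=1,Type=String,Description="g">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="gt">',
    '##FORMAT=<ID=AF,Number=A,Type=Float,Description="af">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="ad">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="dp">',
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample),
    lines), path)
  path
}

test_that("VCF reading derives VAF from AF or AD and decomposes multiallelics", {
  p <- make_vcf("chr1\t100\t.\tA\tG\t.\tPASS\tGENE=NRAS\tGT:AD:DP\t0/1:90,10:100",
                format = "GT:AD:DP")
  calls <- read_vcf_calls(p, "S1", "P")
  expect_equal(calls$vaf, 0.10)
  expect_equal(calls$depth, 100)
  expect_equal(calls$gene, "NRAS")

  p2 <- make_vcf("chr1\t100\t.\tC\tA,T\t.\tPASS\t.\tGT:AF:DP\t0/1:0.1,0.3:500")
  calls2 <- read_vcf_calls(p2, "S1", "P")
  expect_equal(nrow(calls2), 2)
  expect_equal(calls2$alt, c("A", "T"))
  expect_equal(calls2$vaf, c(0.1, 0.3))

  p3 <- make_vcf("chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1")
  expect_warning(calls3 <- read_vcf_calls(p3, "S1", "P"), "skipped")
  expect_equal(nrow(calls3), 0)
})

test_that("normalization left-aligns and trims known representations", {
  ref <- c(chr1 = "GGACTTTGCA")
  # insertion inside a T run is anchored at the leftmost position
  out <- normalize_calls(tibble::tibble(chrom = "chr1", pos = 4L,
                                        ref = "CT", alt = "CTT"), ref)
  expect_equal(out$pos, 4L)
  expect_equal(out$ref, "C")
  expect_equal(out$alt, "CT")

  # already-minimal SNV unchanged
  snv <- tibble::tibble(chrom = "chr1", pos = 5L, ref = "T", alt = "A")
  expect_equal(normalize_calls(snv, ref), snv)

  # CG-repeat deletion left-aligns
  ref2 <- c(c2 = "TTGCGCGCGAA")
  del <- tibble::tibble(chrom = "c2", pos = 3L, ref = "GCGCG", alt = "GCG")
  out2 <- normalize_calls(del, ref2)
  expect_equal(out2$pos, 2L)
  expect_equal(out2$ref, "TGC")
  expect_equal(out2$alt, "T")
  # idempotent
  expect_equal(normalize_calls(out2, ref2), out2)

  # reference mismatch is an error
  expect_error(normalize_calls(tibble::tibble(chrom = "chr1", pos = 1L,
                                              ref = "T", alt = "A"), ref),
               "reference mismatch")
})

test_that("normalization matches the exhaustive parsimony oracle and preserves the haplotype (property)", {
  withr::with_seed(41, {
    n_checked <- 0
    for (rep in 1:60) {
      seq <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE,
                          prob = c(0.4, 0.2, 0.2, 0.2)), collapse = "")
      ref_src <- c(c1 = seq)
      pos <- sample(5:30, 1)
      kind <- sample(c("ins", "del", "snv"), 1)
      if (kind == "snv") {
        ref <- substr(seq, pos, pos)
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      } else if (kind == "ins") {
        ref <- substr(seq, pos, pos)
        alt <- paste0(ref, paste(sample(c("A", "C", "G", "T"),
                                        sample(1:4, 1), replace = TRUE),
                                 collapse = ""))
      } else {
        len <- sample(1:4, 1)
        ref <- substr(seq, pos, pos + len)
        alt <- substr(ref, 1, 1)
      }
      # perturb into a non-minimal equivalent representation by padding
      pad <- sample(0:2, 1)
      ref_p <- substr(seq, pos, pos + nchar(ref) - 1 + pad)
      alt_p <- paste0(alt, substr(seq, pos + nchar(ref),
                                  pos + nchar(ref) + pad - 1))
      got <- normalize_calls(tibble::tibble(chrom = "c1", pos = pos,
                                            ref = ref_p, alt = alt_p), ref_src)
      want <- brute_normalize(seq, pos, ref_p, alt_p)
      expect_equal(got$pos, want$pos, info = paste(seq, pos, ref_p, alt_p))
      expect_equal(got$ref, want$ref, info = paste(seq, pos, ref_p, alt_p))
      expect_equal(got$alt, want$alt, info = paste(seq, pos, ref_p, alt_p))
      # haplotype preserved
      expect_equal(apply_edit(seq, got$pos, got$ref, got$alt),
                   apply_edit(seq, pos, ref_p, alt_p))
      # idempotent
      expect_equal(normalize_calls(got, ref_src), got)
      n_checked <- n_checked + 1
    }
    expect_gte(n_checked, 60)
  })
})

test_that("variant keys identify equivalent variants and separate distinct ones", {
  ref <- c(c1 = "TTGCGCGCGAA")
  reps <- tibble::tibble(chrom = "c1", pos = c(3L, 5L),
                         ref = c("GCGCG", "GCGCG"), alt = c("GCG", "GCG"))
  keys <- variant_key(normalize_calls(reps, ref))
  expect_equal(keys[1], keys[2])

  distinct_vars <- tibble::tibble(chrom = "c1", pos = c(2L, 2L),
                                  ref = c("T", "T"), alt = c("A", "TA"))
  expect_equal(length(unique(variant_key(distinct_vars))), 2)

  # allele-free calls key on hgvs_c: same printed deletion shares a key
  t3 <- load_table3()
  calr <- t3[t3$hgvs_c == "c.1099_1150del", ]
  expect_equal(nrow(calr), 2)   # reported in two different samples
  k <- variant_key(tibble::tibble(chrom = calr$chrom, pos = calr$pos,
                                  ref = NA_character_, alt = NA_character_,
                                  hgvs_c = calr$hgvs_c))
  expect_equal(k[1], k[2])
})

test_that("indel length is the allele-length difference; MNVs are not indels", {
  expect_equal(indel_length("A", "AT"), 1L)
  expect_equal(indel_length("ATTTT", "A"), 4L)
  expect_equal(indel_length("A", "G"), 0L)
  expect_equal(indel_length("AC", "GT"), 0L)
})

test_that("HGVS c. spans parse the clinical dialect and abstain otherwise", {
  expect_equal(hgvs_c_span("c.1749_1784dup"), 36L)
  expect_equal(hgvs_c_span("c.1099_1150del"), 52L)
  expect_equal(hgvs_c_span("c.1734_1769dup"), 36L)
  expect_equal(hgvs_c_span("c.1800_1801ins21"), 21L)
  expect_equal(hgvs_c_span("c.1119delC"), 1L)
  expect_equal(hgvs_c_span("c.937_939dupAAG"), 3L)
  expect_equal(hgvs_c_span("c.1089_1090insGCCCTCTTGTACGG"), 14L)
  expect_equal(hgvs_c_span("c.1934dupG"), 1L)
  expect_equal(hgvs_c_span("c.182A>G"), 0L)
  expect_true(is.na(hgvs_c_span("c.88+2T>G")))
  expect_true(is.na(hgvs_c_span("c.1_3delinsTT")))
})

test_that("every study-table indel span is consistent with its consequence annotation", {
  t3 <- load_table3()
  spans <- hgvs_c_span(t3$hgvs_c)
  expect_false(anyNA(spans))
  # inframe_N annotations carry the indel length in the consequence string
  inframe <- grepl("^inframe_", t3$consequence)
  expect_equal(spans[inframe],
               as.integer(sub("^inframe_", "", t3$consequence[inframe])))
  expect_true(all(spans[t3$consequence == "missense"] == 0))
})

test_that("reporting filter uses inclusive bounds and ordered reasons", {
  calls <- tibble::tibble(
    sample = "S", panel = "P", chrom = "c", pos = 1:5,
    ref = "A", alt = "G",
    vaf = c(0.05, 0.049, 0.40, 0.05, 0.04),
    depth = c(100, 5000, 900, 99, 50),
    consequence = c("missense", "missense", "intronic", "missense", "intergenic"),
    classification = "pathogenic")
  out <- apply_filters(calls, filter_config())
  expect_equal(nrow(out$kept) + nrow(out$removed), nrow(calls))
  expect_equal(out$kept$pos, 1L)                 # 0.05 / 100 kept (inclusive)
  reasons <- setNames(out$removed$reason, out$removed$pos)
  expect_equal(unname(reasons[c("2", "3", "4", "5")]),
               c("vaf", "consequence", "depth", "consequence"))
  # idempotent
  again <- apply_filters(out$kept, filter_config())
  expect_equal(again$kept, out$kept)
  expect_equal(nrow(again$removed), 0)
})

test_that("inframe consequences with length suffixes survive the filter", {
  calls <- tibble::tibble(sample = "S", panel = "P", chrom = "c", pos = 1L,
                          ref = "A", alt = "G", vaf = 0.3, depth = 1000,
                          consequence = "inframe_36",
                          classification = "pathogenic")
  expect_equal(nrow(apply_filters(calls)$kept), 1)
  splice <- dplyr::mutate(calls, consequence = "splice_region")
  expect_equal(apply_filters(splice)$removed$reason, "consequence")
})
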