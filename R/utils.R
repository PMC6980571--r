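# internal helpers shared across modules

`%||%` <- rlang::`%||%`

# merge half-open [start,end) intervals on one contig; returns tibble(start,end)
merge_intervals <- function(start, end) {
  stopifnot(length(start) == length(end))
  if (length(start) == 0) return(tibble(start = integer(), end = integer()))
  ir <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end))
  tibble(start = BiocGenerics::start(ir) - 1L, end = BiocGenerics::end(ir))
}

# total merged width of half-open intervals grouped by chrom
merged_width <- function(chrom, start, end) {
  df <- tibble(chrom = chrom, start = start, end = end)
  df |>
    group_by(chrom) |>
    reframe(merge_intervals(start, end)) |>
    mutate(w = end - start) |>
    pull(w) |>
    sum()
}

# fetch a 1-based inclusive substring of a reference sequence, clipped to the
# contig; `reference` is a named character vector (or coercible DNAStringSet)
ref_fetch <- function(reference, chrom, from, to) {
  seqs <- as_reference(reference)
  if (!chrom %in% names(seqs)) {
    abort(sprintf("contig '%s' not present in reference", chrom))
  }
  s <- seqs[[chrom]]
  n <- nchar(s)
  from <- max(1L, from)
  to <- min(n, to)
  if (from > to) return("")
  substr(s, from, to)
}

as_reference <- function(reference) {
  if (inherits(reference, "DNAStringSet")) {
    setNames(as.character(reference), names(reference))
  } else if (is.character(reference)) {
    if (is.null(names(reference))) abort("reference sequences must be named")
    reference
  } else {
    abort("reference must be a named character vector or a DNAStringSet")
  }
}

#' Read a reference FASTA into a named character vector
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return Named character vector of upper-case sequences, one per contig.
#' @export
read_reference_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(seqs))
  setNames(toupper(as.character(seqs)), nm)
}
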