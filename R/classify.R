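#' Is a variant classification clinically relevant?
#'
#' Clinical relevance follows the reporting rule used for myeloid panels:
#' only variants classified pathogenic or likely pathogenic count. Labels
#' like `"Pathogenic/COSM584"` are split on `/`; the first token is matched
#' case-insensitively (COSMIC identifiers are annotation only). Unknown
#' labels raise an error rather than silently defaulting.
#'
#' @param classification Character vector of classification labels.
#' @return Logical vector.
#' @examples
#' is_clinically_relevant(c("Pathogenic/COSM584", "likely_benign"))
#' @export
is_clinically_relevant <- function(classification) {
  known <- c(pathogenic = TRUE, likely_pathogenic = TRUE, vus = FALSE,
             likely_benign = FALSE, benign = FALSE, unclassified = FALSE)
  tok <- map_chr(strsplit(classification, "/", fixed = TRUE), 1)
  tok <- gsub("[ .]+", "_", tolower(trimws(tok)))
  bad <- !tok %in% names(known) & !is.na(tok)
  if (any(bad)) {
    abort(sprintf("unknown classification label(s): %s",
                  paste(unique(classification[bad]), collapse = ", ")))
  }
  unname(known[tok])
}

#' Prognostic class of a FLT3-ITD allelic ratio
#'
#' The ITD/wild-type allelic ratio stratifies AML prognosis: below 0.5 is
#' favorable, above 0.5 unfavorable. A ratio of exactly 0.5 is assigned to
#' unfavorable (the "high ratio" convention).
#'
#' @param ratio Non-negative allelic ratio(s); decimal-comma strings such as
#'   `"1,11"` are accepted.
#' @return Character vector, `"favorable"` or `"unfavorable"`.
#' @examples
#' flt3_itd_class(c(1.11, 0.49, "1,06"))
#' @export
flt3_itd_class <- function(ratio) {
  ratio <- parse_decimal(ratio)
  if (any(ratio < 0, na.rm = TRUE)) abort("FLT3-ITD ratio must be non-negative")
  ifelse(is.na(ratio), NA_character_,
         ifelse(ratio >= 0.5, "unfavorable", "favorable"))
}

# parse numbers that may use a decimal comma ("1,11" -> 1.11)
parse_decimal <- function(x) {
  if (is.numeric(x)) return(x)
  suppressWarnings(as.numeric(gsub(",", ".", trimws(x), fixed = TRUE)))
}

#' CEBPA allelic-status candidate from NGS calls
#'
#' Short-read sequencing cannot phase the two CEBPA mutations of a biallelic
#' case (they typically sit at opposite ends of the single exon), so NGS can
#' only nominate a candidate status: two or more clinically relevant CEBPA
#' variants in one sample suggest biallelic disease, one suggests
#' monoallelic. Confirmation requires an orthogonal assay.
#'
#' @param calls Filtered, clinically relevant calls for one sample (tibble
#'   with a `gene` column).
#' @return `"none"`, `"monoallelic_candidate"` or `"biallelic_candidate"`.
#' @export
cebpa_allelic_flag <- function(calls) {
  n <- sum(calls$gene == "CEBPA", na.rm = TRUE)
  if (n == 0) "none" else if (n == 1) "monoallelic_candidate" else "biallelic_candidate"
}
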