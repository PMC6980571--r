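# broom-style tidy()/glance() methods for the package's result objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a call matrix into long status records
#'
#' @param x A `call_matrix`.
#' @param ... Unused.
#' @return Tibble with one row per variant x panel (`sample`, `key`, `gene`,
#'   `panel`, `status`, ...).
#' @export
tidy.call_matrix <- function(x, ...) {
  status_long(x)
}

#' One-row summary of a call matrix
#'
#' @param x A `call_matrix`.
#' @param ... Unused.
#' @return Tibble with `n_variants`, `n_panels`, `n_discordant`,
#'   `n_design_gaps` (NI cells), `n_calling_misses` (NC cells).
#' @export
glance.call_matrix <- function(x, ...) {
  st <- as.matrix(as_tibble(x)[matrix_panels(x)])
  tibble(n_variants = nrow(x),
         n_panels = length(matrix_panels(x)),
         n_discordant = count_discordant(x)$n_discordant,
         n_design_gaps = sum(st == "NI"),
         n_calling_misses = sum(st == "NC"))
}

#' Tidy the paired VAFs of a concordance result
#'
#' @param x A `vaf_concordance`.
#' @param ... Unused.
#' @return The pair tibble (`sample`, `key`, `gene`, `vaf_a`, `vaf_b`).
#' @export
tidy.vaf_concordance <- function(x, ...) {
  x$pairs
}

#' One-row summary of a VAF concordance result
#'
#' @param x A `vaf_concordance`.
#' @param ... Unused.
#' @return Tibble with `panel_a`, `panel_b`, `r_squared`, `n_pairs`.
#' @export
glance.vaf_concordance <- function(x, ...) {
  tibble(panel_a = x$panels[1], panel_b = x$panels[2],
         r_squared = x$r_squared, n_pairs = x$n_pairs)
}
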