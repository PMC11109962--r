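# Published per-cell-line RBPJ site tallies, used as numeric anchors for
# sanity checks on the dynamic-site arithmetic.

#' Reference RBPJ site tallies
#'
#' Reported total and dynamic RBPJ binding-site counts for the cell lines
#' in which static/dynamic binding was characterized: Beko (mouse pre-T,
#' GSI contrast), and the TNBC lines HCC1599 and MB157 (GSI-washout
#' contrast).
#'
#' @return Tibble `cell_line`, `n_static`, `n_dynamic`, `n_total`.
#' @export
site_tally_reference <- function() {
  tibble(
    cell_line = c("Beko", "HCC1599", "MB157"),
    n_static = c(3380L, 14010L - 2607L, 7628L - 2040L),
    n_dynamic = c(158L, 2607L, 2040L),
    n_total = c(3380L + 158L, 14010L, 7628L)
  )
}

#' Percentage of dynamic sites
#'
#' @param n_dynamic,n_total Counts.
#' @return `100 * n_dynamic / n_total`.
#' @export
dynamic_percent <- function(n_dynamic, n_total) 100 * n_dynamic / n_total
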