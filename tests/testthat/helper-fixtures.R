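# In-code fixture builders shared across test files.

toy_gene <- function(gene_id, chrom, start, end, strand,
                     exons = NULL, utr5 = NULL, utr3 = NULL) {
  empty <- tibble::tibble(start = integer(), end = integer())
  tibble::tibble(
    gene_id = gene_id, chrom = chrom, start = start, end = end,
    strand = strand,
    tss = if (strand == "+") start else end - 1L,
    exons = list(if (is.null(exons)) empty else exons),
    utr5 = list(if (is.null(utr5)) empty else utr5),
    utr3 = list(if (is.null(utr3)) empty else utr3)
  )
}

toy_site <- function(site_id, chrom, start, end) {
  tibble::tibble(site_id = site_id, chrom = chrom, start = start, end = end)
}

# random replicate peaks on one chromosome for consensus oracle checks
random_replicate_peaks <- function(n_peaks, n_reps, chrom_len = 20000,
                                   width_range = c(100, 400)) {
  n <- n_peaks
  start <- sample.int(chrom_len, n, replace = TRUE)
  width <- sample(width_range[1]:width_range[2], n, replace = TRUE)
  tibble::tibble(
    chrom = "chr1",
    start = start,
    end = start + width,
    p_value = 10^(-runif(n, 1, 14)),
    replicate = sample(sprintf("rep%d", seq_len(n_reps)), n, replace = TRUE)
  )
}

# small labeled feature table with a separable signal, for model tests
toy_feature_table <- function(n = 400, frac_dynamic = 0.25, seed = 42) {
  withr::with_seed(seed, {
    lab <- sample(c("dynamic", "static"), n, replace = TRUE,
                  prob = c(frac_dynamic, 1 - frac_dynamic))
    dyn <- lab == "dynamic"
    tibble::tibble(
      site_id = sprintf("s%04d", seq_len(n)),
      norm_p = pmin(1, pmax(0, rnorm(n, ifelse(dyn, 0.7, 0.3), 0.15))),
      category = factor(
        ifelse(runif(n) < ifelse(dyn, 0.15, 0.75), "promoter", "intergenic"),
        levels = notchdyn:::CATEGORY_LEVELS),
      has_sp1 = runif(n) < ifelse(dyn, 0.1, 0.5),
      has_rbpj_canonical = runif(n) < ifelse(dyn, 0.7, 0.2),
      label = factor(lab, levels = c("dynamic", "static"))
    ) |>
      dplyr::mutate(has_rbpj_degenerate = has_rbpj_canonical |
                      runif(n) < ifelse(dyn, 0.4, 0.15))
  })
}

small_sim_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_chroms = 2L, chrom_length = 600000L,
             n_genes = 200L, n_sites = 400L, ...)
}
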