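# Condition-dependent binding at consensus sites: windowed read counting,
# median-of-ratios normalization, and the fold-change rule that labels a
# site dynamic (log2FC < -0.5 on GSI, or > +0.5 on GSI washout).

#' Count reads in site windows
#'
#' Counts, per sample, the reads overlapping each site extended by `flank`
#' bp on both ends (>= 1 bp overlap; windows clipped at coordinate 0). The
#' flank defaults to 0 for the TF's own sites; chromatin-mark or
#' accessibility matrices use the 500 bp detection window on either side.
#'
#' @param sites Consensus site tibble (`site_id`, `chrom`, `start`, `end`).
#' @param reads Tibble of read/fragment intervals with a `sample_id`
#'   column: `chrom`, `start`, `end`, `sample_id`.
#' @param flank Extension in bp on each side (default 0).
#' @return A wide tibble: `site_id` plus one integer column per sample.
#'   Reads on chromosomes absent from `sites` are ignored with a note.
#' @export
count_in_windows <- function(sites, reads, flank = 0L) {
  stopifnot(flank >= 0)
  samples <- unique(reads$sample_id)
  orphan <- setdiff(unique(reads$chrom), unique(sites$chrom))
  if (length(orphan) > 0) {
    inform(paste0("ignoring reads on chromosomes without sites: ",
                  paste(orphan, collapse = ", ")))
  }
  win <- sites
  win$start <- pmax(0L, win$start - as.integer(flank))
  win$end <- win$end + as.integer(flank)
  win_gr <- as_gr(win)
  out <- tibble(site_id = sites$site_id)
  for (s in samples) {
    rd <- reads[reads$sample_id == s, , drop = FALSE]
    out[[s]] <- GenomicRanges::countOverlaps(win_gr, as_gr(rd),
                                             ignore.strand = TRUE)
  }
  out
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over sites (restricted to
#' sites with positive counts in every sample) of the ratio between the
#' sample's count and the row's geometric mean.
#'
#' @param counts Wide count tibble (`site_id` + one column per sample) or a
#'   numeric matrix with samples in columns.
#' @return Tibble `sample_id`, `size_factor`.
#' @export
size_factors <- function(counts) {
  m <- count_matrix(counts)
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) {
    abort(paste0("no site has positive counts in every sample; ",
                 "supply deeper data or use a pseudo-reference"))
  }
  logm <- log(m[pos, , drop = FALSE])
  ref <- rowMeans(logm)
  sf <- apply(exp(logm - ref), 2, median)
  tibble(sample_id = colnames(m), size_factor = unname(sf))
}

#' @noRd
count_matrix <- function(counts) {
  if (is.matrix(counts)) return(counts)
  m <- as.matrix(counts[setdiff(names(counts), "site_id")])
  rownames(m) <- counts$site_id
  m
}

#' Classify sites as dynamic or static
#'
#' Normalizes counts by median-of-ratios size factors, averages per
#' condition, computes `log2fc = log2((mean_treated + pc) / (mean_control
#' + pc))` and applies the fold-change rule: under the GSI contrast a site
#' is dynamic iff `log2fc < -cutoff` (binding lost when Notch is switched
#' off); under the washout contrast iff `log2fc > +cutoff` (binding
#' regained on reactivation). Inequalities are strict; a site at exactly
#' the cutoff is static.
#'
#' @param counts Wide count tibble from [count_in_windows()].
#' @param samples Sample sheet: `sample_id`, `condition` (one of
#'   `control`, `GSI`, `washout`), `replicate`.
#' @param contrast `"GSI_vs_control"` (treated = GSI, baseline = control)
#'   or `"washout_vs_GSI"` (treated = washout, baseline = GSI).
#' @param cutoff Absolute log2 fold-change cutoff (default 0.5).
#' @param pseudocount Added to both normalized means before the ratio
#'   (default 1), guarding the log at zero counts.
#' @return Tibble `site_id`, `mean_control`, `mean_treated`, `log2fc`,
#'   `label` (`"dynamic"` or `"static"`).
#' @export
classify_sites <- function(counts, samples,
                           contrast = c("GSI_vs_control", "washout_vs_GSI"),
                           cutoff = 0.5, pseudocount = 1) {
  contrast <- match.arg(contrast)
  if (cutoff <= 0) abort("cutoff must be positive")
  cond <- switch(contrast,
    GSI_vs_control = c(baseline = "control", treated = "GSI"),
    washout_vs_GSI = c(baseline = "GSI", treated = "washout"))
  missing_cond <- setdiff(cond, samples$condition)
  if (length(missing_cond) > 0) {
    abort(paste0("contrast condition absent from samples: ",
                 paste(missing_cond, collapse = ", ")))
  }
  m <- count_matrix(counts)
  sf <- size_factors(counts)
  sf <- sf$size_factor[match(colnames(m), sf$sample_id)]
  norm <- sweep(m, 2, sf, "/")
  cond_of <- samples$condition[match(colnames(m), samples$sample_id)]
  mean_base <- rowMeans(norm[, cond_of == cond[["baseline"]], drop = FALSE])
  mean_trt <- rowMeans(norm[, cond_of == cond[["treated"]], drop = FALSE])
  log2fc <- log2((mean_trt + pseudocount) / (mean_base + pseudocount))
  dynamic <- if (contrast == "GSI_vs_control") {
    log2fc < -cutoff
  } else {
    log2fc > cutoff
  }
  tibble(
    site_id = rownames(m),
    mean_control = unname(mean_base),
    mean_treated = unname(mean_trt),
    log2fc = unname(log2fc),
    label = factor(if_else(dynamic, "dynamic", "static"),
                   levels = LABEL_LEVELS)
  )
}
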