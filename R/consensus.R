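# Replicate-validated consensus binding sites: overlap grouping across
# replicates, a k-of-n support rule, and Fisher-combined significance with
# weak/stringent thresholds (w = 1e-6, s = 1e-10 by default, as used for
# the RBPJ replicate validation).

#' Combine p-values by Fisher's method
#'
#' Returns the survival probability of a chi-squared variable with `2k`
#' degrees of freedom at `X = -2 * sum(log(p_i))`. With a single p-value
#' this is the identity.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return A single combined p-value in (0, 1].
#' @examples
#' fisher_combine(c(0.01, 0.01))
#' @export
fisher_combine <- function(p_values) {
  if (length(p_values) == 0) abort("fisher_combine: empty p-value list")
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    abort("fisher_combine: p-values must lie in (0, 1]")
  }
  x <- -2 * sum(log(p_values))
  pchisq(x, df = 2 * length(p_values), lower.tail = FALSE)
}

#' Build replicate-validated consensus sites
#'
#' Pools peaks from all replicates, groups them by transitive closure of
#' >= 1 bp overlap, and keeps a group when (a) at least `min_support`
#' distinct replicates contribute, and (b) the Fisher-combined p-value over
#' one representative peak per replicate (the most significant) is at most
#' `weak_w` -- or the group contains a single peak at or below
#' `stringent_s`, which rescues it from (b) but not from (a). The emitted
#' interval is the union span of the group.
#'
#' @param replicate_peaks Tibble of peaks from all replicates: `chrom`,
#'   `start`, `end`, `p_value`, `replicate`.
#' @param min_support Minimum number of distinct supporting replicates
#'   (e.g. 3 of 5 control replicates for the TF, 3 of 4 for histone marks).
#' @param weak_w Weak combined-significance threshold (default `1e-6`).
#' @param stringent_s Stringent single-peak threshold (default `1e-10`).
#' @return Tibble of consensus sites sorted by position: `site_id`,
#'   `chrom`, `start`, `end`, `support`, `combined_p`, `norm_score`
#'   (min-max normalized `-log10(combined_p)`, see [min_max_normalize()]).
#' @export
build_consensus <- function(replicate_peaks, min_support = 3L,
                            weak_w = 1e-6, stringent_s = 1e-10) {
  stopifnot(all(c("chrom", "start", "end", "p_value", "replicate") %in%
                  names(replicate_peaks)))
  n_reps <- dplyr::n_distinct(replicate_peaks$replicate)
  if (nrow(replicate_peaks) == 0) abort("build_consensus: no peaks")
  if (min_support > n_reps) {
    abort(sprintf("min_support (%d) exceeds replicate count (%d)",
                  min_support, n_reps))
  }
  if (stringent_s > weak_w) abort("stringent_s must be <= weak_w")
  pk <- as_tibble(replicate_peaks)
  pk$p_value <- pmax(pk$p_value, P_FLOOR)

  gr <- as_gr(pk)
  # transitive closure of >= 1 bp overlap: merged spans of the pooled peaks
  # (min.gapwidth = 0 keeps half-open-abutting peaks apart)
  merged <- GenomicRanges::reduce(gr, ignore.strand = TRUE, min.gapwidth = 0L)
  grp <- GenomicRanges::findOverlaps(gr, merged, ignore.strand = TRUE)
  pk$group <- S4Vectors::subjectHits(grp)

  sites <- pk |>
    group_by(.data$group) |>
    summarise(
      chrom = .data$chrom[1],
      start = min(.data$start),
      end = max(.data$end),
      support = dplyr::n_distinct(.data$replicate),
      combined_p = fisher_combine(
        tapply(.data$p_value, .data$replicate, min)),
      min_p = min(.data$p_value),
      .groups = "drop"
    ) |>
    filter(.data$support >= min_support,
           .data$combined_p <= weak_w | .data$min_p <= stringent_s) |>
    arrange(.data$chrom, .data$start) |>
    select(-"group", -"min_p")

  sites$site_id <- sprintf("site_%05d", seq_len(nrow(sites)))
  sites$norm_score <- if (nrow(sites) >= 2) {
    min_max_normalize(sites$combined_p)
  } else {
    rep(0, nrow(sites))
  }
  select(sites, "site_id", "chrom", "start", "end", "support",
         "combined_p", "norm_score")
}

#' Min-max normalize combined p-values
#'
#' Normalizes on the `-log10(p)` scale so the most significant site maps to
#' 1 and the least significant to 0, making peak strength comparable across
#' datasets. Raw p-values cluster near zero and would collapse the dynamic
#' range, hence the log transform.
#'
#' @param combined_p Numeric vector of p-values in (0, 1].
#' @return Numeric vector in \[0, 1\]. If all inputs are identical, all
#'   zeros with a warning.
#' @examples
#' min_max_normalize(c(1e-10, 1e-6, 1e-2))
#' @export
min_max_normalize <- function(combined_p) {
  if (any(combined_p <= 0 | combined_p > 1, na.rm = TRUE)) {
    abort("min_max_normalize: p-values must lie in (0, 1]")
  }
  t <- -log10(pmax(combined_p, P_FLOOR))
  rng <- range(t)
  if (diff(rng) == 0) {
    warn("all combined p-values identical; normalized scores set to 0")
    return(rep(0, length(t)))
  }
  (t - rng[1]) / diff(rng)
}
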