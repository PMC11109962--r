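# Enhancer clusters: stitch acetylation peaks within 12.5 kb, rank by
# aggregate signal, flag the top tier at the rank-signal inflection
# (slope-1 tangent on the scaled curve), and intersect with site classes.

#' Stitch peaks into enhancer clusters
#'
#' Transitively merges peaks on the same chromosome whose gap is at most
#' `stitch_distance` bp (overlapping peaks always merge). Cluster signal is
#' the sum of constituent signals and the span is the union.
#'
#' @param peaks Tibble `chrom`, `start`, `end`, `signal` (signal >= 0).
#' @param stitch_distance Maximum gap merged, in bp (default 12500).
#' @return Tibble `cluster_id`, `chrom`, `start`, `end`,
#'   `constituent_count`, `total_signal`, sorted by position.
#' @export
stitch_enhancers <- function(peaks, stitch_distance = 12500L) {
  if (stitch_distance < 0) abort("stitch_distance must be >= 0")
  if (!"signal" %in% names(peaks)) abort("peaks need a signal column")
  if (any(peaks$signal < 0)) abort("signals must be >= 0")
  gr <- as_gr(peaks)
  merged <- GenomicRanges::reduce(gr, ignore.strand = TRUE,
                                  min.gapwidth = stitch_distance + 1L)
  hit <- GenomicRanges::findOverlaps(gr, merged, ignore.strand = TRUE)
  grp <- S4Vectors::subjectHits(hit)
  out <- as_tibble(peaks) |>
    mutate(.grp = grp) |>
    group_by(.data$.grp) |>
    summarise(chrom = .data$chrom[1], start = min(.data$start),
              end = max(.data$end), constituent_count = n(),
              total_signal = sum(.data$signal), .groups = "drop") |>
    arrange(.data$chrom, .data$start) |>
    select(-".grp")
  mutate(out, cluster_id = sprintf("cluster_%04d", row_number()),
         .before = 1)
}

#' Rank clusters and flag the top tier
#'
#' Clusters are sorted by total signal; rank 1 is the strongest. With rank
#' and signal both rescaled to \[0, 1\] (ascending), the cutoff sits where
#' a slope-1 line is tangent to the curve -- the point of maximal vertical
#' gap below the diagonal -- and clusters with signal strictly above the
#' cutoff are flagged. Fewer than 3 clusters, or all-equal signals, flag
#' nothing.
#'
#' @param clusters Tibble from [stitch_enhancers()].
#' @return The input with `rank` (1 = strongest, unique) and
#'   `is_top_tier` columns, sorted by rank.
#' @export
rank_enhancers <- function(clusters) {
  n <- nrow(clusters)
  out <- clusters |>
    arrange(dplyr::desc(.data$total_signal), .data$chrom, .data$start) |>
    mutate(rank = row_number())
  if (n < 3 || diff(range(out$total_signal)) == 0) {
    return(mutate(out, is_top_tier = FALSE))
  }
  sig <- sort(out$total_signal)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (sig - min(sig)) / (max(sig) - min(sig))
  cutoff <- sig[which.max(x - y)]
  mutate(out, is_top_tier = .data$total_signal > cutoff)
}

#' Overlap of site classes with enhancer clusters
#'
#' For each site class, the fraction of sites falling inside any cluster
#' and its fold enrichment over the random expectation (total cluster span
#' divided by the effective genome span).
#'
#' @param clusters Tibble from [stitch_enhancers()] (optionally filtered
#'   to the top tier).
#' @param dynamic_sites,static_sites Site interval tibbles.
#' @param genome_span Effective genome size in bp.
#' @return Tibble `class`, `n_sites`, `n_in_clusters`, `fraction`, `fold`.
#' @export
intersect_with_classes <- function(clusters, dynamic_sites, static_sites,
                                   genome_span) {
  if (genome_span <= 0) abort("genome_span must be positive")
  if (nrow(dynamic_sites) == 0 || nrow(static_sites) == 0) {
    abort("both site classes must be non-empty")
  }
  span <- sum(clusters$end - clusters$start)
  expected <- span / genome_span
  one <- function(sites, cls) {
    ov <- overlap_fraction(sites, clusters)
    tibble(class = cls, n_sites = nrow(sites),
           n_in_clusters = ov$n_overlap, fraction = ov$fraction,
           fold = ov$fraction / expected)
  }
  bind_rows(one(dynamic_sites, "dynamic"), one(static_sites, "static"))
}
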