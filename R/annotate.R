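# Positioning of binding sites relative to gene models. The site midpoint
# drives every assignment (deterministic single category per site), and
# nearest-TSS ties break on the lexicographically smaller gene_id.

site_midpoint <- function(start, end) as.integer(floor((start + end) / 2))

#' Signed distance to the nearest TSS
#'
#' Distance is midpoint minus TSS, sign-flipped for minus-strand genes, so
#' negative values are upstream of the gene and positive downstream
#' regardless of strand. The nearest TSS by absolute distance wins.
#'
#' @param site One-row interval tibble (`chrom`, `start`, `end`).
#' @param genes Gene tibble from [read_gtf()].
#' @return One-row tibble `gene_id`, `tss_distance`; `gene_id` is `NA`
#'   when no gene shares the site's chromosome.
#' @export
distance_to_tss <- function(site, genes) {
  g <- genes[genes$chrom == site$chrom[1], , drop = FALSE]
  if (nrow(g) == 0) {
    return(tibble(gene_id = NA_character_, tss_distance = NA_integer_))
  }
  mid <- site_midpoint(site$start[1], site$end[1])
  d <- (mid - g$tss) * ifelse(g$strand == "+", 1L, -1L)
  ord <- order(abs(d), g$gene_id)
  tibble(gene_id = g$gene_id[ord[1]], tss_distance = as.integer(d[ord[1]]))
}

#' Categorize a site by its midpoint
#'
#' Tests the midpoint against gene features in precedence order: promoter
#' (TSS +/- window, strand-oriented) > 5' UTR > 3' UTR > gene body (exon or
#' intron, i.e. anywhere in the gene span) > downstream (within
#' `downstream_window` bp past the gene end) > intergenic. UTR categories
#' fire only when UTRs are annotated in the GTF.
#'
#' @param site One-row interval tibble.
#' @param genes Gene tibble from [read_gtf()].
#' @param promoter_window Length-2 vector `(upstream, downstream)` bp
#'   around the TSS (default 3000 each side).
#' @param downstream_window bp past the gene end still called
#'   `downstream` (default 3000).
#' @return A single category string from the closed set.
#' @export
categorize_site <- function(site, genes, promoter_window = c(3000L, 3000L),
                            downstream_window = 3000L) {
  g <- genes[genes$chrom == site$chrom[1], , drop = FALSE]
  if (nrow(g) == 0) return("intergenic")
  mid <- site_midpoint(site$start[1], site$end[1])
  plus <- g$strand == "+"
  prom_lo <- ifelse(plus, g$tss - promoter_window[1], g$tss - promoter_window[2])
  prom_hi <- ifelse(plus, g$tss + promoter_window[2], g$tss + promoter_window[1])
  if (any(mid >= prom_lo & mid <= prom_hi)) return("promoter")
  in_sub <- function(col) {
    any(vapply(seq_len(nrow(g)), function(i) {
      s <- g[[col]][[i]]
      !is.null(s) && nrow(s) > 0 && any(mid >= s$start & mid < s$end)
    }, logical(1)))
  }
  if (in_sub("utr5")) return("five_prime_utr")
  if (in_sub("utr3")) return("three_prime_utr")
  if (any(mid >= g$start & mid < g$end)) return("gene_body")
  down_lo <- ifelse(plus, g$end, g$start - downstream_window)
  down_hi <- ifelse(plus, g$end + downstream_window, g$start)
  if (any(mid >= down_lo & mid < down_hi)) return("downstream")
  "intergenic"
}

#' Annotate sites relative to gene models
#'
#' Vectorized combination of [distance_to_tss()] and [categorize_site()]
#' over a site table.
#'
#' @param sites Site tibble (`site_id`, `chrom`, `start`, `end`).
#' @inheritParams categorize_site
#' @return Tibble `site_id`, `category`, `nearest_gene`, `tss_distance`.
#' @export
annotate_sites <- function(sites, genes, promoter_window = c(3000L, 3000L),
                           downstream_window = 3000L) {
  mids <- site_midpoint(sites$start, sites$end)
  mid_gr <- GenomicRanges::GRanges(sites$chrom,
                                   IRanges::IRanges(mids + 1L, mids + 1L))
  plus <- genes$strand == "+"
  hit_any <- function(lo, hi, chrom) {
    # closed [lo, hi] on midpoints, in 0-based genome positions
    keep <- hi >= lo
    out <- rep(FALSE, nrow(sites))
    if (!any(keep)) return(out)
    gr <- GenomicRanges::GRanges(chrom[keep],
                                 IRanges::IRanges(lo[keep] + 1L,
                                                  hi[keep] + 1L))
    out[unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(mid_gr, gr)))] <- TRUE
    out
  }
  flat_sub <- function(col) {
    n_each <- vapply(genes[[col]], nrow, integer(1))
    if (sum(n_each) == 0) {
      return(rep(FALSE, nrow(sites)))
    }
    sub <- bind_rows(genes[[col]])
    hit_any(sub$start, sub$end - 1L, rep(genes$chrom, n_each))
  }
  prom_lo <- ifelse(plus, genes$tss - promoter_window[1],
                    genes$tss - promoter_window[2])
  prom_hi <- ifelse(plus, genes$tss + promoter_window[2],
                    genes$tss + promoter_window[1])
  down_lo <- ifelse(plus, genes$end, genes$start - downstream_window)
  down_hi <- ifelse(plus, genes$end + downstream_window - 1L,
                    genes$start - 1L)
  in_prom <- hit_any(prom_lo, prom_hi, genes$chrom)
  in_utr5 <- flat_sub("utr5")
  in_utr3 <- flat_sub("utr3")
  in_body <- hit_any(genes$start, genes$end - 1L, genes$chrom)
  in_down <- hit_any(down_lo, down_hi, genes$chrom)
  category <- dplyr::case_when(
    in_prom ~ "promoter",
    in_utr5 ~ "five_prime_utr",
    in_utr3 ~ "three_prime_utr",
    in_body ~ "gene_body",
    in_down ~ "downstream",
    .default = "intergenic"
  )
  # nearest TSS, ties on smaller gene_id
  nearest_gene <- rep(NA_character_, nrow(sites))
  tss_distance <- rep(NA_integer_, nrow(sites))
  for (ch in unique(sites$chrom)) {
    g <- which(genes$chrom == ch)
    si <- which(sites$chrom == ch)
    if (length(g) == 0 || length(si) == 0) next
    sign_g <- ifelse(genes$strand[g] == "+", 1L, -1L)
    ord_ids <- genes$gene_id[g]
    for (i in si) {
      d <- (mids[i] - genes$tss[g]) * sign_g
      k <- order(abs(d), ord_ids)[1]
      nearest_gene[i] <- ord_ids[k]
      tss_distance[i] <- as.integer(d[k])
    }
  }
  tibble(site_id = sites$site_id,
         category = factor(category, levels = CATEGORY_LEVELS),
         nearest_gene = nearest_gene,
         tss_distance = tss_distance)
}

#' Regulatory domains under the basal-plus-extension model
#'
#' Basal domain: TSS - `basal_up` to TSS + `basal_down` in strand
#' orientation. Each side is then extended up to `max_extension` bp from
#' the TSS but never into a neighbouring gene's basal domain.
#' @noRd
regulatory_domains <- function(genes, basal_up = 5000L, basal_down = 1000L,
                               max_extension = 1000000L) {
  plus <- genes$strand == "+"
  basal_lo <- ifelse(plus, genes$tss - basal_up, genes$tss - basal_down)
  basal_hi <- ifelse(plus, genes$tss + basal_down, genes$tss + basal_up)
  dom_lo <- numeric(nrow(genes))
  dom_hi <- numeric(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    same <- which(genes$chrom == genes$chrom[i])
    same <- setdiff(same, i)
    left_walls <- basal_hi[same][basal_hi[same] <= basal_lo[i]]
    right_walls <- basal_lo[same][basal_lo[same] >= basal_hi[i]]
    ext_lo <- max(genes$tss[i] - max_extension,
                  if (length(left_walls)) max(left_walls) + 1 else -Inf)
    ext_hi <- min(genes$tss[i] + max_extension,
                  if (length(right_walls)) min(right_walls) - 1 else Inf)
    dom_lo[i] <- min(basal_lo[i], max(ext_lo, 0))
    dom_hi[i] <- max(basal_hi[i], ext_hi)
  }
  tibble(gene_id = genes$gene_id, chrom = genes$chrom,
         domain_lo = dom_lo, domain_hi = dom_hi,
         basal_lo = basal_lo, basal_hi = basal_hi)
}

#' Associate sites with genes (basal plus extension)
#'
#' A site is associated with every gene whose regulatory domain contains
#' the site midpoint; multiple genes per site are allowed. Defaults (5 kb
#' upstream / 1 kb downstream basal domain, up to 1 Mb extension) are the
#' published defaults of the GREAT basal-plus-extension model.
#'
#' @param sites Site tibble (`site_id`, `chrom`, `start`, `end`).
#' @param genes Gene tibble from [read_gtf()].
#' @param basal_up,basal_down Basal domain extent upstream/downstream of
#'   the TSS, in strand orientation (defaults 5000 and 1000).
#' @param max_extension Maximum extension from the TSS per side
#'   (default 1e6).
#' @return Long tibble `site_id`, `gene_id`, one row per association.
#' @export
associate_genes <- function(sites, genes, basal_up = 5000L,
                            basal_down = 1000L, max_extension = 1000000L) {
  dom <- regulatory_domains(genes, basal_up, basal_down, max_extension)
  mids <- site_midpoint(sites$start, sites$end)
  res <- lapply(seq_len(nrow(sites)), function(i) {
    d <- dom[dom$chrom == sites$chrom[i] &
               dom$domain_lo <= mids[i] & dom$domain_hi >= mids[i], ]
    if (nrow(d) == 0) return(NULL)
    tibble(site_id = sites$site_id[i], gene_id = sort(d$gene_id))
  })
  out <- bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble(site_id = character(), gene_id = character()))
  }
  out
}

#' Count and fraction of sites overlapping another interval set
#'
#' @param sites_a,sites_b Interval tibbles. Overlap means >= 1 shared base.
#' @return One-row tibble `n_overlap`, `fraction` (`NaN` with a warning
#'   when `sites_a` is empty).
#' @export
overlap_fraction <- function(sites_a, sites_b) {
  if (nrow(sites_a) == 0) {
    warn("empty site list; overlap fraction undefined")
    return(tibble(n_overlap = 0L, fraction = NaN))
  }
  n <- if (nrow(sites_b) == 0) 0L else {
    sum(GenomicRanges::countOverlaps(as_gr(sites_a), as_gr(sites_b),
                                     ignore.strand = TRUE) > 0)
  }
  tibble(n_overlap = as.integer(n), fraction = n / nrow(sites_a))
}
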