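# Linking site classes to transcriptional responsiveness: deregulated-gene
# calling (|log2FC| > 1 and adjusted p < 0.05, strict), the
# "both static and dynamic => dynamic" gene-class rule, hypergeometric
# enrichment, and the median split of sites by binding strength.

#' Call deregulated genes
#'
#' `up` iff log2FC > `log2fc_cutoff` and padj < `padj_cutoff`; `down` iff
#' log2FC < `-log2fc_cutoff` and padj < `padj_cutoff`; otherwise `ns`.
#' Inequalities are strict; missing padj gives `ns`.
#'
#' @param table Per-gene tibble with `gene_id`, `log2fc`, `padj`.
#' @param log2fc_cutoff Absolute log2 fold-change cutoff (default 1).
#' @param padj_cutoff Adjusted p-value cutoff (default 0.05).
#' @return The input with a `status` column in `up` / `down` / `ns`.
#' @export
classify_deregulated <- function(table, log2fc_cutoff = 1,
                                 padj_cutoff = 0.05) {
  sig <- !is.na(table$padj) & table$padj < padj_cutoff
  status <- dplyr::case_when(
    sig & table$log2fc > log2fc_cutoff ~ "up",
    sig & table$log2fc < -log2fc_cutoff ~ "down",
    .default = "ns"
  )
  mutate(as_tibble(table), status = factor(status,
                                           levels = c("up", "down", "ns")))
}

#' Assign genes a binding class from their associated sites
#'
#' A gene is `dynamic` when at least one associated site is dynamic (even
#' if it also has static sites), `static` when it has associated sites and
#' none is dynamic, and `unassociated` otherwise.
#'
#' @param associations Tibble `site_id`, `gene_id` from
#'   [associate_genes()].
#' @param site_labels Tibble `site_id`, `label` from [classify_sites()];
#'   must cover every associated site.
#' @param universe Optional character vector of gene ids; genes without
#'   associations are returned as `unassociated`.
#' @return Tibble `gene_id`, `gene_class`.
#' @export
assign_gene_class <- function(associations, site_labels, universe = NULL) {
  missing_sites <- setdiff(associations$site_id, site_labels$site_id)
  if (length(missing_sites) > 0) {
    abort(paste0("association references unlabeled site(s): ",
                 paste(head(missing_sites, 5), collapse = ", ")))
  }
  cls <- associations |>
    left_join(select(site_labels, "site_id", "label"), by = "site_id") |>
    group_by(.data$gene_id) |>
    summarise(gene_class = if_else(any(.data$label == "dynamic"),
                                   "dynamic", "static"),
              .groups = "drop")
  if (!is.null(universe)) {
    rest <- setdiff(universe, cls$gene_id)
    cls <- bind_rows(cls, tibble(gene_id = rest,
                                 gene_class = "unassociated"))
  }
  mutate(cls, gene_class = factor(.data$gene_class,
                                  levels = c("dynamic", "static",
                                             "unassociated"))) |>
    arrange(.data$gene_id)
}

#' Hypergeometric enrichment of deregulated genes in a gene group
#'
#' Upper-tail test of drawing at least the observed number of deregulated
#' genes when sampling `|group|` genes from the universe without
#' replacement.
#'
#' @param group_genes Character vector, the gene group (must be contained
#'   in `universe`).
#' @param deregulated Character vector of deregulated genes (contained in
#'   `universe`).
#' @param universe Character vector, the gene universe.
#' @param group_name Label carried into the result (default `"group"`).
#' @return One-row tibble `group_name`, `n_group`, `n_overlap`,
#'   `expected`, `fold_enrichment`, `p_value`.
#' @export
hypergeom_enrichment <- function(group_genes, deregulated, universe,
                                 group_name = "group") {
  group_genes <- unique(group_genes)
  deregulated <- unique(deregulated)
  universe <- unique(universe)
  if (length(universe) == 0) abort("empty universe")
  if (length(setdiff(group_genes, universe)) > 0) {
    abort("group genes must be a subset of the universe")
  }
  if (length(setdiff(deregulated, universe)) > 0) {
    abort("deregulated genes must be a subset of the universe")
  }
  N <- length(universe)
  K <- length(deregulated)
  n <- length(group_genes)
  obs <- length(intersect(group_genes, deregulated))
  p <- phyper(obs - 1, K, N - K, n, lower.tail = FALSE)
  expected <- n * K / N
  tibble(group_name = group_name, n_group = n, n_overlap = obs,
         expected = expected,
         fold_enrichment = if (n > 0 && K > 0) (obs / n) / (K / N) else 0,
         p_value = p)
}

#' Split sites at the median binding strength
#'
#' Top half strictly above the median `norm_score`; sites at or below the
#' median (including exact ties) go to the bottom half.
#'
#' @param sites Tibble with `site_id` and `norm_score`
#'   (from [build_consensus()]).
#' @return Named list `top`, `bottom` of site-id character vectors.
#' @export
median_split <- function(sites) {
  if (nrow(sites) < 2) abort("median_split needs at least 2 sites")
  med <- median(sites$norm_score)
  top <- sites$site_id[sites$norm_score > med]
  if (length(top) == 0) {
    warn("all sites at or below the median score; top half is empty")
  }
  list(top = top, bottom = setdiff(sites$site_id, top))
}
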