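# Self-contained synthetic dataset with planted ground truth: a random
# genome with gene models, replicate peak calls with heterogeneous
# p-values (per-replicate dropout plus Poisson background, so the k-of-n
# consensus rule is exercised), negative-binomial site counts with a
# planted fold change at dynamic sites, class-conditional motif planting
# and placement, and expression changes coupled to genes near dynamic
# sites.

#' Generator configuration
#'
#' Defaults emulate the structure of the Beko RBPJ experiment at desk
#' scale: 3,500 sites of which ~10% are dynamic, dynamic binding lost at
#' log2FC -1 under GSI, negative-binomial counts at mean depth 80 with
#' dispersion 0.05 over 3+3 replicates, stronger peak p-values at dynamic
#' sites, dynamic sites preferentially distal and RBPJ-motif-marked,
#' static sites promoter-proximal and SP1-marked, and deregulation coupled
#' to dynamic-site-associated genes (0.6 vs 0.1 background).
#'
#' @param seed Integer seed; the entire bundle is a deterministic function
#'   of the configuration.
#' @param n_chroms,chrom_length,n_genes,n_sites,site_width Genome layout.
#' @param frac_dynamic Fraction of sites planted dynamic (default 0.10).
#' @param dynamic_log2fc Planted treatment effect at dynamic sites
#'   (default -1).
#' @param nb_mean_depth,nb_dispersion Negative-binomial count model
#'   (defaults 80 and 0.05).
#' @param min_site_depth Floor on the per-site mean control depth
#'   (default 50), keeping every simulated site at adequate coverage.
#' @param n_replicates Count replicates per condition (default 3).
#' @param n_peak_replicates Peak-call replicates (default 5; consensus
#'   uses 3-of-5).
#' @param peak_dropout Per-replicate probability of missing a true site
#'   (default 0.15).
#' @param background_peaks_per_replicate Poisson mean of spurious peaks
#'   per replicate (default 200).
#' @param pvalue_base Mean `-log10 p` of static-site peaks (default 7).
#' @param pvalue_offset_dynamic Extra `-log10 p` strength at dynamic sites
#'   (default 4).
#' @param motif_probs_dynamic Named probabilities of planting `canonical`,
#'   `degenerate` (only) or `dimer` motifs at dynamic sites.
#' @param motif_probs_static Named probabilities of planting `sp1` or
#'   `canonical` at static sites.
#' @param placement_proximal_static Probability a static site is placed
#'   promoter-proximal (default 0.7).
#' @param placement_distal_dynamic Probability a dynamic site is placed
#'   TSS-distal (default 0.8).
#' @param proximal_max_tss,distal_min_tss Proximal/distal placement bounds
#'   in bp from the nearest TSS.
#' @param coupling_dynamic,coupling_background Deregulation probability
#'   for genes coupled to a dynamic site vs background.
#' @return A validated configuration list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 4L,
                       chrom_length = 2000000L,
                       n_genes = 1200L,
                       gene_region_frac = 0.6,
                       n_sites = 3500L,
                       site_width = 300L,
                       frac_dynamic = 0.10,
                       dynamic_log2fc = -1.0,
                       nb_mean_depth = 80,
                       min_site_depth = 50,
                       nb_dispersion = 0.05,
                       n_replicates = 3L,
                       n_peak_replicates = 5L,
                       peak_dropout = 0.15,
                       background_peaks_per_replicate = 200,
                       pvalue_base = 7,
                       pvalue_offset_dynamic = 4,
                       motif_probs_dynamic = c(canonical = 0.6,
                                               degenerate = 0.2,
                                               dimer = 0.15),
                       motif_probs_static = c(sp1 = 0.5, canonical = 0.15),
                       placement_proximal_static = 0.7,
                       placement_distal_dynamic = 0.8,
                       proximal_max_tss = 1000L,
                       distal_min_tss = 10000L,
                       coupling_dynamic = 0.6,
                       coupling_background = 0.1) {
  cfg <- as.list(environment())
  probs <- c(frac_dynamic, peak_dropout, placement_proximal_static,
             placement_distal_dynamic, coupling_dynamic,
             coupling_background, motif_probs_dynamic, motif_probs_static)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (frac_dynamic <= 0 || frac_dynamic >= 1) {
    abort("frac_dynamic must lie in (0, 1)")
  }
  if (sum(motif_probs_dynamic) > 1 || sum(motif_probs_static) > 1) {
    abort("class-conditional motif probabilities must sum to <= 1")
  }
  if (gene_region_frac <= 0 || gene_region_frac >= 1) {
    abort("gene_region_frac must lie in (0, 1)")
  }
  # rough capacity check at the ~700 bp minimum site spacing: each chrom
  # carries a dense gene region followed by a gene desert where
  # TSS-distal sites live
  min_gap <- 700
  prox_need <- n_sites * (1 - frac_dynamic) * placement_proximal_static
  prox_cap <- n_genes * 2 * proximal_max_tss / min_gap
  distal_need <- n_sites * frac_dynamic * placement_distal_dynamic
  distal_cap <- n_chroms *
    max(0, chrom_length * (1 - gene_region_frac) - distal_min_tss) / min_gap
  if (prox_need > 0.8 * prox_cap || distal_need > 0.8 * distal_cap ||
      n_sites * min_gap > 0.8 * n_chroms * chrom_length) {
    abort("site count exceeds placeable positions for this genome layout")
  }
  structure(cfg, class = "sim_config")
}

#' @noRd
random_chrom_raw <- function(len) {
  sample(charToRaw("ACGT"), len, replace = TRUE)
}

#' Gene models on a dense gene region per chromosome; the remaining
#' chromosome tail is a gene desert where TSS-distal sites can live.
#' @noRd
sim_genes <- function(cfg) {
  per_chrom <- diff(round(seq(0, cfg$n_genes, length.out = cfg$n_chroms + 1)))
  res <- list()
  idx <- 0L
  for (ci in seq_len(cfg$n_chroms)) {
    gpc <- per_chrom[ci]
    if (gpc == 0) next
    region <- floor(cfg$chrom_length * cfg$gene_region_frac)
    slot <- floor(region / gpc)
    if (slot < 2500) abort("gene region too small for this many genes")
    for (j in seq_len(gpc)) {
      idx <- idx + 1L
      slot_start <- (j - 1L) * slot
      glen <- as.integer(round(runif(1, 1500, min(slot - 1000L, 8000L))))
      gstart <- as.integer(slot_start +
        round(runif(1, 200, max(300, slot - glen - 200L))))
      gend <- as.integer(min(gstart + glen, cfg$chrom_length - 1L))
      strand <- sample(c("+", "-"), 1)
      exlen <- min(400L, floor(glen / 3))
      exons <- tibble(start = c(gstart, gend - exlen),
                      end = c(gstart + exlen, gend))
      res[[idx]] <- tibble(
        gene_id = sprintf("gene_%04d", idx),
        chrom = sprintf("chr%d", ci),
        start = gstart, end = gend, strand = strand,
        tss = if (strand == "+") gstart else gend - 1L,
        exons = list(exons),
        utr5 = list(tibble(start = integer(), end = integer())),
        utr3 = list(tibble(start = integer(), end = integer()))
      )
    }
  }
  bind_rows(res)
}

#' @noRd
sim_site_positions <- function(cfg, genes) {
  n <- cfg$n_sites
  is_dynamic <- runif(n) < cfg$frac_dynamic
  placement <- ifelse(is_dynamic,
    ifelse(runif(n) < cfg$placement_distal_dynamic, "distal", "random"),
    ifelse(runif(n) < cfg$placement_proximal_static, "proximal", "random"))
  chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
  tss_by_chrom <- split(genes$tss, factor(genes$chrom, levels = chroms))
  occupied <- stats::setNames(vector("list", cfg$n_chroms), chroms)
  min_gap <- 700L
  half <- as.integer(cfg$site_width %/% 2)
  lo <- cfg$site_width
  hi <- cfg$chrom_length - cfg$site_width
  site_chrom <- character(n)
  site_mid <- integer(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(300L)) {
      if (placement[i] == "proximal") {
        g <- sample.int(nrow(genes), 1)
        chrom <- genes$chrom[g]
        mid <- genes$tss[g] +
          as.integer(round(runif(1, -cfg$proximal_max_tss,
                                 cfg$proximal_max_tss)))
      } else if (placement[i] == "distal") {
        # gene desert: past the gene region plus the distal margin
        chrom <- sample(chroms, 1)
        desert_lo <- floor(cfg$chrom_length * cfg$gene_region_frac) +
          cfg$distal_min_tss
        mid <- as.integer(round(runif(1, desert_lo, hi)))
        tss <- tss_by_chrom[[chrom]]
        if (length(tss) > 0 && min(abs(mid - tss)) < cfg$distal_min_tss) {
          next
        }
      } else {
        chrom <- sample(chroms, 1)
        mid <- as.integer(round(runif(1, lo, hi)))
      }
      mid <- max(lo, min(hi, mid))
      occ <- occupied[[chrom]]
      if (is.null(occ) || !any(abs(occ - mid) < min_gap)) {
        occupied[[chrom]] <- c(occ, mid)
        site_chrom[i] <- chrom
        site_mid[i] <- mid
        placed <- TRUE
        break
      }
    }
    if (!placed) abort("site count exceeds placeable positions")
  }
  tibble(
    site_id = sprintf("tsite_%04d", seq_len(n)),
    chrom = site_chrom,
    start = as.integer(site_mid - half),
    end = as.integer(site_mid - half + cfg$site_width),
    mid = site_mid,
    label = factor(if_else(is_dynamic, "dynamic", "static"),
                   levels = LABEL_LEVELS),
    placement = placement
  )
}

#' Plant motifs by batch raw-vector edits (one subassignment per chrom).
#' @noRd
plant_motifs <- function(cfg, genome_raw, sites) {
  n <- nrow(sites)
  dyn <- sites$label == "dynamic"
  pick <- function(probs, n) {
    u <- runif(n)
    cum <- cumsum(probs)
    out <- rep("none", n)
    for (k in rev(seq_along(probs))) out[u < cum[k]] <- names(probs)[k]
    out
  }
  outcome <- character(n)
  outcome[dyn] <- pick(cfg$motif_probs_dynamic, sum(dyn))
  outcome[!dyn] <- pick(cfg$motif_probs_static, sum(!dyn))
  edits <- list()
  add_edit <- function(chrom, pos0, text) {
    edits[[length(edits) + 1L]] <<- list(chrom = chrom, pos0 = pos0,
                                         bytes = charToRaw(text))
  }
  for (i in seq_len(n)) {
    m <- sites$mid[i]
    ch <- sites$chrom[i]
    switch(outcome[i],
      canonical = add_edit(ch, m - 3L, "TGGGAA"),
      degenerate = add_edit(ch, m - 3L, "TGAGAA"),
      dimer = {
        add_edit(ch, m - 14L, "TGGGAA")
        add_edit(ch, m + 8L, "TTCCCA")  # spacer of 16 nt, head-to-head
      },
      sp1 = add_edit(ch, m - 4L, "GGGGCGGGG"),
      none = NULL)
  }
  for (ch in names(genome_raw)) {
    e <- edits[vapply(edits, function(x) x$chrom == ch, logical(1))]
    if (length(e) == 0) next
    idx <- unlist(lapply(e, function(x) x$pos0 + seq_along(x$bytes)))
    val <- unlist(lapply(e, function(x) x$bytes))
    genome_raw[[ch]][idx] <- val
  }
  list(
    genome_raw = genome_raw,
    flags = tibble(
      site_id = sites$site_id,
      planted_canonical = outcome %in% c("canonical", "dimer"),
      planted_degenerate = outcome %in% c("canonical", "degenerate", "dimer"),
      planted_dimer = outcome == "dimer",
      planted_sp1 = outcome == "sp1"
    )
  )
}

#' @noRd
sim_peaks <- function(cfg, sites, strength) {
  reps <- list()
  for (r in seq_len(cfg$n_peak_replicates)) {
    present <- runif(nrow(sites)) >= cfg$peak_dropout
    s <- sites[present, , drop = FALSE]
    neglog <- pmax(2, strength[present] + rnorm(sum(present)))
    true_pk <- tibble(
      chrom = s$chrom,
      start = pmax(0L, s$start - as.integer(round(runif(sum(present), 0, 100)))),
      end = s$end + as.integer(round(runif(sum(present), 0, 100))),
      p_value = 10^(-neglog)
    )
    n_bg <- rpois(1, cfg$background_peaks_per_replicate)
    bg_start <- as.integer(round(runif(n_bg, 0, cfg$chrom_length - 400)))
    bg <- tibble(
      chrom = sample(sprintf("chr%d", seq_len(cfg$n_chroms)), n_bg,
                     replace = TRUE),
      start = bg_start,
      end = bg_start + 300L,
      p_value = 10^(-runif(n_bg, 2.5, 6.5))
    )
    reps[[r]] <- mutate(bind_rows(true_pk, bg),
                        replicate = sprintf("rep%d", r))
  }
  bind_rows(reps)
}

#' @noRd
sim_counts <- function(cfg, sites) {
  n <- nrow(sites)
  dyn <- sites$label == "dynamic"
  # site strengths vary lognormally around the configured depth, floored
  # so every site keeps adequate coverage; dynamic sites bind stronger
  mu_control <- pmax(cfg$min_site_depth,
                     cfg$nb_mean_depth * exp(rnorm(n, 0, 0.3)) *
                       ifelse(dyn, 1.3, 1))
  mu_gsi <- mu_control * ifelse(dyn, 2^cfg$dynamic_log2fc, 1)
  samples <- tibble(
    sample_id = c(sprintf("control_%d", seq_len(cfg$n_replicates)),
                  sprintf("GSI_%d", seq_len(cfg$n_replicates))),
    condition = rep(c("control", "GSI"), each = cfg$n_replicates),
    replicate = rep(seq_len(cfg$n_replicates), 2)
  )
  lib <- exp(rnorm(nrow(samples), 0, 0.2))
  counts <- tibble(site_id = sites$site_id)
  for (j in seq_len(nrow(samples))) {
    mu <- if (samples$condition[j] == "control") mu_control else mu_gsi
    counts[[samples$sample_id[j]]] <-
      rnbinom(n, mu = mu * lib[j], size = 1 / cfg$nb_dispersion)
  }
  list(counts = counts, samples = samples, mu_control = mu_control)
}

#' @noRd
sim_expression <- function(cfg, genes, sites) {
  dyn_sites <- sites[sites$label == "dynamic", , drop = FALSE]
  coupled <- rep(FALSE, nrow(genes))
  for (i in seq_len(nrow(dyn_sites))) {
    g <- which(genes$chrom == dyn_sites$chrom[i])
    if (length(g) == 0) next
    d <- abs(dyn_sites$mid[i] - genes$tss[g])
    j <- g[which.min(d)]
    if (min(d) <= 200000) coupled[j] <- TRUE
  }
  p_dereg <- ifelse(coupled, cfg$coupling_dynamic, cfg$coupling_background)
  dereg <- runif(nrow(genes)) < p_dereg
  down <- runif(nrow(genes)) < 0.8  # Notch targets mostly lose expression
  log2fc <- ifelse(dereg,
                   ifelse(down, -1, 1) * (1 + rexp(nrow(genes), 1)),
                   rnorm(nrow(genes), 0, 0.4))
  padj <- ifelse(dereg, runif(nrow(genes), 1e-6, 0.049),
                 runif(nrow(genes), 0.05, 1))
  list(
    expression = tibble(gene_id = genes$gene_id, log2fc = log2fc,
                        padj = padj),
    truth_genes = tibble(gene_id = genes$gene_id, coupled = coupled,
                         deregulated = dereg)
  )
}

#' Generate a synthetic analysis bundle
#'
#' Produces, from a single seed, every input the pipeline consumes plus
#' the planted truth: genome sequence (motifs physically written in),
#' gene models, per-replicate peak calls with p-values, a site-by-sample
#' count table, an expression table, and per-site / per-gene truth.
#'
#' @param config A [sim_config()] object.
#' @return A named list: `config`, `genome`
#'   ([Biostrings::DNAStringSet]), `genes`, `peaks`, `counts`, `samples`,
#'   `expression`, `truth_sites`, `truth_genes`.
#' @examples
#' bundle <- simulate_bundle(sim_config(seed = 1, n_chroms = 1,
#'   chrom_length = 200000, n_genes = 12, n_sites = 60))
#' @export
simulate_bundle <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    genome_raw <- stats::setNames(
      lapply(seq_len(config$n_chroms),
             function(i) random_chrom_raw(config$chrom_length)),
      sprintf("chr%d", seq_len(config$n_chroms)))
    genes <- sim_genes(config)
    sites <- sim_site_positions(config, genes)
    planted <- plant_motifs(config, genome_raw, sites)
    strength <- config$pvalue_base + rexp(nrow(sites), 1 / 2) +
      ifelse(sites$label == "dynamic", config$pvalue_offset_dynamic, 0)
    peaks <- sim_peaks(config, sites, strength)
    cnt <- sim_counts(config, sites)
    expr <- sim_expression(config, genes, sites)
    truth_sites <- sites |>
      select("site_id", "chrom", "start", "end", "label", "placement") |>
      left_join(planted$flags, by = "site_id") |>
      mutate(planted_log2fc = if_else(.data$label == "dynamic",
                                      config$dynamic_log2fc, 0),
             base_neglog10_p = strength,
             mu_control = cnt$mu_control)
    list(
      config = config,
      genome = Biostrings::DNAStringSet(
        vapply(planted$genome_raw, rawToChar, character(1))),
      genes = genes,
      peaks = peaks,
      counts = cnt$counts,
      samples = cnt$samples,
      expression = expr$expression,
      truth_sites = truth_sites,
      truth_genes = expr$truth_genes
    )
  })
}

#' Write a synthetic bundle to standard-format files
#'
#' Emits genome FASTA, gene GTF, one narrowPeak per replicate (column 8
#' carries `-log10 p`), and TSVs for counts, sample sheet, expression and
#' truth.
#'
#' @param bundle From [simulate_bundle()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_fasta(bundle$genome, fp("genome.fa"))
  write_gtf(bundle$genes, fp("genes.gtf"))
  for (r in unique(bundle$peaks$replicate)) {
    pk <- bundle$peaks[bundle$peaks$replicate == r, ]
    lines <- sprintf("%s\t%d\t%d\tpeak_%d\t0\t.\t0\t%.6g\t-1\t-1",
                     pk$chrom, pk$start, pk$end, seq_len(nrow(pk)),
                     -log10(pk$p_value))
    readr::write_lines(lines, fp(sprintf("peaks_%s.narrowPeak", r)))
  }
  readr::write_tsv(bundle$counts, fp("counts.tsv"))
  readr::write_tsv(bundle$samples, fp("samples.tsv"))
  readr::write_tsv(bundle$expression, fp("expression.tsv"))
  readr::write_tsv(bundle$truth_sites, fp("truth_sites.tsv"))
  readr::write_tsv(bundle$truth_genes, fp("truth_genes.tsv"))
  invisible(dir)
}

#' Match consensus sites to planted truth sites
#'
#' Overlap join (>= 1 bp) between consensus intervals and truth
#' intervals; when a consensus site overlaps several truth sites the
#' largest overlap wins. Consensus sites without a truth match (background
#' artifacts) get `NA`.
#'
#' @param consensus Tibble from [build_consensus()].
#' @param truth_sites Tibble from [simulate_bundle()].
#' @return `consensus` plus `truth_id` and `truth_label`.
#' @export
match_truth <- function(consensus, truth_sites) {
  hits <- GenomicRanges::findOverlaps(as_gr(consensus), as_gr(truth_sites),
                                      ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  ov <- pmin(consensus$end[q], truth_sites$end[s]) -
    pmax(consensus$start[q], truth_sites$start[s])
  best <- tibble(q = q, s = s, ov = ov) |>
    group_by(.data$q) |>
    slice(which.max(.data$ov)) |>
    ungroup()
  truth_id <- rep(NA_character_, nrow(consensus))
  truth_label <- rep(NA_character_, nrow(consensus))
  truth_id[best$q] <- truth_sites$site_id[best$s]
  truth_label[best$q] <- as.character(truth_sites$label[best$s])
  mutate(consensus, truth_id = truth_id,
         truth_label = factor(truth_label, levels = LABEL_LEVELS))
}

#' Compare predicted labels with planted truth
#'
#' @param predicted Tibble `site_id`, `label` (optionally `p_dynamic` for
#'   an AUC).
#' @param truth Tibble `site_id`, `label` (e.g. `truth_sites` renamed, or
#'   any labeled reference). Ids must match exactly.
#' @return One-row tibble `tp`, `fp`, `tn`, `fn`, `tpr`, `fpr`,
#'   `accuracy`, `auc` (NA without probabilities). Dynamic is the positive
#'   class.
#' @export
truth_compare <- function(predicted, truth) {
  if (length(setdiff(predicted$site_id, truth$site_id)) > 0 ||
      length(setdiff(truth$site_id, predicted$site_id)) > 0) {
    abort("site_id mismatch between predictions and truth")
  }
  m <- inner_join(select(predicted, "site_id", "label",
                         dplyr::any_of("p_dynamic")),
                  select(rename(truth, truth = "label"),
                         "site_id", "truth"),
                  by = "site_id")
  pos <- m$truth == "dynamic"
  pred_pos <- m$label == "dynamic"
  tp <- sum(pos & pred_pos); fn <- sum(pos & !pred_pos)
  fp <- sum(!pos & pred_pos); tn <- sum(!pos & !pred_pos)
  auc <- if ("p_dynamic" %in% names(m) && any(pos) && any(!pos)) {
    r <- rank(m$p_dynamic)
    (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
  } else NA_real_
  tibble(tp = tp, fp = fp, tn = tn, fn = fn,
         tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
         accuracy = (tp + tn) / nrow(m),
         auc = auc)
}

#' Run the binding pipeline on a synthetic bundle
#'
#' Chains consensus building, truth matching, dynamics classification,
#' motif flagging, annotation and feature assembly on an in-memory bundle.
#' Consensus sites without count data (background artifacts surviving the
#' replicate filter, normally none) are dropped.
#'
#' @param bundle From [simulate_bundle()].
#' @param min_support,weak_w,stringent_s Consensus parameters.
#' @param contrast,cutoff Dynamics parameters.
#' @return Named list `consensus` (with truth columns), `dynamics`,
#'   `flags`, `annotations`, `features` (feature table with `label` from
#'   the observed dynamics and `truth` from the planted labels).
#' @export
run_pipeline <- function(bundle, min_support = 3L, weak_w = 1e-6,
                         stringent_s = 1e-10,
                         contrast = "GSI_vs_control", cutoff = 0.5) {
  cons <- build_consensus(bundle$peaks, min_support = min_support,
                          weak_w = weak_w, stringent_s = stringent_s)
  matched <- match_truth(cons, bundle$truth_sites)
  keep <- !is.na(matched$truth_id)
  cons <- matched[keep, , drop = FALSE]
  cnt <- bundle$counts[match(cons$truth_id, bundle$counts$site_id), ]
  cnt$site_id <- cons$site_id
  dyn <- classify_sites(cnt, bundle$samples, contrast = contrast,
                        cutoff = cutoff)
  flags <- flag_sites(cons, bundle$genome)
  annot <- annotate_sites(cons, bundle$genes)
  feats <- build_feature_table(
    select(cons, "site_id", "chrom", "start", "end", "support",
           "combined_p", norm_score = "norm_score"),
    annot, flags, dyn)
  feats$truth <- cons$truth_label
  list(consensus = cons, dynamics = dyn, flags = flags,
       annotations = annot, features = feats)
}
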