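# Independent brute-force oracles. These deliberately share no code with
# the package internals: exhaustive position-by-position motif matching,
# union-find interval grouping, explicit regulatory-domain materialization,
# combinatorial hypergeometric enumeration, and pair-counting AUC.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

REVCOMP <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
             W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
             N = "N")

oracle_revcomp <- function(motif) {
  paste(rev(REVCOMP[strsplit(motif, "")[[1]]]), collapse = "")
}

# exhaustive scan: mismatch count at every offset on one strand
oracle_mismatches <- function(seq_chars, motif) {
  L <- nchar(motif)
  n_off <- length(seq_chars) - L + 1
  if (n_off < 1) return(integer(0))
  mset <- IUPAC_SETS[strsplit(motif, "")[[1]]]
  mm <- integer(n_off)
  for (k in seq_len(L)) {
    mm <- mm + !(seq_chars[k:(k + n_off - 1)] %in% mset[[k]])
  }
  mm
}

oracle_scan <- function(sequence, motif, max_mismatch = 0,
                        both_strands = TRUE) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  res <- list()
  mm <- oracle_mismatches(chars, motif)
  hit <- which(mm <= max_mismatch)
  if (length(hit) > 0) {
    res[[1]] <- data.frame(position = hit - 1L, strand = "+",
                           mismatches = mm[hit])
  }
  if (both_strands) {
    rc <- oracle_revcomp(motif)
    mm2 <- oracle_mismatches(chars, rc)
    hit2 <- which(mm2 <= max_mismatch)
    if (length(hit2) > 0) {
      res[[length(res) + 1]] <- data.frame(position = hit2 - 1L,
                                           strand = "-",
                                           mismatches = mm2[hit2])
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    return(data.frame(position = integer(), strand = character(),
                      mismatches = integer()))
  }
  out[order(out$position, match(out$strand, c("+", "-"))), , drop = FALSE]
}

oracle_dimers <- function(sequence, half_site = "TGGGAA", spacer_min = 15,
                          spacer_max = 17, max_total_mismatch = 2) {
  hits <- oracle_scan(sequence, half_site, max_total_mismatch, TRUE)
  plus <- hits[hits$strand == "+", , drop = FALSE]
  minus <- hits[hits$strand == "-", , drop = FALSE]
  L <- nchar(half_site)
  out <- list()
  for (i in seq_len(nrow(plus))) {
    for (j in seq_len(nrow(minus))) {
      sp <- minus$position[j] - (plus$position[i] + L)
      tot <- plus$mismatches[i] + minus$mismatches[j]
      if (sp >= spacer_min && sp <= spacer_max && tot <= max_total_mismatch) {
        out[[length(out) + 1]] <- data.frame(
          first_position = plus$position[i],
          second_position = minus$position[j],
          spacer = sp, total_mismatches = tot)
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    return(data.frame(first_position = integer(),
                      second_position = integer(), spacer = integer(),
                      total_mismatches = integer()))
  }
  res[order(res$first_position, res$second_position), , drop = FALSE]
}

# union-find transitive-closure grouping on >= 1 bp overlap (half-open)
oracle_group_overlaps <- function(chrom, start, end) {
  n <- length(start)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && chrom[i] == chrom[j] &&
          start[i] < end[j] && start[j] < end[i]) {
        parent[find(i)] <- find(j)
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# explicit basal-plus-extension domain for every gene, then containment
oracle_associations <- function(sites, genes, basal_up = 5000,
                                basal_down = 1000, max_extension = 1e6) {
  doms <- list()
  for (i in seq_len(nrow(genes))) {
    tss <- genes$tss[i]
    if (genes$strand[i] == "+") {
      blo <- tss - basal_up; bhi <- tss + basal_down
    } else {
      blo <- tss - basal_down; bhi <- tss + basal_up
    }
    lo <- max(tss - max_extension, 0)
    hi <- tss + max_extension
    for (j in seq_len(nrow(genes))) {
      if (j == i || genes$chrom[j] != genes$chrom[i]) next
      tssj <- genes$tss[j]
      if (genes$strand[j] == "+") {
        bloj <- tssj - basal_up; bhij <- tssj + basal_down
      } else {
        bloj <- tssj - basal_down; bhij <- tssj + basal_up
      }
      if (bhij <= blo) lo <- max(lo, bhij + 1)
      if (bloj >= bhi) hi <- min(hi, bloj - 1)
    }
    doms[[i]] <- c(min(blo, lo), max(bhi, hi))
  }
  out <- list()
  for (s in seq_len(nrow(sites))) {
    mid <- floor((sites$start[s] + sites$end[s]) / 2)
    for (i in seq_len(nrow(genes))) {
      if (genes$chrom[i] == sites$chrom[s] &&
          mid >= doms[[i]][1] && mid <= doms[[i]][2]) {
        out[[length(out) + 1]] <- data.frame(site_id = sites$site_id[s],
                                             gene_id = genes$gene_id[i])
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    return(data.frame(site_id = character(), gene_id = character()))
  }
  res[order(res$site_id, res$gene_id), , drop = FALSE]
}

oracle_hypergeom_upper <- function(N, K, n, obs) {
  ks <- obs:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

oracle_auc <- function(scores, labels) {
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  tot <- 0
  for (i in pos) {
    for (j in neg) {
      tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
  }
  tot / (length(pos) * length(neg))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
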