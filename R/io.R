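# Readers/writers for the standard formats and the single internal
# coordinate convention: 0-based, half-open, strand in {+, -, *}.

P_FLOOR <- 1e-300

#' Convert an interval tibble to GRanges
#'
#' Internal helper: tibbles store 0-based half-open intervals; GRanges is
#' 1-based closed, so start shifts by one.
#' @noRd
as_gr <- function(df) {
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
}

#' Read peak intervals from BED6 or narrowPeak
#'
#' Parses peak-caller output into the package's interval tibble. narrowPeak
#' stores `-log10(p)` in column 8; it is converted back to a p-value, with
#' p = 0 floored to `1e-300` so downstream log transforms stay finite.
#'
#' @param path Path to a BED6 or narrowPeak file.
#' @param dialect `"bed6"` (>= 3 columns; no p-value column, `p_value` is
#'   `NA`) or `"narrowPeak"` (10 columns, p in column 8 as -log10).
#' @return A tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open), `name`, `score`, `strand`, `p_value`. Input order is
#'   preserved.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t100\t200", "chr1\t300\t400"), f)
#' read_bed(f)
#' @export
read_bed <- function(path, dialect = c("bed6", "narrowPeak")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), score = numeric(), strand = character(),
                  p_value = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  min_cols <- if (dialect == "narrowPeak") 10L else 3L
  bad <- which(ncols < min_cols)
  if (length(bad) > 0) {
    abort(sprintf("malformed %s line %d: expected >= %d columns, got %d",
                  dialect, bad[1], min_cols, ncols[bad[1]]))
  }
  col <- function(i, default = NA_character_) {
    vapply(fields, function(x) if (length(x) >= i) x[i] else default,
           character(1))
  }
  start <- suppressWarnings(as.integer(col(2)))
  end <- suppressWarnings(as.integer(col(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    abort(sprintf("malformed line %d: non-integer coordinates", bad[1]))
  }
  bad <- which(start >= end)
  if (length(bad) > 0) {
    abort(sprintf("start >= end at line %d", bad[1]))
  }
  if (any(start < 0)) abort("negative start coordinate")
  name <- col(4)
  score <- suppressWarnings(as.numeric(col(5)))
  strand <- col(6)
  strand[!strand %in% c("+", "-")] <- "*"
  p_value <- if (dialect == "narrowPeak") {
    neglog10 <- suppressWarnings(as.numeric(col(8)))
    if (anyNA(neglog10)) abort("narrowPeak column 8 (-log10 p) not numeric")
    pmax(10^(-neglog10), P_FLOOR)
  } else {
    rep(NA_real_, length(lines))
  }
  tibble(chrom = col(1), start = start, end = end, name = name,
         score = score, strand = strand, p_value = p_value)
}

#' Write intervals as BED
#'
#' Inverse of [read_bed()] for well-formed input: coordinates and scores
#' round-trip exactly. Missing names/scores/strands are written as the BED
#' placeholders `.`, `0`, `.`.
#'
#' @param x Interval tibble with at least `chrom`, `start`, `end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  name <- if ("name" %in% names(x)) ifelse(is.na(x$name), ".", x$name) else "."
  score <- if ("score" %in% names(x)) {
    ifelse(is.na(x$score), "0", format(x$score, trim = TRUE, scientific = FALSE))
  } else "0"
  strand <- if ("strand" %in% names(x)) {
    ifelse(x$strand %in% c("+", "-"), x$strand, ".")
  } else "."
  readr::write_lines(
    paste(x$chrom, x$start, x$end, name, score, strand, sep = "\t"), path)
  invisible(path)
}

#' Read gene models from GTF
#'
#' Imports `gene` and `exon` features (plus `five_prime_utr` /
#' `three_prime_utr` when annotated) and converts GTF 1-based inclusive
#' coordinates to the internal 0-based half-open convention (start - 1, end
#' unchanged). The TSS is the gene start on `+` genes and `end - 1` on `-`
#' genes.
#'
#' @param path Path to a GTF file with `gene_id` attributes.
#' @return A tibble with one row per gene: `gene_id`, `chrom`, `start`,
#'   `end`, `strand`, `tss`, and list-columns `exons`, `utr5`, `utr3` of
#'   per-gene interval tibbles (`start`, `end`).
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  if (!"gene_id" %in% names(meta)) abort("GTF has no gene_id attributes")
  df <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(meta$type),
    gene_id = as.character(meta$gene_id)
  )
  keep <- c("gene", "exon", "five_prime_utr", "three_prime_utr", "5UTR", "3UTR")
  df <- df[df$type %in% keep, , drop = FALSE]
  df$type[df$type == "5UTR"] <- "five_prime_utr"
  df$type[df$type == "3UTR"] <- "three_prime_utr"
  if (anyNA(df$gene_id)) {
    abort("missing gene_id attribute on a gene/exon feature")
  }
  genes <- df[df$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0) abort("GTF contains no gene features")
  if (any(!genes$strand %in% c("+", "-"))) {
    abort(sprintf("unknown strand '%s' for gene %s",
                  genes$strand[!genes$strand %in% c("+", "-")][1],
                  genes$gene_id[!genes$strand %in% c("+", "-")][1]))
  }
  if (anyDuplicated(genes$gene_id)) {
    abort(sprintf("duplicated gene_id: %s",
                  genes$gene_id[duplicated(genes$gene_id)][1]))
  }
  sub_tbl <- function(type) {
    sub <- df[df$type == type, c("gene_id", "start", "end")]
    split(sub[c("start", "end")], factor(sub$gene_id, levels = genes$gene_id))
  }
  exons <- sub_tbl("exon")
  utr5 <- sub_tbl("five_prime_utr")
  utr3 <- sub_tbl("three_prime_utr")
  # validate exon containment
  for (i in seq_len(nrow(genes))) {
    ex <- exons[[i]]
    if (nrow(ex) > 0 &&
        (min(ex$start) < genes$start[i] || max(ex$end) > genes$end[i])) {
      abort(sprintf("exon outside gene span for gene %s", genes$gene_id[i]))
    }
  }
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  tibble(
    gene_id = genes$gene_id, chrom = genes$chrom,
    start = genes$start, end = genes$end, strand = genes$strand,
    tss = as.integer(tss),
    exons = lapply(exons, function(x) as_tibble(x[order(x$start), ])),
    utr5 = lapply(utr5, as_tibble),
    utr3 = lapply(utr3, as_tibble)
  )
}

#' Write gene models as GTF
#'
#' Inverse of [read_gtf()]: internal 0-based half-open intervals become GTF
#' 1-based inclusive (start + 1, end unchanged).
#'
#' @param genes Gene tibble as returned by [read_gtf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  fmt <- function(chrom, type, start, end, strand, gene_id) {
    sprintf("%s\tnotchdyn\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
            chrom, type, start + 1L, end, strand, gene_id)
  }
  lines <- character(0)
  for (i in seq_len(nrow(genes))) {
    lines <- c(lines, fmt(genes$chrom[i], "gene", genes$start[i],
                          genes$end[i], genes$strand[i], genes$gene_id[i]))
    ex <- genes$exons[[i]]
    if (!is.null(ex) && nrow(ex) > 0) {
      lines <- c(lines, fmt(genes$chrom[i], "exon", ex$start, ex$end,
                            genes$strand[i], genes$gene_id[i]))
    }
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a genome FASTA
#'
#' Sequences are uppercased; any character outside `A`, `C`, `G`, `T`, `N`
#' is rejected (the motif scanner assumes a 4-letter alphabet plus N).
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  freq <- Biostrings::alphabetFrequency(seqs)
  allowed <- c("A", "C", "G", "T", "N")
  extra <- colnames(freq)[colSums(freq) > 0]
  bad <- setdiff(extra, allowed)
  if (length(bad) > 0) {
    abort(paste0("sequence contains characters outside ACGTN: ",
                 paste(bad, collapse = ", ")))
  }
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write a genome FASTA
#' @param seqs A named [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Remove peaks overlapping a blacklist
#'
#' Drops every peak sharing at least one base with a blacklist interval
#' (half-open semantics: abutting intervals do not overlap). With an empty
#' blacklist the input is returned unchanged.
#'
#' @param peaks Interval tibble (`chrom`, `start`, `end`, ...).
#' @param blacklist Interval tibble of regions to exclude.
#' @return The subset of `peaks` with zero blacklist overlap, order
#'   preserved.
#' @export
filter_blacklist <- function(peaks, blacklist) {
  if (nrow(peaks) == 0 || is.null(blacklist) || nrow(blacklist) == 0) {
    return(peaks)
  }
  hits <- GenomicRanges::countOverlaps(as_gr(peaks), as_gr(blacklist),
                                       ignore.strand = TRUE)
  peaks[hits == 0, , drop = FALSE]
}
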