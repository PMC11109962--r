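# Motif content of binding sites: canonical RBPJ (TGGGAA), degenerate RBPJ
# (TGRGAA), SP1, and head-to-head RBPJ dimer (sequence-paired) sites with a
# 15-17 nt spacer and a total mismatch budget of two.

RBPJ_CANONICAL <- "TGGGAA"
RBPJ_DEGENERATE <- "TGRGAA"
SP1_CONSENSUS <- "GGGGCGGGG"

#' @noRd
as_dna <- function(sequence) {
  if (inherits(sequence, "DNAString")) return(sequence)
  Biostrings::DNAString(toupper(as.character(sequence)))
}

#' Scan a sequence for an IUPAC motif
#'
#' Reports every offset where the motif matches with at most `max_mismatch`
#' substitutions. IUPAC ambiguity codes in the motif are honoured (e.g. `R`
#' = A or G); `N` in the scanned sequence matches nothing, so each `N`
#' under the motif costs a mismatch. Minus-strand hits are matches of the
#' reverse complement, reported in plus-strand coordinates.
#'
#' @param sequence DNA string over ACGTN (character or
#'   [Biostrings::DNAString]).
#' @param motif IUPAC motif, length >= 4.
#' @param max_mismatch Maximum substitutions per hit (default 0).
#' @param both_strands Also scan the reverse complement (default TRUE).
#' @return Tibble `position` (0-based match start), `strand`, `mismatches`,
#'   `motif`, sorted by position then strand.
#' @examples
#' scan_iupac("TTGGGAAT", "TGGGAA")
#' @export
scan_iupac <- function(sequence, motif, max_mismatch = 0L,
                       both_strands = TRUE) {
  if (nchar(motif) < 4) abort("motif length must be >= 4")
  if (!grepl("^[ACGTUWSMKRYBDHVN]+$", toupper(motif))) {
    abort(paste0("invalid IUPAC code in motif: ", motif))
  }
  subj <- as_dna(sequence)
  pat <- Biostrings::DNAString(toupper(motif))
  empty <- tibble(position = integer(), strand = character(),
                  mismatches = integer(), motif = character())
  if (length(subj) < length(pat)) return(empty)
  hits_for <- function(p, strand) {
    m <- Biostrings::matchPattern(p, subj, max.mismatch = max_mismatch,
                                  fixed = "subject")
    # keep fully contained matches only (mismatch budgets otherwise admit
    # partial matches hanging over the sequence ends)
    st <- Biostrings::start(m)
    st <- st[st >= 1 & st + length(p) - 1 <= length(subj)]
    if (length(st) == 0) {
      return(tibble(position = integer(), strand = character(),
                    mismatches = integer(), motif = character()))
    }
    mm <- Biostrings::neditStartingAt(p, subj, starting.at = st,
                                      fixed = "subject")
    tibble(position = st - 1L, strand = strand,
           mismatches = as.integer(mm), motif = motif)
  }
  out <- hits_for(pat, "+")
  if (both_strands) {
    out <- bind_rows(out, hits_for(Biostrings::reverseComplement(pat), "-"))
  }
  out <- out[order(out$position, match(out$strand, c("+", "-"))), ]
  out
}

#' Find head-to-head RBPJ dimer (SPS) sites
#'
#' A sequence-paired site is a plus-strand half-site followed by a
#' minus-strand half-site (the reverse complement), facing each other with
#' `spacer_min`-`spacer_max` unconstrained nucleotides between the inner
#' edges of the two half-sites. By default up to two mismatches are allowed
#' in total across both half-sites.
#'
#' @param sequence DNA string over ACGTN.
#' @param half_site IUPAC half-site motif (default `TGGGAA`).
#' @param spacer_min,spacer_max Spacer bounds in nt (defaults 15 and 17).
#' @param max_total_mismatch Total mismatch budget across both half-sites
#'   (default 2).
#' @return Tibble `first_position`, `second_position` (0-based starts of
#'   the plus- and minus-strand half-sites), `spacer`,
#'   `first_mismatches`, `second_mismatches`, `total_mismatches`.
#' @examples
#' sps <- paste0("TGGGAA", strrep("C", 16), "TTCCCA")
#' find_head_to_head_dimers(sps)
#' @export
find_head_to_head_dimers <- function(sequence, half_site = RBPJ_CANONICAL,
                                     spacer_min = 15L, spacer_max = 17L,
                                     max_total_mismatch = 2L) {
  if (spacer_min < 0 || spacer_max < 0) abort("spacer bounds must be >= 0")
  if (spacer_min > spacer_max) abort("spacer_min must be <= spacer_max")
  len <- nchar(half_site)
  hits <- scan_iupac(sequence, half_site, max_mismatch = max_total_mismatch,
                     both_strands = TRUE)
  plus <- hits[hits$strand == "+", ]
  minus <- hits[hits$strand == "-", ]
  if (nrow(plus) == 0 || nrow(minus) == 0) {
    return(tibble(first_position = integer(), second_position = integer(),
                  spacer = integer(), first_mismatches = integer(),
                  second_mismatches = integer(), total_mismatches = integer()))
  }
  pairs <- tidyr::expand_grid(i = seq_len(nrow(plus)), j = seq_len(nrow(minus)))
  sp <- minus$position[pairs$j] - (plus$position[pairs$i] + len)
  tot <- plus$mismatches[pairs$i] + minus$mismatches[pairs$j]
  keep <- sp >= spacer_min & sp <= spacer_max & tot <= max_total_mismatch
  tibble(
    first_position = plus$position[pairs$i][keep],
    second_position = minus$position[pairs$j][keep],
    spacer = as.integer(sp[keep]),
    first_mismatches = plus$mismatches[pairs$i][keep],
    second_mismatches = minus$mismatches[pairs$j][keep],
    total_mismatches = as.integer(tot[keep])
  ) |> arrange(.data$first_position, .data$second_position)
}

#' Extract site sequences from a genome
#' @noRd
site_sequences <- function(sites, genome) {
  missing_chr <- setdiff(unique(sites$chrom), names(genome))
  if (length(missing_chr) > 0) {
    abort(paste0("site chromosome absent from genome: ",
                 paste(missing_chr, collapse = ", ")))
  }
  lens <- Biostrings::width(genome)[match(sites$chrom, names(genome))]
  bad <- which(sites$end > lens | sites$start < 0)
  if (length(bad) > 0) {
    abort(sprintf("site %s outside chromosome bounds",
                  sites$site_id[bad[1]]))
  }
  chars <- stats::setNames(as.character(genome), names(genome))
  seqs <- substr(chars[sites$chrom], sites$start + 1L, sites$end)
  Biostrings::DNAStringSet(unname(seqs))
}

#' Starts of fully contained vmatchPattern hits per sequence
#' @noRd
contained_starts <- function(mindex, widths, patlen) {
  lapply(seq_along(widths), function(i) {
    st <- Biostrings::start(mindex[[i]])
    st[st >= 1 & st + patlen - 1 <= widths[i]]
  })
}

#' Vectorized dimer presence over a DNAStringSet; one vmatchPattern pass
#' per strand, then a per-site spacer/mismatch pairing for sites carrying
#' hits on both strands.
#' @noRd
dimer_present <- function(seqs, half_site, spacer_min, spacer_max,
                          max_total_mismatch) {
  pat <- Biostrings::DNAString(toupper(half_site))
  rcp <- Biostrings::reverseComplement(pat)
  len <- length(pat)
  widths <- Biostrings::width(seqs)
  fwd <- contained_starts(
    Biostrings::vmatchPattern(pat, seqs, max.mismatch = max_total_mismatch,
                              fixed = "subject"), widths, len)
  rev <- contained_starts(
    Biostrings::vmatchPattern(rcp, seqs, max.mismatch = max_total_mismatch,
                              fixed = "subject"), widths, len)
  out <- rep(FALSE, length(seqs))
  cand <- which(lengths(fwd) > 0 & lengths(rev) > 0)
  for (i in cand) {
    fs <- fwd[[i]]
    rs <- rev[[i]]
    sp <- outer(rs, fs + len, "-")
    ok <- sp >= spacer_min & sp <= spacer_max
    if (!any(ok)) next
    fmm <- Biostrings::neditStartingAt(pat, seqs[[i]], starting.at = fs,
                                       fixed = "subject")
    rmm <- Biostrings::neditStartingAt(rcp, seqs[[i]], starting.at = rs,
                                       fixed = "subject")
    tot <- outer(rmm, fmm, "+")
    out[i] <- any(ok & tot <= max_total_mismatch)
  }
  out
}

#' Flag motif content per site
#'
#' Scans each site's sequence (both strands) for the SP1 consensus, the
#' canonical and degenerate RBPJ motifs, and head-to-head RBPJ dimer
#' sites. A flag is TRUE iff at least one qualifying hit occurs anywhere in
#' the site. Because TGGGAA matches TGRGAA, `has_rbpj_canonical` implies
#' `has_rbpj_degenerate`.
#'
#' The bundled SP1 default is the IUPAC consensus `GGGGCGGGG` scanned with
#' one allowed mismatch; single-motif RBPJ scans use zero mismatches (the
#' degeneracy lives in the IUPAC letter, not the budget).
#'
#' @param sites Site tibble (`site_id`, `chrom`, `start`, `end`).
#' @param genome Named [Biostrings::DNAStringSet] covering all site
#'   chromosomes.
#' @param sp1_motif SP1 consensus motif (default `GGGGCGGGG`).
#' @param sp1_max_mismatch Mismatch budget for SP1 (default 1).
#' @param rbpj_max_mismatch Mismatch budget for single RBPJ motifs
#'   (default 0).
#' @param dimer_spacer_min,dimer_spacer_max,dimer_max_mismatch Dimer search
#'   parameters, see [find_head_to_head_dimers()].
#' @return Tibble `site_id`, `has_sp1`, `has_rbpj_canonical`,
#'   `has_rbpj_degenerate`, `has_dimer`.
#' @export
flag_sites <- function(sites, genome, sp1_motif = SP1_CONSENSUS,
                       sp1_max_mismatch = 1L, rbpj_max_mismatch = 0L,
                       dimer_spacer_min = 15L, dimer_spacer_max = 17L,
                       dimer_max_mismatch = 2L) {
  seqs <- site_sequences(sites, genome)
  widths <- Biostrings::width(seqs)
  any_hit <- function(motif, mm) {
    pat <- Biostrings::DNAString(toupper(motif))
    fwd <- contained_starts(
      Biostrings::vmatchPattern(pat, seqs, max.mismatch = mm,
                                fixed = "subject"), widths, length(pat))
    rev <- contained_starts(
      Biostrings::vmatchPattern(Biostrings::reverseComplement(pat), seqs,
                                max.mismatch = mm, fixed = "subject"),
      widths, length(pat))
    lengths(fwd) + lengths(rev) > 0
  }
  has_sp1 <- any_hit(sp1_motif, sp1_max_mismatch)
  has_can <- any_hit(RBPJ_CANONICAL, rbpj_max_mismatch)
  has_deg <- any_hit(RBPJ_DEGENERATE, rbpj_max_mismatch)
  has_dimer <- dimer_present(seqs, half_site = RBPJ_CANONICAL,
                             spacer_min = dimer_spacer_min,
                             spacer_max = dimer_spacer_max,
                             max_total_mismatch = dimer_max_mismatch)
  tibble(site_id = sites$site_id, has_sp1 = has_sp1,
         has_rbpj_canonical = has_can, has_rbpj_degenerate = has_deg,
         has_dimer = has_dimer)
}
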