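#' Find the longest open reading frame of a transcript
#'
#' Scans the three forward frames (FL-cDNA clones are directional, so the
#' reverse strand is not searched) for ATG-initiated ORFs. An ORF normally
#' ends at the first in-frame stop; when no stop occurs before the
#' transcript end the ORF is allowed to run to the last complete codon and
#' is flagged `partial` (3'-truncated clones). The longest ORF in amino
#' acids wins; ties go to the 5'-most start.
#'
#' @param seq DNA string, length >= 3.
#' @return A one-row `data.frame` with `orf_start`, `orf_end` (1-based,
#'   inclusive, stop codon included when present), `frame` (0-2),
#'   `aa_length` (codons excluding the stop) and `partial`; `NULL` if no
#'   ATG-initiated ORF exists.
#' @export
find_longest_orf <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 3L) stop("sequence shorter than one codon")
  best <- NULL
  for (f in 0:2) {
    ncod <- (n - f) %/% 3L
    if (ncod < 1L) next
    starts <- f + 3L * (seq_len(ncod) - 1L) + 1L
    codons <- substring(seq, starts, starts + 2L)
    atg <- which(codons == "ATG")
    if (length(atg) == 0L) next
    stops <- which(codons %in% STOP_CODONS)
    # first stop at or after each ATG
    nxt <- stops[findInterval(atg - 1L, stops) + 1L]
    has_stop <- !is.na(nxt)
    aa_len <- ifelse(has_stop, nxt - atg, ncod - atg + 1L)
    end_codon <- ifelse(has_stop, nxt, ncod)
    keep <- aa_len >= 1L
    if (!any(keep)) next
    # best in this frame: longest, then 5'-most
    o <- order(-aa_len[keep], atg[keep])[1]
    cand <- list(
      orf_start = starts[atg[keep][o]],
      orf_end = starts[end_codon[keep][o]] + 2L,
      frame = f,
      aa_length = aa_len[keep][o],
      partial = !has_stop[keep][o])
    if (is.null(best) ||
        cand$aa_length > best$aa_length ||
        (cand$aa_length == best$aa_length && cand$orf_start < best$orf_start))
      best <- cand
  }
  if (is.null(best)) return(NULL)
  as.data.frame(best)
}

#' Annotate longest ORFs for a transcript collection
#'
#' @param transcripts record table (see [transcript_records()]).
#' @return `data.frame` with one row per transcript: `transcript_id`,
#'   `orf_start`, `orf_end`, `frame`, `aa_length`, `partial`, `utr5_len`,
#'   `utr3_len`. Transcripts without an ORF get `NA` coordinates and
#'   `aa_length` 0.
#' @export
annotate_orfs <- function(transcripts) {
  rows <- lapply(seq_len(nrow(transcripts)), function(k) {
    orf <- find_longest_orf(transcripts$seq[k])
    len <- nchar(transcripts$seq[k])
    if (is.null(orf))
      return(data.frame(transcript_id = transcripts$id[k],
                        orf_start = NA_integer_, orf_end = NA_integer_,
                        frame = NA_integer_, aa_length = 0L, partial = NA,
                        utr5_len = NA_integer_, utr3_len = NA_integer_))
    data.frame(transcript_id = transcripts$id[k],
               orf, utr5_len = orf$orf_start - 1L,
               utr3_len = len - orf$orf_end)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Filter ORF annotations by protein length
#'
#' Keeps transcripts whose predicted protein is strictly longer than
#' `min_aa` amino acids.
#'
#' @param annotations output of [annotate_orfs()].
#' @param min_aa length threshold (default 100; "longer than" is strict).
#' @return Filtered annotation table.
#' @export
orf_size_filter <- function(annotations, min_aa = 100) {
  out <- annotations[!is.na(annotations$aa_length) &
                       annotations$aa_length > min_aa, , drop = FALSE]
  rownames(out) <- NULL
  out
}

gc_frac <- function(x) {
  if (!nzchar(x)) return(NA_real_)
  v <- chars(x)
  sum(v %in% c("G", "C")) / sum(v %in% DNA_BASES)
}

#' Regional GC and codon-usage summary
#'
#' Computes, for every annotated transcript, GC content overall and in the
#' 5'UTR, ORF and 3'UTR, plus GC at the first, second and third codon
#' positions of the ORF (GC1/GC2/GC3). Reported means are per-sequence
#' means averaged over sequences; transcripts lacking a region are excluded
#' from that region's mean. Codon usage is tabulated over all ORF codons
#' (64 codons, stops forming their own family), with relative synonymous
#' frequencies summing to one within each amino-acid family.
#'
#' @param transcripts record table.
#' @param annotations matching output of [annotate_orfs()]; rows without an
#'   ORF are skipped.
#' @return List with `summary` (named numeric vector of mean GC fractions),
#'   `per_transcript` (data.frame) and `codon_usage` (data.frame with codon,
#'   aa, count, freq_in_family).
#' @export
composition_summary <- function(transcripts, annotations) {
  ann <- annotations[!is.na(annotations$orf_start), , drop = FALSE]
  seqs <- setNames(transcripts$seq, transcripts$id)
  codon_counts <- integer(0)
  rows <- lapply(seq_len(nrow(ann)), function(k) {
    s <- seqs[[ann$transcript_id[k]]]
    o1 <- ann$orf_start[k]; o2 <- ann$orf_end[k]
    orf <- substr(s, o1, o2)
    # all ORF codons, terminal stop included, enter the positional GC and
    # codon-usage counts
    p1 <- seq(1L, nchar(orf), by = 3L)
    codons <- substring(orf, p1, p1 + 2L)
    b1 <- substring(orf, p1, p1)
    b2 <- substring(orf, p1 + 1L, p1 + 1L)
    b3 <- substring(orf, p1 + 2L, p1 + 2L)
    data.frame(
      transcript_id = ann$transcript_id[k],
      gc = gc_frac(s),
      gc_utr5 = gc_frac(substr(s, 1L, o1 - 1L)),
      gc_orf = gc_frac(orf),
      gc_utr3 = gc_frac(substr(s, o2 + 1L, nchar(s))),
      gc1 = mean(b1 %in% c("G", "C")),
      gc2 = mean(b2 %in% c("G", "C")),
      gc3 = mean(b3 %in% c("G", "C")),
      codons = I(list(codons)))
  })
  per <- do.call(rbind, rows)
  all_cod <- unlist(per$codons)
  per$codons <- NULL
  cu <- table(factor(all_cod, levels = names(GENETIC_CODE_TABLE)))
  aa <- GENETIC_CODE_TABLE[names(cu)]
  fam_tot <- tapply(as.integer(cu), aa, sum)[aa]
  codon_usage <- data.frame(
    codon = names(cu), aa = unname(aa), count = as.integer(cu),
    freq_in_family = ifelse(fam_tot > 0, as.integer(cu) / fam_tot, 0))
  summary <- c(
    n = nrow(per),
    gc = mean(per$gc, na.rm = TRUE),
    gc_utr5 = mean(per$gc_utr5, na.rm = TRUE),
    gc_utr3 = mean(per$gc_utr3, na.rm = TRUE),
    gc_orf = mean(per$gc_orf, na.rm = TRUE),
    gc1 = mean(per$gc1, na.rm = TRUE),
    gc2 = mean(per$gc2, na.rm = TRUE),
    gc3 = mean(per$gc3, na.rm = TRUE))
  list(summary = summary, per_transcript = per, codon_usage = codon_usage)
}
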