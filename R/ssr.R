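#' Default SSR repeat-count thresholds
#'
#' MISA-convention minimum repeat counts per motif period: mono >= 10,
#' di >= 6, tri/tetra/penta/hexa >= 5.
#'
#' @return Named integer vector, names "1".."6".
#' @export
ssr_default_thresholds <- function() {
  c(`1` = 10L, `2` = 6L, `3` = 5L, `4` = 5L, `5` = 5L, `6` = 5L)
}

# lexicographically minimal rotation of a motif
canonical_motif <- function(motif) {
  v <- chars(motif)
  rots <- vapply(seq_along(v), function(i)
    paste(c(v[i:length(v)], v[seq_len(i - 1L)]), collapse = ""), "")
  min(rots)
}

# TRUE if the motif is itself a repetition of a shorter motif
is_degenerate_motif <- function(motif) {
  p <- nchar(motif)
  for (d in seq_len(p - 1L)) {
    if (p %% d != 0L) next
    if (motif == strrep(substr(motif, 1L, d), p %/% d)) return(TRUE)
  }
  FALSE
}

#' Detect perfect simple sequence repeats
#'
#' Finds maximal, non-extendable perfect tandem repeats of 1-6 nt motifs
#' meeting per-period repeat-count thresholds (MISA-style). Motifs are
#' reported in canonical form (lexicographically minimal rotation, no
#' reverse-complement folding) and motifs that are repetitions of a shorter
#' motif are only reported at their true period. Overlapping repeats of
#' different periods are all reported; interrupted (compound) repeats are
#' not merged.
#'
#' @param seq DNA string.
#' @param thresholds named vector mapping period ("1".."6") to the minimum
#'   repeat count; default [ssr_default_thresholds()].
#' @return `data.frame` with columns `motif` (canonical), `period`,
#'   `repeat_count`, `start`, `end` (1-based inclusive; length =
#'   period x count).
#' @export
detect_ssrs <- function(seq, thresholds = ssr_default_thresholds()) {
  seq <- toupper(seq)
  n <- nchar(seq)
  v <- chars(seq)
  out <- list()
  for (p in as.integer(names(thresholds))) {
    min_count <- thresholds[[as.character(p)]]
    if (n < p * min_count) next
    m <- v[(p + 1L):n] == v[1L:(n - p)]
    r <- rle(m)
    pos <- cumsum(c(1L, r$lengths))
    for (k in seq_along(r$lengths)) {
      if (!r$values[k]) next
      run_start <- pos[k]              # index into m; array starts here
      array_len <- r$lengths[k] + p    # total perfect tandem stretch
      count <- array_len %/% p
      if (count < min_count) next
      motif <- substr(seq, run_start, run_start + p - 1L)
      if (grepl("N", motif, fixed = TRUE)) next
      if (is_degenerate_motif(motif)) next
      out[[length(out) + 1L]] <- data.frame(
        motif = canonical_motif(motif), period = p, repeat_count = count,
        start = run_start, end = run_start + p * count - 1L)
    }
  }
  if (length(out) == 0L)
    return(data.frame(motif = character(0), period = integer(0),
                      repeat_count = integer(0), start = integer(0),
                      end = integer(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$period), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Detect SSRs across a transcript collection
#'
#' @param transcripts record table.
#' @param thresholds see [detect_ssrs()].
#' @return Combined hit table with a `transcript_id` column.
#' @export
detect_ssrs_all <- function(transcripts, thresholds = ssr_default_thresholds()) {
  hits <- lapply(seq_len(nrow(transcripts)), function(k) {
    h <- detect_ssrs(transcripts$seq[k], thresholds)
    if (nrow(h) == 0L) return(NULL)
    cbind(transcript_id = transcripts$id[k], h)
  })
  hits <- Filter(Negate(is.null), hits)
  if (length(hits) == 0L)
    return(data.frame(transcript_id = character(0), motif = character(0),
                      period = integer(0), repeat_count = integer(0),
                      start = integer(0), end = integer(0)))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Localize SSR hits to transcript regions
#'
#' Assigns each hit to 5'UTR / ORF / 3'UTR by the midpoint of its interval
#' and reports the signed distance from the hit start to the first base of
#' the start codon (negative = upstream of ATG). Hits on transcripts
#' without an ORF annotation get region `"unannotated"`.
#'
#' @param hits output of [detect_ssrs_all()].
#' @param annotations output of [annotate_orfs()].
#' @return `hits` with added `region` and `distance_to_start_codon`.
#' @export
localize_ssrs <- function(hits, annotations) {
  ann <- annotations[match(hits$transcript_id, annotations$transcript_id), ]
  mid <- (hits$start + hits$end) %/% 2L
  region <- ifelse(is.na(ann$orf_start), "unannotated",
            ifelse(mid < ann$orf_start, "5'UTR",
            ifelse(mid > ann$orf_end, "3'UTR", "ORF")))
  hits$region <- region
  hits$distance_to_start_codon <-
    ifelse(is.na(ann$orf_start), NA_integer_, hits$start - ann$orf_start)
  hits
}

#' Summarize an SSR hit collection
#'
#' @param hits localized hit table ([localize_ssrs()]).
#' @param transcripts record table the hits were derived from.
#' @param bin_width width of positional histogram bins (nt).
#' @param window_start most-upstream distance binned (default -150, i.e.
#'   150 bp upstream of the start codon).
#' @return List with `fraction_with_ssr` (share of transcripts carrying at
#'   least one SSR), `per_period` and `per_motif` count tables, a
#'   `region_by_period` cross-tab and `position_histogram` (bin_start,
#'   period, count) over `distance_to_start_codon`.
#' @export
ssr_spectrum <- function(hits, transcripts, bin_width = 30L,
                         window_start = -150L) {
  frac <- length(unique(hits$transcript_id)) / nrow(transcripts)
  per_period <- as.data.frame(table(period = hits$period),
                              responseName = "count")
  per_motif <- as.data.frame(table(motif = hits$motif),
                             responseName = "count")
  region_by_period <- if (nrow(hits)) {
    as.data.frame(table(period = hits$period, region = hits$region),
                  responseName = "count")
  } else data.frame(period = integer(0), region = character(0),
                    count = integer(0))
  d <- hits$distance_to_start_codon
  d <- d[!is.na(d) & d >= window_start]
  ph <- if (length(d)) {
    bin <- window_start + bin_width * ((d - window_start) %/% bin_width)
    as.data.frame(table(bin_start = bin), responseName = "count")
  } else data.frame(bin_start = integer(0), count = integer(0))
  ph$bin_start <- as.integer(as.character(ph$bin_start))
  list(fraction_with_ssr = frac, per_period = per_period,
       per_motif = per_motif, region_by_period = region_by_period,
       position_histogram = ph)
}
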