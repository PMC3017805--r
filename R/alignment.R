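#' Pairwise alignment of two sequences
#'
#' The single alignment engine behind every identity-threshold rule in the
#' package. `mode = "local"` is an affine-gap Smith-Waterman; for long
#' sequence pairs the dynamic programme is restricted to a diagonal band
#' around exact k-mer seed hits, while short pairs (product of lengths up to
#' `full_dp_limit`) are solved exhaustively, so banded results can be checked
#' against the exact solution. `mode = "ungapped"` returns the best
#' gap-free local segment.
#'
#' Scoring defaults are BLASTN-like: match +1, mismatch -2, and a gap of
#' length L costs `gap_open + L * gap_ext`. Identity is matches divided by
#' alignment columns, counting gap columns, and `N` bases always count as
#' mismatches. With `strand = "both"` the reverse complement of `b` is also
#' searched and the better orientation reported; subject coordinates always
#' refer to the original `b`.
#'
#' @param a,b DNA strings (query, subject).
#' @param mode `"local"` (gapped) or `"ungapped"`.
#' @param strand `"both"` or `"forward"`.
#' @param match,mismatch,gap_open,gap_ext scoring parameters.
#' @param seed_k seed k-mer length for long pairs.
#' @param band extra band width added around the seed diagonal range.
#' @param full_dp_limit maximum `nchar(a) * nchar(b)` solved exhaustively.
#' @param query_id,subject_id optional ids carried into the result.
#' @return A `pairwise_alignment` (list with score, identity, match/mismatch/
#'   gap counts, 1-based inclusive intervals on both sequences, orientation
#'   and the aligned strings), or `NULL` when no positive-scoring alignment
#'   exists.
#' @export
align <- function(a, b, mode = c("local", "ungapped"),
                  strand = c("both", "forward"),
                  match = 1L, mismatch = -2L, gap_open = 5L, gap_ext = 2L,
                  seed_k = 11L, band = 31L, full_dp_limit = 4e6,
                  query_id = NA_character_, subject_id = NA_character_) {
  mode <- match.arg(mode)
  strand <- match.arg(strand)
  stopifnot(nzchar(a), nzchar(b))
  a <- toupper(a)
  b <- toupper(b)
  orientations <- if (strand == "both") c("forward", "reverse-complement")
                  else "forward"
  best <- NULL
  for (ori in orientations) {
    bb <- if (ori == "forward") b else revcomp(b)
    # lowercase subject Ns so N never matches anything, including N
    bb <- gsub("N", "n", bb, fixed = TRUE)
    hit <- if (mode == "ungapped") {
      c_align_ungapped(a, bb, match, mismatch)
    } else if (as.numeric(nchar(a)) * nchar(bb) <= full_dp_limit) {
      c_align_band(a, bb, match, mismatch, gap_open, gap_ext,
                   -nchar(a), nchar(bb))
    } else {
      rng <- c_seed_diag_range(a, bb, seed_k)
      if (length(rng) == 0L) list(score = 0L)
      else c_align_band(a, bb, match, mismatch, gap_open, gap_ext,
                        rng[1] - band, rng[2] + band)
    }
    if (hit$score <= 0) next
    aln <- build_alignment(hit, ori, nchar(b), query_id, subject_id)
    if (is.null(best) || aln$score > best$score) best <- aln
  }
  best
}

build_alignment <- function(hit, orientation, subject_len,
                            query_id, subject_id) {
  qa <- chars(hit$a_aln)
  sa <- chars(toupper(hit$b_aln))
  gaps <- qa == "-" | sa == "-"
  matches <- sum(!gaps & qa == sa & qa != "N")
  cols <- length(qa)
  s_start <- hit$b_start; s_end <- hit$b_end
  if (orientation == "reverse-complement") {
    tmp <- s_start
    s_start <- subject_len - s_end + 1L
    s_end <- subject_len - tmp + 1L
  }
  structure(list(
    query_id = query_id, subject_id = subject_id,
    score = hit$score, columns = cols, matches = matches,
    mismatches = cols - matches - sum(gaps), gap_columns = sum(gaps),
    identity = matches / cols,
    q_start = hit$a_start, q_end = hit$a_end,
    s_start = s_start, s_end = s_end,
    orientation = orientation,
    q_aln = hit$a_aln, s_aln = toupper(hit$b_aln)
  ), class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf(
    "pairwise_alignment: score %d, %d columns, identity %.3f (%s)\n",
    x$score, x$columns, x$identity, x$orientation))
  cat(sprintf("  query   %d-%d\n  subject %d-%d\n",
              x$q_start, x$q_end, x$s_start, x$s_end))
  invisible(x)
}

# logical vector over alignment columns: TRUE where the column is an
# identical non-gap, non-N base pair
aln_match_vector <- function(aln) {
  qa <- chars(aln$q_aln); sa <- chars(aln$s_aln)
  qa == sa & qa != "-" & qa != "N"
}

# does the alignment contain a window of `width` consecutive columns with
# identity strictly greater than `min_identity`?
has_identity_window <- function(aln, width, min_identity) {
  m <- aln_match_vector(aln)
  n <- length(m)
  if (n < width) return(FALSE)
  cs <- cumsum(m)
  win <- cs[width:n] - c(0, cs)[1:(n - width + 1L)]
  any(win / width > min_identity)
}

#' Longest exact shared substring of two sequences
#'
#' @param a,b DNA strings.
#' @return Integer length of the longest contiguous block present in both
#'   (0 when the sequences share no character).
#' @export
longest_exact_run <- function(a, b) {
  c_longest_common_substring(toupper(a), toupper(b))
}

#' Tabulate alignments in BLAST outfmt-6 style
#'
#' @param alignments list of `pairwise_alignment` objects.
#' @return `data.frame` with columns query, subject, identity, alnlen,
#'   mismatches, gaps, q.start, q.end, s.start, s.end, strand, score.
#' @export
alignment_table <- function(alignments) {
  alignments <- Filter(Negate(is.null), alignments)
  do.call(rbind, c(list(data.frame(
    query = character(0), subject = character(0), identity = numeric(0),
    alnlen = integer(0), mismatches = integer(0), gaps = integer(0),
    q.start = integer(0), q.end = integer(0), s.start = integer(0),
    s.end = integer(0), strand = character(0), score = integer(0))),
    lapply(alignments, function(x) data.frame(
      query = x$query_id, subject = x$subject_id,
      identity = x$identity, alnlen = x$columns,
      mismatches = x$mismatches, gaps = x$gap_columns,
      q.start = x$q_start, q.end = x$q_end,
      s.start = x$s_start, s.end = x$s_end,
      strand = if (x$orientation == "forward") "+" else "-",
      score = x$score))))
}
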