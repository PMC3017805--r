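#' Detect cis-natural-antisense transcript pairs
#'
#' Scans all transcript pairs for a gap-free reverse-complement match of at
#' least `min_overlap` nucleotides with fewer than 2 mismatches ("less than
#' 2 bp" read as at most `max_mismatches` = 1, gap-free, so the ungapped
#' engine is used). Each qualifying pair is reported once with its longest
#' qualifying window; a transcript never pairs with itself. The result is
#' invariant to input order up to row ordering.
#'
#' @param transcripts record table.
#' @param min_overlap minimum overlap length (default 50 nt).
#' @param max_mismatches maximum mismatches in the overlap (default 1).
#' @param seed_k k-mer length of the candidate prefilter (an overlap of 50
#'   with at most one mismatch guarantees an exact run of at least 25 nt).
#' @return `data.frame` with `sense_id`, `antisense_id`, `overlap_length`,
#'   `mismatches` and 1-based inclusive overlap intervals on both
#'   transcripts (antisense interval on its own forward coordinates).
#' @export
detect_nats <- function(transcripts, min_overlap = 50L, max_mismatches = 1L,
                        seed_k = 16L) {
  n <- nrow(transcripts)
  empty <- data.frame(sense_id = character(0), antisense_id = character(0),
                      overlap_length = integer(0), mismatches = integer(0),
                      sense_start = integer(0), sense_end = integer(0),
                      antisense_start = integer(0), antisense_end = integer(0))
  if (n < 2L) return(empty)
  rc <- vapply(transcripts$seq, revcomp, "", USE.NAMES = FALSE)
  # prefilter: pair (i, j) is a candidate when seq_i shares a k-mer with
  # revcomp(seq_j); feed both orientations into one k-mer index
  cand <- c_kmer_candidate_pairs(c(transcripts$seq, rc), seed_k,
                                 max_occ = 500L)
  keep <- (cand[, 1] <= n) != (cand[, 2] <= n)
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  ij <- cbind(ifelse(cand[, 1] <= n, cand[, 1], cand[, 1] - n),
              ifelse(cand[, 2] <= n, cand[, 2], cand[, 2] - n))
  ij <- unique(cbind(pmin(ij[, 1], ij[, 2]), pmax(ij[, 1], ij[, 2])))
  ij <- ij[ij[, 1] != ij[, 2], , drop = FALSE]
  rows <- list()
  for (r in seq_len(nrow(ij))) {
    i <- ij[r, 1]; j <- ij[r, 2]
    w <- c_longest_mismatch_window(transcripts$seq[i], rc[j], max_mismatches)
    if (w$length < min_overlap) next
    nb <- nchar(transcripts$seq[j])
    rows[[length(rows) + 1L]] <- data.frame(
      sense_id = transcripts$id[i], antisense_id = transcripts$id[j],
      overlap_length = w$length, mismatches = w$mismatches,
      sense_start = w$a_start, sense_end = w$a_end,
      antisense_start = nb - w$b_end + 1L, antisense_end = nb - w$b_start + 1L)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$sense_id, out$antisense_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-tabulate NAT pairs by ORF status of their members
#'
#' Members are classed by predicted protein length: `>100aa`, `30-100aa`,
#' or `none` (no ORF or shorter than 30 aa). The pair cell is the
#' unordered combination of the two member classes.
#'
#' @param pairs output of [detect_nats()].
#' @param annotations output of [annotate_orfs()].
#' @return Contingency `data.frame` (class_pair, count); zero-filled when
#'   `pairs` is empty.
#' @export
nat_summary <- function(pairs, annotations) {
  cls <- function(id) {
    aa <- annotations$aa_length[match(id, annotations$transcript_id)]
    ifelse(is.na(aa) | aa < 30, "none",
           ifelse(aa > 100, ">100aa", "30-100aa"))
  }
  lv <- c(">100aa", "30-100aa", "none")
  combos <- outer(lv, lv, function(x, y)
    ifelse(match(x, lv) <= match(y, lv), paste(x, y, sep = "/"),
           paste(y, x, sep = "/")))
  levels_all <- unique(as.vector(combos))
  if (nrow(pairs) == 0L)
    return(data.frame(class_pair = levels_all,
                      count = rep(0L, length(levels_all))))
  a <- cls(pairs$sense_id); b <- cls(pairs$antisense_id)
  cp <- ifelse(match(a, lv) <= match(b, lv), paste(a, b, sep = "/"),
               paste(b, a, sep = "/"))
  as.data.frame(table(class_pair = factor(cp, levels = levels_all)),
                responseName = "count")
}
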