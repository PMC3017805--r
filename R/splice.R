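# Alternative-splicing variant detection without a genome.
#
# Candidate isoform pairs come from within-cluster alignments whose matched
# flanks are near-identical; the structural difference between the two
# transcripts (a large internal gap, mutually exclusive gaps, or a staggered
# single-exon overlap) is then classified into the six AS types using the
# GT-AG rule on the inserted segment. Because alignment gap placement is
# ambiguous when the gap is flanked by equal bases, the insertion register
# is slid across all equivalent placements before a boundary is accepted or
# rejected.

# equivalent placements of an insertion of length L starting at p (1-based)
# in sequence x: all p' with identical deletion result
slide_range <- function(x, p, L) {
  v <- chars(x)
  pmin <- p
  while (pmin > 1L && v[pmin - 1L] == v[pmin + L - 1L]) pmin <- pmin - 1L
  pmax <- p
  while (pmax + L <= length(v) && v[pmax] == v[pmax + L]) pmax <- pmax + 1L
  c(pmin, pmax)
}

# gap runs in an alignment: one row per run of '-' in either sequence,
# with the inserted segment located on the ungapped coordinates of the
# sequence that has bases there
alignment_gap_runs <- function(aln) {
  qa <- chars(aln$q_aln); sa <- chars(aln$s_aln)
  gap_in <- ifelse(qa == "-", "a", ifelse(sa == "-", "b", NA))
  r <- rle(gap_in)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  qpos <- cumsum(qa != "-"); spos <- cumsum(sa != "-")
  rows <- list()
  for (k in seq_along(r$values)) {
    if (is.na(r$values[k])) next
    L <- r$lengths[k]
    if (r$values[k] == "a") {
      # gap in query alignment row -> insertion in subject b
      ins_start <- aln$s_start + (if (starts[k] == 1L) 0L else spos[starts[k] - 1L])
      rows[[length(rows) + 1L]] <- data.frame(
        insert_in = "b", length = L, col_start = starts[k],
        col_end = ends[k], ins_start = ins_start)
    } else {
      ins_start <- aln$q_start + (if (starts[k] == 1L) 0L else qpos[starts[k] - 1L])
      rows[[length(rows) + 1L]] <- data.frame(
        insert_in = "a", length = L, col_start = starts[k],
        col_end = ends[k], ins_start = ins_start)
    }
  }
  if (!length(rows))
    return(data.frame(insert_in = character(0), length = integer(0),
                      col_start = integer(0), col_end = integer(0),
                      ins_start = integer(0)))
  do.call(rbind, rows)
}

# flank statistics: identity and column count outside gap runs >= min_intron
flank_stats <- function(aln, min_intron) {
  m <- aln_match_vector(aln)
  qa <- chars(aln$q_aln); sa <- chars(aln$s_aln)
  isgap <- qa == "-" | sa == "-"
  r <- rle(isgap)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  big <- rep(FALSE, length(m))
  for (k in seq_along(r$values))
    if (r$values[k] && r$lengths[k] >= min_intron)
      big[starts[k]:ends[k]] <- TRUE
  cols <- sum(!big)
  list(columns = cols,
       identity = if (cols > 0) sum(m[!big]) / cols else 0)
}

#' Extract candidate alternative-splicing pairs from clusters
#'
#' Within each cluster of full-length cDNAs, pairs whose matched flanks
#' align at identity greater than `min_flank_identity` over at least
#' `min_flank_cols` columns are kept as AS candidates when they either
#' contain an internal alignment gap of at least `min_intron` nt (intron
#' retention / alternative-site geometries) or show a staggered
#' single-exon-overlap geometry. Singleton clusters contribute nothing.
#'
#' @param clusters cluster assignment of the transcripts
#'   ([cluster_ests()] output, applied to the FL-cDNA set).
#' @param transcripts record table.
#' @param min_flank_identity flank identity threshold (default 0.99,
#'   strict ">99%").
#' @param min_flank_cols minimum matched flank columns (default 100).
#' @param min_intron minimum inferred intron / event gap length
#'   (default 30 nt), below which indels are not treated as AS.
#' @param overhang_min minimum unaligned overhang for the single-exon
#'   overlap geometry.
#' @return List of candidate pair objects (ids, alignment, gap table),
#'   input order deterministic.
#' @export
candidate_as_pairs <- function(clusters, transcripts,
                               min_flank_identity = 0.99,
                               min_flank_cols = 100L, min_intron = 30L,
                               overhang_min = 30L) {
  out <- list()
  for (cl in unique(clusters$cluster_id)) {
    ids <- clusters$read_id[clusters$cluster_id == cl]
    if (length(ids) < 2L) next
    for (pair in combn(ids, 2L, simplify = FALSE)) {
      i <- match(pair[1], transcripts$id); j <- match(pair[2], transcripts$id)
      # intron-tolerant gap costs: a retained intron of any length costs a
      # flat opening penalty, so bridging it always beats dropping a flank
      aln <- align(transcripts$seq[i], transcripts$seq[j],
                   strand = "forward", gap_open = 30, gap_ext = 0,
                   query_id = pair[1], subject_id = pair[2])
      if (is.null(aln)) next
      fs <- flank_stats(aln, min_intron)
      if (fs$columns < min_flank_cols || fs$identity <= min_flank_identity)
        next
      gaps <- alignment_gap_runs(aln)
      gaps <- gaps[gaps$length >= min_intron, , drop = FALSE]
      dovetail <- is_dovetail(aln, nchar(transcripts$seq[i]),
                              nchar(transcripts$seq[j]), overhang_min)
      if (nrow(gaps) == 0L && !dovetail) next
      out[[length(out) + 1L]] <- list(
        a_id = pair[1], b_id = pair[2],
        a_seq = transcripts$seq[i], b_seq = transcripts$seq[j],
        alignment = aln, gaps = gaps, dovetail = dovetail)
    }
  }
  out
}

# staggered overlap: the aligned block reaches one end of each sequence,
# with substantial unaligned overhang left on both outer sides
is_dovetail <- function(aln, na, nb, overhang_min, end_slack = 10L) {
  a3 <- (na - aln$q_end) <= end_slack && (aln$s_start - 1L) <= end_slack &&
    (aln$q_start - 1L) >= overhang_min && (nb - aln$s_end) >= overhang_min
  b3 <- (nb - aln$s_end) <= end_slack && (aln$q_start - 1L) <= end_slack &&
    (aln$s_start - 1L) >= overhang_min && (na - aln$q_end) >= overhang_min
  a3 || b3
}

# boundary classification of one inserted segment, sliding the register
# across equivalent placements; GC-AG is accepted only where GT-AG fails
classify_gap <- function(x, p, L) {
  rng <- slide_range(x, p, L)
  offs <- rng[1]:rng[2]
  offs <- offs[order(abs(offs - p))]
  seg <- function(pp) substr(x, pp, pp + L - 1L)
  for (pp in offs) {
    s <- seg(pp)
    if (startsWith(s, "GT") && endsWith(s, "AG"))
      return(list(type = "IntronR", boundary = "GT-AG", at = pp))
  }
  for (pp in offs) {
    s <- seg(pp)
    if (startsWith(s, "GC") && endsWith(s, "AG"))
      return(list(type = "IntronR", boundary = "GC-AG", at = pp))
  }
  for (pp in offs) {
    if (startsWith(seg(pp), "GT"))
      return(list(type = "AltD", boundary = "GT-", at = pp))
  }
  for (pp in offs) {
    if (endsWith(seg(pp), "AG"))
      return(list(type = "AltA", boundary = "-AG", at = pp))
  }
  list(type = "ExonS", boundary = "", at = p)
}

#' Classify a candidate pair into alternative-splicing types
#'
#' Operational rules (the six-type inventory is figure-defined in the
#' original classification, so these geometries are explicit stand-ins):
#' a single internal insertion beginning GT (or GC where GT fails) and
#' ending AG is intron retention (IntronR); an insertion starting GT only
#' shifts the donor (AltD); ending AG only shifts the acceptor (AltA);
#' an internal insertion with neither boundary is a skipped exon (ExonS);
#' one GT/GC..AG insertion in each transcript at different positions is an
#' alternatively positioned intron (AltP, reported as a single event with
#' `insert_in = "both"`); a staggered single-exon overlap with no large
#' gap is ExonO. Pairs failing every rule are rejected. When several gaps
#' fire different rules, one event row per gap is reported (groups with
#' more than one AS pattern).
#'
#' @param pair one element of [candidate_as_pairs()] output.
#' @return `data.frame` of events (possibly several rows), or `NULL` when
#'   the pair is rejected. Columns: `transcript_a`, `transcript_b`,
#'   `as_type`, `boundary`, `insert_in`, `insert_start`, `insert_end`,
#'   `inferred_intron_length`.
#' @export
classify_as_event <- function(pair) {
  gaps <- pair$gaps
  ev <- function(type, boundary, insert_in, start, len) data.frame(
    transcript_a = pair$a_id, transcript_b = pair$b_id,
    as_type = type, boundary = boundary, insert_in = insert_in,
    insert_start = start, insert_end = if (is.na(start)) NA_integer_
      else start + len - 1L,
    inferred_intron_length = len)
  if (nrow(gaps) == 0L) {
    if (isTRUE(pair$dovetail))
      return(ev("ExonO", "", NA_character_, NA_integer_, NA_integer_))
    return(NULL)
  }
  cls <- lapply(seq_len(nrow(gaps)), function(k) {
    x <- if (gaps$insert_in[k] == "a") pair$a_seq else pair$b_seq
    classify_gap(x, gaps$ins_start[k], gaps$length[k])
  })
  # alternatively positioned intron: exactly one intron-like insertion in
  # each transcript forms a single event, anchored on the first gap
  if (nrow(gaps) == 2L && length(unique(gaps$insert_in)) == 2L &&
      all(vapply(cls, function(z) z$type == "IntronR", TRUE))) {
    return(ev("AltP", cls[[1]]$boundary, "both", cls[[1]]$at,
              gaps$length[1]))
  }
  do.call(rbind, lapply(seq_len(nrow(gaps)), function(k) ev(
    cls[[k]]$type, cls[[k]]$boundary, gaps$insert_in[k], cls[[k]]$at,
    gaps$length[k])))
}

#' Detect and classify AS events for a clustered transcript set
#'
#' @param clusters,transcripts see [candidate_as_pairs()].
#' @param ... thresholds passed to [candidate_as_pairs()].
#' @return Event table (zero rows if none found).
#' @export
detect_as_events <- function(clusters, transcripts, ...) {
  pairs <- candidate_as_pairs(clusters, transcripts, ...)
  evs <- Filter(Negate(is.null), lapply(pairs, classify_as_event))
  if (!length(evs))
    return(data.frame(transcript_a = character(0), transcript_b = character(0),
                      as_type = character(0), boundary = character(0),
                      insert_in = character(0), insert_start = integer(0),
                      insert_end = integer(0),
                      inferred_intron_length = integer(0)))
  out <- do.call(rbind, evs)
  rownames(out) <- NULL
  out
}

#' Summarize retained-intron lengths
#'
#' @param events event table from [detect_as_events()].
#' @return List with `n`, `mean` and `median` of the inferred intron
#'   lengths of IntronR events.
#' @export
intron_size_summary <- function(events) {
  len <- events$inferred_intron_length[events$as_type == "IntronR"]
  if (!length(len)) stop("no IntronR events")
  list(n = length(len), mean = mean(len), median = median(len))
}

#' Count AS events per type
#'
#' @param events event table.
#' @return `data.frame` of counts per `as_type`.
#' @export
as_type_counts <- function(events) {
  as.data.frame(table(as_type = factor(
    events$as_type,
    levels = c("IntronR", "AltP", "ExonO", "ExonS", "AltA", "AltD"))),
    responseName = "count")
}
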