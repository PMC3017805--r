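# Cross-species homolog recognition and stringent one-to-one ortholog
# picking. Ranking uses alignment score rather than E-values: with the
# identity/coverage thresholds doing the real filtering, score order is
# deterministic and independent of database size.

# window of `width` consecutive gap-free columns with identity > min_ident?
has_ungapped_identity_window <- function(aln, width, min_ident) {
  qa <- chars(aln$q_aln); sa <- chars(aln$s_aln)
  m <- qa == sa & qa != "-" & qa != "N" & qa != "X"
  nogap <- qa != "-" & sa != "-"
  n <- length(m)
  if (n < width) return(FALSE)
  cs_m <- cumsum(m); cs_g <- cumsum(!nogap)
  wm <- cs_m[width:n] - c(0, cs_m)[1:(n - width + 1L)]
  wg <- cs_g[width:n] - c(0, cs_g)[1:(n - width + 1L)]
  any(wg == 0 & wm / width > min_ident)
}

# longest-ORF peptide of a record (NULL when no ORF)
orf_peptide <- function(seq) {
  orf <- find_longest_orf(seq)
  if (is.null(orf)) return(NULL)
  pep <- translate_cds(substr(seq, orf$orf_start, orf$orf_end))
  sub("\\*$", "", pep)
}

#' Find homologs of query transcripts in a subject collection
#'
#' Nucleotide level: a subject is a homolog when the local alignment has
#' identity above `nt_identity` and covers more than `nt_coverage` of the
#' query. Protein level: the query's longest-ORF peptide is aligned to the
#' subject's re-predicted longest-ORF peptide, and a homolog requires more
#' than `aa_identity` identity over at least `aa_window` consecutive
#' aligned residues. Queries without an ORF are skipped at protein level.
#'
#' @param queries,subjects record tables.
#' @param level `"nucleotide"` or `"protein"`.
#' @param species label stored with the hits.
#' @param nt_identity,nt_coverage nucleotide thresholds (defaults 0.75,
#'   0.5; both strict).
#' @param aa_identity,aa_window protein thresholds (defaults 0.60, 50 aa).
#' @param seed_k prefilter k-mer length at nucleotide level.
#' @return `data.frame` of hits (query_id, subject_id, species, level,
#'   identity, coverage_of_query, score), score-ranked within query.
#' @export
find_homologs <- function(queries, subjects, level = c("nucleotide", "protein"),
                          species = "subject", nt_identity = 0.75,
                          nt_coverage = 0.5, aa_identity = 0.60,
                          aa_window = 50L, seed_k = 11L) {
  level <- match.arg(level)
  rows <- list()
  if (level == "nucleotide") {
    cand <- c_kmer_candidate_pairs(c(queries$seq, subjects$seq), seed_k,
                                   max_occ = 1000L)
    nq <- nrow(queries)
    keep <- (cand[, 1] <= nq) & (cand[, 2] > nq)
    for (r in which(keep)) {
      i <- cand[r, 1]; j <- cand[r, 2] - nq
      aln <- align(queries$seq[i], subjects$seq[j], strand = "forward",
                   query_id = queries$id[i], subject_id = subjects$id[j])
      if (is.null(aln)) next
      cov <- (aln$q_end - aln$q_start + 1L) / nchar(queries$seq[i])
      if (aln$identity > nt_identity && cov > nt_coverage)
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = queries$id[i], subject_id = subjects$id[j],
          species = species, level = level, identity = aln$identity,
          coverage_of_query = cov, score = aln$score)
    }
  } else {
    qpep <- lapply(queries$seq, orf_peptide)
    spep <- lapply(subjects$seq, orf_peptide)
    for (i in seq_len(nrow(queries))) {
      if (is.null(qpep[[i]])) next
      for (j in seq_len(nrow(subjects))) {
        if (is.null(spep[[j]])) next
        aln <- align(qpep[[i]], spep[[j]], strand = "forward", seed_k = 4L,
                     query_id = queries$id[i], subject_id = subjects$id[j])
        if (is.null(aln)) next
        if (has_ungapped_identity_window(aln, aa_window, aa_identity))
          rows[[length(rows) + 1L]] <- data.frame(
            query_id = queries$id[i], subject_id = subjects$id[j],
            species = species, level = level, identity = aln$identity,
            coverage_of_query =
              (aln$q_end - aln$q_start + 1L) / nchar(qpep[[i]]),
            score = aln$score)
      }
    }
  }
  if (!length(rows))
    return(data.frame(query_id = character(0), subject_id = character(0),
                      species = character(0), level = character(0),
                      identity = numeric(0), coverage_of_query = numeric(0),
                      score = numeric(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$query_id, -out$score, out$subject_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# best peptide-identity subject among the top-`n_top` scoring nucleotide
# hits of `id` in `db`; NA on no hit or tie
best_peptide_partner <- function(id, source_db, target_db, n_top = 3L,
                                 ...) {
  q <- source_db[source_db$id == id, , drop = FALSE]
  hits <- find_homologs(q, target_db, level = "nucleotide", ...)
  if (nrow(hits) == 0L) return(NA_character_)
  top <- head(hits, n_top)
  qp <- orf_peptide(q$seq)
  if (is.null(qp)) return(NA_character_)
  ident <- vapply(top$subject_id, function(sid) {
    # re-predict the subject ORF before comparing peptides
    sp <- orf_peptide(target_db$seq[target_db$id == sid])
    if (is.null(sp)) return(NA_real_)
    aln <- align(qp, sp, strand = "forward", seed_k = 4L)
    if (is.null(aln)) NA_real_ else aln$identity
  }, 0)
  if (all(is.na(ident))) return(NA_character_)
  best <- max(ident, na.rm = TRUE)
  cand <- top$subject_id[!is.na(ident) & ident >= best - 1e-12]
  if (length(cand) != 1L) return(NA_character_)  # tie = ambiguous
  cand
}

#' Pick the one-to-one ortholog of a query in another species
#'
#' Three-step stringent selection: (1) the three best-scoring nucleotide
#' homologs of the query are taken, (2) their ORFs are re-predicted and the
#' predicted peptides aligned to the query peptide, (3) the single subject
#' with the highest peptide identity is accepted only when the reciprocal
#' search from that subject back into the query collection returns the
#' query itself. Ties at any step yield no ortholog.
#'
#' @param query_id id within `queries`.
#' @param queries query-species record table.
#' @param species_db record table of the other species.
#' @param ... thresholds forwarded to [find_homologs()].
#' @return Subject id, or `NA_character_` (no unambiguous reciprocal
#'   one-to-one partner).
#' @export
pick_ortholog <- function(query_id, queries, species_db, ...) {
  fwd <- best_peptide_partner(query_id, queries, species_db, ...)
  if (is.na(fwd)) return(NA_character_)
  back <- best_peptide_partner(fwd, species_db, queries, ...)
  if (is.na(back) || back != query_id) return(NA_character_)
  fwd
}

#' One-to-one ortholog groups across several species
#'
#' @param queries anchor-species record table.
#' @param species_dbs named list of record tables.
#' @param ... thresholds forwarded to [find_homologs()].
#' @return `data.frame` with the anchor id and one column per species;
#'   only groups with an ortholog in every species are kept.
#' @export
find_ortholog_groups <- function(queries, species_dbs, ...) {
  rows <- lapply(queries$id, function(qid) {
    hit <- vapply(species_dbs, function(db)
      pick_ortholog(qid, queries, db, ...), "")
    if (any(is.na(hit))) return(NULL)
    as.data.frame(c(list(anchor_id = qid), as.list(hit)))
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows))
    return(as.data.frame(c(list(anchor_id = character(0)),
                           setNames(rep(list(character(0)),
                                        length(species_dbs)),
                                    names(species_dbs)))))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Partition queries by homolog presence across species
#'
#' With the first species as the reference, each query falls in exactly
#' one of: `shared_all` (homolog in the reference and in every other
#' species), `ref_not_all` (reference homolog but missing from at least
#' one other), `others_not_ref` (no reference homolog yet present in all
#' other species), `no_hit` (everything else, including partial non-
#' reference patterns).
#'
#' @param queries record table.
#' @param species_dbs named list of record tables; first entry is the
#'   reference species.
#' @param ... thresholds forwarded to [find_homologs()].
#' @return List with `category` (named per query), `counts` and
#'   `fractions` over the four categories.
#' @export
partition_shared_unique <- function(queries, species_dbs, ...) {
  stopifnot(length(species_dbs) >= 2L)
  hit <- sapply(species_dbs, function(db) {
    h <- find_homologs(queries, db, level = "nucleotide", ...)
    queries$id %in% h$query_id
  })
  if (is.null(dim(hit))) hit <- matrix(hit, nrow = 1)
  ref <- hit[, 1]
  others_all <- apply(hit[, -1, drop = FALSE], 1, all)
  category <- ifelse(ref & others_all, "shared_all",
              ifelse(ref, "ref_not_all",
              ifelse(others_all, "others_not_ref", "no_hit")))
  lv <- c("shared_all", "ref_not_all", "others_not_ref", "no_hit")
  counts <- table(factor(category, levels = lv))
  list(category = setNames(category, queries$id),
       counts = counts, fractions = counts / nrow(queries))
}
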