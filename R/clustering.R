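#' Cluster ESTs into contigs and singletons
#'
#' Two reads are linked when their local alignment contains a window of
#' `window` consecutive columns with identity strictly greater than
#' `min_identity` (the windowed reading of ">95% similarity over 80
#' consecutive bases", as in TIGR Gene Indices clustering); clusters are
#' the single-linkage transitive closure of this relation. Reads are
#' directional 5' sequences, so only the forward strand is compared.
#' No consensus is called: clusters are used for representative picking
#' and isoform-pair mining only.
#'
#' @param reads record table of ESTs (length >= 100 recommended,
#'   see [length_filter()]).
#' @param min_identity windowed identity threshold (default 0.95, strict).
#' @param window window size in alignment columns (default 80).
#' @param seed_k k-mer length of the candidate-pair prefilter.
#' @return `data.frame` with columns `read_id`, `cluster_id`, `size`;
#'   every read appears exactly once. Cluster ids are assigned in order of
#'   first member appearance.
#' @export
cluster_ests <- function(reads, min_identity = 0.95, window = 80L,
                         seed_k = 12L) {
  n <- nrow(reads)
  if (n == 0L)
    return(data.frame(read_id = character(0), cluster_id = character(0),
                      size = integer(0)))
  cand <- c_kmer_candidate_pairs(reads$seq, seed_k, max_occ = 500L)
  edges <- integer(0)
  if (nrow(cand) > 0) {
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      aln <- align(reads$seq[i], reads$seq[j], strand = "forward")
      if (!is.null(aln) && has_identity_window(aln, window, min_identity))
        edges <- c(edges, i, j)
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  # relabel components by first appearance so output is input-order stable
  first <- match(unique(comp), comp)
  relabel <- match(comp, comp[sort(first)])
  sizes <- tabulate(relabel)
  data.frame(read_id = reads$id,
             cluster_id = sprintf("CL%05d", relabel),
             size = sizes[relabel])
}

#' Cluster-level summary
#'
#' @param clusters output of [cluster_ests()].
#' @return One-row `data.frame`: n_clusters, n_singletons, n_contigs,
#'   mean_size, max_size.
#' @export
cluster_summary <- function(clusters) {
  sz <- tapply(clusters$size, clusters$cluster_id, function(x) x[1])
  data.frame(n_clusters = length(sz),
             n_singletons = sum(sz == 1L),
             n_contigs = sum(sz > 1L),
             mean_size = mean(sz),
             max_size = max(sz))
}

#' Pick one representative per cluster
#'
#' The default policy keeps the longest member (ties by id order) so the
#' choice is reproducible; `policy = "random"` draws one member per cluster
#' under the given seed, mirroring "one randomly chosen clone per contig".
#'
#' @param clusters output of [cluster_ests()].
#' @param reads the clustered record table.
#' @param policy `"longest"` or `"random"`.
#' @param seed RNG seed for the random policy.
#' @return `clusters` with a logical `is_representative` column.
#' @export
select_representatives <- function(clusters, reads,
                                   policy = c("longest", "random"),
                                   seed = 1L) {
  policy <- match.arg(policy)
  len <- nchar(reads$seq[match(clusters$read_id, reads$id)])
  pick_in <- function(idx) {
    if (policy == "longest")
      idx[order(-len[idx], clusters$read_id[idx])][1]
    else idx[sample.int(length(idx), 1L)]
  }
  picks <- if (policy == "random") {
    with_seed(seed, vapply(split(seq_len(nrow(clusters)),
                                 clusters$cluster_id), pick_in, 1L))
  } else {
    vapply(split(seq_len(nrow(clusters)), clusters$cluster_id), pick_in, 1L)
  }
  clusters$is_representative <- seq_len(nrow(clusters)) %in% picks
  clusters
}

#' Filter redundant full-length sequences
#'
#' Greedy longest-first retention: sequences are visited in decreasing
#' length order and dropped when a local alignment to an already retained
#' sequence has identity of at least `min_identity` and covers at least
#' `min_coverage` of the shorter sequence. The coverage requirement keeps
#' a shared domain from collapsing distinct genes.
#'
#' @param transcripts record table.
#' @param min_identity identity threshold (default 0.99; "99% or higher",
#'   inclusive).
#' @param min_coverage minimum aligned fraction of the shorter sequence.
#' @param seed_k k-mer length of the candidate prefilter.
#' @return Retained record table; `attr(, "dropped")` maps each dropped id
#'   to the retained id it matched.
#' @export
filter_redundant <- function(transcripts, min_identity = 0.99,
                             min_coverage = 0.9, seed_k = 16L) {
  n <- nrow(transcripts)
  ord <- order(-nchar(transcripts$seq), transcripts$id)
  cand <- c_kmer_candidate_pairs(transcripts$seq, seed_k, max_occ = 500L)
  nbr <- vector("list", n)
  if (nrow(cand) > 0) {
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      nbr[[i]] <- c(nbr[[i]], j); nbr[[j]] <- c(nbr[[j]], i)
    }
  }
  retained <- logical(n)
  dropped_to <- character(0)
  for (i in ord) {
    hit <- NA_character_
    for (j in nbr[[i]]) {
      if (!retained[j]) next
      a <- transcripts$seq[i]; b <- transcripts$seq[j]
      aln <- align(a, b, strand = "forward")
      if (is.null(aln)) next
      shorter <- min(nchar(a), nchar(b))
      span <- if (nchar(a) <= nchar(b)) aln$q_end - aln$q_start + 1L
              else aln$s_end - aln$s_start + 1L
      if (aln$identity >= min_identity && span / shorter >= min_coverage) {
        hit <- transcripts$id[j]
        break
      }
    }
    if (is.na(hit)) retained[i] <- TRUE
    else dropped_to[transcripts$id[i]] <- hit
  }
  out <- transcripts[retained, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped_to
  out
}
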