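# Dating gene duplications from redundant EST clusters: reads are anchored
# to their FL-cDNA by best ungapped alignment, stacked into a
# reference-anchored multiple alignment (reads are near-identical, so no
# full MSA machinery is needed), sequencing-error singleton variants are
# masked, and clusters that resolve into exactly two haplotypes covering
# the coding region are dated by T = Ks / (2r).

#' @include kaks.R
NULL

#' EST-cluster duplication analysis
#'
#' For every FL-cDNA with at least `min_cluster` assigned ESTs: stack each
#' read's best ungapped alignment onto the reference; at each column, mask
#' (to missing) any allele supported by fewer than `min_support` reads;
#' call the retained polymorphic columns; group reads into haplotypes by
#' single linkage (two reads join when they agree at every retained
#' polymorphic column both cover). Clusters whose reads do not jointly
#' cover the predicted coding region are excluded. For two-haplotype
#' clusters the NG86 Ks between haplotype consensus coding sequences is
#' converted to time by T = Ks/(2r), and times are histogrammed in
#' `bin_my`-My bins.
#'
#' @param fl_cdnas record table of FL-cDNA references.
#' @param ests record table of reads.
#' @param annotations ORF annotations of `fl_cdnas` ([annotate_orfs()]).
#' @param r synonymous substitution rate per site per year.
#' @param min_cluster minimum reads per cluster (default 6).
#' @param min_support minimum reads supporting a retained allele.
#' @param bin_my histogram bin width in million years.
#' @param max_my histogram range end.
#' @param seed_k prefilter k-mer length for read assignment.
#' @return List with `clusters` (per-cluster data.frame: fl_id, n_reads,
#'   n_polymorphic, n_haplotypes, Ks, T_years, status) and `histogram`
#'   (bin_start_my, count over dated clusters).
#' @export
duplication_analysis <- function(fl_cdnas, ests, annotations, r = 6.5e-9,
                                 min_cluster = 6L, min_support = 2L,
                                 bin_my = 5, max_my = 50, seed_k = 16L) {
  n_fl <- nrow(fl_cdnas)
  cand <- c_kmer_candidate_pairs(c(fl_cdnas$seq, ests$seq), seed_k,
                                 max_occ = 2000L)
  keep <- (cand[, 1] <= n_fl) & (cand[, 2] > n_fl)
  cand <- cand[keep, , drop = FALSE]
  # best ungapped assignment per read
  assign_fl <- rep(NA_integer_, nrow(ests))
  assign_score <- rep(-Inf, nrow(ests))
  placements <- vector("list", nrow(ests))
  for (k in seq_len(nrow(cand))) {
    fi <- cand[k, 1]; ri <- cand[k, 2] - n_fl
    hit <- c_align_ungapped(ests$seq[ri], fl_cdnas$seq[fi], 1L, -2L)
    if (hit$score <= 0) next
    if (hit$score > assign_score[ri]) {
      assign_score[ri] <- hit$score
      assign_fl[ri] <- fi
      placements[[ri]] <- hit
    }
  }
  out <- list()
  dated <- numeric(0)
  for (fi in seq_len(n_fl)) {
    reads <- which(assign_fl == fi)
    if (length(reads) < min_cluster) next
    flid <- fl_cdnas$id[fi]
    ref_len <- nchar(fl_cdnas$seq[fi])
    ann <- annotations[annotations$transcript_id == flid, , drop = FALSE]
    row <- function(status, n_poly = NA, n_hap = NA, Ks = NA, T_years = NA)
      data.frame(fl_id = flid, n_reads = length(reads),
                 n_polymorphic = n_poly, n_haplotypes = n_hap,
                 Ks = Ks, T_years = T_years, status = status)
    if (nrow(ann) == 0L || is.na(ann$orf_start)) {
      out[[length(out) + 1L]] <- row("no_orf_annotation"); next
    }
    # reference-anchored stack
    M <- matrix(NA_character_, nrow = length(reads), ncol = ref_len)
    for (t in seq_along(reads)) {
      h <- placements[[reads[t]]]
      bases <- chars(substr(ests$seq[reads[t]], h$a_start, h$a_end))
      M[t, h$b_start:h$b_end] <- bases
    }
    cds_cols <- ann$orf_start:ann$orf_end
    covered <- colSums(!is.na(M)) > 0
    if (!all(covered[cds_cols])) {
      out[[length(out) + 1L]] <- row("cds_not_covered"); next
    }
    # mask under-supported alleles (sequencing error control)
    for (j in which(colSums(!is.na(M)) > 0)) {
      tab <- table(M[, j])
      bad <- names(tab)[tab < min_support]
      if (length(bad)) M[M[, j] %in% bad, j] <- NA
    }
    poly <- which(vapply(seq_len(ref_len), function(j)
      length(unique(M[!is.na(M[, j]), j])) >= 2L, TRUE))
    if (length(poly) == 0L) {
      out[[length(out) + 1L]] <- row("monomorphic", 0L, 1L); next
    }
    # haplotype grouping by agreement at retained polymorphic columns
    P <- M[, poly, drop = FALSE]
    informative <- which(rowSums(!is.na(P)) > 0)
    g <- igraph::make_empty_graph(n = length(informative), directed = FALSE)
    if (length(informative) >= 2L) {
      for (x in seq_along(informative)) for (y in seq_len(x - 1L)) {
        px <- P[informative[x], ]; py <- P[informative[y], ]
        shared <- !is.na(px) & !is.na(py)
        if (any(shared) && all(px[shared] == py[shared]))
          g <- igraph::add_edges(g, c(x, y))
      }
    }
    comp <- igraph::components(g)$membership
    n_hap <- max(comp)
    if (n_hap != 2L) {
      out[[length(out) + 1L]] <- row("not_two_haplotypes",
                                     length(poly), n_hap)
      next
    }
    cons <- sapply(1:2, function(h) {
      rows <- informative[comp == h]
      vapply(cds_cols, function(j) {
        v <- M[rows, j]; v <- v[!is.na(v)]
        if (!length(v)) return(NA_character_)
        names(sort(table(v), decreasing = TRUE))[1]
      }, "")
    })
    if (anyNA(cons)) {
      out[[length(out) + 1L]] <- row("haplotype_cds_incomplete",
                                     length(poly), 2L)
      next
    }
    est <- haplotype_kaks(paste(cons[, 1], collapse = ""),
                          paste(cons[, 2], collapse = ""))
    if (is.null(est) || is.na(est$Ks)) {
      out[[length(out) + 1L]] <- row("ks_undefined", length(poly), 2L)
      next
    }
    T_years <- date_divergence(est$Ks, r)
    dated <- c(dated, T_years)
    out[[length(out) + 1L]] <- row("dated", length(poly), 2L,
                                   est$Ks, T_years)
  }
  clusters <- if (length(out)) do.call(rbind, out)
    else data.frame(fl_id = character(0), n_reads = integer(0),
                    n_polymorphic = integer(0), n_haplotypes = integer(0),
                    Ks = numeric(0), T_years = numeric(0),
                    status = character(0))
  breaks <- seq(0, max_my, by = bin_my)
  counts <- table(cut(dated / 1e6, c(breaks, Inf), right = FALSE))
  histogram <- data.frame(bin_start_my = c(breaks),
                          count = as.integer(counts))
  list(clusters = clusters, histogram = histogram)
}

# NG86 on two equal-length in-frame coding sequences (already anchored on
# the same reference coordinates, so no realignment is needed)
haplotype_kaks <- function(cds_a, cds_b) {
  n <- min(nchar(cds_a), nchar(cds_b))
  n <- n - n %% 3L
  if (n < 30L) return(NULL)
  p1 <- seq(1L, n - 2L, by = 3L)
  ca <- substring(cds_a, p1, p1 + 2L)
  cb <- substring(cds_b, p1, p1 + 2L)
  ok <- !(ca %in% STOP_CODONS) & !(cb %in% STOP_CODONS) &
    !grepl("N", ca) & !grepl("N", cb)
  if (sum(ok) < 10L) return(NULL)
  cnt <- ng86_count(ca[ok], cb[ok])
  list(Ks = jc_correct(cnt$Sd / cnt$S), Ka = jc_correct(cnt$Nd / cnt$N))
}
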