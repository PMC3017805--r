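# Nei-Gojobori (1986) synonymous / nonsynonymous divergence with
# Jukes-Cantor multiple-hit correction, over a peptide-guided codon
# alignment, plus the molecular-clock dating T = Ks / (2r).

#' @include utils.R
NULL

# per-codon (synonymous, nonsynonymous) site counts; mutations creating a
# stop codon count as nonsynonymous
ng86_sites <- function(codon) {
  aa <- GENETIC_CODE_TABLE[[codon]]
  v <- chars(codon)
  syn <- 0
  for (pos in 1:3) {
    for (alt in setdiff(DNA_BASES, v[pos])) {
      w <- v; w[pos] <- alt
      if (GENETIC_CODE_TABLE[[paste(w, collapse = "")]] == aa)
        syn <- syn + 1 / 3
    }
  }
  c(syn = syn, nonsyn = 3 - syn)
}

# observed (synonymous, nonsynonymous) differences between two sense
# codons, averaging over minimal mutational pathways; pathways crossing a
# stop codon are excluded unless every pathway does
ng86_diffs <- function(c1, c2) {
  v1 <- chars(c1); v2 <- chars(c2)
  dpos <- which(v1 != v2)
  nd <- length(dpos)
  if (nd == 0L) return(c(sd = 0, nd = 0))
  perms <- if (nd == 1L) list(dpos)
           else if (nd == 2L) list(dpos, rev(dpos))
           else list(dpos[c(1,2,3)], dpos[c(1,3,2)], dpos[c(2,1,3)],
                     dpos[c(2,3,1)], dpos[c(3,1,2)], dpos[c(3,2,1)])
  path_counts <- function(ord) {
    cur <- v1; s <- 0; n <- 0
    for (pos in ord) {
      nxt <- cur; nxt[pos] <- v2[pos]
      a1 <- GENETIC_CODE_TABLE[[paste(cur, collapse = "")]]
      a2 <- GENETIC_CODE_TABLE[[paste(nxt, collapse = "")]]
      if (a2 == "*" || a1 == "*") return(NULL)
      if (a1 == a2) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    c(s, n)
  }
  res <- Filter(Negate(is.null), lapply(perms, path_counts))
  if (!length(res)) {
    # all pathways cross a stop: fall back to counting without exclusion
    res <- lapply(perms, function(ord) {
      cur <- v1; s <- 0; n <- 0
      for (pos in ord) {
        nxt <- cur; nxt[pos] <- v2[pos]
        same <- GENETIC_CODE_TABLE[[paste(cur, collapse = "")]] ==
          GENETIC_CODE_TABLE[[paste(nxt, collapse = "")]]
        if (same) s <- s + 1 else n <- n + 1
        cur <- nxt
      }
      c(s, n)
    })
  }
  m <- colMeans(do.call(rbind, res))
  c(sd = m[[1]], nd = m[[2]])
}

# site counts for all sense codons, computed once; diff counts are memoised
# per codon pair
NG86_SITES <- local({
  sense <- names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE != "*"]
  m <- vapply(sense, ng86_sites, c(syn = 0, nonsyn = 0))
  colnames(m) <- sense
  m
})
.ng86_diff_cache <- new.env(parent = emptyenv())

ng86_diffs_memo <- function(c1, c2) {
  key <- paste0(c1, c2)
  hit <- .ng86_diff_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- ng86_diffs(c1, c2)
  .ng86_diff_cache[[key]] <- val
  val
}

# fast NG86 counting over parallel codon vectors (sense codons only)
ng86_count <- function(ca, cb) {
  S <- (sum(NG86_SITES["syn", ca]) + sum(NG86_SITES["syn", cb])) / 2
  N <- (sum(NG86_SITES["nonsyn", ca]) + sum(NG86_SITES["nonsyn", cb])) / 2
  diff <- ca != cb
  Sd <- 0; Nd <- 0
  for (k in which(diff)) {
    d <- ng86_diffs_memo(ca[k], cb[k])
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
  }
  list(S = S, N = N, Sd = Sd, Nd = Nd)
}

jc_correct <- function(p) {
  if (is.na(p) || p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' Peptide-guided codon alignment of two coding sequences
#'
#' Both inputs must be ATG-initiated coding sequences with length a
#' multiple of 3 and no internal stop codon; a terminal stop codon is
#' stripped. The translated peptides are globally aligned and the
#' alignment is back-threaded onto the nucleotides; codon pairs at gap
#' columns or containing `N` are excluded.
#'
#' @param cds_a,cds_b coding sequences.
#' @return List with parallel character vectors `codons_a`, `codons_b`.
#' @export
codon_align <- function(cds_a, cds_b) {
  prep <- function(cds) {
    cds <- toupper(cds)
    if (nchar(cds) %% 3L != 0L) stop("CDS length not a multiple of 3")
    if (substr(cds, 1, 3) != "ATG") stop("CDS does not start with ATG")
    p1 <- seq(1L, nchar(cds), by = 3L)
    codons <- substring(cds, p1, p1 + 2L)
    n <- length(codons)
    if (codons[n] %in% STOP_CODONS) codons <- codons[-n]
    aa <- GENETIC_CODE_TABLE[codons]
    aa[is.na(aa)] <- "X"   # codons containing N
    if (any(aa == "*")) stop("internal stop codon")
    list(codons = codons, pep = paste(aa, collapse = ""))
  }
  a <- prep(cds_a); b <- prep(cds_b)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a$pep), Biostrings::AAString(b$pep),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  qa <- chars(as.character(Biostrings::alignedPattern(pa)))
  sa <- chars(as.character(Biostrings::alignedSubject(pa)))
  ia <- cumsum(qa != "-"); ib <- cumsum(sa != "-")
  keep <- qa != "-" & sa != "-"
  ca <- a$codons[ia[keep]]; cb <- b$codons[ib[keep]]
  ok <- !grepl("N", ca, fixed = TRUE) & !grepl("N", cb, fixed = TRUE)
  list(codons_a = ca[ok], codons_b = cb[ok])
}

#' Nei-Gojobori divergence estimate for a codon alignment
#'
#' Synonymous and nonsynonymous site counts are per-codon fractions
#' averaged over both sequences; observed differences average over minimal
#' mutational pathways (stop-crossing pathways excluded). The proportions
#' ps = Sd/S and pn = Nd/N are Jukes-Cantor corrected,
#' d = -(3/4) log(1 - 4p/3). Proportions of 0.75 or more are saturated and
#' yield `NA` distances.
#'
#' @param alignment output of [codon_align()].
#' @param min_codons minimum comparable codon pairs required (default 10);
#'   lower it only for worked examples.
#' @return List of class `divergence_estimate`: `S`, `N`, `Sd`, `Nd`, `ps`,
#'   `pn`, `Ks`, `Ka`, `ratio` (Ka/Ks, `NA` when Ks is 0 or undefined),
#'   `codons_used`, `saturated`.
#' @export
estimate_ka_ks <- function(alignment, min_codons = 10L) {
  ca <- alignment$codons_a; cb <- alignment$codons_b
  ncod <- length(ca)
  if (ncod < min_codons) stop("fewer than ", min_codons,
                              " comparable codons")
  cnt <- ng86_count(ca, cb)
  S <- cnt$S; N <- cnt$N; Sd <- cnt$Sd; Nd <- cnt$Nd
  ps <- Sd / S; pn <- Nd / N
  Ks <- jc_correct(ps); Ka <- jc_correct(pn)
  structure(list(
    S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
    Ks = Ks, Ka = Ka,
    ratio = if (!is.na(Ks) && !is.na(Ka) && Ks > 0) Ka / Ks else NA_real_,
    codons_used = ncod,
    saturated = is.na(Ks) || is.na(Ka)), class = "divergence_estimate")
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat(sprintf(
    "NG86: S=%.2f N=%.2f Sd=%.2f Nd=%.2f  Ks=%.4f Ka=%.4f Ka/Ks=%s\n",
    x$S, x$N, x$Sd, x$Nd, x$Ks, x$Ka,
    ifelse(is.na(x$ratio), "NA", sprintf("%.3f", x$ratio))))
  invisible(x)
}

#' Estimate Ka/Ks for a pair of coding sequences
#'
#' Convenience wrapper: [codon_align()] then [estimate_ka_ks()].
#'
#' @param cds_a,cds_b coding sequences.
#' @return See [estimate_ka_ks()].
#' @export
kaks_pair <- function(cds_a, cds_b) estimate_ka_ks(codon_align(cds_a, cds_b))

#' Molecular-clock dating of a divergence
#'
#' T = Ks / (2 r), with r the synonymous substitution rate per site per
#' year; the grass rate 6.5e-9 is the default.
#'
#' @param Ks synonymous divergence (may be a vector; `NA` propagates).
#' @param r substitution rate per synonymous site per year.
#' @return Divergence time in years.
#' @export
date_divergence <- function(Ks, r = 6.5e-9) {
  stopifnot(r > 0)
  Ks / (2 * r)
}

#' Filter divergence estimates by a Ks window
#'
#' Keeps rows with Ks strictly below `max_ks` (pairs likely orthologous
#' rather than ancient paralogs) and reports how many retained pairs show
#' Ka/Ks > 1 (`attr(, "n_ratio_gt1")`) together with a Ka/Ks bin count
#' table in 0.1-wide bins (`attr(, "ratio_bins")`).
#'
#' @param estimates `data.frame` with columns `Ks` and `ratio`.
#' @param max_ks upper bound (default 0.75, exclusive).
#' @return Filtered `data.frame` with attributes described above.
#' @export
ks_window_filter <- function(estimates, max_ks = 0.75) {
  keep <- !is.na(estimates$Ks) & estimates$Ks < max_ks
  out <- estimates[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_ratio_gt1") <- sum(out$ratio > 1, na.rm = TRUE)
  br <- c(seq(0, 1, by = 0.1), Inf)
  attr(out, "ratio_bins") <- table(cut(out$ratio, br, right = FALSE))
  out
}
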