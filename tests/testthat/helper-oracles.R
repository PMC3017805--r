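# Independent oracles used throughout the suite. Each deliberately takes a
# different route than the package implementation: brute force where the
# package is clever, an external reference implementation where the package
# computes, so an agreement is evidence rather than a tautology.

# --- random sequences --------------------------------------------------

random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# a pair of related sequences: copy with point substitutions and indels
related_pair <- function(n, p_sub = 0.05, n_indel = 1L) {
  a <- random_seq(n)
  v <- strsplit(a, "")[[1]]
  hit <- which(runif(n) < p_sub)
  for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  b <- paste(v, collapse = "")
  for (k in seq_len(n_indel)) {
    pos <- sample(seq(10, nchar(b) - 10), 1)
    if (runif(1) < 0.5) {
      b <- paste0(substr(b, 1, pos), random_seq(sample(1:8, 1)),
                  substr(b, pos + 1, nchar(b)))
    } else {
      b <- paste0(substr(b, 1, pos), substr(b, pos + sample(1:8, 1) + 1,
                                            nchar(b)))
    }
  }
  list(a = a, b = b)
}

# --- alignment oracle: Biostrings local pairwise alignment -------------

biostrings_local_score <- function(a, b, match = 1, mismatch = -2,
                                   gap_open = 5, gap_ext = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = TRUE)
  Biostrings::score(Biostrings::pairwiseAlignment(
    a, b, type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_ext))
}

# --- SSR oracle: brute-force maximal-run scanner -----------------------

brute_force_ssrs <- function(seq, thresholds = ssr_default_thresholds()) {
  v <- strsplit(seq, "")[[1]]
  n <- length(v)
  hits <- list()
  for (p in seq_along(thresholds)) {
    min_count <- thresholds[p]
    i <- 1L
    while (i + p - 1L <= n) {
      motif <- paste(v[i:(i + p - 1L)], collapse = "")
      # extend the run of this motif starting at i
      j <- i
      while (j + 2L * p - 1L <= n &&
             paste(v[(j + p):(j + 2L * p - 1L)], collapse = "") == motif)
        j <- j + p
      count <- (j - i) %/% p + 1L
      end <- i + count * p - 1L
      # maximal (the tandem run cannot be extended left by one base),
      # non-degenerate, long enough
      preceded <- i > 1L && v[i - 1L] == v[i + p - 1L]
      degenerate <- FALSE
      for (d in seq_len(p - 1L)) {
        if (p %% d != 0L) next
        if (identical(strrep(substr(motif, 1L, d), p %/% d), motif))
          degenerate <- TRUE
      }
      has_n <- grepl("N", motif)
      if (count >= min_count && !preceded && !degenerate && !has_n)
        hits[[length(hits) + 1L]] <- data.frame(
          motif = canonical_motif(motif), period = p,
          repeat_count = count, start = i, end = end)
      i <- i + 1L
    }
  }
  if (!length(hits))
    return(data.frame(motif = character(0), period = integer(0),
                      repeat_count = integer(0), start = integer(0),
                      end = integer(0)))
  out <- unique(do.call(rbind, hits))
  out <- out[order(out$start, out$period), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- ORF oracle: exhaustive enumeration --------------------------------

brute_force_longest_orf <- function(seq) {
  n <- nchar(seq)
  best <- NULL
  stops <- c("TAA", "TAG", "TGA")
  for (s in seq_len(max(0L, n - 2L))) {
    if (substr(seq, s, s + 2L) != "ATG") next
    e <- s
    partial <- TRUE
    while (e + 5L <= n) {
      cod <- substr(seq, e + 3L, e + 5L)
      e <- e + 3L
      if (cod %in% stops) { partial <- FALSE; break }
    }
    end <- e + 2L
    # compare by coding codons excluding the stop, like the package
    len <- (end - s + 1L) %/% 3L - (if (partial) 0L else 1L)
    if (is.null(best) || len > best$len ||
        (len == best$len && s < best$start))
      best <- list(start = s, end = end, len = len, partial = partial)
  }
  best
}

# --- longest common substring oracle -----------------------------------

brute_force_lcs <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  best <- 0L
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    k <- 0L
    while (i + k <= na && j + k <= nb &&
           substr(a, i + k, i + k) == substr(b, j + k, j + k))
      k <- k + 1L
    if (k > best) best <- k
  }
  best
}

# --- NG86 oracle: values frozen from an external reference -------------
# implementation (biopython Bio.codonalign cal_dn_ds, method "NG86")

NG86_REFERENCE_PAIRS <- list(
  list(a="ATGATACTCCGCCGAGCGGATGCGCATGCGAGATCTATTAATCCCCAGGATTATGCGGGT",
       b="ATGATACTCCGCCGAGCGGATGCGCATGCGAGATCTATAAATCCCCAAGATCATGCGGGT",
       dN=0.0222238482, dS=0.1543890407),
  list(a="ATGACGACTAGGGGGAGCCGAGTAATGTACCATAGTGCTTGGCATCCCGGATTTAGGAAA",
       b="ATGACGACTAGGGGGAGCCGAGTAATGTACCATAGTGCATGGCATCCCGGATTTAGGAAA",
       dN=0.0000000000, dS=0.0883372767),
  list(a="ATGGATTCTGTAGTTCAAGTAGCCGTTGGCCTTTTGCGGTCTTCGCCAAAGGGCGTTCCA",
       b="ATGGATTCTGTAGTTCAAGTAGCCGTTGGTCTTTTGCGGTCTTCGCCAAAGGGCGTTCCA",
       dN=0.0000000000, dS=0.0612585233),
  list(a="ATGGTGATTACACCTAAAATGCTCCCCTTACGCATTGTCAATGTCGCTCGGACGGATAAT",
       b="ATGCTGATTACACCTAAAATGCTCCCCTTACGCGTTGTCAATGTCGCTCGGACGGATAAT",
       dN=0.0458157690, dS=0.0000000000),
  list(a="ATGGTGAGGGGTGACCACAATCCGCTATATAAGCACAGTACCGGGTCCGCTTTCTCGTGG",
       b="ATGGTTAGGGGTGACCACAATCCGCTATGTAAGCACAGTACCGGGTCCGCATTCTCGTGG",
       dN=0.0214300293, dS=0.1772915835),
  list(a="ATGGAGGCCTATATCACTGGGGAGTCAAGCGCGCTTCAATCTAGGCTTCGGCAGGTGTCG",
       b="ATGGAGGCATATATTACTGGGAAGTCAAGCGCGCTTCAATCTAGGGATCGGCAGGTGGCG",
       dN=0.0931427852, dS=0.1543890407),
  list(a="ATGTATCAAAGCTGTGCGTGCAGACCACGCATGAGTCTGACCTATAGGAGCTGCAACGGT",
       b="ATGTATCGAAGCTGTGCGTGCAGAACACGCATGAGTCATACCTGTAGGAGCTGCAACGGT",
       dN=0.0979651368, dS=0.0468902677),
  list(a="ATGCACGATGCTTGTCAAATACTTGACGACTCCACGTCTGAAGCTACATGTCGAGAAAGC",
       b="ATGCACGATGTTTGTCTAACACTGGACGACTTCACGTCTGTAGCTACATGTCGAGAAAGC",
       dN=0.1151683019, dS=0.0800759816),
  list(a="ATGTACCCTCCAACTATAGCAATGCGCTTACGCTCGTTGTCCAGAAACGGTTTACGGCAC",
       b="ATGTACCCTCCCACAATAGCACTGGGCTTACCCTCGTTGTCCAGAAACGGTTTACGGCAC",
       dN=0.0703640664, dS=0.1432914276),
  list(a="ATGATAAATTGCAACCACCGTCTACATCGTCGACTCCGGGACCGAGACTGCGTAGTAAGG",
       b="ATGATAAATGGCAACCACCGTCTACATCGTCGACACCGGGACCGAGACGGGGTAGTAAGG",
       dN=0.0814753808, dS=0.0348900117),
  list(a="ATGCGTTGTTGCCGGGCTACCGGTACCCCAAGTTTGCTGACGGCAAAGATGTCACGAGGA",
       b="ATGCGTTGTTGCCGGGCTACCGGTACCCCAAGCTTGCTGGCGGCCATGATGTCACGAAGA",
       dN=0.0709189370, dS=0.1399394667),
  list(a="ATGGGGGCCGCCTGGCGCGTCTCTTTAGTAGCCGTCCTTGCCAGACTGTCCCGTCCGGTG",
       b="ATGGGGGCCGCGTGGCGCGTCGCTTTAGGAGCCGTCTTTGCCAGACTGTGCCGTCCGGTG",
       dN=0.0993184392, dS=0.0612585233))

# --- synthetic CDS used in several tests -------------------------------

random_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sense <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  paste(c("ATG", sample(sense, n_codons - 2L, replace = TRUE), "TAA"),
        collapse = "")
}
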