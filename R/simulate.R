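# Seeded generator for FL-cDNA and 5'-EST collections with known ground
# truth: transcript architecture (UTR5 / ORF / UTR3) with grass-like
# GC-rich composition, planted SSRs, alternative-splicing isoform pairs
# with GT-AG (rarely GC-AG) introns, cis-antisense overlaps, and duplicated
# genes at chosen synonymous divergence. All randomness flows from the
# config seed, so regeneration is byte-identical.

#' @include utils.R kaks.R
NULL

#' Simulation configuration
#'
#' Defaults follow the structure of a grass FL-cDNA collection: mean
#' transcript length 1,092 nt, GC3 0.692, mean retained-intron length
#' 218 nt, antisense overlaps of 73-960 nt with mean 467, and EST contigs
#' of mean size 8 (negative binomial truncated at one, so maxima far
#' exceed the mean). AS type probabilities default to the relative
#' abundances of the six types in such collections. EST read length and
#' error rate are engineering defaults for Sanger-style 5' reads, not
#' literature values.
#'
#' @param n_genes number of genes.
#' @param mean_transcript_length mean FL-cDNA length (nt).
#' @param orf_min_aa minimum planted protein length (aa).
#' @param gc3_target target GC at third codon positions of ORFs.
#' @param gc_utr5,gc_utr3 UTR GC fractions.
#' @param utr5_mean,utr5_sd,utr3_mean,utr3_sd UTR length distributions.
#' @param intron_mean_length,intron_min_length retained-intron lengths (nt).
#' @param gcag_fraction fraction of retained introns with GC-AG boundaries.
#' @param ssr_rate_utr5,ssr_rate_orf,ssr_rate_utr3 probability that a
#'   transcript receives one planted SSR in the region.
#' @param as_fraction fraction of genes emitting an isoform pair.
#' @param as_type_probabilities named probabilities over
#'   IntronR/AltP/ExonO/ExonS/AltA/AltD (must sum to 1).
#' @param nat_fraction fraction of genes given a cis-antisense partner.
#' @param nat_overlap_range,nat_overlap_mean,nat_overlap_sd antisense
#'   overlap length distribution (truncated normal, nt).
#' @param duplication_fraction fraction of genes duplicated.
#' @param duplication_ks target synonymous divergence of duplicates.
#' @param est_mean_depth mean EST cluster size (after truncation at 1).
#' @param est_depth_dispersion negative-binomial size parameter.
#' @param est_length_mean,est_length_sd,est_min_length read lengths (nt).
#' @param est_error_rate per-base substitution error rate of reads.
#' @param seed integer seed fixing all randomness.
#' @return Validated config (list, class `simulation_config`).
#' @export
simulation_config <- function(
    n_genes = 100L,
    mean_transcript_length = 1092,
    orf_min_aa = 100L,
    gc3_target = 0.692,
    gc_utr5 = 0.568, gc_utr3 = 0.423,
    utr5_mean = 120, utr5_sd = 40, utr3_mean = 200, utr3_sd = 60,
    intron_mean_length = 218, intron_min_length = 60,
    gcag_fraction = 0.04,
    ssr_rate_utr5 = 0, ssr_rate_orf = 0, ssr_rate_utr3 = 0,
    as_fraction = 0,
    as_type_probabilities = c(IntronR = 120, AltP = 18, ExonO = 92,
                              ExonS = 29, AltA = 15, AltD = 14) / 288,
    nat_fraction = 0,
    nat_overlap_range = c(73, 960), nat_overlap_mean = 467,
    nat_overlap_sd = 150,
    duplication_fraction = 0, duplication_ks = 0.2,
    est_mean_depth = 8, est_depth_dispersion = 0.55,
    est_length_mean = 550, est_length_sd = 80, est_min_length = 100,
    est_error_rate = 0.005,
    seed = 1L) {
  cfg <- as.list(environment())
  types <- c("IntronR", "AltP", "ExonO", "ExonS", "AltA", "AltD")
  if (!setequal(names(cfg$as_type_probabilities), types))
    stop("as_type_probabilities must be named over the six AS types")
  cfg$as_type_probabilities <- cfg$as_type_probabilities[types]
  p <- cfg$as_type_probabilities
  if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-8)
    stop("as_type_probabilities must lie in [0,1] and sum to 1")
  for (f in c("as_fraction", "nat_fraction", "duplication_fraction",
              "est_error_rate", "gc3_target", "gc_utr5", "gc_utr3",
              "gcag_fraction", "ssr_rate_utr5", "ssr_rate_orf",
              "ssr_rate_utr3"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0,1]")
  if (cfg$n_genes < 1) stop("n_genes must be >= 1")
  min_len <- 3 * (cfg$orf_min_aa + 2) + 30
  if (min_len > cfg$mean_transcript_length)
    stop("impossible constraints: minimum ORF (", min_len,
         " nt with UTRs) exceeds mean transcript length ",
         cfg$mean_transcript_length)
  structure(cfg, class = "simulation_config")
}

# GC-ending weight within synonymous families solving for the target GC3,
# given that Met and Trp are fixed G-ending
solve_gc3_weight <- function(gc3_target, f_fixed) {
  p <- (gc3_target - f_fixed) / (1 - f_fixed)
  min(max(p, 0), 1)
}

# fixed G-ending codon share (Met start + sampled Met/Trp) given the
# uniform amino-acid draw; drives the GC3 calibration
calibrated_gc3_weight <- function(cfg) {
  mean_codons <- max((cfg$mean_transcript_length -
                        cfg$utr5_mean - cfg$utr3_mean) / 3,
                     cfg$orf_min_aa + 10)
  f_fixed <- (1 + (mean_codons - 1) * 2 / length(AA20)) / (mean_codons + 1)
  solve_gc3_weight(cfg$gc3_target, f_fixed)
}

# codon sampler: one codon for amino acid `aa` ("\*" for stop), with
# GC-ending codons taking total weight p within the family
sample_codon <- function(aa, p) {
  fam <- names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE == aa]
  gc_end <- substr(fam, 3, 3) %in% c("G", "C")
  if (all(gc_end) || all(!gc_end)) return(sample(fam, 1L))
  w <- ifelse(gc_end, p / sum(gc_end), (1 - p) / sum(!gc_end))
  sample(fam, 1L, prob = w)
}

random_dna <- function(n, gc) {
  if (n <= 0L) return("")
  paste(sample(DNA_BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

AA20 <- setdiff(unique(GENETIC_CODE_TABLE), "*")

# one transcript: returns list(seq, orf_start, orf_end, ssr = data.frame)
# retries until the longest-ORF annotation matches the planted ORF and the
# only detectable SSRs are the planted ones
build_transcript <- function(cfg, p_gc3, plant_ssr_region = NA,
                             max_tries = 60L) {
  codons_mean <- max((cfg$mean_transcript_length -
                        cfg$utr5_mean - cfg$utr3_mean) / 3,
                     cfg$orf_min_aa + 10)
  for (try in seq_len(max_tries)) {
    u5 <- max(10L, round(rnorm(1, cfg$utr5_mean, cfg$utr5_sd)))
    u3 <- max(20L, round(rnorm(1, cfg$utr3_mean, cfg$utr3_sd)))
    n_aa <- max(cfg$orf_min_aa + 5L,
                round(rgamma(1, shape = 6, rate = 6 / codons_mean)))
    aa <- c("M", sample(AA20, n_aa - 1L, replace = TRUE))
    cod <- vapply(aa, sample_codon, "", p = p_gc3)
    stop_cod <- sample_codon("*", p_gc3)
    orf <- paste(c(cod, stop_cod), collapse = "")
    utr5 <- random_dna(u5, cfg$gc_utr5)
    utr3 <- random_dna(u3, cfg$gc_utr3)
    ssr <- data.frame(motif = character(0), period = integer(0),
                      repeat_count = integer(0), start = integer(0),
                      end = integer(0), region = character(0))
    if (!is.na(plant_ssr_region)) {
      ins <- plant_ssr(utr5, orf, utr3, plant_ssr_region)
      utr5 <- ins$utr5; orf <- ins$orf; utr3 <- ins$utr3
      ssr <- ins$ssr
    }
    seq <- paste0(utr5, orf, utr3)
    orf_start <- nchar(utr5) + 1L
    orf_end <- nchar(utr5) + nchar(orf)
    found <- find_longest_orf(seq)
    if (is.null(found) || found$orf_start != orf_start ||
        found$orf_end != orf_end) next
    det <- detect_ssrs(seq)
    if (nrow(det) != nrow(ssr)) next
    if (nrow(ssr) > 0 &&
        !all(det$start == ssr$start & det$end == ssr$end &
               det$motif == ssr$motif)) next
    return(list(seq = seq, orf_start = orf_start, orf_end = orf_end,
                ssr = ssr))
  }
  stop("failed to build a transcript satisfying its own annotation; ",
       "check the configuration")
}

SSR_MOTIFS <- list(
  utr = list(mono = c("A", "T"), di = c("AG", "AT", "CT", "GA", "TC")),
  orf = c("CCG", "AGC", "GGC", "AAG", "GCT"))

# insert one SSR into the named region; ORF insertions are in-frame
# repeats of a non-stop codon so the reading frame survives
plant_ssr <- function(utr5, orf, utr3, region) {
  if (region == "ORF") {
    motif <- sample(SSR_MOTIFS$orf, 1L)
    count <- sample(5:8, 1L)
    ncod <- nchar(orf) %/% 3L
    at_codon <- sample(2:(ncod - 2L), 1L)
    pos <- 3L * (at_codon - 1L)          # insert after this many nt
    orf <- paste0(substr(orf, 1, pos), strrep(motif, count),
                  substr(orf, pos + 1L, nchar(orf)))
    start_in_tx <- nchar(utr5) + pos + 1L
    period <- 3L
  } else {
    utr <- if (region == "5'UTR") utr5 else utr3
    kind <- sample(names(SSR_MOTIFS$utr), 1L)
    motif <- sample(SSR_MOTIFS$utr[[kind]], 1L)
    count <- if (kind == "mono") sample(10:14, 1L) else sample(6:9, 1L)
    pos <- sample(3:(nchar(utr) - 2L), 1L)
    ins <- strrep(motif, count)
    utr <- paste0(substr(utr, 1, pos), ins,
                  substr(utr, pos + 1L, nchar(utr)))
    if (region == "5'UTR") {
      utr5 <- utr
      start_in_tx <- pos + 1L
    } else {
      utr3 <- utr
      start_in_tx <- nchar(utr5) + nchar(orf) + pos + 1L
    }
    period <- nchar(motif)
  }
  list(utr5 = utr5, orf = orf, utr3 = utr3,
       ssr = data.frame(motif = canonical_motif(motif), period = period,
                        repeat_count = count, start = start_in_tx,
                        end = start_in_tx + period * count - 1L,
                        region = region))
}

# inserted-segment constructors for the AS types; each is checked across
# the full slide register so its truth label is unambiguous
draw_intron_len <- function(cfg) {
  max(cfg$intron_min_length,
      round(rgamma(1, shape = 4, rate = 4 / cfg$intron_mean_length)))
}

segment_ok <- function(x, p, L, want) {
  rng <- slide_range(x, p, L)
  starts_gt <- starts_gc <- ends_ag <- FALSE
  gt_ag <- gc_ag <- FALSE
  for (pp in rng[1]:rng[2]) {
    s <- substr(x, pp, pp + L - 1L)
    sgt <- startsWith(s, "GT"); sgc <- startsWith(s, "GC")
    eag <- endsWith(s, "AG")
    starts_gt <- starts_gt || sgt; starts_gc <- starts_gc || sgc
    ends_ag <- ends_ag || eag
    gt_ag <- gt_ag || (sgt && eag); gc_ag <- gc_ag || (sgc && eag)
  }
  switch(want,
    "IntronR-GT" = gt_ag,
    "IntronR-GC" = !gt_ag && gc_ag,
    "AltD" = starts_gt && !ends_ag,
    "AltA" = ends_ag && !starts_gt && !gt_ag && !gc_ag,
    "ExonS" = !starts_gt && !starts_gc && !ends_ag)
}

insert_segment <- function(seq, cfg, want, max_tries = 100L) {
  for (try in seq_len(max_tries)) {
    L <- draw_intron_len(cfg)
    core <- random_dna(L - 4L, 0.42)
    seg <- switch(want,
      "IntronR-GT" = paste0("GT", core, "AG"),
      "IntronR-GC" = paste0("GC", core, "AG"),
      "AltD" = paste0("GT", core, sample(c("CC", "GC", "TC"), 1)),
      "AltA" = paste0(sample(c("CA", "TA", "AA"), 1), core, "AG"),
      "ExonS" = paste0(sample(c("CA", "TG", "AC"), 1), core,
                       sample(c("CC", "GC", "TC"), 1)))
    p <- sample(seq(60L, nchar(seq) - 60L), 1L)
    out <- paste0(substr(seq, 1, p - 1L), seg,
                  substr(seq, p, nchar(seq)))
    if (segment_ok(out, p, L, want))
      return(list(seq = out, at = p, len = L))
  }
  stop("could not construct an unambiguous ", want, " insertion")
}

#' Simulate a FL-cDNA collection with known ground truth
#'
#' Generates `n_genes` gene models and their transcripts. Genes selected
#' for alternative splicing emit two isoforms whose structural difference
#' is guaranteed unambiguous for its truth type; genes selected as
#' antisense donors get a partner transcript beginning with the reverse
#' complement of their 3' end; duplicated genes get a paralog whose coding
#' sequence is mutated to the configured synonymous divergence. Every
#' planted event appears exactly once in the truth table.
#'
#' @param config a [simulation_config()].
#' @return List with `transcripts` (record table), `annotations` (planted
#'   ORF coordinates per transcript), and `truth` (data.frame: event_type
#'   in SSR/AS/NAT/DUP, ids, type, coordinates, parameters).
#' @export
simulate_transcriptome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  with_seed(cfg$seed, {
    p_gc3 <- calibrated_gc3_weight(cfg)

    n <- cfg$n_genes
    n_as <- round(cfg$as_fraction * n)
    n_nat <- round(cfg$nat_fraction * n)
    n_dup <- round(cfg$duplication_fraction * n)
    roles <- rep("plain", n)
    if (n_as > 0) roles[seq_len(n_as)] <- "as"
    if (n_nat > 0) roles[n_as + seq_len(n_nat)] <- "nat"
    if (n_dup > 0) roles[n_as + n_nat + seq_len(n_dup)] <- "dup"
    if (n_as + n_nat + n_dup > n)
      stop("as/nat/duplication fractions exceed the gene count")
    ssr_region <- rep(NA_character_, n)
    plain <- which(roles %in% c("plain", "dup", "nat"))
    for (reg in c("5'UTR", "ORF", "3'UTR")) {
      rate <- switch(reg, "5'UTR" = cfg$ssr_rate_utr5,
                     "ORF" = cfg$ssr_rate_orf, "3'UTR" = cfg$ssr_rate_utr3)
      if (rate <= 0) next
      pick <- plain[is.na(ssr_region[plain]) &
                      runif(length(plain)) < rate]
      ssr_region[pick] <- reg
    }

    ids <- character(0); seqs <- character(0)
    ann <- list(); truth <- list()
    add_tx <- function(id, tx) {
      ids <<- c(ids, id); seqs <<- c(seqs, tx$seq)
      ann[[length(ann) + 1L]] <<- data.frame(
        transcript_id = id, gene_id = attr(tx, "gene_id"),
        orf_start = tx$orf_start, orf_end = tx$orf_end)
      if (!is.null(tx$ssr) && nrow(tx$ssr) > 0)
        truth[[length(truth) + 1L]] <<- data.frame(
          event_type = "SSR", id_a = id, id_b = NA, type = tx$ssr$motif,
          start = tx$ssr$start, end = tx$ssr$end,
          length = tx$ssr$end - tx$ssr$start + 1L, param = tx$ssr$region)
    }
    as_types <- names(cfg$as_type_probabilities)

    for (g in seq_len(n)) {
      gid <- sprintf("G%04d", g)
      tx <- build_transcript(cfg, p_gc3, ssr_region[g])
      attr(tx, "gene_id") <- gid
      base_id <- sprintf("FLC%05d", length(ids) + 1L)

      if (roles[g] == "as") {
        type <- sample(as_types, 1L, prob = cfg$as_type_probabilities)
        iso_id <- sprintf("FLC%05d", length(ids) + 2L)
        if (type == "IntronR") {
          want <- if (runif(1) < cfg$gcag_fraction) "IntronR-GC"
                  else "IntronR-GT"
          ins <- insert_segment(tx$seq, cfg, want)
          add_tx(base_id, tx)
          ids <- c(ids, iso_id); seqs <- c(seqs, ins$seq)
          truth[[length(truth) + 1L]] <- data.frame(
            event_type = "AS", id_a = base_id, id_b = iso_id,
            type = "IntronR", start = ins$at, end = ins$at + ins$len - 1L,
            length = ins$len,
            param = if (want == "IntronR-GC") "GC-AG" else "GT-AG")
        } else if (type %in% c("AltD", "AltA", "ExonS")) {
          ins <- insert_segment(tx$seq, cfg, type)
          add_tx(base_id, tx)
          ids <- c(ids, iso_id); seqs <- c(seqs, ins$seq)
          truth[[length(truth) + 1L]] <- data.frame(
            event_type = "AS", id_a = base_id, id_b = iso_id, type = type,
            start = ins$at, end = ins$at + ins$len - 1L, length = ins$len,
            param = "")
        } else if (type == "AltP") {
          i1 <- insert_segment(tx$seq, cfg, "IntronR-GT")
          # second intron in the other isoform, well away from the first
          repeat {
            i2 <- insert_segment(tx$seq, cfg, "IntronR-GT")
            if (abs(i2$at - i1$at) > i1$len + i2$len + 120) break
          }
          ids <- c(ids, base_id); seqs <- c(seqs, i1$seq)
          ids <- c(ids, iso_id); seqs <- c(seqs, i2$seq)
          truth[[length(truth) + 1L]] <- data.frame(
            event_type = "AS", id_a = base_id, id_b = iso_id,
            type = "AltP", start = i1$at, end = i1$at + i1$len - 1L,
            length = i1$len, param = "GT-AG")
        } else { # ExonO
          L <- nchar(tx$seq)
          o <- min(L - 60L, max(120L, round(rnorm(1, 300, 80))))
          tail_len <- max(120L, round(rnorm(1, 300, 80)))
          b_seq <- paste0(substr(tx$seq, L - o + 1L, L),
                          random_dna(tail_len, 0.45))
          add_tx(base_id, tx)
          ids <- c(ids, iso_id); seqs <- c(seqs, b_seq)
          truth[[length(truth) + 1L]] <- data.frame(
            event_type = "AS", id_a = base_id, id_b = iso_id,
            type = "ExonO", start = L - o + 1L, end = L, length = o,
            param = "")
        }
      } else if (roles[g] == "nat") {
        add_tx(base_id, tx)
        L <- nchar(tx$seq)
        repeat {
          o <- round(rnorm(1, cfg$nat_overlap_mean, cfg$nat_overlap_sd))
          if (o >= cfg$nat_overlap_range[1] &&
              o <= min(cfg$nat_overlap_range[2], L - 20L)) break
        }
        nat_id <- sprintf("NATP%04d", g)
        nat_seq <- paste0(revcomp(substr(tx$seq, L - o + 1L, L)),
                          random_dna(max(150L, round(rnorm(1, 350, 100))),
                                     0.45))
        ids <- c(ids, nat_id); seqs <- c(seqs, nat_seq)
        truth[[length(truth) + 1L]] <- data.frame(
          event_type = "NAT", id_a = base_id, id_b = nat_id,
          type = "cis-NAT", start = L - o + 1L, end = L, length = o,
          param = "")
      } else if (roles[g] == "dup") {
        add_tx(base_id, tx)
        dup_id <- sprintf("DUP%05d", g)
        cds <- substr(tx$seq, tx$orf_start, tx$orf_end)
        mut <- mutate_to_ks(cds, cfg$duplication_ks,
                            seed = cfg$seed + 7L * g)
        dup_seq <- paste0(
          mutate_utr(substr(tx$seq, 1, tx$orf_start - 1L),
                     cfg$duplication_ks / 2),
          mut,
          mutate_utr(substr(tx$seq, tx$orf_end + 1L, nchar(tx$seq)),
                     cfg$duplication_ks / 2))
        ids <- c(ids, dup_id); seqs <- c(seqs, dup_seq)
        ann[[length(ann) + 1L]] <- data.frame(
          transcript_id = dup_id, gene_id = gid,
          orf_start = tx$orf_start, orf_end = tx$orf_start + nchar(mut) - 1L)
        truth[[length(truth) + 1L]] <- data.frame(
          event_type = "DUP", id_a = base_id, id_b = dup_id,
          type = "duplicate", start = NA, end = NA, length = NA,
          param = as.character(cfg$duplication_ks))
      } else {
        add_tx(base_id, tx)
      }
    }

    transcripts <- transcript_records(ids, seqs)
    annotations <- do.call(rbind, ann)
    truth <- if (length(truth)) do.call(rbind, truth)
      else data.frame(event_type = character(0), id_a = character(0),
                      id_b = character(0), type = character(0),
                      start = integer(0), end = integer(0),
                      length = integer(0), param = character(0))
    rownames(truth) <- NULL
    list(transcripts = transcripts, annotations = annotations,
         truth = truth, config = cfg)
  })
}

# substitution noise for UTRs of duplicated genes
mutate_utr <- function(x, p) {
  if (!nzchar(x) || p <= 0) return(x)
  v <- chars(x)
  hit <- which(runif(length(v)) < p)
  for (i in hit) v[i] <- sample(setdiff(DNA_BASES, v[i]), 1L)
  paste(v, collapse = "")
}

#' Simulate directional 5'-EST reads from transcripts
#'
#' Per-transcript read counts follow a negative binomial truncated at one
#' whose truncated mean equals `est_mean_depth`; reads start at or near
#' the 5' end, lengths are normal (`est_length_mean`, `est_length_sd`)
#' truncated to `[est_min_length, transcript length]`, and substitution
#' errors occur at `est_error_rate` per base.
#'
#' @param transcripts record table (sources).
#' @param config a [simulation_config()].
#' @param depth optional integer vector or single value overriding the
#'   random per-transcript depth (e.g. a constant design).
#' @return Record table of reads with a `source_id` column (truth).
#' @export
simulate_ests <- function(transcripts, config, depth = NULL) {
  stopifnot(nrow(transcripts) > 0)
  cfg <- config
  with_seed(cfg$seed + 104729L, {
    mu <- truncated_nb_mu(cfg$est_mean_depth, cfg$est_depth_dispersion)
    n <- nrow(transcripts)
    depths <- if (!is.null(depth)) rep_len(as.integer(depth), n)
      else vapply(seq_len(n), function(i) {
        repeat {
          d <- rnbinom(1, size = cfg$est_depth_dispersion, mu = mu)
          if (d >= 1) return(as.integer(d))
        }
      }, 1L)
    ids <- character(0); seqs <- character(0); src <- character(0)
    for (i in seq_len(n)) {
      tx <- transcripts$seq[i]
      L <- nchar(tx)
      for (r in seq_len(depths[i])) {
        offset <- min(rgeom(1, 0.25), max(0L, L - cfg$est_min_length))
        len <- round(rnorm(1, cfg$est_length_mean, cfg$est_length_sd))
        len <- max(cfg$est_min_length, min(len, L - offset))
        read <- substr(tx, offset + 1L, offset + len)
        if (cfg$est_error_rate > 0) {
          v <- chars(read)
          hit <- which(runif(length(v)) < cfg$est_error_rate)
          for (k in hit) v[k] <- sample(setdiff(DNA_BASES, v[k]), 1L)
          read <- paste(v, collapse = "")
        }
        ids <- c(ids, sprintf("EST%06d", length(ids) + 1L))
        seqs <- c(seqs, read)
        src <- c(src, transcripts$id[i])
      }
    }
    out <- transcript_records(ids, seqs)
    out$source_id <- src
    out
  })
}

# mean parameter mu of a negative binomial such that the zero-truncated
# mean equals `target`
truncated_nb_mu <- function(target, size) {
  f <- function(mu) mu / (1 - dnbinom(0, size = size, mu = mu)) - target
  stats::uniroot(f, c(1e-6, target))$root
}

#' Mutate a coding sequence to a target synonymous divergence
#'
#' Applies random synonymous substitutions (codon-aware rejection
#' sampling, uniform over the three alternative bases, never touching the
#' start codon) until the NG86 Ks between input and output reaches
#' `target_ks`; optionally nonsynonymous substitutions follow until Ka
#' reaches `ka_ks * target_ks`. Matching the NG86 counting assumptions
#' makes downstream recovery unbiased.
#'
#' @param cds ATG-initiated coding sequence, length multiple of 3, no
#'   internal stop.
#' @param target_ks target synonymous divergence (>= 0; values implying a
#'   synonymous difference proportion of 0.749 or more are saturated and
#'   rejected).
#' @param seed RNG seed.
#' @param ka_ks nonsynonymous/synonymous target ratio (default 0: purely
#'   synonymous divergence).
#' @return The mutated coding sequence; `attr(, "achieved_ks")` and
#'   `attr(, "achieved_ka")` record the realized NG86 values.
#' @export
mutate_to_ks <- function(cds, target_ks, seed = 1L, ka_ks = 0) {
  stopifnot(target_ks >= 0)
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L) stop("CDS length not a multiple of 3")
  p_target <- 0.75 * (1 - exp(-4 * target_ks / 3))
  if (p_target >= 0.749)
    stop("target_Ks ", target_ks, " is beyond saturation (ps >= 0.749)")
  if (target_ks == 0 && ka_ks == 0) return(cds)
  p1 <- seq(1L, nchar(cds), by = 3L)
  orig <- substring(cds, p1, p1 + 2L)
  ncod <- length(orig)
  has_stop <- orig %in% STOP_CODONS
  if (any(has_stop[-ncod])) stop("internal stop codon")
  mutable <- setdiff(seq_len(ncod), c(1L, which(has_stop)))
  cur <- orig
  measure <- function() {
    keep <- !has_stop
    cnt <- ng86_count(orig[keep], cur[keep])
    list(ks = jc_correct(cnt$Sd / cnt$S), ka = jc_correct(cnt$Nd / cnt$N))
  }
  with_seed(seed, {
    apply_subs <- function(kind, target, get) {
      if (target <= 0) return()
      repeat {
        m <- measure()
        if (!is.na(get(m)) && get(m) >= target) break
        repeat {
          ci <- sample(mutable, 1L)
          pos <- sample(3L, 1L)
          v <- chars(cur[ci])
          alt <- sample(setdiff(DNA_BASES, v[pos]), 1L)
          w <- v; w[pos] <- alt
          cand <- paste(w, collapse = "")
          if (cand %in% STOP_CODONS) next
          syn <- GENETIC_CODE_TABLE[[cand]] == GENETIC_CODE_TABLE[[cur[ci]]]
          if ((kind == "syn") == syn) {
            cur[ci] <<- cand
            break
          }
        }
      }
    }
    apply_subs("syn", target_ks, function(m) m$ks)
    apply_subs("nonsyn", ka_ks * target_ks, function(m) m$ka)
  })
  out <- paste(cur, collapse = "")
  m <- local({
    keep <- !has_stop
    cnt <- ng86_count(orig[keep], cur[keep])
    list(ks = jc_correct(cnt$Sd / cnt$S), ka = jc_correct(cnt$Nd / cnt$N))
  })
  attr(out, "achieved_ks") <- m$ks
  attr(out, "achieved_ka") <- m$ka
  out
}

#' Simulate a multi-species ortholog panel with known category truth
#'
#' Builds `config$n_genes` query transcripts and, per query, plants
#' orthologous copies in a chosen subset of species databases so that the
#' query's homolog-presence category is known by construction. With the
#' first species as the reference: `shared_all` queries get a copy in
#' every species, `ref_not_all` in the reference but not the last
#' species, `others_not_ref` in every species except the reference, and
#' `no_hit` in none. Copies diverge from the query by synonymous and
#' nonsynonymous substitution to (`ortholog_ks`, `ortholog_ka_ks`), with
#' matched substitution noise in the UTRs; each species also receives
#' `n_decoys` unrelated transcripts.
#'
#' @param config a [simulation_config()]; supplies gene architecture and
#'   the seed.
#' @param species character vector of species names (>= 2; first is the
#'   reference).
#' @param category_fractions named fractions over
#'   shared_all/ref_not_all/others_not_ref/no_hit, summing to 1.
#' @param ortholog_ks synonymous divergence of planted orthologs.
#' @param ortholog_ka_ks Ka/Ks of planted orthologs (> 0 keeps peptides
#'   diverged but recognizable).
#' @param n_decoys unrelated transcripts added per species.
#' @return List with `queries` (record table), `species_dbs` (named list
#'   of record tables), and `truth` (query_id, category, one id column
#'   per species, `NA` where absent).
#' @export
simulate_ortholog_panel <- function(config, species = c("spA", "spB"),
                                    category_fractions = c(
                                      shared_all = 0.4, ref_not_all = 0.2,
                                      others_not_ref = 0.1, no_hit = 0.3),
                                    ortholog_ks = 0.3, ortholog_ka_ks = 0.2,
                                    n_decoys = 3L) {
  stopifnot(inherits(config, "simulation_config"), length(species) >= 2L)
  lv <- c("shared_all", "ref_not_all", "others_not_ref", "no_hit")
  if (!setequal(names(category_fractions), lv) ||
      abs(sum(category_fractions) - 1) > 1e-8)
    stop("category_fractions must be named over ", paste(lv, collapse = "/"),
         " and sum to 1")
  cfg <- config
  n <- cfg$n_genes
  counts <- floor(category_fractions[lv] * n)
  counts["no_hit"] <- counts["no_hit"] + (n - sum(counts))
  categories <- rep(lv, counts)
  with_seed(cfg$seed + 7919L, {
    p_gc3 <- calibrated_gc3_weight(cfg)
    p_utr <- 0.75 * (1 - exp(-4 * ortholog_ks / 3))
    q_ids <- character(0); q_seqs <- character(0)
    sp_ids <- sp_seqs <- setNames(
      rep(list(character(0)), length(species)), species)
    truth <- list()
    for (g in seq_len(n)) {
      tx <- build_transcript(cfg, p_gc3)
      qid <- sprintf("Q%04d", g)
      q_ids <- c(q_ids, qid); q_seqs <- c(q_seqs, tx$seq)
      present <- switch(categories[g],
        shared_all = rep(TRUE, length(species)),
        ref_not_all = c(TRUE, rep(TRUE, length(species) - 2L), FALSE),
        others_not_ref = c(FALSE, rep(TRUE, length(species) - 1L)),
        no_hit = rep(FALSE, length(species)))
      placed <- rep(NA_character_, length(species))
      cds <- substr(tx$seq, tx$orf_start, tx$orf_end)
      for (s in which(present)) {
        mut <- mutate_to_ks(cds, ortholog_ks,
                            seed = cfg$seed + 101L * g + s,
                            ka_ks = ortholog_ka_ks)
        oseq <- paste0(
          mutate_utr(substr(tx$seq, 1, tx$orf_start - 1L), p_utr),
          mut,
          mutate_utr(substr(tx$seq, tx$orf_end + 1L, nchar(tx$seq)), p_utr))
        oid <- sprintf("%s_%04d", species[s], g)
        sp_ids[[s]] <- c(sp_ids[[s]], oid)
        sp_seqs[[s]] <- c(sp_seqs[[s]], oseq)
        placed[s] <- oid
      }
      truth[[g]] <- as.data.frame(c(
        list(query_id = qid, category = categories[g]),
        setNames(as.list(placed), species)))
    }
    for (s in seq_along(species)) for (k in seq_len(n_decoys)) {
      tx <- build_transcript(cfg, p_gc3)
      sp_ids[[s]] <- c(sp_ids[[s]], sprintf("%s_decoy%02d", species[s], k))
      sp_seqs[[s]] <- c(sp_seqs[[s]], tx$seq)
    }
    list(queries = transcript_records(q_ids, q_seqs),
         species_dbs = setNames(lapply(seq_along(species), function(s)
           transcript_records(sp_ids[[s]], sp_seqs[[s]])), species),
         truth = do.call(rbind, truth))
  })
}

#' Write a simulated dataset to disk
#'
#' @param sim output of [simulate_transcriptome()].
#' @param dir output directory (created if needed).
#' @param ests optional read table from [simulate_ests()].
#' @return Invisibly, the paths written (transcript FASTA, truth TSV, and
#'   EST FASTA when given); the seed and paths are echoed to a log file.
#' @export
write_simulation <- function(sim, dir, ests = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(transcripts = file.path(dir, "transcripts.fasta"),
             truth = file.path(dir, "truth.tsv"))
  write_fasta(sim$transcripts, paths["transcripts"])
  write_tsv(sim$truth, paths["truth"])
  if (!is.null(ests)) {
    paths["ests"] <- file.path(dir, "ests.fasta")
    write_fasta(ests[, c("id", "seq", "description")], paths["ests"])
  }
  log <- file.path(dir, "simulation.log")
  writeLines(c(sprintf("seed\t%d", sim$config$seed),
               sprintf("%s\t%s", names(paths), paths)), log)
  invisible(paths)
}
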