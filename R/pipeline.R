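# End-to-end orchestration: every stage writes one TSV into the output
# directory and the run ends with a summary of headline figures plus an
# echo of every threshold, so two runs with the same config are
# byte-identical.

#' Pipeline configuration
#'
#' Bundles a simulation design with every per-stage threshold. All
#' thresholds default to the values used throughout the package;
#' unknown arguments are rejected.
#'
#' @param simulation a [simulation_config()] describing the input data.
#' @param cluster_min_identity,cluster_window transcript/EST clustering
#'   thresholds (identity strict >, window in nt).
#' @param redundancy_identity,redundancy_coverage redundancy-removal
#'   thresholds.
#' @param orf_min_aa ORF size cut (strict >, aa).
#' @param as_min_flank_identity,as_min_flank_cols,as_min_intron
#'   alternative-splicing candidate thresholds.
#' @param nat_min_overlap,nat_max_mismatches antisense thresholds.
#' @param homolog_nt_identity,homolog_nt_coverage nucleotide homolog
#'   thresholds (strict >).
#' @param panel_species,panel_genes,panel_ks,panel_ka_ks ortholog-panel
#'   design (species count includes the reference).
#' @param ks_max upper bound of the retained Ks window.
#' @param clock_rate synonymous substitutions per site per year.
#' @param dup_min_cluster,dup_min_support duplication-dating thresholds.
#' @param dup_bin_my age-histogram bin width (My).
#' @param nj_bootstrap bootstrap replicates for the tree (0 disables).
#' @return Validated config (list, class `pipeline_config`).
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            cluster_min_identity = 0.95,
                            cluster_window = 80L,
                            redundancy_identity = 0.99,
                            redundancy_coverage = 0.9,
                            orf_min_aa = 100L,
                            as_min_flank_identity = 0.99,
                            as_min_flank_cols = 100L,
                            as_min_intron = 30L,
                            nat_min_overlap = 50L,
                            nat_max_mismatches = 1L,
                            homolog_nt_identity = 0.75,
                            homolog_nt_coverage = 0.5,
                            panel_species = 2L,
                            panel_genes = 12L,
                            panel_ks = 0.3,
                            panel_ka_ks = 0.2,
                            ks_max = 0.75,
                            clock_rate = 6.5e-9,
                            dup_min_cluster = 6L,
                            dup_min_support = 2L,
                            dup_bin_my = 5,
                            nj_bootstrap = 0L) {
  stopifnot(inherits(simulation, "simulation_config"))
  cfg <- as.list(environment())
  if (cfg$panel_species < 2L) stop("panel_species must be >= 2")
  structure(cfg, class = "pipeline_config")
}

#' Run the full characterization pipeline
#'
#' Simulates the dataset, then runs clustering, redundancy removal, ORF
#' and composition analysis, SSR profiling, alternative-splicing and
#' antisense detection, a multi-species homology/ortholog panel, Ka/Ks
#' with molecular-clock dating, EST-cluster duplication dating, and a
#' neighbor-joining tree of the panel species. Each stage writes one TSV
#' (the tree as newick) into `out_dir`, and `summary.tsv` collects the
#' headline figures together with every threshold. Deterministic: the
#' same config yields byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list of the per-stage in-memory results.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(out_dir, f)
  summary_rows <- list()
  note <- function(key, value) {
    if (is.null(value) || length(value) == 0L) value <- NA
    summary_rows[[length(summary_rows) + 1L]] <<-
      data.frame(key = key, value = as.character(value))
  }

  # --- simulate ---------------------------------------------------------
  sim <- simulate_transcriptome(cfg$simulation)
  ests <- simulate_ests(sim$transcripts, cfg$simulation)
  write_simulation(sim, out_dir, ests)
  note("n_transcripts", nrow(sim$transcripts))
  note("n_ests", nrow(ests))

  # --- EST clustering ---------------------------------------------------
  clusters <- cluster_ests(ests, min_identity = cfg$cluster_min_identity,
                           window = cfg$cluster_window)
  write_tsv(clusters, path("clusters.tsv"))
  cs <- cluster_summary(clusters)
  note("n_clusters", cs$n_clusters)
  note("n_singleton_clusters", cs$n_singletons)
  note("mean_cluster_size", round(cs$mean_size, 3))
  note("max_cluster_size", cs$max_size)

  # --- redundancy removal on the FL-cDNAs -------------------------------
  nr <- filter_redundant(sim$transcripts,
                         min_identity = cfg$redundancy_identity,
                         min_coverage = cfg$redundancy_coverage)
  dropped <- attr(nr, "dropped")
  write_tsv(nr[, c("id", "description")], path("nonredundant.tsv"))
  note("n_nonredundant", nrow(nr))

  # --- ORF + composition ------------------------------------------------
  ann <- annotate_orfs(sim$transcripts)
  write_tsv(ann, path("orfs.tsv"))
  big <- orf_size_filter(ann, cfg$orf_min_aa)
  note("n_orf_gt_min", nrow(big))
  note("pct_orf_gt_min", round(100 * nrow(big) / nrow(ann), 1))
  comp <- composition_summary(sim$transcripts, big)
  write_tsv(data.frame(key = names(comp$summary),
                       value = unname(comp$summary)),
            path("composition.tsv"))
  note("gc_total", round(comp$summary[["gc"]], 4))
  note("gc3", round(comp$summary[["gc3"]], 4))

  # --- SSRs -------------------------------------------------------------
  ssr_hits <- localize_ssrs(detect_ssrs_all(sim$transcripts), ann)
  write_tsv(ssr_hits, path("ssr.tsv"))
  spec <- ssr_spectrum(ssr_hits, sim$transcripts)
  note("ssr_fraction_with", round(spec$fraction_with_ssr, 4))

  # --- alternative splicing ---------------------------------------------
  tx_groups <- cluster_ests(sim$transcripts,
                            min_identity = cfg$cluster_min_identity,
                            window = cfg$cluster_window)
  as_events <- detect_as_events(
    tx_groups, sim$transcripts,
    min_flank_identity = cfg$as_min_flank_identity,
    min_flank_cols = cfg$as_min_flank_cols,
    min_intron = cfg$as_min_intron)
  write_tsv(as_events, path("as_events.tsv"))
  ac <- as_type_counts(as_events)
  for (k in seq_len(nrow(ac)))
    note(paste0("as_", ac$as_type[k]), ac$count[k])

  # --- antisense --------------------------------------------------------
  nats <- detect_nats(sim$transcripts, min_overlap = cfg$nat_min_overlap,
                      max_mismatches = cfg$nat_max_mismatches)
  write_tsv(nats, path("nats.tsv"))
  note("n_nat_pairs", nrow(nats))

  # --- homology / ortholog panel ----------------------------------------
  panel_cfg <- cfg$simulation
  panel_cfg$n_genes <- cfg$panel_genes
  panel <- simulate_ortholog_panel(
    panel_cfg, species = paste0("sp", seq_len(cfg$panel_species)),
    ortholog_ks = cfg$panel_ks, ortholog_ka_ks = cfg$panel_ka_ks)
  part <- partition_shared_unique(panel$queries, panel$species_dbs,
                                  nt_identity = cfg$homolog_nt_identity,
                                  nt_coverage = cfg$homolog_nt_coverage)
  write_tsv(data.frame(query_id = names(part$category),
                       category = part$category),
            path("homology_partition.tsv"))
  for (k in names(part$counts))
    note(paste0("partition_", k), part$counts[[k]])
  groups <- find_ortholog_groups(panel$queries, panel$species_dbs,
                                 nt_identity = cfg$homolog_nt_identity,
                                 nt_coverage = cfg$homolog_nt_coverage)
  write_tsv(groups, path("ortholog_groups.tsv"))
  note("n_ortholog_groups", nrow(groups))

  # --- Ka/Ks + clock dating on ortholog pairs ---------------------------
  q_ann <- annotate_orfs(panel$queries)
  kaks_rows <- list()
  for (k in seq_len(nrow(groups))) {
    qid <- groups$anchor_id[k]
    qa <- q_ann[q_ann$transcript_id == qid, ]
    if (is.na(qa$orf_start)) next
    q_cds <- substr(panel$queries$seq[panel$queries$id == qid],
                    qa$orf_start, qa$orf_end)
    for (sp in names(panel$species_dbs)) {
      db <- panel$species_dbs[[sp]]
      sseq <- db$seq[db$id == groups[[sp]][k]]
      s_orf <- find_longest_orf(sseq)
      if (is.null(s_orf)) next
      est <- tryCatch(
        kaks_pair(q_cds, substr(sseq, s_orf$orf_start, s_orf$orf_end)),
        error = function(e) NULL)
      if (is.null(est)) next
      kaks_rows[[length(kaks_rows) + 1L]] <- data.frame(
        anchor_id = qid, species = sp, subject_id = groups[[sp]][k],
        Ks = est$Ks, Ka = est$Ka, ratio = est$ratio,
        T_years = if (is.na(est$Ks)) NA else
          date_divergence(est$Ks, cfg$clock_rate))
    }
  }
  kaks_tab <- if (length(kaks_rows)) do.call(rbind, kaks_rows)
    else data.frame(anchor_id = character(0), species = character(0),
                    subject_id = character(0), Ks = numeric(0),
                    Ka = numeric(0), ratio = numeric(0),
                    T_years = numeric(0))
  kept <- ks_window_filter(kaks_tab, cfg$ks_max)
  write_tsv(kaks_tab, path("kaks.tsv"))
  note("n_kaks_pairs", nrow(kaks_tab))
  note("n_ks_in_window", nrow(kept))
  note("n_ratio_gt1", attr(kept, "n_ratio_gt1"))
  note("mean_ks_in_window",
       if (nrow(kept)) round(mean(kept$Ks), 4) else NA)

  # --- duplication dating -----------------------------------------------
  dup <- duplication_analysis(sim$transcripts, ests, ann,
                              r = cfg$clock_rate,
                              min_cluster = cfg$dup_min_cluster,
                              min_support = cfg$dup_min_support,
                              bin_my = cfg$dup_bin_my)
  write_tsv(dup$clusters, path("duplication_clusters.tsv"))
  write_tsv(dup$histogram, path("duplication_histogram.tsv"))
  note("n_dup_dated", sum(dup$clusters$status == "dated"))

  # --- NJ tree of the panel species -------------------------------------
  tree <- NULL
  blocks <- panel_alignment_blocks(panel, groups, q_ann)
  if (length(blocks) >= 1L && cfg$panel_species >= 2L) {
    alignment <- concat_alignment(blocks)
    if (length(alignment) >= 3L) {
      if (cfg$nj_bootstrap > 0L) {
        bs <- bootstrap_support(alignment, cfg$nj_bootstrap,
                                seed = cfg$simulation$seed)
        tree <- bs$tree
      } else {
        tree <- neighbor_joining(build_distance_matrix(alignment))
      }
      write_newick(tree, path("tree.nwk"))
      note("tree_columns", attr(alignment, "total_columns"))
    }
  }

  # --- summary with threshold echo --------------------------------------
  for (f in setdiff(names(cfg), "simulation"))
    note(paste0("threshold_", f), cfg[[f]])
  note("seed", cfg$simulation$seed)
  summary <- do.call(rbind, summary_rows)
  write_tsv(summary, path("summary.tsv"))

  invisible(list(simulation = sim, ests = ests, clusters = clusters,
                 nonredundant = nr, dropped = dropped, annotations = ann,
                 composition = comp, ssr = spec, as_events = as_events,
                 nats = nats, panel = panel, partition = part,
                 ortholog_groups = groups, kaks = kaks_tab,
                 duplication = dup, tree = tree, summary = summary))
}

# equal-length CDS blocks (anchor + each species) from ortholog groups;
# panel orthologs are substitution-only, so CDS lengths match by
# construction and groups violating that are skipped
panel_alignment_blocks <- function(panel, groups, q_ann) {
  blocks <- list()
  for (k in seq_len(nrow(groups))) {
    qid <- groups$anchor_id[k]
    qa <- q_ann[q_ann$transcript_id == qid, ]
    if (is.na(qa$orf_start)) next
    seqs <- c(anchor = substr(panel$queries$seq[panel$queries$id == qid],
                              qa$orf_start, qa$orf_end))
    ok <- TRUE
    for (sp in names(panel$species_dbs)) {
      db <- panel$species_dbs[[sp]]
      sseq <- db$seq[db$id == groups[[sp]][k]]
      s_orf <- find_longest_orf(sseq)
      if (is.null(s_orf)) { ok <- FALSE; break }
      cds <- substr(sseq, s_orf$orf_start, s_orf$orf_end)
      if (nchar(cds) != nchar(seqs[["anchor"]])) { ok <- FALSE; break }
      seqs[[sp]] <- cds
    }
    if (ok) blocks[[length(blocks) + 1L]] <- seqs
  }
  blocks
}

#' Enzyme gene-count ratio table
#'
#' For a per-enzyme table of gene counts in two collections, computes the
#' per-row count ratio rounded half-up to one decimal and the headline
#' mean: the mean of the rounded per-row ratios, rounded to the nearest
#' integer. When a `printed_ratio` column is supplied, rows whose printed
#' value disagrees with the computed rounding are flagged discrepant.
#'
#' @param counts data.frame with columns `enzyme`, `count_a`, `count_b`
#'   (ratio = count_b / count_a) and optionally `printed_ratio`.
#' @return The table with `ratio` (1-dp, half-up) and, when applicable,
#'   `discrepant`; attributes `total_a`, `total_b`, `mean_ratio`
#'   (integer headline).
#' @export
lignin_ratio_table <- function(counts) {
  stopifnot(all(c("enzyme", "count_a", "count_b") %in% names(counts)),
            all(counts$count_a > 0))
  out <- counts
  out$ratio <- round_half_up(out$count_b / out$count_a, 1)
  if ("printed_ratio" %in% names(out))
    out$discrepant <- abs(out$printed_ratio - out$ratio) > 1e-9
  attr(out, "total_a") <- sum(out$count_a)
  attr(out, "total_b") <- sum(out$count_b)
  attr(out, "mean_ratio") <- as.integer(round_half_up(mean(out$ratio), 0))
  out
}
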