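test_that("the configuration validates its inputs", {
  expect_s3_class(simulation_config(), "simulation_config")
  expect_error(simulation_config(as_fraction = 1.2), "\\[0,1\\]")
  expect_error(simulation_config(n_genes = 0), "n_genes")
  expect_error(simulation_config(mean_transcript_length = 200,
                                 orf_min_aa = 100), "impossible")
  expect_error(simulation_config(
    as_type_probabilities = c(IntronR = 1)), "named over")
  expect_error(simulation_config(
    as_type_probabilities = c(IntronR = 0.9, AltP = 0.9, ExonO = 0,
                              ExonS = 0, AltA = 0, AltD = 0)), "sum to 1")
})

test_that("simulation is deterministic in the seed and leaves RNG alone", {
  cfg <- simulation_config(n_genes = 10, as_fraction = 0.2,
                           nat_fraction = 0.1, seed = 1001)
  set.seed(42); before <- .Random.seed
  s1 <- simulate_transcriptome(cfg)
  expect_identical(before, .Random.seed)
  s2 <- simulate_transcriptome(cfg)
  expect_identical(s1, s2)
  s3 <- simulate_transcriptome(simulation_config(n_genes = 10,
                                                 as_fraction = 0.2,
                                                 nat_fraction = 0.1,
                                                 seed = 1002))
  expect_false(identical(s1$transcripts$seq, s3$transcripts$seq))
})

test_that("planted annotations agree with de novo ORF prediction", {
  cfg <- simulation_config(n_genes = 15, seed = 1003)
  sim <- simulate_transcriptome(cfg)
  ann <- annotate_orfs(sim$transcripts)
  m <- match(sim$annotations$transcript_id, ann$transcript_id)
  expect_equal(sim$annotations$orf_start, ann$orf_start[m])
  expect_equal(sim$annotations$orf_end, ann$orf_end[m])
})

test_that("generated composition hits the configured GC3 and lengths", {
  cfg <- simulation_config(n_genes = 60, seed = 1004)
  sim <- simulate_transcriptome(cfg)
  comp <- composition_summary(sim$transcripts, sim$annotations)
  expect_equal(unname(comp$summary[["gc3"]]), cfg$gc3_target,
               tolerance = 0.02)
  expect_equal(mean(nchar(sim$transcripts$seq)),
               cfg$mean_transcript_length, tolerance = 0.15)
  expect_equal(unname(comp$summary[["gc_utr5"]]), cfg$gc_utr5,
               tolerance = 0.05)
  expect_equal(unname(comp$summary[["gc_utr3"]]), cfg$gc_utr3,
               tolerance = 0.05)
})

test_that("every planted event appears exactly once in the truth table", {
  cfg <- simulation_config(n_genes = 30, as_fraction = 0.3,
                           nat_fraction = 0.2, duplication_fraction = 0.1,
                           ssr_rate_utr3 = 0.3, seed = 1005)
  sim <- simulate_transcriptome(cfg)
  tr <- sim$truth
  expect_equal(sum(tr$event_type == "AS"), round(0.3 * 30))
  expect_equal(sum(tr$event_type == "NAT"), round(0.2 * 30))
  expect_equal(sum(tr$event_type == "DUP"), round(0.1 * 30))
  pair_key <- paste(tr$event_type, tr$id_a, tr$id_b, tr$start)
  expect_false(anyDuplicated(pair_key) > 0)
  # all referenced ids exist
  ids <- c(tr$id_a, tr$id_b)
  expect_true(all(ids[!is.na(ids)] %in% sim$transcripts$id))
})

test_that("EST depths follow the truncated design and reads are 5' biased", {
  cfg <- simulation_config(n_genes = 150, seed = 1006)
  sim <- simulate_transcriptome(cfg)
  ests <- simulate_ests(sim$transcripts, cfg)
  depth <- table(ests$source_id)
  expect_true(all(depth >= 1))
  expect_equal(mean(depth), cfg$est_mean_depth, tolerance = 0.15)
  expect_gt(max(depth), 3 * mean(depth))  # heavy right tail
  expect_true(all(nchar(ests$seq) >= cfg$est_min_length))
  # determinism and explicit depth override
  e2 <- simulate_ests(sim$transcripts, cfg)
  expect_identical(ests, e2)
  e3 <- simulate_ests(sim$transcripts[1:5, ], cfg, depth = 3L)
  expect_equal(nrow(e3), 15L)
})

test_that("EST reads map back to their source transcripts", {
  cfg <- simulation_config(n_genes = 5, seed = 1007)
  sim <- simulate_transcriptome(cfg)
  ests <- simulate_ests(sim$transcripts, cfg, depth = 2L)
  for (k in seq_len(nrow(ests))) {
    src <- sim$transcripts$seq[sim$transcripts$id == ests$source_id[k]]
    aln <- align(ests$seq[k], src, strand = "forward")
    expect_gt(aln$identity, 0.98)
  }
})

test_that("simulation files round-trip through disk", {
  cfg <- simulation_config(n_genes = 6, seed = 1008)
  sim <- simulate_transcriptome(cfg)
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir, simulate_ests(sim$transcripts, cfg))
  expect_true(all(file.exists(paths)))
  back <- read_fasta(paths[["transcripts"]])
  expect_equal(back$seq, sim$transcripts$seq)
  log <- readLines(file.path(dir, "simulation.log"))
  expect_true(any(grepl("seed\t1008", log)))
})

test_that("ortholog panel fractions are exact by construction", {
  cfg <- simulation_config(n_genes = 10, seed = 1009)
  pan <- simulate_ortholog_panel(
    cfg, species = c("r", "s", "t"),
    category_fractions = c(shared_all = 0.5, ref_not_all = 0.2,
                           others_not_ref = 0.1, no_hit = 0.2))
  expect_equal(unname(table(pan$truth$category)[
    c("shared_all", "ref_not_all", "others_not_ref", "no_hit")]),
    c(5L, 2L, 1L, 2L), ignore_attr = TRUE)
  # placements match the category semantics
  sa <- pan$truth[pan$truth$category == "shared_all", ]
  expect_false(anyNA(sa[, c("r", "s", "t")]))
  nh <- pan$truth[pan$truth$category == "no_hit", ]
  expect_true(all(is.na(nh$r) & is.na(nh$s) & is.na(nh$t)))
  rna <- pan$truth[pan$truth$category == "ref_not_all", ]
  expect_true(all(!is.na(rna$r) & is.na(rna$t)))
})
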