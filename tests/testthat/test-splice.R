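# one synthetic isoform pair per type, built by hand
pair_with_insert <- function(seg, at = 300L) {
  set.seed(at + nchar(seg))
  base <- random_seq(700)
  iso <- paste0(substr(base, 1, at - 1L), seg, substr(base, at, 700))
  tx <- transcript_records(c("base", "iso"), c(base, iso))
  cl <- data.frame(read_id = c("base", "iso"),
                   cluster_id = "CL00001", size = 2L)
  detect_as_events(cl, tx)
}

test_that("a GT..AG insertion is intron retention with exact bounds", {
  set.seed(601)
  seg <- paste0("GT", random_seq(100, gc = 0.4), "AG")
  ev <- pair_with_insert(seg, at = 250L)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$as_type, "IntronR")
  expect_equal(ev$boundary, "GT-AG")
  expect_equal(ev$insert_in, "b")
  expect_equal(ev$inferred_intron_length, 104L)
})

test_that("reported IntronR boundaries are literal GT/GC..AG substrings", {
  cfg <- simulation_config(n_genes = 20, as_fraction = 1, seed = 602,
                           as_type_probabilities = c(
                             IntronR = 1, AltP = 0, ExonO = 0, ExonS = 0,
                             AltA = 0, AltD = 0))
  sim <- simulate_transcriptome(cfg)
  cl <- cluster_ests(sim$transcripts)
  ev <- detect_as_events(cl, sim$transcripts)
  ir <- ev[ev$as_type == "IntronR", ]
  expect_gt(nrow(ir), 0)
  for (k in seq_len(nrow(ir))) {
    carrier <- if (ir$insert_in[k] == "a") ir$transcript_a[k]
               else ir$transcript_b[k]
    s <- sim$transcripts$seq[sim$transcripts$id == carrier]
    seg <- substr(s, ir$insert_start[k], ir$insert_end[k])
    if (ir$boundary[k] == "GT-AG") expect_true(startsWith(seg, "GT"))
    if (ir$boundary[k] == "GC-AG") expect_true(startsWith(seg, "GC"))
    expect_true(endsWith(seg, "AG"))
  }
})

test_that("donor-only / acceptor-only / boundary-less inserts classify", {
  set.seed(603)
  # AltD: starts GT, no AG end anywhere in the slide register
  ev <- pair_with_insert(paste0("GT", strrep("CCT", 20), "CC"), 260L)
  expect_equal(ev$as_type, "AltD")
  # AltA: ends AG, cannot start GT/GC
  ev <- pair_with_insert(paste0("CA", strrep("TTC", 20), "AG"), 270L)
  expect_equal(ev$as_type, "AltA")
  # ExonS: neither boundary available
  ev <- pair_with_insert(paste0("CC", strrep("TTC", 20), "CC"), 280L)
  expect_equal(ev$as_type, "ExonS")
})

test_that("indels below the intron minimum are not AS events", {
  set.seed(604)
  ev <- pair_with_insert(random_seq(10), 300L)
  expect_equal(nrow(ev), 0L)
})

test_that("staggered overlap with no internal gap is ExonO", {
  set.seed(605)
  a <- random_seq(600)
  b <- paste0(substr(a, 301, 600), random_seq(250))
  tx <- transcript_records(c("a", "b"), c(a, b))
  cl <- data.frame(read_id = c("a", "b"), cluster_id = "CL00001", size = 2L)
  ev <- detect_as_events(cl, tx)
  expect_equal(ev$as_type, "ExonO")
})

test_that("one intron in each isoform at different sites is one AltP event", {
  set.seed(606)
  base <- random_seq(800)
  i1 <- paste0("GT", random_seq(80, 0.4), "AG")
  i2 <- paste0("GT", random_seq(90, 0.4), "AG")
  a <- paste0(substr(base, 1, 199), i1, substr(base, 200, 800))
  b <- paste0(substr(base, 1, 599), i2, substr(base, 600, 800))
  # ensure the inserts classify cleanly on their own first
  tx <- transcript_records(c("a", "b"), c(a, b))
  cl <- data.frame(read_id = c("a", "b"), cluster_id = "CL00001", size = 2L)
  ev <- detect_as_events(cl, tx)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$as_type, "AltP")
  expect_equal(ev$insert_in, "both")
})

test_that("dissimilar flanks disqualify a pair", {
  set.seed(607)
  a <- random_seq(500)
  b <- paste0(substr(a, 1, 250),
              paste0("GT", random_seq(80, 0.4), "AG"),
              random_seq(250))  # second flank unrelated
  tx <- transcript_records(c("a", "b"), c(a, b))
  cl <- data.frame(read_id = c("a", "b"), cluster_id = "CL00001", size = 2L)
  ev <- detect_as_events(cl, tx)
  expect_equal(nrow(ev), 0L)
})

test_that("slide_range covers every equivalent gap placement", {
  # AAAA|GTxxAG|AAAA with homopolymer context slides both ways
  x <- paste0("AAAA", "TTTTT", "AAAA")
  rng <- slide_range(x, 5L, 5L)
  expect_equal(substr(x, rng[1], rng[1] + 4L), "TTTTT")
  expect_equal(substr(x, rng[2], rng[2] + 4L), "TTTTT")
  expect_true(rng[1] <= 5L && rng[2] >= 5L)
})

test_that("generator truth and classifier agree across planted types", {
  cfg <- simulation_config(
    n_genes = 24, as_fraction = 1, seed = 608,
    as_type_probabilities = c(IntronR = 0.25, AltP = 0, ExonO = 0.25,
                              ExonS = 0.2, AltA = 0.15, AltD = 0.15))
  sim <- simulate_transcriptome(cfg)
  truth <- sim$truth[sim$truth$event_type == "AS", ]
  ev <- detect_as_events(cluster_ests(sim$transcripts), sim$transcripts)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  tk <- key(truth$id_a, truth$id_b)
  ek <- key(ev$transcript_a, ev$transcript_b)
  expect_setequal(ek, tk)
  expect_equal(ev$as_type[match(tk, ek)], truth$type)
})

test_that("intron sizes and type counts summarize the event table", {
  ev <- data.frame(
    transcript_a = c("a", "c"), transcript_b = c("b", "d"),
    as_type = c("IntronR", "ExonS"), boundary = c("GT-AG", ""),
    insert_in = c("b", "b"), insert_start = c(10L, 20L),
    insert_end = c(109L, 79L), inferred_intron_length = c(100L, 60L))
  s <- intron_size_summary(ev)
  expect_equal(s$n, 1L)
  expect_equal(s$mean, 100)
  tc <- as_type_counts(ev)
  expect_equal(tc$count[tc$as_type == "IntronR"], 1L)
  expect_equal(sum(tc$count), 2L)
})
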