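make_family <- function(source, n, prefix, p_sub = 0.004) {
  # near-identical fragments of one source transcript
  ids <- sprintf("%s_%02d", prefix, seq_len(n))
  seqs <- vapply(seq_len(n), function(i) {
    off <- sample(0:30, 1)
    len <- sample(300:min(500, nchar(source) - off), 1)
    s <- substr(source, off + 1, off + len)
    v <- strsplit(s, "")[[1]]
    hit <- which(runif(length(v)) < p_sub)
    for (k in hit) v[k] <- sample(setdiff(c("A", "C", "G", "T"), v[k]), 1)
    paste(v, collapse = "")
  }, "")
  transcript_records(ids, seqs)
}

test_that("reads from the same source cluster together, others apart", {
  set.seed(501)
  srcs <- replicate(4, random_seq(700))
  fams <- lapply(1:4, function(i) make_family(srcs[i], 5, paste0("f", i)))
  reads <- do.call(rbind, fams)
  cl <- cluster_ests(reads)
  expect_equal(nrow(cl), 20L)
  # same family -> same cluster; different family -> different cluster
  fam_of <- sub("_.*", "", cl$read_id)
  expect_equal(length(unique(cl$cluster_id)), 4L)
  expect_true(all(tapply(cl$cluster_id, fam_of,
                         function(x) length(unique(x))) == 1L))
})

test_that("clustering is single linkage: a bridging read merges clusters", {
  set.seed(502)
  left <- random_seq(400)
  right <- random_seq(400)
  bridge <- paste0(substr(left, 201, 400), substr(right, 1, 200))
  reads <- transcript_records(c("L", "R", "B"), c(left, right, bridge))
  no_bridge <- cluster_ests(reads[1:2, ])
  expect_equal(length(unique(no_bridge$cluster_id)), 2L)
  with_bridge <- cluster_ests(reads)
  expect_equal(length(unique(with_bridge$cluster_id)), 1L)
})

test_that("the >95% / 80-base window rule is enforced", {
  set.seed(503)
  a <- random_seq(400)
  # identical 79-base window, rest unrelated: must NOT cluster
  b79 <- paste0(random_seq(150), substr(a, 101, 179), random_seq(150))
  # identical 120-base window: must cluster
  b120 <- paste0(random_seq(150), substr(a, 101, 220), random_seq(150))
  cl1 <- cluster_ests(transcript_records(c("a", "b"), c(a, b79)))
  expect_equal(length(unique(cl1$cluster_id)), 2L)
  cl2 <- cluster_ests(transcript_records(c("a", "b"), c(a, b120)))
  expect_equal(length(unique(cl2$cluster_id)), 1L)
})

test_that("cluster ids and sizes are stable and deterministic", {
  set.seed(504)
  src <- random_seq(600)
  reads <- rbind(make_family(src, 4, "x"),
                 transcript_records("solo", random_seq(300)))
  cl1 <- cluster_ests(reads)
  cl2 <- cluster_ests(reads)
  expect_identical(cl1, cl2)
  expect_true(all(grepl("^CL\\d{5}$", cl1$cluster_id)))
  sz <- table(cl1$cluster_id)
  expect_equal(unname(cl1$size), as.integer(sz[cl1$cluster_id]),
               ignore_attr = TRUE)
})

test_that("cluster_summary reports contig/singleton structure", {
  set.seed(505)
  src <- random_seq(600)
  reads <- rbind(make_family(src, 6, "c"),
                 transcript_records(c("s1", "s2"),
                                    c(random_seq(300), random_seq(300))))
  cs <- cluster_summary(cluster_ests(reads))
  expect_equal(cs$n_clusters, 3L)
  expect_equal(cs$n_singletons, 2L)
  expect_equal(cs$max_size, 6L)
  expect_equal(cs$mean_size, 8 / 3)
})

test_that("representative selection takes the longest read, ties by id", {
  clusters <- data.frame(read_id = c("r1", "r2", "r3"),
                         cluster_id = rep("CL00001", 3), size = 3L)
  reads <- transcript_records(c("r1", "r2", "r3"),
                              c(strrep("A", 50), strrep("C", 80),
                                strrep("G", 80)))
  rep1 <- select_representatives(clusters, reads)
  expect_equal(rep1$read_id[rep1$is_representative], "r2")
  set.seed(1)
  rep2 <- select_representatives(clusters, reads, policy = "random",
                                 seed = 99)
  rep3 <- select_representatives(clusters, reads, policy = "random",
                                 seed = 99)
  expect_identical(rep2, rep3)
})

test_that("redundancy filtering drops near-identical shorter sequences", {
  set.seed(506)
  long <- random_seq(800)
  # 99.5% identical contained copy -> dropped
  v <- strsplit(substr(long, 1, 760), "")[[1]]
  for (k in sample(760, 3)) v[k] <- sample(setdiff(c("A","C","G","T"),
                                                   v[k]), 1)
  near <- paste(v, collapse = "")
  other <- random_seq(500)
  tx <- transcript_records(c("long", "near", "other"),
                           c(long, near, other))
  kept <- filter_redundant(tx)
  expect_setequal(kept$id, c("long", "other"))
  expect_equal(attr(kept, "dropped"), c(near = "long"))
})

test_that("low-coverage overlaps are retained", {
  set.seed(507)
  long <- random_seq(800)
  # perfect alignment spanning only half the shorter sequence -> kept
  partial <- paste0(substr(long, 601, 800), random_seq(200))
  tx <- transcript_records(c("long", "partial"), c(long, partial))
  kept <- filter_redundant(tx)
  expect_setequal(kept$id, c("long", "partial"))
})

test_that("redundancy filtering is idempotent", {
  set.seed(508)
  base <- random_seq(600)
  tx <- transcript_records(
    c("a", "b", "c"),
    c(base, paste0(base, "ACGTACGT"), random_seq(400)))
  once <- filter_redundant(tx)
  twice <- filter_redundant(once)
  expect_equal(once$id, twice$id)
  expect_length(attr(twice, "dropped"), 0L)
})
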