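test_that("local alignment score equals the Biostrings reference", {
  set.seed(202)
  for (k in 1:40) {
    pr <- related_pair(sample(80:400, 1), p_sub = runif(1, 0.02, 0.15),
                       n_indel = sample(0:2, 1))
    aln <- align(pr$a, pr$b, strand = "forward")
    expect_equal(aln$score, biostrings_local_score(pr$a, pr$b),
                 info = paste("pair", k))
  }
})

test_that("unrelated random pairs also match the reference score", {
  set.seed(203)
  for (k in 1:15) {
    a <- random_seq(sample(60:200, 1))
    b <- random_seq(sample(60:200, 1))
    aln <- align(a, b, strand = "forward")
    got <- if (is.null(aln)) 0 else aln$score
    expect_equal(got, max(0, biostrings_local_score(a, b)),
                 info = paste("pair", k))
  }
})

test_that("seeded banded alignment equals exhaustive DP on short pairs", {
  set.seed(204)
  for (k in 1:30) {
    pr <- related_pair(sample(150:500, 1), p_sub = runif(1, 0.02, 0.1),
                       n_indel = sample(0:2, 1))
    full <- align(pr$a, pr$b, strand = "forward")
    seeded <- align(pr$a, pr$b, strand = "forward", full_dp_limit = 0)
    expect_false(is.null(seeded))
    expect_equal(seeded$score, full$score, info = paste("pair", k))
    expect_equal(seeded$q_start, full$q_start)
    expect_equal(seeded$q_end, full$q_end)
  }
})

test_that("reverse-complement hits are found and flagged with mapped coords", {
  set.seed(205)
  a <- random_seq(300)
  core <- substr(a, 101, 220)
  b <- paste0(random_seq(50), revcomp(core), random_seq(60))
  fwd_only <- align(a, b, strand = "forward")
  both <- align(a, b, strand = "both")
  expect_equal(both$orientation, "reverse-complement")
  expect_gt(both$score, if (is.null(fwd_only)) 0 else fwd_only$score)
  expect_equal(both$q_start, 101)
  expect_equal(both$q_end, 220)
  # subject interval is reported on the forward strand of the subject
  expect_equal(both$s_start, 51)
  expect_equal(both$s_end, 170)
  expect_equal(substr(b, both$s_start, both$s_end), revcomp(core))
})

test_that("N bases never count as matches", {
  set.seed(201)
  f1 <- random_seq(20); f2 <- random_seq(20)
  # flanks long enough that bridging the N column beats trimming to one side
  aln <- align(paste0(f1, "A", f2), paste0(f1, "N", f2), strand = "forward")
  expect_equal(aln$columns, 41)
  expect_equal(aln$matches, 40)
  expect_equal(aln$mismatches, 1)
  nn <- align(strrep("N", 30), strrep("N", 30), strand = "forward")
  expect_null(nn)
})

test_that("alignment identity and windows are computed over columns", {
  a <- paste0(strrep("A", 50), "CCCCC", strrep("A", 50))
  b <- paste0(strrep("A", 50), "GGGGG", strrep("A", 50))
  aln <- align(a, b, strand = "forward")
  expect_equal(aln$identity, 100 / 105)
  expect_true(has_identity_window(aln, 50L, 0.95))
  expect_false(has_identity_window(aln, 105L, 0.99))
  expect_equal(longest_exact_run(a, b), 50L)
})

test_that("ungapped mode finds the best gap-free diagonal segment", {
  a <- paste0(random_seq(40), "ACGTACGTACGTACGTACGTACGTACGT")
  b <- paste0("ACGTACGTACGTACGTACGTACGTACGT", random_seq(35))
  aln <- align(a, b, mode = "ungapped", strand = "forward")
  expect_equal(aln$gap_columns, 0)
  expect_gte(aln$matches, 28)
  expect_equal(aln$q_end - aln$q_start, aln$s_end - aln$s_start)
})

test_that("alignment is deterministic and symmetric in score", {
  set.seed(206)
  pr <- related_pair(250, p_sub = 0.05, n_indel = 1)
  a1 <- align(pr$a, pr$b)
  a2 <- align(pr$a, pr$b)
  expect_identical(a1, a2)
  expect_equal(align(pr$b, pr$a)$score, a1$score)
})

test_that("alignment_table emits one row per hit in a stable schema", {
  set.seed(207)
  pr <- related_pair(200, 0.03, 1)
  aln <- align(pr$a, pr$b, query_id = "q1", subject_id = "s1")
  tab <- alignment_table(list(aln))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$query, "q1")
  expect_equal(tab$subject, "s1")
  expect_true(all(c("identity", "alnlen", "mismatches", "gaps", "q.start",
                    "q.end", "s.start", "s.end", "strand", "score")
                  %in% names(tab)))
  expect_equal(tab$strand, "+")
  expect_equal(nrow(alignment_table(list(NULL))), 0L)
})
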