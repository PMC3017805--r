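test_that("nucleotide homologs require >75% identity over >50% of query", {
  set.seed(901)
  q <- random_seq(400)
  # ~85% identical over the full length -> hit
  v <- strsplit(q, "")[[1]]
  for (k in sample(400, 60)) v[k] <- sample(setdiff(c("A","C","G","T"),
                                                    v[k]), 1)
  good <- paste(v, collapse = "")
  # identical but covering only 40% of the query -> no hit
  short <- substr(q, 1, 160)
  queries <- transcript_records("q1", q)
  subjects <- transcript_records(c("good", "short"),
                                 c(good, paste0(short, random_seq(20))))
  hits <- find_homologs(queries, subjects, level = "nucleotide",
                        species = "sp")
  expect_equal(hits$subject_id, "good")
  expect_gt(hits$identity, 0.75)
  expect_gt(hits$coverage_of_query, 0.5)
  expect_equal(hits$species, "sp")
})

test_that("protein homologs need >60% identity over 50 consecutive aa", {
  cds <- random_cds(120, seed = 902)
  # synonymous-only divergence: peptide identical -> protein-level hit
  syn <- mutate_to_ks(cds, 0.4, seed = 903)
  queries <- transcript_records("q", cds)
  subjects <- transcript_records("s", as.character(syn))
  hits <- find_homologs(queries, subjects, level = "protein")
  expect_equal(nrow(hits), 1L)
  # a short peptide (< 50 aa) can never satisfy the window
  short_cds <- random_cds(40, seed = 904)
  hits2 <- find_homologs(transcript_records("q", short_cds),
                         transcript_records("s", short_cds),
                         level = "protein")
  expect_equal(nrow(hits2), 0L)
})

test_that("ortholog picking is reciprocal and tie-safe", {
  cfg <- simulation_config(n_genes = 6, seed = 905)
  pan <- simulate_ortholog_panel(cfg, species = c("spA", "spB"),
                                 category_fractions = c(
                                   shared_all = 1, ref_not_all = 0,
                                   others_not_ref = 0, no_hit = 0))
  for (k in seq_len(nrow(pan$truth))) {
    got <- pick_ortholog(pan$truth$query_id[k], pan$queries,
                         pan$species_dbs$spA)
    expect_equal(got, pan$truth$spA[k])
  }
  # a duplicated subject with identical peptides is ambiguous -> NA
  q <- pan$queries[1, , drop = FALSE]
  dbdup <- pan$species_dbs$spA
  twin <- dbdup[dbdup$id == pan$truth$spA[1], ]
  twin$id <- "twin"
  dbdup <- rbind(dbdup, twin)
  expect_true(is.na(pick_ortholog(q$id, pan$queries, dbdup)))
})

test_that("ortholog groups keep only queries matched in every species", {
  cfg <- simulation_config(n_genes = 8, seed = 906)
  pan <- simulate_ortholog_panel(cfg, species = c("spA", "spB"))
  groups <- find_ortholog_groups(pan$queries, pan$species_dbs)
  shared <- pan$truth[pan$truth$category == "shared_all", ]
  expect_setequal(groups$anchor_id, shared$query_id)
  m <- match(groups$anchor_id, shared$query_id)
  expect_equal(groups$spA, shared$spA[m])
  expect_equal(groups$spB, shared$spB[m])
})

test_that("the homolog-presence partition matches planted categories", {
  cfg <- simulation_config(n_genes = 10, seed = 907)
  pan <- simulate_ortholog_panel(
    cfg, species = c("ref", "other1", "other2"),
    category_fractions = c(shared_all = 0.4, ref_not_all = 0.2,
                           others_not_ref = 0.2, no_hit = 0.2))
  part <- partition_shared_unique(pan$queries, pan$species_dbs)
  expect_equal(unname(part$category[pan$truth$query_id]),
               pan$truth$category)
  expect_equal(sum(part$counts), nrow(pan$queries))
  expect_equal(sum(part$fractions), 1)
})

test_that("homolog search is empty-safe and rank-ordered by score", {
  set.seed(908)
  queries <- transcript_records("q", random_seq(300))
  subjects <- transcript_records("s", random_seq(300))
  hits <- find_homologs(queries, subjects)
  expect_equal(nrow(hits), 0L)
  # two subjects at different divergence: the closer one ranks first
  q <- random_seq(400)
  close <- q
  v <- strsplit(q, "")[[1]]
  for (k in sample(400, 40)) v[k] <- sample(setdiff(c("A","C","G","T"),
                                                    v[k]), 1)
  far <- paste(v, collapse = "")
  hits2 <- find_homologs(transcript_records("q", q),
                         transcript_records(c("far", "close"),
                                            c(far, close)))
  expect_equal(hits2$subject_id, c("close", "far"))
})
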