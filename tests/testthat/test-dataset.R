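# Dataset construction: length filter boundaries, pairwise identity,
# redundancy removal, negative sampling.

mk_dataset <- function(prot_seqs, rna_seqs, labels = "positive") {
  np <- length(prot_seqs)
  sequences <- tibble::tibble(
    id = c(sprintf("P%d", seq_len(np)), sprintf("R%d", seq_along(rna_seqs))),
    seq = c(prot_seqs, rna_seqs),
    moltype = rep(c("protein", "rna"), c(np, length(rna_seqs)))
  )
  pairs <- tibble::tibble(protein_id = sprintf("P%d", seq_len(np)),
                          rna_id = sprintf("R%d", seq_len(np)),
                          label = labels)
  pair_dataset(sequences, pairs)
}

test_that("length filter is strict at 25 for proteins, inclusive at 15 for RNA", {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  set.seed(1)
  ds <- mk_dataset(
    prot_seqs = c(random_seq(25, aa), random_seq(26, aa), random_seq(26, aa)),
    rna_seqs = c(random_seq(20, c("A", "C", "G", "U")),
                 random_seq(15, c("A", "C", "G", "U")),
                 random_seq(14, c("A", "C", "G", "U")))
  )
  out <- filter_by_length(ds, filter_config())
  # pair 1: protein length 25 -> dropped; pair 2: 26/15 -> kept;
  # pair 3: RNA length 14 -> dropped
  expect_equal(out$pairs$protein_id, "P2")
  # unreferenced sequences are dropped with their pairs
  expect_setequal(out$sequences$id, c("P2", "R2"))

  empty <- filter_by_length(mk_dataset(character(0), character(0)))
  expect_equal(nrow(empty$pairs), 0)
})

test_that("pairwise identity matches hand values and is symmetric", {
  expect_equal(pairwise_identity("ACGU", "ACGU"), 1.0)
  expect_equal(pairwise_identity("AAAA", "CCCC"), 0.0)
  expect_equal(pairwise_identity("ACGU", "ACGA"), 0.75)
  set.seed(21)
  for (i in 1:10) {
    a <- random_seq(sample(5:40, 1), c("A", "C", "G", "U"))
    b <- random_seq(sample(5:40, 1), c("A", "C", "G", "U"))
    ab <- pairwise_identity(a, b)
    expect_identical(ab, pairwise_identity(b, a))
    expect_gte(ab, 0)
    expect_lte(ab, 1)
    expect_equal(pairwise_identity(a, a), 1.0)
  }
})

test_that("pairwise identity agrees with exhaustive alignment enumeration", {
  set.seed(22)
  for (i in 1:12) {
    a <- random_seq(sample(2:6, 1), c("A", "C", "G", "U"))
    b <- random_seq(sample(2:6, 1), c("A", "C", "G", "U"))
    achievable <- oracle_optimal_identities(a, b)
    expect_true(any(abs(pairwise_identity(a, b) - achievable) < 1e-12),
                info = paste(a, b))
  }
})

test_that("redundancy removal requires similarity on BOTH partners", {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  set.seed(5)
  p <- random_seq(40, aa)
  r1 <- strrep("AC", 15)
  r2 <- strrep("G", 30) # shares no letter with r1: identity 0
  expect_lt(pairwise_identity(r1, r2), 0.30)
  ds <- mk_dataset(c(p, p), c(r1, r2))
  out <- remove_redundant_pairs(ds)
  expect_equal(nrow(out$pairs), 2) # identical proteins, unrelated RNAs

  # two copies of the same pair collapse to one
  dup <- mk_dataset(c(p, p), c(r1, r1))
  expect_equal(nrow(remove_redundant_pairs(dup)$pairs), 1)
})

test_that("redundancy removal scans greedily in input order", {
  # pair2 redundant with pair1; pair3 redundant with pair2 only -> 1 and 3
  # kept. Built from stepwise-mutated sequences: identity(1,2) and (2,3)
  # high, identity(1,3) low.
  p1 <- strrep("AD", 20)
  r1 <- strrep("AC", 15)
  mutate_seq <- function(s, positions, to) {
    v <- strsplit(s, "")[[1]]
    v[positions] <- to
    paste(v, collapse = "")
  }
  # p2 = p1 with 60% changed in first block; p3 = p2 with the rest changed
  p2 <- mutate_seq(p1, 1:24, "W")
  p3 <- mutate_seq(p2, 25:40, "Y")
  r2 <- mutate_seq(r1, 1:18, "G")
  r3 <- mutate_seq(r2, 19:30, "U")
  # sanity: chain structure of similarities at the 30% threshold
  expect_gte(pairwise_identity(p1, p2), 0.30)
  expect_gte(pairwise_identity(p2, p3), 0.30)
  expect_lt(pairwise_identity(p1, p3), 0.30)
  expect_gte(pairwise_identity(r1, r2), 0.30)
  expect_gte(pairwise_identity(r2, r3), 0.30)
  expect_lt(pairwise_identity(r1, r3), 0.30)

  ds <- mk_dataset(c(p1, p2, p3), c(r1, r2, r3))
  out <- remove_redundant_pairs(ds)
  expect_equal(out$pairs$protein_id, c("P1", "P3"))
})

test_that("redundancy removal is idempotent and output is a subset", {
  ds <- generate_synthetic(synthetic_config(n_pairs_per_class = 8,
                                            delta = 0.3, seed = 9))
  once <- remove_redundant_pairs(ds)
  twice <- remove_redundant_pairs(once)
  expect_equal(twice$pairs, once$pairs)
  expect_true(all(paste(once$pairs$protein_id, once$pairs$rna_id) %in%
                    paste(ds$pairs$protein_id, ds$pairs$rna_id)))
})

test_that("negative sampling respects quota, exclusion rule and determinism", {
  ds <- generate_synthetic(synthetic_config(n_pairs_per_class = 10,
                                            delta = 0, seed = 31))
  positives <- pair_dataset(ds$sequences,
                            ds$pairs[ds$pairs$label == "positive", ])
  cfg <- negative_sampling_config(seed = 99)
  out <- sample_negatives(positives, cfg)
  negs <- out$pairs[out$pairs$label == "negative", ]
  expect_equal(nrow(negs), 10)

  # never a positive pair, and every returned pair passes the exclusion
  # rule when re-checked independently
  pos <- positives$pairs
  seqs <- stats::setNames(ds$sequences$seq, ds$sequences$id)
  for (i in seq_len(nrow(negs))) {
    a <- negs$protein_id[[i]]
    b <- negs$rna_id[[i]]
    expect_false(any(pos$protein_id == a & pos$rna_id == b))
    partners <- pos$protein_id[pos$rna_id == b]
    for (c_prot in partners) {
      expect_lt(pairwise_identity(seqs[[a]], seqs[[c_prot]]), 0.30)
    }
  }

  again <- sample_negatives(positives, cfg)
  expect_equal(again$pairs, out$pairs)
})

test_that("negative sampling errors when no admissible negative exists", {
  seqs <- tibble::tibble(id = c("P1", "R1"),
                         seq = c(strrep("MKV", 10), strrep("ACGU", 5)),
                         moltype = c("protein", "rna"))
  positives <- pair_dataset(seqs, tibble::tibble(protein_id = "P1",
                                                 rna_id = "R1",
                                                 label = "positive"))
  expect_error(sample_negatives(positives), "achieved 0")
})

test_that("admissible negatives are exactly the cross pairs of dissimilar proteins", {
  # positives (P1,R1), (P2,R2) with identity(P1,P2) < 30%:
  # admissible negatives = {(P1,R2), (P2,R1)}
  p1 <- strrep("AGV", 10)
  p2 <- strrep("WNH", 10)
  expect_lt(pairwise_identity(p1, p2), 0.30)
  seqs <- tibble::tibble(
    id = c("P1", "P2", "R1", "R2"),
    seq = c(p1, p2, strrep("ACGU", 5), strrep("GGCU", 5)),
    moltype = c("protein", "protein", "rna", "rna")
  )
  positives <- pair_dataset(
    seqs, tibble::tibble(protein_id = c("P1", "P2"),
                         rna_id = c("R1", "R2"),
                         label = "positive"))
  out <- sample_negatives(positives, negative_sampling_config(seed = 4))
  negs <- out$pairs[out$pairs$label == "negative", ]
  expect_setequal(paste(negs$protein_id, negs$rna_id),
                  c("P1 R2", "P2 R1"))
})

test_that("dataset_summary counts pairs, distinct molecules and lengths", {
  # two positives sharing one protein sequence
  seqs <- tibble::tibble(
    id = c("P1", "P2", "R1", "R2"),
    seq = c(strrep("MKV", 10), strrep("MKV", 10),
            strrep("ACGU", 5), strrep("GGCU", 5)),
    moltype = c("protein", "protein", "rna", "rna")
  )
  ds <- pair_dataset(seqs, tibble::tibble(
    protein_id = c("P1", "P2"), rna_id = c("R1", "R2"),
    label = "positive"))
  s <- dataset_summary(ds)
  expect_equal(s$n_pairs, 2)
  expect_equal(s$n_positive, 2)
  expect_equal(s$n_proteins, 1) # identical sequences counted once
  expect_equal(s$n_rnas, 2)
  expect_equal(s$protein_len_max, 30)

  empty <- pair_dataset(seqs[0, ], ds$pairs[0, ])
  s0 <- dataset_summary(empty)
  expect_equal(s0$n_pairs, 0)
  expect_equal(s0$n_proteins, 0)
  # glance() is an alias
  expect_equal(glance(ds), s)
})
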