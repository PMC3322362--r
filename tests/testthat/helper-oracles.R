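# Independent oracles and tiny dataset builders shared across tests.
# Oracles deliberately use naive explicit loops / enumeration, never the
# package's own code paths.

# brute-force sliding-window k-mer frequencies over an integer code vector
# (NA = invalid position); returns counts over valid windows / n valid
oracle_kmer_freq <- function(codes, k, n_classes) {
  counts <- numeric(n_classes^k)
  n_valid <- 0L
  for (start in seq_len(length(codes) - k + 1L)) {
    w <- codes[start:(start + k - 1L)]
    if (anyNA(w)) next
    n_valid <- n_valid + 1L
    idx <- 0L
    for (c in w) idx <- idx * n_classes + (c - 1L)
    counts[idx + 1L] <- counts[idx + 1L] + 1
  }
  counts / n_valid
}

# Mann-Whitney concordance AUC: explicit loop over positive-negative
# score pairs, ties counted 1/2
oracle_auc <- function(scores, labels) {
  sp <- scores[labels == "positive"]
  sn <- scores[labels == "negative"]
  total <- 0
  for (p in sp) {
    for (n in sn) {
      total <- total + (p > n) + 0.5 * (p == n)
    }
  }
  total / (length(sp) * length(sn))
}

# exhaustive global-alignment enumeration (match +1, mismatch 0, gap -1):
# returns every alignment's score, match count and alignment length.
# Exponential; only for very short sequences.
oracle_alignments <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  out <- list()
  recurse <- function(i, j, score, matches, len) {
    if (i > length(av) && j > length(bv)) {
      out[[length(out) + 1L]] <<- c(score = score, matches = matches,
                                    len = len)
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) {
      hit <- av[i] == bv[j]
      recurse(i + 1L, j + 1L, score + as.integer(hit),
              matches + as.integer(hit), len + 1L)
    }
    if (i <= length(av)) recurse(i + 1L, j, score - 1L, matches, len + 1L)
    if (j <= length(bv)) recurse(i, j + 1L, score - 1L, matches, len + 1L)
  }
  recurse(1L, 1L, 0L, 0L, 0L)
  do.call(rbind, out)
}

# identities achievable by score-optimal alignments
oracle_optimal_identities <- function(a, b) {
  alns <- oracle_alignments(a, b)
  best <- alns[alns[, "score"] == max(alns[, "score"]), , drop = FALSE]
  unique(best[, "matches"] / best[, "len"])
}

random_seq <- function(n, alphabet) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# linearly separable toy set: positive pairs are pure-A protein/RNA,
# negative pairs pure-C protein / pure-C RNA (conjoint triad 111 vs 777,
# tetrad AAAA vs CCCC)
toy_separable_dataset <- function(n_per_class = 10, protein_len = 30,
                                  rna_len = 20) {
  n <- n_per_class
  mk <- function(ch, len) strrep(ch, len)
  sequences <- tibble::tibble(
    id = c(sprintf("Ppos%02d", 1:n), sprintf("Pneg%02d", 1:n),
           sprintf("Rpos%02d", 1:n), sprintf("Rneg%02d", 1:n)),
    seq = c(rep(mk("A", protein_len), n), rep(mk("C", protein_len), n),
            rep(mk("A", rna_len), n), rep(mk("C", rna_len), n)),
    moltype = rep(c("protein", "rna"), each = 2 * n)
  )
  # perturb ids' sequences slightly so records are not all identical
  pairs <- tibble::tibble(
    protein_id = c(sprintf("Ppos%02d", 1:n), sprintf("Pneg%02d", 1:n)),
    rna_id = c(sprintf("Rpos%02d", 1:n), sprintf("Rneg%02d", 1:n)),
    label = rep(c("positive", "negative"), each = n)
  )
  pair_dataset(sequences, pairs)
}

# small planted-signal feature tibble, cached per test file run
toy_planted_features <- function(n_per_class = 30, delta = 0.5, seed = 42) {
  encode_dataset(generate_synthetic(synthetic_config(
    n_pairs_per_class = n_per_class, delta = delta, seed = seed)))
}
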