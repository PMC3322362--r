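# Benchmark dataset construction: length filtering, pair-level redundancy
# removal at a sequence-identity threshold, and balanced negative sampling
# with a similarity exclusion rule.

#' Filtering configuration for dataset construction
#'
#' Defaults follow the benchmark construction rules: proteins longer than
#' 25 residues (i.e. minimum length 26), RNAs at least 15 nucleotides, and
#' a 30 percent pairwise identity threshold for redundancy and exclusion.
#'
#' @param min_protein_length Minimum protein length retained (inclusive).
#' @param min_rna_length Minimum RNA length retained (inclusive).
#' @param identity_threshold Fraction in (0, 1]; two sequences with
#'   pairwise identity at or above it count as similar.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_protein_length = 26L, min_rna_length = 15L,
                          identity_threshold = 0.30) {
  stopifnot(min_protein_length > 0, min_rna_length > 0,
            identity_threshold > 0, identity_threshold <= 1)
  structure(list(min_protein_length = as.integer(min_protein_length),
                 min_rna_length = as.integer(min_rna_length),
                 identity_threshold = identity_threshold),
            class = "filter_config")
}

#' Negative-sampling configuration
#'
#' @param seed Integer seed for the pair sampler.
#' @param ratio Negatives drawn per positive (1 gives a balanced set).
#' @param max_attempts Cap on rejection-sampling draws before giving up.
#' @return A list of class `negative_sampling_config`.
#' @export
negative_sampling_config <- function(seed = 1L, ratio = 1.0,
                                     max_attempts = 10000L) {
  stopifnot(ratio > 0, max_attempts >= 1)
  structure(list(seed = as.integer(seed), ratio = ratio,
                 max_attempts = as.integer(max_attempts)),
            class = "negative_sampling_config")
}

#' Filter pairs by sequence length
#'
#' Retains exactly the pairs whose protein is at least
#' `min_protein_length` residues (default: longer than 25) and whose RNA is
#' at least `min_rna_length` nucleotides (default 15). Sequences no longer
#' referenced by any surviving pair are dropped from the dataset.
#'
#' @param dataset A [pair_dataset()].
#' @param config A [filter_config()].
#' @return A filtered [pair_dataset()].
#' @export
filter_by_length <- function(dataset, config = filter_config()) {
  stopifnot(inherits(dataset, "pair_dataset"))
  plen <- nchar(seq_lookup(dataset, dataset$pairs$protein_id))
  rlen <- nchar(seq_lookup(dataset, dataset$pairs$rna_id))
  keep <- plen >= config$min_protein_length & rlen >= config$min_rna_length
  pairs <- dataset$pairs[keep, ]
  used <- unique(c(pairs$protein_id, pairs$rna_id))
  pair_dataset(dataset$sequences[dataset$sequences$id %in% used, ],
               pairs,
               metadata = c(dataset$metadata, list(length_filtered = TRUE)))
}

#' Global pairwise sequence identity
#'
#' Fraction of identical aligned positions over the alignment length of a
#' global (Needleman-Wunsch) alignment scored with match = +1,
#' mismatch = 0, gap = -1 per position. The argument pair is put in
#' canonical (lexicographic) order before aligning so the result is
#' symmetric by construction.
#'
#' @param a,b Sequence strings of the same molecule type.
#' @return Identity fraction in \[0, 1\].
#' @export
#' @examples
#' pairwise_identity("ACGU", "ACGA")  # 0.75
pairwise_identity <- function(a, b) {
  stopifnot(is.character(a), is.character(b), nzchar(a), nzchar(b))
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  letters_seen <- unique(strsplit(paste0(a, b), "", fixed = TRUE)[[1]])
  sub_mat <- matrix(0, length(letters_seen), length(letters_seen),
                    dimnames = list(letters_seen, letters_seen))
  diag(sub_mat) <- 1
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::BString(a), Biostrings::BString(b),
    type = "global", substitutionMatrix = sub_mat,
    gapOpening = 0, gapExtension = 1
  )
  matches <- Biostrings::nmatch(aln)
  aln_len <- nchar(as.character(Biostrings::alignedPattern(aln)))
  matches / aln_len
}

# memoizing wrapper over a set of named sequences: identity by id pair
identity_cache <- function(seqs) {
  cache <- new.env(parent = emptyenv())
  function(id_a, id_b) {
    if (id_a == id_b) return(1.0)
    key <- paste(sort(c(id_a, id_b)), collapse = "\r")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- if (seqs[[id_a]] == seqs[[id_b]]) 1.0 else
      pairwise_identity(seqs[[id_a]], seqs[[id_b]])
    cache[[key]] <- val
    val
  }
}

#' Remove redundant positive pairs
#'
#' Greedy scan in input order: a pair (P, R) is discarded if and only if
#' some already-retained pair (P', R') has protein identity
#' `identity(P, P') >= threshold` and RNA identity
#' `identity(R, R') >= threshold`. Redundancy requires similarity on both
#' partners; pairs sharing a protein but with unrelated RNAs are all kept.
#' The operation is idempotent and its output is a subset of its input.
#'
#' @param dataset A [pair_dataset()] of positive pairs.
#' @param config A [filter_config()]; only `identity_threshold` is used.
#' @return A de-redundified [pair_dataset()].
#' @export
remove_redundant_pairs <- function(dataset, config = filter_config()) {
  stopifnot(inherits(dataset, "pair_dataset"))
  pairs <- dataset$pairs
  if (nrow(pairs) == 0) return(dataset)
  seqs <- stats::setNames(dataset$sequences$seq, dataset$sequences$id)
  ident <- identity_cache(seqs)
  thr <- config$identity_threshold
  kept <- integer(0)
  for (i in seq_len(nrow(pairs))) {
    redundant <- FALSE
    for (j in kept) {
      if (ident(pairs$protein_id[[i]], pairs$protein_id[[j]]) >= thr &&
          ident(pairs$rna_id[[i]], pairs$rna_id[[j]]) >= thr) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) kept <- c(kept, i)
  }
  pairs <- pairs[kept, ]
  used <- unique(c(pairs$protein_id, pairs$rna_id))
  pair_dataset(dataset$sequences[dataset$sequences$id %in% used, ],
               pairs,
               metadata = c(dataset$metadata, list(deredundified = TRUE)))
}

#' Sample non-interacting pairs with a similarity exclusion rule
#'
#' Draws `ratio * n_positives` protein-RNA pairs uniformly (with a seeded
#' generator) from the cross product of the dataset's proteins and RNAs,
#' rejecting (i) exact positive pairs and (ii) candidate pairs (A, B) for
#' which some positive pair (C, B) has protein identity
#' `identity(A, C) >= threshold` — a random pairing similar to a known
#' interaction is not a trustworthy negative.
#'
#' @param positives A [pair_dataset()] whose pairs are the known positives.
#' @param config A [negative_sampling_config()].
#' @param filter A [filter_config()]; supplies the identity threshold.
#' @return A [pair_dataset()] containing the positives plus the sampled
#'   negative pairs (labelled `"negative"`).
#' @export
sample_negatives <- function(positives, config = negative_sampling_config(),
                             filter = filter_config()) {
  stopifnot(inherits(positives, "pair_dataset"))
  pos <- positives$pairs
  if (nrow(pos) == 0) stop("no positive pairs to balance", call. = FALSE)
  prot_ids <- unique(positives$sequences$id[
    positives$sequences$moltype == "protein"])
  rna_ids <- unique(positives$sequences$id[
    positives$sequences$moltype == "rna"])
  n_target <- ceiling(config$ratio * nrow(pos))
  seqs <- stats::setNames(positives$sequences$seq, positives$sequences$id)
  ident <- identity_cache(seqs)
  thr <- filter$identity_threshold
  pos_key <- paste(pos$protein_id, pos$rna_id, sep = "\r")
  # positives partnered with each RNA, for the exclusion rule
  partners <- split(pos$protein_id, pos$rna_id)

  admissible <- function(p, r) {
    if (paste(p, r, sep = "\r") %in% pos_key) return(FALSE)
    for (c_prot in partners[[r]]) {
      if (ident(p, c_prot) >= thr) return(FALSE)
    }
    TRUE
  }

  chosen <- character(0)
  n_attempts <- 0L
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(config$seed)
  out_p <- character(0)
  out_r <- character(0)
  while (length(out_p) < n_target) {
    if (n_attempts >= config$max_attempts) {
      stop("negative sampling exhausted after ", n_attempts,
           " attempts: achieved ", length(out_p), " of ", n_target,
           " requested negatives", call. = FALSE)
    }
    n_attempts <- n_attempts + 1L
    p <- sample(prot_ids, 1)
    r <- sample(rna_ids, 1)
    key <- paste(p, r, sep = "\r")
    if (key %in% chosen) next
    if (!admissible(p, r)) {
      chosen <- c(chosen, key) # inadmissible forever; remember the rejection
      # detect a provably exhausted pool: every cross-product cell visited
      if (length(chosen) >= length(prot_ids) * length(rna_ids)) {
        stop("negative sampling pool exhausted: achieved ", length(out_p),
             " of ", n_target, " requested negatives", call. = FALSE)
      }
      next
    }
    chosen <- c(chosen, key)
    out_p <- c(out_p, p)
    out_r <- c(out_r, r)
  }
  pairs <- dplyr::bind_rows(
    pos,
    tibble::tibble(protein_id = out_p, rna_id = out_r, label = "negative")
  )
  pair_dataset(positives$sequences, pairs,
               metadata = c(positives$metadata,
                            list(negative_seed = config$seed)))
}

#' Summarize a pair dataset
#'
#' @param dataset A [pair_dataset()].
#' @return A one-row tibble: pair counts by label, distinct protein and RNA
#'   counts (distinct by sequence), and length ranges.
#' @export
dataset_summary <- function(dataset) {
  stopifnot(inherits(dataset, "pair_dataset"))
  s <- dataset$sequences
  prot <- s[s$moltype == "protein", ]
  rna <- s[s$moltype == "rna", ]
  lab <- table(factor(dataset$pairs$label,
                      levels = c("positive", "negative", "unlabeled")))
  tibble::tibble(
    n_pairs = nrow(dataset$pairs),
    n_positive = as.integer(lab[["positive"]]),
    n_negative = as.integer(lab[["negative"]]),
    n_unlabeled = as.integer(lab[["unlabeled"]]),
    n_proteins = length(unique(prot$seq)),
    n_rnas = length(unique(rna$seq)),
    protein_len_min = if (nrow(prot)) min(nchar(prot$seq)) else 0L,
    protein_len_max = if (nrow(prot)) max(nchar(prot$seq)) else 0L,
    rna_len_min = if (nrow(rna)) min(nchar(rna$seq)) else 0L,
    rna_len_max = if (nrow(rna)) max(nchar(rna$seq)) else 0L
  )
}

#' @method glance pair_dataset
#' @export
glance.pair_dataset <- function(x, ...) dataset_summary(x)
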