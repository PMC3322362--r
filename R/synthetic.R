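# Synthetic planted-signal data generator.
#
# Emulates the compositional separability the sequence-only predictor
# relies on: background residues are uniform over the molecule's alphabet;
# in positive pairs, selected protein conjoint triads and RNA tetrads are
# over-represented by overwriting sliding positions with signal k-mers at
# a tunable per-position probability (the effect size delta). Negative
# pairs are pure background. Labels are balanced 1:1.

#' Synthetic dataset configuration
#'
#' @param n_pairs_per_class Pairs per class (positives = negatives).
#' @param protein_length,rna_length Sequence lengths (fixed; signal k-mers
#'   overwrite rather than insert, so lengths never shift).
#' @param delta Per-sliding-position probability in \[0, 1\] that a signal
#'   k-mer is planted at that position of a positive-pair sequence; 0 makes
#'   classes indistinguishable.
#' @param signal_protein_triads Character vector of reduced-alphabet triads
#'   (3 group digits each, e.g. `"215"` = \{I,L,F,P\}\{A,G,V\}\{R,K\});
#'   planting realizes a triad by drawing one residue from each group.
#' @param signal_rna_tetrads Character vector of RNA tetrads (e.g.
#'   `"AUUC"`).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_pairs_per_class = 200L,
                             protein_length = 150L,
                             rna_length = 100L,
                             delta = 0.5,
                             signal_protein_triads = "215",
                             signal_rna_tetrads = "AUUC",
                             seed = 1L) {
  stopifnot(n_pairs_per_class >= 1,
            protein_length >= 3, rna_length >= 4,
            delta >= 0, delta <= 1)
  if (!all(grepl("^[1-7]{3}$", signal_protein_triads))) {
    stop("signal_protein_triads must be 3-digit strings over groups 1-7",
         call. = FALSE)
  }
  tet <- toupper(signal_rna_tetrads)
  if (!all(grepl("^[ACGU]{4}$", tet))) {
    stop("signal_rna_tetrads must be 4-letter strings over A/C/G/U",
         call. = FALSE)
  }
  structure(list(n_pairs_per_class = as.integer(n_pairs_per_class),
                 protein_length = as.integer(protein_length),
                 rna_length = as.integer(rna_length),
                 delta = delta,
                 signal_protein_triads = signal_protein_triads,
                 signal_rna_tetrads = tet,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# one background sequence as a character vector
random_chars <- function(n, alphabet) sample(alphabet, n, replace = TRUE)

# overwrite sliding positions with signal k-mers: each position draws
# independently with probability delta, scanning left to right; a draw
# that would overlap an already-planted k-mer is skipped, so every
# planted k-mer survives intact (the signal the encoders must recover)
plant_positions <- function(n_win, k, delta) {
  hit <- which(stats::runif(n_win) < delta)
  planted <- integer(0)
  last_end <- 0L
  for (pos in hit) {
    if (pos > last_end) {
      planted <- c(planted, pos)
      last_end <- pos + k - 1L
    }
  }
  planted
}

plant_signal <- function(chars, kmers, delta) {
  k <- nchar(kmers[[1]])
  n_win <- length(chars) - k + 1L
  if (n_win < 1 || delta == 0) return(chars)
  for (pos in plant_positions(n_win, k, delta)) {
    kmer <- if (length(kmers) == 1) kmers else sample(kmers, 1)
    chars[pos:(pos + k - 1L)] <- strsplit(kmer, "", fixed = TRUE)[[1]]
  }
  chars
}

# realize reduced-alphabet triads as concrete residue triplets by drawing
# one residue from each group
realize_triad <- function(triad) {
  groups <- as.integer(strsplit(triad, "", fixed = TRUE)[[1]])
  vapply(groups, function(g) sample(AA_GROUPS[[g]], 1), character(1))
}

#' Generate a labelled synthetic pair dataset
#'
#' Every pair gets its own protein and RNA. Positive-pair sequences carry
#' the planted compositional signal at effect size `delta`; negative-pair
#' sequences are pure background. Deterministic given the config seed.
#'
#' @param config A [synthetic_config()].
#' @return A balanced, labelled [pair_dataset()].
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_pairs_per_class
  with_seed(config$seed, {
    make_seqs <- function(label_positive) {
      prot <- character(n)
      rna <- character(n)
      for (i in seq_len(n)) {
        pc <- random_chars(config$protein_length, STANDARD_AA)
        rc <- random_chars(config$rna_length, RNA_BASES)
        if (label_positive) {
          # realize a fresh residue triplet per planted window so the
          # signal lives at the reduced-alphabet level, as encoded
          n_win <- config$protein_length - 2L
          for (pos in plant_positions(n_win, 3L, config$delta)) {
            triad <- if (length(config$signal_protein_triads) == 1) {
              config$signal_protein_triads
            } else {
              sample(config$signal_protein_triads, 1)
            }
            pc[pos:(pos + 2L)] <- realize_triad(triad)
          }
          rc <- plant_signal(rc, config$signal_rna_tetrads, config$delta)
        }
        prot[i] <- paste(pc, collapse = "")
        rna[i] <- paste(rc, collapse = "")
      }
      list(prot = prot, rna = rna)
    }
    pos <- make_seqs(TRUE)
    neg <- make_seqs(FALSE)
    sequences <- tibble::tibble(
      id = c(sprintf("P_pos%03d", seq_len(n)), sprintf("P_neg%03d", seq_len(n)),
             sprintf("R_pos%03d", seq_len(n)), sprintf("R_neg%03d", seq_len(n))),
      seq = c(pos$prot, neg$prot, pos$rna, neg$rna),
      moltype = rep(c("protein", "rna"), each = 2 * n)
    )
    pairs <- tibble::tibble(
      protein_id = c(sprintf("P_pos%03d", seq_len(n)),
                     sprintf("P_neg%03d", seq_len(n))),
      rna_id = c(sprintf("R_pos%03d", seq_len(n)),
                 sprintf("R_neg%03d", seq_len(n))),
      label = rep(c("positive", "negative"), each = n)
    )
    pair_dataset(sequences, pairs,
                 metadata = list(generator = "synthetic",
                                 delta = config$delta,
                                 seed = config$seed))
  })
}

#' Write a synthetic dataset as FASTA + pair TSV fixtures
#'
#' Produces `proteins.fasta`, `rnas.fasta` and `pairs.tsv` in `dir`,
#' loadable by [read_fasta()] / [read_pairs()]; regenerating with the same
#' config yields byte-identical files.
#'
#' @param config A [synthetic_config()].
#' @param dir Writable output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
generate_fixture_files <- function(config, dir) {
  dataset <- generate_synthetic(config)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(proteins = file.path(dir, "proteins.fasta"),
             rnas = file.path(dir, "rnas.fasta"),
             pairs = file.path(dir, "pairs.tsv"))
  s <- dataset$sequences
  write_fasta(s[s$moltype == "protein", ], paths[["proteins"]])
  write_fasta(s[s$moltype == "rna", ], paths[["rnas"]])
  write_pairs(dataset, paths[["pairs"]])
  invisible(paths)
}

#' Load a fixture directory back into a pair dataset
#'
#' @param dir Directory written by [generate_fixture_files()].
#' @return A [pair_dataset()].
#' @export
read_fixture_files <- function(dir) {
  proteins <- read_fasta(file.path(dir, "proteins.fasta"), "protein")
  rnas <- read_fasta(file.path(dir, "rnas.fasta"), "rna")
  read_pairs(file.path(dir, "pairs.tsv"), dialect = "id_pairs",
             proteins = proteins, rnas = rnas)
}
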