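# k-mer feature encoders.
#
# A protein is represented by the normalized frequencies of its 3-mers in a
# 7-letter reduced amino-acid alphabet (conjoint triads, 7^3 = 343
# features); an RNA by the normalized frequencies of its 4-mers over
# A/C/G/U (4^4 = 256 features). A pair vector is the concatenation,
# protein part first: 599 features in total.

# The 7 amino-acid groups, classified by dipole moment and side-chain
# volume, in their fixed printed order. The order defines the feature
# indexing and must not change.
AA_GROUPS <- list(
  c("A", "G", "V"),
  c("I", "L", "F", "P"),
  c("Y", "M", "T", "S"),
  c("H", "N", "Q", "W"),
  c("R", "K"),
  c("D", "E"),
  c("C")
)

# residue -> group index (1..7); non-standard letters are absent (NA lookup)
AA_GROUP_LOOKUP <- local({
  idx <- rep(seq_along(AA_GROUPS), lengths(AA_GROUPS))
  stats::setNames(idx, unlist(AA_GROUPS))
})

RNA_BASE_LOOKUP <- c(A = 1L, C = 2L, G = 3L, U = 4L)

#' The 7-group reduced amino-acid alphabet
#'
#' Returns the partition of the 20 standard amino acids into 7 groups by
#' dipole moment and side-chain volume, in the fixed order that defines the
#' conjoint-triad feature indexing.
#'
#' @return A named list of 7 character vectors (`g1` ... `g7`).
#' @export
#' @examples
#' reduced_alphabet()$g5  # the basic residues R, K
reduced_alphabet <- function() {
  stats::setNames(AA_GROUPS, paste0("g", seq_along(AA_GROUPS)))
}

#' Map a protein sequence to reduced-alphabet group indices
#'
#' Each standard residue maps to its group index (1-7, in the printed group
#' order); non-standard letters (ambiguity codes, `U`, `X`, ...) map to
#' `NA` and are thereby flagged rather than dropped, so output length
#' always equals input length.
#'
#' @param seq A canonicalized protein sequence string.
#' @return Integer vector of group indices with `NA` at invalid residues.
#' @export
#' @examples
#' reduce_protein("AGV")  # 1 1 1
#' reduce_protein("CRD")  # 7 5 6
reduce_protein <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  unname(AA_GROUP_LOOKUP[chars])
}

#' Feature names of the 599-dimensional pair encoding
#'
#' Protein features are named `P<g1><g2><g3>` over group digits 1-7,
#' ordered by the index formula `(g1-1)*49 + (g2-1)*7 + g3`; RNA features
#' are named `R_<tetrad>` over A/C/G/U in base-4 order (A before C before G
#' before U).
#'
#' @return Character vector of length 599 (343 protein + 256 RNA names).
#' @export
feature_schema <- function() {
  g <- seq_len(7)
  prot <- sprintf("P%d%d%d",
                  rep(g, each = 49),
                  rep(rep(g, each = 7), times = 7),
                  rep(g, times = 49))
  b <- c("A", "C", "G", "U")
  rna <- sprintf("R_%s%s%s%s",
                 rep(b, each = 64),
                 rep(rep(b, each = 16), times = 4),
                 rep(rep(b, each = 4), times = 16),
                 rep(b, times = 64))
  c(prot, rna)
}

# shared sliding-window k-mer counter: codes is an integer vector with NA at
# invalid positions; returns counts of each of n_classes^k words over windows
# free of NA, normalized by the number of valid windows
kmer_frequencies <- function(codes, k, n_classes, what) {
  L <- length(codes)
  if (L < k) {
    stop("cannot encode ", what, ": length ", L, " < k = ", k, call. = FALSE)
  }
  n_win <- L - k + 1L
  idx <- rep(0L, n_win)
  valid <- rep(TRUE, n_win)
  for (offset in seq_len(k)) {
    slice <- codes[offset:(offset + n_win - 1L)]
    valid <- valid & !is.na(slice)
    slice[is.na(slice)] <- 1L
    idx <- idx * n_classes + (slice - 1L)
  }
  if (!any(valid)) {
    stop("cannot encode ", what, ": no window of ", k,
         " consecutive valid letters", call. = FALSE)
  }
  counts <- tabulate(idx[valid] + 1L, nbins = n_classes^k)
  counts / sum(valid)
}

#' Encode a protein as 343 normalized conjoint-triad frequencies
#'
#' Counts every 3-mer of the reduced-alphabet representation over a sliding
#' window and divides by the number of valid windows, so the vector sums to
#' 1. Windows containing a non-standard residue contribute to neither
#' numerator nor denominator.
#'
#' @param seq A canonicalized protein sequence string (length >= 3 with at
#'   least one window of 3 consecutive standard residues).
#' @param id Optional identifier used in error messages.
#' @return Named numeric vector of length 343.
#' @export
#' @examples
#' v <- encode_protein("MKVRRK")
#' sum(v)  # 1
encode_protein <- function(seq, id = NULL) {
  what <- if (is.null(id)) "protein" else paste0("protein '", id, "'")
  freq <- kmer_frequencies(reduce_protein(seq), k = 3L, n_classes = 7L,
                           what = what)
  stats::setNames(freq, feature_schema()[1:343])
}

#' Encode an RNA as 256 normalized 4-mer frequencies
#'
#' @param seq A canonicalized RNA sequence string (length >= 4 with at
#'   least one window of 4 consecutive A/C/G/U letters).
#' @param id Optional identifier used in error messages.
#' @return Named numeric vector of length 256.
#' @export
#' @examples
#' v <- encode_rna("ACGUACGU")
#' v[["R_ACGU"]]  # 2/5
encode_rna <- function(seq, id = NULL) {
  what <- if (is.null(id)) "rna" else paste0("RNA '", id, "'")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  codes <- unname(RNA_BASE_LOOKUP[chars])
  freq <- kmer_frequencies(codes, k = 4L, n_classes = 4L, what = what)
  stats::setNames(freq, feature_schema()[344:599])
}

#' Encode an RNA-protein pair as a 599-feature vector
#'
#' Concatenates the 343 protein conjoint-triad frequencies and the 256 RNA
#' 4-mer frequencies, protein part first.
#'
#' @param protein_seq,rna_seq Canonicalized sequence strings.
#' @param protein_id,rna_id Optional identifiers for error messages.
#' @return Named numeric vector of length 599.
#' @export
encode_pair <- function(protein_seq, rna_seq,
                        protein_id = NULL, rna_id = NULL) {
  c(encode_protein(protein_seq, protein_id),
    encode_rna(rna_seq, rna_id))
}

#' Encode every pair of a dataset into a feature tibble
#'
#' @param dataset A [pair_dataset()].
#' @return A tibble with columns `protein_id`, `rna_id`, `label`, then the
#'   599 feature columns named by [feature_schema()].
#' @export
encode_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "pair_dataset"))
  p <- dataset$pairs
  prot <- seq_lookup(dataset, p$protein_id)
  rna <- seq_lookup(dataset, p$rna_id)
  mat <- matrix(0, nrow = nrow(p), ncol = 599,
                dimnames = list(NULL, feature_schema()))
  for (i in seq_len(nrow(p))) {
    mat[i, ] <- encode_pair(prot[[i]], rna[[i]],
                            p$protein_id[[i]], p$rna_id[[i]])
  }
  dplyr::bind_cols(
    tibble::tibble(protein_id = p$protein_id, rna_id = p$rna_id,
                   label = p$label),
    tibble::as_tibble(mat)
  )
}

#' Enumerate the amino-acid triplets of a conjoint-triad class
#'
#' A conjoint-triad class such as \{I,L,F,P\}\{A,G,V\}\{R,K\} stands for
#' the Cartesian product of its three residue groups; this expands it to
#' the individual amino-acid 3-mers (here 4 x 3 x 2 = 24 triplets: IAR,
#' IAK, IGR, IGK, ...).
#'
#' @param classes Integer vector of length 3 of group indices (1-7), or a
#'   3-character string of group digits such as `"215"`.
#' @return Character vector of amino-acid triplets, in within-group printed
#'   order.
#' @export
#' @examples
#' enumerate_triplets("215")[1:4]  # IAR IAK IGR IGK
enumerate_triplets <- function(classes) {
  if (is.character(classes) && length(classes) == 1) {
    classes <- suppressWarnings(
      as.integer(strsplit(classes, "", fixed = TRUE)[[1]]))
  }
  classes <- suppressWarnings(as.integer(classes))
  if (length(classes) != 3 || anyNA(classes) ||
      any(classes < 1 | classes > 7)) {
    stop("classes must be 3 group indices in 1..7", call. = FALSE)
  }
  g <- expand.grid(AA_GROUPS[[classes[3]]], AA_GROUPS[[classes[2]]],
                   AA_GROUPS[[classes[1]]], stringsAsFactors = FALSE)
  paste0(g[[3]], g[[2]], g[[1]])
}

# feature name of a protein triad given group indices (1-based)
triad_feature_name <- function(g1, g2, g3) sprintf("P%d%d%d", g1, g2, g3)

# feature name of an RNA tetrad given as e.g. "AUUC"
tetrad_feature_name <- function(tetrad) paste0("R_", toupper(tetrad))
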