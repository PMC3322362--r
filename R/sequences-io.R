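# Sequence and pair-list I/O.
#
# Sequences travel as tibbles with columns id, seq, moltype; a labelled
# collection of pairs plus its sequences is a `pair_dataset`.

STANDARD_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
RNA_BASES <- c("A", "C", "G", "U")

#' Canonicalize a sequence string
#'
#' Uppercases the sequence; for RNA, maps DNA-style `T` to `U`. Letters
#' outside the canonical alphabet (ambiguity codes such as `N`, `X`, `B`)
#' are retained, not dropped: they are flagged by [invalid_positions()] and
#' the k-mer encoders skip any window containing one. Idempotent.
#'
#' @param seq Character vector of sequences.
#' @param moltype `"protein"` or `"rna"`.
#' @return Character vector of canonicalized sequences.
#' @export
canonicalize_seq <- function(seq, moltype = c("protein", "rna")) {
  moltype <- match.arg(moltype)
  out <- toupper(seq)
  if (moltype == "rna") out <- chartr("T", "U", out)
  out
}

#' Positions of non-canonical letters
#'
#' @param seq A single sequence string (canonicalized).
#' @param moltype `"protein"` or `"rna"`.
#' @return Integer vector of 1-based positions whose letter is outside the
#'   canonical alphabet (20 amino acids, or A/C/G/U).
#' @export
invalid_positions <- function(seq, moltype = c("protein", "rna")) {
  moltype <- match.arg(moltype)
  alphabet <- if (moltype == "protein") STANDARD_AA else RNA_BASES
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  which(!chars %in% alphabet)
}

#' Read a FASTA file into a sequence tibble
#'
#' Records are canonicalized per molecule type (case-folded; `T` mapped to
#' `U` for RNA). Record order is preserved. Non-canonical letters are kept
#' in place and reported with a warning; downstream encoders skip windows
#' containing them.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped lines).
#' @param moltype `"protein"` or `"rna"`, applied to every record.
#' @return A tibble with columns `id`, `seq`, `moltype`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">r1", "acgt"), fa)
#' read_fasta(fa, "rna")
read_fasta <- function(path, moltype = c("protein", "rna")) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("malformed FASTA in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  ids <- sub("\\s.*$", "", names(set))
  if (any(ids == "")) {
    stop("malformed FASTA in '", path, "': empty record id", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate sequence id(s) in '", path, "': ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  seqs <- canonicalize_seq(as.character(set), moltype)
  bad <- vapply(seqs, function(s) length(invalid_positions(s, moltype)) > 0,
                logical(1))
  if (any(bad)) {
    warning("non-canonical letters retained in: ",
            paste(ids[bad], collapse = ", "),
            " (windows containing them are skipped by the encoders)",
            call. = FALSE)
  }
  tibble::tibble(id = ids, seq = unname(seqs), moltype = moltype)
}

#' Write a sequence tibble to FASTA
#'
#' @param sequences Tibble with columns `id`, `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::BStringSet(sequences$seq)
  names(set) <- sequences$id
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Construct a pair dataset
#'
#' A `pair_dataset` bundles a sequence table with a labelled pair table and
#' free-form provenance metadata, and validates referential integrity:
#' every pair must name an existing protein and RNA record.
#'
#' @param sequences Tibble with columns `id`, `seq`, `moltype`; ids unique.
#' @param pairs Tibble with columns `protein_id`, `rna_id` and optionally
#'   `label` (one of `"positive"`, `"negative"`, `"unlabeled"`; defaults to
#'   `"unlabeled"`).
#' @param metadata Named list of provenance information.
#' @return An object of class `pair_dataset`.
#' @export
pair_dataset <- function(sequences, pairs, metadata = list()) {
  sequences <- tibble::as_tibble(sequences)
  pairs <- tibble::as_tibble(pairs)
  if (!all(c("id", "seq", "moltype") %in% names(sequences))) {
    stop("sequences must have columns id, seq, moltype", call. = FALSE)
  }
  if (anyDuplicated(sequences$id)) {
    stop("sequence ids must be unique", call. = FALSE)
  }
  if (!all(c("protein_id", "rna_id") %in% names(pairs))) {
    stop("pairs must have columns protein_id, rna_id", call. = FALSE)
  }
  if (!"label" %in% names(pairs)) pairs$label <- "unlabeled"
  stopifnot(all(pairs$label %in% c("positive", "negative", "unlabeled")))
  if (anyDuplicated(pairs[, c("protein_id", "rna_id")])) {
    stop("(protein_id, rna_id) pairs must be unique", call. = FALSE)
  }
  prot_ids <- sequences$id[sequences$moltype == "protein"]
  rna_ids <- sequences$id[sequences$moltype == "rna"]
  missing_p <- setdiff(pairs$protein_id, prot_ids)
  missing_r <- setdiff(pairs$rna_id, rna_ids)
  if (length(missing_p) || length(missing_r)) {
    stop("pairs reference unknown records: ",
         paste(c(missing_p, missing_r), collapse = ", "), call. = FALSE)
  }
  structure(
    list(sequences = sequences,
         pairs = pairs[, c("protein_id", "rna_id", "label")],
         metadata = metadata),
    class = "pair_dataset"
  )
}

#' @export
print.pair_dataset <- function(x, ...) {
  n_prot <- sum(x$sequences$moltype == "protein")
  n_rna <- sum(x$sequences$moltype == "rna")
  lab <- table(factor(x$pairs$label,
                      levels = c("positive", "negative", "unlabeled")))
  cat("<pair_dataset> ", nrow(x$pairs), " pairs (",
      lab[["positive"]], " positive, ", lab[["negative"]], " negative, ",
      lab[["unlabeled"]], " unlabeled); ",
      n_prot, " proteins, ", n_rna, " RNAs\n", sep = "")
  invisible(x)
}

#' Read a two-column pair list
#'
#' Reads tab-delimited pair files in either of two dialects. In
#' `"id_pairs"` the columns are identifiers resolved against separately
#' loaded FASTA tables; in `"seq_pairs"` the columns carry raw sequences
#' and anonymous identifiers (`P<row>`, `R<row>`) are assigned
#' deterministically from row number. An optional third column carries the
#' label (`positive`/`negative`/`unlabeled`); absent, rows default to
#' `default_label`.
#'
#' @param path Path to the TSV file.
#' @param dialect `"id_pairs"` or `"seq_pairs"`.
#' @param proteins,rnas Sequence tibbles from [read_fasta()]; required for
#'   the `"id_pairs"` dialect.
#' @param default_label Label assigned to rows lacking a label column.
#' @return A [pair_dataset()].
#' @export
read_pairs <- function(path, dialect = c("id_pairs", "seq_pairs"),
                       proteins = NULL, rnas = NULL,
                       default_label = "positive") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("pair file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    empty_seq <- tibble::tibble(id = character(), seq = character(),
                                moltype = character())
    return(pair_dataset(empty_seq,
                        tibble::tibble(protein_id = character(),
                                       rna_id = character(),
                                       label = character()),
                        metadata = list(source = path, dialect = dialect)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2 | nf > 3)) {
    stop("pair file '", path, "': expected 2 or 3 tab-delimited columns, ",
         "got ", paste(unique(nf[nf < 2 | nf > 3]), collapse = "/"),
         " at line(s) ", paste(which(nf < 2 | nf > 3), collapse = ", "),
         call. = FALSE)
  }
  col1 <- vapply(fields, `[[`, character(1), 1)
  col2 <- vapply(fields, `[[`, character(1), 2)
  label <- ifelse(nf == 3, vapply(fields, function(f) f[min(3, length(f))],
                                  character(1)), default_label)

  if (dialect == "seq_pairs") {
    prot_seq <- canonicalize_seq(col1, "protein")
    rna_seq <- canonicalize_seq(col2, "rna")
    n <- length(prot_seq)
    sequences <- tibble::tibble(
      id = c(sprintf("P%d", seq_len(n)), sprintf("R%d", seq_len(n))),
      seq = c(prot_seq, rna_seq),
      moltype = rep(c("protein", "rna"), each = n)
    )
    pairs <- tibble::tibble(protein_id = sprintf("P%d", seq_len(n)),
                            rna_id = sprintf("R%d", seq_len(n)),
                            label = label)
    return(pair_dataset(sequences, pairs,
                        metadata = list(source = path, dialect = dialect)))
  }

  if (is.null(proteins) || is.null(rnas)) {
    stop("dialect 'id_pairs' requires `proteins` and `rnas` sequence tables",
         call. = FALSE)
  }
  bad_p <- setdiff(col1, proteins$id)
  bad_r <- setdiff(col2, rnas$id)
  if (length(bad_p) || length(bad_r)) {
    stop("unresolvable id(s) in '", path, "': ",
         paste(unique(c(bad_p, bad_r)), collapse = ", "), call. = FALSE)
  }
  used <- dplyr::bind_rows(
    proteins[proteins$id %in% col1, ],
    rnas[rnas$id %in% col2, ]
  )
  pairs <- tibble::tibble(protein_id = col1, rna_id = col2, label = label)
  pair_dataset(used, pairs,
               metadata = list(source = path, dialect = dialect))
}

#' Write a pair dataset's pair list to TSV
#'
#' Writes columns `protein_id`, `rna_id`, `label` without a header, so that
#' `read_pairs(..., dialect = "id_pairs")` round-trips the pair list
#' exactly. Identifiers may not contain the tab delimiter.
#'
#' @param dataset A [pair_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(dataset, path) {
  stopifnot(inherits(dataset, "pair_dataset"))
  p <- dataset$pairs
  if (any(grepl("\t", c(p$protein_id, p$rna_id), fixed = TRUE))) {
    stop("ids may not contain the tab delimiter", call. = FALSE)
  }
  lines <- sprintf("%s\t%s\t%s", p$protein_id, p$rna_id, p$label)
  writeLines(lines, path)
  invisible(path)
}

#' Sequence lookup helper
#'
#' @param dataset A [pair_dataset()].
#' @param ids Ids to look up.
#' @return Character vector of sequences, named by id.
#' @keywords internal
#' @noRd
seq_lookup <- function(dataset, ids) {
  m <- match(ids, dataset$sequences$id)
  stats::setNames(dataset$sequences$seq[m], ids)
}
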