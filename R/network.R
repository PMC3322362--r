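# Bipartite RNA-protein interaction networks: score candidate pairs with a
# trained model, evaluate recall against known interactions, summarize
# hubs, and export edge lists.
#
# Known-interaction databases list positives only (no validated
# non-interacting pairs exist in them), so network evaluation reports
# recall — the fraction of known interactions recovered — never accuracy.

#' Score candidate pairs and build an interaction network
#'
#' Every candidate (protein, RNA) pair is encoded and scored with the
#' model; an edge is predicted positive when its probability is at or
#' above the threshold. Sequences that cannot be encoded (too short, or no
#' valid k-mer window) are skipped with a warning and recorded in the
#' result, so one bad record does not fail a whole run.
#'
#' @param proteins,rnas Sequence tibbles ([read_fasta()]).
#' @param model An [rpi_model][train_model()].
#' @param candidates `"all"` for the full protein x RNA cross product, or a
#'   tibble with columns `protein_id`, `rna_id`.
#' @param threshold Decision threshold (default 0.50).
#' @return An object of class `rpi_network`: `edges` (tibble `protein_id`,
#'   `rna_id`, `probability`, `predicted`), `proteins`, `rnas`, `skipped`.
#' @export
predict_network <- function(proteins, rnas, model, candidates = "all",
                            threshold = 0.50) {
  stopifnot(inherits(model, "rpi_model"))
  if (identical(candidates, "all")) {
    candidates <- tidyr::expand_grid(protein_id = proteins$id,
                                     rna_id = rnas$id)
  }
  candidates <- tibble::as_tibble(candidates)[, c("protein_id", "rna_id")]

  encode_or_null <- function(seqs, ids, fun) {
    out <- vector("list", length(seqs))
    for (i in seq_along(seqs)) {
      out[[i]] <- tryCatch(fun(seqs[[i]], ids[[i]]), error = function(e) NULL)
    }
    stats::setNames(out, ids)
  }
  prot_vecs <- encode_or_null(proteins$seq, proteins$id, encode_protein)
  rna_vecs <- encode_or_null(rnas$seq, rnas$id, encode_rna)
  bad_prot <- names(prot_vecs)[vapply(prot_vecs, is.null, logical(1))]
  bad_rna <- names(rna_vecs)[vapply(rna_vecs, is.null, logical(1))]
  skipped <- candidates$protein_id %in% bad_prot |
    candidates$rna_id %in% bad_rna
  if (any(skipped)) {
    warning(sum(skipped), " candidate pair(s) skipped: unencodable ",
            "sequence(s) ", paste(c(bad_prot, bad_rna), collapse = ", "),
            call. = FALSE)
  }
  scored <- candidates[!skipped, ]
  prob <- numeric(nrow(scored))
  if (nrow(scored)) {
    mat <- matrix(0, nrow = nrow(scored), ncol = 599,
                  dimnames = list(NULL, feature_schema()))
    for (i in seq_len(nrow(scored))) {
      mat[i, ] <- c(prot_vecs[[scored$protein_id[[i]]]],
                    rna_vecs[[scored$rna_id[[i]]]])
    }
    prob <- predict_proba(model, mat)
  }
  edges <- dplyr::arrange(
    tibble::tibble(protein_id = scored$protein_id,
                   rna_id = scored$rna_id,
                   probability = prob,
                   predicted = classify(prob, threshold)),
    .data$protein_id, .data$rna_id
  )
  structure(list(edges = edges,
                 proteins = tibble::tibble(id = unique(proteins$id)),
                 rnas = tibble::tibble(id = unique(rnas$id)),
                 threshold = threshold,
                 skipped = tibble::tibble(
                   id = c(bad_prot, bad_rna),
                   moltype = c(rep("protein", length(bad_prot)),
                               rep("rna", length(bad_rna))))),
            class = "rpi_network")
}

#' @export
print.rpi_network <- function(x, ...) {
  cat("<rpi_network> ", nrow(x$proteins), " proteins x ", nrow(x$rnas),
      " RNAs; ", nrow(x$edges), " scored edges (",
      sum(x$edges$predicted == "positive"), " positive at threshold ",
      x$threshold, ")\n", sep = "")
  if (nrow(x$skipped)) {
    cat("  skipped unencodable:", paste(x$skipped$id, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @method tidy rpi_network
#' @export
tidy.rpi_network <- function(x, ...) x$edges

#' Recall of known interactions in a predicted network
#'
#' Fraction of known (experimentally supported) pairs whose edge is
#' predicted positive, with counts in the high-confidence band
#' (probability >= 0.80) and the moderate band (0.50 to < 0.80). Because
#' interaction databases carry no negatives, this is recall, not accuracy.
#'
#' @param network An [rpi_network][predict_network()].
#' @param known Tibble with columns `protein_id`, `rna_id` of known
#'   interacting pairs; every known pair must be present (scored) in the
#'   network.
#' @return One-row tibble: `n_known`, `n_predicted`, `recall`,
#'   `band_high` (>= 0.80), `band_mid` (0.50-0.80).
#' @export
recall_on_known <- function(network, known) {
  stopifnot(inherits(network, "rpi_network"))
  known <- tibble::as_tibble(known)[, c("protein_id", "rna_id")]
  hits <- dplyr::inner_join(known, network$edges,
                            by = c("protein_id", "rna_id"))
  if (nrow(hits) < nrow(known)) {
    miss <- dplyr::anti_join(known, network$edges,
                             by = c("protein_id", "rna_id"))
    stop("known pair(s) absent from the network: ",
         paste(paste(miss$protein_id, miss$rna_id, sep = ":"),
               collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    n_known = nrow(known),
    n_predicted = sum(hits$predicted == "positive"),
    recall = sum(hits$predicted == "positive") / nrow(known),
    band_high = sum(hits$probability >= 0.80),
    band_mid = sum(hits$probability >= 0.50 & hits$probability < 0.80)
  )
}

#' Hub nodes of a predicted network
#'
#' Nodes whose positive-edge degree reaches `min_degree` — proteins bound
#' by many RNAs (e.g. a helicase hub) or RNAs bound by many proteins (e.g.
#' an snRNA engaged by an Sm-like protein complex).
#'
#' @param network An [rpi_network][predict_network()].
#' @param min_degree Minimum positive-edge degree (default 2).
#' @return Tibble `id`, `side` (`"protein"`/`"rna"`), `degree`, sorted by
#'   degree descending, ties broken by id.
#' @export
hub_summary <- function(network, min_degree = 2L) {
  stopifnot(inherits(network, "rpi_network"))
  pos <- network$edges[network$edges$predicted == "positive", ]
  deg <- dplyr::bind_rows(
    dplyr::count(pos, id = .data$protein_id, name = "degree") |>
      dplyr::mutate(side = "protein"),
    dplyr::count(pos, id = .data$rna_id, name = "degree") |>
      dplyr::mutate(side = "rna")
  )
  deg <- deg[deg$degree >= min_degree, c("id", "side", "degree")]
  dplyr::arrange(deg, dplyr::desc(.data$degree), .data$id)
}

#' Export a network's edge list
#'
#' `tsv`: all scored edges with columns `protein_id`, `rna_id`,
#' `probability`, `predicted`; re-importable with [read_network_tsv()].
#' `sif`: predicted-positive edges with relation `rpi`. `graphml`:
#' bipartite graph with the probability as an edge attribute.
#'
#' @param network An [rpi_network][predict_network()].
#' @param path Output path.
#' @param format `"tsv"`, `"sif"`, or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("tsv", "sif", "graphml")) {
  stopifnot(inherits(network, "rpi_network"))
  format <- match.arg(format)
  e <- network$edges
  if (format == "tsv") {
    readr::write_tsv(e, path)
  } else if (format == "sif") {
    pos <- e[e$predicted == "positive", ]
    writeLines(sprintf("%s\trpi\t%s", pos$protein_id, pos$rna_id), path)
  } else {
    nodes <- dplyr::bind_rows(
      tibble::tibble(name = network$proteins$id, type = FALSE),
      tibble::tibble(name = network$rnas$id, type = TRUE)
    )
    g <- igraph::graph_from_data_frame(
      data.frame(from = e$protein_id, to = e$rna_id,
                 probability = e$probability,
                 predicted = e$predicted),
      directed = FALSE, vertices = as.data.frame(nodes)
    )
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Re-import a TSV edge list
#'
#' @param path Path written by [export_network()] with `format = "tsv"`.
#' @return Edge tibble `protein_id`, `rna_id`, `probability`, `predicted`.
#' @export
read_network_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    protein_id = readr::col_character(),
    rna_id = readr::col_character(),
    probability = readr::col_double(),
    predicted = readr::col_character()
  ))
}

#' Plot a bipartite interaction network
#'
#' Simple two-column bipartite layout (proteins left, RNAs right) with
#' predicted-positive edges drawn solid and weighted by probability.
#'
#' @param object An [rpi_network][predict_network()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot rpi_network
#' @export
autoplot.rpi_network <- function(object, ...) {
  prot <- tibble::tibble(id = object$proteins$id, x = 0,
                         y = seq_along(object$proteins$id),
                         side = "protein")
  rna <- tibble::tibble(id = object$rnas$id, x = 1,
                        y = seq_along(object$rnas$id) *
                          max(1, nrow(prot)) / max(1, nrow(object$rnas)),
                        side = "rna")
  nodes <- dplyr::bind_rows(prot, rna)
  seg <- object$edges |>
    dplyr::left_join(prot[, c("id", "y")], by = c("protein_id" = "id")) |>
    dplyr::rename(y_prot = "y") |>
    dplyr::left_join(rna[, c("id", "y")], by = c("rna_id" = "id")) |>
    dplyr::rename(y_rna = "y")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = 0, xend = 1, y = .data$y_prot, yend = .data$y_rna,
                   alpha = .data$probability,
                   linetype = .data$predicted)
    ) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     shape = .data$side), size = 3) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$id),
                       hjust = rep(c(1.3, -0.3),
                                   c(nrow(prot), nrow(rna))),
                       size = 3) +
    ggplot2::scale_linetype_manual(
      values = c(positive = "solid", negative = "dotted")) +
    ggplot2::theme_void() +
    ggplot2::labs(alpha = "probability", linetype = "call", shape = NULL)
}
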