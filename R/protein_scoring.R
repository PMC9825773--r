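#' Score every protein for every trained ADR via its STC
#'
#' The single-target-compound (STC) read-out: entry `(a, p)` is the
#' predicted probability of ADR `a`'s classifier evaluated on the
#' embedding of protein `p`'s STC, interpreted as the ADR-relation score
#' of the protein itself.
#'
#' @param bundle An `adr_classifier_bundle`.
#' @param embeddings Full embedding matrix (must contain every STC row).
#' @param net The `hetero_network` the embeddings were trained on.
#' @return An object of class `score_matrix`: numeric ADR-by-protein
#'   matrix with dimnames, all entries in `[0, 1]`.
#' @export
score_proteins <- function(bundle, embeddings, net) {
  stopifnot(inherits(bundle, "adr_classifier_bundle"),
            inherits(net, "hetero_network"))
  proteins <- names(net$stc_of)
  stc_ids <- unname(net$stc_of)
  missing <- proteins[!(stc_ids %in% rownames(embeddings))]
  if (length(missing) > 0L)
    stop("no STC embedding for protein(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  x <- embeddings[stc_ids, , drop = FALSE]
  eta <- bundle$weights %*% t(x) +
    matrix(bundle$intercepts, nrow(bundle$weights), nrow(x))
  scores <- stats::plogis(eta)
  dimnames(scores) <- list(bundle$adr_ids, proteins)
  class(scores) <- c("score_matrix", class(scores))
  scores
}

#' Rank all proteins for one ADR
#'
#' Descending-score ranking with average ranks on ties; the percentile of
#' a protein is `100 * rank / N`.
#'
#' @param scores A `score_matrix`.
#' @param adr ADR identifier (row of the matrix).
#' @return Data frame `protein`, `score`, `rank`, `percentile`, sorted by
#'   rank (ties in protein-identifier order).
#' @export
rank_proteins <- function(scores, adr) {
  s <- score_row(scores, adr)
  r <- rank(-s, ties.method = "average")
  out <- data.frame(protein = names(s), score = unname(s),
                    rank = unname(r), percentile = unname(100 * r / length(s)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$rank, out$protein), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top-k proteins for one ADR
#'
#' First `k` proteins of [rank_proteins()]; ties at the boundary are
#' broken by lexicographic protein identifier, so the selection is
#' deterministic.
#'
#' @param scores A `score_matrix`.
#' @param adr ADR identifier.
#' @param k Number of proteins (default 50).
#' @return Character vector of `k` protein identifiers.
#' @export
top_k <- function(scores, adr, k = 50L) {
  s <- score_row(scores, adr)
  if (k > length(s)) stop("k exceeds the number of proteins")
  rank_proteins(scores, adr)$protein[seq_len(k)]
}

score_row <- function(scores, adr) {
  stopifnot(inherits(scores, "score_matrix"))
  if (!adr %in% rownames(scores)) stop("unknown ADR: ", adr)
  scores[adr, ]
}

#' Write a score matrix in long format
#'
#' Columns `adr_pt`, `protein`, `score`, `rank`, `percentile`, sorted by
#' ADR then rank.
#'
#' @param scores A `score_matrix`.
#' @param path Output TSV.
#' @export
write_scores <- function(scores, path) {
  long <- do.call(rbind, lapply(rownames(scores), function(a) {
    cbind(adr_pt = a, rank_proteins(scores, a))
  }))
  write_tsv(long, path)
}
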