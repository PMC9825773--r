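#' Parameters for second-order biased random walks
#'
#' @param p Return parameter (> 0): weight `1/p` for stepping straight
#'   back to the previous node.
#' @param q In-out parameter (> 0): weight `1/q` for stepping to a node
#'   that is not an out-neighbour of the previous node; common
#'   neighbours get weight 1.
#' @param num_walks Walks started from every node.
#' @param walk_length Maximum nodes per walk.
#' @param seed Integer seed for the walk sampler.
#' @return An object of class `walk_params`.
#' @export
walk_params <- function(p = 1, q = 1, num_walks = 10L, walk_length = 80L,
                        seed = 1L) {
  stopifnot(p > 0, q > 0, num_walks >= 1L, walk_length >= 1L)
  structure(list(p = p, q = q, num_walks = as.integer(num_walks),
                 walk_length = as.integer(walk_length),
                 seed = as.integer(seed)),
            class = "walk_params")
}

#' Parameters for skip-gram embedding training
#'
#' Defaults follow the common node2vec benchmark settings: 128
#' dimensions, window 10, 5 epochs, 5 negative samples.
#'
#' @param dimensions Embedding dimensionality.
#' @param window Maximum context window (shrunk uniformly per position,
#'   in the word2vec tradition).
#' @param epochs Training passes over the walk corpus.
#' @param negative Negative samples per positive pair.
#' @param alpha,min_alpha Initial and final learning rate (linear decay).
#' @param seed Integer seed for initialization and sampling.
#' @return An object of class `embedding_params`.
#' @export
embedding_params <- function(dimensions = 128L, window = 10L, epochs = 5L,
                             negative = 5L, alpha = 0.025,
                             min_alpha = 1e-4, seed = 1L) {
  stopifnot(dimensions >= 1L, window >= 1L, epochs >= 1L, negative >= 1L,
            alpha > 0, min_alpha > 0)
  structure(list(dimensions = as.integer(dimensions),
                 window = as.integer(window), epochs = as.integer(epochs),
                 negative = as.integer(negative), alpha = alpha,
                 min_alpha = min_alpha, seed = as.integer(seed)),
            class = "embedding_params")
}

# 0-based CSR out-adjacency of the network graph, neighbours sorted,
# plus the node-id ordering used for integer coding.
network_csr <- function(net) {
  g <- net$graph
  ids <- igraph::V(g)$name
  al <- igraph::as_adj_list(g, mode = "out")
  al <- lapply(al, function(v) sort(as.integer(v)) - 1L)
  list(ids = ids,
       offset = c(0L, cumsum(lengths(al))),
       adj = as.integer(unlist(al, use.names = FALSE)))
}

#' Second-order transition distribution
#'
#' Probability distribution of the next node of a walk at `curr` that
#' arrived from `prev`: out-neighbours of `curr` get unnormalized weight
#' `1/p` if they equal `prev`, 1 if they are out-neighbours of `prev`,
#' and `1/q` otherwise.
#'
#' @param net A `hetero_network`.
#' @param prev,curr Node identifiers; `(prev, curr)` must be an edge.
#' @param params A [walk_params()] object.
#' @return Named numeric vector of probabilities over the out-neighbours
#'   of `curr`, summing to 1.
#' @export
transition_distribution <- function(net, prev, curr, params) {
  g <- net$graph
  stopifnot(inherits(params, "walk_params"))
  if (!igraph::are_adjacent(g, prev, curr))
    stop(sprintf("(%s, %s) is not an edge", prev, curr))
  succ <- igraph::neighbors(g, curr, mode = "out")$name
  if (length(succ) == 0L) stop(sprintf("node %s has no out-edges", curr))
  prev_nb <- igraph::neighbors(g, prev, mode = "out")$name
  w <- ifelse(succ == prev, 1 / params$p,
              ifelse(succ %in% prev_nb, 1, 1 / params$q))
  stats::setNames(w / sum(w), succ)
}

#' Generate a biased random-walk corpus
#'
#' Starts `num_walks` walks from every node (drugs, proteins and STCs
#' alike). The first step from a start node is uniform over its
#' out-neighbours; subsequent steps follow [transition_distribution()].
#' Walks are truncated at nodes with no out-edge. The start-node
#' visitation order is reshuffled for every repetition. By the network's
#' edge directions, drug and STC nodes can only ever be walk heads: every
#' later position is a protein.
#'
#' @param net A `hetero_network`.
#' @param params A [walk_params()] object.
#' @return A list of character vectors of node identifiers, of length
#'   `num_walks * vcount`.
#' @export
generate_walks <- function(net, params) {
  stopifnot(inherits(net, "hetero_network"), inherits(params, "walk_params"))
  csr <- network_csr(net)
  m <- .cpp_generate_walks(length(csr$ids), csr$offset, csr$adj,
                           params$p, params$q, params$num_walks,
                           params$walk_length, as.double(params$seed))
  apply(m, 1L, function(r) csr$ids[r[r > 0L]], simplify = FALSE)
}

#' Write / read a walk corpus as plain text
#'
#' One walk per line, space-separated node identifiers.
#' @param walks List of character vectors.
#' @param path Output file.
#' @export
write_walks <- function(walks, path) {
  writeLines(vapply(walks, paste, character(1L), collapse = " "), path)
}

#' @rdname write_walks
#' @export
read_walks <- function(path) {
  strsplit(readLines(path), " ", fixed = TRUE)
}

#' Train skip-gram embeddings on a walk corpus
#'
#' Skip-gram with negative sampling (word2vec-style) over within-window
#' co-occurrences, single-threaded and deterministic for a fixed seed.
#'
#' @param walks Walk corpus from [generate_walks()] (list of character
#'   vectors).
#' @param params An [embedding_params()] object.
#' @return A numeric matrix with one row per node that appeared in the
#'   corpus (rownames are node identifiers) and `dimensions` columns.
#' @export
train_embeddings <- function(walks, params) {
  stopifnot(inherits(params, "embedding_params"))
  if (length(walks) == 0L || sum(lengths(walks)) == 0L)
    stop("empty walk corpus")
  vocab <- sort(unique(unlist(walks, use.names = FALSE)))
  sentences <- lapply(walks, function(w) match(w, vocab))
  emb <- .cpp_train_sgns(sentences, length(vocab), params$dimensions,
                         params$window, params$negative, params$epochs,
                         params$alpha, params$min_alpha,
                         as.double(params$seed))
  rownames(emb) <- vocab
  stopifnot(all(is.finite(emb)))
  emb
}

#' Write / read an embedding matrix in word2vec text format
#'
#' Header line "N d", then one `node v1 ... vd` line per node.
#' @param emb Embedding matrix with identifier rownames.
#' @param path File path.
#' @export
write_embeddings <- function(emb, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(nrow(emb), ncol(emb)), con)
  writeLines(paste(rownames(emb),
                   apply(emb, 1L, function(r)
                     paste(formatC(r, format = "g", digits = 17),
                           collapse = " "))), con)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- as.integer(strsplit(lines[1L], " ", fixed = TRUE)[[1L]])
  parts <- strsplit(lines[-1L], " ", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1L), 1L)
  emb <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1L])))
  stopifnot(nrow(emb) == hdr[1L], ncol(emb) == hdr[2L])
  rownames(emb) <- ids
  emb
}
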