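#' Read a confidence-scored interaction table
#'
#' Reads a STRING/STITCH-style tab-separated table (two identifier columns
#' plus an integer `combined_score` in 0-1000), keeps records with
#' `score >= threshold` (700 is the conventional "high confidence" cut and
#' is included), collapses duplicate unordered pairs keeping the maximum
#' score, and drops self-loops. Lines starting with `#` are ignored.
#'
#' @param path TSV file with a header row and three columns.
#' @param threshold Inclusive minimum confidence score (default 700).
#' @return A data.frame `source_id`, `target_id`, `score`, one row per
#'   unordered pair.
#' @export
read_interactions <- function(path, threshold = 700L) {
  df <- read_tsv_checked(path, n_cols = 3L)
  names(df) <- c("source_id", "target_id", "score")
  score_num <- suppressWarnings(as.numeric(df$score))
  bad <- which(!is.finite(score_num) | score_num != as.integer(score_num))
  if (length(bad) > 0L)
    stop(sprintf("non-integer score at data row %d of %s", bad[1L], path))
  df$score <- as.integer(score_num)
  out_of_range <- which(df$score < 0L | df$score > 1000L)
  if (length(out_of_range) > 0L)
    stop(sprintf("score out of range [0, 1000] at data row %d of %s",
                 out_of_range[1L], path))
  df <- df[df$score >= threshold & df$source_id != df$target_id, , drop = FALSE]
  if (nrow(df) == 0L) {
    return(data.frame(source_id = character(), target_id = character(),
                      score = integer(), stringsAsFactors = FALSE))
  }
  # canonical unordered key, keep max score per pair
  a <- pmin(df$source_id, df$target_id)
  b <- pmax(df$source_id, df$target_id)
  key <- paste(a, b, sep = "\r")
  o <- order(key, -df$score)
  keep <- !duplicated(key[o])
  res <- data.frame(source_id = a[o][keep], target_id = b[o][keep],
                    score = df$score[o][keep], stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Read SIDER-style drug-ADR pairs
#'
#' @param path TSV with columns `drug` and `adr_pt` (MedDRA-Preferred-Term
#'   style ADR identifiers).
#' @return A data.frame `drug`, `adr_pt` with duplicates removed.
#' @export
read_drug_adr <- function(path) {
  df <- read_tsv_checked(path, n_cols = 2L)
  names(df) <- c("drug", "adr_pt")
  unique(df)
}

#' Read a benchmark table of known ADR-protein relations
#'
#' @param path TSV with columns `adr_pt` and `protein`.
#' @return A data.frame `adr_pt`, `protein` with duplicates removed.
#' @export
read_benchmark <- function(path) {
  df <- read_tsv_checked(path, n_cols = 2L)
  names(df) <- c("adr_pt", "protein")
  unique(df)
}

read_tsv_checked <- function(path, n_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty file (no header): ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != n_cols)
  if (length(bad) > 0L) {
    # report 1-based line number in the comment-stripped file
    stop(sprintf("malformed row at line %d of %s: expected %d tab-separated fields, got %d",
                 bad[1L], path, n_cols, lengths(parts)[bad[1L]]))
  }
  body <- parts[-1L]
  if (length(body) == 0L) {
    df <- as.data.frame(matrix(character(), ncol = n_cols),
                        stringsAsFactors = FALSE)
    return(df)
  }
  df <- as.data.frame(do.call(rbind, body), stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' Build binary drug-by-ADR training labels
#'
#' Every retained drug has at least one ADR and every retained ADR at
#' least one drug, by construction from the pair list.
#'
#' @param drug_adr Data.frame with columns `drug` and `adr_pt`.
#' @return An object of class `drug_adr_labels`: list with `drugs`,
#'   `adrs` (ordered identifier vectors) and a logical `matrix`
#'   (drug rows by ADR columns).
#' @export
drug_adr_labels <- function(drug_adr) {
  stopifnot(all(c("drug", "adr_pt") %in% names(drug_adr)))
  drug_adr <- unique(drug_adr[, c("drug", "adr_pt")])
  if (nrow(drug_adr) == 0L) stop("no drug-ADR pairs")
  drugs <- sort(unique(drug_adr$drug))
  adrs <- sort(unique(drug_adr$adr_pt))
  m <- matrix(FALSE, length(drugs), length(adrs),
              dimnames = list(drugs, adrs))
  m[cbind(match(drug_adr$drug, drugs), match(drug_adr$adr_pt, adrs))] <- TRUE
  structure(list(drugs = drugs, adrs = adrs, matrix = m),
            class = "drug_adr_labels")
}

#' Restrict labels to a drug subset
#'
#' Drops ADR columns left without a positive drug.
#'
#' @param labels A `drug_adr_labels` object.
#' @param drugs Character vector of drugs to keep.
#' @return A `drug_adr_labels` object.
#' @export
subset_labels <- function(labels, drugs) {
  stopifnot(inherits(labels, "drug_adr_labels"))
  keep <- labels$drugs %in% drugs
  m <- labels$matrix[keep, , drop = FALSE]
  keep_adr <- colSums(m) > 0L
  m <- m[, keep_adr, drop = FALSE]
  structure(list(drugs = rownames(m), adrs = colnames(m), matrix = m),
            class = "drug_adr_labels")
}

#' Assemble the integrated drug / protein / STC network
#'
#' The protein set is the node set of the filtered PPI graph. Drug-target
#' records whose drug has no ADR label or whose protein is absent from
#' the PPI graph are dropped (with a message reporting the counts). Each
#' surviving drug-protein pair becomes one directed drug-to-protein edge;
#' each PPI pair becomes two directed edges; and for every protein one
#' fictitious single-target compound (STC) node is added with a single
#' directed STC-to-protein edge. The resulting graph is directed and
#' unweighted.
#'
#' @param ppi Data.frame from [read_interactions()] (protein-protein).
#' @param drug_target Data.frame from [read_interactions()]
#'   (chemical-protein).
#' @param labels A [drug_adr_labels()] object.
#' @param stc_prefix Reserved identifier prefix for STC nodes.
#' @return An object of class `hetero_network`: list with `graph` (a
#'   directed [igraph::igraph] whose vertices carry a `role` attribute in
#'   `drug`/`protein`/`stc`), `stc_of` (named character vector, protein ->
#'   STC identifier), `roles` (named character vector) and edge-count
#'   components `n_drug_edges`, `n_ppi_pairs`.
#' @export
build_network <- function(ppi, drug_target, labels, stc_prefix = "STC::") {
  stopifnot(inherits(labels, "drug_adr_labels"))
  if (nrow(ppi) == 0L) stop("empty PPI list")
  proteins <- sort(unique(c(ppi$source_id, ppi$target_id)))

  dt <- drug_target
  drop_drug <- !(dt$source_id %in% labels$drugs)
  drop_prot <- !(dt$target_id %in% proteins)
  if (any(drop_drug) || any(drop_prot)) {
    message(sprintf(
      "build_network: dropped %d drug-target records (%d with unlabeled drugs, %d with proteins outside the PPI graph)",
      sum(drop_drug | drop_prot), sum(drop_drug), sum(drop_prot)))
  }
  dt <- dt[!drop_drug & !drop_prot, , drop = FALSE]
  if (nrow(dt) == 0L) stop("no trainable drugs: drug-target records empty after filtering")
  drugs <- sort(unique(dt$source_id))

  stc_of <- stats::setNames(paste0(stc_prefix, proteins), proteins)
  if (any(stc_of %in% c(proteins, drugs)))
    stop("stc_prefix collides with existing identifiers")

  edges <- rbind(
    cbind(dt$source_id, dt$target_id),                 # drug -> protein
    cbind(ppi$source_id, ppi$target_id),               # protein <-> protein
    cbind(ppi$target_id, ppi$source_id),
    cbind(unname(stc_of), proteins)                    # stc -> protein
  )
  roles <- c(stats::setNames(rep("drug", length(drugs)), drugs),
             stats::setNames(rep("protein", length(proteins)), proteins),
             stats::setNames(rep("stc", length(proteins)), unname(stc_of)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1L], to = edges[, 2L], stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = names(roles), role = unname(roles),
                          stringsAsFactors = FALSE))
  structure(list(graph = g, stc_of = stc_of, roles = roles,
                 n_drug_edges = nrow(dt), n_ppi_pairs = nrow(ppi)),
            class = "hetero_network")
}

#' Summary counts for an integrated network
#'
#' @param net A `hetero_network`.
#' @return A list with `drugs`, `proteins`, `stcs`, `edges`. The directed
#'   edge count always equals
#'   `drug-target pairs + 2 * PPI pairs + proteins`.
#' @export
network_stats <- function(net) {
  stopifnot(inherits(net, "hetero_network"))
  roles <- net$roles
  list(drugs = sum(roles == "drug"),
       proteins = sum(roles == "protein"),
       stcs = sum(roles == "stc"),
       edges = igraph::ecount(net$graph))
}

#' Node identifiers of a network, optionally by role
#'
#' @param net A `hetero_network`.
#' @param role One of `"drug"`, `"protein"`, `"stc"`, or `NULL` for all.
#' @return Character vector of node identifiers.
#' @export
node_ids <- function(net, role = NULL) {
  if (is.null(role)) return(names(net$roles))
  names(net$roles)[net$roles == role]
}
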