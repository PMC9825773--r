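#' Confusion counts for one (ADR, protein) pair
#'
#' Treats "targets the protein" as the test and "has the ADR" as the
#' event, over the drug universe of the labels: `tp` drugs target the
#' protein and have the ADR, `fp` target it without the ADR, `fn` have
#' the ADR without targeting it, `tn` neither. The four counts always
#' sum to the number of labeled drugs.
#'
#' @param adr ADR identifier (column of the labels).
#' @param protein Protein identifier.
#' @param drug_targets Named list: drug -> character vector of target
#'   proteins.
#' @param labels A [drug_adr_labels()] object (defines the drug
#'   universe).
#' @return List of class `confusion_counts` with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(adr, protein, drug_targets, labels) {
  stopifnot(inherits(labels, "drug_adr_labels"))
  if (!adr %in% labels$adrs) stop("unknown ADR: ", adr)
  drugs <- labels$drugs
  targets_p <- vapply(drugs, function(d)
    protein %in% drug_targets[[d]], logical(1L))
  has_a <- labels$matrix[, adr]
  structure(list(tp = sum(targets_p & has_a), fp = sum(targets_p & !has_a),
                 fn = sum(!targets_p & has_a), tn = sum(!targets_p & !has_a)),
            class = "confusion_counts")
}

#' PPV, prevalence, VAPPV and positive likelihood ratio from counts
#'
#' `PPV = TP / (TP + FP)`; `prevalence = (TP + FN) / N`;
#' `VAPPV = PPV - prevalence` (0 under independence);
#' `LR = TP * (FP + TN) / (FP * (TP + FN))` (1 under independence).
#' When `FP = 0` or `TP + FN = 0`, the Haldane-Anscombe continuity
#' correction (+0.5 on all four cells) is applied to the LR only. When
#' no drug targets the protein (`TP + FP = 0`), PPV and VAPPV are
#' undefined and returned as `NA` with `ppv_defined = FALSE`.
#'
#' @param counts A `confusion_counts` object (or list with `tp`, `fp`,
#'   `fn`, `tn`).
#' @return List of class `pair_metrics`: `ppv`, `prevalence`, `vappv`,
#'   `lr`, `ppv_defined`, `lr_corrected`.
#' @export
pair_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  n <- tp + fp + fn + tn
  stopifnot(n > 0, tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  prevalence <- (tp + fn) / n
  if (tp + fp == 0) {
    ppv <- NA_real_; vappv <- NA_real_; ppv_defined <- FALSE
  } else {
    ppv <- tp / (tp + fp); vappv <- ppv - prevalence; ppv_defined <- TRUE
  }
  corrected <- (fp == 0) || (tp + fn == 0)
  if (corrected) {
    lr <- ((tp + 0.5) * (fp + tn + 1)) / ((fp + 0.5) * (tp + fn + 1))
  } else {
    lr <- (tp * (fp + tn)) / (fp * (tp + fn))
  }
  structure(list(ppv = ppv, prevalence = prevalence, vappv = vappv, lr = lr,
                 ppv_defined = ppv_defined, lr_corrected = corrected),
            class = "pair_metrics")
}

# drug -> target-set list from filtered interaction records
#' Build a drug -> target-set map from interaction records
#'
#' @param drug_target Data frame with `source_id` (drug) and `target_id`
#'   (protein) columns, as returned by [read_interactions()].
#' @return Named list of character vectors.
#' @export
drug_target_map <- function(drug_target) {
  split(drug_target$target_id, drug_target$source_id)
}

#' Metrics for every (ADR, protein) pair passing support filters
#'
#' Vectorized [confusion_counts()] + [pair_metrics()] over the full
#' cross of label ADRs and candidate proteins, keeping pairs whose
#' protein is targeted by at least `min_support` labeled drugs and whose
#' ADR is carried by at least `min_support` drugs.
#'
#' @param drug_targets Named list: drug -> target proteins.
#' @param labels A [drug_adr_labels()] object.
#' @param proteins Candidate proteins (default: all targeted proteins).
#' @param min_support Minimum support on both margins (default 5).
#' @return Data frame `adr_pt`, `protein`, `tp`, `fp`, `fn`, `tn`,
#'   `ppv`, `prevalence`, `vappv`, `lr`, `ppv_defined`, `lr_corrected`.
#' @export
all_pair_metrics <- function(drug_targets, labels, proteins = NULL,
                             min_support = 5L) {
  stopifnot(inherits(labels, "drug_adr_labels"))
  drugs <- labels$drugs
  if (is.null(proteins))
    proteins <- sort(unique(unlist(drug_targets[drugs], use.names = FALSE)))
  n <- length(drugs)
  # drug x protein indicator
  tmat <- matrix(FALSE, n, length(proteins), dimnames = list(drugs, proteins))
  for (d in drugs) {
    hit <- intersect(drug_targets[[d]], proteins)
    if (length(hit) > 0L) tmat[d, hit] <- TRUE
  }
  amat <- labels$matrix
  m <- colSums(tmat)                       # drugs targeting each protein
  npos <- colSums(amat)                    # drugs carrying each ADR
  keep_p <- proteins[m >= min_support]
  keep_a <- labels$adrs[npos >= min_support]
  if (length(keep_p) == 0L || length(keep_a) == 0L)
    return(data.frame())
  tp <- t(amat[, keep_a, drop = FALSE]) %*% tmat[, keep_p, drop = FALSE]
  fp <- matrix(m[keep_p], length(keep_a), length(keep_p), byrow = TRUE) - tp
  fn <- matrix(npos[keep_a], length(keep_a), length(keep_p)) - tp
  tn <- n - tp - fp - fn
  grid <- expand.grid(adr_pt = keep_a, protein = keep_p,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tp <- as.vector(tp); fp <- as.vector(fp)
  fn <- as.vector(fn); tn <- as.vector(tn)
  prevalence <- (tp + fn) / n
  ppv_defined <- (tp + fp) > 0
  ppv <- ifelse(ppv_defined, tp / (tp + fp), NA_real_)
  corrected <- fp == 0 | (tp + fn) == 0
  lr <- ifelse(corrected,
               ((tp + 0.5) * (fp + tn + 1)) / ((fp + 0.5) * (tp + fn + 1)),
               (tp * (fp + tn)) / (fp * (tp + fn)))
  cbind(grid, data.frame(tp = tp, fp = fp, fn = fn, tn = tn, ppv = ppv,
                         prevalence = prevalence, vappv = ppv - prevalence,
                         lr = lr, ppv_defined = ppv_defined,
                         lr_corrected = corrected))
}

#' Mean VAPPV and LR of the top-k predicted proteins per ADR
#'
#' For each scored ADR, takes the [top_k()] proteins, drops pairs whose
#' protein is targeted by fewer than `min_support` labeled drugs or
#' whose ADR is carried by fewer than `min_support` drugs, and averages
#' VAPPV and LR over the surviving pairs (pairs with undefined PPV are
#' excluded from the VAPPV mean and counted). ADRs with no surviving
#' pair are reported as missing, never as zero.
#'
#' @param scores A `score_matrix`.
#' @param drug_targets Named list: drug -> target proteins.
#' @param labels A [drug_adr_labels()] object.
#' @param k Top proteins per ADR (default 50).
#' @param min_support Support filter on both margins (default 5).
#' @return List with `per_adr` (data frame `adr_pt`, `n_pairs`,
#'   `mean_vappv`, `mean_lr`), `missing_adrs`, `n_undefined_ppv`,
#'   `mean_vappv`, `mean_lr` (overall means over all surviving pairs).
#' @export
evaluate_top_k <- function(scores, drug_targets, labels, k = 50L,
                           min_support = 5L) {
  stopifnot(inherits(scores, "score_matrix"), inherits(labels, "drug_adr_labels"))
  adrs <- intersect(rownames(scores), labels$adrs)
  drugs <- labels$drugs
  target_counts <- table(unlist(lapply(drugs, function(d)
    unique(drug_targets[[d]])), use.names = FALSE))
  adr_support <- colSums(labels$matrix)

  per <- list(); missing <- character(); n_undef <- 0L
  pooled_vappv <- numeric(); pooled_lr <- numeric()
  for (a in adrs) {
    if (adr_support[[a]] < min_support) { missing <- c(missing, a); next }
    prots <- top_k(scores, a, k)
    prots <- prots[!is.na(target_counts[prots]) &
                     target_counts[prots] >= min_support]
    if (length(prots) == 0L) { missing <- c(missing, a); next }
    pm <- lapply(prots, function(p)
      pair_metrics(confusion_counts(a, p, drug_targets, labels)))
    vappv <- vapply(pm, `[[`, numeric(1L), "vappv")
    lr <- vapply(pm, `[[`, numeric(1L), "lr")
    n_undef <- n_undef + sum(is.na(vappv))
    pooled_vappv <- c(pooled_vappv, vappv[!is.na(vappv)])
    pooled_lr <- c(pooled_lr, lr)
    per[[a]] <- data.frame(adr_pt = a, n_pairs = length(prots),
                           mean_vappv = mean(vappv, na.rm = TRUE),
                           mean_lr = mean(lr), stringsAsFactors = FALSE)
  }
  list(per_adr = do.call(rbind, per), missing_adrs = missing,
       n_undefined_ppv = n_undef,
       mean_vappv = if (length(pooled_vappv)) mean(pooled_vappv) else NA_real_,
       mean_lr = if (length(pooled_lr)) mean(pooled_lr) else NA_real_)
}

#' Percentile-rank recovery of benchmark ADR-protein relations
#'
#' For every mappable benchmark pair, looks up the protein's percentile
#' in the ADR's ranking and summarizes the distribution: histogram in 5%
#' bins and the fractions recovered in the top 5% and top 20%.
#'
#' @param scores A `score_matrix`.
#' @param bench Data frame `adr_pt`, `protein` of known relations.
#' @return List with `pairs` (data frame `adr_pt`, `protein`,
#'   `percentile`, `bin`), `histogram` (counts per 5% bin),
#'   `frac_top5`, `frac_top20`, `n_unmapped`.
#' @export
benchmark_recovery <- function(scores, bench) {
  stopifnot(inherits(scores, "score_matrix"),
            all(c("adr_pt", "protein") %in% names(bench)))
  mappable <- bench$adr_pt %in% rownames(scores) &
    bench$protein %in% colnames(scores)
  n_unmapped <- sum(!mappable)
  bench <- bench[mappable, , drop = FALSE]
  if (nrow(bench) == 0L) stop("no benchmark pair maps onto the score matrix")
  pct <- numeric(nrow(bench))
  for (a in unique(bench$adr_pt)) {
    rl <- rank_proteins(scores, a)
    idx <- bench$adr_pt == a
    pct[idx] <- rl$percentile[match(bench$protein[idx], rl$protein)]
  }
  bins <- cut(pct, breaks = seq(0, 100, by = 5), include.lowest = TRUE)
  list(pairs = data.frame(adr_pt = bench$adr_pt, protein = bench$protein,
                          percentile = pct, bin = as.character(bins),
                          stringsAsFactors = FALSE),
       histogram = table(bins),
       frac_top5 = mean(pct <= 5),
       frac_top20 = mean(pct <= 20),
       n_unmapped = n_unmapped)
}

#' Balanced negative-sampling evaluation on a benchmark set
#'
#' Positives are the benchmark pairs; the negative pool is every other
#' (ADR, protein) combination over the benchmark's ADRs and proteins.
#' Each resample draws as many negatives as there are positives and
#' computes AUROC and average precision of the score matrix on the
#' balanced set; the procedure is repeated `n_resamples` times.
#'
#' @param scores A `score_matrix`.
#' @param bench Data frame `adr_pt`, `protein`.
#' @param n_resamples Number of negative resamples (default 1000).
#' @param seed Seed for the resampling.
#' @return List with numeric vectors `auroc`, `ap` (length
#'   `n_resamples`) and their means `mean_auroc`, `mean_ap`.
#' @export
balanced_benchmark_eval <- function(scores, bench, n_resamples = 1000L,
                                    seed = 1L) {
  stopifnot(inherits(scores, "score_matrix"))
  mappable <- bench$adr_pt %in% rownames(scores) &
    bench$protein %in% colnames(scores)
  bench <- unique(bench[mappable, c("adr_pt", "protein"), drop = FALSE])
  if (nrow(bench) == 0L) stop("no benchmark pair maps onto the score matrix")
  adrs <- sort(unique(bench$adr_pt))
  prots <- sort(unique(bench$protein))
  pool <- expand.grid(adr_pt = adrs, protein = prots,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pos_key <- paste(bench$adr_pt, bench$protein, sep = "\r")
  neg <- pool[!(paste(pool$adr_pt, pool$protein, sep = "\r") %in% pos_key), ,
              drop = FALSE]
  n_pos <- nrow(bench)
  if (nrow(neg) < n_pos)
    stop("negative pool smaller than the positive set")
  pos_scores <- scores[cbind(bench$adr_pt, bench$protein)]
  neg_scores_all <- scores[cbind(neg$adr_pt, neg$protein)]

  local_seed(seed)
  au <- numeric(n_resamples); ap <- numeric(n_resamples)
  for (i in seq_len(n_resamples)) {
    ns <- neg_scores_all[sample.int(length(neg_scores_all), n_pos)]
    s <- c(pos_scores, ns)
    y <- rep(c(1L, 0L), each = n_pos)
    au[i] <- auroc(s, y)
    ap[i] <- average_precision(s, y)
  }
  list(auroc = au, ap = ap, mean_auroc = mean(au), mean_ap = mean(ap))
}

#' Jaccard index of two sets
#'
#' @param a,b Vectors treated as sets; their union must be non-empty.
#' @return `|a n b| / |a u b|`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) stop("jaccard undefined for two empty sets")
  length(intersect(a, b)) / u
}

#' Cosine similarity of two vectors
#'
#' @param u,v Numeric vectors of equal length, both non-zero.
#' @return Cosine similarity in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity undefined for a zero vector")
  sum(u * v) / (nu * nv)
}

#' Correlation between drug ADR-profile similarity and embedding similarity
#'
#' Over all drug pairs, compares the Jaccard index of the two drugs' ADR
#' sets with the cosine similarity of their embedding vectors, and
#' summarizes the relationship with similarity bins (boxplot-ready) and
#' a Spearman rank correlation.
#'
#' @param drug_embeddings Embedding matrix restricted to drugs.
#' @param labels A [drug_adr_labels()] object.
#' @param bin_width Width of the Jaccard bins (default 0.1).
#' @return List with `pairs` (data frame `drug_a`, `drug_b`,
#'   `adr_jaccard`, `embedding_cosine`, `bin`), `bin_summary` and
#'   `spearman`.
#' @export
drug_similarity_correlation <- function(drug_embeddings, labels,
                                        bin_width = 0.1) {
  stopifnot(inherits(labels, "drug_adr_labels"))
  drugs <- intersect(labels$drugs, rownames(drug_embeddings))
  if (length(drugs) < 2L) stop("need at least two drugs with embeddings")
  x <- drug_embeddings[drugs, , drop = FALSE]
  xn <- x / sqrt(rowSums(x^2))
  cos_mat <- xn %*% t(xn)
  amat <- labels$matrix[drugs, , drop = FALSE]
  inter <- amat %*% t(amat)
  sizes <- rowSums(amat)
  un <- outer(sizes, sizes, "+") - inter
  jac_mat <- inter / un
  ut <- which(upper.tri(cos_mat), arr.ind = TRUE)
  pairs <- data.frame(drug_a = drugs[ut[, 1L]], drug_b = drugs[ut[, 2L]],
                      adr_jaccard = jac_mat[ut],
                      embedding_cosine = cos_mat[ut],
                      stringsAsFactors = FALSE)
  pairs$bin <- as.character(cut(pairs$adr_jaccard,
                                breaks = seq(0, 1, by = bin_width),
                                include.lowest = TRUE))
  bin_summary <- stats::aggregate(embedding_cosine ~ bin, pairs,
                                  function(v) c(n = length(v), mean = mean(v),
                                                median = stats::median(v)))
  rho <- stats::cor(pairs$adr_jaccard, pairs$embedding_cosine,
                    method = "spearman")
  list(pairs = pairs, bin_summary = bin_summary, spearman = rho)
}

#' Select the confidence-score threshold by drug-pair similarity agreement
#'
#' For each candidate threshold, filters the (unfiltered) drug-target
#' records at that score, forms per-drug target sets, and computes the
#' Pearson correlation over drug pairs between Jaccard similarity of ADR
#' sets and Jaccard similarity of target sets. Returns the threshold
#' maximizing the correlation together with the whole table. Thresholds
#' leaving fewer than two drugs with targets are reported as `NA`.
#'
#' @param drug_target Data frame `source_id`, `target_id`, `score`
#'   (unfiltered records).
#' @param labels A [drug_adr_labels()] object.
#' @param thresholds Integer vector of candidate score thresholds.
#' @return List with `threshold` (argmax) and `table` (data frame
#'   `threshold`, `n_drugs`, `pearson`).
#' @export
select_confidence_threshold <- function(drug_target, labels, thresholds) {
  stopifnot(length(thresholds) >= 2L, inherits(labels, "drug_adr_labels"))
  adr_sets <- apply(labels$matrix, 1L, function(r) labels$adrs[r],
                    simplify = FALSE)
  rows <- lapply(thresholds, function(th) {
    dt <- drug_target[drug_target$score >= th, , drop = FALSE]
    tmap <- split(dt$target_id, dt$source_id)
    drugs <- intersect(labels$drugs, names(tmap))
    if (length(drugs) < 2L)
      return(data.frame(threshold = th, n_drugs = length(drugs),
                        pearson = NA_real_))
    pr <- utils::combn(drugs, 2L)
    ja <- vapply(seq_len(ncol(pr)), function(i)
      jaccard(adr_sets[[pr[1L, i]]], adr_sets[[pr[2L, i]]]), numeric(1L))
    jt <- vapply(seq_len(ncol(pr)), function(i)
      jaccard(tmap[[pr[1L, i]]], tmap[[pr[2L, i]]]), numeric(1L))
    r <- if (stats::sd(ja) == 0 || stats::sd(jt) == 0) NA_real_ else
      stats::cor(ja, jt, method = "pearson")
    data.frame(threshold = th, n_drugs = length(drugs), pearson = r)
  })
  tab <- do.call(rbind, rows)
  if (all(is.na(tab$pearson))) stop("no usable threshold")
  best <- tab$threshold[which.max(tab$pearson)]
  list(threshold = best, table = tab)
}

#' Within-group similarity of ADR score vectors
#'
#' Generalized grouping analysis (e.g. disease-category terms): for each
#' group label, the mean cosine similarity of protein-score vectors over
#' ADR pairs sharing the label is compared against a baseline of ADR
#' pairs sharing no label, with a Welch two-sample t-test per label and
#' Benjamini-Hochberg adjustment across labels.
#'
#' @param scores A `score_matrix`.
#' @param grouping Named list: ADR identifier -> character vector of
#'   group labels (ADRs absent from the list carry no label).
#' @return List with `per_label` (data frame `label`, `n_pairs`,
#'   `mean_cosine`, `p_value`, `p_adjusted`), `baseline_mean`,
#'   `baseline_n`.
#' @export
grouped_score_similarity <- function(scores, grouping) {
  stopifnot(inherits(scores, "score_matrix"))
  adrs <- rownames(scores)
  x <- scores / sqrt(rowSums(scores^2))
  cos_mat <- x %*% t(x)
  labs <- lapply(adrs, function(a) unique(grouping[[a]]))
  names(labs) <- adrs
  ut <- which(upper.tri(cos_mat), arr.ind = TRUE)
  shared <- vapply(seq_len(nrow(ut)), function(i)
    length(intersect(labs[[ut[i, 1L]]], labs[[ut[i, 2L]]])), integer(1L))
  baseline <- cos_mat[ut][shared == 0L]
  if (length(baseline) == 0L)
    stop("empty baseline: every ADR pair shares a label")
  all_labels <- sort(unique(unlist(labs, use.names = FALSE)))
  rows <- lapply(all_labels, function(lb) {
    has <- vapply(seq_len(nrow(ut)), function(i)
      lb %in% labs[[ut[i, 1L]]] && lb %in% labs[[ut[i, 2L]]], logical(1L))
    v <- cos_mat[ut][has]
    if (length(v) < 2L) return(NULL)
    p <- tryCatch(stats::t.test(v, baseline)$p.value, error = function(e) NA_real_)
    data.frame(label = lb, n_pairs = length(v), mean_cosine = mean(v),
               p_value = p, stringsAsFactors = FALSE)
  })
  per_label <- do.call(rbind, rows)
  if (!is.null(per_label))
    per_label$p_adjusted <- stats::p.adjust(per_label$p_value, method = "BH")
  list(per_label = per_label, baseline_mean = mean(baseline),
       baseline_n = length(baseline))
}
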