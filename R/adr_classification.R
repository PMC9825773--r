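#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a uniformly random
#' positive outscores a uniformly random negative, with ties counted as
#' one half.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1 or logical), same length.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("auroc undefined: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Average precision
#'
#' Step-sum over descending-score thresholds:
#' `AP = sum_n (R_n - R_{n-1}) * P_n`, the threshold-weighted mean of
#' precision (no interpolation). Tied scores enter at a single threshold.
#'
#' @inheritParams auroc
#' @return AP in `(0, 1]`.
#' @export
average_precision <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels)
  if (n_pos == 0L) stop("average_precision undefined: no positive labels")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  cum_tp <- cumsum(y)
  cum_n <- seq_along(y)
  # thresholds sit at the last index of each tied-score block
  last_of_block <- c(s[-length(s)] != s[-1L], TRUE)
  tp <- cum_tp[last_of_block]
  n <- cum_n[last_of_block]
  prec <- tp / n
  rec <- tp / n_pos
  sum((rec - c(0, rec[-length(rec)])) * prec)
}

#' Train one ridge-logistic classifier per ADR (binary relevance)
#'
#' Each ADR column of the label matrix is fit independently with
#' L2-regularized logistic regression on the drug embedding rows. The
#' regularization follows the inverse-strength convention `C` (smaller
#' `C`, stronger penalty): the effective glmnet lambda is `1 / (n * C)`.
#' ADR columns with fewer than two positive or two negative drugs are
#' skipped (the fit is not identifiable for the solver) and reported in
#' the `skipped` field.
#'
#' @param drug_embeddings Embedding matrix restricted to drug rows
#'   (rownames are drug identifiers).
#' @param labels A [drug_adr_labels()] object; every labeled drug must
#'   have an embedding row.
#' @param inverse_reg_strength Inverse regularization strength `C`
#'   (default 0.1).
#' @return An object of class `adr_classifier_bundle`: list with
#'   `adr_ids`, `weights` (ADR-by-dimension matrix), `intercepts`,
#'   `inverse_reg_strength` and `skipped`.
#' @export
train_adr_classifiers <- function(drug_embeddings, labels,
                                  inverse_reg_strength = 0.1) {
  stopifnot(inherits(labels, "drug_adr_labels"), inverse_reg_strength > 0)
  missing <- setdiff(labels$drugs, rownames(drug_embeddings))
  if (length(missing) > 0L)
    stop("labeled drugs without embedding rows: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  x <- drug_embeddings[labels$drugs, , drop = FALSE]
  fit <- fit_ridge_many(x, labels$matrix, inverse_reg_strength)
  structure(list(adr_ids = fit$adr_ids, weights = fit$weights,
                 intercepts = fit$intercepts,
                 inverse_reg_strength = inverse_reg_strength,
                 skipped = fit$skipped),
            class = "adr_classifier_bundle")
}

fit_ridge_many <- function(x, y_matrix, C) {
  n <- nrow(x)
  lambda <- 1 / (n * C)
  adrs <- colnames(y_matrix)
  pos <- colSums(y_matrix)
  # the solver needs at least two drugs in each class to be identifiable
  trainable <- pos >= 2L & pos <= n - 2L
  keep <- adrs[trainable]
  w <- matrix(NA_real_, length(keep), ncol(x),
              dimnames = list(keep, colnames(x)))
  b <- stats::setNames(numeric(length(keep)), keep)
  # descending path ending at the target lambda stabilizes the fit
  path <- lambda * c(100, 10, 1)
  for (a in keep) {
    # glmnet warns on rare-but-valid small classes; rarity is expected here
    fit <- withCallingHandlers(
      glmnet::glmnet(x, as.numeric(y_matrix[, a]), family = "binomial",
                     alpha = 0, lambda = path, standardize = FALSE,
                     thresh = 1e-10),
      warning = function(w) {
        if (grepl("fewer than 8", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    cf <- as.numeric(stats::coef(fit, s = lambda))
    b[[a]] <- cf[1L]
    w[a, ] <- cf[-1L]
  }
  stopifnot(all(is.finite(w)), all(is.finite(b)))
  list(adr_ids = keep, weights = w, intercepts = b,
       skipped = adrs[!trainable])
}

#' Predict ADR probability for an embedding vector
#'
#' Logistic of the affine score of the ADR's classifier.
#'
#' @param bundle An `adr_classifier_bundle`.
#' @param adr ADR identifier (must be trained).
#' @param vector A numeric vector of length `d`, or a matrix with `d`
#'   columns for several inputs at once.
#' @return Probability (or vector of probabilities) in `[0, 1]`.
#' @export
predict_proba <- function(bundle, adr, vector) {
  stopifnot(inherits(bundle, "adr_classifier_bundle"))
  if (!adr %in% bundle$adr_ids) stop("unknown or untrained ADR: ", adr)
  if (is.null(dim(vector))) vector <- matrix(vector, nrow = 1L)
  if (ncol(vector) != ncol(bundle$weights))
    stop("dimension mismatch: expected ", ncol(bundle$weights), " features")
  eta <- drop(vector %*% bundle$weights[adr, ] + bundle$intercepts[[adr]])
  stats::plogis(eta)
}

#' Cross-validate the per-ADR classifiers
#'
#' Drugs are partitioned once into `k` folds shared by all ADRs
#' (unstratified drug-level split). Per ADR, out-of-fold predicted
#' probabilities are pooled over folds and a single AUROC and average
#' precision are computed. ADRs with fewer than `min_drugs` positive
#' drugs are excluded from the report, as are ADRs whose pooled
#' out-of-fold labels are single-class.
#'
#' @param drug_embeddings Embedding matrix restricted to drugs.
#' @param labels A [drug_adr_labels()] object.
#' @param k Number of folds (default 10).
#' @param min_drugs Minimum positive drugs for an ADR to be reported
#'   (default 10).
#' @param inverse_reg_strength Passed to the per-fold fits.
#' @param seed Seed for the fold assignment.
#' @return An object of class `cv_report`: list with `per_adr` (data
#'   frame `adr_pt`, `n_drugs`, `auroc`, `ap`), `macro_auroc`,
#'   `macro_ap`, `folds` (named fold index per drug).
#' @export
cross_validate <- function(drug_embeddings, labels, k = 10L, min_drugs = 10L,
                           inverse_reg_strength = 0.1, seed = 1L) {
  stopifnot(inherits(labels, "drug_adr_labels"))
  if (k < 2L) stop("k must be at least 2")
  drugs <- labels$drugs
  if (length(drugs) < k) stop("fewer drugs than folds")
  x <- drug_embeddings[drugs, , drop = FALSE]
  y <- labels$matrix

  local_seed(seed)
  folds <- stats::setNames(sample(rep_len(seq_len(k), length(drugs))), drugs)

  pred <- matrix(NA_real_, length(drugs), ncol(y), dimnames = dimnames(y))
  for (f in seq_len(k)) {
    test <- folds == f
    fit <- fit_ridge_many(x[!test, , drop = FALSE], y[!test, , drop = FALSE],
                          inverse_reg_strength)
    if (length(fit$adr_ids) == 0L) next
    eta <- x[test, , drop = FALSE] %*% t(fit$weights[fit$adr_ids, , drop = FALSE])
    eta <- sweep(eta, 2L, -fit$intercepts[fit$adr_ids], "-")
    pred[test, fit$adr_ids] <- stats::plogis(eta)
  }

  eligible <- colnames(y)[colSums(y) >= min_drugs]
  rows <- lapply(eligible, function(a) {
    ok <- !is.na(pred[, a])
    lab <- y[ok, a]
    if (length(unique(lab)) < 2L) return(NULL)
    data.frame(adr_pt = a, n_drugs = sum(y[, a]),
               auroc = auroc(pred[ok, a], lab),
               ap = average_precision(pred[ok, a], lab),
               stringsAsFactors = FALSE)
  })
  per_adr <- do.call(rbind, rows)
  if (is.null(per_adr))
    stop("no ADR met the minimum-drug rule with both classes present")
  structure(list(per_adr = per_adr,
                 macro_auroc = mean(per_adr$auroc),
                 macro_ap = mean(per_adr$ap),
                 folds = folds),
            class = "cv_report")
}

#' Write a cross-validation report
#'
#' Per-ADR TSV (`adr_pt`, `n_drugs`, `auroc`, `ap`) plus a JSON summary
#' with the macro averages.
#'
#' @param report A `cv_report`.
#' @param tsv_path,json_path Output files.
#' @export
write_cv_report <- function(report, tsv_path, json_path) {
  stopifnot(inherits(report, "cv_report"))
  write_tsv(report$per_adr, tsv_path)
  jsonlite::write_json(list(macro_auroc = report$macro_auroc,
                            macro_ap = report$macro_ap,
                            n_adrs = nrow(report$per_adr)),
                       json_path, auto_unbox = TRUE, digits = NA)
}

#' Grid-search walk parameters by downstream CV performance
#'
#' Runs the full embed / train / cross-validate loop for every `(p, q)`
#' grid point and returns the pair maximizing macro AUROC. Ties are
#' broken toward `(1, 1)`, then lexicographically by `(p, q)`.
#'
#' @param net A `hetero_network`.
#' @param labels A [drug_adr_labels()] object (will be restricted to
#'   network drugs).
#' @param p_grid,q_grid Numeric vectors of candidate values.
#' @param wparams,eparams Base walk / embedding parameters (their `p`,
#'   `q` are overridden per grid point).
#' @param k,min_drugs,inverse_reg_strength,seed CV settings.
#' @return List with `p`, `q` and the full `table` of grid scores.
#' @export
optimize_walk_params <- function(net, labels, p_grid, q_grid,
                                 wparams = walk_params(),
                                 eparams = embedding_params(),
                                 k = 10L, min_drugs = 10L,
                                 inverse_reg_strength = 0.1, seed = 1L) {
  stopifnot(length(p_grid) > 0L, length(q_grid) > 0L)
  grid <- expand.grid(p = p_grid, q = q_grid, KEEP.OUT.ATTRS = FALSE)
  drugs <- node_ids(net, "drug")
  lab <- subset_labels(labels, drugs)
  grid$macro_auroc <- vapply(seq_len(nrow(grid)), function(i) {
    wp <- wparams
    wp$p <- grid$p[i]
    wp$q <- grid$q[i]
    emb <- train_embeddings(generate_walks(net, wp), eparams)
    cv <- cross_validate(emb[intersect(rownames(emb), drugs), , drop = FALSE],
                         lab, k = k, min_drugs = min_drugs,
                         inverse_reg_strength = inverse_reg_strength,
                         seed = seed)
    cv$macro_auroc
  }, numeric(1L))
  pref <- order(-grid$macro_auroc,
                !(grid$p == 1 & grid$q == 1), grid$p, grid$q)
  best <- grid[pref[1L], ]
  list(p = best$p, q = best$q, table = grid)
}
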