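#' Run configuration for the full pipeline
#'
#' Collects every tunable of the pipeline with the method's published
#' defaults: confidence threshold 700, inverse regularization strength
#' 0.1, 10-fold cross-validation, 10-drug minimum per reported ADR,
#' top-50 scoring, 5-drug support filter, 1000 negative resamples. Stage
#' seeds are derived from the single global seed with fixed offsets
#' (walks +1, embedding +2, cross-validation +3, resampling +4) so
#' stages can be rerun independently yet reproducibly.
#'
#' @param ppi_path,drug_target_path,drug_adr_path Input TSV paths.
#' @param benchmark_path Optional benchmark TSV (or `NULL`).
#' @param out_dir Output directory.
#' @param threshold Confidence-score filter (default 700).
#' @param wparams,eparams Walk / embedding parameter objects (their
#'   seeds are overridden by the derived stage seeds).
#' @param inverse_reg_strength Classifier regularization (default 0.1).
#' @param cv_folds,min_drugs,top_k,min_support,n_resamples Evaluation
#'   settings.
#' @param seed Global seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(ppi_path, drug_target_path, drug_adr_path,
                       benchmark_path = NULL, out_dir = tempfile("adrnet_run_"),
                       threshold = 700L, wparams = walk_params(),
                       eparams = embedding_params(),
                       inverse_reg_strength = 0.1, cv_folds = 10L,
                       min_drugs = 10L, top_k = 50L, min_support = 5L,
                       n_resamples = 1000L, seed = 1L) {
  structure(list(ppi_path = ppi_path, drug_target_path = drug_target_path,
                 drug_adr_path = drug_adr_path,
                 benchmark_path = benchmark_path, out_dir = out_dir,
                 threshold = as.integer(threshold), wparams = wparams,
                 eparams = eparams,
                 inverse_reg_strength = inverse_reg_strength,
                 cv_folds = as.integer(cv_folds),
                 min_drugs = as.integer(min_drugs),
                 top_k = as.integer(top_k),
                 min_support = as.integer(min_support),
                 n_resamples = as.integer(n_resamples),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Validate pipeline inputs
#'
#' Dialect checks and identifier-overlap summary: drugs with targets
#' intersected with drugs with ADRs, and targeted proteins present in
#' the PPI table. Empty intersections are fatal for drugs (nothing
#' would be trainable) and warnings otherwise.
#'
#' @param config A [run_config()].
#' @return List with `n_ppi`, `n_drug_target`, `n_drug_adr`,
#'   `drugs_overlap`, `proteins_overlap`, `warnings` (character vector).
#' @export
validate_inputs <- function(config) {
  stopifnot(inherits(config, "run_config"))
  ppi <- read_interactions(config$ppi_path, threshold = 0L)
  dt <- read_interactions(config$drug_target_path, threshold = 0L)
  da <- read_drug_adr(config$drug_adr_path)
  warnings <- character()
  drugs_overlap <- length(intersect(unique(dt$source_id), unique(da$drug)))
  prot_overlap <- length(intersect(unique(dt$target_id),
                                   unique(c(ppi$source_id, ppi$target_id))))
  if (drugs_overlap == 0L)
    stop("no overlap between drugs with targets and drugs with ADRs (count 0)")
  if (prot_overlap == 0L)
    warnings <- c(warnings, "no targeted protein appears in the PPI table")
  list(n_ppi = nrow(ppi), n_drug_target = nrow(dt), n_drug_adr = nrow(da),
       drugs_overlap = drugs_overlap, proteins_overlap = prot_overlap,
       warnings = warnings)
}

#' Run the full pipeline
#'
#' build -> embed -> train -> score -> evaluate. Writes
#' `network_stats.json`, `embeddings.txt`, `cv_report.tsv` /
#' `cv_summary.json`, `scores.tsv`, `metrics.json` and, when a benchmark
#' is supplied, `recovery.tsv` and `resamples.tsv` under
#' `config$out_dir`, together with a `manifest.json` recording the
#' effective parameters and input checksums.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory artifacts: `net`,
#'   `labels`, `embeddings`, `cv`, `bundle`, `scores`, `topk`,
#'   `recovery`, `balanced`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  ppi <- read_interactions(config$ppi_path, config$threshold)
  dt <- read_interactions(config$drug_target_path, config$threshold)
  labels_all <- drug_adr_labels(read_drug_adr(config$drug_adr_path))
  net <- build_network(ppi, dt, labels_all)
  stats <- network_stats(net)
  jsonlite::write_json(stats, file.path(config$out_dir, "network_stats.json"),
                       auto_unbox = TRUE, digits = NA)

  wp <- config$wparams; wp$seed <- config$seed + 1L
  ep <- config$eparams; ep$seed <- config$seed + 2L
  walks <- generate_walks(net, wp)
  emb <- train_embeddings(walks, ep)
  write_embeddings(emb, file.path(config$out_dir, "embeddings.txt"))

  drugs <- intersect(node_ids(net, "drug"), rownames(emb))
  labels <- subset_labels(labels_all, drugs)
  demb <- emb[labels$drugs, , drop = FALSE]

  cv <- cross_validate(demb, labels, k = config$cv_folds,
                       min_drugs = config$min_drugs,
                       inverse_reg_strength = config$inverse_reg_strength,
                       seed = config$seed + 3L)
  write_cv_report(cv, file.path(config$out_dir, "cv_report.tsv"),
                  file.path(config$out_dir, "cv_summary.json"))

  bundle <- train_adr_classifiers(demb, labels, config$inverse_reg_strength)
  scores <- score_proteins(bundle, emb, net)
  write_scores(scores, file.path(config$out_dir, "scores.tsv"))

  tmap <- drug_target_map(dt)
  topk <- evaluate_top_k(scores, tmap, labels, k = min(config$top_k, ncol(scores)),
                         min_support = config$min_support)
  jsonlite::write_json(
    list(macro_auroc = cv$macro_auroc, macro_ap = cv$macro_ap,
         mean_vappv = topk$mean_vappv, mean_lr = topk$mean_lr,
         n_missing_adrs = length(topk$missing_adrs),
         n_undefined_ppv = topk$n_undefined_ppv),
    file.path(config$out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)

  recovery <- NULL; balanced <- NULL
  if (!is.null(config$benchmark_path)) {
    bench <- read_benchmark(config$benchmark_path)
    recovery <- benchmark_recovery(scores, bench)
    write_tsv(recovery$pairs, file.path(config$out_dir, "recovery.tsv"))
    balanced <- balanced_benchmark_eval(scores, bench,
                                        n_resamples = config$n_resamples,
                                        seed = config$seed + 4L)
    write_tsv(data.frame(resample = seq_along(balanced$auroc),
                         auroc = balanced$auroc, ap = balanced$ap),
              file.path(config$out_dir, "resamples.tsv"))
  }

  manifest <- list(
    inputs = lapply(list(ppi = config$ppi_path,
                         drug_target = config$drug_target_path,
                         drug_adr = config$drug_adr_path),
                    function(p) list(path = p, md5 = unname(tools::md5sum(p)))),
    threshold = config$threshold, walk = unclass(config$wparams),
    embedding = unclass(config$eparams),
    inverse_reg_strength = config$inverse_reg_strength,
    cv_folds = config$cv_folds, min_drugs = config$min_drugs,
    top_k = config$top_k, min_support = config$min_support,
    n_resamples = config$n_resamples, seed = config$seed,
    network = stats)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(net = net, labels = labels, embeddings = emb, cv = cv,
                 bundle = bundle, scores = scores, topk = topk,
                 recovery = recovery, balanced = balanced))
}
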