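#' Configuration for a synthetic drug/protein/ADR world
#'
#' Defines a fully synthetic "world" whose interaction tables mimic the
#' dialects of the public databases the pipeline reads: a modular
#' protein-protein interaction (PPI) graph drawn from a stochastic block
#' model, drugs with sampled target sets, and adverse-drug-reaction (ADR)
#' labels causally driven by planted protein modules. Setting
#' `theta_hi == theta_lo` yields a *null* world in which ADR assignment is
#' independent of drug targeting.
#'
#' @param n_proteins Number of proteins.
#' @param n_modules Number of protein modules (equal-size blocks; the
#'   remainder goes to the last block).
#' @param n_drugs Number of drugs.
#' @param n_adrs Number of ADR terms.
#' @param p_in Within-module PPI edge probability.
#' @param p_out Between-module PPI edge probability.
#' @param n_targets_per_drug Targets sampled per drug. Focused drugs whose
#'   module is smaller draw `min(n_targets_per_drug, module size)`.
#' @param focus_prob Probability a drug is module-focused (draws all its
#'   targets from one random module) rather than targeting uniformly.
#' @param theta_hi ADR probability for a drug that targets at least one
#'   protein of the ADR's causal module.
#' @param theta_lo Background ADR probability for unexposed drugs.
#' @param low_score_frac Fraction of PPI and drug-target records whose
#'   confidence score is sampled *below* `score_threshold` (default 0, so
#'   no record is lost to downstream filtering).
#' @param score_threshold Confidence-score filter the downstream reader
#'   applies; emitted scores are uniform on `[score_threshold, 1000]`
#'   unless assigned to the low-score fraction.
#' @param seed Integer seed; the whole world is reproducible from it.
#'
#' @return An object of class `adr_world_config`.
#' @export
world_config <- function(n_proteins = 200L, n_modules = 10L, n_drugs = 100L,
                         n_adrs = 20L, p_in = 0.3, p_out = 0.01,
                         n_targets_per_drug = 10L, focus_prob = 0.7,
                         theta_hi = 0.8, theta_lo = 0.05,
                         low_score_frac = 0, score_threshold = 700L,
                         seed = 1L) {
  cfg <- list(
    n_proteins = as.integer(n_proteins), n_modules = as.integer(n_modules),
    n_drugs = as.integer(n_drugs), n_adrs = as.integer(n_adrs),
    p_in = p_in, p_out = p_out,
    n_targets_per_drug = as.integer(n_targets_per_drug),
    focus_prob = focus_prob, theta_hi = theta_hi, theta_lo = theta_lo,
    low_score_frac = low_score_frac,
    score_threshold = as.integer(score_threshold), seed = as.integer(seed)
  )
  class(cfg) <- "adr_world_config"
  validate_world_config(cfg)
  cfg
}

validate_world_config <- function(cfg) {
  stopifnot(cfg$n_proteins >= cfg$n_modules, cfg$n_modules >= 1L,
            cfg$n_drugs >= 1L, cfg$n_adrs >= 1L,
            cfg$p_in >= 0, cfg$p_in <= 1, cfg$p_out >= 0, cfg$p_out <= 1,
            cfg$theta_hi >= cfg$theta_lo, cfg$theta_lo >= 0, cfg$theta_hi <= 1,
            cfg$focus_prob >= 0, cfg$focus_prob <= 1,
            cfg$low_score_frac >= 0, cfg$low_score_frac <= 1,
            cfg$n_targets_per_drug >= 1L)
  # expected PPI degree must be positive or proteins would be isolated
  blk <- cfg$n_proteins / cfg$n_modules
  exp_deg <- cfg$p_in * (blk - 1) + cfg$p_out * (cfg$n_proteins - blk)
  if (exp_deg <= 0)
    stop("expected PPI degree is 0: increase p_in/p_out or module size")
  invisible(cfg)
}

#' Generate a synthetic world
#'
#' Draws the PPI graph from a stochastic block model with within-module
#' probability `p_in` and between-module probability `p_out`; assigns each
#' ADR one causal module round-robin; samples each drug's target set (from
#' a single random module with probability `focus_prob`, else uniformly
#' over proteins with at least one PPI edge); and assigns drug-ADR pairs
#' with probability `theta_hi` when the drug targets the ADR's causal
#' module and `theta_lo` otherwise. Confidence scores are uniform integers
#' on `[score_threshold, 1000]` (or `[0, score_threshold)` for the
#' low-score fraction), so default worlds survive threshold filtering
#' losslessly.
#'
#' @param config An [world_config()] object.
#' @return An object of class `adr_world`: a list with data frames `ppi`
#'   (`protein_a`, `protein_b`, `combined_score`), `drug_target`
#'   (`chemical`, `protein`, `combined_score`), `drug_adr` (`drug`,
#'   `adr_pt`), `truth` (`adr_pt`, `protein`), the integer map
#'   `module_of` (named by protein), `causal_module` (named by ADR) and
#'   the generating `config`.
#' @export
generate_world <- function(config) {
  validate_world_config(config)
  local_seed(config$seed)

  proteins <- sprintf("P%04d", seq_len(config$n_proteins))
  drugs <- sprintf("D%04d", seq_len(config$n_drugs))
  adrs <- sprintf("ADR%03d", seq_len(config$n_adrs))

  # equal-size modules, remainder to the last block
  blk <- config$n_proteins %/% config$n_modules
  module_of <- pmin(((seq_len(config$n_proteins) - 1L) %/% blk) + 1L,
                    config$n_modules)
  names(module_of) <- proteins

  ppi <- sbm_edges(config$n_proteins, module_of, config$p_in, config$p_out)
  ppi_df <- data.frame(
    protein_a = proteins[ppi[, 1L]],
    protein_b = proteins[ppi[, 2L]],
    combined_score = sample_scores(nrow(ppi), config),
    stringsAsFactors = FALSE
  )

  connected <- sort(unique(c(ppi[, 1L], ppi[, 2L])))
  if (length(connected) == 0L) stop("generated PPI graph has no edges")
  members <- split(connected, module_of[connected])

  causal_module <- ((seq_len(config$n_adrs) - 1L) %% config$n_modules) + 1L
  names(causal_module) <- adrs

  # drug target sets
  target_sets <- vector("list", config$n_drugs)
  focused <- stats::runif(config$n_drugs) < config$focus_prob
  for (d in seq_len(config$n_drugs)) {
    pool <- if (focused[d]) {
      members[[sample.int(length(members), 1L)]]
    } else {
      connected
    }
    k <- min(config$n_targets_per_drug, length(pool))
    target_sets[[d]] <- sort(pool[sample.int(length(pool), k)])
  }
  drug_target_df <- data.frame(
    chemical = rep(drugs, lengths(target_sets)),
    protein = proteins[unlist(target_sets)],
    combined_score = sample_scores(sum(lengths(target_sets)), config),
    stringsAsFactors = FALSE
  )

  # drug m targets module j?
  hits_module <- vapply(seq_len(config$n_drugs), function(d) {
    tabulate(module_of[target_sets[[d]]], nbins = config$n_modules) > 0L
  }, logical(config$n_modules))
  if (is.null(dim(hits_module))) dim(hits_module) <- c(config$n_modules, config$n_drugs)

  exposed <- hits_module[causal_module, , drop = FALSE]   # adr x drug
  theta <- ifelse(exposed, config$theta_hi, config$theta_lo)
  has_adr <- matrix(stats::runif(length(theta)) < theta,
                    nrow = config$n_adrs,
                    dimnames = list(adrs, drugs))
  idx <- which(has_adr, arr.ind = TRUE)
  drug_adr_df <- data.frame(
    drug = drugs[idx[, 2L]],
    adr_pt = adrs[idx[, 1L]],
    stringsAsFactors = FALSE
  )
  drug_adr_df <- drug_adr_df[order(drug_adr_df$drug, drug_adr_df$adr_pt), ,
                             drop = FALSE]
  rownames(drug_adr_df) <- NULL

  # ground truth: each ADR's causal-module proteins (those in the PPI graph)
  truth <- do.call(rbind, lapply(adrs, function(a) {
    mem <- members[[as.character(causal_module[[a]])]]
    if (is.null(mem)) return(NULL)
    data.frame(adr_pt = a, protein = proteins[mem], stringsAsFactors = FALSE)
  }))
  rownames(truth) <- NULL

  structure(list(ppi = ppi_df, drug_target = drug_target_df,
                 drug_adr = drug_adr_df, truth = truth,
                 module_of = module_of, causal_module = causal_module,
                 config = config),
            class = "adr_world")
}

# stochastic-block-model edge sampler over unordered pairs i<j
sbm_edges <- function(n, module_of, p_in, p_out) {
  pairs <- which(upper.tri(matrix(0L, n, n)), arr.ind = TRUE)
  same <- module_of[pairs[, 1L]] == module_of[pairs[, 2L]]
  p <- ifelse(same, p_in, p_out)
  keep <- stats::runif(nrow(pairs)) < p
  pairs[keep, , drop = FALSE]
}

sample_scores <- function(n, config) {
  lo <- stats::runif(n) < config$low_score_frac
  ifelse(lo,
         sample.int(config$score_threshold, n, replace = TRUE) - 1L,
         config$score_threshold +
           sample.int(1001L - config$score_threshold, n, replace = TRUE) - 1L)
}

#' Write a synthetic world to disk
#'
#' Emits `ppi.tsv`, `drug_target.tsv`, `drug_adr.tsv` and `benchmark.tsv`
#' in the tab-separated dialects the pipeline readers expect, plus
#' `config.json`. Files round-trip losslessly through
#' [read_interactions()], [read_drug_adr()] and [read_benchmark()].
#'
#' @param world An `adr_world`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "adr_world"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    ppi = file.path(dir, "ppi.tsv"),
    drug_target = file.path(dir, "drug_target.tsv"),
    drug_adr = file.path(dir, "drug_adr.tsv"),
    benchmark = file.path(dir, "benchmark.tsv"),
    config = file.path(dir, "config.json")
  )
  write_tsv(world$ppi, paths[["ppi"]])
  write_tsv(world$drug_target, paths[["drug_target"]])
  write_tsv(world$drug_adr, paths[["drug_adr"]])
  write_tsv(world$truth[, c("adr_pt", "protein")], paths[["benchmark"]])
  cfg <- unclass(world$config)
  jsonlite::write_json(cfg, paths[["config"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
}

# Run expr-free seeded sampling without clobbering the caller's RNG stream.
local_seed <- function(seed) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    restore <- bquote(assign(".Random.seed", .(old), envir = globalenv()))
    do.call(on.exit, list(restore, add = TRUE), envir = parent.frame())
  }
  set.seed(seed)
  invisible(NULL)
}
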