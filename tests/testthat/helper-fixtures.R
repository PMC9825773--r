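# Shared fixtures and independent oracles, built in code.

# small planted world used across module tests
tiny_world <- function(seed = 11L, ...) {
  generate_world(world_config(n_proteins = 40L, n_modules = 4L,
                              n_drugs = 20L, n_adrs = 6L,
                              n_targets_per_drug = 4L, seed = seed, ...))
}

# build a hetero_network from explicit undirected PPI pairs plus one
# labeled drug so build_network's preconditions hold
toy_ppi_network <- function(pairs, drug_targets = pairs[1, 1]) {
  ppi <- data.frame(source_id = pairs[, 1], target_id = pairs[, 2],
                    score = 900L, stringsAsFactors = FALSE)
  dt <- data.frame(source_id = "DRUG1", target_id = drug_targets,
                   score = 900L, stringsAsFactors = FALSE)
  labels <- drug_adr_labels(data.frame(drug = "DRUG1", adr_pt = "ADR1",
                                       stringsAsFactors = FALSE))
  suppressMessages(build_network(ppi, dt, labels))
}

# the square-with-chord graph: t-v, v-x1, v-x2, t-x1
square_chord_network <- function() {
  toy_ppi_network(rbind(c("t", "v"), c("v", "x1"), c("v", "x2"),
                        c("t", "x1")))
}

# O(n_pos * n_neg) pairwise enumeration oracle for AUROC
auroc_oracle <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  total / (length(pos) * length(neg))
}

# explicit threshold-by-threshold precision-recall step sum for AP
ap_oracle <- function(scores, labels) {
  labels <- as.logical(labels)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels)
  ap <- 0
  prev_recall <- 0
  for (th in thresholds) {
    called <- scores >= th
    precision <- sum(labels & called) / sum(called)
    recall <- sum(labels & called) / n_pos
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

# spreadsheet-style oracle for pair metrics, including the continuity
# correction on the likelihood ratio
pair_metrics_oracle <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  prev <- (tp + fn) / n
  ppv <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  lr <- if (fp == 0 || tp + fn == 0) {
    ((tp + 0.5) * ((fp + 0.5) + (tn + 0.5))) /
      ((fp + 0.5) * ((tp + 0.5) + (fn + 0.5)))
  } else {
    (tp * (fp + tn)) / (fp * (tp + fn))
  }
  list(ppv = ppv, prevalence = prev, vappv = ppv - prev, lr = lr)
}

# empirical conditional next-step samples, keyed by "prev|curr" context
walk_transition_freqs <- function(walks) {
  lens <- lengths(walks)
  tok <- unlist(walks, use.names = FALSE)
  starts <- cumsum(c(1L, lens[-length(lens)]))
  ok <- which(lens >= 3L)
  idx <- unlist(lapply(ok, function(i) starts[i] + 0:(lens[i] - 3L)),
                use.names = FALSE)
  split(tok[idx + 2L], paste(tok[idx], tok[idx + 1L], sep = "|"))
}
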