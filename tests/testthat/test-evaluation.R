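test_that("confusion counts partition the drug universe", {
  # 100 drugs; 10 target p; 8 of those have the ADR; 12 non-targeters have it
  drugs <- sprintf("D%03d", 1:100)
  targets <- stats::setNames(rep(list(character()), 100), drugs)
  for (d in drugs[1:10]) targets[[d]] <- "p"
  with_adr <- c(drugs[1:8], drugs[11:22])
  labels <- drug_adr_labels(data.frame(
    drug = c(with_adr, drugs),
    adr_pt = c(rep("a", length(with_adr)), rep("other", 100))))
  cc <- confusion_counts("a", "p", targets, labels)
  expect_equal(unclass(cc)[c("tp", "fp", "fn", "tn")],
               list(tp = 8L, fp = 2L, fn = 12L, tn = 78L))
  expect_equal(cc$tp + cc$fp + cc$fn + cc$tn, 100L)
  cc0 <- confusion_counts("a", "untargeted", targets, labels)
  expect_equal(cc0$tp + cc0$fp, 0L)
  expect_error(confusion_counts("nope", "p", targets, labels), "unknown ADR")
})

test_that("pair metrics reproduce the worked example", {
  pm <- pair_metrics(list(tp = 8, fp = 2, fn = 12, tn = 78))
  expect_equal(pm$ppv, 0.8)
  expect_equal(pm$prevalence, 0.2)
  expect_equal(pm$vappv, 0.6)
  expect_equal(pm$lr, 16.0)
  expect_false(pm$lr_corrected)
})

test_that("pair metrics handle degenerate counts explicitly", {
  pm <- pair_metrics(list(tp = 0, fp = 5, fn = 10, tn = 85))
  expect_equal(pm$ppv, 0)
  expect_equal(pm$vappv, -pm$prevalence)
  expect_equal(pm$lr, 0)
  # independence: PPV equals prevalence exactly
  pm2 <- pair_metrics(list(tp = 2, fp = 8, fn = 18, tn = 72))
  expect_equal(pm2$vappv, 0)
  # no drug targets the protein: PPV undefined, flagged
  pm3 <- pair_metrics(list(tp = 0, fp = 0, fn = 10, tn = 90))
  expect_true(is.na(pm3$ppv))
  expect_false(pm3$ppv_defined)
  # fp = 0 triggers the continuity correction
  pm4 <- pair_metrics(list(tp = 5, fp = 0, fn = 5, tn = 90))
  expect_true(pm4$lr_corrected)
  expect_equal(pm4$lr, (5.5 * 91) / (0.5 * 11))
})

test_that("pair metrics agree exactly with the spreadsheet oracle", {
  set.seed(5)
  for (i in 1:120) {
    cnt <- as.list(stats::setNames(stats::rpois(4, sample(c(0.5, 3, 20), 1)),
                                   c("tp", "fp", "fn", "tn")))
    if (Reduce(`+`, cnt) == 0) cnt$tn <- 1
    pm <- pair_metrics(cnt)
    orc <- pair_metrics_oracle(cnt$tp, cnt$fp, cnt$fn, cnt$tn)
    expect_identical(pm$ppv, orc$ppv)
    expect_identical(pm$prevalence, orc$prevalence)
    expect_identical(pm$vappv, orc$vappv)
    expect_identical(pm$lr, orc$lr)
  }
})

test_that("vectorized pair metrics equal the per-pair route", {
  w <- tiny_world(seed = 51L)
  labels <- drug_adr_labels(w$drug_adr)
  tmap <- split(w$drug_target$protein, w$drug_target$chemical)
  tab <- all_pair_metrics(tmap, labels, min_support = 2L)
  expect_gt(nrow(tab), 0L)
  set.seed(6)
  for (i in sample(nrow(tab), 20L)) {
    cc <- confusion_counts(tab$adr_pt[i], tab$protein[i], tmap, labels)
    pm <- pair_metrics(cc)
    expect_equal(tab$lr[i], pm$lr)
    expect_equal(tab$vappv[i], pm$vappv)
  }
  # support filters hold
  drug_counts <- table(unlist(lapply(labels$drugs, function(d)
    unique(tmap[[d]])), use.names = FALSE))
  expect_true(all(drug_counts[unique(tab$protein)] >= 2L))
  expect_true(all(colSums(labels$matrix)[unique(tab$adr_pt)] >= 2L))
})

test_that("top-k evaluation applies support filters and reports missing ADRs", {
  sm <- matrix(c(0.9, 0.8, 0.7, 0.2,
                 0.6, 0.5, 0.4, 0.3), 2, byrow = TRUE,
               dimnames = list(c("a1", "a2"), c("P1", "P2", "P3", "P4")))
  class(sm) <- c("score_matrix", class(sm))
  drugs <- sprintf("D%02d", 1:20)
  targets <- stats::setNames(rep(list("P1"), 20), drugs)
  targets[drugs[1:2]] <- list(c("P1", "P2"))   # P2 support 2 < 5
  labels <- drug_adr_labels(data.frame(
    drug = c(drugs[1:8], drugs[1:3], drugs),
    adr_pt = c(rep("a1", 8), rep("a2", 3), rep("pad", 20))))
  res <- evaluate_top_k(sm, targets, labels, k = 3L, min_support = 5L)
  # a2 has 3 < 5 drugs -> missing; a1 keeps only P1 (P2, P3 under-supported)
  expect_true("a2" %in% res$missing_adrs)
  expect_equal(res$per_adr$adr_pt, "a1")
  expect_equal(res$per_adr$n_pairs[res$per_adr$adr_pt == "a1"], 1L)
  single <- pair_metrics(confusion_counts("a1", "P1", targets, labels))
  expect_equal(res$per_adr$mean_lr[res$per_adr$adr_pt == "a1"], single$lr)
  expect_equal(res$per_adr$mean_vappv[res$per_adr$adr_pt == "a1"], single$vappv)
})

test_that("benchmark recovery reports percentiles, bins and top fractions", {
  set.seed(7)
  n <- 200L
  sm <- matrix(stats::runif(3 * n), 3,
               dimnames = list(c("a1", "a2", "a3"), sprintf("P%03d", 1:n)))
  class(sm) <- c("score_matrix", class(sm))
  best <- colnames(sm)[which.max(sm["a1", ])]
  bench <- data.frame(adr_pt = c("a1", "a2", "zz"),
                      protein = c(best, "P001", "P002"))
  rec <- benchmark_recovery(sm, bench)
  expect_equal(rec$n_unmapped, 1L)
  expect_equal(nrow(rec$pairs), 2L)
  expect_lte(rec$pairs$percentile[rec$pairs$adr_pt == "a1"], 100 / n)
  expect_equal(sum(rec$histogram), 2L)
  # percentile invariant under monotone rescaling of that ADR's scores
  sm2 <- sm; sm2["a2", ] <- stats::plogis(5 * sm2["a2", ] - 2)
  class(sm2) <- class(sm)
  rec2 <- benchmark_recovery(sm2, bench)
  expect_equal(rec2$pairs$percentile, rec$pairs$percentile)
  # random benchmark pairs against random scores sit near the null fractions
  big_bench <- data.frame(adr_pt = sample(rownames(sm), 400, TRUE),
                          protein = sample(colnames(sm), 400, TRUE))
  rec3 <- benchmark_recovery(sm, big_bench)
  expect_lt(abs(rec3$frac_top5 - 0.05), 0.04)
  expect_lt(abs(rec3$frac_top20 - 0.20), 0.07)
  expect_error(benchmark_recovery(sm, data.frame(adr_pt = "zz", protein = "P001")),
               "no benchmark pair")
})

test_that("balanced resampling evaluation behaves at both extremes", {
  n <- 30L
  sm <- matrix(0.1, 3, n, dimnames = list(c("a1", "a2", "a3"),
                                          sprintf("P%03d", 1:n)))
  bench <- data.frame(adr_pt = c("a1", "a1", "a2", "a2", "a3"),
                      protein = sprintf("P%03d", 1:5))
  sm[cbind(bench$adr_pt, bench$protein)] <- 0.99
  class(sm) <- c("score_matrix", class(sm))
  res <- balanced_benchmark_eval(sm, bench, n_resamples = 200L, seed = 1L)
  expect_length(res$auroc, 200L)
  expect_true(all(res$auroc == 1))
  expect_true(all(res$ap == 1))
  res2 <- balanced_benchmark_eval(sm, bench, n_resamples = 200L, seed = 1L)
  expect_identical(res$auroc, res2$auroc)
})

test_that("jaccard and cosine follow their definitions", {
  expect_equal(jaccard(c("a", "b"), c("b", "c")), 1 / 3)
  expect_equal(jaccard(c("a", "a", "b"), c("a", "b")), 1)
  expect_error(jaccard(character(), character()), "undefined")
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
})

test_that("drug similarity correlation detects identical profiles and nulls", {
  set.seed(8)
  emb <- matrix(stats::rnorm(20 * 8), 20,
                dimnames = list(sprintf("D%02d", 1:20), NULL))
  emb["D02", ] <- emb["D01", ]
  adr <- data.frame(drug = rep(sprintf("D%02d", 1:20), each = 2),
                    adr_pt = c(rbind(sample(sprintf("A%02d", 1:30), 20, TRUE),
                                     sample(sprintf("A%02d", 1:30), 20, TRUE))))
  adr$adr_pt[adr$drug == "D02"] <- adr$adr_pt[adr$drug == "D01"]
  labels <- drug_adr_labels(adr)
  res <- drug_similarity_correlation(emb, labels)
  dup <- res$pairs[res$pairs$drug_a == "D01" & res$pairs$drug_b == "D02", ]
  expect_equal(dup$adr_jaccard, 1)
  expect_equal(dup$embedding_cosine, 1)
  expect_equal(nrow(res$pairs), choose(20, 2))
  # random labels vs random embeddings: correlation near zero
  expect_lt(abs(res$spearman), 0.35)
})

test_that("confidence-threshold selection recovers the planted cutoff", {
  # signal targets scored >= 700 follow drug ADR structure; noise targets
  # scored < 700 are random, so correlation peaks once noise is filtered
  set.seed(9)
  drugs <- sprintf("D%02d", 1:24)
  groups <- rep(1:4, each = 6)
  adr <- data.frame(drug = drugs, adr_pt = paste0("A", groups))
  labels <- drug_adr_labels(adr)
  signal <- data.frame(source_id = drugs,
                       target_id = paste0("T", groups),
                       score = 850L)
  noise <- data.frame(source_id = rep(drugs, 3),
                      target_id = sample(paste0("N", 1:40), 72, TRUE),
                      score = sample(200:699, 72, TRUE))
  dt <- rbind(signal, noise)
  res <- select_confidence_threshold(dt, labels, thresholds = c(300L, 500L, 700L))
  expect_equal(res$threshold, 700L)
  expect_equal(nrow(res$table), 3L)
  expect_equal(which.max(res$table$pearson), 3L)
})

test_that("grouped score similarity separates planted groups from baseline", {
  set.seed(10)
  base <- matrix(stats::runif(6 * 40), 6,
                 dimnames = list(sprintf("a%d", 1:6), sprintf("P%03d", 1:40)))
  base["a2", ] <- base["a1", ] + stats::rnorm(40, sd = 0.05)
  base["a3", ] <- base["a1", ] + stats::rnorm(40, sd = 0.05)
  sm <- pmin(pmax(base, 0.001), 0.999)
  class(sm) <- c("score_matrix", class(sm))
  grouping <- list(a1 = "G1", a2 = "G1", a3 = "G1", a4 = "G2", a5 = "G2")
  res <- grouped_score_similarity(sm, grouping)
  g1 <- res$per_label[res$per_label$label == "G1", ]
  expect_gt(g1$mean_cosine, res$baseline_mean)
  expect_true(all(c("p_value", "p_adjusted") %in% names(res$per_label)))
  # identical rows give cosine exactly 1
  sm2 <- sm; sm2["a2", ] <- sm2["a1", ]; sm2["a3", ] <- sm2["a1", ]
  class(sm2) <- class(sm)
  res2 <- grouped_score_similarity(sm2, grouping)
  expect_equal(res2$per_label$mean_cosine[res2$per_label$label == "G1"], 1)
  expect_error(grouped_score_similarity(sm, list(a1 = "G", a2 = "G", a3 = "G",
                                                 a4 = "G", a5 = "G", a6 = "G")),
               "baseline")
})
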