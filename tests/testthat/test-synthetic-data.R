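test_that("complete one-module graph yields all unordered pairs", {
  w <- generate_world(world_config(n_proteins = 4L, n_modules = 1L,
                                   n_drugs = 2L, n_adrs = 2L,
                                   n_targets_per_drug = 2L, p_in = 1,
                                   p_out = 0, seed = 3L))
  expect_equal(nrow(w$ppi), choose(4, 2))
  expect_true(all(w$ppi$protein_a != w$ppi$protein_b))
})

test_that("invalid configs are rejected", {
  expect_error(world_config(n_proteins = 3, n_modules = 5), "n_proteins")
  expect_error(world_config(theta_hi = 0.1, theta_lo = 0.5), "theta_hi")
  expect_error(world_config(p_in = 0, p_out = 0), "expected PPI degree")
})

test_that("planted world matches its exposure model within sampling error", {
  cfg <- world_config(n_proteins = 300L, n_modules = 10L, n_drugs = 120L,
                      n_adrs = 20L, p_in = 0.3, p_out = 0.01,
                      focus_prob = 0.7, theta_hi = 0.8, theta_lo = 0.05,
                      seed = 1L)
  w <- generate_world(cfg)
  tmap <- split(w$drug_target$protein, w$drug_target$chemical)
  has <- matrix(FALSE, cfg$n_drugs, cfg$n_adrs,
                dimnames = list(sprintf("D%04d", 1:cfg$n_drugs),
                                sprintf("ADR%03d", 1:cfg$n_adrs)))
  has[cbind(w$drug_adr$drug, w$drug_adr$adr_pt)] <- TRUE
  exposed <- sapply(colnames(has), function(a) {
    m <- w$causal_module[[a]]
    sapply(rownames(has), function(d) any(w$module_of[tmap[[d]]] == m))
  })
  rate_exp <- mean(has[exposed])
  rate_une <- mean(has[!exposed])
  se_exp <- sqrt(0.8 * 0.2 / sum(exposed))
  se_une <- sqrt(0.05 * 0.95 / sum(!exposed))
  expect_lt(abs(rate_exp - 0.8), 3 * se_exp)
  expect_lt(abs(rate_une - 0.05), 3 * se_une)
})

test_that("null world has equal ADR rates for exposed and unexposed drugs", {
  w <- generate_world(world_config(n_proteins = 100L, n_modules = 5L,
                                   n_drugs = 300L, n_adrs = 10L,
                                   theta_hi = 0.1, theta_lo = 0.1, seed = 7L))
  tmap <- split(w$drug_target$protein, w$drug_target$chemical)
  # pooled odds ratio between "targets causal module" and "has ADR"
  tab <- matrix(0, 2, 2)
  drugs <- sprintf("D%04d", 1:300)
  has <- matrix(FALSE, 300, 10, dimnames = list(drugs, sprintf("ADR%03d", 1:10)))
  has[cbind(w$drug_adr$drug, w$drug_adr$adr_pt)] <- TRUE
  for (a in colnames(has)) {
    m <- w$causal_module[[a]]
    ex <- sapply(drugs, function(d) any(w$module_of[tmap[[d]]] == m))
    tab <- tab + table(factor(ex, c(FALSE, TRUE)),
                       factor(has[, a], c(FALSE, TRUE)))
  }
  or <- (tab[2, 2] * tab[1, 1]) / (tab[2, 1] * tab[1, 2])
  expect_lt(abs(log(or)), 0.25)
})

test_that("worlds are reproducible from the seed and differ across seeds", {
  w1 <- tiny_world(seed = 5L)
  w2 <- tiny_world(seed = 5L)
  w3 <- tiny_world(seed = 6L)
  expect_identical(w1$ppi, w2$ppi)
  expect_identical(w1$drug_adr, w2$drug_adr)
  expect_false(identical(w1$ppi, w3$ppi))

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_world(w1, d1); write_world(w2, d2)
  for (f in c("ppi.tsv", "drug_target.tsv", "drug_adr.tsv", "benchmark.tsv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("within-module edge fraction increases with p_in at fixed p_out", {
  frac_within <- function(p_in) {
    w <- generate_world(world_config(n_proteins = 100L, n_modules = 5L,
                                     n_drugs = 5L, n_adrs = 2L,
                                     n_targets_per_drug = 2L,
                                     p_in = p_in, p_out = 0.02, seed = 21L))
    mo <- w$module_of
    mean(mo[w$ppi$protein_a] == mo[w$ppi$protein_b])
  }
  fr <- vapply(c(0.05, 0.2, 0.5), frac_within, numeric(1L))
  expect_true(all(diff(fr) > 0))
})

test_that("written world round-trips losslessly through the readers", {
  w <- tiny_world(seed = 9L)
  d <- withr::local_tempdir()
  write_world(w, d)
  ppi <- read_interactions(file.path(d, "ppi.tsv"), threshold = 700L)
  expect_equal(nrow(ppi), nrow(w$ppi))
  key_in <- sort(paste(pmin(w$ppi$protein_a, w$ppi$protein_b),
                       pmax(w$ppi$protein_a, w$ppi$protein_b), w$ppi$combined_score))
  key_out <- sort(paste(ppi$source_id, ppi$target_id, ppi$score))
  expect_identical(key_in, key_out)
  da <- read_drug_adr(file.path(d, "drug_adr.tsv"))
  expect_setequal(paste(da$drug, da$adr_pt),
                  paste(w$drug_adr$drug, w$drug_adr$adr_pt))
  bench <- read_benchmark(file.path(d, "benchmark.tsv"))
  expect_equal(nrow(bench), nrow(w$truth))
})

test_that("drugs with zero sampled ADRs remain in the target table", {
  w <- generate_world(world_config(n_proteins = 30L, n_modules = 3L,
                                   n_drugs = 60L, n_adrs = 3L,
                                   n_targets_per_drug = 3L,
                                   theta_hi = 0.05, theta_lo = 0.05,
                                   seed = 13L))
  drugs_with_targets <- unique(w$drug_target$chemical)
  drugs_with_adrs <- unique(w$drug_adr$drug)
  expect_gt(length(setdiff(drugs_with_targets, drugs_with_adrs)), 0L)
})

test_that("every targeted protein appears in the PPI table and truth maps to causal modules", {
  w <- tiny_world(seed = 17L)
  ppi_prots <- unique(c(w$ppi$protein_a, w$ppi$protein_b))
  expect_true(all(w$drug_target$protein %in% ppi_prots))
  expect_true(all(w$truth$adr_pt %in% sprintf("ADR%03d", 1:6)))
  for (a in unique(w$truth$adr_pt)) {
    prots <- w$truth$protein[w$truth$adr_pt == a]
    expect_true(all(w$module_of[prots] == w$causal_module[[a]]))
  }
})

test_that("low-score fraction produces records that filtering removes", {
  w <- generate_world(world_config(n_proteins = 50L, n_modules = 2L,
                                   n_drugs = 10L, n_adrs = 3L,
                                   low_score_frac = 0.4, seed = 19L))
  expect_gt(sum(w$ppi$combined_score < 700L), 0L)
  d <- withr::local_tempdir()
  write_world(w, d)
  kept <- read_interactions(file.path(d, "ppi.tsv"), threshold = 700L)
  expect_equal(nrow(kept), sum(w$ppi$combined_score >= 700L))
})
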