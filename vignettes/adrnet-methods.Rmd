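---
title: "Predicting ADR-related proteins with single-target-compound read-out"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting ADR-related proteins with single-target-compound read-out}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Most adverse drug reactions (ADRs) arise from drugs perturbing proteins —
both intended targets and off-targets. Methods that infer ADR–protein
relations only from observed drug–target pairs can, by construction, never
score a protein that no catalogued drug binds. `adrnet` implements a
network-embedding approach that removes this restriction: every protein of
a protein–protein interaction (PPI) network receives a score for every
ADR, whether or not any drug is known to target it.

The trick is the *single-target compound* (STC): for each protein `P`, a
fictitious compound node `STC::P` is added to the network with exactly one
directed edge `STC::P -> P`. STCs are structurally drug-like — they sit
upstream of the protein layer exactly as drugs do — so once the network is
embedded, STC vectors live in the same space as drug vectors. A classifier
trained to predict "drug causes ADR `a`" from drug vectors can then be
applied to `STC::P`'s vector, and its output is read as the relation score
between protein `P` and ADR `a`.

## The pipeline

1. **Inputs.** Three tab-separated tables in public-database dialects:
   PPI links and chemical–protein links with confidence scores 0–1000
   (STRING / STITCH style), and drug–ADR pairs with MedDRA-Preferred-Term
   style identifiers (SIDER style). Records below the confidence threshold
   (default 700, the conventional "high confidence" cut, inclusive) are
   dropped; duplicate unordered pairs collapse to their maximum score;
   self-loops are removed.
2. **Integrated network.** Drug–target records are kept only when the drug
   has at least one ADR and the protein occurs in the filtered PPI graph.
   Each kept drug–protein pair becomes one directed edge, each PPI pair two
   directed edges, and each protein gains its STC with a single outgoing
   edge. With `D` kept drug–protein pairs, `P` PPI pairs and `S` proteins
   the graph has exactly `D + 2P + S` directed edges — an identity the
   package asserts on every build. The graph is unweighted after filtering.
3. **Embedding.** Second-order biased random walks (node2vec): from `curr`,
   arrived from `prev`, an out-neighbour `s` has unnormalized weight `1/p`
   if `s = prev`, `1` if `s` is an out-neighbour of `prev`, and `1/q`
   otherwise. Walks start from every node; by the edge directions, drugs
   and STCs occur only as walk heads and every later position is a protein,
   so drug and STC vectors are trained purely from protein context. This is
   faithful to the construction, not an artifact. The walk corpus feeds a
   skip-gram model with negative sampling.
4. **Classification.** One L2-regularized logistic regression per ADR on
   the drug vectors (binary relevance), evaluated by 10-fold
   cross-validation with a fold partition shared across ADRs and pooled
   out-of-fold scores; macro AUROC and macro average precision summarize
   performance over ADRs with at least 10 positive drugs.
5. **Read-out and evaluation.** Scores for all proteins come from applying
   each ADR's classifier to the STC vectors; rankings use average ranks on
   ties and percentiles `100 * rank / N`. The evaluation suite computes
   per-(ADR, protein) confusion counts over the labeled drugs, PPV,
   prevalence, VAPPV, the positive likelihood ratio, top-k averages under
   support filters, benchmark percentile recovery, balanced
   negative-sampling AUROC/AP, drug-pair similarity correlation, and
   grouped score-vector similarity.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `threshold` | 700 | inclusive confidence-score cut for both interaction tables |
| `p`, `q` | 1, 1 | walk return / in-out bias; `optimize_walk_params()` grid-searches them against downstream CV macro AUROC, with ties broken toward (1, 1) |
| `num_walks`, `walk_length` | 10, 80 | walks per node and walk length |
| `dimensions`, `window`, `negative`, `epochs` | 128, 10, 5, 5 | skip-gram settings, following common node2vec benchmark conventions |
| `inverse_reg_strength` | 0.1 | classifier regularization in the inverse-strength (`C`) convention of summed-loss solvers; internally mapped to a glmnet ridge penalty `lambda = 1/(n * C)` |
| `min_drugs` | 10 | minimum positive drugs for an ADR to appear in the CV report |
| `top_k`, `min_support` | 50, 5 | top proteins per ADR scored by VAPPV/LR; pairs whose protein is targeted by fewer than 5 labeled drugs, or whose ADR is carried by fewer than 5 drugs, are excluded |
| `n_resamples` | 1000 | negative resamples in the balanced benchmark evaluation |

A note on the regularization convention: in summed-loss solvers the
penalty-to-data ratio depends on the number of drugs, so a fixed `C = 0.1`
is a much stronger effective penalty at a few hundred drugs than at a few
thousand. The package reproduces that convention faithfully; on small
simulated cohorts, cross-validated AUROC is therefore regularization-limited
rather than embedding-limited (we verified that an oracle representation of
the generative structure scores the same under the same penalty).

## What the synthetic generator emulates

`generate_world()` plants a ground truth that the pipeline should recover:

- The PPI graph is a stochastic block model: proteins split into
  equal-size modules, edges within a module with probability `p_in` and
  between modules with probability `p_out` (`p_in > p_out` plants
  community structure that walk-based embedding can detect).
- Each ADR is assigned one causal module round-robin, so every module is
  causal for some ADR whenever there are at least as many ADRs as modules.
- Each drug draws `n_targets_per_drug` targets, from one random module
  with probability `focus_prob` (0.7 by default) and uniformly otherwise.
  The default of 10 targets per drug reflects a realistic high-confidence
  target-set size while keeping target sets sparse relative to the 20–30
  protein modules used in tests; drugs whose focus module is smaller draw
  the whole module.
- A drug acquires an ADR with probability `theta_hi` if it targets at
  least one protein of the ADR's causal module and `theta_lo` otherwise.
  Setting `theta_hi = theta_lo` gives a *null world* in which labels are
  independent of targeting — the world in which VAPPV must average 0 and
  the likelihood ratio 1.
- Confidence scores are uniform on `[threshold, 1000]`, so filtering is
  exercised but lossless by default; `low_score_frac` plants sub-threshold
  records to test the filter. Drugs that sample zero ADRs stay in the
  target table on purpose: the network builder must drop them.
- Targets are drawn only from proteins that received at least one PPI
  edge, so every targeted protein is embeddable by construction.

The generator does **not** attempt realistic degree distributions, score
distributions, chemical structure, or a MedDRA-style ADR hierarchy, and
its modules are disjoint where real pathways overlap. Passing tests on
these worlds demonstrate that the machinery recovers planted signal and
respects the published filters and formulas — not that the method attains
any particular accuracy on real STRING/STITCH/SIDER data.

## Numerical and design choices

- **Walk sampling and skip-gram training** are implemented in C++ with a
  self-contained xorshift generator, single-threaded; identical seeds give
  bit-identical walks and embeddings on any platform. The skip-gram uses
  the word2vec conventions: dynamic (uniformly shrunk) windows,
  unigram^0.75 negative-sampling table, linear learning-rate decay from
  0.025 to 1e-4, no frequent-word subsampling (the vocabulary is small and
  drug/STC nodes are rare, so subsampling would mostly add variance).
- **Ridge fits** run on a short descending lambda path ending at the
  target penalty for solver stability; ADR columns with fewer than two
  drugs in either class are skipped and reported, never silently dropped.
- **AUROC** uses the Mann–Whitney rank formulation with half-credit ties;
  **average precision** is the uninterpolated threshold step-sum. Both are
  tested against brute-force enumeration oracles.
- **Likelihood-ratio degeneracies**: when `FP = 0` or `TP + FN = 0` the
  Haldane–Anscombe +0.5 correction is applied to all four cells, for the
  LR only. Undefined PPVs (nobody targets the protein) are flagged and
  excluded from means, with exclusion counts reported.
- **Ties** in protein ranking get average ranks; `top_k` breaks boundary
  ties lexicographically so runs are reproducible.
- **Fold assignment** is a single unstratified drug-level partition shared
  by all ADRs; out-of-fold scores are pooled before computing per-ADR
  metrics. Pooling across fold models is slightly pessimistic under pure
  noise (fold intercepts track training prevalence), which the test suite
  documents rather than hides.
- **Grouped score similarity** uses Welch's t-test per group label against
  the share-no-label baseline, with Benjamini–Hochberg adjustment across
  labels; pairs are the unit of analysis, so p-values inherit the usual
  dependence caveat of pairwise designs.
- **Stage seeds** derive from the single global seed with fixed offsets
  (+1 walks, +2 embedding, +3 CV, +4 resampling), so any stage can be
  rerun in isolation.

## Problem sizes used in the tests

The packaged study conditions are desk-scale: planted worlds of 300
proteins in 10 modules, 120 drugs and 20 ADRs (embedded at 64 dimensions,
10 walks of length 40 per node, three seed replicates), and null worlds of
200 proteins, 400 drugs and 20 ADRs averaged over ten seeds. At these
sizes the full planted-world pipeline recovers the causal modules
(truth-pair AUROC around 0.95, median truth-protein percentile around 6%)
while cross-validated drug-level macro AUROC sits in the mid-0.6s,
regularization-limited as discussed above.

## Known limitations

- Identifier harmonization across databases is out of scope; inputs are
  assumed pre-harmonized.
- Only the node2vec-style backend is provided; alternative embedding
  algorithms are not implemented.
- Multi-worker training would relax bit-level determinism and is not
  offered; training is single-threaded.
- Published duplicate-record handling at database scale is unstated; the
  max-score rule is this package's choice, as is reading the minimum-drug
  rule for cross-validation as a minimum on *positive* drugs.
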