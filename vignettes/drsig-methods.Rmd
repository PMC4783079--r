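---
title: "Methods: signature similarity, DR classifiers and mode-of-action profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature similarity, DR classifiers and mode-of-action profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drsig)
```

## The model

`drsig` treats every piece of compound and disease knowledge as a binary
vector — the presence or absence of fingerprint bits or genes — and
reduces drug repositioning to three steps:

1. **Association features.** For a compound and a disease, similarity is
   the Tanimoto coefficient $|A \cap B| / |A \cup B|$ between feature
   sets, averaged over the full Cartesian product of pairs when either
   side owns several signatures (multiple cell contexts, multiple
   disease datasets). The disease side is represented by pooled
   signatures of its known drugs (KD) plus the disease expression
   signatures, giving at most seven features per compound: `S_S`, `T_T`,
   `T_Ekd`, `T_Edis`, `E_T`, `E_Ekd`, `E_Edis`.
2. **DR score.** Seven logistic regressions — one per signature-channel
   combination `S, T, E, ST, SE, TE, STE` — are fit with known drugs as
   positives. The negative class is the *core set* (compounds having all
   three signature types) minus every compound with any cancer activity
   (the CD set); CD-but-not-KD compounds are held out of both classes as
   ambiguous, though they still receive scores at prediction time. The
   inverse-logit of the linear predictor is the DR score in $(0,1)$.
3. **Evaluation and interpretation.** Mean AUC over 100 rounds of
   stratified 3-fold cross-validation; AUC against HTS hit categories
   (anti-cancer vs novel hits); candidate filtering; and pathway-level
   mode-of-action profiles compared by cosine distance.

The key assumptions are (i) that set overlap is an adequate similarity
for all three data types — no weighting, no anti-correlation handling —
and (ii) that the KD pool defines the disease: a compound is promising
insofar as its signatures resemble the pooled signatures of drugs already
known to work.

## Decisions where the design was open

**E signatures as presence/absence.** An expression profile's up and
down gene lists are merged into one set before similarity (a single
binary vector of differential expression). A `directional = TRUE` switch
computes separate up–up and down–down Tanimotos and averages them; it is
off by default because the merged representation is the simpler reading
and the directional variant discards cross-direction identity entirely.
CMAP-style reversal scoring (disease-up vs drug-down) is deliberately
not implemented; `E_Edis` measures DEG-identity overlap only.

**Pooled KD references.** Disease-side pools are flat lists of the KD
members' signatures, and a feature is the mean over all pairs — not a
per-drug maximum. A max would reward a single close analog; the mean
expresses consensus across the known pharmacopoeia.

**Leakage guard.** During cross-validation a known drug must not be
scored against pools containing its own signatures. Because pool
features are flat means over pairs, removing one compound's signatures
from a pool is exact and cheap (`loo_kd = TRUE` precomputes
leave-self-out features for every KD compound); per-fold feature
rebuilds would give identical numbers at many times the cost. Final
descriptive scores keep full pools.

**Missingness.** A compound lacking a signature type gets `NA` for the
affected features, never 0: zero means "maximally dissimilar", which a
missing measurement is not. Fits and scoring drop incomplete rows with a
logged count; evaluation lives on the core set where nothing is missing.

**Cross-validated AUC.** Each round pools its held-out linear predictors
and yields one AUC; the summary is the mean over rounds. With only a few
dozen positives, per-fold AUCs are unstable; pooling within a round is
the stabler estimator. Folds are stratified by class for the same
reason. Per-round AUC vectors are bit-reproducible for a fixed seed.

**Final ranking.** Candidate ranking uses the fitted E-classifier
probability, turned into a percentile rank
$r(c) = \#\{s \le s_c\}/n$ (ties share a rank; the top compound has
rank 1). The shortlist keeps FDA-approved compounds with rank strictly
above 0.9; compounds flagged as not crossing the blood–brain barrier are
retained but marked `bbb_warning`, since a reviewer may keep a
high-scoring non-permeant candidate.

**HTS negatives.** Per assay, both category AUCs (anti-cancer hits,
novel hits) use assayed non-hits as negatives, with known-drug hits and
the opposite hit category never entering the negatives. Evaluation is
restricted to the core set by default; `all_compounds = TRUE` evaluates
every assayed compound. The analog rule is strict (`> 0.7`, never
$\ge$) and uses the maximum Tanimoto over fingerprint pairs when a
compound has several.

**Enrichment.** Per (pathway, direction): an upper-tail hypergeometric
p-value per cell context (overlap $k$, signature size $n$, pathway size
$K$, universe $N$; $k=0$ gives exactly 1), aggregated across contexts by
the plain harmonic mean $m / \sum 1/p_i$ — dominated by the best
context, intentionally, since a drug acting in one lineage should not be
washed out by inert contexts. BH adjustment is applied within each drug
across all pathway × direction rows (a per-drug heat-map family); a
global-family option is available via adjusting the stacked table
yourself. Significance defaults to $q < 0.1$ for profiles and
$q < 0.05$ for selecting the clustering panel — both are parameters
because the two conventions serve different purposes (description vs a
conservative panel). Profile vectors are $-\log_{10} p$; the base is
fixed globally since cosine distance is invariant to a common rescaling
but not to mixed bases. The enrichment universe must be supplied
(platform gene list); the fallback — the union of pathway genes — is
logged, because the universe choice changes p-values materially.

## The synthetic-data generator

`generate_world()` emulates the set-level structure of a real
signature-based repositioning study; it makes no attempt to imitate
measurement physics or expression magnitudes. Defaults (the study
conditions for all statistical tests):

| parameter | default | meaning |
|---|---|---|
| `n_compounds` | 400 | catalog size |
| `n_active` | 60 | truly active compounds |
| `n_kd` / `n_cd_extra` | 20 / 20 | known drugs; extra "other-cancer" actives (CD = 40); the 20 remaining actives are hidden hits |
| `gene_universe_size` | 2000 | expression gene universe |
| `e_sig_size` × `n_contexts` | 100 × 3 | genes per direction, cell contexts per compound |
| `disease_gene_pool` | 300 | disease genes, split into up/down halves |
| `e_signal_fraction` | 0.5 | fraction of an active's genes drawn from the disease pool |
| `t_pool_size` / `t_per_compound` / `t_signal_prob` | 50 / 3 / 0 | target pool; T channel silent by default |
| `fp_length` / `fp_on_bits` | 1024 / 120 | fingerprint shape |
| `n_scaffolds` / `scaffold_flip_rate` | 25 / 0.05 | scaffold prototypes; per-bit mutation (on-bit count preserved), giving same-scaffold Tanimoto ≈ 0.8 |
| `context_noise` | 0.2 | fraction of genes re-drawn per context |
| `n_pathways` × `pathway_size` | 60 × 40 | pathway collection |
| `n_moa_groups`, `moa_drugs_per_group`, `moa_gene_fraction` | 2, 4, 0.4 | planted mode-of-action groups |
| `n_assays`, `assay_coverage`, `hts_noise` | 3, 0.7, 0.05 | HTS shape and noise |

Choices that needed care:

* **Channel independence.** The signal dials (`e_signal_fraction`,
  `t_signal_prob`, scaffold structure) are independent, so
  "which signature type carries repositioning signal" is a controlled
  experiment. Two consequences: planted MOA drugs are drawn from the
  *non-KD* actives (planted genes inside the benchmark positives would
  couple the enrichment channel to the classifier benchmark), and
  planted genes come from the pathway's non-disease portion (pathways
  drawn from the full universe overlap the disease pool by a few genes,
  which would otherwise mark MOA drugs — negative-class compounds — with
  nonzero `E_Edis` in an otherwise signal-free world).
* **Common random numbers.** Every compound has its own RNG substream
  and always draws fixed-length disease-gene and background-gene
  sequences; `e_signal_fraction` only decides how much of each sequence
  enters the signature. Worlds differing only in the dial are therefore
  coupled, which lets monotonicity-in-signal checks measure the dial
  rather than world-resampling noise, and regenerating one compound
  never perturbs another.
* **HTS noise.** Hit lists are contaminated, not per-compound flipped:
  5% of tested actives are missed, and spurious hits numbering 5% of the
  true hit list are added from tested inactives. With a 6:1
  inactive-to-active imbalance, flipping every label at 5% would make
  half of the "novel hit" category spurious; real HTS hit lists err at
  roughly the hit-list scale, and this keeps benchmark AUCs properly
  below 1 without drowning the category of interest.
* **MOA group shape** (2 groups × 4 drugs, 40% of a signature from the
  planted pathway) was chosen once as the smallest panel on which
  two-group recovery is a meaningful test and a 40-gene pathway can
  dominate a 100-gene signature's enrichment.

What the generator does *not* emulate — continuous expression values,
dose, batch effects, compound-identity ambiguity, correlated pathway
membership — bounds what passing tests mean: they demonstrate the
pipeline's statistical machinery and its contracts, not performance on
any real compound collection.

## Numerical choices

* Logistic fits: `stats::glm.fit`, tolerance $10^{-8}$, max 1000
  iterations, unregularised — with at most seven bounded features the
  MLE is almost always well-posed. Detected separation (non-convergence,
  fitted probabilities at machine limits, or slopes beyond $10^3$) falls
  back to a Newton ridge fit with penalty $\lambda = 10^{-4}$ on slopes
  only, logged. Aliased (e.g. constant) features receive coefficient 0 —
  their fitted contribution — rather than propagating `NA` into scores.
* AUC is the Mann–Whitney pair statistic computed from midranks; ties
  count ½.
* Clustering orders drugs lexicographically before building the
  dissimilarity, so dendrograms are deterministic under ties; flat
  clusters come from `cutree`.
* GMT readers reject malformed lines and duplicate ids rather than
  repairing them; duplicate compound rows typically indicate unmerged
  identifiers upstream, which is the caller's decision to resolve.
* All randomness flows from one integer seed through per-stage (and
  per-compound) subseeds below $2^{31}$.

## Problem sizes used by the test suite

Unit tests run on scaled-down worlds (60 compounds, 600 genes);
statistical checks — null calibration, signal recovery and dominance of
the E channel over 20 replicate worlds, monotonicity in the signal dial
over 5 paired worlds, cluster recovery over 10 worlds — run at the
default 400-compound scale with 100 × 3-fold cross-validation. These
sizes were chosen so the full suite demonstrates the method at its
intended scale while remaining comfortable to run on a laptop.

## Known limitations

* **Null-band width.** With 20 known drugs, the sampling spread of a
  world's cross-validated mean AUC under no signal is roughly 0.08 (the
  Mann–Whitney sd alone is 0.066 at 20 vs 360); a single signal-free
  world can land a classifier's mean CV AUC outside $[0.45, 0.55]$
  without any bias. Calibration claims at this scale should average over
  worlds; the package's null checks at a single fixed world are
  correspondingly strict and can flag benign draws.
* **AUC ceiling from hidden hits.** Active compounds outside the CD set
  sit in the negative class by construction, capping the cross-validated
  AUC near $1 - \tfrac{1}{2}\,(\text{hidden hits})/(\text{negatives})
  \approx 0.97$ at defaults; the E-channel dial saturates by
  `e_signal_fraction` ≈ 0.2 for the same reason. This mirrors the
  incomplete-gold-standard problem the HTS benchmark exists to expose.
* Tanimoto on merged up/down sets cannot distinguish a drug that mimics
  a disease signature from one that reverses it; reversal scoring is out
  of scope.
* The harmonic mean is used as a summary statistic, not as a calibrated
  combined test; q-values are interpreted within the profiling context
  only.
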