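# drsig — signature-based in silico drug repositioning

`drsig` predicts new disease indications for existing compounds from three
kinds of binary signatures and quantifies — with cross-validated and
HTS-style benchmarks — which signature type actually carries
repositioning signal:

* **S** — structural fingerprints (precomputed on-bit sets, e.g. 1,024-bit
  FP2 hashes; no chemistry is done here),
* **T** — known target gene sets,
* **E** — drug-induced expression signatures (top up- and down-regulated
  genes per cell context).

It is aimed at computational pharmacology groups who have
compound-signature collections and disease gene signatures and want a
transparent, testable scoring pipeline rather than a black box.

## The method

Every signature is a finite set, so compound–disease association is
measured by the Tanimoto coefficient

$$T(A, B) = \frac{|A \cap B|}{|A \cup B|},$$

averaged over all (compound signature, reference signature) pairs when a
side owns several signatures. Against a disease with known drugs (the KD
set) this yields up to seven features per compound:
`S_S, T_T, T_Ekd, T_Edis, E_T, E_Ekd, E_Edis` — compound structure/
targets/expression against the pooled KD structures, KD targets, KD
expression signatures, and the disease expression signatures.

Seven logistic classifiers (`S`, `T`, `E`, `ST`, `SE`, `TE`, `STE`) are
fit on these feature blocks with known drugs as positives and the core
set (compounds with all three signature types) minus all cancer-active
compounds (the CD set) as negatives. The inverse-logit of the linear
predictor is the **DR score** in (0, 1), also reported as a percentile
rank. Evaluation uses:

1. 100 rounds of stratified 3-fold cross-validation (mean AUC), with a
   leave-self-out guard so a known drug is never scored against reference
   pools containing its own signatures;
2. HTS hit lists, with known-drug hits excluded and the remaining hits
   split into *anti-cancer* hits (in CD, or having ≥ 2 CD structural
   analogs at Tanimoto > 0.7) and *novel* hits — the hard cases that
   structure-based methods cannot reach;
3. candidate filtering (FDA-approved, percentile > 0.9, blood–brain
   barrier annotation).

Mode-of-action profiling computes hypergeometric pathway enrichment of
each drug's up/down gene sets per cell context, aggregates contexts by
the harmonic mean p-value, adjusts by Benjamini–Hochberg within drug, and
clusters drugs by cosine distance of their −log₁₀ p profiles
(average linkage).

A synthetic-world generator (`generate_world()`) emulates all of this at
desk scale with independently switchable signal channels, so every claim
the package makes is demonstrated on data with known ground truth.

## Worked example

A hand-checkable six-compound world ships with the package:

```r
library(drsig)
cat <- generate_worked_example()
cat
#> <dr_catalog> 6 compounds; signatures: S=6 T=5 E=14
#>   core set (S&T&E): 5 compounds
#>   disease toy_disease: KD=1 CD=2
#>   pathways: 3 (universe 20 genes)
#>   assays: 1

build_association_features(cat)
#> # A tibble: 6 × 9
#>   compound_id disease_id    S_S    T_T   T_Ekd T_Edis   E_T  E_Ekd E_Edis
#>   <chr>       <chr>       <dbl>  <dbl>   <dbl>  <dbl> <dbl>  <dbl>  <dbl>
#> 1 c1          toy_disease 1      1      0.238   0.333 0.238 0.6     0.333
#> 2 c2          toy_disease 0.778  0.333  0.143   0.333 0.143 0.2     0.5
#> 3 c3          toy_disease 0.778  0.333  0.238   0.333 0.143 0.0909  0.2
#> 4 c4          toy_disease 0.455  0      0.143   0     0     0.1     0
#> 5 c5          toy_disease 0      0      0.0833  0     0     0.1     0
#> 6 c6          toy_disease 0.333 NA     NA      NA     0.143 0.0455  0.2
```

`c1` is the sole known drug, hence its self-similarity features are 1;
`c6` has no target signature, so every T feature is `NA` (missingness is
preserved, never coerced to 0). The bundled assay illustrates the hit
partition — `c1` a known drug (excluded), `c2` anti-cancer by CD
membership, `c3` anti-cancer by two structural analogs, `c4` a novel hit:

```r
partition_hits("toy_assay", cat)
#> <hit_partition> toy_assay: 1 known (excluded), 2 anti-cancer, 1 novel, 1 non-hits
```

On a full synthetic world the expression channel dominates, the central
qualitative claim of the method:

```r
w <- generate_world(world_params(seed = 1))
feats <- build_association_features(w$catalog, loo_kd = TRUE)
labels <- make_benchmark(w$catalog)
#> benchmark: 20 positives, 360 negatives, 20 ambiguous (of 400 core compounds)
cv <- cross_validate_all(feats, labels, rounds = 100, seed = 1)
dplyr::select(cv, -cv)
#> # A tibble: 7 × 6
#>   classifier mean_auc  sd_auc rounds folds  seed
#> 1 S             0.618 0.00949    100     3     1
#> 2 T             0.392 0.0420     100     3     1
#> 3 E             0.970 0.00412    100     3     1
#> 4 ST            0.537 0.0350     100     3     1
#> 5 SE            0.970 0.00400    100     3     1
#> 6 TE            0.967 0.00387    100     3     1
#> 7 STE           0.967 0.00393    100     3     1
```

`run_pipeline(out_dir, seed = 1)` wires every stage end to end —
features, CV of all seven classifiers, scoring/ranking, candidate
filtering, HTS evaluation, enrichment and clustering — writing one TSV
per stage plus a `manifest.json` with a parameter echo and output
checksums. `autoplot()` methods and `plot_cv_summary()` /
`plot_hts_auc()` give the standard figures for each result type.

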