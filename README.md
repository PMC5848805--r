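# serumchallenge

Comparative analysis of fibroblast **serum-challenge** experiments in two
species (human and chimpanzee). Serum-starved fibroblasts re-exposed to
serum mount a wound-healing-like transcriptional program that overlaps the
expression profile of epithelial tumours; running the assay in both
species and profiling it with RNA-seq and DNase-seq turns it into a
comparative experiment on how a core physiological response diverges over
short evolutionary time. This package is for genomicists who want that
whole analysis as tested, reusable R functions — with a synthetic-data
generator so every stage can be validated end to end without any
downloads.

## What it implements

* **Differential expression** — per-gene negative binomial GLM with log
  link and offset log(library size × TMM factor),
  Var(y) = μ + φμ², likelihood-ratio χ² tests between nested formulas
  (`~species` vs `~1` per time point, `~time` vs `~1` per species),
  BH-FDR. TMM factors use a 30% trim on M, 5% on A. Dispersions are
  per-gene Pearson moment estimates shrunk toward a lowess trend with an
  empirically estimated weight.
* **Gene set enrichment** — the weighted running-sum statistic
  (hit increments |r|^w normalized, miss decrements 1/(N−N_h)), ES in
  [−1, 1], gene-label permutation p-values, NES, sign-stratified FDR;
  plus hypergeometric category enrichment against a user background and
  the set algebra for serum-specific / species-common category lists.
* **DHS window harmonization** — the pooled peaks of all samples are
  partitioned at every peak boundary into disjoint windows (50–2,000 bp
  kept), scored per sample with the best overlapping peak
  (−10·log10 p), flagged active per (species, time) when any replicate
  has signal, and classified shared / species-specific; differential
  accessibility reuses the NB GLM on window counts at 5% FDR, and
  `bedtools intersect -u`-style external overlap is built in.
* **Fuzzy trajectory clustering** — row-standardized log2 activity
  profiles, the dimension-based fuzzifier estimator, seeded fuzzy
  c-means, cluster-number choice from the minimum-centroid-distance
  curve, and opening/closing/transient labeling with a 0.6 membership
  floor.
* **Gene linking** — nearest-TSS assignment (midpoint distance,
  deterministic tie-breaks), windows-per-gene cluster summaries,
  Spearman correlations of accessibility with expression, and
  exact-score PWM scanning on both strands.
* **Selection tests** — isoform collapse by max dN, dN/dS > 1 fractions
  with Fisher enrichment (dS = 0 genes reported separately), dN
  percentiles, outgroup-parsimony substitution counts, and a one-sided
  promoter-versus-intron binomial likelihood-ratio test (χ²₁, halved
  tail, α = 0.01).
* **Synthetic data** — NB counts over the 4-time-point, 4+3-replicate
  two-species design with planted fold-changes and serum-response sets;
  jittered peak calls over planted shared/species-specific windows with
  opening/closing trajectories; three-taxon promoter/intron alignments
  with planted human-branch acceleration — all with truth tables, and a
  plain-text fixture-bundle writer (BED/TSV/GMT/FASTA + JSON manifest).

`run_pipeline()` chains everything deterministically from one seed;
`inst/scripts/serum_pipeline.R` wraps it for the shell.

## Worked example

```r
library(serumchallenge)

cfg  <- sim_config(n_genes = 1000, n_windows = 400, seed = 42)
expr <- simulate_expression(cfg)

de <- lapply(setNames(nm = levels(cfg$design$time)), function(tp)
  de_test(expr$counts, ~species, ~1,
          samples = cfg$design$sample[cfg$design$time == tp]))
summarize_de_counts(de)
#>   time higher_in_A higher_in_B total ratio_B_A
#> 1  Pre          55          61   116      1.11
#> 2   T0          52          63   115      1.21
#> 3  T12          53          60   113      1.13
#> 4  T24          50          57   107      1.14
```

About 11% of genes are called at 10% FDR per time point — the generator
plants a ±2 log2 species shift in 10% of genes, so the table is the
planted signal plus the controlled false-discovery margin, split by
direction (species A = human, B = chimpanzee).

```r
dhs <- simulate_dhs(cfg)
w   <- build_windows(dhs$peaks)          # harmonized windows, 50-2000 bp
sc  <- score_and_classify(w, dhs$peaks, cfg$design)
classification_summary(sc$windows$class)
#>               class   n
#> 1            shared 199
#> 2 speciesA_specific 131
#> 3 speciesB_specific  70
#> 4          inactive   0
#> 5             total 400
```

The three sharing classes recompose the 400 planted windows exactly
(the generator's 0.475/0.363/0.162 mixture). Clustering the human
trajectories and linking them to the synthetic annotation:

```r
pm   <- standardize_profiles(sc$scores, cfg$design, "human")
m    <- estimate_fuzzifier(pm)           # 2.82 for these dimensions
fc   <- fuzzy_cmeans(pm, choose_cluster_number(pm, 2:6, m, seed = 42)$c,
                     m, seed = 42)
labs <- trajectory_classes(fc)           # membership floor 0.6

links <- nearest_tss(sc$windows, dhs$annotation)
asg <- data.frame(species = "human",
                  label = labs$window_labels,
                  gene  = links$gene[match(names(labs$window_labels),
                                           links$window)])
cluster_gene_summary(asg)
#>   species   label n_windows n_genes ratio
#> 1   human opening        98      51  1.92
#> 2   human closing        45      36  1.25
```

98 windows labeled opening versus 45 closing reflects the planted
0.3/0.1 trajectory mixture restricted to windows active in human, and
the `ratio` column is windows per distinct linked gene — the summary
whose published analogue contrasts opening chromatin concentrated ~2.7
sites per gene against closing chromatin at ~1.4.

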