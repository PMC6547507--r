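# crossfoot

Cross-link-aware genomic footprinting of transcription factors in R.

## The problem

Genomic footprinting infers transcription-factor (TF) occupancy from
nucleotide-resolution DNase I cleavage or Tn5 insertion counts: a bound
protein shields its motif, leaving a local count depletion (a *footprint*)
inside accessible chromatin. Two things routinely defeat it: the probing
enzymes' intrinsic k-mer sequence preferences, and the short chromatin
residence times of many TFs ("dynamic" TFs such as NF-κB or AP-1), which
protect their sites only a small fraction of the time and so leave little
or no footprint in native assays. Mild formaldehyde cross-linking before
DNase digestion can freeze transient binding and deepen those footprints;
the same treatment degrades transposase-based (ATAC) footprinting.

`crossfoot` is for computational biologists analysing such data — or
designing such experiments — and provides the full analysis path:

* per-base cut/insertion count extraction from BED or BAM, depth
  normalisation to 10 M mapped reads, and exact uniform subsampling
  (`extract_cuts`, `normalize_density`, `subsample_track`);
* data-driven k-mer (dimer/tetramer) cleavage-bias estimation and
  bias-adjusted expectations (`fit_bias`, `expected_counts`);
* FDR-controlled footprint detection by binomial depletion tests —
  a count-level statistic, deliberately independent of bias-prone
  cleavage-shape signatures (`call_footprints`);
* per-motif-site footprint z-scores and aggregate profiles
  (`score_sites`, `aggregate_profile`);
* ROC / precision-recall evaluation against reference binding sets, with
  DeLong's test for correlated auROCs (`roc_curve`, `compare_auroc`,
  `precision_recall`);
* TF regulatory networks from footprints near TSSs, compared by Jaccard
  index (`build_network`, `jaccard_index`, `similarity_matrix`);
* a synthetic-data generator that emulates accessible chromatin, sequence
  bias, and residence-time-dependent protection under a cross-link capture
  parameter κ (`simulation_config`, `simulate_genome`, `simulate_cuts`),
  plus one-call orchestration (`run_simulate`, `run_compare`).

## The model in brief

Counts at position *i* are Poisson with strand-summed mean
λ(i)·b(i)·p(i), where λ is the accessibility rate (peak vs background),
b(i) the k-mer bias multiplier at the cut position, and
p(i) = 1 − δ_eff inside truly bound sites. The effective protection

    δ_eff = δ · (κ + (1 − κ)·ρ)

combines a TF's maximal protection δ, its intrinsic residence fraction ρ
(≈ 0.1 for dynamic TFs, 1 for stable ones), and the sample's cross-link
capture efficiency κ ∈ [0, 1]. A candidate window is tested against its
flanks with the lower binomial tail P(X ≤ obs_in | n, p₀),
p₀ = exp_in/(exp_in + exp_flank); overlapping windows are reduced
greedily in ascending p order and Benjamini–Hochberg FDR is applied
across the selected candidates (footprints: q ≤ 0.01). Details and design
rationale are in the methods vignette
(`vignettes/crossfoot-methods.Rmd`).

## Worked example

A native versus cross-linked comparison for one dynamic TF on synthetic
data (1 Mb genome, 200 accessible regions, planted dimer bias, 800 motif
sites at 50% occupancy):

```r
library(crossfoot)

cfg <- simulation_config(
  genome_length = 1e6, n_peaks = 200, peak_width = 400,
  peak_rate = 1.0, background_rate = 0.02,
  bias_table = random_bias_table(k = 2, sd = 0.5, seed = 1),
  tf_specs = list(
    tf_spec("RELA", "GGGACTTTCC", n_sites = 800, occupancy = 0.5,
            protection = 0.9, dynamic = TRUE)),
  seed = 1)
sim <- simulate_genome(cfg)
native <- simulate_cuts(sim, kappa = 0,   label = "native",      stream = 0L)
xl     <- simulate_cuts(sim, kappa = 0.9, label = "crosslinked", stream = 1L)

model <- fit_bias(native, sim$genome, sim$peaks, k = 2)
fp <- call_footprints(xl, sim$peaks, model = model, genome = sim$genome)

score_one <- function(track) {
  sc <- score_sites(track, sim$sites, regions = sim$peaks,
                    model = model, genome = sim$genome)
  roc_curve(label_sites(sc, sim$sites[sim$sites$bound]))
}
roc_n <- score_one(native)
roc_x <- score_one(xl)
compare_auroc(roc_x, roc_n, paired = TRUE)
```

Output (abridged):

```
cut_track 'native' (DNase)
  cut events: 100,629 | total_mapped: 100,629
bias_model: k = 2 ( 16 of 16 k-mers )
  rate range: 0.745 - 1.63
FDR-1% footprints (cross-linked): 159
ROC: 371 positives / 429 negatives; auROC = 0.5396   # native
ROC: 371 positives / 429 negatives; auROC = 0.9947   # cross-linked
DeLong: auROC 0.995 vs 0.540, p = 8.04e-110
```

Read: in the native sample the dynamic TF's sites are barely
distinguishable from unbound ones (auROC 0.54 — it protects its motif
only ~10% of the time), while cross-link capture (κ = 0.9) deepens the
footprints until bound sites are almost perfectly ranked (auROC 0.99);
DeLong's paired test puts the difference far beyond chance, and 159
footprints pass FDR 1% in the cross-linked sample. Setting
`tn5_interference = 1` in the configuration reproduces the opposite,
ATAC-like behaviour, where cross-linking degrades the prediction.

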