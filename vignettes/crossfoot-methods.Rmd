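---
title: "Methods: cross-link-aware TF footprinting with crossfoot"
author: "crossfoot authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-link-aware TF footprinting with crossfoot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossfoot)
```

# The problem

Genomic footprinting infers transcription-factor (TF) occupancy from
nucleotide-resolution DNase I cleavage (DNase-seq) or Tn5 insertion
(ATAC-seq) counts: a protein bound to its motif shields the underlying
bases, leaving a local depletion — a *footprint* — inside otherwise
accessible chromatin. Two obstacles make this hard in practice. First, the
probing enzymes have intrinsic sequence preferences at the cleavage
position, so raw count dips can reflect sequence composition rather than
protection. Second, many TFs bind chromatin only transiently ("dynamic"
TFs, with residence times of seconds); averaged over a cell population
they protect their sites only a small fraction of the time and leave
little or no footprint. Mild formaldehyde cross-linking before digestion
can freeze transient binding in place and deepen those footprints in a
DNase assay, while the same treatment impairs transposase-based assays.

`crossfoot` implements the complete computational path for this setting —
count extraction, bias correction, FDR-controlled footprint detection,
per-site scoring, ROC/PR evaluation against reference binding, and
regulatory-network construction — together with a synthetic-data generator
that emulates the cross-linking physics, so every statistical property of
the pipeline can be validated end to end without external data.

# The synthetic count model

The generator (`simulation_config()`, `simulate_genome()`,
`simulate_cuts()`) draws a random genome of configurable GC content,
places `n_peaks` non-overlapping accessible regions of width `peak_width`,
and plants each TF's fixed motif at `n_sites` non-overlapping positions
inside peaks (random strand; the motif, or its reverse complement, is
embedded verbatim). Each site is truly bound with probability `occupancy`.

Counts are Poisson. On strand $s$ at position $i$ the expected count is

$$ m_s(i) = \tfrac12\,\lambda(i)\, b_s(i)\, p(i)\,(1 - \kappa\iota), $$

with:

* $\lambda(i)$ — `peak_rate` ($\lambda_{\text{peak}}$, default 1 cut/bp, a
  deeply sequenced library) inside peaks, `background_rate`
  ($\lambda_{\text{bg}}$, default 0.02) outside;
* $b_s(i)$ — the bias-table multiplier of the k-mer a cut at $i$ is
  attributed to *on that strand* (see below);
* $p(i) = 1 - \delta_{\text{eff}}$ inside a truly bound site, 1 elsewhere;
* $(1-\kappa\iota)$ — transposase interference (below; $\iota = 0$ for
  DNase-like samples).

We deliberately draw the two strands as independent Poissons with the
strand-oriented bias multiplier, rather than drawing one total and
splitting it 50/50. The enzyme acts on each strand in its own local
sequence context; drawing per strand makes the generator exactly
consistent with the estimator's attribution convention, so parameter
recovery can be tested sharply. The strand-summed count remains Poisson
with mean $\lambda b p (1-\kappa\iota)$ where $b$ is the mean of the two
orientations' multipliers, and with the default strand-symmetric tables
the conditional split is 50/50 binomial.

Overdispersion (negative-binomial noise), paired-end fragment-length
structure, PCR duplicates, mappability, and nucleosome positioning are
deliberately out of scope: the generator validates the statistics of
depletion testing, not library artefacts. A single chromosome (`chrS1`)
is the default.

## K-mer attribution convention

A cut at 0-based position $i$ is attributed, on the plus strand, to the
k-mer spanning $[\,i-\lfloor k/2\rfloor,\; i-\lfloor k/2\rfloor+k)$; for
the default dimer model ($k=2$) this is the dinucleotide whose *second*
base is the cut base, matching the convention that cleavage occurs between
the two bases of the dimer. Minus-strand cuts use the mirror-image window,
reverse complemented. Windows containing `N` or running off the chromosome
get multiplier 1 everywhere (never an error).

## The protection model

For a bound site of a TF with maximal protection $\delta$ and intrinsic
residence fraction $\rho$, the effective depletion is

$$ \delta_{\text{eff}} = \delta\,\bigl(\kappa + (1-\kappa)\rho\bigr), $$

where $\kappa \in [0,1]$ is the *cross-link capture* efficiency of the
sample. $\kappa$ abstracts cross-linker concentration and exposure time
into a single interpretable knob: $\kappa = 0$ is a native sample in which
a dynamic TF protects only during its residence fraction
($\delta_{\text{eff}} = \delta\rho$), and $\kappa \to 1$ freezes transient
binding so that $\delta_{\text{eff}} \to \delta$. Stable TFs have
$\rho = 1$ and are unaffected by $\kappa$. The defaults ($\rho = 0.1$ for
dynamic TFs, $\delta = 0.9$) give native dynamic-TF footprints that are
barely detectable (auROC near 0.55 under the default depth) and captured
footprints that are nearly as deep as stable ones — the qualitative
contrast the method is designed to exploit. No attempt is made to
calibrate $\rho$ or $\kappa$ to a physical formaldehyde concentration or
duration; they are abstractions, and published residence-time data are too
heterogeneous to pin them down.

## Transposase interference

For ATAC-like samples the option `tn5_interference` ($\iota \in [0,1]$)
models the empirical fact that cross-linking *hurts* transposase-based
footprinting. It acts twice: the global rate is multiplied by
$(1-\kappa\iota)$ (cross-linked chromatin yields fewer insertions
overall), and the capture entering $\delta_{\text{eff}}$ is attenuated to
$\kappa_{\text{eff}} = \kappa(1-\iota)$. The second term is essential:
cross-linked (fixed) templates are exactly the ones carrying the deepened
footprints, and if the transposase cannot insert into them those
footprints are never sampled — the surviving reads come from
non-cross-linked templates that look native. A pure depth penalty cannot
reverse the benefit of capture (a deepened footprint survives a tenfold
depth loss easily; we verified this directly), whereas capture attenuation
reproduces the observed reversal: with $\iota$ large, the cross-linked
sample scores *worse* than the native one. This is a documented
demonstration of the mechanism, not a calibrated model of Tn5 chemistry.

## Site placement margin

Depletion tests compare a candidate window against flanks that must lie
inside the same accessible region (background cleavage outside peaks is
orders of magnitude lower, so flanks crossing the peak boundary would
wreck the null proportion). Consequently the outermost `flank_width`
(default 50 bp) bases of each region are structurally untestable. The
generator therefore keeps planted sites at least `site_margin` (default
50 bp) away from peak edges — matching the default flank width, and
consistent with the biological tendency of functional motifs to sit in
peak interiors rather than at accessibility boundaries.

# Bias estimation

`fit_bias()` estimates the enzyme's k-mer preference directly from the
data, as a ratio estimator over background intervals:

$$ r(w) = \frac{\text{fraction of cuts attributed to } w}
               {\text{fraction of background bases whose k-mer is } w}, $$

renormalised to background-weighted mean 1. Background k-mer frequencies
count both orientations of every base, mirroring the cut attribution, so
unbiased data give $r(w) = 1$ for all $w$ up to sampling error. The
background defaults to the supplied accessible regions (not the whole
genome) because all downstream tests run inside peaks; a whole-genome
background can be supplied instead. K-mers absent from the background are
excluded (and reported); `k = 0` yields the uniform, unadjusted model, and
`k = 4` a tetramer model. A single shared table is used for both strands
(minus-strand cuts are reverse complemented before lookup), which halves
the variance and is standard practice.

One known bias-of-the-bias: cuts inside true footprints are not masked
during fitting, so deep and frequent footprints slightly flatten the
estimated table. At realistic footprint densities (a few percent of peak
bases) the effect is negligible — recovery of planted dimer tables
achieves Pearson $r > 0.99$ on log rates at the default depth.

`expected_counts()` converts rates to expectations by local
renormalisation: the observed total of an interval is distributed over its
positions proportionally to $r$, so interval totals are conserved exactly
and only rate *ratios* ever matter downstream.

# Footprint detection

`call_footprints()` is a count-level detector: it tests total depletion of
a window against its flanks and makes no use of cleavage-shape signatures,
which are the most bias-prone feature of footprint data. Within each
region every window of width 6-40 bp (stride 1) is scored against the
pooled 50 bp flanks on each side via the binomial lower tail:

$$ n = o_{\text{in}} + o_{\text{fl}}, \quad
   p_0 = \frac{e_{\text{in}}}{e_{\text{in}} + e_{\text{fl}}}, \quad
   p = P\bigl(X \le o_{\text{in}}\bigr),\; X \sim \mathrm{Bin}(n, p_0), $$

with expectations from the bias model. The signed z-score
$(o_{\text{in}} - np_0)/\sqrt{np_0(1-p_0)}$ (negative = protected) is kept
for site-level scoring. $n = 0$ is defined as no evidence ($p = 1$,
$z = 0$).

Overlapping windows are then reduced by greedy selection in ascending
p-value order (ties: wider window first, then leftmost start), and
Benjamini-Hochberg FDR is applied *across the greedy-selected,
non-overlapping candidates genome-wide* — not across all overlapping
windows, whose tests would be massively dependent. Footprints are the
selected candidates with $q \le$ `fdr` (default 0.01, i.e. FDR 1%). Pooling
the two flanks rather than testing them separately buys robustness to
one-sided peak-edge effects. Regions shorter than
`min(width) + 2 * flank_width` cannot host any testable window and are
skipped (counted in the `skipped` attribute).

Selecting minima of correlated p-values before BH is mildly
anti-conservative in principle; empirically, on null simulations with a
planted dimer bias corrected by a fitted model (20 seeds, 1 Mb), the
FDR-1% call fraction stays orders of magnitude below 1% of selected
candidates, because binomial p-values at realistic depths are too coarse
for selection alone to reach the BH threshold. The calibration is
re-checked by the acceptance suite on every run.

Depth-matched comparison across samples composes uniform event
subsampling (exact multivariate hypergeometric draws), calling, and
counting, averaged over five rounds by convention
(`count_footprints_subsampled()`).

# Motif-site scoring and profiles

`score_sites()` applies the same depletion statistic to fixed motif
sites versus their 50 bp flanks, after restricting to sites fully inside
the supplied accessible regions (dropped sites are counted). Sites are
scored independently, without deduplication of overlapping occurrences.
`aggregate_profile()` averages strand-summed counts around motif centres
(centre $= \lfloor(\text{start}_0+\text{end}_0)/2\rfloor$), reversing
minus-strand sites so profiles are motif-oriented; offsets that fall off
the chromosome are excluded per site rather than zero-padded. Aggregate
profiles are provided for inspection, but individual-site scores are the
unit of evaluation: averaging over heterogeneous sites hides exactly the
occupancy differences one is after.

# Evaluation against reference binding

`label_sites()` marks a site positive iff it overlaps a reference binding
peak by at least 1 bp (half-open convention: an abutting site is
negative). `roc_curve()` sweeps thresholds over unique scores (ties
grouped into single vertices), with the convention that more negative
z-scores mean more bound; the trapezoidal auROC then equals the
tie-corrected Mann-Whitney statistic, which the test suite verifies
against exhaustive pair counting. `precision_recall()` uses the same tie
grouping and a step-wise integral for average precision, for the common
case of heavily unbalanced labels.

`compare_auroc()` implements DeLong's placement-based variance estimate
for the difference of two auROCs. The paired variant (two scorings of the
same sites — the natural comparison across cross-linking conditions)
accounts for the covariance between curves and refers $z$ to a normal;
the unpaired variant adds independent variances and uses a
Welch-Satterthwaite t reference, matching the behaviour of the widely
used `pROC` implementation, against which the test suite checks both
variants to 6 decimals.

# Regulatory networks

`build_network()` emits a directed edge $A \to B$ when an FDR-filtered
footprint overlaps (≥ 1 bp) a motif site of TF $A$ whose centre lies
within 5 kb of the transcription start site of gene $B$. Distance is
measured from the motif-site centre to the TSS point; with several TSS
records per gene the nearest is used. Every edge carries its full
evidence list (footprint, site, q-value, signed distance). Networks are
compared by the Jaccard index of their edge sets (`jaccard_index()`,
`similarity_matrix()`), and `edge_diff()` tri-partitions two edge sets
into shared and condition-specific edges — e.g. the edges recovered only
after cross-linking. Two empty networks are defined as identical
(Jaccard 1) with a warning rather than an error, so grid comparisons never
abort on a degenerate sample.

# Determinism and numerical choices

All randomness flows from a single master seed through deterministic
child streams (one per generator operation), so adding an operation never
perturbs earlier draws, identical configurations yield byte-identical
outputs, and the full demonstration pipeline re-run under a fixed seed
reproduces every output file bit for bit. Library code saves and restores
the caller's RNG state.

Default geometry: footprint widths 6-40 bp, flanks 50 bp per side,
FDR 1%, dimer bias model, 5 kb TSS window, ATAC shift +4/−5 (the
field-standard Tn5 offset; configurable, off for DNase), MAPQ ≥ 10 for BAM
input, duplicates retained by default (cut pileups are the signal at high
depth; a `drop_duplicates` flag is provided).

The validation suite exercises the pipeline at problem sizes chosen to
make every stochastic assertion sharp yet cheap: 0.5-2 Mb genomes,
100-400 peaks of 400 bp, up to 2,000 motif sites, 10-20 independent seeds
for calibration and recovery checks, and 3-SE tolerances for Monte-Carlo
comparisons. These sizes are the package's own validation choices;
nothing in the method depends on them.

# What passing tests do and do not show

The generator reproduces the statistical structure the pipeline reasons
about — Poisson cut counts with k-mer bias, occupancy-dependent depletion
whose depth responds to capture, accessible regions on a neutral
background, and truth-matched reference binding and TSS annotations. It
does not emulate overdispersion, chromatin heterogeneity between cells
beyond the binary bound/unbound mixture, soft (informational) motif
matches, duplicated or unmappable sequence, or nucleosome footprints.
Passing the suite therefore demonstrates that the statistics are
implemented correctly and calibrated under the stated model, and that the
cross-linking contrast is recovered when the model's assumptions hold; it
does not by itself guarantee the same power or calibration on real
libraries, where the bias model and the Poisson assumption are
approximations.

# A minimal session

```{r example, eval = FALSE}
cfg <- demo_config(seed = 1)
sims <- run_simulate(cfg, "demo_sim", kappa_grid = c(0, 0.5, 0.9))
ref <- lapply(setNames(nm = names(cfg$tf_specs)), function(tf)
  sims$sim$sites[sims$sim$sites$tf == tf & sims$sim$sites$bound])
res <- run_compare(sims$tracks, sims$sim$genome, sims$sim$peaks,
                   sims$sim$sites, reference_peaks = ref,
                   tss = sims$annotations$tss, out_dir = "demo_out",
                   subsample_to = "min")
res$roc_summary
res$jaccard
```
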