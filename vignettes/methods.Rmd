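---
title: "From fluorescence traces to functional organization: the caimnet methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From fluorescence traces to functional organization: the caimnet methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caimnet)
```

caimnet analyzes calcium-imaging recordings of *clustered* neuronal
cultures: networks of tens of neuronal islands (clusters) grown in
millimetre-scale cavities, each cluster imaged as one ROI at 20 ms frames.
The pipeline runs

traces → onsets → firing sequences → (activity statistics, functional
connectivity, communities, topology)

and ships a synthetic generator that produces ground-truth activity with
the same statistical structure, so every stage can be validated against a
known answer. This vignette explains each model and the choices behind the
defaults.

## The synthetic generator

The generator is a statistical emulator of a clustered culture, not a
biophysical model. A `ca_network` places `n_clusters` uniformly in a
3.5 mm cavity and assigns spatially contiguous communities (consecutive
angular sectors, sizes within one cluster of each other). Activity has
three ingredients:

* **Community events.** Each community ignites as a homogeneous Poisson
  process (`ignition_rate`, default 2 events/min per community). A Poisson
  renewal process is the simplest model consistent with collective events
  separated by a few seconds with no claimed temporal structure.
* **Recruitment.** Each member joins its community's event with
  probability `participation` (0.75), outsiders join with
  `cross_participation` (0.05); joiners receive exponential delays with
  scale `delay_scale` (30 ms), so a 5–15-cluster event spans roughly
  100 ms (the expected maximum of ~10 exponential delays is about three
  times the scale).
* **Independent firing.** A small per-cluster Poisson rate
  (`independent_rate`, 0.1/min) models clusters firing outside collective
  events.

With the defaults and 3 communities of 12, a cluster fires at about
2 × 0.75 + 4 × 0.05 + 0.1 ≈ 1.8 times/min — inside the 1–2 firings/min
band typical of these cultures — and the culture produces ~6 collective
events/min, i.e. inter-event intervals of a few seconds.

**Ignition scales with recruitment mass.** A community's effective
ignition rate is its nominal rate multiplied by the current *recruitment
mass* (summed member participation plus outsider cross-participation)
relative to the unperturbed mass. Collective ignition is a recruitment
phenomenon: a community whose members are silenced or whose couplings are
weakened ignites less often. Without this coupling, silencing clusters
would leave the sequence rate Ψ untouched (events would still ignite and
still recruit ≥ 2 members), which contradicts what chemical damage does to
these cultures.

**Perturbations** (`perturbation_spec`) emulate chemical insults: a
fraction of clusters silenced outright (participation and independent rate
zeroed), multiplicative weakening of cross-community (and optionally
within-community) participation, and boosting of independent firing in a
subset. Magnitudes are free parameters — no quantitative dose→effect
mapping exists — with defaults grading from near-identity (magnetic
nanoparticles) to severe (30% silenced, cross-coupling × 0.3).

**Traces.** Each onset contributes a transient with a 50 ms linear rise,
1 s exponential decay and unit amplitude (typical bulk Fluo-4 kinetics at
room temperature), superposed on a zero baseline with white Gaussian noise
(sd 0.05, i.e. SNR 20).

What the generator does *not* emulate: photobleaching and slow baseline
drift, motion artifacts, heterogeneous per-cluster amplitudes and
kinetics, inter-community event correlations, and bursty (non-Poisson)
ignition. Passing tests therefore show the analysis recovers the
structure this model encodes, not that it is robust to every artifact of
real recordings. One consequence worth naming: because clusters join
foreign communities' events *independently*, a cross-community pair is
always slightly anti-correlated relative to a null that preserves
marginal participation rates, so baseline graphs have essentially no
significant cross-community links. Real cultures do show such links, so
analyses whose substance is the pruning of integrative links (e.g. a
rising local-efficiency ratio after damage) are not reproduced by this
generator.

## Onset detection

A cluster firing ramps the fluorescence sharply, so onsets are frames
where amplitude and derivative are concurrently high:

* baseline: running 10th percentile over a 30 s window (robust to
  transients, tracks slow drift), evaluated on half-window blocks and
  interpolated;
* noise sd: 1.4826 × MAD of the residual; thresholds are centered on the
  residual *median*, because the percentile baseline sits ~1.3 sd below
  the noise mean and an uncentered "3 sd" would effectively be 1.7 sd;
* derivative: forward difference of a 3-frame smoothed trace, with its own
  MAD scale;
* candidate events: runs of ≥ 3 consecutive frames above the `amp_k` = 3
  amplitude threshold whose peak reaches twice that threshold. Noise
  excursions last one or two frames and graze the threshold; transients
  last ~100 frames and peak at ~20 sd. The onset is the first frame of
  the run where the derivative exceeds its `deriv_k` = 2 threshold, and
  onsets closer than 500 ms merge.

The thresholds are conventions, not measured constants; they are
config-overridable and logged. On synthetic recordings at SNR 20 the
defaults give precision and recall of about 0.95. Two limitations are
inherent: a transient starting on the decay shoulder of another (< ~1 s
apart) may be merged, and raising `amp_k` can occasionally *split* such a
merged event, so threshold-monotonicity of the onset count holds only for
separated transients.

## Sequences and the coactivation matrix

A firing sequence is the concatenated activation of ≥ 2 distinct clusters
with consecutive onsets ≤ 200 ms apart; the same gap separates sequences.
Chaining uses the gap to the *previous* onset (not to the sequence start).
A cluster firing twice inside one chain keeps its first activation — the
coactivation matrix is binary and delays need one time per cluster.
Single-cluster chains (independently firing clusters) are discarded. The
N × M binary matrix `X` records which cluster joined which sequence; its
rows are activity histories.

## Activity statistics and drift correction

φ_i is the firing rate of cluster i (firings/min), Φ their mean over all
clusters (silent ones included), Ψ the number of sequences per minute.
Slow changes in temperature or medium between the two recordings shift
every cavity's activity; this common-mode drift is estimated from the
unperturbed control cavity as r = Φ_C,2/Φ_C,1 (and r_Ψ from the control
Ψ), and perturbed-cavity second-recording quantities are divided by it.
Division (not subtraction) because drift is multiplicative on rates. If
the control has no sequences in a recording, r_Ψ falls back to r with a
warning; a fully silent control is an error — drift is unmeasurable.

Per-cluster change is summarized by the bounded normalization
(φᴾ − φ⁰)/(φᴾ + φ⁰) ∈ [−1, 1], zero when both silent, −1 for clusters
silenced by the insult. It is antisymmetric under swapping conditions.
The distribution is summarized by a least-squares Gaussian fit (μ, σ) on a
Freedman–Diaconis histogram and the bias-corrected Fisher skewness γ
computed from the raw sample (γ is defined as 0 for degenerate samples).
Condition comparisons use the two-sided Student's t-test within clustered
cultures and the Kolmogorov–Smirnov test across culture types; stars are
`*` p < 0.05, `**` p < 0.005.

## Functional connectivity

Within each sequence, every ordered pair activating at t_i < t_j adds
exp(−(t_j − t_i)/τ) to the directed weight w_ij; earlier activation leads.
The exponential with τ = 0.2 s (the sequence window) is the minimal
decaying kernel at the only timescale the sequence definition introduces;
both the form and τ are configurable. Simultaneous activations contribute
1 in both directions — there is no basis for breaking ties.

Raw weights are not comparable across recordings, so they are z-scored
against a null that preserves each cluster's number of firings: each
cluster's participation row is independently *cyclically shifted* across
sequence slots (destroying co-activation structure, preserving counts),
and each surrogate sequence reassigns its slot's observed relative
activation times by random permutation to its new members (drawing from
the pooled delay distribution only when a surrogate sequence outgrows its
slot). W = (w − mean_surr)/sd_surr, with W = 0 where sd_surr = 0 (pairs
never co-active in the null — avoids division blow-ups). Links with
W > 1.95 (upper tail of the ≈95% interval, 500 surrogates) are
significant; negative scores mean "less co-active than chance" and are
disregarded. On community-free synthetic activity the fraction of
significant links is below ~1%, i.e. the null is calibrated, slightly
conservatively (the z-distribution is light-tailed, so the 1.95 cut is
stricter than its Gaussian nominal 2.5%).

Between-condition change is the difference of z-scored weights on the
union of significant links (absent link = 0); its location (median) and
skewness summarize whether damage removed or added coupling.

## Communities

The Jaccard similarity of two activity histories is the number of
concurrent activations over the occurrences where at least one fired;
pairs of silent clusters are defined as 0. Raw Jaccard distances
D = 1 − J are z-scored against 500 surrogates that permute each row of X
independently (preserving per-cluster firing counts):
Z = (mean(S) − D)/sd(S), positive when more similar than chance, and
mapped to a bounded distance D_norm = 1 − Φ_N(Z) (standard normal CDF).
The CDF mapping is monotone, bounded in [0, 1] and comparable across
recordings; sd = 0 pairs sit at 0.5, and silent clusters are forced to
distance 1 so they end as singleton communities. Average-linkage
clustering (stats::hclust) builds the dendrogram; cutting at distance d
keeps subtrees merging above d, with labels assigned in leaf order.

**Threshold selection.** Partitions are scanned at thresholds in steps of
0.01 from 0 past the top merge. For each threshold, MVI is the mean
Variation of Information between its partition and the partitions at all
other thresholds; VI = H(X|Y) + H(Y|X) in bits (base 2 — any base only
rescales). Jumps of ΔMVI bound plateaus of stable structure. The selected
threshold is the midpoint of the plateau with *minimal* MVI among
partitions with ≥ 2 communities: the structure that disagrees least with
every other scale, i.e. the minimal yet significant community structure
short of the trivial single community. On the five-cluster worked example
(histories {1,2,5}, {1,2,5}, {1,2}, {3,4}, {3,4}) this selects two
moduli, {1,2,5} and {3,4} — any cut along that plateau, e.g. d = 0.75,
gives the same partition — and on planted 2- and 3-community synthetic
cavities it recovers the ground truth with VI = 0. A literal
"largest ΔMVI jump" rule is unstable here because normalized distances
saturate near 0 and 1, making the first scan step (singletons → blocks)
always the largest jump.

Before/after comparison reports the moduli counts, the VI between the two
partitions, and the split/merge mapping of communities.

## Network topology

Five descriptors of the significant-link graph (z-scored weights):
node strength (in + out); global efficiency (mean inverse geodesic over
ordered pairs, lengths = inverse weights after rescaling by the maximum
weight; disconnected pairs contribute 0); local efficiency (mean over
nodes with ≥ 2 neighbors of the efficiency of the in/out-neighbor
subgraph); the directed weighted clustering coefficient (Fagiolo's
triangle fraction, averaged over nodes with ≥ 2 neighbors); and
assortativity, the Pearson correlation of total weighted degree across
directed links — defined as 0 when all linked degrees are equal (regular
graphs) and missing on an empty graph. Geodesics come from igraph's
Dijkstra implementation. After/before ratios divide element-wise, with
zero denominators giving NA rather than errors. Uniform weight scaling
moves only the strength ratio; efficiencies and clustering are invariant
by construction.

## Homogeneous cultures

Homogeneous cultures show all-or-none network bursts instead of community
structure; ROIs are grid elements (30 × 30 per cavity, ~5–10 neurons
each). A burst is a sequence (same chaining rule) engaging at least half
of all ROIs (`min_fraction = 0.5` — a convention; the all-or-none regime
makes the result insensitive to it). The effect of an insult is the
burst-count ratio after/before, divided by the control's ratio, mirroring
the drift correction of clustered cavities.

## The experiment pipeline

`run_pipeline()` drives the standard four-cavity layout (one control plus
up to three perturbed cavities) from a single config (R list or YAML):
simulate → render traces → detect onsets → sequences → summaries →
graphs → communities → topology, then drift-corrects and assembles a
JSON-ready summary. Every stage seed derives deterministically from the
master seed, so a rerun of the same config is byte-identical; the summary
records the config hash. Setting `from_traces = FALSE` analyzes
ground-truth onsets directly (useful to separate detection error from
downstream statistics).

## Problem sizes and numerical choices

Validation uses 30–36 clusters in 2–3 communities and 30-minute
recordings — the size of a real cavity experiment — with 500 surrogates
for both nulls; unit tests use smaller, faster configurations since the
properties they check are size-independent. Further conventions:
dendrogram ties are resolved deterministically by hclust's ordering;
degenerate samples (constant, empty) yield defined values (skewness 0,
Jaccard 0, W = 0) rather than NaN; all RNG flows through per-call seeds
and the global RNG state is restored afterwards.
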