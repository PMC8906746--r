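---
title: "Methods: population-genomic analyses of betta domestication"
author: "bettapop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-genomic analyses of betta domestication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

bettapop packages, as reusable and tested functions, the computational
analyses used to dissect the domestication history of the Siamese fighting
fish (*Betta splendens*): where did ornamental betta come from, how strong
was the domestication bottleneck, which genomic regions were swept during
breeding, how is sex determined, and how are color phenotypes quantified.
Because the underlying resequencing data are not redistributable, every
stage is driven by a coalescent-backed synthetic-data generator whose
defaults mirror the study conditions; this vignette explains each model,
its assumptions, the tunable parameters, and what the synthetic tests do
and do not demonstrate about real data.

## The synthetic-data generator

`simulate_panel()` draws phased haplotype panels under a user-specified
demography (populations, splits, admixture pulses, instantaneous
bottlenecks) with the msprime coalescent engine, called through a bundled
Python backend. Defaults follow the study constants: mutation rate
$\mu = 3.75\times10^{-9}$ per bp per generation, recombination
6.6 cM/Mb, and a genome of 21 chromosomes (14 Mb each at full scale; most
tests use a scaled-down genome — e.g. 21 × 2 Mb for bottleneck work and
4 × 2 Mb for the species scenario — so the whole suite runs on a desk
machine; statistical expectations are unchanged by genome length, only
their variance).

`default_scenario()` provides the five-population history used throughout:
an outgroup, two candidate donor species (mahachaiensis-like and
imbellis-like), wild splendens, and an ornamental population splitting
from wild splendens 4,000 generations ago. The interspecies split times
(120k/250k/500k generations at $N_e$ = 10,000) are generator
configuration, not study estimates: they are chosen deep enough that
donor haplotypes are clearly differentiated (as the real species are) and
are not meant to date the real radiation.

Planted signals provide ground truth: `plant_tracts()` copies donor
haplotypes into a recipient over an interval (introgression),
`plant_sweep()` copies one core haplotype onto a fraction $f$ of a
group's haplotypes (sweeps), `assign_sex()` draws gonadal sex from XX/XY
status with configurable penetrance, and `observe_trio()` adds a
read-count observation layer (Poisson depth, binomial allele counts,
re-called genotypes) to true trio genotypes. In the group-differential
scan test the planted sweep uses $f = 1$: the emulated signal is the
near-fixed dmrt1-class sweep, and a hard sweep makes the planted truth
unambiguous. The trio observation model calls a genotype heterozygous
when the minor-read fraction is at least 0.2 and scales GQ as the
phred-gap between the best and second-best binomial likelihood (capped at
99); this is deliberately simple — only the downstream behavior of the
filters matters, not the calling model itself.

What the generator does *not* emulate: alignment artifacts, indels and
structural variation, base-quality error profiles, population structure
within populations, and phasing errors. Tests passing on these panels
show the statistics and callers are implemented correctly, not that the
filters would remove every artifact class in real sequencing data.

## Genotype filtering and the Mendelian-error ROC

`apply_filters()` implements the study thresholds (site MQ ≥ 50; genotype
GQ ≥ 30, DP ≥ 4, ≥ 2 reads per called allele; heterozygote VAF within
[0.25, 0.75]; paired removal of variants within 3 bp; site missingness
≤ 0.2). Genotype-level rules run before site-level rules because
missingness is defined over nulled genotypes. The "two reads supporting
the genotype" rule is read as: both alleles of a het, or the single
allele of a homozygote, need ≥ 2 reads. `filter_roc()` traces retained
variants against trio Mendelian errors over a threshold grid — the
procedure used to choose the thresholds in the first place.
`coverage_region_mask()` flags 1000-bp windows (500-bp slide) whose
log2-median-normalized counts deviate > 2.5 SD within a sample, or whose
cross-sample variance exceeds the median variance by > 2.5 SD. Mappability
masking is not reimplemented: in the study nearly all (98%) of
mappability-masked regions were already caught by the coverage filter.

## Introgression: quartet statistics and tract calling

`pattern_stats()` computes Patterson's D and $f_4$ from group
derived-allele frequencies, with a 20-block equal-SNP jackknife Z. The
windowed statistic is $f_{dM}$ (100-SNP windows, 25-SNP step), the
bounded, symmetric modification of the $f_d$ admixture estimator: the
denominator replaces the donor frequency with
$p_D = \max(p_2, p_3)$ when $p_2 \ge p_1$ (and symmetrically with
$p_1$ otherwise, negated), so positive values indicate gene flow into
p2 and negative into p1. The original analysis cites but does not restate
this definition, so it is fixed explicitly in `fdm_scan()`.

Tract calling follows the study chain: MAD winsorization (running window
of 15 f_dM windows, clip at 3 × 1.4826 × MAD around the running median;
parameters are configurable — they are chosen to clip single-window
outliers without flattening multi-window tracts), then least-squares
changepoint segmentation. The segmentation algorithm was not named in the
study; optimal partitioning with a BIC-style penalty
($2\hat\sigma^2 \log T$ per changepoint, $\hat\sigma$ from robust first
differences) is used because it is deterministic and exact; any method
passing the noiseless-step oracle (changepoint within ±1 window) is
conformant. Segments with mean $f_{dM} > 0.2$ (the valley of the
empirically bimodal segment-mean distribution; configurable) are kept and
merged across gaps ≤ 5 kb. Tract endpoints are the midpoints of the first
and last constituent windows, which slightly shrinks every called tract —
the round-trip acceptance uses 80-kb planted tracts, where this boundary
loss is a small fraction.

`assign_ancestry()` resolves the donor of a called tract with the
local-tree rule: an NJ tree over the tract haplotypes, then mean
patristic distance from the focal haplotype to each species. A donor is
accepted iff (a) the focal haplotype is closer to it than to the
conspecific (splendens) references and (b) closer than the mean + 2 SD of
the within-splendens pairwise distances. The study's "2 SD" sentence is
ambiguous about which distance it bounds; this implementation bounds the
candidate donor distance and does not silently change that reading.
Local trees are NJ rather than maximum likelihood: at the level compared
(topology and assignment on clean tracts) the two agree, and NJ removes
an external dependency. Exact ties are reported `unassigned` rather than
resolved arbitrarily.

## Selection scans and the permutation test

`h_scan()` is the pairwise identity-tract statistic: for every haplotype
pair the bp length of the maximal identical run containing the focal
SNP, truncated at the terminal SNPs (no extrapolation beyond data),
averaged over pairs; a pair discordant at the focal SNP contributes 0.
`g_stats()` computes G1, G12 and G2/G1 over 200-SNP windows from the
window haplotype spectrum. `tajima_d()` uses the standard constants in
10-kb windows with 100-bp slide, dropping windows with ≤ 3 kb accessible.
`ld_r2()` computes haplotype $r^2$ (MAF ≥ 0.2, pairs ≤ 999 kb, 3-bp decay
bins) and an interchromosomal baseline after 100-kb thinning.

`delta_scan_permutation()` tests group differences in a scan: loci are
clumped into LD blocks (consecutive sites chained while adjacent
$r^2 > 0.8$; the study does not give its algorithm), each clump
represented by its maximum value per group (the maximum, not the mean,
because a sweep needs only one extreme locus per block; configurable).
Per chromosome the pooled clump values of both groups are randomly
reassigned 1000 times preserving group sizes, and the genome-wide
threshold is the 99th percentile of all permuted $|\Delta|$ (the Methods'
$\alpha = 0.01$; a figure legend elsewhere says $\alpha = 0.05$ — the
discrepancy is surfaced by making the percentile an argument, defaulting
to 99). The permutation pool is sorted before reassignment so the
threshold is exactly invariant to swapping the group labels. Because the
pooled null contains any true signal, the test loses power when a sweep
occupies a non-trivial fraction of the genome; the synthetic power check
therefore plants a 30-kb sweep in an 8-Mb genome, qualitatively matching
the study's regime of small sweeps in a large genome.

## Bottleneck inference from the SFS

The demographic contribution is the single-instantaneous-bottleneck
model: a constant diploid $N_e$ whose coalescent receives $I$ extra
units of coalescent opportunity (intensity, $I =$ duration / (2
$N_{e,\mathrm{bottleneck}}$)) at $T_b$ generations ago, with no real
time elapsing. `expected_sfs()` computes $E[\xi_i] = \mu L \, E[B_i]$ by
Monte Carlo over the genealogical lineage-count chain combined with the
exact exchangeable-coalescent probability that a lineage among $k$
subtends $i$ of $n$ leaves, $\binom{n-i-1}{k-2}/\binom{n-1}{k-1}$; this
is equivalent to averaging over full genealogies but needs no trees. At
$I = 0$ the constant-size closed form $\theta L / i$ is the correctness
oracle.

`fit_bottleneck()` maximizes a composite likelihood by Nelder-Mead on
transformed parameters ($\log N_e$; $T_b$ logistic-bounded in (1, 3000];
$I = x^2$ so the no-bottleneck boundary is reachable), from five seeded
random restarts plus a start at the null optimum, each polished by a
second simplex pass. Every likelihood evaluation re-seeds the Monte Carlo
(400 lineage-chain replicates by default) with the same stream — common
random numbers — so the surface is deterministic within a fit. The
default likelihood is Poisson across SFS classes rather than
multinomial-given-S: with the monomorphic classes excluded, the
multinomial shape depends only on $(T_b/2N_e, I)$, so $N_e$ and $T_b$
sit on an exact ridge and the bottleneck time is unidentifiable; the
Poisson form factorizes into that same multinomial shape times a Poisson
term for the total segregating-site count, and it is the total count that
pins $N_e$. A multinomial option is retained for shape-only work. The
null model ($I = 0$) is fitted with the same Monte Carlo machinery and
its optimum seeds one alternative start, so the reported alternative
likelihood can never fall below the null. `coalesced_fraction()` reports
the Monte Carlo mean of (lineages entering − lineages leaving)/(entering)
at the burst — an explicit convention, stated because the study's
software may count differently.

Desk-scale validation mirrors the study's grid design at reduced genome
size: 35 diploids on 21 × 2-Mb chromosomes, bottleneck at the middle
timing (500 generations) with intensity 0.4, five replicate panels;
recovery is judged within a factor of two of truth, and constant-size
data must prefer the null.

## Sex-determination statistics and color phenotyping

The sex module wraps exact tests in the study's framing:
`penetrance_report()` (XX→female and XY→male rates with binomial tests
against 0.5 and a cross-cohort Fisher comparison of XX penetrance),
`ase_test()` (allele-specific expression against a balanced binomial),
`class_diversity()` (per-class X/Y nucleotide diversity and the Y:X
ratio), and `bonferroni_threshold()` ($-\log_{10}(\alpha/\text{blocks})$).
Two-sided exact tests use the point-probability rule (sum of outcomes no
more likely than observed) — the study does not state its sidedness
convention, and one of its printed binomial values (0.00048 for 10 of 11)
matches no standard test of those counts, so it is documented but not
asserted anywhere. `site_association()` is a plain allelic Fisher test
after MAF/missingness/LD-prune presets; it deliberately omits the
kinship-corrected mixed model used on the real cohort and is intended
only for synthetic panels where relatedness is controlled.

Color phenotyping classifies calibrated HSV pixels with the study's
ranges (red hue [0, 0.045] ∪ [0.98, 1]; blue [0.6, 0.728]; black value
≤ 0.3, taking precedence, with hue classes requiring value > 0.3; no
saturation gate). The iterative range-derivation procedure is not re-run;
the ranges are constants. Calibration is a least-squares affine transform
in linear RGB fitted on the 24 color-checker patches; hue statistics use
circular means. `make_color_fixture()` builds images with known class
proportions for recovery tests; it does not emulate lighting gradients,
specular highlights, or segmentation error.

## Numerical choices and limitations

* Windows in SNP units (f_dM, G) drop partial tail windows; windows in bp
  (Tajima's D, diversity) are emitted with their accessible length and
  dropped below 3 kb accessible.
* Undefined statistics (zero denominators, S = 0, empty classes) are NA
  with a reason, never silently zero.
* All stochastic functions take an integer seed and restore the caller's
  RNG state; simulation outputs record their seed.
* The coalescent backend is exact but neutral: no selection is simulated,
  so planted sweeps are idealizations (instant copy of a core haplotype)
  rather than trajectories.
* Recovery percentages quoted for tract calling depend on tract length;
  sub-20-kb tracts lose a large boundary fraction to the window/segment
  resolution and are not claimed.
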