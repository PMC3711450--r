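---
title: "Calling viewpoint interactions from 3C-seq data: methods and design"
author: "viewcall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling viewpoint interactions from 3C-seq data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viewcall)
```

## The problem

Viewpoint-anchored chromosome conformation capture sequencing (3C-seq,
equivalently 4C-seq) asks a single question of the genome: which loci are in
physical contact with one chosen restriction fragment, the *viewpoint*?
Cross-linked chromatin is digested with a 6-cutter (HindIII, EcoRI, BamHI,
...), ligated under dilution so that spatially proximal fragments join,
and the viewpoint's ligation partners are amplified by inverse PCR and
sequenced. After primer trimming and alignment, each read's 5' end marks
the restriction-fragment boundary of one captured partner.

Two systematic features dominate the raw counts. First, sequencing depth
differs between libraries, and the per-region count distribution is heavy
tailed, so naive scaling misbehaves. Second, contact frequency decays
strongly with genomic distance from the viewpoint — nearby loci are
cross-linked by random proximity, not specific interaction. An interaction
caller must normalize the first and model away the second before any
region can be declared significantly contacted.

`viewcall` implements the full path from aligned reads to calls: in-silico
digestion, fragment- or window-level counting, power-law normalization,
distance-decay background correction with a cubic smoothing spline,
Z-score/p-value/q-value interaction scoring in cis and trans, replicate
combination, gene annotation, track export and domainogram matrices —
plus a generative simulator so that the entire pipeline is testable with
known ground truth.

## Fragment map and counting

`digest_genome()` cuts at every exact occurrence of the recognition site.
The cut is placed at the first base of the site, so the site belongs to the
downstream fragment; this matches how primer-trimmed 3C-seq reads abut the
site boundary. An enzyme's biochemical cleavage offset within the site can
be supplied (`cleavage_offset`, default 0) but is rarely needed, since only
fragment boundaries — not the few bases around them — carry information
here. IUPAC codes in the site expand to character classes; ambiguous bases
in the genome (`N` runs) never match, which errs on the side of longer
fragments rather than spurious cuts. Palindromic sites (every common
6-cutter) are searched on the forward strand only.

In memory, every interval lives in a `GRanges` with the usual Bioconductor
1-based closed coordinates; every file written or read (BED, bedGraph,
TSV) uses BED-style 0-based half-open coordinates. Keeping one convention
per medium and converting only at the I/O layer avoids the classical
off-by-one zoo.

Reads are assigned to regions by their strand-aware 5' position — the
ligation-junction end — not by midpoint or overlap, because a 3C-seq read
starts where the captured fragment was ligated. The *informative-read*
filter keeps only reads whose 5' end lies within `tolerance` bp of a
fragment boundary; true ligation junctions abut restriction sites, whereas
reads from incompletely digested or randomly sheared chromatin start
anywhere. The default tolerance is 1 bp: end repair and aligner soft-clip
rounding commonly shift a read by a single base, and a strict 0 remains
selectable. Duplicate reads are *not* collapsed by default — distinct
ligation events from the same junction legitimately share coordinates — but
`collapse = TRUE` keeps one read per (chromosome, 5', strand). The mapping
quality cutoff defaults to 10, enough to remove most multi-mappers without
thinning the library.

Window-based counting (`count_per_window()`) tiles each chromosome with
fixed windows (minimum 1 kb); the overlapping mode steps by half a window
so each read lands in two windows, smoothing the arbitrary phase of the
tiling.

## Power-law normalization

Per-region 3C-seq counts, like CAGE and ChIP-seq counts, approximately
follow a power law: the reverse cumulative
$R(t) = \#\{\text{regions with count} \ge t\}$ is close to linear in
log–log space. `fit_powerlaw()` removes regions with fewer than
`min_count` (default 50) reads and the viewpoint fragment ± 1 neighbour
(self-ligation signal), evaluates $R(t)$ at each distinct observed count,
and fits $\log_{10} R = l + \alpha\,\log_{10} t$ by unweighted ordinary
least squares.

`powerlaw_normalize()` then maps every count onto a fixed reference law
with exponent $\alpha_{\mathrm{ref}} = -1.35$ and library size
$n_0 = 10^6$ reads:

$$ t' = 10^{\left(l + \alpha \log_{10} t - l_{\mathrm{ref}}\right) / \alpha_{\mathrm{ref}}}. $$

The reference offset is the package's own convention:
$l_{\mathrm{ref}} = \log_{10}\!\big(n_0 / \zeta(-\alpha_{\mathrm{ref}})\big)
\approx 5.461$, with $\zeta$ evaluated numerically; it is chosen so that a
library drawn from the reference law with $n_0$ total reads maps onto
itself ($t' = t$ when $\alpha = \alpha_{\mathrm{ref}}$ and
$l = l_{\mathrm{ref}}$). The absolute constant is immaterial downstream —
all statistics are invariant to a global rescaling of the signal — but it
is fixed, documented and used consistently. The mapping is strictly
increasing, so ranks and ties are preserved; zero counts map to zero.
`rpowerlaw()` draws counts from the reference law by inverse transform
(optionally restricted to the fitting domain $t \ge t_{\min}$), which is
how the slope-recovery checks generate their input.

A practical caveat worth stating plainly: the slope estimate is only as
good as the number of regions that survive the count filter. On a library
where merely ~50 regions clear the 50-count threshold, the distinct-count
OLS estimator has a standard deviation around 0.26 and a visible bias, so
slope-recovery checks in this package draw their counts from the reference
law over the fitting domain itself (10,000 regions at $t \ge 50$), where
the estimator is unbiased to within 0.02 and has standard deviation ~0.04.

Simple RPM (`simple_rpm()`, counts scaled to a million-read library) is
retained as the baseline normalization and as the averaging currency for
replicate reports.

## Cis interaction calling

Contact signal decays with distance from the viewpoint; the decay, not any
specific contact, is the null. `fit_cis_background()` fits a cubic
smoothing spline (`stats::smooth.spline`) of normalized signal against
distance to the viewpoint midpoint. The smoothing parameter `spar`
follows the classical parameterization — roughness penalty
$\lambda = r\cdot 256^{3\,\mathrm{spar}-1}$ with $r$ the design-dependent
scale factor — and is restricted to $[0.06, 0.4]$ (default 0.1, a steady
intermediate stiffness); values outside the range require an explicit
override because they either chase noise or flatten the decay into the
signal. The residual standard deviation is a *single scalar* over the
fitted regions, and each cis region is scored as

$$ z = \frac{\mathrm{obs} - \mathrm{exp}}{\mathrm{SD}},\qquad
   p = 1 - \Phi(z). $$

Design choices that the underlying formula leaves open, and how this
package resolves them:

* **Absolute distance by default.** Up- and downstream arms are pooled,
  doubling the points per distance stratum; the decay is approximately
  symmetric. `signed_distance = TRUE` fits the arms separately.
* **Zero-signal regions are excluded from the spline fit but retained for
  scoring.** Zeros dominate the far-cis tail and would drag the spline to
  the floor; their expected value is read off the fitted curve (clamped at
  0), and their z-scores come out negative, as they should.
* **The viewpoint fragment ± 1 is excluded from fitting** — self-ligation
  and re-ligation signal, not contacts — but still scored, so the
  viewpoint's towering signal is visible in outputs rather than silently
  missing.
* **Upper tail only.** Only enrichment over the background constitutes an
  interaction; depleted regions are not calls.
* At least 30 non-zero cis regions are required for a fit; a constant
  signal (residual SD 0) is a degenerate background and an error.

## Trans interaction calling

Trans chromosomes carry no proximity bias, so no scaling is needed: the
mean and standard deviation of the signal over the whole data set —
excluding everything within ±100 kb of the viewpoint, whose signal is
proximity-driven — form the null, and each trans region is scored with the
same $z$ formula. Captured trans contacts must clear the global signal
level, a deliberately hard bar: trans counts are dominated by random
ligation, and the replicate machinery below is the intended instrument for
separating the rare real ones.

## From p-values to q-values

`qvalues()` implements Storey-style FDR with bootstrap estimation of the
true-null proportion $\pi_0$: on the grid $\lambda = 0.05, 0.10, \ldots,
0.95$, $\hat\pi_0(\lambda) = \#\{p > \lambda\} / (m(1-\lambda))$; 100
bootstrap resamples estimate the mean squared error of each candidate
around the most conservative plug-in, and the MSE-minimizing $\lambda$ is
selected, with $\hat\pi_0$ clamped to $(0, 1]$. The q-value is the
$\pi_0$-scaled step-up
$q_{(i)} = \min_{j \ge i} \hat\pi_0\, m\, p_{(j)} / j$; with $\pi_0 = 1$
this is exactly Benjamini–Hochberg, which is the cross-check used in the
test suite.

Two numerical guards matter in practice and are part of the estimator:

1. Grid values $\lambda$ with **no exceedances** ($\#\{p>\lambda\} = 0$)
   are dropped: they lie beyond the support of the p-values and would
   force $\hat\pi_0 = 0$, i.e. every region significant.
2. When the **majority of grid estimates are ≥ 1** the p-value
   distribution is super-uniform (a conservative null — for instance,
   discrete low counts whose z-scores sit below a cis-inflated global
   mean, a situation the trans batch regularly produces on small genomes),
   and no $\pi_0 < 1$ is identifiable; $\hat\pi_0 = 1$ is returned. This
   errs conservative by construction: on a mixed batch with genuine
   signal, most grid estimates fall below 1 and the guard never triggers.

Cis and trans q-values are computed in separate batches. They answer
different null hypotheses, and the dense cis batch would otherwise dictate
$\pi_0$ for the sparse trans batch.

## Replicates

Each replicate is called on its own; `combine_replicates()` then forms the
candidate set as the **union** (significant in ≥ 1 replicate) or
**intersection** (significant in all) of the per-replicate significant
sets. Counts, RPM and normalized signal are averaged over *all* replicates
— not only the supporting ones — so the reported values are representative;
the `support` column exposes the asymmetry. Per-replicate p-values are
combined with Fisher's method, $X = -2\sum_i \ln p_i \sim \chi^2_{2k}$,
and q-values are recomputed on the combined batch. Intersection is the
instrument for removing random-ligation signal: a ligation artefact has no
reason to recur in an independently prepared library, whereas a real
contact does.

## Annotation, export, domainograms

`annotate_genes()` reports a gene when a significant call overlaps its
strand-aware proximity window, from 50 kb upstream of the gene start to
5 kb downstream of the gene end by default (mirrored for minus-strand
genes — "upstream" is in gene orientation). Each gene appears once with
its best (minimum-q) supporting call.

`export_bedgraph()` writes the UCSC dialect (one `track type=bedGraph`
line, then `chrom start end value`, 0-based half-open, zero-valued regions
omitted); `export_text()` writes the full call table with floats at six
significant digits. The two carry identical region–value pairs, and the
test suite re-parses both with an independent reader.

`domainogram_matrix()` repeats the window analysis for every window size
from 2 kb to 30 kb in 1-kb steps (29 rows), tiling each size across a span
around the viewpoint and running the full normalize-and-call pipeline per
row; the cell records the q-value of the window covering each 1-kb grid
position. Rows with fewer than 30 windows cannot support a spline
background, so the span should be at least 15 times the largest window
size. The exported matrix holds $-\log_{10} q$ capped at 10 — the cap is a
display convention for the colour scale, chosen here and documented, since
q-values below $10^{-10}$ are visually indistinguishable anyway.

## The simulator: what it emulates, and what it does not

`simulation_config()` describes a generative model with known ground
truth: i.i.d. uniform random chromosomes; a viewpoint mid-chromosome;
cis reads drawn per fragment with probability proportional to a shifted
power law $(1 + |d|/d_0)^{-\gamma}$ times a per-fragment spike fold;
a fixed fraction of reads scattered uniformly over trans fragments;
5' ends placed on a fragment boundary with probability
`informative_fraction`, else uniformly inside the fragment.

Defaults — the conditions under which the package's quantitative checks
run — are two 5-Mb chromosomes, HindIII, $\gamma = 1.2$, $d_0 = 10$ kb,
5% trans reads, 90% informative reads and $2\times10^5$ reads. The decay
is a shifted power law rather than an exponential because the method's
normalization assumes power-law-like count decay, and the spike set used
by the recovery checks places 20 fragments at 50–500 kb from the
viewpoint (ten per side, 50-kb steps) at 10-fold enrichment — the distance
band of typical enhancer–promoter contacts — chosen once as the study
condition. Test problem sizes (20 null replicates at these defaults for
the false-discovery check; a 20-Mb genome for the fragment-length check;
10,000 regions for slope recovery) are the package's desk-scale choices
that keep the whole suite within a coffee break.

What the simulator deliberately does **not** model: sequence content of
reads (alignments are emitted directly, with mapping quality fixed), PCR
duplicates, mappability and GC biases, enzyme digestion efficiency
gradients, chromatin-domain structure (TAD boundaries produce decay
heterogeneity in real data), and inter-replicate overdispersion beyond
Poisson resampling. Passing the suite therefore demonstrates that the
statistics do what they claim on data obeying the model's assumptions;
it does not certify performance on any particular real library, where
background heterogeneity is the dominant analytical difficulty.

## Known limitations

* A single global residual SD makes far-cis calls conservative and
  near-viewpoint calls permissive when the noise scale varies with
  distance; distance-stratified variance is out of scope, matching the
  single-scalar definition of the method.
* The trans bar (global mean/SD) is intentionally strict; on small
  simulated genomes where cis regions are half the data set it is stricter
  still (see the π0 guard above).
* Interactions between two non-viewpoint loci (Hi-C-style matrices) are
  out of scope; the model is strictly viewpoint-anchored.

## A minimal run

```{r example, eval = FALSE}
cfg <- simulation_config(seed = 42)
genome <- simulate_genome(cfg)
fm <- digest_genome(genome, cfg$site)
cfg$spikes <- default_spikes(fm, cfg$vp)
sim <- simulate_3cseq(cfg, fm)

sig <- count_per_fragment(sim$reads, fm)
sig <- simple_rpm(sig)
fit <- fit_powerlaw(sig, vp = cfg$vp)
sig <- powerlaw_normalize(sig, fit)

calls <- call_interactions(sig, cfg$vp)
summary(calls)
plot(calls, max_distance = 5e5)
export_bedgraph(sig, "signals.bedGraph")
export_text(calls, "interactions.tsv")
```

The same stages are scriptable from a shell through the subcommand
interface (`run_cli()`; wrapper at
`system.file("cli", "viewcall.R", package = "viewcall")`), which writes
its effective configuration alongside every output for reproducibility.
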