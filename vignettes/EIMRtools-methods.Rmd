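---
title: "Methods: hormone-induced binding regions, motif resampling, and chromatin assay quantification"
author: "EIMRtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hormone-induced binding regions, motif resampling, and chromatin assay quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages({
    library(EIMRtools)
    library(GenomicRanges)
})
```

# Scope and model

EIMRtools quantifies hormone-dependent recruitment of a chromatin
remodeller in four coordinated analyses, motivated by the biology of the
*Drosophila* ecdysone response: the nuclear receptor EcR binds
ecdysone-response elements in hormone-regulated genes and, through a
direct interaction, can recruit the CHD-family remodeller dMi-2,
increasing its chromatin association upon hormone exposure and
stimulating its nucleosome-remodelling activity. The four analyses are:

1. **EIMR calling** — classifying genomic regions whose ChIP-seq tag
   density increases upon hormone treatment;
2. **motif enrichment** — testing whether a receptor-binding motif is
   over-represented inside those regions, against a resampling null of
   size-matched random regions;
3. **assay quantification** — relative expression by the
   $\Delta\Delta C_t$ method and MNase protection with the study's
   rescaling conventions;
4. **remodelling kinetics** — one-phase exponential fits to restriction
   enzyme accessibility (REA) time courses.

A synthetic-data generator produces all required inputs with recorded
ground truth, so each analysis is testable end to end without access to
the original sequencing data.

# EIMR calling

Tags are 5′ positions of uniquely mapped reads, carried per condition in
a `TagLane` together with the lane's total number of uniquely mapped
reads $N$. Counts are normalized to tags per million,
$n = k \cdot 10^6 / N$, and each candidate peak receives the induction
ratio

$$r = \frac{(k_{+} + c)\,10^6 / N_{+}}{(k_{-} + c)\,10^6 / N_{-}},$$

with a pseudocount $c = 1$ raw tag added to both conditions. The
pseudocount is our choice (the classification rule itself says nothing
about zero counts); adding it symmetrically guarantees a finite positive
ratio and perturbs well-covered peaks negligibly. A peak is classified
as hormone-induced when $r \ge 2.3$; the threshold is **inclusive** and
exposed as a parameter. Two peaks are considered to overlap when they
share at least 1 bp; strand is ignored.

Candidate peaks may be supplied externally as a BED file. When they are
not, `callCandidatePeaks()` provides a deliberately simple Poisson
sliding-window scanner: a window of width $w$ with count $k$ is retained
when $P(X \ge k \mid \lambda_{\text{local}}) < \alpha$ with
$\lambda_{\text{local}} = \max(\text{genome rate},
\text{flank rate}) \cdot w$, and retained windows within the merge gap
are fused. It is plumbing for producing a peak universe, not a
re-implementation of a full peak caller (no duplicate removal, no
fragment-shift model, no multiple-testing control). By default the
pipeline calls candidates on the pooled two-condition lane, a choice we
made because pooling is symmetric in the two conditions; ratios are then
computed per candidate from the separate lanes.

Tags are counted at their 5′ positions without fragment extension — no
shift model is assumed. Internally coordinates live in `GRanges`
(1-based, closed, the Bioconductor convention); BED input and output is
converted at the boundary by `rtracklayer`, so the half-open BED
semantics of "shared base" arithmetic are preserved exactly.

# Motif enrichment by size-matched resampling

`scanMotif()` reports every position, on both strands, where an IUPAC
consensus matches exactly or a log-odds PWM scores at or above its
threshold. A window containing `N` never matches; palindromic motifs
yield one hit per strand at the same position. Each hit is a distinct
(position, strand) pair, and the identical convention is applied to
observed and resampled counts, so the convention cannot bias the test.

The observed statistic is the number of hits whose full footprint lies
inside at least one region (partial overlaps do not count, and a hit
covered by several regions counts once). The null distribution is built
by `buildNull()`: $B$ times (default 10,000), draw exactly as many
random regions as observed with the identical multiset of lengths — the
chromosome chosen with probability proportional to its placeable start
count ($\mathrm{len} - L + 1$), the start uniform, so placement is
uniform over all valid genomic positions — and count hits the same way.
Sampled regions may overlap one another and the observed regions; no
GC or mappability matching is attempted (the null matches size and
number only). The enrichment P value is the one-sided upper tail of a
normal approximation,

$$p = 1 - \Phi\!\left(\frac{c_{\text{obs}} - \hat\mu}{\hat\sigma}\right),$$

with $\hat\mu$ and the unbiased ($n-1$) $\hat\sigma$ estimated from the
$B$ simulated counts. A degenerate null ($\hat\sigma = 0$) gives
$p = 0$ when $c_{\text{obs}} > \hat\mu$ and $p = 1$ otherwise. The
add-one empirical tail proportion $(\#\{c_b \ge c_{\text{obs}}\} + 1) /
(B + 1)$ is always reported alongside, and the seed is recorded in the
result for reproducibility.

The motif model itself is a required user input: the receptor-binding
motif used in the original bioinformatic analysis is not published, so
printed values that depend on it are not recoverable from a motif
supplied here. The package reads MEME minimal format or a plain IUPAC
string; the MEME parser is a small built-in (about thirty lines) because
the installed stack offers none.

# qPCR and MNase quantification

`ddct()` implements pure $\Delta\Delta C_t$ with amplification
efficiency fixed at 2.0 per cycle; no efficiency correction or standard
curve is modelled. Per replicate $i$,
$\Delta C_{t,i} = C_{t,\text{target},i} - C_{t,\text{ref},i}$
(replicates paired by index, with unpaired wells falling back to the
sample's mean reference $C_t$),
$\Delta\Delta C_{t,i} = \Delta C_{t,i} -
\overline{\Delta C_t}_{\text{calibrator}}$, and
$\mathrm{rel}_i = 2^{-\Delta\Delta C_{t,i}}$. The mean and standard
deviation are then taken over the per-replicate $\mathrm{rel}_i$ — the
mean-of-ratios convention — so the reported dispersion is on the ratio
scale; the alternative (exponentiating the mean $C_t$) is equally
defensible, and the difference is second-order at triplicate noise.
Each gene is finally rescaled so the calibrator's mean relative level
is exactly 1. Time courses can be rescaled to 100 at the control
condition's latest time point (`timecourseRescale()`), and treated /
untreated fold changes anchored at 1 (`foldChangeVsUntreated()`).

MNase protection is the digested sample's qPCR signal relative to the
matched undigested sample, $2^{-(C_{t,\text{dig}} -
C_{t,\text{undig}})}$, rescaled per genomic region so the most
protected sample is exactly 1.

# Remodelling kinetics

REA time courses report the percentage of nucleosomal DNA cut by a
restriction enzyme whose site is exposed by remodelling:
$\mathrm{pct} = 100 \cdot \mathrm{cut} / (\mathrm{cut} +
\mathrm{uncut})$. Per condition, the one-phase exponential

$$Y(t) = Y_0 + (\mathrm{Plateau} - Y_0)\left(1 - e^{-K t}\right)$$

is fitted by box-constrained Levenberg–Marquardt least squares
(`minpack.lm`), with $0 \le Y_0 \le 100$, $0 \le \mathrm{Plateau} \le
100$, $K > 0$, convergence at relative tolerance $10^{-12}$ within 1000
iterations, and deterministic initialization ($Y_0$ from the earliest
point, Plateau from the latest, $K = \ln 2 / \mathrm{median}(t)$). The
rising-to-plateau parameterization is an explicit assumption: the
common desktop fitting software's "one-phase decay" family is an
exponential approach to a plateau, and percent-cut data rise, so the
association sign convention is the only one consistent with the data.
Whether $Y_0$ should be fixed or fitted, and whether fits should use
replicate means (as plotted) or all points pooled, are both exposed as
options; the defaults fit all three parameters on replicate means.
Flat data are handled exactly ($Y_0 = \mathrm{Plateau}$, RSS 0);
non-convergence is flagged, never silent.

`stimulationSummary()` compares conditions against a baseline by the
ratio of rate constants and the plateau difference, with per-timepoint
mean ± s.e.m. across replicates — the quantitative comparator for
statements like "adding the receptor stimulates remodelling".

# The synthetic-data generator

The generator emulates the shapes of the study's deposited inputs at a
toy scale chosen so the full battery runs in seconds:

* **Genome**: two 500 kb chromosomes of i.i.d. sequence at 43% GC
  (fly-like), with a 12 bp nuclear-receptor-style consensus
  (`RGGTCANTGACC`, an inverted-repeat half-site arrangement) planted at
  non-overlapping recorded positions — 60 inside the induced regions,
  150 outside.
* **Tag lanes**: Poisson background at 0.1 tags/bp (≈10⁵ tags per
  lane — the deposited lanes' 10⁷ scale reduced 100-fold), 40 planted
  1 kb peaks with 5-fold untreated in-peak enrichment, 20 of them
  hormone-induced at a true *normalized* ratio of 3.0 and 20 unchanged
  at 1.0. Because lane totals themselves depend on the spiked tags, the
  treated-lane peak intensities are calibrated through the linear
  self-consistency $s = A/(A + M - Q)$ for the expected lane-total
  ratio $s$ (with $A$ the expected background outside peaks, $M$ and
  $Q$ the plain and ratio-weighted sums of untreated peak means), so
  the expected normalized ratio of every peak equals its configured
  truth. Lane totals are inflated 25% above the stored tag count,
  mimicking uniquely mapped reads outside the analysis.
* **qPCR**: $C_t = C_{t,\text{base}} - \log_2(\text{expression}) +
  \mathcal N(0, 0.2)$ cycles, triplicates; 0.2 cycles is routine
  instrument-level precision. Noiseless tables invert exactly.
* **REA**: four replicates at 2.5/5/10/20 min with Gaussian percent-cut
  noise (sd 2, typical densitometry scatter), emitted as (cut, uncut)
  pairs summing to 100 so `percentCut()` inverts exactly. Default
  truths: baseline remodeller (plateau 40, $K$ 0.08 min⁻¹), stimulated
  (plateau 80, $K$ 0.2), receptor alone (plateau 8 — essentially
  inactive).
* **MNase**: two regions mirroring an 80% and a 20% protection loss
  upon remodeller depletion, Ct noise sd 0.1.

Gaussian noise on the $C_t$ and percent scales is standard practice for
these assays, not derived from the study. Every output is a
deterministic function of (config, seed), and `truth.json` records all
planted ground truth, so downstream recovery can be scored without
re-reading configurations.

What the generator does *not* emulate — and therefore what passing
tests cannot certify about real data: read-level sequencing artifacts
(mappability, duplicates, GC bias), fragment-length effects,
correlated qPCR pipetting errors, biological replicate variability, and
motif models with realistic information content. Recovery results on
synthetic data establish correctness of the computations, not
robustness to these real-data phenomena.

# Numerical and test-design choices

* **Degenerate inputs.** Zero-count peaks are handled by the
  pseudocount; a zero-variance motif null yields the 0/1 P value rule;
  flat kinetics short-circuit the optimizer; samples missing reference
  wells or undigested controls are excluded with warnings, and regions
  on unannotated chromosomes are flagged `"unannotated"` rather than
  erroring.
* **Tie-breaks.** Nearest-TSS ties resolve to the smaller coordinate,
  then lexicographic gene id, making annotation deterministic.
* **Ratio scale invariance.** Multiplying raw counts and lane totals by
  a common factor leaves $r$ unchanged only if the pseudocount scales
  with them; with $c$ fixed in raw-tag units the perturbation is
  $O(1/k)$. The property suite tests the exact invariance with the
  scaled pseudocount and finiteness with the fixed one.
* **Bias testing with multiplicity.** The kinetics recovery suite
  checks standardized parameter bias over a 3 × 3 grid of truths. A
  plain "within 2 standard errors" rule applied to 27 simultaneous
  cell/parameter checks would false-alarm with probability ≈ 0.72 for
  an exactly unbiased estimator, so the familywise check uses the
  Šidák-adjusted bound for 27 comparisons at the same individual rate
  (≈ 3.06 SE); individual 2-SE coverage is also asserted to exceed
  70%. The grid reveals a genuine small upward plateau bias when
  $K t_{\max} \approx 1$ (the $K = 0.05$ column): with the curve still
  far from saturation at the last time point, the plateau is weakly
  identified and constrained nonlinear least squares is not exactly
  unbiased there. This is a property of the estimator, documented
  rather than hidden.
* **Problem sizes.** Test and acceptance workloads use the toy scale
  above (20-seed recovery runs, 200 × 500 resampling replications,
  50-simulation bias cells), sizes we chose to make the statistical
  assertions sharp while keeping the whole battery interactive.

# Worked example

```{r example}
cfg <- simConfig()
sim <- simulateTagLanes(cfg$seqlengths, cfg$peaks, seed = 1)
peaks <- GRanges(cfg$peaks$chrom,
    IRanges(cfg$peaks$start + 1L, cfg$peaks$end))
eimrs <- classifyEimrs(peaks, sim$minus, sim$plus)
table(called = eimrs$induced, truth = sim$truth$trueRatio[
    match(paste(seqnames(eimrs), start(eimrs)),
        paste(sim$truth$chrom, sim$truth$start + 1L))])
```

```{r example-motif}
induced <- peaks[cfg$peaks$ratio > 1]
gen <- makeGenome(cfg$seqlengths, cfg$motif,
    nBackground = cfg$nBackgroundMotifs,
    nInRegion = cfg$nInRegionMotifs, regions = induced, seed = 2)
hits <- scanMotif(gen$genome, motifConsensus(cfg$motif))
buildNull(induced, hits, cfg$seqlengths, B = 1000, seed = 3)
```

# Known limitations

The peak scanner is a Poisson window filter, not a modern peak caller;
the motif null matches size and number but not composition; the
$\Delta\Delta C_t$ implementation assumes perfect doubling per cycle;
the kinetics model is a single exponential and will summarize biphasic
remodelling poorly; and all statistical guarantees quoted here are
demonstrated on the synthetic generator's assumptions, as discussed
above.
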