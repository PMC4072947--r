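---
title: "Measuring Pol II elongation waves: model, parameters and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring Pol II elongation waves: model, parameters and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement model

DRB reversibly blocks the transition of RNA polymerase II into productive
elongation. Removing it releases a synchronized cohort of polymerases
from each promoter; labeling nascent RNA with 4sU for a window ending
at time $t$ after release and sequencing the labeled fraction yields,
per gene, a coverage profile with a sharp *wave front* at

$$\mathrm{front}(t) = V\,(t - D),$$

where $V$ is the gene's elongation rate (kb/min) and $D$ the delay
between drug removal and elongation restart (min). Behind the front,
if polymerases enter elongation at a constant initiation frequency $I$,
the labeled signal at TSS offset $x$ after labeling time $T$ is

$$S(x) = I\,\bigl(T - D - x/V\bigr), \qquad 0 \le x \le V\,(T-D),$$

a straight line hitting zero exactly at the front $B = V\,(T-D)$. The
package estimates, per gene:

1. the front position ("boundary") in each post-release sample,
2. $V$ and $D$ from the line of boundary position versus time across
   replicates, and
3. the relative initiation frequency $I = bV/B$ from the intercept $b$
   of the fitted decay line.

Only intronic coverage is used: intron signal decays within minutes of
transcription, so it proxies nascent RNA and suppresses mature-mRNA
contamination. A 100-bp bin counts as intronic only if it overlaps no
exon of the gene.

# Pipeline stages and parameters

All tunables live in a `WaveParams` object (`waveParams()`), are
serialized as flat YAML (`writeWaveParams()` / `readWaveParams()`, with
unknown keys rejected), and default to the values below.

## Coverage and eligibility

* `binSize = 100` bp. Coverage is the count of read 5' ends per bin,
  normalized to $10^6$ per sample; the rRNA-dominated contig
  `chrUn_gl000220` is excluded before normalization.
* `minGeneKb = 25` (strict): shorter genes cannot separate a 4-min from
  an 8-min front at typical rates.
* `minPositiveBins = 20` positive intron bins on the *averaged raw 0-min
  profile*: boundary calling needs a usable control profile.

## Boundary detection (`callBoundary`)

Each sample profile and the averaged 0-min control are smoothed with a
cubic smoothing spline (`smoothingP = 1e-5`, see *Numerical choices*),
background-corrected, and compared:

* Background per bin is the mode of the histogram
  ($\lceil\sqrt{n}\rceil$ bins) of all smoothed values *downstream* of
  that bin (`backgroundTrack`); bins with fewer than 10 downstream
  values inherit the last computed estimate. The mode, not the mean,
  because downstream of the front the distribution is background plus a
  signal tail; the mode ignores the tail.
* The *rough* boundary is the first bin at offset `startOffsetKb = 2.5`
  kb or beyond where the corrected sample drops to within
  `roughTolerance = 0.10` of the corrected control (promoter-proximal
  bins are skipped because paused-polymerase signal is shared between
  sample and control).
* The *refined* boundary sharpens the call using the derivative of the
  ratio of the corrected sample to the smoothed control (control
  pseudocount `pseudocountZero = 0.01`): from the most downstream local
  minimum deeper than `derivMinThreshold = -0.01` upstream of the rough
  call, the first bin where the derivative has flattened to
  `derivZeroThreshold = -0.002` wins, capped at
  `refineWindowKb = 2` kb past the rough call, else the rough call
  stands.

## Rates and QC (`estimateRates`)

A gene needs boundaries in both 4-min replicates and at least three of
the four 8-min replicates. The modified Thompson tau test
(`thompsonTauFilter`, `tauAlpha = 0.05`, at most one removal, applied
to the 8-min set) rejects a single discordant replicate. $V$ is the
OLS slope of boundary position against time over all retained replicate
points; the reported interval is the 50% two-sided CI half-width of the
slope, and $D = -\mathrm{intercept}/V$. QC (`qcFilter`) requires the
8-min mean boundary at or past the 4-min mean, a positive rate, CI
half-width at most `ciMaxKbPerMin = 0.5`, and $D$ within
`delayRange = [-1, 4]` min; all genes stay in the output with a reason.

## Initiation (`estimateInitiation`)

Per 8-min replicate, the decay line is fitted to the raw 8-min signal
divided by (raw 0-min mean + `pseudocountInitiation = 1`) over offsets
up to that replicate's own boundary $B$ (at least 5 bins), and
$I = bV/B$ uses the consensus $V$. Replicate estimates pass the same
tau filter and are averaged. `excludeFirstKb = 2` re-runs the fit
without the first 2 kb as a robustness check against
promoter-proximal-pausing signal; on pause-free data the two variants
agree (the acceptance suite checks Pearson $\ge 0.95$).

Because the denominator carries a +1 pseudocount on top of the 0-min
background, the scale of $\hat I$ is shrunk by a common factor
(background mean + 1); estimates are therefore *relative*, which is all
the gene-to-gene comparisons require.

# Numerical choices

**Spline abscissa in base pairs.** The smoothing spline minimizes
$p\sum_i (y_i - f(x_i))^2 + (1-p)\int f''(x)^2\,dx$ (solved exactly via
the Reinsch banded system; `Matrix` sparse solve). With
$p = 10^{-5}$ the effective bandwidth depends on the units of $x$:
evaluating at genomic bp offsets gives an equivalent kernel of roughly
half a bin, which denoises while keeping the wave-front knee inside one
100-bp bin. Evaluating the same $p$ on bin indices would smooth over
~18 bins and displace the knee by more than a kilobase, destroying the
single-bin front-recovery property the acceptance suite asserts. The
abscissa is therefore bp.

**Refined-boundary semantics.** The derivative of the sample/control
ratio is most negative where the wave decays fastest and returns to ~0
past the front. Scanning from the most downstream qualifying minimum
and taking the *first* flattened bin lands one bin past the knee;
noiseless recovery is accurate to $[-0.1, +0.2]$ kb of $V(8-D)$ by
construction of the grid test.

**Background-corrected control near zero.** The rough rule compares
against $1.1\times$ the corrected control; where the corrected control
is exactly zero this degenerates to "sample must reach zero", which the
floor-at-zero of background correction makes attainable. This is the
intended behavior: it makes the rough call the first bin that is
indistinguishable from control.

**Truncated waves.** When $V(8-D)$ exceeds the annotated gene length
the front is unobservable; background correction flattens the truncated
tail and the boundary call degenerates to the gene tail. Such genes are
caught by the QC rules (most often the CI or delay rule), not by a
special case.

# The simulator and what passing does (not) show

`simulateCohort()` draws per-gene parameters
$V \sim U(2,6)$ kb/min, $D \sim U(0,2)$ min, $I \sim U(5,20)$,
lengths $U(30,65)$ kb, and emits per-bin counts
$\mathrm{NB}(\mu = \mathrm{bg} + I\max(0, t - D - x/V),\ k = 10)$
with background mean 1 — a leaky-inhibition floor with realistic
overdispersion — on a synthetic chromosome with alternating strands,
200-bp exons every ~3 kb (intron fraction ~0.93) and mature-mRNA
leakage on exon bins, under the study's replicate design
(4 x 0-min, 2 x 4-min, 4 x 8-min). These defaults were fixed before the
validation thresholds were measured and are not tuned to them.

Passing the simulated-cohort checks demonstrates that the estimator
inverts its own generative model under calibrated noise. It does *not*
demonstrate robustness to what the model omits: within-gene velocity
variation, promoter-proximal pausing (the simulator is pause-free, so
the 2-kb-exclusion check only verifies neutrality, not correction),
splicing-intermediate contamination, mappability gaps, or partial DRB
synchronization. Cohort sizes used in the tests (tens to 200 genes) are
the package's own computational-budget choice, not an empirical claim
about attainable genome-wide yields.

# Limitations

* One front per gene and per sample: internal initiation sites,
  alternative TSSs and convergent transcription confound the call.
* $V$ is a gene-level average; the two-timepoint design cannot resolve
  positional velocity changes.
* $I$ is relative and depends on the denominator pseudocount
  convention; only rank/ratio statements across genes are supported.
* Genes shorter than ~`25` kb, or with fronts beyond the gene end at
  8 min (fast genes, short genes), are structurally unmeasurable and
  are reported with reasons rather than estimated.
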