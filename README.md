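# txwave

Genome-wide RNA polymerase II elongation rates, delay times and relative
initiation frequencies from DRB-release / metabolic-labeling nascent-RNA
sequencing (4sUDRB-seq-style experiments).

## Scientific problem

Treating cells with DRB reversibly stalls Pol II near promoters. Washing
the drug out releases a synchronized *wave* of polymerases into each gene
body; pulse-labeling nascent RNA with 4sU and sequencing it at several
times after release photographs the wave mid-flight. The wave front of a
gene at time *t* sits at

```
front(t) = V * (t - D)
```

where *V* is the elongation rate (kb/min) and *D* the delay between drug
removal and productive elongation. Behind the front, under constant
initiation frequency *I*, the amount of nascent signal at offset *x*
accumulated by labeling time *T* is linear:

```
signal(x) = I * (T - D - x / V),   0 <= x <= front(T)
```

so the front positions across timepoints give *V* and *D* by a straight
line, and the intercept *b* of the decay fit gives the relative initiation
frequency *I = b * V / B* (with *B* the front position).

txwave implements the full measurement chain: binned intronic coverage
(introns proxy nascent RNA and avoid mature-mRNA contamination), smoothing
and background correction, two-stage wave-front detection
(similarity-to-control, then derivative refinement), replicate-level rate
fits with a modified Thompson tau outlier test and QC rules, initiation
inference, metagene profiles, and a calibrated generative simulator for
validation.

## Worked example

```r
library(txwave)

we  <- simulateCohort(nGenes = 20, seed = 7)   # 4 x 0-min, 2 x 4-min, 4 x 8-min
res <- runPipeline(we)

tab <- merge(res$rates, truthTable(we)[, c("gene_id", "V_true", "D_true")])
head(tab[tab$pass_qc, c("gene_id", "rate_kb_per_min", "ci_half_width",
                        "delay_min", "V_true", "D_true")], 5)
```

```
  gene_id rate_kb_per_min ci_half_width delay_min V_true D_true
 SIMG0001            5.34        0.0813     0.538   5.20  0.384
 SIMG0002            3.46        0.0527     1.034   3.53  1.009
 SIMG0003            5.14        0.0350     1.645   5.04  1.528
 SIMG0004            3.70        0.0454     1.270   3.75  1.387
 SIMG0006            3.13        0.0229     1.364   3.28  1.318
```

18 of 20 genes pass QC; the estimated initiation frequencies track the
generative ones with Spearman correlation 0.992:

```r
ini <- merge(res$initiation, truthTable(we)[, c("gene_id", "I_true")])
cor(ini$relative_I, ini$I_true, method = "spearman", use = "complete.obs")
#> 0.992
```

(Estimates are *relative*: with the simulator's unit background the
denominator pseudocount halves the scale uniformly, which cancels in all
gene-to-gene comparisons.)

Real data enters through `binCoverage()` (SAM/BAM or bedGraph),
`readGeneModels()` (refFlat, genePred or BED12) and
`extractIntronSignal()`; a thin CLI wrapping simulate / run / metagene is
installed at `inst/scripts/wavecall`.

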