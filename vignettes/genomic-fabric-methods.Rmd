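---
title: "Genomic fabric analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic fabric analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genefabric)
```

## The model

A replicated two-condition expression experiment (here labelled "N" for the
reference and "L" for the experimental condition, with 4 biological
replicates each as the default design) is summarized gene by gene with three
mutually independent primary characteristics:

* **AVE** — the average normalized expression level, taken over all
  biological replicates of all microarray spots redundantly probing the
  gene.
* **REV** — the relative expression variation, a corrected coefficient of
  variation in percent. With $s$ spots and $n$ replicates, the per-spot
  replicate variances are pooled ($\nu = s(n-1)$ degrees of freedom) and the
  sample CV is multiplied by the chi-square mid-interval factor
  $c = \tfrac12\left(\sqrt{\nu/\chi^2_{0.975,\nu}} +
  \sqrt{\nu/\chi^2_{0.025,\nu}}\right)$, which compensates the strong
  downward noise of a CV estimated from few replicates ($c = 2.1475$ at
  $\nu = 3$). Pooling *within*-spot variances means a constant intensity
  offset between a gene's redundant spots — a probe-affinity artifact, not
  biological variability — does not inflate REV.
* **COR** — the Pearson correlation of two genes' expression values across
  replicates. Spot $k$ of gene $i$ is paired with spot $k$ of gene $j$
  ($k = 1..\min(s_i, s_j)$, spots in file order) within each replicate, so a
  pair contributes $n\cdot\min(s_i,s_j)$ points. The two-tailed critical
  value at level $\alpha$ is the Student-$t$ closed form
  $r_c = t_c/\sqrt{t_c^2 + \mathrm{df}}$, $\mathrm{df} = n_\text{points}-2$:
  0.950 for single-spot pairs at $n=4$, 0.71 for two spots, 0.58 for three.
  Pairs at or beyond $\pm r_c$ are called synergistic/antagonistic; pairs
  with $|COR| < 0.05$ are called independent; everything between is left
  unclassified. No multiple-testing correction is applied anywhere — the
  per-pair $\alpha = 0.05$ convention is part of the method being
  implemented.

From these, three derived characteristics:

* **REC** $= \mathrm{median}(\text{REV})/\text{REV}_\text{gene}$ — relative
  expression control, high for tightly controlled transcripts; the median
  gene scores 1, so the transcriptome-wide distribution is centred there by
  construction.
* **COORD** $= 100\,(S + A - I)/P$ — the coordination degree over a partner
  universe of size $P$: synergisms and antagonisms both witness
  coordination, independences subtract, unclassified partners dilute the
  denominator only.
* **GCH** $= \text{REC}\cdot\exp(4\,\langle COR^2\rangle)$ — the gene
  commanding height, ranking genes by control strength amplified by
  coordination power; the top gene is the Gene Master Regulator of the
  profiled phenotype. The exponent 4 follows the fabric-analysis
  convention and is configurable (`gch_exponent`).

Regulation between conditions is decided per gene by a composite criterion:
the signed expression ratio $x$ (negative for down-regulation, $|x|\ge 1$)
must clear the gene's own cut-off
$\mathrm{CUT} = 1 + \sqrt{2}\,\sqrt{\text{REV}_N^2 + \text{REV}_L^2}/100$
while the heteroscedastic (Welch) $t$-test of the spot-averaged replicate
values gives $p < \alpha$. A uniform 1.5× rule is too stringent for stable
genes and too lax for noisy ones; `compare_fixed_cutoff()` reports the four
disagreement categories. Every gene, regulated or not, contributes the
weighted individual regulation
$\mathrm{WIR} = \text{AVE}_N (|x|-1)\,\mathrm{sign}(x)(1-p)$, and a pathway
aggregates them as $\mathrm{WPR} = \sqrt{\langle \mathrm{WIR}^2\rangle}$.

## Pathway coupling denominators

The intra-pathway coordination degree divides the distinct-pair class
counts by the **ordered** pair count $G(G-1)$, and the inter-pathway degree
divides by $|A|\,|B| - |A\cap B|$. These conventions are deliberate: they
are the ones under which every published working value of the method's
source analyses reproduces exactly, and the intra convention halves the
naive distinct-pair fractions, which a reader comparing against
$\binom{G}{2}$ should keep in mind. The remodeling ratio of a coupling is
reported with magnitude $\ge 1$ and a negative sign when the coupling
weakened (13.82% → 2.91% is −4.75×).

## Numerical and edge-case choices

* The single-spot correlation cut-off at $n = 4$, $\alpha = 0.05$ computes
  to 0.9500; some fabric-analysis literature prints 0.951. We report the
  computed closed-form value; `alpha` is configurable if a different
  operating point is wanted.
* A pair with zero variance in either vector has an undefined correlation:
  it is recorded as `NA` and classified `unclassified` (denominator-only).
* REV = 0 (all replicates identical) makes REC infinite; it is capped at
  10^6 with a warning.
* A spot carrying any missing or non-positive intensity in either condition
  is eliminated from both conditions; the gene keeps its other spots. The
  filter is idempotent and the dropped count is retained in the dataset and
  the run manifest.
* Zero variance in both Welch groups with equal means returns $p = 1$.
* ΔREC is $(\text{REC}_L - \text{REC}_N)\cdot 100$ (percent), ΔCOORD a plain
  difference in percentage points. The pathway-level control change is
  $100\,(\overline{\text{REC}}_L/\overline{\text{REC}}_N - 1)$ over the
  quantified members; this aggregation choice is explicit because several
  published pathway-level control-change figures cannot be reconstructed
  from any simple combination of the printed per-gene values.

## The synthetic fabric generator

`generate_fabric()` emulates the statistical structure of a two-condition
microarray study with known ground truth:

* 4 biological replicates per condition (configurable);
* 1–3 redundant spots per gene with probabilities (0.6, 0.3, 0.1) — the
  emulated platform probes most genes once and a minority redundantly; no
  published distribution exists, so this was fixed once as a realistic
  choice;
* baseline AVE drawn log-normal(meanlog 0, sdlog 2): a median-normalized
  transcriptome whose most expressed genes reach the 10³ scale, matching
  the magnitude of top myofilament transcripts in the emulated data;
* true per-gene CVs log-uniform on [1%, 100%], the range observed for real
  REVs; both AVE and CV accept exact per-gene overrides for planting ground
  truth;
* correlation blocks: each block draws one latent standard-normal factor
  per replicate and condition, and member $i$ loads on it with
  $\ell_i = \pm\sqrt{\rho}$, so two same-sign members correlate at $+\rho$
  and opposite-sign members at $-\rho$; genes outside blocks are
  independent;
* regulated genes get their baseline AVE multiplied by a true fold in the
  experimental condition;
* redundant spots share the replicate value plus multiplicative jitter with
  SD equal to 20% of the gene's CV. A single-spot gene's spot *is* the
  replicate measurement and carries no extra jitter: this keeps the imposed
  CV and pair correlations exact at the observable level for single-spot
  genes, which is what makes the generator's ground truth usable for
  recall/precision scoring. Values are clipped at 10⁻⁶ of the median
  baseline AVE; the clipping probability is negligible for CVs up to about
  a third.

What the generator does **not** emulate: probe-sequence affinity biases,
array spatial artifacts, normalization residuals, heavy-tailed technical
noise, and condition-dependent correlation structure beyond the imposed
blocks. Tests passing on synthetic fabrics therefore validate the
arithmetic and the statistical power of the measures under idealized noise,
not robustness to real microarray artifacts.

Validation problem sizes were chosen to make the recovery properties sharp
but cheap: 500 genes for regulated-gene recall at fold 4×/CV 10% (observed
recall is essentially complete), 2000 null genes for the type-I rate of the
composite criterion (well under the nominal level, since the CUT condition
is conjoined with the $t$-test), and 200 two-gene blocks at $\rho = 0.995$
for synergism recall at $n = 4$ (the Fisher-z argument puts the per-pair
recall near 0.88 against the 0.95 single-spot cut-off).

## Pipeline scope

A full transcriptome of $N$ genes has $N(N-1)/2$ distinct pairs — about
1.9×10⁸ at $N = 19{,}605$ — so `run_gfp()` computes pairs only within and
between the configured gene sets plus named anchor genes by default;
`all_pairs: true` opts into the quadratic scan. All randomness flows from
the single configuration seed, and the run manifest records input digests
so that identical configurations can be verified to give bit-identical
outputs.

## Known limitations

* The pair-scope restriction means per-gene COORD/GCH computed by the
  pipeline are relative to the configured scope, not the full
  transcriptome, unless `all_pairs` is set.
* REV pooling assumes equal replicate counts across a gene's spots (true
  for the supported input layout, where dropping is per-spot).
* The GCH exponential form and the REC ratio form follow the
  fabric-analysis literature's conventions; both are isolated behind
  single functions (`compute_gch()`, `compute_rec()`) should a variant
  parameterization be needed.
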