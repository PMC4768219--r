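---
title: "Methods: classifying cross talk between cytokine- and heat-shock-driven transcription"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying cross talk between cytokine- and heat-shock-driven transcription}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

# The problem

Two major stress-response programs shape a cell's transcriptome: the
TNFα/NF-κB axis, which drives inflammatory and cytokine-response genes, and
the heat-shock response, in which trimerised HSF1 binds heat-shock elements
(HSEs) and activates chaperone genes. The two programs interfere: cells
pre-exposed to heat shock typically fail to activate canonical NF-κB
targets, yet some genes are activated by both stimuli and respond even more
strongly to the combination. `stressxtalk` implements the integrative
analysis needed to map this cross talk gene by gene from a factorial
experiment over four conditions — untreated control (`Ctr`), cytokine alone
(`TNF`), heat shock alone (`HS`), and heat shock followed by cytokine
(`HS_TNF`) — together with promoter motif prediction, HSF1 ChIP-seq peak
assignment, and term-overrepresentation statistics.

```{r}
library(stressxtalk)
```

# Differential expression: the ratio + FDR call rule

For a contrast (treated, reference) the per-gene *signal ratio* is
$2^{\bar{x}_T - \bar{x}_R}$ on log2 intensities. A gene is called **up**
when its ratio exceeds 1.2 and its q-value is below 0.05, **down** when the
ratio falls below 0.8 at the same q threshold, and **none** otherwise. The
ratio comparisons are strict, so a ratio of exactly 1.2 is never a call.
These defaults (a 20% change at FDR 0.05) can be reconfigured in
`call_de()` and `pipeline_config()`.

Significance comes from a moderated two-sample t statistic. Per-gene pooled
variances $s_g^2$ (on $d_g = n_1+n_2-2$ degrees of freedom) are shrunk
toward a prior $(d_0, s_0^2)$:

$$\tilde{s}_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},\qquad
t_g = \frac{\bar{x}_T - \bar{x}_R}{\tilde{s}_g \sqrt{1/n_1 + 1/n_2}},$$

with $t_g$ referred to a Student distribution on $d_0 + d_g$ degrees of
freedom. The prior is fitted by matching the mean and variance of
$\log s_g^2$ to a scaled inverse-chi-square model (digamma/trigamma
moments). The two boundary cases make the statistic auditable: `d0 = 0`
reduces exactly to the textbook pooled t test (checked against an
independent implementation to 1e-10 in the test suite), and `d0 = Inf`
scores every gene against the shared prior variance. When log-variance
dispersion does not exceed its pure sampling component, moment matching has
no finite solution and the fit falls back to `d0 = Inf`; a data set in
which every gene has zero variance is rejected as degenerate (for noise-free
synthetic data, pass `moderation_params(0, 1)` explicitly).

q-values use Storey's estimator by default, matching the FDR methodology
this kind of microarray study relies on: $\hat\pi_0(\lambda)$ is computed
on the grid $\lambda = 0.05, \dots, 0.95$ and smoothed with a df = 3
spline, and the estimate at $\lambda = 0.95$ (clipped to $(0,1]$) scales
the Benjamini–Hochberg step-up quantities. When the smoother is unstable
the estimate falls back to $\pi_0 = 1$, i.e. plain BH; `method = "bh"`
forces that behaviour. FDR is estimated per contrast, not globally across
contrasts.

# Combined-effect (interaction) modes

The analysis centres on genes modulated by the cytokine (TNF vs Ctr). For
each such gene the HS_TNF-vs-TNF contrast measures what heat-shock
pre-treatment did to the cytokine response, and the same ratio/FDR
machinery classifies it:

| TNF call | HS_TNF vs TNF | mode |
|---|---|---|
| up | significant increase | `enhanced_activation` (co-activation) |
| up | significant decrease | `suppressed_activation` (antagonism) |
| down | significant decrease | `enhanced_repression` (co-repression) |
| down | significant increase | `relieved_repression` |
| up/down | neither | `unaffected` |

A gene is flagged **co-activated** when its activation is enhanced *and*
heat shock alone also upregulates it; **co-repressed** mirrors this for
downregulated genes. These flags are provably contained in the
direction-concordant overlap sets (TNF-up ∩ HS-up, TNF-down ∩ HS-down),
one of the structural invariants in the test suite. A uniform decision rule
across all four modes was a deliberate design choice: published examples of
this analysis report the mode proportions but not an explicit rule, and the
presence of unlabelled genes with ratios as low as 0.63 in the published
worked-example panel implies a significance filter beyond the ratio alone.
Requiring q < 0.05 in addition to the ratio reproduces the panel's seven
co-activation labels exactly; it also explains why one unlabelled gene
(ratio 0.63) would be labelled antagonistic if significance were assumed
for every row. The reverse analysis — the effect of the cytokine on
HS-modulated genes — uses the same operations with the HS_TNF-vs-HS
contrast.

Percentages in the reporting layer are rounded to the nearest integer,
except that values below 2% are reported to the nearest half point, so
that small subsets (e.g. 3 of 193 genes, 1.55%) survive rounding as 1.5%
instead of collapsing to an integer.

# Promoter motifs

The proximal promoter is the kilobase immediately upstream of the TSS,
`[TSS-1000, TSS)` in strand-aware coordinates. Both strands of each
promoter are scanned with log-odds PWMs
($\sum_j \log_2 p_j(b)/\pi(b)$); windows containing N are skipped, and a
hit requires at least 80% of the maximal attainable score, a common
relative-threshold convention for TRANSFAC-style matrices. Both the
threshold and the matrices are configurable (JASPAR-style text via
`read_jaspar()`); the shipped defaults are a κB matrix built from the
canonical RelA/p50 decamer consensus GGGRNNYYCC and an HSE built by
`build_hse_pwm(3)` as three alternating-orientation nGAAn pentamers
(consensus nGAAnnTTCnnGAAn), with invariant positions at probability 0.97
before pseudocounting and degenerate positions at background. Every matrix
receives a pseudocount of 0.01 per cell before normalisation. Because the
matrices and threshold of the original genome-wide scans are not published,
absolute motif counts are not reproducible; the published counts are used
only through their percentage arithmetic.

# HSF1 binding

The regulatory window spans 7500 bp upstream to 2500 bp downstream of the
TSS, oriented by strand and clipped at the chromosome start — wide enough
to catch distal promoter binding, following the promoter-array-style window
used in this analysis tradition. (A narrower −2500..+500 window appears in
parts of that literature; both extents are exposed as configuration.) Peaks
are assigned to a gene when they overlap its window by at least 1 bp under
0-based half-open (BED) semantics; a peak may serve several genes. For
genes with several annotated TSSs, the 5'-most is used.

A gene shows *induced binding* when its window holds heat-shock binding
significantly above the control, after either 10 or 20 min of heat shock
(the union of the two timepoints). Two evidence routes exist. With only
peak sets (BED), the best HS peak score in the window must reach a minimum
score (default 5, i.e. an adjusted p of 1e-5 on −log10-scored peaks) and
exceed the best overlapping control score by a ratio (default 1.5). With
binned tag tracks, the window's HS tag count is tested against the
depth-scaled control count by a Poisson upper tail, BH-adjusted across
genes. The built-in peak caller is the same Poisson machinery per bin
against a depth-scaled input/reference track floored at the global
background rate, with adjacent significant bins merged; it is deliberately
minimal — no fragment-shift model, no local-background hierarchy — and is
validated for calibration (null false-positive control) rather than for
feature parity with production callers.

# Overrepresentation

Term enrichment is the hypergeometric upper tail
$P[X \ge k]$ for $k$ annotated genes in a subset of $n$ against $K$ of $N$
in the background, with the background universe always passed explicitly
(the "all detected genes" set, never silently inferred from the annotation
file). Terms are flat labels — no ontology ancestry is propagated. The
default significance rule is unadjusted p < 0.05 to match practice in this
analysis tradition; BH adjustment is available. Comparative enrichment (a
subset against the TNF-modulated set versus against the whole universe) is
two calls with different backgrounds.

# The synthetic-data generator

`sim_config()` fixes the study conditions: four conditions with three
replicates each (the replicate structure of the emulated design), log2
baseline intensities N(8, 1.5²), replicate noise sd 0.25, and a planted
effect of 2 log2 units. Effects are additive on the log2 scale and
mode-specific rather than a generic interaction term, because the modes are
defined phenomenologically: suppressed-activation genes are TNF-activated
but sit at their HS level under the combined treatment (half of them
HS-downregulated, half HS-neutral, mirroring the observation that slightly
more than half of antagonised genes are themselves HS-repressed);
co-activated genes gain the planted effect from each stimulus and twice it
from the combination. The default mode mix (60% null, 8% antagonised, 4%
co-activated, 3% co-repressed, 3% relieved, 10% single-stimulus TNF, 12%
single-stimulus HS) keeps the qualitative ordering of the real data —
antagonism is the largest co-affected class — while leaving every class
populated at simulation sizes of a few thousand genes.

Genes sit on one synthetic chromosome at a fixed 20-kb TSS spacing, so
10-kb regulatory windows of neighbours never overlap and planted binding is
attributable to exactly one gene. Promoters are i.i.d. background (uniform
base composition by default) with motif consensus instances inserted at
recorded offsets and strands; planting probabilities are class-dependent so
TNF-responsive classes are κB-enriched and HS-responsive classes
HSE-enriched. Binding uses a shared basal peak set placed independently of
the truth plus, for induced genes, a strong peak (score 10–30 versus basal
2–6) inside the window at both HS timepoints, with a 30% chance of a weak
control-leak peak; peak widths are uniform on 200–800 bp, the typical
sonicated chromatin fragment range. Term tables carry four marker terms
enriched in the co-affected classes over a 5% background rate.

Every generator derives an independent seed from `rng_seed`, so artifacts
are bit-reproducible and reproducible independently of call order. What
the generator does *not* emulate: probe-level microarray effects and
normalisation artifacts, correlated replicate structure (the emulated
design pooled biological RNA and ran technical replicates; the generator's
noise is generic i.i.d.), read-level ChIP-seq (no FASTQ), linked genes
sharing windows, and non-uniform genomic background. Passing recovery
tests on these simulations therefore demonstrates the correctness of the
statistical machinery under its own assumptions, not performance on raw
instrument data.

# Numerical choices and degenerate inputs

* Zero posterior variance in the moderated test yields $t = \pm\infty$,
  p = 0 for a non-zero mean difference and $t = 0$, p = 1 otherwise, so the
  noise-free limit classifies planted modes with accuracy 1 (a test-suite
  invariant).
* The trigamma inverse in the moderation fit uses Newton iteration with the
  standard asymptotic guards; genes with exactly zero variance are excluded
  from the moment fit and an all-zero-variance matrix is an error.
* `smooth.spline` failures in $\hat\pi_0$ estimation (few distinct
  p-values) degrade to BH rather than erroring.
* Peak merging treats bins as adjacent only when `end == next start` on the
  same chromosome; p-values are floored at 1e-300 before `-log10` scoring.
* Ties in PWM consensus extraction resolve to the alphabetically first
  base; "N" columns contribute zero log-odds either way.
* Empty inputs return empty, correctly-typed tables throughout (a sequence
  shorter than the motif is an empty scan, not an error).

# Problem sizes used in validation

The bundled checks run the generator at 5000 genes × 10 seeds for
recovery metrics (mode-classification accuracy, DE sensitivity and realized
FDR, induced-binding sensitivity), 2000 genes for null calibration of the
moderated test, and 50 seeds × 1000 bins for peak-caller calibration —
sizes at which the binomial/multinomial tolerances in the tests are sharp
enough to be meaningful while a full run stays comfortably interactive.

# Known limitations

* The moderated statistic assumes roughly normal log2 intensities with
  gene-specific variances exchangeable under a single inverse-chi-square
  prior; heavy-tailed noise will inflate the prior df estimate.
* The score-route induced-binding rule compares peak scores, which are
  caller-dependent; cross-caller score scales should use the tag-count
  route instead.
* Flat-label enrichment ignores term ancestry, so parent/child terms are
  tested as unrelated.
* The built-in peak caller is for simulation-scale data and method
  validation, not a substitute for a production caller on real read data.
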