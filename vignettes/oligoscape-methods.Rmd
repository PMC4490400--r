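---
title: "Cohort-level genomics of anaplastic oligodendroglioma: models and methods"
author: "oligoscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cohort-level genomics of anaplastic oligodendroglioma: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligoscape)
```

# Scope

Anaplastic oligodendroglioma (AO) is a WHO grade III glial tumour defined
molecularly by IDH mutation and 1p/19q co-deletion. `oligoscape` implements
the cohort-level statistical layer of an AO exome/array/RNA-seq study as a
reusable, testable pipeline: everything downstream of variant calling,
segmentation and normalisation, and upstream of biological interpretation.
Read alignment, somatic calling, per-gene driver-significance engines
(MutSigCV-style), dye-bias normalisation, segmentation and fusion discovery
are deliberately out of scope; their outputs are this package's inputs.

Because the cohorts such analyses run on are controlled-access, the package
ships a synthetic-cohort generator whose draws have exactly the statistical
structure the analyses assume, with exported ground truth. Every stage is
exercised against generated cohorts; nothing requires a download.

# The binomial gene-set burden test

The central statistic asks whether a gene set P carries more somatic
mutations than a uniform per-base mutation process would give it. With G the
universe of sequenced genes with coding lengths L(g), S the tumour cohort of
size $n$, $A(G,S)$ the total mutation count across the cohort, and
$L(X) = \sum_{g \in X} L(g)$, the observed count $m$ in P is referred to

$$X \sim \mathrm{Binomial}\!\left(k,\; p\right),\qquad
k = n \cdot L(P),\qquad p = \frac{A(G,S)}{n \cdot L(G)},$$

and the reported value is the exact upper tail $P(X \ge m)$.

Numerical choices:

* The tail is the survival function evaluated at $m - 1$ in log space
  (regularised incomplete beta), exact with no normal approximation. It is
  stable for $k$ well beyond $10^8$ — tails with $\log p \approx -400$
  evaluate cleanly.
* $P(X \ge 0) = 1$ exactly, so an unmutated set never looks depleted.
* Set members absent from the sequenced universe are excluded from $L(P)$
  (the formula is defined over genes sequenced with sufficient coverage);
  the exclusion count is logged so denominators are never silently wrong.
* Across a scanned collection we report raw binomial P values — the
  convention for this statistic — plus Benjamini–Hochberg q-values as a
  clearly labelled extra column. Overlapping sets are tested marginally
  with no joint correction.

The per-base model is also exactly the generator's null (below), which makes
calibration checks meaningful: on null cohorts the fraction of random
50-gene sets at $p < 0.05$ sits near, and slightly below, 5% — slightly
below because the discrete tail is conservative.

The length input is deliberately explicit: whether $L(\cdot)$ should be
exonic length or total targeted footprint is a property of the capture
design, so the package requires `coding_length_bp` as data and never infers
it. Gene identity is by case-sensitive symbol with no alias resolution.

# Copy-number aberrations and LOH

Segments arrive as allele-specific copy-number calls (total and minor-allele
copy number per interval, with probe support), plus a per-sample ploidy.
Classification is ploidy-relative, with thresholds applied to real-valued
copy number exactly as stated — no rounding:

| category | rule |
|---|---|
| homozygous deletion | total CN $= 0$ |
| high-level amplification | total CN $>$ ploidy $+ 2$ |
| gain | total CN $\ge$ ploidy $+ 1$ |
| loss | total CN $\le$ ploidy $- 1$ |
| neutral | otherwise |

The printed rules overlap (CN $= 0$ also satisfies the loss rule; an
amplification also satisfies gain), so we impose the precedence homozygous
deletion $>$ amplification $>$ gain/loss $>$ neutral; every segment gets
exactly one category. LOH is flagged independently whenever minor CN $= 0$,
which covers copy-neutral LOH (total $=$ ploidy, minor $= 0$).

Focal events — homozygous deletions and high-level amplifications — must be
supported by at least five consecutive probes. This deterministic
minimum-probe filter stands in for any manual curation of doubtful events:
reproducibility was preferred over heuristic review.

Arm-level recurrence uses segment-length-weighted coverage with 1-based
inclusive lengths (end − start + 1): a sample has "lost an arm" when
loss-classified segments cover at least a fraction (default 0.9) of the
arm's length. The 0.9 default is ours: co-deletion and recurrent arm losses
are whole-arm events, but segmentation jitters boundaries, so demanding
100% coverage would be brittle while 50% would admit focal losses. Arm
coordinates ship as an hg19 table with boundaries at centromere gap
midpoints.

# Molecular subtype assignment

The conventional three-way partition: IDH-mutant 1p/19q co-deleted,
IDH-mutant non-co-deleted, IDH wild-type. IDH-mutant status is defined
narrowly by the hotspots — IDH1 codon R132 or IDH2 codon R172; other
IDH1/IDH2 variants (an IDH2 P162S, say) do not qualify. IDH status takes
precedence, so a hypothetical IDH-wild-type sample with 1p/19q loss is
still IDHwt. Co-deletion requires the arm-loss rule above on both 1p and
19q; absent coverage of either arm propagates as non-codel with a warning
rather than a hard failure.

TERT promoter annotation matches the two recurrent hg19 positions on
chromosome 5 — 1,295,228 (C228T) and 1,295,250 (C250T), G>A on the assayed
strand. The allele check is enforced as a warning, not an error, since the
strand convention of an assay table is a frequent source of benign
disagreement; position is the call-defining evidence.

# Mutation landscape

Per-sample burden counts all somatic mutations and divides by the target
footprint in Mb; the cohort-level mutations-per-Mb convention counts total,
not non-silent, mutations (a flag switches). "Non-silent" is fixed to
{missense, nonsense, splice site, frameshift, in-frame indel}. Samples above
3× the cohort median rate are flagged as hypermutators in the log but never
excluded automatically — exclusion is an analyst's decision.

The substitution spectrum collapses the 12 ordered single-base changes onto
6 classes by reverse-complementing purine-reference changes (G>A becomes
C>T), the standard pyrimidine-reference convention.

Sample ordering for landscape (oncoprint) display uses memo-sort, the
standard mutual-exclusivity ordering: genes ranked by descending mutation
frequency, samples sorted by the descending binary word over the ranked
genes, ties broken stably by sample identifier. The output is always a
permutation of the samples and is invariant to input column order.

# Fusion filtering

Chimeric-transcript candidates are reduced to high-confidence calls by three
rules, applied per candidate row: spanning reads strictly greater than 2;
total supporting reads at least 10 (note the asymmetry — strict versus
inclusive — is intentional and pinned by boundary tests); and the gene pair
must not appear in a normal-tissue blacklist. Blacklist matching defaults to
unordered pairs, the conservative choice given that orientation conventions
differ between callers; ordered semantics are available. Every rejected
candidate reports the first rule it failed, in the order spanning, total,
blacklist. The filter is idempotent.

# Expression contrast

Differential expression between mutant and wild-type groups uses a per-gene
two-sample t-test on log2 intensities — Welch by default, pooled-variance as
an option. The original analysis of this design used limma's moderated
t-test; empirical-Bayes variance moderation is intentionally not replicated
here, and all of this package's statistical properties (type-I behaviour,
recovery) are defined against its own test. At the 20-per-group scale the
generator emulates, moderation mostly matters for very small groups; users
wanting moderated statistics can export the matrix to limma directly.

A gene is called significant iff raw $p < 0.05$ and $|\mathrm{logFC}| >
0.6$; whether the original threshold was adjusted is not stated, so we treat
it as raw and report BH q-values alongside, flagged as extra. logFC is
mutant minus wild-type, so downregulation in mutants is negative. Genes with
zero variance are dropped from the universe (logged), since a t-statistic is
undefined for them.

Gene-set over-representation in the significant list is the hypergeometric
upper tail — draw |DE| genes from the universe without replacement, compute
$P(\text{overlap} \ge \text{observed})$. Gene-set activity is the per-sample
mean over set members present in the matrix, with samples ranked by
descending activity and stable ties.

# Cohort statistics

Mutation frequencies carry exact Clopper–Pearson intervals, obtained by
inverting the binomial tails (beta-quantile form); degenerate bounds are
exactly 0 and 1. This method was fixed because it reproduces the published
AO TCF12 interval for 10 carriers of 134 tumours: point 7.5%, bounds
3.6365% and 13.2959% — printed as 3.6–13.2% at one truncated decimal.
Exactness makes coverage conservative (the analytic coverage at
$p = 0.075$, $n = 134$ is 95.26%).

2×2 comparisons report the closed-form chi-square
$N(ad-bc)^2 / ((a{+}b)(c{+}d)(a{+}c)(b{+}d))$, its Yates-corrected variant
on request, and Fisher's exact two-sided p by the point-probability
convention (documented because two-sided Fisher conventions differ). A zero
margin leaves the chi-square undefined while Fisher is still computed.
Survival analysis and power computations are out of scope.

# The synthetic generator

What it emulates, with defaults fixed at the emulated study's scale:

* **Mutations** — 51 samples over a 50 Mb universe (10,000 genes × 5 kb) at
  1.6×10⁻⁶ mutations per base per sample; per-gene, per-sample counts are
  Binomial(L(g), rate × multiplier), i.e. independent per-base events — the
  burden test's exact null, so calibration tests are meaningful and spike
  multipliers cleanly break the null for recovery tests. The substitution
  mix is C>T-dominant (weight 0.55) with random reporting strand; 40% of
  records are non-silent, matching the emulated cohort's arithmetic of ~37
  non-silent among ~93 mutations per sample. Designated samples receive an
  IDH1 R132H (or, 15% of the time, IDH2 R172K) hotspot record.
* **Copy number** — whole-arm events drawn independently per sample at
  stated frequencies; comma-joined arm groups ("4p,4q", "1p,19q") are lost
  jointly. Lost arms are ploidy−1 with minor 0; background is neutral;
  planted focal homozygous deletions split the surrounding arm segment so
  profiles always validate as non-overlapping. Probe counts come from a
  uniform 300 probes/Mb density.
* **Expression** — per-gene baseline N(7, 1) log2 intensity plus N(0, 0.5)
  per-sample noise; shifted sets add their stated log2 shift in the mutant
  group.
* **Fusions** — true candidates satisfy all three filter rules; each decoy
  class violates exactly one designated rule.

Every generator is a pure function of its parameters and a single explicit
seed (verified by double-run identity), and every emitted file passes the
package's own validators. `write_synthetic_bundle()` emits a complete,
subtype-consistent input directory plus `truth.json`.

What the generator does **not** emulate — and hence what passing recovery
tests do not demonstrate about real data: trinucleotide-context signatures
(only the 6-class marginal is matched), covariate structure in mutation
rate (replication timing, expression level — the reason MutSigCV-class
methods exist), subclonal copy-number mixtures and normal contamination,
segmentation noise beyond whole-arm jitter, correlated expression modules,
and read-level artefacts. The burden test's known vulnerability to
rate covariates is untouched by these tests, since the generator's null is
uniform by construction.

# Problem sizes and determinism

The packaged checks run at deliberately chosen scales: calibration uses one
51-sample, 50 Mb null cohort and 10,000 random 50-gene sets; recovery uses
200 replicate 20-sample cohorts scanning 100 sets each; expression recovery
uses 100 replicates of a 2,000-gene, 20 vs 20 design with 50 scanned sets;
interval coverage uses 5,000 simulated draws. These sizes give the binomial
sampling error on each estimated rate a comfortable margin relative to the
property bounds they are checked against. All randomness flows from
explicit seeds; reruns are byte-identical.

# Known limitations

* The burden test assumes a uniform per-base rate; on real cohorts it will
  rank covariate-driven hot sets (large, late-replicating genes) above
  truth. It reproduces the published statistic; it is not a driver caller.
* Arm-call thresholds (0.9 coverage) and the generator's whole-arm geometry
  are idealisations; heavily fragmented real profiles will sit closer to
  the threshold.
* The expression contrast is unmoderated; very small groups lose power
  relative to limma.
* Gene symbols are matched exactly; harmonising aliases across input tables
  is the caller's responsibility.
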