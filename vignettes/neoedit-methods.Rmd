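---
title: "Models and design choices in neoedit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in neoedit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoedit)
```

This vignette documents the statistical models behind `neoedit`, the
parameters that matter, the numerical choices made where the method left
room, and what validation on synthetic cohorts does and does not
demonstrate about real data.

## The read-count model for cancer cell fractions

Every inference in the package rests on one generative model: a mutation
present in a fraction CCF of tumor cells, on one chromosomal copy, in a
sample of purity $p$ with locus copy numbers $CN_t$ (tumor) and $CN_n$
(normal), produces alternate reads at expected frequency

$$\mathrm{VAF}(\mathrm{CCF}) = \frac{p\,\mathrm{CCF}}{CN_n (1-p) + p\, CN_t},$$

and the observed alternate count $x$ out of depth $N$ is
$\mathrm{Binomial}(N, \mathrm{VAF}(\mathrm{CCF}))$. The inverse mapping is
the mutation copy number
$n_\mathrm{mut} = \mathrm{VAF}\cdot\frac1p\,[p\,CN_t + CN_n(1-p)]$, the
fraction of tumor cells carrying the mutation multiplied by the number of
mutated copies.

Two classifiers are built on this model, and both are exposed because
different studies use different ones; neither is declared canonical:

* **Interval rule** (`ccf_posterior()`): the binomial likelihood is
  evaluated on the closed grid $0.01, 0.02, \ldots, 1.00$ (100 points),
  normalized under a flat prior, and the mutation is clonal when the 95%
  credible interval overlaps 1.
* **Threshold rule** (`infer_multiplicity()`): multiplicity $C$ is chosen
  by binomial maximum likelihood among $1,\dots,CN_t$; the mutation is
  clonal when $n_\mathrm{mut}/C > 0.95$ (strict).

### Numerical choices

* The 95% interval on the discrete posterior is **equal-tailed**: the
  largest prefix and suffix of the grid each holding at most 2.5% of the
  mass are dropped. The interval definition was genuinely open; the
  equal-tailed form is order-independent and reproducible, and "overlaps
  1" reduces to the upper bound reaching the last grid point (within half
  a grid step, $\varepsilon = 0.005$).
* All binomial pmfs are computed in log space, so depths up to $10^3$
  cannot underflow.
* In the threshold rule the expected read fractions are clamped to
  $[10^{-6}, 1-10^{-6}]$: with $p = 1$ and $C = CN_t$ the expected
  fraction is exactly 1, which would give zero likelihood to any
  $x < N$ and make the argmax degenerate.
* Multiplicity likelihood ties break toward the smallest $C$, the
  conservative (higher-CCF) choice.
* $n_\mathrm{mut}/C$ may exceed 1 from sampling noise; the raw value is
  retained (`ccf_raw`) and the capped value classifies.
* The multiplicity range runs over the **total** copy number $CN_t$;
  allele-specific major/minor columns are accepted and validated but do
  not restrict the range.
* Mutations falling in no copy-number segment default to diploid with a
  warning; mutations in $CN_t = 0$ segments are excluded (the VAF model
  is undefined there) and counted.

### A boundary bias worth knowing about

Both classifiers are biased *against* clonality exactly at CCF = 1,
because the estimate sits on the boundary of the parameter space: any
downward sampling fluctuation pulls the interval or the point estimate
below the cutoff, while upward fluctuations cannot compensate. The effect
is computable exactly. At depth 200 and purity 0.8, summing over the
binomial distribution of $x$, a truly clonal mutation is called clonal
with probability 0.891 by the interval rule and 0.692 by the threshold
rule; at depth 100 the numbers are lower still. (The subclonal side is
essentially error-free: a true CCF of 0.3 is called subclonal with
probability ~1 under both rules.) The test suite therefore validates
per-mutation calibration against this exact oracle rather than against a
nominal recall, and fraction-of-clonal-mutations summaries are best read
from the Dirichlet-process cluster weights, which do not suffer the
boundary effect — a cluster *located* at 1 absorbs its members regardless
of their individual fluctuations.

## Purity estimation

Marker mutations known to be homozygous in the originating cell line have
expected VAF 1 in a pure sample; in a contaminated sample the expectation
is exactly $p$ when the marker lies in a diploid region. `estimate_purity()`
is the arithmetic mean marker VAF over diploid segments. With 200 markers
at depth 100 the standard error is about 0.003, so the ±0.02 recovery
asserted in the tests has a wide safety margin. When no marker qualifies
the function refuses and asks for an explicit purity rather than guessing.

## Dirichlet-process clustering

Clonal architecture is modeled as a mixture over CCF space with an
unknown number of components. The sampler is a truncated stick-breaking
Gibbs sampler chosen to reuse the package's own grid machinery and to
stay dependency-free:

* truncation at $K_{\max} = 20$ components; stick fractions
  $v_k \sim \mathrm{Beta}(1+n_k, \alpha+n_{>k})$;
* concentration $\alpha$ under a $\mathrm{Gamma}(1,1)$ prior, resampled
  every iteration;
* component locations sampled by **grid-Gibbs** over the same 100-point
  CCF grid (per dimension for joint 2-sample fits), with the full
  binomial read likelihood and each mutation's own purity and copy
  numbers — no conjugate approximation;
* assignments by Gumbel-max categorical draws;
* defaults: 2000 iterations, 1000 burn-in, seed 17. The fit is a
  deterministic function of data and seed.

Component summaries are label-switching-safe: clusters are reported
sorted by location. A component is retained when it holds at least
`min_weight` (default 1%) of the mutations at the posterior-mode
assignment; members of dropped components are reassigned to the nearest
retained cluster in location space. Reported locations are
occupancy-weighted posterior means, and cluster weights are final
membership fractions. With a single mutation the sampler collapses to the
grid posterior of that mutation, which the tests verify by comparing the
empirical location CDF at 5000 kept samples against `ccf_posterior()`.

For two samples fitted jointly, each mutation needs read counts in both;
`pair_counts()` encodes absence as zero alternate reads at the sample's
median depth (floored at 30), so a lost subclone appears as a cluster at
$(\mathrm{CCF}_1 > 0, \mathrm{CCF}_2 \approx 0)$, off the leading
diagonal. `density_grid()` histograms the stored stick-weighted location
samples; unoccupied components carry only the residual stick mass
(about $\alpha/(n+\alpha)$), so the grid is dominated by real structure.

## Neoantigen filters

Mutant 8–11-mers are enumerated as every full-length window containing
the substituted residue; an interior missense site yields exactly
$8+9+10+11 = 38$ peptides. Binding affinities are consumed from an
external predictor's table and aggregated per peptide as the minimum IC50
across alleles (the strongest binder determines immunogenicity).
Thresholds are strict at the conventional values: binder iff
IC50 < 500 nM, expressed iff normalized counts > 5; the two filters
commute. Candidates with no affinity entry are excluded, never imputed.
Stop-gained mutations produce no mutant peptide (a premature stop creates
no novel residues), so they count as nonsynonymous mutations but not as
neoantigen sources. Neoantigen status is collapsed to mutation
granularity: a mutation is neoantigenic if any of its peptides survives
both filters, which is the granularity at which editing statistics are
computed.

## Editing statistics

Group membership uses the presence-in-any collapse over replicates, after
the ≥10-alternate-reads detectability filter; the filter is applied to
the final mutation table. Mutation identity across samples is the
`(chrom, pos, ref, alt)` key; gene and consequence are annotations.
`editing_report()` partitions baseline and comparison key sets into
shared/lost/gained with percentages relative to the baseline size, and,
when annotations are supplied, reports the same partition for expressed
strong-binder neoantigens plus per-class loss fractions
(neoantigenic-subclonal, neoantigenic-clonal, non-neoantigenic). The
non-neoantigenic loss fraction doubles as the detection-noise floor
against which a genuine editing signal must stand out. No hypothesis
tests are attached to the ratios; they are reported descriptively.

## The synthetic cohort generator

`sim_config()` defaults describe the kind of sample the pipeline targets:
a hypermutated, mostly diploid carcinoma cell-line transplant.

| parameter | default | rationale |
|---|---|---|
| clones | CCF 1.0 at 70%, CCF 0.4 at 30% | dominant clonal cluster with a 60–70% clonal fraction |
| purity | 0.8 | transplanted-tumor purities sit in (0.5, 1] |
| depth | Poisson(100), floored at 10 | exome-like coverage variability |
| copy numbers | 19 diploid autosomes, one focal gain (CN 4), one focal loss (CN 1) | mostly diploid genome with focal events |
| consequences | 94% missense / 6% stop-gained | observed nonsynonymous composition of hypermutated lines |
| binder fraction | 0.5 of missense | about half of missense mutations yield a predicted strong binder |
| expressed fraction | 0.5 of genes | together with the binder fraction gives an expressed-neoantigen:mutation ratio ≈ 0.25 |
| markers | 200 homozygous diploid, multiplicity 2 | purity estimation support |

Read counts follow exactly the binomial model above (markers at
multiplicity $= CN_t$, so their expected VAF is $p$ in diploid regions).
Editing in `simulate_pair()` removes an exact rounded count of eligible
neoantigenic mutations from the clone structure — biological loss, not
read masking — so the derived sample draws zero alternate reads for them;
gained mutations are injected as new subclonal variants private to the
derived sample. Replicates redraw depths and counts independently and
apply per-mutation Bernoulli detection dropout.

What the generator does **not** emulate: sequencing error and strand
bias, mapping artifacts, germline contamination of the somatic call set,
indels, subclonal copy-number changes, correlated dropout between
replicates, and any dependence of immunogenicity on peptide sequence.
Passing the synthetic validation therefore demonstrates that the
inferential chain is correct under its own model assumptions — it does
not certify calibration on real reads, where the binomial noise model is
optimistic.

## Problem sizes used in validation

The test suite and the acceptance script run at deliberately moderate
sizes — cohorts of 300–2000 mutations at ~100–200× depth, DP fits of
300–1000 mutations with 600–2000 Gibbs iterations — which keep the full
validation run in the low minutes on a single core while leaving the
Monte-Carlo error of every asserted quantity well inside its tolerance
(e.g. cluster locations ±0.05, editing fraction ±5 percentage points).

## Known limitations

* Joint DP fits support at most two samples; multi-region designs need
  pairwise fits.
* No joint purity–ploidy inference: purity comes from homozygous markers
  or the caller.
* LOH segments and binding affinities are consumed, never computed.
* The per-mutation clonality classifiers carry the boundary bias
  described above; population-level clonal fractions should come from
  cluster weights.
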