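---
title: "Calling Polycomb domains and profiling their nucleosome-scale topology"
author: "pcgtopo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling Polycomb domains and profiling their nucleosome-scale topology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcgtopo)
```

# The model

`pcgtopo` analyses broad H3K27me3-enriched (Polycomb, PcG) chromatin
domains from replicated ChIP-seq coverage. Its statistical model is
deliberately minimal: read-base coverage summed in 100 bp windows at 50 bp
steps is treated as approximately Poisson in unenriched background, and
enrichment is whatever exceeds that Poisson expectation reproducibly
across replicates. On top of the called domains, the package's
contribution is a family of *topology* parameters that measure whether the
nucleosome-scale shape of the enrichment profile — not just its amount —
is conserved across replicates and across biological conditions.

## Domain calling

Three thresholds are applied in sequence.

**Coverage minimum `T`.** For every integer threshold $t$ the number of
windows genome-wide with coverage sum $> t$ is compared with the Poisson
prediction $N \cdot P(X > t)$, $X \sim \mathrm{Pois}(\hat\lambda)$,
$\hat\lambda$ the genome-wide mean window sum. `poisson_threshold` returns
the smallest $t$ at which the observed count is at least `excess_ratio`
(default 2) times the prediction, clamped into a configurable band. Two
numerical choices matter here:

* A *minimum observed-window count* (`min_windows`, default 30) guards the
  crossing rule. Without it, the single largest window in any finite
  sample always produces a spurious crossing in the extreme tail, where
  the prediction is essentially zero; requiring ~30 windows makes a
  2-fold excess at the crossing point overwhelmingly unlikely under a
  pure Poisson sample while costing nothing when genuine enriched mass
  (thousands of windows) is present.
* The *clamp band* exists because deep genome-wide libraries justify only
  minor adjustments of `T` around its operating point; both the excess
  ratio and the band are exposed in the configuration rather than fixed.

**Composite threshold.** A window is *composite-enriched* when at least a
fraction `f` (default 2/3) of the replicates meet or exceed `T` at that
window. The boundary is inclusive: three replicates at exactly `T` count.

**Density threshold.** A candidate core enrichment domain (CED) is any run
of 40 consecutive *enriched* windows whose positions (window starts) span
at most 4 kb. "Consecutive" refers to the ordered list of enriched
windows, so small internal gaps of unenriched windows are tolerated as
long as the density bound holds; at the default geometry the minimum
accepted density is exactly 40 bins over 80 step positions, i.e. 50%. The
span is measured over window *positions* rather than window extents: this
makes the 50% density statement exact and bounds CED interval length to
[2050, 4100] bp. Overlapping candidate runs are kept (deduplicated by
identical span) and resolved by the merge stage.

**Correlation filter and merging.** For each candidate CED, per-replicate
vectors $v_i(w) = \ln(\text{sum})$ (or 0 when the sum is below `T`) are
formed over the CED's windows, and the mean of the off-diagonal entries of
their pairwise Pearson correlation matrix — the *mean correlation
estimate*, meanCE — is computed. Pairs in which either vector has zero
variance contribute 0 rather than being dropped: this keeps meanCE defined
and penalises uninformative replicates (a configuration switch restores
drop behaviour). Natural logarithm is used; correlation is invariant to
the log base, so the choice is documented purely for bit-reproducibility.
CEDs with meanCE $\le 0$ are discarded, and surviving CEDs that overlap by
at least one base (half-open coordinates; touching intervals do not
overlap) are merged transitively into disjoint PcG regions.

The caller is deterministic, strand-ignorant (micrococcal-nuclease
chromatin gives no basis for a shift model), and anchored: windows start
at position 0, trailing partial windows are dropped, and all coordinates
are 0-based half-open.

## Topology parameters

Within a region, fixed 2 kb segments slide at 50 bp steps, anchored at the
region start with the trailing partial segment dropped. Per segment:

* **LCE** (local correlation estimate) applies the meanCE construction to
  the segment's 39 windows. It is scale-invariant: multiplying a replicate
  by a positive constant (above threshold) leaves it unchanged.
* **LCS** (local coverage sum) is the segment total of replicate-mean
  window sums; it scales linearly with coverage. Replicate mean rather
  than sum is used — a pure scale factor, invisible to every downstream
  correlation.

Correlating two conditions' per-segment LCE (or LCS) vectors yields
region-level `lce_corr` and `lcs_corr` (`region_correlation`; Pearson by
default, rank correlation by option; zero-variance or <3 complete
segments report missing). The diagnostic contrast is a region with high
`lcs_corr` but low `lce_corr`: its coverage envelope is conserved while
its fine-scale topology has remodeled.

**eigenCE** is the largest eigenvalue of the replicate correlation matrix
divided by its trace. For a compound-symmetric $3 \times 3$ matrix with
off-diagonal $r \ge 0$ this equals $(1 + 2r)/3$ exactly; for $r < 0$ the
leading eigenvalue switches to the contrast component $1 - r$, so the
identity holds only on the non-negative branch — the relevant one, since
CEDs with non-positive estimates never reach this stage.

## Cross-condition comparison

Matched groups are built around genes: regions from each
condition-replicate set that overlap a shared gene are collected, and a
group is retained when at least one condition is fully represented with
pairwise reciprocal span overlap $\ge$ 50% among its replicate
representatives. *Reciprocal span overlap* is intersection over union (a
switch selects intersection over the shorter span). The outer comparison
boundary is the maximal extension of members that overlap their
condition's mean boundary interval, where the mean boundary is the
per-condition mean of representative starts and ends across replicates —
one reading of an under-specified rule; it is the package's documented
default.

Span change is called from the nine pairwise RL (region-length) ratios
between two conditions' three replicate spans: `increase` requires all
nine above the all-comparisons threshold *and* their mean above the mean
threshold; `decrease` is the same rule on the reciprocals, which makes the
call exactly antisymmetric under side swap. Fold change is assigned only
when the summed-span ratio and the largest-region ratio agree in
direction, with the largest-region ratio as the magnitude.

## Region-gene statistics

Genes link to regions by any-overlap ($\ge$ 1 bp). Regions are classed by
the majority direction of their significantly changed genes (FDR < 0.05),
with ties and gene-less regions excluded from up:down ratios. Resampling
p-values for a subset's median logFC use samples with replacement from the
population, with the add-one correction, so the attainable floor at depth
$n$ is $1/(n+1)$. The virtual-region null places span-matched intervals
uniformly on the genome and accepts a placement only when its
gene-clustering statistic — the mean number of linked genes per
gene-overlapping region — is within a relative tolerance (default 20%) of
the real set's value, with rejection sampling capped at 100 attempts; an
exclusion mode additionally redraws any virtual region touching a
real-set-linked gene. Significance of the real up:down ratio against the
pooled null counts uses Fisher's exact test; two-sided tests are the
default throughout. Genes spanning two regions contribute to both regions'
direction calls but are counted once in gene-level ratios. BH FDR is the
standard step-up adjustment.

# The synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
under which all end-to-end properties are demonstrated.

* **Design**: 3 replicates in each of six conditions (monocyte/dendritic
  cell crossed with newborn/young-adult/old-adult), 36 bp reads, and
  Poisson background coverage with a default mean of 30 per 100 bp window
  — a depth at which the data-driven coverage minimum lands in the high
  40s, the regime the calling thresholds were designed for.
* **Planted domains** default to log-normal spans with median 10 kb
  (capped at 178 kb, the scale of the largest Polycomb domains) at 6x
  enrichment. Edge windows receive proportional partial enrichment, so
  boundaries are soft at the sub-window scale exactly as in real pileups.
* **Internal structure.** Within a domain the expected rate is the product
  of (i) a smooth coverage envelope — a random-phase sinusoid with log
  amplitude 0.5 and 20 kb period, shared across conditions — and (ii)
  mean-one relative modulation blocks of 200 bp (nucleosome scale), whose
  contrast level is drawn per 2 kb tile from a range (log-sd 0.02-0.6,
  weighted toward the flat end) that straddles the Poisson noise floor.
  This produces the full range of local correlation values observed in
  real enrichment profiles: flat tiles yield LCE near zero, structured
  tiles near one.
* **Remodeling modes.** `span_change` rescales the interval about its
  midpoint in the target conditions; `coverage_change` multiplies the
  enrichment; `topology_shuffle` permutes the relative modulation blocks
  across the domain independently per condition while leaving the
  position-fixed envelope untouched, so 2 kb window-sum totals are
  conserved in expectation (the envelope component exactly) while the
  fine-scale arrangement decorrelates. This is precisely the perturbation
  the LCE-vs-LCS contrast is built to detect, and the within-condition
  replicate structure is unaffected because replicates are independent
  Poisson draws around the shared (shuffled) condition profile.
* **Expression.** Genes are placed uniformly; genes overlapping
  span-increase domains receive a planted negative logFC (default $-2$),
  with symmetric defaults for the other remodeling classes; per-gene
  noise doubles as the standard error for p-values, so null z-scores are
  standard normal and BH control is exact under the null. Baseline logCPM
  decreases with overlapping-domain span at 0.37 per kb, reproducing
  \>50-fold repression at ~15 kb spans; a +1 activation shift for
  domain-linked genes supports the differentiation-activation analysis.
* An optional reads mode emits 36 bp intervals whose pileup reproduces the
  window rates, at a read-start density of
  $\lambda / (\text{read length} \times \text{window})$ per bp, so the
  pileup operation is exercised without genome-scale cost.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: read sequences and mappability, GC bias,
fragment-length structure, input/control normalisation, copy-number and
blacklist artefacts, inter-replicate depth differences, and any
heavier-than-Poisson replicate noise. The generator's replicate noise is
exactly Poisson around a shared profile; real replicates add biological
and library-preparation variance that would lower LCE values globally.
Conclusions about detection rates and calibration therefore transfer to
real data only qualitatively.

# Problem sizes and numerical choices

The test suite and the acceptance script run at sizes chosen to make the
measured properties stable: planted-domain recovery uses a two-chromosome
5 Mb genome with 20 domains over 100 seeds (2000 domain instances);
topology detection uses 100 shuffled plus 100 control domains; the
resampling calibrations use 20 simulated datasets with 150 virtual-region
draws each and 120 regions / 900 genes on a 10 Mb genome, a size at which
the planted 0.8 down-bias sits in the high-power regime of Fisher's test.
Correlation kernels are computed from cumulative sums (constant-time per
candidate range) and verified against direct `stats::cor` computation to
$10^{-8}$; variance terms below $10^{-7}$ are treated as zero, the
threshold sitting many orders of magnitude above accumulated rounding for
genuine variation and below any real signal.

# Known limitations

* The coverage-minimum rule formalises a visual criterion; its
  `excess_ratio`, guard count and clamp band are defensible defaults, not
  estimates.
* The outer-boundary rule for matched groups implements one reading of an
  ambiguous prescription (per-condition mean of replicate boundaries);
  alternative readings would shift outer extents by fractions of a member
  span.
* The clustering-correction statistic for the virtual-region null (mean
  linked genes per overlapping region, ±20%) is one of several reasonable
  choices; both statistic and tolerance are configuration-exposed.
* Quantile-restricted subset ratios report region-level majority ratios
  with gene-level Fisher tests; with very small subsets the region ratio
  is undefined whenever no majority-down region remains, and is reported
  as missing rather than imputed.
* The package consumes aligned read intervals or binned tracks and a
  precomputed expression table; alignment and differential-expression
  model fitting are out of scope.
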