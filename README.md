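# pcgtopo

Broad domains of the repressive histone mark H3K27me3 demarcate
Polycomb-group (PcG) chromatin in vertebrate genomes. These domains span
kilobases to megabases, repress the genes they overlap, and remodel during
differentiation and postnatal development. Standard peak callers describe
them by span and coverage only; `pcgtopo` additionally quantifies the
*nucleosome-scale conservation of their internal topology* across replicate
ChIP-seq experiments, a dimension of epigenome structure that span and
coverage miss.

The package is aimed at computational epigenomics work with replicated
binned ChIP-seq coverage: it calls domains, profiles their internal
structure, matches them across conditions (cell state, donor age), and
links their properties to gene-expression change with resampling null
models. A synthetic-data generator with planted domains and known ground
truth makes every stage testable end to end.

## The method

**Domain calling** proceeds through three thresholds on 100 bp coverage
windows tiled at 50 bp steps:

1. *Coverage minimum* `T`: chosen where the genome-wide observed exceedance
   count crosses twice the Poisson prediction at the genome-wide mean
   window sum (`poisson_threshold`).
2. *Composite threshold*: a window is enriched when `T` is met or exceeded
   in at least 2 of 3 replicates (`composite_mask`).
3. *Density threshold*: a candidate core enrichment domain (CED) is any run
   of 40 consecutive enriched windows whose positions span at most 4 kb —
   at least 50% of the 50 bp positions enriched, small internal gaps
   allowed (`density_scan`).

Each candidate CED is scored by the **mean correlation estimate**: with
per-replicate vectors `v_i(w) = ln(coverage)` (or 0 below `T`) over the CED
windows,

    meanCE = mean of the off-diagonal entries of the pairwise
             Pearson correlation matrix of v_1, v_2, v_3

CEDs with meanCE <= 0 are discarded; overlapping survivors merge into
disjoint PcG regions (`merge_ceds`, `call_regions`).

**Topology profiling** slides fixed 2 kb segments at 50 bp steps inside a
region and computes per segment the *local correlation estimate* (LCE, the
meanCE construction on the segment's windows) and the *local coverage sum*
(LCS, the segment total of replicate-mean coverage). Correlating two
conditions' per-segment vectors gives region-level `lce_corr` and
`lcs_corr`: a region whose coverage envelope is conserved but whose
fine-scale topology has remodeled shows high `lcs_corr` with much lower
`lce_corr`. An eigenvalue variant (`eigen_ce`, largest eigenvalue of the
replicate correlation matrix over its trace) satisfies
`eigenCE = (1 + 2 meanCE) / 3` under compound symmetry.

**Comparison and association**: regions are matched across conditions
through shared genes with >= 50% reciprocal span overlap
(`match_regions`), span change is called only when all nine
replicate-pair RL ratios agree and their mean clears a threshold
(`span_change_call`), and region properties are linked to expression via
span-quantile curves, majority-direction up:down ratios, 10K-with-
replacement median-shift p-values, span-matched virtual-region nulls with
a gene-clustering correction, quantile/direction-restricted subsets with
Fisher tests, and Benjamini-Hochberg FDR (`bh_fdr`).

## Worked example

Simulate one chromosome with a planted 26 kb domain at 6x enrichment plus
a 12 kb domain whose topology is shuffled in the second condition, then
call and profile:

```r
library(pcgtopo)

cs <- c(chr1 = 2e6)
doms <- list(planted_domain("chr1", 500000, 526000, enrichment = 6),
             planted_domain("chr1", 1200000, 1212000,
                            remodeling = "topology_shuffle",
                            conditions = "Mo_Yo"))
cfg <- sim_config(cs, conditions = c("Mo_Cb", "Mo_Yo"), domains = doms,
                  n_genes = 60, seed = 42)
bundle <- simulate_tracks(cfg)
mo_cb <- bundle$groups$Mo_Cb

th <- poisson_threshold(enrichment_curve(mo_cb$tracks[[1]]))
th
#> <poisson_threshold> T = 47 (pre-clamp 47, crossing found), excess ratio 2.00, band [0, 752]

regions <- call_regions(mo_cb, pipeline_config(coverage_min = th$threshold))
regions[, c("region_id", "span_bp", "n_ceds", "mean_ce")]
#>              region_id span_bp n_ceds   mean_ce
#> 1   chr1:499950-526050   26100    482 0.8562536
#> 2 chr1:1199950-1212050   12100    202 0.6213715

reg <- regions[2, ]
region_correlation(segment_profiles(bundle$groups$Mo_Cb, reg, th$threshold),
                   segment_profiles(bundle$groups$Mo_Yo, reg, th$threshold))
#>              region_id        pair   lce_corr  lcs_corr n_segments
#> 1 chr1:1199950-1212050 Mo_Cb-Mo_Yo -0.4755063 0.8012882        203
```

Both planted domains are recovered with boundaries within one window step
(the caller reports `chr1:499950-526050` for the domain planted at
`500000-526000`). The data-driven coverage minimum lands at `T = 47`. For
the shuffled domain the coverage envelope remains correlated between
conditions (`lcs_corr = 0.80`) while the topology profile decorrelates
(`lce_corr = -0.48`): exactly the dissociation the LCE parameter is
designed to expose, invisible to span or coverage alone.

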