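---
title: "Methods: bioassessment metrics, null-model co-occurrence networks, and mixed models for stream macroinvertebrate communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bioassessment metrics, null-model co-occurrence networks, and mixed models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

`benthonet` implements an end-to-end analysis relating oil-and-gas
development (OGD) to stream benthic macroinvertebrate (BMI) communities:
well-to-catchment attribution, sample-level bioassessment metrics,
significance-filtered co-occurrence networks built from stratified
10-sample subsets, and confound-controlled linear mixed models. Because the
statewide monitoring data that motivate this design are not bundled, the
package ships a first-class synthetic-data generator with *planted* stress
effects and co-occurrence structure, so every downstream stage is testable
against a known truth.

## The synthetic world

Each simulated collection event ("sample") carries the covariates the
analysis conditions on: watershed (HUC8), ecoregion, acid-mine-drainage
(AMD) flag, developed land cover (DLC, a fraction), season, stream type,
date, and catchment area (km²). Samples are organized in strata keyed by
(HUC8, OGD group), with the four joint groups `none`, `cogd_only`,
`uogd_only`, `both`; development-present strata are guaranteed planted well
densities that round to at least one well, so attribution-based
classification reproduces the stratum.

**Counts.** The field protocol fixes sample size by subsampling to a target
of 200 ± 20 individuals. The generator mirrors this exactly: a total is
drawn uniformly in `target_total ± tolerance_halfwidth` (defaults 200, 20)
and allocated across taxa by a single multinomial draw — a log-linear
multinomial rather than per-taxon negative binomials, so totals are exactly
controlled and the count-conservation invariant is testable.

**Planted stress.** The expected log-abundance of taxon *t* in sample *i*
is

  base_t + s_i · m(tol_t) + b · u[block(t), i]

where `s_i = β_cogd z(cogd_i) + β_uogd z(uogd_i) + β_dlc z(dlc_i)` is the
composite planted stress (z-scored planted densities and DLC, weighted by
the configured effect sizes), and `m(tol) = max((5 − tol)/5, 0)` grades the
response by pollution tolerance: sensitive taxa (tolerance < 5) carry a
positive multiplier, so a *negative* effect size (a harmful exposure)
depresses them under rising exposure; tolerant taxa carry no direct term.
Tolerant taxa nonetheless *increase in relative abundance* — the
fixed-total multinomial reallocates the individuals the sensitive taxa
lose — which is exactly the replacement mechanism stress bioassessment
describes ("sensitive decline, tolerant persist"). We deliberately did
**not** give tolerant taxa a symmetric absolute boost: in taxon draws whose
dominant taxa happen to be sensitive, an absolute tolerant bloom *evens*
the community and can raise detected richness under stress, flipping the
planted sign — an artifact of the response encoding, not of the biology
being emulated. The package fixes the convention by its observable
consequence, asserted in the test suite: a negative planted slope lowers
EPT richness and (at severe stress) total richness.

A related, honest property of fixed-count subsampling: at *mild* planted
stress, total richness responds weakly and can even tick upward, because
individuals reallocated away from sensitive taxa surface rare tolerant
taxa above the ~200-count detection threshold. EPT richness, which counts
only sensitive taxa, is monotone at any stress level. The headline
sign-recovery test therefore plants severe conventional-development stress
(`β_cogd = −2` per stress SD), the regime in which every richness-based
metric moves the way the bioassessment literature describes.

**Co-occurrence structure.** Taxa are partitioned into `n_blocks` latent
blocks; per sample, each block receives a shared standard-normal site
factor scaled by `block_strength` (`b` above). Within-block taxa therefore
rise and fall together, producing positive within-block associations whose
strength is tunable; `block_strength = 0` is the exchangeable null.

**Tolerance and trait assignment.** EPT taxa (Ephemeroptera, Plecoptera,
Trichoptera) draw tolerance from U(0, 6) and other orders from U(2, 10), so
sensitive-taxa metrics have signal; functional feeding groups (FFGs) are
drawn from a fixed categorical distribution covering the five analyzed
groups plus `unknown` and `piercer`, with each analyzed group guaranteed at
least one taxon. The real monitoring programme's abundance distribution is
not published; the generator's dispersion (log-normal taxon baselines,
sd 1) is a free parameter, chosen once as typical of riffle communities,
not calibrated to agency data.

**What a green test does *not* establish.** The generator emulates the
sampling protocol, covariate structure and a plausible response model — it
does not emulate spatial autocorrelation along stream networks, detection
error, taxonomic drift over three decades, or the empirical abundance
distribution. Green acceptance tests certify that the *pipeline* recovers
what was planted under its stated assumptions, not that the effect sizes of
any particular real-world system are reproduced.

**Seeding.** One global integer seed spawns keyed substreams per operation
(`substream_seed`, a 32-bit FNV-1a hash of `key # seed`). Ensemble
replicates key their streams by `huc8|group|rep`, so results are invariant
to the processing order of strata — an invariant the suite checks by
permuting stratum order.

## Well attribution

Wells carry planar km coordinates, a development type
(conventional/unconventional), an `active`/`inactive` status and a spud
date. Attribution is a ray-casting point-in-polygon join (boundary points
count as *inside* — a deterministic, documented convention), or a
precomputed membership table. Only **active** wells spudded **strictly
before** the sample date are counted ("prior to sampling" is read
literally; same-day spuds are excluded), split by type, and divided by the
catchment area to give COGD/UOGD densities; presence flags are
`count ≥ 1`. Self-intersecting polygons are rejected. Real geodetic
projections, stream-raster snapping and agency database formats are out of
scope.

## Bioassessment metrics

Per sample: richness; Shannon diversity in natural-log units
(`H = −Σ p log p`, bounded by `log(richness)`); EPT richness counting taxa
that are both in an EPT order *and* have pollution tolerance ≤ 4
(inclusive); FFG proportions, individual-based over the five analyzed
groups with `unknown` and `piercer` individuals removed from numerator and
denominator; and mean pollution tolerance (unweighted by default,
abundance-weighted on request).

The composite index of biotic integrity (IBI) used by state agencies is
defined in external calibration reports, so the package provides a
documented **surrogate**: four components (richness, EPT richness, Shannon,
and `10 − mean tolerance`) are rescaled to [0, 100] by clamped linear
interpolation between a configurable floor and ceiling, and averaged. The
default calibration (richness 0–30, EPT 0–15, Shannon 0–3, tolerance score
0–10) reflects typical ranges of ~200-count riffle samples. The surrogate
preserves the *role* of an ensemble condition score — monotone in each
component, bounded, decreasing under planted stress — and nothing else is
claimed for it.

## Co-occurrence networks

Networks are built from 10-sample observation matrices drawn within
(HUC8 × OGD group) strata of a filtered subset: spring, wadeable, no AMD,
DLC ≤ 20% (inclusive). Strata need at least 15 classified samples; 10
samples are drawn without replacement per replicate, 100 replicates per
stratum.

**Pair statistic.** Pearson correlation of `log(x+1)` abundances across the
10 sites. The upstream methodology delegates this choice to an existing
framework without printing it; the transform is variance-stabilizing for
multiplicative count noise, and the statistic is isolated behind one
function so rank or binary alternatives can be swapped.

**Null model.** 100 richness-preserving null communities: each null site
has exactly the observed site's richness, taxa drawn without replacement
with probability proportional to their *regional* occurrence frequency
(over the whole filtered subset), abundances resampled with replacement
from each taxon's regional pool of observed nonzero abundances. Pairs give
`SES = (r_obs − mean r_null)/sd(r_null)` (sample sd), two-sided p-values
from the standard normal, and Benjamini–Hochberg adjustment per network;
edges are retained at `q < 10⁻⁴` by default.

**A numerical consequence worth stating plainly.** With 10 sites, |r| ≤ 1
and the null sd of r is ≈ 1/3, so |SES| saturates near 3.3 and
normal-approximation p-values floor near 10⁻³. At the default threshold,
sparse synthetic networks are therefore typically *edgeless* — which is
also what the null-calibration acceptance test expects at 10⁻⁴. The
planted-structure recovery test runs the same BH filter at `q < 0.05`,
where a block-structured world concentrates retained positive-SES edges
within blocks. The 100-permutation design cannot resolve empirical p-values
near 10⁻⁴ at all, which is why the package uses the normal approximation of
the SES rather than permutation ranks — the only internally consistent
reading of a 10⁻⁴ FDR with 100 permutations.

**Topology.** Size counts all matrix taxa (isolated nodes included);
connectance is retained edges over `size(size−1)/2`; mean co-occurrence
strength is the mean |SES| of retained edges (sign-ambiguous "average
effect size" is resolved to magnitude, matching the stress hypothesis);
modularity is Newman's Q of the partition found by a deterministic greedy
agglomeration on |SES|-weighted edges, merging the best positive-gain pair
with lexicographic tie-breaking — determinism is required for exact
testability, and the implementation is verified against closed forms (two
disjoint unit triangles → Q = 0.5; complete graph, one community → Q = 0)
and against igraph's Q on its own partitions. Empty networks report
connectance, strength and modularity as 0 so the ensemble table stays
rectangular. Composition metrics (mean tolerance, FFG node proportions)
are unweighted over node taxa.

## Models

Sample-level models: z-scored taxonomic responses on z-scored COGD density,
UOGD density and DLC, with independent (crossed) random intercepts for
ecoregion and AMD presence, restricted to spring samples. FFG responses are
left in proportion units. Network-level models: topology/composition
responses on the two marginal presence flags with a HUC8 random intercept.
All mixed models are REML fits (lme4) reporting standardized β, Wald normal
95% CIs (`β ± 1.96 se`), normal-approximation p-values and the conventional
significance stars (0.05/0.01/0.001). No degrees-of-freedom correction is
applied — the upstream reporting convention gives only CIs and stars, and
Wald is the simplest defensible choice; at the sample sizes involved the
difference is negligible. Grouping factors observed at a single level are
dropped (a one-level intercept is inestimable); with none left the fit
degenerates to OLS, which the suite pins to machine precision. Boundary
(singular) fits are treated as valid zero variance estimates, not
convergence failures. An ordinary least squares of per-network IBI (the
mean surrogate IBI of the 10 subsampled samples — the aggregation is not
dictated upstream, and the mean is the natural choice) on the four topology
metrics reports R²; constant predictors are dropped (edgeless-network
degeneracy), and rank deficiency among the rest is an error, not a silent
pseudo-inverse.

## Design choices where the design was genuinely open

- **Stratification label.** Classification is the joint 4-way
  (COGD × UOGD) label, not two binary passes — a binary reading would
  double-count samples across strata.
- **Replicate independence.** The 100 subsamples per stratum are drawn
  independently (samples recur across replicates); drawing 10 of ≥ 15
  a hundred times forces reuse.
- **EPT definition.** Order membership *and* tolerance ≤ 4, boundary
  inclusive; whether agencies exclude further taxa is not documented
  upstream, so nothing further is excluded here.
- **BH step-up.** "False discovery rate" is implemented as
  Benjamini–Hochberg per network: canonical, monotone (`q ≥ p`), exactly
  testable by hand. Local-FDR variants would change which edges survive;
  the filter is one isolated function.
- **Degenerate inputs.** Empty samples make Shannon/mean-tolerance/FFG
  proportions *signalled* undefineds, not silent zeros; zero-area
  catchments, floor-equals-ceiling calibrations, self-intersecting
  polygons, and k larger than a stratum are errors.

## Known limitations

- The SES ceiling discussed above means the default 10⁻⁴ threshold is
  effectively a "no edges at desk scale" regime for 10-site matrices; the
  statewide analyses that motivated the threshold had the same matrix size,
  so we surface the tension rather than hiding it — the threshold is a
  config parameter.
- Planar geometry only; no geodetic projection or catchment nesting beyond
  what the membership table expresses.
- The surrogate IBI is not any agency's published formula, and the
  generator is not calibrated to any agency's abundance distributions.
- Wald inference ignores degrees-of-freedom corrections; at stratum sizes
  near the minimum this is anti-conservative for the network-level models.
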