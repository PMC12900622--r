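---
title: "Methods: statistics, models and design choices in mtphylogeo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: statistics, models and design choices in mtphylogeo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtphylogeo)
```

`mtphylogeo` analyses a multiple sequence alignment of mitochondrial
sequences labelled with populations and (optionally) groups.  This vignette
is the package's own account of what each method computes, which knobs
matter, what the synthetic-data generator does and does not emulate, and
where the design was genuinely open.

## Input handling and the missing-data policy

All statistics operate on the *retained columns* of a `filtered_alignment`.
The default policy, `complete_deletion`, removes every column containing a
gap, `N` or any IUPAC ambiguity from all downstream statistics, so a single
effective length `k_eff` scales π and θ_W everywhere and every pair of
sequences is compared over the same sites.  The alternative `pairwise`
policy keeps all columns and lets each sequence pair use its own comparable
sites; it changes only how π averages (each pair is scaled by its own valid
length).  Complete deletion is the default because it makes every
downstream quantity refer to one well-defined set of sites — the
convention of the classic sequence-polymorphism tools.  Haplotype identity
is exact string equality on retained columns; under the default policy no
ambiguity codes survive, so the question of whether `N` "matches" anything
never arises.

## Diversity

* `haplotype_diversity`: Hd = n/(n−1)·(1 − Σ pᵢ²).  Hd = 0 exactly when one
  haplotype is present; Hd = 1 exactly when all n sequences differ.
* `nucleotide_diversity`: mean per-site proportion of differences over all
  C(n,2) pairs.
* `watterson_theta`: S/(a₁·k_eff), used internally by Tajima's D.

Thresholds Hd > 0.5 and π > 0.005 (strict) are exposed by
`classify_diversity` as the conventional flags for "high" haplotype and
nucleotide diversity.

## Differentiation

**Gst / Nst** (`gst_nst`).  Both are within/total diversity decompositions
over populations.  The frequency-only version (Gst) uses the sample-size
corrected estimators: within-population diversity averaged over K
populations with the harmonic-mean sample size ñ as
ĥ_S = ñ/(ñ−1)·(1 − mean_k Σ pᵢₖ²), and total diversity from mean
frequencies with the ĥ_S/(ñK) correction.  Nst is structurally identical
but weights each haplotype pair by its per-site distance (no
substitution-model correction, since none is standard at intraspecific
divergences).  With the 0/1 "distance" Nst reduces exactly to Gst, which
the tests exploit as an internal consistency check.  Significance of
Nst > Gst is assessed by permuting individuals among populations;
populations with fewer than two individuals are excluded first.

**AMOVA** (`amova`).  Distance-based hierarchical analysis of molecular
variance on squared pairwise-difference distances (for sequences, the
number of differing retained columns).  Sums of squares are computed from
the distance matrix (SS of a set = Σ_{i<j} d²ᵢⱼ/n_set), variance components
from the standard nested expected-mean-square coefficients, and
Φ-statistics from the components.  The identity
(1−Φ_CT)(1−Φ_SC) = (1−Φ_ST) holds on every run and is asserted in the
tests.  Permutation schemes follow the hierarchy: Φ_ST permutes individuals
among populations without restriction, Φ_SC within groups, Φ_CT permutes
whole populations among groups.  All permutation p-values use the add-one
convention (exceedances+1)/(B+1) with permuted ≥ observed counting as an
exceedance; B defaults to 1000.  A group containing a single population
makes Φ_SC degenerate and is flagged rather than hidden.

**Pairwise Fst / Nm** (`pairwise_fst`, `gene_flow`).  Each pair's Fst is
the two-level Φ_ST of the AMOVA restricted to the pair — the convention of
distance-based sequence analyses (whether published group-level values are
pairwise Φ_ST or averages of population pairs is usually unstated; pairwise
Φ_ST is assumed here).  Nm = (1−Fst)/(4·Fst), with Fst = 0 mapping to +Inf
and Fst = 1 to 0.  Negative Fst estimates (common in small samples) are
reported as computed in the Fst matrix but clamped to 0 for Nm with a
warning, so the gene-flow matrix never contains negative migrant numbers.

## Neutrality tests

Tajima's D uses the standard constants; S = 0 is an error (rendered as an
em-dash in reports).  Fu's Fs evaluates S′ = P(K ≥ Nh) under the Ewens
sampling distribution at θ = k̄ — the mean pairwise difference, not
Watterson's θ, following the statistic's original definition.  Unsigned
Stirling numbers of the first kind are computed by their recurrence
entirely in log space; the tests check agreement with exact integers up to
n = 20 and finiteness at n = 97.  Nh = 1 is the S′ = 1 boundary and
returns +Inf with a warning.

p-values (`neutrality_pvalues`) come from a parametric bootstrap: neutral
constant-size coalescent replicates at the observed n and θ = k̄, scored
with the same statistics, lower tail, add-one convention.  A caveat worth
stating: the null distribution of Fs is skewed such that the conventional
"significant at 5%" call corresponds to the 2% quantile; the
`Fs_significant` field applies that 2% threshold while the displayed stars
follow the usual 0.05/0.01/0.001 cutoffs.

Under neutrality the *mean* of Tajima's D is slightly negative (its
normalization does not centre it exactly at zero); our simulator reproduces
the same small negative offset as an independent coalescent simulator at
matched conditions, and the calibration test uses n = 10, θ = 5 where the
offset (≈ −0.05) is comfortably inside the ±0.1 acceptance band.

## Mismatch distribution and sudden expansion

`expansion_model_freqs` evaluates the expected pairwise-difference
distribution for a population that grew instantaneously from scaled size
θ₀ to θ₁ at time τ (mutational units) ago, derived from the two-epoch
pairwise coalescent:

F_j = F̂_j(θ₁)·P(Gamma(j+1) ≤ τ(θ₁+1)/θ₁) + e^{−τ/θ₁} Σ_m F̂_m(θ₀)·Pois_{j−m}(τ),

with F̂_j(θ) = θ^j/(θ+1)^{j+1} the equilibrium geometric distribution.  At
τ = 0 it collapses to F̂(θ₀); with θ₀ = 0 and θ₁ → ∞ it approaches
Poisson(τ) — both limits are asserted in tests.  The vector is renormalized
over 0..j_max.

`fit_sudden_expansion` minimizes SSD = Σ(obs_j − F_j)² with Nelder–Mead on
a transformed scale (√τ, √θ₀, log(θ₁−θ₀)) from 10 random multi-starts
(fixed seed) because the SSD surface is multi-modal in τ and flat in θ₁;
ties break toward the smallest τ, and θ₁ is capped at 10,000 as an
effectively-infinite size.  Harpending's raggedness uses the boundary
convention x_{d+1} = 0, i.e. the sum runs one class past the largest
observed difference — implementations differ on this point, so it is fixed
explicitly.  Goodness-of-fit p-values simulate B (default 100) coalescent
datasets under the fitted parameters, refit each, and count exceedances of
SSD and r.  The expansion-time conversion t = τ/(2μk) takes μ in
substitutions/site/Myr and returns Myr; μ and k are user inputs because the
appropriate rate and alignment length depend on the locus analysed.

## The synthetic-data generator

`sim_coalescent` runs a backward-in-time structured Kingman coalescent:
demes in groups, per-pair within-deme coalescence at rate 1 (time in units
of N generations, haploid), per-lineage migration at M/2 split between
same-group targets (M_within) and other-group targets (M_between), mutation
as Poisson(θ/2 per unit branch length) with θ = 2Nμ_locus per locus.  A
sudden expansion divides the size by `growth` at time τ_sim/θ in the past
(τ_sim in the same mutational units as the mismatch model, making
parameter-recovery experiments direct).  Deep group divergence is modelled
by `t_pool`: before that time the demes are isolated tiers; at `t_pool` all
lineages merge into one panmictic deme — the standard picture of refugia
that split from a single ancestral population.  Infinite-sites mutation
assigns each mutation a fresh column (error if the locus is exhausted);
the Jukes–Cantor option draws columns with replacement to allow homoplasy
when network tests want it.  There is no recombination (mitochondrial
locus), no selection, and no sequencing error.

`sim_survey_design` freezes one reference scenario: 97 individuals in 24
populations of 1–6 individuals forming 4 groups (10+12+1+1 populations),
θ = 1.2 per locus over L = 3409 sites, M_within = 4, M_between = 0,
t_pool = 15, and a within-group sudden expansion (τ = 4, growth 100).
These values were chosen once so the scenario reproduces the qualitative
structure such surveys report — high Hd (≳0.93) with low π (0.003–0.005),
the among-group AMOVA component dominant, group-level Fst in the 0.5–0.9
range — and are not tuned thereafter.  What passing tests on simulated
data do **not** show: robustness to alignment error, substitution-model
misspecification, homoplasy at mitogenome scale (the reference scenario is
infinite-sites), sequencing artefacts, or uneven missing data.

## Pipeline conventions

`run_pipeline` writes per-population and per-group diversity tables,
Gst/Nst with a structure verdict, the AMOVA table, combined Fst/Nm
half-matrices (lower triangle Fst, upper Nm, thresholds Fst > 0.25 and
Nm > 1 noted in the header), a neutrality/mismatch table and network
edge/node tables.  Group statistics pool all individuals of the group
rather than averaging populations.  Populations with n < 2 are excluded
from diversity and permutation statistics and rendered as an em-dash, as
are undefined statistics (e.g. neutrality rows for groups with n < 4 or
S = 0).  Stage seeds are derived from the single mandatory seed by fixed
offsets, so identical inputs and seed reproduce byte-identical tables.

## Median-joining networks

`mj_network` iterates: (1) Hamming distances over current node sequences;
(2) the ε-relaxed minimum spanning network — every link whose weight is at
most the MST bottleneck distance of its endpoints plus ε (ε = 0, the
default, yields the minimum spanning network, which contains every MST);
(3) for each connected triple, the quasi-median — the column-wise majority
consensus, branching over columns where all three states differ (triples
with more than two such columns are skipped to bound the closure); novel
medians join the node set; (4) unsampled nodes of degree ≤ 2 whose removal
does not lengthen the path between their neighbours are pruned; repeat to a
fixed point.  Site weights are uniform.  The Steiner-tree post-processing
(MP heuristic) found in some full median-joining implementations is deliberately not
implemented; for the small ε values used in practice the quasi-median
closure already recovers the textbook cases, and the brute-force
Steiner-point oracle in the tests confirms it on those.  Sampled
haplotypes keep their IDs; medians are named mv1, mv2, … in creation
order; the default path is fully deterministic, and the `seed` argument
exists only for API symmetry.

## Problem sizes used by the test-suite experiments

Calibration and recovery experiments run at desk scale, chosen as the
smallest sizes at which the checked expectation is sharp: 1000 neutral
replicates at n = 10, θ = 5 for the Tajima's D / Watterson calibration;
2000 replicates of n = 2 for E[k̄] = θ; 100 simulated expansion datasets
(n = 60, θ₁ = 50, τ = 4) for τ recovery; 10–12 replicate island-model
datasets per migration rate for the Fst monotonicity check; and the full
97-individual reference survey for the end-to-end pipeline test
(200 permutations, 200 null replicates, 20 bootstrap refits).

## Known limitations

* Gst/Nst estimator families differ subtly between programs; parity with
  any specific tool is approximate, and the permutation test compares the
  package's own estimators under label exchange.
* Distances carry no substitution-model correction, appropriate for
  intraspecific divergence but not for deeper comparisons.
* Fu's Fs p-values rely on the constant-size null; with strong structure
  in the data the bootstrap conditions only on pooled θ.
* The mismatch model is the demographic (not spatial) sudden-expansion
  model.
* Median-joining with many high-homoplasy characters can produce large
  median closures; the per-triple branching cap trades completeness for
  boundedness there.
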