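---
title: "Quantifying household microbiota sharing: models and methods"
author: "microShare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying household microbiota sharing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microShare)
```

# The problem

Human-associated microbial communities differ among individuals, and part
of that variation tracks who we live with. Cohabiting couples, their
children, and even their dogs exchange microbes through direct and
indirect contact, and the strength of that exchange differs across body
habitats (gut, tongue, skin). microShare implements the statistical
machinery for asking, from 16S rRNA phylotype (OTU) tables: do members of
the same household carry more similar microbiota than members of
different households, at which body sites, for which kinds of host pairs
(couples, parent–child, parent–infant, dog–dog, owner–dog), and how do
age and dog ownership reshape those communities?

The package covers the full analysis path: reading the field's standard
formats (classic tab-separated OTU tables, BIOM-JSON, newick trees,
`#SampleID` mapping files), depth filtering and rarefaction, phylogenetic
alpha and beta diversity (Faith's PD, unweighted and weighted UniFrac),
ordination (PCoA), a dyadic within- vs between-household permutation
test, one-way PERMANOVA, shared-phylotype accounting, age-trajectory
regression, and Gibbs-sampling source attribution — plus a synthetic-data
generator that reproduces the household/dog/age structure the analysis
assumes, so every stage is testable without any sequencing data.

# Community metrics

## UniFrac

Both variants are computed from one per-edge summary of the rooted
phylotype tree: for every edge, which samples have at least one read on a
descendant tip, and what fraction of each sample's reads descend from it.

* **Unweighted** UniFrac between samples $i$ and $j$ is the branch length
  observed in exactly one of the two samples divided by the branch length
  observed in either. Presence means count $\ge 1$ on the rarefied table
  — the pipeline rarefies first, so no additional relative-abundance
  floor is applied.
* **Weighted** UniFrac is $\sum_e \ell_e\,\lvert p_{ie}-p_{je}\rvert$
  over edges, with $p$ the proportion of the sample's reads below the
  edge. The **raw** (unnormalized) form is the default; `normalized =
  TRUE` divides by $\sum_k d_k (p_{ik}+p_{jk})$ over tips ($d_k$ =
  root-to-tip distance), bounding the result in $[0,1]$. Both forms are
  exposed because analyses in this literature rarely state which was
  used; every property the test suite relies on holds for either.

The implementation is validated edge-for-edge against a brute-force
oracle that enumerates every edge's descendant tip set independently, on
a thousand random tree × abundance instances (agreement to $10^{-12}$).

## Faith's phylogenetic diversity

PD is the total branch length of the minimal subtree spanning a sample's
observed taxa **and the tree root**. Implementations genuinely differ on
root inclusion, so the choice is stated here: root-inclusive, which makes
PD monotone under taxon addition and strictly positive for any non-empty
sample. Empty samples score 0 with a warning rather than erroring, so
rarefaction curves stay total.

## Rarefaction

`rarefyCounts()` subsamples exactly `depth` reads per sample *without*
replacement (multivariate hypergeometric). Each sample draws from an RNG
substream keyed by a hash of the sample id, so results do not depend on
sample order or on which other samples are present. The conventional
depth in this kind of survey is 5000 reads, with shallower samples
removed beforehand by `filterByDepth()`.

## PCoA

`pcoa()` double-centers $-D^2/2$ and eigendecomposes. Coordinates are
returned only for positive eigenvalues; negative eigenvalues (from
non-Euclidean dissimilarities such as unweighted UniFrac) are reported so
the user can judge distortion, and are never silently absorbed.

# The dyadic permutation test

The central inference contrasts *within-household* against
*between-household* pairwise distances for a specific comparison
category at a specific body site:

| category | within pairs | between pairs |
|---|---|---|
| families | same-household humans | cross-household humans |
| spouses | the household's adult_M × adult_F | all cross-household adult combinations |
| father/mother–child | parent × own child (3–18 y) | parent × other households' children |
| father/mother–infant | parent × own infant (< 1 y) | parent × other households' infants |
| dogs | cohabiting dogs | dogs of different households |
| owner_own_dog | dog-owning adult × own dog | same adults × other households' dogs |

For the spouses category the between set deliberately includes
cross-household same-sex adult pairs ("all combinations" of the same
adults), while same-household same-sex pairs are excluded from the
universe. The child age window (3–18 y) follows the dyad definitions
rather than the age-group bins used for taxon summaries (1–17 y); both
bounds are arguments.

All candidate distances are ranked jointly (midranks for ties) and

$$R=\frac{\bar r_{between}-\bar r_{within}}{N/2}\in[-1,1],$$

an ANOSIM-like statistic: $R>0$ means household members are more similar.
The null distribution permutes **family labels among the eligible
individuals within each role stratum** (which household each mother
belongs to is shuffled among mothers, independently of fathers, children,
dogs). Permuting at the individual level rather than permuting raw
distance labels preserves the dyad structure of every permuted dataset —
dyadic distances sharing an individual are not exchangeable, so naive
distance-label permutation would be invalid. The test is one-sided
(within more similar), and the p-value uses the add-one estimator
$(1+\#\{R_{perm}\ge R_{obs}\})/(1+n_{perm})$ so $p>0$ always; 10,000
permutations is the conventional default. Permutations that leave a
category with no within pairs (possible for sparse parent–child designs)
are skipped and counted in the result's diagnostics, as is a universe
with fewer than 100 distinct permutations. Calibration is verified by
simulation: under a generator configuration with every sharing effect
disabled, the test rejects at $0.05\pm0.02$ over 1000 datasets.

Bonferroni correction across body sites is left to reporting time: the
dyadic R tables are conventionally shown uncorrected, while the
taxon-level Wilcoxon/ANOVA analyses below apply Bonferroni by default.

# One-way PERMANOVA

For $N$ samples in $a$ groups,
$SS_{total}=\sum_{i<j}d_{ij}^2/N$,
$SS_{within}=\sum_g \sum_{i<j\in g} d_{ij}^2/n_g$, and
pseudo-$F = (SS_{between}/(a-1))/(SS_{within}/(N-a))$, tested by 999
whole-label permutations. The reported component of variation is
$\sqrt{\max(0,(MS_{between}-MS_{within})/\bar n)}$ with
$\bar n=(N-\sum n_g^2/N)/(a-1)$, i.e. on the distance scale. A worked
4-sample instance (two groups of two, within-distance 0.1,
between-distance 1) gives pseudo-$F=199$ and anchors the unit tests; the
implementation also matches a naive double-loop evaluation and
`vegan::adonis2` on random instances. One caution: when *all* pairwise
distances are equal, $MS_{between}=MS_{within}=d^2/2$ and pseudo-$F=1$
(not 0) — equidistance carries no group signal but is not zero
between-group sum of squares.

# Age trajectories

`ageTrajectory()` computes, per participant, the mean distance between
their sample at a site and all baseline adults' samples at that site,
then fits mean distance against age by ordinary least squares. Baseline
adults default to ages 30–45. The focal participant is always excluded;
their **own household is excluded too by default**
(`include_own_family = FALSE`) so that household sharing does not
masquerade as an age effect — an analysis choice the source literature
leaves open, reversible by flag.

A caveat the test suite encodes: the generator's age effect decays
exponentially with age (weight $e^{-age/\tau}$, $\tau = 1.5$ y), so a
*linear* fit of distance on age explains only part of the variance even
when the age effect is the only effect present. On age-effect-only
configurations the fit reliably shows a negative slope with $r^2$ around
0.3–0.4 (offspring-only fits); testing against an $r^2$ of, say, 0.5
would misrepresent what a straight line can capture of an exponential
trajectory.

# Shared phylotypes and taxon summaries

`sharedPhylotypes()` counts presence-set intersections; tables should be
rarefied to a common depth first (warning otherwise), so richness
differences do not masquerade as sharing differences.
`sharedByTaxonFamily()` partitions each pair's shared count by
taxonomy-family label — the per-family counts sum exactly to the total —
and compares within vs between pairs per family by two-sided Wilcoxon
rank-sum, Bonferroni-corrected across families. `stats::wilcox.test`
supplies the rank-sum machinery (exact below 50 observations without
ties, normal approximation with continuity correction otherwise).

`collapseToFamily()` produces percent abundances per taxonomy family;
`taxonAgeAnova()` retains families above 1% and runs a one-way ANOVA
across age groups (infant < 1 y, child 1–17, adult 18–59, senior ≥ 60),
Bonferroni over retained families. The 1% retention rule is applied to
the grand mean across tested samples; whether the source convention was
per-group or overall is unstated, so `filter_scope = "per_group"` is
available.

# Source attribution

`fitSources()` pools training counts per declared source environment
(e.g. oral, fecal), excluding the sink's own household by default
(leave-one-out) so a household cannot explain itself.
`estimateMixture()` runs a collapsed Gibbs sampler over per-read source
assignments $z_i \in$ sources $\cup$ {unknown}:

$$P(z_i=s\mid\cdot)\propto
\frac{m_{s,t_i}+n^{-i}_{s,t_i}+\alpha_s}
     {m_{s,\cdot}+n^{-i}_{s,\cdot}+T\alpha_s}\,
(n^{-i}_s+\beta),$$

with training counts $m$ zero (and $\alpha$ = `alpha_unknown`) for the
unknown source. Defaults $\alpha=0.001$, $\alpha_{unknown}=0.1$,
$\beta=10$ follow the published defaults of the method family this
implements. Proportions are posterior means of $n_s/N$ over `n_draws`
sweeps after `burn_in`; a single chain is run (restarts via different
seeds) because the clean-mixture posteriors involved here are effectively
unimodal at survey depths. On synthetic 50/50 mixtures of well-separated
sources at depth 5000 the sampler recovers proportions within ±0.05; a
sink of taxa unseen in any source lands ≥ 90% in "unknown". One
identifiability note: when the taxon space is very small, the unknown
source's flatness penalty $T\,\alpha_{unknown}$ is weak and the unknown
can imitate a real source; with realistic taxon counts (hundreds) the
attribution is sharp.

# The synthetic cohort generator

`simulateHouseholds()` reproduces the surveyed design: 60 households —
17 with children, 17 with dogs, 8 with both, 18 with neither — each with
one adult couple; child-type households add 1–3 children and dog-type
households 1–2 dogs. Humans contribute five samples (fecal, tongue,
forehead, both palms), dogs seven (adding four paws). Offspring ages are
drawn from a mixture calibrated to the cohort's age table (about a third
infants at 0.5–1 y, most of the rest 1–6 y, a small 12–18 y tail): a
flat Uniform(0.5, 18) would produce almost no infants and leave the
infant dyad categories and the age analyses untestable against any
realistic cohort.

`simulateCounts()` draws, per (species, site): a Dirichlet baseline over
a sparse taxon mask, with human skin weighted toward
Propionibacteriaceae/Streptococcaceae/Staphylococcaceae, tongue and gut
toward their signature families, and dog sites flat and even; then a
family profile Dirichlet(`kappa_family` × baseline); then per-individual
targets:

* adults mix $(1-w_{sp})\,\phi + w_{sp}\,\psi$, where $\psi$ is a
  couple-shared draw taken at *individual-scale* dispersion
  (`kappa_individual`) around the family profile — this keeps the spouse
  effect tunable by $w_{sp}$ alone, and in particular alive when the
  family effect is switched off (`kappa_family = Inf`), which the
  calibration suite relies on;
* children mix toward an infant signature (the site baseline tilted
  strongly toward Streptococcaceae) with weight $e^{-age/\tau}$,
  $\tau=1.5$ y, on top of a parental-contact mixture with weight
  $w_{pc}$;
* skin sites of humans in dog-owning households mix in $w_{dog}$ of a
  family dog-source profile restricted to taxa rare on human skin —
  rare-taxon mass moves unweighted UniFrac but barely moves the weighted
  variant, mirroring how dog ownership shows up in membership-based but
  not abundance-based comparisons.

Individual profiles are Dirichlet(`kappa_individual` × target); counts
are Multinomial at lognormal depths (median 20,000 reads, so a small
fraction of samples falls under the 5000-read filter, as in real
surveys). Defaults: `kappa_site = 50`, `kappa_family = 30`,
`kappa_individual = 200`, `w_sp = 0.35`, `w_pc = 0.2`, `w_dog = 0.15`.
Every stage is deterministic given `seed`.

What the generator does **not** emulate: sequence-level error, chimeras
and PCR bias (it starts at the OTU table); senior adults (couples are
26–59, whereas real cohorts include elderly partners); cats and other
pets (flags only); longitudinal sampling; and cross-site transfer within
a host (tongue→palm), so source-attribution runs on synthetic palms
correctly attribute almost everything to "unknown". Passing tests
therefore demonstrate that the machinery measures what it claims under a
known generative model — not that any particular real-world effect size
will be reproduced.

With the default concentrations the family effect is strong (dyadic R
near 1 on the full synthetic cohort); parameter-recovery tests therefore
work on configurations that isolate single effects — e.g. spouse-only
sharing (`kappa_family = Inf`) shows mean spouse R rising monotonically
over $w_{sp}\in\{0, 0.2, 0.4, 0.6\}$, and a dogs-only cohort shows the
dog effect on forehead but not fecal distances.

# Numerical and testing choices

* Distance matrices tolerate asymmetry up to $10^{-8}$ on read
  (averaged away); beyond that is an error. Computed UniFrac matrices
  clamp $-10^{-17}$-scale rounding noise to zero.
* Ranks use midranks for ties throughout.
* Per-sample/per-iteration RNG substreams are derived by hashing the
  sample id (and depth/iteration for rarefaction curves) into a 31-bit
  seed, so any subset of samples reproduces identically.
* Problem sizes in the test and acceptance suites are chosen to exercise
  the full pipeline at desk scale: null calibration uses 1000 datasets of
  8 couple-only households × 40 taxa at depth ≈ 400 with 99 permutations;
  the UniFrac oracle uses 1000 random trees of ≤ 16 tips; parameter
  recovery uses 20 seeds per grid point on 8-household cohorts; the
  acceptance script runs one full 60-household cohort at the survey's
  scale (≈ 1100 samples, 500 taxa, depth ≈ 20,000, rarefied to 5000).

# Limitations

The dyadic test assumes one sample per individual per site; replicate
samples must be collapsed or disambiguated upstream. The
`owner_other_dog` contrast permutes household dog-ownership flags rather
than family labels, a coarser null; `nonowner_dog` is a sharing stratum
only. PERMANOVA here is strictly one-way (family membership); factorial
designs with partial sums of squares and residual permutation are out of
scope, as are mixed-effects variance decompositions and stepwise
distance-based model selection.
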