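---
title: "Dominant-model co-segregation analysis of bovine HAPH: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dominant-model co-segregation analysis of bovine HAPH: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haphseg)
```

# The model and its assumptions

High-altitude pulmonary hypertension in cattle is treated throughout
this package as an autosomal dominant trait with incomplete penetrance.
Three quantities describe the generative model:

* **carrier frequency** — the population frequency of the causal
  haplotype carrier state (default 0.41, the carrier fraction observed
  when screening a lowland herd of 32 animals);
* **penetrance** — the probability that a carrier living at altitude
  develops HAPH (default 0.75);
* **phenocopy rate** — the probability that a non-carrier develops HAPH
  anyway (default 0.05). HAPH is polygenic and environmental in part,
  so affected non-carriers exist; without a phenocopy channel the
  simulator could not reproduce the incomplete genotype–phenotype
  concordance real herds show.

Disease status is assigned from mean pulmonary artery pressure (PAP,
mm Hg). The default thresholds mirror field practice at or above
7,000 ft: strictly above 50 mm Hg is affected, strictly below 39 mm Hg
unaffected, and the band between is an uncertain zone whose animals are
excluded from filtering and association (`classify_status()`). A
replication-herd convention with inclusive bounds (affected at
PAP ≥ 45) is available through the `*_inclusive` flags.

## The co-segregation filter

Under the dominant model an animal is a *carrier* of a variant iff its
genotype contains at least one alternate allele. For an extreme-design
screen of $n_A$ affected versus $n_U$ unaffected exomes, a variant
passes a filter stage $(m, M)$ iff

$$\#\{\text{affected carriers}\} \ge m \quad\text{and}\quad
  \#\{\text{unaffected carriers}\} \le M.$$

The default cascade for a 5 vs 5 design evaluates three stages —
(5, 0), (4, 1) and (4, 0) — each **independently** on the
class-filtered variants rather than sequentially on each other's
output; the nesting $S(5,0) \subseteq S(4,0) \subseteq S(4,1)$ is then
a mathematical property of the thresholds, which the test suite
verifies, and reporting all three reproduces the narrative of a staged
screen. Class filtering keeps non-synonymous substitutions and short
coding insertions/deletions; consequence classes must arrive annotated
(via the `CLASS` INFO key or the variant table), since annotation
itself is out of scope.

A gene passes a stage iff at least one of its variants does. Counts
are reported per gene because candidate lists in this design are read
gene-wise; the per-variant counts are retained in the report details.
Within a gene, variants with bit-identical carrier vectors collapse
into one *cis-haplotype unit* (`collapse_cis()`): two variants carried
by exactly the same animals in the same gene are, for every analysis
here, one dominant allele. Collapsing is idempotent, and a gene may
yield several units when carrier sets differ, so the unit count lies
between the gene count and the variant count.

### Missing genotypes

Upstream variant calling (alignment, joint genotyping, quality
filtering) is out of scope; the filter must still define behaviour for
missing calls (`./.`). The default policy `as_noncarrier` treats a
missing call as homozygous reference — conservative for the
affected-carrier requirement, anti-conservative for the unaffected
bound. Two alternatives are selectable: `as_fail` (a variant with any
missing call among status-assigned samples fails outright) and
`exclude_sample` (the sample is dropped from that variant's counts
while the absolute thresholds stand). Missing calls are never silently
coerced at parse time; the VCF reader preserves them as `NA`.

## Association statistics

All statistics operate on the carrier-by-status table
$(a, b; c, d)$ = (affected carriers, affected non-carriers, unaffected
carriers, unaffected non-carriers).

* **Pearson χ²** (1 df), *no continuity correction by default*: on the
  herd-scale tables this package targets, the uncorrected statistic is
  the published convention — on (15, 5; 4, 17) it gives
  p = 3.3 × 10⁻⁴, whereas the Yates-corrected value does not reproduce
  that. The Yates variant (deviation `|ad − bc|` reduced by n/2,
  floored at zero) is available by flag, as is Fisher's exact view of
  small tables through `stats::fisher.test` if a user prefers it; the
  package default stays χ².
* **Cochran–Armitage trend** with dose weights (0, 1, 2); with weights
  (0, 1, 1) it reduces algebraically to the uncorrected carrier χ²,
  which the tests check numerically.
* **Wilcoxon rank-sum** on PAP between carriers and non-carriers:
  mid-ranks for ties; for total n ≤ 20 the two-sided p is computed by
  full enumeration of all $\binom{n}{n_A}$ rank assignments
  (probability of a rank-sum deviation at least as large as observed);
  larger samples use the normal approximation with tie correction and
  no continuity correction.
* **RR and OR** with log-scale Wald 95% intervals (z = 1.96). The
  Wald/Woolf interval is the one whose RR bounds reproduce published
  herd-scale values exactly. Zero cells leave the interval undefined
  unless the 0.5 continuity (Haldane–Anscombe) flag is set.
* **Predictive values** are Bayes-rule post-test probabilities under an
  *assumed* prevalence (default 0.5, the working likelihood that a
  susceptible animal moved to altitude develops HAPH); they are not
  estimated from the case-control table margins, which carry no
  prevalence information.
* **Multi-herd pooling** is cell-wise addition of the per-herd tables,
  matching a simple joint analysis rather than a stratified
  (Mantel–Haenszel) one, which the published joint p-value reflects.

## Expression enrichment

The enrichment procedure asks whether a hypoxia-target gene set is
over-represented among genes upregulated in affected carriers:

1. **Expression floor** — a gene counts as reliably measured iff its
   group-mean log2 expression strictly exceeds 7 units in the affected
   *or* the unaffected group ("either group" is read as OR over group
   means; strictness at the boundary is asserted by test).
2. **Per-gene calls** — up iff two-sided uncorrected t-test p < 0.05
   *and* linear fold change $2^{\bar{x}_A - \bar{x}_U} > 1.25$; down
   symmetrically. "Uncorrected" is read as no multiple-testing
   adjustment. The t-test defaults to Welch (unequal variances), with
   pooled-variance Student's by flag. Fold change comes from
   anti-logged group means, the standard array convention, not from
   per-sample ratio means.
3. **Background expectation** — the fractions of *all* floor-passing
   genes called up and down under the same criteria.
4. **Three-category χ²** (up, down, neither; 2 df). The default
   `rounded_counts` mode rounds each expected tail count to an integer
   and lets the "neither" category absorb the remainder — with 68
   expressed set genes and 7%/8% background rates the expected counts
   are (5, 5, 58) and the statistic 96.4. The statistically cleaner
   `raw_proportions` mode (expected (4.76, 5.44, 57.8), statistic
   103.3) is retained and flagged in the result, because rounding
   expected counts, while conventional in this literature, is not a
   statistical necessity.

Degenerate inputs are reported, not patched: a zero expected count or
a zero table margin yields an `NA` statistic with an explanatory note.

## Diversity selection

The pairwise distance between two animals is the number of differing
microsatellite alleles: per marker, $2 - |\text{multiset
intersection}|$ of the two unordered allele pairs, summed over the
panel. Markers with missing alleles in either animal contribute zero
and are counted in an attribute so users can audit the effect. The
verbal definition is all the upstream tooling provides, so the subset
objective had to be fixed here: `select_diverse_subset()` maximises
the **total within-subset pairwise distance**, exhaustively when the
number of subsets is within a budget (default 10⁶), and otherwise by a
multi-start greedy max-min construction with steepest-ascent 1-swap
refinement, flagged `greedy` in the output. Maximum-dispersion subset
selection is NP-hard in general, so the heuristic carries no optimality
guarantee; on the small panels where exhaustive search is feasible the
property tests observe agreement. Ties break lexicographically by
sample id, making every selection deterministic.

# The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the analyses
assume, not sequencing data itself:

* carrier status is drawn per animal at the carrier frequency; carriers
  become affected with probability `penetrance`, non-carriers with
  probability `phenocopy`; animals are accepted until the requested
  affected/unaffected group sizes fill (rejection sampling conditioned
  on status, so the case-control design is exact);
* PAP is drawn from status-specific normals truncated below at
  15 mm Hg — defaults 94.2 ± 5.3 for affected extremes and 30.8 ± 0.8
  for unaffected, the extreme-group moments this design selects for.
  The uncertain zone (39–50) is populated only if group definitions
  request it;
* the causal unit is emitted as **two** heterozygous variant records in
  one gene with identical carrier sets — a planted cis pair — because
  haplotype collapsing is part of what needs testing; carriers are
  heterozygous by default (hom-alt carriers optional via a
  Hardy–Weinberg flag);
* background variants draw carrier frequencies uniformly from a
  configurable interval and carrier states independently of phenotype;
* microsatellite alleles are uniform over 8 labels per marker,
  independent across markers — no published allele-frequency spectrum
  exists for the panel, so the simplest exchangeable model is used.

Everything is a pure function of (config, seed); two runs with the
same seed are `identical()`. What the generator deliberately does
**not** model: linkage disequilibrium beyond the planted pair, pedigree
and herd structure, breed-specific allele spectra, and covariate
effects of age or altitude on PAP (no quantitative covariate model is
published, so guessing one would only manufacture false realism).
Passing tests therefore demonstrate correctness of the *algorithms*
under the stated statistical structure, not robustness to relatedness
or stratification in real herds.

`simulate_expression()` adds a log2 expression matrix: background genes
at a common baseline with Gaussian noise, gene-set genes shifted upward
in affected carriers only, and a configurable fraction of genes parked
below the expression floor to exercise the floor filter.

# Numerical and testing choices

* Problem sizes in the test suite are chosen for a desk-scale run:
  the brute-force filter oracle covers 10⁴ random variants, simulator
  parameter recovery uses 200 replicates of a 200 + 200 cohort against
  the analytic case-control relative risk implied by Bayes' rule, and
  the null calibration of the enrichment test uses 500 simulated
  datasets. The whole suite completes in well under a minute.
* The null enrichment calibration uses a 300-gene set over a 3,000-gene
  background with 10 samples per group, so that expected tail counts
  sit near 5 and the 2-df χ² approximation is serviceable; the
  accepted rejection band (2–9%) is the binomial 3σ interval around 5%
  at 500 replicates widened for that approximation.
* `power_of_design()` is validated against the closed-form per-variant
  false-pass probability
  $\left[\sum_{k \ge m} \binom{n_A}{k} c^k (1-c)^{n_A-k}\right](1-c)^{n_U}$
  for background carrier frequency $c$, within 3 s.e. of the simulated
  rate.
* VCF handling is deliberately a minimal dialect: CHROM–FORMAT + GT,
  multi-allelic records split per alternate allele, phase ignored,
  `GENE`/`CLASS`/`ANN` INFO keys. The writer emits plain text so that
  write–read round trips are byte-stable; the suite cross-checks the
  writer's output against an independent VCF reader. Symbolic alleles,
  breakends and likelihood fields are out of scope.

# Known limitations

* The published OR interval upper bound for the herd-1 table is not
  reproduced by the Woolf/Wald formula (which gives ≈ 56.4); the method
  behind that printed bound is unstated, so this package reports Wald
  and documents the difference rather than forcing agreement.
* Armitage trend p-values on real herds require the het/hom-alt split,
  which published tables do not provide; the implementation is
  validated against `stats::prop.trend.test` instead.
* The filter cascade presumes statuses are already dichotomised;
  animals in the uncertain PAP zone must be excluded upstream, and the
  package errors rather than guessing.
* Expected-count rounding in the enrichment default slightly inflates
  the statistic relative to `raw_proportions`; users doing anything
  other than reproducing the conventional computation should prefer
  the raw mode.
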