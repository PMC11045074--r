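---
title: "Close-kin inference with LOD scores: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Close-kin inference with LOD scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinlod)
```

`kinlod` turns diploid microsatellite genotypes plus survey metadata into
an annotated list of close-kin pairs with calibrated error rates, and
tests whether kinship is associated with geography. This vignette is the
package's account of the underlying science: the likelihood model and its
assumptions, the tunable parameters, the Monte-Carlo calibration, what
the synthetic-data generator does and does not emulate, and the design
decisions taken where more than one reasonable choice existed.

## The pairwise kinship likelihood

A pairwise kinship hypothesis is summarised by its Cotterman
identity-by-descent (IBD) coefficients $(\kappa_0, \kappa_1, \kappa_2)$:
the probabilities that the pair shares 0, 1 or 2 alleles IBD at an
autosomal locus. The package fixes the classical values — unrelated
$(1,0,0)$, parent–offspring $(0,1,0)$, full siblings
$(\tfrac14,\tfrac12,\tfrac14)$, second-degree kin $(\tfrac12,\tfrac12,0)$
and self/monozygotic $(0,0,1)$ — and assembles the true genotype-pair
probability at each locus as

$$P(g_i, g_j \mid K) \;=\; \kappa_0\,P(g_i)P(g_j)
  \;+\; \kappa_1\,P(g_i)\,T(g_j \mid g_i)
  \;+\; \kappa_2\,P(g_i)\,\mathbb{1}[g_i = g_j],$$

where $P(\cdot)$ is the Hardy–Weinberg genotype probability (with the
usual $2pq$ factor for heterozygotes) and $T$ is the Mendelian
parent–offspring transition: one allele transmitted uniformly from the
pair's shared ancestor, the other an independent population draw. The
assumptions this inherits are the standard ones: Hardy–Weinberg
proportions and known allele frequencies (in practice estimated from the
sample), independent (unlinked) loci, no inbreeding (three-coefficient
IBD rather than the nine-state identity coefficients), and no mutation
in transmission. Half siblings, grandparent–grandchild and avuncular
pairs share $(\tfrac12,\tfrac12,0)$ and are therefore a single category,
labelled HS; an HS call never asserts half-sibship specifically.

The LOD score is the natural-log likelihood ratio against unrelatedness,
summed over loci typed in **both** members of the pair; the per-pair
locus count is reported as `n_loci` alongside every score. Scoring over
shared typed loci (rather than renormalising to a fixed panel) was an
open choice; it is the standard likelihood treatment of missingness and
is exact when missingness is unrelated to genotype.

## The genotyping-error model

Observed genotypes pass through a constant, independent per-allele error
channel with rate $\epsilon$ (default 0.0077 per allele, a rate
established for right-whale microsatellite panels): each observed allele
equals the true allele with probability $1-\epsilon$. What replaces a
mis-read allele is underdetermined by "constant and independent per-allele
error", so both natural completions are implemented:

* `freq_draw` (default): the observed allele is a fresh draw from the
  population frequencies (self-replacement allowed). This is the
  simplest channel consistent with the marginal allele distribution.
* `uniform_other`: uniform over the other $k-1$ alleles of the locus.

The choice matters little at $\epsilon \approx 0.008$ but both are
exposed because the original convention cannot be recovered from the
method description alone. With $\epsilon > 0$ every genotype pair has
positive probability under every hypothesis, so a single
Mendelian-incompatible locus costs a large but finite LOD penalty
instead of $-\infty$; the multimodal shape of the unrelated LOD
distribution (one mode per count of incompatible loci) follows directly
and is verified in the test suite.

All per-locus tables — Hardy–Weinberg vectors, the PO transition, the
genotype-level error kernel and the resulting observed-pair probability
matrices per hypothesis — are precomputed when `kin_model()` is fitted,
so scoring 14,535 pairs or simulating $10^6$ calibration pairs is a
matter of table lookups. The matrices are explicitly symmetrised after
assembly so that LOD scores are exactly order-invariant at floating-point
level.

## Duplicate and resample detection

Survey datasets contain records that are the same individual twice:
either two biopsies at the same encounter, or the same animal re-sampled
in a different year. Records are merged when their self/monozygotic LOD
(SELF versus unrelated) exceeds a threshold **and** SELF is the
maximum-likelihood hypothesis for the pair — the second condition is
essential, because a true parent–offspring pair can reach a moderately
high self-LOD while its PO LOD is higher still. The threshold is
calibrated by simulating unrelated pairs and choosing the smallest value
whose expected number of false merges in a dataset of the given size is
below 0.01, floored at 0 (a merged pair must at minimum be likelier self
than unrelated). Merged groups sharing one date and position are tagged
as same-encounter duplicates, others as resamples; the earliest record
represents the individual. The matching criterion used by the original
individual-identification work is not specified there; this LOD-based
rule is this package's reconstruction, chosen for consistency with the
likelihood framework used everywhere else. Allele frequencies are
estimated once before deduplication (to score the merge pass) and
re-estimated on unique individuals for all downstream scoring, which
keeps duplicate records from double-counting alleles.

## Cut-off calibration and corrected kin counts

`simulate()` on a fitted model draws genotype pairs of a chosen true
category (IBD state per locus from $\kappa$, shared alleles copied,
free alleles as Hardy–Weinberg draws, then the error channel) and scores
them exactly as data pairs are scored. False-positive rates at a cut-off
$c$ are the fraction of simulated unrelated pairs with scored LOD $> c$
*and* the target maximum-likelihood category; false-negative rates are
the fraction of simulated PO pairs failing that joint criterion.
Expected false-positive counts multiply the per-pair rate by the total
number of comparisons — justified because true kin are a negligible
fraction of all pairs. Expected false negatives scale with the unknown
true kin count, so the bias-corrected count
$N = \text{observed} - E[\text{FP}] + r_{\text{FN}} N$ is solved as a
fixed point (iterated to relative tolerance $10^{-6}$; the closed form
$(\text{observed} - E[\text{FP}])/(1 - r_{\text{FN}})$ is the same
number). Tail rates below one simulated count resolve to zero rather
than being extrapolated; no importance sampling is attempted.

Default replicates are $10^6$ for a production calibration and $10^4$ to
$10^5$ in the test suite and examples; the calibration quantities used by
the tests (FN rates around 0.15–0.2 at the default cut-off) are stable
at those sizes.

A known limitation, visible in the package's own planted-truth battery:
because allele frequencies are plugged in from the same modest sample
being analysed (342 gene copies per locus here), simulated calibration
pairs are slightly easier to classify than real pairs generated under
the true frequencies, so the corrected count carries a small negative
bias at study-sized samples. With the true generating frequencies the
estimator is unbiased. This is inherent to the plug-in design the method
uses, not to this implementation.

## Classification, annotation, triads

Dyads are data pairs whose `LOD_PO` exceeds the working cut-off (default
6, the value at which expected false positives stay in the low single
digits while power remains high for first-degree kin). Maximum-likelihood
categories are assigned over {PO, FS, HS, U}; SELF is excluded once
deduplication has run. Ties break toward the less related category —
conservative against declaring kin. FS-classified dyads are retained but
flagged low-confidence: at this marker informativeness the FS likelihood
surface overlaps PO and HS broadly, so an FS label is weak evidence of
full sibship.

Maternal-consistency annotation uses the maternally inherited mtDNA
haplotype: a shared known haplotype with sexes {M, F} is labelled MS
(consistent with mother–son), {F, F} MD (mother–daughter), {M, M} none;
differing known haplotypes exclude a maternal link, and any unknown
haplotype or sex yields "n/a". The label never designates which member
is the parent. When both body lengths are known, the larger individual
is flagged as the presumed mother (for MS only if the larger one is the
female); the flag is a consistency note and never changes the label.
A female–female dyad chain (one female in two dyads) admits both a
mother-with-two-daughters and a grandmother–mother–grandchild reading;
the package reports the connected structure and leaves the
interpretation to age data it does not have.

Triads are connected components with three or more members in the graph
whose edges are dyads; components of two remain plain dyads. Elapsed
time between a dyad's two sampling events is reported in whole years
(calendar days / 365.25, floored), so two captures in one austral season
count as 0 — the convention that reproduces year-count summaries from
printed dates.

## Geography and kinship

Longitude differences use the minimal angular convention
($\min(|\Delta|, 360-|\Delta|)$, always in $[0, 180]$), since feeding
-ground samples can straddle the antimeridian. The Wilcoxon rank-sum
test compares Δ longitude between ML-classified PO and U pairs (HS
calls are too unreliable individually to form a group); it enumerates
the exact null only when both groups have at most 10 pairs and no ties,
otherwise it uses the tie-corrected normal approximation, two-sided
throughout. Field-observed mother–calf pairs are excluded from the
spatial analyses — they are sampled together by construction and would
inject a trivial proximity signal. Pair non-independence (each
individual appears in $n-1$ pairs) is accepted; the package's null
simulations confirm the test's type-I error stays near nominal in this
design.

The tail analysis regresses the $\tau$-quantile of `LOD_HS` on Δ
longitude and SameDayPos (same calendar day **and** same survey vessel)
by minimising the pinball loss
$\sum_i \rho_\tau(y_i - b_0 - b_1\,\text{SameDayPos}_i - b_2\,\Delta\text{lon}_i)$,
$\rho_\tau(u) = u(\tau - \mathbb{1}[u<0])$. The solver is written for
this small fixed design: an intercept-only problem returns the
closed-form empirical quantile (type-1); otherwise iteratively
reweighted least squares provides a start, Nelder–Mead polishes it, and
a final search over exact interpolations of the smallest-residual
observations lands on an optimal vertex (an optimum of this LP
interpolates $p$ data points). On random problems the solver matches
the pinball loss of specialised quantile-regression software to within
$10^{-8}$. Confidence bands are pair-level bootstrap percentiles
(default 95%, seeded); the bootstrap treats pairs as exchangeable units,
the same pragmatic approximation as the rank-sum test. Sector
restrictions default to 85–135°E for the rank-sum run and 80–135°E for
the quantile regression — the two slightly different sector definitions
the motivating study uses, kept distinct deliberately and both
configurable.

## The synthetic-data generator

`simulate_population()` exists so that every stage is testable against
known truth. It emulates the *shape* of an Antarctic feeding-ground
biopsy survey: 14 microsatellite loci with 2–15 alleles and
Dirichlet-sampled frequencies, founders in Hardy–Weinberg proportions,
Mendelian transmission, mtDNA haplotypes (8 by default) copied from the
mother, near-even sex ratio, per-allele genotyping error at 0.0077,
sampling seasons 1993–2019 concentrated at 85–135°E with occasional
lower-latitude events, per-year survey-event days shared by several
animals (so the SameDayPos covariate has support), field-flagged
mother–calf pairs sharing one event, and injected same-encounter
duplicates and later-dated resamples. Rather than free random mating
over generations, the pedigree is built from explicit kin units
(unrelated singletons, PO/HS/FS pairs, mother-plus-two-offspring
triads) so fixtures contain exact planted-kin counts; the ground-truth
relationship table is derived by an independent pedigree walk. The
pinned `sim_srw_study()` configuration yields 183 records collapsing to
171 individuals (4 duplicates + 8 resamples).

What it does **not** emulate — and therefore what passing tests cannot
show about real data: linkage and null alleles, allele-size mutation,
age structure and realistic movement (positions are event centres plus
noise; body lengths are two normal ranges exercising only the
presumed-mother flag), non-random sampling with respect to kinship, and
real mtDNA haplotype frequency structure. Tests on this generator
validate the inference machinery, not field realism.

## Numerical and reproducibility choices

Natural logarithms throughout. Genotypes are canonical unordered pairs,
so representation never affects equality. Probability tables are
symmetrised; normalisation is verified to $10^{-9}$ and oracle
equivalence (exhaustive enumeration over ordered allele tuples) to
$10^{-12}$ in the tests. Degenerate inputs have defined results rather
than errors where a result is meaningful: monomorphic loci are "not
testable" in the Hardy–Weinberg check, pairs with no shared typed locus
are "unscorable", an empty Wilcoxon group is "not testable", a
degenerate quantile-regression design falls back to intercept-only with
a warning, and a negative corrected kin count is returned flagged. All
simulation entry points take explicit seeds and never draw from
wall-clock state; the full pipeline derives per-stage streams from one
master seed, and identical inputs plus seed reproduce every output file
byte-for-byte. Test-suite problem sizes (2×10^4 calibration pairs per
category, 20-seed recovery batteries, 10-fixture sensitivity batteries)
were chosen so that each check has adequate power while the whole suite
stays in the minutes range.
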