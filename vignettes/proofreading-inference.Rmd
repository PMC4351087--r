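---
title: "Fluctuation-assay rates and polymerase proofreading inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fluctuation-assay rates and polymerase proofreading inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluctproof)
```

## The assay and the questions it answers

A yeast reversion reporter carries a single point mutation (`trp5-G148T`,
`-A149C`, `-G148A`, `-A149G`, `-G148C` or `-A149T`) that can return to wild
type through exactly one base-pair substitution. Because the reporter sits
next to a dependable replication origin in both orientations (F and R), the
strand on which each reverting mispair arises is known: Pol ε replicates
the leading strand, Pol δ the lagging strand. In diploid strains deleted
for *MSH6* (no MutSα mismatch recognition) and carrying exonuclease-dead
alleles of *POL2* (Pol ε, `pol2-4`) or *POL3* (Pol δ, `pol3-5DV`) in
heterozygous or homozygous form, reversion rates expose how misinsertion,
mispair extension, polymerase dissociation and proofreading by other
polymerase molecules combine into a fixed mutation.

The package implements that analysis end to end:

1. **Rate estimation** (`estimateM`, `profileCI`, `estimateRate`):
   maximum-likelihood mutations-per-culture under the Luria–Delbrück
   (Lea–Coulson) distribution, with profile-likelihood intervals.
2. **Strand inference** (`assignMispair`, `equivalentMispairPairs`): the
   deterministic allele × orientation × polymerase → (template, primer)
   mapping.
3. **Proofreading inference** (`rateRatio`, `inferRescueFraction`,
   `buildComparisonTables`): het/hom and cross-polymerase comparisons, and
   the rescued-error fraction *f*.
4. **A mechanistic fork simulator** (`mutationProbability`,
   `simulateForkMC`, `generateStudy`): the synthetic-data generator whose
   closed form doubles as the model being fitted.
5. **Oligo-transformation statistics** (`relativeTransformation`,
   `mannWhitney`, `predictOligoOutcome`).

## The Luria–Delbrück estimator

Each culture grows from a small inoculum to $N$ cells; mutations arise
during growth at per-cell rate $\mu$, and each founds a clone whose size at
plating follows the classic $\lfloor 1/U \rfloor$ law ($U \sim
\mathrm{Unif}(0,1)$) — the Lea–Coulson formulation with no mutant fitness
differential and deterministic exponential growth, so the expected number
of mutation events per culture is $m = \mu(N - n_0)$. The mutant-count
probabilities follow the recursion

$$p_0 = e^{-m}, \qquad p_n = \frac{m}{n} \sum_{i=0}^{n-1}
\frac{p_i}{n-i+1},$$

which we evaluate in compiled code. `estimateM` maximizes
$\sum_i \log p_{c_i}(m)$ over $\log m$ on the bracket $[10^{-8}, 10^3]$
(relative tolerance $10^{-6}$); all-zero counts give the boundary MLE
$m = 0$, whose interval lower bound is 0 and upper bound is the closed form
$\chi^2_{1,\text{level}}/(2C)$ for $C$ cultures.

Numerical choices worth knowing:

* **Censoring cap.** The distribution's tail is so heavy that a single
  culture can return a colony count in the tens of thousands (a jackpot).
  Counts above 5000 enter the likelihood as the exact tail mass
  $P(X \ge 5000)$ rather than a point mass. This is the correct censored
  likelihood, loses essentially no information about $m$ (the tail beyond
  the cap carries $\sim m/5000$ probability), and keeps the $O(n^2)$
  recursion affordable inside the optimizer. Counts above $10^5$
  additionally draw a warning so that data-entry errors are not silently
  absorbed.
* **Profile intervals.** Endpoints solve
  $2[\ell(\hat m) - \ell(m)] = \chi^2_{1,\text{level}}$ by bisection on
  each side of the MLE (geometric midpoints, relative tolerance
  $10^{-8}$). The 83% level uses the quantile $\approx 1.883$, the 95%
  level $3.841$. These are the two working levels of the interval-overlap
  significance rules below.
* **Unimodality.** The log-likelihood is unimodal in $\log m$ on this
  family (checked by grid scan in the test suite), which justifies
  bracketed one-dimensional optimization.
* **Partial plating.** The simulator supports binomial thinning
  (`plated_fraction < 1`) but the estimator assumes full plating and warns
  otherwise; no plating correction is attempted.
* **Aggregation.** When several experiments exist for one genotype, the
  estimate whose rate is the median is carried forward with its own
  intervals (lower median for even counts, ties broken by experiment id).
* **Units.** Rates are reported as $\mu = m/N$ per cell; we keep the unit
  naming neutral (per cell division vs per cell per generation is a
  convention the data cannot distinguish).

### The interval-overlap significance rule

Two estimates are called different when their confidence intervals at a
chosen level are disjoint. For independent Gaussian estimates with equal
standard errors the implied two-sided level is
$2(1-\Phi(\sqrt{2}\,z_{(1+\text{level})/2}))$: non-overlap of 95% intervals
corresponds to $\alpha \approx 0.0056$ (a much stricter test than commonly
assumed), while non-overlap of 83% intervals corresponds to
$\alpha \approx 0.052$ — the conventional 0.05. `impliedAlpha` computes the
general form, and the two-fold Pol ε comparisons are therefore tested at
the 83% level by default while everything else uses 95%.

## Strand inference

`candidateMispairs` derives, for each allele, the two strand-specific
(template, primer) mispairs that can produce the reversion; they are
complementary images of each other (A-G on one strand is T-C on the
other). The orientation rule — in F the leading-strand polymerase copies
the reporter's coding ("top") strand as template, in R the roles swap — is
a single constant fixed by reproducing all sixteen published
template/primer assignments, which the test suite reconstructs as a golden
table. The identical-base alleles (G148C, A149T) follow the same generic
rule but are flagged `extrapolated` because the published comparisons omit
them (their mispairs barely extend and their rates stay near background).

## The fork model

For one replication of the assayed site, a reversion is fixed when three
stages succeed:

1. **Insertion.** A molecule drawn from the replicating polymerase's pool
   misinserts with probability `insProb[mispair]` if proofreading-dead
   (pool fraction $1-w_{\text{pol}}$); proficient molecules contribute only
   through the escape probability `exoEscape` (default 0).
2. **Survival.** The engaged polymerase extends the 3′ mispair with
   probability $e$; failing that it dissociates, and the exposed terminus
   is engaged by a molecule from the Pol δ pool — wild-type (and excising,
   probability $w_\delta r$) or proofreading-dead, which re-engages and
   extends with probability $e' = e$. The geometric loop gives
   $$P_{\text{survive}} = e + (1-e)\,
   \frac{(1-w_\delta r)\,e'}{1-(1-w_\delta r)(1-e')},$$
   with the degenerate no-extension, no-rescue case ($e = 0$,
   $w_\delta r = 0$) counting as no reversion. The rescue pool is always
   Pol δ: the model's hard rule is that Pol δ proofreads exposed termini on
   both strands (in cis and in trans) and Pol ε proofreads nothing but its
   own active site.
3. **Mismatch repair.** A surviving mismatch escapes with probability
   $1-\text{mmrEfficiency}$ (0.99 efficiency for MMR-proficient strains, 0
   for *msh6*).

A genotype-independent `backgroundRate` ($10^{-10}$) adds the
damage-driven floor. An 8-oxoG-A mispair is modelled as invisible to every
exonuclease — retained regardless of pool composition, extended with
certainty, never rescued — while remaining a substrate for MMR; this
reproduces the observation that its reversion signal is unchanged across
proofreading genotypes.

Two consequences the tests assert analytically: with a fully wild-type
Pol δ pool the Pol ε hom:het ratio is exactly 2 (insertion scales with the
mutant fraction and survival is zygosity-independent), and the hom:het
ratio for Pol δ is $2/P_{\text{survive}}(\text{het})$, so a 32-fold ratio
implies $f = 1 - 2/32 \approx 94\%$ of errors rescued.

`simulateForkMC` replays the same chain event by event (vectorized across
replications, with a re-engagement cap of 1000 and overflows counted as no
reversion) and serves as the stochastic oracle for the closed form.

### Rescued-fraction inference

`inferRescueFraction` inverts the half-rate expectation: if a heterozygous
pool shows rate $\mu_{het}$ and the homozygote $\mu_{hom}$, then
$f = 1 - 2/R$ with $R = \mu_{hom}/\mu_{het}$. Ratios below 2 carry no
rescue signal and are reported as $f = 0$ with `valid = FALSE`. Applied to
the published Pol δ ratios $\{32, 46, 12, 32\}$ this gives
$f = \{0.94, 0.96, 0.83, 0.94\}$ — median 94%, supporting the headline
"more than 90%" claim, though the smallest ratio alone sits below it; the
package reproduces this faithfully rather than smoothing it away. Ratio
uncertainty is not propagated analytically (significance uses only
interval overlap), but interval endpoints can be ratioed for conservative
bounds, which is what the end-to-end recovery test does.

## What the synthetic-data generator emulates — and what it does not

`generateStudy` chains `mutationProbability` →
`simulateFluctuationAssay` over a design (by default 4 alleles × 2
orientations × 5 genotype classes = 40 strains) and writes the standard
culture TSV plus a YAML ground-truth sidecar carrying each strain's true
rate and, for polymerase-mutant strains, the rescued fraction a
heterozygous pool would show. One seed per experiment is derived from the
study seed by drawing from `sample.int` under the study seed, so studies
are reproducible end to end.

Default study conditions: $N = 2\times10^8$ cells plated, inoculum
$10^3$, 24 cultures per experiment (typical bench values; the source data
do not state theirs), insertion probabilities between $4\times10^{-9}$ and
$1.2\times10^{-7}$ per site replication and extension probabilities
between 0.001 and 0.05 chosen once so that (i) homozygous-deficient
double-mutant strains land in the estimator's comfortable $m$ range, (ii)
het/hom ratios for Pol δ land in the observed 12–46-fold regime (small
extension probabilities are exactly what make trans/cis rescue strong),
and (iii) pyrimidine-primer mispairs (T-C/C-T, T-G) out-extend their
complements (A-G/G-A, A-C), reproducing the orientation bias.

The generator is faithful to the estimator's assumptions by construction —
that is what makes simulator/estimator consistency a meaningful test — so
passing tests demonstrate internal coherence and correct implementation,
not that real cultures obey the Lea–Coulson idealization. Real data add
phenotypic lag, mutant/wild-type fitness differences, plating losses,
culture-to-culture $N$ variation and sequence-context effects, none of
which are modelled. Absolute published reversion rates are therefore not
reproduction targets (their raw colony counts are unpublished); the
package targets the *structure* of the analysis: ratios, significance
calls, and the rescued fraction.

## Oligo-transformation analysis

Relative transformation is the per-replicate ratio of test-oligo to
control-oligo colonies, averaged with SD (per-replicate ratio first, then
mean — not a ratio of means). Rendering follows the source convention:
`"0"` means no revertants at all, `"0.00"` means revertants seen but below
1/100 of control, otherwise two decimals. `mannWhitney` compares genotypes
by an exact two-sided rank-sum test when the pooled sample is ≤ 20 with no
ties — full enumeration of all $\binom{n}{n_a}$ rank splits, counting
splits whose U deviates from its null mean at least as much as observed —
and falls back to midranks with the tie-corrected normal approximation
otherwise. Two-sidedness is our choice (the source does not state
sidedness). `predictOligoOutcome` maps an oligo's terminal mispair through
the fork model's survival term times MMR escape, on a shared arbitrary
scale per genotype panel (annealing efficiency and strand preference are
absorbed into the scale, not modelled).

## Worked example

```{r example}
params <- defaultForkParams()
design <- list(
  StrainGenotype("G148T", "R", pol3 = "hom"),
  StrainGenotype("G148T", "R", pol3 = "het")
)
study <- generateStudy(params, design, n_cultures = 24, seed = 20260919)
ests <- suppressWarnings(lapply(study, estimateRate))
ests[[1]]

inf <- inferRescueFraction(ests[[1]], ests[[2]])
unlist(inf)

# ground truth the generator recorded
attr(study, "truth")$true_f_het
```

The inferred $f$ recovers the generator's truth within the precision a
24-culture experiment allows; the end-to-end test repeats this over 20
seeds with interval-propagated bounds and requires ≥ 90% coverage.

## Problem sizes used by the test suite

Distributional checks run at $10^5$ cultures (total-variation distance
< 0.01 against the recursion), MLE recovery at 1000 cultures, interval
coverage at 2000 simulated 24-culture experiments, Monte-Carlo fork checks
at $2\times10^4$–$10^6$ replications, and the calibration of the overlap
rule at $10^6$ simulated pairs. These sizes make the stochastic assertions
sharp enough to catch implementation errors while keeping a full run in
the minutes range on one core.

## Known limitations

* Salvador-style exact interval methods may differ slightly from profile
  likelihood; published interval endpoints are not reproduction targets.
* The estimator ignores partial plating and phenotypic lag; the median
  aggregation rule discards between-experiment variance.
* The fork model collapses MMR to a single escape probability and treats
  the re-engaging mutant Pol δ's extension probability as equal to the
  inserting polymerase's for the same mispair.
* Leading/lagging assignment assumes every fork comes from the nearby
  origin; fork passage from elsewhere is not modelled.
* Oligo predictions are relative only; per-strand annealing preference is
  a free scale factor.
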