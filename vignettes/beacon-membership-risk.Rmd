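---
title: "Membership-inference risk of genomic beacons: model, attack and defenses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membership-inference risk of genomic beacons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A beacon answers yes/no queries of the form *"does any genome in this dataset
carry allele X at position Y of chromosome Z?"*. An adversary holding a copy
of a target's genome can query the sites where that copy carries an alternate
allele. If the target is one of the beacon's $N$ members, essentially every
answer is *yes*; if not, an answer is *no* whenever none of the $N$ members
carries the allele. A likelihood-ratio test over the binary response vector
$R = x_1,\dots,x_n$ therefore decides membership. `beaconrisk` implements
that test, the closed-form risk analysis a data owner can run before
publishing a beacon, and two randomized-response defenses.

## The response model

Two hypotheses about a target:

* $H_0$ (not in the beacon): each answer is Bernoulli with yes-probability
  $\theta_0 = 1 - D_N$, where $D_N$ is the probability that none of the $N$
  genomes carries the queried allele at a site where the target carries it.
* $H_1$ (in the beacon): a *no* requires both a mismatch between the
  adversary's copy and the beacon's copy of the target (probability
  $\delta$, the sequencing-error / variant-calling discordance rate) and
  absence among the other $N-1$ genomes, so the yes-probability is
  $\theta_1 = 1 - \delta D_{N-1}$.

The log likelihood-ratio reduces to a linear function of the yes-count,
$$\Lambda = n B + C \sum_i x_i, \qquad
B = \log\frac{D_N}{\delta D_{N-1}}, \quad
C = \log\frac{\delta D_{N-1}(1-D_N)}{D_N(1-\delta D_{N-1})},$$
and since $C < 0$ whenever $\delta D_{N-1} < D_N$, thresholding $\Lambda$ is
equivalent to thresholding $\sum_i x_i$. `lrt_statistics()` computes both
forms and the package's tests verify they agree to $10^{-9}$ relative on
random inputs.

## $D_N$ and the beta spectrum model

The adversary is assumed to know only the shape of the allele-frequency
spectrum, summarized by a beta fit $f \sim \mathrm{Beta}(a', b')$. With
$a = a'+1$, $b = b'+1$ the model uses the closed form
$$D_N \approx \frac{\Gamma(a+b)}{\Gamma(b)\,(2N+a+b)^a},$$
evaluated in log-gamma space (`compute_dn()`) so that no $N$ overflows. The
shifted exponents encode that queried sites are not spectrum-random: they are
sites the target carries. `exact_dn()` provides the exact beta expectation
$E_{f\sim\mathrm{Beta}(a,b)}[(1-f)^{2N}] = B(a, b+2N)/B(a,b)$ as an
independent oracle; the approximation stays within 1% of it across the
parameter ranges of the published table, which the test suite asserts.

**A caution the tests are explicit about.** The closed form corresponds to
heterozygosity-weighted site use ($f$ at queried sites
$\sim \mathrm{Beta}(a'+1, b'+1)$), while the attack as operationalized
queries *every* site where the copy carries at least one alternate allele.
Under the generative simulation the per-query no-rate for non-members is
therefore not exactly $D_N$: on neutral panels with the moment fit the model
value is roughly 20% below the realized rate. The model-agreement tests
check the binomial law exactly under the model's own premise (simulating
queried-site frequencies from $\mathrm{Beta}(a,b)$), and separately check
that the generative pipeline's no-rate stays within a factor two of $D_N$
with binomial dispersion at the empirical rate. Pretending the two coincide
to Monte-Carlo precision would be false at scale.

## Fitting $(a', b')$

`fit_beta()` defaults to the method of moments. This is a deliberate choice:
the published parameter tables for neutral site-frequency spectra are moment
fits — the moment estimator applied to the exact $1/i$ spectrum of a
population of 10,000 diploids reproduces the published simulation row
$(a', b') = (0.1179, 1.1188)$ to four decimals, while the maximum-likelihood
fit of the same spectrum lands far away ($\approx (0.20, 1.73)$), because a
two-parameter beta cannot represent a $1/f$-like density and the two
estimators disagree precisely when the model is misspecified. For samples
that genuinely are beta-distributed, `method = "mle"` (BFGS on log-shapes,
analytic gradient, $10^{-8}$ gradient tolerance) recovers parameters more
efficiently and is cross-checked against `fitdistrplus` in the tests.

## The decision threshold

With $R_e = \frac1n\sum x_i$ approximately
$\mathcal N(\theta_0, \sigma_0^2)$, $\sigma_0^2 = D_N(1-D_N)/n$ under $H_0$,
the $\alpha$-level threshold on the yes-count is
$$t'_\alpha = \lfloor n(z\sigma_0 + \theta_0)\rfloor,$$
with $z = 1.65$ at $\alpha = 0.05$ (the rounded table value; the exact
quantile 1.6449 is available via `paper_z = FALSE` and differs by far less
than one count at realistic scales). The expected budget is
$n = \lfloor N^{a'+1}\rfloor$. Flooring both reproduces four of the five
published threshold rows exactly and the fifth within one count; the
published table is internally inconsistent at the $\pm 1$ level under any
single rounding rule, so the tests accept $\pm 1$ there.

Two readings of the decision rule exist and `decide_membership()` implements
both:

* `rule = "min_yes"` (default): $\sum x_i \ge t'_\alpha$ concludes
  membership — the operational reading, under which $t'_\alpha$ is *the
  number of yes-answers the adversary needs*. At the published parameter
  scales $t'_\alpha$ equals the full budget $n$, so the operational test
  degenerates to "every queried allele is present", which is exactly what
  gives the attack its power there.
* `rule = "strict"`: $\sum x_i > t'_\alpha$, the literal inequality of the
  threshold derivation. It is conservative: whenever
  $n \le z^2(1-D_N)/D_N$ the threshold equals $n$ and nothing can ever be
  rejected. The analytic power companion `power_analytic()` exposes the
  resulting step: with $\delta = 0$, power under the strict rule jumps from
  0 to 1 at $n \approx z^2(1-D_N)/D_N$.

Thresholds are always recomputed at the number of queries actually issued,
so partial budgets remain calibrated; the published analysis computes
$t'_\alpha$ only at the nominal $n = N^{a'+1}$.

**Calibration regime.** The normal approximation is a large-count
approximation: it is accurate when $nD_N$ is large (tens), where the test
suite verifies type-I error $\approx \alpha$ within Monte-Carlo and
discreteness error. At the published table's own scales $nD_N \approx 1$–$4$
and the threshold is degenerate ($t'_\alpha = n$): the strict rule then
rejects nothing and the min-yes rule is the all-yes test with true
false-positive rate $(1-p_{\text{no}})^n$ — about 0.04 at the 5,000-query,
$N = 1000$ study point, i.e. close to the nominal 0.05 by arithmetic
accident rather than by asymptotics. The package reports empirical type-I
error alongside power so this is visible rather than hidden.

## What the generator emulates — and what it does not

`sample_neutral_frequencies()` draws derived-allele counts
$i \in \{1,\dots,2M-1\}$ with $P(i) \propto 1/i$ (the standard neutral
site-frequency spectrum for $M$ diploids, i.e. $2M$ chromosomes — the
genomes are taken as diploid throughout, which is what the $2N$ exponent in
$D_N$ presumes) and sets $f = i/2M$. Genotypes are independent
$\mathrm{Binomial}(2, f)$ per site (Hardy–Weinberg, no linkage
disequilibrium, no demography, no sex chromosomes). Relatives share each
site's genotype with probability $\varphi$ and redraw otherwise; sequencing
error reverts alternate-allele sites of the adversary's copy to homozygous
reference independently at rate $\delta$.

Consequences worth knowing:

* Without LD, queries are exchangeable; the seeded shuffle in
  `select_query_positions()` is then only a tie-break, not a power choice.
  Against real genomes, correlated sites would make the effective number of
  independent queries smaller than $n$.
* Reversion-only sequencing error means an in-beacon target's queried sites
  are always truly carried, so $\delta$ affects the decision only through
  the threshold ($\theta_1$ differs from 1 by $\delta D_{N-1} \sim 10^{-6}$
  at the study's $\delta = 10^{-3}$ — statistically invisible at any tested
  scale). A symmetric error model that also invents alternate calls would
  lower power; it is out of scope here.
* Passing tests on this generator demonstrate the attack's statistical
  machinery, not its performance on real, linked, structured genomes.

Default study conditions follow the published protocol: population of
20,000 diploids, panels of $10^5$–$10^6$ SNPs (the tests and the acceptance
script use $10^5$, which keeps the full pipeline under half a minute while
leaving every rate's Monte-Carlo error well below the tested tolerances),
beacons of 1,000–2,000 members, cohorts of 100+ members and 100+
non-members (the published experiments use 400+400), $\delta = 10^{-3}$,
$\alpha = 0.05$, kinship $\varphi \in \{1, 0.5, 0.25, 0.125\}$.
`beacon_power_study()` materializes only the genomes the study touches
(members and targets); the remaining population enters through the
spectrum, which is statistically equivalent and keeps memory flat.

## The defenses

Both mechanisms preprocess the stored presence bits; the catalogue and the
member count never change.

* *Random position elimination*: each bit is truthful with probability $b$,
  flipped with probability $1-b$ (false positives and negatives alike). A
  deletion-only variant (presence→absence) is available behind
  `deletion_only = TRUE` for comparison.
* *Biased randomized response* (two-coin): truthful outright with
  probability $b$, otherwise truthful again with probability $b$ and flipped
  with probability $1-b$ — net truthful probability $1-(1-b)^2$, and
  $\epsilon$-differentially private with
  $\epsilon = |\ln(1/(1-b)^2 - 1)|$ (`epsilon_of_bias()`), zero at
  $b = 1 - 1/\sqrt2$ and infinite (flagged) at the deterministic ends
  $b \in \{0, 1\}$.

The mechanisms coincide at $b_1 = 2b_2 - b_2^2$ (`bias_equivalence()`), which
the tests verify empirically with a two-proportion test. Bias is accepted on
the $[0,1]$ scale or as a percentage (50/75/90, the experiment scale).
Preprocessing is the default deployment because an online coin
(`answer_online()`) can be averaged away by repeating a query — the package
demonstrates that inference attack in its tests.

`confusion_accuracy()` measures utility over the whole catalogued entry set
(the quantity both mechanisms control); a query-stream variant would weight
sites by query frequency and is intentionally not the default basis.
`privacy_utility_sweep()` recomputes the attack threshold for the perturbed
response distribution by default (`recalibrate = TRUE`): under a mechanism
truthful with probability $q$ the null yes-rate becomes
$q\theta_0 + (1-q)(1-\theta_0)$, and reusing the unperturbed threshold
(`recalibrate = FALSE`, the mechanism-unaware adversary) collapses power
against any perturbation at the all-yes threshold. The sweep's tested claim
is qualitative — power non-decreasing in achieved accuracy; exact power
values at specific bias/budget pairs depend on evaluation details the
published description does not pin down, and are not asserted.

## Numerical conventions and degenerate inputs

* Coordinates are 0-based half-open internally, 1-based in every on-disk
  format (beacon TSV, panel TSV, VCF); conversion happens only at IO
  boundaries.
* Simulated panels use the abstract allele token `ALT`; nucleotide alleles
  appear only in VCF-derived beacons. Queries off the catalogue answer "no",
  as public beacons do.
* $D_0 := 1$ (with no other genome the allele is certainly absent), used for
  the $N = 1$ beacon edge case and flagged on the profile.
* Targets with no alternate sites produce an empty query list and are
  flagged inconclusive, never rejected.
* $\delta = 0$ under $H_1$ with an observed "no" yields
  $L_{H_1} = -\infty$ and an explicit impossibility flag instead of a
  numeric error.
* All randomness flows through explicit per-operation seeds
  (`withr::with_seed`); no function mutates the caller's RNG state when a
  seed is given, and identical seeds give bit-identical outputs, including
  across the serialization round trip.

## Limitations

* The adversary model is the weak, spectrum-only one. An adversary with
  per-site allele frequencies from a public reference panel would order
  queries by informativeness and need fewer of them; that stronger attack is
  out of scope.
* The risk model's normal approximation is unreliable exactly where beacons
  are most vulnerable (small $nD_N$); use the empirical pipeline, not only
  the closed form, when deciding whether to publish a beacon.
* No linkage, demography, or genotyping-platform ascertainment; absolute
  power numbers on real data will differ from the simulation's.
* The differential-privacy guarantee is per released bit; composition across
  the whole catalogue or across repeated releases is not accounted.
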