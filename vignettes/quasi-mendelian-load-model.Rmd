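---
title: "Exact case-control inference under a quasi-Mendelian load-threshold model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact case-control inference under a quasi-Mendelian load-threshold model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quasimendel)
```

## The scientific problem

Hereditary retinal degenerations (HRD) are, with few exceptions, strictly
Mendelian: one dominant or two recessive mutations in a single gene are both
necessary and sufficient for disease.  Some alleles, however, refuse to fit
this scheme.  The motivating case is a frequent nonsense variant in the
ciliary gene *RP1* (population allele frequency about 0.6% in Japan) that is
demonstrably benign in heterozygous *and* homozygous carriers, acts as a
classical recessive allele when in *trans* with a severe *RP1* null, and is
nevertheless significantly enriched among patients who carry no other
recognized *RP1* mutation.  The parsimonious model is a *mutational-load
threshold*: each allele contributes a dose-weighted amount of functional
damage, and disease manifests when the summed load crosses a threshold.  A
hypomorphic allele then behaves "quasi-Mendelianly": Mendelian in some
genotype contexts, an oligogenic risk factor in others.

`quasimendel` implements the statistical machinery needed to detect and
characterize such an allele — exact 2x2 inference, Hardy-Weinberg testing,
genotype QC, relatedness screening, carrier tallies, and a
carrier-conditioned association scan — together with a forward simulator of
that load-threshold model, so the entire pipeline can be exercised and
validated without access-restricted genotype data.

## The penetrance model

An individual's load is $L = \sum_v d_v w_v$, with $d_v \in \{0,1,2\}$ the
dosage of variant $v$ and $w_v \in [0,1]$ its severity weight.  Affection is
deterministic: affected iff $L \ge T$.  The package defaults are

* $w = 1$ for severe null alleles (complete loss of one copy's function),
* $w = 0.5$ for the frequent hypomorph,
* $w \in \{0.5, 1\}$ for panel-gene modifiers, $w = 0$ for neutral
  polymorphisms,
* threshold $T = 1.5$.

This is the minimal assignment reproducing every genotype-phenotype fact of
the motivating study: null/null and null/hypomorph genotypes are affected
(load 2 and 1.5); a homozygous hypomorph (load 1) and heterozygous carriers
of any single allele are healthy; a hypomorph heterozygote acquiring one
severe modifier allele elsewhere (load 0.5 + 1) crosses the threshold.  The
weights and threshold are configuration values, not biological claims: the
underlying study describes the threshold model only conceptually, and any
$(w, T)$ with $w_{\mathrm{null}} + w_{\mathrm{hypo}} \ge T$,
$2w_{\mathrm{hypo}} < T$ reproduces the same facts.  Penetrance is complete
and there are no phenocopies by default (`phenocopy_rate` is a knob).

## Generator calibration

`default_hrd_loci()` defines the reference scenario: 205 biallelic loci
comprising the three *RP1* alleles, 178 panel variants inside the 0.1-5%
control-frequency scan window (3 planted high-weight EYS-like modifiers at
control frequencies 0.017, 0.002 and 0.004 — the values reported for the
top association hits — plus 9 severe and 20 moderate modifiers and 146
neutral polymorphisms), and 24 out-of-window variants exercising the
frequency filter.  The severe-null frequency 1/1048 comes from one carrier
observed among 524 screened controls; the hypomorph frequency is the
reported 0.006.

The remaining modifier frequencies were set once, analytically, to make the
ascertained case cohort reproduce the reported effect size at the top hit.
Writing $\lambda_s = 2\sum_s q_s = 0.1$ for severe modifiers and
$\lambda_m = 2\sum_m q_m = 0.32$ for moderate ones, a hypomorph
heterozygote is affected with probability
$P \approx [1-e^{-\lambda_s}] + P(\mathrm{Poisson}(\lambda_m) \ge 2)
\approx 0.095 + 0.042 \approx 0.133$, and the planted 0.017-frequency
modifier is the causal route in $2 \times 0.017 / 0.133 \approx 0.25$ of
cases, i.e. an expected case allele frequency of about 0.127 against a
control frequency of 0.017 — matching the reported 0.125 vs 0.017.  These
defaults were fixed from this arithmetic and not revisited.

A consequence worth stating plainly: with 28 cases (56 alleles), the
Bonferroni threshold $0.05/178 = 2.81\times10^{-4}$ requires at least 7
case alt alleles (the exact p at 6 alleles is $4.3\times10^{-4}$), and a
binomial draw at frequency 0.125 yields 7 or more with probability only
about 0.56.  Detection of the planted modifier at the reported effect size
is therefore a coin-toss event per simulated cohort, not a near-certainty;
single-seed demonstrations succeed routinely, but replication frequencies
across seeds sit near that binomial bound.  This mirrors the original
design's marginal power rather than a defect of the simulator, and it is
why the test suite bounds detection counts conservatively.

What the generator does *not* emulate: linkage disequilibrium (the two
reported hits were explicitly not in LD; all loci are sampled
independently), haplotype structure, de-novo mutation, genotyping error
beyond the planted QC failures, population stratification, and incomplete
penetrance.  Passing tests therefore validate the statistical machinery
under idealized sampling, not robustness to confounding in real cohorts.
The deterministic model also overstates population prevalence somewhat
(any two severe modifier alleles suffice for disease); this inflates
nothing in the carrier-conditioned analyses, which condition on affection
and carrier status.

## Exact inference conventions

All 2x2 inference conditions on both margins of the allele-count table.

* **Two-sided p** uses the point-probability method: the sum of central
  hypergeometric masses not exceeding the observed mass, with a relative
  tolerance of $10^{-7}$ when comparing masses so that floating-point ties
  are counted as ties.  This is the convention of the standard exact-test
  implementation in R, and reproduces the published p-values digit for
  digit.  Degenerate tables (an empty alt or ref column) admit a single
  configuration and return p = 1 with an undefined odds ratio.
* **The odds ratio** is the conditional maximum-likelihood estimate under
  the noncentral hypergeometric likelihood, found by bisection on
  $\log\psi$ of the monotone equation $E_\psi[A] = a$, starting from
  $[-30, 30]$ and widening automatically for extreme tables, with absolute
  tolerance $10^{-8}$.  Masses are computed from log-binomial coefficients
  to avoid overflow.  At the support boundary the estimate is exactly 0 or
  $\infty$.
* **Confidence bounds** invert the one-sided noncentral tails at
  $(1-\mathrm{level})/2$ per side by the same bisection.  The bounds
  always bracket the estimate when it is finite and nonzero.  Agreement
  with `stats::fisher.test` is to four or more significant digits except
  on extreme tables, where that function's looser root-finding tolerance
  shows; the test suite arbitrates such cases with an independent
  enumeration oracle.
* **The HWE exact test** enumerates heterozygote counts at fixed allele
  counts (the standard biallelic exact test, two-sided by the same
  point-probability rule).  A one-sided heterozygote-excess tail is
  exposed separately; the simulator reports it phred-scaled as the
  ExcessHet site annotation.  The two-sided test, not the one-sided
  variant, backs the QC cascade's HWE rule.

## QC cascade semantics

The six rules run in their stated order, each on the survivors of the
previous one, and every removal is charged to the first rule failed:

1. calls with DP < 8 or GQ < 20 become missing (boundary values kept);
2. sites with mean GQ $\le$ 35 over unmasked calls are excluded
   (boundary excluded);
3. sites with call rate $\le$ 0.9, computed on post-mask missingness, are
   excluded (the rule order implies the call-rate sees masked calls);
4. sites with exact HWE p $\le \alpha/m$ are excluded, with $m$ the
   number of polymorphic sites entering the rule (the divisor is not
   stated upstream; counting the actually tested sites is the
   conservative reading and is recomputed per run);
5. sites failing the VQSR flag are excluded (the flag is consumed from
   the input; no recalibration is performed);
6. the hard filter QD $\ge$ 2, FS $\le$ 60, MQ $\ge$ 40, MQRankSum
   $\ge -12.5$, ReadPosRankSum $\ge -8$, SOR $\le$ 3, ExcessHet $\le$ 20,
   all boundaries inclusive for keeping; missing metric values (e.g.
   rank-sums at sites without heterozygotes) pass and are flagged in the
   report.

Two deliberate edge behaviours: the cascade is idempotent in practice but
not by construction — rerunning shrinks the HWE Bonferroni divisor, so a
site with p in the hairline window between the two cutoffs could flip; and
when per-call failure rates are high, chance clustering of masked calls
can push an unplanted site over the call-rate boundary, so audit fixtures
for exact attribution use modest per-call rates.

## Relatedness estimation

Pairwise IBD is estimated by the method of moments on IBS counts: expected
IBS-class probabilities given IBD state are computed per site from allele
frequencies with a small-sample correction obtained by drawing the four
(IBD 0) or three (IBD 1) latent alleles *without replacement* from the
$2N$ alleles of the frequency sample; $\hat z_0$ follows from the IBS0
count, $\hat z_1$ from the IBS1 residual, $\hat z_2$ as the remainder, and
$\widehat{\pi} = \hat z_2 + \hat z_1/2$.  Negative solutions are clipped
to zero and renormalized — the behaviour of the standard tooling — which
makes the reported $\widehat{\pi}$ non-negative and slightly positively
biased for unrelated pairs (the unclipped solutions, which are unbiased,
are returned alongside).  Frequencies default to the analyzed sample
itself, as in the motivating analysis, accepting the associated
small-sample bias; sites with in-sample MAF below 0.01 are dropped as
uninformative.  Useful precision needs thousands of sites: the package's
reference check uses 5,000 independent sites for 28 individuals, where all
378 unrelated pairs fall well under the 0.2 relatedness threshold, while
the 205-locus demo panel is far too small for stable estimates and its
relatedness output is illustrative only.

## Association scan conventions

Tests are allelic (2N-allele denominators), forced by the reported
frequencies (0.125 = 7/56 alleles in 28 diploids).  The control-frequency
window 0.001-0.05 is inclusive at both ends; the index variant is excluded
regardless of frequency; variant-to-gene and consequence annotation are
inputs, never computed.  Multiple testing uses Bonferroni only, with the
divisor equal to the number of variants actually tested.  Q-Q plots use
$(i - 0.5)/n$ expected quantiles.  In the bundled pipeline the window
filter consumes the population frequency table (emulating filtering on a
reference-panel database), which makes the number of tests deterministic;
`assoc_scan()` falls back to cohort-estimated frequencies when no table is
given, in which case boundary variants drift in and out with sampling
noise.

## Numerical choices and degenerate inputs

Probability ties use relative tolerance $10^{-7}$; root-finding runs to
interval width $10^{-8}$ on the log-odds scale with automatic bracket
widening; hypergeometric and HWE masses are computed via `lchoose`/
`lfactorial` and renormalized over the support; monomorphic sites return
HWE p = 1 and are excluded from the HWE Bonferroni divisor; empty groups,
negative counts, frequencies outside (0,1), and unsatisfiable
ascertainment predicates (capped at $10^7$ rejection draws per requested
case, with an early abort after $10^6$ fruitless draws) raise errors
rather than degrade silently.  Missing dosages contribute no load in the
simulator, are excluded from tally and scan denominators pairwise, and are
skipped pairwise in IBS counting.

## Problem sizes used by the checks

The suite validates the Fisher p against full enumeration for every table
with $n \le 60$, the CMLE against generic likelihood maximization to
$10^{-4}$ on random tables with $n \le 200$, HWE super-uniformity on
10,000 simulated sites of 100 individuals, family-wise error on 200 null
scans of 50 variants at the full 28-vs-3554 cohort size, and
planted-modifier recovery on 20 simulated cohorts at the full size.  These
sizes were chosen so each check completes in seconds to a few minutes on
one core while leaving sampling error well below the asserted margins.

## Known limitations

* The load-threshold model is deterministic and single-threshold; real
  oligogenic architectures presumably involve variable expressivity,
  environmental modifiers, and incomplete penetrance.
* No LD, stratification, or haplotype structure is simulated, so the scan
  is validated only under exchangeable sampling.
* The conditional-MLE odds ratio is biased away from 1 for sparse tables
  (a property of the estimator, visible in the wide reported intervals of
  low-count hits).
* Relatedness estimates use in-sample frequencies and clipping, so small
  positive $\widehat{\pi}$ values for truly unrelated pairs are expected
  and should be read against the 0.2 decision threshold, not as point
  estimates of kinship.
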