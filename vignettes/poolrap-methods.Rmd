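---
title: "Models and methods: drift, Pool-Seq noise and AP/RAP differentiation testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: drift, Pool-Seq noise and AP/RAP differentiation testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolrap)
```

## The question the package addresses

Evolve-and-resequence (E&R) experiments in outcrossing organisms such as
*Drosophila* often start from a panel of freshly established isofemale
lines: pooling females from the lines yields an outbred ancestral
population (AP), and because the lines themselves are kept alive, an
almost identical reconstituted ancestral population (RAP) can be assembled
from the same lines years later as an unbiased reference for the evolved
populations. The approach is only valid if allele frequencies inside the
lines are not systematically shifted while the lines are maintained — by
selection or by drift — between the founding of the AP and the assembly of
the RAP.

`poolrap` provides both halves of the computational argument:

1. a **neutral simulator** that quantifies how much allele-frequency
   change (AFC) drift alone produces in a panel of isofemale lines, and
   how much apparent AFC the Pool-Seq read-sampling step adds on top; and
2. a **differentiation pipeline** that takes pooled allele counts for
   AP and RAP replicates (sync format), applies SNP-calling filters,
   equalizes coverage by subsampling, and tests every SNP with a
   replicate-stratified Cochran–Mantel–Haenszel (CMH) test under
   Benjamini–Hochberg FDR control.

A synthetic-data generator ties the two together so that the whole
pipeline can be exercised, end to end, with no external data.

## The neutral drift model

Each isofemale line descends from a cross between two individuals drawn
from a parental population in Hardy–Weinberg equilibrium, so a line
carries **4 founder chromosomes** per locus. For a SNP with parental
focal-allele frequency $p$:

* **Founding.** Two genotypes are drawn per line from the trinomial HWE
  distribution $(p^2, 2pq, q^2)$ (contributing 2, 1 or 0 focal copies
  each) and summed, giving a copy number $k \in \{0,\dots,4\}$. The sum
  of the two trinomial draws is exactly $\mathrm{Binomial}(4, p)$; the
  test suite verifies this equivalence against the binomial pmf by
  goodness of fit.
* **Fixation.** Lines are maintained at small census size for tens of
  generations, long enough that within-line polymorphism is lost. Under
  neutrality a line with $k$ copies fixes the focal allele with
  probability $k/4$; `simulate_fixation()` applies this single-step
  resolution directly rather than iterating generations (a
  generation-wise Wright–Fisher mode is a non-goal — with ≥ 50
  generations at tiny size, essentially every line reaches fixation and
  the endpoint distribution is the same).
* **AFC.** With $n$ lines, the panel-wide initial frequency is
  $f_0 = \frac{1}{4n}\sum_i k_i$ and the final frequency is the fraction
  of lines fixed for the focal allele. Fixation is a martingale step
  ($E[f_1 \mid \text{panel}] = f_0$), and the AFC variance has the
  closed form
  $$\operatorname{Var}(f_1 - f_0) = \frac{3}{4}\,\frac{p(1-p)}{n},$$
  since $E[(k/4)(1-k/4)] = \tfrac34 p(1-p)$ for
  $k \sim \mathrm{Binomial}(4,p)$ — an identity the tests first verify by
  exhaustive enumeration over $k$ and then by simulation.

**Pool-Seq noise** is modelled as one extra round of binomial sampling:
for each SNP a sequencing depth $c$ is drawn (from a constant or an
empirical per-site coverage distribution) and the observed count is
$\mathrm{Binomial}(c, f)$. The pool is treated as effectively infinite:
with hundreds of pooled females, read sampling — not the finite number of
chromosomes in the pool — dominates the noise, so no intermediate
hypergeometric stage is modelled. Coverage draws are independent across
SNPs and between the initial and final sampling rounds. SNPs are
independent throughout; linkage is not modelled.

### The parental spectrum and its calibration

The parental allele-frequency spectrum is exponential, truncated to
$(0, 0.5]$ so the focal allele is the parental minor allele. The
exponential **rate** is a free parameter of the model: it controls how
rare typical variants are and thereby the typical drift AFC, via the
scaling $\text{median}\,|{\rm AFC}| \approx 0.6745\sqrt{\tfrac34 p(1-p)/n}$
for given $p$. We calibrated the default against that closed-form oracle
(and its direct simulation) for a 202-line panel and froze **rate = 15**.
A noteworthy numerical feature: with 202 lines the AFC lives on a lattice
with spacing $1/808$, so the median snaps to lattice points — rates
between roughly 13 and 17 all give a median drift $|{\rm AFC}|$ of
$6/808 \approx 0.0074$, making the calibration insensitive to the exact
rate. Both rate and truncation are exposed in every simulation entry
point.

```{r drift, eval = FALSE}
sim <- simulate_drift(5e5, n_lines = 202, seed = 1)
median(sim$afc_abs)   # ~0.0074: drift alone moves frequencies very little
summarize_afc(simulate_drift(1e5, coverage = 40, seed = 1))
```

At 40× coverage the observed median $|{\rm AFC}|$ is roughly three times
the drift-only value: most of the apparent frequency change in a
realistic AP/RAP comparison is sequencing noise, not evolution. The
inflation shrinks as coverage grows (`poolseq_sample()` across 30×, 60×,
120×, 500× shows the monotone decline; note that observed-AFC medians are
themselves lattice-valued in multiples of $1/c$, so adjacent coverages
can tie on the median even though the mean declines strictly).

## The differentiation pipeline

The pipeline consumes PoPoolation-style **sync** files (tab-separated;
per-population `A:T:C:G:N:del` count fields; 1-based positions) and
mirrors the standard Pool-Seq workflow:

1. **Masking** (`apply_mask()`): repeat/indel masks are BED-style 0-based
   half-open intervals; a site at 1-based position $p$ is masked iff
   $s \le p-1 < e$. The off-by-one between the two conventions is
   explicit and tested. Mask construction is out of scope.
2. **SNP calling** (`call_snps()`): a site is kept iff every population's
   A+T+C+G coverage lies in $[30, 500]$ (defaults; N/del are not alleles
   and never count toward coverage), the minor allele — identified from
   counts pooled across **all** populations, ties broken A<C<G<T —
   reaches a summed count of 8, and no third allele does (strictly
   biallelic pipeline; near-triallelic sites are dropped and logged,
   since the CMH stage is defined on 2×2 tables). The pooled
   interpretation of the minimum count matches the established min-count
   semantics of Pool-Seq SNP callers and its purpose of filtering
   sequencing errors.
3. **Subsampling** (`subsample_calls()`): per population and site, the
   major/minor counts are reduced **without replacement** (a multivariate
   hypergeometric draw) to a common target coverage — 30× here, set by
   the lowest-coverage population — so that no population contributes
   more read information than another. Draws are taken in canonical
   (chrom, pos, population) order from a single seeded stream, making
   results reproducible and independent of row order.
4. **CMH testing** (`cmh_test()`): each SNP contributes K strata, one per
   replicate (AP, RAP) pair — here (AP1, RAP1) and (AP2, RAP2) — and the
   1-df CMH chi-square combines them. Strata with $n_k \le 1$ or a zero
   margin are uninformative and skipped; SNPs where every stratum is
   uninformative are reported with $p = 1$ (not dropped) so SNP sets stay
   comparable between analyses. The continuity correction defaults on,
   matching `stats::mantelhaen.test`; both modes are exposed since
   standard Pool-Seq CMH implementations differ here. The statistic is
   computed vectorised over all SNPs and is verified against both an
   independent scalar implementation of the closed form and
   `stats::mantelhaen.test` to 1e-10.
5. **Dual-mapper intersection** (`merge_dual_mappers()`): mapping
   artifacts can masquerade as frequency change, so the analysis can be
   run on alignments from two mappers; only SNPs found by both are kept,
   each with its larger (more conservative) p-value. In this package the
   "two mappers" are simply two pipeline inputs keyed by (chrom, pos).
6. **FDR control** (`bh_adjust()`, via `stats::p.adjust`): SNP-wise
   Benjamini–Hochberg; significance is strict, $q < 0.01$. An optional
   pooled-MAF ≥ 0.2 pre-filter (`maf_filter()`, MAF pooled over all four
   populations after subsampling — the replicate-symmetric choice)
   re-runs BH on the retained subset as a sensitivity check.

```{r pipeline, eval = FALSE}
exp <- generate_experiment(experiment_config(n_snps = 1e5, seed = 1))
fit <- run_pipeline(exp$sync, filter = filter_config(target_coverage = 30),
                    seed = 1)
glance(fit)     # n_significant = 0 under the null
autoplot(fit)   # Manhattan plot of -log10 p
```

## What the synthetic generator does and does not emulate

`generate_experiment()` builds a complete 4-population experiment from
one line panel per SNP: AP1 and AP2 are replicate pools of the **same**
founder lines (they share the true $f_0$), and RAP1 and RAP2 are both
assembled from the same lines after **one** fixation realization (they
share $f_1$). Sharing line-level truth across replicates is what makes
the CMH strata consistent, exactly as pooling the same physical lines
does in the real design; only sequencing (coverage draw, binomial reads,
optional uniform base mis-reads at rate ε < 0.01) is independent across
the four pools. The 5-females-vs-1-female-per-line difference between AP
and RAP pools changes pool size, not expected frequency, and pool-size
effects are subsumed by the binomial read model. Synthetic coordinates
are drawn without replacement per chromosome on a six-arm Drosophila-like
scaffold and sorted. A `spike_selection()` hook shifts a chosen fraction
of SNPs' final frequencies to support power analyses.

Passing tests on these data therefore demonstrate the statistical
machinery under binomial sequencing noise and shared-line truth; they do
**not** probe real-data complications the generator deliberately omits:
mapping bias (represented only by the intersection contract), linkage
between SNPs, base-quality errors beyond the uniform mis-read model,
coverage autocorrelation along the genome, or residual within-line
heterozygosity in the RAPs.

## Numerical choices and degenerate inputs

* All randomness flows from explicit seeds (`withr::with_seed`); the same
  seed gives bit-identical output, and per-stage seeds in `run_pipeline()`
  are derived from the master seed. Unseeded calls use the session RNG.
* Large simulations are processed in chunks of 50,000 SNPs (the
  `chunk_size` argument), bounding memory at roughly
  `chunk_size × n_lines` integers; results depend on `chunk_size` only
  through the RNG stream layout.
* CMH margin products are computed in double precision — at 500×
  coverage they overflow 32-bit integers.
* Under the null the CMH p-value distribution is only approximately
  uniform at low coverage: read counts are discrete, and the measured
  Kolmogorov–Smirnov distance from uniformity shrinks from ≈ 0.09 at 30×
  to ≈ 0.01 at 1000× (uncorrected statistic). This conservatism is a
  property of the test on discrete tables, not an implementation
  artifact, and it works in the direction of fewer false positives.
* Empty masks, empty call sets, all-uninformative SNPs and
  already-at-target subsampling are all exercised identity/contract
  cases, not errors; genuinely impossible requests (subsampling more
  reads than exist, invalid configs) fail fast with named keys.
* `subsample_calls()` drops the (rare) sites where a third allele
  absorbed enough coverage that major+minor falls below the target, and
  reports how many.

## Problem sizes used in the shipped analyses

The package's own acceptance analyses run at desk scale, chosen so the
whole suite completes in minutes on a laptop: 5×10⁵ SNPs for the drift
median (the lattice argument above makes this statistically equivalent
to much larger runs), 10⁵-SNP experiments (×20 seeds) for the null
pipeline, and 10⁶ draws for the fixation and founding checks. All sizes
are arguments, so full-scale runs (e.g. 5×10⁶ SNPs) are one parameter
away.

## Known limitations

* The exponential-spectrum rate is a modelling choice calibrated to a
  202-line panel; analyses of panels with very different line numbers or
  source populations should re-examine it.
* The CMH test assumes independent strata and a common odds ratio; it is
  defined here only for biallelic SNPs and K replicate pairs.
* BH control is nominal under independence; under positive dependence it
  remains conservative, but no dependence-adjusted variant is provided.
* No selection, mutation, migration or linkage inside the simulator; the
  spike mechanism shifts truth frequencies directly rather than modelling
  a selective trajectory.
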