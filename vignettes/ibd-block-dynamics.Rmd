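---
title: "Simulating and estimating IBD block-length dynamics"
author: "ibdblocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and estimating IBD block-length dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibdblocks)
```

## The model

`ibdblocks` simulates, forward in time, the identity-by-descent (IBD)
structure of chromosomes in the simplest population model in which
junction dynamics are non-trivial:

* a constant number N of diploid, monoecious individuals;
* panmictic random mating **without selfing**: each offspring draws an
  ordered pair of two *distinct* parents uniformly at random, independently
  across offspring (so family sizes are multinomial, the standard
  Wright–Fisher scheme adapted to exclude selfing);
* drift is the only evolutionary force — no mutation, selection, migration
  or population-size change;
* founders are unrelated and non-inbred: each of the 2N founder chromosome
  copies carries its own origin label, so generation 0 contains no IBD at
  all and, because the two parents of any offspring are distinct, neither
  does generation 1 (an exact identity the tests rely on);
* one chromosome per genome, modelled as a **continuum** on [0, l] Morgan.

Meiosis follows the Haldane no-interference model: the crossover count per
gamete is Poisson with mean l and positions are i.i.d. uniform on (0, l).
Measuring positions in Morgan makes this equivalent to any map with varying
local recombination rate, which is why no rate-variation option exists.

A chromosome is stored as a `Mosaic`: breakpoints plus one founder-origin
label per segment. A crossover falling between two tracts of identical
origin is invisible — the spliced gamete is re-normalized so that adjacent
segments always differ in origin, and stored breakpoints are exactly the
chromosome's junctions.

## Block definitions

For a homologous pair (by default the two homologues within one individual
— homozygosity by descent), project onto the pair's IBD axis whether the
two origins agree at each position:

* a **relaxed IBD block** is a maximal tract that is IBD at every position,
  the shared origin being free to change along it;
* a **strict IBD block** additionally keeps the same origin throughout, so
  it contains no junction; strict blocks partition the relaxed blocks;
* a junction is **external** when it delimits an IBD and a non-IBD tract,
  **internal** when it falls inside one.

All downstream theory uses relaxed blocks. Per individual the package
records d (total relaxed-IBD length), k (block count), h = 1 − d/l,
z (external-junction count, one per carrying homologue) and the number of
chromosome tips inside an IBD tract. Every individual satisfies the edge
identity 2k = z + tips: each block has two edges, and each edge is an
external junction or an IBD tip. The engine computes z by classifying
actual breakpoints rather than from the identity, so the identity is a
genuine invariant check of the implementation (and of the measure-zero
argument below).

## Estimators and theory

Three mean block-length measures for a dataset of R replicates at one
generation:

* `lengthAR(x, t)` = Σ block lengths / Σ block counts, pooled — the mean
  of a block drawn uniformly from the whole dataset;
* `lengthPW(x, t)` = mean over replicates of the within-replicate ratio —
  a block drawn from a randomly drawn population;
* `lengthIW(x, t)` = mean over individuals of the per-individual ratio —
  a block drawn from a randomly drawn individual.

Because populations (individuals) differ in their block counts, the last
two samplings are size-biased relative to the first; the pooled measure is
an asymptotic lower bound of both, which the reference experiment
reproduces.

The pooled measure estimates E(L) = E(D)/E(K). With E(H) the expected
non-IBD proportion and E(Z) the expected external junctions per Morgan,
`expectedD()` returns l(1 − E(H)), `expectedK()` returns
0.5 l E(Z) + (1 − E(H)) (half the expected block edges), `expectedLFinite()`
their ratio, and `expectedLStam()` the stationary infinite-chromosome limit
(1 − E(H))/(0.5 E(Z)), strictly larger whenever E(H) < 1 and E(Z) > 0.
The package deliberately takes E(H) and E(Z) as *inputs* (plug-in
estimates from the simulation via `empiricalMoments()`, or user-supplied
values): closed-form recursions for them under specific models are prior
work outside this package's scope.

## Numerical choices

* **Coordinates and boundaries.** Segments are half-open [a, b) with the
  final segment closed at l. A junction exactly at a relaxed-block boundary
  is external; "inside" means strictly inside. Under this convention
  zero-length blocks cannot arise and extraction is deterministic.
* **Coincident positions.** Two crossovers at the same floating-point
  position, or a crossover exactly on an existing junction, have
  probability zero under the continuous model; exact collisions between
  drawn crossover positions are re-drawn. A junction position carried by
  both homologues (an inherited, shared junction) is projected once onto
  the IBD axis but annotated once per carrier; almost surely its two sides
  agree in IBD status, so it is internal and the edge identity is
  unaffected — the simulation checks, rather than assumes, this.
* **Starting homologue.** A fair, crossover-independent coin per meiosis
  (the standard convention; the pair of products is unaffected).
* **Strict vs relaxed totals.** The two totals are accumulated over
  different partitions, so their equality is asserted to 1e-12 (absolute,
  lengths are O(1) Morgan) rather than bitwise — a real floating-point
  consistency check, not a shared sum.
* **Zero-block units.** In `lengthPW`/`lengthIW`, replicates or individuals
  without blocks contribute an undefined 0/0 term; they are **excluded**
  from the mean (the conditional-sampling reading: a block drawn from a
  randomly drawn unit must exist) and counted in the report. The
  alternative — counting them as 0 — is available via
  `zeroBlockPolicy = "zero"` for sensitivity analysis; the choice matters
  mainly in early generations when blocks are rare.
* **Standard errors.** Between-replicate for `lengthPW`/`lengthIW`;
  nonparametric bootstrap over replicates (`bootstrapSE_AR`) for the pooled
  measure. These exist for test tolerances and error bars, not as
  distributional claims.
* **Reproducibility.** One root seed; per-replicate child seeds are drawn
  once from it (`set.seed(seed); sample.int(2^31 − 2, R)`) and recorded, so
  replicates are independent streams and each can be re-run alone. Engine
  randomness goes through R's RNG.

## The reference experiment and what it shows

`meanLengthCurves()` runs the model at N = 20, l = 1 Morgan and evaluates
all measures plus the prediction each generation. The defaults — 100
generations, 10,000 replicates — are the package's chosen desk-scale study
size: the two headline relations (the pooled measure tracks the
finite-chromosome prediction to well under 2% by generation 10, and stays
at or below the population- and individual-wise measures everywhere) are
stable at this size, while a run completes in about two minutes on one
core. Larger designs (500 generations, 10⁶ replicates) are plain parameter
overrides, not a different code path.

The test suite uses the same conditions: structural identities are checked
exhaustively on a 100-replicate trajectory set (~2·10⁵ individuals), the
crossover model is calibrated on 10⁵ meioses (mean junction count within
1 ± 0.01, zero-class within 3 SE of e⁻¹, χ² goodness of fit vs Poisson(1)
at α = 0.01), and the per-locus non-IBD frequency is validated against an
independent label-only single-locus simulation of the identical mating
scheme — a useful oracle because at a single locus recombination is
irrelevant, so the two implementations share no code path.

## What the generator does and does not emulate

The simulator *is* the model above; passing tests show the extraction and
estimators are exact for it and that the finite-length prediction holds in
it. Real data differ in ways the model excludes by design: crossover
interference (junction counts are under-dispersed in real meioses),
mutation and genotyping error (real IBD is detected through IBS, with
false block breaks and joins), multiple chromosomes, sex-specific maps,
selfing, overlapping generations, demographic change and selection.
E(L) = E(D)/E(K) itself is insensitive to demography and selection — those
enter through E(D) and E(K) — but the simulator's trajectories of E(H) and
E(Z) are specific to the drift-only scheme, including its choice of
sampling parents *with* replacement across offspring (family sizes
multinomial); fixed-family-size schemes decay slightly differently.

## Known limitations

* Only pairs of homologues (n = 2) are analysed; the ratio formula extends
  to n-tuples but no extraction for n > 2 is implemented.
* The theory layer provides no closed forms for E(H) and E(Z) over time —
  by design, see above.
* `pairing = "random-pair"` (chromosomes re-paired across individuals each
  generation) is exposed for exploration but not validated against theory;
  the within-individual pairing is the supported, tested mode.
* Distributions (beyond means and Monte-Carlo SEs) of the population- and
  individual-wise measures are not provided; only the pooled measure has a
  closed-form target.
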