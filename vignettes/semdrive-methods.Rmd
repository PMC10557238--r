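---
title: "Modeling small-molecule-inducible self-eliminating gene drives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling small-molecule-inducible self-eliminating gene drives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semdrive)
```

## The system being modeled

A CRISPR homing gene drive biases its own inheritance: in a drive/wild-type
heterozygote the drive's endonuclease cleaves the homologous wild-type
allele, and homologous-recombination (HR) repair copies the drive in its
place, pushing transmission above the Mendelian 50%. A *self-eliminating
mechanism* (SEM) makes such a drive biodegradable: a second, highly
site-specific endonuclease is encoded inside the construct together with
its own target site, flanked by direct repeats. When that endonuclease is
activated — here, by an externally applied small molecule ("spraying") —
it cuts the construct, and single-strand annealing (SSA) between the
direct repeats excises the transgene, leaving behind a *cut-resistant*
wild-type allele that the drive can no longer home against. The intended
trajectory is: release, super-Mendelian spread, spray, excision, and
restoration of a (cut-resistant) wild-type population.

`semdrive` simulates this programme end to end for a single panmictic
mosquito population: inheritance cubes for five SEM designs, a
stage-structured lifecycle expressed as a stochastic Petri net (SPN),
stochastic and deterministic samplers with first-order sparsity-aware
hazard evaluation, timed release and spray events, and ensemble summaries
in a long, plot-ready format.

## Alleles and designs

At the drive locus the model distinguishes:

* `W` — susceptible wild-type;
* `G` — intact drive construct: homing-active and SEM-capable;
* `H` — construct whose secondary endonuclease has been activated; a
  transient state that resolves during the next gametogenesis;
* `V` — excised cut-resistant wild-type, the intended end product;
* `S` — construct whose SEM target site was disrupted by NHEJ
  (excision-immune but still homing-active); only present when
  `sem_resistance = TRUE`;
* `R`, `B` — in-frame and out-of-frame drive-resistant NHEJ products
  (REDUCED carries `R`; COMPLETE carries both);
* `B0` — the unviable NHEJ product of the SIMPLIFIED flavor. It is kept as
  an explicit token in gametes and offspring genotypes with viability 0,
  rather than renormalizing gamete distributions, so that probability mass
  is conserved and testable end to end. Carriers are removed at the egg
  stage.

Five designs place the construct and, for trans-acting variants, a
separate SEM-element locus (`E`/`w`, inherited Mendelianly) on autosomes
or the X chromosome: `CIS_AUTO`, `CIS_X`, `TRANS_AUTO_AUTO`,
`TRANS_AUTO_X`, `TRANS_X_AUTO`. X-linked loci are hemizygous in males
(label suffix `Y`); offspring sex then follows the sex chromosomes, and
for all-autosomal designs sex is assigned at adult emergence with
probability `phi`.

## Gametogenesis model

For each parent, gamete formation is serialized as:

1. **Homing.** Each `W` opposite an active drive allele (`G`, `H`, or `S`)
   is cleaved with probability $p$; a cleaved allele is converted by HR
   with probability $q$, else the NHEJ branch yields the flavor's
   resistance product ($R$ with probability $\rho$, $B$ otherwise, for
   COMPLETE; $R$ for REDUCED; lethal `B0` for SIMPLIFIED). `V`, `R`, `B`,
   and `S` are never cleaved. Hemizygous X-linked males have no homolog,
   so no homing occurs in them.
2. **Meiosis.** One allele per locus, uniformly; loci assort
   independently.
3. **SEM activation.** Each `G` in the gamete pool becomes `H` with
   probability $a$ while the molecule is present.
4. **SEM resolution.** Each *parental* `H` resolves: SSA with probability
   $b$, yielding `V` with probability $c$ and susceptible `W` otherwise;
   the NHEJ branch ($1-b$) yields `S` when `sem_resistance = TRUE` and
   otherwise leaves `H` to be re-resolved next generation (this keeps mass
   conserved without enlarging the alphabet). An `H` newly created in
   step 3 is not re-resolved in the same gametogenesis.

Two modeling choices here were genuinely open and are worth stating:

* **What HR copies.** When the homing template is `H`, conversion yields
  `G`, not `H`: activation of the secondary endonuclease is a
  protein-level state, not a heritable DNA difference. When the template
  is `S`, conversion yields `S`, since the disrupted SEM target site *is*
  a DNA lesion. `H` and `S` home like `G` because the drive cassette is
  intact until excision completes.
* **Which alleles released males carry.** Released "SEM-homozygous" males
  are `GG` (intact construct; the molecule is absent at release time).
  This is configurable.

With `inducible_drive = TRUE` homing requires the molecule ($p$ treated as
0 otherwise); with `inducible_sem = TRUE` (the canonical configuration)
steps 3–4 are skipped entirely without the molecule. For trans-acting
designs, both steps additionally require at least one copy of the element
`E` in the parent.

The inheritance cube is the outer product of the parents' final gamete
distributions, marginalized onto canonical offspring genotypes. Note that
the Mendelian limit ($p = 0$, $a = 0$ gives exactly the Mendelian cube)
refers to the *uninduced* construct: with an always-on SEM and $b > 0$,
parental `H` alleles resolve even when $a = 0$.

## Lifecycle and equilibrium

The lifecycle is the standard egg → larva → pupa → adult chain with
Erlang-distributed aquatic dwell times (sub-stage chains of shape
`n_E`, `n_L`, `n_P`), density-dependent larval mortality
$\mu_L (1 + N_L/K)$, near-instant mating, and mated females that store
their mate's genotype (no remating). Defaults are Aedes/Anopheles-scale
values: `beta = 32` eggs/female/day, `t_E = 1`, `t_L = 14`, `t_P = 1`
days with 2 sub-stages each, adult mortality `0.123`/day (about an 8-day
life expectancy), `nu = 1`/day, `phi = 0.5`, and baseline larval mortality
`mu_L = 0.3`/day. The unmated-female pool is a transient mating
compartment: with `nu = 1`/day females mate within about a day of
emergence, and adult female mortality acts on the mated compartment. This
keeps the single-genotype model at exactly ten transitions (oviposition,
three advances, three aquatic deaths, mating, two adult deaths).

Because the adult loop must balance at equilibrium, the larval survival
required at equilibrium is fixed by the non-larval parameters alone:

$$\beta\, s_E\, s_L\, s_P\, \phi = \mu_F,$$

where $s_X$ are Erlang-chain stage survivals. This gives the equilibrium
per-capita larval death rate in closed form, and from it every stage
occupancy and the density parameter $K$ that realizes a requested adult
total (`solve_carrying_capacity()`). No root-finding is involved, and
`equilibrium_state(round = FALSE)` is an exact fixed point of the
mean-field equations. For X-linked designs the cube itself forces a 1/2
sex split at oviposition, so the closed form assumes `phi = 0.5` there.

## Samplers and numerical choices

The SPN is simulated by three interchangeable samplers sharing one hazard
evaluation:

* **Gillespie direct method** — exact; used for small-population
  validation (e.g. the pure-death chain, whose mean extinction time
  $\sum_{k=1}^{n} 1/(\mu k)$ the test suite reproduces).
* **Poisson tau-leaping** (default) — each transition fires
  $\mathrm{Poisson}(h\,\Delta t)$ times; removals are truncated at the
  tokens available at group entry and applied in a fixed group order
  (oviposition, advances, emergence, deaths, larval deaths, mating), so
  the update is deterministic given the RNG stream and counts never go
  negative.
* **Mean-field** — classical RK4 on the expected flows, with cube rows
  entering as expected offspring kernels; used for equilibria and as the
  reference in sampler-agreement checks.

**Step size.** The stiffest hazards in the default lifecycle are the
egg/pupal advances (2/day) and the equilibrium larval death rate
(~1.5/day). A leap of 1 day violates the tau-leaping validity condition
for these hazards and produces period-two oscillation in the aquatic
stages; the default is therefore `dt = 0.25` day, which keeps
$h\,\Delta t \le 0.5$ everywhere and matches the mean-field trajectory to
within Monte-Carlo error in the test suite. The recording grid stays at 1
day.

**Sparsity.** Every transition has exactly one input place, so the
first-order sparsity rule is exact here: if the first input place is
empty the transition is disabled and its hazard is zero by the SPN
enabling rule. In sparse mode the hazard function is simply not evaluated
for such transitions (a skip counter tracks this); dense and sparse modes
return identical hazard vectors and, with the same seed, bit-identical
trajectories, because randomness consumption does not depend on skipping.
In the canonical scenario most genotype places are empty, and about 94%
of hazard evaluations are skipped. No wall-clock claim is attached to
this — the test surface asserts skip counts and equivalence instead.

**RNG.** One seed per repetition (`seed + rep - 1`), so ensembles are
reproducible and any single repetition can be re-run in isolation.

## Events

Releases add their token count to the adult male (or unmated female)
place of the released genotype exactly at the release time. Daily
small-molecule spraying over a window is approximated as sustained
induction: a global binary molecule state is on inside each
`spray_window(start, end)` and selects the induced inheritance kernel at
oviposition. Windows may not overlap.

## The canonical scenario

`preset_fig2d()` encodes the demonstration study: a `CIS_AUTO`,
SIMPLIFIED-flavor, SEM-inducible drive with cleavage $p = 0.5$ and HR
$q = 1$ (no resistance alleles), SEM cleavage $a = 0.5$ with perfect SSA
repair to `V` ($b = c = 1$); a 2000-adult equilibrium population; four
weekly releases of 100 `GG` males starting at day 91 (~3 months); a spray
window over days [365, 547) (~6 months starting at the 1-year mark); a
730-day horizon; tau-leaping with `dt = 0.25`; 100 repetitions by default
(tests and the acceptance script use 20 to stay within a desk-scale
compute budget). The expected behavior — drive exceeding half of all
adult alleles before spraying, a transient `H` pulse during the window,
monotone accumulation of `V`, and collapse of the drive below 5% with
`W + V` approaching 1 by day 730 — is asserted quantitatively in
`tests/testthat/test-acceptance.R` and recomputed by
`scripts/acceptance.R`.

## Analysis conventions

Allele accounting counts adults only, each contributing its somatic
genotype once: stored mate genotypes and aquatic stages are excluded by
default (both toggleable), matching what an adult field survey would see,
and `Y` placeholders are never counted. Proportions divide by the total
number of counted alleles over the full alphabet for the selected sex
set. "95% quantiles" are the central empirical interval: 2.5% and 97.5%
order statistics with linear interpolation (R's default type 7).
Summaries are emitted as long tables (`time, sex, feature, stat, value`)
so that a ggplot2 call like
`ggplot(tab, aes(time, value, colour = feature)) + facet_wrap(~stat)`
works directly.

## What the synthetic conditions do and do not show

The generator's defaults *are* the study conditions: a closed, well-mixed
population at demographic equilibrium, neutral fitness for all transgenic
alleles, a binary global molecule state, and no seasonality, migration,
maternal nuclease deposition, or epidemiological layer. Passing tests
therefore demonstrate the internal consistency of the inheritance model,
the samplers, and the analysis chain under those idealized conditions —
not field performance. Fitness costs are exposed as hooks (viability
multipliers in the cube) but default to 1; the COMPLETE flavor's broken
allele `B` is likewise viability-neutral by default.

## Known limitations

* Remating, sperm storage, and maternal effects are not modeled.
* The molecule state is global and binary; pharmacokinetics of the small
  molecule are folded into the per-gametogenesis probability $a$.
* Trans-acting SEM elements are inherited Mendelianly and are not
  themselves drivable.
* Erlang shapes are fixed per stage; temperature- or rainfall-driven
  time-varying rates are out of scope.
* The tau-leap uses fixed steps; there is no adaptive step selection, so
  users who change lifecycle rates should keep the fastest per-capita
  hazard times `dt` well below 1.
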