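---
title: "Simulating genome evolution in haplodiploid populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating genome evolution in haplodiploid populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

About 15% of animal species — ants, bees, wasps, thrips, bark beetles —
are haplodiploid: unfertilized eggs develop into haploid males, fertilized
eggs into diploid females.  A male transmits his single genome clonally to
his daughters and has no sons; a female transmits a recombined gamete to
every offspring.  Because a haploid male expresses every allele he carries,
recessive mutations that are hidden in diploid heterozygotes are fully
visible to selection in half the haplodiploid population.  `haplodrift`
simulates this inheritance system forward in time, individual by individual,
next to a matched diploid model with the identical reproduction scheme, so
that the fates of neutral, advantageous and deleterious mutations can be
compared between the two systems.

An individual is two genome slots; a haplodiploid male's second slot is an
empty *null genome*.  A genome is a sparse set of mutation identifiers over
`L` discrete loci (positions `0 .. L-1`).  Each generation (non-overlapping):

1. **Fitness.** Each mutation contributes a multiplicative factor:
   `1 + s` in homozygotes, `1 + s*h` in heterozygotes, and
   `1 + s*h_haploid` in hemizygous males.  The haploid dominance coefficient
   `h_haploid` is 1 in all standard treatments, so a male carrier has
   fitness `1 + s` regardless of `h`.  A mutation-free individual has
   fitness exactly 1.
2. **Parentage.** For each of exactly `Nf` daughters and `Nm` sons, a mother
   is drawn from the females with probability proportional to fitness, with
   replacement, and independently a father from the males (sons have no
   father in haplodiploid mode).  Fitness therefore acts as reproduction
   success; selection is soft and the census is hard-fixed.
3. **Meiosis.** A maternal gamete receives `Poisson(r*(L-1))` crossover
   breakpoints at distinct uniform positions in `[1, L)`, alternating
   strands across half-open segments starting from a uniformly chosen
   strand.  Haploid fathers transmit a clonal copy of their single genome.
   Every transmitted gamete then receives `Poisson(mu*L)` de novo mutations
   at uniform positions; each event is a fresh record with its own
   identifier (two records may share a position; homozygosity is per
   identifier, never per position).
4. **Bookkeeping.** A mutation present in every non-null genome copy is
   fixed: it is logged with its fixation generation and purged (purging
   multiplies all fitnesses within a sex by a common factor, so the
   fitness-proportional sampling is unaffected).  Mutations with zero
   copies are purged silently.

With a 1:1 sex ratio, a haplodiploid population of `2N` individuals carries
`3N` genome copies against `4N` in the diploid population — `1.5N` vs `2N`
per the usual accounting — so `1.5N mu L` vs `2N mu L` new mutations enter
per generation.  Neutral theory then predicts identical substitution rates
`mu*L` in both systems (influx times fixation probability `1/copies`),
which the package reproduces and tests.

## Parameters and defaults

| parameter | meaning | default |
|---|---|---|
| `Nm`, `Nf` | males / females in the fixed census | 1000 / 1000 |
| `L` | genome length (loci) | 1e6 |
| `mu` | mutation rate per locus per generation | 1e-8 |
| `r` | recombination rate per adjacent locus pair | 1e-6 |
| `s` | selection coefficient of the run's mutation type | 0 |
| `h` | dominance coefficient in diploid genotypes | 0 |
| `h_haploid` | dominance in hemizygous males | 1 |
| `burn_in` | generations before the recorded window | 15000 |
| `run_generations` | recorded generations | 35000 |

The defaults are the standard study conditions for the full-scale treatment
comparisons.  With these values each gamete carries 0.01 expected new
mutations and one expected crossover, so genomes stay sparse.  The burn-in
matters because the two population types have different effective sizes and
reach mutation–drift balance at different times; a fixation is attributed
to the generation in which the copy count first reaches the census, so
mutations arising during the burn-in but fixing later count in the recorded
window.

Populations are initialized mutation-free.  The simulator *is* the data
generator: no empirical data enter anywhere, and what passing tests show is
internal consistency of the model plus agreement with exact single-locus
theory — not correspondence with any real genome, which would additionally
involve variable recombination and mutation landscapes, demography,
selective interference among mutation types, and non-equilibrium histories.

## Implementation and numerical choices

Two implementations of the identical lifecycle ship in the package.
`hd_next_generation()` is a plain-R reference written directly over the
exported meiosis/fitness operations; it is the executable definition and is
exercised at small sizes in the tests.  `hd_simulate()` defaults to a
compiled engine that represents genomes as bitsets over the segregating
mutations (position-sorted backbone plus a small unsorted tail of recent
mutations, compacted periodically) so that crossover segments become
word-range copies and fitness reduces to population counts.  The two
engines draw random numbers in different orders and therefore agree in
distribution, not draw for draw; both are bit-reproducible given
`(config, seed)`.  The compiled engine requires `s > -1` (log-scale fitness
weights); the fitness functions themselves implement the clamp-at-zero rule
for pathological `s <= -1`.  Mean fitness per sex is reported excluding
fixed mutations.

Other choices made where the design was genuinely open, all documented
here as the package's own decisions:

* **Mating scheme.** Independent fitness-proportional draws with
  replacement per offspring (promiscuity), the Wright–Fisher-equivalent
  choice for a reproduction-success model.  No brood structure, no
  monogamy.
* **Sex ratio.** Deterministic: exactly `Nm` sons and `Nf` daughters each
  generation, minimizing variance around the stated census.
* **Crossovers.** Poisson count, uniform distinct breakpoints, no
  interference — the standard flat map implied by a single rate `r`.
  A mutation exactly at a breakpoint belongs to the right-hand segment
  (half-open segments).
* **Paternal gametes.** Haploid fathers do not recombine (recombining with
  a null genome is undefined); their clonal copies, like all transmitted
  gametes, are subject to de novo mutation.
* **Ties and ordering.** Genomes are sorted by `(position, id)`;
  registry identifiers are assigned sequentially from 1 in creation order.

## The exact oracle

For small censuses the package builds the exact one-generation Markov chain
of a single mutation under either inheritance system
(`hd_markov_chain()`).  Allele counts alone are not Markov — the split of
female copies between heterozygotes and homozygotes changes the
fitness-weighted transmission probability — so the chain state is
genotype-resolved: female genotype counts plus male carrier counts
(haplodiploid) or male genotype counts (diploid).  Given the two
transmission probabilities, offspring genotype counts are multinomial, which
makes the transition exact for the simulator's own mating scheme; any change
to the lifecycle's parent-sampling decision must be mirrored in the chain —
that coupling is the point of the oracle.  Fixation probabilities come from
a dense linear solve of the transient system; rows of the transition matrix
sum to 1 within 1e-12 and the solve is checked against the closed form
`1/(3N)` (haplodiploid, one neutral copy, either placement) and `1/(4N)`
(diploid) to 1e-10.  The test suite also runs 20,000 single-locus engine
replicates per point of the grid `s ∈ {0, ±0.05} × h ∈ {0, 1} × mode` at
`Nm = Nf = 3` and requires the empirical fixation frequency to fall inside
the exact value's central 99% binomial band.

## Validation scales

The default test suite uses desk-scale problem sizes, chosen once and stated
here: neutral substitution runs at `Nm = Nf = 50` for 5,000 + 20,000
generations (expected 200 fixations, accepted within 3 Poisson standard
deviations); oracle-agreement grids as above; and population-type
comparisons at `Nm = Nf = 100`, `mu = 1e-6`, 2,000 + 8,000 generations with
20 replicates per arm for the recessive (`h = 0`) comparison and 6 per arm
for the dominant (`h = 1`) comparison.  The full-scale design (200
replicates of 1,000 + 1,000 individuals for 15,000 + 35,000 generations) is
available behind `hd_preset("figure1_full")` and an explicit
acknowledgement flag, as it represents days of compute on one core.

## A caution about raising the mutation rate

The scaled comparisons raise `mu` from 1e-8 to 1e-6 so that fixation counts
are informative at a small census.  That change is not neutral to the
biology: at `mu = 1e-6` several hundred new mutations enter per generation
and thousands segregate simultaneously, so linked selection (clonal
interference) dominates, whereas at the full-scale parameters fewer than
0.05 mutations enter per generation and sites evolve essentially
independently.  For fully recessive advantageous mutations the haplodiploid
advantage survives interference and the scaled comparison reproduces it
(the suite asserts it at p < 0.01).  For fully dominant advantageous
mutations the classical expectation — fewer fixations in haplodiploids
because of the 1.5N vs 2N influx, an expectation the package's own
single-locus probabilities confirm (haplodiploid:diploid rate ratio 0.83 at
`s = 0.01`, `h = 1`, `Nm = Nf = 100`) — is *inverted* in the scaled
full-genome runs: under heavy interference, the clonal transmission of
entire paternal genomes amplifies high-fitness multi-mutation haplotypes
intact, and haplodiploid populations fix substantially more dominant
beneficial mutations than diploid ones.  Both engines reproduce this
independently.  The corresponding suite assertion, which encodes the
classical direction at the scaled parameters, is expected to fail and is
kept as an honest record of this regime change; conclusions about dominant
mutations should be drawn at realistic mutation influx only.

## Known limitations

Single linear chromosome, one mutation type per run, no epistasis, no
recombination-rate or mutation-rate maps, no gene conversion or crossover
interference, no demography (constant census, no migration or structure),
no selfing or mate-choice models, and no tree-sequence recording.  The VCF
export uses placeholder alleles (`A`/`T`) since the model tracks mutation
identities, not nucleotides.
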