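# haplodrift

Individual-based forward-time simulation of genome evolution in
**haplodiploid** populations — ants, bees, wasps and other taxa in which
haploid males develop from unfertilized eggs and diploid females from
fertilized eggs — alongside a matched **diploid** model with the identical
reproduction scheme.

In a haplodiploid population a male carries one genome (his second genome
slot is an empty "null" genome), inherits it as a recombined gamete from
his mother, and passes a clonal copy to every daughter.  A hemizygous male
carrier of a mutation with selection coefficient *s* has relative fitness
1 + *s* (haploid dominance coefficient 1), while diploid genotypes have
fitnesses 1, 1 + *sh*, 1 + *s*.  Fitness acts as reproduction success
across non-overlapping generations with a hard-fixed census of *N*♂ + *N*♀,
so the model behaves like a Wright–Fisher model with soft selection.  The
key structural contrast with an equal-census diploid population is
chromosome accounting: 1.5*N* vs 2*N* genome copies at a 1:1 sex ratio,
hence 1.5*Nμ* vs 2*Nμ* mutations entering per genome-length unit per
generation, while recessive mutations are fully exposed to selection in
haploid males but masked in diploid heterozygotes.

The package provides:

* `hd_config()` / `hd_simulate()` — single runs (compiled bitset engine,
  plus a pure-R reference implementation of the same lifecycle);
* `hd_next_generation()`, `hd_recombine()`, `hd_individual_fitness()`, … —
  the exported building blocks of the lifecycle;
* `hd_markov_chain()` / `hd_fixation_probability()` — an exact single-locus
  Markov chain for small censuses, the validation oracle for the simulator;
* `hd_treatment_grid()` / `hd_run_grid()` / `hd_compare()` — replicated
  treatment grids with Wilcoxon rank-sum comparisons between population
  types (equal-individual or equal-chromosome pairing);
* `hd_export_vcf()` — VCF 4.2 export of segregating variants with haploid
  male genotypes;
* a thin command-line interface in `exec/haplodrift`
  (`simulate`, `grid`, `oracle`, `compare`, `export-vcf`).

## Worked example

A neutral haplodiploid run at a small census (μL = 0.01 new mutations per
gamete), and exact single-copy fixation probabilities at a tiny census:

```r
library(haplodrift)

cfg <- hd_config("haplodiploid", Nm = 50, Nf = 50,
                 burn_in = 2000, run_generations = 10000, seed = 7)
res <- hd_simulate(cfg)
res
#> <hd_result> haplodiploid (cpp engine), 2000 + 10000 generations
#>   recorded window: 84 fixations (0.0084 per generation), 18 segregating at end

hd_oracle_table(3, 3, s_values = c(0, 0.05), h_values = 0)
#>           mode Nm Nf    s h placement fixation_probability
#> 1 haplodiploid  3  3 0.00 0    female           0.11111111
#> 2 haplodiploid  3  3 0.00 0      male           0.11111111
#> 3 haplodiploid  3  3 0.05 0    female           0.12823208
#> 4 haplodiploid  3  3 0.05 0      male           0.13125555
#> 5      diploid  3  3 0.00 0    female           0.08333333
#> 6      diploid  3  3 0.00 0      male           0.08333333
#> 7      diploid  3  3 0.05 0    female           0.09301859
#> 8      diploid  3  3 0.05 0      male           0.09301859
```

The neutral substitution rate matches the theoretical μL = 0.01 per
generation (84 fixations over 10,000 generations is within drift noise).
The oracle table shows the two neutral closed forms — 1/(3·3) = 0.111 for
any single copy in the haplodiploid population and 1/(4·3) = 0.083 in the
diploid one — and the haplodiploid advantage for an advantageous recessive
mutation (0.128 vs 0.093 from a female-genome copy).

The test suite validates the simulator against the exact chain over a grid
of selection and dominance coefficients (20,000 single-locus replicates per
point inside the exact value's 99% binomial band), and runs replicated
scaled treatment comparisons between the population types.  See the
methods vignette (`vignettes/haplodiploid-simulation.Rmd`) for the model,
the design decisions, the validation scales, and an important caution about
linked selection when the mutation rate is scaled up.

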