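# linkbal

Forward-time simulation of two linked balanced polymorphisms with no
epistasis between them.

## The question

A polymorphism maintained by balancing selection survives only if selection
beats drift, which hinges on the product `N_e * s` of effective population
size and selection coefficient. When `N_e * s` is of order 1–10, the fate of
the polymorphism is sensitive to its genomic neighborhood. `linkbal` asks a
sharp version of that question: if two loci are each under *independent*
symmetric overdominance — no fitness interaction whatsoever, the epistasis
residual `a - b - c + d` across genotype classes is exactly zero — does
tight linkage alone make both polymorphisms last longer? The simulations
show it does, strongly, for intermediate selection: two "buddy" loci can
both be retained indefinitely where either alone would drift to fixation.

It is aimed at population geneticists studying balancing selection,
supergenes and the interpretation of clustered selection signals: the
central point is that clustered balanced polymorphisms are *not* evidence of
co-adaptation.

## Model in brief

Wright–Fisher diploid population, `N` individuals (`N_e = 2N`), two
diallelic loci, four gamete haplotypes `AB, Ab, aB, ab`. Per generation the
deterministic selection–recombination recursion

    x_i' = (x_i w_i ∓ r (w_AB,ab x_AB x_ab − w_Ab,aB x_Ab x_aB)) / w̄

is followed by one multinomial draw of `2N` gametes. Fitness is
`1 + s × (number of heterozygous loci)` (additive scheme) or the product of
per-locus factors with a huge dominance coefficient (multiplicative scheme,
`w_het = w(1 + d·s_hom)`). Recombination is parameterized as
`ρ = 4 N_e r`. No mutation: fixation is absorbing, and each replicate
records the fixation generation per locus (censored at the horizon
`G = 50 N_e`) plus which haplotypes survived. An exact Markov-chain oracle
(`N ≤ 4`) validates the stochastic machinery by linear algebra.

## Worked example

Intermediate selection (`N_e s = 10`), moderate linkage (`ρ = 1`):

```r
library(linkbal)
p <- sim_params(additive_scheme(0.005), N = 1000, rho = 1, G = 100000,
                replicates = 200, seed = 11)
summarize_cell(run_cell(p))
#>       s Ne_s rho replicates n_fixed n_similar_two n_opposite_two n_three n_all
#> 1 0.005   10   1        200     138            27              5      20    10
#>   retained_both retained_any   mtf
#> 1            35           62 56325
```

35/200 = 17.5% of replicates kept both loci polymorphic for all 50 `N_e`
generations, and the median locus took ~56,000 generations (28 `N_e`) to
fix. Rerun with `rho = 10` and retention collapses below 1%; with `rho = 0`
it rises above 80% — linkage alone is doing the work. The same comparison at
weak selection (`s = 0.0025`) gives ≤2.5% retention at every `ρ`, and at
strong selection (`s = 0.01`) retention is high at every `ρ`: the
linkage effect peaks where selection and drift are evenly matched.

For a parameter sweep with TSV output and the per-`N_e s` regression table:

```r
g <- grid_spec(s_values = c(0.002, 0.005), rho_values = c(0.01, 0.1, 1, 10),
               replicates = 1000, seed = 1)
run_grid(g, out_dir = "results/")
```

A thin command-line wrapper with the same functionality lives at
`inst/cli/linkbal.R` (subcommands `simulate`, `grid`, `oracle`).

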