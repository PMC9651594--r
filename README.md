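# privgoods

Eco-evolutionary consumer-resource models of partially privatized public
goods in well-mixed microbial communities.

## The problem

Secreted microbial products such as siderophores (iron-scavenging
compounds) and leaked fixed nitrogen are *public consumables*: any cell can
take them up from the shared pool and use them exclusively, drawing the
pool down. In unstructured environments like the surface ocean, producers
cannot shelter behind spatial assortment, so why is costly production not
simply lost to non-producing "cheater" lineages? `privgoods` implements
mechanistic, resource-explicit models of this question, centered on
*privatization*: the producer retains a fraction α of its own product for
private use and leaks the rest.

Two models are provided:

* a **single-resource model** — producer vs. loss-of-function non-producer
  with growth functions `g1(R) = (α − γ) f(R) + U(R)` and `g2(R) = U(R)`,
  where the classic `R*` rule decides competition and the producer wins
  exactly when privatization exceeds production cost (α > γ);
* a **colimitation model** of marine cyanobacteria — four state variables
  (fixed nitrogen `N`, siderophores `S`, strain densities), facultative
  production `f_N = ℓb/(ℓ+N)`, `f_S = mq/(m+S)`, Michaelis–Menten uptake,
  and biochemically dependent colimitation in which siderophore (iron)
  uptake sets the half-saturation of growth on acquired nitrogen:
  `G = r·η/(η + h(S))` with `η = α f_N + U_N` and
  `h(S) = (r/c)(U_S + k_S)/U_S`.

On top of the dynamics the package provides the full analysis tool-chain:
single-strain equilibria, zero net growth isoclines (ZNGIs) with their
asymptotes `S*`/`N*`, supply-point mapping and impact vectors, invasion
analysis and pairwise-competition classification, analytic privatization
bounds `α > γ/𝒮`, seeded random-parameter viability/invasibility screens
over the four strain variants (Full, LOFN, LOFS, LOFB), and adaptive
dynamics (pairwise invasibility plots, ESS location, ZNGI envelopes,
critical N:S supply ratios).

## Worked example

```r
library(privgoods)

pars <- colim_params(b = 1)          # default environment, fixation rate 1
strains <- derive_strains(pars)      # Full, LOFN, LOFS, LOFB variants

# minimum nitrogen requirement of the dual loss-of-function strain
asymptote_nstar(strains$LOFB)
#> [1] 0.34375

# equilibrate a Full-strain monoculture (N0 = S0 = x0 = 0.3, horizon 1e5)
eq <- integrate_to_equilibrium(strains$Full)
eq
#> Equilibrium result [viable_equilibrium] at t = 92.20657
#>   resources: S = 1.582269  N = 1.253506
#>   densities: Full 0.7255493

# a siderophore-loss mutant invades with growth equal to the production cost
invasion_growth_rate(strains$LOFS, eq)
#> [1] 0.2710794
strains$Full$beta * siderophore_production_rate(eq$resources[["S"]], 1.75, 1)
#> [1] 0.2710794

# evolution of the fixation maximum: loss vs. interior optimum
find_ess(colim_params(alpha = 0.5,  gamma = 0.35), "b", n_grid = 11)$regime
#> [1] "loss_of_trait"
find_ess(colim_params(alpha = 0.62, gamma = 0.25), "b", n_grid = 11)$ess_value
#> [1] 0.4834393
```

The invasion growth of the siderophore-loss mutant equals the production
cost `β·f_S(S*)` exactly — siderophores are fully public, so losing
production is always favored; fixation, being partially privatized, can
instead reach a positive evolutionarily stable rate when privatization is
high and cost low.

A small command-line wrapper over the same functions lives at
`inst/cli/privgoods.R`:

```sh
Rscript inst/cli/privgoods.R screen-table --n 2000 --seed 1 --out results/
Rscript inst/cli/privgoods.R ess --trait b --out results/
```

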