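# coevoBC

Coupled eco-evolutionary host–parasitoid dynamics for biological control.

Importation biological control releases a parasitoid against an insect pest
and hopes the suppression lasts. Whether it does can hinge on evolution: a
sexually reproducing pest keeps generating additive genetic variance (AGV)
for resistance, while a thelytokous (clonally reproducing) parasitoid has
essentially none for counter-adaptation. `coevoBC` is built for theoretical
ecologists and biocontrol scientists who want to explore that asymmetry
quantitatively, using two New Zealand pasture systems as the motivating
parameterizations: the Argentine stem weevil *Listronotus bonariensis* with
its asexual parasitoid *Microctonus hyperodae*, and the lucerne weevil
*Sitona discoideus* with the sexual *M. aethiopoides*.

## The model

Discrete, non-overlapping generations. Host density `N` and parasitoid
density `P` follow a Hochberg–Holt-type map,

    N[t+1] = lambda_t * N * g(N) * (alpha + (1 - alpha) * f)
    P[t+1] = c * N * g(N) * (1 - alpha) * (1 - f)

with Beverton–Holt self-limitation `g(N) = 1 / (1 + N (lambda_t - 1) / K)`
and a May-type negative-binomial escape function with egg-limited
saturation,

    f = [1 + a P / (kappa (1 + a N g (1 - alpha) / eta_t))]^(-kappa),

where small `kappa` means aggregated attacks. Each species carries one
quantitative character (host resistance `n`, parasitoid virulence `p`); the
resistant host fraction is `alpha = 1 - exp(-(n - p)^2)`; characters incur
linear costs (`lambda_t = lambda* - C_n n`, `eta_t = eta* - C_p p`) and
evolve by the breeder's-equation recursion

    n[t+1] = n[t] + Gamma_n * d ln(W_n) / d n,

with `Gamma = 0` encoding strict asexuality. A three-species extension
introduces a second parasitoid into an established system mid-run, sharing
the same host resistance character. See the methods vignette
(`vignettes/coevolution-methods.Rmd`) for assumptions, numerical choices
and limitations.

## Worked example

```r
library(coevoBC)

# asexual parasitoid (Gamma_p = 0) against a sexual host (Gamma_n = 0.01)
b <- baseline_params(Gamma_p = 0)
tr <- simulate_coevolution(b$host, b$parasitoid, sim_config(generations = 300))
tr
#> <trajectory> 300 generations, 1 parasitoid
#>   parasitoid_1: persisted, final parasitism 0.054, final resistance 0.917

# how outcomes change with the parasitoid:host AGV ratio
agv_ratio_sweep(c(0, 1, 3, 10))
#>   ratio Gamma_p final_parasitism final_resistance
#> 1     0    0.00           0.0467         9.27e-01
#> 2     1    0.01           0.5011         3.09e-01
#> 3     3    0.03           0.7276         1.21e-04
#> 4    10    0.10           0.7282         1.15e-06
```

Against a non-evolving parasitoid the host evolves resistance (92% of hosts
refractory by generation 300) and parasitism collapses to ~5%. Once the
parasitoid's AGV reaches about three times the host's, resistance never
emerges and parasitism plateaus near 73%.

Other entry points:

* `simulate_coevolution()` with two parasitoids — introduction experiments
  (who excludes whom, and at what parasitism rate).
* `introduction_grid()` — the full AGV-by-AGV introduction grid with
  pre-introduction rates, final rates and extinction flags.
* `run_sensitivity()` — 6000-sample Latin hypercube over the documented
  parameter ranges, PRCC of the resistant proportion against every
  parameter, bootstrap confidence intervals.
* `system_prediction()` — decades-ahead parasitism-rate predictions for
  either study system from literature parameter ranges.
* `generate_field_data()` / `compare_model_to_field()` — beta-binomial
  synthetic site-level observations and the F-test-gated Student/Welch
  comparison of model versus field parasitism.

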