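# switchpool

Multi-scale modelling of cellular decision making with a stochastic
bistable switch, applied to growth initiation of ovarian follicles.

## The problem and who this is for

A primordial ovarian follicle may rest for months or for decades before it
irreversibly starts to grow; the pool of ~10⁶ follicles present at birth
empties over ~50 years, while the gene regulation inside each follicle
runs on minutes.  `switchpool` is for systems biologists and modellers who
want to study how such decades-long tissue-level time constants emerge
from fast single-cell stochastic kinetics — and to reproduce, perturb and
extend every quantitative step of that argument.

## The model

Each cell carries a two-component positive-feedback switch

$$
\dot x = k_1 + V_1\frac{y^h}{M_1^h+y^h} - u_1 x,\qquad
\dot y = V_2\frac{x^h}{M_2^h+x^h} - u_2 y,
$$

which is bistable at the nominal constants (low "off" and high "on"
state).  Treating the rate laws as stochastic propensities on integer
copy numbers, collapsing the on-region (x + y ≥ L, L = 55) into one
absorbing state, and truncating gives a finite continuous-time Markov
chain dP/dt = AP.  The rightmost eigenvalue λ₁ of the non-absorbing block
is real, simple and negative; the per-cell switching rate is |λ₁| and

- the off-state probability decays as c₁·e^{λ₁t} (half-life ≈ 5.9 years
  at nominal parameters),
- a pool of N₀ independent cells has N_r(t) ~ Binomial(N₀, 1 − p_on(t)),
  giving a sharply peaked depletion-time distribution
  P(T_d ≤ t) = P(N_r(t) ≤ N_d),
- suppression of initiation by growing follicles
  (k₁(n₂) = k₁,max·K_n/(K_n+n₂)) turns the rate into λ₁(n₂) inside a
  two-compartment delay model which is far more robust to parameter
  variation than the single-cell chain.

The package implements the deterministic switch analysis, the sparse
generator and its dominant mode, the master-equation transient, exact
Gillespie simulation (Rcpp), the binomial depletion statistics, the
delayed-feedback population model, one-at-a-time sensitivity scans, a
synthetic cohort generator, and a config-driven pipeline/CLI.

## Worked example

```r
library(switchpool)

p <- switchParameters()          # nominal kinetic constants
findEquilibria(p)
#>           x          y stability ...
#> 1  5.500686  0.5796843    stable          # I, the off state
#> 2 19.323880 17.3754018    saddle          # II
#> 3 54.435200 50.1427679    stable          # III, the on state

G <- buildGenerator(p, 55)       # absorbing Markov chain, n = 1597
dominantMode(G)
#> SpectralSummary (dominant decay mode)
#>   lambda1   : -2.220719e-07 per minute (sparse solve, boundary 55)
#>   rate      : 0.116721 per year
#>   half-life : 5.938 years

sol <- solveCme(G)               # master-equation transient to 80 years
depletionTimeStats(sol, poolConfig(N0 = 1e6, Nd = 1e3))
#> Depletion-time distribution (binomial pool on the switching curve)
#>   E[Td] = 59.18 years, sd = 0.272 years (normal binomial CDF)

fp <- feedbackParameters()       # population model with AMH-type feedback
traj <- simulateDde(fp, tEndYears = 100, stopBelow = 500)
depletionTimeFromTrajectory(traj, 1e3)
#> [1] 49.10776
```

Reading: a single cell flips its switch with a half-life of ~5.9 years;
a million independent cells deplete to the menopause threshold at
59.2 ± 0.27 years; adding the growth-suppression feedback moves the
depletion age to ~49 years and buffers it against parameter variation
(compare `runScan("single_cell")` with `runScan("population")`).

A command-line wrapper over the same pipeline lives at
`inst/scripts/switchpool.R`:

```sh
Rscript inst/scripts/switchpool.R lambda1 --out results/
Rscript inst/scripts/switchpool.R all --config my_config.yaml --out results/
```

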