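# debsim

Simulation of the **standard Dynamic Energy Budget (DEB) model** for an
ectotherm under constant and seasonally oscillating food, built to study how
resource availability drives *interspecific* variation in body mass,
reproductive output and maturation.

## The model

An individual is described by four state variables: reserve energy *E* (J),
structural volume *V* (cm³), cumulative maturity *E_H* (J) and cumulative
reproduction energy *E_R* (J). Food enters through the scaled functional
response *f* ∈ [0, 1]; assimilation scales with structural surface area,
*ṗ_A = f·{ṗ_Am}·V^(2/3)*. Mobilized reserve, *ṗ_C = E·(v̇·V^(−1/3) − ṙ)*, is
split by the kappa rule: a fraction κ pays somatic maintenance
*ṗ_S = [ṗ_M]·V* and growth, the rest pays maturity maintenance *ṗ_J* and
either maturation (juveniles) or reproduction (adults):

    dE/dt   = ṗ_A − ṗ_C
    dV/dt   = (κ·ṗ_C − ṗ_S) / [E_G]        (= ṙ·V)
    dE_H/dt = (1−κ)·ṗ_C − ṗ_J,  dE_R/dt = 0        while E_H < E_H^p
    dE_H/dt = 0,  dE_R/dt = (1−κ)·ṗ_C − ṗ_J        afterwards

with the specific growth rate

    ṙ = (κ·v̇·E/V^(4/3) − [ṗ_M]) / (κ·E/V + [E_G]).

Life-stage switches (birth = feeding on, puberty = reproduction on) are
one-way latches on *E_H*, located during integration by the solver's
rootfinding. There is no starvation clamping: under food shortage *ṙ* can be
negative and the organism shrinks. Seasonal food is
*f(t) = f̄ + f_a·sin(2πt/365 + φ)*, with four labelled start phases
corresponding to birth at different points of the annual cycle. Observables:
dry biomass *B = d_V·V + (w_E/μ̄_E)·E* (g), wet biomass *5·B*.

At constant *f* two closed forms validate the numerics: the reserve density
equilibrates at *E/V = f·[E_m]* with *[E_m] = {ṗ_Am}/v̇*, and structural
length approaches *L_∞ = κ·f·{ṗ_Am}/[ṗ_M]*.

The interspecific study sweeps a factorial grid of 48 parameter sets
(v̇ ∈ {0.2, 0.3, 0.4, 0.5} cm/d, {ṗ_Am} ∈ {2000, 4000, 6000, 8000} J/(d·cm²),
κ ∈ {0.43, 0.51, 0.58}), each standing for a species, across constant food
levels *f* ∈ {0.2, …, 1} and seasonal environments with
f̄ ∈ {0.4, 0.6, 0.8}, f_a = 0.2.

The package also implements the parameter-space curation pipeline used to
justify that grid from a species-parameter collection: model-type /
lifespan / completeness filtering, 1.5-IQR outlier fences, equal-width joint
discretization of ({ṗ_Am}, v̇), frequency pruning, deduplication and
edge-isolation pruning — plus a seeded synthetic table generator so the
pipeline is fully testable offline.

## Worked example

```r
library(debsim)

p <- deb_params(p_Am_max = 4000, v_dot = 0.3, kappa = 0.51, species_id = "demo")
traj <- deb_simulate(p, seasonal_forcing(f_mean = 0.6, f_amp = 0.2), duration = 1095)
summary(traj)
#> DEB run summary [ok]
#>   time to puberty: 0.449 d (ceiling 1 d)
#>   dry biomass: terminal 0.1505 g; window mean 0.2452 g [0.04942, 0.5361]
#>   reproduction energy: window mean 4.741e+05 J, window net 4.576e+05 J
```

The summary discards the ontogenetic transient and reports statistics over
the trailing two years: this species reaches puberty within its first day,
its dry biomass oscillates with the food season between 0.05 and 0.54 g
around a mean of 0.245 g, and it commits on average ~4.7·10⁵ J of cumulative
energy to reproduction over that window.

The seasonal-surplus mechanism — the same species does *better* in a
fluctuating environment than at the same average food held constant:

```r
compare_environments()
#> Constant vs seasonal environment (same annual mean f = 0.8 )
#>   constant : steady-state dry biomass 0.009704 g, window-mean E_R 1.143e+05 J
#>   seasonal : window-mean dry biomass 0.01099 g, window-mean E_R 1.282e+05 J
#>   final-year mean assimilation: dynamic 124 J/d vs fixed-volume reference 113.8 J/d
```

Because the assimilation surface *V^(2/3)* grows during the good season, the
individual's realized assimilation (124 J/d) exceeds what a fixed surface
would harvest from the same food cycle (113.8 J/d): the good season
overcompensates the bad one, yielding ~13% more biomass and ~12% more
reproduction than the constant environment.

Sweeps and the curation pipeline:

```r
grid <- build_parameter_grid()        # 48 species
sw   <- constant_sweep(grid)          # 240 runs, ~10 s
all(reserve_density_check(sw)$pass)   # analytic validation
maturation_table(sw)                  # per-level maturation statistics
combos <- curate_parameter_space(bundled_fixture())
```

A YAML-driven runner (`run_deb_config()`) executes whole task lists
(sweeps, validation, comparison, curation, synthetic tables) and writes CSV
outputs plus a JSON manifest.

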