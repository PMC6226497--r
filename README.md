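# tpfret

Photon-by-photon maximum-likelihood analysis of binding transition paths in
single-molecule FRET experiments.

## What it does

In immobilized-molecule FRET experiments on binding reactions, association
of the labeled partners shows up as a rapid jump in transfer efficiency.
The jump itself — the transition path from the first encounter to the
stably bound complex — lasts only tens of microseconds, far below the
resolution of binned trajectories, but at count rates of 100–500
photons/ms the raw photon stream around the jump still constrains both its
duration and the shape of the free-energy barrier being crossed.

`tpfret` implements the full analysis chain:

- **Photon likelihood engine.** For a two-channel (donor/acceptor) photon
  stream with inter-photon times τᵢ and colors cᵢ, the likelihood under a
  continuous-time Markov model with generator **K** and per-state photon
  rate matrices **n**_D, **n**_A is

  L = **p**ᵀ_fin ∏ᵢ **n**_{cᵢ} exp[(**K** − **n**_D − **n**_A) τᵢ] **p**_ini,

  evaluated with per-photon renormalization in a compiled kernel. Used both
  for long-trace kinetics (association/dissociation/blinking rates via a
  three-state model with a dark state) and for transition windows. A
  Viterbi decoder yields the most likely state path.
- **Transition-path estimation.** Each ≥1 ms, ≥1000-photon window around a
  single transition is compared under an instantaneous two-state model and
  a three-state model with a virtual intermediate of lifetime τ_I and
  efficiency E_I. The pooled log-likelihood difference surface Δln L(τ_I,
  E_I) over all transitions peaks at the mean transition-path time
  ⟨t_TP⟩ = τ̂_I and intermediate efficiency Ê_I; bootstrap resampling gives
  standard errors, and a deletion control verifies the peak is caused by
  the transitions themselves.
- **Barrier-shape inference.** Transition-path-time densities p(t_TP) for
  candidate barrier shapes (parabolic, flat, metastable intermediate) are
  solved from the Smoluchowski equation by spectral expansion; photon-level
  simulations matched to the measured cohort are analyzed identically and
  compared to the measured per-transition histogram by χ² distance and a
  k-sample Anderson–Darling test, after calibrating each candidate's
  diffusion coefficient on a 90–130% mean grid.
- **Kramers arithmetic.** Barrier heights from escape times and the
  preexponential time τ₀ = 2π τ_r, with symmetric- and asymmetric-exit
  variants, plus the splitting-probability identity behind the factor-1/2
  mapping between three-state and two-state rate coefficients.
- **Synthetic data.** Window cohorts, Gillespie long traces with blinking,
  and Brownian-dynamics transition paths converted to photons through the
  Förster equation — the package's stand-in for measured trajectories.

## Worked example

```r
library(tpfret)

## a synthetic cohort of 250 binding transitions: 200 photons/ms,
## exponential transition-path times with an 80 us mean, E_I = 0.72
cfg <- simulationConfig(nTransitions = 250)
report <- runTransitionPipeline(pipelineConfig(cfg, nBootstrap = 200, seed = 1))

round(report$tTP * 1e6, 1)   # mean transition-path time, us
#> [1] 68.1
round(report$eHat, 3)        # intermediate transfer efficiency
#> [1] 0.702
round(report$seTau * 1e6, 1) # bootstrap standard error, us
#> [1] 11.7
report$pooled
#> LikelihoodSurface (61 tau x 91 E grid, 250 transitions pooled)
#>   max Delta lnL = 68.836 at tau = 68.1 us, E = 0.702
```

The pooled surface peaks within one bootstrap standard error of the
generating values (80 µs, 0.72); the error shrinks as 1/√n toward the
few-µs level at full cohort sizes.

```r
## Kramers estimates: reconfiguration time 75 ns gives the preexponential
## tau0 = 2*pi*75 ns ~ 0.5 us; escape time 80 us
kramersPrefactor(75e-9) * 1e6                # 0.471 us ~ 0.5 us
kramersBarrierHeight(80e-6, 0.5e-6)          # 5.77 -> ~5.8 kT (symmetric)
kramersBarrierHeight(80e-6, 0.5e-6, FALSE)   # 5.08 -> ~5.0 kT (single exit)
```

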