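# softmsm

Soft Markov state models and contact kinetics for disordered protein
ensembles.

## What this package is for

Intrinsically disordered peptides (the amyloid-beta 42-mer is the
motivating case) interconvert rapidly between weakly metastable
conformations, and small molecules can bind them in a "disordered"
mode: skipping between transient contacts while leaving — or even
increasing — the peptide's conformational entropy. Resolving that
mechanism takes kinetics estimated from large molecular-dynamics
trajectory ensembles: state populations and lifetimes, relaxation
timescales, contact formation/rupture kinetics, and local dihedral
dynamics.

`softmsm` is an R package for that analysis. It is aimed at
computational biophysicists who have (or simulate) multi-trajectory
ensembles of a peptide with an optional ligand and want a validated,
reproducible kinetic-model pipeline at desk scale.

## The model in brief

A *soft state assignment* maps each frame x_t to a probability vector
chi(x_t) over k metastable states (a neural softmax classifier trained
by maximizing the VAMP-2 score at lag tau). The *Koopman matrix* is
estimated from soft transition counts

    C_ij = sum_t chi_i(x_t) chi_j(x_{t+tau}),   K = row-normalized C,

with equilibrium distribution pi (leading left eigenvector of K). With
hard 0/1 assignments this is exactly the classical count-based Markov
state model. Derived observables:

* relaxation timescales  t_i = -tau / ln |lambda_i|,
* state lifetimes        t̄_i = -tau / ln K_ii,
* transition rates       K_ij(tau) / tau  (1/us),
* equilibrium frame weights  w_t ∝ sum_i pi_i chi_i(x_t) / N_i,
* Ramachandran entropy (nats, 100x100-bin phi/psi histograms), state
  entropy, circular chi1 autocorrelation at fixed lag,
* per-contact lifetimes from 2x2 transition matrices at the lag, and
  conditional ring-stacking probabilities.

Models are validated by implied-timescale flatness, the
Chapman–Kolmogorov test K(tau)^n vs K(n tau) with trajectory-bootstrap
bands, and timescale convergence in the number of trajectories.
Multi-model errors follow the split/trial protocol (20 randomized 9:1
train/validation splits over a common 10% test set, 3 trials each,
best test-set VAMP-2 kept; reported intervals are bootstrap percentiles
of the mean over models).

A synthetic-trajectory generator (global Markov state process at 250 ps
steps, von Mises dihedral emissions, rotamer-hopping chi1 dynamics,
telegraph-process ligand contacts, optional 3D coordinates by
internal-coordinate chain construction) provides ground truth with
closed-form kinetics, so every estimator is tested by parameter
recovery.

## Worked example

Generate the default benchmark (2 global states, 50 trajectories x
2000 frames at 250 ps; slowest true timescale 33.2 ns, populations
1/3 : 2/3), train a soft-assignment model, and recover the kinetics:

```r
library(softmsm)

spec  <- groundTruthSpec(seed = 42)
bench <- makeBenchmarkEnsemble(spec)
analyticKinetics(spec)$timescales
#> [1] 33.20818

fit <- trainAssignmentModel(expandCircular(bench$features), k = 2, seed = 11)
fit$koopman
#> KoopmanModel: 2 states, tau = 5 ns
#>   pi: 0.3386, 0.6614
#>   diag(K): 0.9074, 0.9526
relaxationTimescales(fit$koopman)
#> [1] 33.15808
stateLifetimes(fit$koopman)
#> [1]  51.46426 102.98808
```

The recovered slowest timescale (33.16 ns vs 33.21 true), lifetimes
(51.5 / 103.0 ns vs 49.9 / 99.9 true) and populations (0.339 / 0.661
vs 1/3, 2/3) are all within a few percent of the generator's ground
truth. The model is Markovian at the 5 ns lag:

```r
chapmanKolmogorov(fit$assignment, tau = 5, nMax = 5)
#> Chapman-Kolmogorov report at tau = 5 ns
#>   n = 1: max |K(tau)^n - K(n tau)| = 0  [within band]
#>   n = 2: max |K(tau)^n - K(n tau)| = 0.001077  [within band]
#>   n = 3: max |K(tau)^n - K(n tau)| = 0.00143  [within band]
#>   n = 4: max |K(tau)^n - K(n tau)| = 0.003451  [within band]
#>   n = 5: max |K(tau)^n - K(n tau)| = 0.006236  [within band]
```

Transient ligand contacts are telegraph processes with mean on-time
20 ns; the per-contact Markov-model estimator at the same lag recovers
them:

```r
contactLifetime(bench$contacts, lagNs = 5)
#>   contact probability lifetime flag
#> 1     Y10     0.19112 20.57777   ok
#> 2     F19     0.51591 24.60221   ok
```

(Y10: true occupancy 0.2, true mean on-time 20 ns. The faster-cycling
F19 contact illustrates the small positive bias of the fixed-lag
lifetime estimator when dwells approach the lag; the analytic value of
the estimator itself is 22.8 ns there.)

The whole flow — featurize/load, filter unbound frames, train across
splits, align states, validate, observables, dynamics, contacts, with
provenance-stamped CSV/JSON reports — is available as

```r
runPipeline(pipelineConfig(nModels = 20, preset = "desk",
                           outDir = "report", seed = 1))
```

or from a shell via `Rscript inst/scripts/run_pipeline.R --config
config.yaml`.

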