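# discountrl

Joint hierarchical Bayesian models of **model-based control** (two-step
sequential decision task) and **temporal discounting** (adaptive
intertemporal choice task), with full generative simulators for both tasks
so that the entire analysis pipeline can be validated by parameter recovery
on synthetic populations.

## The problem

Model-based reinforcement learning — planning through an internal model of
the environment — has been proposed as the mechanism by which people value
delayed rewards: better simulation of the future should mean shallower
discounting. Testing that idea requires measuring, for each person, (a) how
much their trial-by-trial choices in a two-step task reflect planning versus
habit, and (b) how steeply they discount delayed money, and then asking
whether the two covary across people. `discountrl` implements the complete
machinery for this joint analysis for researchers in computational
psychiatry and decision neuroscience.

## The models

**Two-step task.** A hybrid learner combines model-free SARSA(λ = 1) values
(Q-values initialized at 0.5, eligibility trace propagating the second-stage
prediction error to the first stage, non-chosen values decaying to baseline)
with model-based values from a Bellman backup through the veridical
transition probabilities (0.7/0.3). Stage-1 choice is softmax in

```
β_mb · Q_mb(a) + β_mf · Q_mf(s1, a) + p · rep(a) + β_bias · bias(a)
```

and stage-2 choice is softmax with weight β₂. An alternative reading is a
logistic *stay* regression on previous reward (±1), previous transition type
(±1) and their interaction. **Intertemporal choice.** Exponential
`A·e^(−kD)` or hyperbolic `A/(1+kD)` discounting with softmax sensitivity θ,
delays scaled to one year.

**The joint hierarchy.** Every subject-level parameter gets a group-level
Gaussian; the discount rate k gets a half-Gaussian or log-normal group
distribution; and the model-based / model-free weights are coupled to the
z-scored (identity- or log-transformed) discount rate:

```
β_mb,i ~ Normal(μ_mb + ω_mb · z_i,  σ_mb²),   z_i = standardize(f(k_i))
```

The coupling slopes ω_mb, ω_mf — and their difference, the *differential
effect* of discount rate on model-based versus model-free control — are the
quantities of interest. Eight model variants (2 two-step forms × 2 discount
functions × 2 group distributions of k) × 3 data partitions reproduce the
full analysis grid. Posteriors are sampled by an adaptive
Metropolis-within-Gibbs sampler with hierarchy-interweaving moves (compiled
in C++), gated on split-R̂ < 1.1 for all group-level parameters.

## Worked example

Simulate a 20-subject population with no true coupling, fit the joint
RL + hyperbolic + normal-k model, and summarize the couplings:

```r
library(discountrl)
pop <- generate_population(20, group_spec(),
                           configs = study_config(2, n_twostep_trials = 100),
                           seed = 42)
model <- build_joint_model(model_config("rl", "hyper", "normal", "combined"),
                           pop$datasets)
model
#> joint model: rl + hyper discounting, normal group k, partition combined
#>   20 subjects, 176 parameters

fit <- fit_model(model, n_chains = 4, n_iter = 2000, n_warmup = 1000, seed = 7)
summarize_draws(fit, c("omega_mb", "omega_mf", "mu_mb", "mu_mf", "mu_k"))
#>      param   median ci_low ci_high rhat
#> 1 omega_mb  0.36844 -1.353   2.146 1.02
#> 2 omega_mf -0.00911 -0.667   0.634 1.00
#> 3    mu_mb  3.07753  1.260   4.947 1.01
#> 4    mu_mf  2.35207  1.681   3.064 1.02
#> 5     mu_k  0.96777  0.187   1.304 1.02

differential_effect(fit)
#>        param median ci_low ci_high
#> 1 omega_diff   0.41  -1.54     2.3
```

Both coupling posteriors straddle zero, as they should for data generated
with `omega_mb = omega_mf = 0`: the model finds engaged two-step behaviour
(μ_mb, μ_mf well above zero) and a discount rate near the generating value
(μ_k ≈ 1 per scaled year), but no discount–control relationship. At this
small example size a few group-level R̂ values can sit just above the 1.1
gate (`check_convergence(fit)` reports them); the packaged recovery studies
run 40 subjects, where all group-level parameters pass.

Higher-level drivers:

```r
grid <- run_grid(datasets, mcmc = list(n_chains = 4, n_iter = 1500, n_warmup = 500))
rec  <- recovery_study(group_spec(omega_mb = 0.5, sigma_mb = 0.2, sigma_mf = 0.2))
```

`run_grid()` fits all 8 variants × 3 partitions with per-cell seeds and
failure capture; `recovery_study()` tabulates coupling coverage against
known ground truth. Trial-level data round-trip through plain CSV via
`read_trials()` / `write_trials()`.

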