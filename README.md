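# rewardmem

Model-based analysis of how reward shapes associative memory formation,
trial by trial.

## The problem

In a probabilistic-feedback associative memory task, participants learn
which of two objects each of six cartoon characters prefers, guided by
positive/negative feedback that is predetermined per character: "high"
characters give positive feedback on 8 of 10 trials, "medium" on 5/10,
"low" on 2/10 (60 trials per session, blocked by character). Memory for the
character–object pairings is tested later. Because the ratios differ,
characters acquire different expected values and every feedback event
carries a reward prediction error — the two quantities dopamine neuron
activity is known to track. The analysis asks whether reward anticipation
(expected value, V) and reward delivery (prediction error, δ) independently
raise the probability that a trial's association is encoded.

`rewardmem` is for researchers who want to run, extend, or stress-test this
analysis: it provides the task-design generator, the learning model, six
candidate encoding models, the maximum-likelihood machinery, AIC model
comparison, the permutation statistics, and a synthetic cohort generator so
the entire pipeline is testable without access to raw behavioral data.

## The model

Expected values follow the delta rule per character *c*:

    δ(t) = r(t) − V_c(t)
    V_c(t+1) = V_c(t) + α · δ(t)

and the probability of later remembering trial *t*'s association is
logistic in a linear reward signal, `p_Memory(t) = 1 / (1 + exp(−R(t)))`,
with six candidates for R(t): a constant (`baseline`); adding signed
prediction error (`pe`), unsigned prediction error (`abs_pe`), or expected
value (`ev`); and the two-term combinations (`pe_ev`, `abs_pe_ev`). Scale
factors are bounded in [−2, 2], α in [0, 1]. Each participant's 60 test
outcomes are fit by minimising the Bernoulli negative log-likelihood (LLE)
with an exhaustive parameter-grid scan refined by bounded Nelder–Mead
search, and models are compared by `AIC = 2k + 2·LLE`.

## Worked example

```r
library(rewardmem)

# one encoding session and one synthetic participant at the reference
# group-mean generative parameters
design <- generate_session_design(seed = 1)
design
#> <session_design> s1 (20min): 6 characters, 60 trials, 30 positive feedbacks

gen <- reference_group_params("pe_ev", "20min")
round(gen, 3)
#>         C0    C_delta C_absdelta        C_V      alpha
#>      0.350      0.725      0.000      1.156      0.329

rec <- simulate_participant(design, "pe_ev", gen, seed = 7)
fit <- fit_participant("pe_ev", design, rec$y)
fit
#> <fit_result> p1, model pe_ev: LLE 37.191, k 4, AIC 82.383

# a 25-participant heterogeneous cohort, three models, AIC comparison
cohort <- simulate_cohort(25, "pe_ev",
                          reference_param_sampler("pe_ev", "20min"),
                          base_seed = 11)
fits <- fit_cohort(cohort, models = c("baseline", "pe", "pe_ev"),
                   options = fit_options(grid_step_scale = 0.25,
                                         grid_step_alpha = 0.1))
compare_models(fits, n_perm = 2000, seed = 5)
#> <comparison_result> 25 participants; best model: pe
#>      model k mean_lle sem_lle mean_aic sem_aic p_vs_best
#> 1 baseline 1    37.10  1.0268    76.20   2.054 0.0679660
#> 2       pe 3    34.07  0.9793    74.14   1.959        NA
#> 3    pe_ev 4    33.74  0.9532    75.49   1.906 0.0004998

condition_means(cohort_trials(cohort), "feedback")
#>   feedback n_trials n_participants proportion_correct        sem
#> 1        0      750             25          0.5600000 0.03696846
#> 2        1      750             25          0.7146667 0.02687970
```

Reading the output: the single-participant fit recovers a positive
prediction-error weight (its LLE of 37.2 beats the ~41.6 of a coin-flip
predictor), and at the cohort level memory is better for associations
encoded under positive (0.715) than negative feedback (0.560) — the reward-
delivery effect. The two-term model fits best in raw likelihood but, at one
60-trial session per participant, its AIC penalty often hands the formal
win to a smaller model; the methods vignette
(`vignettes/reward-memory-modelling.Rmd`) analyses exactly when and why.

A command-line wrapper covers the same pipeline stage by stage
(`simulate`, `fit`, `compare`, `analyze`, `report`):

```sh
Rscript exec/rewardmem simulate --out run1 --seed 1
Rscript exec/rewardmem fit --out run1
Rscript exec/rewardmem compare --out run1
Rscript exec/rewardmem analyze --out run1
Rscript exec/rewardmem report --out run1
```

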