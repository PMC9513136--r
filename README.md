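# itclab

Simulation and analysis of **intertemporal-choice (ITC) experiments with
adaptive staircase titration**, for researchers in behavioral decision
science and computational psychiatry who study delay discounting and
cognitive interventions against impulsivity.

In an ITC task, a participant repeatedly chooses between a fixed immediate
reward (10,000 KRW here) and a larger delayed reward. The delayed reward is
titrated by an adaptive staircase: 12 arms (6 delays — 1, 10, 21, 50, 90,
180 days — crossed with 2 initial delayed rewards, 15,000 and 20,000 KRW),
5 titration steps per arm, randomly interleaved within each of 3 blocks of
60 trials (180 trials per session). Choices are modelled by hyperbolic
discounting with a softmax choice rule:

```
SV = V / (1 + k·D)
P(immediate) = 1 / (1 + exp(-μ · (SV_immediate − SV_delayed)))
```

where `k ∈ (0, 1)` is the per-day discount rate (larger k = more impulsive)
and `μ ≥ 0` the inverse temperature (per KRW). Each participant-session is
fit by maximum likelihood (multi-start Nelder–Mead in transformed space)
with explicit diagnostics for non-unique solutions. Pre/post intervention
designs are analysed with `Δlog k = log10 k_pre − log10 k_post` (positive =
impulsivity reduced), MAD outlier exclusion, bootstrap t and correlation
tests (shift-to-null / pair-breaking resampling), a time-by-type
mixed-design ANOVA, sliding-window learning curves for the intervention
tasks (Serial-7s working memory, spatial attention), and binned
performance–effect associations. A synthetic cohort generator with known
ground truth makes the whole pipeline testable end to end.

## Worked example

Simulate one agent's closed-loop staircase session, refit it, then run a
small two-group pre/post study through the full pipeline:

```r
library(itclab)

session <- simulate_agent_session(discount_params(k = 0.01, mu = 5e-4), seed = 42)
p_immediate_ratio(session)
#> [1] 0.4277778
fit_mle(session, seed = 1)
#> ITC hyperbolic-softmax fit: k = 0.0096492 (log10 k = -2.016), mu = 0.0005831
#>   logLik = -93.090 over 180 trials; 10 starts; unique: TRUE

design <- cohort_design(
  groups = list(list(label = "working_memory", n = 12, delta_log10_k = 0.3),
                list(label = "rest",           n = 12, delta_log10_k = 0)),
  wm_trials = 120, seed = 7)
report <- run_pipeline(pipeline_config(design = design,
                                       analysis = list(B = 2000), seed = 7))
report$counts
#> $n_input: 24   $n_excluded_nonunique: 1   $n_excluded_mad: 3   $n_included: 20
report$group_effects
#>            group  n mean_delta_log_k sd_delta_log_k mean_delta_p_immediate        t     p_boot   cohen_d
#> 1           rest 11        0.1549822      0.1818170             0.01262626 2.827115 0.02548726 0.8524074
#> 2 working_memory  9        0.2825889      0.1709033             0.03395062 4.960503 0.01299350 1.6535011
report$anova
#>            term df         ss          F            p
#> 1          type  1 0.15591908  0.3843228 5.430679e-01
#> 3          time  1 0.45115962 28.7852796 4.241101e-05
#> 4   time_x_type  1 0.04030159  2.5713570 1.262165e-01
```

Reading the output: the true agent (`k = 0.01`, i.e. `log10 k = -2`) is
recovered at `log10 k̂ = -2.016`. In the cohort, one of 24 participants is
dropped because the likelihood did not identify a unique `(k, μ)`, three
more as 3-MAD outliers on the log10 k estimates. The working-memory group's
mean `Δlog k = 0.28` recovers its generating effect (0.3); the rest group's
0.15 reflects a positive mean shift at this small n (its generating effect
is 0, with test–retest noise of 0.1 decades). The ANOVA decomposes log10 k
into the between factor (`type`), the repeated factor (`time`) and their
interaction.

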