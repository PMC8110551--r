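# spebf — semi-parametric empirical Bayes factors for GWAS summary statistics

`spebf` performs per-SNP Bayes factor analysis of case-control GWAS summary
statistics (β̂ⱼ, Vⱼ) — the per-SNP log odds ratio estimate and its variance
— for statistical geneticists who want an association measure that weighs
false negatives as well as false positives, and who distrust a fixed
parametric prior for the effect-size distribution.

Under asymptotic normality, β̂ⱼ | βⱼ ~ N(βⱼ, Vⱼ), and across the genome

    f(β̂ⱼ) = (1 − π) φ(β̂ⱼ; 0, Vⱼ) + π ∫ φ(β̂ⱼ; β, Vⱼ) g(β) dβ,

with π the non-null proportion and g the effect-size distribution of
associated SNPs.  The Bayes factor convention is
BF = Pr(β̂ | H₀) / Pr(β̂ | H₁): **small values favor association**, and H₀
is rejected when BF < R / (Pr(H₀)/Pr(H₁)) with R the false-negative /
false-positive cost ratio.  Two priors for β under H₁ are provided:

* **ABF** — Wakefield's approximate Bayes factor with the fixed normal
  N(0, W) prior, in closed form
  `sqrt((V+W)/V) * exp(-(z²/2) · W/(V+W))`, z = β̂/√V; by default
  W = 0.21², i.e. a 95% prior belief that the odds ratio is in [1/1.5, 1.5].
* **SP-EBF** — the semi-parametric empirical Bayes factor
  `φ(β̂; 0, V) / Σₖ φ(β̂; tₖ, V) p̂ₖ`, whose discrete prior
  ĝ = Σₖ p̂ₖ δ(tₖ) (grid excludes zero) and non-null proportion π̂ are
  estimated from all m SNPs jointly by a smoothing-and-roughening EM — an
  EM whose early iterations kernel-smooth the fitted masses with a
  decaying bandwidth to regularize the otherwise spiky nonparametric MLE.

The package also provides posterior null probabilities (the local-fdr
analog), the Bayesian decision rule, P/ABF/SP-EBF rankings, a calibrated
simulator of case-control summary statistics with known (π, g), recovery
metrics (Wasserstein-1 between ĝ and g), daner-style summary file I/O, and
a five-subcommand command-line pipeline.  See the methods vignette
(`vignettes/spebf-methods.Rmd`) for the model, algorithm defaults, and
limitations.

## Worked example

A published bipolar-disorder SNP had |β̂| = 0.271 with two-sided
P = 6.97×10⁻¹⁰.  Reconstructing its variance and computing the ABF:

```r
library(spebf)
v <- derive_var_from_p(0.271, 6.97e-10)   # z = 6.1668, V = 0.001931
abf(0.271, v, abf_prior(W = 0.21^2))
#> [1] 5.986e-08
```

(The value published alongside those inputs is 5.53×10⁻⁸; the ~8%
difference is rounding of the printed 3-significant-digit inputs.)
An ABF of 6×10⁻⁸ means the observed estimate is about 17 million times
more likely under association than under the null.

End to end on simulated data with a sharply peaked true g (all non-null
effects at 0.15, π = 0.05, 20,000 SNPs):

```r
sim <- simulate_summary(sim_config(m = 20000, pi_true = 0.05,
                                   g_spec = g_point_masses(0.15), seed = 61))
fit <- fit_prior(sim$summaries)
fit$prior
#> Nonparametric effect-size prior: B = 200 mass points on [-0.2866, 0.2866]
#>   pi (non-null proportion) = 0.0639; mean(g) = 0.1223, sd(g) = 0.06235

tab <- rank_table(sim$summaries, abf_prior(), fit$prior)
tab[order(tab$rank_p)[1:5], c("snp_id","beta_hat","p","abf","spebf",
                              "rank_p","rank_abf","rank_spebf")]
#>      snp_id beta_hat        p      abf    spebf rank_p rank_abf rank_spebf
#>  snp0001403    0.198 2.20e-19 3.74e-17 3.20e-17      1        1          1
#>  snp0005938    0.205 4.04e-19 6.75e-17 9.18e-17      2        2          3
#>  snp0016853    0.202 6.65e-19 1.10e-16 1.19e-16      3        3          5
#>  snp0010216    0.195 8.21e-19 1.36e-16 8.86e-17      4        4          2
#>  snp0002495    0.195 9.21e-19 1.52e-16 9.79e-17      5        5          4
```

The fitted π̂ (0.064) brackets the true 0.05 and ĝ concentrates near the
true effect 0.15.  The ABF ranking tracks the P-value ranking almost
exactly (Spearman 0.867 overall) while the SP-EBF, informed by the
estimated effect-size distribution, reorders more aggressively
(Spearman 0.699): among the top five, SNPs whose β̂ sits closest to the
prior's support move up.

From a shell (wrapper installed at `inst/cli/spebf`):

```sh
spebf simulate --m 20000 --pi 0.05 --g point_masses:0.15;1 --seed 61 --out sim.tsv
spebf fit --in sim.tsv --prior-out prior.tsv
spebf score --in sim.tsv --prior prior.tsv --w 0.0441 \
    --decision-R 1 --prior-odds from_fit --out scores.tsv
```

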