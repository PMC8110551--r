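---
title: "Semi-parametric empirical Bayes factors for GWAS summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-parametric empirical Bayes factors for GWAS summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spebf)
```

## The model

For SNP $j$ of $m$, a case-control GWAS reports an estimated log odds ratio
$\hat\beta_j$ with sampling variance $V_j$ (equivalently a standard error or
a two-sided Wald $P$ value).  Asymptotically
$\hat\beta_j \mid \beta_j \sim N(\beta_j, V_j)$, and the marginal
distribution of $\hat\beta_j$ across the genome is modeled as a two-group
mixture

$$f(\hat\beta_j) = (1-\pi)\,\varphi(\hat\beta_j;0,V_j)
  + \pi \int \varphi(\hat\beta_j;\beta,V_j)\,g(\beta)\,d\beta,$$

where $\pi$ is the proportion of truly associated (non-null) SNPs and $g$
is the distribution of their effect sizes.  The Bayes factor here is
$\mathrm{BF}(\hat\beta_j) = \Pr(\hat\beta_j \mid H_0)/\Pr(\hat\beta_j \mid H_1)$:
**small values favor association**, and $H_0$ is rejected when
$\mathrm{BF} < R / (\Pr(H_0)/\Pr(H_1))$ with $R = c_{FN}/c_{FP}$ the
relative cost of a false negative ([`decide()`]).

Two priors for $\beta$ under $H_1$ are implemented:

* **ABF** (`abf()`): the fixed normal $N(0, W)$, giving the closed form
  $\sqrt{(V+W)/V}\,\exp\{-(z^2/2)\,W/(V+W)\}$.  The default
  $W = 0.21^2$ encodes a 95% prior belief that the odds ratio lies in
  $[1/1.5, 1.5]$; `w_from_or_interval()` generalizes this construction
  (note $\log(1.5)/\Phi^{-1}(0.975) = 0.2069$, conventionally rounded to
  0.21 — the package keeps both the rounded and exact paths).
* **SP-EBF** (`spebf()`): a nonparametric discrete $g$ estimated from the
  data itself, $\hat g = \sum_k \hat p_k \delta_{t_k}$ on a grid $t$ that
  excludes zero (the null's point mass at zero is carried by $1-\pi$, not
  by $g$).  Then
  $\mathrm{SPEBF}(\hat\beta_j) =
  \varphi(\hat\beta_j;0,V_j) / \sum_k \varphi(\hat\beta_j;t_k,V_j)\,\hat p_k$.

The practical difference: when the estimated $g$ concentrates on small
effects — as genome-wide data typically indicate — the SP-EBF attributes
relatively more evidence to SNPs with small $|\hat\beta_j|$ and less to the
few large-effect outliers, whereas the wide normal ABF prior acts almost as
a non-informative prior and reproduces the $P$-value ranking.

## Estimating the prior: smoothing-and-roughening EM

`fit_prior()` maximizes the marginal likelihood over $(\pi, p)$ with $t$
fixed:

1. **Grid**: $B$ (even) points equally spaced on $[-L, L]$,
   $L = \texttt{span\_factor} \times \max_j |\hat\beta_j|$, arranged so 0
   falls exactly midway between the central pair — an even $B$ excludes
   zero by construction.
2. **Initialization**: $p_k = 1/B$, $\pi = \texttt{pi\_init}$.
3. **E-step**: per-SNP responsibilities over the $B+1$ components
   $\{H_0, t_1, \dots, t_B\}$, computed by log-sum-exp.
4. **M-step**: $\pi \leftarrow m^{-1}\sum_j (1 - r_{j0})$,
   $p_k \leftarrow \sum_j r_{jk} / \sum_j \sum_{k'} r_{jk'}$.
5. **Smoothing**: for the first `smooth_iters` iterations the updated
   masses are convolved on the grid with a Gaussian kernel of bandwidth
   $h_i = h_0\,\mathrm{decay}^{\,i}$ (mass-conserving, renormalized).
   The unregularized nonparametric MLE of a mixing distribution is
   notoriously spiky (a few isolated atoms); early wide smoothing spreads
   mass plausibly, and the decaying bandwidth ("roughening") hands over to
   plain EM, restoring likelihood monotonicity before convergence is
   judged.
6. **Convergence**: on the relative change of the marginal log-likelihood,
   tested only across pure EM steps (never across a smoothing
   perturbation), with tolerance `tol`.

### Defaults and why

| parameter | default | units / meaning |
|---|---|---|
| `grid_size` (B) | 200 | mass points; even so 0 is excluded |
| `span_factor` | 1.2 | grid half-range over $\max|\hat\beta|$; covers every observed estimate with margin |
| `pi_init` | 0.01 | a GWAS-plausible non-null fraction |
| `max_iter` | 500 | EM iterations |
| `tol` | 1e-8 | relative log-likelihood change |
| `smooth_h0` | `"auto"` = grid range / 20 | initial kernel bandwidth (log-OR units) |
| `smooth_decay` | 0.9 | geometric bandwidth decay per iteration |
| `smooth_iters` | 50 | iterations with smoothing active |
| `var_range` | [1e-8, 100] | SNPs with $V_j$ outside are excluded from *fitting* only |

No canonical bandwidth schedule exists for smoothing-and-roughening
estimation of a mixing distribution; these values are this package's
documented, configurable stand-in, chosen before any result was inspected
and kept fixed.  All of them are exposed both in `fit_config()` and on the `fit`
subcommand, so an externally specified schedule can be reproduced exactly.

Implementation notes: the $m \times B$ log-density matrix is precomputed
once and the EM loop runs in C++; `loglik_trace[i]` is the log-likelihood
of the parameters *entering* iteration $i$ (with smoothing disabled this is
the textbook monotone EM sequence), and the returned prior is the model of
the final E-step, so the last trace entry is its exact log-likelihood.
Scoring (`spebf()`, `mixture_loglik()`) uses an independent pure-R
chunked log-sum-exp path, so the fitting and scoring routes check each
other in the test suite.

$\hat\pi$ is a byproduct of the fit and can serve as the prior odds
$(1-\hat\pi)/\hat\pi$ in the decision rule
(`decision_config(prior_odds = "from_fit")`).  Identifiability caveat:
because grid points approach zero arbitrarily closely as $B$ grows, the
likelihood is nearly flat along exchanges between the null component and
near-zero mass of $g$; $\hat\pi$ is therefore well bounded but only weakly
point-identified when $g$ has substantial density near zero (see
limitations).

## What the simulator emulates — and what it does not

`simulate_summary()` generates the data structure the method consumes:
$m$ SNPs; a fraction `pi_true` non-null with $\beta \sim g$ (normal,
Laplace, point masses, or arbitrary — including asymmetric — mixtures);
MAF $f \sim U(0.05, 0.5)$; sampling variance from the standard 2×2-table
approximation $V = (1/n_{\mathrm{case}} + 1/n_{\mathrm{control}})/(2f(1-f))$;
$\hat\beta \sim N(\beta, V)$; two-sided Wald $P$.  Defaults
($n_{\mathrm{case}} = 7482$, $n_{\mathrm{control}} = 9250$) echo the scale
of the bipolar-disorder meta-analysis that motivates the defaults elsewhere
in the package.  The $V$ formula is a documented modeling choice: it gives
the realistic MAF–variance coupling of real summary files.

Not emulated: linkage disequilibrium (SNPs are independent, so ranking
comparisons ignore the redundancy of LD blocks), genotyping/imputation
error, case-control ascertainment, allele-frequency mismatch between
cohorts.  A green recovery test therefore establishes correctness of the
estimator under its own sampling assumptions, not robustness to the full
messiness of real GWAS data.

`evaluate_recovery()` scores a fit by $\hat\pi - \pi$ and the
Wasserstein-1 distance $\int |F_{\hat g} - F_g|$, integrated on a merged
knot grid so that discrete-vs-discrete comparisons are exact.

## Numerical choices

* All densities are handled in log space end to end; Bayes factors span
  hundreds of orders of magnitude in GWAS, and `abf()`/`spebf()` expose
  `log10 = TRUE` for values that underflow as doubles.
* $P \to z$ inversion uses the upper-tail quantile
  (`qnorm(p/2, lower.tail = FALSE)`) — never $1 - p/2$ arithmetic — and is
  stable down to $P \approx 10^{-300}$.
* Inside log-sum-exp, terms more than 45 nats below the row maximum are
  skipped (relative error $< 3 \times 10^{-20}$).
* An SP-EBF whose denominator underflows even in log space returns `+Inf`
  with a warning, never a silent `NaN`.
* Ranks (1 = most significant) break ties deterministically by
  (chromosome, position, SNP id).  Coordinates are otherwise opaque labels.
* Variance-source precedence on input is se > var > reconstruction from
  $(\hat\beta, P)$, with conflicts above 5% relative warned about; a
  strict-inequality decision rule (`bf < R/prior_odds`) means a BF exactly
  at threshold is not rejected.

## Design decisions taken where the design was open

* **Grid from the fitting subset**: SNPs with $V_j$ outside `var_range`
  are excluded from both the grid construction and the EM (their extreme
  $\hat\beta$ would inflate the span), but are always scored: the prior is
  fixed at scoring time.
* **Convergence suspension during smoothing**: the smoothing step keeps
  perturbing $p$ even at a likelihood stationary point, so the stopping
  rule is evaluated only across pure M-step transitions.
* **Reported SP-EBF is the pure density ratio** $f_0/\hat f_1$, not a
  $\hat\pi$-weighted posterior quantity; posterior null probabilities are
  available separately (`posterior_null_prob()`), and the two are linked by
  the verified identity $\Pr(H_0 \mid \hat\beta) =
  \mathrm{BF} \cdot \mathrm{PO}/(1 + \mathrm{BF} \cdot \mathrm{PO})$.
* **CLI `--g` parser** covers `normal`, `laplace` and `point_masses`;
  general mixtures are constructed in R with `g_mixture()` (nested
  component syntax on a command line buys nothing scientifically).
* **Lossless companion writer**: `write_results()` keeps its fixed
  6-significant-digit schema; `write_summary()` exists for full-precision
  round trips of summary tables.

## Known limitations

* $\hat\pi$ is biased downward when $g$ has a sharp mode at zero: non-null
  SNPs with $|\beta|$ well below the noise scale
  $\sqrt{V} \approx 0.02$–$0.05$ are statistically indistinguishable from
  null, and the EM allocates them to the null component.  The test suite
  documents this honestly: recovery simulations with a normal and an
  asymmetric bimodal $g$ meet their tolerances, while the Laplace scenario
  (density kinked at zero) misses the $\pm 50\%$ relative band on
  $\hat\pi$ and the $W_1 \le 0.02$ bound at $m = 50{,}000$ and is left
  failing rather than re-tuned.
* The method consumes summary statistics only; it cannot detect or correct
  allele-harmonization errors against a reference panel, and it treats
  SNPs as independent (no LD-aware region grouping or clumping).
* The discrete $\hat g$ is a point estimate; no uncertainty intervals for
  $g$ or $\hat\pi$ are provided.
* MAF-dependent specifications of the ABF prior variance $W$ are out of
  scope; $W$ is a single constant per analysis.

## A minimal end-to-end run

```{r pipeline, eval = FALSE}
sim <- simulate_summary(sim_config(m = 20000, pi_true = 0.05,
                                   g_spec = g_point_masses(0.15), seed = 61))
fit <- fit_prior(sim$summaries)
fit$prior            # estimated pi and moments of g
tab <- rank_table(sim$summaries, abf_prior(), fit$prior)
head(tab[order(tab$rank_spebf), ])
evaluate_recovery(fit$prior, sim$truth)
```

The same pipeline from a shell:

```sh
spebf simulate --m 20000 --pi 0.05 --g point_masses:0.15;1 --seed 61 --out sim.tsv
spebf fit --in sim.tsv --prior-out prior.tsv
spebf score --in sim.tsv --prior prior.tsv --decision-R 1 \
    --prior-odds from_fit --out scores.tsv
```
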