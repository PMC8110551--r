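#' Effect-size distribution specifications
#'
#' Constructors for the non-null effect-size distribution g used by
#' [simulate_summary()] and [evaluate_recovery()].  Each returns a list with
#' a sampler `r(n)`, a vectorized CDF `cdf(x)`, exact `mean` and `sd`, a
#' plotting/integration `support` range, and `knots` (jump points, for
#' discrete components).
#'
#' @param mean,sd normal mean and standard deviation (sd > 0).
#' @return A list of class `spebf_g`.
#' @rdname g_spec
#' @export
g_normal <- function(mean = 0, sd = 0.05) {
  stopifnot(is.finite(mean), is.finite(sd), sd > 0)
  structure(list(
    type = "normal", params = list(mean = mean, sd = sd),
    r = function(n) rnorm(n, mean, sd),
    cdf = function(x) pnorm(x, mean, sd),
    mean = mean, sd = sd,
    support = c(mean - 8 * sd, mean + 8 * sd),
    knots = numeric(0)), class = "spebf_g")
}

#' @param location,scale Laplace location and scale (scale > 0); the sd is
#'   `sqrt(2) * scale`.
#' @rdname g_spec
#' @export
g_laplace <- function(location = 0, scale = 0.05) {
  stopifnot(is.finite(location), is.finite(scale), scale > 0)
  structure(list(
    type = "laplace", params = list(location = location, scale = scale),
    r = function(n) {
      # inverse-CDF draw from U(-1/2, 1/2)
      u <- runif(n) - 0.5
      location - scale * sign(u) * log1p(-2 * abs(u))
    },
    cdf = function(x) {
      q <- (x - location) / scale
      ifelse(q < 0, 0.5 * exp(q), 1 - 0.5 * exp(-q))
    },
    mean = location, sd = sqrt(2) * scale,
    support = c(location - 12 * scale, location + 12 * scale),
    knots = numeric(0)), class = "spebf_g")
}

#' @param locations,weights point-mass locations and simplex weights.
#' @rdname g_spec
#' @export
g_point_masses <- function(locations, weights = rep(1, length(locations))) {
  stopifnot(length(locations) >= 1L, length(weights) == length(locations),
            all(is.finite(locations)), all(is.finite(weights)),
            all(weights >= 0), sum(weights) > 0)
  weights <- weights / sum(weights)
  mu <- sum(weights * locations)
  sdv <- sqrt(max(0, sum(weights * locations^2) - mu^2))
  structure(list(
    type = "point_masses", params = list(locations = locations, weights = weights),
    r = function(n) sample(locations, n, replace = TRUE, prob = weights),
    cdf = function(x) vapply(x, function(xi) sum(weights[locations <= xi]),
                             numeric(1)),
    mean = mu, sd = sdv,
    support = range(locations) + c(-1, 1) * max(0.1, diff(range(locations))),
    knots = sort(locations)), class = "spebf_g")
}

#' @param components list of `spebf_g` objects; `weights` their simplex
#'   mixing weights.  Asymmetric mixtures are the intended use.
#' @rdname g_spec
#' @export
g_mixture <- function(components, weights) {
  stopifnot(is.list(components), length(components) >= 1L,
            all(vapply(components, inherits, logical(1), "spebf_g")),
            length(weights) == length(components),
            all(weights >= 0), sum(weights) > 0)
  weights <- weights / sum(weights)
  mu <- sum(weights * vapply(components, `[[`, numeric(1), "mean"))
  m2 <- sum(weights * vapply(components, function(g) g$sd^2 + g$mean^2,
                             numeric(1)))
  structure(list(
    type = "mixture", params = list(components = components, weights = weights),
    r = function(n) {
      k <- sample.int(length(components), n, replace = TRUE, prob = weights)
      out <- numeric(n)
      for (i in seq_along(components)) {
        idx <- which(k == i)
        if (length(idx)) out[idx] <- components[[i]]$r(length(idx))
      }
      out
    },
    cdf = function(x) {
      out <- 0
      for (i in seq_along(components))
        out <- out + weights[i] * components[[i]]$cdf(x)
      out
    },
    mean = mu, sd = sqrt(max(0, m2 - mu^2)),
    support = range(vapply(components, `[[`, numeric(2), "support")),
    knots = sort(unlist(lapply(components, `[[`, "knots")))), class = "spebf_g")
}

#' Simulation configuration
#'
#' Defaults emulate the scale of a bipolar-disorder GWAS meta-analysis
#' (7482 cases, 9250 controls); per-SNP sampling variances follow the
#' standard 2x2-table log odds ratio approximation
#' \eqn{V = (1/n_{case} + 1/n_{control}) / (2 f (1-f))} at MAF \eqn{f}.
#'
#' @param m number of SNPs.
#' @param pi_true non-null proportion in \[0, 1\].
#' @param g_spec a `spebf_g` effect-size distribution.
#' @param n_case,n_control case/control counts.
#' @param maf_min,maf_max MAF drawn uniformly on this range.
#' @param seed integer RNG seed.
#' @return A list of class `spebf_sim_config`.
#' @export
sim_config <- function(m, pi_true, g_spec = g_normal(), n_case = 7482L,
                       n_control = 9250L, maf_min = 0.05, maf_max = 0.5,
                       seed = 1L) {
  stopifnot(m >= 1L, pi_true >= 0, pi_true <= 1, inherits(g_spec, "spebf_g"),
            n_case >= 1L, n_control >= 1L,
            maf_min > 0, maf_max <= 0.5, maf_min < maf_max)
  structure(list(m = as.integer(m), pi_true = pi_true, g_spec = g_spec,
                 n_case = as.integer(n_case), n_control = as.integer(n_control),
                 maf_min = maf_min, maf_max = maf_max, seed = as.integer(seed)),
            class = "spebf_sim_config")
}

#' Simulate GWAS summary statistics with known truth
#'
#' Per SNP: draw the null/non-null indicator with probability `pi_true`;
#' draw the true log odds ratio from `g_spec` if non-null (0 otherwise);
#' draw MAF uniformly; set V from MAF and the case/control counts; draw
#' `beta_hat ~ N(beta, V)`; compute the two-sided Wald P.  Draws are made in
#' a fixed order (null flags, effects, MAFs, noise) from a single seeded
#' generator, so output is byte-reproducible from the seed.
#'
#' @param cfg a [sim_config()].
#' @return A list with `summaries` (a [summary_table()]) and `truth`
#'   (per-SNP `beta`, `is_null`, plus `pi_true` and the `g` object).
#' @export
simulate_summary <- function(cfg) {
  stopifnot(inherits(cfg, "spebf_sim_config"))
  set.seed(cfg$seed)
  m <- cfg$m
  is_null <- runif(m) >= cfg$pi_true
  beta <- cfg$g_spec$r(m)
  beta[is_null] <- 0
  maf <- runif(m, cfg$maf_min, cfg$maf_max)
  v <- (1 / cfg$n_case + 1 / cfg$n_control) / (2 * maf * (1 - maf))
  beta_hat <- rnorm(m, beta, sqrt(v))
  z <- beta_hat / sqrt(v)
  df <- data.frame(
    snp_id = sprintf("snp%07d", seq_len(m)), chrom = "1", pos = seq_len(m),
    beta_hat = beta_hat, var = v, z = z, p = 2 * pnorm(-abs(z)), maf = maf,
    stringsAsFactors = FALSE)
  summaries <- summary_table(df, provenance = list(
    path = "<simulated>", config = cfg))
  truth <- list(beta = beta, is_null = is_null, pi_true = cfg$pi_true,
                g = cfg$g_spec, config = cfg)
  list(summaries = summaries, truth = truth)
}

# Wasserstein-1 between a discrete distribution (t, p) and a spebf_g truth:
# integral of |F_fit - F_true| over a merged knot grid, midpoint rule
# (exact when both CDFs are step functions with jumps on the grid).
.w1_discrete_vs_g <- function(t, p, g) {
  lo <- min(c(t, g$support[1], g$knots))
  hi <- max(c(t, g$support[2], g$knots))
  xs <- sort(unique(c(seq(lo, hi, length.out = 4001L), t, g$knots)))
  mid <- (xs[-1] + xs[-length(xs)]) / 2
  f_fit <- c(0, cumsum(p))[findInterval(mid, t) + 1L]
  f_true <- g$cdf(mid)
  sum(diff(xs) * abs(f_fit - f_true))
}

#' Score recovery of the prior against simulation truth
#'
#' Quantifies how well a fitted prior reproduces the generating one:
#' the error in the non-null proportion, the Wasserstein-1 distance between
#' the fitted discrete g and the true g, and their first two moments.
#'
#' @param fitted a [nonparam_prior()] (e.g. `fit_prior(...)$prior`).
#' @param truth the `truth` element returned by [simulate_summary()].
#' @return A list with `pi_hat`, `pi_true`, `pi_error`, `wasserstein1`,
#'   `mean_fit`, `mean_true`, `sd_fit`, `sd_true`.
#' @export
evaluate_recovery <- function(fitted, truth) {
  stopifnot(inherits(fitted, "spebf_np_prior"), inherits(truth$g, "spebf_g"))
  mu <- sum(fitted$p * fitted$t)
  sdv <- sqrt(max(0, sum(fitted$p * fitted$t^2) - mu^2))
  list(pi_hat = fitted$pi, pi_true = truth$pi_true,
       pi_error = fitted$pi - truth$pi_true,
       wasserstein1 = .w1_discrete_vs_g(fitted$t, fitted$p, truth$g),
       mean_fit = mu, mean_true = truth$g$mean,
       sd_fit = sdv, sd_true = truth$g$sd)
}
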