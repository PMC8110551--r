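#' Discretized nonparametric effect-size prior
#'
#' The non-null effect-size distribution g is represented by mass-point
#' probabilities `p` at grid points `t` (which exclude zero: the null's
#' point mass at 0 is carried separately by `1 - pi`), together with `pi`,
#' the prior probability of non-null association.
#'
#' @param t strictly increasing grid of mass points, none equal to zero.
#' @param p nonnegative masses summing to 1 (within 1e-8; renormalized).
#' @param pi prior probability of H1, in \[0, 1\].
#' @return A list of class `spebf_np_prior` with elements `t`, `p`, `pi`.
#' @export
nonparam_prior <- function(t, p, pi) {
  stopifnot(is.numeric(t), is.numeric(p), length(t) == length(p),
            length(t) >= 2L)
  if (any(!is.finite(t)) || any(!is.finite(p)))
    stop("nonparam_prior: non-finite t or p")
  if (is.unsorted(t, strictly = TRUE))
    stop("nonparam_prior: t must be strictly increasing")
  if (any(t == 0)) stop("nonparam_prior: grid must exclude 0")
  if (any(p < 0)) stop("nonparam_prior: masses must be nonnegative")
  s <- sum(p)
  if (abs(s - 1) > 1e-8) stop("nonparam_prior: masses must sum to 1")
  p <- p / s
  if (!is.finite(pi) || pi < 0 || pi > 1)
    stop("nonparam_prior: pi must lie in [0, 1]")
  structure(list(t = t, p = p, pi = pi), class = "spebf_np_prior")
}

#' @export
print.spebf_np_prior <- function(x, ...) {
  mu <- sum(x$p * x$t)
  sdv <- sqrt(max(0, sum(x$p * x$t^2) - mu^2))
  cat(sprintf(
    "Nonparametric effect-size prior: B = %d mass points on [%.4g, %.4g]\n",
    length(x$t), min(x$t), max(x$t)))
  cat(sprintf("  pi (non-null proportion) = %.4g; mean(g) = %.4g, sd(g) = %.4g\n",
              x$pi, mu, sdv))
  invisible(x)
}

#' Build a symmetric mass-point grid excluding zero
#'
#' `B` (even) points, equally spaced on `[-L, L]` with
#' `L = span_factor * max(|beta_hat|)`, placed so 0 falls exactly midway
#' between the two central points — zero is excluded by construction.
#'
#' @param summaries a `spebf_summary` table, or a numeric vector of effect
#'   estimates.
#' @param B even number of grid points, >= 2.
#' @param span_factor multiple of `max(|beta_hat|)` used as the half-range.
#' @return Numeric grid of length `B`.
#' @export
make_grid <- function(summaries, B = 200L, span_factor = 1.2) {
  beta <- if (is.numeric(summaries)) summaries else summaries$beta_hat
  stopifnot(length(beta) >= 1L, is.finite(span_factor), span_factor > 0)
  B <- as.integer(B)
  if (B < 2L || B %% 2L != 0L)
    stop("make_grid: B must be an even integer >= 2")
  L <- span_factor * max(abs(beta))
  if (L == 0) stop("make_grid: all effect estimates are zero; grid degenerate")
  d <- 2 * L / B
  half <- d * (seq_len(B %/% 2L) - 0.5)
  c(-rev(half), half)
}

# per-SNP log of sum_k p_k * phi(beta; t_k, V); chunked log-sum-exp.
# Independent pure-R path: the EM in src/em.cpp never calls this.
log_f1_np <- function(beta_hat, var, t, p, chunk = 4096L) {
  m <- max(length(beta_hat), length(var))
  beta_hat <- rep_len(beta_hat, m)
  lp <- ifelse(p > 0, log(p), -Inf)
  out <- numeric(m)
  sdv <- rep_len(sqrt(var), m)
  for (lo in seq(1L, m, by = chunk)) {
    hi <- min(lo + chunk - 1L, m)
    idx <- lo:hi
    A <- vapply(seq_along(t), function(k)
      lp[k] + dnorm(beta_hat[idx], t[k], sdv[idx], log = TRUE),
      numeric(length(idx)))
    if (length(idx) == 1L) A <- matrix(A, nrow = 1L)
    # row maxima by pmax reduction (max.col mishandles -Inf entries)
    rmax <- A[, 1L]
    for (k in seq_along(t)[-1L]) rmax <- pmax(rmax, A[, k])
    lse <- rep(-Inf, length(idx))
    fin <- is.finite(rmax)
    if (any(fin))
      lse[fin] <- rmax[fin] + log(rowSums(exp(A[fin, , drop = FALSE] - rmax[fin])))
    out[idx] <- lse
  }
  out
}

#' Marginal log-likelihood of the two-group mixture
#'
#' \deqn{\sum_j \log\left[(1-\pi)\varphi(\hat\beta_j; 0, V_j) +
#'   \pi \sum_k \varphi(\hat\beta_j; t_k, V_j)\, p_k\right]}
#' evaluated with log-sum-exp stabilization.
#'
#' @param summaries a `spebf_summary` table (or data.frame with `beta_hat`,
#'   `var`).
#' @param prior a [nonparam_prior()].
#' @return Scalar log-likelihood.
#' @export
mixture_loglik <- function(summaries, prior) {
  stopifnot(inherits(prior, "spebf_np_prior"))
  b <- summaries$beta_hat; v <- summaries$var
  l0 <- dnorm(b, 0, sqrt(v), log = TRUE)
  if (prior$pi == 0) return(sum(l0))
  lf1 <- log_f1_np(b, v, prior$t, prior$p)
  if (prior$pi == 1) return(sum(lf1))
  a0 <- log1p(-prior$pi) + l0
  a1 <- log(prior$pi) + lf1
  mx <- pmax(a0, a1)
  sum(mx + log(exp(a0 - mx) + exp(a1 - mx)))
}

#' Configuration for the smoothing-and-roughening EM
#'
#' @param grid_size even number of mass points B (default 200).
#' @param span_factor grid half-range as a multiple of `max(|beta_hat|)`.
#' @param pi_init starting value of the non-null proportion.
#' @param max_iter maximum EM iterations.
#' @param tol relative change in the post-M-step log-likelihood declaring
#'   convergence (tested only once smoothing is inactive).
#' @param smooth_h0 initial Gaussian smoothing bandwidth; `"auto"` uses
#'   (grid range)/20.  Set 0 to disable smoothing (plain EM / NPMLE).
#' @param smooth_decay geometric decay of the bandwidth per iteration.
#' @param smooth_iters number of initial iterations with smoothing active.
#' @param var_range fitting is restricted to SNPs with `var` inside this
#'   range (numerical hygiene; excluded SNPs are still scored later).
#' @return A list of class `spebf_fit_config`.
#' @export
fit_config <- function(grid_size = 200L, span_factor = 1.2, pi_init = 0.01,
                       max_iter = 500L, tol = 1e-8, smooth_h0 = "auto",
                       smooth_decay = 0.9, smooth_iters = 50L,
                       var_range = c(1e-8, 1e2)) {
  stopifnot(pi_init > 0, pi_init < 1, max_iter >= 1L, tol > 0,
            smooth_decay > 0, smooth_decay <= 1, smooth_iters >= 0L,
            length(var_range) == 2L, var_range[1] < var_range[2])
  if (!identical(smooth_h0, "auto"))
    stopifnot(is.numeric(smooth_h0), smooth_h0 >= 0)
  structure(list(grid_size = as.integer(grid_size), span_factor = span_factor,
                 pi_init = pi_init, max_iter = as.integer(max_iter), tol = tol,
                 smooth_h0 = smooth_h0, smooth_decay = smooth_decay,
                 smooth_iters = as.integer(smooth_iters),
                 var_range = var_range),
            class = "spebf_fit_config")
}

#' Fit the nonparametric prior by smoothing-and-roughening EM
#'
#' Estimates `(t, p, pi)` of the two-group mixture by an EM whose M-step
#' update of the masses is followed, during the first `smooth_iters`
#' iterations, by a Gaussian-kernel smoothing of the masses on the grid with
#' geometrically decaying bandwidth.  Early smoothing regularizes the
#' otherwise spiky nonparametric MLE; once smoothing switches off the
#' iterations are plain EM and the recorded log-likelihood (always taken at
#' the post-M-step, pre-smoothing parameters) is non-decreasing.
#'
#' @param summaries a `spebf_summary` table (>= 100 records recommended: the
#'   estimator relies on genome-scale parallel structure).
#' @param config a [fit_config()].
#' @return A list of class `spebf_fit` with elements `prior`
#'   (a [nonparam_prior()]) and `diagnostics` (log-likelihood trace, pi
#'   trace, smoothing schedule, convergence flag, config echo).
#'   `loglik_trace[i]` is the marginal log-likelihood of the parameters
#'   entering iteration i; the returned prior is the model of the final
#'   iteration, so the last trace entry is its exact log-likelihood.
#' @export
fit_prior <- function(summaries, config = fit_config()) {
  stopifnot(inherits(config, "spebf_fit_config"))
  b_all <- summaries$beta_hat; v_all <- summaries$var
  if (length(b_all) < 100L)
    warning("fit_prior: fewer than 100 SNPs; the estimate of g will be poor")
  ok <- is.finite(b_all) & is.finite(v_all) &
    v_all >= config$var_range[1] & v_all <= config$var_range[2]
  if (!all(ok))
    warning("fit_prior: excluding ", sum(!ok),
            " SNP(s) with var outside [", config$var_range[1], ", ",
            config$var_range[2], "] from fitting (they are still scorable)")
  b <- b_all[ok]; v <- v_all[ok]
  if (length(b) < 2L) stop("fit_prior: too few usable SNPs")

  t <- make_grid(b, B = config$grid_size, span_factor = config$span_factor)
  h0 <- if (identical(config$smooth_h0, "auto")) diff(range(t)) / 20
        else config$smooth_h0
  h_sched <- h0 * config$smooth_decay^(seq_len(config$max_iter) - 1)
  if (config$smooth_iters < config$max_iter)
    h_sched[seq(config$smooth_iters + 1L, config$max_iter)] <- 0

  fit <- em_fit_cpp(b, v, t, config$pi_init, h_sched,
                    config$max_iter, config$tol)

  prior <- nonparam_prior(t, fit$p, fit$pi)
  diagnostics <- structure(list(
    loglik_trace = fit$loglik_trace,
    n_iter = fit$n_iter,
    converged = fit$converged,
    smoothing_schedule = h_sched[seq_len(fit$n_iter)],
    pi_trace = fit$pi_trace,
    n_fit = length(b), n_excluded = sum(!ok),
    config_echo = config), class = "spebf_fit_diagnostics")
  structure(list(prior = prior, diagnostics = diagnostics),
            class = "spebf_fit")
}

#' @export
print.spebf_fit <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf(
    "smoothing-and-roughening EM fit: %d iterations (%s), loglik %.4f\n",
    d$n_iter, if (d$converged) "converged" else "max_iter reached",
    d$loglik_trace[d$n_iter]))
  print(x$prior)
  invisible(x)
}

#' Serialize a fitted prior to TSV
#'
#' Two columns `t`, `p` preceded by a `#pi=<value>` header line.
#' @param prior a [nonparam_prior()].
#' @param path output path.
#' @export
write_prior <- function(prior, path) {
  stopifnot(inherits(prior, "spebf_np_prior"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#pi=%.17g", prior$pi), con)
  writeLines("t\tp", con)
  writeLines(sprintf("%.17g\t%.17g", prior$t, prior$p), con)
  invisible(NULL)
}

#' Read a fitted prior written by [write_prior()]
#' @param path file path.
#' @return A [nonparam_prior()].
#' @export
read_prior <- function(path) {
  lines <- readLines(path)
  piline <- grep("^#pi=", lines, value = TRUE)
  if (length(piline) != 1L) stop("read_prior: missing #pi= header in ", path)
  pi <- as.numeric(sub("^#pi=", "", piline))
  dat <- read.table(text = lines[!startsWith(lines, "#")], header = TRUE)
  nonparam_prior(dat$t, dat$p, pi)
}
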