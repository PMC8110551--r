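#' Normal effect-size prior for the approximate Bayes factor
#'
#' The ABF places a \eqn{N(0, W)} prior on the log odds ratio.  The default
#' \eqn{W = 0.21^2} encodes a 95\% belief that the odds ratio lies within
#' 1/1.5 to 1.5.
#'
#' @param W prior variance, > 0 (W = 0 is allowed and makes the ABF
#'   identically 1: H1 degenerates to H0).
#' @param provenance how W was chosen ("fixed", or set by
#'   [w_from_or_interval()]).
#' @return A list of class `spebf_abf_prior`.
#' @export
abf_prior <- function(W = 0.21^2, provenance = list(kind = "fixed")) {
  stopifnot(is.numeric(W), length(W) == 1L, is.finite(W), W >= 0)
  structure(list(W = W, provenance = provenance), class = "spebf_abf_prior")
}

#' @export
print.spebf_abf_prior <- function(x, ...) {
  cat(sprintf("ABF prior N(0, W): W = %.6g (sd %.4g), %s\n",
              x$W, sqrt(x$W), x$provenance$kind))
  invisible(x)
}

#' Prior variance W from a symmetric odds-ratio belief interval
#'
#' Solves for W such that a `coverage` central interval of the N(0, W)
#' effect-size prior maps to odds ratios in `[1/or_upper, or_upper]`:
#' \deqn{W = \left(\log(\mathrm{OR}_u) / \Phi^{-1}((1+c)/2)\right)^2.}
#' With `or_upper = 1.5`, `coverage = 0.95` this gives sd(W) = 0.2069,
#' conventionally rounded to 0.21.
#'
#' @param or_upper upper odds-ratio bound, > 1.
#' @param coverage central prior coverage of the interval, in (0, 1).
#' @return An [abf_prior()] with provenance `"or_interval"`.
#' @export
w_from_or_interval <- function(or_upper, coverage = 0.95) {
  if (!is.finite(or_upper) || or_upper <= 1)
    stop("w_from_or_interval: or_upper must exceed 1")
  if (!is.finite(coverage) || coverage <= 0 || coverage >= 1)
    stop("w_from_or_interval: coverage must lie in (0, 1)")
  W <- (log(or_upper) / qnorm((1 + coverage) / 2))^2
  abf_prior(W, provenance = list(kind = "or_interval", or_upper = or_upper,
                                 coverage = coverage))
}

#' Wakefield's approximate Bayes factor
#'
#' Closed form of the ratio of the sampling density of \eqn{\hat\beta} under
#' H0 to its marginal density under H1 with a \eqn{N(0, W)} effect-size
#' prior:
#' \deqn{\mathrm{ABF} = \sqrt{\frac{V+W}{V}}
#'   \exp\left(-\frac{z^2}{2}\,\frac{W}{V+W}\right), \quad z = \hat\beta/\sqrt V.}
#' Small values favor association.  Computed in log space; use
#' `log10 = TRUE` to obtain `log10(ABF)` directly when values underflow.
#'
#' @param beta_hat effect estimate(s), log odds ratio units.
#' @param var positive sampling variance(s) of `beta_hat`.
#' @param prior an [abf_prior()].
#' @param log10 return log10(ABF) instead of ABF.
#' @return Numeric vector of Bayes factors (or their log10).
#' @examples
#' abf(0.271, derive_var_from_p(0.271, 6.97e-10))  # ~5.5e-8 range
#' @export
abf <- function(beta_hat, var, prior = abf_prior(), log10 = FALSE) {
  if (any(!is.finite(var)) || any(var <= 0))
    stop("abf: var must be positive and finite")
  W <- prior$W
  z2 <- beta_hat^2 / var
  log_abf <- 0.5 * log1p(W / var) - (z2 / 2) * (W / (var + W))
  if (log10) log_abf / log(10) else exp(log_abf)
}
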