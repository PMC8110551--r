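#' Semi-parametric empirical Bayes factor
#'
#' The ratio of the null sampling density of \eqn{\hat\beta} to its marginal
#' density under H1 with the fitted discrete effect-size prior:
#' \deqn{\mathrm{SPEBF}(\hat\beta) = \frac{\varphi(\hat\beta; 0, V)}
#'   {\sum_k \varphi(\hat\beta; t_k, V)\, \hat p_k}.}
#' Small values favor association.  Computed in log space; if the
#' denominator underflows even in log space (all prior mass numerically
#' outside the support of \eqn{\hat\beta}) the value is `+Inf` with a
#' warning, never a silent `NaN`.
#'
#' @param beta_hat effect estimate(s).
#' @param var positive sampling variance(s).
#' @param prior a [nonparam_prior()] (only `t` and `p` are used).
#' @param log10 return log10(SPEBF) instead of SPEBF.
#' @return Numeric vector of Bayes factors (or their log10).
#' @export
spebf <- function(beta_hat, var, prior, log10 = FALSE) {
  stopifnot(inherits(prior, "spebf_np_prior"))
  if (any(!is.finite(var)) || any(var <= 0))
    stop("spebf: var must be positive and finite")
  lf0 <- dnorm(beta_hat, 0, sqrt(var), log = TRUE)
  lf1 <- log_f1_np(beta_hat, var, prior$t, prior$p)
  bad <- !is.finite(lf1)
  if (any(bad))
    warning("spebf: denominator underflowed for ", sum(bad),
            " SNP(s); returning +Inf (no prior support near beta_hat)")
  lbf <- lf0 - lf1
  lbf[bad] <- Inf
  if (log10) lbf / log(10) else exp(lbf)
}

#' Posterior probability of the null hypothesis
#'
#' \deqn{\Pr(H_0 \mid \hat\beta) = \frac{(1-\pi) f_0(\hat\beta)}
#'   {(1-\pi) f_0(\hat\beta) + \pi \hat f_1(\hat\beta)},}
#' the local-false-discovery-rate analog; algebraically equal to
#' `BF * prior_odds / (1 + BF * prior_odds)` with prior odds
#' \eqn{(1-\pi)/\pi}.
#'
#' @inheritParams spebf
#' @return Probabilities in \[0, 1\].
#' @export
posterior_null_prob <- function(beta_hat, var, prior) {
  stopifnot(inherits(prior, "spebf_np_prior"))
  if (prior$pi <= 0 || prior$pi >= 1)
    stop("posterior_null_prob: requires 0 < pi < 1 in the prior")
  lf0 <- dnorm(beta_hat, 0, sqrt(var), log = TRUE)
  lf1 <- log_f1_np(beta_hat, var, prior$t, prior$p)
  a0 <- log1p(-prior$pi) + lf0
  a1 <- log(prior$pi) + lf1
  out <- plogis(a0 - a1)
  out[!is.finite(a1)] <- 1  # no H1 support: posterior mass entirely on H0
  out
}

#' Decision-rule configuration
#'
#' @param R relative cost of a false negative to a false positive,
#'   \eqn{R = c_{FN}/c_{FP}}, > 0.
#' @param prior_odds prior odds \eqn{\Pr(H_0)/\Pr(H_1)} (> 0), or the string
#'   `"from_fit"` to use \eqn{(1-\hat\pi)/\hat\pi} from a fitted prior at
#'   decision time.
#' @return A list of class `spebf_decision_config`.
#' @export
decision_config <- function(R = 1, prior_odds = 1) {
  stopifnot(is.numeric(R), length(R) == 1L, is.finite(R), R > 0)
  if (!identical(prior_odds, "from_fit"))
    stopifnot(is.numeric(prior_odds), length(prior_odds) == 1L,
              is.finite(prior_odds), prior_odds > 0)
  structure(list(R = R, prior_odds = prior_odds),
            class = "spebf_decision_config")
}

#' Bayesian decision rule
#'
#' Rejects H0 when `bf < R / prior_odds` (strict inequality): equivalently,
#' when the posterior odds of H0 fall below the relative cost R.
#'
#' @param bf Bayes factor(s) (ABF or SP-EBF).
#' @param cfg a [decision_config()].
#' @param np optional fitted [nonparam_prior()], required when
#'   `cfg$prior_odds == "from_fit"`.
#' @return Logical vector: `TRUE` = reject H0.
#' @export
decide <- function(bf, cfg = decision_config(), np = NULL) {
  stopifnot(inherits(cfg, "spebf_decision_config"))
  prior_odds <- cfg$prior_odds
  if (identical(prior_odds, "from_fit")) {
    if (is.null(np)) stop("decide: prior_odds = 'from_fit' needs a fitted prior")
    if (np$pi <= 0 || np$pi >= 1)
      stop("decide: fitted pi is degenerate; supply prior_odds explicitly")
    prior_odds <- (1 - np$pi) / np$pi
  }
  bf < cfg$R / prior_odds
}

# rank ascending by value with deterministic (chrom, pos, snp_id) tie-break
.rank_by <- function(value, chrom, pos, snp_id) {
  ord <- order(value, chrom, pos, snp_id)
  r <- integer(length(value))
  r[ord] <- seq_along(ord)
  r
}

#' Per-SNP Bayes-factor table with rankings
#'
#' Joins each SNP's summary record with its ABF, SP-EBF and posterior null
#' probability, and ranks the SNPs by P value, ABF and SP-EBF (rank 1 = most
#' significant, i.e. smallest value; ties broken by chrom, pos, snp_id).
#' All SNPs are scored, including any that were excluded from prior fitting:
#' the prior is fixed at scoring time.
#'
#' @param summaries a `spebf_summary` table.
#' @param abf_prior an [abf_prior()].
#' @param np a fitted [nonparam_prior()].
#' @return A data.frame of class `spebf_bf_table` with columns `snp_id`,
#'   `chrom`, `pos`, `beta_hat`, `var`, `z`, `p`, `maf` (if present), `abf`,
#'   `log10_abf`, `spebf`, `log10_spebf`, `post_null_prob`, `neg_log10_p`,
#'   `neg_log10_abf`, `neg_log10_spebf`, `rank_p`, `rank_abf`, `rank_spebf`.
#'   The `neg_log10_*` columns are the -log10 panels conventionally plotted
#'   genome-wide; [write_results()] writes its fixed 15-column schema
#'   without them.
#' @export
rank_table <- function(summaries, abf_prior = spebf::abf_prior(), np) {
  stopifnot(inherits(np, "spebf_np_prior"),
            inherits(abf_prior, "spebf_abf_prior"))
  df <- as.data.frame(summaries)
  if (is.null(df$p)) df$p <- 2 * pnorm(-abs(df$z))
  l10_abf <- abf(df$beta_hat, df$var, abf_prior, log10 = TRUE)
  l10_spebf <- spebf(df$beta_hat, df$var, np, log10 = TRUE)
  df$abf <- 10^l10_abf
  df$log10_abf <- l10_abf
  df$spebf <- 10^l10_spebf
  df$log10_spebf <- l10_spebf
  df$post_null_prob <- if (np$pi > 0 && np$pi < 1)
    posterior_null_prob(df$beta_hat, df$var, np) else NA_real_
  # -log10 panels for Manhattan-style plotting parity
  df$neg_log10_p <- -log10(df$p)
  df$neg_log10_abf <- -l10_abf
  df$neg_log10_spebf <- -l10_spebf
  df$rank_p <- .rank_by(df$p, df$chrom, df$pos, df$snp_id)
  df$rank_abf <- .rank_by(l10_abf, df$chrom, df$pos, df$snp_id)
  df$rank_spebf <- .rank_by(l10_spebf, df$chrom, df$pos, df$snp_id)
  structure(df, class = c("spebf_bf_table", "data.frame"))
}

#' @export
print.spebf_bf_table <- function(x, ...) {
  cat("Bayes-factor table:", nrow(x), "SNPs (rank 1 = most significant)\n")
  print(utils::head(as.data.frame(x)[order(x$rank_spebf), ]), ...)
  invisible(x)
}
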