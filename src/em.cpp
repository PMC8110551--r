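// Smoothing-and-roughening EM for the two-group GWAS mixture
//   f(b_j) = (1-pi) phi(b_j; 0, V_j) + pi sum_k p_k phi(b_j; t_k, V_j).
// The per-SNP x grid log-density matrix is precomputed once (it never
// changes across iterations); each iteration is then a single fused pass
// computing the E-step responsibilities AND the marginal log-likelihood at
// the parameters entering the iteration.  loglik_trace[i] is therefore the
// log-likelihood of the model used by iteration i's E-step; with smoothing
// disabled this is the standard monotone EM sequence.  The returned (p, pi)
// are the parameters of the final E-step, so the last trace entry is their
// exact log-likelihood.  Terms more than DROP nats below a row's maximum
// are skipped inside log-sum-exp (relative error < 3e-20 per term).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double DROP = 45.0;

// mass-conserving Gaussian-kernel smoothing of p on grid t, bandwidth h:
// each source mass p_l is redistributed with kernel weights normalized
// over destinations, then the result is renormalized against float drift.
static void smooth_masses(std::vector<double>& p, const NumericVector& t,
                          double h) {
  const int B = (int)p.size();
  std::vector<double> out(B, 0.0), w(B);
  const double inv2h2 = 1.0 / (2.0 * h * h);
  for (int l = 0; l < B; ++l) {
    if (p[l] <= 0.0) continue;
    double C = 0.0;
    for (int k = 0; k < B; ++k) {
      const double d = t[k] - t[l];
      w[k] = std::exp(-d * d * inv2h2);
      C += w[k];
    }
    const double scale = p[l] / C;
    for (int k = 0; k < B; ++k) out[k] += scale * w[k];
  }
  double s = 0.0;
  for (int k = 0; k < B; ++k) s += out[k];
  for (int k = 0; k < B; ++k) p[k] = out[k] / s;
}

// [[Rcpp::export]]
List em_fit_cpp(NumericVector beta_hat, NumericVector var, NumericVector t,
                double pi_init, NumericVector h_schedule, int max_iter,
                double tol) {
  const int m = beta_hat.size();
  const int B = t.size();
  if (B < 2) stop("em_fit_cpp: grid must have at least 2 points");
  if (var.size() != m) stop("em_fit_cpp: length mismatch");
  if (h_schedule.size() < max_iter) stop("em_fit_cpp: short smoothing schedule");

  // precompute log densities, row-contiguous m x B
  std::vector<double> Lt((size_t)m * B), l0(m);
  const double LOG2PI = std::log(2.0 * M_PI);
  for (int j = 0; j < m; ++j) {
    const double v = var[j];
    const double c = -0.5 * (LOG2PI + std::log(v));
    const double inv2v = 1.0 / (2.0 * v);
    const double b = beta_hat[j];
    l0[j] = c - b * b * inv2v;
    double* Lj = &Lt[(size_t)j * B];
    for (int k = 0; k < B; ++k) {
      const double d = b - t[k];
      Lj[k] = c - d * d * inv2v;
    }
  }

  std::vector<double> p(B, 1.0 / B), logp(B), s(B), wrow(B);
  double pi = pi_init;
  std::vector<double> ll_trace, pi_trace;
  ll_trace.reserve(max_iter);
  pi_trace.reserve(max_iter);
  bool converged = false;
  int iters = 0;

  for (int it = 0; it < max_iter; ++it) {
    const double lpi = (pi > 0.0) ? std::log(pi) : R_NegInf;
    const double l1p = (pi < 1.0) ? std::log1p(-pi) : R_NegInf;
    for (int k = 0; k < B; ++k)
      logp[k] = (p[k] > 0.0) ? lpi + std::log(p[k]) : R_NegInf;

    // fused pass: responsibilities and log-likelihood at (pi, p)
    std::fill(s.begin(), s.end(), 0.0);
    double sum_r1 = 0.0, ll = 0.0;
    for (int j = 0; j < m; ++j) {
      const double* Lj = &Lt[(size_t)j * B];
      const double a0 = l1p + l0[j];
      double mx = a0;
      for (int k = 0; k < B; ++k) {
        wrow[k] = logp[k] + Lj[k];
        if (wrow[k] > mx) mx = wrow[k];
      }
      if (!std::isfinite(mx))
        stop("fit_prior: non-finite likelihood at iteration %d", it + 1);
      double tot = 0.0;
      const double d0 = a0 - mx;
      const double e0 = (d0 > -DROP) ? std::exp(d0) : 0.0;
      tot += e0;
      for (int k = 0; k < B; ++k) {
        const double d = wrow[k] - mx;
        wrow[k] = (d > -DROP) ? std::exp(d) : 0.0;
        tot += wrow[k];
      }
      ll += mx + std::log(tot);
      const double inv = 1.0 / tot;
      sum_r1 += 1.0 - e0 * inv;
      for (int k = 0; k < B; ++k)
        if (wrow[k] > 0.0) s[k] += wrow[k] * inv;
    }
    if (!std::isfinite(ll))
      stop("fit_prior: non-finite likelihood at iteration %d", it + 1);
    ll_trace.push_back(ll);
    pi_trace.push_back(pi);
    iters = it + 1;

    // convergence on the log-likelihood change across one pure M-step:
    // requires that no smoothing perturbed the parameters in between
    if (it > 0 && h_schedule[it - 1] <= 0.0) {
      const double prev = ll_trace[it - 1];
      if (std::fabs(ll - prev) / std::max(std::fabs(prev), 1e-300) < tol) {
        converged = true;
        break;  // report the current (pi, p): ll is their log-likelihood
      }
    }
    if (it == max_iter - 1) break;  // report pre-M-step parameters

    // M-step
    const double pi_new = sum_r1 / m;
    double denom = 0.0;
    for (int k = 0; k < B; ++k) denom += s[k];
    std::vector<double> p_new(B);
    if (denom > 0.0) {
      for (int k = 0; k < B; ++k) p_new[k] = s[k] / denom;
    } else {
      p_new = p;  // no non-null mass assigned; masses unchanged
    }
    double psum = 0.0;
    for (int k = 0; k < B; ++k) {
      if (p_new[k] < 0.0)
        stop("fit_prior: negative mass at iteration %d", it + 1);
      psum += p_new[k];
    }
    if (std::fabs(psum - 1.0) > 1e-10)
      stop("fit_prior: masses left the simplex at iteration %d", it + 1);
    for (int k = 0; k < B; ++k) p_new[k] /= psum;
    if (pi_new < 0.0 || pi_new > 1.0)
      stop("fit_prior: pi outside [0,1] at iteration %d", it + 1);

    // smoothing step (the "roughening" happens as the bandwidth decays)
    const double h = h_schedule[it];
    if (h > 0.0) smooth_masses(p_new, t, h);
    p = p_new;
    pi = pi_new;

    if (it % 32 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["p"] = NumericVector(p.begin(), p.end()),
    _["pi"] = pi,
    _["loglik_trace"] = NumericVector(ll_trace.begin(), ll_trace.end()),
    _["pi_trace"] = NumericVector(pi_trace.begin(), pi_trace.end()),
    _["n_iter"] = iters,
    _["converged"] = converged);
}
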