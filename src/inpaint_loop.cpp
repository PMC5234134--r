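#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Full Gaussian-diffusion inpainting iteration, mirroring the R building
// blocks exactly (forward differences with trailing zero, their algebraic
// adjoint, momentum extrapolation, POCS re-insertion).  Kept in compiled
// code because the loop touches every sinogram bin hundreds of times.
// [[Rcpp::export(name = ".run_inpainting_cpp")]]
List run_inpainting_cpp(NumericMatrix x_ori, NumericMatrix prior,
                        NumericMatrix w, IntegerMatrix keep,
                        double lambda, double mu, double eta, int max_iter,
                        bool use_momentum, bool grad_at_extrapolated,
                        bool stop_norm_omega) {
  const int nr = x_ori.nrow(), nc = x_ori.ncol();
  const size_t n = (size_t)nr * nc;
  NumericMatrix x_prev(nr, nc), x_curr(nr, nc), x_next(nr, nc),
                x_bar(nr, nc), r(nr, nc), dv(nr, nc), dd(nr, nc),
                div(nr, nc);
  std::copy(x_ori.begin(), x_ori.end(), x_prev.begin());
  std::copy(x_ori.begin(), x_ori.end(), x_curr.begin());
  NumericVector rel_trace(max_iter), rel_trace_omega(max_iter),
                energy_trace(max_iter), trace_energy(max_iter);
  double t_k = 1.0;
  int k = 0;
  bool converged = false, zero_norm = false;
  double u0 = -1.0;
  int n_diverging = 0;

  // initial energy for the divergence guard
  {
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i)
        r(i, j) = x_ori(i, j) - mu * prior(i, j);
    double u = 0.0;
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        const double gv = (i < nr - 1) ? r(i + 1, j) - r(i, j) : 0.0;
        const double gd = (j < nc - 1) ? r(i, j + 1) - r(i, j) : 0.0;
        u += w(i, j) * (gv * gv + gd * gd);
      }
    u0 = 0.5 * u;
  }

  while (k < max_iter) {
    const double t_next = 0.5 * (1.0 + std::sqrt(1.0 + 4.0 * t_k * t_k));
    const double coef = use_momentum ? (t_k - 1.0) / t_next : 0.0;
    for (size_t q = 0; q < n; ++q)
      x_bar[q] = x_curr[q] + coef * (x_curr[q] - x_prev[q]);
    const NumericMatrix& gsrc = grad_at_extrapolated ? x_bar : x_curr;
    for (size_t q = 0; q < n; ++q) r[q] = gsrc[q] - mu * prior[q];
    // weighted forward-difference gradient of r
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        dv(i, j) = (i < nr - 1) ? w(i, j) * (r(i + 1, j) - r(i, j)) : 0.0;
        dd(i, j) = (j < nc - 1) ? w(i, j) * (r(i, j + 1) - r(i, j)) : 0.0;
      }
    // adjoint of the gradient
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        const double tv = (i > 0 ? dv(i - 1, j) : 0.0) - dv(i, j);
        const double td = (j > 0 ? dd(i, j - 1) : 0.0) - dd(i, j);
        div(i, j) = tv + td;
      }
    // gradient step from the momentum point, then POCS
    double nk2 = 0.0, diff2 = 0.0, nk2_om = 0.0, diff2_om = 0.0;
    for (size_t q = 0; q < n; ++q) {
      const double xt = x_bar[q] - lambda * div[q];
      x_next[q] = keep[q] == 1 ? x_ori[q] : xt;
      nk2 += x_curr[q] * x_curr[q];
      const double dq = x_next[q] - x_curr[q];
      diff2 += dq * dq;
      if (keep[q] == 0) { nk2_om += x_curr[q] * x_curr[q]; diff2_om += dq * dq; }
    }
    double rel;
    const double denom2 = stop_norm_omega ? nk2_om : nk2;
    const double num2 = stop_norm_omega ? diff2_om : diff2;
    if (denom2 == 0.0) { rel = 0.0; zero_norm = true; }
    else rel = std::sqrt(num2 / denom2);
    // energies at the new iterate
    double u = 0.0, te = 0.0;
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        const double rq = x_next(i, j) - mu * prior(i, j);
        const double gv = (i < nr - 1) ?
          (x_next(i + 1, j) - mu * prior(i + 1, j)) - rq : 0.0;
        const double gd = (j < nc - 1) ?
          (x_next(i, j + 1) - mu * prior(i, j + 1)) - rq : 0.0;
        u += w(i, j) * (gv * gv + gd * gd);
        if (keep(i, j) == 0) te += rq * rq;
      }
    u *= 0.5;
    rel_trace[k] = nk2 > 0.0 ? std::sqrt(diff2 / nk2) : 0.0;
    rel_trace_omega[k] = nk2_om > 0.0 ? std::sqrt(diff2_om / nk2_om) : 0.0;
    energy_trace[k] = u;
    trace_energy[k] = te;
    ++k;
    n_diverging = (u0 > 0.0 && u > 10.0 * u0) ? n_diverging + 1 : 0;
    if (n_diverging >= 20)
      stop("diffusion iteration diverged: energy exceeded 10x its initial value for 20 consecutive iterations");
    std::swap(x_prev, x_curr);
    std::swap(x_curr, x_next);
    t_k = t_next;
    if (rel < eta) { converged = true; break; }
  }
  return List::create(
    _["sinogram"] = x_curr,
    _["k"] = k,
    _["converged"] = converged,
    _["t_curr"] = t_k,
    _["zero_norm"] = zero_norm,
    _["rel_trace"] = rel_trace[Range(0, std::max(0, k - 1))],
    _["rel_trace_omega"] = rel_trace_omega[Range(0, std::max(0, k - 1))],
    _["energy_trace"] = energy_trace[Range(0, std::max(0, k - 1))],
    _["trace_energy"] = trace_energy[Range(0, std::max(0, k - 1))]);
}
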