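#include <Rcpp.h>
using namespace Rcpp;

// Euler–Maruyama first-passage times for a non-negative evidence
// accumulator with piecewise-constant input.
//
// Each row of `values` is one realisation of the input signal X(t);
// `breaks` are the (shared) segment onset times, breaks[0] == 0. The
// accumulator starts at `start_bias`, is clamped at zero after every step,
// and a leave is triggered the first time it exceeds `threshold`. Per-step
// noise s.d. is sigma*sqrt(dt) (Euler–Maruyama) unless `literal_noise`,
// which uses sigma per step verbatim.
// [[Rcpp::export]]
List ddm_first_passage_batch(NumericMatrix values, NumericVector breaks,
                             double horizon, double threshold,
                             double drift_gain, double noise_sd,
                             double start_bias, double dt,
                             bool literal_noise = false) {
  const int n = values.nrow();
  const int nseg = values.ncol();
  if (breaks.size() != nseg)
    stop("length(breaks) must equal ncol(values)");
  if (!(dt > 0) || !(horizon > 0))
    stop("dt and horizon must be positive");
  if (!R_finite(threshold) || !R_finite(drift_gain) || !R_finite(noise_sd) ||
      !R_finite(start_bias))
    stop("non-finite model parameter");

  NumericVector lt(n);
  LogicalVector censored(n);
  const double step_sd = literal_noise ? noise_sd : noise_sd * std::sqrt(dt);
  const int nsteps = (int)std::ceil(horizon / dt - 1e-9);
  const bool noisy = noise_sd > 0;

  for (int i = 0; i < n; ++i) {
    double ea = start_bias;
    int seg = 0;
    bool crossed = ea > threshold;
    if (crossed) { lt[i] = 0.0; censored[i] = false; continue; }
    for (int s = 0; s < nsteps; ++s) {
      double t = s * dt;
      while (seg + 1 < nseg && t >= breaks[seg + 1] - 1e-12) ++seg;
      double inc = (drift_gain - values(i, seg)) * dt;
      if (noisy) inc += step_sd * R::norm_rand();
      ea += inc;
      if (ea < 0.0) ea = 0.0;
      if (ea > threshold) {
        lt[i] = (s + 1) * dt;
        crossed = true;
        break;
      }
    }
    if (!crossed) { lt[i] = horizon; censored[i] = true; }
  }
  return List::create(_["leaving_time"] = lt, _["censored"] = censored);
}

// Full evidence trace for a single signal realisation (diagnostics /
// plotting). Returns the trace up to the first crossing or the horizon.
// [[Rcpp::export]]
List ddm_trace_cpp(NumericVector values, NumericVector breaks,
                   double horizon, double threshold, double drift_gain,
                   double noise_sd, double start_bias, double dt,
                   bool literal_noise = false) {
  const int nseg = values.size();
  if (breaks.size() != nseg) stop("length(breaks) must equal length(values)");
  const double step_sd = literal_noise ? noise_sd : noise_sd * std::sqrt(dt);
  const int nsteps = (int)std::ceil(horizon / dt - 1e-9);
  std::vector<double> ea_out;
  ea_out.reserve(nsteps + 1);
  double ea = start_bias;
  ea_out.push_back(ea);
  int seg = 0;
  bool crossed = ea > threshold;
  int s = 0;
  const bool noisy = noise_sd > 0;
  for (; s < nsteps && !crossed; ++s) {
    double t = s * dt;
    while (seg + 1 < nseg && t >= breaks[seg + 1] - 1e-12) ++seg;
    double inc = (drift_gain - values[seg]) * dt;
    if (noisy) inc += step_sd * R::norm_rand();
    ea += inc;
    if (ea < 0.0) ea = 0.0;
    ea_out.push_back(ea);
    if (ea > threshold) crossed = true;
  }
  NumericVector ea_vec(ea_out.begin(), ea_out.end());
  NumericVector times(ea_vec.size());
  for (int j = 0; j < times.size(); ++j) times[j] = j * dt;
  return List::create(_["times"] = times, _["ea"] = ea_vec,
                      _["leaving_time"] = crossed ? s * dt : horizon,
                      _["censored"] = !crossed);
}
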