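#include <Rcpp.h>
using namespace Rcpp;

// Single-spin Metropolis kernel shared by both entry points.
// Energy difference for flipping spin i, from the cached local field
// m_i = sum_j J_ij sigma_j (J_ii = 1, so the self-term is removed here):
//   dH = 2 sigma_i [ (2/Ns) (m_i - sigma_i) + h_i - h_b ]
// Acceptance: certain if dH <= 0, else with probability exp(-beta dH).
// Uses R's RNG so reproducibility flows from set.seed() on the R side.

static inline void local_fields(const NumericMatrix& J, const int* s,
                                double* m, int Ns) {
  for (int i = 0; i < Ns; ++i) {
    double acc = 0.0;
    for (int j = 0; j < Ns; ++j) acc += J(i, j) * s[j];
    m[i] = acc;
  }
}

static inline void sweep(const NumericMatrix& J, int* s, double* m,
                         const double* h, double h_b, double beta,
                         int Ns, int n_attempts) {
  for (int t = 0; t < n_attempts; ++t) {
    int i = (int)(unif_rand() * Ns);
    if (i >= Ns) i = Ns - 1;
    double si = (double)s[i];
    // m includes the self term J_ii * s_i; remove it (J_ii is 1 for the
    // standard kernel but 0 in the zero-recurrence control)
    double dH = 2.0 * si * ((2.0 / Ns) * (m[i] - J(i, i) * si) + h[i] - h_b);
    bool accept;
    if (dH <= 0.0) {
      accept = true;
    } else {
      double x = beta * dH;
      // acceptance probability below exp(-40) ~ 4e-18: reject outright
      accept = (x <= 40.0) && (unif_rand() < std::exp(-x));
    }
    if (accept) {
      s[i] = -s[i];
      double d = 2.0 * s[i];
      for (int j = 0; j < Ns; ++j) m[j] += d * J(j, i);
    }
  }
}

//' @noRd
// [[Rcpp::export]]
IntegerMatrix cpp_spin_equilibrate(IntegerMatrix states, NumericMatrix J,
                                   NumericMatrix h, double h_b, double beta,
                                   int n_attempts) {
  int Ns = states.nrow(), N = states.ncol();
  IntegerMatrix out = clone(states);
  std::vector<double> m(Ns);
  std::vector<int> s(Ns);
  std::vector<double> hv(Ns);
  for (int a = 0; a < N; ++a) {
    for (int i = 0; i < Ns; ++i) { s[i] = out(i, a); hv[i] = h(i, a); }
    local_fields(J, s.data(), m.data(), Ns);
    sweep(J, s.data(), m.data(), hv.data(), h_b, beta, Ns, n_attempts);
    for (int i = 0; i < Ns; ++i) out(i, a) = s[i];
  }
  return out;
}

// Summed Gaussian receptive fields on the ring, for all agents at once.
// delta and amp have length N*M (focal agent a slow, source m fast);
// delta[a*M + m] = frame origin of agent a minus world bearing of source m.
// H[i, a] += amp * pref * exp(-wrap(alpha_i + delta)^2 / (2 sigma^2)).
// Contributions smaller than exp(-40) of the peak are dropped.
//' @noRd
// [[Rcpp::export]]
NumericMatrix cpp_gauss_fields(NumericVector alpha, NumericVector delta,
                               NumericVector amp, int N, int M,
                               double sigma, double pref) {
  int Ns = alpha.size();
  NumericMatrix H(Ns, N);
  double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double TWO_PI = 2.0 * M_PI;
  for (int a = 0; a < N; ++a) {
    double* col = &H(0, a);
    for (int m = 0; m < M; ++m) {
      double am = amp[a * M + m];
      if (am == 0.0) continue;
      double de = delta[a * M + m];
      double w = am * pref;
      for (int i = 0; i < Ns; ++i) {
        double d = alpha[i] + de;
        d -= TWO_PI * std::floor((d + M_PI) / TWO_PI);  // -> (-pi, pi]
        double x = d * d * inv2s2;
        if (x < 40.0) col[i] += w * std::exp(-x);
      }
    }
  }
  return H;
}

// Long-run sampler for small rings (Ns <= 20): runs the chain and counts
// visits to each of the 2^Ns states (bit i set <=> sigma_i == +1), sampling
// every `thin` attempts after `burn` attempts.
//' @noRd
// [[Rcpp::export]]
NumericVector cpp_spin_chain_counts(IntegerVector init, NumericMatrix J,
                                    NumericVector h, double h_b, double beta,
                                    double burn, double n_samples, int thin) {
  int Ns = init.size();
  if (Ns > 20) stop("state enumeration limited to Ns <= 20");
  std::vector<int> s(Ns);
  for (int i = 0; i < Ns; ++i) s[i] = init[i];
  std::vector<double> m(Ns);
  local_fields(J, s.data(), m.data(), Ns);
  std::vector<double> hv(h.begin(), h.end());
  long long nburn = (long long)burn;
  for (long long t = 0; t < nburn; ++t)
    sweep(J, s.data(), m.data(), hv.data(), h_b, beta, Ns, 1);
  NumericVector counts((int)1 << Ns);
  long long ns = (long long)n_samples;
  for (long long k = 0; k < ns; ++k) {
    sweep(J, s.data(), m.data(), hv.data(), h_b, beta, Ns, thin);
    unsigned idx = 0;
    for (int i = 0; i < Ns; ++i) if (s[i] > 0) idx |= (1u << i);
    counts[idx] += 1.0;
  }
  return counts;
}
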