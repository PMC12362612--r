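// Exact stochastic simulation (Gillespie direct method) over the encoded
// reaction tables. Uses R's RNG so that set.seed() in R makes trajectories
// reproducible. States are integer molecule counts; Hill and
// Michaelis-Menten propensities convert counts to concentrations via the
// system size omega.

#include <Rcpp.h>
using namespace Rcpp;

static inline double propensity(int type, double rate, int s1, int s2,
                                double K, double m, int act,
                                const std::vector<double>& x, double omega) {
  switch (type) {
  case 0: // zeroth order
    return rate * omega;
  case 1: { // Hill-gated zeroth order
    double y = x[s1] / omega;
    double ym = std::pow(y, m), Km = std::pow(K, m);
    double h = act ? ym / (Km + ym) : Km / (Km + ym);
    return rate * omega * h;
  }
  case 2: // first order
    return rate * x[s1];
  case 3: // bimolecular
    return rate * x[s1] * x[s2] / omega;
  case 4: { // Michaelis-Menten degradation, first order in the catalyst s1
    double y = x[s2] / omega;
    return rate * x[s1] * y / (y + K);
  }
  }
  return 0.0;
}

// [[Rcpp::export]]
List ssa_direct_cpp(NumericMatrix stoich, IntegerVector type,
                    NumericVector rate, IntegerVector s1, IntegerVector s2,
                    NumericVector K, NumericVector m, IntegerVector act,
                    NumericVector x0, NumericVector out_times, double omega) {
  const int nsp = stoich.nrow(), nr = stoich.ncol();
  const int nt = out_times.size();
  std::vector<double> x(x0.begin(), x0.end());
  NumericMatrix out(nt, nsp);
  std::vector<double> a(nr);

  RNGScope scope;
  double t = 0.0;
  int next_out = 0;
  const double t_end = out_times[nt - 1];
  bool absorbed = false;

  while (true) {
    double a0 = 0.0;
    for (int j = 0; j < nr; ++j) {
      a[j] = propensity(type[j], rate[j], s1[j], s2[j], K[j], m[j], act[j],
                        x, omega);
      a0 += a[j];
    }
    double t_next;
    if (a0 <= 0.0) { // absorbing state: hold until the end of the horizon
      absorbed = true;
      t_next = t_end + 1.0;
    } else {
      t_next = t + exp_rand() / a0;
    }
    while (next_out < nt && out_times[next_out] < t_next) {
      for (int i = 0; i < nsp; ++i) out(next_out, i) = x[i];
      ++next_out;
    }
    if (next_out >= nt) break;
    t = t_next;
    // pick the firing reaction
    double u = unif_rand() * a0, acc = 0.0;
    int j = nr - 1;
    for (int jj = 0; jj < nr; ++jj) {
      acc += a[jj];
      if (u <= acc) { j = jj; break; }
    }
    for (int i = 0; i < nsp; ++i) {
      x[i] += stoich(i, j);
      if (x[i] < 0) x[i] = 0; // defensive; propensities vanish at 0
    }
  }
  return List::create(_["states"] = out, _["absorbed"] = absorbed);
}
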