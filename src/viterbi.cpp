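#include <Rcpp.h>
using namespace Rcpp;

// Two-state Viterbi decoder for the wheel-marker HMM.
// States: 0 = bottom, 1 = top.  Emission model: P(obs | top) = p_top,
// P(obs | bottom) = 1 - p_top.  Log-space throughout; ties between staying
// and switching are broken toward staying in the current state.
// [[Rcpp::export(name = ".viterbi_core")]]
IntegerVector viterbi_core(NumericVector p_top, double p_stay,
                           NumericVector init) {
  const int n = p_top.size();
  if (n == 0) stop("empty emission sequence");
  const double eps = 1e-12;
  const double l_stay = std::log(p_stay);
  const double l_switch = std::log(1.0 - p_stay);

  std::vector<unsigned char> back_b(n), back_t(n);
  double clamped0 = std::min(std::max(p_top[0], eps), 1.0 - eps);
  double db = std::log(init[0]) + std::log(1.0 - clamped0);
  double dt = std::log(init[1]) + std::log(clamped0);

  for (int i = 1; i < n; ++i) {
    double p = std::min(std::max(p_top[i], eps), 1.0 - eps);
    double eb = std::log(1.0 - p);
    double et = std::log(p);
    // state bottom: stay from bottom vs switch from top (ties -> stay)
    double from_b = db + l_stay, from_t = dt + l_switch;
    double nb;
    if (from_b >= from_t) { nb = from_b + eb; back_b[i] = 0; }
    else                  { nb = from_t + eb; back_b[i] = 1; }
    // state top: stay from top vs switch from bottom
    double sfrom_t = dt + l_stay, sfrom_b = db + l_switch;
    double nt;
    if (sfrom_t >= sfrom_b) { nt = sfrom_t + et; back_t[i] = 1; }
    else                    { nt = sfrom_b + et; back_t[i] = 0; }
    db = nb; dt = nt;
  }

  IntegerVector path(n);
  int s = (dt >= db) ? 1 : 0;  // final tie -> top (arbitrary but fixed)
  path[n - 1] = s;
  for (int i = n - 1; i > 0; --i) {
    s = (s == 0) ? back_b[i] : back_t[i];
    path[i - 1] = s;
  }
  return path;
}
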