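#include <Rcpp.h>
using namespace Rcpp;

// Two-state (active/rest) minute chain. All randomness is supplied from R
// (vector u of uniforms) so reproducibility rests entirely on R's RNG.
// p_enter[i]: P(active -> rest) at minute i; p_exit[i]: P(rest -> active).
// Returns 1 for active minutes, 0 for rest minutes. Chain starts active.
// [[Rcpp::export]]
IntegerVector two_state_path(NumericVector u, NumericVector p_enter,
                             NumericVector p_exit) {
  const int n = u.size();
  if (p_enter.size() != n || p_exit.size() != n)
    stop("u, p_enter and p_exit must have equal length");
  IntegerVector s(n);
  int state = 1;
  for (int i = 0; i < n; ++i) {
    if (state == 1) {
      if (u[i] < p_enter[i]) state = 0;
    } else {
      if (u[i] < p_exit[i]) state = 1;
    }
    s[i] = state;
  }
  return s;
}
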