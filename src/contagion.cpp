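#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Fixed-step explicit (Euler) integration of one arm of the contagion model.
//
// Cells are indexed 1..n_cells away from the seed (the first divider, SOP0),
// which sits at index 0, is never simulated, and is treated as divided at
// t = 0. For each undivided cell i:
//
//   dA_i/dt = r / (1 + I_i) - A_i / rho
//   dI_i/dt = mu * m_i(t)   - I_i / delta
//
// where m_i(t) counts the immediate undivided neighbours of i. Cell i
// divides at the first time A_i reaches theta; the division instant is
// located by linear interpolation within the step, and the divided cell is
// permanently removed from its neighbours' m counts from the following step
// on.
//
// Boundary: with open_end = false (the default used by the R wrapper) the
// distal cell behaves as if the row continued with a permanently undivided
// phantom neighbour, so every simulated cell starts with m = 2 and the arm
// behaves like the head of an infinite row; with open_end = true the distal
// cell has a single neighbour (m starts at 1) and can divide early, seeding
// a backward wave from the row end.
//
// Initial conditions: A_i(0) = 0 and I_i(0) = mu * delta * m_i(0-), the
// steady state of I with every cell (seed included) still undivided; the
// seed's division at t = 0 then drops m_1 by one.
//
// [[Rcpp::export]]
List simulate_arm_cpp(int n_cells, double r, double mu, double rho,
                      double delta, double theta, double dt, double t_max,
                      bool open_end, bool record, int record_every) {
  std::vector<double> A(n_cells, 0.0), I(n_cells), div_time(n_cells, NA_REAL);
  std::vector<bool> divided(n_cells, false);
  std::vector<int> m(n_cells);

  for (int i = 0; i < n_cells; ++i)
    m[i] = (open_end && i == n_cells - 1) ? 1 : 2;
  for (int i = 0; i < n_cells; ++i) I[i] = mu * delta * m[i];
  m[0] -= 1;  // the seed divides at t = 0

  const int n_steps = (int)std::ceil(t_max / dt);
  int n_left = n_cells;

  std::vector<double> rec_t;
  std::vector<double> rec_A, rec_I;  // row-major: sample-by-sample blocks
  if (record) {
    rec_t.push_back(0.0);
    for (int i = 0; i < n_cells; ++i) rec_A.push_back(A[i]);
    for (int i = 0; i < n_cells; ++i) rec_I.push_back(I[i]);
  }

  for (int s = 0; s < n_steps && n_left > 0; ++s) {
    double t = s * dt;
    std::vector<int> just_divided;

    for (int i = 0; i < n_cells; ++i) {
      if (divided[i]) continue;
      double A_old = A[i];
      A[i] += dt * (r / (1.0 + I[i]) - A[i] / rho);
      I[i] += dt * (mu * m[i] - I[i] / delta);
      if (A[i] >= theta) {
        double frac = (A[i] > A_old) ? (theta - A_old) / (A[i] - A_old) : 1.0;
        div_time[i] = t + dt * frac;
        divided[i] = true;
        just_divided.push_back(i);
        --n_left;
      }
    }
    // release inhibition on neighbours from the next step on
    for (size_t k = 0; k < just_divided.size(); ++k) {
      int i = just_divided[k];
      if (i > 0) m[i - 1] -= 1;
      if (i + 1 < n_cells) m[i + 1] -= 1;
    }

    if (record && ((s + 1) % record_every == 0 || n_left == 0)) {
      rec_t.push_back((s + 1) * dt);
      for (int i = 0; i < n_cells; ++i) rec_A.push_back(A[i]);
      for (int i = 0; i < n_cells; ++i) rec_I.push_back(I[i]);
    }
  }

  List out = List::create(_["division_time"] = NumericVector(div_time.begin(),
                                                             div_time.end()));
  if (record) {
    int n_samp = rec_t.size();
    NumericMatrix Am(n_samp, n_cells), Im(n_samp, n_cells);
    for (int s = 0; s < n_samp; ++s)
      for (int i = 0; i < n_cells; ++i) {
        Am(s, i) = rec_A[(size_t)s * n_cells + i];
        Im(s, i) = rec_I[(size_t)s * n_cells + i];
      }
    out["time"] = NumericVector(rec_t.begin(), rec_t.end());
    out["A"] = Am;
    out["I"] = Im;
  }
  return out;
}
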