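#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Bioenergetic consumer-resource dynamics for one inter-introduction segment.
// State y = (B0, B_1..B_S). The attack matrix A ((S+1) x S, basal resource in
// row 0), handling times h, metabolic losses x and the competition matrix C
// (S x S, entry (i,j) = pressure on focal i from j, zero diagonal) are fixed
// while the species set is fixed, so they are precomputed once per segment.
struct FwSystem {
  int S;
  double n0, l, e;
  const double* A;   // column-major (S+1) x S
  const double* C;   // column-major S x S
  std::vector<double> m, h, x;

  void rhs(const double* y, double* dy) const {
    const int P = S + 1;
    // P_i = sum_k A(k,i) y_k ; w_i = B_i / (m_i * (1 + h_i P_i))
    std::vector<double> w(S), Pi(S);
    for (int i = 0; i < S; ++i) {
      const double* a = A + (size_t)i * P;
      double acc = 0.0;
      for (int k = 0; k < P; ++k) acc += a[k] * y[k];
      Pi[i] = acc;
      w[i] = y[i + 1] / (m[i] * (1.0 + h[i] * acc));
    }
    // predation loss on each prey k: y_k * sum_i A(k,i) w_i
    std::vector<double> loss(P, 0.0);
    for (int i = 0; i < S; ++i) {
      const double* a = A + (size_t)i * P;
      const double wi = w[i];
      if (wi != 0.0)
        for (int k = 0; k < P; ++k) loss[k] += a[k] * wi;
    }
    dy[0] = n0 - y[0] * loss[0] - l * y[0];
    for (int i = 0; i < S; ++i) {
      double comp = 0.0;
      const double* ci = C + (size_t)i;  // row i, stride S
      for (int j = 0; j < S; ++j) comp += ci[(size_t)j * S] * y[j + 1];
      dy[i + 1] = e * w[i] * Pi[i]            // assimilated consumption
                - y[i + 1] * loss[i + 1]      // losses to predators
                - y[i + 1] * comp             // interference competition
                - x[i] * y[i + 1];            // respiration / mortality
    }
  }
};

// Classic Runge-Kutta-Fehlberg 4(5) with adaptive step-size control and a
// mixed absolute/relative error norm. Biomasses are clamped non-negative
// after each accepted step (excursions are below atol by construction).
// [[Rcpp::export]]
List fw_integrate_cpp(double B0, NumericVector B,
                      NumericVector m, NumericMatrix A, NumericMatrix C,
                      NumericVector h, NumericVector x,
                      double n0, double l, double e,
                      double t_span, double rtol, double atol) {
  const int S = B.size();
  const int n = S + 1;
  FwSystem sys;
  sys.S = S; sys.n0 = n0; sys.l = l; sys.e = e;
  sys.A = A.begin(); sys.C = C.begin();
  sys.m.assign(m.begin(), m.end());
  sys.h.assign(h.begin(), h.end());
  sys.x.assign(x.begin(), x.end());

  std::vector<double> y(n);
  y[0] = B0;
  for (int i = 0; i < S; ++i) y[i + 1] = B[i];

  if (t_span <= 0.0) {
    return List::create(_["B0"] = y[0],
                        _["B"] = NumericVector(y.begin() + 1, y.end()),
                        _["status"] = "ok", _["nsteps"] = 0);
  }

  std::vector<double> k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), yt(n), y4(n), y5(n);
  double t = 0.0;
  double hstep = std::min(0.1, t_span);
  const double hmin = t_span * 1e-12;
  long nsteps = 0;
  const long maxsteps = 50000000L;
  std::string status = "ok";

  while (t < t_span) {
    if (++nsteps > maxsteps) { status = "maxsteps"; break; }
    if (hstep < hmin) { status = "stepsize_underflow"; break; }
    if (t + hstep > t_span) hstep = t_span - t;

    sys.rhs(y.data(), k1.data());
    for (int i = 0; i < n; ++i) yt[i] = y[i] + hstep * (0.25 * k1[i]);
    sys.rhs(yt.data(), k2.data());
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + hstep * (3.0 / 32.0 * k1[i] + 9.0 / 32.0 * k2[i]);
    sys.rhs(yt.data(), k3.data());
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + hstep * (1932.0 / 2197.0 * k1[i] - 7200.0 / 2197.0 * k2[i]
                              + 7296.0 / 2197.0 * k3[i]);
    sys.rhs(yt.data(), k4.data());
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + hstep * (439.0 / 216.0 * k1[i] - 8.0 * k2[i]
                              + 3680.0 / 513.0 * k3[i] - 845.0 / 4104.0 * k4[i]);
    sys.rhs(yt.data(), k5.data());
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + hstep * (-8.0 / 27.0 * k1[i] + 2.0 * k2[i]
                              - 3544.0 / 2565.0 * k3[i] + 1859.0 / 4104.0 * k4[i]
                              - 11.0 / 40.0 * k5[i]);
    sys.rhs(yt.data(), k6.data());

    double errmax = 0.0;
    bool finite = true;
    for (int i = 0; i < n; ++i) {
      y4[i] = y[i] + hstep * (25.0 / 216.0 * k1[i] + 1408.0 / 2565.0 * k3[i]
                              + 2197.0 / 4104.0 * k4[i] - 0.2 * k5[i]);
      y5[i] = y[i] + hstep * (16.0 / 135.0 * k1[i] + 6656.0 / 12825.0 * k3[i]
                              + 28561.0 / 56430.0 * k4[i] - 9.0 / 50.0 * k5[i]
                              + 2.0 / 55.0 * k6[i]);
      if (!std::isfinite(y5[i])) { finite = false; break; }
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
      double err = std::fabs(y5[i] - y4[i]) / sc;
      if (err > errmax) errmax = err;
    }

    if (!finite) { hstep *= 0.25; continue; }

    if (errmax <= 1.0) {           // accept (local extrapolation: keep 5th order)
      t += hstep;
      for (int i = 0; i < n; ++i) y[i] = y5[i] < 0.0 ? 0.0 : y5[i];
      double fac = errmax > 0.0 ? 0.9 * std::pow(errmax, -0.2) : 4.0;
      hstep *= std::min(4.0, std::max(0.2, fac));
    } else {
      double fac = 0.9 * std::pow(errmax, -0.25);
      hstep *= std::min(0.9, std::max(0.1, fac));
    }
  }

  for (int i = 0; i < n; ++i)
    if (!std::isfinite(y[i])) { status = "nonfinite"; break; }

  return List::create(_["B0"] = y[0],
                      _["B"] = NumericVector(y.begin() + 1, y.end()),
                      _["status"] = status,
                      _["nsteps"] = (double)nsteps);
}
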