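// Transient EMU balance integrator.
//
// State = concatenated MIDs of all internal EMUs. For EMU i of a species
// with pool P_i (umol/gDW):
//   P_i * dx_i/dt = sum_j w_j * conv(sources_j) - (sum_j w_j) * x_i
// where w_j are unidirectional fluxes (already converted to umol/s)
// producing the EMU's species and conv() is the discrete convolution of
// the source EMU MIDs (external sources have constant prescribed MIDs).
// Integrated with an adaptive Dormand-Prince RK5(4) scheme.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct EmuSystem {
  int n_emu;
  std::vector<int> sizes;       // carbons per EMU
  std::vector<int> offsets;     // state offset per EMU
  std::vector<double> inv_pool; // 1 / pool size
  std::vector<double> totalin;  // sum of producer weights per EMU
  // flattened producer terms
  std::vector<int> term_emu;
  std::vector<double> term_w;
  std::vector<int> term_src_begin; // index into src arrays
  std::vector<int> term_nsrc;
  std::vector<int> src_type;    // 0 internal EMU, 1 external MID
  std::vector<int> src_idx;     // EMU index or external MID index
  std::vector<std::vector<double>> ext_mids;
  int nstate;
};

// MIDs have at most MAXC carbons -> MAXC+1 entries; fixed stack buffers
// keep the convolution loop allocation-free.
#define MAXB 16

static void deriv(const EmuSystem& sys, const double* x, double* dxdt) {
  std::fill(dxdt, dxdt + sys.nstate, 0.0);
  double acc[MAXB], buf2[MAXB];
  const size_t nterm = sys.term_emu.size();
  for (size_t t = 0; t < nterm; ++t) {
    double w = sys.term_w[t];
    if (w == 0.0) continue;
    int pe = sys.term_emu[t];
    int plen = sys.sizes[pe] + 1;
    int sb = sys.term_src_begin[t];
    int ns = sys.term_nsrc[t];
    const double* cur;
    int curlen;
    {
      int st = sys.src_type[sb], si = sys.src_idx[sb];
      if (st == 0) { cur = x + sys.offsets[si]; curlen = sys.sizes[si] + 1; }
      else { cur = sys.ext_mids[si].data(); curlen = (int)sys.ext_mids[si].size(); }
    }
    if (ns == 1) {
      double* out = dxdt + sys.offsets[pe];
      for (int i = 0; i < plen; ++i) out[i] += w * cur[i];
      continue;
    }
    for (int i = 0; i < curlen; ++i) acc[i] = cur[i];
    for (int s = 1; s < ns; ++s) {
      int st = sys.src_type[sb + s], si = sys.src_idx[sb + s];
      const double* b;
      int blen;
      if (st == 0) { b = x + sys.offsets[si]; blen = sys.sizes[si] + 1; }
      else { b = sys.ext_mids[si].data(); blen = (int)sys.ext_mids[si].size(); }
      int outlen = curlen + blen - 1;
      for (int i = 0; i < outlen; ++i) buf2[i] = 0.0;
      for (int i = 0; i < curlen; ++i) {
        double ai = acc[i];
        for (int j = 0; j < blen; ++j) buf2[i + j] += ai * b[j];
      }
      for (int i = 0; i < outlen; ++i) acc[i] = buf2[i];
      curlen = outlen;
    }
    double* out = dxdt + sys.offsets[pe];
    for (int i = 0; i < plen; ++i) out[i] += w * acc[i];
  }
  for (int e = 0; e < sys.n_emu; ++e) {
    int off = sys.offsets[e], len = sys.sizes[e] + 1;
    double ti = sys.totalin[e], ip = sys.inv_pool[e];
    for (int i = 0; i < len; ++i)
      dxdt[off + i] = (dxdt[off + i] - ti * x[off + i]) * ip;
  }
}

// Dormand-Prince 5(4) coefficients
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
static const double e1 = 35.0 / 384 - 5179.0 / 57600,
                    e3 = 500.0 / 1113 - 7571.0 / 16695,
                    e4 = 125.0 / 192 - 393.0 / 640,
                    e5 = -2187.0 / 6784 + 92097.0 / 339200,
                    e6 = 11.0 / 84 - 187.0 / 2100,
                    e7 = -1.0 / 40;

// [[Rcpp::export(name = ".emu_integrate_cpp")]]
NumericMatrix emu_integrate_cpp(IntegerVector sizes, IntegerVector offsets,
                                NumericVector pools, IntegerVector term_emu,
                                NumericVector term_w, IntegerVector term_nsrc,
                                IntegerVector src_type, IntegerVector src_idx,
                                List ext_mids, NumericVector x0,
                                NumericVector times, double rtol, double atol,
                                double hmax, int max_steps = 400000) {
  EmuSystem sys;
  sys.n_emu = sizes.size();
  sys.sizes.assign(sizes.begin(), sizes.end());
  sys.offsets.assign(offsets.begin(), offsets.end());
  sys.inv_pool.resize(sys.n_emu);
  for (int i = 0; i < sys.n_emu; ++i) {
    if (pools[i] <= 0) stop("pool sizes must be strictly positive");
    sys.inv_pool[i] = 1.0 / pools[i];
  }
  sys.term_emu.assign(term_emu.begin(), term_emu.end());
  sys.term_w.assign(term_w.begin(), term_w.end());
  sys.term_nsrc.assign(term_nsrc.begin(), term_nsrc.end());
  sys.term_src_begin.resize(sys.term_emu.size());
  int acc = 0;
  for (size_t i = 0; i < sys.term_emu.size(); ++i) {
    sys.term_src_begin[i] = acc;
    acc += sys.term_nsrc[i];
  }
  sys.src_type.assign(src_type.begin(), src_type.end());
  sys.src_idx.assign(src_idx.begin(), src_idx.end());
  for (int i = 0; i < ext_mids.size(); ++i) {
    NumericVector m = ext_mids[i];
    sys.ext_mids.push_back(std::vector<double>(m.begin(), m.end()));
  }
  sys.totalin.assign(sys.n_emu, 0.0);
  for (size_t t = 0; t < sys.term_emu.size(); ++t)
    sys.totalin[sys.term_emu[t]] += sys.term_w[t];
  sys.nstate = x0.size();

  int nt = times.size();
  NumericMatrix out(nt, sys.nstate);
  std::vector<double> y(x0.begin(), x0.end());
  std::vector<double> k1(sys.nstate), k2(sys.nstate), k3(sys.nstate),
      k4(sys.nstate), k5(sys.nstate), k6(sys.nstate), k7(sys.nstate),
      ytmp(sys.nstate), y5(sys.nstate);

  double t = times[0];
  for (int j = 0; j < sys.nstate; ++j) out(0, j) = y[j];

  double h = 1e-3;
  bool have_k1 = false;
  int steps = 0;

  for (int it = 1; it < nt; ++it) {
    double tend = times[it];
    while (t < tend) {
      if (++steps > max_steps) stop("EMU integrator exceeded step limit");
      if (h > hmax) h = hmax;
      if (t + h > tend) h = tend - t;
      if (!have_k1) { deriv(sys, y.data(), k1.data()); have_k1 = true; }
      for (int j = 0; j < sys.nstate; ++j) ytmp[j] = y[j] + h * a21 * k1[j];
      deriv(sys, ytmp.data(), k2.data());
      for (int j = 0; j < sys.nstate; ++j)
        ytmp[j] = y[j] + h * (a31 * k1[j] + a32 * k2[j]);
      deriv(sys, ytmp.data(), k3.data());
      for (int j = 0; j < sys.nstate; ++j)
        ytmp[j] = y[j] + h * (a41 * k1[j] + a42 * k2[j] + a43 * k3[j]);
      deriv(sys, ytmp.data(), k4.data());
      for (int j = 0; j < sys.nstate; ++j)
        ytmp[j] = y[j] + h * (a51 * k1[j] + a52 * k2[j] + a53 * k3[j] + a54 * k4[j]);
      deriv(sys, ytmp.data(), k5.data());
      for (int j = 0; j < sys.nstate; ++j)
        ytmp[j] = y[j] + h * (a61 * k1[j] + a62 * k2[j] + a63 * k3[j] +
                              a64 * k4[j] + a65 * k5[j]);
      deriv(sys, ytmp.data(), k6.data());
      for (int j = 0; j < sys.nstate; ++j)
        y5[j] = y[j] + h * (b1 * k1[j] + b3 * k3[j] + b4 * k4[j] + b5 * k5[j] +
                            b6 * k6[j]);
      deriv(sys, y5.data(), k7.data());
      double errnorm = 0.0;
      for (int j = 0; j < sys.nstate; ++j) {
        double err = h * (e1 * k1[j] + e3 * k3[j] + e4 * k4[j] + e5 * k5[j] +
                          e6 * k6[j] + e7 * k7[j]);
        double sc = atol + rtol * std::max(std::fabs(y[j]), std::fabs(y5[j]));
        double r = err / sc;
        errnorm += r * r;
      }
      errnorm = std::sqrt(errnorm / sys.nstate);
      if (!std::isfinite(errnorm)) {
        h *= 0.1;
        if (h < 1e-12) stop("EMU integrator diverged (non-finite state)");
        continue;
      }
      if (errnorm <= 1.0) {
        t += h;
        std::swap(y, y5);
        std::copy(k7.begin(), k7.end(), k1.begin()); // FSAL
        have_k1 = true;
        double fac = (errnorm > 1e-12) ? 0.9 * std::pow(errnorm, -0.2) : 5.0;
        h *= std::min(5.0, std::max(0.2, fac));
      } else {
        double fac = 0.9 * std::pow(errnorm, -0.2);
        h *= std::min(1.0, std::max(0.1, fac));
        if (h < 1e-12) stop("EMU integrator step size underflow");
      }
    }
    for (int j = 0; j < sys.nstate; ++j) out(it, j) = y[j];
  }
  return out;
}
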