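// Compiled inner loop of the simulation engine.
//
// Mirrors the pure-R step (tg_step) exactly, including the order in which
// random numbers are consumed: (perturbation draws when due), r1..r4 for the
// vascular operator, then the glycolysis-fraction uniforms. Sparse operators
// arrive as the CSC slots of dgCMatrix objects; the chemical value arrays may
// be mutated by the column perturbation and are returned to the caller.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// y = T x for a CSC matrix (column scatter)
static void csc_mult(const IntegerVector& p, const IntegerVector& ri,
                     const NumericVector& x, const std::vector<double>& v,
                     std::vector<double>& out) {
  std::fill(out.begin(), out.end(), 0.0);
  const int ncol = p.size() - 1;
  for (int j = 0; j < ncol; ++j) {
    const double vj = v[j];
    if (vj == 0.0) continue;
    for (int k = p[j]; k < p[j + 1]; ++k) out[ri[k]] += x[k] * vj;
  }
}

// Pairwise strict-order preservation with ties unconstrained: sorted by the
// old values, the max of each tie group's new values must stay below the min
// of the next group's.
static bool ranks_preserved(const std::vector<double>& oldv,
                            const std::vector<double>& newv) {
  const int m = oldv.size();
  if (m < 2) return true;
  std::vector<int> ord(m);
  for (int i = 0; i < m; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return oldv[a] < oldv[b]; });
  int i = 0;
  bool first = true;
  double prev_max = 0.0;
  while (i < m) {
    int j = i;
    double gmin = newv[ord[i]], gmax = newv[ord[i]];
    while (j + 1 < m && oldv[ord[j + 1]] == oldv[ord[i]]) {
      ++j;
      gmin = std::min(gmin, newv[ord[j]]);
      gmax = std::max(gmax, newv[ord[j]]);
    }
    if (!first && !(prev_max < gmin)) return false;
    prev_max = gmax;
    first = false;
    i = j + 1;
  }
  return true;
}

static void perturb_matrix(const IntegerVector& p, NumericVector& x,
                           const std::vector<bool>& active, double mag) {
  const int ncol = p.size() - 1;
  std::vector<double> oldv, newv;
  for (int j = 0; j < ncol; ++j) {
    if (!active[j]) continue;
    const int lo = p[j], hi = p[j + 1];
    const int m = hi - lo;
    if (m <= 0) continue;
    oldv.assign(x.begin() + lo, x.begin() + hi);
    double s = 0.0;
    for (int k = 0; k < m; ++k) s += oldv[k];
    newv.resize(m);
    for (int tries = 0; tries < 100; ++tries) {
      double sn = 0.0;
      for (int k = 0; k < m; ++k) {
        const double u = R::runif(-1.0, 1.0);
        newv[k] = oldv[k] * std::exp(mag * u);
        sn += newv[k];
      }
      const double sc = s / sn;
      for (int k = 0; k < m; ++k) newv[k] *= sc;
      if (ranks_preserved(oldv, newv)) break;
    }
    for (int k = 0; k < m; ++k) x[lo + k] = newv[k];
  }
}

// [[Rcpp::export]]
List run_chunk_cpp(List state,
                   IntegerVector To_p, IntegerVector To_i, NumericVector To_x_in,
                   NumericVector To_base_x,
                   IntegerVector Tgl_p, IntegerVector Tgl_i, NumericVector Tgl_x_in,
                   NumericVector Tgl_base_x,
                   IntegerVector Tc_p, IntegerVector Tc_i, NumericVector Tc_x,
                   List par, int n_steps, int step_offset) {
  std::vector<double> l = as<std::vector<double>>(state["l"]);
  std::vector<double> nc = as<std::vector<double>>(state["nc"]);
  std::vector<double> nn = as<std::vector<double>>(state["nn"]);
  std::vector<double> o = as<std::vector<double>>(state["o"]);
  std::vector<double> gl = as<std::vector<double>>(state["gl"]);
  std::vector<double> ob = as<std::vector<double>>(state["o_b"]);
  std::vector<double> glb = as<std::vector<double>>(state["gl_b"]);
  std::vector<double> obmax = as<std::vector<double>>(state["o_b_max"]);
  std::vector<double> glbmax = as<std::vector<double>>(state["gl_b_max"]);
  std::vector<double> sw = as<std::vector<double>>(state["sw"]);
  const int nv = l.size();

  NumericVector To_x = clone(To_x_in);
  NumericVector Tgl_x = clone(Tgl_x_in);

  const double dt = par["delta_tau"], M = par["M"], Mmax = par["M_max"];
  const double Ko = par["K_o"], Kgl = par["K_gl"], K = par["K_ATP"];
  const double lambda = par["lambda"], cc = par["cc"], amax = par["a_max"];
  const double beta1 = par["beta1"], beta2 = par["beta2"];
  const double vr = par["v_r"], ve = par["v_e"];
  const double ho = par["h_o"], hgl = par["h_gl"];
  const double o0 = par["o0_bar"], gl0 = par["gl0_bar"];
  const int kappa = par["kappa"];
  const int pper = par["perturb_period"];
  const double pmag = par["perturb_magnitude"];

  std::vector<double> buf(nv), excess(nv);
  RNGScope rngScope;

  for (int sstep = step_offset + 1; sstep <= step_offset + n_steps; ++sstep) {
    // --- column perturbation of the chemical matrices ---
    if (pper > 0 && pmag > 0 && sstep % pper == 0) {
      std::vector<bool> active(nv, false);
      for (int j = 0; j < nv; ++j) {
        if (l[j] + nc[j] > 0) {
          active[j] = true;
          for (int k = Tc_p[j]; k < Tc_p[j + 1]; ++k) active[Tc_i[k]] = true;
        }
      }
      // restart from the nominal kernels so deviations stay bounded
      std::copy(To_base_x.begin(), To_base_x.end(), To_x.begin());
      std::copy(Tgl_base_x.begin(), Tgl_base_x.end(), Tgl_x.begin());
      perturb_matrix(To_p, To_x, active, pmag);
      perturb_matrix(Tgl_p, Tgl_x, active, pmag);
    }

    // --- F_vr: vascular remodeling ---
    // draw order matches the R path: full r1, r2, r3, r4 vectors
    std::vector<double> r1(nv), r2(nv), r3(nv), r4(nv);
    for (int v = 0; v < nv; ++v) r1[v] = R::runif(0.0, 1.0);
    for (int v = 0; v < nv; ++v) r2[v] = R::runif(0.0, 1.0);
    for (int v = 0; v < nv; ++v) r3[v] = R::runif(0.0, 1.0);
    for (int v = 0; v < nv; ++v) r4[v] = R::runif(0.0, 1.0);
    for (int v = 0; v < nv; ++v) {
      const double ob_bar = ob[v] + r1[v] * ((o0 - o[v]) / dt);
      const double glb_bar = glb[v] + r2[v] * ((gl0 - gl[v]) / dt);
      if (l[v] + nc[v] > 0) {
        double fr = (l[v] + nc[v]) / M;
        fr = std::min(std::max(fr, 0.0), 1.0);
        double fe = (M - l[v] - nc[v] - nn[v]) / M;
        fe = std::min(std::max(fe, 0.0), 1.0);
        const double fac = 1.0 - fr * r3[v] * vr + sw[v] * fe * r4[v] * ve;
        obmax[v] = std::max(fac * obmax[v], 0.0);
        glbmax[v] = std::max(fac * glbmax[v], 0.0);
      }
      ob[v] = std::min(std::max(ob_bar, -obmax[v]), obmax[v]);
      glb[v] = std::min(std::max(glb_bar, -glbmax[v]), glbmax[v]);
    }

    // --- F_pn: metabolism / proliferation / necrosis ---
    std::vector<double> uu(nv);
    for (int v = 0; v < nv; ++v) uu[v] = R::runif(0.0, 1.0);
    for (int v = 0; v < nv; ++v) {
      // step 1: normal cells consume first
      const double lnorm = std::max(M - l[v] - nc[v] - nn[v], 0.0);
      const double o_in = o[v] + ob[v] * dt;
      const double gl_in = gl[v] + glb[v] * dt;
      const double O1 = o_in - lnorm * (Ko * dt);
      const double Gl1 = gl_in - lnorm * (Kgl * dt);
      double Oav, Glav;
      if (O1 >= 0 && Gl1 >= 0) {
        Oav = O1;
        Glav = Gl1;
      } else {
        double Nn = std::min(o_in / (Ko * dt), gl_in / (Kgl * dt));
        Nn = std::max(Nn, 0.0);
        Oav = std::max(o_in - Nn * (Ko * dt), 0.0);
        Glav = std::max(gl_in - Nn * (Kgl * dt), 0.0);
        nn[v] += lnorm - Nn;
      }
      // step 2: tumor cells
      if (l[v] <= 0) {
        o[v] = Oav;
        gl[v] = Glav;
        continue;
      }
      const double den = l[v] * K * dt;
      const double bl = 1.0 - 6.0 * Oav / den;
      const double bh = (36.0 * Glav / den - 1.0) / 17.0;
      const double lo = std::max(bl, beta1);
      const double hi = std::min(bh, beta2);
      if (lo <= hi) {
        // feasible: proliferate at the resource-limited mitosis rate
        const double bt = lo + uu[v] * (hi - lo);
        const double g_o = ((1.0 - bt) / 6.0) * K * dt;
        const double g_gl = ((17.0 * bt + 1.0) / 36.0) * K * dt;
        const double prolif = (lambda - 1.0) * l[v] * (cc / dt);
        const double a_o = (bt != 1.0)
          ? (Oav - l[v] * g_o) / (prolif * g_o) : R_PosInf;
        const double a_gl = (Glav - l[v] * g_gl) / (prolif * g_gl);
        const double a = std::max(std::min(std::min(a_o, a_gl), amax), 0.0);
        const double lv = l[v];
        l[v] = lv + a * lv;
        o[v] = (bt != 1.0)
          ? std::max(Oav - lv * g_o - prolif * a * g_o, 0.0) : Oav;
        gl[v] = std::max(Glav - lv * g_gl - prolif * a * g_gl, 0.0);
      } else {
        // starvation: survivors set by the binding resource
        const double bt = beta1 + uu[v] * (beta2 - beta1);
        const double g_o = ((1.0 - bt) / 6.0) * K * dt;
        const double g_gl = ((17.0 * bt + 1.0) / 36.0) * K * dt;
        double Nc = (bt != 1.0)
          ? std::min(Oav / g_o, Glav / g_gl) : Glav / g_gl;
        Nc = std::min(std::max(Nc, 0.0), l[v]);
        nc[v] += l[v] - Nc;
        l[v] = Nc;
        o[v] = (bt != 1.0) ? std::max(Oav - Nc * g_o, 0.0) : Oav;
        gl[v] = std::max(Glav - Nc * g_gl, 0.0);
      }
    }

    // --- F_o, F_gl: chemical diffusion ---
    csc_mult(To_p, To_i, To_x, o, buf);
    o.swap(buf);
    csc_mult(Tgl_p, Tgl_i, Tgl_x, gl, buf);
    gl.swap(buf);

    // --- F_c: tumor-cell invasion every kappa steps ---
    if (sstep % kappa == 0) {
      bool any = false;
      for (int v = 0; v < nv; ++v) {
        const double s1 = std::max(Mmax - nc[v] - nn[v], 0.0);
        const double s2 = std::min(l[v], s1);
        excess[v] = l[v] - s2;
        buf[v] = s2;
        if (excess[v] > 0) any = true;
      }
      if (any) {
        for (int j = 0; j < nv; ++j) {
          const double ej = excess[j];
          if (ej == 0.0) continue;
          for (int k = Tc_p[j]; k < Tc_p[j + 1]; ++k) {
            buf[Tc_i[k]] += Tc_x[k] * ej;
          }
        }
        l.swap(buf);
      }
    }

    // --- angiogenesis switch on the post-diffusion fields ---
    for (int v = 0; v < nv; ++v) {
      sw[v] = (l[v] > 0 && (o[v] < ho * o0 || gl[v] < hgl * gl0)) ? 1.0 : 0.0;
    }
  }

  return List::create(
    _["l"] = wrap(l), _["nc"] = wrap(nc), _["nn"] = wrap(nn),
    _["o"] = wrap(o), _["gl"] = wrap(gl), _["o_b"] = wrap(ob),
    _["gl_b"] = wrap(glb), _["o_b_max"] = wrap(obmax),
    _["gl_b_max"] = wrap(glbmax), _["sw"] = wrap(sw),
    _["To_x"] = To_x, _["Tgl_x"] = Tgl_x);
}
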