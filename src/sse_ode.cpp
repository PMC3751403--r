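// E/D ordinary differential equations for state-dependent birth-death
// (SSE) likelihoods, integrated branch-by-branch with an adaptive
// Cash-Karp Runge-Kutta 4(5) scheme.  Two model families:
//   BiSSE  : 2 states, pars (lambda0, lambda1, mu0, mu1, q01, q10)
//   GeoSSE : 3 states A, B, AB, pars (sA, sB, sAB, xA, xB, dA, dB)
// D vectors are renormalised at the start of each branch and the log
// factors accumulated, so 40-Myr branches do not underflow.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

enum ModelFamily { BISSE = 0, GEOSSE = 1 };

static inline void bisse_rhs(const double *y, double *dy, const double *p) {
  const double la0 = p[0], la1 = p[1], mu0 = p[2], mu1 = p[3];
  const double q01 = p[4], q10 = p[5];
  const double E0 = y[0], E1 = y[1], D0 = y[2], D1 = y[3];
  dy[0] = mu0 - (mu0 + la0 + q01) * E0 + la0 * E0 * E0 + q01 * E1;
  dy[1] = mu1 - (mu1 + la1 + q10) * E1 + la1 * E1 * E1 + q10 * E0;
  dy[2] = -(mu0 + la0 + q01) * D0 + q01 * D1 + 2.0 * la0 * E0 * D0;
  dy[3] = -(mu1 + la1 + q10) * D1 + q10 * D0 + 2.0 * la1 * E1 * D1;
}

// states ordered A, B, AB; widespread (AB) lineages speciate within
// region A (rate sA, daughters A + AB), within region B (sB, B + AB),
// or between regions (sAB, daughters A + B); region loss xA: AB -> B,
// xB: AB -> A; range expansion dA: A -> AB, dB: B -> AB.
static inline void geosse_rhs(const double *y, double *dy, const double *p) {
  const double sA = p[0], sB = p[1], sAB = p[2];
  const double xA = p[3], xB = p[4], dA = p[5], dB = p[6];
  const double EA = y[0], EB = y[1], EAB = y[2];
  const double DA = y[3], DB = y[4], DAB = y[5];
  dy[0] = xA - (sA + dA + xA) * EA + dA * EAB + sA * EA * EA;
  dy[1] = xB - (sB + dB + xB) * EB + dB * EAB + sB * EB * EB;
  dy[2] = -(sA + sB + sAB + xA + xB) * EAB + xA * EB + xB * EA
          + sA * EA * EAB + sB * EB * EAB + sAB * EA * EB;
  dy[3] = -(sA + dA + xA) * DA + dA * DAB + 2.0 * sA * EA * DA;
  dy[4] = -(sB + dB + xB) * DB + dB * DAB + 2.0 * sB * EB * DB;
  dy[5] = -(sA + sB + sAB + xA + xB) * DAB + xA * DB + xB * DA
          + sA * (EA * DAB + EAB * DA) + sB * (EB * DAB + EAB * DB)
          + sAB * (EA * DB + EB * DA);
}

// Cash-Karp tableau
static const double CK_B[6][5] = {
  {0, 0, 0, 0, 0},
  {1.0 / 5, 0, 0, 0, 0},
  {3.0 / 40, 9.0 / 40, 0, 0, 0},
  {3.0 / 10, -9.0 / 10, 6.0 / 5, 0, 0},
  {-11.0 / 54, 5.0 / 2, -70.0 / 27, 35.0 / 27, 0},
  {1631.0 / 55296, 175.0 / 512, 575.0 / 13824, 44275.0 / 110592,
   253.0 / 4096}};
static const double CK_C5[6] = {37.0 / 378, 0, 250.0 / 621, 125.0 / 594, 0,
                                512.0 / 1771};
static const double CK_C4[6] = {2825.0 / 27648, 0, 18575.0 / 48384,
                                13525.0 / 55296, 277.0 / 14336, 1.0 / 4};

// integrate y' = f(y) over [0, len]; returns false on failure
static bool integrate_branch(double *y, int dim, double len, int model,
                             const double *pars, double atol, double rtol) {
  if (len <= 0.0)
    return true;
  double t = 0.0, h = len;
  double k[6][6], ytmp[6], y5[6], y4[6];
  const double hmin = len * 1e-12;
  int nstep = 0;
  while (t < len) {
    if (t + h > len)
      h = len - t;
    // stages
    for (int s = 0; s < 6; s++) {
      for (int i = 0; i < dim; i++) {
        double acc = y[i];
        for (int j = 0; j < s; j++)
          acc += h * CK_B[s][j] * k[j][i];
        ytmp[i] = acc;
      }
      if (model == BISSE)
        bisse_rhs(ytmp, k[s], pars);
      else
        geosse_rhs(ytmp, k[s], pars);
    }
    double errmax = 0.0;
    for (int i = 0; i < dim; i++) {
      double s5 = 0.0, s4 = 0.0;
      for (int s = 0; s < 6; s++) {
        s5 += CK_C5[s] * k[s][i];
        s4 += CK_C4[s] * k[s][i];
      }
      y5[i] = y[i] + h * s5;
      y4[i] = y[i] + h * s4;
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
      double e = std::fabs(y5[i] - y4[i]) / sc;
      if (e > errmax)
        errmax = e;
    }
    if (!std::isfinite(errmax))
      return false;
    if (errmax <= 1.0) {
      t += h;
      for (int i = 0; i < dim; i++)
        y[i] = y5[i];
      double fac = (errmax > 0) ? 0.9 * std::pow(errmax, -0.2) : 5.0;
      if (fac > 5.0)
        fac = 5.0;
      h *= fac;
    } else {
      double fac = 0.9 * std::pow(errmax, -0.25);
      if (fac < 0.1)
        fac = 0.1;
      h *= fac;
      if (h < hmin)
        return false;
    }
    if (++nstep > 1000000)
      return false;
  }
  // clamp small numerical excursions
  int nst = dim / 2;
  for (int i = 0; i < nst; i++) {
    if (y[i] < 0.0)
      y[i] = 0.0;
    if (y[i] > 1.0)
      y[i] = 1.0;
  }
  for (int i = nst; i < dim; i++)
    if (y[i] < 0.0)
      y[i] = 0.0;
  return true;
}

// [[Rcpp::export(name = ".sse_loglik_cpp")]]
List sse_loglik_cpp(IntegerMatrix edge, NumericVector edge_length, int ntip,
                    IntegerVector tip_state, NumericVector pars, int model,
                    NumericVector f, int root_type, NumericVector root_p,
                    bool cond_surv, double atol, double rtol) {
  const int nstate = (model == BISSE) ? 2 : 3;
  const int dim = 2 * nstate;
  const int nedge = edge.nrow();
  const int nnode_total = ntip + (nedge / 2) + 1; // binary tree
  const double *p = pars.begin();

  // per-node combined (at-node) D and E, plus child counters
  std::vector<double> D(nnode_total * 3, 0.0), E(nnode_total * 3, 0.0);
  std::vector<int> nseen(nnode_total, 0);
  double lq = 0.0;
  int rootnode = -1;

  for (int e = 0; e < nedge; e++) {
    int parent = edge(e, 0) - 1, child = edge(e, 1) - 1;
    double y[6];
    if (child < ntip) {
      int st = tip_state[child]; // 0-based state index
      for (int i = 0; i < nstate; i++) {
        y[i] = 1.0 - f[i];
        y[nstate + i] = (i == st) ? f[i] : 0.0;
      }
    } else {
      if (nseen[child] != 2)
        stop("internal error: edges not in postorder");
      for (int i = 0; i < nstate; i++) {
        y[i] = E[child * 3 + i];
        y[nstate + i] = D[child * 3 + i];
      }
    }
    // renormalise D
    double q = 0.0;
    for (int i = 0; i < nstate; i++)
      q += y[nstate + i];
    if (q > 0) {
      for (int i = 0; i < nstate; i++)
        y[nstate + i] /= q;
      lq += std::log(q);
    } else {
      return List::create(_["loglik"] = R_NegInf, _["ok"] = false);
    }
    if (!integrate_branch(y, dim, edge_length[e], model, p, atol, rtol))
      return List::create(_["loglik"] = R_NegInf, _["ok"] = false);

    // deposit at parent
    if (nseen[parent] == 0) {
      for (int i = 0; i < nstate; i++) {
        E[parent * 3 + i] = y[i];
        D[parent * 3 + i] = y[nstate + i];
      }
      nseen[parent] = 1;
    } else if (nseen[parent] == 1) {
      double Dl[3], Dr[3], Dn[3];
      for (int i = 0; i < nstate; i++) {
        Dl[i] = D[parent * 3 + i];
        Dr[i] = y[nstate + i];
      }
      if (model == BISSE) {
        Dn[0] = p[0] * Dl[0] * Dr[0];
        Dn[1] = p[1] * Dl[1] * Dr[1];
      } else {
        const double sA = p[0], sB = p[1], sAB = p[2];
        Dn[0] = sA * Dl[0] * Dr[0];
        Dn[1] = sB * Dl[1] * Dr[1];
        Dn[2] = 0.5 * (sA * (Dl[0] * Dr[2] + Dl[2] * Dr[0]) +
                       sB * (Dl[1] * Dr[2] + Dl[2] * Dr[1]) +
                       sAB * (Dl[0] * Dr[1] + Dl[1] * Dr[0]));
      }
      for (int i = 0; i < nstate; i++)
        D[parent * 3 + i] = Dn[i]; // keep E from first child (ultrametric)
      nseen[parent] = 2;
      rootnode = parent; // last node combined in postorder is the root
    } else {
      stop("polytomy encountered: SSE likelihoods require a binary tree");
    }
  }

  double Droot[3], Eroot[3], sumD = 0.0;
  for (int i = 0; i < nstate; i++) {
    Droot[i] = D[rootnode * 3 + i];
    Eroot[i] = E[rootnode * 3 + i];
    sumD += Droot[i];
  }
  if (!(sumD > 0.0) || !std::isfinite(sumD))
    return List::create(_["loglik"] = R_NegInf, _["ok"] = false);

  double w[3];
  for (int i = 0; i < nstate; i++) {
    if (root_type == 0)
      w[i] = Droot[i] / sumD; // observed-data (FitzJohn) weighting
    else if (root_type == 1)
      w[i] = 1.0 / nstate;
    else
      w[i] = root_p[i];
  }
  double L = 0.0;
  for (int i = 0; i < nstate; i++)
    L += w[i] * Droot[i];
  double ll = std::log(L) + lq;
  if (cond_surv) {
    double la[3], denom = 0.0;
    if (model == BISSE) {
      la[0] = p[0];
      la[1] = p[1];
    } else {
      la[0] = p[0];
      la[1] = p[1];
      la[2] = p[0] + p[1] + p[2];
    }
    for (int i = 0; i < nstate; i++)
      denom += w[i] * la[i] * (1.0 - Eroot[i]) * (1.0 - Eroot[i]);
    if (!(denom > 0.0))
      return List::create(_["loglik"] = R_NegInf, _["ok"] = false);
    ll -= std::log(denom);
  }
  NumericVector rd(nstate), re(nstate);
  for (int i = 0; i < nstate; i++) {
    rd[i] = Droot[i];
    re[i] = Eroot[i];
  }
  return List::create(_["loglik"] = ll, _["ok"] = true, _["root_D"] = rd,
                      _["root_E"] = re, _["log_comp"] = lq);
}
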