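// 1D-0D pulse-wave network solver core.
//
// Each vessel is a 1D axisymmetric tube governed by
//   dA/dt + dQ/dz = 0
//   dQ/dt + d/dz(Q^2/A) + (A/rho) dP/dz + K_R Q/A = 0
// closed by the elastic tube law P = P0 + beta (sqrt(A/A0) - 1).  For uniform
// reference properties the pressure-gradient term is conservative,
//   (A/rho) dP/dz = d/dz [ beta A^{3/2} / (3 rho sqrt(A0)) ],
// and interior nodes advance with the Richtmyer two-step Lax-Wendroff scheme.
// Boundary nodes are set from the outgoing characteristic invariant
// W+- = u +- 4c (c = c0 (A/A0)^{1/4}) evaluated at the characteristic foot,
// combined with the attached element: prescribed inflow, RCR Windkessel
// (implicit-Euler capacitor), non-reflecting state, branching junction
// (mass conservation enforced exactly by construction, static- or
// total-pressure continuity solved by Newton), or Young stenosis interface
// (flow continuous, pressure jump with viscous/turbulent/inertial terms).
//
// All quantities are SI: m, s, Pa, m^2, m^3/s.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Tube {
  int n;
  double ds, A0, beta, P0, rho, KR, c0;
  std::vector<double> A, Q, An, Qn;
};

inline double pres(const Tube& tb, double A) {
  return tb.P0 + tb.beta * (std::sqrt(A / tb.A0) - 1.0);
}
inline double dpres(const Tube& tb, double A) {
  return tb.beta / (2.0 * std::sqrt(A * tb.A0));
}
inline double cel(const Tube& tb, double A) {
  return tb.c0 * std::pow(A / tb.A0, 0.25);
}
inline double flux2(const Tube& tb, double A, double Q) {
  return Q * Q / A + tb.beta * A * std::sqrt(A) / (3.0 * tb.rho * std::sqrt(tb.A0));
}

// Outgoing characteristic invariant at a tube end, traced to its foot at the
// previous time level (side 0 = left/s=0, 1 = right/s=L).  The friction
// source changes u along the characteristic by -K_R (Q/A)/A dt; the
// correction keeps boundary states consistent with steady friction balances.
double charOut(const Tube& tb, int side, double dt) {
  if (side == 1) {
    int n = tb.n;
    double u = tb.Q[n - 1] / tb.A[n - 1];
    double c = cel(tb, tb.A[n - 1]);
    double th = (u + c) * dt / tb.ds;
    th = std::max(0.0, std::min(1.0, th));
    double Af = tb.A[n - 1] * (1.0 - th) + tb.A[n - 2] * th;
    double Qf = tb.Q[n - 1] * (1.0 - th) + tb.Q[n - 2] * th;
    return Qf / Af + 4.0 * cel(tb, Af) - dt * tb.KR * Qf / (Af * Af);
  }
  double u = tb.Q[0] / tb.A[0];
  double c = cel(tb, tb.A[0]);
  double th = (c - u) * dt / tb.ds;
  th = std::max(0.0, std::min(1.0, th));
  double Af = tb.A[0] * (1.0 - th) + tb.A[1] * th;
  double Qf = tb.Q[0] * (1.0 - th) + tb.Q[1] * th;
  return Qf / Af - 4.0 * cel(tb, Af) - dt * tb.KR * Qf / (Af * Af);
}

struct Inlet {
  int tube, side;
};
struct Terminal {
  int tube, side;
  double R1, R2, C, Pout, Pc;
};
struct NonReflecting {
  int tube, side;
  double Wref;  // incoming invariant pinned to the reference state
};
struct JunctionEnd {
  int tube, side;
};
struct Junction {
  std::vector<JunctionEnd> ends;
  std::vector<double> Asol, qsol;  // warm start
};
struct Stenosis {
  int tubeL, tubeR;  // coupling: right end of tubeL to left end of tubeR
  double kv, kt, ku; // collapsed coefficients (Pa s/m^3 style)
  double Qprev;
};

// dense Gaussian elimination with partial pivoting; row-major a (m x m)
bool solveLin(std::vector<double>& a, std::vector<double>& b, int m) {
  for (int col = 0; col < m; ++col) {
    int piv = col;
    double best = std::fabs(a[col * m + col]);
    for (int r = col + 1; r < m; ++r) {
      double v = std::fabs(a[r * m + col]);
      if (v > best) {
        best = v;
        piv = r;
      }
    }
    if (best == 0.0) return false;
    if (piv != col) {
      for (int k = 0; k < m; ++k) std::swap(a[col * m + k], a[piv * m + k]);
      std::swap(b[col], b[piv]);
    }
    for (int r = col + 1; r < m; ++r) {
      double f = a[r * m + col] / a[col * m + col];
      if (f == 0.0) continue;
      for (int k = col; k < m; ++k) a[r * m + k] -= f * a[col * m + k];
      b[r] -= f * b[col];
    }
  }
  for (int r = m - 1; r >= 0; --r) {
    double s = b[r];
    for (int k = r + 1; k < m; ++k) s -= a[r * m + k] * b[k];
    b[r] = s / a[r * m + r];
  }
  return true;
}

}  // namespace

// Interior Richtmyer Lax-Wendroff update for a single tube; end nodes are
// returned unchanged (they belong to boundary couplings).
// [[Rcpp::export(name = ".lw_interior_step_cpp")]]
List lw_interior_step_cpp(NumericVector A, NumericVector Q, double A0,
                          double beta, double P0, double rho, double KR,
                          double ds, double dt) {
  int n = A.size();
  Tube tb;
  tb.n = n;
  tb.ds = ds;
  tb.A0 = A0;
  tb.beta = beta;
  tb.P0 = P0;
  tb.rho = rho;
  tb.KR = KR;
  tb.c0 = std::sqrt(beta / (2.0 * rho));
  tb.A.assign(A.begin(), A.end());
  tb.Q.assign(Q.begin(), Q.end());

  double lamMax = 0.0;
  for (int i = 0; i < n; ++i) {
    if (!(tb.A[i] > 0.0)) stop("collapse: non-positive area at node %d", i + 1);
    double lam = std::fabs(tb.Q[i] / tb.A[i]) + cel(tb, tb.A[i]);
    lamMax = std::max(lamMax, lam);
  }
  double courant = lamMax * dt / ds;

  NumericVector An(clone(A)), Qn(clone(Q));
  std::vector<double> Ah(n - 1), Qh(n - 1);
  for (int i = 0; i < n - 1; ++i) {
    double s2a = -KR * tb.Q[i] / tb.A[i];
    double s2b = -KR * tb.Q[i + 1] / tb.A[i + 1];
    Ah[i] = 0.5 * (tb.A[i] + tb.A[i + 1]) - 0.5 * dt / ds * (tb.Q[i + 1] - tb.Q[i]);
    Qh[i] = 0.5 * (tb.Q[i] + tb.Q[i + 1]) -
            0.5 * dt / ds * (flux2(tb, tb.A[i + 1], tb.Q[i + 1]) - flux2(tb, tb.A[i], tb.Q[i])) +
            0.25 * dt * (s2a + s2b);
    if (!(Ah[i] > 0.0)) stop("collapse: non-positive half-step area");
  }
  for (int i = 1; i < n - 1; ++i) {
    double sl = -KR * Qh[i - 1] / Ah[i - 1];
    double sr = -KR * Qh[i] / Ah[i];
    An[i] = tb.A[i] - dt / ds * (Qh[i] - Qh[i - 1]);
    Qn[i] = tb.Q[i] -
            dt / ds * (flux2(tb, Ah[i], Qh[i]) - flux2(tb, Ah[i - 1], Qh[i - 1])) +
            0.5 * dt * (sl + sr);
  }
  return List::create(_["A"] = An, _["Q"] = Qn, _["courant"] = courant);
}

// Full network driver.  `tubes` is a list of lists (n, ds, A0, beta, P0, rho,
// KR, A, Q); couplings are lists of index records (1-based from R).
// [[Rcpp::export(name = ".run_network_cpp")]]
List run_network_cpp(List tubesIn, List junctionsIn, List terminalsIn,
                     List inletsIn, List stenosesIn, List nonreflIn,
                     NumericVector inflow_t, NumericVector inflow_q,
                     double period, double dt, int steps_per_cycle,
                     int out_stride, int max_cycles, double tol_cycle,
                     bool total_pressure, double newton_tol, int newton_maxit) {
  int nt = tubesIn.size();
  std::vector<Tube> tubes(nt);
  int totalNodes = 0;
  for (int i = 0; i < nt; ++i) {
    List tl = tubesIn[i];
    Tube& tb = tubes[i];
    tb.n = as<int>(tl["n"]);
    tb.ds = as<double>(tl["ds"]);
    tb.A0 = as<double>(tl["A0"]);
    tb.beta = as<double>(tl["beta"]);
    tb.P0 = as<double>(tl["P0"]);
    tb.rho = as<double>(tl["rho"]);
    tb.KR = as<double>(tl["KR"]);
    tb.c0 = std::sqrt(tb.beta / (2.0 * tb.rho));
    NumericVector A0v = tl["A"], Q0v = tl["Q"];
    tb.A.assign(A0v.begin(), A0v.end());
    tb.Q.assign(Q0v.begin(), Q0v.end());
    tb.An = tb.A;
    tb.Qn = tb.Q;
    totalNodes += tb.n;
  }

  std::vector<Inlet> inlets;
  for (int i = 0; i < inletsIn.size(); ++i) {
    List il = inletsIn[i];
    inlets.push_back({as<int>(il["tube"]) - 1, as<int>(il["side"])});
  }
  std::vector<Terminal> terms;
  for (int i = 0; i < terminalsIn.size(); ++i) {
    List tl = terminalsIn[i];
    terms.push_back({as<int>(tl["tube"]) - 1, as<int>(tl["side"]),
                     as<double>(tl["R1"]), as<double>(tl["R2"]),
                     as<double>(tl["C"]), as<double>(tl["Pout"]),
                     as<double>(tl["Pc0"])});
  }
  std::vector<NonReflecting> nrefl;
  for (int i = 0; i < nonreflIn.size(); ++i) {
    List nl = nonreflIn[i];
    int tu = as<int>(nl["tube"]) - 1, sd = as<int>(nl["side"]);
    const Tube& tb = tubes[tu];
    int end = sd == 1 ? tb.n - 1 : 0;
    double u = tb.Q[end] / tb.A[end], c = cel(tb, tb.A[end]);
    double W = sd == 1 ? u - 4.0 * c : u + 4.0 * c;  // incoming invariant
    nrefl.push_back({tu, sd, W});
  }
  std::vector<Junction> juncs;
  for (int i = 0; i < junctionsIn.size(); ++i) {
    List jl = junctionsIn[i];
    IntegerVector jt = jl["tubes"], jsd = jl["sides"];
    Junction J;
    for (int k = 0; k < jt.size(); ++k) J.ends.push_back({jt[k] - 1, jsd[k]});
    int m = (int)J.ends.size();
    J.Asol.resize(m);
    J.qsol.assign(m, 0.0);
    for (int k = 0; k < m; ++k) {
      const Tube& tb = tubes[J.ends[k].tube];
      int end = J.ends[k].side == 1 ? tb.n - 1 : 0;
      J.Asol[k] = tb.A[end];
      J.qsol[k] = (J.ends[k].side == 1 ? 1.0 : -1.0) * tb.Q[end];
    }
    juncs.push_back(J);
  }
  std::vector<Stenosis> stens;
  for (int i = 0; i < stenosesIn.size(); ++i) {
    List sl = stenosesIn[i];
    stens.push_back({as<int>(sl["tubeL"]) - 1, as<int>(sl["tubeR"]) - 1,
                     as<double>(sl["kv"]), as<double>(sl["kt"]),
                     as<double>(sl["ku"]), as<double>(sl["Q0"])});
  }

  auto inflowAt = [&](double t) {
    double tc = t - std::floor(t / period) * period;  // t mod period
    int m = inflow_t.size();
    if (m == 0) return 0.0;
    if (tc <= inflow_t[0]) return inflow_q[0];
    for (int i = 1; i < m; ++i) {
      if (tc <= inflow_t[i]) {
        double w = (tc - inflow_t[i - 1]) / (inflow_t[i] - inflow_t[i - 1]);
        return inflow_q[i - 1] * (1.0 - w) + inflow_q[i] * w;
      }
    }
    return inflow_q[m - 1];
  };

  int nSlots = steps_per_cycle / out_stride + 1;
  std::vector<NumericMatrix> outA(nt), outP(nt), outQ(nt);
  for (int i = 0; i < nt; ++i) {
    outA[i] = NumericMatrix(nSlots, tubes[i].n);
    outP[i] = NumericMatrix(nSlots, tubes[i].n);
    outQ[i] = NumericMatrix(nSlots, tubes[i].n);
  }
  std::vector<double> prevP, curP;
  prevP.reserve((size_t)nSlots * totalNodes);
  curP.reserve((size_t)nSlots * totalNodes);

  auto storedVolume = [&]() {
    double vol = 0.0;
    for (int i = 0; i < nt; ++i) {
      const Tube& tb = tubes[i];
      for (int j = 0; j < tb.n - 1; ++j)
        vol += 0.5 * (tb.A[j] + tb.A[j + 1]) * tb.ds;
    }
    return vol;
  };

  double maxDefect = 0.0, maxCourant = 0.0;
  double inletVol = 0.0, storedStart = 0.0, storedEnd = 0.0;
  std::vector<double> termVol(terms.size(), 0.0);
  NumericVector convHist(max_cycles, NA_REAL);
  bool converged = false;
  int cyclesRun = 0;

  auto snapshot = [&](int slot) {
    for (int i = 0; i < nt; ++i) {
      Tube& tb = tubes[i];
      for (int j = 0; j < tb.n; ++j) {
        outA[i](slot, j) = tb.A[j];
        outP[i](slot, j) = pres(tb, tb.A[j]);
        outQ[i](slot, j) = tb.Q[j];
        curP.push_back(outP[i](slot, j));
      }
    }
  };

  for (int cycle = 0; cycle < max_cycles && !converged; ++cycle) {
    cyclesRun = cycle + 1;
    curP.clear();
    inletVol = 0.0;
    std::fill(termVol.begin(), termVol.end(), 0.0);
    storedStart = storedVolume();
    snapshot(0);

    for (int ls = 0; ls < steps_per_cycle; ++ls) {
      double t = cycle * period + ls * dt;
      double tNew = t + dt;

      // 1) outgoing invariants at all coupled ends (old time level)
      // 2) interior LW update into An/Qn
      for (int i = 0; i < nt; ++i) {
        Tube& tb = tubes[i];
        int n = tb.n;
        tb.An = tb.A;
        tb.Qn = tb.Q;
        double lamMax = 0.0;
        for (int j = 0; j < n; ++j) {
          if (!(tb.A[j] > 0.0) || !std::isfinite(tb.A[j]) || !std::isfinite(tb.Q[j]))
            stop("instability: invalid state in tube %d at t = %g s", i + 1, t);
          lamMax = std::max(lamMax, std::fabs(tb.Q[j] / tb.A[j]) + cel(tb, tb.A[j]));
        }
        double cfl = lamMax * dt / tb.ds;
        maxCourant = std::max(maxCourant, cfl);
        if (cfl > 1.0)
          stop("CFL violation in tube %d at t = %g s (Courant %.3f); reduce dt to <= %g",
               i + 1, t, cfl, 0.9 * tb.ds / lamMax);
        std::vector<double> Ah(n - 1), Qh(n - 1);
        for (int j = 0; j < n - 1; ++j) {
          double s2a = -tb.KR * tb.Q[j] / tb.A[j];
          double s2b = -tb.KR * tb.Q[j + 1] / tb.A[j + 1];
          Ah[j] = 0.5 * (tb.A[j] + tb.A[j + 1]) -
                  0.5 * dt / tb.ds * (tb.Q[j + 1] - tb.Q[j]);
          Qh[j] = 0.5 * (tb.Q[j] + tb.Q[j + 1]) -
                  0.5 * dt / tb.ds *
                      (flux2(tb, tb.A[j + 1], tb.Q[j + 1]) - flux2(tb, tb.A[j], tb.Q[j])) +
                  0.25 * dt * (s2a + s2b);
          if (!(Ah[j] > 0.0))
            stop("collapse: non-positive half-step area in tube %d at t = %g s", i + 1, t);
        }
        for (int j = 1; j < n - 1; ++j) {
          double sl = -tb.KR * Qh[j - 1] / Ah[j - 1];
          double sr = -tb.KR * Qh[j] / Ah[j];
          tb.An[j] = tb.A[j] - dt / tb.ds * (Qh[j] - Qh[j - 1]);
          tb.Qn[j] = tb.Q[j] -
                     dt / tb.ds * (flux2(tb, Ah[j], Qh[j]) - flux2(tb, Ah[j - 1], Qh[j - 1])) +
                     0.5 * dt * (sl + sr);
        }
      }

      // 3) boundary couplings (use old state for characteristics)
      // inlets: prescribed flow
      for (auto& in : inlets) {
        Tube& tb = tubes[in.tube];
        double Qb = inflowAt(tNew);
        double sgn = in.side == 1 ? -1.0 : 1.0;  // inflow direction along s
        double Qs = sgn * Qb;
        double W = charOut(tb, in.side, dt);
        int end = in.side == 1 ? tb.n - 1 : 0;
        double A = tb.A[end];
        for (int it = 0; it < newton_maxit; ++it) {
          double c = cel(tb, A);
          double f = in.side == 1 ? (Qs / A + 4.0 * c - W) : (Qs / A - 4.0 * c - W);
          if (std::fabs(f) < newton_tol * tb.c0) break;
          double df = -Qs / (A * A) + (in.side == 1 ? 1.0 : -1.0) * c / A;
          double Anew = A - f / df;
          if (!(Anew > 0.2 * A)) Anew = 0.2 * A;
          if (Anew > 5.0 * A) Anew = 5.0 * A;
          A = Anew;
        }
        tb.An[end] = A;
        tb.Qn[end] = Qs;
      }

      // terminals: RCR Windkessel, implicit-Euler capacitor
      for (size_t k = 0; k < terms.size(); ++k) {
        Terminal& tm = terms[k];
        Tube& tb = tubes[tm.tube];
        double W = charOut(tb, tm.side, dt);
        int end = tm.side == 1 ? tb.n - 1 : 0;
        double denom = 1.0 + dt / (tm.R2 * tm.C);
        double dPcdQ = (dt / tm.C) / denom;
        double A = tb.A[end];
        double qout = 0.0;
        for (int it = 0; it < newton_maxit; ++it) {
          double c = cel(tb, A);
          double u = tm.side == 1 ? (W - 4.0 * c) : (W + 4.0 * c);
          qout = (tm.side == 1 ? 1.0 : -1.0) * A * u;  // flow out of the tube
          double PcNew = (tm.Pc + dt / tm.C * (qout + tm.Pout / tm.R2)) / denom;
          double g = pres(tb, A) - tm.R1 * qout - PcNew;
          if (std::fabs(g) < newton_tol * tb.beta) break;
          double dudA = (tm.side == 1 ? -1.0 : 1.0) * c / A;
          double dqdA = (tm.side == 1 ? 1.0 : -1.0) * (u + A * dudA);
          double dg = dpres(tb, A) - (tm.R1 + dPcdQ) * dqdA;
          double Anew = A - g / dg;
          if (!(Anew > 0.2 * A)) Anew = 0.2 * A;
          if (Anew > 5.0 * A) Anew = 5.0 * A;
          A = Anew;
        }
        double c = cel(tb, A);
        double u = tm.side == 1 ? (W - 4.0 * c) : (W + 4.0 * c);
        qout = (tm.side == 1 ? 1.0 : -1.0) * A * u;
        tm.Pc = (tm.Pc + dt / tm.C * (qout + tm.Pout / tm.R2)) / denom;
        tb.An[end] = A;
        tb.Qn[end] = A * u;
        termVol[k] += qout * dt;
      }

      // non-reflecting ends: pin the incoming invariant to its reference
      for (auto& nr : nrefl) {
        Tube& tb = tubes[nr.tube];
        double W = charOut(tb, nr.side, dt);
        int end = nr.side == 1 ? tb.n - 1 : 0;
        double u, c;
        if (nr.side == 1) {
          u = 0.5 * (W + nr.Wref);
          c = 0.125 * (W - nr.Wref);
        } else {
          u = 0.5 * (W + nr.Wref);
          c = 0.125 * (nr.Wref - W);
        }
        double A = tb.A0 * std::pow(std::max(c, 1e-12) / tb.c0, 4.0);
        tb.An[end] = A;
        tb.Qn[end] = A * u;
      }

      // junctions: Newton on (A_1..A_m, q_1..q_{m-1}); q_m = -sum (exact mass)
      for (auto& J : juncs) {
        int m = (int)J.ends.size();
        int dim = 2 * m - 1;
        std::vector<double> W(m);
        for (int k = 0; k < m; ++k)
          W[k] = charOut(tubes[J.ends[k].tube], J.ends[k].side, dt);
        std::vector<double> A(J.Asol), q(J.qsol);
        double betaRef = tubes[J.ends[0].tube].beta;
        bool ok = false;
        for (int it = 0; it < newton_maxit; ++it) {
          q[m - 1] = 0.0;
          double s = 0.0;
          for (int k = 0; k < m - 1; ++k) s += q[k];
          q[m - 1] = -s;
          std::vector<double> res(dim, 0.0), jac((size_t)dim * dim, 0.0);
          std::vector<double> u(m), c(m), sg(m);
          for (int k = 0; k < m; ++k) {
            const Tube& tb = tubes[J.ends[k].tube];
            sg[k] = J.ends[k].side == 1 ? 1.0 : -1.0;
            u[k] = sg[k] * q[k] / A[k];
            c[k] = cel(tb, A[k]);
            res[k] = u[k] + (J.ends[k].side == 1 ? 4.0 : -4.0) * c[k] - W[k];
          }
          for (int k = 1; k < m; ++k) {
            const Tube& t0 = tubes[J.ends[0].tube];
            const Tube& tk = tubes[J.ends[k].tube];
            double p0 = pres(t0, A[0]), pk = pres(tk, A[k]);
            res[m - 1 + k] = p0 - pk;
            if (total_pressure)
              res[m - 1 + k] += 0.5 * t0.rho * u[0] * u[0] - 0.5 * tk.rho * u[k] * u[k];
          }
          double err = 0.0;
          for (int k = 0; k < m; ++k)
            err = std::max(err, std::fabs(res[k]) / tubes[J.ends[k].tube].c0);
          for (int k = 1; k < m; ++k)
            err = std::max(err, std::fabs(res[m - 1 + k]) / betaRef);
          if (err < newton_tol) {
            ok = true;
            break;
          }
          // Jacobian
          for (int k = 0; k < m; ++k) {
            const Tube& tb = tubes[J.ends[k].tube];
            double dcdA = c[k] / (4.0 * A[k]);
            jac[(size_t)k * dim + k] =
                -u[k] / A[k] + (J.ends[k].side == 1 ? 4.0 : -4.0) * dcdA;
            for (int j = 0; j < m - 1; ++j) {
              double dqk = (k == j) ? 1.0 : (k == m - 1 ? -1.0 : 0.0);
              if (dqk != 0.0) jac[(size_t)k * dim + (m + j)] = sg[k] * dqk / A[k];
            }
          }
          for (int k = 1; k < m; ++k) {
            const Tube& t0 = tubes[J.ends[0].tube];
            const Tube& tk = tubes[J.ends[k].tube];
            size_t r = (size_t)(m - 1 + k) * dim;
            jac[r + 0] = dpres(t0, A[0]);
            jac[r + k] = -dpres(tk, A[k]);
            if (total_pressure) {
              jac[r + 0] += -t0.rho * u[0] * u[0] / A[0];
              jac[r + k] += tk.rho * u[k] * u[k] / A[k];
              for (int j = 0; j < m - 1; ++j) {
                double dq0 = (0 == j) ? 1.0 : 0.0;
                double dqk = (k == j) ? 1.0 : (k == m - 1 ? -1.0 : 0.0);
                jac[r + m + j] += t0.rho * u[0] * sg[0] * dq0 / A[0] -
                                  tk.rho * u[k] * sg[k] * dqk / A[k];
              }
            }
          }
          std::vector<double> rhs(res);
          if (!solveLin(jac, rhs, dim))
            stop("junction Newton: singular Jacobian at t = %g s", t);
          for (int k = 0; k < m; ++k) {
            double Anew = A[k] - rhs[k];
            if (!(Anew > 0.2 * A[k])) Anew = 0.2 * A[k];
            if (Anew > 5.0 * A[k]) Anew = 5.0 * A[k];
            A[k] = Anew;
          }
          for (int j = 0; j < m - 1; ++j) q[j] -= rhs[m + j];
        }
        if (!ok) stop("junction Newton did not converge at t = %g s", t);
        q[m - 1] = 0.0;
        {
          double s = 0.0;
          for (int k = 0; k < m - 1; ++k) s += q[k];
          q[m - 1] = -s;
        }
        double defect = 0.0;
        for (int k = 0; k < m; ++k) defect += q[k];
        maxDefect = std::max(maxDefect, std::fabs(defect));
        for (int k = 0; k < m; ++k) {
          Tube& tb = tubes[J.ends[k].tube];
          int end = J.ends[k].side == 1 ? tb.n - 1 : 0;
          double sgk = J.ends[k].side == 1 ? 1.0 : -1.0;
          tb.An[end] = A[k];
          tb.Qn[end] = sgk * q[k];
        }
        J.Asol = A;
        J.qsol = q;
      }

      // stenosis couplings: 3-unknown Newton (A_L, A_R, Q)
      for (auto& st : stens) {
        Tube& tL = tubes[st.tubeL];
        Tube& tR = tubes[st.tubeR];
        double Wp = charOut(tL, 1, dt);
        double Wm = charOut(tR, 0, dt);
        double AL = tL.A[tL.n - 1], AR = tR.A[0];
        double Q = 0.5 * (tL.Q[tL.n - 1] + tR.Q[0]);
        double betaRef = tL.beta;
        bool ok = false;
        for (int it = 0; it < newton_maxit; ++it) {
          double cL = cel(tL, AL), cR = cel(tR, AR);
          double dP = st.kv * Q + st.kt * Q * std::fabs(Q) + st.ku * (Q - st.Qprev) / dt;
          double r1 = Q / AL + 4.0 * cL - Wp;
          double r2 = Q / AR - 4.0 * cR - Wm;
          double r3 = pres(tL, AL) - pres(tR, AR) - dP;
          double err = std::max({std::fabs(r1) / tL.c0, std::fabs(r2) / tR.c0,
                                 std::fabs(r3) / betaRef});
          if (err < newton_tol) {
            ok = true;
            break;
          }
          double ddPdQ = st.kv + 2.0 * st.kt * std::fabs(Q) + st.ku / dt;
          double j11 = -Q / (AL * AL) + cL / AL, j13 = 1.0 / AL;
          double j22 = -Q / (AR * AR) - cR / AR, j23 = 1.0 / AR;
          double j31 = dpres(tL, AL), j32 = -dpres(tR, AR), j33 = -ddPdQ;
          std::vector<double> jac = {j11, 0.0, j13, 0.0, j22, j23, j31, j32, j33};
          std::vector<double> rhs = {r1, r2, r3};
          if (!solveLin(jac, rhs, 3))
            stop("stenosis Newton: singular Jacobian at t = %g s", t);
          double ALn = AL - rhs[0], ARn = AR - rhs[1];
          if (!(ALn > 0.2 * AL)) ALn = 0.2 * AL;
          if (!(ARn > 0.2 * AR)) ARn = 0.2 * AR;
          AL = std::min(ALn, 5.0 * AL);
          AR = std::min(ARn, 5.0 * AR);
          Q -= rhs[2];
        }
        if (!ok) stop("stenosis Newton did not converge at t = %g s", t);
        st.Qprev = Q;
        tL.An[tL.n - 1] = AL;
        tL.Qn[tL.n - 1] = Q;
        tR.An[0] = AR;
        tR.Qn[0] = Q;
      }

      // 4) commit and accumulate conservation integrals
      for (int i = 0; i < nt; ++i) {
        tubes[i].A.swap(tubes[i].An);
        tubes[i].Q.swap(tubes[i].Qn);
      }
      for (auto& in : inlets) inletVol += inflowAt(tNew) * dt;

      if ((ls + 1) % out_stride == 0) snapshot((ls + 1) / out_stride);
    }

    storedEnd = storedVolume();

    // cycle-to-cycle convergence on P
    if (!prevP.empty()) {
      double maxRel = 0.0;
      size_t nn = curP.size();
      // per-sample relative change, normalised by the cycle pressure scale
      double scale = 0.0;
      for (size_t i = 0; i < nn; ++i) scale = std::max(scale, std::fabs(curP[i]));
      if (scale <= 0.0) scale = 1.0;
      for (size_t i = 0; i < nn; ++i)
        maxRel = std::max(maxRel, std::fabs(curP[i] - prevP[i]) / scale);
      convHist[cycle] = maxRel;
      if (maxRel < tol_cycle) converged = true;
    }
    prevP = curP;
  }

  List tubesOut(nt);
  for (int i = 0; i < nt; ++i)
    tubesOut[i] = List::create(_["A"] = outA[i], _["P"] = outP[i], _["Q"] = outQ[i]);
  NumericVector pcs(terms.size());
  NumericVector tvol(terms.size());
  for (size_t k = 0; k < terms.size(); ++k) {
    pcs[k] = terms[k].Pc;
    tvol[k] = termVol[k];
  }
  NumericVector times(nSlots);
  for (int s = 0; s < nSlots; ++s) times[s] = s * out_stride * dt;

  return List::create(
      _["tubes"] = tubesOut, _["times"] = times, _["cycles"] = cyclesRun,
      _["converged"] = converged, _["conv_history"] = convHist,
      _["conservation"] = List::create(
          _["inlet_volume"] = inletVol, _["terminal_volumes"] = tvol,
          _["stored_start"] = storedStart, _["stored_end"] = storedEnd,
          _["max_junction_defect"] = maxDefect, _["max_courant"] = maxCourant),
      _["terminal_pc"] = pcs, _["dt"] = dt);
}
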