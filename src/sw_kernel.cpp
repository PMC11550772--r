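// Compiled kernels: periodic neighbor lists, Stillinger-Weber (MX2-type)
// energy/forces, and a monotone FIRE / steepest-descent minimizer.
//
// Conventions: positions in Angstrom, energies in eV, forces in eV/A.
// The cell matrix has the three cell vectors as rows; pbc flags per axis.
// Periodic interactions are handled by explicit image enumeration, so cells
// shorter than the cutoff (e.g. short-period primitive tube cells) are
// treated exactly: every image pair, including an atom with its own image,
// contributes separately.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

struct NeighEntry {
  int j;            // neighbour atom index
  int s0, s1, s2;   // image shift in cell-vector units
};

struct NeighList {
  std::vector<std::vector<NeighEntry>> nb;  // full list per atom
  double built_cutoff;
};

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

static void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

// perpendicular width of the cell along axis k
static double perp_width(const NumericMatrix& cell, int k) {
  double a[3], b[3], c[3], n[3];
  int k1 = (k + 1) % 3, k2 = (k + 2) % 3;
  for (int d = 0; d < 3; ++d) {
    a[d] = cell(k, d); b[d] = cell(k1, d); c[d] = cell(k2, d);
  }
  cross3(b, c, n);
  double nn = std::sqrt(dot3(n, n));
  if (nn < 1e-12) return std::fabs(std::sqrt(dot3(a, a)));
  return std::fabs(dot3(a, n)) / nn;
}

// Full neighbour list via ghost-image enumeration with grid binning.
static NeighList build_neighlist(const std::vector<double>& pos, int n,
                                 const NumericMatrix& cell,
                                 const LogicalVector& pbc, double cutoff) {
  NeighList nl;
  nl.built_cutoff = cutoff;
  nl.nb.assign(n, {});

  int nimg[3] = {0, 0, 0};
  for (int k = 0; k < 3; ++k) {
    if (pbc[k]) {
      double w = perp_width(cell, k);
      if (w < 1e-6) stop("degenerate periodic cell vector on axis %d", k + 1);
      nimg[k] = (int)std::ceil(cutoff / w);
    }
  }

  struct Ghost { double x, y, z; int j, s0, s1, s2; };
  std::vector<Ghost> ghosts;
  ghosts.reserve((size_t)n * (2 * nimg[0] + 1) * (2 * nimg[1] + 1) *
                 (2 * nimg[2] + 1));
  for (int s0 = -nimg[0]; s0 <= nimg[0]; ++s0)
    for (int s1 = -nimg[1]; s1 <= nimg[1]; ++s1)
      for (int s2 = -nimg[2]; s2 <= nimg[2]; ++s2) {
        double off[3];
        for (int d = 0; d < 3; ++d)
          off[d] = s0 * cell(0, d) + s1 * cell(1, d) + s2 * cell(2, d);
        for (int j = 0; j < n; ++j)
          ghosts.push_back({pos[3 * j] + off[0], pos[3 * j + 1] + off[1],
                            pos[3 * j + 2] + off[2], j, s0, s1, s2});
      }

  // grid binning over the ghost bounding box
  double lo[3] = {1e300, 1e300, 1e300}, hi[3] = {-1e300, -1e300, -1e300};
  for (auto& g : ghosts) {
    lo[0] = std::min(lo[0], g.x); hi[0] = std::max(hi[0], g.x);
    lo[1] = std::min(lo[1], g.y); hi[1] = std::max(hi[1], g.y);
    lo[2] = std::min(lo[2], g.z); hi[2] = std::max(hi[2], g.z);
  }
  double bs = std::max(cutoff, 1e-3);
  int nb0 = std::max(1, (int)((hi[0] - lo[0]) / bs) + 1);
  int nb1 = std::max(1, (int)((hi[1] - lo[1]) / bs) + 1);
  int nb2 = std::max(1, (int)((hi[2] - lo[2]) / bs) + 1);
  std::vector<std::vector<int>> bins((size_t)nb0 * nb1 * nb2);
  auto binidx = [&](double x, double y, double z) {
    int b0 = std::min(nb0 - 1, std::max(0, (int)((x - lo[0]) / bs)));
    int b1 = std::min(nb1 - 1, std::max(0, (int)((y - lo[1]) / bs)));
    int b2 = std::min(nb2 - 1, std::max(0, (int)((z - lo[2]) / bs)));
    return (size_t)(b0 * nb1 + b1) * nb2 + b2;
  };
  for (int g = 0; g < (int)ghosts.size(); ++g)
    bins[binidx(ghosts[g].x, ghosts[g].y, ghosts[g].z)].push_back(g);

  double c2 = cutoff * cutoff;
  for (int i = 0; i < n; ++i) {
    double xi = pos[3 * i], yi = pos[3 * i + 1], zi = pos[3 * i + 2];
    int b0 = std::min(nb0 - 1, std::max(0, (int)((xi - lo[0]) / bs)));
    int b1 = std::min(nb1 - 1, std::max(0, (int)((yi - lo[1]) / bs)));
    int b2 = std::min(nb2 - 1, std::max(0, (int)((zi - lo[2]) / bs)));
    for (int d0 = std::max(0, b0 - 1); d0 <= std::min(nb0 - 1, b0 + 1); ++d0)
      for (int d1 = std::max(0, b1 - 1); d1 <= std::min(nb1 - 1, b1 + 1); ++d1)
        for (int d2 = std::max(0, b2 - 1); d2 <= std::min(nb2 - 1, b2 + 1); ++d2)
          for (int g : bins[(size_t)(d0 * nb1 + d1) * nb2 + d2]) {
            const Ghost& gh = ghosts[g];
            if (gh.j == i && gh.s0 == 0 && gh.s1 == 0 && gh.s2 == 0) continue;
            double dx = gh.x - xi, dy = gh.y - yi, dz = gh.z - zi;
            double r2 = dx * dx + dy * dy + dz * dz;
            if (r2 < c2) nl.nb[i].push_back({gh.j, gh.s0, gh.s1, gh.s2});
          }
  }
  return nl;
}

// [[Rcpp::export]]
List nr_neighbor_pairs(NumericMatrix positions, NumericMatrix cell,
                       LogicalVector pbc, double cutoff) {
  int n = positions.nrow();
  std::vector<double> pos(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) pos[3 * i + d] = positions(i, d);
  NeighList nl = build_neighlist(pos, n, cell, pbc, cutoff);
  std::vector<int> oi, oj;
  std::vector<double> od;
  for (int i = 0; i < n; ++i)
    for (auto& e : nl.nb[i]) {
      // keep each unordered image pair once
      if (e.j < i) continue;
      if (e.j == i) {
        if (e.s0 < 0 || (e.s0 == 0 && (e.s1 < 0 || (e.s1 == 0 && e.s2 < 0))))
          continue;
      }
      double d[3];
      for (int dd = 0; dd < 3; ++dd)
        d[dd] = pos[3 * e.j + dd] + e.s0 * cell(0, dd) + e.s1 * cell(1, dd) +
                e.s2 * cell(2, dd) - pos[3 * i + dd];
      double r = std::sqrt(dot3(d, d));
      if (r < cutoff) { oi.push_back(i + 1); oj.push_back(e.j + 1); od.push_back(r); }
    }
  return List::create(_["i"] = oi, _["j"] = oj, _["d"] = od);
}

// Full directed neighbour list with displacement vectors (every image
// entry appears in both directions).
// [[Rcpp::export]]
List nr_neighbor_vectors(NumericMatrix positions, NumericMatrix cell,
                         LogicalVector pbc, double cutoff) {
  int n = positions.nrow();
  std::vector<double> pos(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) pos[3 * i + d] = positions(i, d);
  NeighList nl = build_neighlist(pos, n, cell, pbc, cutoff);
  std::vector<int> oi, oj;
  std::vector<double> dx, dy, dz, od;
  for (int i = 0; i < n; ++i)
    for (auto& e : nl.nb[i]) {
      double d[3];
      for (int dd = 0; dd < 3; ++dd)
        d[dd] = pos[3 * e.j + dd] + e.s0 * cell(0, dd) + e.s1 * cell(1, dd) +
                e.s2 * cell(2, dd) - pos[3 * i + dd];
      double r = std::sqrt(dot3(d, d));
      if (r < cutoff) {
        oi.push_back(i + 1); oj.push_back(e.j + 1);
        dx.push_back(d[0]); dy.push_back(d[1]); dz.push_back(d[2]);
        od.push_back(r);
      }
    }
  return List::create(_["i"] = oi, _["j"] = oj, _["dx"] = dx, _["dy"] = dy,
                      _["dz"] = dz, _["d"] = od);
}

// ---------------- Stillinger-Weber -------------------------------------

struct SWParams {
  int ntypes;
  // pair tables (ntypes x ntypes), 0 entries disable the interaction
  std::vector<double> A, B, p, q, sigma, rc2;   // two-body
  std::vector<double> gamma, rc3;               // three-body legs
  std::vector<double> lambda, cos0;             // (apex, j, k) cubes
  double rcmax;
  int at(int a, int b) const { return a * ntypes + b; }
  int at3(int a, int b, int c) const { return (a * ntypes + b) * ntypes + c; }
};

static SWParams unpack_params(List par) {
  SWParams P;
  NumericMatrix A = par["A"], B = par["B"], p = par["p"], q = par["q"],
                sigma = par["sigma"], rc2 = par["rc2"], gamma = par["gamma"],
                rc3 = par["rc3"];
  NumericVector lambda = par["lambda"], cos0 = par["cos0"];
  P.ntypes = A.nrow();
  int nt = P.ntypes;
  P.A.resize(nt * nt); P.B.resize(nt * nt); P.p.resize(nt * nt);
  P.q.resize(nt * nt); P.sigma.resize(nt * nt); P.rc2.resize(nt * nt);
  P.gamma.resize(nt * nt); P.rc3.resize(nt * nt);
  for (int a = 0; a < nt; ++a)
    for (int b = 0; b < nt; ++b) {
      int k = P.at(a, b);
      P.A[k] = A(a, b); P.B[k] = B(a, b); P.p[k] = p(a, b); P.q[k] = q(a, b);
      P.sigma[k] = sigma(a, b); P.rc2[k] = rc2(a, b);
      P.gamma[k] = gamma(a, b); P.rc3[k] = rc3(a, b);
    }
  P.lambda.assign(lambda.begin(), lambda.end());
  P.cos0.assign(cos0.begin(), cos0.end());
  if ((int)P.lambda.size() != nt * nt * nt)
    stop("lambda cube has wrong length");
  P.rcmax = 0;
  for (int k = 0; k < nt * nt; ++k) {
    if (P.A[k] > 0) P.rcmax = std::max(P.rcmax, P.rc2[k]);
    P.rcmax = std::max(P.rcmax, P.rc3[k]);
  }
  return P;
}

static inline double pair_phi(const SWParams& P, int k, double r, double* dphi) {
  double A = P.A[k];
  if (A <= 0 || r >= P.rc2[k]) { if (dphi) *dphi = 0; return 0; }
  double s = P.sigma[k], rc = P.rc2[k], B = P.B[k], pp = P.p[k], qq = P.q[k];
  double sp = std::pow(s / r, pp), sq = std::pow(s / r, qq);
  double ex = std::exp(s / (r - rc));
  double f = B * sp - sq;
  double phi = A * f * ex;
  if (dphi) {
    double fp = (-pp * B * sp + qq * sq) / r;
    *dphi = A * ex * (fp - f * s / ((r - rc) * (r - rc)));
  }
  return phi;
}

// Evaluate energy / per-atom energies / forces given a neighbour list.
static void sw_compute(const std::vector<double>& pos, int n,
                       const std::vector<int>& typ, const NumericMatrix& cell,
                       const SWParams& P, const NeighList& nl,
                       bool want_forces, double* energy,
                       std::vector<double>* per_atom,
                       std::vector<double>* forces) {
  double E = 0;
  if (per_atom) per_atom->assign(n, 0.0);
  if (forces) forces->assign(3 * n, 0.0);

  std::vector<double> dvec; dvec.reserve(64 * 3);
  std::vector<double> rr; rr.reserve(64);
  std::vector<int> jj; jj.reserve(64);

  for (int i = 0; i < n; ++i) {
    int ti = typ[i];
    // gather displacement vectors for this atom's entries
    dvec.clear(); rr.clear(); jj.clear();
    for (auto& e : nl.nb[i]) {
      double d[3];
      for (int dd = 0; dd < 3; ++dd)
        d[dd] = pos[3 * e.j + dd] + e.s0 * cell(0, dd) + e.s1 * cell(1, dd) +
                e.s2 * cell(2, dd) - pos[3 * i + dd];
      double r = std::sqrt(dot3(d, d));
      dvec.push_back(d[0]); dvec.push_back(d[1]); dvec.push_back(d[2]);
      rr.push_back(r); jj.push_back(e.j);
    }
    int m = (int)rr.size();

    // two-body: full list, half weight
    for (int e = 0; e < m; ++e) {
      int k = P.at(ti, typ[jj[e]]);
      double r = rr[e];
      if (P.A[k] <= 0 || r >= P.rc2[k]) continue;
      double dphi;
      double phi = pair_phi(P, k, r, want_forces ? &dphi : nullptr);
      E += 0.5 * phi;
      if (per_atom) (*per_atom)[i] += 0.5 * phi;
      if (want_forces) {
        // F_i += dphi * dhat (each directed entry contributes to i only)
        double inv = 1.0 / r;
        (*forces)[3 * i]     += dphi * dvec[3 * e] * inv;
        (*forces)[3 * i + 1] += dphi * dvec[3 * e + 1] * inv;
        (*forces)[3 * i + 2] += dphi * dvec[3 * e + 2] * inv;
      }
    }

    // three-body: apex i, unordered neighbour pairs within rc3
    for (int e1 = 0; e1 < m; ++e1) {
      int tj = typ[jj[e1]];
      int kij = P.at(ti, tj);
      double r1 = rr[e1];
      if (P.rc3[kij] <= 0 || r1 >= P.rc3[kij]) continue;
      double g1 = std::exp(P.gamma[kij] / (r1 - P.rc3[kij]));
      double dg1 = -P.gamma[kij] / ((r1 - P.rc3[kij]) * (r1 - P.rc3[kij])) * g1;
      const double* u = &dvec[3 * e1];
      for (int e2 = e1 + 1; e2 < m; ++e2) {
        int tk = typ[jj[e2]];
        double lam = P.lambda[P.at3(ti, tj, tk)];
        if (lam <= 0) continue;
        int kik = P.at(ti, tk);
        double r2 = rr[e2];
        if (P.rc3[kik] <= 0 || r2 >= P.rc3[kik]) continue;
        double g2 = std::exp(P.gamma[kik] / (r2 - P.rc3[kik]));
        const double* v = &dvec[3 * e2];
        double cth = dot3(u, v) / (r1 * r2);
        double dc = cth - P.cos0[P.at3(ti, tj, tk)];
        double e3 = lam * g1 * g2 * dc * dc;
        E += e3;
        if (per_atom) (*per_atom)[i] += e3;
        if (want_forces) {
          double dg2 = -P.gamma[kik] / ((r2 - P.rc3[kik]) * (r2 - P.rc3[kik])) * g2;
          double pref = lam * 2.0 * dc * g1 * g2;
          double Fu[3], Fv[3];
          for (int dd = 0; dd < 3; ++dd) {
            double uh = u[dd] / r1, vh = v[dd] / r2;
            // dE/du and dE/dv
            Fu[dd] = lam * dg1 * g2 * dc * dc * uh +
                     pref * (vh - cth * uh) / r1;
            Fv[dd] = lam * g1 * dg2 * dc * dc * vh +
                     pref * (uh - cth * vh) / r2;
          }
          for (int dd = 0; dd < 3; ++dd) {
            (*forces)[3 * jj[e1] + dd] -= Fu[dd];
            (*forces)[3 * jj[e2] + dd] -= Fv[dd];
            (*forces)[3 * i + dd]      += Fu[dd] + Fv[dd];
          }
        }
      }
    }
  }
  *energy = E;
}

// [[Rcpp::export]]
List sw_eval_cpp(NumericMatrix positions, IntegerVector types,
                 NumericMatrix cell, LogicalVector pbc, List params,
                 bool forces = true) {
  int n = positions.nrow();
  std::vector<double> pos(3 * n);
  std::vector<int> typ(types.begin(), types.end());
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) pos[3 * i + d] = positions(i, d);
  SWParams P = unpack_params(params);
  NeighList nl = build_neighlist(pos, n, cell, pbc, P.rcmax);
  double E;
  std::vector<double> pa, fo;
  sw_compute(pos, n, typ, cell, P, nl, forces, &E, &pa, forces ? &fo : nullptr);
  NumericVector per(pa.begin(), pa.end());
  List out = List::create(_["energy"] = E, _["per_atom"] = per);
  if (forces) {
    NumericMatrix F(n, 3);
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) F(i, d) = fo[3 * i + d];
    out["forces"] = F;
  }
  return out;
}

static double norm2(const std::vector<double>& v) {
  double s = 0;
  for (double x : v) s += x * x;
  return std::sqrt(s);
}

// FIRE (fast inertial relaxation engine) with a monotone-acceptance
// safeguard: a trial step that raises the energy is rejected, the velocity
// reset and the time step halved, so the accepted-energy trajectory is
// non-increasing.  algorithm = 0 -> FIRE, 1 -> steepest descent.
// [[Rcpp::export]]
List sw_minimize_cpp(NumericMatrix positions, IntegerVector types,
                     NumericMatrix cell, LogicalVector pbc, List params,
                     double energy_tol, double force_tol, int max_iterations,
                     int max_evaluations, int algorithm = 0,
                     double etol_mode_initial = 1.0) {
  int n = positions.nrow();
  std::vector<double> pos(3 * n), trial(3 * n);
  std::vector<int> typ(types.begin(), types.end());
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) pos[3 * i + d] = positions(i, d);
  SWParams P = unpack_params(params);

  const double skin = 0.5;
  NeighList nl = build_neighlist(pos, n, cell, pbc, P.rcmax + skin);
  std::vector<double> ref = pos;   // positions at last list build

  auto maybe_rebuild = [&](const std::vector<double>& x) {
    double dmax2 = 0;
    for (int i = 0; i < n; ++i) {
      double dx = x[3 * i] - ref[3 * i], dy = x[3 * i + 1] - ref[3 * i + 1],
             dz = x[3 * i + 2] - ref[3 * i + 2];
      dmax2 = std::max(dmax2, dx * dx + dy * dy + dz * dz);
    }
    if (dmax2 > 0.25 * skin * skin / 4.0) {
      nl = build_neighlist(x, n, cell, pbc, P.rcmax + skin);
      ref = x;
    }
  };

  int nev = 0;
  double E;
  std::vector<double> pa, F;
  sw_compute(pos, n, typ, cell, P, nl, true, &E, &pa, &F); ++nev;
  if (!std::isfinite(E)) stop("non-finite energy at the starting configuration");
  double E0 = E;
  double Eref = (etol_mode_initial > 0.5) ? std::fabs(E0) : 0.0;

  std::vector<double> v(3 * n, 0.0);
  double dt = 0.05, dtmax = 0.4, alpha = 0.1;
  const double finc = 1.1, fdec = 0.5, falpha = 0.99;
  const int Nmin = 5;
  int npos = 0, iter = 0;
  bool converged = false;
  const double dmax_step = 0.15;   // per-atom displacement cap, Angstrom
  std::vector<double> traj;
  traj.push_back(E);

  for (iter = 1; iter <= max_iterations; ++iter) {
    if (norm2(F) < force_tol) { converged = true; break; }
    if (algorithm == 0) {
      double P_ = 0;
      for (int k = 0; k < 3 * n; ++k) P_ += F[k] * v[k];
      double fn = norm2(F), vn = norm2(v);
      if (P_ > 0) {
        for (int k = 0; k < 3 * n; ++k)
          v[k] = (1 - alpha) * v[k] + alpha * vn * F[k] / std::max(fn, 1e-30);
        if (++npos > Nmin) { dt = std::min(dt * finc, dtmax); alpha *= falpha; }
      } else {
        std::fill(v.begin(), v.end(), 0.0);
        dt = std::max(dt * fdec, 1e-6);
        alpha = 0.1; npos = 0;
      }
      for (int k = 0; k < 3 * n; ++k) v[k] += dt * F[k];
    } else {
      for (int k = 0; k < 3 * n; ++k) v[k] = F[k];
    }
    // displacement with per-atom cap
    double scale = 1.0, maxd = 0.0;
    for (int i = 0; i < n; ++i) {
      double dx = dt * v[3 * i], dy = dt * v[3 * i + 1], dz = dt * v[3 * i + 2];
      maxd = std::max(maxd, std::sqrt(dx * dx + dy * dy + dz * dz));
    }
    if (maxd > dmax_step) scale = dmax_step / maxd;
    for (int k = 0; k < 3 * n; ++k) trial[k] = pos[k] + scale * dt * v[k];

    maybe_rebuild(trial);
    double Enew;
    std::vector<double> panew, Fnew;
    sw_compute(trial, n, typ, cell, P, nl, true, &Enew, &panew, &Fnew); ++nev;
    if (!std::isfinite(Enew)) {
      warning("non-finite energy during minimization; returning last good state");
      break;
    }
    if (Enew <= E + 1e-12 * std::max(1.0, std::fabs(E))) {
      double dE = std::fabs(Enew - E);
      pos = trial; E = Enew; pa = panew; F = Fnew;
      traj.push_back(E);
      double denom = (Eref > 0) ? Eref : std::max(1.0, std::fabs(E));
      if (dE / denom < energy_tol && norm2(F) < force_tol) {
        converged = true; break;
      }
    } else {
      std::fill(v.begin(), v.end(), 0.0);
      dt *= 0.5; npos = 0;
      if (dt < 1e-9) break;
    }
    if (nev >= max_evaluations) break;
  }

  NumericMatrix X(n, 3), Fm(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      X(i, d) = pos[3 * i + d];
      Fm(i, d) = F[3 * i + d];
    }
  return List::create(_["positions"] = X, _["energy"] = E,
                      _["per_atom"] = NumericVector(pa.begin(), pa.end()),
                      _["forces"] = Fm, _["converged"] = converged,
                      _["iterations"] = iter, _["evaluations"] = nev,
                      _["trajectory"] = NumericVector(traj.begin(), traj.end()));
}
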