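// Coupled tissue/airway time-stepper for the fiber-gel vocal fold model.
// Tissue: lumped-mass central-difference update of the assembled sparse
// stiffness (CSC triplet arrays from R's dgCMatrix) with Kelvin-Voigt
// damping and one-sided penalty collision at the glottal midplane.
// Airway: Kelly-Lochbaum wave-reflection tubes (two half-passes per
// sample; section length = c / (2 fs)), quadratic glottal junction,
// first-order radiation reflection filter at the lips.

#include <Rcpp.h>
using namespace Rcpp;

// y = K x for a symmetric CSC matrix given by (p, i, x) slots
static void csc_matvec(const IntegerVector &Kp, const IntegerVector &Ki,
                       const NumericVector &Kx, const std::vector<double> &x,
                       std::vector<double> &y) {
  const int n = Kp.size() - 1;
  std::fill(y.begin(), y.end(), 0.0);
  for (int j = 0; j < n; ++j) {
    const double xj = x[j];
    if (xj == 0.0) continue;
    for (int idx = Kp[j]; idx < Kp[j + 1]; ++idx) y[Ki[idx]] += Kx[idx] * xj;
  }
}

// positive root of the glottal junction quadratic; flow rectified at 0
static double glottal_flow_scalar(double Ag, double dp, double Z, double rho) {
  if (Ag <= 1e-8 || dp <= 0.0) return 0.0;
  const double c2 = rho / (2.0 * Ag * Ag);
  return (-Z + std::sqrt(Z * Z + 4.0 * c2 * dp)) / (2.0 * c2);
}

// [[Rcpp::export]]
List cpp_glottal_flow(double Ag, double F_sub, double B_sup, double A_sub,
                      double A_sup, double rho, double c) {
  const double Z = rho * c * (1.0 / A_sub + 1.0 / A_sup);
  const double dp = 2.0 * (F_sub - B_sup);
  const double ug = glottal_flow_scalar(Ag, dp, Z, rho);
  const double p_sub = 2.0 * F_sub - rho * c * ug / A_sub;
  const double p_sup = 2.0 * B_sup + rho * c * ug / A_sup;
  return List::create(_["ug"] = ug, _["p_sub"] = p_sub, _["p_sup"] = p_sup,
                      _["dp"] = dp);
}

// Bernoulli-below-minimum / jet-above pressure profile on the glottal
// rows (inferior first). Open glottis: energy-conserving Bernoulli
// referenced to the subglottal pressure below the minimum diameter, jet
// (supraglottal pressure, no recovery) at and above it. Closed glottis:
// everything below the lowest closed row, and that row's upstream face,
// sees the stagnation (subglottal) pressure; everything above sees the
// supraglottal pressure.
static void surface_pressure_rows(const std::vector<double> &a_rows,
                                  double ug, double p_sub, double p_sup,
                                  double rho, std::vector<double> &p) {
  const int nr = (int)a_rows.size();
  const double tiny = 1e-8;
  int kclose = -1;
  for (int k = 0; k < nr; ++k)
    if (a_rows[k] <= tiny) { kclose = k; break; }
  int kmin = 0;
  double amin = a_rows[0];
  for (int k = 1; k < nr; ++k)
    if (a_rows[k] < amin) { amin = a_rows[k]; kmin = k; }
  for (int k = 0; k < nr; ++k) {
    if (kclose >= 0) {
      p[k] = (k <= kclose) ? p_sub : p_sup;
    } else if (k < kmin) {
      if (ug != 0.0) {
        const double q = ug / a_rows[k];
        p[k] = p_sub - 0.5 * rho * q * q;
      } else {
        p[k] = p_sub;
      }
    } else {
      p[k] = p_sup;
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_surface_pressures(NumericVector a_rows, double ug,
                                    double p_sub, double p_sup, double rho) {
  std::vector<double> a(a_rows.begin(), a_rows.end()), p(a_rows.size());
  surface_pressure_rows(a, ug, p_sub, p_sup, rho, p);
  return NumericVector(p.begin(), p.end());
}

struct RadFilter {
  double b0, b1, a1;  // B[n] = b0 F[n] + b1 F[n-1] - a1 B[n-1]
  double zF = 0.0, zB = 0.0;
  double step(double Fin) {
    const double Bout = b0 * Fin + b1 * zF - a1 * zB;
    zF = Fin; zB = Bout;
    return Bout;
  }
};

struct Waveguide {
  std::vector<double> Fs, Bs, Fe, Be;    // sub / supra forward & backward
  std::vector<double> rs, re;            // junction reflection coefficients
  double loss, PL, r_lung, zc_s, zc_e, rho, c;
  RadFilter rad;

  void init(const NumericVector &A_sub, const NumericVector &A_sup,
            double loss_, double PL_, double r_lung_, double rho_, double c_,
            double b0, double b1, double a1) {
    const int ns = A_sub.size(), ne = A_sup.size();
    Fs.assign(ns, 0.0); Bs.assign(ns, 0.0);
    Fe.assign(ne, 0.0); Be.assign(ne, 0.0);
    rs.resize(ns - 1); re.resize(ne - 1);
    for (int i = 0; i < ns - 1; ++i)
      rs[i] = (A_sub[i] - A_sub[i + 1]) / (A_sub[i] + A_sub[i + 1]);
    for (int i = 0; i < ne - 1; ++i)
      re[i] = (A_sup[i] - A_sup[i + 1]) / (A_sup[i] + A_sup[i + 1]);
    loss = loss_; PL = PL_; r_lung = r_lung_; rho = rho_; c = c_;
    zc_s = rho * c / A_sub[ns - 1];
    zc_e = rho * c / A_sup[0];
    rad.b0 = b0; rad.b1 = b1; rad.a1 = a1; rad.zF = 0.0; rad.zB = 0.0;
  }

  // waves about to arrive at the glottal junction this half-pass
  double f_arr() const { return loss * Fs.back(); }
  double b_arr() const { return loss * Be.front(); }

  // advance every wave one section, scatter at junctions, apply the
  // glottal junction with flow ug; returns the oral pressure sample
  double half_pass(double ug, double &p_sub_g, double &p_sup_g) {
    const int ns = Fs.size(), ne = Fe.size();
    std::vector<double> fa(ns), ba(ns), fae(ne), bae(ne);
    for (int i = 0; i < ns; ++i) { fa[i] = loss * Fs[i]; ba[i] = loss * Bs[i]; }
    for (int i = 0; i < ne; ++i) { fae[i] = loss * Fe[i]; bae[i] = loss * Be[i]; }

    std::vector<double> nFs(ns), nBs(ns), nFe(ne), nBe(ne);
    for (int i = 0; i < ns - 1; ++i) {
      nFs[i + 1] = (1.0 + rs[i]) * fa[i] - rs[i] * ba[i + 1];
      nBs[i] = rs[i] * fa[i] + (1.0 - rs[i]) * ba[i + 1];
    }
    for (int i = 0; i < ne - 1; ++i) {
      nFe[i + 1] = (1.0 + re[i]) * fae[i] - re[i] * bae[i + 1];
      nBe[i] = re[i] * fae[i] + (1.0 - re[i]) * bae[i + 1];
    }
    // lung end: constant-pressure source behind a matched termination
    nFs[0] = 0.5 * PL + r_lung * ba[0];
    // glottal junction
    const double F_arr = fa[ns - 1], B_arr = bae[0];
    nBs[ns - 1] = F_arr - zc_s * ug;
    nFe[0] = B_arr + zc_e * ug;
    p_sub_g = 2.0 * F_arr - zc_s * ug;
    p_sup_g = 2.0 * B_arr + zc_e * ug;
    // lip end: radiation reflection, oral pressure = incident + reflected
    const double F_lip = fae[ne - 1];
    const double B_lip = rad.step(F_lip);
    nBe[ne - 1] = B_lip;
    Fs.swap(nFs); Bs.swap(nBs); Fe.swap(nFe); Be.swap(nBe);
    return F_lip + B_lip;
  }
};

// One Kelly-Lochbaum junction scatter: incident forward wave from the
// left section and backward wave from the right section produce the
// outgoing transmitted/reflected waves.
// [[Rcpp::export]]
List cpp_scatter_junction(double F_in, double B_in, double A_left,
                          double A_right) {
  const double r = (A_left - A_right) / (A_left + A_right);
  return List::create(
      _["F_out"] = (1.0 + r) * F_in - r * B_in,
      _["B_out"] = r * F_in + (1.0 - r) * B_in,
      _["r"] = r);
}

// Waveguide-only runner: drive the tract with a prescribed glottal flow
// (PL source optional); returns oral pressure and glottal-end pressures.
// [[Rcpp::export]]
List cpp_wg_run(NumericVector A_sub, NumericVector A_sup, NumericVector ug,
                double loss, double PL, double r_lung, double rho, double c,
                double rad_b0, double rad_b1, double rad_a1) {
  const int n = ug.size();
  Waveguide wg;
  wg.init(A_sub, A_sup, loss, PL, r_lung, rho, c, rad_b0, rad_b1, rad_a1);
  NumericVector po(n), psub(n), psup(n);
  double ps, pe, po1;
  for (int t = 0; t < n; ++t) {
    po1 = wg.half_pass(ug[t], ps, pe);
    wg.half_pass(ug[t], ps, pe);
    po[t] = po1; psub[t] = ps; psup[t] = pe;
  }
  return List::create(_["po"] = po, _["p_sub"] = psub, _["p_sup"] = psup);
}

// Full coupled run: layered fold FEM + glottal aerodynamics + airways.
// [[Rcpp::export]]
List cpp_fg_simulate(
    IntegerVector Kp, IntegerVector Ki, NumericVector Kx,  // stiffness (CSC)
    NumericVector Mdof, double beta, double damp_a, LogicalVector free_dof,
    IntegerMatrix med_ids,        // n_slices x (n_rows+1) medial node ids
    NumericMatrix xi0_med,        // rest half-widths at medial nodes
    NumericMatrix med_area,       // pressure areas of medial nodes
    NumericVector slice_wgt,      // trapezoid weights per slice
    double dy,
    NumericVector contact_k, NumericVector contact_c,  // per medial row col.
    IntegerVector inf_ids, NumericVector inf_area,
    IntegerVector sup_ids, NumericVector sup_area,
    NumericVector A_sub, NumericVector A_sup,
    double loss, double r_lung, double rho_air, double c_air,
    double rad_b0, double rad_b1, double rad_a1,
    double PL, int ramp_samples,
    int nsteps, double dt,
    NumericVector u0, NumericVector v0,
    double abort_disp,
    bool aero, NumericVector p_rows_const,
    bool track_energy) {

  const int ndof = Mdof.size();
  const int n_slices = med_ids.nrow(), n_rows_n = med_ids.ncol();
  std::vector<double> u(u0.begin(), u0.end()), v(v0.begin(), v0.end());
  std::vector<double> w(ndof), f_int(ndof), f_ext(ndof), ku(ndof);

  Waveguide wg;
  wg.init(A_sub, A_sup, loss, PL, r_lung, rho_air, c_air,
          rad_b0, rad_b1, rad_a1);
  const double Zj = rho_air * c_air * (1.0 / A_sub[A_sub.size() - 1] +
                                       1.0 / A_sup[0]);

  NumericVector po(nsteps), ugv(nsteps), agv(nsteps);
  NumericVector energy(track_energy ? nsteps : 0);
  std::vector<double> a_rows(n_rows_n), p_rows(n_rows_n);
  bool aborted = false;
  double max_disp = 0.0;
  int t_end = nsteps;

  for (int t = 0; t < nsteps; ++t) {
    // ---- glottal geometry from current displacements ----
    double Ag = R_PosInf;
    int kmin = 0;
    for (int k = 0; k < n_rows_n; ++k) {
      double a = 0.0;
      for (int s = 0; s < n_slices; ++s) {
        const int nd = med_ids(s, k) - 1;  // 1-based ids
        const double wk = xi0_med(s, k) + u[2 * nd];
        if (wk > 0.0) a += 2.0 * slice_wgt[s] * wk * dy;
      }
      a_rows[k] = a;
      if (a < Ag) { Ag = a; kmin = k; }
    }
    agv[t] = Ag;

    // ---- aerodynamics and airway pressures ----
    double ug = 0.0, p_sub_g = 0.0, p_sup_g = 0.0, po_t = 0.0;
    if (aero) {
      const double ramp = ramp_samples > 0 ?
        std::min(1.0, (t + 1.0) / ramp_samples) : 1.0;
      wg.PL = PL * ramp;
      ug = glottal_flow_scalar(Ag, 2.0 * (wg.f_arr() - wg.b_arr()), Zj,
                               rho_air);
      po_t = wg.half_pass(ug, p_sub_g, p_sup_g);
      surface_pressure_rows(a_rows, ug, p_sub_g, p_sup_g, rho_air, p_rows);
      // second half-pass (sound travels two sections per sample)
      const double ug2 = glottal_flow_scalar(
          Ag, 2.0 * (wg.f_arr() - wg.b_arr()), Zj, rho_air);
      double d1, d2;
      wg.half_pass(ug2, d1, d2);
    } else {
      for (int k = 0; k < n_rows_n; ++k) p_rows[k] = p_rows_const[k];
      p_sub_g = p_rows_const[0];
      p_sup_g = p_rows_const[n_rows_n - 1];
    }
    ugv[t] = ug;
    po[t] = po_t;

    // ---- external nodal forces ----
    std::fill(f_ext.begin(), f_ext.end(), 0.0);
    for (int k = 0; k < n_rows_n; ++k)
      for (int s = 0; s < n_slices; ++s) {
        const int nd = med_ids(s, k) - 1;
        f_ext[2 * nd] += p_rows[k] * med_area(s, k);
      }
    if (aero) {
      for (int i = 0; i < inf_ids.size(); ++i)
        f_ext[2 * (inf_ids[i] - 1) + 1] += p_sub_g * inf_area[i];
      for (int i = 0; i < sup_ids.size(); ++i)
        f_ext[2 * (sup_ids[i] - 1) + 1] -= p_sup_g * sup_area[i];
    }
    // collision penalty + contact damping on penetrating medial nodes
    for (int k = 0; k < n_rows_n; ++k)
      for (int s = 0; s < n_slices; ++s) {
        const int nd = med_ids(s, k) - 1;
        const double wk = xi0_med(s, k) + u[2 * nd];
        if (wk < 0.0) {
          f_ext[2 * nd] += -contact_k[k] * wk - contact_c[k] * v[2 * nd];
        }
      }

    // ---- internal forces: K (u + beta v) ----
    for (int d = 0; d < ndof; ++d) w[d] = u[d] + beta * v[d];
    csc_matvec(Kp, Ki, Kx, w, f_int);

    if (track_energy) csc_matvec(Kp, Ki, Kx, u, ku);

    // ---- central-difference update on free dofs ----
    // the discrete invariant of the undamped scheme pairs consecutive
    // half-step velocities: E = v_{n-1/2} M v_{n+1/2} / 2 + u_n K u_n / 2
    double md = 0.0, e_kin = 0.0, e_el = 0.0;
    for (int d = 0; d < ndof; ++d) {
      if (track_energy) e_el += 0.5 * u[d] * ku[d];
      if (!free_dof[d]) continue;
      const double v_old = v[d];
      const double a = (f_ext[d] - f_int[d]) / Mdof[d] - damp_a * v[d];
      v[d] += dt * a;
      u[d] += dt * v[d];
      if (track_energy) e_kin += 0.5 * Mdof[d] * v_old * v[d];
      const double au = std::fabs(u[d]);
      if (au > md) md = au;
    }
    if (track_energy) energy[t] = e_kin + e_el;
    if (md > max_disp) max_disp = md;
    if (!std::isfinite(md) || md > abort_disp) {
      aborted = true;
      t_end = t + 1;
      break;
    }
  }

  return List::create(
      _["po"] = po, _["ug"] = ugv, _["ag"] = agv,
      _["energy"] = energy,
      _["u"] = NumericVector(u.begin(), u.end()),
      _["v"] = NumericVector(v.begin(), v.end()),
      _["aborted"] = aborted, _["max_disp"] = max_disp,
      _["n_done"] = t_end);
}
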