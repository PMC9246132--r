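#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Power-law assembly feedback (1 + n)^(-alpha), evaluated in log space so
// that large |alpha| and n cannot overflow.
static inline double size_feedback(double n, double alpha) {
  if (alpha == 0.0) return 1.0;
  return std::exp(-alpha * std::log1p(n));
}

// Disassembly n^beta with the boundary rule K_off(0) = 0, which also
// regularizes the beta < 0 divergence at vanishing size.
static inline double off_rate(double n, double kminus, double beta) {
  if (n <= 0.0) return 0.0;
  if (beta == 0.0) return kminus;
  if (beta == 1.0) return kminus * n;
  return kminus * std::exp(beta * std::log(n));
}

// Exact Gillespie simulation of M structures drawing subunits from a shared
// pool.  Channel order is fixed: (on_1, off_1, ..., on_M, off_M)[, production]
// [, growth].  Two uniforms are consumed per step, r1 for the waiting time and
// r2 for channel selection, in that order.
//
// mode: 0 = limiting pool (assembly uses N_av / V), 1 = constant subunit
// concentration rho (pool bookkeeping is still carried for reporting, but the
// assembly propensity ignores it and structures are independent).
//
// form[i]: 0 = power-law feedback k+ * (1+n)^(-alpha); 1 = linear assembly
// (c0 + c1 * n), used by the phase-separation droplet reduction.
//
// record_dt <= 0 records every event; otherwise the state is sampled on the
// regular grid t0, t0 + dt, ... (the value recorded at a grid time is the
// state holding at that instant).
// [[Rcpp::export]]
List ssa_core_cpp(NumericVector n0, double N0, double V0,
                  NumericVector alpha, NumericVector beta,
                  NumericVector kplus, NumericVector kminus,
                  int mode, double rho,
                  IntegerVector form, NumericVector c0, NumericVector c1,
                  double t0, double t_max, double max_events,
                  double record_dt,
                  double prod_rate, double prod_DeltaN,
                  double growth_g, double growth_dV) {
  const int M = n0.size();
  std::vector<double> n(n0.begin(), n0.end());
  double nsum = 0.0;
  for (int i = 0; i < M; ++i) nsum += n[i];
  double Ntot = N0;
  double Nav = Ntot - nsum;
  if (mode == 0 && Nav < 0)
    stop("initial sizes exceed the total pool");
  double V = V0;
  double deltaN = 0.0;  // cumulative subunits produced by the production channel

  const bool has_prod = prod_rate > 0.0;
  const bool has_growth = growth_g > 0.0;
  const int n_chan = 2 * M + (has_prod ? 1 : 0) + (has_growth ? 1 : 0);
  std::vector<double> R(n_chan);

  const bool every_event = record_dt <= 0.0;
  std::vector<double> rec_t;
  std::vector<double> rec_n;   // row-major M columns
  std::vector<double> rec_Nav, rec_Ntot, rec_V;
  std::vector<int> rec_ev;

  double t = t0;
  double next_rec = t0;
  bool absorbed = false;
  double n_events = 0.0;

  auto record_state = [&](int ev) {
    rec_t.push_back(t);
    for (int i = 0; i < M; ++i) rec_n.push_back(n[i]);
    rec_Nav.push_back(Nav);
    rec_Ntot.push_back(Ntot);
    rec_V.push_back(V);
    if (every_event) rec_ev.push_back(ev);
  };

  if (every_event) record_state(0);

  while (t < t_max && n_events < max_events) {
    // propensities
    double Rtot = 0.0;
    double pool_factor = (mode == 0) ? (Nav / V) : rho;
    for (int i = 0; i < M; ++i) {
      double on;
      if (form[i] == 0)
        on = kplus[i] * pool_factor * size_feedback(n[i], alpha[i]);
      else
        on = (c0[i] + c1[i] * n[i]) * pool_factor;
      if (mode == 0 && Nav <= 0.0) on = 0.0;
      double off = off_rate(n[i], kminus[i], beta[i]);
      R[2 * i] = on;
      R[2 * i + 1] = off;
      Rtot += on + off;
    }
    int idx = 2 * M;
    if (has_prod) {
      double rp = prod_rate * (prod_DeltaN - deltaN);
      if (rp < 0.0) rp = 0.0;
      R[idx] = rp;
      Rtot += rp;
      ++idx;
    }
    if (has_growth) {
      R[idx] = growth_g;
      Rtot += growth_g;
    }

    if (Rtot <= 0.0) {
      // absorbing state: it holds for the rest of the run
      absorbed = true;
      if (R_finite(t_max)) t = t_max;
      break;
    }

    double r1 = unif_rand();
    double tau = std::log(1.0 / r1) / Rtot;
    double t_next = t + tau;

    if (!every_event) {
      // emit grid samples for the state that holds over [t, t_next)
      while (next_rec <= t_max && next_rec < t_next) {
        double t_save = t;
        t = next_rec;        // record at the grid time
        record_state(0);
        t = t_save;
        next_rec += record_dt;
      }
    }

    if (t_next >= t_max) { t = t_max; break; }
    t = t_next;

    double r2 = unif_rand();
    double target = r2 * Rtot, cum = 0.0;
    int j = n_chan - 1;
    for (int k = 0; k < n_chan; ++k) {
      cum += R[k];
      if (target < cum) { j = k; break; }
    }

    if (j < 2 * M) {
      int i = j / 2;
      if (j % 2 == 0) { n[i] += 1.0; Nav -= 1.0; }
      else            { n[i] -= 1.0; Nav += 1.0; }
    } else if (has_prod && j == 2 * M) {
      deltaN += 1.0; Nav += 1.0; Ntot += 1.0;
    } else {  // growth channel
      Ntot += 1.0; Nav += 1.0; V += growth_dV;
    }
    n_events += 1.0;
    if (every_event) record_state(j + 1);
  }

  if (!every_event) {
    while (next_rec <= t_max + 1e-12 * std::max(1.0, t_max)) {
      double t_save = t;
      t = next_rec;
      record_state(0);
      t = t_save;
      next_rec += record_dt;
      if (rec_t.size() > 100000000) stop("recording grid too fine");
    }
  } else {
    // close the trajectory at the final time so holding-time weights cover it
    if (t > rec_t.back()) record_state(0);
  }

  int n_rec = rec_t.size();
  NumericMatrix sizes(n_rec, M);
  for (int r = 0; r < n_rec; ++r)
    for (int i = 0; i < M; ++i) sizes(r, i) = rec_n[(size_t)r * M + i];

  return List::create(
      _["times"] = NumericVector(rec_t.begin(), rec_t.end()),
      _["sizes"] = sizes,
      _["N_av"] = NumericVector(rec_Nav.begin(), rec_Nav.end()),
      _["N_total"] = NumericVector(rec_Ntot.begin(), rec_Ntot.end()),
      _["V"] = NumericVector(rec_V.begin(), rec_V.end()),
      _["events"] = IntegerVector(rec_ev.begin(), rec_ev.end()),
      _["absorbed"] = absorbed,
      _["n_events"] = n_events,
      _["t_end"] = t);
}

// Gillespie simulation of one or more nuclei growing by envelope (or
// nucleoplasm) subunit assembly, each coupled to its own microtubule aster
// of n_f filaments; all nuclei share one envelope-subunit pool N and all
// filaments share one tubulin pool Nm.  The assembly propensity of nucleus
// i is proportional to the shell volume accessible to its aster,
// (4*pi/3) * ((Lbar_i + R_i)^3 - R_i^3), times the available density
// (N - sum n)/V.  Filaments follow the antenna law: per-filament
// disassembly km_minus * L, assembly km_plus * (Nm - sum L)/V, set to zero
// for nucleus i's filaments under confinement once Lbar_i + R_i >= R_sys.
//
// geometry: 0 = surface growth (4*pi*R^2 = n*dsub),
//           1 = volume growth ((4*pi/3)*R^3 = n*dsub).
// dsub is the subunit area (um^2) or volume (um^3); dL the tubulin step (um).
// [[Rcpp::export]]
List ssa_nucleus_cpp(int n_nuclei, int n_filaments,
                     double N, double Nm, double V,
                     double kplus, double kminus,
                     double km_plus, double km_minus,
                     int geometry, double dsub, double dL,
                     double R_sys,
                     double t_max, double record_dt) {
  const int nn = n_nuclei, nf = n_filaments;
  std::vector<double> n(nn, 0.0);
  std::vector<std::vector<double>> L(nn, std::vector<double>(nf, 0.0));
  std::vector<double> Lsum(nn, 0.0);
  double nsum = 0.0, Lall = 0.0;

  const double FOUR_PI = 4.0 * M_PI;
  auto radius = [&](double x) {
    if (geometry == 0) return std::sqrt(x * dsub / FOUR_PI);
    return std::cbrt(3.0 * x * dsub / FOUR_PI);
  };

  std::vector<double> rec_t, rec_n, rec_R, rec_Lbar;  // row-major nn columns
  double t = 0.0, next_rec = 0.0;
  const bool every_event = record_dt <= 0.0;

  auto record_state = [&](double at) {
    rec_t.push_back(at);
    for (int i = 0; i < nn; ++i) {
      rec_n.push_back(n[i]);
      rec_R.push_back(radius(n[i]));
      rec_Lbar.push_back(nf > 0 ? (Lsum[i] / nf) * dL : 0.0);
    }
  };
  record_state(0.0);

  // channels: per nucleus (on, off), then per nucleus per filament (on, off)
  const int n_chan = 2 * nn + 2 * nn * nf;
  std::vector<double> R(n_chan);
  while (t < t_max) {
    double Rtot = 0.0;
    double pool = (N - nsum) / V;
    double fil_pool = km_plus * (Nm - Lall) / V;
    if (Nm - Lall <= 0.0) fil_pool = 0.0;
    for (int i = 0; i < nn; ++i) {
      double Rn = radius(n[i]);
      double Lbar = nf > 0 ? (Lsum[i] / nf) * dL : 0.0;
      double outer = Lbar + Rn;
      double Vacc = (FOUR_PI / 3.0) * (outer * outer * outer - Rn * Rn * Rn);
      double on = kplus * Vacc * pool;
      if (N - nsum <= 0.0) on = 0.0;
      R[2 * i] = on;
      R[2 * i + 1] = kminus * n[i];
      Rtot += R[2 * i] + R[2 * i + 1];
      bool hindered = R_finite(R_sys) && (outer >= R_sys);
      double on_fil = hindered ? 0.0 : fil_pool;
      for (int k = 0; k < nf; ++k) {
        R[2 * nn + 2 * (i * nf + k)] = on_fil;
        R[2 * nn + 2 * (i * nf + k) + 1] = km_minus * L[i][k];
        Rtot += on_fil + km_minus * L[i][k];
      }
    }
    if (Rtot <= 0.0) break;

    double r1 = unif_rand();
    double t_next = t + std::log(1.0 / r1) / Rtot;
    if (!every_event) {
      while (next_rec <= t_max && next_rec < t_next) {
        record_state(next_rec);
        next_rec += record_dt;
      }
    }
    if (t_next >= t_max) { t = t_max; break; }
    t = t_next;

    double r2 = unif_rand();
    double target = r2 * Rtot, cum = 0.0;
    int j = n_chan - 1;
    for (int k = 0; k < n_chan; ++k) {
      cum += R[k];
      if (target < cum) { j = k; break; }
    }
    if (j < 2 * nn) {
      int i = j / 2;
      if (j % 2 == 0) { n[i] += 1.0; nsum += 1.0; }
      else if (n[i] > 0.0) { n[i] -= 1.0; nsum -= 1.0; }
    } else {
      int q = (j - 2 * nn) / 2;
      int i = q / nf, k = q % nf;
      if ((j - 2 * nn) % 2 == 0) { L[i][k] += 1.0; Lsum[i] += 1.0; Lall += 1.0; }
      else if (L[i][k] > 0.0)    { L[i][k] -= 1.0; Lsum[i] -= 1.0; Lall -= 1.0; }
    }
    if (every_event) record_state(t);
  }

  if (!every_event) {
    while (next_rec <= t_max + 1e-12 * std::max(1.0, t_max)) {
      record_state(next_rec);
      next_rec += record_dt;
    }
  }

  int n_rec = rec_t.size();
  NumericMatrix nm(n_rec, nn), Rm(n_rec, nn), Lm(n_rec, nn);
  for (int r = 0; r < n_rec; ++r)
    for (int i = 0; i < nn; ++i) {
      nm(r, i) = rec_n[(size_t)r * nn + i];
      Rm(r, i) = rec_R[(size_t)r * nn + i];
      Lm(r, i) = rec_Lbar[(size_t)r * nn + i];
    }

  return List::create(
      _["times"] = NumericVector(rec_t.begin(), rec_t.end()),
      _["n"] = nm,
      _["R_n"] = Rm,
      _["Lbar"] = Lm,
      _["t_end"] = t);
}
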