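// Metropolis-within-Gibbs sampler for the hierarchical two-state switching
// first-difference correlated random walk (DCRWS) state-space model.
//
// Model, per track, on a regular grid x_0..x_T (lon/lat degrees):
//   d_t = x_t - x_{t-1}
//   d_t | d_{t-1}, b_t ~ N2( gamma_{b_t} * R(theta_{b_t}) d_{t-1}, Sigma ),  t = 2..T
//   b_t in {1,2} Markov:  P(b_t = 1 | b_{t-1} = k) = alpha_k
// Observation for a fix y in interval [t_i, t_{i+1}) at fraction j:
//   y_c = (1-j) x_{i,c} + j x_{i+1,c} + tau_c * eps,  eps ~ t(nu_c)   (c = lon, lat)
// with (nu, tau) fixed per Argos location class.
//
// Movement parameters (gamma, theta, alpha, Sigma) are shared across tracks;
// latent locations and states are per track.  States are updated by
// single-site Gibbs, locations and parameters by adaptive random-walk
// Metropolis (adaptation during burn-in only), alpha by conjugate Beta Gibbs.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

struct TrackData {
  int T;                       // number of steps; T+1 grid points
  std::vector<double> xlon, xlat;   // latent locations, length T+1
  std::vector<int> b;               // states 1/2, index 1..T used (0 unused)
  // observations
  std::vector<double> ylon, ylat, jfrac, nulon, nulat, taulon, taulat;
  std::vector<int> idx;             // 0-based interval index, in [0, T-1]
  std::vector<std::vector<int> > fix_in;   // interval -> fix indices
  // adaptive per-site proposal scales (log)
  std::vector<double> ls_x;
};

struct Params {
  double gamma[2];   // persistence, state 1 (transit) > state 2
  double theta[2];   // mean turn angle, radians
  double alpha[2];   // P(b_t = 1 | b_{t-1} = k)
  double sd1, sd2, rho;   // Sigma = [[sd1^2, rho sd1 sd2],[rho sd1 sd2, sd2^2]]
  // derived
  double si11, si12, si22, logdet;
  void refresh() {
    double s11 = sd1 * sd1, s22 = sd2 * sd2, s12 = rho * sd1 * sd2;
    double det = s11 * s22 - s12 * s12;
    logdet = std::log(det);
    si11 = s22 / det; si22 = s11 / det; si12 = -s12 / det;
  }
};

const double LOG2PI = 1.8378770664093453;

inline double ldnorm2(double ex, double ey, const Params& p) {
  double q = p.si11 * ex * ex + 2.0 * p.si12 * ex * ey + p.si22 * ey * ey;
  return -LOG2PI - 0.5 * p.logdet - 0.5 * q;
}

// log density of process term t (t in 2..T) for track under state bt
inline double proc_term(const TrackData& tr, int t, int bt, const Params& p) {
  int k = bt - 1;
  double g = p.gamma[k], c = std::cos(p.theta[k]), s = std::sin(p.theta[k]);
  double dpx = tr.xlon[t - 1] - tr.xlon[t - 2];
  double dpy = tr.xlat[t - 1] - tr.xlat[t - 2];
  double mx = g * (c * dpx - s * dpy);
  double my = g * (s * dpx + c * dpy);
  double ex = (tr.xlon[t] - tr.xlon[t - 1]) - mx;
  double ey = (tr.xlat[t] - tr.xlat[t - 1]) - my;
  return ldnorm2(ex, ey, p);
}

// log observation density of fix f given current latent path
inline double obs_term(const TrackData& tr, int f) {
  int i = tr.idx[f];
  double j = tr.jfrac[f];
  double px = (1.0 - j) * tr.xlon[i] + j * tr.xlon[i + 1];
  double py = (1.0 - j) * tr.xlat[i] + j * tr.xlat[i + 1];
  double rl = (tr.ylon[f] - px) / tr.taulon[f];
  double rt = (tr.ylat[f] - py) / tr.taulat[f];
  return R::dt(rl, tr.nulon[f], 1) - std::log(tr.taulon[f]) +
         R::dt(rt, tr.nulat[f], 1) - std::log(tr.taulat[f]);
}

// all observation terms touching grid point t (fixes in intervals t-1 and t)
inline double obs_around(const TrackData& tr, int t) {
  double ll = 0.0;
  if (t - 1 >= 0)
    for (size_t u = 0; u < tr.fix_in[t - 1].size(); ++u)
      ll += obs_term(tr, tr.fix_in[t - 1][u]);
  if (t <= tr.T - 1)
    for (size_t u = 0; u < tr.fix_in[t].size(); ++u)
      ll += obs_term(tr, tr.fix_in[t][u]);
  return ll;
}

// process terms touching grid point t: {t, t+1, t+2} clipped to [2, T]
inline double proc_around(const TrackData& tr, int t, const Params& p) {
  double ll = 0.0;
  int lo = t < 2 ? 2 : t, hi = t + 2 > tr.T ? tr.T : t + 2;
  for (int s = lo; s <= hi; ++s) ll += proc_term(tr, s, tr.b[s], p);
  return ll;
}

inline double wrap_angle(double th) {
  double u = (th + M_PI) / (2.0 * M_PI);
  u -= std::floor(u);
  return u * 2.0 * M_PI - M_PI;
}

// forward-filtering backward-sampling update of one track's state path:
// exact joint draw of b_{1..T} given locations and parameters (the Markov
// chain over states with the process densities as emissions; the first
// difference has no process term, so its emission is flat)
void update_b(TrackData& tr, const Params& p) {
  int T = tr.T;
  std::vector<double> a(2 * (T + 1));
  a[2 * 1 + 0] = 0.5; a[2 * 1 + 1] = 0.5;       // uniform prior on b_1
  for (int t = 2; t <= T; ++t) {
    double e0 = proc_term(tr, t, 1, p);
    double e1 = proc_term(tr, t, 2, p);
    double m = e0 > e1 ? e0 : e1;
    e0 = std::exp(e0 - m); e1 = std::exp(e1 - m);
    double p0 = a[2 * (t - 1)], p1 = a[2 * (t - 1) + 1];
    double f0 = e0 * (p0 * p.alpha[0] + p1 * p.alpha[1]);
    double f1 = e1 * (p0 * (1.0 - p.alpha[0]) + p1 * (1.0 - p.alpha[1]));
    double z = f0 + f1;
    if (z <= 0) { f0 = 0.5; f1 = 0.5; z = 1.0; }
    a[2 * t] = f0 / z; a[2 * t + 1] = f1 / z;
  }
  double pr1 = a[2 * T] / (a[2 * T] + a[2 * T + 1]);
  tr.b[T] = (R::unif_rand() < pr1) ? 1 : 2;
  for (int t = T - 1; t >= 1; --t) {
    double trans0 = tr.b[t + 1] == 1 ? p.alpha[0] : 1.0 - p.alpha[0];
    double trans1 = tr.b[t + 1] == 1 ? p.alpha[1] : 1.0 - p.alpha[1];
    double w0 = a[2 * t] * trans0, w1 = a[2 * t + 1] * trans1;
    tr.b[t] = (R::unif_rand() * (w0 + w1) < w0) ? 1 : 2;
  }
}

// random-walk Metropolis update of every latent location of one track
void update_x(TrackData& tr, const Params& p, bool adapt, double eta,
              long& acc, long& tot) {
  for (int t = 0; t <= tr.T; ++t) {
    // mixture proposal: mostly the adapted per-site scale, occasionally a
    // fixed process-scale kick so a site can never freeze at a biased
    // location once its scale has shrunk to the observation scale
    bool kick = R::unif_rand() < 0.05;
    double s = kick ? 0.05 : std::exp(tr.ls_x[t]);
    double ox = tr.xlon[t], oy = tr.xlat[t];
    double ll0 = proc_around(tr, t, p) + obs_around(tr, t);
    tr.xlon[t] = ox + s * R::norm_rand();
    tr.xlat[t] = oy + s * R::norm_rand();
    double ll1 = proc_around(tr, t, p) + obs_around(tr, t);
    bool ok = std::log(R::unif_rand()) < ll1 - ll0;
    if (!ok) { tr.xlon[t] = ox; tr.xlat[t] = oy; } else ++acc;
    ++tot;
    if (adapt && !kick) tr.ls_x[t] += eta * ((ok ? 1.0 : 0.0) - 0.3);
  }
}

// total process loglik over terms in a given state, for parameter updates
double proc_ll_state(const std::vector<TrackData>& trs, int state,
                     const Params& p) {
  double ll = 0.0;
  for (size_t i = 0; i < trs.size(); ++i)
    for (int t = 2; t <= trs[i].T; ++t)
      if (trs[i].b[t] == state) ll += proc_term(trs[i], t, state, p);
  return ll;
}

double proc_ll_all(const std::vector<TrackData>& trs, const Params& p) {
  double ll = 0.0;
  for (size_t i = 0; i < trs.size(); ++i)
    for (int t = 2; t <= trs[i].T; ++t)
      ll += proc_term(trs[i], t, trs[i].b[t], p);
  return ll;
}

// log prior of (log sd) under half-t(df, scale) on sd, including Jacobian
inline double lp_logsd(double lsd, double df, double scale) {
  double sd = std::exp(lsd);
  return R::dt(sd / scale, df, 1) + lsd;
}

}  // namespace

// [[Rcpp::export(name = ".dcrws_chain")]]
List dcrws_chain(List tracks, List init, List priors, List ctrl) {
  int n_iter = as<int>(ctrl["n_iter"]);
  int n_burn = as<int>(ctrl["n_burn"]);
  int thin = as<int>(ctrl["thin"]);

  double sd_df = as<double>(priors["sd_df"]);
  double sd_scale = as<double>(priors["sd_scale"]);

  Params p;
  NumericVector g0 = init["gamma"], th0 = init["theta"], a0 = init["alpha"];
  p.gamma[0] = g0[0]; p.gamma[1] = g0[1];
  p.theta[0] = th0[0]; p.theta[1] = th0[1];
  p.alpha[0] = a0[0]; p.alpha[1] = a0[1];
  p.sd1 = as<double>(init["sd1"]);
  p.sd2 = as<double>(init["sd2"]);
  p.rho = as<double>(init["rho"]);
  p.refresh();

  int ntr = tracks.size();
  std::vector<TrackData> trs(ntr);
  for (int i = 0; i < ntr; ++i) {
    List tl = tracks[i];
    TrackData& tr = trs[i];
    tr.T = as<int>(tl["T"]);
    NumericMatrix x0 = tl["x0"];
    tr.xlon.assign(x0.nrow(), 0.0); tr.xlat.assign(x0.nrow(), 0.0);
    for (int r = 0; r < x0.nrow(); ++r) { tr.xlon[r] = x0(r, 0); tr.xlat[r] = x0(r, 1); }
    IntegerVector b0 = tl["b0"];
    tr.b.assign(tr.T + 1, 1);
    for (int t = 1; t <= tr.T; ++t) tr.b[t] = b0[t - 1];
    NumericMatrix y = tl["obs"], nu = tl["nu"], tau = tl["tau"];
    IntegerVector ix = tl["idx"];
    NumericVector jf = tl["j"];
    int n = y.nrow();
    tr.ylon.resize(n); tr.ylat.resize(n); tr.jfrac.resize(n);
    tr.nulon.resize(n); tr.nulat.resize(n);
    tr.taulon.resize(n); tr.taulat.resize(n); tr.idx.resize(n);
    tr.fix_in.assign(tr.T, std::vector<int>());
    for (int f = 0; f < n; ++f) {
      tr.ylon[f] = y(f, 0); tr.ylat[f] = y(f, 1);
      tr.nulon[f] = nu(f, 0); tr.nulat[f] = nu(f, 1);
      tr.taulon[f] = tau(f, 0); tr.taulat[f] = tau(f, 1);
      tr.idx[f] = ix[f]; tr.jfrac[f] = jf[f];
      tr.fix_in[tr.idx[f]].push_back(f);
    }
    // start location proposals at the process scale everywhere; burn-in
    // adaptation shrinks pinned sites down to the observation scale (the
    // reverse start would freeze any macroscopic initialization bias)
    tr.ls_x.assign(tr.T + 1, std::log(0.05));
  }

  // parameter proposal scales (log), adapted during burn-in, target 0.44
  double ls_g[2] = {std::log(0.05), std::log(0.05)};
  double ls_t[2] = {std::log(0.3), std::log(0.3)};
  double ls_s[3] = {std::log(0.1), std::log(0.1), std::log(0.2)};
  long acc_x = 0, tot_x = 0, acc_par = 0, tot_par = 0;

  // retention fires at iter = n_burn, n_burn + thin, ... < n_iter
  int n_ret = (n_iter - n_burn + thin - 1) / thin;
  NumericMatrix out_par(n_ret, 9);
  List out_tracks(ntr);
  std::vector<NumericMatrix> out_lon(ntr), out_lat(ntr);
  std::vector<std::vector<double> > bsum(ntr);
  for (int i = 0; i < ntr; ++i) {
    out_lon[i] = NumericMatrix(n_ret, trs[i].T + 1);
    out_lat[i] = NumericMatrix(n_ret, trs[i].T + 1);
    bsum[i].assign(trs[i].T, 0.0);
  }

  RNGScope scope;
  int ret = 0;
  for (int iter = 0; iter < n_iter; ++iter) {
    bool adapt = iter < n_burn;
    double eta = 0.05 / std::sqrt(1.0 + 0.05 * iter);

    for (int i = 0; i < ntr; ++i) {
      update_b(trs[i], p);
      update_x(trs[i], p, adapt, eta, acc_x, tot_x);
    }

    // several parameter sweeps per location sweep: parameter conditionals
    // are cheap relative to the path update and mix slowly otherwise
    for (int sweep = 0; sweep < 3; ++sweep) {

    // gamma_k: flat prior on [0,1] with ordering gamma_1 > gamma_2
    for (int k = 0; k < 2; ++k) {
      double prop = p.gamma[k] + std::exp(ls_g[k]) * R::norm_rand();
      bool valid = prop >= 0.0 && prop <= 1.0 &&
        (k == 0 ? prop > p.gamma[1] : prop < p.gamma[0]);
      bool ok = false;
      if (valid) {
        double ll0 = proc_ll_state(trs, k + 1, p);
        Params q = p; q.gamma[k] = prop;
        double ll1 = proc_ll_state(trs, k + 1, q);
        ok = std::log(R::unif_rand()) < ll1 - ll0;
        if (ok) p.gamma[k] = prop;
      }
      ++tot_par; if (ok) ++acc_par;
      if (adapt) ls_g[k] += eta * ((ok ? 1.0 : 0.0) - 0.44);
    }

    // theta_k: uniform prior on (-pi, pi], wrapped random walk
    for (int k = 0; k < 2; ++k) {
      double prop = wrap_angle(p.theta[k] + std::exp(ls_t[k]) * R::norm_rand());
      double ll0 = proc_ll_state(trs, k + 1, p);
      Params q = p; q.theta[k] = prop;
      double ll1 = proc_ll_state(trs, k + 1, q);
      bool ok = std::log(R::unif_rand()) < ll1 - ll0;
      if (ok) p.theta[k] = prop;
      ++tot_par; if (ok) ++acc_par;
      if (adapt) ls_t[k] += eta * ((ok ? 1.0 : 0.0) - 0.44);
    }

    // Sigma: half-t priors on sds (log scale), uniform prior on rho (atanh)
    for (int k = 0; k < 3; ++k) {
      Params q = p;
      double lp0, lp1;
      if (k < 3 && k != 2) {
        double lsd = std::log(k == 0 ? p.sd1 : p.sd2);
        double prop = lsd + std::exp(ls_s[k]) * R::norm_rand();
        if (k == 0) q.sd1 = std::exp(prop); else q.sd2 = std::exp(prop);
        lp0 = lp_logsd(lsd, sd_df, sd_scale);
        lp1 = lp_logsd(prop, sd_df, sd_scale);
      } else {
        double z = std::atanh(p.rho);
        double prop = z + std::exp(ls_s[2]) * R::norm_rand();
        q.rho = std::tanh(prop);
        lp0 = std::log1p(-p.rho * p.rho);   // Jacobian of tanh, uniform prior
        lp1 = std::log1p(-q.rho * q.rho);
      }
      q.refresh();
      double ll0 = proc_ll_all(trs, p) + lp0;
      double ll1 = proc_ll_all(trs, q) + lp1;
      bool ok = std::log(R::unif_rand()) < ll1 - ll0;
      if (ok) p = q;
      ++tot_par; if (ok) ++acc_par;
      if (adapt) ls_s[k] += eta * ((ok ? 1.0 : 0.0) - 0.44);
    }

    }  // parameter sweeps

    // alpha_k: conjugate Beta(1 + n_{k->1}, 1 + n_{k->2}) Gibbs
    {
      double n11 = 0, n12 = 0, n21 = 0, n22 = 0;
      for (int i = 0; i < ntr; ++i)
        for (int t = 1; t < trs[i].T; ++t) {
          int from = trs[i].b[t], to = trs[i].b[t + 1];
          if (from == 1) { if (to == 1) ++n11; else ++n12; }
          else { if (to == 1) ++n21; else ++n22; }
        }
      p.alpha[0] = R::rbeta(1.0 + n11, 1.0 + n12);
      p.alpha[1] = R::rbeta(1.0 + n21, 1.0 + n22);
    }

    if (iter >= n_burn && (iter - n_burn) % thin == 0) {
      out_par(ret, 0) = p.gamma[0]; out_par(ret, 1) = p.gamma[1];
      out_par(ret, 2) = p.theta[0]; out_par(ret, 3) = p.theta[1];
      out_par(ret, 4) = p.alpha[0]; out_par(ret, 5) = p.alpha[1];
      out_par(ret, 6) = p.sd1; out_par(ret, 7) = p.sd2; out_par(ret, 8) = p.rho;
      for (int i = 0; i < ntr; ++i) {
        for (int t = 0; t <= trs[i].T; ++t) {
          out_lon[i](ret, t) = trs[i].xlon[t];
          out_lat[i](ret, t) = trs[i].xlat[t];
        }
        for (int t = 1; t <= trs[i].T; ++t) bsum[i][t - 1] += trs[i].b[t];
      }
      ++ret;
    }
  }

  for (int i = 0; i < ntr; ++i) {
    out_tracks[i] = List::create(
      _["lon"] = out_lon[i], _["lat"] = out_lat[i],
      _["b_mean"] = NumericVector(bsum[i].begin(), bsum[i].end()) /
                    static_cast<double>(n_ret > 0 ? n_ret : 1));
  }

  colnames(out_par) = CharacterVector::create(
    "gamma1", "gamma2", "theta1", "theta2",
    "alpha1", "alpha2", "sigma_lon", "sigma_lat", "rho");

  return List::create(
    _["params"] = out_par,
    _["tracks"] = out_tracks,
    _["accept"] = NumericVector::create(
      _["x"] = tot_x ? static_cast<double>(acc_x) / tot_x : NA_REAL,
      _["par"] = tot_par ? static_cast<double>(acc_par) / tot_par : NA_REAL));
}
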