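#include <Rcpp.h>
using namespace Rcpp;

// Sequential belief filters for the three agent families (ideal observer,
// delta-rule RL, particle filter) and the trial-log likelihood built on
// them. The recursions mirror the R implementations in R/agents.R exactly
// (a test asserts agreement); this compiled path exists because model
// fitting evaluates the likelihood thousands of times.

static const double PRIOR_SD = 28.86751345948129; // 100/sqrt(12)

struct Params {
  double lr, gain, beta_t, bonus, rating_sd, conf_sd, conc;
};

struct State {
  int model; // 0 ideal, 1 rl, 2 particle
  double ev[2], esd[2], m2[2];
  int nobs[2];
  int np;
  // particles are grid indices: resampling only ever duplicates grid points,
  // so the beta log-density terms can be cached per grid point
  std::vector<int> idx[2];
  std::vector<double> lw[2];
  std::vector<double> grid, am1, bm1, lconst;

  void reset(const Params &p) {
    for (int a = 0; a < 2; ++a) {
      ev[a] = 50.0; esd[a] = PRIOR_SD; m2[a] = 0.0; nobs[a] = 0;
    }
    if (model == 2) {
      grid.resize(np); am1.resize(np); bm1.resize(np); lconst.resize(np);
      double mean = 0, msq = 0;
      for (int j = 0; j < np; ++j) {
        grid[j] = 100.0 * (j + 0.5) / np;
        double mu = std::min(std::max(grid[j] / 100.0, 1e-4), 1.0 - 1e-4);
        double aa = p.conc * mu, bb = p.conc * (1.0 - mu);
        am1[j] = aa - 1.0; bm1[j] = bb - 1.0;
        lconst[j] = std::lgamma(aa + bb) - std::lgamma(aa) - std::lgamma(bb);
        mean += grid[j]; msq += grid[j] * grid[j];
      }
      mean /= np; msq /= np;
      for (int a = 0; a < 2; ++a) {
        idx[a].resize(np); lw[a].resize(np);
        for (int j = 0; j < np; ++j) {
          idx[a][j] = j;
          lw[a][j] = -std::log((double)np);
        }
      }
      esd[0] = esd[1] = std::sqrt(msq - mean * mean);
    }
  }

  double latent_conf(int a, const Params &p) const {
    double disp;
    if (model == 0) {
      int n = nobs[a];
      if (n < 2) disp = PRIOR_SD / std::sqrt((double)std::max(n, 1));
      else disp = esd[a] / std::sqrt((double)n);
    } else disp = esd[a];
    double c = 1.0 - p.gain * disp / 100.0;
    return std::min(std::max(c, 0.0), 1.0);
  }

  void update(int a, double x, const Params &p) {
    if (model == 0) {
      int n = nobs[a] + 1;
      if (n == 1) { ev[a] = x; m2[a] = 0.0; }
      else {
        double d = x - ev[a];
        ev[a] += d / n;
        m2[a] += d * (x - ev[a]);
        esd[a] = std::sqrt(m2[a] / (n - 1));
      }
      nobs[a] = n;
    } else if (model == 1) {
      double pe = x - ev[a];
      esd[a] = (1.0 - p.lr) * esd[a] + p.lr * std::fabs(pe);
      ev[a] += p.lr * pe;
      nobs[a] += 1;
    } else {
      std::vector<int> &ix = idx[a];
      std::vector<double> &ll = lw[a];
      double px = std::min(std::max(x / 100.0, 0.005), 0.995);
      double lpx = std::log(px), lqx = std::log1p(-px);
      double mx = -INFINITY;
      for (int j = 0; j < np; ++j) {
        int g = ix[j];
        ll[j] += lconst[g] + am1[g] * lpx + bm1[g] * lqx;
        if (ll[j] > mx) mx = ll[j];
      }
      if (!std::isfinite(mx)) { // underflow: re-initialize (rare)
        for (int j = 0; j < np; ++j) {
          ix[j] = j;
          ll[j] = -std::log((double)np);
        }
        mx = ll[0];
      }
      // long-double accumulators mirror R's summation, so the reference
      // implementation and this filter stay numerically interchangeable
      long double sum = 0;
      for (int j = 0; j < np; ++j) sum += std::exp(ll[j] - mx);
      double lse = mx + std::log((double)sum);
      long double ess_den = 0;
      for (int j = 0; j < np; ++j) {
        ll[j] -= lse;
        double w = std::exp(ll[j]);
        ess_den += (long double)w * w;
      }
      if (1.0 / (double)ess_den < np / 2.0) { // systematic resampling, fixed offset
        std::vector<double> cw(np);
        std::vector<int> ni(np);
        long double c = 0;
        for (int j = 0; j < np; ++j) { c += std::exp(ll[j]); cw[j] = (double)c; }
        int k = 0;
        for (int j = 0; j < np; ++j) {
          double u = (j + 0.5) / np;
          while (k < np - 1 && cw[k] < u) ++k;
          ni[j] = ix[k];
        }
        ix = ni;
        for (int j = 0; j < np; ++j) ll[j] = -std::log((double)np);
      }
      long double evv = 0, ev2 = 0;
      for (int j = 0; j < np; ++j) {
        double w = std::exp(ll[j]);
        double mj = grid[ix[j]];
        evv += (long double)w * mj; ev2 += (long double)w * mj * mj;
      }
      double ev_d = (double)evv, ev2_d = (double)ev2;
      ev[a] = ev_d;
      esd[a] = std::sqrt(std::max(ev2_d - ev_d * ev_d, 0.0));
      nobs[a] += 1;
    }
  }
};

static Params unpack(const NumericVector &par) {
  Params p;
  p.lr = par[0]; p.gain = par[1]; p.beta_t = par[2]; p.bonus = par[3];
  p.rating_sd = par[4]; p.conf_sd = par[5]; p.conc = par[6];
  return p;
}

// Negative log-likelihood of a (single-subject, time-ordered) trial log.
// design: 1 = rating trials reveal an outcome and rate one arm,
//         2 = rating trials show nothing and rate both arms.
// [[Rcpp::export(name = ".bm_nll_cpp")]]
double bm_nll_cpp(IntegerVector block, IntegerVector is_choice, IntegerVector arm,
                  NumericVector outcome, NumericVector vr, NumericVector bc,
                  NumericVector vr_other, NumericVector bc_other,
                  int design, int model, NumericVector par, int n_particles) {
  Params p = unpack(par);
  State st;
  st.model = model;
  st.np = n_particles;
  st.reset(p);
  int n = block.size();
  int cur_block = n > 0 ? block[0] : 0;
  double nll = 0.0;
  for (int i = 0; i < n; ++i) {
    if (block[i] != cur_block) { st.reset(p); cur_block = block[i]; }
    int a = arm[i];
    if (!is_choice[i]) {
      if (design == 1 && !NumericVector::is_na(outcome[i]))
        st.update(a, outcome[i], p);
      if (!NumericVector::is_na(vr[i]))
        nll -= R::dnorm(vr[i], st.ev[a], p.rating_sd, 1);
      if (!NumericVector::is_na(bc[i]))
        nll -= R::dnorm(bc[i], st.latent_conf(a, p), p.conf_sd, 1);
      if (design == 2) {
        int o = 1 - a;
        if (!NumericVector::is_na(vr_other[i]))
          nll -= R::dnorm(vr_other[i], st.ev[o], p.rating_sd, 1);
        if (!NumericVector::is_na(bc_other[i]))
          nll -= R::dnorm(bc_other[i], st.latent_conf(o, p), p.conf_sd, 1);
      }
    } else {
      double pch;
      if (st.ev[0] == st.ev[1]) pch = 0.5;
      else {
        int hi = st.ev[1] > st.ev[0] ? 1 : 0;
        double dv = std::fabs(st.ev[0] - st.ev[1]);
        double lin = -p.beta_t * dv / 100.0 + p.bonus * (1.0 - st.latent_conf(hi, p));
        double p_lo = 1.0 / (1.0 + std::exp(-lin));
        pch = (a == hi) ? 1.0 - p_lo : p_lo;
      }
      nll -= std::log(std::max(pch, 1e-12));
      if (!NumericVector::is_na(outcome[i])) st.update(a, outcome[i], p);
    }
  }
  return nll;
}

// Per-trial latent trajectory (state after each trial's update), for
// checking the compiled filter against the R agents.
// [[Rcpp::export(name = ".bm_traj_cpp")]]
NumericMatrix bm_traj_cpp(IntegerVector block, IntegerVector is_choice,
                          IntegerVector arm, NumericVector outcome,
                          int design, int model, NumericVector par,
                          int n_particles) {
  Params p = unpack(par);
  State st;
  st.model = model;
  st.np = n_particles;
  st.reset(p);
  int n = block.size();
  int cur_block = n > 0 ? block[0] : 0;
  NumericMatrix out(n, 6);
  colnames(out) = CharacterVector::create("est_value0", "est_sd0", "est_value1",
                                          "est_sd1", "conf0", "conf1");
  for (int i = 0; i < n; ++i) {
    if (block[i] != cur_block) { st.reset(p); cur_block = block[i]; }
    int a = arm[i];
    bool update = !NumericVector::is_na(outcome[i]) &&
      (is_choice[i] || design == 1);
    if (update) st.update(a, outcome[i], p);
    out(i, 0) = st.ev[0]; out(i, 1) = st.esd[0];
    out(i, 2) = st.ev[1]; out(i, 3) = st.esd[1];
    out(i, 4) = st.latent_conf(0, p); out(i, 5) = st.latent_conf(1, p);
  }
  return out;
}
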