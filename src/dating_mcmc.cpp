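// Metropolis-Hastings sampler for per-gene divergence dating on a fixed
// rooted binary topology: node ages with parent>child constraints, per-branch
// lognormal rate multipliers (or a strict clock), GTR+G+I substitution
// parameters, a constant-size coalescent prior on node ages, and a narrow
// normal calibration on the root age.  Proposal scales adapt during burn-in
// only, so detailed balance holds for the recorded samples.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>

using namespace Rcpp;

namespace {

struct Tree {
  int ntip, nnode, root;
  arma::imat edges;              // postorder, 1-based
  std::vector<int> parent;       // 0-based node -> parent (-1 at root)
  std::vector<std::vector<int>> children;
  std::vector<int> edge_of_child; // node -> incoming edge index
};

struct Subst {
  arma::vec freq;        // 4
  arma::mat U, Uinv;     // eigen system of normalized GTR generator
  arma::vec lam;
  arma::vec class_rate;  // ncat gamma classes (+ invariant handled separately)
  double pinv;
};

void gtr_eigen(const arma::vec& exch, const arma::vec& freq, Subst& S) {
  arma::mat Q(4, 4, arma::fill::zeros);
  int idx = 0; // order: AC, AG, AT, CG, CT, GT
  for (int i = 0; i < 4; ++i)
    for (int j = i + 1; j < 4; ++j) {
      Q(i, j) = exch(idx) * freq(j);
      Q(j, i) = exch(idx) * freq(i);
      ++idx;
    }
  for (int i = 0; i < 4; ++i) Q(i, i) = -arma::accu(Q.row(i));
  double mu = 0.0;
  for (int i = 0; i < 4; ++i) mu -= freq(i) * Q(i, i);
  Q /= mu;
  arma::vec sq = arma::sqrt(S.freq);
  arma::mat B = arma::diagmat(sq) * Q * arma::diagmat(1.0 / sq);
  arma::mat Bs = 0.5 * (B + B.t());
  arma::vec ev; arma::mat V;
  arma::eig_sym(ev, V, Bs);
  S.lam = ev;
  S.U = arma::diagmat(1.0 / sq) * V;
  S.Uinv = V.t() * arma::diagmat(sq);
}

void gamma_rates(double alpha, int ncat, arma::vec& out) {
  // category means of the discretized gamma(alpha, alpha), mean 1
  out.set_size(ncat);
  double prev = 0.0;
  for (int k = 0; k < ncat; ++k) {
    double ub = (k == ncat - 1) ? 1.0 : (double)(k + 1) / ncat;
    double qb = (k == ncat - 1) ? arma::datum::inf
                                : R::qgamma(ub, alpha, 1.0 / alpha, 1, 0);
    double pu = (k == ncat - 1) ? 1.0 : R::pgamma(qb, alpha + 1.0, 1.0 / alpha, 1, 0);
    out(k) = ncat * (pu - prev);
    prev = pu;
  }
}

class Lik {
public:
  Lik(const arma::imat& tips, const arma::vec& w, const Tree& tr)
      : tip_states(tips), weights(w), tree(tr) {
    npat = tips.n_cols;
    partial.resize(tr.nnode);
  }
  double eval(const std::vector<double>& blen, const Subst& S) {
    const int ncat = S.class_rate.n_elem;
    arma::mat class_ll(npat, ncat + 1);
    arma::vec logscale(npat);
    arma::mat contrib(4, npat);
    for (int c = 0; c <= ncat; ++c) {
      double rate = (c == ncat) ? 0.0 : S.class_rate(c) / std::max(1.0 - S.pinv, 1e-12);
      logscale.zeros();
      for (int n = tree.ntip; n < tree.nnode; ++n) partial[n].reset();
      for (arma::uword e = 0; e < tree.edges.n_rows; ++e) {
        int pa = tree.edges(e, 0) - 1, ch = tree.edges(e, 1) - 1;
        arma::mat P = S.U * arma::diagmat(arma::exp(S.lam * blen[e] * rate)) * S.Uinv;
        P.transform([](double v) { return v < 0.0 ? 0.0 : v; });
        if (ch < tree.ntip) {
          for (int p = 0; p < npat; ++p) {
            int s = tip_states(ch, p);
            if (s == 0) contrib.col(p).ones();
            else contrib.col(p) = P.col(s - 1);
          }
        } else {
          contrib = P * partial[ch];
          double mn = contrib.min();
          if (mn < 1e-30) {
            arma::rowvec mx = arma::max(contrib, 0);
            for (int p = 0; p < npat; ++p) {
              double m = std::max(mx(p), 1e-300);
              contrib.col(p) /= m;
              logscale(p) += std::log(m);
            }
          }
        }
        if (partial[pa].is_empty()) partial[pa] = contrib;
        else partial[pa] %= contrib;
      }
      arma::rowvec rl = S.freq.t() * partial[tree.root - 1];
      for (int p = 0; p < npat; ++p)
        class_ll(p, c) = std::log(std::max(rl(p), 1e-300)) + logscale(p);
    }
    double total = 0.0;
    double lp_g = std::log((1.0 - S.pinv) / ncat);
    double lp_i = std::log(std::max(S.pinv, 1e-300));
    for (int p = 0; p < npat; ++p) {
      double mx = -arma::datum::inf;
      for (int c = 0; c <= ncat; ++c) {
        double v = class_ll(p, c) + (c == ncat ? lp_i : lp_g);
        if (v > mx) mx = v;
      }
      double s = 0.0;
      for (int c = 0; c <= ncat; ++c)
        s += std::exp(class_ll(p, c) + (c == ncat ? lp_i : lp_g) - mx);
      total += weights(p) * (mx + std::log(s));
    }
    return total;
  }
private:
  const arma::imat& tip_states;
  const arma::vec& weights;
  const Tree& tree;
  int npat;
  std::vector<arma::mat> partial;
};

} // namespace

// [[Rcpp::export]]
List dating_mcmc_cpp(const arma::imat& tip_states,  // ntip x npat, 1..4, 0 NA
                     const arma::vec& weights,
                     const arma::imat& edges,        // postorder, 1-based
                     int ntip, int nnode, int root,
                     const arma::vec& init_ages,     // length nnode (tips 0)
                     const arma::vec& base_freq,
                     double root_mean, double root_sd,
                     double log_theta_min, double log_theta_max,
                     int chain, int burnin, int thin,
                     bool lognormal_clock,
                     double mu_init,
                     int ncat, int seed) {
  Tree tr;
  tr.ntip = ntip; tr.nnode = nnode; tr.root = root; tr.edges = edges;
  tr.parent.assign(nnode, -1);
  tr.children.assign(nnode, {});
  tr.edge_of_child.assign(nnode, -1);
  const int nedge = edges.n_rows;
  for (int e = 0; e < nedge; ++e) {
    int pa = edges(e, 0) - 1, ch = edges(e, 1) - 1;
    tr.parent[ch] = pa;
    tr.children[pa].push_back(ch);
    tr.edge_of_child[ch] = e;
  }

  std::mt19937_64 rng(seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::normal_distribution<double> norm(0.0, 1.0);

  // state
  std::vector<double> age(init_ages.begin(), init_ages.end());
  std::vector<double> z(nedge, 0.0);
  double log_mu = std::log(mu_init);
  double S_clock = lognormal_clock ? 0.1 : 0.0;
  arma::vec exch(6, arma::fill::ones);
  double alpha = 1.0, pinv = 0.05;
  double log_theta = std::log(std::max(root_mean / 4.0, 1.1e-3));
  log_theta = std::min(std::max(log_theta, log_theta_min), log_theta_max);

  Subst sub;
  sub.freq = base_freq;
  gtr_eigen(exch, base_freq, sub);
  gamma_rates(alpha, ncat, sub.class_rate);
  sub.pinv = pinv;

  Lik lik(tip_states, weights, tr);

  auto branch_lengths = [&](std::vector<double>& bl) {
    double mu = std::exp(log_mu);
    for (int e = 0; e < nedge; ++e) {
      int pa = edges(e, 0) - 1, ch = edges(e, 1) - 1;
      double rate = lognormal_clock
        ? mu * std::exp(S_clock * z[e] - 0.5 * S_clock * S_clock)
        : mu;
      bl[e] = rate * (age[pa] - age[ch]);
    }
  };

  auto log_prior = [&]() {
    // coalescent on internal node ages
    std::vector<double> t;
    for (int n = ntip; n < nnode; ++n) t.push_back(age[n]);
    std::sort(t.begin(), t.end());
    double theta = std::exp(log_theta);
    double lp = 0.0, prev = 0.0;
    int k = ntip;
    for (double ti : t) {
      double comb = 0.5 * k * (k - 1);
      lp += -std::log(theta) - comb * (ti - prev) / theta;
      prev = ti; --k;
    }
    // root calibration
    double r = age[root - 1];
    lp += R::dnorm(r, root_mean, root_sd, 1);
    // clock priors
    if (lognormal_clock) {
      for (int e = 0; e < nedge; ++e) lp += R::dnorm(z[e], 0.0, 1.0, 1);
      lp += R::dexp(S_clock, 1.0 / 3.0, 1); // mean 1/3
    }
    // substitution priors: log-uniform within bounds (bounds checked in moves)
    return lp;
  };

  std::vector<double> bl(nedge);
  branch_lengths(bl);
  double cur_ll = lik.eval(bl, sub);
  double cur_lp = log_prior();

  // proposal machinery
  enum Move { M_AGE, M_ROOT, M_Z, M_MU, M_S, M_EXCH, M_ALPHA, M_PINV, M_THETA,
              M_AGESCALE, M_RIDGE, M_UPDOWN, M_AGERATE, N_MOVES };
  std::vector<double> scale(N_MOVES, 0.1);
  scale[M_AGE] = 0.5; scale[M_ROOT] = root_sd * 2.0; scale[M_Z] = 0.5;
  scale[M_MU] = 0.2; scale[M_S] = 0.3; scale[M_EXCH] = 0.3;
  scale[M_ALPHA] = 0.4; scale[M_PINV] = 0.1; scale[M_THETA] = 0.5;
  scale[M_AGESCALE] = 0.1; scale[M_RIDGE] = 0.3; scale[M_UPDOWN] = 0.1;
  std::vector<double> wts(N_MOVES, 1.0);
  int n_internal_nonroot = nnode - ntip - 1;
  wts[M_AGE] = std::max(n_internal_nonroot, 1);
  wts[M_ROOT] = 1.5; wts[M_Z] = lognormal_clock ? nedge * 0.5 : 0.0;
  wts[M_MU] = 2.0; wts[M_S] = lognormal_clock ? 1.0 : 0.0;
  wts[M_EXCH] = 1.5; wts[M_ALPHA] = 1.0; wts[M_PINV] = 1.0; wts[M_THETA] = 1.0;
  wts[M_AGESCALE] = 2.0; wts[M_RIDGE] = lognormal_clock ? 2.0 : 0.0;
  wts[M_UPDOWN] = 2.0;
  // the age-rate and ridge translations skip the likelihood entirely, so
  // they are cheap; weighting them up buys mixing almost for free
  wts[M_AGERATE] = lognormal_clock ? 3.0 * std::max(n_internal_nonroot, 1) : 0.0;
  if (lognormal_clock) wts[M_RIDGE] = 4.0;
  double wsum = 0.0; for (double w : wts) wsum += w;
  std::vector<double> acc(N_MOVES, 0.0), tries(N_MOVES, 0.0);
  std::vector<double> win_acc(N_MOVES, 0.0), win_try(N_MOVES, 0.0);

  std::vector<int> internal_nonroot;
  for (int n = ntip; n < nnode; ++n) if (n != root - 1) internal_nonroot.push_back(n);
  std::vector<double> saved_ages, saved_z;

  int n_samples = (chain - burnin) / thin;
  int ncol = (nnode - ntip) + 5 + 6 + 2; // ages, mu,S,alpha,pinv,theta, exch(6), ll,lp
  arma::mat samples(std::max(n_samples, 0), ncol);
  int srow = 0;

  for (int iter = 1; iter <= chain; ++iter) {
    // pick move
    double u = unif(rng) * wsum, cum = 0.0;
    int mv = 0;
    for (; mv < N_MOVES; ++mv) { cum += wts[mv]; if (u <= cum) break; }
    if (mv >= N_MOVES) mv = N_MOVES - 1;
    win_try[mv] += 1; tries[mv] += 1;

    bool need_ll = true, need_eig = false, need_rates = false;
    double old_val = 0.0; int idx = -1;
    double log_hastings = 0.0;
    bool reject = false;

    switch (mv) {
      case M_AGE: {
        idx = internal_nonroot[(int)(unif(rng) * internal_nonroot.size())];
        double lo = 0.0;
        for (int ch : tr.children[idx]) lo = std::max(lo, age[ch]);
        double hi = age[tr.parent[idx]];
        old_val = age[idx];
        if (unif(rng) < 0.5) {
          age[idx] = lo + unif(rng) * (hi - lo); // bounds fixed => symmetric
        } else {
          // reflected normal walk within the bracket (symmetric)
          double w = hi - lo;
          if (w <= 0) { reject = true; break; }
          double x = age[idx] + norm(rng) * scale[M_AGE] * w;
          for (int it = 0; it < 100 && (x < lo || x > hi); ++it) {
            if (x < lo) x = 2 * lo - x;
            if (x > hi) x = 2 * hi - x;
          }
          if (x < lo || x > hi) { reject = true; break; }
          age[idx] = x;
        }
        break;
      }
      case M_ROOT: {
        idx = root - 1;
        double lo = 0.0;
        for (int ch : tr.children[idx]) lo = std::max(lo, age[ch]);
        old_val = age[idx];
        age[idx] += norm(rng) * scale[M_ROOT];
        if (age[idx] <= lo) reject = true;
        break;
      }
      case M_Z: {
        idx = (int)(unif(rng) * nedge);
        old_val = z[idx];
        z[idx] += norm(rng) * scale[M_Z];
        break;
      }
      case M_MU: {
        old_val = log_mu;
        log_mu += norm(rng) * scale[M_MU];
        if (log_mu < std::log(1e-8) || log_mu > std::log(10.0)) reject = true;
        break;
      }
      case M_S: {
        old_val = S_clock;
        double lo = std::log(std::max(S_clock, 1e-6));
        double nw = lo + norm(rng) * scale[M_S];
        log_hastings = nw - lo; // log-scale walk
        S_clock = std::exp(nw);
        if (S_clock > 5.0) reject = true;
        break;
      }
      case M_EXCH: {
        idx = (int)(unif(rng) * 5); // keep GT fixed at 1
        old_val = exch(idx);
        double lo = std::log(exch(idx));
        double nw = lo + norm(rng) * scale[M_EXCH];
        log_hastings = nw - lo;
        exch(idx) = std::exp(nw);
        if (exch(idx) < 1e-4 || exch(idx) > 1e4) reject = true;
        need_eig = true;
        break;
      }
      case M_ALPHA: {
        old_val = alpha;
        double lo = std::log(alpha);
        double nw = lo + norm(rng) * scale[M_ALPHA];
        log_hastings = nw - lo;
        alpha = std::exp(nw);
        if (alpha < 0.02 || alpha > 100.0) reject = true;
        need_rates = true;
        break;
      }
      case M_PINV: {
        old_val = pinv;
        pinv += norm(rng) * scale[M_PINV];
        if (pinv < 0.0) pinv = -pinv;           // reflect at 0
        if (pinv > 0.9) pinv = 1.8 - pinv;      // reflect at 0.9
        if (pinv < 0.0 || pinv > 0.9) reject = true;
        sub.pinv = pinv;
        break;
      }
      case M_THETA: {
        old_val = log_theta;
        log_theta += norm(rng) * scale[M_THETA];
        if (log_theta < log_theta_min || log_theta > log_theta_max) reject = true;
        need_ll = false;
        break;
      }
      case M_AGESCALE: {
        // scale every internal non-root age by f; order within the scaled
        // block is preserved, only the root bound can be violated
        double f = std::exp(norm(rng) * scale[M_AGESCALE]);
        saved_ages.assign(age.begin(), age.end());
        for (int n : internal_nonroot) age[n] *= f;
        for (int e = 0; e < nedge; ++e)
          if (age[edges(e, 0) - 1] <= age[edges(e, 1) - 1]) reject = true;
        log_hastings = internal_nonroot.size() * std::log(f);
        break;
      }
      case M_RIDGE: {
        // shift log mu and compensate branch-rate deviates so branch
        // substitution lengths (hence the likelihood) are unchanged
        double d = norm(rng) * scale[M_RIDGE];
        if (S_clock < 1e-8) { reject = true; break; }
        saved_z.assign(z.begin(), z.end());
        old_val = log_mu;
        log_mu += d;
        for (int e = 0; e < nedge; ++e) z[e] -= d / S_clock;
        if (log_mu < std::log(1e-8) || log_mu > std::log(10.0)) reject = true;
        need_ll = false;
        break;
      }
      case M_AGERATE: {
        // slide one internal node's age while rescaling the rate deviates
        // of its three adjacent branches so branch substitution lengths
        // (hence the likelihood) are unchanged; volume-preserving in
        // (age, z) since z shifts are deterministic given the new age
        if (S_clock < 1e-8) { reject = true; break; }
        idx = internal_nonroot[(int)(unif(rng) * internal_nonroot.size())];
        double lo = 0.0;
        for (int ch : tr.children[idx]) lo = std::max(lo, age[ch]);
        double hi = age[tr.parent[idx]];
        if (hi - lo <= 1e-12) { reject = true; break; }
        saved_z.assign(z.begin(), z.end());
        old_val = age[idx];
        double t_new = lo + unif(rng) * (hi - lo);
        std::vector<int> adj;
        adj.push_back(tr.edge_of_child[idx]);
        for (int ch : tr.children[idx]) adj.push_back(tr.edge_of_child[ch]);
        bool bad = false;
        for (int e : adj) {
          int pa = edges(e, 0) - 1, ch = edges(e, 1) - 1;
          double dur_old = age[pa] - age[ch];
          double pa_age = (pa == idx) ? t_new : age[pa];
          double ch_age = (ch == idx) ? t_new : age[ch];
          double dur_new = pa_age - ch_age;
          if (dur_old <= 1e-12 || dur_new <= 1e-12) { bad = true; break; }
          z[e] += (std::log(dur_old) - std::log(dur_new)) / S_clock;
        }
        if (bad) { z.assign(saved_z.begin(), saved_z.end()); reject = true; break; }
        age[idx] = t_new;
        need_ll = false;
        break;
      }
      case M_UPDOWN: {
        // scale internal non-root ages up while scaling the clock rate
        // down: moves along the age/rate ridge with the root held fixed
        double d = norm(rng) * scale[M_UPDOWN];
        double f = std::exp(d);
        saved_ages.assign(age.begin(), age.end());
        old_val = log_mu;
        for (int n : internal_nonroot) age[n] *= f;
        log_mu -= d;
        for (int e = 0; e < nedge; ++e)
          if (age[edges(e, 0) - 1] <= age[edges(e, 1) - 1]) reject = true;
        if (log_mu < std::log(1e-8) || log_mu > std::log(10.0)) reject = true;
        log_hastings = internal_nonroot.size() * d;
        break;
      }
    }

    bool accepted = false;
    if (!reject) {
      Subst sub_old = sub;
      if (need_eig) gtr_eigen(exch, base_freq, sub);
      if (need_rates) gamma_rates(alpha, ncat, sub.class_rate);
      double new_ll = cur_ll;
      if (need_ll) { branch_lengths(bl); new_ll = lik.eval(bl, sub); }
      double new_lp = log_prior();
      double ratio = (new_ll - cur_ll) + (new_lp - cur_lp) + log_hastings;
      if (std::log(unif(rng)) < ratio) {
        cur_ll = new_ll; cur_lp = new_lp; accepted = true;
      } else {
        sub = sub_old;
      }
    }
    if (!accepted) { // restore
      switch (mv) {
        case M_AGE: case M_ROOT: age[idx] = old_val; break;
        case M_Z: z[idx] = old_val; break;
        case M_MU: log_mu = old_val; break;
        case M_S: S_clock = old_val; break;
        case M_EXCH: exch(idx) = old_val; break;
        case M_ALPHA: alpha = old_val; break;
        case M_PINV: pinv = old_val; sub.pinv = old_val; break;
        case M_THETA: log_theta = old_val; break;
        case M_AGESCALE: age.assign(saved_ages.begin(), saved_ages.end()); break;
        case M_RIDGE:
          log_mu = old_val;
          z.assign(saved_z.begin(), saved_z.end());
          break;
        case M_UPDOWN:
          log_mu = old_val;
          age.assign(saved_ages.begin(), saved_ages.end());
          break;
        case M_AGERATE:
          age[idx] = old_val;
          z.assign(saved_z.begin(), saved_z.end());
          break;
      }
    } else { win_acc[mv] += 1; acc[mv] += 1; }

    // adapt during burn-in only
    if (iter <= burnin && iter % 50 == 0) {
      for (int m = 0; m < N_MOVES; ++m) {
        if (win_try[m] >= 10) {
          double r = win_acc[m] / win_try[m];
          scale[m] *= std::exp(0.3 * (r - 0.3));
          scale[m] = std::min(std::max(scale[m], 1e-7), 50.0);
          win_acc[m] = 0; win_try[m] = 0;
        }
      }
    }

    if (iter > burnin && (iter - burnin) % thin == 0 && srow < n_samples) {
      int cix = 0;
      for (int n = ntip; n < nnode; ++n) samples(srow, cix++) = age[n];
      samples(srow, cix++) = std::exp(log_mu);
      samples(srow, cix++) = S_clock;
      samples(srow, cix++) = alpha;
      samples(srow, cix++) = pinv;
      samples(srow, cix++) = std::exp(log_theta);
      for (int i = 0; i < 6; ++i) samples(srow, cix++) = exch(i);
      samples(srow, cix++) = cur_ll;
      samples(srow, cix++) = cur_lp;
      ++srow;
    }
  }

  arma::vec acc_rate(N_MOVES);
  for (int m = 0; m < N_MOVES; ++m)
    acc_rate(m) = tries[m] > 0 ? acc[m] / tries[m] : NA_REAL;

  return List::create(_["samples"] = samples,
                      _["acceptance"] = acc_rate,
                      _["scales"] = NumericVector(scale.begin(), scale.end()));
}
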