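// No-U-Turn sampling of the reduced-parameter posterior through the GP
// emulator stack.  This mirrors the R reference implementation
// (nuts_chain) but fuses the likelihood, gradient and tree construction
// into compiled code: the per-case MCMC batteries evaluate millions of
// emulator gradients, which dominates the cost of the inverse study.
//
// Sampling parameterization: t in R^5 with
//   log theta_j = ql + (qu - ql) * sigmoid(t_j)   (j = 1..4)
//   log sigma_tilde^2 = vl + (vu - vl) * sigmoid(t_5),
// a smooth bijection onto the uniform prior box (Jacobian included), so
// NUTS sees no hard support boundaries.  R's RNG is used throughout, so
// set.seed() in R makes chains reproducible.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Posterior {
  // emulator stack
  const double *X, *alpha, *invlam2;
  int n, D, m;
  std::vector<double> sigf2, ymean, ysd, center, scale;
  // observation + noise model
  std::vector<double> ystrain;
  double y0, sigma0_sq, edp;
  // prior box in (log theta, log sigma^2) space
  double ql, qu, vl, vu;

  // log posterior and gradient in t-space; returns value
  double eval(const double* t, double* grad, bool do_grad) const {
    double s[5], q[5], w[5], lo[5];
    for (int j = 0; j < 4; ++j) { w[j] = qu - ql; lo[j] = ql; }
    w[4] = vu - vl; lo[4] = vl;
    double jac = 0.0;
    for (int j = 0; j < 5; ++j) {
      s[j] = 1.0 / (1.0 + std::exp(-t[j]));
      q[j] = lo[j] + w[j] * s[j];
      jac += std::log(s[j]) + std::log1p(-s[j]);
    }
    // emulator inputs u = (log theta, edp), standardized
    double u[5] = {q[0], q[1], q[2], q[3], edp};
    double z[5];
    for (int k = 0; k < D; ++k) z[k] = (u[k] - center[k]) / scale[k];

    std::vector<double> A(n * D);
    for (int k = 0; k < D; ++k) {
      const double* Xk = X + (size_t)k * n;
      double* Ak = &A[(size_t)k * n];
      for (int i = 0; i < n; ++i) Ak[i] = Xk[i] - z[k];
    }
    std::vector<double> mean(m), G;
    if (do_grad) G.assign((size_t)D * m, 0.0);
    std::vector<double> wv(n);
    for (int j = 0; j < m; ++j) {
      const double* aj = alpha + (size_t)j * n;
      const double* lj = invlam2 + (size_t)j * D;
      double mw = 0.0;
      for (int i = 0; i < n; ++i) {
        double qd = 0.0;
        for (int k = 0; k < D; ++k) {
          const double d = A[(size_t)k * n + i];
          qd += d * d * lj[k];
        }
        const double wij = std::exp(-0.5 * qd) * aj[i];
        wv[i] = wij;
        mw += wij;
      }
      mean[j] = ymean[j] + ysd[j] * sigf2[j] * mw;
      if (do_grad) {
        for (int k = 0; k < D; ++k) {
          const double* Ak = &A[(size_t)k * n];
          double g = 0.0;
          for (int i = 0; i < n; ++i) g += Ak[i] * wv[i];
          G[(size_t)k * m + j] = ysd[j] * sigf2[j] * lj[k] * g / scale[k];
        }
      }
    }
    const double s2 = std::exp(q[4]);
    const double r0 = y0 - mean[0];
    double ssq = 0.0;
    for (int j = 1; j < m; ++j) {
      const double r = ystrain[j - 1] - mean[j];
      ssq += r * r;
    }
    double ll = -0.5 * std::log(sigma0_sq) - r0 * r0 / (2.0 * sigma0_sq) -
                12.0 * q[4] - ssq / (2.0 * s2);
    // uniform priors via Jacobian: + sum(log theta) + v/2 + logistic jac
    double lp = ll + q[0] + q[1] + q[2] + q[3] + 0.5 * q[4] + jac;
    if (do_grad) {
      double dll_dq[5];
      for (int k = 0; k < 4; ++k) {
        double acc = G[(size_t)k * m + 0] * (r0 / sigma0_sq);
        for (int j = 1; j < m; ++j) {
          const double r = ystrain[j - 1] - mean[j];
          acc += G[(size_t)k * m + j] * (r / s2);
        }
        dll_dq[k] = acc;
      }
      dll_dq[4] = -12.0 + ssq / (2.0 * s2);
      const double dprior_dq[5] = {1.0, 1.0, 1.0, 1.0, 0.5};
      for (int j = 0; j < 5; ++j) {
        const double dq_dt = w[j] * s[j] * (1.0 - s[j]);
        grad[j] = (dll_dq[j] + dprior_dq[j]) * dq_dt + (1.0 - 2.0 * s[j]);
      }
    }
    return lp;
  }
};

// dense metric: M^-1 = Sigma with upper Cholesky U (Sigma = U'U);
// identity when !dense.
struct Metric {
  bool dense = false;
  double Sigma[25], U[25];
  void vel(const double* p, double* out) const {
    if (!dense) { for (int i = 0; i < 5; ++i) out[i] = p[i]; return; }
    for (int i = 0; i < 5; ++i) {
      double a = 0.0;
      for (int j = 0; j < 5; ++j) a += Sigma[i * 5 + j] * p[j];
      out[i] = a;
    }
  }
  double kin(const double* p) const {
    double v[5]; vel(p, v);
    double k = 0.0;
    for (int i = 0; i < 5; ++i) k += p[i] * v[i];
    return 0.5 * k;
  }
  void draw(double* p) const {
    double z[5];
    for (int i = 0; i < 5; ++i) z[i] = norm_rand();
    if (!dense) { for (int i = 0; i < 5; ++i) p[i] = z[i]; return; }
    // solve U p = z (U upper triangular)
    for (int i = 4; i >= 0; --i) {
      double a = z[i];
      for (int j = i + 1; j < 5; ++j) a -= U[i * 5 + j] * p[j];
      p[i] = a / U[i * 5 + i];
    }
  }
  // returns false if the Cholesky fails
  bool set(const double* S) {
    double Uc[25];
    for (int i = 0; i < 25; ++i) Uc[i] = 0.0;
    for (int j = 0; j < 5; ++j) {       // column j of upper factor
      double d = S[j * 5 + j];
      for (int k = 0; k < j; ++k) d -= Uc[k * 5 + j] * Uc[k * 5 + j];
      if (d <= 0.0) return false;
      Uc[j * 5 + j] = std::sqrt(d);
      for (int i = j + 1; i < 5; ++i) {
        double a = S[j * 5 + i];
        for (int k = 0; k < j; ++k) a -= Uc[k * 5 + j] * Uc[k * 5 + i];
        Uc[j * 5 + i] = a / Uc[j * 5 + j];
      }
    }
    for (int i = 0; i < 25; ++i) { Sigma[i] = S[i]; U[i] = Uc[i]; }
    dense = true;
    return true;
  }
};

struct State { double q[5], p[5], lp; };

struct Tree {
  State minus_, plus_, prop;
  long n; bool stop; double alpha; long n_alpha;
};

struct Sampler {
  const Posterior* post;
  Metric metric;
  double eps;

  bool leapfrog(const State& in, double dir_eps, State& out) const {
    double g[5], v[5];
    double lp0 = post->eval(in.q, g, true);
    (void)lp0;
    for (int i = 0; i < 5; ++i) out.p[i] = in.p[i] + 0.5 * dir_eps * g[i];
    metric.vel(out.p, v);
    for (int i = 0; i < 5; ++i) out.q[i] = in.q[i] + dir_eps * v[i];
    out.lp = post->eval(out.q, g, true);
    if (!std::isfinite(out.lp)) return false;
    bool ok = true;
    for (int i = 0; i < 5; ++i) {
      out.p[i] += 0.5 * dir_eps * g[i];
      if (!std::isfinite(out.p[i]) || !std::isfinite(out.q[i])) ok = false;
    }
    return ok;
  }

  void build_tree(const State& s, double logu, int dir, int depth, double H0,
                  Tree& t) const {
    const double DMAX = 1000.0;
    if (depth == 0) {
      State st;
      bool ok = leapfrog(s, dir * eps, st);
      double H = ok ? st.lp - metric.kin(st.p) : -INFINITY;
      t.minus_ = st; t.plus_ = st; t.prop = st;
      t.n = (std::isfinite(H) && logu <= H) ? 1 : 0;
      t.stop = !std::isfinite(H) || (logu > H + DMAX);
      t.alpha = std::isfinite(H) ? std::min(1.0, std::exp(H - H0)) : 0.0;
      t.n_alpha = 1;
      return;
    }
    build_tree(s, logu, dir, depth - 1, H0, t);
    if (t.stop) return;
    Tree t2;
    if (dir == -1) {
      build_tree(t.minus_, logu, dir, depth - 1, H0, t2);
      t.minus_ = t2.minus_;
    } else {
      build_tree(t.plus_, logu, dir, depth - 1, H0, t2);
      t.plus_ = t2.plus_;
    }
    if (t2.n > 0 && unif_rand() < (double)t2.n / std::max<long>(t.n + t2.n, 1)) {
      t.prop = t2.prop;
    }
    double dq[5], vm[5], vp[5];
    for (int i = 0; i < 5; ++i) dq[i] = t.plus_.q[i] - t.minus_.q[i];
    metric.vel(t.minus_.p, vm); metric.vel(t.plus_.p, vp);
    double sm = 0.0, sp = 0.0;
    for (int i = 0; i < 5; ++i) { sm += dq[i] * vm[i]; sp += dq[i] * vp[i]; }
    t.n += t2.n;
    t.stop = t2.stop || sm < 0.0 || sp < 0.0;
    t.alpha += t2.alpha;
    t.n_alpha += t2.n_alpha;
  }
};

} // namespace

// [[Rcpp::export]]
List nuts_chain_stack_cpp(NumericMatrix X, NumericMatrix alpha,
                          NumericMatrix invlam2, NumericVector sigf2,
                          NumericVector y_mean, NumericVector y_sd,
                          NumericVector center, NumericVector scale,
                          double y0, NumericVector ystrain,
                          double sigma0_sq, double edp,
                          double ql, double qu, double vl, double vu,
                          NumericVector t_init, int n_warmup, int n_draws,
                          double target_accept, int max_treedepth) {
  Posterior post;
  post.X = X.begin(); post.alpha = alpha.begin(); post.invlam2 = invlam2.begin();
  post.n = X.nrow(); post.D = X.ncol(); post.m = alpha.ncol();
  if (post.D != 5) stop("nuts_chain_stack_cpp: expected 5 emulator inputs");
  post.sigf2 = as<std::vector<double> >(sigf2);
  post.ymean = as<std::vector<double> >(y_mean);
  post.ysd = as<std::vector<double> >(y_sd);
  post.center = as<std::vector<double> >(center);
  post.scale = as<std::vector<double> >(scale);
  post.ystrain = as<std::vector<double> >(ystrain);
  post.y0 = y0; post.sigma0_sq = sigma0_sq; post.edp = edp;
  post.ql = ql; post.qu = qu; post.vl = vl; post.vu = vu;

  Sampler smp;
  smp.post = &post;

  double q[5], g[5];
  for (int i = 0; i < 5; ++i) q[i] = t_init[i];
  double lpv = post.eval(q, g, true);
  if (!std::isfinite(lpv)) stop("nuts: initial point has zero posterior density");

  // initial step size: halve until a single leapfrog keeps >50% acceptance
  smp.eps = 0.1;
  for (int t = 0; t < 30; ++t) {
    State s0, s1;
    for (int i = 0; i < 5; ++i) s0.q[i] = q[i];
    smp.metric.draw(s0.p);
    s0.lp = lpv;
    bool ok = smp.leapfrog(s0, smp.eps, s1);
    double dH = ok ? (s1.lp - smp.metric.kin(s1.p)) - (s0.lp - smp.metric.kin(s0.p))
                   : -INFINITY;
    if (!std::isfinite(dH) || dH < std::log(0.5)) smp.eps *= 0.5; else break;
  }

  // dual averaging
  double mu_da = std::log(10.0 * smp.eps), log_eps_bar = 0.0, H_bar = 0.0;
  const double gamma = 0.05, t0da = 10.0, kappa = 0.75;

  // two covariance-adaptation windows
  int w1lo = (int)(n_warmup * 0.25), w1hi = (int)(n_warmup * 0.5);
  int w2lo = w1hi, w2hi = (int)(n_warmup * 0.85);
  std::vector<double> buf; buf.reserve((size_t)(w1hi - w1lo) * 5);
  int win_idx = 1, win_lo = w1lo, win_hi = w1hi;

  NumericMatrix draws(n_draws, 5);
  double accept_sum = 0.0;
  long n_div = 0;
  int total = n_warmup + n_draws;

  for (int it = 1; it <= total; ++it) {
    State cur;
    for (int i = 0; i < 5; ++i) cur.q[i] = q[i];
    smp.metric.draw(cur.p);
    cur.lp = post.eval(cur.q, g, true);
    double H0 = cur.lp - smp.metric.kin(cur.p);
    double logu = H0 + std::log(unif_rand());

    Tree tree;
    tree.minus_ = cur; tree.plus_ = cur; tree.prop = cur;
    tree.n = 1; tree.stop = false;
    double alpha_acc = 0.0; long n_alpha = 1;
    int depth = 0;
    while (!tree.stop && depth < max_treedepth) {
      int dir = (unif_rand() < 0.5) ? -1 : 1;
      Tree sub;
      if (dir == -1) {
        smp.build_tree(tree.minus_, logu, dir, depth, H0, sub);
        tree.minus_ = sub.minus_;
      } else {
        smp.build_tree(tree.plus_, logu, dir, depth, H0, sub);
        tree.plus_ = sub.plus_;
      }
      if (!sub.stop && sub.n > 0 &&
          unif_rand() < (double)sub.n / std::max<long>(tree.n, 1)) {
        tree.prop = sub.prop;
      }
      tree.n += sub.n;
      double dq[5], vm[5], vp[5];
      for (int i = 0; i < 5; ++i) dq[i] = tree.plus_.q[i] - tree.minus_.q[i];
      smp.metric.vel(tree.minus_.p, vm); smp.metric.vel(tree.plus_.p, vp);
      double sm = 0.0, sp = 0.0;
      for (int i = 0; i < 5; ++i) { sm += dq[i] * vm[i]; sp += dq[i] * vp[i]; }
      bool uturn = sm < 0.0 || sp < 0.0;
      if (sub.stop && depth == 0) ++n_div;
      tree.stop = tree.stop || sub.stop || uturn;
      alpha_acc += sub.alpha; n_alpha += sub.n_alpha;
      ++depth;
    }
    for (int i = 0; i < 5; ++i) q[i] = tree.prop.q[i];
    lpv = tree.prop.lp;
    double a_frac = n_alpha > 0 ? alpha_acc / n_alpha : 0.0;

    if (it <= n_warmup) {
      H_bar = (1.0 - 1.0 / (it + t0da)) * H_bar + (target_accept - a_frac) / (it + t0da);
      double log_eps = mu_da - std::sqrt((double)it) / gamma * H_bar;
      double w = std::pow((double)it, -kappa);
      log_eps_bar = w * log_eps + (1.0 - w) * log_eps_bar;
      smp.eps = std::exp(log_eps);
      if (it > win_lo && it <= win_hi) {
        for (int i = 0; i < 5; ++i) buf.push_back(q[i]);
      }
      if (it == win_hi && !buf.empty()) {
        int nb = (int)(buf.size() / 5);
        double meanb[5] = {0, 0, 0, 0, 0};
        for (int r = 0; r < nb; ++r)
          for (int i = 0; i < 5; ++i) meanb[i] += buf[(size_t)r * 5 + i];
        for (int i = 0; i < 5; ++i) meanb[i] /= nb;
        double S[25];
        for (int i = 0; i < 25; ++i) S[i] = 0.0;
        for (int r = 0; r < nb; ++r)
          for (int i = 0; i < 5; ++i)
            for (int j = 0; j < 5; ++j)
              S[i * 5 + j] += (buf[(size_t)r * 5 + i] - meanb[i]) *
                              (buf[(size_t)r * 5 + j] - meanb[j]);
        double lam = nb > 1 ? (double)nb / (nb + 5.0) : 0.0;
        for (int i = 0; i < 5; ++i)
          for (int j = 0; j < 5; ++j) {
            double c = nb > 1 ? S[i * 5 + j] / (nb - 1) : 0.0;
            S[i * 5 + j] = lam * c + ((i == j) ? (1.0 - lam) * 1e-3 + 1e-8 : 0.0);
          }
        smp.metric.set(S);
        smp.eps = std::exp(log_eps_bar);
        mu_da = std::log(10.0 * smp.eps); H_bar = 0.0; log_eps_bar = std::log(smp.eps);
        buf.clear();
        if (win_idx == 1) { win_idx = 2; win_lo = w2lo; win_hi = w2hi; }
      }
      if (it == n_warmup) smp.eps = std::exp(log_eps_bar);
    } else {
      for (int i = 0; i < 5; ++i) draws(it - n_warmup - 1, i) = q[i];
      accept_sum += a_frac;
    }
  }
  return List::create(_["draws"] = draws,
                      _["eps"] = smp.eps,
                      _["accept"] = accept_sum / std::max(n_draws, 1),
                      _["n_divergent"] = (double)n_div);
}
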