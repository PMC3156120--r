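// Spherical minimax / least-squares center finding and random-walk nulls.
//
// The two optimization problems solved here are
//   cap:  minimize over unit c   max_i  acos(c . d_i)   (smallest enclosing cap)
//   sd:   minimize over unit c   mean_i acos(c . d_i)^2 (spherical standard deviation)
// with the d_i unit rows of D. Both are attacked by projected Barzilai-Borwein
// gradient descent on the sphere from multiple starting centers; the non-smooth
// minimax objective is smoothed by log-sum-exp with a continuation schedule and
// finished by an exact equal-angle solve on the active set.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double DOT_CLAMP = 1.0 - 1e-14;

// objective + (optionally) Euclidean gradient at unit vector c
static double eval_obj(const arma::mat &D, const arma::vec &c, bool minimax,
                       double mu, arma::vec *grad) {
  const arma::uword n = D.n_rows;
  arma::vec t = arma::clamp(D * c, -DOT_CLAMP, DOT_CLAMP);
  arma::vec th = arma::acos(t);
  if (minimax) {
    double m = th.max();
    arma::vec w = arma::exp((th - m) / mu);
    double sw = arma::accu(w);
    if (grad) {
      arma::vec coef = (w / sw) / arma::sqrt(1.0 - t % t);
      *grad = -(D.t() * coef);
    }
    return m + mu * std::log(sw);
  }
  double f = arma::dot(th, th) / n;
  if (grad) {
    arma::vec coef(n);
    for (arma::uword i = 0; i < n; ++i) {
      double s2 = 1.0 - t[i] * t[i];
      // th/sin(th) -> 1 as th -> 0; keep it finite near the poles
      coef[i] = (th[i] < 1e-8) ? 1.0 : th[i] / std::sqrt(std::max(s2, 1e-30));
    }
    *grad = -(2.0 / n) * (D.t() * coef);
  }
  return f;
}

// reported angles clamp dots to [-1, 1] exactly so coincident directions
// yield radius 0; the looser DOT_CLAMP above is only for gradient safety
static double max_angle(const arma::mat &D, const arma::vec &c) {
  arma::vec t = arma::clamp(D * c, -1.0, 1.0);
  return arma::acos(t).max();
}

static double rms_angle(const arma::mat &D, const arma::vec &c) {
  arma::vec t = arma::clamp(D * c, -1.0, 1.0);
  arma::vec th = arma::acos(t);
  return std::sqrt(arma::dot(th, th) / D.n_rows);
}

// projected BB gradient descent on the unit sphere
static arma::vec descend(const arma::mat &D, arma::vec c, bool minimax,
                         double mu, int maxit, double gtol) {
  c = arma::normalise(c);
  arma::vec g, gt, c_prev, gt_prev;
  double f = eval_obj(D, c, minimax, mu, &g);
  gt = g - arma::dot(g, c) * c;
  double step = 0.1;
  for (int it = 0; it < maxit; ++it) {
    double gn = arma::norm(gt);
    if (gn < gtol) break;
    if (it > 0) {
      arma::vec s = c - c_prev;
      arma::vec y = gt - gt_prev;
      double sy = arma::dot(s, y);
      step = (sy > 1e-16) ? arma::dot(s, s) / sy : 0.1;
      step = std::min(std::max(step, 1e-9), 10.0);
    }
    double a = step, f_new = f;
    arma::vec c_new = c;
    for (int ls = 0; ls < 40; ++ls) {
      c_new = arma::normalise(c - a * gt);
      f_new = eval_obj(D, c_new, minimax, mu, nullptr);
      if (f_new <= f - 1e-4 * a * gn * gn) break;
      a *= 0.5;
    }
    if (f_new >= f && arma::norm(c_new - c) < 1e-16) break;
    c_prev = c;
    gt_prev = gt;
    c = c_new;
    f = eval_obj(D, c, minimax, mu, &g);
    gt = g - arma::dot(g, c) * c;
  }
  return c;
}

// exact equal-angle center of the active support set; accepted only if it
// lowers the max angle over the full set
static void polish_cap(const arma::mat &D, arma::vec &c, double &r) {
  arma::vec t = arma::clamp(D * c, -DOT_CLAMP, DOT_CLAMP);
  arma::vec th = arma::acos(t);
  double m = th.max();
  arma::uvec act = arma::find(th >= m - 1e-4);
  if (act.n_elem == 0) return;
  arma::mat DA = D.rows(act);
  arma::mat G = DA * DA.t();
  arma::vec lam;
  if (!arma::solve(lam, G, arma::ones(act.n_elem),
                   arma::solve_opts::no_approx)) {
    lam = arma::pinv(G) * arma::ones(act.n_elem);
  }
  arma::vec x = DA.t() * lam;
  double nx = arma::norm(x);
  if (nx < 1e-12) return;
  for (int sgn : {1, -1}) {
    arma::vec cc = (double)sgn * x / nx;
    double rr = max_angle(D, cc);
    if (rr < r) {
      r = rr;
      c = cc;
    }
  }
}

static void solve_cap(const arma::mat &D, const arma::mat &starts,
                      arma::vec &best_c, double &best_r) {
  static const double mus[] = {5e-2, 1e-2, 2e-3, 4e-4, 8e-5,
                               1.6e-5, 3.2e-6, 6.4e-7, 1.28e-7};
  best_r = R_PosInf;
  best_c = arma::normalise(D.row(0).t());
  for (arma::uword s = 0; s < starts.n_rows; ++s) {
    arma::vec c = arma::normalise(starts.row(s).t());
    for (double mu : mus) c = descend(D, c, true, mu, 150, mu * 1e-2);
    double r = max_angle(D, c);
    if (r < best_r) {
      best_r = r;
      best_c = c;
    }
  }
  polish_cap(D, best_c, best_r);
}

static void solve_sd(const arma::mat &D, const arma::mat &starts,
                     arma::vec &best_c, double &best_v) {
  best_v = R_PosInf;
  best_c = arma::normalise(D.row(0).t());
  for (arma::uword s = 0; s < starts.n_rows; ++s) {
    arma::vec c = descend(D, arma::normalise(starts.row(s).t()), false, 0.0,
                          500, 1e-13);
    double v = rms_angle(D, c);
    if (v < best_v) {
      best_v = v;
      best_c = c;
    }
  }
}

// ---- start policies -------------------------------------------------------

static arma::vec random_unit(int d) {
  arma::vec z(d);
  for (int j = 0; j < d; ++j) z[j] = norm_rand();
  double n = arma::norm(z);
  if (n < 1e-300) {
    z.zeros();
    z[0] = 1.0;
    return z;
  }
  return z / n;
}

// d == 3: 8 octant points + normalized mean + n_random random unit vectors
// d != 3: normalized mean + every input direction + n_random random vectors
static arma::mat default_starts(const arma::mat &D, int n_random) {
  const int d = D.n_cols;
  std::vector<arma::vec> S;
  arma::vec mn = arma::mean(D, 0).t();
  double nm = arma::norm(mn);
  if (nm > 1e-12) S.push_back(mn / nm);
  if (d == 3) {
    const double q = 1.0 / std::sqrt(3.0);
    for (int a = -1; a <= 1; a += 2)
      for (int b = -1; b <= 1; b += 2)
        for (int cc = -1; cc <= 1; cc += 2)
          S.push_back(arma::vec({a * q, b * q, cc * q}));
  } else {
    for (arma::uword i = 0; i < D.n_rows; ++i)
      S.push_back(D.row(i).t());
  }
  for (int k = 0; k < n_random; ++k) S.push_back(random_unit(d));
  arma::mat out(S.size(), d);
  for (size_t i = 0; i < S.size(); ++i) out.row(i) = S[i].t();
  return out;
}

// ---- one-shot solvers (starts supplied from R) ----------------------------

// [[Rcpp::export]]
List cpp_cap(const arma::mat &D, const arma::mat &starts) {
  arma::vec c;
  double r;
  solve_cap(D, starts, c, r);
  return List::create(_["center"] = NumericVector(c.begin(), c.end()),
                      _["radius_rad"] = r);
}

// [[Rcpp::export]]
List cpp_sd(const arma::mat &D, const arma::mat &starts) {
  arma::vec c;
  double v;
  solve_sd(D, starts, c, v);
  return List::create(_["center"] = NumericVector(c.begin(), c.end()),
                      _["rms_rad"] = v);
}

// ---- random-walk machinery ------------------------------------------------

// directions from the first point of a walk through each subsequent point;
// the walk has n_dirs unit-length displacements with uniform direction
static arma::mat walk_directions(int n_dirs, int d) {
  arma::mat out(n_dirs, d);
  arma::vec pos(d, arma::fill::zeros);
  for (int i = 0; i < n_dirs; ++i) {
    pos += random_unit(d);
    double n = arma::norm(pos);
    arma::vec dir = (n > 1e-12) ? arma::vec(pos / n) : random_unit(d);
    out.row(i) = dir.t();
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_null_radius(int n_dirs, int d, int n_reps,
                              int n_random_starts) {
  NumericVector out(n_reps);
  for (int r = 0; r < n_reps; ++r) {
    if (r % 256 == 0) checkUserInterrupt();
    arma::mat D = walk_directions(n_dirs, d);
    if (n_dirs == 1) {
      out[r] = 0.0;
      continue;
    }
    arma::vec c;
    double rad;
    solve_cap(D, default_starts(D, n_random_starts), c, rad);
    out[r] = rad * 180.0 / M_PI;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_null_discrimination(int n_dirs_a, int n_dirs_b, int d,
                                      int n_reps, int n_random_starts) {
  NumericVector out(n_reps);
  for (int r = 0; r < n_reps; ++r) {
    if (r % 256 == 0) checkUserInterrupt();
    arma::mat A = walk_directions(n_dirs_a, d);
    arma::mat B = walk_directions(n_dirs_b, d);
    arma::vec ca, cb;
    double va, vb;
    solve_sd(A, default_starts(A, n_random_starts), ca, va);
    solve_sd(B, default_starts(B, n_random_starts), cb, vb);
    double mx = std::max(va, vb);
    if (mx < 1e-12) {
      out[r] = R_PosInf;
      continue;
    }
    double dot = std::max(-DOT_CLAMP, std::min(DOT_CLAMP, arma::dot(ca, cb)));
    out[r] = std::acos(dot) / mx;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_null_proximity(int n_dirs, int d, const arma::vec &ref,
                                 int n_reps, int n_random_starts) {
  arma::vec refu = arma::normalise(ref);
  NumericVector out(n_reps);
  for (int r = 0; r < n_reps; ++r) {
    if (r % 256 == 0) checkUserInterrupt();
    arma::mat D = walk_directions(n_dirs, d);
    arma::vec c;
    double v;
    solve_sd(D, default_starts(D, n_random_starts), c, v);
    double dot = std::max(-DOT_CLAMP, std::min(DOT_CLAMP, arma::dot(c, refu)));
    out[r] = std::acos(dot) * 180.0 / M_PI;
  }
  return out;
}
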