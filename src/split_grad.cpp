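// Compiled core of the gradient split learner: the Adam loop minimizing
// ||w||_{1/2} (smoothed) + C * f(w, b), with f the size-weighted fuzzy
// two-group impurity over features (all rows) and targets (labeled rows).
// Mirrors the R reference implementation in R/impurity.R; dense features
// only (the R path handles sparse inputs).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct GroupOut {
  double imp;
  vec g; // d imp / d a_i, length n
};

// imp and gradient of one fuzzy group with weight totals Ax (features,
// all rows) and Ay (targets, labeled rows); xs1/xs2 are the weighted
// column sums of Xs and Xs^2 under this group's weights.
GroupOut group_terms(const mat& Xs, const mat& Ys, const mat& Xs2,
                     const mat& Ys2, const vec& px, const vec& py,
                     bool use_x, bool use_y, const vec& qx, const vec& qy,
                     double Ax, double Ay, const vec& xs1, const vec& xs2,
                     const vec& ys1, const vec& ys2) {
  const uword n = Xs.n_rows;
  const uword L = Ys.n_rows;
  GroupOut out;
  out.imp = 0.0;
  out.g = zeros<vec>(n);
  if (use_x && Ax > 1e-12) {
    vec m1 = xs1 / Ax;
    vec varx = xs2 / Ax - m1 % m1;
    double ix = dot(px, varx);
    out.imp += ix;
    out.g += (qx - 2.0 * (Xs * (px % m1)) + dot(px, m1 % m1) - ix) / Ax;
  }
  if (use_y && Ay > 1e-12) {
    vec m1 = ys1 / Ay;
    vec vary = ys2 / Ay - m1 % m1;
    double iy = dot(py, vary);
    out.imp += iy;
    out.g.head(L) += (qy - 2.0 * (Ys * (py % m1)) + dot(py, m1 % m1) - iy) / Ay;
  }
  return out;
}

} // namespace

// [[Rcpp::export(name = ".cpp_learn_split_grad")]]
Rcpp::List cpp_learn_split_grad(const arma::mat& Xs, const arma::mat& Ys,
                                const arma::vec& p, const arma::vec& w_init,
                                double C, int opt_iters, double lr,
                                double beta1, double beta2, double adam_eps) {
  const uword n = Xs.n_rows;
  const uword D = Xs.n_cols;
  const uword L = Ys.n_rows;
  const double eps_pen = 1e-8;

  const vec px = p.head(D);
  const vec py = p.tail(p.n_elem - D);
  const bool use_x = any(px > 0);
  const bool use_y = any(py > 0);
  const mat Xs2 = square(Xs);
  const mat Ys2 = square(Ys);
  const vec csx = sum(Xs, 0).t();
  const vec csx2 = sum(Xs2, 0).t();
  const vec csy = sum(Ys, 0).t();
  const vec csy2 = sum(Ys2, 0).t();
  const vec qx = use_x ? vec(Xs2 * px) : zeros<vec>(n);
  const vec qy = use_y ? vec(Ys2 * py) : zeros<vec>(L);

  vec w = w_init;
  double b = 0.0;
  vec mw = zeros<vec>(D), vw = zeros<vec>(D);
  double mb = 0.0, vb = 0.0;

  vec best_w = w;
  double best_b = b;
  double best_obj = datum::inf;

  for (int it = 1; it <= opt_iters + 1; ++it) {
    vec z = Xs * w + b;
    vec s = 1.0 / (1.0 + exp(-z));
    double S = accu(s);
    vec sl = s.head(L);
    double Sl = accu(sl);

    vec t1 = use_x ? vec(Xs.t() * s) : zeros<vec>(D);
    vec t2 = use_x ? vec(Xs2.t() * s) : zeros<vec>(D);
    vec u1 = use_y ? vec(Ys.t() * sl) : zeros<vec>(py.n_elem);
    vec u2 = use_y ? vec(Ys2.t() * sl) : zeros<vec>(py.n_elem);

    GroupOut pos = group_terms(Xs, Ys, Xs2, Ys2, px, py, use_x, use_y,
                               qx, qy, S, Sl, t1, t2, u1, u2);
    GroupOut neg = group_terms(Xs, Ys, Xs2, Ys2, px, py, use_x, use_y,
                               qx, qy, n - S, L - Sl, csx - t1, csx2 - t2,
                               csy - u1, csy2 - u2);
    double f = S * pos.imp + (n - S) * neg.imp;
    double obj = accu(sqrt(abs(w) + eps_pen)) + C * f;
    if (!std::isfinite(obj)) {
      Rcpp::stop("non-finite split objective at Adam iteration %d", it);
    }
    if (obj < best_obj) {
      best_obj = obj;
      best_w = w;
      best_b = b;
    }
    if (it > opt_iters) break; // final candidate evaluated, no more steps

    vec dfds = (pos.imp - neg.imp) + S * pos.g - (n - S) * neg.g;
    vec dz = dfds % s % (1.0 - s);
    vec gw = sign(w) / (2.0 * sqrt(abs(w) + eps_pen)) + C * (Xs.t() * dz);
    double gb = C * accu(dz);

    mw = beta1 * mw + (1.0 - beta1) * gw;
    vw = beta2 * vw + (1.0 - beta2) * square(gw);
    mb = beta1 * mb + (1.0 - beta1) * gb;
    vb = beta2 * vb + (1.0 - beta2) * gb * gb;
    double c1 = 1.0 - std::pow(beta1, it);
    double c2 = 1.0 - std::pow(beta2, it);
    w -= lr * (mw / c1) / (sqrt(vw / c2) + adam_eps);
    b -= lr * (mb / c1) / (std::sqrt(vb / c2) + adam_eps);
  }

  return Rcpp::List::create(Rcpp::Named("w") = best_w,
                            Rcpp::Named("b") = best_b,
                            Rcpp::Named("objective") = best_obj);
}
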