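// Block gradient-ascent core for latent space item response models.
//
// The response matrix may be a dummy expansion of ordinal items: `item`
// maps each (dummy) column to its original item, whose single coordinate
// vector w is shared by all of that item's columns. For binary data the
// map is the identity.
//
// Each parameter block is updated by a gradient step whose initial length
// comes from a Barzilai-Borwein estimate of the local inverse curvature,
// safeguarded by backtracking halving (accepting ties), so the objective
// trace is non-decreasing by construction. Probabilities and the
// person-by-item distance matrix are cached between block updates; only
// coordinate updates recompute distances.
//
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static const double P_EPS = 1e-12;
static const int MAX_HALVINGS = 10;

// person-by-item Euclidean distance matrix (item-level, J columns)
static mat dist_matrix(const mat& Z, const mat& W) {
  const vec z2 = sum(square(Z), 1);
  const vec w2 = sum(square(W), 1);
  mat d2 = -2.0 * Z * W.t();
  d2.each_col() += z2;
  d2.each_row() += w2.t();
  d2.elem(find(d2 < 0)).zeros();  // numerical guard
  return sqrt(d2);
}

struct Model {
  const mat& Y;        // N x Jd responses (0/1; value irrelevant where unobserved)
  const mat& M;        // N x Jd observation indicator
  const uvec& item;    // Jd -> 0..J-1
  const umat& Wfix;    // J x D, 1 = coordinate held at zero (echelon anchor)
  bool penalized;      // true: subtract (lambda/2) * sum of squares
  double lambda;
  bool clamped = false;

  // Bernoulli log-likelihood given distances; stores probabilities in P.
  // Split into vectorizable passes: eta and p first, then the masked
  // log-likelihood accumulation written as y*eta - log(1 + exp(eta))
  // with eta bounded so the exponential cannot overflow.
  double loglik(const vec& theta, const vec& beta, const mat& Dm, mat& P) {
    const uword N = Y.n_rows;
    std::vector<double> eta(N);
    double ll = 0.0;
    for (uword j = 0; j < Y.n_cols; ++j) {
      const double* dcol = Dm.colptr(item(j));
      const double* ycol = Y.colptr(j);
      const double* mcol = M.colptr(j);
      const double* th = theta.memptr();
      double* pcol = P.colptr(j);
      const double bj = beta(j);
      double emax = 0.0;
      for (uword p = 0; p < N; ++p) {
        double e = th[p] + bj - dcol[p];
        emax = std::max(emax, std::abs(e));
        eta[p] = std::min(std::max(e, -36.0), 36.0);  // p stays in ~[2e-16, 1-2e-16]
      }
      if (emax > 36.0) clamped = true;
      for (uword p = 0; p < N; ++p) pcol[p] = 1.0 / (1.0 + std::exp(-eta[p]));
      for (uword p = 0; p < N; ++p) {
        // y*log(p) + (1-y)*log(1-p) rewritten as y*eta + log(1-p)
        ll += mcol[p] * (ycol[p] * eta[p] + std::log1p(-pcol[p]));
      }
    }
    return ll;
  }

  double penalty(const vec& theta, const vec& beta, const mat& Z, const mat& W) const {
    if (!penalized) return 0.0;
    return 0.5 * lambda * (dot(theta, theta) + dot(beta, beta) +
                           accu(square(Z)) + accu(square(W)));
  }

  // gradients of the objective from cached probabilities and distances
  void gradients(const vec& theta, const vec& beta, const mat& Z, const mat& W,
                 const mat& Dm, const mat& P,
                 vec& g_theta, vec& g_beta, mat& g_Z, mat& g_W) {
    const uword N = Y.n_rows, Jd = Y.n_cols, J = W.n_rows;
    g_theta.zeros(N);
    g_beta.set_size(Jd);
    mat S(N, J, fill::zeros);  // residuals / distance, aggregated per item
    for (uword j = 0; j < Jd; ++j) {
      const uword i = item(j);
      const double* dcol = Dm.colptr(i);
      const double* ycol = Y.colptr(j);
      const double* mcol = M.colptr(j);
      const double* pcol = P.colptr(j);
      double* scol = S.colptr(i);
      double gb = 0.0;
      for (uword p = 0; p < N; ++p) {
        if (mcol[p] == 0) continue;
        const double r = ycol[p] - pcol[p];
        g_theta(p) += r;
        gb += r;
        if (dcol[p] > 0) scol[p] += r / dcol[p];  // subgradient 0 at d = 0
      }
      g_beta(j) = gb;
    }
    const vec rowS = sum(S, 1);
    const vec colS = sum(S, 0).t();
    g_Z = -(Z.each_col() % rowS) + S * W;
    g_W = S.t() * Z - (W.each_col() % colS);
    if (penalized) {
      g_theta -= lambda * theta;
      g_beta -= lambda * beta;
      g_Z -= lambda * Z;
      g_W -= lambda * W;
    }
    g_W.elem(find(Wfix == 1)).zeros();
  }
};

// Barzilai-Borwein memory and safeguarded step for one parameter block
struct BlockStep {
  double step;
  bool have_prev = false;
  vec x_prev, g_prev;

  explicit BlockStep(double s0) : step(s0) {}

  double initial(const vec& x, const vec& g) {
    double s = step;
    if (have_prev) {
      const vec dx = x - x_prev;
      const vec dg = g - g_prev;
      const double denom = std::abs(dot(dx, dg));
      if (denom > 1e-300) {
        s = dot(dx, dx) / denom;
        s = std::min(std::max(s, 1e-8), 1e3);
      }
    }
    x_prev = x;
    g_prev = g;
    have_prev = true;
    return s;
  }

  void accept(double s) { step = s; }
  void reject() { have_prev = false; step = std::max(step * 0.5, 1e-8); }
};

// scale each (theta_p, row of X) pair onto the ball of radius C
static void project_rows(vec& theta, mat& X, double C) {
  for (uword p = 0; p < X.n_rows; ++p) {
    double n2 = theta(p) * theta(p) + dot(X.row(p), X.row(p));
    if (n2 > C * C) {
      const double s = C / std::sqrt(n2);
      theta(p) *= s;
      X.row(p) *= s;
    }
  }
}

// [[Rcpp::export]]
Rcpp::List lsirm_fit_core(const arma::mat& Y, const arma::mat& M,
                          const arma::uvec& item, const arma::umat& Wfix,
                          std::string method, double lambda,
                          double C_person, double C_item,
                          arma::vec theta, arma::vec beta,
                          arma::mat Z, arma::mat W,
                          int max_iter, double rel_tol, double step_init) {
  Model mod{Y, M, item, Wfix, method == "pjml", lambda};
  const bool cjml = method == "cjml";
  const uword N = Y.n_rows, Jd = Y.n_cols, D = Z.n_cols;

  mat Dm = dist_matrix(Z, W);
  mat P(N, Jd), Ptmp(N, Jd);
  double f = mod.loglik(theta, beta, Dm, P) - mod.penalty(theta, beta, Z, W);
  std::vector<double> trace;
  trace.reserve(max_iter + 1);
  trace.push_back(f);

  vec g_theta, g_beta;
  mat g_Z, g_W;
  BlockStep bs_th(step_init), bs_be(step_init), bs_Z(step_init), bs_W(step_init),
      bs_per(step_init), bs_it(step_init);
  bool converged = false;
  int iter = 0;

  // generic safeguarded ascent step for one block; `propose` builds the
  // trial parameters for step length s, `eval` returns the objective at
  // the trial (updating Ptmp and, for coordinate blocks, a trial Dm);
  // `commit` installs the accepted trial
  bool any_accept = false;
  auto update = [&](BlockStep& bs, const vec& x, const vec& g,
                    std::function<double(double)> eval,
                    std::function<void()> commit) {
    double s = bs.initial(x, g);
    for (int h = 0; h <= MAX_HALVINGS; ++h) {
      const double f_new = eval(s);
      if (f_new >= f) {
        f = f_new;
        bs.accept(s);
        commit();
        any_accept = true;
        return;
      }
      s *= 0.5;
    }
    bs.reject();  // no-op update
  };

  vec th_try(N), be_try(Jd);
  mat Z_try, W_try, Dm_try;

  for (iter = 1; iter <= max_iter; ++iter) {
    const double f_prev = f;
    any_accept = false;
    mod.gradients(theta, beta, Z, W, Dm, P, g_theta, g_beta, g_Z, g_W);
    if (!cjml) {
      // sequential single-block updates: theta, beta, Z, W
      update(bs_th, theta, g_theta,
             [&](double s) {
               th_try = theta + s * g_theta;
               return mod.loglik(th_try, beta, Dm, Ptmp) -
                      mod.penalty(th_try, beta, Z, W);
             },
             [&] { theta = th_try; P = Ptmp; });
      mod.gradients(theta, beta, Z, W, Dm, P, g_theta, g_beta, g_Z, g_W);
      update(bs_be, beta, g_beta,
             [&](double s) {
               be_try = beta + s * g_beta;
               return mod.loglik(theta, be_try, Dm, Ptmp) -
                      mod.penalty(theta, be_try, Z, W);
             },
             [&] { beta = be_try; P = Ptmp; });
      mod.gradients(theta, beta, Z, W, Dm, P, g_theta, g_beta, g_Z, g_W);
      update(bs_Z, vectorise(Z), vectorise(g_Z),
             [&](double s) {
               Z_try = Z + s * g_Z;
               Dm_try = dist_matrix(Z_try, W);
               return mod.loglik(theta, beta, Dm_try, Ptmp) -
                      mod.penalty(theta, beta, Z_try, W);
             },
             [&] { Z = Z_try; Dm = Dm_try; P = Ptmp; });
      mod.gradients(theta, beta, Z, W, Dm, P, g_theta, g_beta, g_Z, g_W);
      update(bs_W, vectorise(W), vectorise(g_W),
             [&](double s) {
               W_try = W + s * g_W;
               Dm_try = dist_matrix(Z, W_try);
               return mod.loglik(theta, beta, Dm_try, Ptmp) -
                      mod.penalty(theta, beta, Z, W_try);
             },
             [&] { W = W_try; Dm = Dm_try; P = Ptmp; });
    } else {
      // alternating person / item block updates with gradient projection
      update(bs_per, join_cols(theta, vectorise(Z)),
             join_cols(g_theta, vectorise(g_Z)),
             [&](double s) {
               th_try = theta + s * g_theta;
               Z_try = Z + s * g_Z;
               project_rows(th_try, Z_try, C_person);
               Dm_try = dist_matrix(Z_try, W);
               return mod.loglik(th_try, beta, Dm_try, Ptmp);
             },
             [&] { theta = th_try; Z = Z_try; Dm = Dm_try; P = Ptmp; });
      mod.gradients(theta, beta, Z, W, Dm, P, g_theta, g_beta, g_Z, g_W);
      update(bs_it, join_cols(beta, vectorise(W)),
             join_cols(g_beta, vectorise(g_W)),
             [&](double s) {
               be_try = beta + s * g_beta;
               W_try = W + s * g_W;
               // project (beta_j, w_item(j)) jointly per dummy item
               for (uword j = 0; j < Jd; ++j) {
                 const uword i = item(j);
                 double n2 = be_try(j) * be_try(j) + dot(W_try.row(i), W_try.row(i));
                 if (n2 > C_item * C_item) {
                   const double sc = C_item / std::sqrt(n2);
                   be_try(j) *= sc;
                   W_try.row(i) *= sc;
                 }
               }
               Dm_try = dist_matrix(Z, W_try);
               return mod.loglik(theta, be_try, Dm_try, Ptmp);
             },
             [&] { beta = be_try; W = W_try; Dm = Dm_try; P = Ptmp; });
    }
    trace.push_back(f);
    // a sweep where every block update was rejected is a step-size search,
    // not convergence (ties count as acceptances)
    if (any_accept &&
        std::abs(f - f_prev) / (std::abs(f_prev) + 1e-10) < rel_tol) {
      converged = true;
      break;
    }
  }
  (void)D;

  return Rcpp::List::create(
      Rcpp::Named("theta") = theta, Rcpp::Named("beta") = beta,
      Rcpp::Named("Z") = Z, Rcpp::Named("W") = W,
      Rcpp::Named("objective") = f,
      Rcpp::Named("trace") = trace,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("n_iter") = std::min(iter, max_iter),
      Rcpp::Named("clamped") = mod.clamped);
}

// [[Rcpp::export]]
double lsirm_loglik_core(const arma::mat& Y, const arma::mat& M,
                         const arma::uvec& item, const arma::vec& theta,
                         const arma::vec& beta, const arma::mat& Z,
                         const arma::mat& W, double gamma) {
  const mat Dm = gamma * dist_matrix(Z, W);
  double ll = 0.0;
  for (uword j = 0; j < Y.n_cols; ++j) {
    const uword i = item(j);
    for (uword p = 0; p < Y.n_rows; ++p) {
      if (M(p, j) == 0) continue;
      double pr = 1.0 / (1.0 + std::exp(-(theta(p) + beta(j) - Dm(p, i))));
      pr = std::min(std::max(pr, P_EPS), 1.0 - P_EPS);
      ll += Y(p, j) > 0.5 ? std::log(pr) : std::log1p(-pr);
    }
  }
  return ll;
}
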