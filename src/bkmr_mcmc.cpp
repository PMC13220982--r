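// Gaussian-process kernel machine regression with spike-and-slab variable
// selection, fit by Metropolis-within-Gibbs against the marginalized
// representation Y ~ N(X beta, sigma2 * (I + lambda * K)).
//
// All randomness goes through R's RNG (unif_rand / norm_rand / rgamma) so a
// set.seed() in R — including L'Ecuyer-CMRG streams — makes runs bit
// reproducible.
//
// Duplicate-row reduction: bootstrap-resampled datasets contain repeated
// exposure rows, so K = P Ku P' with Ku the kernel on the u unique rows and
// P the n x u indicator. Writing C = P'P = diag(counts) and W = C^{1/2},
// every likelihood piece factors exactly through the u x u matrix
//   B = I_u + (lambda/(1+jitter)) * W Ku W:
//   log|A|            = n log(1+jitter) + log|B|,
//   resid' A^-1 resid = (resid'resid - lt * s' Ku W B^-1 W^-1 s)/(1+jitter),
// with A = (1+jitter) I_n + lambda K, lt = lambda/(1+jitter), s = P'resid
// (identities: A = (1+j)(I + lt P Ku P'), Woodbury on P Ku P', and
// (I + lt C Ku)^-1 = W B^-1 W^-1). With no duplicates (u = n, C = I) this
// reduces to the standard dense computation at the same cost.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// K(za, zb) = exp(-sum_m r_m (za_m - zb_m)^2)
// [[Rcpp::export]]
arma::mat rbf_kernel_cpp(const arma::mat& Za, const arma::mat& Zb,
                         const arma::vec& r) {
  const uword na = Za.n_rows, nb = Zb.n_rows, M = r.n_elem;
  mat S(na, nb, fill::zeros);
  for (uword m = 0; m < M; ++m) {
    if (r(m) == 0.0) continue;
    const double rm = r(m);
    for (uword j = 0; j < nb; ++j) {
      const double zbj = Zb(j, m);
      double* sj = S.colptr(j);
      const double* za = Za.colptr(m);
      for (uword i = 0; i < na; ++i) {
        const double d = za[i] - zbj;
        sj[i] += rm * d * d;
      }
    }
  }
  return exp(-S);
}

// log N(y; X beta, sigma2 * (I*(1+jitter) + lambda*K)), dense route
// [[Rcpp::export]]
double marginal_loglik_cpp(const arma::vec& y, const arma::mat& X,
                           const arma::vec& beta, double sigma2,
                           double lambda, const arma::mat& K, double jitter) {
  const uword n = y.n_elem;
  mat A = lambda * K;
  A.diag() += 1.0 + jitter;
  mat L;
  if (!chol(L, A, "lower")) {
    Rcpp::stop("Cholesky factorization of I + lambda*K failed");
  }
  vec v = solve(trimatl(L), y - X * beta);
  double logdet = 2.0 * sum(log(L.diag()));
  return -0.5 * (double)n * std::log(2.0 * M_PI * sigma2)
         - 0.5 * logdet - 0.5 * dot(v, v) / sigma2;
}

static vec rnorm_vec(uword n) {
  vec z(n);
  for (uword i = 0; i < n; ++i) z(i) = norm_rand();
  return z;
}

// squared-difference cube D(:,:,m) = (za_m,i - zb_m,j)^2
static cube sqdiff_cube(const mat& Za, const mat& Zb) {
  const uword na = Za.n_rows, nb = Zb.n_rows, M = Za.n_cols;
  cube D(na, nb, M);
  for (uword m = 0; m < M; ++m) {
    for (uword j = 0; j < nb; ++j) {
      const double zbj = Zb(j, m);
      double* dj = D.slice(m).colptr(j);
      const double* za = Za.colptr(m);
      for (uword i = 0; i < na; ++i) {
        const double d = za[i] - zbj;
        dj[i] = d * d;
      }
    }
  }
  return D;
}

// B = I + lt * W Ku W from Ku
static void make_B(mat& B, const mat& Ku, const vec& W, double lt) {
  B = lt * Ku;
  B.each_col() %= W;
  B.each_row() %= W.t();
  B.diag() += 1.0;
}

// standalone reduced logdet/quad, exported for oracle cross-checks in tests
// [[Rcpp::export]]
Rcpp::List reduced_quad_logdet_cpp(const arma::vec& y, const arma::mat& X,
                                   const arma::vec& beta,
                                   const arma::mat& Zu,
                                   const arma::uvec& grp,  // 0-based, len n
                                   const arma::vec& counts,
                                   const arma::vec& r, double lambda,
                                   double jitter) {
  const uword n = y.n_elem, u = Zu.n_rows, p = X.n_cols;
  vec W = sqrt(counts), Winv = 1.0 / W;
  mat Ku = rbf_kernel_cpp(Zu, Zu, r);
  double lt = lambda / (1.0 + jitter);
  mat B;
  make_B(B, Ku, W, lt);
  mat Lb;
  if (!chol(Lb, B, "lower")) Rcpp::stop("reduced Cholesky failed");
  double logdet = (double)n * std::log1p(jitter)
                + 2.0 * sum(log(Lb.diag()));
  vec resid = y - X * beta;
  vec s(u, fill::zeros);
  for (uword i = 0; i < n; ++i) s(grp(i)) += resid(i);
  double rss = dot(resid, resid);
  vec q1 = solve(trimatl(Lb), W % (Ku * s));
  vec q2 = solve(trimatl(Lb), Winv % s);
  double quad = (rss - lt * dot(q1, q2)) / (1.0 + jitter);
  (void)p;
  return Rcpp::List::create(Rcpp::Named("logdet") = logdet,
                            Rcpp::Named("quad") = quad);
}

// [[Rcpp::export]]
Rcpp::List bkmr_mcmc_cpp(const arma::vec& y, const arma::mat& Z,
                         const arma::mat& X, const arma::mat& Znew,
                         const arma::uvec& grp, const arma::vec& counts,
                         const arma::mat& Zu,
                         int iters, int burnin, int thin, bool varsel,
                         double a_sig, double b_sig,
                         double a_lam, double b_lam, double lam_step,
                         double r_step, double r_slab_max, double r_birth_max,
                         double delta_prior, double jitter,
                         double lambda_init, double r_init,
                         bool h_draw_noise) {
  const uword n = y.n_elem, M = Z.n_cols, p = X.n_cols, G = Znew.n_rows;
  const uword u = Zu.n_rows;
  const int T = (iters - burnin) / thin;
  if (T <= 0) Rcpp::stop("no retained draws: check iters/burnin/thin");
  const double onepj = 1.0 + jitter;
  const double log1pj = std::log1p(jitter);

  cube Du = sqdiff_cube(Zu, Zu);
  cube Dnew;
  if (G > 0) Dnew = sqdiff_cube(Znew, Zu);

  // fixed data summaries
  const vec W = sqrt(counts), Winv = 1.0 / W;
  mat Sx(u, p, fill::zeros);
  vec sy(u, fill::zeros);
  for (uword i = 0; i < n; ++i) {
    sy(grp(i)) += y(i);
    for (uword j = 0; j < p; ++j) Sx(grp(i), j) += X(i, j);
  }
  const mat XtX = X.t() * X;
  const vec Xty = X.t() * y;
  const double yy = dot(y, y);

  // state
  vec r(M, fill::value(r_init));
  ivec delta(M, fill::ones);
  double lambda = lambda_init;
  double sigma2 = var(y);
  if (sigma2 <= 0) sigma2 = 1.0;
  vec beta = solve(XtX, Xty);

  mat Su(u, u, fill::zeros);
  for (uword m = 0; m < M; ++m) Su += r(m) * Du.slice(m);
  mat Ku = exp(-Su);
  double lt = lambda / onepj;
  mat B, Lb;
  make_B(B, Ku, W, lt);
  if (!chol(Lb, B, "lower")) Rcpp::stop("initial Cholesky failed");
  double logdet = (double)n * log1pj + 2.0 * sum(log(Lb.diag()));

  vec s = sy - Sx * beta;
  double rss = yy - 2.0 * dot(beta, Xty) + dot(beta, XtX * beta);
  auto quad_of = [&](const mat& Ku_, const mat& Lb_) {
    vec q1 = solve(trimatl(Lb_), W % (Ku_ * s));
    vec q2 = solve(trimatl(Lb_), Winv % s);
    return (rss - lt * dot(q1, q2)) / onepj;
  };
  double quad = quad_of(Ku, Lb);
  if (!(std::isfinite(quad))) Rcpp::stop("non-finite likelihood at initialization");

  // proposal workspaces
  mat Su2(u, u), Ku2(u, u), B2(u, u), Lb2;
  mat Snew;
  if (G > 0) Snew.set_size(G, u);

  // storage
  mat r_s(T, M), delta_s(T, M), beta_s(T, p), h_s;
  vec lam_s(T), sig_s(T);
  if (G > 0) h_s.set_size(T, G);
  // move-type counters: 0 lambda, 1 within, 2 birth, 3 death
  vec n_prop(4, fill::zeros), n_acc(4, fill::zeros);

  const double log_prior_odds = std::log(delta_prior / (1.0 - delta_prior));

  int t_store = 0;
  for (int iter = 1; iter <= iters; ++iter) {
    // --- one Metropolis move on a randomly chosen component of (r, lambda)
    int j = (int)std::floor(unif_rand() * (double)(M + 1));
    if (j > (int)M) j = (int)M;

    if (j == (int)M) {
      // lambda: log-scale random walk (Ku unchanged)
      n_prop(0) += 1;
      double lam_new = lambda * std::exp(lam_step * norm_rand());
      double lt_new = lam_new / onepj;
      make_B(B2, Ku, W, lt_new);
      if (chol(Lb2, B2, "lower")) {
        double logdet2 = (double)n * log1pj + 2.0 * sum(log(Lb2.diag()));
        vec q1 = solve(trimatl(Lb2), W % (Ku * s));
        vec q2 = solve(trimatl(Lb2), Winv % s);
        double quad2 = (rss - lt_new * dot(q1, q2)) / onepj;
        double logalpha =
          -0.5 * (logdet2 - logdet) - 0.5 * (quad2 - quad) / sigma2
          + a_lam * (std::log(lam_new) - std::log(lambda))
          - b_lam * (lam_new - lambda);
        if (std::log(unif_rand()) < logalpha) {
          lambda = lam_new; lt = lt_new;
          B.swap(B2); Lb.swap(Lb2);
          logdet = logdet2; quad = quad2;
          n_acc(0) += 1;
        }
      }
    } else {
      // r_j: mixed move (birth / death / within-model random walk)
      double r_old = r(j);
      double r_new;
      int mtype;            // 1 within, 2 birth, 3 death
      double log_qratio;    // proposal + prior correction
      if (!varsel) {
        mtype = 1;
        double base = (r_old > 0 ? r_old : 1e-4);
        r_new = base * std::exp(r_step * norm_rand());
        log_qratio = std::log(r_new) - std::log(base);
        if (r_new > r_slab_max) r_new = -1.0;  // outside slab: auto-reject
      } else if (delta(j) == 0) {
        mtype = 2;  // birth, proposed with probability 1 from the spike
        r_new = unif_rand() * r_birth_max;
        // prior odds + slab/proposal density ratio + death-choice probability
        log_qratio = log_prior_odds + std::log(r_birth_max / r_slab_max)
                   + std::log(0.5);
      } else if (unif_rand() < 0.5) {
        mtype = 3;  // death
        r_new = 0.0;
        log_qratio = -log_prior_odds - std::log(r_birth_max / r_slab_max)
                   - std::log(0.5);
      } else {
        mtype = 1;  // within-model log random walk under the uniform slab
        r_new = r_old * std::exp(r_step * norm_rand());
        log_qratio = std::log(r_new) - std::log(r_old);
        if (r_new > r_slab_max) r_new = -1.0;
      }
      n_prop(mtype) += 1;
      if (r_new >= 0.0) {
        Su2 = Su;
        Su2 += (r_new - r_old) * Du.slice(j);
        Ku2 = exp(-Su2);
        make_B(B2, Ku2, W, lt);
        if (chol(Lb2, B2, "lower")) {
          double logdet2 = (double)n * log1pj + 2.0 * sum(log(Lb2.diag()));
          vec q1 = solve(trimatl(Lb2), W % (Ku2 * s));
          vec q2 = solve(trimatl(Lb2), Winv % s);
          double quad2 = (rss - lt * dot(q1, q2)) / onepj;
          double logalpha =
            -0.5 * (logdet2 - logdet) - 0.5 * (quad2 - quad) / sigma2
            + log_qratio;
          if (std::log(unif_rand()) < logalpha) {
            r(j) = r_new;
            delta(j) = (r_new > 0.0) ? 1 : 0;
            Su.swap(Su2); Ku.swap(Ku2); B.swap(B2); Lb.swap(Lb2);
            logdet = logdet2; quad = quad2;
            n_acc(mtype) += 1;
          }
        }
      }
    }

    // --- Gibbs: beta | rest ~ N((X'A^-1 X)^-1 X'A^-1 y, sigma2 (X'A^-1 X)^-1)
    // X'A^-1 X = (X'X - lt U1'U2)/(1+j), U1 = Lb^-1 (W o Ku Sx),
    // U2 = Lb^-1 (Winv o Sx); similarly X'A^-1 y with sy.
    {
      mat KSx = Ku * Sx;
      KSx.each_col() %= W;
      mat U1 = solve(trimatl(Lb), KSx);
      mat Sxw = Sx;
      Sxw.each_col() %= Winv;
      mat U2 = solve(trimatl(Lb), Sxw);
      vec u2y = solve(trimatl(Lb), Winv % sy);
      mat XtAiX = (XtX - lt * U1.t() * U2) / onepj;
      XtAiX = 0.5 * (XtAiX + XtAiX.t());
      vec XtAiy = (Xty - lt * U1.t() * u2y) / onepj;
      mat Lbb = chol(XtAiX, "lower");
      vec betahat = solve(XtAiX, XtAiy);
      beta = betahat + std::sqrt(sigma2) * solve(trimatu(Lbb.t()), rnorm_vec(p));
      s = sy - Sx * beta;
      rss = yy - 2.0 * dot(beta, Xty) + dot(beta, XtX * beta);
      if (rss < 0) rss = 0;
      quad = quad_of(Ku, Lb);
    }

    // --- Gibbs: sigma2 | rest ~ IG(a_sig + n/2, b_sig + quad/2)
    sigma2 = (b_sig + 0.5 * quad) / R::rgamma(a_sig + 0.5 * (double)n, 1.0);

    // --- store
    if (iter > burnin && (iter - burnin) % thin == 0) {
      r_s.row(t_store) = r.t();
      delta_s.row(t_store) = conv_to<rowvec>::from(delta);
      lam_s(t_store) = lambda;
      sig_s(t_store) = sigma2;
      beta_s.row(t_store) = beta.t();
      if (G > 0) {
        // GP conditional at Znew given (Y, params):
        // hmean = lambda Kx e with e = P' A^-1 resid (u-vector)
        Snew.zeros();
        for (uword m = 0; m < M; ++m) {
          if (r(m) != 0.0) Snew += r(m) * Dnew.slice(m);
        }
        mat Kx = exp(-Snew);   // G x u
        vec v = solve(trimatu(Lb.t()), solve(trimatl(Lb), Winv % s));
        vec e = (s - lt * (counts % (Ku * (W % v)))) / onepj;
        vec hmean = lambda * (Kx * e);
        if (h_draw_noise) {
          // Kx P' A^-1 P Kx' = (Kx C Kx' - lt G1'G2)/(1+j)
          mat Kxt = Kx.t();                   // u x G
          mat KxtC = Kxt;
          KxtC.each_col() %= counts;
          mat term0 = Kxt.t() * KxtC;         // Kx C Kx'
          mat KuKxtC = Ku * KxtC;
          KuKxtC.each_col() %= W;
          mat G1 = solve(trimatl(Lb), KuKxtC);
          mat KxtW = Kxt;
          KxtW.each_col() %= W;
          mat G2 = solve(trimatl(Lb), KxtW);
          mat KAiK = (term0 - lt * G1.t() * G2) / onepj;
          mat Kself = rbf_kernel_cpp(Znew, Znew, r);
          mat Hcov = sigma2 * (lambda * Kself - lambda * lambda * KAiK);
          Hcov = 0.5 * (Hcov + Hcov.t());
          Hcov.diag() += 1e-8 * sigma2 * std::max(1.0, lambda);
          mat Lh;
          if (chol(Lh, Hcov, "lower")) hmean += Lh * rnorm_vec(G);
        }
        h_s.row(t_store) = hmean.t();
      }
      ++t_store;
    }
  }

  vec acc_rate(4);
  for (int k = 0; k < 4; ++k) {
    acc_rate(k) = n_prop(k) > 0 ? n_acc(k) / n_prop(k) : NA_REAL;
  }

  return Rcpp::List::create(
    Rcpp::Named("r") = r_s,
    Rcpp::Named("delta") = delta_s,
    Rcpp::Named("lambda") = lam_s,
    Rcpp::Named("sigma2") = sig_s,
    Rcpp::Named("beta") = beta_s,
    Rcpp::Named("h") = h_s,
    Rcpp::Named("accept") = Rcpp::NumericVector::create(
      Rcpp::Named("lambda") = acc_rate(0),
      Rcpp::Named("r_within") = acc_rate(1),
      Rcpp::Named("r_birth") = acc_rate(2),
      Rcpp::Named("r_death") = acc_rate(3)));
}

// Per-draw GP conditional at new points, for post-hoc surface queries;
// same duplicate-row reduction as the sampler.
// [[Rcpp::export]]
arma::mat posterior_h_cpp(const arma::vec& y, const arma::mat& X,
                          const arma::mat& Znew, const arma::uvec& grp,
                          const arma::vec& counts, const arma::mat& Zu,
                          const arma::mat& r_s, const arma::vec& lam_s,
                          const arma::vec& sig_s, const arma::mat& beta_s,
                          double jitter, bool draw_noise) {
  const uword T = r_s.n_rows, G = Znew.n_rows, n = y.n_elem;
  const uword u = Zu.n_rows, M = Zu.n_cols;
  const double onepj = 1.0 + jitter;
  cube Du = sqdiff_cube(Zu, Zu);
  cube Dnew = sqdiff_cube(Znew, Zu);
  const vec W = sqrt(counts), Winv = 1.0 / W;
  mat Sx(u, X.n_cols, fill::zeros);
  vec sy(u, fill::zeros);
  for (uword i = 0; i < n; ++i) {
    sy(grp(i)) += y(i);
    for (uword j = 0; j < X.n_cols; ++j) Sx(grp(i), j) += X(i, j);
  }
  mat out(T, G);
  mat Su(u, u), Snew(G, u), B, Lb;
  for (uword t = 0; t < T; ++t) {
    vec r = r_s.row(t).t();
    double lambda = lam_s(t), sigma2 = sig_s(t);
    double lt = lambda / onepj;
    Su.zeros();
    Snew.zeros();
    for (uword m = 0; m < M; ++m) {
      if (r(m) == 0.0) continue;
      Su += r(m) * Du.slice(m);
      Snew += r(m) * Dnew.slice(m);
    }
    mat Ku = exp(-Su);
    make_B(B, Ku, W, lt);
    if (!chol(Lb, B, "lower")) Rcpp::stop("Cholesky failed in posterior_h");
    vec beta = beta_s.row(t).t();
    vec s = sy - Sx * beta;
    mat Kx = exp(-Snew);
    vec v = solve(trimatu(Lb.t()), solve(trimatl(Lb), Winv % s));
    vec e = (s - lt * (counts % (Ku * (W % v)))) / onepj;
    vec hmean = lambda * (Kx * e);
    if (draw_noise) {
      mat Kxt = Kx.t();
      mat KxtC = Kxt;
      KxtC.each_col() %= counts;
      mat term0 = Kxt.t() * KxtC;
      mat KuKxtC = Ku * KxtC;
      KuKxtC.each_col() %= W;
      mat G1 = solve(trimatl(Lb), KuKxtC);
      mat KxtW = Kxt;
      KxtW.each_col() %= W;
      mat G2 = solve(trimatl(Lb), KxtW);
      mat KAiK = (term0 - lt * G1.t() * G2) / onepj;
      mat Kself = rbf_kernel_cpp(Znew, Znew, r);
      mat Hcov = sigma2 * (lambda * Kself - lambda * lambda * KAiK);
      Hcov = 0.5 * (Hcov + Hcov.t());
      Hcov.diag() += 1e-8 * sigma2 * std::max(1.0, lambda);
      mat Lh;
      if (chol(Lh, Hcov, "lower")) hmean += Lh * rnorm_vec(G);
    }
    out.row(t) = hmean.t();
  }
  return out;
}
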