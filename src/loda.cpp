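// Core numerics: MCMC sampler for the multivariate GLMM and the per-draw
// evaluation of the marginal / conditional / random-effects predictive
// densities. All random numbers come from R's RNG so that set.seed() in R
// controls every draw.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Marker {
  int family; // 0 gaussian, 1 poisson, 2 bernoulli
  arma::vec y;
  arma::mat X;          // n x p fixed design
  arma::mat Z;          // n x k random design
  arma::uvec zidx;      // 0-based positions of this marker's effects in b
  arma::uvec pid;       // 0-based patient index per row
  std::vector<arma::uvec> rows; // row indices per patient
  std::vector<arma::mat> ZtZ;   // per patient k x k
  std::vector<arma::vec> Zty;   // per patient k
  std::vector<arma::mat> ZtX;   // per patient k x p
  arma::mat XtX;                // global p x p
};

struct ModelData {
  int N = 0, q = 0;
  std::vector<Marker> mk;
};

ModelData build_model_data(const List& md) {
  ModelData out;
  out.N = as<int>(md["n"]);
  out.q = as<int>(md["q"]);
  List mks = md["markers"];
  for (int r = 0; r < mks.size(); ++r) {
    List m = mks[r];
    Marker M;
    M.family = as<int>(m["family"]);
    M.y = as<arma::vec>(m["y"]);
    M.X = as<arma::mat>(m["X"]);
    M.Z = as<arma::mat>(m["Z"]);
    M.zidx = as<arma::uvec>(m["zidx"]) - 1;
    M.pid = as<arma::uvec>(m["pid"]) - 1;
    std::vector<std::vector<arma::uword>> tmp(out.N);
    for (arma::uword k = 0; k < M.pid.n_elem; ++k) tmp[M.pid[k]].push_back(k);
    M.rows.resize(out.N);
    M.ZtZ.resize(out.N);
    M.Zty.resize(out.N);
    M.ZtX.resize(out.N);
    for (int i = 0; i < out.N; ++i) {
      M.rows[i] = arma::uvec(tmp[i]);
      if (M.rows[i].n_elem) {
        arma::mat Zi = M.Z.rows(M.rows[i]);
        M.ZtZ[i] = Zi.t() * Zi;
        M.Zty[i] = Zi.t() * M.y.elem(M.rows[i]);
        M.ZtX[i] = Zi.t() * M.X.rows(M.rows[i]);
      } else {
        M.ZtZ[i].zeros(M.Z.n_cols, M.Z.n_cols);
        M.Zty[i].zeros(M.Z.n_cols);
        M.ZtX[i].zeros(M.Z.n_cols, M.X.n_cols);
      }
    }
    M.XtX = M.X.t() * M.X;
    out.mk.push_back(std::move(M));
  }
  return out;
}

double rnorm1() { return R::norm_rand(); }

arma::vec mvn_sample_prec(const arma::vec& mean, const arma::mat& cholP_upper) {
  arma::vec z(mean.n_elem);
  for (arma::uword i = 0; i < z.n_elem; ++i) z[i] = rnorm1();
  return mean + arma::solve(arma::trimatu(cholP_upper), z);
}

// W ~ Wishart(df, S) via Bartlett; cholS_lower is chol(S, lower).
arma::mat rwishart(double df, const arma::mat& cholS_lower) {
  const arma::uword q = cholS_lower.n_rows;
  arma::mat A(q, q, arma::fill::zeros);
  for (arma::uword i = 0; i < q; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - static_cast<double>(i)));
    for (arma::uword j = 0; j < i; ++j) A(i, j) = rnorm1();
  }
  arma::mat LA = cholS_lower * A;
  return LA * LA.t();
}

// log-likelihood contribution of one observation, with all constants
double obs_loglik(int family, double y, double eta, double phi2) {
  switch (family) {
  case 0: {
    double r = y - eta;
    return -0.5 * std::log(2.0 * M_PI * phi2) - 0.5 * r * r / phi2;
  }
  case 1:
    return y * eta - std::exp(eta) - std::lgamma(y + 1.0);
  default:
    return y * eta - std::log1p(std::exp(eta));
  }
}

// y*eta - b(eta) part only (constants cancel in Metropolis ratios)
double obs_loglik_kernel(int family, double y, double eta, double phi2) {
  switch (family) {
  case 0: {
    double r = y - eta;
    return -0.5 * r * r / phi2;
  }
  case 1:
    return y * eta - std::exp(eta);
  default:
    return y * eta - std::log1p(std::exp(eta));
  }
}

double mvn_logpdf_prec(const arma::vec& x, const arma::vec& mean,
                       const arma::mat& Omega, double logdet_Omega) {
  arma::vec d = x - mean;
  double quad = arma::dot(d, Omega * d);
  return -0.5 * x.n_elem * std::log(2.0 * M_PI) + 0.5 * logdet_Omega - 0.5 * quad;
}

double log_sum_exp(const arma::vec& x) {
  double m = x.max();
  if (!std::isfinite(m)) return m;
  return m + std::log(arma::accu(arma::exp(x - m)));
}

// Conditional log-likelihood of patient i at b (all markers, full constants)
double patient_loglik(const ModelData& md, int i, const arma::vec& b,
                      const std::vector<arma::vec>& alpha,
                      const arma::vec& phi2, bool kernel_only = false) {
  double ll = 0.0;
  int gi = 0;
  for (size_t r = 0; r < md.mk.size(); ++r) {
    const Marker& M = md.mk[r];
    double p2 = (M.family == 0) ? phi2[gi] : 1.0;
    if (M.family == 0) ++gi;
    const arma::uvec& rw = M.rows[i];
    if (!rw.n_elem) continue;
    arma::vec eta = M.Z.rows(rw) * b.elem(M.zidx);
    if (M.X.n_cols) eta += M.X.rows(rw) * alpha[r];
    for (arma::uword k = 0; k < rw.n_elem; ++k) {
      ll += kernel_only ? obs_loglik_kernel(M.family, M.y[rw[k]], eta[k], p2)
                        : obs_loglik(M.family, M.y[rw[k]], eta[k], p2);
    }
  }
  return ll;
}

// Newton ascent to the mode of log f(y|b) + log N(b; mu, D); returns mode,
// sets P to the negative Hessian (posterior precision) at the mode.
arma::vec laplace_mode(const ModelData& md, int i, const arma::vec& start,
                       const std::vector<arma::vec>& alpha, const arma::vec& phi2,
                       const arma::vec& mu, const arma::mat& Omega,
                       arma::mat& P, int max_iter = 40) {
  arma::vec b = start;
  auto objective = [&](const arma::vec& bb) {
    arma::vec d = bb - mu;
    return patient_loglik(md, i, bb, alpha, phi2, true) -
           0.5 * arma::dot(d, Omega * d);
  };
  double f = objective(b);
  arma::vec g(md.q);
  for (int it = 0; it < max_iter; ++it) {
    g = -(Omega * (b - mu));
    P = Omega;
    int gi = 0;
    for (size_t r = 0; r < md.mk.size(); ++r) {
      const Marker& M = md.mk[r];
      double p2 = (M.family == 0) ? phi2[gi] : 1.0;
      if (M.family == 0) ++gi;
      const arma::uvec& rw = M.rows[i];
      if (!rw.n_elem) continue;
      arma::mat Zi = M.Z.rows(rw);
      arma::vec eta = Zi * b.elem(M.zidx);
      if (M.X.n_cols) eta += M.X.rows(rw) * alpha[r];
      arma::vec gr(rw.n_elem), w(rw.n_elem);
      for (arma::uword k = 0; k < rw.n_elem; ++k) {
        double y = M.y[rw[k]];
        switch (M.family) {
        case 0: gr[k] = (y - eta[k]) / p2; w[k] = 1.0 / p2; break;
        case 1: { double lam = std::exp(eta[k]); gr[k] = y - lam; w[k] = lam; break; }
        default: { double pr = 1.0 / (1.0 + std::exp(-eta[k]));
                   gr[k] = y - pr; w[k] = pr * (1.0 - pr); }
        }
      }
      g.elem(M.zidx) += Zi.t() * gr;
      P.submat(M.zidx, M.zidx) += Zi.t() * (Zi.each_col() % w);
    }
    arma::vec step = arma::solve(P, g, arma::solve_opts::likely_sympd);
    double lambda = 1.0;
    arma::vec bn;
    double fn = f;
    for (int h = 0; h < 30; ++h) {
      bn = b + lambda * step;
      fn = objective(bn);
      if (std::isfinite(fn) && fn >= f - 1e-12) break;
      lambda *= 0.5;
    }
    double moved = arma::norm(bn - b);
    b = bn; f = fn;
    if (moved < 1e-9 || arma::norm(g) < 1e-9) break;
  }
  // refresh P at the final iterate
  P = Omega;
  int gi = 0;
  for (size_t r = 0; r < md.mk.size(); ++r) {
    const Marker& M = md.mk[r];
    double p2 = (M.family == 0) ? phi2[gi] : 1.0;
    if (M.family == 0) ++gi;
    const arma::uvec& rw = M.rows[i];
    if (!rw.n_elem) continue;
    arma::mat Zi = M.Z.rows(rw);
    arma::vec eta = Zi * b.elem(M.zidx);
    if (M.X.n_cols) eta += M.X.rows(rw) * alpha[r];
    arma::vec w(rw.n_elem);
    for (arma::uword k = 0; k < rw.n_elem; ++k) {
      switch (M.family) {
      case 0: w[k] = 1.0 / p2; break;
      case 1: w[k] = std::exp(eta[k]); break;
      default: { double pr = 1.0 / (1.0 + std::exp(-eta[k]));
                 w[k] = pr * (1.0 - pr); }
      }
    }
    P.submat(M.zidx, M.zidx) += Zi.t() * (Zi.each_col() % w);
  }
  return b;
}

} // namespace

// [[Rcpp::export]]
List cpp_mcmc_mglmm(List md_list, List cfg) {
  ModelData md = build_model_data(md_list);
  const int N = md.N, q = md.q;
  const int n_burn = as<int>(cfg["n_burn"]);
  const int n_thin = as<int>(cfg["n_thin"]);
  const int n_keep = as<int>(cfg["n_keep"]);
  const bool fix_D = as<bool>(cfg["fix_D"]);
  const bool fix_phi = as<bool>(cfg["fix_phi"]);
  const bool store_b = as<bool>(cfg["store_b"]);
  List prior = cfg["prior"];
  const double mu_prec = as<double>(prior["mu_prec"]);
  const double alpha_prec = as<double>(prior["alpha_prec"]);
  const double phi_a = as<double>(prior["phi_a"]);
  const double phi_b = as<double>(prior["phi_b"]);
  const double nu0 = as<double>(prior["nu0"]);
  const arma::mat S0 = as<arma::mat>(prior["S0"]);
  const double target_acc = 0.35;

  List init = cfg["init"];
  arma::vec mu = as<arma::vec>(init["mu"]);
  arma::mat D = as<arma::mat>(init["D"]);
  arma::mat b = as<arma::mat>(init["b"]); // q x N
  List alpha_init = init["alpha"];
  std::vector<arma::vec> alpha;
  for (size_t r = 0; r < md.mk.size(); ++r) alpha.push_back(as<arma::vec>(alpha_init[r]));
  arma::vec phi2 = as<arma::vec>(init["phi2"]); // per gaussian marker

  // index bookkeeping
  arma::uvec gauss_set; // components belonging to gaussian markers
  {
    std::vector<arma::uword> gs;
    for (const Marker& M : md.mk)
      if (M.family == 0)
        for (arma::uword j = 0; j < M.zidx.n_elem; ++j) gs.push_back(M.zidx[j]);
    std::sort(gs.begin(), gs.end());
    gauss_set = arma::uvec(gs);
  }
  std::vector<arma::uword> ng;
  for (int j = 0; j < q; ++j)
    if (!arma::any(gauss_set == (arma::uword)j)) ng.push_back(j);
  arma::uvec nongauss_set(ng);
  // map component -> (marker, column) for non-gaussian components
  std::vector<std::vector<std::pair<int, int>>> comp_use(q);
  for (size_t r = 0; r < md.mk.size(); ++r)
    for (arma::uword c = 0; c < md.mk[r].zidx.n_elem; ++c)
      comp_use[md.mk[r].zidx[c]].push_back({(int)r, (int)c});

  // maintained linear predictors for non-gaussian markers
  std::vector<arma::vec> eta(md.mk.size());
  auto refresh_eta = [&](size_t r) {
    const Marker& M = md.mk[r];
    eta[r].set_size(M.y.n_elem);
    for (arma::uword k = 0; k < M.y.n_elem; ++k) {
      arma::vec bi = b.col(M.pid[k]);
      double e = arma::dot(M.Z.row(k).t(), bi.elem(M.zidx));
      if (M.X.n_cols) e += arma::dot(M.X.row(k).t(), alpha[r]);
      eta[r][k] = e;
    }
  };
  for (size_t r = 0; r < md.mk.size(); ++r)
    if (md.mk[r].family != 0) refresh_eta(r);

  // adaptive scales
  arma::mat ls_b(q, N, arma::fill::value(std::log(0.5)));
  std::vector<double> ls_alpha(md.mk.size(), std::log(0.1));
  arma::vec acc_b_sum(q, arma::fill::zeros);
  arma::vec acc_b_n(q, arma::fill::zeros);
  std::vector<double> acc_a_sum(md.mk.size(), 0.0), acc_a_n(md.mk.size(), 0.0);

  // storage
  arma::mat keep_mu(n_keep, q);
  arma::cube keep_D(q, q, n_keep);
  std::vector<arma::mat> keep_alpha;
  for (size_t r = 0; r < md.mk.size(); ++r)
    keep_alpha.push_back(arma::mat(n_keep, md.mk[r].X.n_cols));
  int n_gauss = 0;
  for (const Marker& M : md.mk) if (M.family == 0) ++n_gauss;
  arma::mat keep_phi(n_keep, n_gauss);
  arma::mat b_mean(q, N, arma::fill::zeros);
  arma::cube keep_b;
  if (store_b) keep_b.set_size(q, N, n_keep);

  const int total_iter = n_burn + n_thin * n_keep;
  int kept = 0;
  const arma::uword nG = gauss_set.n_elem, nN = nongauss_set.n_elem;

  // positions of each gaussian marker's components within gauss_set
  std::vector<arma::uvec> gpos(md.mk.size());
  for (size_t r = 0; r < md.mk.size(); ++r) {
    if (md.mk[r].family != 0) continue;
    arma::uvec pos(md.mk[r].zidx.n_elem);
    for (arma::uword c = 0; c < md.mk[r].zidx.n_elem; ++c)
      pos[c] = arma::as_scalar(arma::find(gauss_set == md.mk[r].zidx[c], 1));
    gpos[r] = pos;
  }

  for (int it = 1; it <= total_iter; ++it) {
    const bool adapting = it <= n_burn;
    const double gam = 1.0 / std::pow((double)it, 0.6);
    arma::mat Omega;
    if (!arma::inv_sympd(Omega, D))
      stop("random-effects covariance became non-positive-definite at iteration %d", it);
    arma::mat OmGG, OmGN;
    arma::vec muG, muN;
    if (nG) {
      OmGG = Omega.submat(gauss_set, gauss_set);
      muG = mu.elem(gauss_set);
      if (nN) {
        OmGN = Omega.submat(gauss_set, nongauss_set);
        muN = mu.elem(nongauss_set);
      }
    }

    // --- per-patient random effects ---
    for (int i = 0; i < N; ++i) {
      if (nG) {
        arma::mat P = OmGG;
        arma::vec rhs = OmGG * muG;
        if (nN) {
          arma::vec bi = b.col(i);
          rhs -= OmGN * (bi.elem(nongauss_set) - muN);
        }
        int gi = 0;
        for (size_t r = 0; r < md.mk.size(); ++r) {
          const Marker& M = md.mk[r];
          if (M.family != 0) continue;
          double p2 = phi2[gi++];
          if (!M.rows[i].n_elem) continue;
          P.submat(gpos[r], gpos[r]) += M.ZtZ[i] / p2;
          arma::vec zr = M.Zty[i];
          if (M.X.n_cols) zr -= M.ZtX[i] * alpha[r];
          rhs.elem(gpos[r]) += zr / p2;
        }
        arma::mat U;
        if (!arma::chol(U, P))
          stop("gaussian-block precision not positive definite at iteration %d", it);
        arma::vec mean = arma::solve(P, rhs, arma::solve_opts::likely_sympd);
        arma::vec bg = mvn_sample_prec(mean, U);
        for (arma::uword c = 0; c < nG; ++c) b(gauss_set[c], i) = bg[c];
      }
      // scalar Metropolis for components of non-gaussian markers
      for (arma::uword jj = 0; jj < nN; ++jj) {
        arma::uword j = nongauss_set[jj];
        double om = Omega(j, j);
        arma::vec dev = b.col(i) - mu;
        double m = mu[j] - (arma::dot(Omega.row(j).t(), dev) -
                            om * (b(j, i) - mu[j])) / om;
        double bj = b(j, i);
        double prop = bj + std::exp(ls_b(j, i)) * rnorm1();
        double dlp = -0.5 * om * ((prop - m) * (prop - m) - (bj - m) * (bj - m));
        for (auto& rc : comp_use[j]) {
          const Marker& M = md.mk[rc.first];
          if (M.family == 0) continue; // gaussian handled conjugately
          const arma::uvec& rw = M.rows[i];
          for (arma::uword k = 0; k < rw.n_elem; ++k) {
            double z = M.Z(rw[k], rc.second);
            double e0 = eta[rc.first][rw[k]];
            double e1 = e0 + z * (prop - bj);
            dlp += obs_loglik_kernel(M.family, M.y[rw[k]], e1, 1.0) -
                   obs_loglik_kernel(M.family, M.y[rw[k]], e0, 1.0);
          }
        }
        double aprob = std::min(1.0, std::exp(dlp));
        if (R::unif_rand() < aprob) {
          for (auto& rc : comp_use[j]) {
            const Marker& M = md.mk[rc.first];
            if (M.family == 0) continue;
            const arma::uvec& rw = M.rows[i];
            for (arma::uword k = 0; k < rw.n_elem; ++k)
              eta[rc.first][rw[k]] += M.Z(rw[k], rc.second) * (prop - bj);
          }
          b(j, i) = prop;
        }
        if (adapting) ls_b(j, i) += gam * (aprob - target_acc);
        else { acc_b_sum[j] += aprob; acc_b_n[j] += 1.0; }
      }
    }

    // --- fixed coefficients ---
    {
      int gi = 0;
      for (size_t r = 0; r < md.mk.size(); ++r) {
        Marker& M = md.mk[r];
        int p = M.X.n_cols;
        double p2 = (M.family == 0) ? phi2[gi] : 1.0;
        if (M.family == 0) ++gi;
        if (!p) continue;
        if (M.family == 0) {
          arma::vec zb(M.y.n_elem);
          for (arma::uword k = 0; k < M.y.n_elem; ++k) {
            arma::vec bi = b.col(M.pid[k]);
            zb[k] = arma::dot(M.Z.row(k).t(), bi.elem(M.zidx));
          }
          arma::mat P = M.XtX / p2 + alpha_prec * arma::eye(p, p);
          arma::vec rhs = M.X.t() * (M.y - zb) / p2;
          arma::mat U; arma::chol(U, P);
          alpha[r] = mvn_sample_prec(arma::solve(P, rhs, arma::solve_opts::likely_sympd), U);
        } else {
          arma::vec a0 = alpha[r];
          arma::vec prop = a0;
          for (int c = 0; c < p; ++c) prop[c] += std::exp(ls_alpha[r]) * rnorm1();
          arma::vec de = M.X * (prop - a0);
          double dlp = -0.5 * alpha_prec * (arma::dot(prop, prop) - arma::dot(a0, a0));
          for (arma::uword k = 0; k < M.y.n_elem; ++k) {
            dlp += obs_loglik_kernel(M.family, M.y[k], eta[r][k] + de[k], 1.0) -
                   obs_loglik_kernel(M.family, M.y[k], eta[r][k], 1.0);
          }
          double aprob = std::min(1.0, std::exp(dlp));
          if (R::unif_rand() < aprob) {
            alpha[r] = prop;
            eta[r] += de;
          }
          if (adapting) ls_alpha[r] += gam * (aprob - target_acc);
          else { acc_a_sum[r] += aprob; acc_a_n[r] += 1.0; }
        }
      }
    }

    // --- residual variances ---
    if (!fix_phi) {
      int gi = 0;
      for (size_t r = 0; r < md.mk.size(); ++r) {
        const Marker& M = md.mk[r];
        if (M.family != 0) continue;
        double ssr = 0.0;
        for (arma::uword k = 0; k < M.y.n_elem; ++k) {
          arma::vec bi = b.col(M.pid[k]);
          double e = arma::dot(M.Z.row(k).t(), bi.elem(M.zidx));
          if (M.X.n_cols) e += arma::dot(M.X.row(k).t(), alpha[r]);
          double rr = M.y[k] - e;
          ssr += rr * rr;
        }
        double shape = phi_a + 0.5 * M.y.n_elem;
        double rate = phi_b + 0.5 * ssr;
        phi2[gi] = 1.0 / R::rgamma(shape, 1.0 / rate);
        ++gi;
      }
    }

    // --- random-effect means ---
    {
      arma::vec bsum = arma::sum(b, 1);
      arma::mat P = (double)N * Omega + mu_prec * arma::eye(q, q);
      arma::vec rhs = Omega * bsum;
      arma::mat U;
      arma::chol(U, P);
      mu = mvn_sample_prec(arma::solve(P, rhs, arma::solve_opts::likely_sympd), U);
    }

    // --- random-effect covariance ---
    if (!fix_D) {
      arma::mat S = S0;
      for (int i = 0; i < N; ++i) {
        arma::vec d = b.col(i) - mu;
        S += d * d.t();
      }
      arma::mat Sinv;
      if (!arma::inv_sympd(Sinv, S))
        stop("inverse-Wishart scale not positive definite at iteration %d", it);
      arma::mat L = arma::chol(Sinv, "lower");
      arma::mat W = rwishart(nu0 + N, L);
      if (!arma::inv_sympd(D, W))
        stop("sampled covariance not positive definite at iteration %d", it);
      D = 0.5 * (D + D.t());
    }

    if (!mu.is_finite() || !D.is_finite())
      stop("divergent chain (nonfinite parameters) at iteration %d", it);

    if (it > n_burn && (it - n_burn) % n_thin == 0) {
      keep_mu.row(kept) = mu.t();
      keep_D.slice(kept) = D;
      for (size_t r = 0; r < md.mk.size(); ++r)
        if (md.mk[r].X.n_cols) keep_alpha[r].row(kept) = alpha[r].t();
      int gi = 0;
      for (const Marker& M : md.mk) {
        if (M.family == 0) {
          keep_phi(kept, gi) = std::sqrt(phi2[gi]);
          ++gi;
        }
      }
      b_mean += b;
      if (store_b) keep_b.slice(kept) = b;
      ++kept;
    }
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
  }
  if (kept) b_mean /= (double)kept;

  List acc_b(nongauss_set.n_elem);
  CharacterVector acc_b_names(nongauss_set.n_elem);
  for (arma::uword jj = 0; jj < nongauss_set.n_elem; ++jj) {
    arma::uword j = nongauss_set[jj];
    acc_b[jj] = acc_b_n[j] > 0 ? acc_b_sum[j] / acc_b_n[j] : NA_REAL;
    acc_b_names[jj] = std::to_string(j + 1);
  }
  acc_b.attr("names") = acc_b_names;
  List acc_a(md.mk.size());
  for (size_t r = 0; r < md.mk.size(); ++r)
    acc_a[r] = acc_a_n[r] > 0 ? acc_a_sum[r] / acc_a_n[r] : NA_REAL;

  List alpha_out(md.mk.size());
  for (size_t r = 0; r < md.mk.size(); ++r) alpha_out[r] = keep_alpha[r];

  List out = List::create(
    _["mu"] = keep_mu, _["D"] = keep_D, _["alpha"] = alpha_out,
    _["phi"] = keep_phi, _["b_mean"] = b_mean,
    _["accept_b"] = acc_b, _["accept_alpha"] = acc_a);
  if (store_b) out["b"] = keep_b;
  return out;
}

// Per-draw predictive densities and averaged group probabilities.
//
// draws_by_group: list of G lists with elements mu (M x q), D (q x q x M),
// alpha (list per marker, M x p), phi (M x n_gaussian, residual SDs).
// Returns a list of n x G probability matrices per requested approach.
// [[Rcpp::export]]
List cpp_group_probabilities(List md_list, List draws_by_group,
                             arma::vec log_prior, bool want_marginal,
                             bool want_conditional, bool want_ranef,
                             int n_mc, double is_inflate) {
  ModelData md = build_model_data(md_list);
  const int N = md.N, q = md.q;
  const int G = draws_by_group.size();
  bool all_gauss = true;
  for (const Marker& M : md.mk) if (M.family != 0) all_gauss = false;

  std::vector<arma::mat> mu_g;
  std::vector<arma::cube> D_g;
  std::vector<std::vector<arma::mat>> alpha_g(G);
  std::vector<arma::mat> phi_g;
  for (int g = 0; g < G; ++g) {
    List dg = draws_by_group[g];
    mu_g.push_back(as<arma::mat>(dg["mu"]));
    D_g.push_back(as<arma::cube>(dg["D"]));
    List al = dg["alpha"];
    for (int r = 0; r < al.size(); ++r) alpha_g[g].push_back(as<arma::mat>(al[r]));
    phi_g.push_back(as<arma::mat>(dg["phi"]));
  }
  const int M = mu_g[0].n_rows;
  for (int g = 1; g < G; ++g)
    if ((int)mu_g[g].n_rows != M)
      stop("groups carry different numbers of posterior draws (%d vs %d)",
           (int)mu_g[g].n_rows, M);

  arma::mat P_marg(N, G, arma::fill::zeros), P_cond(N, G, arma::fill::zeros),
      P_ranef(N, G, arma::fill::zeros);
  // warm starts for the Laplace mode, per patient x group
  std::vector<arma::mat> warm(G, arma::mat(q, N));
  bool warm_ok = false;

  const bool need_mode = want_conditional || want_ranef || !all_gauss;

  for (int m = 0; m < M; ++m) {
    // per-group per-draw parameter views
    std::vector<arma::vec> mu_m(G), phi2_m(G);
    std::vector<arma::mat> Om_m(G);
    std::vector<double> logdetOm(G);
    std::vector<std::vector<arma::vec>> al_m(G);
    for (int g = 0; g < G; ++g) {
      mu_m[g] = mu_g[g].row(m).t();
      arma::mat Dm = D_g[g].slice(m);
      if (!arma::inv_sympd(Om_m[g], Dm))
        stop("posterior draw %d of group %d has a non-PD covariance", m + 1, g);
      double sign;
      arma::log_det(logdetOm[g], sign, Om_m[g]);
      arma::vec ph = phi_g[g].n_cols ? phi_g[g].row(m).t() : arma::vec();
      phi2_m[g] = ph % ph;
      for (size_t r = 0; r < md.mk.size(); ++r) {
        arma::vec a = alpha_g[g][r].n_cols ? alpha_g[g][r].row(m).t() : arma::vec();
        al_m[g].push_back(a);
      }
    }
    for (int i = 0; i < N; ++i) {
      arma::vec lf_marg(G), lf_cond(G), lf_ranef(G);
      arma::mat eps;
      if (want_marginal && !all_gauss) {
        eps.set_size(q, n_mc);
        for (arma::uword k = 0; k < eps.n_elem; ++k) eps[k] = rnorm1();
      }
      for (int g = 0; g < G; ++g) {
        arma::mat P;
        arma::vec bhat;
        if (all_gauss) {
          // conjugate posterior for b: precision and mean in closed form
          P = Om_m[g];
          arma::vec rhs = Om_m[g] * mu_m[g];
          int gi = 0;
          for (size_t r = 0; r < md.mk.size(); ++r) {
            const Marker& Mk = md.mk[r];
            double p2 = phi2_m[g][gi++];
            if (!Mk.rows[i].n_elem) continue;
            P.submat(Mk.zidx, Mk.zidx) += Mk.ZtZ[i] / p2;
            arma::vec zr = Mk.Zty[i];
            if (Mk.X.n_cols) zr -= Mk.ZtX[i] * al_m[g][r];
            rhs.elem(Mk.zidx) += zr / p2;
          }
          bhat = arma::solve(P, rhs, arma::solve_opts::likely_sympd);
        } else {
          arma::vec start = warm_ok ? warm[g].col(i) : mu_m[g];
          bhat = laplace_mode(md, i, start, al_m[g], phi2_m[g], mu_m[g],
                              Om_m[g], P);
          warm[g].col(i) = bhat;
        }
        double ll_cond = patient_loglik(md, i, bhat, al_m[g], phi2_m[g]);
        double lp_prior = mvn_logpdf_prec(bhat, mu_m[g], Om_m[g], logdetOm[g]);
        if (want_conditional) lf_cond[g] = ll_cond;
        if (want_ranef) lf_ranef[g] = lp_prior;
        if (want_marginal) {
          if (all_gauss) {
            double sign, logdetP;
            arma::log_det(logdetP, sign, P);
            lf_marg[g] = ll_cond + lp_prior +
                         0.5 * q * std::log(2.0 * M_PI) - 0.5 * logdetP;
          } else {
            // importance sampling around the Laplace mode, common random
            // numbers (eps) across groups
            arma::mat U;
            if (!arma::chol(U, P)) stop("Laplace precision not positive definite");
            double sign, logdetP;
            arma::log_det(logdetP, sign, P);
            const double s = std::sqrt(is_inflate);
            arma::vec lw(n_mc);
            for (int k = 0; k < n_mc; ++k) {
              arma::vec bk = bhat + s * arma::solve(arma::trimatu(U), eps.col(k));
              // proposal N(bhat, inflate * P^-1); its quadratic form at bk
              // reduces to eps'eps because bk was built from eps
              double lq = -0.5 * q * std::log(2.0 * M_PI * is_inflate) +
                          0.5 * logdetP -
                          0.5 * arma::dot(eps.col(k), eps.col(k));
              double lp = patient_loglik(md, i, bk, al_m[g], phi2_m[g]) +
                          mvn_logpdf_prec(bk, mu_m[g], Om_m[g], logdetOm[g]);
              lw[k] = lp - lq;
            }
            lf_marg[g] = log_sum_exp(lw) - std::log((double)n_mc);
          }
        }
      }
      auto accumulate = [&](arma::mat& acc, const arma::vec& lf) {
        arma::vec lp = lf + log_prior;
        double lse = log_sum_exp(lp);
        for (int g = 0; g < G; ++g) acc(i, g) += std::exp(lp[g] - lse);
      };
      if (want_marginal) accumulate(P_marg, lf_marg);
      if (want_conditional) accumulate(P_cond, lf_cond);
      if (want_ranef) accumulate(P_ranef, lf_ranef);
    }
    warm_ok = !all_gauss && need_mode;
    if (m % 20 == 0) Rcpp::checkUserInterrupt();
  }
  List out;
  if (want_marginal) out["marginal"] = P_marg / (double)M;
  if (want_conditional) out["conditional"] = P_cond / (double)M;
  if (want_ranef) out["random_effects"] = P_ranef / (double)M;
  return out;
}
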