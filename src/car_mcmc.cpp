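// Metropolis-within-Gibbs sampler for the Poisson / proper-CAR disease
// mapping model, with optional data cloning (L independent latent vectors
// attached to L copies of the count vector, sharing the hyperparameters).
//
// Model:  C_i ~ Poisson(theta_i E_i),  log(theta_i) = mu + eta_i,
//         eta ~ N(0, Sigma),  Sigma = sigma2 (I - lambda D)^{-1} P,
//         P = diag(1/E_i), D_ij = sqrt(E_j/E_i) for adjacent pairs.
//
// Key identities used throughout (B_ij = sqrt(E_i E_j) on edges, A the
// 0/1 adjacency):
//   Sigma^{-1}      = (diag(E) - lambda B) / sigma2
//   log det Sigma   = m log sigma2 - sum_i log E_i - sum_k log(1 - lambda a_k)
// where a_k are the eigenvalues of A (P^{-1/2} D P^{1/2} equals A exactly),
// so the admissible lambda interval is (1/min(a), 1/max(a)) and the log
// determinant costs O(m) for any lambda.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Nbr {
  std::vector<std::vector<int> > idx;     // neighbour indices
  std::vector<std::vector<double> > w;    // matching sqrt(E_i E_j)
};

inline double clamp(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// sum over clones of eta' (diag(E) - lambda B) eta, split into the
// E-weighted square part and the edge cross part (lambda-free pieces)
inline void quad_parts(const NumericMatrix& eta, const NumericVector& E,
                       const IntegerVector& ei, const IntegerVector& ej,
                       const NumericVector& bw, double& sq, double& cross) {
  sq = 0.0; cross = 0.0;
  int m = eta.nrow(), L = eta.ncol(), ne = ei.size();
  for (int l = 0; l < L; ++l) {
    for (int i = 0; i < m; ++i) sq += E[i] * eta(i, l) * eta(i, l);
    for (int e = 0; e < ne; ++e)
      cross += bw[e] * eta(ei[e], l) * eta(ej[e], l);
  }
}

inline double logdet_term(double lambda, const NumericVector& evals) {
  double s = 0.0;
  for (int k = 0; k < evals.size(); ++k) {
    double v = 1.0 - lambda * evals[k];
    if (v <= 0.0) return R_NegInf;
    s += std::log(v);
  }
  return s;
}

}  // namespace

// [[Rcpp::export]]
List car_mcmc_cpp(IntegerVector C, NumericVector E,
                  IntegerVector edge_i, IntegerVector edge_j,
                  NumericVector evals,
                  int L,
                  double mu_mean, double mu_var,
                  double sig_shape, double sig_rate,
                  double lam_lo, double lam_hi,
                  int n_iter, int n_burn, int thin,
                  bool update_mu, bool update_sigma, bool update_lambda,
                  bool use_data,
                  double mu0, double sigma20, double lambda0,
                  NumericVector eta0,
                  bool save_eta) {
  const int m = C.size();
  const int ne = edge_i.size();

  NumericVector bw(ne);
  Nbr nbr;
  nbr.idx.resize(m);
  nbr.w.resize(m);
  for (int e = 0; e < ne; ++e) {
    int a = edge_i[e], b = edge_j[e];
    double w = std::sqrt(E[a] * E[b]);
    bw[e] = w;
    nbr.idx[a].push_back(b); nbr.w[a].push_back(w);
    nbr.idx[b].push_back(a); nbr.w[b].push_back(w);
  }

  double mu = mu0;
  double sigma2 = sigma20;
  double lambda = lambda0;
  NumericMatrix eta(m, L);
  if (eta0.size() == m) {
    for (int l = 0; l < L; ++l)
      for (int i = 0; i < m; ++i) eta(i, l) = eta0[i];
  }

  // adaptive random-walk step sizes (log scale adjusted during burn-in)
  std::vector<double> step_eta(m, 0.5);
  double step_mu = 0.1, step_s = 0.5, step_u = 0.5;
  std::vector<int> acc_eta(m, 0), try_eta(m, 0);
  int acc_mu = 0, try_mu = 0, acc_s = 0, try_s = 0, acc_u = 0, try_u = 0;
  int acc_sc = 0, try_sc = 0;
  double step_tr = 0.1;
  int acc_tr = 0, try_tr = 0;
  long long acc_eta_tot = 0, try_eta_tot = 0;
  const double target = 0.44;
  const int adapt_every = 50;

  const int n_keep = (n_iter > n_burn) ? (n_iter - n_burn) / thin : 0;
  NumericVector out_mu(n_keep), out_sigma2(n_keep), out_lambda(n_keep);
  NumericMatrix out_eta(save_eta ? n_keep : 0, save_eta ? m : 0);
  int kept = 0;

  RNGScope scope;

  for (int it = 0; it < n_iter; ++it) {
    // --- latent spatial effects, single-site, all clones ---
    for (int l = 0; l < L; ++l) {
      for (int i = 0; i < m; ++i) {
        double cur = eta(i, l);
        double prop = cur + step_eta[i] * norm_rand();
        double si = 0.0;
        for (size_t t = 0; t < nbr.idx[i].size(); ++t)
          si += nbr.w[i][t] * eta(nbr.idx[i][t], l);
        double d = 0.0;
        if (use_data) {
          d += C[i] * (prop - cur)
             - E[i] * std::exp(mu) * (std::exp(prop) - std::exp(cur));
        }
        d += -(0.5 / sigma2) * E[i] * (prop * prop - cur * cur)
           + (lambda / sigma2) * (prop - cur) * si;
        ++try_eta[i]; ++try_eta_tot;
        if (std::log(unif_rand()) < d) {
          eta(i, l) = prop;
          ++acc_eta[i]; ++acc_eta_tot;
        }
      }
    }

    // --- overall level mu ---
    if (update_mu) {
      double prop = mu + step_mu * norm_rand();
      double d = -0.5 * ((prop - mu_mean) * (prop - mu_mean)
                         - (mu - mu_mean) * (mu - mu_mean)) / mu_var;
      if (use_data) {
        // sum over clones and regions: C_i dmu - E_i e^{eta}(e^{mu'} - e^{mu})
        double Se = 0.0;
        long long Ctot = 0;
        for (int l = 0; l < L; ++l)
          for (int i = 0; i < m; ++i) Se += E[i] * std::exp(eta(i, l));
        for (int i = 0; i < m; ++i) Ctot += C[i];
        d += (double)Ctot * (double)L * (prop - mu)
           - (std::exp(prop) - std::exp(mu)) * Se;
      }
      ++try_mu;
      if (std::log(unif_rand()) < d) { mu = prop; ++acc_mu; }
    }

    // --- joint translation: (mu, eta) -> (mu + d, eta - d) ---
    // leaves every Poisson mean exp(mu + eta_i) untouched, so it slides
    // along the mu / mean(eta) ridge that single moves cross slowly;
    // only the normal prior on mu and the MVN prior on eta change
    if (update_mu) {
      double dshift = step_tr * norm_rand();
      double d = -0.5 * ((mu + dshift - mu_mean) * (mu + dshift - mu_mean)
                         - (mu - mu_mean) * (mu - mu_mean)) / mu_var;
      // quad change per clone: (eta-d)'M(eta-d) - eta'M eta
      //   = -2 d 1'M eta + d^2 1'M 1
      double oneM1 = 0.0;
      for (int i = 0; i < m; ++i) oneM1 += E[i];
      for (int e = 0; e < ne; ++e) oneM1 -= 2.0 * lambda * bw[e];
      for (int l = 0; l < L; ++l) {
        double oneMeta = 0.0;
        for (int i = 0; i < m; ++i) oneMeta += E[i] * eta(i, l);
        for (int e = 0; e < ne; ++e)
          oneMeta -= lambda * bw[e] * (eta(edge_i[e], l) + eta(edge_j[e], l));
        d += -0.5 * (-2.0 * dshift * oneMeta + dshift * dshift * oneM1)
             / sigma2;
      }
      ++try_tr;
      if (std::log(unif_rand()) < d) {
        mu += dshift;
        for (int l = 0; l < L; ++l)
          for (int i = 0; i < m; ++i) eta(i, l) -= dshift;
        ++acc_tr;
      }
    }

    // --- spatial dispersion sigma2: exact conjugate Gibbs draw ---
    // eta | sigma2 is MVN with precision (diag(E) - lambda B)/sigma2, so
    // sigma2 | eta ~ IG(shape + Lm/2, rate + quad/2)
    if (update_sigma) {
      double sq, cross;
      quad_parts(eta, E, edge_i, edge_j, bw, sq, cross);
      double quad = sq - 2.0 * lambda * cross;
      double sh = sig_shape + 0.5 * L * m;
      double rt = sig_rate + 0.5 * quad;
      sigma2 = rt / Rf_rgamma(sh, 1.0);
      ++try_s; ++acc_s;
    }

    // --- joint scaling move: (sigma2, eta) -> (c sigma2, sqrt(c) eta) ---
    // leaves quad/sigma2 invariant, so it moves the dispersion through the
    // data term instead of the prior and decouples the chain when the
    // latent effects are weakly identified
    if (update_sigma) {
      double logc = step_s * norm_rand();
      double c = std::exp(logc);
      double sc = std::sqrt(c);
      double d = 0.0;
      // MVN eta part + transformation Jacobian c^{Lm/2 + 1}
      d += -0.5 * L * m * logc + (0.5 * L * m + 1.0) * logc;
      // IG prior on sigma2
      d += -(sig_shape + 1.0) * logc
           - sig_rate * (1.0 / (c * sigma2) - 1.0 / sigma2);
      if (use_data) {
        double emu = std::exp(mu);
        for (int l = 0; l < L; ++l) {
          for (int i = 0; i < m; ++i) {
            double e0 = eta(i, l), e1 = sc * e0;
            d += C[i] * (e1 - e0) - E[i] * emu *
              (std::exp(e1) - std::exp(e0));
          }
        }
      }
      ++try_sc;
      if (std::log(unif_rand()) < d) {
        sigma2 *= c;
        for (int l = 0; l < L; ++l)
          for (int i = 0; i < m; ++i) eta(i, l) *= sc;
        ++acc_sc;
      }
    }

    // --- spatial autocorrelation lambda (random walk on logit scale) ---
    if (update_lambda) {
      double sq, cross;
      quad_parts(eta, E, edge_i, edge_j, bw, sq, cross);
      double u_cur = std::log((lambda - lam_lo) / (lam_hi - lambda));
      double u_prop = u_cur + step_u * norm_rand();
      double lam_prop = lam_lo + (lam_hi - lam_lo) /
        (1.0 + std::exp(-u_prop));
      double ld_cur = logdet_term(lambda, evals);
      double ld_prop = logdet_term(lam_prop, evals);
      if (R_finite(ld_prop)) {
        // uniform prior on (lam_lo, lam_hi); logit Jacobian
        double lp_cur = 0.5 * L * ld_cur + lambda * cross / sigma2
          + std::log(lambda - lam_lo) + std::log(lam_hi - lambda);
        double lp_prop = 0.5 * L * ld_prop + lam_prop * cross / sigma2
          + std::log(lam_prop - lam_lo) + std::log(lam_hi - lam_prop);
        ++try_u;
        if (std::log(unif_rand()) < lp_prop - lp_cur) {
          lambda = lam_prop; ++acc_u;
        }
      } else {
        ++try_u;
      }
    }

    // --- burn-in step-size adaptation ---
    if (it < n_burn && (it + 1) % adapt_every == 0) {
      for (int i = 0; i < m; ++i) {
        if (try_eta[i] > 0) {
          double r = (double)acc_eta[i] / try_eta[i];
          step_eta[i] *= std::exp(clamp(r - target, -0.25, 0.25));
          acc_eta[i] = 0; try_eta[i] = 0;
        }
      }
      if (try_mu > 0) {
        step_mu *= std::exp(clamp((double)acc_mu / try_mu - target,
                                  -0.25, 0.25));
        acc_mu = 0; try_mu = 0;
      }
      if (try_tr > 0) {
        step_tr *= std::exp(clamp((double)acc_tr / try_tr - target,
                                  -0.25, 0.25));
        acc_tr = 0; try_tr = 0;
      }
      if (try_sc > 0) {
        step_s *= std::exp(clamp((double)acc_sc / try_sc - target,
                                 -0.25, 0.25));
        acc_sc = 0; try_sc = 0;
      }
      if (try_u > 0) {
        step_u *= std::exp(clamp((double)acc_u / try_u - target,
                                 -0.25, 0.25));
        acc_u = 0; try_u = 0;
      }
    }

    if (it >= n_burn && (it - n_burn) % thin == 0 && kept < n_keep) {
      out_mu[kept] = mu;
      out_sigma2[kept] = sigma2;
      out_lambda[kept] = lambda;
      if (save_eta)
        for (int i = 0; i < m; ++i) out_eta(kept, i) = eta(i, 0);
      ++kept;
    }
  }

  double ar_eta = try_eta_tot > 0 ? (double)acc_eta_tot / try_eta_tot
                                  : NA_REAL;
  double ar_mu = try_mu > 0 ? (double)acc_mu / try_mu : NA_REAL;
  double ar_s = try_sc > 0 ? (double)acc_sc / try_sc : NA_REAL;
  double ar_u = try_u > 0 ? (double)acc_u / try_u : NA_REAL;

  return List::create(
    _["mu"] = out_mu, _["sigma2"] = out_sigma2, _["lambda"] = out_lambda,
    _["eta"] = out_eta,
    _["accept"] = NumericVector::create(
      _["eta"] = ar_eta, _["mu"] = ar_mu, _["sigma2"] = ar_s,
      _["lambda"] = ar_u));
}
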