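// Metropolis-within-Gibbs sampler for the hierarchical community occupancy
// model:
//   z_ij ~ Bern(psi_ij),  logit psi_ij = alpha[i, site_j] + b1_i*x1_j + b2_i*x2_j
//   y_ijk ~ Bern(z_ij * p_ijk),  logit p_ijk = ap_i + be_i * effort_jk
// with species-level parameters drawn from community normals and priors
//   community means ~ N(0, prior_mu_sd), community sds ~ U(0, prior_sd_upper).
//
// z is drawn from its exact full conditional; species-level scalars use
// adaptive random-walk Metropolis tuned during burn-in; community means have
// conjugate normal updates; community sds use random-walk Metropolis.
//
// Detection likelihoods are aggregated over the distinct effort values
// (occasions share one of a handful of effort levels), which makes each
// iteration O(I*J*C) rather than O(I*J*K).

#include <Rcpp.h>
#include <numeric>
using namespace Rcpp;

static inline double log_psi(double L) {    // log plogis(L)
  return -log1p(std::exp(-L));
}
static inline double log_1mpsi(double L) {  // log (1 - plogis(L))
  return -L - log1p(std::exp(-L));
}

struct Adapt {
  std::vector<double> sd;
  std::vector<int> acc, tries;
  void init(int n, double s) {
    sd.assign(n, s); acc.assign(n, 0); tries.assign(n, 0);
  }
  void tune() {
    for (size_t i = 0; i < sd.size(); ++i) {
      if (tries[i] < 10) continue;
      double rate = (double)acc[i] / tries[i];
      if (rate < 0.25) sd[i] *= 0.8;
      else if (rate > 0.45) sd[i] *= 1.25;
      acc[i] = 0; tries[i] = 0;
    }
  }
};

// [[Rcpp::export]]
NumericMatrix community_occu_mcmc(IntegerVector y_flat, IntegerVector dims,
                                  NumericMatrix effort_z, IntegerVector site,
                                  NumericVector x1, NumericVector x2,
                                  int n_sites, int n_iter, int n_burn,
                                  int thin, double prior_mu_sd,
                                  double prior_sd_upper, List inits) {
  const int I = dims[0], J = dims[1], K = dims[2], S = n_sites;
  auto Y = [&](int i, int j, int k) { return y_flat[i + I * (j + J * k)]; };

  // ---- distinct effort classes over active cells ----
  std::vector<double> eclass;
  std::vector<int> cell_class(J * K, -1);
  for (int j = 0; j < J; ++j) {
    for (int k = 0; k < K; ++k) {
      double e = effort_z(j, k);
      if (!R_finite(e)) continue;
      int c = -1;
      for (size_t q = 0; q < eclass.size(); ++q)
        if (std::fabs(eclass[q] - e) < 1e-12) { c = (int)q; break; }
      if (c < 0) { eclass.push_back(e); c = (int)eclass.size() - 1; }
      cell_class[j + J * k] = c;
    }
  }
  const int C = (int)eclass.size();

  // m[j][c]: active occasions of class c at station j
  std::vector<int> m(J * C, 0);
  for (int j = 0; j < J; ++j)
    for (int k = 0; k < K; ++k) {
      int c = cell_class[j + J * k];
      if (c >= 0) m[j + J * c]++;
    }
  // n1[i][j][c]: detections per class; det_any[i][j]
  std::vector<int> n1(I * J * C, 0);
  std::vector<int> det_any(I * J, 0);
  for (int i = 0; i < I; ++i)
    for (int j = 0; j < J; ++j)
      for (int k = 0; k < K; ++k) {
        int c = cell_class[j + J * k];
        if (c < 0) continue;
        if (Y(i, j, k) == 1) {
          n1[i + I * (j + J * c)]++;
          det_any[i + I * j] = 1;
        }
      }

  // ---- state ----
  NumericMatrix alpha = clone(as<NumericMatrix>(inits["alpha"]));  // I x S
  NumericVector b1 = clone(as<NumericVector>(inits["b1"]));
  NumericVector b2 = clone(as<NumericVector>(inits["b2"]));
  NumericVector ap = clone(as<NumericVector>(inits["ap"]));
  NumericVector be = clone(as<NumericVector>(inits["be"]));
  NumericVector mu_alpha = clone(as<NumericVector>(inits["mu_alpha"]));
  NumericVector sd_alpha = clone(as<NumericVector>(inits["sd_alpha"]));
  double mu_b1 = inits["mu_b1"], sd_b1 = inits["sd_b1"];
  double mu_b2 = inits["mu_b2"], sd_b2 = inits["sd_b2"];
  double mu_p = inits["mu_p"], sd_p = inits["sd_p"];
  double mu_e = inits["mu_e"], sd_e = inits["sd_e"];

  std::vector<int> z(I * J, 0);
  for (int i = 0; i < I; ++i)
    for (int j = 0; j < J; ++j)
      z[i + I * j] = det_any[i + I * j] ? 1 : (unif_rand() < 0.5 ? 1 : 0);

  // linear predictor cache L[i][j]
  std::vector<double> L(I * J);
  auto refresh_L_row = [&](int i) {
    for (int j = 0; j < J; ++j)
      L[i + I * j] = alpha(i, site[j] - 1) + b1[i] * x1[j] + b2[i] * x2[j];
  };
  for (int i = 0; i < I; ++i) refresh_L_row(i);

  // detection p caches per (i, class)
  std::vector<double> logp(I * C), log1mp(I * C);
  auto refresh_p_row = [&](int i) {
    for (int c = 0; c < C; ++c) {
      double lp = ap[i] + be[i] * eclass[c];
      logp[i + I * c] = log_psi(lp);
      log1mp[i + I * c] = log_1mpsi(lp);
    }
  };
  for (int i = 0; i < I; ++i) refresh_p_row(i);

  // aggregated detection counts over occupied stations
  std::vector<double> A(I * C), M(I * C);
  auto refresh_AM = [&]() {
    std::fill(A.begin(), A.end(), 0.0);
    std::fill(M.begin(), M.end(), 0.0);
    for (int i = 0; i < I; ++i)
      for (int j = 0; j < J; ++j) {
        if (!z[i + I * j]) continue;
        for (int c = 0; c < C; ++c) {
          A[i + I * c] += n1[i + I * (j + J * c)];
          M[i + I * c] += m[j + J * c];
        }
      }
  };

  // stations per site
  std::vector<std::vector<int>> site_members(S);
  for (int j = 0; j < J; ++j) site_members[site[j] - 1].push_back(j);

  Adapt ad_alpha, ad_b1, ad_b2, ad_ap, ad_be, ad_hsd;
  ad_alpha.init(I * S, 0.5);
  ad_b1.init(I, 0.3); ad_b2.init(I, 0.3);
  ad_ap.init(I, 0.3); ad_be.init(I, 0.3);
  ad_hsd.init(S + 4, 0.3);  // sd_alpha[1..S], sd_b1, sd_b2, sd_p, sd_e

  const int P = I * S + 4 * I + 2 * S + 8;
  const int n_keep = (n_iter - n_burn) / thin;
  NumericMatrix out(n_keep, P);
  int row = 0;

  auto occ_ll_species_site = [&](int i, const std::vector<int>& js) {
    double ll = 0.0;
    for (int j : js) {
      double Lij = L[i + I * j];
      ll += z[i + I * j] ? log_psi(Lij) : log_1mpsi(Lij);
    }
    return ll;
  };

  for (int it = 0; it < n_iter; ++it) {
    // -- z from its full conditional --
    for (int i = 0; i < I; ++i) {
      for (int j = 0; j < J; ++j) {
        if (det_any[i + I * j]) { z[i + I * j] = 1; continue; }
        double logq = 0.0;
        for (int c = 0; c < C; ++c) {
          int mjc = m[j + J * c];
          if (mjc) logq += mjc * log1mp[i + I * c];
        }
        double Lij = L[i + I * j];
        double lp1 = log_psi(Lij) + logq, lp0 = log_1mpsi(Lij);
        double pcond = 1.0 / (1.0 + std::exp(lp0 - lp1));
        z[i + I * j] = unif_rand() < pcond ? 1 : 0;
      }
    }
    refresh_AM();

    // -- detection intercept and effort slope, per species --
    for (int i = 0; i < I; ++i) {
      // ap[i]
      {
        int id = i;
        double prop = ap[i] + norm_rand() * ad_ap.sd[id];
        double dll = R::dnorm(prop, mu_p, sd_p, 1) -
                     R::dnorm(ap[i], mu_p, sd_p, 1);
        for (int c = 0; c < C; ++c) {
          double lp = prop + be[i] * eclass[c];
          dll += A[i + I * c] * (log_psi(lp) - logp[i + I * c]) +
                 (M[i + I * c] - A[i + I * c]) *
                     (log_1mpsi(lp) - log1mp[i + I * c]);
        }
        ad_ap.tries[id]++;
        if (std::log(unif_rand()) < dll) {
          ap[i] = prop; refresh_p_row(i); ad_ap.acc[id]++;
        }
      }
      // be[i]
      {
        int id = i;
        double prop = be[i] + norm_rand() * ad_be.sd[id];
        double dll = R::dnorm(prop, mu_e, sd_e, 1) -
                     R::dnorm(be[i], mu_e, sd_e, 1);
        for (int c = 0; c < C; ++c) {
          double lp = ap[i] + prop * eclass[c];
          dll += A[i + I * c] * (log_psi(lp) - logp[i + I * c]) +
                 (M[i + I * c] - A[i + I * c]) *
                     (log_1mpsi(lp) - log1mp[i + I * c]);
        }
        ad_be.tries[id]++;
        if (std::log(unif_rand()) < dll) {
          be[i] = prop; refresh_p_row(i); ad_be.acc[id]++;
        }
      }
    }

    // -- occupancy parameters, per species --
    for (int i = 0; i < I; ++i) {
      for (int s = 0; s < S; ++s) {
        int id = i + I * s;
        double cur = alpha(i, s);
        double prop = cur + norm_rand() * ad_alpha.sd[id];
        double dll = R::dnorm(prop, mu_alpha[s], sd_alpha[s], 1) -
                     R::dnorm(cur, mu_alpha[s], sd_alpha[s], 1);
        double delta = prop - cur;
        for (int j : site_members[s]) {
          double Lold = L[i + I * j], Lnew = Lold + delta;
          dll += z[i + I * j] ? (log_psi(Lnew) - log_psi(Lold))
                              : (log_1mpsi(Lnew) - log_1mpsi(Lold));
        }
        ad_alpha.tries[id]++;
        if (std::log(unif_rand()) < dll) {
          alpha(i, s) = prop;
          for (int j : site_members[s]) L[i + I * j] += delta;
          ad_alpha.acc[id]++;
        }
      }
      // b1[i], b2[i]
      for (int which = 0; which < 2; ++which) {
        NumericVector& b = which == 0 ? b1 : b2;
        const NumericVector& x = which == 0 ? x1 : x2;
        double mu_h = which == 0 ? mu_b1 : mu_b2;
        double sd_h = which == 0 ? sd_b1 : sd_b2;
        Adapt& ad = which == 0 ? ad_b1 : ad_b2;
        double cur = b[i];
        double prop = cur + norm_rand() * ad.sd[i];
        double dll = R::dnorm(prop, mu_h, sd_h, 1) -
                     R::dnorm(cur, mu_h, sd_h, 1);
        double delta = prop - cur;
        for (int j = 0; j < J; ++j) {
          double Lold = L[i + I * j], Lnew = Lold + delta * x[j];
          dll += z[i + I * j] ? (log_psi(Lnew) - log_psi(Lold))
                              : (log_1mpsi(Lnew) - log_1mpsi(Lold));
        }
        ad.tries[i]++;
        if (std::log(unif_rand()) < dll) {
          b[i] = prop;
          for (int j = 0; j < J; ++j) L[i + I * j] += delta * x[j];
          ad.acc[i]++;
        }
      }
    }

    // -- community means: conjugate normal updates --
    double tau0 = 1.0 / (prior_mu_sd * prior_mu_sd);
    auto update_mu = [&](double sum, int n, double sdc) {
      double taul = n / (sdc * sdc);
      double v = 1.0 / (taul + tau0);
      return v * (sum / (sdc * sdc)) + std::sqrt(v) * norm_rand();
    };
    for (int s = 0; s < S; ++s) {
      double sum = 0;
      for (int i = 0; i < I; ++i) sum += alpha(i, s);
      mu_alpha[s] = update_mu(sum, I, sd_alpha[s]);
    }
    mu_b1 = update_mu(std::accumulate(b1.begin(), b1.end(), 0.0), I, sd_b1);
    mu_b2 = update_mu(std::accumulate(b2.begin(), b2.end(), 0.0), I, sd_b2);
    mu_p = update_mu(std::accumulate(ap.begin(), ap.end(), 0.0), I, sd_p);
    mu_e = update_mu(std::accumulate(be.begin(), be.end(), 0.0), I, sd_e);

    // -- community sds: random-walk Metropolis, U(0, upper) prior --
    auto update_sd = [&](double cur, double mu, const double* xv, int n,
                         int adid) -> double {
      double prop = cur + norm_rand() * ad_hsd.sd[adid];
      ad_hsd.tries[adid]++;
      if (prop <= 1e-6 || prop > prior_sd_upper) return cur;
      double dll = 0;
      for (int i = 0; i < n; ++i)
        dll += R::dnorm(xv[i], mu, prop, 1) - R::dnorm(xv[i], mu, cur, 1);
      if (std::log(unif_rand()) < dll) { ad_hsd.acc[adid]++; return prop; }
      return cur;
    };
    std::vector<double> col(I);
    for (int s = 0; s < S; ++s) {
      for (int i = 0; i < I; ++i) col[i] = alpha(i, s);
      sd_alpha[s] = update_sd(sd_alpha[s], mu_alpha[s], col.data(), I, s);
    }
    sd_b1 = update_sd(sd_b1, mu_b1, REAL(b1), I, S);
    sd_b2 = update_sd(sd_b2, mu_b2, REAL(b2), I, S + 1);
    sd_p = update_sd(sd_p, mu_p, REAL(ap), I, S + 2);
    sd_e = update_sd(sd_e, mu_e, REAL(be), I, S + 3);

    if (it < n_burn && (it + 1) % 50 == 0) {
      ad_alpha.tune(); ad_b1.tune(); ad_b2.tune();
      ad_ap.tune(); ad_be.tune(); ad_hsd.tune();
    }

    if (it >= n_burn && (it - n_burn) % thin == thin - 1 && row < n_keep) {
      int col_i = 0;
      for (int s = 0; s < S; ++s)
        for (int i = 0; i < I; ++i) out(row, col_i++) = alpha(i, s);
      for (int i = 0; i < I; ++i) out(row, col_i++) = b1[i];
      for (int i = 0; i < I; ++i) out(row, col_i++) = b2[i];
      for (int i = 0; i < I; ++i) out(row, col_i++) = ap[i];
      for (int i = 0; i < I; ++i) out(row, col_i++) = be[i];
      for (int s = 0; s < S; ++s) out(row, col_i++) = mu_alpha[s];
      for (int s = 0; s < S; ++s) out(row, col_i++) = sd_alpha[s];
      out(row, col_i++) = mu_b1; out(row, col_i++) = sd_b1;
      out(row, col_i++) = mu_b2; out(row, col_i++) = sd_b2;
      out(row, col_i++) = mu_p;  out(row, col_i++) = sd_p;
      out(row, col_i++) = mu_e;  out(row, col_i++) = sd_e;
      row++;
    }
    if ((it + 1) % 1000 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
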