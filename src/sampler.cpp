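#include <Rcpp.h>
#include <functional>
using namespace Rcpp;

// Metropolis-Hastings block sampler targeting p(z, theta, phi | y).
//
// Likelihood pieces per sample i (K categories, S samples):
//   z_{i,t} ~ Poisson(sf_i * theta_t)                     (bottleneck)
//   y^mc_i | z_i ~ DirMult(n_i, phi * z_i)                (clonal growth)
//   pooled y^sc   ~ Multinomial(., theta)                 (isolates)
//   pooled x (WT) ~ Multinomial(., theta)   only when include_wt
// Prior: theta ~ Dirichlet(1,...,1); phi flat on (0, phi_max].
//
// Scan order: Z -> theta -> phi, one-at-a-time +/-1 walk for each z
// coordinate (auto-rejecting below the support floor), Dirichlet(c*theta)
// proposal for theta, log-scale Gaussian walk for phi. Proposal scales are
// adapted toward 20-40% acceptance during burn-in only, then frozen, so
// detailed balance holds for every saved draw. All randomness comes from R's
// RNG stream.

// Dirichlet-multinomial z-dependent log-likelihood terms for one sample.
static double dm_terms(const IntegerMatrix& ymc, const IntegerMatrix& z,
                       int i, double phi, int n_i, double ztot_i) {
  if (n_i == 0) return 0.0;
  if (ztot_i <= 0.0) return R_NegInf;
  double out = R::lgammafn(phi * ztot_i) - R::lgammafn(n_i + phi * ztot_i);
  for (int t = 0; t < ymc.nrow(); ++t) {
    int y = ymc(t, i);
    if (y > 0) {
      double a = phi * z(t, i);
      if (a <= 0.0) return R_NegInf;
      out += R::lgammafn(a + y) - R::lgammafn(a);
    }
  }
  return out;
}

// [[Rcpp::export(name = ".sampler_run")]]
List sampler_run(IntegerMatrix ymc, NumericVector ysc, NumericVector xwt,
                 bool include_wt, NumericVector sf,
                 int draws, int burnin, int thin,
                 NumericVector theta_init, IntegerMatrix z_init,
                 double phi_init, double c_init, double sigma_init,
                 bool adapt, double phi_max,
                 bool do_z, bool do_theta, bool do_phi, bool save_z) {
  const int K = ysc.size();
  const int S = ymc.ncol();
  if (S > 0 && ymc.nrow() != K) stop("ymc row count mismatch");

  IntegerVector n(S);
  for (int i = 0; i < S; ++i) {
    int tot = 0;
    for (int t = 0; t < K; ++t) tot += ymc(t, i);
    n[i] = tot;
  }

  IntegerMatrix z = clone(z_init);
  NumericVector theta = clone(theta_init);
  NumericVector ltheta(K);
  for (int t = 0; t < K; ++t) ltheta[t] = log(theta[t]);
  double phi = phi_init;

  std::vector<double> ztot(S, 0.0);       // sum_t z_{i,t}
  std::vector<double> zrow(K, 0.0);       // sum_i z_{i,t}
  for (int i = 0; i < S; ++i)
    for (int t = 0; t < K; ++t) { ztot[i] += z(t, i); zrow[t] += z(t, i); }

  // multinomial exponents for the theta block
  NumericVector w_fixed(K);
  for (int t = 0; t < K; ++t)
    w_fixed[t] = ysc[t] + (include_wt ? xwt[t] : 0.0);

  double cc = c_init, sigma = sigma_init;
  const int G = draws;
  NumericMatrix thetas(G, K);
  NumericVector phis(G);
  NumericMatrix zsum(K, S);               // running mean of saved z
  IntegerMatrix zlast(K, S);

  long att_z = 0, acc_z = 0, att_t = 0, acc_t = 0, att_p = 0, acc_p = 0;
  long w_att_t = 0, w_acc_t = 0, w_att_p = 0, w_acc_p = 0;  // adaptation window

  RNGScope scope;
  const int total = burnin + G * thin;
  int saved = 0;

  for (int scan = 0; scan < total; ++scan) {
    bool warm = scan < burnin;

    if (do_z) {
      for (int i = 0; i < S; ++i) {
        if (n[i] == 0 && sf[i] <= 0) continue;
        for (int t = 0; t < K; ++t) {
          ++att_z;
          int z0 = z(t, i);
          int dz = (unif_rand() < 0.5) ? 1 : -1;
          int z1 = z0 + dz;
          int floor_t = (ymc(t, i) > 0) ? 1 : 0;
          if (z1 < floor_t) continue;  // below support: acceptance prob 0
          double lam = sf[i] * theta[t];
          double delta;
          if (dz > 0) delta = log(lam) - log((double)z0 + 1.0);
          else        delta = -log(lam) + log((double)z0);
          if (n[i] > 0) {
            double S0 = ztot[i], S1 = S0 + dz;
            if (S1 <= 0.0) continue;   // DM mass would be zero
            delta += R::lgammafn(phi * S1) - R::lgammafn(n[i] + phi * S1)
                   - R::lgammafn(phi * S0) + R::lgammafn(n[i] + phi * S0);
            int y = ymc(t, i);
            if (y > 0) {
              double a0 = phi * z0, a1 = phi * z1;
              delta += R::lgammafn(a1 + y) - R::lgammafn(a1)
                     - R::lgammafn(a0 + y) + R::lgammafn(a0);
            }
          }
          if (delta >= 0.0 || log(unif_rand()) < delta) {
            z(t, i) = z1;
            ztot[i] += dz;
            zrow[t] += dz;
            ++acc_z;
          }
        }
      }
    }

    if (do_theta && K > 1) {
      ++att_t; ++w_att_t;
      NumericVector g(K);
      double gsum = 0.0;
      bool ok = true;
      for (int t = 0; t < K; ++t) {
        g[t] = R::rgamma(cc * theta[t], 1.0);
        gsum += g[t];
      }
      if (gsum <= 0.0) ok = false;
      NumericVector thn(K), lthn(K);
      if (ok) {
        for (int t = 0; t < K; ++t) {
          thn[t] = g[t] / gsum;
          if (thn[t] <= 0.0 || !R_finite(thn[t])) { ok = false; break; }
          lthn[t] = log(thn[t]);
        }
      }
      if (ok) {
        double delta = 0.0;
        for (int t = 0; t < K; ++t) {
          double w = zrow[t] + w_fixed[t];
          delta += w * (lthn[t] - ltheta[t]);
          // q(theta | c*theta') - q(theta' | c*theta)
          delta += -R::lgammafn(cc * thn[t]) + (cc * thn[t] - 1.0) * ltheta[t]
                   + R::lgammafn(cc * theta[t]) - (cc * theta[t] - 1.0) * lthn[t];
        }
        if (delta >= 0.0 || log(unif_rand()) < delta) {
          theta = thn; ltheta = lthn;
          ++acc_t; ++w_acc_t;
        }
      }
    }

    if (do_phi) {
      ++att_p; ++w_att_p;
      double lphi1 = log(phi) + sigma * norm_rand();
      double phi1 = exp(lphi1);
      if (phi1 > 0.0 && phi1 <= phi_max) {
        double delta = lphi1 - log(phi);  // Jacobian of the log walk
        for (int i = 0; i < S; ++i) {
          delta += dm_terms(ymc, z, i, phi1, n[i], ztot[i])
                 - dm_terms(ymc, z, i, phi, n[i], ztot[i]);
          if (delta == R_NegInf) break;
        }
        if (delta >= 0.0 || log(unif_rand()) < delta) {
          phi = phi1;
          ++acc_p; ++w_acc_p;
        }
      }
    }

    if (adapt && warm && (scan + 1) % 50 == 0) {
      if (w_att_t > 0) {
        double r = (double)w_acc_t / w_att_t;
        if (r < 0.20) cc *= 1.5;        // tighter proposals
        else if (r > 0.40) cc /= 1.5;   // bolder proposals
        if (cc < (double)K) cc = (double)K;
        if (cc > 1e9) cc = 1e9;
      }
      if (w_att_p > 0) {
        double r = (double)w_acc_p / w_att_p;
        if (r < 0.20) sigma /= 1.5;
        else if (r > 0.40) sigma *= 1.5;
        if (sigma < 1e-3) sigma = 1e-3;
        if (sigma > 10.0) sigma = 10.0;
      }
      w_att_t = w_acc_t = w_att_p = w_acc_p = 0;
    }
    if (warm && scan + 1 == burnin) {
      // reset acceptance accounting so reported rates describe the frozen chain
      att_z = acc_z = att_t = acc_t = att_p = acc_p = 0;
    }

    if (!warm && ((scan - burnin + 1) % thin == 0)) {
      for (int t = 0; t < K; ++t) thetas(saved, t) = theta[t];
      phis[saved] = phi;
      if (save_z)
        for (int i = 0; i < S; ++i)
          for (int t = 0; t < K; ++t) zsum(t, i) += z(t, i);
      ++saved;
    }
    if (scan % 512 == 0) checkUserInterrupt();
  }

  if (save_z && saved > 0)
    for (int i = 0; i < S; ++i)
      for (int t = 0; t < K; ++t) zsum(t, i) /= saved;
  for (int i = 0; i < S; ++i)
    for (int t = 0; t < K; ++t) zlast(t, i) = z(t, i);

  return List::create(
    _["thetas"] = thetas, _["phis"] = phis,
    _["accept"] = NumericVector::create(
      _["z"] = att_z ? (double)acc_z / att_z : NA_REAL,
      _["theta"] = att_t ? (double)acc_t / att_t : NA_REAL,
      _["phi"] = att_p ? (double)acc_p / att_p : NA_REAL),
    _["proposal"] = NumericVector::create(_["c"] = cc, _["sigma"] = sigma),
    _["z_mean"] = zsum, _["z_last"] = zlast);
}

// Number of K x 2 tables with row margins s and first-column total m.
// [[Rcpp::export(name = ".fisher_table_count")]]
double fisher_table_count(IntegerVector s, int m) {
  std::vector<double> dp(m + 1, 0.0);
  dp[0] = 1.0;
  for (int t = 0; t < s.size(); ++t) {
    std::vector<double> nxt(m + 1, 0.0);
    for (int j = 0; j <= m; ++j) {
      if (dp[j] == 0.0) continue;
      int top = std::min(s[t], m - j);
      for (int x = 0; x <= top; ++x) {
        nxt[j + x] += dp[j];
        if (nxt[j + x] > 1e300) return R_PosInf;
      }
    }
    dp.swap(nxt);
  }
  return dp[m];
}

// Exact Fisher p-value by depth-first enumeration of the margin-constrained
// table space: total multivariate hypergeometric probability of tables whose
// log-ordinate is <= the observed one (ties included, small tolerance).
// [[Rcpp::export(name = ".fisher_exact_enum")]]
double fisher_exact_enum(IntegerVector s, int m, double obs_logord,
                         double tol) {
  const int K = s.size();
  int total = 0;
  for (int t = 0; t < K; ++t) total += s[t];
  double lnorm = R::lchoose((double)total, (double)m);
  // suffix sums of s for feasibility pruning
  std::vector<int> suf(K + 1, 0);
  for (int t = K - 1; t >= 0; --t) suf[t] = suf[t + 1] + s[t];
  double acc = 0.0;
  std::vector<int> xs(K, 0);
  std::function<void(int, int, double)> rec = [&](int t, int rem, double lo) {
    if (t == K) {
      if (rem == 0 && lo - lnorm <= obs_logord + tol) acc += exp(lo - lnorm);
      return;
    }
    int hi = std::min(s[t], rem);
    int low = std::max(0, rem - suf[t + 1]);
    for (int x = low; x <= hi; ++x)
      rec(t + 1, rem - x, lo + R::lchoose((double)s[t], (double)x));
  };
  rec(0, m, 0.0);
  return acc;
}
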