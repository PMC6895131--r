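// Adaptive component-wise random-walk Metropolis for the single-season
// occupancy model with the latent state marginalized out.
//
// Parameter layout (one species, one covariate scale):
//   alpha[0..nd-1]  detection fixed effects (logit scale)
//   beta[0..no-1]   occurrence fixed effects (logit scale)
//   v_site[0..S-1]  site random intercepts, non-centered (u = sigma * v)
//   v_area[0..A-1]  fire-area random intercepts, non-centered
//   ls_site, ls_area  log SDs of the random intercepts (HalfNormal priors
//                     on the natural scale, sampled on the log scale with
//                     the Jacobian included)
// The non-centered parameterization avoids the funnel between the
// intercept SDs and their group effects when data per group are sparse.
// Reported draws contain u = sigma * v, not v.
//
// Likelihood caches kept in sync across updates:
//   etaDet  per-night linear predictor of detection
//   A       per-period sum of log Bernoulli(y | p) terms
//   Q       per-period sum of log(1 - p) (the all-miss probability)
//   psil    per-period linear predictor of occurrence
//   ll      per-period marginal log-likelihood
// Updating a detection coefficient touches only etaDet/A/Q; an occurrence
// coefficient only psil; a random intercept only its group's periods; a
// log-sigma rescales one set of intercepts. One sweep costs O(nights).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double lse2(double a, double b) {
  return (a > b) ? a + std::log1p(std::exp(b - a))
                 : b + std::log1p(std::exp(a - b));
}
static inline double log_expit(double x) {   // log(1/(1+exp(-x)))
  return (x > 0) ? -std::log1p(std::exp(-x)) : x - std::log1p(std::exp(x));
}
static inline double dnorm_log(double x, double sd) {
  return -0.5 * (x / sd) * (x / sd) - std::log(sd) - 0.9189385332046727;
}

// [[Rcpp::export]]
List occu_mcmc_chain(IntegerVector y, IntegerVector night_period,
                     NumericMatrix Xdet, NumericMatrix Xocc,
                     IntegerVector site, IntegerVector area,
                     int n_site, int n_area,
                     int iter, int warmup,
                     double prior_sd_fixed, double prior_sigma_scale,
                     NumericVector init) {
  const int nN = Xdet.nrow(), nd = Xdet.ncol();
  const int nP = Xocc.nrow(), no = Xocc.ncol();
  const int npar = nd + no + n_site + n_area + 2;
  if (init.size() != npar) stop("init has wrong length");
  const int iSite0 = nd + no, iArea0 = iSite0 + n_site;
  const int iLsS = iArea0 + n_area, iLsA = iLsS + 1;

  std::vector<double> th(init.begin(), init.end());

  // group -> period index lists
  std::vector<std::vector<int> > perBySite(n_site), perByArea(n_area);
  for (int i = 0; i < nP; ++i) {
    perBySite[site[i]].push_back(i);
    perByArea[area[i]].push_back(i);
  }

  std::vector<bool> det(nP, false);
  for (int k = 0; k < nN; ++k) if (y[k] == 1) det[night_period[k]] = true;

  // ---- caches ----
  std::vector<double> etaDet(nN), A(nP), Q(nP), psil(nP), lpsi(nP),
      l1mpsi(nP), ll(nP);
  std::vector<double> nEtaDet(nN), nA(nP), nQ(nP), nPsil(nP), nLpsi(nP),
      nL1mpsi(nP), nLl(nP);

  auto detFromEta = [&](const std::vector<double>& eta, std::vector<double>& Ao,
                        std::vector<double>& Qo) {
    std::fill(Ao.begin(), Ao.end(), 0.0);
    std::fill(Qo.begin(), Qo.end(), 0.0);
    for (int k = 0; k < nN; ++k) {
      const double lp = log_expit(eta[k]), l1mp = log_expit(-eta[k]);
      const int i = night_period[k];
      Ao[i] += (y[k] == 1) ? lp : l1mp;
      Qo[i] += l1mp;
    }
  };
  auto perLl = [&](int i, const std::vector<double>& Ao,
                   const std::vector<double>& Qo, double lps, double l1mps) {
    return det[i] ? lps + Ao[i] : lse2(lps + Qo[i], l1mps);
  };

  // initialize caches
  for (int k = 0; k < nN; ++k) {
    double e = 0.0;
    for (int c = 0; c < nd; ++c) e += Xdet(k, c) * th[c];
    etaDet[k] = e;
  }
  detFromEta(etaDet, A, Q);
  double sigS = std::exp(th[iLsS]), sigA = std::exp(th[iLsA]);
  double llTot = 0.0;
  for (int i = 0; i < nP; ++i) {
    double e = 0.0;
    for (int c = 0; c < no; ++c) e += Xocc(i, c) * th[nd + c];
    e += sigS * th[iSite0 + site[i]] + sigA * th[iArea0 + area[i]];
    psil[i] = e;
    lpsi[i] = log_expit(e);
    l1mpsi[i] = log_expit(-e);
    ll[i] = perLl(i, A, Q, lpsi[i], l1mpsi[i]);
    llTot += ll[i];
  }

  // ---- adaptation state ----
  std::vector<double> step(npar, 0.1);
  std::vector<int> accWin(npar, 0);
  const int window = 50;
  int windowIdx = 0;

  const int keep = iter - warmup;
  NumericMatrix draws(keep, npar), psiDraws(keep, nP), pzDraws(keep, nP),
      llDraws(keep, nP);
  std::vector<double> accTot(npar, 0.0);

  for (int it = 0; it < iter; ++it) {
    // --- detection fixed effects ---
    for (int c = 0; c < nd; ++c) {
      const double delta = R::norm_rand() * step[c];
      const double cand = th[c] + delta;
      for (int k = 0; k < nN; ++k) nEtaDet[k] = etaDet[k] + delta * Xdet(k, c);
      detFromEta(nEtaDet, nA, nQ);
      double nTot = 0.0;
      for (int i = 0; i < nP; ++i) {
        nLl[i] = perLl(i, nA, nQ, lpsi[i], l1mpsi[i]);
        nTot += nLl[i];
      }
      const double lr = (nTot - llTot) +
          dnorm_log(cand, prior_sd_fixed) - dnorm_log(th[c], prior_sd_fixed);
      if (std::log(R::unif_rand()) < lr) {
        th[c] = cand;
        etaDet.swap(nEtaDet); A.swap(nA); Q.swap(nQ); ll.swap(nLl);
        llTot = nTot;
        ++accWin[c]; accTot[c] += 1.0;
      }
    }
    // --- occurrence fixed effects ---
    for (int c = 0; c < no; ++c) {
      const int j = nd + c;
      const double delta = R::norm_rand() * step[j];
      const double cand = th[j] + delta;
      double nTot = 0.0;
      for (int i = 0; i < nP; ++i) {
        nPsil[i] = psil[i] + delta * Xocc(i, c);
        nLpsi[i] = log_expit(nPsil[i]);
        nL1mpsi[i] = log_expit(-nPsil[i]);
        nLl[i] = perLl(i, A, Q, nLpsi[i], nL1mpsi[i]);
        nTot += nLl[i];
      }
      const double lr = (nTot - llTot) +
          dnorm_log(cand, prior_sd_fixed) - dnorm_log(th[j], prior_sd_fixed);
      if (std::log(R::unif_rand()) < lr) {
        th[j] = cand;
        psil.swap(nPsil); lpsi.swap(nLpsi); l1mpsi.swap(nL1mpsi); ll.swap(nLl);
        llTot = nTot;
        ++accWin[j]; accTot[j] += 1.0;
      }
    }
    // --- non-centered random intercepts (standard-normal v) ---
    for (int g = 0; g < n_site + n_area; ++g) {
      const bool isSite = g < n_site;
      const int j = isSite ? iSite0 + g : iArea0 + (g - n_site);
      const double sig = isSite ? sigS : sigA;
      const std::vector<int>& per = isSite ? perBySite[g] : perByArea[g - n_site];
      const double delta = R::norm_rand() * step[j];
      const double cand = th[j] + delta;
      const double dU = sig * delta;
      double dLl = 0.0;
      for (size_t q = 0; q < per.size(); ++q) {
        const int i = per[q];
        const double np = psil[i] + dU;
        nPsil[i] = np;
        nLpsi[i] = log_expit(np);
        nL1mpsi[i] = log_expit(-np);
        nLl[i] = perLl(i, A, Q, nLpsi[i], nL1mpsi[i]);
        dLl += nLl[i] - ll[i];
      }
      const double lr = dLl + dnorm_log(cand, 1.0) - dnorm_log(th[j], 1.0);
      if (std::log(R::unif_rand()) < lr) {
        th[j] = cand;
        for (size_t q = 0; q < per.size(); ++q) {
          const int i = per[q];
          psil[i] = nPsil[i]; lpsi[i] = nLpsi[i]; l1mpsi[i] = nL1mpsi[i];
          ll[i] = nLl[i];
        }
        llTot += dLl;
        ++accWin[j]; accTot[j] += 1.0;
      }
    }
    // --- log sigmas (rescale all of one group's intercepts) ---
    for (int which = 0; which < 2; ++which) {
      const int j = which == 0 ? iLsS : iLsA;
      const int v0 = which == 0 ? iSite0 : iArea0;
      const double sigOld = which == 0 ? sigS : sigA;
      const IntegerVector& grp = which == 0 ? site : area;
      const double cand = th[j] + R::norm_rand() * step[j];
      const double sigNew = std::exp(cand);
      const double dSig = sigNew - sigOld;
      double nTot = 0.0;
      for (int i = 0; i < nP; ++i) {
        nPsil[i] = psil[i] + dSig * th[v0 + grp[i]];
        nLpsi[i] = log_expit(nPsil[i]);
        nL1mpsi[i] = log_expit(-nPsil[i]);
        nLl[i] = perLl(i, A, Q, nLpsi[i], nL1mpsi[i]);
        nTot += nLl[i];
      }
      double lr = (nTot - llTot) +
          dnorm_log(sigNew, prior_sigma_scale) -
          dnorm_log(sigOld, prior_sigma_scale) +
          (cand - th[j]);  // Jacobian of sigma = exp(ls)
      if (std::log(R::unif_rand()) < lr) {
        th[j] = cand;
        if (which == 0) sigS = sigNew; else sigA = sigNew;
        psil.swap(nPsil); lpsi.swap(nLpsi); l1mpsi.swap(nL1mpsi); ll.swap(nLl);
        llTot = nTot;
        ++accWin[j]; accTot[j] += 1.0;
      }
    }

    // --- adapt during warmup ---
    if (it < warmup && (it + 1) % window == 0) {
      ++windowIdx;
      const double gain = 1.0 / std::sqrt((double)windowIdx);
      for (int j = 0; j < npar; ++j) {
        const double rate = (double)accWin[j] / window;
        step[j] *= std::exp(gain * (rate - 0.44));
        accWin[j] = 0;
      }
    }

    // --- store (random effects reported on the u = sigma * v scale) ---
    if (it >= warmup) {
      const int r = it - warmup;
      for (int j = 0; j < iSite0; ++j) draws(r, j) = th[j];
      for (int s = 0; s < n_site; ++s) draws(r, iSite0 + s) = sigS * th[iSite0 + s];
      for (int a = 0; a < n_area; ++a) draws(r, iArea0 + a) = sigA * th[iArea0 + a];
      draws(r, iLsS) = th[iLsS];
      draws(r, iLsA) = th[iLsA];
      for (int i = 0; i < nP; ++i) {
        const double psi = 1.0 / (1.0 + std::exp(-psil[i]));
        psiDraws(r, i) = psi;
        llDraws(r, i) = ll[i];
        pzDraws(r, i) = det[i] ? 1.0 : std::exp(lpsi[i] + Q[i] - ll[i]);
      }
    }
  }

  NumericVector acc(npar);
  for (int j = 0; j < npar; ++j) acc[j] = accTot[j] / iter;
  return List::create(_["draws"] = draws, _["psi"] = psiDraws,
                      _["pz"] = pzDraws, _["loglik"] = llDraws,
                      _["accept"] = acc,
                      _["step"] = NumericVector(step.begin(), step.end()));
}
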