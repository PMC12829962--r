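#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Fast engine for one batch-culture round of the lineage-based model.
//
// The RNG call sequence is a contract shared with the pure-R reference
// engine (R/tube.R): every draw below must appear there in the same order
// under the same guard, so that seeded runs are bit-identical between the
// two engines. All probabilistic draws go through R's RNG (RNGScope is
// installed by the Rcpp attribute wrapper).
//
// Per time-step:
//   1. permutation of lineages: L draws of unif_rand() (only if L > 1)
//   2. depletion flags, rescaled preferences, u_i, S_i^max  (no RNG)
//   3. degradation, sequential in permuted order            (no RNG)
//   4. activation: per lineage, one rpois iff lambda > 0 and eligible > 0
//   5. replication: one rpois iff lambda > 0; one rbinom iff divisions > 0
//      and mu > 0; per mutant, one rlnorm per unmasked investment entry
//   6. death: one rpois iff p_death > 0 and S > 0; one rhyper iff both
//      sub-populations are non-empty and deaths > 0
// Sums that the R side computes with sum() are accumulated in long double
// to match R's internal LDOUBLE accumulation.

struct Lin {
  int sp;                   // species index, 0-based
  int lid;                  // lineage id, 1-based (as seen from R)
  std::vector<double> f;    // investment vector, length Kt
  double p0, p1;            // inactive / active cell counts
  std::vector<char> flag;   // per-nutrient depletion flag for this round
};

static inline double ld_sum(const std::vector<double>& x) {
  long double s = 0.0L;
  for (double v : x) s += v;
  return (double)s;
}

// [[Rcpp::export]]
List cpp_run_round(IntegerVector sp, IntegerVector lid, NumericMatrix fmat,
                   NumericVector p0, NumericVector p1, LogicalMatrix flags,
                   NumericVector N, NumericVector T,
                   NumericVector N0, NumericVector T0,
                   NumericVector a, NumericVector r,
                   NumericMatrix nmat, NumericMatrix mmat,
                   IntegerMatrix maskf,
                   double K, int t_end, double mu, double sdlog,
                   bool maint_revert, int lid_start) {
  const int J = N.size(), Kt = T.size();
  const int npool = a.size();
  int next_lid = lid_start;

  std::vector<Lin> lins;
  for (int i = 0; i < sp.size(); ++i) {
    Lin l;
    l.sp = sp[i] - 1;
    l.lid = lid[i];
    l.f.resize(Kt);
    for (int k = 0; k < Kt; ++k) l.f[k] = fmat(i, k);
    l.p0 = p0[i];
    l.p1 = p1[i];
    l.flag.resize(J);
    for (int j = 0; j < J; ++j) l.flag[j] = flags(i, j) ? 1 : 0;
    lins.push_back(l);
  }

  std::vector<double> Nc(N.begin(), N.end()), Tc(T.begin(), T.end());
  NumericMatrix traj(t_end, npool);

  for (int t = 0; t < t_end; ++t) {
    int L = (int)lins.size();
    if (L > 0) {
      // 1. permutation --------------------------------------------------
      std::vector<int> perm(L);
      for (int i = 0; i < L; ++i) perm[i] = i;
      if (L > 1) {
        std::vector<double> keys(L);
        for (int i = 0; i < L; ++i) keys[i] = unif_rand();
        std::stable_sort(perm.begin(), perm.end(),
                         [&](int x, int y) { return keys[x] < keys[y]; });
      }

      // 2. flags, nhat, u, smax (index order, no RNG) -------------------
      std::vector<std::vector<double>> nhat(L, std::vector<double>(J, 0.0));
      std::vector<double> uvec(L, 0.0), smax(L, 0.0), fdot(L, 0.0);
      for (int i = 0; i < L; ++i) {
        Lin& ln = lins[i];
        for (int j = 0; j < J; ++j)
          if (!ln.flag[j] && Nc[j] < nmat(ln.sp, j)) ln.flag[j] = 1;
        long double us = 0.0L;
        for (int j = 0; j < J; ++j) if (!ln.flag[j]) us += nmat(ln.sp, j);
        uvec[i] = (double)us;
        if (uvec[i] > 0) {
          for (int j = 0; j < J; ++j)
            nhat[i][j] = ln.flag[j] ? 0.0 : nmat(ln.sp, j) / uvec[i];
          double mn = R_PosInf;
          for (int j = 0; j < J; ++j)
            if (nhat[i][j] > 0) mn = std::min(mn, Nc[j] / nhat[i][j]);
          smax[i] = std::floor(mn);
        }
        fdot[i] = ld_sum(ln.f);
      }

      // 3. degradation (permuted order, no RNG) -------------------------
      for (int ii = 0; ii < L; ++ii) {
        int i = perm[ii];
        Lin& ln = lins[i];
        double S = ln.p0 + ln.p1;
        if (S <= 0 || uvec[i] <= 0 || fdot[i] <= 0) continue;
        double C = std::min(S, smax[i]);
        if (C <= 0) continue;
        long double fact = 0.0L;
        for (int k = 0; k < Kt; ++k) if (Tc[k] > 0) fact += ln.f[k];
        double factive = (double)fact;
        if (factive <= 0) continue;
        for (int k = 0; k < Kt; ++k) {
          if (Tc[k] > 0) {
            double rem = C * ln.f[k] * uvec[i];
            Tc[k] -= std::min(rem, Tc[k]);
          }
        }
        for (int j = 0; j < J; ++j) {
          double cost = C * nhat[i][j] * factive;
          Nc[j] -= std::min(cost, Nc[j]);
        }
      }

      // 4. activation (permuted order) ----------------------------------
      std::vector<double> Nsnap(Nc);
      for (int ii = 0; ii < L; ++ii) {
        int i = perm[ii];
        Lin& ln = lins[i];
        double onemf = 1.0 - fdot[i];
        if (uvec[i] <= 0) {
          if (maint_revert && ln.p1 > 0) { ln.p0 += ln.p1; ln.p1 = 0; }
          continue;
        }
        // maintenance of already-active cells
        if (ln.p1 > 0 && onemf > 0) {
          if (!maint_revert) {
            for (int j = 0; j < J; ++j) {
              double c = ln.p1 * nhat[i][j] * onemf;
              Nc[j] -= std::min(c, Nc[j]);
            }
          } else {
            double afford = R_PosInf;
            for (int j = 0; j < J; ++j)
              if (nhat[i][j] > 0)
                afford = std::min(afford, Nc[j] / (nhat[i][j] * onemf));
            double paid = std::min(ln.p1, std::floor(afford));
            for (int j = 0; j < J; ++j) {
              double c = paid * nhat[i][j] * onemf;
              Nc[j] -= std::min(c, Nc[j]);
            }
            if (paid < ln.p1) { ln.p0 += (ln.p1 - paid); ln.p1 = paid; }
          }
        }
        // new activations
        long double acc = 0.0L;
        for (int j = 0; j < J; ++j) acc += nhat[i][j] * Nsnap[j] / N0[j];
        double pact = a[ln.sp] * onemf * uvec[i] * (double)acc;
        double nelig = std::min(ln.p0, smax[i]);
        if (pact > 0 && nelig > 0) {
          double lam = pact * nelig;
          double act = std::min(R::rpois(lam), nelig);
          if (onemf > 0) {
            double afford = R_PosInf;
            for (int j = 0; j < J; ++j)
              if (nhat[i][j] > 0)
                afford = std::min(afford, Nc[j] / (nhat[i][j] * onemf));
            act = std::min(act, std::floor(afford));
          }
          if (act > 0) {
            for (int j = 0; j < J; ++j) {
              double c = act * nhat[i][j] * onemf;
              Nc[j] -= std::min(c, Nc[j]);
            }
            ln.p0 -= act;
            ln.p1 += act;
          }
        }
      }

      // 5. replication + mutation (permuted order) ----------------------
      std::vector<Lin> newborn;
      for (int ii = 0; ii < L; ++ii) {
        int i = perm[ii];
        Lin& ln = lins[i];
        double prob = r[ln.sp] * (1.0 - fdot[i]);
        if (prob <= 0 || ln.p1 <= 0) continue;
        double lam = prob * ln.p1;
        double d = std::min(R::rpois(lam), ln.p1);
        if (d <= 0) continue;
        ln.p1 -= d;
        double nmut = 0;
        if (mu > 0) nmut = R::rbinom(d, mu);
        ln.p0 += 2.0 * d - nmut;
        for (int mti = 0; mti < (int)nmut; ++mti) {
          Lin nb;
          nb.sp = ln.sp;
          nb.lid = next_lid++;
          nb.f = ln.f;
          for (int k = 0; k < Kt; ++k)
            if (maskf(ln.sp, k)) nb.f[k] *= R::rlnorm(0.0, sdlog);
          double tot = ld_sum(nb.f);
          if (tot > 1.0) for (int k = 0; k < Kt; ++k) nb.f[k] /= tot;
          nb.p0 = 1;
          nb.p1 = 0;
          nb.flag = ln.flag;
          newborn.push_back(nb);
        }
      }
      for (auto& nb : newborn) lins.push_back(nb);

      // 6. death (permuted order, then newborns in creation order) ------
      int Lall = (int)lins.size();
      for (int ii = 0; ii < Lall; ++ii) {
        int i = (ii < L) ? perm[ii] : ii;
        Lin& ln = lins[i];
        double S = ln.p0 + ln.p1;
        if (S <= 0) continue;
        long double pd = 0.0L;
        for (int k = 0; k < Kt; ++k) {
          double T2 = Tc[k] * Tc[k];
          pd += (mmat(ln.sp, k) * T2) / (T2 + K * K);
        }
        double pdeath = std::min(1.0, (double)pd);
        if (pdeath <= 0) continue;
        double deaths = std::min(R::rpois(pdeath * S), S);
        if (deaths <= 0) continue;
        double d1;
        if (ln.p1 <= 0) d1 = 0;
        else if (ln.p0 <= 0) d1 = deaths;
        else d1 = R::rhyper(ln.p1, ln.p0, deaths);
        ln.p1 -= d1;
        ln.p0 -= (deaths - d1);
      }

      // prune extinct lineages (order preserved)
      std::vector<Lin> kept;
      kept.reserve(lins.size());
      for (auto& ln : lins) if (ln.p0 + ln.p1 > 0) kept.push_back(ln);
      lins.swap(kept);
    }

    for (auto& ln : lins) traj(t, ln.sp) += ln.p0 + ln.p1;
  }

  int L = (int)lins.size();
  IntegerVector osp(L), olid(L);
  NumericVector op0(L), op1(L);
  NumericMatrix of(L, Kt);
  LogicalMatrix oflag(L, J);
  for (int i = 0; i < L; ++i) {
    osp[i] = lins[i].sp + 1;
    olid[i] = lins[i].lid;
    op0[i] = lins[i].p0;
    op1[i] = lins[i].p1;
    for (int k = 0; k < Kt; ++k) of(i, k) = lins[i].f[k];
    for (int j = 0; j < J; ++j) oflag(i, j) = lins[i].flag[j] != 0;
  }
  return List::create(
    _["sp"] = osp, _["lid"] = olid, _["f"] = of,
    _["p0"] = op0, _["p1"] = op1, _["flags"] = oflag,
    _["N"] = NumericVector(Nc.begin(), Nc.end()),
    _["T"] = NumericVector(Tc.begin(), Tc.end()),
    _["traj"] = traj, _["next_lid"] = next_lid);
}

// Deterministic seed mixing (splitmix64-flavoured) for the named-substream
// discipline: any (species set, run, round, tube, process) is replayable in
// isolation from a small integer key path. Result fits in a 32-bit R integer.
// [[Rcpp::export]]
int cpp_mix_seed(IntegerVector keys) {
  uint64_t h = 0x9E3779B97F4A7C15ULL;
  for (int i = 0; i < keys.size(); ++i) {
    uint64_t z = (uint64_t)(uint32_t)keys[i];
    h ^= z + 0x9E3779B97F4A7C15ULL + (h << 6) + (h >> 2);
    h *= 0xBF58476D1CE4E5B9ULL;
    h ^= h >> 27;
    h *= 0x94D049BB133111EBULL;
    h ^= h >> 31;
  }
  return (int)(h % 2147483647ULL);
}
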