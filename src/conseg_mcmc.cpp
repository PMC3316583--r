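#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Gibbs/Metropolis sampler for the multiple change-point mixture model.
//
// Data:   codes x_1..x_N, each in {0..m-1} (conservation codes).
// Model:  boundary indicators b_j ~ Bern(rho) at each of the N-1
//         between-character positions; segment labels z_s ~ Cat(pi);
//         per-segment code proportions ~ Dirichlet(alpha_{z_s}),
//         integrated out analytically (Dirichlet-multinomial marginal);
//         rho ~ Beta(1,1), pi ~ Dirichlet(1,..,1),
//         alpha_{gc} ~ log-uniform(1e-3, 1e6).
//
// Moves per iteration:
//   1. exact Gibbs sweep over all boundaries, labels marginalized
//      (log-sum-exp over classes of the segment marginal),
//   2. Gibbs resample of each segment label,
//   3. conjugate Dirichlet update of pi,
//   4. conjugate Beta update of rho,
//   5. Metropolis updates of each class's alpha vector with labels
//      marginalized out: a moment-anchored independence proposal, a
//      joint scale move (step-size mixture), and two log-normal
//      random-walk sweeps (steps adapted toward 0.44 acceptance during
//      burn-in only).
//
// All randomness goes through R's RNG so set.seed() in R gives
// bit-identical chains.

static const double ALPHA_LO = 1e-3;
static const double ALPHA_HI = 1e6;
static const int    TAB_MAX  = 2048;   // lgamma tables cached up to this count

// Dirichlet-multinomial log marginal of one segment's ordered codes:
// log Gamma(A)/Gamma(A+n) + sum_c log Gamma(a_c+n_c)/Gamma(a_c)
static inline double dm_direct(const std::vector<double>& a, double A,
                               const int* cnt, int m) {
  int n = 0;
  for (int c = 0; c < m; ++c) n += cnt[c];
  if (n == 0) return 0.0;
  double v = lgamma(A) - lgamma(A + n);
  for (int c = 0; c < m; ++c)
    if (cnt[c] > 0) v += lgamma(a[c] + cnt[c]) - lgamma(a[c]);
  return v;
}

struct Tables {
  // la[g][c][n] = lgamma(alpha_gc + n) - lgamma(alpha_gc), n = 0..TAB_MAX
  // lt[g][n]    = lgamma(A_g) - lgamma(A_g + n)
  int k, m;
  std::vector<std::vector<double> > la;  // k*m vectors
  std::vector<std::vector<double> > lt;  // k vectors
  std::vector<double> A;                 // row sums of alpha

  void build(const std::vector<std::vector<double> >& alpha, int g) {
    double s = 0.0;
    for (int c = 0; c < m; ++c) s += alpha[g][c];
    A[g] = s;
    double lgA = lgamma(s);
    std::vector<double>& t = lt[g];
    for (int n = 0; n <= TAB_MAX; ++n) t[n] = lgA - lgamma(s + n);
    for (int c = 0; c < m; ++c) {
      std::vector<double>& u = la[g * m + c];
      double lga = lgamma(alpha[g][c]);
      for (int n = 0; n <= TAB_MAX; ++n) u[n] = lgamma(alpha[g][c] + n) - lga;
    }
  }

  void init(int k_, int m_, const std::vector<std::vector<double> >& alpha) {
    k = k_; m = m_;
    la.assign(k * m, std::vector<double>(TAB_MAX + 1));
    lt.assign(k, std::vector<double>(TAB_MAX + 1));
    A.assign(k, 0.0);
    for (int g = 0; g < k; ++g) build(alpha, g);
  }

  // DM log marginal for class g and counts cnt (length m), with fallback
  // beyond the cached range
  inline double dm(int g, const int* cnt,
                   const std::vector<std::vector<double> >& alpha) const {
    int n = 0;
    for (int c = 0; c < m; ++c) n += cnt[c];
    if (n == 0) return 0.0;
    double v;
    if (n <= TAB_MAX) {
      v = lt[g][n];
      for (int c = 0; c < m; ++c) v += la[g * m + c][cnt[c]];
    } else {
      v = lgamma(A[g]) - lgamma(A[g] + n);
      for (int c = 0; c < m; ++c) {
        if (cnt[c] == 0) continue;
        if (cnt[c] <= TAB_MAX) v += la[g * m + c][cnt[c]];
        else v += lgamma(alpha[g][c] + cnt[c]) - lgamma(alpha[g][c]);
      }
    }
    return v;
  }
};

// label-marginalized log evidence of one segment:
// log sum_g pi_g * DM_g(counts); terms > 34 nats below the max are dropped
// (relative error < 2e-15)
static inline double seg_evidence(const Tables& tab,
                                  const std::vector<std::vector<double> >& alpha,
                                  const std::vector<double>& logpi,
                                  int k, const int* cnt, double* work) {
  double mx = -INFINITY;
  for (int g = 0; g < k; ++g) {
    work[g] = logpi[g] + tab.dm(g, cnt, alpha);
    if (work[g] > mx) mx = work[g];
  }
  double s = 0.0;
  for (int g = 0; g < k; ++g)
    if (work[g] > mx - 34.0) s += exp(work[g] - mx);
  return mx + log(s);
}

static inline double logaddexp(double a, double b) {
  if (a == -INFINITY) return b;
  if (b == -INFINITY) return a;
  double mx = a > b ? a : b;
  return mx + log1p(exp(-fabs(a - b)));
}

static double rgamma_pos(double shape) {
  double g = R::rgamma(shape, 1.0);
  // guard against underflow to 0 for tiny shapes
  if (g <= 0.0) g = 1e-300;
  return g;
}

// [[Rcpp::export(name = ".conseg_mcmc_cpp")]]
List conseg_mcmc_cpp(IntegerVector codes, int m, int k, int n_iter,
                     IntegerVector b_init, NumericVector pi_init,
                     NumericMatrix alpha_init, double rho_init,
                     bool fix_pi, bool fix_alpha, bool fix_rho,
                     double alpha_step_init, int adapt_until) {
  const int N = codes.size();
  if (N < 1) stop("empty code sequence");
  if (k < 1) stop("k must be >= 1");
  const int nb = N - 1;

  RNGScope scope;

  // prefix counts: cum[c*(N+1) + i] = #codes==c in positions 1..i
  std::vector<int> cum((size_t)m * (N + 1), 0);
  for (int c = 0; c < m; ++c) {
    int* row = &cum[(size_t)c * (N + 1)];
    for (int i = 0; i < N; ++i)
      row[i + 1] = row[i] + (codes[i] == c ? 1 : 0);
  }
  // boundary state
  std::vector<char> b(nb > 0 ? nb : 1, 0);
  for (int j = 0; j < nb; ++j) b[j] = (char)(b_init[j] != 0);

  std::vector<std::vector<double> > alpha(k, std::vector<double>(m));
  for (int g = 0; g < k; ++g)
    for (int c = 0; c < m; ++c) alpha[g][c] = alpha_init(g, c);
  std::vector<double> pi(k), logpi(k);
  for (int g = 0; g < k; ++g) { pi[g] = pi_init[g]; logpi[g] = log(pi[g]); }
  double rho = rho_init;

  Tables tab;
  tab.init(k, m, alpha);

  std::vector<double> step((size_t)k * m, alpha_step_init);

  // per-segment storage (rebuilt each iteration)
  std::vector<int> seg_start, seg_end, seg_label;
  std::vector<int> seg_cnt;  // m counts per segment, flattened

  // outputs
  List out_cp(n_iter), out_lab(n_iter);
  NumericVector out_loglik(n_iter), out_rho(n_iter);
  IntegerVector out_ncp(n_iter);
  NumericMatrix out_pi(n_iter, k), out_alpha(n_iter, k * m);
  std::vector<double> acc_cnt((size_t)k * m, 0.0), try_cnt((size_t)k * m, 0.0);

  std::vector<double> work(k);
  std::vector<int> cntL(m), cntR(m), cntM(m);

  for (int iter = 0; iter < n_iter; ++iter) {
    // ---- 1. boundary Gibbs sweep (labels marginalized) ----
    if (nb > 0) {
      double logodds_rho = log(rho) - log1p(-rho);
      int prev = 0;             // start (0-based) of current segment
      int nextb = N;            // next active boundary > j (position index)
      // find first active boundary
      nextb = N;
      for (int j = 1; j <= nb; ++j) if (b[j - 1]) { nextb = j; break; }
      for (int j = 1; j <= nb; ++j) {
        if (nextb <= j) {       // passed it; rescan forward
          nextb = N;
          for (int t = j + 1; t <= nb; ++t) if (b[t - 1]) { nextb = t; break; }
        }
        int rend = nextb;       // right segment is [j, rend)
        for (int c = 0; c < m; ++c) {
          const int* row = &cum[(size_t)c * (N + 1)];
          cntL[c] = row[j] - row[prev];
          cntR[c] = row[rend] - row[j];
          cntM[c] = cntL[c] + cntR[c];
        }
        double lsplit = seg_evidence(tab, alpha, logpi, k, &cntL[0], &work[0])
                      + seg_evidence(tab, alpha, logpi, k, &cntR[0], &work[0])
                      + logodds_rho;
        double lmerge = seg_evidence(tab, alpha, logpi, k, &cntM[0], &work[0]);
        double d = lsplit - lmerge;
        double p1 = (d > 35.0) ? 1.0 : (d < -35.0 ? 0.0 : 1.0 / (1.0 + exp(-d)));
        bool on = unif_rand() < p1;
        b[j - 1] = (char)on;
        if (on) prev = j;
      }
    }

    // ---- rebuild segment list ----
    seg_start.clear(); seg_end.clear();
    seg_start.push_back(0);
    for (int j = 1; j <= nb; ++j)
      if (b[j - 1]) { seg_end.push_back(j); seg_start.push_back(j); }
    seg_end.push_back(N);
    int S = (int)seg_start.size();
    seg_cnt.assign((size_t)S * m, 0);
    for (int s = 0; s < S; ++s)
      for (int c = 0; c < m; ++c) {
        const int* row = &cum[(size_t)c * (N + 1)];
        seg_cnt[(size_t)s * m + c] = row[seg_end[s]] - row[seg_start[s]];
      }

    // ---- 2. Gibbs labels ----
    seg_label.assign(S, 0);
    for (int s = 0; s < S; ++s) {
      const int* cnt = &seg_cnt[(size_t)s * m];
      double mx = -INFINITY;
      for (int g = 0; g < k; ++g) {
        work[g] = logpi[g] + tab.dm(g, cnt, alpha);
        if (work[g] > mx) mx = work[g];
      }
      double tot = 0.0;
      for (int g = 0; g < k; ++g) { work[g] = exp(work[g] - mx); tot += work[g]; }
      double u = unif_rand() * tot, acc = 0.0;
      int pick = k - 1;
      for (int g = 0; g < k; ++g) { acc += work[g]; if (u <= acc) { pick = g; break; } }
      seg_label[s] = pick;
    }

    // ---- 3. pi ----
    if (!fix_pi) {
      std::vector<double> d(k, 1.0);
      for (int s = 0; s < S; ++s) d[seg_label[s]] += 1.0;
      double tot = 0.0;
      for (int g = 0; g < k; ++g) { d[g] = rgamma_pos(d[g]); tot += d[g]; }
      for (int g = 0; g < k; ++g) { pi[g] = d[g] / tot; logpi[g] = log(pi[g]); }
    }

    // ---- 4. rho ----
    if (!fix_rho && nb > 0) {
      int ncp = S - 1;
      rho = R::rbeta(1.0 + ncp, 1.0 + (nb - ncp));
      if (rho <= 0.0) rho = 1e-12;
      if (rho >= 1.0) rho = 1.0 - 1e-12;
    }

    // ---- 5. alpha MH with labels marginalized out (partially
    //         collapsed: alpha is updated against
    //         sum_g pi_g DM_g per segment, so segments re-associate
    //         softly during the move; labels are redrawn from their
    //         full conditional on the next iteration).  Per class:
    //         (i) a moment-anchored independence proposal of the whole
    //         alpha vector, (ii) a joint scale move with a step-size
    //         mixture (local refinement + one-jump returns from the
    //         flat high-concentration region), (iii) two random-walk
    //         sweeps over components. ----
    if (!fix_alpha) {
      bool adapting = iter < adapt_until;
      std::vector<double> lrest(S), lcur(S);
      for (int g = 0; g < k; ++g) {
        bool gdirty = false;
        // log sum_{h != g} pi_h DM_h per segment, and current class-g term
        for (int s = 0; s < S; ++s) {
          const int* cnt = &seg_cnt[(size_t)s * m];
          double mx = -INFINITY;
          for (int h = 0; h < k; ++h) {
            work[h] = logpi[h] + tab.dm(h, cnt, alpha);
            if (h != g && work[h] > mx) mx = work[h];
          }
          if (k == 1) { lrest[s] = -INFINITY; lcur[s] = work[g]; continue; }
          double ssum = 0.0;
          for (int h = 0; h < k; ++h)
            if (h != g && work[h] > mx - 40.0) ssum += exp(work[h] - mx);
          lrest[s] = mx + log(ssum);
          lcur[s] = work[g];
        }
        // marginal log-lik contribution of class g given candidate terms
        // lnew[s] = logpi_g + dm_g_candidate(counts_s)
        // delta = sum_s [ logaddexp(lrest, lnew) - logaddexp(lrest, lcur) ]
        double Acur = 0.0;
        for (int c = 0; c < m; ++c) Acur += alpha[g][c];

        // pooled (smoothed) code proportions of currently-assigned
        // segments: anchor for the independence proposal
        std::vector<double> pooled(m, 0.5);
        double ptot = 0.0;
        for (int s = 0; s < S; ++s) {
          if (seg_label[s] != g) continue;
          const int* cnt = &seg_cnt[(size_t)s * m];
          for (int c = 0; c < m; ++c) pooled[c] += cnt[c];
        }
        for (int c = 0; c < m; ++c) ptot += pooled[c];

        // (i) independence proposal centered at Acur * pooled mean
        {
          const double sd = 0.3;
          std::vector<double> anew(m);
          bool ok = true;
          double lq_fwd = 0.0, lq_rev = 0.0;
          for (int c = 0; c < m; ++c) {
            double muc = log(Acur * pooled[c] / ptot);
            double z = norm_rand();
            anew[c] = exp(muc + sd * z);
            if (anew[c] < ALPHA_LO || anew[c] > ALPHA_HI) { ok = false; break; }
            lq_fwd += -0.5 * z * z;
          }
          if (ok) {
            double Anew = 0.0;
            for (int c = 0; c < m; ++c) Anew += anew[c];
            for (int c = 0; c < m; ++c) {
              double mur = log(Anew * pooled[c] / ptot);
              double zr = (log(alpha[g][c]) - mur) / sd;
              lq_rev += -0.5 * zr * zr;
            }
            double dll = 0.0;
            for (int s = 0; s < S; ++s) {
              const int* cnt = &seg_cnt[(size_t)s * m];
              double lnew = logpi[g] + dm_direct(anew, Anew, cnt, m);
              dll += logaddexp(lrest[s], lnew) - logaddexp(lrest[s], lcur[s]);
            }
            double lr = dll + lq_rev - lq_fwd;
            if (lr >= 0.0 || unif_rand() < exp(lr)) {
              alpha[g] = anew; Acur = Anew; gdirty = true;
              for (int s = 0; s < S; ++s) {
                const int* cnt = &seg_cnt[(size_t)s * m];
                lcur[s] = logpi[g] + dm_direct(alpha[g], Acur, cnt, m);
              }
            }
          }
        }

        // (ii) joint scale move
        {
          double sstep = (unif_rand() < 0.5) ? 0.3 : 3.0;
          double f = exp(sstep * norm_rand());
          bool ok = true;
          for (int c = 0; c < m; ++c) {
            double v = alpha[g][c] * f;
            if (v < ALPHA_LO || v > ALPHA_HI) { ok = false; break; }
          }
          if (ok) {
            std::vector<double> anew(alpha[g]);
            for (int c = 0; c < m; ++c) anew[c] *= f;
            double Anew = Acur * f;
            double dll = 0.0;
            for (int s = 0; s < S; ++s) {
              const int* cnt = &seg_cnt[(size_t)s * m];
              double lnew = logpi[g] + dm_direct(anew, Anew, cnt, m);
              dll += logaddexp(lrest[s], lnew) - logaddexp(lrest[s], lcur[s]);
            }
            if (dll >= 0.0 || unif_rand() < exp(dll)) {
              alpha[g] = anew; Acur = Anew; gdirty = true;
              for (int s = 0; s < S; ++s) {
                const int* cnt = &seg_cnt[(size_t)s * m];
                lcur[s] = logpi[g] + dm_direct(alpha[g], Acur, cnt, m);
              }
            }
          }
        }

        // (iii) component random-walk sweeps
        for (int rep = 0; rep < 2; ++rep) {
          for (int c = 0; c < m; ++c) {
            size_t gc = (size_t)g * m + c;
            try_cnt[gc] += 1.0;
            double cur = alpha[g][c];
            double prop = cur * exp(step[gc] * norm_rand());
            bool ok = (prop >= ALPHA_LO && prop <= ALPHA_HI);
            double accepted = 0.0;
            if (ok) {
              std::vector<double> anew(alpha[g]);
              anew[c] = prop;
              double Anew = Acur - cur + prop;
              double dll = 0.0;
              for (int s = 0; s < S; ++s) {
                const int* cnt = &seg_cnt[(size_t)s * m];
                double lnew = logpi[g] + dm_direct(anew, Anew, cnt, m);
                dll += logaddexp(lrest[s], lnew) - logaddexp(lrest[s], lcur[s]);
              }
              if (dll >= 0.0 || unif_rand() < exp(dll)) {
                alpha[g][c] = prop;
                Acur = Anew;
                accepted = 1.0;
                gdirty = true;
                for (int s = 0; s < S; ++s) {
                  const int* cnt = &seg_cnt[(size_t)s * m];
                  lcur[s] = logpi[g] + dm_direct(alpha[g], Acur, cnt, m);
                }
              }
            }
            acc_cnt[gc] += accepted;
            if (adapting) {
              step[gc] *= exp(0.05 * (accepted - 0.44));
              if (step[gc] < 0.01) step[gc] = 0.01;
              if (step[gc] > 1.5)  step[gc] = 1.5;
            }
          }
        }
        if (gdirty) tab.build(alpha, g);
      }
    }

    // ---- record ----
    double ll = 0.0;
    for (int s = 0; s < S; ++s)
      ll += tab.dm(seg_label[s], &seg_cnt[(size_t)s * m], alpha);
    out_loglik[iter] = ll;
    out_ncp[iter] = S - 1;
    out_rho[iter] = rho;
    for (int g = 0; g < k; ++g) out_pi(iter, g) = pi[g];
    for (int g = 0; g < k; ++g)
      for (int c = 0; c < m; ++c) out_alpha(iter, g * m + c) = alpha[g][c];
    IntegerVector cp(S - 1), lab(S);
    for (int s = 0; s < S - 1; ++s) cp[s] = seg_end[s];        // 1..N-1
    for (int s = 0; s < S; ++s) lab[s] = seg_label[s] + 1;     // 1..k
    out_cp[iter] = cp;
    out_lab[iter] = lab;
  }

  NumericVector acc((size_t)k * m);
  for (size_t i = 0; i < (size_t)k * m; ++i)
    acc[i] = try_cnt[i] > 0 ? acc_cnt[i] / try_cnt[i] : NA_REAL;

  return List::create(
    _["changepoints"] = out_cp,
    _["labels"] = out_lab,
    _["loglik"] = out_loglik,
    _["n_changepoints"] = out_ncp,
    _["rho"] = out_rho,
    _["pi"] = out_pi,
    _["alpha"] = out_alpha,
    _["alpha_acceptance"] = acc);
}

// Accumulate per-position class membership counts over retained samples.
// [[Rcpp::export(name = ".profile_counts_cpp")]]
IntegerMatrix profile_counts_cpp(List cps, List labs, int N, int k) {
  int S = cps.size();
  IntegerMatrix out(N, k);
  for (int s = 0; s < S; ++s) {
    IntegerVector cp = cps[s], lab = labs[s];
    int nseg = lab.size();
    int from = 0;
    for (int i = 0; i < nseg; ++i) {
      int to = (i < nseg - 1) ? cp[i] : N;   // [from, to) 0-based
      int g = lab[i] - 1;
      for (int p = from; p < to; ++p) out(p, g) += 1;
      from = to;
    }
  }
  return out;
}
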