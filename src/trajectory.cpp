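#include <Rcpp.h>
using namespace Rcpp;

// Trial-level belief-update engine, vectorised across subjects.
//
// Model codes: 1 Rescorla-Wagner, 2 dual-rate RW, 3 RW/Pearce-Hall hybrid
// (squared PE), 4 hybrid (absolute PE), 5 leaky beta, 6 asymmetric leaky
// beta, 7 = "6A" (attention-modulated updating), 8 = "6B" (attention value
// bonus), 9 = "6A_bin", 10 = "6B_bin" (binary fixation weighting).
//
// Parameter matrix columns (S x 11):
// 0 alpha, 1 alpha_pos, 2 alpha_neg, 3 omega, 4 k, 5 tau, 6 tau_pos,
// 7 tau_neg, 8 lam, 9 gamma, 10 theta.
//
// Outcomes o1/o2 and fixation proportions f1/f2 are S x T matrices; fixation
// columns hold the *current* trial's outcome-phase proportions, and the
// engine applies the one-trial lag itself (neutral 0.5/0.5 at block starts).
// Belief state is re-initialised at every block boundary.

static const double AB_FLOOR = 1e-6;

inline double clip01(double x) {
  if (x < 0.0) return 0.0;
  if (x > 1.0) return 1.0;
  return x;
}

inline void beta_moments_cpp(double A, double B, double &mu, double &s2) {
  double n = A + B;
  mu = A / n;
  s2 = A * B / (n * n * (n + 1.0));
}

// [[Rcpp::export(name = ".traj_engine_cpp")]]
List traj_engine_cpp(int model, NumericMatrix params,
                     NumericMatrix o1, NumericMatrix o2,
                     IntegerVector block,
                     Nullable<NumericMatrix> f1_, Nullable<NumericMatrix> f2_,
                     bool full) {
  int S = o1.nrow(), T = o1.ncol();
  bool beta_family = model >= 5;
  bool needs_fix = model >= 7;
  NumericMatrix f1, f2;
  if (needs_fix) {
    if (f1_.isNull() || f2_.isNull())
      stop("attention-coupled models require fixation inputs");
    f1 = as<NumericMatrix>(f1_);
    f2 = as<NumericMatrix>(f2_);
  }

  NumericMatrix mu_pre1(S, T), mu_pre2(S, T);
  NumericMatrix mu_post1, mu_post2, sig_pre1, sig_pre2, sig_post1, sig_post2,
      A1o, B1o, A2o, B2o, d1o, d2o, at1o, at2o;
  if (full) {
    mu_post1 = NumericMatrix(S, T); mu_post2 = NumericMatrix(S, T);
    sig_pre1 = NumericMatrix(S, T); sig_pre2 = NumericMatrix(S, T);
    sig_post1 = NumericMatrix(S, T); sig_post2 = NumericMatrix(S, T);
    A1o = NumericMatrix(S, T); B1o = NumericMatrix(S, T);
    A2o = NumericMatrix(S, T); B2o = NumericMatrix(S, T);
    d1o = NumericMatrix(S, T); d2o = NumericMatrix(S, T);
    at1o = NumericMatrix(S, T); at2o = NumericMatrix(S, T);
  }

  std::vector<double> V1(S), V2(S), A1(S), B1(S), A2(S), B2(S),
      at1(S), at2(S), fl1(S), fl2(S);

  for (int t = 0; t < T; ++t) {
    bool reset = (t == 0) || (block[t] != block[t - 1]);
    for (int s = 0; s < S; ++s) {
      if (reset) {
        V1[s] = 0.5; V2[s] = 0.5;
        A1[s] = 1.0; B1[s] = 1.0; A2[s] = 1.0; B2[s] = 1.0;
        at1[s] = clip01(params(s, 0)); at2[s] = at1[s];
        fl1[s] = 0.5; fl2[s] = 0.5;
      }
      double alpha = params(s, 0), ap = params(s, 1), an = params(s, 2),
             om = params(s, 3), k = params(s, 4), tau = params(s, 5),
             tp = params(s, 6), tn = params(s, 7), lam = params(s, 8),
             gam = params(s, 9), th = params(s, 10);
      double ox1 = o1(s, t), ox2 = o2(s, t);

      if (!beta_family) {
        double mp1 = V1[s], mp2 = V2[s];
        double del1 = ox1 - mp1, del2 = ox2 - mp2;
        double nV1, nV2, nat1 = at1[s], nat2 = at2[s];
        if (model == 1) {
          nV1 = clip01(mp1 + alpha * del1 + om * (ox2 - mp1));
          nV2 = clip01(mp2 + alpha * del2 + om * (ox1 - mp2));
        } else if (model == 2) {
          double a1 = del1 > 0 ? ap : an, a2 = del2 > 0 ? ap : an;
          nV1 = clip01(mp1 + a1 * del1 + om * (ox2 - mp1));
          nV2 = clip01(mp2 + a2 * del2 + om * (ox1 - mp2));
        } else { // 3, 4: dynamic learning rate, no cross-stimulus term
          nV1 = clip01(mp1 + at1[s] * del1);
          nV2 = clip01(mp2 + at2[s] * del2);
          double m1 = model == 3 ? del1 * del1 : std::fabs(del1);
          double m2 = model == 3 ? del2 * del2 : std::fabs(del2);
          nat1 = at1[s] + k * (m1 - at1[s]);
          nat2 = at2[s] + k * (m2 - at2[s]);
        }
        mu_pre1(s, t) = mp1; mu_pre2(s, t) = mp2;
        if (full) {
          mu_post1(s, t) = nV1; mu_post2(s, t) = nV2;
          sig_pre1(s, t) = NA_REAL; sig_pre2(s, t) = NA_REAL;
          sig_post1(s, t) = NA_REAL; sig_post2(s, t) = NA_REAL;
          A1o(s, t) = NA_REAL; B1o(s, t) = NA_REAL;
          A2o(s, t) = NA_REAL; B2o(s, t) = NA_REAL;
          d1o(s, t) = del1; d2o(s, t) = del2;
          at1o(s, t) = at1[s]; at2o(s, t) = at2[s];
        }
        V1[s] = nV1; V2[s] = nV2; at1[s] = nat1; at2[s] = nat2;
      } else {
        if (model == 5) { tp = tau; tn = tau; }
        double mp1, sp1, mp2, sp2;
        beta_moments_cpp(A1[s], B1[s], mp1, sp1);
        beta_moments_cpp(A2[s], B2[s], mp2, sp2);
        double del1 = ox1 - mp1, del2 = ox2 - mp2;
        double fx1 = fl1[s], fx2 = fl2[s];
        double nA1, nB1, nA2, nB2;
        if (model == 5 || model == 6) {
          nA1 = (1 - lam) * A1[s] + tp * ox1 + om * ox2;
          nB1 = (1 - lam) * B1[s] + tn * (1 - ox1) + om * (1 - ox2);
          nA2 = (1 - lam) * A2[s] + tp * ox2 + om * ox1;
          nB2 = (1 - lam) * B2[s] + tn * (1 - ox2) + om * (1 - ox1);
        } else if (model == 7 || model == 9) {
          double pi1, pi2;
          if (model == 7) {
            pi1 = fx1 * gam + (1 - gam);
            pi2 = fx2 * gam + (1 - gam);
          } else {
            // binary weighting as printed in the source description: pi = 1
            // when the stimulus wins fixation, else 1 - (fx - fy) * gamma
            // (which exceeds 1 for the losing stimulus; kept as printed).
            pi1 = fx1 > fx2 ? 1.0 : 1.0 - (fx1 - fx2) * gam;
            pi2 = fx2 > fx1 ? 1.0 : 1.0 - (fx2 - fx1) * gam;
          }
          nA1 = (1 - lam) * A1[s] + tp * pi1 * ox1 + om * fx2 * ox2;
          nB1 = (1 - lam) * B1[s] + tn * pi1 * (1 - ox1) + om * fx2 * (1 - ox2);
          nA2 = (1 - lam) * A2[s] + tp * pi2 * ox2 + om * fx1 * ox1;
          nB2 = (1 - lam) * B2[s] + tn * pi2 * (1 - ox2) + om * fx1 * (1 - ox1);
        } else if (model == 8) {
          nA1 = (1 - lam) * A1[s] + tp * ox1 + om * fx2 * ox2 + th * fx1;
          nB1 = (1 - lam) * B1[s] + tn * (1 - ox1) + om * fx2 * (1 - ox2);
          nA2 = (1 - lam) * A2[s] + tp * ox2 + om * fx1 * ox1 + th * fx2;
          nB2 = (1 - lam) * B2[s] + tn * (1 - ox2) + om * fx1 * (1 - ox1);
        } else { // 10: binary value bonus; cross-stimulus term unweighted
          double b1 = fx1 > fx2 ? (fx1 - fx2) * th : 0.0;
          double b2 = fx2 > fx1 ? (fx2 - fx1) * th : 0.0;
          nA1 = (1 - lam) * A1[s] + tp * ox1 + om * ox2 + b1;
          nB1 = (1 - lam) * B1[s] + tn * (1 - ox1) + om * (1 - ox2);
          nA2 = (1 - lam) * A2[s] + tp * ox2 + om * ox1 + b2;
          nB2 = (1 - lam) * B2[s] + tn * (1 - ox2) + om * (1 - ox1);
        }
        nA1 = std::max(nA1, AB_FLOOR); nB1 = std::max(nB1, AB_FLOOR);
        nA2 = std::max(nA2, AB_FLOOR); nB2 = std::max(nB2, AB_FLOOR);
        mu_pre1(s, t) = mp1; mu_pre2(s, t) = mp2;
        if (full) {
          double mq1, sq1, mq2, sq2;
          beta_moments_cpp(nA1, nB1, mq1, sq1);
          beta_moments_cpp(nA2, nB2, mq2, sq2);
          mu_post1(s, t) = mq1; mu_post2(s, t) = mq2;
          sig_pre1(s, t) = sp1; sig_pre2(s, t) = sp2;
          sig_post1(s, t) = sq1; sig_post2(s, t) = sq2;
          A1o(s, t) = nA1; B1o(s, t) = nB1; A2o(s, t) = nA2; B2o(s, t) = nB2;
          d1o(s, t) = del1; d2o(s, t) = del2;
          at1o(s, t) = NA_REAL; at2o(s, t) = NA_REAL;
        }
        A1[s] = nA1; B1[s] = nB1; A2[s] = nA2; B2[s] = nB2;
        if (needs_fix) { fl1[s] = f1(s, t); fl2[s] = f2(s, t); }
      }
    }
  }

  if (!full) return List::create(_["mu_pre1"] = mu_pre1, _["mu_pre2"] = mu_pre2);
  return List::create(
      _["mu_pre1"] = mu_pre1, _["mu_pre2"] = mu_pre2,
      _["mu_post1"] = mu_post1, _["mu_post2"] = mu_post2,
      _["sigma2_pre1"] = sig_pre1, _["sigma2_pre2"] = sig_pre2,
      _["sigma2_post1"] = sig_post1, _["sigma2_post2"] = sig_post2,
      _["A1"] = A1o, _["B1"] = B1o, _["A2"] = A2o, _["B2"] = B2o,
      _["delta1"] = d1o, _["delta2"] = d2o,
      _["alpha_t1"] = at1o, _["alpha_t2"] = at2o);
}
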