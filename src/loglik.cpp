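#include <Rcpp.h>
using namespace Rcpp;

// Softmax log-probability of option `pick` under values q and inverse
// temperature beta, with max-subtraction for stability and a 1e-300 floor
// guarding extreme beta.
static inline double softmax_logprob(const double *q, double beta, int pick) {
  double z[3], zmax;
  for (int j = 0; j < 3; ++j) z[j] = beta * q[j];
  zmax = std::max(z[0], std::max(z[1], z[2]));
  double denom = 0.0;
  for (int j = 0; j < 3; ++j) denom += std::exp(z[j] - zmax);
  double p = std::exp(z[pick] - zmax) / denom;
  if (p < 1e-300) p = 1e-300;
  return std::log(p);
}

// One pass of the observational-learning likelihood.  kind: 0 = full,
// 1 = action_only, 2 = reward_only.  `starts` holds the 0-based indices of
// trials at which the learner state resets (block boundaries).
static void obs_loglik_one(const IntegerVector &pc, const IntegerVector &pr,
                           const IntegerVector &yc, const IntegerVector &starts,
                           double av, double aa, double wa, double beta,
                           int kind, double *out) {
  int n = pc.size();
  std::vector<bool> reset(n, false);
  for (int k = 0; k < starts.size(); ++k) reset[starts[k]] = true;
  double V[3], A[3], Q[3];
  for (int t = 0; t < n; ++t) {
    if (reset[t]) {
      V[0] = V[1] = V[2] = 0.5;
      A[0] = A[1] = A[2] = 1.0 / 3.0;
    }
    int c = pc[t];
    // partner acts first: vicarious reward update then action-tendency update
    V[c] += av * ((double)pr[t] - V[c]);
    for (int j = 0; j < 3; ++j) A[j] += aa * ((j == c ? 1.0 : 0.0) - A[j]);
    if (kind == 0) {
      for (int j = 0; j < 3; ++j) Q[j] = (1.0 - wa) * V[j] + wa * A[j];
      out[t] = softmax_logprob(Q, beta, yc[t]);
    } else if (kind == 1) {
      out[t] = softmax_logprob(A, beta, yc[t]);
    } else {
      out[t] = softmax_logprob(V, beta, yc[t]);
    }
  }
}

// [[Rcpp::export]]
NumericVector obs_loglik_cpp(IntegerVector pc, IntegerVector pr,
                             IntegerVector yc, IntegerVector starts,
                             double alpha_v, double alpha_a, double w_a,
                             double beta, int kind) {
  NumericVector out(pc.size());
  obs_loglik_one(pc, pr, yc, starts, alpha_v, alpha_a, w_a, beta, kind,
                 REAL(out));
  return out;
}

// Pointwise log-likelihood for a batch of parameter draws (rows of
// `params`: alpha_v, alpha_a, w_a, beta on the natural scale).
// Returns draws x trials.
// [[Rcpp::export]]
NumericMatrix obs_loglik_draws_cpp(IntegerVector pc, IntegerVector pr,
                                   IntegerVector yc, IntegerVector starts,
                                   NumericMatrix params, int kind) {
  int d = params.nrow(), n = pc.size();
  NumericMatrix out(d, n);
  std::vector<double> row(n);
  for (int i = 0; i < d; ++i) {
    obs_loglik_one(pc, pr, yc, starts, params(i, 0), params(i, 1),
                   params(i, 2), params(i, 3), kind, row.data());
    for (int t = 0; t < n; ++t) out(i, t) = row[t];
  }
  return out;
}

// Batched per-subject total log-likelihood: trials of all subjects are
// concatenated; `subj_start` (length n_subj + 1) delimits each subject's
// slice, `starts` marks reset indices in the concatenated order, and
// `params` has one row (alpha_v, alpha_a, w_a, beta) per subject.
// [[Rcpp::export]]
NumericVector obs_loglik_batch_cpp(IntegerVector pc, IntegerVector pr,
                                   IntegerVector yc, IntegerVector starts,
                                   IntegerVector subj_start,
                                   NumericMatrix params, int kind) {
  int n_subj = params.nrow();
  int n = pc.size();
  std::vector<bool> reset(n, false);
  for (int k = 0; k < starts.size(); ++k) reset[starts[k]] = true;
  NumericVector out(n_subj);
  for (int i = 0; i < n_subj; ++i) {
    double av = params(i, 0), aa = params(i, 1), wa = params(i, 2),
           beta = params(i, 3);
    double V[3], A[3], Q[3], tot = 0.0;
    for (int t = subj_start[i]; t < subj_start[i + 1]; ++t) {
      if (reset[t]) {
        V[0] = V[1] = V[2] = 0.5;
        A[0] = A[1] = A[2] = 1.0 / 3.0;
      }
      int c = pc[t];
      V[c] += av * ((double)pr[t] - V[c]);
      for (int j = 0; j < 3; ++j) A[j] += aa * ((j == c ? 1.0 : 0.0) - A[j]);
      if (kind == 0) {
        for (int j = 0; j < 3; ++j) Q[j] = (1.0 - wa) * V[j] + wa * A[j];
        tot += softmax_logprob(Q, beta, yc[t]);
      } else if (kind == 1) {
        tot += softmax_logprob(A, beta, yc[t]);
      } else {
        tot += softmax_logprob(V, beta, yc[t]);
      }
    }
    out[i] = tot;
  }
  return out;
}

// Information-bonus Q-learning likelihood of a choice sequence.  Each
// trial the observed choice is scored under the bonus-augmented values
// q + kappa / N (counts start at 1), then the chosen option's value is
// delta-rule updated from the observed reward and its count incremented.
static void info_loglik_one(const IntegerVector &choices,
                            const IntegerVector &rewards,
                            const IntegerVector &starts, double alpha,
                            double beta, double kappa, double *out) {
  int n = choices.size();
  std::vector<bool> reset(n, false);
  for (int k = 0; k < starts.size(); ++k) reset[starts[k]] = true;
  double q[3], cnt[3], val[3];
  for (int t = 0; t < n; ++t) {
    if (reset[t]) {
      q[0] = q[1] = q[2] = 0.5;
      cnt[0] = cnt[1] = cnt[2] = 1.0;
    }
    for (int j = 0; j < 3; ++j) val[j] = q[j] + kappa / cnt[j];
    int c = choices[t];
    out[t] = softmax_logprob(val, beta, c);
    q[c] += alpha * ((double)rewards[t] - q[c]);
    cnt[c] += 1.0;
  }
}

// [[Rcpp::export]]
NumericVector info_loglik_cpp(IntegerVector choices, IntegerVector rewards,
                              IntegerVector starts, double alpha, double beta,
                              double kappa) {
  NumericVector out(choices.size());
  info_loglik_one(choices, rewards, starts, alpha, beta, kappa, REAL(out));
  return out;
}

// Batched per-subject total information-bonus log-likelihood (layout as
// obs_loglik_batch_cpp; params rows: alpha, beta, kappa).
// [[Rcpp::export]]
NumericVector info_loglik_batch_cpp(IntegerVector choices,
                                    IntegerVector rewards,
                                    IntegerVector starts,
                                    IntegerVector subj_start,
                                    NumericMatrix params) {
  int n_subj = params.nrow();
  int n = choices.size();
  std::vector<bool> reset(n, false);
  for (int k = 0; k < starts.size(); ++k) reset[starts[k]] = true;
  NumericVector out(n_subj);
  for (int i = 0; i < n_subj; ++i) {
    double alpha = params(i, 0), beta = params(i, 1), kappa = params(i, 2);
    double q[3], cnt[3], val[3], tot = 0.0;
    for (int t = subj_start[i]; t < subj_start[i + 1]; ++t) {
      if (reset[t]) {
        q[0] = q[1] = q[2] = 0.5;
        cnt[0] = cnt[1] = cnt[2] = 1.0;
      }
      for (int j = 0; j < 3; ++j) val[j] = q[j] + kappa / cnt[j];
      int c = choices[t];
      tot += softmax_logprob(val, beta, c);
      q[c] += alpha * ((double)rewards[t] - q[c]);
      cnt[c] += 1.0;
    }
    out[i] = tot;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix info_loglik_draws_cpp(IntegerVector choices,
                                    IntegerVector rewards,
                                    IntegerVector starts,
                                    NumericMatrix params) {
  int d = params.nrow(), n = choices.size();
  NumericMatrix out(d, n);
  std::vector<double> row(n);
  for (int i = 0; i < d; ++i) {
    info_loglik_one(choices, rewards, starts, params(i, 0), params(i, 1),
                    params(i, 2), row.data());
    for (int t = 0; t < n; ++t) out(i, t) = row[t];
  }
  return out;
}
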