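// Panel-data log-likelihood for a continuous-time multistate Markov model.
//
// The R front end collapses the dataset into weighted "terms": unique
// combinations of (covariate pattern, age-band segmentation, observed state
// pair, exact-death flag).  Each term references one transition-probability
// matrix per age-band segment ("jobs": unique (generator combo, interval
// length) pairs).  This keeps each likelihood evaluation O(#unique terms),
// not O(#subjects), which is what makes desk-scale ML fits fast.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Scaling-and-squaring [6/6] Pade matrix exponential.  Unlike
// arma::expmat it never throws on extreme intensities proposed by the
// optimiser; the generator is scaled below norm 0.5 first.
static arma::mat expm_pade(const arma::mat& A) {
  const int n = A.n_rows;
  const double nrm = arma::norm(A, "inf");
  int j = 0;
  if (nrm > 0.5) j = (int)std::ceil(std::log2(nrm / 0.5));
  arma::mat As = A / std::pow(2.0, j);
  arma::mat X(n, n, arma::fill::eye), N(n, n, arma::fill::eye),
            D(n, n, arma::fill::eye);
  double cf = 1.0, sgn = 1.0;
  for (int k = 1; k <= 6; ++k) {
    cf *= (double)(6 - k + 1) / (k * (12 - k + 1));
    sgn = -sgn;
    X = As * X;
    N += cf * X;
    D += sgn * cf * X;
  }
  arma::mat P = arma::solve(D, N);
  for (int i = 0; i < j; ++i) P = P * P;
  return P;
}

// [[Rcpp::export]]
double panel_loglik_cpp(const arma::vec& theta,
                        const arma::mat& A,           // (G*K) x p design
                        const arma::ivec& from,       // K (1-based states)
                        const arma::ivec& to,
                        const arma::ivec& rate_zero,  // K, 0/1
                        const int n_states,
                        const arma::ivec& job_combo,  // J (1-based combo)
                        const arma::vec& job_dur,     // J
                        const arma::ivec& term_off,   // T (0-based offsets)
                        const arma::ivec& term_nseg,  // T
                        const arma::ivec& term_jobs,  // flattened 1-based jobs
                        const arma::ivec& term_r,     // T (1-based)
                        const arma::ivec& term_s,     // T
                        const arma::vec& term_w,      // T weights
                        const arma::ivec& term_death, // T, 0/1
                        const arma::ivec& term_death_combo) // T (1-based/0)
{
  const int K = from.n_elem;
  const arma::vec q = arma::exp(A * theta);
  if (!q.is_finite())
    return -std::numeric_limits<double>::infinity();
  const int G = q.n_elem / K;

  arma::cube Q(n_states, n_states, G, arma::fill::zeros);
  for (int g = 0; g < G; ++g) {
    for (int k = 0; k < K; ++k) {
      if (rate_zero[k]) continue;
      const double v = q[g * K + k];
      Q(from[k] - 1, to[k] - 1, g) += v;
      Q(from[k] - 1, from[k] - 1, g) -= v;
    }
  }

  const int J = job_combo.n_elem;
  arma::cube P(n_states, n_states, J);
  for (int j = 0; j < J; ++j) {
    arma::mat Pj = expm_pade(Q.slice(job_combo[j] - 1) * job_dur[j]);
    if (!Pj.is_finite())
      return -std::numeric_limits<double>::infinity();
    // clamp round-off (and pathological intensities proposed by the
    // optimiser) so that log P can never become positive
    P.slice(j) = arma::clamp(Pj, 0.0, 1.0);
  }

  const int T = term_r.n_elem;
  double ll = 0.0;
  arma::mat M;
  for (int i = 0; i < T; ++i) {
    const int off = term_off[i], ns = term_nseg[i];
    const arma::mat* MM;
    if (ns == 1) {
      MM = &P.slice(term_jobs[off] - 1);
    } else {
      M = P.slice(term_jobs[off] - 1);
      for (int sg = 1; sg < ns; ++sg) M = M * P.slice(term_jobs[off + sg] - 1);
      MM = &M;
    }
    const int r = term_r[i] - 1, s = term_s[i] - 1;
    double contrib;
    if (term_death[i]) {
      // exactly observed absorption: sum_s' P_{r,s'}(t-) q_{s',s}
      const int gc = term_death_combo[i] - 1;
      contrib = 0.0;
      for (int k = 0; k < K; ++k)
        if (to[k] - 1 == s && !rate_zero[k])
          contrib += (*MM)(r, from[k] - 1) * q[gc * K + k];
    } else {
      contrib = (*MM)(r, s);
    }
    if (!(contrib > 0.0))
      return -std::numeric_limits<double>::infinity();
    ll += term_w[i] * std::log(contrib);
  }
  return ll;
}
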