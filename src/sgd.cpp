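#include <Rcpp.h>
using namespace Rcpp;

// Biased matrix-factorization SGD.
//
// Per rating r (dataset d, configuration a), with e = r - (mu + ba + bd +
// q_a . p_d), the update rules are
//   ba <- ba + gamma * (e - lambda * ba)
//   bd <- bd + gamma * (e - lambda * bd)
//   q_a <- q_a + gamma * (e * p_d - lambda * q_a)
//   p_d <- p_d + gamma * (e * q_a - lambda * p_d)
// with q_a/p_d updated simultaneously (both right-hand sides use the
// pre-update vectors). `perm` holds one seeded shuffle of 1..n per epoch so
// training order is reproducible from R's RNG. Returns updated parameters
// plus the regularized training loss evaluated after every epoch:
//   L = sum_r [ e^2 + lambda * (ba^2 + bd^2 + ||q_a||^2 + ||p_d||^2) ].

// [[Rcpp::export]]
List sgd_train_cpp(NumericVector b_d, NumericVector b_a,
                   NumericMatrix p, NumericMatrix q,
                   IntegerVector d_idx, IntegerVector a_idx,
                   NumericVector r, double mu, double gamma, double lambda,
                   IntegerMatrix perm) {
  NumericVector bd = clone(b_d);
  NumericVector ba = clone(b_a);
  NumericMatrix P = clone(p);
  NumericMatrix Q = clone(q);
  const int n = r.size();
  const int k = P.ncol();
  const int epochs = perm.nrow();
  NumericVector loss(epochs);
  std::vector<double> qa_old(k);

  for (int e = 0; e < epochs; ++e) {
    for (int t = 0; t < n; ++t) {
      const int i = perm(e, t) - 1;
      const int d = d_idx[i] - 1;
      const int a = a_idx[i] - 1;
      double pred = mu + ba[a] + bd[d];
      for (int f = 0; f < k; ++f) pred += Q(a, f) * P(d, f);
      const double err = r[i] - pred;
      ba[a] += gamma * (err - lambda * ba[a]);
      bd[d] += gamma * (err - lambda * bd[d]);
      for (int f = 0; f < k; ++f) qa_old[f] = Q(a, f);
      for (int f = 0; f < k; ++f) {
        const double pd = P(d, f);
        Q(a, f) += gamma * (err * pd - lambda * qa_old[f]);
        P(d, f) += gamma * (err * qa_old[f] - lambda * pd);
      }
    }
    double L = 0.0;
    for (int i = 0; i < n; ++i) {
      const int d = d_idx[i] - 1;
      const int a = a_idx[i] - 1;
      double pred = mu + ba[a] + bd[d];
      double reg = ba[a] * ba[a] + bd[d] * bd[d];
      for (int f = 0; f < k; ++f) {
        pred += Q(a, f) * P(d, f);
        reg += Q(a, f) * Q(a, f) + P(d, f) * P(d, f);
      }
      const double err = r[i] - pred;
      L += err * err + lambda * reg;
    }
    loss[e] = L;
  }
  return List::create(_["b_d"] = bd, _["b_a"] = ba, _["p"] = P, _["q"] = Q,
                      _["loss"] = loss);
}
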