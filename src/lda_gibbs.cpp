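#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for latent Dirichlet allocation.
// docs: list of integer vectors of 0-based word ids; V: vocabulary size;
// N: topics; iters: full sweeps over all tokens. Uses R's RNG, so results
// are reproducible under set.seed() in the calling R code.
// [[Rcpp::export]]
List lda_gibbs_train(List docs, int V, int N, double alpha, double beta,
                     int iters) {
  RNGScope scope;
  int D = docs.size();
  IntegerMatrix nwt(N, V);   // topic x word counts
  IntegerMatrix ndt(D, N);   // document x topic counts
  IntegerVector nt(N);       // tokens per topic
  std::vector< std::vector<int> > w(D), z(D);

  for (int d = 0; d < D; ++d) {
    IntegerVector wd = docs[d];
    int L = wd.size();
    w[d].assign(wd.begin(), wd.end());
    z[d].resize(L);
    for (int i = 0; i < L; ++i) {
      int t = (int)(unif_rand() * N);
      if (t >= N) t = N - 1;
      z[d][i] = t;
      nwt(t, w[d][i])++;
      ndt(d, t)++;
      nt[t]++;
    }
  }

  std::vector<double> p(N);
  double Vb = V * beta;
  for (int it = 0; it < iters; ++it) {
    for (int d = 0; d < D; ++d) {
      int L = w[d].size();
      for (int i = 0; i < L; ++i) {
        int wi = w[d][i], zi = z[d][i];
        nwt(zi, wi)--; ndt(d, zi)--; nt[zi]--;
        double tot = 0.0;
        for (int t = 0; t < N; ++t) {
          p[t] = (nwt(t, wi) + beta) / (nt[t] + Vb) * (ndt(d, t) + alpha);
          tot += p[t];
        }
        double u = unif_rand() * tot;
        int t = 0;
        double c = p[0];
        while (u > c && t < N - 1) c += p[++t];
        z[d][i] = t;
        nwt(t, wi)++; ndt(d, t)++; nt[t]++;
      }
    }
  }
  return List::create(_["nwt"] = nwt, _["ndt"] = ndt, _["nt"] = nt);
}

// Gibbs inference for a new document with the topic-word distribution
// (phi, N x V) frozen. Returns theta averaged over `samples` states taken
// every `thin` sweeps after `burnin` sweeps.
// [[Rcpp::export]]
NumericVector lda_infer_theta(IntegerVector wdoc, NumericMatrix phi,
                              double alpha, int burnin, int samples,
                              int thin) {
  RNGScope scope;
  int N = phi.nrow();
  int L = wdoc.size();
  std::vector<int> z(L);
  std::vector<int> cnt(N, 0);
  std::vector<double> p(N);
  NumericVector theta(N);

  for (int i = 0; i < L; ++i) {
    int t = (int)(unif_rand() * N);
    if (t >= N) t = N - 1;
    z[i] = t;
    cnt[t]++;
  }
  int kept = 0;
  int total = burnin + samples * thin;
  for (int it = 0; it < total; ++it) {
    for (int i = 0; i < L; ++i) {
      int wi = wdoc[i], zi = z[i];
      cnt[zi]--;
      double tot = 0.0;
      for (int t = 0; t < N; ++t) {
        p[t] = phi(t, wi) * (cnt[t] + alpha);
        tot += p[t];
      }
      double u = unif_rand() * tot;
      int t = 0;
      double c = p[0];
      while (u > c && t < N - 1) c += p[++t];
      z[i] = t;
      cnt[t]++;
    }
    if (it >= burnin && ((it - burnin) % thin) == 0) {
      for (int t = 0; t < N; ++t) theta[t] += (cnt[t] + alpha) / (L + N * alpha);
      kept++;
    }
  }
  for (int t = 0; t < N; ++t) theta[t] /= kept;
  return theta;
}
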