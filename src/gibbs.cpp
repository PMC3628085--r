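#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler over per-read source assignments for one sink
// sample. Sources are rows of `m` (training counts, S x T); an implicit
// "unknown" source has no training counts and its own per-taxon
// pseudocount. Conditional for read i of taxon t:
//   P(z_i = s) ~ (m[s,t] + n^{-i}[s,t] + alpha_s) /
//                (m[s,.] + n^{-i}[s,.] + T * alpha_s) * (n^{-i}[s] + beta)
// with m = 0 and alpha = alpha_unknown for the unknown source.
// Uses R's RNG so set.seed() in R controls the chain.
// [[Rcpp::export]]
List gibbs_sources_cpp(IntegerVector sink, NumericMatrix m,
                       NumericVector alpha, double beta,
                       int n_draws, int burn_in) {
  const int S = m.nrow();          // known sources
  const int K = S + 1;             // + unknown
  const int T = m.ncol();
  if (alpha.size() != K) stop("alpha must have length S + 1");

  // expand sink counts into reads
  std::vector<int> read_taxon;
  for (int t = 0; t < T; ++t)
    for (int c = 0; c < sink[t]; ++c) read_taxon.push_back(t);
  const int N = (int)read_taxon.size();
  if (N == 0) stop("sink sample is empty");

  std::vector<double> m_tot(S, 0.0);
  for (int s = 0; s < S; ++s)
    for (int t = 0; t < T; ++t) m_tot[s] += m(s, t);

  // current assignment counts
  std::vector<int> z(N);
  std::vector< std::vector<int> > n_st(K, std::vector<int>(T, 0));
  std::vector<int> n_s(K, 0);
  for (int i = 0; i < N; ++i) {
    int s = (int)(unif_rand() * K);
    if (s >= K) s = K - 1;
    z[i] = s;
    n_st[s][read_taxon[i]]++;
    n_s[s]++;
  }

  std::vector<double> prob(K), acc(K, 0.0), acc2(K, 0.0);
  int kept = 0;
  for (int it = 0; it < burn_in + n_draws; ++it) {
    for (int i = 0; i < N; ++i) {
      const int t = read_taxon[i];
      const int old = z[i];
      n_st[old][t]--; n_s[old]--;
      double tot = 0.0;
      for (int s = 0; s < S; ++s) {
        double p = (m(s, t) + n_st[s][t] + alpha[s]) /
                   (m_tot[s] + n_s[s] + T * alpha[s]) * (n_s[s] + beta);
        prob[s] = p; tot += p;
      }
      {
        double p = (n_st[S][t] + alpha[S]) /
                   ((double)n_s[S] + T * alpha[S]) * (n_s[S] + beta);
        prob[S] = p; tot += p;
      }
      double u = unif_rand() * tot;
      int s_new = 0;
      double cum = 0.0;
      for (; s_new < K; ++s_new) {
        cum += prob[s_new];
        if (u <= cum) break;
      }
      if (s_new >= K) s_new = K - 1;
      z[i] = s_new;
      n_st[s_new][t]++; n_s[s_new]++;
    }
    if (it >= burn_in) {
      for (int s = 0; s < K; ++s) {
        double p = (double)n_s[s] / N;
        acc[s] += p; acc2[s] += p * p;
      }
      kept++;
    }
  }

  NumericVector mean_p(K), sd_p(K);
  for (int s = 0; s < K; ++s) {
    mean_p[s] = acc[s] / kept;
    double v = acc2[s] / kept - mean_p[s] * mean_p[s];
    sd_p[s] = v > 0 ? std::sqrt(v) : 0.0;
  }
  return List::create(_["mean"] = mean_p, _["sd"] = sd_p,
                      _["n_reads"] = N, _["kept"] = kept);
}
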