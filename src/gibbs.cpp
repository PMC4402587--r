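#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Collapsed Gibbs sampler for LDA on a flattened token stream.
//
// doc, word: 0-based token-level document and vocabulary indices.
// Count tables are kept topic-major (T x D, T x W) so the inner loop over
// topics walks contiguous memory, and as doubles with the Dirichlet prior
// baked in (ndj holds alpha + n, njw holds beta + n): the sampling kernel
// then needs no int-to-double conversion or prior addition per topic. The
// +-1 updates stay exact at these magnitudes; integer tables are recovered
// by rounding on return. Randomness goes through R's RNG (unif_rand) so a
// set.seed() call on the R side makes the whole chain reproducible.
//
// The kernel drops the (T*alpha + n_d,-i,*) factor of the full conditional
// because it does not depend on the candidate topic.
// [[Rcpp::export]]
List gibbs_lda_cpp(IntegerVector doc, IntegerVector word,
                   int n_docs, int n_words, int n_topics,
                   double alpha, double beta,
                   int sweeps, int burn_in,
                   bool save_samples, bool track_logjoint) {
  const int N = doc.size();
  const int D = n_docs, W = n_words, T = n_topics;
  const double Wbeta = W * beta;

  std::vector<int> z(N), nd(D, 0);
  std::vector<double> ndj((size_t)T * D, alpha), njw((size_t)T * W, beta),
      nj(T, 0.0), invden(T), p(T);

  RNGScope scope;

  for (int i = 0; i < N; ++i) {
    int t = (int)(unif_rand() * T);
    if (t >= T) t = T - 1;
    z[i] = t;
    ndj[(size_t)T * doc[i] + t] += 1.0;
    njw[(size_t)T * word[i] + t] += 1.0;
    nj[t] += 1.0;
    nd[doc[i]]++;
  }
  for (int j = 0; j < T; ++j) invden[j] = 1.0 / (Wbeta + nj[j]);

  int n_save = save_samples ? (sweeps - burn_in) : 0;
  IntegerMatrix zsamp(n_save > 0 ? n_save : 1, n_save > 0 ? N : 1);
  NumericVector logjoint(track_logjoint ? sweeps : 0);

  for (int s = 0; s < sweeps; ++s) {
    for (int i = 0; i < N; ++i) {
      const int d = doc[i], w = word[i];
      const int t = z[i];
      double *__restrict ndj_d = &ndj[(size_t)T * d];
      double *__restrict njw_w = &njw[(size_t)T * w];
      ndj_d[t] -= 1.0; njw_w[t] -= 1.0; nj[t] -= 1.0;
      invden[t] = 1.0 / (Wbeta + nj[t]);
      double tot = 0.0;
      for (int j = 0; j < T; ++j) {
        tot += njw_w[j] * ndj_d[j] * invden[j];
        p[j] = tot;
      }
      const double u = unif_rand() * tot;
      int tn = 0;
      while (tn < T - 1 && p[tn] < u) ++tn;
      z[i] = tn;
      ndj_d[tn] += 1.0; njw_w[tn] += 1.0; nj[tn] += 1.0;
      invden[tn] = 1.0 / (Wbeta + nj[tn]);
    }
    if (save_samples && s >= burn_in) {
      for (int i = 0; i < N; ++i) zsamp(s - burn_in, i) = z[i];
    }
    if (track_logjoint) {
      // log P(z, w) with theta, phi integrated out (symmetric priors);
      // tables already hold prior + count
      double lj = 0.0;
      lj += D * (R::lgammafn(T * alpha) - T * R::lgammafn(alpha));
      lj += T * (R::lgammafn(Wbeta) - W * R::lgammafn(beta));
      for (int d = 0; d < D; ++d) {
        const double *row = &ndj[(size_t)T * d];
        for (int j = 0; j < T; ++j) lj += R::lgammafn(row[j]);
        lj -= R::lgammafn(T * alpha + nd[d]);
      }
      for (int j = 0; j < T; ++j) lj -= R::lgammafn(Wbeta + nj[j]);
      for (int w = 0; w < W; ++w) {
        const double *col = &njw[(size_t)T * w];
        for (int j = 0; j < T; ++j) lj += R::lgammafn(col[j]);
      }
      logjoint[s] = lj;
    }
    if (s % 64 == 0) Rcpp::checkUserInterrupt();
  }

  IntegerMatrix ndj_out(D, T), njw_out(T, W);
  IntegerVector nj_out(T);
  for (int d = 0; d < D; ++d)
    for (int j = 0; j < T; ++j)
      ndj_out(d, j) = (int)std::lround(ndj[(size_t)T * d + j] - alpha);
  for (int w = 0; w < W; ++w)
    for (int j = 0; j < T; ++j)
      njw_out(j, w) = (int)std::lround(njw[(size_t)T * w + j] - beta);
  for (int j = 0; j < T; ++j) nj_out[j] = (int)std::lround(nj[j]);

  List out = List::create(
      _["z"] = IntegerVector(z.begin(), z.end()),
      _["ndj"] = ndj_out,
      _["njw"] = njw_out,
      _["nj"] = nj_out,
      _["nd"] = IntegerVector(nd.begin(), nd.end()));
  if (save_samples) out["z_samples"] = zsamp;
  if (track_logjoint) out["logjoint"] = logjoint;
  return out;
}
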