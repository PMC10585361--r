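#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for the Dirichlet-multinomial mixture (GSDMM).
// Documents are passed as parallel lists of 0-based term-id vectors and
// count vectors. State counts are kept in doubles (values stay integral).
//
// Per-document conditional, evaluated in log space:
//   p(z_d = k | rest) proportional to
//     (m_k^{-d} + alpha)
//     * prod_{w in d} prod_{j=1..c_dw} (n_kw^{-d} + beta + j - 1)
//     / prod_{i=1..N_d} (n_k^{-d} + V beta + i - 1)
//
// After `iterations` sweeps, `record_sweeps` additional sweeps are run and
// the assignment configuration after each is encoded as sum_d z_d * K^d
// (caller must ensure K^D fits in an int). Used by exactness checks.
//
// When check_invariants is true the three count identities
// (sum_k m_k = D, sum_w n_kw = n_k, sum_k n_k = total tokens) are verified
// after every sweep; violations are counted, not silently ignored.

// [[Rcpp::export]]
List gsdmm_gibbs_cpp(List doc_ids, List doc_cnts, int V, int K,
                     double alpha, double beta, int iterations,
                     IntegerVector z_init, bool check_invariants,
                     int record_sweeps) {
  const int D = doc_ids.size();
  std::vector<std::vector<int>> ids(D), cnts(D);
  std::vector<int> ndoc(D);
  double total_tokens = 0.0;
  for (int d = 0; d < D; ++d) {
    IntegerVector iv = doc_ids[d];
    IntegerVector cv = doc_cnts[d];
    ids[d].assign(iv.begin(), iv.end());
    cnts[d].assign(cv.begin(), cv.end());
    int nd = 0;
    for (size_t t = 0; t < cnts[d].size(); ++t) nd += cnts[d][t];
    ndoc[d] = nd;
    total_tokens += nd;
  }

  std::vector<int> z(z_init.begin(), z_init.end());
  std::vector<double> m(K, 0.0), n_k(K, 0.0);
  std::vector<double> n_kw((size_t)K * V, 0.0);

  for (int d = 0; d < D; ++d) {
    int k = z[d];
    m[k] += 1.0;
    n_k[k] += ndoc[d];
    for (size_t t = 0; t < ids[d].size(); ++t)
      n_kw[(size_t)k * V + ids[d][t]] += cnts[d][t];
  }

  const double vbeta = V * beta;
  std::vector<double> logp(K), prob(K);
  int violations = 0;
  IntegerVector codes(record_sweeps);

  RNGScope scope;

  int total_sweeps = iterations + record_sweeps;
  for (int sweep = 0; sweep < total_sweeps; ++sweep) {
    for (int d = 0; d < D; ++d) {
      int kold = z[d];
      m[kold] -= 1.0;
      n_k[kold] -= ndoc[d];
      for (size_t t = 0; t < ids[d].size(); ++t)
        n_kw[(size_t)kold * V + ids[d][t]] -= cnts[d][t];

      double maxlp = R_NegInf;
      for (int k = 0; k < K; ++k) {
        double lp = std::log(m[k] + alpha);
        double *row = &n_kw[(size_t)k * V];
        for (size_t t = 0; t < ids[d].size(); ++t) {
          double base = row[ids[d][t]] + beta;
          for (int j = 0; j < cnts[d][t]; ++j) lp += std::log(base + j);
        }
        double denb = n_k[k] + vbeta;
        for (int i = 0; i < ndoc[d]; ++i) lp -= std::log(denb + i);
        logp[k] = lp;
        if (lp > maxlp) maxlp = lp;
      }
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        prob[k] = std::exp(logp[k] - maxlp);
        tot += prob[k];
      }
      double u = R::unif_rand() * tot;
      int knew = 0;
      double acc = 0.0;
      for (int k = 0; k < K; ++k) {
        acc += prob[k];
        if (u <= acc) { knew = k; break; }
        if (k == K - 1) knew = k;
      }

      z[d] = knew;
      m[knew] += 1.0;
      n_k[knew] += ndoc[d];
      for (size_t t = 0; t < ids[d].size(); ++t)
        n_kw[(size_t)knew * V + ids[d][t]] += cnts[d][t];
    }

    if (check_invariants) {
      double sm = 0.0, sk = 0.0;
      bool bad = false;
      for (int k = 0; k < K; ++k) {
        sm += m[k];
        sk += n_k[k];
        double rw = 0.0;
        for (int w = 0; w < V; ++w) rw += n_kw[(size_t)k * V + w];
        if (rw != n_k[k]) bad = true;
      }
      if (sm != (double)D || sk != total_tokens) bad = true;
      if (bad) ++violations;
    }

    if (sweep >= iterations) {
      long code = 0, mult = 1;
      for (int d = 0; d < D; ++d) {
        code += z[d] * mult;
        mult *= K;
      }
      codes[sweep - iterations] = (int)code;
    }
  }

  NumericMatrix nkw_out(K, V);
  for (int k = 0; k < K; ++k)
    for (int w = 0; w < V; ++w)
      nkw_out(k, w) = n_kw[(size_t)k * V + w];

  return List::create(_["z"] = IntegerVector(z.begin(), z.end()),
                      _["m"] = NumericVector(m.begin(), m.end()),
                      _["n_k"] = NumericVector(n_k.begin(), n_k.end()),
                      _["n_kw"] = nkw_out,
                      _["codes"] = codes,
                      _["invariant_violations"] = violations);
}
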