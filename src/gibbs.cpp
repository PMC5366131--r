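#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for Bayesian source tracking.
//
// Each sink read carries a latent source assignment among K known sources
// plus an "unknown" source. Known-source emission terms are fixed by the
// source count tables (collapsing their Dirichlet posterior); the unknown
// source's emission distribution is collapsed over the reads currently
// assigned to it. Full conditional for a read of taxon t:
//   known k:  p ∝ (c_kt + a1) / (C_k + a1*T) * (n_k^- + beta)
//   unknown:  p ∝ (u_t^- + a2) / (U^- + a2*T) * (n_unk^- + beta)
// Uses R's RNG, so results are reproducible under set.seed().

// [[Rcpp::export]]
List gibbs_st_cpp(IntegerVector read_taxon,   // 0-based taxon of each sink read
                  NumericMatrix src_counts,   // K x T source count table
                  double alpha1, double alpha2, double beta,
                  int burnin, int n_draws, int spacing, int restarts) {
  const int N = read_taxon.size();
  const int K = src_counts.nrow();
  const int T = src_counts.ncol();
  const int S = K + 1;                        // + unknown

  // fixed emission term for known sources
  NumericMatrix src_term(K, T);
  for (int k = 0; k < K; ++k) {
    double Ck = 0.0;
    for (int t = 0; t < T; ++t) Ck += src_counts(k, t);
    for (int t = 0; t < T; ++t)
      src_term(k, t) = (src_counts(k, t) + alpha1) / (Ck + alpha1 * T);
  }

  NumericVector pi_mean(S);
  int total_sweeps = burnin + n_draws * spacing;
  NumericMatrix trace(restarts * n_draws, S);
  std::vector<int> z(N);
  std::vector<double> n_src(S);
  std::vector<double> u_taxon(T);
  std::vector<double> probs(S);

  RNGScope scope;
  int trace_row = 0;
  for (int r = 0; r < restarts; ++r) {
    std::fill(n_src.begin(), n_src.end(), 0.0);
    std::fill(u_taxon.begin(), u_taxon.end(), 0.0);
    // random initial assignment
    for (int i = 0; i < N; ++i) {
      int zi = (int)std::floor(unif_rand() * S);
      if (zi == S) zi = S - 1;
      z[i] = zi;
      n_src[zi] += 1.0;
      if (zi == K) u_taxon[read_taxon[i]] += 1.0;
    }
    double U = n_src[K];
    NumericVector pi_restart(S);
    int kept = 0;
    for (int sweep = 0; sweep < total_sweeps; ++sweep) {
      for (int i = 0; i < N; ++i) {
        int t = read_taxon[i];
        int zi = z[i];
        n_src[zi] -= 1.0;
        if (zi == K) { u_taxon[t] -= 1.0; U -= 1.0; }
        double tot = 0.0;
        for (int k = 0; k < K; ++k) {
          probs[k] = src_term(k, t) * (n_src[k] + beta);
          tot += probs[k];
        }
        probs[K] = (u_taxon[t] + alpha2) / (U + alpha2 * T) * (n_src[K] + beta);
        tot += probs[K];
        double u = unif_rand() * tot;
        int knew = 0;
        double acc = probs[0];
        while (u > acc && knew < S - 1) { ++knew; acc += probs[knew]; }
        z[i] = knew;
        n_src[knew] += 1.0;
        if (knew == K) { u_taxon[t] += 1.0; U += 1.0; }
      }
      if (sweep >= burnin && ((sweep - burnin + 1) % spacing == 0)) {
        for (int s = 0; s < S; ++s) {
          double frac = n_src[s] / N;
          pi_restart[s] += frac;
          trace(trace_row, s) = frac;
        }
        ++trace_row;
        ++kept;
      }
    }
    for (int s = 0; s < S; ++s) pi_mean[s] += pi_restart[s] / kept;
  }
  for (int s = 0; s < S; ++s) pi_mean[s] /= restarts;
  return List::create(_["pi"] = pi_mean, _["trace"] = trace);
}
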