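// Wright-Fisher inner loop: per generation, Poisson-distributed point
// mutations, genic (no-dominance) selection with multiplicative fitness
// across codon sites, and multinomial resampling of the 2N gene copies.
// Gene copies are stored column-contiguous so offspring copying is a
// memcpy; fitness is maintained incrementally (recomputed only for mutated
// copies, inherited through resampling). Uses R's RNG so runs are
// reproducible under set.seed().

#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// pop:     K x L matrix of 1-based codon indices (K = 2N gene copies)
// sitefit: L x 64 fitness factor per (site, codon); 0 = lethal (stop)
// muttab:  64 x 9 result codon of mutating codon c at slot s
//          (slot = 3*basepos + altbase)
// anc:     ancestry labels carried along for the coalescence check
// stop_mode: 0 = run all gens; 1 = stop when ancestry labels coalesce
// [[Rcpp::export(name = ".cpp_wf_run")]]
List cpp_wf_run(IntegerMatrix pop, NumericMatrix sitefit,
                IntegerMatrix muttab, double mu, int gens,
                IntegerVector anc, int stop_mode) {
  const int K = pop.nrow(), L = pop.ncol();
  // transpose: copy c occupies cur[c*L .. c*L+L-1]
  std::vector<int> cur((size_t)K * L), nxt((size_t)K * L);
  for (int i = 0; i < K; i++)
    for (int s = 0; s < L; s++)
      cur[(size_t)i * L + s] = pop(i, s);
  std::vector<int> canc(anc.begin(), anc.end()), nanc(K);
  std::vector<double> w(K), wn(K), cw(K);

  const double* fit = REAL(sitefit);  // L x 64 column-major
  auto copy_fitness = [&](const int* g) {
    double f = 1.0;
    for (int s = 0; s < L; s++) f *= fit[(size_t)(g[s] - 1) * L + s];
    return f;
  };
  for (int i = 0; i < K; i++) w[i] = copy_fitness(&cur[(size_t)i * L]);

  const double lambda = (double)K * L * 3.0 * mu;
  int g = 0;
  bool coalesced = false;
  for (g = 0; g < gens; g++) {
    // mutation
    int nm = (int)R::rpois(lambda);
    for (int m = 0; m < nm; m++) {
      int i = (int)(unif_rand() * K); if (i >= K) i = K - 1;
      int s = (int)(unif_rand() * L); if (s >= L) s = L - 1;
      int slot = (int)(unif_rand() * 9); if (slot >= 9) slot = 8;
      int* gi = &cur[(size_t)i * L];
      int nc = muttab(gi[s] - 1, slot);
      if (nc != gi[s]) {
        gi[s] = nc;
        w[i] = copy_fitness(gi);
      }
    }
    // selection + resampling
    double tot = 0.0;
    for (int i = 0; i < K; i++) { tot += w[i]; cw[i] = tot; }
    if (tot <= 0.0) stop("all gene copies have fitness 0");
    for (int i = 0; i < K; i++) {
      double u = unif_rand() * tot;
      int lo = 0, hi = K - 1;
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (cw[mid] < u) lo = mid + 1; else hi = mid;
      }
      std::memcpy(&nxt[(size_t)i * L], &cur[(size_t)lo * L],
                  sizeof(int) * L);
      wn[i] = w[lo];
      nanc[i] = canc[lo];
    }
    cur.swap(nxt);
    w.swap(wn);
    canc.swap(nanc);
    if (stop_mode == 1) {
      bool all_eq = true;
      for (int i = 1; i < K; i++)
        if (canc[i] != canc[0]) { all_eq = false; break; }
      if (all_eq) { coalesced = true; g++; break; }
    }
  }
  IntegerMatrix out(K, L);
  for (int i = 0; i < K; i++)
    for (int s = 0; s < L; s++)
      out(i, s) = cur[(size_t)i * L + s];
  return List::create(_["pop"] = out,
                      _["anc"] = IntegerVector(canc.begin(), canc.end()),
                      _["generations"] = g, _["coalesced"] = coalesced);
}
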