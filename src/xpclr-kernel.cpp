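#include <Rcpp.h>
using namespace Rcpp;

// Component likelihood E_q[ Binom(k | m, q) ] for q ~ Normal(mean, sd^2)
// truncated to (0,1) with the tail mass placed as atoms at 0 and 1.
// `bin_grid` is the precomputed dbinom(k_j, m_j, q_g) matrix (grid x sites)
// shared across components of the same window; the quadrature is the
// midpoint rule on the uniform grid. Components with sd below `sd_collapse`
// are evaluated as a point mass at the mean.
// [[Rcpp::export(name = ".component_lik_cpp")]]
NumericVector component_lik_cpp(NumericVector mean, NumericVector sd,
                                IntegerVector k, IntegerVector m,
                                NumericVector q_grid,
                                NumericMatrix bin_grid,
                                double sd_collapse) {
  const int n = mean.size();
  const int ng = q_grid.size();
  NumericVector out(n);
  const double inv_ng = 1.0 / ng;
  for (int j = 0; j < n; ++j) {
    const double mu = mean[j];
    const double s = sd[j];
    if (s < sd_collapse) {
      double p = mu < 0.0 ? 0.0 : (mu > 1.0 ? 1.0 : mu);
      out[j] = R::dbinom(k[j], m[j], p, 0);
      continue;
    }
    const double inv_s = 1.0 / s;
    const double norm = M_1_SQRT_2PI * inv_s;
    double acc = 0.0;
    for (int g = 0; g < ng; ++g) {
      const double z = (q_grid[g] - mu) * inv_s;
      acc += norm * std::exp(-0.5 * z * z) * bin_grid(g, j);
    }
    double lik = acc * inv_ng;
    if (k[j] == 0) lik += R::pnorm(0.0, mu, s, 1, 0);
    if (k[j] == m[j]) lik += R::pnorm(1.0, mu, s, 0, 0);
    out[j] = lik;
  }
  return out;
}

// One gamete per entry of `parents`: meiosis with Poisson(rrate*len)
// crossovers at uniform positions, random starting haplotype. Uses R's RNG
// (so results are reproducible under set.seed). `h` rows are haplotypes,
// diploid i owns rows 2i-1, 2i (1-based).
// [[Rcpp::export(name = ".make_gametes_cpp")]]
IntegerMatrix make_gametes_cpp(IntegerMatrix h, NumericVector pos,
                               double len, double rrate,
                               IntegerVector parents) {
  const int n = parents.size();
  const int S = pos.size();
  IntegerMatrix out(n, S);
  std::vector<double> bp;
  for (int i = 0; i < n; ++i) {
    const int rowA = 2 * parents[i] - 2;   // 0-based row of first haplotype
    int ncx = (int) R::rpois(rrate * len);
    const int coin = (unif_rand() < 0.5) ? 0 : 1;
    if (ncx == 0 || S == 0) {
      for (int s = 0; s < S; ++s) out(i, s) = h(rowA + coin, s);
      continue;
    }
    bp.resize(ncx);
    for (int b = 0; b < ncx; ++b) bp[b] = unif_rand() * len;
    std::sort(bp.begin(), bp.end());
    for (int s = 0; s < S; ++s) {
      int cnt = (int)(std::upper_bound(bp.begin(), bp.end(), pos[s]) -
                      bp.begin());
      out(i, s) = h(rowA + ((cnt + coin) & 1), s);
    }
  }
  return out;
}
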