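#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for a STRUCTURE-like admixture model with dominant
// (recessive-null) biallelic markers. Each individual i has admixture
// proportions q_i (K-vector, Dirichlet(alpha) prior); each cluster k has a
// band-allele frequency p_kl per locus (Beta(1,1) prior). Individuals are
// diploid: the band phenotype y_il = 1 iff at least one of the two allele
// copies is the presence allele; y_il = 0 iff the genotype is
// homozygous-null. The two latent allele copies per (i,l) each carry a
// cluster-of-origin z and an allele state a in {0,1}; they are resampled
// jointly given the phenotype, then P and Q are drawn from their Beta /
// Dirichlet full conditionals.
//
// Uses R's RNG throughout, so set.seed() in R gives bit-reproducible runs.

static const double P_EPS = 1e-9;

// sample index from unnormalised weights w[0..n-1] summing to tot
static int sample_cat(const double *w, int n, double tot) {
  double u = unif_rand() * tot;
  double acc = 0.0;
  for (int s = 0; s < n; ++s) {
    acc += w[s];
    if (u <= acc) return s;
  }
  return n - 1;
}

// [[Rcpp::export(name = ".admixture_gibbs_cpp")]]
List admixture_gibbs_cpp(IntegerMatrix y, int K, int n_burnin, int n_iter,
                         double alpha, int thinning) {
  const int N = y.nrow(), L = y.ncol();
  if (K < 1 || K > N) stop("K must be in [1, number of specimens]");
  if (n_iter < 1) stop("n_iter must be >= 1");
  if (alpha <= 0) stop("alpha must be > 0");
  if (thinning < 1) thinning = 1;

  NumericMatrix P(K, L);   // presence-allele frequency per cluster x locus
  NumericMatrix Q(N, K);   // admixture proportions
  // init: P from prior, Q uniform
  for (int k = 0; k < K; ++k)
    for (int l = 0; l < L; ++l) P(k, l) = R::rbeta(1.0, 1.0);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < K; ++k) Q(i, k) = 1.0 / K;

  const int n_sweeps = n_burnin + n_iter;
  const int n_keep = n_iter / thinning;
  NumericVector trace(n_keep);
  NumericMatrix Qsum(N, K);
  NumericMatrix Psum(K, L);
  int kept = 0, averaged = 0;

  // per-sweep sufficient statistics
  std::vector<double> n1(K * L), n0(K * L);  // allele counts per cluster x locus
  std::vector<double> m(N * K);              // allele copies per indiv x cluster
  std::vector<double> w(2 * K);              // per-copy state weights

  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    std::fill(n1.begin(), n1.end(), 0.0);
    std::fill(n0.begin(), n0.end(), 0.0);
    std::fill(m.begin(), m.end(), 0.0);

    for (int i = 0; i < N; ++i) {
      for (int l = 0; l < L; ++l) {
        // state s = 2k + a: cluster k, allele a (1 = presence)
        double W0 = 0.0, Wtot = 0.0;
        for (int k = 0; k < K; ++k) {
          double q = Q(i, k), p = P(k, l);
          w[2 * k] = q * (1.0 - p);
          w[2 * k + 1] = q * p;
          W0 += w[2 * k];
          Wtot += w[2 * k] + w[2 * k + 1];
        }
        int k1, a1, k2, a2;
        if (y(i, l) == 0) {
          // both copies null; origins independent with weight q_k (1-p_kl)
          {
            double u = unif_rand() * W0, acc = 0.0;
            k1 = K - 1;
            for (int k = 0; k < K; ++k) { acc += w[2 * k]; if (u <= acc) { k1 = k; break; } }
          }
          {
            double u = unif_rand() * W0, acc = 0.0;
            k2 = K - 1;
            for (int k = 0; k < K; ++k) { acc += w[2 * k]; if (u <= acc) { k2 = k; break; } }
          }
          a1 = a2 = 0;
        } else {
          // joint over (s1, s2) excluding both-null; marginal of copy 1:
          // P(s1) proportional to w[s1] * (Wtot - [a1==0] * W0)
          double tot = 0.0;
          for (int s = 0; s < 2 * K; ++s)
            tot += w[s] * (Wtot - ((s % 2 == 0) ? W0 : 0.0));
          double u = unif_rand() * tot, acc = 0.0;
          int s1 = 2 * K - 1;
          for (int s = 0; s < 2 * K; ++s) {
            acc += w[s] * (Wtot - ((s % 2 == 0) ? W0 : 0.0));
            if (u <= acc) { s1 = s; break; }
          }
          k1 = s1 / 2; a1 = s1 % 2;
          if (a1 == 1) {
            int s2 = sample_cat(&w[0], 2 * K, Wtot);
            k2 = s2 / 2; a2 = s2 % 2;
          } else {
            // copy 2 must be a presence allele
            double Wp = Wtot - W0;
            double u2 = unif_rand() * Wp, acc2 = 0.0;
            k2 = K - 1;
            for (int k = 0; k < K; ++k) {
              acc2 += w[2 * k + 1];
              if (u2 <= acc2) { k2 = k; break; }
            }
            a2 = 1;
          }
        }
        if (a1) n1[k1 * L + l] += 1.0; else n0[k1 * L + l] += 1.0;
        if (a2) n1[k2 * L + l] += 1.0; else n0[k2 * L + l] += 1.0;
        m[i * K + k1] += 1.0;
        m[i * K + k2] += 1.0;
      }
    }

    // P | counts ~ Beta(1 + n1, 1 + n0), clamped off the boundaries
    for (int k = 0; k < K; ++k)
      for (int l = 0; l < L; ++l) {
        double p = R::rbeta(1.0 + n1[k * L + l], 1.0 + n0[k * L + l]);
        if (p < P_EPS) p = P_EPS;
        if (p > 1.0 - P_EPS) p = 1.0 - P_EPS;
        P(k, l) = p;
      }

    // Q_i | origins ~ Dirichlet(alpha + m_i.)
    for (int i = 0; i < N; ++i) {
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        double g = R::rgamma(alpha + m[i * K + k], 1.0);
        Q(i, k) = g;
        tot += g;
      }
      for (int k = 0; k < K; ++k) Q(i, k) /= tot;
    }

    if (sweep >= n_burnin) {
      int post = sweep - n_burnin;
      if ((post + 1) % thinning == 0 && kept < n_keep) {
        // phenotype log-likelihood at current (Q, P)
        double ll = 0.0;
        for (int i = 0; i < N; ++i)
          for (int l = 0; l < L; ++l) {
            double W0 = 0.0;
            for (int k = 0; k < K; ++k) W0 += Q(i, k) * (1.0 - P(k, l));
            double p0 = W0 * W0;
            ll += (y(i, l) == 0) ? std::log(p0) : std::log1p(-p0);
          }
        trace[kept++] = ll;
      }
      for (int i = 0; i < N; ++i)
        for (int k = 0; k < K; ++k) Qsum(i, k) += Q(i, k);
      for (int k = 0; k < K; ++k)
        for (int l = 0; l < L; ++l) Psum(k, l) += P(k, l);
      ++averaged;
    }
  }

  for (int i = 0; i < N; ++i)
    for (int k = 0; k < K; ++k) Qsum(i, k) /= averaged;
  for (int k = 0; k < K; ++k)
    for (int l = 0; l < L; ++l) Psum(k, l) /= averaged;

  return List::create(_["Q"] = Qsum, _["P"] = Psum, _["loglik_trace"] = trace);
}
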