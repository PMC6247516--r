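#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the admixture model with correlated allele frequencies
// (F-model).  Genotypes are integer allele indices, one column pair per
// locus, 0 = missing.  Uses R's RNG so set.seed() governs reproducibility.

// Fast auxiliary uniform stream (xoshiro128+) for the very frequent
// allele-origin and Dirichlet draws; seeded from R's RNG so set.seed()
// stays in control of reproducibility.
struct FastUnif {
  uint64_t s0, s1;
  explicit FastUnif(uint64_t seed) {
    // splitmix64 initialisation
    for (uint64_t *s : {&s0, &s1}) {
      seed += 0x9e3779b97f4a7c15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      *s = z ^ (z >> 31);
    }
  }
  inline double next() {
    uint64_t x = s0, y = s1;
    uint64_t r = x + y;
    y ^= x;
    s0 = ((x << 55) | (x >> 9)) ^ y ^ (y << 14);
    s1 = (y << 36) | (y >> 28);
    return (r >> 11) * 0x1.0p-53;
  }
};

static inline int sample_prob(const double *p, int K, double norm, FastUnif &rng) {
  double u = rng.next() * norm, c = 0.0;
  for (int k = 0; k < K; ++k) { c += p[k]; if (u <= c) return k; }
  return K - 1;
}

static inline double fast_norm(FastUnif &rng) {
  // Box-Muller (single value; simplicity over caching)
  double u1 = rng.next(), u2 = rng.next();
  if (u1 < 1e-300) u1 = 1e-300;
  return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
}

// Marsaglia-Tsang gamma generator on the fast uniform stream
static double fast_rgamma(double shape, FastUnif &rng) {
  if (shape < 1.0) {
    double u = rng.next();
    if (u < 1e-300) u = 1e-300;
    return fast_rgamma(shape + 1.0, rng) * std::pow(u, 1.0 / shape);
  }
  const double d = shape - 1.0 / 3.0;
  const double c = 1.0 / std::sqrt(9.0 * d);
  for (;;) {
    double x = fast_norm(rng);
    double v = 1.0 + c * x;
    if (v <= 0.0) continue;
    v = v * v * v;
    double u = rng.next();
    double x2 = x * x;
    if (u < 1.0 - 0.0331 * x2 * x2) return d * v;
    if (u < 1e-300) u = 1e-300;
    if (std::log(u) < 0.5 * x2 + d * (1.0 - v + std::log(v))) return d * v;
  }
}

static inline double clog(double x) { return std::log(x > 1e-300 ? x : 1e-300); }

// Dirichlet draw into row `k` of `out` with parameters theta[j]
static void rdirichlet_row(NumericMatrix out, int k, const std::vector<double> &theta,
                           FastUnif &rng) {
  int A = theta.size();
  double s = 0.0;
  std::vector<double> g(A);
  for (int j = 0; j < A; ++j) {
    double x = fast_rgamma(theta[j], rng);
    g[j] = (x > 0.0) ? x : 1e-300;
    s += g[j];
  }
  for (int j = 0; j < A; ++j) out(k, j) = g[j] / s;
}

// [[Rcpp::export(name = ".admix_gibbs")]]
List admix_gibbs(IntegerMatrix geno, IntegerVector n_alleles, int K,
                 int burn_in, int n_iter, int thin,
                 double alpha_init, double alpha_max, double alpha_prop_sd,
                 double f_init, double f_prior_shape, double f_prior_rate,
                 double f_prop_sd, double lambda, double pa_step) {
  RNGScope scope;
  FastUnif fast((uint64_t)(R::unif_rand() * 9007199254740992.0));
  const int n = geno.nrow();
  const int L = n_alleles.size();
  if (geno.ncol() != 2 * L) stop("genotype matrix must have 2 columns per locus");
  if (thin < 1) thin = 1;
  const int n_samp = n_iter / thin;

  // state
  std::vector<NumericMatrix> P(L);      // K x A_l cluster frequencies
  std::vector<NumericVector> PA(L);     // ancestral frequencies
  NumericVector Fk(K, f_init);
  NumericMatrix Q(n, K);
  double alpha = alpha_init;

  for (int l = 0; l < L; ++l) {
    int A = n_alleles[l];
    P[l] = NumericMatrix(K, A);
    PA[l] = NumericVector(A, 1.0 / A);
    for (int k = 0; k < K; ++k)
      for (int j = 0; j < A; ++j) P[l](k, j) = 1.0 / A;
  }
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) Q(i, k) = 1.0 / K;

  // storage
  NumericVector loglik_trace(n_samp);
  NumericVector alpha_trace(n_samp), f_trace(n_samp * K);
  // visit histogram of per-individual origin counts m_ik (for the
  // Rao-Blackwellised posterior of q: a Beta mixture over m), accumulated
  // every post-burn-in sweep
  NumericVector m_hist((R_xlen_t)n * K * (2 * L + 1));
  double alpha_sum = 0.0; R_xlen_t alpha_n = 0;
  std::vector<NumericMatrix> P_sum(L);
  for (int l = 0; l < L; ++l) P_sum[l] = NumericMatrix(K, n_alleles[l]);

  std::vector<std::vector<double>> counts(L); // K x A_l allele-copy counts
  for (int l = 0; l < L; ++l) counts[l].assign(K * n_alleles[l], 0.0);
  std::vector<double> m(n * K);               // per-individual origin counts
  std::vector<double> pk(K), theta(std::max(32, K));

  // individual-major copy of the genotype table for cache-friendly sweeps
  std::vector<int> geno_t((size_t)n * 2 * L);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 2 * L; ++j) geno_t[(size_t)i * 2 * L + j] = geno(i, j);

  const int total = burn_in + n_iter;
  int stored = 0;

  for (int iter = 0; iter < total; ++iter) {
    // log-likelihood is evaluated on the retained (thinned) sweeps only;
    // those sampled scalars form the trace behind the lnPD estimate
    bool record = iter >= burn_in && ((iter - burn_in) % thin) == 0 && stored < n_samp;

    // --- Z update (allele-copy origins), accumulating counts and logL ----
    if (K == 1) {
      // origins are degenerate: counts are fixed by the data (computed on
      // the first sweep); only the likelihood needs refreshing when stored
      if (iter == 0) {
        for (int l = 0; l < L; ++l) {
          std::fill(counts[l].begin(), counts[l].end(), 0.0);
          for (int i = 0; i < n; ++i)
            for (int c = 0; c < 2; ++c) {
              int a = geno_t[(size_t)i * 2 * L + 2 * l + c];
              if (a > 0) counts[l][a - 1] += 1.0;
            }
        }
      }
      if (record) {
        double logL1 = 0.0;
        for (int l = 0; l < L; ++l) {
          const double *pl = REAL(P[l]);
          for (int i = 0; i < n; ++i)
            for (int c = 0; c < 2; ++c) {
              int a = geno_t[(size_t)i * 2 * L + 2 * l + c];
              if (a > 0) logL1 += clog(pl[a - 1]);
            }
        }
        loglik_trace[stored] = logL1;
      }
    } else {
    for (int l = 0; l < L; ++l) std::fill(counts[l].begin(), counts[l].end(), 0.0);
    std::fill(m.begin(), m.end(), 0.0);
    double logL = 0.0;
    const double *qd = REAL(Q);
    for (int i = 0; i < n; ++i) {
      double *mi = &m[(size_t)i * K];
      const int *gi = &geno_t[(size_t)i * 2 * L];
      for (int k = 0; k < K; ++k) pk[k] = qd[(size_t)k * n + i];
      for (int l = 0; l < L; ++l) {
        const double *pl = REAL(P[l]);
        for (int c = 0; c < 2; ++c) {
          int a = gi[2 * l + c];
          if (a <= 0) continue;
          const double *pa = pl + (size_t)(a - 1) * K;  // column (k fast)
          double norm = 0.0;
          double w[8];
          double *pw = (K <= 8) ? w : theta.data();
          for (int k = 0; k < K; ++k) { pw[k] = pk[k] * pa[k]; norm += pw[k]; }
          if (record) logL += clog(norm);
          int z = (K == 1) ? 0 : sample_prob(pw, K, norm, fast);
          counts[l][z * n_alleles[l] + (a - 1)] += 1.0;
          mi[z] += 1.0;
        }
      }
    }
    if (record) loglik_trace[stored] = logL;
    }

    // --- P update: conjugate Dirichlet under the F-model prior ----------
    for (int l = 0; l < L; ++l) {
      int A = n_alleles[l];
      if ((int)theta.size() < A) theta.resize(A);
      for (int k = 0; k < K; ++k) {
        double ck = (1.0 - Fk[k]) / Fk[k];
        std::vector<double> th(A);
        for (int j = 0; j < A; ++j) th[j] = PA[l][j] * ck + counts[l][k * A + j];
        rdirichlet_row(P[l], k, th, fast);
      }
    }

    // --- ancestral frequency update: pairwise mass-transfer Metropolis --
    for (int l = 0; l < L; ++l) {
      int A = n_alleles[l];
      if (A < 2) continue;
      int n_moves = std::max(2, A / 2);
      for (int rep = 0; rep < n_moves; ++rep) {
        int a = (int)(R::unif_rand() * A); if (a >= A) a = A - 1;
        int b = (int)(R::unif_rand() * (A - 1)); if (b >= a) b += 1;
        double d = R::norm_rand() * pa_step;
        double pa_new = PA[l][a] + d, pb_new = PA[l][b] - d;
        if (pa_new <= 1e-9 || pb_new <= 1e-9) continue;
        double lr = (lambda - 1.0) * (clog(pa_new) + clog(pb_new) - clog(PA[l][a]) - clog(PA[l][b]));
        for (int k = 0; k < K; ++k) {
          double ck = (1.0 - Fk[k]) / Fk[k];
          lr += R::lgammafn(PA[l][a] * ck) + R::lgammafn(PA[l][b] * ck)
              - R::lgammafn(pa_new * ck) - R::lgammafn(pb_new * ck)
              + (pa_new - PA[l][a]) * ck * clog(P[l](k, a))
              + (pb_new - PA[l][b]) * ck * clog(P[l](k, b));
        }
        if (lr >= 0.0 || R::unif_rand() < std::exp(lr)) { PA[l][a] = pa_new; PA[l][b] = pb_new; }
      }
    }

    // --- drift F update: random-walk Metropolis, Gamma prior ------------
    for (int k = 0; k < K; ++k) {
      double fnew = Fk[k] + R::norm_rand() * f_prop_sd;
      if (fnew <= 1e-6 || fnew >= 1.0 - 1e-6) continue;
      double cold = (1.0 - Fk[k]) / Fk[k], cnew = (1.0 - fnew) / fnew;
      double lr = (f_prior_shape - 1.0) * (clog(fnew) - clog(Fk[k])) - f_prior_rate * (fnew - Fk[k]);
      for (int l = 0; l < L; ++l) {
        int A = n_alleles[l];
        lr += R::lgammafn(cnew) - R::lgammafn(cold);
        for (int j = 0; j < A; ++j) {
          lr += R::lgammafn(PA[l][j] * cold) - R::lgammafn(PA[l][j] * cnew)
              + PA[l][j] * (cnew - cold) * clog(P[l](k, j));
        }
      }
      if (lr >= 0.0 || R::unif_rand() < std::exp(lr)) Fk[k] = fnew;
    }

    // --- Q update --------------------------------------------------------
    double sum_log_q = 0.0;
    if (K > 1) {
      std::vector<double> th(K);
      for (int i = 0; i < n; ++i) {
        for (int k = 0; k < K; ++k) th[k] = alpha + m[(size_t)i * K + k];
        rdirichlet_row(Q, i, th, fast);
        for (int k = 0; k < K; ++k) sum_log_q += clog(Q(i, k));
      }
    }

    // --- alpha update: random-walk Metropolis, uniform(0, alpha_max) ----
    if (K > 1) {
      double anew = alpha + R::norm_rand() * alpha_prop_sd;
      if (anew > 1e-6 && anew < alpha_max) {
        double lr = n * (R::lgammafn(K * anew) - K * R::lgammafn(anew)
                       - R::lgammafn(K * alpha) + K * R::lgammafn(alpha))
                  + (anew - alpha) * sum_log_q;
        if (lr >= 0.0 || R::unif_rand() < std::exp(lr)) alpha = anew;
      }
    }

    // --- accumulate origin-count histogram and alpha mean ---------------
    if (iter >= burn_in) {
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k) {
          int mk = (int)m[(size_t)i * K + k];
          m_hist[((R_xlen_t)i * K + k) * (2 * L + 1) + mk] += 1.0;
        }
      alpha_sum += alpha; ++alpha_n;
    }

    // --- record ----------------------------------------------------------
    if (record) {
      alpha_trace[stored] = alpha;
      for (int k = 0; k < K; ++k) f_trace[stored * K + k] = Fk[k];
      for (int l = 0; l < L; ++l)
        for (int k = 0; k < K; ++k)
          for (int j = 0; j < n_alleles[l]; ++j) P_sum[l](k, j) += P[l](k, j);
      ++stored;
    }
    if ((iter & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  List P_mean(L);
  for (int l = 0; l < L; ++l) {
    NumericMatrix pm(K, n_alleles[l]);
    for (int k = 0; k < K; ++k)
      for (int j = 0; j < n_alleles[l]; ++j) pm(k, j) = P_sum[l](k, j) / stored;
    P_mean[l] = pm;
  }

  // copies with data per individual (the Dirichlet total of each m_i)
  IntegerVector n_copies(n);
  for (int i = 0; i < n; ++i) {
    int tot = 0;
    for (int j = 0; j < 2 * L; ++j) if (geno_t[(size_t)i * 2 * L + j] > 0) ++tot;
    n_copies[i] = tot;
  }

  return List::create(
    _["n_stored"] = stored,
    _["P_mean"] = P_mean, _["alpha_trace"] = alpha_trace,
    _["f_trace"] = f_trace, _["loglik_trace"] = loglik_trace,
    _["m_hist"] = m_hist, _["n_copies"] = n_copies,
    _["alpha_mean"] = (alpha_n > 0) ? alpha_sum / alpha_n : alpha_init);
}

// Permutation null for the Hardy-Weinberg test: re-pair the 2n pooled allele
// copies at random and count heterozygous pairs.
// [[Rcpp::export(name = ".hwe_perm_het")]]
IntegerVector hwe_perm_het(IntegerVector alleles, int n_perm) {
  RNGScope scope;
  int m2 = alleles.size();           // 2n allele copies
  int n = m2 / 2;
  std::vector<int> pool(alleles.begin(), alleles.end());
  IntegerVector het(n_perm);
  for (int p = 0; p < n_perm; ++p) {
    // Fisher-Yates shuffle via R RNG
    for (int i = m2 - 1; i > 0; --i) {
      int j = (int)(R::unif_rand() * (i + 1)); if (j > i) j = i;
      std::swap(pool[i], pool[j]);
    }
    int h = 0;
    for (int i = 0; i < n; ++i) if (pool[2 * i] != pool[2 * i + 1]) ++h;
    het[p] = h;
  }
  return het;
}
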