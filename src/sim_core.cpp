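#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Meiosis on a single chromosome: Poisson(chrom_len) crossovers at uniform
// map positions (no interference), then recurrent mutation flipping each
// transmitted allele with probability mut_rate. Uses R's RNG throughout so
// set.seed() in R makes runs bit-identical.
template <typename T>
static void make_gamete(const T *h1, const T *h2, int n_loci,
                        const double *pos, double chrom_len,
                        double mut_rate, T *out) {
  int n_xo = (int) R::rpois(chrom_len);
  // current strand: 0 -> h1, 1 -> h2
  int strand = (unif_rand() < 0.5) ? 0 : 1;
  if (n_xo == 0) {
    const T *src = strand ? h2 : h1;
    std::copy(src, src + n_loci, out);
  } else {
    std::vector<double> xo(n_xo);
    for (int k = 0; k < n_xo; ++k) xo[k] = unif_rand() * chrom_len;
    std::sort(xo.begin(), xo.end());
    int lo = 0;
    for (int k = 0; k < n_xo; ++k) {
      // loci with pos < xo[k] come from current strand
      int hi = (int)(std::lower_bound(pos + lo, pos + n_loci, xo[k]) - pos);
      const T *src = strand ? h2 : h1;
      std::copy(src + lo, src + hi, out + lo);
      lo = hi;
      strand = 1 - strand;
    }
    const T *src = strand ? h2 : h1;
    std::copy(src + lo, src + n_loci, out + lo);
  }
  if (mut_rate > 0) {
    // K ~ Binomial(n_loci, mu) mutations at K distinct uniform loci is
    // exactly per-locus independent Bernoulli(mu) flips.
    int K = (int) R::rbinom((double) n_loci, mut_rate);
    if (K > 0) {
      std::vector<int> idx;
      idx.reserve(K);
      while ((int) idx.size() < K) {
        int j = (int)(unif_rand() * n_loci);
        if (j >= n_loci) j = n_loci - 1;
        if (std::find(idx.begin(), idx.end(), j) == idx.end()) idx.push_back(j);
      }
      for (int k = 0; k < K; ++k) out[idx[k]] = 1 - out[idx[k]];
    }
  }
}

// Run a whole sequence of random-union-of-gametes generations (historical
// phases and breed formation): each offspring draws one gamete from a random
// male and one from a random female; offspring sexes are exactly balanced by
// random assignment. sizes[t] is the census of generation t+1.
// [[Rcpp::export]]
List cpp_run_phase(IntegerMatrix haps0, IntegerVector sex0,
                   IntegerVector sizes, NumericVector positions,
                   double chrom_len, double mut_rate) {
  int n_loci = haps0.nrow();
  int n0 = haps0.ncol() / 2;
  int max_n = n0;
  for (int t = 0; t < sizes.size(); ++t)
    if (sizes[t] > max_n) max_n = sizes[t];

  std::vector<unsigned char> cur((size_t)n_loci * 2 * max_n),
      nxt((size_t)n_loci * 2 * max_n);
  for (size_t k = 0; k < (size_t)n_loci * 2 * n0; ++k)
    cur[k] = (unsigned char) haps0[k];
  std::vector<int> sex(sex0.begin(), sex0.end()), sex_next; // 0 = M, 1 = F
  const double *pos = positions.begin();
  int n_cur = n0;

  for (int t = 0; t < sizes.size(); ++t) {
    int n_new = sizes[t];
    std::vector<int> males, females;
    for (int i = 0; i < n_cur; ++i)
      (sex[i] == 0 ? males : females).push_back(i);
    if (males.empty() || females.empty())
      stop("population lost one sex during the phase schedule");
    for (int k = 0; k < n_new; ++k) {
      int s = males[(int)(unif_rand() * males.size())];
      int d = females[(int)(unif_rand() * females.size())];
      make_gamete(&cur[(size_t)n_loci * 2 * s],
                  &cur[(size_t)n_loci * (2 * s + 1)], n_loci, pos, chrom_len,
                  mut_rate, &nxt[(size_t)n_loci * 2 * k]);
      make_gamete(&cur[(size_t)n_loci * 2 * d],
                  &cur[(size_t)n_loci * (2 * d + 1)], n_loci, pos, chrom_len,
                  mut_rate, &nxt[(size_t)n_loci * (2 * k + 1)]);
    }
    // balanced sexes via partial Fisher-Yates
    sex_next.assign(n_new, 1);
    for (int k = 0; k < n_new / 2; ++k) sex_next[k] = 0;
    for (int k = n_new - 1; k > 0; --k) {
      int j = (int)(unif_rand() * (k + 1));
      std::swap(sex_next[k], sex_next[j]);
    }
    cur.swap(nxt);
    sex = sex_next;
    n_cur = n_new;
  }

  IntegerMatrix out(n_loci, 2 * n_cur);
  for (size_t k = 0; k < (size_t)n_loci * 2 * n_cur; ++k)
    out[k] = cur[k];
  return List::create(_["haps"] = out, _["sex"] = wrap(sex));
}

// [[Rcpp::export]]
IntegerMatrix cpp_gamete(IntegerMatrix haps, int parent,
                         NumericVector positions, double chrom_len,
                         double mut_rate) {
  int n_loci = haps.nrow();
  IntegerMatrix out(n_loci, 1);
  make_gamete(&haps(0, 2 * parent), &haps(0, 2 * parent + 1), n_loci,
              positions.begin(), chrom_len, mut_rate, &out(0, 0));
  return out;
}

// Offspring haplotypes for one generation. sires/dams are 0-based individual
// indices into `haps` (individual i owns columns 2i, 2i+1). Offspring k gets
// its first haplotype from sires[k], second from dams[k].
// [[Rcpp::export]]
IntegerMatrix cpp_offspring(IntegerMatrix haps, IntegerVector sires,
                            IntegerVector dams, NumericVector positions,
                            double chrom_len, double mut_rate) {
  int n_loci = haps.nrow();
  int n_off = sires.size();
  IntegerMatrix out(n_loci, 2 * n_off);
  const double *pos = positions.begin();
  for (int k = 0; k < n_off; ++k) {
    int s = sires[k], d = dams[k];
    make_gamete(&haps(0, 2 * s), &haps(0, 2 * s + 1), n_loci, pos, chrom_len,
                mut_rate, &out(0, 2 * k));
    make_gamete(&haps(0, 2 * d), &haps(0, 2 * d + 1), n_loci, pos, chrom_len,
                mut_rate, &out(0, 2 * k + 1));
  }
  return out;
}

// Inverse-Gaussian sampler (Michael, Schucany & Haas).
static double rinvgauss(double mu, double lambda) {
  double v = norm_rand();
  double y = v * v;
  double x = mu + (mu * mu * y) / (2.0 * lambda) -
             (mu / (2.0 * lambda)) *
                 std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0) x = 1e-12;
  double u = unif_rand();
  if (u <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// Bayesian LASSO with dominance: y = mu + X a + Z d + e.
// a_j ~ N(0, sigma_e2 * tau2_j), tau2_j ~ Exp(rate lambda2/2),
// lambda2 ~ Gamma(shape, rate); d_j ~ N(0, sigma_d2),
// sigma_d2 ~ scaled-inv-chi2(df_d, S_d); sigma_e2 ~ scaled-inv-chi2(df_e, S_e)
// (density of scaled-inv-chi2(df,S) proportional to
//  (s2)^(-df/2-1) exp(-df*S/(2 s2))).
// fix_* <= 0 means "sample"; positive values freeze that variance (used by
// tests to compare against the conjugate ridge closed form).
// [[Rcpp::export]]
List cpp_blasso(NumericVector y, NumericMatrix X, NumericMatrix Z,
                int n_iter, int burn_in, double df_e, double S_e, double df_d,
                double S_d, double lam_shape, double lam_rate,
                double fix_sigma_e2, double fix_sigma_d2, double fix_tau2) {
  int n = y.size(), m = X.ncol();
  std::vector<double> e(n), a(m, 0.0), d(m, 0.0), tau2(m, 1.0);
  std::vector<double> cx(m), cz(m);
  for (int j = 0; j < m; ++j) {
    double sx = 0, sz = 0;
    const double *xj = &X(0, j), *zj = &Z(0, j);
    for (int i = 0; i < n; ++i) { sx += xj[i] * xj[i]; sz += zj[i] * zj[i]; }
    cx[j] = sx; cz[j] = sz;
  }
  double mu = mean(y);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;
  double var_y = 0;
  for (int i = 0; i < n; ++i) var_y += e[i] * e[i];
  var_y /= std::max(1, n - 1);

  bool do_e2 = fix_sigma_e2 <= 0, do_d2 = fix_sigma_d2 <= 0,
       do_tau = fix_tau2 <= 0;
  double sigma_e2 = do_e2 ? std::max(var_y / 2.0, 1e-8) : fix_sigma_e2;
  double sigma_d2 = do_d2 ? std::max(S_d, 1e-8) : fix_sigma_d2;
  if (!do_tau) std::fill(tau2.begin(), tau2.end(), fix_tau2);
  double lambda2 = 1.0;

  std::vector<double> sum_a(m, 0.0), sum_d(m, 0.0), sum_a2(m, 0.0),
      sum_d2(m, 0.0);
  double sum_mu = 0, sum_se2 = 0, sum_sd2 = 0, sum_l2 = 0;
  int kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    // (i) intercept
    double se = 0;
    for (int i = 0; i < n; ++i) se += e[i];
    double mu_new = R::rnorm((se + n * mu) / n, std::sqrt(sigma_e2 / n));
    double dmu = mu_new - mu;
    for (int i = 0; i < n; ++i) e[i] -= dmu;
    mu = mu_new;

    // (ii) additive effects, marker-specific shrinkage
    for (int j = 0; j < m; ++j) {
      const double *xj = &X(0, j);
      double old = a[j], aj;
      if (cx[j] <= 0) {
        aj = R::rnorm(0.0, std::sqrt(sigma_e2 * tau2[j]));
      } else {
        double rhs = 0;
        for (int i = 0; i < n; ++i) rhs += xj[i] * e[i];
        rhs += cx[j] * old;
        double prec = cx[j] + 1.0 / tau2[j];
        aj = R::rnorm(rhs / prec, std::sqrt(sigma_e2 / prec));
      }
      double da = aj - old;
      if (da != 0 && cx[j] > 0)
        for (int i = 0; i < n; ++i) e[i] -= xj[i] * da;
      a[j] = aj;
    }

    // (iii) marker variances 1/tau2 ~ inverse-Gaussian
    if (do_tau) {
      for (int j = 0; j < m; ++j) {
        double aj = std::fabs(a[j]);
        double mup = std::sqrt(lambda2 * sigma_e2) / std::max(aj, 1e-10);
        if (mup > 1e8) mup = 1e8;
        double inv = rinvgauss(mup, lambda2);
        tau2[j] = 1.0 / std::max(inv, 1e-12);
      }
      // (iv) lambda2 from its gamma full conditional
      double st = 0;
      for (int j = 0; j < m; ++j) st += tau2[j];
      lambda2 = R::rgamma(lam_shape + m, 1.0 / (lam_rate + st / 2.0));
    }

    // (v) dominance effects, common prior variance sigma_d2
    for (int j = 0; j < m; ++j) {
      const double *zj = &Z(0, j);
      double old = d[j], dj;
      if (cz[j] <= 0) {
        dj = R::rnorm(0.0, std::sqrt(sigma_d2));
      } else {
        double rhs = 0;
        for (int i = 0; i < n; ++i) rhs += zj[i] * e[i];
        rhs += cz[j] * old;
        double prec = cz[j] + sigma_e2 / sigma_d2;
        dj = R::rnorm(rhs / prec, std::sqrt(sigma_e2 / prec));
      }
      double dd = dj - old;
      if (dd != 0 && cz[j] > 0)
        for (int i = 0; i < n; ++i) e[i] -= zj[i] * dd;
      d[j] = dj;
    }

    // (vi) dominance variance
    if (do_d2) {
      double sd2 = 0;
      for (int j = 0; j < m; ++j) sd2 += d[j] * d[j];
      sigma_d2 = (S_d * df_d + sd2) / R::rchisq(df_d + m);
    }

    // (vii) residual variance
    if (do_e2) {
      double sse = 0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      sigma_e2 = (S_e * df_e + sse) / R::rchisq(df_e + n);
    }

    if (it >= burn_in) {
      ++kept;
      sum_mu += mu; sum_se2 += sigma_e2; sum_sd2 += sigma_d2; sum_l2 += lambda2;
      for (int j = 0; j < m; ++j) {
        sum_a[j] += a[j]; sum_a2[j] += a[j] * a[j];
        sum_d[j] += d[j]; sum_d2[j] += d[j] * d[j];
      }
    }
  }

  NumericVector ahat(m), dhat(m), asd(m), dsd(m);
  for (int j = 0; j < m; ++j) {
    ahat[j] = sum_a[j] / kept;
    dhat[j] = sum_d[j] / kept;
    double va = sum_a2[j] / kept - ahat[j] * ahat[j];
    double vd = sum_d2[j] / kept - dhat[j] * dhat[j];
    asd[j] = std::sqrt(std::max(va, 0.0));
    dsd[j] = std::sqrt(std::max(vd, 0.0));
  }
  return List::create(
      _["a_hat"] = ahat, _["d_hat"] = dhat, _["a_sd"] = asd, _["d_sd"] = dsd,
      _["mu_hat"] = sum_mu / kept, _["sigma_e2"] = sum_se2 / kept,
      _["sigma_d2"] = sum_sd2 / kept, _["lambda2"] = sum_l2 / kept,
      _["n_kept"] = kept);
}
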