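#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// pi = k_hat^alpha * (1 - d_hat)^beta with the 0^0 = 1 convention
static inline double attach_prob(double k_hat, double d_hat, double alpha,
                                 double beta) {
  double b = (alpha == 0.0) ? 1.0 : std::pow(k_hat, alpha);
  double c = (beta == 0.0) ? 1.0 : std::pow(1.0 - d_hat, beta);
  return b * c;
}

// Fixed-m growth: coords are pre-sampled (one row per node, arrival order);
// the seed graph is the complete graph on the first n0 nodes. Targets are
// sampled without replacement with probability proportional to pi, falling
// back to uniform when all probabilities vanish. Uses R's RNG.
// [[Rcpp::export]]
IntegerMatrix cpp_grow_plain(NumericMatrix coords, int n0, int m,
                             double alpha, double beta) {
  int N = coords.nrow(), s = coords.ncol();
  int L = n0 * (n0 - 1) / 2 + m * (N - n0);
  IntegerMatrix edges(L, 2);
  int ne = 0;
  for (int i = 0; i < n0; ++i)
    for (int j = i + 1; j < n0; ++j) {
      edges(ne, 0) = i + 1;
      edges(ne, 1) = j + 1;
      ++ne;
    }
  std::vector<double> deg(N, 0.0);
  for (int i = 0; i < n0; ++i) deg[i] = n0 - 1;
  double dmax = 0.0;
  for (int i = 0; i < n0; ++i)
    for (int j = i + 1; j < n0; ++j) {
      double d2 = 0.0;
      for (int k = 0; k < s; ++k) {
        double dx = coords(i, k) - coords(j, k);
        d2 += dx * dx;
      }
      dmax = std::max(dmax, std::sqrt(d2));
    }
  std::vector<double> p(N), d(N);
  for (int i = n0; i < N; ++i) {
    double kmax = 0.0, dnew = 0.0;
    for (int j = 0; j < i; ++j) kmax = std::max(kmax, deg[j]);
    double psum = 0.0;
    for (int j = 0; j < i; ++j) {
      double d2 = 0.0;
      for (int k = 0; k < s; ++k) {
        double dx = coords(i, k) - coords(j, k);
        d2 += dx * dx;
      }
      d[j] = std::sqrt(d2);
      dnew = std::max(dnew, d[j]);
      double d_hat = (dmax > 0) ? std::min(d[j] / dmax, 1.0) : 0.0;
      p[j] = attach_prob(deg[j] / kmax, d_hat, alpha, beta);
      psum += p[j];
    }
    if (psum <= 0.0) {
      for (int j = 0; j < i; ++j) p[j] = 1.0;
      psum = i;
    }
    for (int t = 0; t < m; ++t) {  // sequential weighted draw, no repeats
      double u = unif_rand() * psum, acc = 0.0;
      int pick = -1;
      for (int j = 0; j < i; ++j) {
        acc += p[j];
        if (u <= acc) { pick = j; break; }
      }
      if (pick < 0) {  // numerical tail: last positive-probability node
        for (int j = i - 1; j >= 0; --j)
          if (p[j] > 0) { pick = j; break; }
      }
      edges(ne, 0) = pick + 1;
      edges(ne, 1) = i + 1;
      ++ne;
      deg[pick] += 1.0;
      psum -= p[pick];
      p[pick] = 0.0;
      if (psum <= 0.0 && t + 1 < m) {  // refill uniformly over the unused
        psum = 0.0;
        bool used;
        for (int j = 0; j < i; ++j) {
          used = false;
          for (int tt = ne - 1; tt >= ne - 1 - t; --tt)
            if (edges(tt, 0) == j + 1) { used = true; break; }
          p[j] = used ? 0.0 : 1.0;
          psum += p[j];
        }
      }
    }
    deg[i] = m;
    dmax = std::max(dmax, dnew);
  }
  return edges;
}

// Accelerated hidden-variable growth: nodes arrive in row order, each
// existing node j gets an independent Bernoulli link with probability
// pi_ij. Normalizations use the placed nodes only. Uses R's RNG.
// [[Rcpp::export]]
IntegerMatrix cpp_grow_accelerated(NumericMatrix coords,
                                   NumericVector hidden, double alpha,
                                   double beta) {
  int N = coords.nrow(), s = coords.ncol();
  std::vector<int> efrom, eto;
  efrom.reserve(N * 4);
  eto.reserve(N * 4);
  double dmax = 0.0, kmax = hidden[0];
  std::vector<double> d(N);
  for (int i = 1; i < N; ++i) {
    double dnew = 0.0;
    for (int j = 0; j < i; ++j) {
      double d2 = 0.0;
      for (int k = 0; k < s; ++k) {
        double dx = coords(i, k) - coords(j, k);
        d2 += dx * dx;
      }
      d[j] = std::sqrt(d2);
      dnew = std::max(dnew, d[j]);
    }
    for (int j = 0; j < i; ++j) {
      double d_hat = (dmax > 0) ? std::min(d[j] / dmax, 1.0) : 0.0;
      double pi = attach_prob(hidden[j] / kmax, d_hat, alpha, beta);
      if (unif_rand() < pi) {
        efrom.push_back(j + 1);
        eto.push_back(i + 1);
      }
    }
    dmax = std::max(dmax, dnew);
    kmax = std::max(kmax, (double)hidden[i]);
  }
  int L = efrom.size();
  IntegerMatrix edges(L, 2);
  for (int e = 0; e < L; ++e) {
    edges(e, 0) = efrom[e];
    edges(e, 1) = eto[e];
  }
  return edges;
}
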