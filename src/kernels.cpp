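#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// One pass of faithful sampling: walk the pick order, each still-unregistered
// event becomes a representative and registers every unregistered event
// within L1 distance h. The unregistered set is kept compact so each pass is
// O(sum of remaining set sizes).
// [[Rcpp::export(name = ".faithfulSampleCpp")]]
List faithfulSampleCpp(NumericMatrix X, double h, IntegerVector pickOrder) {
  const int n = X.nrow(), d = X.ncol();
  std::vector<int> memb(n, 0);          // 1-based community id, 0 = none
  std::vector<int> reps;
  std::vector<int> unreg(n);
  std::vector<int> pos(n);              // position of event in unreg, -1 gone
  for (int i = 0; i < n; ++i) { unreg[i] = i; pos[i] = i; }
  int nUnreg = n;

  for (int t = 0; t < n && nUnreg > 0; ++t) {
    int p = pickOrder[t] - 1;
    if (memb[p] != 0) continue;
    int cid = (int)reps.size() + 1;
    reps.push_back(p + 1);
    // scan the compact unregistered list; compact in place as we register
    int w = 0;
    for (int u = 0; u < nUnreg; ++u) {
      int j = unreg[u];
      double dist = 0.0;
      for (int c = 0; c < d; ++c) {
        dist += std::fabs(X(j, c) - X(p, c));
        if (dist > h) break;
      }
      if (dist <= h) {
        memb[j] = cid;
        pos[j] = -1;
      } else {
        unreg[w] = j;
        pos[j] = w;
        ++w;
      }
    }
    nUnreg = w;
  }

  return List::create(_["membership"] = IntegerVector(memb.begin(), memb.end()),
                      _["representatives"] = IntegerVector(reps.begin(),
                                                           reps.end()));
}

// Community similarity matrix: S[c,c'] = sum over member pairs of
// exp(-||x_i - x_j||^2 / (2 sigma^2)); the diagonal runs over all ordered
// pairs including i == j. Pairs of communities whose total contribution is
// provably below `tol` (from representative distance minus both community
// radii) are skipped and set to zero.
// [[Rcpp::export(name = ".similarityMatrixCpp")]]
NumericMatrix similarityMatrixCpp(NumericMatrix X, List communities,
                                  IntegerVector representatives,
                                  double sigma, double tol) {
  const int m = communities.size(), d = X.ncol();
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);

  // contiguous row-major coordinate buffer per community (cache locality:
  // the pair loop touches every member-pair of nearby communities)
  std::vector< std::vector<double> > coords(m);
  std::vector<int> sz(m);
  for (int c = 0; c < m; ++c) {
    IntegerVector v = communities[c];
    sz[c] = v.size();
    coords[c].resize((size_t)sz[c] * d);
    for (int i = 0; i < sz[c]; ++i)
      for (int k = 0; k < d; ++k)
        coords[c][(size_t)i * d + k] = X(v[i] - 1, k);
  }

  // Euclidean radius of each community around its representative, for the
  // lower bound on cross-pair distances.
  std::vector<double> rad(m, 0.0), repc((size_t)m * d);
  for (int c = 0; c < m; ++c) {
    int r = representatives[c] - 1;
    for (int k = 0; k < d; ++k) repc[(size_t)c * d + k] = X(r, k);
    double worst = 0.0;
    for (int i = 0; i < sz[c]; ++i) {
      double d2 = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = coords[c][(size_t)i * d + k] - repc[(size_t)c * d + k];
        d2 += diff * diff;
      }
      if (d2 > worst) worst = d2;
    }
    rad[c] = std::sqrt(worst);
  }

  NumericMatrix S(m, m);
  for (int a = 0; a < m; ++a) {
    const double *pa = coords[a].data();
    // diagonal: ordered pairs, i == j contributes 1 each
    double diag = (double)sz[a];
    for (int i = 0; i + 1 < sz[a]; ++i)
      for (int j = i + 1; j < sz[a]; ++j) {
        double d2 = 0.0;
        for (int k = 0; k < d; ++k) {
          double diff = pa[(size_t)i * d + k] - pa[(size_t)j * d + k];
          d2 += diff * diff;
        }
        diag += 2.0 * std::exp(-d2 * inv2s2);
      }
    S(a, a) = diag;

    for (int b = a + 1; b < m; ++b) {
      double dr2 = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = repc[(size_t)a * d + k] - repc[(size_t)b * d + k];
        dr2 += diff * diff;
      }
      double dmin = std::sqrt(dr2) - rad[a] - rad[b];
      if (dmin > 0.0) {
        double bound = (double)sz[a] * (double)sz[b] *
                       std::exp(-dmin * dmin * inv2s2);
        if (bound < tol) { S(a, b) = 0.0; S(b, a) = 0.0; continue; }
      }
      const double *pb = coords[b].data();
      double s = 0.0;
      for (int i = 0; i < sz[a]; ++i)
        for (int j = 0; j < sz[b]; ++j) {
          double d2 = 0.0;
          for (int k = 0; k < d; ++k) {
            double diff = pa[(size_t)i * d + k] - pb[(size_t)j * d + k];
            d2 += diff * diff;
          }
          s += std::exp(-d2 * inv2s2);
        }
      S(a, b) = s;
      S(b, a) = s;
    }
  }
  return S;
}
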