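// Bicubic Hermite patch evaluation and closest-point projection.
// Nodes carry 12 DoF: position, d/dxi1, d/dxi2, d2/dxi1dxi2 (3 components each),
// stored as rows of a n x 12 matrix in that column order.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// 1-D cubic Hermite basis at t: h[0]=value@0, h[1]=deriv@0, h[2]=value@1, h[3]=deriv@1
static inline void basis1(double t, double* h, double* hd, double* hdd) {
  double t2 = t * t, t3 = t2 * t;
  h[0] = 2 * t3 - 3 * t2 + 1;
  h[1] = t3 - 2 * t2 + t;
  h[2] = -2 * t3 + 3 * t2;
  h[3] = t3 - t2;
  if (hd) {
    hd[0] = 6 * t2 - 6 * t;
    hd[1] = 3 * t2 - 4 * t + 1;
    hd[2] = -6 * t2 + 6 * t;
    hd[3] = 3 * t2 - 2 * t;
  }
  if (hdd) {
    hdd[0] = 12 * t - 6;
    hdd[1] = 6 * t - 4;
    hdd[2] = -12 * t + 6;
    hdd[3] = 6 * t - 2;
  }
}

// 16 tensor-product weights, local corner order (0,0),(1,0),(0,1),(1,1),
// DoF-group order (pos, d1, d2, d12) within each corner.
static inline void weights16(const double* h1, const double* h2, double* w) {
  static const int ca[4] = {0, 1, 0, 1};
  static const int cb[4] = {0, 0, 1, 1};
  for (int k = 0; k < 4; ++k) {
    int a = ca[k], b = cb[k];
    w[k * 4 + 0] = h1[2 * a] * h2[2 * b];
    w[k * 4 + 1] = h1[2 * a + 1] * h2[2 * b];
    w[k * 4 + 2] = h1[2 * a] * h2[2 * b + 1];
    w[k * 4 + 3] = h1[2 * a + 1] * h2[2 * b + 1];
  }
}

// gather the 16 x 3 DoF coefficients of every element into a flat cache:
// coef[e * 48 + i * 3 + c], i = corner*4 + group
static std::vector<double> elemCoefs(const NumericMatrix& nodes,
                                     const IntegerMatrix& elements) {
  int ne = elements.nrow();
  std::vector<double> coef((size_t)ne * 48);
  for (int e = 0; e < ne; ++e) {
    for (int k = 0; k < 4; ++k) {
      int nd = elements(e, k) - 1;
      for (int g = 0; g < 4; ++g) {
        for (int c = 0; c < 3; ++c) {
          coef[(size_t)e * 48 + (k * 4 + g) * 3 + c] = nodes(nd, g * 3 + c);
        }
      }
    }
  }
  return coef;
}

// evaluate one element from its coefficient block
static inline void evalCoef(const double* coef, double x1, double x2,
                            double* S, double* J1, double* J2,
                            double* H11, double* H22, double* H12) {
  double h1[4], h1d[4], h1dd[4], h2[4], h2d[4], h2dd[4];
  bool first = (J1 != nullptr), second = (H11 != nullptr);
  basis1(x1, h1, first ? h1d : nullptr, second ? h1dd : nullptr);
  basis1(x2, h2, first ? h2d : nullptr, second ? h2dd : nullptr);
  double w[16], w1[16], w2[16], w11[16], w22[16], w12[16];
  weights16(h1, h2, w);
  if (first) { weights16(h1d, h2, w1); weights16(h1, h2d, w2); }
  if (second) {
    weights16(h1dd, h2, w11);
    weights16(h1, h2dd, w22);
    weights16(h1d, h2d, w12);
  }
  for (int c = 0; c < 3; ++c) {
    double s = 0, j1 = 0, j2 = 0, a11 = 0, a22 = 0, a12 = 0;
    for (int i = 0; i < 16; ++i) {
      double v = coef[i * 3 + c];
      s += w[i] * v;
      if (first) { j1 += w1[i] * v; j2 += w2[i] * v; }
      if (second) { a11 += w11[i] * v; a22 += w22[i] * v; a12 += w12[i] * v; }
    }
    S[c] = s;
    if (first) { J1[c] = j1; J2[c] = j2; }
    if (second) { H11[c] = a11; H22[c] = a22; H12[c] = a12; }
  }
}

static inline double dist2(const double* S, const double* p) {
  double d0 = S[0] - p[0], d1 = S[1] - p[1], d2 = S[2] - p[2];
  return d0 * d0 + d1 * d1 + d2 * d2;
}

// [[Rcpp::export(name = ".cpp_eval_element")]]
NumericMatrix cpp_eval_element(NumericMatrix nodes, IntegerMatrix elements,
                               IntegerVector elem, NumericVector xi1,
                               NumericVector xi2, int order) {
  // order: 0 value, 1 d1, 2 d2, 11 d11, 22 d22, 12 d12
  std::vector<double> coef = elemCoefs(nodes, elements);
  int m = elem.size();
  NumericMatrix out(m, 3);
  double S[3], J1[3], J2[3], H11[3], H22[3], H12[3];
  for (int i = 0; i < m; ++i) {
    int e = elem[i] - 1;
    bool second = (order > 2);
    evalCoef(&coef[(size_t)e * 48], xi1[i], xi2[i], S,
             (order >= 1) ? J1 : nullptr, (order >= 1) ? J2 : nullptr,
             second ? H11 : nullptr, second ? H22 : nullptr,
             second ? H12 : nullptr);
    const double* src = S;
    if (order == 1) src = J1;
    else if (order == 2) src = J2;
    else if (order == 11) src = H11;
    else if (order == 22) src = H22;
    else if (order == 12) src = H12;
    for (int c = 0; c < 3; ++c) out(i, c) = src[c];
  }
  return out;
}

// damped Newton minimisation of |S(xi) - p|^2 within one element,
// starting at (x1, x2). Returns squared distance; updates x1/x2; ok=false on
// divergence (caller falls back to the grid optimum).
static double newtonRefine(const double* coef, const double* p,
                           double& x1, double& x2, double f0, int maxIter,
                           bool& ok) {
  double S[3], J1[3], J2[3], H11[3], H22[3], H12[3];
  double f = f0;
  ok = true;
  for (int it = 0; it < maxIter; ++it) {
    evalCoef(coef, x1, x2, S, J1, J2, H11, H22, H12);
    double d[3] = {S[0] - p[0], S[1] - p[1], S[2] - p[2]};
    double g1 = 0, g2 = 0, a11 = 0, a22 = 0, a12 = 0;
    for (int c = 0; c < 3; ++c) {
      g1 += 2 * J1[c] * d[c];
      g2 += 2 * J2[c] * d[c];
      a11 += 2 * (J1[c] * J1[c] + d[c] * H11[c]);
      a22 += 2 * (J2[c] * J2[c] + d[c] * H22[c]);
      a12 += 2 * (J1[c] * J2[c] + d[c] * H12[c]);
    }
    double det = a11 * a22 - a12 * a12;
    double s1, s2;
    if (std::fabs(det) < 1e-14 || !std::isfinite(det)) {
      double gn = std::sqrt(g1 * g1 + g2 * g2);
      if (gn < 1e-14) break;
      s1 = -g1 / gn * 0.05;
      s2 = -g2 / gn * 0.05;
    } else {
      s1 = -(a22 * g1 - a12 * g2) / det;
      s2 = -(-a12 * g1 + a11 * g2) / det;
    }
    double lam = 1.0, nx1 = x1, nx2 = x2, nf = f;
    bool improved = false;
    for (int h = 0; h < 10; ++h) {
      double t1 = std::min(1.0, std::max(0.0, x1 + lam * s1));
      double t2 = std::min(1.0, std::max(0.0, x2 + lam * s2));
      evalCoef(coef, t1, t2, S, nullptr, nullptr, nullptr, nullptr, nullptr);
      double ft = dist2(S, p);
      if (std::isfinite(ft) && ft <= f + 1e-15) {
        nx1 = t1; nx2 = t2; nf = ft; improved = true;
        break;
      }
      lam *= 0.5;
    }
    if (!improved) { ok = (it > 0); break; }
    double step = std::max(std::fabs(nx1 - x1), std::fabs(nx2 - x2));
    x1 = nx1; x2 = nx2; f = nf;
    if (step < 1e-12) break;
  }
  if (!std::isfinite(f) || f > f0) ok = false;
  return f;
}

// Closest-point projection of a point set onto the mesh.
// ptSurf[i] == 0 means "any surface"; otherwise only elements with a
// matching elemSurf code are searched. Coarse xi-grid search (lowest element
// index wins exact ties) seeds damped Newton refinement in each of the best
// few candidate elements; on divergence the grid optimum is kept.
// Returns m x 5: (element 1-based, xi1, xi2, distance, newton_ok).
// [[Rcpp::export(name = ".cpp_project")]]
NumericMatrix cpp_project(NumericMatrix nodes, IntegerMatrix elements,
                          IntegerVector elemSurf, NumericMatrix pts,
                          IntegerVector ptSurf, int grid, int maxNewton) {
  int m = pts.nrow(), ne = elements.nrow();
  NumericMatrix out(m, 5);
  if (grid < 2) grid = 2;
  std::vector<double> g(grid);
  for (int i = 0; i < grid; ++i) g[i] = (double)i / (grid - 1);
  std::vector<double> coef = elemCoefs(nodes, elements);

  // cache grid positions per element
  int g2n = grid * grid;
  std::vector<double> gp((size_t)ne * g2n * 3);
  double S[3];
  for (int e = 0; e < ne; ++e) {
    for (int a = 0; a < grid; ++a) {
      for (int b = 0; b < grid; ++b) {
        evalCoef(&coef[(size_t)e * 48], g[a], g[b], S, nullptr, nullptr,
                 nullptr, nullptr, nullptr);
        size_t off = ((size_t)e * g2n + a * grid + b) * 3;
        gp[off] = S[0]; gp[off + 1] = S[1]; gp[off + 2] = S[2];
      }
    }
  }

  const int TOPK = 5;
  for (int i = 0; i < m; ++i) {
    double p[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    int surf = ptSurf[i];
    // per-element grid optima; keep the TOPK best elements (ascending order
    // scan with strict comparisons => lowest element id wins ties)
    int topE[TOPK];
    double topF[TOPK], topX1[TOPK], topX2[TOPK];
    for (int k = 0; k < TOPK; ++k) { topE[k] = -1; topF[k] = R_PosInf; }
    for (int e = 0; e < ne; ++e) {
      if (surf != 0 && elemSurf[e] != surf) continue;
      double bf = R_PosInf; int ba = 0, bb = 0;
      const double* base = &gp[(size_t)e * g2n * 3];
      for (int a = 0; a < grid; ++a) {
        for (int b = 0; b < grid; ++b) {
          const double* q = base + (a * grid + b) * 3;
          double f = dist2(q, p);
          if (f < bf) { bf = f; ba = a; bb = b; }
        }
      }
      // insert into top-k
      if (bf < topF[TOPK - 1]) {
        int k = TOPK - 1;
        while (k > 0 && bf < topF[k - 1]) {
          topF[k] = topF[k - 1]; topE[k] = topE[k - 1];
          topX1[k] = topX1[k - 1]; topX2[k] = topX2[k - 1];
          --k;
        }
        topF[k] = bf; topE[k] = e; topX1[k] = g[ba]; topX2[k] = g[bb];
      }
    }
    if (topE[0] < 0) {
      out(i, 0) = NA_REAL; out(i, 1) = NA_REAL; out(i, 2) = NA_REAL;
      out(i, 3) = NA_REAL; out(i, 4) = 0;
      continue;
    }
    int bestE = topE[0];
    double bestF = topF[0], bx1 = topX1[0], bx2 = topX2[0];
    bool anyOk = false;
    for (int k = 0; k < TOPK; ++k) {
      if (topE[k] < 0) continue;
      double x1 = topX1[k], x2 = topX2[k];
      bool ok;
      double f = newtonRefine(&coef[(size_t)topE[k] * 48], p, x1, x2,
                              topF[k], maxNewton, ok);
      if (!ok) { x1 = topX1[k]; x2 = topX2[k]; f = topF[k]; }
      anyOk = anyOk || ok;
      if (f < bestF) { bestF = f; bestE = topE[k]; bx1 = x1; bx2 = x2; }
    }
    out(i, 0) = bestE + 1;
    out(i, 1) = bx1;
    out(i, 2) = bx2;
    out(i, 3) = std::sqrt(bestF);
    out(i, 4) = anyOk ? 1 : 0;
  }
  return out;
}

// Accumulate the fitting normal equations for fixed projections:
// A = sum_p gamma_p w_p w_p' (4n x 4n), B = sum_p gamma_p w_p z_p' (4n x 3),
// where w_p holds the 16 bicubic basis weights of point p scattered to the
// global per-coordinate DoF indices (4 per node).
// [[Rcpp::export(name = ".cpp_normal_eqs")]]
List cpp_normal_eqs(IntegerMatrix elements, IntegerVector projElem,
                    NumericVector xi1, NumericVector xi2,
                    NumericVector gamma, NumericMatrix pts, int nNodes) {
  int m = projElem.size();
  int dim = 4 * nNodes;
  NumericMatrix A(dim, dim);
  NumericMatrix B(dim, 3);
  double* a = A.begin();
  double* b = B.begin();
  double h1[4], h2[4], w[16];
  int idx[16];
  for (int p = 0; p < m; ++p) {
    int e = projElem[p] - 1;
    basis1(xi1[p], h1, nullptr, nullptr);
    basis1(xi2[p], h2, nullptr, nullptr);
    weights16(h1, h2, w);
    for (int k = 0; k < 4; ++k) {
      int nd = elements(e, k) - 1;
      for (int g = 0; g < 4; ++g) idx[k * 4 + g] = nd * 4 + g;
    }
    double gm = gamma[p];
    for (int i = 0; i < 16; ++i) {
      double wi = gm * w[i];
      int ii = idx[i];
      for (int j = 0; j < 16; ++j) {
        a[(size_t)idx[j] * dim + ii] += wi * w[j];
      }
      for (int c = 0; c < 3; ++c) {
        b[(size_t)c * dim + ii] += wi * pts(p, c);
      }
    }
  }
  return List::create(Named("A") = A, Named("B") = B);
}
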