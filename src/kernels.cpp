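// Low-level image and optimization kernels.
//
// Conventions: images are R matrices (column-major, nrow = image height).
// All neighborhood operations use reflect padding via index mirroring, so
// results are defined up to the image border. Pixel subsets are passed as
// 0-based (row, col) index vectors.

#include <Rcpp.h>
#include <queue>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// mirror index into [0, n-1] (reflect-101 style without repeating the edge
// sample would change border statistics; we use symmetric half-sample
// reflection: -1 -> 0, n -> n-1), supports arbitrary overshoot.
static inline int mirror(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  return (i < n) ? i : period - 1 - i;
}

// ---------------------------------------------------------------------------
// Grayscale morphological reconstruction by dilation (Vincent 1993, hybrid
// raster / FIFO algorithm, 8-connectivity). marker <= mask is assumed.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cc_reconstruct")]]
NumericMatrix cc_reconstruct(NumericMatrix marker, NumericMatrix mask) {
  int nr = marker.nrow(), nc = marker.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("marker and mask dimensions differ");
  NumericMatrix J(clone(marker));

  // raster scan: neighbors already visited (N+)
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double v = J(r, c);
      if (r > 0) {
        v = std::max(v, J(r - 1, c));
        if (c > 0) v = std::max(v, J(r - 1, c - 1));
        if (c < nc - 1) v = std::max(v, J(r - 1, c + 1));
      }
      if (c > 0) v = std::max(v, J(r, c - 1));
      J(r, c) = std::min(v, mask(r, c));
    }
  }

  // anti-raster scan (N-), queue boundary pixels
  std::queue<std::pair<int, int> > fifo;
  for (int c = nc - 1; c >= 0; --c) {
    for (int r = nr - 1; r >= 0; --r) {
      double v = J(r, c);
      if (r < nr - 1) {
        v = std::max(v, J(r + 1, c));
        if (c > 0) v = std::max(v, J(r + 1, c - 1));
        if (c < nc - 1) v = std::max(v, J(r + 1, c + 1));
      }
      if (c < nc - 1) v = std::max(v, J(r, c + 1));
      J(r, c) = std::min(v, mask(r, c));
      // enqueue if some N- neighbor could still grow
      bool push = false;
      const int dr[4] = {1, 1, 1, 0};
      const int dc[4] = {-1, 0, 1, 1};
      for (int k = 0; k < 4 && !push; ++k) {
        int rr = r + dr[k], ccol = c + dc[k];
        if (rr < 0 || rr >= nr || ccol < 0 || ccol >= nc) continue;
        if (J(rr, ccol) < J(r, c) && J(rr, ccol) < mask(rr, ccol)) push = true;
      }
      if (push) fifo.push(std::make_pair(r, c));
    }
  }

  // propagation
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  while (!fifo.empty()) {
    int r = fifo.front().first, c = fifo.front().second;
    fifo.pop();
    for (int k = 0; k < 8; ++k) {
      int rr = r + dr8[k], ccol = c + dc8[k];
      if (rr < 0 || rr >= nr || ccol < 0 || ccol >= nc) continue;
      if (J(rr, ccol) < J(r, c) && mask(rr, ccol) != J(rr, ccol)) {
        J(rr, ccol) = std::min(J(r, c), mask(rr, ccol));
        fifo.push(std::make_pair(rr, ccol));
      }
    }
  }
  return J;
}

// ---------------------------------------------------------------------------
// Binary thinning to a 1-px skeleton, Guo & Hall (1989) two-subiteration
// scheme. Preserves topology and keeps line endpoints, so non-connected
// branches survive. A final pass removes residual 2x2 foreground blocks by
// deleting simple (non-end) points.
// ---------------------------------------------------------------------------

static inline int at(const IntegerMatrix& M, int r, int c) {
  if (r < 0 || r >= M.nrow() || c < 0 || c >= M.ncol()) return 0;
  return M(r, c) != 0 ? 1 : 0;
}

// [[Rcpp::export(name = ".cc_thin")]]
IntegerMatrix cc_thin(IntegerMatrix img) {
  IntegerMatrix M(clone(img));
  int nr = M.nrow(), nc = M.ncol();
  bool changed = true;
  int guard = 0;
  while (changed && ++guard < 10000) {
    changed = false;
    for (int iter = 0; iter < 2; ++iter) {
      std::vector<std::pair<int, int> > del;
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (!at(M, r, c)) continue;
          int p2 = at(M, r - 1, c),     p3 = at(M, r - 1, c + 1);
          int p4 = at(M, r, c + 1),     p5 = at(M, r + 1, c + 1);
          int p6 = at(M, r + 1, c),     p7 = at(M, r + 1, c - 1);
          int p8 = at(M, r, c - 1),     p9 = at(M, r - 1, c - 1);
          int C = ((!p2) & (p3 | p4)) + ((!p4) & (p5 | p6)) +
                  ((!p6) & (p7 | p8)) + ((!p8) & (p9 | p2));
          int N1 = (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8);
          int N2 = (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9);
          int N = std::min(N1, N2);
          int m = (iter == 0) ? ((p6 | p7 | (!p9)) & p8)
                              : ((p2 | p3 | (!p5)) & p4);
          if (C == 1 && N >= 2 && N <= 3 && m == 0)
            del.push_back(std::make_pair(r, c));
        }
      }
      for (size_t i = 0; i < del.size(); ++i) M(del[i].first, del[i].second) = 0;
      if (!del.empty()) changed = true;
    }
  }
  // remove residual 2x2 blocks: delete a simple, non-endpoint corner
  bool block = true;
  guard = 0;
  while (block && ++guard < 1000) {
    block = false;
    for (int c = 0; c + 1 < nc && !block; ++c) {
      for (int r = 0; r + 1 < nr && !block; ++r) {
        if (at(M, r, c) && at(M, r + 1, c) && at(M, r, c + 1) && at(M, r + 1, c + 1)) {
          int best_r = -1, best_c = -1;
          const int rr[4] = {r, r + 1, r, r + 1};
          const int cc2[4] = {c, c, c + 1, c + 1};
          for (int k = 0; k < 4; ++k) {
            int p2 = at(M, rr[k] - 1, cc2[k]),     p3 = at(M, rr[k] - 1, cc2[k] + 1);
            int p4 = at(M, rr[k], cc2[k] + 1),     p5 = at(M, rr[k] + 1, cc2[k] + 1);
            int p6 = at(M, rr[k] + 1, cc2[k]),     p7 = at(M, rr[k] + 1, cc2[k] - 1);
            int p8 = at(M, rr[k], cc2[k] - 1),     p9 = at(M, rr[k] - 1, cc2[k] - 1);
            // Hilditch crossing number
            int seq[9] = {p2, p3, p4, p5, p6, p7, p8, p9, p2};
            int A = 0;
            for (int s = 0; s < 8; ++s) if (seq[s] == 0 && seq[s + 1] == 1) ++A;
            int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
            if (A == 1 && B >= 3) { best_r = rr[k]; best_c = cc2[k]; break; }
          }
          if (best_r >= 0) { M(best_r, best_c) = 0; block = true; }
        }
      }
    }
  }
  return M;
}

// ---------------------------------------------------------------------------
// Sliding-window order statistics (min, median, max) with reflect padding.
// rows/cols: 0-based pixel subset; empty => all pixels (full rasters).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cc_order_stats")]]
NumericMatrix cc_order_stats(NumericMatrix img, int ksize,
                             IntegerVector rows, IntegerVector cols) {
  int nr = img.nrow(), nc = img.ncol(), h = ksize / 2;
  int n = rows.size() ? rows.size() : nr * nc;
  NumericMatrix out(n, 3);
  std::vector<double> buf(ksize * ksize);
  for (int i = 0; i < n; ++i) {
    int r = rows.size() ? rows[i] : (i % nr);
    int c = rows.size() ? cols[i] : (i / nr);
    int m = 0;
    for (int dc = -h; dc <= h; ++dc)
      for (int dr = -h; dr <= h; ++dr)
        buf[m++] = img(mirror(r + dr, nr), mirror(c + dc, nc));
    std::sort(buf.begin(), buf.end());
    out(i, 0) = buf.front();
    out(i, 1) = buf[m / 2];
    out(i, 2) = buf.back();
  }
  return out;
}

// ---------------------------------------------------------------------------
// Local binary pattern (8 neighbors, radius 1) + local contrast (population
// variance of the 8 neighbors). Neighbor order E, NE, N, NW, W, SW, S, SE
// with bit weights 1, 2, 4, ..., 128; bit set when neighbor >= center.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cc_lbp")]]
NumericMatrix cc_lbp(NumericMatrix img, IntegerVector rows, IntegerVector cols) {
  int nr = img.nrow(), nc = img.ncol();
  const int dr[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  const int dc[8] = {1, 1, 0, -1, -1, -1, 0, 1};
  int n = rows.size() ? rows.size() : nr * nc;
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    int r = rows.size() ? rows[i] : (i % nr);
    int c = rows.size() ? cols[i] : (i / nr);
    double ctr = img(r, c), s = 0, s2 = 0;
    int code = 0;
    for (int k = 0; k < 8; ++k) {
      double v = img(mirror(r + dr[k], nr), mirror(c + dc[k], nc));
      if (v >= ctr) code |= (1 << k);
      s += v; s2 += v * v;
    }
    out(i, 0) = code;
    double mu = s / 8.0;
    out(i, 1) = std::max(0.0, s2 / 8.0 - mu * mu);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Haralick (1973) texture features from a symmetric gray-level co-occurrence
// matrix accumulated over the kernel-sized neighborhood of each pixel
// (distance 1, four directions pooled, reflect padding). img must already be
// quantized to integer levels 0..nlevels-1. Returns n x 13 matrix, feature
// order: ASM, CON, COR, SSV, IDM, SAV, SVA, SEN, ENT, DVA, DOE, IMOC1, IMOC2.
// Natural logarithms; 0 log 0 := 0.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cc_haralick")]]
NumericMatrix cc_haralick(IntegerMatrix img, int ksize, int nlevels,
                          IntegerVector rows, IntegerVector cols) {
  int nr = img.nrow(), nc = img.ncol(), h = ksize / 2;
  int n = rows.size() ? rows.size() : nr * nc;
  NumericMatrix out(n, 13);
  int L = nlevels;
  std::vector<double> P(L * L), px(L), py(L), pxy(2 * L), pdiff(L);
  const int dr[4] = {0, 1, 1, 1};     // E, S, SE, SW offsets
  const int dc[4] = {1, 0, 1, -1};

  for (int i = 0; i < n; ++i) {
    int r0 = rows.size() ? rows[i] : (i % nr);
    int c0 = rows.size() ? cols[i] : (i / nr);
    std::fill(P.begin(), P.end(), 0.0);
    double total = 0;
    for (int dcw = -h; dcw <= h; ++dcw) {
      for (int drw = -h; drw <= h; ++drw) {
        int r = r0 + drw, c = c0 + dcw;
        int a = img(mirror(r, nr), mirror(c, nc));
        for (int k = 0; k < 4; ++k) {
          int r2 = drw + dr[k], c2 = dcw + dc[k];
          if (r2 < -h || r2 > h || c2 < -h || c2 > h) continue; // pair within window
          int b = img(mirror(r0 + r2, nr), mirror(c0 + c2, nc));
          P[a * L + b] += 1.0;
          P[b * L + a] += 1.0;   // symmetric
          total += 2.0;
        }
      }
    }
    if (total <= 0) { for (int f = 0; f < 13; ++f) out(i, f) = 0; continue; }
    for (int k = 0; k < L * L; ++k) P[k] /= total;

    std::fill(px.begin(), px.end(), 0.0);
    std::fill(py.begin(), py.end(), 0.0);
    std::fill(pxy.begin(), pxy.end(), 0.0);
    std::fill(pdiff.begin(), pdiff.end(), 0.0);
    double asm_ = 0, con = 0, idm = 0, ent = 0, sij = 0;
    for (int a = 0; a < L; ++a) {
      for (int b = 0; b < L; ++b) {
        double p = P[a * L + b];
        if (p <= 0) continue;
        px[a] += p; py[b] += p;
        pxy[a + b] += p;
        pdiff[std::abs(a - b)] += p;
        asm_ += p * p;
        con += (a - b) * (a - b) * p;
        idm += p / (1.0 + (a - b) * (a - b));
        ent -= p * std::log(p);
        sij += (double)(a + 1) * (b + 1) * p;   // 1-based level indices
      }
    }
    double mux = 0, muy = 0, sx = 0, sy = 0, hx = 0, hy = 0;
    for (int a = 0; a < L; ++a) {
      mux += (a + 1) * px[a];
      muy += (a + 1) * py[a];
      if (px[a] > 0) hx -= px[a] * std::log(px[a]);
      if (py[a] > 0) hy -= py[a] * std::log(py[a]);
    }
    for (int a = 0; a < L; ++a) {
      sx += (a + 1 - mux) * (a + 1 - mux) * px[a];
      sy += (a + 1 - muy) * (a + 1 - muy) * py[a];
    }
    sx = std::sqrt(sx); sy = std::sqrt(sy);
    double cor = (sx > 0 && sy > 0) ? (sij - mux * muy) / (sx * sy) : 0.0;
    double ssv = 0;   // sum of squares: variance about the marginal mean
    for (int a = 0; a < L; ++a)
      for (int b = 0; b < L; ++b)
        ssv += (a + 1 - mux) * (a + 1 - mux) * P[a * L + b];
    double sav = 0, sen = 0;
    for (int k = 0; k < 2 * L; ++k) {
      double p = pxy[k];
      if (p <= 0) continue;
      sav += (k + 2) * p;              // k = (a+1)+(b+1)-2
      sen -= p * std::log(p);
    }
    double sva = 0;
    for (int k = 0; k < 2 * L; ++k)
      sva += (k + 2 - sen) * (k + 2 - sen) * pxy[k];   // classic f7 (centred at f8)
    double mud = 0, doe = 0;
    for (int k = 0; k < L; ++k) {
      mud += k * pdiff[k];
      if (pdiff[k] > 0) doe -= pdiff[k] * std::log(pdiff[k]);
    }
    double dva = 0;
    for (int k = 0; k < L; ++k) dva += (k - mud) * (k - mud) * pdiff[k];
    // information measures of correlation
    double hxy1 = 0, hxy2 = 0;
    for (int a = 0; a < L; ++a) {
      for (int b = 0; b < L; ++b) {
        double q = px[a] * py[b];
        if (q <= 0) continue;
        hxy2 -= q * std::log(q);
        double p = P[a * L + b];
        if (p > 0) hxy1 -= p * std::log(q);
      }
    }
    double hmax = std::max(hx, hy);
    double imoc1 = (hmax > 0) ? (ent - hxy1) / hmax : 0.0;
    double arg = 1.0 - std::exp(-2.0 * (hxy2 - ent));
    double imoc2 = (arg > 0) ? std::sqrt(arg) : 0.0;

    out(i, 0) = asm_; out(i, 1) = con;  out(i, 2) = cor;  out(i, 3) = ssv;
    out(i, 4) = idm;  out(i, 5) = sav;  out(i, 6) = sva;  out(i, 7) = sen;
    out(i, 8) = ent;  out(i, 9) = dva;  out(i, 10) = doe; out(i, 11) = imoc1;
    out(i, 12) = imoc2;
  }
  return out;
}

// ---------------------------------------------------------------------------
// L1-penalized logistic regression over a lambda path: IRLS with cyclic
// coordinate descent on the penalized weighted least-squares subproblem,
// warm starts along the path. X is expected standardized; the intercept is
// unpenalized. Objective (reported per outer iteration for the last lambda):
//   -(1/n) sum_i [y_i log p_i + (1-y_i) log(1-p_i)] + lambda * ||beta||_1
// ---------------------------------------------------------------------------

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// [[Rcpp::export(name = ".cc_lasso_logistic_path")]]
List cc_lasso_logistic_path(NumericMatrix X, NumericVector y,
                            NumericVector lambdas, double tol, int maxit) {
  int n = X.nrow(), p = X.ncol(), nl = lambdas.size();
  NumericMatrix B(p, nl);
  NumericVector B0(nl);
  List obj_trace(nl);

  std::vector<double> beta(p, 0.0);
  double b0 = 0.0;
  {
    double ybar = mean(y);
    ybar = std::min(std::max(ybar, 1e-10), 1.0 - 1e-10);
    b0 = std::log(ybar / (1.0 - ybar));
  }
  std::vector<double> eta(n), pr(n), w(n), z(n);

  for (int l = 0; l < nl; ++l) {
    double lam = lambdas[l];
    std::vector<double> objs;
    for (int outer = 0; outer < maxit; ++outer) {
      // IRLS weights / working response at current coefficients
      for (int i = 0; i < n; ++i) {
        double e = b0;
        for (int j = 0; j < p; ++j) if (beta[j] != 0.0) e += X(i, j) * beta[j];
        eta[i] = e;
        double pi = 1.0 / (1.0 + std::exp(-e));
        pi = std::min(std::max(pi, 1e-5), 1.0 - 1e-5);
        pr[i] = pi;
        w[i] = pi * (1.0 - pi);
        z[i] = e + (y[i] - pi) / w[i];
      }
      // penalized objective at current state
      double nll = 0.0;
      for (int i = 0; i < n; ++i)
        nll -= y[i] * std::log(pr[i]) + (1.0 - y[i]) * std::log(1.0 - pr[i]);
      double l1 = 0.0;
      for (int j = 0; j < p; ++j) l1 += std::fabs(beta[j]);
      objs.push_back(nll / n + lam * l1);

      // coordinate descent on the weighted least-squares approximation,
      // with the usual active-set strategy: full sweeps only to admit new
      // features, repeated sweeps over the active set in between
      std::vector<double> res(n);  // z - eta_current
      for (int i = 0; i < n; ++i) res[i] = z[i] - eta[i];
      std::vector<double> swx2(p, 0.0);
      for (int j = 0; j < p; ++j) {
        double s2 = 0;
        for (int i = 0; i < n; ++i) s2 += w[i] * X(i, j) * X(i, j);
        swx2[j] = s2;
      }
      // convergence is judged on the weighted squared coefficient change
      // (the usual coordinate-descent stopping rule), which is robust to
      // the slow zig-zag of heavily correlated feature columns
      auto update_coord = [&](int j) -> double {
        if (swx2[j] <= 0) return 0.0;
        double swxr = 0;
        for (int i = 0; i < n; ++i) swxr += w[i] * X(i, j) * res[i];
        double zj = swxr / n + (swx2[j] / n) * beta[j];
        double nb = soft(zj, lam) / (swx2[j] / n);
        double d = nb - beta[j];
        if (d != 0.0) {
          for (int i = 0; i < n; ++i) res[i] -= d * X(i, j);
          beta[j] = nb;
        }
        return (swx2[j] / n) * d * d;
      };
      auto update_intercept = [&]() -> double {
        double sw = 0, swr = 0;
        for (int i = 0; i < n; ++i) { sw += w[i]; swr += w[i] * res[i]; }
        double d = swr / sw;
        for (int i = 0; i < n; ++i) res[i] -= d;
        b0 += d;
        return (sw / n) * d * d;
      };
      for (int cycle = 0; cycle < maxit; ++cycle) {
        // full sweep
        double cd_delta = update_intercept();
        for (int j = 0; j < p; ++j) cd_delta = std::max(cd_delta, update_coord(j));
        if (cd_delta < tol) break;
        // active-set sweeps
        std::vector<int> active;
        for (int j = 0; j < p; ++j) if (beta[j] != 0.0) active.push_back(j);
        for (int sweep = 0; sweep < maxit; ++sweep) {
          double d2 = update_intercept();
          for (size_t a = 0; a < active.size(); ++a)
            d2 = std::max(d2, update_coord(active[a]));
          if (d2 < tol) break;
        }
      }
      // outer convergence: weighted squared change of the linear predictor
      double outer_delta = 0.0;
      for (int i = 0; i < n; ++i) {
        double d = z[i] - res[i] - eta[i];
        outer_delta = std::max(outer_delta, w[i] * d * d);
      }
      if (outer_delta < tol) break;
    }
    for (int j = 0; j < p; ++j) B(j, l) = beta[j];
    B0[l] = b0;
    obj_trace[l] = wrap(objs);
  }
  return List::create(_["beta"] = B, _["intercept"] = B0,
                      _["objective"] = obj_trace);
}

// ---------------------------------------------------------------------------
// 8-connected component labelling of a binary mask (BFS, raster-scan seed
// order so label ids are deterministic).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cc_label8")]]
IntegerMatrix cc_label8(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        int lin = stack.back(); stack.pop_back();
        int rr = lin % nr, cc2 = lin / nr;
        for (int k = 0; k < 8; ++k) {
          int r2 = rr + dr8[k], c2 = cc2 + dc8[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) != 0 && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return lab;
}
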