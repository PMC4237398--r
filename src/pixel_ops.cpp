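#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
using namespace Rcpp;

// Pixel-level primitives shared by the patch metrics and distance code.
// Matrices are R column-major; (r, c) indexes with r fastest.

// [[Rcpp::export]]
IntegerMatrix label_components_cpp(const LogicalMatrix& focal, int connectivity) {
  const int nr = focal.nrow(), nc = focal.ncol();
  IntegerMatrix labels(nr, nc);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int nn = (connectivity == 8) ? 8 : 4;
  const int* dr = (connectivity == 8) ? dr8 : dr4;
  const int* dc = (connectivity == 8) ? dc8 : dc4;

  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!focal(r, c) || labels(r, c) != 0) continue;
      ++next;
      labels(r, c) = next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int i = 0; i < nn; ++i) {
          int rr = p.first + dr[i], cc = p.second + dc[i];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (focal(rr, cc) && labels(rr, cc) == 0) {
            labels(rr, cc) = next;
            q.push(std::make_pair(rr, cc));
          }
        }
      }
    }
  }
  labels.attr("n") = next;
  return labels;
}

// Per-patch count of exposed 4-neighbour pixel faces.
// status codes for off-patch pixels: 0 = non-focal land, 1 = nodata,
// faces against the grid boundary behave like nodata.
// include_boundary: count faces against nodata/grid boundary as edge.
// [[Rcpp::export]]
NumericVector patch_edge_faces_cpp(const IntegerMatrix& labels,
                                   const LogicalMatrix& nodata,
                                   int n_patches,
                                   bool include_boundary) {
  const int nr = labels.nrow(), nc = labels.ncol();
  NumericVector faces(n_patches);
  const int dr[4] = {-1, 0, 0, 1};
  const int dc[4] = {0, -1, 1, 0};
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int lab = labels(r, c);
      if (lab == 0) continue;
      for (int i = 0; i < 4; ++i) {
        int rr = r + dr[i], cc = c + dc[i];
        bool outside = (rr < 0 || rr >= nr || cc < 0 || cc >= nc);
        if (outside || nodata(rr, cc)) {
          if (include_boundary) faces[lab - 1] += 1.0;
        } else if (labels(rr, cc) != lab) {
          faces[lab - 1] += 1.0;
        }
      }
    }
  }
  return faces;
}

// 1-D squared distance transform (Felzenszwalb & Huttenlocher 2012).
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Exact Euclidean distance transform: squared pixel distance to the nearest
// TRUE seed, Inf when no seed exists. A large finite sentinel stands in for
// "no seed" inside the 1-D passes (the FH recursion is not Inf-safe).
// [[Rcpp::export]]
NumericMatrix edt_sq_cpp(const LogicalMatrix& seed) {
  const int nr = seed.nrow(), nc = seed.ncol();
  const double BIG = 1e15;  // >> nr^2 + nc^2 for any sane raster
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = seed(r, c) ? 0.0 : BIG;

  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) f[r] = out(r, c);
    dt1d(f, d, nr);
    for (int r = 0; r < nr; ++r) out(r, c) = d[r];
  }
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f[c] = out(r, c);
    dt1d(f, d, nc);
    for (int c = 0; c < nc; ++c) out(r, c) = d[c];
  }
  const double cutoff = (double)nr * nr + (double)nc * nc + 1.0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (out(r, c) > cutoff) out(r, c) = R_PosInf;
  return out;
}

// Multi-source BFS growth: propagate assigned class codes (> 0) into
// unassigned land pixels (0), 4-neighbour, seeds processed in scan order.
// Pixels where land is false are left untouched.
// [[Rcpp::export]]
IntegerMatrix grow_classes_cpp(const IntegerMatrix& classes,
                               const LogicalMatrix& land) {
  const int nr = classes.nrow(), nc = classes.ncol();
  IntegerMatrix out = clone(classes);
  std::queue<std::pair<int, int> > q;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (out(r, c) > 0 && land(r, c)) q.push(std::make_pair(r, c));
  const int dr[4] = {-1, 0, 0, 1};
  const int dc[4] = {0, -1, 1, 0};
  while (!q.empty()) {
    std::pair<int, int> p = q.front();
    q.pop();
    int cls = out(p.first, p.second);
    for (int i = 0; i < 4; ++i) {
      int rr = p.first + dr[i], cc = p.second + dc[i];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (land(rr, cc) && out(rr, cc) == 0) {
        out(rr, cc) = cls;
        q.push(std::make_pair(rr, cc));
      }
    }
  }
  return out;
}
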