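#include <Rcpp.h>
#include <map>
#include <queue>
#include <utility>
#include <vector>

using namespace Rcpp;

// Connectivity is 8-connected (2D) / 26-connected (3D) throughout.
// Linear indices are 0-based, column-major with dim = (nx, ny, nz).

namespace {

struct Grid {
  int nx, ny, nz;
  Grid(IntegerVector dim) {
    nx = dim[0];
    ny = dim.size() > 1 ? dim[1] : 1;
    nz = dim.size() > 2 ? dim[2] : 1;
  }
  int n() const { return nx * ny * nz; }
  // collect linear indices of all in-bounds neighbours of i into out;
  // returns the count
  int neighbours(int i, std::vector<int> &out) const {
    int x = i % nx, y = (i / nx) % ny, z = i / (nx * ny);
    out.clear();
    for (int dz = -1; dz <= 1; ++dz) {
      int zz = z + dz;
      if (zz < 0 || zz >= nz) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int yy = y + dy;
        if (yy < 0 || yy >= ny) continue;
        for (int dx = -1; dx <= 1; ++dx) {
          int xx = x + dx;
          if (xx < 0 || xx >= nx) continue;
          if (dx == 0 && dy == 0 && dz == 0) continue;
          out.push_back(xx + nx * (yy + ny * zz));
        }
      }
    }
    return (int)out.size();
  }
};

} // namespace

// Candidate maxima: single pixels, or connected equal-intensity plateaus,
// strictly above background B and strictly above every adjacent
// non-plateau pixel. Returns a plateau label grid (1..k, raster order of
// the first-scanned member) plus per-candidate value and centroid
// (0-based, unweighted mean of plateau pixel coordinates).
// [[Rcpp::export]]
List cpp_candidates(NumericVector v, IntegerVector dim, double B) {
  Grid g(dim);
  int n = g.n();
  IntegerVector labels(n, 0);
  std::vector<int> nb;
  std::vector<char> ismax(n, 0);
  for (int i = 0; i < n; ++i) {
    if (!(v[i] > B)) continue;
    g.neighbours(i, nb);
    bool ok = true;
    for (size_t k = 0; k < nb.size(); ++k)
      if (v[nb[k]] > v[i]) { ok = false; break; }
    ismax[i] = ok;
  }
  std::vector<double> val, cx, cy, cz;
  std::vector<int> maxidx;
  std::vector<char> seen(n, 0);
  int next = 0;
  std::vector<int> comp;
  for (int i = 0; i < n; ++i) {
    if (!ismax[i] || seen[i]) continue;
    // flood over equal-valued is-max pixels; reject if any member touches
    // an equal-valued pixel that is not a strict candidate (the plateau
    // then leaks downhill through it)
    comp.clear();
    bool valid = true;
    std::queue<int> q;
    q.push(i);
    seen[i] = 1;
    while (!q.empty()) {
      int p = q.front();
      q.pop();
      comp.push_back(p);
      g.neighbours(p, nb);
      for (size_t k = 0; k < nb.size(); ++k) {
        int j = nb[k];
        if (v[j] != v[i]) continue;
        if (!ismax[j]) { valid = false; continue; }
        if (!seen[j]) { seen[j] = 1; q.push(j); }
      }
    }
    if (!valid) continue;
    ++next;
    double sx = 0, sy = 0, sz = 0;
    for (size_t k = 0; k < comp.size(); ++k) {
      int p = comp[k];
      labels[p] = next;
      sx += p % g.nx;
      sy += (p / g.nx) % g.ny;
      sz += p / (g.nx * g.ny);
    }
    double m = (double)comp.size();
    double ccx = sx / m, ccy = sy / m, ccz = sz / m;
    // representative pixel: plateau member closest to the centroid,
    // ties by raster order (comp is BFS order; re-scan deterministic)
    int best = comp[0];
    double bd = R_PosInf;
    std::vector<int> sorted(comp);
    std::sort(sorted.begin(), sorted.end());
    for (size_t k = 0; k < sorted.size(); ++k) {
      int p = sorted[k];
      double dx = p % g.nx - ccx, dy = (p / g.nx) % g.ny - ccy,
             dz = p / (g.nx * g.ny) - ccz;
      double dd = dx * dx + dy * dy + dz * dz;
      if (dd < bd - 1e-12) { bd = dd; best = p; }
    }
    val.push_back(v[i]);
    maxidx.push_back(best);
    cx.push_back(ccx);
    cy.push_back(ccy);
    cz.push_back(ccz);
  }
  return List::create(_["labels"] = labels, _["value"] = wrap(val),
                      _["max_idx"] = wrap(maxidx), _["cx"] = wrap(cx),
                      _["cy"] = wrap(cy), _["cz"] = wrap(cz));
}

// Uphill-gradient expansion: pixels above B are visited in descending
// intensity (ties by ascending linear/raster index); each unlabelled
// pixel takes the label of its highest-intensity already-labelled
// neighbour (ties by lowest label id, then raster order of the
// neighbour). Pixels with no labelled neighbour at their turn stay 0.
// [[Rcpp::export]]
IntegerVector cpp_expand(NumericVector v, IntegerVector dim,
                         IntegerVector cand_labels, double B) {
  Grid g(dim);
  int n = g.n();
  IntegerVector labels = clone(cand_labels);
  std::vector<int> ord;
  ord.reserve(n);
  for (int i = 0; i < n; ++i)
    if (v[i] > B) ord.push_back(i);
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (v[a] != v[b]) return v[a] > v[b];
    return a < b;
  });
  std::vector<int> nb;
  for (size_t t = 0; t < ord.size(); ++t) {
    int i = ord[t];
    if (labels[i] != 0) continue;
    g.neighbours(i, nb);
    double bestv = R_NegInf;
    int bestlab = 0, bestj = -1;
    for (size_t k = 0; k < nb.size(); ++k) {
      int j = nb[k];
      int lj = labels[j];
      if (lj == 0) continue;
      if (v[j] > bestv || (v[j] == bestv && (lj < bestlab ||
          (lj == bestlab && j < bestj)))) {
        bestv = v[j];
        bestlab = lj;
        bestj = j;
      }
    }
    if (bestlab > 0) labels[i] = bestlab;
  }
  return labels;
}

// Saddles: for every pair of adjacent pixels with different positive
// labels, the candidate saddle is the lower of the two intensities; the
// saddle of a touching pair of peaks is the maximum candidate. One row
// per unordered pair (a < b).
// [[Rcpp::export]]
DataFrame cpp_saddles(NumericVector v, IntegerVector dim,
                      IntegerVector labels) {
  Grid g(dim);
  int n = g.n();
  std::map<std::pair<int, int>, double> sad;
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    int a = labels[i];
    if (a == 0) continue;
    g.neighbours(i, nb);
    for (size_t k = 0; k < nb.size(); ++k) {
      int j = nb[k];
      if (j < i) continue;
      int b = labels[j];
      if (b == 0 || b == a) continue;
      std::pair<int, int> key(std::min(a, b), std::max(a, b));
      double s = std::min(v[i], v[j]);
      auto it = sad.find(key);
      if (it == sad.end() || s > it->second) sad[key] = s;
    }
  }
  int m = (int)sad.size();
  IntegerVector pa(m), pb(m);
  NumericVector ps(m);
  int r = 0;
  for (auto it = sad.begin(); it != sad.end(); ++it, ++r) {
    pa[r] = it->first.first;
    pb[r] = it->first.second;
    ps[r] = it->second;
  }
  return DataFrame::create(_["peak_id"] = pa, _["neighbour_id"] = pb,
                           _["saddle_value"] = ps);
}
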