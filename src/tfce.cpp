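// Threshold-free cluster enhancement on ROI-to-ROI statistic matrices,
// plus the connected-component labelling both neighbourhood rules use.
//
// Two neighbourhood rules:
//   0 "matrix_image_4": the (ROI-sorted) N x N symmetric matrix is treated
//     as a 2-D image; suprathreshold entries are neighbours when adjacent
//     horizontally or vertically, both symmetric halves present in the
//     image. Component extent = number of suprathreshold entries.
//   1 "edge_graph": suprathreshold edges (i < j) are neighbours when they
//     share an ROI. Component extent = number of suprathreshold edges.

#include <Rcpp.h>
#include <vector>
#include <stack>
using namespace Rcpp;

// 4-connected component labelling of a binary mask (diagonal entries of a
// stat matrix are 0 and fall below any positive level on their own).
// [[Rcpp::export]]
IntegerMatrix cpp_label_image4(const LogicalMatrix& mask) {
  const int n = mask.nrow(), m = mask.ncol();
  IntegerMatrix lab(n, m);
  int next = 0;
  std::stack<std::pair<int, int> > st;
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      st.push(std::make_pair(i, j));
      lab(i, j) = next;
      while (!st.empty()) {
        int ci = st.top().first, cj = st.top().second;
        st.pop();
        const int di[4] = {-1, 1, 0, 0};
        const int dj[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          int ni = ci + di[k], nj = cj + dj[k];
          if (ni < 0 || ni >= n || nj < 0 || nj >= m) continue;
          if (mask(ni, nj) && !lab(ni, nj)) {
            lab(ni, nj) = next;
            st.push(std::make_pair(ni, nj));
          }
        }
      }
    }
  }
  return lab;
}

namespace {

struct UF {
  std::vector<int> p;
  UF(int n) : p(n) { for (int i = 0; i < n; ++i) p[i] = i; }
  int find(int x) { while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; } return x; }
  void unite(int a, int b) { p[find(a)] = find(b); }
};

}  // namespace

// Component labels for the edge-graph rule: labels both (i,j) and (j,i)
// of each suprathreshold edge; 0 elsewhere. Components share an ROI.
// [[Rcpp::export]]
IntegerMatrix cpp_label_edge_graph(const LogicalMatrix& mask) {
  const int n = mask.nrow();
  UF uf(n);
  for (int j = 1; j < n; ++j)
    for (int i = 0; i < j; ++i)
      if (mask(i, j)) uf.unite(i, j);
  // densify root ids over edges only
  IntegerMatrix lab(n, n);
  std::vector<int> remap(n, 0);
  int next = 0;
  for (int j = 1; j < n; ++j)
    for (int i = 0; i < j; ++i)
      if (mask(i, j)) {
        int r = uf.find(i);
        if (!remap[r]) remap[r] = ++next;
        lab(i, j) = lab(j, i) = remap[r];
      }
  return lab;
}

// One-tailed TFCE: stat is a symmetric non-negative matrix (one tail of a
// signed map), already in ROI-sorted order for the image neighbourhood.
// Midpoint discretization of the height integral over n_steps levels from
// h0 to max(stat). Buffers are reused across levels; flood fill uses a
// preallocated index stack.
// [[Rcpp::export]]
NumericMatrix cpp_tfce_tail(const NumericMatrix& stat, double E, double H,
                            int n_steps, double h0, int neighbourhood) {
  const int n = stat.nrow();
  const int nn = n * n;
  NumericMatrix out(n, n);
  const double* sp = stat.begin();
  double* op = out.begin();
  double hmax = 0;
  for (int k = 0; k < nn; ++k)
    if (sp[k] > hmax) hmax = sp[k];
  if (hmax <= h0) return out;
  const double dh = (hmax - h0) / n_steps;

  std::vector<int> lab(nn);
  std::vector<int> stk(nn);
  std::vector<double> extent;
  std::vector<double> inc;
  std::vector<int> parent(n), remap(n);

  for (int s = 0; s < n_steps; ++s) {
    const double h = h0 + (s + 0.5) * dh;
    const double hH = std::pow(h, H) * dh;
    int ncomp = 0;
    std::fill(lab.begin(), lab.end(), 0);

    if (neighbourhood == 0) {
      // 4-connected components of the suprathreshold image
      for (int start = 0; start < nn; ++start) {
        if (sp[start] < h || lab[start]) continue;
        ++ncomp;
        int top = 0;
        stk[top++] = start;
        lab[start] = ncomp;
        int cnt = 0;
        while (top) {
          const int cur = stk[--top];
          ++cnt;
          const int i = cur % n, j = cur / n;
          if (i > 0     && sp[cur - 1] >= h && !lab[cur - 1]) { lab[cur - 1] = ncomp; stk[top++] = cur - 1; }
          if (i < n - 1 && sp[cur + 1] >= h && !lab[cur + 1]) { lab[cur + 1] = ncomp; stk[top++] = cur + 1; }
          if (j > 0     && sp[cur - n] >= h && !lab[cur - n]) { lab[cur - n] = ncomp; stk[top++] = cur - n; }
          if (j < n - 1 && sp[cur + n] >= h && !lab[cur + n]) { lab[cur + n] = ncomp; stk[top++] = cur + n; }
        }
        if ((int)extent.size() < ncomp + 1) extent.resize(ncomp + 1);
        extent[ncomp] = cnt;
      }
    } else {
      // edge-graph components: union-find over ROIs
      for (int i = 0; i < n; ++i) parent[i] = i;
      bool any = false;
      for (int j = 1; j < n; ++j)
        for (int i = 0; i < j; ++i)
          if (sp[i + j * n] >= h) {
            any = true;
            int a = i, b = j;
            while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
            while (parent[b] != b) { parent[b] = parent[parent[b]]; b = parent[b]; }
            if (a != b) parent[a] = b;
          }
      if (!any) continue;
      std::fill(remap.begin(), remap.end(), 0);
      if ((int)extent.size() < n + 1) extent.resize(n + 1);
      for (int j = 1; j < n; ++j)
        for (int i = 0; i < j; ++i)
          if (sp[i + j * n] >= h) {
            int r = i;
            while (parent[r] != r) r = parent[r];
            if (!remap[r]) { remap[r] = ++ncomp; extent[ncomp] = 0; }
            const int c = remap[r];
            lab[i + j * n] = c;
            lab[j + i * n] = c;
            extent[c] += 1.0;
          }
    }
    if (!ncomp) continue;

    if ((int)inc.size() < ncomp + 1) inc.resize(ncomp + 1);
    for (int c = 1; c <= ncomp; ++c)
      inc[c] = std::pow(extent[c], E) * hH;
    for (int k = 0; k < nn; ++k)
      if (lab[k]) op[k] += inc[lab[k]];
  }
  return out;
}
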