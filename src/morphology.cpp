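// Low-level image morphology kernels: seeded watershed flooding, grey-scale
// erosion/dilation, morphological reconstruction, regional maxima, connected
// components and hole filling. All matrices are column-major (R layout),
// coordinates are (row, col). Connectivity is 8 unless stated otherwise.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>

using namespace Rcpp;

namespace {

struct PqItem {
  double value;
  unsigned long age; // FIFO tie-break -> deterministic flooding
  int idx;
  int label; // basin the pixel was reached from
};

struct PqCompare {
  bool operator()(const PqItem& a, const PqItem& b) const {
    if (a.value != b.value) return a.value > b.value; // min-heap on value
    return a.age > b.age;
  }
};

inline void neighbours(int idx, int nr, int nc, int conn, int* out, int* n_out) {
  int r = idx % nr, c = idx / nr;
  int k = 0;
  for (int dc = -1; dc <= 1; ++dc) {
    for (int dr = -1; dr <= 1; ++dr) {
      if (dr == 0 && dc == 0) continue;
      if (conn == 4 && dr != 0 && dc != 0) continue;
      int rr = r + dr, cc = c + dc;
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      out[k++] = rr + cc * nr;
    }
  }
  *n_out = k;
}

} // namespace

// Meyer's seeded watershed on a relief. markers: 0 = unlabeled, >0 = seed
// labels. Every pixel receives the label of the basin that floods it first
// (no watershed-line pixels; boundaries are recovered from label changes).
// [[Rcpp::export]]
IntegerMatrix cpp_ws_flood(NumericMatrix relief, IntegerMatrix markers,
                           int conn = 8) {
  int nr = relief.nrow(), nc = relief.ncol(), n = nr * nc;
  if (markers.nrow() != nr || markers.ncol() != nc)
    stop("relief and markers must be congruent");
  IntegerMatrix labels(nr, nc);
  std::vector<char> queued(n, 0);
  std::priority_queue<PqItem, std::vector<PqItem>, PqCompare> pq;
  unsigned long age = 0;
  int nb[8], k;

  for (int i = 0; i < n; ++i) {
    labels[i] = markers[i];
    if (markers[i] > 0) queued[i] = 1;
  }
  for (int i = 0; i < n; ++i) {
    if (labels[i] > 0) {
      neighbours(i, nr, nc, conn, nb, &k);
      for (int j = 0; j < k; ++j) {
        int m = nb[j];
        if (!queued[m]) {
          queued[m] = 1;
          pq.push({relief[m], age++, m, labels[i]});
        }
      }
    }
  }
  while (!pq.empty()) {
    PqItem it = pq.top();
    pq.pop();
    int i = it.idx;
    if (labels[i] > 0) continue;
    labels[i] = it.label; // basin that reached the pixel first
    neighbours(i, nr, nc, conn, nb, &k);
    for (int j = 0; j < k; ++j) {
      int m = nb[j];
      if (!queued[m]) {
        queued[m] = 1;
        pq.push({relief[m], age++, m, it.label});
      }
    }
  }
  return labels;
}

// Grey-scale dilation/erosion with an arbitrary structuring element given as
// offset vectors (dr, dc). Out-of-frame samples are ignored (border = -Inf
// for dilation, +Inf for erosion), the EBImage convention.
// [[Rcpp::export]]
NumericMatrix cpp_grey_morph(NumericMatrix img, IntegerVector dr,
                             IntegerVector dc, bool dilate) {
  int nr = img.nrow(), nc = img.ncol(), ns = dr.size();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double best = dilate ? -std::numeric_limits<double>::infinity()
                           : std::numeric_limits<double>::infinity();
      for (int s = 0; s < ns; ++s) {
        int rr = r + dr[s], cc = c + dc[s];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        double v = img(rr, cc);
        if (dilate ? (v > best) : (v < best)) best = v;
      }
      out(r, c) = best;
    }
  }
  return out;
}

// Morphological reconstruction by dilation (Vincent's hybrid algorithm):
// largest image <= mask whose peaks grow from marker. Requires
// marker <= mask everywhere. 8-connectivity.
// [[Rcpp::export]]
NumericMatrix cpp_reconstruct_dilate(NumericMatrix marker, NumericMatrix mask) {
  int nr = marker.nrow(), nc = marker.ncol(), n = nr * nc;
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("marker and mask must be congruent");
  NumericMatrix J(nr, nc);
  for (int i = 0; i < n; ++i) {
    if (marker[i] > mask[i]) stop("marker must be <= mask everywhere");
    J[i] = marker[i];
  }
  int nb[8], k;
  // raster scan (N+ neighbourhood: already-visited neighbours)
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double m = J(r, c);
      for (int dc2 = -1; dc2 <= 0; ++dc2) {
        for (int dr2 = -1; dr2 <= 1; ++dr2) {
          if (dc2 == 0 && dr2 >= 0) continue;
          int rr = r + dr2, cc = c + dc2;
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (J(rr, cc) > m) m = J(rr, cc);
        }
      }
      J(r, c) = std::min(m, mask(r, c));
    }
  }
  // anti-raster scan + queue seeding
  std::queue<int> fifo;
  for (int c = nc - 1; c >= 0; --c) {
    for (int r = nr - 1; r >= 0; --r) {
      double m = J(r, c);
      for (int dc2 = 0; dc2 <= 1; ++dc2) {
        for (int dr2 = -1; dr2 <= 1; ++dr2) {
          if (dc2 == 0 && dr2 <= 0) continue;
          int rr = r + dr2, cc = c + dc2;
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (J(rr, cc) > m) m = J(rr, cc);
        }
      }
      J(r, c) = std::min(m, mask(r, c));
      // queue if some N- neighbour could still grow
      int idx = r + c * nr;
      neighbours(idx, nr, nc, 8, nb, &k);
      for (int j = 0; j < k; ++j) {
        int q = nb[j];
        if (J[q] < J[idx] && J[q] < mask[q]) {
          fifo.push(idx);
          break;
        }
      }
    }
  }
  while (!fifo.empty()) {
    int i = fifo.front();
    fifo.pop();
    neighbours(i, nr, nc, 8, nb, &k);
    for (int j = 0; j < k; ++j) {
      int q = nb[j];
      if (J[q] < J[i] && mask[q] != J[q]) {
        double v = std::min(J[i], mask[q]);
        if (v > J[q]) {
          J[q] = v;
          fifo.push(q);
        }
      }
    }
  }
  return J;
}

// Regional maxima: connected plateaus with no strictly greater neighbour.
// [[Rcpp::export]]
LogicalMatrix cpp_regional_maxima(NumericMatrix img, int conn = 8) {
  int nr = img.nrow(), nc = img.ncol(), n = nr * nc;
  std::vector<char> state(n, 0); // 0 unknown, 1 max, 2 not max
  LogicalMatrix out(nr, nc);
  int nb[8], k;
  std::vector<int> plateau;
  std::queue<int> fifo;
  for (int i = 0; i < n; ++i) {
    if (state[i] != 0) continue;
    double v = img[i];
    plateau.clear();
    bool is_max = true;
    fifo.push(i);
    state[i] = 1;
    plateau.push_back(i);
    while (!fifo.empty()) {
      int p = fifo.front();
      fifo.pop();
      neighbours(p, nr, nc, conn, nb, &k);
      for (int j = 0; j < k; ++j) {
        int q = nb[j];
        if (img[q] > v) {
          is_max = false;
        } else if (img[q] == v && state[q] == 0) {
          state[q] = 1;
          fifo.push(q);
          plateau.push_back(q);
        }
      }
    }
    if (!is_max)
      for (size_t j = 0; j < plateau.size(); ++j) state[plateau[j]] = 2;
  }
  for (int i = 0; i < n; ++i) out[i] = (state[i] == 1);
  return out;
}

// Connected-component labeling of a binary mask.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int conn = 8) {
  int nr = mask.nrow(), nc = mask.ncol(), n = nr * nc;
  IntegerMatrix labels(nr, nc);
  int next = 0, nb[8], k;
  std::queue<int> fifo;
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] > 0) continue;
    ++next;
    labels[i] = next;
    fifo.push(i);
    while (!fifo.empty()) {
      int p = fifo.front();
      fifo.pop();
      neighbours(p, nr, nc, conn, nb, &k);
      for (int j = 0; j < k; ++j) {
        int q = nb[j];
        if (mask[q] && labels[q] == 0) {
          labels[q] = next;
          fifo.push(q);
        }
      }
    }
  }
  return labels;
}

// Fill holes: background components (4-connected) not touching the border
// become foreground.
// [[Rcpp::export]]
LogicalMatrix cpp_fill_holes(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol(), n = nr * nc;
  std::vector<char> outside(n, 0);
  std::queue<int> fifo;
  int nb[8], k;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (r != 0 && r != nr - 1 && c != 0 && c != nc - 1) continue;
      int i = r + c * nr;
      if (!mask[i] && !outside[i]) {
        outside[i] = 1;
        fifo.push(i);
      }
    }
  }
  while (!fifo.empty()) {
    int p = fifo.front();
    fifo.pop();
    neighbours(p, nr, nc, 4, nb, &k);
    for (int j = 0; j < k; ++j) {
      int q = nb[j];
      if (!mask[q] && !outside[q]) {
        outside[q] = 1;
        fifo.push(q);
      }
    }
  }
  LogicalMatrix out(nr, nc);
  for (int i = 0; i < n; ++i) out[i] = mask[i] || !outside[i];
  return out;
}
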