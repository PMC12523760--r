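#include <Rcpp.h>
using namespace Rcpp;

// Guo-Hall thinning of a binary mask to a 1-pixel, 8-connected skeleton.
// Two sub-iterations repeated to a fixed point, so the result is idempotent
// under re-thinning by construction. Guo-Hall is preferred over Zhang-Suen
// because it does not leave 2-pixel staircases on shallow diagonals.
// [[Rcpp::export]]
LogicalMatrix thin_mask_c(LogicalMatrix m) {
  const int nr = m.nrow(), nc = m.ncol();
  std::vector<unsigned char> img((size_t)nr * nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      img[(size_t)c * nr + r] = m(r, c) ? 1 : 0;

  auto at = [&](int r, int c) -> unsigned char {
    if (r < 0 || r >= nr || c < 0 || c >= nc) return 0;
    return img[(size_t)c * nr + r];
  };

  std::vector<size_t> kill;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int step = 0; step < 2; ++step) {
      kill.clear();
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (!img[(size_t)c * nr + r]) continue;
          // p2..p9 clockwise from north
          int p2 = at(r - 1, c),     p3 = at(r - 1, c + 1),
              p4 = at(r, c + 1),     p5 = at(r + 1, c + 1),
              p6 = at(r + 1, c),     p7 = at(r + 1, c - 1),
              p8 = at(r, c - 1),     p9 = at(r - 1, c - 1);
          int C = ((!p2) & (p3 | p4)) + ((!p4) & (p5 | p6)) +
                  ((!p6) & (p7 | p8)) + ((!p8) & (p9 | p2));
          int N1 = (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8);
          int N2 = (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9);
          int N = N1 < N2 ? N1 : N2;
          int mcond = (step == 0) ? ((p6 | p7 | (!p9)) & p8)
                                  : ((p2 | p3 | (!p5)) & p4);
          if (C == 1 && N >= 2 && N <= 3 && mcond == 0)
            kill.push_back((size_t)c * nr + r);
        }
      }
      if (!kill.empty()) {
        changed = true;
        for (size_t k : kill) img[k] = 0;
      }
    }
  }

  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = img[(size_t)c * nr + r] != 0;
  return out;
}

static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// Classify skeleton pixels by 8-neighbour count and trace the simple pixel
// paths joining node pixels (degree != 2). Node-free cycles get a synthetic
// anchor pixel. Returns 1-based column-major linear indices as used by R.
// [[Rcpp::export]]
List trace_skeleton_c(LogicalMatrix m) {
  const int nr = m.nrow(), nc = m.ncol();
  const size_t n = (size_t)nr * nc;
  std::vector<unsigned char> sk(n, 0);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      sk[(size_t)c * nr + r] = m(r, c) ? 1 : 0;

  auto inb = [&](int r, int c) { return r >= 0 && r < nr && c >= 0 && c < nc; };
  auto idx = [&](int r, int c) { return (size_t)c * nr + r; };

  IntegerMatrix deg(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!sk[idx(r, c)]) continue;
      int d = 0;
      for (int k = 0; k < 8; ++k) {
        int rr = r + DR[k], cc = c + DC[k];
        if (inb(rr, cc) && sk[idx(rr, cc)]) ++d;
      }
      deg(r, c) = d;
    }
  }

  auto isnode = [&](int r, int c) {
    return sk[idx(r, c)] && deg(r, c) != 2;
  };

  std::vector<unsigned char> used(n, 0);  // degree-2 pixels consumed by a path
  std::list<std::vector<int>> paths;      // each path: pixel linear indices (0-based)

  // walk from a node pixel (r0,c0) into its degree-2 neighbour (r1,c1)
  auto walk = [&](int r0, int c0, int r1, int c1) {
    std::vector<int> path;
    path.push_back((int)idx(r0, c0));
    int pr = r0, pc = c0, r = r1, cq = c1;
    used[idx(r, cq)] = 1;
    path.push_back((int)idx(r, cq));
    while (true) {
      int nxr = -1, nxc = -1;
      for (int k = 0; k < 8; ++k) {
        int rr = r + DR[k], cc = cq + DC[k];
        if (!inb(rr, cc) || !sk[idx(rr, cc)]) continue;
        if (rr == pr && cc == pc) continue;
        nxr = rr; nxc = cc;
        if (isnode(rr, cc)) break;  // prefer terminating at a node
      }
      if (nxr < 0) break;  // dead end (should not happen on degree-2 chains)
      path.push_back((int)idx(nxr, nxc));
      if (isnode(nxr, nxc)) break;
      if (used[idx(nxr, nxc)]) break;  // safety against loops
      used[idx(nxr, nxc)] = 1;
      pr = r; pc = cq; r = nxr; cq = nxc;
    }
    paths.push_back(path);
  };

  // edges incident to node pixels
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!isnode(r, c)) continue;
      for (int k = 0; k < 8; ++k) {
        int rr = r + DR[k], cc = c + DC[k];
        if (!inb(rr, cc) || !sk[idx(rr, cc)]) continue;
        if (isnode(rr, cc)) {
          // direct node-node adjacency; emit once
          if (idx(r, c) < idx(rr, cc)) {
            std::vector<int> p{(int)idx(r, c), (int)idx(rr, cc)};
            paths.push_back(p);
          }
        } else if (!used[idx(rr, cc)]) {
          walk(r, c, rr, cc);
        }
      }
    }
  }

  // node-free cycles: remaining unvisited degree-2 pixels
  std::vector<int> anchors;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!sk[idx(r, c)] || isnode(r, c) || used[idx(r, c)]) continue;
      // anchor this cycle here and trace it once around
      anchors.push_back((int)idx(r, c));
      used[idx(r, c)] = 1;
      std::vector<int> path;
      path.push_back((int)idx(r, c));
      int pr = r, pc = c, cr = -1, ccq = -1;
      for (int k = 0; k < 8; ++k) {
        int rr = r + DR[k], cc = c + DC[k];
        if (inb(rr, cc) && sk[idx(rr, cc)]) { cr = rr; ccq = cc; break; }
      }
      if (cr < 0) continue;
      while (true) {
        path.push_back((int)idx(cr, ccq));
        if (used[idx(cr, ccq)]) break;  // back at the anchor
        used[idx(cr, ccq)] = 1;
        int nxr = -1, nxc = -1;
        for (int k = 0; k < 8; ++k) {
          int rr = cr + DR[k], cc = ccq + DC[k];
          if (!inb(rr, cc) || !sk[idx(rr, cc)]) continue;
          if (rr == pr && cc == pc) continue;
          if (!used[idx(rr, cc)] || (int)idx(rr, cc) == anchors.back()) {
            nxr = rr; nxc = cc;
            if ((int)idx(rr, cc) == anchors.back()) break;
          }
        }
        if (nxr < 0) break;
        pr = cr; pc = ccq; cr = nxr; ccq = nxc;
      }
      paths.push_back(path);
    }
  }

  List pl(paths.size());
  int i = 0;
  for (auto &p : paths) {
    IntegerVector v(p.size());
    for (size_t j = 0; j < p.size(); ++j) v[j] = p[j] + 1;  // 1-based for R
    pl[i++] = v;
  }
  IntegerVector anc(anchors.size());
  for (size_t j = 0; j < anchors.size(); ++j) anc[j] = anchors[j] + 1;

  return List::create(_["deg"] = deg, _["paths"] = pl, _["anchors"] = anc);
}

// Windowed GLCM entropy. `q` holds quantized gray levels 1..levels (0 = skip).
// For each window the symmetric co-occurrence counts are accumulated over all
// supplied offsets, normalized, and reduced to -sum(p*log2(p)).
// [[Rcpp::export]]
NumericMatrix glcm_entropy_c(IntegerMatrix q, int window, int stride,
                             int levels, IntegerVector dr, IntegerVector dc) {
  const int nr = q.nrow(), nc = q.ncol();
  const int no = dr.size();
  const int wr = (nr - window) / stride + 1;
  const int wc = (nc - window) / stride + 1;
  NumericMatrix out(wr, wc);
  std::vector<double> counts((size_t)levels * levels);

  for (int wi = 0; wi < wr; ++wi) {
    for (int wj = 0; wj < wc; ++wj) {
      const int r0 = wi * stride, c0 = wj * stride;
      std::fill(counts.begin(), counts.end(), 0.0);
      double total = 0.0;
      for (int k = 0; k < no; ++k) {
        const int d_r = dr[k], d_c = dc[k];
        for (int c = c0; c < c0 + window; ++c) {
          const int cc = c + d_c;
          if (cc < c0 || cc >= c0 + window) continue;
          for (int r = r0; r < r0 + window; ++r) {
            const int rr = r + d_r;
            if (rr < r0 || rr >= r0 + window) continue;
            const int a = q(r, c), b = q(rr, cc);
            if (a < 1 || b < 1) continue;
            counts[(size_t)(a - 1) * levels + (b - 1)] += 1.0;
            counts[(size_t)(b - 1) * levels + (a - 1)] += 1.0;
            total += 2.0;
          }
        }
      }
      if (total <= 0) {
        out(wi, wj) = NA_REAL;
        continue;
      }
      double H = 0.0;
      for (double v : counts) {
        if (v > 0) {
          double p = v / total;
          H -= p * std::log2(p);
        }
      }
      out(wi, wj) = H;
    }
  }
  return out;
}

// Footprint of a polyline stroke: union of discs of given radius centred on
// each (row, col) point. Returns sorted 1-based linear pixel indices.
// [[Rcpp::export]]
IntegerVector stamp_path_c(IntegerVector rows, IntegerVector cols,
                           double radius, int nr, int nc) {
  const int np = rows.size();
  const int R = (int)std::floor(radius);
  const double r2 = radius * radius;
  std::vector<unsigned char> hit((size_t)nr * nc, 0);
  std::vector<int> out;
  for (int i = 0; i < np; ++i) {
    const int pr = rows[i] - 1, pc = cols[i] - 1;
    for (int dc = -R; dc <= R; ++dc) {
      for (int dr = -R; dr <= R; ++dr) {
        if (dr * dr + dc * dc > r2) continue;
        const int r = pr + dr, c = pc + dc;
        if (r < 0 || r >= nr || c < 0 || c >= nc) continue;
        const size_t id = (size_t)c * nr + r;
        if (!hit[id]) {
          hit[id] = 1;
          out.push_back((int)id + 1);
        }
      }
    }
  }
  std::sort(out.begin(), out.end());
  return IntegerVector(out.begin(), out.end());
}
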