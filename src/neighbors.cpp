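// Periodic neighbor searches for orthorhombic boxes.
//
// All routines assume coordinates in Angstrom and an orthorhombic box
// (3 positive edge lengths). The minimum-image convention is valid for
// pair cutoffs up to half the smallest box edge; callers enforce that.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline double min_image_d2(const double* a, const double* b,
                                  const double* box, bool periodic) {
  double d2 = 0.0;
  for (int k = 0; k < 3; ++k) {
    double d = a[k] - b[k];
    if (periodic) d -= box[k] * std::round(d / box[k]);
    d2 += d * d;
  }
  return d2;
}

// Simple cell list over an orthorhombic box. Cells are at least `width`
// wide so that all neighbors within `width` lie in the 27 surrounding
// cells (with periodic wrapping of cell indices).
struct CellList {
  int n[3];
  double lo[3], w[3], box[3];
  bool periodic;
  std::vector<std::vector<int> > cells;

  CellList(const NumericMatrix& coords, const std::vector<int>& idx,
           double width, const NumericVector& boxv, bool periodic_)
      : periodic(periodic_) {
    for (int k = 0; k < 3; ++k) box[k] = periodic_ ? boxv[k] : 0.0;
    if (periodic) {
      for (int k = 0; k < 3; ++k) {
        lo[k] = 0.0;
        n[k] = std::max(1, (int)std::floor(box[k] / width));
        w[k] = box[k] / n[k];
      }
    } else {
      double hi[3];
      for (int k = 0; k < 3; ++k) { lo[k] = R_PosInf; hi[k] = R_NegInf; }
      for (size_t i = 0; i < idx.size(); ++i)
        for (int k = 0; k < 3; ++k) {
          double v = coords(idx[i], k);
          if (v < lo[k]) lo[k] = v;
          if (v > hi[k]) hi[k] = v;
        }
      for (int k = 0; k < 3; ++k) {
        if (!R_FINITE(lo[k])) { lo[k] = 0.0; hi[k] = 0.0; }
        n[k] = std::max(1, (int)std::floor((hi[k] - lo[k]) / width) + 1);
        w[k] = width;
      }
    }
    cells.resize((size_t)n[0] * n[1] * n[2]);
    for (size_t i = 0; i < idx.size(); ++i)
      cells[cell_of(coords, idx[i])].push_back(idx[i]);
  }

  int clampwrap(int c, int k) const {
    if (periodic) {
      c %= n[k];
      if (c < 0) c += n[k];
      return c;
    }
    return std::min(std::max(c, 0), n[k] - 1);
  }

  size_t cell_of(const NumericMatrix& coords, int i) const {
    int c[3];
    for (int k = 0; k < 3; ++k) {
      double v = coords(i, k) - lo[k];
      if (periodic) {
        v -= box[k] * std::floor(v / box[k]);
        int ck = (int)std::floor(v / w[k]);
        c[k] = (ck >= n[k]) ? n[k] - 1 : ck; // guard fp edge
      } else {
        c[k] = clampwrap((int)std::floor(v / w[k]), k);
      }
    }
    return ((size_t)c[0] * n[1] + c[1]) * n[2] + c[2];
  }

  // Visit atoms in the 27 neighbor cells of point p (deduplicated when a
  // dimension has fewer than 3 cells). f returns true to stop early.
  template <typename F>
  bool visit_neighbors(const NumericMatrix& coords, const double* p, F f) const {
    int c[3];
    for (int k = 0; k < 3; ++k) {
      double v = p[k] - lo[k];
      if (periodic) v -= box[k] * std::floor(v / box[k]);
      int ck = (int)std::floor(v / w[k]);
      c[k] = periodic ? ((ck >= n[k]) ? n[k] - 1 : std::max(ck, 0))
                      : clampwrap(ck, k);
    }
    int lists[3][3], nls[3];
    for (int k = 0; k < 3; ++k) {
      nls[k] = 0;
      for (int d = -1; d <= 1; ++d) {
        int cc = clampwrap(c[k] + d, k);
        bool seen = false;
        for (int t = 0; t < nls[k]; ++t)
          if (lists[k][t] == cc) { seen = true; break; }
        if (!seen) lists[k][nls[k]++] = cc;
      }
    }
    for (int a = 0; a < nls[0]; ++a)
      for (int b = 0; b < nls[1]; ++b)
        for (int e = 0; e < nls[2]; ++e) {
          const std::vector<int>& cell =
              cells[((size_t)lists[0][a] * n[1] + lists[1][b]) * n[2] + lists[2][e]];
          for (size_t t = 0; t < cell.size(); ++t)
            if (f(cell[t])) return true;
        }
    return false;
  }
};

static std::vector<int> seq_idx(int n) {
  std::vector<int> v(n);
  for (int i = 0; i < n; ++i) v[i] = i;
  return v;
}

// [[Rcpp::export]]
NumericVector min_image_dist_cpp(NumericMatrix a, NumericMatrix b,
                                 NumericVector box) {
  int n = a.nrow();
  if (b.nrow() != n) stop("coordinate sets must have equal row counts");
  NumericVector out(n);
  double bx[3] = { box[0], box[1], box[2] };
  for (int i = 0; i < n; ++i) {
    double pa[3] = { a(i, 0), a(i, 1), a(i, 2) };
    double pb[3] = { b(i, 0), b(i, 1), b(i, 2) };
    out[i] = std::sqrt(min_image_d2(pa, pb, bx, true));
  }
  return out;
}

// For each sink atom: is any source atom within `cutoff` (minimum image)?
// [[Rcpp::export]]
LogicalVector sinks_within_cpp(NumericMatrix coords, IntegerVector src,
                               IntegerVector sink, double cutoff,
                               NumericVector box, bool periodic) {
  std::vector<int> sidx(src.begin(), src.end());
  CellList cl(coords, sidx, cutoff, box, periodic);
  double c2 = cutoff * cutoff;
  int ns = sink.size();
  LogicalVector out(ns);
  double bx[3] = { box[0], box[1], box[2] };
  for (int i = 0; i < ns; ++i) {
    double p[3] = { coords(sink[i], 0), coords(sink[i], 1), coords(sink[i], 2) };
    out[i] = cl.visit_neighbors(coords, p, [&](int j) {
      double q[3] = { coords(j, 0), coords(j, 1), coords(j, 2) };
      return min_image_d2(p, q, bx, periodic) <= c2;
    });
  }
  return out;
}

// Number of probe atoms having any `existing` atom closer than `cutoff`.
// Early exit once `maxhits` probe atoms clash (0 = count all).
// [[Rcpp::export]]
int count_clashes_cpp(NumericMatrix existing, NumericMatrix probe,
                      double cutoff, NumericVector box, bool periodic,
                      int maxhits) {
  if (existing.nrow() == 0 || probe.nrow() == 0) return 0;
  CellList cl(existing, seq_idx(existing.nrow()), cutoff, box, periodic);
  double c2 = cutoff * cutoff;
  double bx[3] = { box[0], box[1], box[2] };
  int hits = 0;
  for (int i = 0; i < probe.nrow(); ++i) {
    double p[3] = { probe(i, 0), probe(i, 1), probe(i, 2) };
    bool hit = cl.visit_neighbors(existing, p, [&](int j) {
      double q[3] = { existing(j, 0), existing(j, 1), existing(j, 2) };
      return min_image_d2(p, q, bx, periodic) < c2;
    });
    if (hit && ++hits == maxhits) return hits;
  }
  return hits;
}

// Cross-chain steric relaxation helper: for every pair of atoms from
// different chains closer than `cutoff`, accumulate on each chain a push
// vector (away from the clashing partner, scaled by the overlap depth).
// Returns per-chain push vectors and the clashing pair count.
// [[Rcpp::export]]
List chain_push_cpp(NumericMatrix coords, IntegerVector chain, double cutoff,
                    NumericVector box, bool periodic) {
  int natoms = coords.nrow();
  int nchain = 0;
  for (int i = 0; i < natoms; ++i) nchain = std::max(nchain, chain[i] + 1);
  NumericMatrix push(nchain, 3);
  CellList cl(coords, seq_idx(natoms), cutoff, box, periodic);
  double c2 = cutoff * cutoff;
  double bx[3] = { box[0], box[1], box[2] };
  long npair = 0;
  for (int i = 0; i < natoms; ++i) {
    double p[3] = { coords(i, 0), coords(i, 1), coords(i, 2) };
    cl.visit_neighbors(coords, p, [&](int j) {
      if (j <= i || chain[j] == chain[i]) return false;
      double q[3] = { coords(j, 0), coords(j, 1), coords(j, 2) };
      double d2 = min_image_d2(p, q, bx, periodic);
      if (d2 < c2) {
        ++npair;
        double d = std::sqrt(d2);
        double depth = cutoff - d;
        double u[3];
        for (int k = 0; k < 3; ++k) {
          double dk = p[k] - q[k];
          if (periodic) dk -= bx[k] * std::round(dk / bx[k]);
          u[k] = (d > 1e-9) ? dk / d : ((k == 0) ? 1.0 : 0.0);
          push(chain[i], k) += u[k] * depth;
          push(chain[j], k) -= u[k] * depth;
        }
      }
      return false;
    });
  }
  return List::create(_["push"] = push, _["n_clash"] = (double)npair);
}

// Minimum cross-set distance (used by bound/unbound classification and
// assembly diagnostics). Brute force within cells; cutoff bounds search.
// Returns cutoff if nothing closer is found.
// [[Rcpp::export]]
NumericVector min_dist_to_set_cpp(NumericMatrix query, NumericMatrix ref,
                                  double cutoff, NumericVector box,
                                  bool periodic) {
  CellList cl(ref, seq_idx(ref.nrow()), cutoff, box, periodic);
  double bx[3] = { box[0], box[1], box[2] };
  int n = query.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double p[3] = { query(i, 0), query(i, 1), query(i, 2) };
    double best = cutoff * cutoff;
    cl.visit_neighbors(ref, p, [&](int j) {
      double q[3] = { ref(j, 0), ref(j, 1), ref(j, 2) };
      double d2 = min_image_d2(p, q, bx, periodic);
      if (d2 < best) best = d2;
      return false;
    });
    out[i] = std::sqrt(best);
  }
  return out;
}
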