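// Compiled core: expected-Euler-characteristic significance evaluation,
// agglomerative segmentation of the aggregate profile, and Monte-Carlo
// estimation of Euler curves under the cyclic-shift null.

#include <Rcpp.h>
#include <queue>
#include <algorithm>
#include <vector>
#include <cmath>
#include <climits>
#include <limits>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Significance table
//
// Per unordered scale pair (w_a, w_b): log expected Euler characteristic
// tabulated on an ascending threshold grid (isotonic-cleaned, floored), valid
// through index tstar; beyond that a Gaussian-style tail
// log E[chi](t) = logv[tstar] - b * (t^2 - thr[tstar]^2).
// Lookup: linear interpolation of log E in t within the grid, then bilinear
// interpolation in (log wL, log wR) across the symmetrised scale grid.
// ---------------------------------------------------------------------------

struct SigTable {
  std::vector<double> log_w;      // log of scale grid values (ascending)
  std::vector<double> thr;        // threshold grid (ascending, thr[0] == 0)
  NumericMatrix logv;             // n_pairs x n_thr
  std::vector<int> tstar;         // 0-based last valid threshold index
  std::vector<double> tail_b;     // tail decay coefficient, > 0
  IntegerMatrix pair_id;          // n_s x n_s, 0-based row into logv
  int n_s;
  int n_thr;
};

static SigTable make_sig_table(const List& tab) {
  SigTable st;
  NumericVector lw = tab["log_w"], th = tab["thresholds"], tb = tab["tail_b"];
  IntegerVector ts = tab["tstar0"];
  st.log_w.assign(lw.begin(), lw.end());
  st.thr.assign(th.begin(), th.end());
  st.tail_b.assign(tb.begin(), tb.end());
  st.tstar.assign(ts.begin(), ts.end());
  st.logv = as<NumericMatrix>(tab["logv"]);
  st.pair_id = as<IntegerMatrix>(tab["pair_id0"]);
  st.n_s = st.pair_id.nrow();
  st.n_thr = (int) st.thr.size();
  return st;
}

// log E[chi] for one tabulated pair at |t|
static double pair_log_eval(const SigTable& st, int p, double t) {
  const int ks = st.tstar[p];
  const double tmax = st.thr[ks];
  if (t >= tmax) {
    return st.logv(p, ks) - st.tail_b[p] * (t * t - tmax * tmax);
  }
  // locate t in thr[0..ks]
  int lo = 0, hi = ks;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (st.thr[mid] <= t) lo = mid; else hi = mid;
  }
  const double t0 = st.thr[lo], t1 = st.thr[hi];
  const double f = (t1 > t0) ? (t - t0) / (t1 - t0) : 0.0;
  return (1.0 - f) * st.logv(p, lo) + f * st.logv(p, hi);
}

// bracketing index i such that log_w[i] <= x <= log_w[i+1], plus fraction
static void grid_locate(const std::vector<double>& g, double x, int& i, double& f) {
  const int n = (int) g.size();
  if (n == 1 || x <= g[0]) { i = 0; f = 0.0; return; }
  if (x >= g[n - 1]) { i = n - 2; f = 1.0; return; }
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (g[mid] <= x) lo = mid; else hi = mid;
  }
  i = lo;
  f = (x - g[lo]) / (g[hi] - g[lo]);
}

static double sig_eval(const SigTable& st, double t, double wL, double wR) {
  t = std::fabs(t);
  const double wmin = std::exp(st.log_w[0]);
  const double wmax = std::exp(st.log_w[st.n_s - 1]);
  if (wL < wmin) wL = wmin; else if (wL > wmax) wL = wmax;
  if (wR < wmin) wR = wmin; else if (wR > wmax) wR = wmax;
  if (st.n_s == 1) return std::exp(pair_log_eval(st, st.pair_id(0, 0), t));
  int i, j; double fx, fy;
  grid_locate(st.log_w, std::log(wL), i, fx);
  grid_locate(st.log_w, std::log(wR), j, fy);
  const double v00 = pair_log_eval(st, st.pair_id(i, j), t);
  const double v10 = pair_log_eval(st, st.pair_id(i + 1, j), t);
  const double v01 = pair_log_eval(st, st.pair_id(i, j + 1), t);
  const double v11 = pair_log_eval(st, st.pair_id(i + 1, j + 1), t);
  const double v = (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
                   (1 - fx) * fy * v01 + fx * fy * v11;
  return std::exp(v);
}

// [[Rcpp::export]]
NumericVector cpp_significance(NumericVector t, NumericVector wl,
                               NumericVector wr, List table) {
  SigTable st = make_sig_table(table);
  const int n = t.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k)
    out[k] = sig_eval(st, t[k], wl[k], wr[k]);
  return out;
}

// ---------------------------------------------------------------------------
// Agglomerative segmentation
//
// Start with one segment per probe; repeatedly merge the adjacent pair whose
// boundary has the largest (least significant) expected Euler characteristic,
// rescoring only the <= 2 neighbouring boundaries after each merge, until all
// remaining boundaries have sig <= E. Lazy-deletion max-heap keyed by
// (sig, leftmost position) keeps the run in P log P.
// ---------------------------------------------------------------------------

struct HeapEntry {
  double sig;
  int seg;      // left segment id == boundary position (for tie-breaking)
  int version;
};

struct HeapCmp {
  bool operator()(const HeapEntry& a, const HeapEntry& b) const {
    if (a.sig != b.sig) return a.sig < b.sig;   // max-heap on sig
    return a.seg > b.seg;                        // leftmost wins ties
  }
};

// [[Rcpp::export]]
List cpp_segment(NumericVector agg, IntegerVector chrom_start, double E,
                 List table, bool diagnostics = false) {
  SigTable st = make_sig_table(table);
  const int P = agg.size();
  const int n_chr = chrom_start.size() - 1; // chrom_start has n_chr+1 entries (0-based, last = P)

  std::vector<int> nxt(P), prv(P), width(P), chrom(P), version(P, 0);
  std::vector<double> segsum(P);
  std::vector<bool> alive(P, true);
  std::vector<char> has_rb(P, false);   // segment has a right boundary (same chrom)

  for (int c = 0; c < n_chr; ++c) {
    for (int g = chrom_start[c]; g < chrom_start[c + 1]; ++g) {
      chrom[g] = c;
      width[g] = 1;
      segsum[g] = agg[g];
      prv[g] = g - 1;
      nxt[g] = g + 1;
    }
  }

  // build the initial boundary set in one O(P) heapify
  std::vector<HeapEntry> init;
  init.reserve(P);
  for (int s = 0; s < P; ++s) {
    const int r = nxt[s];
    if (r >= P || chrom[r] != chrom[s]) continue;
    has_rb[s] = true;
    const double jump = segsum[r] / width[r] - segsum[s] / width[s];
    const double sig = sig_eval(st, jump, (double) width[s], (double) width[r]);
    init.push_back(HeapEntry{sig, s, 0});
  }
  init.reserve((size_t) 3 * P + 16);
  std::priority_queue<HeapEntry, std::vector<HeapEntry>, HeapCmp>
      heap(HeapCmp(), std::move(init));
  auto push_boundary = [&](int s) {
    const int r = nxt[s];
    if (r >= P || chrom[r] != chrom[s]) { has_rb[s] = false; return; }
    has_rb[s] = true;
    const double jump = segsum[r] / width[r] - segsum[s] / width[s];
    const double sig = sig_eval(st, jump, (double) width[s], (double) width[r]);
    heap.push(HeapEntry{sig, s, version[s]});
  };

  int max_rescored = 0;
  while (!heap.empty()) {
    HeapEntry top = heap.top();
    if (!alive[top.seg] || top.version != version[top.seg] || !has_rb[top.seg]) {
      heap.pop();
      continue;
    }
    if (top.sig <= E) break;
    heap.pop();
    const int L = top.seg;
    const int R = nxt[L];
    // merge R into L
    segsum[L] += segsum[R];
    width[L] += width[R];
    alive[R] = false;
    nxt[L] = nxt[R];
    if (nxt[R] < P) prv[nxt[R]] = L;
    int rescored = 0;
    version[L]++;
    push_boundary(L);                   // boundary (L, new right neighbour)
    if (has_rb[L]) rescored++;
    if (prv[L] >= 0 && chrom[prv[L]] == chrom[L]) {
      version[prv[L]]++;
      push_boundary(prv[L]);            // boundary (left neighbour, L)
      rescored++;
    }
    if (rescored > max_rescored) max_rescored = rescored;
  }

  // collect segments in genome order
  std::vector<int> starts, widths;
  std::vector<double> means;
  std::vector<int> bpos;                // boundary: index of last probe of left segment
  std::vector<double> bjump, bsig;
  for (int c = 0; c < n_chr; ++c) {
    int s = chrom_start[c];
    while (s < chrom_start[c + 1]) {
      starts.push_back(s);
      widths.push_back(width[s]);
      means.push_back(segsum[s] / width[s]);
      const int r = nxt[s];
      if (r < chrom_start[c + 1]) {
        const double jump = segsum[r] / width[r] - segsum[s] / width[s];
        bpos.push_back(s + width[s] - 1);
        bjump.push_back(jump);
        bsig.push_back(sig_eval(st, jump, (double) width[s], (double) width[r]));
      }
      s = r;
    }
  }

  List out = List::create(
    _["start"] = wrap(starts), _["width"] = wrap(widths), _["mean"] = wrap(means),
    _["boundary"] = wrap(bpos), _["jump"] = wrap(bjump), _["sig"] = wrap(bsig));
  if (diagnostics) out["max_rescored"] = max_rescored;
  return out;
}

// ---------------------------------------------------------------------------
// Monte-Carlo Euler curves under the cyclic-shift null
//
// For each permutation: rotate every sample's profile by its offset over the
// concatenated genome, sum into an aggregate, and for every unordered scale
// pair count excursion-set components of the break-recurrence track at every
// threshold (runs never span chromosome boundaries).
//
// Counting: components of {track >= thr} equal (# elements >= thr) minus
// (# adjacent pairs with both >= thr), so one signed histogram per scale
// pair over the threshold grid suffices: +1 at bin(value) per element, -1 at
// bin(min(value, previous)) per adjacent pair, then a suffix sum over bins.
// The negative excursion side uses the mirrored values. Because the
// aggregate is piecewise constant between its run boundaries, the track is
// piecewise linear with vertices ("knots") only where a window edge crosses
// a run boundary, and a monotone stretch contributes exactly the same
// component counts as the single step between its endpoint values; when the
// aggregate has few runs the track is therefore evaluated at knots only.
// ---------------------------------------------------------------------------

#define BR_MAX_THR 32

static inline int thr_bin(const double* thr, double v) {
  // number of grid thresholds <= v (0 when v < thr[0]); grid padded to
  // BR_MAX_THR with +inf. Fast path for values below the first positive
  // threshold, branchless binary search otherwise.
  if (v < thr[1]) return v >= thr[0];
  int pos = 0;
  for (int step = BR_MAX_THR / 2; step; step >>= 1)
    if (thr[pos + step - 1] <= v) pos += step;
  return pos;
}

struct PairHist {
  std::vector<long long> pos, neg;   // signed counts per bin 0..n_thr
  void init(int n_thr) {
    pos.assign(n_thr + 1, 0);
    neg.assign(n_thr + 1, 0);
  }
};

// feed one monotone track step prev -> cur (or a track start when first).
// An upcrossing of thr[k] adds one positive excursion component (mirrored
// for the negative side); encoded as +1/-1 into a signed histogram whose
// suffix sums give the counts. The side select compiles to conditional
// moves; an equal-valued step cancels itself.
static inline void hist_step(PairHist& h, const double* thr,
                             double prev, double cur, bool first) {
  if (first) {
    h.pos[thr_bin(thr, cur)] += 1;
    h.neg[thr_bin(thr, -cur)] += 1;
  } else if (cur > prev) {
    if (cur < thr[0]) return;                    // entirely below the grid
    if (prev >= thr[0] && cur < thr[1]) return;  // both in the lowest bin
    h.pos[thr_bin(thr, cur)] += 1;
    h.pos[thr_bin(thr, prev)] -= 1;
  } else if (cur < prev) {
    if (-cur < thr[0]) return;
    if (-prev >= thr[0] && -cur < thr[1]) return;
    h.neg[thr_bin(thr, -cur)] += 1;
    h.neg[thr_bin(thr, -prev)] -= 1;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_euler_curve_counts(NumericMatrix mt, IntegerVector chrom_start,
                                     IntegerMatrix offsets, IntegerVector scales,
                                     NumericVector thresholds) {
  const int P = mt.nrow();          // mt is P x n_samples (transposed matrix)
  const int S = mt.ncol();
  const int n_perm = offsets.nrow();
  const int n_s = scales.size();
  const int n_thr = thresholds.size();
  const int n_chr = chrom_start.size() - 1;
  const int n_pairs = n_s * (n_s + 1) / 2;

  if (n_thr > BR_MAX_THR) stop("threshold grid too large");
  std::vector<double> thr(BR_MAX_THR, std::numeric_limits<double>::infinity());
  std::copy(thresholds.begin(), thresholds.end(), thr.begin());
  const double* tg = thr.data();
  std::vector<double> agg(P), S1(P + 1);
  std::vector<PairHist> hist(n_pairs);
  for (int p = 0; p < n_pairs; ++p) hist[p].init(n_thr);
  std::vector<int> runstart;         // positions g with agg[g] != agg[g-1]
  std::vector<std::vector<int>> ab_knots((size_t) n_s * n_chr);

  for (int perm = 0; perm < n_perm; ++perm) {
    std::fill(agg.begin(), agg.end(), 0.0);
    for (int s = 0; s < S; ++s) {
      const int off = offsets(perm, s);
      const double* col = &mt(0, s);
      double* a = agg.data();
      const int head = P - off;
      for (int g = 0; g < head; ++g) a[g + off] += col[g];
      for (int g = head; g < P; ++g) a[g + off - P] += col[g];
    }
    S1[0] = 0.0;
    for (int g = 0; g < P; ++g) S1[g + 1] = S1[g] + agg[g];

    // aggregate run boundaries per chromosome (within-chromosome changes)
    runstart.clear();
    std::vector<int> chr_lo(n_chr), chr_hi(n_chr); // slice of runstart per chrom
    for (int c = 0; c < n_chr; ++c) {
      chr_lo[c] = (int) runstart.size();
      for (int g = chrom_start[c] + 1; g < chrom_start[c + 1]; ++g)
        if (agg[g] != agg[g - 1]) runstart.push_back(g);
      chr_hi[c] = (int) runstart.size();
    }
    // pre-merge the two left-window knot streams (B-1, B+wa-1) per scale
    for (int ia = 0; ia < n_s; ++ia) {
      const int wa = scales[ia];
      for (int c = 0; c < n_chr; ++c) {
        std::vector<int>& v = ab_knots[(size_t) ia * n_chr + c];
        v.clear();
        const int nb = chr_hi[c] - chr_lo[c];
        const int* B = runstart.data() + chr_lo[c];
        v.reserve(2 * nb);
        int i = 0, j = 0;
        while (i < nb || j < nb) {
          const int x = (i < nb) ? B[i] - 1 : INT_MAX;
          const int y = (j < nb) ? B[j] + wa - 1 : INT_MAX;
          if (x <= y) { v.push_back(x); ++i; } else { v.push_back(y); ++j; }
        }
      }
    }

    int pair = 0;
    for (int ia = 0; ia < n_s; ++ia) {
      for (int ib = ia; ib < n_s; ++ib, ++pair) {
        const int wa = scales[ia], wb = scales[ib];
        PairHist& h = hist[pair];
        for (int c = 0; c < n_chr; ++c) {
          const int c0 = chrom_start[c], c1 = chrom_start[c + 1];
          if (c1 - c0 < wa + wb) continue;
          const int i0 = c0 + wa - 1, i1 = c1 - wb - 1;
          const int nb = chr_hi[c] - chr_lo[c];
          const int track_len = i1 - i0 + 1;
          const double inv_a = 1.0 / wa, inv_b = 1.0 / wb;  // scales are
          // powers of two by default, so the reciprocal product is exact
          auto track_at = [&](int i) {
            return (S1[i + 1 + wb] - S1[i + 1]) * inv_b -
                   (S1[i + 1] - S1[i + 1 - wa]) * inv_a;
          };
          if (3 * nb + 2 < track_len) {
            // sparse: evaluate at knots only (slope changes where a window
            // edge crosses a run boundary)
            const int* B = runstart.data() + chr_lo[c];
            const std::vector<int>& AB = ab_knots[(size_t) ia * n_chr + c];
            const int m = (int) AB.size();
            // skip knot candidates at or below the first boundary
            int pa = (int) (std::lower_bound(AB.begin(), AB.end(), i0 + 1) -
                            AB.begin());
            int pc = (int) (std::lower_bound(B, B + nb, i0 + wb + 2) - B);
            double prev = track_at(i0);
            hist_step(h, tg, 0.0, prev, true);
            int last = i0;
            while (pa < m || pc < nb) {
              const int x = (pa < m) ? AB[pa] : INT_MAX;
              const int y = (pc < nb) ? B[pc] - wb - 1 : INT_MAX;
              int nxt;
              if (x <= y) { nxt = x; ++pa; } else { nxt = y; ++pc; }
              if (nxt <= last) continue;    // below range or duplicate knot
              if (nxt > i1) break;
              const double cur = track_at(nxt);
              hist_step(h, tg, prev, cur, false);
              prev = cur;
              last = nxt;
            }
            if (last < i1) {
              const double cur = track_at(i1);
              hist_step(h, tg, prev, cur, false);
            }
          } else {
            // dense fallback
            double prev = 0.0;
            for (int i = i0; i <= i1; ++i) {
              const double cur = track_at(i);
              hist_step(h, tg, prev, cur, i == i0);
              prev = cur;
            }
          }
        }
      }
    }
  }

  NumericMatrix acc(n_pairs, n_thr);
  for (int p = 0; p < n_pairs; ++p) {
    long long sp = 0, sn = 0;
    for (int k = n_thr; k >= 1; --k) {
      sp += hist[p].pos[k];
      sn += hist[p].neg[k];
      acc(p, k - 1) = (double) (sp + sn) / n_perm;
    }
  }
  return acc;
}

// [[Rcpp::export]]
double cpp_max_abs_t(NumericVector agg, IntegerVector chrom_start,
                     IntegerVector scales) {
  const int P = agg.size();
  const int n_chr = chrom_start.size() - 1;
  std::vector<double> S1(P + 1);
  S1[0] = 0.0;
  for (int g = 0; g < P; ++g) S1[g + 1] = S1[g] + agg[g];
  double tmax = 0.0;
  for (int is = 0; is < scales.size(); ++is) {
    const int w = scales[is];
    for (int c = 0; c < n_chr; ++c) {
      const int c0 = chrom_start[c], c1 = chrom_start[c + 1];
      if (c1 - c0 < 2 * w) continue;
      for (int i = c0 + w - 1; i <= c1 - w - 1; ++i) {
        const double t = (S1[i + 1 + w] - 2.0 * S1[i + 1] + S1[i + 1 - w]) / w;
        const double a = std::fabs(t);
        if (a > tmax) tmax = a;
      }
    }
  }
  return tmax;
}
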