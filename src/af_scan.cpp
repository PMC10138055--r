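// Exhaustive scan over the non-empty phenotype subsets Omega = {0,1}^K \ 0
// for the adaptive Fisher statistics. Inputs are -log p matrices for the
// pooled permutation null (N = B*p rows) and the observed genes (G rows).
//
// Subsets are identified by integers s = 1..2^K-1 with bit k-1 <-> phenotype
// k. Subset sums are built by extending the subset-without-its-highest-bit
// by one column (a depth-first walk with one length-N add per subset), which
// reproduces the plain left-to-right sum over ascending phenotype index
// bit-for-bit, so results are reproducible against a naive R loop.
//
// Tie-breaking for the argmin/argmax weight (pooled p-values are discrete,
// ties are common under strong signal). AFp default ("centered evidence"):
// prefer the smaller pooled count, then the larger mean-centered statistic
// u - E(u(w)) — which keeps a phenotype in the subset only when its -log p
// exceeds its null expectation — then smaller cardinality, then the smaller
// subset index. AFz (continuous, ties rare): larger z, then larger u, then
// smaller cardinality, then index.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <cmath>
#include <vector>
#include <algorithm>
#include <limits>
using namespace Rcpp;

namespace {

// monotone linear binning of a non-negative value (clamped in double
// before the cast so huge observed statistics cannot overflow int)
static inline int bucket_of(double x, double scale) {
  const double qd = x * scale;
  return qd >= 65535.0 ? 65535 : (int)qd;
}

struct ScanState {
  int K = 0, N = 0, G = 0;
  bool do_afp = false, do_afz = false, need_null_T = false;
  int tie_mode = 2;   // 0: u first; 1: cardinality first;
                      // 2: centered evidence u - E(u) first (default)

  // DFS stacks of subset sums, depth 0..K-1
  std::vector<std::vector<double>> un_stack, uo_stack;

  // bucket-ranking buffers: values are binned by monotone linear
  // quantization (64 superbuckets, then 1024 fine buckets inside each, so
  // both scatter passes stay cache-resident); exact comparisons happen
  // only inside the (tiny) fine buckets
  static const int NB = 1 << 16;        // total fine resolution
  static const int NSB = 64;            // superbuckets (top 6 bits)
  double gscale = 0.0;                  // fixed quantization scale: the
                                        // bound sum_k max(col_k) covers
                                        // every subset sum, so binning can
                                        // fuse with the moment passes
  std::vector<double>   bval, bval2;    // bucket-ordered values
  std::vector<uint32_t> bidx, bidx2;    // matching original indices
  std::vector<uint16_t> qtmp, bq;       // per-element quantized bucket,
                                        // computed once per subset
  uint32_t o1[NSB + 1];                 // superbucket offsets
  uint32_t h2[1025];                    // fine histogram / offsets

  // running results
  std::vector<int>    p_best_cnt, p_best_card, p_best_s, p_null_T;
  std::vector<double> p_best_u, p_best_cu;
  std::vector<double> z_best, z_best_u, z_null_T;
  std::vector<int>    z_best_card, z_best_s;

  void process(int s, int depth);
  void dfs(const NumericMatrix& nlp_null, const NumericMatrix& nlp_obs,
           int s, int hb, int depth);
};

void ScanState::process(int s, int depth) {
  const int card = depth + 1;
  const std::vector<double>& u_null = un_stack[depth];
  const std::vector<double>& u_obs = uo_stack[depth];
  const double scale = gscale;

  // pass A: AFz running sum fused with the superbucket histogram (the
  // x87 accumulation chain is latency-bound, so the histogram increments
  // ride along nearly for free)
  double m = 0.0;
  const bool need_mean = do_afz || (do_afp && tie_mode == 2);
  if (do_afp) std::memset(o1, 0, sizeof(o1));
  if (need_mean && do_afp) {
    long double acc = 0.0L;
    for (int i = 0; i < N; ++i) {
      const double u = u_null[i];
      acc += u;
      const int q = bucket_of(u, scale);
      qtmp[i] = (uint16_t)q;
      o1[(q >> 10) + 1]++;
    }
    m = (double)(acc / N);
  } else if (need_mean) {
    long double acc = 0.0L;
    for (int i = 0; i < N; ++i) acc += u_null[i];
    m = (double)(acc / N);
  } else {
    for (int i = 0; i < N; ++i) {
      const int q = bucket_of(u_null[i], scale);
      qtmp[i] = (uint16_t)q;
      o1[(q >> 10) + 1]++;
    }
  }

  // pass B: AFz sum of squared deviations fused with the superbucket
  // scatter
  double sdev = 0.0;
  if (do_afp) {
    for (int q = 1; q <= NSB; ++q) o1[q] += o1[q - 1];
    uint32_t fill[NSB];
    std::memcpy(fill, o1, sizeof(uint32_t) * NSB);
    if (do_afz) {
      long double ss = 0.0L;
      for (int i = 0; i < N; ++i) {
        const double u = u_null[i];
        const double d = u - m;
        ss += (long double)(d * d);
        const uint16_t q = qtmp[i];
        const uint32_t pos = fill[q >> 10]++;
        bval[pos] = u;
        bidx[pos] = (uint32_t)i;
        bq[pos] = q;
      }
      sdev = std::sqrt((double)(ss / N));
    } else {
      for (int i = 0; i < N; ++i) {
        const uint16_t q = qtmp[i];
        const uint32_t pos = fill[q >> 10]++;
        bval[pos] = u_null[i];
        bidx[pos] = (uint32_t)i;
        bq[pos] = q;
      }
    }
  } else if (do_afz) {
    long double ss = 0.0L;
    for (int i = 0; i < N; ++i) {
      const double d = u_null[i] - m;
      ss += (long double)(d * d);
    }
    sdev = std::sqrt((double)(ss / N));
  }

  if (do_afz) {
    if (!(sdev > 0.0)) stop("degenerate null subset (sd = 0): subset %d", s);
    if (need_null_T) {
      for (int i = 0; i < N; ++i) {
        const double z = (u_null[i] - m) / sdev;
        if (z > z_null_T[i]) z_null_T[i] = z;
      }
    }
    for (int g = 0; g < G; ++g) {
      const double z = (u_obs[g] - m) / sdev;
      bool take = z > z_best[g];
      if (!take && z == z_best[g]) {
        take = u_obs[g] > z_best_u[g] ||
          (u_obs[g] == z_best_u[g] &&
           (card < z_best_card[g] ||
            (card == z_best_card[g] && s < z_best_s[g])));
      }
      if (take) {
        z_best[g] = z; z_best_u[g] = u_obs[g];
        z_best_card[g] = card; z_best_s[g] = s;
      }
    }
  }

  if (do_afp) {

    // pass 2: within each superbucket slice, scatter by the low 10 bits
    // into the second buffer, insertion-sort the fine runs, and assign
    // tie-run >= counts for the null draws (self-inclusive); afterwards
    // every slice of bval2 is fully sorted ascending
    for (int sb = 0; sb < NSB; ++sb) {
      const int lo = (int)o1[sb], hi = (int)o1[sb + 1];
      const int m = hi - lo;
      if (m == 0) continue;
      std::memset(h2, 0, sizeof(h2));
      for (int a = lo; a < hi; ++a) h2[(bq[a] & 1023) + 1]++;
      for (int q = 1; q <= 1024; ++q) h2[q] += h2[q - 1];
      for (int a = lo; a < hi; ++a) {
        const uint32_t pos = (uint32_t)lo + h2[bq[a] & 1023]++;
        bval2[pos] = bval[a];
        bidx2[pos] = bidx[a];
      }
      // h2[q] is now the END offset (relative to lo) of fine bucket q
      int run_start = 0;
      for (int q = 0; q < 1024; ++q) {
        const int fe = (int)h2[q];
        const int fm = fe - run_start;
        if (fm > 1 && fm <= 48) {
          const int flo = lo + run_start, fhi = lo + fe;
          for (int a = flo + 1; a < fhi; ++a) {
            const double v = bval2[a]; const uint32_t ix = bidx2[a];
            int b2 = a - 1;
            while (b2 >= flo && bval2[b2] > v) {
              bval2[b2 + 1] = bval2[b2]; bidx2[b2 + 1] = bidx2[b2]; --b2;
            }
            bval2[b2 + 1] = v; bidx2[b2 + 1] = ix;
          }
        } else if (fm > 48) {
          const int flo = lo + run_start;
          std::vector<std::pair<double, uint32_t>> tmp(fm);
          for (int a = 0; a < fm; ++a)
            tmp[a] = {bval2[flo + a], bidx2[flo + a]};
          std::sort(tmp.begin(), tmp.end(),
                    [](const std::pair<double, uint32_t>& x,
                       const std::pair<double, uint32_t>& y) {
                      return x.first < y.first;
                    });
          for (int a = 0; a < fm; ++a) {
            bval2[flo + a] = tmp[a].first;
            bidx2[flo + a] = tmp[a].second;
          }
        }
        run_start = fe;
      }
      if (need_null_T) {
        const int above = N - hi;
        int i2 = hi - 1;
        while (i2 >= lo) {
          int j2 = i2;
          while (j2 > lo && bval2[j2 - 1] == bval2[i2]) --j2;
          const int cnt = above + (hi - j2);
          for (int a = j2; a <= i2; ++a) {
            const uint32_t oi = bidx2[a];
            if (cnt < p_null_T[oi]) p_null_T[oi] = cnt;
          }
          i2 = j2 - 1;
        }
      }
    }
    for (int g = 0; g < G; ++g) {
      const double x = u_obs[g];
      const int sb = bucket_of(x, scale) >> 10;
      const int lo = (int)o1[sb], hi = (int)o1[sb + 1];
      const double* beg = bval2.data() + lo;
      const double* end = bval2.data() + hi;
      const int ge_in = (int)(end - std::lower_bound(beg, end, x));
      const int cnt = (N - hi) + ge_in;     // everything above this slice

      bool take = cnt < p_best_cnt[g];
      if (!take && cnt == p_best_cnt[g]) {
        if (tie_mode == 2) {
          const double cu = u_obs[g] - m;
          take = cu > p_best_cu[g] ||
            (cu == p_best_cu[g] &&
             (card < p_best_card[g] ||
              (card == p_best_card[g] && s < p_best_s[g])));
        } else if (tie_mode == 1) {
          take = card < p_best_card[g] ||
            (card == p_best_card[g] &&
             (u_obs[g] > p_best_u[g] ||
              (u_obs[g] == p_best_u[g] && s < p_best_s[g])));
        } else {
          take = u_obs[g] > p_best_u[g] ||
            (u_obs[g] == p_best_u[g] &&
             (card < p_best_card[g] ||
              (card == p_best_card[g] && s < p_best_s[g])));
        }
      }
      if (take) {
        p_best_cnt[g] = cnt; p_best_u[g] = u_obs[g];
        p_best_cu[g] = u_obs[g] - m;
        p_best_card[g] = card; p_best_s[g] = s;
      }
    }
  }
}

void ScanState::dfs(const NumericMatrix& nlp_null,
                    const NumericMatrix& nlp_obs,
                    int s, int hb, int depth) {
  process(s, depth);
  for (int j = hb + 1; j < K; ++j) {
    const double* cn = &nlp_null(0, j);
    const double* co = &nlp_obs(0, j);
    const std::vector<double>& pun = un_stack[depth];
    const std::vector<double>& puo = uo_stack[depth];
    std::vector<double>& nun = un_stack[depth + 1];
    std::vector<double>& nuo = uo_stack[depth + 1];
    for (int i = 0; i < N; ++i) nun[i] = pun[i] + cn[i];
    for (int g = 0; g < G; ++g) nuo[g] = puo[g] + co[g];
    dfs(nlp_null, nlp_obs, s | (1 << j), j, depth + 1);
  }
}

} // namespace

// [[Rcpp::export]]
List af_scan_cpp(NumericMatrix nlp_null, NumericMatrix nlp_obs,
                 bool do_afp, bool do_afz, bool need_null_T,
                 int tie_mode = 2) {
  ScanState st;
  st.K = nlp_null.ncol();
  st.N = nlp_null.nrow();
  st.G = nlp_obs.nrow();
  if (nlp_obs.ncol() != st.K) stop("observed and null matrices disagree on K");
  if (st.K < 1 || st.K > 20) stop("K out of range");
  if (st.N < 1) stop("empty null table");
  st.do_afp = do_afp; st.do_afz = do_afz; st.need_null_T = need_null_T;
  st.tie_mode = tie_mode;
  const int K = st.K, N = st.N, G = st.G;
  const int S = (1 << K) - 1;

  st.un_stack.assign(K, std::vector<double>(N));
  st.uo_stack.assign(K, std::vector<double>(G));
  if (do_afp) {
    st.bval.resize(N); st.bval2.resize(N);
    st.bidx.resize(N); st.bidx2.resize(N);
    st.qtmp.resize(N); st.bq.resize(N);
    double bound = 0.0;
    for (int k = 0; k < K; ++k) {
      double mx = 0.0;
      const double* cn = &nlp_null(0, k);
      for (int i = 0; i < N; ++i) if (cn[i] > mx) mx = cn[i];
      bound += mx;
    }
    st.gscale = bound > 0.0 ? (double)(ScanState::NB - 1) / bound : 0.0;
    st.p_best_cnt.assign(G, std::numeric_limits<int>::max());
    st.p_best_u.assign(G, -1.0);
    st.p_best_cu.assign(G, -std::numeric_limits<double>::infinity());
    st.p_best_card.assign(G, K + 1);
    st.p_best_s.assign(G, S + 1);
    if (need_null_T)
      st.p_null_T.assign(N, std::numeric_limits<int>::max());
  }
  if (do_afz) {
    st.z_best.assign(G, -std::numeric_limits<double>::infinity());
    st.z_best_u.assign(G, -1.0);
    st.z_best_card.assign(G, K + 1);
    st.z_best_s.assign(G, S + 1);
    if (need_null_T)
      st.z_null_T.assign(N, -std::numeric_limits<double>::infinity());
  }

  for (int k = 0; k < K; ++k) {
    const double* cn = &nlp_null(0, k);
    const double* co = &nlp_obs(0, k);
    std::copy(cn, cn + N, st.un_stack[0].begin());
    std::copy(co, co + G, st.uo_stack[0].begin());
    st.dfs(nlp_null, nlp_obs, 1 << k, k, 0);
  }

  List out;
  if (do_afp) {
    IntegerMatrix W(G, K);
    for (int g = 0; g < G; ++g)
      for (int k = 0; k < K; ++k)
        W(g, k) = (st.p_best_s[g] >> k) & 1;
    out["afp"] = List::create(
      _["count"] = IntegerVector(st.p_best_cnt.begin(), st.p_best_cnt.end()),
      _["u"] = NumericVector(st.p_best_u.begin(), st.p_best_u.end()),
      _["w"] = W,
      _["subset"] = IntegerVector(st.p_best_s.begin(), st.p_best_s.end()),
      _["null_count"] = need_null_T
        ? IntegerVector(st.p_null_T.begin(), st.p_null_T.end())
        : IntegerVector(0));
  }
  if (do_afz) {
    IntegerMatrix W(G, K);
    for (int g = 0; g < G; ++g)
      for (int k = 0; k < K; ++k)
        W(g, k) = (st.z_best_s[g] >> k) & 1;
    out["afz"] = List::create(
      _["stat"] = NumericVector(st.z_best.begin(), st.z_best.end()),
      _["w"] = W,
      _["subset"] = IntegerVector(st.z_best_s.begin(), st.z_best_s.end()),
      _["null_stat"] = need_null_T
        ? NumericVector(st.z_null_T.begin(), st.z_null_T.end())
        : NumericVector(0));
  }
  out["N"] = N;
  return out;
}
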