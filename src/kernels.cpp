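#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

static inline int code_base(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1; // N and anything else matches nothing
  }
}

struct HwResult {
  int dist; // edit distance of pattern vs best substring of text
  int end;  // 0-based index of the last text character of that substring
};

// Blocked bit-parallel (Myers) edit distance of `pattern` against the
// best-matching substring of `text` (infix / semi-global mode: both ends of
// the text are free, the whole pattern is consumed). The pattern is padded
// with non-matching rows to a multiple of 64; padding contributes exactly
// pad extra edits, subtracted on return.
static HwResult hw_core(const std::string &pattern, const std::string &text) {
  const int m = (int)pattern.size();
  const int n = (int)text.size();
  if (m == 0) return {0, -1};
  const int b = (m + 63) / 64;
  const int mp = b * 64;
  const int pad = mp - m;

  std::vector<uint64_t> Peq((size_t)b * 4, 0);
  for (int i = 0; i < m; ++i) {
    int c = code_base(pattern[(size_t)i]);
    if (c >= 0) Peq[(size_t)(i / 64) * 4 + c] |= (uint64_t)1 << (i % 64);
  }
  std::vector<uint64_t> VP(b, ~(uint64_t)0), VN(b, 0);
  const uint64_t HB = (uint64_t)1 << 63;
  int score = mp;
  int best = mp;
  int best_end = -1;
  for (int j = 0; j < n; ++j) {
    int c = code_base(text[(size_t)j]);
    int hin = 0;
    for (int v = 0; v < b; ++v) {
      uint64_t Eq = (c >= 0) ? Peq[(size_t)v * 4 + c] : 0;
      uint64_t Pv = VP[v], Mv = VN[v];
      uint64_t Xv = Eq | Mv;
      if (hin < 0) Eq |= 1;
      uint64_t Xh = (((Eq & Pv) + Pv) ^ Pv) | Eq;
      uint64_t Ph = Mv | ~(Xh | Pv);
      uint64_t Mh = Pv & Xh;
      int hout = 0;
      if (Ph & HB) hout = 1; else if (Mh & HB) hout = -1;
      Ph <<= 1; Mh <<= 1;
      if (hin < 0) Mh |= 1; else if (hin > 0) Ph |= 1;
      VP[v] = Mh | ~(Xv | Ph);
      VN[v] = Ph & Xv;
      hin = hout;
    }
    score += hin;
    if (score < best) { best = score; best_end = j; }
  }
  return {best - pad, best_end};
}

// [[Rcpp::export]]
int hw_distance_cpp(std::string pattern, std::string text) {
  return hw_core(pattern, text).dist;
}

static void kmer_codes(const std::string &s, int k, std::vector<uint64_t> &out) {
  out.clear();
  const int n = (int)s.size();
  if (n < k) return;
  uint64_t code = 0, mask = (k == 32) ? ~(uint64_t)0 : (((uint64_t)1 << (2 * k)) - 1);
  int run = 0; // valid bases accumulated
  for (int i = 0; i < n; ++i) {
    int c = code_base(s[(size_t)i]);
    if (c < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)c) & mask;
    if (++run >= k) out.push_back(code);
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
}

static int shared_kmers(const std::vector<uint64_t> &a, const std::vector<uint64_t> &b) {
  int hits = 0;
  size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] < b[j]) ++i;
    else if (b[j] < a[i]) ++j;
    else { ++hits; ++i; ++j; }
  }
  return hits;
}

static std::string revcomp_str(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (char &c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'T': c = 'A'; break;
      case 'C': c = 'G'; break; case 'G': c = 'C'; break;
      default: c = 'N';
    }
  }
  return r;
}

// Anchored spanning test for one orientation: the full reference must align
// end to end with identity >= min_identity, and each reference end (an
// anchor window of W bp) must align, at a read position consistent with the
// full alignment, with identity >= min_identity. The anchor requirement is
// what distinguishes a native from a flank-swapped reference: the full-
// reference identity alone barely drops when only one flank (a small
// fraction of the reference) disagrees, but that flank's anchor cannot
// reach the identity bar against unrelated sequence.
static double spans_one_orientation(const std::string &pat,
                                    const std::string &la,
                                    const std::string &ra,
                                    const std::string &read,
                                    double min_identity) {
  const int m = (int)pat.size();
  const int W = (int)la.size();
  const int n = (int)read.size();
  HwResult full = hw_core(pat, read);
  double id_full = 1.0 - (double)full.dist / m;
  if (id_full < min_identity) return id_full;
  if (W == m) return id_full; // anchors degenerate to the full reference
  const int tol = std::max(50, (int)std::lround((1.0 - min_identity) * m) + 50);

  // left anchor should sit near read position full.end - m + 1
  int ls = full.end - m + 1 - tol;
  int le = full.end - m + W + tol;
  if (ls < 0) ls = 0;
  if (le > n - 1) le = n - 1;
  if (le - ls + 1 < W) return -1.0;
  HwResult lr = hw_core(la, read.substr((size_t)ls, (size_t)(le - ls + 1)));
  if (1.0 - (double)lr.dist / W < min_identity) return -1.0;

  // right anchor should end near full.end
  int rs = full.end - W + 1 - tol;
  int re = full.end + tol;
  if (rs < 0) rs = 0;
  if (re > n - 1) re = n - 1;
  if (re - rs + 1 < W) return -1.0;
  HwResult rr = hw_core(ra, read.substr((size_t)rs, (size_t)(re - rs + 1)));
  if (1.0 - (double)rr.dist / W < min_identity) return -1.0;
  return id_full;
}

// For each (read, reference) pair, decide whether the read spans the
// reference end to end (on either strand): full-reference identity
// 1 - dist/|ref| >= min_identity plus positionally consistent end anchors
// (see spans_one_orientation). A sorted-k-mer prefilter (k = prefilter_k)
// skips read/orientation pairs sharing no exact k-mer with the reference;
// exact containment always shares k-mers, so the error-free limit is
// unaffected. Returns a list with the 0/1 span matrix and the full-reference
// identity matrix (NA when not evaluated, -1 when an anchor failed).
// [[Rcpp::export]]
List count_spanning_cpp(CharacterVector refs, CharacterVector reads,
                        double min_identity, int prefilter_k = 11,
                        int anchor_width = 250) {
  const int nr = refs.size(), nq = reads.size();
  IntegerMatrix span(nq, nr);
  NumericMatrix ident(nq, nr);
  std::fill(ident.begin(), ident.end(), NA_REAL);

  std::vector<std::string> R(nr), Rrc(nr), La(nr), Ra(nr), Larc(nr), Rarc(nr);
  std::vector<std::vector<uint64_t>> Rk(nr), Rrck(nr);
  std::vector<int> Rlen(nr);
  for (int r = 0; r < nr; ++r) {
    R[r] = as<std::string>(refs[r]);
    Rrc[r] = revcomp_str(R[r]);
    const int m = (int)R[r].size();
    Rlen[r] = m;
    int W = std::min(anchor_width, std::max(50, m / 4));
    if (W > m) W = m;
    La[r] = R[r].substr(0, (size_t)W);
    Ra[r] = R[r].substr((size_t)(m - W));
    Larc[r] = Rrc[r].substr(0, (size_t)W);
    Rarc[r] = Rrc[r].substr((size_t)(m - W));
    kmer_codes(R[r], prefilter_k, Rk[r]);
    kmer_codes(Rrc[r], prefilter_k, Rrck[r]);
  }

  std::vector<uint64_t> qk;
  for (int q = 0; q < nq; ++q) {
    std::string read = as<std::string>(reads[q]);
    kmer_codes(read, prefilter_k, qk);
    for (int r = 0; r < nr; ++r) {
      const int m = Rlen[r];
      if ((int)read.size() < m) {
        // a read shorter than the reference cannot cover it at high identity
        if ((double)read.size() / m < min_identity) continue;
      }
      int hf = shared_kmers(Rk[r], qk);
      int hr = shared_kmers(Rrck[r], qk);
      if (hf == 0 && hr == 0) continue;
      double best = -1.0;
      bool fwd_first = hf >= hr;
      for (int pass = 0; pass < 2; ++pass) {
        bool use_fwd = (pass == 0) ? fwd_first : !fwd_first;
        int hits = use_fwd ? hf : hr;
        if (hits == 0) continue;
        double id = use_fwd
          ? spans_one_orientation(R[r], La[r], Ra[r], read, min_identity)
          : spans_one_orientation(Rrc[r], Larc[r], Rarc[r], read, min_identity);
        if (id > best) best = id;
        if (best >= min_identity) break;
      }
      ident(q, r) = best;
      if (best >= min_identity) span(q, r) = 1;
    }
  }
  return List::create(_["span"] = span, _["identity"] = ident);
}

// Maximal bounded-Hamming-distance repeat windows between S and T via exact
// k-mer seeding (pigeonhole-complete for k <= floor(min_len/(max_mm+1))) and
// mismatch-bounded extension. Returns 0-based start_s, start_t, len, mm.
// `skip_same_diag`: skip seed pairs with start_s == start_t (self-comparison
// trivial diagonal). `period`: if > 0, additionally skip seeds whose diagonal
// (start_s - start_t) is a multiple of `period` (images of the trivial
// diagonal when a circular sequence is unrolled to two copies).
// [[Rcpp::export]]
DataFrame repeat_windows_cpp(std::string S, std::string T, int k, int min_len,
                             int max_mm, bool skip_same_diag = false,
                             int period = 0) {
  const int ns = (int)S.size(), nt = (int)T.size();
  std::vector<int> out_i, out_j, out_len, out_mm;

  if (ns < k || nt < k || k < 1 || k > 12)
    return DataFrame::create(_["start_s"] = out_i, _["start_t"] = out_j,
                             _["len"] = out_len, _["mm"] = out_mm);

  // bucket T k-mer positions by code
  const uint32_t nbuck = (uint32_t)1 << (2 * k);
  std::vector<int> bcount(nbuck + 1, 0);
  std::vector<int> tcode(nt, -1);
  {
    uint32_t code = 0, mask = nbuck - 1;
    int run = 0;
    for (int j = 0; j < nt; ++j) {
      int c = code_base(T[(size_t)j]);
      if (c < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint32_t)c) & mask;
      if (++run >= k) { tcode[j - k + 1] = (int)code; bcount[code + 1]++; }
    }
  }
  for (uint32_t b = 0; b < nbuck; ++b) bcount[b + 1] += bcount[b];
  std::vector<int> bpos(bcount[nbuck]);
  {
    std::vector<int> cur(bcount.begin(), bcount.end() - 1);
    for (int j = 0; j + k <= nt; ++j)
      if (tcode[j] >= 0) bpos[(size_t)cur[tcode[j]]++] = j;
  }

  struct Rec { int i, j, len, mm; };
  std::vector<Rec> recs;

  int lmm[16], rmm[16];

  uint32_t code = 0, mask = nbuck - 1;
  int run = 0;
  for (int i = 0; i < ns; ++i) {
    int c = code_base(S[(size_t)i]);
    if (c < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint32_t)c) & mask;
    if (++run < k) continue;
    const int is = i - k + 1; // seed start in S
    for (int bi = bcount[code]; bi < bcount[code + 1]; ++bi) {
      const int js = bpos[(size_t)bi];
      const long long d = (long long)is - (long long)js;
      if (skip_same_diag && d == 0) continue;
      if (period > 0 && d % period == 0) continue;
      // if the previous position on this diagonal also matches, the k-mer one
      // step left is a seed too and yields the same maximal windows: extend
      // only from the leftmost seed of each exact run
      if (is > 0 && js > 0 && S[(size_t)(is - 1)] == T[(size_t)(js - 1)] &&
          code_base(S[(size_t)(is - 1)]) >= 0) continue;

      // extend left from (is-1, js-1), collecting up to max_mm+1 mismatches
      int nl = 0;
      {
        int p = is - 1, q = js - 1;
        while (p >= 0 && q >= 0 && nl <= max_mm) {
          char a = S[(size_t)p], b2 = T[(size_t)q];
          if (a == 'N' || b2 == 'N' || code_base(a) < 0 || code_base(b2) < 0) break;
          if (a != b2) lmm[nl++] = p;
          --p; --q;
        }
        // boundary position (first reachable S index) stored in lmm[nl] slot
        lmm[nl] = p; // p is one left of last scanned; window start floor = p+1
      }
      int nr_ = 0;
      {
        int p = is + k, q = js + k;
        while (p < ns && q < nt && nr_ <= max_mm) {
          char a = S[(size_t)p], b2 = T[(size_t)q];
          if (a == 'N' || b2 == 'N' || code_base(a) < 0 || code_base(b2) < 0) break;
          if (a != b2) rmm[nr_++] = p;
          ++p; ++q;
        }
        rmm[nr_] = p; // window end ceiling = p-1
      }
      // nl / nr_ include a possible (max_mm+1)-th sentinel mismatch
      const int nlm = std::min(nl, max_mm + 1);
      const int nrm = std::min(nr_, max_mm + 1);
      for (int a = 0; a <= max_mm; ++a) {
        const int b2 = max_mm - a;
        const int mmL = std::min(a, nlm);
        const int mmR = std::min(b2, nrm);
        const int mm = mmL + mmR;
        bool leftRoom = (a < nlm);
        bool rightRoom = (b2 < nrm);
        if (mm < max_mm && (leftRoom || rightRoom)) continue; // not maximal
        // window extends past the allowed mismatches and stops just inside
        // the next mismatch, or reaches the scanned boundary
        int start = leftRoom ? (lmm[a] + 1) : (lmm[nl] + 1);
        int end = rightRoom ? (rmm[b2] - 1) : (rmm[nr_] - 1);
        const int len = end - start + 1;
        if (len < min_len) continue;
        recs.push_back({start, (int)(start - d), len, mm});
      }
    }
  }

  // dedupe identical windows found from multiple internal seeds
  std::sort(recs.begin(), recs.end(), [](const Rec &a, const Rec &b) {
    if (a.i != b.i) return a.i < b.i;
    if (a.j != b.j) return a.j < b.j;
    if (a.len != b.len) return a.len < b.len;
    return a.mm < b.mm;
  });
  recs.erase(std::unique(recs.begin(), recs.end(), [](const Rec &a, const Rec &b) {
    return a.i == b.i && a.j == b.j && a.len == b.len && a.mm == b.mm;
  }), recs.end());

  out_i.reserve(recs.size()); out_j.reserve(recs.size());
  out_len.reserve(recs.size()); out_mm.reserve(recs.size());
  for (const Rec &r : recs) {
    out_i.push_back(r.i); out_j.push_back(r.j);
    out_len.push_back(r.len); out_mm.push_back(r.mm);
  }
  return DataFrame::create(_["start_s"] = out_i, _["start_t"] = out_j,
                           _["len"] = out_len, _["mm"] = out_mm);
}

// Booth's algorithm: index (0-based) of the lexicographically least rotation.
// [[Rcpp::export]]
int least_rotation_cpp(std::string s) {
  const int n = (int)s.size();
  if (n == 0) return 0;
  std::string ss = s + s;
  std::vector<int> f(2 * n, -1);
  int kk = 0;
  for (int j = 1; j < 2 * n; ++j) {
    char sj = ss[(size_t)j];
    int i = f[j - kk - 1];
    while (i != -1 && sj != ss[(size_t)(kk + i + 1)]) {
      if (sj < ss[(size_t)(kk + i + 1)]) kk = j - i - 1;
      i = f[i];
    }
    if (sj != ss[(size_t)(kk + i + 1)]) {
      if (sj < ss[(size_t)kk]) kk = j;
      f[j - kk] = -1;
    } else {
      f[j - kk] = i + 1;
    }
  }
  return kk;
}
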