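#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
#include <cmath>
#include <limits>
#include <string>
#include <vector>

using namespace Rcpp;

// k-mers are packed 2 bits per base (A=0, C=1, G=2, T=3) into a 64-bit key,
// which bounds k at 31; anything outside {A,C,G,T} breaks the current window.
typedef std::unordered_map<uint64_t, double> KmerMap;

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

static inline bool is_acgt(char c) { return base_code(c) >= 0; }

static inline uint64_t kmask(int k) {
  return (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
}

// encode s[pos, pos+k) ; returns false if any base is not A/C/G/T
static bool encode_kmer(const char* s, int pos, int k, uint64_t& out) {
  uint64_t v = 0;
  for (int t = 0; t < k; ++t) {
    int c = base_code(s[pos + t]);
    if (c < 0) return false;
    v = (v << 2) | (uint64_t)c;
  }
  out = v;
  return true;
}

static double map_lookup(const KmerMap& m, uint64_t key) {
  KmerMap::const_iterator it = m.find(key);
  return (it == m.end()) ? 0.0 : it->second;
}

// count for the k-mer starting at 0-based `pos` in `s` (0 if out of range or
// the window contains a non-ACGT base)
static double window_count(const KmerMap& m, const std::string& s, int pos, int k) {
  if (pos < 0 || pos + k > (int)s.size()) return 0.0;
  uint64_t key;
  if (!encode_kmer(s.c_str(), pos, k, key)) return 0.0;
  return map_lookup(m, key);
}

// ---------------------------------------------------------------- k-mer table

// [[Rcpp::export]]
SEXP kmer_map_new() {
  XPtr<KmerMap> p(new KmerMap(), true);
  return p;
}

// [[Rcpp::export]]
void kmer_map_add(SEXP ptr, CharacterVector seqs, int k) {
  XPtr<KmerMap> map(ptr);
  const uint64_t mask = kmask(k);
  for (R_xlen_t r = 0; r < seqs.size(); ++r) {
    SEXP el = STRING_ELT(seqs, r);
    if (el == NA_STRING) continue;
    const char* s = CHAR(el);
    int n = (int)LENGTH(el);
    uint64_t val = 0;
    int run = 0;  // length of the current stretch of valid bases
    for (int i = 0; i < n; ++i) {
      int c = base_code(s[i]);
      if (c < 0) { run = 0; val = 0; continue; }
      val = ((val << 2) | (uint64_t)c) & mask;
      if (++run >= k) {
        (*map)[val] += 1.0;
        run = k;  // avoid unbounded growth on long reads
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector kmer_map_lookup(SEXP ptr, CharacterVector kmers, int k) {
  XPtr<KmerMap> map(ptr);
  R_xlen_t n = kmers.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    SEXP el = STRING_ELT(kmers, i);
    if (el == NA_STRING) { out[i] = 0.0; continue; }
    if ((int)LENGTH(el) != k)
      stop("query length %d does not match table k = %d", (int)LENGTH(el), k);
    uint64_t key;
    out[i] = encode_kmer(CHAR(el), 0, k, key) ? map_lookup(*map, key) : 0.0;
  }
  return out;
}

// [[Rcpp::export]]
double kmer_map_size(SEXP ptr) {
  XPtr<KmerMap> map(ptr);
  return (double)map->size();
}

// [[Rcpp::export]]
double kmer_map_total(SEXP ptr) {
  XPtr<KmerMap> map(ptr);
  double tot = 0.0;
  for (KmerMap::const_iterator it = map->begin(); it != map->end(); ++it)
    tot += it->second;
  return tot;
}

// [[Rcpp::export]]
List kmer_map_dump(SEXP ptr, int k) {
  XPtr<KmerMap> map(ptr);
  std::vector<uint64_t> keys;
  keys.reserve(map->size());
  for (KmerMap::const_iterator it = map->begin(); it != map->end(); ++it)
    keys.push_back(it->first);
  std::sort(keys.begin(), keys.end());  // lexicographic in A<C<G<T, stable output
  R_xlen_t n = (R_xlen_t)keys.size();
  CharacterVector km(n);
  NumericVector ct(n);
  std::string buf(k, 'A');
  const char* bases = "ACGT";
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t v = keys[i];
    for (int t = k - 1; t >= 0; --t) {
      buf[t] = bases[v & 3ULL];
      v >>= 2;
    }
    km[i] = buf;
    ct[i] = (*map)[keys[i]];
  }
  return List::create(_["kmer"] = km, _["count"] = ct);
}

// [[Rcpp::export]]
void kmer_map_set(SEXP ptr, CharacterVector kmers, NumericVector counts, int k) {
  XPtr<KmerMap> map(ptr);
  if (kmers.size() != counts.size()) stop("kmers and counts differ in length");
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    SEXP el = STRING_ELT(kmers, i);
    if ((int)LENGTH(el) != k) stop("k-mer of wrong length at entry %d", (int)(i + 1));
    uint64_t key;
    if (!encode_kmer(CHAR(el), 0, k, key))
      stop("k-mer with non-ACGT base at entry %d", (int)(i + 1));
    (*map)[key] = counts[i];
  }
}

// ------------------------------------------------------------------- overlap

struct Ovl {
  int b;        // 1-based start of the overlap in X
  int len;      // overlap length
  int mism;     // mismatching (comparable) positions
  double ratio;
  int status;   // 0 = candidate found, 2 = no valid offset
};

// mismatches in the overlap at offset b; positions where either base is not
// A/C/G/T (i.e. N) are not counted
static int mismatches_at(const char* x, int nx, const char* y, int ny, int b) {
  int len = std::min(nx - b + 1, ny);
  int m = 0;
  for (int t = 0; t < len; ++t) {
    char cx = x[b - 1 + t], cy = y[t];
    if (cx != cy && is_acgt(cx) && is_acgt(cy)) ++m;
  }
  return m;
}

static Ovl best_overlap(const char* x, int nx, const char* y, int ny, int omega) {
  Ovl res;
  res.b = 0; res.len = 0; res.mism = 0;
  res.ratio = std::numeric_limits<double>::infinity();
  res.status = 2;
  if (omega < 1) return res;
  int max_b = nx - omega + 1;
  if (max_b < 1 || ny < omega) return res;
  for (int b = 1; b <= max_b; ++b) {
    int len = std::min(nx - b + 1, ny);
    int m = mismatches_at(x, nx, y, ny, b);
    double ratio = (double)m / (double)len;
    if (ratio < res.ratio) {  // strict improvement keeps the smallest b on ties
      res.ratio = ratio;
      res.b = b;
      res.len = len;
      res.mism = m;
      res.status = 0;
    }
  }
  return res;
}

// [[Rcpp::export]]
int cpp_count_mismatches(std::string x, std::string y, int b) {
  int nx = (int)x.size(), ny = (int)y.size();
  if (b < 1 || b > nx) stop("offset b must be in [1, nchar(x)]");
  return mismatches_at(x.c_str(), nx, y.c_str(), ny, b);
}

// [[Rcpp::export]]
List cpp_find_best_overlap(std::string x, std::string y, int omega) {
  Ovl o = best_overlap(x.c_str(), (int)x.size(), y.c_str(), (int)y.size(), omega);
  return List::create(
    _["offset"] = o.b, _["overlap_length"] = o.len,
    _["mismatch_count"] = o.mism, _["mismatch_ratio"] = o.ratio,
    _["status"] = o.status);
}

// ---------------------------------------------------------------- resolution

// first pass: quality-score-based correction, in place
static void quality_pass_core(std::string& x, std::vector<int>& qx,
                              std::string& y, std::vector<int>& qy,
                              int b, int delta) {
  int nx = (int)x.size(), ny = (int)y.size();
  int len = std::min(nx - b + 1, ny);
  for (int t = 0; t < len; ++t) {
    int i = b - 1 + t;  // 0-based in X
    int ip = t;         // 0-based in Y
    char cx = x[i], cy = y[ip];
    if (cx == cy) continue;
    bool xn = !is_acgt(cx), yn = !is_acgt(cy);
    if (xn && yn) continue;                     // both indecisive: skip
    if (xn) { x[i] = cy; qx[i] = qy[ip]; continue; }  // the other base is informative
    if (yn) { y[ip] = cx; qy[ip] = qx[i]; continue; }
    if (qx[i] - qy[ip] > delta)      { y[ip] = cx; qy[ip] = qx[i]; }
    else if (qy[ip] - qx[i] > delta) { x[i]  = cy; qx[i]  = qy[ip]; }
    // |dq| <= delta: left for the context pass
  }
}

// context votes for the mismatch at 1-based (i in X, ip in Y).
// Returns per-window j, both counts and the vote; honors skip (left underrun
// of either read), break (right overrun of either read, or an uncorrected
// downstream mismatch for j > 1).
static void collect_votes_core(const std::string& x, const std::vector<int>& qx,
                               const std::string& y, const std::vector<int>& qy,
                               int i, int ip, const KmerMap& map, int k,
                               bool weighted,
                               std::vector<int>& js,
                               std::vector<double>& fc, std::vector<double>& rc,
                               std::vector<int>& vote) {
  int nx = (int)x.size(), ny = (int)y.size();
  double wx = 1.0, wy = 1.0;
  if (weighted) {
    wx = std::pow(10.0, -qx[i - 1] / 10.0);
    wy = std::pow(10.0, -qy[ip - 1] / 10.0);
  }
  for (int j = 1; j <= k; ++j) {
    if (i - k + j < 1 || ip - k + j < 1) continue;       // left boundary
    if (i + j - 1 > nx || ip + j - 1 > ny) break;        // right boundary
    if (j > 1 && x[i + j - 2] != y[ip + j - 2]) break;   // uncorrected mismatch ahead
    double cx = window_count(map, x, i - k + j - 1, k);
    double cy = window_count(map, y, ip - k + j - 1, k);
    double sx = cx * wx, sy = cy * wy;
    js.push_back(j);
    fc.push_back(cx);
    rc.push_back(cy);
    vote.push_back(sx > sy ? 1 : (sy > sx ? -1 : 0));
  }
}

// second pass: context-based correction, in place; left-to-right so that
// corrected bases feed later windows
static void context_pass_core(std::string& x, std::vector<int>& qx,
                              std::string& y, std::vector<int>& qy,
                              int b, const KmerMap& map, int k, bool weighted) {
  int nx = (int)x.size(), ny = (int)y.size();
  int len = std::min(nx - b + 1, ny);
  for (int t = 0; t < len; ++t) {
    int i = b + t;    // 1-based in X
    int ip = t + 1;   // 1-based in Y
    if (x[i - 1] == y[ip - 1]) continue;
    std::vector<int> js, vote;
    std::vector<double> fc, rc;
    collect_votes_core(x, qx, y, qy, i, ip, map, k, weighted, js, fc, rc, vote);
    int fwd = 0, rev = 0;
    for (size_t v = 0; v < vote.size(); ++v) {
      if (vote[v] > 0) ++fwd; else if (vote[v] < 0) ++rev;
    }
    if (fwd > rev) { y[ip - 1] = x[i - 1]; qy[ip - 1] = qx[i - 1]; }
    else           { x[i - 1] = y[ip - 1]; qx[i - 1] = qy[ip - 1]; }
  }
}

static std::vector<int> as_ivec(IntegerVector v) {
  return std::vector<int>(v.begin(), v.end());
}

// [[Rcpp::export]]
List cpp_quality_pass(std::string x, IntegerVector qx,
                      std::string y, IntegerVector qy, int b, int delta) {
  std::vector<int> vqx = as_ivec(qx), vqy = as_ivec(qy);
  quality_pass_core(x, vqx, y, vqy, b, delta);
  return List::create(_["x"] = x, _["qx"] = wrap(vqx),
                      _["y"] = y, _["qy"] = wrap(vqy));
}

// [[Rcpp::export]]
List cpp_collect_votes(std::string x, IntegerVector qx,
                       std::string y, IntegerVector qy,
                       int i, int ip, SEXP ptr, int k, bool weighted) {
  XPtr<KmerMap> map(ptr);
  std::vector<int> js, vote;
  std::vector<double> fc, rc;
  collect_votes_core(x, as_ivec(qx), y, as_ivec(qy), i, ip, *map, k, weighted,
                     js, fc, rc, vote);
  return List::create(_["j"] = wrap(js), _["forward_count"] = wrap(fc),
                      _["reverse_count"] = wrap(rc), _["vote"] = wrap(vote));
}

// [[Rcpp::export]]
List cpp_context_pass(std::string x, IntegerVector qx,
                      std::string y, IntegerVector qy,
                      int b, SEXP ptr, int k, bool weighted) {
  XPtr<KmerMap> map(ptr);
  std::vector<int> vqx = as_ivec(qx), vqy = as_ivec(qy);
  context_pass_core(x, vqx, y, vqy, b, *map, k, weighted);
  return List::create(_["x"] = x, _["qx"] = wrap(vqx),
                      _["y"] = y, _["qy"] = wrap(vqy));
}

// --------------------------------------------------------------- full merges

// Merge a batch of preprocessed pairs (Y already reverse-complemented).
// status: 0 merged, 1 abandoned (mismatch ratio > gamma), 2 no valid offset.
// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector xs, List qxs,
                     CharacterVector ys, List qys,
                     SEXP ptr, int k, int omega, double gamma, int delta,
                     bool weighted) {
  XPtr<KmerMap> map(ptr);
  R_xlen_t n = xs.size();
  if (ys.size() != n || qxs.size() != n || qys.size() != n)
    stop("forward and reverse batches differ in length");
  IntegerVector status(n), offset(n), ovl_len(n), mism(n);
  NumericVector ratio(n);
  CharacterVector merged(n);
  List merged_qual(n);
  for (R_xlen_t r = 0; r < n; ++r) {
    std::string x = as<std::string>(xs[r]);
    std::string y = as<std::string>(ys[r]);
    std::vector<int> qx = as_ivec(qxs[r]);
    std::vector<int> qy = as_ivec(qys[r]);
    int nx = (int)x.size(), ny = (int)y.size();
    if ((int)qx.size() != nx || (int)qy.size() != ny)
      stop("sequence/quality length mismatch at pair %d", (int)(r + 1));
    Ovl o = best_overlap(x.c_str(), nx, y.c_str(), ny, omega);
    offset[r] = o.b;
    ovl_len[r] = o.len;
    mism[r] = o.mism;
    ratio[r] = o.ratio;
    if (o.status == 2) {
      status[r] = 2;
      merged[r] = NA_STRING;
      merged_qual[r] = R_NilValue;
      continue;
    }
    if (o.ratio > gamma) {  // give up: too many mismatches
      status[r] = 1;
      merged[r] = NA_STRING;
      merged_qual[r] = R_NilValue;
      continue;
    }
    quality_pass_core(x, qx, y, qy, o.b, delta);
    context_pass_core(x, qx, y, qy, o.b, *map, k, weighted);
    // elongated read: X(1 : b-1) then the full (corrected) Y
    int b = o.b;
    std::string z = x.substr(0, b - 1) + y;
    std::vector<int> qz(qx.begin(), qx.begin() + (b - 1));
    qz.insert(qz.end(), qy.begin(), qy.end());
    // positions that stayed N on both reads carry no information
    int len = std::min(nx - b + 1, ny);
    for (int t = 0; t < len; ++t)
      if (!is_acgt(x[b - 1 + t]) && !is_acgt(y[t])) qz[b - 1 + t] = 0;
    status[r] = 0;
    merged[r] = z;
    merged_qual[r] = wrap(qz);
  }
  return List::create(_["status"] = status, _["offset"] = offset,
                      _["overlap_length"] = ovl_len,
                      _["mismatch_count"] = mism,
                      _["mismatch_ratio"] = ratio,
                      _["merged_seq"] = merged,
                      _["merged_qual"] = merged_qual);
}
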