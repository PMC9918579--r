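#include <Rcpp.h>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// Decode a UTF-8 byte sequence into code points so that umlauts and "ß"
// count as single characters, as they do on a QWERTZ keyboard.
static std::vector<uint32_t> utf8_decode(const char *s) {
  std::vector<uint32_t> out;
  const unsigned char *p = reinterpret_cast<const unsigned char *>(s);
  while (*p) {
    uint32_t cp;
    int n;
    if (*p < 0x80)       { cp = *p;         n = 1; }
    else if (*p < 0xE0)  { cp = *p & 0x1F;  n = 2; }
    else if (*p < 0xF0)  { cp = *p & 0x0F;  n = 3; }
    else                 { cp = *p & 0x07;  n = 4; }
    ++p;
    for (int i = 1; i < n && *p; ++i, ++p) cp = (cp << 6) | (*p & 0x3F);
    out.push_back(cp);
  }
  return out;
}

// Jaro similarity: matches within a window of floor(max(la, lb)/2) - 1,
// half-transpositions among matched characters counted pairwise.
static double jaro_sim(const std::vector<uint32_t> &a,
                       const std::vector<uint32_t> &b) {
  const int la = a.size(), lb = b.size();
  if (la == 0 && lb == 0) return 1.0;
  if (la == 0 || lb == 0) return 0.0;
  int window = std::max(la, lb) / 2 - 1;
  if (window < 0) window = 0;
  std::vector<char> am(la, 0), bm(lb, 0);
  int m = 0;
  for (int i = 0; i < la; ++i) {
    const int lo = std::max(0, i - window);
    const int hi = std::min(lb - 1, i + window);
    for (int j = lo; j <= hi; ++j) {
      if (!bm[j] && a[i] == b[j]) {
        am[i] = bm[j] = 1;
        ++m;
        break;
      }
    }
  }
  if (m == 0) return 0.0;
  int half_transpositions = 0, k = 0;
  for (int i = 0; i < la; ++i) {
    if (!am[i]) continue;
    while (!bm[k]) ++k;
    if (a[i] != b[k]) ++half_transpositions;
    ++k;
  }
  const double t = half_transpositions / 2.0;
  return ((double)m / la + (double)m / lb + (m - t) / m) / 3.0;
}

// Levenshtein distance, unit costs.
static int lev_dist(const std::vector<uint32_t> &a,
                    const std::vector<uint32_t> &b) {
  const int la = a.size(), lb = b.size();
  std::vector<int> prev(lb + 1), cur(lb + 1);
  for (int j = 0; j <= lb; ++j) prev[j] = j;
  for (int i = 1; i <= la; ++i) {
    cur[0] = i;
    for (int j = 1; j <= lb; ++j) {
      const int sub = prev[j - 1] + (a[i - 1] != b[j - 1]);
      cur[j] = std::min(std::min(prev[j] + 1, cur[j - 1] + 1), sub);
    }
    std::swap(prev, cur);
  }
  return prev[lb];
}

// Optimal string alignment: Levenshtein plus adjacent transposition,
// each substring edited at most once (restricted Damerau-Levenshtein).
static int osa_dist(const std::vector<uint32_t> &a,
                    const std::vector<uint32_t> &b) {
  const int la = a.size(), lb = b.size();
  std::vector<std::vector<int> > d(la + 1, std::vector<int>(lb + 1));
  for (int i = 0; i <= la; ++i) d[i][0] = i;
  for (int j = 0; j <= lb; ++j) d[0][j] = j;
  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      const int cost = a[i - 1] != b[j - 1];
      int v = std::min(std::min(d[i - 1][j] + 1, d[i][j - 1] + 1),
                       d[i - 1][j - 1] + cost);
      if (i > 1 && j > 1 && a[i - 1] == b[j - 2] && a[i - 2] == b[j - 1])
        v = std::min(v, d[i - 2][j - 2] + 1);
      d[i][j] = v;
    }
  }
  return d[la][lb];
}

// [[Rcpp::export(name = ".string_distance_cpp")]]
NumericVector string_distance_cpp(CharacterVector a, CharacterVector b,
                                  std::string method) {
  const R_xlen_t n = a.size();
  if (b.size() != n) stop("`a` and `b` must have the same length");
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (CharacterVector::is_na(a[i]) || CharacterVector::is_na(b[i])) {
      out[i] = NA_REAL;
      continue;
    }
    std::vector<uint32_t> x = utf8_decode(Rf_translateCharUTF8(a[i]));
    std::vector<uint32_t> y = utf8_decode(Rf_translateCharUTF8(b[i]));
    if (method == "jaro") {
      out[i] = 1.0 - jaro_sim(x, y);
    } else {
      const int lmax = std::max(x.size(), y.size());
      if (lmax == 0) {
        out[i] = 0.0;
      } else if (method == "levenshtein") {
        out[i] = (double)lev_dist(x, y) / lmax;
      } else if (method == "osa") {
        out[i] = (double)osa_dist(x, y) / lmax;
      } else {
        stop("unknown method: %s", method.c_str());
      }
    }
  }
  return out;
}
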