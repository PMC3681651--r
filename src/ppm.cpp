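#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

// Prediction by Partial Matching (escape method C, full symbol exclusion)
// over a finite integer alphabet, returning the ideal arithmetic code
// length in bits: the accumulated -log2 of the predictive probability of
// every symbol, escape events included.
//
// The model is built online: each symbol is coded under the statistics of
// the prefix before it, then all context counts (orders 0..max_order) are
// updated. The order -1 fallback is a uniform model over the not-yet
// excluded alphabet. Deterministic: no randomness, no ties.
//
// Contexts live in an array trie: node i stores one child index and one
// count per symbol. A rolling vector cur[d] holds the node of the length-d
// suffix ending at the current position, so each symbol costs O(max_order)
// amortized rather than O(max_order^2) re-walks.

namespace {

struct Trie {
  // flattened: for node i and symbol s, child = kids[i*A + s], count = cnt[i*A + s]
  std::vector<int32_t> kids;
  std::vector<uint32_t> cnt;
  int A;
  explicit Trie(int alphabet) : A(alphabet) { new_node(); }
  int32_t new_node() {
    int32_t id = static_cast<int32_t>(kids.size() / A);
    kids.insert(kids.end(), A, -1);
    cnt.insert(cnt.end(), A, 0u);
    return id;
  }
  int32_t child(int32_t node, int sym) { return kids[static_cast<size_t>(node) * A + sym]; }
  int32_t child_make(int32_t node, int sym) {
    size_t k = static_cast<size_t>(node) * A + sym;
    if (kids[k] < 0) {
      int32_t id = new_node();
      kids[k] = id;  // new_node() may reallocate but index k stays valid
    }
    return kids[k];
  }
  uint32_t count(int32_t node, int sym) const { return cnt[static_cast<size_t>(node) * A + sym]; }
  void bump(int32_t node, int sym) { ++cnt[static_cast<size_t>(node) * A + sym]; }
};

}  // namespace

// [[Rcpp::export(name = ".ppm_code_length")]]
double ppm_code_length(Rcpp::IntegerVector x, int alphabet_size, int max_order) {
  const int n = x.size();
  if (alphabet_size < 1) Rcpp::stop("alphabet_size must be >= 1");
  if (max_order < 0) Rcpp::stop("max_order must be >= 0");
  if (n == 0) return 0.0;

  const int A = alphabet_size;
  Trie trie(A);
  // cur[d] = trie node of the suffix of length d ending just before position t
  // (-1 if that path does not exist yet; paths are created on update, so in
  // practice cur[d] is valid whenever d <= t).
  std::vector<int32_t> cur(static_cast<size_t>(max_order) + 1, -1);
  cur[0] = 0;  // root = empty context

  std::vector<uint8_t> excluded(A, 0);
  std::vector<int> excl_touched;
  excl_touched.reserve(A);

  double bits = 0.0;

  for (int t = 0; t < n; ++t) {
    const int sym = x[t];
    if (sym == NA_INTEGER || sym < 0 || sym >= A)
      Rcpp::stop("symbol at position %d is outside the declared alphabet", t + 1);

    const int dmax = std::min(max_order, t);
    // ---- code sym: escape down from the longest context ----
    std::fill(excluded.begin(), excluded.end(), 0);
    int n_excluded = 0;
    bool coded = false;
    for (int d = dmax; d >= 0 && !coded; --d) {
      const int32_t node = cur[d];
      if (node < 0) continue;
      // totals over non-excluded symbols
      uint32_t tot = 0; int q = 0; uint32_t csym = 0;
      for (int s = 0; s < A; ++s) {
        if (excluded[s]) continue;
        uint32_t c = trie.count(node, s);
        if (c > 0) { tot += c; ++q; if (s == sym) csym = c; }
      }
      if (q == 0) continue;  // nothing predictable here: free skip
      if (csym > 0) {
        bits -= std::log2(static_cast<double>(csym) / (tot + q));
        coded = true;
      } else {
        // escape (method C: escape mass = number of distinct symbols)
        bits -= std::log2(static_cast<double>(q) / (tot + q));
        for (int s = 0; s < A; ++s)
          if (!excluded[s] && trie.count(node, s) > 0) { excluded[s] = 1; ++n_excluded; }
      }
    }
    if (!coded) {
      // order -1: uniform over the remaining alphabet
      bits += std::log2(static_cast<double>(A - n_excluded));
    }

    // ---- update counts in contexts of every order 0..dmax ----
    for (int d = 0; d <= dmax; ++d) trie.bump(cur[d], sym);

    // ---- roll suffix pointers: new length-d suffix = old length-(d-1) + sym ----
    const int ndmax = std::min(max_order, t + 1);
    for (int d = ndmax; d >= 1; --d) {
      int32_t parent = cur[d - 1];
      cur[d] = (parent >= 0) ? trie.child_make(parent, sym) : -1;
    }
    // cur[0] stays root
  }
  return bits;
}

// Batch NCS adjacency: code lengths of each row and each ordered
// concatenation of a binary raster window. Rows are units, columns 1-ms
// bins. Returns the dense NCS matrix with zero diagonal. Pairs where
// either train has no spikes carry no pattern evidence and score 0
// (mirrors the surrogate-test degenerate rule p = 1). Doing the pair
// loop here avoids 2*n^2 R-to-C++ crossings per window.
// [[Rcpp::export(name = ".ncs_matrix_binary")]]
Rcpp::NumericMatrix ncs_matrix_binary(Rcpp::IntegerMatrix raster, int max_order) {
  const int nu = raster.nrow(), nb = raster.ncol();
  if (nu < 2) Rcpp::stop("need at least 2 units");
  if (nb < 2) Rcpp::stop("window shorter than 2 bins");

  std::vector<Rcpp::IntegerVector> rows(nu);
  std::vector<double> cx(nu);
  std::vector<bool> has_spike(nu);
  for (int i = 0; i < nu; ++i) {
    Rcpp::IntegerVector r(nb);
    int tot = 0;
    for (int j = 0; j < nb; ++j) { r[j] = raster(i, j); tot += r[j]; }
    rows[i] = r;
    has_spike[i] = tot > 0;
    cx[i] = ppm_code_length(r, 2, max_order);
  }
  Rcpp::NumericMatrix out(nu, nu);
  Rcpp::IntegerVector xy(2 * nb);
  for (int i = 0; i < nu; ++i) {
    for (int j = 0; j < nu; ++j) {
      if (i == j) continue;
      if (!has_spike[i] || !has_spike[j]) { out(i, j) = 0.0; continue; }
      for (int b = 0; b < nb; ++b) { xy[b] = rows[i][b]; xy[nb + b] = rows[j][b]; }
      double cxy = ppm_code_length(xy, 2, max_order);
      double mx = std::max(cx[i], cx[j]), mn = std::min(cx[i], cx[j]);
      if (mx <= 0) Rcpp::stop("both sequences have zero code length");
      double v = 1.0 - (cxy - mn) / mx;
      if (v < 0) v = 0; else if (v > 1) v = 1;
      out(i, j) = v;
    }
  }
  return out;
}
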