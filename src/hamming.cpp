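#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Pack each 0/1 row of an n x d integer matrix into 64-bit words so that
// Hamming distance and bit-intersection counts reduce to XOR/AND + popcount.
static void pack_rows(const IntegerMatrix& m, std::vector<uint64_t>& out,
                      int& words) {
  const int n = m.nrow(), d = m.ncol();
  words = (d + 63) / 64;
  out.assign((size_t)n * words, 0ULL);
  for (int j = 0; j < d; ++j) {
    const int w = j >> 6;
    const uint64_t bit = 1ULL << (j & 63);
    for (int i = 0; i < n; ++i) {
      if (m(i, j)) out[(size_t)i * words + w] |= bit;
    }
  }
}

static inline int popcount64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0;
  while (x) { x &= x - 1; ++c; }
  return c;
#endif
}

// 1-nearest-neighbour labels under Hamming distance (== squared Euclidean on
// binary vectors). Ties resolve to the lowest training-row index.
// [[Rcpp::export]]
IntegerVector nn1_predict_cpp(IntegerMatrix train_bits, IntegerVector train_labels,
                              IntegerMatrix test_bits) {
  const int ntr = train_bits.nrow(), nte = test_bits.nrow();
  if (train_bits.ncol() != test_bits.ncol())
    stop("train/test bit widths differ");
  if (train_labels.size() != ntr)
    stop("one label per training row required");
  if (ntr == 0) stop("empty training set");
  int words;
  std::vector<uint64_t> tr, te;
  pack_rows(train_bits, tr, words);
  pack_rows(test_bits, te, words);
  IntegerVector out(nte);
  for (int i = 0; i < nte; ++i) {
    const uint64_t* q = &te[(size_t)i * words];
    int best = INT32_MAX, best_row = 0;
    for (int t = 0; t < ntr; ++t) {
      const uint64_t* p = &tr[(size_t)t * words];
      int dist = 0;
      for (int w = 0; w < words; ++w) dist += popcount64(q[w] ^ p[w]);
      if (dist < best) { best = dist; best_row = t; if (dist == 0) break; }
    }
    out[i] = train_labels[best_row];
  }
  return out;
}

// Largest Tanimoto similarity of each query row to any reference row.
// Two all-zero fingerprints count as identical (similarity 1).
// [[Rcpp::export]]
NumericVector max_tanimoto_cpp(IntegerMatrix query, IntegerMatrix reference) {
  const int nq = query.nrow(), nr = reference.nrow();
  if (query.ncol() != reference.ncol()) stop("bit widths differ");
  int words;
  std::vector<uint64_t> q, r;
  pack_rows(query, q, words);
  pack_rows(reference, r, words);
  std::vector<int> rpop(nr, 0);
  for (int t = 0; t < nr; ++t) {
    int c = 0;
    for (int w = 0; w < words; ++w) c += popcount64(r[(size_t)t * words + w]);
    rpop[t] = c;
  }
  NumericVector out(nq);
  for (int i = 0; i < nq; ++i) {
    const uint64_t* a = &q[(size_t)i * words];
    int apop = 0;
    for (int w = 0; w < words; ++w) apop += popcount64(a[w]);
    double best = (nr > 0) ? -1.0 : NA_REAL;
    for (int t = 0; t < nr; ++t) {
      const uint64_t* b = &r[(size_t)t * words];
      int inter = 0;
      for (int w = 0; w < words; ++w) inter += popcount64(a[w] & b[w]);
      const int uni = apop + rpop[t] - inter;
      const double sim = (uni == 0) ? 1.0 : (double)inter / uni;
      if (sim > best) { best = sim; if (best >= 1.0) break; }
    }
    out[i] = best;
  }
  return out;
}
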