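#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// A=0, C=1, G=2, T/U=3; anything else -1 (breaks k-mer windows)
static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': case 'U': case 'u': return 3;
    default: return -1;
  }
}

// Eulerian circuit on the de Bruijn graph B(4, order-1), Hierholzer's
// algorithm. `perm` gives, for each (order-1)-mer node, the order in which
// its four outgoing edge symbols are consumed (length 4^(order-1) * 4,
// values 0..3). Edge labels of the circuit, read cyclically, contain every
// order-mer exactly once. Returns the 4^order symbol codes.
// [[Rcpp::export]]
IntegerVector debruijn_cycle_cpp(int order, IntegerVector perm) {
  if (order < 1 || order > 13) stop("order out of supported range");
  long long n_nodes = 1LL << (2 * (order - 1));
  long long n_edges = n_nodes * 4;
  if ((long long)perm.size() != n_edges) stop("perm must have length 4^order");
  long long mask = n_nodes - 1;

  std::vector<unsigned char> next_edge((size_t)n_nodes, 0);
  std::vector<long long> vstack;
  std::vector<int> estack;
  vstack.reserve(1024);
  estack.reserve(1024);
  std::vector<int> circuit;
  circuit.reserve((size_t)n_edges);

  vstack.push_back(0);
  estack.push_back(-1);
  while (!vstack.empty()) {
    long long v = vstack.back();
    if (next_edge[(size_t)v] < 4) {
      int s = perm[v * 4 + next_edge[(size_t)v]++];
      vstack.push_back(((v << 2) | s) & mask);
      estack.push_back(s);
    } else {
      if (estack.back() >= 0) circuit.push_back(estack.back());
      vstack.pop_back();
      estack.pop_back();
    }
  }
  if ((long long)circuit.size() != n_edges)
    stop("internal error: Eulerian circuit incomplete");
  std::reverse(circuit.begin(), circuit.end());
  return wrap(circuit);
}

// Counts of all overlapping k-mers (with multiplicity) across sequences,
// indexed by k-mer code (lexicographic over A<C<G<T/U). Windows containing
// a non-ACGT/U character are skipped.
// [[Rcpp::export]]
IntegerVector count_kmers_cpp(CharacterVector seqs, int k) {
  if (k < 1 || k > 12) stop("k out of supported range");
  long long nk = 1LL << (2 * k);
  IntegerVector counts((R_xlen_t)nk);
  long long mask = nk - 1;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    long long code = 0;
    int valid = 0;
    for (const char *p = s; *p; ++p) {
      int b = base_code(*p);
      if (b < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | b) & mask;
      if (++valid >= k) counts[(R_xlen_t)code]++;
    }
  }
  return counts;
}

// Unique (k-mer code, sequence index) presence pairs: each sequence
// contributes each of its distinct k-mers once. 1-based indices on both
// sides (codes returned as code+1) for direct use from R.
// [[Rcpp::export]]
List kmer_seq_pairs_cpp(CharacterVector seqs, int k) {
  if (k < 1 || k > 12) stop("k out of supported range");
  long long nk = 1LL << (2 * k);
  long long mask = nk - 1;
  std::vector<int> kk, ss;
  std::vector<long long> buf;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    buf.clear();
    long long code = 0;
    int valid = 0;
    for (const char *p = s; *p; ++p) {
      int b = base_code(*p);
      if (b < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | b) & mask;
      if (++valid >= k) buf.push_back(code);
    }
    std::sort(buf.begin(), buf.end());
    buf.erase(std::unique(buf.begin(), buf.end()), buf.end());
    for (size_t j = 0; j < buf.size(); ++j) {
      kk.push_back((int)buf[j] + 1);
      ss.push_back((int)i + 1);
    }
  }
  return List::create(_["kmer_code"] = wrap(kk), _["seq_index"] = wrap(ss));
}

// Sum-over-windows PWM occupancy: for each sequence, the sum over all
// ungapped windows of the product of per-position base probabilities.
// pfm is a 4 x L matrix (rows A, C, G, U). Windows with invalid bases skip.
// [[Rcpp::export]]
NumericVector pwm_occupancy_cpp(CharacterVector seqs, NumericMatrix pfm) {
  if (pfm.nrow() != 4) stop("pfm must have 4 rows (A, C, G, U)");
  int L = pfm.ncol();
  NumericVector out(seqs.size());
  std::vector<int> codes;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    codes.clear();
    for (const char *p = s; *p; ++p) codes.push_back(base_code(*p));
    double total = 0.0;
    int n = (int)codes.size();
    for (int start = 0; start + L <= n; ++start) {
      double prod = 1.0;
      bool ok = true;
      for (int j = 0; j < L; ++j) {
        int b = codes[start + j];
        if (b < 0) { ok = false; break; }
        prod *= pfm(b, j);
      }
      if (ok) total += prod;
    }
    out[i] = total;
  }
  return out;
}
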