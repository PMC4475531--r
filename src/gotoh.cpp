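#include <Rcpp.h>
#include <string>
#include <vector>
#include <climits>

using namespace Rcpp;

// Glocal affine-gap alignment (Gotoh three-state recurrences).
// Contract: the full query must be aligned; the target may overhang freely
// on either side. Gap of length g costs gap_open + (g-1)*gap_extend
// (both negative). CIGAR ops: M (align), I (query base vs gap),
// D (gap vs target base). Terminal query gaps are reported as I here;
// the R layer rewrites them as soft clips for SAM emission.

static const int NEG = INT_MIN / 4;

// [[Rcpp::export]]
List gotoh_cpp(std::string query, std::string target,
               int match, int mismatch, int gap_open, int gap_extend) {
  const int m = (int) query.size();
  const int n = (int) target.size();
  if (m == 0 || n == 0) stop("gotoh_cpp: empty sequence");

  // H: best score ending in aligned/any state; E: gap in target (op I);
  // F: gap in query (op D). (m+1) x (n+1), row-major.
  std::vector<int> H((m + 1) * (n + 1), NEG);
  std::vector<int> E((m + 1) * (n + 1), NEG);
  std::vector<int> F((m + 1) * (n + 1), NEG);
  const int W = n + 1;

  for (int j = 0; j <= n; ++j) H[j] = 0;      // free leading target overhang
  for (int i = 1; i <= m; ++i) {               // query overhang = insertions
    E[i * W] = gap_open + (i - 1) * gap_extend;
    H[i * W] = E[i * W];
  }

  for (int i = 1; i <= m; ++i) {
    const char qc = query[i - 1];
    for (int j = 1; j <= n; ++j) {
      const int idx = i * W + j;
      const int up = (i - 1) * W + j, left = i * W + (j - 1),
                diag = (i - 1) * W + (j - 1);
      int e = H[up] + gap_open;
      if (E[up] != NEG && E[up] + gap_extend > e) e = E[up] + gap_extend;
      E[idx] = e;
      int f = H[left] + gap_open;
      if (F[left] != NEG && F[left] + gap_extend > f) f = F[left] + gap_extend;
      F[idx] = f;
      const char tc = target[j - 1];
      const int s = (qc == tc && qc != 'N') ? match : mismatch;
      int h = H[diag] + s;
      if (E[idx] > h) h = E[idx];
      if (F[idx] > h) h = F[idx];
      H[idx] = h;
    }
  }

  // free trailing target overhang: best over last row, leftmost end on ties
  int best = NEG, jend = 0;
  for (int j = 0; j <= n; ++j)
    if (H[m * W + j] > best) { best = H[m * W + j]; jend = j; }

  // traceback
  std::string ops;
  ops.reserve(m + n);
  int i = m, j = jend;
  char state = 'H';
  while (i > 0) {
    const int idx = i * W + j;
    if (state == 'H') {
      if (j > 0) {
        const char tc = target[j - 1];
        const int s = (query[i - 1] == tc && query[i - 1] != 'N') ? match
                                                                  : mismatch;
        if (H[idx] == H[(i - 1) * W + (j - 1)] + s) {
          ops.push_back('M');
          --i; --j;
          continue;
        }
      }
      if (H[idx] == F[idx]) { state = 'F'; continue; }
      state = 'E';
      continue;
    } else if (state == 'E') {
      ops.push_back('I');
      const int up = (i - 1) * W + j;
      state = (E[idx] == H[up] + gap_open) ? 'H' : 'E';
      --i;
    } else { // F
      ops.push_back('D');
      const int left = i * W + (j - 1);
      state = (F[idx] == H[left] + gap_open) ? 'H' : 'F';
      --j;
    }
  }
  const int target_offset = j;

  // run-length encode reversed ops
  std::string cigar;
  int k = (int) ops.size();
  int p = k - 1;
  while (p >= 0) {
    const char op = ops[p];
    int run = 0;
    while (p >= 0 && ops[p] == op) { ++run; --p; }
    cigar += std::to_string(run);
    cigar.push_back(op);
  }

  return List::create(_["score"] = best, _["cigar"] = cigar,
                      _["target_offset"] = target_offset);
}
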