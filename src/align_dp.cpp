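#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// Alignment core: local alignment under a two-piece (dual) affine gap cost.
// A gap of length L costs min(gap_open + L*gap_extend,
//                             long_gap_open + L*long_gap_extend),
// implemented with two parallel affine gap states per direction (Durbin-style
// E/F states, doubled). The long-gap piece keeps multi-kilobase deletions as
// a single D run instead of fragmenting them into mismatch stretches.
//
// Free end handling: both query ends may be soft-clipped and both reference
// ends are free, so the optimum is a maximal-scoring contiguous placement
// (Smith-Waterman recursion); the mappability floor is enforced by the
// caller.
//
// Traceback byte layout per cell:
//   bits 0-2: source of H (0 stop, 1 diag, 2 E1, 3 E2, 4 F1, 5 F2)
//   bit 3: E1 extends (came from E1, else opened from H)
//   bit 4: E2 extends;  bit 5: F1 extends;  bit 6: F2 extends
// E states consume reference (CIGAR D), F states consume query (CIGAR I).

static const int NEG_INF = INT_MIN / 4;

// [[Rcpp::export]]
List align_dp_cpp(const std::string& query, const std::string& ref,
                  int match, int mismatch,
                  int gap_open, int gap_extend,
                  int long_gap_open, int long_gap_extend) {
  const int n = (int) query.size();
  const int m = (int) ref.size();
  if (n == 0 || m == 0) stop("empty sequence");
  const double cells = (double)(n + 1) * (double)(m + 1);
  if (cells > 2.1e9) stop("alignment problem too large");

  std::vector<int> H(m + 1, 0), Hprev(m + 1, 0);
  std::vector<int> E1(m + 1), E2(m + 1);      // current row, gap in query (D)
  std::vector<int> F1(m + 1, NEG_INF), F2(m + 1, NEG_INF); // gap in ref (I)
  std::vector<uint8_t> tb((size_t)(n + 1) * (m + 1), 0);

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    Hprev.swap(H);
    H[0] = 0;
    E1[0] = NEG_INF; E2[0] = NEG_INF;
    const char qc = query[i - 1];
    uint8_t* tbrow = &tb[(size_t)i * (m + 1)];
    for (int j = 1; j <= m; ++j) {
      uint8_t t = 0;
      // E: deletion from reference, moving along j within row i
      int e1o = H[j - 1] - gap_open - gap_extend;
      int e1e = E1[j - 1] - gap_extend;
      if (e1e >= e1o) { E1[j] = e1e; t |= 0x08; } else E1[j] = e1o;
      int e2o = H[j - 1] - long_gap_open - long_gap_extend;
      int e2e = E2[j - 1] - long_gap_extend;
      if (e2e >= e2o) { E2[j] = e2e; t |= 0x10; } else E2[j] = e2o;
      // F: insertion relative to reference, moving along i within column j
      int f1o = Hprev[j] - gap_open - gap_extend;
      int f1e = F1[j] - gap_extend;
      if (f1e >= f1o) { F1[j] = f1e; t |= 0x20; } else F1[j] = f1o;
      int f2o = Hprev[j] - long_gap_open - long_gap_extend;
      int f2e = F2[j] - long_gap_extend;
      if (f2e >= f2o) { F2[j] = f2e; t |= 0x40; } else F2[j] = f2o;

      const char rc = ref[j - 1];
      int diag = Hprev[j - 1] + ((qc == rc && qc != 'N' && rc != 'N') ? match : -mismatch);

      int h = 0; uint8_t src = 0;
      if (diag > h) { h = diag; src = 1; }
      if (E1[j] > h) { h = E1[j]; src = 2; }
      if (E2[j] > h) { h = E2[j]; src = 3; }
      if (F1[j] > h) { h = F1[j]; src = 4; }
      if (F2[j] > h) { h = F2[j]; src = 5; }
      H[j] = h;
      tbrow[j] = t | src;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  // traceback from (bi, bj) in state H
  std::string ops;              // reversed op chars
  ops.reserve(n + 16);
  int i = bi, j = bj;
  int state = 0;                // 0 = H, 1 = E1, 2 = E2, 3 = F1, 4 = F2
  while (true) {
    uint8_t t = tb[(size_t)i * (m + 1) + j];
    if (state == 0) {
      uint8_t src = t & 0x07;
      if (src == 0) break;
      if (src == 1) {
        ops.push_back((query[i - 1] == ref[j - 1] &&
                       query[i - 1] != 'N' && ref[j - 1] != 'N') ? '=' : 'X');
        --i; --j;
      } else if (src == 2) state = 1;
      else if (src == 3) state = 2;
      else if (src == 4) state = 3;
      else state = 4;
    } else if (state == 1) {
      ops.push_back('D'); bool ext = t & 0x08; --j; if (!ext) state = 0;
    } else if (state == 2) {
      ops.push_back('D'); bool ext = t & 0x10; --j; if (!ext) state = 0;
    } else if (state == 3) {
      ops.push_back('I'); bool ext = t & 0x20; --i; if (!ext) state = 0;
    } else {
      ops.push_back('I'); bool ext = t & 0x40; --i; if (!ext) state = 0;
    }
  }

  // run-length encode (reversing), with soft clips at the query ends
  std::string cigar;
  char buf[16];
  if (i > 0) { snprintf(buf, sizeof(buf), "%dS", i); cigar += buf; }
  int k = (int) ops.size() - 1;
  while (k >= 0) {
    char op = ops[k];
    int run = 0;
    while (k >= 0 && ops[k] == op) { ++run; --k; }
    snprintf(buf, sizeof(buf), "%d%c", run, op);
    cigar += buf;
  }
  if (n - bi > 0) { snprintf(buf, sizeof(buf), "%dS", n - bi); cigar += buf; }

  return List::create(_["score"] = best,
                      _["q_start"] = i, _["q_end"] = bi,
                      _["r_start"] = j, _["r_end"] = bj,
                      _["cigar"] = cigar);
}

// Error-tolerant infix search of a primer within a text window
// (unit-cost edit distance; pattern aligned globally, text ends free).
// Returns, per text, the minimal edit count and the 1-based end position of
// the pattern's placement (smallest end among minimal-edit placements), or
// edits = max_edits + 1 when no placement is within budget.

// [[Rcpp::export]]
DataFrame primer_scan_cpp(CharacterVector texts, std::string pattern,
                          int max_edits) {
  const int plen = (int) pattern.size();
  const int nt = texts.size();
  IntegerVector edits(nt), endpos(nt);
  std::vector<int> col(plen + 1), ncol(plen + 1);
  for (int r = 0; r < nt; ++r) {
    std::string txt = as<std::string>(texts[r]);
    const int tlen = (int) txt.size();
    int bestE = max_edits + 1, bestEnd = NA_INTEGER;
    for (int k = 0; k <= plen; ++k) col[k] = k;   // column for text prefix 0
    if (col[plen] < bestE) { bestE = col[plen]; bestEnd = 0; }
    for (int j = 1; j <= tlen; ++j) {
      ncol[0] = 0;                                 // free text prefix
      const char tc = txt[j - 1];
      for (int k = 1; k <= plen; ++k) {
        int sub = col[k - 1] + (pattern[k - 1] == tc ? 0 : 1);
        int del = col[k] + 1;       // skip text char
        int ins = ncol[k - 1] + 1;  // skip pattern char
        int v = sub;
        if (del < v) v = del;
        if (ins < v) v = ins;
        ncol[k] = v;
      }
      col.swap(ncol);
      if (col[plen] < bestE) { bestE = col[plen]; bestEnd = j; }
    }
    edits[r] = bestE;
    endpos[r] = bestEnd;
  }
  return DataFrame::create(_["edits"] = edits, _["end"] = endpos);
}

// Per-read sequencing-error injection (substitution / insertion /
// deletion, disjoint per base), using R's RNG so results are reproducible
// under set.seed().

// [[Rcpp::export]]
CharacterVector mutate_reads_cpp(const std::string& tmpl, int n,
                                 double sub, double ins, double del) {
  CharacterVector out(n);
  const char* bases = "ACGT";
  const int L = (int) tmpl.size();
  std::string buf;
  for (int r = 0; r < n; ++r) {
    buf.clear();
    buf.reserve(L + 16);
    for (int i = 0; i < L; ++i) {
      double u = R::unif_rand();
      char c = tmpl[i];
      if (u < sub) {
        int cur = 0;
        switch (c) { case 'A': cur = 0; break; case 'C': cur = 1; break;
                     case 'G': cur = 2; break; case 'T': cur = 3; break;
                     default: cur = (int)(R::unif_rand() * 4.0); }
        int alt = (cur + 1 + (int)(R::unif_rand() * 3.0)) % 4;
        buf.push_back(bases[alt]);
      } else if (u < sub + del) {
        // base dropped
      } else if (u < sub + del + ins) {
        buf.push_back(c);
        buf.push_back(bases[(int)(R::unif_rand() * 4.0)]);
      } else {
        buf.push_back(c);
      }
    }
    out[r] = buf;
  }
  return out;
}
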