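#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

// Gotoh local alignment (affine gaps) with full traceback.
// Gap of length L costs gap_open + L * gap_extend (both passed as positive costs).
// Returns 0-based half-open coordinates on query and target plus a cs-style
// difference string in forward-target orientation:
//   :N match run, *TQ mismatch (target base, query base), +SEQ insertion in
//   query, -SEQ deletion from query (target bases skipped).
// band <= 0 means full dynamic programming; band > 0 restricts the computed
// cells to |j - i*m/n| <= band (a diagonal band scaled for length difference).

static const int NEG = -(1 << 28);

// [[Rcpp::export]]
List align_pair_cpp(std::string q, std::string t, int match, int mismatch,
                    int gap_open, int gap_extend, int band) {
  const int n = (int)q.size(), m = (int)t.size();
  if (n == 0 || m == 0)
    return List::create(_["score"] = 0, _["qstart"] = 0, _["qend"] = 0,
                        _["tstart"] = 0, _["tend"] = 0, _["cs"] = "");
  // traceback byte: bits 0-1 H source (0 stop, 1 diag, 2 E, 3 F),
  // bit 2: E opened here, bit 3: F opened here
  std::vector<uint8_t> tb((size_t)(n + 1) * (size_t)(m + 1), 0);
  std::vector<int> Hprev(m + 1, 0), Hcur(m + 1, 0);
  std::vector<int> Fprev(m + 1, NEG), Fcur(m + 1, NEG);
  const int oe = gap_open + gap_extend;
  int best = 0, bi = 0, bj = 0;

  for (int i = 1; i <= n; ++i) {
    int jlo = 1, jhi = m;
    if (band > 0) {
      int center = (int)((double)i * (double)m / (double)n + 0.5);
      jlo = std::max(1, center - band);
      jhi = std::min(m, center + band);
      std::fill(Hcur.begin(), Hcur.end(), NEG);
      std::fill(Fcur.begin(), Fcur.end(), NEG);
    }
    Hcur[0] = 0;
    int Eleft = NEG;
    const char qc = q[(size_t)i - 1];
    uint8_t *tbrow = &tb[(size_t)i * (size_t)(m + 1)];
    const char *tp = t.c_str();
    for (int j = jlo; j <= jhi; ++j) {
      uint8_t code = 0;
      // E: gap in query (consume target base j)
      int e_open = Hcur[j - 1] - oe;
      int e_ext = Eleft - gap_extend;
      int e;
      if (e_open >= e_ext) { e = e_open; code |= 4; } else e = e_ext;
      // F: gap in target (consume query base i)
      int f_open = Hprev[j] - oe;
      int f_ext = Fprev[j] - gap_extend;
      int f;
      if (f_open >= f_ext) { f = f_open; code |= 8; } else f = f_ext;
      const char tc = tp[j - 1];
      int diag = Hprev[j - 1] +
        ((qc == tc && qc != 'N' && tc != 'N') ? match : mismatch);
      int h = 0; uint8_t src = 0;
      if (diag > h) { h = diag; src = 1; }
      if (e > h) { h = e; src = 2; }
      if (f > h) { h = f; src = 3; }
      Hcur[j] = h; Fcur[j] = f; Eleft = e;
      tbrow[j] = code | src;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
    if (band <= 0) {
      // restore invariants for the next row in full mode
      Hcur.assign(m + 1, 0);
      Fcur.assign(m + 1, NEG);
    }
  }

  if (best <= 0)
    return List::create(_["score"] = 0, _["qstart"] = 0, _["qend"] = 0,
                        _["tstart"] = 0, _["tend"] = 0, _["cs"] = "");

  // traceback from (bi, bj)
  std::vector<char> op, qb, tbch;
  int i = bi, j = bj;
  int state = 0;  // 0 = H, 1 = E, 2 = F
  while (i > 0 || j > 0) {
    const size_t c = (size_t)i * (size_t)(m + 1) + (size_t)j;
    if (state == 0) {
      uint8_t src = tb[c] & 3;
      if (src == 0) break;
      if (src == 1) {
        char qc = q[(size_t)i - 1], tc = t[(size_t)j - 1];
        op.push_back((qc == tc && qc != 'N') ? 'M' : 'X');
        qb.push_back(qc); tbch.push_back(tc);
        --i; --j;
      } else if (src == 2) state = 1;
      else state = 2;
    } else if (state == 1) {  // E: deletion (target base without query)
      op.push_back('D'); qb.push_back('-'); tbch.push_back(t[(size_t)j - 1]);
      bool opened = (tb[c] & 4) != 0;
      --j;
      if (opened) state = 0;
    } else {  // F: insertion (query base without target)
      op.push_back('I'); qb.push_back(q[(size_t)i - 1]); tbch.push_back('-');
      bool opened = (tb[c] & 8) != 0;
      --i;
      if (opened) state = 0;
    }
    if (i == 0 && j == 0) break;
  }
  const int qstart = i, tstart = j;

  // ops are reversed; build cs string forward
  std::string cs;
  cs.reserve(op.size() + 16);
  int k = (int)op.size() - 1;
  while (k >= 0) {
    char o = op[(size_t)k];
    if (o == 'M') {
      int run = 0;
      while (k >= 0 && op[(size_t)k] == 'M') { ++run; --k; }
      cs += ":" + std::to_string(run);
    } else if (o == 'X') {
      cs += "*";
      cs += tbch[(size_t)k];
      cs += qb[(size_t)k];
      --k;
    } else if (o == 'I') {
      cs += "+";
      while (k >= 0 && op[(size_t)k] == 'I') { cs += qb[(size_t)k]; --k; }
    } else {  // D
      cs += "-";
      while (k >= 0 && op[(size_t)k] == 'D') { cs += tbch[(size_t)k]; --k; }
    }
  }

  return List::create(_["score"] = best, _["qstart"] = qstart, _["qend"] = bi,
                      _["tstart"] = tstart, _["tend"] = bj, _["cs"] = cs);
}

// Walk a cs difference string and extract the insertion at a deletion
// junction. Returns a one-element character vector: the inserted sequence
// (possibly ""), or NA when the read is not callable at the junction
// (insufficient coverage or flanking aligned bases). Throws when the cs
// string is inconsistent with the coordinates.
// [[Rcpp::export]]
CharacterVector extract_cs_insertion_cpp(std::string cs, int tstart, int tend,
                                         int junction, int flank, int tol) {
  if (tstart > junction - flank || tend < junction + flank)
    return CharacterVector::create(NA_STRING);
  int tpos = tstart;
  long aligned_left = 0, aligned_right = 0;
  std::string ins;
  size_t p = 0;
  const size_t L = cs.size();
  while (p < L) {
    char op = cs[p++];
    if (op == ':') {
      int len = 0;
      while (p < L && cs[p] >= '0' && cs[p] <= '9') len = len * 10 + (cs[p++] - '0');
      int lo = tpos, hi = tpos + len;
      aligned_left += std::max(0, std::min(hi, junction) - lo);
      aligned_right += std::max(0, hi - std::max(lo, junction));
      tpos = hi;
    } else if (op == '*') {
      if (p + 2 > L) stop("malformed cs string");
      p += 2;
      if (tpos < junction) aligned_left += 1; else aligned_right += 1;
      tpos += 1;
    } else if (op == '+') {
      std::string seq;
      while (p < L && ((cs[p] >= 'A' && cs[p] <= 'Z') || (cs[p] >= 'a' && cs[p] <= 'z')))
        seq += (char)toupper(cs[p++]);
      if (std::abs(tpos - junction) <= tol) ins += seq;
    } else if (op == '-') {
      int len = 0;
      while (p < L && ((cs[p] >= 'A' && cs[p] <= 'Z') || (cs[p] >= 'a' && cs[p] <= 'z'))) {
        ++len; ++p;
      }
      tpos += len;
    } else {
      stop("malformed cs string");
    }
  }
  if (tpos != tend) stop("cs string inconsistent with target coordinates");
  if (aligned_left < flank || aligned_right < flank)
    return CharacterVector::create(NA_STRING);
  return CharacterVector::create(ins);
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t k = 0; k < x.size(); ++k) {
    std::string s = as<std::string>(x[k]);
    std::string r(s.rbegin(), s.rend());
    for (auto &c : r) {
      switch (c) {
        case 'A': c = 'T'; break; case 'T': c = 'A'; break;
        case 'C': c = 'G'; break; case 'G': c = 'C'; break;
        case 'a': c = 't'; break; case 't': c = 'a'; break;
        case 'c': c = 'g'; break; case 'g': c = 'c'; break;
        default: c = 'N';
      }
    }
    out[k] = r;
  }
  if (x.size() > 0 && !Rf_isNull(x.attr("names"))) out.attr("names") = x.attr("names");
  return out;
}
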