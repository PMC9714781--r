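#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Smith-Waterman-Gotoh local alignment with affine gaps and full traceback.
// Scoring: match/mismatch per base; a gap of length L costs gap_open + L * gap_ext.
// Traceback preference on ties: diagonal > gap-in-ref (I) > gap-in-query (D),
// which keeps alignments maximally anchored on substitutions.
//
// DP uses rolling rows for the score matrices; the traceback is a packed
// byte per cell: bits 0-1 = H source (0 stop, 1 diag, 2 E, 3 F),
// bit 2 = E opened here, bit 3 = F opened here.

static const int NEG_INF = -1 << 28;

struct AlnResult {
  int score, qstart, qend, sstart, send, matches, aln_length;
  std::string cigar;
};

static AlnResult sw_core(const std::string& query, const std::string& ref,
                         int match, int mismatch, int gap_open, int gap_ext) {
  const int n = (int)query.size();
  const int m = (int)ref.size();
  const int oc = gap_open + gap_ext;

  std::vector<int> Hrow((size_t)m + 1, 0);
  std::vector<int> Erow((size_t)m + 1, NEG_INF);
  std::vector<unsigned char> tb((size_t)n * m, 0);

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const char qc = query[(size_t)i - 1];
    int Hdiag = Hrow[0];  // H[i-1][j-1]
    int Hleft = 0;        // H[i][j-1]
    int Fcur = NEG_INF;   // F[i][j-1] -> F[i][j]
    unsigned char* tbrow = &tb[(size_t)(i - 1) * m];
    for (int j = 1; j <= m; ++j) {
      unsigned char code = 0;
      // E: vertical gap (consumes query)
      int e_open = Hrow[j] - oc, e_ext = Erow[j] - gap_ext;
      int e;
      if (e_open >= e_ext) { e = e_open; code |= 4; }
      else e = e_ext;
      // F: horizontal gap (consumes ref)
      int f_open = Hleft - oc, f_ext = Fcur - gap_ext;
      int f;
      if (f_open >= f_ext) { f = f_open; code |= 8; }
      else f = f_ext;
      int diag = Hdiag + (qc == ref[(size_t)j - 1] ? match : mismatch);
      int h = 0; unsigned char src = 0;
      if (diag >= h) { h = diag; src = 1; }
      if (e > h) { h = e; src = 2; }
      if (f > h) { h = f; src = 3; }
      if (h <= 0) { h = 0; src = 0; }
      tbrow[j - 1] = code | src;
      Hdiag = Hrow[j];
      Hrow[j] = h; Erow[j] = e;
      Hleft = h; Fcur = f;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  // traceback from (bi, bj)
  std::string ops;  // reversed
  int i = bi, j = bj, matches = 0;
  char state = 'H';
  while (i > 0 && j > 0) {
    unsigned char code = tb[(size_t)(i - 1) * m + (j - 1)];
    if (state == 'H') {
      unsigned char src = code & 3;
      if (src == 0) break;
      if (src == 1) {
        ops.push_back('M');
        if (query[(size_t)i - 1] == ref[(size_t)j - 1]) ++matches;
        --i; --j;
      } else if (src == 2) state = 'E';
      else state = 'F';
    } else if (state == 'E') {
      ops.push_back('I');
      if (code & 4) state = 'H';
      --i;
    } else {
      ops.push_back('D');
      if (code & 8) state = 'H';
      --j;
    }
  }

  std::string cigar;
  int run = 0; char cur = 0;
  for (int t = (int)ops.size() - 1; t >= 0; --t) {
    if (ops[(size_t)t] == cur) ++run;
    else {
      if (run > 0) cigar += std::to_string(run) + cur;
      cur = ops[(size_t)t]; run = 1;
    }
  }
  if (run > 0) cigar += std::to_string(run) + cur;

  AlnResult r;
  r.score = best; r.qstart = i; r.qend = bi; r.sstart = j; r.send = bj;
  r.matches = matches; r.aln_length = (int)ops.size(); r.cigar = cigar;
  return r;
}

// [[Rcpp::export(name = ".sw_align")]]
List sw_align(const std::string& query, const std::string& ref,
              int match = 2, int mismatch = -2,
              int gap_open = 6, int gap_ext = 1) {
  AlnResult r = sw_core(query, ref, match, mismatch, gap_open, gap_ext);
  return List::create(
    _["score"] = r.score,
    _["qstart"] = r.qstart, _["qend"] = r.qend,
    _["sstart"] = r.sstart, _["send"] = r.send,
    _["cigar"] = r.cigar,
    _["matches"] = r.matches,
    _["aln_length"] = r.aln_length);
}

// one query against many references; vector results in reference order
// [[Rcpp::export(name = ".sw_align_multi")]]
List sw_align_multi(const std::string& query, const CharacterVector& refs,
                    int match = 2, int mismatch = -2,
                    int gap_open = 6, int gap_ext = 1) {
  const int k = refs.size();
  IntegerVector score(k), qstart(k), qend(k), sstart(k), send(k), matches(k),
      aln_length(k);
  CharacterVector cigar(k);
  for (int r = 0; r < k; ++r) {
    AlnResult a = sw_core(query, as<std::string>(refs[r]),
                          match, mismatch, gap_open, gap_ext);
    score[r] = a.score; qstart[r] = a.qstart; qend[r] = a.qend;
    sstart[r] = a.sstart; send[r] = a.send; matches[r] = a.matches;
    aln_length[r] = a.aln_length; cigar[r] = a.cigar;
  }
  return List::create(
    _["score"] = score, _["qstart"] = qstart, _["qend"] = qend,
    _["sstart"] = sstart, _["send"] = send, _["cigar"] = cigar,
    _["matches"] = matches, _["aln_length"] = aln_length);
}
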