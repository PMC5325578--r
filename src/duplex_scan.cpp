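#include <Rcpp.h>
using namespace Rcpp;

// Bases are encoded 0=A, 1=C, 2=G, 3=T; anything else (N etc.) never pairs.
// Pair states: 0 = Watson-Crick, 1 = G:U wobble, 2 = mismatch.
static inline int pair_state(int m, int t) {
  if (m < 0 || t < 0) return 2;
  if ((m == 0 && t == 3) || (m == 3 && t == 0) ||
      (m == 1 && t == 2) || (m == 2 && t == 1)) return 0;
  // miRNA G : target T(U)  or  miRNA U(T) : target G
  if ((m == 2 && t == 3) || (m == 3 && t == 2)) return 1;
  return 2;
}

static inline double base_penalty(int st) {
  return st == 0 ? 0.0 : (st == 1 ? 0.5 : 1.0);
}

static inline char state_sym(int st) {
  return st == 0 ? ':' : (st == 1 ? '.' : ' ');
}

struct Hits {
  std::vector<int> start, end, site, gap_pos, bulge_pos;
  std::vector<double> score;
  std::vector<std::string> path;
  void push(int s, int e, int si, double sc, int g, int b, const std::string& p) {
    start.push_back(s); end.push_back(e); site.push_back(si);
    score.push_back(sc); gap_pos.push_back(g); bulge_pos.push_back(b);
    path.push_back(p);
  }
};

// Exhaustive antiparallel duplex scan of one miRNA against one transcript.
//
// miRNA position 1 (5') pairs the 3'-most base of the target window.
// Penalties: mismatch 1, G:U 0.5, gap/bulge 1; doubled when the miRNA
// position lies in the core 2-13 (a bulge between miRNA b and b+1 is
// doubled when both flanks are in the core, i.e. b in 2..12).
// A candidate requires score <= max_score, Watson-Crick pairs at miRNA
// positions 10 and 11, and no gap/bulge at or between those positions.
// site = 1-based target position paired with miRNA position 10.
// [[Rcpp::export]]
DataFrame scan_duplex_cpp(IntegerVector mir, IntegerVector tgt, double max_score) {
  const int L = mir.size(), n = tgt.size();
  const double eps = 1e-9;
  Hits h;

  // ungapped windows of length L
  for (int s = 0; s + L <= n; ++s) {
    double sc = 0.0; bool ok = true; int site = 0;
    std::string path(L, ' ');
    for (int i = 1; i <= L; ++i) {
      int tpos = s + L - i;
      int st = pair_state(mir[i - 1], tgt[tpos]);
      if ((i == 10 || i == 11) && st != 0) { ok = false; break; }
      double pen = base_penalty(st);
      if (i >= 2 && i <= 13) pen *= 2.0;
      sc += pen;
      if (sc > max_score + eps) { ok = false; break; }
      path[i - 1] = state_sym(st);
      if (i == 10) site = tpos + 1;
    }
    if (ok) h.push(s + 1, s + L, site, sc, 0, 0, path);
  }

  // one target gap: miRNA position g unpaired, window length L-1
  for (int g = 1; g <= L; ++g) {
    if (g == 10 || g == 11) continue;
    double gpen = (g >= 2 && g <= 13) ? 2.0 : 1.0;
    if (gpen > max_score + eps) continue;
    for (int s = 0; s + (L - 1) <= n; ++s) {
      double sc = gpen; bool ok = true; int site = 0;
      std::string path(L, ' ');
      path[g - 1] = '-';
      int idx = s + L - 2;
      for (int i = 1; i <= L; ++i) {
        if (i == g) continue;
        int st = pair_state(mir[i - 1], tgt[idx]);
        if ((i == 10 || i == 11) && st != 0) { ok = false; break; }
        double pen = base_penalty(st);
        if (i >= 2 && i <= 13) pen *= 2.0;
        sc += pen;
        if (sc > max_score + eps) { ok = false; break; }
        path[i - 1] = state_sym(st);
        if (i == 10) site = idx + 1;
        --idx;
      }
      if (ok) h.push(s + 1, s + L - 1, site, sc, g, 0, path);
    }
  }

  // one bulged target base between miRNA positions b and b+1, window L+1
  for (int b = 1; b <= L - 1; ++b) {
    if (b == 10) continue;
    double bpen = (b >= 2 && b <= 12) ? 2.0 : 1.0;
    if (bpen > max_score + eps) continue;
    for (int s = 0; s + (L + 1) <= n; ++s) {
      double sc = bpen; bool ok = true; int site = 0;
      std::string path(L + 1, ' ');
      int idx = s + L;
      int pi = 0;
      for (int i = 1; i <= L; ++i) {
        int st = pair_state(mir[i - 1], tgt[idx]);
        if ((i == 10 || i == 11) && st != 0) { ok = false; break; }
        double pen = base_penalty(st);
        if (i >= 2 && i <= 13) pen *= 2.0;
        sc += pen;
        if (sc > max_score + eps) { ok = false; break; }
        path[pi++] = state_sym(st);
        if (i == 10) site = idx + 1;
        --idx;
        if (i == b) { path[pi++] = '^'; --idx; }
      }
      if (ok) h.push(s + 1, s + L + 1, site, sc, 0, b, path);
    }
  }

  return DataFrame::create(
    _["start"] = h.start, _["end"] = h.end, _["site"] = h.site,
    _["score"] = h.score, _["gap_pos"] = h.gap_pos,
    _["bulge_pos"] = h.bulge_pos, _["pairing"] = h.path,
    _["stringsAsFactors"] = false);
}
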