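#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Semi-global affine-gap alignment of a read against an amplicon reference.
// The read is aligned end to end; reference overhangs at either end are free
// (standard "glocal" convention for amplicon reads fully contained in the
// reference). Scoring: match +2, mismatch -3, gap open -8, gap extend -1,
// i.e. a gap of length L costs 8 + L. 'N' (either sequence) never matches.
//
// Tie-breaking is deterministic: on equal score the traceback prefers a
// diagonal step (match/mismatch) over a gap, then a gap in the read
// (reference base consumed) over a gap in the reference; among equal-score
// end columns the leftmost is chosen. This makes alignments byte-stable.

static const int MATCH = 2;
static const int MISMATCH = -3;
static const int GAP_OPEN = 8;   // cost of the first gapped base (8 + 1*ext applied together below)
static const int GAP_EXT = 1;
static const int NEG_INF = -1000000000;

inline int subscore(char a, char b) {
  if (a == 'N' || b == 'N') return MISMATCH;
  return (a == b) ? MATCH : MISMATCH;
}

// [[Rcpp::export]]
List cpp_align_read(std::string read, std::string ref) {
  const int m = (int) read.size();
  const int n = (int) ref.size();
  if (m == 0) stop("empty read");
  if (n == 0) stop("empty reference");

  // State matrices: M diag, IX gap in reference (read base over '-'),
  // IY gap in read ('-' over reference base).
  std::vector<int> M((m + 1) * (n + 1), NEG_INF);
  std::vector<int> IX((m + 1) * (n + 1), NEG_INF);
  std::vector<int> IY((m + 1) * (n + 1), NEG_INF);
  const int W = n + 1;
#define AT(i, j) ((i) * W + (j))

  // Row 0: zero read consumed, any reference prefix skipped for free.
  for (int j = 0; j <= n; ++j) M[AT(0, j)] = 0;
  // Column 0: read prefix hangs off the left reference end -> penalized gap.
  for (int i = 1; i <= m; ++i) IX[AT(i, 0)] = -(GAP_OPEN + GAP_EXT * i);

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const int s = subscore(read[i - 1], ref[j - 1]);
      int dm = M[AT(i - 1, j - 1)], dx = IX[AT(i - 1, j - 1)], dy = IY[AT(i - 1, j - 1)];
      int best = dm >= dx ? dm : dx;
      if (dy > best) best = dy;
      if (best > NEG_INF) M[AT(i, j)] = best + s;

      int xm = M[AT(i - 1, j)], xx = IX[AT(i - 1, j)], xy = IY[AT(i - 1, j)];
      int open = (xm >= xy ? xm : xy);
      int bx = NEG_INF;
      if (open > NEG_INF) bx = open - (GAP_OPEN + GAP_EXT);
      if (xx > NEG_INF && xx - GAP_EXT > bx) bx = xx - GAP_EXT;
      IX[AT(i, j)] = bx;

      int ym = M[AT(i, j - 1)], yy = IY[AT(i, j - 1)], yx = IX[AT(i, j - 1)];
      int openy = (ym >= yx ? ym : yx);
      int by = NEG_INF;
      if (openy > NEG_INF) by = openy - (GAP_OPEN + GAP_EXT);
      if (yy > NEG_INF && yy - GAP_EXT > by) by = yy - GAP_EXT;
      IY[AT(i, j)] = by;
    }
  }

  // Final: best over end columns (trailing reference overhang free),
  // leftmost column wins ties; state preference M > IY > IX.
  int best = NEG_INF, bj = 0, bstate = 0; // 0 = M, 1 = IY, 2 = IX
  for (int j = 0; j <= n; ++j) {
    int vals[3] = { M[AT(m, j)], IY[AT(m, j)], IX[AT(m, j)] };
    for (int s = 0; s < 3; ++s) {
      if (vals[s] > best) { best = vals[s]; bj = j; bstate = s; }
    }
  }

  // Traceback.
  std::string ap, ar; // aligned read / aligned reference, built reversed
  int i = m, j = bj, state = bstate;
  while (i > 0) {
    if (state == 0) { // M
      if (j == 0) stop("internal traceback error");
      ap.push_back(read[i - 1]);
      ar.push_back(ref[j - 1]);
      const int s = subscore(read[i - 1], ref[j - 1]);
      const int target = M[AT(i, j)] - s;
      // preference: M > IY > IX
      if (M[AT(i - 1, j - 1)] == target) state = 0;
      else if (IY[AT(i - 1, j - 1)] == target) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) { // IY: '-' in read over ref base
      ap.push_back('-');
      ar.push_back(ref[j - 1]);
      const int cur = IY[AT(i, j)];
      if (M[AT(i, j - 1)] == cur + GAP_OPEN + GAP_EXT) state = 0;
      else if (IY[AT(i, j - 1)] == cur + GAP_EXT) state = 1;
      else state = 2;
      --j;
    } else { // IX: read base over '-'
      ap.push_back(read[i - 1]);
      ar.push_back('-');
      if (j == 0) { --i; continue; }
      const int cur = IX[AT(i, j)];
      if (M[AT(i - 1, j)] == cur + GAP_OPEN + GAP_EXT) state = 0;
      else if (IX[AT(i - 1, j)] == cur + GAP_EXT) state = 2;
      else state = 1;
      --i;
    }
  }
  const int ref_start = j + 1; // 1-based first reference column in the alignment
  std::reverse(ap.begin(), ap.end());
  std::reverse(ar.begin(), ar.end());

  int matches = 0, cols = (int) ap.size();
  for (int k = 0; k < cols; ++k) {
    if (ap[k] != '-' && ap[k] == ar[k] && ap[k] != 'N') ++matches;
  }

  return List::create(
    _["score"] = best,
    _["aligned_read"] = ap,
    _["aligned_ref"] = ar,
    _["ref_start"] = ref_start,
    _["ref_end"] = bj,
    _["identity"] = cols > 0 ? (double) matches / (double) cols : 0.0
  );
#undef AT
}

// [[Rcpp::export]]
IntegerVector cpp_align_scores(CharacterVector reads, std::string ref) {
  const int nr = reads.size();
  IntegerVector out(nr);
  for (int k = 0; k < nr; ++k) {
    List a = cpp_align_read(as<std::string>(reads[k]), ref);
    out[k] = as<int>(a["score"]);
  }
  return out;
}
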