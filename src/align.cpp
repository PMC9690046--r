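// Pairwise DP alignment kernels: banded global (complete mitogenomes vs the
// 16.5 kb reference) and semi-global (HVR fragments located within the
// reference, free reference end gaps). Affine gap penalties; the query may
// carry IUPAC ambiguity codes, which score as a match against any component
// base. The reference is plain A/C/G/T.
#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstring>
#include <climits>

using namespace Rcpp;

static const int NEG_INF = INT_MIN / 4;

// bitmask of component bases per ASCII char (A=1, C=2, G=4, T=8)
static int iupac_mask(char c) {
  switch (c) {
    case 'A': return 1;  case 'C': return 2;  case 'G': return 4;  case 'T': return 8;
    case 'R': return 1|4; case 'Y': return 2|8; case 'S': return 2|4; case 'W': return 1|8;
    case 'K': return 4|8; case 'M': return 1|2;
    case 'B': return 2|4|8; case 'D': return 1|4|8; case 'H': return 1|2|8; case 'V': return 1|2|4;
    case 'N': return 1|2|4|8;
    default:  return 0;
  }
}

// traceback codes
enum { FROM_M = 0, FROM_X = 1, FROM_Y = 2, FROM_NONE = 3 };

// Build aligned strings from pointer matrices. X consumes reference only
// (gap in query = deletion); Y consumes query only (insertion).
struct TBEntry { unsigned char m, x, y; };

// Banded global alignment.
// ref length n, qry length m; column offset d = j - i constrained to
// [dlo, dhi] with dlo = min(0, n-m) - band, dhi = max(0, n-m) + band.
// Returns ref_aln, qry_aln, score, band_edge (true if the optimal traceback
// touched the band boundary, meaning the band may have clipped the optimum).
// [[Rcpp::export]]
List cpp_align_banded(std::string ref, std::string qry,
                      int match, int mismatch, int gap_open, int gap_extend,
                      int band) {
  const int n = (int) ref.size(), m = (int) qry.size();
  const int dlo = std::min(0, n - m) - band;
  const int dhi = std::max(0, n - m) + band;
  const int W = dhi - dlo + 1;

  std::vector<int> rmask(n), qmask(m);
  for (int j = 0; j < n; ++j) rmask[j] = iupac_mask(ref[j]);
  for (int i = 0; i < m; ++i) qmask[i] = iupac_mask(qry[i]);

  // scores: two rolling rows; traceback: full (m+1) x W
  std::vector<int> Mprev(W, NEG_INF), Xprev(W, NEG_INF), Yprev(W, NEG_INF);
  std::vector<int> Mcur(W, NEG_INF),  Xcur(W, NEG_INF),  Ycur(W, NEG_INF);
  std::vector<TBEntry> tb((size_t)(m + 1) * W);

  // first gap base costs gap_open, each further base gap_extend
  // row i = 0: j = d - dlo index; only j >= 0 meaningful (d = j since i=0)
  for (int d = dlo; d <= dhi; ++d) {
    int k = d - dlo;
    TBEntry &t = tb[k];
    t.m = t.x = t.y = FROM_NONE;
    if (d == 0) { Mprev[k] = 0; }
    else if (d > 0 && d <= n) { // leading gap in query over ref 1..d
      Xprev[k] = gap_open + (d - 1) * gap_extend;
      t.x = (d == 1) ? FROM_M : FROM_X;
    }
  }

  for (int i = 1; i <= m; ++i) {
    std::fill(Mcur.begin(), Mcur.end(), NEG_INF);
    std::fill(Xcur.begin(), Xcur.end(), NEG_INF);
    std::fill(Ycur.begin(), Ycur.end(), NEG_INF);
    const int qm = qmask[i - 1];
    for (int k = 0; k < W; ++k) {
      const int j = i + dlo + k;
      if (j < 0 || j > n) continue;
      TBEntry &t = tb[(size_t) i * W + k];
      t.m = t.x = t.y = FROM_NONE;
      if (j >= 1) {
        // M: diagonal from (i-1, j-1) -> same k in previous row
        int best = NEG_INF; unsigned char from = FROM_NONE;
        if (Mprev[k] > best) { best = Mprev[k]; from = FROM_M; }
        if (Xprev[k] > best) { best = Xprev[k]; from = FROM_X; }
        if (Yprev[k] > best) { best = Yprev[k]; from = FROM_Y; }
        if (best > NEG_INF) {
          int s = (qm & rmask[j - 1]) ? match : mismatch;
          Mcur[k] = best + s; t.m = from;
        }
        // X: from (i, j-1) -> k-1 in current row
        if (k >= 1) {
          int fromM = (Mcur[k - 1] > NEG_INF) ? Mcur[k - 1] + gap_open : NEG_INF;
          int fromX = (Xcur[k - 1] > NEG_INF) ? Xcur[k - 1] + gap_extend : NEG_INF;
          if (fromM >= fromX) { if (fromM > NEG_INF) { Xcur[k] = fromM; t.x = FROM_M; } }
          else { Xcur[k] = fromX; t.x = FROM_X; }
        }
      }
      // Y: from (i-1, j) -> k+1 in previous row
      if (k + 1 < W) {
        int fromM = (Mprev[k + 1] > NEG_INF) ? Mprev[k + 1] + gap_open : NEG_INF;
        int fromY = (Yprev[k + 1] > NEG_INF) ? Yprev[k + 1] + gap_extend : NEG_INF;
        if (fromM >= fromY) { if (fromM > NEG_INF) { Ycur[k] = fromM; t.y = FROM_M; } }
        else { Ycur[k] = fromY; t.y = FROM_Y; }
      }
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }

  // end cell (i=m, j=n) -> k = n - m - dlo
  const int kend = n - m - dlo;
  if (kend < 0 || kend >= W) stop("band does not contain the global end cell");
  int score = Mprev[kend]; unsigned char state = FROM_M;
  if (Xprev[kend] > score) { score = Xprev[kend]; state = FROM_X; }
  if (Yprev[kend] > score) { score = Yprev[kend]; state = FROM_Y; }
  if (score <= NEG_INF) stop("no alignment within band");

  // traceback
  std::string ra, qa; ra.reserve(n + 16); qa.reserve(n + 16);
  bool band_edge = false;
  int i = m, j = n;
  while (i > 0 || j > 0) {
    int k = j - i - dlo;
    if (k == 0 || k == W - 1) band_edge = true;
    const TBEntry &t = tb[(size_t) i * W + k];
    if (state == FROM_M) {
      unsigned char from = t.m;
      ra.push_back(ref[j - 1]); qa.push_back(qry[i - 1]);
      --i; --j; state = from;
    } else if (state == FROM_X) {
      unsigned char from = t.x;
      ra.push_back(ref[j - 1]); qa.push_back('-');
      --j; state = from;
    } else if (state == FROM_Y) {
      unsigned char from = t.y;
      ra.push_back('-'); qa.push_back(qry[i - 1]);
      --i; state = from;
    } else {
      stop("traceback failure (internal)");
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(qa.begin(), qa.end());

  return List::create(_["ref_aln"] = ra, _["qry_aln"] = qa,
                      _["ref_start"] = 1, _["score"] = score,
                      _["band_edge"] = band_edge);
}

// Semi-global: the query aligns fully; leading/trailing reference is free.
// Full DP over (m+1) x (n+1); rolling score rows + full traceback pointers.
// [[Rcpp::export]]
List cpp_align_semiglobal(std::string ref, std::string qry,
                          int match, int mismatch, int gap_open, int gap_extend) {
  const int n = (int) ref.size(), m = (int) qry.size();
  std::vector<int> rmask(n), qmask(m);
  for (int j = 0; j < n; ++j) rmask[j] = iupac_mask(ref[j]);
  for (int i = 0; i < m; ++i) qmask[i] = iupac_mask(qry[i]);

  std::vector<int> Mprev(n + 1, 0), Xprev(n + 1, NEG_INF), Yprev(n + 1, NEG_INF);
  std::vector<int> Mcur(n + 1), Xcur(n + 1), Ycur(n + 1);
  std::vector<TBEntry> tb((size_t)(m + 1) * (n + 1));
  for (int j = 0; j <= n; ++j) { TBEntry &t = tb[j]; t.m = t.x = t.y = FROM_NONE; }

  for (int i = 1; i <= m; ++i) {
    const int qm = qmask[i - 1];
    Mcur[0] = NEG_INF; Xcur[0] = NEG_INF;
    {
      TBEntry &t0 = tb[(size_t) i * (n + 1)];
      t0.m = t0.x = t0.y = FROM_NONE;
      int fromM = (Mprev[0] > NEG_INF) ? Mprev[0] + gap_open : NEG_INF;
      int fromY = (Yprev[0] > NEG_INF) ? Yprev[0] + gap_extend : NEG_INF;
      if (fromM >= fromY) { Ycur[0] = fromM; t0.y = FROM_M; }
      else { Ycur[0] = fromY; t0.y = FROM_Y; }
    }
    for (int j = 1; j <= n; ++j) {
      TBEntry &t = tb[(size_t) i * (n + 1) + j];
      t.m = t.x = t.y = FROM_NONE;
      int best = NEG_INF; unsigned char from = FROM_NONE;
      if (Mprev[j - 1] > best) { best = Mprev[j - 1]; from = FROM_M; }
      if (Xprev[j - 1] > best) { best = Xprev[j - 1]; from = FROM_X; }
      if (Yprev[j - 1] > best) { best = Yprev[j - 1]; from = FROM_Y; }
      int s = (qm & rmask[j - 1]) ? match : mismatch;
      Mcur[j] = (best > NEG_INF) ? best + s : NEG_INF;
      t.m = from;
      int fromM = (Mcur[j - 1] > NEG_INF) ? Mcur[j - 1] + gap_open : NEG_INF;
      int fromX = (Xcur[j - 1] > NEG_INF) ? Xcur[j - 1] + gap_extend : NEG_INF;
      if (fromM >= fromX) { Xcur[j] = fromM; t.x = FROM_M; }
      else { Xcur[j] = fromX; t.x = FROM_X; }
      int fromM2 = (Mprev[j] > NEG_INF) ? Mprev[j] + gap_open : NEG_INF;
      int fromY2 = (Yprev[j] > NEG_INF) ? Yprev[j] + gap_extend : NEG_INF;
      if (fromM2 >= fromY2) { Ycur[j] = fromM2; t.y = FROM_M; }
      else { Ycur[j] = fromY2; t.y = FROM_Y; }
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }

  // best end: i = m, any j; query must be fully consumed (M or Y state)
  int score = NEG_INF, jend = 0; unsigned char state = FROM_M;
  for (int j = 0; j <= n; ++j) {
    if (Mprev[j] > score) { score = Mprev[j]; jend = j; state = FROM_M; }
    if (Yprev[j] > score) { score = Yprev[j]; jend = j; state = FROM_Y; }
  }
  if (score <= NEG_INF) stop("semi-global alignment failed");

  std::string ra, qa; ra.reserve(m + 16); qa.reserve(m + 16);
  int i = m, j = jend;
  while (i > 0) {
    const TBEntry &t = tb[(size_t) i * (n + 1) + j];
    if (state == FROM_M) {
      unsigned char from = t.m;
      ra.push_back(ref[j - 1]); qa.push_back(qry[i - 1]);
      --i; --j; state = from;
    } else if (state == FROM_X) {
      unsigned char from = t.x;
      ra.push_back(ref[j - 1]); qa.push_back('-');
      --j; state = from;
    } else if (state == FROM_Y) {
      unsigned char from = t.y;
      ra.push_back('-'); qa.push_back(qry[i - 1]);
      --i; state = from;
    } else {
      stop("traceback failure (internal)");
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(qa.begin(), qa.end());

  return List::create(_["ref_aln"] = ra, _["qry_aln"] = qa,
                      _["ref_start"] = j + 1, _["score"] = score,
                      _["band_edge"] = false);
}
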