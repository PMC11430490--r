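#include <Rcpp.h>
#include <cstring>
#include <vector>
using namespace Rcpp;

// Global affine-gap alignment (Gotoh three-state DP) with an optional band
// around the main diagonal. Gap cost convention: a run of k gap columns
// costs gap_open + k * gap_extend (the opening penalty is a surcharge on
// top of the per-base extension). Tie-breaking is deterministic: diagonal
// (match state M) is preferred over up (X: gap in the query), which is
// preferred over left (Y: gap in the reference), both for the final state
// and for every predecessor choice.

static const double NEG = -1e30;

// state codes: 0 = M, 1 = X (up), 2 = Y (left)
static inline int best3(double m, double x, double y, double *out) {
  int s = 0;
  double b = m;
  if (x > b) { b = x; s = 1; }
  if (y > b) { b = y; s = 2; }
  *out = b;
  return s;
}

// [[Rcpp::export(name = ".cpp_global_align")]]
List cpp_global_align(std::string a, std::string b, double match,
                      double mismatch, double gap_open, double gap_extend,
                      int band) {
  const int n = (int)a.size();
  const int m = (int)b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");
  if (band <= 0) band = std::max(n, m);
  int diff = std::abs(n - m);
  if (band < diff + 1) band = diff + 1;
  if (band > std::max(n, m)) band = std::max(n, m);
  const int w = 2 * band + 1;

  // rolling score rows; full traceback (packed 2 bits per state)
  std::vector<double> Mp(w, NEG), Xp(w, NEG), Yp(w, NEG);
  std::vector<double> Mc(w, NEG), Xc(w, NEG), Yc(w, NEG);
  std::vector<unsigned char> tb((size_t)(n + 1) * w, 0);

  // column index within band for row i: c = j - i + band
  // row 0: M[0][0] = 0; Y[0][j] = open + j*ext
  for (int j = 0; j <= std::min(m, band); ++j) {
    int c = j + band; // i = 0
    if (c >= w) break;
    if (j == 0) {
      Mp[c] = 0.0;
    } else {
      Yp[c] = gap_open + j * gap_extend;
      tb[(size_t)0 * w + c] |= (unsigned char)(2 << 4); // Y from Y
    }
  }

  for (int i = 1; i <= n; ++i) {
    std::fill(Mc.begin(), Mc.end(), NEG);
    std::fill(Xc.begin(), Xc.end(), NEG);
    std::fill(Yc.begin(), Yc.end(), NEG);
    int jlo = std::max(0, i - band);
    int jhi = std::min(m, i + band);
    for (int j = jlo; j <= jhi; ++j) {
      int c = j - i + band;
      unsigned char t = 0;
      if (j == 0) {
        Xc[c] = gap_open + i * gap_extend;
        t |= (unsigned char)(1 << 2); // X from X
      } else {
        // M: diagonal from (i-1, j-1) -> same c in previous row
        double diagM = Mp[c], diagX = Xp[c], diagY = Yp[c];
        double bestd;
        int sd = best3(diagM, diagX, diagY, &bestd);
        if (bestd > NEG / 2) {
          double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
          // N never matches anything, including another N
          if (a[i - 1] == 'N' || b[j - 1] == 'N') s = mismatch;
          Mc[c] = bestd + s;
          t |= (unsigned char)sd;
        }
        // X (up): from (i-1, j) -> c + 1 in previous row
        if (c + 1 < w) {
          double xm = Mp[c + 1] + gap_open + gap_extend;
          double xx = Xp[c + 1] + gap_extend;
          double xy = Yp[c + 1] + gap_open + gap_extend;
          double bx;
          int sx = best3(xm, xx, xy, &bx);
          if (bx > NEG / 2) {
            Xc[c] = bx;
            t |= (unsigned char)(sx << 2);
          }
        }
        // Y (left): from (i, j-1) -> c - 1 in current row
        if (c - 1 >= 0) {
          double ym = Mc[c - 1] + gap_open + gap_extend;
          double yx = Xc[c - 1] + gap_open + gap_extend;
          double yy = Yc[c - 1] + gap_extend;
          double by;
          int sy = best3(ym, yx, yy, &by);
          if (by > NEG / 2) {
            Yc[c] = by;
            t |= (unsigned char)(sy << 4);
          }
        }
      }
      tb[(size_t)i * w + c] = t;
    }
    std::swap(Mp, Mc);
    std::swap(Xp, Xc);
    std::swap(Yp, Yc);
  }

  int cend = m - n + band;
  double score;
  int state = best3(Mp[cend], Xp[cend], Yp[cend], &score);
  if (score < NEG / 2) stop("alignment infeasible within band %d", band);

  // traceback
  std::string ra, rb;
  ra.reserve(n + m);
  rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int c = j - i + band;
    unsigned char t = tb[(size_t)i * w + c];
    if (state == 0) {
      ra.push_back(a[i - 1]);
      rb.push_back(b[j - 1]);
      state = t & 3;
      --i;
      --j;
    } else if (state == 1) {
      ra.push_back(a[i - 1]);
      rb.push_back('-');
      state = (t >> 2) & 3;
      --i;
    } else {
      ra.push_back('-');
      rb.push_back(b[j - 1]);
      state = (t >> 4) & 3;
      --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["ref"] = ra, _["query"] = rb, _["score"] = score,
                      _["band"] = band);
}
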