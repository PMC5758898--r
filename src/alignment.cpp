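// Alignment primitives: BLOSUM62 local-alignment scoring (similarity graph),
// progressive profile alignment (internal MSA fallback), p-distances.
#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Residue order: A R N D C Q E G H I L K M F P S T W Y V B Z X *
static const int NAA = 24;
static const char AA_ORDER[NAA + 1] = "ARNDCQEGHILKMFPSTWYVBZX*";
static const int BLOSUM62[NAA][NAA] = {
  { 4,-1,-2,-2, 0,-1,-1, 0,-2,-1,-1,-1,-1,-2,-1, 1, 0,-3,-2, 0,-2,-1, 0,-4},
  {-1, 5, 0,-2,-3, 1, 0,-2, 0,-3,-2, 2,-1,-3,-2,-1,-1,-3,-2,-3,-1, 0,-1,-4},
  {-2, 0, 6, 1,-3, 0, 0, 0, 1,-3,-3, 0,-2,-3,-2, 1, 0,-4,-2,-3, 3, 0,-1,-4},
  {-2,-2, 1, 6,-3, 0, 2,-1,-1,-3,-4,-1,-3,-3,-1, 0,-1,-4,-3,-3, 4, 1,-1,-4},
  { 0,-3,-3,-3, 9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1,-3,-3,-2,-4},
  {-1, 1, 0, 0,-3, 5, 2,-2, 0,-3,-2, 1, 0,-3,-1, 0,-1,-2,-1,-2, 0, 3,-1,-4},
  {-1, 0, 0, 2,-4, 2, 5,-2, 0,-3,-3, 1,-2,-3,-1, 0,-1,-3,-2,-2, 1, 4,-1,-4},
  { 0,-2, 0,-1,-3,-2,-2, 6,-2,-4,-4,-2,-3,-3,-2, 0,-2,-2,-3,-3,-1,-2,-1,-4},
  {-2, 0, 1,-1,-3, 0, 0,-2, 8,-3,-3,-1,-2,-1,-2,-1,-2,-2, 2,-3, 0, 0,-1,-4},
  {-1,-3,-3,-3,-1,-3,-3,-4,-3, 4, 2,-3, 1, 0,-3,-2,-1,-3,-1, 3,-3,-3,-1,-4},
  {-1,-2,-3,-4,-1,-2,-3,-4,-3, 2, 4,-2, 2, 0,-3,-2,-1,-2,-1, 1,-4,-3,-1,-4},
  {-1, 2, 0,-1,-3, 1, 1,-2,-1,-3,-2, 5,-1,-3,-1, 0,-1,-3,-2,-2, 0, 1,-1,-4},
  {-1,-1,-2,-3,-1, 0,-2,-3,-2, 1, 2,-1, 5, 0,-2,-1,-1,-1,-1, 1,-3,-1,-1,-4},
  {-2,-3,-3,-3,-2,-3,-3,-3,-1, 0, 0,-3, 0, 6,-4,-2,-2, 1, 3,-1,-3,-3,-1,-4},
  {-1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4, 7,-1,-1,-4,-3,-2,-2,-1,-2,-4},
  { 1,-1, 1, 0,-1, 0, 0, 0,-1,-2,-2, 0,-1,-2,-1, 4, 1,-3,-2,-2, 0, 0, 0,-4},
  { 0,-1, 0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1, 1, 5,-2,-2, 0,-1,-1, 0,-4},
  {-3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1, 1,-4,-3,-2,11, 2,-3,-4,-3,-2,-4},
  {-2,-2,-2,-3,-2,-1,-2,-3, 2,-1,-1,-2,-1, 3,-3,-2,-2, 2, 7,-1,-3,-2,-1,-4},
  { 0,-3,-3,-3,-1,-2,-2,-3,-3, 3, 1,-2, 1,-1,-2,-2, 0,-3,-1, 4,-3,-2,-1,-4},
  {-2,-1, 3, 4,-3, 0, 1,-1, 0,-3,-4, 0,-3,-3,-2, 0,-1,-4,-3,-3, 4, 1,-1,-4},
  {-1, 0, 0, 1,-3, 3, 4,-2, 0,-3,-3, 1,-1,-3,-1, 0,-1,-3,-2,-2, 1, 4,-1,-4},
  { 0,-1,-1,-1,-2,-1,-1,-1,-1,-1,-1,-1,-1,-1,-2, 0, 0,-2,-1,-1,-1,-1,-1,-4},
  {-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4, 1}
};

static int aa_index_table[256];
static bool aa_table_ready = false;

static void init_aa_table() {
  if (aa_table_ready) return;
  for (int i = 0; i < 256; ++i) aa_index_table[i] = -1;
  for (int i = 0; i < NAA; ++i) {
    aa_index_table[(unsigned char)AA_ORDER[i]] = i;
    aa_index_table[(unsigned char)tolower(AA_ORDER[i])] = i;
  }
  // rare letters mapped to X
  const char *rare = "UOJuoj";
  for (const char *p = rare; *p; ++p) aa_index_table[(unsigned char)*p] = 22;
  aa_table_ready = true;
}

static std::vector<int> encode_aa(const std::string &s, bool strict) {
  init_aa_table();
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int idx = aa_index_table[(unsigned char)s[i]];
    if (idx < 0) {
      if (strict) stop("non-amino-acid character '%s' in sequence", std::string(1, s[i]).c_str());
      idx = 22;
    }
    v[i] = idx;
  }
  return v;
}

// Smith-Waterman local alignment score, affine gaps: a gap of length L costs
// gap_open + gap_extend * L (BLAST convention for open=11, extend=1).
// Banded variant indexed by diagonal offset d = j - i: only diagonals in
// [min(0, m-n) - band, max(0, m-n) + band] are explored (band < 0 = full).
// Out-of-band predecessors act like the SW "restart at 0" floor, so the
// banded score never exceeds the full score.
static int sw_raw(const std::vector<int> &a, const std::vector<int> &b,
                  int gap_open, int gap_extend, int band) {
  const int n = (int)a.size(), m = (int)b.size();
  if (band < 0) band = std::max(n, m);
  const int dmin = std::min(0, m - n) - band;
  const int dmax = std::max(0, m - n) + band;
  const int W = dmax - dmin + 1;
  const int NEG = -(1 << 28);
  std::vector<int> Mprev(W + 2, 0), Mcur(W + 2, 0);
  std::vector<int> Yprev(W + 2, NEG), Ycur(W + 2, NEG);
  // index shift: diagonal d stored at d - dmin + 1; sentinels at 0 and W+1
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    const int *arow = BLOSUM62[a[i - 1]];
    int lo = std::max(dmin, 1 - i), hi = std::min(dmax, m - i);
    int X = NEG;  // gap-in-b state, runs left-to-right within the row
    Mcur[lo - dmin] = 0;          // left sentinel for this row
    for (int d = lo; d <= hi; ++d) {
      const int k = d - dmin + 1;
      const int j = i + d;
      int y = std::max(Mprev[k + 1] - gap_open - gap_extend,
                       Yprev[k + 1] - gap_extend);
      X = std::max(Mcur[k - 1] - gap_open - gap_extend, X - gap_extend);
      int s = Mprev[k] + arow[b[j - 1]];
      int v = s > 0 ? s : 0;
      if (X > v) v = X;
      if (y > v) v = y;
      Mcur[k] = v;
      Ycur[k] = y;
      if (v > best) best = v;
    }
    // cells outside [lo, hi] must read as fresh starts next row
    if (lo - dmin >= 1) { Mcur[lo - dmin] = 0; Ycur[lo - dmin] = NEG; }
    if (hi + 1 - dmin + 1 <= W + 1) { Mcur[hi + 1 - dmin + 1] = 0; Ycur[hi + 1 - dmin + 1] = NEG; }
    std::swap(Mprev, Mcur);
    std::swap(Yprev, Ycur);
  }
  return best;
}

// [[Rcpp::export]]
double sw_raw_score_cpp(std::string a, std::string b,
                        double gap_open = 11.0, double gap_extend = 1.0,
                        int band = -1) {
  std::vector<int> ea = encode_aa(a, true), eb = encode_aa(b, true);
  if (ea.empty() || eb.empty()) stop("empty sequence");
  return (double)sw_raw(ea, eb, (int)gap_open, (int)gap_extend, band);
}

// Batch scoring of candidate pairs (1-based indices into seqs).
// [[Rcpp::export]]
NumericVector sw_raw_scores_pairs_cpp(std::vector<std::string> seqs,
                                      IntegerVector ia, IntegerVector ib,
                                      double gap_open = 11.0, double gap_extend = 1.0,
                                      int band = -1) {
  const int np = ia.size();
  std::vector<std::vector<int> > enc(seqs.size());
  for (size_t i = 0; i < seqs.size(); ++i) enc[i] = encode_aa(seqs[i], false);
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    out[p] = (double)sw_raw(enc[ia[p] - 1], enc[ib[p] - 1],
                            (int)gap_open, (int)gap_extend, band);
    if (p % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// ---- progressive profile alignment ------------------------------------------
// Profiles are residue-count matrices (NAA+1 rows; last row counts gaps).
// Column-column score: mean pairwise BLOSUM62 over residues, with residue/gap
// pairs scored at -gap_col and gap/gap pairs at 0.

struct Profile {
  std::vector<std::string> rows;   // aligned rows
  std::vector<int> ids;           // original sequence indices
  int len() const { return rows.empty() ? 0 : (int)rows[0].size(); }
};

static void profile_counts(const Profile &p, std::vector<std::vector<double> > &cnt) {
  init_aa_table();
  const int L = p.len();
  cnt.assign(L, std::vector<double>(NAA + 1, 0.0));
  for (size_t r = 0; r < p.rows.size(); ++r) {
    for (int j = 0; j < L; ++j) {
      char c = p.rows[r][j];
      if (c == '-') cnt[j][NAA] += 1.0;
      else {
        int idx = aa_index_table[(unsigned char)c];
        cnt[j][idx < 0 ? 22 : idx] += 1.0;
      }
    }
  }
}

static Profile merge_profiles(const Profile &A, const Profile &B, double gap_col) {
  const int n = A.len(), m = B.len();
  const double nA = (double)A.rows.size(), nB = (double)B.rows.size();
  std::vector<std::vector<double> > ca, cb;
  profile_counts(A, ca);
  profile_counts(B, cb);
  // Precompute per-column BLOSUM sums for A against each residue class.
  // sa[i][r] = sum over residues x in column i of count * B62[x][r]; gap part
  // handled apart.  B's columns are stored sparsely (few residues per column).
  std::vector<std::vector<double> > sa(n, std::vector<double>(NAA, 0.0));
  std::vector<double> gapA(n), gapB(m);
  for (int i = 0; i < n; ++i) {
    gapA[i] = ca[i][NAA];
    for (int x = 0; x < NAA; ++x) {
      double cx = ca[i][x];
      if (cx == 0.0) continue;
      for (int r = 0; r < NAA; ++r) sa[i][r] += cx * BLOSUM62[x][r];
    }
  }
  std::vector<std::vector<std::pair<int, double> > > sb(m);
  for (int j = 0; j < m; ++j) {
    gapB[j] = cb[j][NAA];
    for (int r = 0; r < NAA; ++r)
      if (cb[j][r] != 0.0) sb[j].push_back(std::make_pair(r, cb[j][r]));
  }
  const double inv_nAB = 1.0 / (nA * nB);

  auto col_score = [&](int i, int j) -> double {
    double s = 0.0;
    const std::vector<std::pair<int, double> > &cj = sb[j];
    const std::vector<double> &si = sa[i];
    for (size_t q = 0; q < cj.size(); ++q) s += cj[q].second * si[cj[q].first];
    double resA = nA - gapA[i], resB = nB - gapB[j];
    s += -gap_col * (gapA[i] * resB + gapB[j] * resA);
    return s * inv_nAB;
  };

  // Global NW with linear gap penalty on columns.
  std::vector<std::vector<double> > D(n + 1, std::vector<double>(m + 1, 0.0));
  std::vector<std::vector<char> > tb(n + 1, std::vector<char>(m + 1, 0));
  for (int i = 1; i <= n; ++i) { D[i][0] = D[i - 1][0] - gap_col; tb[i][0] = 1; }
  for (int j = 1; j <= m; ++j) { D[0][j] = D[0][j - 1] - gap_col; tb[0][j] = 2; }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double d = D[i - 1][j - 1] + col_score(i - 1, j - 1);
      double u = D[i - 1][j] - gap_col;
      double l = D[i][j - 1] - gap_col;
      if (d >= u && d >= l) { D[i][j] = d; tb[i][j] = 0; }
      else if (u >= l)      { D[i][j] = u; tb[i][j] = 1; }
      else                  { D[i][j] = l; tb[i][j] = 2; }
    }
  }
  // Trace back; build merged rows.
  std::vector<char> ops;  // 0 diag, 1 up (col from A only), 2 left (col from B only)
  int i = n, j = m;
  while (i > 0 || j > 0) {
    char t = tb[i][j];
    ops.push_back(t);
    if (t == 0) { --i; --j; }
    else if (t == 1) --i;
    else --j;
  }
  std::reverse(ops.begin(), ops.end());
  Profile out;
  out.ids = A.ids;
  out.ids.insert(out.ids.end(), B.ids.begin(), B.ids.end());
  const int L = (int)ops.size();
  out.rows.assign(A.rows.size() + B.rows.size(), std::string());
  for (auto &r : out.rows) r.reserve(L);
  int pi = 0, pj = 0;
  for (int t = 0; t < L; ++t) {
    bool useA = ops[t] != 2, useB = ops[t] != 1;
    for (size_t r = 0; r < A.rows.size(); ++r)
      out.rows[r].push_back(useA ? A.rows[r][pi] : '-');
    for (size_t r = 0; r < B.rows.size(); ++r)
      out.rows[A.rows.size() + r].push_back(useB ? B.rows[r][pj] : '-');
    if (useA) ++pi;
    if (useB) ++pj;
  }
  return out;
}

// merge: hclust-style merge matrix (negative = singleton index, positive =
// earlier merge result, both 1-based in R convention).
// [[Rcpp::export]]
CharacterVector progressive_align_cpp(std::vector<std::string> seqs,
                                      IntegerMatrix merge, double gap_col = 8.0) {
  const int n = (int)seqs.size();
  if (n == 1) return CharacterVector::create(seqs[0]);
  std::vector<Profile> merged(merge.nrow());
  auto fetch = [&](int code) -> Profile {
    if (code < 0) {
      Profile p;
      p.rows.push_back(seqs[-code - 1]);
      p.ids.push_back(-code - 1);
      return p;
    }
    return merged[code - 1];
  };
  for (int k = 0; k < merge.nrow(); ++k) {
    Profile A = fetch(merge(k, 0));
    Profile B = fetch(merge(k, 1));
    merged[k] = merge_profiles(A, B, gap_col);
    Rcpp::checkUserInterrupt();
  }
  const Profile &fin = merged[merge.nrow() - 1];
  CharacterVector out(n);
  for (size_t r = 0; r < fin.rows.size(); ++r) out[fin.ids[r]] = fin.rows[r];
  return out;
}

// ---- p-distance on an alignment ---------------------------------------------
// Pairwise-deletion proportion of differing sites; NA if no comparable sites.
// [[Rcpp::export]]
NumericMatrix pdist_cpp(std::vector<std::string> rows) {
  const int n = (int)rows.size();
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const std::string &a = rows[i], &b = rows[j];
      size_t L = std::min(a.size(), b.size());
      long ncomp = 0, ndiff = 0;
      for (size_t s = 0; s < L; ++s) {
        char x = a[s], y = b[s];
        if (x == '-' || y == '-' || x == 'N' || y == 'N' || x == 'n' || y == 'n') continue;
        ++ncomp;
        if (toupper(x) != toupper(y)) ++ndiff;
      }
      double d = ncomp > 0 ? (double)ndiff / (double)ncomp : NA_REAL;
      D(i, j) = d;
      D(j, i) = d;
    }
  }
  return D;
}
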