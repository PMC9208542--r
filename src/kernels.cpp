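#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double NEG_INF = -1e300;

static inline double lse2(double a, double b) {
  if (a < b) std::swap(a, b);
  if (a - b > 36.0) return a; // below double precision of log1p(exp(.))
  return a + std::log1p(std::exp(b - a));
}
static inline double lse3(double a, double b, double c) {
  return lse2(lse2(a, b), c);
}

// Global alignment with affine gaps (Gotoh) over a precomputed cell-score
// matrix S (n x m). A gap run of length k costs gap_open + k * gap_ext.
// Traceback tie-break: diagonal (M), then up (gap in b), then left (gap in a).
// Returns 1-based index vectors ai, bi per alignment column; 0 marks a gap.
// [[Rcpp::export]]
List affine_align_cpp(NumericMatrix S, double gap_open, double gap_ext) {
  int n = S.nrow(), m = S.ncol();
  double go = gap_open + gap_ext; // cost of the first residue of a gap run
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  // pointer codes: 1 = from M, 2 = from X (up), 3 = from Y (left), 0 = origin
  IntegerMatrix pM(n + 1, m + 1), pX(n + 1, m + 1), pY(n + 1, m + 1);

  M(0, 0) = 0.0; X(0, 0) = NEG_INF; Y(0, 0) = NEG_INF;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG_INF; Y(i, 0) = NEG_INF;
    X(i, 0) = -(gap_open + i * gap_ext);
    pX(i, 0) = (i == 1) ? 1 : 2;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG_INF; X(0, j) = NEG_INF;
    Y(0, j) = -(gap_open + j * gap_ext);
    pY(0, j) = (j == 1) ? 1 : 3;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: consume a_i and b_j
      double vm = M(i - 1, j - 1), vx = X(i - 1, j - 1), vy = Y(i - 1, j - 1);
      int arg = 1; double best = vm;
      if (vx > best) { best = vx; arg = 2; }
      if (vy > best) { best = vy; arg = 3; }
      M(i, j) = S(i - 1, j - 1) + best; pM(i, j) = arg;
      // X: consume a_i against a gap (vertical / "up")
      vm = M(i - 1, j) - go; vx = X(i - 1, j) - gap_ext; vy = Y(i - 1, j) - go;
      arg = 1; best = vm;
      if (vx > best) { best = vx; arg = 2; }
      if (vy > best) { best = vy; arg = 3; }
      X(i, j) = best; pX(i, j) = arg;
      // Y: consume b_j against a gap (horizontal / "left")
      vm = M(i, j - 1) - go; vx = X(i, j - 1) - go; vy = Y(i, j - 1) - gap_ext;
      arg = 1; best = vm;
      if (vx > best) { best = vx; arg = 2; }
      if (vy > best) { best = vy; arg = 3; }
      Y(i, j) = best; pY(i, j) = arg;
    }
  }

  int state = 1; double score = M(n, m);
  if (X(n, m) > score) { score = X(n, m); state = 2; }
  if (Y(n, m) > score) { score = Y(n, m); state = 3; }

  std::vector<int> ai, bi;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 1) {
      int p = pM(i, j);
      ai.push_back(i); bi.push_back(j);
      --i; --j; state = p;
    } else if (state == 2) {
      int p = pX(i, j);
      ai.push_back(i); bi.push_back(0);
      --i; state = p;
    } else {
      int p = pY(i, j);
      ai.push_back(0); bi.push_back(j);
      --j; state = p;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["score"] = score,
                      _["ai"] = wrap(ai), _["bi"] = wrap(bi));
}

// Profile HMM dynamic programming, glocal (Plan7-style) mode.
//
// ME: L x n matrix of log match-emission probabilities per (state, residue)
// IE: n vector of log insert-emission probabilities per residue
// NL: n vector of log null (background) emission per residue
// TR: L x 7 matrix of log transitions [MM, MI, MD, IM, II, DM, DD]; row k
//     holds transitions out of state k (M_k/I_k/D_k); disallowed = -inf.
// ln_loop / ln_exit: log self-loop and exit probabilities of the N and C
//     flanking insert states (flanks emit from the background).
// Returns log P(seq | model) in nats; the caller converts to bit odds.
// [[Rcpp::export]]
double hmm_forward_cpp(NumericMatrix ME, NumericVector IE, NumericVector NL,
                       NumericMatrix TR, double ln_loop, double ln_exit) {
  int L = ME.nrow(), n = ME.ncol();
  if (n < 1) return NEG_INF;
  std::vector<double> Ncur(n + 1, NEG_INF);
  Ncur[0] = 0.0;
  for (int i = 1; i <= n; ++i) Ncur[i] = Ncur[i - 1] + ln_loop + NL[i - 1];

  // row-wise over residues; Mrow/Irow/Drow indexed 1..L
  std::vector<double> Mprev(L + 1, NEG_INF), Iprev(L + 1, NEG_INF),
      Dprev(L + 1, NEG_INF), Mcur(L + 1), Icur(L + 1), Dcur(L + 1);
  std::vector<double> Cv(n + 1, NEG_INF);

  for (int i = 1; i <= n; ++i) {
    std::fill(Mcur.begin(), Mcur.end(), NEG_INF);
    std::fill(Icur.begin(), Icur.end(), NEG_INF);
    std::fill(Dcur.begin(), Dcur.end(), NEG_INF);
    // match states
    Mcur[1] = ME(0, i - 1) + Ncur[i - 1] + ln_exit;
    for (int k = 2; k <= L; ++k) {
      double v = lse3(Mprev[k - 1] + TR(k - 2, 0),
                      Iprev[k - 1] + TR(k - 2, 3),
                      Dprev[k - 1] + TR(k - 2, 5));
      Mcur[k] = ME(k - 1, i - 1) + v;
    }
    // insert states (I_k exists for k = 1..L-1)
    for (int k = 1; k <= L - 1; ++k) {
      Icur[k] = IE[i - 1] + lse2(Mprev[k] + TR(k - 1, 1),
                                 Iprev[k] + TR(k - 1, 4));
    }
    // delete states (D_k exists for k = 2..L-1), same-row sweep
    for (int k = 2; k <= L - 1; ++k) {
      Dcur[k] = lse2(Mcur[k - 1] + TR(k - 2, 2),
                     Dcur[k - 1] + TR(k - 2, 6));
    }
    Cv[i] = lse2(Mcur[L], Cv[i - 1] + ln_loop + NL[i - 1]);
    std::swap(Mprev, Mcur); std::swap(Iprev, Icur); std::swap(Dprev, Dcur);
  }
  return Cv[n] + ln_exit;
}

// Viterbi counterpart; returns the score and, per residue, the emitting state
// type (0 = N flank, 1 = match, 2 = insert, 3 = C flank) and match index.
// [[Rcpp::export]]
List hmm_viterbi_cpp(NumericMatrix ME, NumericVector IE, NumericVector NL,
                     NumericMatrix TR, double ln_loop, double ln_exit) {
  int L = ME.nrow(), n = ME.ncol();
  std::vector<double> Nv(n + 1, NEG_INF);
  Nv[0] = 0.0;
  for (int i = 1; i <= n; ++i) Nv[i] = Nv[i - 1] + ln_loop + NL[i - 1];

  NumericMatrix M(n + 1, L + 1), I(n + 1, L + 1), D(n + 1, L + 1);
  IntegerMatrix pM(n + 1, L + 1), pI(n + 1, L + 1), pD(n + 1, L + 1);
  std::fill(M.begin(), M.end(), NEG_INF);
  std::fill(I.begin(), I.end(), NEG_INF);
  std::fill(D.begin(), D.end(), NEG_INF);
  // pointer codes: 0 = entry from N flank, 1 = M, 2 = I, 3 = D
  std::vector<double> Cv(n + 1, NEG_INF);
  std::vector<int> pC(n + 1, -1); // 1 = entry from M_L at i, 3 = C loop

  for (int i = 1; i <= n; ++i) {
    M(i, 1) = ME(0, i - 1) + Nv[i - 1] + ln_exit;
    pM(i, 1) = 0;
    for (int k = 2; k <= L; ++k) {
      double vm = M(i - 1, k - 1) + TR(k - 2, 0);
      double vi = I(i - 1, k - 1) + TR(k - 2, 3);
      double vd = D(i - 1, k - 1) + TR(k - 2, 5);
      int arg = 1; double best = vm;
      if (vi > best) { best = vi; arg = 2; }
      if (vd > best) { best = vd; arg = 3; }
      M(i, k) = ME(k - 1, i - 1) + best; pM(i, k) = arg;
    }
    for (int k = 1; k <= L - 1; ++k) {
      double vm = M(i - 1, k) + TR(k - 1, 1);
      double vi = I(i - 1, k) + TR(k - 1, 4);
      if (vm >= vi) { I(i, k) = IE[i - 1] + vm; pI(i, k) = 1; }
      else          { I(i, k) = IE[i - 1] + vi; pI(i, k) = 2; }
    }
    for (int k = 2; k <= L - 1; ++k) {
      double vm = M(i, k - 1) + TR(k - 2, 2);
      double vd = D(i, k - 1) + TR(k - 2, 6);
      if (vm >= vd) { D(i, k) = vm; pD(i, k) = 1; }
      else          { D(i, k) = vd; pD(i, k) = 3; }
    }
    double enter = M(i, L);
    double loop = Cv[i - 1] + ln_loop + NL[i - 1];
    if (enter >= loop) { Cv[i] = enter; pC[i] = 1; }
    else               { Cv[i] = loop;  pC[i] = 3; }
  }

  double score = Cv[n] + ln_exit;
  IntegerVector type(n, 0), kidx(n, 0);
  if (score <= NEG_INF / 2 || n == 0) {
    return List::create(_["score"] = score, _["type"] = type, _["k"] = kidx);
  }
  int i = n;
  // C flank
  while (i > 0 && pC[i] == 3) { type[i - 1] = 3; kidx[i - 1] = 0; --i; }
  // i now at last residue emitted by M_L
  int state = 1, k = L;
  while (i > 0) {
    if (state == 1) {
      type[i - 1] = 1; kidx[i - 1] = k;
      int p = pM(i, k);
      if (p == 0) { // entry from N flank; residues 1..i-1 are N
        --i;
        while (i > 0) { type[i - 1] = 0; kidx[i - 1] = 0; --i; }
        break;
      } else if (p == 3) { // delete chain ending at D_{k-1} on row i-1
        --i; --k;
        while (pD(i, k) == 3) { --k; }
        // pD == 1: predecessor is M_{k-1} on same row
        --k; state = 1;
      } else {
        state = p; --i; --k;
      }
    } else { // state == 2, insert I_k
      type[i - 1] = 2; kidx[i - 1] = k;
      int p = pI(i, k);
      state = p; --i;
    }
  }
  return List::create(_["score"] = score, _["type"] = type, _["k"] = kidx);
}
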