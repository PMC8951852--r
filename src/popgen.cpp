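#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Coalescent null engine for the neutrality statistics.
//
// Simulates standard constant-size coalescent genealogies and places
// mutations either uniformly on the total branch length conditioned on a
// fixed segregating-site count S (the Arlequin/DnaSP-style null) or as a
// Poisson process with rate theta/2 per lineage per unit of scaled time.
// Sites are infinite-sites: every mutation is its own column.  Uses R's RNG
// so set.seed() in R makes runs reproducible.
// ---------------------------------------------------------------------------

static double logaddexp(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = std::max(a, b);
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// log unsigned Stirling numbers of the first kind |S_n^k|, k = 1..n
static std::vector<double> logStirlingRow(int n) {
  std::vector<double> row(2, R_NegInf);
  row[1] = 0.0;  // |S_1^1| = 1
  for (int m = 1; m < n; ++m) {
    std::vector<double> nxt(m + 2, R_NegInf);
    for (int k = 1; k <= m + 1; ++k) {
      double a = (k <= m) ? std::log((double)m) + row[k] : R_NegInf;
      double b = (k >= 2) ? row[k - 1] : R_NegInf;
      nxt[k] = logaddexp(a, b);
    }
    row.swap(nxt);
  }
  return row;  // row[k] = log|S_n^k|
}

struct TajimaConst {
  double a1, a2, b1, b2, c1, c2, e1, e2;
};

static TajimaConst tajimaConstants(int n) {
  TajimaConst tc;
  tc.a1 = 0.0; tc.a2 = 0.0;
  for (int i = 1; i <= n - 1; ++i) {
    tc.a1 += 1.0 / i;
    tc.a2 += 1.0 / ((double)i * i);
  }
  tc.b1 = (n + 1.0) / (3.0 * (n - 1.0));
  tc.b2 = 2.0 * (n * n + n + 3.0) / (9.0 * n * (n - 1.0));
  tc.c1 = tc.b1 - 1.0 / tc.a1;
  tc.c2 = tc.b2 - (n + 2.0) / (tc.a1 * n) + tc.a2 / (tc.a1 * tc.a1);
  tc.e1 = tc.c1 / tc.a1;
  tc.e2 = tc.c2 / (tc.a1 * tc.a1 + tc.a2);
  return tc;
}

static double tajimaDfromkS(double k, int S, const TajimaConst& tc) {
  if (S < 1) return NA_REAL;
  double denom = std::sqrt(tc.e1 * S + tc.e2 * (double)S * (S - 1));
  if (denom <= 0) return NA_REAL;
  return (k - S / tc.a1) / denom;
}

// Fu's Fs from mean pairwise differences k (theta-hat), haplotype count K
static double fuFs(double k, int K, int n, const std::vector<double>& lgS) {
  if (k <= 0) return NA_REAL;
  double lth = std::log(k);
  double lrf = 0.0;  // log rising factorial theta*(theta+1)*...*(theta+n-1)
  for (int i = 0; i < n; ++i) lrf += std::log(k + i);
  double lSp = R_NegInf;
  for (int j = K; j <= n; ++j)
    lSp = logaddexp(lSp, lgS[j] + j * lth - lrf);
  double Sp = std::exp(lSp);
  if (Sp >= 1.0 - 1e-15) Sp = 1.0 - 1e-15;
  if (Sp <= 1e-300) Sp = 1e-300;
  return std::log(Sp / (1.0 - Sp));
}

// one coalescent genealogy: returns per-mutation derived-tip index lists
// via flat storage, plus computes the three statistics directly
struct SimStats { int S; double D, Fs, R2; };

static SimStats simOne(int n, int fixedS, double theta,
                       const TajimaConst& tc,
                       const std::vector<double>& lgS,
                       std::vector<int>& scratch_active,
                       std::vector<double>& times,
                       std::vector<int>& left, std::vector<int>& right) {
  int m = 2 * n - 1;
  times.assign(m, 0.0);
  left.assign(m, -1);
  right.assign(m, -1);
  std::vector<int>& active = scratch_active;
  active.clear();
  for (int i = 0; i < n; ++i) active.push_back(i);
  double t = 0.0;
  int nxt = n;
  while ((int)active.size() > 1) {
    int k = active.size();
    double rate = k * (k - 1) / 2.0;
    t += exp_rand() / rate;
    int i = (int)(unif_rand() * k); if (i == k) i = k - 1;
    int j = (int)(unif_rand() * (k - 1)); if (j == k - 1) j = k - 2;
    if (j >= i) ++j;
    int a = active[i], b = active[j];
    times[nxt] = t;
    left[nxt] = a; right[nxt] = b;
    if (i > j) std::swap(i, j);
    active[i] = nxt;
    active.erase(active.begin() + j);
    ++nxt;
  }
  int root = m - 1;
  // branch lengths (node -> parent); root has none
  std::vector<double> blen(m, 0.0);
  for (int v = n; v < m; ++v) {
    blen[left[v]] = times[v] - times[left[v]];
    blen[right[v]] = times[v] - times[right[v]];
  }
  double Ltot = 0.0;
  for (int v = 0; v < root; ++v) Ltot += blen[v];
  // mutations per branch
  std::vector<int> mut(m, 0);
  int M = 0;
  if (fixedS >= 0) {
    M = fixedS;
    for (int s = 0; s < M; ++s) {
      double u = unif_rand() * Ltot, acc = 0.0;
      int v = 0;
      for (; v < root; ++v) { acc += blen[v]; if (u <= acc) break; }
      if (v == root) v = root - 1;
      mut[v]++;
    }
  } else {
    for (int v = 0; v < root; ++v) {
      int x = (int)R::rpois(0.5 * theta * blen[v]);
      mut[v] += x; M += x;
    }
  }
  SimStats st; st.S = M;
  if (M == 0) { st.D = NA_REAL; st.Fs = NA_REAL; st.R2 = NA_REAL; return st; }
  // tips under each node (post-order by construction: children < parent id
  // is NOT guaranteed for tips vs internals, but left/right < v holds)
  std::vector<std::vector<int> > tips(m);
  for (int v = 0; v < n; ++v) tips[v].push_back(v);
  for (int v = n; v < m; ++v) {
    tips[v] = tips[left[v]];
    tips[v].insert(tips[v].end(), tips[right[v]].begin(), tips[right[v]].end());
  }
  // incidence matrix n x M
  std::vector<std::vector<char> > inc(n, std::vector<char>(M, 0));
  std::vector<int> csize; csize.reserve(M);
  int col = 0;
  for (int v = 0; v < root; ++v) {
    for (int r = 0; r < mut[v]; ++r) {
      for (size_t q = 0; q < tips[v].size(); ++q) inc[tips[v][q]][col] = 1;
      csize.push_back((int)tips[v].size());
      ++col;
    }
  }
  double k = 0.0;
  double npairs = n * (n - 1) / 2.0;
  for (int c = 0; c < M; ++c)
    k += csize[c] * (double)(n - csize[c]) / npairs;
  // singleton counts per sequence (folded: derived count 1 or n-1)
  std::vector<int> U(n, 0);
  for (int c = 0; c < M; ++c) {
    if (csize[c] == 1) {
      for (int i = 0; i < n; ++i) if (inc[i][c]) { U[i]++; break; }
    } else if (csize[c] == n - 1) {
      for (int i = 0; i < n; ++i) if (!inc[i][c]) { U[i]++; break; }
    }
  }
  // distinct haplotypes
  std::vector<std::vector<char> > rows = inc;
  std::sort(rows.begin(), rows.end());
  int K = (int)(std::unique(rows.begin(), rows.end()) - rows.begin());
  st.D = tajimaDfromkS(k, M, tc);
  st.Fs = fuFs(k, K, n, lgS);
  double ss = 0.0;
  for (int i = 0; i < n; ++i) ss += (U[i] - k / 2.0) * (U[i] - k / 2.0);
  st.R2 = std::sqrt(ss / n) / M;
  return st;
}

// [[Rcpp::export(name = ".cpp_null_neutrality")]]
NumericMatrix cpp_null_neutrality(int n, int S, double theta, int reps,
                                  bool fixedS) {
  if (n < 2) stop("n must be >= 2");
  TajimaConst tc = tajimaConstants(n);
  std::vector<double> lgS = logStirlingRow(n);
  NumericMatrix out(reps, 4);
  colnames(out) = CharacterVector::create("S", "D", "Fs", "R2");
  std::vector<int> act; std::vector<double> tm; std::vector<int> lf, rg;
  for (int r = 0; r < reps; ++r) {
    SimStats st = simOne(n, fixedS ? S : -1, theta, tc, lgS, act, tm, lf, rg);
    out(r, 0) = st.S; out(r, 1) = st.D; out(r, 2) = st.Fs; out(r, 3) = st.R2;
  }
  return out;
}

// ---------------------------------------------------------------------------
// AMOVA on squared inter-haplotype distances.
// ---------------------------------------------------------------------------

// sum over unordered pairs within each population / group of d2, weighted
struct AmovaSS { double total, wp, wg; };

static AmovaSS amovaSS(const NumericMatrix& d2, const std::vector<int>& popOf,
                       const std::vector<int>& grpOfPop, int P, int G) {
  int N = popOf.size();
  std::vector<double> sswp(P, 0.0), sswg(G, 0.0);
  std::vector<int> np(P, 0);
  std::vector<double> ng(G, 0.0);
  double sst = 0.0;
  for (int i = 0; i < N; ++i) np[popOf[i]]++;
  for (int p = 0; p < P; ++p) ng[grpOfPop[p]] += np[p];
  for (int i = 0; i < N; ++i) {
    int pi = popOf[i], gi = grpOfPop[pi];
    for (int j = i + 1; j < N; ++j) {
      double v = d2(i, j);
      sst += v;
      int pj = popOf[j];
      if (pi == pj) sswp[pi] += v;
      if (gi == grpOfPop[pj]) sswg[gi] += v;
    }
  }
  AmovaSS out;
  out.total = sst / N;
  out.wp = 0.0;
  for (int p = 0; p < P; ++p) if (np[p] > 0) out.wp += sswp[p] / np[p];
  out.wg = 0.0;
  for (int g = 0; g < G; ++g) if (ng[g] > 0) out.wg += sswg[g] / ng[g];
  return out;
}

struct AmovaFit {
  double ssA, ssB, ssW, s2a, s2b, s2c, phiCT, phiSC, phiST;
  double dfA, dfB, dfW;
};

static AmovaFit amovaDecompose(const NumericMatrix& d2,
                               const std::vector<int>& popOf,
                               const std::vector<int>& grpOfPop,
                               int P, int G) {
  int N = popOf.size();
  std::vector<int> np(P, 0);
  for (int i = 0; i < N; ++i) np[popOf[i]]++;
  std::vector<double> Ng(G, 0.0), sum2g(G, 0.0);
  double sum2 = 0.0;
  for (int p = 0; p < P; ++p) {
    Ng[grpOfPop[p]] += np[p];
    sum2g[grpOfPop[p]] += (double)np[p] * np[p];
    sum2 += (double)np[p] * np[p];
  }
  AmovaSS ss = amovaSS(d2, popOf, grpOfPop, P, G);
  AmovaFit f;
  f.ssA = ss.total - ss.wg;
  f.ssB = ss.wg - ss.wp;
  f.ssW = ss.wp;
  f.dfA = G - 1;
  f.dfB = P - G;
  f.dfW = N - P;
  f.s2c = f.ssW / f.dfW;
  double sA = 0.0;  // sum over groups of (sum n_p^2)/N_g
  for (int g = 0; g < G; ++g) if (Ng[g] > 0) sA += sum2g[g] / Ng[g];
  double nb = (N - sA) / f.dfB;
  f.s2b = (f.ssB / f.dfB - f.s2c) / nb;
  if (G > 1) {
    double nprime = (sA - sum2 / N) / f.dfA;
    double sumNg2 = 0.0;
    for (int g = 0; g < G; ++g) sumNg2 += Ng[g] * Ng[g];
    double ndprime = (N - sumNg2 / N) / f.dfA;
    f.s2a = (f.ssA / f.dfA - f.s2c - nprime * f.s2b) / ndprime;
  } else {
    f.s2a = 0.0;
  }
  double tot = f.s2a + f.s2b + f.s2c;
  f.phiCT = (G > 1) ? f.s2a / tot : NA_REAL;
  double bc = f.s2b + f.s2c;
  // fully differentiated groups leave no within-group variance: Phi_SC -> 0
  f.phiSC = (bc != 0.0) ? f.s2b / bc : 0.0;
  f.phiST = (G > 1) ? (f.s2a + f.s2b) / tot : f.s2b / tot;
  return f;
}

static void shuffle(std::vector<int>& v) {
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1)); if (j > i) j = i;
    std::swap(v[i], v[j]);
  }
}

// [[Rcpp::export(name = ".cpp_amova2")]]
List cpp_amova2(NumericMatrix d2, IntegerVector popOfInd,
                IntegerVector grpOfPop, int perms) {
  int N = popOfInd.size();
  int P = grpOfPop.size();
  int G = 0;
  for (int p = 0; p < P; ++p) G = std::max(G, grpOfPop[p] + 1);
  std::vector<int> popOf(popOfInd.begin(), popOfInd.end());
  std::vector<int> grp(grpOfPop.begin(), grpOfPop.end());
  AmovaFit obs = amovaDecompose(d2, popOf, grp, P, G);
  int cCT = 0, cSC = 0, cST = 0;
  if (perms > 0) {
    // Phi_ST: permute individuals among all populations
    std::vector<int> lab = popOf;
    for (int r = 0; r < perms; ++r) {
      shuffle(lab);
      AmovaFit f = amovaDecompose(d2, lab, grp, P, G);
      if (f.phiST >= obs.phiST - 1e-12) ++cST;
    }
    // Phi_CT: permute whole populations among groups
    if (G > 1) {
      std::vector<int> glab = grp;
      for (int r = 0; r < perms; ++r) {
        shuffle(glab);
        AmovaFit f = amovaDecompose(d2, popOf, glab, P, G);
        if (f.phiCT >= obs.phiCT - 1e-12) ++cCT;
      }
    }
    // Phi_SC: permute individuals among populations within their group
    std::vector<std::vector<int> > idxByGroup(G);
    for (int i = 0; i < N; ++i) idxByGroup[grp[popOf[i]]].push_back(i);
    std::vector<int> lab2 = popOf;
    for (int r = 0; r < perms; ++r) {
      for (int g = 0; g < G; ++g) {
        std::vector<int>& idx = idxByGroup[g];
        std::vector<int> vals(idx.size());
        for (size_t q = 0; q < idx.size(); ++q) vals[q] = popOf[idx[q]];
        shuffle(vals);
        for (size_t q = 0; q < idx.size(); ++q) lab2[idx[q]] = vals[q];
      }
      AmovaFit f = amovaDecompose(d2, lab2, grp, P, G);
      if (f.phiSC >= obs.phiSC - 1e-12) ++cSC;
    }
  }
  double pCT = (G > 1 && perms > 0) ? (cCT + 1.0) / (perms + 1.0) : NA_REAL;
  double pSC = perms > 0 ? (cSC + 1.0) / (perms + 1.0) : NA_REAL;
  double pST = perms > 0 ? (cST + 1.0) / (perms + 1.0) : NA_REAL;
  return List::create(
    _["ss"] = NumericVector::create(obs.ssA, obs.ssB, obs.ssW),
    _["df"] = NumericVector::create(obs.dfA, obs.dfB, obs.dfW),
    _["sigma2"] = NumericVector::create(obs.s2a, obs.s2b, obs.s2c),
    _["phi"] = NumericVector::create(obs.phiCT, obs.phiSC, obs.phiST),
    _["pvals"] = NumericVector::create(pCT, pSC, pST));
}

// one-level decomposition for pairwise Phi_ST between two populations
// [[Rcpp::export(name = ".cpp_phist_pair")]]
List cpp_phist_pair(NumericMatrix d2, IntegerVector popOfInd, int perms) {
  int N = popOfInd.size();
  int P = 0;
  for (int i = 0; i < N; ++i) P = std::max(P, popOfInd[i] + 1);
  std::vector<int> popOf(popOfInd.begin(), popOfInd.end());
  std::vector<int> onegrp(P, 0);
  AmovaFit obs = amovaDecompose(d2, popOf, onegrp, P, 1);
  int cnt = 0;
  if (perms > 0) {
    std::vector<int> lab = popOf;
    for (int r = 0; r < perms; ++r) {
      shuffle(lab);
      AmovaFit f = amovaDecompose(d2, lab, onegrp, P, 1);
      if (f.phiST >= obs.phiST - 1e-12) ++cnt;
    }
  }
  double p = perms > 0 ? (cnt + 1.0) / (perms + 1.0) : NA_REAL;
  return List::create(_["phist"] = obs.phiST,
                      _["sigma2"] = NumericVector::create(obs.s2b, obs.s2c),
                      _["p"] = p);
}
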