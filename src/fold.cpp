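#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>
using namespace Rcpp;

// Bases are encoded 0=A, 1=C, 2=G, 3=U. Pair indices into the stack table:
// 0=AU, 1=UA, 2=CG, 3=GC, 4=GU, 5=UG; -1 = not an admissible pair.
static inline int pair_index(int x, int y) {
  if (x == 0 && y == 3) return 0;
  if (x == 3 && y == 0) return 1;
  if (x == 1 && y == 2) return 2;
  if (x == 2 && y == 1) return 3;
  if (x == 2 && y == 3) return 4;
  if (x == 3 && y == 2) return 5;
  return -1;
}

struct LoopModel {
  double hairpin_base, bulge_base, internal_base, loop_log_coef;
  double asym_coef, asym_max, ml_a, ml_b, ml_c;
  int max_loop, min_hairpin;

  double hairpin(int n) const {
    if (n < min_hairpin) return 1e9;
    return hairpin_base + loop_log_coef * std::log((double)n / min_hairpin);
  }
  double bulge(int n) const {
    return bulge_base + loop_log_coef * std::log((double)n);
  }
  double internal(int n1, int n2) const {
    int n = n1 + n2;
    double asym = asym_coef * std::abs(n1 - n2);
    if (asym > asym_max) asym = asym_max;
    return internal_base + loop_log_coef * std::log(n / 2.0) + asym;
  }
  // energy of the loop between closing pair (i,j) and inner pair: g1/g2
  // unpaired nucleotides on each side; g1 == g2 == 0 is a stack (not here)
  double interior(int g1, int g2) const {
    if (g1 + g2 > max_loop) return 1e9;
    if (g1 == 0 || g2 == 0) return bulge(g1 + g2);
    return internal(g1, g2);
  }
};

static LoopModel make_model(NumericVector p) {
  LoopModel m;
  m.hairpin_base  = p["hairpin_base"];
  m.bulge_base    = p["bulge_base"];
  m.internal_base = p["internal_base"];
  m.loop_log_coef = p["loop_log_coef"];
  m.asym_coef     = p["asym_coef"];
  m.asym_max      = p["asym_max"];
  m.ml_a          = p["ml_a"];
  m.ml_b          = p["ml_b"];
  m.ml_c          = p["ml_c"];
  m.max_loop      = (int)p["max_loop"];
  m.min_hairpin   = (int)p["min_hairpin"];
  return m;
}

static const double INF = 1e9;

// Zuker-style minimum free energy folding over the nearest-neighbour model:
// V(i,j) best energy with (i,j) paired; WM for multiloop components; W external.
// [[Rcpp::export]]
List fold_cpp(IntegerVector seq, NumericMatrix stack, NumericVector params) {
  const int n = seq.size();
  LoopModel mod = make_model(params);
  std::vector<std::vector<double>> V(n, std::vector<double>(n, INF));
  std::vector<std::vector<double>> WM(n, std::vector<double>(n, INF));

  for (int span = mod.min_hairpin + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int pij = pair_index(seq[i], seq[j]);
      if (pij >= 0) {
        double best = mod.hairpin(j - i - 1);
        // stack + interior loops: inner pair (k,l)
        int kmax = std::min(j - 1, i + mod.max_loop + 1);
        for (int k = i + 1; k <= kmax; ++k) {
          int g1 = k - i - 1;
          int lmin = std::max(k + mod.min_hairpin + 1, j - 1 - (mod.max_loop - g1));
          for (int l = j - 1; l >= lmin; --l) {
            if (V[k][l] >= INF) continue;
            int pkl = pair_index(seq[k], seq[l]);
            if (pkl < 0) continue;
            int g2 = j - l - 1;
            double e;
            if (g1 == 0 && g2 == 0) e = stack(pij, pkl);
            else e = mod.interior(g1, g2);
            if (e + V[k][l] < best) best = e + V[k][l];
          }
        }
        // multiloop: closing pair + >= 2 branches inside
        for (int k = i + 1; k < j - 1; ++k) {
          if (WM[i + 1][k] < INF && WM[k + 1][j - 1] < INF) {
            double e = mod.ml_a + mod.ml_b + WM[i + 1][k] + WM[k + 1][j - 1];
            if (e < best) best = e;
          }
        }
        V[i][j] = best;
      }
      // WM: >= 1 multiloop branch within [i, j]
      double w = INF;
      if (WM[i + 1][j] < INF) w = std::min(w, WM[i + 1][j] + mod.ml_c);
      if (WM[i][j - 1] < INF) w = std::min(w, WM[i][j - 1] + mod.ml_c);
      if (V[i][j] < INF) w = std::min(w, V[i][j] + mod.ml_b);
      for (int k = i; k < j; ++k)
        if (WM[i][k] < INF && WM[k + 1][j] < INF)
          w = std::min(w, WM[i][k] + WM[k + 1][j]);
      WM[i][j] = w;
    }
    // spans shorter than a hairpin: WM from single unpaired positions stays INF
  }
  // short spans WM base cases handled implicitly (INF: no branch fits)

  std::vector<double> W(n + 1, 0.0);
  for (int j = 0; j < n; ++j) {
    W[j + 1] = W[j];
    for (int i = 0; i <= j; ++i)
      if (V[i][j] < INF && W[i] + V[i][j] < W[j + 1])
        W[j + 1] = W[i] + V[i][j];
  }

  // traceback (deterministic, case order fixed; 5'-most pairing preferred)
  std::vector<int> pt(n, 0);
  std::vector<std::pair<std::pair<int,int>, int>> stk; // ((i,j), state) 0=V,1=WM
  const double EPS = 1e-7;
  {
    int j = n - 1;
    while (j >= 0) {
      if (std::fabs(W[j + 1] - W[j]) < EPS) { --j; continue; }
      bool found = false;
      for (int i = 0; i <= j && !found; ++i) {
        if (V[i][j] < INF && std::fabs(W[i] + V[i][j] - W[j + 1]) < EPS) {
          stk.push_back({{i, j}, 0});
          j = i - 1;
          found = true;
        }
      }
      if (!found) --j; // numerical safety
    }
  }
  while (!stk.empty()) {
    auto fr = stk.back(); stk.pop_back();
    int i = fr.first.first, j = fr.first.second, st = fr.second;
    if (st == 0) {
      pt[i] = j + 1; pt[j] = i + 1;
      int pij = pair_index(seq[i], seq[j]);
      if (std::fabs(V[i][j] - mod.hairpin(j - i - 1)) < EPS) continue;
      bool done = false;
      int kmax = std::min(j - 1, i + mod.max_loop + 1);
      for (int k = i + 1; k <= kmax && !done; ++k) {
        int g1 = k - i - 1;
        int lmin = std::max(k + mod.min_hairpin + 1, j - 1 - (mod.max_loop - g1));
        for (int l = j - 1; l >= lmin && !done; --l) {
          if (V[k][l] >= INF) continue;
          int pkl = pair_index(seq[k], seq[l]);
          if (pkl < 0) continue;
          int g2 = j - l - 1;
          double e = (g1 == 0 && g2 == 0) ? stack(pij, pkl) : mod.interior(g1, g2);
          if (std::fabs(V[i][j] - (e + V[k][l])) < EPS) {
            stk.push_back({{k, l}, 0});
            done = true;
          }
        }
      }
      if (done) continue;
      for (int k = i + 1; k < j - 1 && !done; ++k) {
        if (WM[i + 1][k] < INF && WM[k + 1][j - 1] < INF &&
            std::fabs(V[i][j] - (mod.ml_a + mod.ml_b + WM[i + 1][k] + WM[k + 1][j - 1])) < EPS) {
          stk.push_back({{i + 1, k}, 1});
          stk.push_back({{k + 1, j - 1}, 1});
          done = true;
        }
      }
    } else {
      // WM
      double w = WM[i][j];
      if (V[i][j] < INF && std::fabs(w - (V[i][j] + mod.ml_b)) < EPS) {
        stk.push_back({{i, j}, 0});
        continue;
      }
      if (i + 1 <= j && WM[i + 1][j] < INF && std::fabs(w - (WM[i + 1][j] + mod.ml_c)) < EPS) {
        stk.push_back({{i + 1, j}, 1});
        continue;
      }
      if (i <= j - 1 && WM[i][j - 1] < INF && std::fabs(w - (WM[i][j - 1] + mod.ml_c)) < EPS) {
        stk.push_back({{i, j - 1}, 1});
        continue;
      }
      bool done = false;
      for (int k = i; k < j && !done; ++k) {
        if (WM[i][k] < INF && WM[k + 1][j] < INF &&
            std::fabs(w - (WM[i][k] + WM[k + 1][j])) < EPS) {
          stk.push_back({{i, k}, 1});
          stk.push_back({{k + 1, j}, 1});
          done = true;
        }
      }
    }
  }

  return List::create(_["mfe"] = W[n], _["pairs"] = wrap(pt));
}

// Intermolecular hybridisation: monotone non-crossing pairing between strand a
// and strand b (b passed already reversed so indices run parallel). Energy =
// stacks over adjacent pairs + bulge/internal penalties over gaps; no
// intramolecular structure, no initiation term.
// [[Rcpp::export]]
List duplex_cpp(IntegerVector a, IntegerVector brev, NumericMatrix stack,
                NumericVector params) {
  const int n = a.size(), m = brev.size();
  LoopModel mod = make_model(params);
  // D(i,j): best energy of a hybrid whose rightmost pair is (i,j)
  std::vector<std::vector<double>> D(n, std::vector<double>(m, INF));
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      int pij = pair_index(a[i], brev[j]);
      if (pij < 0) continue;
      double best = 0.0; // (i,j) is the only/first pair
      int i0min = std::max(0, i - mod.max_loop - 1);
      for (int i0 = i - 1; i0 >= i0min; --i0) {
        int g1 = i - i0 - 1;
        int j0min = std::max(0, j - 1 - (mod.max_loop - g1));
        for (int j0 = j - 1; j0 >= j0min; --j0) {
          if (D[i0][j0] >= INF) continue;
          int p0 = pair_index(a[i0], brev[j0]);
          int g2 = j - j0 - 1;
          double e = (g1 == 0 && g2 == 0) ? stack(p0, pij) : mod.interior(g1, g2);
          if (D[i0][j0] + e < best) best = D[i0][j0] + e;
        }
      }
      D[i][j] = best;
    }
  }
  double mfe = 0.0;
  int bi = -1, bj = -1;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j)
      if (D[i][j] < mfe) { mfe = D[i][j]; bi = i; bj = j; }

  // traceback of the pairing map (partner of a[i] in reversed-b coordinates)
  std::vector<int> pt(n, 0);
  const double EPS = 1e-7;
  int i = bi, j = bj;
  while (i >= 0 && j >= 0) {
    pt[i] = j + 1;
    bool moved = false;
    int pij = pair_index(a[i], brev[j]);
    int i0min = std::max(0, i - mod.max_loop - 1);
    for (int i0 = i - 1; i0 >= i0min && !moved; --i0) {
      int g1 = i - i0 - 1;
      int j0min = std::max(0, j - 1 - (mod.max_loop - g1));
      for (int j0 = j - 1; j0 >= j0min && !moved; --j0) {
        if (D[i0][j0] >= INF) continue;
        int p0 = pair_index(a[i0], brev[j0]);
        int g2 = j - j0 - 1;
        double e = (g1 == 0 && g2 == 0) ? stack(p0, pij) : mod.interior(g1, g2);
        if (std::fabs(D[i][j] - (D[i0][j0] + e)) < EPS) {
          i = i0; j = j0; moved = true;
        }
      }
    }
    if (!moved) break;
  }
  return List::create(_["mfe"] = mfe, _["pairs"] = wrap(pt));
}

// Leftmost occurrence of the 3' adapter: smallest start s (0-based) such that
// the overlap of adapter with read[s..] is >= min_overlap nt with <= max_mm
// mismatches. Returns 1-based start, or 0 when absent.
// [[Rcpp::export]]
IntegerVector locate_adapter_cpp(CharacterVector reads, std::string adapter,
                                 int min_overlap, int max_mm) {
  const int alen = adapter.size();
  const int nr = reads.size();
  IntegerVector out(nr);
  for (int r = 0; r < nr; ++r) {
    const char *rd = CHAR(STRING_ELT(reads, r));
    int len = LENGTH(STRING_ELT(reads, r));
    int hit = 0;
    for (int s = 0; s + min_overlap <= len; ++s) {
      int span = std::min(alen, len - s);
      int mm = 0;
      for (int k = 0; k < span; ++k) {
        if (rd[s + k] != adapter[k] && ++mm > max_mm) break;
      }
      if (mm <= max_mm) { hit = s + 1; break; }
    }
    out[r] = hit;
  }
  return out;
}
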