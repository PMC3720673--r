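#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

static const int INF = 100000000;

// bases coded 0=A,1=C,2=G,3=U,4=N; pair types 0=none,1=AU,2=CG,3=GC,4=UA,5=GU,6=UG
static inline int pair_type(int a, int b) {
  if (a == 0 && b == 3) return 1;
  if (a == 1 && b == 2) return 2;
  if (a == 2 && b == 1) return 3;
  if (a == 3 && b == 0) return 4;
  if (a == 2 && b == 3) return 5;
  if (a == 3 && b == 2) return 6;
  return 0;
}

struct Frame { int mat; int i; int j; }; // mat: 0=V,1=WM,2=WM2

// Minimum-free-energy pseudoknot-free fold, integer decikcal/mol.
// Loop model: hairpin/interior cost vectors indexed by loop size,
// stack matrix for adjacent pairs, linear multibranch term.
// [[Rcpp::export]]
List fold_engine_cpp(IntegerVector seq, IntegerMatrix stack,
                     IntegerVector hairpin_cost, IntegerVector interior_cost,
                     int mb_close, int mb_branch, int mb_unpaired,
                     int min_hairpin) {
  const int n = seq.size();
  std::string db(n, '.');
  if (n < min_hairpin + 2) {
    return List::create(_["energy"] = 0, _["structure"] = db);
  }
  std::vector<int> V((size_t)n * n, INF), WM((size_t)n * n, INF),
                   WM2((size_t)n * n, INF);
  std::vector<int> pt((size_t)n * n, 0);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      pt[(size_t)i * n + j] = pair_type(seq[i], seq[j]);
#define IX(i, j) ((size_t)(i) * n + (j))

  int cap = 0; // largest interior size with finite cost
  for (int s = 0; s < interior_cost.size(); ++s)
    if (interior_cost[s] < INF) cap = s;

  for (int d = 1; d < n; ++d) {
    for (int i = 0; i + d < n; ++i) {
      const int j = i + d;
      // V(i,j): i pairs j
      if (pt[IX(i, j)] != 0 && d > min_hairpin) {
        int best = hairpin_cost[d - 1]; // loop size j-i-1
        // stack / interior / bulge
        for (int p = i + 1; p <= j - 2 && p - i - 1 <= cap; ++p) {
          const int s1 = p - i - 1;
          for (int q = j - 1; q > p; --q) {
            const int s2 = j - q - 1;
            if (s1 + s2 > cap && !(s1 == 0 && s2 == 0)) break;
            const int v = V[IX(p, q)];
            if (v >= INF) continue;
            int cost;
            if (s1 == 0 && s2 == 0)
              cost = stack(pt[IX(i, j)] - 1, pt[IX(p, q)] - 1);
            else
              cost = interior_cost[s1 + s2];
            if (cost >= INF) continue;
            if (cost + v < best) best = cost + v;
          }
        }
        // multibranch closure
        if (j - i >= 2) {
          const int w2 = WM2[IX(i + 1, j - 1)];
          if (w2 < INF && mb_close + mb_branch + w2 < best)
            best = mb_close + mb_branch + w2;
        }
        V[IX(i, j)] = best;
      }
      // WM2(i,j): >= 2 branches in i..j
      {
        int best = INF;
        for (int k = i; k < j; ++k) {
          const int a = WM[IX(i, k)], b = WM[IX(k + 1, j)];
          if (a < INF && b < INF && a + b < best) best = a + b;
        }
        WM2[IX(i, j)] = best;
      }
      // WM(i,j): >= 1 branch
      {
        int best = INF;
        if (V[IX(i, j)] < INF) best = V[IX(i, j)] + mb_branch;
        if (WM2[IX(i, j)] < best) best = WM2[IX(i, j)];
        if (i + 1 <= j && WM[IX(i + 1, j)] < INF &&
            WM[IX(i + 1, j)] + mb_unpaired < best)
          best = WM[IX(i + 1, j)] + mb_unpaired;
        if (j - 1 >= i && WM[IX(i, j - 1)] < INF &&
            WM[IX(i, j - 1)] + mb_unpaired < best)
          best = WM[IX(i, j - 1)] + mb_unpaired;
        WM[IX(i, j)] = best;
      }
    }
  }

  // external loop
  std::vector<int> W(n + 1, 0);
  for (int j = 1; j <= n; ++j) {
    int best = W[j - 1];
    for (int i = 1; i <= j; ++i) {
      const int v = V[IX(i - 1, j - 1)];
      if (v < INF && W[i - 1] + v < best) best = W[i - 1] + v;
    }
    W[j] = best;
  }

  // traceback (fixed deterministic preference order)
  std::vector<Frame> todo;
  {
    int j = n;
    while (j > 0) {
      if (W[j] == W[j - 1]) { --j; continue; }
      bool found = false;
      for (int i = 1; i <= j && !found; ++i) {
        const int v = V[IX(i - 1, j - 1)];
        if (v < INF && W[i - 1] + v == W[j]) {
          todo.push_back({0, i - 1, j - 1});
          j = i - 1;
          found = true;
        }
      }
      if (!found) break; // defensive; cannot happen
    }
  }
  while (!todo.empty()) {
    Frame f = todo.back();
    todo.pop_back();
    const int i = f.i, j = f.j;
    if (f.mat == 0) { // V
      db[i] = '(';
      db[j] = ')';
      const int target = V[IX(i, j)];
      bool done = false;
      for (int p = i + 1; p <= j - 2 && p - i - 1 <= cap && !done; ++p) {
        const int s1 = p - i - 1;
        for (int q = j - 1; q > p; --q) {
          const int s2 = j - q - 1;
          if (s1 + s2 > cap && !(s1 == 0 && s2 == 0)) break;
          const int v = V[IX(p, q)];
          if (v >= INF) continue;
          int cost;
          if (s1 == 0 && s2 == 0)
            cost = stack(pt[IX(i, j)] - 1, pt[IX(p, q)] - 1);
          else
            cost = interior_cost[s1 + s2];
          if (cost < INF && cost + v == target) {
            todo.push_back({0, p, q});
            done = true;
            break;
          }
        }
      }
      if (done) continue;
      if (target == hairpin_cost[j - i - 1]) continue;
      // multibranch
      todo.push_back({2, i + 1, j - 1});
    } else if (f.mat == 2) { // WM2
      const int target = WM2[IX(i, j)];
      for (int k = i; k < j; ++k) {
        const int a = WM[IX(i, k)], b = WM[IX(k + 1, j)];
        if (a < INF && b < INF && a + b == target) {
          todo.push_back({1, i, k});
          todo.push_back({1, k + 1, j});
          break;
        }
      }
    } else { // WM
      const int target = WM[IX(i, j)];
      if (V[IX(i, j)] < INF && V[IX(i, j)] + mb_branch == target) {
        todo.push_back({0, i, j});
      } else if (WM2[IX(i, j)] == target) {
        todo.push_back({2, i, j});
      } else if (i + 1 <= j && WM[IX(i + 1, j)] < INF &&
                 WM[IX(i + 1, j)] + mb_unpaired == target) {
        todo.push_back({1, i + 1, j});
      } else {
        todo.push_back({1, i, j - 1});
      }
    }
  }
#undef IX
  return List::create(_["energy"] = W[n], _["structure"] = db);
}
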