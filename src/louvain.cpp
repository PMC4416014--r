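#include <Rcpp.h>
#include <random>
#include <vector>
using namespace Rcpp;

// One local-moving phase of the Louvain-style mixed-modularity optimizer.
//
// Nodes are 0-based; cls is 0 for class A, 1 for class B; channel is
// 0 = AA, 1 = AB, 2 = BB. Self-loop edges (u == v) contribute to channel
// totals and degrees but never change a move's gain, so they are excluded
// from the adjacency used for candidate moves.
//
// The gain of assigning node v (class A) to module c, with v held out of
// every module, is
//   [ w_AA(v,c)/mA - dA(v) * dA(c) / (2 mA^2)
//   + w_AB(v,c)/mPi - kPi(v) * dPi(c) / mPi^2 ] / 3
// and symmetrically for class B. Moves require strictly positive gain over
// staying; among equal gains the first candidate encountered wins. Sweeps
// repeat (order reshuffled each sweep when shuffled = true) until one full
// sweep makes no move.
// [[Rcpp::export]]
List cpp_local_moving(int n, IntegerVector cls,
                      IntegerVector eu, IntegerVector ev,
                      NumericVector ew, IntegerVector ech,
                      IntegerVector membership0,
                      int seed, bool shuffled) {
  const int m = eu.size();
  double mA = 0, mPi = 0, mB = 0;
  std::vector<double> dA(n, 0), kPi(n, 0), dPi(n, 0), dB(n, 0);
  std::vector<int> adj_head(n + 1, 0);

  for (int i = 0; i < m; ++i) {
    const int u = eu[i], v = ev[i], c = ech[i];
    const double w = ew[i];
    if (c == 0) { mA += w; }
    else if (c == 1) { mPi += w; }
    else { mB += w; }
    if (u == v) {
      if (c == 0) dA[u] += 2 * w;
      else if (c == 2) dB[u] += 2 * w;
      // an AB self-loop is impossible (endpoint classes differ)
      continue;
    }
    if (c == 0) { dA[u] += w; dA[v] += w; }
    else if (c == 2) { dB[u] += w; dB[v] += w; }
    else {
      if (cls[u] == 0) { kPi[u] += w; dPi[v] += w; }
      else { kPi[v] += w; dPi[u] += w; }
    }
    adj_head[u + 1]++; adj_head[v + 1]++;
  }
  for (int i = 0; i < n; ++i) adj_head[i + 1] += adj_head[i];
  std::vector<int> adj_nb(adj_head[n]);
  std::vector<double> adj_w(adj_head[n]);
  std::vector<int> adj_ch(adj_head[n]);
  {
    std::vector<int> pos(adj_head.begin(), adj_head.end() - 1);
    for (int i = 0; i < m; ++i) {
      const int u = eu[i], v = ev[i];
      if (u == v) continue;
      adj_nb[pos[u]] = v; adj_w[pos[u]] = ew[i]; adj_ch[pos[u]++] = ech[i];
      adj_nb[pos[v]] = u; adj_w[pos[v]] = ew[i]; adj_ch[pos[v]++] = ech[i];
    }
  }

  std::vector<int> memb(membership0.begin(), membership0.end());
  int n_mod = 0;
  for (int i = 0; i < n; ++i) n_mod = std::max(n_mod, memb[i] + 1);
  std::vector<double> modA(n_mod, 0), modKPi(n_mod, 0),
                      modDPi(n_mod, 0), modB(n_mod, 0);
  for (int i = 0; i < n; ++i) {
    modA[memb[i]] += dA[i];
    modKPi[memb[i]] += kPi[i];
    modDPi[memb[i]] += dPi[i];
    modB[memb[i]] += dB[i];
  }

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::mt19937 rng(static_cast<unsigned>(seed));

  // scratch: weight from the current node to each touched module, per channel
  std::vector<double> wAA(n_mod, 0), wAB(n_mod, 0), wBB(n_mod, 0);
  std::vector<int> touched;
  touched.reserve(64);

  double total_gain = 0;
  bool moved_any = true;
  int sweeps = 0;
  while (moved_any) {
    moved_any = false;
    ++sweeps;
    if (shuffled) std::shuffle(order.begin(), order.end(), rng);
    for (int oi = 0; oi < n; ++oi) {
      const int v = order[oi];
      const int s = memb[v];
      touched.clear();
      for (int j = adj_head[v]; j < adj_head[v + 1]; ++j) {
        const int c = memb[adj_nb[j]];
        if (wAA[c] == 0 && wAB[c] == 0 && wBB[c] == 0) touched.push_back(c);
        if (adj_ch[j] == 0) wAA[c] += adj_w[j];
        else if (adj_ch[j] == 1) wAB[c] += adj_w[j];
        else wBB[c] += adj_w[j];
      }
      // hold v out of its module
      modA[s] -= dA[v]; modKPi[s] -= kPi[v];
      modDPi[s] -= dPi[v]; modB[s] -= dB[v];

      const bool isA = (cls[v] == 0);
      auto gain_of = [&](int c) -> double {
        double g = 0;
        if (mA > 0 && isA)
          g += wAA[c] / mA - dA[v] * modA[c] / (2 * mA * mA);
        if (mB > 0 && !isA)
          g += wBB[c] / mB - dB[v] * modB[c] / (2 * mB * mB);
        if (mPi > 0) {
          if (isA) g += wAB[c] / mPi - kPi[v] * modDPi[c] / (mPi * mPi);
          else     g += wAB[c] / mPi - dPi[v] * modKPi[c] / (mPi * mPi);
        }
        return g / 3.0;
      };
      double best_gain = gain_of(s);
      int best = s;
      bool s_seen = false;
      for (size_t ti = 0; ti < touched.size(); ++ti) {
        const int c = touched[ti];
        if (c == s) { s_seen = true; continue; }
        const double g = gain_of(c);
        if (g > best_gain) { best_gain = g; best = c; }
      }
      (void)s_seen;
      if (best != s) {
        total_gain += best_gain - gain_of(s);
        memb[v] = best;
        moved_any = true;
      }
      modA[memb[v]] += dA[v]; modKPi[memb[v]] += kPi[v];
      modDPi[memb[v]] += dPi[v]; modB[memb[v]] += dB[v];
      for (size_t ti = 0; ti < touched.size(); ++ti) {
        wAA[touched[ti]] = 0; wAB[touched[ti]] = 0; wBB[touched[ti]] = 0;
      }
    }
    if (sweeps > 10000) stop("local moving failed to converge");
  }

  return List::create(_["membership"] = IntegerVector(memb.begin(), memb.end()),
                      _["gain"] = total_gain,
                      _["sweeps"] = sweeps);
}
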