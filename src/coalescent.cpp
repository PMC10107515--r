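// Structured-coalescent engine for two demes with piecewise-constant sizes and
// migration, in coalescent time units of 2*N_anc generations (ancestral size 1).
//
// Each simulated genealogy relates n1 + n2 gene copies ("frequency panel")
// sampled from demes 1 (diploid population D) and 2 (tetraploid population T).
// Under the infinite-sites model the expected number of segregating sites whose
// derived allele subtends a copies in deme 1 and b copies in deme 2 is
// proportional to the expected total branch length carrying that configuration,
// so the engine accumulates E[branch length] per (a, b) cell.
//
// Epoch rows are ordered backward from the present: (duration, nu1, nu2,
// m12, m21) where m12 is the backward rate at which a lineage currently in
// deme 1 traces its ancestry to deme 2 (forward migrants into deme 1), and
// duration is in units of 2*N_anc generations. After the last row all
// lineages merge into the ancestral population of relative size 1.
//
// Randomness is drawn exclusively through std::mt19937_64 + inverse-transform
// uniforms so that results are bit-reproducible for a given seed.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Engine {
  std::mt19937_64 rng;
  std::uniform_real_distribution<double> unif{0.0, 1.0};

  explicit Engine(uint64_t seed) : rng(seed) {}

  double runif01() {
    double u;
    do {
      u = unif(rng);
    } while (u <= 0.0 || u >= 1.0);
    return u;
  }
  double rexp(double rate) { return -std::log(runif01()) / rate; }
  int rint(int n) {  // uniform on 0..n-1
    return static_cast<int>(std::floor(runif01() * n)) % n;
  }
};

struct Branch {
  int a;       // subtended copies in deme 1
  int b;       // subtended copies in deme 2
  double len;  // branch length
};

// reusable per-tree workspace (allocated once per exported call)
struct Workspace {
  std::vector<int> a, b, deme_of, pos;
  std::vector<double> birth;
  std::vector<int> members[2];
  std::vector<Branch> branches;

  void reserve(int cap) {
    a.reserve(cap); b.reserve(cap); deme_of.reserve(cap);
    pos.reserve(cap); birth.reserve(cap);
    members[0].reserve(cap); members[1].reserve(cap);
    branches.reserve(cap);
  }
};

// Simulate one genealogy; fill ws.branches with every non-root branch.
void simulate_tree(Engine &eng, int n1, int n2,
                   const double *ep_mat, int n_ep, Workspace &ws) {
  const int ntot = n1 + n2;
  ws.a.assign(ntot, 0); ws.b.assign(ntot, 0);
  ws.birth.assign(ntot, 0.0); ws.deme_of.assign(ntot, 0);
  ws.pos.assign(ntot, 0);
  ws.members[0].clear(); ws.members[1].clear();
  ws.branches.clear();

  for (int i = 0; i < n1; ++i) {
    ws.a[i] = 1; ws.deme_of[i] = 0;
    ws.pos[i] = static_cast<int>(ws.members[0].size());
    ws.members[0].push_back(i);
  }
  for (int i = n1; i < ntot; ++i) {
    ws.b[i] = 1; ws.deme_of[i] = 1;
    ws.pos[i] = static_cast<int>(ws.members[1].size());
    ws.members[1].push_back(i);
  }

  auto remove_from_deme = [&](int i) {
    int d = ws.deme_of[i];
    int p = ws.pos[i];
    int last = ws.members[d].back();
    ws.members[d][p] = last;
    ws.pos[last] = p;
    ws.members[d].pop_back();
  };
  auto add_to_deme = [&](int i, int d) {
    ws.deme_of[i] = d;
    ws.pos[i] = static_cast<int>(ws.members[d].size());
    ws.members[d].push_back(i);
  };
  auto epoch_col = [&](int ep, int col) { return ep_mat[col * n_ep + ep]; };

  double t = 0.0;
  int ep = 0;
  bool ancestral = (n_ep == 0);
  double ep_end = ancestral ? 0.0 : epoch_col(0, 0);
  double nu1 = ancestral ? 1.0 : epoch_col(0, 1);
  double nu2 = ancestral ? 1.0 : epoch_col(0, 2);
  double m12 = ancestral ? 0.0 : epoch_col(0, 3);
  double m21 = ancestral ? 0.0 : epoch_col(0, 4);

  if (ancestral) {
    while (!ws.members[1].empty()) {
      int i = ws.members[1].back();
      remove_from_deme(i);
      add_to_deme(i, 0);
    }
  }

  int alive = ntot;
  while (alive > 1) {
    const int k1 = static_cast<int>(ws.members[0].size());
    const int k2 = static_cast<int>(ws.members[1].size());
    const double cr1 = (k1 >= 2) ? 0.5 * k1 * (k1 - 1) / nu1 : 0.0;
    const double cr2 = (k2 >= 2) ? 0.5 * k2 * (k2 - 1) / nu2 : 0.0;
    const double mr1 = k1 * m12;
    const double mr2 = k2 * m21;
    const double total = cr1 + cr2 + mr1 + mr2;

    double dt = (total > 0.0) ? eng.rexp(total) : R_PosInf;
    if (!ancestral && t + dt >= ep_end) {
      t = ep_end;
      ++ep;
      if (ep >= n_ep) {
        ancestral = true;
        nu1 = 1.0; nu2 = 1.0; m12 = 0.0; m21 = 0.0;
        while (!ws.members[1].empty()) {
          int i = ws.members[1].back();
          remove_from_deme(i);
          add_to_deme(i, 0);
        }
      } else {
        ep_end += epoch_col(ep, 0);
        nu1 = epoch_col(ep, 1); nu2 = epoch_col(ep, 2);
        m12 = epoch_col(ep, 3); m21 = epoch_col(ep, 4);
      }
      continue;
    }
    t += dt;

    double u = eng.runif01() * total;
    if (u < cr1 + cr2) {
      const int d = (u < cr1) ? 0 : 1;
      const int k = static_cast<int>(ws.members[d].size());
      int ii = eng.rint(k);
      int jj = eng.rint(k - 1);
      if (jj >= ii) ++jj;
      const int i = ws.members[d][ii];
      const int j = ws.members[d][jj];
      ws.branches.push_back({ws.a[i], ws.b[i], t - ws.birth[i]});
      ws.branches.push_back({ws.a[j], ws.b[j], t - ws.birth[j]});
      const int p = static_cast<int>(ws.a.size());
      ws.a.push_back(ws.a[i] + ws.a[j]);
      ws.b.push_back(ws.b[i] + ws.b[j]);
      ws.birth.push_back(t);
      ws.deme_of.push_back(d);
      ws.pos.push_back(0);
      remove_from_deme(i);
      remove_from_deme(j);
      add_to_deme(p, d);
      --alive;
    } else if (u < cr1 + cr2 + mr1) {
      const int i = ws.members[0][eng.rint(k1)];
      remove_from_deme(i);
      add_to_deme(i, 1);
    } else {
      const int i = ws.members[1][eng.rint(k2)];
      remove_from_deme(i);
      add_to_deme(i, 0);
    }
  }
  // root branch has no parent and is not emitted
}

}  // namespace

// [[Rcpp::export]]
List coal_branch_spectrum(int n1, int n2, NumericMatrix epochs,
                          int n_trees, int n_batches, double seed) {
  if (n1 < 1 || n2 < 1) stop("panel sizes must be >= 1");
  if (n_trees < 1) stop("n_trees must be >= 1");
  if (n_batches < 1) n_batches = 1;
  if (n_batches > n_trees) n_batches = n_trees;
  Engine eng(static_cast<uint64_t>(seed));
  Workspace ws;
  ws.reserve(4 * (n1 + n2));

  const int nr = n1 + 1, ncol = n2 + 1;
  std::vector<double> W(static_cast<size_t>(nr) * ncol, 0.0);
  std::vector<std::vector<double>> batches;
  const bool want_batches = n_batches > 1;
  if (want_batches)
    batches.assign(n_batches, std::vector<double>(W.size(), 0.0));

  for (int s = 0; s < n_trees; ++s) {
    simulate_tree(eng, n1, n2, REAL(epochs), epochs.nrow(), ws);
    const int q = (s * n_batches) / n_trees;
    for (const Branch &br : ws.branches) {
      const size_t cell = static_cast<size_t>(br.b) * nr + br.a;
      W[cell] += br.len;
      if (want_batches) batches[q][cell] += br.len;
    }
  }

  NumericMatrix Wout(nr, ncol);
  const double inv = 1.0 / n_trees;
  for (size_t k = 0; k < W.size(); ++k) Wout[k] = W[k] * inv;

  List bl(want_batches ? n_batches : 1);
  if (want_batches) {
    for (int q = 0; q < n_batches; ++q) {
      const int lo = (q * n_trees) / n_batches;
      const int hi = ((q + 1) * n_trees) / n_batches;
      const double bw = 1.0 / (hi - lo);
      NumericMatrix B(nr, ncol);
      for (size_t k = 0; k < W.size(); ++k) B[k] = batches[q][k] * bw;
      bl[q] = B;
    }
  } else {
    bl[0] = Wout;
  }
  return List::create(_["W"] = Wout, _["batches"] = bl);
}

// Draw per-site derived-allele panel configurations: for each site simulate an
// independent genealogy and pick one branch with probability proportional to
// its length (the infinite-sites placement of a single mutation).
// [[Rcpp::export]]
IntegerMatrix coal_sample_sites(int n1, int n2, NumericMatrix epochs,
                                int n_sites, double seed) {
  if (n1 < 1 || n2 < 1) stop("panel sizes must be >= 1");
  if (n_sites < 1) stop("n_sites must be >= 1");
  Engine eng(static_cast<uint64_t>(seed));
  Workspace ws;
  ws.reserve(4 * (n1 + n2));
  IntegerMatrix out(n_sites, 2);
  for (int s = 0; s < n_sites; ++s) {
    simulate_tree(eng, n1, n2, REAL(epochs), epochs.nrow(), ws);
    double tot = 0.0;
    for (const Branch &br : ws.branches) tot += br.len;
    double u = eng.runif01() * tot;
    double acc = 0.0;
    int chosen = static_cast<int>(ws.branches.size()) - 1;
    for (size_t k = 0; k < ws.branches.size(); ++k) {
      acc += ws.branches[k].len;
      if (u <= acc) { chosen = static_cast<int>(k); break; }
    }
    out(s, 0) = ws.branches[chosen].a;
    out(s, 1) = ws.branches[chosen].b;
  }
  return out;
}
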