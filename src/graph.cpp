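#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// A tissue graph as a rotation system: cells are nodes, each node stores the
// cyclic (counter-clockwise) order of its neighbours.  Cell ids are 1-based
// and contiguous; a dividing mother keeps its id for the first daughter and
// the second daughter takes the next free id, so ids are never retired.
struct TG {
  std::vector< std::vector<int> > adj; // adj[id-1]: cyclic neighbour order
  std::vector<int> gen;                // completed divisions per cell
};

typedef XPtr<TG> TGPtr;

// [[Rcpp::export]]
SEXP tg_new(List adj, IntegerVector gen) {
  TG* g = new TG();
  int n = adj.size();
  g->adj.resize(n);
  g->gen.assign(gen.begin(), gen.end());
  for (int i = 0; i < n; ++i) {
    IntegerVector v = adj[i];
    g->adj[i].assign(v.begin(), v.end());
  }
  return TGPtr(g, true);
}

// [[Rcpp::export]]
SEXP tg_clone(SEXP p) {
  TGPtr g(p);
  TG* h = new TG(*g);
  return TGPtr(h, true);
}

// [[Rcpp::export]]
int tg_ncells(SEXP p) { TGPtr g(p); return g->adj.size(); }

// [[Rcpp::export]]
List tg_adj(SEXP p) {
  TGPtr g(p);
  int n = g->adj.size();
  List out(n);
  for (int i = 0; i < n; ++i) out[i] = wrap(g->adj[i]);
  return out;
}

// [[Rcpp::export]]
IntegerVector tg_gen(SEXP p) { TGPtr g(p); return wrap(g->gen); }

// [[Rcpp::export]]
IntegerVector tg_degrees(SEXP p) {
  TGPtr g(p);
  int n = g->adj.size();
  IntegerVector d(n);
  for (int i = 0; i < n; ++i) d[i] = g->adj[i].size();
  return d;
}

// Validate rotation-system invariants.  Returns a character vector of
// problems (empty when the graph is consistent).
// [[Rcpp::export]]
CharacterVector tg_validate(SEXP p) {
  TGPtr g(p);
  std::vector<std::string> probs;
  int n = g->adj.size();
  for (int i = 0; i < n && (int)probs.size() < 20; ++i) {
    const std::vector<int>& v = g->adj[i];
    if ((int)v.size() < 3)
      probs.push_back("cell " + std::to_string(i + 1) + " has degree < 3");
    for (size_t k = 0; k < v.size(); ++k) {
      int j = v[k];
      if (j < 1 || j > n) {
        probs.push_back("cell " + std::to_string(i + 1) + " lists unknown neighbour");
        continue;
      }
      if (j == i + 1)
        probs.push_back("cell " + std::to_string(i + 1) + " neighbours itself");
      // single occurrence
      for (size_t l = k + 1; l < v.size(); ++l)
        if (v[l] == j)
          probs.push_back("cell " + std::to_string(i + 1) + " lists neighbour " +
                          std::to_string(j) + " twice");
      // symmetry
      const std::vector<int>& w = g->adj[j - 1];
      bool found = false;
      for (size_t l = 0; l < w.size(); ++l) if (w[l] == i + 1) { found = true; break; }
      if (!found)
        probs.push_back("adjacency " + std::to_string(i + 1) + "->" +
                        std::to_string(j) + " is not symmetric");
    }
  }
  return wrap(probs);
}

static int draw_split(int rule, int n) {
  // rule: 1 = equal, 2 = random, 3 = pascal; returns arc size a in [0, n-2]
  int m = n - 2;
  if (rule == 1) {
    if (m % 2 == 0) return m / 2;
    return (m - 1) / 2 + (unif_rand() < 0.5 ? 1 : 0);
  } else if (rule == 2) {
    int a = (int)std::floor(unif_rand() * (m + 1));
    if (a > m) a = m;
    return a;
  } else if (rule == 3) {
    // binomial split over the non-junction neighbours with both daughters
    // receiving at least one, so daughters have >= 4 neighbours (the
    // Gibson-type kernel); a triangular mother (m == 1) is forced to a
    // {3,4} split.
    if (m < 2) return (int)std::floor(unif_rand() * (m + 1));
    return 1 + (int)R::rbinom((double)(m - 2), 0.5);
  }
  stop("unknown rule code");
  return -1;
}

static void replace_after(std::vector<int>& v, int oldid, int insid, bool before) {
  // locate oldid in v; keep it and insert insid before/after it
  for (size_t k = 0; k < v.size(); ++k) {
    if (v[k] == oldid) {
      v.insert(v.begin() + (before ? k : k + 1), insid);
      return;
    }
  }
  stop("rotation order corrupted: expected neighbour not found");
}

static void subst(std::vector<int>& v, int oldid, int newid) {
  for (size_t k = 0; k < v.size(); ++k)
    if (v[k] == oldid) { v[k] = newid; return; }
  stop("rotation order corrupted: expected neighbour not found");
}

// Divide `cell`.  start_wall: 1-based wall index, 0 = draw uniformly.
// split: arc size a in [0, n-2], -1 = draw from the rule.
// Returns c(d1, d2, mother_n, d1_n, d2_n, j1, j2).
static IntegerVector divide_impl(TG* g, int cell, int rule, int start_wall,
                                 int split) {
  int n_cells = g->adj.size();
  if (cell < 1 || cell > n_cells) stop("no such cell: %d", cell);
  std::vector<int> v = g->adj[cell - 1]; // copy: mother order
  int n = v.size();
  if (n < 3) stop("cell %d has degree < 3", cell);
  int i = (start_wall > 0) ? (start_wall - 1)
                           : (int)std::floor(unif_rand() * n);
  if (i >= n) i = n - 1;
  int a = (split >= 0) ? split : draw_split(rule, n);
  if (a < 0 || a > n - 2) stop("arc split a=%d out of range for degree %d", a, n);

  int d1 = cell;
  int d2 = n_cells + 1;
  int j1 = v[i % n];
  int j2 = v[(i + a + 1) % n];

  // daughter rotation orders (counter-clockwise, consistent with mother)
  std::vector<int> o1, o2;
  o1.reserve(a + 3);
  o2.reserve(n - a + 1);
  o1.push_back(j1);
  for (int k = 1; k <= a; ++k) o1.push_back(v[(i + k) % n]);
  o1.push_back(j2);
  o1.push_back(d2);
  o2.push_back(j2);
  for (int k = a + 2; k <= n - 1; ++k) o2.push_back(v[(i + k) % n]);
  o2.push_back(j1);
  o2.push_back(d1);

  // junction neighbours become adjacent to both daughters; orientation puts
  // d1 on the side of the first arc for j1 and d2 on the side of the second
  // arc for j2 (insert d2 after the mother entry in j1, before it in j2).
  replace_after(g->adj[j1 - 1], cell, d2, false);
  replace_after(g->adj[j2 - 1], cell, d2, true);
  // second-arc neighbours now border d2 instead of the mother
  for (int k = a + 2; k <= n - 1; ++k) subst(g->adj[v[(i + k) % n] - 1], cell, d2);
  // first-arc neighbours keep bordering id `cell`, which is now d1: no-op

  g->adj[cell - 1] = o1;
  g->adj.push_back(o2);
  int gd = g->gen[cell - 1] + 1;
  g->gen[cell - 1] = gd;
  g->gen.push_back(gd);

  return IntegerVector::create(d1, d2, n, a + 3, n + 1 - a, j1, j2);
}

// [[Rcpp::export]]
IntegerVector tg_divide(SEXP p, int cell, int rule, int start_wall = 0,
                        int split = -1) {
  TGPtr g(p);
  return divide_impl(g, cell, rule, start_wall, split);
}

// One complete division round without replacement: every cell present at the
// start divides exactly once, in uniformly shuffled order, asynchronously.
// Returns an integer matrix with one row per division:
// mother_n, d1_n, d2_n, d1, d2.
// [[Rcpp::export]]
IntegerMatrix tg_run_round(SEXP p, int rule) {
  TGPtr g(p);
  int N = g->adj.size();
  std::vector<int> ord(N);
  for (int i = 0; i < N; ++i) ord[i] = i + 1;
  for (int i = N - 1; i > 0; --i) { // Fisher-Yates with R's RNG
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(ord[i], ord[j]);
  }
  IntegerMatrix ev(N, 5);
  for (int k = 0; k < N; ++k) {
    IntegerVector r = divide_impl(g, ord[k], rule, 0, -1);
    ev(k, 0) = r[2]; ev(k, 1) = r[3]; ev(k, 2) = r[4];
    ev(k, 3) = r[0]; ev(k, 4) = r[1];
  }
  return ev;
}

// n_events divisions of uniformly selected cells (with replacement).
// [[Rcpp::export]]
IntegerMatrix tg_run_events(SEXP p, int rule, int n_events) {
  TGPtr g(p);
  IntegerMatrix ev(n_events, 5);
  for (int k = 0; k < n_events; ++k) {
    int N = g->adj.size();
    int c = (int)std::floor(unif_rand() * N) + 1;
    if (c > N) c = N;
    IntegerVector r = divide_impl(g, c, rule, 0, -1);
    ev(k, 0) = r[2]; ev(k, 1) = r[3]; ev(k, 2) = r[4];
    ev(k, 3) = r[0]; ev(k, 4) = r[1];
  }
  return ev;
}

// Run n_events with-replacement divisions while auditing the conservation
// laws against the actual graph state: before each division the degrees of
// the mother's neighbours are recorded from the adjacency itself, and after
// the division they are recomputed and compared.  Violations counted:
//  - deg(d1) + deg(d2) != mother_n + 4
//  - the number of former neighbours that gained exactly one neighbour is
//    not exactly 2, or any other former neighbour changed degree
//  - the neighbourhood degree total did not rise by exactly 2.
// [[Rcpp::export]]
List tg_run_events_audited(SEXP p, int rule, int n_events) {
  TGPtr g(p);
  IntegerMatrix ev(n_events, 3);
  int violations = 0;
  for (int k = 0; k < n_events; ++k) {
    int N = g->adj.size();
    int c = (int)std::floor(unif_rand() * N) + 1;
    if (c > N) c = N;
    std::vector<int> nb = g->adj[c - 1];
    std::vector<int> pre(nb.size());
    int pre_tot = 0;
    for (size_t t = 0; t < nb.size(); ++t) {
      pre[t] = g->adj[nb[t] - 1].size();
      pre_tot += pre[t];
    }
    IntegerVector r = divide_impl(g, c, rule, 0, -1);
    ev(k, 0) = r[2]; ev(k, 1) = r[3]; ev(k, 2) = r[4];
    int d1n = g->adj[r[0] - 1].size();
    int d2n = g->adj[r[1] - 1].size();
    bool bad = (d1n + d2n != r[2] + 4) || (d1n != r[3]) || (d2n != r[4]);
    int gained = 0, post_tot = 0;
    for (size_t t = 0; t < nb.size(); ++t) {
      int post = g->adj[nb[t] - 1].size();
      post_tot += post;
      if (post == pre[t] + 1) ++gained;
      else if (post != pre[t]) bad = true;
    }
    if (gained != 2 || post_tot != pre_tot + 2) bad = true;
    if (bad) ++violations;
  }
  return List::create(Named("events") = ev,
                      Named("violations") = violations);
}

// [[Rcpp::export]]
IntegerVector tg_cell_adj(SEXP p, int cell) {
  TGPtr g(p);
  if (cell < 1 || cell > (int)g->adj.size()) stop("no such cell: %d", cell);
  return wrap(g->adj[cell - 1]);
}

// Monte-Carlo sampling of a single cell's division outcome: each repetition
// divides `cell` in a private copy of the graph, recording the two daughter
// degrees.  Used to compare realised divisions against analytic matrices.
// [[Rcpp::export]]
IntegerMatrix tg_sample_divisions(SEXP p, int cell, int rule, int reps) {
  TGPtr g(p);
  IntegerMatrix out(reps, 2);
  for (int k = 0; k < reps; ++k) {
    TG h(*g);
    IntegerVector r = divide_impl(&h, cell, rule, 0, -1);
    out(k, 0) = r[3];
    out(k, 1) = r[4];
  }
  return out;
}
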