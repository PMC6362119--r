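#include <Rcpp.h>
#include <vector>
#include <string>
#include <unordered_set>
#include <cstring>
#include <algorithm>
using namespace Rcpp;

// Coalescent machinery for divergence-only demographies of haploid
// (mtDNA-like) populations.  Time runs backwards in generations; the
// coalescence rate for k lineages in a population of size Ne is
// k(k-1)/2 / Ne per generation, so E[T2] = Ne and E[pi] = 2*Ne*mu.
// All randomness comes from R's RNG (set.seed() in R controls everything).

namespace {

struct Genealogy {
  int n;                      // tips
  std::vector<int> parent;    // 2n-1 entries, root has -1
  std::vector<double> time;   // node ages, tips at 0
};

// events: columns (time, type, a, b); type 0 = merge (lineages of pop a
// move into pop b), type 1 = resize (pop a gets Ne = b).  Rows must be
// sorted by time; same-time rows are applied in order.
Genealogy simulate_genealogy_core(const std::vector<int>& ss,
                                  std::vector<double> Ne,
                                  const NumericMatrix& events) {
  const int P = (int) ss.size();
  if ((int) Ne.size() < P) stop("Ne vector shorter than number of populations");
  int n = 0;
  for (int p = 0; p < P; ++p) {
    if (ss[p] < 0) stop("negative sample size");
    n += ss[p];
  }
  if (n < 1) stop("no samples");
  for (int p = 0; p < P; ++p)
    if (!(Ne[p] > 0)) stop("non-positive Ne");
  const int nev = events.nrow();
  for (int e = 1; e < nev; ++e)
    if (events(e, 0) < events(e - 1, 0)) stop("event times must be non-decreasing");

  Genealogy g;
  g.n = n;
  g.parent.assign(2 * n - 1, -1);
  g.time.assign(2 * n - 1, 0.0);

  std::vector< std::vector<int> > active(P);
  {
    int id = 0;
    for (int p = 0; p < P; ++p)
      for (int i = 0; i < ss[p]; ++i) active[p].push_back(id++);
  }
  int nextNode = n, totalActive = n, ev = 0;
  double t = 0.0;
  while (totalActive > 1) {
    double rate = 0.0;
    for (int p = 0; p < P; ++p) {
      const double k = (double) active[p].size();
      if (k > 1.0) rate += k * (k - 1.0) * 0.5 / Ne[p];
    }
    const double tNext = (rate > 0.0) ? t + R::exp_rand() / rate : R_PosInf;
    if (ev < nev && events(ev, 0) <= tNext) {
      t = events(ev, 0);
      const int type = (int) events(ev, 1);
      const int a = (int) events(ev, 2);
      if (a < 0 || a >= P) stop("event references unknown population");
      if (type == 0) {
        const int b = (int) events(ev, 3);
        if (b < 0 || b >= P || b == a) stop("bad merge target");
        for (size_t x = 0; x < active[a].size(); ++x) active[b].push_back(active[a][x]);
        active[a].clear();
      } else {
        if (!(events(ev, 3) > 0)) stop("non-positive Ne in resize event");
        Ne[a] = events(ev, 3);
      }
      ++ev;
      continue;
    }
    if (!R_FINITE(tNext))
      stop("lineages cannot coalesce: populations remain isolated and no events are left");
    t = tNext;
    // choose the population in which the coalescence happens
    double u = unif_rand() * rate, acc = 0.0;
    int pick = -1;
    for (int p = 0; p < P; ++p) {
      const double k = (double) active[p].size();
      if (k > 1.0) {
        acc += k * (k - 1.0) * 0.5 / Ne[p];
        pick = p;
        if (u <= acc) break;
      }
    }
    std::vector<int>& A = active[pick];
    const int k = (int) A.size();
    int i = (int) (unif_rand() * k);       if (i >= k) i = k - 1;
    int j = (int) (unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
    if (j >= i) ++j;
    g.parent[A[i]] = nextNode;
    g.parent[A[j]] = nextNode;
    g.time[nextNode] = t;
    if (i < j) std::swap(i, j);            // remove the larger index first
    A[i] = A.back(); A.pop_back();
    A[j] = A.back(); A.pop_back();
    A.push_back(nextNode);
    ++nextNode;
    --totalActive;
  }
  return g;
}

void mutate_branch(std::vector<int>& work, int L, double expected,
                   std::vector< std::pair<int,int> >& undo) {
  const int nm = (int) R::rpois(expected);
  for (int m = 0; m < nm; ++m) {
    int s = (int) (unif_rand() * L); if (s >= L) s = L - 1;
    int shift = 1 + (int) (unif_rand() * 3.0); if (shift > 3) shift = 3;
    undo.push_back(std::make_pair(s, work[s]));
    work[s] = (work[s] + shift) & 3;       // Jukes-Cantor: any other base
  }
}

void evolve_node(int v, int root, const Genealogy& g,
                 const std::vector< std::vector<int> >& children,
                 std::vector<int>& work, int L, double mu, int* seqs) {
  std::vector< std::pair<int,int> > undo;
  if (v != root) {
    const double blen = g.time[g.parent[v]] - g.time[v];
    mutate_branch(work, L, mu * blen * (double) L, undo);
  }
  if (v < g.n) {
    std::memcpy(seqs + (size_t) v * L, work.data(), sizeof(int) * (size_t) L);
  } else {
    for (size_t c = 0; c < children[v].size(); ++c)
      evolve_node(children[v][c], root, g, children, work, L, mu, seqs);
  }
  for (int q = (int) undo.size() - 1; q >= 0; --q) work[undo[q].first] = undo[q].second;
}

// fills seqs (L x n, individual-major) with states 0..3
void evolve_core(const Genealogy& g, int L, double mu, int* seqs) {
  const int total = 2 * g.n - 1;
  std::vector< std::vector<int> > children(total);
  const int root = total - 1;
  for (int v = 0; v < total - 1; ++v)
    if (g.parent[v] >= 0) children[g.parent[v]].push_back(v);
  std::vector<int> work(L);
  for (int s = 0; s < L; ++s) {
    int b = (int) (unif_rand() * 4.0); if (b > 3) b = 3;
    work[s] = b;                           // equal ancestral base frequencies
  }
  evolve_node(root, root, g, children, work, L, mu, seqs);
}

inline int n_stats(int P) { return 4 * P + P * (P - 1); }

// Summary statistics in DIYABC's spirit, fixed order:
//   per population p:       nhap_p, segsites_p, mpd_p, private_p
//   per ordered pair p<q:   dxy_pq (mean between-sample pairwise diffs),
//                           fst_pq (Hudson: 1 - mean within / between)
// seqs is L x n column-major; pop is 0-based of length n.
void compute_stats_core(const int* seqs, int L, int n,
                        const std::vector<int>& pop, int P, double* out) {
  std::vector<int> var;
  {
    const int* ref = seqs;
    std::vector<char> flag((size_t) L, 0);
    for (int i = 1; i < n; ++i) {
      const int* ci = seqs + (size_t) i * L;
      for (int s = 0; s < L; ++s) if (ci[s] != ref[s]) flag[s] = 1;
    }
    for (int s = 0; s < L; ++s) if (flag[s]) var.push_back(s);
  }
  const int Sv = (int) var.size();
  std::vector<unsigned char> V((size_t) Sv * n);
  for (int i = 0; i < n; ++i) {
    const int* ci = seqs + (size_t) i * L;
    for (int s = 0; s < Sv; ++s) V[(size_t) i * Sv + s] = (unsigned char) ci[var[s]];
  }
  std::vector<int> D((size_t) n * n, 0);
  for (int i = 0; i < n; ++i) {
    const unsigned char* vi = V.data() + (size_t) i * Sv;
    for (int j = i + 1; j < n; ++j) {
      const unsigned char* vj = V.data() + (size_t) j * Sv;
      int d = 0;
      for (int s = 0; s < Sv; ++s) d += (vi[s] != vj[s]);
      D[(size_t) i * n + j] = d;
      D[(size_t) j * n + i] = d;
    }
  }
  std::vector< std::vector<int> > members(P);
  for (int i = 0; i < n; ++i) {
    if (pop[i] < 0 || pop[i] >= P) stop("population index out of range");
    members[pop[i]].push_back(i);
  }
  std::vector<double> nhap(P, 0.0), seg(P, 0.0), mpd(P, 0.0), priv(P, 0.0);
  for (int p = 0; p < P; ++p) {
    const std::vector<int>& mem = members[p];
    const int np = (int) mem.size();
    if (np == 0) continue;
    std::unordered_set<std::string> H;
    for (int q = 0; q < np; ++q)
      H.insert(std::string((const char*) (V.data() + (size_t) mem[q] * Sv), (size_t) Sv));
    nhap[p] = (double) H.size();
    int sp = 0;
    for (int s = 0; s < Sv; ++s) {
      const unsigned char a0 = V[(size_t) mem[0] * Sv + s];
      for (int q = 1; q < np; ++q)
        if (V[(size_t) mem[q] * Sv + s] != a0) { ++sp; break; }
    }
    seg[p] = (double) sp;
    double tot = 0.0; long cnt = 0;
    for (int a = 0; a < np; ++a)
      for (int b = a + 1; b < np; ++b) { tot += D[(size_t) mem[a] * n + mem[b]]; ++cnt; }
    mpd[p] = cnt ? tot / (double) cnt : 0.0;
  }
  // a pooled segregating site is private to pop k iff every carrier of a
  // non-major allele belongs to k
  for (int s = 0; s < Sv; ++s) {
    int cnts[4] = {0, 0, 0, 0};
    for (int i = 0; i < n; ++i) cnts[V[(size_t) i * Sv + s]]++;
    int maj = 0;
    for (int b = 1; b < 4; ++b) if (cnts[b] > cnts[maj]) maj = b;
    int carrierPop = -2;                   // -2 none seen, -1 mixed
    for (int i = 0; i < n; ++i) {
      if (V[(size_t) i * Sv + s] != (unsigned char) maj) {
        if (carrierPop == -2) carrierPop = pop[i];
        else if (carrierPop != pop[i]) { carrierPop = -1; break; }
      }
    }
    if (carrierPop >= 0) priv[carrierPop] += 1.0;
  }
  int o = 0;
  for (int p = 0; p < P; ++p) {
    out[o++] = nhap[p]; out[o++] = seg[p]; out[o++] = mpd[p]; out[o++] = priv[p];
  }
  for (int p = 0; p < P; ++p) {
    for (int q = p + 1; q < P; ++q) {
      const std::vector<int>& mp = members[p];
      const std::vector<int>& mq = members[q];
      double tot = 0.0;
      for (size_t a = 0; a < mp.size(); ++a)
        for (size_t b = 0; b < mq.size(); ++b) tot += D[(size_t) mp[a] * n + mq[b]];
      const double nn = (double) mp.size() * (double) mq.size();
      const double db = nn > 0 ? tot / nn : 0.0;
      const double dw = 0.5 * (mpd[p] + mpd[q]);
      out[o++] = db;
      out[o++] = (db > 0.0) ? 1.0 - dw / db : 0.0;
    }
  }
}

} // namespace

// [[Rcpp::export(name = ".sim_genealogy_cpp")]]
List sim_genealogy_cpp(IntegerVector sampleSizes, NumericVector Ne, NumericMatrix events) {
  std::vector<int> ss(sampleSizes.begin(), sampleSizes.end());
  std::vector<double> ne(Ne.begin(), Ne.end());
  Genealogy g = simulate_genealogy_core(ss, ne, events);
  IntegerVector tipPop(g.n);
  {
    int id = 0;
    for (size_t p = 0; p < ss.size(); ++p)
      for (int i = 0; i < ss[p]; ++i) tipPop[id++] = (int) p;
  }
  return List::create(_["parent"] = IntegerVector(g.parent.begin(), g.parent.end()),
                      _["time"]   = NumericVector(g.time.begin(), g.time.end()),
                      _["tipPop"] = tipPop,
                      _["n"]      = g.n);
}

// [[Rcpp::export(name = ".sim_alignment_cpp")]]
IntegerMatrix sim_alignment_cpp(IntegerVector sampleSizes, NumericVector Ne,
                                NumericMatrix events, int L, double mu) {
  if (L < 1) stop("L must be >= 1");
  if (mu < 0) stop("mu must be >= 0");
  std::vector<int> ss(sampleSizes.begin(), sampleSizes.end());
  std::vector<double> ne(Ne.begin(), Ne.end());
  Genealogy g = simulate_genealogy_core(ss, ne, events);
  IntegerMatrix seqs(L, g.n);
  evolve_core(g, L, mu, INTEGER(seqs));
  return seqs;
}

// [[Rcpp::export(name = ".evolve_sequences_cpp")]]
IntegerMatrix evolve_sequences_cpp(IntegerVector parent, NumericVector time,
                                   int ntips, int L, double mu) {
  if (L < 1) stop("L must be >= 1");
  if (mu < 0) stop("mu must be >= 0");
  Genealogy g;
  g.n = ntips;
  g.parent.assign(parent.begin(), parent.end());
  g.time.assign(time.begin(), time.end());
  if ((int) g.parent.size() != 2 * ntips - 1) stop("parent must have length 2*ntips-1");
  IntegerMatrix seqs(L, ntips);
  evolve_core(g, L, mu, INTEGER(seqs));
  return seqs;
}

// [[Rcpp::export(name = ".seq_stats_cpp")]]
NumericVector seq_stats_cpp(IntegerMatrix seqs, IntegerVector pop, int P) {
  const int L = seqs.nrow(), n = seqs.ncol();
  if ((int) pop.size() != n) stop("pop must have one entry per individual");
  std::vector<int> pv(pop.begin(), pop.end());
  NumericVector out(n_stats(P));
  compute_stats_core(INTEGER(seqs), L, n, pv, P, REAL(out));
  return out;
}

// Draw parameters from independent uniform priors, simulate, summarize.
// eventTemplate columns (time, type, a, b): for resize rows b is a 0-based
// index into the drawn parameter vector; merge rows use b as the target pop.
// Initial Ne of sampled population p is parameter p.
// [[Rcpp::export(name = ".sim_stats_batch_cpp")]]
List sim_stats_batch_cpp(int nsim, IntegerVector sampleSizes, NumericMatrix eventTemplate,
                         NumericVector lower, NumericVector upper, int L, double mu) {
  const int P = sampleSizes.size();
  const int npar = lower.size();
  if (upper.size() != npar) stop("prior bound length mismatch");
  if (npar < P) stop("need at least one Ne parameter per sampled population");
  std::vector<int> ss(sampleSizes.begin(), sampleSizes.end());
  int n = 0;
  for (int p = 0; p < P; ++p) n += ss[p];
  std::vector<int> pop(n);
  {
    int id = 0;
    for (int p = 0; p < P; ++p)
      for (int i = 0; i < ss[p]; ++i) pop[id++] = p;
  }
  const int ns = n_stats(P);
  NumericMatrix params(nsim, npar), stats(nsim, ns);
  std::vector<int> seqbuf((size_t) L * n);
  std::vector<double> tmp(ns), par(npar), ne(P);
  NumericMatrix evn(clone(eventTemplate));
  for (int r = 0; r < nsim; ++r) {
    if ((r & 1023) == 0) Rcpp::checkUserInterrupt();
    for (int q = 0; q < npar; ++q) {
      par[q] = lower[q] + unif_rand() * (upper[q] - lower[q]);
      params(r, q) = par[q];
    }
    for (int p = 0; p < P; ++p) ne[p] = par[p];
    for (int e = 0; e < eventTemplate.nrow(); ++e) {
      if ((int) eventTemplate(e, 1) == 1) {
        const int idx = (int) eventTemplate(e, 3);
        if (idx < 0 || idx >= npar) stop("resize parameter index out of range");
        evn(e, 3) = par[idx];
      } else {
        evn(e, 3) = eventTemplate(e, 3);
      }
    }
    Genealogy g = simulate_genealogy_core(ss, ne, evn);
    evolve_core(g, L, mu, seqbuf.data());
    compute_stats_core(seqbuf.data(), L, n, pop, P, tmp.data());
    for (int c = 0; c < ns; ++c) stats(r, c) = tmp[c];
  }
  return List::create(_["params"] = params, _["stats"] = stats);
}
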