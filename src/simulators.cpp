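// Simulation cores: pairwise SMC' in natural time, multi-sample SMC' through
// the selfing time rescaling, a forward Wright-Fisher oracle with explicit
// selfing, and a hot loop for LD-decay. All randomness comes from R's RNG so
// set.seed() governs every simulator.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Piecewise-constant demographic model in natural time (generations b.p.).
// Epoch columns: start_time, N, sigma, rec_rate. F = sigma/(2-sigma),
// pairwise coalescence rate lambda = (1+F)/(2N), effective pair
// recombination hazard density h = 2 r (1-F).
// ---------------------------------------------------------------------------
struct PwModel {
  std::vector<double> t0, N, sigma, r, F, lam, h, Hc;
  int k;
};

static PwModel make_model(const NumericMatrix &ep) {
  PwModel m;
  m.k = ep.nrow();
  for (int i = 0; i < m.k; ++i) {
    m.t0.push_back(ep(i, 0));
    m.N.push_back(ep(i, 1));
    m.sigma.push_back(ep(i, 2));
    m.r.push_back(ep(i, 3));
    double F = ep(i, 2) / (2.0 - ep(i, 2));
    m.F.push_back(F);
    m.lam.push_back((1.0 + F) / (2.0 * ep(i, 1)));
    m.h.push_back(2.0 * ep(i, 3) * (1.0 - F));
  }
  m.Hc.assign(m.k, 0.0);
  for (int i = 1; i < m.k; ++i)
    m.Hc[i] = m.Hc[i - 1] + m.h[i - 1] * (m.t0[i] - m.t0[i - 1]);
  return m;
}

static int epoch_at(const PwModel &m, double t) {
  int e = 0;
  while (e + 1 < m.k && m.t0[e + 1] <= t) ++e;
  return e;
}

static double Hint(const PwModel &m, double s) {
  int e = epoch_at(m, s);
  return m.Hc[e] + m.h[e] * (s - m.t0[e]);
}

// inverse of the cumulative pair recombination hazard (valid for H inside the
// support of the density, i.e. where some epoch has h > 0)
static double Hinv(const PwModel &m, double H) {
  int e = 0;
  while (e + 1 < m.k && m.Hc[e + 1] < H) ++e;
  while (m.h[e] <= 0.0 && e + 1 < m.k) ++e; // skip zero-density epochs
  return m.t0[e] + (H - m.Hc[e]) / m.h[e];
}

// first event time after `start` for an inhomogeneous Poisson process with
// rate mult * lambda(t)
static double draw_rate_time(const PwModel &m, double start, double mult) {
  double E = exp_rand();
  int e = epoch_at(m, start);
  double t = start;
  for (;;) {
    double rate = mult * m.lam[e];
    double tend = (e + 1 < m.k) ? m.t0[e + 1] : R_PosInf;
    if (rate > 0.0) {
      double need = E / rate;
      if (t + need < tend) return t + need;
      E -= rate * (tend - t);
    }
    if (e + 1 >= m.k) return R_PosInf; // unreachable: lambda > 0 everywhere
    t = tend;
    ++e;
  }
}

// floor continuous breakpoints to integer bp, drop empty pieces, merge
// adjacent equal ages
static NumericMatrix finish_segments(const std::vector<double> &bs,
                                     const std::vector<double> &be,
                                     const std::vector<double> &bt,
                                     double L) {
  std::vector<double> s2, e2, t2;
  for (size_t i = 0; i < bs.size(); ++i) {
    double a = std::floor(bs[i]), b = std::floor(be[i]);
    if (i + 1 == bs.size()) b = L;
    if (b <= a) continue;
    if (!t2.empty() && t2.back() == bt[i] && e2.back() == a) {
      e2.back() = b;
    } else {
      s2.push_back(a);
      e2.push_back(b);
      t2.push_back(bt[i]);
    }
  }
  NumericMatrix out(t2.size(), 3);
  for (size_t i = 0; i < t2.size(); ++i) {
    out(i, 0) = s2[i];
    out(i, 1) = e2[i];
    out(i, 2) = t2[i];
  }
  colnames(out) = CharacterVector::create("start", "end", "tmrca");
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_simulate_pair(NumericMatrix epochs, double L) {
  PwModel m = make_model(epochs);
  std::vector<double> bs, be, bt;
  double s = draw_rate_time(m, 0.0, 1.0);
  double pos = 0.0, segstart = 0.0;
  for (;;) {
    double Hs = Hint(m, s);
    double d = (Hs > 0.0) ? exp_rand() / Hs : R_PosInf;
    if (pos + d >= L) {
      bs.push_back(segstart);
      be.push_back(L);
      bt.push_back(s);
      break;
    }
    pos += d;
    // breakpoint: detachment height u with density proportional to h(u)
    double u = Hinv(m, unif_rand() * Hs);
    // floating lineage below the current MRCA: two partner branches, so rate
    // 2*lambda; half of those events re-join the detached lineage's own
    // branch and are silent
    double w = draw_rate_time(m, u, 2.0);
    double news = s;
    if (w < s) {
      if (unif_rand() < 0.5) news = w; // joined the other branch
    } else {
      news = draw_rate_time(m, s, 1.0); // root lineage above s
    }
    if (news != s) {
      bs.push_back(segstart);
      be.push_back(pos);
      bt.push_back(s);
      segstart = pos;
      s = news;
    }
  }
  return finish_segments(bs, be, bt, L);
}

// ---------------------------------------------------------------------------
// Multi-sample SMC' in rescaled time tau with dtau = (1-F(t)) dt. In tau the
// per-lineage per-bp recombination rate is the raw r of the epoch, the
// pairwise coalescence rate is 1/(2*Ntilde) with
// Ntilde = N (1-F)/(1+F), and branch lengths mapped back to natural time
// carry mutations at the plain rate mu.
// ---------------------------------------------------------------------------
struct TauModel {
  std::vector<double> tau0, t0, oneF, pr, r, Rc;
  int k;
  int epoch(double tau) const {
    int e = 0;
    while (e + 1 < k && tau0[e + 1] <= tau) ++e;
    return e;
  }
  double t_of_tau(double tau) const {
    int e = epoch(tau);
    return t0[e] + (tau - tau0[e]) / oneF[e];
  }
  double Rint(double tau) const {
    int e = epoch(tau);
    return Rc[e] + r[e] * (tau - tau0[e]);
  }
  double Rinv(double R) const {
    int e = 0;
    while (e + 1 < k && Rc[e + 1] < R) ++e;
    while (r[e] <= 0.0 && e + 1 < k) ++e;
    return tau0[e] + (R - Rc[e]) / r[e];
  }
};

static TauModel make_tau_model(const NumericMatrix &ep) {
  TauModel m;
  m.k = ep.nrow();
  double tau = 0.0;
  for (int i = 0; i < m.k; ++i) {
    double F = ep(i, 2) / (2.0 - ep(i, 2));
    double oneF = 1.0 - F;
    if (i > 0) tau += (ep(i, 0) - ep(i - 1, 0)) * m.oneF[i - 1];
    m.tau0.push_back(i == 0 ? 0.0 : tau);
    m.t0.push_back(ep(i, 0));
    m.oneF.push_back(oneF);
    double Ntil = ep(i, 1) * oneF / (1.0 + F);
    m.pr.push_back(1.0 / (2.0 * Ntil));
    m.r.push_back(ep(i, 3));
  }
  m.Rc.assign(m.k, 0.0);
  for (int i = 1; i < m.k; ++i)
    m.Rc[i] = m.Rc[i - 1] + m.r[i - 1] * (m.tau0[i] - m.tau0[i - 1]);
  return m;
}

// first event after `start` (in tau) with rate mult * pr(tau)
static double draw_tau_rate_time(const TauModel &m, double start, double mult) {
  double E = exp_rand();
  int e = m.epoch(start);
  double tau = start;
  for (;;) {
    double rate = mult * m.pr[e];
    double tend = (e + 1 < m.k) ? m.tau0[e + 1] : R_PosInf;
    double need = E / rate;
    if (tau + need < tend) return tau + need;
    E -= rate * (tend - tau);
    if (e + 1 >= m.k) return R_PosInf;
    tau = tend;
    ++e;
  }
}

struct LocalTree {
  int n, root;
  std::vector<int> parent, child1, child2;
  std::vector<double> time; // node heights in tau
  LocalTree(int n_) : n(n_), root(-1), parent(2 * n_ - 1, -1),
                      child1(2 * n_ - 1, -1), child2(2 * n_ - 1, -1),
                      time(2 * n_ - 1, 0.0) {}
};

// coalescence height for the floating lineage started at height u: rate at
// tau is B(tau) * pr(tau) where B(tau) = n - #internal nodes at or below tau
// (which is 1 above the root and stays there)
static double draw_float_height(const TauModel &m, const LocalTree &T,
                                double u) {
  std::vector<double> nt;
  nt.reserve(T.n - 1);
  for (int v = T.n; v < 2 * T.n - 1; ++v) nt.push_back(T.time[v]);
  std::sort(nt.begin(), nt.end());
  double E = exp_rand();
  double tau = u;
  size_t idx = std::upper_bound(nt.begin(), nt.end(), u) - nt.begin();
  int e = m.epoch(u);
  for (;;) {
    int B = T.n - (int)idx;
    if (B < 1) B = 1;
    double tend_node = (idx < nt.size()) ? nt[idx] : R_PosInf;
    double tend_ep = (e + 1 < m.k) ? m.tau0[e + 1] : R_PosInf;
    double tend = std::min(tend_node, tend_ep);
    double rate = B * m.pr[e];
    double need = E / rate;
    if (tau + need < tend) return tau + need;
    if (std::isinf(tend)) return tau + need; // top stratum: rate constant
    E -= rate * (tend - tau);
    tau = tend;
    if (tend == tend_node && idx < nt.size()) ++idx;
    if (tend == tend_ep && e + 1 < m.k) ++e;
  }
}

// [[Rcpp::export]]
List cpp_simulate_sample(NumericMatrix epochs, int n, double L, double mu,
                         IntegerMatrix pairs) {
  if (n < 2 || n > 64) stop("n must be between 2 and 64");
  TauModel m = make_tau_model(epochs);
  LocalTree T(n);

  // initial coalescent tree at position 0
  {
    std::vector<int> active(n);
    for (int i = 0; i < n; ++i) active[i] = i;
    int nxt = n;
    double tau = 0.0;
    while ((int)active.size() > 1) {
      int k = active.size();
      double mult = k * (k - 1) / 2.0;
      tau = draw_tau_rate_time(m, tau, mult);
      int i = (int)std::floor(unif_rand() * k);
      int j = (int)std::floor(unif_rand() * (k - 1));
      if (j >= i) ++j;
      int a = active[i], b = active[j];
      T.parent[a] = nxt;
      T.parent[b] = nxt;
      T.child1[nxt] = a;
      T.child2[nxt] = b;
      T.time[nxt] = tau;
      if (i > j) std::swap(i, j);
      active[i] = nxt;
      active.erase(active.begin() + j);
      ++nxt;
    }
    T.root = active[0];
    T.parent[T.root] = -1;
  }

  int npairs = pairs.nrow();
  std::vector<std::vector<double>> pr_s(npairs), pr_e(npairs), pr_t(npairs);
  std::vector<double> cur_mrca(npairs, -1.0);
  std::vector<double> run_start(npairs, 0.0);

  std::vector<double> mut_pos;
  std::vector<uint64_t> mut_mask;

  std::vector<double> rlen(2 * n - 1), wts(2 * n - 1);
  std::vector<uint64_t> leaf(2 * n - 1);
  std::vector<int> order(2 * n - 1);
  std::vector<long> anc_mark(2 * n - 1, -1);
  long mrca_stamp = 0;

  // per-tree precomputation: post-order leaf masks, natural-time branch
  // lengths, recombination weights in tau
  long n_trees = 0;
  auto prep_tree = [&](double &Wtot, double &Ltot) {
    // topological order by height (leaves first)
    int cnt = 0;
    for (int v = 0; v < 2 * n - 1; ++v) order[cnt++] = v;
    std::sort(order.begin(), order.end(), [&](int a, int b) {
      return T.time[a] < T.time[b];
    });
    Wtot = 0.0;
    Ltot = 0.0;
    for (int ii = 0; ii < 2 * n - 1; ++ii) {
      int v = order[ii];
      leaf[v] = (v < n) ? (uint64_t(1) << v) : (leaf[T.child1[v]] | leaf[T.child2[v]]);
      if (v == T.root) {
        rlen[v] = 0.0;
        wts[v] = 0.0;
      } else {
        int p = T.parent[v];
        rlen[v] = m.t_of_tau(T.time[p]) - m.t_of_tau(T.time[v]);
        wts[v] = m.Rint(T.time[p]) - m.Rint(T.time[v]);
        Ltot += rlen[v];
        Wtot += wts[v];
      }
    }
  };

  auto pair_mrca = [&](int i, int j) {
    ++mrca_stamp;
    int v = i;
    while (v != -1) {
      anc_mark[v] = mrca_stamp;
      v = T.parent[v];
    }
    v = j;
    while (anc_mark[v] != mrca_stamp) v = T.parent[v];
    return m.t_of_tau(T.time[v]);
  };

  auto emit_segment = [&](double a, double b, double Ltot) {
    if (b <= a) return;
    // mutations
    if (mu > 0.0 && Ltot > 0.0) {
      int nm = (int)R::rpois(mu * Ltot * (b - a));
      for (int q = 0; q < nm; ++q) {
        double z = unif_rand() * Ltot, acc = 0.0;
        int v = 0;
        for (int w = 0; w < 2 * n - 1; ++w) {
          acc += rlen[w];
          if (z <= acc) { v = w; break; }
        }
        mut_pos.push_back(a + unif_rand() * (b - a));
        mut_mask.push_back(leaf[v]);
      }
    }
    // tracked pair runs
    for (int p = 0; p < npairs; ++p) {
      double tm = pair_mrca(pairs(p, 0), pairs(p, 1));
      if (cur_mrca[p] < 0.0) {
        cur_mrca[p] = tm;
        run_start[p] = a;
      } else if (tm != cur_mrca[p]) {
        pr_s[p].push_back(run_start[p]);
        pr_e[p].push_back(a);
        pr_t[p].push_back(cur_mrca[p]);
        cur_mrca[p] = tm;
        run_start[p] = a;
      }
    }
  };

  double Wtot, Ltot;
  prep_tree(Wtot, Ltot);
  ++n_trees;
  double pos = 0.0, segstart = 0.0;
  for (;;) {
    double d = (Wtot > 0.0) ? exp_rand() / Wtot : R_PosInf;
    if (pos + d >= L) {
      emit_segment(segstart, L, Ltot);
      break;
    }
    pos += d;
    // pick recombination point (branch c, height u) with density r(tau) dtau
    double z = unif_rand() * Wtot, acc = 0.0;
    int c = -1;
    for (int v = 0; v < 2 * n - 1; ++v) {
      if (v == T.root) continue;
      acc += wts[v];
      if (z <= acc) { c = v; break; }
    }
    if (c < 0) continue; // numerical corner
    double lowR = m.Rint(T.time[c]);
    double u = m.Rinv(lowR + unif_rand() * wts[c]);
    // coalescence height of the floating lineage
    double w = draw_float_height(m, T, u);
    // choose target branch uniformly among branches crossing w
    int B = 0;
    for (int v = 0; v < 2 * n - 1; ++v) {
      if (v == T.root) continue;
      if (T.time[v] <= w && w < T.time[T.parent[v]]) ++B;
    }
    bool above_root = (w >= T.time[T.root]);
    if (above_root) B = 1;
    int pick = (int)std::floor(unif_rand() * B);
    int tv = -1;
    if (!above_root) {
      int seen = 0;
      for (int v = 0; v < 2 * n - 1; ++v) {
        if (v == T.root) continue;
        if (T.time[v] <= w && w < T.time[T.parent[v]]) {
          if (seen == pick) { tv = v; break; }
          ++seen;
        }
      }
    }
    if (tv == c) continue; // silent back-coalescence: tree unchanged
    // consequential event: close the segment under the old tree
    emit_segment(segstart, pos, Ltot);
    segstart = pos;
    // subtree prune and regraft
    int p = T.parent[c];
    int q = (T.child1[p] == c) ? T.child2[p] : T.child1[p];
    int pp = T.parent[p];
    if (pp >= 0) {
      if (T.child1[pp] == p) T.child1[pp] = q; else T.child2[pp] = q;
      T.parent[q] = pp;
    } else {
      T.root = q;
      T.parent[q] = -1;
    }
    if (tv == p) tv = q;
    if (tv == -1) tv = T.root;
    int pv = T.parent[tv];
    int x = p; // reuse the removed node
    T.time[x] = w;
    T.child1[x] = c;
    T.child2[x] = tv;
    T.parent[c] = x;
    T.parent[tv] = x;
    if (pv < 0) {
      T.parent[x] = -1;
      T.root = x;
    } else {
      if (T.child1[pv] == tv) T.child1[pv] = x; else T.child2[pv] = x;
      T.parent[x] = pv;
    }
    prep_tree(Wtot, Ltot);
    ++n_trees;
  }

  // close pair runs
  for (int p = 0; p < npairs; ++p) {
    if (cur_mrca[p] >= 0.0) {
      pr_s[p].push_back(run_start[p]);
      pr_e[p].push_back(L);
      pr_t[p].push_back(cur_mrca[p]);
    }
  }

  // assemble the alignment: sort, floor, drop integer collisions
  int S = mut_pos.size();
  std::vector<int> sidx(S);
  for (int i = 0; i < S; ++i) sidx[i] = i;
  std::sort(sidx.begin(), sidx.end(), [&](int a, int b) {
    return mut_pos[a] < mut_pos[b];
  });
  std::vector<int> keep;
  keep.reserve(S);
  int last = -1;
  for (int i = 0; i < S; ++i) {
    int ip = (int)std::floor(mut_pos[sidx[i]]);
    if (ip == last) continue;
    last = ip;
    keep.push_back(sidx[i]);
  }
  int S2 = keep.size();
  IntegerVector positions(S2);
  IntegerMatrix geno(n, S2);
  for (int j = 0; j < S2; ++j) {
    positions[j] = (int)std::floor(mut_pos[keep[j]]);
    uint64_t msk = mut_mask[keep[j]];
    for (int i = 0; i < n; ++i)
      geno(i, j) = (msk >> i) & 1 ? 1 : 0;
  }

  List pairsegs(npairs);
  for (int p = 0; p < npairs; ++p) {
    NumericMatrix sm = finish_segments(pr_s[p], pr_e[p], pr_t[p], L);
    pairsegs[p] = sm;
  }
  return List::create(_["positions"] = positions, _["geno"] = geno,
                      _["pair_segments"] = pairsegs,
                      _["n_trees"] = (double)n_trees);
}

// ---------------------------------------------------------------------------
// Forward Wright-Fisher oracle with explicit selfing. Diploid individuals;
// each offspring selfs with probability sigma(t) else outcrosses between two
// distinct parents; meiosis with crossovers at rate r(t) per bp. Genealogies
// of sampled chromosome pairs are traced back through the stored pedigree.
// ---------------------------------------------------------------------------
struct Meiosis {
  int parent;
  uint8_t phase0;
  uint32_t xo_begin, xo_end; // into per-generation crossover pool
};

// [[Rcpp::export]]
List cpp_wf_oracle(NumericMatrix epochs, int n_sample, double L, double mu,
                   int generations, IntegerMatrix pairs, bool within) {
  PwModel m = make_model(epochs);
  int G = generations;
  auto N_at_gen = [&](int g) {
    double tb = (double)(G - g);
    return (int)std::lround(m.N[epoch_at(m, tb)]);
  };
  auto sigma_at_gen = [&](int g) {
    double tb = (double)(G - g);
    return m.sigma[epoch_at(m, tb)];
  };
  auto r_at_gen = [&](int g) {
    double tb = (double)(G - g);
    return m.r[epoch_at(m, tb)];
  };

  std::vector<std::vector<Meiosis>> hist(G + 1);
  std::vector<std::vector<double>> xo(G + 1);

  bool track_mut = (mu > 0.0);
  std::vector<std::vector<double>> mut_prev, mut_cur;
  if (track_mut) mut_prev.assign(2 * N_at_gen(0), std::vector<double>());

  for (int g = 1; g <= G; ++g) {
    int Np = N_at_gen(g - 1), Nc = N_at_gen(g);
    double sg = sigma_at_gen(g), rg = r_at_gen(g);
    hist[g].resize(2 * Nc);
    if (track_mut) mut_cur.assign(2 * Nc, std::vector<double>());
    for (int i = 0; i < Nc; ++i) {
      int p1 = (int)std::floor(unif_rand() * Np);
      int p2;
      if (unif_rand() < sg || Np == 1) {
        p2 = p1;
      } else {
        do { p2 = (int)std::floor(unif_rand() * Np); } while (p2 == p1);
      }
      int par[2] = {p1, p2};
      for (int hpl = 0; hpl < 2; ++hpl) {
        Meiosis rec;
        rec.parent = par[hpl];
        rec.phase0 = (uint8_t)(unif_rand() < 0.5 ? 0 : 1);
        rec.xo_begin = (uint32_t)xo[g].size();
        int nxo = (int)R::rpois(rg * L);
        std::vector<double> cx(nxo);
        for (int q = 0; q < nxo; ++q) cx[q] = unif_rand() * L;
        std::sort(cx.begin(), cx.end());
        for (double v : cx) xo[g].push_back(v);
        rec.xo_end = (uint32_t)xo[g].size();
        hist[g][2 * i + hpl] = rec;
        if (track_mut) {
          // inherit mutations through the crossover mosaic
          std::vector<double> &dst = mut_cur[2 * i + hpl];
          double a = 0.0;
          int phase = rec.phase0;
          size_t ci = rec.xo_begin;
          while (a < L) {
            double b = (ci < rec.xo_end) ? xo[g][ci] : L;
            const std::vector<double> &src = mut_prev[2 * rec.parent + phase];
            auto lo = std::lower_bound(src.begin(), src.end(), a);
            auto hi = std::lower_bound(src.begin(), src.end(), b);
            dst.insert(dst.end(), lo, hi);
            a = b;
            phase ^= 1;
            ++ci;
          }
          int nm = (int)R::rpois(mu * L);
          for (int q = 0; q < nm; ++q) dst.push_back(unif_rand() * L);
          std::sort(dst.begin(), dst.end());
        }
      }
    }
    if (track_mut) mut_prev.swap(mut_cur);
  }

  // sample chromosomes at the present generation
  int Nfin = N_at_gen(G);
  std::vector<int> chrom_ids;
  std::vector<int> ind_ids;
  if (within) {
    int nind = n_sample / 2;
    if (nind > Nfin) stop("not enough individuals");
    std::vector<int> pool(Nfin);
    for (int i = 0; i < Nfin; ++i) pool[i] = i;
    for (int i = 0; i < nind; ++i) {
      int j = i + (int)std::floor(unif_rand() * (Nfin - i));
      std::swap(pool[i], pool[j]);
      chrom_ids.push_back(2 * pool[i]);
      chrom_ids.push_back(2 * pool[i] + 1);
      ind_ids.push_back(pool[i]);
      ind_ids.push_back(pool[i]);
    }
  } else {
    if (n_sample > Nfin) stop("not enough individuals");
    std::vector<int> pool(Nfin);
    for (int i = 0; i < Nfin; ++i) pool[i] = i;
    for (int i = 0; i < n_sample; ++i) {
      int j = i + (int)std::floor(unif_rand() * (Nfin - i));
      std::swap(pool[i], pool[j]);
      chrom_ids.push_back(2 * pool[i] + (unif_rand() < 0.5 ? 0 : 1));
      ind_ids.push_back(pool[i]);
    }
  }

  struct Seg { double a, b; int id; };
  auto map_back = [&](std::vector<Seg> &line, int g) {
    std::vector<Seg> out;
    out.reserve(line.size());
    for (const Seg &sg : line) {
      const Meiosis &rec = hist[g][sg.id];
      double a = sg.a;
      int phase = rec.phase0;
      size_t ci = rec.xo_begin;
      // advance crossovers below a
      while (ci < rec.xo_end && xo[g][ci] <= a) {
        phase ^= 1;
        ++ci;
      }
      while (a < sg.b) {
        double b = (ci < rec.xo_end) ? std::min((double)xo[g][ci], sg.b) : sg.b;
        if (b > a) out.push_back({a, b, 2 * rec.parent + phase});
        a = b;
        if (ci < rec.xo_end && xo[g][ci] <= a + 0.0) {
          if (xo[g][ci] <= a) { phase ^= 1; ++ci; }
        }
      }
    }
    std::sort(out.begin(), out.end(), [](const Seg &x, const Seg &y) {
      return x.id < y.id || (x.id == y.id && x.a < y.a);
    });
    // merge contiguous same-id pieces
    std::vector<Seg> merged;
    for (const Seg &sg : out) {
      if (!merged.empty() && merged.back().id == sg.id &&
          merged.back().b == sg.a)
        merged.back().b = sg.b;
      else
        merged.push_back(sg);
    }
    return merged;
  };

  int npairs = pairs.nrow();
  List pairsegs(npairs);
  for (int p = 0; p < npairs; ++p) {
    std::vector<Seg> A{{0.0, L, chrom_ids[pairs(p, 0)]}};
    std::vector<Seg> B{{0.0, L, chrom_ids[pairs(p, 1)]}};
    std::vector<double> rs, re, rt;
    for (int g = G; g >= 1 && !A.empty() && !B.empty(); --g) {
      A = map_back(A, g);
      B = map_back(B, g);
      // intersect on shared chromosome ids
      std::vector<Seg> A2, B2;
      size_t ia = 0, ib = 0;
      std::vector<std::pair<double, double>> hits;
      for (const Seg &sa : A) {
        for (const Seg &sb : B) {
          if (sa.id == sb.id) {
            double lo = std::max(sa.a, sb.a), hi = std::min(sa.b, sb.b);
            if (hi > lo) {
              rs.push_back(lo);
              re.push_back(hi);
              rt.push_back((double)(G - g + 1));
              hits.push_back({lo, hi});
            }
          }
        }
      }
      if (!hits.empty()) {
        auto subtract = [&](std::vector<Seg> &line) {
          std::vector<Seg> nw;
          for (const Seg &sg : line) {
            std::vector<std::pair<double, double>> cuts;
            for (auto &h : hits) {
              double lo = std::max(sg.a, h.first), hi = std::min(sg.b, h.second);
              if (hi > lo) cuts.push_back({lo, hi});
            }
            std::sort(cuts.begin(), cuts.end());
            double a = sg.a;
            for (auto &cpt : cuts) {
              if (cpt.first > a) nw.push_back({a, cpt.first, sg.id});
              a = std::max(a, cpt.second);
            }
            if (a < sg.b) nw.push_back({a, sg.b, sg.id});
          }
          line.swap(nw);
        };
        subtract(A);
        subtract(B);
      }
    }
    // censored (uncoalesced at the founder generation) intervals get NA age
    for (const Seg &sg : A) {
      rs.push_back(sg.a);
      re.push_back(sg.b);
      rt.push_back(NA_REAL);
    }
    // sort by start and merge equal adjacent ages
    std::vector<int> idx(rs.size());
    for (size_t i = 0; i < idx.size(); ++i) idx[i] = i;
    std::sort(idx.begin(), idx.end(), [&](int x, int y) {
      return rs[x] < rs[y];
    });
    std::vector<double> s3, e3, t3;
    for (int iidx : idx) {
      s3.push_back(rs[iidx]);
      e3.push_back(re[iidx]);
      t3.push_back(rt[iidx]);
    }
    pairsegs[p] = finish_segments(s3, e3, t3, L);
  }

  // alignment from forward-tracked mutations
  IntegerVector positions(0);
  IntegerMatrix geno(chrom_ids.size(), 0);
  if (track_mut) {
    std::vector<double> allpos;
    for (int id : chrom_ids) {
      const std::vector<double> &v = mut_prev[id];
      allpos.insert(allpos.end(), v.begin(), v.end());
    }
    std::sort(allpos.begin(), allpos.end());
    allpos.erase(std::unique(allpos.begin(), allpos.end()), allpos.end());
    int nc = chrom_ids.size();
    std::vector<std::vector<int>> carr(allpos.size());
    for (int i = 0; i < nc; ++i) {
      for (double v : mut_prev[chrom_ids[i]]) {
        size_t j = std::lower_bound(allpos.begin(), allpos.end(), v) -
                   allpos.begin();
        carr[j].push_back(i);
      }
    }
    std::vector<int> keep;
    int lastip = -1;
    for (size_t j = 0; j < allpos.size(); ++j) {
      int cnt = carr[j].size();
      if (cnt == 0 || cnt == nc) continue; // fixed or absent in the sample
      int ip = (int)std::floor(allpos[j]);
      if (ip == lastip) continue;
      lastip = ip;
      keep.push_back(j);
    }
    positions = IntegerVector(keep.size());
    geno = IntegerMatrix(nc, keep.size());
    for (size_t q = 0; q < keep.size(); ++q) {
      positions[q] = (int)std::floor(allpos[keep[q]]);
      for (int i : carr[keep[q]]) geno(i, q) = 1;
    }
  }

  return List::create(_["positions"] = positions, _["geno"] = geno,
                      _["pair_segments"] = pairsegs,
                      _["individuals"] = wrap(ind_ids));
}

// ---------------------------------------------------------------------------
// LD decay: mean haplotype r^2 in physical-distance bins.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_ld_bins(IntegerMatrix geno, IntegerVector pos, IntegerVector sites,
                 NumericVector breaks, double max_pairs) {
  int S = sites.size(), nh = geno.nrow(), nb = breaks.size() - 1;
  NumericVector sums(nb), counts(nb);
  if (S < 2)
    return List::create(_["sums"] = sums, _["counts"] = counts);
  std::vector<double> freq(S);
  for (int i = 0; i < S; ++i) {
    int c = 0, col = sites[i];
    for (int h = 0; h < nh; ++h) c += geno(h, col);
    freq[i] = (double)c / nh;
  }
  double lo = breaks[0], hi = breaks[nb];
  auto add_pair = [&](int i, int j) {
    double d = std::fabs((double)(pos[sites[i]] - pos[sites[j]]));
    if (d < lo || d >= hi) return;
    int b = nb - 1;
    for (int q = 1; q <= nb; ++q)
      if (d < breaks[q]) { b = q - 1; break; }
    double pA = freq[i], pB = freq[j];
    double den = pA * (1 - pA) * pB * (1 - pB);
    if (den <= 0) return;
    int cAB = 0, ci = sites[i], cj = sites[j];
    for (int h = 0; h < nh; ++h) cAB += geno(h, ci) & geno(h, cj);
    double pAB = (double)cAB / nh;
    double D = pAB - pA * pB;
    sums[b] += D * D / den;
    counts[b] += 1.0;
  };
  double total = (double)S * (S - 1) / 2.0;
  if (total <= max_pairs) {
    for (int i = 0; i < S - 1; ++i)
      for (int j = i + 1; j < S; ++j) add_pair(i, j);
  } else {
    for (double t = 0; t < max_pairs; ++t) {
      int i = (int)std::floor(unif_rand() * S);
      int j = (int)std::floor(unif_rand() * (S - 1));
      if (j >= i) ++j;
      add_pair(std::min(i, j), std::max(i, j));
    }
  }
  return List::create(_["sums"] = sums, _["counts"] = counts);
}
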