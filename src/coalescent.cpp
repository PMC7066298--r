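#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Structured-coalescent engine shared by the expected-JAFS tally and the
// one-SNP-per-locus genotype simulator.
//
// Scaling conventions (standard two-population diffusion scaling):
//   * time in units of 2*Nref generations;
//   * deme of relative size nu: coalescence rate 1/nu per lineage pair;
//   * mig(a,b) = 2*Nref*m_ab = scaled rate of gene flow into deme a from
//     deme b forward in time; a lineage currently in deme a relocates to
//     deme b backward in time at rate mig(a,b)/2.
//
// Epochs are ordered backward in time.  Epoch e carries a `map` vector
// relabelling the demes of epoch e-1 into its own deme space (merges).
// The final epoch must guarantee coalescence (single deme, or positive
// migration connecting all demes); R-side constructors enforce this.
//
// A lineage's subtended tip set never changes between its birth (at a
// tip or a coalescence) and its death (next coalescence), so branch
// contributions are tallied once, at death, instead of per event; with
// per-deme lineage lists every event is then O(#demes), which keeps
// migration-heavy parameter corners fast.

struct Epoch {
  double duration;                        // Inf for the terminal epoch
  std::vector<double> sizes;              // relative deme sizes
  std::vector<std::vector<double> > bmig; // backward per-lineage rates M_ab/2
  std::vector<double> row_rate;           // total migration rate per lineage
  std::vector<int> map;                   // previous-epoch deme -> this deme
};

static std::vector<Epoch> parse_epochs(List epochs_r) {
  std::vector<Epoch> out;
  int ne = epochs_r.size();
  for (int e = 0; e < ne; ++e) {
    List ep = epochs_r[e];
    Epoch E;
    E.duration = as<double>(ep["duration"]);
    NumericVector sz = ep["sizes"];
    int D = sz.size();
    E.sizes.assign(sz.begin(), sz.end());
    NumericMatrix mg = ep["mig"];
    if (mg.nrow() != D || mg.ncol() != D)
      stop("epoch migration matrix does not match deme count");
    E.bmig.assign(D, std::vector<double>(D, 0.0));
    E.row_rate.assign(D, 0.0);
    for (int a = 0; a < D; ++a) {
      for (int b = 0; b < D; ++b) {
        if (a == b) continue;
        double r = mg(a, b) / 2.0;
        if (r < 0 || !R_FINITE(r)) stop("migration rates must be finite and >= 0");
        E.bmig[a][b] = r;
        E.row_rate[a] += r;
      }
      if (E.sizes[a] <= 0 || !R_FINITE(E.sizes[a]))
        stop("deme sizes must be finite and > 0");
    }
    IntegerVector mp = ep["map"];
    E.map.assign(mp.begin(), mp.end());
    out.push_back(E);
  }
  return out;
}

struct Lineage {
  int c1, c2;        // descendant tip counts in pop 1 / pop 2
  int set_id;        // descendant leaf-set index (SNP simulation), or -1
  double birth;      // time the lineage appeared
};

// Per-deme membership with O(1) insert/remove (swap with last).
struct DemeLists {
  std::vector<std::vector<int> > members;  // lineage ids per deme
  std::vector<int> pos;                    // position of lineage in its deme
  std::vector<int> deme;                   // deme of lineage

  void init(int n_lineages, int D, const std::vector<int> &start_deme) {
    members.assign(D, std::vector<int>());
    pos.assign(n_lineages, -1);
    deme.assign(n_lineages, -1);
    for (int i = 0; i < (int)start_deme.size(); ++i) add(i, start_deme[i]);
  }
  void add(int lin, int d) {
    deme[lin] = d;
    pos[lin] = members[d].size();
    members[d].push_back(lin);
  }
  void remove(int lin) {
    int d = deme[lin], p = pos[lin];
    int last = members[d].back();
    members[d][p] = last;
    pos[last] = p;
    members[d].pop_back();
    deme[lin] = -1;
  }
  void move(int lin, int to) { remove(lin); add(lin, to); }
  void remap(int n_slots, const std::vector<int> &mp, int D_new) {
    std::vector<int> cur_deme(deme);
    std::vector<int> alive;
    for (int i = 0; i < (int)deme.size(); ++i)
      if (deme[i] >= 0) alive.push_back(i);
    members.assign(D_new, std::vector<int>());
    for (size_t j = 0; j < alive.size(); ++j) {
      int i = alive[j];
      int d = mp[cur_deme[i]];
      deme[i] = d;
      pos[i] = members[d].size();
      members[d].push_back(i);
    }
  }
};

// Simulate one genealogy.  on_death(lineage_index, branch_length) fires
// for every lineage that coalesces (every branch of the tree); merging
// of tip-descendant bookkeeping is handled here, extra payload merging
// via on_merge(parent_slot, child_slot).
template <class DeathFn, class MergeFn>
static void simulate_genealogy(const std::vector<int> &sample_demes,
                               const std::vector<Epoch> &epochs,
                               std::vector<Lineage> &lin,
                               DeathFn on_death, MergeFn on_merge) {
  int n = sample_demes.size();
  int n_slots = 2 * n - 1;
  lin.resize(n_slots);
  DemeLists dl;
  dl.init(n_slots, epochs[0].sizes.size(), sample_demes);
  int k = n, next_slot = n;
  size_t ei = 0;
  double t = 0.0, epoch_end = epochs[0].duration;
  long guard = 0;

  while (k > 1) {
    const Epoch &E = epochs[ei];
    int D = E.sizes.size();
    double coal_tot = 0, mig_tot = 0;
    for (int d = 0; d < D; ++d) {
      double kd = dl.members[d].size();
      coal_tot += kd * (kd - 1) / 2.0 / E.sizes[d];
      mig_tot += kd * E.row_rate[d];
    }
    double rate = coal_tot + mig_tot;
    double dt = (rate > 0) ? exp_rand() / rate : R_PosInf;
    if (t + dt >= epoch_end) {
      if (!R_FINITE(epoch_end))
        stop("coalescent cannot complete: zero total rate in unbounded epoch");
      t = epoch_end;
      ei++;
      if (ei >= epochs.size())
        stop("ran out of epochs before coalescence completed");
      dl.remap(n_slots, epochs[ei].map, epochs[ei].sizes.size());
      epoch_end = (R_FINITE(epochs[ei].duration))
                      ? t + epochs[ei].duration : R_PosInf;
      continue;
    }
    t += dt;
    double u = unif_rand() * rate;
    bool done = false;
    for (int d = 0; d < D && !done; ++d) {
      double kd = dl.members[d].size();
      double cr = kd * (kd - 1) / 2.0 / E.sizes[d];
      if (u < cr) {
        int a = (int)(unif_rand() * kd);
        int b = (int)(unif_rand() * (kd - 1));
        if (b >= a) b++;
        int ia = dl.members[d][a], ib = dl.members[d][b];
        on_death(ia, t - lin[ia].birth);
        on_death(ib, t - lin[ib].birth);
        int ip = next_slot++;
        lin[ip].c1 = lin[ia].c1 + lin[ib].c1;
        lin[ip].c2 = lin[ia].c2 + lin[ib].c2;
        lin[ip].birth = t;
        lin[ip].set_id = -1;
        on_merge(ip, ia, ib);
        dl.remove(ia);
        dl.remove(ib);
        dl.add(ip, d);
        k--;
        done = true;
        break;
      }
      u -= cr;
      double mr = kd * E.row_rate[d];
      if (u < mr) {
        int a = (int)(unif_rand() * kd);
        int ia = dl.members[d][a];
        double v = unif_rand() * E.row_rate[d];
        int dest = -1;
        for (int b2 = 0; b2 < D; ++b2) {
          if (b2 == d) continue;
          v -= E.bmig[d][b2];
          if (v <= 0) { dest = b2; break; }
        }
        if (dest < 0) dest = (D - 1 == d) ? D - 2 : D - 1;
        dl.move(ia, dest);
        done = true;
        break;
      }
      u -= mr;
    }
    if (++guard > 2000000000L) stop("coalescent event guard exceeded");
  }
}

//' @noRd
// [[Rcpp::export(name = ".coal_expected_jafs_cpp")]]
List coal_expected_jafs_cpp(int n1, int n2, List epochs_r, int n_genealogies) {
  if (n1 < 1 || n2 < 1) stop("n1 and n2 must be >= 1");
  if (n_genealogies < 1) stop("n_genealogies must be >= 1");
  std::vector<Epoch> epochs = parse_epochs(epochs_r);
  int nc = (n1 + 1) * (n2 + 1);
  std::vector<double> tally(nc), sum(nc, 0.0), sumsq(nc, 0.0);
  std::vector<int> sample_demes(n1 + n2);
  for (int i = 0; i < n1; ++i) sample_demes[i] = 0;
  for (int i = 0; i < n2; ++i) sample_demes[n1 + i] = 1;
  std::vector<Lineage> lin;

  for (int g = 0; g < n_genealogies; ++g) {
    std::fill(tally.begin(), tally.end(), 0.0);
    lin.assign(2 * (n1 + n2) - 1, Lineage());
    for (int i = 0; i < n1 + n2; ++i) {
      lin[i].c1 = i < n1 ? 1 : 0;
      lin[i].c2 = i < n1 ? 0 : 1;
      lin[i].birth = 0.0;
      lin[i].set_id = -1;
    }
    simulate_genealogy(
        sample_demes, epochs, lin,
        [&](int i, double len) {
          tally[lin[i].c1 * (n2 + 1) + lin[i].c2] += len;
        },
        [](int, int, int) {});
    for (int c = 0; c < nc; ++c) {
      sum[c] += tally[c];
      sumsq[c] += tally[c] * tally[c];
    }
  }
  NumericMatrix mean(n1 + 1, n2 + 1), se(n1 + 1, n2 + 1);
  for (int i = 0; i <= n1; ++i)
    for (int j = 0; j <= n2; ++j) {
      int c = i * (n2 + 1) + j;
      double m = sum[c] / n_genealogies;
      mean(i, j) = m;
      double v = sumsq[c] / n_genealogies - m * m;
      if (v < 0) v = 0;
      se(i, j) = std::sqrt(v / n_genealogies);
    }
  return List::create(_["mean"] = mean, _["se"] = se);
}

//' @noRd
// [[Rcpp::export(name = ".coal_sim_snps_cpp")]]
IntegerMatrix coal_sim_snps_cpp(IntegerVector sample_demes_r, List epochs_r,
                                int n_loci) {
  if (n_loci < 1) stop("n_loci must be >= 1");
  std::vector<Epoch> epochs = parse_epochs(epochs_r);
  int n = sample_demes_r.size();
  std::vector<int> sample_demes(sample_demes_r.begin(), sample_demes_r.end());
  IntegerMatrix geno(n_loci, n);
  std::vector<Lineage> lin;
  std::vector<std::vector<int> > sets;  // descendant leaves per slot
  std::vector<int> chosen;

  for (int l = 0; l < n_loci; ++l) {
    int n_slots = 2 * n - 1;
    sets.assign(n_slots, std::vector<int>());
    lin.assign(n_slots, Lineage());
    for (int i = 0; i < n; ++i) {
      sets[i].push_back(i);
      lin[i].set_id = i;
      lin[i].c1 = lin[i].c2 = 0;
      lin[i].birth = 0.0;
    }
    double total_len = 0.0;
    chosen.clear();
    simulate_genealogy(
        sample_demes, epochs, lin,
        [&](int i, double len) {
          // stream-sample the mutation branch proportional to length
          total_len += len;
          if (unif_rand() < len / total_len) chosen = sets[i];
        },
        [&](int ip, int ia, int ib) {
          sets[ip] = sets[ia];
          sets[ip].insert(sets[ip].end(), sets[ib].begin(), sets[ib].end());
        });
    for (size_t i = 0; i < chosen.size(); ++i) geno(l, chosen[i]) = 1;
  }
  return geno;
}

// ---------------------------------------------------------------------------
// Independent forward-in-time validation simulator: per-site Wright-Fisher
// binomial frequency dynamics for two demes splitting from an ancestral
// population initialized at the neutral stationary spectrum (E[S_i] = theta/i
// sites at derived count i).  Used as an oracle for the coalescent engine,
// never as the likelihood backend.  Migration enters as the per-generation
// probability q12 (q21) that a deme-1 (deme-2) copy picks its parent from
// the other deme; q_ab = M_ab / (2 * N_anc).  Post-split phases run forward
// in time, oldest first.
// ---------------------------------------------------------------------------

//' @noRd
// [[Rcpp::export(name = ".wf_expected_jafs_cpp")]]
NumericMatrix wf_expected_jafs_cpp(double theta, int N_anc, int N1, int N2,
                                   NumericVector q12, NumericVector q21,
                                   IntegerVector t_gens,
                                   int n1, int n2, int extra_burnin) {
  if (theta <= 0) stop("theta must be > 0");
  if (N_anc < 2 || N1 < 1 || N2 < 1) stop("population sizes too small");
  if (q12.size() != t_gens.size() || q21.size() != t_gens.size())
    stop("phase vectors must have equal length");
  std::vector<int> x;  // ancestral-phase derived counts
  x.reserve((size_t)(theta * std::log((double)N_anc) * 1.3) + 64);
  for (int i = 1; i < N_anc; ++i) {
    int s = (int)R::rpois(theta / i);
    for (int j = 0; j < s; ++j) x.push_back(i);
  }
  double influx_anc = theta / 2.0;
  for (int g = 0; g < extra_burnin; ++g) {
    size_t w = 0;
    for (size_t s = 0; s < x.size(); ++s) {
      int nx = (int)R::rbinom((double)N_anc, (double)x[s] / N_anc);
      if (nx > 0 && nx < N_anc) x[w++] = nx;
    }
    x.resize(w);
    int nnew = (int)R::rpois(influx_anc);
    for (int j = 0; j < nnew; ++j) x.push_back(1);
  }
  // split
  std::vector<int> x1(x.size()), x2(x.size());
  size_t w = 0;
  for (size_t s = 0; s < x.size(); ++s) {
    double p = (double)x[s] / N_anc;
    int a = (int)R::rbinom((double)N1, p);
    int b = (int)R::rbinom((double)N2, p);
    if ((a > 0 || b > 0) && (a < N1 || b < N2)) { x1[w] = a; x2[w] = b; w++; }
  }
  x1.resize(w); x2.resize(w);
  double influx_split = theta / 2.0 * ((double)N1 + N2) / N_anc;
  double p_deme1 = (double)N1 / (N1 + N2);
  for (int ph = 0; ph < t_gens.size(); ++ph) {
    double qa = q12[ph], qb = q21[ph];
    for (int g = 0; g < t_gens[ph]; ++g) {
      size_t ww = 0;
      for (size_t s = 0; s < x1.size(); ++s) {
        double f1 = (double)x1[s] / N1, f2 = (double)x2[s] / N2;
        double p1 = (1.0 - qa) * f1 + qa * f2;
        double p2 = (1.0 - qb) * f2 + qb * f1;
        int a = (int)R::rbinom((double)N1, p1);
        int b = (int)R::rbinom((double)N2, p2);
        if ((a > 0 || b > 0) && (a < N1 || b < N2)) { x1[ww] = a; x2[ww] = b; ww++; }
      }
      x1.resize(ww); x2.resize(ww);
      int nnew = (int)R::rpois(influx_split);
      for (int j = 0; j < nnew; ++j) {
        if (unif_rand() < p_deme1) { x1.push_back(1); x2.push_back(0); }
        else { x1.push_back(0); x2.push_back(1); }
      }
    }
  }
  // project each surviving site to (n1, n2) by hypergeometric expectation
  NumericMatrix out(n1 + 1, n2 + 1);
  std::vector<double> h1(n1 + 1), h2(n2 + 1);
  for (size_t s = 0; s < x1.size(); ++s) {
    for (int i = 0; i <= n1; ++i)
      h1[i] = R::dhyper(i, x1[s], N1 - x1[s], n1, 0);
    for (int j = 0; j <= n2; ++j)
      h2[j] = R::dhyper(j, x2[s], N2 - x2[s], n2, 0);
    for (int i = 0; i <= n1; ++i) {
      if (h1[i] == 0) continue;
      for (int j = 0; j <= n2; ++j) out(i, j) += h1[i] * h2[j];
    }
  }
  return out;
}
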