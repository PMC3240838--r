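// Compiled simulation core: the generational loop at sweep scale.
// All randomness is drawn from R's RNG (unif_rand / norm_rand), so a run is
// fully reproducible from set.seed() in the calling R code.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

// Experience-update rule for the willingness to escalate.
inline double update_w(double w, double U, bool won) {
  if (U == 0.0) return w;
  double out;
  if (won) out = (U > 0.0) ? w + U * (1.0 - w) : w + U * w;
  else     out = (U > 0.0) ? w - U * w         : w - U * (1.0 - w);
  if (out < 0.0) out = 0.0;
  if (out > 1.0) out = 1.0;
  return out;
}

struct FightOut {
  bool i_wins;
  int length;
  bool forced_i, forced_j;
  bool cap;
};

// Sequential-assessment fight. Mutates the two fitness values (costs are
// charged every round, including the final one).
inline FightOut fight(double s_i, double s_j, double &F_i, double &F_j,
                      double T_i, double T_j, double sigma, int max_rounds) {
  const double c_i = std::exp(s_j - s_i);
  const double c_j = std::exp(s_i - s_j);
  const double ds = s_i - s_j;
  double d_i = 0.0, d_j = 0.0;
  int r = 0;
  bool give_i = false, give_j = false, forced_i = false, forced_j = false;
  bool cap = false;
  for (;;) {
    ++r;
    F_i -= c_i;
    F_j -= c_j;
    d_i -= ds + sigma * norm_rand();
    d_j -= -ds + sigma * norm_rand();
    forced_i = F_i < 0.0;
    forced_j = F_j < 0.0;
    give_i = (d_i > T_i) || forced_i;
    give_j = (d_j > T_j) || forced_j;
    if (give_i || give_j) break;
    if (r >= max_rounds) { cap = true; break; }
  }
  FightOut out;
  out.length = r;
  out.forced_i = forced_i;
  out.forced_j = forced_j;
  out.cap = cap;
  if (cap || (give_i && give_j)) out.i_wins = unif_rand() < 0.5;
  else out.i_wins = !give_i;
  return out;
}

inline int rand_below(int n) {  // uniform integer in [0, n)
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

}  // namespace

// [[Rcpp::export]]
List run_fight_cpp(double s_i, double s_j, double F_i, double F_j,
                   double T_i, double T_j, double sigma_eps,
                   int max_fight_rounds) {
  FightOut f = fight(s_i, s_j, F_i, F_j, T_i, T_j, sigma_eps,
                     max_fight_rounds);
  return List::create(
    _["i_wins"] = f.i_wins, _["length"] = f.length,
    _["forced_giveup_i"] = f.forced_i, _["forced_giveup_j"] = f.forced_j,
    _["cap_breached"] = f.cap,
    _["fitness_i"] = F_i, _["fitness_j"] = F_j);
}

// [[Rcpp::export]]
List sim_engine_cpp(int n_groups, int group_size, int n_rounds,
                    double benefit, double F0, double sigma_eps,
                    double mutation_prob,
                    NumericVector U0, NumericVector T0,
                    int n_generations, int max_fight_rounds,
                    double U_lo, double U_hi, double T_lo, double T_hi,
                    bool evolve, bool record_final) {
  const int gs = group_size;
  const int n = n_groups * gs;
  const int gs2 = gs * gs;
  if (U0.size() != n || T0.size() != n)
    stop("U0/T0 must have one entry per individual");

  std::vector<double> s(n), F(n, F0), U(n), T(n);
  std::vector<double> w((size_t)n_groups * gs2, 1.0);
  std::vector<char> dis(n, 0);
  for (int k = 0; k < n; ++k) {
    s[k] = unif_rand();
    U[k] = U0[k];
    T[k] = T0[k];
  }

  // dyad list (i < j), local indices within a group
  const int ndyads = gs * (gs - 1) / 2;
  std::vector<int> dy_i(ndyads), dy_j(ndyads);
  {
    int k = 0;
    for (int i = 0; i < gs - 1; ++i)
      for (int j = i + 1; j < gs; ++j) { dy_i[k] = i; dy_j[k] = j; ++k; }
  }
  std::vector<int> order(ndyads);

  // per-generation summaries
  std::vector<double> sm_U, sm_T, sm_F, sm_len;
  std::vector<int> sm_gen, sm_nf, sm_forced;
  sm_U.reserve(n_generations);

  // final-generation measurement layer
  std::vector<int> tall;
  std::vector<int> flens;
  std::vector<int> lg_round, lg_group, lg_i, lg_j, lg_winner, lg_flen;
  std::vector<char> lg_ei, lg_ej, lg_fought;
  if (record_final) tall.assign((size_t)n_groups * gs2, 0);

  long cap_breaches = 0;

  for (int gen = 1; gen <= n_generations; ++gen) {
    const bool final_gen = (gen == n_generations);
    const bool rec = record_final && final_gen;
    long n_fights = 0;
    double tot_len = 0.0;

    // ---- conflict phase ----
    for (int round = 1; round <= n_rounds; ++round) {
      for (int g = 0; g < n_groups; ++g) {
        const int base = g * gs;
        double *wg = &w[(size_t)g * gs2];
        // randomize dyad execution order
        for (int k = 0; k < ndyads; ++k) order[k] = k;
        for (int k = ndyads - 1; k > 0; --k) {
          int m = rand_below(k + 1);
          std::swap(order[k], order[m]);
        }
        for (int kk = 0; kk < ndyads; ++kk) {
          const int li = dy_i[order[kk]], lj = dy_j[order[kk]];
          const int i = base + li, j = base + lj;
          const bool esc_i = !dis[i] && (unif_rand() < wg[li * gs + lj]);
          const bool esc_j = !dis[j] && (unif_rand() < wg[lj * gs + li]);
          const bool fought = esc_i && esc_j;
          bool i_wins;
          int flen = 0;
          bool forced_i = false, forced_j = false;
          if (!esc_i && !esc_j) {
            i_wins = unif_rand() < 0.5;
          } else if (!fought) {
            i_wins = esc_i;
          } else {
            FightOut f = fight(s[i], s[j], F[i], F[j], T[i], T[j],
                               sigma_eps, max_fight_rounds);
            i_wins = f.i_wins;
            flen = f.length;
            forced_i = f.forced_i;
            forced_j = f.forced_j;
            if (f.cap) ++cap_breaches;
            ++n_fights;
            tot_len += flen;
          }
          F[i_wins ? i : j] += benefit;
          if (esc_i || esc_j) {
            // both updates use pre-conflict willingness and the own U
            if (!dis[i]) wg[li * gs + lj] =
              update_w(wg[li * gs + lj], U[i], i_wins);
            if (!dis[j]) wg[lj * gs + li] =
              update_w(wg[lj * gs + li], U[j], !i_wins);
          }
          // fitness floor: negative fitness disables all future escalation
          if (!dis[i] && (forced_i || F[i] < 0.0)) {
            dis[i] = 1;
            for (int m = 0; m < gs; ++m) wg[li * gs + m] = 0.0;
          }
          if (!dis[j] && (forced_j || F[j] < 0.0)) {
            dis[j] = 1;
            for (int m = 0; m < gs; ++m) wg[lj * gs + m] = 0.0;
          }
          if (rec) {
            if (esc_i || esc_j) {
              const int wi = i_wins ? li : lj, lo = i_wins ? lj : li;
              ++tall[(size_t)g * gs2 + wi + lo * gs];
            }
            if (fought) flens.push_back(flen);
            lg_round.push_back(round);
            lg_group.push_back(g + 1);
            lg_i.push_back(li + 1);
            lg_j.push_back(lj + 1);
            lg_ei.push_back(esc_i);
            lg_ej.push_back(esc_j);
            lg_fought.push_back(fought);
            lg_winner.push_back((i_wins ? li : lj) + 1);
            lg_flen.push_back(fought ? flen : NA_INTEGER);
          }
        }
      }
    }

    // ---- end-of-phase summary ----
    double mu = 0, mt = 0, mf = 0;
    int nforced = 0;
    for (int k = 0; k < n; ++k) {
      mu += U[k]; mt += T[k]; mf += F[k];
      if (dis[k]) ++nforced;
    }
    sm_gen.push_back(gen);
    sm_U.push_back(mu / n);
    sm_T.push_back(mt / n);
    sm_F.push_back(mf / n);
    sm_nf.push_back((int)n_fights);
    sm_len.push_back(n_fights > 0 ? tot_len / n_fights : NA_REAL);
    sm_forced.push_back(nforced);

    if (final_gen || !evolve) continue;

    // ---- reproduction (within natal group), death, migration ----
    std::vector<double> nU(n), nT(n), nS(n);
    std::vector<double> prob(gs);
    int off = 0;
    for (int g = 0; g < n_groups; ++g) {
      const int base = g * gs;
      double tot = 0.0;
      for (int k = 0; k < gs; ++k) {
        prob[k] = F[base + k] > 0.0 ? F[base + k] : 0.0;
        tot += prob[k];
      }
      for (int e = 0; e < gs; ++e) {
        int pick;
        if (tot <= 0.0) {
          pick = rand_below(gs);
        } else {
          double r = unif_rand() * tot, acc = 0.0;
          pick = gs - 1;
          for (int k = 0; k < gs; ++k) {
            acc += prob[k];
            if (r < acc) { pick = k; break; }
          }
        }
        const int p = base + pick;
        double u = U[p], t = T[p];
        if (unif_rand() < mutation_prob) {
          u = U_lo + unif_rand() * (U_hi - U_lo);
          t = T_lo + unif_rand() * (T_hi - T_lo);
        }
        nU[off] = u; nT[off] = t; nS[off] = unif_rand();
        ++off;
      }
    }
    // global uniform permutation of offspring into equal-size groups
    std::vector<int> perm(n);
    for (int k = 0; k < n; ++k) perm[k] = k;
    for (int k = n - 1; k > 0; --k) {
      int m = rand_below(k + 1);
      std::swap(perm[k], perm[m]);
    }
    for (int k = 0; k < n; ++k) {
      U[k] = nU[perm[k]]; T[k] = nT[perm[k]]; s[k] = nS[perm[k]];
      F[k] = F0;
      dis[k] = 0;
    }
    std::fill(w.begin(), w.end(), 1.0);
  }

  // ---- assemble output ----
  DataFrame summary = DataFrame::create(
    _["generation"] = sm_gen, _["mean_U"] = sm_U, _["mean_T"] = sm_T,
    _["mean_fitness"] = sm_F, _["n_fights"] = sm_nf,
    _["mean_fight_length"] = sm_len, _["n_forced_giveups"] = sm_forced);

  IntegerVector grp(n), idv(n);
  for (int g = 0; g < n_groups; ++g)
    for (int k = 0; k < gs; ++k) { grp[g * gs + k] = g + 1; idv[g * gs + k] = k + 1; }
  DataFrame individuals = DataFrame::create(
    _["group"] = grp, _["id"] = idv, _["s"] = NumericVector(s.begin(), s.end()),
    _["fitness"] = NumericVector(F.begin(), F.end()),
    _["U"] = NumericVector(U.begin(), U.end()),
    _["T"] = NumericVector(T.begin(), T.end()));

  List out = List::create(
    _["summary"] = summary, _["individuals"] = individuals,
    _["tallies"] = R_NilValue, _["fight_lengths"] = R_NilValue,
    _["conflict_log"] = R_NilValue,
    _["cap_breaches"] = (double)cap_breaches);

  if (record_final && n_generations > 0) {
    IntegerVector ta(tall.begin(), tall.end());
    ta.attr("dim") = IntegerVector::create(gs, gs, n_groups);
    out["tallies"] = ta;
    out["fight_lengths"] = IntegerVector(flens.begin(), flens.end());
    out["conflict_log"] = DataFrame::create(
      _["round"] = lg_round, _["group"] = lg_group,
      _["i"] = lg_i, _["j"] = lg_j,
      _["escalated_i"] = LogicalVector(lg_ei.begin(), lg_ei.end()),
      _["escalated_j"] = LogicalVector(lg_ej.begin(), lg_ej.end()),
      _["fought"] = LogicalVector(lg_fought.begin(), lg_fought.end()),
      _["winner"] = lg_winner, _["fight_length"] = lg_flen);
  }
  return out;
}
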