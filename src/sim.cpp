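// Core iteration loop of the chromatin micromodel.
//
// Each time-step, every histone of every block makes at most one
// modification change: its outgoing shift probabilities are modulated by the
// block's current DNA-methylation level (H3/H4 only) and one neighbour is
// drawn categorically.  Block ledgers, transcription intervals and the
// conditional methylation update follow.  Uses R's RNG (unif_rand) so runs
// are bit-reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct Space {
  int n;
  const int *ptr;   // length n + 1, 0-based offsets into nbr
  const int *nbr;   // 1-based neighbour state indices
  const int *bal;   // ace - met per state
  const int *ace;
  const int *met;
  const int *ph;
  bool modulated;   // methylation acts on H3/H4 only
};

} // namespace

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(IntegerVector block_type,   // 0 promoter, 1 gene, 2 other
              IntegerVector promoter_of,  // 1-based controlling promoter, 0 none
              List spaces,                // unique histone spaces
              IntegerVector slot_space,   // 1-based space id per histone slot
              List probs,                 // per slot: probs aligned with nbr
              IntegerMatrix state0,       // slots x blocks, 1-based
              NumericVector D0,
              LogicalVector pinned,
              double max_ace, double max_met,
              double k, double PT, double kappa, int m,
              double gate_frac, double block_thresh,
              int iterations, int record_every,
              bool keep_visits) {
  const int B = block_type.size();
  const int S = slot_space.size();

  std::vector<Space> sp(spaces.size());
  for (int i = 0; i < spaces.size(); ++i) {
    List L = spaces[i];
    IntegerVector ptr = L["ptr"], nbr = L["nbr"], bal = L["bal"],
                  ace = L["ace"], met = L["met"], ph = L["ph"];
    sp[i].n = as<int>(L["n"]);
    sp[i].ptr = INTEGER(ptr);
    sp[i].nbr = nbr.size() ? INTEGER(nbr) : nullptr;
    sp[i].bal = INTEGER(bal);
    sp[i].ace = INTEGER(ace);
    sp[i].met = INTEGER(met);
    sp[i].ph = INTEGER(ph);
    sp[i].modulated = as<bool>(L["modulated"]);
  }
  std::vector<const double *> pr(S);
  for (int s = 0; s < S; ++s) {
    NumericVector v = probs[s];
    pr[s] = v.size() ? REAL(v) : nullptr;
  }

  IntegerMatrix state = clone(state0);
  NumericVector D = clone(D0);

  // block ledgers from the initial states
  std::vector<double> ace_tot(B, 0.0), met_tot(B, 0.0), ph_tot(B, 0.0);
  for (int b = 0; b < B; ++b)
    for (int s = 0; s < S; ++s) {
      const Space &sc = sp[slot_space[s] - 1];
      int a = state(s, b) - 1;
      ace_tot[b] += sc.ace[a];
      met_tot[b] += sc.met[a];
      ph_tot[b] += sc.ph[a];
    }

  List visits(S);
  std::vector<int *> vis(S, nullptr);
  if (keep_visits)
    for (int s = 0; s < S; ++s) {
      IntegerMatrix vm(sp[slot_space[s] - 1].n, B);
      visits[s] = vm;
      vis[s] = INTEGER(vm);
    }

  const int n_rec = record_every > 0 ? iterations / record_every : 0;
  const int n_int = m > 0 ? iterations / m : 0;
  NumericMatrix D_trace(n_rec, B), ace_trace(n_rec, B), met_trace(n_rec, B),
                ph_trace(n_rec, B), T_trace(n_int, B);

  std::vector<double> bal_acc(B, 0.0);
  std::vector<double> w;
  w.reserve(32);

  RNGScope scope;

  int rec_row = 0, int_row = 0;
  for (int t = 1; t <= iterations; ++t) {
    for (int b = 0; b < B; ++b) {
      const double Db = D[b];
      for (int s = 0; s < S; ++s) {
        const Space &sc = sp[slot_space[s] - 1];
        int a = state(s, b);
        const int off = sc.ptr[a - 1];
        const int deg = sc.ptr[a] - off;
        if (deg > 0) {
          const int bal_a = sc.bal[a - 1];
          double tot = 0.0;
          w.resize(deg);
          for (int j = 0; j < deg; ++j) {
            double p = pr[s][off + j];
            if (sc.modulated) {
              const int d = sc.bal[sc.nbr[off + j] - 1] - bal_a;
              if (d > 0) p *= 2.0 - Db / k;
              else if (d < 0) p *= Db / k;
              if (p < 0.0) p = 0.0; else if (p > 1.0) p = 1.0;
            }
            w[j] = p;
            tot += p;
          }
          if (tot > 0.0) {
            double u = unif_rand() * tot, cum = 0.0;
            int pick = deg - 1;
            for (int j = 0; j < deg; ++j) {
              cum += w[j];
              if (u < cum) { pick = j; break; }
            }
            const int nb = sc.nbr[off + pick];
            ace_tot[b] += sc.ace[nb - 1] - sc.ace[a - 1];
            met_tot[b] += sc.met[nb - 1] - sc.met[a - 1];
            ph_tot[b] += sc.ph[nb - 1] - sc.ph[a - 1];
            state(s, b) = nb;
            a = nb;
          }
        }
        if (keep_visits) ++vis[s][(a - 1) + sc.n * b];
      }
      const double r_ace = ace_tot[b] / max_ace;
      const double r_met = met_tot[b] / max_met;
      bal_acc[b] += r_ace - r_met;
      if (!pinned[b]) {
        if (unif_rand() < gate_frac * D[b]) {
          const double A = (r_met + (1.0 - r_ace)) / 2.0;
          const double R = unif_rand();
          double d = D[b] + R * (A - D[b]);
          if (d < 0.0) d = 0.0; else if (d > 1.0) d = 1.0;
          D[b] = d;
        }
      }
    }
    if (m > 0 && t % m == 0 && int_row < n_int) {
      for (int b = 0; b < B; ++b) {
        double Tb = PT * std::exp(kappa * bal_acc[b] / m);
        if (Tb > 1.0) Tb = 1.0;
        T_trace(int_row, b) = Tb;
        bal_acc[b] = 0.0;
      }
      for (int b = 0; b < B; ++b)
        if (block_type[b] == 1 && promoter_of[b] > 0 &&
            D[promoter_of[b] - 1] > block_thresh)
          T_trace(int_row, b) = 0.0;
      ++int_row;
    }
    if (record_every > 0 && t % record_every == 0 && rec_row < n_rec) {
      for (int b = 0; b < B; ++b) {
        D_trace(rec_row, b) = D[b];
        ace_trace(rec_row, b) = ace_tot[b];
        met_trace(rec_row, b) = met_tot[b];
        ph_trace(rec_row, b) = ph_tot[b];
      }
      ++rec_row;
    }
  }

  return List::create(
      _["state"] = state, _["D"] = D,
      _["ace"] = NumericVector(ace_tot.begin(), ace_tot.end()),
      _["met"] = NumericVector(met_tot.begin(), met_tot.end()),
      _["ph"] = NumericVector(ph_tot.begin(), ph_tot.end()),
      _["visits"] = visits,
      _["D_trace"] = D_trace, _["ace_trace"] = ace_trace,
      _["met_trace"] = met_trace, _["ph_trace"] = ph_trace,
      _["T_trace"] = T_trace);
}
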