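#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Stochastic engine for nucleation-limited Bcl10 filament growth with
// autophagosome-mediated degradation. One call advances a single simulated
// cell; all randomness flows through R's RNG so set.seed() controls runs.
//
// State encoding
//   site_status: 0 inactive, 1 active-nucleating (empty), 2 occupied
//   filaments:   len >= 0 (len == -1 marks a removed slot),
//                site (0-based nucleation-site index, -1 if none),
//                grow (1 = growth-enabled), consuming (1 = daughter being
//                consumed by its autophagosome)
//   autophagosomes: state 0 free, 1 attached, 2 consuming;
//                fil (0-based filament), pos (1..len), mode 0 end, 1 interior
//
// Growth laws (per active growth-enabled structure, per iteration)
//   0 "per_monomer":  arrivals ~ Binomial(free, p_collide_bcl10), each
//                     arrival attaches with the phase probability; several
//                     monomers may add in one iteration (mass-action reading
//                     of the per-site collision constant)
//   1 "mass_action":  at most one monomer, with prob
//                     min(1, p_collide_bcl10 * free) * p_phase
//   2 "per_site":     at most one monomer, with prob p_collide_bcl10 * p_phase

struct Params {
  double p_activate, p_attach, p_grow;
  int    n_barrier;
  double p_collide_carma, p_collide_bcl10, p_collide_auto, p_attach_auto;
  double p_degrade, p_detach;
  int    punctum_len, max_iter, growth_law, target_choice, mode;
};

static Params read_params(const List &p) {
  Params q;
  q.p_activate      = as<double>(p["p_activate"]);
  q.p_attach        = as<double>(p["p_attach"]);
  q.p_grow          = as<double>(p["p_grow"]);
  q.n_barrier       = as<int>(p["n_barrier"]);
  q.p_collide_carma = as<double>(p["p_collide_carma"]);
  q.p_collide_bcl10 = as<double>(p["p_collide_bcl10"]);
  q.p_collide_auto  = as<double>(p["p_collide_auto"]);
  q.p_attach_auto   = as<double>(p["p_attach_auto"]);
  q.p_degrade       = as<double>(p["p_degrade"]);
  q.p_detach        = as<double>(p["p_detach"]);
  q.punctum_len     = as<int>(p["punctum_len"]);
  q.max_iter        = as<int>(p["max_iter"]);
  q.growth_law      = as<int>(p["growth_law"]);
  q.target_choice   = as<int>(p["target_choice"]);
  q.mode            = as<int>(p["mode"]); // 0 growth-only, 1 growth+degradation
  return q;
}

// [[Rcpp::export]]
List run_cell_cpp(List state, List params, int n_iter, bool record_trace) {
  Params P = read_params(params);

  std::vector<int> site_status = as<std::vector<int>>(state["site_status"]);
  std::vector<int> flen  = as<std::vector<int>>(state["fil_len"]);
  std::vector<int> fsite = as<std::vector<int>>(state["fil_site"]);
  std::vector<int> fgrow = as<std::vector<int>>(state["fil_grow"]);
  std::vector<int> fcons = as<std::vector<int>>(state["fil_consuming"]);
  std::vector<int> astate = as<std::vector<int>>(state["auto_state"]);
  std::vector<int> afil   = as<std::vector<int>>(state["auto_fil"]);
  std::vector<int> apos   = as<std::vector<int>>(state["auto_pos"]);
  std::vector<int> amode  = as<std::vector<int>>(state["auto_mode"]);
  long long freem    = as<double>(state["free_monomers"]);
  long long degraded = as<double>(state["degraded_monomers"]);
  double synapse = as<double>(state["synapse_fraction"]);

  long long initial = freem + degraded;
  for (size_t i = 0; i < flen.size(); ++i) if (flen[i] > 0) initial += flen[i];

  const int n_sites = site_status.size();
  const int n_auto  = astate.size();
  const double p_act = P.p_collide_carma * synapse * P.p_activate;

  std::vector<double> trace; // row-major, 9 cols
  const int TC = 9;
  auto filamentous = [&]() {
    long long s = 0;
    for (size_t i = 0; i < flen.size(); ++i) if (flen[i] > 0) s += flen[i];
    return s;
  };
  auto record = [&](int iter) {
    if (!record_trace) return;
    long long fil = 0; int nstr = 0, npunc = 0, nlong = 0, ndeg = 0;
    double suml = 0, sumlnp = 0;
    for (size_t i = 0; i < flen.size(); ++i) {
      if (flen[i] <= 0) continue;
      fil += flen[i]; ++nstr; suml += flen[i];
      if (flen[i] < P.punctum_len) ++npunc; else { ++nlong; sumlnp += flen[i]; }
    }
    for (int a = 0; a < n_auto; ++a) if (astate[a] != 0) ++ndeg;
    trace.push_back(iter);
    trace.push_back((double)freem);
    trace.push_back((double)fil);
    trace.push_back((double)degraded);
    trace.push_back(nstr);
    trace.push_back(npunc);
    trace.push_back(nstr ? suml / nstr : NA_REAL);
    trace.push_back(nlong ? sumlnp / nlong : NA_REAL);
    trace.push_back(ndeg);
  };

  auto shuffled = [&](int n) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(idx[i], idx[j]);
    }
    return idx;
  };

  record(0);
  int iter = 0;
  int limit = (n_iter > 0) ? n_iter : P.max_iter;

  while (iter < limit) {
    // termination checks (before stepping)
    if (P.mode == 0 && freem == 0) break;
    if (P.mode == 1 && freem + filamentous() == 0) break;
    ++iter;

    // --- phase 1: activation of Carma1 nucleation sites -------------------
    if (p_act > 0) {
      std::vector<int> ord = shuffled(n_sites);
      for (int k = 0; k < n_sites; ++k) {
        int s = ord[k];
        if (site_status[s] != 0) continue;
        if (unif_rand() < p_act) {
          site_status[s] = 2;
          flen.push_back(0); fsite.push_back(s);
          fgrow.push_back(1); fcons.push_back(0);
        }
      }
    }

    // --- phase 2: monomer attachment --------------------------------------
    {
      // sites whose filament was fully degraded are active-nucleating
      // again: give each a fresh empty filament slot
      for (int s = 0; s < n_sites; ++s) {
        if (site_status[s] != 1) continue;
        site_status[s] = 2;
        flen.push_back(0); fsite.push_back(s);
        fgrow.push_back(1); fcons.push_back(0);
      }
      std::vector<int> grower;
      for (size_t i = 0; i < flen.size(); ++i)
        if (flen[i] >= 0 && fgrow[i]) grower.push_back((int)i);
      std::vector<int> ord = shuffled((int)grower.size());
      for (size_t k = 0; k < ord.size() && freem > 0; ++k) {
        int f = grower[ord[k]];
        double p_phase = (flen[f] < P.n_barrier) ? P.p_attach : P.p_grow;
        int gained = 0;
        bool multi = (P.growth_law == 0) ||
                     (P.growth_law == 3 && flen[f] >= P.n_barrier);
        if (multi) {
          int arrivals = (int)R::rbinom((double)freem, P.p_collide_bcl10);
          if (arrivals > 0) gained = (int)R::rbinom((double)arrivals, p_phase);
          if (gained > freem) gained = (int)freem;
        } else if (P.growth_law == 3) {
          double pc = std::min(1.0, P.p_collide_bcl10 * (double)freem);
          if (unif_rand() < pc * p_phase) gained = 1;
        } else {
          double pc = (P.growth_law == 1)
            ? std::min(1.0, P.p_collide_bcl10 * (double)freem)
            : P.p_collide_bcl10;
          if (unif_rand() < pc * p_phase) gained = 1;
        }
        if (gained > 0) { flen[f] += gained; freem -= gained; }
      }
    }

    // --- phase 3: autophagosome dynamics -----------------------------------
    if (n_auto > 0) {
      std::vector<int> ord = shuffled(n_auto);
      for (int k = 0; k < n_auto; ++k) {
        int a = ord[k];
        if (astate[a] == 0) {
          // free: collide with a filament, then attach
          double tot = 0; int navail = 0;
          for (size_t i = 0; i < flen.size(); ++i)
            if (flen[i] > 0 && !fcons[i]) { tot += flen[i]; ++navail; }
          if (navail == 0) continue;
          if (unif_rand() >= P.p_collide_auto) continue;
          int target = -1;
          if (P.target_choice == 0) { // length-weighted
            double u = unif_rand() * tot, acc = 0;
            for (size_t i = 0; i < flen.size(); ++i) {
              if (flen[i] > 0 && !fcons[i]) {
                acc += flen[i];
                if (u <= acc) { target = (int)i; break; }
              }
            }
            if (target < 0) for (int i = (int)flen.size() - 1; i >= 0; --i)
              if (flen[i] > 0 && !fcons[i]) { target = i; break; }
          } else { // uniform over available filaments
            int j = (int)(unif_rand() * navail), c = 0;
            if (j >= navail) j = navail - 1;
            for (size_t i = 0; i < flen.size(); ++i)
              if (flen[i] > 0 && !fcons[i] && c++ == j) { target = (int)i; break; }
          }
          if (unif_rand() < P.p_attach_auto) {
            int L = flen[target];
            int pos = 1 + (int)(unif_rand() * L);
            if (pos > L) pos = L;
            astate[a] = 1; afil[a] = target; apos[a] = pos;
            amode[a] = (pos == L) ? 0 : 1; // terminal monomer => end mode
          }
        } else if (astate[a] == 1) {
          int f = afil[a];
          if (flen[f] <= 0) { astate[a] = 0; continue; } // filament vanished
          if (apos[a] > flen[f]) apos[a] = flen[f];
          if (unif_rand() < P.p_degrade) {
            if (amode[a] == 0 || apos[a] == flen[f]) {
              // end-mode: peel one monomer off the attached end
              flen[f] -= 1; ++degraded;
              if (apos[a] > flen[f]) apos[a] = flen[f];
              if (flen[f] == 0) {
                if (fsite[f] >= 0) site_status[fsite[f]] = 1; // site free again
                flen[f] = -1; astate[a] = 0;
              }
            } else {
              // interior: scission at pos -> stable daughter 1 (keeps site),
              // daughter 2 consumed monomer-by-monomer by this autophagosome
              int j = apos[a], L = flen[f];
              int len1 = j - 1, len2 = L - j + 1;
              // re-home other autophagosomes attached to f
              for (int b = 0; b < n_auto; ++b) {
            if (b == a || astate[b] != 1 || afil[b] != f) continue;
                if (apos[b] <= len1) continue;        // stays on daughter 1
                astate[b] = 0;                        // lost its segment
              }
              flen[f] = len1;
              if (len1 == 0) {
                if (fsite[f] >= 0) site_status[fsite[f]] = 1;
                flen[f] = -1;
              } else {
                fgrow[f] = 0; // daughter 1 is stable: no further growth
              }
              flen.push_back(len2); fsite.push_back(-1);
              fgrow.push_back(0); fcons.push_back(1);
              astate[a] = 2; afil[a] = (int)flen.size() - 1; apos[a] = len2;
              amode[a] = 0;
            }
          } else if (unif_rand() < P.p_detach) {
            astate[a] = 0;
          }
        } else { // consuming daughter 2 (never detaches)
          int f = afil[a];
          if (flen[f] <= 0) { astate[a] = 0; continue; }
          if (unif_rand() < P.p_degrade) {
            flen[f] -= 1; ++degraded;
            if (flen[f] == 0) { flen[f] = -1; astate[a] = 0; }
          }
        }
      }
    }

    // --- integer monomer ledger -------------------------------------------
    long long total = freem + degraded + filamentous();
    if (total != initial)
      stop("monomer ledger violation: %lld != %lld at iteration %d",
           total, initial, iter);
    record(iter);

    if (n_iter < 0 && P.mode == 1 && P.max_iter == iter) break;
  }

  List out_state = List::create(
    _["site_status"] = wrap(site_status),
    _["fil_len"] = wrap(flen), _["fil_site"] = wrap(fsite),
    _["fil_grow"] = wrap(fgrow), _["fil_consuming"] = wrap(fcons),
    _["auto_state"] = wrap(astate), _["auto_fil"] = wrap(afil),
    _["auto_pos"] = wrap(apos), _["auto_mode"] = wrap(amode),
    _["free_monomers"] = (double)freem,
    _["degraded_monomers"] = (double)degraded,
    _["synapse_fraction"] = synapse);

  NumericMatrix tr;
  if (record_trace) {
    int nrow = (int)(trace.size() / TC);
    tr = NumericMatrix(nrow, TC);
    for (int r = 0; r < nrow; ++r)
      for (int c = 0; c < TC; ++c) tr(r, c) = trace[(size_t)r * TC + c];
    colnames(tr) = CharacterVector::create(
      "iter", "free", "filamentous", "degraded", "n_structures", "n_puncta",
      "mean_len", "mean_len_filament", "n_active_degradation");
  }
  return List::create(_["state"] = out_state, _["trace"] = tr,
                      _["iterations"] = iter);
}
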