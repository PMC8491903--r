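#include <Rcpp.h>
using namespace Rcpp;

// Exact Gillespie simulation of the two-type birth-death-mutation process
// under a piecewise-constant dosing schedule.
//
// Propensities (crowding split between births and deaths by theta, drug
// kill d(u) on sensitive cells only, mutation decoupled from birth):
//   beta_S  = (b_S - (b_S - th_S) N/K) S
//   delta_S = (d_S + (th_S - d_S) N/K + d(u)) S
//   beta_R  = (b_R - (b_R - th_R) N/K) R
//   delta_R = (d_R + (th_R - d_R) N/K) R
//   m       = mu(u) S
// each clamped at zero (N > K can occur stochastically). Within a segment
// all rates are constant between events, so drawing the waiting time from
// the current total rate and advancing to the segment boundary when the
// draw overshoots is exact (memorylessness).
//
// Each mutation founds its own resistant lineage, tracked as a separate
// sub-counter so that establishment (lineage alive at T) is well defined;
// resistant birth/death events pick a lineage proportionally to its size.
//
// Uses R's RNG, so results are reproducible via set.seed() on the R side.

// [[Rcpp::export]]
List ssa_core(double S0, double R0, double t_end,
              NumericVector seg_start, NumericVector seg_death,
              NumericVector seg_mu,
              double bS, double dS, double thS,
              double bR, double dR, double thR,
              double K, double max_events, bool track) {
  double S = S0, R = R0, t = 0.0;
  const double invK = R_finite(K) ? 1.0 / K : 0.0;
  const int nseg = seg_start.size();
  int seg = 0;
  while (seg + 1 < nseg && seg_start[seg + 1] <= t) ++seg;

  std::vector<double> mut_times;
  std::vector<double> lineage;   // per-lineage resistant counts
  bool has_init_lineage = track && R0 > 0;
  if (has_init_lineage) lineage.push_back(R0);

  double n_events = 0.0;
  int status = 0;                // 0 ok, 1 event cap hit

  while (t < t_end) {
    if (S <= 0 && R <= 0) break;
    double du = seg_death[seg];
    double mu = seg_mu[seg];
    double f = (S + R) * invK;
    double a_bS = (bS - (bS - thS) * f) * S; if (a_bS < 0) a_bS = 0;
    double a_dS = (dS + (thS - dS) * f + du) * S; if (a_dS < 0) a_dS = 0;
    double a_bR = (bR - (bR - thR) * f) * R; if (a_bR < 0) a_bR = 0;
    double a_dR = (dR + (thR - dR) * f) * R; if (a_dR < 0) a_dR = 0;
    double a_m = mu * S; if (a_m < 0) a_m = 0;
    double total = a_bS + a_dS + a_bR + a_dR + a_m;

    double seg_end = (seg + 1 < nseg) ? seg_start[seg + 1] : t_end;
    if (seg_end > t_end) seg_end = t_end;

    if (total <= 0) {            // frozen state: jump to next rate change
      t = seg_end;
      if (seg + 1 < nseg && t >= seg_start[seg + 1]) ++seg;
      if (t >= t_end) break;
      continue;
    }

    double tau = R::exp_rand() / total;
    if (t + tau >= seg_end) {    // no event before the rates change
      t = seg_end;
      if (seg + 1 < nseg && t >= seg_start[seg + 1]) ++seg;
      continue;
    }
    t += tau;
    n_events += 1.0;
    if (n_events > max_events) { status = 1; break; }

    double e = unif_rand() * total;
    if (e < a_bS) {
      S += 1;
    } else if (e < a_bS + a_dS) {
      S -= 1;
    } else if (e < a_bS + a_dS + a_bR) {
      R += 1;
      if (track) {
        double pick = unif_rand() * (R - 1);
        double cum = 0.0;
        for (size_t i = 0; i < lineage.size(); ++i) {
          cum += lineage[i];
          if (pick < cum) { lineage[i] += 1; break; }
        }
      }
    } else if (e < a_bS + a_dS + a_bR + a_dR) {
      R -= 1;
      if (track) {
        double pick = unif_rand() * (R + 1);
        double cum = 0.0;
        for (size_t i = 0; i < lineage.size(); ++i) {
          cum += lineage[i];
          if (pick < cum) { lineage[i] -= 1; break; }
        }
      }
    } else {
      S -= 1;
      R += 1;
      mut_times.push_back(t);
      if (track) lineage.push_back(1.0);
    }
  }
  int n_mut = mut_times.size();
  LogicalVector alive(n_mut);
  if (track) {
    size_t off = has_init_lineage ? 1 : 0;
    for (int i = 0; i < n_mut; ++i) alive[i] = lineage[i + off] > 0;
  }
  return List::create(
    _["final_S"] = S, _["final_R"] = R, _["t_final"] = t,
    _["extinct"] = (S <= 0 && R <= 0),
    _["mutation_times"] = NumericVector(mut_times.begin(), mut_times.end()),
    _["lineage_alive"] = alive,
    _["n_events"] = n_events, _["status"] = status);
}
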