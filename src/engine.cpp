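#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Counter-based uniform stream: every variate is a pure function of
// (seed, patient, slot). This gives per-patient streams that are stable under
// cohort-size changes, and common random numbers across scenario variants
// because a draw's identity (which patient, which cycle, which modality) fixes
// its slot regardless of what else the scenario schedules.
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline double u01(uint64_t seed, uint64_t patient, uint64_t slot) {
  uint64_t h = splitmix64(seed ^ splitmix64(patient ^ splitmix64(slot)));
  // 53-bit mantissa, strictly inside (0, 1) so qnorm/log are always finite
  return ((h >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

// slot layout per patient (slots are sparse; only identity matters)
static const uint64_t SLOT_RECUR = 0, SLOT_SITE = 1, SLOT_D = 2, SLOT_EPS = 3,
                      SLOT_LUNG = 4;
static inline uint64_t slot_test(int cycle, int mod) {
  return 64ULL + (uint64_t)(cycle - 1) * 32ULL + (uint64_t)mod;
}
static inline uint64_t slot_mort(int cycle) {
  return (1ULL << 20) + (uint64_t)cycle;
}

// met codes: 0 none, 1 liver, 2 lung, 3 multiple_other
static inline bool operable_site(int met, double u_lung, double p_lung) {
  if (met == 3) return false;
  if (met == 2) return u_lung < p_lung;
  return true; // none (local-only) or liver
}

// [[Rcpp::export]]
NumericVector cpp_stream_uniform(double seed, NumericVector patient,
                                 NumericVector slot) {
  R_xlen_t n = patient.size();
  if (slot.size() != n) stop("patient and slot must have equal length");
  NumericVector out(n);
  uint64_t s = (uint64_t)seed;
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = u01(s, (uint64_t)patient[i], (uint64_t)slot[i]);
  return out;
}

// [[Rcpp::export]]
List cpp_run_cohort(int n, double seed, int horizon, double p_recur,
                    NumericVector site_prob, IntegerVector site_met,
                    double r_d, double xdu_c, double r_u, double xds_c,
                    double r_s, double sigma_c, double p_mort_cycle,
                    NumericVector sens, NumericVector spec,
                    LogicalMatrix detect, IntegerMatrix schedule,
                    double le_salvage_c, double le_palliative_c,
                    double p_lung_operable, bool exact_eligibility) {
  const int n_mod = sens.size();
  const int n_site = site_prob.size();
  if (detect.nrow() != n_mod || detect.ncol() != n_site)
    stop("detect matrix must be n_modalities x n_sites");
  if (schedule.nrow() != horizon || schedule.ncol() != n_mod)
    stop("schedule matrix must be horizon x n_modalities");
  if (n_mod > 32) stop("at most 32 modalities supported");
  const uint64_t sd = (uint64_t)seed;

  LogicalVector will_recur(n), salvage(n), s_clipped(n);
  IntegerVector site(n, NA_INTEGER), dx_mode(n, 0), death_cause(n, 0);
  NumericVector D(n, NA_REAL), U(n, NA_REAL), S(n, NA_REAL), eps(n, NA_REAL),
      dx_time(n, NA_REAL), death_time(n, NA_REAL);

  for (int i = 0; i < n; ++i) {
    const uint64_t pid = (uint64_t)(i + 1);
    const bool recur = u01(sd, pid, SLOT_RECUR) < p_recur;
    will_recur[i] = recur;
    int st = -1;
    double Di = 0, Ui = 0, Si = 0;
    if (recur) {
      const double us = u01(sd, pid, SLOT_SITE);
      double acc = 0;
      for (int k = 0; k < n_site; ++k) {
        acc += site_prob[k];
        if (us < acc || k == n_site - 1) { st = k; break; }
      }
      Di = -log1p(-u01(sd, pid, SLOT_D)) / r_d;
      double e = (sigma_c > 0)
                     ? R::qnorm(u01(sd, pid, SLOT_EPS), 0.0, sigma_c, 1, 0)
                     : 0.0;
      Ui = Di + xdu_c * (1.0 + r_u * Di);
      Si = Di + xds_c * (1.0 + r_s * Di) + e;
      if (Si < Di) { Si = Di; s_clipped[i] = true; }
      site[i] = st + 1;
      D[i] = Di; U[i] = Ui; S[i] = Si; eps[i] = e;
    }
    const double u_lung = u01(sd, pid, SLOT_LUNG);

    bool dx = false, dead = false;
    double cancer_death = R_PosInf;
    for (int c = 1; c <= horizon && !dead; ++c) {
      // (1) symptomatic interval detection at continuous time S in (c-1, c]
      if (!dx && recur && Si > (double)(c - 1) && Si <= (double)c) {
        dx = true;
        dx_time[i] = Si; dx_mode[i] = 2;
        const double t_elig = exact_eligibility ? Si : (double)(c - 1);
        salvage[i] = (t_elig < Ui) && operable_site(site_met[st], u_lung,
                                                    p_lung_operable);
        cancer_death = Si + (salvage[i] ? le_salvage_c : le_palliative_c);
      }
      // (2) scheduled surveillance at the cycle boundary
      if (!dx) {
        bool any_pos = false;
        for (int m = 0; m < n_mod; ++m) {
          if (!schedule(c - 1, m)) continue;
          const double uu = u01(sd, pid, slot_test(c, m));
          const bool det = recur && Di <= (double)c && detect(m, st >= 0 ? st : 0) && st >= 0;
          const double p_pos = det ? sens[m] : (1.0 - spec[m]);
          if (uu < p_pos) any_pos = true;
        }
        // any positive triggers a full workup with perfect combined accuracy:
        // a diagnosis is recorded iff some recurrence is actually detectable
        if (any_pos && recur && Di <= (double)c) {
          dx = true;
          dx_time[i] = (double)c; dx_mode[i] = 1;
          const double t_elig = exact_eligibility ? (double)c : (double)(c - 1);
          salvage[i] = (t_elig < Ui) && operable_site(site_met[st], u_lung,
                                                      p_lung_operable);
          cancer_death = (double)c + (salvage[i] ? le_salvage_c : le_palliative_c);
        }
      }
      // (3) deaths: assigned cancer death first (continuous time within the
      // cycle), then the background mortality draw at the boundary
      if (cancer_death <= (double)c) {
        death_time[i] = cancer_death; death_cause[i] = 1; dead = true;
      } else if (u01(sd, pid, slot_mort(c)) < p_mort_cycle) {
        death_time[i] = (double)c; death_cause[i] = 2; dead = true;
      }
    }
  }

  return List::create(
      _["patient"] = seq_len(n), _["will_recur"] = will_recur,
      _["site"] = site, _["D"] = D, _["U"] = U, _["S"] = S, _["eps"] = eps,
      _["s_clipped"] = s_clipped, _["dx_time"] = dx_time,
      _["dx_mode"] = dx_mode, _["salvage"] = salvage,
      _["death_time"] = death_time, _["death_cause"] = death_cause);
}
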