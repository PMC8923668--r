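// Monte Carlo engines for promoter-state switching and footprint-limited
// RNA Pol II traffic on a single gene. Two engines with the same contract:
//  - event-driven: exponential waiting times for promoter transitions and
//    loading attempts (thinning against a constant bound for time-varying
//    attempt rates), deterministic elongation;
//  - fixed-step: per-nucleotide updates (dt = 1/v min) with Bernoulli draws,
//    the reference implementation on short runs.
// Both use R's RNG, so results are reproducible under set.seed().

#include <Rcpp.h>
#include <deque>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct SegmentOut {
  NumericMatrix nascent;      // n_loci x n_samples, C.U.
  IntegerMatrix completed;    // cumulative completions by each sample
  IntegerMatrix mature_alive; // completions within segment alive at sample
  IntegerVector alive_end;    // alive at segment end
  LogicalVector final_active, final_memory;
  IntegerMatrix state;        // active + 2*memory at each sample
  List positions;             // per sample: list of per-locus positions
};

inline double load_rate(int model, bool active, bool memory, double t,
                        double polB, double polL, double polH, double alpha) {
  switch (model) {
    case 1: return active ? polL : polB;       // two-state: k_pol in polL slot
    case 2: return alpha * t;                  // accelerating attempts
    default: return active ? (memory ? polH : polL) : polB;
  }
}

inline int probes_leq(const std::vector<double>& probes, double pos) {
  return (int)(std::upper_bound(probes.begin(), probes.end(), pos) -
               probes.begin());
}

} // namespace

// [[Rcpp::export(name = ".simulate_segment_cpp")]]
List simulate_segment_cpp(int n_loci, int model,
                          double act_rate, double conv_rate,
                          double polB, double polL, double polH, double alpha,
                          double footprint, double v, double L,
                          NumericVector probes,
                          double duration, NumericVector sample_times,
                          LogicalVector init_active, LogicalVector init_memory,
                          double tau, int engine, bool detail) {
  const int ns = sample_times.size();
  const int npr = probes.size();
  std::vector<double> pr(probes.begin(), probes.end());
  for (int j = 0; j < ns; ++j) {
    if (sample_times[j] < 0 || sample_times[j] > duration + 1e-9)
      stop("sample times must lie within the segment");
    if (j > 0 && sample_times[j] <= sample_times[j - 1])
      stop("sample times must be strictly increasing");
  }
  if (tau <= 0) stop("mRNA lifetime tau must be > 0");
  if (footprint < 0 || v <= 0 || L <= 0) stop("invalid gene/rate geometry");

  NumericMatrix nascent(n_loci, ns);
  IntegerMatrix completed(n_loci, ns), mature_alive(n_loci, ns),
      state(n_loci, ns);
  IntegerVector alive_end(n_loci), completed_end(n_loci);
  LogicalVector fin_act(n_loci), fin_mem(n_loci);
  List positions(detail ? ns : 0);
  std::vector<std::vector<std::vector<double>>> pos_store;
  if (detail) pos_store.assign(ns, std::vector<std::vector<double>>(n_loci));

  const double Tgene = L / v;

  if (engine == 0) {
    // -------- event-driven --------
    // Models 1/3 have piecewise-constant attempt rates: draw exact
    // exponential waits and redraw on promoter transitions (memoryless).
    // Model 2 has a linearly increasing rate: thin against alpha*duration.
    double B = alpha * duration; // model-2 thinning bound

    for (int i = 0; i < n_loci; ++i) {
      double t = 0.0;
      bool active = init_active[i], memory = init_memory[i];
      std::deque<double> loads; // load times of Pol IIs on the gene (FIFO)
      int comp = 0;
      double t_act = (!active && act_rate > 0) ? exp_rand() / act_rate
                                               : R_PosInf;
      double t_conv = (!memory && conv_rate > 0) ? exp_rand() / conv_rate
                                                 : R_PosInf;
      double r_cur = (model == 2)
          ? B
          : load_rate(model, active, memory, t, polB, polL, polH, alpha);
      double t_att = (r_cur > 0) ? exp_rand() / r_cur : R_PosInf;
      int si = 0;
      while (true) {
        double t_comp = loads.empty() ? R_PosInf : loads.front() + Tgene;
        double t_samp = (si < ns) ? sample_times[si] : R_PosInf;
        double t_next = std::min(std::min(t_act, t_conv),
                                 std::min(t_att, std::min(t_comp, t_samp)));
        if (t_next > duration) break;
        if (t_comp <= t_next) {
          // eviction of a finished transcript; assign an exponential lifetime
          t = t_comp;
          loads.pop_front();
          ++comp;
          double life = exp_rand() * tau;
          for (int j = si; j < ns; ++j) {
            if (sample_times[j] >= t && sample_times[j] < t + life)
              mature_alive(i, j)++;
          }
          if (t + life > duration) alive_end[i]++;
          continue;
        }
        if (t_samp <= t_next) {
          t = t_samp;
          double sig = 0.0;
          for (double u : loads) sig += probes_leq(pr, v * (t - u));
          nascent(i, si) = sig / npr;
          completed(i, si) = comp;
          state(i, si) = (active ? 1 : 0) + (memory ? 2 : 0);
          if (detail) {
            std::vector<double>& pv = pos_store[si][i];
            for (double u : loads) pv.push_back(v * (t - u));
          }
          ++si;
          continue;
        }
        if (t_act <= t_next || t_conv <= t_next) {
          if (t_act <= t_next) { t = t_act; active = true; t_act = R_PosInf; }
          else { t = t_conv; memory = true; t_conv = R_PosInf; }
          if (model != 2) { // rate changed; redraw the attempt wait
            r_cur = load_rate(model, active, memory, t, polB, polL, polH,
                              alpha);
            t_att = (r_cur > 0) ? t + exp_rand() / r_cur : R_PosInf;
          }
          continue;
        }
        // loading attempt (model 2: thinned to the instantaneous rate)
        t = t_att;
        t_att = (r_cur > 0) ? t + exp_rand() / r_cur : R_PosInf;
        bool accept = true;
        if (model == 2) {
          double r = alpha * t;
          accept = (unif_rand() < r / B);
        }
        if (accept) {
          bool blocked = !loads.empty() && v * (t - loads.back()) < footprint;
          if (!blocked) loads.push_back(t);
        }
      }
      // transcripts still elongating at segment end do not complete
      fin_act[i] = active;
      fin_mem[i] = memory;
      completed_end[i] = comp;
    }
  } else {
    // -------- fixed-step (dt = 1/v) --------
    double dt = 1.0 / v;
    long nsteps = (long)std::llround(duration * v);
    double rmax = (model == 2) ? alpha * duration
                               : std::max(polB, std::max(polL, polH));
    if (act_rate * dt > 1.0)
      stop("activation probability k_A*dt exceeds 1; reduce k_A");
    if (conv_rate * dt > 1.0)
      stop("conversion probability k_C*dt exceeds 1; reduce k_C");
    if (rmax * dt > 1.0)
      stop("loading probability k_pol*dt exceeds 1; reduce the loading rate");
    int Lnt = (int)std::llround(L);
    int fnt = (int)std::ceil(footprint);
    for (int i = 0; i < n_loci; ++i) {
      bool active = init_active[i], memory = init_memory[i];
      std::deque<int> pos; // nt positions, front = oldest (largest)
      int comp = 0, si = 0;
      for (long k = 1; k <= nsteps; ++k) {
        double t = k * dt;
        if (!active && act_rate > 0 && unif_rand() < act_rate * dt)
          active = true;
        if (!memory && conv_rate > 0 && unif_rand() < conv_rate * dt)
          memory = true;
        double r = load_rate(model, active, memory, t, polB, polL, polH,
                             alpha);
        if (r > 0 && unif_rand() < r * dt) {
          if (pos.empty() || pos.back() >= fnt) pos.push_back(0);
        }
        for (auto& p : pos) ++p;
        while (!pos.empty() && pos.front() >= Lnt) {
          pos.pop_front();
          ++comp;
          double life = exp_rand() * tau;
          for (int j = si; j < ns; ++j) {
            if (sample_times[j] >= t && sample_times[j] < t + life)
              mature_alive(i, j)++;
          }
          if (t + life > duration) alive_end[i]++;
        }
        while (si < ns && sample_times[si] <= t + 0.5 * dt) {
          double sig = 0.0;
          for (int p : pos) sig += probes_leq(pr, (double)p);
          nascent(i, si) = sig / npr;
          completed(i, si) = comp;
          state(i, si) = (active ? 1 : 0) + (memory ? 2 : 0);
          if (detail) {
            std::vector<double>& pv = pos_store[si][i];
            for (int p : pos) pv.push_back((double)p);
          }
          ++si;
        }
      }
      fin_act[i] = active;
      fin_mem[i] = memory;
      completed_end[i] = comp;
    }
  }

  if (detail) {
    for (int j = 0; j < ns; ++j) {
      List lj(n_loci);
      for (int i = 0; i < n_loci; ++i) lj[i] = wrap(pos_store[j][i]);
      positions[j] = lj;
    }
  }
  return List::create(_["nascent"] = nascent, _["completed"] = completed,
                      _["completed_end"] = completed_end,
                      _["mature_alive"] = mature_alive,
                      _["alive_end"] = alive_end,
                      _["final_active"] = fin_act,
                      _["final_memory"] = fin_mem, _["state"] = state,
                      _["positions"] = positions);
}
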