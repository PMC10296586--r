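// Event-driven simulation of excitable-refractory (leaky integrate-and-fire)
// neurons on a directed graph with real-valued per-edge transmission delays.
// No fixed time step: membrane potentials are advanced lazily at event times
// via closed-form exponential decay, so delivery times are exact
// (arrival = emission + delay in double precision).
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Delivery {
  double t;
  int edge;       // -1 for external (forced) input
  long long seq;  // insertion order, final tie-break
  int target;
  double w;
};

// min-heap on (time, edge id, seq): deterministic processing order even for
// exact dead-heat arrivals, which matter under unit delays
struct DelivCmp {
  bool operator()(const Delivery& a, const Delivery& b) const {
    if (a.t != b.t) return a.t > b.t;
    if (a.edge != b.edge) return a.edge > b.edge;
    return a.seq > b.seq;
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_simulate_spiking(int n,
                          IntegerVector e_src, IntegerVector e_tgt,
                          NumericVector e_w, NumericVector e_delay,
                          double threshold, double reset, double rest,
                          double leak_tau, double refractory,
                          IntegerVector s_unit, NumericVector s_time,
                          NumericVector s_amp,
                          double t_end,
                          LogicalVector record_spike,
                          bool record_deliveries,
                          double max_events) {
  const int ne = e_src.size();

  // CSR of out-edges per neuron
  std::vector<int> deg(n, 0);
  for (int e = 0; e < ne; ++e) deg[e_src[e]]++;
  std::vector<int> off(n + 1, 0);
  for (int i = 0; i < n; ++i) off[i + 1] = off[i] + deg[i];
  std::vector<int> adj(ne);
  {
    std::vector<int> pos(off.begin(), off.end() - 1);
    for (int e = 0; e < ne; ++e) adj[pos[e_src[e]]++] = e;
  }

  std::priority_queue<Delivery, std::vector<Delivery>, DelivCmp> q;
  long long seq = 0;
  for (int i = 0; i < s_unit.size(); ++i) {
    if (s_time[i] <= t_end)
      q.push(Delivery{s_time[i], -1, seq++, s_unit[i], s_amp[i]});
  }

  std::vector<double> v(n, rest), t_last(n, 0.0), refr_until(n, -1.0);

  std::vector<int> sp_unit;
  std::vector<double> sp_time;
  std::vector<int> dl_unit;
  std::vector<double> dl_time;

  double processed = 0.0;
  while (!q.empty()) {
    Delivery d = q.top();
    q.pop();
    if (d.t > t_end) break;
    if (++processed > max_events)
      stop("event budget exceeded (%.0f events); raise max_events or shorten the run",
           max_events);

    const int i = d.target;
    if (d.edge >= 0 && record_deliveries) {
      dl_unit.push_back(i);
      dl_time.push_back(d.t);
    }
    // absolute refractory: kicks arriving while silenced are discarded
    if (d.t < refr_until[i]) continue;

    // lazy exponential decay toward rest since the last update
    v[i] = rest + (v[i] - rest) * std::exp(-(d.t - t_last[i]) / leak_tau);
    t_last[i] = d.t;
    v[i] += d.w;

    if (v[i] >= threshold) {
      if (record_spike[i]) {
        sp_unit.push_back(i);
        sp_time.push_back(d.t);
      }
      v[i] = reset;
      refr_until[i] = d.t + refractory;
      for (int p = off[i]; p < off[i + 1]; ++p) {
        const int e = adj[p];
        const double ta = d.t + e_delay[e];
        if (ta <= t_end)
          q.push(Delivery{ta, e, seq++, e_tgt[e], e_w[e]});
      }
    }
  }

  return List::create(
      _["spike_unit"] = wrap(sp_unit),
      _["spike_time"] = wrap(sp_time),
      _["deliv_unit"] = wrap(dl_unit),
      _["deliv_time"] = wrap(dl_time));
}
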