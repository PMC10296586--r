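// Event-driven integration of a generalised Kuramoto network: k-dimensional
// clocks whose phases wind linearly between events, coupled by directed edges
// that fire when a designated sender phase upward-crosses an edge-specific
// trigger value, incur a real-valued delay, and apply an additive
// phase-resetting kick to the receiver.  Between events the flow is exactly
// linear, so all crossing and arrival times are closed-form.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

const double TWO_PI = 6.283185307179586476925286766559;

inline double pmod(double x) {
  double r = x - TWO_PI * std::floor(x / TWO_PI);
  if (r >= TWO_PI) r -= TWO_PI;   // guard against rounding at the boundary
  return (r < 0) ? 0.0 : r;
}

struct Ev {
  double t;
  int kind;      // 0 = external stimulus, 1 = arrival, 2 = emission candidate
  int edge;      // -1 for stimulus
  int aux;       // stimulus index, or sender version for candidates
  long long seq;
};

struct EvCmp {
  bool operator()(const Ev& a, const Ev& b) const {
    if (a.t != b.t) return a.t > b.t;
    if (a.edge != b.edge) return a.edge > b.edge;
    if (a.kind != b.kind) return a.kind > b.kind;
    return a.seq > b.seq;
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_simulate_clocks(int nc,
                         IntegerVector koff,        // length nc+1, phase offsets
                         NumericVector phase0,      // concatenated phases
                         NumericVector rate,        // concatenated rates
                         IntegerVector e_src, IntegerVector e_tgt,
                         IntegerVector e_trig_phase, // 0-based within sender
                         NumericVector e_trig_value,
                         NumericVector e_delay,
                         IntegerVector prm_off,     // length ne+1 into prm_val
                         NumericVector prm_val,     // concatenated kick/target vectors
                         IntegerVector prm_type,    // 0 = additive kick, 1 = pull
                         NumericVector prm_strength,// pull strength per edge
                         IntegerVector st_clock, NumericVector st_time,
                         IntegerVector st_phase,    // 0-based
                         NumericVector st_value,
                         IntegerVector st_mode,     // 0 = additive kick, 1 = reset
                         double t_end, double sample_dt,
                         IntegerVector observed,    // 0-based clock ids
                         double max_events) {
  const int ne = e_src.size();

  std::vector<int> deg(nc, 0);
  for (int e = 0; e < ne; ++e) deg[e_src[e]]++;
  std::vector<int> off(nc + 1, 0);
  for (int i = 0; i < nc; ++i) off[i + 1] = off[i] + deg[i];
  std::vector<int> adj(ne);
  {
    std::vector<int> pos(off.begin(), off.end() - 1);
    for (int e = 0; e < ne; ++e) adj[pos[e_src[e]]++] = e;
  }

  std::vector<double> ph(phase0.begin(), phase0.end());
  std::vector<double> t_upd(nc, 0.0);
  std::vector<int> ver(nc, 0);

  std::priority_queue<Ev, std::vector<Ev>, EvCmp> q;
  long long seq = 0;

  // phase of clock c, component j (global index), at absolute time t
  auto phase_at = [&](int c, int g, double t) {
    return pmod(ph[g] + rate[g] * (t - t_upd[c]));
  };

  // next strict upward crossing of edge e's trigger after time t
  auto push_candidate = [&](int e, double t) {
    const int c = e_src[e];
    const int g = koff[c] + e_trig_phase[e];
    const double w = rate[g];
    if (w <= 0) return;                       // never crosses
    double gap = pmod(e_trig_value[e] - phase_at(c, g, t));
    if (gap < 1e-9) gap = TWO_PI;             // sitting at the trigger: full turn
    const double tn = t + gap / w;
    if (tn <= t_end) q.push(Ev{tn, 2, e, ver[c], seq++});
  };

  auto wind_to = [&](int c, double t) {
    for (int g = koff[c]; g < koff[c + 1]; ++g)
      ph[g] = pmod(ph[g] + rate[g] * (t - t_upd[c]));
    t_upd[c] = t;
  };

  auto rearm = [&](int c, double t) {
    ver[c]++;
    for (int p = off[c]; p < off[c + 1]; ++p) push_candidate(adj[p], t);
  };

  for (int e = 0; e < ne; ++e) push_candidate(e, 0.0);
  for (int i = 0; i < st_clock.size(); ++i)
    if (st_time[i] <= t_end) q.push(Ev{st_time[i], 0, -1, i, seq++});

  // sampling grid 0, dt, 2dt, ...; a sample at time s reflects the state
  // before events scheduled exactly at s
  const int nsamp = (int)std::floor(t_end / sample_dt) + 1;
  const int nobs = observed.size();
  int obs_rows = 0;
  for (int i = 0; i < nobs; ++i)
    obs_rows += koff[observed[i] + 1] - koff[observed[i]];
  NumericMatrix samples(obs_rows, nsamp);
  NumericVector sample_times(nsamp);
  int next_s = 0;

  auto take_samples_until = [&](double t) {
    while (next_s < nsamp) {
      const double s = next_s * sample_dt;
      if (s > t) break;
      sample_times[next_s] = s;
      int r = 0;
      for (int i = 0; i < nobs; ++i) {
        const int c = observed[i];
        for (int g = koff[c]; g < koff[c + 1]; ++g)
          samples(r++, next_s) = phase_at(c, g, s);
      }
      next_s++;
    }
  };

  std::vector<int> ev_edge;
  std::vector<double> ev_emit, ev_arr;

  double processed = 0.0;
  while (!q.empty()) {
    Ev ev = q.top();
    q.pop();
    if (ev.t > t_end) break;
    if (++processed > max_events)
      stop("event budget exceeded (%.0f events); raise max_events or shorten the run",
           max_events);
    take_samples_until(ev.t);

    if (ev.kind == 2) {                      // emission candidate
      const int e = ev.edge;
      const int c = e_src[e];
      if (ev.aux != ver[c]) continue;        // stale: sender was kicked since
      const double ta = ev.t + e_delay[e];
      ev_edge.push_back(e);
      ev_emit.push_back(ev.t);
      ev_arr.push_back(ta);
      if (ta <= t_end) q.push(Ev{ta, 1, e, 0, seq++});
      // sender phases untouched by its own emission: next crossing is one turn on
      const int g = koff[c] + e_trig_phase[e];
      const double tn = ev.t + TWO_PI / rate[g];
      if (tn <= t_end) q.push(Ev{tn, 2, e, ver[c], seq++});
    } else if (ev.kind == 1) {               // arrival: apply the PRM
      const int e = ev.edge;
      const int c = e_tgt[e];
      wind_to(c, ev.t);
      int j = 0;
      if (prm_type[e] == 0) {                // additive phase kick
        for (int g = koff[c]; g < koff[c + 1]; ++g)
          ph[g] = pmod(ph[g] + prm_val[prm_off[e] + j++]);
      } else {                               // pull toward a target phase vector
        const double s = prm_strength[e];
        for (int g = koff[c]; g < koff[c + 1]; ++g) {
          ph[g] = pmod(ph[g] + s * std::sin(prm_val[prm_off[e] + j++] - ph[g]));
        }
      }
      rearm(c, ev.t);
    } else {                                 // external stimulus event
      const int i = ev.aux;
      const int c = st_clock[i];
      wind_to(c, ev.t);
      const int g = koff[c] + st_phase[i];
      ph[g] = (st_mode[i] == 1) ? pmod(st_value[i]) : pmod(ph[g] + st_value[i]);
      rearm(c, ev.t);
    }
  }
  take_samples_until(t_end);

  return List::create(
      _["sample_times"] = sample_times,
      _["phases"] = samples,
      _["ev_edge"] = wrap(ev_edge),
      _["ev_emit"] = wrap(ev_emit),
      _["ev_arrival"] = wrap(ev_arr));
}
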