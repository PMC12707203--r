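// Discrete-event core for the WSLS agent simulation.
//
// Each of Nu users emits an open-loop Poisson stream of requests to its
// current server (several requests may be in flight). A request travels a
// deterministic one-way latency d_i, is blocked if it finds the k-place
// buffer full (loss), otherwise is served FCFS by one of c exponential
// processors. The user learns the outcome after the return latency; a
// delivered response is a failure when its return delay exceeds the timeout
// tau. When an agent's per-stay failure counter reaches its tolerance for
// the current server it shifts (optionally updating its failure-probability
// estimates and tolerance vector first) and resets the counter. Outcomes of
// requests sent before a shift still count in the system metrics but never
// toward the new stay's counter.
//
// Determinism contract: one mt19937_64 engine keyed by the config seed, with
// hand-rolled uniform/exponential transforms; event ties broken by insertion
// sequence number.

#include <Rcpp.h>
#include <queue>
#include <deque>
#include <vector>
#include <cstdint>
#include <cmath>
#include <random>
using namespace Rcpp;

namespace {

struct SimRng {
  std::mt19937_64 eng;
  explicit SimRng(uint64_t seed) : eng(seed) {}
  double unif() {  // (0,1), 53-bit
    return ((eng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double expo(double rate) { return -std::log(unif()) / rate; }
  int below(int n) {  // uniform on {0, ..., n-1}
    int r = static_cast<int>(unif() * n);
    return r >= n ? n - 1 : r;
  }
};

enum EvType { EMIT = 0, ARRIVE = 1, DEPART = 2, DELIVER = 3, SAMPLE = 4, BREAKPT = 5 };

struct Event {
  double t;
  uint64_t seq;
  int type;
  int a;  // user (EMIT) or request id (ARRIVE/DEPART/DELIVER)
  int b;  // emission epoch (EMIT)
};
struct EventLater {
  bool operator()(const Event& x, const Event& y) const {
    if (x.t != y.t) return x.t > y.t;
    return x.seq > y.seq;
  }
};

struct Request {
  int user, server;
  double t_emit;
  uint64_t stay;
  int failed;
};

struct Server {
  double mu, d;
  int c, k;
  int in_system = 0, busy = 0;
  std::deque<int> waitq;
};

struct User {
  int server;
  uint64_t stay = 0;
  int failcnt = 0;
  long attempts = 0;  // outcomes observed during the current stay (R)
};

}  // namespace

// [[Rcpp::export(name = ".des_run")]]
List des_run(int Nu,
             NumericVector mu, NumericVector d, IntegerVector cproc,
             IntegerVector kbuf,
             double tau, int latency_factor,
             NumericVector seg_end,     // cumulative schedule breakpoints
             NumericVector seg_lambda,  // per-user rate on each segment
             double duration, double sample_dt,
             int adaptive, double beta, double x0,
             IntegerMatrix tol_init,    // Nu x Ng
             int shift_proportional,
             IntegerVector init_assign, // length Nu, 0-based; -1 = random
             double seed) {
  const int Ng = mu.size();
  if (Ng < 2) stop("shifting is undefined with fewer than 2 goods");
  SimRng rng(static_cast<uint64_t>(seed));

  std::vector<Server> srv(Ng);
  for (int i = 0; i < Ng; ++i) {
    srv[i].mu = mu[i]; srv[i].d = d[i];
    srv[i].c = cproc[i]; srv[i].k = kbuf[i];
  }
  std::vector<User> usr(Nu);
  std::vector<int> occ(Ng, 0);
  std::vector<int> tol(static_cast<size_t>(Nu) * Ng);
  std::vector<double> est(static_cast<size_t>(Nu) * Ng, x0);
  std::vector<double> tol_sum(Ng, 0.0);  // population totals per server
  for (int u = 0; u < Nu; ++u) {
    int s = init_assign[u] >= 0 ? init_assign[u] : rng.below(Ng);
    usr[u].server = s;
    occ[s]++;
    for (int i = 0; i < Ng; ++i) {
      tol[static_cast<size_t>(u) * Ng + i] = tol_init(u, i);
      tol_sum[i] += tol_init(u, i);
    }
  }

  std::priority_queue<Event, std::vector<Event>, EventLater> pq;
  uint64_t seq = 0;
  auto push = [&](double t, int type, int a, int b) {
    if (t <= duration) pq.push(Event{t, seq++, type, a, b});
  };

  // request pool
  std::vector<Request> req;
  std::vector<int> freelist;
  auto new_req = [&](int user, int server, double t_emit, uint64_t stay) {
    int id;
    if (!freelist.empty()) { id = freelist.back(); freelist.pop_back(); }
    else { id = static_cast<int>(req.size()); req.push_back(Request{}); }
    req[id] = Request{user, server, t_emit, stay, 0};
    return id;
  };

  // workload schedule
  int nseg = seg_end.size();
  int epoch = 0;
  double lambda = seg_lambda[0];
  for (int s = 1; s < nseg; ++s) push(seg_end[s - 1], BREAKPT, s, 0);
  if (lambda > 0)
    for (int u = 0; u < Nu; ++u) push(rng.expo(lambda), EMIT, u, epoch);

  // sampling
  int nsamp = static_cast<int>(std::floor(duration / sample_dt + 1e-9));
  for (int s = 1; s <= nsamp; ++s)
    push(std::min(s * sample_dt, duration), SAMPLE, s - 1, 0);
  NumericVector out_t(nsamp);
  IntegerMatrix out_occ(nsamp, Ng);
  NumericMatrix out_att(nsamp, Ng), out_fail(nsamp, Ng),
      out_rate(nsamp, Ng), out_meant(nsamp, Ng);
  NumericVector out_sys(nsamp);
  std::vector<double> win_att(Ng, 0.0), win_fail(Ng, 0.0);
  double tot_att = 0, tot_fail = 0;

  auto do_shift = [&](int u, int s) {
    size_t base = static_cast<size_t>(u) * Ng;
    if (adaptive) {
      long R = usr[u].attempts;
      if (R < tol[base + s]) stop("internal: attempts R below tolerance at shift");
      est[base + s] = (1.0 - beta) * est[base + s] +
                      beta * static_cast<double>(tol[base + s]) / R;
      // move one tolerance unit toward the lowest estimated failure
      double xmin = est[base];
      for (int j = 1; j < Ng; ++j) if (est[base + j] < xmin) xmin = est[base + j];
      int nmin = 0, pick = -1;
      for (int j = 0; j < Ng; ++j) if (est[base + j] == xmin) nmin++;
      int which = rng.below(nmin);  // uniform among tied minima
      for (int j = 0, c2 = 0; j < Ng; ++j)
        if (est[base + j] == xmin && c2++ == which) { pick = j; break; }
      if (est[base + pick] < est[base + s] && tol[base + s] > 1) {
        tol[base + s]--; tol_sum[s] -= 1.0;
        tol[base + pick]++; tol_sum[pick] += 1.0;
      }
    }
    // destination
    int dest;
    if (shift_proportional) {
      double tot = 0;
      for (int j = 0; j < Ng; ++j) if (j != s) tot += tol[base + j];
      if (tot <= 0) stop("proportional shift rule: all other goods have zero tolerance");
      double r = rng.unif() * tot, acc = 0;
      dest = -1;
      for (int j = 0; j < Ng; ++j) {
        if (j == s) continue;
        acc += tol[base + j];
        if (r <= acc) { dest = j; break; }
      }
      if (dest < 0) for (int j = Ng - 1; j >= 0; --j) if (j != s) { dest = j; break; }
    } else {
      int r = rng.below(Ng - 1);
      dest = r >= s ? r + 1 : r;
    }
    occ[s]--; occ[dest]++;
    usr[u].server = dest;
    usr[u].stay++;
    usr[u].failcnt = 0;
    usr[u].attempts = 0;
  };

  while (!pq.empty()) {
    Event ev = pq.top(); pq.pop();
    double t = ev.t;
    switch (ev.type) {
      case EMIT: {
        if (ev.b != epoch) break;  // stale schedule epoch
        int u = ev.a;
        if (lambda > 0) push(t + rng.expo(lambda), EMIT, u, epoch);
        int s = usr[u].server;
        int id = new_req(u, s, t, usr[u].stay);
        push(t + srv[s].d, ARRIVE, id, 0);
        break;
      }
      case ARRIVE: {
        int id = ev.a;
        Server& S = srv[req[id].server];
        if (S.in_system >= S.k) {
          req[id].failed = 1;  // loss: user learns after the return leg
          push(t + S.d, DELIVER, id, 0);
        } else {
          S.in_system++;
          if (S.busy < S.c) {
            S.busy++;
            push(t + rng.expo(S.mu), DEPART, id, 0);
          } else S.waitq.push_back(id);
        }
        break;
      }
      case DEPART: {
        int id = ev.a;
        Server& S = srv[req[id].server];
        S.in_system--; S.busy--;
        if (!S.waitq.empty()) {
          int nxt = S.waitq.front(); S.waitq.pop_front();
          S.busy++;
          push(t + rng.expo(S.mu), DEPART, nxt, 0);
        }
        double delay = (latency_factor == 2)
                           ? (t + S.d - req[id].t_emit)   // out + wait + service + back
                           : (t - req[id].t_emit);        // out + wait + service
        req[id].failed = delay > tau ? 1 : 0;
        push(t + S.d, DELIVER, id, 0);
        break;
      }
      case DELIVER: {
        int id = ev.a;
        int u = req[id].user, s = req[id].server;
        win_att[s] += 1; tot_att += 1;
        if (req[id].failed) { win_fail[s] += 1; tot_fail += 1; }
        if (req[id].stay == usr[u].stay) {
          usr[u].attempts++;
          if (req[id].failed) {
            usr[u].failcnt++;
            if (usr[u].failcnt >= tol[static_cast<size_t>(u) * Ng + s])
              do_shift(u, s);
          }
        }
        freelist.push_back(id);
        break;
      }
      case SAMPLE: {
        int s = ev.a;
        out_t[s] = t;
        double wa = 0, wf = 0;
        for (int i = 0; i < Ng; ++i) {
          out_occ(s, i) = occ[i];
          out_att(s, i) = win_att[i];
          out_fail(s, i) = win_fail[i];
          out_rate(s, i) = win_att[i] > 0 ? win_fail[i] / win_att[i] : 0.0;
          out_meant(s, i) = tol_sum[i] / Nu;
          wa += win_att[i]; wf += win_fail[i];
          win_att[i] = 0; win_fail[i] = 0;
        }
        out_sys[s] = wa > 0 ? wf / wa : 0.0;
        break;
      }
      case BREAKPT: {
        lambda = seg_lambda[ev.a];
        epoch++;
        if (lambda > 0)
          for (int u = 0; u < Nu; ++u) push(t + rng.expo(lambda), EMIT, u, epoch);
        break;
      }
    }
  }

  IntegerMatrix tol_final(Nu, Ng);
  IntegerVector assign_final(Nu);
  for (int u = 0; u < Nu; ++u) {
    assign_final[u] = usr[u].server;
    for (int i = 0; i < Ng; ++i)
      tol_final(u, i) = tol[static_cast<size_t>(u) * Ng + i];
  }
  return List::create(
      _["t"] = out_t, _["occupancy"] = out_occ,
      _["attempts"] = out_att, _["failures"] = out_fail,
      _["fail_rate"] = out_rate, _["sys_fail"] = out_sys,
      _["mean_tol"] = out_meant,
      _["tol_final"] = tol_final, _["assign_final"] = assign_final,
      _["total_attempts"] = tot_att, _["total_failures"] = tot_fail);
}
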