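// Discrete-event core for whole-hospital patient flow.
//
// All randomness is drawn on the R side: the engine receives a fully
// materialised patient table (arrival times, triage, admission decisions,
// class, and every length-of-stay draw) and is itself deterministic.
// Units: ED admission side, AMU, medical ward, surgical ward.
//
// Bed semantics: an admitted ED patient boards in (keeps occupying) an ED
// bed until an inpatient bed frees; a medical patient who finishes the AMU
// leg boards in the AMU bed until a medical-ward bed frees. Queue discipline
// everywhere: triage ascending (urgent first), then request time, then id.

#include <Rcpp.h>
#include <queue>
#include <deque>
#include <set>
#include <vector>
#include <tuple>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

enum Loc {
  GONE = 0,     // exited (see dispo) or not yet arrived
  ED_WAIT = 1,  // waiting for ED treatment space
  ED_TREAT = 2, // in ED bed, under treatment
  ED_BOARD = 3, // admitted, boarding in ED bed
  IN_AMU = 4,   // in AMU bed, on AMU leg
  AMU_BOARD = 5,// finished AMU leg, boarding in AMU bed
  IN_MED = 6,
  IN_SURG = 7,
  SURG_WAIT = 8,// elective waiting for a surgical bed (holds no bed)
  BACKLOG = 9   // postponed elective awaiting rescheduling
};

enum Dispo {
  IN_SYSTEM = 0,
  ED_DISCHARGED = 1,
  COMPLETED = 2,
  TRANSFERRED = 3,
  DIVERTED = 4,
  EARLY_DISCHARGED = 5,
  IN_BACKLOG = 6
};

enum EvType { EV_ED_END = 0, EV_AMU_END = 1, EV_WARD_END = 2 };

struct Ev {
  double t;
  int type, pid, epoch;
};
struct EvCmp {
  bool operator()(const Ev& a, const Ev& b) const {
    if (a.t != b.t) return a.t > b.t;
    if (a.type != b.type) return a.type > b.type;
    return a.pid > b.pid;
  }
};

typedef std::tuple<int, double, int> QKey; // (triage, request time, pid)
typedef std::set<QKey> PQueue;

struct Engine {
  // ---- patient table (inputs) ----
  int n;
  const double *t_arr, *ed_los, *amu_los, *ward_los;
  const int *stream, *mode, *triage;
  const int *admitted, *cls; // cls: 0 medical, 1 surgical

  // ---- parameters ----
  int cap_base[4];   // ED, AMU, MED, SURG
  int delta[4];
  bool episodic;
  int thr_ed, thr_queue;
  double thr_occ;
  bool conjunctive;
  int transfer_n, discharge_any_n, discharge_med_n, discharge_surg_n;
  int postpone_n, divert_n;
  bool allow_fallback;
  int horizon;
  double dw_start, dw_len; // daily inpatient discharge window; dw_len 0 = off

  // ---- state ----
  int cap[4];
  int occ[4];
  PQueue ed_wait, med_q, surg_q;
  std::deque<int> backlog;
  std::priority_queue<Ev, std::vector<Ev>, EvCmp> heap;
  std::vector<int> loc, dispo, epoch;
  std::vector<double> req_time, sched_end;
  // milestones
  std::vector<double> m_ed_bed, m_admit_req, m_ward_bed, m_exit;

  bool in_episode, activated;
  int ep_start, divert_quota, postpone_pending;
  bool cap_violation;

  // ---- outputs ----
  std::vector<int> sn_ed_occ, sn_queue, sn_inp_occ, sn_inp_cap, sn_congested;
  std::vector<int> ep_s, ep_e;
  std::vector<double> iv_time;
  std::vector<int> iv_action, iv_pid, iv_ep_start;
  long n_transferred, n_discharged, n_postponed, n_diverted, n_activations;

  void init(int n_) {
    n = n_;
    loc.assign(n, GONE); dispo.assign(n, IN_SYSTEM); epoch.assign(n, 0);
    req_time.assign(n, NA_REAL); sched_end.assign(n, NA_REAL);
    m_ed_bed.assign(n, NA_REAL); m_admit_req.assign(n, NA_REAL);
    m_ward_bed.assign(n, NA_REAL); m_exit.assign(n, NA_REAL);
    for (int u = 0; u < 4; ++u) {
      cap[u] = cap_base[u] + (episodic ? 0 : delta[u]);
      occ[u] = 0;
    }
    in_episode = false; activated = false; ep_start = -1;
    divert_quota = 0; postpone_pending = 0; cap_violation = false;
    n_transferred = n_discharged = n_postponed = n_diverted = 0;
    n_activations = 0;
    sn_ed_occ.reserve(horizon); sn_queue.reserve(horizon);
    sn_inp_occ.reserve(horizon); sn_inp_cap.reserve(horizon);
    sn_congested.reserve(horizon);
  }

  void push_ev(double t, int type, int pid) {
    Ev e; e.t = t; e.type = type; e.pid = pid; e.epoch = epoch[pid];
    heap.push(e);
  }
  void log_iv(double t, int action, int pid) {
    iv_time.push_back(t); iv_action.push_back(action);
    iv_pid.push_back(pid); iv_ep_start.push_back(ep_start);
  }

  // Ward discharges happen inside a daily window: a scheduled end falling
  // outside it is deferred to the next window, placed deterministically by
  // the fractional hour of the raw end time.
  double adjust_exit(double end) const {
    if (dw_len <= 0) return end;
    double hod = end - std::floor(end / 24.0) * 24.0;
    if (hod >= dw_start && hod < dw_start + dw_len) return end;
    double frac = end - std::floor(end);
    double cand = std::floor(end / 24.0) * 24.0 + dw_start + dw_len * frac;
    if (cand <= end) cand += 24.0;
    return cand;
  }

  // ---- seating ----
  void seat_ed(int pid, double t) {
    loc[pid] = ED_TREAT; ++occ[0]; ++epoch[pid];
    m_ed_bed[pid] = t; sched_end[pid] = t + ed_los[pid];
    push_ev(sched_end[pid], EV_ED_END, pid);
  }
  void seat_amu(int pid, double t) { // fresh AMU leg
    loc[pid] = IN_AMU; ++occ[1]; ++epoch[pid];
    if (ISNA(m_ward_bed[pid])) m_ward_bed[pid] = t;
    sched_end[pid] = t + amu_los[pid];
    push_ev(sched_end[pid], EV_AMU_END, pid);
  }
  void seat_med(int pid, double t, double dur) {
    loc[pid] = IN_MED; ++occ[2]; ++epoch[pid];
    if (ISNA(m_ward_bed[pid])) m_ward_bed[pid] = t;
    sched_end[pid] = adjust_exit(t + dur);
    push_ev(sched_end[pid], EV_WARD_END, pid);
  }
  void seat_surg(int pid, double t) {
    loc[pid] = IN_SURG; ++occ[3]; ++epoch[pid];
    if (ISNA(m_ward_bed[pid])) m_ward_bed[pid] = t;
    sched_end[pid] = adjust_exit(t + ward_los[pid]);
    push_ev(sched_end[pid], EV_WARD_END, pid);
  }

  // ---- queue fills (each drains as far as capacity allows) ----
  void fill_ed(double t) {
    while (occ[0] < cap[0] && !ed_wait.empty()) {
      int pid = std::get<2>(*ed_wait.begin());
      ed_wait.erase(ed_wait.begin());
      seat_ed(pid, t);
    }
  }
  // seat ED medical boarders into a free AMU bed
  void fill_amu(double t) {
    while (occ[1] < cap[1]) {
      PQueue::iterator pick = med_q.end();
      for (PQueue::iterator it = med_q.begin(); it != med_q.end(); ++it) {
        if (loc[std::get<2>(*it)] == ED_BOARD) { pick = it; break; }
      }
      if (pick == med_q.end()) break;
      int pid = std::get<2>(*pick);
      med_q.erase(pick);
      seat_amu(pid, t);
      --occ[0]; fill_ed(t);
    }
  }
  void fill_med(double t) {
    while (occ[2] < cap[2] && !med_q.empty()) {
      int pid = std::get<2>(*med_q.begin());
      med_q.erase(med_q.begin());
      if (loc[pid] == AMU_BOARD) {
        seat_med(pid, t, ward_los[pid]);
        --occ[1]; fill_amu(t);
      } else { // ED boarder goes direct: AMU leg folded into ward stay
        seat_med(pid, t, amu_los[pid] + ward_los[pid]);
        --occ[0]; fill_ed(t);
      }
    }
  }
  void fill_surg(double t) {
    while (occ[3] < cap[3]) {
      if (!surg_q.empty()) {
        int pid = std::get<2>(*surg_q.begin());
        bool was_board = (loc[pid] == ED_BOARD);
        surg_q.erase(surg_q.begin());
        seat_surg(pid, t);
        if (was_board) { --occ[0]; fill_ed(t); }
      } else if (!in_episode && !backlog.empty()) {
        int pid = backlog.front(); backlog.pop_front();
        seat_surg(pid, t);
      } else break;
    }
  }
  void fill_all(double t) { fill_med(t); fill_surg(t); fill_amu(t); fill_ed(t); }

  // ---- event handlers ----
  void handle_arrival(int pid, double t) {
    if (stream[pid] == 0) { // ED arrival
      if (mode[pid] == 1 && divert_quota > 0) {
        loc[pid] = GONE; dispo[pid] = DIVERTED; m_exit[pid] = t;
        --divert_quota; ++n_diverted;
        log_iv(t, 4, pid);
        return;
      }
      if (occ[0] < cap[0]) seat_ed(pid, t);
      else { loc[pid] = ED_WAIT; req_time[pid] = t;
             ed_wait.insert(QKey(triage[pid], t, pid)); }
    } else { // elective
      if (postpone_pending > 0) {
        loc[pid] = BACKLOG; backlog.push_back(pid);
        --postpone_pending; ++n_postponed;
        log_iv(t, 3, pid);
        return;
      }
      // outside episodes, the oldest backlog patients take free beds
      // before a newly arriving elective
      if (!in_episode) {
        while (occ[3] < cap[3] && surg_q.empty() && !backlog.empty()) {
          int b = backlog.front(); backlog.pop_front();
          seat_surg(b, t);
        }
      }
      if (occ[3] < cap[3] && surg_q.empty()) {
        seat_surg(pid, t);
      } else {
        loc[pid] = SURG_WAIT; req_time[pid] = t;
        surg_q.insert(QKey(triage[pid], t, pid));
      }
    }
  }

  void handle_ed_end(int pid, double t) {
    if (!admitted[pid]) {
      loc[pid] = GONE; dispo[pid] = ED_DISCHARGED; m_exit[pid] = t;
      ++epoch[pid];
      --occ[0]; fill_ed(t);
      return;
    }
    m_admit_req[pid] = t; ++epoch[pid];
    if (cls[pid] == 0) { // medical: AMU if free, else ward, else board
      if (occ[1] < cap[1]) { seat_amu(pid, t); --occ[0]; fill_ed(t); }
      else if (occ[2] < cap[2]) {
        seat_med(pid, t, amu_los[pid] + ward_los[pid]);
        --occ[0]; fill_ed(t);
      } else {
        loc[pid] = ED_BOARD; req_time[pid] = t;
        med_q.insert(QKey(triage[pid], t, pid));
      }
    } else {
      if (occ[3] < cap[3]) { seat_surg(pid, t); --occ[0]; fill_ed(t); }
      else {
        loc[pid] = ED_BOARD; req_time[pid] = t;
        surg_q.insert(QKey(triage[pid], t, pid));
      }
    }
  }

  void handle_amu_end(int pid, double t) {
    ++epoch[pid];
    if (occ[2] < cap[2]) {
      seat_med(pid, t, ward_los[pid]);
      --occ[1]; fill_amu(t);
    } else {
      loc[pid] = AMU_BOARD; req_time[pid] = t;
      med_q.insert(QKey(triage[pid], t, pid));
    }
  }

  void handle_ward_end(int pid, double t) {
    int was = loc[pid];
    loc[pid] = GONE; dispo[pid] = COMPLETED; m_exit[pid] = t; ++epoch[pid];
    if (was == IN_MED) { --occ[2]; fill_med(t); }
    else { --occ[3]; fill_surg(t); }
  }

  // ---- interventions ----
  void remove_from_queue(PQueue& q, int pid) {
    q.erase(QKey(triage[pid], req_time[pid], pid));
  }

  void do_transfers(double t) {
    if (transfer_n <= 0) return;
    // ED boarders: least urgent (triage desc) first, then longest boarding
    std::vector<int> pool;
    for (PQueue::const_iterator it = med_q.begin(); it != med_q.end(); ++it)
      if (loc[std::get<2>(*it)] == ED_BOARD) pool.push_back(std::get<2>(*it));
    for (PQueue::const_iterator it = surg_q.begin(); it != surg_q.end(); ++it)
      if (loc[std::get<2>(*it)] == ED_BOARD) pool.push_back(std::get<2>(*it));
    std::sort(pool.begin(), pool.end(), [this](int a, int b) {
      if (triage[a] != triage[b]) return triage[a] > triage[b];
      if (req_time[a] != req_time[b]) return req_time[a] < req_time[b];
      return a < b;
    });
    int k = std::min((int)pool.size(), transfer_n);
    for (int i = 0; i < k; ++i) {
      int pid = pool[i];
      if (cls[pid] == 0) remove_from_queue(med_q, pid);
      else remove_from_queue(surg_q, pid);
      loc[pid] = GONE; dispo[pid] = TRANSFERRED; m_exit[pid] = t;
      ++epoch[pid]; --occ[0]; ++n_transferred;
      log_iv(t, 1, pid);
    }
  }

  // remaining hours to scheduled final discharge, used to pick
  // nearest-to-discharge inpatients
  double remaining_h(int pid, double t) const {
    switch (loc[pid]) {
      case IN_AMU:    return (sched_end[pid] - t) + ward_los[pid];
      case AMU_BOARD: return ward_los[pid];
      default:        return sched_end[pid] - t;
    }
  }

  void discharge_one(int pid, double t) {
    int was = loc[pid];
    loc[pid] = GONE; dispo[pid] = EARLY_DISCHARGED; m_exit[pid] = t;
    ++epoch[pid]; ++n_discharged;
    log_iv(t, 2, pid);
    if (was == IN_AMU) --occ[1];
    else if (was == AMU_BOARD) { remove_from_queue(med_q, pid); --occ[1]; }
    else if (was == IN_MED) --occ[2];
    else --occ[3];
  }

  std::vector<int> discharge_pool(double t, int want_cls) {
    // want_cls: -1 any, 0 medical units (AMU/med), 1 surgical ward
    std::vector<int> pool;
    for (int pid = 0; pid < n; ++pid) {
      int l = loc[pid];
      bool med_unit = (l == IN_AMU || l == AMU_BOARD || l == IN_MED);
      bool surg_unit = (l == IN_SURG);
      if (!med_unit && !surg_unit) continue;
      if (want_cls == 0 && !med_unit) continue;
      if (want_cls == 1 && !surg_unit) continue;
      pool.push_back(pid);
    }
    return pool;
  }

  int pick_discharges(double t, int want_cls, int k) {
    if (k <= 0) return 0;
    std::vector<int> pool = discharge_pool(t, want_cls);
    std::vector<int> elig;
    for (size_t i = 0; i < pool.size(); ++i)
      if (triage[pool[i]] >= 4) elig.push_back(pool[i]);
    if (allow_fallback && (int)elig.size() < k)
      for (size_t i = 0; i < pool.size(); ++i)
        if (triage[pool[i]] == 3) elig.push_back(pool[i]);
    // nearest-to-scheduled-discharge first within the eligible tier
    // (triage >= 4 pool before any fallback triage-3 pool)
    std::sort(elig.begin(), elig.end(), [this, t](int a, int b) {
      int ta = triage[a] >= 4 ? 0 : 1, tb = triage[b] >= 4 ? 0 : 1;
      if (ta != tb) return ta < tb;
      double ra = remaining_h(a, t), rb = remaining_h(b, t);
      if (ra != rb) return ra < rb;
      return a < b;
    });
    int done = std::min((int)elig.size(), k);
    for (int i = 0; i < done; ++i) discharge_one(elig[i], t);
    return done;
  }

  void do_postpones(double t) {
    if (postpone_n <= 0) return;
    // defer the most recently scheduled waiting electives first
    std::vector<int> waiting;
    for (PQueue::const_iterator it = surg_q.begin(); it != surg_q.end(); ++it)
      if (loc[std::get<2>(*it)] == SURG_WAIT) waiting.push_back(std::get<2>(*it));
    std::sort(waiting.begin(), waiting.end(), [this](int a, int b) {
      if (req_time[a] != req_time[b]) return req_time[a] > req_time[b];
      return a > b;
    });
    int k = std::min((int)waiting.size(), postpone_n);
    for (int i = 0; i < k; ++i) {
      int pid = waiting[i];
      remove_from_queue(surg_q, pid);
      loc[pid] = BACKLOG; backlog.push_back(pid);
      ++n_postponed;
      log_iv(t, 3, pid);
    }
    postpone_pending = postpone_n - k;
  }

  void activate(double t) {
    activated = true; ++n_activations;
    if (episodic) for (int u = 0; u < 4; ++u) cap[u] = cap_base[u] + delta[u];
    do_transfers(t);
    pick_discharges(t, 0, discharge_med_n);
    pick_discharges(t, 1, discharge_surg_n);
    pick_discharges(t, -1, discharge_any_n);
    do_postpones(t);
    divert_quota = divert_n;
    fill_all(t);
  }

  void close_episode(int h) {
    ep_s.push_back(ep_start); ep_e.push_back(h);
    in_episode = false; activated = false;
    divert_quota = 0; postpone_pending = 0;
    if (episodic) for (int u = 0; u < 4; ++u) cap[u] = cap_base[u];
    fill_all((double)h); // drain backlog / seat queues after episode
  }

  void hourly_check(int h) {
    int inp_occ = occ[1] + occ[2] + occ[3];
    int inp_cap = cap[1] + cap[2] + cap[3];
    double frac = inp_cap > 0 ? (double)inp_occ / inp_cap : 0.0;
    int qlen = (int)ed_wait.size();
    bool c_ed = occ[0] >= thr_ed;
    bool c_occ = frac >= thr_occ - 1e-12;
    bool c_q = qlen >= thr_queue;
    bool congested = conjunctive ? (c_ed && c_occ && c_q)
                                 : (c_ed || c_occ || c_q);
    sn_ed_occ.push_back(occ[0]); sn_queue.push_back(qlen);
    sn_inp_occ.push_back(inp_occ); sn_inp_cap.push_back(inp_cap);
    sn_congested.push_back(congested ? 1 : 0);
    for (int u = 0; u < 4; ++u)
      if (occ[u] > cap[u] && !episodic) cap_violation = true;

    if (congested) {
      if (!in_episode) { in_episode = true; activated = false; ep_start = h; }
      else if (!activated && h == ep_start + 1) activate((double)h);
    } else if (in_episode) {
      close_episode(h);
    }
  }

  void run() {
    int ai = 0;       // next arrival index
    int next_h = 0;   // next hourly check
    while (true) {
      double t_ev = heap.empty() ? R_PosInf : heap.top().t;
      double t_ar = ai < n ? t_arr[ai] : R_PosInf;
      double t_h = next_h < horizon ? (double)next_h : R_PosInf;
      double tmin = std::min(t_ev, std::min(t_ar, t_h));
      if (tmin >= (double)horizon) break; // nothing after the horizon matters
      if (t_ev <= t_ar && t_ev <= t_h) {
        Ev e = heap.top(); heap.pop();
        if (e.epoch != epoch[e.pid]) continue; // stale (patient moved on)
        if (e.type == EV_ED_END) handle_ed_end(e.pid, e.t);
        else if (e.type == EV_AMU_END) handle_amu_end(e.pid, e.t);
        else handle_ward_end(e.pid, e.t);
      } else if (t_ar <= t_h) {
        handle_arrival(ai, t_ar); ++ai;
      } else {
        hourly_check(next_h); ++next_h;
      }
    }
    if (in_episode) { ep_s.push_back(ep_start); ep_e.push_back(horizon); }
  }
};

} // namespace

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(NumericVector t_arr, IntegerVector stream, IntegerVector mode,
              IntegerVector triage, IntegerVector admitted, IntegerVector cls,
              NumericVector ed_los, NumericVector amu_los,
              NumericVector ward_los,
              IntegerVector cap, IntegerVector delta, bool episodic,
              int thr_ed, double thr_occ, int thr_queue, bool conjunctive,
              IntegerVector actions, bool allow_fallback, int horizon,
              double dw_start, double dw_len) {
  int n = t_arr.size();
  for (int i = 1; i < n; ++i)
    if (t_arr[i] < t_arr[i - 1]) stop("arrival times must be non-decreasing");

  Engine eng;
  eng.t_arr = REAL(t_arr); eng.ed_los = REAL(ed_los);
  eng.amu_los = REAL(amu_los); eng.ward_los = REAL(ward_los);
  eng.stream = INTEGER(stream); eng.mode = INTEGER(mode);
  eng.triage = INTEGER(triage); eng.admitted = INTEGER(admitted);
  eng.cls = INTEGER(cls);
  for (int u = 0; u < 4; ++u) {
    eng.cap_base[u] = cap[u];
    eng.delta[u] = delta[u];
  }
  eng.episodic = episodic;
  eng.thr_ed = thr_ed; eng.thr_occ = thr_occ; eng.thr_queue = thr_queue;
  eng.conjunctive = conjunctive;
  eng.transfer_n = actions[0];
  eng.discharge_any_n = actions[1];
  eng.discharge_med_n = actions[2];
  eng.discharge_surg_n = actions[3];
  eng.postpone_n = actions[4];
  eng.divert_n = actions[5];
  eng.allow_fallback = allow_fallback;
  eng.horizon = horizon;
  eng.dw_start = dw_start; eng.dw_len = dw_len;
  eng.init(n);
  eng.run();

  // final dispositions
  IntegerVector fin(n);
  for (int i = 0; i < n; ++i) {
    if (eng.loc[i] == GONE) fin[i] = eng.dispo[i];
    else if (eng.loc[i] == BACKLOG) fin[i] = IN_BACKLOG;
    else fin[i] = IN_SYSTEM;
  }

  return List::create(
    _["snapshots"] = List::create(
      _["ed_occupied"] = wrap(eng.sn_ed_occ),
      _["ed_queue_len"] = wrap(eng.sn_queue),
      _["inpatient_occupied"] = wrap(eng.sn_inp_occ),
      _["inpatient_capacity"] = wrap(eng.sn_inp_cap),
      _["congested"] = wrap(eng.sn_congested)),
    _["patients"] = List::create(
      _["t_ed_bed"] = wrap(eng.m_ed_bed),
      _["t_admit_request"] = wrap(eng.m_admit_req),
      _["t_ward_bed"] = wrap(eng.m_ward_bed),
      _["t_exit"] = wrap(eng.m_exit),
      _["disposition"] = fin),
    _["episodes"] = List::create(
      _["start_h"] = wrap(eng.ep_s),
      _["end_h"] = wrap(eng.ep_e)),
    _["interventions"] = List::create(
      _["time_h"] = wrap(eng.iv_time),
      _["action"] = wrap(eng.iv_action),
      _["patient"] = wrap(eng.iv_pid),
      _["episode_start_h"] = wrap(eng.iv_ep_start)),
    _["counters"] = List::create(
      _["transferred"] = (double)eng.n_transferred,
      _["early_discharged"] = (double)eng.n_discharged,
      _["postponed"] = (double)eng.n_postponed,
      _["diverted"] = (double)eng.n_diverted,
      _["activations"] = (double)eng.n_activations),
    _["capacity_violation"] = eng.cap_violation);
}
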