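// Stepping engine for the lattice tumor-immune model.
//
// All randomness is drawn from R's global RNG stream via unif_rand(), so a
// run is fully reproducible from set.seed(). The per-step draw order is
// fixed and documented: (1) DC vaccine placement (partial Fisher-Yates over
// the empty sites in column-major order), (2) no draws for the humoral/field
// updates, (3) a Fisher-Yates shuffle of the alive agents followed by each
// agent's interaction rule and then its movement. Agents are stored in
// creation order: the initial column-major scan of the occupancy matrix,
// then daughters/injected cells in order of appearance. Daughters created
// during a step act from the next step onward.
//
// The oxygen field is kept at block resolution: after each diffusion sweep
// every 3x3 block is uniform except for the re-imposed Dirichlet boundary
// sites, so the engine stores one interior value and one (boundary-aware)
// block mean per block instead of the full site grid. Site-level lookups
// and the exported state reconstruct the site values exactly.

#include <Rcpp.h>
#include <cmath>
#include <map>
#include <vector>

using namespace Rcpp;

namespace {

const int DR8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
const int DC8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

enum Kind {
  EMPTY = 0, TUMOR = 1, DC_IN = 2, DC_AC = 3, T_IN = 4, TREG = 5, EFF = 6
};

struct Pars {
  double gamma, a, r, beta, r_At, r_Ht, r_Ar, r_Hr, lambda_s, D_act, C_act,
      mu, r_Ae, r_He, D_inact, eta, k, P_Treg, P_tumor, f_bar, c, l, alpha,
      U_boundary, ode_dt;
  int M, N;
};

Pars read_pars(const List& p) {
  Pars q;
  q.gamma = as<double>(p["gamma"]);
  q.a = as<double>(p["a"]);
  q.r = as<double>(p["r"]);
  q.beta = as<double>(p["beta"]);
  q.r_At = as<double>(p["r_At"]);
  q.r_Ht = as<double>(p["r_Ht"]);
  q.r_Ar = as<double>(p["r_Ar"]);
  q.r_Hr = as<double>(p["r_Hr"]);
  q.lambda_s = as<double>(p["lambda_s"]);
  q.D_act = as<double>(p["D_act"]);
  q.C_act = as<double>(p["C_act"]);
  q.mu = as<double>(p["mu"]);
  q.r_Ae = as<double>(p["r_Ae"]);
  q.r_He = as<double>(p["r_He"]);
  q.D_inact = as<double>(p["D_inact"]);
  q.eta = as<double>(p["eta"]);
  q.k = as<double>(p["k"]);
  q.P_Treg = as<double>(p["P_Treg"]);
  q.P_tumor = as<double>(p["P_tumor"]);
  q.f_bar = as<double>(p["f_bar"]);
  q.c = as<double>(p["c"]);
  q.l = as<double>(p["l"]);
  q.alpha = as<double>(p["alpha"]);
  q.U_boundary = as<double>(p["U_boundary"]);
  q.M = as<int>(p["M"]);
  q.N = as<int>(p["N"]);
  // the adenosine balance is a daily-timescale ODE integrated at the
  // lattice step: dt_minutes minutes = dt_minutes/1440 days per step
  q.ode_dt = as<double>(p["dt_minutes"]) / 1440.0;
  return q;
}

inline double clamp01(double x) { return x < 0 ? 0 : (x > 1 ? 1 : x); }

// uniform index in 0..k-1 from one unif_rand() draw
inline int ridx(int k) {
  int j = (int)(unif_rand() * k);
  return j >= k ? k - 1 : j;
}

struct Agent {
  int kind, r, c, dir, steps;
  bool alive;
};

struct Sim {
  Pars P;
  int N, nb;
  std::vector<Agent> ag;
  std::vector<int> grid;     // col-major, agent index + 1, 0 = empty
  std::vector<double> vin;   // per-block interior site value
  std::vector<double> V;     // per-block mean (boundary sites included)
  std::vector<int> tcount;   // tumor sites per block
  std::vector<int> nbd;      // Dirichlet boundary sites per block
  double Ad, px, s_raw, S_t;
  std::vector<double> sbuf;
  int spos;
  long divisions, kills, dc_injected, dc_shortfall;
  // incremental bookkeeping of the tumor neighborhood (tumor sites and
  // their Moore neighbors): per-site cover counts, per-block covered
  // interior sites, and covered boundary sites
  std::vector<int> cover;
  std::vector<int> covint;
  long covbnd, cov_total;
  std::vector<double> A;  // scratch for diffuse()

  inline int idx(int i, int j) const { return i + N * j; }
  inline int bidx(int i, int j) const { return (i / 3) + nb * (j / 3); }
  inline bool inside(int i, int j) const {
    return i >= 0 && i < N && j >= 0 && j < N;
  }
  inline bool on_boundary(int i, int j) const {
    return i == 0 || i == N - 1 || j == 0 || j == N - 1;
  }
  // oxygen concentration at a site
  inline double uat(int i, int j) const {
    return on_boundary(i, j) ? P.U_boundary : vin[bidx(i, j)];
  }

  void from_state(const List& state) {
    N = P.N;
    nb = N / 3;
    IntegerMatrix kind = state["kind"];
    IntegerMatrix dir = state["dir"];
    IntegerMatrix steps = state["steps"];
    NumericMatrix Um = state["U"];
    if (kind.nrow() != N || kind.ncol() != N)
      stop("state grid does not match params$N");
    grid.assign((size_t)N * N, 0);
    ag.clear();
    for (int j = 0; j < N; ++j) {
      for (int i = 0; i < N; ++i) {
        int kk = kind(i, j);
        if (kk != 0) {
          Agent a;
          a.kind = kk;
          a.r = i;
          a.c = j;
          a.dir = dir(i, j);
          a.steps = steps(i, j);
          a.alive = true;
          ag.push_back(a);
          grid[idx(i, j)] = (int)ag.size();
        }
      }
    }
    V.assign((size_t)nb * nb, 0.0);
    vin.assign((size_t)nb * nb, 0.0);
    tcount.assign((size_t)nb * nb, 0);
    nbd.assign((size_t)nb * nb, 0);
    for (int bj = 0; bj < nb; ++bj) {
      for (int bi = 0; bi < nb; ++bi) {
        double s = 0;
        int b = bi + nb * bj;
        for (int j = 3 * bj; j < 3 * bj + 3; ++j) {
          for (int i = 3 * bi; i < 3 * bi + 3; ++i) {
            s += Um(i, j);
            if (on_boundary(i, j)) ++nbd[b];
            int a = grid[idx(i, j)];
            if (a && ag[a - 1].kind == TUMOR) ++tcount[b];
          }
        }
        V[b] = s / 9.0;
        vin[b] = V[b];  // only read after the first diffusion sweep
      }
    }
    Ad = as<double>(state["Ad"]);
    px = as<double>(state["px"]);
    s_raw = as<double>(state["s_raw"]);
    NumericVector sb = state["s_buf"];
    if ((int)sb.size() != P.M) stop("s_buf length does not match params$M");
    sbuf.assign(sb.begin(), sb.end());
    spos = as<int>(state["s_pos"]) - 1;  // R is 1-based
    if (spos < 0 || spos >= P.M) spos = 0;
    divisions = kills = dc_injected = dc_shortfall = 0;
    cover.assign((size_t)N * N, 0);
    covint.assign((size_t)nb * nb, 0);
    covbnd = cov_total = 0;
    for (size_t a = 0; a < ag.size(); ++a)
      if (ag[a].alive && ag[a].kind == TUMOR) cover_add(ag[a].r, ag[a].c);
  }

  void cover_add(int r0, int c0) {
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        int i = r0 + di, j = c0 + dj;
        if (!inside(i, j)) continue;
        if (cover[idx(i, j)]++ == 0) {
          if (on_boundary(i, j)) ++covbnd; else ++covint[bidx(i, j)];
          ++cov_total;
        }
      }
    }
  }

  void cover_remove(int r0, int c0) {
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        int i = r0 + di, j = c0 + dj;
        if (!inside(i, j)) continue;
        if (--cover[idx(i, j)] == 0) {
          if (on_boundary(i, j)) --covbnd; else --covint[bidx(i, j)];
          --cov_total;
        }
      }
    }
  }

  List to_state(int t_now) const {
    IntegerMatrix kind(N, N), dir(N, N), steps(N, N);
    NumericMatrix Um(N, N);
    std::fill(dir.begin(), dir.end(), -1);
    for (int j = 0; j < N; ++j)
      for (int i = 0; i < N; ++i) Um(i, j) = uat(i, j);
    for (size_t a = 0; a < ag.size(); ++a) {
      if (!ag[a].alive) continue;
      kind(ag[a].r, ag[a].c) = ag[a].kind;
      dir(ag[a].r, ag[a].c) = ag[a].dir;
      steps(ag[a].r, ag[a].c) = ag[a].steps;
    }
    NumericVector sb(sbuf.begin(), sbuf.end());
    return List::create(
        _["N"] = N, _["kind"] = kind, _["dir"] = dir, _["steps"] = steps,
        _["U"] = Um, _["Ad"] = Ad, _["px"] = px, _["s_raw"] = s_raw,
        _["s_buf"] = sb, _["s_pos"] = spos + 1, _["S_t"] = S_t,
        _["t"] = t_now);
  }

  // ---- humoral ----------------------------------------------------------

  void humoral_pre(double dose_px_amt, double dose_s_amt) {
    if (dose_px_amt > 0) px += dose_px_amt;
    px *= (1.0 - P.eta);
    if (dose_s_amt > 0) s_raw += dose_s_amt;
    s_raw *= (1.0 - P.lambda_s);
    sbuf[spos] = s_raw;
    spos = (spos + 1) % P.M;
    double ss = 0;
    for (int i = 0; i < P.M; ++i) ss += sbuf[i];
    S_t = ss / P.M;
  }

  void adenosine_step(double Ue) {
    Ad = Ad + (P.beta + P.a / (Ue + P.c) - P.r * Ad - P.gamma * S_t * Ad) *
                  P.ode_dt;
    if (Ad < 0) Ad = 0;
  }

  // ---- oxygen -----------------------------------------------------------

  void diffuse() {
    A.assign((size_t)nb * nb, 0.0);
    for (int bj = 0; bj < nb; ++bj) {
      for (int bi = 0; bi < nb; ++bi) {
        double s = 0;
        int cnt = 0;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            int ii = bi + di, jj = bj + dj;
            if (ii >= 0 && ii < nb && jj >= 0 && jj < nb) {
              s += V[ii + nb * jj];
              ++cnt;
            }
          }
        }
        A[bi + nb * bj] = s / cnt;
      }
    }
    for (int b = 0; b < nb * nb; ++b) {
      double nv = P.alpha * A[b] + (1.0 - P.alpha) * V[b] -
                  P.f_bar * (tcount[b] / 9.0) + P.k * px;
      if (nv < 0) nv = 0;
      vin[b] = nv;
      // block mean after the Dirichlet boundary is re-imposed
      V[b] = nbd[b] == 0
                 ? nv
                 : (nv * (9 - nbd[b]) + P.U_boundary * nbd[b]) / 9.0;
    }
  }

  // mean oxygen over tumor sites and their Moore neighbors (union);
  // grid mean when no tumor exists
  double u_eff() const {
    double s = 0;
    if (cov_total == 0) {
      for (int b = 0; b < nb * nb; ++b) s += V[b] * 9.0;
      return s / ((double)N * N);
    }
    for (int b = 0; b < nb * nb; ++b)
      if (covint[b]) s += covint[b] * vin[b];
    s += covbnd * P.U_boundary;
    return s / cov_total;
  }

  // ---- protocol ---------------------------------------------------------

  void inject_dc(int count) {
    if (count <= 0) return;
    std::vector<int> emp;
    emp.reserve((size_t)N * N);
    for (int id = 0; id < N * N; ++id)
      if (grid[id] == 0) emp.push_back(id);
    int m = count <= (int)emp.size() ? count : (int)emp.size();
    dc_shortfall += count - m;
    for (int i = 0; i < m; ++i) {
      int j = i + ridx((int)emp.size() - i);
      std::swap(emp[i], emp[j]);
      Agent a;
      a.kind = DC_AC;
      a.r = emp[i] % N;
      a.c = emp[i] / N;
      a.dir = -1;
      a.steps = 0;
      a.alive = true;
      ag.push_back(a);
      grid[emp[i]] = (int)ag.size();
    }
    dc_injected += m;
  }

  // ---- agent rules ------------------------------------------------------

  void move_to(int ai, int nr, int nc) {
    Agent& a = ag[ai];
    grid[idx(a.r, a.c)] = 0;
    a.r = nr;
    a.c = nc;
    grid[idx(nr, nc)] = ai + 1;
  }

  void levy_move(int ai) {
    Agent& a = ag[ai];
    if (a.steps == 0) {
      int dlist[8], k = 0;
      for (int d = 0; d < 8; ++d) {
        int nr = a.r + DR8[d], nc = a.c + DC8[d];
        if (inside(nr, nc) && grid[idx(nr, nc)] == 0) dlist[k++] = d;
      }
      if (k == 0) return;  // defer the fresh draw to the next step
      double uz = unif_rand();
      double zr = std::ceil(std::pow(1.0 - uz, -1.0 / P.l));
      int z = zr >= 2147483647.0 ? 2147483647 : (int)zr;
      if (z < 1) z = 1;
      int d = dlist[ridx(k)];
      move_to(ai, a.r + DR8[d], a.c + DC8[d]);
      a.dir = d;
      a.steps = z - 1;
    } else {
      int d = a.dir;
      int nr = a.r + DR8[d], nc = a.c + DC8[d];
      a.steps -= 1;
      if (!inside(nr, nc)) {
        a.dir = 7 - d;  // bounce: mirror the stored direction
      } else if (grid[idx(nr, nc)] == 0) {
        move_to(ai, nr, nc);
      }
      // occupied target: wait this step
    }
  }

  void brownian_move(int ai) {
    Agent& a = ag[ai];
    int d = ridx(8);
    int nr = a.r + DR8[d], nc = a.c + DC8[d];
    if (inside(nr, nc) && grid[idx(nr, nc)] == 0) move_to(ai, nr, nc);
  }

  void tumor_rule(int ai) {
    int er[8], ec[8], k = 0;
    {
      const Agent& a = ag[ai];
      for (int d = 0; d < 8; ++d) {
        int nr = a.r + DR8[d], nc = a.c + DC8[d];
        if (inside(nr, nc) && grid[idx(nr, nc)] == 0) {
          er[k] = nr;
          ec[k] = nc;
          ++k;
        }
      }
      if (k == 0) return;
      double u = unif_rand();
      double p = clamp01(P.P_tumor + P.r_Ht / (uat(a.r, a.c) + P.c) +
                         P.r_At * Ad);
      if (u >= p) return;
    }
    int j = ridx(k);
    Agent d;
    d.kind = TUMOR;
    d.r = er[j];
    d.c = ec[j];
    d.dir = -1;
    d.steps = 0;
    d.alive = true;
    ag.push_back(d);  // may invalidate references into ag
    grid[idx(er[j], ec[j])] = (int)ag.size();
    ++tcount[bidx(er[j], ec[j])];
    cover_add(er[j], ec[j]);
    ++divisions;
  }

  bool has_neighbor_kind(const Agent& a, int kind) const {
    for (int d = 0; d < 8; ++d) {
      int nr = a.r + DR8[d], nc = a.c + DC8[d];
      if (!inside(nr, nc)) continue;
      int g = grid[idx(nr, nc)];
      if (g && ag[g - 1].kind == kind) return true;
    }
    return false;
  }

  void dcin_rule(int ai) {
    Agent& a = ag[ai];
    if (!has_neighbor_kind(a, TUMOR)) return;
    if (unif_rand() < P.D_act) {
      a.kind = DC_AC;
      a.dir = -1;
      a.steps = 0;
    }
  }

  void dcac_rule(int ai) {
    Agent& a = ag[ai];
    if (!has_neighbor_kind(a, TREG)) return;
    if (unif_rand() < P.D_inact) {
      a.kind = DC_IN;
      a.dir = -1;
      a.steps = 0;  // fresh Levy run drawn at the next movement
    }
  }

  void tin_rule(int ai) {
    Agent& a = ag[ai];
    int dr_[8], dc_[8], k = 0;
    for (int d = 0; d < 8; ++d) {
      int nr = a.r + DR8[d], nc = a.c + DC8[d];
      if (!inside(nr, nc)) continue;
      int g = grid[idx(nr, nc)];
      if (g && ag[g - 1].kind == DC_AC) {
        dr_[k] = nr;
        dc_[k] = nc;
        ++k;
      }
    }
    if (k == 0) return;
    if (unif_rand() >= P.C_act) return;
    int j = ridx(k);  // activating DC chosen uniformly
    double p = clamp01(P.P_Treg + P.r_Hr / (uat(dr_[j], dc_[j]) + P.c) +
                       P.r_Ar * Ad);
    a.kind = (unif_rand() < p) ? TREG : EFF;
    a.dir = -1;
    a.steps = 0;
  }

  void eff_rule(int ai) {
    Agent& a = ag[ai];
    int tlist[8], k = 0;
    for (int d = 0; d < 8; ++d) {
      int nr = a.r + DR8[d], nc = a.c + DC8[d];
      if (!inside(nr, nc)) continue;
      int g = grid[idx(nr, nc)];
      if (g && ag[g - 1].kind == TUMOR) tlist[k++] = g - 1;
    }
    if (k == 0) return;
    int j = tlist[ridx(k)];
    double mu_bar =
        clamp01(P.mu - P.r_He / (uat(a.r, a.c) + P.c) - P.r_Ae * Ad);
    if (unif_rand() < mu_bar) {
      ag[j].alive = false;
      grid[idx(ag[j].r, ag[j].c)] = 0;
      --tcount[bidx(ag[j].r, ag[j].c)];
      cover_remove(ag[j].r, ag[j].c);
      ++kills;
    }
  }

  void agent_phase() {
    std::vector<int> order;
    order.reserve(ag.size());
    for (int i = 0; i < (int)ag.size(); ++i)
      if (ag[i].alive) order.push_back(i);
    for (int i = (int)order.size() - 1; i > 0; --i) {
      int j = ridx(i + 1);
      std::swap(order[i], order[j]);
    }
    for (size_t oi = 0; oi < order.size(); ++oi) {
      int ai = order[oi];
      if (!ag[ai].alive) continue;
      switch (ag[ai].kind) {
        case TUMOR:
          tumor_rule(ai);
          break;
        case DC_IN:
          dcin_rule(ai);
          if (ag[ai].kind == DC_IN) levy_move(ai); else brownian_move(ai);
          break;
        case DC_AC:
          dcac_rule(ai);
          if (ag[ai].kind == DC_IN) levy_move(ai); else brownian_move(ai);
          break;
        case T_IN:
          tin_rule(ai);
          if (ag[ai].kind == T_IN) levy_move(ai); else brownian_move(ai);
          break;
        case TREG:
          brownian_move(ai);
          break;
        case EFF:
          eff_rule(ai);
          brownian_move(ai);
          break;
      }
    }
  }

  // ---- recording --------------------------------------------------------

  void record_row(NumericMatrix& rec, int row, int step_done) {
    int counts[7] = {0, 0, 0, 0, 0, 0, 0};
    for (size_t a = 0; a < ag.size(); ++a)
      if (ag[a].alive) ++counts[ag[a].kind];
    double Ue = u_eff();
    double mu_sum = 0;
    int n_eff = 0, rim = 0;
    for (size_t a = 0; a < ag.size(); ++a) {
      if (!ag[a].alive || ag[a].kind != EFF) continue;
      ++n_eff;
      mu_sum += clamp01(P.mu - P.r_He / (uat(ag[a].r, ag[a].c) + P.c) -
                        P.r_Ae * Ad);
      bool near = false;
      for (int dj = -2; dj <= 2 && !near; ++dj) {
        for (int di = -2; di <= 2 && !near; ++di) {
          int i = ag[a].r + di, j = ag[a].c + dj;
          if (!inside(i, j)) continue;
          int g = grid[idx(i, j)];
          if (g && ag[g - 1].kind == TUMOR) near = true;
        }
      }
      if (near) ++rim;
    }
    double cyto_amb = clamp01(P.mu - P.r_He / (Ue + P.c) - P.r_Ae * Ad);
    rec(row, 0) = step_done;
    rec(row, 1) = counts[TUMOR];
    rec(row, 2) = counts[DC_IN];
    rec(row, 3) = counts[DC_AC];
    rec(row, 4) = counts[T_IN];
    rec(row, 5) = counts[TREG];
    rec(row, 6) = counts[EFF];
    rec(row, 7) = Ad;
    rec(row, 8) = px;
    rec(row, 9) = s_raw;
    rec(row, 10) = S_t;
    rec(row, 11) = Ue;
    rec(row, 12) = cyto_amb;
    rec(row, 13) = n_eff > 0 ? mu_sum / n_eff : NA_REAL;
    rec(row, 14) = rim;
    rec(row, 15) = (double)divisions;
    rec(row, 16) = (double)kills;
    rec(row, 17) = (double)dc_injected;
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_simulate(List state, List params, IntegerVector px_steps,
                  NumericVector px_amounts, IntegerVector s_steps,
                  NumericVector s_amounts, IntegerVector dc_steps,
                  IntegerVector dc_counts, int n_steps, int record_every) {
  Sim sim;
  sim.P = read_pars(params);
  sim.from_state(state);

  std::map<int, double> px_dose, s_dose;
  std::map<int, int> dc_dose;
  for (int i = 0; i < px_steps.size(); ++i)
    px_dose[px_steps[i]] += px_amounts[i];
  for (int i = 0; i < s_steps.size(); ++i) s_dose[s_steps[i]] += s_amounts[i];
  for (int i = 0; i < dc_steps.size(); ++i) dc_dose[dc_steps[i]] += dc_counts[i];

  int t0 = as<int>(state["t"]);
  int n_rec = 0;
  for (int t = t0; t < t0 + n_steps; ++t)
    if ((t + 1) % record_every == 0 || t == t0 + n_steps - 1) ++n_rec;
  NumericMatrix rec(n_rec, 18);
  int row = 0;
  for (int t = t0; t < t0 + n_steps; ++t) {
    std::map<int, int>::iterator dcit = dc_dose.find(t);
    if (dcit != dc_dose.end()) sim.inject_dc(dcit->second);
    std::map<int, double>::iterator it = px_dose.find(t);
    double dpx = it != px_dose.end() ? it->second : 0.0;
    it = s_dose.find(t);
    double ds = it != s_dose.end() ? it->second : 0.0;
    sim.humoral_pre(dpx, ds);
    sim.diffuse();
    double Ue = sim.u_eff();
    sim.adenosine_step(Ue);
    sim.agent_phase();
    if ((t + 1) % record_every == 0 || t == t0 + n_steps - 1)
      sim.record_row(rec, row++, t + 1);
    if (t % 1024 == 0) Rcpp::checkUserInterrupt();
  }
  colnames(rec) = CharacterVector::create(
      "step", "tumor_sites", "n_dc_inactive", "n_dc_active", "n_t_inactive",
      "n_treg", "n_effector", "adenosine", "px", "s_raw", "s_filtered",
      "mean_oxygen", "cytotoxicity", "mean_cytotoxicity", "rim_effectors",
      "divisions", "kills", "dc_injected");
  return List::create(_["records"] = rec,
                      _["state"] = sim.to_state(t0 + n_steps),
                      _["dc_shortfall"] = (double)sim.dc_shortfall);
}
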