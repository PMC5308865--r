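#include <Rcpp.h>
using namespace Rcpp;

// Vicsek-style huddling agents: circles of radius agent_r inside a circular
// arena, with circumferential thermal sensors, homeothermotaxis turning,
// contact heat exchange, and excluded-volume resolution.

struct Reading {
  double t_l, t_r, a, t_c; // t_c meaningful only when a < 1
  double s_l, s_r;
};

// Sensor s sits at angular offset delta = 2*pi*s/ns from the heading.
// left: delta in (0, pi); right: delta in (pi, 2*pi); the two on-axis
// sensors (s = 0 and, for even ns, s = ns/2) are assigned alternately
// (first -> left, second -> right).
static Reading sense_one(int i, const NumericVector &x, const NumericVector &y,
                         const NumericVector &theta, const NumericVector &tb,
                         double ta, double tp, double sigma, int ns,
                         double agent_r) {
  int n = x.size();
  double sum_l = 0, sum_r = 0, sum_c = 0;
  int n_l = 0, n_r = 0, n_amb = 0, n_con = 0, axis_seen = 0;
  for (int s = 0; s < ns; ++s) {
    double delta = 2.0 * M_PI * s / ns;
    double phi = theta[i] + delta;
    double px = x[i] + agent_r * std::cos(phi);
    double py = y[i] + agent_r * std::sin(phi);
    // nearest other agent whose body strictly contains the sensor point
    double best_d2 = R_PosInf;
    int best = -1;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = px - x[j], dy = py - y[j];
      double d2 = dx * dx + dy * dy;
      if (d2 < agent_r * agent_r && d2 < best_d2) {
        best_d2 = d2;
        best = j;
      }
    }
    double temp;
    if (best >= 0) {
      temp = tb[best];
      ++n_con;
      sum_c += temp;
    } else {
      temp = ta;
      ++n_amb;
    }
    bool on_axis = (s == 0) || (ns % 2 == 0 && 2 * s == ns);
    bool left;
    if (on_axis) {
      left = (axis_seen % 2 == 0);
      ++axis_seen;
    } else {
      left = (2 * s < ns);
    }
    if (left) {
      sum_l += temp;
      ++n_l;
    } else {
      sum_r += temp;
      ++n_r;
    }
  }
  Reading r;
  r.t_l = n_l > 0 ? sum_l / n_l : ta;
  r.t_r = n_r > 0 ? sum_r / n_r : ta;
  r.a = (double)n_amb / ns;
  r.t_c = n_con > 0 ? sum_c / n_con : NA_REAL;
  double drive = sigma * (tp - tb[i]);
  r.s_l = 1.0 / (1.0 + std::exp(-drive * r.t_l));
  r.s_r = 1.0 / (1.0 + std::exp(-drive * r.t_r));
  return r;
}

// [[Rcpp::export]]
List sense_cpp(NumericVector x, NumericVector y, NumericVector theta,
               NumericVector tb, int i, double ta, double tp, double sigma,
               int nsensors, double agent_r) {
  Reading r = sense_one(i - 1, x, y, theta, tb, ta, tp, sigma, nsensors,
                        agent_r);
  return List::create(_["t_l"] = r.t_l, _["t_r"] = r.t_r, _["a"] = r.a,
                      _["t_c"] = r.t_c, _["s_l"] = r.s_l, _["s_r"] = r.s_r);
}

// union-find over the contact graph: edge when centre distance is below
// 2 * agent_r * (1 + slack)
static int uf_find(std::vector<int> &p, int i) {
  while (p[i] != i) {
    p[i] = p[p[i]];
    i = p[i];
  }
  return i;
}

static void components(const NumericVector &x, const NumericVector &y,
                       double agent_r, double slack, std::vector<int> &lab,
                       int &ncomp) {
  int n = x.size();
  std::vector<int> p(n);
  for (int i = 0; i < n; ++i) p[i] = i;
  double thr = 2.0 * agent_r * (1.0 + slack);
  double thr2 = thr * thr;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j];
      if (dx * dx + dy * dy < thr2) {
        int ri = uf_find(p, i), rj = uf_find(p, j);
        if (ri != rj) p[ri] = rj;
      }
    }
  lab.assign(n, 0);
  std::vector<int> remap(n, -1);
  ncomp = 0;
  for (int i = 0; i < n; ++i) {
    int r = uf_find(p, i);
    if (remap[r] < 0) remap[r] = ncomp++;
    lab[i] = remap[r] + 1;
  }
}

// [[Rcpp::export]]
IntegerVector label_groups_cpp(NumericVector x, NumericVector y,
                               double agent_r, double slack) {
  std::vector<int> lab;
  int ncomp;
  components(x, y, agent_r, slack, lab, ncomp);
  return wrap(lab);
}

// Pairs are pushed apart only when their centre distance falls below
// 2*agent_r - overlap_tol: bodies are compressible up to the tolerance, and
// the residual overlap is what the circumferential sensors register as
// contact.
static void resolve(NumericVector &x, NumericVector &y, double agent_r,
                    double arena_r, double overlap_tol, int sweeps) {
  int n = x.size();
  double sep = 2.0 * agent_r - overlap_tol;
  for (int it = 0; it < sweeps; ++it) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double dx = x[j] - x[i], dy = y[j] - y[i];
        double d = std::sqrt(dx * dx + dy * dy);
        if (d < sep) {
          double push;
          if (d < 1e-9) {
            // coincident centres: separate along a fixed axis
            dx = 1.0;
            dy = 0.0;
            d = 1.0;
            push = agent_r;
          } else {
            push = (sep - d) / 2.0;
          }
          x[i] -= push * dx / d;
          y[i] -= push * dy / d;
          x[j] += push * dx / d;
          y[j] += push * dy / d;
        }
      }
    double rmax = arena_r - agent_r;
    for (int i = 0; i < n; ++i) {
      double rr = std::sqrt(x[i] * x[i] + y[i] * y[i]);
      if (rr > rmax) {
        x[i] *= rmax / rr;
        y[i] *= rmax / rr;
      }
    }
  }
}

// [[Rcpp::export]]
List resolve_overlaps_cpp(NumericVector x, NumericVector y, double agent_r,
                          double arena_r, double overlap_tol, int sweeps) {
  NumericVector xx = clone(x), yy = clone(y);
  resolve(xx, yy, agent_r, arena_r, overlap_tol, sweeps);
  return List::create(_["x"] = xx, _["y"] = yy);
}

// Full run. Each step: sense all -> turn & move all -> resolve -> heat
// (using the step-start sensor readings). Records, per step, the sensed
// exposed-area fraction, the post-update body temperature and positions,
// and the contact-graph group count.
// [[Rcpp::export]]
List run_abm_cpp(NumericVector x0, NumericVector y0, NumericVector theta0,
                 NumericVector tb0, NumericVector g, NumericVector k2,
                 double ta, double tp, double k1, double sigma, double v1,
                 double v2, double dt, int t, int nsensors, double agent_r,
                 double arena_r, double slack, double overlap_tol,
                 int n_resolve, bool record) {
  int n = x0.size();
  NumericVector x = clone(x0), y = clone(y0), theta = clone(theta0),
                tb = clone(tb0);
  NumericMatrix A_rec, TB_rec, X_rec, Y_rec;
  IntegerVector ng_rec;
  if (record) {
    A_rec = NumericMatrix(t, n);
    TB_rec = NumericMatrix(t, n);
    X_rec = NumericMatrix(t, n);
    Y_rec = NumericMatrix(t, n);
    ng_rec = IntegerVector(t);
  }
  NumericVector tb_sum(n), a_prev(n);
  double a_sum = 0.0, flow_sum = 0.0, groups_sum = 0.0;
  long flow_n = 0;
  std::vector<double> a_now(n), tc_now(n), dtheta(n);
  std::vector<int> lab;
  int ncomp;

  for (int it = 0; it < t; ++it) {
    for (int i = 0; i < n; ++i) {
      Reading r = sense_one(i, x, y, theta, tb, ta, tp, sigma, nsensors,
                            agent_r);
      a_now[i] = r.a;
      tc_now[i] = r.t_c;
      dtheta[i] = std::atan(v2 * (r.s_l - r.s_r) / (r.s_l + r.s_r));
    }
    for (int i = 0; i < n; ++i) {
      theta[i] += dt * dtheta[i];
      x[i] += dt * v1 * std::cos(theta[i]);
      y[i] += dt * v1 * std::sin(theta[i]);
    }
    resolve(x, y, agent_r, arena_r, overlap_tol, n_resolve);
    for (int i = 0; i < n; ++i) {
      double dT = g[i] - k1 * a_now[i] * (tb[i] - ta);
      if (a_now[i] < 1.0)
        dT -= k2[i] * (1.0 - a_now[i]) * (tb[i] - tc_now[i]);
      tb[i] += dt * dT;
    }
    components(x, y, agent_r, slack, lab, ncomp);
    for (int i = 0; i < n; ++i) {
      tb_sum[i] += tb[i];
      a_sum += a_now[i];
      if (it > 0) {
        flow_sum += std::abs(a_now[i] - a_prev[i]) / dt;
        ++flow_n;
      }
      a_prev[i] = a_now[i];
    }
    groups_sum += ncomp;
    if (record) {
      for (int i = 0; i < n; ++i) {
        A_rec(it, i) = a_now[i];
        TB_rec(it, i) = tb[i];
        X_rec(it, i) = x[i];
        Y_rec(it, i) = y[i];
      }
      ng_rec[it] = ncomp;
    }
  }
  List out = List::create(
      _["mean_tb"] = (NumericVector)(tb_sum / (double)t),
      _["huddling"] = 1.0 - a_sum / ((double)t * n),
      _["pup_flow"] = flow_n > 0 ? flow_sum / flow_n : 0.0,
      _["groups_mean"] = groups_sum / t,
      _["x_final"] = x, _["y_final"] = y, _["theta_final"] = theta,
      _["tb_final"] = tb);
  if (record) {
    out["a"] = A_rec;
    out["tb"] = TB_rec;
    out["x"] = X_rec;
    out["y"] = Y_rec;
    out["ngroups"] = ng_rec;
  }
  return out;
}
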