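#include <Rcpp.h>
using namespace Rcpp;

// Group merge/split dynamics over a partition of N individuals.
// membership[i] is an arbitrary integer group label; only equality matters.

static void group_sizes(const IntegerVector &membership, IntegerVector &sizes,
                        int &ngroups) {
  int n = membership.size();
  ngroups = 0;
  for (int i = 0; i < n; ++i) {
    int s = 0;
    bool first = true;
    for (int j = 0; j < n; ++j) {
      if (membership[j] == membership[i]) {
        ++s;
        if (j < i) first = false;
      }
    }
    sizes[i] = s;
    if (first) ++ngroups;
  }
}

static inline double merge_prob(double ga, int na, double gb, int nb,
                                double ta, double tp, double k1) {
  double expo = (ga * std::pow((double)na, 0.25) +
                 gb * std::pow((double)nb, 0.25)) / k1 - 2.0 * (tp - ta);
  // exp overflow -> p1 = 0; underflow -> p1 = 1: both are the correct limits
  return 1.0 / (1.0 + std::exp(expo));
}

// Uniformly chosen individual index (0-based): selection probability of a
// group is proportional to its size.
static inline int pick_uniform(int n) {
  int i = (int)std::floor(unif_rand() * n);
  if (i >= n) i = n - 1;
  return i;
}

// b uniform over individuals outside a's group
static inline int pick_b(const IntegerVector &membership, int a) {
  int n = membership.size();
  int n_out = 0;
  for (int j = 0; j < n; ++j)
    if (membership[j] != membership[a]) ++n_out;
  int k = pick_uniform(n_out);
  for (int j = 0; j < n; ++j) {
    if (membership[j] != membership[a]) {
      if (k == 0) return j;
      --k;
    }
  }
  return -1; // unreachable when a's group is not the whole population
}

static int next_label(const IntegerVector &membership) {
  int m = membership[0];
  for (int j = 1; j < membership.size(); ++j)
    if (membership[j] > m) m = membership[j];
  return m + 1;
}

// One merge/split iteration, in place. fresh is the next unused group label.
static void step_inplace(IntegerVector &membership, const NumericVector &g,
                         double ta, double tp, double k1, int &fresh) {
  int n = membership.size();
  IntegerVector sizes(n);
  int ngroups;
  group_sizes(membership, sizes, ngroups);

  if (ngroups == 1) {
    // p1 = 0: a uniformly chosen individual splits off
    int a = pick_uniform(n);
    membership[a] = fresh++;
    return;
  }

  int a = pick_uniform(n);
  int b = pick_b(membership, a);
  bool do_merge;
  if (ngroups == n) {
    do_merge = true; // p2 = 0
  } else {
    double p1 = merge_prob(g[a], sizes[a], g[b], sizes[b], ta, tp, k1);
    do_merge = unif_rand() < p1;
  }
  if (do_merge) {
    int la = membership[a], lb = membership[b], lnew = fresh++;
    for (int j = 0; j < n; ++j)
      if (membership[j] == la || membership[j] == lb) membership[j] = lnew;
  } else {
    membership[a] = fresh++; // no-op relabel when a is already a singleton
  }
}

// [[Rcpp::export]]
double merge_probability_cpp(double ga, int na, double gb, int nb,
                             double ta, double tp, double k1) {
  return merge_prob(ga, na, gb, nb, ta, tp, k1);
}

// [[Rcpp::export]]
IntegerVector sample_pair_cpp(IntegerVector membership) {
  int n = membership.size();
  int distinct = 0;
  IntegerVector sizes(n);
  group_sizes(membership, sizes, distinct);
  if (distinct < 2) stop("sample_pair requires at least two groups");
  int a = pick_uniform(n);
  int b = pick_b(membership, a);
  return IntegerVector::create(a + 1, b + 1);
}

// [[Rcpp::export]]
IntegerVector mc_step_cpp(IntegerVector membership, NumericVector g,
                          double ta, double tp, double k1) {
  IntegerVector m = clone(membership);
  int fresh = next_label(m);
  step_inplace(m, g, ta, tp, k1, fresh);
  return m;
}

// Full run: records every individual's group size after each iteration.
// [[Rcpp::export]]
IntegerMatrix run_mc_cpp(IntegerVector membership0, NumericVector g,
                         double ta, double tp, double k1, int t) {
  IntegerVector m = clone(membership0);
  int n = m.size();
  int fresh = next_label(m);
  IntegerMatrix out(t, n);
  IntegerVector sizes(n);
  int ngroups;
  for (int it = 0; it < t; ++it) {
    step_inplace(m, g, ta, tp, k1, fresh);
    group_sizes(m, sizes, ngroups);
    for (int j = 0; j < n; ++j) out(it, j) = sizes[j];
  }
  return out;
}

// Summary-only run for the evolutionary loop: per-individual mean body
// temperature plus huddling/grouping summaries, without storing the
// trajectory.
// [[Rcpp::export]]
List run_mc_summary_cpp(IntegerVector membership0, NumericVector g,
                        double ta, double tp, double k1, int t) {
  IntegerVector m = clone(membership0);
  int n = m.size();
  int fresh = next_label(m);
  IntegerVector sizes(n);
  int ngroups;
  NumericVector tb_sum(n);
  double h_sum = 0.0, h2_sum = 0.0, groups_sum = 0.0;
  for (int it = 0; it < t; ++it) {
    step_inplace(m, g, ta, tp, k1, fresh);
    group_sizes(m, sizes, ngroups);
    double a_sum = 0.0;
    for (int j = 0; j < n; ++j) {
      double a = std::pow((double)sizes[j], -0.25);
      a_sum += a;
      tb_sum[j] += ta + g[j] / (a * k1);
    }
    double h = 1.0 - a_sum / n;
    h_sum += h;
    h2_sum += h * h;
    groups_sum += ngroups;
  }
  double h_mean = h_sum / t;
  double h_var = h2_sum / t - h_mean * h_mean;
  if (h_var < 0) h_var = 0;
  return List::create(
    _["mean_tb"] = (NumericVector)(tb_sum / (double)t),
    _["h_mean"] = h_mean,
    _["pup_flow"] = std::sqrt(h_var),
    _["groups_mean"] = groups_sum / t);
}
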