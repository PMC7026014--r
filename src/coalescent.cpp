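// Compiled kernels for the coalescent application: Felsenstein pruning under
// the Jukes-Cantor model, the Kingman coalescent prior, the marginalised
// leaf-addition proposal density, the annealed bridge density, and a
// Metropolis-within-Gibbs sweep. Trees are parent-pointer vectors with node
// heights; leaves are nodes 0..nleaf-1 (0-based here; 1-based in R).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------------------
// tree helpers

static int find_root(const IntegerVector& parent) {
  for (int i = 0; i < parent.size(); ++i)
    if (parent[i] < 0) return i;
  stop("tree has no root");
}

static void children_of(const IntegerVector& parent, std::vector<int>& ch1,
                        std::vector<int>& ch2) {
  int m = parent.size();
  ch1.assign(m, -1);
  ch2.assign(m, -1);
  for (int i = 0; i < m; ++i) {
    int p = parent[i];
    if (p < 0) continue;
    if (ch1[p] < 0) ch1[p] = i;
    else if (ch2[p] < 0) ch2[p] = i;
    else stop("node with more than two children");
  }
}

// nodes sorted by height ascending (children strictly below parents)
static std::vector<int> height_order(const NumericVector& heights) {
  std::vector<int> ord(heights.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int)i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return heights[a] < heights[b]; });
  return ord;
}

static bool heights_valid(const IntegerVector& parent, const NumericVector& heights,
                          int nleaf) {
  int m = parent.size();
  for (int i = 0; i < nleaf; ++i)
    if (heights[i] != 0.0) return false;
  for (int i = 0; i < m; ++i) {
    int p = parent[i];
    if (p >= 0 && !(heights[p] > heights[i])) return false;
  }
  return true;
}

// ---------------------------------------------------------------------------
// Jukes-Cantor pruning likelihood
//
// Branch of duration l carries d = (theta/2) * l expected substitutions per
// site; P(same) = 1/4 + 3/4 exp(-4d/3), P(diff) = 1/4 - 1/4 exp(-4d/3);
// uniform root frequencies. Site patterns are compressed columns with counts.

static double jc_loglik_impl(const IntegerVector& parent, const NumericVector& heights,
                             int nleaf, const IntegerMatrix& patt,
                             const NumericVector& counts, double theta) {
  int m = parent.size();
  int npat = patt.ncol();
  if (npat == 0) return 0.0;
  if (m == 1) {  // a single sequence: uniform stationary distribution
    double tot = 0.0;
    for (int i = 0; i < npat; ++i) tot += counts[i];
    return tot * std::log(0.25);
  }
  std::vector<double> L((size_t)m * 4 * npat, 0.0);
  std::vector<double> scale_log(npat, 0.0);
  std::vector<int> ch1, ch2;
  children_of(parent, ch1, ch2);
  std::vector<int> ord = height_order(heights);
  for (int oi = 0; oi < m; ++oi) {
    int v = ord[oi];
    double* Lv = &L[(size_t)v * 4 * npat];
    if (v < nleaf) {
      for (int s = 0; s < npat; ++s) Lv[4 * s + patt(v, s)] = 1.0;
      continue;
    }
    for (int s = 0; s < npat * 4; ++s) Lv[s] = 1.0;
    int kids[2] = {ch1[v], ch2[v]};
    for (int k = 0; k < 2; ++k) {
      int c = kids[k];
      if (c < 0) stop("internal node without two children");
      double d = 0.5 * theta * (heights[v] - heights[c]);
      double e = std::exp(-4.0 * d / 3.0);
      double psame = 0.25 + 0.75 * e;
      double pdiff = 0.25 - 0.25 * e;
      const double* Lc = &L[(size_t)c * 4 * npat];
      for (int s = 0; s < npat; ++s) {
        double tot = Lc[4 * s] + Lc[4 * s + 1] + Lc[4 * s + 2] + Lc[4 * s + 3];
        for (int a = 0; a < 4; ++a)
          Lv[4 * s + a] *= pdiff * tot + (psame - pdiff) * Lc[4 * s + a];
      }
    }
    // rescale to avoid underflow on deep trees
    for (int s = 0; s < npat; ++s) {
      double mx = std::max(std::max(Lv[4 * s], Lv[4 * s + 1]),
                           std::max(Lv[4 * s + 2], Lv[4 * s + 3]));
      if (mx > 0 && mx < 1e-200) {
        for (int a = 0; a < 4; ++a) Lv[4 * s + a] /= mx;
        scale_log[s] += std::log(mx);
      }
    }
  }
  int root = find_root(parent);
  const double* Lr = &L[(size_t)root * 4 * npat];
  double ll = 0.0;
  for (int s = 0; s < npat; ++s) {
    double site = 0.25 * (Lr[4 * s] + Lr[4 * s + 1] + Lr[4 * s + 2] + Lr[4 * s + 3]);
    if (site <= 0) return NEG_INF;
    ll += counts[s] * (std::log(site) + scale_log[s]);
  }
  return ll;
}

// [[Rcpp::export(name = ".jc_loglik_cpp")]]
double jc_loglik_cpp(IntegerVector parent, NumericVector heights, int nleaf,
                     IntegerMatrix patt, NumericVector counts, double theta) {
  return jc_loglik_impl(parent, heights, nleaf, patt, counts, theta);
}

// ---------------------------------------------------------------------------
// Kingman coalescent log prior: -sum_a C(a,2) l^(a) over inter-coalescence
// intervals (labelled-history density; the pair-choice and rate constants
// cancel exactly).

static double coal_log_prior_impl(const IntegerVector& parent,
                                  const NumericVector& heights, int nleaf) {
  if (!heights_valid(parent, heights, nleaf)) return NEG_INF;
  int m = parent.size();
  std::vector<double> hs;
  for (int i = nleaf; i < m; ++i) hs.push_back(heights[i]);
  std::sort(hs.begin(), hs.end());
  double lp = 0.0, prev = 0.0;
  int k = nleaf;  // lineages in the current interval
  for (size_t i = 0; i < hs.size(); ++i) {
    lp -= 0.5 * k * (k - 1) * (hs[i] - prev);
    prev = hs[i];
    --k;
  }
  return lp;
}

// [[Rcpp::export(name = ".coal_log_prior_cpp")]]
double coal_log_prior_cpp(IntegerVector parent, NumericVector heights, int nleaf) {
  return coal_log_prior_impl(parent, heights, nleaf);
}

// ---------------------------------------------------------------------------
// leaf removal: delete leaf `leaf` and its parent, re-index the survivors
// (remaining leaves keep their indices; internals shift down).

struct ReducedTree {
  IntegerVector parent;
  NumericVector heights;
};

static ReducedTree remove_leaf_impl(const IntegerVector& parent,
                                    const NumericVector& heights, int leaf) {
  int m = parent.size();
  int p = parent[leaf];
  if (p < 0) stop("cannot remove the only node");
  std::vector<int> ch1, ch2;
  children_of(parent, ch1, ch2);
  int sib = (ch1[p] == leaf) ? ch2[p] : ch1[p];
  std::vector<int> newid(m, -1);
  int nid = 0;
  for (int i = 0; i < m; ++i)
    if (i != leaf && i != p) newid[i] = nid++;
  IntegerVector par2(m - 2);
  NumericVector h2(m - 2);
  for (int i = 0; i < m; ++i) {
    if (newid[i] < 0) continue;
    int pp = (i == sib) ? parent[p] : parent[i];
    par2[newid[i]] = (pp < 0) ? -1 : newid[pp];
    h2[newid[i]] = heights[i];
  }
  return ReducedTree{par2, h2};
}

// [[Rcpp::export(name = ".remove_leaf_cpp")]]
List remove_leaf_cpp(IntegerVector parent, NumericVector heights, int leaf) {
  ReducedTree rt = remove_leaf_impl(parent, heights, leaf);
  return List::create(_["parent"] = rt.parent, _["heights"] = rt.heights);
}

// leaves under the sibling subtree of `leaf` (the inverse-image set Lambda)
static std::vector<int> lambda_set(const IntegerVector& parent, int nleaf, int leaf) {
  std::vector<int> ch1, ch2;
  children_of(parent, ch1, ch2);
  int p = parent[leaf];
  int sib = (ch1[p] == leaf) ? ch2[p] : ch1[p];
  std::vector<int> out, stack{sib};
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    if (v < nleaf) out.push_back(v);
    else {
      stack.push_back(ch1[v]);
      stack.push_back(ch2[v]);
    }
  }
  return out;
}

// [[Rcpp::export(name = ".lambda_set_cpp")]]
IntegerVector lambda_set_cpp(IntegerVector parent, int nleaf, int leaf) {
  std::vector<int> lam = lambda_set(parent, nleaf, leaf);
  IntegerVector out(lam.size());
  for (size_t i = 0; i < lam.size(); ++i) out[i] = lam[i] + 1;  // 1-based for R
  return out;
}

// ---------------------------------------------------------------------------
// attachment-proposal log density: logsumexp over s in Lambda of
// log chi_g(s) + log chi_h(h_new | s). chi_h is log-normal (Laplace fit) or
// Exp(1) per candidate leaf.

static double logsumexp2(const std::vector<double>& x) {
  double m = NEG_INF;
  for (double v : x) m = std::max(m, v);
  if (!std::isfinite(m)) return m;
  double s = 0.0;
  for (double v : x) s += std::exp(v - m);
  return m + std::log(s);
}

static double height_logdens(double h, bool use_lap, double mlog, double sdlog) {
  if (h <= 0) return NEG_INF;
  if (!use_lap) return -h;  // Exp(1)
  double z = (std::log(h) - mlog) / sdlog;
  return -std::log(h) - std::log(sdlog) - 0.918938533204672742 - 0.5 * z * z;
}

static double proposal_logdens_impl(const IntegerVector& parent,
                                    const NumericVector& heights, int nleaf,
                                    int new_leaf, const NumericVector& log_chi_g,
                                    const NumericVector& lap_mean,
                                    const NumericVector& lap_sd,
                                    const LogicalVector& use_lap) {
  double h_new = heights[parent[new_leaf]];
  std::vector<int> lam = lambda_set(parent, nleaf, new_leaf);
  std::vector<double> terms;
  terms.reserve(lam.size());
  for (int s : lam)
    terms.push_back(log_chi_g[s] +
                    height_logdens(h_new, use_lap[s], lap_mean[s], lap_sd[s]));
  return logsumexp2(terms);
}

// [[Rcpp::export(name = ".coal_proposal_logdens_cpp")]]
double coal_proposal_logdens_cpp(IntegerVector parent, NumericVector heights,
                                 int nleaf, int new_leaf, NumericVector log_chi_g,
                                 NumericVector lap_mean, NumericVector lap_sd,
                                 LogicalVector use_lap) {
  return proposal_logdens_impl(parent, heights, nleaf, new_leaf - 1, log_chi_g,
                               lap_mean, lap_sd, use_lap);
}

// ---------------------------------------------------------------------------
// bridge densities. The end target is the (t+1)-leaf posterior
//   log pi_{t+1} = coalescent prior + JC likelihood + Gamma(theta; 1, rate);
// the start is the pushforward of the t-leaf posterior through leaf addition,
//   log phi_from = log pi_t(reduced tree, theta) + log q(lineage, height).

struct BridgeData {
  IntegerMatrix full_patt;
  NumericVector full_counts;
  IntegerMatrix red_patt;
  NumericVector red_counts;
  double theta_shape, theta_rate;
  NumericVector log_chi_g, lap_mean, lap_sd;
  LogicalVector use_lap;
};

static double log_theta_prior(double theta, double shape, double rate) {
  if (theta <= 0) return NEG_INF;
  return shape * std::log(rate) - std::lgamma(shape) +
         (shape - 1) * std::log(theta) - rate * theta;
}

static double log_phi_to_impl(const IntegerVector& parent, const NumericVector& heights,
                              double theta, int nleaf, const BridgeData& bd) {
  double lp = coal_log_prior_impl(parent, heights, nleaf);
  if (!std::isfinite(lp)) return NEG_INF;
  return lp + jc_loglik_impl(parent, heights, nleaf, bd.full_patt, bd.full_counts, theta) +
         log_theta_prior(theta, bd.theta_shape, bd.theta_rate);
}

static double log_phi_from_impl(const IntegerVector& parent, const NumericVector& heights,
                                double theta, int nleaf, const BridgeData& bd) {
  int new_leaf = nleaf - 1;  // the most recently added sequence
  ReducedTree rt = remove_leaf_impl(parent, heights, new_leaf);
  double lp = coal_log_prior_impl(rt.parent, rt.heights, nleaf - 1);
  if (!std::isfinite(lp)) return NEG_INF;
  double ll = jc_loglik_impl(rt.parent, rt.heights, nleaf - 1, bd.red_patt,
                             bd.red_counts, theta);
  double lq = proposal_logdens_impl(parent, heights, nleaf - 1, new_leaf,
                                    bd.log_chi_g, bd.lap_mean, bd.lap_sd, bd.use_lap);
  return lp + ll + log_theta_prior(theta, bd.theta_shape, bd.theta_rate) + lq;
}

static BridgeData bridge_data_from_list(const List& bd) {
  return BridgeData{bd["full_patt"], bd["full_counts"], bd["red_patt"],
                    bd["red_counts"], bd["theta_shape"], bd["theta_rate"],
                    bd["log_chi_g"], bd["lap_mean"], bd["lap_sd"], bd["use_lap"]};
}

// [[Rcpp::export(name = ".coal_log_phi_cpp")]]
NumericVector coal_log_phi_cpp(List states, List bridge_data, bool to_side) {
  BridgeData bd = bridge_data_from_list(bridge_data);
  int P = states.size();
  NumericVector out(P);
  for (int p = 0; p < P; ++p) {
    List st = states[p];
    IntegerVector parent = st["parent"];
    NumericVector heights = st["heights"];
    double theta = st["theta"];
    int nleaf = st["n_leaves"];
    out[p] = to_side ? log_phi_to_impl(parent, heights, theta, nleaf, bd)
                     : log_phi_from_impl(parent, heights, theta, nleaf, bd);
  }
  return out;
}

// ---------------------------------------------------------------------------
// MCMC sweep, invariant for gamma * log_phi_to + (1-gamma) * log_phi_from.
// Moves: per-internal-node height slide within (max child, parent), root
// log-scale move, height-preserving restricted subtree-prune-regraft, and a
// log-theta random walk. Uses R's RNG so set.seed() governs everything.

static double bridged_logdens(const IntegerVector& parent, const NumericVector& heights,
                              double theta, int nleaf, double gamma,
                              const BridgeData& bd) {
  double lt = log_phi_to_impl(parent, heights, theta, nleaf, bd);
  if (gamma >= 1.0) return lt;
  if (!std::isfinite(lt)) return NEG_INF;
  double lf = log_phi_from_impl(parent, heights, theta, nleaf, bd);
  return gamma * lt + (1.0 - gamma) * lf;
}

static void mark_subtree(const std::vector<int>& ch1, const std::vector<int>& ch2,
                         int a, std::vector<bool>& mark) {
  std::vector<int> stack{a};
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    mark[v] = true;
    if (ch1[v] >= 0) {
      stack.push_back(ch1[v]);
      stack.push_back(ch2[v]);
    }
  }
}

// [[Rcpp::export(name = ".coal_mcmc_sweep_cpp")]]
List coal_mcmc_sweep_cpp(IntegerVector parent_in, NumericVector heights_in,
                         double theta, int nleaf, double gamma, List bridge_data,
                         double sc_height, double sc_root, double sc_theta,
                         bool topology_moves, int n_topo, int n_sweeps) {
  BridgeData bd = bridge_data_from_list(bridge_data);
  IntegerVector parent = clone(parent_in);
  NumericVector heights = clone(heights_in);
  int m = parent.size();
  int root = find_root(parent);
  double cur = bridged_logdens(parent, heights, theta, nleaf, gamma, bd);
  int n_acc = 0, n_prop = 0;
  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    std::vector<int> ch1, ch2;
    // (i) internal-node height slides
    for (int v = nleaf; v < m; ++v) {
      if (v == root) continue;
      children_of(parent, ch1, ch2);
      double lo = std::max(heights[ch1[v]], heights[ch2[v]]);
      double hi = heights[parent[v]];
      double hprop = heights[v] + sc_height * R::norm_rand();
      ++n_prop;
      if (hprop <= lo || hprop >= hi) continue;
      double old = heights[v];
      heights[v] = hprop;
      double nd = bridged_logdens(parent, heights, theta, nleaf, gamma, bd);
      if (std::log(R::unif_rand()) < nd - cur) {
        cur = nd;
        ++n_acc;
      } else heights[v] = old;
    }
    // (ii) root height, multiplicative
    if (m > 1) {
      children_of(parent, ch1, ch2);
      double lo = std::max(heights[ch1[root]], heights[ch2[root]]);
      double old = heights[root];
      double hprop = old * std::exp(sc_root * R::norm_rand());
      ++n_prop;
      if (hprop > lo) {
        heights[root] = hprop;
        double nd = bridged_logdens(parent, heights, theta, nleaf, gamma, bd);
        if (std::log(R::unif_rand()) < nd - cur + std::log(hprop / old)) {
          cur = nd;
          ++n_acc;
        } else heights[root] = old;
      }
    }
    // (iii) height-preserving SPR: detach a subtree, regraft at the same
    // height onto a uniformly chosen edge spanning that height (symmetric)
    if (topology_moves && m >= 5) {
      for (int rep = 0; rep < n_topo; ++rep) {
        ++n_prop;
        int a = (int)std::floor(R::unif_rand() * (m - 1));
        if (a >= root) ++a;  // uniform over non-root nodes
        int p = parent[a];
        if (parent[p] < 0) continue;  // parent is root: nothing spans above
        children_of(parent, ch1, ch2);
        int sib = (ch1[p] == a) ? ch2[p] : ch1[p];
        int pp = parent[p];
        double hp = heights[p];
        std::vector<bool> insub(m, false);
        mark_subtree(ch1, ch2, a, insub);
        // detached parents: parent of sib becomes pp
        std::vector<int> cand;
        for (int b = 0; b < m; ++b) {
          if (insub[b] || b == p) continue;
          int pb = (b == sib) ? pp : parent[b];
          if (pb < 0) continue;
          if (heights[b] < hp && heights[pb] > hp) cand.push_back(b);
        }
        if (cand.empty()) continue;
        int b = cand[(int)std::floor(R::unif_rand() * cand.size())];
        IntegerVector par2 = clone(parent);
        par2[sib] = pp;
        int q = (b == sib) ? pp : parent[b];
        par2[b] = p;
        par2[p] = q;
        double nd = bridged_logdens(par2, heights, theta, nleaf, gamma, bd);
        if (std::log(R::unif_rand()) < nd - cur) {
          parent = par2;
          cur = nd;
          ++n_acc;
        }
      }
    }
    // (iv) log-theta random walk
    {
      ++n_prop;
      double tprop = theta * std::exp(sc_theta * R::norm_rand());
      double nd = bridged_logdens(parent, heights, tprop, nleaf, gamma, bd);
      if (std::log(R::unif_rand()) < nd - cur + std::log(tprop / theta)) {
        theta = tprop;
        cur = nd;
        ++n_acc;
      }
    }
  }
  return List::create(_["parent"] = parent, _["heights"] = heights,
                      _["theta"] = theta, _["n_accept"] = n_acc,
                      _["n_prop"] = n_prop);
}
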