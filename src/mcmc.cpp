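// Mutation-tree MCMC core.
//
// Genotype observations are collapsed to unique (pattern, weight) rows before
// entering C++: cells sharing an observed genotype (and timepoint) contribute
// identical likelihood factors, so the per-iteration cost is
// O(n_patterns * (n_events + 1)) rather than O(n_cells * ...).
//
// Codes: 0 = wild type, 1 = mutant, 3 = missing (no likelihood factor).
// Trees are parent vectors over events 1..J with 0 denoting the wild-type
// root. All randomness goes through R's RNG so results are reproducible
// under set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct LikContext {
  int P, J;
  std::vector<double> base;    // [p] sum of log f(D_pj | 0); depends on alpha only
  std::vector<double> delta;   // [p*J + j] log f(D_pj | 1) - log f(D_pj | 0)
  std::vector<int> code;       // [p*J + j]
  std::vector<double> w;       // pattern weights (cell counts)
  double log_n_nodes;          // log(J + 1), uniform attachment prior

  void init(const IntegerMatrix& D, const NumericVector& wt, double alpha) {
    P = D.nrow();
    J = D.ncol();
    code.resize((size_t)P * J);
    base.assign(P, 0.0);
    delta.assign((size_t)P * J, 0.0);
    w.assign(wt.begin(), wt.end());
    log_n_nodes = std::log((double)(J + 1));
    const double la = std::log(alpha), l1a = std::log1p(-alpha);
    for (int p = 0; p < P; ++p)
      for (int j = 0; j < J; ++j) {
        int d = D(p, j);
        code[(size_t)p * J + j] = d;
        if (d == 0) base[p] += l1a;
        else if (d == 1) base[p] += la;
      }
    (void)la;
  }

  // refresh delta for a new beta vector
  void set_beta(const std::vector<double>& beta, double alpha) {
    const double la = std::log(alpha), l1a = std::log1p(-alpha);
    for (int j = 0; j < J; ++j) {
      double lb = std::log(beta[j]), l1b = std::log1p(-beta[j]);
      for (int p = 0; p < P; ++p) {
        int d = code[(size_t)p * J + j];
        double dd = 0.0;
        if (d == 0) dd = lb - l1a;        // obs 0: true 1 -> beta, true 0 -> 1-alpha
        else if (d == 1) dd = l1b - la;   // obs 1: true 1 -> 1-beta, true 0 -> alpha
        delta[(size_t)p * J + j] = dd;
      }
    }
  }
};

// topological order of events (parents before children); parent[j] in 0..J
void topo_order(const std::vector<int>& parent, std::vector<int>& order) {
  int J = (int)parent.size() - 1; // parent is 1-indexed with dummy slot 0
  order.clear();
  std::vector<int> depth(J + 1, -1);
  depth[0] = 0;
  for (int j = 1; j <= J; ++j) {
    // walk up to a node of known depth
    std::vector<int> stack;
    int v = j;
    while (depth[v] < 0) { stack.push_back(v); v = parent[v]; }
    int d = depth[v];
    for (int k = (int)stack.size() - 1; k >= 0; --k) depth[stack[k]] = ++d;
  }
  // counting sort by depth
  std::vector<std::vector<int>> buckets(J + 2);
  for (int j = 1; j <= J; ++j) buckets[depth[j]].push_back(j);
  for (auto& b : buckets) for (int j : b) order.push_back(j);
}

// marginal log-likelihood: per pattern, logsumexp over attachment nodes
double tree_loglik(const LikContext& L, const std::vector<int>& parent,
                   std::vector<double>& S /* scratch, size (J+1) */) {
  std::vector<int> order;
  topo_order(parent, order);
  double total = 0.0;
  for (int p = 0; p < L.P; ++p) {
    const double* dl = &L.delta[(size_t)p * L.J];
    S[0] = 0.0;
    for (int v : order) S[v] = S[parent[v]] + dl[v - 1];
    double mx = S[0];
    for (int v = 1; v <= L.J; ++v) if (S[v] > mx) mx = S[v];
    double sum = 0.0;
    for (int v = 0; v <= L.J; ++v) sum += std::exp(S[v] - mx);
    total += L.w[p] * (L.base[p] + mx + std::log(sum) - L.log_n_nodes);
  }
  return total;
}

// subtree membership of node i (including i)
void subtree_of(const std::vector<int>& parent, int i, std::vector<char>& in) {
  int J = (int)parent.size() - 1;
  in.assign(J + 1, 0);
  in[i] = 1;
  // ancestor walk per node (J small)
  for (int j = 1; j <= J; ++j) {
    int v = j;
    while (v != 0 && !in[v]) v = parent[v];
    if (v != 0 && in[v]) in[j] = 1;
  }
}

bool is_ancestor(const std::vector<int>& parent, int anc, int node) {
  int v = node;
  while (v != 0) {
    v = parent[v];
    if (v == anc) return true;
  }
  return false;
}

bool constraints_ok(const std::vector<int>& parent, const IntegerMatrix& con) {
  for (int r = 0; r < con.nrow(); ++r)
    if (!is_ancestor(parent, con(r, 0), con(r, 1))) return false;
  return true;
}

double reflect01(double x) {
  while (x < 0.0 || x > 1.0) {
    if (x < 0.0) x = -x;
    if (x > 1.0) x = 2.0 - x;
  }
  return x;
}

bool lex_less(const std::vector<int>& a, const std::vector<int>& b) {
  for (size_t k = 1; k < a.size(); ++k) {
    if (a[k] < b[k]) return true;
    if (a[k] > b[k]) return false;
  }
  return false;
}

} // namespace

// [[Rcpp::export]]
double cpp_tree_loglik(IntegerMatrix D, NumericVector w, double alpha,
                       NumericVector beta, IntegerVector parent) {
  LikContext L;
  L.init(D, w, alpha);
  std::vector<double> b(beta.begin(), beta.end());
  L.set_beta(b, alpha);
  std::vector<int> par(L.J + 1, 0);
  for (int j = 0; j < L.J; ++j) par[j + 1] = parent[j];
  std::vector<double> S(L.J + 1);
  return tree_loglik(L, par, S);
}

// learn_mode: 0 = beta fixed, 1 = single global beta (uniform[0,1] prior),
//             2 = locus-specific beta_j (Gaussian prior, truncated to [0,1])
// [[Rcpp::export]]
List cpp_mcmc(IntegerMatrix D, NumericVector w, double alpha,
              NumericVector beta_init, int learn_mode,
              double prior_mean, double prior_sd,
              double prop_sd, int n_iter, int burn_in, int thin,
              NumericVector move_weights, double beta_move_prob,
              IntegerMatrix constraints, bool record_states) {
  LikContext L;
  L.init(D, w, alpha);
  const int J = L.J;
  std::vector<double> beta(beta_init.begin(), beta_init.end());
  L.set_beta(beta, alpha);

  // initial tree: star (all events children of root); must satisfy
  // constraints, so chain ancestor constraints onto the star where needed
  std::vector<int> parent(J + 1, 0);
  for (int r = 0; r < constraints.nrow(); ++r)
    parent[constraints(r, 1)] = constraints(r, 0);

  std::vector<double> S(J + 1);
  double ll = tree_loglik(L, parent, S);

  std::vector<int> map_parent = parent;
  double map_ll = ll;

  int n_rec = 0;
  for (int it = burn_in; it < n_iter; ++it) if ((it - burn_in) % thin == 0) ++n_rec;
  IntegerMatrix rec_parent(record_states ? n_rec : 0, J);
  NumericMatrix rec_beta(n_rec, learn_mode == 2 ? J : 1);
  NumericVector rec_ll(n_rec);
  int rec_i = 0;

  double cum_w0 = move_weights[0];
  double cum_w1 = cum_w0 + move_weights[1];
  double wsum = cum_w1 + move_weights[2];
  cum_w0 /= wsum; cum_w1 /= wsum;

  int acc_tree = 0, n_tree = 0, acc_beta = 0, n_beta = 0;
  std::vector<char> sub;
  const bool learn = learn_mode > 0;

  for (int it = 0; it < n_iter; ++it) {
    if (learn && unif_rand() < beta_move_prob) {
      // ---- error-rate update ----
      ++n_beta;
      std::vector<double> beta_new = beta;
      double log_prior_ratio = 0.0;
      if (learn_mode == 1) {
        double b = reflect01(beta[0] + norm_rand() * prop_sd);
        for (int j = 0; j < J; ++j) beta_new[j] = b;
      } else {
        int j = (int)(unif_rand() * J);
        if (j == J) j = J - 1;
        double b = reflect01(beta[j] + norm_rand() * prop_sd);
        beta_new[j] = b;
        double z1 = (b - prior_mean) / prior_sd;
        double z0 = (beta[j] - prior_mean) / prior_sd;
        log_prior_ratio = 0.5 * (z0 * z0 - z1 * z1);
      }
      // guard against log(0)
      bool ok = true;
      for (int j = 0; j < J; ++j)
        if (beta_new[j] <= 0.0 || beta_new[j] >= 1.0) { ok = false; break; }
      if (ok) {
        L.set_beta(beta_new, alpha);
        double ll_new = tree_loglik(L, parent, S);
        if (std::log(unif_rand()) < ll_new - ll + log_prior_ratio) {
          beta = beta_new; ll = ll_new; ++acc_beta;
          if (ll > map_ll + 1e-9) { map_ll = ll; map_parent = parent; }
        } else {
          L.set_beta(beta, alpha);
        }
      }
    } else {
      // ---- tree move ----
      ++n_tree;
      std::vector<int> pnew = parent;
      double u = unif_rand();
      bool structural = true;
      if (u < cum_w0) {
        // prune-and-reattach: new parent uniform over non-descendants
        int i = 1 + (int)(unif_rand() * J); if (i > J) i = J;
        subtree_of(parent, i, sub);
        std::vector<int> allowed;
        for (int v = 0; v <= J; ++v) if (!sub[v]) allowed.push_back(v);
        int q = allowed[(int)(unif_rand() * allowed.size()) % allowed.size()];
        pnew[i] = q;
      } else if (u < cum_w1 && J >= 2) {
        // node-label swap
        int i = 1 + (int)(unif_rand() * J); if (i > J) i = J;
        int k = 1 + (int)(unif_rand() * (J - 1)); if (k > J - 1) k = J - 1;
        if (k >= i) ++k;
        std::vector<int> p2(J + 1);
        for (int v = 1; v <= J; ++v) {
          int src = (v == i) ? k : (v == k) ? i : v;
          int pa = parent[src];
          if (pa == i) pa = k; else if (pa == k) pa = i;
          p2[v] = pa;
        }
        p2[0] = 0;
        pnew = p2;
      } else if (J >= 2) {
        // subtree swap (identity proposal if the two subtrees are nested)
        int i = 1 + (int)(unif_rand() * J); if (i > J) i = J;
        int k = 1 + (int)(unif_rand() * (J - 1)); if (k > J - 1) k = J - 1;
        if (k >= i) ++k;
        if (is_ancestor(parent, i, k) || is_ancestor(parent, k, i)) {
          structural = false;
        } else {
          int tmp = pnew[i]; pnew[i] = pnew[k]; pnew[k] = tmp;
        }
      } else {
        structural = false; // single-event tree: swaps are identities
      }
      if (structural && constraints_ok(pnew, constraints)) {
        double ll_new = tree_loglik(L, pnew, S);
        if (std::log(unif_rand()) < ll_new - ll) {
          parent = pnew; ll = ll_new; ++acc_tree;
          if (ll > map_ll + 1e-9 ||
              (ll > map_ll - 1e-9 && lex_less(parent, map_parent))) {
            map_ll = std::max(map_ll, ll);
            map_parent = parent;
          }
        }
      }
    }
    if (it >= burn_in && (it - burn_in) % thin == 0) {
      if (record_states)
        for (int j = 0; j < J; ++j) rec_parent(rec_i, j) = parent[j + 1];
      if (learn_mode == 2)
        for (int j = 0; j < J; ++j) rec_beta(rec_i, j) = beta[j];
      else
        rec_beta(rec_i, 0) = beta[0];
      rec_ll[rec_i] = ll;
      ++rec_i;
    }
  }

  IntegerVector map_out(J);
  for (int j = 0; j < J; ++j) map_out[j] = map_parent[j + 1];
  return List::create(
    _["map_parent"] = map_out,
    _["map_loglik"] = map_ll,
    _["parents"] = rec_parent,
    _["beta"] = rec_beta,
    _["loglik"] = rec_ll,
    _["accept_tree"] = n_tree ? (double)acc_tree / n_tree : NA_REAL,
    _["accept_beta"] = n_beta ? (double)acc_beta / n_beta : NA_REAL);
}

// Posterior attachment sampler with a latent clonal composition.
//
// For each posterior draw (tree + beta) a short Gibbs chain alternates
// between (i) assigning each cell to a tree node with probability
// proportional to pi[t][v] * P(D_c | node v) and (ii) resampling the
// per-timepoint composition pi[t] ~ Dirichlet(1 + counts). A flat
// attachment prior instead of the learned pi would bias subclone sizes by
// O(beta) toward descendant clones (a dropout makes a parent-clone cell
// look equally attachable below); the latent composition removes that bias
// and yields calibrated credible intervals. Nodes at-or-below any event
// unobserved at a timepoint (under THAT draw's tree) get zero probability.
//
// parents: draws x J; betas: draws x (J or 1); observed: T x J in {0,1}
// (1 = mutation j observed at timepoint t); pattern_tp: 0-based timepoint
// per pattern; n_sweeps: Gibbs sweeps per draw (the last is recorded).
// Returns counts: draws x (T*(J+1)) and mean attachment probs P x (J+1).
// [[Rcpp::export]]
List cpp_attach(IntegerMatrix D, NumericVector w, double alpha,
                IntegerMatrix parents, NumericMatrix betas,
                IntegerMatrix observed, IntegerVector pattern_tp,
                int n_sweeps) {
  LikContext L;
  L.init(D, w, alpha);
  const int J = L.J, P = L.P;
  const int n_draws = parents.nrow();
  const int T = observed.nrow();
  const int N = J + 1;

  NumericMatrix counts(n_draws, T * N);
  NumericMatrix mean_prob(P, N);
  std::vector<double> S((size_t)P * N), prob(N);
  std::vector<int> par(N, 0), order;
  std::vector<double> beta(J), pi((size_t)T * N), tot_cnt((size_t)T * N);
  std::vector<char> mask((size_t)T * N);

  for (int d = 0; d < n_draws; ++d) {
    for (int j = 0; j < J; ++j)
      beta[j] = betas.ncol() == J ? betas(d, j) : betas(d, 0);
    L.set_beta(beta, alpha);
    for (int j = 0; j < J; ++j) par[j + 1] = parents(d, j);
    topo_order(par, order);
    // node mask per timepoint: allowed iff no unobserved event on root path
    for (int t = 0; t < T; ++t) {
      mask[(size_t)t * N] = 1;
      for (int v : order) {
        char ok = mask[(size_t)t * N + par[v]];
        if (ok && !observed(t, v - 1)) ok = 0;
        mask[(size_t)t * N + v] = ok;
      }
    }
    // per-pattern per-node log-likelihoods (fixed within the draw)
    for (int p = 0; p < P; ++p) {
      double* Sp = &S[(size_t)p * N];
      const double* dl = &L.delta[(size_t)p * J];
      Sp[0] = 0.0;
      for (int v : order) Sp[v] = Sp[par[v]] + dl[v - 1];
    }
    // init composition: uniform over allowed nodes
    for (int t = 0; t < T; ++t) {
      int n_allowed = 0;
      for (int v = 0; v < N; ++v) n_allowed += mask[(size_t)t * N + v];
      for (int v = 0; v < N; ++v)
        pi[(size_t)t * N + v] =
          mask[(size_t)t * N + v] ? 1.0 / n_allowed : 0.0;
    }
    for (int sweep = 0; sweep < n_sweeps; ++sweep) {
      const bool last = sweep == n_sweeps - 1;
      std::fill(tot_cnt.begin(), tot_cnt.end(), 0.0);
      for (int p = 0; p < P; ++p) {
        const double* Sp = &S[(size_t)p * N];
        int tp = pattern_tp[p];
        const char* mk = &mask[(size_t)tp * N];
        const double* pit = &pi[(size_t)tp * N];
        double mx = R_NegInf;
        for (int v = 0; v < N; ++v)
          if (mk[v] && Sp[v] > mx) mx = Sp[v];
        double tot = 0.0;
        for (int v = 0; v < N; ++v) {
          prob[v] = mk[v] ? pit[v] * std::exp(Sp[v] - mx) : 0.0;
          tot += prob[v];
        }
        for (int v = 0; v < N; ++v) prob[v] /= tot;
        if (last)
          for (int v = 0; v < N; ++v) mean_prob(p, v) += prob[v] / n_draws;
        // multinomial assignment of the w[p] cells via sequential binomials
        double rem_p = 1.0;
        int rem_n = (int)std::lround(L.w[p]);
        for (int v = 0; v < N && rem_n > 0; ++v) {
          if (prob[v] <= 0.0) continue;
          int nv;
          if (prob[v] >= rem_p) nv = rem_n;
          else nv = (int)R::rbinom(rem_n, prob[v] / rem_p);
          tot_cnt[(size_t)tp * N + v] += nv;
          if (last) counts(d, tp * N + v) += nv;
          rem_n -= nv;
          rem_p -= prob[v];
        }
      }
      if (!last) {
        // composition update: pi[t] ~ Dirichlet(1 + counts[t]) on allowed nodes
        for (int t = 0; t < T; ++t) {
          double sum = 0.0;
          for (int v = 0; v < N; ++v) {
            size_t i = (size_t)t * N + v;
            pi[i] = mask[i] ? R::rgamma(1.0 + tot_cnt[i], 1.0) : 0.0;
            sum += pi[i];
          }
          for (int v = 0; v < N; ++v) pi[(size_t)t * N + v] /= sum;
        }
      }
    }
  }
  return List::create(_["counts"] = counts, _["mean_prob"] = mean_prob);
}
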