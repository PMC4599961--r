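#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Development core: iterate S(t+1) = sigma(W (2 S(t) - 1)) with
// sigma(x) = 1/(1+exp(-a x)). Expression lives in (0,1); the regulatory input
// is centered at the basal point 0.5, so sigma(-x) = 1 - sigma(x) makes the
// inverted state 1-S* a fixed point whenever S* is (the twin-attractor
// structure behind phenotype inversions). Genes with no inputs sit at
// sigma(0) = 0.5 exactly.
// Convergence: max per-gene step change < tol for `window` consecutive steps
// within max_steps. Optional clamped genes (held at fixed values throughout,
// used by the logic-goal variant).
// ---------------------------------------------------------------------------

struct DevResult {
  bool converged;
  int steps;
};

// W is column-major N x N (w_ij at W[i + N*j]); s is modified in place.
static DevResult develop_core(const double* W, int N, double* s,
                              double a, int max_steps, double tol, int window,
                              const int* clamp_idx, int n_clamp,
                              const double* clamp_val) {
  std::vector<double> snew(N);
  int run = 0;
  for (int c = 0; c < n_clamp; ++c) s[clamp_idx[c]] = clamp_val[c];
  for (int t = 1; t <= max_steps; ++t) {
    for (int i = 0; i < N; ++i) {
      double x = 0.0;
      for (int j = 0; j < N; ++j) x += W[i + N * j] * (2.0 * s[j] - 1.0);
      snew[i] = 1.0 / (1.0 + std::exp(-a * x));
    }
    for (int c = 0; c < n_clamp; ++c) snew[clamp_idx[c]] = clamp_val[c];
    double dmax = 0.0;
    for (int i = 0; i < N; ++i) {
      double d = std::fabs(snew[i] - s[i]);
      if (d > dmax) dmax = d;
      s[i] = snew[i];
    }
    run = (dmax < tol) ? run + 1 : 0;
    if (run >= window) return DevResult{true, t};
  }
  return DevResult{false, max_steps};
}

// [[Rcpp::export]]
List cpp_develop(NumericMatrix W, NumericVector s0, double a, int max_steps,
                 double tol, int window,
                 IntegerVector clamp_idx, NumericVector clamp_val) {
  int N = W.nrow();
  NumericVector s = clone(s0);
  std::vector<int> ci(clamp_idx.size());
  for (int c = 0; c < clamp_idx.size(); ++c) ci[c] = clamp_idx[c] - 1;
  DevResult r = develop_core(REAL(W), N, REAL(s), a, max_steps, tol, window,
                             ci.data(), (int)ci.size(),
                             clamp_val.size() ? REAL(clamp_val) : nullptr);
  return List::create(_["phenotype"] = s, _["converged"] = r.converged,
                      _["steps"] = r.steps);
}

// ---------------------------------------------------------------------------
// Mutation operator. Event count ~ Poisson(mu); each event picks a uniform
// matrix element; zero elements gain a N(0,1) weight with prob rho; nonzero
// elements are zeroed with prob phi, otherwise redrawn from N(0,1).
// Only realized changes are recorded as events (i, j, old, new), 1-based.
// ---------------------------------------------------------------------------

// Applies mutations to genome column g (length N*N); appends realized events.
static void mutate_in_place(double* g, int N, double mu, double rho, double phi,
                            std::vector<double>* events) {
  int nn = N * N;
  int k = (int)R::rpois(mu);
  for (int e = 0; e < k; ++e) {
    int idx = (int)(unif_rand() * nn);
    if (idx >= nn) idx = nn - 1;
    double old = g[idx];
    double val = old;
    if (old == 0.0) {
      if (unif_rand() < rho) val = norm_rand();
    } else {
      if (unif_rand() < phi) val = 0.0; else val = norm_rand();
    }
    if (val != old) {
      g[idx] = val;
      if (events) {
        events->push_back((double)(idx % N) + 1); // i (row)
        events->push_back((double)(idx / N) + 1); // j (col)
        events->push_back(old);
        events->push_back(val);
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_mutate(NumericMatrix W, double mu, double rho, double phi) {
  int N = W.nrow();
  NumericMatrix out = clone(W);
  std::vector<double> ev;
  mutate_in_place(REAL(out), N, mu, rho, phi, &ev);
  int ne = (int)ev.size() / 4;
  NumericMatrix em(ne, 4);
  for (int r = 0; r < ne; ++r)
    for (int c = 0; c < 4; ++c) em(r, c) = ev[4 * r + c];
  colnames(em) = CharacterVector::create("i", "j", "old", "new");
  return List::create(_["W"] = out, _["events"] = em);
}

// ---------------------------------------------------------------------------
// One generation of Wright-Fisher selection for one species.
// role: 0 = host  f = exp(-(1-D)/alpha)
//       1 = parasite/stabilizing f = exp(-D/alpha)
// Every current individual is scored once against a freshly drawn random
// opponent phenotype (column of opp_phen, the other species' pre-update
// generation). Parents of the M_out offspring slots are sampled with
// probability proportional to fitness; offspring are produced by
// reproduction (asexual clone or sexual row-wise recombination) + mutation +
// development. Non-converged offspring have zero fitness: they are discarded
// and the slot is redrawn (attempt budget guards against degenerate configs).
// ---------------------------------------------------------------------------

// roulette draw on a cumulative weight vector (strictly positive total)
static int roulette(const std::vector<double>& cum) {
  double u = unif_rand() * cum.back();
  int lo = 0, hi = (int)cum.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cum[mid] < u) lo = mid + 1; else hi = mid;
  }
  return lo;
}

// [[Rcpp::export]]
List cpp_evolve_generation(NumericMatrix genomes, NumericMatrix opp_phen,
                           NumericMatrix phen, NumericVector s0, int role,
                           int M_out, double a, int max_steps, double tol,
                           int window, double mu, double rho, double phi,
                           bool sexual, double alpha, int max_attempts,
                           bool sqrt_dist, bool threshold_selection) {
  int N = s0.size();
  int nn = N * N;
  int M = genomes.ncol();
  int M_opp = opp_phen.ncol();
  NumericMatrix new_genomes(nn, M_out);
  NumericMatrix new_phen(N, M_out);
  IntegerMatrix parents(M_out, 2);
  std::vector<double> events; // child, i, j, old, new
  std::vector<double> child(nn), cev;
  std::vector<double> s(N);
  const double* G = REAL(genomes);
  const double* OP = REAL(opp_phen);
  const double* PH = REAL(phen);

  // fitness of each current individual vs a fresh random opponent
  NumericVector fitness(M);
  std::vector<double> cum(M);
  double total = 0.0;
  for (int k = 0; k < M; ++k) {
    int o = (int)(unif_rand() * M_opp); if (o >= M_opp) o = M_opp - 1;
    double ss = 0.0;
    for (int i = 0; i < N; ++i) {
      double d = PH[i + N * (size_t)k] - OP[i + N * (size_t)o];
      ss += d * d;
    }
    double D = sqrt_dist ? std::sqrt(ss / N) : ss / N;
    double f = (role == 0) ? std::exp(-(1.0 - D) / alpha)
                           : std::exp(-D / alpha);
    fitness[k] = f;
    total += f;
    cum[k] = total;
  }

  int accepted = 0, attempts = 0;
  while (accepted < M_out && attempts < max_attempts) {
    ++attempts;
    int p1, p2 = NA_INTEGER;
    if (threshold_selection) {
      p1 = (int)(unif_rand() * M); if (p1 >= M) p1 = M - 1;
    } else {
      p1 = roulette(cum);
    }
    if (sexual) {
      do {
        if (threshold_selection) {
          p2 = (int)(unif_rand() * M); if (p2 >= M) p2 = M - 1;
        } else {
          p2 = roulette(cum);
        }
      } while (p2 == p1);
      for (int i = 0; i < N; ++i) {
        const double* src = G + (unif_rand() < 0.5 ? p1 : p2) * (size_t)nn;
        for (int j = 0; j < N; ++j) child[i + N * j] = src[i + N * j];
      }
    } else {
      const double* src = G + p1 * (size_t)nn;
      std::copy(src, src + nn, child.begin());
    }
    cev.clear();
    mutate_in_place(child.data(), N, mu, rho, phi, &cev);
    for (int i = 0; i < N; ++i) s[i] = s0[i];
    DevResult dr = develop_core(child.data(), N, s.data(), a, max_steps, tol,
                                window, nullptr, 0, nullptr);
    if (!dr.converged) continue;
    if (threshold_selection) {
      // survival: candidate's own fitness vs a fresh random opponent must
      // exceed a U(0,1) draw
      int o = (int)(unif_rand() * M_opp); if (o >= M_opp) o = M_opp - 1;
      double ss2 = 0.0;
      for (int i = 0; i < N; ++i) {
        double d = s[i] - OP[i + N * (size_t)o];
        ss2 += d * d;
      }
      double D = sqrt_dist ? std::sqrt(ss2 / N) : ss2 / N;
      double f = (role == 0) ? std::exp(-(1.0 - D) / alpha)
                             : std::exp(-D / alpha);
      if (f < unif_rand()) continue;
    }
    std::copy(child.begin(), child.end(),
              REAL(new_genomes) + accepted * (size_t)nn);
    for (int i = 0; i < N; ++i) new_phen(i, accepted) = s[i];
    parents(accepted, 0) = p1 + 1;
    parents(accepted, 1) = sexual ? p2 + 1 : NA_INTEGER;
    for (size_t e = 0; e < cev.size(); e += 4) {
      events.push_back((double)(accepted + 1));
      events.push_back(cev[e]); events.push_back(cev[e + 1]);
      events.push_back(cev[e + 2]); events.push_back(cev[e + 3]);
    }
    ++accepted;
  }
  int ne = (int)events.size() / 5;
  NumericMatrix em(ne, 5);
  for (int r = 0; r < ne; ++r)
    for (int c = 0; c < 5; ++c) em(r, c) = events[5 * r + c];
  colnames(em) = CharacterVector::create("child", "i", "j", "old", "new");
  return List::create(_["genomes"] = new_genomes, _["phen"] = new_phen,
                      _["parents"] = parents, _["events"] = em,
                      _["attempts"] = attempts, _["accepted"] = accepted,
                      _["fitness"] = fitness);
}

// ---------------------------------------------------------------------------
// Gaussian-grid mutation sweep. For each interaction (i,j) and each grid value
// l: replace w_ij -> l, develop from s0, classify against the reference
// phenotype (basal set taken from the reference network):
//   inversion : L1 over non-basal genes  > p_flip   * (N - Nb)
//   unchanged : L1 over non-basal genes <= same_tol * (N - Nb)
//   partial   : otherwise;   nonviable : development did not converge.
// Accumulates the Gaussian mass (weights[l] = delta * f(l)) per class.
// ---------------------------------------------------------------------------

static void sweep_one(const double* W0, int N, int i, int j,
                      const double* s0, const double* ref,
                      const char* basal, int Nb,
                      double a, int max_steps, double tol, int window,
                      const double* grid, const double* wts, int G,
                      double p_flip, double same_tol,
                      double* m_inv, double* m_unch, double* m_part,
                      double* m_nonv) {
  int nn = N * N;
  std::vector<double> W(W0, W0 + nn), s(N);
  double w_old = W0[i + N * j];
  double thr_inv = p_flip * (N - Nb);
  double thr_same = same_tol * (N - Nb);
  *m_inv = *m_unch = *m_part = *m_nonv = 0.0;
  for (int g = 0; g < G; ++g) {
    double l = grid[g];
    if (l == w_old) { *m_unch += wts[g]; continue; }
    W[i + N * j] = l;
    for (int k = 0; k < N; ++k) s[k] = s0[k];
    DevResult dr = develop_core(W.data(), N, s.data(), a, max_steps, tol,
                                window, nullptr, 0, nullptr);
    if (!dr.converged) { *m_nonv += wts[g]; continue; }
    double d = 0.0;
    for (int k = 0; k < N; ++k)
      if (!basal[k]) d += std::fabs(s[k] - ref[k]);
    if (Nb < N && d > thr_inv) *m_inv += wts[g];
    else if (d <= thr_same) *m_unch += wts[g];
    else *m_part += wts[g];
  }
}

// [[Rcpp::export]]
List cpp_sensitivity_masses(NumericMatrix W, NumericVector s0,
                            double a, int max_steps, double tol, int window,
                            NumericVector grid, NumericVector weights,
                            double p_flip, double same_tol) {
  int N = W.nrow();
  NumericVector ref = clone(s0);
  DevResult dr = develop_core(REAL(W), N, REAL(ref), a, max_steps, tol, window,
                              nullptr, 0, nullptr);
  if (!dr.converged) stop("reference network does not reach a steady state");
  std::vector<bool> basal(N);
  int Nb = 0;
  for (int i = 0; i < N; ++i) {
    bool b = true;
    for (int j = 0; j < N; ++j) if (W(i, j) != 0.0) { b = false; break; }
    basal[i] = b;
    if (b) ++Nb;
  }
  NumericMatrix inv(N, N), unch(N, N), part(N, N), nonv(N, N);
  // basal mask as plain array for sweep_one
  std::vector<char> bm(N);
  for (int i = 0; i < N; ++i) bm[i] = basal[i];
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < N; ++i) {
      double mi, mu_, mp, mn;
      sweep_one(REAL(W), N, i, j, REAL(s0), REAL(ref), bm.data(), Nb,
                a, max_steps, tol, window, REAL(grid), REAL(weights),
                grid.size(), p_flip, same_tol, &mi, &mu_, &mp, &mn);
      inv(i, j) = mi; unch(i, j) = mu_; part(i, j) = mp; nonv(i, j) = mn;
    }
  return List::create(_["inversion"] = inv, _["unchanged"] = unch,
                      _["partial"] = part, _["nonviable"] = nonv,
                      _["phenotype"] = ref, _["n_basal"] = Nb);
}

// [[Rcpp::export]]
List cpp_interaction_masses(NumericMatrix W, NumericVector s0, int i, int j,
                            double a, int max_steps, double tol, int window,
                            NumericVector grid, NumericVector weights,
                            double p_flip, double same_tol) {
  int N = W.nrow();
  NumericVector ref = clone(s0);
  DevResult dr = develop_core(REAL(W), N, REAL(ref), a, max_steps, tol, window,
                              nullptr, 0, nullptr);
  if (!dr.converged) stop("reference network does not reach a steady state");
  std::vector<char> bm(N);
  int Nb = 0;
  for (int r = 0; r < N; ++r) {
    bool b = true;
    for (int c = 0; c < N; ++c) if (W(r, c) != 0.0) { b = false; break; }
    bm[r] = b;
    if (b) ++Nb;
  }
  double mi, mu_, mp, mn;
  sweep_one(REAL(W), N, i - 1, j - 1, REAL(s0), REAL(ref), bm.data(), Nb,
            a, max_steps, tol, window, REAL(grid), REAL(weights), grid.size(),
            p_flip, same_tol, &mi, &mu_, &mp, &mn);
  return List::create(_["inversion"] = mi, _["unchanged"] = mu_,
                      _["partial"] = mp, _["nonviable"] = mn);
}

// ---------------------------------------------------------------------------
// Environmental robustness: n_pert perturbed copies of s0 (each gene flipped
// s -> 1-s independently with prob rate), developed; mean L1/N distance to the
// unperturbed phenotype, excluding inversions and non-converged runs.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_env_robustness(NumericMatrix W, NumericVector s0, double rate,
                        int n_pert, double a, int max_steps, double tol,
                        int window, double p_flip) {
  int N = W.nrow();
  NumericVector ref = clone(s0);
  DevResult dr = develop_core(REAL(W), N, REAL(ref), a, max_steps, tol, window,
                              nullptr, 0, nullptr);
  if (!dr.converged) stop("reference network does not reach a steady state");
  std::vector<bool> basal(N);
  int Nb = 0;
  for (int i = 0; i < N; ++i) {
    bool b = true;
    for (int j = 0; j < N; ++j) if (W(i, j) != 0.0) { b = false; break; }
    basal[i] = b;
    if (b) ++Nb;
  }
  double thr_inv = p_flip * (N - Nb);
  std::vector<double> s(N);
  double total = 0.0;
  int used = 0, n_inv = 0, n_nc = 0;
  for (int k = 0; k < n_pert; ++k) {
    for (int i = 0; i < N; ++i) {
      double v = s0[i];
      if (unif_rand() < rate) v = 1.0 - v;
      s[i] = v;
    }
    DevResult d2 = develop_core(REAL(W), N, s.data(), a, max_steps, tol,
                                window, nullptr, 0, nullptr);
    if (!d2.converged) { ++n_nc; continue; }
    double dnb = 0.0, dall = 0.0;
    for (int i = 0; i < N; ++i) {
      double d = std::fabs(s[i] - ref[i]);
      dall += d;
      if (!basal[i]) dnb += d;
    }
    if (Nb < N && dnb > thr_inv) { ++n_inv; continue; }
    total += dall / N;
    ++used;
  }
  return List::create(_["mean_distance"] = used ? total / used : 0.0,
                      _["n_used"] = used, _["n_inversion"] = n_inv,
                      _["n_nonconverged"] = n_nc);
}

// ---------------------------------------------------------------------------
// Mutation-only density walk: each individual mutates once per generation
// (no reproduction, no selection). Returns the population mean density
// recorded every record_every generations, plus final genomes.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_mutation_only(NumericMatrix genomes, int N, double mu, double rho,
                       double phi, int generations, int record_every) {
  int M = genomes.ncol();
  int nn = N * N;
  NumericMatrix G = clone(genomes);
  double* g = REAL(G);
  int nrec = generations / record_every;
  NumericVector dens(nrec);
  IntegerVector gen_out(nrec);
  int r = 0;
  for (int t = 1; t <= generations; ++t) {
    for (int m = 0; m < M; ++m)
      mutate_in_place(g + m * (size_t)nn, N, mu, rho, phi, nullptr);
    if (t % record_every == 0) {
      double nz = 0.0;
      for (size_t k = 0; k < (size_t)nn * M; ++k) if (g[k] != 0.0) nz += 1.0;
      dens[r] = nz / ((double)nn * M);
      gen_out[r] = t;
      ++r;
    }
  }
  return List::create(_["generation"] = gen_out, _["density"] = dens,
                      _["genomes"] = G);
}

// ---------------------------------------------------------------------------
// Logic-goal (MVG) variant: 4 clamped input genes, binary output read from
// one gene (threshold 0.5) at steady state. patterns is 16 x 4 (0/1).
// Returns per-pattern output: 1, 0, or NA (non-converged).
// ---------------------------------------------------------------------------

static int eval_pattern(const double* W, int N, const double* s0,
                        const int* input_idx, const double* pattern,
                        int output_idx, double a, int max_steps, double tol,
                        int window) {
  std::vector<double> s(s0, s0 + N);
  double cv[4];
  int ci[4];
  for (int c = 0; c < 4; ++c) { ci[c] = input_idx[c]; cv[c] = pattern[c]; }
  DevResult dr = develop_core(W, N, s.data(), a, max_steps, tol, window,
                              ci, 4, cv);
  if (!dr.converged) return NA_INTEGER;
  return s[output_idx] > 0.5 ? 1 : 0;
}

// [[Rcpp::export]]
IntegerVector cpp_logic_outputs(NumericMatrix W, NumericVector s0,
                                IntegerVector input_idx, int output_idx,
                                IntegerMatrix patterns, double a,
                                int max_steps, double tol, int window) {
  int N = W.nrow();
  int P = patterns.nrow();
  int ii[4];
  for (int c = 0; c < 4; ++c) ii[c] = input_idx[c] - 1;
  IntegerVector out(P);
  double pat[4];
  for (int p = 0; p < P; ++p) {
    for (int c = 0; c < 4; ++c) pat[c] = (double)patterns(p, c);
    out[p] = eval_pattern(REAL(W), N, REAL(s0), ii, pat, output_idx - 1,
                          a, max_steps, tol, window);
  }
  return out;
}

// For each interaction (i,j): sensitive iff some grid mutation w_ij -> l makes
// the network match `goal` on at least min_correct of the 16 patterns.
// [[Rcpp::export]]
LogicalMatrix cpp_mvg_sensitivity(NumericMatrix W, NumericVector s0,
                                  IntegerVector input_idx, int output_idx,
                                  IntegerMatrix patterns, IntegerVector goal,
                                  NumericVector grid, int min_correct,
                                  double a, int max_steps, double tol,
                                  int window) {
  int N = W.nrow();
  int nn = N * N;
  int P = patterns.nrow();
  int Gn = grid.size();
  int ii[4];
  for (int c = 0; c < 4; ++c) ii[c] = input_idx[c] - 1;
  LogicalMatrix sens(N, N);
  std::vector<double> Wm(REAL(W), REAL(W) + nn);
  double pat[4];
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < N; ++i) {
      double w_old = Wm[i + N * j];
      bool found = false;
      for (int g = 0; g < Gn && !found; ++g) {
        Wm[i + N * j] = grid[g];
        int correct = 0;
        for (int p = 0; p < P; ++p) {
          if (correct + (P - p) < min_correct) break; // cannot reach threshold
          for (int c = 0; c < 4; ++c) pat[c] = (double)patterns(p, c);
          int o = eval_pattern(Wm.data(), N, REAL(s0), ii, pat, output_idx - 1,
                               a, max_steps, tol, window);
          if (o != NA_INTEGER && o == goal[p]) ++correct;
        }
        if (correct >= min_correct) found = true;
      }
      Wm[i + N * j] = w_old;
      sens(i, j) = found;
    }
  return sens;
}

// One generation of the single-population logic-goal engine: parents sampled
// with probability proportional to fitness = fraction of the 16 patterns
// matching the goal (non-converged pattern counts as incorrect); asexual
// reproduction + mutation.
// [[Rcpp::export]]
List cpp_evolve_logic_generation(NumericMatrix genomes, NumericVector s0,
                                 IntegerVector input_idx, int output_idx,
                                 IntegerMatrix patterns, IntegerVector goal,
                                 double a, int max_steps, double tol,
                                 int window, double mu, double rho, double phi,
                                 int max_attempts) {
  int N = s0.size();
  int nn = N * N;
  int M = genomes.ncol();
  int P = patterns.nrow();
  NumericMatrix new_genomes(nn, M);
  IntegerVector parents(M);
  std::vector<double> events, cev;
  std::vector<double> child(nn);
  int ii[4];
  for (int c = 0; c < 4; ++c) ii[c] = input_idx[c] - 1;
  const double* G = REAL(genomes);
  double pat[4];

  // fitness of each current individual under the current goal
  std::vector<double> cum(M);
  double total = 0.0;
  NumericVector pfit(M);
  for (int k = 0; k < M; ++k) {
    int correct = 0;
    for (int p = 0; p < P; ++p) {
      for (int c = 0; c < 4; ++c) pat[c] = (double)patterns(p, c);
      int o = eval_pattern(G + k * (size_t)nn, N, REAL(s0), ii, pat,
                           output_idx - 1, a, max_steps, tol, window);
      if (o != NA_INTEGER && o == goal[p]) ++correct;
    }
    pfit[k] = (double)correct / P;
    total += pfit[k];
    cum[k] = total;
  }
  if (total <= 0.0)
    stop("logic-goal population has zero total fitness");

  int accepted = 0, attempts = 0;
  while (accepted < M && attempts < max_attempts) {
    ++attempts;
    int p1 = roulette(cum);
    const double* src = G + p1 * (size_t)nn;
    std::copy(src, src + nn, child.begin());
    cev.clear();
    mutate_in_place(child.data(), N, mu, rho, phi, &cev);
    std::copy(child.begin(), child.end(),
              REAL(new_genomes) + accepted * (size_t)nn);
    parents[accepted] = p1 + 1;
    for (size_t e = 0; e < cev.size(); e += 4) {
      events.push_back((double)(accepted + 1));
      events.push_back(cev[e]); events.push_back(cev[e + 1]);
      events.push_back(cev[e + 2]); events.push_back(cev[e + 3]);
    }
    ++accepted;
  }
  int ne = (int)events.size() / 5;
  NumericMatrix em(ne, 5);
  for (int r = 0; r < ne; ++r)
    for (int c = 0; c < 5; ++c) em(r, c) = events[5 * r + c];
  colnames(em) = CharacterVector::create("child", "i", "j", "old", "new");
  return List::create(_["genomes"] = new_genomes, _["fitness"] = pfit,
                      _["parents"] = parents, _["events"] = em,
                      _["attempts"] = attempts, _["accepted"] = accepted);
}
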