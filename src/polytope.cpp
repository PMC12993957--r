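// Compiled cores for archetypal simplex fitting and convex-hull volume.
// Both are hot paths inside the shuffle test (hundreds of refits per stratum),
// hence C++ rather than R.
#include <RcppArmadillo.h>
#include <map>
#include <vector>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// ---------------------------------------------------------------------------
// Projection of points onto the simplex spanned by the rows of V.
//
// For each row x of X solve  min ||x - V' w||^2  s.t.  w >= 0, sum(w) = 1.
// The equality-constrained solution on each support subset is obtained from
// its KKT system; the optimum is the best feasible subset solution. With
// k <= 6 vertices exhaustive subset enumeration (<= 63 subsets) is cheap and
// exact; the full-support solution is tried first because interior points
// dominate in practice.
// ---------------------------------------------------------------------------

// KKT matrix inverse for the equality-constrained (sum-to-one) problem on a
// vertex subset; computed once per subset per V, reused for all points.
static bool kkt_inverse(const mat& G, const uvec& idx, mat& Minv) {
  const uword s = idx.n_elem;
  mat M(s + 1, s + 1, fill::zeros);
  M.submat(0, 0, s - 1, s - 1) = 2.0 * G.submat(idx, idx);
  M.submat(0, s, s - 1, s).fill(1.0);
  M.submat(s, 0, s, s - 1).fill(1.0);
  if (rcond(M) < 1e-12) return false;   // affinely dependent subset
  return inv(Minv, M);
}

// Weights for all points; X is n x d, V is k x d. Returns n x k.
static mat simplex_weights(const mat& X, const mat& V) {
  const uword n = X.n_rows, k = V.n_rows;
  if (k > 12) Rcpp::stop("simplex projection supports at most 12 vertices");
  mat G = V * V.t();              // k x k Gram
  mat C = V * X.t();              // k x n, column i = V x_i
  mat W(n, k, fill::zeros);
  const double tol = -1e-10;

  // batch full-support solution: sol = Minv * [2C; 1]
  uvec full = regspace<uvec>(0, k - 1);
  mat Minv_full;
  bool full_ok = kkt_inverse(G, full, Minv_full);
  uvec pending;
  if (full_ok) {
    mat RHS(k + 1, n);
    RHS.rows(0, k - 1) = 2.0 * C;
    RHS.row(k).fill(1.0);
    mat SOL = Minv_full * RHS;            // (k+1) x n
    std::vector<uword> bad;
    for (uword i = 0; i < n; ++i) {
      vec w = SOL.submat(0, i, k - 1, i);
      if (w.min() >= tol) {
        w.elem(find(w < 0)).zeros();
        w /= accu(w);
        W.row(i) = w.t();
      } else {
        bad.push_back(i);
      }
    }
    pending = uvec(bad);
  } else {
    pending = regspace<uvec>(0, n - 1);
  }
  if (pending.n_elem == 0) return W;

  // proper subsets, batched over all pending points per subset
  std::vector<unsigned int> masks;
  for (unsigned int m = 1; m < (1u << k) - 1u; ++m) masks.push_back(m);
  const uword np = pending.n_elem;
  mat Cp = C.cols(pending);               // k x np
  vec best_obj(np);
  best_obj.fill(datum::inf);
  mat best_W(k, np, fill::zeros);
  for (unsigned int m : masks) {
    std::vector<uword> ids;
    for (uword j = 0; j < k; ++j) if (m & (1u << j)) ids.push_back(j);
    uvec idx(ids);
    const uword s = idx.n_elem;
    if (s == 1) {
      rowvec obj = G(idx(0), idx(0)) - 2.0 * Cp.row(idx(0));
      for (uword i = 0; i < np; ++i) {
        if (obj(i) < best_obj(i)) {
          best_obj(i) = obj(i);
          best_W.col(i).zeros();
          best_W(idx(0), i) = 1.0;
        }
      }
      continue;
    }
    mat Minv;
    if (!kkt_inverse(G, idx, Minv)) continue;
    mat RHS(s + 1, np);
    RHS.rows(0, s - 1) = 2.0 * Cp.rows(idx);
    RHS.row(s).fill(1.0);
    mat SOL = Minv * RHS;                 // (s+1) x np
    mat Ws = SOL.rows(0, s - 1);          // s x np
    mat Gs = G.submat(idx, idx);
    mat GW = Gs * Ws;
    rowvec obj = sum(Ws % GW, 0) - 2.0 * sum(Ws % Cp.rows(idx), 0);
    for (uword i = 0; i < np; ++i) {
      if (Ws.col(i).min() < tol) continue;
      if (obj(i) < best_obj(i)) {
        best_obj(i) = obj(i);
        best_W.col(i).zeros();
        best_W.submat(idx, uvec{i}) = Ws.col(i);
      }
    }
  }
  for (uword i = 0; i < np; ++i) {
    vec w = best_W.col(i);
    if (!w.is_finite() || accu(w) <= 0) Rcpp::stop("simplex projection failed");
    w.elem(find(w < 0)).zeros();
    w /= accu(w);
    W.row(pending(i)) = w.t();
  }
  return W;
}

// [[Rcpp::export(name = ".simplex_weights_cpp")]]
arma::mat simplex_weights_cpp(const arma::mat& X, const arma::mat& V) {
  return simplex_weights(X, V);
}

// ---------------------------------------------------------------------------
// Alternating fit with data-point-constrained vertices: exact simplex-weight
// projection alternated with a discrete coordinate-descent vertex update
// (each vertex moves to the data point closest to its unconstrained
// least-squares optimum). Constraining vertices to actual cells keeps the
// polytope inside the data cloud -- with free vertices any enclosing simplex
// is a degenerate zero-loss solution -- and the expansion step afterwards
// makes the simplex maximal within the data.
// ---------------------------------------------------------------------------

// Frank-Wolfe projection of a target onto conv(X), warm-started at v0.
static rowvec fw_project(const rowvec& g, const mat& X, const rowvec& v0,
                         int iters) {
  rowvec v = v0;
  for (int t = 0; t < iters; ++t) {
    rowvec dir = g - v;
    double nd = norm(dir, 2);
    if (nd < 1e-12) break;
    vec sc = X * dir.t();
    rowvec s = X.row(index_max(sc));
    rowvec step = s - v;
    double denom = dot(step, step);
    if (denom < 1e-24) break;
    double gam = dot(dir, step) / denom;
    if (gam <= 0) break;
    if (gam > 1) gam = 1;
    v += gam * step;
  }
  return v;
}

static void aa_core(const mat& X, mat& V, mat& W, double& sse,
                    int maxit, double tol) {
  const uword k = V.n_rows;
  sse = datum::inf;
  for (int it = 0; it < maxit; ++it) {
    W = simplex_weights(X, V);
    mat R = X - W * V;
    double new_sse = accu(square(R));
    bool stalled = (sse - new_sse) <= tol * std::max(sse, 1e-12);
    sse = new_sse;
    if (stalled && it > 0) break;
    // vertex update: coordinate descent over archetypes; each vertex moves
    // toward its fixed-W least-squares optimum, projected onto conv(X)
    for (uword j = 0; j < k; ++j) {
      vec wj = W.col(j);
      double s2 = dot(wj, wj);
      rowvec target;
      if (s2 < 1e-12) {
        vec rn = sum(square(R), 1);       // dead vertex: worst-fit point
        target = X.row(index_max(rn));
      } else {
        target = (wj.t() * (R + wj * V.row(j))) / s2;
      }
      rowvec v_new = fw_project(target, X, V.row(j), 10);
      R -= wj * (v_new - V.row(j));
      V.row(j) = v_new;
    }
  }
  W = simplex_weights(X, V);
  sse = accu(square(X - W * V));
}

// [[Rcpp::export(name = ".aa_fit_cpp")]]
Rcpp::List aa_fit_cpp(const arma::mat& X, const arma::mat& V0,
                      int maxit = 100, double tol = 1e-8) {
  mat V = V0, W;
  double sse;
  aa_core(X, V, W, sse, maxit, tol);
  return Rcpp::List::create(Rcpp::Named("vertices") = V,
                            Rcpp::Named("weights") = W,
                            Rcpp::Named("sse") = sse);
}

// forward declaration (defined below)
double hull_volume_cpp(const arma::mat& X0);

// ---------------------------------------------------------------------------
// Full fit: furthest-point initialization with restarts, alternating
// optimization, and outward expansion about the vertex centroid until the
// target fraction of points has non-negative affine barycentric weights.
// One implementation serves both the observed fit and the shuffle-null
// refits, so the two sides of the test share every numerical convention.
// ---------------------------------------------------------------------------

struct FitResult {
  mat V_exp, V_raw, W;
  double sse, expansion;
  bool ok;
};

static mat init_far(const mat& X, uword k, uword start) {
  const uword n = X.n_rows;
  mat V(k, X.n_cols);
  V.row(0) = X.row(start);
  vec mind(n);
  for (uword i = 0; i < n; ++i)
    mind(i) = norm(X.row(i) - V.row(0), 2);
  for (uword j = 1; j < k; ++j) {
    uword nxt = index_max(mind);
    V.row(j) = X.row(nxt);
    for (uword i = 0; i < n; ++i) {
      double d2 = norm(X.row(i) - V.row(j), 2);
      if (d2 < mind(i)) mind(i) = d2;
    }
  }
  return V;
}

static FitResult do_fit(const mat& X, uword k, int restarts, int maxit,
                        double tol, double expand_q, std::mt19937& rng) {
  const uword n = X.n_rows;
  FitResult best;
  best.ok = false;
  best.sse = datum::inf;
  rowvec ctr = mean(X, 0);
  uword far = 0;
  double fd = -1.0;
  for (uword i = 0; i < n; ++i) {
    double d = norm(X.row(i) - ctr, 2);
    if (d > fd) { fd = d; far = i; }
  }
  std::uniform_int_distribution<uword> pick(0, n - 1);
  for (int r = 0; r < restarts; ++r) {
    uword start = (r == 0) ? far : pick(rng);
    mat V = init_far(X, k, start);
    mat W;
    double sse;
    aa_core(X, V, W, sse, maxit, tol);
    if (!best.ok || sse < best.sse) {
      best.ok = true;
      best.sse = sse;
      best.V_raw = V;
      best.W = W;
    }
  }
  // expansion: affine barycentric weights by least squares on [V'; 1]
  mat A(X.n_cols + 1, k);
  A.rows(0, X.n_cols - 1) = best.V_raw.t();
  A.row(X.n_cols).fill(1.0);
  mat B(X.n_cols + 1, n);
  B.rows(0, X.n_cols - 1) = X.t();
  B.row(X.n_cols).fill(1.0);
  mat Wb;
  if (!solve(Wb, A, B)) {                 // k x n
    best.expansion = 1.0;
    best.V_exp = best.V_raw;
    return best;
  }
  vec gam(n);
  for (uword i = 0; i < n; ++i)
    gam(i) = 1.0 - (double)k * Wb.col(i).min();
  vec gs = sort(gam);
  uword qi = (uword)std::ceil(expand_q * n) - 1;
  if (qi >= n) qi = n - 1;
  double gstar = std::max(1.0, gs(qi));
  rowvec vc = mean(best.V_raw, 0);
  best.V_exp = (best.V_raw.each_row() - vc) * gstar;
  best.V_exp.each_row() += vc;
  best.expansion = gstar;
  return best;
}

// goodness statistic compared between observed and shuffled data.
// k >= 3: project points and (raw) vertices to the first k-1 columns, expand
// the projected simplex about its centroid until expand_q of the points have
// non-negative barycentric coordinates (the enclosing simplex in the test
// space), then take hull volume / simplex volume. k = 2: fraction of total
// variance along the fitted segment.
static double tstat_cpp(const mat& X, const mat& V_raw, uword k,
                        double expand_q) {
  if (k == 2) {
    rowvec u = V_raw.row(1) - V_raw.row(0);
    double nu = norm(u, 2);
    if (nu <= 0) return 0.0;
    vec proj = X * (u.t() / nu);
    double along = var(proj);
    double total = accu(var(X, 0, 0));
    return total > 0 ? along / total : 0.0;
  }
  const uword m = k - 1, n = X.n_rows;
  mat P = X.cols(0, m - 1);
  mat Vm = V_raw.cols(0, m - 1);
  // exact barycentric coordinates in the projection (full-dim simplex)
  mat A(k, k);
  A.rows(0, m - 1) = Vm.t();
  A.row(m).fill(1.0);
  mat B(k, n);
  B.rows(0, m - 1) = P.t();
  B.row(m).fill(1.0);
  mat Wb;
  if (!solve(Wb, A, B)) return datum::inf;   // degenerate projected simplex
  vec gam(n);
  for (uword i = 0; i < n; ++i)
    gam(i) = 1.0 - (double)k * Wb.col(i).min();
  vec gs = sort(gam);
  uword qi = (uword)std::ceil(expand_q * n);
  if (qi < 1) qi = 1;
  if (qi > n) qi = n;
  double gstar = std::max(1.0, gs(qi - 1));
  rowvec vc = mean(Vm, 0);
  mat Ve = (Vm.each_row() - vc) * gstar;
  Ve.each_row() += vc;
  mat E = Ve.rows(1, k - 1);
  E.each_row() -= Ve.row(0);
  double dfact = 1.0;
  for (uword j = 2; j <= m; ++j) dfact *= (double)j;
  double sv = std::abs(det(E)) / dfact;
  if (sv <= 0) return datum::inf;
  return hull_volume_cpp(P) / sv;
}

// [[Rcpp::export(name = ".tstat_cpp")]]
double tstat_export(const arma::mat& X, const arma::mat& V_raw,
                    double expand_q = 0.99) {
  return tstat_cpp(X, V_raw, V_raw.n_rows, expand_q);
}

// projected enclosing simplex (k-1 dims): expansion factor and vertices
// [[Rcpp::export(name = ".enclose_projected_cpp")]]
Rcpp::List enclose_projected(const arma::mat& X, const arma::mat& V_raw,
                             double expand_q = 0.99) {
  const uword k = V_raw.n_rows, m = k - 1, n = X.n_rows;
  if (m < 1) Rcpp::stop("need k >= 2");
  mat P = X.cols(0, m - 1);
  mat Vm = V_raw.cols(0, m - 1);
  if (m == 0) Rcpp::stop("degenerate");
  mat A(k, k);
  if (m >= 1) {
    A.rows(0, m - 1) = Vm.t();
    A.row(m).fill(1.0);
  }
  mat B(k, n);
  B.rows(0, m - 1) = P.t();
  B.row(m).fill(1.0);
  mat Wb;
  if (!solve(Wb, A, B)) Rcpp::stop("degenerate projected simplex");
  vec gam(n);
  for (uword i = 0; i < n; ++i)
    gam(i) = 1.0 - (double)k * Wb.col(i).min();
  vec gs = sort(gam);
  uword qi = (uword)std::ceil(expand_q * n);
  if (qi < 1) qi = 1;
  if (qi > n) qi = n;
  double gstar = std::max(1.0, gs(qi - 1));
  rowvec vc = mean(Vm, 0);
  mat Ve = (Vm.each_row() - vc) * gstar;
  Ve.each_row() += vc;
  return Rcpp::List::create(Rcpp::Named("vertices") = Ve,
                            Rcpp::Named("points") = P,
                            Rcpp::Named("gamma") = gstar);
}

// [[Rcpp::export(name = ".fit_simplex_cpp")]]
Rcpp::List fit_simplex_cpp(const arma::mat& X, int k, int restarts,
                           int maxit, double tol, double expand_q,
                           unsigned int seed) {
  std::mt19937 rng(seed);
  FitResult f = do_fit(X, (uword)k, restarts, maxit, tol, expand_q, rng);
  return Rcpp::List::create(Rcpp::Named("vertices") = f.V_exp,
                            Rcpp::Named("vertices_raw") = f.V_raw,
                            Rcpp::Named("weights") = f.W,
                            Rcpp::Named("sse") = f.sse,
                            Rcpp::Named("expansion") = f.expansion);
}

// Null distribution of the goodness statistic: each trial permutes every
// column independently, refits, recomputes the statistic.
// [[Rcpp::export(name = ".shuffle_tstats_cpp")]]
arma::vec shuffle_tstats_cpp(const arma::mat& X, int k, int n_shuffles,
                             int restarts, int maxit, double tol,
                             double expand_q, unsigned int seed) {
  std::mt19937 rng(seed);
  const uword n = X.n_rows, d = X.n_cols;
  vec out(n_shuffles);
  mat S = X;
  for (int s = 0; s < n_shuffles; ++s) {
    for (uword j = 0; j < d; ++j) {
      // Fisher-Yates on column j
      for (uword i = n - 1; i > 0; --i) {
        std::uniform_int_distribution<uword> pick(0, i);
        uword t = pick(rng);
        std::swap(S(i, j), S(t, j));
      }
    }
    FitResult f = do_fit(S, (uword)k, restarts, maxit, tol, expand_q, rng);
    out(s) = f.ok ? tstat_cpp(S, f.V_raw, (uword)k, expand_q) : datum::inf;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Convex-hull volume by the beneath-beyond incremental algorithm.
//
// Points are joggled by a tiny deterministic perturbation (relative 1e-8) to
// put them in general position, as qhull's joggle option does; the induced
// relative volume error is of the same magnitude. Facets are stored with an
// outward normal/offset; the hull volume is the sum of cone volumes from an
// interior point. Intended for 2-5 dimensions.
// ---------------------------------------------------------------------------

struct Facet {
  std::vector<int> v;   // d vertex indices
  vec normal;
  double offset;
  bool alive;
};

static vec facet_normal(const mat& P, const std::vector<int>& ids) {
  const uword d = P.n_cols;
  mat E(d - 1, d);
  for (uword i = 1; i < d; ++i)
    E.row(i - 1) = P.row(ids[i]) - P.row(ids[0]);
  mat ns = null(E);
  if (ns.n_cols != 1) {
    // degenerate facet; fall back to SVD's smallest right-singular vector
    mat U, Vv;
    vec s;
    svd(U, s, Vv, E);
    return Vv.col(d - 1);
  }
  return ns.col(0);
}

// [[Rcpp::export(name = ".hull_volume_cpp")]]
double hull_volume_cpp(const arma::mat& X0) {
  const uword n = X0.n_rows, d = X0.n_cols;
  if (d < 1) Rcpp::stop("need at least 1 dimension");
  if (d == 1) return X0.max() - X0.min();
  if (n < d + 1) Rcpp::stop("need at least d+1 points");

  mat X = X0;
  double scale = 0.0;
  for (uword j = 0; j < d; ++j)
    scale = std::max(scale, X.col(j).max() - X.col(j).min());
  if (scale <= 0) Rcpp::stop("degenerate point set (zero extent)");

  // deterministic joggle
  std::mt19937 rng(88172645u);
  std::uniform_real_distribution<double> unif(-1.0, 1.0);
  const double jog = 1e-8 * scale;
  for (uword i = 0; i < n; ++i)
    for (uword j = 0; j < d; ++j)
      X(i, j) += jog * unif(rng);

  // initial affinely independent d+1 points: greedy farthest from affine hull
  std::vector<int> init;
  {
    uword i0 = index_max(X.col(0));
    init.push_back((int)i0);
    mat B(d, 0);  // orthonormal basis of current affine directions
    while (init.size() < d + 1) {
      vec p0 = X.row(init[0]).t();
      double best = -1.0;
      int besti = -1;
      for (uword i = 0; i < n; ++i) {
        vec r = X.row(i).t() - p0;
        if (B.n_cols > 0) r -= B * (B.t() * r);
        double nr = norm(r);
        if (nr > best) { best = nr; besti = (int)i; }
      }
      if (best < 1e-9 * scale)
        Rcpp::stop("degenerate point set: affine rank below dimension");
      vec r = X.row(besti).t() - p0;
      if (B.n_cols > 0) r -= B * (B.t() * r);
      r /= norm(r);
      B = join_rows(B, r);
      init.push_back(besti);
    }
  }

  vec o(d, fill::zeros);
  for (int id : init) o += X.row(id).t();
  o /= (double)(d + 1);

  std::vector<Facet> facets;
  auto add_facet = [&](const std::vector<int>& ids) {
    Facet f;
    f.v = ids;
    f.normal = facet_normal(X, ids);
    f.offset = dot(f.normal, X.row(ids[0]).t());
    if (dot(f.normal, o) > f.offset) {
      f.normal = -f.normal;
      f.offset = -f.offset;
    }
    f.alive = true;
    facets.push_back(f);
  };

  // initial simplex facets: leave one vertex out
  for (uword leave = 0; leave < d + 1; ++leave) {
    std::vector<int> ids;
    for (uword j = 0; j < d + 1; ++j)
      if (j != leave) ids.push_back(init[j]);
    add_facet(ids);
  }

  // process remaining points in order of decreasing distance from o
  std::vector<std::pair<double, int>> order;
  std::vector<bool> used(n, false);
  for (int id : init) used[id] = true;
  for (uword i = 0; i < n; ++i) {
    if (used[i]) continue;
    order.push_back({-norm(X.row(i).t() - o), (int)i});
  }
  std::sort(order.begin(), order.end());

  const double eps_vis = 1e-9 * scale;
  for (auto& pr : order) {
    int pi = pr.second;
    vec p = X.row(pi).t();
    std::vector<int> visible;
    for (size_t f = 0; f < facets.size(); ++f) {
      if (!facets[f].alive) continue;
      if (dot(facets[f].normal, p) - facets[f].offset > eps_vis)
        visible.push_back((int)f);
    }
    if (visible.empty()) continue;
    // horizon ridges: (d-1)-subsets shared by exactly one visible facet
    std::map<std::vector<int>, int> ridge_count;
    for (int f : visible) {
      const std::vector<int>& vv = facets[f].v;
      for (uword drop = 0; drop < d; ++drop) {
        std::vector<int> ridge;
        for (uword j = 0; j < d; ++j)
          if (j != drop) ridge.push_back(vv[j]);
        std::sort(ridge.begin(), ridge.end());
        ridge_count[ridge] += 1;
      }
    }
    for (int f : visible) facets[f].alive = false;
    for (auto& rc : ridge_count) {
      if (rc.second != 1) continue;
      std::vector<int> ids = rc.first;
      ids.push_back(pi);
      add_facet(ids);
    }
    // compact occasionally
    if (facets.size() > 4096) {
      std::vector<Facet> keep;
      keep.reserve(facets.size());
      for (auto& f : facets) if (f.alive) keep.push_back(f);
      facets.swap(keep);
    }
  }

  double dfact = 1.0;
  for (uword j = 2; j <= d; ++j) dfact *= (double)j;
  double vol = 0.0;
  mat D(d, d);
  for (auto& f : facets) {
    if (!f.alive) continue;
    for (uword j = 0; j < d; ++j)
      D.row(j) = X.row(f.v[j]) - o.t();
    vol += std::abs(det(D));
  }
  return vol / dfact;
}
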