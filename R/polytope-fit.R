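# Simplex (polytope) fitting in PC space and its significance machinery.

# Affine barycentric weights (sum to one, sign-free) of points w.r.t. the
# vertex rows of V, by least squares on the affine hull. For a full-
# dimensional simplex (k = d + 1) this is the exact barycentric coordinate.
affine_barycentric <- function(points, vertices) {
  A <- rbind(t(vertices), 1)                      # (d+1) x k
  B <- rbind(t(points), 1)                        # (d+1) x n
  qr_A <- qr(A)
  if (qr_A$rank < nrow(vertices))
    stop("degenerate simplex: affinely dependent vertices")
  t(qr.coef(qr_A, B))                             # n x k
}

# Furthest-point initialization: greedy max-min distance vertex picks.
init_vertices <- function(points, k, start) {
  n <- nrow(points)
  sel <- integer(k)
  sel[1] <- start
  mind <- sqrt(rowSums(sweep(points, 2, points[start, ])^2))
  for (j in seq_len(k - 1L)) {
    nxt <- which.max(mind)
    sel[j + 1L] <- nxt
    d2 <- sqrt(rowSums(sweep(points, 2, points[nxt, ])^2))
    mind <- pmin(mind, d2)
  }
  points[sel, , drop = FALSE]
}

affine_rank <- function(points) {
  ctr <- sweep(points, 2, colMeans(points))
  s <- svd(ctr, nu = 0, nv = 0)$d
  sum(s > 1e-10 * max(s[1], 1e-300))
}

#' Fit a k-vertex simplex to points
#'
#' Archetypal-analysis alternating optimization: exact projection of each
#' point onto the current simplex (convex weights) alternated with a
#' least-squares vertex update, minimizing `sum_i ||x_i - V' w_i||^2`.
#' Restarts are initialized from extreme data points (furthest-point
#' selection; the first restart starts from the point furthest from the
#' centroid, later restarts from random points). After optimization the
#' vertices are expanded outward about their centroid by the smallest factor
#' that places at least `expand_quantile` of the cells inside (affine
#' barycentric coordinates all non-negative), honoring the convention that
#' the fitted polytope is a maximal simplex lying within the data.
#'
#' @param points n x d numeric matrix (PC scores).
#' @param k number of vertices (2..d+1).
#' @param seed integer seed, or `NULL` to derive one from the current RNG.
#' @param restarts number of initializations (default 10); the best final
#'   loss wins.
#' @param expand_quantile coverage target of the expansion step
#'   (default 0.99).
#' @param maxit,tol optimizer controls (relative SSE stall at `tol`).
#' @return List of class `simplex_fit`: `vertices` (k x d archetype
#'   positions, constrained to the data's convex hull), `vertices_expanded`
#'   (enclosing simplex), `weights` (n x k convex weights w.r.t. `vertices`),
#'   `sse`, `expansion` (the scale factor), `k`, `d`.
#' @export
fit_simplex <- function(points, k, seed = 1L, restarts = 10,
                        expand_quantile = 0.99, maxit = 15, tol = 1e-6) {
  points <- as.matrix(points)
  n <- nrow(points); d <- ncol(points)
  if (k < 2) stop("k must be >= 2")
  if (k > d + 1) stop("k must be <= d + 1")
  if (n < k) stop("need at least k points")
  ar <- affine_rank(points)
  if (ar < k - 1)
    stop("degenerate points: affine rank ", ar, " < k - 1 = ", k - 1)
  cseed <- if (is.null(seed)) sample.int(.Machine$integer.max, 1)
           else as.integer(seed)
  f <- .fit_simplex_cpp(points, as.integer(k), as.integer(restarts),
                        as.integer(maxit), tol, expand_quantile, cseed)
  structure(list(vertices = f$vertices_raw, vertices_expanded = f$vertices,
                 weights = f$weights, sse = f$sse, expansion = f$expansion,
                 k = k, d = d),
            class = "simplex_fit")
}

#' Explained-variance curve over vertex counts
#'
#' `EV(k) = 1 - SSE(k) / SST` for simplex fits at each `k`. Fits at `k + 1`
#' are warm-started from the fit at `k` (plus the worst-residual point), so
#' the curve is non-decreasing by construction.
#'
#' @param points n x d matrix.
#' @param k_range vertex counts to evaluate (default `2:(d+1)`).
#' @param seed integer seed or `NULL`.
#' @param restarts fresh restarts per k, in addition to the warm start.
#' @return Named numeric vector `EV(k)`, with the underlying `simplex_fit`
#'   objects in attribute `"fits"`.
#' @export
explained_variance_curve <- function(points, k_range = NULL, seed = 1L,
                                     restarts = 10) {
  points <- as.matrix(points)
  d <- ncol(points)
  if (is.null(k_range)) k_range <- 2:(d + 1)
  k_range <- sort(unique(k_range))
  if (!is.null(seed)) set.seed(seed)
  sst <- sum(sweep(points, 2, colMeans(points))^2)
  ev <- numeric(length(k_range))
  fits <- vector("list", length(k_range))
  prev <- NULL
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    fit <- fit_simplex(points, k, seed = NULL, restarts = restarts)
    if (!is.null(prev)) {
      resid <- points - prev$weights %*% prev$vertices
      worst <- which.max(rowSums(resid^2))
      V0 <- rbind(prev$vertices, points[worst, ])
      if (nrow(V0) == k) {
        warm <- .aa_fit_cpp(points, V0, 20L, 1e-6)
        if (warm$sse < fit$sse) {
          # rebuild the enclosing representation around the warm solution
          Wb <- affine_barycentric(points, warm$vertices)
          gam <- 1 - k * apply(Wb, 1, min)
          gam_star <- max(1, sort(gam)[ceiling(0.99 * nrow(points))])
          Vc <- colMeans(warm$vertices)
          fit <- structure(list(vertices = warm$vertices,
                                vertices_expanded =
                                  sweep(sweep(warm$vertices, 2, Vc) *
                                          gam_star, 2, Vc, `+`),
                                weights = warm$weights, sse = warm$sse,
                                expansion = gam_star, k = k, d = d),
                           class = "simplex_fit")
        }
      }
    }
    ev[i] <- 1 - fit$sse / sst
    fits[[i]] <- fit
    prev <- fit
  }
  names(ev) <- k_range
  attr(ev, "fits") <- fits
  ev
}

#' Elbow selection on an explained-variance curve
#'
#' Picks the `k` whose point `(k, EV(k))` has maximal perpendicular distance
#' to the chord joining the curve's endpoints; ties go to the smaller `k`.
#' A monotone-linear curve (all distances ~ 0) returns the smallest `k` with
#' a warning.
#'
#' @param ev_curve named numeric vector, names = vertex counts.
#' @return The selected vertex count `k*` (integer).
#' @export
find_elbow <- function(ev_curve) {
  ks <- as.numeric(names(ev_curve))
  if (length(ks) < 3) {
    warning("elbow needs >= 3 curve points; returning smallest k")
    return(as.integer(min(ks)))
  }
  p1 <- c(ks[1], ev_curve[1])
  p2 <- c(ks[length(ks)], ev_curve[length(ks)])
  v <- p2 - p1
  nv <- sqrt(sum(v^2))
  dist <- vapply(seq_along(ks), function(i) {
    w <- c(ks[i], ev_curve[i]) - p1
    abs(v[1] * w[2] - v[2] * w[1]) / nv
  }, numeric(1))
  if (max(dist) < 1e-12) {
    warning("linear explained-variance curve; returning smallest k")
    return(as.integer(min(ks)))
  }
  as.integer(ks[which(dist >= max(dist) - 1e-12)[1]])
}

#' Convex-hull volume
#'
#' Exact hull volume via an incremental beneath-beyond construction (with a
#' deterministic relative 1e-8 joggle for general position); in one
#' dimension the range width.
#'
#' @param points n x m matrix, n >= m + 1, affinely full rank.
#' @return Positive hull volume.
#' @export
hull_volume <- function(points) {
  points <- as.matrix(points)
  d <- ncol(points)
  if (d >= 2 && nrow(points) < d + 1)
    stop("need at least d+1 points")
  if (d >= 2 && affine_rank(points) < d)
    stop("degenerate point set: affine rank below dimension")
  if (d >= 2 && nrow(points) == d + 1) {
    # exact simplex: determinant formula, no joggle
    E <- sweep(points[-1, , drop = FALSE], 2, points[1, ])
    return(abs(det(E)) / factorial(d))
  }
  .hull_volume_cpp(points)
}

#' Volume of a simplex from its vertices
#'
#' `|det(v_2 - v_1, ..., v_k - v_1)| / (k - 1)!` for `k` vertices in
#' `k - 1` dimensions; degenerate simplices return 0.
#'
#' @param vertices k x (k-1) matrix.
#' @return Non-negative volume.
#' @export
simplex_volume <- function(vertices) {
  vertices <- as.matrix(vertices)
  k <- nrow(vertices)
  if (ncol(vertices) != k - 1) stop("need k vertices in k - 1 dimensions")
  if (k == 1) return(0)
  E <- sweep(vertices[-1, , drop = FALSE], 2, vertices[1, ])
  abs(det(E)) / factorial(k - 1)
}

# Goodness-of-fit statistic compared between observed and shuffled data.
# k >= 3: enclosing t-ratio in the first k-1 components (the raw vertices are
# projected and expanded to cover 99% of the points there). k = 2: the
# t-ratio is undefined in 1-D, so the statistic is the fraction of total
# variance lying along the fitted segment direction.
t_statistic <- function(points, vertices, expand_quantile = 0.99) {
  .tstat_cpp(as.matrix(points), as.matrix(vertices), expand_quantile)
}

#' t-ratio of data to fitted simplex
#'
#' The ratio of the data's convex-hull volume to the fitted simplex's
#' volume, both in the first `k - 1` components; values near 1 indicate
#' simplex-like data. For `k = 2` use the 1-D surrogate inside
#' [shuffle_test()] instead.
#'
#' @param points n x (k-1) matrix of projected scores.
#' @param vertices k x (k-1) simplex vertices.
#' @return Positive t-ratio.
#' @export
t_ratio <- function(points, vertices) {
  vertices <- as.matrix(vertices)
  points <- as.matrix(points)
  k <- nrow(vertices)
  if (ncol(points) != k - 1 || ncol(vertices) != k - 1)
    stop("t-ratio is computed in k - 1 dimensions")
  sv <- simplex_volume(vertices)
  if (sv <= 0) stop("degenerate simplex in t-ratio")
  hull_volume(points) / sv
}

#' Shuffle test of polytope significance
#'
#' Each trial independently permutes every PC column across cells (the PCs
#' are shuffled, not the genes, which keeps the test calibrated), refits a
#' k-vertex simplex, and recomputes the goodness statistic. The p-value is
#' `(1 + #(shuffled >= observed)) / (1 + n_shuffles)` (add-one convention:
#' never exactly zero). Observed and shuffled fits share the same optimizer
#' budget; only the restart count differs.
#'
#' @param points n x d PC score matrix.
#' @param k vertex count.
#' @param n_shuffles number of trials (default 1000).
#' @param seed integer seed or `NULL`.
#' @param restarts restarts for the observed fit (default 10).
#' @param shuffle_restarts restarts per shuffled refit (default 3).
#' @param fit optional pre-computed `simplex_fit` for the observed data.
#' @param maxit,tol,expand_quantile optimizer controls shared by both sides.
#' @return List: `p_value`, `t_obs`, `t_null` (length `n_shuffles`), `fit`.
#' @export
shuffle_test <- function(points, k, n_shuffles = 1000, seed = 1L,
                         restarts = 10, shuffle_restarts = 3, fit = NULL,
                         maxit = 15, tol = 1e-6, expand_quantile = 0.99) {
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  points <- as.matrix(points)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(fit)) fit <- fit_simplex(points, k, seed = NULL,
                                       restarts = restarts, maxit = maxit,
                                       tol = tol,
                                       expand_quantile = expand_quantile)
  t_obs <- t_statistic(points, fit$vertices, expand_quantile)
  cseed <- sample.int(.Machine$integer.max, 1)
  t_null <- as.vector(.shuffle_tstats_cpp(points, as.integer(k),
                                          as.integer(n_shuffles),
                                          as.integer(shuffle_restarts),
                                          as.integer(maxit), tol,
                                          expand_quantile, cseed))
  p <- (1 + sum(t_null >= t_obs)) / (1 + n_shuffles)
  list(p_value = p, t_obs = t_obs, t_null = t_null, fit = fit)
}

#' Percent of cells inside the fitted simplex
#'
#' Fraction of points whose barycentric coordinates with respect to the
#' simplex are all at least `-tol` (the boundary counts as inside). Requires
#' a full-dimensional simplex (`k = d + 1`).
#'
#' @param points n x d matrix.
#' @param vertices (d+1) x d simplex vertices.
#' @param tol barycentric tolerance (default 1e-9).
#' @return Fraction in `[0, 1]`.
#' @export
percent_inside <- function(points, vertices, tol = 1e-9) {
  points <- as.matrix(points)
  vertices <- as.matrix(vertices)
  if (nrow(vertices) != ncol(vertices) + 1)
    stop("percent_inside needs a full-dimensional simplex (k = d + 1)")
  A <- rbind(t(vertices), 1)
  if (abs(det(A)) < 1e-300) stop("degenerate simplex")
  W <- solve(A, rbind(t(points), 1))              # k x n barycentric
  mean(apply(W, 2, min) >= -tol)
}

#' Bootstrap confidence regions for vertex positions
#'
#' Resamples cells with replacement, refits the simplex, matches replicate
#' vertices to the reference fit by minimum-total-distance (Hungarian)
#' assignment, and reports the per-vertex mean and covariance of matched
#' positions. Rank-degenerate replicates are discarded and counted.
#'
#' @param points n x d matrix the fit was computed on.
#' @param k vertex count (ignored when `fit` is supplied).
#' @param n_boot bootstrap replicates (default 100).
#' @param seed integer seed or `NULL`.
#' @param fit optional reference `simplex_fit`.
#' @param restarts restarts per replicate fit.
#' @return List of class `vertex_bootstrap`: `mean` (k x d), `cov` (list of
#'   d x d matrices), `n_used`, `n_discarded`.
#' @export
bootstrap_vertices <- function(points, k = NULL, n_boot = 100, seed = 1L,
                               fit = NULL, restarts = 3) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(fit)) {
    if (is.null(k)) stop("supply k or a fit")
    fit <- fit_simplex(points, k, seed = NULL)
  }
  k <- fit$k
  ref <- fit$vertices
  sams <- vector("list", n_boot)
  n_disc <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    rep_fit <- tryCatch(fit_simplex(points[idx, , drop = FALSE], k,
                                    seed = NULL, restarts = restarts),
                        error = function(e) NULL)
    if (is.null(rep_fit)) { n_disc <- n_disc + 1L; next }
    V <- rep_fit$vertices
    D <- outer(seq_len(k), seq_len(k),
               Vectorize(function(i, j) sqrt(sum((ref[i, ] - V[j, ])^2))))
    assign <- clue::solve_LSAP(D)
    sams[[b]] <- V[as.integer(assign), , drop = FALSE]
  }
  sams <- Filter(Negate(is.null), sams)
  if (length(sams) == 0) stop("all bootstrap replicates degenerate")
  arr <- simplify2array(sams)                     # k x d x B
  mean_v <- apply(arr, c(1, 2), mean)
  cov_v <- lapply(seq_len(k), function(i) stats::cov(t(arr[i, , ])))
  structure(list(mean = mean_v, cov = cov_v,
                 n_used = length(sams), n_discarded = n_disc),
            class = "vertex_bootstrap")
}

#' Dimension sweep with early stopping at significance
#'
#' For each dimension `d` (default 5, 4, 3, 2, capped at the retained
#' components), takes the first `d` retained PCs, computes the
#' explained-variance curve over `k = 2..d+1`, selects `k*` by elbow (for
#' two-point curves the curve is anchored at `EV(1) = 0`), and runs the
#' shuffle test, stopping at the first `p <` `alpha`. All computed p-values
#' are retained for cell-type aggregation. If no dimension is significant
#' the fit at the first dimension is returned flagged non-significant.
#'
#' @param x a `pc_space`, `stratum_space`, or a matrix of retained PC
#'   scores.
#' @param dims dimensions to sweep, in order (default `c(5, 4, 3, 2)`).
#' @param alpha significance threshold (default 0.05).
#' @param n_shuffles shuffle trials per test (default 1000).
#' @param seed integer seed.
#' @param restarts,shuffle_restarts optimizer restarts.
#' @param stratum_id optional identifier carried into the result.
#' @return An object of class `polytope_fit`; see [fit_polytope()].
#' @export
sweep_dimensions <- function(x, dims = c(5, 4, 3, 2), alpha = 0.05,
                             n_shuffles = 1000, seed = 1L, restarts = 10,
                             shuffle_restarts = 3, stratum_id = NULL) {
  scores <- if (inherits(x, "stratum_space")) retained_scores(x$pc)
            else if (inherits(x, "pc_space")) retained_scores(x)
            else as.matrix(x)
  n_pc <- ncol(scores)
  if (n_pc < 2) stop("fewer than 2 retained components; stratum skipped")
  dims <- pmin(dims, n_pc)
  dims <- dims[dims >= 2]
  dims <- dims[!duplicated(dims)]
  if (length(dims) == 0) stop("no usable dimensions")
  records <- list()
  first_result <- NULL
  final <- NULL
  for (d in dims) {
    pts <- scores[, seq_len(d), drop = FALSE]
    k_max <- min(d + 1, nrow(pts) - 1L)
    ev <- explained_variance_curve(pts, 2:k_max, seed = derive_seed(seed, d),
                                   restarts = restarts)
    ev_in <- if (length(ev) < 3) {
      c(stats::setNames(0, "1"), ev)
    } else ev
    k_star <- suppressWarnings(find_elbow(ev_in))
    if (k_star < 2) k_star <- 2L
    st <- shuffle_test(pts, k_star, n_shuffles = n_shuffles,
                       seed = derive_seed(seed, 100 + d),
                       restarts = restarts,
                       shuffle_restarts = shuffle_restarts)
    records[[length(records) + 1L]] <-
      data.frame(dim = d, k = k_star, p = st$p_value)
    res <- list(dim = d, k = k_star, ev = ev, st = st, points = pts)
    if (is.null(first_result)) first_result <- res
    if (st$p_value < alpha) { final <- res; break }
  }
  if (is.null(final)) final <- first_result
  pvals <- do.call(rbind, records)
  st <- final$st
  k <- final$k
  enc <- tryCatch(.enclose_projected_cpp(final$points, st$fit$vertices, 0.99),
                  error = function(e) NULL)
  pct <- if (is.null(enc)) NA_real_ else
    tryCatch(percent_inside(enc$points, enc$vertices),
             error = function(e) NA_real_)
  structure(list(stratum_id = stratum_id,
                 dimension = final$dim, k = k,
                 vertices = st$fit$vertices,
                 vertices_tspace = if (is.null(enc)) NULL else enc$vertices,
                 weights = st$fit$weights,
                 sse = st$fit$sse,
                 expansion = st$fit$expansion,
                 ev_curve = final$ev,
                 t_ratio = st$t_obs,
                 t_null = st$t_null,
                 p_value = st$p_value,
                 p_values = pvals,
                 n_shuffles = n_shuffles,
                 significant = st$p_value < alpha,
                 alpha = alpha,
                 pct_inside = pct,
                 points = final$points,
                 bootstrap = NULL,
                 seed = seed),
            class = "polytope_fit")
}

#' Fit a significance-tested polytope to expression data
#'
#' The central model-fitting entry point. Given PC scores (or a prepared
#' stratum space), either sweeps dimensions 5 to 2 with elbow-selected
#' vertex counts ([sweep_dimensions()]) or, when `k` is given, fits and
#' tests a single k-vertex simplex in the supplied space. Returns a
#' `polytope_fit` model object with `print`, `summary`, `coef`, `predict`,
#' `fitted`, `residuals`, `simulate` and `plot` methods.
#'
#' @param x matrix of PC scores, `pc_space`, or `stratum_space`.
#' @param k optional fixed vertex count; `NULL` (default) sweeps.
#' @param dims dimensions for the sweep.
#' @param alpha significance level (default 0.05).
#' @param n_shuffles shuffle trials (default 1000).
#' @param n_boot bootstrap replicates for vertex confidence regions
#'   (0 disables).
#' @param seed integer seed.
#' @param ... passed to [sweep_dimensions()].
#' @return A `polytope_fit`.
#' @export
fit_polytope <- function(x, k = NULL, dims = c(5, 4, 3, 2), alpha = 0.05,
                         n_shuffles = 1000, n_boot = 0, seed = 1L, ...) {
  if (is.null(k)) {
    fit <- sweep_dimensions(x, dims = dims, alpha = alpha,
                            n_shuffles = n_shuffles, seed = seed, ...)
  } else {
    scores <- if (inherits(x, "stratum_space")) retained_scores(x$pc)
              else if (inherits(x, "pc_space")) retained_scores(x)
              else as.matrix(x)
    d_use <- min(ncol(scores), max(k - 1, 2))
    pts <- scores[, seq_len(d_use), drop = FALSE]
    st <- shuffle_test(pts, k, n_shuffles = n_shuffles,
                       seed = derive_seed(seed, 100 + d_use), ...)
    sst <- sum(sweep(pts, 2, colMeans(pts))^2)
    enc <- tryCatch(.enclose_projected_cpp(pts, st$fit$vertices, 0.99),
                    error = function(e) NULL)
    pct <- if (is.null(enc)) NA_real_ else
      tryCatch(percent_inside(enc$points, enc$vertices),
               error = function(e) NA_real_)
    fit <- structure(list(stratum_id = NULL, dimension = d_use, k = k,
                          vertices = st$fit$vertices,
                          vertices_tspace = if (is.null(enc)) NULL else enc$vertices,
                          weights = st$fit$weights, sse = st$fit$sse,
                          expansion = st$fit$expansion,
                          ev_curve = stats::setNames(1 - st$fit$sse / sst, k),
                          t_ratio = st$t_obs, t_null = st$t_null,
                          p_value = st$p_value,
                          p_values = data.frame(dim = d_use, k = k,
                                                p = st$p_value),
                          n_shuffles = n_shuffles,
                          significant = st$p_value < alpha, alpha = alpha,
                          pct_inside = pct, points = pts, bootstrap = NULL,
                          seed = seed),
                     class = "polytope_fit")
  }
  if (n_boot > 0) {
    fit$bootstrap <- bootstrap_vertices(fit$points, fit = fit,
                                        n_boot = n_boot,
                                        seed = derive_seed(seed, 999L))
  }
  fit
}
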