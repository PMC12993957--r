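test_that("fit_simplex recovers exact vertices from vertex-only data", {
  V <- rbind(c(0, 0), c(4, 0), c(0, 3))
  pts <- V[rep(1:3, each = 20), ]
  f <- fit_simplex(pts, 3, seed = 1)
  err <- matched_vertex_error(V, f$vertices)
  expect_lt(err, 1e-6)
  expect_lt(f$sse, 1e-10)
  expect_equal(f$expansion, 1, tolerance = 1e-9)
})

test_that("fit_simplex enforces its contract", {
  pts <- matrix(rnorm(60), 30, 2)
  expect_error(fit_simplex(pts, 1), "k must be >= 2")
  expect_error(fit_simplex(pts, 4), "k must be <= d \\+ 1")
  expect_error(fit_simplex(pts[1:2, ], 3), "at least k points")
  line <- cbind(1:30, 2 * (1:30))      # affine rank 1
  expect_error(fit_simplex(line, 3), "affine rank")
})

test_that("uniform triangle fill is recovered within 5% of the diameter", {
  set.seed(2)
  V <- rbind(c(-1, 0), c(3, 1), c(1, 4))
  W <- matrix(rgamma(3000, 1), 1000)
  W <- W / rowSums(W)
  pts <- W %*% V
  f <- fit_simplex(pts, 3, seed = 2)
  expect_lt(matched_vertex_error(V, f$vertices), 0.05)
})

test_that("explained variance curve is monotone, bounded and elbow-consistent", {
  set.seed(3)
  V <- rbind(c(0, 0, 0), c(5, 0, 0), c(0, 5, 0))
  W <- matrix(rgamma(1800, 0.7), 600)
  W <- W / rowSums(W)
  pts <- W %*% V + matrix(rnorm(1800, 0, 0.05), 600)
  ev <- explained_variance_curve(pts, 2:4, seed = 3)
  expect_true(all(ev >= 0 & ev <= 1))
  expect_true(all(diff(ev) >= -1e-9))
  # triangle: the gain from 2 to 3 dwarfs the gain from 3 to 4
  expect_gt(ev["3"] - ev["2"], 5 * (ev["4"] - ev["3"]))
  # 1-D data: a segment explains essentially everything at k = 2
  seg <- cbind(seq(0, 1, length.out = 300), 0) +
    matrix(rnorm(600, 0, 1e-4), 300)
  ev_seg <- explained_variance_curve(seg, 2:3, seed = 1)
  expect_gt(ev_seg["2"], 0.999)
  # EV equals 1 - SSE/SST recomputed from the returned weights
  fits <- attr(ev, "fits")
  sst <- sum(sweep(pts, 2, colMeans(pts))^2)
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    sse <- sum((pts - f$weights %*% f$vertices)^2)
    expect_equal(unname(ev[i]), 1 - sse / sst, tolerance = 1e-8)
  }
})

test_that("elbow selection matches hand-computed chord distances", {
  ev <- c(`2` = 0.5, `3` = 0.8, `4` = 0.9, `5` = 0.93, `6` = 0.95)
  # hand computation: chord from (2, 0.5) to (6, 0.95)
  chord <- function(k, e) {
    v <- c(6 - 2, 0.95 - 0.5)
    w <- c(k - 2, e - 0.5)
    abs(v[1] * w[2] - v[2] * w[1]) / sqrt(sum(v^2))
  }
  d3 <- chord(3, 0.8); d4 <- chord(4, 0.9); d5 <- chord(5, 0.93)
  expect_equal(round(c(d3, d4, d5), 3), c(0.186, 0.174, 0.092),
               tolerance = 0.005)
  expect_equal(find_elbow(ev), 3L)
  # step curve
  expect_equal(find_elbow(c(`2` = 0.1, `3` = 0.99, `4` = 0.99, `5` = 0.99)),
               3L)
  # perfectly linear curve: smallest k with warning
  lin <- c(`2` = 0.2, `3` = 0.4, `4` = 0.6, `5` = 0.8)
  expect_warning(k_lin <- find_elbow(lin), "linear")
  expect_equal(k_lin, 2L)
})

test_that("hull volume matches analytic and independent oracles", {
  # unit square (2-D, exact)
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5))
  expect_equal(hull_volume(sq), 1, tolerance = 1e-6)
  # unit cube and 4-D cross-check against analytic corner volumes
  cu <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(hull_volume(cu), 1, tolerance = 1e-6)
  # unit 3-simplex: 1/3! = 1/6
  s3 <- rbind(rep(0, 3), diag(3))
  expect_equal(hull_volume(s3), 1 / 6, tolerance = 1e-6)
  # random 2-D clouds against chull + shoelace
  set.seed(7)
  for (r in 1:5) {
    X <- matrix(rnorm(80 * 2), 80)
    expect_equal(hull_volume(X), shoelace_hull_area(X), tolerance = 1e-6)
  }
  # simplex-hulled clouds in 2-4 dims against the analytic volume
  for (d in 2:4) {
    for (r in 1:3) {
      set.seed(10 * d + r)
      cl <- random_simplex_cloud(d)
      expect_equal(hull_volume(cl$points), cl$volume, tolerance = 1e-6)
    }
  }
  expect_error(hull_volume(matrix(1:4, 2, 2)), "d\\+1 points")
  degen <- cbind(1:10, 1:10)
  expect_error(hull_volume(degen), "affine rank|degenerate")
})

test_that("simplex volume matches the determinant formula and the hull", {
  expect_equal(simplex_volume(rbind(c(0, 0), c(1, 0), c(0, 1))), 0.5)
  expect_equal(simplex_volume(rbind(c(0, 0), c(1, 1), c(2, 2))), 0)
  set.seed(9)
  V <- matrix(rnorm(12), 4, 3)
  expect_equal(simplex_volume(V), hull_volume(V), tolerance = 1e-6)
  expect_error(simplex_volume(matrix(rnorm(8), 4, 2)), "k - 1 dimensions")
})

test_that("t-ratio behaves like an enclosing-simplex statistic", {
  V <- rbind(c(0, 0), c(2, 0), c(0, 2))
  # data exactly the triangle's vertices: hull = simplex, ratio 1
  pts <- V[rep(1:3, each = 10), ]
  expect_equal(t_ratio(pts, V), 1, tolerance = 1e-6)
  # data filling a shrunken copy: hull strictly smaller than the simplex
  set.seed(4)
  W <- matrix(rgamma(900, 1), 300)
  W <- W / rowSums(W)
  inner <- 0.5 * W %*% V + 0.25 * matrix(rep(colSums(V) / 3, each = 300), 300)
  expect_lt(t_ratio(inner, V), 1)
  expect_error(t_ratio(pts, rbind(c(0, 0), c(1, 1), c(2, 2))), "degenerate")
})

test_that("shuffle test separates planted simplex from its own null", {
  set.seed(5)
  V <- rbind(c(0, 0), c(4, 0), c(0, 3))
  W <- matrix(rgamma(3000, 0.65), 1000)
  W <- W / rowSums(W)
  pts <- W %*% V + matrix(rnorm(2000, 0, 0.05), 1000)
  st <- shuffle_test(pts, 3, n_shuffles = 100, seed = 6)
  expect_equal(st$p_value, 1 / 101)       # the minimum under add-one
  expect_length(st$t_null, 100)
  expect_error(shuffle_test(pts, 3, n_shuffles = 0), "n_shuffles")
})

test_that("percent_inside agrees exactly with a facet-orientation oracle", {
  set.seed(8)
  V <- rbind(c(0, 0), c(3, 0.5), c(1, 2.5))
  pts <- matrix(runif(400, -0.5, 3), 200, 2)
  got <- percent_inside(pts, V)
  oracle <- mean(facet_sign_inside(pts, V))
  expect_equal(got, oracle)
  # vertices themselves and the centroid count as inside
  expect_equal(percent_inside(V, V), 1)
  expect_equal(percent_inside(rbind(colMeans(V)), V), 1)
  expect_error(percent_inside(pts, rbind(c(0, 0), c(1, 1), c(2, 2))),
               "degenerate")
})

test_that("bootstrap matching is a permutation and tracks noise", {
  set.seed(9)
  V <- rbind(c(0, 0), c(4, 0), c(0, 3))
  # zero-noise vertex-only data: vanishing vertex covariance
  pts0 <- V[rep(1:3, each = 40), ]
  b0 <- bootstrap_vertices(pts0, k = 3, n_boot = 30, seed = 1)
  expect_lt(max(vapply(b0$cov, function(m) sum(diag(m)), numeric(1))), 1e-10)
  expect_equal(b0$n_used + b0$n_discarded, 30)
  # covariance grows with planted noise
  tr_at <- function(sig) {
    set.seed(11)
    W <- matrix(rgamma(1200, 0.65), 400)
    W <- W / rowSums(W)
    pts <- W %*% V + matrix(rnorm(800, 0, sig), 400)
    b <- bootstrap_vertices(pts, k = 3, n_boot = 30, seed = 2)
    mean(vapply(b$cov, function(m) sum(diag(m)), numeric(1)))
  }
  traces <- c(tr_at(0.01), tr_at(0.1), tr_at(0.5))
  expect_true(all(diff(traces) > 0))
})

test_that("dimension sweep stops at significance and records all p-values", {
  set.seed(10)
  # planted tetrahedron occupying 3 dims of a 6-dim space
  V <- rbind(c(0, 0, 0), c(6, 0, 0), c(0, 6, 0), c(2, 2, 5))
  W <- matrix(rgamma(2400, 0.65), 600)
  W <- W / rowSums(W)
  pts <- cbind(W %*% V, matrix(rnorm(1800, 0, 0.3), 600)) +
    matrix(rnorm(3600, 0, 0.15), 600)
  pc <- pca_linear(pts, 6)
  fit <- sweep_dimensions(pc, dims = c(5, 4, 3, 2), alpha = 0.05,
                          n_shuffles = 100, seed = 3)
  expect_s3_class(fit, "polytope_fit")
  expect_true(fit$significant)
  expect_equal(fit$k, 4)
  expect_lt(fit$p_value, 0.05)
  expect_equal(nrow(fit$p_values), match(fit$dimension, c(5, 4, 3, 2)))
  # max k over the default dims is 6
  expect_true(all(fit$p_values$k <= 6))
  # a null stratum sweeps all dims and reports 4 p-values, flagged
  null_pts <- matrix(rnorm(500 * 6), 500) %*% diag(c(5, 4, 3, 2, 1.5, 1))
  pcn <- pca_linear(null_pts, 6)
  fitn <- sweep_dimensions(pcn, dims = c(5, 4, 3, 2), alpha = 0.05,
                           n_shuffles = 60, seed = 4)
  if (!fitn$significant) {
    expect_equal(nrow(fitn$p_values), 4)
    expect_equal(fitn$dimension, 5)
  }
  expect_error(sweep_dimensions(matrix(rnorm(50), 50, 1)), "fewer than 2")
})

test_that("polytope_fit methods expose the model coherently", {
  set.seed(12)
  V <- rbind(c(0, 0), c(4, 0), c(0, 3))
  W <- matrix(rgamma(900, 0.65), 300)
  W <- W / rowSums(W)
  pts <- W %*% V + matrix(rnorm(600, 0, 0.05), 300)
  fit <- fit_polytope(pts, k = 3, n_shuffles = 60, seed = 2)
  expect_s3_class(fit, "polytope_fit")
  expect_output(print(fit), "vertices in")
  expect_output(print(summary(fit)), "Explained-variance")
  expect_equal(dim(coef(fit)), c(3, 2))
  pw <- predict(fit)
  expect_equal(dim(pw), c(300, 3))
  expect_true(all(abs(rowSums(predict(fit, pts[1:5, ])) - 1) < 1e-9))
  expect_equal(dim(fitted(fit)), dim(pts))
  expect_equal(residuals(fit), pts - fitted(fit))
  sim <- simulate(fit, nsim = 2, seed = 3, n = 50)
  expect_length(sim, 2)
  expect_equal(dim(sim[[1]]), c(50, 2))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
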