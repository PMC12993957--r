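test_that("vertex distance ranking matches brute force and isometries", {
  set.seed(1)
  S <- matrix(rnorm(120), 60, 2)
  v <- c(0.3, -0.2)
  ord <- rank_cells_by_vertex_distance(S, v)
  d <- sqrt(rowSums(sweep(S, 2, v)^2))
  expect_equal(ord, order(d, seq_along(d)))
  expect_equal(d[ord], sort(d))
  # a cell coinciding with the vertex comes first
  S2 <- rbind(S, v)
  expect_equal(rank_cells_by_vertex_distance(S2, v)[1], 61L)
  # rigid rotation leaves the ordering invariant
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(rank_cells_by_vertex_distance(S %*% R, as.numeric(v %*% R)),
               ord)
})

test_that("the exact Mann-Whitney p matches small-sample enumeration", {
  # bin (5,6,7) vs rest (1,2,3): most extreme of C(6,3)=20 orderings
  X <- matrix(c(5, 6, 7, 1, 2, 3), ncol = 1)
  p <- paretocell:::mann_whitney_columns(X, 1:3)
  expect_equal(p, 1 / 20)
  # constant gene
  Xc <- matrix(1, 6, 1)
  expect_equal(paretocell:::mann_whitney_columns(Xc, 1:3), 1)
})

test_that("vectorized Mann-Whitney agrees with wilcox.test across regimes", {
  set.seed(2)
  # with ties (counts) and larger groups: normal approximation path
  X <- matrix(rpois(80 * 20, 3), 80, 20)
  bin <- 1:12
  p_pkg <- paretocell:::mann_whitney_columns(X, bin)
  p_ref <- mw_oracle(X, bin)
  expect_equal(p_pkg, unname(p_ref), tolerance = 1e-8)
  # tie-free small samples: exact path
  Y <- matrix(rnorm(30 * 10), 30, 10)
  p_pkg2 <- paretocell:::mann_whitney_columns(Y, 1:10)
  p_ref2 <- mw_oracle(Y, 1:10)
  expect_equal(p_pkg2, unname(p_ref2), tolerance = 1e-10)
})

test_that("enrichment flags planted markers with positive effect", {
  set.seed(3)
  n <- 200
  X <- matrix(rpois(n * 50, 5), n, 50)
  ord <- seq_len(n)
  X[1:20, 1:5] <- rpois(20 * 5, 25)       # genes 1-5 hot in the nearest bin
  colnames(X) <- sprintf("g%02d", 1:50)
  e <- enrich_vertex(X, ord, bin_fraction = 0.10)
  expect_equal(nrow(e), 50)
  expect_true(all(e$p[1:5] < 1e-4))
  expect_true(all(e$effect_size[1:5] > 0))
  expect_gt(min(e$p[6:50]), 0.001)
  expect_error(enrich_vertex(X[1:8, ], 1:8), "all cells")
})

test_that("BH step-up matches the hand-computed worked example", {
  p <- c(0.01, 0.02, 0.03, 0.04, 0.05)
  expect_equal(bh_correct(p), rep(0.05, 5))
  expect_equal(bh_correct(0.03), 0.03)
  # monotone: sorting by p sorts by q
  set.seed(4)
  pr <- runif(50)
  q <- bh_correct(pr)
  expect_true(all(diff(q[order(pr)]) >= -1e-12))
  expect_true(all(q >= pr - 1e-12))
  expect_true(all(q <= 1))
})

test_that("uniform p-values rarely pass the 0.10 BH cap under the null", {
  set.seed(5)
  hits <- replicate(100, sum(bh_correct(runif(1000)) < 0.10))
  expect_lt(mean(hits) / 1000, 0.01)    # mean discovery fraction ~ 0
})

test_that("top_markers applies the q/effect filters and the up-to rule", {
  tab <- data.frame(stratum_id = "s", vertex = 1,
                    gene_id = sprintf("g%02d", 1:6),
                    effect_size = c(5, 4, 3, -2, 6, 1),
                    p = c(0.001, 0.002, 0.003, 0.001, 0.2, 0.004),
                    q = c(0.01, 0.02, 0.03, 0.01, 0.5, 0.04))
  got <- top_markers(tab, 1, n = 10)
  # only significant, positive-effect genes, by descending effect
  expect_equal(got, c("g01", "g02", "g03", "g06"))
  expect_equal(top_markers(tab, 1, n = 2), c("g01", "g02"))
  none <- top_markers(tab[tab$q > 0.2, ], 1)
  expect_length(none, 0)
  expect_true(attr(none, "flagged"))
})

test_that("vertex_enrichment finds planted markers at their own vertex", {
  set.seed(6)
  spec <- random_archetype_spec(3, 80, n_markers = 6, marker_fold = 4,
                                seed = 8)
  g <- generate_stratum(400, 80, spec, seed = 8)
  x <- as.matrix(g$counts)
  x <- x * (1e4 / pmax(rowSums(x), 1))
  colnames(x) <- sprintf("g%02d", 1:80)
  pc <- pca_linear(x, 5)
  fit <- fit_polytope(pc$scores[, 1:2], k = 3, n_shuffles = 60, seed = 2)
  tab <- vertex_enrichment(fit, x, stratum_id = "toy")
  expect_true(all(c("vertex", "gene_id", "effect_size", "p", "q", "rank")
                  %in% names(tab)))
  expect_equal(sort(unique(tab$vertex)), 1:3)
  # every vertex of this strong planted fit has enriched genes, and the
  # top markers of each vertex are dominated by one planted marker set
  marker_sets <- lapply(g$truth$marker_genes,
                        function(ix) sprintf("g%02d", ix))
  overlap <- sapply(1:3, function(v) {
    tm <- top_markers(tab, v)
    expect_gt(length(tm), 0)
    max(sapply(marker_sets, function(ms) length(intersect(tm, ms))))
  })
  expect_true(all(overlap >= 4))
})
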