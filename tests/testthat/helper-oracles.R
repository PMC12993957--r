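# Independent oracles used across the test files.

# exact 2-D polygon area of the convex hull via chull + shoelace
shoelace_hull_area <- function(pts) {
  h <- grDevices::chull(pts)
  p <- pts[h, , drop = FALSE]
  n <- nrow(p)
  j <- c(2:n, 1)
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}

# membership of points in a full-dimensional simplex by facet orientation
# signs (determinant test, no barycentric solve)
facet_sign_inside <- function(points, vertices, tol = 1e-9) {
  k <- nrow(vertices)
  d <- ncol(vertices)
  stopifnot(k == d + 1)
  apply(points, 1, function(x) {
    for (leave in seq_len(k)) {
      face <- vertices[-leave, , drop = FALSE]
      opp <- vertices[leave, ]
      M_opp <- cbind(rbind(face, opp), 1)
      M_x <- cbind(rbind(face, x), 1)
      s_opp <- det(M_opp)
      s_x <- det(M_x)
      # x must be on the same side of the facet plane as the opposite vertex
      if (s_opp * s_x < -tol * abs(s_opp)) return(FALSE)
    }
    TRUE
  })
}

# random point set whose convex hull is a known simplex: k = d+1 random
# vertices plus interior Dirichlet fill; analytic volume = |det| / d!
random_simplex_cloud <- function(d, n_interior = 60, scale = 2) {
  repeat {
    V <- matrix(stats::rnorm((d + 1) * d, sd = scale), d + 1, d)
    vol <- abs(det(sweep(V[-1, , drop = FALSE], 2, V[1, ]))) / factorial(d)
    if (vol > 0.1) break
  }
  W <- matrix(stats::rgamma(n_interior * (d + 1), 1), n_interior)
  W <- W / rowSums(W)
  list(points = rbind(V, W %*% V), vertices = V, volume = vol)
}

# Monte-Carlo rejection estimate of a simplex-hulled cloud's volume, with
# membership via exact barycentric coordinates (independent linear solve)
mc_simplex_volume <- function(vertices, n_mc = 2e5) {
  d <- ncol(vertices)
  lo <- apply(vertices, 2, min)
  hi <- apply(vertices, 2, max)
  Z <- sapply(seq_len(d), function(j) stats::runif(n_mc, lo[j], hi[j]))
  A <- rbind(t(vertices), 1)
  Wb <- solve(A, rbind(t(Z), 1))
  inside <- apply(Wb, 2, min) >= 0
  mean(inside) * prod(hi - lo)
}

# dense-loop Mann-Whitney oracle via stats::wilcox.test, one gene at a time
mw_oracle <- function(X, bin_idx) {
  apply(X, 2, function(v) {
    if (max(v) == min(v)) return(1)
    suppressWarnings(stats::wilcox.test(v[bin_idx], v[-bin_idx],
                                        alternative = "greater")$p.value)
  })
}

# exhaustive Poisson-binomial tail over all 2^D outcomes
pb_tail_enum <- function(q, threshold) {
  D <- length(q)
  total <- 0
  for (mask in 0:(2^D - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(D)]
    if (sum(bits) < threshold) next
    total <- total + prod(ifelse(bits == 1, q, 1 - q))
  }
  total
}

# matched mean vertex error (Hungarian assignment), as fraction of diameter
matched_vertex_error <- function(V_true, V_fit) {
  k <- nrow(V_true)
  D <- as.matrix(stats::dist(rbind(V_true, V_fit)))[seq_len(k),
                                                    k + seq_len(k)]
  a <- clue::solve_LSAP(D)
  mean(D[cbind(seq_len(k), as.integer(a))]) / max(stats::dist(V_true))
}

# small deterministic atlas for IO/QC tests
tiny_atlas <- function(n_cells = 30, n_genes = 20, seed = 1) {
  set.seed(seed)
  counts <- matrix(rpois(n_cells * n_genes, 5), n_cells)
  cell_meta <- data.frame(cell_id = sprintf("c%02d", seq_len(n_cells)),
                          donor = rep(c("D1", "D2"), length.out = n_cells),
                          tissue = "T1",
                          cell_type = rep(c("A", "B"), length.out = n_cells),
                          stringsAsFactors = FALSE)
  gene_meta <- data.frame(gene_id = sprintf("g%02d", seq_len(n_genes)),
                          is_protein_coding = rep(TRUE, n_genes),
                          is_mitochondrial = c(TRUE, TRUE, rep(FALSE, n_genes - 2)),
                          is_artifact = c(FALSE, FALSE, TRUE, rep(FALSE, n_genes - 3)),
                          stringsAsFactors = FALSE)
  expression_atlas(counts, cell_meta, gene_meta)
}
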