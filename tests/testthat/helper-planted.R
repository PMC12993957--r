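# Planted-geometry generators shared by the heavier statistical tests.

# regular simplex with unit edge, scaled; k = 3 (triangle) or 4 (tetrahedron)
regular_simplex <- function(k, edge = 10) {
  V <- if (k == 3) {
    rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  } else if (k == 4) {
    rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
          c(0.5, sqrt(3) / 6, sqrt(6) / 3))
  } else stop("k must be 3 or 4")
  V * edge
}

# Dirichlet(0.65) fill of a planted simplex plus isotropic vertex noise
# expressed as a fraction of the edge length
planted_simplex_points <- function(k, n, noise_frac = 0.05, edge = 10,
                                   seed = 1) {
  set.seed(seed)
  V <- regular_simplex(k, edge)
  W <- matrix(stats::rgamma(n * k, 0.65), n)
  W <- W / rowSums(W)
  pts <- W %*% V + matrix(stats::rnorm(n * ncol(V), 0, noise_frac * edge), n)
  list(points = pts, vertices = V, edge = edge)
}

# one end-to-end discrimination replicate: synthetic atlas with two polytopal
# cell types and one null cell type, full pipeline, scaled shuffles
endtoend_replicate <- function(seed, n_shuffles = 200) {
  ga <- generate_atlas(4, 2,
                       list(alpha_like = list(k = 3),
                            beta_like = list(k = 4),
                            null_type = "null"),
                       n_genes = 300, size_range = c(100, 200),
                       qc_contamination = 0.05, seed = seed)
  cfg <- pipeline_config(n_shuffles = n_shuffles, n_boot = 0,
                         seed = seed + 1)
  res <- run_pipeline(ga$atlas, cfg)
  list(accepted = sort(res$celltype$accepted),
       truth = sort(setdiff(ga$truth$cell_types, ga$truth$null_cell_types)),
       result = res)
}
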