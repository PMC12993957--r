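test_that("rare-gene filter removes genes below the cell-support threshold", {
  # toy matrix with known support per gene
  counts <- matrix(0, 10, 6)
  support <- c(10, 5, 4, 1, 0, 7)
  for (j in seq_len(6)) if (support[j] > 0) counts[seq_len(support[j]), j] <- 2
  cm <- data.frame(cell_id = paste0("c", 1:10), donor = "D", tissue = "T",
                   cell_type = "A")
  gm <- data.frame(gene_id = paste0("g", 1:6), is_protein_coding = TRUE,
                   is_mitochondrial = FALSE, is_artifact = FALSE)
  atlas <- expression_atlas(counts, cm, gm)
  f5 <- filter_rare_genes(atlas, 5)
  expect_setequal(f5$gene_meta$gene_id, c("g1", "g2", "g6"))
  f0 <- filter_rare_genes(atlas, 0)
  expect_equal(ncol(f0$counts), 6)
  expect_error(filter_rare_genes(atlas, 100), "all genes")
})

test_that("QC metrics match a dense-loop recomputation", {
  atlas <- tiny_atlas(20, 8, seed = 2)
  m <- compute_qc_metrics(atlas)
  X <- as.matrix(atlas$counts)
  g <- atlas$gene_meta
  for (i in c(1, 7, 20)) {
    tot <- sum(X[i, ])
    expect_equal(m$pct_mito[i], sum(X[i, g$is_mitochondrial]) / tot)
    expect_equal(m$pct_artifact[i], sum(X[i, g$is_artifact]) / tot)
    expect_equal(m$n_genes_expressed[i], sum(X[i, ] > 0))
    expect_equal(m$total_counts[i], tot)
    expect_equal(m$n_umi[i], tot)
    pc_sel <- g$is_protein_coding & !g$is_mitochondrial & !g$is_artifact
    expect_equal(m$protein_coding_counts[i], sum(X[i, pc_sel]))
  }
})

test_that("an all-zero cell is flagged with zero fractions", {
  counts <- matrix(3, 5, 4)
  counts[2, ] <- 0
  cm <- data.frame(cell_id = paste0("c", 1:5), donor = "D", tissue = "T",
                   cell_type = "A")
  gm <- data.frame(gene_id = paste0("g", 1:4), is_protein_coding = TRUE,
                   is_mitochondrial = c(TRUE, FALSE, FALSE, FALSE),
                   is_artifact = FALSE)
  m <- compute_qc_metrics(expression_atlas(counts, cm, gm))
  expect_true(m$zero_total[2])
  expect_equal(m$pct_mito[2], 0)
  expect_equal(m$pct_artifact[2], 0)
  expect_equal(m$pct_mito[1], 0.25)
})

test_that("upper-decile filter uses strict exceedance of the 0.9 quantile", {
  m <- data.frame(v = 1:10)
  keep <- filter_upper_decile(m, "v")
  # 90th percentile of 1..10 (linear interpolation) is 9.1: only 10 removed
  expect_equal(which(!keep), 10L)
  # constant metric removes nothing
  m2 <- data.frame(v = rep(4, 12))
  expect_true(all(filter_upper_decile(m2, "v")))
  # two metrics with disjoint top cells: union removed
  m3 <- data.frame(a = c(rep(1, 19), 9), b = c(9, rep(1, 19)))
  keep3 <- filter_upper_decile(m3, c("a", "b"))
  expect_setequal(which(!keep3), c(1L, 20L))
})

test_that("protein-coding floor flags at-or-below threshold only", {
  m <- data.frame(cell_id = c("a", "b", "c"),
                  protein_coding_counts = c(100, 101, 12))
  expect_setequal(assert_min_protein_coding(m, 100), c("a", "c"))
  expect_setequal(assert_min_protein_coding(m, 11), character(0))
})

test_that("normalization scales each cell to 10,000 and preserves proportions", {
  atlas <- tiny_atlas(25, 12, seed = 8)
  na <- normalize_and_strip(atlas)
  expect_true(all(abs(Matrix::rowSums(na$norm) - 1e4) < 1e-6))
  # proportions within a cell preserved among retained genes
  X <- as.matrix(atlas$counts)
  g <- atlas$gene_meta
  sel <- g$is_protein_coding & !g$is_mitochondrial & !g$is_artifact
  i <- 3
  expect_equal(as.numeric(na$norm[i, ]) / sum(na$norm[i, ]),
               X[i, sel] / sum(X[i, sel]), ignore_attr = TRUE)
  # a cell of counts (1,2,2) scales to (2000,4000,4000)
  counts <- matrix(c(1, 2, 2), 1, 3)
  cm <- data.frame(cell_id = "c1", donor = "D", tissue = "T", cell_type = "A")
  gm <- data.frame(gene_id = paste0("g", 1:3), is_protein_coding = TRUE,
                   is_mitochondrial = FALSE, is_artifact = FALSE)
  n1 <- normalize_and_strip(expression_atlas(counts, cm, gm))
  expect_equal(as.numeric(n1$norm[1, ]), c(2000, 4000, 4000))
  # mito/artifact genes are stripped from the modeling matrix but kept in
  # the all-genes matrix on the same scale
  expect_equal(ncol(na$norm), sum(sel))
  expect_equal(ncol(na$norm_all), ncol(X))
  expect_equal(as.numeric(na$norm_all[i, which(sel)]),
               as.numeric(na$norm[i, ]))
})

test_that("stratification applies the size window with seeded downsampling", {
  set.seed(1)
  n <- 260
  counts <- matrix(rpois(n * 10, 6), n)
  cm <- data.frame(cell_id = sprintf("c%03d", 1:n),
                   donor = c(rep("D1", 49), rep("D2", 211)),
                   tissue = "T1",
                   cell_type = "A")
  gm <- data.frame(gene_id = paste0("g", 1:10), is_protein_coding = TRUE,
                   is_mitochondrial = FALSE, is_artifact = FALSE)
  na <- normalize_and_strip(expression_atlas(counts, cm, gm))
  st <- stratify(na, min_cells = 50, max_cells = 100, seed = 7)
  # the 49-cell donor group is excluded; the 211-cell group is capped at 100
  expect_length(st, 1)
  expect_equal(st[[1]]$donor, "D2")
  expect_equal(nrow(st[[1]]$x), 100)
  expect_equal(st[[1]]$n_cells_original, 211)
  st2 <- stratify(na, min_cells = 50, max_cells = 100, seed = 7)
  expect_identical(st[[1]]$cell_ids, st2[[1]]$cell_ids)
  st3 <- stratify(na, min_cells = 50, max_cells = 100, seed = 8)
  expect_false(identical(st[[1]]$cell_ids, st3[[1]]$cell_ids))
})

test_that("stratum count on a generated atlas matches the planted truth", {
  ga <- generate_atlas(2, 2, list(A = list(k = 3), N = "null"),
                       n_genes = 150, size_range = c(120, 160), seed = 9)
  a <- filter_rare_genes(ga$atlas, 5)
  qc <- apply_cell_qc(a)
  na <- normalize_and_strip(qc$atlas)
  st <- stratify(na, seed = 1, qc_metrics = qc$metrics)
  expect_length(st, length(ga$truth$strata))
  expect_setequal(names(st), names(ga$truth$strata))
})
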