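test_that("vertex graph weights are shared-gene counts", {
  l1 <- LETTERS[1:10]
  l2 <- c(LETTERS[1:5], LETTERS[11:15])
  l3 <- LETTERS[16:25]
  A <- build_vertex_graph(list(l1, l2, l3))
  expect_equal(A[1, 2], 5L)
  expect_equal(A[1, 3], 0L)
  expect_equal(A, t(A))
  expect_true(all(diag(A) == 0))
  # brute-force double loop
  ml <- replicate(6, sample(LETTERS, 8), simplify = FALSE)
  B <- build_vertex_graph(ml)
  for (i in 1:6) for (j in 1:6) {
    if (i == j) next
    expect_equal(B[i, j], length(intersect(ml[[i]], ml[[j]])))
  }
})

test_that("disconnected weight blocks yield exactly two clusters", {
  block <- matrix(10, 3, 3); diag(block) <- 0
  A <- rbind(cbind(block, matrix(0, 3, 3)),
             cbind(matrix(0, 3, 3), block))
  labels <- cluster_vertices(A, seed = 1)
  expect_equal(length(unique(labels)), 2)
  expect_equal(length(unique(labels[1:3])), 1)
  expect_equal(length(unique(labels[4:6])), 1)
  expect_false(labels[1] == labels[4])
})

test_that("coverage filter counts distinct donors against the roster", {
  labels <- c(1, 1, 1, 2, 2)
  donors <- c("D1", "D2", "D1", "D3", "D3")
  cov <- coverage_filter(labels, donors, c("D1", "D2", "D3", "D4"),
                         threshold = 0.5)
  expect_equal(cov$coverage[cov$cluster == 1], 0.5)   # 2 of 4, boundary
  expect_true(cov$accepted[cov$cluster == 1])
  cov23 <- coverage_filter(labels, donors, c("D1", "D2", "D3", "D4"),
                           threshold = 2 / 3)
  expect_false(cov23$accepted[cov23$cluster == 1])
  # redundant vertices from a single donor never lift coverage
  cov1 <- coverage_filter(rep(1, 4), rep("D1", 4), c("D1", "D2", "D3"))
  expect_equal(cov1$coverage, 1 / 3)
  expect_false(cov1$accepted)
})

test_that("consensus genes drop frequency-one entries and rank by frequency", {
  got <- consensus_genes(list(c("A", "B", "C"), c("A", "B"), c("A")))
  expect_equal(got$gene, c("A", "B"))
  expect_equal(got$frequency, c(3L, 2L))
  same <- consensus_genes(replicate(5, LETTERS[1:10], simplify = FALSE))
  expect_equal(nrow(same), 10)
  expect_true(all(same$frequency == 5))
  nothing <- consensus_genes(list(c("A"), c("B")))
  expect_equal(nrow(nothing), 0)
  expect_true(attr(nothing, "flagged"))
})

make_nodes <- function(markers_per_arch, donors, tissues, scramble = 0,
                       seed = 1) {
  # one vertex node per (donor, tissue, archetype)
  set.seed(seed)
  gene_pool <- sprintf("x%03d", 1:500)
  rows <- list()
  for (d in donors) for (t in tissues) {
    for (a in seq_along(markers_per_arch)) {
      ml <- markers_per_arch[[a]]
      if (scramble > 0) {
        swap <- sample(length(ml), round(scramble * length(ml)))
        ml[swap] <- sample(gene_pool, length(swap))
      }
      rows[[length(rows) + 1]] <- data.frame(
        stratum_id = paste(d, t, sep = "|"), vertex = a, donor = d,
        tissue = t, stringsAsFactors = FALSE)
      rows[[length(rows)]]$markers <- list(ml)
    }
  }
  do.call(rbind, rows)
}

test_that("zero-jitter planted archetypes align perfectly", {
  skip_if_not_installed("mclust")
  markers <- split(sprintf("m%02d", 1:40), rep(1:4, each = 10))
  donors <- sprintf("D%d", 1:3)
  nodes <- make_nodes(markers, donors, c("T1", "T2"))
  al <- align_archetypes(nodes, donors_available = donors, seed = 1)
  truth <- rep(1:4, times = 6)
  ari <- mclust::adjustedRandIndex(al$labels, truth)
  expect_equal(ari, 1)
  acc <- Filter(function(cl) cl$accepted, al$clusters)
  expect_length(acc, 4)
  for (cl in acc) {
    expect_equal(cl$donor_coverage, 1)
    expect_setequal(cl$consensus$gene, markers[[cl$members$vertex[1]]])
    expect_equal(cl$annotation, "unannotated")
  }
})

test_that("alignment is robust to moderate marker-list noise", {
  skip_if_not_installed("mclust")
  markers <- split(sprintf("m%02d", 1:40), rep(1:4, each = 10))
  donors <- sprintf("D%d", 1:3)
  nodes <- make_nodes(markers, donors, c("T1", "T2"), scramble = 0.3,
                      seed = 5)
  al <- align_archetypes(nodes, donors_available = donors, seed = 1)
  truth <- rep(1:4, times = 6)
  expect_gte(mclust::adjustedRandIndex(al$labels, truth), 0.9)
})

test_that("alignment is invariant to node permutation", {
  skip_if_not_installed("mclust")
  markers <- split(sprintf("m%02d", 1:30), rep(1:3, each = 10))
  donors <- sprintf("D%d", 1:3)
  nodes <- make_nodes(markers, donors, c("T1", "T2"), scramble = 0.2,
                      seed = 9)
  al1 <- align_archetypes(nodes, donors, seed = 1)
  perm <- sample(nrow(nodes))
  al2 <- align_archetypes(nodes[perm, ], donors, seed = 1)
  expect_equal(mclust::adjustedRandIndex(al1$labels[perm], al2$labels), 1)
})

test_that("empty-marker nodes are excluded and reported", {
  markers <- split(sprintf("m%02d", 1:20), rep(1:2, each = 10))
  nodes <- make_nodes(markers, c("D1", "D2"), "T1")
  nodes$markers[[1]] <- character(0)
  al <- align_archetypes(nodes, c("D1", "D2"), seed = 1)
  expect_equal(nrow(al$excluded_nodes), 1)
  expect_equal(length(al$labels), nrow(nodes) - 1)
})

test_that("archetype profiles put planted markers highest at their own cluster", {
  # two strata sharing two archetypes, planted markers expressed at vertex 1
  set.seed(13)
  spec <- random_archetype_spec(3, 60, n_markers = 5, seed = 13)
  fits <- list(); strata <- list(); spaces <- list(); rows <- list()
  for (sid in c("D1|T1|ct", "D2|T1|ct")) {
    g <- generate_stratum(300, 60, spec, seed = nchar(sid) + which(sid == c("D1|T1|ct", "D2|T1|ct")))
    x <- as.matrix(g$counts); x <- x * (1e4 / pmax(rowSums(x), 1))
    colnames(x) <- sprintf("g%02d", 1:60)
    pc <- pca_linear(x, 5)
    fit <- fit_polytope(pc$scores[, 1:2], k = 3, n_shuffles = 30, seed = 3)
    fit$stratum_id <- sid
    tab <- vertex_enrichment(fit, x, stratum_id = sid)
    fits[[sid]] <- fit
    strata[[sid]] <- list(x_all = x)
    spaces[[sid]] <- list(keep_cells = rep(TRUE, 300))
    for (v in 1:3) {
      rows[[paste(sid, v)]] <- data.frame(stratum_id = sid, vertex = v,
                                          donor = substr(sid, 1, 2),
                                          tissue = "T1")
      rows[[paste(sid, v)]]$markers <- list(top_markers(tab, v))
    }
  }
  nodes <- do.call(rbind, rows)
  al <- align_archetypes(nodes, c("D1", "D2"), seed = 1)
  prof <- archetype_expression_profile(al, fits, strata, spaces,
                                       closest_fraction = 0.05)
  expect_equal(ncol(prof$profile), length(prof$genes))
  # for each accepted cluster the consensus genes are higher in their own
  # archetype than in the pooled others
  for (i in seq_along(al$clusters)) {
    cl <- al$clusters[[i]]
    if (!cl$accepted || nrow(cl$consensus) == 0) next
    own <- prof$profile[i, prof$genes %in% cl$consensus$gene]
    oth <- prof$other[i, prof$genes %in% cl$consensus$gene]
    expect_gt(mean(own > oth), 0.7)
  }
})
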