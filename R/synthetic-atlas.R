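#' Specify a planted archetype structure
#'
#' An `archetype_spec` describes the generative model for one polytopal cell
#' type: `k` archetype expression profiles (rows of `vertex_profiles`, linear
#' scale), per-archetype marker genes whose profile entry is elevated by a
#' fold factor at their own archetype only, a Dirichlet concentration for the
#' per-cell mixture weights, and a count-noise model. Cells are convex
#' combinations of the archetype profiles plus counting noise, so in
#' expression space they populate a `k`-vertex simplex.
#'
#' @param vertex_profiles numeric matrix, `k x genes`, non-negative mean
#'   expression of each archetype. Row sums must be positive.
#' @param marker_genes list of length `k`; element `a` holds the column
#'   indices (or names) of the markers of archetype `a`. A gene may mark at
#'   most one archetype.
#' @param dirichlet_alpha positive scalar; concentration of the flat
#'   Dirichlet from which mixture weights are drawn. The default 0.65 keeps
#'   vertices populated while leaving the interior non-empty.
#' @param noise_model `"poisson"`, `"negative_binomial"`, or `"none"` (the
#'   zero-noise limit, returning expected expression directly).
#' @param dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); ignored for other noise models.
#' @param seed integer seed stored with the spec and used as the default for
#'   [generate_stratum()].
#' @return An object of class `archetype_spec`.
#' @seealso [random_archetype_spec()], [generate_stratum()]
#' @export
archetype_spec <- function(vertex_profiles, marker_genes,
                           dirichlet_alpha = 0.65,
                           noise_model = c("poisson", "negative_binomial", "none"),
                           dispersion = 0.5, seed = 1L) {
  noise_model <- match.arg(noise_model)
  vertex_profiles <- as.matrix(vertex_profiles)
  k <- nrow(vertex_profiles)
  if (k < 2) stop("need at least 2 archetypes (k >= 2)")
  if (any(vertex_profiles < 0)) stop("vertex_profiles must be non-negative")
  if (any(rowSums(vertex_profiles) <= 0)) stop("vertex_profiles row sums must be > 0")
  if (dirichlet_alpha <= 0) stop("dirichlet_alpha must be > 0")
  if (noise_model == "negative_binomial" && dispersion <= 0)
    stop("dispersion must be > 0 for negative_binomial noise")
  if (length(marker_genes) != k) stop("marker_genes must have one element per archetype")
  flat <- unlist(marker_genes)
  if (anyDuplicated(flat)) stop("each marker gene may mark exactly one archetype")
  structure(list(n_archetypes = k,
                 vertex_profiles = vertex_profiles,
                 marker_genes = marker_genes,
                 dirichlet_alpha = dirichlet_alpha,
                 noise_model = noise_model,
                 dispersion = dispersion,
                 seed = as.integer(seed)),
            class = "archetype_spec")
}

#' Draw a random archetype specification
#'
#' Builds an [archetype_spec()] with log-normal baseline gene means shared by
#' all archetypes, mild per-archetype profile jitter on non-marker genes, and
#' `n_markers` dedicated marker genes per archetype whose entry at their own
#' archetype is the baseline times `marker_fold` (other archetypes keep the
#' un-jittered baseline, so the planted marker mean is strictly largest at
#' its own archetype).
#'
#' @param k number of archetypes (2-6).
#' @param n_genes number of genes the profiles span.
#' @param n_markers markers per archetype.
#' @param marker_fold fold elevation of a marker at its archetype (> 1).
#' @param profile_sdlog sdlog of the multiplicative jitter distinguishing
#'   archetype profiles on non-marker genes.
#' @param meanlog,sdlog log-normal parameters of baseline gene means.
#' @param seed integer seed.
#' @inheritParams archetype_spec
#' @return An `archetype_spec`.
#' @export
random_archetype_spec <- function(k, n_genes, n_markers = 10, marker_fold = 4,
                                  dirichlet_alpha = 0.65,
                                  noise_model = "poisson", dispersion = 0.5,
                                  profile_sdlog = 0.25,
                                  meanlog = 1, sdlog = 1, seed = 1L) {
  if (k < 2 || k > 6) stop("k must be in 2..6")
  if (k * n_markers > n_genes) stop("not enough genes for the requested markers")
  if (marker_fold <= 1) stop("marker_fold must be > 1")
  set.seed(seed)
  base <- stats::rlnorm(n_genes, meanlog = meanlog, sdlog = sdlog)
  prof <- matrix(rep(base, each = k), nrow = k)
  jit <- matrix(exp(stats::rnorm(k * n_genes, 0, profile_sdlog)), nrow = k)
  prof <- prof * jit
  markers <- split(seq_len(k * n_markers), rep(seq_len(k), each = n_markers))
  for (a in seq_len(k)) {
    idx <- markers[[a]]
    prof[, idx] <- rep(base[idx], each = k)     # un-jittered baseline
    prof[a, idx] <- base[idx] * marker_fold     # elevated at own archetype
  }
  names(markers) <- NULL
  archetype_spec(prof, markers, dirichlet_alpha = dirichlet_alpha,
                 noise_model = noise_model, dispersion = dispersion,
                 seed = seed)
}

#' Generate one stratum with planted simplex structure
#'
#' Cell `i`'s expected expression is `s_i * sum_a w_ia * vertex_profiles[a, ]`
#' with mixture weights `w_i ~ Dirichlet(alpha)` and a per-cell library-size
#' factor `s_i ~ log-normal(0, library_sdlog)` (removed downstream by the
#' 10,000-count normalization). Counts are drawn per the spec's noise model.
#'
#' @param n_cells number of cells (>= 1).
#' @param n_genes number of genes; must equal `ncol(spec$vertex_profiles)`.
#' @param spec an [archetype_spec()].
#' @param seed integer seed; defaults to `spec$seed`.
#' @param library_sdlog sdlog of the per-cell library-size factor; 0 disables
#'   library-size variation.
#' @return A list with `counts` (sparse `n_cells x n_genes` matrix) and
#'   `truth` (class `planted_truth`): vertex profiles, mixture weights,
#'   marker assignment and the polytopal flag.
#' @export
generate_stratum <- function(n_cells, n_genes, spec, seed = spec$seed,
                             library_sdlog = 0.3) {
  stopifnot(inherits(spec, "archetype_spec"))
  if (n_cells < 1) stop("n_cells must be >= 1")
  k <- spec$n_archetypes
  if (n_genes != ncol(spec$vertex_profiles))
    stop("n_genes does not match spec$vertex_profiles")
  if (k > n_genes) stop("k must not exceed n_genes")
  set.seed(seed)
  W <- rdirichlet_flat(n_cells, k, spec$dirichlet_alpha)
  s <- if (library_sdlog > 0) stats::rlnorm(n_cells, 0, library_sdlog) else rep(1, n_cells)
  mu <- (W %*% spec$vertex_profiles) * s
  counts <- switch(spec$noise_model,
    poisson = matrix(stats::rpois(length(mu), mu), nrow = n_cells),
    negative_binomial = matrix(stats::rnbinom(length(mu), mu = mu,
                                              size = 1 / spec$dispersion),
                               nrow = n_cells),
    none = mu)
  counts <- Matrix::Matrix(counts, sparse = TRUE)
  truth <- structure(list(vertex_profiles = spec$vertex_profiles,
                          weights = W,
                          marker_genes = spec$marker_genes,
                          polytopal = TRUE,
                          library_factors = s),
                     class = "planted_truth")
  list(counts = counts, truth = truth)
}

#' Generate a null stratum with no polytope structure
#'
#' Genes are mutually independent: each gene has a fixed log-normal rate and
#' counts are Poisson draws around it, identically across cells. This is the
#' null regime the shuffle test should not reject.
#'
#' @param n_cells,n_genes dimensions of the stratum.
#' @param seed integer seed.
#' @param meanlog,sdlog log-normal parameters of the per-gene rates.
#' @return Sparse `n_cells x n_genes` count matrix.
#' @export
generate_null_stratum <- function(n_cells, n_genes, seed = 1L,
                                  meanlog = 1, sdlog = 1) {
  if (n_cells < 1) stop("n_cells must be >= 1")
  set.seed(seed)
  lambda <- stats::rlnorm(n_genes, meanlog = meanlog, sdlog = sdlog)
  counts <- matrix(stats::rpois(n_cells * n_genes,
                                rep(lambda, each = n_cells)),
                   nrow = n_cells)
  Matrix::Matrix(counts, sparse = TRUE)
}

#' Generate a synthetic atlas with donor/tissue replication
#'
#' Emulates the donor-tissue-cell-type stratification of a whole-body atlas:
#' every (donor, tissue, cell type) combination becomes one stratum. Strata
#' of the same cell type share the archetype identity (same marker genes);
#' per-stratum multiplicative vertex jitter can be added. A fraction of cells
#' receive inflated mitochondrial/artifact counts to exercise the QC filters,
#' and cell types declared `"null"` carry no polytope structure.
#'
#' @param n_donors,n_tissues number of donors and tissues.
#' @param cell_types named list; each element is either the string `"null"`
#'   or a list of arguments to [random_archetype_spec()] (e.g. `list(k = 3)`).
#' @param n_genes total genes, including mitochondrial/artifact/non-coding.
#' @param qc_contamination fraction of cells per stratum with inflated
#'   mitochondrial and artifact counts (in `[0, 1]`).
#' @param size_range integer range; per-stratum cell counts are drawn
#'   uniformly from it (within `[50, 2000]`).
#' @param vertex_jitter sdlog of per-stratum multiplicative jitter applied to
#'   archetype profiles (0 = identical profiles across strata).
#' @param mito_frac,artifact_frac fraction of genes flagged mitochondrial /
#'   dissociation-artifact.
#' @param inflate_factor count multiplier applied to mito/artifact genes of
#'   contaminated cells.
#' @param seed integer base seed; per-stratum seeds are derived from it with
#'   a counter, so the atlas is fully reproducible.
#' @return A list with `atlas` (an `expression_atlas`) and `truth` (atlas
#'   parameters, per-stratum records with polytopal flags and seeds, and the
#'   per-cell-type marker assignment).
#' @export
generate_atlas <- function(n_donors, n_tissues, cell_types,
                           n_genes = 300, qc_contamination = 0.05,
                           size_range = c(100, 250), vertex_jitter = 0,
                           mito_frac = 0.04, artifact_frac = 0.04,
                           inflate_factor = 8, seed = 1L) {
  if (n_donors < 1) stop("need at least one donor")
  if (qc_contamination < 0 || qc_contamination > 1)
    stop("qc_contamination must be in [0, 1]")
  if (size_range[1] < 50 || size_range[2] > 2000 || size_range[1] > size_range[2])
    stop("size_range must lie within [50, 2000]")
  if (is.null(names(cell_types)) || any(names(cell_types) == ""))
    stop("cell_types must be a named list")
  is_null_ct <- vapply(cell_types, function(x) identical(x, "null"), logical(1))
  if (!any(is_null_ct))
    warning("no null cell type declared; downstream FDR checks lose their negative control")

  gene_id <- sprintf("G%04d", seq_len(n_genes))
  n_mito <- max(2L, round(mito_frac * n_genes))
  n_art <- max(2L, round(artifact_frac * n_genes))
  n_nc <- max(2L, round(0.02 * n_genes))
  is_mito <- c(rep(TRUE, n_mito), rep(FALSE, n_genes - n_mito))
  is_art <- c(rep(FALSE, n_mito), rep(TRUE, n_art), rep(FALSE, n_genes - n_mito - n_art))
  is_pc <- rep(TRUE, n_genes)
  is_pc[(n_mito + n_art + 1):(n_mito + n_art + n_nc)] <- FALSE
  gene_meta <- data.frame(gene_id = gene_id,
                          is_protein_coding = is_pc,
                          is_mitochondrial = is_mito,
                          is_artifact = is_art,
                          stringsAsFactors = FALSE)
  model_genes <- which(is_pc & !is_mito & !is_art)

  # one spec per polytopal cell type, planted on the modeling genes
  specs <- vector("list", length(cell_types))
  names(specs) <- names(cell_types)
  ct_counter <- 0L
  for (ct in names(cell_types)) {
    ct_counter <- ct_counter + 1L
    if (is_null_ct[[ct]]) next
    args <- cell_types[[ct]]
    args$n_genes <- length(model_genes)
    args$seed <- args$seed %||% derive_seed(seed, ct_counter)
    specs[[ct]] <- do.call(random_archetype_spec, args)
  }

  set.seed(derive_seed(seed, 0L))
  # baseline rates for genes outside the planted profiles
  aux_lambda <- stats::rlnorm(n_genes, meanlog = 0.5, sdlog = 0.8)

  counts_list <- list()
  cell_meta_list <- list()
  strata_truth <- list()
  counter <- 0L
  for (donor in sprintf("D%02d", seq_len(n_donors))) {
    for (tissue in sprintf("T%02d", seq_len(n_tissues))) {
      for (ct in names(cell_types)) {
        counter <- counter + 1L
        sseed <- derive_seed(seed, counter)
        set.seed(sseed)
        size_opts <- seq.int(size_range[1], size_range[2])
        n_cells <- size_opts[sample.int(length(size_opts), 1)]
        full <- matrix(0, n_cells, n_genes)
        if (is_null_ct[[ct]]) {
          full <- as.matrix(generate_null_stratum(n_cells, n_genes,
                                                  seed = sseed))
          truth_w <- NULL
        } else {
          spec <- specs[[ct]]
          if (vertex_jitter > 0) {
            set.seed(derive_seed(sseed, 1L))
            jit <- matrix(exp(stats::rnorm(length(spec$vertex_profiles), 0,
                                           vertex_jitter)),
                          nrow = spec$n_archetypes)
            prof <- spec$vertex_profiles * jit
            # keep the marker invariant under jitter
            for (a in seq_len(spec$n_archetypes)) {
              idx <- spec$marker_genes[[a]]
              prof[, idx] <- spec$vertex_profiles[, idx]
            }
            spec_s <- spec
            spec_s$vertex_profiles <- prof
          } else spec_s <- spec
          gs <- generate_stratum(n_cells, length(model_genes), spec_s,
                                 seed = derive_seed(sseed, 2L))
          full[, model_genes] <- as.matrix(gs$counts)
          truth_w <- gs$truth$weights
          # non-modeling genes: independent baseline counts
          set.seed(derive_seed(sseed, 3L))
          aux <- setdiff(seq_len(n_genes), model_genes)
          full[, aux] <- matrix(stats::rpois(n_cells * length(aux),
                                             rep(aux_lambda[aux], each = n_cells)),
                                nrow = n_cells)
        }
        if (is_null_ct[[ct]]) {
          # null strata already cover all genes; nothing more to fill
        }
        # QC contamination: inflate mito/artifact counts of a cell fraction
        contam <- integer(0)
        if (qc_contamination > 0) {
          set.seed(derive_seed(sseed, 4L))
          n_bad <- round(qc_contamination * n_cells)
          if (n_bad > 0) {
            contam <- sample(n_cells, n_bad)
            bad_genes <- which(is_mito | is_art)
            full[contam, bad_genes] <- full[contam, bad_genes] * inflate_factor +
              matrix(stats::rpois(length(contam) * length(bad_genes), 3),
                     nrow = length(contam))
          }
        }
        key <- paste(donor, tissue, ct, sep = "|")
        cid <- sprintf("%s|%s|%s|c%04d", donor, tissue, ct, seq_len(n_cells))
        counts_list[[key]] <- full
        cell_meta_list[[key]] <- data.frame(cell_id = cid, donor = donor,
                                            tissue = tissue, cell_type = ct,
                                            stringsAsFactors = FALSE)
        strata_truth[[key]] <- list(key = key, donor = donor, tissue = tissue,
                                    cell_type = ct, n_cells = n_cells,
                                    polytopal = !is_null_ct[[ct]],
                                    seed = sseed,
                                    contaminated_cells = cid[contam],
                                    weights = truth_w)
      }
    }
  }

  counts <- Matrix::Matrix(do.call(rbind, counts_list), sparse = TRUE)
  cell_meta <- do.call(rbind, cell_meta_list)
  rownames(cell_meta) <- NULL
  dimnames(counts) <- list(cell_meta$cell_id, gene_id)
  atlas <- expression_atlas(counts, cell_meta, gene_meta)
  marker_ids <- lapply(specs, function(sp) {
    if (is.null(sp)) return(NULL)
    lapply(sp$marker_genes, function(ix) gene_id[model_genes[ix]])
  })
  truth <- structure(list(strata = strata_truth,
                          cell_types = names(cell_types),
                          null_cell_types = names(cell_types)[is_null_ct],
                          markers = marker_ids,
                          specs = specs,
                          model_genes = gene_id[model_genes],
                          qc_contamination = qc_contamination,
                          seed = seed),
                     class = "atlas_truth")
  list(atlas = atlas, truth = truth)
}

#' Write an atlas to Matrix Market plus TSV metadata
#'
#' Writes `matrix.mtx` (1-based indices per the Matrix Market standard),
#' `cells.tsv`, `genes.tsv`, and optionally `truth.json` (per-stratum
#' polytopal flags, seeds and marker assignment; mixture weights are kept
#' only in the in-memory truth object).
#'
#' @param atlas an `expression_atlas`.
#' @param dir output directory (created if needed).
#' @param truth optional `atlas_truth` from [generate_atlas()].
#' @return `dir`, invisibly.
#' @export
write_atlas <- function(atlas, dir, truth = NULL) {
  stopifnot(inherits(atlas, "expression_atlas"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(atlas$counts, file.path(dir, "matrix.mtx"))
  utils::write.table(atlas$cell_meta, file.path(dir, "cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(atlas$gene_meta, file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(truth)) {
    tr <- unclass(truth)
    tr$strata <- lapply(tr$strata, function(s) s[setdiff(names(s), "weights")])
    tr$specs <- NULL
    jsonlite::write_json(tr, file.path(dir, "truth.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(dir)
}

#' Read an atlas written by [write_atlas()]
#'
#' @param dir directory containing `matrix.mtx`, `cells.tsv`, `genes.tsv`.
#' @return An `expression_atlas`.
#' @export
read_atlas <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  cells <- utils::read.delim(file.path(dir, "cells.tsv"), stringsAsFactors = FALSE)
  genes <- utils::read.delim(file.path(dir, "genes.tsv"), stringsAsFactors = FALSE)
  for (fl in c("is_protein_coding", "is_mitochondrial", "is_artifact"))
    genes[[fl]] <- as.logical(genes[[fl]])
  dimnames(counts) <- list(cells$cell_id, genes$gene_id)
  expression_atlas(counts, cells, genes)
}
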