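# S3 methods for the polytope_fit model object.

#' @exportS3Method base::print
print.polytope_fit <- function(x, ...) {
  cat("Polytope fit")
  if (!is.null(x$stratum_id)) cat(" [", x$stratum_id, "]", sep = "")
  cat(":", x$k, "vertices in", x$dimension, "PCs\n")
  cat(sprintf("  t-ratio statistic: %.4g   p = %.4g (%d shuffles)%s\n",
              x$t_ratio, x$p_value, x$n_shuffles,
              if (isTRUE(x$significant)) "  *" else ""))
  cat(sprintf("  explained variance at k: %.3f   cells inside: %.1f%%\n",
              unname(x$ev_curve[as.character(x$k)]), 100 * x$pct_inside))
  invisible(x)
}

#' @exportS3Method base::summary
summary.polytope_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.polytope_fit")
}

#' @exportS3Method base::print
print.summary.polytope_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nExplained-variance curve:\n")
  print(round(f$ev_curve, 4))
  cat("\nRecorded p-values (dimension sweep):\n")
  print(f$p_values, row.names = FALSE)
  cat(sprintf("\nExpansion factor: %.4f   SSE: %.4g\n", f$expansion, f$sse))
  if (!is.null(f$bootstrap)) {
    tr <- vapply(f$bootstrap$cov, function(m) sum(diag(m)), numeric(1))
    cat("Bootstrap vertex covariance traces:",
        paste(signif(tr, 3), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.polytope_fit <- function(object, expanded = FALSE, ...) {
  if (expanded) object$vertices_expanded else object$vertices
}

#' Predict convex mixture weights for new points
#'
#' Projects new points onto the fitted simplex and returns their convex
#' weights over the vertices (the inferred task mixtures).
#'
#' @param object a `polytope_fit`.
#' @param newdata n x d matrix in the fit's PC space; defaults to the
#'   fitting points.
#' @param ... unused.
#' @return n x k weight matrix (rows sum to 1).
#' @export
predict.polytope_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$weights)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$vertices))
    stop("newdata dimension mismatch")
  .simplex_weights_cpp(newdata, object$vertices)
}

#' @export
fitted.polytope_fit <- function(object, ...) {
  object$weights %*% object$vertices
}

#' @export
residuals.polytope_fit <- function(object, ...) {
  object$points - fitted(object)
}

#' Simulate points from a fitted polytope
#'
#' Draws cells as Dirichlet mixtures of the fitted vertices (flat
#' concentration `alpha`), the generative counterpart of the Pareto mixture
#' model in PC space.
#'
#' @param object a `polytope_fit`.
#' @param nsim number of datasets.
#' @param seed integer seed or `NULL`.
#' @param n points per dataset (default: as fitted).
#' @param alpha Dirichlet concentration (default 0.65).
#' @param ... unused.
#' @return A list of `nsim` matrices.
#' @export
simulate.polytope_fit <- function(object, nsim = 1, seed = NULL,
                                  n = nrow(object$points), alpha = 0.65, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i) {
    W <- rdirichlet_flat(n, object$k, alpha)
    W %*% object$vertices
  })
}

# covariance -> ellipse outline (2 PCs) at ~95% coverage
ellipse_outline <- function(mu, sigma, prob = 0.95, n = 60) {
  r <- sqrt(stats::qchisq(prob, df = 2))
  th <- seq(0, 2 * pi, length.out = n)
  circ <- cbind(cos(th), sin(th)) * r
  eig <- eigen(sigma[1:2, 1:2, drop = FALSE], symmetric = TRUE)
  shape <- eig$vectors %*% diag(sqrt(pmax(eig$values, 0)))
  sweep(circ %*% t(shape), 2, mu[1:2], `+`)
}

#' Plot a fitted polytope in the first two PCs
#'
#' Scatter of the cells with the fitted simplex outline and, when a
#' bootstrap is attached, the 95% confidence ellipses of vertex positions.
#'
#' @param x a `polytope_fit`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.polytope_fit <- function(x, ...) {
  pts <- x$points[, 1:2, drop = FALSE]
  graphics::plot(pts, pch = 16, cex = 0.4, col = "grey40",
                 xlab = "PC1", ylab = "PC2",
                 main = sprintf("%d-vertex polytope (p = %.3g)",
                                x$k, x$p_value), ...)
  V <- x$vertices[, 1:2, drop = FALSE]
  ord <- order(atan2(V[, 2] - mean(V[, 2]), V[, 1] - mean(V[, 1])))
  graphics::polygon(V[ord, 1], V[ord, 2], border = "red3", lwd = 2)
  graphics::points(V, pch = 17, col = "red3", cex = 1.2)
  if (!is.null(x$bootstrap)) {
    for (i in seq_len(x$k)) {
      el <- ellipse_outline(x$bootstrap$mean[i, ], x$bootstrap$cov[[i]])
      graphics::lines(el, col = "red3", lty = 2)
    }
  }
  invisible(x)
}

#' @importFrom stats qchisq simulate fitted residuals coef predict
NULL
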