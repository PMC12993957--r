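# Cell-type level significance: donor-majority rule, Storey pi0, exact
# Poisson-binomial false-positive probability, total-FDR acceptance.

#' Donor significance flags for one cell type
#'
#' A donor is flagged iff any of its tissue strata has any recorded p-value
#' below `alpha`; `m_d` counts ALL recorded p-values of that donor
#' (including the excess p-values from testing multiple dimensions), which
#' is deliberately conservative.
#'
#' @param pvals data frame with columns `donor`, `tissue`, `p`, one row per
#'   recorded p-value, restricted to one cell type.
#' @param alpha significance threshold (default 0.05).
#' @return List: `flags` (named logical per donor), `m_d` (named integer).
#' @export
donor_flags <- function(pvals, alpha = 0.05) {
  stopifnot(all(c("donor", "p") %in% names(pvals)))
  donors <- sort(unique(pvals$donor))
  flags <- vapply(donors, function(d) any(pvals$p[pvals$donor == d] < alpha),
                  logical(1))
  m_d <- vapply(donors, function(d) sum(pvals$donor == d), integer(1))
  list(flags = stats::setNames(flags, donors),
       m_d = stats::setNames(m_d, donors))
}

#' Storey estimate of the null proportion pi0
#'
#' `pi0 = #(p > lambda) / ((1 - lambda) m)` at `lambda = 0.5`, clipped to
#' `(0, 1]` (floor `1/m`). With fewer than 20 p-values the estimate is
#' unstable and 1 is returned (conservative) with a warning.
#'
#' @param pvalues numeric vector of p-values.
#' @param lambda tail threshold (default 0.5).
#' @return Estimated null proportion in `(0, 1]`.
#' @export
estimate_pi0 <- function(pvalues, lambda = 0.5) {
  m <- length(pvalues)
  if (m < 20) {
    warning("fewer than 20 p-values; returning pi0 = 1")
    return(1)
  }
  est <- sum(pvalues > lambda) / ((1 - lambda) * m)
  min(1, max(est, 1 / m))
}

# exact Poisson-binomial distribution by dynamic programming
poisson_binomial_pmf <- function(q) {
  pmf <- c(1, numeric(length(q)))
  for (qi in q) {
    pmf <- c(pmf * (1 - qi), 0) + c(0, pmf * qi)
    pmf <- pmf[seq_len(length(q) + 1)]
  }
  pmf
}

#' False-positive probability of a cell-type call
#'
#' Under the null, a donor with `m_d` recorded p-values is flagged with
#' probability `q_d = 1 - (1 - pi0 * alpha)^{m_d}` (the per-test null rate
#' `alpha` deflated by the empirical null proportion `pi0`). The cell-type
#' call requires a donor majority, so its false-positive probability is the
#' exact Poisson-binomial tail `P(#flagged >= ceiling(D / 2))`, computed by
#' dynamic programming.
#'
#' @param m_d integer vector, recorded p-values per donor (length `D`).
#' @param alpha per-test false-positive rate (default 0.05).
#' @param pi0 null proportion in `(0, 1]` (default 1).
#' @return Probability in `[0, 1]`.
#' @export
false_positive_probability <- function(m_d, alpha = 0.05, pi0 = 1) {
  D <- length(m_d)
  if (D < 1) stop("need at least one donor")
  rate <- pi0 * alpha
  if (rate < 0 || rate > 1) stop("pi0 * alpha must be in [0, 1]")
  q <- 1 - (1 - rate)^m_d
  pmf <- poisson_binomial_pmf(q)
  thr <- ceiling(D / 2)
  sum(pmf[(thr + 1):(D + 1)])
}

#' Accept cell types up to a total FDR cap
#'
#' Cell types passing the donor-majority rule are sorted by ascending
#' false-positive probability; the largest prefix whose mean (the total FDR
#' of the accepted set: expected false positives over accepted count) is
#' below `fdr_cap` is accepted.
#'
#' @param p_fp named numeric vector of per-cell-type false-positive
#'   probabilities.
#' @param fdr_cap total FDR cap (default 0.10).
#' @return List: `accepted` (names), `total_fdr`, `curve` (data frame of
#'   the FDR vs number retained, the acceptance CDF).
#' @export
accept_cell_types <- function(p_fp, fdr_cap = 0.10) {
  if (length(p_fp) == 0) {
    return(list(accepted = character(0), total_fdr = 0,
                curve = data.frame(n_retained = integer(0), fdr = numeric(0)),
                note = "no qualifying cell types"))
  }
  ord <- order(p_fp, names(p_fp))
  sorted <- p_fp[ord]
  cm <- cumsum(sorted) / seq_along(sorted)
  n_acc <- if (any(cm < fdr_cap)) max(which(cm < fdr_cap)) else 0L
  list(accepted = names(sorted)[seq_len(n_acc)],
       total_fdr = if (n_acc > 0) unname(cm[n_acc]) else 0,
       curve = data.frame(n_retained = seq_along(sorted), fdr = unname(cm)))
}

#' Aggregate stratum p-values to cell-type significance calls
#'
#' The full aggregation: per cell type, donor flags and p-value counts;
#' a cell type qualifies when at least 50% of its available donors are
#' flagged; pi0 is estimated once from all recorded p-values; qualifying
#' cell types get an exact false-positive probability and are accepted up
#' to a total FDR below `fdr_cap`.
#'
#' @param pvals data frame with columns `cell_type`, `donor`, `tissue`,
#'   `p` (one row per recorded p-value).
#' @param alpha per-stratum significance threshold (default 0.05).
#' @param fdr_cap total FDR cap (default 0.10).
#' @return List: `table` (per-cell-type data frame with donor counts,
#'   flags, `pi0`, `p_fp`, `qualified`, `accepted`, `total_fdr`), `pi0`,
#'   `accepted`, `total_fdr`, `curve`.
#' @export
aggregate_significance <- function(pvals, alpha = 0.05, fdr_cap = 0.10) {
  stopifnot(all(c("cell_type", "donor", "p") %in% names(pvals)))
  pi0 <- suppressWarnings(estimate_pi0(pvals$p))
  cts <- sort(unique(pvals$cell_type))
  rows <- lapply(cts, function(ct) {
    sub <- pvals[pvals$cell_type == ct, , drop = FALSE]
    df <- donor_flags(sub, alpha)
    D <- length(df$flags)
    qualified <- sum(df$flags) >= ceiling(D / 2)
    p_fp <- if (qualified) false_positive_probability(df$m_d, alpha, pi0) else NA_real_
    data.frame(cell_type = ct, donors_available = D,
               donors_flagged = sum(df$flags),
               m_total = sum(df$m_d), qualified = qualified, p_fp = p_fp,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  qual <- tab[tab$qualified, , drop = FALSE]
  acc <- accept_cell_types(stats::setNames(qual$p_fp, qual$cell_type), fdr_cap)
  tab$accepted <- tab$cell_type %in% acc$accepted
  tab$pi0 <- pi0
  list(table = tab, pi0 = pi0, accepted = acc$accepted,
       total_fdr = acc$total_fdr, curve = acc$curve)
}
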